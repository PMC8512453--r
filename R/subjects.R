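#' Generate a synthetic child subject profile
#'
#' Draws one subject from the cohort model: age from a normal distribution
#' with mean 9.7 y and SD 1.9 y truncated to [7, 13]; sex with equal
#' probability; height from an age-linked normal (about 138 cm at the mean
#' age, 6 cm per year of age); weight via BMI drawn near 16.3 kg/m^2.
#' Deterministic given `seed`.
#'
#' @param seed Non-negative integer seed; the same seed always returns the
#'   identical profile.
#' @return A list of class `subject_profile` with fields `subject_id`,
#'   `sex` (`"male"`/`"female"`), `age` (years), `height` (cm),
#'   `weight` (kg).
#' @export
#' @examples
#' s <- make_subject(1)
#' s$age
make_subject <- function(seed) {
  stop_if_not_scalar_number(seed, "seed", min = 0)
  with_seed(split_seed(seed, "subject"), {
    age <- rtrunc_norm(1, mean = 9.7, sd = 1.9, lo = 7, hi = 13)
    sex <- if (runif(1) < 0.5) "male" else "female"
    height <- max(100, 138.3 + 6 * (age - 9.7) + rnorm(1, 0, 5))
    bmi <- rtrunc_norm(1, mean = 16.3, sd = 2.4, lo = 12, hi = 30)
    weight <- bmi * (height / 100)^2
    structure(list(
      subject_id = paste0("S", format(seed, scientific = FALSE, trim = TRUE)),
      sex = sex, age = age, height = height, weight = weight
    ), class = "subject_profile")
  })
}

#' Generate a cohort of synthetic subjects
#'
#' @param n Number of subjects.
#' @param seed Global seed; each subject's seed is derived with
#'   [split_seed()] so cohorts of different sizes share leading members.
#' @return A list of `subject_profile` objects with unique ids.
#' @export
make_cohort <- function(n, seed = 1L) {
  stop_if_not_scalar_number(n, "n", min = 1)
  subjects <- lapply(seq_len(n), function(i) {
    s <- make_subject(split_seed(seed, paste0("cohort:", i)))
    s$subject_id <- sprintf("S%03d", i)
    s
  })
  subjects
}

# Truncated-normal draws by rejection; the truncation bounds here are only
# ~1.5-1.7 SD from the mean, so acceptance is high.
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 8, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# Mean of N(mean, sd) truncated to [lo, hi]; used as the Monte-Carlo oracle
# for the age generator.
trunc_norm_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject %s> %s, %.1f y, %.1f cm, %.1f kg\n",
              x$subject_id, x$sex, x$age, x$height, x$weight))
  invisible(x)
}

validate_subject <- function(subject) {
  stopifnot(is.list(subject),
            all(c("subject_id", "sex", "age", "height", "weight") %in%
                  names(subject)))
  if (!subject$sex %in% c("male", "female")) {
    stop("`sex` must be \"male\" or \"female\"", call. = FALSE)
  }
  if (subject$weight <= 0 || subject$height <= 0) {
    stop("height and weight must be positive", call. = FALSE)
  }
  if (subject$age < 3 || subject$age >= 18) {
    stop("age must be in [3, 18) (child/adolescent BMR bands)", call. = FALSE)
  }
  invisible(subject)
}
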