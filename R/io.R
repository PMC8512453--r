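#' Write and read breath-record tables
#'
#' Comma-separated UTF-8 text with mandatory header
#' `time_s,vo2_ml_min,vco2_ml_min`. The reader validates the schema and
#' strict time ordering, naming the first offending row on failure.
#'
#' @param series Breath series `data.frame`.
#' @param path File path.
#' @return `read_breath_table()` returns the validated series;
#'   `write_breath_table()` returns `path` invisibly.
#' @export
write_breath_table <- function(series, path) {
  stopifnot(all(c("time_s", "vo2_ml_min", "vco2_ml_min") %in% names(series)))
  write.csv(series[, c("time_s", "vo2_ml_min", "vco2_ml_min")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_breath_table
#' @export
read_breath_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path)
  need <- c("time_s", "vo2_ml_min", "vco2_ml_min")
  if (nrow(df) == 0) stop("breath table is empty: ", path, call. = FALSE)
  if (!all(need %in% names(df))) {
    stop("breath table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad) > 0) {
    stop(sprintf("breath times not strictly increasing at row %d",
                 bad[1] + 1L), call. = FALSE)
  }
  df
}

#' Write and read raw acceleration tables
#'
#' Comma-separated text with columns `time_s,x_g,y_g,z_g`, one row per
#' sample; the fixed sampling rate is declared in a leading header comment
#' (`# rate_hz: 30`). The reader checks the declared rate against the
#' median sample spacing (warning when they disagree by more than 2%) and
#' reports sampling gaps longer than 1.5 sample intervals as missing
#' spans.
#'
#' @param samples Sample `data.frame` (`time_s`, `x_g`, `y_g`, `z_g`).
#' @param path File path.
#' @param rate Sampling rate in Hz; defaults to the table's `rate_hz`
#'   attribute.
#' @return `read_accel_table()` returns `list(samples, rate, gaps)` where
#'   `gaps` is a `data.frame` of missing spans (`from_s`, `to_s`);
#'   `write_accel_table()` returns `path` invisibly.
#' @export
write_accel_table <- function(samples, path, rate = attr(samples, "rate_hz")) {
  stopifnot(all(c("time_s", "x_g", "y_g", "z_g") %in% names(samples)),
            !is.null(rate))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz: %g", rate), con)
  write.csv(samples[, c("time_s", "x_g", "y_g", "z_g")], con,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_accel_table
#' @export
read_accel_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  m <- regmatches(first, regexec("^#\\s*rate_hz:\\s*([0-9.]+)", first))[[1]]
  if (length(m) < 2) {
    stop("acceleration table must declare its rate in a '# rate_hz:' header",
         call. = FALSE)
  }
  rate <- as.numeric(m[2])
  df <- read.csv(path, comment.char = "#")
  need <- c("time_s", "x_g", "y_g", "z_g")
  if (!all(need %in% names(df))) {
    stop("acceleration table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(vapply(df[need], is.numeric, logical(1)))) {
    stop("acceleration table contains non-numeric cells", call. = FALSE)
  }
  dt <- diff(df$time_s)
  gaps <- data.frame(from_s = numeric(0), to_s = numeric(0))
  if (length(dt) > 0) {
    measured <- 1 / stats::median(dt)
    if (is.finite(measured) && abs(measured - rate) / rate > 0.02) {
      warning(sprintf(
        "declared rate %g Hz but measured spacing suggests %.3g Hz",
        rate, measured), call. = FALSE)
    }
    big <- which(dt > 1.5 / rate)
    if (length(big) > 0) {
      gaps <- data.frame(from_s = df$time_s[big], to_s = df$time_s[big + 1L])
    }
  }
  attr(df, "rate_hz") <- rate
  list(samples = df, rate = rate, gaps = gaps)
}

#' Write and read parent-reported sleep/non-wear logs
#'
#' Comma-separated text with columns `date` (ISO-8601), `start_hms`,
#' `end_hms` (`HH:MM:SS`, `24:00:00` allowed as end of day), and `kind`
#' (`sleep` or `nonwear`).
#'
#' @param log Log `data.frame`.
#' @param path File path.
#' @return `read_activity_log()` returns the validated log;
#'   `write_activity_log()` returns `path` invisibly.
#' @export
write_activity_log <- function(log, path) {
  stopifnot(all(c("date", "start_hms", "end_hms", "kind") %in% names(log)))
  out <- log
  out$date <- format(as.Date(log$date))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_activity_log
#' @export
read_activity_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, colClasses = "character")
  need <- c("date", "start_hms", "end_hms", "kind")
  if (!all(need %in% names(df))) {
    stop("log must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$kind %in% c("sleep", "nonwear"))) {
    stop("log kind must be 'sleep' or 'nonwear'", call. = FALSE)
  }
  s <- hms_to_seconds(df$start_hms)
  e <- hms_to_seconds(df$end_hms)
  if (any(e <= s)) {
    stop("log intervals must have end after start", call. = FALSE)
  }
  df$date <- as.Date(df$date)
  df
}
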