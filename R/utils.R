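#' Derive a stream-specific seed from a global seed
#'
#' One global integer seed drives all stochastic draws in the package.
#' Each simulation function derives its own sub-seed from the global seed
#' and a short string key (e.g. `"gas:S12"`), so modules can be re-run
#' independently without replaying the whole draw sequence.
#'
#' The key is hashed with a 31-ary polynomial rolling hash and combined
#' with the seed by a Lehmer-style multiply, everything reduced modulo
#' 2147483629 (a prime below 2^31) so results stay valid R integers.
#'
#' @param seed Non-negative integer global seed.
#' @param key Character scalar naming the stream.
#' @return An integer seed in `[0, 2147483628]`.
#' @export
#' @examples
#' split_seed(1, "gas:S1")
split_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed), seed >= 0)
  stopifnot(is.character(key), length(key) == 1L)
  m <- 2147483629
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% m
  as.integer((as.numeric(seed) %% m * 48271 + h) %% m)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  code
}

# Lognormal multiplicative noise factors with mean exactly 1 and the given
# coefficient of variation; cv = 0 returns 1s without touching the RNG.
mult_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

stop_if_not_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                      closed_min = TRUE, closed_max = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (closed_min) x >= min else x > min) &&
    (if (closed_max) x <= max else x < max)
  if (!ok) {
    stop(sprintf("`%s` must be a single finite number in %s%s, %s%s",
                 name, if (closed_min) "[" else "(", format(min),
                 format(max), if (closed_max) "]" else ")"), call. = FALSE)
  }
  invisible(x)
}
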