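# Internal helpers shared across modules.

#' Derive a stage seed from a root seed
#'
#' Deterministically maps a root seed plus a stage label to a new 31-bit seed,
#' so every stochastic stage of a pipeline run is independently reproducible
#' from one root seed.
#'
#' @param seed integer root seed.
#' @param stage character stage label.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  as.integer(((seed %% 1048573) * 4099 + h * 31 + 17) %% 2147483645 + 1)
}

# Wilson score interval for a binomial proportion; preferred over the Wald
# interval for the small per-field counts typical of single-molecule fields.
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  mid <- (p + z^2 / (2 * n)) / den
  hw <- (z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) / den
  c(lower = max(0, mid - hw), upper = min(1, mid + hw))
}

# Robust per-frame noise estimate from first differences: for additive white
# noise sd(diff) = sqrt(2) * sd, and the MAD ignores the sparse level changes.
robust_noise_sd <- function(x) {
  if (length(x) < 3L) return(0)
  stats::mad(diff(x)) / sqrt(2)
}

assert_prob <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(what, " must lie in [0, 1]", call. = FALSE)
  invisible(x)
}

assert_pos <- function(x, what, strict = TRUE) {
  ok <- is.numeric(x) & !is.na(x) & (if (strict) x > 0 else x >= 0)
  if (!all(ok)) stop(what, if (strict) " must be > 0" else " must be >= 0",
                     call. = FALSE)
  invisible(x)
}
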