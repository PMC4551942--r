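# Penalized least-squares change-point segmentation and photobleaching step
# counting.

#' Segment a trace into piecewise-constant levels
#'
#' Binary segmentation minimizing residual sum of squares: the best split of
#' a segment is accepted when it reduces the RSS by more than `penalty`, and
#' both halves are segmented recursively. The default penalty is
#' `3 * sigma^2 * log(n)` with `sigma` the robust (difference-MAD) noise.
#'
#' @param x numeric vector (a trace's intensities).
#' @param penalty RSS-reduction needed to accept a change point; `NULL` for
#'   the default above.
#' @param min_length minimum segment length in frames.
#' @return a data.frame with one row per segment: `start`, `end` (1-based,
#'   inclusive), `mean`.
#' @export
segment_trace <- function(x, penalty = NULL, min_length = 2L) {
  n <- length(x)
  stopifnot(n >= 2 * min_length)
  sigma <- robust_noise_sd(x)
  if (is.null(penalty))
    penalty <- 3 * max(sigma, 1e-6 * (diff(range(x)) + 1))^2 * log(n)
  s1 <- c(0, cumsum(x)); s2 <- c(0, cumsum(x^2))
  seg_cost <- function(a, b) {
    m <- b - a + 1
    (s2[b + 1] - s2[a]) - (s1[b + 1] - s1[a])^2 / m
  }
  bps <- integer(0)
  queue <- list(c(1L, n))
  while (length(queue)) {
    ab <- queue[[1]]; queue <- queue[-1]
    a <- ab[1]; b <- ab[2]
    if (b - a + 1 < 2 * min_length) next
    t <- (a + min_length - 1L):(b - min_length)
    m1 <- t - a + 1; m2 <- b - t
    c1 <- (s2[t + 1] - s2[a]) - (s1[t + 1] - s1[a])^2 / m1
    c2 <- (s2[b + 1] - s2[t + 1]) - (s1[b + 1] - s1[t + 1])^2 / m2
    gain <- seg_cost(a, b) - (c1 + c2)
    k <- which.max(gain)
    if (gain[k] > penalty) {
      bp <- t[k]
      bps <- c(bps, bp)
      queue <- c(queue, list(c(a, bp)), list(c(bp + 1L, b)))
    }
  }
  bps <- sort(bps)
  starts <- c(1L, bps + 1L); ends <- c(bps, n)
  data.frame(start = starts, end = ends,
             mean = vapply(seq_along(starts), function(i)
               mean(x[starts[i]:ends[i]]), numeric(1)))
}

#' Count photobleaching steps in an intensity trace
#'
#' Fits a piecewise-constant model by penalized change-point segmentation
#' ([segment_trace()]) and counts downward level changes larger than
#' `3 *` the robust noise. With `quantize = TRUE` (default) near-coincident
#' bleach events merged into one large drop are resolved by dividing each
#' drop by the smallest significant drop and rounding — appropriate when all
#' fluorophores share one unit brightness, as in a uniformly labeled sample.
#'
#' @param trace a `pife_trace` or numeric intensity vector (>= 10 frames).
#' @param penalty passed to [segment_trace()].
#' @param quantize resolve merged steps by drop-size quantization.
#' @return integer step count, with attributes `bleached` (final level is at
#'   background), `unbound` (whole trace at background) and `segments` (the
#'   fitted segmentation).
#' @examples
#' kin <- slide_kinetics(noise_sd = 40, bleach_lifetime = 8)
#' tr <- generate_pife_trace(kin, "multimer", seed = 3, n_fluorophores = 2)
#' count_bleach_steps(tr$trace)
#' @export
count_bleach_steps <- function(trace, penalty = NULL, quantize = TRUE) {
  x <- trace_values(trace)
  if (length(x) < 10) stop("trace too short to segment (need >= 10 frames)")
  sigma <- robust_noise_sd(x)
  thr <- 3 * max(sigma, 1e-9 + 1e-6 * max(abs(x)))
  seg <- segment_trace(x, penalty = penalty)
  seg <- drop_transition_segments(seg)
  m <- seg$mean
  unbound <- all(abs(m) < thr) && max(abs(x)) < 2 * thr
  drops <- -diff(m)
  drops <- drops[drops > thr]
  count <- if (length(drops) == 0) 0L
  else if (quantize) {
    unit <- min(drops)
    as.integer(sum(pmax(1, round(drops / unit))))
  } else length(drops)
  bleached <- abs(m[length(m)]) < thr && !unbound
  structure(as.integer(count), bleached = bleached, unbound = unbound,
            segments = seg)
}

# A level change that falls inside a camera frame leaves one frame at an
# intermediate value, which the segmentation may isolate as a tiny segment
# between its neighbours. Such monotone "staircase" segments of <= max_len
# frames are instrument artifacts, not levels; drop them so the change
# counts as a single step.
drop_transition_segments <- function(seg, max_len = 2L) {
  repeat {
    n <- nrow(seg)
    if (n < 3) return(seg)
    len <- seg$end - seg$start + 1
    mid <- 2:(n - 1)
    between <- (seg$mean[mid] - seg$mean[mid - 1]) *
      (seg$mean[mid + 1] - seg$mean[mid]) > 0
    kill <- mid[between & len[mid] <= max_len]
    if (length(kill) == 0) return(seg)
    k <- kill[1]
    seg$end[k - 1] <- seg$end[k]          # absorb leftward; means untouched
    seg <- seg[-k, , drop = FALSE]
  }
}

trace_values <- function(trace) {
  if (inherits(trace, "pife_trace")) trace$intensity
  else if (is.numeric(trace)) as.numeric(trace)
  else stop("expected a pife_trace or a numeric vector")
}

trace_exposure <- function(trace, default = 0.030) {
  if (inherits(trace, "pife_trace") && is.finite(trace$exposure))
    trace$exposure else default
}
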