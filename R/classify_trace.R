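# Sliding/static classification of PIFE traces, peak extraction, and
# dwell-time / sliding-duration summaries.

# Deterministic 2-level fit: k-means on intensities with centers seeded at
# the 25% / 75% quantiles (no RNG involved).
fit_two_levels <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  if (diff(q) <= 0)
    return(list(lo = mean(x), hi = mean(x), gap = 0,
                assign = rep(1L, length(x))))
  km <- suppressWarnings(stats::kmeans(x, centers = matrix(q), iter.max = 50))
  lo <- min(km$centers); hi <- max(km$centers)
  assign_hi <- as.integer(km$cluster == which.max(km$centers))
  list(lo = lo, hi = hi, gap = hi - lo, assign = assign_hi)
}

# First frame of the trailing background run (background = segment mean
# within 3 robust sigma of zero); length(x) + 1 when the trace never
# bleaches. Traces are background-subtracted, so "background" is level 0.
bleach_start_index <- function(x, seg = NULL) {
  sigma <- robust_noise_sd(x)
  thr <- 3 * max(sigma, 1e-9 + 1e-6 * max(abs(x)))
  # no frame ever near background => never bleached; skip the segmentation
  if (is.null(seg) && stats::quantile(x, 0.01) > 2 * thr)
    return(length(x) + 1L)
  if (is.null(seg)) seg <- segment_trace(x)
  bg <- abs(seg$mean) < thr
  if (!bg[length(bg)]) return(length(x) + 1L)
  i <- length(bg)
  while (i > 1 && bg[i - 1]) i <- i - 1
  seg$start[i]
}

# Collapse level-assignment runs shorter than min_run into their
# neighbours, so single-frame noise excursions do not count as crossings.
collapse_short_runs <- function(assign, min_run = 2L) {
  repeat {
    r <- rle(assign)
    if (length(r$lengths) <= 1 || all(r$lengths >= min_run)) break
    k <- which.min(r$lengths)
    r$values[k] <- if (k > 1) r$values[k - 1] else r$values[k + 1]
    assign <- inverse.rle(r)
  }
  assign
}

#' Classify a PIFE trace as sliding, static, or rejected
#'
#' The trace is truncated at the first photobleach (trailing background run
#' of its change-point segmentation). The pre-bleach segment is called
#' \emph{sliding} when a two-level fit finds levels whose ratio lies in
#' `[ratio_min, ratio_max]` (the PIFE enhancement band), the level gap is
#' resolvable above noise, and the trace makes at least `min_transitions`
#' full crossings between the levels; \emph{static} when it sits at one
#' stable level with coefficient of variation below `cv_max`; otherwise
#' \emph{rejected}. Pre-bleach segments shorter than `min_pre_bleach`
#' seconds are rejected as insufficient data.
#'
#' @param trace a `pife_trace` or numeric intensity vector.
#' @param min_transitions minimum number of full level crossings for
#'   sliding.
#' @param ratio_min,ratio_max accepted high/low level ratio band.
#' @param cv_max maximum coefficient of variation for a static call.
#' @param min_pre_bleach minimum usable pre-bleach span, seconds.
#' @param static_min_span minimum pre-bleach span, seconds, before a trace
#'   may be called static. A static call asserts the *absence* of level
#'   crossings, which is only evidenced by watching the molecule for several
#'   typical fluctuation periods (second-scale on this platform); shorter
#'   quiet traces are rejected as ambiguous rather than counted as static,
#'   which would otherwise bias sliding fractions downward for molecules
#'   that photobleach early.
#' @param min_run minimum run length (frames) for a level visit to count.
#' @return label character (`"sliding"`, `"static"` or `"rejected"`), with
#'   attributes `levels` (lo, hi), `ratio`, `transitions`, `cv`,
#'   `bleach_index` and `reason` (for rejections).
#' @examples
#' tr <- generate_pife_trace(slide_kinetics(), "sliding", seed = 11)
#' classify_trace(tr$trace)
#' @export
classify_trace <- function(trace, min_transitions = 3L, ratio_min = 1.5,
                           ratio_max = 3.5, cv_max = 0.15,
                           min_pre_bleach = 1, static_min_span = 8,
                           min_run = 2L) {
  x <- trace_values(trace)
  dt <- trace_exposure(trace)
  seg <- segment_trace(x)
  b <- bleach_start_index(x, seg)
  pre <- x[seq_len(b - 1L)]
  res <- function(label, reason = NA_character_, lv = NULL, ratio = NA_real_,
                  transitions = NA_integer_, cv = NA_real_) {
    structure(label, levels = lv, ratio = ratio, transitions = transitions,
              cv = cv, bleach_index = b, reason = reason)
  }
  if (length(pre) * dt < min_pre_bleach)
    return(res("rejected", "insufficient pre-bleach data"))
  sigma <- robust_noise_sd(pre)
  lv <- fit_two_levels(pre)
  ratio <- if (lv$lo > 0) lv$hi / lv$lo else Inf
  transitions <- NA_integer_
  if (lv$gap > 4 * max(sigma, 1e-12) && ratio >= ratio_min &&
      ratio <= ratio_max) {
    a <- collapse_short_runs(lv$assign, min_run)
    transitions <- length(rle(a)$lengths) - 1L
    if (transitions >= min_transitions)
      return(res("sliding", lv = c(lo = lv$lo, hi = lv$hi), ratio = ratio,
                 transitions = transitions))
  }
  mu <- mean(pre)
  cv <- if (mu > 0) stats::sd(pre) / mu else Inf
  if (cv < cv_max) {
    if (length(pre) * dt < static_min_span)
      return(res("rejected", "too short to rule out sliding",
                 lv = c(lo = lv$lo, hi = lv$hi), ratio = ratio,
                 transitions = transitions, cv = cv))
    return(res("static", lv = c(lo = lv$lo, hi = lv$hi), ratio = ratio,
               transitions = transitions, cv = cv))
  }
  res("rejected", "neither two-level fluctuation nor stable level",
      lv = c(lo = lv$lo, hi = lv$hi), ratio = ratio,
      transitions = transitions, cv = cv)
}

# Moving average with edge shrinkage (partial windows at the ends).
moving_avg <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  cs <- c(0, cumsum(x))
  half <- (w - 1) %/% 2
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + (w - 1 - half), n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Extract peak times and peak-to-peak dwell intervals from a sliding trace
#'
#' After moving-average smoothing, the two intensity levels are fitted and
#' every contiguous episode above their midpoint is taken as one enhancement
#' peak (an episode's maximum necessarily exceeds the lower level by at
#' least half the level gap, the prominence floor); the peak time is the
#' episode's maximum. Dwell times \eqn{\delta t} are successive peak-time
#' differences; the trailing interval from the last peak to bleach or
#' acquisition end is returned separately as censored.
#'
#' @param trace a `pife_trace` or numeric vector (classified sliding).
#' @param smooth_window moving-average window in frames.
#' @return list of class `peak_intervals`: `peak_times` (s), `intervals`
#'   (uncensored dwell times, s), `censored_interval` (s, `NA` if no peak),
#'   `n_peaks`.
#' @export
peak_intervals <- function(trace, smooth_window = 5L) {
  x <- trace_values(trace)
  dt <- trace_exposure(trace)
  b <- bleach_start_index(x)
  pre <- x[seq_len(b - 1L)]
  out <- structure(list(peak_times = numeric(0), intervals = numeric(0),
                        censored_interval = NA_real_, n_peaks = 0L),
                   class = "peak_intervals")
  if (length(pre) < max(4, smooth_window)) return(out)
  sm <- moving_avg(pre, smooth_window)
  lv <- fit_two_levels(sm)
  sigma_sm <- robust_noise_sd(pre) / sqrt(max(1, smooth_window))
  if (lv$gap <= 4 * max(sigma_sm, 1e-12)) return(out)  # no two levels
  mid <- (lv$lo + lv$hi) / 2
  above <- sm > mid
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  peak_idx <- integer(0)
  for (k in which(r$values)) {
    seg <- starts[k]:ends[k]
    peak_idx <- c(peak_idx, seg[which.max(sm[seg])])
  }
  if (length(peak_idx) == 0) return(out)
  peak_times <- (peak_idx - 1) * dt
  t_stop <- (b - 1L) * dt            # bleach or acquisition end
  out$peak_times <- peak_times
  out$intervals <- diff(peak_times)
  out$censored_interval <- t_stop - peak_times[length(peak_times)]
  out$n_peaks <- length(peak_idx)
  out
}

#' Full per-trace analysis
#'
#' Combines classification, photobleach-step counting, peak extraction and
#' sliding-segment bookkeeping into one verdict.
#'
#' The sliding segment runs from the trace start (molecules are already
#' bound and sliding when acquisition begins) to the last level crossing; it
#' is flagged censored when bleaching or the end of acquisition cuts it off,
#' i.e. when the trace is still fluctuating within `censor_gap` multiples of
#' its median crossing interval of the stop time.
#'
#' @param trace a `pife_trace` or numeric vector.
#' @param smooth_window passed to [peak_intervals()].
#' @param censor_gap multiple of the median inter-crossing interval used to
#'   decide whether sliding was still ongoing at the stop time.
#' @param ... passed to [classify_trace()].
#' @return list of class `trace_verdict`: `label`, `bleach_steps`,
#'   `peak_times`, `dwell_intervals`, `censored_interval`,
#'   `sliding_segments` (data.frame `start`, `end`, `censored`), `bleach_time`.
#' @export
analyze_trace <- function(trace, smooth_window = 5L, censor_gap = 2, ...) {
  x <- trace_values(trace)
  dt <- trace_exposure(trace)
  label <- classify_trace(trace, ...)
  b <- attr(label, "bleach_index")
  t_stop <- (b - 1L) * dt
  bleached <- b <= length(x)
  verdict <- list(label = as.character(label),
                  bleach_steps = 0L,
                  peak_times = numeric(0), dwell_intervals = numeric(0),
                  censored_interval = NA_real_,
                  sliding_segments = data.frame(start = numeric(0),
                                                end = numeric(0),
                                                censored = logical(0)),
                  bleach_time = if (bleached) t_stop else NA_real_,
                  classifier = attributes(label))
  if (verdict$label == "sliding") {
    verdict$bleach_steps <- as.integer(bleached)
    pk <- peak_intervals(trace, smooth_window)
    verdict$peak_times <- pk$peak_times
    verdict$dwell_intervals <- pk$intervals
    verdict$censored_interval <- pk$censored_interval
    # crossing times from the collapsed two-level assignment
    pre <- x[seq_len(b - 1L)]
    lv <- fit_two_levels(pre)
    a <- collapse_short_runs(lv$assign, 2L)
    cross_idx <- cumsum(rle(a)$lengths)
    cross_idx <- cross_idx[-length(cross_idx)]
    cross_t <- cross_idx * dt
    if (length(cross_t) >= 1) {
      gap_ref <- if (length(cross_t) >= 3) censor_gap * stats::median(diff(cross_t))
                 else 1
      last <- cross_t[length(cross_t)]
      censored <- (t_stop - last) < max(gap_ref, 2 * dt)
      verdict$sliding_segments <- data.frame(
        start = 0, end = if (censored) t_stop else last, censored = censored)
    }
  } else if (verdict$label == "static") {
    verdict$bleach_steps <- count_bleach_steps(x)
  } else if (max(abs(x)) > 0) {
    verdict$bleach_steps <- tryCatch(count_bleach_steps(x),
                                     error = function(e) 0L)
  }
  structure(verdict, class = "trace_verdict")
}

#' Mean sliding duration with censoring correction
#'
#' Naive mean of observed sliding-segment durations, plus a Kaplan-Meier
#' mean restricted to the acquisition window using the per-segment censoring
#' flags — the correction for photobleaching and finite acquisition that a
#' naive average lacks. Both the per-trace total of sliding episodes and the
#' longest single episode are summarized.
#'
#' @param verdicts a list of `trace_verdict` objects (or a data.frame with
#'   columns `duration` and `censored`).
#' @param restrict restriction time for the Kaplan-Meier mean, seconds
#'   (default 60, a typical acquisition limit).
#' @return list of class `sliding_durations`: `naive_mean`,
#'   `km_restricted_mean`, `naive_mean_longest`, `n`, `n_censored`,
#'   `durations`, `censored`, `dominant_censoring` (`TRUE` when every
#'   segment is censored; the naive mean is then reported with a warning).
#' @export
sliding_durations <- function(verdicts, restrict = 60) {
  if (is.data.frame(verdicts)) {
    durations <- verdicts$duration
    longest <- verdicts$duration
    censored <- verdicts$censored
  } else {
    segs <- lapply(verdicts, function(v) {
      if (!inherits(v, "trace_verdict") || v$label != "sliding") return(NULL)
      v$sliding_segments
    })
    segs <- segs[!vapply(segs, is.null, logical(1))]
    segs <- segs[vapply(segs, nrow, integer(1)) > 0]
    if (length(segs) == 0) stop("no sliding segments to summarize")
    durations <- vapply(segs, function(s) sum(s$end - s$start), numeric(1))
    longest <- vapply(segs, function(s) max(s$end - s$start), numeric(1))
    censored <- vapply(segs, function(s) any(s$censored), logical(1))
  }
  naive <- mean(durations)
  all_censored <- all(censored)
  if (all_censored)
    warning("all sliding segments censored; naive mean reported")
  km_mean <- NA_real_
  if (!all_censored) {
    fit <- survival::survfit(survival::Surv(durations, !censored) ~ 1)
    tab <- summary(fit, rmean = restrict)$table
    km_mean <- unname(tab[grep("rmean", names(tab))[1]])
  }
  structure(list(naive_mean = naive, km_restricted_mean = km_mean,
                 naive_mean_longest = mean(longest),
                 n = length(durations), n_censored = sum(censored),
                 durations = durations, censored = censored,
                 dominant_censoring = all_censored),
            class = "sliding_durations")
}

#' Dwell-time means across duplex lengths with monotonicity test
#'
#' Summarizes peak-to-peak dwell times per duplex length (mean with a seeded
#' bootstrap CI) and tests for the length dependence expected of genuine 1D
#' sliding — longer duplexes take longer per sliding round — by one-sided
#' Mann-Whitney tests between adjacent lengths.
#'
#' @param dwell_sets named list of numeric dwell-time vectors; names are
#'   duplex lengths in bp. Empty classes are dropped with a warning; at
#'   least two non-empty classes are required.
#' @param n_boot bootstrap resamples for the CI.
#' @param seed seed for the bootstrap.
#' @param alpha significance level of the adjacent-pair tests.
#' @return list of class `dwell_vs_length`: `summary` (data.frame
#'   `length_bp`, `n`, `mean`, `ci_lower`, `ci_upper`), `pairwise`
#'   (data.frame of adjacent one-sided tests), `monotone_increasing`.
#' @export
dwell_vs_length <- function(dwell_sets, n_boot = 1000L, seed = 1L,
                            alpha = 0.05) {
  stopifnot(is.list(dwell_sets), !is.null(names(dwell_sets)))
  sizes <- vapply(dwell_sets, length, integer(1))
  if (any(sizes == 0)) {
    warning("dropping empty dwell class(es): ",
            paste(names(dwell_sets)[sizes == 0], collapse = ", "))
    dwell_sets <- dwell_sets[sizes > 0]
  }
  if (length(dwell_sets) < 2)
    stop("need dwell times for at least 2 duplex lengths")
  len <- as.numeric(names(dwell_sets))
  if (any(is.na(len))) stop("dwell_sets names must be duplex lengths in bp")
  ord <- order(len)
  dwell_sets <- dwell_sets[ord]; len <- len[ord]
  set.seed(seed)
  summ <- do.call(rbind, lapply(seq_along(dwell_sets), function(i) {
    x <- dwell_sets[[i]]
    bm <- replicate(n_boot, mean(sample(x, replace = TRUE)))
    data.frame(length_bp = len[i], n = length(x), mean = mean(x),
               ci_lower = unname(stats::quantile(bm, 0.025)),
               ci_upper = unname(stats::quantile(bm, 0.975)))
  }))
  pw <- do.call(rbind, lapply(seq_len(length(dwell_sets) - 1), function(i) {
    p <- stats::wilcox.test(dwell_sets[[i]], dwell_sets[[i + 1]],
                            alternative = "less", exact = FALSE)$p.value
    data.frame(shorter_bp = len[i], longer_bp = len[i + 1], p_value = p,
               significant = p < alpha)
  }))
  structure(list(summary = summ, pairwise = pw,
                 monotone_increasing = all(pw$significant)),
            class = "dwell_vs_length")
}
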