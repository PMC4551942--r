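#' Simulate a reflecting nearest-neighbour random walk
#'
#' Continuous-time random walk on lattice positions `1..L` with hop rate
#' `rate` in each direction and reflecting ends, simulated exactly by
#' uniformization (a Poisson(`2 * rate`) event clock; a step off the lattice
#' is a self-loop).
#'
#' @param L lattice length (sites).
#' @param rate hop rate per direction, events/s.
#' @param t_end simulated time span, seconds.
#' @param pos0 initial site in `1..L`.
#' @return list with `times` (event times, s), `pos` (site after each event)
#'   and `pos0`.
#' @keywords internal
simulate_reflecting_walk <- function(L, rate, t_end, pos0) {
  stopifnot(L >= 2, rate > 0, t_end >= 0, pos0 >= 1, pos0 <= L)
  n_ev <- stats::rpois(1, 2 * rate * t_end)
  if (n_ev == 0) return(list(times = numeric(0), pos = integer(0), pos0 = pos0))
  times <- sort(stats::runif(n_ev, 0, t_end))
  steps <- sample(c(-1L, 1L), n_ev, replace = TRUE)
  pos <- integer(n_ev)
  p <- as.integer(pos0)
  for (i in seq_len(n_ev)) {
    q <- p + steps[i]
    if (q >= 1L && q <= L) p <- q
    pos[i] <- p
  }
  list(times = times, pos = pos, pos0 = as.integer(pos0))
}

# Integrate a piecewise-constant signal over uniform camera frames.
# breaks[i] starts the piece with value vals[i]; the signal ends at t_end.
# Returns per-frame time-averaged values (length n_frames).
integrate_piecewise <- function(breaks, vals, t_end, n_frames, dt) {
  out <- numeric(n_frames)
  ends <- c(breaks[-1], t_end)
  for (i in seq_along(breaks)) {
    a <- breaks[i]; b <- min(ends[i], t_end)
    if (b <= a || vals[i] == 0) next
    i0 <- max(1L, floor(a / dt + 1e-12) + 1L)
    i1 <- min(n_frames, ceiling(b / dt - 1e-12))
    if (i1 < i0) next
    j <- i0:i1
    ov <- pmin(b, j * dt) - pmax(a, (j - 1) * dt)
    out[j] <- out[j] + vals[i] * ov
  }
  out / dt
}

#' Generate a single synthetic smPIFE intensity trace
#'
#' Emulates the trace phenotypes seen on a PIFE platform where the RNA is
#' dye-labeled and the protein is surface-anchored:
#' \describe{
#'   \item{`sliding`}{the duplex register performs a reflecting random walk
#'     (see [simulate_reflecting_walk()]); the dye emits
#'     `enhancement * baseline_intensity` while the register lies within the
#'     PIFE proximity window (`pife_window_bp` sites from the dye-proximal
#'     end) and `baseline_intensity` otherwise, producing the two-level
#'     fluctuation characteristic of 1D sliding.}
#'   \item{`static`}{constant enhanced level until photobleaching.}
#'   \item{`multimer`}{`n_fluorophores` superposed static dyes with
#'     independent bleach times, i.e. multi-step photobleaching.}
#'   \item{`unbound`}{background only.}
#' }
#' All traces are background-subtracted counts with additive Gaussian read
#' noise; photobleaching times are exponential with mean `bleach_lifetime`.
#' By default each frame integrates the levels occupied during the exposure.
#'
#' @param kin a [slide_kinetics()] object.
#' @param kind one of `"sliding"`, `"static"`, `"multimer"`, `"unbound"`.
#' @param seed integer seed (bit-reproducible output).
#' @param n_fluorophores number of dyes for `kind = "multimer"` (>= 2).
#' @param trace_id identifier stored with the trace.
#' @return list with `trace` (class `pife_trace`: `time`, `intensity`,
#'   `trace_id`, `exposure`) and `truth` (class `trace_truth`: `kind`,
#'   `state_path` — register site at each frame start up to the first bleach,
#'   sliding only —, `bleach_times`, `true_peak_times` — entry times into the
#'   proximity window —, and `slide_end`).
#' @examples
#' kin <- slide_kinetics(noise_sd = 0, bleach_lifetime = Inf, acquisition = 5)
#' tr <- generate_pife_trace(kin, "static", seed = 7)
#' unique(tr$trace$intensity)  # constant enhanced level
#' @export
generate_pife_trace <- function(kin, kind = c("sliding", "static", "multimer",
                                              "unbound"),
                                seed, n_fluorophores = 2L, trace_id = "trace") {
  stopifnot(inherits(kin, "slide_kinetics"))
  kind <- match.arg(kind)
  set.seed(seed)
  dt <- kin$exposure
  n_frames <- floor(kin$acquisition / dt + 1e-9)
  t_end <- n_frames * dt
  I0 <- kin$baseline_intensity
  Ihi <- I0 * kin$enhancement
  rbleach <- function(k = 1) if (is.finite(kin$bleach_lifetime))
    stats::rexp(k, 1 / kin$bleach_lifetime) else rep(Inf, k)

  truth <- list(kind = kind, state_path = integer(0),
                bleach_times = numeric(0), true_peak_times = numeric(0),
                slide_end = NA_real_)

  if (kind == "unbound") {
    breaks <- 0; vals <- 0
  } else if (kind == "static") {
    tb <- rbleach()
    truth$bleach_times <- tb
    breaks <- c(0, min(tb, t_end)); vals <- c(Ihi, 0)
  } else if (kind == "multimer") {
    if (n_fluorophores < 2) stop("a multimer needs n_fluorophores >= 2")
    tb <- sort(rbleach(n_fluorophores))
    truth$bleach_times <- tb
    breaks <- c(0, pmin(tb, t_end))
    vals <- I0 * (n_fluorophores:0)
  } else { # sliding
    tb <- rbleach()
    t_slide <- if (is.finite(kin$slide_lifetime))
      stats::rexp(1, 1 / kin$slide_lifetime) else Inf
    truth$bleach_times <- tb
    truth$slide_end <- t_slide
    L <- kin$duplex_length; w <- kin$pife_window_bp
    t_walk <- min(t_end, tb, t_slide)
    pos0 <- sample.int(L, 1)  # stationary law of the reflecting walk: uniform
    walk <- simulate_reflecting_walk(L, kin$hop_rate, t_walk, pos0)
    enh <- c(walk$pos0, walk$pos) <= w
    tt <- c(0, walk$times)
    keep <- c(TRUE, diff(enh) != 0)         # level-change breakpoints
    breaks <- tt[keep]; levels <- ifelse(enh[keep], Ihi, I0)
    truth$true_peak_times <- tt[keep][c(enh[keep][1], diff(enh[keep]) == 1)]
    # frozen level after the sliding episode ends, then bleach, then dark
    vals <- levels
    if (t_slide < min(tb, t_end)) {
      frozen <- levels[length(levels)]
      breaks <- c(breaks, t_slide); vals <- c(vals, frozen)
    }
    if (tb < t_end) { breaks <- c(breaks, tb); vals <- c(vals, 0) }
    # register site at each frame start, up to the first bleach
    n_alive <- min(n_frames, ceiling(min(tb, t_end) / dt))
    fstarts <- (seq_len(n_alive) - 1) * dt
    idx <- findInterval(pmin(fstarts, t_walk), c(0, walk$times))
    truth$state_path <- c(walk$pos0, walk$pos)[idx]
  }

  intensity <- if (kin$frame_integration)
    integrate_piecewise(breaks, vals, t_end, n_frames, dt)
  else {
    fstarts <- (seq_len(n_frames) - 1) * dt
    vals[findInterval(fstarts, breaks)]
  }
  if (kin$noise_sd > 0)
    intensity <- intensity + stats::rnorm(n_frames, 0, kin$noise_sd)

  trace <- structure(list(time = (seq_len(n_frames) - 1) * dt,
                          intensity = intensity, trace_id = trace_id,
                          exposure = dt), class = "pife_trace")
  list(trace = trace, truth = structure(truth, class = "trace_truth"))
}

#' @export
print.pife_trace <- function(x, ...) {
  cat(sprintf("pife_trace '%s': %d frames at %g s (%.1f s)\n", x$trace_id,
              length(x$intensity), x$exposure,
              length(x$intensity) * x$exposure))
  invisible(x)
}

#' Generate a population of smPIFE traces from a mixture of phenotypes
#'
#' Draws `n` traces i.i.d. from a labeled mixture of trace kinds; each trace
#' gets its own derived seed so any one trace is independently reproducible.
#'
#' @param mixture named numeric vector of non-negative weights summing to 1;
#'   names from `sliding`, `static`, `multimer`, `unbound`.
#' @param n number of traces (> 0).
#' @param kin a [slide_kinetics()] object.
#' @param seed integer root seed.
#' @param n_fluorophores dye count used for multimer traces.
#' @return an object of class `trace_set`: `traces` (list of `pife_trace`),
#'   `truth` (list of `trace_truth`) and `labels` (character).
#' @export
generate_trace_population <- function(mixture, n, kin, seed,
                                      n_fluorophores = 2L) {
  stopifnot(inherits(kin, "slide_kinetics"))
  if (!is.numeric(mixture) || is.null(names(mixture)))
    stop("mixture must be a named numeric vector of weights")
  if (!all(names(mixture) %in% c("sliding", "static", "multimer", "unbound")))
    stop("unknown trace kind in mixture")
  if (any(mixture < 0) || abs(sum(mixture) - 1) > 1e-8)
    stop("mixture weights must be non-negative and sum to 1")
  if (n <= 0 || n != round(n)) stop("n must be a positive integer")
  set.seed(seed)
  labels <- sample(names(mixture), n, replace = TRUE, prob = mixture)
  seeds <- sample.int(2147483646L, n)
  out <- vector("list", n); truth <- vector("list", n)
  for (i in seq_len(n)) {
    g <- generate_pife_trace(kin, labels[i], seed = seeds[i],
                             n_fluorophores = n_fluorophores,
                             trace_id = sprintf("trace_%04d", i))
    out[[i]] <- g$trace; truth[[i]] <- g$truth
  }
  structure(list(traces = out, truth = truth, labels = labels),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("trace_set: %d traces (%s)\n", length(x$traces),
              paste(sprintf("%s=%d", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = ", ")))
  invisible(x)
}
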