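#' Exact quantities of the reflecting-walk sliding model
#'
#' Linear-algebra solutions for the continuous-time nearest-neighbour random
#' walk on `1..L` with hop rate `rate` per direction and reflecting ends —
#' the generative model behind sliding PIFE traces. These are computed from
#' the chain's generator matrix, independently of the stochastic simulation,
#' and serve as analytic references for dwell-time and occupancy statistics.
#'
#' `walk_stationary()` returns the stationary distribution (uniform for this
#' chain). `walk_window_occupancy()` is the stationary probability that the
#' register lies in the PIFE proximity window (sites `1..window`), i.e. the
#' long-run fraction of time the trace spends at the enhanced level.
#' `walk_mean_return()` is the mean time between successive entries into the
#' window — the expected peak-to-peak dwell time \eqn{\delta t} — computed as
#' (mean exit time of the window from the entry site) + (mean first-passage
#' time back to the window), each via a first-step linear solve.
#'
#' @param L lattice length (>= 2).
#' @param window proximity window size in sites (`1 <= window < L`).
#' @param rate hop rate per direction, events/s.
#' @return `walk_stationary`: numeric length `L`; `walk_window_occupancy`:
#'   scalar probability; `walk_mean_return`: scalar seconds.
#' @examples
#' walk_window_occupancy(40, 14)     # 14/40
#' walk_mean_return(10, 1, 20)       # L / rate = 0.5 s
#' @export
walk_stationary <- function(L) {
  stopifnot(L >= 2)
  Q <- walk_generator(L, 1)
  # solve pi Q = 0 with sum(pi) = 1
  A <- rbind(t(Q), rep(1, L))
  b <- c(rep(0, L), 1)
  pi <- qr.solve(A, b)
  pi / sum(pi)
}

#' @rdname walk_stationary
#' @export
walk_window_occupancy <- function(L, window) {
  stopifnot(window >= 1, window < L)
  sum(walk_stationary(L)[seq_len(window)])
}

#' @rdname walk_stationary
#' @export
walk_mean_return <- function(L, window, rate) {
  stopifnot(L >= 2, window >= 1, window < L, rate > 0)
  Q <- walk_generator(L, rate)
  inside <- seq_len(window); outside <- setdiff(seq_len(L), inside)
  # mean exit time of the window, started at the entry site (= `window`,
  # reached from `window + 1`): absorb on `outside`
  h_exit <- solve(Q[inside, inside, drop = FALSE], rep(-1, length(inside)))
  # mean first-passage time back into the window from `window + 1`
  h_ret <- solve(Q[outside, outside, drop = FALSE], rep(-1, length(outside)))
  unname(h_exit[window] + h_ret[1])
}

walk_generator <- function(L, rate) {
  Q <- matrix(0, L, L)
  for (i in seq_len(L)) {
    if (i > 1) Q[i, i - 1] <- rate
    if (i < L) Q[i, i + 1] <- rate
    Q[i, i] <- -sum(Q[i, ])
  }
  Q
}
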