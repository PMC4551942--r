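#' Colocalize spots between two channels
#'
#' Greedy nearest-neighbour matching: after correcting channel B positions by
#' the known inter-channel registration `offset`, candidate pairs within
#' `radius_px` are accepted in order of increasing distance (ties broken by
#' lower spot index in A, then in B); each spot is matched at most once.
#'
#' @param spots_a,spots_b `spot_set` data.frames (or any data.frame with
#'   columns `x` and `y`, in pixels).
#' @param radius_px matching radius in pixels (> 0).
#' @param offset numeric length-2, (x, y) shift of channel B relative to
#'   channel A in pixels; subtracted from B before matching.
#' @return a list of class `coloc_result`: `matches` (data.frame `index_a`,
#'   `index_b`, `distance`), `unmatched_a`, `unmatched_b` (integer indices),
#'   and `n_matched`.
#' @export
colocalize <- function(spots_a, spots_b, radius_px = 2, offset = c(0, 0)) {
  stopifnot(is.data.frame(spots_a), is.data.frame(spots_b),
            all(c("x", "y") %in% names(spots_a)),
            all(c("x", "y") %in% names(spots_b)),
            length(offset) == 2L)
  assert_pos(radius_px, "radius_px")
  na <- nrow(spots_a); nb <- nrow(spots_b)
  empty <- data.frame(index_a = integer(0), index_b = integer(0),
                      distance = numeric(0))
  if (na == 0 || nb == 0)
    return(structure(list(matches = empty, unmatched_a = seq_len(na),
                          unmatched_b = seq_len(nb), n_matched = 0L),
                     class = "coloc_result"))
  bx <- spots_b$x - offset[1]; by <- spots_b$y - offset[2]
  d2 <- outer(spots_a$x, bx, `-`)^2 + outer(spots_a$y, by, `-`)^2
  cand <- which(d2 <= radius_px^2, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(structure(list(matches = empty, unmatched_a = seq_len(na),
                          unmatched_b = seq_len(nb), n_matched = 0L),
                     class = "coloc_result"))
  dist <- sqrt(d2[cand])
  ord <- order(dist, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]; dist <- dist[ord]
  used_a <- logical(na); used_b <- logical(nb)
  ia <- integer(0); ib <- integer(0); dd <- numeric(0)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    ia <- c(ia, i); ib <- c(ib, j); dd <- c(dd, dist[k])
  }
  structure(list(
    matches = data.frame(index_a = ia, index_b = ib, distance = dd),
    unmatched_a = which(!used_a), unmatched_b = which(!used_b),
    n_matched = length(ia)), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("colocalization: %d matched, %d unmatched in A, %d in B\n",
              x$n_matched, length(x$unmatched_a), length(x$unmatched_b)))
  invisible(x)
}

#' Bound fraction of protein spots with Wilson confidence interval
#'
#' The central pull-down quantification: the fraction of immobilized protein
#' spots occupied by a labeled RNA, `sum(n_rna_bound) / sum(n_protein)` over
#' fields of view, with a 95% Wilson score interval on the pooled counts.
#' The per-field breakdown (including the mean of per-field fractions, an
#' alternative per-field-average summary) is retained.
#'
#' @param n_rna_bound integer vector, RNA-occupied protein spots per field.
#' @param n_protein integer vector (same length), protein spots per field;
#'   the pooled total must be positive.
#' @param conf confidence level of the Wilson interval.
#' @return a list of class `binding_summary`: `n_protein`, `n_rna_bound`
#'   (pooled counts), `bound_fraction`, `ci95`, `fields_of_view`,
#'   `mean_per_field`, and `per_field` (data.frame).
#' @examples
#' bound_fraction(85, 100)$bound_fraction
#' @export
bound_fraction <- function(n_rna_bound, n_protein, conf = 0.95) {
  stopifnot(length(n_rna_bound) == length(n_protein))
  assert_pos(n_rna_bound, "n_rna_bound", strict = FALSE)
  assert_pos(n_protein, "n_protein", strict = FALSE)
  if (sum(n_protein) == 0)
    stop("bound fraction undefined: no protein spots")
  if (any(n_rna_bound > n_protein))
    stop("n_rna_bound exceeds n_protein in some field")
  x <- sum(n_rna_bound); n <- sum(n_protein)
  per_field <- data.frame(field = seq_along(n_protein),
                          n_protein = n_protein, n_rna_bound = n_rna_bound,
                          fraction = ifelse(n_protein > 0,
                                            n_rna_bound / n_protein, NA_real_))
  structure(list(
    n_protein = n, n_rna_bound = x, bound_fraction = x / n,
    ci95 = wilson_ci(x, n, conf), fields_of_view = length(n_protein),
    mean_per_field = mean(per_field$fraction, na.rm = TRUE),
    per_field = per_field), class = "binding_summary")
}

#' @export
print.binding_summary <- function(x, ...) {
  cat(sprintf(
    "bound fraction: %.3f (95%% CI %.3f-%.3f), %d/%d spots over %d field(s)\n",
    x$bound_fraction, x$ci95[1], x$ci95[2], x$n_rna_bound, x$n_protein,
    x$fields_of_view))
  invisible(x)
}

#' Fit a saturating binding curve to spot counts vs concentration
#'
#' Least-squares fit of `count = Nmax * c / (c + c50)`, the hyperbolic
#' saturation seen when counting pulled-down molecules against serially
#' diluted lysate.
#'
#' @param concentrations numeric vector (>= 3 points, any concentration
#'   unit).
#' @param counts numeric vector of spot counts, same length.
#' @return a list of class `saturation_fit`: `nmax`, `c50`, `residuals`,
#'   `r_squared`, `poor_fit` (`TRUE` when R-squared < 0.5), `fitted`.
#' @examples
#' conc <- c(10, 25, 50, 100, 200, 400)
#' fit <- saturation_curve(conc, 1000 * conc / (conc + 50))
#' c(fit$nmax, fit$c50)
#' @export
saturation_curve <- function(concentrations, counts) {
  stopifnot(length(concentrations) == length(counts))
  if (length(concentrations) < 3)
    stop("need at least 3 concentration points to fit Nmax and c50")
  assert_pos(concentrations, "concentrations")
  assert_pos(counts, "counts", strict = FALSE)
  nmax0 <- max(counts) * 1.2
  half <- nmax0 / 2
  c50_0 <- stats::approx(counts, concentrations, xout = half, ties = mean,
                         rule = 2)$y
  dat <- data.frame(conc = concentrations, count = counts)
  fit <- minpack.lm::nlsLM(count ~ nmax * conc / (conc + c50), data = dat,
                           start = list(nmax = nmax0, c50 = max(c50_0, 1e-12)),
                           lower = c(0, 1e-12),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  fitted <- co[["nmax"]] * concentrations / (concentrations + co[["c50"]])
  ss_res <- sum((counts - fitted)^2)
  ss_tot <- sum((counts - mean(counts))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  if (r2 < 0.5) warning("poor saturation fit (R-squared < 0.5)")
  structure(list(nmax = unname(co[["nmax"]]), c50 = unname(co[["c50"]]),
                 residuals = counts - fitted, r_squared = r2,
                 poor_fit = r2 < 0.5, fitted = fitted),
            class = "saturation_fit")
}
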