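# Shrake-Rupley solvent-accessible surface area and buried-interface
# contact area from atomic coordinates.

#' Default van der Waals radii (Angstrom) by element
#'
#' @return named numeric vector; elements not listed fall back to 1.7.
#' @export
vdw_radii <- function() {
  c(C = 1.7, N = 1.55, O = 1.52, P = 1.8, S = 1.8, H = 1.2)
}

#' Construct an atom set
#'
#' @param coords numeric matrix (n x 3) of coordinates in Angstrom.
#' @param elements character vector of element symbols (used to look up vdW
#'   radii); ignored when `radii` is given.
#' @param radii explicit per-atom vdW radii in Angstrom (> 0).
#' @param chains chain labels (default all `"A"`).
#' @return data.frame of class `atom_set` with columns `x`, `y`, `z`,
#'   `element`, `radius`, `chain`.
#' @export
atom_set <- function(coords, elements = NULL, radii = NULL, chains = NULL) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) >= 1, all(is.finite(coords)))
  n <- nrow(coords)
  if (is.null(radii)) {
    if (is.null(elements)) stop("give either elements or radii")
    tab <- vdw_radii()
    radii <- unname(tab[toupper(elements)])
    radii[is.na(radii)] <- 1.7
  }
  assert_pos(radii, "radii")
  if (is.null(elements)) elements <- rep(NA_character_, n)
  if (is.null(chains)) chains <- rep("A", n)
  structure(data.frame(x = coords[, 1], y = coords[, 2], z = coords[, 3],
                       element = rep_len(elements, n),
                       radius = rep_len(radii, n),
                       chain = rep_len(as.character(chains), n)),
            class = c("atom_set", "data.frame"))
}

#' Read atom sets from a PDB file
#'
#' Uses `bio3d` to parse single- or multi-model PDB files. Hydrogens are
#' kept if present; radii are assigned from [vdw_radii()] by element.
#'
#' @param path PDB file.
#' @return a list of `atom_set` objects, one per model.
#' @export
read_atom_set <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  el <- pdb$atom$elesy
  if (is.null(el) || all(is.na(el)) || all(el == ""))
    el <- substr(trimws(pdb$atom$elety), 1, 1)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  lapply(seq_len(nrow(xyz)), function(m) {
    atom_set(matrix(xyz[m, ], ncol = 3, byrow = TRUE),
             elements = el, chains = pdb$atom$chain)
  })
}

# Quasi-uniform points on the unit sphere (Fibonacci lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's sphere is inflated by the probe radius and covered with
#' `n_points` quasi-uniform test points; a point is solvent-exposed iff it
#' lies outside every other inflated sphere. The atom's SASA is
#' `4 * pi * (r + probe)^2` times its exposed fraction.
#'
#' @param atoms an `atom_set`.
#' @param probe_radius solvent probe radius, Angstrom (water: 1.4).
#' @param n_points test points per atom.
#' @return numeric vector of per-atom areas (Angstrom^2); `sum()` gives the
#'   molecular SASA.
#' @examples
#' a <- atom_set(rbind(c(0, 0, 0)), radii = 1.7)
#' sasa(a)  # isolated sphere: 4 * pi * 3.1^2
#' @export
sasa <- function(atoms, probe_radius = 1.4, n_points = 960L) {
  stopifnot(inherits(atoms, "atom_set"), nrow(atoms) >= 1)
  assert_pos(probe_radius, "probe_radius", strict = FALSE)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (anyDuplicated(round(xyz, 6)))
    warning("duplicate atom coordinates: occlusion is degenerate")
  R <- atoms$radius + probe_radius
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  d2 <- as.matrix(stats::dist(xyz))^2
  areas <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    if (length(nb) == 0) { areas[i] <- 4 * pi * R[i]^2; next }
    P <- sweep(pts * R[i], 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    # check nearest occluders first so most points die early
    for (j in nb[order(d2[i, nb])]) {
      if (!any(exposed)) break
      dx <- P[exposed, 1] - xyz[j, 1]
      dy <- P[exposed, 2] - xyz[j, 2]
      dz <- P[exposed, 3] - xyz[j, 3]
      exposed[exposed] <- dx * dx + dy * dy + dz * dz > R[j]^2
    }
    areas[i] <- 4 * pi * R[i]^2 * sum(exposed) / n_points
  }
  areas
}

#' Buried-interface contact area between two chain groups
#'
#' The standard buried solvent-accessible surface area proxy for interface
#' size: `(SASA(A) + SASA(B) - SASA(A+B)) / 2`, where each term is the total
#' SASA of the group computed in isolation or in the complex.
#'
#' @param atoms an `atom_set` containing both groups (one model), or a list
#'   of `atom_set` models as returned by [read_atom_set()] — per-model areas
#'   and their mean/SD are then reported.
#' @param chains_a,chains_b chain labels defining the two groups (both
#'   nonempty and disjoint).
#' @param probe_radius,n_points passed to [sasa()].
#' @return for a single model, the contact area in Angstrom^2 (scalar). For
#'   a model list, a list of class `contact_area_models` with `per_model`,
#'   `mean` and `sd`.
#' @export
contact_area <- function(atoms, chains_a, chains_b, probe_radius = 1.4,
                         n_points = 960L) {
  if (is.list(atoms) && !is.data.frame(atoms)) {
    per <- vapply(atoms, contact_area, numeric(1), chains_a = chains_a,
                  chains_b = chains_b, probe_radius = probe_radius,
                  n_points = n_points)
    return(structure(list(per_model = per, mean = mean(per),
                          sd = if (length(per) > 1) stats::sd(per) else NA_real_),
                     class = "contact_area_models"))
  }
  stopifnot(inherits(atoms, "atom_set"))
  in_a <- atoms$chain %in% chains_a
  in_b <- atoms$chain %in% chains_b
  if (!any(in_a) || !any(in_b))
    stop("both chain groups must be nonempty")
  if (any(in_a & in_b)) stop("chain groups must be disjoint")
  a <- atoms[in_a, , drop = FALSE]; class(a) <- class(atoms)
  b <- atoms[in_b, , drop = FALSE]; class(b) <- class(atoms)
  ab <- atoms[in_a | in_b, , drop = FALSE]; class(ab) <- class(atoms)
  (sum(sasa(a, probe_radius, n_points)) + sum(sasa(b, probe_radius, n_points)) -
     sum(sasa(ab, probe_radius, n_points))) / 2
}

#' @export
print.contact_area_models <- function(x, ...) {
  cat(sprintf("contact area: %.1f +/- %s A^2 over %d model(s)\n", x$mean,
              ifelse(is.na(x$sd), "NA", sprintf("%.1f", x$sd)),
              length(x$per_model)))
  invisible(x)
}
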