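#' Generate a synthetic two-channel TIRF field of view
#'
#' Renders a field of surface-immobilized protein spots (channel 1) of which a
#' Bernoulli(`bound_fraction_true`) subset carries a co-located labeled-RNA
#' spot (channel 2). Each spot is an isotropic 2D Gaussian of width
#' `psf_sigma` and peak amplitude `spot_amplitude`; photon counting is
#' emulated by Poisson-sampling the expected image (background + spots), so a
#' field with `spot_amplitude = 0` is pure `Poisson(background_mean)`.
#'
#' Coordinates are 0-based with pixel centers at integers; `x` runs along
#' columns and `y` along rows. The RNA channel is shifted by the known
#' inter-channel registration offset `channel_offsets` (nm).
#'
#' @param config a [sim_config()].
#' @param channel_offsets numeric length-2, (x, y) registration shift of the
#'   RNA channel relative to the protein channel, in nm.
#' @return a list of class `fov_sim` with elements `protein` and `rna`
#'   (objects of class `image_stack`) and `truth`, a data.frame with one row
#'   per protein spot: `spot_id`, `x`, `y` (protein-channel pixels), `bound`
#'   (logical), and `x_rna`, `y_rna` (RNA-channel pixels, `NA` when unbound).
#' @examples
#' fov <- generate_fov(sim_config(seed = 1, n_protein_spots = 20))
#' sum(fov$truth$bound)
#' @export
generate_fov <- function(config, channel_offsets = c(0, 0)) {
  stopifnot(inherits(config, "sim_config"), length(channel_offsets) == 2L)
  set.seed(config$seed)
  nr <- config$fov_shape[1]; nc <- config$fov_shape[2]
  margin <- ceiling(4 * config$psf_sigma) + 1
  if (2 * margin >= min(nr, nc)) stop("field too small for the PSF margin")

  pos <- draw_positions(config$n_protein_spots, nr, nc, margin,
                        config$min_separation)
  n <- config$n_protein_spots
  bound <- if (n > 0) stats::rbinom(n, 1L, config$bound_fraction_true) == 1L
           else logical(0)
  off_px <- channel_offsets / config$pixel_size

  truth <- data.frame(
    spot_id = seq_len(n), x = pos$x, y = pos$y, bound = bound,
    x_rna = ifelse(bound, pos$x + off_px[1], NA_real_),
    y_rna = ifelse(bound, pos$y + off_px[2], NA_real_)
  )

  render <- function(x, y) {
    frames <- vector("list", config$n_frames)
    expected <- render_spots(nr, nc, x, y, config$spot_amplitude,
                             config$psf_sigma) + config$background_mean
    for (f in seq_len(config$n_frames)) {
      frames[[f]] <- matrix(stats::rpois(nr * nc, expected), nr, nc)
    }
    frames
  }
  protein <- image_stack(render(pos$x, pos$y), pixel_size = config$pixel_size,
                         exposure = config$exposure)
  rna <- image_stack(render(truth$x_rna[bound], truth$y_rna[bound]),
                     pixel_size = config$pixel_size,
                     exposure = config$exposure)
  structure(list(protein = protein, rna = rna, truth = truth,
                 channel_offsets = channel_offsets, config = config),
            class = "fov_sim")
}

# Uniform positions with an optional minimum-separation constraint, filled by
# rejection sampling with a bounded retry budget.
draw_positions <- function(n, nr, nc, margin, min_sep) {
  if (n == 0) return(list(x = numeric(0), y = numeric(0)))
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L; budget <- 200L * n
  while (length(xs) < n) {
    tries <- tries + 1L
    if (tries > budget)
      stop(sprintf(
        "could not place %d spots at min separation %.1f px in %d tries",
        n, min_sep, budget))
    x <- stats::runif(1, margin, nc - 1 - margin)
    y <- stats::runif(1, margin, nr - 1 - margin)
    if (min_sep > 0 && length(xs) &&
        any((xs - x)^2 + (ys - y)^2 < min_sep^2)) next
    xs <- c(xs, x); ys <- c(ys, y)
  }
  list(x = xs, y = ys)
}

# Sum of 2D Gaussians rendered on local windows (+/- 4 sigma) for speed.
render_spots <- function(nr, nc, x, y, amplitude, sigma) {
  img <- matrix(0, nr, nc)
  if (length(x) == 0 || amplitude == 0) return(img)
  hw <- ceiling(4 * sigma)
  for (i in seq_along(x)) {
    cx <- x[i]; cy <- y[i]
    c0 <- max(0, floor(cx) - hw); c1 <- min(nc - 1, ceiling(cx) + hw)
    r0 <- max(0, floor(cy) - hw); r1 <- min(nr - 1, ceiling(cy) + hw)
    cols <- c0:c1; rows <- r0:r1
    gx <- exp(-(cols - cx)^2 / (2 * sigma^2))
    gy <- exp(-(rows - cy)^2 / (2 * sigma^2))
    img[rows + 1, cols + 1] <- img[rows + 1, cols + 1] +
      amplitude * outer(gy, gx)
  }
  img
}

#' Construct an image stack
#'
#' A time series of 2D count frames with pixel geometry metadata; the
#' in-memory counterpart of a multi-page 16-bit grayscale TIFF.
#'
#' @param frames a matrix or list of matrices (counts).
#' @param pixel_size nm per pixel.
#' @param exposure seconds per frame.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size = NA_real_, exposure = NA_real_) {
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(length(frames) >= 1, all(vapply(frames, is.matrix, logical(1))))
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1) stop("all frames must share one shape")
  structure(list(frames = frames, pixel_size = pixel_size,
                 exposure = exposure), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("image_stack: %d frame(s) of %d x %d px (%g nm/px)\n",
              length(x$frames), d[1], d[2], x$pixel_size))
  invisible(x)
}
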