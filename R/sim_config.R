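#' Configuration for a synthetic TIRF field of view
#'
#' Describes a single-molecule pull-down field: surface-immobilized protein
#' spots imaged as diffraction-limited Gaussians over a Poisson camera
#' background, with a controlled fraction of spots carrying a co-located
#' labeled-RNA spot in a second channel.
#'
#' @param seed integer seed; identical configuration and seed give
#'   bit-identical output.
#' @param fov_shape integer length-2, field size in pixels (rows, columns).
#' @param pixel_size pixel pitch in nm/pixel.
#' @param psf_sigma Gaussian PSF width in pixels; must be positive.
#' @param background_mean mean camera background in counts/pixel/frame
#'   (Poisson).
#' @param spot_amplitude peak amplitude of a spot above background, counts.
#' @param n_protein_spots number of immobilized protein spots.
#' @param bound_fraction_true probability in `[0, 1]` that a protein spot is
#'   occupied by a labeled RNA.
#' @param exposure camera exposure per frame, seconds.
#' @param acquisition total acquisition time, seconds.
#' @param n_frames frames rendered per channel.
#' @param min_separation minimum center-to-center spot distance in pixels
#'   (0 disables the constraint).
#' @return an object of class `sim_config`.
#' @seealso [generate_fov()]
#' @export
sim_config <- function(seed,
                       fov_shape = c(256L, 256L),
                       pixel_size = 107,
                       psf_sigma = 1.3,
                       background_mean = 100,
                       spot_amplitude = 800,
                       n_protein_spots = 150L,
                       bound_fraction_true = 0.85,
                       exposure = 0.030,
                       acquisition = 60,
                       n_frames = 1L,
                       min_separation = 0) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed == round(seed))
  stopifnot(length(fov_shape) == 2L, all(fov_shape >= 8))
  assert_pos(pixel_size, "pixel_size")
  assert_pos(psf_sigma, "psf_sigma")
  assert_pos(background_mean, "background_mean", strict = FALSE)
  assert_pos(spot_amplitude, "spot_amplitude", strict = FALSE)
  stopifnot(n_protein_spots >= 0, n_protein_spots == round(n_protein_spots))
  assert_prob(bound_fraction_true, "bound_fraction_true")
  assert_pos(exposure, "exposure")
  if (acquisition < exposure) stop("acquisition must be >= exposure")
  stopifnot(n_frames >= 1, min_separation >= 0)
  structure(list(
    seed = as.integer(seed), fov_shape = as.integer(fov_shape),
    pixel_size = pixel_size, psf_sigma = psf_sigma,
    background_mean = background_mean, spot_amplitude = spot_amplitude,
    n_protein_spots = as.integer(n_protein_spots),
    bound_fraction_true = bound_fraction_true,
    exposure = exposure, acquisition = acquisition,
    n_frames = as.integer(n_frames), min_separation = min_separation
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("TIRF field simulation config\n")
  cat(sprintf("  field: %d x %d px (%g nm/px), psf sigma %g px\n",
              x$fov_shape[1], x$fov_shape[2], x$pixel_size, x$psf_sigma))
  cat(sprintf("  %d protein spots, true bound fraction %.3f\n",
              x$n_protein_spots, x$bound_fraction_true))
  cat(sprintf("  background %g counts, amplitude %g counts, seed %d\n",
              x$background_mean, x$spot_amplitude, x$seed))
  invisible(x)
}

#' Kinetic parameters of the sliding PIFE trace generator
#'
#' A dsRBP anchored to the surface holds an RNA duplex whose register performs
#' a nearest-neighbour continuous-time random walk over `duplex_length`
#' lattice positions with reflecting ends. The dye at the duplex end is
#' fluorescence-enhanced (PIFE) whenever the protein-bound register lies
#' within `pife_range` of it; with the A-form helical rise this distance maps
#' to a proximity window of `floor(pife_range / rise_per_bp)` base pairs.
#'
#' @param duplex_length duplex length in base pairs (lattice size, >= 2).
#' @param hop_rate hop rate per direction, events/s.
#' @param rise_per_bp helical rise, nm per base pair (A-form default 0.28).
#' @param pife_range PIFE distance sensitivity range, nm.
#' @param enhancement fold fluorescence enhancement inside the window
#'   (>= 1; default 2.25, midpoint of the characteristic 2-2.5x band).
#' @param baseline_intensity unenhanced dye intensity, counts/frame.
#' @param bleach_lifetime mean exponential photobleaching lifetime, seconds
#'   (`Inf` disables bleaching).
#' @param noise_sd Gaussian read-noise sd, counts.
#' @param exposure camera exposure, seconds/frame.
#' @param acquisition acquisition length, seconds.
#' @param slide_lifetime mean exponential duration of the sliding episode,
#'   seconds; after it ends the molecule freezes at its current level
#'   (`Inf` = slides until bleach).
#' @param frame_integration if `TRUE` (default) a frame records the
#'   time-weighted mixture of the levels occupied during the exposure;
#'   if `FALSE` the level at the frame start is sampled.
#' @return an object of class `slide_kinetics`; element `pife_window_bp`
#'   holds the derived proximity window.
#' @seealso [generate_pife_trace()]
#' @export
slide_kinetics <- function(duplex_length = 40L,
                           hop_rate = 40,
                           rise_per_bp = 0.28,
                           pife_range = 4.0,
                           enhancement = 2.25,
                           baseline_intensity = 500,
                           bleach_lifetime = 30,
                           noise_sd = 50,
                           exposure = 0.030,
                           acquisition = 60,
                           slide_lifetime = Inf,
                           frame_integration = TRUE) {
  if (duplex_length < 2) stop("duplex_length must be >= 2")
  if (enhancement < 1) stop("enhancement must be >= 1")
  assert_pos(hop_rate, "hop_rate")
  assert_pos(rise_per_bp, "rise_per_bp")
  assert_pos(pife_range, "pife_range")
  assert_pos(baseline_intensity, "baseline_intensity")
  assert_pos(bleach_lifetime, "bleach_lifetime")
  assert_pos(noise_sd, "noise_sd", strict = FALSE)
  assert_pos(exposure, "exposure")
  if (acquisition < exposure) stop("acquisition must be >= exposure")
  assert_pos(slide_lifetime, "slide_lifetime")
  w <- floor(pife_range / rise_per_bp)
  if (w < 1) stop("pife_range / rise_per_bp must give a window of >= 1 bp")
  if (w >= duplex_length)
    stop("PIFE window covers the whole duplex; increase duplex_length")
  structure(list(
    duplex_length = as.integer(duplex_length), hop_rate = hop_rate,
    rise_per_bp = rise_per_bp, pife_range = pife_range,
    pife_window_bp = as.integer(w), enhancement = enhancement,
    baseline_intensity = baseline_intensity,
    bleach_lifetime = bleach_lifetime, noise_sd = noise_sd,
    exposure = exposure, acquisition = acquisition,
    slide_lifetime = slide_lifetime,
    frame_integration = isTRUE(frame_integration)
  ), class = "slide_kinetics")
}

#' @export
print.slide_kinetics <- function(x, ...) {
  cat("PIFE sliding kinetics\n")
  cat(sprintf("  duplex %d bp, hop rate %g /s, window %d bp (%g nm at %g nm/bp)\n",
              x$duplex_length, x$hop_rate, x$pife_window_bp,
              x$pife_range, x$rise_per_bp))
  cat(sprintf("  enhancement %gx over I0 = %g counts, noise sd %g\n",
              x$enhancement, x$baseline_intensity, x$noise_sd))
  cat(sprintf("  exposure %g s, acquisition %g s, bleach lifetime %g s\n",
              x$exposure, x$acquisition, x$bleach_lifetime))
  invisible(x)
}
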