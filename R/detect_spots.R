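#' Detect diffraction-limited spots in a TIRF frame
#'
#' Laplacian-of-Gaussian (LoG) blob detection at the PSF scale: the frame is
#' convolved with a scale-normalized, sign-flipped LoG kernel so that
#' Gaussian spots give positive peaks; local maxima exceeding
#' `median + snr_threshold * MAD` of the response are kept, maxima closer
#' than `2 * psf_sigma` are merged to the brighter one, and positions are
#' refined to sub-pixel precision by an intensity centroid in a 3x3 window.
#'
#' Coordinates follow the generator convention: 0-based, `x` along columns,
#' `y` along rows, pixel centers at integers.
#'
#' @param frame a numeric matrix of counts, or an [image_stack()] (frames are
#'   averaged before detection).
#' @param psf_sigma expected spot width in pixels (> 0).
#' @param snr_threshold detection threshold in robust noise units (MAD) of
#'   the LoG response.
#' @param min_separation merge radius in pixels; defaults to `2 * psf_sigma`.
#' @param frame_index stored in the output table.
#' @param saturation_level counts at which a pixel is considered saturated;
#'   saturated frames are flagged via the `saturated` attribute, not clipped.
#' @return a data.frame of class `spot_set` with columns `x`, `y`,
#'   `peak_intensity`, `response`, `frame_index`, ordered by decreasing
#'   response. Attribute `saturated` is `TRUE` if any pixel reached
#'   `saturation_level`.
#' @examples
#' fov <- generate_fov(sim_config(seed = 2, n_protein_spots = 12,
#'                                min_separation = 8))
#' nrow(detect_spots(fov$protein, psf_sigma = 1.3))
#' @export
detect_spots <- function(frame, psf_sigma, snr_threshold = 5,
                         min_separation = NULL, frame_index = 1L,
                         saturation_level = 65535) {
  if (inherits(frame, "image_stack"))
    frame <- Reduce(`+`, frame$frames) / length(frame$frames)
  stopifnot(is.matrix(frame), is.numeric(frame))
  if (any(frame < 0)) stop("frame must be non-negative")
  assert_pos(psf_sigma, "psf_sigma")
  if (is.null(min_separation)) min_separation <- 2 * psf_sigma
  saturated <- any(frame >= saturation_level)
  if (saturated) warning("frame contains saturated pixels; detections kept")

  resp <- log_response(frame, psf_sigma)
  # numerical floor keeps FFT ringing out on noise-free frames
  noise <- max(stats::mad(resp), 1e-8 * max(abs(resp)))
  thr <- stats::median(resp) + snr_threshold * noise

  nr <- nrow(frame); nc <- ncol(frame)
  core <- resp[2:(nr - 1), 2:(nc - 1)]
  is_max <- core > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (core >= resp[2:(nr - 1) + dr, 2:(nc - 1) + dc])
  }
  idx <- which(is_max, arr.ind = TRUE)
  spots <- data.frame(x = numeric(0), y = numeric(0),
                      peak_intensity = numeric(0), response = numeric(0),
                      frame_index = integer(0))
  if (nrow(idx) > 0) {
    rows <- idx[, 1] + 1L; cols <- idx[, 2] + 1L
    rvals <- resp[cbind(rows, cols)]
    ord <- order(rvals, decreasing = TRUE)
    rows <- rows[ord]; cols <- cols[ord]; rvals <- rvals[ord]
    keep <- merge_maxima(rows, cols, min_separation)
    rows <- rows[keep]; cols <- cols[keep]; rvals <- rvals[keep]
    cen <- t(vapply(seq_along(rows), function(i)
      centroid3x3(frame, rows[i], cols[i]), numeric(2)))
    spots <- data.frame(
      x = cen[, 2] - 1, y = cen[, 1] - 1,
      peak_intensity = frame[cbind(rows, cols)],
      response = rvals, frame_index = as.integer(frame_index))
  }
  structure(spots, class = c("spot_set", "data.frame"), saturated = saturated)
}

# Scale-normalized negative-LoG filtering; positive response on bright blobs.
log_response <- function(frame, sigma) {
  hw <- max(2L, ceiling(4 * sigma))
  ax <- seq(-hw, hw)
  g <- exp(-ax^2 / (2 * sigma^2))
  r2 <- outer(ax^2, ax^2, `+`)
  kern <- outer(g, g) * (r2 - 2 * sigma^2) / sigma^2
  kern <- -(kern - mean(kern))                     # zero-DC, blob-positive
  kern <- kern / sum(kern[kern > 0])
  as.matrix(EBImage::filter2(frame, kern))
}

# Greedy suppression: maxima are pre-sorted by decreasing response; a
# candidate within `min_sep` of an already kept (brighter) one is dropped.
merge_maxima <- function(rows, cols, min_sep) {
  n <- length(rows)
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (any(keep & (rows[seq_len(n)] - rows[i])^2 +
              (cols[seq_len(n)] - cols[i])^2 < min_sep^2)) next
    keep[i] <- TRUE
  }
  keep
}

centroid3x3 <- function(frame, r, c) {
  rr <- max(1, r - 1):min(nrow(frame), r + 1)
  cc <- max(1, c - 1):min(ncol(frame), c + 1)
  w <- frame[rr, cc, drop = FALSE] - min(frame[rr, cc])
  if (sum(w) == 0) return(c(r, c))
  c(sum(rr * rowSums(w)) / sum(w), sum(cc * colSums(w)) / sum(w))
}
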