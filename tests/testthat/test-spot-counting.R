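test_that("a blank background frame yields no detections", {
  set.seed(21)
  frame <- matrix(rpois(128 * 128, 100), 128, 128)
  expect_equal(nrow(detect_spots(frame, psf_sigma = 1.3, snr_threshold = 5)), 0)
})

test_that("well-separated bright spots are all found with no false positives", {
  cfg <- sim_config(seed = 22, n_protein_spots = 50L,
                    spot_amplitude = 10 * sqrt(100), min_separation = 8,
                    fov_shape = c(256L, 256L))
  fov <- generate_fov(cfg)
  sp <- detect_spots(fov$protein, psf_sigma = cfg$psf_sigma, snr_threshold = 5)
  expect_equal(nrow(sp), 50)
  d2 <- outer(sp$x, fov$truth$x, `-`)^2 + outer(sp$y, fov$truth$y, `-`)^2
  expect_true(all(apply(d2, 1, min) < 1))      # every detection is a true spot
  expect_true(all(apply(d2, 2, min) < 1))      # every true spot is detected
})

test_that("detection recall and precision hold at moderate SNR", {
  for (s in 1:3) {
    cfg <- sim_config(seed = 30 + s, n_protein_spots = 80L,
                      spot_amplitude = 8 * sqrt(100),
                      min_separation = 4 * 4 * 1.3, fov_shape = c(512L, 512L))
    fov <- generate_fov(cfg)
    sp <- detect_spots(fov$protein, cfg$psf_sigma)
    d2 <- outer(sp$x, fov$truth$x, `-`)^2 + outer(sp$y, fov$truth$y, `-`)^2
    recall <- mean(apply(d2, 2, min) < 4)
    precision <- mean(apply(d2, 1, min) < 4)
    expect_gte(recall, 0.95)
    expect_gte(precision, 0.95)
  }
})

test_that("spots closer than the merge radius are reported once", {
  img <- matrix(0, 64, 64)
  render <- function(img, x, y, amp, s) {
    for (c0 in 1:64) for (r0 in 1:64)
      img[r0, c0] <- img[r0, c0] +
        amp * exp(-((c0 - 1 - x)^2 + (r0 - 1 - y)^2) / (2 * s^2))
    img
  }
  img <- render(img, 30, 30, 500, 1.3)
  img <- render(img, 31.5, 30, 500, 1.3)   # separation 1.5 px < 2 * sigma
  sp <- detect_spots(img + 10, psf_sigma = 1.3, snr_threshold = 5)
  expect_equal(nrow(sp), 1)
})

test_that("saturated frames are flagged rather than clipped", {
  set.seed(23)
  frame <- matrix(rpois(64 * 64, 50), 64, 64)
  frame[32, 32] <- 70000
  expect_warning(sp <- detect_spots(frame, 1.3), "saturated")
  expect_true(attr(sp, "saturated"))
})

test_that("colocalization matches identical lists exactly and far lists not
           at all", {
  a <- data.frame(x = c(10, 20, 30), y = c(10, 20, 30))
  cl <- colocalize(a, a, radius_px = 2)
  expect_equal(cl$n_matched, 3)
  expect_equal(cl$matches$distance, c(0, 0, 0))
  b <- data.frame(x = a$x + 50, y = a$y)
  expect_equal(colocalize(a, b, radius_px = 2)$n_matched, 0)
  # known registration offset is corrected before matching
  expect_equal(colocalize(a, b, radius_px = 2, offset = c(50, 0))$n_matched, 3)
})

test_that("colocalization count is symmetric up to tie-breaking", {
  set.seed(24)
  a <- data.frame(x = runif(60, 0, 100), y = runif(60, 0, 100))
  b <- data.frame(x = runif(70, 0, 100), y = runif(70, 0, 100))
  expect_equal(colocalize(a, b, 3)$n_matched, colocalize(b, a, 3)$n_matched)
})

test_that("generator fields colocalize at the expected binomial rate", {
  cfg <- sim_config(seed = 25, n_protein_spots = 500L,
                    bound_fraction_true = 0.5, fov_shape = c(700L, 700L),
                    min_separation = 6)
  fov <- generate_fov(cfg)
  sa <- detect_spots(fov$protein, cfg$psf_sigma)
  sb <- detect_spots(fov$rna, cfg$psf_sigma)
  cl <- colocalize(sa, sb, radius_px = 2)
  expect_lt(abs(cl$n_matched - 250), 3 * sqrt(500 * 0.25))
})

test_that("bound fraction arithmetic, errors, and pooling invariance", {
  expect_equal(bound_fraction(0, 100)$bound_fraction, 0)
  expect_equal(bound_fraction(85, 100)$bound_fraction, 0.85)
  expect_error(bound_fraction(0, 0), "undefined")
  expect_error(bound_fraction(10, 5), "exceeds")
  bs <- bound_fraction(c(40, 45), c(50, 50))
  expect_true(bs$ci95[1] <= bs$bound_fraction &&
                bs$bound_fraction <= bs$ci95[2])
  # pooled ratio is invariant under relabeling fields of view
  expect_equal(bound_fraction(c(45, 40), c(50, 50))$bound_fraction,
               bs$bound_fraction)
  expect_equal(bs$fields_of_view, 2)
})

test_that("saturation curve is recovered exactly from noiseless points and
           within 10% from noisy ones", {
  conc <- c(5, 10, 25, 50, 100, 200, 400)
  counts <- 1000 * conc / (conc + 50)
  fit <- saturation_curve(conc, counts)
  expect_equal(fit$nmax, 1000, tolerance = 1e-6)
  expect_equal(fit$c50, 50, tolerance = 1e-6)
  expect_false(fit$poor_fit)
  expect_error(saturation_curve(100, 900), "3 concentration")

  set.seed(26)
  noisy <- counts[1:6] * (1 + rnorm(6, 0, 0.05))
  fit2 <- saturation_curve(conc[1:6], noisy)
  expect_lt(abs(fit2$nmax - 1000) / 1000, 0.10)
})
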