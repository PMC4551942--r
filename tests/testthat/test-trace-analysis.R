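test_that("bleach step counting handles the canonical cases", {
  # noiseless single drop
  x <- c(rep(1000, 50), rep(0, 50))
  expect_equal(as.integer(count_bleach_steps(x)), 1L)
  expect_true(attr(count_bleach_steps(x), "bleached"))
  # constant nonzero: no steps, not bleached
  y <- rep(800, 60)
  cy <- count_bleach_steps(y)
  expect_equal(as.integer(cy), 0L)
  expect_false(attr(cy, "bleached"))
  # all-background: zero steps, flagged unbound
  set.seed(31)
  z <- rnorm(100, 0, 5)
  cz <- count_bleach_steps(z)
  expect_equal(as.integer(cz), 0L)
  expect_true(attr(cz, "unbound"))
  expect_error(count_bleach_steps(rep(1, 5)), "short")
})

test_that("generated multimers are counted at realistic noise", {
  kin <- slide_kinetics(noise_sd = 50, bleach_lifetime = 10)  # I0 / 10 noise
  hits <- 0L
  for (s in 1:20) {
    tm <- generate_pife_trace(kin, "multimer", seed = 40 + s,
                              n_fluorophores = 2)
    hits <- hits + (as.integer(count_bleach_steps(tm$trace)) == 2L)
  }
  expect_gte(hits, 19)
})

test_that("classification labels the canonical trace shapes", {
  # constant noiseless trace is static
  const <- structure(list(time = (0:399) * 0.03, intensity = rep(900, 400),
                          trace_id = "c", exposure = 0.03),
                     class = "pife_trace")
  expect_equal(as.character(classify_trace(const)), "static")
  # square wave at the PIFE enhancement ratio with 6 transitions is sliding
  sq <- square_wave_trace(500, 1125, half_period = 60, n_frames = 420)
  lab <- classify_trace(sq)
  expect_equal(as.character(lab), "sliding")
  expect_gte(attr(lab, "transitions"), 6)
  # a trace that bleaches almost immediately is rejected
  early <- structure(list(time = (0:399) * 0.03,
                          intensity = c(rep(900, 20), rnorm(380, 0, 5)),
                          trace_id = "e", exposure = 0.03),
                     class = "pife_trace")
  expect_equal(as.character(classify_trace(early)), "rejected")
})

test_that("false-sliding rate on pure static populations is below 2%", {
  kin <- slide_kinetics()
  pop <- generate_trace_population(c(static = 1.0), 1000, kin, seed = 44)
  labs <- vapply(pop$traces, function(tr) as.character(classify_trace(tr)),
                 character(1))
  expect_lte(mean(labs == "sliding"), 0.02)
})

test_that("dwell extraction is exact on noiseless periodic traces", {
  # period 10 s square wave at 30 ms exposure
  sq <- square_wave_trace(500, 1125, half_period = 167, n_frames = 2000)
  pk <- peak_intervals(sq)
  expect_gt(length(pk$intervals), 3)
  expect_true(all(abs(pk$intervals - 167 * 2 * 0.03) <= 0.03 + 1e-9))
  # constant trace: no peaks, empty interval list (not an error)
  const <- rep(800, 500)
  expect_equal(peak_intervals(const)$n_peaks, 0)
  expect_length(peak_intervals(const)$intervals, 0)
})

test_that("detected peaks track the generator's true peaks on clean traces", {
  kin <- slide_kinetics(duplex_length = 10L, pife_range = 0.28, hop_rate = 20,
                        noise_sd = 0, bleach_lifetime = Inf, exposure = 0.001,
                        acquisition = 30)
  det <- c(); tru <- c()
  for (s in 1:5) {
    g <- generate_pife_trace(kin, "sliding", seed = 1000 + s)
    det <- c(det, peak_intervals(g$trace, smooth_window = 1)$intervals)
    tru <- c(tru, diff(g$truth$true_peak_times))
  }
  se <- stats::sd(det) / sqrt(length(det))
  expect_lt(abs(mean(det) - mean(tru)), 3 * se)
})

test_that("sliding durations: naive mean, censoring warning, KM correction", {
  d <- data.frame(duration = c(10, 20, 30), censored = FALSE)
  expect_equal(sliding_durations(d)$naive_mean, 20)
  dc <- data.frame(duration = rep(60, 5), censored = TRUE)
  expect_warning(res <- sliding_durations(dc), "censored")
  expect_equal(res$naive_mean, 60)
  expect_true(res$dominant_censoring)

  # generator: exponential sliding lifetime 35 s under bleach lifetime 30 s;
  # the KM restricted mean must sit closer to E[min(X, 60)] than the naive
  kin <- slide_kinetics(slide_lifetime = 35)
  pop <- generate_trace_population(c(sliding = 1.0), 400, kin, seed = 99)
  verd <- lapply(pop$traces, analyze_trace)
  res <- sliding_durations(verd, restrict = 60)
  target <- truncated_exp_mean(35, 60)
  expect_lt(res$naive_mean, 35)
  expect_lt(abs(res$km_restricted_mean - target),
            abs(res$naive_mean - target))
})

test_that("dwell-vs-length guards its inputs", {
  same <- list(`25` = rep(c(1, 2, 3), 20), `40` = rep(c(1, 2, 3), 20))
  dv <- dwell_vs_length(same, n_boot = 200, seed = 2)
  expect_false(dv$monotone_increasing)
  expect_error(dwell_vs_length(list(`25` = 1:10)), "2 duplex")
  expect_warning(
    dv2 <- dwell_vs_length(list(`25` = 1:10, `40` = 2:12,
                                `55` = numeric(0)), n_boot = 100, seed = 2),
    "empty")
  expect_equal(nrow(dv2$summary), 2)
})
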