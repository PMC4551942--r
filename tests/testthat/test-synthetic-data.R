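test_that("configuration invariants are enforced", {
  expect_error(sim_config(seed = 1, bound_fraction_true = 1.2), "0, 1")
  expect_error(sim_config(seed = 1, psf_sigma = 0), "psf_sigma")
  expect_error(sim_config(seed = 1, exposure = 0.1, acquisition = 0.05),
               "acquisition")
  expect_error(slide_kinetics(duplex_length = 1), "duplex_length")
  expect_error(slide_kinetics(enhancement = 0.9), "enhancement")
  expect_error(slide_kinetics(pife_range = 0.1), "window")
  expect_error(slide_kinetics(hop_rate = 0), "hop_rate")
  expect_equal(slide_kinetics()$pife_window_bp, 14L)  # 4 nm / 0.28 nm per bp
})

test_that("empty field is background only with an empty truth table", {
  cfg <- sim_config(seed = 4, n_protein_spots = 0L, fov_shape = c(64L, 64L))
  fov <- generate_fov(cfg)
  expect_equal(nrow(fov$truth), 0)
  # pure Poisson background: mean close to background_mean, no structure
  m <- fov$protein$frames[[1]]
  expect_equal(mean(m), cfg$background_mean, tolerance = 0.02)
})

test_that("bound_fraction_true = 1 co-locates every RNA spot", {
  cfg <- sim_config(seed = 5, n_protein_spots = 200L,
                    bound_fraction_true = 1, fov_shape = c(512L, 512L),
                    min_separation = 6)
  fov <- generate_fov(cfg, channel_offsets = c(107, 0))  # 1 px x-shift
  expect_equal(sum(fov$truth$bound), 200)
  expect_true(all(abs(fov$truth$x_rna - fov$truth$x - 1) < 1e-12))
  expect_true(all(fov$truth$y_rna == fov$truth$y))
})

test_that("identical seed gives bit-identical fields and a reproducible
           binomial bound count", {
  cfg <- sim_config(seed = 6, n_protein_spots = 1000L,
                    bound_fraction_true = 0.85, fov_shape = c(700L, 700L),
                    min_separation = 4)
  f1 <- generate_fov(cfg)
  f2 <- generate_fov(cfg)
  expect_identical(f1$protein$frames, f2$protein$frames)
  expect_identical(f1$rna$frames, f2$rna$frames)
  expect_identical(f1$truth, f2$truth)
  # the count is the seed-fixed binomial draw, near n * p
  expect_lt(abs(sum(f1$truth$bound) - 850), 3 * sqrt(1000 * 0.85 * 0.15) + 1)
})

test_that("infeasible packing under minimum separation fails explicitly", {
  cfg <- sim_config(seed = 7, n_protein_spots = 500L,
                    fov_shape = c(48L, 48L), min_separation = 10)
  expect_error(generate_fov(cfg), "min separation")
})

test_that("background photon statistics are Poisson", {
  cfg <- sim_config(seed = 8, n_protein_spots = 0L,
                    fov_shape = c(350L, 350L), background_mean = 100)
  px <- as.vector(generate_fov(cfg)$protein$frames[[1]])
  expect_gte(length(px), 1e5)
  # chi-square GOF against Poisson(100) on binned counts
  brks <- c(-Inf, stats::qpois(seq(0.1, 0.9, by = 0.1), 100), Inf)
  obs <- table(cut(px, brks))
  p <- diff(stats::ppois(c(-Inf, stats::qpois(seq(0.1, 0.9, by = 0.1), 100),
                           Inf), 100))
  expect_gt(stats::chisq.test(as.vector(obs), p = p / sum(p))$p.value, 0.01)
})

test_that("static and multimer traces have the prescribed step structure", {
  kin <- slide_kinetics(noise_sd = 0, bleach_lifetime = Inf, acquisition = 10)
  tr <- generate_pife_trace(kin, "static", seed = 9)
  expect_equal(range(tr$trace$intensity),
               rep(kin$baseline_intensity * kin$enhancement, 2),
               tolerance = 1e-9)
  expect_length(tr$trace$intensity, floor(10 / 0.03))

  kin2 <- slide_kinetics(noise_sd = 0, bleach_lifetime = 5, acquisition = 60)
  tm <- generate_pife_trace(kin2, "multimer", seed = 10, n_fluorophores = 2)
  x <- tm$trace$intensity
  drops <- which(diff(x) < -kin2$baseline_intensity / 2)
  expect_length(drops, 2)             # exactly two downward steps
  # at the recorded bleach times (within one frame)
  expect_equal(sort(tm$trace$time[drops]), sort(tm$truth$bleach_times),
               tolerance = 0.04)
  expect_error(generate_pife_trace(kin2, "multimer", seed = 1,
                                   n_fluorophores = 1), "n_fluorophores")
})

test_that("L = 2 sliding alternates two levels with Exp(k) sojourns", {
  kin <- slide_kinetics(duplex_length = 2L, pife_range = 0.28, hop_rate = 5,
                        noise_sd = 0, bleach_lifetime = Inf,
                        acquisition = 200, exposure = 0.002)
  expect_equal(kin$pife_window_bp, 1L)
  tr <- generate_pife_trace(kin, "sliding", seed = 12)
  lv <- sort(unique(round(tr$trace$intensity)))
  # intermediate frame values only at transitions; extremes are I0 and a*I0
  expect_equal(range(lv), c(500, 1125))
  # sojourn mean = 1 / k (exit rate k at a boundary site of the
  # self-loop reflecting walk)
  dwell <- diff(tr$truth$true_peak_times)
  expect_gt(length(dwell), 100)
  # dwell = in-window + out-of-window sojourn: mean 2/k
  expect_lt(abs(mean(dwell) - 2 / 5), 3 * stats::sd(dwell) / sqrt(length(dwell)))
})

test_that("long-run enhanced-level occupancy matches the chain solve", {
  kin <- slide_kinetics(duplex_length = 40L, hop_rate = 40, noise_sd = 0,
                        bleach_lifetime = Inf, acquisition = 300,
                        exposure = 0.01)
  tr <- generate_pife_trace(kin, "sliding", seed = 13)
  occ_sim <- mean(tr$truth$state_path <= kin$pife_window_bp)
  occ_theory <- walk_window_occupancy(40, 14)
  expect_equal(occ_theory, 14 / 40)   # uniform stationary law
  n <- length(tr$truth$state_path)
  # frames are correlated; allow a generous effective-sample-size factor
  se <- sqrt(occ_theory * (1 - occ_theory) / (n / 100))
  expect_lt(abs(occ_sim - occ_theory), 3 * se)
})

test_that("mean true peak interval matches the brute-force linear solve", {
  kin <- slide_kinetics(duplex_length = 10L, pife_range = 0.28, hop_rate = 20,
                        noise_sd = 0, bleach_lifetime = Inf,
                        acquisition = 120, exposure = 0.005)
  ivals <- unlist(lapply(1:4, function(s) {
    diff(generate_pife_trace(kin, "sliding", seed = 100 + s)$truth$true_peak_times)
  }))
  theory <- walk_mean_return(10, 1, 20)
  expect_equal(theory, 10 / 20, tolerance = 1e-10)  # closed form L / k
  expect_lt(abs(mean(ivals) - theory),
            3 * stats::sd(ivals) / sqrt(length(ivals)))
})

test_that("trace populations respect mixture weights and determinism", {
  kin <- slide_kinetics(acquisition = 1)   # short traces: labels are the point
  expect_error(generate_trace_population(c(sliding = 0.5), 10, kin, 1),
               "sum to 1")
  expect_error(generate_trace_population(c(bogus = 1), 10, kin, 1), "kind")
  expect_error(generate_trace_population(c(sliding = 1), 0, kin, 1),
               "positive")

  p1 <- generate_trace_population(c(sliding = 1.0), 50, kin, seed = 14)
  expect_true(all(p1$labels == "sliding"))

  p2 <- generate_trace_population(c(sliding = 0.7, static = 0.3), 10000,
                                  kin, seed = 15)
  f <- mean(p2$labels == "sliding")
  expect_lt(abs(f - 0.7), 3 * sqrt(0.7 * 0.3 / 10000))

  a <- generate_trace_population(c(sliding = 1.0), 1, kin, seed = 16)
  b <- generate_trace_population(c(sliding = 1.0), 1, kin, seed = 16)
  expect_identical(a$traces[[1]]$intensity, b$traces[[1]]$intensity)
  expect_identical(a$truth, b$truth)
})
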