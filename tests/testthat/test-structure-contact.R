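test_that("SASA matches closed forms for isolated and distant atoms", {
  a1 <- atom_set(rbind(c(0, 0, 0)), radii = 1.7)
  expect_equal(sasa(a1), 4 * pi * 3.1^2, tolerance = 1e-9)
  a2 <- atom_set(rbind(c(0, 0, 0), c(100, 0, 0)), radii = c(1.7, 1.52))
  expect_equal(sasa(a2), c(4 * pi * 3.1^2, 4 * pi * 2.92^2),
               tolerance = 1e-9)
})

test_that("overlapping pair matches the spherical-cap closed form within 2%", {
  for (d in c(2.0, 2.5, 3.5)) {
    at <- atom_set(rbind(c(0, 0, 0), c(d, 0, 0)), radii = c(1.7, 1.52))
    s <- sasa(at, probe_radius = 1.4, n_points = 960)
    R1 <- 3.1; R2 <- 2.92
    expect_lt(abs(s[1] - cap_exposed_area(R1, R2, d)) /
                cap_exposed_area(R1, R2, d), 0.02)
    expect_lt(abs(s[2] - cap_exposed_area(R2, R1, d)) /
                cap_exposed_area(R2, R1, d), 0.02)
  }
})

test_that("SASA converges: doubling test points changes totals < 0.5%", {
  set.seed(51)
  at <- atom_set(matrix(rnorm(150, sd = 4), ncol = 3),
                 radii = runif(50, 1.2, 1.8))
  s1 <- sum(sasa(at, n_points = 960))
  s2 <- sum(sasa(at, n_points = 1920))
  expect_lt(abs(s2 - s1) / s1, 0.005)
})

test_that("duplicate atom coordinates raise a degeneracy warning", {
  at <- atom_set(rbind(c(0, 0, 0), c(0, 0, 0)), radii = c(1.7, 1.7))
  expect_warning(sasa(at), "duplicate")
})

test_that("non-touching chain groups have zero contact area", {
  at <- atom_set(rbind(c(0, 0, 0), c(50, 0, 0)), radii = c(1.7, 1.7),
                 chains = c("A", "B"))
  expect_equal(contact_area(at, "A", "B"), 0, tolerance = 1e-9)
  expect_error(contact_area(at, "A", "C"), "nonempty")
})

test_that("contact area is symmetric, matches the grid oracle, and grows on
           approach", {
  toy <- two_chain_toy()
  ca <- contact_area(toy, "A", "B")
  expect_gt(ca, 0)
  expect_equal(contact_area(toy, "B", "A"), ca, tolerance = 1e-9)
  oracle <- contact_area_oracle(toy, "A", "B")
  expect_lt(abs(ca - oracle) / oracle, 0.03)
  # translating chain B toward A monotonically increases the interface
  shift_b <- function(dx) {
    t2 <- toy
    t2$x[t2$chain == "B"] <- t2$x[t2$chain == "B"] + dx
    t2
  }
  cas <- vapply(c(1.5, 0.5, 0), function(d) contact_area(shift_b(d), "A", "B"),
                numeric(1))
  expect_true(all(diff(cas) > 0))
})

test_that("multi-model coordinate files give per-model areas with mean and SD", {
  toy <- two_chain_toy()
  xyz1 <- as.matrix(toy[, c("x", "y", "z")])
  xyz2 <- xyz1
  xyz2[toy$chain == "B", 1] <- xyz2[toy$chain == "B", 1] + 0.4
  path <- tempfile(fileext = ".pdb")
  write_multimodel_pdb(path, list(xyz1, xyz2), toy$chain)
  models <- read_atom_set(path)
  expect_length(models, 2)
  expect_equal(nrow(models[[1]]), 20)
  res <- contact_area(models, "A", "B")
  expect_length(res$per_model, 2)
  expect_false(is.na(res$sd))
  expect_equal(res$mean, mean(res$per_model))
})

test_that("fully overlapped duplicate chains warn but return a value", {
  xyz <- matrix(rnorm(30, sd = 2), ncol = 3)
  at <- atom_set(rbind(xyz, xyz), radii = 1.6,
                 chains = rep(c("A", "B"), each = 10))
  expect_warning(ca <- contact_area(at, "A", "B"), "duplicate")
  expect_true(is.finite(ca))
})
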