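# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own algorithms.

# Exposed area of sphere 1 (radius R1) partially occluded by sphere 2
# (radius R2) at center distance d: spherical-cap closed form.
cap_exposed_area <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * R1^2)
  h <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h
}

# Grid-integration SASA oracle: deterministic latitude/longitude quadrature
# on each inflated sphere (equal-area latitude bands), independent of the
# package's Fibonacci-lattice construction.
sasa_grid_oracle <- function(atoms, probe = 1.4, n_lat = 48, n_lon = 96) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  R <- atoms$radius + probe
  n <- nrow(xyz)
  # equal-area bands: cos(theta) uniform
  ct <- seq(1 - 1 / n_lat, -1 + 1 / n_lat, length.out = n_lat)
  st <- sqrt(pmax(0, 1 - ct^2))
  lon <- seq(0, 2 * pi, length.out = n_lon + 1)[-1]
  dirs <- do.call(rbind, lapply(seq_len(n_lat), function(i)
    cbind(st[i] * cos(lon), st[i] * sin(lon), ct[i])))
  w <- 4 * pi / nrow(dirs)                      # equal weights by design
  areas <- numeric(n)
  for (i in seq_len(n)) {
    P <- sweep(dirs * R[i], 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, nrow(P))
    for (j in seq_len(n)) {
      if (j == i) next
      dd <- (P[, 1] - xyz[j, 1])^2 + (P[, 2] - xyz[j, 2])^2 +
        (P[, 3] - xyz[j, 3])^2
      exposed <- exposed & dd > R[j]^2
    }
    areas[i] <- R[i]^2 * w * sum(exposed)
  }
  areas
}

contact_area_oracle <- function(atoms, chains_a, chains_b, probe = 1.4) {
  ina <- atoms$chain %in% chains_a
  inb <- atoms$chain %in% chains_b
  sub <- function(keep) {
    s <- atoms[keep, , drop = FALSE]
    class(s) <- class(atoms)
    s
  }
  (sum(sasa_grid_oracle(sub(ina), probe)) +
     sum(sasa_grid_oracle(sub(inb), probe)) -
     sum(sasa_grid_oracle(sub(ina | inb), probe))) / 2
}

# Restricted mean of an exponential lifetime: E[min(X, t_max)], X ~ Exp(mean).
truncated_exp_mean <- function(mean_lifetime, t_max) {
  mean_lifetime * (1 - exp(-t_max / mean_lifetime))
}

# Noise-free square-wave trace alternating lo/hi with the given half-period
# (in frames); returns a pife_trace-compatible object.
square_wave_trace <- function(lo, hi, half_period, n_frames, exposure = 0.03) {
  lev <- rep(rep(c(lo, hi), length.out = 2 * ceiling(n_frames / half_period / 2)),
             each = half_period)[seq_len(n_frames)]
  structure(list(time = (seq_len(n_frames) - 1) * exposure, intensity = lev,
                 trace_id = "square", exposure = exposure),
            class = "pife_trace")
}

# A 20-atom two-chain toy complex with a genuine interface.
two_chain_toy <- function() {
  set.seed(11)
  a <- cbind(x = rnorm(12, 0, 1.5), y = rnorm(12, 0, 1.5),
             z = seq(0, 11) * 1.2)
  b <- cbind(x = rnorm(8, 3.8, 1.0), y = rnorm(8, 0.5, 1.0),
             z = seq(2, 9) * 1.2)
  atom_set(rbind(a, b), radii = c(runif(12, 1.5, 1.8), runif(8, 1.5, 1.8)),
           chains = c(rep("A", 12), rep("B", 8)))
}

# Minimal fixed-width writer for a tiny multi-model PDB fixture.
write_multimodel_pdb <- function(path, models, chains, element = "C") {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(models)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- models[[m]]
    for (i in seq_len(nrow(xyz))) {
      writeLines(sprintf(
        "ATOM  %5d  %-3s TOY %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        i, element, chains[i], i, xyz[i, 1], xyz[i, 2], xyz[i, 3], element),
        con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
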