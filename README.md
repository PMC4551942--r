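# smpife

Single-molecule pull-down and PIFE analysis for double-stranded RNA binding
proteins (dsRBPs).

dsRBPs (TRBP, Staufen1, ADAR1, ADAD2, ...) recognize the A-form helix of
double-stranded RNA largely independently of sequence. Two single-molecule
assays profile how they do it:

* **SiMPull** (single-molecule pull-down): the tagged protein is captured
  from lysate onto a passivated imaging surface; labeled RNA is added and
  both channels are imaged by TIRF microscopy. Counting protein spots and
  RNA-occupied protein spots gives a *bound fraction* per RNA substrate —
  a relative affinity readout.
* **smPIFE** (single-molecule protein-induced fluorescence enhancement): a
  dye on the RNA brightens ~2–2.5× whenever the protein is within ~4 nm.
  A protein diffusing along the duplex produces a fluctuating two-level
  intensity trace; an immobile one produces a constant enhanced level that
  ends in a photobleaching step.

`smpife` implements the full quantitative chain for both assays, plus the
statistics built on top of them, with a ground-truth synthetic data
generator so that every stage is testable without microscope data:

* spot detection (Laplacian-of-Gaussian, MAD-robust threshold, sub-pixel
  centroids), two-channel colocalization, bound fractions with Wilson 95%
  intervals, and saturation-curve fits `N(c) = Nmax·c/(c + c50)`;
* PIFE trace classification (sliding / static / rejected), photobleaching
  step counting by penalized change-point segmentation, peak-to-peak dwell
  times δt with censoring-aware bookkeeping, and Kaplan–Meier-corrected
  sliding durations;
* the structured/non-structured **affinity ratio** S/N (ratio of mean bound
  fractions; 1 = no bias toward either substrate class);
* the **avidity lower bound** for flexibly linked binding domains,
  `Kd_bound = Π Kd_i / c_ref^(n−1)` with a 1 mM effective reference
  concentration, and the independence gap `Kd_exp / Kd_bound`;
* buried solvent-accessible surface area (Shrake–Rupley) as the
  **contact area** `(SASA_A + SASA_B − SASA_AB)/2` between protein and RNA
  chains of a PDB model;
* a generator producing TIRF fields (Gaussian PSF spots over Poisson
  background, 16-bit TIFF) and PIFE traces (reflecting lattice random walk
  with a 14-bp proximity window, exponential photobleaching, Gaussian read
  noise) with JSON ground truth.

The sliding model is a nearest-neighbour continuous-time random walk on the
`L`-bp duplex with hop rate `k` per direction and reflecting ends. Its
stationary law is uniform, so the enhanced-level occupancy is `w/L`
(window `w = floor(4 nm / 0.28 nm per bp) = 14` bp) and the mean
peak-to-peak dwell time is the chain's mean first-return time to the
window, `L/k` — the package computes these independently of the simulation
by linear solves of the generator matrix (`walk_stationary()`,
`walk_mean_return()`), which the test suite uses as oracles.

## Worked example

```r
library(smpife)

# default study conditions: 2 fields x 150 spots at true bound fraction
# 0.85; 200 traces from a 70/30 sliding/static mixture, alpha = 2.25
rep <- run_pipeline(default_run_config(seed = 7))
print(rep)
#> pipeline report (seed 7 )
#>   bound fraction 0.850 (CI 0.805-0.886) from 300 protein spots
#>   sliding fraction 0.656 (101 sliding / 53 static / 46 rejected)
#>   avidity lower bound 2.49e-11 M
```

The pooled bound fraction (255/300 = 0.850, Wilson CI 0.805–0.886) recovers
the generator's truth of 0.85; the classified sliding fraction 0.656 sits
close to the 0.70 mixture weight (molecules that photobleach before three
level crossings are rejected as ambiguous rather than miscounted). The
avidity line is the two-domain worked example:

```r
bound <- avidity_lower_bound(c(113e-9, 220e-9))   # single-domain Kd values
as.numeric(bound) * 1e12
#> [1] 24.86                                        # pM
independence_gap(250e-12, as.numeric(bound))
#> experimental / predicted Kd = 10.1 (domains not fully independent)
```

A measured Kd an order of magnitude above the full-independence product
means the two domains do not engage the RNA independently.

A command-line front end over the same functions is installed at
`inst/cli/smpife.R` (subcommands `simulate`, `count`, `traces`, `models`,
`contact`, `run`, `fixtures`), e.g.

```sh
Rscript inst/cli/smpife.R models --kd 113e-9,220e-9 --experimental-kd 250e-12
Rscript inst/cli/smpife.R run --config run_config.yaml --out out/
```

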