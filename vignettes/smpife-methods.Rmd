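---
title: "Models and methods behind smpife"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smpife}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smpife)
```

`smpife` analyzes the two single-molecule assays used to profile
double-stranded RNA binding proteins — pull-down spot counting (bound
fractions) and protein-induced fluorescence enhancement traces (sliding
kinetics) — together with the statistics layered on top of them and a
synthetic-data generator that provides ground truth for every stage. This
vignette describes the underlying models, the parameters that matter and
their defaults, the numerical choices, and what the package's passing tests
do and do not establish about real microscope data.

## The synthetic field model

A pull-down field of view is modeled as `n` point emitters at uniformly
random sub-pixel positions (optionally with a minimum separation,
filled by rejection sampling with a bounded retry budget and an explicit
failure when packing is infeasible). Each emitter is an isotropic 2D
Gaussian of width `psf_sigma` (default 1.3 px — a diffraction-limited PSF
at a typical ~107 nm/px TIRF magnification) and peak amplitude
`spot_amplitude` (default 800 counts) on a uniform background
(default 100 counts). Photon counting is emulated by Poisson-sampling the
expected image, so a field with zero amplitude is exactly
`Poisson(background_mean)` pixel noise — a property the test suite checks
by a chi-square goodness-of-fit on more than 10^5 pixels.

A Bernoulli(`bound_fraction_true`) subset of protein spots carries a
co-located spot in the RNA channel, shifted by the known inter-channel
registration offset. The default true bound fraction of 0.85 represents a
strong binder (bound fractions in the 80–90% range); two fields of 150
spots are the default field density, typical of a well-loaded
single-molecule surface. The camera model is Poisson background plus
Gaussian read noise on traces; no EM-gain register statistics, stage
drift, or defocus are simulated.

## The sliding trace model

The PIFE geometry is reduced to one dimension: the protein is anchored,
and the RNA duplex register performs a nearest-neighbour continuous-time
random walk on `L` lattice sites (one per base pair) with hop rate
`k_hop` per direction and reflecting ends. The dye at the duplex end is
enhanced whenever the register lies within the proximity window of
`floor(pife_range / rise_per_bp)` sites. Defaults: `pife_range = 4` nm
(the distance scale over which PIFE responds sharply), A-form rise
0.28 nm/bp, hence a 14-bp window; enhancement `alpha = 2.25`, the midpoint
of the characteristic 2–2.5-fold band; `L = 40` bp and `k_hop = 40`/s,
which give a mean peak-to-peak dwell time `L/k = 1` s, the second-scale
periodicity seen in sliding traces.

Three modeling decisions deserve emphasis:

* **Binary distance gating.** Enhancement is all-or-none inside the
  window. Only a range bound is known for PIFE's distance response, so
  the simplest model consistent with sharp distance sensitivity is used;
  no continuous distance–intensity law is assumed.
* **Reflection as rejection.** At a boundary site, a step off the lattice
  is a self-loop (the move is rejected). This convention makes the
  stationary law exactly uniform, so the enhanced-level occupancy is
  `w/L` and the mean first-return time to the window is `L/k`; both are
  computed independently by linear solves of the generator matrix
  (`walk_stationary()`, `walk_mean_return()`) and used as oracles in the
  tests. Under the alternative "bounce" convention the stationary law
  would not be uniform, which would contradict the occupancy identity.
* **Frame integration.** A camera frame (default 30 ms exposure, 60 s
  acquisition) records the time-weighted mixture of the levels occupied
  during the exposure; per-frame point sampling is available via
  `frame_integration = FALSE`. Integration produces the partial-step
  frames that real cameras produce, which several analysis steps must
  (and do) tolerate.

Photobleaching is exponential with mean `bleach_lifetime` (default 30 s,
so that a 60-s acquisition loses a realistic share of molecules to
bleaching). An optional exponential `slide_lifetime` lets a molecule stop
sliding and freeze at its current level, which is how uncensored sliding
durations arise; by default molecules slide until they bleach. Static
traces hold `alpha * I0` until bleaching; multimeric spots superpose `k`
unit-brightness fluorophores with independent bleach times; unbound traces
are background only. Read noise is Gaussian (default sd `I0/10`).

Dye blinking is deliberately absent, and the classifier is accordingly
blinking-naive: a real trace with long dark states would be segmented at
the blink, not recognized. The true dye–protein geometry on structured
RNAs (pre-let7-like stems, bulged hairpins, tRNA-like folds) is unknown;
only duplex-lattice geometry is modeled, so structured-substrate PIFE
traces are outside the generator's scope.

## Spot counting

Detection is Laplacian-of-Gaussian at the PSF scale: the frame is
convolved (FFT) with a scale-normalized, sign-flipped LoG kernel, local
maxima above `median + snr_threshold × MAD` of the response are kept
(default threshold 5 robust SDs; a small numerical floor keeps FFT
ringing out of noise-free frames), maxima closer than `2·psf_sigma` are
merged to the brighter one, and positions are refined by a 3×3 intensity
centroid. Saturated frames are flagged, never clipped. On generator
fields with SNR ≥ 8 and spots separated by ≥ 4 PSF widths, recall and
precision both exceed 0.95 (tested over several seeds).

Colocalization is greedy nearest-neighbour matching within a radius
(default 2 px) after correcting the known channel registration offset;
ties break by smaller distance, then lower spot index, and each spot
matches at most once. The bound fraction is the pooled ratio of matched
to protein spots across fields of view, with a Wilson score interval —
chosen over the Wald interval because per-field counts can be small. The
per-field breakdown and the mean of per-field fractions (an alternative
summary sometimes used as a per-field-average proxy) are both retained.
Saturation of spot counts against applied concentration is fit as
`N(c) = Nmax·c/(c + c50)` by Levenberg–Marquardt least squares, with a
poor-fit flag at R² < 0.5.

## Trace analysis

**Segmentation.** All step analysis rests on penalized least-squares
change-point segmentation (binary segmentation; a split is accepted when
it reduces the residual sum of squares by more than
`3·sigma²·log(n)`, with `sigma` the difference-MAD robust noise). A level
change that falls inside a frame leaves one intermediate-valued frame,
which the segmentation may isolate; such monotone "staircase" segments of
at most 2 frames are camera artifacts and are removed before steps are
counted.

**Photobleaching steps** are downward level changes exceeding 3 robust
SDs. Near-coincident bleach events merge into one large drop; since a
uniformly labeled sample has one unit brightness per fluorophore, drops
are divided by the smallest significant drop and rounded
(`quantize = TRUE`), which resolves merged double steps. The counter
recovers 1–3 fluorophores with ≥ 95% accuracy at noise up to `I0/8`. The
trace's bleach point is the start of the trailing run of
background-level segments; traces that never reach background are flagged
unbleached.

**Classification.** The pre-bleach segment is fit with two levels
(1D k-means seeded deterministically at the quartiles). A trace is
*sliding* when the level ratio lies in the PIFE band
(`ratio_min = 1.5` to `ratio_max = 3.5`), the gap is resolvable
(> 4 robust SDs), and the trace makes at least `min_transitions = 3` full
crossings (level-assignment runs shorter than 2 frames are collapsed so
single-frame noise excursions do not count). A trace is *static* when it
sits at one level with coefficient of variation below `cv_max = 0.15` —
but only if it was observed for at least `static_min_span = 8` s before
bleaching. This asymmetry is deliberate: a sliding call is positively
evidenced by crossings, whereas a static call asserts their absence,
which a short trace cannot establish. Without it, molecules that
photobleach before their third crossing are silently counted as static
and the recovered sliding fraction of a 70/30 mixture drops from ~0.68
to ~0.59. Everything else — including short quiet traces and traces whose
two fitted levels sit outside the PIFE band — is *rejected*, and sliding
fractions are computed over classified (non-rejected) molecules only,
mirroring the usual practice of quality-filtering single-molecule traces.

**Dwell times.** After moving-average smoothing (default 5 frames =
150 ms, fast relative to the second-scale periodicity of sliding traces;
edge windows shrink rather than pad), every contiguous episode above the
midpoint of the two fitted levels is one enhancement peak (its maximum
necessarily exceeds the lower level by half the gap, the prominence
floor); the peak time is the episode maximum. δt values are successive
peak-time differences; the trailing interval to bleach or acquisition end
is returned separately as censored and excluded from δt lists.

**Sliding durations.** A sliding segment runs from the trace start
(molecules are already bound when acquisition begins) to the last level
crossing. It is flagged censored when the trace was plausibly still
fluctuating at its stop time — when the quiet tail is shorter than twice
the median inter-crossing interval. Both the naive mean duration and a
Kaplan–Meier mean restricted to the acquisition window (via the
`survival` package) are reported: photobleaching and the 60-s acquisition
limit truncate observed durations, so the naive mean is biased downward,
and the KM estimate moves it toward the truncated-lifetime expectation.
Two caveats are inherent and worth stating: trace selection is itself
biased (molecules whose sliding ends very early tend to be classified
static or rejected), and at 30-ms resolution the quiet-tail lengths of
censored and genuinely ended traces overlap, so censoring flags are
imperfect. The tests therefore check the direction and improvement of the
correction (KM closer than naive to the closed-form truncated mean), not
exact recovery. Both the per-trace total of sliding episodes and the
longest single episode are summarized, since either convention may be
wanted.

**Length dependence.** `dwell_vs_length()` summarizes δt per duplex
length with seeded bootstrap CIs and tests adjacent lengths by one-sided
Mann–Whitney. One property of the generator matters when interpreting
this test: measured δt sets are heavy-tailed mixtures of short
window-boundary flickers (whose median is length-independent) and rare
deep excursions (which carry the length dependence in the mean), so
rank-based tests are insensitive here even when the means are clearly
ordered; the acceptance check of the length trend therefore asserts
strictly increasing means with separated bootstrap CIs.

## Resolution limits of dwell extraction

With exponential sojourns, arbitrarily short window entries and exits
always exist, and any finite exposure merges some of them. At the default
30-ms exposure roughly two-thirds of entry events of the default kinetics
are unresolvable, inflating measured mean δt several-fold over the
chain's mean first-return time; this is a property of the binary-gated
lattice model (real sliding traces show cleaner second-scale
oscillations), not of the extraction code. Consistency between the
extractor and the chain oracle is therefore verified in a
resolution-adequate regime — 1–2 ms exposure, no noise, unit smoothing —
where the measured mean matches the linear-solve first-return time within
Monte-Carlo error, and with long acquisitions (240 s) for the
length-dependence check so that the deep-excursion tail, which dominates
the mean at `L = 55`, is actually sampled. A related scaling argument
shows that exact frame-level agreement between detected and true peak
sequences is unattainable for the stochastic model at any exposure
(the merging bias is itself proportional to the exposure), so exactness
is asserted on noiseless periodic traces and statistical agreement on
stochastic ones.

## Binding models

The **affinity ratio** S/N is the mean bound fraction over structured
substrates divided by the mean over simple duplexes; 1 means no
class bias. Its CI is a seeded nonparametric bootstrap over class
members; the reciprocal identity `S/N × N/S = 1` and exact neutrality at
equal means are tested.

The **avidity lower bound** treats flexibly linked binding domains as
fully independent, multiplying single-domain dissociation constants and
referencing each tether by an effective local concentration:
`Kd_bound = prod(Kd_i) / c_ref^(n-1)`. The reference defaults to 1 mM,
the effective-concentration scale of a domain held by a ~60-residue
flexible linker; with the two TRBP domain constants (113 nM and 220 nM)
it gives 24.86 pM, and a measured 250 pM for the linked construct sits an
order of magnitude (10.06×) above that bound — the signature of
domains that are not fully independent. A 1 M reference would make the
two-domain product 24.9 fM, three orders stronger, which corresponds to
no physically meaningful tethered geometry; making the reference explicit
both fixes the unit analysis of the product rule and generalizes it to
n domains. The bound is permutation-symmetric and strictly tightens with
each added domain stronger than the reference — both tested properties.

## Contact areas

Solvent-accessible surface area is computed by Shrake–Rupley: each atom's
van der Waals sphere (C 1.7, N 1.55, O 1.52, P 1.8, S 1.8, H 1.2 Å;
unknown elements 1.7 Å) is inflated by the probe radius (default 1.4 Å,
water) and covered with `n_points = 960` Fibonacci-lattice test points; a
point is exposed iff it lies outside every other inflated sphere. The
implementation is validated against the isolated-sphere and two-sphere
spherical-cap closed forms (within 2%) and an independent
latitude–longitude grid quadrature (within 3% on a two-chain toy), and
doubling the point count changes totals by under 0.5%. The contact area
between chain groups A and B is `(SASA_A + SASA_B − SASA_AB)/2`;
multi-model PDB files (e.g. trajectory snapshots) give per-model areas
with mean ± SD. Duplicate atom coordinates trigger a degeneracy warning
but still return a value. No force-field energies are computed.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → count → traces → models under a single
root seed; every stochastic stage derives its own seed deterministically
from the root seed and the stage name, so any stage can be reproduced in
isolation and a rerun is byte-identical. The demo configuration
(2 × 150-spot fields at bound fraction 0.85; 200 traces of a 70/30
sliding/static mixture) runs in well under a minute on one core. Problem
sizes used by the test suite — e.g. 100 pipeline replicates for the
Wilson-interval calibration, 2000 traces for mixture recovery, ~500
dwell intervals for the first-return comparison — were chosen as the
smallest sizes at which the statistical assertions have comfortable
power.

One calibration subtlety: the Wilson interval's exact coverage at
`p = 0.85` oscillates with n and peaks near 0.958 for realistic pooled
spot counts, so a 100-replicate calibration check at a "≥ 95 of 100"
bar is near its own operating point; the chosen field size (2 × 150
spots) sits at a coverage-favourable n.

## Known limitations

* The generator's binary PIFE gating and lattice geometry are the
  simplest models consistent with the distance-sensitivity and
  enhancement ranges; passing tests demonstrate internal consistency of
  generator and analysis, not accuracy of either on real traces.
* No blinking, FRET, drift, defocus or EM-gain statistics are simulated;
  the classifier is blinking-naive.
* Censoring detection for sliding durations is heuristic and imperfect at
  30-ms resolution (overlapping quiet-tail distributions); the KM
  correction reduces, but does not remove, truncation bias.
* Structured-RNA dye geometry is not modeled; only duplex substrates are
  simulated.
* The avidity bound is a lower bound under full independence with an
  assumed 1 mM effective concentration; it is a comparison point, not a
  prediction of measured affinity.
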