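---
title: "Models and methods behind the duotune noise pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the duotune noise pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duotune)
```

`duotune` pairs a generative model of bicistronic autoregulated expression
circuits with the cytometry analysis chain used to characterize them:
density gating on scatter, density estimation on log-spaced bins, gamma
fitting by least squares, and control-strain background subtraction. This
vignette explains the models, the numerical choices, and what the
synthetic data can and cannot tell you about real measurements.

## The circuit model

A cell carries `N` copies of a plasmid expressing a reporter G (and, in
the autoregulated mode, the repressor from the same mRNA). The
deterministic skeleton uses two Hill functions:

* inducer inactivation, ρ(I) = 1 / (1 + (I/K~d~)^h~I~) — the fraction of
  repressor still able to bind its operator at inducer concentration I;
* promoter repression, a(R) = basal + (1 − basal) / (1 + (R/K~R~)^h~R~) —
  per-copy activity at active-repressor level R.

In **constitutive** mode the repressor pool is fixed at R₀ and
G_det = N·α·a(R₀·ρ(I)). In **autoregulated** mode the repressor is
produced in proportion r to the reporter (the bicistron), so G_det solves

> G = N · α · a(r · G · ρ(I)).

The right-hand side is strictly decreasing in G, so the fixed point is
unique and bracketed by [0, N·α]; `steady_state_reporter()` finds it with
`stats::uniroot()` at tolerance `1e-10 · N·α`, solved once per distinct
copy number. The test suite cross-checks the solver against an independent
bisection oracle to 1e-8 relative over a 100-point random parameter sweep.

Autoregulation is what produces *dosage compensation*: in the
strong-repression limit (basal = 0, h~R~ = 1) the fixed point approaches
G ≈ √(N·α·K~R~/r), so the elasticity d log G / d log N approaches 1/2,
while the constitutive circuit has elasticity exactly 1. Halving the copy
number therefore drops the mean far less with feedback than without —
the qualitative behavior measured when a circuit is moved from a
medium-copy (p15A-like, `N_mean = 10`) to a low-copy (pSC101-like,
`N_mean = 4`) backbone.

### Stochastic layers

* **Copy number** — negative binomial with mean `N_mean` and
  variance/mean `N_disp` (default 2), floored at 1 because a transformed,
  antibiotic-selected cell carries at least one plasmid. `N_disp ≤ 1`
  falls back to Poisson and `N_disp = 0` gives a constant copy number.
  No copy-number measurements exist for these constructs; these are
  conventional overdispersed defaults.
* **Intrinsic noise** — G ~ Gamma(shape = G_det/b, scale = b) with burst
  size `b` (default 10 proteins). The gamma burst approximation (rather
  than a kinetic simulation) matches the analysis pipeline's own working
  assumption that single-cell distributions are gamma-like; no kinetic
  rates are available to parameterize anything finer.
* **Extrinsic noise** — a lognormal cell-size factor `s` with mean exactly
  1 and CV² `size_cv2` (default 0.05, a typical extrinsic contribution for
  exponentially growing *E. coli*) multiplies every channel of a cell.
  `burst = 0` and `size_cv2 = 0` are supported as exact deterministic
  limits; the closed-form tests rely on them.

### Regulator defaults

ATc binds TetR about three orders of magnitude more tightly (in molar
terms) than IPTG binds LacI. The defaults encode this by working in each
inducer's natural unit: `tetr_circuit()` has `Kd_I = 10` on an nM scale
with h~I~ = 2 (two ATc per TetR dimer), `laci_circuit()` has `Kd_I = 10`
on a µM scale with h~I~ = 1.3 (weak effective cooperativity). The standard
ladders are 1–125 nM ATc and 0–1250 µM IPTG (ten doses).

## The measurement model

`simulate_flow_sample()` maps cells to cytometer events:

* fl1 = (G · maturation + autofluorescence · s) · (1 + ε),
  ε ~ N(0, `instrument_cv`);
* FSC area and SSC height proportional to `s` with channel-specific
  multiplicative noise (defaults 15% and 25%), which reproduces the
  weak scatter–fluorescence correlation through cell size;
* maturation fractions default to 1 − exp(−60/τ) for a 60-minute
  translation-arrest chase with τ = 5.6 min (GFP-like) and τ = 25.7 min
  (RFP-like): 0.99998 and 0.903;
* a `debris_fraction` (default 2%) of events is replaced by small dim
  particles — exponential fluorescence around `debris_scale` (20 AU) and
  a sub-cellular scatter mode — emulating the low-fluorescence stragglers
  that escape gating in real data;
* a control sample (`simulate_control_sample()`) is the same measurement
  applied to a zero-reporter population: autofluorescence only.

Every generator call seeds one RNG (`set.seed(seed)`) and draws in a
fixed, documented order, so identical arguments are bit-reproducible.

## Density gating

`density_gate()` retains the fraction of events nearest the mode of the
2D histogram of (log₁₀ FSC area, log₁₀ SSC height). Numerical choices,
none of which are dictated by the protocol the gate reproduces:

* 64 × 64 bins, equal width in log₁₀, spanning the central 99.9% of each
  channel; out-of-range events are clamped into edge bins. Log axes were
  chosen because scatter spans decades; whether the original gate used
  linear or log axes is not recorded.
* The histogram is smoothed with a separable truncated-Gaussian kernel
  (σ = 1 bin, radius 4σ) with edge renormalization so border bins are not
  artificially deflated; smoothing stabilizes the mode against bin noise.
* Whole bins are retained in decreasing smoothed-density order; inside the
  one boundary bin, events are taken in ascending row order until the
  count equals `round(target_fraction · n)` exactly. This makes the
  retained *count* deterministic and the retained *set* stable up to the
  boundary-bin tie class under row permutation.
* Events with nonpositive scatter cannot be log-binned; they are routed to
  an underflow class and never retained. Degenerate inputs (all events in
  one bin) retain the first `round(f·n)` rows and flag the result.

## Log-binned density and the gamma fit

`log_binned_pdf()` drops nonpositive values (they arise in
background-subtracted or noisy channels), requires at least 100 positive
values, and bins the rest on `n_bins = 48` bins spaced evenly in log space
over the full used range, reporting density per linear AU
(count / (n·width)), which integrates to 1 exactly. Bin centers are
geometric midpoints. All-equal input is refused rather than fit as a point
mass.

`fit_gamma()` minimizes the squared difference between the binned density
and a gamma density at the bin centers, by Levenberg–Marquardt
(`minpack.lm::nls.lm`) over log-parameters, bounded to
k, θ ∈ (10⁻⁶, 10⁹), initialized from method-of-moments on the binned
density. On non-convergence the moment initializer is returned flagged;
the caller decides.

The residuals are **Poisson-weighted**: each bin's squared residual is
divided by the squared standard error of its density estimate,
s_b = √max(count, 1) / (N·w_b). This choice is load-bearing. On
log-spaced bins the lowest bins are narrow in linear units and hold only
a handful of events; their density estimates carry errors as large as the
density itself, and the single smallest event always occupies a
vanishing-width first bin whose spurious density spike can exceed the true
maximum several-fold. An unweighted fit lets those few bins dominate —
for near-exponential samples (shape ≈ 1) it can chase the spike to a
degenerate optimum — while the weighted fit keeps every bin's influence
proportional to its information content. The oracle-equivalence suite
(fitted mean and variance vs method-of-moments on clean gamma samples,
n = 10⁵, shapes 1–50) holds at 5% only with the weighting.

Fitting the density instead of averaging events is also what confers
robustness: sparse low-value contaminant events occupy low-count bins
with little weight, so the fitted mean moves less than the plain sample
mean. The suite asserts this with 2% contamination at 1% of the mean.

## Expression metrics

* The **control background** is the plain mean of the density-gated
  control-sample fluorescence, not a gamma fit: only the first moment is
  subtracted, the control distribution is a narrow instrument-noise peak
  (for which a 48-bin log-range fit spanning stray debris decades is
  ill-posed), and the scatter gate already removes the debris mode.
* **CV² = fitted variance / background-subtracted mean²**. The choice of
  the *subtracted* mean in the denominator (the variance is left
  unadjusted) is flagged in the output; with background ≪ signal the two
  conventions agree closely, and the result is flagged undefined whenever
  the subtracted mean is nonpositive.
* **Dose response** averages replicates (with SEM) per condition; the
  dynamic range is max/min of the mean over *nonzero* doses — the
  zero-inducer condition is reported separately since it cannot sit on a
  log axis.
* **Backbone comparison** computes 100·(1 − mean_low/mean_high) per
  matched condition, then averages with SEM over conditions.
* **Crosstalk** on a complete (ATc × IPTG) grid: per channel and per
  own-inducer level, the spread (max − min) of the replicate-averaged
  mean across the *other* inducer's levels, relative to the mean at that
  row's lowest other-inducer level, maximized over own levels. The
  baseline denominator makes a doubling score exactly 1; channels are
  declared independent at tolerance 0.05, a choice made here since only
  graphical evidence of independence exists.

## Synthetic microscopy

`simulate_image()` renders cells as randomly placed, non-overlapping
ellipses (defaults: semi-axes 11 × 4 px at 100 nm/px, a rod-like *E. coli*
footprint; linear dimensions scale with √s so area tracks cell size).
Pixels inside a cell hold the reporter *concentration* (G/s, times
`conc_scale`) plus a diffuse unbound-protein level, so mean intensity is a
concentration proxy and integrated intensity a total-protein proxy — with
size variation on, the concentration CV² is strictly the smaller of the
two, and the suite checks precisely that ordering. Single-mRNA spots add
2D Gaussians (PSF σ = 1.3 px, truncated at 5σ) integrating to
fluorophores × `photon_scale`; a 24-tandem-site mRNA bound by dimeric coat
protein carries up to 48 fluorophores, and the rendered kernel integral is
verified to 0.1%. Intensities are calibrated as photons: optional Poisson
shot noise precedes the camera offset and Gaussian read noise. Shot noise
is not ornamental — a flat unbound background raises the in-cell
background *SD* only through photon statistics, and that is what makes
spot SNR fall as unbound protein rises, the behavior the sweep test
checks. Coordinates are 1-based R matrix indices (row, col) with pixel
centers at integers.

`quantify_cells()` implements the mask protocol: per-label mean intensity
minus the mean of a cell-free region (the largest connected background
component if it has ≥ 1000 px, else all unmasked pixels — the reference
protocol never defined this region geometrically). `spot_snr()` scores
(peak − local background mean) / SD(local background) in an annulus of
4–7 PSF σ around the spot, intersected with the cell and excluding all
spot cores; at 3σ a bright spot's own tail still inflates the background
SD by tens of percent, which is why the inner radius is 4σ. Too-small
annuli are widened to the whole cell and flagged.

## Problem sizes and determinism

The shipped tests run the full chain at the study scale (30,000 events
per sample; 10-dose × 3-replicate pipelines; 10⁵-draw fit oracles;
1024² px images with 150–200 cells) and complete in well under a minute
in total. `run_pipeline()` derives every per-sample seed from the config
seed by fixed offsets and logs all of them plus the full configuration to
a JSON sidecar; rerunning an identical config reproduces the summary CSV
byte for byte.

## What the generator does not capture

The synthetic data reproduce the *statistical structure* the analysis
assumes — gamma-like marginals, multiplicative size variation,
autofluorescence background, debris, weak scatter–fluorescence coupling —
not the biology or instrument in full. There is no kinetic (Gillespie)
simulation, no cell-cycle or partitioning noise, no plasmid
incompatibility or growth-rate coupling, no spectral spillover, and
fluorophore maturation is a scalar fraction rather than a process. Passing
tests therefore validate the *pipeline* (its estimators, invariances and
contracts) and the circuit model's qualitative claims (dosage
compensation, monotone induction, two-channel independence); they do not
certify parameter values against any real instrument. Cell segmentation
is likewise out of scope: masks are ground truth by construction, matching
a workflow in which segmentation was manual.
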