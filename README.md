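# duotune

Synthetic single-cell gene-expression circuits and the cytometry noise
pipeline that quantifies them.

## The problem

Plasmid-borne expression systems in which a repressor (TetR or LacI) is
translated *bicistronically* with the gene of interest, from the very
promoter the repressor shuts off, give negative autoregulation on both
proteins. Such circuits buffer plasmid copy-number fluctuations ("dosage
compensation"), linearize the inducer dose response, and keep cell-to-cell
expression noise below the extrinsic noise limit (CV² ≈ 0.1) seen for
chromosomal genes. Two such circuits with orthogonal regulators
(TetR/ATc on one origin, LacI/IPTG on a compatible origin) allow
independent, low-noise tuning of two genes in the same *E. coli* cell.

Quantifying these claims from flow cytometry requires a specific analysis
chain: density-gate events on scatter to select typical-size cells,
estimate the fluorescence probability density on log-spaced bins, fit a
gamma density by least squares, and subtract the mean of a non-fluorescent
control strain. `duotune` implements both halves at desk scale:

* **Generators** — a parametric circuit model (Hill repression, inducer
  inactivation, autoregulation fixed point, negative-binomial plasmid copy
  number, gamma burst noise, lognormal cell size), a cytometer measurement
  model (autofluorescence, maturation, instrument noise, scatter channels,
  debris events), and a fluorescence-microscopy image synthesizer with
  diffraction-limited single-mRNA spots.
* **Analysis** — 2D scatter density gating, log-binned density estimation,
  Poisson-weighted least-squares gamma fits, background-subtracted means,
  CV² noise, dose-response / backbone / two-channel crosstalk summaries,
  mask-based image quantification, and spot signal-to-noise scoring.

## The model in brief

Active repressor fraction under inducer I: ρ(I) = 1 / (1 + (I/K_d)^h_I).
Per-copy promoter activity under active repressor R: a(R) = basal +
(1 − basal) / (1 + (R/K_R)^h_R). With N plasmid copies and gain α, a
constitutive circuit expresses G = N·α·a(R₀·ρ); an autoregulated bicistron
solves the fixed point G = N·α·a(r·G·ρ(I)), which is unique because the
right-hand side decreases in G. Intrinsic noise enters as a gamma burst law
G ~ Gamma(G_det/b, b), and a lognormal size factor (mean 1, CV² = 0.05 by
default) multiplies all channels of a cell. Measured noise is
CV² = σ²/μ², with μ and σ² taken from the gamma fit and μ
background-subtracted.

## Worked example

Simulate one ATc-induced sample of a TetR-autoregulated p15A-like circuit,
measure 30,000 events, and run the full analysis chain:

```r
library(duotune)

circ <- tetr_circuit()                      # p15A-like, ATc-inducible
meas <- measurement_params()                # 30,000 events, 2% debris
pop  <- simulate_population(circ, inducer = 25, n_cells = 30000, seed = 1)
ev   <- simulate_flow_sample(pop, meas, seed = 2, sample_id = "atc25",
                             atc_nM = 25)
ctrl <- simulate_control_sample(meas, seed = 3)

gate <- density_gate(ev, target_fraction = 1/3)
gate
#> <gate_result> retained 10000 events (0.3333 of total; target 0.3333)

fit_sample_gamma(ev$fl1_area[gate$retain])
#> <gamma_fit>
#>   shape k = 17.676  scale theta = 67.461
#>   mean = 1192.5  variance = 80444  CV^2 = 0.056573

bg <- control_mean_from_events(ctrl)        # 98.42 AU autofluorescence
s  <- summarize_sample(ev, control_mean = bg, gate = gate)
round(s$mean_bgsub, 1)
#> [1] 1094
round(s$cv2, 4)
#> [1] 0.0672
```

The gate keeps exactly one third of the events; the fitted,
background-subtracted mean (1094 AU) recovers the simulated ground-truth
mean reporter level (1104 AU) within 1%, and the measured noise
(CV² = 0.067) sits below the extrinsic noise limit of 0.1 — the burst
(1/k ≈ 0.009), cell-size (0.05) and instrument (0.0025) contributions in
the generator's budget.

An entire experiment (ladder × replicates, with per-replicate controls) is
one call:

```r
cfg <- run_config(regulator = "lacI")   # 10-dose IPTG ladder, 3 replicates
res <- run_pipeline(cfg, outdir = "out")   # summaries.csv + run_log.json
dose_response(res)
```

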