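# isokin

Turnover kinetics of free amino acids from continuous ¹⁵N stable-isotope
labeling measured by LC-MS.

When a plant (here, duckweed growing on ¹⁵N-salts medium) is fed heavy
nitrogen, each free amino-acid pool progressively replaces its ¹⁴N with ¹⁵N.
Tracking the *unlabeled* isotopologue — the M0 fraction of the isotopic
envelope — over time gives a compact readout of pool turnover. Most pools do
not label to completion: the M0 fraction decays to a plateau, interpreted as
a metabolically inactive sub-pool (e.g. vacuolar storage). `isokin`
implements the full analysis for this kind of experiment, for metabolomics
researchers running labeling time courses under contrasting growth
conditions (mixotrophic, photoautotrophic, heterotrophic):

- **Isotopologue masses** — monoisotopic masses from elemental formulas and
  the ¹⁵N isotopologue m/z ladder (spacing 0.997035 Da; ¹³C species are
  deliberately not targeted).
- **Extraction** — per-isotopologue extracted ion chromatograms from mzML
  (via Bioconductor's `mzR`), trapezoidal integration over fixed retention
  windows, and the M0 fraction of each envelope.
- **Kinetics** — the plateau-exponential model

  M0(t) = (1 − c)·e^(−kt) + c

  fitted jointly to all replicates by bounded nonlinear least squares
  (k ≥ 0, 0 ≤ c ≤ 1), where k (h⁻¹) is the turnover constant and c the
  labeling plateau.
- **Pools and flux** — pool sizes from time-zero samples against a fully
  labeled internal standard (μmol/mg extract residue), active pools
  P·(1 − c), and turnover-adjusted pools f = k·P (μmol/mg/h, a
  flux-dimension quantity for cross-amino-acid comparison).
- **Clustering** — Hartigan–Wong k-means of labeling trajectories (0–32 h)
  and of flux values, with an explicit between/total sum-of-squares rule
  for choosing k, and per-cluster decay refits.
- **Statistics** — pairwise condition comparisons by two-tailed t tests,
  Welch by default, pooled-variance where an F test indicates equal
  variances.
- **Synthetic data** — a generator that emulates the whole experiment
  (binomial ¹⁵N envelopes, replicate noise, internal-standard spikes,
  optional mzML rendering), used throughout the tests for parameter
  recovery.

## Worked example

Simulate a light-with-sucrose experiment (3 replicates, published
reference kinetics as truth), fit every amino acid, and estimate pools:

```r
library(isokin)

cfg  <- sim_config(conditions = "light_sucrose", n_replicates = 3L)
sim  <- simulate_dataset(cfg, seed = 42)
fits <- fit_all(sim$observations)
head(fits[!fits$excluded, c("code","condition","k","se_k","c","se_c","converged")], 5)
#>   code     condition      k   se_k     c   se_c converged
#> 1    A light_sucrose 0.8378 0.0403 0.119 0.0106      TRUE
#> 2    D light_sucrose 0.3276 0.0230 0.279 0.0178      TRUE
#> 3    E light_sucrose 0.8312 0.0445 0.172 0.0111      TRUE
#> 4    F light_sucrose 0.3375 0.0311 0.326 0.0217      TRUE
#> 5    G light_sucrose 0.0874 0.0110 0.204 0.0590      TRUE
```

Alanine was simulated with k = 0.85 h⁻¹, c = 0.13 and noise sd 0.02 on the
M0 fraction; the fit recovers k = 0.84 ± 0.04 and c = 0.119 ± 0.011. Each
row's fit is a full model object:

```r
fit <- attr(fits, "fits")[["A|light_sucrose"]]
fit
#> Plateau-exponential labeling fit: M0(t) = (1 - c) exp(-k t) + c
#>   window: 0-16 h, n = 18
#>   Estimate Std. Error
#> k   0.8378     0.0403
#> c   0.1186     0.0106
```

with `summary()`, `coef()`, `vcov()`, `predict()`, `residuals()`,
`simulate()` and `plot()` methods. Pool sizes follow from the time-zero
internal-standard ratios (true pool here: 0.004 μmol/mg):

```r
pr <- pool_replicates(sim$observations, sim$standards, sim$metadata)
pt <- pool_table(pr, fits)
head(pt[, c("code","p_initial","p_active","flux","flux_active")], 4)
#>   code p_initial p_active    flux flux_active
#> 1    A   0.00394  0.00347 0.00330    0.002911
#> 2    D   0.00333  0.00240 0.00109    0.000785
#> 3    E   0.00377  0.00312 0.00313    0.002594
#> 4    F   0.00433  0.00292 0.00146    0.000986
```

`p_initial` is the total pool (μmol/mg residue), `p_active` the part that
exchanges label, and `flux = k·p_initial` the turnover-adjusted pool. The
whole chain — including mzML rendering and re-extraction, clustering and
pairwise statistics — runs end-to-end through `run_pipeline()`; see the
methods vignette (`vignettes/labeling-kinetics.Rmd`).

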