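---
title: "Modeling amino-acid turnover from 15N labeling time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling amino-acid turnover from 15N labeling time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isokin)
```

## The experiment and the model

In a continuous-labeling experiment, plants growing on medium whose sole
nitrogen sources are ¹⁵N salts progressively replace ¹⁴N with ¹⁵N in every
nitrogen-containing metabolite. For each free amino acid we observe, at each
sampling time, the isotopic envelope: the integrated LC-MS areas of the
species carrying 0, 1, ..., n heavy nitrogens. The analysis tracks the
**M0 fraction** — the unlabeled species' share of the total envelope —
which starts at 1 and decays as the pool turns over.

`isokin` models this decay as a first-order exchange with a plateau:

$$M_0(t) = (1 - c)\,e^{-kt} + c$$

with two interpretable parameters:

* **k** (h⁻¹): the turnover constant of the exchanging part of the pool.
* **c** (dimensionless, in [0, 1]): the asymptotic unlabeled fraction.
  A pool that labeled completely would have c = 0; observed plateaus
  above zero are read as a metabolically inactive sub-pool (for example
  vacuolar storage) that does not exchange on the experimental timescale.

The model assumes a single well-mixed active pool with constant precursor
enrichment, which is reasonable once the inorganic nitrogen supply is fully
labeled from t = 0. It deliberately excludes biexponential or
multi-compartment alternatives: with 6–11 time points and replicate scatter,
two extra parameters are rarely identifiable, and the plateau already
absorbs the leading effect of compartmentation. This is a known limitation,
not an oversight — a pool with two sub-pools exchanging at different rates
will be summarized by an effective (k, c) pair.

### Fitting

`m0_decay()` fits all replicate observations jointly (not replicate means):
the replicate scatter carries the information that determines the standard
errors, and joint fitting weighs time points with more surviving replicates
appropriately. Estimation is bounded nonlinear least squares
(Levenberg–Marquardt with box constraints via `minpack.lm`): k ∈ [0, ∞),
c ∈ [0, 1]. The bounds encode the physics — negative turnover and plateaus
outside [0, 1] are meaningless — and stabilize slow-turnover series where
an unconstrained fit can wander.

Numerical choices:

* **Initialization.** c₀ = mean M0 at the last in-window time point; k₀
  from a log-linear regression of (M0 − c₀) on t over the points above the
  provisional plateau, falling back to 0.1 h⁻¹ when that regression is
  degenerate. This is robust across the three orders of magnitude of k the
  reference table spans (0.02–1.51 h⁻¹).
* **Convergence.** Relative cost tolerance 1e−10, at most 1000 iterations;
  the `converged` flag is carried through all downstream tables. Singular
  fits (for instance a constant M0 series, which contains no decay
  information) return `converged = FALSE` with the optimizer's message
  rather than fabricated estimates.
* **Standard errors** are the usual asymptotic ones from the Jacobian at
  the optimum.

### Fit windows

Fits use the 0–16 h window by default: most amino acids reach their plateau
near 16 h, and later points add plateau replication but no rate
information while exposing the fit to slow secondary drift. Slow-labeling
series need longer windows to see the plateau at all, and
`select_fit_window()` encodes those cases: 0–32 h for lysine in the dark,
0–64 h for tryptophan in the light without sucrose and for alanine,
arginine, threonine and tryptophan in the dark. Every window is overridable
through configuration.

Histidine is excluded from modeling in all conditions, and valine and
tyrosine outside the light-with-sucrose condition, for data quality;
glutamate has no usable dark-condition series. Leucine and isoleucine
co-elute on the cHILIC column and are treated as a single joint species
(`"I/L"`) throughout.

## Masses and extraction

Isotopologue targets are computed from elemental formulas with an embedded
monoisotopic mass table (C, H, N, O, S, ¹⁵N, proton) rather than an
external calculator, as protonated positive-mode ions by default. Only the
¹⁵N ladder (spacing 0.997035 Da) is generated: the tracer is nitrogen, and
¹³C isotopologues (spacing 1.003355 Da) are distinct species that a narrow
m/z window must *not* absorb. At amino-acid masses (m/z < 300) the two
ladders differ by more than 20 ppm, so the default ±10 ppm window —
matched to a 70,000-resolution Orbitrap — provably separates them; a test
asserts this for every species in the table.

EICs are integrated by the trapezoid rule over the full configured
retention window, without peak detection. The quantity of interest is a
*ratio* of areas within one envelope; identical windows across
isotopomers cancel peak-shape effects, and absent isotopologues are
informative zeros, not missing values. An envelope whose total area falls
below a configurable floor is flagged rather than silently normalized.

## Pools, active pools and flux

Pool sizes are estimated from time-zero samples against a fully labeled
internal amino-acid standard spiked into the reconstituted dry residue at
0.02 mM, assuming equimolar detector response between an amino acid and
its labeled analogue (the premise of all isotope-dilution quantification):

$$P = \frac{A_{analyte}}{A_{standard}} \cdot
      \frac{c_{std}\,[\mathrm{mM}] \times V_{recon}\,[\mathrm{mL}]}
           {m_{residue}\,[\mathrm{mg}]}
  \quad [\mu\mathrm{mol/mg}]$$

The defaults reproduce the experimental bookkeeping (residue reconstituted
at 2 mg/mL; 1 μL injected): mM × mL = μmol, divided by residue mass. The
exact arithmetic linking these constants is stated here as this package's
explicit contract, since relative quantification admits several equivalent
conventions.

Two derived quantities follow. The **active pool** is
$P_{active} = P \cdot (1 - c)$: the plateau is read as the inactive
proportion, so the exchanging pool is the complement. (The commonly
quoted shorthand "initial pool minus the plateau-proportional part",
written naively as $P - (P - c)$, collapses algebraically to $c$; the
pool-scaled form is the one with correct units and is what all
downstream comparisons use.) The **turnover-adjusted pool**
$f = k \cdot P$ (μmol/mg/h) has flux dimensions and makes turnover
comparable across pools of very different size, but is *not* a pathway
flux: it aggregates every reaction exchanging nitrogen through the pool.

## Clustering

Trajectory clustering uses k-means (Hartigan–Wong, squared Euclidean) on
the matrix of replicate-mean M0 fractions over the shared time grid up to
32 h. M0 fractions are already commensurate on [0, 1], so no feature
scaling is applied. Because Hartigan–Wong is a local optimizer, every
clustering uses 25 random restarts (50 in optimality tests) under a fixed
seed, and cluster ids are canonicalized by first appearance so equal-cost
solutions resolve deterministically. Tests verify, by exhaustive partition
enumeration on up to 8 trajectories, that the restarted optimizer attains
the global within-SS optimum, and that the within + between = total
decomposition holds to 1e−8 relative.

The number of clusters is chosen by an explicit rule — the smallest k
whose between-cluster share of total SS reaches 0.85, falling back to the
within-SS elbow — because "maximize between, minimize within" needs a
tie-break to be reproducible. The threshold is configuration, not dogma.
Flux values are clustered one-dimensionally per condition with the same
machinery, defaulting to 3 clusters (4 for light with sucrose, where the
trajectory analysis distinguishes four groups). Each trajectory cluster is
refitted as one pooled plateau-exponential model.

## Pairwise statistics

Pool and flux quantities are compared across the three condition pairs per
amino acid with two-tailed two-sample t tests: Welch (unequal variance) by
default, switching to the pooled-variance Student test when a two-sided
variance-ratio F test fails to reject equality at α = 0.05. The F-test
gate level is not a published constant; 0.05 is this package's default and
is configurable. No multiplicity correction is applied by default —
comparisons are reported per pair, as is conventional for this design —
but Benjamini–Hochberg adjustment is available as an option.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes, with the study's own conditions as defaults:

* 17 amino-acid species with their real formulas and nitrogen counts;
  reference (k, c) truth per condition from the published table.
* Per-condition time grids — {0, 1, 2, 4, 8, 16, 32, 64, 128} h, with
  additional 0.25 and 0.5 h samples outside the light-with-sucrose
  condition — and 5 replicates by default. (The source experiments
  disagree internally about which condition ran 3 replicates; 5 is the
  default and any condition can be overridden to 3.)
* M0 decay following the plateau-exponential model, with additive
  Gaussian noise (sd 0.02, clipped to [0, 1]) on the fraction — the scale
  suggested by the published standard errors — and/or multiplicative
  area noise (CV 0.1).
* Envelopes built from a per-atom enrichment p = 1 − M0^(1/n), giving
  binomial isotopologue fractions: the minimal assumption of uniform,
  independent labeling across a molecule's nitrogens. An optional
  per-site enrichment vector (Poisson-binomial envelope) exists for
  exploring site-inhomogeneous labeling, e.g. the hypothesis that
  glutamine's amide and amino nitrogens turn over at different rates;
  it is off by default because no default behavior can be justified.
* Internal-standard areas consistent with a configured true pool
  (default 0.004 μmol/mg) under the pool estimator's own model, and
  optional rendering of every sample as a centroided mzML file with
  Gaussian chromatographic peaks (σ = 0.04 min, 0.01-min scans) inside
  synthetic retention windows.

What the generator does **not** emulate — and therefore what passing
tests cannot certify about real data — includes chromatographic
co-elution and retention drift, ion suppression and saturation,
¹³C natural abundance within the measured envelope, heteroscedastic
detector noise, and biological deviation from the single-pool model
itself. Parameter-recovery results on synthetic data validate the
estimator chain, not the model's adequacy for any particular organism.

Retention-time windows in the built-in table are synthetic, plausible
HILIC values used by the simulator and fixtures; they are not measured
values and must be replaced for real data.

## Problem sizes and determinism

The validation suite exercises desk-scale versions of the full design:
noiseless round trips of all ~44 published (k, c) pairs; a 200-dataset
stochastic recovery at 5 replicates and noise sd 0.02; a
15-amino-acid × 11-time-point × 3-replicate mzML write/extract loop
(areas recovered within 1%, M0 fractions within 0.5 percentage points);
and clustering optimality on up to 8 trajectories, where exhaustive
enumeration is feasible. All randomness flows through explicit seeds;
reruns with identical configuration produce byte-identical stage outputs
and manifest, which the pipeline records (package version, configuration
hash, seeds).

## Known limitations

* Single-pool, single-rate model per amino acid; no compartment
  resolution and no precursor-enrichment correction.
* Pool estimates assume equimolar analyte/standard response and carry
  the internal standard's accuracy.
* Integration without peak detection assumes clean, isolated retention
  windows; heavily overlapping chromatography would need an upstream
  deconvolution step this package does not provide.
* k-selection by an SS-share threshold is a reproducible convention, not
  an inferential procedure; cluster counts should be sanity-checked
  against the scan it reports.
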