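---
title: "Projecting blood-derived DNAm lifestyle predictors into brain: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting blood-derived DNAm lifestyle predictors into brain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methbridge)
```

## The scientific problem

Lifestyle exposures — smoking, alcohol intake, adiposity, circulating HDL
cholesterol — leave reproducible marks on blood DNA methylation (DNAm).
Penalized-regression "episcores" trained in large blood cohorts summarize
those marks as a weighted sum of beta values over a trait-specific CpG set:

$$\mathrm{score}_i \;=\; w_0 + \sum_j w_j\,\beta_{ij},$$

with $\beta_{ij} \in [0,1]$ the methylation fraction of CpG $j$ in sample
$i$. Whether such blood-trained signatures carry over to brain tissue is an
open question: matched ante-mortem blood and post-mortem brain samples are
rare, and cross-tissue methylation correlation is known to be site- and
region-dependent. `methbridge` implements the full analysis pipeline for
such matched designs — QC, platform harmonization, score projection,
phenotype derivation, and correlation inference — together with a synthetic
cohort generator with known ground truth, so every stage is testable without
access-restricted human data.

The emulated design is deliberately concrete: 14 individuals, each with one
blood sample (Illumina 450K) and post-mortem samples from five Brodmann
areas (EPIC array) — BA17, BA20/21, BA24, BA35, BA46 — with one BA35
(hippocampus) specimen unavailable, i.e. 69 brain samples. The single CpG
cg05575921 (*AHRR*), the strongest known blood correlate of smoking and
hypomethylated in smokers, is carried through every analysis alongside the
four trait scores.

## Quality control

Two filter sets mirror standard array practice, applied as pure functions
`(BetaMatrix, thresholds) -> (BetaMatrix, QcReport)`:

* **Brain (EPIC)**, in this order: (1) drop samples in which >1% of probes
  have detection p > 0.05; (2) drop probes with beadcount < 3 in >5% of the
  remaining samples; (3) drop probes with detection p > 0.05 in >1% of the
  remaining samples. The source protocol lists the rules in this order
  without stating whether samples or probes go first; samples-first is
  adopted (a removed sample should not condemn probes), the order is part of
  the documented contract, and a test fixture demonstrates that the two
  orders genuinely differ. Every removal carries the *first* rule that
  fired.
* **Blood (450K)**: drop probes detected (p < 0.01) in fewer than 95% of
  samples, then drop samples detecting fewer than 450,000 probes. That
  sample threshold is an absolute count tied to a 485,512-probe array; on
  smaller matrices it is rescaled proportionally (factor logged) so the rule
  remains exercisable at desk scale. Note an interaction at very small
  sample counts: with fewer than 20 samples, a single failing sample drags
  each probe it misses below the 95% detection rule, so the probe rule
  (which runs first) absorbs the failure. This is a property of the rules
  themselves, not of the implementation.
* **Sex check**: sex is predicted from each sample's mean beta over
  X-linked probes — X-inactivation leaves females with intermediate
  methylation, hence a higher mean X beta than males. The split is a
  deterministic 2-means (centres seeded at the observed extremes, higher
  centre = female). The prediction method is not specified in the source
  protocols; 2-means was chosen for determinism and testability. If the two
  centres are closer than 0.05 mean-beta units the cohort is treated as
  single-sex and the check is skipped; `recorded_sex = "unknown"` samples
  are exempt.
* Strict inequalities are implemented exactly as printed (">1%", "<3",
  ">5%", "<95%", "<450 000").

## Score projection

`project_scores()` computes the weighted sum over the weight-table CpGs that
are present and non-missing, **without rescaling** for missing terms:
rescaling would silently change the score's units relative to the published
predictors. Instead per-sample coverage (`n_cpgs_used / n_weights`) is
reported and samples under `min_coverage` (default 0.95, the level the
published predictors retain on both platforms) are flagged — never dropped.
Platform differences are handled by `harmonize_platforms()`, which subsets
all matrices to their probe intersection (optionally further restricted to
a 450K probe list); the platform label on a `BetaMatrix` is metadata only.
The projection is exactly linear in the weights, which the tests exploit:
additivity over disjoint weight sets, exact scale equivariance, probe-order
invariance, and agreement with an element-by-element brute-force
accumulation to 1e−12 *absolute* error (near-cancelling sums make a
relative bound meaningless in doubles).

## Phenotypes

Smoking status uses the cohort coding 0 = never, 1 = former, 2 = current.
Pack years is cigarettes/day × years smoked ÷ 20. The conventional phrasing
"packs per day × years ÷ 20" double-converts if taken literally (a pack *is*
20 cigarettes); the cigarettes-based form is implemented, prominently, in
`derive_pack_years()`. Rules: never-smokers are 0 by definition; a missing
start age is imputed with the cohort mean (16 years); missing cigarettes/day
leaves pack years missing and the individual is excluded from pack-years
analyses (never imputed) — with the default design 5 of 14 individuals are
excluded, leaving the analysable subset of 9. Years smoked is assessment age
minus start age for current smokers and stop age minus start age for former
smokers; a former smoker without a stop age stays missing (the source
protocol is silent here; missingness is the conservative reading).

## Correlation inference

Every correlation is reported as (r, n, p, 95% CI) with pairwise-complete
n — that is how the per-cell n of 13 (missing BA35 specimen) and 9
(pack-years subset) arise naturally. The p-value is two-sided from
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ df; sidedness is never stated in the
source results, and two-sided is the conservative default. The CI is
Fisher-z: $\tanh(\operatorname{atanh} r \pm 1.96/\sqrt{n-3})$. Spearman is
Pearson on average ranks with the same t approximation — adequate at
n ≥ 9 — with an exact permutation p available behind a flag for n ≤ 8
(8! = 40,320 orderings enumerated). Degenerate inputs (n < 3, zero
variance) yield a result flagged `undefined` rather than NaN. No
multiple-testing correction is applied, matching the unadjusted reporting
convention; the run log annotates the number of tests instead.

`correlation_power()` quantifies why no regression modelling is attempted
at n = 14: Monte-Carlo power of the two-sided Pearson test, cross-checked
against the Fisher-z closed form
$\Phi(-z_{\alpha/2} + \operatorname{atanh}(\rho)\sqrt{n-3}) +
\Phi(-z_{\alpha/2} - \operatorname{atanh}(\rho)\sqrt{n-3})$.
At n = 14 and ρ = 0.5 the power is ≈ 0.45 — a coin flip. The original
study's supplementary power procedure is not described in its main text, so
this simulator is a declared stand-in, not a reproduction.

## The synthetic cohort generator

`simulate_cohort()` draws from a latent factor model, with all effects on
the M-value (logit) scale and outputs as betas:

$$T_{ik} \sim N(0,1), \qquad
S_{ik}^{\mathrm{blood}} = \lambda_k T_{ik} + \sqrt{1-\lambda_k^2}\,
\varepsilon,\qquad
S_{ikr} = \rho_{kr} S_{ik}^{\mathrm{blood}} + \sqrt{1-\rho_{kr}^2}\,
\varepsilon,$$
$$m_{ijr} = \mu_j + c\,w_j\,S_{ikr} + \sigma_{\mathrm{cpg}}\varepsilon,
\qquad \beta = \frac{2^m}{2^m + 1} \in [0.001, 0.999].$$

Design choices and their reasons:

* **Region coupling is specified at the score level** ($\rho_{kr}$, the
  quantity the concordance analyses measure), not per CpG — true per-CpG
  blood–brain coupling distributions are unknown, so the factor model is a
  declared assumption, not an inference. A corollary: two regions coupled
  to blood at $\rho_1, \rho_2$ have inter-region correlation
  $\rho_1\rho_2$.
* **CpG loadings are proportional to the fixture weights** ($c\,w_j$), so
  the projected score is, to first order, the sufficient statistic of the
  latent factor and recovery targets are analytic. With the default
  $c = 0.2$ M-units the logistic is locally near-linear and the attenuation
  of the score-level Pearson correlation is ≲ 0.03; in the noiseless-CpG
  limit the blood–brain score correlation recovers $\rho_{kr}$ to within
  sampling error (verified at n = 2000, tolerance ±0.05).
* **Defaults are the stated world**: 14 individuals; default
  $\rho_{kr}$ values mirror the regionally variable coupling reported for
  this design (smoking–BA46 0.5, BMI–BA46 −0.72, HDL–BA20/21 0.55, …) with
  0.2 for unreported cells ("generally weak"); phenotype means/SDs match
  the cohort summary table (HDL 1.49 (0.4) mmol/l, BMI 25.5 (5.1), alcohol
  14 (15) units/week, assessment age 77.9 (1.7), start age 16 (2), status
  split 5 current / 7 former / 2 never, 5 of 14 missing cigarettes/day);
  $\lambda = 0.7$ and $\sigma_{\mathrm{cpg}} = 0.5$ are realistic
  moderate-signal choices fixed once. The 64% male fraction matches the
  described cohort.
* **QC-failure planting is opt-in and defaults to zero**: the emulated
  counts (69 samples) describe a post-QC dataset. When failures are
  planted, each failing probe's detection-p failures are spread over its
  own disjoint ~10% of clean brain samples, so the >1% per-sample rule
  cannot fire collaterally at desk-scale probe counts and planted
  probe/sample failures remain exactly recoverable with their correct
  reason codes.
* **What a green test does not establish**: the generator has no cell-type
  composition mixtures, no age effects, genome-scale probe counts, batch
  structure, or realistic per-CpG coupling heterogeneity. Green
  property/recovery tests validate the *pipeline's* correctness on data
  satisfying the factor model, not the biological fidelity of that model.

At the design's actual size the generator also demonstrates the central
caveat quantitatively: across 500 replicate cohorts at n = 14 and
ρ = 0.5, the central 95% range of the estimated blood–brain correlation is
wider than ±0.3 (≈ ±0.5 in practice) — single-cohort r values at this n are
order-of-magnitude statements, not estimates.

## Numerical and degenerate-input conventions

* Betas are clamped to [0.001, 0.999] in the generator; the logit/expit
  pair round-trips to 1e−12 on that range.
* Missing cells are parsed as missing, never 0 (a beta of 0 is a real
  measurement); missing-value tokens are the empty cell and `NA`.
* Perfectly monotone Spearman inputs (|r| = 1) report the smallest positive
  double rather than p = 0, keeping p ∈ (0, 1].
* Ties in Spearman use average ranks.
* `correlate()` clamps numerically out-of-range r into [−1, 1] before the
  t transform.
* All file outputs carry a `#` provenance header (package version, input
  md5s, seed — no timestamps), so reruns with identical config and seed are
  byte-identical.

## Known limitations

* The sex predictor is a two-cluster heuristic; it needs both sexes present
  and ≥ 2 samples, and abstains (with a warning) otherwise.
* The blood call-rate rule loses its intended semantics below ~20 samples
  (see above); real blood QC operates on hundreds of samples.
* The power simulator is a generic Pearson-test calculator, not a
  reconstruction of any specific supplementary procedure.
* Linear mixed-effects modelling of covariates (post-mortem interval,
  brain pH, neuronal proportion) is deliberately out of scope: at n = 14 it
  is underpowered, which `correlation_power()` makes explicit.
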