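---
title: "Methods: two-sample and allele-score MR for kidney function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample and allele-score MR for kidney function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

## The causal question and the MR model

Blood homocysteine and the vitamins in its metabolic pathway (folate,
cobalamin) correlate with kidney function, but the kidney also clears
homocysteine, so observational estimates are contaminated by reverse
causation and confounding. Mendelian randomization treats genetic variants
as instruments: writing `G_j` for a variant, `X` for the exposure biomarker
(in SD units) and `Y` for log eGFR, the working model behind every estimator
here is

```
bx_j = gamma_j + e_xj            (exposure GWAS)
by_j = theta * gamma_j + alpha_j + e_yj   (outcome GWAS)
```

where `theta` is the causal effect of one SD of exposure on log eGFR and
`alpha_j` is a direct (pleiotropic) path that a valid instrument does not
have. The three instrument assumptions map onto package components:
relevance is enforced by genome-wide-significant instruments
(`filter_genome_wide()`, default threshold 5e-8); independence and exclusion
cannot be proven, so the estimator suite spans methods that trade efficiency
for robustness to `alpha_j != 0`; and directionality is checked by Steiger
filtering.

Estimates are reported as percent change in eGFR per SD of exposure,
`100 (exp(beta) - 1)` — the exact transform, not the small-effect `100 beta`
approximation (they differ by under 0.005 points at these effect sizes).

## Instruments and reconstructed standard errors

The packaged instrument tables (18 homocysteine, 3 folate, 14 cobalamin
variants; per-SD betas) print no standard errors, so
`se_from_beta_pval()` reconstructs `se = |beta| / z` with `z` obtained by
inverting the chi-square survival function on the log-probability scale; a
naive `qnorm(p/2)` underflows below p ~ 1e-300 while the log-space route is
exact down to the smallest positive double. Reconstructed SEs inherit the
rounding of the printed values — an irreducible (and small: two to three
significant digits) source of imprecision that propagates to every
downstream weight.

The tables also print only the effect allele. Harmonization therefore
supports an effect-allele-only mode: the exposure allele is matched against
the outcome's two alleles, and a variant matching neither is dropped as
non-overlapping, because without the second allele strand cannot be
disambiguated. One pathway variant (MTHFR rs1801133) appears in two
instruments on opposite effect alleles; the fixtures store rows verbatim and
harmonization resolves the orientation per analysis.

## Harmonization choices

* **Palindromic variants** (A/T, C/G): allele letters cannot resolve strand.
  The default policy `infer_by_eaf` orients by allele frequency — flip when
  the exposure and outcome frequencies straddle 0.5, drop when either lies
  within `eaf_tolerance` (default 0.08, i.e. in [0.42, 0.58]) of 0.5. This
  matches common two-sample practice; a strict `drop` policy is available,
  and every decision is written to the per-SNP audit log. Whether the
  original analysis dropped or inferred palindromic variants is not
  documented; both behaviours are supported and neither is asserted.
* **Duplicate outcome records** for an instrument rsid are an error rather
  than a silent first match: meta-analysis dumps occasionally contain
  multi-allelic duplicates, and picking one arbitrarily is not reproducible.
* **Steiger filtering** drops a variant when it explains more variance in
  the outcome than in the exposure. The default r-squared uses only printed
  quantities: `r2 = z^2 / (z^2 + n - 2)` with `z` recovered from the
  p-value in log space; `r2 = 2 eaf (1-eaf) beta^2` is available for
  SE-free, per-SD inputs. Ties are kept, and the result is independent of
  input order.

## Estimators and their tunables

All methods consume the harmonized, Steiger-filtered set.

* **IVW (fixed effects)** — the main estimator; exact zero-intercept
  weighted least squares with weights `se_out^-2`. Efficient, and unbiased
  only if all instruments are valid.
* **MR-Egger** — weighted least squares with a free intercept; the slope is
  robust to directional pleiotropy under the InSIDE assumption (instrument
  strength independent of direct effects), and the intercept p-value is the
  pleiotropy test. Egger is not invariant to allele coding, so variants are
  first re-expressed to positive exposure effects — a convention that must
  be fixed and is logged. SEs come from a parametric bootstrap (each
  replicate redraws all effects from `Normal(estimate, se)`, re-orients,
  refits; default `n_boot = 1000`, which puts the Monte-Carlo error of the
  SE near 2%; the bootstrap is seeded and bit-reproducible).
* **Penalized weighted median** — the weighted median of per-variant Wald
  ratios (cumulative-weight interpolation) is consistent while valid
  instruments hold over half the weight. Penalization converts each
  variant's heterogeneity contribution against the unpenalized median into
  an upper-tail chi-square(1) probability `q_j` and multiplies its weight by
  `min(1, penalty_k * q_j)`; `penalty_k = 20`, the originating method's
  convention. The bootstrap SE follows the reference convention for this
  estimator: replicates redraw the ratios but hold the observed (penalized)
  weights fixed. Re-deriving weights inside each replicate inflates the SE
  by ~20% at 16 variants and pushes empirical coverage to ~99%; with fixed
  weights, measured coverage is ~96% at nominal 95%.
* **Contamination mixture** — each variant's ratio is modelled as valid
  (normal around `theta` with its own SE) or invalid (normal around zero
  with dispersion `psi`); the profile log-likelihood takes the larger
  per-variant term on a grid of `grid_points = 5001` candidate values
  spanning the ratio range padded by twice the largest ratio SE (widened
  and retried if the maximum lands on an edge). `psi` defaults to
  `1.5 * sd(ratios)`, the reference implementation's convention. The
  confidence set is the likelihood-ratio region at `1 - alpha` and may be a
  union of disjoint segments; the reported CI is its envelope, the p-value a
  likelihood-ratio test of `theta = 0`.
* **Wald ratio** — single-variant `by / bx` with first-order SE
  `se_out / |bx|`. The second-order term (exposure-side uncertainty) is
  available behind a flag but negligible here: the weakest packaged
  instrument has |z| ~ 5.6. Single-variant estimates are reported on the
  per-SD exposure scale with no further scaling.

## The allele-score arm

The individual-level replication regresses eGFR on a standardized
dosage-weighted score. Standardization makes the coefficient "eGFR change
per 1 SD of score" and renders it exactly invariant to positive rescaling of
the instrument weights. eGFR uses the CKD-EPI 2009 creatinine equation in
its exact general form `141 min(Scr/k,1)^a max(Scr/k,1)^-1.209 0.993^age
(1.018 if female)`; the race coefficient is omitted by default (current
reporting convention) with a flag for strict historical replication. Note
the stratified presentation of the same equation rounds the female
sub-knot prefactor 141 x 1.018 = 143.538 to 144; the package uses the exact
form. The regression is ordinary least squares on complete cases via
Householder QR, with `n_used` reported per model — the clinical sensitivity
model (adding hypertension, diabetes, obesity) analyses fewer individuals
than the main model, mirroring how such cohorts report two analysis-set
sizes. The outcome is continuous eGFR on its raw scale (mL/min/1.73 m^2);
a linear model is the appropriate fit (a footnote in the source table calls
the model "logistic", which is inconsistent with its own continuous-outcome
header and is treated as a typo). Rank deficiency is an error naming the
collinear columns rather than a silent coefficient drop.

## What the generators emulate — and what they do not

`simulate_summary()` produces two-sample summary statistics under the
working model above: uniform allele frequencies on `eaf_range`, instrument
strengths resampled from the packaged per-SD betas (or half-normal),
per-allele SEs `se^2 = sd_trait^2 / (2 eaf (1-eaf) n)` with default sample
sizes 44,147 (exposure) and 567,460 (outcome), and `outcome_sd = 0.2` — the
population SD of log eGFR in adults; with a unit-variance outcome the
simulated CIs would be ~5x wider than the reported ones, so the trait scale
matters. The default causal effect is `theta = -0.0095` log-eGFR per SD
(about −0.95% eGFR change), making recovery tests directly interpretable.
Pleiotropy is configurable (fraction invalid, direct-effect mean/SD, and an
InSIDE-violation correlation); direct effects are defined on the
exposure-increasing allele — the convention under which "directional"
pleiotropy is what MR-Egger's intercept absorbs. With sign-mixed instrument
betas, attaching direct effects to the tabulated allele instead would make
the pleiotropy orientation-dependent and bias Egger itself. Allele
scrambling randomly re-expresses outcome records on the opposite allele to
exercise harmonization, which must (and does, exactly) undo it.

`simulate_cohort()` draws genotypes binomially at the instrument
frequencies, builds a unit-variance latent exposure from standardized
genotypes plus a shared confounder, log-normal eGFR centered at 92.5
mL/min/1.73 m^2 (SD 0.16 on the log scale), ages 40–69, 46% male, batches,
10 PCs, comorbidity flags, and missingness of 4.7% (creatinine/eGFR) and
1.2% (comorbidities) matching the relative analysis-set sizes such cohorts
report. Creatinine is back-derived by inverting CKD-EPI so the phenotype
round-trips exactly. The confounder is a single standard-normal factor
loading on both exposure and outcome — the minimal structure that biases the
naive regression while MR stays consistent.

Deliberately not emulated: linkage disequilibrium between instruments (they
are pruned by construction), population stratification beyond PC noise,
genotype QC artefacts, strand mislabeling beyond allele scrambling, and
winner's-curse inflation of the published instrument effects. Passing tests
on these generators therefore demonstrate correctness of the estimators and
plumbing under the stated model, not robustness to every pathology of real
GWAS data.

## Randomness, determinism and problem sizes

Every stochastic component takes a seed; per-component streams are derived
from one root seed via a rolling-hash `derive_seed()`, so adding a generator
never perturbs existing draws, and identical configurations reproduce
reports bit for bit (provenance blocks embed a config hash, the seed and the
package version). Test and script problem sizes were chosen to make
Monte-Carlo error small relative to the asserted margins while staying
desk-scale: 500 replicate datasets for bias/coverage of IVW and the
penalized weighted median (binomial SD of a 95% coverage estimate ~1
point), 200 replicates for the pleiotropy-robustness comparison, and 200
simulated cohorts of 20,000 for null coverage of the allele-score arm.

## Known limitations

* The contamination-mixture point estimate is grid-quantized; its accuracy
  target is the grid step against a finer-grid oracle, while its distance to
  the true effect is governed by sampling noise (~2e-4 on the ratio scale at
  these sample sizes), which no grid refinement reduces.
* Bootstrap SEs for Egger and the weighted median are themselves Monte-Carlo
  estimates; at the default `n_boot = 1000` their relative error is ~2%.
* Reconstructed instrument SEs carry the rounding of the printed betas and
  p-values.
* The effect-allele-only harmonization mode cannot rescue a variant whose
  printed allele matches neither outcome allele; such variants are dropped
  and logged rather than guessed.
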