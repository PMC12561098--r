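---
title: "Methods: two-step MR mediation with mrtriad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-step MR mediation with mrtriad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtriad)
```

## The model

Two-sample Mendelian randomization treats genetic variants as instruments:
if a variant affects the outcome only through the exposure (exclusion
restriction), is associated with the exposure (relevance), and is independent
of confounders, then the ratio of its outcome to its exposure association
estimates the causal effect. mrtriad applies this twice to decompose a total
effect:

- step 1: phenotype → metabolite, effect β₁;
- step 2: metabolite → outcome, effect β₂, estimated after removing any
  instrument used in step 1, so the two stages do not reuse information;
- total: phenotype → outcome, effect β₃.

The indirect (mediated) effect is β₁β₂ and the mediation proportion
β₁β₂/β₃. Because the three estimates come from separate GWAS samples, their
sampling errors are treated as independent; the delta-method variance of the
indirect effect is β₁²se₂² + β₂²se₁², and the proportion variance adds the
β₃ term (β₁β₂/β₃²)²se₃² by default (`proportion_se3_term = FALSE` gives the
two-term variant; both are implemented because conventions differ and the
choice matters for the interval, not the point estimate). All binary-trait
effects live on the log-odds scale; the mediation proportion is therefore a
ratio of log-odds effects. Proportions are reported as percentages with
three decimals in printed tables.

Two caveats are intrinsic to the decomposition. The proportion is undefined
when β₃ = 0 (flagged, not fabricated), and |proportion| > 1 ("inconsistent
mediation") can occur when direct and indirect paths have opposite signs or
the total effect is underestimated; such rows are returned with a flag
rather than truncated.

## Instruments and harmonization

Defaults follow genome-wide convention: selection at p ≤ 5×10⁻⁸ and greedy
LD clumping at r² < 0.001, visiting variants in ascending p-value order with
ties broken lexicographically by rsid so the result is deterministic and
independent of input row order. Variants absent from a supplied LD matrix
are treated as independent; no LD panel is ever constructed from genotypes.
Instrument strength is summarized by the single-instrument approximation
F = (β/se)² (the conventional screen is F > 10) and by the cumulative
explained variance Σ 2·eaf·(1−eaf)·β², which assumes a unit-variance trait.

Harmonization aligns each instrument and its outcome record on one effect
allele: exact matches are kept, reversed codings are sign-flipped with the
allele frequency complemented, and irreconcilable allele sets are dropped as
mismatches. Palindromic variants (A/T, C/G) cannot be strand-resolved from
alleles alone; they are retained only when both allele frequencies exist,
both fall outside the ambiguity window [0.42, 0.58] (half-width 0.08,
configurable), and both lie on the same side of 0.5. Every exclusion is
recorded with a reason — nothing is dropped silently.

## Estimators

**IVW.** The inverse-variance-weighted estimate is the zero-intercept
weighted regression of outcome on exposure effects with weights 1/se_out².
The multiplicative random-effects variant (the default, `ivw_mre`) inflates
the fixed-effect standard error by √max(1, Q/(n−1)), absorbing balanced
heterogeneity without changing the point estimate; the fixed-effect variant
remains available for diagnostics, and a single-instrument IVW reduces
exactly to the Wald ratio.

**MR-Egger.** The same regression with a free intercept, after orienting all
rows so exposure effects are non-negative (the intercept is only
interpretable for a fixed orientation; the synthetic generator uses the same
exposure-increasing-allele convention). The intercept tests directional
pleiotropy; the slope is the adjusted effect. Inference uses the t
distribution with n−2 degrees of freedom and the same multiplicative
inflation, never deflating below the fixed-effect error. All other
estimators use normal-theory p-values — a deliberate convention, stated here
because mixing t and normal tails silently is a common source of small
discrepancies between MR implementations.

**Weighted median.** The weighted median of per-variant Wald ratios
(weights 1/se_ratio², first order), interpolated linearly at cumulative
weight 0.5; consistent while valid instruments carry more than half the
weight. Its standard error comes from a parametric bootstrap resampling
(β_exp, β_out) jointly; `n_boot = 1000` by default and the seed is a
required argument so pipeline results are reproducible by construction.

**BWMR.** A Bayesian outlier-robust estimator with the hierarchical model
β_out,j ~ Normal(θ·β_exp,j, se_out,j² + θ²·se_exp,j² + τ²), a weak
Normal(0, 5²) prior on θ and a half-Normal(0.5) prior on the pleiotropy
scale τ. The posterior is computed on a deterministic (θ, τ) grid — 201 × 61
points centred on the IVW estimate — so results carry no Monte Carlo error;
the grid widens once if more than 10⁻⁴ of the mass reaches an edge and
estimation fails loudly if mass still escapes. Per-variant outlier weights
are the standardized-residual densities at the posterior mean, normalized to
(0, 1]: a gross outlier receives the minimum weight. This is a grid-posterior
formulation of the Bayesian-weighting idea, not a port of any particular
variational algorithm; its contract is behavioural — agreement with IVW
within one fixed-effect standard error when τ = 0, and downweighting of
injected outliers — and both contracts are tested.

## Sensitivity diagnostics and method selection

Cochran's Q is computed on the Wald-ratio scale (weights
(β_exp/se_out)²), which is algebraically identical to the weighted residual
sum of squares about the zero-intercept IVW fit on the regression weight
scale (1/se_out²). Rucker's Q is the residual sum about the Egger fit on
that same regression scale; because the Egger model nests the IVW model,
Rucker's Q never exceeds Cochran's Q, and the gap measures how much
heterogeneity the intercept absorbs. Both conventions are stated to avoid a
silent scale mismatch when comparing against other software.

The global pleiotropy test builds its observed statistic leave-one-out: each
variant's outcome effect is compared with the prediction of the IVW fit
excluding that variant, standardized by its own standard error, and the
squared residuals are summed. The null distribution comes from parametric
simulation (β_out,j drawn at the leave-one-out prediction with its own
standard error), with the statistic recomputed identically on each simulated
dataset; p-values use the (1 + exceedances)/(n_sim + 1) correction so they
are never exactly zero, and fewer than 100 simulations is rejected as
unstably coarse. The default is 1000. Simulations run in canonical variant
order (sorted rsid) so every p-value is invariant to input row order. The
per-variant outlier test compares each observed squared residual with its
own simulated null, Bonferroni-adjusts across variants, and reports the
outlier-corrected IVW fit with flagged variants removed.

The primary-method decision rule, with all gates at α = 0.05: IVW
(multiplicative random effects) when neither the global test nor the Egger
intercept indicates pleiotropy; the Egger slope when the intercept is
significant (directional pleiotropy); the weighted median when the global
test fires without a directional intercept — the "weighted MR model" branch
is mapped to the weighted median rather than a mode-based estimator, a
deliberate resolution of an ambiguous phrase, chosen because the median is
the weighted estimator with an explicit validity guarantee in this stack.

## Colocalization

Per-variant evidence is the Wakefield approximate Bayes factor
log ABF = ½[ln(se²/(se²+W)) + z²·W/(se²+W)] with W the prior effect
variance — prior standard deviation 0.15 for quantitative and 0.2 for binary
traits, the field-standard defaults. The five-hypothesis posterior
enumerates: no association (H0), trait-specific association (H1, H2), two
distinct causal variants (H3), one shared variant (H4), with priors
p1 = p2 = 10⁻⁴ and p12 = 10⁻⁵. All sums are accumulated with log-sum-exp;
H3 uses a stable log-difference, and with a single shared variant H3 is
structurally zero and flagged. The posterior is renormalized to machine
precision (the tests assert deviation ≤ 10⁻⁹). Windows default to ±250 kb
around the lead instrument (a 500 kb region). Evidence tiers: PPH4 ≥ 0.8
"colocalized", 0.5 ≤ PPH4 < 0.8 "suggestive", else "none". No multi-signal
(SuSiE-style) or LD-aware fine-mapping is attempted.

## LD-score regression screen

The single-component model regresses per-variant χ² statistics on
N·ℓ/M (sample size × LD score / number of variants); the slope estimates the
SNP heritability and the free intercept absorbs confounding inflation and
sample overlap — no explicit overlap correction is taken as input. Weights
are the standard heteroskedasticity form 1/(1 + N·h²·ℓ/M)², iterated twice
from an ordinary least-squares start (stated explicitly since conventions
vary). Cross-trait genetic covariance regresses z₁z₂ on √(N₁N₂)·ℓ/M with the
geometric mean of the two traits' weights, and rg = cov_g/√(h₁²h₂²).
Standard errors come from a delete-one block jackknife over 200 contiguous
equal-count blocks, recomputing all three regressions per deleted block so
heritability uncertainty propagates into the rg error. Estimates of rg
outside [−1, 1] are flagged and clipped at ±1.25; non-positive heritability
makes rg undefined (flagged, not clamped). Binary traits are analysed on the
observed scale only — no liability conversion is attempted, which makes
absolute h² for case-control traits non-comparable with liability-scale
reports. The screen gate is Bonferroni: α/m over the phenotype family
(0.05/6 ≈ 8.33×10⁻³ for six phenotypes).

## Screening, grouping, and evidence tiers

Step-1 results are screened per phenotype across the whole metabolite family
by Benjamini–Hochberg FDR, separately for the primary method and the
BWMR check, keeping a metabolite only when both adjusted p-values fall below
0.05 with sign-concordant estimates. FDR families are per phenotype, not
global — the per-phenotype family matches how each metabolome-wide scan is
actually run and keeps the screen's meaning stable as phenotypes are added.

Shared mediators are metabolites significant for at least two phenotypes,
excluding membership patterns that reflect phenotypic redundancy rather than
shared biology (by default the adiposity-only pair BMI+WC). Step-2 excludes
from the metabolite's instruments the union of the step-1 instruments of all
phenotypes the metabolite is grouped with, so a single β₂ serves every
triangle of that metabolite — matching how a single mediator→outcome
estimate is reported across phenotypes.

Reverse MR is run both ways, but only the mediator → phenotype test gates a
triangle: a metabolite with a significant reverse effect on its phenotype
cannot be read as that phenotype's mediator, and the exclusion is per
phenotype–metabolite pair (the same metabolite may remain a mediator of
another phenotype). The outcome → mediator test is recorded in the report
but does not gate, because in a system where the outcome's heritable signal
flows through the mediator the outcome's "instruments" are the mediator's
own variants and the test is structurally confounded.

Evidence tiers combine colocalization and external validation: two stars
when the metabolite both passed colocalization (tier "colocalized" or
"suggestive") and replicated with concordant sign at p < 0.05 in the
validation outcome; one star when exactly one holds; none otherwise. Step-2
significance is nominal p < 0.05 — an acknowledged limitation of the
two-step design rather than a multiplicity-corrected claim.

## The synthetic-data generator

`simulate_triangle()` draws per-variant exposure effects from a half-normal
(effects coded per exposure-increasing allele, the orientation convention
directional pleiotropy is defined against), rescaled so the instrument panel
explains exactly the target variance; the mediator inherits θ_xm·γ plus its
own specific instruments, and the outcome receives
θ_direct·γ + θ_my·(mediator effect) plus a pleiotropy term on the exposure
instruments: zero-mean (balanced), mean-shifted (directional), or correlated
with instrument strength (violating the InSIDE assumption). Observed effects
add sampling noise with se = 1/√(2·maf·(1−maf)·N), the standard
regression-error approximation, with allele frequencies uniform on
[0.05, 0.5]; generated p-values are floored at 10⁻³⁰⁰ so extreme signals
survive the (0, 1] validity check. The identity
θ_total = θ_direct + θ_xm·θ_my is asserted at construction. All generators
are pure functions of (configuration, seed).

Default sample sizes emulate the study design the package targets: a
300,000-person exposure GWAS with 100 instruments explaining 6% of variance,
an 8,000-person metabolite GWAS whose 20 loci explain 15% (metabolite
architectures are dominated by few large-effect loci), and a binary outcome
GWAS of 26,554. With θ_xm = 0.3, θ_my = 0.25, θ_direct = 0.175 the true
total effect is 0.25 and the true mediation proportion 0.30.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: linkage disequilibrium among instruments
(variants are LD-free unless an LD matrix is supplied), winner's-curse
inflation from selecting instruments in the same sample that estimates them
beyond what the threshold itself induces, population stratification and
relatedness, strand-ambiguous variants (panels are non-palindromic by
construction, as after upstream QC), liability-scale effects for binary
traits, and between-SNP effect-size/frequency coupling. Calibration and
recovery results on this generator demonstrate internal correctness of the
estimators under their stated assumptions, not robustness to every
real-data pathology.

`simulate_coloc_region()` produces LD-free 500 kb regions with one shared or
two distinct causal variants; `simulate_ldsc_pair()` draws LD scores from
1 + Gamma(2, rate 0.02) (positive, mean ≈ 100) and z-pairs with exactly the
covariance structure the LDSC model inverts.

## Pipeline, reproducibility, and problem sizes

`run_pipeline()` executes the stages in order (screen, total effects with
method selection, step-1 MR with FDR screen, shared-mediator grouping,
step-2 MR with instrument exclusion, reverse MR, colocalization, validation,
mediation with tiers), records per-pair instrument failures without aborting,
and writes TSV/JSON reports plus a run log carrying the configuration hash,
seed, thresholds, and package version — reruns with the same configuration
and seed are byte-identical. All randomness (bootstrap, simulated nulls) is
seeded from explicit arguments.

The test suite runs its simulations at sizes chosen to make each check
informative while keeping the default run fast: 1000 replicates for the
Egger-intercept calibration, 500 for the null type-I error of Cochran's Q
and the global pleiotropy test (400 simulations per test), 200 for the
weighted-median robustness and the full-pipeline recovery of the planted
0.30 mediation proportion (with 200 pleiotropy simulations and 100 bootstrap
draws per run), 20 seeds for colocalization recovery, and 5000-variant
panels for LD-score regression. These are the package's own choices of
problem size; the statistical assertions use tolerance bands appropriate to
the binomial or Monte Carlo error at those sizes.

## Known limitations

- Mediation intervals assume independent (β₁, β₂, β₃); overlapping GWAS
  samples would induce covariances the delta method here ignores.
- No multivariable MR: mediators are analysed one at a time, so correlated
  mediators can double-count shared pathways.
- The distortion component of the outlier-removal procedure (significance of
  the estimate shift after outlier removal) is out of scope; only the global
  and per-variant outlier tests are implemented.
- No Steiger directionality filtering; directionality is addressed by the
  reverse-MR stage instead.
- LDSC is single-component (no partitioned heritability) and observed-scale
  only.
- Colocalization assumes at most one causal variant per trait per region.
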