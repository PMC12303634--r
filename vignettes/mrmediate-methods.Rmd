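---
title: "Methods: two-sample MR and two-step mediation in mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR and two-step mediation in mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The model

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome from GWAS summary statistics alone. For each
instrumental SNP $j$ we observe the exposure association
$\hat\gamma_j \sim N(\gamma_j, \sigma_{\gamma j}^2)$ from one GWAS and the
outcome association $\hat\Gamma_j \sim N(\Gamma_j, \sigma_{\Gamma j}^2)$
from an independent GWAS. Under the instrumental-variable assumptions
(relevance, independence from confounders, and exclusion restriction),
$\Gamma_j = \beta\,\gamma_j$ and each ratio
$\hat\beta_j = \hat\Gamma_j/\hat\gamma_j$ estimates the causal effect
$\beta$. The package implements the standard estimator battery on
harmonized $(\hat\gamma_j, \hat\Gamma_j)$ pairs:

* **Wald ratio** (single SNP): $\hat\Gamma/\hat\gamma$ with first-order SE
  $\sigma_\Gamma/|\hat\gamma|$. The second-order delta term is omitted,
  matching common practice; with instruments passing $F > 10$ its
  contribution is below a few percent of the SE.
* **IVW**: the precision-weighted average of ratios with weights
  $w_j = (\hat\gamma_j/\sigma_{\Gamma j})^2$, equivalently weighted
  regression of $\hat\Gamma$ on $\hat\gamma$ through the origin. The error
  model is chosen by Cochran's Q: fixed effects when the heterogeneity
  test does not reject at 0.05, otherwise multiplicative random effects
  ($\mathrm{SE} = \mathrm{SE}_{FE}\sqrt{Q/(J-1)}$, floored at the
  fixed-effects SE). The paper-facing convention of reporting
  fixed-effects IVW absent heterogeneity and random-effects otherwise is
  the `auto` default.
* **MR-Egger**: weighted least squares of $\hat\Gamma$ on $\hat\gamma$
  with a free intercept after orienting every SNP to $\hat\gamma \ge 0$.
  The slope is the causal estimate; the intercept estimates the average
  directional pleiotropy. Coefficient SEs use the residual scale floored
  at 1 (no artificial precision gain from under-dispersion) and t
  reference distributions with $J-2$ df.
* **Weighted median**: the ratio distribution's weighted median via the
  half-weight-offset interpolation; consistent while valid instruments
  carry more than half the weight. SE by parametric bootstrap of the
  ratios.
* **Mode-based (simple/weighted)**: the argmax of a Gaussian kernel
  density over the ratios, bandwidth
  $\phi \cdot 0.9\min(\mathrm{sd}, \mathrm{IQR}/1.34)\,J^{-1/5}$
  evaluated on a 512-point grid spanning the ratio range plus three
  bandwidths; consistent under the zero-modal-pleiotropy assumption.
  When every ratio coincides the bandwidth degenerates and the common
  ratio is returned with the fixed-effects IVW SE.

Confidence intervals are normal ($\pm 1.96\,\mathrm{SE}$; t with $J-2$ df
for Egger), and odds ratios are $e^\beta$ for binary outcomes.

## Instrument selection and harmonization

Instruments are selected by a fixed stage order — significance threshold,
confounder exclusion list, palindrome removal, greedy LD clumping,
variance-explained/F computation, weak-instrument removal ($F \le 10$
dropped) — with counts recorded per stage so input = retained + removed.
Role-specific defaults follow the study design: molecular exposures at
$p < 5\times10^{-6}$, immune-cell mediators at $p < 1\times10^{-5}$,
disease traits used as exposures at $p < 5\times10^{-8}$; relaxing a
threshold for instrument-poor traits is an explicit caller decision,
never automatic. Clumping is greedy by ascending p-value (ties broken by
rsID) with window 10,000 kb and $r^2 < 0.001$ against a user-supplied LD
matrix; without one, SNPs are assumed pre-clumped and a warning is
logged. Confounder screening is a static one-rsID-per-line exclusion
list rather than a web-service lookup, keeping runs reproducible.

Per-SNP variance explained defaults to the t-statistic form
$r^2 = t^2/(t^2 + n - 2)$, which needs no allele frequency and makes
$F = (n-2)r^2/(1-r^2)$ exactly the squared Wald t; the
$2\hat\gamma^2\,\mathrm{eaf}(1-\mathrm{eaf})$ form for standardized
continuous traits is available by option.

Harmonization aligns outcome to exposure effect alleles by rsID:
identical alleles are kept, swapped alleles negate the outcome beta and
complement its frequency, and opposite-strand records are complemented
then re-matched. Palindromic SNPs (A/T, C/G) are always dropped — no
frequency-based rescue — trading power for fidelity to the design the
package mirrors.

## Sensitivity battery

Cochran's Q (IVW weights, $\chi^2_{J-1}$), the Egger intercept test,
MR-PRESSO, leave-one-out IVW, and the Steiger directionality test run on
every pair. MR-PRESSO simulates the null of its leave-one-out weighted
residual sum of squares (1000 draws by default) with add-one smoothing,
so empirical p-values are bounded below by $1/(n_{sim}+1)$; per-SNP
outlier p-values are Bonferroni-scaled by $J$ and the distortion test
compares the outlier-stripped IVW estimate against removals of equally
many random SNPs. Steiger compares summed instrument $r^2$ on the two
traits with the two-sample Fisher z test; the t-statistic $r^2$ is used
for both trait types, which for binary traits is an approximation on the
log-odds scale (no liability-scale correction — the package takes no
prevalence input). Pairs whose Steiger flag points the wrong way are
excluded from result tables, and IVW/Egger slope-sign disagreement is
flagged.

## FDR and two-step mediation

IVW p-values are Benjamini–Hochberg adjusted per family, one family
being all exposures of a panel against one outcome; `bh_fdr()` accepts a
family size larger than the number supplied so a partially analysed
catalog still counts its full panel (the 91-protein worked value
$3.61\times10^{-10} \times 91 = 3.29\times10^{-8}$ assumes exactly
this). For the mediator-screen family whose published arithmetic implies
an effective family of about 10 while 12 candidates were screened, the
family size stays caller-configurable; the pipeline defaults to the
number of surviving mediators.

The mediation calculus is the product of coefficients: with total effect
$\beta$ (exposure→outcome), $\beta_1$ (exposure→mediator) and $\beta_2$
(mediator→outcome), the indirect effect is $\beta_1\beta_2$ and the
mediated proportion $\beta_1\beta_2/\beta$. Step 1 requires FDR-significant
total effects; step 2 screens mediators against the outcome at nominal
significance (a panel-wide FDR over hundreds of immune phenotypes would
leave no candidates — the published design also carried nominally
significant cells into mediation); step 3 FDR-adjusts
exposure→mediator effects over the surviving mediators. No SE or CI is
attached to the proportion (point estimate only), and proportions
outside [0, 1] — possible in univariable two-step MR — are reported with
a warning rather than truncated.

## The synthetic generator

`simulate_sumstats_pair()` emulates a GWAS summary-statistics pair with
known truth: per SNP a minor-allele frequency from `maf_range`
(default 0.05–0.5), a latent instrument effect from $N(0, 0.05)$
truncated so the expected F exceeds 10, standard errors from the
standardized-trait formula $1/\sqrt{2n\,\mathrm{maf}(1-\mathrm{maf})}$,
and observed effects drawn around the truth at those SEs. Effect alleles
are oriented to be exposure-increasing ($\gamma_j > 0$); directional
pleiotropy is only a meaningful notion relative to that orientation, and
with mixed signs a planted mean pleiotropy would cancel out of every
directional diagnostic. Default scenario sizes (J = 50, n = 50,000,
$\beta = 0.3$) are typical of a well-powered molecular-trait GWAS.

Two generative anchorings are provided. The default generates outcome
effects from the *realized* exposure associations
($\hat\Gamma \sim N(\beta\hat\gamma, \sigma_\Gamma)$): this is exactly
the sampling model under which the first-order estimators are derived
(the NOME assumption), so unbiasedness, 95% coverage and nominal Q
calibration hold by construction and deviations in tests indicate real
defects. `nome = FALSE` anchors on the latent effects instead, injecting
exposure-side measurement error into the causal path; the per-SNP ratio
variance then inflates by $1 + \beta^2\sigma_\gamma^2/\sigma_\Gamma^2$
independently of instrument strength, visibly over-dispersing Q — a
property-style test demonstrates exactly this contrast. The generator
does not model LD between instruments (LD enters only through the
separate block-matrix builder), allele-frequency differences between
studies, sample overlap, or winner's curse, so passing tests speak to
estimator correctness under the stated model, not to robustness against
those real-data complications.

`simulate_mediation_triple()` shares one rsID namespace across three
tables: J exposure instruments carrying $\gamma_j$, $\beta_1\gamma_j$
and $\beta\gamma_j$ on exposure, mediator and outcome, plus J
independent mediator instruments carrying $\delta_k$ on the mediator and
$\beta_2\delta_k$ on the outcome, so each mediation step has its proper
instrument set.

## Numerical choices and determinism

Monte-Carlo p-values use add-one smoothing; bootstrap SEs default to
1000 replicates with a fixed default seed (20250721), and every
stochastic routine takes an explicit seed so pipeline reruns are
byte-identical. Ties in clumping are broken lexicographically by rsID,
making selection invariant to input row order. Result TSVs render
floating point with 15 significant digits and round-trip losslessly.
The bandwidth multiplier $\phi$ of the mode estimators is exposed but
defaults to 1; the 512-point KDE grid matches the bandwidth rule's
resolution (refining it 40-fold moves the mode by less than the grid
step, which a test verifies against a dense-grid oracle).

The test-suite simulation studies use 40–400 replicates per property and
instrument counts of 12–50 — sizes at which Monte-Carlo error is well
inside the asserted bands; the acceptance script re-runs the central
properties at 200 replicates (50 for MR-PRESSO, whose null simulation
dominates the cost at 500 draws).

## Known limitations

* Weighted-median superiority over IVW is regime-dependent: when planted
  pleiotropy is small relative to the ratio sampling noise (separation
  of a few SEs), both biases scale with the same noise and the median's
  advantage is modest; it dominates clearly only for gross invalidity or
  much larger outcome GWAS. The robustness checks report both biases
  rather than assuming a fixed ratio.
* Binary traits are handled on the log-odds scale throughout, including
  the Steiger $r^2$ approximation; no liability-scale conversion.
* One estimate per exposure–outcome pair: no multivariable MR, so
  mediation "direct effects" are derived by subtraction in the truth
  records, not estimated.
* LD information must be supplied (or SNPs pre-clumped); the package
  never estimates LD from a reference panel.
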