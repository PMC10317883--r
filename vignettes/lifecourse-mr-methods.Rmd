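---
title: "Separating childhood from adulthood genetic effects: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating childhood from adulthood genetic effects: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lifecourseMR)
```

## The scientific problem

Adiposity in childhood and adiposity in adulthood are strongly genetically
correlated, and childhood body size causally influences adulthood body
size. A univariable Mendelian-randomisation (MR) analysis that instruments
the childhood exposure therefore estimates a *total* effect that includes
the downstream path through the adulthood exposure. The lifecourse design
asks a different question: what does the childhood exposure do to an
outcome *directly*, at fixed genetic liability to the adulthood exposure?
Multivariable MR (MVMR) answers it by regressing variant–outcome effects
jointly on the variant–childhood and variant–adulthood effect vectors.

This package implements the full design on synthetic data with a known
causal structure so that every estimator property claimed here is
measurable. Nothing in the package downloads or depends on real cohort
data.

## Structural model and generator

The cohort generator simulates a biallelic variant panel laid out in LD
blocks, and phenotypes

$$C = G\gamma_C + \lambda_C U + \varepsilon_C,\qquad
  A = \varphi C + G\gamma_A + \lambda_A U + \varepsilon_A,$$
$$Y = \theta_C C + \theta_A A + \lambda_Y U + \varepsilon_Y
  \quad\text{or}\quad
  Y \sim \mathrm{Bernoulli}\bigl(\mathrm{logit}^{-1}(\alpha + \theta_C C +
  \theta_A A + \lambda_Y U)\bigr),$$

with $U \sim N(0,1)$ a shared confounder. Residual variances are solved
analytically — including the cross-covariance between the $\varphi$ path
and the direct adulthood genetics — so $C$ and $A$ have unit variance; the
binary intercept $\alpha$ is solved on the simulated liabilities to match
the configured prevalence to within 0.002. Effects $\gamma$ are drawn once
per variant from zero-mean normals and rescaled so each component's genetic
variance $\sum 2\gamma^2 p(1-p)$ equals its configured value exactly, which
makes the heritability bookkeeping of every downstream test exact rather
than approximate.

**LD model.** Within a block each haplotype is a latent multivariate normal
with exchangeable correlation `ld_rho`, thresholded at the
allele-frequency quantile; dosage is the sum of two haplotypes. This is the
simplest generator with a tunable between-variant r², which is all the
clumping and proxy machinery needs to be exercised; it makes no attempt to
mimic human LD maps, imputation, relatedness or population structure.
Blocks never mix childhood-specific, adulthood-specific and shared
variants, so LD cannot blur the age-specificity that the design depends on.

**Two-sample structure.** Exposure, outcome and validation cohorts share
the variant panel and the true effect vectors but no individuals; outcome
GWAS are computed in the outcome cohort only. Each stage draws from a
labelled sub-stream of one master seed, so a bundle is reproducible
bit-for-bit and stages can be re-run in isolation.

## Default parameters and why

| parameter | default | rationale |
|---|---|---|
| panel | 300 variants: 100 child-specific / 150 adult-specific / 50 shared | desk-scale mirror of an instrument set with more adulthood than childhood signals |
| per-allele effect SD | 0.0874 (shared-on-adult scaled by $1/\sqrt2$) | gives per-variant $F \approx n r^2 \approx 60$ in a cohort of 20,000 — the per-variant strength implied by large-biobank adiposity instruments, and strong enough that genome-wide selection is near-deterministic (little winner's curse) |
| LD blocks | size 5, latent $\rho = 0.3$ | within-block dosage $r^2 \approx$ 0.03–0.08, far above the 0.001 clumping threshold, so clumping genuinely collapses blocks |
| $\varphi$ | 0.3 | moderate causal tracking of childhood into adulthood body size |
| confounder loadings | 0.15 each | confounding present but not dominant |
| cohorts | 20,000 exposure / 20,000 outcome / 5,000 validation | large enough for stable instrument selection, small enough that a replicate takes about two seconds |
| recall cuts, misclassification | (1/3, 2/3), 0.10 | three roughly equal recall categories with moderate recall error |
| reference distribution | normal, mean 17.8, SD 2.8 kg/m² | documented placeholder for an age-11 BMI distribution in a mid-century British birth cohort; configurable, including an empirical quantile table |
| selection | $p \le 5\times10^{-8}$, $r^2 \le 0.001$, 250 kb, $0.01 \le \mathrm{MAF} \le 0.99$ | genome-wide convention |
| proxies | $r^2 > 0.8$ within 250 kb | convention; the strict inequality matters at the boundary |

The outcome menu (seven oral-glucose-tolerance traits, fasting glucose,
fasting insulin, and a binary disease outcome observed in two studies and
meta-analysed) shares one liability machinery with outcome-specific
$(\theta_C, \theta_A)$ pairs, configured so the childhood direct effect is
protective or null and the adulthood direct effect damaging on each
trait's natural orientation. These are design choices for a plausible
emulation, not estimates of any real trait.

## Phenotype construction

The recall variable is collapsed from the true childhood value by its
empirical quantile against the cut proportions, with adjacent-category
misclassification. The anchored reconstruction partitions the probability
axis at the *observed* category proportions, draws $u$ uniformly on the
individual's segment and assigns $Q(u)$ from the reference quantile
function; the sample then reproduces the reference marginal exactly in
distribution while preserving the anchor's ordering. Segments are disjoint
— the construction adds no overlap or extra noise between categories,
which is one consistent reading of how such a variable can be built; its
fidelity (Kolmogorov–Smirnov distance to the reference, and rank
correlation with the truth versus the raw 3-level coding) is measured, not
assumed.

One property of this construction is worth stating plainly: because the
within-category refinement is *random*, the assigned value carries no rank
information beyond the category — its Spearman correlation with the truth
is in fact marginally below that of the midrank-coded category variable
(random tie-breaking can only lose to midranks). The construction's value
is elsewhere: it yields a continuous phenotype on the correct measurement
scale with the correct marginal distribution, which is what the GWAS and
the SD-unit effect reporting need; only an assignment informed by
additional within-category signal could also improve the rank correlation.

Both exposures are rank inverse-normalised (Blom offset 3/8, average rank
for ties) and then residualised on sex, age and a collapsed centre factor,
in that order, before association testing. Residualisation uses ordinary
least squares; a constant covariate column is absorbed into the intercept,
any other rank deficiency is an error naming the offending columns.

## Estimators and numerical choices

All estimators are written against explicit weighted normal equations with
weights $1/\mathrm{se}^2_{\text{outcome}}$:

* **IVW** through the origin; the standard error is inflated by
  $\sqrt{\mathrm{MSE}}$ only when the weighted residual mean square exceeds
  1 (a multiplicative random-effects guard — conservative, and the common
  practice when the error model is unstated). A single variant degrades to
  the Wald ratio with a warning.
* **MR-Egger** adds an intercept after flipping rows so exposure betas are
  non-negative (required for the intercept to be interpretable); needs at
  least 3 variants and non-degenerate exposure betas. Intercepts with
  $p < 0.01$ are flagged in the pipeline's sensitivity reporting.
* **MVMR** has no intercept, needs $\ge$ 3 variants, both exposures
  measured for every instrument (never zero-imputed), and a full-rank
  exposure-beta matrix. An *exactly* zero exposure column is handled as the
  nested case: the other exposure's estimate collapses to univariable IVW
  on the same rows. Standard errors use outcome-variance weights only; no
  correction is made for sampling error in the exposure betas (see
  limitations).
* **Steiger filtering** retains a variant when its exposure variance
  explained $2\beta_x^2 p(1-p)$ strictly exceeds the outcome variance
  explained; the boundary case of equality is removed (and logged). In the
  multi-exposure set the larger of the two exposure variances is compared.
* **Harmonisation** orients by allele labels, negating and complementing
  swapped rows; palindromic variants are kept only when both frequencies
  sit on the same side of 0.5 and outside [0.42, 0.58]; non-palindromic
  rows disagreeing in frequency by more than 0.08 are dropped. Every drop
  carries a reason code. Proxies (strictly $r^2 > 0.8$, $\le$ 250 kb) borrow
  the proxy's outcome effect sign-aligned by the dosage correlation while
  keeping the index variant's exposure effect.
* **Clumping ties** on p are broken by (chromosome, position, id) so
  selection is deterministic; removal requires proximity *and* correlation
  jointly, with cross-chromosome r² treated as zero.
* **Meta-analysis** pools on the log-odds scale for binary outcomes and
  exponentiates only for reporting.
* P-values are two-sided normal throughout, and intervals are
  estimate ± 1.96 se, matching the summary-statistic convention.

## The replication harness and how performance is judged

`replicate_study()` repeats the whole pipeline over independent seeds and
reports, per method/exposure/outcome: the Monte-Carlo mean, bias against
the configured truth, the **empirical SE** (the standard deviation of the
estimates across replicates, in the usual simulation-study sense), the
standard error of the Monte-Carlo mean, and 95% CI coverage.

Two canonical experiments are exported:

* `recovery_config()` — the default design with one continuous outcome and
  direct effects $(-0.05, +0.15)$, analysed on the directly simulated
  exposures. Consistency is judged at the scale of the empirical SE, and
  coverage should sit near 0.95. Judging the *mean* against truth at the
  scale of the SE of the mean would instead demand relative bias below
  about 0.1% at 200 replicates, which no uncorrected ratio-type MR
  estimator can promise: sampling error in the exposure betas induces an
  $O(1/F)$ regression-dilution bias (here $\sim$0.5–1%, amplified in MVMR
  by the correlation between the two exposures' beta vectors). That bias
  is a property of the estimator, not a bug; the package reports it rather
  than hiding it.
* `attenuation_config()` — $\theta_C = 0$, $\varphi = 0.5$,
  $\theta_A = 0.2$, and **no shared variants**. Path tracing then gives a
  univariable childhood estimand of exactly
  $\theta_C + \varphi\theta_A = 0.10$, and the MVMR childhood direct effect
  is 0. Shared variants are excluded by design: a variant with direct
  effects on both exposures has a Wald ratio of
  $\theta_A(\gamma'/\gamma + \varphi)$, which breaks the closed form — that
  is precisely the pleiotropy MVMR is for, and with shared variants present
  only the MVMR claim survives (the default recovery experiment keeps
  them).

Recovery experiments bypass the recall construction
(`use_recall = FALSE`): the anchored variable is a shrunken monotone
transform of the truth, so GWAS betas on it are rescaled and "truth" is
only defined on the simulated scale. The default pipeline analyses the
constructed phenotype, as the design intends — its MR estimates are per SD
of the *constructed* exposure, which is also why the pipeline's childhood
estimates run slightly larger than the configured $\theta_C$.

The Egger intercept test's size is measured at the summary-statistic level
(`egger_null_rejection()`): true exposure effects drawn from a zero-mean
normal, measured with small error, outcome effects generated with zero
intercept. This isolates the test from instrument-selection effects and
runs in seconds; with 50 instruments and normal-approximation p-values the
rejection rate at $\alpha = 0.05$ sits a little above nominal (the
multiplicative guard truncates downward error inflation), around 0.03–0.07.

**Problem sizes.** The default experiments use cohorts of 20,000, a
300-variant panel, and 200 replicates in the test suite (100 in the
analysis scripts, 60 in the acceptance script); a replicate takes roughly
two seconds. These sizes were chosen so the Monte-Carlo standard errors are
small relative to the effects being checked.

## What the synthetic design does and does not show

The generator emulates: age-specific and shared genetic components, a
causal childhood→adulthood path, confounding, recall coarsening with
misclassification, two-sample separation, allele-orientation noise,
missing outcome variants, palindromic ambiguity, and multi-study binary
outcomes. Passing tests therefore demonstrate the *pipeline's* correctness
and the *estimators'* behaviour under this structure.

They do not demonstrate robustness to features the generator omits:
realistic LD and allele-frequency spectra, population stratification,
relatedness, sample overlap between exposure and outcome GWAS, selection
bias, non-linear or age-varying effects, or directional pleiotropy beyond
the shared-variant mechanism. The MVMR standard errors ignore exposure-beta
uncertainty (no conditional-F weak-instrument machinery), which is
defensible at the instrument strengths simulated here (mean F well above
100) but would understate uncertainty with weak instruments. Genetic
correlation estimation (LD-score style) is out of scope entirely.
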