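---
title: "Bidirectional two-sample Mendelian randomization with bimr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional two-sample Mendelian randomization with bimr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimr)
```

## The design

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome using genetic variants as instrumental variables,
with the variant-exposure and variant-outcome associations taken from two
separate GWAS. A variant is a valid instrument when it is (i) associated
with the exposure, (ii) independent of confounders of the
exposure-outcome relationship, and (iii) affects the outcome only through
the exposure (no horizontal pleiotropy). `bimr` implements the full
analysis for a pair of binary traits — the motivating application is the
bidirectional relationship between major depressive disorder (MDD) and
gastroesophageal reflux disease (GERD) — run in both directions with
direction-specific instruments.

For variant $j$ let $\hat\gamma_j$ ($\sigma_{Xj}$) be its estimated
log-odds effect on the exposure and $\hat\Gamma_j$ ($\sigma_{Yj}$) its
effect on the outcome, after harmonization to a common effect allele. The
per-variant Wald ratio is $\hat\beta_j = \hat\Gamma_j/\hat\gamma_j$ with
first-order standard error $\sigma_{Yj}/|\hat\gamma_j|$. All causal
effects are log-OR of the outcome per unit log-OR of the exposure, and are
also reported as odds ratios by exponentiation.

## Instrument selection and harmonization

Instruments are the exposure associations at $p \le 5\times10^{-8}$
(`select_by_pvalue()`), pruned to mutual independence by greedy LD
clumping (`ld_clump()`): variants are visited in order of ascending
p-value (ties broken lexicographically by id, for determinism) and a
variant is discarded when its squared correlation with an already-accepted
variant exceeds 0.001, or, when the pair has no LD entry, when it lies
within 10,000 kb of one on the same chromosome; an LD entry always takes
precedence over physical distance. The LD matrix is an input — `bimr`
does not compute LD from reference panels.

`harmonize()` aligns each shared variant's outcome association onto the
exposure's effect allele, handling swapped alleles (sign flip, frequency
complement) and strand flips (allele complement). Palindromic variants
(A/T, C/G) carry no strand information, so they are retained only when
both effect-allele frequencies are available, both sit outside
$[0.42, 0.58]$, and both fall on the same side of 0.5 after nominal
alignment; an opposite-side pair could in principle be rescued by
flipping, but we treat it as unresolvable and drop it, preferring a lost
instrument to a silently wrong sign. The 0.42 bound is the common
conservative default; it is tunable (`palindrome_eaf_limit`). Variants in
the exposure but absent from the outcome are dropped — no proxy lookup.

## The estimators

**IVW.** With weights $w_j = (\hat\gamma_j/\sigma_{Yj})^2$ (first-order:
exposure-side uncertainty is ignored in the weight, matching the Wald SE
definition), $\hat\theta = \sum w_j\hat\beta_j / \sum w_j$, equivalent to
weighted regression of $\hat\Gamma$ on $\hat\gamma$ through the origin.
The fixed-effect SE is $(\sum w_j)^{-1/2}$; the principal analysis is the
multiplicative random-effects model, which inflates the SE by
$\max\{1, \sqrt{Q/(J-1)}\}$ where $Q$ is Cochran's statistic at
$\hat\theta$ — heterogeneity widens the interval but never narrows it.
Normal reference for p-values and CIs.

**MR-Egger.** Weighted regression of $\hat\Gamma_j$ on $\hat\gamma_j$
*with* an intercept (weights $1/\sigma_{Yj}^2$), after orienting all
exposure effects positive. The slope is the pleiotropy-corrected effect;
the intercept estimates the mean directional pleiotropic effect, and its
two-sided test is the standard directional-pleiotropy diagnostic. SEs
carry the multiplicative overdispersion $\max\{1,\sqrt{Q_E/(J-2)}\}$ and
inference uses $t_{J-2}$. The intercept is unbiased for the mean direct
effect under InSIDE *and* negligible measurement error in
$\hat\gamma$ (NOME); with noisy exposure effects it inherits a dilution
bias of order $\theta\bar\gamma(1-\lambda)$, where $\lambda$ is the
regression-dilution factor — our simulation tests therefore validate the
intercept under effectively NOME conditions (a very large exposure GWAS).

**Weighted median.** Ratio estimates sorted ascending; with normalized
weights $w'_j \propto 1/\mathrm{se}(\hat\beta_j)^2$ and midpoint
cumulative weights $s_j = \sum_{i\le j} w'_i - w'_j/2$, the estimate is
the linear interpolation of the sorted ratios at $s = 1/2$. It is
consistent when valid instruments contribute at least half the weight.
The SE is a seeded parametric bootstrap (default 1,000 replicates,
ratios redrawn from $N(\hat\beta_j, \mathrm{se}_j^2)$).

**Contamination mixture.** Each ratio comes either from a valid component
$N(\theta, \mathrm{se}_j^2)$ or an invalid component
$N(0, \mathrm{se}_j^2+\psi^2)$. The profile log-likelihood at a candidate
$\theta$ takes the better component per variant and sums; the estimate
maximizes it over a grid (default: IVW estimate $\pm 10$ SE in 2,001
steps — wide enough to contain any plausible interval, fine enough that
discretization error is far below the SE) and the 95% confidence set is
$\{\theta: 2[\ell(\hat\theta)-\ell(\theta)] \le 3.84\}$, possibly a union
of disjoint intervals. $\psi$ defaults to 1.5 times the SD of the ratio
estimates (with a fallback to the median ratio SE for degenerate,
zero-spread sets). A 1-df likelihood-ratio test of $\theta=0$ supplies
the reported p-value.

**MR-PRESSO.** The global test compares the observed sum of leave-one-out
weighted squared residuals with a parametric null in which *both* effect
estimates are redrawn ($\hat\gamma^*_j \sim N(\hat\gamma_j,
\sigma_{Xj}^2)$, $\hat\Gamma^*_j \sim N(\hat\theta_{(-j)}\hat\gamma_j,
\sigma_{Yj}^2)$). Resampling only the outcome side would leave the
exposure-noise contribution to the observed residuals unmatched in the
null and make the global test anticonservative whenever exposure effects
carry estimation noise; the test suite's null-calibration check holds for
the both-sides null. Per-variant
outlier p-values are the exceedance fractions of each variant's simulated
residuals, Bonferroni-corrected across variants and flagged at 0.05. The
distortion test compares the relative change
$(\hat\theta_{corr}-\hat\theta_{raw})/|\hat\theta_{raw}|$ with the
changes from removing 1,000 random subsets of the same size. All
empirical p-values use $(r+1)/(n_{sim}+1)$, so zero p-values cannot
occur; everything is seeded and bit-reproducible.

## Instrument strength and power

Per-variant F statistics are $(\hat\gamma_j/\sigma_{Xj})^2$; the variance
explained uses the standardized-trait approximation
$r^2_j = 2f_j(1-f_j)\hat\gamma_j^2$ (with $f_j$ the effect-allele
frequency), summed to $R^2$ and converted to an aggregate
$F = \frac{n-k-1}{k}\frac{R^2}{1-R^2}$. Analytic power for a binary
outcome with $n$ samples and case fraction $K$ at two-sided level
$\alpha$ is
$\Phi(|\ln \mathrm{OR}|\sqrt{n\,r^2\,K(1-K)} - z_{1-\alpha/2})$ — the
standard approximation given that the IVW variance is roughly
$1/(n\,r^2\,K(1-K))$. Both formulas are stated in output metadata
because different online calculators make slightly different
approximations; published F and power values can only be matched exactly
when the $r^2$ behind them is known.

## The synthetic-data generator

`generate_two_sample()` draws minor-allele frequencies
$f_j \sim U(0.10, 0.35)$ and true exposure effects
$\gamma_j \sim N(0.15, 0.03^2)$ — at biobank-scale sample sizes this
gives per-variant F statistics of a few hundred, matching strongly
instrumented analyses. Standard errors follow the case-control
allele-count approximation
$\sigma = 1/\sqrt{2f(1-f)\,n\,K(1-K)}$, so `n_exposure`, `n_outcome` and
the case fractions are interpretable as real case/non-case counts. True
outcome effects are $\Gamma_j = \theta\gamma_j + \alpha_j$, where the
direct effects $\alpha_j$ are zero (`none`), mean-zero (`balanced`),
positive-mean (`directional`) or correlated with $\gamma_j$
(`inside_violating`) for a configurable fraction of variants. Reported
orientation (which allele is "effect") is randomized per study, and
outcome records may be reported on the opposite strand, so generated
tables exercise the whole harmonization path; a configurable fraction of
variants is palindromic. Everything is driven by one seed and is
bit-reproducible.

Two scenario packs mirror the motivating study designs:
`"mdd_to_gerd"` (31 instruments; exposure GWAS 173,005 with 59,851
cases; outcome GWAS 385,276 with 80,265 cases; true effect $\ln 1.31$)
and `"gerd_to_mdd"` (24 instruments; designs reversed; true effect
$\ln 1.28$).

What the generator does *not* emulate: realistic LD (only identity
matrices plus optional correlated test blocks), sample overlap between
the two GWAS, allele-frequency estimation noise (reported frequencies are
the true ones — at these sample sizes frequency error is negligible
against the 0.42 palindrome bound), winner's-curse selection of
instruments, and population stratification. Passing simulation tests
therefore demonstrate correctness of the estimators under their stated
sampling models, not robustness to those real-data complications.

## Worked example

```{r example, eval = FALSE}
sim <- generate_two_sample(mr_scenario("mdd_to_gerd", seed = 1))
dir <- tempfile()
paths <- write_two_sample(sim, dir)

report <- mr_run_direction(paths[["exposure"]], paths[["outcome"]],
                           config = mr_config(seed = 1),
                           ld = paths[["ld"]],
                           exposure_name = "MDD", outcome_name = "GERD")
report
plot(report$fit)
```

The same pair of tables can be analyzed in both directions with
`mr_run_bidirectional()`, which flags identical inputs as complete sample
overlap and tolerates one direction failing (e.g. too few instruments)
while the other completes.

## Numerical and design choices

- **First-order weights** everywhere ($\sigma_{Yj}$ only): consistent
  with the Wald SE definition; recorded in report metadata.
- **Normal reference** for IVW and weighted-median inference, $t_{J-2}$
  for Egger: the documented convention, so tests can be exact.
- **Degenerate inputs:** one instrument degenerates IVW to the Wald ratio
  with a warning; Egger and the weighted median refuse fewer than 3
  instruments, MR-PRESSO fewer than 4; zero-spread ratio sets give
  $Q = 0$, every estimator returning the common ratio, and a positive
  fallback $\psi$ for the contamination mixture.
- **Tie-breaks:** equal clumping p-values resolve lexicographically.
- **Seeds** are explicit arguments with a fixed default (1); all
  stochastic components restore the caller's RNG state.
- **Empirical p-values** use $(r+1)/(n+1)$.
- No multiple-testing adjustment is applied across directions or
  outcomes; the report notes this.

Simulation problem sizes in the test suite (1,000 replicates for type-I
error and CI coverage, 100–500 for recovery and detection checks, 500–
1,000 inner replicates for MR-PRESSO) were chosen so Monte-Carlo error is
small against each tested tolerance while the whole suite runs in well
under a minute per property on a laptop.

## Limitations

- Correlated instruments are not modelled: the IVW/Egger/median
  likelihoods assume independent variants, which is why clumping at
  $r^2 \le 0.001$ precedes estimation.
- No proxy-variant substitution, no multivariable MR, no mode-based or
  MR-RAPS estimators, no Steiger directionality filtering.
- Binary-trait SE approximations assume logistic-scale effects from
  roughly balanced, well-powered case-control GWAS; rare-disease designs
  (case fractions near 0) stretch the approximation.
- The Egger intercept's dilution bias under weak instruments (NOME
  violation) is inherent to the estimator; `bimr` reports per-variant F
  statistics so users can judge exposure-noise severity.
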