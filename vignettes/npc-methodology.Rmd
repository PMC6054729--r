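---
title: "Permutation inference for two-group clinical comparisons: partial tests, nonparametric combination, and Holm step-down"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation inference for two-group clinical comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npcholm)
```

## The problem

A clinical cohort is split into two diagnostic groups — here Crohn's disease
(CD) and ulcerative colitis (UC), the two inflammatory bowel diseases — and
compared on $K$ outcome variables of mixed type: ages, therapy durations and
comorbidity scores (numeric) alongside smoking status, surgery, adverse
events and other yes/no indicators (categorical). Three questions arise:

1. Does each variable, marginally, differ between the groups?
2. Do the groups differ *at all*, jointly over all $K$ variables?
3. Which marginal findings survive correction for testing $K$ hypotheses
   at once?

`npcholm` answers all three within one permutation framework, avoiding the
normality and homoscedasticity assumptions that parametric multivariate
tests would impose on exactly the kind of skewed, mixed-type data clinical
registries produce.

## Model and procedure

Write the data as $X_{icu}$, $i = 1, \dots, K$ variables, $c = 1, 2$ groups,
$u = 1, \dots, n_c$ units. The global null is the intersection
$H_0 = \bigcap_i \{X_{i1} \overset{d}{=} X_{i2}\}$ against the union
alternative $H_1 = \bigcup_i \{X_{i1} \overset{d}{\ne} X_{i2}\}$. Under
$H_0$ the pooled units are exchangeable between groups, which licenses
permutation inference.

**Partial tests.** Each variable gets a one-dimensional statistic,
significant for large values:

* numeric: $T_i = |\bar{X}_{i1} - \bar{X}_{i2}|$, the unstandardized
  absolute mean difference (a pooled-variance studentized version is
  available via `analysis_config(studentize = TRUE)` for unequal-variance
  robustness; the default is the plainer statistic);
* categorical: the likelihood-ratio statistic
  $G = 2 \sum_{\text{cells}} O \ln(O/E)$ of the $2 \times L$ group-by-level
  table, with $0 \ln(0/E) = 0$, referred to its permutation distribution
  rather than the asymptotic $\chi^2$ — the asymptotic reference would sit
  oddly in an otherwise exact framework.

**Conditional Monte Carlo.** One sequence of $B$ group reassignments is
drawn (uniform shuffles of the observed label vector; the first
"reassignment" is always the observed labeling itself), and *every*
variable's statistic is recomputed on *the same* sequence. The raw p-value
is

$$\hat{p}_i = \frac{\#\{b : T_{ib} \ge T_{i,\mathrm{obs}}\}}{B},$$

so $\hat p \in [1/B, 1]$: with the study's $B = 10{,}000$ the smallest
attainable raw p-value is 0.0001 and the largest below 1 is 0.9999 —
precisely the extreme values a practitioner sees in this kind of output.
When $\binom{n_1+n_2}{n_1}$ is small (at most `exact_threshold`, default
20,000) the package switches to exhaustive enumeration and the p-values are
exact rather than estimated.

**Nonparametric combination.** Sharing the assignment sequence is what makes
the joint distribution of $(T_{1b}, \dots, T_{Kb})$ carry the dependence
among variables without modeling it. Each column is converted to
significance levels $\lambda_{ib}$ (the within-column survival fraction of
$T_{ib}$), each row is collapsed by a combining function $\psi$ —

* Fisher: $-2\sum_i \ln \lambda_i$ (default),
* Liptak: $\sum_i \Phi^{-1}(1-\lambda_i)$,
* Tippett: $\max_i (1-\lambda_i)$,

— and the combined p-value is the survival level of the observed row's
$\psi$ within the $B$ combined values. Rejection at level $\alpha$ tests the
global null. The default is Fisher, the combination literature's customary
choice; all three are exposed because they weight evidence differently
(Tippett follows the single strongest variable, Fisher and Liptak aggregate).

**Holm step-down.** Raw partial p-values are sorted ascending and hypotheses
rejected while $p_{(i)} < \alpha/(K-i+1)$; the first failure stops the
procedure. Adjusted p-values use the monotone form
$q_{(i)} = \max_{j \le i} \min(\text{cap}, (K-j+1)\,p_{(j)})$, so
thresholding $q \le \alpha$ reproduces the sequential decisions at every
level. This controls the familywise error rate and dominates the classical
Bonferroni correction.

## Worked example

```{r example}
model <- default_model()        # the published CD/UC cohort structure
cohort <- generate_cohort(model, seed = 7)
cohort

report <- run_analysis(cohort, config = analysis_config(B = 2000, seed = 1))
head(render_report(report, style = "holm"), 8)
```

The multiplicity stage is also available standalone. Applied to the raw
p-values published by the study the synthetic model emulates, it reproduces
the published adjusted values and the nine-variable significant set:

```{r published}
tab <- adjust_pvalues(ibd_raw_pvalues(), alpha = 0.05, cap = 0.9999)
tab[tab$significant, c("variable", "raw_p", "rank_i", "adj_p")]
```

## Numerical choices

* **Identity assignment included.** The observed labeling is counted in both
  numerator and denominator of every p-value, guaranteeing $\hat p \ge 1/B$
  and the validity of the estimator at any $B$.
* **Tie tolerance.** Two statistic values within $10^{-12}$ (relative) are
  tied: permutations of the same sums differ only by floating-point
  reassociation, and without the tolerance such noise would randomly break
  exact ties.
* **Clamping.** For Fisher/Liptak, significance levels are clamped into
  $[1/(2B),\, 1 - 1/(2B)]$ before the log/quantile transform. The clamp
  keeps $\psi$ finite at the attainable extremes and, being strictly
  monotone on the attainable grid, never reorders rows.
* **Duplicated random splits are kept.** Deduplicating Monte Carlo
  reassignments would bias the estimator; exact mode enumerates each
  distinct split exactly once instead.
* **Missing data.** Units missing a variable are removed for that variable
  only (casewise per-variable deletion, valid under MCAR — listwise deletion
  would discard information the permutation framework can use). The
  unit-level assignment sequence is generated once and restricted to each
  variable's complete cases, the closest feasible preservation of joint
  processing under missingness. If a permuted split leaves one group empty
  among a variable's complete cases (conceivable only under extreme
  missingness), that row's statistic is set to $-\infty$ — never extreme,
  significance level 1 — rather than dropped, keeping the $B \times K$
  matrix row-aligned.
* **Degenerate variables** (a single observed value, or one group fully
  missing) yield a flagged result with $p = 1$ and a warning instead of
  aborting a $K$-variable run.
* **Ties among raw p-values** in the Holm sort are broken by input order
  (stable sort); the cumulative-maximum adjustment makes the adjusted values
  invariant to the tie order.
* **Adjusted-p cap.** Default 1. `cap = 0.9999` reproduces the convention of
  permutation software whose p-value grid at $B = 10{,}000$ saturates at
  0.9999; the published adjusted values this package reproduces use that
  convention.
* **Floor rendering.** A combined p-value at the $1/B$ floor is rendered
  `0.0000 (< 1e-04)` in the summary style: the estimate is an upper-bounded
  "below resolution", not a literal zero.

## The synthetic cohort generator

The generator exists because the study's patient records were never
deposited. `default_model()` transcribes the published per-group summaries —
631 CD and 1091 UC patients; 5 numeric variables as mean ± SD; 17 binary
variables as the first printed percentage — and `generate_cohort()` draws
numeric cells as independent Gaussians and binary cells as independent
Bernoullis at those parameters. `null_model()` copies group-1 parameters
over group 2 for exact-null size simulations.

Deliberate simplifications, and what they imply:

* **Gaussian numerics.** Real ages and durations are non-negative and
  skewed; the generator matches the first two moments, which is what the
  mean-difference statistic consumes. Permutation validity never needed
  normality. Zero-truncation is available per variable; the Charlson
  comorbidity index (an integer score) is generated as a zero-truncated
  Gaussian rounded to the nearest integer, which necessarily shifts its
  sample mean above the nominal parameter.
* **Independence across variables.** The study quantifies no correlation
  structure, so none is invented. Consequently passing tests demonstrate
  correct behaviour under independence; the NPC machinery itself is
  dependence-agnostic by construction, but the simulations here do not
  exercise dependent data.
* **Cohort-wide durations.** Therapy-duration variables are generated for
  every unit, although in the real cohort they are meaningful only for the
  treated subset (18.4%/8.7% of patients for biologics). At the full
  $n = 1722$ an effect of 3.8 months against SDs of 7–9 is overwhelming
  (normal-theory $z \approx 9$), so synthetic cohorts make
  "duration of biological treatment" far *more* significant than the
  published raw p-value of 0.0053 obtained from the treated subset. This is
  the main respect in which the generator's significance pattern differs
  from the published one, and it is why effect-recovery simulations
  recover a superset of the published nine-variable significant set rather
  than exactly that set (the Charlson score, amplified further by
  truncation, behaves similarly). The generator nevertheless keeps the
  published cohort-level parameters: re-scoping durations to a treated
  subset would require treatment-conditional parameters the study does not
  report.

## Simulation scale

The shipped checks use problem sizes chosen to give stable Monte Carlo
estimates while remaining comfortably reproducible on a laptop: size
control on 1,000 null cohorts of $n = 60/100$ with $K = 10$ and $B = 1000$
(the 99% binomial band around $\alpha = 0.05$ is then $\pm 1.8$ points);
effect recovery on 100 cohorts at the full published sizes with $B = 2000$
(p-value resolution 0.0005, an order of magnitude below the smallest Holm
threshold at $K = 22$); oracle equivalence by exhaustive enumeration on
cohorts of at most 10 units, where the full split set is at most
$\binom{10}{5} = 252$.

## Limitations

* Two groups only; no stratification, no restricted (one-sided
  multivariate) alternatives, no post-stratification adjustment.
* No imputation: missingness handling is deletion under an MCAR assumption.
* The generator reproduces marginal moments, not dependence, skewness,
  center effects or the treated-subset structure of duration variables; see
  above for what that implies about effect-recovery results.
* Holm is the only multiplicity procedure offered (no FDR control).
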