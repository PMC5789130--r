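---
title: "Signal detection with gamma-Poisson shrinkage, MCEM confounder filtering, and multi-source combination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal detection with gamma-Poisson shrinkage, MCEM confounder filtering, and multi-source combination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvmcem)
```

This vignette is the package's own account of the statistical machinery:
the models, the numerical choices behind them, what the synthetic data
generator does and does not emulate, and the known limitations. Everything
quantitative stated here is computed by the test suite or by
`scripts/acceptance.R`; nothing is quoted from external analyses.

## 1. Data model and contingency statistics

A spontaneous case report is a set of drugs, a set of ADRs, a reporting
year, and optionally a reporter-designated primary-suspect drug per ADR.
Counting is per distinct report: a drug or ADR repeated within one report
counts once. For a drug–ADR pair, the 2×2 table cells are `n00` (reports
with both), `n01` (drug without the ADR), `n10` (ADR without the drug) and
`n11` (neither); the expected count under independence is

$$E = \frac{(n_{00}+n_{01})\,(n_{00}+n_{10})}{n_{++}},$$

the product of the with-drug and with-ADR margins over the grand total —
the standard relative-reporting-ratio baseline. A widely circulated
alternative printing of this baseline multiplies the drug margin by the
*without*-ADR column $(n_{01}+n_{11})$ instead; that form would make $E$
the expectation of a drug-and-no-ADR cell, so we treat it as an erratum,
but expose it behind `strict_margins = TRUE` in `build_contingency()` and
`expected_count()` for auditability.

`build_contingency()` supports three counting modes: `cooccurrence`
(every drug in a report is credited with every ADR in it), `assigned`
(each ADR occurrence credits exactly one drug — or fractional weights
summing to one, which is how the MCEM running mean enters), and
`primary_suspect` (reporter annotations where available, co-occurrence
fallback elsewhere, so partially annotated corpora remain scorable). Under
`assigned` counting, per-ADR count mass is conserved: summing `n00` over
drugs recovers the number of reports mentioning the ADR.

## 2. The gamma-Poisson shrinker

The observed count for a pair is modelled as Poisson with mean $\lambda E$,
and the relative reporting ratio $\lambda$ receives the five-parameter
mixture prior

$$\lambda \sim w\,\mathrm{Ga}(\alpha_1, \beta_1) + (1-w)\,\mathrm{Ga}(\alpha_2, \beta_2)$$

(shape/rate). The marginal probability of a count is negative binomial,

$$f(n_{00}; \alpha, \beta, E) = \Bigl(1+\tfrac{\beta}{E}\Bigr)^{-n_{00}}
\Bigl(1+\tfrac{E}{\beta}\Bigr)^{-\alpha}
\frac{\Gamma(\alpha+n_{00})}{\Gamma(\alpha)\,\Gamma(n_{00}+1)},$$

computed in log space throughout. Two deliberate reading corrections are
baked in, both verifiable by the normalization and quadrature tests:

* the denominator carries $\Gamma(n_{00}+1)$ — i.e. $n_{00}!$ — without
  which the density does not sum to one over the count support; writing it
  as a gamma function also lets fractional Monte Carlo counts be scored;
* the posterior mixture weight on the components
  $\mathrm{Ga}(\alpha_k+n_{00}, \beta_k+E)$ is the *posterior* probability
  $Q_n = w f_1 / (w f_1 + (1-w) f_2)$, not the prior weight $w$; all
  posterior summaries (mean, variance, quantiles) use $Q_n$.

The posterior expectation of $\log_2\lambda$ uses the digamma identity
$\mathbb E[\ln\lambda] = \psi(\alpha+n_{00}) - \ln(\beta+E)$ per component;
`EBGM` is two to that power, and `EB05`/`EB95` invert the posterior mixture
CDF by bracketed root finding between the two component quantiles (which
provably bracket the mixture quantile) at 1e-9 relative tolerance. The
posterior variance of $\log_2\lambda$ (trigamma within-component variance
plus between-component spread) is carried along so SRS signals can enter
the combination stage with an honest uncertainty.

### Prior estimation

The prior is fitted by maximizing the summed log marginal likelihood with
BFGS on transformed parameters (logit weight, log gamma parameters). Three
fixed starting points are used — DuMouchel's canonical start
$(w, \alpha_1, \beta_1, \alpha_2, \beta_2) = (1/3, 0.2, 0.1, 2, 4)$ plus
two fixed perturbations of it — rather than randomly jittered starts, so
the fit is a deterministic function of the data and needs no random
stream. Convergence failures are reported through `converged = FALSE`,
never silently, and all-identical counts trigger a degeneracy warning.

Gamma parameters are boxed to $[10^{-8}, 10^8]$ with a smooth penalty.
This is a numerical-validity constraint, not a statistical prior: beyond
$\alpha \approx 2^{53}$ the difference
$\ln\Gamma(\alpha+n)-\ln\Gamma(\alpha)$ is no longer representable in
double precision and a runaway point-mass component can masquerade as an
infinite-likelihood optimum. Within the box the likelihood surface is
evaluated accurately and the constraint is never active at legitimate
optima.

## 3. The MCEM confounder filter

The filter operationalizes the assumption that each ADR occurrence in each
report has one major causal drug. Iteration 0 scores all co-occurring
pairs. Each subsequent iteration:

1. for every (report, ADR) occurrence, draws one drug from the report's
   drug set with probability proportional to
   $\max(\mathrm{score}, \mathrm{floor})$ of the (drug, ADR) pair — EBGM by
   default, EB05 optionally; the floor (default $10^{-6}$) keeps drugs
   unseen in early iterations samplable;
2. rebuilds counts. Two counting modes are supported because "accumulate
   the sampled drug across iterations" is ambiguous: `last_sample` uses
   the current draw only (textbook MCEM with Monte Carlo sample size one),
   while the default `cumulative_mean` uses the running mean of all
   post-burn-in draws as fractional counts, which suppresses Monte Carlo
   noise and converges as iterations accumulate;
3. refits the prior (initialized at the previous optimum) and rescores.

The stopping objective is the fitted prior's attained marginal
log-likelihood — the M-step's maximized value — and the loop stops when its
absolute change drops below `tol` (default $10^{-3}$). The scored pair
universe is frozen at the iteration-0 co-occurrence pairs so this objective
is comparable across iterations. In practice the objective change scales
with the number of reports and rarely crosses a fixed threshold; the
`max_iter` cap (with `converged = FALSE` recorded in the trace) is then the
effective stopping rule, which is also the method's acknowledged weak
point. Draws are vectorized with the Gumbel-max trick; runs are
bit-reproducible given the configuration, and the caller's RNG state is
restored afterwards.

If an iteration's counts are exactly those of the previous iteration (for
instance when every report has a single drug and every assignment is
forced), the previous fit is reused, so the degenerate case reproduces
plain MGPS scores exactly rather than up to optimizer noise.

## 4. Multi-source combination

Scores from $K$ sources enter on a common unbounded scale — $\log_2$
relative risk. SRS signals use the posterior mean and variance of
$\log_2\lambda$; external sources supply their own score and variance
columns. The model is the normal–normal hierarchy

$$y^{(l)} \mid \varphi_l \sim N(\varphi_l, \sigma_l^2), \qquad
\varphi_l \sim N(\theta, \tau^2),$$

with the shrinkage estimate
$\hat\varphi_l = c_l\,y^{(l)} + (1-c_l)\,\theta$,
$c_l = \tau^2/(\tau^2+\sigma_l^2)$.

The pair summary $y^{(l)}$ is a reliability-weighted pooling: within a
source, a pair's replicate scores (e.g. per-year tables) combine by
inverse-variance weighting; across sources, weights are the reciprocal of
each source's *mean* variance, normalized over the sources that observe the
pair, so $y^{(l)}$ is a convex combination and
$\sigma_l^2 = \sum_k w_k^2 v_{lk} / (\sum_k w_k)^2$ follows by error
propagation. The normalization and the propagation variance are our
resolutions of two defects in the commonly printed pooling formula, whose
inner summation indices cannot be evaluated as written; the unnormalized
literal form remains available behind `strict_eq10 = TRUE`. Variance
propagation is used rather than the empirical across-source variance
because the latter is undefined for a pair observed by a single source.

$\theta$ and $\tau^2$ are estimated by EM on the summaries: E-step
$m_l = c_l y_l + (1-c_l)\theta$, $v_l = c_l \sigma_l^2$; M-step
$\theta \leftarrow \overline{m_l}$,
$\tau^2 \leftarrow \overline{v_l + (m_l-\theta)^2}$, with $\tau^2$ floored
at $10^{-12}$ and convergence at $10^{-8}$ on the larger parameter change.
The marginal likelihood is non-decreasing across iterations (a tested
invariant). Estimating from the summaries $y^{(l)}$ — not jointly from the
raw per-source scores — matches the conditional-independence reading of
the hierarchy.

One behavior worth knowing: when one source scores vastly more pairs than
the others — a full SRS table next to claims scores available only for
reference pairs — the thousands of single-source null pairs enter the EM
data as near-identical, confidently shrunk summaries, and the Gaussian
likelihood then prefers $\tau^2 \to 0$, collapsing every $\hat\varphi_l$
toward $\theta$ and destroying the ranking. The model is answering
honestly that the declared variances explain all of the bulk's spread, but
it is the wrong experimental design. Combination studies therefore
conventionally restrict to the pairs common to all sources;
`combine_signals(..., common_only = TRUE)` (the pipeline default) applies
exactly that restriction, and the hierarchy then sees a balanced mix of
signal and null pairs with a healthy $\tau^2$. Users combining unrestricted
score tables should inspect the fitted $\tau^2$.

## 5. Evaluation

AUC uses the Mann–Whitney rank formulation with ties counted one half.
Reference pairs that never received a score are, by default, assigned the
minimum observed score minus one so that absence of evidence ranks below
all evidence for every method symmetrically; `missing_scores = "exclude"`
drops them instead. Both conventions are common and the choice is exposed
because it matters for sparse negatives. Per-outcome AUCs and their mean
("average AUC") are reported alongside the pooled AUC. Signal calling uses
a strict inequality (`EB05 > 2` by default), and `detection_timeline()`
reports the earliest year a rule fires on cumulative per-year scorings.

## 6. The synthetic study and what it shows

The generator emulates the structure the method targets, with defaults
chosen once as a realistic desk-scale study and used by the tests and the
acceptance script:

* 20,000 reports over 200 drugs and 30 ADRs; 25 planted causal pairs at
  relative risk 5 (`causal_rr`);
* 48% of reports mention 2–4 drugs (`p_multi_drug`), drawn with
  probability 0.9 from one of 40 co-prescription clusters of 5 drugs —
  the confounding mechanism, chosen as the simplest device that makes
  cluster-mates of a causal drug inherit a spurious association
  (empirically, their co-occurrence relative reporting ratio exceeds 1.2,
  a tested invariant);
* each drug in a report triggers its planted ADR with probability
  `background_adr_rate × causal_rr` (capped at one); ADRs with no causal
  drug present appear at the background rate of 0.01 per report, so ADRs
  are rare events; every occurrence is dropped with probability 0.2
  (under-reporting), and reports left empty are discarded and regenerated;
* reporters record a primary suspect for 70% of causally triggered,
  retained occurrences, and point at the true cause 60% of the time —
  deliberate imperfection, since real reporter annotations are unreliable;
* external sources score the reference pairs as true $\log_2$ RR plus
  Gaussian noise with per-source standard deviations (0.3 and 0.8 by
  default) and honestly declared variances, so the reliability ordering
  of the pooling weights is observable.

The reference standard pairs every planted positive with its cluster-mate
negatives — exactly the confounded pairs the filter must suppress — plus
random negatives up to three per positive.

What passing tests show: on data generated by this mechanism, the MCEM
step reallocates count mass from confounders to causal drugs and improves
the ranking AUC over plain co-occurrence MGPS (mean over 20 seeds), and
combination with reliable external sources improves it further. What they
do not show: performance on real SRS corpora, whose vocabulary sizes,
duplicate reports, terminology hierarchies, longitudinal patterns and
label noise the generator deliberately does not model, and for which the
drug-drug-interaction and cohort-heterogeneity cases excluded here
(one-cause-per-ADR is an assumption, not a fact) can matter.

## 7. Problem sizes and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `tol` (MCEM) | 1e-3 | stop when the marginal log-likelihood change falls below this |
| `max_iter` (MCEM) | 50 | iteration cap; 6 is used in the bundled studies, by when count fractions have stabilized |
| `burn_in` | 1 | draws excluded from the running mean |
| `score_floor` | 1e-6 | sampling floor preventing zero-probability lock-in |
| `count_mode` | cumulative_mean | fractional running-mean counts |
| EM `tol` | 1e-8 | hyperparameter convergence |
| quantile tolerance | 1e-9 (rel.) | EB05/EB95 root finding |

The test suite runs the full 20-seed MCEM study at 20,000 reports in a few
minutes; unit tests use scaled-down configurations (hundreds to thousands
of reports) of the same generator.

## 8. Known limitations

* The MCEM stopping rule is heuristic; with likelihood changes scaling in
  the data size, the iteration cap is usually what stops the loop.
* One prior is fitted per report set, unstratified (no age/sex/year
  strata), and only pairwise associations are scored (no higher-order
  item sets, no drug–drug interactions).
* The combination stage assumes approximately Gaussian, unbiased scores on
  the log2 scale; heavily shrunk SRS scores violate unbiasedness and can
  drive $\tau^2$ to zero (section 4).
* Reference standards with negatives that never co-occur make the AUC
  depend on the missing-score convention; both conventions are provided.
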