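# pvmcem

Drug safety signal detection from spontaneous adverse-event reports, with
explicit handling of concomitant-drug confounding and multi-source evidence
combination.

## The problem

Spontaneous reporting systems (SRS) such as FAERS collect case reports, each
listing the drugs a patient received and the adverse drug reactions (ADRs)
observed. Disproportionality analysis flags drug–ADR pairs whose observed
report count exceeds what independence would predict. Two well-known
obstacles are:

* **Concomitant confounding** — roughly half of reports mention several
  drugs, and when only one of them caused an ADR, its co-prescribed
  companions inherit a spurious association.
* **Single-source weakness** — SRS data are under-reported and biased, and
  truly causal ADRs are rare; other observational health data (claims, EHR)
  see different slices of reality with different reliability.

`pvmcem` implements a three-stage answer for R users (pharmacoepidemiologists
and methods researchers):

1. **MGPS** — the Multi-item Gamma Poisson Shrinker. For pair *(i, j)* with
   observed count *n₀₀* and expected count
   *E = (n₀₀+n₀₁)(n₀₀+n₁₀)/n₊₊*, the relative reporting ratio λ gets a
   two-component gamma mixture prior
   *λ ~ w·Ga(α₁, β₁) + (1−w)·Ga(α₂, β₂)*, fitted by maximum marginal
   likelihood over all pairs. Posterior summaries per pair: the mixture
   weight *Qₙ*, the posterior mean of log₂ λ (whose power-of-two scale is
   **EBGM**), and posterior quantiles **EB05**/**EB95**. `EB05 > 2` is the
   conventional signal rule.
2. **MCEM confounder filtering** — a Monte Carlo EM loop that assumes each
   ADR occurrence in each report has one major drug. Each iteration samples
   that drug with probability proportional to the current scores
   (normalized within the report), rebuilds the counts from the sampled
   assignments (running-mean fractional counts by default), refits the
   prior and rescores, until the marginal log-likelihood stabilizes.
   Confounders progressively lose count mass to the true cause.
3. **Signal combination** — per-pair scores from several sources (SRS,
   claims, …) on a common log₂ scale are pooled into a summary *y⁽ˡ⁾* using
   inverse-variance weighting within a source and reliability weights
   *w_k ∝ 1 / (mean variance of source k)* across sources, then shrunk
   through the normal–normal hierarchy *y⁽ˡ⁾ ~ N(φ_l, σ_l²)*,
   *φ_l ~ N(θ, τ²)* with EM-estimated hyperparameters:
   *φ̂_l = c_l y⁽ˡ⁾ + (1−c_l)θ*, *c_l = τ²/(τ²+σ_l²)*.

A synthetic report generator with planted causal pairs, cluster
co-prescription confounding, under-reporting and noisy external sources
makes the whole pipeline runnable and testable without any data download.

## Worked example

```r
library(pvmcem)

cfg <- sim_config(seed = 42)          # 20,000 reports, 200 drugs, 30 ADRs,
sim <- simulate_reports(cfg)          # 25 planted causal pairs at RR 5
sim$reports
#> case_reports: 20000 reports, 200 distinct drugs, 30 distinct ADRs, 660 suspect annotations

fit <- run_mcem(sim$reports, mcem_config(max_iter = 6, seed = 43))
fit
#> mcem_fit: 6 sampling iteration(s), converged: FALSE (tol 0.001, cumulative_mean counting)
#>   final marginal loglik: -11603.9381 over 5997 pairs

ref <- simulate_reference(sim$truth)  # planted positives + confounded negatives
evaluate_scores(fit$scores_initial, ref, "ebgm")$pooled_auc   # 0.9880
evaluate_scores(fit$scores, ref, "ebgm")$pooled_auc           # 1.0000

head(fit$scores[order(-fit$scores$ebgm), c("drug_id","adr_id","n00","E","ebgm","eb05")], 5)
#>      drug_id adr_id  n00     E  ebgm  eb05
#> 2657    D089   A018 39.0 8.306 3.657 3.631
#> 3629    D122   A001 36.2 7.982 3.657 3.631
#> ...

src  <- rbind(simulate_source_scores(sim$truth, ref),
              mgps_as_source(fit$scores, "srs"))
comb <- combine_signals(src, common_only = TRUE)  # pairs scored by every source
#> theta = -0.445, tau2 = 1.340; AUC(phi_hat) = 1.0000 over 125 common pairs

call_signals(fit$scores, reference = ref)
#> EB05 > 2 calls: 25, precision 1.000
```

The interpretation: before filtering, cluster-mates of causal drugs carry
inflated counts and the co-occurrence MGPS ranking is imperfect
(AUC 0.988); after six sampling iterations the causal drugs have absorbed
the count mass of their confounders and every planted pair outranks every
negative control. All 25 planted pairs — and nothing else — clear the
`EB05 > 2` rule.

A full run (simulate → mgps → mcem → combine → evaluate) with artifact
manifest is available as `run_pipeline(pipeline_config(out = "run1", seed = 1))`
or from the shell via the bundled script:

```sh
Rscript inst/cli/pvmcem.R pipeline --config run.yaml
```

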