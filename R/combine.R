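#' Read a per-source signal-score table
#'
#' Delimited table with columns `source_id`, `drug_id`, `adr_id`, `score`,
#' `variance`; scores are expected on a common unbounded (log) scale and
#' every variance must be positive.  A source may contribute several scores
#' for the same pair (e.g. one per reporting year).
#'
#' @param path file path.
#' @return data frame of source scores.
#' @export
read_source_scores <- function(path) {
  x <- read_tsv(path)
  need <- c("source_id", "drug_id", "adr_id", "score", "variance")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stopf("source-score file %s lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  validate_source_scores(as.data.frame(x))
}

validate_source_scores <- function(scores) {
  if (!all(is.finite(scores$score)))
    stopf("non-finite score values in source scores")
  if (any(!is.finite(scores$variance)) || any(scores$variance <= 0))
    stopf("every source-score variance must be positive and finite")
  scores
}

#' Reliability-weighted per-pair summary statistic
#'
#' Pools the scores each source holds for a drug-ADR pair into one summary
#' per pair.  Within a source the pair's scores are combined by
#' inverse-variance weighting (`u_lk`, with pooled variance
#' `v_lk = 1 / sum(1/sigma2)`); across sources the summaries are averaged
#' with weights `w_k = 1 / mean source variance` — a source whose scores
#' are noisy overall is down-weighted for every pair.  Weights are
#' normalized over the sources that actually observe the pair, so the
#' summary is a convex combination, and its variance follows by propagation:
#' `sigma_l^2 = sum w_k^2 v_lk / (sum w_k)^2`.
#'
#' With `strict_eq10 = TRUE` the raw reciprocal-mean-variance weights are
#' used without normalization (audit switch reproducing the unnormalized
#' printed form of the pooling formula).
#'
#' @param scores data frame with columns `source_id`, `drug_id`, `adr_id`,
#'   `score`, `variance` (all variances > 0).
#' @param strict_eq10 audit switch, see above.
#' @return data frame with one row per pair: `drug_id`, `adr_id`, `y`
#'   (summary score), `sigma2` (summary variance), `n_sources`.
#' @export
summarize_pair_scores <- function(scores, strict_eq10 = FALSE) {
  validate_source_scores(scores)
  dt <- as.data.table(scores)
  if (nrow(dt) == 0L) stopf("no source scores supplied")
  smv <- dt[, .(mean_var = mean(variance)), by = source_id]
  per <- dt[, .(u = sum(score / variance) / sum(1 / variance),
                v = 1 / sum(1 / variance)),
            by = .(source_id, drug_id, adr_id)]
  per <- merge(per, smv, by = "source_id")
  per[, w0 := 1 / mean_var]
  if (strict_eq10) {
    out <- per[, .(y = sum(w0 * u),
                   sigma2 = sum(w0^2 * v),
                   n_sources = .N),
               by = .(drug_id, adr_id)]
  } else {
    out <- per[, .(y = sum(w0 * u) / sum(w0),
                   sigma2 = sum(w0^2 * v) / sum(w0)^2,
                   n_sources = .N),
               by = .(drug_id, adr_id)]
  }
  setorder(out, drug_id, adr_id)
  as.data.frame(out)
}

#' Cross-source pooling weights
#'
#' The (normalized) weight each source receives in
#' [summarize_pair_scores()]: the reciprocal of the source's mean score
#' variance.  Exposed so the reliability ordering can be inspected.
#'
#' @inheritParams summarize_pair_scores
#' @return named numeric vector of weights summing to 1.
#' @export
source_weights <- function(scores) {
  validate_source_scores(scores)
  dt <- as.data.table(scores)
  smv <- dt[, .(mean_var = mean(variance)), by = source_id]
  w <- 1 / smv$mean_var
  setNames(w / sum(w), smv$source_id)
}

#' EM estimation of the normal-normal hyperparameters
#'
#' The per-pair summaries are modelled as `y_l ~ N(phi_l, sigma_l^2)` with
#' `phi_l ~ N(theta, tau^2)`.  `theta` (grand prior mean) and `tau^2`
#' (between-signal variance) are estimated by EM: the E-step computes the
#' posterior mean `m_l = c_l y_l + (1 - c_l) theta` and variance
#' `v_l = c_l sigma_l^2` with `c_l = tau^2 / (tau^2 + sigma_l^2)`; the
#' M-step sets `theta = mean(m_l)` and
#' `tau^2 = mean(v_l + (m_l - theta)^2)`.  The marginal log-likelihood
#' `sum_l log N(y_l; theta, tau^2 + sigma_l^2)` is non-decreasing across
#' iterations; `tau^2` is floored at 1e-12.
#'
#' @param y numeric vector of per-pair summary scores (length >= 2).
#' @param sigma2 matching vector of positive summary variances.
#' @param tol convergence tolerance on `max(|d theta|, |d tau2|)`.
#' @param max_iter maximum EM iterations.
#' @return list with `theta`, `tau2`, `n_iter`, `converged`, `loglik`
#'   (final) and `loglik_trace` (one value per iteration).
#' @export
fit_shrinkage_em <- function(y, sigma2, tol = 1e-8, max_iter = 1000L) {
  if (length(y) < 2L) stopf("need at least 2 summaries to estimate theta and tau2")
  if (length(sigma2) != length(y)) stopf("y and sigma2 lengths differ")
  if (any(sigma2 <= 0)) stopf("all summary variances must be > 0")
  floor2 <- 1e-12
  theta <- mean(y)
  tau2 <- max(var(y) - mean(sigma2), 0.1 * var(y), floor2)
  ll_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    cl <- tau2 / (tau2 + sigma2)
    m <- cl * y + (1 - cl) * theta
    v <- cl * sigma2
    theta_new <- mean(m)
    tau2_new <- max(mean(v + (m - theta_new)^2), floor2)
    ll_trace <- c(ll_trace,
                  sum(dnorm(y, theta_new, sqrt(tau2_new + sigma2), log = TRUE)))
    delta <- max(abs(theta_new - theta), abs(tau2_new - tau2))
    theta <- theta_new
    tau2 <- tau2_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(theta = theta, tau2 = tau2, n_iter = it, converged = converged,
       loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace)
}

#' Shrinkage estimates of the combined signal
#'
#' `phi_hat_l = c_l y_l + (1 - c_l) theta` with
#' `c_l = tau^2 / (tau^2 + sigma_l^2)`: each pair's summary is pulled
#' towards the grand mean in proportion to its own uncertainty.
#'
#' @param summaries output of [summarize_pair_scores()] (columns `y`,
#'   `sigma2`).
#' @param theta,tau2 fitted hyperparameters.
#' @return `summaries` with added columns `c_l`, `phi_hat`, `theta`,
#'   `tau2`.
#' @export
eb_combine <- function(summaries, theta, tau2) {
  assert_number(theta, "theta")
  assert_number(tau2, "tau2", lower = 0)
  out <- as.data.frame(summaries)
  out$c_l <- tau2 / (tau2 + out$sigma2)
  out$phi_hat <- out$c_l * out$y + (1 - out$c_l) * theta
  out$theta <- theta
  out$tau2 <- tau2
  class(out) <- c("combined_signals", "data.frame")
  out
}

#' Full multi-source signal combination
#'
#' Summarizes per-source scores per pair, fits the normal-normal
#' hyperparameters by EM, and returns the shrinkage estimates.
#'
#' With `common_only = TRUE` (recommended when one source scores vastly
#' more pairs than the others, e.g. a full SRS score table next to
#' reference-pair claims scores), the combination is restricted to the
#' pairs observed in every source.  A dominant single-source bulk of
#' near-identical, confidently-shrunk scores otherwise drives the
#' between-signal variance estimate towards zero and flattens the
#' combined ranking.
#'
#' @inheritParams summarize_pair_scores
#' @inheritParams fit_shrinkage_em
#' @param common_only restrict to pairs present in all sources.
#' @return A `combined_signals` data frame (see [eb_combine()]), with the
#'   EM fit in attribute `"em_fit"`.
#' @export
combine_signals <- function(scores, strict_eq10 = FALSE, tol = 1e-8,
                            max_iter = 1000L, common_only = FALSE) {
  if (common_only) {
    dt <- as.data.table(scores)
    K <- length(unique(dt$source_id))
    cov <- dt[, .(k = length(unique(source_id))), by = .(drug_id, adr_id)]
    keep <- cov[k == K, .(drug_id, adr_id)]
    if (nrow(keep) == 0L)
      stopf("no pair is observed in all %d sources", K)
    scores <- as.data.frame(merge(dt, keep, by = c("drug_id", "adr_id")))
  }
  summaries <- summarize_pair_scores(scores, strict_eq10 = strict_eq10)
  fit <- fit_shrinkage_em(summaries$y, summaries$sigma2, tol = tol,
                          max_iter = max_iter)
  out <- eb_combine(summaries, fit$theta, fit$tau2)
  attr(out, "em_fit") <- fit
  out
}

#' Convert MGPS scores to source-score rows
#'
#' Re-expresses an `mgps_scores` table as rows of a multi-source score
#' table: the score is `eblog2` (posterior mean of log2 lambda) and the
#' variance the posterior variance of log2 lambda, so spontaneous-report
#' signals enter the combination stage on the same log2 scale as
#' observational sources.
#'
#' @param scores an `mgps_scores` data frame (needs `var_eblog2`).
#' @param source_id label for the source (default `"srs"`).
#' @return data frame with columns `source_id`, `drug_id`, `adr_id`,
#'   `score`, `variance`.
#' @export
mgps_as_source <- function(scores, source_id = "srs") {
  if (!"var_eblog2" %in% names(scores))
    stopf("scores must carry the posterior log2 variance (column var_eblog2)")
  data.frame(source_id = source_id, drug_id = scores$drug_id,
             adr_id = scores$adr_id, score = scores$eblog2,
             variance = scores$var_eblog2, stringsAsFactors = FALSE)
}
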