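#' Configuration for the Monte Carlo EM confounder filter
#'
#' @param max_iter maximum number of sampling iterations.
#' @param tol stopping threshold on the absolute change of the fitted
#'   prior's marginal log-likelihood between consecutive iterations
#'   (heuristic threshold; 1e-3 by default).
#' @param burn_in iterations excluded from cumulative averaging (must be
#'   `< max_iter`).
#' @param count_mode `"cumulative_mean"` (fractional counts equal to the
#'   running mean of all post-burn-in sampled assignments; lower Monte
#'   Carlo noise) or `"last_sample"` (counts from the current iteration's
#'   single draw; textbook MCEM with Monte Carlo sample size 1).
#' @param seed integer seed for the sampling stream.
#' @param score_floor small positive floor applied to sampling scores so
#'   drugs unseen in early iterations keep nonzero selection probability.
#' @param sampling_score score field driving the assignment probabilities
#'   (`"ebgm"` by default, `"eb05"` optionally).
#' @param refit_prior refit the mixture prior at every iteration (default)
#'   or keep the iteration-0 prior fixed.
#' @return An object of class `mcem_config`.
#' @export
mcem_config <- function(max_iter = 50L, tol = 1e-3, burn_in = 1L,
                        count_mode = c("cumulative_mean", "last_sample"),
                        seed = 1L, score_floor = 1e-6,
                        sampling_score = c("ebgm", "eb05"),
                        refit_prior = TRUE) {
  count_mode <- match.arg(count_mode)
  sampling_score <- match.arg(sampling_score)
  if (!is.numeric(tol) || tol <= 0) stopf("tol must be > 0")
  max_iter <- as.integer(max_iter)
  burn_in <- as.integer(burn_in)
  if (max_iter < 1L) stopf("max_iter must be >= 1")
  if (burn_in < 0L || burn_in >= max_iter)
    stopf("burn_in must satisfy 0 <= burn_in < max_iter")
  structure(list(max_iter = max_iter, tol = tol, burn_in = burn_in,
                 count_mode = count_mode, seed = as.integer(seed),
                 score_floor = score_floor, sampling_score = sampling_score,
                 refit_prior = isTRUE(refit_prior)),
            class = "mcem_config")
}

#' Per-report drug sampling probabilities for one ADR
#'
#' Normalizes the signal scores of the drugs mentioned in a report to a
#' selection probability for the given ADR:
#' `p(d) = max(score(d, adr), floor) / sum_d' max(score(d', adr), floor)`.
#' Drugs absent from the score table receive the floor.
#'
#' @param drug_ids drugs mentioned in the report (non-empty).
#' @param scores named numeric vector of scores indexed by drug id (the
#'   slice of the score table for the target ADR), or `NULL`.
#' @param floor small positive score floor.
#' @return named numeric probability vector summing to 1.
#' @examples
#' sampling_probabilities(c("A", "B"), c(A = 3, B = 1))  # 0.75, 0.25
#' @export
sampling_probabilities <- function(drug_ids, scores = NULL, floor = 1e-6) {
  if (length(drug_ids) == 0L) stopf("empty drug set")
  if (floor <= 0) stopf("floor must be > 0")
  s <- rep(floor, length(drug_ids))
  names(s) <- drug_ids
  if (!is.null(scores)) {
    hit <- intersect(drug_ids, names(scores))
    s[hit] <- pmax(scores[hit], floor)
  }
  s / sum(s)
}

# attach the sampling score to candidate triples; unscored pairs get floor
triple_scores <- function(triples, scores, field, floor) {
  sc <- as.data.table(as.data.frame(scores))[, c("drug_id", "adr_id", field),
                                             with = FALSE]
  setnames(sc, field, "score")
  tr <- merge(triples, sc, by = c("drug_id", "adr_id"), all.x = TRUE,
              sort = FALSE)
  setkey(tr, report_id, adr_id, drug_id)
  tr[is.na(score) | score < floor, score := floor]
  tr
}

#' Sample one major drug per ADR occurrence
#'
#' For each (report, ADR) occurrence, draws one drug from the report's drug
#' set with probability proportional to `max(score, floor)` of the
#' (drug, ADR) pair — one categorical draw per occurrence.  Draws are
#' vectorized via the Gumbel-max trick and are reproducible for a fixed
#' seed.
#'
#' @param reports a `case_reports` object.
#' @param scores an `mgps_scores` data frame (or any frame with `drug_id`,
#'   `adr_id` and the score field).
#' @param floor score floor, see [sampling_probabilities()].
#' @param field score column to use (default `"ebgm"`).
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return A data frame with columns `report_id`, `adr_id`, `drug_id`
#'   (class `mcem_assignment`): exactly one row per (report, ADR)
#'   occurrence, the drug always a member of that report's drug set.
#' @export
sample_assignment <- function(reports, scores, floor = 1e-6, field = "ebgm",
                              seed = NULL) {
  stopifnot(inherits(reports, "case_reports"))
  tr <- triple_scores(candidate_triples(reports), scores, field, floor)
  draw <- function() {
    tr[, key_ := log(score) - log(-log(runif(.N)))]
    sel <- tr[tr[, .I[which.max(key_)], by = .(report_id, adr_id)]$V1]
    out <- as.data.frame(sel[, .(report_id, adr_id, drug_id)])
    class(out) <- c("mcem_assignment", "data.frame")
    out
  }
  if (is.null(seed)) draw() else local_seed(seed, draw())
}

# contingency table from fractional assignment weights on the fixed
# co-occurrence pair universe
contingency_from_weights <- function(triples, w, margins, strict_margins = FALSE) {
  tmp <- triples[, .(drug_id, adr_id)][, weight := w]
  n00_dt <- tmp[, .(n00 = sum(weight)), by = .(drug_id, adr_id)]
  finish_contingency(n00_dt, margins, include_zero = FALSE,
                     strict_margins = strict_margins)
}

#' Run the Monte Carlo EM confounder-filtering loop
#'
#' Iteration 0 scores all co-occurring pairs with plain co-occurrence MGPS.
#' Each subsequent iteration (the Monte Carlo E-step) samples one major
#' drug per ADR per report with probability proportional to the current
#' scores, rebuilds the drug-ADR counts under the configured counting mode,
#' refits the mixture prior (the M-step) and rescores.  The loop stops when
#' the change in the fitted prior's marginal log-likelihood drops below
#' `config$tol`, or at `max_iter`.  The scored pair universe is held fixed
#' at the iteration-0 co-occurrence pairs so the objective is comparable
#' across iterations.
#'
#' Runs are bit-reproducible: identical `(reports, config)` give identical
#' traces, and the caller's RNG state is left untouched.
#'
#' @param reports a `case_reports` object.
#' @param config an [mcem_config()].
#' @return An object of class `mcem_fit`: list with `trace` (one row per
#'   iteration: `iter`, `loglik`, prior parameters), `scores` (final
#'   `mgps_scores` including EB05/EB95), `scores_initial` (iteration-0
#'   co-occurrence scores), `assignment` (last sampled draw), `weights`
#'   (terminal per-triple fractional counts), `prior`, `converged`,
#'   `n_iter`, `config`.
#' @export
run_mcem <- function(reports, config = mcem_config()) {
  stopifnot(inherits(reports, "case_reports"), inherits(config, "mcem_config"))
  if (nrow(reports$reports) == 0L) stopf("empty report collection")

  margins <- report_margins(reports)
  triples <- candidate_triples(reports)

  ct <- build_contingency(reports, "cooccurrence")
  prior <- fit_mgps_prior(ct)
  scores <- mgps_score(ct, prior, quantiles = NULL)
  scores_initial <- scores

  trace <- data.frame(iter = 0L, loglik = prior$loglik, w = prior$w,
                      alpha1 = prior$alpha1, beta1 = prior$beta1,
                      alpha2 = prior$alpha2, beta2 = prior$beta2,
                      prior_converged = prior$converged)
  prev_ll <- prior$loglik
  prev_n00 <- ct$n00
  converged <- FALSE
  n_done <- 0L
  cum <- NULL
  n_acc <- 0L
  last_assignment <- NULL
  w_vec <- NULL

  local_seed(config$seed, {
    for (it in seq_len(config$max_iter)) {
      tr <- triple_scores(triples, scores, config$sampling_score,
                          config$score_floor)
      tr[, key_ := log(score) - log(-log(runif(.N)))]
      sel_idx <- tr[, .I[which.max(key_)], by = .(report_id, adr_id)]$V1
      ind <- numeric(nrow(tr))
      ind[sel_idx] <- 1
      last_assignment <- as.data.frame(
        tr[sel_idx, .(report_id, adr_id, drug_id)])

      if (config$count_mode == "cumulative_mean" && it > config$burn_in) {
        n_acc <- n_acc + 1L
        if (is.null(cum)) cum <- numeric(nrow(tr))
        cum <- cum + (ind - cum) / n_acc
        w_vec <- cum
      } else {
        w_vec <- ind
      }

      ct <- contingency_from_weights(triples, w_vec, margins)
      if (isTRUE(all(ct$n00 == prev_n00))) {
        # counts unchanged (e.g. forced assignments): reuse the previous
        # fit so degenerate data reproduce plain MGPS exactly
        ll <- prev_ll
      } else if (config$refit_prior) {
        prior <- fit_mgps_prior(ct, init = prior)
        scores <- mgps_score(ct, prior, quantiles = NULL)
        ll <- prior$loglik
      } else {
        scores <- mgps_score(ct, prior, quantiles = NULL)
        ll <- mixture_loglik(ct$n00, ct$E, prior$w, prior$alpha1,
                             prior$beta1, prior$alpha2, prior$beta2)
      }
      trace <- rbind(trace, data.frame(
        iter = it, loglik = ll, w = prior$w, alpha1 = prior$alpha1,
        beta1 = prior$beta1, alpha2 = prior$alpha2, beta2 = prior$beta2,
        prior_converged = prior$converged))
      rownames(trace) <- NULL
      n_done <- it
      prev_n00 <- ct$n00
      delta <- abs(ll - prev_ll)
      prev_ll <- ll
      if (delta < config$tol) { converged <- TRUE; break }
    }
  })

  final_scores <- mgps_score(ct, prior, quantiles = c(0.05, 0.95))
  weights <- as.data.frame(triples[, .(report_id, adr_id, drug_id)])
  weights$weight <- w_vec

  structure(list(
    trace = trace, scores = final_scores, scores_initial = scores_initial,
    assignment = last_assignment, weights = weights, prior = prior,
    converged = converged, n_iter = n_done, config = config
  ), class = "mcem_fit")
}

#' @export
print.mcem_fit <- function(x, ...) {
  cat(sprintf(
    "mcem_fit: %d sampling iteration(s), converged: %s (tol %.3g, %s counting)\n",
    x$n_iter, x$converged, x$config$tol, x$config$count_mode))
  cat(sprintf("  final marginal loglik: %.4f over %d pairs\n",
              x$trace$loglik[nrow(x$trace)], nrow(x$scores)))
  invisible(x)
}
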