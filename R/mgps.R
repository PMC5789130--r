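#' Two-component gamma mixture prior for the relative reporting ratio
#'
#' The relative reporting ratio lambda of a drug-ADR pair is modelled a
#' priori as a mixture of two gamma distributions,
#' `w Ga(alpha1, beta1) + (1 - w) Ga(alpha2, beta2)` (shape/rate
#' parameterization).  One component typically captures the null bulk of
#' pairs near lambda = 1, the other the long tail of true signals.
#'
#' @param w mixture weight of the first component, in `[0, 1]`.
#' @param alpha1,beta1 shape and rate of the first gamma component (> 0).
#' @param alpha2,beta2 shape and rate of the second gamma component (> 0).
#' @param loglik attained marginal log-likelihood (set by [fit_mgps_prior()]).
#' @param converged optimizer convergence flag.
#' @param n_iter optimizer iteration count.
#' @return An object of class `mgps_prior`.
#' @export
mgps_prior <- function(w, alpha1, beta1, alpha2, beta2,
                       loglik = NA_real_, converged = NA, n_iter = NA_integer_) {
  assert_number(w, "w", 0, 1)
  for (nm in c("alpha1", "beta1", "alpha2", "beta2")) {
    v <- get(nm)
    assert_number(v, nm, lower = 0, strict = TRUE)
  }
  structure(list(w = w, alpha1 = alpha1, beta1 = beta1,
                 alpha2 = alpha2, beta2 = beta2,
                 loglik = loglik, converged = converged,
                 n_iter = as.integer(n_iter)),
            class = "mgps_prior")
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat(sprintf(
    "mgps_prior: w = %.4f | Ga(%.4g, %.4g) + Ga(%.4g, %.4g)\n",
    x$w, x$alpha1, x$beta1, x$alpha2, x$beta2))
  if (is.finite(x$loglik))
    cat(sprintf("  marginal loglik = %.4f (converged: %s, %d fn evals)\n",
                x$loglik, x$converged, x$n_iter))
  invisible(x)
}

#' Negative-binomial marginal density of an observed count
#'
#' Marginal probability of observing `n00` reports for a pair with expected
#' count `E` when the count is `Poisson(lambda * E)` and
#' `lambda ~ Ga(alpha, beta)`:
#' `(1 + beta/E)^(-n00) (1 + E/beta)^(-alpha) Gamma(alpha + n00) /
#' (Gamma(alpha) Gamma(n00 + 1))`.
#' Computed in log space; `n00!` is generalized to `Gamma(n00 + 1)` so
#' fractional counts (cumulative Monte Carlo averages) are scoreable.
#' For integer counts the density sums to 1 over `n00 = 0, 1, 2, ...`.
#'
#' @param n00 observed count(s), >= 0 (may be fractional).
#' @param E expected count(s) under independence, > 0.
#' @param alpha,beta gamma shape and rate, > 0.
#' @param log if `TRUE`, return log density.
#' @return numeric vector of (log) densities.
#' @examples
#' mgps_marginal_density(0, E = 1, alpha = 1, beta = 1)  # 0.5
#' @export
mgps_marginal_density <- function(n00, E, alpha, beta, log = FALSE) {
  if (any(!is.finite(n00)) || any(!is.finite(E)) ||
      any(!is.finite(alpha)) || any(!is.finite(beta)))
    stopf("non-finite inputs to mgps_marginal_density")
  if (any(n00 < 0)) stopf("n00 must be >= 0")
  if (any(E <= 0) || any(alpha <= 0) || any(beta <= 0))
    stopf("E, alpha and beta must be > 0")
  lf <- -n00 * log1p(beta / E) - alpha * log1p(E / beta) +
    lgamma(alpha + n00) - lgamma(alpha) - lgamma(n00 + 1)
  if (log) lf else exp(lf)
}

# component log marginal densities under a prior, as a 2-column matrix
component_logdens <- function(n00, E, prior) {
  cbind(mgps_marginal_density(n00, E, prior$alpha1, prior$beta1, log = TRUE),
        mgps_marginal_density(n00, E, prior$alpha2, prior$beta2, log = TRUE))
}

mixture_loglik <- function(n00, E, w, alpha1, beta1, alpha2, beta2) {
  l1 <- mgps_marginal_density(n00, E, alpha1, beta1, log = TRUE)
  l2 <- mgps_marginal_density(n00, E, alpha2, beta2, log = TRUE)
  if (w >= 1) return(sum(l1))
  if (w <= 0) return(sum(l2))
  sum(logaddexp(log(w) + l1, log1p(-w) + l2))
}

# deterministic starting points: DuMouchel's canonical start plus two fixed
# perturbations, so multistart needs no random number stream
prior_starts <- function() {
  list(
    c(w = 1 / 3, alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4),
    c(w = 0.5, alpha1 = 0.1, beta1 = 0.05, alpha2 = 4, beta2 = 8),
    c(w = 0.2, alpha1 = 0.5, beta1 = 0.25, alpha2 = 1, beta2 = 2)
  )
}

#' Fit the mixture prior by maximum marginal likelihood
#'
#' Maximizes the marginal log-likelihood
#' `sum_pairs log[w f(n00; alpha1, beta1, E) + (1 - w) f(n00; alpha2, beta2, E)]`
#' over the five prior parameters by quasi-Newton (BFGS) optimization on a
#' logit-transformed weight and log-transformed gamma parameters.  Without
#' a user-supplied `init` the optimizer is run from three fixed starting
#' points and the best optimum kept, which makes the fit fully
#' deterministic.
#'
#' @param stats a `contingency` data frame (or any data frame with numeric
#'   columns `n00` and `E > 0`); at least 2 pairs.
#' @param init optional `mgps_prior` (or named numeric vector) used as the
#'   single starting point.
#' @param maxit maximum BFGS iterations per start.
#' @param reltol relative convergence tolerance on the log-likelihood.
#' @return An `mgps_prior` with `loglik`, `converged` and `n_iter` filled
#'   in.  Non-convergence is reported through `converged = FALSE`, never
#'   silently.  Degenerate data (all counts identical) triggers a warning.
#' @export
fit_mgps_prior <- function(stats, init = NULL, maxit = 500L, reltol = 1e-10) {
  n00 <- as.numeric(stats$n00)
  E <- as.numeric(stats$E)
  if (length(n00) < 2L) stopf("need at least 2 pairs to fit the prior")
  if (any(E <= 0)) stopf("all expected counts must be > 0")
  if (length(unique(n00)) == 1L)
    warning("degenerate data: all n00 identical; the mixture prior is not identifiable",
            call. = FALSE)

  to_par <- function(p) c(stats::qlogis(min(max(p[1L], 1e-12), 1 - 1e-12)),
                          log(p[2L]), log(p[3L]), log(p[4L]), log(p[5L]))
  from_par <- function(par) c(stats::plogis(par[1L]), exp(par[2L]),
                              exp(par[3L]), exp(par[4L]), exp(par[5L]))
  # gamma parameters are boxed to [1e-8, 1e8]: beyond ~2^53 the difference
  # lgamma(alpha + n) - lgamma(alpha) degenerates in double precision and
  # the likelihood of a runaway point-mass component is spuriously inflated
  box <- log(1e8)
  nll <- function(par) {
    p <- from_par(par)
    if (any(!is.finite(p)) || any(p[2:5] <= 0)) return(1e300)
    pen <- sum(pmax(0, abs(log(p[2:5])) - box)^2) * 1e6
    v <- -mixture_loglik(n00, E, p[1L], pmin(pmax(p[2L], 1e-8), 1e8),
                         pmin(pmax(p[3L], 1e-8), 1e8),
                         pmin(pmax(p[4L], 1e-8), 1e8),
                         pmin(pmax(p[5L], 1e-8), 1e8)) + pen
    if (!is.finite(v)) 1e300 else v
  }

  starts <- if (!is.null(init)) {
    p0 <- if (inherits(init, "mgps_prior"))
      c(init$w, init$alpha1, init$beta1, init$alpha2, init$beta2)
    else as.numeric(init[c("w", "alpha1", "beta1", "alpha2", "beta2")])
    list(p0)
  } else {
    prior_starts()
  }

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(to_par(s), nll, method = "BFGS",
            control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stopf("prior fit failed from every starting point")
  p <- from_par(best$par)
  p[2:5] <- pmin(pmax(p[2:5], 1e-8), 1e8)
  mgps_prior(p[1L], p[2L], p[3L], p[4L], p[5L],
             loglik = -best$value,
             converged = best$convergence == 0L,
             n_iter = best$counts[["function"]])
}

#' Posterior mixture weight Qn
#'
#' Posterior probability that a pair's relative reporting ratio came from
#' the first prior component given its observed count:
#' `Qn = w f1 / (w f1 + (1 - w) f2)`, evaluated from log densities with a
#' log-sum-exp guard so it never degenerates to 0/0.
#'
#' @param n00 observed count(s).
#' @param E expected count(s).
#' @param prior an `mgps_prior`.
#' @return numeric vector in `[0, 1]`.
#' @export
posterior_qn <- function(n00, E, prior) {
  stopifnot(inherits(prior, "mgps_prior"))
  if (prior$w >= 1) return(rep(1, length(n00)))
  if (prior$w <= 0) return(rep(0, length(n00)))
  ld <- component_logdens(n00, E, prior)
  lq1 <- log(prior$w) + ld[, 1L]
  lq2 <- log1p(-prior$w) + ld[, 2L]
  1 / (1 + exp(lq2 - lq1))
}

#' Posterior expectation of log2(lambda)
#'
#' Under the posterior mixture
#' `Qn Ga(alpha1 + n00, beta1 + E) + (1 - Qn) Ga(alpha2 + n00, beta2 + E)`,
#' the expectation of `log2(lambda)` is
#' `{Qn [psi(alpha1 + n00) - ln(beta1 + E)] +
#'   (1 - Qn) [psi(alpha2 + n00) - ln(beta2 + E)]} / ln 2`,
#' with `psi` the digamma function.  `EBGM = 2^eblog2` is the empirical
#' Bayes geometric mean of the posterior.
#'
#' @inheritParams posterior_qn
#' @return numeric vector.
#' @export
posterior_eblog2 <- function(n00, E, prior) {
  stopifnot(inherits(prior, "mgps_prior"))
  qn <- posterior_qn(n00, E, prior)
  m1 <- digamma(prior$alpha1 + n00) - log(prior$beta1 + E)
  m2 <- digamma(prior$alpha2 + n00) - log(prior$beta2 + E)
  (qn * m1 + (1 - qn) * m2) / log(2)
}

#' Posterior variance of log2(lambda)
#'
#' Mixture variance of `log2 lambda` under the posterior: the Qn-weighted
#' within-component trigamma variances plus the between-component spread of
#' the component means.  Used as the sampling variance when MGPS signals
#' enter the multi-source combination stage on the log2 scale.
#'
#' @inheritParams posterior_qn
#' @return numeric vector of variances.
#' @export
posterior_log2_var <- function(n00, E, prior) {
  stopifnot(inherits(prior, "mgps_prior"))
  qn <- posterior_qn(n00, E, prior)
  l2 <- log(2)
  m1 <- (digamma(prior$alpha1 + n00) - log(prior$beta1 + E)) / l2
  m2 <- (digamma(prior$alpha2 + n00) - log(prior$beta2 + E)) / l2
  v1 <- trigamma(prior$alpha1 + n00) / l2^2
  v2 <- trigamma(prior$alpha2 + n00) / l2^2
  m <- qn * m1 + (1 - qn) * m2
  qn * (v1 + (m1 - m)^2) + (1 - qn) * (v2 + (m2 - m)^2)
}

#' Posterior quantile of lambda
#'
#' Inverts the posterior mixture CDF
#' `Qn P(Ga(alpha1 + n00, beta1 + E) <= x) + (1 - Qn) P(Ga(alpha2 + n00, beta2 + E) <= x)`
#' by bracketed root finding between the two component quantiles (which
#' bound the mixture quantile), to 1e-9 relative tolerance.  `q = 0.05`
#' yields EB05, `q = 0.95` EB95.
#'
#' @inheritParams posterior_qn
#' @param q probability level(s) in (0, 1).
#' @return numeric vector of quantiles.
#' @export
posterior_quantile <- function(n00, E, prior, q = 0.05) {
  stopifnot(inherits(prior, "mgps_prior"))
  if (any(q <= 0) || any(q >= 1)) stopf("q must lie strictly in (0, 1)")
  k <- max(length(n00), length(E), length(q))
  n00 <- rep_len(n00, k); E <- rep_len(E, k); q <- rep_len(q, k)
  qn <- posterior_qn(n00, E, prior)
  a1 <- prior$alpha1 + n00; b1 <- prior$beta1 + E
  a2 <- prior$alpha2 + n00; b2 <- prior$beta2 + E
  out <- numeric(k)
  for (i in seq_len(k)) {
    q1 <- qgamma(q[i], shape = a1[i], rate = b1[i])
    q2 <- qgamma(q[i], shape = a2[i], rate = b2[i])
    if (qn[i] >= 1 - 1e-14) { out[i] <- q1; next }
    if (qn[i] <= 1e-14) { out[i] <- q2; next }
    lo <- min(q1, q2); hi <- max(q1, q2)
    if (hi - lo < .Machine$double.eps * max(1, hi)) { out[i] <- lo; next }
    f <- function(x)
      qn[i] * pgamma(x, a1[i], rate = b1[i]) +
      (1 - qn[i]) * pgamma(x, a2[i], rate = b2[i]) - q[i]
    # the mixture quantile lies between the component quantiles; rounding
    # can leave f with the same sign at both ends of the bracket
    flo <- f(lo); fhi <- f(hi)
    if (flo >= 0) { out[i] <- lo; next }
    if (fhi <= 0) { out[i] <- hi; next }
    r <- tryCatch(
      uniroot(f, lower = lo, upper = hi, extendInt = "no",
              tol = 1e-9 * max(1, hi)),
      error = function(e)
        stopf("posterior quantile bracket failure (pathological parameters): %s",
              conditionMessage(e)))
    out[i] <- r$root
  }
  out
}

#' Score all drug-ADR pairs with MGPS posterior summaries
#'
#' Computes, for every pair in a contingency table, the posterior mixture
#' weight `qn`, posterior expectation of log2 lambda (`eblog2`), its
#' geometric-mean scale `ebgm = 2^eblog2`, posterior quantiles (`eb05`,
#' `eb95` by default), and the posterior variance of log2 lambda
#' (`var_eblog2`).  If no prior is supplied one is fitted to `stats` by
#' [fit_mgps_prior()] first.
#'
#' @param stats a `contingency` data frame.
#' @param prior an `mgps_prior`, or `NULL` to fit one from `stats`.
#' @param quantiles posterior quantile levels to compute (set `NULL` to
#'   skip the relatively expensive quantile inversion).
#' @return A data frame of class `mgps_scores` with one row per pair and
#'   the fitted/supplied prior in attribute `"prior"`.  Scoring is a pure
#'   function of `(n00, E)` given the prior.
#' @export
mgps_score <- function(stats, prior = NULL, quantiles = c(0.05, 0.95)) {
  if (any(stats$E <= 0))
    stopf("all pairs must have E > 0; use include_zero = FALSE or drop empty margins")
  if (is.null(prior)) prior <- fit_mgps_prior(stats)
  stopifnot(inherits(prior, "mgps_prior"))
  n00 <- as.numeric(stats$n00)
  E <- as.numeric(stats$E)
  out <- data.frame(
    drug_id = stats$drug_id, adr_id = stats$adr_id,
    n00 = n00, E = E,
    qn = posterior_qn(n00, E, prior),
    eblog2 = posterior_eblog2(n00, E, prior),
    stringsAsFactors = FALSE
  )
  out$ebgm <- 2^out$eblog2
  out$var_eblog2 <- posterior_log2_var(n00, E, prior)
  if (!is.null(quantiles)) {
    for (q in quantiles) {
      col <- sprintf("eb%02.0f", 100 * q)
      out[[col]] <- posterior_quantile(n00, E, prior, q)
    }
  }
  attr(out, "prior") <- prior
  class(out) <- c("mgps_scores", "data.frame")
  out
}

#' Write or read MGPS scores / prior parameters
#'
#' Scores go to a delimited table; the prior is serialized to a small YAML
#' sidecar carrying the attained log-likelihood and convergence metadata.
#'
#' @param x an `mgps_scores` data frame or `mgps_prior`.
#' @param path output path.
#' @return `path` (writers, invisibly) or the read object.
#' @export
write_scores <- function(x, path) {
  write_tsv(as.data.table(as.data.frame(x)), path)
}

#' @rdname write_scores
#' @export
write_mgps_prior <- function(x, path) {
  stopifnot(inherits(x, "mgps_prior"))
  yaml::write_yaml(list(
    w = x$w, alpha1 = x$alpha1, beta1 = x$beta1,
    alpha2 = x$alpha2, beta2 = x$beta2,
    loglik = x$loglik, converged = x$converged, n_iter = x$n_iter
  ), path)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_mgps_prior <- function(path) {
  p <- yaml::read_yaml(path)
  mgps_prior(p$w, p$alpha1, p$beta1, p$alpha2, p$beta2,
             loglik = p$loglik %||% NA_real_,
             converged = p$converged %||% NA,
             n_iter = p$n_iter %||% NA_integer_)
}
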