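# Shared fixtures and independent oracles, built in code at test time.

# small hand-rolled report collection used across modules
tiny_reports <- function() {
  case_reports(
    report_id = c("r1", "r2", "r3", "r4"),
    year = c(2008L, 2008L, 2009L, 2010L),
    drugs = list(c("A", "B"), c("A", "C"), "B", c("B", "C")),
    adrs = list("X", c("X", "Y"), "Y", "X"),
    primary_suspect = list(c(X = "A"), NULL, c(Y = "B"), NULL)
  )
}

# grid priors exercised by the posterior-oracle checks
oracle_priors <- function() {
  list(
    mgps_prior(w = 1 / 3, alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4),
    mgps_prior(w = 0.7, alpha1 = 1, beta1 = 1, alpha2 = 5, beta2 = 1),
    mgps_prior(w = 0.1, alpha1 = 0.05, beta1 = 0.05, alpha2 = 10, beta2 = 5)
  )
}

# Independent quadrature oracle for the Poisson-gamma-mixture posterior:
# works directly from Bayes' rule on the unnormalized product
# Poisson(n00; lambda E) x prior mixture density, with no use of the
# conjugate closed form the package implements.  All integrals run in
# t = log(lambda) space so that small-shape priors (posterior mass at
# extremely small lambda) stay resolvable.
oracle_posterior <- function(n00, E, prior) {
  w <- prior$w; a1 <- prior$alpha1; b1 <- prior$beta1
  a2 <- prior$alpha2; b2 <- prior$beta2
  lp_t <- function(t) {
    l <- exp(t)
    c1 <- a1 * log(b1) - lgamma(a1) + (a1 - 1) * t - b1 * l
    c2 <- a2 * log(b2) - lgamma(a2) + (a2 - 1) * t - b2 * l
    mix <- if (w >= 1) c1
           else if (w <= 0) c2
           else {
             m <- pmax(log(w) + c1, log(1 - w) + c2)
             m + log1p(exp(pmin(log(w) + c1, log(1 - w) + c2) - m))
           }
    mix + n00 * (t + log(E)) - l * E - lgamma(n00 + 1) + t  # + t: Jacobian
  }
  tgrid <- seq(-900, 60, length.out = 12000)
  lv <- lp_t(tgrid)
  C <- max(lv[is.finite(lv)])
  t_mode <- tgrid[which.max(lv)]
  f0 <- function(t) {
    v <- exp(lp_t(t) - C)
    v[!is.finite(v)] <- 0
    v
  }
  int <- function(g, lower, upper) {
    if (upper <= lower) return(0)
    tryCatch(
      stats::integrate(g, lower, upper, rel.tol = 1e-11, abs.tol = 0,
                       subdivisions = 4000L)$value,
      error = function(e)
        stats::integrate(g, lower, upper, rel.tol = 1e-9,
                         abs.tol = 1e-290, subdivisions = 4000L)$value)
  }
  breaks <- sort(unique(pmin(pmax(
    c(-900, t_mode - 30, t_mode - 3, t_mode, t_mode + 3, t_mode + 30, 60),
    -900), 60)))
  seg <- function(g) vapply(seq_len(length(breaks) - 1L), function(j)
    int(g, breaks[j], breaks[j + 1L]), numeric(1))
  Z_seg <- seg(f0)
  Z <- sum(Z_seg)
  mean_log2 <- sum(seg(function(t) t * f0(t))) / (Z * log(2))
  cdf_t <- function(t0) {
    if (t0 <= breaks[1L]) return(0)
    full <- which(breaks[-1L] <= t0)
    lo <- if (length(full)) breaks[max(full) + 1L] else breaks[1L]
    (sum(Z_seg[full]) + int(f0, lo, min(t0, breaks[length(breaks)]))) / Z
  }
  quantile <- function(q) {
    r <- stats::uniroot(function(t) cdf_t(t) - q, lower = -900, upper = 60,
                        tol = 1e-11)
    exp(r$root)
  }
  list(mean_log2 = mean_log2, cdf = function(x) cdf_t(log(x)),
       quantile = quantile)
}

# exhaustive concordant-pair AUC (ties count 1/2)
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# brute-force 2x2 recount by a double loop over reports
oracle_contingency <- function(reports, drug, adr) {
  ids <- reports$reports$report_id
  has_d <- vapply(ids, function(r)
    drug %in% reports$drugs$drug_id[reports$drugs$report_id == r], logical(1))
  has_a <- vapply(ids, function(r)
    adr %in% reports$adrs$adr_id[reports$adrs$report_id == r], logical(1))
  c(n00 = sum(has_d & has_a), n01 = sum(has_d & !has_a),
    n10 = sum(!has_d & has_a), n11 = sum(!has_d & !has_a))
}
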