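mk_scores <- function(source_id, drug_id, adr_id, score, variance) {
  data.frame(source_id = source_id, drug_id = drug_id, adr_id = adr_id,
             score = score, variance = variance, stringsAsFactors = FALSE)
}

test_that("summary statistic reduces to identity for a single source", {
  s <- mk_scores("A", "d1", "x", 1.2, 0.5)
  out <- summarize_pair_scores(s)
  expect_equal(out$y, 1.2)
  expect_equal(out$sigma2, 0.5)
  expect_equal(out$n_sources, 1L)
})

test_that("symmetric sources average to the midpoint", {
  s <- rbind(mk_scores("A", "d1", "x", 1.0, 0.5),
             mk_scores("B", "d1", "x", 3.0, 0.5))
  out <- summarize_pair_scores(s)
  expect_equal(out$y, 2.0)
})

test_that("reliability weighting matches the hand-evaluated pooling formula", {
  # source mean variances {A: 1, B: 4} -> normalized weights {0.8, 0.2}
  s <- rbind(mk_scores("A", "d1", "x", 2, 1),
             mk_scores("B", "d1", "x", 6, 4))
  out <- summarize_pair_scores(s)
  expect_equal(out$y, 0.8 * 2 + 0.2 * 6)
  expect_equal(out$sigma2, 0.8^2 * 1 + 0.2^2 * 4)
  # the strict (unnormalized) printed form, behind the audit flag
  strict <- summarize_pair_scores(s, strict_eq10 = TRUE)
  expect_equal(strict$y, 1 * 2 + 0.25 * 6)
})

test_that("within-source replicates pool by inverse variance", {
  s <- rbind(mk_scores("A", "d1", "x", 1, 1),
             mk_scores("A", "d1", "x", 3, 0.25))
  out <- summarize_pair_scores(s)
  u <- (1 / 1 * 1 + 1 / 0.25 * 3) / (1 / 1 + 1 / 0.25)
  expect_equal(out$y, u)
  expect_equal(out$sigma2, 1 / (1 / 1 + 1 / 0.25))
})

test_that("pairs missing from a source renormalize over observed sources", {
  s <- rbind(mk_scores("A", c("d1", "d2"), "x", c(2, 5), 1),
             mk_scores("B", "d1", "x", 4, 2))
  out <- summarize_pair_scores(s)
  d2 <- out[out$drug_id == "d2", ]
  expect_equal(d2$y, 5)          # only source A observes d2
  expect_equal(d2$n_sources, 1L)
})

test_that("raising a source's mean variance strictly lowers its weight", {
  s <- rbind(mk_scores("A", c("d1", "d2"), "x", c(1, 2), 1),
             mk_scores("B", c("d1", "d2"), "x", c(1, 2), 1))
  w1 <- source_weights(s)
  s2 <- s
  s2$variance[s2$source_id == "B"] <- 2
  w2 <- source_weights(s2)
  expect_lt(w2[["B"]], w1[["B"]])
  expect_gt(w2[["A"]], w1[["A"]])
  expect_equal(sum(w2), 1)
})

test_that("input validation rejects bad variances", {
  expect_error(summarize_pair_scores(mk_scores("A", "d", "x", 1, 0)),
               "positive")
  expect_error(summarize_pair_scores(mk_scores("A", "d", "x", 1, -2)),
               "positive")
  expect_error(summarize_pair_scores(mk_scores("A", "d", "x", NaN, 1)),
               "non-finite")
})

test_that("EM converges to a fixed point with no between-signal spread", {
  out <- fit_shrinkage_em(rep(1.7, 50), runif(50, 0.1, 2))
  expect_equal(out$theta, 1.7, tolerance = 1e-6)
  expect_lt(out$tau2, 1e-6)
  expect_true(out$converged)
})

test_that("EM marginal likelihood is non-decreasing and recovers hyperparameters", {
  set.seed(303)
  L <- 2000
  sigma2 <- runif(L, 0.05, 0.5)
  phi <- rnorm(L, 1.5, sqrt(0.6))
  y <- rnorm(L, phi, sqrt(sigma2))
  fit <- fit_shrinkage_em(y, sigma2)
  expect_true(all(diff(fit$loglik_trace) >= -1e-9))
  expect_equal(fit$theta, 1.5, tolerance = 0.05)
  expect_equal(fit$tau2, 0.6, tolerance = 0.1)
})

test_that("shrinkage estimates obey the limits and the ordering", {
  summ <- data.frame(drug_id = "d", adr_id = "x", y = 3, sigma2 = 1e-300)
  expect_equal(eb_combine(summ, theta = 0, tau2 = 1)$phi_hat, 3)
  summ$sigma2 <- 0.7
  expect_equal(eb_combine(summ, theta = -1, tau2 = 0)$phi_hat, -1)
  expect_equal(eb_combine(summ, theta = 0, tau2 = 0.7)$phi_hat, 1.5)

  set.seed(5)
  summ <- data.frame(drug_id = sprintf("d%d", 1:40), adr_id = "x",
                     y = rnorm(40), sigma2 = runif(40, 0.1, 2))
  fit <- fit_shrinkage_em(summ$y, summ$sigma2)
  comb <- eb_combine(summ, fit$theta, fit$tau2)
  expect_true(all(abs(comb$phi_hat - fit$theta) <= abs(comb$y - fit$theta) + 1e-12))
  expect_true(all(comb$c_l > 0 & comb$c_l < 1))
})

test_that("a single source reduces to plain normal-normal shrinkage", {
  set.seed(6)
  s <- mk_scores("A", sprintf("d%d", 1:60), "x", rnorm(60, 1, 1),
                 runif(60, 0.2, 0.8))
  comb <- combine_signals(s)
  fit <- fit_shrinkage_em(s$score, s$variance)
  direct <- eb_combine(data.frame(drug_id = s$drug_id, adr_id = s$adr_id,
                                  y = s$score, sigma2 = s$variance),
                       fit$theta, fit$tau2)
  m <- merge(as.data.frame(comb), direct, by = "drug_id")
  expect_equal(m$phi_hat.x, m$phi_hat.y, tolerance = 1e-10)
})

test_that("noising one source hurts the combination less than that source alone", {
  n_seeds <- 20L
  d_comb <- d_single <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    set.seed(400 + s)
    L <- 200
    label <- rep(c(1, 0), c(40, 160))
    truth <- ifelse(label == 1, log2(4), 0)
    pairs <- sprintf("d%03d", 1:L)
    clean <- rbind(
      mk_scores("A", pairs, "x", truth + rnorm(L, 0, 0.4), 0.16),
      mk_scores("B", pairs, "x", truth + rnorm(L, 0, 0.4), 0.16))
    noisy <- clean
    corrupt <- noisy$source_id == "B"
    noisy$score[corrupt] <- noisy$score[corrupt] + rnorm(L, 0, 3)
    noisy$variance[corrupt] <- 0.16 + 9
    auc_of <- function(scores, col) {
      m <- merge(data.frame(drug_id = pairs, label = label), scores,
                 by = "drug_id")
      auc_score(m$label, m[[col]])
    }
    a_comb_clean <- auc_of(combine_signals(clean), "phi_hat")
    a_comb_noisy <- auc_of(combine_signals(noisy), "phi_hat")
    a_b_clean <- auc_of(clean[clean$source_id == "B", ], "score")
    a_b_noisy <- auc_of(noisy[noisy$source_id == "B", ], "score")
    d_comb[s] <- a_comb_clean - a_comb_noisy
    d_single[s] <- a_b_clean - a_b_noisy
  }
  expect_lt(mean(d_comb), mean(d_single))
})

test_that("common_only restricts combination to fully observed pairs", {
  s <- rbind(mk_scores("A", c("d1", "d2", "d3"), "x", c(1, 2, 3), 0.5),
             mk_scores("B", c("d1", "d2"), "x", c(1, 2), 0.5))
  all_pairs <- combine_signals(s)
  common <- combine_signals(s, common_only = TRUE)
  expect_equal(sort(all_pairs$drug_id), c("d1", "d2", "d3"))
  expect_equal(sort(common$drug_id), c("d1", "d2"))
  only_a <- mk_scores("A", "d1", "x", 1, 0.5)
  only_b <- mk_scores("B", "d2", "x", 2, 0.5)
  expect_error(combine_signals(rbind(only_a, only_b), common_only = TRUE),
               "no pair")
})

test_that("mgps scores convert to combination-ready source rows", {
  cr <- tiny_reports()
  sc <- mgps_score(build_contingency(cr, "cooccurrence"),
                   mgps_prior(0.33, 0.2, 0.1, 2, 4))
  src <- mgps_as_source(sc, "srs")
  expect_named(src, c("source_id", "drug_id", "adr_id", "score", "variance"))
  expect_equal(src$score, sc$eblog2)
  expect_true(all(src$variance > 0))
})

test_that("source-score files round-trip", {
  s <- rbind(mk_scores("A", c("d1", "d2"), "x", c(1.5, -0.2), c(0.3, 0.4)),
             mk_scores("B", "d1", "x", 0.9, 1.1))
  f <- withr::local_tempfile(fileext = ".tsv")
  pvmcem:::write_tsv(data.table::as.data.table(s), f)
  back <- read_source_scores(f)
  expect_equal(as.data.frame(back), s)
})
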