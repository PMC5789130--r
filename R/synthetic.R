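#' Configuration for the synthetic spontaneous-report generator
#'
#' The generator emulates the statistical structure of spontaneous
#' reporting systems that the confounder-filtering and combination stages
#' assume: multi-drug reports (~48% of reports mention more than one drug),
#' exactly one causal drug per ADR occurrence with concomitant drugs
#' co-prescribed in clusters (the confounding mechanism), rare ADRs, and
#' under-reporting.
#'
#' @param n_reports number of reports to generate (each with >= 1 ADR).
#' @param n_drugs,n_adrs vocabulary sizes.
#' @param n_causal_pairs number of planted causal drug-ADR pairs (distinct
#'   drugs; distinct ADRs while possible).
#' @param causal_rr relative risk of a planted pair (>= 1): a causal drug
#'   triggers its ADR with probability `background_adr_rate * causal_rr`
#'   (capped at 1).
#' @param background_adr_rate per-report probability an ADR appears with no
#'   causal drug present.
#' @param p_multi_drug probability a report mentions more than one drug.
#' @param max_drugs_per_report multi-drug reports draw 2..this many drugs
#'   uniformly.
#' @param n_clusters number of co-prescription clusters (contiguous blocks
#'   of the drug vocabulary).
#' @param p_cluster probability a report's drugs are drawn from a single
#'   cluster rather than uniformly (the confounder-inheritance mechanism).
#' @param underreporting_prob probability any triggered ADR occurrence is
#'   omitted from the report.
#' @param suspect_prob probability the reporter records a primary-suspect
#'   drug for a causally triggered ADR.
#' @param suspect_accuracy probability a recorded suspect is the true
#'   cause (otherwise a random other drug in the report).
#' @param years reporting years sampled uniformly per report.
#' @param n_sources number of external score sources to simulate.
#' @param source_sd per-source score noise standard deviations (recycled to
#'   `n_sources`); unequal values make the reliability ordering testable.
#' @param scores_per_pair replicate scores per pair per source.
#' @param n_negatives_per_positive target ratio of negative to positive
#'   pairs in the generated reference standard.
#' @param seed integer seed; every generator output is a deterministic
#'   function of the configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_reports = 20000L, n_drugs = 200L, n_adrs = 30L,
                       n_causal_pairs = 25L, causal_rr = 5,
                       background_adr_rate = 0.01, p_multi_drug = 0.48,
                       max_drugs_per_report = 4L, n_clusters = 40L,
                       p_cluster = 0.9, underreporting_prob = 0.2,
                       suspect_prob = 0.7, suspect_accuracy = 0.6,
                       years = 2007:2014, n_sources = 2L,
                       source_sd = c(0.3, 0.8), scores_per_pair = 1L,
                       n_negatives_per_positive = 3L, seed = 1L) {
  cfg <- list(n_reports = as.integer(n_reports), n_drugs = as.integer(n_drugs),
              n_adrs = as.integer(n_adrs),
              n_causal_pairs = as.integer(n_causal_pairs),
              causal_rr = causal_rr,
              background_adr_rate = background_adr_rate,
              p_multi_drug = p_multi_drug,
              max_drugs_per_report = as.integer(max_drugs_per_report),
              n_clusters = as.integer(n_clusters), p_cluster = p_cluster,
              underreporting_prob = underreporting_prob,
              suspect_prob = suspect_prob, suspect_accuracy = suspect_accuracy,
              years = as.integer(years), n_sources = as.integer(n_sources),
              source_sd = rep_len(source_sd, n_sources),
              scores_per_pair = as.integer(scores_per_pair),
              n_negatives_per_positive = as.integer(n_negatives_per_positive),
              seed = as.integer(seed))
  for (p in c("background_adr_rate", "p_multi_drug", "p_cluster",
              "underreporting_prob", "suspect_prob", "suspect_accuracy"))
    assert_number(cfg[[p]], p, 0, 1)
  assert_number(cfg$causal_rr, "causal_rr", lower = 1)
  if (cfg$n_reports < 1L) stopf("n_reports must be >= 1")
  if (cfg$n_causal_pairs > cfg$n_drugs)
    stopf("cannot plant more causal pairs than drugs")
  if (cfg$max_drugs_per_report < 2L)
    stopf("max_drugs_per_report must be >= 2")
  if (cfg$n_drugs %% cfg$n_clusters != 0L)
    stopf("n_drugs must be a multiple of n_clusters")
  if (cfg$n_drugs %/% cfg$n_clusters < cfg$max_drugs_per_report)
    stopf("cluster size must be >= max_drugs_per_report")
  if (any(cfg$source_sd < 0)) stopf("source_sd must be >= 0")
  structure(cfg, class = "sim_config")
}

drug_ids <- function(n) sprintf("D%03d", seq_len(n))
adr_ids <- function(n) sprintf("A%03d", seq_len(n))

# draw k distinct column indices per row from pools of width `width` using
# repeated max-of-random-keys passes (vectorized over rows)
sample_distinct_rows <- function(m, k, width) {
  U <- matrix(runif(m * width), m, width)
  out <- matrix(NA_integer_, m, max(k))
  for (j in seq_len(max(k))) {
    idx <- max.col(U)
    out[, j] <- idx
    U[cbind(seq_len(m), idx)] <- -1
  }
  out
}

#' Generate synthetic case reports with planted ground truth
#'
#' Per report: a drug set is drawn (from one co-prescription cluster with
#' probability `p_cluster`, otherwise uniformly); every drug in the report
#' independently triggers its planted causal ADR with probability
#' `background_adr_rate * causal_rr` (capped at 1); ADRs with no causal
#' drug in the report appear at `background_adr_rate`; each occurrence is
#' then dropped with probability `underreporting_prob`; reports left with
#' zero ADRs are discarded and generation continues until `n_reports`
#' survive.  Each causally triggered occurrence is recorded with its single
#' causal drug in the ground truth (if two causal drugs trigger the same
#' ADR in one report, one is chosen at random as the cause).
#'
#' @param config a [sim_config()].
#' @return list with `reports` (a `case_reports` object) and `truth`
#'   (class `sim_truth`): `causal_pairs` (`drug_id`, `adr_id`, `log2_rr`),
#'   `assignments` (the true causal drug per retained (report, ADR)
#'   occurrence), `clusters` (drug -> cluster id), and the `config`.
#' @export
simulate_reports <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  p_trig <- min(cfg$background_adr_rate * cfg$causal_rr, 1)
  keep_p <- 1 - cfg$underreporting_prob
  exp_adr <- keep_p * (cfg$n_adrs * cfg$background_adr_rate +
                         cfg$n_causal_pairs / cfg$n_drugs * p_trig)
  if (exp_adr < 1e-6)
    stopf("infeasible configuration: expected ADR count per report is ~0 (under-reporting %.2f, background rate %.4g)",
          cfg$underreporting_prob, cfg$background_adr_rate)

  drugs_all <- drug_ids(cfg$n_drugs)
  adrs_all <- adr_ids(cfg$n_adrs)
  csize <- cfg$n_drugs %/% cfg$n_clusters
  cluster_of <- rep(seq_len(cfg$n_clusters), each = csize)

  local_seed(cfg$seed, {
    causal_drug_idx <- sample.int(cfg$n_drugs, cfg$n_causal_pairs)
    causal_adr_idx <- if (cfg$n_causal_pairs <= cfg$n_adrs)
      sample.int(cfg$n_adrs, cfg$n_causal_pairs)
    else
      sample.int(cfg$n_adrs, cfg$n_causal_pairs, replace = TRUE)
    # drug index -> its causal ADR index (NA if none); one causal ADR/drug
    causal_map <- rep(NA_integer_, cfg$n_drugs)
    causal_map[causal_drug_idx] <- causal_adr_idx

    kept_drugs <- vector("list", 0L)
    kept_occ <- vector("list", 0L)
    n_kept <- 0L
    next_id <- 1L
    guard <- 0L
    while (n_kept < cfg$n_reports) {
      guard <- guard + 1L
      if (guard > 2000L)
        stopf("infeasible configuration: report acceptance rate is ~0")
      m <- min(50000L, max(5000L,
                           ceiling((cfg$n_reports - n_kept) * 1.3 /
                                     max(min(exp_adr, 0.8), 0.02))))
      nd <- ifelse(runif(m) < cfg$p_multi_drug,
                   sample(2:cfg$max_drugs_per_report, m, replace = TRUE), 1L)
      use_cl <- runif(m) < cfg$p_cluster
      cl <- sample.int(cfg$n_clusters, m, replace = TRUE)

      kmax <- max(nd)
      dmat <- matrix(NA_integer_, m, kmax)
      if (any(use_cl)) {
        rows <- which(use_cl)
        loc <- sample_distinct_rows(length(rows), nd[rows], csize)
        dmat[rows, ] <- loc + (cl[rows] - 1L) * csize
      }
      if (any(!use_cl)) {
        rows <- which(!use_cl)
        dmat[rows, ] <- sample_distinct_rows(length(rows), nd[rows],
                                             cfg$n_drugs)
      }
      sel <- col(dmat) <= nd  # first nd[i] columns of row i
      dlong <- data.table(rid = row(dmat)[sel], didx = dmat[sel])

      # causal triggers: drug mentions whose causal ADR fires
      cand <- dlong[!is.na(causal_map[didx])]
      cand[, aidx := causal_map[didx]]
      cand <- cand[runif(.N) < p_trig]
      if (nrow(cand) > 1L) {
        cand <- cand[sample.int(.N)]          # random cause among multiple triggers
        cand <- cand[!duplicated(cand, by = c("rid", "aidx"))]
      }

      # background occurrences for (report, ADR) with no causal drug present
      bg_idx <- which(runif(m * cfg$n_adrs) < cfg$background_adr_rate)
      bg <- data.table(rid = ((bg_idx - 1L) %/% cfg$n_adrs) + 1L,
                       aidx = ((bg_idx - 1L) %% cfg$n_adrs) + 1L)
      caused_pairs <- unique(dlong[!is.na(causal_map[didx]),
                                   .(rid, aidx = causal_map[didx])])
      bg <- bg[!caused_pairs, on = c("rid", "aidx")]
      bg[, didx := NA_integer_]

      occ <- rbind(cand[, .(rid, aidx, didx)], bg)
      occ <- occ[runif(.N) >= cfg$underreporting_prob]   # under-reporting
      if (nrow(occ) == 0L) next
      keep_rids <- sort(unique(occ$rid))
      take <- keep_rids[seq_len(min(length(keep_rids),
                                    cfg$n_reports - n_kept))]
      occ <- occ[rid %in% take]
      dl <- dlong[rid %in% take]
      rid_map <- setNames(n_kept + seq_along(take), take)
      occ[, rid := rid_map[as.character(rid)]]
      dl[, rid := rid_map[as.character(rid)]]
      kept_occ[[length(kept_occ) + 1L]] <- occ
      kept_drugs[[length(kept_drugs) + 1L]] <- dl
      n_kept <- n_kept + length(take)
    }

    occ <- rbindlist(kept_occ)
    dl <- rbindlist(kept_drugs)
    occ[, report_id := sprintf("R%06d", rid)]
    dl[, report_id := sprintf("R%06d", rid)]

    # reporter-designated suspects for causal occurrences
    causal_occ <- occ[!is.na(didx)]
    sus <- NULL
    if (nrow(causal_occ)) {
      rec <- causal_occ[runif(.N) < cfg$suspect_prob]
      if (nrow(rec)) {
        correct <- runif(nrow(rec)) < cfg$suspect_accuracy
        rec[, sus_didx := didx]
        wrong <- which(!correct)
        if (length(wrong)) {
          # a random co-reported drug other than the cause, if any
          alt <- merge(rec[wrong, .(rid, didx, row_ = wrong)],
                       dl[, .(rid, alt_didx = didx)],
                       by = "rid", allow.cartesian = TRUE)
          alt <- alt[alt_didx != didx]
          if (nrow(alt)) {
            alt <- alt[sample.int(.N)]
            alt <- alt[!duplicated(row_)]
            rec[alt$row_, sus_didx := alt$alt_didx]
          }
        }
        sus <- rec[, .(report_id, aidx, sus_didx)]
      }
    }

    # assemble the case_reports object
    ord <- unique(dl[order(rid)], by = c("rid", "didx"))
    drugs_by <- split(drugs_all[ord$didx], ord$rid)
    occ_u <- unique(occ[, .(rid, aidx)])[order(rid, aidx)]
    adrs_by <- split(adrs_all[occ_u$aidx], occ_u$rid)
    ids <- sprintf("R%06d", as.integer(names(adrs_by)))
    yrs <- sample(cfg$years, length(ids), replace = TRUE)

    ps <- NULL
    if (!is.null(sus) && nrow(sus)) {
      sus_by <- split(sus, sus$report_id)
      ps <- lapply(ids, function(id) {
        s <- sus_by[[id]]
        if (is.null(s)) return(NULL)
        s <- s[!duplicated(aidx)]
        setNames(drugs_all[s$sus_didx], adrs_all[s$aidx])
      })
    }

    reports <- case_reports(ids, yrs, drugs_by, adrs_by, ps)

    truth <- structure(list(
      causal_pairs = data.frame(
        drug_id = drugs_all[causal_drug_idx],
        adr_id = adrs_all[causal_adr_idx],
        log2_rr = log2(cfg$causal_rr), stringsAsFactors = FALSE),
      assignments = as.data.frame(
        occ[!is.na(didx), .(report_id,
                            adr_id = adrs_all[aidx],
                            drug_id = drugs_all[didx])]),
      clusters = data.frame(drug_id = drugs_all, cluster = cluster_of,
                            stringsAsFactors = FALSE),
      config = cfg
    ), class = "sim_truth")

    list(reports = reports, truth = truth)
  })
}

#' Generate a reference standard from planted truth
#'
#' Positives are the planted causal pairs.  Negatives are (i) every
#' cluster-mate pair — a non-causal drug from the causal drug's
#' co-prescription cluster paired with the same ADR; exactly the
#' confounded pairs the MCEM step must suppress — plus (ii) random
#' non-causal pairs drawn to reach `n_negatives_per_positive` negatives
#' per positive (if the cluster-mates alone exceed that target they are
#' all kept).
#'
#' @param truth a `sim_truth` object.
#' @return data frame with columns `drug_id`, `adr_id`, `label`,
#'   `outcome_group`.
#' @export
simulate_reference <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  cfg <- truth$config
  cp <- truth$causal_pairs
  cl <- setNames(truth$clusters$cluster, truth$clusters$drug_id)
  mates <- do.call(rbind, lapply(seq_len(nrow(cp)), function(i) {
    same <- names(cl)[cl == cl[[cp$drug_id[i]]]]
    same <- setdiff(same, cp$drug_id[i])
    if (!length(same)) return(NULL)
    data.frame(drug_id = same, adr_id = cp$adr_id[i], stringsAsFactors = FALSE)
  }))
  mates <- unique(mates)
  key <- function(d) paste(d$drug_id, d$adr_id)
  mates <- mates[!key(mates) %in% key(cp), , drop = FALSE]
  target <- cfg$n_negatives_per_positive * nrow(cp)
  neg <- mates
  local_seed(cfg$seed + 1L, {
    if (nrow(neg) < target) {
      all_pairs <- expand.grid(drug_id = drug_ids(cfg$n_drugs),
                               adr_id = adr_ids(cfg$n_adrs),
                               stringsAsFactors = FALSE)
      pool <- all_pairs[!key(all_pairs) %in% c(key(cp), key(neg)), ]
      extra <- pool[sample.int(nrow(pool), min(target - nrow(neg),
                                               nrow(pool))), ]
      neg <- rbind(neg, extra)
    }
  })
  out <- rbind(
    data.frame(drug_id = cp$drug_id, adr_id = cp$adr_id, label = 1L,
               stringsAsFactors = FALSE),
    data.frame(drug_id = neg$drug_id, adr_id = neg$adr_id, label = 0L,
               stringsAsFactors = FALSE))
  out$outcome_group <- out$adr_id
  out <- out[order(-out$label, out$drug_id, out$adr_id), ]
  rownames(out) <- NULL
  out
}

#' Simulate per-source signal-score tables
#'
#' For each source, each reference pair receives `scores_per_pair` scores
#' equal to its true log2 relative risk (0 for non-causal pairs) plus
#' Gaussian noise with the source's standard deviation; the declared
#' variance column is that standard deviation squared.  Unequal per-source
#' noise makes the reliability-based pooling order observable.
#'
#' @param truth a `sim_truth` object.
#' @param reference optional reference standard (defaults to
#'   [simulate_reference()] of `truth`); scores are generated for its
#'   pairs.
#' @return data frame with columns `source_id`, `drug_id`, `adr_id`,
#'   `score`, `variance`.
#' @export
simulate_source_scores <- function(truth, reference = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  cfg <- truth$config
  if (is.null(reference)) reference <- simulate_reference(truth)
  truth_lrr <- ifelse(reference$label == 1L, log2(cfg$causal_rr), 0)
  local_seed(cfg$seed + 2L, {
    out <- lapply(seq_len(cfg$n_sources), function(k) {
      sdk <- cfg$source_sd[k]
      do.call(rbind, lapply(seq_len(cfg$scores_per_pair), function(r) {
        data.frame(source_id = sprintf("S%02d", k),
                   drug_id = reference$drug_id,
                   adr_id = reference$adr_id,
                   score = truth_lrr + rnorm(nrow(reference), 0, sdk),
                   variance = max(sdk^2, 1e-12),
                   stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, out)
  })
}
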