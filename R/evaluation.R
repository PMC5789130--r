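#' Area under the ROC curve
#'
#' Mann-Whitney rank formulation: the probability that a random positive
#' outranks a random negative, with tied scores counted 1/2.
#'
#' @param labels 0/1 (or logical) vector; both classes must be present.
#' @param scores matching numeric score vector.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_score(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.1))  # 0.75
#' @export
auc_score <- function(labels, scores) {
  labels <- as.integer(as.logical(labels) | labels == 1)
  if (length(labels) != length(scores)) stopf("labels and scores lengths differ")
  if (anyNA(labels) || anyNA(scores)) stopf("missing values in labels or scores")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stopf("AUC needs at least one positive and one negative")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Read a labelled reference standard
#'
#' Delimited table of drug-ADR pairs with columns `drug_id`, `adr_id`,
#' `label` (1 = positive association, 0 = negative control) and optionally
#' `outcome_group` for per-outcome metrics (defaults to the ADR id).
#'
#' @param path file path.
#' @return data frame of reference pairs.
#' @export
read_reference <- function(path) {
  x <- as.data.frame(read_tsv(path))
  need <- c("drug_id", "adr_id", "label")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stopf("reference file %s lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  validate_reference(x)
}

validate_reference <- function(ref) {
  ref <- as.data.frame(ref)
  if (anyDuplicated(ref[, c("drug_id", "adr_id")]))
    stopf("duplicate (drug, ADR) pairs in the reference standard")
  if (!all(ref$label %in% c(0L, 1L)))
    stopf("reference labels must be 0 or 1")
  if (!"outcome_group" %in% names(ref)) ref$outcome_group <- ref$adr_id
  ref
}

#' Evaluate a score table against a reference standard
#'
#' Joins scores onto labelled reference pairs and reports the pooled AUC,
#' per-outcome AUCs, and their mean ("average AUC").  Reference pairs that
#' never received a score (e.g. never co-occurred) are by default assigned
#' the minimum observed score minus one, so absence of evidence ranks below
#' every scored pair for every method symmetrically; `missing_scores =
#' "exclude"` drops them instead.
#'
#' @param scores a data frame with `drug_id`, `adr_id` and the score
#'   column.
#' @param reference a reference-standard data frame (see
#'   [read_reference()]).
#' @param score_col score column to rank by (default `"ebgm"`).
#' @param missing_scores `"penalize"` (default) or `"exclude"`.
#' @return An object of class `eval_report`: list with `pooled_auc`,
#'   `per_group` (data frame of per-outcome AUCs), `average_auc`, `n_pos`,
#'   `n_neg`, `n_missing`.
#' @export
evaluate_scores <- function(scores, reference, score_col = "ebgm",
                            missing_scores = c("penalize", "exclude")) {
  missing_scores <- match.arg(missing_scores)
  ref <- validate_reference(reference)
  if (!score_col %in% names(scores))
    stopf("score column '%s' not found", score_col)
  sc <- as.data.frame(scores)[, c("drug_id", "adr_id", score_col)]
  names(sc)[3L] <- "score"
  m <- merge(ref, sc, by = c("drug_id", "adr_id"), all.x = TRUE)
  n_missing <- sum(is.na(m$score))
  if (n_missing > 0L) {
    if (missing_scores == "exclude") {
      m <- m[!is.na(m$score), , drop = FALSE]
    } else {
      m$score[is.na(m$score)] <- min(m$score, na.rm = TRUE) - 1
    }
  }
  if (nrow(m) == 0L) stopf("no reference pairs left to evaluate")
  pooled <- auc_score(m$label, m$score)
  groups <- split(m, m$outcome_group)
  per <- lapply(names(groups), function(g) {
    gm <- groups[[g]]
    ok <- length(unique(gm$label)) == 2L
    data.frame(outcome_group = g,
               auc = if (ok) auc_score(gm$label, gm$score) else NA_real_,
               n_pos = sum(gm$label == 1L), n_neg = sum(gm$label == 0L))
  })
  per <- do.call(rbind, per)
  structure(list(
    pooled_auc = pooled,
    per_group = per,
    average_auc = mean(per$auc, na.rm = TRUE),
    n_pos = sum(m$label == 1L), n_neg = sum(m$label == 0L),
    n_missing = n_missing, score_col = score_col
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report (%s): pooled AUC %.4f | average AUC %.4f\n",
              x$score_col, x$pooled_auc, x$average_auc))
  cat(sprintf("  %d positives, %d negatives (%d without a score)\n",
              x$n_pos, x$n_neg, x$n_missing))
  print(x$per_group, row.names = FALSE)
  invisible(x)
}

#' Call signals at a fixed threshold
#'
#' Returns the pairs whose score strictly exceeds the threshold.  The
#' conventional rule is EB05 > 2: the posterior 5th percentile of the
#' relative reporting ratio above twice the expected rate.  If a reference
#' standard is supplied, precision is computed over called pairs that
#' appear in the reference; when none do, precision is undefined and
#' reported as such.
#'
#' @param scores score data frame.
#' @param field score column the rule applies to (default `"eb05"`).
#' @param threshold strict lower bound (default 2).
#' @param reference optional reference standard.
#' @return list with `called` (data frame), `n_called`, and when a
#'   reference is given `tp`, `fp`, `precision`, `precision_defined`.
#' @export
call_signals <- function(scores, field = "eb05", threshold = 2,
                         reference = NULL) {
  if (!field %in% names(scores))
    stopf("score column '%s' not found", field)
  called <- as.data.frame(scores)[scores[[field]] > threshold, , drop = FALSE]
  out <- list(called = called, n_called = nrow(called),
              field = field, threshold = threshold)
  if (!is.null(reference)) {
    ref <- validate_reference(reference)
    m <- merge(called[, c("drug_id", "adr_id")], ref,
               by = c("drug_id", "adr_id"))
    out$tp <- sum(m$label == 1L)
    out$fp <- sum(m$label == 0L)
    out$precision_defined <- nrow(m) > 0L
    out$precision <- if (out$precision_defined) out$tp / nrow(m) else NA_real_
  }
  out
}

#' Score reports cumulatively by reporting year
#'
#' Rebuilds the contingency table and MGPS scores on the reports received
#' up to each year, emulating what a surveillance system would have seen at
#' that point in time.
#'
#' @param reports a `case_reports` object.
#' @param years years to evaluate (default: all years present, ascending).
#' @param mode counting mode passed to [build_contingency()].
#' @param ... further arguments to [build_contingency()].
#' @return named list of `mgps_scores`, one per year.
#' @export
score_by_year <- function(reports, years = NULL, mode = "cooccurrence", ...) {
  stopifnot(inherits(reports, "case_reports"))
  if (is.null(years)) years <- sort(unique(reports$reports$year))
  out <- lapply(years, function(y) {
    sub <- filter_reports(reports, max_year = y)
    mgps_score(build_contingency(sub, mode = mode, ...))
  })
  names(out) <- as.character(years)
  out
}

#' Earliest detection year of a drug-ADR signal
#'
#' Given per-year score tables (e.g. from [score_by_year()]), returns the
#' first year in which the calling rule fires for the pair, or
#' `NA_integer_` if it never fires.
#'
#' @param per_year_scores named list of score tables; names are years.
#' @param drug_id,adr_id the pair of interest.
#' @param field,threshold the calling rule (default EB05 > 2).
#' @return first detection year as integer, or `NA_integer_`.
#' @export
detection_timeline <- function(per_year_scores, drug_id, adr_id,
                               field = "eb05", threshold = 2) {
  if (is.null(names(per_year_scores)))
    stopf("per_year_scores must be a named list (names = years)")
  years <- sort(as.integer(names(per_year_scores)))
  seen <- FALSE
  for (y in years) {
    sc <- as.data.frame(per_year_scores[[as.character(y)]])
    row <- sc[sc$drug_id == drug_id & sc$adr_id == adr_id, , drop = FALSE]
    if (nrow(row) == 0L) next
    seen <- TRUE
    if (any(row[[field]] > threshold)) return(y)
  }
  if (!seen) stopf("pair (%s, %s) absent from every year", drug_id, adr_id)
  NA_integer_
}
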