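#' Build a collection of spontaneous case reports
#'
#' A case report is one spontaneous adverse-event record: the set of drugs
#' the patient received, the set of adverse drug reactions (ADRs) observed,
#' the reporting year, and optionally the reporter-designated primary
#' suspect drug for individual ADRs.  Drugs and ADRs are deduplicated within
#' a report (counting is per distinct report, not per mention).
#'
#' @param report_id character vector of unique report identifiers.
#' @param year integer vector of reporting years (same length).
#' @param drugs list of character vectors, one per report; each non-empty.
#' @param adrs list of character vectors, one per report; each non-empty.
#' @param primary_suspect optional list, one element per report: either
#'   `NULL` or a named character vector mapping ADR id -> suspected drug id.
#'   Every suspect drug must belong to the report's drug set and every named
#'   ADR to its ADR set.
#' @return An object of class `case_reports`: a list of long-format tables
#'   (`reports`, `drugs`, `adrs`, `suspects`).
#' @examples
#' cr <- case_reports(
#'   report_id = c("r1", "r2"),
#'   year = c(2008L, 2009L),
#'   drugs = list(c("A", "B"), "A"),
#'   adrs = list("X", c("X", "Y")),
#'   primary_suspect = list(c(X = "A"), NULL)
#' )
#' n_reports(cr)
#' @export
case_reports <- function(report_id, year, drugs, adrs, primary_suspect = NULL) {
  n <- length(report_id)
  if (n == 0L) stopf("empty report collection")
  report_id <- as.character(report_id)
  if (anyDuplicated(report_id)) stopf("duplicated report_id values")
  if (length(year) != n || length(drugs) != n || length(adrs) != n)
    stopf("report_id, year, drugs and adrs must have equal length")
  year <- as.integer(year)
  drugs <- lapply(drugs, function(d) unique(as.character(d)))
  adrs <- lapply(adrs, function(a) unique(as.character(a)))
  if (any(lengths(drugs) == 0L)) stopf("every report needs at least one drug")
  if (any(lengths(adrs) == 0L)) stopf("every report needs at least one ADR")

  sus <- NULL
  if (!is.null(primary_suspect)) {
    if (length(primary_suspect) != n)
      stopf("primary_suspect must have one element per report")
    keep <- !vapply(primary_suspect, is.null, logical(1L))
    if (any(keep)) {
      idx <- which(keep)
      sus <- data.table(
        report_id = rep(report_id[idx], lengths(primary_suspect[idx])),
        adr_id = unlist(lapply(primary_suspect[idx], names)),
        drug_id = unname(unlist(primary_suspect[idx]))
      )
      for (i in idx) {
        ps <- primary_suspect[[i]]
        if (is.null(names(ps)) || any(names(ps) == ""))
          stopf("report %s: primary_suspect must be a named vector (ADR -> drug)",
                report_id[i])
        bad_d <- setdiff(ps, drugs[[i]])
        if (length(bad_d))
          stopf("report %s: suspect drug '%s' not among the report's drugs",
                report_id[i], bad_d[1L])
        bad_a <- setdiff(names(ps), adrs[[i]])
        if (length(bad_a))
          stopf("report %s: suspect ADR '%s' not among the report's ADRs",
                report_id[i], bad_a[1L])
      }
    }
  }
  if (is.null(sus))
    sus <- data.table(report_id = character(), adr_id = character(),
                      drug_id = character())

  out <- list(
    reports = data.table(report_id = report_id, year = year),
    drugs = data.table(report_id = rep(report_id, lengths(drugs)),
                       drug_id = unlist(drugs) %||% character()),
    adrs = data.table(report_id = rep(report_id, lengths(adrs)),
                      adr_id = unlist(adrs) %||% character()),
    suspects = sus
  )
  setkey(out$drugs, report_id, drug_id)
  setkey(out$adrs, report_id, adr_id)
  setkey(out$suspects, report_id, adr_id)
  structure(out, class = "case_reports")
}

#' @export
print.case_reports <- function(x, ...) {
  cat(sprintf(
    "case_reports: %d reports, %d distinct drugs, %d distinct ADRs, %d suspect annotations\n",
    nrow(x$reports), length(unique(x$drugs$drug_id)),
    length(unique(x$adrs$adr_id)), nrow(x$suspects)))
  invisible(x)
}

#' Number of reports in a collection
#' @param x a `case_reports` object.
#' @return integer count.
#' @export
n_reports <- function(x) {
  stopifnot(inherits(x, "case_reports"))
  nrow(x$reports)
}

#' Subset a report collection
#'
#' @param x a `case_reports` object.
#' @param report_ids report identifiers to keep, or `NULL`.
#' @param max_year keep reports with `year <= max_year`, or `NULL`.
#' @return a `case_reports` object.
#' @export
filter_reports <- function(x, report_ids = NULL, max_year = NULL) {
  stopifnot(inherits(x, "case_reports"))
  keep <- x$reports$report_id
  if (!is.null(report_ids)) keep <- intersect(keep, as.character(report_ids))
  if (!is.null(max_year))
    keep <- intersect(keep, x$reports$report_id[x$reports$year <= max_year])
  if (length(keep) == 0L) stopf("empty report collection after filtering")
  out <- list(
    reports = x$reports[report_id %in% keep],
    drugs = x$drugs[report_id %in% keep],
    adrs = x$adrs[report_id %in% keep],
    suspects = x$suspects[report_id %in% keep]
  )
  structure(out, class = "case_reports")
}

#' Read case reports from a delimited file
#'
#' The file is UTF-8 delimited text with a header row and columns
#' `report_id`, `year`, `drugs`, `adrs`, `primary_suspect`.  `drugs` and
#' `adrs` are pipe-separated identifier lists; `primary_suspect` is a
#' pipe-separated list of `adr:drug` tokens and may be empty.  Validation
#' errors cite 1-based file line numbers (the header is line 1).
#'
#' @param path file path.
#' @param sep field delimiter (default tab).
#' @return a `case_reports` object.
#' @export
read_reports <- function(path, sep = "\t") {
  if (!file.exists(path)) stopf("report file not found: %s", path)
  raw <- data.table::fread(path, sep = sep, header = TRUE,
                           colClasses = "character", na.strings = NULL,
                           data.table = TRUE)
  need <- c("report_id", "year", "drugs", "adrs")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stopf("report file %s lacks required column(s): %s", path,
          paste(miss, collapse = ", "))
  if (nrow(raw) == 0L) stopf("report file %s contains no reports", path)
  if (!"primary_suspect" %in% names(raw)) raw$primary_suspect <- ""

  line <- seq_len(nrow(raw)) + 1L
  yr <- suppressWarnings(as.integer(raw$year))
  if (anyNA(yr))
    stopf("line %d: year '%s' is not an integer",
          line[which(is.na(yr))[1L]], raw$year[which(is.na(yr))[1L]])

  split_pipe <- function(s) strsplit(s, "|", fixed = TRUE)
  drugs <- split_pipe(raw$drugs)
  adrs <- split_pipe(raw$adrs)
  empty_d <- which(lengths(drugs) == 0L | raw$drugs == "")
  if (length(empty_d)) stopf("line %d: empty drug list", line[empty_d[1L]])
  empty_a <- which(lengths(adrs) == 0L | raw$adrs == "")
  if (length(empty_a)) stopf("line %d: empty ADR list", line[empty_a[1L]])

  suspects <- vector("list", nrow(raw))
  has_ps <- which(!is.na(raw$primary_suspect) & raw$primary_suspect != "")
  for (i in has_ps) {
    toks <- strsplit(raw$primary_suspect[i], "|", fixed = TRUE)[[1L]]
    m <- regexpr(":", toks, fixed = TRUE)
    if (any(m < 1L))
      stopf("line %d: malformed primary_suspect token '%s' (expected adr:drug)",
            line[i], toks[which(m < 1L)[1L]])
    a <- substr(toks, 1L, m - 1L)
    d <- substr(toks, m + 1L, nchar(toks))
    suspects[[i]] <- setNames(d, a)
  }

  tryCatch(
    case_reports(raw$report_id, yr, drugs, adrs, suspects),
    error = function(e) stopf("report file %s: %s", path, conditionMessage(e))
  )
}

#' Write case reports to a delimited file
#'
#' Inverse of [read_reports()]; the round trip is lossless.
#'
#' @param x a `case_reports` object.
#' @param path output file path.
#' @param sep field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_reports <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "case_reports"))
  join <- function(dt, val) {
    agg <- dt[, .(s = paste(get(val), collapse = "|")), by = report_id]
    setNames(agg$s, agg$report_id)
  }
  ds <- join(x$drugs, "drug_id")
  as <- join(x$adrs, "adr_id")
  ps <- character(0)
  if (nrow(x$suspects)) {
    agg <- x$suspects[, .(s = paste(paste0(adr_id, ":", drug_id),
                                    collapse = "|")), by = report_id]
    ps <- setNames(agg$s, agg$report_id)
  }
  out <- data.table(
    report_id = x$reports$report_id,
    year = x$reports$year,
    drugs = unname(ds[x$reports$report_id]),
    adrs = unname(as[x$reports$report_id]),
    primary_suspect = ifelse(x$reports$report_id %in% names(ps),
                             unname(ps[x$reports$report_id]), "")
  )
  data.table::fwrite(out, path, sep = sep, quote = FALSE)
  invisible(path)
}

# All (report, adr, drug) candidate triples: the cross product of a report's
# ADRs with its drugs.  Row order is deterministic (keyed).
candidate_triples <- function(reports) {
  tr <- merge(reports$adrs, reports$drugs, by = "report_id",
              allow.cartesian = TRUE)
  setkey(tr, report_id, adr_id, drug_id)
  tr
}

# Per-drug / per-ADR report margins and the grand total.
report_margins <- function(reports) {
  list(
    n_drug = reports$drugs[, .(n_drug = .N), by = drug_id],
    n_adr = reports$adrs[, .(n_adr = .N), by = adr_id],
    n_total = nrow(reports$reports)
  )
}

# Assemble a contingency table from per-pair n00 counts and margins.
finish_contingency <- function(n00_dt, margins, include_zero, strict_margins) {
  if (include_zero) {
    univ <- CJ(drug_id = margins$n_drug$drug_id,
               adr_id = margins$n_adr$adr_id, unique = TRUE)
    ct <- merge(univ, n00_dt, by = c("drug_id", "adr_id"), all.x = TRUE)
    ct[is.na(n00), n00 := 0]
  } else {
    ct <- copy(n00_dt)
  }
  ct <- merge(ct, margins$n_drug, by = "drug_id")
  ct <- merge(ct, margins$n_adr, by = "adr_id")
  N <- margins$n_total
  ct[, n01 := n_drug - n00]
  ct[, n10 := n_adr - n00]
  ct[, n11 := N - n_drug - n_adr + n00]
  if (strict_margins) {
    ct[, E := n_drug * (n01 + n11) / N]
  } else {
    ct[, E := n_drug * n_adr / N]
  }
  setorder(ct, drug_id, adr_id)
  out <- as.data.frame(ct[, .(drug_id, adr_id, n00, n01, n10, n11, E)])
  attr(out, "n_total") <- N
  attr(out, "strict_margins") <- strict_margins
  class(out) <- c("contingency", "data.frame")
  out
}

#' Drug-ADR 2x2 contingency statistics from case reports
#'
#' For every drug-ADR pair, counts the number of reports in the four cells
#' of the 2x2 table (`n00` = with drug and ADR, `n01` = with drug without
#' ADR, `n10` = with ADR without drug, `n11` = neither) and the expected
#' count under independence `E`.  Three counting modes are supported:
#'
#' * `cooccurrence`: a report mentioning drug *i* and ADR *j* contributes 1
#'   to `n00(i, j)` for every such pair.
#' * `assigned`: each (report, ADR) occurrence contributes its full unit of
#'   count only to the single drug given by `assignment` (or fractionally,
#'   per `weights`); the report still counts towards `n01` for its other
#'   drugs.
#' * `primary_suspect`: like `assigned`, using the reporter-designated
#'   suspect; (report, ADR) occurrences without a recorded suspect fall
#'   back to plain co-occurrence counting so partially annotated data stay
#'   usable.
#'
#' @param reports a `case_reports` object.
#' @param mode counting mode, see above.
#' @param assignment for `mode = "assigned"`: a data frame with columns
#'   `report_id`, `adr_id`, `drug_id` giving each ADR occurrence its single
#'   major drug; must cover every (report, ADR) occurrence.
#' @param weights for `mode = "assigned"`: alternatively a data frame with
#'   columns `report_id`, `adr_id`, `drug_id`, `weight` of non-negative
#'   fractional counts summing to 1 over drugs within each (report, ADR)
#'   (tolerance 1e-6), as produced by cumulative Monte Carlo averaging.
#' @param include_zero if `TRUE`, emit a row for every drug x ADR
#'   combination (needed when scoring against a reference standard whose
#'   negatives never co-occur); default emits only pairs with `n00 > 0`
#'   observed under the chosen mode (plus co-occurring pairs whose assigned
#'   count is zero).
#' @param strict_margins if `TRUE`, compute `E` from the literal
#'   drug-margin x without-ADR-column product `(n00+n01)(n01+n11)/n++`
#'   (audit switch); the default uses the standard relative-reporting-ratio
#'   baseline `(n00+n01)(n00+n10)/n++`.
#' @return A data frame of class `contingency` with columns `drug_id`,
#'   `adr_id`, `n00`, `n01`, `n10`, `n11`, `E`, and attribute `n_total`.
#' @export
build_contingency <- function(reports,
                              mode = c("cooccurrence", "assigned",
                                       "primary_suspect"),
                              assignment = NULL, weights = NULL,
                              include_zero = FALSE, strict_margins = FALSE) {
  stopifnot(inherits(reports, "case_reports"))
  mode <- match.arg(mode)
  if (nrow(reports$reports) == 0L) stopf("empty report collection")
  margins <- report_margins(reports)

  if (mode == "cooccurrence") {
    tr <- candidate_triples(reports)
    n00_dt <- tr[, .(n00 = as.numeric(.N)), by = .(drug_id, adr_id)]
    return(finish_contingency(n00_dt, margins, include_zero, strict_margins))
  }

  if (mode == "assigned") {
    if (is.null(assignment) && is.null(weights))
      stopf("mode 'assigned' requires `assignment` or `weights`")
    if (!is.null(weights)) {
      w <- as.data.table(weights)[, .(report_id = as.character(report_id),
                                      adr_id = as.character(adr_id),
                                      drug_id = as.character(drug_id),
                                      weight = as.numeric(weight))]
      if (any(w$weight < 0)) stopf("negative assignment weights")
    } else {
      a <- as.data.table(assignment)[, .(report_id = as.character(report_id),
                                         adr_id = as.character(adr_id),
                                         drug_id = as.character(drug_id))]
      w <- a[, weight := 1.0]
    }
    unknown <- setdiff(w$report_id, reports$reports$report_id)
    if (length(unknown))
      stopf("assignment references unknown report '%s'", unknown[1L])
    chk <- merge(w, reports$drugs, by = c("report_id", "drug_id"))
    if (nrow(chk) != nrow(w))
      stopf("assignment assigns a drug outside its report's drug set")
    sums <- w[, .(s = sum(weight)), by = .(report_id, adr_id)]
    if (any(abs(sums$s - 1) > 1e-6))
      stopf("assignment weights do not sum to 1 within 1e-6 for %d (report, ADR) occurrence(s)",
            sum(abs(sums$s - 1) > 1e-6))
    occ <- unique(reports$adrs[, .(report_id, adr_id)])
    covered <- merge(occ, unique(sums[, .(report_id, adr_id)]),
                     by = c("report_id", "adr_id"))
    if (nrow(covered) != nrow(occ))
      stopf("assignment does not cover all (report, ADR) occurrences (%d of %d covered)",
            nrow(covered), nrow(occ))
    n00_dt <- w[, .(n00 = sum(weight)), by = .(drug_id, adr_id)]
    # keep all co-occurring pairs in the universe even if their assigned
    # count is zero, so scored pair sets are stable across counting modes
    cooc <- candidate_triples(reports)[, .(drug_id, adr_id)]
    cooc <- unique(cooc)
    n00_dt <- merge(cooc, n00_dt, by = c("drug_id", "adr_id"), all.x = TRUE)
    n00_dt[is.na(n00), n00 := 0]
    return(finish_contingency(n00_dt, margins, include_zero, strict_margins))
  }

  # primary_suspect: suspect occurrences get weight 1 on the suspect drug;
  # unannotated occurrences contribute plain co-occurrence
  occ <- unique(reports$adrs[, .(report_id, adr_id)])
  sus <- unique(reports$suspects[, .(report_id, adr_id, drug_id)])
  sus_first <- sus[!duplicated(sus[, .(report_id, adr_id)])]
  unann <- occ[!sus_first, on = c("report_id", "adr_id")]
  fallback <- merge(unann, reports$drugs, by = "report_id",
                    allow.cartesian = TRUE)
  w <- rbind(sus_first[, .(report_id, adr_id, drug_id, weight = 1.0)],
             fallback[, .(report_id, adr_id, drug_id, weight = 1.0)])
  n00_dt <- w[, .(n00 = sum(weight)), by = .(drug_id, adr_id)]
  cooc <- unique(candidate_triples(reports)[, .(drug_id, adr_id)])
  n00_dt <- merge(cooc, n00_dt, by = c("drug_id", "adr_id"), all.x = TRUE)
  n00_dt[is.na(n00), n00 := 0]
  finish_contingency(n00_dt, margins, include_zero, strict_margins)
}

#' Expected count under drug-ADR independence
#'
#' `E = (n00 + n01)(n00 + n10) / n++`: the product of the with-drug and
#' with-ADR report margins over the grand total.  The `strict_margins`
#' switch instead uses the without-ADR column `(n01 + n11)` as the second
#' factor, reproducing a common alternative printing of the baseline.
#'
#' @param stats a data frame with columns `n00`, `n01`, `n10`, `n11`.
#' @param strict_margins audit switch, see [build_contingency()].
#' @return numeric vector of expected counts.
#' @examples
#' expected_count(data.frame(n00 = 5, n01 = 15, n10 = 20, n11 = 60))  # 5
#' @export
expected_count <- function(stats, strict_margins = FALSE) {
  need <- c("n00", "n01", "n10", "n11")
  if (!all(need %in% names(stats)))
    stopf("`stats` must contain columns %s", paste(need, collapse = ", "))
  N <- stats$n00 + stats$n01 + stats$n10 + stats$n11
  if (any(N <= 0)) stopf("zero grand total in contingency stats")
  if (strict_margins) {
    (stats$n00 + stats$n01) * (stats$n01 + stats$n11) / N
  } else {
    (stats$n00 + stats$n01) * (stats$n00 + stats$n10) / N
  }
}

#' Write a contingency table to a delimited file
#' @param x a `contingency` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contingency <- function(x, path) {
  write_tsv(as.data.table(x)[, .(drug_id, adr_id, n00, n01, n10, n11, E)],
            path)
}
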