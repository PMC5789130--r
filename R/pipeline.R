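#' Default pipeline configuration
#'
#' A nested list describing a full run: output directory, stage selection,
#' global seed, and per-stage settings.  The same schema is accepted as a
#' YAML file by [run_pipeline()].  The single global seed is expanded into
#' fixed per-stage offsets (simulation `seed`, sampling `seed + 1000`) so
#' adding or removing a stage never perturbs another stage's random stream.
#'
#' @param out output directory.
#' @param seed global integer seed.
#' @param stages character vector among `simulate`, `mgps`, `mcem`,
#'   `combine`, `evaluate` (dependency order is enforced).
#' @param sim named list of [sim_config()] overrides.
#' @param mcem named list of [mcem_config()] overrides.
#' @param combine named list: `strict_eq10`, `tol`, `max_iter`,
#'   `include_srs` (append the MCEM scores as an additional source,
#'   default `TRUE`), `common_only` (combine only pairs present in every
#'   source, default `TRUE`).
#' @param evaluate named list: `score` column for evaluation (default
#'   `ebgm`), `threshold` and `field` for signal calling.
#' @param reports_file,source_scores_file,reference_file input paths used
#'   when the `simulate` stage is skipped.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out, seed = 1L,
                            stages = c("simulate", "mgps", "mcem",
                                       "combine", "evaluate"),
                            sim = list(), mcem = list(), combine = list(),
                            evaluate = list(),
                            reports_file = NULL, source_scores_file = NULL,
                            reference_file = NULL) {
  known <- c("simulate", "mgps", "mcem", "combine", "evaluate")
  bad <- setdiff(stages, known)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  structure(list(out = out, seed = as.integer(seed),
                 stages = known[known %in% stages],
                 sim = sim, mcem = mcem, combine = combine,
                 evaluate = evaluate,
                 reports_file = reports_file,
                 source_scores_file = source_scores_file,
                 reference_file = reference_file),
            class = "pipeline_config")
}

load_pipeline_config <- function(config) {
  if (inherits(config, "pipeline_config")) return(config)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("config must be a list or a YAML file path")
  if (is.null(config$out)) stopf("config field 'out' (output directory) is required")
  do.call(pipeline_config, config[intersect(names(config),
                                            names(formals(pipeline_config)))])
}

#' Run the end-to-end signal-detection pipeline
#'
#' Executes the requested stages in dependency order
#' (simulate -> mgps -> mcem -> combine -> evaluate), writing every
#' artifact as a delimited text table under the output directory together
#' with a `manifest.json` recording the configuration, seed and MD5 hash of
#' every file, so every number is traceable to (inputs, seed, parameters).
#' Reruns with an identical configuration are byte-identical.  On a stage
#' error, files created by the failed run are removed.
#'
#' @param config a [pipeline_config()], a plain named list with the same
#'   fields, or the path of a YAML file holding one.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  cfg <- load_pipeline_config(config)
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  artifact <- function(name) {
    p <- file.path(cfg$out, name)
    written <<- c(written, p)
    p
  }
  on_fail <- function(e) {
    unlink(written)
    stopf("pipeline stage failed: %s", conditionMessage(e))
  }

  tryCatch({
    reports <- NULL; reference <- NULL; source_scores <- NULL
    mcem_fit <- NULL; mgps_scores <- NULL

    if ("simulate" %in% cfg$stages) {
      sc <- do.call(sim_config, modifyList(list(seed = cfg$seed), cfg$sim))
      sim <- simulate_reports(sc)
      reports <- sim$reports
      reference <- simulate_reference(sim$truth)
      source_scores <- simulate_source_scores(sim$truth, reference)
      write_reports(reports, artifact("reports.tsv"))
      write_tsv(sim$truth$causal_pairs, artifact("truth_causal_pairs.tsv"))
      write_tsv(sim$truth$assignments, artifact("truth_assignments.tsv"))
      write_tsv(reference, artifact("reference.tsv"))
      write_tsv(source_scores, artifact("source_scores.tsv"))
    } else {
      if (any(c("mgps", "mcem") %in% cfg$stages)) {
        if (is.null(cfg$reports_file))
          stopf("stage requires 'reports_file' when simulate is skipped")
        reports <- read_reports(cfg$reports_file)
      }
      if (!is.null(cfg$source_scores_file))
        source_scores <- read_source_scores(cfg$source_scores_file)
      if (!is.null(cfg$reference_file))
        reference <- read_reference(cfg$reference_file)
    }

    if ("mgps" %in% cfg$stages) {
      ct <- build_contingency(reports, "cooccurrence")
      mgps_scores <- mgps_score(ct)
      write_contingency(ct, artifact("contingency.tsv"))
      write_scores(mgps_scores, artifact("mgps_scores.tsv"))
      write_mgps_prior(attr(mgps_scores, "prior"), artifact("mgps_prior.yaml"))
    }

    if ("mcem" %in% cfg$stages) {
      mc <- do.call(mcem_config,
                    modifyList(list(seed = cfg$seed + 1000L), cfg$mcem))
      mcem_fit <- run_mcem(reports, mc)
      write_tsv(mcem_fit$trace, artifact("mcem_trace.tsv"))
      write_scores(mcem_fit$scores, artifact("mcem_scores.tsv"))
      write_tsv(mcem_fit$assignment, artifact("mcem_assignment.tsv"))
      write_mgps_prior(mcem_fit$prior, artifact("mcem_prior.yaml"))
    }

    combined <- NULL
    if ("combine" %in% cfg$stages) {
      if (is.null(source_scores))
        stopf("combine stage requires source scores (simulate stage or 'source_scores_file')")
      ss <- source_scores
      include_srs <- cfg$combine$include_srs %||% TRUE
      if (include_srs) {
        srs_scores <- if (!is.null(mcem_fit)) mcem_fit$scores else mgps_scores
        if (!is.null(srs_scores))
          ss <- rbind(ss, mgps_as_source(srs_scores, "srs"))
      }
      combined <- combine_signals(ss,
                                  strict_eq10 = cfg$combine$strict_eq10 %||% FALSE,
                                  tol = cfg$combine$tol %||% 1e-8,
                                  max_iter = cfg$combine$max_iter %||% 1000L,
                                  common_only = cfg$combine$common_only %||% TRUE)
      write_tsv(as.data.table(as.data.frame(combined)),
                artifact("combined_signals.tsv"))
    }

    if ("evaluate" %in% cfg$stages) {
      if (is.null(reference))
        stopf("evaluate stage requires a reference standard (simulate stage or 'reference_file')")
      score_col <- cfg$evaluate$score %||% "ebgm"
      rows <- list()
      add_eval <- function(method, scores, col) {
        ev <- evaluate_scores(scores, reference, score_col = col)
        rows[[length(rows) + 1L]] <<- data.frame(
          method = method, pooled_auc = ev$pooled_auc,
          average_auc = ev$average_auc, n_pos = ev$n_pos, n_neg = ev$n_neg)
      }
      if (!is.null(mgps_scores)) add_eval("mgps", mgps_scores, score_col)
      if (!is.null(mcem_fit)) {
        add_eval("mcem_mgps", mcem_fit$scores, score_col)
        calls <- call_signals(mcem_fit$scores,
                              field = cfg$evaluate$field %||% "eb05",
                              threshold = cfg$evaluate$threshold %||% 2,
                              reference = reference)
        write_tsv(as.data.table(calls$called), artifact("called_signals.tsv"))
      }
      if (!is.null(combined)) add_eval("combined", combined, "phi_hat")
      if (!length(rows)) stopf("evaluate stage found no scores to evaluate")
      write_tsv(rbindlist(rows), artifact("evaluation.tsv"))
    }

    manifest <- list(
      package = "pvmcem",
      version = as.character(packageVersion("pvmcem")),
      seed = cfg$seed,
      stages = cfg$stages,
      config = cfg[c("sim", "mcem", "combine", "evaluate")],
      files = as.list(setNames(unname(tools::md5sum(sort(written))),
                               basename(sort(written))))
    )
    jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
  }, error = on_fail)
}
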