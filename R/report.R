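# Pipeline orchestration: simulate -> watch -> cpet -> associate, the
# sample-exclusion flow table, and the reproducibility manifest.

#' Pipeline configuration
#'
#' @param params A [cohort_params()] object for the synthetic stage.
#' @param analysis An [analysis_config()] for the association stage.
#' @param stages Stages to run, in order; `associate` requires both
#'   `watch` and `cpet`.
#' @param out_dir Optional directory; when set, every stage output is
#'   written as CSV and the manifest as JSON.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(params = cohort_params(),
                            analysis = analysis_config(),
                            stages = c("simulate", "watch", "cpet",
                                       "associate"),
                            out_dir = NULL) {
  stages <- match.arg(stages, c("simulate", "watch", "cpet", "associate"),
                      several.ok = TRUE)
  structure(list(params = params, analysis = analysis, stages = stages,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes the configured stages in order: synthetic cohort and
#' streams, watch-stream processing, CPET index derivation, and the
#' association battery on the joined table. Per-stage record counts and
#' every filter's before/after sample size are collected into the
#' exclusion-flow table. Outputs are a deterministic function of the
#' configuration (including the seed).
#'
#' @param config A [pipeline_config()].
#' @return List with `cohort`, `streams`, `watch`, `cpet_results`,
#'   `analysis_table`, `results`, `flow` and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$params
  ac <- config$analysis
  st <- config$stages
  need <- function(stage, deps) {
    missing <- setdiff(deps, st)
    if (stage %in% st && length(missing) > 0) {
      stop(sprintf("stage '%s' requires stage(s): %s", stage,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  need("watch", "simulate")
  need("cpet", "simulate")
  need("associate", c("simulate", "watch", "cpet"))

  out <- list()
  if ("simulate" %in% st) {
    out$cohort <- generate_cohort(p)
    out$streams <- generate_watch_streams(out$cohort, p)
    out$sessions <- generate_cpet_sessions(out$cohort, p)
  }
  if ("watch" %in% st) {
    out$watch <- process_watch(out$streams$hr, out$streams$steps,
                               min_days = ac$min_days, tz = p$tz)
  }
  if ("cpet" %in% st) {
    anthro <- out$cohort$covariates[
      c("participant_id", "age", "sex", "height_cm", "weight_kg")]
    out$cpet_results <- process_cpet(out$sessions$breath, out$sessions$sbp,
                                     anthro, rer_cut = ac$rer_cut)
  }
  if ("associate" %in% st) {
    out$analysis_table <- build_analysis_table(
      out$watch$participant_summaries, out$cpet_results,
      out$cohort$covariates, state_pool_min = ac$state_pool_min)
    out$results <- run_battery(config = ac,
                               analysis_table = out$analysis_table)
    out$flow <- exclusion_flow(out$cohort$covariates,
                               out$watch$participant_summaries,
                               out$cpet_results, rer_cut = ac$rer_cut)
  }

  out$manifest <- build_manifest(config, out)
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

#' Sample-exclusion flow table
#'
#' Ordered accounting of the analysis-sample construction: starting
#' cohort, participants without watch data, participants short of the
#' 30-day HR or step inclusion cuts, participants with missing
#' covariates or CPET indices, and the effort filter. Conservation
#' holds by construction: each row's `n_after` equals the next row's
#' `n_before`.
#'
#' @param covariates Cohort covariate table.
#' @param watch_summaries Participant watch summaries.
#' @param cpet_results Per-participant CPET results.
#' @param rer_cut Effort cut for the final (sensitivity) row.
#' @return Tibble `criterion`, `n_before`, `n_excluded`, `n_after`.
#' @export
exclusion_flow <- function(covariates, watch_summaries, cpet_results,
                           rer_cut = 1.05) {
  ids <- covariates$participant_id
  steps <- list()
  add <- function(criterion, keep_ids) {
    steps[[length(steps) + 1L]] <<- tibble::tibble(
      criterion = criterion, n_before = length(ids),
      n_excluded = length(ids) - length(keep_ids),
      n_after = length(keep_ids))
    ids <<- keep_ids
  }
  ws <- watch_summaries
  add("has smartwatch data",
      intersect(ids, ws$participant_id))
  add("30+ days of HR data with nonactive records",
      intersect(ids, ws$participant_id[ws$include_hr]))
  add("30+ valid step days",
      intersect(ids, ws$participant_id[ws$include_steps]))
  cp <- cpet_results[!is.na(cpet_results$peak_vo2) &
                       !is.na(cpet_results$vat_vo2), ]
  add("complete CPET indices", intersect(ids, cp$participant_id))
  add(sprintf("peak RER >= %.2f (effort sensitivity)", rer_cut),
      intersect(ids, cp$participant_id[cp$peak_rer >= rer_cut]))
  dplyr::bind_rows(steps)
}

# manifest: config hash, seed, stage row counts, output digests
build_manifest <- function(config, out) {
  digests <- lapply(out[setdiff(names(out), "manifest")], function(x) {
    if (is.data.frame(x)) object_md5(x)
    else if (is.list(x)) lapply(x[vapply(x, is.data.frame, logical(1))],
                                object_md5)
    else NULL
  })
  list(
    package_version = as.character(utils::packageVersion("wearcpet")),
    seed = config$params$seed,
    config_hash = object_md5(config[c("params", "analysis", "stages")]),
    stages = config$stages,
    n_participants = config$params$n_participants,
    digests = digests)
}

# write stage outputs as CSV plus the manifest as JSON
write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    write.csv(x, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
  }
  if (!is.null(out$cohort)) {
    wr(out$cohort$covariates, "covariates")
    wr(out$cohort$truth, "ground_truth")
  }
  if (!is.null(out$streams)) {
    wr(out$streams$hr, "hr_records")
    wr(out$streams$steps, "step_records")
  }
  if (!is.null(out$watch)) {
    wr(out$watch$day_summaries, "day_summaries")
    wr(out$watch$participant_summaries, "participant_summaries")
  }
  if (!is.null(out$cpet_results)) wr(out$cpet_results, "cpet_results")
  if (!is.null(out$results)) wr(out$results, "model_results")
  if (!is.null(out$flow)) wr(out$flow, "exclusion_flow")
  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Plain-text report of the battery results
#'
#' Formats the primary grid as a fixed-width table (one block per
#' outcome-model cell) for quick inspection.
#'
#' @param results Output of [run_battery()].
#' @return Character vector of report lines (invisibly printed with
#'   `cat` when `print = TRUE`).
#' @param print Print to the console.
#' @export
format_results_table <- function(results, print = FALSE) {
  lines <- character(0)
  prim <- results[results$analysis == "primary", , drop = FALSE]
  for (oc in unique(prim$outcome)) {
    for (md in unique(prim$model)) {
      cell <- prim[prim$outcome == oc & prim$model == md, , drop = FALSE]
      lines <- c(lines, sprintf("== %s | %s (n=%d) ==", oc, md, cell$n[1]))
      lines <- c(lines, sprintf("  %-24s beta=%10.3f  se=%8.3f  FDR-p=%.4g",
                                cell$exposure, cell$beta, cell$se,
                                cell$p_fdr))
    }
  }
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}
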