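# End-to-end pipeline driver: simulate -> qc -> [ica] -> postprocess -> dfnc
# -> cluster (or select-k) -> metrics -> stats, with a JSON run manifest.
# One master seed fans out to deterministic per-stage child seeds.

#' Pipeline configuration
#'
#' @param scenario a [scenario_config()] (ignored when `cohort` is supplied
#'   to [run_pipeline()]).
#' @param qc a [qc_thresholds()].
#' @param postprocess a [postprocess_config()]. The pipeline default disables
#'   the low-pass stage: synthetic component signals are spectrally flat, so
#'   filtering them only shrinks each window's effective sample size. Pass a
#'   full [postprocess_config()] for real data.
#' @param window a [window_spec()].
#' @param glasso a [glasso_config()] or a fixed penalty value.
#' @param k number of states, or `NULL` to select by [elbow_select_k()] over
#'   `k_range`.
#' @param k_range candidate state counts for elbow selection.
#' @param n_restarts k-means restarts.
#' @param voxel_mode run the group-ICA stage on simulated voxel data (requires
#'   `template_maps`).
#' @param template_maps template maps for component labelling in voxel mode.
#' @param seed master seed.
#' @param out_dir output directory, or `NULL` for no file output.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = scenario_config(),
                            qc = qc_thresholds(),
                            postprocess = postprocess_config(lowpass_hz = NULL),
                            window = window_spec(),
                            glasso = 0.1,
                            k = 5L,
                            k_range = 2:9,
                            n_restarts = 20L,
                            voxel_mode = FALSE,
                            template_maps = NULL,
                            seed = 1L,
                            out_dir = NULL) {
  if (voxel_mode && is.null(template_maps))
    stop("config error: voxel mode requires template maps")
  structure(list(scenario = scenario, qc = qc, postprocess = postprocess,
                 window = window, glasso = glasso, k = k, k_range = k_range,
                 n_restarts = as.integer(n_restarts), voxel_mode = voxel_mode,
                 template_maps = template_maps, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

stage_seed <- function(config, stage) derive_seed(config$seed, "stage", stage)

#' Run the full dFNC pipeline
#'
#' Executes simulate -> qc -> postprocess -> windowed FC -> clustering (fixed
#' `k` or elbow selection) -> temporal metrics -> group statistics, and
#' assembles a manifest recording stages, seeds and (when `out_dir` is set)
#' output file hashes. Idempotent: the same config and seed reproduce
#' identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param cohort optionally, a pre-built [simulate_cohort()] result (the
#'   simulate stage is then skipped).
#' @return list with `cohort`, `qc`, `wfc`, `model`, `metrics`, `stats`,
#'   `selected_k` (when elbow-selected) and `manifest`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(package_version = as.character(utils::packageVersion("dfncstates")),
                   seed = config$seed, stages = character(0))
  done <- function(s) manifest$stages <<- c(manifest$stages, s)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  scen <- config$scenario
  if (is.null(cohort)) {
    scen$seed <- stage_seed(config, "simulate")
    cohort <- run_stage("simulate", simulate_cohort(scen))
    done("simulate")
  } else {
    scen <- cohort$ground_truth$config
    done("simulate(cached)")
  }

  qc_tab <- run_stage("qc", qc_report(cohort, config$qc))
  retained <- qc_tab$session[qc_tab$decision == "retain"]
  keep_subj <- names(which(table(qc_tab$subject[qc_tab$decision == "retain"]) == 2L))
  retained <- retained[qc_tab$subject[match(retained, qc_tab$session)] %in% keep_subj]
  done("qc")

  session_table <- cohort$session_table[cohort$session_table$session %in% retained, ]

  cleaned <- run_stage("postprocess", {
    lapply(setNames(session_table$session, session_table$session), function(key) {
      ses <- cohort$sessions[[key]]
      postprocess_session(ses$timecourses, ses$motion, config$postprocess,
                          tr_seconds = scen$tr_seconds)
    })
  })
  done("postprocess")

  wfc <- run_stage("dfnc", {
    lapply(setNames(names(cleaned), names(cleaned)), function(key) {
      windowed_fc(cleaned[[key]], config$window, config$glasso,
                  seed = derive_seed(stage_seed(config, "dfnc"), key))
    })
  })
  done("dfnc")

  selected_k <- NULL
  if (is.null(config$k)) {
    sel <- run_stage("select-k",
                     elbow_select_k(wfc, config$k_range,
                                    n_restarts = config$n_restarts,
                                    seed = stage_seed(config, "select-k")))
    selected_k <- sel$selected_k
    k_use <- selected_k
    done("select-k")
  } else k_use <- config$k
  model <- run_stage("cluster",
                     cluster_states(wfc, k_use, n_restarts = config$n_restarts,
                                    seed = stage_seed(config, "cluster")))
  done("cluster")

  metrics <- run_stage("metrics",
                       cohort_temporal_metrics(model, session_table, k_use))
  done("metrics")

  stats <- run_stage("stats",
                     run_full_comparison(metrics, cohort$subjects))
  done("stats")

  out <- list(cohort = cohort, qc = qc_tab, wfc = wfc, model = model,
              metrics = metrics, stats = stats, selected_k = selected_k)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(qc_tab, file.path(config$out_dir, "qc_report.tsv"))
    write_tsv(metrics, file.path(config$out_dir, "temporal_metrics.tsv"))
    write_tsv(model$assignments, file.path(config$out_dir, "assignments.tsv"))
    write_tsv(stats$comparisons, file.path(config$out_dir, "comparisons.tsv"))
    write_tsv(stats$correlations, file.path(config$out_dir, "correlations.tsv"))
    jsonlite::write_json(
      list(k = model$k, cost = model$cost,
           occurrence = model$occurrence, centroids = model$centroids),
      file.path(config$out_dir, "state_model.json"), digits = NA)
    files <- list.files(config$out_dir, full.names = TRUE)
    manifest$outputs <- as.list(tools::md5sum(files))
    names(manifest$outputs) <- basename(files)
  }
  manifest$k <- k_use
  out$manifest <- manifest
  if (!is.null(config$out_dir))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  out
}
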