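# End-to-end orchestration: model dRDMs -> model-space validation -> data
# dRDMs -> GLM -> feature fits -> permutation thresholds -> thresholded maps.
#
# The pipeline is driven by a single validated config that is serialized
# (with its hash) next to every output, so a run can be reproduced exactly
# from its output directory alone.

#' Pipeline configuration
#'
#' @param radius_mm,window_ms,step_ms,lag_ms,epoch_ms,window_mode searchlight
#'   geometry, passed to [searchlight_config()].
#' @param n_perm permutation iterations for the null.
#' @param quantiles quantile ladder for thresholding; the first entry is the
#'   working threshold.
#' @param seed RNG seed for the permutation null.
#' @param feature_matrix_path CSV path for the phone-feature matrix; NULL
#'   uses the packaged default.
#' @param likelihood_csv optional path to a long-format likelihood CSV.
#' @param mesh_tsv optional path to a mesh TSV.
#' @param output_dir directory for persisted outputs; NULL keeps everything
#'   in memory.
#' @param run_validation compute the second-order model-space diagnostics.
#' @param per_window_maps also persist per-window GLM coefficients (the
#'   default reports only epoch-averaged summaries).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(radius_mm = 20, window_ms = 60, step_ms = 10,
                            lag_ms = 100, epoch_ms = 270,
                            window_mode = "standard",
                            n_perm = 100,
                            quantiles = c(0.95, 0.99, 0.999),
                            seed = 1,
                            feature_matrix_path = NULL,
                            likelihood_csv = NULL,
                            mesh_tsv = NULL,
                            output_dir = NULL,
                            run_validation = TRUE,
                            per_window_maps = FALSE) {
  cfg <- searchlight_config(radius_mm, window_ms, step_ms, lag_ms, epoch_ms,
                            window_mode)
  if (any(quantiles <= 0 | quantiles >= 1))
    ssrsa_error("quantiles must lie in (0, 1)", "ssrsa_invalid_input")
  if (n_perm < 1)
    ssrsa_error("n_perm must be >= 1", "ssrsa_invalid_input")
  structure(list(searchlight = cfg, n_perm = n_perm,
                 quantiles = sort(quantiles),
                 seed = as.integer(seed),
                 feature_matrix_path = feature_matrix_path,
                 likelihood_csv = likelihood_csv, mesh_tsv = mesh_tsv,
                 output_dir = output_dir,
                 run_validation = run_validation,
                 per_window_maps = per_window_maps),
            class = "pipeline_config")
}

#' Hash of a pipeline config
#'
#' MD5 of the config's YAML serialization; embedded in every output table
#' for provenance.
#'
#' @param config a `pipeline_config`.
#' @return character hash.
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(rapply(unclass(config), unclass, how = "replace"), f)
  unname(tools::md5sum(f))
}

write_stamped <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: build the phone model set from likelihood streams;
#' (optionally) second-order model-space diagnostics; searchlight data
#' dRDMs; per-window GLM fits; epoch-averaged feature fit maps; permutation
#' null and thresholds; thresholded maps. Supplying no epochs runs the
#' model-side stages only. Every persisted table carries the config hash.
#'
#' @param config a `pipeline_config`.
#' @param streams a `likelihood_streams` (or NULL to read
#'   `config$likelihood_csv`).
#' @param epochs a `source_epochs`, or NULL for a model-only run.
#' @param mesh a `source_mesh` (or NULL to read `config$mesh_tsv`).
#' @param inventory phone inventory to model (default: all centre phones in
#'   the streams).
#' @param verbose print per-stage progress.
#' @return list with elements (as applicable): `model_set`, `validation`,
#'   `data_drdms`, `fit`, `feature_fits`, `nulls`, `thresholded`, `log`
#'   (per-stage counts and timings), `config`, `config_hash`.
#' @export
run_pipeline <- function(config, streams = NULL, epochs = NULL, mesh = NULL,
                         inventory = NULL, verbose = FALSE) {
  hash <- config_hash(config)
  scfg <- config$searchlight
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  log <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      ssrsa_error(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                  "ssrsa_stage_failure"))
    log[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    if (verbose) message(sprintf("[%s] done in %.1fs", name, log[[name]]$seconds))
    res
  }

  if (is.null(streams)) {
    if (is.null(config$likelihood_csv))
      ssrsa_error("no likelihood streams supplied (in memory or via config)",
                  "ssrsa_invalid_input")
    streams <- stage("read_streams", read_likelihood_csv(config$likelihood_csv))
  }
  fm <- stage("feature_matrix", {
    if (is.null(config$feature_matrix_path)) default_feature_matrix()
    else load_feature_matrix(config$feature_matrix_path)
  })
  onsets <- config_window_onsets(scfg)
  model_set <- stage("build_models",
                     build_model_set(streams, inventory, onsets, scfg$window_ms))
  log$build_models$n_models <- length(model_set$phones)
  log$build_models$n_frames <- n_model_frames(model_set)

  result <- list(model_set = model_set, config = config, config_hash = hash,
                 feature_matrix = fm)

  if (config$run_validation) {
    result$validation <- stage("validate_models", tryCatch(
      feature_cluster_diagnostics(model_set, fm),
      ssrsa_error = function(e) {
        warning(sprintf("model-space validation skipped: %s", conditionMessage(e)))
        NULL
      }))
    if (!is.null(out_dir) && !is.null(result$validation))
      write_stamped(result$validation,
                    file.path(out_dir, "model_validation.csv"), hash)
  }

  if (is.null(epochs)) {
    result$log <- log
    if (!is.null(out_dir))
      yaml::write_yaml(list(config_hash = hash, log = log,
                            mode = "model-only"),
                       file.path(out_dir, "run_report.yaml"))
    return(result)
  }

  if (is.null(mesh)) {
    if (is.null(config$mesh_tsv))
      ssrsa_error("source epochs supplied without a mesh", "ssrsa_invalid_input")
    mesh <- stage("read_mesh", read_mesh_tsv(config$mesh_tsv))
  }
  data_drdms <- stage("build_data_rdms",
                      build_data_drdms(epochs, mesh, scfg, verbose = FALSE))
  log$build_data_rdms$n_vertices <- length(data_drdms)
  log$build_data_rdms$n_rdms <- length(data_drdms) * length(onsets)

  fit <- stage("glm_fit", fit_drdms(data_drdms, model_set))
  fits <- stage("feature_fits", feature_fit_map(fit, fm))
  nulls <- stage("permutation_null",
                 build_null(data_drdms, model_set, fm,
                            n_perm = config$n_perm, seed = config$seed))
  log$permutation_null$n_perm <- config$n_perm
  log$permutation_null$pool_size <- config$n_perm * length(data_drdms)
  thresholded <- stage("threshold_maps",
                       threshold_feature_maps(fits, nulls,
                                              q = config$quantiles[1],
                                              report_quantiles = config$quantiles))

  result$data_drdms <- data_drdms
  result$fit <- fit
  result$feature_fits <- fits
  result$nulls <- nulls
  result$thresholded <- thresholded
  result$log <- log

  if (!is.null(out_dir)) {
    if (config$per_window_maps)
      write_glm_csv(fit, file.path(out_dir, "glm_per_window.csv"))
    eb <- epoch_average_betas(fit)
    write_stamped(data.frame(vertex_id = rep(colnames(eb$betas),
                                             each = nrow(eb$betas)),
                             phone = rep(rownames(eb$betas),
                                         times = ncol(eb$betas)),
                             beta = as.vector(eb$betas)),
                  file.path(out_dir, "epoch_betas.csv"), hash)
    write_stamped(thresholded$table, file.path(out_dir, "feature_maps.csv"),
                  hash)
    write_stamped(thresholded$summary,
                  file.path(out_dir, "feature_summary.csv"), hash)
    yaml::write_yaml(list(config_hash = hash, log = log, mode = "full"),
                     file.path(out_dir, "run_report.yaml"))
  }
  result
}
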