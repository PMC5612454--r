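# Self-contained validation experiments on synthetic data.
#
# Two standard study designs are packaged so that calibration and recovery
# claims are reproducible with one call each: a pure-noise design that checks
# the permutation threshold's false-positive rate, and a single-implant
# design that checks spatial and model-identity recovery. Both run the full
# pipeline (generator -> model dRDMs -> searchlight -> GLM -> feature fits ->
# permutation thresholds); only the problem sizes are reduced relative to a
# full-scale analysis.

# shared scaffolding: random lexicon over `inventory`, model set, epochs
simulation_scaffold <- function(seed, inventory, n_conditions, phones_per_word,
                                grid_dims, grid_spacing_mm, n_subjects,
                                noise_sd, implants, cfg) {
  strings <- with_seed(seed, lapply(seq_len(n_conditions), function(i)
    sample(inventory, phones_per_word, replace = TRUE)))
  names(strings) <- sprintf("w%03d", seq_len(n_conditions))
  spec <- synthetic_spec(phone_strings = strings, inventory = inventory,
                         epoch_ms = cfg$epoch_ms,
                         grid_dims = grid_dims,
                         grid_spacing_mm = grid_spacing_mm,
                         n_subjects = n_subjects, noise_sd = noise_sd,
                         implants = implants, seed = seed)
  streams <- gen_likelihood_streams(spec)
  model_set <- suppressWarnings(
    build_model_set(streams$streams, NULL, config_window_onsets(cfg),
                    cfg$window_ms))
  src <- gen_source_epochs(spec, model_set, cfg)
  list(spec = spec, model_set = model_set, epochs = src$epochs,
       mesh = src$mesh, truth = src$truth)
}

#' Null-calibration study: false-positive rate of the permutation threshold
#'
#' Generates pure-noise source epochs (no implants), runs the full pipeline,
#' and reports the fraction of (feature, vertex) cells whose observed
#' epoch-averaged feature fit exceeds the q-quantile permutation threshold.
#' Under the null this fraction should sit near 1 - q.
#'
#' @param seed RNG seed for this run.
#' @param q threshold quantile.
#' @param n_conditions,n_subjects,grid_dims,grid_spacing_mm,n_perm study size.
#' @param fm feature matrix (default: the packaged 40-phone matrix).
#' @param cfg searchlight configuration.
#' @return list: `survival_rate`, `n_cells`, `n_vertices`.
#' @export
null_calibration_run <- function(seed, q = 0.95,
                                 n_conditions = 24, n_subjects = 2,
                                 grid_dims = c(6, 6, 4),
                                 grid_spacing_mm = 15,
                                 n_perm = 100,
                                 fm = default_feature_matrix(),
                                 cfg = searchlight_config()) {
  sc <- simulation_scaffold(seed, fm$phones, n_conditions, 3, grid_dims,
                            grid_spacing_mm, n_subjects, 1, list(), cfg)
  dd <- build_data_drdms(sc$epochs, sc$mesh, cfg)
  fit <- fit_drdms(dd, sc$model_set)
  fits <- suppressWarnings(feature_fit_map(fit, fm))
  nulls <- suppressWarnings(build_null(dd, sc$model_set, fm,
                                       n_perm = n_perm, seed = seed + 1))
  th <- threshold_feature_maps(fits, nulls, q)
  list(survival_rate = mean(th$table$survives),
       n_cells = nrow(th$table), n_vertices = length(dd))
}

# compact articulatory matrix over the 8-phone recovery inventory
recovery_feature_matrix <- function() {
  ind <- rbind(stop = c(p = 1, t = 1, k = 1, s = 0, m = 0, n = 0, aa = 0, ih = 0),
               fricative = c(p = 0, t = 0, k = 0, s = 1, m = 0, n = 0, aa = 0, ih = 0),
               nasal = c(p = 0, t = 0, k = 0, s = 0, m = 1, n = 1, aa = 0, ih = 0),
               vowel = c(p = 0, t = 0, k = 0, s = 0, m = 0, n = 0, aa = 1, ih = 1),
               voiced = c(p = 0, t = 0, k = 0, s = 0, m = 1, n = 1, aa = 1, ih = 1))
  feature_matrix(ind, c("manner", "manner", "manner", "broad", "broad"))
}

#' Implant-recovery study: does the pipeline find what was planted?
#'
#' Implants one phone model's representational geometry at a known patch,
#' runs the full pipeline, and scores (a) whether the implanted phone has
#' the top epoch-averaged coefficient at the implant centre, (b) whether the
#' centre survives the q-threshold for the implanted phone's feature, and
#' (c) the survival rate among far vertices (at least `far_mm` from the
#' centre), which should stay at the nominal false-positive level.
#'
#' @param seed RNG seed for this run.
#' @param amplitude implant effect amplitude (relative to unit noise).
#' @param implant_phone phone whose model is implanted.
#' @param implant_feature feature scored for threshold survival (must carry
#'   the implanted phone).
#' @param q threshold quantile.
#' @param far_mm distance defining "far" vertices (three patch radii by
#'   default).
#' @param n_conditions,n_subjects,grid_dims,grid_spacing_mm,n_perm study size.
#' @param cfg searchlight configuration.
#' @return list: `top_phone` (logical), `centre_survives` (logical),
#'   `far_rate`, `beta_centre` (named coefficient vector at the centre).
#' @export
implant_recovery_run <- function(seed, amplitude = 1,
                                 implant_phone = "m",
                                 implant_feature = "nasal",
                                 q = 0.95, far_mm = 60,
                                 n_conditions = 16, n_subjects = 2,
                                 grid_dims = c(5, 5, 3),
                                 grid_spacing_mm = 15,
                                 n_perm = 140,
                                 cfg = searchlight_config()) {
  fm <- recovery_feature_matrix()
  centre <- "v0001"
  implants <- list(list(centre = centre, source = implant_phone,
                        amplitude = amplitude))
  sc <- simulation_scaffold(seed, fm$phones, n_conditions, 3, grid_dims,
                            grid_spacing_mm, n_subjects, 1, implants, cfg)
  dd <- build_data_drdms(sc$epochs, sc$mesh, cfg)
  fit <- fit_drdms(dd, sc$model_set)
  eb <- epoch_average_betas(fit)
  top <- names(which.max(eb$betas[, centre])) == implant_phone
  fits <- suppressWarnings(feature_fit_map(fit, fm))
  nulls <- suppressWarnings(build_null(dd, sc$model_set, fm,
                                       n_perm = n_perm, seed = seed + 1))
  th <- threshold_feature_maps(fits, nulls, q)
  tab <- th$table[th$table$feature == implant_feature, ]
  mesh <- sc$mesh
  dist0 <- sqrt((mesh$x_mm - mesh$x_mm[1])^2 + (mesh$y_mm - mesh$y_mm[1])^2 +
                  (mesh$z_mm - mesh$z_mm[1])^2)
  far <- mesh$vertex_id[dist0 >= far_mm]
  list(top_phone = top,
       centre_survives = tab$survives[tab$vertex_id == centre],
       far_rate = mean(tab$survives[tab$vertex_id %in% far]),
       beta_centre = eb$betas[, centre])
}
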