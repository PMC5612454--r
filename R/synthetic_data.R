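# Synthetic inputs with known ground truth.
#
# The generator emulates the three inputs the pipeline consumes: (1)
# triphone log-likelihood streams in which each condition's phone string is
# laid out over the epoch and the active triphone receives a high
# log-likelihood baseline; (2) a regular 3D grid standing in for a source
# mesh; (3) per-subject source epochs consisting of Gaussian background
# noise plus, at chosen patches, response structure whose condition-pair
# correlation geometry matches a chosen model RDM ("geometry injection").
# Because the implanted geometry is known exactly, searchlight + GLM
# recovery, spatial specificity and null calibration can all be scored.

#' Specification for synthetic data generation
#'
#' Defaults mirror the full-scale study conditions this pipeline targets:
#' 400 word conditions, 16 subjects, a 270 ms model epoch of 10 ms
#' likelihood frames, 1 ms source sampling and a 100 ms processing lag.
#' Validation suites run the same generator at reduced scale.
#'
#' @param n_conditions number of conditions (words).
#' @param inventory phone inventory for the synthetic lexicon.
#' @param phone_strings named list of per-condition phone strings (character
#'   vectors over the inventory); if NULL, random strings of
#'   `phones_per_word` phones are drawn.
#' @param phones_per_word length of generated phone strings.
#' @param epoch_ms,frame_ms model epoch and likelihood frame step (ms).
#' @param high_loglik,low_loglik log-likelihood baselines for the active
#'   versus inactive triphone columns.
#' @param loglik_noise_sd i.i.d. Gaussian noise added to every likelihood cell.
#' @param grid_dims integer 3-vector: synthetic mesh grid extent (vertices
#'   per axis).
#' @param grid_spacing_mm grid spacing in mm.
#' @param n_subjects number of subjects.
#' @param sample_ms source sampling step (ms).
#' @param noise_sd standard deviation of the source background noise.
#' @param implants list of implants, each `list(centre = <vertex id>,
#'   source = <phone or feature name>, amplitude = <effect size>)`;
#'   amplitude scales the implanted structure relative to unit-variance
#'   noise.
#' @param seed RNG seed (mandatory: generation is a pure function of the
#'   spec).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_conditions = 400,
                           inventory = c("p", "t", "k", "b", "d", "g", "s", "z",
                                         "m", "n", "l", "r", "aa", "eh", "ih", "uw"),
                           phone_strings = NULL,
                           phones_per_word = 3,
                           epoch_ms = 270, frame_ms = 10,
                           high_loglik = 0, low_loglik = -10,
                           loglik_noise_sd = 1,
                           grid_dims = c(8, 8, 4), grid_spacing_mm = 5,
                           n_subjects = 16, sample_ms = 1,
                           noise_sd = 1,
                           implants = list(),
                           seed) {
  if (missing(seed))
    ssrsa_error("synthetic_spec requires an explicit seed", "ssrsa_invalid_input")
  for (imp in implants) {
    if (is.null(imp$centre) || is.null(imp$source))
      ssrsa_error("each implant needs a centre vertex and a source model",
                  "ssrsa_invalid_input")
    if (!is.null(imp$amplitude) && imp$amplitude < 0)
      ssrsa_error("implant amplitudes must be >= 0", "ssrsa_invalid_input")
  }
  if (!is.null(phone_strings)) {
    bad <- setdiff(unique(unlist(phone_strings)), inventory)
    if (length(bad) > 0)
      ssrsa_error(sprintf("phone string symbols not in inventory: %s",
                          paste(bad, collapse = ", ")), "ssrsa_invalid_input")
    n_conditions <- length(phone_strings)
  }
  structure(list(n_conditions = n_conditions, inventory = inventory,
                 phone_strings = phone_strings,
                 phones_per_word = phones_per_word,
                 epoch_ms = epoch_ms, frame_ms = frame_ms,
                 high_loglik = high_loglik, low_loglik = low_loglik,
                 loglik_noise_sd = loglik_noise_sd,
                 grid_dims = grid_dims, grid_spacing_mm = grid_spacing_mm,
                 n_subjects = n_subjects, sample_ms = sample_ms,
                 noise_sd = noise_sd, implants = implants, seed = seed),
            class = "synthetic_spec")
}

#' Read / write a synthetic spec as YAML
#' @param spec a `synthetic_spec`.
#' @param path YAML file path.
#' @return `path` invisibly (write); a `synthetic_spec` (read).
#' @export
write_synthetic_yaml <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_synthetic_yaml
#' @export
read_synthetic_yaml <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(synthetic_spec, v[!vapply(v, is.null, TRUE)])
}

# Lay a phone string over n_frames in equal-duration segments; returns for
# each frame the (left, centre, right) active triphone, with the string's
# own edge phone reused as context at the boundaries.
align_phone_string <- function(phones, n_frames) {
  k <- length(phones)
  seg <- ceiling(seq_len(n_frames) / (n_frames / k))
  seg[seg > k] <- k
  left <- phones[pmax(seg - 1, 1)]
  right <- phones[pmin(seg + 1, k)]
  data.frame(frame = seq_len(n_frames), left = left, centre = phones[seg],
             right = right, stringsAsFactors = FALSE)
}

#' Generate synthetic triphone likelihood streams
#'
#' Every condition's phone string is laid over the epoch in equal-duration
#' segments. The triphone column matching the frame's active
#' (previous, current, next) phones receives the high baseline, all others
#' the low baseline, plus i.i.d. Gaussian noise. Conditions sharing a
#' centre phone in a window are therefore more correlated within that
#' phone's column group, which is the block structure the model RDMs are
#' built to expose.
#'
#' @param spec a `synthetic_spec`.
#' @return list: `streams` (a `likelihood_streams`), `truth` (per-condition
#'   phone alignment and the phone strings used).
#' @export
gen_likelihood_streams <- function(spec) {
  n_frames <- spec$epoch_ms / spec$frame_ms
  with_seed(spec$seed, {
    strings <- spec$phone_strings
    if (is.null(strings)) {
      strings <- lapply(seq_len(spec$n_conditions), function(i)
        sample(spec$inventory, spec$phones_per_word, replace = TRUE))
      names(strings) <- sprintf("w%03d", seq_len(spec$n_conditions))
    }
    if (is.null(names(strings)))
      names(strings) <- sprintf("w%03d", seq_along(strings))
    aligns <- lapply(strings, align_phone_string, n_frames = n_frames)
    tri_lab <- sort(unique(unlist(lapply(aligns, function(a)
      paste0(a$left, "-", a$centre, "+", a$right)))))
    parts <- do.call(rbind, strsplit(tri_lab, "[-+]"))
    tt <- triphone_table(parts[, 1], parts[, 2], parts[, 3], spec$inventory)
    streams <- lapply(names(strings), function(cond) {
      a <- aligns[[cond]]
      m <- matrix(spec$low_loglik, n_frames, length(tri_lab),
                  dimnames = list(NULL, tri_lab))
      active <- match(paste0(a$left, "-", a$centre, "+", a$right), tri_lab)
      m[cbind(a$frame, active)] <- spec$high_loglik
      m + matrix(stats::rnorm(length(m), 0, spec$loglik_noise_sd),
                 nrow(m), ncol(m))
    })
    names(streams) <- names(strings)
    list(streams = likelihood_streams(streams, tt, spec$frame_ms),
         truth = list(phone_strings = strings, alignment = aligns))
  })
}

#' Responses realising a target correlation geometry
#'
#' Converts a target RDM to similarities S = 1 - target, projects S onto
#' the positive semidefinite cone (eigenvalue clipping at zero), factors the
#' projection as L L', and returns X = L G with G an r x m standard
#' Gaussian matrix. Rows of X then have covariance (approximately) S, so
#' their empirical pairwise correlation RDM converges to the target as m
#' grows.
#'
#' @param target an `rdm` with entries in [0, 2].
#' @param m number of response columns.
#' @param seed RNG seed.
#' @return condition x m numeric matrix, rownames = conditions.
#' @export
embed_target_rdm <- function(target, m, seed) {
  if (m < 3)
    ssrsa_error("need m >= 3 response columns", "ssrsa_invalid_input")
  tv <- unclass(target)
  if (min(tv) < -1e-9 || max(tv) > 2 + 1e-9)
    ssrsa_error("target RDM entries must lie in [0, 2]", "ssrsa_invalid_input")
  S <- 1 - tv
  diag(S) <- 1
  eg <- eigen(S, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  L <- eg$vectors %*% diag(sqrt(d), length(d))
  X <- with_seed(seed, L %*% matrix(stats::rnorm(length(d) * m), length(d), m))
  rownames(X) <- rownames(tv)
  X
}

#' Build the synthetic source mesh grid
#'
#' A regular 3D millimetre grid; Euclidean patch geometry is all the
#' searchlight needs, so no cortical surface is simulated.
#'
#' @param spec a `synthetic_spec`.
#' @return a `source_mesh` with ids "v<index>" in grid (x fastest) order.
#' @export
gen_mesh <- function(spec) {
  g <- expand.grid(x = seq_len(spec$grid_dims[1]),
                   y = seq_len(spec$grid_dims[2]),
                   z = seq_len(spec$grid_dims[3]))
  source_mesh(sprintf("v%04d", seq_len(nrow(g))),
              g$x * spec$grid_spacing_mm,
              g$y * spec$grid_spacing_mm,
              g$z * spec$grid_spacing_mm,
              hemisphere = "lh", in_mask = TRUE)
}

# Resolve an implant's source model to a target dRDM: a phone's dRDM, or for
# a feature name the entrywise average of the feature's phone dRDMs.
implant_target_drdm <- function(source, model_set, fm = NULL) {
  if (source %in% model_set$phones) return(model_set$drdms[[source]])
  if (!is.null(fm) && source %in% fm$features) {
    carriers <- intersect(fm$phones[fm$indicator[source, ] == 1],
                          model_set$phones)
    if (length(carriers) == 0)
      ssrsa_error(sprintf("feature '%s' has no modelled phones", source),
                  "ssrsa_invalid_input")
    n_win <- length(model_set$drdms[[1]]$frames)
    frames <- lapply(seq_len(n_win), function(w)
      average_rdms(lapply(carriers, function(ph) model_set$drdms[[ph]]$frames[[w]])))
    return(dynamic_rdm(frames, model_set$drdms[[1]]$window_ms,
                       model_set$drdms[[1]]$step_ms,
                       model_set$drdms[[1]]$onsets_ms))
  }
  ssrsa_error(sprintf("implant source '%s' is neither a modelled phone nor a feature",
                      source), "ssrsa_invalid_input")
}

#' Generate synthetic source epochs with implanted geometry
#'
#' The mesh is a regular grid; every epoch is i.i.d. Gaussian background
#' noise. For each implant and each model window position, responses whose
#' pairwise correlation geometry matches that window's target model RDM are
#' added (scaled by the implant amplitude) to the implant patch over the
#' lagged window samples. Implant structure is shared across subjects;
#' noise is independent per subject. Epoch time runs from 0 to
#' `epoch_ms + lag_ms` so every lagged window fits.
#'
#' @param spec a `synthetic_spec`.
#' @param model_set a `phone_model_set` supplying the target dRDMs.
#' @param cfg a `searchlight_config` (window geometry, lag, patch radius).
#' @param fm optional `feature_matrix`, needed for feature-named implants.
#' @return list: `epochs` (a `source_epochs`), `mesh` (a `source_mesh`),
#'   `truth` (per implant: centre, patch members, source, amplitude).
#' @export
gen_source_epochs <- function(spec, model_set, cfg, fm = NULL) {
  mesh <- gen_mesh(spec)
  conds <- rdm_conditions(model_set$drdms[[1]])
  onsets <- config_window_onsets(cfg)
  nsamp_win <- round(cfg$window_ms / spec$sample_ms)
  n_samples <- round((spec$epoch_ms + cfg$lag_ms) / spec$sample_ms)
  n_vert <- nrow(mesh)
  # resolve implants and reject overlapping patches (ambiguous ground truth)
  implants <- lapply(spec$implants, function(imp) {
    patch <- patch_members(mesh, imp$centre, cfg$radius_mm)
    list(centre = imp$centre, patch = patch, source = imp$source,
         amplitude = if (is.null(imp$amplitude)) 1 else imp$amplitude,
         drdm = implant_target_drdm(imp$source, model_set, fm))
  })
  if (length(implants) > 1) {
    for (i in seq_along(implants)[-1])
      for (j in seq_len(i - 1))
        if (length(intersect(implants[[i]]$patch, implants[[j]]$patch)) > 0)
          ssrsa_error("implant patches overlap: ground truth would be ambiguous",
                      "ssrsa_invalid_input")
  }
  # shared implant signal, built once per (implant, window)
  signal <- lapply(seq_along(implants), function(k) {
    imp <- implants[[k]]
    rows <- match(imp$patch, mesh$vertex_id)
    lapply(seq_along(onsets), function(w) {
      target <- imp$drdm$frames[[w]]
      X <- embed_target_rdm(target, length(rows) * nsamp_win,
                            seed = (spec$seed + 7919L * k + w) %% .Machine$integer.max)
      list(rows = rows, onset = onsets[w], X = X * imp$amplitude)
    })
  })
  subjects <- sprintf("s%02d", seq_len(spec$n_subjects))
  epochs <- with_seed(spec$seed + 104729L, {
    lapply(subjects, function(subj) {
      per_cond <- lapply(conds, function(cond) {
        m <- matrix(stats::rnorm(n_vert * n_samples, 0, spec$noise_sd),
                    n_vert, n_samples)
        ci <- match(cond, conds)
        for (k in seq_along(implants)) {
          for (sw in signal[[k]]) {
            first <- round((sw$onset + cfg$lag_ms) / spec$sample_ms) + 1
            block <- matrix(sw$X[ci, ], length(sw$rows), nsamp_win, byrow = TRUE)
            m[sw$rows, first:(first + nsamp_win - 1)] <-
              m[sw$rows, first:(first + nsamp_win - 1)] + block
          }
        }
        m
      })
      names(per_cond) <- conds
      per_cond
    })
  })
  names(epochs) <- subjects
  truth <- lapply(implants, function(imp)
    imp[c("centre", "patch", "source", "amplitude")])
  list(epochs = source_epochs(epochs, mesh$vertex_id, spec$sample_ms, t0_ms = 0),
       mesh = mesh, truth = truth)
}
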