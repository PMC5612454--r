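# Permutation null for feature fits and quantile thresholding.
#
# Under the null hypothesis that no phonetic information distinguishes the
# conditions' neural responses, the condition labels of a data RDM are
# exchangeable: permuting its rows and columns by one random relabelling
# (models untouched) and refitting the GLM simulates a draw from the null.
# Feature fits from permuted fits are pooled over all masked vertices and
# iterations into one null distribution per feature -- separate per feature
# because different numbers of phones contribute to each -- and the
# empirical q-quantile of that pool is the feature's significance threshold
# theta_f. Observed fit maps are thresholded at fit > theta_f.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  force(expr)
}

#' Permute the conditions of an RDM
#'
#' Reindexes rows and columns by one permutation, so position k of the
#' result holds original condition `perm[k]`. Symmetry and the zero
#' diagonal are preserved by construction.
#'
#' @param x an `rdm`.
#' @param perm integer permutation of `seq_len(n)` or a permutation of the
#'   condition labels.
#' @return an `rdm` (condition labels keep their original order; the values
#'   are relabelled).
#' @export
permute_conditions <- function(x, perm) {
  conds <- rdm_conditions(x)
  n <- length(conds)
  if (is.character(perm)) perm <- match(perm, conds)
  perm <- as.integer(perm)
  if (length(perm) != n || anyNA(perm) || !setequal(perm, seq_len(n)))
    ssrsa_error("perm must be a permutation of the conditions",
                "ssrsa_invalid_input")
  rdm(unclass(x)[perm, perm], conds)
}

# Index vector idx with utv(permute_conditions(r, perm)) == utv(r)[idx].
# Precomputing it lets the permutation null reindex vectorized RDMs without
# rebuilding matrices.
utv_permutation_index <- function(perm, n) {
  pair_id <- matrix(0L, n, n)
  pr <- upper_triangle_pairs(n)
  pair_id[pr] <- seq_len(nrow(pr))
  pair_id[pr[, c(2, 1)]] <- seq_len(nrow(pr))
  pair_id[cbind(perm[pr[, 1]], perm[pr[, 2]])]
}

#' Feature fit map from epoch-averaged coefficients
#'
#' @param fit a `glm_fit_map` (fits at every window; coefficients are
#'   epoch-averaged first) or the output of [epoch_average_betas()].
#' @param fm a `feature_matrix`.
#' @return feature x vertex numeric matrix of fits.
#' @export
feature_fit_map <- function(fit, fm) {
  if (inherits(fit, "glm_fit_map")) fit <- epoch_average_betas(fit)
  betas <- fit$betas
  common <- intersect(fm$phones, rownames(betas))
  absent <- setdiff(fm$phones, rownames(betas))
  if (length(absent) > 0)
    warning(sprintf("no coefficient for phone(s) %s: contributing 0",
                    paste(absent, collapse = ", ")))
  b <- matrix(0, length(fm$phones), ncol(betas),
              dimnames = list(fm$phones, colnames(betas)))
  b[common, ] <- betas[common, , drop = FALSE]
  fm$indicator %*% b
}

#' Build per-feature permutation null distributions
#'
#' Each iteration draws one random condition permutation and applies it to
#' every vertex's data RDMs (one shared permutation per iteration, keeping
#' the spatial structure of the null exchangeable with the observed maps;
#' set `per_vertex_perms = TRUE` for independent per-vertex permutations).
#' The GLM is refitted, coefficients are epoch-averaged, feature fits
#' recomputed, and the values pooled over vertices and iterations.
#'
#' @param data_drdms named list (by vertex) of `dynamic_rdm`.
#' @param model_set a `phone_model_set`.
#' @param fm a `feature_matrix`.
#' @param n_perm number of permutation iterations; aim for
#'   `n_perm * n_vertices >= 10000` pooled samples per feature (a smaller
#'   pool warns).
#' @param seed RNG seed (required: nulls must be reproducible).
#' @param per_vertex_perms draw an independent permutation per vertex.
#' @return named list (by feature) of `null_distribution` objects: `samples`
#'   (pooled null fits), `n_perm`, `n_vertices`.
#' @export
build_null <- function(data_drdms, model_set, fm, n_perm, seed,
                       per_vertex_perms = FALSE) {
  if (n_perm < 1)
    ssrsa_error("n_perm must be >= 1", "ssrsa_invalid_input")
  vertices <- names(data_drdms)
  n_vert <- length(vertices)
  if (n_perm * n_vert < 10000)
    warning(sprintf(
      "null pool has %d samples per feature (< 10000): thresholds will be noisy",
      n_perm * n_vert))
  conds <- rdm_conditions(data_drdms[[1]])
  n <- length(conds)
  n_win <- length(data_drdms[[1]]$frames)
  # precompute per-window pseudoinverse operators and data vectors
  pinvs <- vector("list", n_win)
  Ys <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    X <- glm_design(lapply(model_set$drdms, function(d) d$frames[[w]]))
    sv <- svd(X)
    tol <- max(dim(X)) * .Machine$double.eps * max(sv$d)
    pos <- sv$d > tol
    pinvs[[w]] <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    Ys[[w]] <- sapply(data_drdms, function(d) upper_triangle_vector(d$frames[[w]]))
  }
  phones <- model_set$phones
  ind <- matrix(0, length(fm$features), length(phones),
                dimnames = list(fm$features, phones))
  common <- intersect(fm$phones, phones)
  ind[, common] <- fm$indicator[, common]
  samples <- array(NA_real_, c(length(fm$features), n_vert, n_perm),
                   dimnames = list(fm$features, vertices, NULL))
  with_seed(seed, {
    for (it in seq_len(n_perm)) {
      if (per_vertex_perms) {
        idx <- sapply(seq_len(n_vert), function(v)
          utv_permutation_index(sample.int(n), n))
        beta_sum <- 0
        for (w in seq_len(n_win)) {
          Yp <- Ys[[w]][cbind(as.vector(idx),
                              rep(seq_len(n_vert), each = nrow(idx)))]
          dim(Yp) <- dim(Ys[[w]])
          beta_sum <- beta_sum + pinvs[[w]] %*% Yp
        }
      } else {
        idx <- utv_permutation_index(sample.int(n), n)
        beta_sum <- 0
        for (w in seq_len(n_win))
          beta_sum <- beta_sum + pinvs[[w]] %*% Ys[[w]][idx, , drop = FALSE]
      }
      beta_avg <- (beta_sum / n_win)[-1, , drop = FALSE]  # drop intercept
      rownames(beta_avg) <- phones
      samples[, , it] <- ind %*% beta_avg
    }
  })
  out <- lapply(fm$features, function(f)
    structure(list(feature = f, samples = as.vector(samples[f, , ]),
                   n_perm = n_perm, n_vertices = n_vert),
              class = "null_distribution"))
  names(out) <- fm$features
  out
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null distribution for '%s': %d samples (%d perms x %d vertices)\n",
              x$feature, length(x$samples), x$n_perm, x$n_vertices))
  invisible(x)
}

#' Per-feature null quantile threshold
#'
#' Empirical order-statistic quantile (inverted-CDF, type 1) of the pooled
#' null: conservative for thresholds on large pooled samples.
#'
#' @param null a `null_distribution`.
#' @param q quantile in (0, 1).
#' @return the threshold theta_f.
#' @export
null_threshold <- function(null, q) {
  if (length(null$samples) == 0)
    ssrsa_error("empty null distribution", "ssrsa_invalid_input")
  if (q <= 0 || q >= 1)
    ssrsa_error("quantile must be in (0, 1)", "ssrsa_invalid_input")
  unname(stats::quantile(null$samples, q, type = 1))
}

#' Threshold feature fit maps against their permutation nulls
#'
#' For each feature, theta_f is the q-quantile of its pooled null and the
#' surviving set is the vertices with fit strictly above theta_f. The
#' summary additionally reports, per feature, the most conservative
#' standard quantile (largest of 0.95, 0.99, 0.999) at which any vertex
#' still survives.
#'
#' @param fits feature x vertex matrix from [feature_fit_map()].
#' @param nulls named list of `null_distribution` from [build_null()].
#' @param q quantile for the working threshold (default 0.95).
#' @param report_quantiles quantile ladder for the per-feature
#'   most-conservative-survival report.
#' @return object of class `thresholded_maps`: `table` (long data.frame:
#'   vertex_id, feature, fit, threshold, quantile, survives) and `summary`
#'   (per feature: threshold, n_surviving, best_quantile).
#' @export
threshold_feature_maps <- function(fits, nulls, q = 0.95,
                                   report_quantiles = c(0.95, 0.99, 0.999)) {
  feats <- rownames(fits)
  missing <- setdiff(feats, names(nulls))
  if (length(missing) > 0)
    ssrsa_error(sprintf("no null distribution for feature(s): %s",
                        paste(missing, collapse = ", ")), "ssrsa_invalid_input")
  tab <- do.call(rbind, lapply(feats, function(f) {
    th <- null_threshold(nulls[[f]], q)
    data.frame(vertex_id = colnames(fits), feature = f,
               fit = fits[f, ], threshold = th, quantile = q,
               survives = fits[f, ] > th, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  summary <- do.call(rbind, lapply(feats, function(f) {
    th <- null_threshold(nulls[[f]], q)
    best <- NA_real_
    for (qq in sort(report_quantiles)) {
      if (any(fits[f, ] > null_threshold(nulls[[f]], qq))) best <- qq
    }
    data.frame(feature = f, threshold = th, quantile = q,
               n_surviving = sum(fits[f, ] > th),
               best_quantile = best, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, summary = summary), class = "thresholded_maps")
}

#' @export
print.thresholded_maps <- function(x, ...) {
  surv <- x$summary[x$summary$n_surviving > 0, ]
  cat(sprintf("thresholded feature maps: %d features, %d with surviving vertices at q=%.3g\n",
              nrow(x$summary), nrow(surv), x$summary$quantile[1]))
  invisible(x)
}

#' Write thresholded maps as TSV
#' @param maps a `thresholded_maps`.
#' @param path TSV file path.
#' @return `path`, invisibly.
#' @export
write_threshold_tsv <- function(maps, path) {
  utils::write.table(maps$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
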