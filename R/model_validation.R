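# Second-order analysis of the phone model space.
#
# Before fitting phone models to brain data it is worth asking whether the
# articulatory feature system actually describes the geometry of the model
# space itself: models of phones sharing a feature should have similar RDMs.
# The diagnostics here operate on the model-by-model Spearman similarity
# matrix at each window position: a Davies-Bouldin index for the 2-cluster
# split induced by each feature, a distance-based eta-squared (share of
# pairwise dissimilarity variance explained by the split), and a non-metric
# MDS embedding for visual inspection.

#' Second-order model similarity matrix at one window position
#'
#' Entry (i, j) is the Spearman rank correlation between the upper-triangle
#' vectors of model i's and model j's RDM frames at the given window. The
#' associated distance form is 1 - rho.
#'
#' @param model_set a `phone_model_set`.
#' @param window_index window position (1-based).
#' @return object of class `second_order_matrix`: list with `rho` (symmetric
#'   matrix, unit diagonal), `models`, `window_index`.
#' @export
second_order_matrix <- function(model_set, window_index) {
  phones <- model_set$phones
  if (length(phones) < 2)
    ssrsa_error("need at least 2 models for a second-order matrix",
                "ssrsa_invalid_input")
  utvs <- sapply(phones, function(ph) {
    fr <- model_set$drdms[[ph]]$frames[[window_index]]
    v <- upper_triangle_vector(fr)
    if (stats::sd(v) == 0)
      ssrsa_error(sprintf("constant model RDM frame for phone '%s' at window %d",
                          ph, window_index), "ssrsa_degenerate_input")
    v
  })
  rho <- stats::cor(utvs, method = "spearman")
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  structure(list(rho = rho, models = phones, window_index = window_index),
            class = "second_order_matrix")
}

#' @export
print.second_order_matrix <- function(x, ...) {
  cat(sprintf("second-order model similarity: %d x %d (window %d), rho in [%.3f, 1]\n",
              length(x$models), length(x$models), x$window_index, min(x$rho)))
  invisible(x)
}

#' Davies-Bouldin index for a binary labelling of points
#'
#' For the two clusters induced by a binary feature: (s1 + s2) / d12, where
#' s_g is the mean Euclidean distance of cluster g's points to their
#' centroid and d12 the distance between the two centroids. Lower values
#' mean better-separated clusters. Values are only comparable between
#' labellings of the same point set.
#'
#' @param points numeric matrix, one row per model.
#' @param labels logical or 0/1 vector, one per row.
#' @param feature optional feature name for error messages.
#' @return the index (numeric scalar >= 0).
#' @export
davies_bouldin <- function(points, labels, feature = "feature") {
  points <- as.matrix(points)
  labels <- as.logical(labels)
  if (length(labels) != nrow(points))
    ssrsa_error("one label per point required", "ssrsa_invalid_input")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 < 2 || n0 < 2)
    ssrsa_error(sprintf(
      "'%s' splits the models %d/%d: both classes need >= 2 members for within-cluster dispersion",
      feature, n1, n0), "ssrsa_invalid_input")
  centroid <- function(m) colMeans(m)
  disp <- function(m, c0) mean(sqrt(rowSums(sweep(m, 2, c0)^2)))
  c1 <- centroid(points[labels, , drop = FALSE])
  c0 <- centroid(points[!labels, , drop = FALSE])
  d12 <- sqrt(sum((c1 - c0)^2))
  if (d12 == 0)
    ssrsa_error(sprintf("'%s': coincident cluster centroids", feature),
                "ssrsa_degenerate_input")
  (disp(points[labels, , drop = FALSE], c1) +
     disp(points[!labels, , drop = FALSE], c0)) / d12
}

#' Distance-based eta-squared for a binary labelling
#'
#' Share of pairwise squared-dissimilarity variance explained by the split:
#' SS_total = (1/N) * sum over all pairs of d^2; SS_within = sum over groups
#' g of (1/n_g) * sum over within-group pairs of d^2; eta^2 = (SS_total -
#' SS_within) / SS_total, clipped to [0, 1]. Conventional effect-size
#' benchmarks are 0.01 / 0.06 / 0.14 (small / medium / large).
#'
#' @param distances symmetric model x model dissimilarity matrix.
#' @param labels logical or 0/1 vector.
#' @param feature optional feature name for error messages.
#' @return eta-squared in [0, 1].
#' @export
eta_squared <- function(distances, labels, feature = "feature") {
  distances <- as.matrix(distances)
  labels <- as.logical(labels)
  n <- nrow(distances)
  if (length(labels) != n)
    ssrsa_error("one label per model required", "ssrsa_invalid_input")
  if (sum(labels) == 0 || sum(!labels) == 0)
    ssrsa_error(sprintf("'%s': a class is empty", feature), "ssrsa_invalid_input")
  d2 <- distances^2
  ss_total <- sum(d2[lower.tri(d2)]) / n
  ss_within <- 0
  for (g in c(TRUE, FALSE)) {
    idx <- which(labels == g)
    if (length(idx) >= 2) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[lower.tri(sub)]) / length(idx)
    }
  }
  if (ss_total == 0) {
    warning(sprintf("'%s': all models coincide; eta-squared defined as 0", feature))
    return(0)
  }
  min(max((ss_total - ss_within) / ss_total, 0), 1)
}

#' Rank-transformed model coordinates for cluster diagnostics
#'
#' Represents each model by the rank transform of its RDM frame's
#' upper-triangle vector, so Euclidean geometry on the points matches the
#' Spearman geometry of the second-order matrix.
#'
#' @param model_set a `phone_model_set`.
#' @param window_index window position.
#' @param rank_transform if FALSE, use the raw upper-triangle vectors.
#' @return numeric matrix, one row per model.
#' @export
model_points <- function(model_set, window_index, rank_transform = TRUE) {
  pts <- t(sapply(model_set$phones, function(ph) {
    v <- upper_triangle_vector(model_set$drdms[[ph]]$frames[[window_index]])
    if (rank_transform) rank(v) else v
  }))
  rownames(pts) <- model_set$phones
  pts
}

#' Per-feature cluster diagnostics across the epoch
#'
#' For every feature whose split of the modelled phones has >= 2 members on
#' each side, computes the Davies-Bouldin index and eta-squared at each
#' window position, then summarises by mean and standard deviation over the
#' epoch.
#'
#' @param model_set a `phone_model_set`.
#' @param fm a `feature_matrix`.
#' @param windows window indices to evaluate (default: all).
#' @param rank_transform passed to [model_points()].
#' @return data.frame: feature, category, n_in, n_out, db_index_mean,
#'   db_index_sd, eta_sq_mean, eta_sq_sd; attribute `per_window` holds the
#'   full per-window values.
#' @export
feature_cluster_diagnostics <- function(model_set, fm,
                                        windows = seq_along(model_set$onsets_ms),
                                        rank_transform = TRUE) {
  phones <- model_set$phones
  usable <- Filter(function(f) {
    lab <- fm$indicator[f, phones]
    sum(lab == 1) >= 2 && sum(lab == 0) >= 2
  }, intersect(fm$features, fm$features[apply(
    fm$indicator[, phones, drop = FALSE], 1, function(r) any(r == 1) && any(r == 0))]))
  if (length(usable) == 0)
    ssrsa_error("no feature splits the modelled phones with >= 2 per class",
                "ssrsa_invalid_input")
  per_window <- lapply(windows, function(w) {
    pts <- model_points(model_set, w, rank_transform)
    som <- second_order_matrix(model_set, w)
    dist2 <- 1 - som$rho
    t(sapply(usable, function(f) {
      lab <- fm$indicator[f, phones] == 1
      c(db = davies_bouldin(pts, lab, f), eta = eta_squared(dist2, lab, f))
    }))
  })
  db <- sapply(per_window, function(m) m[, "db"])
  eta <- sapply(per_window, function(m) m[, "eta"])
  if (length(usable) == 1) { db <- t(db); eta <- t(eta) }
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  out <- data.frame(
    feature = usable,
    category = unname(fm$categories[usable]),
    n_in = vapply(usable, function(f) sum(fm$indicator[f, phones] == 1), 0L),
    n_out = vapply(usable, function(f) sum(fm$indicator[f, phones] == 0), 0L),
    db_index_mean = rowMeans(as.matrix(db)),
    db_index_sd = apply(as.matrix(db), 1, sd0),
    eta_sq_mean = rowMeans(as.matrix(eta)),
    eta_sq_sd = apply(as.matrix(eta), 1, sd0),
    row.names = NULL)
  attr(out, "per_window") <- list(db = db, eta = eta, windows = windows)
  out
}

#' Non-metric MDS embedding of a model dissimilarity matrix
#'
#' Embeds the models in `dim` dimensions by stress minimisation
#' (Kruskal's non-metric MDS, classical-scaling and random restarts; the
#' lowest-stress solution wins) and reports the Pearson correlation between
#' embedded pairwise distances and the input dissimilarities. The
#' correlation quantifies how faithful the low-dimensional picture is; it is
#' reported, never a pass/fail statistic.
#'
#' @param distances symmetric dissimilarity matrix (e.g. 1 - rho from
#'   [second_order_matrix()]).
#' @param dim embedding dimensionality.
#' @param n_restarts random restarts in addition to the classical-scaling
#'   initialisation.
#' @param seed RNG seed for the restarts.
#' @return list: `coordinates` (model x dim), `distance_dissimilarity_correlation`,
#'   `stress` (Kruskal stress, percent).
#' @export
mds_embed <- function(distances, dim = 2, n_restarts = 4, seed = 1) {
  d <- as.matrix(distances)
  if (nrow(d) < dim + 1)
    ssrsa_error("need more models than embedding dimensions", "ssrsa_invalid_input")
  # isoMDS requires strictly positive off-diagonal dissimilarities
  off <- d[lower.tri(d)]
  eps <- max(off) * 1e-6
  if (any(off <= 0)) {
    warning("non-positive dissimilarities nudged to a small epsilon for MDS")
    d[d <= 0] <- eps
    diag(d) <- 0
  }
  dd <- stats::as.dist(d)
  fits <- list()
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  # classical-scaling start, padded with tiny jitter when the input spans
  # fewer than `dim` dimensions (isoMDS needs a full-rank configuration)
  init0 <- suppressWarnings(stats::cmdscale(dd, k = dim))
  if (ncol(init0) < dim)
    init0 <- cbind(init0, matrix(stats::rnorm(nrow(d) * (dim - ncol(init0)),
                                              0, max(abs(init0)) * 1e-4),
                                 nrow(d)))
  fits[[1]] <- tryCatch(MASS::isoMDS(dd, y = init0, k = dim, trace = FALSE),
                        error = function(e) NULL)
  for (r in seq_len(n_restarts)) {
    init <- matrix(stats::rnorm(nrow(d) * dim), nrow(d), dim)
    fits[[r + 1]] <- tryCatch(MASS::isoMDS(dd, y = init, k = dim, trace = FALSE),
                              error = function(e) NULL)
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0)
    ssrsa_error("MDS failed to converge from any initialisation",
                "ssrsa_mds_failure")
  cors <- vapply(fits, function(f) {
    emb <- as.matrix(stats::dist(f$points))
    stats::cor(emb[lower.tri(emb)], d[lower.tri(d)])
  }, 0)
  stresses <- vapply(fits, function(f) f$stress, 0)
  # non-metric stress only constrains ranks: among (near-)equal-stress
  # solutions prefer the most linear distance-dissimilarity relation
  near <- which(stresses <= min(stresses) + 1e-6)
  best <- near[which.max(cors[near])]
  coords <- fits[[best]]$points
  rownames(coords) <- rownames(d)
  list(coordinates = coords,
       distance_dissimilarity_correlation = cors[best],
       stress = stresses[best])
}
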