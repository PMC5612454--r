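# Core RDM primitives: construction, vectorization, comparison.
#
# An `rdm` is a symmetric numeric matrix with a zero diagonal whose rows and
# columns are indexed by condition labels (the experimental stimuli, e.g.
# words). Correlation-distance RDMs have entries in [0, 2]. These objects are
# the common currency of every downstream stage: model streams, searchlight
# data streams, GLM fitting and permutation statistics all consume and
# produce them.

ssrsa_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ssrsa_error")))
}

#' Validate a set of condition labels
#'
#' Conditions index the rows/columns of every RDM in an analysis. Labels must
#' be unique and there must be at least 3 of them (correlation distance needs
#' response vectors of length >= 3 elsewhere in the pipeline, and permutation
#' nulls need a non-trivial number of relabellings). Fewer than 10 conditions
#' triggers a warning: the analysis runs, but rank statistics and permutation
#' nulls become coarse.
#'
#' @param labels character vector of condition identifiers.
#' @return the validated labels, as character.
#' @export
condition_set <- function(labels) {
  labels <- as.character(labels)
  if (anyDuplicated(labels))
    ssrsa_error("condition labels must be unique", "ssrsa_invalid_conditions")
  n <- length(labels)
  if (n < 3)
    ssrsa_error(sprintf("need at least 3 conditions, got %d", n),
                "ssrsa_invalid_conditions")
  if (n < 10)
    warning(sprintf("only %d conditions: rank statistics and permutation nulls will be coarse", n))
  labels
}

#' Construct an RDM from a dissimilarity matrix
#'
#' @param values symmetric numeric matrix with zero diagonal.
#' @param conditions condition labels (defaults to the matrix dimnames).
#' @param check_range if TRUE, require entries in [0, 2] (the range of
#'   correlation distances).
#' @return an object of class `rdm`: the matrix with condition dimnames.
#' @export
rdm <- function(values, conditions = rownames(values), check_range = FALSE) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n)
    ssrsa_error("RDM must be square", "ssrsa_invalid_rdm")
  if (is.null(conditions)) conditions <- paste0("cond", seq_len(n))
  conditions <- suppressWarnings(condition_set(conditions))
  if (length(conditions) != n)
    ssrsa_error("condition labels do not match matrix size", "ssrsa_invalid_rdm")
  if (!all(is.finite(values)))
    ssrsa_error("RDM entries must be finite", "ssrsa_invalid_rdm")
  if (max(abs(values - t(values))) > 1e-8)
    ssrsa_error("RDM must be symmetric", "ssrsa_invalid_rdm")
  if (max(abs(diag(values))) > 1e-12)
    ssrsa_error("RDM diagonal must be zero", "ssrsa_invalid_rdm")
  if (check_range && (min(values) < -1e-12 || max(values) > 2 + 1e-12))
    ssrsa_error("correlation-distance RDM entries must lie in [0, 2]",
                "ssrsa_invalid_rdm")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  dimnames(values) <- list(conditions, conditions)
  class(values) <- c("rdm", class(values))
  values
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("RDM: %d conditions, entries in [%.4g, %.4g]\n",
              nrow(x), min(x), max(x)))
  invisible(x)
}

#' Condition labels of an RDM or dynamic RDM
#' @param x an `rdm` or `dynamic_rdm`.
#' @return character vector of condition labels.
#' @export
rdm_conditions <- function(x) {
  if (inherits(x, "dynamic_rdm")) return(rownames(x$frames[[1]]))
  rownames(x)
}

#' Correlation distance between two response vectors
#'
#' The dissimilarity used throughout the pipeline: 1 minus the Pearson
#' correlation, bounded in [0, 2]. Zero-variance inputs are an error rather
#' than a silent NaN: a degenerate response vector upstream would otherwise
#' corrupt GLM fits invisibly.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param what optional labels used in error messages to identify the inputs.
#' @return 1 - cor(x, y).
#' @export
correlation_distance <- function(x, y, what = c("x", "y")) {
  if (length(x) != length(y))
    ssrsa_error("vectors must have equal length", "ssrsa_invalid_input")
  if (length(x) < 3)
    ssrsa_error("correlation distance needs vectors of length >= 3",
                "ssrsa_invalid_input")
  for (i in 1:2) {
    v <- if (i == 1) x else y
    if (stats::sd(v) == 0)
      ssrsa_error(sprintf("zero-variance response vector: %s", what[i]),
                  "ssrsa_degenerate_input")
  }
  d <- 1 - stats::cor(x, y)
  min(max(d, 0), 2)
}

#' Build an RDM from a condition-by-feature response matrix
#'
#' Each row is one condition's response pattern; entry (i, j) of the result is
#' the correlation distance between rows i and j.
#'
#' @param responses numeric matrix, one row per condition, >= 3 columns.
#' @param conditions condition labels (defaults to rownames).
#' @return an `rdm`.
#' @export
rdm_from_response_matrix <- function(responses, conditions = rownames(responses)) {
  responses <- as.matrix(responses)
  n <- nrow(responses)
  if (is.null(conditions)) conditions <- paste0("cond", seq_len(n))
  if (ncol(responses) < 3)
    ssrsa_error("need >= 3 response features per condition", "ssrsa_invalid_input")
  sds <- apply(responses, 1, stats::sd)
  if (any(sds == 0))
    ssrsa_error(sprintf("constant response pattern for condition(s): %s",
                        paste(conditions[sds == 0], collapse = ", ")),
                "ssrsa_degenerate_input")
  d <- 1 - stats::cor(t(responses))
  d[d < 0] <- 0
  d[d > 2] <- 2
  diag(d) <- 0
  rdm(d, conditions)
}

#' Upper-triangle vectorization of an RDM
#'
#' Fixed row-major traversal of the strict upper triangle: (1,2), (1,3), ...,
#' (1,n), (2,3), ..., (n-1,n). Every vectorized RDM in the package (GLM
#' design columns, Spearman comparisons, permutation indexing) uses this one
#' order. Length is n(n-1)/2.
#'
#' @param x an `rdm` (or symmetric matrix).
#' @return numeric vector of length n(n-1)/2.
#' @export
upper_triangle_vector <- function(x) {
  x <- unclass(x)
  # for a symmetric matrix, column-major traversal of the strict lower
  # triangle visits exactly the row-major upper-triangle entries
  x[lower.tri(x)]
}

#' Pair indices matching [upper_triangle_vector()]
#'
#' @param n number of conditions.
#' @return integer matrix with columns i, j giving, for each vector element,
#'   the (row, column) condition pair it came from, in traversal order.
#' @export
upper_triangle_pairs <- function(n) {
  j <- rep(seq_len(n), each = n)[lower.tri(diag(n))]
  i <- rep(seq_len(n), times = n)[lower.tri(diag(n))]
  # lower.tri in column-major order yields (row > col); swap to (i < j)
  cbind(i = j, j = i)[order(j, i), , drop = FALSE]
}

#' Rebuild an RDM from its upper-triangle vector
#'
#' Inverse of [upper_triangle_vector()]; round-trips losslessly.
#'
#' @param values numeric vector of length n(n-1)/2.
#' @param conditions condition labels (length n).
#' @return an `rdm`.
#' @export
rdm_from_upper_triangle <- function(values, conditions) {
  n <- length(conditions)
  if (length(values) != n * (n - 1) / 2)
    ssrsa_error(sprintf("vector length %d does not match %d conditions",
                        length(values), n), "ssrsa_invalid_input")
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- values
  m <- m + t(m)
  rdm(m, conditions)
}

#' Spearman rank correlation between two RDMs
#'
#' The second-order similarity used to compare model RDMs with each other:
#' Spearman's rank correlation of the two upper-triangle vectors.
#'
#' @param a,b `rdm` objects over the same conditions.
#' @return correlation in [-1, 1].
#' @export
spearman_rdm_correlation <- function(a, b) {
  if (!identical(rdm_conditions(a), rdm_conditions(b)))
    ssrsa_error("RDMs must share one condition set", "ssrsa_invalid_input")
  va <- upper_triangle_vector(a)
  vb <- upper_triangle_vector(b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    ssrsa_error("constant upper-triangle vector: Spearman correlation undefined",
                "ssrsa_degenerate_input")
  stats::cor(va, vb, method = "spearman")
}

#' Entrywise average of RDMs
#'
#' Used to pool per-subject searchlight RDMs into one group RDM per vertex
#' and window. Symmetry and the zero diagonal are preserved exactly.
#'
#' @param rdms non-empty list of `rdm` objects over one condition set.
#' @return an `rdm`.
#' @export
average_rdms <- function(rdms) {
  if (length(rdms) == 0)
    ssrsa_error("cannot average an empty list of RDMs", "ssrsa_invalid_input")
  conds <- rdm_conditions(rdms[[1]])
  for (r in rdms)
    if (!identical(rdm_conditions(r), conds))
      ssrsa_error("all RDMs must share one condition set", "ssrsa_invalid_input")
  m <- Reduce(`+`, lapply(rdms, unclass)) / length(rdms)
  rdm(m, conds)
}

#' Construct a dynamic RDM (dRDM)
#'
#' A dRDM is a time-indexed sequence of RDMs, one per sliding-window
#' position, all over the same condition set. Both phone model streams and
#' per-vertex brain data streams are dRDMs.
#'
#' @param frames list of `rdm` objects, one per window position.
#' @param window_ms sliding-window width in ms.
#' @param step_ms window step in ms.
#' @param onsets_ms optional numeric vector of window onset times (ms).
#' @return an object of class `dynamic_rdm`.
#' @export
dynamic_rdm <- function(frames, window_ms, step_ms, onsets_ms = NULL) {
  if (length(frames) == 0)
    ssrsa_error("a dynamic RDM needs at least one frame", "ssrsa_invalid_input")
  conds <- rdm_conditions(frames[[1]])
  for (f in frames)
    if (!identical(rdm_conditions(f), conds))
      ssrsa_error("all dRDM frames must share one condition set",
                  "ssrsa_invalid_input")
  if (window_ms <= 0 || step_ms <= 0)
    ssrsa_error("window_ms and step_ms must be positive", "ssrsa_invalid_input")
  if (is.null(onsets_ms)) onsets_ms <- (seq_along(frames) - 1) * step_ms
  if (length(onsets_ms) != length(frames))
    ssrsa_error("onsets_ms must match the number of frames", "ssrsa_invalid_input")
  structure(list(frames = frames, window_ms = window_ms, step_ms = step_ms,
                 onsets_ms = onsets_ms),
            class = "dynamic_rdm")
}

#' @export
print.dynamic_rdm <- function(x, ...) {
  cat(sprintf("dynamic RDM: %d frames of %d x %d (window %d ms, step %d ms)\n",
              length(x$frames), nrow(x$frames[[1]]), nrow(x$frames[[1]]),
              x$window_ms, x$step_ms))
  invisible(x)
}

#' @export
length.dynamic_rdm <- function(x) length(x$frames)

#' Write / read an RDM stack as a long-format CSV
#'
#' Plain-text persistence for dRDMs: one row per (frame, condition pair)
#' holding the upper-triangle value. Text CSV keeps outputs portable and
#' diffable; the format round-trips exactly at full double precision.
#'
#' @param drdm a `dynamic_rdm`.
#' @param path CSV file path.
#' @return `path`, invisibly (write); a `dynamic_rdm` (read).
#' @export
write_drdm_csv <- function(drdm, path) {
  conds <- rdm_conditions(drdm)
  pr <- upper_triangle_pairs(length(conds))
  rows <- do.call(rbind, lapply(seq_along(drdm$frames), function(k) {
    data.frame(frame = k, onset_ms = drdm$onsets_ms[k],
               cond_i = conds[pr[, "i"]], cond_j = conds[pr[, "j"]],
               value = upper_triangle_vector(drdm$frames[[k]]))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_drdm_csv
#' @param window_ms,step_ms window geometry to attach on read.
#' @export
read_drdm_csv <- function(path, window_ms, step_ms) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  conds <- unique(c(rows$cond_i, rows$cond_j))
  frames <- lapply(split(rows, rows$frame), function(fr)
    rdm_from_upper_triangle(fr$value, conds))
  onsets <- vapply(split(rows, rows$frame), function(fr) fr$onset_ms[1], 0)
  dynamic_rdm(unname(frames), window_ms, step_ms, unname(onsets))
}
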