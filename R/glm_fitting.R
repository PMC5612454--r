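# Simultaneous multi-model GLM: fit all phone model RDMs to each data RDM.
#
# On upper-triangle vectors, the data RDM D is modelled as
#   D = beta_1 * M_1 + sum_phi beta_phi * M_phi + E
# with M_1 the constant (all-ones) predictor and E minimised in sum-squared
# error. Predictors enter raw: the equation is stated on the RDMs
# themselves, and feature fits sum raw coefficients across phones, so any
# rescaling of predictors would silently reweight features. Acoustically
# similar phones yield collinear model RDMs; rank-deficient designs are
# solved by the minimum-norm least-squares solution (SVD pseudoinverse) with
# a warning and a condition-number report, never by dropping predictors --
# the pipeline's remedy for coefficient trade-off between competitor phones
# is the downstream feature aggregation.

# SVD pseudoinverse fit shared by all GLM entry points.
# Returns list(coef = p x k matrix for k right-hand sides, rank, condition_number).
pinv_lsfit <- function(X, Y, warn_context = NULL) {
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * max(sv$d)
  pos <- sv$d > tol
  rank <- sum(pos)
  if (rank < ncol(X))
    warning(sprintf(
      "rank-deficient design (rank %d of %d predictors)%s: minimum-norm solution used",
      rank, ncol(X), if (is.null(warn_context)) "" else paste0(" at ", warn_context)))
  cond <- if (rank > 0) max(sv$d) / min(sv$d[pos]) else Inf
  coef <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% Y) / sv$d[pos])
  list(coef = coef, rank = rank, condition_number = cond)
}

# Design matrix from a named list of model RDMs: constant column then one
# column per phone model's upper-triangle vector.
glm_design <- function(models) {
  utvs <- sapply(models, upper_triangle_vector)
  X <- cbind(1, utvs)
  colnames(X) <- c("(intercept)", names(models))
  X
}

#' Fit all phone model RDMs to one data RDM
#'
#' Ordinary least squares on upper-triangle vectors with an explicit
#' constant predictor.
#'
#' @param data an `rdm`.
#' @param models named list of model `rdm`s over the same conditions.
#' @return object of class `rsa_glm`: list with `betas` (named per-phone
#'   coefficients), `intercept`, `residual_ss`, `rank`, `condition_number`.
#' @export
fit_phone_glm <- function(data, models) {
  if (length(models) == 0)
    ssrsa_error("need at least one model RDM", "ssrsa_invalid_input")
  if (is.null(names(models)))
    ssrsa_error("models must be a named list", "ssrsa_invalid_input")
  conds <- rdm_conditions(data)
  for (m in models)
    if (!identical(rdm_conditions(m), conds))
      ssrsa_error("data and model RDMs must share one condition set",
                  "ssrsa_invalid_input")
  y <- upper_triangle_vector(data)
  if (stats::sd(y) == 0)
    ssrsa_error("constant data RDM vector: nothing to fit", "ssrsa_degenerate_input")
  X <- glm_design(models)
  fit <- pinv_lsfit(X, y)
  beta <- drop(fit$coef)
  resid <- y - drop(X %*% fit$coef)
  structure(list(betas = stats::setNames(beta[-1], names(models)),
                 intercept = beta[1],
                 residual_ss = sum(resid^2),
                 rank = fit$rank,
                 condition_number = fit$condition_number),
            class = "rsa_glm")
}

#' @export
print.rsa_glm <- function(x, ...) {
  cat(sprintf("RSA GLM: %d phone models, residual SS %.4g, condition number %.3g\n",
              length(x$betas), x$residual_ss, x$condition_number))
  invisible(x)
}

#' Fit every (vertex, window) data RDM against the matching model frames
#'
#' Window w of each vertex's data dRDM is regressed on window w of every
#' phone model dRDM (window indices are shared between the streams: the lag
#' was already applied when the data dRDMs were built). Fits are independent
#' across vertices; for speed the per-window pseudoinverse is computed once
#' and applied to all vertices jointly, which is numerically identical to
#' looped single fits.
#'
#' @param data_drdms named list (by vertex) of `dynamic_rdm`.
#' @param model_set a `phone_model_set`.
#' @return object of class `glm_fit_map`: `betas` array (phone x window x
#'   vertex), `intercept` (window x vertex), `residual_ss` (window x
#'   vertex), `condition_numbers` (per window), `phones`, `vertices`.
#' @export
fit_drdms <- function(data_drdms, model_set) {
  if (length(data_drdms) == 0)
    ssrsa_error("no data dRDMs supplied", "ssrsa_invalid_input")
  n_win <- length(data_drdms[[1]]$frames)
  for (d in data_drdms)
    if (length(d$frames) != n_win)
      ssrsa_error("all vertices must have the same number of windows",
                  "ssrsa_invalid_input")
  n_win_model <- length(model_set$drdms[[1]]$frames)
  if (n_win_model != n_win)
    ssrsa_error(sprintf(
      "window counts differ after lag alignment: %d data vs %d model frames",
      n_win, n_win_model), "ssrsa_invalid_input")
  phones <- model_set$phones
  vertices <- names(data_drdms)
  betas <- array(NA_real_, c(length(phones), n_win, length(vertices)),
                 dimnames = list(phones, NULL, vertices))
  intercept <- matrix(NA_real_, n_win, length(vertices),
                      dimnames = list(NULL, vertices))
  residual_ss <- matrix(NA_real_, n_win, length(vertices),
                        dimnames = list(NULL, vertices))
  cond_nums <- numeric(n_win)
  for (w in seq_len(n_win)) {
    X <- glm_design(lapply(model_set$drdms, function(d) d$frames[[w]]))
    Y <- sapply(data_drdms, function(d) upper_triangle_vector(d$frames[[w]]))
    fit <- pinv_lsfit(X, Y, warn_context = sprintf("window %d", w))
    betas[, w, ] <- fit$coef[-1, , drop = FALSE]
    intercept[w, ] <- fit$coef[1, ]
    residual_ss[w, ] <- colSums((Y - X %*% fit$coef)^2)
    cond_nums[w] <- fit$condition_number
  }
  structure(list(betas = betas, intercept = intercept,
                 residual_ss = residual_ss, condition_numbers = cond_nums,
                 phones = phones, vertices = vertices),
            class = "glm_fit_map")
}

#' @export
print.glm_fit_map <- function(x, ...) {
  cat(sprintf("GLM fit map: %d phones x %d windows x %d vertices\n",
              dim(x$betas)[1], dim(x$betas)[2], dim(x$betas)[3]))
  invisible(x)
}

#' Epoch-averaged phone coefficients
#'
#' Averages each phone's coefficient (and the intercept) across all window
#' positions, per vertex. Feature fits and permutation thresholds are
#' computed from these epoch-averaged coefficients when summarising the
#' whole analysis epoch.
#'
#' @param fit a `glm_fit_map` (all vertices) or `rsa_glm` list for one
#'   vertex.
#' @return list with `betas` (phone x vertex matrix) and `intercept`
#'   (per-vertex vector).
#' @export
epoch_average_betas <- function(fit) {
  if (inherits(fit, "glm_fit_map")) {
    b <- apply(fit$betas, c(1, 3), mean)
    if (is.null(dim(b)))
      b <- matrix(b, nrow = length(fit$phones),
                  dimnames = list(fit$phones, fit$vertices))
    return(list(betas = b, intercept = colMeans(fit$intercept)))
  }
  if (inherits(fit, "rsa_glm")) fit <- list(fit)
  if (length(fit) == 0)
    ssrsa_error("no window results to average", "ssrsa_invalid_input")
  bmat <- sapply(fit, function(f) f$betas)
  if (is.null(dim(bmat))) bmat <- matrix(bmat, nrow = 1,
                                         dimnames = list(names(fit[[1]]$betas)))
  list(betas = rowMeans(bmat),
       intercept = mean(vapply(fit, function(f) f$intercept, 0)))
}

#' Write a GLM fit map as a long-format CSV
#'
#' One row per (vertex, window, phone) coefficient, plus per-fit residual
#' sum of squares and per-window design condition number.
#'
#' @param fit a `glm_fit_map`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_glm_csv <- function(fit, path) {
  d <- expand.grid(phone = fit$phones, window = seq_len(dim(fit$betas)[2]),
                   vertex_id = fit$vertices, stringsAsFactors = FALSE)
  d$beta <- as.vector(fit$betas)
  d$residual_ss <- fit$residual_ss[cbind(d$window, match(d$vertex_id, fit$vertices))]
  d$condition_number <- fit$condition_numbers[d$window]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
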