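# Articulatory feature space: the binary phone-by-feature indicator matrix
# and the aggregation of per-phone GLM coefficients into per-feature fits.
#
# Each phone either exhibits or lacks each articulatory feature (sonorant,
# nasal, vowel frontness, ...). The fit of a feature f at a searchlight
# location is the sum of the GLM coefficients of the phones exhibiting f:
#   fit_f = sum_phi chi_f(phi) * beta_phi
# with chi_f the indicator row for f. The intercept coefficient is never
# included. Aggregating over features links together the contributions of
# acoustically similar competitor phones whose individual coefficients trade
# off against each other in the GLM.

#' Construct a feature matrix
#'
#' @param indicator binary feature x phone matrix (rownames = feature names,
#'   colnames = phone symbols).
#' @param categories character vector, one category per feature row (e.g.
#'   "broad", "place", "manner", "frontness", "closeness", "roundedness").
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(indicator, categories) {
  indicator <- as.matrix(indicator)
  if (is.null(rownames(indicator)) || is.null(colnames(indicator)))
    ssrsa_error("indicator needs feature rownames and phone colnames",
                "ssrsa_invalid_input")
  if (!all(indicator %in% c(0, 1)))
    ssrsa_error("feature matrix cells must be 0 or 1", "ssrsa_invalid_input")
  if (length(categories) != nrow(indicator))
    ssrsa_error("one category per feature row required", "ssrsa_invalid_input")
  empty_f <- rownames(indicator)[rowSums(indicator) == 0]
  if (length(empty_f) > 0)
    ssrsa_error(sprintf("feature(s) with no phones: %s",
                        paste(empty_f, collapse = ", ")), "ssrsa_invalid_input")
  empty_p <- colnames(indicator)[colSums(indicator) == 0]
  if (length(empty_p) > 0)
    ssrsa_error(sprintf("phone(s) with no features: %s",
                        paste(empty_p, collapse = ", ")), "ssrsa_invalid_input")
  structure(list(indicator = indicator,
                 features = rownames(indicator),
                 phones = colnames(indicator),
                 categories = stats::setNames(as.character(categories),
                                              rownames(indicator))),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature matrix: %d features (%d categories) x %d phones\n",
              length(x$features), length(unique(x$categories)),
              length(x$phones)))
  invisible(x)
}

#' Load a phone-by-feature matrix from CSV
#'
#' Expected layout: first column `feature`, second column `category`,
#' remaining columns one per phone with 0/1 cells.
#'
#' @param path CSV file path.
#' @param inventory optional phone inventory to check the columns against;
#'   mismatches are reported phone-by-phone.
#' @return a `feature_matrix`.
#' @export
load_feature_matrix <- function(path, inventory = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(d) < 3 || names(d)[1] != "feature" || names(d)[2] != "category")
    ssrsa_error("feature CSV must start with columns 'feature', 'category'",
                "ssrsa_invalid_input")
  ind <- as.matrix(d[, -(1:2), drop = FALSE])
  rownames(ind) <- d$feature
  if (!is.null(inventory)) {
    missing <- setdiff(inventory, colnames(ind))
    extra <- setdiff(colnames(ind), inventory)
    msgs <- c(
      if (length(missing) > 0)
        sprintf("inventory phones missing from matrix: %s",
                paste(missing, collapse = ", ")),
      if (length(extra) > 0)
        sprintf("matrix phones not in inventory: %s",
                paste(extra, collapse = ", ")))
    if (length(msgs) > 0)
      ssrsa_error(paste(msgs, collapse = "; "), "ssrsa_invalid_input")
  }
  feature_matrix(ind, d$category)
}

#' The packaged default articulatory feature matrix
#'
#' A 40-phone British English inventory scored on 24 binary articulatory
#' features in six category groups: broad phonetic categories (sonorant,
#' obstruent, voiced), consonant place, consonant manner, vowel frontness,
#' vowel closeness and vowel roundedness. Shipped as an editable CSV
#' (`system.file("extdata", "phone_features.csv", package = "ssrsa")`): the
#' matrix is configuration, not code, and analyses with a different phone set
#' or feature system should supply their own file to [load_feature_matrix()].
#'
#' @return a `feature_matrix`.
#' @export
default_feature_matrix <- function() {
  load_feature_matrix(system.file("extdata", "phone_features.csv",
                                  package = "ssrsa", mustWork = TRUE))
}

#' Write a feature matrix to CSV
#'
#' Inverse of [load_feature_matrix()]; round-trips every cell.
#'
#' @param fm a `feature_matrix`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  d <- data.frame(feature = fm$features,
                  category = unname(fm$categories[fm$features]),
                  fm$indicator, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Aggregate phone coefficients into one feature's fit
#'
#' fit_f = sum over phones phi with feature f of beta_phi. Phones present in
#' the matrix but absent from `betas` (e.g. dropped low-frequency phones)
#' contribute 0, with a warning. The GLM intercept is never part of the sum.
#'
#' @param betas named numeric vector of per-phone GLM coefficients.
#' @param feature feature name.
#' @param fm a `feature_matrix`.
#' @return the feature fit (numeric scalar).
#' @export
feature_fit <- function(betas, feature, fm) {
  if (!feature %in% fm$features)
    ssrsa_error(sprintf("unknown feature '%s'", feature), "ssrsa_invalid_input")
  carriers <- fm$phones[fm$indicator[feature, ] == 1]
  absent <- setdiff(carriers, names(betas))
  if (length(absent) > 0)
    warning(sprintf("no coefficient for phone(s) %s: contributing 0 to '%s'",
                    paste(absent, collapse = ", "), feature))
  sum(betas[intersect(carriers, names(betas))])
}

#' All feature fits from one coefficient vector
#'
#' @param betas named numeric vector of per-phone GLM coefficients.
#' @param fm a `feature_matrix`.
#' @return named numeric vector, one fit per feature, in matrix row order.
#' @export
all_feature_fits <- function(betas, fm) {
  common <- intersect(fm$phones, names(betas))
  absent <- setdiff(fm$phones, names(betas))
  if (length(absent) > 0)
    warning(sprintf("no coefficient for phone(s) %s: contributing 0",
                    paste(absent, collapse = ", ")))
  b <- stats::setNames(numeric(length(fm$phones)), fm$phones)
  b[common] <- betas[common]
  drop(fm$indicator %*% b)
}
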