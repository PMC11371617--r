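#' Iterative random-forest (missForest-style) imputation
#'
#' Missing cells start at their column means; then, per round, each column
#' with missing cells (ascending missing count) gets a fresh regression
#' forest fitted on the rows observed in that column — predictors are all
#' other columns of the current completed matrix — and its missing cells are
#' overwritten by the forest predictions.  Rounds stop at the first increase
#' of the normalized squared change between successive imputations (the
#' previous round's matrix is returned) or after `max_iter` rounds.  The
#' forest is an in-package tree ensemble (bootstrap rows, random feature
#' subsets, variance-reduction splits, ties to the lowest feature index) and
#' is bitwise reproducible for a given `seed`.
#'
#' @inheritParams impute_mean
#' @param n_trees trees per forest (default 100).
#' @param mtry features tried per split; default `ceiling((T - 1) / 3)`.
#' @param min_leaf minimum rows per leaf (default 5).
#' @param seed integer seed; per-(round, column) streams are derived from it.
#' @param max_iter round cap (default 10).
#' @return An `imputation_result`.
#' @export
impute_forest <- function(matrix, n_trees = 100L, mtry = NULL,
                          min_leaf = 5L, seed = 1L, max_iter = 10L) {
  X <- as_grid_matrix(matrix)
  D <- nrow(X); Tw <- ncol(X)
  if (n_trees < 1L) {
    bi_stop("binimpute_config_error", "n_trees must be >= 1")
  }
  if (D < 4L) {
    bi_stop("binimpute_config_error",
            "forest imputation needs at least 4 days")
  }
  check_no_empty_columns(X)
  if (is.null(mtry)) mtry <- ceiling(max(Tw - 1L, 1L) / 3)
  miss <- is.na(X)
  mu <- colMeans(X, na.rm = TRUE)
  Xc <- X
  Xc[miss] <- mu[which(miss, arr.ind = TRUE)[, 2L]]
  cols <- which(colSums(miss) > 0L)
  cols <- cols[order(colSums(miss)[cols], cols)]
  if (!length(cols)) {
    return(new_imputation_result(Xc, miss, "rf", n_iterations = 0L))
  }
  if (Tw == 1L) {                      # no predictors: column mean is all
    return(new_imputation_result(Xc, miss, "rf", n_iterations = 0L))
  }
  prev_diff <- Inf
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    Xnew <- Xc
    for (j in cols) {
      obs_r <- which(!miss[, j])
      mis_r <- which(miss[, j])
      sj <- as.integer((as.double(seed) * 7919 + (iter + 1L) * 131 + j) %%
                         2147483647)
      pred <- rf_fit_predict(Xnew[obs_r, -j, drop = FALSE], Xnew[obs_r, j],
                             Xnew[mis_r, -j, drop = FALSE],
                             as.integer(n_trees), as.integer(mtry),
                             as.integer(min_leaf), sj)
      Xnew[mis_r, j] <- pred
    }
    diff <- sum((Xnew[miss] - Xc[miss])^2) / max(sum(Xnew[miss]^2), 1e-12)
    if (diff > prev_diff) {        # criterion rose: keep the previous round
      converged <- TRUE
      break
    }
    Xc <- Xnew
    prev_diff <- diff
    iter <- iter + 1L
  }
  new_imputation_result(Xc, miss, "rf", n_iterations = max(iter, 1L),
                        converged = converged)
}
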