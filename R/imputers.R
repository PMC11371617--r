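#' @title Imputation algorithms over the day-by-slot matrix contract
#' @description All imputers consume a `daygrid` (or plain numeric matrix
#'   with `NA` for missing cells), treat rows (days) as statistical samples
#'   and columns (clock slots) as variables, fill every missing cell, and
#'   never touch an observed one.  Algorithm short names follow the common
#'   benchmarking labels: `em` (Gaussian expectation-maximization), `ii`
#'   (chained ridge regressions), `knn` (missing-aware nearest neighbours),
#'   `rf` (iterative random forest), `si` (cross-day column mean).
#' @name imputers
NULL

as_grid_matrix <- function(matrix) {
  x <- if (inherits(matrix, "daygrid")) {
    v <- matrix$values
    v[matrix$missing_mask] <- NA_real_
    v
  } else {
    as.matrix(matrix)
  }
  dimnames(x) <- NULL
  x
}

new_imputation_result <- function(filled, miss, algorithm,
                                  n_iterations = 1L, converged = TRUE,
                                  extra = list()) {
  idx <- which(miss, arr.ind = TRUE)
  cells <- data.frame(day = idx[, 1L], slot = idx[, 2L],
                      value = filled[miss])
  structure(c(list(filled = filled, imputed_cells = cells,
                   algorithm = algorithm,
                   n_iterations = as.integer(n_iterations),
                   converged = converged), extra),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("<imputation_result> %s: %d cells filled, %d iteration(s)%s\n",
              x$algorithm, nrow(x$imputed_cells), x$n_iterations,
              if (x$converged) ", converged" else " (not converged)"))
  invisible(x)
}

check_no_empty_columns <- function(X) {
  n_obs <- colSums(!is.na(X))
  if (any(n_obs == 0L)) {
    bi_stop("binimpute_degenerate_column",
            "slot column %d has no observed value",
            which(n_obs == 0L)[1L])
  }
}

#' Cross-day column-mean imputation
#'
#' Each missing cell is filled with the arithmetic mean of the observed
#' values at the same clock slot on the other days (the `si` baseline).
#'
#' @param matrix a `daygrid` or numeric matrix with `NA` for missing.
#' @return An `imputation_result`.
#' @export
impute_mean <- function(matrix) {
  X <- as_grid_matrix(matrix)
  check_no_empty_columns(X)
  miss <- is.na(X)
  mu <- colMeans(X, na.rm = TRUE)
  filled <- X
  if (any(miss)) {
    idx <- which(miss, arr.ind = TRUE)
    filled[miss] <- mu[idx[, 2L]]
  }
  new_imputation_result(filled, miss, "si")
}

#' k-nearest-neighbour imputation with missing-aware distances
#'
#' Donor days are ranked by the missing-aware Euclidean distance
#' `sqrt(T/|C| * sum_{t in C} (a_t - b_t)^2)` over the columns `C` observed
#' in both rows (the scaling makes distances comparable across pairs with
#' different overlap).  Each missing cell is the (weighted) mean of the `k`
#' nearest donors observed at that column; donors missing there are skipped
#' in favour of the next nearest, and the column mean is used when no donor
#' has the column.  Ties in distance resolve by the lower row index.
#'
#' @inheritParams impute_mean
#' @param k number of donor rows (clipped to `D - 1` with a warning).
#' @param weighting `"uniform"` or `"distance"` (inverse-distance weights;
#'   zero-distance donors, if any, take over with uniform weights).
#' @return An `imputation_result`.
#' @export
impute_knn <- function(matrix, k = 5L, weighting = c("uniform", "distance")) {
  weighting <- match.arg(weighting)
  X <- as_grid_matrix(matrix)
  check_no_empty_columns(X)
  miss <- is.na(X)
  D <- nrow(X); Tw <- ncol(X)
  if (k < 1L) bi_stop("binimpute_config_error", "k must be >= 1")
  if (k > D - 1L) {
    warning(sprintf("k = %d exceeds the %d available donors; clipped", k,
                    D - 1L), call. = FALSE)
    k <- D - 1L
  }
  mu <- colMeans(X, na.rm = TRUE)
  filled <- X
  targets <- which(rowSums(miss) > 0L)
  for (d in targets) {
    dists <- rep(Inf, D)
    for (o in seq_len(D)) {
      if (o == d) next
      shared <- !miss[d, ] & !miss[o, ]
      nc <- sum(shared)
      if (nc > 0L) {
        dists[o] <- sqrt(Tw / nc * sum((X[d, shared] - X[o, shared])^2))
      }
    }
    ord <- order(dists)                      # stable: ties by row index
    ord <- ord[is.finite(dists[ord]) & ord != d]
    for (j in which(miss[d, ])) {
      donors <- ord[!miss[ord, j]]
      if (!length(donors)) {
        filled[d, j] <- mu[j]
        next
      }
      donors <- utils::head(donors, k)
      dv <- X[donors, j]
      dd <- dists[donors]
      filled[d, j] <- if (weighting == "uniform") {
        mean(dv)
      } else if (any(dd == 0)) {
        mean(dv[dd == 0])
      } else {
        sum(dv / dd) / sum(1 / dd)
      }
    }
  }
  new_imputation_result(filled, miss, "knn")
}

# observed-data Gaussian log-likelihood for a block of rows sharing one
# missingness pattern; Cholesky fast path, eigen fallback for a singular
# covariance (pseudo-determinant over the support).
gauss_obs_loglik <- function(Xo, mu_o, S_oo) {
  n <- nrow(Xo); p <- ncol(Xo)
  if (p == 0L) return(0)
  ctr <- sweep(Xo, 2L, mu_o)
  ch <- tryCatch(chol(S_oo), error = function(e) NULL)
  if (!is.null(ch)) {
    z <- backsolve(ch, t(ctr), transpose = TRUE)
    logdet <- 2 * sum(log(diag(ch)))
    return(-0.5 * (n * (p * log(2 * pi) + logdet) + sum(z^2)))
  }
  e <- eigen(S_oo, symmetric = TRUE)
  keep <- e$values > max(e$values, 0) * 1e-12
  r <- sum(keep)
  if (r == 0L) return(-Inf)
  z <- (ctr %*% e$vectors[, keep, drop = FALSE]) %*%
    diag(1 / sqrt(e$values[keep]), r)
  -0.5 * (n * (r * log(2 * pi) + sum(log(e$values[keep]))) + sum(z^2))
}

#' Fit a Gaussian model to a matrix with missing cells by EM
#'
#' Fits a multivariate normal over the columns, treating missing cells as
#' latent.  Initialization: `mu` = column means, `sigma` = diagonal of
#' column variances.  Each E-step computes, per missingness pattern, the
#' conditional mean of the missing coordinates given the observed ones and
#' the conditional covariance correction; the M-step re-estimates `mu` and
#' `sigma` from the completed sufficient statistics and then shrinks the
#' covariance towards its diagonal, `sigma <- (1 - w) sigma + w diag(sigma)`.
#' Shrinkage keeps `sigma` positive definite when the window is wider than
#' the number of days (e.g. 360 slots from 30 days); with `shrinkage = 0`
#' this is plain EM and the observed-data log-likelihood recorded in
#' `loglik_trace` is non-decreasing.
#'
#' @details For windows much wider than the number of days (e.g. the 24-h
#'   baseline: 1440 slots from 30 days) the shrunken covariance is diagonal
#'   plus a rank-`D` term, and the E-step and likelihood are evaluated
#'   through the Woodbury identity instead of dense Cholesky factorizations;
#'   `method = "auto"` picks this path when it applies (it requires
#'   `shrinkage > 0`).  Both paths compute the same model up to numerical
#'   round-off.
#'
#' @inheritParams impute_mean
#' @param shrinkage diagonal shrinkage weight in `[0, 1]` (default 0.1).
#' @param tol stop when the largest relative change of any imputed value
#'   falls below this (default `1e-6`).
#' @param max_iter iteration cap (default 100).
#' @param method `"auto"`, `"dense"` or `"lowrank"` (see Details).
#' @return A `gaussian_model` list: `mu`, `sigma`, `shrinkage`,
#'   `loglik_trace`, `filled`, `n_iterations`, `converged`.
#' @export
fit_em <- function(matrix, shrinkage = 0.1, tol = 1e-6, max_iter = 100L,
                   method = c("auto", "dense", "lowrank")) {
  method <- match.arg(method)
  X <- as_grid_matrix(matrix)
  D <- nrow(X); Tw <- ncol(X)
  if (D < 2L) bi_stop("binimpute_config_error", "EM needs at least 2 days")
  if (shrinkage < 0 || shrinkage > 1) {
    bi_stop("binimpute_config_error", "shrinkage must be in [0, 1]")
  }
  check_no_empty_columns(X)
  miss <- is.na(X)
  if (method == "auto") {
    method <- if (shrinkage > 0 && Tw > 4L * D) "lowrank" else "dense"
  }
  if (method == "lowrank") {
    if (shrinkage <= 0) {
      bi_stop("binimpute_config_error",
              "the low-rank EM path requires shrinkage > 0")
    }
    return(fit_em_lowrank(X, miss, shrinkage, tol, max_iter))
  }
  mu <- colMeans(X, na.rm = TRUE)
  v <- apply(X, 2L, stats::var, na.rm = TRUE)
  vfloor <- max(mean(v[is.finite(v) & v > 0]), 1e-8)
  if (!is.finite(vfloor)) vfloor <- 1e-8
  v[!is.finite(v) | v <= 0] <- vfloor
  sigma <- diag(v, Tw)

  pat_key <- apply(miss, 1L, function(m) paste(which(m), collapse = ","))
  patterns <- split(seq_len(D), pat_key)
  any_missing <- any(miss)
  Xc <- X
  Xc[miss] <- mu[which(miss, arr.ind = TRUE)[, 2L]]
  imp_prev <- Xc[miss]
  loglik <- numeric(0)
  converged <- !any_missing
  iter <- 0L
  repeat {
    iter <- iter + 1L
    S_corr <- matrix(0, Tw, Tw)
    for (gi in seq_along(patterns)) {
      key <- names(patterns)[gi]
      rows <- patterns[[gi]]
      if (!nzchar(key)) {
        Xc[rows, ] <- X[rows, ]
        next
      }
      m <- as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
      o <- setdiff(seq_len(Tw), m)
      if (length(o) == 0L) {
        Xc[rows, ] <- rep(mu, each = length(rows))
        S_corr <- S_corr + length(rows) * sigma
        next
      }
      ch <- tryCatch(chol(sigma[o, o, drop = FALSE]), error = function(e) NULL)
      if (is.null(ch)) {
        bi_stop("binimpute_numerical_error",
                "covariance is not positive definite; increase shrinkage")
      }
      K <- sigma[m, o, drop = FALSE] %*% chol2inv(ch)
      ctr <- sweep(X[rows, o, drop = FALSE], 2L, mu[o])
      Xc[rows, m] <- rep(mu[m], each = length(rows)) + ctr %*% t(K)
      Cmm <- sigma[m, m, drop = FALSE] - K %*% sigma[o, m, drop = FALSE]
      S_corr[m, m] <- S_corr[m, m] + length(rows) * Cmm
    }
    mu <- colMeans(Xc)
    S <- (crossprod(sweep(Xc, 2L, mu)) + S_corr) / D
    sigma <- (1 - shrinkage) * S + shrinkage * diag(diag(S), Tw)
    ll <- 0
    for (gi in seq_along(patterns)) {
      key <- names(patterns)[gi]
      rows <- patterns[[gi]]
      m <- if (nzchar(key)) as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
           else integer(0)
      o <- setdiff(seq_len(Tw), m)
      ll <- ll + gauss_obs_loglik(X[rows, o, drop = FALSE], mu[o],
                                  sigma[o, o, drop = FALSE])
    }
    loglik <- c(loglik, ll)
    if (!any_missing) { converged <- TRUE; break }
    imp_new <- Xc[miss]
    delta <- max(abs(imp_new - imp_prev)) / (max(abs(imp_prev)) + 1e-12)
    imp_prev <- imp_new
    # the first E-step uses the diagonal init and reproduces the mean fill,
    # so its zero change is not evidence of convergence
    if (iter >= 2L && delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  structure(list(mu = mu, sigma = sigma, shrinkage = shrinkage,
                 loglik_trace = loglik, filled = Xc,
                 n_iterations = iter, converged = converged),
            class = "gaussian_model")
}

# EM through the Woodbury identity for sigma = diag(d) + W W'.  Exact same
# model as the dense path, but E-step and likelihood cost O(T D^2) instead
# of O(T^3), which makes whole-day (1440-slot) windows tractable.
fit_em_lowrank <- function(X, miss, shrinkage, tol, max_iter) {
  D <- nrow(X); Tw <- ncol(X)
  mu <- colMeans(X, na.rm = TRUE)
  v <- apply(X, 2L, stats::var, na.rm = TRUE)
  vfloor <- max(mean(v[is.finite(v) & v > 0]), 1e-8)
  if (!is.finite(vfloor)) vfloor <- 1e-8
  v[!is.finite(v) | v <= 0] <- vfloor
  d <- v
  W <- matrix(0, Tw, 0L)

  pat_key <- apply(miss, 1L, function(m) paste(which(m), collapse = ","))
  patterns <- split(seq_len(D), pat_key)
  u <- sort(unique(which(miss, arr.ind = TRUE)[, 2L]))
  any_missing <- any(miss)
  Xc <- X
  Xc[miss] <- mu[which(miss, arr.ind = TRUE)[, 2L]]
  imp_prev <- Xc[miss]
  loglik <- numeric(0)
  converged <- !any_missing
  iter <- 0L
  repeat {
    iter <- iter + 1L
    S_corr_uu <- matrix(0, length(u), length(u))
    for (gi in seq_along(patterns)) {
      key <- names(patterns)[gi]
      rows <- patterns[[gi]]
      if (!nzchar(key)) next
      m <- as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
      o <- setdiff(seq_len(Tw), m)
      pos <- match(m, u)
      if (length(o) == 0L) {
        Xc[rows, ] <- rep(mu, each = length(rows))
        Smm <- diag(d, Tw) + tcrossprod(W)
        S_corr_uu[pos, pos] <- S_corr_uu[pos, pos] + length(rows) * Smm
        next
      }
      do <- d[o]
      Wo <- W[o, , drop = FALSE]
      Wm <- W[m, , drop = FALSE]
      r <- ncol(W)
      ctr <- t(X[rows, o, drop = FALSE]) - mu[o]          # To x n
      if (r == 0L) {
        Xc[rows, m] <- rep(mu[m], each = length(rows))
        Cmm <- diag(d[m], length(m))
      } else {
        G <- crossprod(Wo, Wo / do)
        M <- G; diag(M) <- diag(M) + 1
        B1 <- ctr / do
        Y <- crossprod(Wo, B1)                            # r x n
        V <- B1 - (Wo / do) %*% solve(M, Y)               # sigma_oo^-1 ctr
        Xc[rows, m] <- rep(mu[m], each = length(rows)) +
          t(Wm %*% crossprod(Wo, V))
        H <- G %*% solve(M)                               # Wo' sig^-1 Wo
        H <- (H + t(H)) / 2
        Cmm <- diag(d[m], length(m)) + tcrossprod(Wm) -
          Wm %*% H %*% t(Wm)
      }
      S_corr_uu[pos, pos] <- S_corr_uu[pos, pos] + length(rows) * Cmm
    }
    mu <- colMeans(Xc)
    A <- sweep(Xc, 2L, mu)
    diag_corr <- numeric(Tw)
    diag_corr[u] <- diag(S_corr_uu)
    diagS <- (colSums(A^2) + diag_corr) / D
    diagS[diagS <= 0] <- vfloor
    d <- pmax(shrinkage * diagS, 1e-12)
    scale <- sqrt((1 - shrinkage) / D)
    W <- t(A) * scale
    if (length(u) && any(S_corr_uu != 0)) {
      e <- eigen((S_corr_uu + t(S_corr_uu)) / 2, symmetric = TRUE)
      keep <- e$values > max(e$values, 0) * 1e-12
      if (any(keep)) {
        Wc <- matrix(0, Tw, sum(keep))
        Wc[u, ] <- e$vectors[, keep, drop = FALSE] %*%
          diag(sqrt(e$values[keep]), sum(keep))
        W <- cbind(W, scale * Wc)
      }
    }
    ll <- 0
    for (gi in seq_along(patterns)) {
      key <- names(patterns)[gi]
      rows <- patterns[[gi]]
      m <- if (nzchar(key)) as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
           else integer(0)
      o <- setdiff(seq_len(Tw), m)
      if (!length(o)) next
      do <- d[o]
      Wo <- W[o, , drop = FALSE]
      ctr <- t(X[rows, o, drop = FALSE]) - mu[o]
      B1 <- ctr / do
      q <- colSums(ctr * B1)
      logdet <- sum(log(do))
      if (ncol(W)) {
        G <- crossprod(Wo, Wo / do)
        M <- G; diag(M) <- diag(M) + 1
        chM <- chol(M)
        Y <- crossprod(Wo, B1)
        Z <- backsolve(chM, Y, transpose = TRUE)
        q <- q - colSums(Z^2)
        logdet <- logdet + 2 * sum(log(diag(chM)))
      }
      ll <- ll - 0.5 * (length(rows) * (length(o) * log(2 * pi) + logdet) +
                          sum(q))
    }
    loglik <- c(loglik, ll)
    if (!any_missing) { converged <- TRUE; break }
    imp_new <- Xc[miss]
    delta <- max(abs(imp_new - imp_prev)) / (max(abs(imp_prev)) + 1e-12)
    imp_prev <- imp_new
    if (iter >= 2L && delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  sigma <- diag(d, Tw) + tcrossprod(W)
  structure(list(mu = mu, sigma = sigma, shrinkage = shrinkage,
                 loglik_trace = loglik, filled = Xc,
                 n_iterations = iter, converged = converged),
            class = "gaussian_model")
}

#' EM (Gaussian conditional-mean) imputation
#'
#' Runs [fit_em()] and fills every missing cell with its conditional mean
#' under the final Gaussian model.  On a single-column matrix this reduces
#' to the column mean.
#'
#' @inheritParams fit_em
#' @return An `imputation_result` with the fitted model in `$model`.
#' @export
impute_em <- function(matrix, shrinkage = 0.1, tol = 1e-6, max_iter = 100L) {
  X <- as_grid_matrix(matrix)
  model <- fit_em(X, shrinkage = shrinkage, tol = tol, max_iter = max_iter)
  new_imputation_result(model$filled, is.na(X), "em",
                        n_iterations = model$n_iterations,
                        converged = model$converged,
                        extra = list(model = model))
}

# ridge least squares: returns c(intercept, coefficients); dual form when
# the design is wider than tall so whole-day windows stay tractable.
ridge_fit <- function(Xd, y, ridge) {
  n <- nrow(Xd); p <- ncol(Xd)
  xm <- colMeans(Xd); ym <- mean(y)
  Xc <- sweep(Xd, 2L, xm); yc <- y - ym
  beta <- tryCatch({
    if (p <= n) {
      solve(crossprod(Xc) + diag(ridge, p), crossprod(Xc, yc))
    } else {
      a <- solve(tcrossprod(Xc) + diag(ridge, n), yc)
      crossprod(Xc, a)
    }
  }, error = function(e) NULL)
  if (is.null(beta)) {
    bi_stop("binimpute_numerical_error",
            "singular regression design; use ridge > 0")
  }
  c(ym - sum(xm * beta), beta)
}

#' Chained ridge-regression (iterative) imputation
#'
#' MICE-style round robin: missing cells start at their column means; then,
#' repeatedly, each column with missing cells (in ascending order of missing
#' count) is regressed on all other columns — a ridge-penalized linear fit
#' on the rows observed in that column, predictors taken from the current
#' completed matrix — and its missing cells are overwritten with the
#' predictions, until the largest relative change of any imputed value drops
#' below `tol` or `max_iter` rounds have run.  `max_iter = 0` returns the
#' mean initialization.
#'
#' @inheritParams impute_mean
#' @param ridge ridge penalty (default `1e-3`); `ridge = 0` fails on a
#'   singular design.
#' @param tol,max_iter convergence controls (defaults `1e-6`, 100).
#' @return An `imputation_result`.
#' @export
impute_iterative <- function(matrix, ridge = 1e-3, tol = 1e-6,
                             max_iter = 100L) {
  X <- as_grid_matrix(matrix)
  D <- nrow(X)
  if (D < 3L) {
    bi_stop("binimpute_config_error",
            "iterative imputation needs at least 3 days")
  }
  check_no_empty_columns(X)
  miss <- is.na(X)
  mu <- colMeans(X, na.rm = TRUE)
  Xc <- X
  Xc[miss] <- mu[which(miss, arr.ind = TRUE)[, 2L]]
  cols <- which(colSums(miss) > 0L)
  cols <- cols[order(colSums(miss)[cols], cols)]
  if (!length(cols) || max_iter == 0L) {
    return(new_imputation_result(Xc, miss, "ii", n_iterations = 0L,
                                 converged = !any(miss) && max_iter > 0L))
  }
  imp_prev <- Xc[miss]
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (j in cols) {
      obs_r <- which(!miss[, j])
      fit <- ridge_fit(Xc[obs_r, -j, drop = FALSE], Xc[obs_r, j], ridge)
      mis_r <- which(miss[, j])
      Xc[mis_r, j] <- as.numeric(fit[1L] +
        Xc[mis_r, -j, drop = FALSE] %*% fit[-1L])
    }
    imp_new <- Xc[miss]
    delta <- max(abs(imp_new - imp_prev)) / (max(abs(imp_prev)) + 1e-12)
    imp_prev <- imp_new
    if (delta < tol) { converged <- TRUE; break }
  }
  new_imputation_result(Xc, miss, "ii", n_iterations = iter,
                        converged = converged)
}

#' Run an imputer by its short name
#'
#' @inheritParams impute_mean
#' @param algorithm one of `"em"`, `"ii"`, `"knn"`, `"rf"`, `"si"`.
#' @param params named list of algorithm arguments (e.g. `list(k = 3)`).
#' @return An `imputation_result`.
#' @export
impute_by_name <- function(matrix, algorithm, params = list()) {
  fun <- switch(as.character(algorithm),
                em = impute_em, ii = impute_iterative, knn = impute_knn,
                rf = impute_forest, si = impute_mean, NULL)
  if (is.null(fun)) {
    bi_stop("binimpute_config_error",
            "unknown algorithm '%s'; choose one of em, ii, knn, rf, si",
            algorithm)
  }
  keep <- intersect(names(params), names(formals(fun)))
  do.call(fun, c(list(matrix), params[keep]))
}
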