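#' Multiple imputation by predictive mean matching with chained equations
#'
#' Missing expression cells are imputed feature-by-feature in a chained
#' (fully conditional) sweep: each feature with missing cells is regressed by
#' ordinary least squares on all other features over its observed rows,
#' predicted means are computed for its missing rows, and every missing cell
#' is filled with the observed value of one of the `k_neighbors` donors whose
#' predicted mean is closest (drawn uniformly). Missing cells are initialized
#' with the feature mean, `n_sweeps` passes are run per imputation, and the
#' final matrix is the arithmetic mean of `n_imputations` independent
#' imputations (seeded `seed`, `seed + 1`, ...). Observed cells are returned
#' bit-identical.
#'
#' @param X Numeric matrix, donors x features, `NA` marking missing cells.
#' @param n_imputations Number of independent imputations averaged (default 5).
#' @param k_neighbors Size of the predictive-mean donor pool (default 5).
#' @param n_sweeps Chained-equation passes per imputation (default 10).
#' @param seed Integer seed; imputation `i` uses `seed + i - 1`.
#' @return Completed matrix of the same shape; attribute `n_imputations`
#'   records the averaging count.
#' @export
impute_pmm <- function(X, n_imputations = 5L, k_neighbors = 5L, n_sweeps = 10L,
                       seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) >= 2L, ncol(X) >= 2L)
  if (!anyNA(X)) return(X)
  obs <- !is.na(X)
  if (any(colSums(obs) == 0L)) {
    stop("feature(s) with all cells missing: ",
         paste(colnames(X)[colSums(obs) == 0L], collapse = ", "), call. = FALSE)
  }
  if (any(colSums(obs) < k_neighbors)) {
    stop("every feature needs >= k_neighbors observed values", call. = FALSE)
  }
  if (any(rowSums(obs) == 0L)) {
    stop("donor(s) with no observed features cannot be imputed", call. = FALSE)
  }

  acc <- matrix(0, nrow(X), ncol(X))
  for (i in seq_len(n_imputations)) {
    set.seed(seed + i - 1L)
    acc <- acc + pmm_single(X, obs, k_neighbors, n_sweeps)
  }
  out <- acc / n_imputations
  out[obs] <- X[obs]
  dimnames(out) <- dimnames(X)
  attr(out, "n_imputations") <- n_imputations
  out
}

# One chained-equations imputation; assumes RNG already seeded.
pmm_single <- function(X, obs, k, n_sweeps) {
  filled <- X
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) filled[!obs[, j], j] <- mu[j]
  targets <- which(colSums(!obs) > 0L)
  for (s in seq_len(n_sweeps)) {
    for (j in targets) {
      oj <- obs[, j]
      pred <- ols_predict(filled[, -j, drop = FALSE], filled[oj, j], oj)
      pool_val <- X[oj, j]
      pool_pred <- pred[oj]
      for (r in which(!oj)) {
        d <- abs(pool_pred - pred[r])
        nn <- order(d)[seq_len(k)]
        filled[r, j] <- pool_val[nn[sample.int(k, 1L)]]
      }
    }
  }
  filled
}

# OLS of y (over rows `rows`) on predictors Z; predictions for all rows.
# Rank-deficient fits fall back to the pivoted columns (qr in lm.fit).
ols_predict <- function(Z, y, rows) {
  Zi <- cbind(1, Z)
  fit <- stats::lm.fit(Zi[rows, , drop = FALSE], y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  drop(Zi %*% beta)
}
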