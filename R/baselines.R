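#' Two-group MANOVA (Hotelling's T-squared) association test
#'
#' Tests whether the multivariate mean expression vector differs between the
#' two genotype classes. For two groups one-way MANOVA is exactly Hotelling's
#' two-sample T-squared:
#' `T2 = (n0*n1/(n0+n1)) * t(d) %*% solve(S) %*% d` with `d` the mean
#' difference and `S` the pooled covariance, converted to
#' `F = ((n0+n1-p-1)/(p*(n0+n1-2))) * T2` on `(p, n0+n1-p-1)` degrees of
#' freedom. Zero-variance and collinear features are dropped before inversion
#' (linear methods otherwise fail on all-zero features).
#'
#' @param X Numeric matrix, donors x features, complete.
#' @param y Binary genotype (0/1, no missing after alignment).
#' @param gene_id,variant_id Identifiers for the output record.
#' @return One-row `assoc_result` data.frame: `gene`, `variant`, `method`
#'   (`"manova"`), `statistic` (the F value), `p_value`, `flag`.
#' @export
manova_test <- function(X, y, gene_id = "gene", variant_id = "variant") {
  al <- align_xy(X, y)
  X <- al$X; y <- al$y
  X <- drop_degenerate_features(X)
  p <- ncol(X)
  n0 <- sum(y == 0L); n1 <- sum(y == 1L)
  if (min(n0, n1) < p + 2L) {
    stop("each class needs at least p + 2 members for Hotelling's T2", call. = FALSE)
  }
  d <- colMeans(X[y == 1L, , drop = FALSE]) - colMeans(X[y == 0L, , drop = FALSE])
  S0 <- stats::cov(X[y == 0L, , drop = FALSE])
  S1 <- stats::cov(X[y == 1L, , drop = FALSE])
  S <- ((n0 - 1) * S0 + (n1 - 1) * S1) / (n0 + n1 - 2)
  Sinv <- tryCatch(solve(S), error = function(e) {
    stop("pooled covariance singular after degenerate-feature removal", call. = FALSE)
  })
  T2 <- (n0 * n1 / (n0 + n1)) * drop(t(d) %*% Sinv %*% d)
  Fstat <- ((n0 + n1 - p - 1) / (p * (n0 + n1 - 2))) * T2
  pval <- stats::pf(Fstat, p, n0 + n1 - p - 1, lower.tail = FALSE)
  assoc_result(gene_id, variant_id, "manova", Fstat, pval)
}

#' Reverse (genotype-on-expression) logistic regression test
#'
#' Regresses the binary genotype on all expression features jointly
#' (intercept plus one slope per feature, fit by iteratively reweighted least
#' squares via [stats::glm()]) and compares against the intercept-only model
#' with a likelihood-ratio chi-squared test on `p` degrees of freedom. On
#' separation or non-convergence the fit falls back to a lightly
#' ridge-penalized IRLS (`lambda = 1e-6`), flagged `"ridge"` in the output.
#'
#' @inheritParams manova_test
#' @return One-row `assoc_result` data.frame (`method = "reverse_logistic"`).
#' @export
reverse_logistic_test <- function(X, y, gene_id = "gene", variant_id = "variant") {
  al <- align_xy(X, y)
  X <- al$X; y <- al$y
  stopifnot(ncol(X) < nrow(X))
  if (length(unique(y)) < 2L) stop("both genotype classes must be present", call. = FALSE)
  Xu <- drop_degenerate_features(X, allow_empty = TRUE)
  p <- ncol(Xu)
  if (p == 0L) {
    # all features constant: no information, LRT statistic 0 by convention
    return(assoc_result(gene_id, variant_id, "reverse_logistic", 0, 1))
  }
  df <- as.data.frame(Xu)
  names(df) <- paste0("V", seq_len(p))
  df$y <- y
  fit <- suppressWarnings(stats::glm(y ~ ., family = stats::binomial(), data = df))
  mu <- stats::fitted(fit)
  separated <- !fit$converged || any(mu > 1 - 1e-8) || any(mu < 1e-8)
  flag <- ""
  if (separated) {
    lrt <- ridge_logistic_lrt(Xu, y, lambda = 1e-6)
    flag <- "ridge"
  } else {
    lrt <- fit$null.deviance - fit$deviance
  }
  lrt <- max(lrt, 0)
  pval <- stats::pchisq(lrt, df = p, lower.tail = FALSE)
  assoc_result(gene_id, variant_id, "reverse_logistic", lrt, pval, flag)
}

# Ridge-penalized logistic IRLS; returns the (penalized) LRT vs intercept-only.
ridge_logistic_lrt <- function(X, y, lambda = 1e-6, max_iter = 100L) {
  Z <- cbind(1, X)
  k <- ncol(Z)
  pen <- diag(c(0, rep(lambda, k - 1L)))
  beta <- rep(0, k)
  for (it in seq_len(max_iter)) {
    eta <- drop(Z %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    zw <- eta + (y - mu) / w
    H <- crossprod(Z, Z * w) + pen
    beta_new <- drop(solve(H, crossprod(Z, w * zw)))
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  eta <- drop(Z %*% beta)
  dev <- -2 * sum(y * stats::plogis(eta, log.p = TRUE) +
                    (1 - y) * stats::plogis(-eta, log.p = TRUE))
  p1 <- mean(y)
  dev0 <- -2 * (sum(y) * log(p1) + sum(1 - y) * log(1 - p1))
  dev0 - dev
}

#' Per-feature Welch t-test p-values
#'
#' Two-sided Welch (unequal-variance) two-sample t-test of each expression
#' feature between the genotype classes; the single-feature building block
#' for the Cauchy combination. A feature with zero variance in both classes
#' gets p = 1.
#'
#' @inheritParams manova_test
#' @return Numeric vector of p-values, one per feature.
#' @export
per_feature_pvalues <- function(X, y) {
  al <- align_xy(X, y)
  X <- al$X; y <- al$y
  n0 <- sum(y == 0L); n1 <- sum(y == 1L)
  stopifnot(n0 >= 2L, n1 >= 2L)
  X0 <- X[y == 0L, , drop = FALSE]
  X1 <- X[y == 1L, , drop = FALSE]
  m0 <- colMeans(X0); m1 <- colMeans(X1)
  v0 <- colSums(sweep(X0, 2, m0)^2) / (n0 - 1)
  v1 <- colSums(sweep(X1, 2, m1)^2) / (n1 - 1)
  se2 <- v0 / n0 + v1 / n1
  tstat <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se2 == 0] <- 1
  unname(p)
}

#' Cauchy combination of p-values
#'
#' Combines dependent p-values via the Cauchy transform:
#' `T = mean(tan((0.5 - p) * pi))`, combined p
#' `= 0.5 - atan(T) / pi`. Inputs are clipped to `[1e-15, 1 - 1e-15]` to keep
#' the tangent finite. A single p-value is returned unchanged (closed-form
#' identity).
#'
#' @param p Numeric vector of p-values in (0, 1).
#' @return Combined p-value in (0, 1].
#' @export
cauchy_combine <- function(p) {
  if (length(p) == 0L) stop("cauchy_combine needs at least one p-value", call. = FALSE)
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  T <- mean(tan((0.5 - p) * pi))
  0.5 - atan(T) / pi
}

#' Cauchy combination association test
#'
#' Runs [per_feature_pvalues()] (Welch t per feature) and combines them with
#' [cauchy_combine()].
#'
#' @inheritParams manova_test
#' @return One-row `assoc_result` data.frame (`method = "cauchy"`;
#'   `statistic` is the Cauchy combination statistic T).
#' @export
cauchy_test <- function(X, y, gene_id = "gene", variant_id = "variant") {
  p <- per_feature_pvalues(X, y)
  pc <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  T <- mean(tan((0.5 - pc) * pi))
  assoc_result(gene_id, variant_id, "cauchy", T, cauchy_combine(p))
}

#' Construct a baseline association record
#'
#' @param gene_id,variant_id Identifiers.
#' @param method `"manova"`, `"reverse_logistic"` or `"cauchy"`.
#' @param statistic Test statistic (finite).
#' @param p_value p-value in (0, 1].
#' @param flag Optional annotation (e.g. `"ridge"`).
#' @return One-row `assoc_result` data.frame.
#' @export
assoc_result <- function(gene_id, variant_id, method, statistic, p_value,
                         flag = "") {
  p_value <- max(p_value, 1e-300)  # keep extreme tails inside (0, 1]
  stopifnot(is.finite(statistic), p_value > 0, p_value <= 1)
  out <- data.frame(gene = gene_id, variant = variant_id, method = method,
                    statistic = statistic, p_value = p_value, flag = flag,
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  out
}

# Shared alignment: drop donors with missing genotype, coerce y to 0/1 int.
align_xy <- function(X, y) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  keep <- !is.na(y)
  list(X = X[keep, , drop = FALSE], y = as.integer(y[keep]))
}

# Drop zero-variance features, then collinear ones via pivoted QR on the
# centered matrix.
drop_degenerate_features <- function(X, allow_empty = FALSE) {
  v <- apply(X, 2, stats::var)
  keep <- v > .Machine$double.eps
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance feature(s) dropped", call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  if (ncol(X) == 0L) {
    if (allow_empty) return(X)
    stop("no non-degenerate features left", call. = FALSE)
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qr_ <- qr(Xc)
  if (qr_$rank < ncol(X)) {
    keep_idx <- sort(qr_$pivot[seq_len(qr_$rank)])
    warning(ncol(X) - qr_$rank, " collinear feature(s) dropped", call. = FALSE)
    X <- X[, keep_idx, drop = FALSE]
  }
  X
}
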