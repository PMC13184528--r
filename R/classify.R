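#' Eligibility of a variant for genotype classification
#'
#' Variants with fewer than `min_minority` donors in the less common genotype
#' class are excluded, so that each of the four stratified folds holds at
#' least one minority-class donor.
#'
#' @param y A [binarize_dominant()] genotype (or 0/1 vector).
#' @param min_minority Minimum minority-class count (default 4).
#' @return Logical scalar.
#' @export
eligible <- function(y, min_minority = 4L) {
  minority_count(y) >= min_minority
}

#' Confusion matrix for binary predictions
#'
#' Class 1 (the carrier class under the dominant coding) is the positive
#' class.
#'
#' @param truth,pred Integer 0/1 vectors of equal length.
#' @return Named integer vector `c(TP, FP, FN, TN)` of class
#'   `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  cm <- c(TP = sum(truth == 1L & pred == 1L),
          FP = sum(truth == 0L & pred == 1L),
          FN = sum(truth == 1L & pred == 0L),
          TN = sum(truth == 0L & pred == 0L))
  structure(as.integer(cm), names = names(cm), class = "confusion_matrix")
}

#' Macro F1 score
#'
#' Arithmetic mean of the per-class F1 scores (harmonic mean of precision and
#' recall per class), with any 0/0 term defined as 0.
#'
#' @param cm A [confusion_matrix()] (or named vector with TP/FP/FN/TN).
#' @return Value in \[0, 1\].
#' @export
macro_f1 <- function(cm) {
  f1_class <- function(tp, fp, fn) {
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  (f1_class(cm[["TP"]], cm[["FP"]], cm[["FN"]]) +
      f1_class(cm[["TN"]], cm[["FN"]], cm[["FP"]])) / 2
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the value
#' defined as 0 whenever any factor of the denominator is 0 (e.g. an
#' all-one-class prediction).
#'
#' @param cm A [confusion_matrix()].
#' @return Value in \[-1, 1\].
#' @export
mcc <- function(cm) {
  tp <- as.numeric(cm[["TP"]]); fp <- as.numeric(cm[["FP"]])
  fn <- as.numeric(cm[["FN"]]); tn <- as.numeric(cm[["TN"]])
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Soft-voting prediction from base-learner probabilities
#'
#' Averages the class-probability matrices of the base learners elementwise
#' and predicts the argmax per donor; an exact tie goes to class 0.
#'
#' @param prob_list List of donors x 2 probability matrices (columns = class
#'   0, class 1), each row summing to 1 within 1e-6.
#' @return Integer vector of predicted labels.
#' @export
soft_vote <- function(prob_list) {
  stopifnot(length(prob_list) >= 1L)
  dims <- vapply(prob_list, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != 2L)) {
    stop("probability arrays must share shape donors x 2", call. = FALSE)
  }
  for (p in prob_list) {
    if (any(abs(rowSums(p) - 1) > 1e-6)) stop("probability rows must sum to 1", call. = FALSE)
  }
  avg <- Reduce(`+`, prob_list) / length(prob_list)
  as.integer(avg[, 2L] > avg[, 1L])
}

#' Hidden-layer size for the 2D perceptron
#'
#' `ceil(m * n / 2)` where `m` is the exon count and `n` the tissue count of
#' the flattened 2D input.
#'
#' @param m,n Grid dimensions (both >= 1).
#' @return Integer hidden-layer size.
#' @export
mlp_hidden_size <- function(m, n) {
  stopifnot(m >= 1L, n >= 1L)
  as.integer(ceiling(m * n / 2))
}

#' Classifier specification
#'
#' @param kind `"ensemble"` (random forest + calibrated SVM, soft vote) or
#'   `"mlp"` (single-hidden-layer perceptron for 2D exon x tissue input).
#' @param n_trees Random-forest size (default 100).
#' @param svm_cost SVM cost parameter C (default 1; RBF kernel, Platt-type
#'   probability calibration always on).
#' @param n_folds Stratified CV folds (default 4).
#' @param mlp_max_iter Optimizer iteration cap for the perceptron.
#' @param seed Integer seed controlling fold assignment and learner RNG.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("ensemble", "mlp"), n_trees = 100L,
                            svm_cost = 1, n_folds = 4L, mlp_max_iter = 500L,
                            seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_folds >= 2L, n_trees >= 1L, svm_cost > 0)
  structure(list(kind = kind, n_trees = as.integer(n_trees),
                 svm_cost = svm_cost, n_folds = as.integer(n_folds),
                 mlp_max_iter = as.integer(mlp_max_iter),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

# Stratified fold assignment: per class, shuffle then deal round-robin.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated classification scores for one (gene, variant) pair
#'
#' Runs stratified `n_folds`-fold cross-validation (seeded by `spec$seed`).
#' Within each fold the features are z-scored with statistics fit on the
#' training rows only, the classifier is fit on the training rows (ensemble:
#' probability random forest + RBF-kernel SVM with Platt-type calibration,
#' soft vote; mlp: one hidden layer of [mlp_hidden_size()] on the flattened
#' 2D grid), and out-of-fold predictions are pooled into a single confusion
#' matrix from which macro F1 and MCC are computed.
#'
#' @param X Numeric matrix, donors x features, no missing cells. For
#'   `kind = "mlp"` attach `attr(X, "grid_dim") <- c(m, n)`.
#' @param y Binary genotype aligned with `X` rows (no missing donors).
#' @param spec A [classifier_spec()].
#' @param fold_zscore Standardize per training fold (default). Set FALSE when
#'   `X` was already standardized globally.
#' @return List with `macro_f1`, `mcc`, and the pooled `confusion` matrix, or
#'   `NULL` (with a warning) if no valid fold assignment is found in 5
#'   attempts.
#' @export
cross_validated_scores <- function(X, y, spec = classifier_spec(),
                                   fold_zscore = TRUE) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (anyNA(X)) stop("X must be complete (impute first)", call. = FALSE)
  if (anyNA(y)) {
    keep <- !is.na(y)
    X <- X[keep, , drop = FALSE]
    y <- as.integer(y[keep])
  }
  y <- as.integer(y)
  if (!eligible(y)) stop("variant not eligible: minority class < 4", call. = FALSE)

  fold <- NULL
  for (attempt in 0:4) {
    set.seed(spec$seed + 1000L * attempt)
    cand <- stratified_folds(y, spec$n_folds)
    ok <- all(vapply(seq_len(spec$n_folds), function(f) {
      length(unique(y[cand != f])) == 2L
    }, logical(1)))
    if (ok) { fold <- cand; break }
  }
  if (is.null(fold)) {
    warning("no fold assignment with both classes in every training set; variant skipped",
            call. = FALSE)
    return(NULL)
  }

  pred <- integer(length(y))
  for (f in seq_len(spec$n_folds)) {
    tr <- fold != f
    Z <- if (fold_zscore) zscore(X, stats_from = which(tr)) else X
    pred[!tr] <- if (spec$kind == "ensemble") {
      fit_predict_ensemble(Z[tr, , drop = FALSE], y[tr], Z[!tr, , drop = FALSE], spec)
    } else {
      fit_predict_mlp(Z[tr, , drop = FALSE], y[tr], Z[!tr, , drop = FALSE], spec,
                      grid_dim = attr(X, "grid_dim"))
    }
  }
  cm <- confusion_matrix(y, pred)
  list(macro_f1 = macro_f1(cm), mcc = mcc(cm), confusion = cm)
}

fit_predict_ensemble <- function(Xtr, ytr, Xte, spec) {
  dtr <- as.data.frame(Xtr)
  names(dtr) <- paste0("V", seq_len(ncol(Xtr)))
  dte <- as.data.frame(Xte)
  names(dte) <- names(dtr)
  yf <- factor(ytr, levels = c(0L, 1L))

  rf <- ranger::ranger(x = dtr, y = yf, num.trees = spec$n_trees,
                       probability = TRUE, num.threads = 1L,
                       seed = sample.int(.Machine$integer.max, 1L))
  p_rf <- stats::predict(rf, data = dte, num.threads = 1L)$predictions
  p_rf <- p_rf[, c("0", "1"), drop = FALSE]

  sv <- e1071::svm(x = Xtr, y = yf, kernel = "radial", cost = spec$svm_cost,
                   probability = TRUE, scale = FALSE)
  pred_sv <- stats::predict(sv, Xte, probability = TRUE)
  p_sv_raw <- attr(pred_sv, "probabilities")
  if (is.null(p_sv_raw)) {
    # calibration can fail on very small minority classes; fall back to the
    # hard margin prediction as a degenerate probability
    p_sv_raw <- cbind(`0` = as.numeric(pred_sv == "0"),
                      `1` = as.numeric(pred_sv == "1"))
  }
  p_sv <- p_sv_raw[, c("0", "1"), drop = FALSE]

  soft_vote(list(unname(p_rf), unname(p_sv)))
}

fit_predict_mlp <- function(Xtr, ytr, Xte, spec, grid_dim = NULL) {
  if (is.null(grid_dim)) {
    # treat a flat feature vector as a 1 x p grid
    grid_dim <- c(1L, ncol(Xtr))
  }
  h <- mlp_hidden_size(grid_dim[1L], grid_dim[2L])
  ytab <- cbind(`0` = as.integer(ytr == 0L), `1` = as.integer(ytr == 1L))
  fit <- nnet::nnet(x = Xtr, y = ytab, size = h, softmax = TRUE,
                    maxit = spec$mlp_max_iter, trace = FALSE, MaxNWts = 100000L)
  p <- stats::predict(fit, Xte, type = "raw")
  as.integer(p[, "1"] > p[, "0"])
}

#' Repeated cross-validation scores for one (gene, variant) pair
#'
#' Calls [cross_validated_scores()] `n_iter` times with seeds
#' `spec$seed + 0 .. n_iter - 1` and aggregates macro F1 and MCC as medians
#' across the iterations.
#'
#' @param X,y,spec,fold_zscore As in [cross_validated_scores()].
#' @param n_iter Number of repeated runs (default 3).
#' @param gene_id,variant_id Identifiers recorded in the output row.
#' @return One-row `pair_scores` data.frame with columns `gene`, `variant`,
#'   `f1_iter1..k`, `mcc_iter1..k`, `f1_median`, `mcc_median`, or `NULL` if
#'   every iteration was skipped.
#' @export
run_iterations <- function(X, y, spec = classifier_spec(), n_iter = 3L,
                           gene_id = "gene", variant_id = "variant",
                           fold_zscore = TRUE) {
  f1 <- mc <- rep(NA_real_, n_iter)
  for (i in seq_len(n_iter)) {
    it_spec <- spec
    it_spec$seed <- spec$seed + i - 1L
    res <- cross_validated_scores(X, y, it_spec, fold_zscore = fold_zscore)
    if (is.null(res)) return(NULL)
    f1[i] <- res$macro_f1
    mc[i] <- res$mcc
  }
  row <- data.frame(gene = gene_id, variant = variant_id,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n_iter)) row[[paste0("f1_iter", i)]] <- f1[i]
  for (i in seq_len(n_iter)) row[[paste0("mcc_iter", i)]] <- mc[i]
  row$f1_median <- stats::median(f1)
  row$mcc_median <- stats::median(mc)
  class(row) <- c("pair_scores", "data.frame")
  row
}

#' Rank (gene, variant) pairs by classification performance
#'
#' Descending by the chosen metric; ties broken by the other metric
#' (descending), then by variant ID (ascending) for a deterministic order.
#'
#' @param scores A `pair_scores` data.frame (rows from [run_iterations()]).
#' @param metric `"f1_median"` or `"mcc_median"`.
#' @return The reordered `pair_scores` data.frame.
#' @export
rank_pairs <- function(scores, metric = c("f1_median", "mcc_median")) {
  metric <- match.arg(metric)
  other <- setdiff(c("f1_median", "mcc_median"), metric)
  ord <- order(-scores[[metric]], -scores[[other]], scores$variant)
  out <- scores[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
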