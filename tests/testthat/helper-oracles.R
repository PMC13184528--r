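# Independent oracles used to cross-check package computations.

# Brute-force macro F1 from raw label vectors: per-class precision/recall by
# direct counting, no confusion-matrix arithmetic shared with the package.
oracle_macro_f1 <- function(truth, pred) {
  f1_of <- function(cls) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(truth)) {
      if (pred[i] == cls && truth[i] == cls) tp <- tp + 1
      if (pred[i] == cls && truth[i] != cls) fp <- fp + 1
      if (pred[i] != cls && truth[i] == cls) fn <- fn + 1
    }
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }
  (f1_of(0) + f1_of(1)) / 2
}

# Brute-force MCC as the Pearson correlation of the two binary vectors
# (an algebraically equivalent but independently coded route); degenerate
# vectors map to 0 as the package defines.
oracle_mcc <- function(truth, pred) {
  if (length(unique(truth)) < 2 || length(unique(pred)) < 2) return(0)
  stats::cor(truth, pred)
}

# Exhaustive two-sided Fisher p for a 2x2 table: sum over the hypergeometric
# support of all tables at most as probable as the observed one.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b  # row 1
  n <- c + d  # row 2
  k <- a + c  # col 1
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# A small complete genotype_set for evaluate/preprocess tests.
toy_gset <- function(dosage, chrom = "1", pos = NULL, ids = NULL) {
  n_var <- nrow(dosage)
  if (is.null(pos)) pos <- seq_len(n_var) * 1000L
  if (is.null(ids)) {
    ids <- if (!is.null(rownames(dosage))) rownames(dosage)
           else paste0("v", seq_len(n_var))
  }
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- paste0("D", seq_len(ncol(dosage)))
  }
  rownames(dosage) <- ids
  genotype_set(
    data.frame(variant_id = ids, chrom = rep_len(chrom, n_var), pos = pos,
               ref = "A", alt = "G", stringsAsFactors = FALSE),
    dosage)
}

fixture <- function(name) {
  system.file("extdata", name, package = "mtclass", mustWork = TRUE)
}
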