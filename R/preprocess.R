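#' Select variable genes across all samples
#'
#' Two-stage filter used before cis-eQTL testing: genes with expression equal
#' to zero in more than half of the samples are removed, then the top 50% of
#' the survivors by across-sample variance are kept (ceiling on odd counts;
#' variance ties broken by gene ID so the cut is deterministic).
#'
#' @param expr Numeric matrix, samples x genes (column names are gene IDs).
#' @return Character vector of kept gene IDs.
#' @export
select_variable_genes <- function(expr) {
  stopifnot(is.matrix(expr), ncol(expr) >= 1L, nrow(expr) >= 2L)
  zero_frac <- colMeans(expr == 0, na.rm = TRUE)
  surv <- colnames(expr)[zero_frac <= 0.5]
  if (length(surv) == 0L) {
    warning("all genes removed by the zero-expression filter", call. = FALSE)
    return(character(0))
  }
  v <- apply(expr[, surv, drop = FALSE], 2, stats::var, na.rm = TRUE)
  n_keep <- ceiling(length(surv) / 2)
  ord <- order(-v, surv)
  sort(surv[ord[seq_len(n_keep)]])
}

#' Extract candidate cis-eQTLs for a gene
#'
#' Keeps variants on the gene's chromosome whose position lies within
#' `window` bp of the gene body (inclusive at both bounds) and whose minor
#' allele frequency, computed from non-missing dosages as
#' `min(p, 1 - p)` with `p = sum(dosage) / (2 * n_called)`, is at least
#' `maf_min`. Variants with zero called genotypes are dropped with a warning.
#'
#' @param gset A [genotype_set()].
#' @param gene A list or one-row data.frame with `gene_id`, `chrom`, `start`,
#'   `end` (1-based inclusive gene-body span).
#' @param window Flanking window in bp (default 10 kb).
#' @param maf_min Minimum minor allele frequency (default 0.05, inclusive).
#' @return A [genotype_set()] restricted to the kept variants.
#' @export
extract_cis_variants <- function(gset, gene, window = 10000L, maf_min = 0.05) {
  stopifnot(inherits(gset, "genotype_set"))
  if (gene$start > gene$end) stop("gene start must be <= end", call. = FALSE)
  v <- gset$variants
  in_win <- v$chrom == gene$chrom &
    v$pos >= gene$start - window & v$pos <= gene$end + window
  maf <- variant_maf(gset$dosage)
  uncalled <- in_win & is.na(maf)
  if (any(uncalled)) {
    warning(sum(uncalled), " cis variant(s) with zero called genotypes dropped",
            call. = FALSE)
  }
  keep <- in_win & !is.na(maf) & maf >= maf_min
  genotype_set(v[keep, , drop = FALSE], gset$dosage[keep, , drop = FALSE])
}

#' Minor allele frequency per variant
#'
#' @param dosage Variants x donors dosage matrix (0/1/2/NA).
#' @return Numeric vector of MAFs (`NA` where no genotype is called).
#' @export
variant_maf <- function(dosage) {
  n_called <- rowSums(!is.na(dosage))
  p <- rowSums(dosage, na.rm = TRUE) / (2 * n_called)
  p[n_called == 0L] <- NA_real_
  pmin(p, 1 - p)
}

#' Filter variants and donors by genotyping call rate
#'
#' Restricts to autosomes, then removes variants with call rate below
#' `threshold` (boundary kept), then removes donors with call rate below
#' `threshold` over the remaining variants.
#'
#' @param gset A [genotype_set()].
#' @param threshold Minimum call rate (default 0.90).
#' @param autosomes_only Drop non-autosomal variants first (default TRUE).
#' @return Filtered [genotype_set()].
#' @export
filter_call_rate <- function(gset, threshold = 0.90, autosomes_only = TRUE) {
  stopifnot(inherits(gset, "genotype_set"))
  v <- gset$variants
  d <- gset$dosage
  if (autosomes_only) {
    auto <- grepl("^(chr)?([1-9]|1[0-9]|2[0-2])$", v$chrom)
    v <- v[auto, , drop = FALSE]
    d <- d[auto, , drop = FALSE]
  }
  if (nrow(d) > 0L) {
    vr <- rowMeans(!is.na(d))
    keep_v <- vr >= threshold
    v <- v[keep_v, , drop = FALSE]
    d <- d[keep_v, , drop = FALSE]
  }
  if (nrow(d) == 0L) stop("no variants survive the call-rate filter", call. = FALSE)
  dr <- colMeans(!is.na(d))
  keep_d <- dr >= threshold
  if (!any(keep_d)) stop("no donors survive the call-rate filter", call. = FALSE)
  genotype_set(v, d[, keep_d, drop = FALSE])
}

#' Collapse dosages to a dominant-model binary genotype
#'
#' Carriers of at least one alternate allele (dosage 1 or 2) are coded 1,
#' reference homozygotes 0; missing stays missing. The minority-class count
#' (over non-missing donors) is attached as attribute `minority_count`.
#'
#' @param dosages Numeric/integer vector of dosages in \{0,1,2,NA\} (one
#'   variant across donors). Already-binary input is returned unchanged
#'   (idempotent).
#' @return Integer vector in \{0,1,NA\} of class `binary_genotype`, with
#'   attribute `minority_count`.
#' @export
binarize_dominant <- function(dosages) {
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    stop("dosages must lie in {0,1,2,NA}", call. = FALSE)
  }
  y <- as.integer(dosages >= 1)
  names(y) <- names(dosages)
  structure(y, minority_count = min(sum(y == 0L, na.rm = TRUE),
                                    sum(y == 1L, na.rm = TRUE)),
            class = "binary_genotype")
}

#' Minority-class count of a binary genotype
#'
#' @param y A [binarize_dominant()] result or plain 0/1 vector.
#' @return Integer minority count over non-missing donors.
#' @export
minority_count <- function(y) {
  mc <- attr(y, "minority_count")
  if (!is.null(mc)) return(mc)
  min(sum(y == 0L, na.rm = TRUE), sum(y == 1L, na.rm = TRUE))
}

#' Aggregate single-cell expression to donor x cell-type pseudobulk
#'
#' For each (donor, cell type), sums the normalized expression of all cells of
#' that type, and keeps only cell types observed in every donor so the
#' resulting feature matrix has no missing cells.
#'
#' @param cells data.frame with columns `donor`, `cell_type`, `value`
#'   (normalized expression of one gene per cell). An optional `gene` column
#'   may hold several genes, in which case a named list of matrices is
#'   returned.
#' @return Donor x cell-type numeric matrix (or a named list of them).
#' @export
pseudobulk <- function(cells) {
  stopifnot(all(c("donor", "cell_type", "value") %in% names(cells)))
  if ("gene" %in% names(cells) && length(unique(cells$gene)) > 1L) {
    return(lapply(split(cells, cells$gene), pseudobulk))
  }
  donors <- sort(unique(cells$donor))
  agg <- tapply(cells$value, list(cells$donor, cells$cell_type), sum)
  full <- colSums(is.na(agg)) == 0L
  if (!any(full)) stop("no cell type is observed in every donor", call. = FALSE)
  agg[donors, full, drop = FALSE]
}

#' Select highly variable genes from a cell table
#'
#' Ranks genes by the variance of their normalized expression across all
#' cells (cells where a gene is unrecorded count as zero, the sparse-matrix
#' convention) and keeps the `n_top` most variable. Ties at the boundary are
#' broken by lexicographic gene ID.
#'
#' @param cells data.frame with columns `cell`, `gene`, `value`.
#' @param n_top Number of genes to keep (default 3000).
#' @return Character vector of kept gene IDs.
#' @export
select_hvg <- function(cells, n_top = 3000L) {
  stopifnot(all(c("cell", "gene", "value") %in% names(cells)))
  n_cells <- length(unique(cells$cell))
  s1 <- tapply(cells$value, cells$gene, sum)
  s2 <- tapply(cells$value^2, cells$gene, sum)
  v <- (s2 - s1^2 / n_cells) / (n_cells - 1)
  genes <- names(v)
  if (length(genes) < n_top) {
    warning("fewer genes than n_top; keeping all", call. = FALSE)
    n_top <- length(genes)
  }
  ord <- order(-v, genes)
  sort(genes[ord[seq_len(n_top)]])
}

#' Z-score standardize a feature matrix
#'
#' Each feature (column) is centered and scaled using the population standard
#' deviation (denominator `n`). When `stats_from` is given, the mean and SD
#' are estimated on those rows only (the training fold) and applied to all
#' rows, keeping cross-validation leakage-free. Zero-variance features map to
#' all-zeros.
#'
#' @param X Numeric matrix, donors x features, no missing cells.
#' @param stats_from Optional row indices used to estimate the statistics.
#' @return Standardized matrix of the same shape.
#' @export
zscore <- function(X, stats_from = NULL) {
  stopifnot(is.matrix(X))
  if (anyNA(X)) stop("zscore requires a complete matrix (impute first)", call. = FALSE)
  ref <- if (is.null(stats_from)) X else X[stats_from, , drop = FALSE]
  n <- nrow(ref)
  mu <- colMeans(ref)
  sdp <- sqrt(pmax(colMeans(ref^2) - mu^2, 0))
  sdp[sdp < .Machine$double.eps^0.5 * (1 + abs(mu))] <- 0
  Z <- sweep(X, 2, mu, "-")
  nz <- sdp > 0
  Z[, nz] <- sweep(Z[, nz, drop = FALSE], 2, sdp[nz], "/")
  Z[, !nz] <- 0
  Z
}
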