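#' Count GWAS-catalog positions near a variant
#'
#' Number of unique catalog positions on the same chromosome within
#' `window` bp (inclusive both sides) of the variant position. Binary search
#' on the sorted per-chromosome index.
#'
#' @param chrom,pos Variant chromosome and 1-based position.
#' @param catalog A [read_gwas_catalog()] / [gwas_catalog()] index.
#' @param window Distance cutoff in bp (default 10 kb).
#' @return Integer hit count.
#' @export
gwas_hits <- function(chrom, pos, catalog, window = 10000L) {
  v <- catalog[[as.character(chrom)]]
  if (is.null(v) || length(v) == 0L) return(0L)
  findInterval(pos + window, v) - findInterval(pos - window - 1L, v)
}

#' Tie-adjusted GWAS hit count over the top N variants
#'
#' The top of a ranking may end inside a block of tied scores, so exactly N
#' variants cannot always be selected. Let M be the smallest prefix length
#' that is at least N and does not bisect a tied score block; the raw hit
#' count (sum of [gwas_hits()] over the M variants) is rescaled by `N / M`.
#'
#' @param ranked data.frame already sorted by the declared key, with columns
#'   `chrom`, `pos`, and `score` (the sort key values, used only to locate
#'   ties).
#' @param catalog A GWAS position index.
#' @param N Number of top variants requested.
#' @param window Colocalization window in bp.
#' @return List with `adjusted` (raw * N/M), `raw`, `M`, `N`.
#' @export
topn_adjusted_hits <- function(ranked, catalog, N, window = 10000L) {
  stopifnot(nrow(ranked) >= 1L, N >= 1L)
  n <- nrow(ranked)
  if (N > n) {
    warning("N exceeds the number of ranked variants; using all", call. = FALSE)
    N <- n
  }
  M <- N
  while (M < n && ranked$score[M + 1L] == ranked$score[M]) M <- M + 1L
  raw <- sum(vapply(seq_len(M), function(i) {
    gwas_hits(ranked$chrom[i], ranked$pos[i], catalog, window)
  }, integer(1)))
  list(adjusted = raw * N / M, raw = raw, M = M, N = N)
}

#' Cumulative tie-adjusted GWAS hit curve
#'
#' Evaluates [topn_adjusted_hits()] over a grid of prefix sizes, producing the
#' cumulative colocalization curve used to compare ranking methods.
#'
#' @inheritParams topn_adjusted_hits
#' @param N_grid Integer vector of prefix sizes.
#' @return data.frame with columns `N`, `M`, `raw`, `adjusted`.
#' @export
gwas_hit_curve <- function(ranked, catalog, N_grid, window = 10000L) {
  rows <- lapply(N_grid, function(N) {
    h <- topn_adjusted_hits(ranked, catalog, N, window)
    data.frame(N = h$N, M = h$M, raw = h$raw, adjusted = h$adjusted)
  })
  do.call(rbind, rows)
}

#' Overlap of top-ranked eGenes with a disease gene list
#'
#' Disease genes absent from the background (tested) gene list are filtered
#' out, the first `top` unique gene IDs are taken in rank order, and the
#' overlap size is returned.
#'
#' @param ranked_genes Character vector of gene IDs in rank order (repeats
#'   allowed: a gene with several eQTLs counts once, at its best rank).
#' @param disease_genes Character vector of disease-associated genes.
#' @param background_genes Character vector of all tested genes.
#' @param top Number of unique top genes to take (default 100).
#' @return Integer overlap count.
#' @export
overlap_top_genes <- function(ranked_genes, disease_genes, background_genes,
                              top = 100L) {
  disease <- intersect(disease_genes, background_genes)
  uniq <- unique(ranked_genes)
  if (length(uniq) < top) {
    warning("fewer than ", top, " unique genes; using all", call. = FALSE)
    top <- length(uniq)
  }
  length(intersect(uniq[seq_len(top)], disease))
}

#' Chromatin-state label for variant positions
#'
#' @param chrom,pos Parallel vectors of variant coordinates (1-based).
#' @param states `GRanges` of state segments from [read_bed_states()].
#' @return Character vector of state labels (`"Unannotated"` where no segment
#'   covers the position).
#' @export
state_labels <- function(chrom, pos, states) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hit <- GenomicRanges::findOverlaps(q, states, select = "first")
  lab <- rep("Unannotated", length(q))
  ok <- !is.na(hit)
  lab[ok] <- states$state[hit[ok]]
  lab
}

#' Chromatin-state enrichment of top variants
#'
#' For each state, builds the 2x2 table of top vs background (all tested
#' minus top) variants inside vs outside the state, computes the two-sided
#' Fisher exact p-value and odds ratio (Haldane 0.5 correction on zero
#' cells), and applies Benjamini-Hochberg correction across states (one call
#' = one tissue).
#'
#' @param top data.frame of top variants with columns `variant_id`, `chrom`,
#'   `pos`; must be a subset of `all_tested`.
#' @param all_tested data.frame of all tested variants (same columns).
#' @param states `GRanges` from [read_bed_states()].
#' @return `enrichment_result` data.frame with columns `label`, `a`, `b`,
#'   `c`, `d`, `odds_ratio`, `fisher_p`, `fdr_q`.
#' @export
chromatin_enrichment <- function(top, all_tested, states) {
  if (!all(top$variant_id %in% all_tested$variant_id)) {
    stop("top variants must be a subset of all tested variants", call. = FALSE)
  }
  bg <- all_tested[!(all_tested$variant_id %in% top$variant_id), , drop = FALSE]
  lab_top <- state_labels(top$chrom, top$pos, states)
  lab_bg <- state_labels(bg$chrom, bg$pos, states)
  labels <- sort(unique(c(lab_top, lab_bg)))
  rows <- lapply(labels, function(s) {
    a <- sum(lab_top == s); b <- nrow(top) - a
    cc <- sum(lab_bg == s); d <- nrow(bg) - cc
    ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))
    data.frame(label = s, a = a, b = b, c = cc, d = d,
               odds_ratio = odds_ratio_2x2(a, b, cc, d),
               fisher_p = ft$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_q <- stats::p.adjust(out$fisher_p, method = "BH")
  class(out) <- c("enrichment_result", "data.frame")
  out
}

# Cross-product odds ratio with Haldane-Anscombe 0.5 correction whenever a
# zero cell would make it 0/0, 0 or infinite.
odds_ratio_2x2 <- function(a, b, c, d) {
  if (min(a, b, c, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

#' Prune variants in high linkage disequilibrium
#'
#' Scans variants in genomic order; a variant is dropped when its squared
#' Pearson correlation with any retained variant among the previous
#' `window_variants` exceeds `r2_max` (strict inequality: r-squared exactly at
#' the threshold is kept). Genotypes may be dosages or binarized; r-squared
#' against a zero-variance vector is defined as 0.
#'
#' @param gset A [genotype_set()] (variants assumed sorted by chrom, pos; they
#'   are re-sorted defensively).
#' @param r2_max LD threshold (default 0.50).
#' @param window_variants Sliding-window size in variants (default 200).
#' @return A [genotype_set()] of the retained variants.
#' @export
ld_prune <- function(gset, r2_max = 0.50, window_variants = 200L) {
  v <- gset$variants
  ord <- order(v$chrom, v$pos)
  v <- v[ord, , drop = FALSE]
  d <- gset$dosage[ord, , drop = FALSE]
  n <- nrow(v)
  kept <- integer(0)
  for (i in seq_len(n)) {
    recent <- kept[kept >= i - window_variants & v$chrom[kept] == v$chrom[i]]
    drop_i <- FALSE
    for (j in recent) {
      r2 <- r2_genotype(d[i, ], d[j, ])
      # strict > threshold; the epsilon keeps pairs whose r2 equals the
      # threshold exactly up to double rounding
      if (r2 > r2_max + 1e-12) { drop_i <- TRUE; break }
    }
    if (!drop_i) kept <- c(kept, i)
  }
  genotype_set(v[kept, , drop = FALSE], d[kept, , drop = FALSE])
}

# Squared Pearson correlation over jointly non-missing donors; 0 when either
# vector is degenerate.
r2_genotype <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(0)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' Differential eQTLs: strong by classification, weak by linear tests
#'
#' Variants whose median macro F1 is at or above the `f1_pct` percentile of
#' the classification scores while every baseline method's p-value is at or
#' above its own `p_pct` percentile. Percentiles are computed on the shared
#' (e.g. post-LD-pruning) variant universe.
#'
#' @param scores `pair_scores` data.frame (`variant`, `f1_median`).
#' @param baselines `assoc_result` data.frame (`variant`, `method`,
#'   `p_value`), possibly several methods.
#' @param f1_pct Percentile for the classification score (default 90).
#' @param p_pct Percentile for baseline p-values (default 10).
#' @return Character vector of differential variant IDs.
#' @export
differential_eqtls <- function(scores, baselines, f1_pct = 90, p_pct = 10) {
  universe <- scores$variant
  for (m in unique(baselines$method)) {
    universe <- intersect(universe, baselines$variant[baselines$method == m])
  }
  if (length(universe) == 0L) stop("empty variant universe intersection", call. = FALSE)
  sc <- scores[match(universe, scores$variant), ]
  sel <- sc$f1_median >= stats::quantile(sc$f1_median, f1_pct / 100)
  for (m in unique(baselines$method)) {
    bm <- baselines[baselines$method == m, ]
    pm <- bm$p_value[match(universe, bm$variant)]
    sel <- sel & pm >= stats::quantile(pm, p_pct / 100)
  }
  universe[sel]
}

#' Canonical MHC region (GRCh38)
#'
#' @return List with `chrom`, `start`, `end` for chr6:28,477,797-33,448,354.
#' @export
mhc_region <- function() {
  list(chrom = "6", start = 28477797L, end = 33448354L)
}

#' Enrichment of a selected variant set in a genomic region
#'
#' Compares the proportion of selected variants inside the region against the
#' proportion over the whole tested universe (the selected set is part of the
#' universe, matching the top-vs-genome-wide contrast): Fisher's exact test
#' on the 2x2 table `[[k, n-k], [K, N-K]]` and the cross-product odds ratio,
#' which equals `[p1/(1-p1)] / [p2/(1-p2)]` for the two proportions.
#'
#' @param selected Character vector of selected variant IDs (subset of the
#'   universe).
#' @param universe data.frame of all tested variants: `variant_id`, `chrom`,
#'   `pos`.
#' @param region List with `chrom`, `start`, `end` (1-based inclusive);
#'   default [mhc_region()].
#' @return `enrichment_result` data.frame (one row; `label` is
#'   `"chrom:start-end"`).
#' @export
region_enrichment <- function(selected, universe, region = mhc_region()) {
  stopifnot(all(selected %in% universe$variant_id))
  if (region$end < region$start) stop("empty region", call. = FALSE)
  chrom_match <- sub("^chr", "", universe$chrom) == sub("^chr", "", region$chrom)
  in_region <- chrom_match & universe$pos >= region$start & universe$pos <= region$end
  is_sel <- universe$variant_id %in% selected
  k <- sum(is_sel & in_region); n <- sum(is_sel)
  K <- sum(in_region); N <- nrow(universe)
  ft <- stats::fisher.test(matrix(c(k, n - k, K, N - K), 2, byrow = TRUE))
  out <- data.frame(label = paste0(region$chrom, ":", region$start, "-", region$end),
                    a = k, b = n - k, c = K, d = N - K,
                    odds_ratio = odds_ratio_2x2(k, n - k, K, N - K),
                    fisher_p = ft$p.value, fdr_q = ft$p.value,
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}
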