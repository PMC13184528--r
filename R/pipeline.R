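#' Assemble a pipeline run configuration
#'
#' Collects paths, thresholds, the classifier specification, and the global
#' seed for one pipeline run. The configuration is serialized verbatim into a
#' JSON sidecar next to every output, so any output can be regenerated from
#' its sidecar alone.
#'
#' @param genotypes Path to a VCF (`.vcf`/`.vcf.gz`) or internal genotype TSV.
#' @param expression Path to the donor x feature expression TSV (the feature
#'   vector of one gene).
#' @param gene_id Gene identifier recorded in the output.
#' @param gene Optional gene model (list with `gene_id`, `chrom`, `start`,
#'   `end`); when given, candidate variants are restricted to the cis window.
#' @param window_bp cis-window size (default 10000).
#' @param maf_min MAF threshold (default 0.05).
#' @param call_rate_min Genotyping-rate threshold (default 0.90).
#' @param min_minority Minority-class eligibility threshold (default 4).
#' @param n_iterations Repeated CV runs per pair (default 3).
#' @param classifier A [classifier_spec()].
#' @param impute Whether to run [impute_pmm()] when the expression matrix has
#'   missing cells (default TRUE).
#' @param global_zscore If TRUE, features are standardized once on all donors
#'   instead of per training fold (the leakage-prone but literal reading;
#'   default FALSE).
#' @param threads Worker processes for per-pair parallelism (default 1;
#'   results are identical for any worker count).
#' @param seed Global seed.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(genotypes, expression, gene_id = "gene", gene = NULL,
                       window_bp = 10000L, maf_min = 0.05,
                       call_rate_min = 0.90, min_minority = 4L,
                       n_iterations = 3L, classifier = classifier_spec(),
                       impute = TRUE, global_zscore = FALSE, threads = 1L,
                       seed = 1L, out_dir = ".") {
  stopifnot(maf_min >= 0, maf_min <= 0.5, call_rate_min >= 0,
            call_rate_min <= 1, n_iterations >= 1L, threads >= 1L)
  structure(list(genotypes = genotypes, expression = expression,
                 gene_id = gene_id, gene = gene,
                 window_bp = as.integer(window_bp), maf_min = maf_min,
                 call_rate_min = call_rate_min,
                 min_minority = as.integer(min_minority),
                 n_iterations = as.integer(n_iterations),
                 classifier = unclass(classifier), impute = impute,
                 global_zscore = global_zscore, threads = as.integer(threads),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# Deterministic per-pair seed: global seed plus a polynomial hash of the
# variant ID, independent of worker scheduling.
derive_seed <- function(seed, id) {
  h <- 0
  for (ch in utf8ToInt(id)) h <- (h * 31 + ch) %% 2147483647
  as.integer((seed + h) %% 2147483647)
}

read_genotypes_any <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) read_vcf(path) else read_genotype_tsv(path)
}

#' Run the full genotype-classification pipeline for one gene
#'
#' Reads genotypes and the gene's expression features, applies the call-rate
#' and autosome filters, restricts to the cis window and MAF threshold (when
#' a gene model is given), imputes missing expression if requested,
#' dominant-binarizes each variant, skips ineligible variants, scores each
#' (gene, variant) pair with repeated stratified cross-validation, and writes
#' the ranked scores TSV plus a JSON sidecar holding the full configuration
#' and the per-filter exclusion counts.
#'
#' @param config A [run_config()].
#' @return The ranked `pair_scores` data.frame, invisibly; side effects:
#'   `<out_dir>/scores.tsv` and `<out_dir>/scores.json`.
#' @export
mtclass_classify <- function(config) {
  stopifnot(inherits(config, "run_config"))
  gset <- read_genotypes_any(config$genotypes)
  X <- read_expression(config$expression)
  n_input <- nrow(gset$variants)

  gset <- filter_call_rate(gset, threshold = config$call_rate_min)
  n_call <- nrow(gset$variants)
  if (!is.null(config$gene)) {
    gset <- extract_cis_variants(gset, config$gene, window = config$window_bp,
                                 maf_min = config$maf_min)
  } else {
    maf <- variant_maf(gset$dosage)
    keep <- !is.na(maf) & maf >= config$maf_min
    gset <- genotype_set(gset$variants[keep, , drop = FALSE],
                         gset$dosage[keep, , drop = FALSE])
  }
  n_cis <- nrow(gset$variants)

  donors <- intersect(colnames(gset$dosage), rownames(X))
  if (length(donors) == 0L) {
    stop("no donors shared between genotypes and expression", call. = FALSE)
  }
  X <- X[donors, , drop = FALSE]
  dosage <- gset$dosage[, donors, drop = FALSE]

  if (anyNA(X)) {
    if (!config$impute) stop("expression has missing cells and impute = FALSE", call. = FALSE)
    X <- impute_pmm(X, seed = config$seed)
  }

  spec <- do.call(classifier_spec, config$classifier[
    c("kind", "n_trees", "svm_cost", "n_folds", "mlp_max_iter", "seed")])
  if (config$global_zscore) X <- zscore(X)

  ids <- gset$variants$variant_id
  skipped <- character(0)
  score_one <- function(vid) {
    y <- binarize_dominant(dosage[vid, ])
    if (!eligible(y, config$min_minority)) {
      return(list(row = NULL, skip = "minority"))
    }
    keep <- !is.na(y)
    sp <- spec
    sp$seed <- derive_seed(config$seed, vid)
    row <- run_iterations(X[keep, , drop = FALSE], as.integer(y[keep]), sp,
                          n_iter = config$n_iterations,
                          gene_id = config$gene_id, variant_id = vid,
                          fold_zscore = !config$global_zscore)
    list(row = row, skip = if (is.null(row)) "refold" else NA_character_)
  }
  results <- if (config$threads > 1L) {
    parallel::mclapply(ids, score_one, mc.cores = config$threads)
  } else {
    lapply(ids, score_one)
  }
  rows <- Filter(Negate(is.null), lapply(results, `[[`, "row"))
  skipped <- ids[vapply(results, function(r) !is.na(r$skip) && is.null(r$row),
                        logical(1))]
  if (length(rows) == 0L) stop("no eligible variants to score", call. = FALSE)
  scores <- do.call(rbind, rows)
  class(scores) <- c("pair_scores", "data.frame")
  scores <- rank_pairs(scores)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out_tsv <- file.path(config$out_dir, "scores.tsv")
  write_scores(scores, out_tsv)
  sidecar <- list(
    config = unclass(config),
    counts = list(input_variants = n_input,
                  after_call_rate = n_call,
                  after_cis_maf = n_cis,
                  skipped_ineligible = length(skipped),
                  scored = nrow(scores)),
    skipped_variants = as.list(skipped)
  )
  jsonlite::write_json(sidecar, file.path(config$out_dir, "scores.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  message("scored ", nrow(scores), "/", n_input, " variants (",
          length(skipped), " ineligible)")
  invisible(scores)
}

#' Run the linear baseline tests for one gene
#'
#' Same input handling as [mtclass_classify()], but each eligible variant is
#' tested with two-group MANOVA, reverse logistic regression, and the Cauchy
#' combination of per-feature Welch t-tests.
#'
#' @param config A [run_config()].
#' @param methods Subset of `c("manova", "reverse_logistic", "cauchy")`.
#' @return `assoc_result` data.frame, invisibly; writes
#'   `<out_dir>/baselines.tsv` (+ `.json` sidecar).
#' @export
mtclass_baselines <- function(config,
                              methods = c("manova", "reverse_logistic", "cauchy")) {
  stopifnot(inherits(config, "run_config"))
  methods <- match.arg(methods, several.ok = TRUE)
  gset <- read_genotypes_any(config$genotypes)
  X <- read_expression(config$expression)
  gset <- filter_call_rate(gset, threshold = config$call_rate_min)
  donors <- intersect(colnames(gset$dosage), rownames(X))
  if (length(donors) == 0L) stop("no donors shared", call. = FALSE)
  X <- X[donors, , drop = FALSE]
  if (anyNA(X)) X <- impute_pmm(X, seed = config$seed)
  rows <- list()
  for (vid in gset$variants$variant_id) {
    y <- binarize_dominant(gset$dosage[vid, donors])
    if (!eligible(y, config$min_minority)) next
    keep <- !is.na(y)
    Xi <- X[keep, , drop = FALSE]
    yi <- as.integer(y[keep])
    for (m in methods) {
      res <- tryCatch(switch(m,
        manova = manova_test(Xi, yi, config$gene_id, vid),
        reverse_logistic = reverse_logistic_test(Xi, yi, config$gene_id, vid),
        cauchy = cauchy_test(Xi, yi, config$gene_id, vid)),
        error = function(e) NULL)
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0L) stop("no baseline results produced", call. = FALSE)
  out <- do.call(rbind, rows)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(out, file.path(config$out_dir, "baselines.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(config = unclass(config), methods = methods),
                       file.path(config$out_dir, "baselines.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(out)
}
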