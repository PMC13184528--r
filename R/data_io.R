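#' Read genotypes from a VCF file
#'
#' Parses a VCF (4.x) with [vcfR::read.vcfR()] and collapses diploid GT calls
#' to alternate-allele dosages: `0/0 -> 0`, `0/1 -> 1`, `1/1 -> 2`,
#' `./.` (or any half-missing call) -> `NA`. Phased separators (`|`) are
#' treated like unphased ones.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param region Optional region string `"chrom:start-end"` (1-based,
#'   inclusive); only variants inside it are returned.
#' @param multiallelic How to handle sites with more than one ALT allele:
#'   `"skip"` (default; dropped with a warning) or `"split"` (one record per
#'   ALT allele, dosage counting that allele only).
#' @return A `genotype_set`: a list with `$variants` (data.frame with columns
#'   `variant_id`, `chrom`, `pos`, `ref`, `alt`) and `$dosage` (integer matrix,
#'   variants x donors, values 0/1/2/NA). Variant IDs default to
#'   `chrom_pos_ref_alt` when the VCF ID column is missing (`.`).
#' @export
read_vcf <- function(path, region = NULL, multiallelic = c("skip", "split")) {
  multiallelic <- match.arg(multiallelic)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e), call. = FALSE)
  )
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(genotype_set(empty_variant_table(), matrix(integer(0), 0, 0)))
  }
  if (is.null(vcf@gt) || ncol(vcf@gt) < 2L) {
    stop("VCF '", path, "' carries no genotype columns", call. = FALSE)
  }
  fmt_field <- vcf@gt[, 1L]
  if (!all(grepl("(^|:)GT(:|$)", fmt_field))) {
    bad <- which(!grepl("(^|:)GT(:|$)", fmt_field))[1L]
    stop("VCF '", path, "': no GT field for variant record ", bad, call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  donors <- colnames(gt)

  pos <- as.integer(fix$POS)
  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
    if (length(m) != 4L) stop("region must be 'chrom:start-end'", call. = FALSE)
    keep <- fix$CHROM == m[2L] & pos >= as.integer(m[3L]) & pos <= as.integer(m[4L])
  }

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  rows <- list()
  dose <- list()
  for (i in which(keep)) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    if (length(alts) > 1L && multiallelic == "skip") next
    for (a in seq_along(alts)) {
      id <- fix$ID[i]
      if (is.na(id) || id == ".") id <- paste(fix$CHROM[i], pos[i], fix$REF[i], alts[a], sep = "_")
      if (length(alts) > 1L) id <- paste0(id, "_alt", a)
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = id, chrom = fix$CHROM[i], pos = pos[i],
        ref = fix$REF[i], alt = alts[a], stringsAsFactors = FALSE
      )
      dose[[length(dose) + 1L]] <- gt_to_dosage(gt[i, ], allele = a)
    }
  }
  if (any(multi & keep) && multiallelic == "skip") {
    warning(sum(multi & keep), " multiallelic site(s) skipped", call. = FALSE)
  }
  if (length(rows) == 0L) {
    return(genotype_set(empty_variant_table(), matrix(integer(0), 0, length(donors),
                                                      dimnames = list(NULL, donors))))
  }
  variants <- do.call(rbind, rows)
  dosage <- do.call(rbind, dose)
  dimnames(dosage) <- list(variants$variant_id, donors)
  genotype_set(variants, dosage)
}

empty_variant_table <- function() {
  data.frame(variant_id = character(0), chrom = character(0), pos = integer(0),
             ref = character(0), alt = character(0), stringsAsFactors = FALSE)
}

#' @keywords internal
gt_to_dosage <- function(gt, allele = 1L) {
  out <- rep(NA_integer_, length(gt))
  ok <- !is.na(gt) & gt != "." & gt != "./." & gt != ".|."
  parts <- strsplit(gt[ok], "[/|]")
  out[ok] <- vapply(parts, function(p) {
    if (any(p == ".")) return(NA_integer_)
    sum(p == as.character(allele))
  }, integer(1))
  names(out) <- names(gt)
  out
}

#' Construct a genotype set
#'
#' A `genotype_set` couples a variant table with a variants x donors dosage
#' matrix. Donor order is shared by all variants (a dataset-wide invariant).
#'
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`.
#' @param dosage integer matrix (variants x donors), values in \{0,1,2,NA\}.
#' @return An object of class `genotype_set`.
#' @export
genotype_set <- function(variants, dosage) {
  stopifnot(is.data.frame(variants), is.matrix(dosage),
            nrow(variants) == nrow(dosage))
  if (nrow(variants) > 0L) {
    if (any(variants$pos < 1L)) stop("variant positions must be >= 1", call. = FALSE)
    vals <- dosage[!is.na(dosage)]
    if (length(vals) && !all(vals %in% c(0L, 1L, 2L))) {
      stop("dosages must lie in {0,1,2,NA}", call. = FALSE)
    }
    if (anyDuplicated(variants$variant_id)) stop("duplicate variant IDs", call. = FALSE)
  }
  structure(list(variants = variants, dosage = dosage), class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat("genotype_set:", nrow(x$variants), "variants x", ncol(x$dosage), "donors\n")
  invisible(x)
}

#' Read genotypes from the internal TSV dialect
#'
#' A fixture-friendly flat format: columns `variant_id`, `chrom`, `pos`,
#' `ref`, `alt`, then one column per donor holding dosages 0/1/2 (empty or
#' `NA` for missing).
#'
#' @param path Path to the TSV.
#' @return A [genotype_set()].
#' @export
read_genotype_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("variant_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df))) {
    stop("genotype TSV must carry columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  donors <- setdiff(names(df), need)
  dosage <- as.matrix(df[, donors, drop = FALSE])
  storage.mode(dosage) <- "integer"
  rownames(dosage) <- df$variant_id
  variants <- df[, need]
  variants$pos <- as.integer(variants$pos)
  for (col in c("variant_id", "chrom", "ref", "alt")) {
    variants[[col]] <- as.character(variants[[col]])
  }
  genotype_set(variants, dosage)
}

#' Write a genotype set to the internal TSV dialect
#'
#' @param gset A [genotype_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(gset, path) {
  df <- cbind(gset$variants, as.data.frame(gset$dosage, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a donor x feature expression matrix
#'
#' Expects a TSV whose header row names the features and whose first column
#' holds donor IDs. Missing cells are the literal `NA` (or empty). Any other
#' non-numeric cell is an error naming its coordinates.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix (donors x features) with `NA` marking missing cells.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("expression TSV needs a donor column plus >=1 feature", call. = FALSE)
  donors <- df[[1L]]
  if (anyDuplicated(donors)) {
    stop("duplicated donor ID(s): ",
         paste(unique(donors[duplicated(donors)]), collapse = ", "), call. = FALSE)
  }
  vals <- df[, -1L, drop = FALSE]
  X <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(donors, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    cell <- vals[[j]]
    miss <- is.na(cell) | cell == "NA" | cell == ""
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!miss & is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric cell at donor '%s', feature '%s': '%s'",
                   donors[bad[1L]], colnames(vals)[j], cell[bad[1L]]), call. = FALSE)
    }
    num[miss] <- NA_real_
    X[, j] <- num
  }
  X
}

#' Read a GWAS-catalog-style table into a position index
#'
#' Rows with a missing position are dropped; duplicate (chromosome, position)
#' entries are collapsed; positions are sorted within chromosome. The column
#' names are configurable because catalog exports vary.
#'
#' @param path Path to the TSV.
#' @param chrom_col,pos_col Column names holding chromosome and 1-based
#'   position.
#' @return A `gwas_catalog`: named list, one sorted integer vector of unique
#'   positions per chromosome.
#' @export
read_gwas_catalog <- function(path, chrom_col = "CHR_ID", pos_col = "CHR_POS") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c(chrom_col, pos_col) %in% names(df))) {
    stop("catalog lacks column(s) ", chrom_col, " / ", pos_col, call. = FALSE)
  }
  chrom <- df[[chrom_col]]
  pos <- suppressWarnings(as.integer(df[[pos_col]]))
  ok <- !is.na(pos) & !is.na(chrom) & chrom != ""
  if (!any(ok)) {
    warning("GWAS catalog has no usable rows; returning empty index", call. = FALSE)
    return(structure(list(), class = "gwas_catalog"))
  }
  idx <- lapply(split(pos[ok], chrom[ok]), function(p) sort(unique(p)))
  structure(idx, class = "gwas_catalog")
}

#' Build a GWAS position index from vectors
#'
#' @param chrom,pos Parallel vectors of chromosome labels and 1-based
#'   positions.
#' @return A `gwas_catalog` (see [read_gwas_catalog()]).
#' @export
gwas_catalog <- function(chrom, pos) {
  ok <- !is.na(pos) & !is.na(chrom)
  idx <- lapply(split(as.integer(pos[ok]), chrom[ok]), function(p) sort(unique(p)))
  structure(idx, class = "gwas_catalog")
}

#' Read chromatin-state segments from a BED file
#'
#' Loads a 4+-column BED (chrom, start, end, state label) through
#' [rtracklayer::import()], which converts the half-open 0-based BED
#' convention to 1-based closed `GRanges` coordinates. A 1-based variant
#' position `p` falls inside BED interval `(s, e]` iff `s < p <= e`, i.e.
#' `start(gr) <= p <= end(gr)` after import. Intervals must be non-overlapping
#' within a chromosome (ChromHMM segmentations are).
#'
#' @param path Path to the BED file.
#' @return A `GRanges` with metadata column `state`.
#' @export
read_bed_states <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) stop("malformed BED '", path, "': ", conditionMessage(e), call. = FALSE)
  )
  if (any(GenomicRanges::width(gr) < 1L)) {
    bad <- which(GenomicRanges::width(gr) < 1L)[1L]
    stop("BED interval ", bad, " has end <= start", call. = FALSE)
  }
  if (is.null(gr$name)) stop("BED file needs a 4th (state label) column", call. = FALSE)
  ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE)
  if (length(ov) > 0L) {
    stop("overlapping state intervals (e.g. records ",
         S4Vectors::queryHits(ov)[1L], " and ", S4Vectors::subjectHits(ov)[1L], ")",
         call. = FALSE)
  }
  gr$state <- gr$name
  gr
}

#' Write pair scores to TSV
#'
#' Emits one row per (gene, variant) pair with per-iteration macro F1 and MCC
#' columns (`f1_iter1..k`, `mcc_iter1..k`) followed by `f1_median` and
#' `mcc_median`. Numbers are printed with 6 decimals, so the file round-trips
#' losslessly at that precision.
#'
#' @param scores A `pair_scores` data.frame as returned by [run_iterations()]
#'   / [rank_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  num <- vapply(scores, is.numeric, logical(1))
  out <- scores
  out[num] <- lapply(out[num], function(x) sprintf("%.6f", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pair scores written by [write_scores()]
#'
#' @param path Path to the scores TSV.
#' @return A `pair_scores` data.frame.
#' @export
read_scores <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  class(df) <- c("pair_scores", "data.frame")
  df
}
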