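test_that("GWAS hit counting uses an inclusive 10 kb window and unique positions", {
  cat <- gwas_catalog(chrom = rep("1", 3), pos = c(95000L, 109999L, 110001L))
  # 110001 is 10001 bp away -> outside
  expect_equal(gwas_hits("1", 100000L, cat), 2L)
  expect_equal(gwas_hits("2", 100000L, cat), 0L)
  expect_equal(gwas_hits("1", 100000L, structure(list(), class = "gwas_catalog")), 0L)
  # duplicates collapse before counting; insertion order is irrelevant
  cat_dup <- gwas_catalog(rep("1", 5), c(110001L, 95000L, 95000L, 109999L, 95000L))
  expect_equal(gwas_hits("1", 100000L, cat_dup), 2L)
  # symmetric window: exact boundary on both sides
  cat_edge <- gwas_catalog(rep("1", 2), c(90000L, 110000L))
  expect_equal(gwas_hits("1", 100000L, cat_edge), 2L)
})

test_that("tie-adjusted top-N hits rescale by N/M", {
  # no ties: factor 1
  ranked <- data.frame(chrom = "1", pos = seq(1e6, by = 50000L, length.out = 20),
                       score = seq(1, 0.05, length.out = 20))
  cat <- gwas_catalog(rep("1", 3), c(1000000L, 1050000L, 5000000L))
  h <- topn_adjusted_hits(ranked, cat, N = 5)
  expect_equal(h$M, 5L)
  expect_equal(h$adjusted, h$raw)

  # a tie block spanning the cut forces M > N and the N/M adjustment:
  # 1100 tied variants, catalog hits on 220 of them -> 220 * 1000/1100 = 200
  n_tied <- 1100L
  pos <- seq(1e6, by = 100000L, length.out = n_tied + 50L)
  ranked2 <- data.frame(chrom = "1", pos = pos,
                        score = c(rep(0.9, n_tied), seq(0.8, 0.3, length.out = 50L)))
  cat2 <- gwas_catalog(rep("1", 220L), pos[seq_len(220L)])
  h2 <- topn_adjusted_hits(ranked2, cat2, N = 1000L)
  expect_equal(h2$M, 1100L)
  expect_equal(h2$raw, 220L)
  expect_equal(h2$adjusted, 200)

  # all variants tied -> M equals the total count
  ranked3 <- data.frame(chrom = "1", pos = pos[1:30], score = rep(1, 30))
  expect_equal(topn_adjusted_hits(ranked3, cat, N = 10)$M, 30L)
  expect_warning(topn_adjusted_hits(ranked[1:3, ], cat, N = 10), "using all")
})

test_that("the cumulative hit curve is non-decreasing in raw hits", {
  set.seed(60)
  ranked <- data.frame(chrom = "1",
                       pos = sort(sample.int(5e6, 200)),
                       score = sort(runif(200), decreasing = TRUE))
  cat <- gwas_catalog(rep("1", 50), sample.int(5e6, 50))
  curve <- gwas_hit_curve(ranked, cat, N_grid = c(10, 50, 100, 200))
  expect_true(all(diff(curve$raw) >= 0))
  expect_equal(curve$N, c(10, 50, 100, 200))
})

test_that("top-gene overlap uses unique genes filtered to the background", {
  # plain-text disease lists read with readLines
  disease <- readLines(fixture("toy_disease_genes.txt"))
  expect_equal(overlap_top_genes(c("GENE_A", "GENE_Q"), disease,
                                 background_genes = c("GENE_A", "GENE_Q"),
                                 top = 2), 1L)

  ranked <- c("g1", "g2", "g2", "g3", "g4", "g5")  # g2 repeats (two eQTLs)
  background <- paste0("g", 1:10)
  expect_equal(overlap_top_genes(ranked, c("g2", "g4"), background, top = 3),
               1L)  # top-3 unique = g1,g2,g3 -> only g2 overlaps
  # disease genes outside the background are ignored
  expect_equal(overlap_top_genes(ranked, c("gX", "gY"), background, top = 3), 0L)
  expect_warning(ov <- overlap_top_genes(ranked, c("g5"), background, top = 100),
                 "fewer than")
  expect_equal(ov, 1L)
})

test_that("chromatin-state enrichment builds the right 2x2 tables", {
  states <- read_bed_states(fixture("toy_states.bed"))
  # 100 top variants, 30 inside 7_Enh [999000,1002000) -> 1-based 999001..1002000
  top <- data.frame(variant_id = paste0("t", 1:100),
                    chrom = "1",
                    pos = c(rep(1000000L, 30), rep(1020000L, 70)))
  bg <- data.frame(variant_id = paste0("b", 1:1000),
                   chrom = "1",
                   pos = c(rep(1001000L, 100), rep(1020000L, 900)))
  res <- chromatin_enrichment(rbind(top), rbind(top, bg), states)
  enh <- res[res$label == "7_Enh", ]
  expect_equal(c(enh$a, enh$b, enh$c, enh$d), c(30, 70, 100, 900))
  expect_equal(enh$odds_ratio, 30 * 900 / (70 * 100), tolerance = 1e-12)
  expect_equal(enh$fisher_p,
               fisher.test(matrix(c(30, 70, 100, 900), 2, byrow = TRUE))$p.value)
  # BH q-values never fall below their p-values
  expect_true(all(res$fdr_q >= res$fisher_p - 1e-15))
  # identical proportions -> OR 1, p 1
  res_null <- chromatin_enrichment(
    data.frame(variant_id = "x1", chrom = "1", pos = 1020000L),
    data.frame(variant_id = c("x1", "x2"), chrom = "1", pos = rep(1020000L, 2)),
    states)
  un <- res_null[res_null$label == "Unannotated", ]
  expect_equal(un$fisher_p, 1)
  # zero cells get a finite Haldane-corrected odds ratio
  expect_true(all(is.finite(res$odds_ratio)))
})

test_that("LD pruning drops r2 > 0.5 within the window and keeps the boundary", {
  set.seed(61)
  base <- sample(0:2, 400, replace = TRUE, prob = c(0.49, 0.42, 0.09))
  dosage <- rbind(v1 = base,
                  v2 = base,                          # r2 = 1 -> dropped
                  v3 = sample(base),                  # shuffled -> independent
                  v4 = sample(0:2, 400, replace = TRUE, prob = c(0.25, 0.5, 0.25)))
  gs <- toy_gset(dosage, pos = c(1000L, 2000L, 3000L, 4000L))
  kept <- ld_prune(gs)
  expect_false("v2" %in% kept$variants$variant_id)
  expect_true(all(c("v1", "v3", "v4") %in% kept$variants$variant_id))
  # retained set contains no pair above the threshold
  d <- kept$dosage
  for (i in seq_len(nrow(d) - 1)) {
    for (j in (i + 1):nrow(d)) {
      expect_lte(mtclass:::r2_genotype(d[i, ], d[j, ]), 0.5 + 1e-12)
    }
  }
  # r2 exactly 0.50 sits on the strict boundary and is kept
  x <- c(1L, 1L, 1L, 0L, 0L, 0L)
  yv <- c(1L, 1L, 1L, 1L, 0L, 0L)
  expect_equal(cor(x, yv)^2, 0.5, tolerance = 1e-12)
  gs2 <- toy_gset(rbind(a = x, b = yv), pos = c(100L, 200L))
  expect_equal(nrow(ld_prune(gs2)$variants), 2L)
  # zero-variance vector: r2 defined as 0, variant retained
  gs3 <- toy_gset(rbind(a = x, z = rep(1L, 6)), pos = c(100L, 200L))
  expect_equal(nrow(ld_prune(gs3)$variants), 2L)
})

test_that("differential eQTLs combine the F1 and baseline-p percentiles", {
  set.seed(62)
  n <- 200
  ids <- sprintf("v%03d", 1:n)
  scores <- data.frame(gene = "g", variant = ids,
                       f1_median = runif(n, 0.4, 0.8))
  scores$f1_median[1] <- 0.99  # v001: top by F1
  base <- rbind(
    data.frame(gene = "g", variant = ids, method = "manova",
               statistic = 1, p_value = runif(n, 0.2, 1), flag = ""),
    data.frame(gene = "g", variant = ids, method = "reverse_logistic",
               statistic = 1, p_value = runif(n, 0.2, 1), flag = ""))
  diff1 <- differential_eqtls(scores, base)
  expect_true("v001" %in% diff1)
  # same variant with a tiny MANOVA p drops out
  base2 <- base
  base2$p_value[base2$variant == "v001" & base2$method == "manova"] <- 1e-6
  expect_false("v001" %in% differential_eqtls(scores, base2))
  # percentiles are recomputed on the (sub)universe actually shared
  sub <- scores[1:100, ]
  diff_sub <- differential_eqtls(sub, base[base$variant %in% sub$variant, ])
  thr <- quantile(sub$f1_median, 0.9)
  expect_true(all(sub$f1_median[match(diff_sub, sub$variant)] >= thr))
  # disjoint universes are an error
  expect_error(differential_eqtls(scores[1:5, ],
                                  base[base$variant %in% ids[6:10], ]),
               "empty")
})

test_that("region enrichment reproduces the odds-from-proportions identity", {
  # selected 40/400 in region vs universe 100/4000
  uni <- data.frame(variant_id = sprintf("u%04d", 1:4000),
                    chrom = "6",
                    pos = c(rep(30000000L, 100), rep(50000000L, 3900)))
  sel <- c(sprintf("u%04d", 1:40),          # in region
           sprintf("u%04d", 201:560))       # outside
  res <- region_enrichment(sel, uni)
  p1 <- 40 / 400; p2 <- 100 / 4000
  expect_equal(res$odds_ratio, (p1 / (1 - p1)) / (p2 / (1 - p2)),
               tolerance = 1e-12)
  # Fisher p matches the exhaustive hypergeometric oracle on a small table
  uni_small <- data.frame(variant_id = sprintf("s%03d", 1:150),
                          chrom = "6",
                          pos = c(rep(30000000L, 30), rep(50000000L, 120)))
  sel_small <- c(sprintf("s%03d", 1:10), sprintf("s%03d", 31:70))
  res_small <- region_enrichment(sel_small, uni_small)
  expect_equal(res_small$fisher_p,
               oracle_fisher_p(res_small$a, res_small$b, res_small$c, res_small$d),
               tolerance = 1e-9)
  expect_error(region_enrichment(sel, uni,
                                 region = list(chrom = "6", start = 10L, end = 5L)),
               "empty region")
})

test_that("uniformly drawn selections have odds ratios near 1", {
  set.seed(63)
  uni <- data.frame(variant_id = sprintf("u%05d", 1:5000),
                    chrom = "6",
                    pos = c(rep(30000000L, 500), rep(50000000L, 4500)))
  ors <- replicate(30, {
    sel <- sample(uni$variant_id, 500)
    region_enrichment(sel, uni)$odds_ratio
  })
  expect_lt(abs(mean(ors) - 1), 0.15)
})
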