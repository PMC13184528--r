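test_that("eligibility requires four donors in the minority class", {
  y3 <- binarize_dominant(c(rep(0, 20), 2, 1, 1))
  expect_false(eligible(y3))
  y4 <- binarize_dominant(c(rep(0, 20), 2, 1, 1, 1))
  expect_true(eligible(y4))
  expect_false(eligible(binarize_dominant(rep(0, 20))))
})

test_that("macro F1 and MCC match their closed-form examples", {
  expect_equal(macro_f1(confusion_matrix(rep(c(1, 0), each = 4),
                                         rep(c(1, 0), each = 4))), 1)
  expect_equal(mcc(confusion_matrix(rep(c(1, 0), each = 4),
                                    rep(c(1, 0), each = 4))), 1)

  # TP=3, FN=1, FP=1, TN=3
  truth <- c(1, 1, 1, 1, 0, 0, 0, 0)
  pred <- c(1, 1, 1, 0, 1, 0, 0, 0)
  cm <- confusion_matrix(truth, pred)
  expect_equal(macro_f1(cm), 0.75)
  expect_equal(mcc(cm), 0.5)

  # all-class-0 prediction: class-1 F1 = 0, class-0 F1 = 2/3
  cm0 <- confusion_matrix(c(1, 1, 1, 1, 0, 0, 0, 0), rep(0, 8))
  expect_equal(macro_f1(cm0), 1 / 3, tolerance = 1e-12)
  expect_equal(mcc(cm0), 0)  # zero-denominator rule
})

test_that("metrics agree with brute-force oracles over random label pairs", {
  set.seed(101)
  max_f1_diff <- 0
  max_mcc_diff <- 0
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    truth <- rbinom(n, 1, runif(1, 0.1, 0.9))
    pred <- rbinom(n, 1, runif(1, 0.1, 0.9))
    cm <- confusion_matrix(truth, pred)
    max_f1_diff <- max(max_f1_diff, abs(macro_f1(cm) - oracle_macro_f1(truth, pred)))
    max_mcc_diff <- max(max_mcc_diff, abs(mcc(cm) - oracle_mcc(truth, pred)))
  }
  expect_lt(max_f1_diff, 1e-12)
  expect_lt(max_mcc_diff, 1e-12)
})

test_that("perfect macro F1, perfect MCC, and zero errors coincide", {
  set.seed(102)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    truth <- rbinom(n, 1, 0.5)
    pred <- truth
    if (i %% 2 == 0 && n > 1) pred[sample(n, 1)] <- 1 - pred[sample(n, 1)]
    cm <- confusion_matrix(truth, pred)
    errors <- cm[["FP"]] + cm[["FN"]]
    expect_equal(macro_f1(cm) == 1, errors == 0 && length(unique(truth)) == 2)
    expect_equal(mcc(cm) == 1, errors == 0 && length(unique(truth)) == 2)
  }
})

test_that("soft voting averages probabilities with ties to class 0", {
  p_rf <- rbind(c(0.1, 0.9))
  p_svm <- rbind(c(0.3, 0.7))
  expect_equal(soft_vote(list(p_rf, p_svm)), 1L)
  expect_equal(soft_vote(list(rbind(c(0.6, 0.4)), rbind(c(0.4, 0.6)))), 0L)
  expect_equal(soft_vote(list(rbind(c(0.2, 0.8)))), 1L)
  expect_error(soft_vote(list(rbind(c(0.5, 0.5)), rbind(c(0.5, 0.5, 0)))),
               "shape")
  expect_error(soft_vote(list(rbind(c(0.9, 0.9)))), "sum to 1")
})

test_that("MLP hidden size is ceil(mn/2)", {
  expect_equal(mlp_hidden_size(10, 9), 45L)
  expect_equal(mlp_hidden_size(3, 3), 5L)
  expect_equal(mlp_hidden_size(1, 1), 1L)
})

test_that("a large mean shift is classified near-perfectly", {
  sc <- sim_scenario(n_donors = 100, effect_type = "mean_shift",
                     effect_size = 5, seed = 31)
  d <- simulate_scenario(sc)
  cv <- cross_validated_scores(d$X, as.integer(d$y), classifier_spec(seed = 1))
  expect_gte(cv$macro_f1, 0.95)
  expect_gte(cv$mcc, 0.9)
})

test_that("duplicated feature columns barely change the scores", {
  sc <- sim_scenario(n_donors = 150, effect_type = "mean_shift",
                     effect_size = 2, seed = 33)
  d <- simulate_scenario(sc)
  y <- as.integer(d$y)
  base <- cross_validated_scores(d$X, y, classifier_spec(seed = 5))
  dup <- cross_validated_scores(cbind(d$X, d$X), y, classifier_spec(seed = 5))
  expect_lt(abs(base$macro_f1 - dup$macro_f1), 0.1)
})

test_that("repeated runs are seeded and aggregated as medians", {
  sc <- sim_scenario(n_donors = 80, effect_type = "mean_shift",
                     effect_size = 1, seed = 35)
  d <- simulate_scenario(sc)
  y <- as.integer(d$y)
  ps <- run_iterations(d$X, y, classifier_spec(seed = 2), n_iter = 3,
                       gene_id = "g", variant_id = "v")
  f1s <- unlist(ps[paste0("f1_iter", 1:3)])
  expect_equal(ps$f1_median, median(f1s))
  expect_equal(ps$mcc_median, median(unlist(ps[paste0("mcc_iter", 1:3)])))
  # bit-identical on re-run with the same seed
  expect_identical(ps, run_iterations(d$X, y, classifier_spec(seed = 2),
                                      n_iter = 3, gene_id = "g", variant_id = "v"))
  # n_iter = 1: median equals the single score
  ps1 <- run_iterations(d$X, y, classifier_spec(seed = 2), n_iter = 1)
  expect_equal(ps1$f1_median, ps1$f1_iter1)
})

test_that("the 2D perceptron path trains and scores", {
  set.seed(36)
  m <- 3; n_t <- 4
  sc <- sim_scenario(n_donors = 100, n_features = m * n_t,
                     effect_type = "mean_shift", effect_size = 4, seed = 37)
  d <- simulate_scenario(sc)
  X <- d$X
  attr(X, "grid_dim") <- c(m, n_t)
  cv <- cross_validated_scores(X, as.integer(d$y),
                               classifier_spec(kind = "mlp", seed = 1))
  expect_gte(cv$macro_f1, 0.9)
})

test_that("pair ranking orders by metric, then the other metric, then ID", {
  sc <- data.frame(
    gene = "g", variant = c("vC", "vA", "vB", "vD"),
    f1_median = c(0.5, 1.0, 0.5, 0.5),
    mcc_median = c(0.9, 1.0, 0.8, 0.9),
    stringsAsFactors = FALSE)
  class(sc) <- c("pair_scores", "data.frame")
  ranked <- rank_pairs(sc)
  expect_equal(ranked$variant, c("vA", "vC", "vD", "vB"))
  ranked_mcc <- rank_pairs(sc, metric = "mcc_median")
  expect_equal(ranked_mcc$variant[1], "vA")
})

test_that("median macro F1 and median MCC are strongly rank-correlated", {
  set.seed(40)
  rows <- list()
  effects <- runif(24, 0, 3)
  for (i in seq_along(effects)) {
    sc <- sim_scenario(n_donors = 80, effect_type = "mean_shift",
                       effect_size = effects[i], seed = 400 + i)
    d <- simulate_scenario(sc)
    cv <- cross_validated_scores(d$X, as.integer(d$y),
                                 classifier_spec(seed = 500 + i))
    rows[[i]] <- c(cv$macro_f1, cv$mcc)
  }
  m <- do.call(rbind, rows)
  expect_gt(cor(m[, 1], m[, 2], method = "spearman"), 0.9)
})
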