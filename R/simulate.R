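#' Define a simulation scenario
#'
#' Full parameterization of one synthetic experiment: donors, correlated
#' multi-feature expression, and the geometry through which the genotype
#' perturbs it.
#'
#' @param n_donors Number of donors (default 200).
#' @param n_features Number of expression features, e.g. tissues (default 9).
#' @param maf Minor allele frequency in (0, 0.5] (default 0.3, which after
#'   dominant collapse yields roughly balanced classes).
#' @param effect_type One of `"null"`, `"mean_shift"`, `"additive"`,
#'   `"multiplicative"`, `"variance_only"`, `"interaction"`.
#' @param effect_size Effect magnitude in residual-SD units (ignored for
#'   `null` and `variance_only`).
#' @param variance_ratio Carrier / non-carrier noise-SD ratio (>= 1; used by
#'   `variance_only`).
#' @param feature_correlation Exchangeable correlation rho in \[0, 1) between
#'   features (default 0.3). A full correlation matrix can be supplied via
#'   `correlation_matrix`.
#' @param affected_fraction Fraction of features carrying the effect
#'   (default 1).
#' @param baseline_mean Baseline mean expression of every feature (default 1;
#'   must be non-zero for the multiplicative geometry to act).
#' @param missing_rate MCAR missingness rate in \[0, 1) applied by
#'   [simulate_scenario()] when > 0.
#' @param correlation_matrix Optional full correlation matrix overriding the
#'   exchangeable structure.
#' @param seed Integer seed; all draws are reproducible given it.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(n_donors = 200L, n_features = 9L, maf = 0.3,
                         effect_type = c("null", "mean_shift", "additive",
                                         "multiplicative", "variance_only",
                                         "interaction"),
                         effect_size = 1, variance_ratio = 1,
                         feature_correlation = 0.3, affected_fraction = 1,
                         baseline_mean = 1, missing_rate = 0,
                         correlation_matrix = NULL, seed = 1L) {
  effect_type <- match.arg(effect_type)
  stopifnot(n_donors >= 8L, n_features >= 1L, maf > 0, maf <= 0.5,
            variance_ratio >= 1, feature_correlation >= 0,
            feature_correlation < 1, affected_fraction > 0,
            affected_fraction <= 1, missing_rate >= 0, missing_rate < 1)
  structure(list(n_donors = as.integer(n_donors),
                 n_features = as.integer(n_features), maf = maf,
                 effect_type = effect_type, effect_size = effect_size,
                 variance_ratio = variance_ratio,
                 feature_correlation = feature_correlation,
                 affected_fraction = affected_fraction,
                 baseline_mean = baseline_mean, missing_rate = missing_rate,
                 correlation_matrix = correlation_matrix,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' @param n Number of donors.
#' @param maf Minor allele frequency in (0, 0.5].
#' @param seed Optional integer seed (the current RNG stream is used when
#'   `NULL`).
#' @return Integer dosage vector with HWE class probabilities
#'   `((1-maf)^2, 2 maf (1-maf), maf^2)`.
#' @export
simulate_genotypes <- function(n, maf, seed = NULL) {
  stopifnot(maf > 0, maf <= 0.5)
  if (!is.null(seed)) set.seed(seed)
  sample(0:2, n, replace = TRUE,
         prob = c((1 - maf)^2, 2 * maf * (1 - maf), maf^2))
}

#' Simulate a correlated expression matrix under a genetic-effect geometry
#'
#' Baseline rows are multivariate normal with unit variances, mean
#' `baseline_mean`, and exchangeable correlation `feature_correlation` (or
#' the supplied matrix). The effect is then applied to the affected feature
#' subset (the first `ceil(affected_fraction * n_features)` features):
#' \describe{
#'   \item{null}{no change.}
#'   \item{mean_shift}{`+ effect_size` for carriers (dosage >= 1;
#'     dominant-aligned).}
#'   \item{additive}{`+ effect_size * dosage`.}
#'   \item{multiplicative}{mean scaled by `(1 + effect_size)^dosage`.}
#'   \item{variance_only}{residual SD multiplied by `variance_ratio` for
#'     carriers; means untouched.}
#'   \item{interaction}{`+/- effect_size` with alternating sign across the
#'     affected features for carriers, so pooled per-feature mean differences
#'     cancel while the multivariate pattern separates the classes.}
#' }
#'
#' @param dosages Integer dosage vector (0/1/2) from [simulate_genotypes()].
#' @param scenario A [sim_scenario()].
#' @param seed Optional seed (defaults to `scenario$seed + 1` so that
#'   genotypes and expression use distinct streams).
#' @return Numeric matrix, donors x features.
#' @export
simulate_expression <- function(dosages, scenario, seed = scenario$seed + 1L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(dosages)
  p <- scenario$n_features
  Sigma <- scenario$correlation_matrix
  if (is.null(Sigma)) {
    rho <- scenario$feature_correlation
    Sigma <- matrix(rho, p, p)
    diag(Sigma) <- 1
  }
  n_aff <- ceiling(scenario$affected_fraction * p)
  if (n_aff < 1L) stop("affected feature subset is empty", call. = FALSE)
  aff <- seq_len(n_aff)
  mu0 <- scenario$baseline_mean
  eff <- scenario$effect_size

  E <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = Sigma)
  carrier <- dosages >= 1L
  if (scenario$effect_type == "variance_only") {
    E[carrier, aff] <- E[carrier, aff] * scenario$variance_ratio
  }
  X <- E + mu0
  shift <- matrix(0, n, p)
  shift[, aff] <- switch(
    scenario$effect_type,
    null = 0,
    variance_only = 0,
    mean_shift = as.numeric(carrier) * eff,
    additive = dosages * eff,
    multiplicative = mu0 * ((1 + eff)^dosages - 1),
    interaction = outer(as.numeric(carrier),
                        rep_len(c(1, -1), n_aff)) * eff
  )
  X <- X + shift
  dimnames(X) <- list(paste0("D", seq_len(n)), paste0("F", seq_len(p)))
  X
}

#' Inject missing-completely-at-random cells
#'
#' @param X Numeric matrix, donors x features.
#' @param missing_rate Cell-wise missingness rate in \[0, 1). A vector of
#'   per-feature rates (length `ncol(X)`) emulates feature-structured
#'   missingness.
#' @param seed Optional integer seed.
#' @return `X` with masked cells set to `NA`. A donor left fully missing has
#'   its mask redrawn once; if still fully missing, an error is raised.
#' @export
inject_missing <- function(X, missing_rate, seed = NULL) {
  stopifnot(all(missing_rate >= 0), all(missing_rate < 1))
  if (!is.null(seed)) set.seed(seed)
  if (all(missing_rate == 0)) return(X)
  rate <- matrix(missing_rate, nrow(X), ncol(X), byrow = TRUE)
  mask <- matrix(stats::runif(length(X)) < rate, nrow(X))
  for (r in which(rowSums(!mask) == 0L)) {
    mask[r, ] <- stats::runif(ncol(X)) < rate[r, ]
    if (all(mask[r, ])) stop("donor ", r, " left with no observed features", call. = FALSE)
  }
  X[mask] <- NA_real_
  X
}

#' Draw one complete scenario replicate
#'
#' Generates genotypes, the binary (dominant) class labels, and the
#' expression matrix for a scenario, applying missingness if requested.
#'
#' @param scenario A [sim_scenario()].
#' @return List with `dosages`, `y` ([binarize_dominant()] labels), and `X`.
#' @export
simulate_scenario <- function(scenario) {
  dos <- simulate_genotypes(scenario$n_donors, scenario$maf, seed = scenario$seed)
  X <- simulate_expression(dos, scenario)
  if (scenario$missing_rate > 0) {
    X <- inject_missing(X, scenario$missing_rate, seed = scenario$seed + 2L)
  }
  list(dosages = dos, y = binarize_dominant(dos), X = X)
}

#' Benchmark classification and linear methods over simulated replicates
#'
#' For each scenario and replicate, draws genotypes and expression, then runs
#' the requested methods: `"mtclass"` records the cross-validated macro F1
#' and MCC (single CV run per replicate), the baselines record p-values.
#' Replicates where the dominant-collapsed genotype has fewer than four
#' minority donors are redrawn (fresh seed), mirroring the eligibility rule.
#'
#' @param scenarios A [sim_scenario()] or list of them.
#' @param methods Character subset of
#'   `c("mtclass", "manova", "reverse_logistic", "cauchy")`.
#' @param n_replicates Replicates per scenario (default 100).
#' @param seed Global seed; replicate r of scenario s uses derived seeds.
#' @param spec [classifier_spec()] used for the mtclass runs.
#' @return data.frame with columns `scenario`, `effect_type`, `replicate`,
#'   `method`, `metric` (`"macro_f1"`, `"mcc"` or `"p_value"`), `value`.
#' @export
run_benchmark <- function(scenarios,
                          methods = c("mtclass", "manova",
                                      "reverse_logistic", "cauchy"),
                          n_replicates = 100L, seed = 1L,
                          spec = classifier_spec()) {
  if (inherits(scenarios, "sim_scenario")) scenarios <- list(scenarios)
  methods <- match.arg(methods, several.ok = TRUE)
  out <- vector("list", 0L)
  for (s in seq_along(scenarios)) {
    sc <- scenarios[[s]]
    for (r in seq_len(n_replicates)) {
      rep_seed <- (seed + 7919L * (s - 1L) + 104729L * (r - 1L)) %% 2147483647L
      draw <- NULL
      for (retry in 0:49) {
        sc_r <- sc
        sc_r$seed <- (rep_seed + 3L * retry) %% 2147483647L
        cand <- simulate_scenario(sc_r)
        if (eligible(cand$y)) { draw <- cand; break }
      }
      if (is.null(draw)) stop("could not draw an eligible genotype vector", call. = FALSE)
      y <- as.integer(draw$y)
      X <- draw$X
      for (m in methods) {
        val <- switch(
          m,
          mtclass = {
            sp <- spec
            sp$seed <- rep_seed
            cv <- cross_validated_scores(X, y, sp)
            if (is.null(cv)) next
            out[[length(out) + 1L]] <- data.frame(
              scenario = s, effect_type = sc$effect_type, replicate = r,
              method = m, metric = "mcc", value = cv$mcc)
            cv$macro_f1
          },
          manova = manova_test(X, y)$p_value,
          reverse_logistic = reverse_logistic_test(X, y)$p_value,
          cauchy = cauchy_test(X, y)$p_value
        )
        metric <- if (m == "mtclass") "macro_f1" else "p_value"
        out[[length(out) + 1L]] <- data.frame(
          scenario = s, effect_type = sc$effect_type, replicate = r,
          method = m, metric = metric, value = val)
      }
    }
  }
  do.call(rbind, out)
}

#' Summarize a benchmark table
#'
#' Per scenario x method: median score / p-value, empirical power at a
#' p-value threshold `alpha` (baselines) and mean score (mtclass).
#'
#' @param bench Output of [run_benchmark()].
#' @param alpha Rejection threshold for baseline power (default 0.05).
#' @return Summary data.frame.
#' @export
summarize_benchmark <- function(bench, alpha = 0.05) {
  keys <- unique(bench[, c("scenario", "effect_type", "method", "metric")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    v <- bench$value[bench$scenario == k$scenario & bench$method == k$method &
                       bench$metric == k$metric]
    data.frame(k, n = length(v), median = stats::median(v), mean = mean(v),
               power = if (k$metric == "p_value") mean(v < alpha) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a simulated scenario to disk as fixture files
#'
#' Emits the internal genotype TSV, the expression TSV, and a truth TSV
#' (variant, effect_type, effect_size) so simulated datasets can round-trip
#' through the file-based pipeline.
#'
#' @param scenario A [sim_scenario()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_scenario <- function(scenario, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  draw <- simulate_scenario(scenario)
  donors <- rownames(draw$X)
  variants <- data.frame(variant_id = "sim_variant_1", chrom = "1",
                         pos = 1000000L, ref = "A", alt = "G",
                         stringsAsFactors = FALSE)
  dosage <- matrix(as.integer(draw$dosages), nrow = 1,
                   dimnames = list("sim_variant_1", donors))
  paths <- c(
    genotypes = file.path(dir, paste0(prefix, "_genotypes.tsv")),
    expression = file.path(dir, paste0(prefix, "_expression.tsv")),
    truth = file.path(dir, paste0(prefix, "_truth.tsv"))
  )
  write_genotype_tsv(genotype_set(variants, dosage), paths[["genotypes"]])
  utils::write.table(data.frame(donor = donors, draw$X, check.names = FALSE),
                     paths[["expression"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(variant = "sim_variant_1",
                                effect_type = scenario$effect_type,
                                effect_size = scenario$effect_size),
                     paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
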