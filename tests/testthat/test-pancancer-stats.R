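test_that("wilcoxon engine gives exact small-sample p-values", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p, 0.1) # 2 * 1/20 over C(6,3) rank assignments
  expect_equal(res$statistic, 0)

  expect_warning(res2 <- wilcoxon_rank_sum(c(2, 2), c(2, 2)), "identical")
  expect_equal(res2$p, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")

  # spot-check against exhaustive enumeration on random tie-free inputs
  withr::with_seed(42, {
    for (i in 1:25) {
      n <- sample(2:5, 1)
      m <- sample(2:5, 1)
      x <- sample(100, n)
      y <- sample(100, m) + 0.5
      expect_equal(wilcoxon_rank_sum(x, y)$p, oracle_wilcoxon_p(x, y))
    }
  })
})

test_that("significance markers follow the conventional thresholds", {
  expect_identical(
    significance_marker(c(1e-5, 5e-4, 0.005, 0.03, 0.2)),
    c("****", "***", "**", "*", "ns")
  )
})

test_that("family consistency binomial reproduces closed forms", {
  res <- family_consistency_binomial(13, n_cancers = 13)
  expect_equal(res$p, (1 / 3)^13)
  expect_equal(res$p, oracle_binomial_tail(13, 13, 1 / 3))
  expect_equal(family_consistency_binomial(0, n_cancers = 13)$p, 1)
  expect_equal(family_consistency_binomial(1, n_cancers = 2)$p, 5 / 9)
  # direction-vector interface counts the focal direction
  res2 <- family_consistency_binomial(c("down", "down", "ns", "up"))
  expect_equal(res2$k, 2)
  expect_equal(res2$n, 4)
  expect_equal(res2$p, oracle_binomial_tail(2, 4, 1 / 3))
  # pmf-summation agreement across random (k, n, p0)
  withr::with_seed(9, {
    for (i in 1:20) {
      n <- sample(1:20, 1)
      k <- sample(0:n, 1)
      p0 <- runif(1, 0.1, 0.9)
      expect_equal(
        family_consistency_binomial(k, n_cancers = n, null_prob = p0)$p,
        oracle_binomial_tail(k, n, p0),
        tolerance = 1e-12
      )
    }
  })
  expect_error(family_consistency_binomial(0, n_cancers = 0), ">= 1")
})

test_that("per-cancer differential expression calls the planted direction", {
  co <- small_cohort(seed = 21)
  de <- diffexp_per_cancer(co$expr, co$samples, "TTLL11", min_samples_per_arm = 10)
  expect_equal(nrow(de), 4) # 3 cancers + PANCAN
  expect_true(all(de$direction == "down"))
  expect_true(all(de$median_tumor < de$median_healthy))
  expect_error(diffexp_per_cancer(co$expr, co$samples, "NOPE", min_samples_per_arm = 10), "not in expression")
})

test_that("PANCAN row equals the single cancer's pooled test on a one-cancer table", {
  co <- generate_cohort(small_config(seed = 22, n_cancers = 1L))
  de <- diffexp_per_cancer(co$expr, co$samples, "TTLL11", min_samples_per_arm = 10)
  expect_equal(nrow(de), 2)
  expect_equal(de$p_two_sided[1], de$p_two_sided[2])
  expect_equal(de$statistic[1], de$statistic[2])
})

test_that("direction calls are invariant under strictly monotone transforms", {
  co <- small_cohort(seed = 23)
  de1 <- diffexp_per_cancer(co$expr, co$samples, "TTLL11", min_samples_per_arm = 10)
  expr2 <- log_normalize(2^co$expr - 1 + 5) # strictly monotone remap
  de2 <- diffexp_per_cancer(expr2, co$samples, "TTLL11", min_samples_per_arm = 10)
  expect_identical(de1$direction, de2$direction)
  expect_equal(de1$p_two_sided, de2$p_two_sided)
})

test_that("stratification takes the inclusive top decile per regulator", {
  # 10 tumor samples; regulator A increasing, B decreasing
  samples <- tibble::tibble(
    sample_id = sprintf("t%02d", 1:10), cancer_type = "C1",
    sample_class = "primary_tumor", aneuploidy_score = 0
  )
  expr <- rbind(A = 1:10, B = 10:1)
  colnames(expr) <- samples$sample_id
  st <- stratify_by_regulators(expr, samples, c("A", "B"), 0.10)
  expect_setequal(st$sample_id[st$stratum == "regulator_high"], c("t01", "t10"))
  expect_length(st$sample_id[st$stratum == "regulator_low"], 0)

  # single regulator, 20 samples: |high| = |low| = 2
  samples2 <- tibble::tibble(
    sample_id = sprintf("t%02d", 1:20), cancer_type = "C1",
    sample_class = "primary_tumor", aneuploidy_score = 0
  )
  expr2 <- matrix(1:20, 1, dimnames = list("A", samples2$sample_id))
  st2 <- stratify_by_regulators(expr2, samples2, "A", 0.10)
  expect_equal(sum(st2$stratum == "regulator_high"), 2)
  expect_equal(sum(st2$stratum == "regulator_low"), 2)

  # fully tied arm: high and low would coincide -> cancer skipped
  expr3 <- matrix(5, 1, 20, dimnames = list("A", samples2$sample_id))
  expect_warning(st3 <- stratify_by_regulators(expr3, samples2, "A", 0.10), "overlap")
  expect_equal(nrow(st3), 0)

  # too few tumor samples for the fraction -> skipped
  expect_warning(
    st4 <- stratify_by_regulators(expr[, 1:5], samples[1:5, ], "A", 0.10),
    "fewer"
  )
  expect_equal(nrow(st4), 0)
})

test_that("strata stay disjoint and cover the per-regulator minimum", {
  withr::with_seed(31, {
    for (i in 1:10) {
      n <- sample(12:40, 1)
      samples <- tibble::tibble(
        sample_id = sprintf("t%03d", 1:n), cancer_type = "C1",
        sample_class = "primary_tumor", aneuploidy_score = 0
      )
      expr <- matrix(rnorm(2 * n), 2, dimnames = list(c("A", "B"), samples$sample_id))
      st <- stratify_by_regulators(expr, samples, c("A", "B"), 0.10)
      hi <- st$sample_id[st$stratum == "regulator_high"]
      lo <- st$sample_id[st$stratum == "regulator_low"]
      expect_length(intersect(hi, lo), 0)
      expect_gte(length(hi), ceiling(0.10 * n))
    }
  })
})

test_that("strata comparisons mark empty strata untestable", {
  co <- small_cohort(seed = 24)
  st <- stratify_by_regulators(co$expr, co$samples, co$truth$regulator_genes, 0.10)
  st$stratum[st$stratum == "regulator_low"] <- "other" # force an empty stratum
  cmp <- compare_strata_expression(co$expr, co$samples, st, "TTLL11")
  lows <- cmp[cmp$comparison == "healthy_vs_low", ]
  expect_true(all(!lows$testable))
  expect_true(all(is.na(lows$p_two_sided)))
  highs <- cmp[cmp$comparison == "healthy_vs_high", ]
  expect_true(all(highs$testable))
})

test_that("a regulator-conditional downshift shows up in high but not low strata", {
  hits <- 0
  for (s in 1:10) {
    co <- generate_cohort(small_config(
      seed = s, n_cancers = 5L,
      n_healthy = 25L, n_tumor = 25L, conditional_downshift = TRUE
    ))
    st <- stratify_by_regulators(co$expr, co$samples, co$truth$regulator_genes, 0.10)
    cmp <- compare_strata_expression(co$expr, co$samples, st, "TTLL11")
    pan <- cmp[cmp$cancer_type == "PANCAN", ]
    p_hi <- pan$p_two_sided[pan$comparison == "healthy_vs_high"]
    p_lo <- pan$p_two_sided[pan$comparison == "healthy_vs_low"]
    # the low stratum (bottom decile of BOTH regulators) is tiny and may be
    # empty; an untestable low comparison also means no spurious signal
    if (p_hi < 0.05 && (is.na(p_lo) || p_lo >= 0.05)) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("oncogene effect test normalizes against the matched control arm", {
  # normalized value arithmetic: TPM 3 against a control arm mean log-TPM of 1
  expect_equal(normalize_to_control(3, 1), 1.0)

  design <- tibble::tibble(
    sample_id = sprintf("s%d", 1:8),
    cell_line = rep(c("L1", "L2"), each = 4),
    condition = rep(c("Empty", "Empty", "CCNE1", "CCNE1"), 2),
    timepoint_h = 48L
  )
  expr <- matrix(c(1, 1, 2, 2, 3, 3, 5, 5), 1, dimnames = list("g", design$sample_id))
  et <- oncogene_effect_test(expr, design, "g")
  # treated minus matched control means: (2-1, 2-1, 5-3, 5-3)
  expect_equal(
    et$normalized$normalized_log2[et$normalized$condition == "CCNE1"],
    c(1, 1, 2, 2)
  )
  expect_equal(
    et$normalized$normalized_log2[et$normalized$condition == "Empty"],
    rep(0, 4)
  )
  # a missing matched control arm errors
  design2 <- design[design$condition != "Empty" | design$cell_line != "L2", ]
  expect_error(
    oncogene_effect_test(expr[, design2$sample_id, drop = FALSE], design2, "g"),
    "control arm"
  )
})

test_that("planted overexpression factor is detected for CCNE1/CDC25A but not MYC", {
  hits <- 0
  for (s in 1:10) {
    oe <- generate_overexpression_experiment(small_config(seed = s, n_genes = 20L))
    et <- oncogene_effect_test(oe$expr, oe$design, "TTLL11")
    p <- stats::setNames(et$tests$p, et$tests$condition)
    if (p[["CCNE1"]] < 0.05 && p[["CDC25A"]] < 0.05 && p[["MYC"]] >= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("promoter window membership is strand-aware and medians are per sample", {
  ann <- tibble::tibble(
    gene_id = c("gP", "gM"), length_bp = 1000L, chrom = "chr1",
    tss = c(10000, 50000), strand = c("+", "-")
  )
  samples <- tibble::tibble(
    sample_id = c("h1", "h2", "h3", "t1", "t2", "t3"), cancer_type = "C1",
    sample_class = rep(c("healthy_solid", "primary_tumor"), each = 3),
    aneuploidy_score = c(NA, NA, NA, 1, 2, 3)
  )
  probes <- tibble::tibble(
    probe_id = c("p1", "p2", "p3", "p4"),
    chrom = "chr1",
    position = c(9000, 9900, 10050, 50100)
  )
  betas <- matrix(0.5, 4, 6, dimnames = list(probes$probe_id, samples$sample_id))
  betas["p1", ] <- 0.8
  betas["p2", ] <- 0.6
  betas["p3", ] <- 0.9
  meth <- methylation_table(probes, betas)

  # constant betas across samples make the Wilcoxon degenerate (p = 1 warning)
  res <- suppressWarnings(promoter_methylation_test(meth, ann, samples, "gP", window_bp = 1500))
  expect_setequal(res$probes, c("p1", "p2")) # 10050 is downstream of the + TSS
  expect_true(all(res$per_sample$median_beta == 0.7))

  res_m <- suppressWarnings(promoter_methylation_test(meth, ann, samples, "gM", window_bp = 1500))
  expect_identical(res_m$probes, "p4") # TSS+100 is upstream on the - strand

  ann2 <- ann
  ann2$tss[1] <- 99999999
  res_none <- promoter_methylation_test(meth, ann2, samples, "gP")
  expect_false(res_none$testable)
})

test_that("promoter methylation test runs per cancer on a generated cohort", {
  # probes land uniformly within +/-2 kb of each TSS, so some genes have no
  # probe in their 1.5 kb upstream window; find one that does
  co <- small_cohort(seed = 25)
  res <- NULL
  for (g in co$truth$genes) {
    res <- promoter_methylation_test(co$methylation, co$annotation, co$samples, g)
    if (res$testable) break
  }
  expect_true(res$testable)
  expect_equal(nrow(res$tests), 4) # 3 cancers + PANCAN
  expect_true(all(res$tests$testable))
  expect_true(all(res$tests$p_two_sided >= 0 & res$tests$p_two_sided <= 1))
})
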