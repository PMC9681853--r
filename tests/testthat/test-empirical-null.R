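test_that("spearman matches closed forms and the rank-Pearson oracle", {
  expect_equal(spearman_rho(1:4, c(10, 20, 30, 40)), 1)
  expect_equal(spearman_rho(1:4, c(40, 30, 20, 10)), -1)
  expect_equal(spearman_rho(c(1, 2, 2, 3), c(1, 3, 2, 4)), 4.5 / sqrt(22.5))
  expect_warning(r <- spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(r))
  expect_error(spearman_rho(c(1, NA), c(2, 3)), ">= 3 complete pairs")

  withr::with_seed(7, {
    for (i in 1:100) {
      n <- sample(4:30, 1)
      x <- sample(10, n, replace = TRUE) + runif(n, 0, 0.01) * rbinom(n, 1, 0.5)
      y <- sample(8, n, replace = TRUE)
      if (length(unique(x)) == 1 || length(unique(y)) == 1) next
      expect_lt(abs(spearman_rho(x, y) - oracle_spearman(x, y)), 1e-12)
    }
  })
})

test_that("standardized one-sided p matches direct arithmetic", {
  vals <- c(a = -0.8, b = -0.1, c = 0.0, d = 0.1, e = 0.2)
  res <- standardized_one_sided_p(vals, "a", "lower", min_genes = 5)
  expect_equal(res$z, (-0.8 - mean(vals)) / sd(vals))
  expect_equal(res$p_one_sided, pnorm(res$z))
  expect_equal(round(res$z, 3), -1.716)
  expect_equal(round(res$p_one_sided, 4), 0.0431)

  # focal at the mean -> p = 0.5; focal at mean + 1 sd, lower tail -> Phi(1)
  v2 <- stats::setNames(rnorm(100), sprintf("g%03d", 1:100))
  v2[["g001"]] <- mean(v2[-1]) # nearly the mean of all
  v2[["g001"]] <- (mean(v2) * 100 - v2[["g001"]]) / 99 # exact fixed point
  res2 <- standardized_one_sided_p(v2, "g001")
  expect_equal(res2$p_one_sided, 0.5, tolerance = 1e-10)
  v3 <- v2
  v3[["g001"]] <- mean(v3) + sd(v3)
  # iterate the fixed point: focal exactly 1 sd above the mean
  for (i in 1:200) v3[["g001"]] <- mean(v3) + sd(v3)
  res3 <- standardized_one_sided_p(v3, "g001")
  expect_equal(res3$p_one_sided, pnorm(1), tolerance = 1e-6)
})

test_that("standardized p is affine-invariant and its tails sum to one", {
  withr::with_seed(13, {
    vals <- stats::setNames(rnorm(200, 3, 2), sprintf("g%03d", 1:200))
  })
  lo <- standardized_one_sided_p(vals, "g007", "lower")
  up <- standardized_one_sided_p(vals, "g007", "upper")
  expect_equal(lo$p_one_sided + up$p_one_sided, 1)
  shifted <- standardized_one_sided_p(5 * vals - 11, "g007", "lower")
  expect_equal(shifted$z, lo$z, tolerance = 1e-12)
  expect_error(standardized_one_sided_p(vals[1:10], "g007"), ">= 30")
  expect_error(standardized_one_sided_p(rep(c(x = 1), 40), "x"), "zero spread")
})

test_that("genome-wide association recovers planted and degenerate correlations", {
  co <- small_cohort(seed = 41)
  tab <- genomewide_association(co$expr, co$samples, "CANCER01")
  expect_equal(nrow(tab), nrow(co$expr))
  # a gene whose expression ranks exactly like the score
  tum <- co$samples$sample_id[co$samples$cancer_type == "CANCER01" &
    co$samples$sample_class == "primary_tumor"]
  expr2 <- co$expr
  expr2["G00010", tum] <- co$samples$aneuploidy_score[match(tum, co$samples$sample_id)] + 1
  tab2 <- genomewide_association(expr2, co$samples, "CANCER01")
  expect_equal(tab2$rho[tab2$gene_id == "G00010"], 1)
  expect_error(genomewide_association(co$expr, co$samples, "NOCANCER"), "scored tumor samples")
})

test_that("shuffled aneuploidy scores give near-zero mean association", {
  co <- generate_cohort(small_config(seed = 42, n_genes = 500L, n_tumor = 25L))
  sh <- co$samples
  tum <- sh$sample_class == "primary_tumor"
  withr::with_seed(1, {
    sh$aneuploidy_score[tum] <- sample(sh$aneuploidy_score[tum])
  })
  tab <- dplyr::bind_rows(lapply(
    co$truth$cancers,
    function(ct) genomewide_association(co$expr, sh, ct)
  ))
  expect_lt(abs(mean(tab$rho, na.rm = TRUE)), 0.02)
})

test_that("pan-cancer median association reduces to the single-cancer test", {
  expect_equal(median(c(-0.3, -0.2, -0.4)), -0.3)
  co <- small_cohort(seed = 43)
  tab1 <- genomewide_association(co$expr, co$samples, "CANCER01")
  single <- standardized_one_sided_p(
    stats::setNames(tab1$rho, tab1$gene_id), "TTLL11", "lower"
  )
  via_pancan <- pancan_median_association(tab1, "TTLL11", "lower")
  expect_equal(via_pancan$z, single$z)
  expect_equal(via_pancan$p_one_sided, single$p_one_sided)
})

test_that("planted aneuploidy coupling yields a lower-tail focal signal", {
  co <- generate_cohort(small_config(seed = 44, n_genes = 300L, n_tumor = 25L, n_cancers = 6L))
  tabs <- lapply(co$truth$cancers, function(ct) genomewide_association(co$expr, co$samples, ct))
  res <- pancan_median_association(tabs, "TTLL11", "lower")
  expect_lt(res$p_one_sided, 0.05)
  expect_lt(res$value, 0)
})

test_that("mutation rates per kb follow count / length arithmetic", {
  ann <- tibble::tibble(
    gene_id = c("gA", "gB", "gC"), length_bp = c(2000L, 4000L, 1000L),
    chrom = "chr1", tss = c(0, 0, 0), strand = "+"
  )
  mut <- tibble::tibble(
    gene_id = rep("gA", 4), sample_id = sprintf("s%d", 1:4),
    cancer_type = "C1", effect_class = c("missense", "missense", "truncating", "missense")
  )
  rates <- mutation_rate_per_kb(mut, ann)
  expect_equal(unname(rates), c(2.0, 0.0, 0.0))
  # doubling the length halves the rate
  ann2 <- ann
  ann2$length_bp <- ann2$length_bp * 2L
  expect_equal(unname(mutation_rate_per_kb(mut, ann2)["gA"]), 1.0)
  # effect-class filter
  expect_equal(
    unname(mutation_rate_per_kb(mut, ann, effect_class = "truncating")["gA"]),
    0.5
  )
  mut_bad <- mut
  mut_bad$gene_id[1] <- "gZ"
  expect_error(mutation_rate_per_kb(mut_bad, ann), "missing from annotation")
})

test_that("a focal rate at the genome mean is at the null center", {
  rates <- stats::setNames(rep(c(1, 2, 3), each = 20), sprintf("g%02d", 1:60))
  rates[["g01"]] <- mean(rates[-1]) # close to overall mean
  rates[["g01"]] <- (sum(rates) - rates[["g01"]]) / 59
  for (i in 1:100) rates[["g01"]] <- mean(rates)
  res <- standardized_one_sided_p(rates, "g01", "lower")
  expect_equal(res$p_one_sided, 0.5, tolerance = 1e-8)
})

test_that("planted mutation depletion drives the focal z negative", {
  co <- generate_cohort(small_config(seed = 45, n_genes = 500L, n_cancers = 13L))
  md <- mutation_depletion_test(co$mutations, co$annotation, "TTLL11")
  expect_equal(nrow(md$per_cancer), 13)
  expect_lt(md$pooled$z, 0)
  expect_true(all(md$per_cancer$p_one_sided >= 0 & md$per_cancer$p_one_sided <= 1))
})
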