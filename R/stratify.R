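# Stratification of tumor samples by upstream-regulator expression, and the
# comparison of a target gene's expression across the resulting strata.

#' Stratify tumor samples by regulator expression
#'
#' Within each cancer type, tumor samples in the top `decile_fraction` of
#' expression of *any* regulator form the `regulator_high` stratum; samples
#' in the bottom `decile_fraction` of *every* regulator form
#' `regulator_low`; the rest are `other`. The quantile boundary is the
#' inclusive nearest-rank: the k-th largest (smallest) value with
#' k = ceiling(fraction * n), ties at the boundary included. A cancer whose
#' high and low strata would overlap (fully tied arm) is skipped with a
#' warning, as is a cancer with fewer tumor samples than `1/decile_fraction`.
#'
#' @param expr Expression matrix.
#' @param samples Sample table.
#' @param regulator_gene_ids Character vector of regulator genes.
#' @param decile_fraction Stratum fraction per regulator (default 0.10).
#' @return Tibble: sample_id, cancer_type, stratum
#'   (regulator_high / regulator_low / other) for tumor samples of the
#'   cancers that could be stratified.
#' @export
stratify_by_regulators <- function(expr, samples, regulator_gene_ids,
                                   decile_fraction = 0.10) {
  stopifnot(length(regulator_gene_ids) >= 1)
  missing_reg <- setdiff(regulator_gene_ids, rownames(expr))
  if (length(missing_reg) > 0) {
    stop("regulator gene(s) not in expression matrix: ", paste(missing_reg, collapse = ", "))
  }
  tum <- samples[samples$sample_class == "primary_tumor" &
    samples$sample_id %in% colnames(expr), ]
  out <- list()
  for (ct in unique(tum$cancer_type)) {
    ids <- tum$sample_id[tum$cancer_type == ct]
    n <- length(ids)
    if (n < 1 / decile_fraction) {
      warning(sprintf("cancer %s: %d tumor samples, fewer than 1/%.2g; skipped", ct, n, decile_fraction))
      next
    }
    k <- ceiling(decile_fraction * n)
    high <- character(0)
    low <- ids
    for (rg in regulator_gene_ids) {
      v <- expr[rg, ids]
      hi_cut <- sort(v, decreasing = TRUE)[k]
      lo_cut <- sort(v)[k]
      high <- union(high, ids[v >= hi_cut])
      low <- intersect(low, ids[v <= lo_cut])
    }
    if (length(intersect(high, low)) > 0) {
      warning(sprintf("cancer %s: high and low strata overlap (tied expression); skipped", ct))
      next
    }
    stratum <- rep("other", n)
    stratum[ids %in% high] <- "regulator_high"
    stratum[ids %in% low] <- "regulator_low"
    out[[ct]] <- tibble::tibble(sample_id = ids, cancer_type = ct, stratum = stratum)
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      sample_id = character(0), cancer_type = character(0), stratum = character(0)
    ))
  }
  dplyr::bind_rows(out)
}

strata_one <- function(vals_stratum, vals_healthy, cancer_type, comparison, gene_id, alpha) {
  if (length(vals_stratum) == 0 || length(vals_healthy) == 0) {
    return(tibble::tibble(
      cancer_type = cancer_type, gene_id = gene_id, comparison = comparison,
      statistic = NA_real_, p_two_sided = NA_real_, direction = NA_character_,
      median_stratum = NA_real_, median_healthy = NA_real_,
      n_stratum = length(vals_stratum), n_healthy = length(vals_healthy),
      testable = FALSE
    ))
  }
  wt <- wilcoxon_rank_sum(vals_stratum, vals_healthy)
  med_s <- median(vals_stratum)
  med_h <- median(vals_healthy)
  direction <- if (wt$p < alpha) {
    if (med_s < med_h) "down" else if (med_s > med_h) "up" else "ns"
  } else {
    "ns"
  }
  tibble::tibble(
    cancer_type = cancer_type, gene_id = gene_id, comparison = comparison,
    statistic = wt$statistic, p_two_sided = wt$p, direction = direction,
    median_stratum = med_s, median_healthy = med_h,
    n_stratum = length(vals_stratum), n_healthy = length(vals_healthy),
    testable = TRUE
  )
}

#' Compare target-gene expression between healthy tissue and regulator strata
#'
#' For every stratified cancer (plus a pooled PANCAN row) runs two Wilcoxon
#' rank-sum tests of the target gene: healthy versus `regulator_high` tumors
#' and healthy versus `regulator_low` tumors. An empty stratum yields a row
#' marked untestable rather than an error.
#'
#' @param expr Expression matrix.
#' @param samples Sample table.
#' @param strata Output of [stratify_by_regulators()].
#' @param target_gene Gene whose expression is compared.
#' @param alpha Significance level for direction calls (default 0.05).
#' @return Tibble with one row per (cancer, comparison), `comparison` in
#'   `healthy_vs_high` / `healthy_vs_low`, plus PANCAN rows.
#' @export
compare_strata_expression <- function(expr, samples, strata, target_gene,
                                      alpha = 0.05) {
  if (!target_gene %in% rownames(expr)) stop("gene not in expression matrix: ", target_gene)
  healthy <- samples[samples$sample_class == "healthy_solid" &
    samples$sample_id %in% colnames(expr), ]
  vals <- expr[target_gene, ]
  rows <- list()
  for (ct in unique(strata$cancer_type)) {
    st <- strata[strata$cancer_type == ct, ]
    h_ids <- healthy$sample_id[healthy$cancer_type == ct]
    hi <- st$sample_id[st$stratum == "regulator_high"]
    lo <- st$sample_id[st$stratum == "regulator_low"]
    rows[[paste0(ct, ":hi")]] <- strata_one(vals[hi], vals[h_ids], ct, "healthy_vs_high", target_gene, alpha)
    rows[[paste0(ct, ":lo")]] <- strata_one(vals[lo], vals[h_ids], ct, "healthy_vs_low", target_gene, alpha)
  }
  h_all <- healthy$sample_id[healthy$cancer_type %in% unique(strata$cancer_type)]
  hi_all <- strata$sample_id[strata$stratum == "regulator_high"]
  lo_all <- strata$sample_id[strata$stratum == "regulator_low"]
  rows[["PANCAN:hi"]] <- strata_one(vals[hi_all], vals[h_all], "PANCAN", "healthy_vs_high", target_gene, alpha)
  rows[["PANCAN:lo"]] <- strata_one(vals[lo_all], vals[h_all], "PANCAN", "healthy_vs_low", target_gene, alpha)
  dplyr::bind_rows(rows)
}

#' Test a focal gene's response to oncogene overexpression
#'
#' Normalizes log2(TPM + 1) expression of the target gene against the mean of
#' the matched Empty-vector control arm (same cell line and timepoint), then
#' for each oncogene runs a two-sided Wilcoxon rank-sum test of the treated
#' samples' normalized values against the Empty samples' normalized values.
#'
#' @param oe_expr Expression matrix in log2(TPM + 1) units.
#' @param design Design tibble with sample_id, cell_line, condition,
#'   timepoint_h (conditions must include `"Empty"` for every cell line and
#'   timepoint present).
#' @param target_gene Gene to test.
#' @param control_condition Name of the control arm (default `"Empty"`).
#' @return List with `normalized` (tibble: sample_id, condition, cell_line,
#'   timepoint_h, normalized_log2) and `tests` (tibble: condition, p,
#'   median_normalized, n).
#' @export
oncogene_effect_test <- function(oe_expr, design, target_gene,
                                 control_condition = "Empty") {
  if (!target_gene %in% rownames(oe_expr)) stop("gene not in expression matrix: ", target_gene)
  stopifnot(all(c("sample_id", "cell_line", "condition", "timepoint_h") %in% names(design)))
  vals <- oe_expr[target_gene, design$sample_id]
  key <- paste(design$cell_line, design$timepoint_h)
  ctrl <- design$condition == control_condition
  if (!all(unique(key) %in% key[ctrl])) {
    stop("missing matched '", control_condition, "' control arm for some (cell line, timepoint)")
  }
  ctrl_mean <- tapply(vals[ctrl], key[ctrl], mean)
  normalized <- tibble::tibble(
    sample_id = design$sample_id,
    condition = design$condition,
    cell_line = design$cell_line,
    timepoint_h = design$timepoint_h,
    normalized_log2 = as.numeric(vals - ctrl_mean[key])
  )
  oncogenes <- setdiff(unique(design$condition), control_condition)
  ctrl_norm <- normalized$normalized_log2[normalized$condition == control_condition]
  tests <- dplyr::bind_rows(lapply(oncogenes, function(og) {
    treated <- normalized$normalized_log2[normalized$condition == og]
    wt <- wilcoxon_rank_sum(treated, ctrl_norm)
    tibble::tibble(
      condition = og, p = wt$p, statistic = wt$statistic,
      median_normalized = median(treated), n = length(treated)
    )
  }))
  list(normalized = normalized, tests = tests)
}

#' Normalize one log2(TPM + 1) value against a control-arm mean
#'
#' Helper exposing the control normalization on its own: `log2(tpm + 1)`
#' minus the mean log2(TPM + 1) of the matched control arm.
#'
#' @param tpm Raw TPM value(s).
#' @param control_mean_log2 Mean log2(TPM + 1) of the matched control arm.
#' @return Normalized value(s) in log2 units.
#' @export
normalize_to_control <- function(tpm, control_mean_log2) {
  log2(tpm + 1) - control_mean_log2
}
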