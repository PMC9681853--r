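# Promoter methylation testing: per-sample median beta of probes falling in
# the upstream promoter window, compared tumor vs healthy per cancer.

#' Promoter window of a gene
#'
#' The window covers `window_bp` bases immediately upstream of the TSS,
#' strand-aware: `[tss - window_bp, tss)` on the + strand and
#' `(tss, tss + window_bp]` on the - strand (0-based positions).
#'
#' @param tss 0-based TSS coordinate.
#' @param strand `"+"` or `"-"`.
#' @param window_bp Window width in bp (default 1500).
#' @return Numeric `c(start, end)`, inclusive probe-position bounds.
#' @export
promoter_window <- function(tss, strand, window_bp = 1500L) {
  stopifnot(strand %in% c("+", "-"))
  if (strand == "+") {
    c(max(tss - window_bp, 0), tss - 1)
  } else {
    c(tss + 1, tss + window_bp)
  }
}

#' Promoter methylation test for one gene
#'
#' Selects methylation probes within the upstream promoter window of
#' `gene_id`, computes each sample's median beta across those probes, and
#' compares tumor versus healthy medians with a Wilcoxon rank-sum test per
#' cancer type plus a pooled PANCAN row. If no probe falls in the window the
#' gene is reported untestable.
#'
#' @param meth A `methylation_table`.
#' @param annotation Gene annotation (chrom, tss, strand).
#' @param samples Sample table.
#' @param gene_id Gene whose promoter is tested.
#' @param window_bp Upstream window in bp (default 1500).
#' @param alpha Significance level for the direction call (default 0.05).
#' @return List with `testable` flag, `probes` (ids used), `per_sample`
#'   (tibble sample_id, median_beta) and `tests` (tibble per cancer +
#'   PANCAN: p, median beta per arm, direction).
#' @export
promoter_methylation_test <- function(meth, annotation, samples, gene_id,
                                      window_bp = 1500L, alpha = 0.05) {
  stopifnot(inherits(meth, "methylation_table"))
  ann <- annotation[annotation$gene_id == gene_id, ]
  if (nrow(ann) == 0) stop("gene not in annotation: ", gene_id)
  win <- promoter_window(ann$tss, ann$strand, window_bp)
  in_win <- meth$probes$chrom == ann$chrom &
    meth$probes$position >= win[1] & meth$probes$position <= win[2]
  if (!any(in_win)) {
    return(list(
      testable = FALSE, probes = character(0),
      per_sample = NULL, tests = NULL
    ))
  }
  probe_ids <- meth$probes$probe_id[in_win]
  sub <- meth$betas[probe_ids, , drop = FALSE]
  med <- apply(sub, 2, median, na.rm = TRUE)
  shared <- intersect(names(med), samples$sample_id)
  st <- samples[match(shared, samples$sample_id), ]
  med <- med[shared]
  is_tumor <- st$sample_class == "primary_tumor"
  test_rows <- function(sel, label) {
    vt <- med[sel & is_tumor]
    vh <- med[sel & !is_tumor]
    if (length(vt) == 0 || length(vh) == 0) {
      return(tibble::tibble(
        cancer_type = label, p_two_sided = NA_real_, direction = NA_character_,
        median_beta_tumor = NA_real_, median_beta_healthy = NA_real_,
        n_tumor = length(vt), n_healthy = length(vh), testable = FALSE
      ))
    }
    wt <- wilcoxon_rank_sum(vt, vh)
    dirn <- if (wt$p < alpha) {
      if (median(vt) > median(vh)) "up" else if (median(vt) < median(vh)) "down" else "ns"
    } else {
      "ns"
    }
    tibble::tibble(
      cancer_type = label, p_two_sided = wt$p, direction = dirn,
      median_beta_tumor = median(vt), median_beta_healthy = median(vh),
      n_tumor = length(vt), n_healthy = length(vh), testable = TRUE
    )
  }
  cancers <- unique(st$cancer_type)
  tests <- dplyr::bind_rows(c(
    lapply(cancers, function(ct) test_rows(st$cancer_type == ct, ct)),
    list(test_rows(rep(TRUE, nrow(st)), "PANCAN"))
  ))
  list(
    testable = TRUE, probes = probe_ids,
    per_sample = tibble::tibble(sample_id = shared, median_beta = as.numeric(med)),
    tests = tests
  )
}
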