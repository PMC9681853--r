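# Per-cancer two-group testing and the family-wide consistency test.

#' Wilcoxon rank-sum test
#'
#' Two-sided unmatched Wilcoxon (Mann-Whitney) test. For small tie-free
#' samples (n + m <= 16) the p-value is exact (enumeration over rank
#' assignments); otherwise the normal approximation with tie correction and
#' continuity correction is used. Degenerate input where every value is
#' identical across both samples returns p = 1 with a warning.
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `statistic` (the Mann-Whitney U of `x`) and `p` (two-sided).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1) {
    warning("all values identical across both samples; p = 1")
    return(list(statistic = length(x) * length(y) / 2, p = 1))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && (length(x) + length(y)) <= 16
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE, alternative = "two.sided")
  )
  list(statistic = unname(ht$statistic), p = min(ht$p.value, 1))
}

#' Significance marker for a nominal p-value
#'
#' The conventional star annotation: `****` for p <= 1e-4, `***` for
#' p <= 1e-3, `**` for p <= 0.01, `*` for p <= 0.05, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of markers.
#' @export
significance_marker <- function(p) {
  cut_points <- c(1e-4, 1e-3, 1e-2, 5e-2)
  marks <- c("****", "***", "**", "*")
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    i <- which(pp <= cut_points)
    if (length(i) == 0) "ns" else marks[i[1]]
  }, character(1))
}

diffexp_one <- function(vals_tumor, vals_healthy, cancer_type, gene_id, alpha) {
  wt <- wilcoxon_rank_sum(vals_tumor, vals_healthy)
  med_t <- median(vals_tumor)
  med_h <- median(vals_healthy)
  direction <- if (wt$p < alpha) {
    if (med_t < med_h) "down" else if (med_t > med_h) "up" else "ns"
  } else {
    "ns"
  }
  tibble::tibble(
    cancer_type = cancer_type, gene_id = gene_id,
    statistic = wt$statistic, p_two_sided = wt$p, direction = direction,
    median_tumor = med_t, median_healthy = med_h,
    n_tumor = length(vals_tumor), n_healthy = length(vals_healthy)
  )
}

#' Per-cancer differential expression of one gene
#'
#' Runs a two-sided Wilcoxon rank-sum test of tumor versus healthy expression
#' of `gene_id` in every cancer type passing the per-arm size filter, plus a
#' pooled PANCAN row combining all retained cancers. The direction call is
#' the sign of median(tumor) - median(healthy) when the nominal p is below
#' `alpha`, else `"ns"`.
#'
#' @param expr Expression matrix.
#' @param samples Sample table.
#' @param gene_id Gene to test (must be a row of `expr`).
#' @param alpha Significance level for the direction call (default 0.05).
#' @param min_samples_per_arm Per-arm cohort filter (default 20).
#' @return Tibble of per-cancer rows plus one `"PANCAN"` row.
#' @export
diffexp_per_cancer <- function(expr, samples, gene_id, alpha = 0.05,
                               min_samples_per_arm = 20L) {
  if (!gene_id %in% rownames(expr)) stop("gene not in expression matrix: ", gene_id)
  cancers <- filter_cancers_by_arm_size(expr, samples, min_samples_per_arm)
  if (length(cancers) == 0) stop("no cancer type passes the per-arm size filter")
  present <- samples[samples$sample_id %in% colnames(expr) &
    samples$cancer_type %in% cancers, ]
  vals <- expr[gene_id, present$sample_id]
  is_tumor <- present$sample_class == "primary_tumor"
  rows <- lapply(cancers, function(ct) {
    sel <- present$cancer_type == ct
    diffexp_one(vals[sel & is_tumor], vals[sel & !is_tumor], ct, gene_id, alpha)
  })
  pancan <- diffexp_one(vals[is_tumor], vals[!is_tumor], "PANCAN", gene_id, alpha)
  dplyr::bind_rows(c(rows, list(pancan)))
}

#' Family-wide direction-consistency binomial test
#'
#' Tests whether a focal gene's direction call is more consistent across
#' cancers than expected if each cancer independently produced one of the
#' three calls (down / up / ns) at random. The one-sided tail probability is
#' P(K >= k | n, p0) with k the number of cancers in which the focal gene is
#' called in the `direction` of interest and p0 the null probability of a
#' single call (default 1/3). With k = n = 13 this evaluates to
#' (1/3)^13 = 6.27e-7.
#'
#' @param directions Character vector of per-cancer direction calls for the
#'   focal gene (values in down/up/ns), or an integer `k` when `n_cancers`
#'   is given directly.
#' @param n_cancers Number of cancers n (defaults to `length(directions)`).
#' @param direction Direction counted as a success (default `"down"`).
#' @param null_prob Null probability of a single call (default 1/3).
#' @return List with `p`, `k`, `n`, `null_prob`.
#' @export
family_consistency_binomial <- function(directions, n_cancers = NULL,
                                        direction = "down", null_prob = 1 / 3) {
  if (is.numeric(directions) && length(directions) == 1 && !is.null(n_cancers)) {
    k <- as.integer(directions)
  } else {
    stopifnot(all(directions %in% c("down", "up", "ns")))
    if (is.null(n_cancers)) n_cancers <- length(directions)
    k <- sum(directions == direction)
  }
  n <- as.integer(n_cancers)
  if (n == 0) stop("n_cancers must be >= 1")
  stopifnot(k >= 0, k <= n)
  p <- pbinom(k - 1L, size = n, prob = null_prob, lower.tail = FALSE)
  list(p = p, k = k, n = n, null_prob = null_prob)
}
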