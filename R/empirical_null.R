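# Genome-wide empirical-null tests: the focal gene's statistic (aneuploidy
# association or mutation rate per kb) is standardized against the
# distribution of the same statistic over all genes, and a one-sided
# normal-theory p is assigned to the resulting one-sample z.

#' Tie-aware Spearman correlation
#'
#' Pearson correlation of average ranks. Pairs with a missing value in either
#' vector are removed pairwise; a constant vector yields `NA` with a warning.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return Spearman rho in \[-1, 1\], or `NA`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop("need >= 3 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("constant vector; Spearman correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Genome-wide expression-aneuploidy association for one cancer
#'
#' Spearman correlation between every gene's expression and the aneuploidy
#' score, across the scored tumor samples of one cancer type.
#'
#' @param expr Expression matrix.
#' @param samples Sample table (tumor rows carry aneuploidy scores).
#' @param cancer_type Cancer type to use.
#' @param min_pairs Minimum scored tumor samples (default 3).
#' @return Tibble: cancer_type, gene_id, rho (one row per gene; genes with a
#'   constant expression vector get `NA`).
#' @export
genomewide_association <- function(expr, samples, cancer_type, min_pairs = 3L) {
  sel <- samples$cancer_type == cancer_type &
    samples$sample_class == "primary_tumor" &
    !is.na(samples$aneuploidy_score) &
    samples$sample_id %in% colnames(expr)
  ids <- samples$sample_id[sel]
  if (length(ids) < min_pairs) {
    stop(sprintf("cancer %s has %d scored tumor samples; need >= %d", cancer_type, length(ids), min_pairs))
  }
  score <- samples$aneuploidy_score[sel]
  sub <- expr[, ids, drop = FALSE]
  rho <- suppressWarnings(as.numeric(cor(t(sub), score, method = "spearman")))
  constant <- apply(sub, 1, function(v) length(unique(v[!is.na(v)])) <= 1)
  rho[constant] <- NA_real_
  tibble::tibble(cancer_type = cancer_type, gene_id = rownames(expr), rho = rho)
}

#' One-sided p of a focal gene against the genome-wide null
#'
#' Standardizes the focal gene's statistic against the distribution of the
#' statistic over all genes (one-sample z with the sample sd, denominator
#' n - 1) and returns the one-sided normal-theory p: `pnorm(z)` for the
#' lower tail, `1 - pnorm(z)` for the upper. The focal gene's empirical
#' quantile within the distribution is reported alongside as a diagnostic.
#'
#' @param values Named numeric vector of the per-gene statistic (the null
#'   distribution; must include `focal_gene`); `NA`s are dropped.
#' @param focal_gene Name of the focal gene.
#' @param tail `"lower"` (default) or `"upper"`.
#' @param min_genes Minimum genes required in the null (default 30).
#' @return List with `focal_gene`, `value`, `z`, `p_one_sided`,
#'   `empirical_quantile`, `n_genes`, `tail`.
#' @export
standardized_one_sided_p <- function(values, focal_gene, tail = c("lower", "upper"),
                                     min_genes = 30L) {
  tail <- match.arg(tail)
  if (!focal_gene %in% names(values)) stop("focal gene not in the statistic vector: ", focal_gene)
  v <- values[!is.na(values)]
  if (!focal_gene %in% names(v)) stop("focal gene's statistic is missing (NA)")
  if (length(v) < min_genes) stop("need >= ", min_genes, " genes in the null distribution")
  mu <- mean(v)
  sdv <- sd(v)
  if (sdv == 0) stop("null distribution has zero spread")
  z <- (v[[focal_gene]] - mu) / sdv
  p <- if (tail == "lower") pnorm(z) else pnorm(z, lower.tail = FALSE)
  eq <- if (tail == "lower") mean(v <= v[[focal_gene]]) else mean(v >= v[[focal_gene]])
  list(
    focal_gene = focal_gene, value = v[[focal_gene]], z = z,
    p_one_sided = p, empirical_quantile = eq,
    n_genes = length(v), tail = tail
  )
}

#' Pan-cancer association summary via per-gene median correlation
#'
#' Takes per-cancer association tables, computes each gene's median rho
#' across all cancers (genes with a missing rho in any cancer are dropped so
#' the null stays comparable across genes), and re-runs the standardized
#' one-sided test on the medians.
#'
#' @param tables Tibble of stacked per-cancer association rows
#'   (cancer_type, gene_id, rho) or a list of such tibbles.
#' @param focal_gene Focal gene id.
#' @param tail `"lower"` (default) or `"upper"`.
#' @param drop_incomplete Drop genes absent (or `NA`) in any cancer
#'   (default `TRUE`); otherwise medians use available cancers.
#' @return As [standardized_one_sided_p()], plus `median_rho` (the per-gene
#'   medians) and `n_cancers`.
#' @export
pancan_median_association <- function(tables, focal_gene, tail = c("lower", "upper"),
                                      drop_incomplete = TRUE) {
  tail <- match.arg(tail)
  if (is.data.frame(tables)) tab <- tables else tab <- dplyr::bind_rows(tables)
  n_cancers <- length(unique(tab$cancer_type))
  if (n_cancers < 1) stop("need >= 1 cancer for the pan-cancer median")
  wide <- split(tab$rho, tab$gene_id)
  counts <- vapply(wide, function(v) sum(!is.na(v)), integer(1))
  keep <- if (drop_incomplete) counts == n_cancers else counts >= 1
  if (!any(keep)) stop("no gene observed in all cancers")
  med <- vapply(wide[keep], median, numeric(1), na.rm = TRUE)
  res <- standardized_one_sided_p(med, focal_gene, tail)
  res$median_rho <- med
  res$n_cancers <- n_cancers
  res
}

#' Per-gene mutation rate per kilobase
#'
#' Counts mutation records per gene (optionally restricted to one cancer
#' type and/or effect class) and divides by gene length in kb. Genes with no
#' record get rate 0.
#'
#' @param mutations Mutation table (gene_id, sample_id, cancer_type,
#'   effect_class).
#' @param annotation Gene annotation (gene_id, length_bp); defines the gene
#'   universe of the returned vector.
#' @param cancer_type Optional cancer type filter.
#' @param effect_class Optional effect-class filter.
#' @return Named numeric vector of rates (mutations per kb) over the genes
#'   of `annotation`.
#' @export
mutation_rate_per_kb <- function(mutations, annotation, cancer_type = NULL,
                                 effect_class = NULL) {
  unknown <- setdiff(unique(mutations$gene_id), annotation$gene_id)
  if (length(unknown) > 0) {
    stop("mutated gene(s) missing from annotation: ", paste(head(unknown, 3), collapse = ", "))
  }
  sub <- mutations
  if (!is.null(cancer_type)) sub <- sub[sub$cancer_type %in% cancer_type, ]
  if (!is.null(effect_class)) sub <- sub[sub$effect_class %in% effect_class, ]
  counts <- table(factor(sub$gene_id, levels = annotation$gene_id))
  rate <- as.numeric(counts) / (annotation$length_bp / 1000)
  stats::setNames(rate, annotation$gene_id)
}

#' Mutation-depletion test of a focal gene
#'
#' Per cancer type (and optionally per effect class), standardizes the focal
#' gene's mutation rate per kb against all genes' rates and reports the
#' one-sided lower-tail p; a pooled summary across cancers takes each gene's
#' median per-cancer rate and re-runs the test, mirroring the association
#' pipeline.
#'
#' @param mutations Mutation table.
#' @param annotation Gene annotation.
#' @param focal_gene Focal gene id.
#' @param effect_class Optional effect-class filter applied throughout.
#' @param tail Test tail (default `"lower"`: depletion).
#' @return List with `per_cancer` (tibble: cancer_type, rate, z, p_one_sided,
#'   empirical_quantile) and `pooled` (the median-rate test result).
#' @export
mutation_depletion_test <- function(mutations, annotation, focal_gene,
                                    effect_class = NULL, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  cancers <- sort(unique(mutations$cancer_type))
  per <- lapply(cancers, function(ct) {
    rates <- mutation_rate_per_kb(mutations, annotation, cancer_type = ct, effect_class = effect_class)
    res <- standardized_one_sided_p(rates, focal_gene, tail)
    tibble::tibble(
      cancer_type = ct, rate = res$value, z = res$z,
      p_one_sided = res$p_one_sided, empirical_quantile = res$empirical_quantile
    )
  })
  rate_mat <- vapply(cancers, function(ct) {
    mutation_rate_per_kb(mutations, annotation, cancer_type = ct, effect_class = effect_class)
  }, numeric(nrow(annotation)))
  med <- apply(rate_mat, 1, median)
  names(med) <- annotation$gene_id
  pooled <- standardized_one_sided_p(med, focal_gene, tail)
  list(per_cancer = dplyr::bind_rows(per), pooled = pooled)
}
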