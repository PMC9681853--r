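# Tumor-vs-healthy co-expression rewiring of a focal gene: per-class
# co-expression signatures (Spearman rho of every gene against the focal
# gene), preranked GSEA on each, and the per-set Delta NES
# (NES_tumor - NES_healthy) with the enriched-in-either-class qualifier.

#' Co-expression signature of a focal gene within one sample class
#'
#' Spearman correlation between the focal gene and every other gene across
#' the samples of one class (healthy_solid or primary_tumor), pooled over
#' all cancer types by default; the focal gene itself is excluded. Returns a
#' ranked signature (descending rho).
#'
#' @param expr Expression matrix.
#' @param samples Sample table.
#' @param focal_gene Focal gene id.
#' @param sample_class `"primary_tumor"` or `"healthy_solid"`.
#' @param cancer_types Optional subset of cancer types (default: all).
#' @return A `ranked_signature` over `nrow(expr) - 1` genes.
#' @export
coexpression_signature <- function(expr, samples, focal_gene,
                                   sample_class = c("primary_tumor", "healthy_solid"),
                                   cancer_types = NULL) {
  sample_class <- match.arg(sample_class)
  if (!focal_gene %in% rownames(expr)) stop("focal gene not in expression matrix: ", focal_gene)
  sel <- samples$sample_class == sample_class & samples$sample_id %in% colnames(expr)
  if (!is.null(cancer_types)) sel <- sel & samples$cancer_type %in% cancer_types
  ids <- samples$sample_id[sel]
  if (length(ids) < 3) stop("need >= 3 samples of class ", sample_class)
  focal <- expr[focal_gene, ids]
  if (length(unique(focal[!is.na(focal)])) == 1) stop("focal gene is constant in class ", sample_class)
  others <- setdiff(rownames(expr), focal_gene)
  rho <- suppressWarnings(as.numeric(
    cor(t(expr[others, ids, drop = FALSE]), focal, method = "spearman")
  ))
  names(rho) <- others
  rho <- rho[!is.na(rho)]
  rank_signature(rho, descending = TRUE)
}

#' Delta-NES differential co-expression enrichment
#'
#' Runs the gene-set collection against the tumor and the healthy
#' co-expression signatures with *paired* per-set permutation seeds (so
#' comparing a signature against itself yields exactly zero delta for every
#' set), then records, for each set tested in both classes,
#' `delta_nes = nes_tumor - nes_healthy` and whether the set qualifies as
#' enriched (BH FDR below `fdr_threshold` in at least one class). Sorted by
#' `|delta_nes|` descending.
#'
#' @param sig_tumor,sig_healthy Ranked signatures over the same gene universe.
#' @param collection Gene-set collection.
#' @param n_permutations,seed,weight,min_set_size,max_set_size As
#'   [run_collection()].
#' @param fdr_threshold Enrichment FDR threshold (default 0.05).
#' @return Tibble: set_name, nes_tumor, nes_healthy, delta_nes, fdr_tumor,
#'   fdr_healthy, qualifies.
#' @export
delta_nes_analysis <- function(sig_tumor, sig_healthy, collection,
                               n_permutations = 1000L, seed = 1L, weight = 1,
                               min_set_size = 5L, max_set_size = 5000L,
                               fdr_threshold = 0.05) {
  if (length(intersect(sig_tumor$gene_ids, sig_healthy$gene_ids)) == 0) {
    stop("tumor and healthy signatures share no genes")
  }
  res_t <- run_collection(sig_tumor, collection,
    n_permutations = n_permutations,
    seed = seed, weight = weight, min_set_size = min_set_size, max_set_size = max_set_size
  )
  res_h <- run_collection(sig_healthy, collection,
    n_permutations = n_permutations,
    seed = seed, weight = weight, min_set_size = min_set_size, max_set_size = max_set_size
  )
  shared <- intersect(res_t$set_name, res_h$set_name)
  it <- match(shared, res_t$set_name)
  ih <- match(shared, res_h$set_name)
  out <- tibble::tibble(
    set_name = shared,
    nes_tumor = res_t$nes[it],
    nes_healthy = res_h$nes[ih],
    delta_nes = res_t$nes[it] - res_h$nes[ih],
    fdr_tumor = res_t$fdr_bh[it],
    fdr_healthy = res_h$fdr_bh[ih],
    qualifies = pmin(res_t$fdr_bh[it], res_h$fdr_bh[ih]) < fdr_threshold
  )
  out[order(-abs(out$delta_nes)), ]
}

#' Intersect the member lists of qualifying gene sets
#'
#' Exact set intersection across all named sets, plus Venn-style pairwise
#' overlap counts.
#'
#' @param qualifying_sets Names of >= 2 sets.
#' @param collection Gene-set collection containing them.
#' @return List with `intersection` (character vector), `pairwise` (tibble:
#'   set_a, set_b, overlap) and `n_intersection`.
#' @export
intersect_enriched_targets <- function(qualifying_sets, collection) {
  if (length(qualifying_sets) < 2) stop("need >= 2 qualifying sets to intersect")
  missing_sets <- setdiff(qualifying_sets, names(collection))
  if (length(missing_sets) > 0) stop("set(s) not in collection: ", paste(missing_sets, collapse = ", "))
  members <- collection[qualifying_sets]
  inter <- Reduce(intersect, members)
  pairs <- utils::combn(qualifying_sets, 2)
  pairwise <- tibble::tibble(
    set_a = pairs[1, ], set_b = pairs[2, ],
    overlap = vapply(seq_len(ncol(pairs)), function(i) {
      length(intersect(members[[pairs[1, i]]], members[[pairs[2, i]]]))
    }, integer(1))
  )
  list(intersection = inter, pairwise = pairwise, n_intersection = length(inter))
}

#' Rank target genes by co-expression with the focal gene
#'
#' Orders the given targets by their tumor-signature Spearman rho, by
#' absolute value (default) or signed, and returns the top `top_k`.
#'
#' @param sig_tumor Tumor co-expression `ranked_signature`.
#' @param target_genes Targets, all present in the signature.
#' @param top_k Number of genes to return (default all).
#' @param by `"absolute"` (default) or `"signed"` ordering.
#' @return Tibble: gene_id, rho, ordered as requested.
#' @export
rank_targets_by_coexpression <- function(sig_tumor, target_genes,
                                         top_k = length(target_genes),
                                         by = c("absolute", "signed")) {
  by <- match.arg(by)
  if (length(target_genes) == 0) stop("empty target list")
  missing_genes <- setdiff(target_genes, sig_tumor$gene_ids)
  if (length(missing_genes) > 0) {
    stop("target(s) not in signature: ", paste(head(missing_genes, 3), collapse = ", "))
  }
  rho <- sig_tumor$scores[match(target_genes, sig_tumor$gene_ids)]
  ord <- if (by == "absolute") order(-abs(rho), target_genes) else order(-rho, target_genes)
  out <- tibble::tibble(gene_id = target_genes[ord], rho = rho[ord])
  head(out, max(top_k, 0))
}
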