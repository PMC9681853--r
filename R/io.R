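# Tabular formats used throughout the pipeline.
#
# ExpressionMatrix  - numeric matrix, rownames = gene ids, colnames = sample ids,
#                     values in log2(x + 1) units, finite and >= 0.
# SampleTable       - tibble: sample_id, cancer_type, sample_class
#                     (healthy_solid | primary_tumor), aneuploidy_score
#                     (NA for healthy samples).
# GeneAnnotation    - tibble: gene_id, length_bp, chrom, tss (0-based), strand.
# MutationTable     - tibble: gene_id, sample_id, cancer_type, effect_class,
#                     one row per somatic mutation record.
# MethylationTable  - list(probes = tibble(probe_id, chrom, position),
#                     betas = matrix probes x samples in [0, 1]).
# GeneSetCollection - named list of character vectors (unique members),
#                     "descriptions" attribute parallel to the names.
#
# All genomic coordinates are 0-based; BED intervals are half-open.

SAMPLE_CLASSES <- c("healthy_solid", "primary_tumor")

#' Validate an expression matrix
#'
#' Checks the invariants of the pipeline's expression container: a numeric
#' genes-by-samples matrix with unique row and column names and finite,
#' non-negative values.
#'
#' @param mat Numeric matrix, rownames = gene ids, colnames = sample ids.
#' @return The matrix, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("expression matrix must be a numeric matrix")
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("expression matrix must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(mat))) {
    dup <- rownames(mat)[duplicated(rownames(mat))][1]
    stop("duplicate gene id in expression matrix: ", dup)
  }
  if (anyDuplicated(colnames(mat))) {
    dup <- colnames(mat)[duplicated(colnames(mat))][1]
    stop("duplicate sample id in expression matrix: ", dup)
  }
  bad <- which(!is.finite(mat) & !is.na(mat))
  if (length(bad) > 0) {
    stop("non-finite expression value at position ", bad[1])
  }
  if (any(mat < 0, na.rm = TRUE)) {
    stop("negative expression value; matrix must be in log2(x + 1) units")
  }
  invisible(mat)
}

#' Read a genes-by-samples expression TSV
#'
#' Expects a header row of sample ids and a first column of gene ids; all
#' remaining cells numeric (empty cells are treated as missing and dropped
#' pairwise by downstream stages).
#'
#' @param path TSV path.
#' @return A validated expression matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs a gene-id column plus >=1 sample column: ", path)
  genes <- df[[1]]
  if (anyDuplicated(genes)) {
    stop("duplicate gene id in ", path, ": ", genes[duplicated(genes)][1])
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals) & vals != "", arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-numeric expression cell at gene '%s', sample '%s' in %s",
      genes[bad[1, 1]], colnames(vals)[bad[1, 2]], path
    ))
  }
  dimnames(num) <- list(genes, colnames(df)[-1])
  validate_expression_matrix(num)
  num
}

#' Write a genes-by-samples expression TSV
#'
#' Values are formatted with 17 significant digits so that a write/read
#' round trip reproduces the doubles exactly.
#'
#' @param mat Expression matrix.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  validate_expression_matrix(mat)
  fmt <- function(v) {
    out <- formatC(v, digits = 17, format = "g")
    out[is.na(v)] <- ""
    trimws(out)
  }
  lines <- c(
    paste(c("gene_id", colnames(mat)), collapse = "\t"),
    vapply(seq_len(nrow(mat)), function(i) {
      paste(c(rownames(mat)[i], fmt(mat[i, ])), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Validate a sample table
#' @param samples Tibble with sample_id, cancer_type, sample_class,
#'   aneuploidy_score columns.
#' @return The table, invisibly, if valid.
#' @export
validate_sample_table <- function(samples) {
  need <- c("sample_id", "cancer_type", "sample_class", "aneuploidy_score")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) stop("sample table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in sample table")
  if (!all(samples$sample_class %in% SAMPLE_CLASSES)) {
    stop("sample_class must be one of: ", paste(SAMPLE_CLASSES, collapse = ", "))
  }
  if (any(is.na(samples$cancer_type) | samples$cancer_type == "")) {
    stop("cancer_type must be non-empty")
  }
  healthy_scored <- samples$sample_class == "healthy_solid" & !is.na(samples$aneuploidy_score)
  if (any(healthy_scored)) stop("aneuploidy_score must be absent for healthy samples")
  if (any(samples$aneuploidy_score < 0, na.rm = TRUE)) stop("aneuploidy_score must be >= 0")
  invisible(samples)
}

#' Read / write a sample table TSV
#' @param path TSV path.
#' @return A validated sample-table tibble.
#' @export
read_sample_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    cancer_type = readr::col_character(),
    sample_class = readr::col_character(),
    aneuploidy_score = readr::col_double()
  ), progress = FALSE)
  validate_sample_table(df)
  df
}

#' @rdname read_sample_tsv
#' @param samples Sample-table tibble.
#' @export
write_sample_tsv <- function(samples, path) {
  validate_sample_table(samples)
  readr::write_tsv(samples, path, na = "")
  invisible(path)
}

#' Read / write a gene annotation TSV
#'
#' Columns: gene_id, length_bp (> 0), chrom, tss (0-based), strand (+/-).
#' @param path TSV path.
#' @return A gene-annotation tibble.
#' @export
read_gene_annotation_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    length_bp = readr::col_integer(),
    chrom = readr::col_character(),
    tss = readr::col_double(),
    strand = readr::col_character()
  ), progress = FALSE)
  validate_gene_annotation(df)
  df
}

#' @rdname read_gene_annotation_tsv
#' @param annotation Gene-annotation tibble.
#' @export
write_gene_annotation_tsv <- function(annotation, path) {
  validate_gene_annotation(annotation)
  readr::write_tsv(annotation, path)
  invisible(path)
}

#' @rdname read_gene_annotation_tsv
#' @export
validate_gene_annotation <- function(annotation) {
  need <- c("gene_id", "length_bp", "chrom", "tss", "strand")
  miss <- setdiff(need, names(annotation))
  if (length(miss) > 0) stop("annotation missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(annotation$gene_id)) stop("duplicate gene_id in annotation")
  if (any(annotation$length_bp <= 0)) stop("length_bp must be > 0")
  if (any(annotation$tss < 0)) stop("tss must be a non-negative 0-based coordinate")
  if (!all(annotation$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  invisible(annotation)
}

#' Read / write a mutation record TSV
#'
#' One row per somatic mutation: gene_id, sample_id, cancer_type, effect_class.
#' @param path TSV path.
#' @return A mutation-table tibble.
#' @export
read_mutation_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    sample_id = readr::col_character(),
    cancer_type = readr::col_character(),
    effect_class = readr::col_character()
  ), progress = FALSE)
}

#' @rdname read_mutation_tsv
#' @param mutations Mutation-table tibble.
#' @export
write_mutation_tsv <- function(mutations, path) {
  readr::write_tsv(mutations, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: tab-separated lines of set name, description, then
#' member gene ids. Duplicate members within a set are dropped with a warning.
#'
#' @param path GMT path.
#' @return Named list of character vectors with a "descriptions" attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descs <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has %d fields; need set name, description, >=1 member", i, length(fields)))
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0) stop(sprintf("GMT line %d (%s) has an empty member list", i, fields[1]))
    if (anyDuplicated(members)) {
      warning(sprintf("GMT set '%s': %d duplicate member(s) dropped", fields[1], sum(duplicated(members))))
      members <- unique(members)
    }
    sets[[fields[1]]] <- members
    descs[fields[1]] <- fields[2]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' @rdname read_gmt
#' @param collection Named list of member vectors.
#' @export
write_gmt <- function(collection, path) {
  descs <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(nm) {
    d <- if (!is.null(descs) && nm %in% names(descs)) descs[[nm]] else "na"
    paste(c(nm, d, collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write methylation probes (BED + beta TSV)
#'
#' Probe coordinates travel as 4-column BED (chrom, start, end, probe_id;
#' 0-based half-open) and per-sample beta values as a probes-by-samples TSV
#' whose first column is probe_id. Betas must lie in \[0, 1\].
#'
#' @param bed_path BED path for probe coordinates.
#' @param beta_path TSV path for beta values.
#' @return A `methylation_table` list with elements `probes` (tibble) and
#'   `betas` (matrix).
#' @export
read_methylation <- function(bed_path, beta_path) {
  bed <- readr::read_tsv(bed_path,
    col_names = c("chrom", "start", "end", "probe_id"),
    col_types = "cddc", progress = FALSE
  )
  betas <- read_expression_like_tsv(beta_path, "probe_id")
  meth <- methylation_table(
    probes = tibble::tibble(probe_id = bed$probe_id, chrom = bed$chrom, position = bed$start),
    betas = betas[bed$probe_id, , drop = FALSE]
  )
  meth
}

#' @rdname read_methylation
#' @param meth A `methylation_table`.
#' @export
write_methylation <- function(meth, bed_path, beta_path) {
  stopifnot(inherits(meth, "methylation_table"))
  bed <- sprintf(
    "%s\t%d\t%d\t%s",
    meth$probes$chrom, as.integer(meth$probes$position),
    as.integer(meth$probes$position) + 1L, meth$probes$probe_id
  )
  writeLines(bed, bed_path)
  df <- tibble::as_tibble(meth$betas, rownames = "probe_id")
  readr::write_tsv(df, beta_path)
  invisible(c(bed_path, beta_path))
}

#' @rdname read_methylation
#' @param probes Tibble with probe_id, chrom, position (0-based).
#' @param betas Probes-by-samples matrix in \[0, 1\].
#' @export
methylation_table <- function(probes, betas) {
  stopifnot(all(c("probe_id", "chrom", "position") %in% names(probes)))
  if (any(probes$position < 0)) stop("probe positions must be non-negative")
  if (anyDuplicated(probes$probe_id)) stop("duplicate probe_id")
  stopifnot(is.matrix(betas), nrow(betas) == nrow(probes))
  if (any(betas < 0 | betas > 1, na.rm = TRUE)) stop("beta values must lie in [0, 1]")
  if (is.null(rownames(betas))) rownames(betas) <- probes$probe_id
  structure(list(probes = probes, betas = betas), class = "methylation_table")
}

# shared reader for matrix-shaped TSVs whose first column is an id
read_expression_like_tsv <- function(path, id_name) {
  spec <- do.call(readr::cols, c(
    list(.default = readr::col_double()),
    stats::setNames(list(readr::col_character()), id_name)
  ))
  df <- readr::read_tsv(path, col_types = spec, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Log-normalize a matrix of non-negative counts or TPMs
#'
#' Applies `log2(x + 1)` elementwise; the standard transform for expression
#' abundances before rank-based testing. Matrices that are already
#' log-normalized should be passed through untouched (`transform = "none"`).
#'
#' @param raw Numeric matrix (or vector) of raw values, all `>= 0`.
#' @param transform `"log2p1"` (default) or `"none"` for pre-normalized input.
#' @return Matrix of the same shape in log2(x + 1) units.
#' @export
log_normalize <- function(raw, transform = c("log2p1", "none")) {
  transform <- match.arg(transform)
  if (any(raw < 0, na.rm = TRUE)) stop("raw values must be >= 0")
  if (transform == "none") return(raw)
  log2(raw + 1)
}

#' Retain cancer types with enough samples in both arms
#'
#' A cancer type is kept only when it has at least `min_samples_per_arm`
#' healthy-solid AND at least that many primary-tumor samples among the
#' samples actually present in the expression matrix. Order follows first
#' appearance in the sample table.
#'
#' @param expr Expression matrix (columns define the usable samples).
#' @param samples Sample table.
#' @param min_samples_per_arm Per-arm minimum (default 20).
#' @return Character vector of retained cancer types (possibly empty).
#' @export
filter_cancers_by_arm_size <- function(expr, samples, min_samples_per_arm = 20L) {
  validate_sample_table(samples)
  present <- samples[samples$sample_id %in% colnames(expr), ]
  cancers <- unique(present$cancer_type)
  keep <- vapply(cancers, function(ct) {
    sub <- present[present$cancer_type == ct, ]
    n_h <- sum(sub$sample_class == "healthy_solid")
    n_t <- sum(sub$sample_class == "primary_tumor")
    n_h >= min_samples_per_arm && n_t >= min_samples_per_arm
  }, logical(1))
  cancers[keep]
}
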