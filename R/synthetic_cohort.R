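# Synthetic multi-cancer cohorts with planted, recorded effects.
#
# The generator emulates the statistical structure the screening pipeline
# assumes in real pan-cancer data: per-cancer healthy/tumor arms of
# log-normalized expression, a focal gene downshifted in every tumor arm,
# per-tumor aneuploidy scores negatively coupled to the focal gene, somatic
# mutation records with a depleted focal-gene rate, promoter methylation
# probes, and one transcription-factor target set whose members co-express
# with the focal gene in tumors only. Every planted parameter (and every
# realized effect size) is recorded in the returned truth object so each
# downstream stage has a parameter-recovery oracle.

#' Configuration of a synthetic multi-cancer cohort
#'
#' Defaults describe the emulated study: 13 cancer types with 25 healthy and
#' 25 tumor samples each, 2000 genes, a focal gene shifted by -1.5 log2 units
#' in every tumor arm, tumor aneuploidy scores targeting Spearman rho = -0.3
#' with the focal gene, a 5x depleted focal mutation rate, and one tumor-only
#' rewired target set (latent-factor weight 0.6).
#'
#' @param n_cancers Number of cancer types (default 13).
#' @param n_healthy,n_tumor Samples per arm per cancer (default 25 each).
#' @param n_genes Number of genes (default 2000).
#' @param focal_gene Focal gene id (default `"TTLL11"`).
#' @param focal_downshift Planted tumor shift of the focal gene, log2 units
#'   (default -1.5).
#' @param aneuploidy_coupling Target Spearman correlation between focal
#'   expression and aneuploidy among tumor samples (default -0.3).
#' @param aneuploidy_range Inclusive integer range of aneuploidy scores
#'   (default `c(0, 39)`).
#' @param n_gene_sets Number of transcription-factor target sets (default 20).
#' @param set_size_range Inclusive range of set sizes (default `c(25, 200)`).
#' @param rewired_set Name of the tumor-rewired set (default `"TF01"`).
#' @param rewiring_weight Loading of the tumor-only shared latent factor on
#'   the focal gene and every rewired-set member (default 0.6; 0 disables).
#' @param mutation_base_rate Somatic mutations per kb per tumor sample
#'   (default 0.02).
#' @param focal_depletion_factor Multiplier on the focal gene's mutation rate
#'   (default 0.2; 1 disables depletion).
#' @param meth_shape1,meth_shape2 Beta shape parameters of probe betas
#'   (defaults 2 and 5, promoter-hypomethylated).
#' @param probes_per_gene Promoter-region probes simulated per gene (default 3).
#' @param regulator_genes Two gene ids used as upstream regulators for
#'   stratification scenarios (default the 2nd and 3rd gene).
#' @param conditional_downshift If `TRUE`, the focal downshift is applied only
#'   to tumor samples in the top `decile_fraction` of either regulator
#'   (default `FALSE`: applied to every tumor sample).
#' @param decile_fraction Fraction defining regulator-high tumors when
#'   `conditional_downshift` is on (default 0.10).
#' @param oe_factor Multiplier applied to the focal gene's TPM under CCNE1 and
#'   CDC25A overexpression in [generate_overexpression_experiment()]
#'   (default 0.7; 1 disables).
#' @param rng_seed Integer global seed; all stages derive child seeds from it.
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_cancers = 13L,
                          n_healthy = 25L,
                          n_tumor = 25L,
                          n_genes = 2000L,
                          focal_gene = "TTLL11",
                          focal_downshift = -1.5,
                          aneuploidy_coupling = -0.3,
                          aneuploidy_range = c(0L, 39L),
                          n_gene_sets = 20L,
                          set_size_range = c(25L, 200L),
                          rewired_set = "TF01",
                          rewiring_weight = 0.6,
                          mutation_base_rate = 0.02,
                          focal_depletion_factor = 0.2,
                          meth_shape1 = 2,
                          meth_shape2 = 5,
                          probes_per_gene = 3L,
                          regulator_genes = NULL,
                          conditional_downshift = FALSE,
                          decile_fraction = 0.10,
                          oe_factor = 0.7,
                          rng_seed = 1L) {
  stopifnot(n_cancers >= 1, n_healthy >= 1, n_tumor >= 1, n_genes >= 10)
  stopifnot(abs(aneuploidy_coupling) < 1)
  stopifnot(length(aneuploidy_range) == 2, aneuploidy_range[1] < aneuploidy_range[2])
  stopifnot(n_gene_sets >= 1, set_size_range[1] >= 2, set_size_range[2] < n_genes)
  stopifnot(mutation_base_rate > 0, focal_depletion_factor > 0)
  stopifnot(rewiring_weight >= 0)
  cfg <- list(
    n_cancers = as.integer(n_cancers),
    n_healthy = as.integer(n_healthy),
    n_tumor = as.integer(n_tumor),
    n_genes = as.integer(n_genes),
    focal_gene = focal_gene,
    focal_downshift = focal_downshift,
    aneuploidy_coupling = aneuploidy_coupling,
    aneuploidy_range = as.integer(aneuploidy_range),
    n_gene_sets = as.integer(n_gene_sets),
    set_size_range = as.integer(set_size_range),
    rewired_set = rewired_set,
    rewiring_weight = rewiring_weight,
    mutation_base_rate = mutation_base_rate,
    focal_depletion_factor = focal_depletion_factor,
    meth_shape1 = meth_shape1,
    meth_shape2 = meth_shape2,
    probes_per_gene = as.integer(probes_per_gene),
    regulator_genes = regulator_genes,
    conditional_downshift = isTRUE(conditional_downshift),
    decile_fraction = decile_fraction,
    oe_factor = oe_factor,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "cohort_config"
  cfg
}

# Solve for the noise scale sigma of the latent construction
#   latent = z_focal + sigma * eps,   score = monotone(latent)
# such that the bivariate-normal Spearman correlation
#   rho_s = (6 / pi) * asin(r / 2),  r = 1 / sqrt(1 + sigma^2)
# hits the target magnitude. Root-finding on sigma.
aneuploidy_noise_scale <- function(target_rho) {
  target <- abs(target_rho)
  if (target < 1e-8) return(Inf)
  f <- function(sigma) (6 / pi) * asin(1 / (2 * sqrt(1 + sigma^2))) - target
  # sigma = 0 gives rho_s ~ 0.5167... (max); large sigma gives ~ 0
  if (f(0) <= 0) stop("aneuploidy_coupling magnitude above the attainable ~0.52 for this construction")
  uniroot(f, c(0, 1e6), tol = 1e-10)$root
}

#' Generate a synthetic multi-cancer cohort
#'
#' Deterministic given `config$rng_seed`: every stage draws from a child seed
#' derived by [derive_seed()]. Per-gene baselines are Normal in log2 units
#' with means ~ Uniform(1, 10) (the focal gene's from Uniform(5, 10), so the
#' planted downshift cannot hit the zero floor) and sd 1; values are clamped
#' at 0 to respect the expression-matrix invariant.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `expr` (expression matrix), `samples`
#'   (sample table), `mutations` (mutation table), `methylation`
#'   (`methylation_table`), `annotation` (gene annotation), `gene_sets`
#'   (collection), and `truth` (list of planted plus realized parameters).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  genes <- c(cfg$focal_gene, sprintf("G%05d", seq_len(cfg$n_genes - 1L)))
  cancers <- sprintf("CANCER%02d", seq_len(cfg$n_cancers))
  regulators <- cfg$regulator_genes
  if (is.null(regulators)) regulators <- genes[2:3]
  stopifnot(all(regulators %in% genes), !cfg$focal_gene %in% regulators)

  # ---- gene annotation -------------------------------------------------
  withr::with_seed(derive_seed(cfg$rng_seed, "annotation"), {
    length_bp <- as.integer(round(exp(runif(cfg$n_genes, log(500), log(1e5)))))
    strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  })
  annotation <- tibble::tibble(
    gene_id = genes,
    length_bp = length_bp,
    chrom = "chr1",
    tss = as.numeric(seq_len(cfg$n_genes)) * 1e5,
    strand = strand
  )

  # ---- sample table ----------------------------------------------------
  per_cancer <- cfg$n_healthy + cfg$n_tumor
  samples <- tibble::tibble(
    sample_id = sprintf("S%05d", seq_len(cfg$n_cancers * per_cancer)),
    cancer_type = rep(cancers, each = per_cancer),
    sample_class = rep(rep(c("healthy_solid", "primary_tumor"),
      times = c(cfg$n_healthy, cfg$n_tumor)
    ), cfg$n_cancers),
    aneuploidy_score = NA_real_
  )
  is_tumor <- samples$sample_class == "primary_tumor"

  # ---- expression ------------------------------------------------------
  n_samp <- nrow(samples)
  withr::with_seed(derive_seed(cfg$rng_seed, "expression"), {
    base_mean <- runif(cfg$n_genes, 1, 10)
    base_mean[1] <- runif(1, 5, 10) # focal gene: keep clear of the zero floor
    expr <- matrix(rnorm(cfg$n_genes * n_samp, mean = base_mean, sd = 1),
      nrow = cfg$n_genes, ncol = n_samp
    )
  })
  dimnames(expr) <- list(genes, samples$sample_id)

  # tumor-only shared latent factor: focal gene + rewired-set members
  withr::with_seed(derive_seed(cfg$rng_seed, "gene_sets"), {
    sizes <- sample(seq(cfg$set_size_range[1], cfg$set_size_range[2]),
      cfg$n_gene_sets,
      replace = TRUE
    )
    pool <- setdiff(genes, c(cfg$focal_gene, regulators))
    gene_sets <- lapply(sizes, function(k) sample(pool, k))
  })
  names(gene_sets) <- sprintf("TF%02d", seq_len(cfg$n_gene_sets))
  attr(gene_sets, "descriptions") <- stats::setNames(
    rep("synthetic transcription-factor target set", cfg$n_gene_sets),
    names(gene_sets)
  )
  stopifnot(cfg$rewired_set %in% names(gene_sets))

  if (cfg$rewiring_weight > 0) {
    withr::with_seed(derive_seed(cfg$rng_seed, "rewiring"), {
      latent <- rnorm(sum(is_tumor))
    })
    loaded <- c(cfg$focal_gene, gene_sets[[cfg$rewired_set]])
    expr[loaded, is_tumor] <- expr[loaded, is_tumor] +
      cfg$rewiring_weight * matrix(latent,
        nrow = length(loaded), ncol = sum(is_tumor), byrow = TRUE
      )
  }

  # planted focal downshift (global or regulator-conditional)
  shifted <- is_tumor
  if (cfg$conditional_downshift) {
    high <- rep(FALSE, n_samp)
    for (ct in cancers) {
      idx <- which(is_tumor & samples$cancer_type == ct)
      for (rg in regulators) {
        k <- ceiling(cfg$decile_fraction * length(idx))
        cut <- sort(expr[rg, idx], decreasing = TRUE)[k]
        high[idx[expr[rg, idx] >= cut]] <- TRUE
      }
    }
    shifted <- high
  }
  expr[cfg$focal_gene, shifted] <- expr[cfg$focal_gene, shifted] + cfg$focal_downshift
  expr[expr < 0] <- 0

  # ---- aneuploidy scores ----------------------------------------------
  sigma <- aneuploidy_noise_scale(cfg$aneuploidy_coupling)
  rng <- cfg$aneuploidy_range
  mid <- mean(rng)
  spread <- diff(range(rng)) / 6
  realized_rho <- stats::setNames(numeric(cfg$n_cancers), cancers)
  withr::with_seed(derive_seed(cfg$rng_seed, "aneuploidy"), {
    for (ct in cancers) {
      idx <- which(is_tumor & samples$cancer_type == ct)
      x <- expr[cfg$focal_gene, idx]
      z <- if (sd(x) > 0) (x - mean(x)) / sd(x) else rep(0, length(x))
      eps <- rnorm(length(idx))
      latent <- if (is.finite(sigma)) {
        (sign(cfg$aneuploidy_coupling) * z + sigma * eps) / sqrt(1 + sigma^2)
      } else {
        eps
      }
      score <- pmin(pmax(round(mid + spread * latent), rng[1]), rng[2])
      samples$aneuploidy_score[idx] <- score
      realized_rho[ct] <- suppressWarnings(cor(x, score, method = "spearman"))
    }
  })

  # ---- mutations -------------------------------------------------------
  rate <- rep(cfg$mutation_base_rate, cfg$n_genes)
  rate[1] <- rate[1] * cfg$focal_depletion_factor
  effect_classes <- c("missense", "truncating", "synonymous")
  mut_list <- vector("list", cfg$n_cancers)
  withr::with_seed(derive_seed(cfg$rng_seed, "mutations"), {
    for (ci in seq_along(cancers)) {
      ct <- cancers[ci]
      tum <- samples$sample_id[is_tumor & samples$cancer_type == ct]
      lambda <- rate * (annotation$length_bp / 1000) * length(tum)
      counts <- rpois(cfg$n_genes, lambda)
      total <- sum(counts)
      mut_list[[ci]] <- tibble::tibble(
        gene_id = rep(genes, counts),
        sample_id = sample(tum, total, replace = TRUE),
        cancer_type = ct,
        effect_class = sample(effect_classes, total, replace = TRUE)
      )
    }
  })
  mutations <- dplyr::bind_rows(mut_list)

  # ---- methylation -----------------------------------------------------
  withr::with_seed(derive_seed(cfg$rng_seed, "methylation"), {
    offsets <- round(runif(cfg$n_genes * cfg$probes_per_gene, -2000, 2000))
    betas <- matrix(
      rbeta(cfg$n_genes * cfg$probes_per_gene * n_samp, cfg$meth_shape1, cfg$meth_shape2),
      nrow = cfg$n_genes * cfg$probes_per_gene, ncol = n_samp
    )
  })
  probe_gene <- rep(seq_len(cfg$n_genes), each = cfg$probes_per_gene)
  probes <- tibble::tibble(
    probe_id = sprintf("cg%07d", seq_along(probe_gene)),
    chrom = "chr1",
    position = pmax(annotation$tss[probe_gene] + offsets, 0)
  )
  colnames(betas) <- samples$sample_id
  rownames(betas) <- probes$probe_id
  methylation <- methylation_table(probes, betas)

  validate_expression_matrix(expr)
  validate_sample_table(samples)

  truth <- list(
    config = unclass(cfg),
    genes = genes,
    cancers = cancers,
    regulator_genes = regulators,
    realized_downshift = stats::setNames(vapply(cancers, function(ct) {
      sel <- samples$cancer_type == ct
      median(expr[cfg$focal_gene, sel & is_tumor]) -
        median(expr[cfg$focal_gene, sel & !is_tumor])
    }, numeric(1)), cancers),
    realized_aneuploidy_rho = realized_rho,
    aneuploidy_noise_scale = sigma,
    rewired_members = gene_sets[[cfg$rewired_set]],
    mutation_rates_per_kb = stats::setNames(rate, genes)
  )

  list(
    expr = expr, samples = samples, mutations = mutations,
    methylation = methylation, annotation = annotation,
    gene_sets = gene_sets, truth = truth
  )
}

#' Generate a synthetic oncogene-overexpression experiment
#'
#' Emulates a 4-cell-line inducible overexpression screen: each cell line
#' carries an Empty-vector control plus three oncogene constructs (CCNE1,
#' CDC25A, MYC), profiled at 48 h and 120 h with two replicates — 64 samples,
#' 16 per oncogene arm. Expression is returned in log2(TPM + 1) units. CCNE1
#' and CDC25A multiply the focal gene's TPM by `oe_factor` (default 0.7);
#' MYC applies no consistent effect.
#'
#' @param config A [cohort_config()]; uses `n_genes`, `focal_gene`,
#'   `oe_factor` and `rng_seed`.
#' @return List with `expr` (log2(TPM+1) matrix), `design` (tibble:
#'   sample_id, cell_line, condition, timepoint_h, replicate), and `truth`.
#' @export
generate_overexpression_experiment <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  cell_lines <- c("RPE1", "MDAMB231", "HCC1806", "BT549")
  conditions <- c("Empty", "CCNE1", "CDC25A", "MYC")
  timepoints <- c(48L, 120L)
  design <- expand.grid(
    replicate = 1:2, timepoint_h = timepoints,
    condition = conditions, cell_line = cell_lines,
    stringsAsFactors = FALSE
  )
  design <- tibble::as_tibble(design[, c("cell_line", "condition", "timepoint_h", "replicate")])
  design$sample_id <- sprintf(
    "%s_%s_%dh_r%d",
    design$cell_line, design$condition, design$timepoint_h, design$replicate
  )
  genes <- c(cfg$focal_gene, sprintf("G%05d", seq_len(cfg$n_genes - 1L)))

  withr::with_seed(derive_seed(cfg$rng_seed, "overexpression"), {
    # baseline TPMs: per-gene, with a mild cell-line effect; log-normal noise
    base_log <- runif(cfg$n_genes, 1, 8) # log2 TPM scale
    line_fx <- matrix(rnorm(cfg$n_genes * length(cell_lines), sd = 0.2),
      nrow = cfg$n_genes
    )
    noise <- matrix(rnorm(cfg$n_genes * nrow(design), sd = 0.3), nrow = cfg$n_genes)
  })
  colnames(line_fx) <- cell_lines
  log_tpm <- base_log + line_fx[, design$cell_line] + noise
  tpm <- 2^log_tpm - 1
  tpm[tpm < 0] <- 0
  affected <- design$condition %in% c("CCNE1", "CDC25A")
  tpm[1, affected] <- tpm[1, affected] * cfg$oe_factor
  expr <- log2(tpm + 1)
  dimnames(expr) <- list(genes, design$sample_id)

  truth <- list(
    config = unclass(cfg),
    planted_factor = cfg$oe_factor,
    affected_conditions = c("CCNE1", "CDC25A"),
    null_conditions = "MYC"
  )
  list(expr = expr, design = design, truth = truth)
}
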