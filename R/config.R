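#' Analysis configuration
#'
#' Bundles the thresholds shared by the screening stages: the significance
#' level for per-cancer direction calls, the minimum per-arm cohort size used
#' to retain a cancer type, the FDR threshold for enriched gene sets, the
#' quantile fraction used to stratify tumors by regulator expression, the
#' promoter window size, and the number of gene-set permutations.
#'
#' @param alpha Two-sided significance level for per-cancer tests (default 0.05).
#' @param min_samples_per_arm Minimum number of samples required in *both* the
#'   healthy and the tumor arm for a cancer type to be retained (default 20).
#' @param fdr_threshold BH FDR threshold below which a gene set counts as
#'   enriched (default 0.05).
#' @param decile_fraction Fraction of tumor samples taken as the "high" (and
#'   "low") stratum per regulator (default 0.10).
#' @param promoter_window_bp Width of the upstream promoter window, in bp,
#'   used for methylation probes (default 1500).
#' @param n_permutations Gene permutations per gene set (default 1000).
#' @param binomial_null_prob Null probability that a single cancer yields any
#'   one of the three direction calls (down/up/ns); default 1/3.
#' @param gsea_weight Weight exponent on |score| in the running sum (default 1).
#' @param min_set_size,max_set_size Gene-set size bounds after intersection
#'   with the signature (defaults 5 and 5000).
#' @param rng_seed Optional integer seed recorded in run manifests.
#'
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(alpha = 0.05,
                            min_samples_per_arm = 20L,
                            fdr_threshold = 0.05,
                            decile_fraction = 0.10,
                            promoter_window_bp = 1500L,
                            n_permutations = 1000L,
                            binomial_null_prob = 1 / 3,
                            gsea_weight = 1,
                            min_set_size = 5L,
                            max_set_size = 5000L,
                            rng_seed = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  stopifnot(min_samples_per_arm >= 1)
  stopifnot(decile_fraction > 0, decile_fraction < 0.5)
  stopifnot(fdr_threshold > 0, fdr_threshold < 1)
  stopifnot(promoter_window_bp > 0)
  stopifnot(n_permutations >= 1)
  stopifnot(binomial_null_prob > 0, binomial_null_prob < 1)
  stopifnot(min_set_size >= 1, max_set_size >= min_set_size)
  cfg <- list(
    alpha = alpha,
    min_samples_per_arm = as.integer(min_samples_per_arm),
    fdr_threshold = fdr_threshold,
    decile_fraction = decile_fraction,
    promoter_window_bp = as.integer(promoter_window_bp),
    n_permutations = as.integer(n_permutations),
    binomial_null_prob = binomial_null_prob,
    gsea_weight = gsea_weight,
    min_set_size = as.integer(min_set_size),
    max_set_size = as.integer(max_set_size),
    rng_seed = rng_seed
  )
  class(cfg) <- "analysis_config"
  cfg
}

#' Read an analysis configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose keys are
#'   arguments of [analysis_config()].
#' @return An `analysis_config` list.
#' @export
read_analysis_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config file must be .yaml, .yml or .json: ", path)
  }
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(analysis_config, raw)
}

#' Derive a child RNG seed from a global seed and a stage label
#'
#' All stochastic stages draw their own child seed by stable hashing of the
#' global seed and a stage name, so each stage is reproducible in isolation.
#' The hash is a 31-ary polynomial over the label's UTF-8 bytes, reduced
#' modulo 2^31 - 1 (always a valid positive R integer seed).
#'
#' @param seed Integer global seed.
#' @param label Character stage label.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1, is.finite(seed), length(label) == 1)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(as.character(label))) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

#' Write a JSON run manifest
#'
#' Records the seed, the configuration (plus its md5 hash) and the package
#' version next to a run's outputs, so a result directory is self-describing.
#'
#' @param path Output JSON path.
#' @param seed Integer seed used for the run.
#' @param config An `analysis_config` (or any serializable list).
#' @param extra Optional named list of additional fields.
#' @return Invisibly, the manifest list.
#' @export
write_run_manifest <- function(path, seed, config, extra = list()) {
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(cfg_json, tmp)
  manifest <- c(
    list(
      seed = seed,
      config = unclass(config),
      config_md5 = unname(tools::md5sum(tmp)),
      package = "pancanscreen",
      version = as.character(utils::packageVersion("pancanscreen"))
    ),
    extra
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
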