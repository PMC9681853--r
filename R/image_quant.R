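# Background-subtracted immunofluorescence intensity ratios for ROI-level
# measurements of a tubulin post-translational-modification channel against
# the total-tubulin channel:
#
#   normalized = (RawIntensity_x  - Area * mean(Noise_x))
#              / (RawIntensity_tub - Area * mean(Noise_tub))
#
# Raw intensities are summed signal over one ROI drawn identically on both
# channels; each noise term is the mean background intensity per unit area
# over at least three background regions within the cell.

#' Normalized PTM / tubulin intensity of one ROI
#'
#' Vectorized over measurements. A negative numerator (PTM signal below
#' background) is allowed and returned as a negative ratio; a non-positive
#' denominator (tubulin signal at or below background) is an error naming
#' the offending ROI.
#'
#' @param raw_x Summed PTM-channel intensity (a.u.), >= 0.
#' @param raw_tub Summed tubulin-channel intensity (a.u.), >= 0.
#' @param area ROI area (consistent units across channels), > 0.
#' @param noise_x_mean,noise_tub_mean Mean background intensity per unit
#'   area per channel, from >= 3 background regions.
#' @param n_noise_regions Number of background regions averaged (default 3;
#'   fewer than 3 triggers a warning).
#' @param roi_id Optional identifier used in error messages.
#' @return Numeric vector of dimensionless normalized intensities.
#' @export
normalized_intensity <- function(raw_x, raw_tub, area, noise_x_mean,
                                 noise_tub_mean, n_noise_regions = 3L,
                                 roi_id = seq_along(raw_x)) {
  if (any(area <= 0)) stop("ROI area must be > 0")
  if (any(raw_x < 0) || any(raw_tub < 0)) stop("raw intensities must be >= 0")
  if (any(n_noise_regions < 3)) {
    warning("noise mean from fewer than 3 background regions")
  }
  num <- raw_x - area * noise_x_mean
  den <- raw_tub - area * noise_tub_mean
  bad <- which(den <= 0)
  if (length(bad) > 0) {
    stop(
      "non-positive background-subtracted tubulin signal for ROI ",
      paste(roi_id[head(bad, 3)], collapse = ", ")
    )
  }
  num / den
}

#' Group summary of normalized intensities
#'
#' Mean and sample sd of normalized intensity per experimental group (the
#' mean +/- SD reporting convention), with an optional two-group Wilcoxon
#' comparison.
#'
#' @param values Numeric vector of normalized intensities.
#' @param group_labels Group label per measurement.
#' @param compare Optional character(2) of group names to compare with a
#'   two-sided Wilcoxon rank-sum test.
#' @return List with `summary` (tibble: group, n, mean, sd — sd is `NA` for
#'   singleton groups) and `comparison` (`NULL` or list with groups and p).
#' @export
batch_normalize <- function(values, group_labels, compare = NULL) {
  stopifnot(length(values) == length(group_labels))
  if (any(table(group_labels) < 1)) stop("each group needs >= 1 measurement")
  groups <- unique(group_labels)
  summary <- dplyr::bind_rows(lapply(groups, function(g) {
    v <- values[group_labels == g]
    tibble::tibble(
      group = g, n = length(v), mean = mean(v),
      sd = if (length(v) > 1) sd(v) else NA_real_
    )
  }))
  comparison <- NULL
  if (!is.null(compare)) {
    stopifnot(length(compare) == 2, all(compare %in% groups))
    wt <- wilcoxon_rank_sum(values[group_labels == compare[1]], values[group_labels == compare[2]])
    comparison <- list(groups = compare, p = wt$p, statistic = wt$statistic)
  }
  list(summary = summary, comparison = comparison)
}

#' Simulate two-channel ROI measurements with planted intensity ratios
#'
#' Fixture generator for the quantification stage: each group gets ROIs
#' whose background-subtracted PTM/tubulin ratio is the planted group ratio
#' up to multiplicative noise; areas, gains and backgrounds vary per ROI.
#'
#' @param group_ratios Named numeric vector of planted ratios per group.
#' @param n_per_group ROIs per group (default 50).
#' @param noise_sd Multiplicative noise sd on the planted ratio (default 0.05).
#' @param seed Integer seed.
#' @return Tibble: roi_id, group, raw_x, raw_tub, area, noise_x_mean,
#'   noise_tub_mean, true_ratio.
#' @export
simulate_roi_measurements <- function(group_ratios, n_per_group = 50L,
                                      noise_sd = 0.05, seed = 1L) {
  stopifnot(!is.null(names(group_ratios)))
  n <- n_per_group * length(group_ratios)
  withr::with_seed(seed, {
    area <- runif(n, 50, 400)
    noise_tub <- runif(n, 1, 5)
    noise_x <- runif(n, 1, 5)
    tub_signal <- runif(n, 500, 5000) # background-subtracted tubulin signal
    ratio <- rep(unname(group_ratios), each = n_per_group) *
      exp(rnorm(n, sd = noise_sd))
  })
  tibble::tibble(
    roi_id = sprintf("roi%04d", seq_len(n)),
    group = rep(names(group_ratios), each = n_per_group),
    raw_x = ratio * tub_signal + area * noise_x,
    raw_tub = tub_signal + area * noise_tub,
    area = area,
    noise_x_mean = noise_x,
    noise_tub_mean = noise_tub,
    true_ratio = ratio
  )
}
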