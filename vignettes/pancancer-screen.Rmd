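---
title: "Screening a focal gene for consistent pan-cancer dysregulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening a focal gene for consistent pan-cancer dysregulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancanscreen)
```

## The screen

`pancanscreen` implements a multi-stage computational screen for a focal gene
(the motivating case is the tubulin glutamylase TTLL11, screened against the
rest of its enzyme family) that asks whether the gene is *consistently*
dysregulated across cancer cohorts, and whether the dysregulation is tied to
chromosomal instability and to a tumor-specific transcriptional program. The
stages are:

1. **Per-cancer differential expression.** For every cancer type with at
   least 20 healthy-solid and 20 primary-tumor samples, a two-sided Wilcoxon
   rank-sum test compares the focal gene's log-normalized expression between
   arms; a direction (down / up / ns) is called from the sign of the median
   difference at the nominal level. A pooled PANCAN row repeats the test on
   all retained samples.
2. **Family-wide consistency.** If a gene is called "down" in $k$ of $n$
   cancers, the chance of such consistency under a null in which each cancer
   independently produces one of the three calls with probability $1/3$ is
   the binomial tail $P(K \ge k \mid n, 1/3)$. With $k = n = 13$ this is
   $(1/3)^{13} \approx 6.3\times10^{-7}$. The null probability is a
   parameter: the three-way-uniform null is a modelling choice, not a
   mathematical necessity.
3. **Aneuploidy association against a genome-wide empirical null.** Per
   cancer, the Spearman correlation $\rho_g$ between every gene's expression
   and the per-tumor aneuploidy score is computed; the focal gene's $\rho$
   is standardized against the distribution of all genes' $\rho$ (one-sample
   $z$, sample sd) and a one-sided normal-theory $p$ is taken, lower tail
   for anticorrelation. The PANCAN view takes each gene's median $\rho$
   across cancers (genes observed in all cancers) and repeats the test.
4. **Mutation-rate depletion.** Per-gene somatic mutation counts divided by
   gene length in kb give per-kb rates; the focal gene's rate is tested
   against the genome-wide rate distribution by the same standardized
   one-sided construction, pooled across cancers by per-gene median rates.
5. **Co-expression rewiring (ΔNES).** Spearman co-expression signatures of
   the focal gene are computed separately in tumor and healthy samples
   (pooled across cancers), each is run through preranked GSEA against a
   transcription-factor target-set collection, and each set's
   $\Delta\mathrm{NES} = \mathrm{NES}_{tumor} - \mathrm{NES}_{healthy}$ is
   reported, flagged by whether the set is enriched (BH FDR < 0.05) in at
   least one class.
6. **Downstream corroboration.** Stratification of tumors by upstream
   regulators (top/bottom decile rule), control-normalized oncogene
   overexpression testing, promoter methylation testing, and the
   background-subtracted immunofluorescence intensity ratio.

## The GSEA engine

The enrichment score is the classic weighted Kolmogorov–Smirnov running sum:
walking down the ranked list, the sum rises by $|s_g|^w / \sum_{set}|s|^w$
at members ($w = 1$ by default) and falls by $1/(N - n_{set})$ at
non-members; the ES is the signed extreme of largest magnitude. The null is
*gene permutation* — random same-size sets — which matches preranked GSEA
semantics; NES divides the ES by the mean |ES| of same-sign null draws, and
the permutation $p$ is $(1 + b)/(1 + m)$ over same-sign draws, so $p$ can
never be zero. Each set's permutation stream derives from a child seed
hashed from the global seed and the set name, which makes results invariant
to collection order and makes the tumor/healthy runs in the ΔNES stage use
*paired* permutations — comparing a signature with itself gives exactly zero
delta for every set.

Numerical details worth knowing: a magnitude tie between the positive and
negative running-sum extreme is resolved to the positive extreme, with a
$10^{-12}$ tolerance so the choice does not depend on the accumulation
order of floating-point sums. Ranking ties are broken lexicographically by
gene id and the policy is recorded in the signature object.

## The synthetic cohort generator

Because the original study's inputs (pan-cancer expression, methylation and
mutation matrices, aneuploidy catalogues, ChIP-seq target lists) are
multi-gigabyte downloads, every stage here is validated against synthetic
cohorts in which the *assumed* data-generating structure is planted
explicitly and recorded:

* 13 cancer types, 25 healthy + 25 tumor samples each, 2000 genes
  (`cohort_config()` defaults). Per-gene baselines are Normal in log2 units
  with means from $U(1, 10)$ and sd 1; values clamp at 0 to respect the
  non-negativity invariant. The focal gene's baseline mean is drawn from
  $U(5, 10)$ so the planted shift cannot press against the zero floor and
  bias the realized effect.
* a **−1.5 log2 downshift** of the focal gene in every tumor arm;
* per-tumor integer **aneuploidy scores (0–39)** coupled to the focal
  gene's standardized expression through a latent affine construction
  $\ell = \pm z_{focal} + \sigma\varepsilon$: the noise scale $\sigma$ is
  found by root-finding on the bivariate-normal identity
  $\rho_s = \tfrac{6}{\pi}\arcsin(r/2)$, $r = 1/\sqrt{1+\sigma^2}$, so the
  realized Spearman correlation hits the target (−0.3 by default) up to the
  mild attenuation of rounding and clamping;
* **mutation records**: per-gene Poisson counts at 0.02 mutations/kb per
  tumor sample, the focal gene's rate multiplied by 0.2, assigned to random
  tumor samples with random effect classes; gene lengths are log-uniform on
  [500 bp, 100 kb], a realistic span that makes the per-kb normalization
  matter;
* one **rewired target set** whose members and the focal gene share a
  tumor-only latent factor with loading 0.6, giving tumor-specific pairwise
  co-expression of roughly $w^2/(1+w^2) \approx 0.26$ and nothing in
  healthy samples;
* **methylation probes**, three per gene within ±2 kb of the TSS, with
  Beta(2, 5) betas and no planted arm difference (the methylation stage is
  expected to report a null, mirroring the negative finding it emulates);
* a **4 cell line × {Empty, CCNE1, CDC25A, MYC} × 2 timepoint × 2
  replicate** overexpression experiment (64 samples, 16 per oncogene arm)
  in which CCNE1 and CDC25A multiply the focal gene's TPM by 0.7 and MYC
  does nothing.

All randomness flows from one seed through stage-labelled child seeds
(`derive_seed()`), so each stage is individually reproducible and the
tumor/healthy GSEA runs can be paired.

What the generator deliberately does **not** emulate: batch effects, tumor
purity, copy-number-driven expression dosage, correlated gene-gene baseline
structure beyond the planted factor, and mutation hotspots or
trinucleotide-context models. Passing recovery tests on these cohorts
therefore shows that the statistics recover the effects they assume when
those effects are present and clean — not that the screen is robust to the
confounders of real TCGA data.

## Choices made where the design was open

* **"Log-normalized" units** are taken as $\log_2(x+1)$, and the transform
  is exposed (`log_normalize(..., transform = "none")`) so pre-normalized
  matrices pass through untouched.
* **Standardization** uses the sample sd ($n-1$); the source method says
  only "standardized". The one-sided $p$ is normal-theory on the $z$ (a
  one-sample Z test); the focal gene's empirical genome-wide quantile is
  reported alongside as a diagnostic, since the two differ when the null
  distribution is far from normal (see limitations).
* **PANCAN medians** drop genes not observed in every cancer, keeping the
  null comparable across genes; median-of-available is available as an
  option. The per-cancer statistics are pooled *after* the median, exactly
  in the order the method describes, not standardized per cancer first.
* **Stratification deciles** are computed per cancer type with the
  inclusive nearest-rank boundary (ties included); a cancer whose high and
  low strata would overlap is skipped rather than double-assigned. The
  "high" stratum is the union over regulators of top deciles, the "low"
  stratum the intersection of bottom deciles.
* **ΔNES bookkeeping**: NES is computed in both classes for every set
  regardless of significance, and the enriched-in-either-class filter is
  recorded as a `qualifies` flag rather than by dropping rows — computing
  both is lossless and keeps the ambiguity of one-sided enrichment visible.
* **Target ranking** by co-expression defaults to absolute $\rho$ (signed
  ordering is an option); "top co-expressing" is ambiguous between the two.
* **Per-cancer p-values are nominal**; BH across cancers is available but
  off by default, matching the reporting convention the screen emulates.
* **ROI intensities** are consumed as summed signal plus a mean background
  per unit area (the noise term is multiplied by the ROI area, which is
  only dimensionally consistent if the raw intensity is a sum).

## Problem sizes used by the test suite

The packaged checks run engine-level oracles exhaustively at small sizes
(all rank assignments for $n+m \le 10$; all $2^{12}-2$ subsets of a
12-gene list), parameter recovery on 20 default-size cohorts (13 × 50
samples, 2000 genes, 1000 permutations per gene set), and null calibration
on 200 cohorts scaled to 500 genes — calibration of a p-value does not
depend on the gene count, and the smaller cohorts keep the suite fast on a
single CPU.

## Known limitations

* The **mutation-rate empirical null is a heavy-tailed scale mixture**: the
  per-kb rate of a short gene is estimated from a handful of counts, so its
  sampling noise dominates the cross-gene spread. Two consequences, both
  visible in the packaged checks: the normal-theory one-sided $p$ for the
  focal mutation rate is *not* uniform under a fully null generator (the
  companion empirical quantile is, by exchangeability), and the power to
  flag even a five-fold depleted gene at the default mutation rates is
  modest — the genome-wide sd caps the attainable $|z|$ near 2. On real
  exomes, with orders of magnitude more samples and mutations per gene, the
  same construction is considerably better behaved; a count-based test
  (e.g. Poisson regression with a length offset) would be the principled
  alternative and is deliberately out of scope here because the screen
  reproduces the standardization procedure as described.
* The aneuploidy coupling calibration is exact for the latent construction
  before rounding and clamping; at the default 0–39 integer range the
  attenuation is well under the ±0.1 tolerance the generator promises, but
  extremely narrow score ranges would attenuate more.
* The Wilcoxon engine switches from exact enumeration to the tie-corrected
  normal approximation at $n+m > 16$ or in the presence of ties; nominal
  levels at small, heavily tied samples inherit the approximation's known
  conservatism.
* GSEA permutation p-values are bounded below by $1/(m+1)$; with the
  default 1000 permutations and 20 sets, BH-adjusted FDRs below ≈0.02 are
  not attainable, which matters if many sets are truly enriched.
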