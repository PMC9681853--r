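# pancanscreen

Pan-cancer screening for consistently dysregulated focal genes.

Large-scale tumor atlases make it possible to ask a sharp question about a
single gene: is it dysregulated *consistently* — across every cancer type,
in the same direction, in a way tied to chromosomal instability and to a
tumor-specific transcriptional program? `pancanscreen` implements that
screen as a reusable R pipeline. The motivating application is the tubulin
glutamylase TTLL11, which stands out within its enzyme family as
downregulated in tumors, anticorrelated with aneuploidy, depleted of
somatic mutations, and co-expression-rewired toward transcription-factor
target programs; the package generalizes the analysis so any focal gene or
gene family can be screened, and ships a synthetic cohort generator that
plants every effect the analysis assumes so each stage has a
parameter-recovery oracle.

The statistical core, for a focal gene $g$:

* **Per-cancer differential expression** — two-sided Wilcoxon rank-sum test
  of $\log_2(x+1)$ expression, tumor vs unmatched healthy solid tissue, per
  cancer type with ≥ 20 samples per arm, plus a pooled PANCAN test;
  direction called from the median difference at the nominal level.
* **Family consistency** — for $k$ of $n$ cancers called "down", the
  binomial tail $P(K \ge k \mid n, p_0 = 1/3)$; with $k = n = 13$,
  $(1/3)^{13} \approx 6.3 \times 10^{-7}$.
* **Genome-wide empirical nulls** — the focal gene's expression–aneuploidy
  Spearman $\rho$ (and, separately, its somatic mutation rate per kb) is
  standardized against the distribution of the same statistic over all
  genes, $z = (v_g - \bar v)/s_v$, with a one-sided normal-theory $p$;
  pan-cancer pooling takes per-gene medians across cancers and repeats the
  test.
* **Co-expression rewiring** — Spearman co-expression signatures of $g$
  computed separately in tumor and healthy samples are run through a
  from-scratch preranked GSEA (running-sum ES, gene-permutation NES, BH
  FDR), and each transcription-factor target set is scored by
  $\Delta\mathrm{NES} = \mathrm{NES}_{tumor} - \mathrm{NES}_{healthy}$.
* **Corroborating stages** — tumor stratification by upstream-regulator
  expression (top/bottom decile rule), oncogene-overexpression effect tests
  normalized to matched empty-vector controls, promoter methylation tests
  (median beta of probes within 1500 bp upstream of the TSS), and
  background-subtracted immunofluorescence intensity ratios
  $(I_x - A\bar{N_x}) / (I_{tub} - A\bar{N_{tub}})$.

## Worked example

Generate the default synthetic cohort — 13 cancer types, 25 healthy + 25
tumor samples each, 2000 genes, with a −1.5 log2 focal downshift, a −0.3
focal–aneuploidy Spearman coupling, a 5× depleted focal mutation rate and
one tumor-rewired target set planted — and run the screen:

```r
library(pancanscreen)

cfg <- cohort_config(rng_seed = 1)
cohort <- generate_cohort(cfg)

de <- diffexp_per_cancer(cohort$expr, cohort$samples, "TTLL11")
head(de[, c("cancer_type", "p_two_sided", "direction",
            "median_tumor", "median_healthy")], 4)
#>   cancer_type p_two_sided direction median_tumor median_healthy
#> 1 CANCER01     0.0000197  down              4.79           6.28
#> 2 CANCER02     0.0000234  down              4.82           6.00
#> 3 CANCER03     0.00000562 down              4.42           6.14
#> 4 CANCER04     0.000245   down              4.31           5.81

calls <- de$direction[de$cancer_type != "PANCAN"]
fam <- family_consistency_binomial(calls)
sprintf("down in %d/%d cancers; binomial P = %.3g", fam$k, fam$n, fam$p)
#> "down in 13/13 cancers; binomial P = 6.27e-07"

assoc <- lapply(unique(cohort$samples$cancer_type), function(ct)
  genomewide_association(cohort$expr, cohort$samples, ct))
aneu <- pancan_median_association(assoc, "TTLL11", tail = "lower")
sprintf("PANCAN median rho = %.3f, z = %.2f, one-sided P = %.3g",
        aneu$value, aneu$z, aneu$p_one_sided)
#> "PANCAN median rho = -0.335, z = -4.47, one-sided P = 3.84e-06"

sig_t <- coexpression_signature(cohort$expr, cohort$samples, "TTLL11", "primary_tumor")
sig_h <- coexpression_signature(cohort$expr, cohort$samples, "TTLL11", "healthy_solid")
dn <- delta_nes_analysis(sig_t, sig_h, cohort$gene_sets, n_permutations = 1000, seed = 1)
head(dn[, c("set_name", "nes_tumor", "nes_healthy", "delta_nes", "qualifies")], 3)
#>   set_name nes_tumor nes_healthy delta_nes qualifies
#> 1     TF01  3.410262   -1.089540  4.499803      TRUE
#> 2     TF12  1.318662   -1.106084  2.424746     FALSE
#> 3     TF17  1.132214   -1.184402  2.316616     FALSE
```

The focal gene is called down in all 13 cancers — family-consistency
binomial P ≈ 6.3 × 10⁻⁷, reproducing the screen's headline analytic value —
its median expression–aneuploidy correlation across cancers is strongly
negative relative to the genome-wide null, and the planted rewired set
(`TF01`) is the only set enriched at FDR < 0.05 and carries the largest
ΔNES. Every planted parameter is recorded in `cohort$truth` for
parameter-recovery checks.

## Documentation

The methods vignette (`vignettes/pancancer-screen.Rmd`) describes the
model and its assumptions, the synthetic-data generator and what it does
and does not emulate, the numerical choices (tie handling, standardization
conventions, permutation pairing) and known limitations — including the
heavy-tailed behaviour of the mutation-rate null at desk-scale cohort
sizes.
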