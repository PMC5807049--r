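# reprodyn

Integrative analysis of transcriptional and epigenetic dynamics across
somatic-cell reprogramming time courses, modelled on the transition from
human fibroblasts to naive induced pluripotent stem cells (iPSCs) under a
doxycycline-inducible OSKM system with 5iLAF naive induction.

Reprogramming to naive pluripotency is not a simple interpolation between the
start and end states: gene networks re-activate in ordered waves that mirror
embryonic development run backwards, including a transient pulse of
transcripts whose expression normally peaks at the 8-cell (8C) stage of the
human embryo — the stage of embryonic genome activation. Detecting and
characterising these waves requires joint analysis of RNA-seq time courses,
transposable-element (TE) expression, RRBS DNA methylation, and histone-mark
ChIP-seq. `reprodyn` packages that analysis as a set of composable, tested
stages, together with simulators that generate every input with planted
ground truth so the full pipeline can be validated at desk scale.

The package is aimed at computational biologists analysing multi-omic
time-course experiments of reprogramming or differentiation, and at method
developers who need a transparent, reproducible reference implementation of
the individual analysis rules.

## Core quantities

- **Stage-specificity score.** For an entity (gene or TE) with expression
  `x_1, ..., x_T` over stages, the score at stage `s` is
  `x_s / mean(x)`, and a stage-specific entity must attain its unique maximum
  at `s`. Scores average to 1 across stages by construction. Low-expression
  candidates (mean < 1e-4 for repeats) are discarded first.
- **Differential expression rule.** Between adjacent timepoints, a gene is DE
  when `|log2((FPKM_b + 1)/(FPKM_a + 1))| > 0.58` (fold change > 1.5).
  Combined DE genes are clustered by k-means (default `k = 14`) in
  correlation distance `1 - Pearson`, and cluster centroids are categorised
  as down-regulated, up-regulated, or transiently up-regulated with a peak
  timepoint.
- **Repeat-class FPKM.** Reads are summed over the elements of a family or
  class and divided by the summed genomic coverage of the unit in kilobases
  and the per-million library-size factor:
  `FPKM = count / (coverage_kb * total_reads / 1e6)`.
- **Methylation dynamics.** Per-cytosine ratios `meth/total`; differentially
  methylated cytosines (DMCs) require a proportion-test p-value below alpha
  *and* an absolute ratio difference of at least 0.1; same-direction DMCs
  within 200 bp merge into DMRs (>= 3 DMCs); naive-specific DMRs are the
  same-direction reciprocal-overlap intersection of the naive-vs-somatic and
  naive-vs-primed DMR sets.
- **Promoter chromatin states.** 200-bp-binned mark tracks are normalized to
  1 million reads, binarized against the genome-wide Poisson rate
  (p < 1e-4), and promoters (TSS +/- 2 kb) take one of four states per mark
  pair — e.g. H3K4me3-only, H3K27me3-only, both (bivalent), none — with
  promoters spanning multiple distinct-state segments discarded. State flows
  across timepoints are tabulated as alluvial count matrices that conserve
  the gene universe exactly.
- **CpG-density classes.** The promoter CpG ratio is the maximum over 500-bp
  windows stepped by 50 bp of `#CpG * L / (#C * #G)`; promoters are HCP
  (ratio > 0.75 and GC > 0.55), LCP (ratio < 0.48) or ICP (otherwise), and
  per-gene regulation modes combine expression-vs-H3K4me3 and
  expression-vs-methylation correlations.

## Worked example

Plant forty 8C-specific genes in a 1,000-gene embryo reference, recover them,
then do the same for transposable elements and test class enrichment:

```r
library(reprodyn)

sim <- simulate_embryo_reference(n_genes = 1000, fold = 5, noise_sd = 0.2,
                                 n_stage_specific_per_stage = 40, seed = 1)
hits <- identify_stage_specific_genes(sim$expression, "8C", score_threshold = 2)
nrow(hits)
#> [1] 40
head(hits, 3)
#>       entity    score
#> 1 gene_00033 3.964145
#> 2 gene_00018 3.876637
#> 3 gene_00028 3.871587
mean(sim$truth$stage_specific$gene %in% hits$entity)  # recall
#> [1] 1
```

All forty planted genes are recovered (score approx. 3.2 expected for a
5-fold peak over 7 stages, against a threshold of 2), with no false
positives. TE quantification aggregates counts by genomic coverage before
scoring, and the planted LTR burst shows up as class-level enrichment:

```r
tes <- simulate_repeat_dataset(n_elements = 300, n_specific = 15, fold = 10, seed = 2)
fpkm <- repeat_fpkm(tes$counts, unit_coverage_kb(tes$annotation, "element"),
                    tes$total_mapped_reads)
top <- top_n_specific_tes(fpkm, "8C", n = 15)
class_enrichment(top$entity, tes$annotation, rownames(tes$counts))
#>   class odds_ratio      p_value n_set_in_class n_class
#> 1   DNA          0 1.000000e+00              0      30
#> 2  LINE          0 1.000000e+00              0      90
#> 3   LTR        Inf 6.153226e-07             15     120
#> 4  SINE          0 1.000000e+00              0      60
```

Time-course clustering recovers the three planted dynamic patterns:

```r
tc <- simulate_timecourse_expression(600, paste0("d", 1:8),
        pattern_mix = c(down = 1/3, up = 1/3, transient = 1/3),
        noise_sd = 0.3, transient_peak = "d4", seed = 3)
cluster_dynamics(log_transform(tc$expression), k = 3, seed = 1)
#> Dynamic expression clusters (correlation-distance k-means)
#>   k = 3 | genes clustered: 600 | zero-variance dropped: 0
#>   cluster categories: down-regulated: 1, up-regulated: 1, transiently up-regulated: 1, other: 0
```

See `vignettes/reprogramming-roadmap.Rmd` for the full methods account.

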