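---
title: "Methods: dissecting reprogramming time courses with reprodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting reprogramming time courses with reprodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reprodyn)
```

## Scope and model of the data

`reprodyn` analyses multi-omic time courses from somatic-cell reprogramming
experiments: one RNA-seq FPKM profile per timepoint (eleven ordered samples
from starting fibroblasts through induction days to the derived naive iPSC
line, by default), an embryo-stage reference expression matrix (oocyte
through late blastocyst), repeat-element read counts with a
RepeatMasker-style element/family/class annotation, per-cytosine RRBS
methylated/total counts, and 200-bp-binned histone-mark ChIP-seq tracks. The
package assumes quantification has already happened — it consumes matrices
and tables, not reads — and that each timepoint is a single (bulk) sample.
All stages therefore use rules that are meaningful without replicate-based
variance estimation; nothing in the package models biological replicates
beyond simple averaging.

The pipeline answers five questions: which genes and transposable elements
are specific to a developmental stage (and do they re-activate during
reprogramming); how do dynamic genes cluster into expression waves; how does
DNA methylation change globally, regionally, and at imprints; how do promoter
chromatin states flow between timepoints; and how does promoter CpG density
stratify the coupling between transcription and epigenetic change.

## Stage specificity

The specificity score of an entity at stage $s$ is $x_s / \bar{x}$, its
expression there over its mean across stages. The score is scale-free,
averages to exactly 1 across stages, and a stage-specific call additionally
requires the entity's maximum to be *uniquely* attained at $s$: a tie means
the data cannot distinguish the stage, so ties disqualify by default
(`allow_ties = FALSE` is configurable). All-zero rows have no defined score
and are excluded with a message rather than silently scored 0.

Candidate filtering removes rows whose mean expression is strictly below
`min_avg`; the boundary is deliberately read strictly, so a row at exactly
the threshold is retained. The default is 1e-4 FPKM for repeats and 0 (off)
for genes: repeat FPKM values computed over megabase-scale class coverage are
legitimately tiny, so the filter exists mainly to drop numerically
meaningless repeat rows, while gene matrices are usually pre-filtered
upstream.

The score threshold for calling stage-specific genes defaults to 2.0. There
is no canonical published value for this cutoff; 2.0 sits comfortably between
the null expectation (a flat entity scores 1 everywhere, and at lognormal
noise of sd 0.2-0.3 the maximum of seven stage scores rarely approaches 2)
and the planted-signal regime (a 5-fold peak over 7 stages scores
$5/(11/7) \approx 3.2$). Counts of stage-specific genes are therefore
threshold-dependent and should be reported together with the threshold.

Set enrichment (e.g. of stage-specific genes within a dynamic cluster) is a
one-sided Fisher's exact test on the 2x2 membership table, whose p-value is
the hypergeometric upper tail of the overlap; the test suite checks this
identity against an explicit summation oracle over every 2x2 table with
universe size up to 30.

## Expression dynamics

FPKM values are transformed as $\log_2(\mathrm{FPKM}+1)$. The differential
expression rule between adjacent timepoints is a pseudo-counted fold change:
DE iff $|\log_2((b+1)/(a+1))| > 0.58$ (fold change > 1.5). The pseudo-count
appears inside the ratio as well as in the transform so that the rule is
defined at zero expression and consistent with the transform; single-sample
timepoints preclude variance-model alternatives. The threshold is strict
(`>`), which matters at the boundary: a 1 to 2 FPKM step gives
$\log_2(3/2) = 0.585 > 0.58$ and is DE.

Genes DE in at least one adjacent comparison form the dynamic set, clustered
by k-means in correlation distance. Correlation distance is realised exactly:
rows are standardised to zero mean and unit norm, after which squared
Euclidean distance equals $2(1 - r)$; `stats::kmeans` (Hartigan-Wong) then
runs with 50 restarts under a fixed seed. This buys the robustness and
determinism of the stock implementation instead of a bespoke k-means;
zero-variance rows, which have no direction in correlation space, are
excluded with a message. `k = 14` is the default for full-scale time courses;
the validation suite uses `k = 3` against three planted patterns.

Cluster centroids are categorised with a log2-scale margin (default 0.5,
about 1.4-fold): up-regulated when the trajectory ends more than the margin
above its start with the maximum at the end, down-regulated symmetric,
transiently up-regulated when an interior maximum beats both endpoints by the
margin (annotated with the peak timepoint), and "other" otherwise. The margin
is a presentation threshold, not an inference: it only separates
visually-flat centroids from called patterns, and any serious use should
report centroid trajectories alongside the labels.

Sample-level structure uses the Pearson correlation matrix over common genes
(zero-variance samples produce flagged `NA` entries, never silent zeros) and
classical (Torgerson) multidimensional scaling via `stats::cmdscale`, with
Euclidean distance on log2 values as the default and the usual caveat that
MDS output is unique only up to rotation and sign.

## Repeat quantification

Element counts aggregate to family or class level by summation, conserving
totals within each partition exactly. The FPKM of an aggregated unit divides
the summed count by the unit's genomic coverage in kilobases — the sum of
member element lengths — and by the per-million library-size factor. The
library-size factor is included by default so the quantity matches its name
(reads per kilobase per *million mapped reads*) and is comparable across
samples; `per_million = FALSE` gives the bare reads-per-kilobase form for
workflows that normalise elsewhere. The ingest model takes the count table at
face value: multi-mapper resolution is upstream's concern, and whether counts
came from unique or all alignments should be stated with the data.

## Methylation dynamics

Per-site ratios are `meth/total` for covered sites. Global dynamics are the
unweighted mean ratio over sites covered at `min_coverage` or more — every
covered site counts equally; a site-weighted alternative is a deliberate
non-default because RRBS coverage is strongly non-uniform and
coverage-weighting would let a few deep CpG islands dominate the global
trend.

DMC calling between two samples tests equality of the two proportions per
site and gates calls on effect size: DMC iff $p < \alpha$ (0.05) **and**
$|\Delta\text{ratio}| \ge$ `min_delta` (0.1), with direction the sign of the
change. The default test is the uncorrected two-sample score (chi-square)
test. The choice between the score test and Fisher's exact test (available as
`test = "fisher"`) was made from an exact power analysis at the package's
design conditions — coverage ~20x per sample, planted effects of
$\Delta = 0.4$ from the methylated compartment (~0.9): enumerating all count
pairs shows the two-sided Fisher test, being conservative at these depths,
cannot exceed ~74% detection there (exact size ~0.02 at the null), while the
score test reaches ~84% power with exact size 0.042-0.053 across null rates —
within the nominal level's sampling band. Both tests are antisymmetric in the
sample order and the suite verifies calibration and power empirically.
Benjamini-Hochberg adjustment across sites is available (`fdr = TRUE`) but
off by default, since single-comparison DMC lists feeding region merging are
conventionally thresholded on raw p.

DMRs merge same-direction DMCs within `max_gap = 200` bp, keep regions with
at least `min_dmcs = 3` supporting calls, and record the mean delta. These
merge parameters are field conventions rather than derived quantities, and
published DMR counts are strongly parameter-dependent; they are exposed in
full. Naive-specific DMRs are regions from the naive-vs-somatic comparison
that reciprocally overlap (>= 50% of both regions) a same-direction region in
the naive-vs-primed comparison — the set logic that isolates changes
distinguishing the naive state from both references. Coordinates are 0-based
half-open throughout. CpG strand collapsing is not performed; the two
strands of a CpG are independent records unless merged upstream.

Imprint-region and promoter methylation use the same unweighted site mean
within supplied BED intervals, flagging regions with no qualifying site.
Per-gene methylation-expression coupling is the Pearson correlation of the
two per-sample vectors, requiring at least 3 defined pairs and flagging
zero-variance genes as undefined rather than zero.

## Promoter chromatin states

Mark tracks are normalized to 1 million reads for signal display and
profiles, and binarized for state calls: a bin is "present" when the Poisson
upper-tail p-value of its count under the genome-wide mean rate is below
1e-4, the long-standing default of binarization-based chromatin-state
analysis. A full emission/transition HMM is deliberately not fitted: the
downstream use collapses to presence/absence of two marks, so a rule-based
four-state labelling (A-only, B-only, both, none) over merged
constant-state segments reproduces the analysis semantics transparently.
This is the package's one intentional methodological substitution and it is
worth restating: states here are threshold calls, not posterior decodings.

A promoter (TSS +/- 2 kb; the flank is fixed by the definition of the
promoter universe, not tuned) takes the state of the single segment it
overlaps. Promoters overlapping more than one *distinct-state* segment are
discarded — "distinct state" rather than "distinct segment" is the operative
reading, since two adjacent same-state segments cannot occur after merging.
Genes off the binned grid are discarded with their own reason code. Discarded
genes stay in the accounting: transition (alluvial) matrices include an
explicit discarded stratum so that every adjacent-timepoint matrix sums to
the full gene universe, a conservation property the suite checks exactly.

TSS profiles average strand-reoriented signal vectors (upstream negative)
over a gene set on the shared bin grid, reporting the number of genes used.

## CpG density and integration

The local CpG ratio of a window is the observed/expected form
$\#\mathrm{CpG} \cdot L / (\#C \cdot \#G)$ with GC content
$(\#C + \#G)/L$; windows with no C or no G have ratio 0 by definition. The
promoter-level value is the maximum over 500-bp windows stepped by 50 bp,
with the leftmost window winning ties. Note a property of the
observed/expected form worth knowing: windows that barely clip the edge of a
CpG-dense block can show very large ratios (few CpGs, but even fewer expected),
so the max-window statistic is stable on compositionally homogeneous
promoters but can be spiky on sharp composition boundaries; the classifier
cutoffs are calibrated for the homogeneous case. Classes are HCP
(ratio > 0.75 and GC > 0.55), LCP (ratio < 0.48), ICP otherwise — the
standard two-threshold convention for human promoters.

Regulation modes combine two per-gene correlations across timepoints:
histone-regulated when expression correlates with promoter H3K4me3 at
$r \ge 0.5$, methylation-regulated when expression anti-correlates with
promoter methylation at $r \le -0.5$, "both" when both hold. The 0.5
threshold is explicitly heuristic — with ~11 timepoints it corresponds
roughly to a nominal p of 0.1 — and the supporting correlations are stored in
the output so any re-thresholding is reproducible. A zero-variance arm is
undefined and simply cannot fire.

Activation timing per up-regulated gene is the first timepoint at which
log-expression crosses the midpoint of its own start-to-end range;
half-demethylation time is defined symmetrically downward. The midpoint
crossing was chosen over fixed thresholds because it is invariant to each
gene's expression scale; genes that do not end above their start are flagged
and excluded from timing rather than forced into it. Classes are compared
with a Kruskal-Wallis rank test (degenerate all-tied inputs report p = 1 by
convention, as identical distributions).

## What the simulators emulate — and what they do not

Each pipeline stage has a generator that emits its inputs with planted truth:

- expression time courses with monotone, transient and flat templates under
  multiplicative lognormal noise (`noise_sd` on the natural-log scale,
  default 0.3, a typical bulk-RNA-seq dispersion scale);
- an embryo-stage reference with `fold`-times peaks at chosen stages
  (default fold 5, sd 0.2);
- repeat counts as Poisson draws around lognormal per-element rates, with a
  planted class-specific burst at one stage;
- methylomes with binomial counts around a per-timepoint trend (default a
  linear 0.8 to 0.3 global demethylation, site-level sd 0.05) and planted
  DMRs that start in the direction-appropriate compartment of the bimodal
  methylome (0.9 for hypo, 0.1 for hyper);
- 200-bp binned mark tracks with Poisson(depth 20) promoter bins over a
  Poisson(1) background, on a genome with one gene per 200 kb so that marked
  promoter bins do not inflate the genome-wide binarization rate — the
  realistic sparse-genome regime the binarizer assumes;
- promoter sequences tiled from fixed-composition 500-bp blocks whose
  windowed CpG ratio and GC content place each promoter unambiguously in its
  class (ratios 1.20 / 0.60 / 0.29 at GC 0.60).

Identical seeds give identical outputs, every truth label resolves against
the emitted data, and generators default to one sample per timepoint with a
planted-truth bundle alongside.

These generators are intentionally idealised. They do not simulate reads,
alignment or mapping artifacts, transcript-length effects, batch structure,
replicate variability, single-cell sparsity, bisulfite conversion failure,
copy-number variation, or genuine genomic sequence. A passing validation
therefore demonstrates that each stage implements its stated rule correctly
and recovers effects of the planted size under the stated noise — it does not
certify performance on real libraries, where upstream quantification quality
dominates.

## Validation problem sizes and numerical conventions

The validation suite and `scripts/acceptance.R` run at desk scale: 1,000
random rows for the specificity oracle (agreement to 1e-12), 5,000 genes with
200 planted 8C genes for recovery (precision/recall >= 0.9 at threshold 2),
10,000 sites each for DMC null calibration (empirical rate within
$\alpha + 3\,\mathrm{SE}$), DMC power (>= 80% at $\Delta = 0.4$, coverage
20), and trend recovery (within 0.02 per timepoint at coverage 50), 200 genes
by 4 timepoints for promoter-state recovery (>= 95% with exact alluvial
conservation), 200 random 4-kb promoters for the exhaustive CpG window oracle
(exact equality), 600 genes for clustering recovery (adjusted Rand index
>= 0.9 at noise 0.3), and every 2x2 table with universe <= 30 for the
Fisher/hypergeometric identity. These sizes were chosen so each check has
tight sampling error while the whole validation completes in well under a
minute per stage.

Other conventions: ties in TE rankings break lexicographically by id so
output order is deterministic; empty DMC/DMR inputs return typed empty frames
rather than NULL; methylation ratios pushed outside [0, 1] by a planted
offset are clamped with a warning rather than rejected; and degenerate
statistical inputs (all-zero expression rows, zero-variance vectors,
uncovered sites, empty regions) are flagged and excluded, never coerced to a
numeric default.

## Known limitations

Published headline numbers from real datasets (counts of stage-specific
genes, DMR tallies, enrichment p-values on specific gene sets) depend on the
underlying datasets and on the exact thresholds used, and are not
reproduction targets of this package; the package reproduces the *rules* and
validates them on planted truth. Cross-system comparisons (naive vs primed courses from
different libraries) require pre-harmonised matrices — batch correction is
out of scope. GFOLD-style posterior fold changes, HMM chromatin-state
learning, peak calling and GO annotation are likewise out of scope by design;
where a stage replaces such a tool with a rule, the vignette section above
says so explicitly.
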