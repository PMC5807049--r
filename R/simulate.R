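#' Simulate a reprogramming time-course expression matrix with planted dynamics
#'
#' Generates a gene-by-timepoint FPKM matrix in which a configurable fraction
#' of genes follows one of three dynamic templates — monotone down-regulation,
#' monotone up-regulation, or a transient pulse peaking at an interior
#' timepoint — with the remainder flat background. Multiplicative lognormal
#' noise models between-timepoint FPKM variability; with `noise_sd = 0` rows
#' equal their templates exactly.
#'
#' @param n_genes Number of genes (>= 10).
#' @param timepoints Ordered sample labels (>= 3); defaults to the eleven
#'   reprogramming timepoints of [reprogramming_timepoints()].
#' @param pattern_mix Named fractions over `c("down","up","transient","flat")`
#'   summing to 1. Integer gene counts are assigned by largest remainder, so
#'   the planted counts match the fractions exactly whenever they divide.
#' @param noise_sd Standard deviation of the lognormal noise on the natural
#'   log scale.
#' @param base_fpkm,high_fpkm Low and high ends of the dynamic templates.
#' @param transient_peak Optional timepoint label (or index) at which every
#'   transient gene peaks; by default each transient gene draws its own
#'   interior peak.
#' @param seed Integer RNG seed; identical seed and configuration give
#'   identical output.
#'
#' @return A list with `expression` (numeric matrix, genes x timepoints) and
#'   `truth`, a list holding `patterns` (data.frame of gene, pattern and, for
#'   transient genes, the peak timepoint) and `rng_seed`.
#' @export
simulate_timecourse_expression <- function(n_genes = 2000,
                                           timepoints = reprogramming_timepoints(),
                                           pattern_mix = c(down = 0.25, up = 0.25,
                                                           transient = 0.2, flat = 0.3),
                                           noise_sd = 0.3,
                                           base_fpkm = 1,
                                           high_fpkm = 10,
                                           transient_peak = NULL,
                                           seed = 1L) {
  if (n_genes < 10) stop("n_genes must be >= 10", call. = FALSE)
  if (length(timepoints) < 3) stop("need at least 3 timepoints", call. = FALSE)
  known <- c("down", "up", "transient", "flat")
  if (is.null(names(pattern_mix)) || !all(names(pattern_mix) %in% known)) {
    stop("pattern_mix must be named with a subset of down/up/transient/flat",
         call. = FALSE)
  }
  mix <- stats::setNames(numeric(4), known)
  mix[names(pattern_mix)] <- pattern_mix
  counts <- allocate_counts(n_genes, mix)
  set.seed(seed)

  nt <- length(timepoints)
  down_tpl <- exp(seq(log(high_fpkm), log(base_fpkm), length.out = nt))
  up_tpl <- rev(down_tpl)
  flat_tpl <- rep(base_fpkm, nt)
  transient_tpl <- function(peak) {
    # log-scale triangle: baseline, full height at the peak, half-height shoulders
    tpl <- rep(log(base_fpkm), nt)
    tpl[peak] <- log(high_fpkm)
    for (j in c(peak - 1L, peak + 1L)) {
      if (j >= 1 && j <= nt) tpl[j] <- (log(base_fpkm) + log(high_fpkm)) / 2
    }
    exp(tpl)
  }

  pattern <- rep(known, counts)
  genes <- sprintf("gene_%05d", seq_len(n_genes))
  peaks <- rep(NA_character_, n_genes)
  m <- matrix(0, n_genes, nt, dimnames = list(genes, timepoints))
  interior <- 2:(nt - 1)
  fixed_peak <- NULL
  if (!is.null(transient_peak)) {
    fixed_peak <- if (is.character(transient_peak)) {
      match(transient_peak, timepoints)
    } else {
      as.integer(transient_peak)
    }
    if (is.na(fixed_peak) || fixed_peak < 2 || fixed_peak > nt - 1) {
      stop("transient_peak must be an interior timepoint", call. = FALSE)
    }
  }
  for (i in seq_len(n_genes)) {
    tpl <- switch(pattern[i],
      down = down_tpl,
      up = up_tpl,
      flat = flat_tpl,
      transient = {
        pk <- fixed_peak %||%
          (if (length(interior) == 1) interior else sample(interior, 1))
        peaks[i] <- timepoints[pk]
        transient_tpl(pk)
      }
    )
    m[i, ] <- tpl
  }
  if (noise_sd > 0) {
    m <- m * exp(matrix(stats::rnorm(n_genes * nt, 0, noise_sd), n_genes, nt))
  }
  label <- c(down = "down-regulated", up = "up-regulated",
             transient = "transient-up", flat = "flat")[pattern]
  truth <- list(
    patterns = data.frame(gene = genes, pattern = unname(label),
                          peak_timepoint = peaks, stringsAsFactors = FALSE),
    rng_seed = seed
  )
  list(expression = m, truth = truth)
}

#' Simulate an embryo-stage reference expression matrix with stage-specific genes
#'
#' For each requested stage, plants genes whose mean expression is `fold` times
#' their baseline at that stage only; all other genes sit at a stage-independent
#' baseline. Lognormal noise applies multiplicatively.
#'
#' @param n_genes Total genes, including planted ones.
#' @param stages Ordered stage labels; defaults to [embryo_stages()].
#' @param specific_stages Stages to plant specific genes for (must be a subset
#'   of `stages`).
#' @param n_stage_specific_per_stage Planted genes per requested stage.
#' @param fold Stage/baseline expression ratio for planted genes (> 1).
#' @param baseline_fpkm Baseline expression level.
#' @param noise_sd Lognormal noise standard deviation (natural log scale).
#' @param seed Integer RNG seed.
#'
#' @return A list with `expression` (genes x stages) and `truth`, whose
#'   `stage_specific` data.frame maps each planted gene to its stage.
#' @export
simulate_embryo_reference <- function(n_genes = 5000,
                                      stages = embryo_stages(),
                                      specific_stages = "8C",
                                      n_stage_specific_per_stage = 200,
                                      fold = 5,
                                      baseline_fpkm = 2,
                                      noise_sd = 0.2,
                                      seed = 1L) {
  if (fold <= 1) stop("fold must be > 1", call. = FALSE)
  if (!all(specific_stages %in% stages)) {
    stop("specific_stages must be a subset of stages", call. = FALSE)
  }
  n_planted <- n_stage_specific_per_stage * length(specific_stages)
  if (n_planted > n_genes) stop("more planted genes than n_genes", call. = FALSE)
  set.seed(seed)

  genes <- sprintf("gene_%05d", seq_len(n_genes))
  m <- matrix(baseline_fpkm, n_genes, length(stages),
              dimnames = list(genes, stages))
  planted_gene <- character(0)
  planted_stage <- character(0)
  idx <- 1L
  for (s in specific_stages) {
    rows <- idx:(idx + n_stage_specific_per_stage - 1L)
    m[rows, s] <- baseline_fpkm * fold
    planted_gene <- c(planted_gene, genes[rows])
    planted_stage <- c(planted_stage, rep(s, length(rows)))
    idx <- idx + n_stage_specific_per_stage
  }
  if (noise_sd > 0) {
    m <- m * exp(matrix(stats::rnorm(length(m), 0, noise_sd), nrow(m), ncol(m)))
  }
  truth <- list(
    stage_specific = data.frame(gene = planted_gene, stage = planted_stage,
                                stringsAsFactors = FALSE),
    rng_seed = seed
  )
  list(expression = m, truth = truth)
}

#' Simulate repeat-element read counts with annotation and planted specificity
#'
#' Emits an integer element-by-sample count matrix, a RepeatMasker-style
#' annotation (element, family, class, genomic length) and planted
#' stage-specific elements whose Poisson read rate is multiplied by `fold`
#' at one stage.
#'
#' @param n_elements Number of repeat elements.
#' @param classes Named fractions of elements per repeat class, summing to 1.
#' @param samples Ordered sample labels.
#' @param families_per_class Number of synthetic families within each class.
#' @param length_range Genomic length range (bp) of individual elements.
#' @param mean_reads Mean Poisson read rate per element per sample.
#' @param n_specific Number of planted stage-specific elements.
#' @param specific_stage Stage at which planted elements are boosted.
#' @param specific_class Class the planted elements are drawn from (planted
#'   elements are reassigned to this class), so class-level enrichment of the
#'   planted set is itself planted.
#' @param fold Rate multiplier at the specific stage.
#' @param seed Integer RNG seed.
#'
#' @return A list with `counts` (integer matrix), `annotation` (data.frame:
#'   element, family, class, length_bp), `total_mapped_reads` (per-sample
#'   library sizes) and `truth` (planted elements, seed).
#' @export
simulate_repeat_dataset <- function(n_elements = 400,
                                    classes = c(LTR = 0.4, LINE = 0.3,
                                                SINE = 0.2, DNA = 0.1),
                                    samples = embryo_stages(),
                                    families_per_class = 3,
                                    length_range = c(500, 8000),
                                    mean_reads = 50,
                                    n_specific = 20,
                                    specific_stage = "8C",
                                    specific_class = names(classes)[1],
                                    fold = 10,
                                    seed = 1L) {
  if (abs(sum(classes) - 1) > 1e-8) stop("class fractions must sum to 1", call. = FALSE)
  if (n_specific > 0 && !specific_stage %in% samples) {
    stop("specific_stage must be one of samples", call. = FALSE)
  }
  set.seed(seed)
  n_per_class <- allocate_counts(n_elements, classes)
  cls <- rep(names(classes), n_per_class)
  elements <- sprintf("%s_elem_%04d", cls, seq_len(n_elements))
  fam <- paste0(cls, "-fam", sample.int(families_per_class, n_elements, replace = TRUE))
  len <- sample(length_range[1]:length_range[2], n_elements, replace = TRUE)
  if (any(len <= 0)) stop("element lengths must be > 0", call. = FALSE)

  # planted stage-specific elements, all from one class
  spec_idx <- integer(0)
  if (n_specific > 0) {
    pool <- which(cls == specific_class)
    if (length(pool) < n_specific) stop("not enough elements in specific_class", call. = FALSE)
    spec_idx <- pool[seq_len(n_specific)]
  }

  base_rate <- stats::rlnorm(n_elements, log(mean_reads), 0.5)
  rate <- matrix(base_rate, n_elements, length(samples))
  colnames(rate) <- samples
  if (length(spec_idx)) rate[spec_idx, specific_stage] <- rate[spec_idx, specific_stage] * fold
  counts <- matrix(stats::rpois(length(rate), rate), n_elements, length(samples),
                   dimnames = list(elements, samples))
  annotation <- data.frame(element = elements, family = fam, class = cls,
                           length_bp = len, stringsAsFactors = FALSE)
  truth <- list(
    specific_elements = data.frame(element = elements[spec_idx],
                                   stage = rep(specific_stage, length(spec_idx)),
                                   stringsAsFactors = FALSE),
    rng_seed = seed
  )
  list(counts = counts, annotation = annotation,
       total_mapped_reads = colSums(counts), truth = truth)
}

#' Simulate a per-cytosine methylation table with a global trend and planted DMRs
#'
#' Background site ratios follow a per-timepoint target mean (e.g. the global
#' demethylation from ~0.8 in fibroblasts to ~0.3 in naive iPSCs) plus a
#' site-level offset; methylated counts are Binomial(coverage, ratio). Sites
#' inside planted DMR intervals start from a direction-appropriate compartment
#' (`hypo` from the methylated compartment, `hyper` from the unmethylated one)
#' and shift by `delta` in the affected samples. Ratios pushed outside [0, 1]
#' are clamped with a warning.
#'
#' @param n_sites Number of cytosine sites.
#' @param timepoints Ordered sample labels.
#' @param trend Target mean ratio per timepoint in [0, 1]; default a linear
#'   0.8 to 0.3 decline.
#' @param dmr_spec Optional data.frame (chrom, start, end, direction, delta)
#'   of disjoint planted DMR intervals; `direction` is "hypo" or "hyper".
#' @param dmr_samples Samples in which the DMR offset applies (default: the
#'   last timepoint).
#' @param dmr_base Base ratio of DMR sites in unaffected samples, named by
#'   direction; defaults to 0.9 (hypo) and 0.1 (hyper), the two modes of a
#'   bimodal methylome.
#' @param coverage Per-site read coverage: a single integer, a vector recycled
#'   over sites, or a function(n) returning integer coverages. Sites drawing
#'   coverage 0 are excluded from the emitted table.
#' @param site_sd Standard deviation of the per-site offset around the trend.
#' @param spacing Mean genomic spacing between consecutive sites (bp).
#' @param seed Integer RNG seed.
#'
#' @return A list with `table` — a long data.frame (chrom, pos, strand, sample,
#'   meth, total); positions 0-based — and `truth` (trend, planted DMRs, the
#'   affected samples, seed).
#' @export
simulate_methylome <- function(n_sites = 10000,
                               timepoints = reprogramming_timepoints(),
                               trend = NULL,
                               dmr_spec = NULL,
                               dmr_samples = NULL,
                               dmr_base = c(hypo = 0.9, hyper = 0.1),
                               coverage = 50,
                               site_sd = 0.05,
                               spacing = 100,
                               seed = 1L) {
  nt <- length(timepoints)
  trend <- trend %||% seq(0.8, 0.3, length.out = nt)
  if (length(trend) != nt) stop("trend must have one value per timepoint", call. = FALSE)
  if (any(trend < 0 | trend > 1)) stop("trend values must lie in [0, 1]", call. = FALSE)
  if (!is.null(dmr_spec)) {
    o <- order(dmr_spec$start)
    if (any(dmr_spec$start[o][-1] < dmr_spec$end[o][-nrow(dmr_spec)])) {
      stop("dmr_spec intervals must be disjoint", call. = FALSE)
    }
  }
  dmr_samples <- dmr_samples %||% timepoints[nt]
  set.seed(seed)

  pos <- cumsum(pmax(1, stats::rpois(n_sites, spacing)))
  cov_fun <- if (is.function(coverage)) coverage else function(n) {
    rep_len(as.integer(coverage), n)
  }

  offset <- stats::rnorm(n_sites, 0, site_sd)
  ratio <- outer(offset, trend, `+`) # sites x timepoints

  in_dmr <- rep(NA_integer_, n_sites)
  if (!is.null(dmr_spec)) {
    for (j in seq_len(nrow(dmr_spec))) {
      hit <- which(pos >= dmr_spec$start[j] & pos < dmr_spec$end[j])
      in_dmr[hit] <- j
      base <- dmr_base[[dmr_spec$direction[j]]]
      ratio[hit, ] <- base + offset[hit]
      shift <- if (dmr_spec$direction[j] == "hypo") -dmr_spec$delta[j] else dmr_spec$delta[j]
      aff <- timepoints %in% dmr_samples
      ratio[hit, aff] <- ratio[hit, aff] + shift
    }
  }
  if (any(ratio < 0 | ratio > 1)) {
    warning("some site ratios fell outside [0, 1] and were clamped")
    ratio <- clamp01(ratio)
  }

  tab <- vector("list", nt)
  for (t in seq_len(nt)) {
    total <- cov_fun(n_sites)
    keep <- total > 0
    meth <- stats::rbinom(sum(keep), total[keep], ratio[keep, t])
    tab[[t]] <- data.frame(
      chrom = "chr1", pos = pos[keep], strand = "+",
      sample = timepoints[t], meth = meth, total = total[keep],
      stringsAsFactors = FALSE
    )
  }
  truth <- list(trend = stats::setNames(trend, timepoints),
                dmrs = dmr_spec, dmr_samples = dmr_samples,
                site_in_dmr = in_dmr, positions = pos, rng_seed = seed)
  list(table = do.call(rbind, tab), truth = truth)
}

#' Simulate binned histone-mark tracks with planted promoter states
#'
#' Builds a synthetic genome of well-spaced genes and, for each timepoint and
#' each of a pair of marks, a dense 200-bp-binned count track: promoter bins of
#' genes whose planted state carries the mark draw Poisson(`depth`) counts, all
#' other bins Poisson(`background`). States are the four-way rule used for
#' promoter classification: first-mark-only, second-mark-only, both, none.
#'
#' @param n_genes Number of genes in the synthetic genome.
#' @param timepoints Ordered stage labels (default four reprogramming stages).
#' @param marks Length-2 character vector of mark names.
#' @param state_assignments Optional gene x timepoint character matrix over
#'   `c("<markA>-only","<markB>-only","both","none")`; random if omitted.
#' @param bin_size Bin width in bp.
#' @param depth Poisson rate of promoter bins carrying a mark.
#' @param background Poisson rate of all other bins.
#' @param flank Promoter half-width around the TSS (bp).
#' @param spacing Distance between consecutive TSSs (bp); promoters must not
#'   overlap (an error if `spacing < 2 * flank` would let conflicting states
#'   collide).
#' @param seed Integer RNG seed.
#'
#' @return A list with `tracks` (list of [mark_track()] objects keyed
#'   `"<mark>|<timepoint>"`), `gene_model` (data.frame: gene, chrom, tss,
#'   strand), and `truth` (`states` matrix, seed).
#' @export
simulate_chromatin_tracks <- function(n_genes = 200,
                                      timepoints = c("hiF-T", "8d", "14d", "niPSC-T"),
                                      marks = c("H3K4me3", "H3K27me3"),
                                      state_assignments = NULL,
                                      bin_size = 200,
                                      depth = 20,
                                      background = 1,
                                      flank = 2000,
                                      spacing = 2e5,
                                      seed = 1L) {
  stopifnot(length(marks) == 2)
  if (spacing < 2 * flank) {
    stop("overlapping promoters: spacing must be >= 2 * flank", call. = FALSE)
  }
  states4 <- c(paste0(marks[1], "-only"), paste0(marks[2], "-only"), "both", "none")
  set.seed(seed)

  genes <- sprintf("gene_%04d", seq_len(n_genes))
  tss <- as.integer(seq_len(n_genes) * spacing)
  # keep TSSs on the bin grid so planted promoters align with whole bins
  tss <- (tss %/% bin_size) * bin_size
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  gene_model <- data.frame(gene = genes, chrom = "chr1", tss = tss,
                           strand = strand, stringsAsFactors = FALSE)
  chrom_len <- (n_genes + 1L) * spacing
  n_bins <- ceiling(chrom_len / bin_size)

  if (is.null(state_assignments)) {
    state_assignments <- matrix(sample(states4, n_genes * length(timepoints),
                                       replace = TRUE),
                                n_genes, length(timepoints),
                                dimnames = list(genes, timepoints))
  } else {
    if (!all(state_assignments %in% states4)) {
      stop("state_assignments contains labels outside the four states", call. = FALSE)
    }
    state_assignments <- state_assignments[genes, timepoints, drop = FALSE]
  }

  prom_bins <- lapply(seq_len(n_genes), function(i) {
    lo <- (tss[i] - flank) %/% bin_size
    hi <- (tss[i] + flank - 1L) %/% bin_size
    (lo:hi) + 1L # 1-based bin indices
  })

  tracks <- list()
  for (t in timepoints) {
    for (k in 1:2) {
      mk <- marks[k]
      rate <- rep(background, n_bins)
      carries <- state_assignments[, t] %in% c(paste0(mk, "-only"), "both")
      for (i in which(carries)) rate[prom_bins[[i]]] <- depth
      if (depth == 0) rate[] <- 0
      counts <- stats::rpois(n_bins, rate)
      tracks[[paste(mk, t, sep = "|")]] <- mark_track(
        counts = counts, bin_size = bin_size, mark = mk, timepoint = t,
        chrom = "chr1"
      )
    }
  }
  truth <- list(states = state_assignments, rng_seed = seed)
  list(tracks = tracks, gene_model = gene_model, truth = truth)
}

# class-specific 500-bp composition blocks: CpG count k with 150 C and 150 G
# per block gives windowed observed/expected CpG ratio k * 500 / (150 * 150)
.cpg_block_params <- list(
  HCP = list(k = 54L, target_ratio = 1.2),   # ratio 1.20, GC 0.60
  ICP = list(k = 27L, target_ratio = 0.6),   # ratio 0.60, GC 0.60
  LCP = list(k = 13L, target_ratio = 13 * 500 / 22500) # ratio 0.289, GC 0.60
)

.cpg_block <- function(class, block_len = 500L, n_c = 150L, n_g = 150L) {
  k <- .cpg_block_params[[class]]$k
  n_at <- block_len - 2L * k - (n_c - k) - (n_g - k)
  at1 <- n_at %/% 2L
  at2 <- n_at - at1
  # order chosen so no junction creates an extra CpG dinucleotide
  c(rep(c("C", "G"), k), rep("C", n_c - k), sample(c("A", "T"), at1, replace = TRUE),
    rep("G", n_g - k), sample(c("A", "T"), at2, replace = TRUE))
}

#' Simulate promoter sequences with planted CpG-density classes
#'
#' Emits one 2 * `flank` bp sequence per gene, tiled from 500-bp composition
#' blocks whose windowed CpG observed/expected ratio and GC content place the
#' promoter unambiguously in its assigned class under [classify_promoter()]
#' (HCP ratio 1.20, ICP 0.60, LCP 0.29; GC 0.60 throughout). A/T filler
#' positions are randomised; composition counts are not.
#'
#' @param n_genes Number of promoters, used when `class_assignments` is a
#'   fraction vector.
#' @param class_assignments Either a named fraction vector over
#'   `c("HCP","ICP","LCP")` summing to 1, or a character vector of classes,
#'   one per gene.
#' @param flank Promoter half-width (bp); sequences have length `2 * flank`.
#' @param seed Integer RNG seed.
#'
#' @return A list with `sequences` (named character vector of promoter
#'   sequences), `gene_model` (gene, chrom, tss, strand) and `truth`
#'   (`classes` named character vector, seed).
#' @export
simulate_promoter_sequences <- function(n_genes = 150,
                                        class_assignments = c(HCP = 1 / 3,
                                                              ICP = 1 / 3,
                                                              LCP = 1 / 3),
                                        flank = 2000,
                                        seed = 1L) {
  set.seed(seed)
  if (is.numeric(class_assignments)) {
    if (!all(names(class_assignments) %in% c("HCP", "ICP", "LCP"))) {
      stop("class fractions must be named HCP/ICP/LCP", call. = FALSE)
    }
    counts <- allocate_counts(n_genes, class_assignments)
    classes <- rep(names(class_assignments), counts)
  } else {
    classes <- as.character(class_assignments)
    if (!all(classes %in% c("HCP", "ICP", "LCP"))) {
      stop("class assignments must be HCP, ICP or LCP", call. = FALSE)
    }
    n_genes <- length(classes)
  }
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  n_blocks <- ceiling(2 * flank / 500)
  seqs <- vapply(classes, function(cl) {
    paste(unlist(replicate(n_blocks, .cpg_block(cl), simplify = FALSE))[
      seq_len(2 * flank)], collapse = "")
  }, character(1))
  names(seqs) <- genes
  gene_model <- data.frame(gene = genes, chrom = "chr1",
                           tss = as.integer(seq_len(n_genes) * 10000L),
                           strand = "+", stringsAsFactors = FALSE)
  truth <- list(classes = stats::setNames(classes, genes), rng_seed = seed)
  list(sequences = seqs, gene_model = gene_model, truth = truth)
}
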