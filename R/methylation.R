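#' Per-site methylation ratio
#'
#' @param meth,total Methylated and total read counts (vectors); sites with
#'   `total == 0` get `NA` (callers exclude them).
#' @return `meth / total`, in [0, 1] where defined.
#' @export
site_ratio <- function(meth, total) {
  if (any(meth > total, na.rm = TRUE) || any(meth < 0, na.rm = TRUE)) {
    stop("need 0 <= meth <= total", call. = FALSE)
  }
  ifelse(total > 0, meth / total, NA_real_)
}

#' Global mean methylation of a sample
#'
#' Unweighted mean of per-site ratios over all sites covered at or above
#' `min_coverage` — the quantity tracked to show global demethylation across
#' a reprogramming course.
#'
#' @param table Methylation table: data.frame with columns `chrom`, `pos`,
#'   `strand`, `sample`, `meth`, `total`.
#' @param sample Sample label.
#' @param min_coverage Minimum total reads per site.
#' @return A list: `mean_ratio`, `n_sites`.
#' @export
methylation_global_mean <- function(table, sample, min_coverage = 1) {
  x <- table[table$sample == sample & table$total >= min_coverage, ]
  if (nrow(x) == 0) stop("no qualifying sites for sample ", sample, call. = FALSE)
  list(mean_ratio = mean(x$meth / x$total), n_sites = nrow(x))
}

#' Call differentially methylated cytosines between two samples
#'
#' Sites covered at `min_coverage` in both samples are tested for a difference
#' in methylation proportion; a DMC requires both `p < alpha` and an absolute
#' ratio difference of at least `min_delta`. The default test is the
#' uncorrected two-sample score (chi-square) test; `test = "fisher"` uses the
#' two-sided Fisher's exact test instead (more conservative at low coverage).
#' Direction is the sign of `ratio_b - ratio_a`: "hypo" for loss, "hyper" for
#' gain in `sample_b`.
#'
#' @param table Methylation table (see [methylation_global_mean()]).
#' @param sample_a,sample_b Sample labels of the comparison.
#' @param min_coverage Minimum total reads in each sample (default 5).
#' @param alpha Significance level on the (optionally adjusted) p-value.
#' @param min_delta Minimum |ratio_b - ratio_a| (default 0.1).
#' @param test "score" (default) or "fisher".
#' @param fdr Apply Benjamini-Hochberg adjustment before thresholding
#'   (default FALSE; `alpha` then applies to raw p-values).
#' @return data.frame with one row per tested site: `chrom`, `pos`, `strand`,
#'   `meth_a`, `total_a`, `meth_b`, `total_b`, `ratio_a`, `ratio_b`, `delta`,
#'   `p_value`, `is_dmc`, `direction` (NA when not a DMC).
#' @export
call_dmcs <- function(table, sample_a, sample_b, min_coverage = 5,
                      alpha = 0.05, min_delta = 0.1,
                      test = c("score", "fisher"), fdr = FALSE) {
  test <- match.arg(test)
  a <- table[table$sample == sample_a & table$total >= min_coverage, ]
  b <- table[table$sample == sample_b & table$total >= min_coverage, ]
  key_a <- paste(a$chrom, a$pos, a$strand)
  key_b <- paste(b$chrom, b$pos, b$strand)
  i <- match(key_a, key_b)
  keep <- !is.na(i)
  a <- a[keep, ]
  b <- b[i[keep], ]
  if (nrow(a) == 0) {
    return(data.frame(chrom = character(0), pos = integer(0), strand = character(0),
                      meth_a = integer(0), total_a = integer(0),
                      meth_b = integer(0), total_b = integer(0),
                      ratio_a = numeric(0), ratio_b = numeric(0), delta = numeric(0),
                      p_value = numeric(0), is_dmc = logical(0),
                      direction = character(0), stringsAsFactors = FALSE))
  }
  ratio_a <- a$meth / a$total
  ratio_b <- b$meth / b$total
  delta <- ratio_b - ratio_a
  p <- if (test == "score") {
    prop_score_p(a$meth, a$total, b$meth, b$total)
  } else {
    vapply(seq_len(nrow(a)), function(j) {
      stats::fisher.test(matrix(c(a$meth[j], a$total[j] - a$meth[j],
                                  b$meth[j], b$total[j] - b$meth[j]), 2))$p.value
    }, numeric(1))
  }
  p_eff <- if (fdr) stats::p.adjust(p, "BH") else p
  is_dmc <- p_eff < alpha & abs(delta) >= min_delta
  data.frame(
    chrom = a$chrom, pos = a$pos, strand = a$strand,
    meth_a = a$meth, total_a = a$total, meth_b = b$meth, total_b = b$total,
    ratio_a = ratio_a, ratio_b = ratio_b, delta = delta, p_value = p,
    is_dmc = is_dmc,
    direction = ifelse(is_dmc, ifelse(delta < 0, "hypo", "hyper"), NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Merge DMCs into differentially methylated regions
#'
#' Same-direction DMCs on the same chromosome whose consecutive positions are
#' at most `max_gap` apart are merged; regions supported by at least
#' `min_dmcs` calls are kept. Intervals are 0-based half-open,
#' `[first_pos, last_pos + 1)`.
#'
#' @param dmcs Output of [call_dmcs()].
#' @param max_gap Maximum gap between supporting DMCs (bp).
#' @param min_dmcs Minimum number of supporting DMCs.
#' @param comparison Optional label stored with each region.
#' @return data.frame: `chrom`, `start`, `end`, `direction`, `mean_delta`,
#'   `n_dmcs`, `comparison`.
#' @export
call_dmrs <- function(dmcs, max_gap = 200, min_dmcs = 3, comparison = NA_character_) {
  x <- dmcs[dmcs$is_dmc, ]
  out <- list()
  for (dir in c("hypo", "hyper")) {
    for (chr in unique(x$chrom[x$direction == dir])) {
      y <- x[x$direction == dir & x$chrom == chr, ]
      y <- y[order(y$pos), ]
      grp <- cumsum(c(1, diff(y$pos) > max_gap))
      for (g in split(y, grp)) {
        if (nrow(g) >= min_dmcs) {
          out[[length(out) + 1]] <- data.frame(
            chrom = chr, start = min(g$pos), end = max(g$pos) + 1L,
            direction = dir, mean_delta = mean(g$delta), n_dmcs = nrow(g),
            comparison = comparison, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      direction = character(0), mean_delta = numeric(0),
                      n_dmcs = integer(0), comparison = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Naive-specific DMRs by same-direction reciprocal overlap
#'
#' Regions from the first list (e.g. naive iPSC vs somatic) that reciprocally
#' overlap — by at least `min_overlap_fraction` of both regions — a region of
#' the same direction in the second list (e.g. naive vs primed iPSC). These
#' are the regions that distinguish the naive state from both references.
#'
#' @param dmrs_vs_somatic,dmrs_vs_primed DMR data.frames from [call_dmrs()].
#' @param min_overlap_fraction Reciprocal overlap fraction (default 0.5).
#' @return The qualifying subset of `dmrs_vs_somatic`.
#' @export
naive_specific_dmrs <- function(dmrs_vs_somatic, dmrs_vs_primed,
                                min_overlap_fraction = 0.5) {
  if (nrow(dmrs_vs_somatic) == 0 || nrow(dmrs_vs_primed) == 0) {
    return(dmrs_vs_somatic[integer(0), , drop = FALSE])
  }
  g1 <- GenomicRanges::GRanges(dmrs_vs_somatic$chrom,
                               IRanges::IRanges(dmrs_vs_somatic$start + 1,
                                                dmrs_vs_somatic$end))
  g2 <- GenomicRanges::GRanges(dmrs_vs_primed$chrom,
                               IRanges::IRanges(dmrs_vs_primed$start + 1,
                                                dmrs_vs_primed$end))
  hits <- GenomicRanges::findOverlaps(g1, g2)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(g1)[q],
                                           IRanges::ranges(g2)[s]))
  ok <- dmrs_vs_somatic$direction[q] == dmrs_vs_primed$direction[s] &
    ov / IRanges::width(g1)[q] >= min_overlap_fraction &
    ov / IRanges::width(g2)[s] >= min_overlap_fraction
  dmrs_vs_somatic[sort(unique(q[ok])), , drop = FALSE]
}

#' Mean methylation of genomic regions in one sample
#'
#' Unweighted mean of per-site ratios inside each region (0-based half-open);
#' regions without a qualifying site are flagged with `NA` so summaries can
#' exclude them.
#'
#' @param table Methylation table.
#' @param regions data.frame with `chrom`, `start`, `end` (and optionally a
#'   `name` column carried through).
#' @param sample Sample label.
#' @param min_coverage Minimum site coverage.
#' @return `regions` with added columns `mean_ratio` and `n_sites`.
#' @export
region_methylation <- function(table, regions, sample, min_coverage = 1) {
  x <- table[table$sample == sample & table$total >= min_coverage, ]
  gr_sites <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$pos + 1, x$pos + 1))
  gr_reg <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start + 1, regions$end))
  hits <- GenomicRanges::findOverlaps(gr_reg, gr_sites)
  ratio <- x$meth / x$total
  mean_ratio <- rep(NA_real_, nrow(regions))
  n_sites <- integer(nrow(regions))
  if (length(hits)) {
    agg <- tapply(ratio[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), mean)
    cnt <- table(S4Vectors::queryHits(hits))
    idx <- as.integer(names(agg))
    mean_ratio[idx] <- as.numeric(agg)
    n_sites[as.integer(names(cnt))] <- as.integer(cnt)
  }
  regions$mean_ratio <- mean_ratio
  regions$n_sites <- n_sites
  regions
}

#' Per-gene correlation of promoter methylation with expression
#'
#' Pearson correlation of the per-sample promoter methylation ratio with the
#' per-sample expression value, gene by gene. Genes with fewer than 3 defined
#' pairs are skipped; zero-variance genes are flagged undefined.
#'
#' @param meth Gene x sample matrix of promoter methylation ratios.
#' @param expr Gene x sample expression matrix (same genes/samples or a
#'   superset; matched by names).
#' @return data.frame: `gene`, `r`, `n`, `flag` ("ok", "undefined"
#'   zero-variance, or "skipped" for < 3 pairs, with `r = NA`).
#' @export
methylation_expression_correlation <- function(meth, expr) {
  genes <- intersect(rownames(meth), rownames(expr))
  samples <- intersect(colnames(meth), colnames(expr))
  res <- lapply(genes, function(g) {
    x <- meth[g, samples]
    y <- expr[g, samples]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) {
      return(data.frame(gene = g, r = NA_real_, n = sum(ok), flag = "skipped",
                        stringsAsFactors = FALSE))
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(data.frame(gene = g, r = NA_real_, n = sum(ok), flag = "undefined",
                        stringsAsFactors = FALSE))
    }
    data.frame(gene = g, r = stats::cor(x[ok], y[ok]), n = sum(ok), flag = "ok",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
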