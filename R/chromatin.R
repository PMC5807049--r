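#' Construct a binned histone-mark track
#'
#' A dense fixed-width-bin read-count track for one mark at one timepoint on
#' one chromosome (multi-chromosome analyses use one track object per
#' chromosome or share the grid convention across objects).
#'
#' @param counts Non-negative integer vector of per-bin read counts, bin 1
#'   covering `[0, bin_size)`.
#' @param bin_size Bin width in bp (default 200).
#' @param mark Mark name (e.g. "H3K4me3").
#' @param timepoint Sample/timepoint label.
#' @param chrom Chromosome name.
#' @param total_reads Total mapped reads (defaults to `sum(counts)`).
#' @return Object of class `mark_track`.
#' @export
mark_track <- function(counts, bin_size = 200, mark, timepoint,
                       chrom = "chr1", total_reads = sum(counts)) {
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  structure(
    list(counts = as.numeric(counts), bin_size = bin_size, mark = mark,
         timepoint = timepoint, chrom = chrom, total_reads = total_reads),
    class = "mark_track"
  )
}

#' @export
print.mark_track <- function(x, ...) {
  cat(sprintf("mark_track: %s @ %s (%s), %d bins of %d bp, %s reads\n",
              x$mark, x$timepoint, x$chrom, length(x$counts), x$bin_size,
              format(x$total_reads, big.mark = ",")))
  invisible(x)
}

#' Depth-normalize a track to 1 million reads
#'
#' @param track A [mark_track()].
#' @return The track with a `signal` element, `count * 1e6 / total_reads`.
#' @export
normalize_track <- function(track) {
  if (track$total_reads <= 0) stop("total mapped reads must be > 0", call. = FALSE)
  track$signal <- track$counts * 1e6 / track$total_reads
  track
}

#' Binarize a track against its genome-wide Poisson background
#'
#' A bin is called present (1) when the upper-tail Poisson p-value of its
#' count under the genome-wide mean rate falls below `p_threshold` — the
#' standard presence/absence binarization for chromatin-state analysis.
#'
#' @param track A [mark_track()].
#' @param p_threshold Upper-tail p-value cutoff (default 1e-4).
#' @return The track with a logical `binary` element.
#' @export
binarize_track <- function(track, p_threshold = 1e-4) {
  lambda <- mean(track$counts)
  p <- stats::ppois(track$counts - 1, lambda, lower.tail = FALSE)
  track$binary <- p < p_threshold
  track
}

# run-length segments of the joint two-mark state along a binary grid
.state_segments <- function(bin_a, bin_b, bin_size) {
  code <- bin_a + 2L * bin_b # 0 none, 1 A-only, 2 B-only, 3 both
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  data.frame(start = starts * bin_size, end = ends * bin_size,
             code = r$values)
}

#' Classify gene promoters into four chromatin states
#'
#' Consecutive bins with the same joint state of the two binarized marks are
#' merged into segments; a gene takes the state of the single segment its
#' promoter (TSS +/- `flank`) overlaps. Promoters overlapping segments of more
#' than one distinct state are discarded, as are promoters off the binned
#' grid.
#'
#' @param track_a,track_b Binarized [mark_track()]s (see [binarize_track()])
#'   on the same grid: mark A and mark B of the pair (e.g. H3K4me3 and
#'   H3K27me3 for bivalency, or H3K4me2 and H3K4me3 for the active pair).
#' @param gene_model data.frame: `gene`, `chrom`, `tss`, `strand`.
#' @param flank Promoter half-width (bp, default 2000).
#' @return data.frame: `gene`, `state` (one of `"<A>-only"`, `"<B>-only"`,
#'   `"both"`, `"none"`, `"discarded"`), `reason` (NA, "multiple_states" or
#'   "off_grid").
#' @export
classify_promoters <- function(track_a, track_b, gene_model, flank = 2000) {
  if (is.null(track_a$binary) || is.null(track_b$binary)) {
    stop("tracks must be binarized first (see binarize_track)", call. = FALSE)
  }
  if (length(track_a$binary) != length(track_b$binary) ||
      track_a$bin_size != track_b$bin_size) {
    stop("tracks must share one bin grid", call. = FALSE)
  }
  bs <- track_a$bin_size
  seg <- .state_segments(track_a$binary, track_b$binary, bs)
  labels <- c("none", paste0(track_a$mark, "-only"),
              paste0(track_b$mark, "-only"), "both")
  grid_end <- length(track_a$binary) * bs

  state <- character(nrow(gene_model))
  reason <- rep(NA_character_, nrow(gene_model))
  for (i in seq_len(nrow(gene_model))) {
    lo <- gene_model$tss[i] - flank
    hi <- gene_model$tss[i] + flank
    if (lo < 0 || hi > grid_end || gene_model$chrom[i] != track_a$chrom) {
      state[i] <- "discarded"
      reason[i] <- "off_grid"
      next
    }
    codes <- unique(seg$code[seg$start < hi & seg$end > lo])
    if (length(codes) > 1) {
      state[i] <- "discarded"
      reason[i] <- "multiple_states"
    } else {
      state[i] <- labels[codes + 1L]
    }
  }
  data.frame(gene = gene_model$gene, state = state, reason = reason,
             stringsAsFactors = FALSE)
}

#' Chromatin-state transition counts across ordered timepoints
#'
#' For each adjacent pair of timepoints, the count matrix of genes moving
#' between promoter states (the numbers behind an alluvial plot). Genes
#' discarded at a timepoint occupy an explicit "discarded" stratum so every
#' matrix conserves the full gene universe.
#'
#' @param states Gene x timepoint character matrix of promoter states (e.g.
#'   built from repeated [classify_promoters()] calls), or a list of
#'   per-timepoint data.frames from `classify_promoters` sharing one gene set.
#' @return A list of transition matrices named "t1->t2"; rows are the source
#'   state, columns the destination.
#' @export
state_transitions <- function(states) {
  if (is.list(states) && !is.matrix(states)) {
    genes <- states[[1]]$gene
    for (s in states) {
      if (!identical(sort(s$gene), sort(genes))) {
        stop("mismatched gene sets across timepoints", call. = FALSE)
      }
    }
    states <- do.call(cbind, lapply(states, function(s) {
      s$state[match(genes, s$gene)]
    }))
    rownames(states) <- genes
  }
  lv <- sort(unique(as.vector(states)))
  out <- list()
  for (j in seq_len(ncol(states) - 1)) {
    nm <- paste0(colnames(states)[j] %||% j, "->",
                 colnames(states)[j + 1] %||% (j + 1))
    out[[nm]] <- table(factor(states[, j], lv), factor(states[, j + 1], lv))
  }
  out
}

#' Average signal profile around transcription start sites
#'
#' Per-gene signal vectors over TSS +/- `window`, reoriented by strand
#' (upstream is negative), averaged over the gene set.
#'
#' @param track A normalized [mark_track()] (see [normalize_track()]).
#' @param gene_model data.frame: `gene`, `chrom`, `tss`, `strand`; genes whose
#'   window leaves the grid are skipped and counted.
#' @param genes Optional subset of gene ids to profile.
#' @param window Half-width of the profiled window (bp).
#' @return Object of class `tss_profile`: data.frame `position` (bp relative
#'   to the TSS, bin midpoints), `signal` (mean), plus attribute `n_genes`.
#' @export
tss_profile <- function(track, gene_model, genes = NULL, window = 5000) {
  if (is.null(track$signal)) stop("track must be normalized first", call. = FALSE)
  if (!is.null(genes)) gene_model <- gene_model[gene_model$gene %in% genes, ]
  if (nrow(gene_model) == 0) stop("empty gene set", call. = FALSE)
  bs <- track$bin_size
  half <- window %/% bs
  n_bins <- length(track$signal)
  prof <- matrix(NA_real_, nrow(gene_model), 2 * half)
  used <- 0L
  for (i in seq_len(nrow(gene_model))) {
    if (gene_model$chrom[i] != track$chrom) next
    tss_bin <- gene_model$tss[i] %/% bs + 1L
    idx <- (tss_bin - half):(tss_bin + half - 1L)
    if (idx[1] < 1 || idx[length(idx)] > n_bins) next
    v <- track$signal[idx]
    if (gene_model$strand[i] == "-") v <- rev(v)
    used <- used + 1L
    prof[used, ] <- v
  }
  if (used == 0) stop("no genes inside the binned grid", call. = FALSE)
  pos <- (seq_len(2 * half) - half - 1L) * bs + bs / 2
  out <- data.frame(position = pos, signal = colMeans(prof[seq_len(used), , drop = FALSE]))
  attr(out, "n_genes") <- used
  class(out) <- c("tss_profile", class(out))
  out
}

#' @export
plot.tss_profile <- function(x, ...) {
  graphics::plot(x$position, x$signal, type = "l",
                 xlab = "distance to TSS (bp)", ylab = "mean signal", ...)
  graphics::abline(v = 0, lty = 2, col = "grey")
  invisible(x)
}
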