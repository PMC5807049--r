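# cumulative per-base indicators used by the sliding-window scan
.seq_profile <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  amb <- !(ch %in% c("A", "C", "G", "T"))
  if (any(amb)) {
    message(sum(amb), " ambiguous bases excluded from CpG counts")
  }
  is_c <- ch == "C"
  is_g <- ch == "G"
  cg_start <- c(is_c[-length(ch)] & is_g[-1], FALSE)
  list(n = length(ch), cum_c = cumsum(is_c), cum_g = cumsum(is_g),
       cum_cg = cumsum(cg_start))
}

.window_stats <- function(prof, start, len) {
  end <- start + len - 1L
  at <- function(cum, i) if (i == 0) 0 else cum[i]
  n_c <- at(prof$cum_c, end) - at(prof$cum_c, start - 1L)
  n_g <- at(prof$cum_g, end) - at(prof$cum_g, start - 1L)
  # CpG dinucleotides fully inside the window start at positions start..end-1
  n_cg <- at(prof$cum_cg, end - 1L) - at(prof$cum_cg, start - 1L)
  ratio <- if (n_c == 0 || n_g == 0) 0 else n_cg * len / (n_c * n_g)
  c(cpg_ratio = ratio, gc_content = (n_c + n_g) / len)
}

#' CpG observed/expected ratio and GC content of one window
#'
#' The CpG ratio is `#CpG * length / (#C * #G)` (observed over expected
#' dinucleotide count), defined as 0 when the window has no C or no G;
#' GC content is `(#C + #G) / length`. Ambiguity codes are excluded from
#' the counts (with a message).
#'
#' @param window A/C/G/T character string.
#' @return Named numeric vector: `cpg_ratio`, `gc_content`.
#' @export
local_cpg_ratio <- function(window) {
  if (!nzchar(window)) stop("empty window", call. = FALSE)
  prof <- .seq_profile(window)
  .window_stats(prof, 1L, prof$n)
}

#' Maximum local CpG ratio of a promoter sequence
#'
#' Slides a `window`-bp window in `step`-bp increments across the promoter
#' (TSS +/- 2 kb by construction) and returns the maximum CpG ratio with the
#' GC content of the maximizing window (leftmost on ties). Sequences shorter
#' than one window are scored as a single full-length window with a message.
#'
#' @param seq Promoter sequence (character).
#' @param window Window length in bp (default 500).
#' @param step Step in bp (default 50).
#' @return A list: `cpg_ratio` (the max), `gc_content` (at the maximizing
#'   window), `window_start` (1-based offset of that window).
#' @export
transcript_cpg_ratio <- function(seq, window = 500, step = 50) {
  prof <- .seq_profile(seq)
  if (prof$n < window) {
    message("sequence shorter than one window; scored as a single window")
    st <- .window_stats(prof, 1L, prof$n)
    return(list(cpg_ratio = unname(st["cpg_ratio"]),
                gc_content = unname(st["gc_content"]), window_start = 1L))
  }
  starts <- seq.int(1L, prof$n - window + 1L, by = step)
  stats_m <- vapply(starts, function(s) .window_stats(prof, s, window), numeric(2))
  best <- which.max(stats_m["cpg_ratio", ])
  list(cpg_ratio = unname(stats_m["cpg_ratio", best]),
       gc_content = unname(stats_m["gc_content", best]),
       window_start = starts[best])
}

#' Classify a promoter by CpG density
#'
#' High-CpG promoters (HCP) have max CpG ratio > `hcp_ratio` and GC content >
#' `hcp_gc` at the maximizing window; low-CpG promoters (LCP) have ratio <
#' `lcp_ratio`; everything else is intermediate (ICP).
#'
#' @param cpg_ratio Max local CpG observed/expected ratio.
#' @param gc_content GC content of the maximizing window.
#' @param hcp_ratio,hcp_gc,lcp_ratio Class cutoffs (defaults 0.75, 0.55, 0.48).
#' @return "HCP", "ICP" or "LCP" (vectorised).
#' @export
classify_promoter <- function(cpg_ratio, gc_content,
                              hcp_ratio = 0.75, hcp_gc = 0.55, lcp_ratio = 0.48) {
  ifelse(cpg_ratio > hcp_ratio & gc_content > hcp_gc, "HCP",
         ifelse(cpg_ratio < lcp_ratio, "LCP", "ICP"))
}

#' Assign a per-gene regulation mode from expression/epigenome correlations
#'
#' A gene is histone-regulated when its expression correlates positively with
#' promoter H3K4me3 signal (`r >= r_threshold`), methylation-regulated when
#' expression correlates negatively with promoter methylation
#' (`r <= -r_threshold`), "both" when both hold, otherwise unclassified.
#' A zero-variance input leaves that arm undefined; the mode comes from the
#' remaining arm.
#'
#' @param expr,meth,k4me3 Per-timepoint vectors (>= 3 values each) of
#'   expression, promoter methylation ratio and promoter H3K4me3 signal.
#' @param r_threshold Correlation threshold (default 0.5).
#' @return A list: `mode`, `r_histone`, `r_methylation`.
#' @export
assign_regulation_mode <- function(expr, meth, k4me3, r_threshold = 0.5) {
  if (length(expr) < 3) stop("need >= 3 timepoints", call. = FALSE)
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
  }
  r_h <- safe_cor(expr, k4me3)
  r_m <- safe_cor(expr, meth)
  hist_reg <- !is.na(r_h) && r_h >= r_threshold
  meth_reg <- !is.na(r_m) && r_m <= -r_threshold
  mode <- if (hist_reg && meth_reg) "both"
  else if (hist_reg) "histone-regulated"
  else if (meth_reg) "methylation-regulated"
  else "unclassified"
  list(mode = mode, r_histone = r_h, r_methylation = r_m)
}

#' Activation kinetics of up-regulated genes by promoter CpG class
#'
#' The activation time of a gene is the first timepoint at which its
#' log-expression exceeds the midpoint of its own trajectory,
#' `(start + end) / 2`; the half-demethylation time is defined symmetrically
#' as the first timepoint at which promoter methylation falls below its
#' trajectory midpoint. Genes whose expression does not end above its start
#' are flagged and excluded from timing. Classes are compared with a
#' Kruskal-Wallis rank test on activation times.
#'
#' @param expr Gene x timepoint log-expression matrix of up-regulated genes.
#' @param classes Named character vector (HCP/ICP/LCP) over the genes.
#' @param meth Optional gene x timepoint promoter methylation matrix for the
#'   half-demethylation times.
#' @return A list: `timing` (per-gene data.frame with `activation_time`,
#'   `half_demethylation_time`, `flagged`), `class_summary` (per-class median
#'   activation time and gene counts), `rank_test` (the `kruskal.test` result,
#'   or NULL if fewer than 2 classes have timed genes).
#' @export
cpg_class_kinetics <- function(expr, classes, meth = NULL) {
  genes <- intersect(rownames(expr), names(classes))
  nt <- ncol(expr)
  first_cross <- function(x, up = TRUE) {
    mid <- (x[1] + x[nt]) / 2
    hit <- if (up) which(x > mid) else which(x < mid)
    if (length(hit)) hit[1] else NA_integer_
  }
  act <- vapply(genes, function(g) {
    x <- expr[g, ]
    if (x[nt] <= x[1]) return(NA_integer_)
    first_cross(x, up = TRUE)
  }, integer(1))
  flagged <- vapply(genes, function(g) expr[g, nt] <= expr[g, 1], logical(1))
  demeth <- rep(NA_integer_, length(genes))
  if (!is.null(meth)) {
    demeth <- vapply(genes, function(g) {
      if (!g %in% rownames(meth)) return(NA_integer_)
      x <- meth[g, ]
      if (x[nt] >= x[1]) return(NA_integer_)
      first_cross(x, up = FALSE)
    }, integer(1))
  }
  timing <- data.frame(gene = genes, cpg_class = classes[genes],
                       activation_time = act,
                       half_demethylation_time = demeth,
                       flagged = flagged, row.names = NULL,
                       stringsAsFactors = FALSE)
  ok <- timing[!timing$flagged & !is.na(timing$activation_time), ]
  class_summary <- do.call(rbind, lapply(split(ok, ok$cpg_class), function(d) {
    data.frame(cpg_class = d$cpg_class[1], n = nrow(d),
               median_activation = stats::median(d$activation_time),
               median_half_demethylation =
                 stats::median(d$half_demethylation_time, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(class_summary) <- NULL
  rank_test <- NULL
  if (length(unique(ok$cpg_class)) >= 2) {
    if (length(unique(ok$activation_time)) < 2) {
      # all timed genes tied: distributions identical by construction
      rank_test <- list(statistic = c(`Kruskal-Wallis chi-squared` = 0),
                        p.value = 1,
                        method = "Kruskal-Wallis rank sum test (degenerate: all values tied)")
    } else {
      rank_test <- stats::kruskal.test(ok$activation_time,
                                       factor(ok$cpg_class))
    }
  }
  list(timing = timing, class_summary = class_summary, rank_test = rank_test)
}
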