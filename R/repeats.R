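#' Aggregate repeat-element counts to family or class level
#'
#' Sums read counts over the members of each family or class; at
#' `level = "element"` this is the identity. Totals are conserved within every
#' partition.
#'
#' @param counts Integer element x sample matrix with element row names.
#' @param annotation data.frame with columns `element`, `family`, `class`,
#'   `length_bp`.
#' @param level One of "element", "family", "class".
#' @return Unit x sample count matrix.
#' @export
aggregate_counts <- function(counts, annotation,
                             level = c("class", "family", "element")) {
  level <- match.arg(level)
  missing <- setdiff(rownames(counts), annotation$element)
  if (length(missing)) {
    stop("unannotated elements: ", paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ..." else "", call. = FALSE)
  }
  if (level == "element") return(counts)
  key <- annotation[[level]][match(rownames(counts), annotation$element)]
  rowsum(counts, group = key)
}

#' Summed genomic coverage (kb) of repeat units
#'
#' Coverage of a family or class is the sum of its member element lengths,
#' reported in kilobases; at element level it is the element's own length.
#'
#' @inheritParams aggregate_counts
#' @return Named numeric vector of coverage in kb.
#' @export
unit_coverage_kb <- function(annotation, level = c("class", "family", "element")) {
  level <- match.arg(level)
  if (any(annotation$length_bp <= 0)) {
    stop("element lengths must be > 0", call. = FALSE)
  }
  if (level == "element") {
    return(stats::setNames(annotation$length_bp / 1000, annotation$element))
  }
  v <- tapply(annotation$length_bp, annotation[[level]], sum) / 1000
  stats::setNames(as.numeric(v), names(v))
}

#' Repeat FPKM from aggregated counts and genomic coverage
#'
#' FPKM of a repeat unit is its summed read count divided by the genomic
#' coverage of the unit in kilobases and (by default) by the per-million
#' library-size factor: `count / (coverage_kb * total_mapped_reads / 1e6)`.
#' `per_million = FALSE` gives the bare reads-per-kilobase quantity.
#'
#' @param agg_counts Unit x sample count matrix (from [aggregate_counts()]).
#' @param coverage_kb Named coverage vector (from [unit_coverage_kb()]); must
#'   cover every row and be > 0.
#' @param total_mapped_reads Per-sample library sizes (scalar or named vector
#'   over the columns), > 0.
#' @param per_million Include the per-million mapped-reads factor (default
#'   TRUE, so the unit is FPKM).
#' @return Numeric unit x sample FPKM matrix.
#' @export
repeat_fpkm <- function(agg_counts, coverage_kb, total_mapped_reads,
                        per_million = TRUE) {
  cov <- coverage_kb[rownames(agg_counts)]
  if (any(is.na(cov)) || any(cov <= 0)) {
    stop("coverage_kb must be > 0 and cover every unit", call. = FALSE)
  }
  if (any(total_mapped_reads <= 0)) stop("total_mapped_reads must be > 0", call. = FALSE)
  tot <- rep_len(total_mapped_reads, ncol(agg_counts))
  scale <- if (per_million) tot / 1e6 else rep(1, ncol(agg_counts))
  sweep(agg_counts / cov, 2, scale, "/")
}

#' Stage-specific repeats by specificity scoring
#'
#' Applies the candidate filter and the stage-specificity score to a repeat
#' FPKM matrix (element, family or class level alike).
#'
#' @param fpkm Repeat FPKM matrix.
#' @param stage Stage of interest.
#' @param score_threshold Minimum score (default 2).
#' @param min_avg Mean-expression filter (default 1e-4, the repeat filter).
#' @return data.frame: `entity`, `score`, descending.
#' @export
stage_specific_repeats <- function(fpkm, stage, score_threshold = 2,
                                   min_avg = 1e-4) {
  identify_stage_specific_genes(fpkm, stage, score_threshold = score_threshold,
                                min_avg = min_avg)
}

#' Per-class enrichment of a repeat set
#'
#' One one-sided Fisher test per repeat class: is `te_set` over-represented in
#' the class members within `universe`?
#'
#' @param te_set Character vector of element ids (subset of `universe`).
#' @param annotation Repeat annotation (element, family, class, length_bp).
#' @param universe Character vector of element ids under consideration.
#' @return data.frame: `class`, `odds_ratio`, `p_value`, `n_set_in_class`,
#'   `n_class`.
#' @export
class_enrichment <- function(te_set, annotation, universe) {
  classes <- sort(unique(annotation$class[annotation$element %in% universe]))
  res <- lapply(classes, function(cl) {
    members <- annotation$element[annotation$class == cl]
    members <- intersect(members, universe)
    et <- enrichment_test(te_set, members, universe)
    data.frame(class = cl, odds_ratio = et$odds_ratio, p_value = et$p_value,
               n_set_in_class = et$table["in_a", "in_b"],
               n_class = length(members), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
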