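#' Time-point specificity score of one expression row
#'
#' The score of an entity at a stage is its expression there divided by its
#' mean expression across all stages; a stage-specific entity must in addition
#' attain its (unique, unless `allow_ties`) maximum at that stage.
#'
#' @param x Non-negative numeric vector named by stage.
#' @param stage Stage label (or index) to score.
#' @param allow_ties If `TRUE`, a tied maximum still counts as maximal.
#' @return A list: `score` (`x[stage] / mean(x)`), `is_max_at_stage`. For an
#'   all-zero row the score is undefined and `NA` is returned in `score`.
#' @export
specificity_score <- function(x, stage, allow_ties = FALSE) {
  mu <- mean(x)
  if (mu <= 0) {
    return(list(score = NA_real_, is_max_at_stage = FALSE))
  }
  xs <- if (is.character(stage)) x[[stage]] else x[[stage]]
  mx <- max(x)
  n_max <- sum(x == mx)
  at_max <- xs == mx && (allow_ties || n_max == 1)
  list(score = xs / mu, is_max_at_stage = at_max)
}

#' Specificity scores for every row of an expression matrix
#'
#' Vectorised form of [specificity_score()]. All-zero rows are excluded with
#' a message (their score is undefined).
#'
#' @param m Expression matrix (entities x stages).
#' @param stage Stage label, a column of `m`.
#' @param allow_ties Passed through.
#' @return data.frame: `entity`, `score`, `is_max_at_stage`.
#' @export
specificity_scores <- function(m, stage, allow_ties = FALSE) {
  assert_expression_matrix(m)
  if (!stage %in% colnames(m)) stop(sprintf("stage '%s' not in matrix", stage), call. = FALSE)
  mu <- rowMeans(m)
  zero <- mu <= 0
  if (any(zero)) {
    message(sum(zero), " all-zero rows excluded (undefined score)")
    m <- m[!zero, , drop = FALSE]
    mu <- mu[!zero]
  }
  mx <- apply(m, 1, max)
  n_max <- rowSums(m == mx)
  data.frame(
    entity = rownames(m),
    score = m[, stage] / mu,
    is_max_at_stage = (m[, stage] == mx) & (allow_ties | n_max == 1),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Drop low-expression candidate rows
#'
#' Removes rows whose mean expression is strictly lower than `min_avg`
#' (the repeat-expression filter; rows at exactly `min_avg` are retained).
#'
#' @param m Expression matrix.
#' @param min_avg Minimum mean expression.
#' @return The filtered matrix; the number of removed rows is reported with a
#'   message.
#' @export
filter_candidates <- function(m, min_avg = 1e-4) {
  assert_expression_matrix(m)
  keep <- rowMeans(m) >= min_avg
  if (any(!keep)) message(sum(!keep), " rows below mean expression ", min_avg, " removed")
  m[keep, , drop = FALSE]
}

#' Identify genes peaking at a given stage
#'
#' Candidates passing the mean-expression filter whose specificity score at
#' `stage` is at least `score_threshold` and whose maximum is uniquely
#' attained there, sorted by descending score. This is the rule used to call
#' e.g. 8-cell-stage genes from an embryo reference matrix.
#'
#' @param m Expression matrix (genes x stages).
#' @param stage Stage of interest.
#' @param score_threshold Minimum specificity score (default 2).
#' @param min_avg Mean-expression filter (default 0: off for genes).
#' @param allow_ties Passed to the scorer.
#' @return data.frame: `entity`, `score`, ordered by descending score.
#' @export
identify_stage_specific_genes <- function(m, stage, score_threshold = 2,
                                          min_avg = 0, allow_ties = FALSE) {
  m <- filter_candidates(m, min_avg)
  if (nrow(m) == 0) {
    return(data.frame(entity = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  sc <- specificity_scores(m, stage, allow_ties)
  sc <- sc[sc$is_max_at_stage & sc$score >= score_threshold, c("entity", "score")]
  sc <- sc[order(-sc$score, sc$entity), ]
  rownames(sc) <- NULL
  sc
}

#' Top-N stage-specific transposable elements
#'
#' After the candidate filter and the unique-maximum requirement, the `n`
#' highest-scoring elements at `stage`; ties broken lexicographically by id.
#'
#' @param te_m TE expression matrix.
#' @param stage Stage of interest.
#' @param n Number of elements to return (default 100).
#' @param min_avg Mean-expression filter (default 1e-4).
#' @return data.frame: `entity`, `score`, `rank`. If fewer than `n` qualify,
#'   all are returned with a warning.
#' @export
top_n_specific_tes <- function(te_m, stage, n = 100, min_avg = 1e-4) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  te_m <- filter_candidates(te_m, min_avg)
  sc <- specificity_scores(te_m, stage)
  sc <- sc[sc$is_max_at_stage, c("entity", "score")]
  sc <- sc[order(-sc$score, sc$entity), ]
  if (nrow(sc) < n) {
    warning("only ", nrow(sc), " qualifying elements (requested ", n, ")")
    n <- nrow(sc)
  }
  out <- utils::head(sc, n)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' One-sided Fisher enrichment of one gene set within another
#'
#' Builds the 2x2 membership table of `set_a` and `set_b` over `universe` and
#' tests enrichment (over-representation) with a one-sided Fisher's exact
#' test; the p-value equals the hypergeometric upper tail of the overlap.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector of all entities.
#' @return A list: `odds_ratio` (conditional MLE), `p_value`, `table`.
#' @export
enrichment_test <- function(set_a, set_b, universe) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("set_a and set_b must be subsets of universe", call. = FALSE)
  }
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  tab <- matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                  sum(!in_a & in_b), sum(!in_a & !in_b)),
                2, 2, byrow = TRUE,
                dimnames = list(c("in_a", "not_a"), c("in_b", "not_b")))
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}
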