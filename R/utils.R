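# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# split n into integer counts proportional to `fractions` (largest remainder,
# so e.g. 30% of 1000 is exactly 300)
allocate_counts <- function(n, fractions) {
  stopifnot(n >= 0, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("pattern fractions must sum to 1", call. = FALSE)
  }
  raw <- n * fractions
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

assert_expression_matrix <- function(m, arg = "matrix") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (any(m < 0)) {
    stop(sprintf("`%s` contains negative values; FPKM must be >= 0", arg),
         call. = FALSE)
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    stop(sprintf("`%s` must have unique row names (entity ids)", arg),
         call. = FALSE)
  }
  if (is.null(colnames(m))) {
    stop(sprintf("`%s` must have column names (ordered sample labels)", arg),
         call. = FALSE)
  }
  invisible(m)
}

# two-sided two-sample proportion score test (uncorrected chi-square on the
# 2x2 table), vectorised; returns 1 where the pooled rate is degenerate
prop_score_p <- function(m1, n1, m2, n2) {
  p1 <- m1 / n1
  p2 <- m2 / n2
  pbar <- (m1 + m2) / (n1 + n2)
  se2 <- pbar * (1 - pbar) * (1 / n1 + 1 / n2)
  z2 <- ifelse(se2 > 0, (p1 - p2)^2 / se2, 0)
  stats::pchisq(z2, df = 1, lower.tail = FALSE)
}
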