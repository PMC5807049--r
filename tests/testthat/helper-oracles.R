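# independent brute-force oracles used to check pipeline operations

# two-line specificity score: explicit mean, explicit division
oracle_specificity <- function(row, stage) {
  mu <- sum(row) / length(row)
  row[[stage]] / mu
}

# one-sided hypergeometric enrichment p by explicit summation over the tail
oracle_hyper_p <- function(overlap, n_a, n_b, n_universe) {
  hi <- min(n_a, n_b)
  if (overlap > hi) return(0)
  sum(vapply(overlap:hi, function(i) {
    choose(n_a, i) * choose(n_universe - n_a, n_b - i) / choose(n_universe, n_b)
  }, numeric(1)))
}

# two-sided Fisher p for a 2x2 by explicit minimum-likelihood summation
oracle_fisher2_p <- function(m1, u1, m2, u2) {
  k <- m1 + m2
  n1 <- m1 + u1
  n2 <- m2 + u2
  supp <- max(0, k - n2):min(k, n1)
  pr <- vapply(supp, function(i) {
    choose(n1, i) * choose(n2, k - i) / choose(n1 + n2, k)
  }, numeric(1))
  obs <- pr[supp == m1]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# exhaustive sliding-window CpG scan using naive substring counting
oracle_cpg_max <- function(seq, window = 500, step = 50) {
  n <- nchar(seq)
  starts <- seq.int(1L, n - window + 1L, by = step)
  best <- -Inf
  best_gc <- NA_real_
  for (s in starts) {
    w <- substr(seq, s, s + window - 1L)
    ch <- strsplit(w, "")[[1]]
    n_c <- sum(ch == "C")
    n_g <- sum(ch == "G")
    n_cg <- sum(ch[-window] == "C" & ch[-1] == "G")
    r <- if (n_c == 0 || n_g == 0) 0 else n_cg * window / (n_c * n_g)
    if (r > best) {
      best <- r
      best_gc <- (n_c + n_g) / window
    }
  }
  list(cpg_ratio = best, gc_content = best_gc)
}

random_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}
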