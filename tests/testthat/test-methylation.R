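meth_table <- function(pos, meth_a, total_a, meth_b, total_b,
                       samples = c("a", "b")) {
  rbind(
    data.frame(chrom = "chr1", pos = pos, strand = "+", sample = samples[1],
               meth = meth_a, total = total_a, stringsAsFactors = FALSE),
    data.frame(chrom = "chr1", pos = pos, strand = "+", sample = samples[2],
               meth = meth_b, total = total_b, stringsAsFactors = FALSE)
  )
}

test_that("site ratios and global means follow their definitions", {
  expect_equal(site_ratio(c(3, 0, 20), c(10, 20, 20)), c(0.3, 0, 1))
  expect_true(is.na(site_ratio(0, 0)))
  expect_error(site_ratio(5, 3), "meth <= total")

  tab <- data.frame(chrom = "chr1", pos = c(1, 2), strand = "+", sample = "a",
                    meth = c(2, 8), total = c(10, 10), stringsAsFactors = FALSE)
  expect_equal(methylation_global_mean(tab, "a")$mean_ratio, 0.5)
  tab$total[2] <- 3
  expect_equal(methylation_global_mean(tab, "a", min_coverage = 5)$mean_ratio, 0.2)
  expect_error(methylation_global_mean(tab, "a", min_coverage = 50), "qualifying")
})

test_that("DMC calls combine significance with the effect-size gate", {
  tab <- meth_table(pos = c(100, 200, 300),
                    meth_a = c(20, 10, 10), total_a = c(20, 20, 20),
                    meth_b = c(0, 10, 14), total_b = c(20, 20, 20))
  dm <- call_dmcs(tab, "a", "b")
  expect_true(dm$is_dmc[dm$pos == 100])
  expect_identical(dm$direction[dm$pos == 100], "hypo")
  expect_false(dm$is_dmc[dm$pos == 200]) # identical counts
  # tiny delta with enormous coverage: significant but below min_delta
  big <- meth_table(500, 5000, 10000, 5500, 10000)
  dm2 <- call_dmcs(big, "a", "b")
  expect_lt(dm2$p_value, 0.001)
  expect_false(dm2$is_dmc)
})

test_that("the exact-test option matches the two-sided Fisher oracle", {
  set.seed(3)
  pos <- 1:40
  ma <- rbinom(40, 20, 0.5)
  mb <- rbinom(40, 20, 0.5)
  tab <- meth_table(pos, ma, 20, mb, 20)
  dm <- call_dmcs(tab, "a", "b", test = "fisher", min_delta = 0)
  oracle <- mapply(function(a, b) oracle_fisher2_p(a, 20 - a, b, 20 - b), ma, mb)
  expect_equal(dm$p_value, unname(oracle), tolerance = 1e-9)
  # extreme table: p is the two-tail hypergeometric point mass
  ext <- call_dmcs(meth_table(1, 20, 20, 0, 20), "a", "b", test = "fisher")
  expect_equal(ext$p_value, 2 / choose(40, 20), tolerance = 1e-12)
  expect_true(ext$is_dmc && ext$direction == "hypo")
})

test_that("DMC calling is antisymmetric in the sample order", {
  set.seed(4)
  tab <- meth_table(1:50, rbinom(50, 20, 0.7), 20, rbinom(50, 20, 0.3), 20)
  ab <- call_dmcs(tab, "a", "b")
  ba <- call_dmcs(tab, "b", "a")
  expect_identical(ab$is_dmc, ba$is_dmc)
  called <- ab$is_dmc
  expect_true(all(ab$direction[called] != ba$direction[called]))
  expect_equal(ab$delta, -ba$delta)
})

test_that("DMR merging respects gap, support and direction purity", {
  dmcs <- data.frame(
    chrom = "chr1", pos = c(100, 150, 220), strand = "+",
    delta = c(-0.5, -0.4, -0.6), p_value = 1e-6, is_dmc = TRUE,
    direction = "hypo", stringsAsFactors = FALSE
  )
  r <- call_dmrs(dmcs, max_gap = 200, min_dmcs = 3)
  expect_identical(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(100, 221))
  expect_equal(r$mean_delta, -0.5)
  expect_identical(nrow(call_dmrs(dmcs[1:2, ], min_dmcs = 3)), 0L)

  # interleaved directions build separate same-direction regions
  inter <- data.frame(
    chrom = "chr1", pos = c(10, 20, 30, 15, 25, 35), strand = "+",
    delta = c(-0.4, -0.4, -0.4, 0.4, 0.4, 0.4), p_value = 1e-6, is_dmc = TRUE,
    direction = rep(c("hypo", "hyper"), each = 3), stringsAsFactors = FALSE
  )
  r2 <- call_dmrs(inter, max_gap = 50, min_dmcs = 3)
  expect_identical(nrow(r2), 2L)
  expect_setequal(r2$direction, c("hypo", "hyper"))
})

test_that("DMR regions are disjoint per direction with enough support", {
  sim <- suppressWarnings(simulate_methylome(
    2000, paste0("t", 1:2), trend = c(0.85, 0.85),
    dmr_spec = data.frame(chrom = "chr1", start = c(0, 50000),
                          end = c(3000, 53000), direction = "hypo",
                          delta = 0.5),
    dmr_samples = "t2", coverage = 30, seed = 6
  ))
  dm <- call_dmcs(sim$table, "t1", "t2")
  regs <- call_dmrs(dm)
  expect_true(all(regs$n_dmcs >= 3))
  for (dir in unique(regs$direction)) {
    r <- regs[regs$direction == dir, ]
    r <- r[order(r$start), ]
    if (nrow(r) > 1) expect_true(all(r$start[-1] >= r$end[-nrow(r)]))
  }
})

test_that("naive-specific DMRs require same-direction reciprocal overlap", {
  mk <- function(start, end, dir) {
    data.frame(chrom = "chr1", start = start, end = end, direction = dir,
               mean_delta = ifelse(dir == "hypo", -0.4, 0.4), n_dmcs = 5L,
               comparison = NA_character_, stringsAsFactors = FALSE)
  }
  a <- rbind(mk(0, 100, "hypo"), mk(1000, 1100, "hypo"), mk(5000, 5100, "hyper"))
  b <- rbind(mk(0, 100, "hypo"), mk(40, 140, "hypo"), mk(5000, 5100, "hypo"))
  res <- naive_specific_dmrs(a, b)
  expect_identical(res$start, 0)          # identical region retained
  # 60% overlap retained at threshold 0.5
  res2 <- naive_specific_dmrs(mk(0, 100, "hypo"), mk(40, 140, "hypo"))
  expect_identical(nrow(res2), 1L)
  # opposite direction never matches, nor a region unique to one list
  expect_identical(nrow(naive_specific_dmrs(mk(5000, 5100, "hyper"),
                                            mk(5000, 5100, "hypo"))), 0L)
})

test_that("region methylation averages covered sites and flags empty regions", {
  tab <- data.frame(chrom = "chr1", pos = c(10, 20, 500), strand = "+",
                    sample = "a", meth = c(4, 6, 9), total = 10,
                    stringsAsFactors = FALSE)
  regs <- data.frame(chrom = "chr1", start = c(0, 100), end = c(50, 200))
  rm <- region_methylation(tab, regs, "a")
  expect_equal(rm$mean_ratio[1], 0.5)
  expect_true(is.na(rm$mean_ratio[2]))
  expect_identical(rm$n_sites, c(2L, 0L))
})

test_that("methylation-expression correlation handles perfect and degenerate cases", {
  meth <- rbind(g1 = c(0.9, 0.5, 0.1), g2 = c(0.5, 0.5, 0.5), g3 = c(0.2, NA, NA))
  expr <- rbind(g1 = c(1, 5, 9), g2 = c(1, 5, 9), g3 = c(1, 5, 9))
  colnames(meth) <- colnames(expr) <- paste0("t", 1:3)
  r <- methylation_expression_correlation(meth, expr)
  expect_equal(r$r[r$gene == "g1"], -1)
  expect_identical(r$flag[r$gene == "g2"], "undefined")
  expect_identical(r$flag[r$gene == "g3"], "skipped")
})

test_that("independent methylation and expression give near-zero mean correlation", {
  set.seed(12)
  n <- 300
  meth <- matrix(runif(n * 8), n, 8, dimnames = list(sprintf("g%03d", 1:n), paste0("t", 1:8)))
  expr <- matrix(rexp(n * 8), n, 8, dimnames = dimnames(meth))
  r <- methylation_expression_correlation(meth, expr)
  expect_lt(abs(mean(r$r, na.rm = TRUE)), 0.05)
})
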