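make_mat <- function(values, genes, samples) {
  matrix(values, length(genes), length(samples), byrow = TRUE,
         dimnames = list(genes, samples))
}

test_that("log transform is the pseudo-counted log2 and rejects negatives", {
  m <- make_mat(c(0, 1, 7, 3), c("g1", "g2"), c("a", "b"))
  lt <- log_transform(m)
  expect_equal(unname(lt["g1", ]), c(0, 1))
  expect_equal(unname(lt["g2", "a"]), 3) # log2(8)
  m[1, 1] <- -1
  expect_error(log_transform(m), "negative")
})

test_that("DE calls follow the pseudo-counted fold-change rule with direction", {
  m <- make_mat(c(1, 2, 5, 5, 9, 4), c("g1", "g2", "g3"), c("a", "b"))
  de <- call_de_genes(m, "a", "b")
  expect_setequal(de$gene, c("g1", "g3"))
  expect_identical(de$direction[de$gene == "g1"], "up")   # log2(3/2) = 0.585 > 0.58
  expect_identical(de$direction[de$gene == "g3"], "down") # log2(5/10) = -1
  expect_error(call_de_genes(m, "a", "zz"), "unknown sample")
})

test_that("DE direction is antisymmetric in the sample order", {
  set.seed(42)
  m <- matrix(rexp(200, 0.2), 50, 4,
              dimnames = list(sprintf("g%02d", 1:50), paste0("t", 1:4)))
  for (j in 1:3) {
    fwd <- call_de_genes(m, paste0("t", j), paste0("t", j + 1))
    rev <- call_de_genes(m, paste0("t", j + 1), paste0("t", j))
    expect_setequal(fwd$gene, rev$gene)
    o <- match(fwd$gene, rev$gene)
    expect_true(all(fwd$direction != rev$direction[o]))
    expect_equal(fwd$log2fc, -rev$log2fc[o])
  }
})

test_that("combined DE set is a union with per-comparison records", {
  m <- make_mat(c(1, 1, 8, 1,
                  2, 2, 2, 2,
                  1, 8, 8, 1), c("g1", "g2", "g3"), paste0("t", 1:4))
  cds <- combined_de_set(m)
  expect_setequal(cds$genes, c("g1", "g3"))
  expect_false("g2" %in% cds$genes)
  expect_true(cds$hits["g1", "t2->t3"])
  expect_identical(sum(cds$genes == "g3"), 1L) # set semantics
})

test_that("correlation-distance k-means recovers exact groups and scale-invariance", {
  base1 <- c(1, 2, 3, 4, 5)
  base2 <- c(5, 4, 3, 2, 1)
  m <- rbind(
    matrix(rep(base1, 5), 5, 5, byrow = TRUE),
    matrix(rep(base2, 5), 5, 5, byrow = TRUE),
    2 * base1 # scaled copy correlates perfectly with group 1
  )
  rownames(m) <- sprintf("g%02d", 1:11)
  colnames(m) <- paste0("t", 1:5)
  cl <- cluster_dynamics(m, k = 2, seed = 1)
  a <- cl$assignment
  expect_identical(length(unique(a[1:5])), 1L)
  expect_identical(length(unique(a[6:10])), 1L)
  expect_false(a[1] == a[6])
  expect_identical(unname(a["g11"]), unname(a["g01"]))
})

test_that("clustering is deterministic under a fixed seed and drops flat rows", {
  set.seed(8)
  m <- matrix(rexp(300), 60, 5,
              dimnames = list(sprintf("g%02d", 1:60), paste0("t", 1:5)))
  m <- rbind(m, flat = rep(2, 5))
  expect_message(c1 <- cluster_dynamics(m, k = 4, seed = 99), "zero-variance")
  suppressMessages(c2 <- cluster_dynamics(m, k = 4, seed = 99))
  expect_identical(c1$assignment, c2$assignment)
  expect_identical(c1$dropped, "flat")
  expect_error(cluster_dynamics(m, k = 1), "k must be")
})

test_that("centroid patterns are categorized with peak annotation", {
  cent <- rbind(c(5, 4, 3, 2, 1), c(1, 2, 3, 4, 5), c(1, 1, 6, 1, 1))
  colnames(cent) <- paste0("t", 1:5)
  cats <- categorize_patterns(cent)
  expect_identical(cats$category,
                   c("down-regulated", "up-regulated", "transiently up-regulated"))
  expect_identical(cats$peak_timepoint[3], "t3")
})

test_that("sample correlation is symmetric, unit-diagonal and flags zero variance", {
  m <- cbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1))
  r <- sample_correlation(m)
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(r, t(r))
  m2 <- cbind(m, flat = c(1, 1, 1))
  expect_warning(r2 <- sample_correlation(m2), "zero-variance")
  expect_true(all(is.na(r2["flat", c("a", "b", "c")])))
})

test_that("correlation matrices are positive semi-definite", {
  set.seed(5)
  for (i in 1:5) {
    m <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, paste0("s", 1:4)))
    ev <- eigen(sample_correlation(m), symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-10))
  }
})

test_that("classical MDS reproduces simple geometries", {
  # three equidistant samples -> equilateral triangle
  d3 <- matrix(1, 3, 3) - diag(3)
  xy <- mds_embedding(d3)
  pd <- as.matrix(dist(xy))
  off <- pd[upper.tri(pd)]
  expect_lt(max(off) - min(off), 1e-9)

  # four collinear points recover spacing up to sign on axis 1
  pts <- c(0, 1, 2, 3)
  d4 <- abs(outer(pts, pts, "-"))
  emb <- mds_embedding(d4, dims = 1)
  got <- emb[, 1] - mean(emb[, 1])
  expect_true(max(abs(got - (pts - mean(pts)))) < 1e-9 ||
              max(abs(got + (pts - mean(pts)))) < 1e-9)

  # duplicated sample -> coincident points
  d5 <- as.matrix(dist(c(0, 0, 5, 9)))
  emb5 <- mds_embedding(d5)
  expect_lt(sqrt(sum((emb5[1, ] - emb5[2, ])^2)), 1e-6)

  ns <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(mds_embedding(ns), "symmetric")
})
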