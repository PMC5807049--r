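flat_track <- function(counts, mark = "H3K4me3", tp = "t1", bin_size = 200) {
  mark_track(counts, bin_size = bin_size, mark = mark, timepoint = tp)
}

test_that("normalization scales to one million reads and is depth-invariant", {
  tr <- mark_track(c(5, 0, 10), mark = "H3K4me3", timepoint = "t1",
                   total_reads = 5e6)
  nt <- normalize_track(tr)
  expect_equal(nt$signal, c(1, 0, 2))
  dbl <- mark_track(c(10, 0, 20), mark = "H3K4me3", timepoint = "t1",
                    total_reads = 1e7)
  expect_equal(normalize_track(dbl)$signal, nt$signal)
  zero <- mark_track(rep(0, 3), mark = "m", timepoint = "t",
                     total_reads = 1e6)
  expect_equal(normalize_track(zero)$signal, c(0, 0, 0))
  expect_error(normalize_track(mark_track(rep(0, 3), mark = "m", timepoint = "t")),
               "> 0")
})

test_that("binarization flags only bins far above the genome-wide rate", {
  counts <- c(rep(1, 999), 20)
  b <- binarize_track(flat_track(counts))
  expect_false(any(b$binary[1:999]))
  expect_true(b$binary[1000]) # Poisson(~1) upper tail of 20 is << 1e-4
  u <- binarize_track(flat_track(rep(7, 500)))
  expect_false(any(u$binary)) # uniform track: no bin beats its own mean
})

make_binary_track <- function(binary, mark, bin_size = 200) {
  tr <- mark_track(rep(0, length(binary)), bin_size = bin_size, mark = mark,
                   timepoint = "t1", total_reads = 1)
  tr$binary <- binary
  tr
}

test_that("promoter classification applies the four-state and discard rules", {
  nb <- 100 # grid of 100 bins x 200 bp
  a <- rep(FALSE, nb)
  b <- rep(FALSE, nb)
  a[11:30] <- TRUE          # A-only segment [2000, 6000)
  a[41:60] <- TRUE; b[41:60] <- TRUE # both segment [8000, 12000)
  ta <- make_binary_track(a, "H3K4me3")
  tb <- make_binary_track(b, "H3K27me3")
  gm <- data.frame(
    gene = c("bivalent", "aonly", "silent", "straddler", "offgrid"),
    chrom = "chr1",
    tss = c(10000, 4000, 15000, 6000, 100),
    strand = "+", stringsAsFactors = FALSE
  )
  st <- classify_promoters(ta, tb, gm)
  expect_identical(st$state[st$gene == "bivalent"], "both")
  expect_identical(st$state[st$gene == "aonly"], "H3K4me3-only")
  expect_identical(st$state[st$gene == "silent"], "none")
  expect_identical(st$state[st$gene == "straddler"], "discarded")
  expect_identical(st$reason[st$gene == "straddler"], "multiple_states")
  expect_identical(st$reason[st$gene == "offgrid"], "off_grid")
  # no marks anywhere: every on-grid gene is "none"
  st0 <- classify_promoters(make_binary_track(rep(FALSE, nb), "H3K4me3"),
                            make_binary_track(rep(FALSE, nb), "H3K27me3"),
                            gm[gm$gene != "offgrid", ])
  expect_true(all(st0$state == "none"))
})

test_that("classification is invariant to whole-bin grid translation", {
  set.seed(31)
  nb <- 300
  a <- runif(nb) < 0.1
  b <- runif(nb) < 0.1
  gm <- data.frame(gene = paste0("g", 1:5), chrom = "chr1",
                   tss = c(10000, 20000, 30000, 40000, 50000),
                   strand = "+", stringsAsFactors = FALSE)
  st <- classify_promoters(make_binary_track(a, "A"), make_binary_track(b, "B"), gm)
  shift_bins <- 7L
  gm2 <- transform(gm, tss = tss + shift_bins * 200L)
  st2 <- classify_promoters(make_binary_track(c(rep(FALSE, shift_bins), a), "A"),
                            make_binary_track(c(rep(FALSE, shift_bins), b), "B"),
                            gm2)
  expect_identical(st$state, st2$state)
})

test_that("state transitions count gene flows and conserve the universe", {
  states <- cbind(
    t1 = c("both", "both", "none", "H3K4me3-only"),
    t2 = c("H3K4me3-only", "both", "none", "H3K4me3-only"),
    t3 = c("H3K4me3-only", "both", "discarded", "H3K4me3-only")
  )
  rownames(states) <- paste0("g", 1:4)
  tr <- state_transitions(states)
  expect_identical(length(tr), 2L)
  m1 <- tr[["t1->t2"]]
  expect_identical(sum(m1), 4L)
  expect_identical(unname(m1["both", "H3K4me3-only"]), 1L)
  expect_identical(unname(m1["both", "both"]), 1L)
  # static genes sit on the diagonal
  m2 <- tr[["t2->t3"]]
  expect_identical(unname(m2["H3K4me3-only", "H3K4me3-only"]), 2L)
  expect_identical(unname(m2["none", "discarded"]), 1L)
  expect_identical(sum(m2), 4L)
})

test_that("mismatched gene sets across timepoints are rejected", {
  s1 <- data.frame(gene = c("a", "b"), state = "none", reason = NA)
  s2 <- data.frame(gene = c("a", "c"), state = "none", reason = NA)
  expect_error(state_transitions(list(s1, s2)), "mismatched")
})

test_that("TSS profiles are strand-aware averages", {
  nb <- 200
  counts <- rep(0, nb)
  counts[100:104] <- c(10, 20, 30, 0, 0) # asymmetric peak right of bin 100
  tr <- normalize_track(mark_track(counts, mark = "m", timepoint = "t",
                                   total_reads = 1e6))
  gm_plus <- data.frame(gene = "gp", chrom = "chr1", tss = 99 * 200, strand = "+")
  gm_minus <- data.frame(gene = "gm", chrom = "chr1", tss = 99 * 200, strand = "-")
  pp <- tss_profile(tr, gm_plus, window = 1000)
  pm <- tss_profile(tr, gm_minus, window = 1000)
  expect_equal(pm$signal, rev(pp$signal)) # strand flip mirrors the profile
  expect_false(isTRUE(all.equal(pp$signal, rev(pp$signal)))) # peak is asymmetric

  # uniform track gives a flat profile at the uniform value
  tru <- normalize_track(mark_track(rep(3, nb), mark = "m", timepoint = "t",
                                    total_reads = 1e6))
  pu <- tss_profile(tru, gm_plus, window = 1000)
  expect_true(all(pu$signal == pu$signal[1]))

  # two genes with identical planted context equal the single-gene profile
  gm2 <- data.frame(gene = c("g1", "g2"), chrom = "chr1",
                    tss = c(99, 99) * 200, strand = "+")
  p2 <- tss_profile(tr, gm2, window = 1000)
  expect_equal(p2$signal, pp$signal)
  expect_identical(attr(p2, "n_genes"), 2L)
  expect_error(tss_profile(tr, gm_plus[0, ]), "empty gene set")
})

test_that("planted promoter states round-trip through the classifier", {
  states4 <- c("H3K4me3-only", "H3K27me3-only", "both", "none")
  plan <- matrix(rep(states4, each = 10), 40, 2,
                 dimnames = list(sprintf("gene_%04d", 1:40), c("t1", "t2")))
  sim <- simulate_chromatin_tracks(40, c("t1", "t2"), state_assignments = plan,
                                   depth = 30, background = 1, seed = 13)
  cls <- lapply(c("t1", "t2"), function(tp) {
    classify_promoters(binarize_track(sim$tracks[[paste0("H3K4me3|", tp)]]),
                       binarize_track(sim$tracks[[paste0("H3K27me3|", tp)]]),
                       sim$gene_model)
  })
  for (j in 1:2) {
    agree <- mean(cls[[j]]$state == sim$truth$states[, j])
    expect_gte(agree, 0.95)
  }
})
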