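#' Log-transform an FPKM matrix
#'
#' Elementwise `log2(FPKM + 1)`, the pseudo-counted transform used throughout
#' downstream dynamics analysis.
#'
#' @param m Non-negative numeric matrix (genes x samples) with unique row
#'   names and ordered column names.
#' @return Matrix of the same shape, `log2(m + 1)`.
#' @export
log_transform <- function(m) {
  assert_expression_matrix(m)
  log2(m + 1)
}

#' Call differentially expressed genes between two adjacent timepoints
#'
#' A gene is differentially expressed when the pseudo-counted log2 fold change
#' `log2((FPKM_b + 1) / (FPKM_a + 1))` exceeds the threshold in absolute value
#' (default 0.58, i.e. fold change > 1.5).
#'
#' @param m FPKM matrix.
#' @param t_a,t_b Sample labels of the comparison (must be columns of `m`).
#' @param log2fc_threshold Strict threshold on |log2FC|.
#' @return data.frame with one row per DE gene: `gene`, `log2fc`, `direction`
#'   ("up" when expression rises from `t_a` to `t_b`, else "down").
#' @export
call_de_genes <- function(m, t_a, t_b, log2fc_threshold = 0.58) {
  assert_expression_matrix(m)
  for (s in c(t_a, t_b)) {
    if (!s %in% colnames(m)) stop(sprintf("unknown sample label '%s'", s), call. = FALSE)
  }
  lfc <- log2((m[, t_b] + 1) / (m[, t_a] + 1))
  de <- abs(lfc) > log2fc_threshold
  data.frame(
    gene = rownames(m)[de],
    log2fc = unname(lfc[de]),
    direction = ifelse(lfc[de] > 0, "up", "down"),
    stringsAsFactors = FALSE
  )
}

#' Union of DE genes over all adjacent timepoint pairs
#'
#' Runs [call_de_genes()] on every pair of neighbouring samples in the stored
#' column order and returns the combined gene set with a record of which
#' comparisons fired.
#'
#' @inheritParams call_de_genes
#' @return A list: `genes` (character vector, each DE gene once), `hits`
#'   (logical gene x comparison matrix), `comparisons` (labels "a->b").
#' @export
combined_de_set <- function(m, log2fc_threshold = 0.58) {
  assert_expression_matrix(m)
  if (ncol(m) < 2) stop("need at least 2 samples", call. = FALSE)
  pairs <- cbind(colnames(m)[-ncol(m)], colnames(m)[-1])
  labels <- paste(pairs[, 1], pairs[, 2], sep = "->")
  hits <- matrix(FALSE, nrow(m), nrow(pairs),
                 dimnames = list(rownames(m), labels))
  for (j in seq_len(nrow(pairs))) {
    de <- call_de_genes(m, pairs[j, 1], pairs[j, 2], log2fc_threshold)
    hits[de$gene, j] <- TRUE
  }
  keep <- rowSums(hits) > 0
  list(genes = rownames(m)[keep], hits = hits[keep, , drop = FALSE],
       comparisons = labels)
}

#' Cluster dynamic genes by correlation-distance k-means
#'
#' Genes are clustered on their log-expression trajectories with distance
#' `1 - Pearson(row_i, row_j)`, realised by standardising each row to zero
#' mean and unit norm before Euclidean k-means (`stats::kmeans`,
#' Hartigan-Wong, 50 restarts). Zero-variance rows cannot be placed in
#' correlation space and are excluded with a message.
#'
#' @param logm Log-scale expression matrix restricted to the dynamic (DE)
#'   gene set.
#' @param k Number of clusters (default 14).
#' @param seed Integer RNG seed; fixed seed gives identical assignments.
#' @param nstart Number of k-means restarts.
#' @param margin Log2 margin passed to [categorize_patterns()].
#' @return An object of class `dynamic_clusters`: list with `k`, `assignment`
#'   (named integer vector), `centroids` (cluster x timepoint means of
#'   `logm`), `category` (per-cluster pattern labels with peak annotation),
#'   `dropped` (zero-variance genes), `withinss`.
#' @export
cluster_dynamics <- function(logm, k = 14, seed = 1L, nstart = 50, margin = 0.5) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (!is.matrix(logm) || !is.numeric(logm)) stop("logm must be a numeric matrix", call. = FALSE)
  v <- apply(logm, 1, stats::var)
  dropped <- rownames(logm)[v == 0 | is.na(v)]
  if (length(dropped)) {
    message(length(dropped), " zero-variance genes excluded from clustering")
    logm <- logm[!(rownames(logm) %in% dropped), , drop = FALSE]
  }
  if (nrow(logm) < k) stop("fewer genes than clusters", call. = FALSE)

  z <- logm - rowMeans(logm)
  z <- z / sqrt(rowSums(z^2)) # unit norm => squared Euclidean = 2(1 - Pearson)
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = nstart, iter.max = 100)

  centroids <- t(vapply(seq_len(k), function(cl) {
    colMeans(logm[km$cluster == cl, , drop = FALSE])
  }, numeric(ncol(logm))))
  rownames(centroids) <- paste0("cluster_", seq_len(k))
  category <- categorize_patterns(centroids, margin = margin)

  structure(
    list(k = k, assignment = stats::setNames(km$cluster, rownames(logm)),
         centroids = centroids, category = category, dropped = dropped,
         withinss = km$tot.withinss),
    class = "dynamic_clusters"
  )
}

#' @export
print.dynamic_clusters <- function(x, ...) {
  cat("Dynamic expression clusters (correlation-distance k-means)\n")
  cat("  k =", x$k, "| genes clustered:", length(x$assignment),
      "| zero-variance dropped:", length(x$dropped), "\n")
  tab <- table(factor(x$category$category,
                      c("down-regulated", "up-regulated",
                        "transiently up-regulated", "other")))
  cat("  cluster categories:",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Plot cluster centroid trajectories
#'
#' @param x A `dynamic_clusters` object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.dynamic_clusters <- function(x, ...) {
  graphics::matplot(t(x$centroids), type = "l", lty = 1,
                    xlab = "timepoint", ylab = "mean log2(FPKM + 1)",
                    xaxt = "n", ...)
  graphics::axis(1, at = seq_len(ncol(x$centroids)),
                 labels = colnames(x$centroids), las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Categorize cluster centroid patterns
#'
#' Labels each centroid trajectory as down-regulated, up-regulated,
#' transiently up-regulated (with the peak timepoint) or other. A trajectory
#' is transient when an interior maximum exceeds both endpoints by `margin`;
#' up/down when the end-to-start difference exceeds `margin` with the maximum
#' at the corresponding endpoint.
#'
#' @param centroids Cluster x timepoint matrix of mean log-expression.
#' @param margin Log2-scale margin separating the categories.
#' @return data.frame: `cluster`, `category`, `peak_timepoint` (NA unless
#'   transient).
#' @export
categorize_patterns <- function(centroids, margin = 0.5) {
  nt <- ncol(centroids)
  res <- lapply(seq_len(nrow(centroids)), function(i) {
    y <- centroids[i, ]
    amax <- which.max(y)
    cat_lab <- "other"
    peak <- NA_character_
    if (amax > 1 && amax < nt &&
        y[amax] - y[1] > margin && y[amax] - y[nt] > margin) {
      cat_lab <- "transiently up-regulated"
      peak <- colnames(centroids)[amax] %||% as.character(amax)
    } else if (y[nt] - y[1] > margin && amax == nt) {
      cat_lab <- "up-regulated"
    } else if (y[1] - y[nt] > margin && amax == 1) {
      cat_lab <- "down-regulated"
    }
    data.frame(cluster = rownames(centroids)[i] %||% as.character(i),
               category = cat_lab, peak_timepoint = peak,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Sample-by-sample Pearson correlation matrix
#'
#' @param m Expression matrix (entities x samples) on whatever scale the
#'   comparison should use (typically log2(FPKM + 1)).
#' @return Symmetric samples x samples Pearson matrix with unit diagonal;
#'   entries involving a zero-variance sample are `NA` (with a warning), never
#'   silently zero.
#' @export
sample_correlation <- function(m) {
  if (!is.matrix(m) || nrow(m) < 2) stop("need >= 2 common entities", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  r <- suppressWarnings(stats::cor(m))
  if (any(sds == 0)) {
    warning("zero-variance sample(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "),
            "; correlations set to NA")
    r[sds == 0, ] <- NA
    r[, sds == 0] <- NA
  }
  diag(r) <- 1
  r
}

#' Classical multidimensional scaling of a sample distance structure
#'
#' Torgerson's classical scaling (`stats::cmdscale`) on a distance matrix, or
#' on a correlation matrix converted via `d = 1 - r`.
#'
#' @param x Square symmetric matrix: distances, or correlations if
#'   `input = "correlation"`.
#' @param dims Number of output dimensions.
#' @param input Either "distance" or "correlation".
#' @return Samples x `dims` coordinate matrix, centred; orientation is
#'   arbitrary up to sign/rotation as usual for MDS.
#' @export
mds_embedding <- function(x, dims = 2, input = c("distance", "correlation")) {
  input <- match.arg(input)
  if (!is.matrix(x) || nrow(x) != ncol(x) ||
      max(abs(x - t(x))) > 1e-8) {
    stop("input must be a square symmetric matrix", call. = FALSE)
  }
  d <- if (input == "correlation") 1 - x else x
  stats::cmdscale(stats::as.dist(d), k = dims)
}
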