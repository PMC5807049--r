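# readers/writers for the plain-text interchange formats used by the pipeline

#' Read a tab-delimited expression matrix
#'
#' First column: entity id; remaining columns: one per ordered sample.
#'
#' @param path File path.
#' @return Numeric matrix with entity row names and sample column names.
#' @export
read_expression_matrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  assert_expression_matrix(m)
}

#' Write a tab-delimited expression matrix
#'
#' @param m Expression matrix.
#' @param path Output path.
#' @param id_column Name of the id column (default "gene").
#' @export
write_expression_matrix <- function(m, path, id_column = "gene") {
  d <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(d)[1] <- id_column
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene model as BED6
#'
#' One 0-based half-open interval per gene promoter (TSS +/- `flank`), strand
#' aware.
#'
#' @param gene_model data.frame: `gene`, `chrom`, `tss`, `strand`.
#' @param path Output path.
#' @param flank Promoter half-width (bp).
#' @export
write_gene_model_bed <- function(gene_model, path, flank = 2000) {
  bed <- data.frame(
    chrom = gene_model$chrom,
    start = pmax(0, gene_model$tss - flank),
    end = gene_model$tss + flank,
    name = gene_model$gene,
    score = 0,
    strand = gene_model$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of regions
#'
#' @param path BED3+ file (0-based half-open).
#' @return data.frame: `chrom`, `start`, `end`, and `name` when present.
#' @export
read_bed <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(d)[1:3] <- c("chrom", "start", "end")
  if (ncol(d) >= 4) names(d)[4] <- "name"
  d
}

#' Write / read a bedGraph-like methylation table
#'
#' Columns: chrom, pos (0-based), strand, sample, meth, total.
#'
#' @param table Methylation table data.frame.
#' @param path File path.
#' @export
write_methylation_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_methylation_table
#' @export
read_methylation_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a RepeatMasker-style annotation table
#'
#' Tab-delimited with columns element, family, class, length_bp.
#'
#' @param path File path.
#' @return Annotation data.frame.
#' @export
read_repeat_annotation <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("element", "family", "class", "length_bp")
  if (!all(need %in% names(d))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  d
}

#' Write / read promoter sequences as FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path FASTA path.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a simulation truth bundle as JSON
#'
#' @param truth Truth list from a simulator.
#' @param path Output path.
#' @export
write_truth_bundle <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
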