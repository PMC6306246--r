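#' Two-layer expression matrix
#'
#' Container for gene x sample counts quantified separately from exonic and
#' intronic reads. Intronic reads are assumed to derive from unspliced
#' (nuclear) transcripts, so keeping the layers separate is what allows the
#' nuclear-fraction estimators and intron-aware clustering downstream.
#'
#' @param exonic gene x sample matrix of non-negative integer exonic read
#'   counts. Row and column names are used as gene and sample identifiers.
#' @param intronic matching matrix of intronic read counts; defaults to all
#'   zeros (e.g. exon-only quantification).
#' @param genes,samples identifier vectors; default to the dimnames of
#'   `exonic`.
#' @param gene_length optional named numeric vector of annotated transcript
#'   lengths in bases (exonic models), used only for FPKM.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `genes`, `samples`, `exonic`, `intronic` and optionally `gene_length`.
#' @export
expression_matrix <- function(exonic, intronic = NULL, genes = rownames(exonic),
                              samples = colnames(exonic), gene_length = NULL) {
  exonic <- as.matrix(exonic)
  if (is.null(intronic)) {
    intronic <- matrix(0, nrow(exonic), ncol(exonic))
  }
  intronic <- as.matrix(intronic)
  if (!all(dim(exonic) == dim(intronic))) {
    stop("exonic and intronic layers must share dimensions")
  }
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(exonic)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(exonic)))
  if (length(genes) != nrow(exonic) || length(samples) != ncol(exonic)) {
    stop("annotation length does not match matrix dimensions")
  }
  if (anyDuplicated(genes) || anyDuplicated(samples)) {
    stop("duplicate gene or sample identifiers")
  }
  if (min(exonic) < 0 || min(intronic) < 0) {
    stop("negative counts are not allowed")
  }
  dimnames(exonic) <- dimnames(intronic) <- list(genes, samples)
  obj <- list(genes = as.character(genes), samples = as.character(samples),
              exonic = exonic, intronic = intronic)
  if (!is.null(gene_length)) {
    obj$gene_length <- stats::setNames(as.numeric(gene_length), genes)
  }
  class(obj) <- "ExpressionMatrix"
  obj
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (exonic + intronic layers)\n",
              length(x$genes), length(x$samples)))
  cat(sprintf("  total exonic reads: %.3g; total intronic reads: %.3g\n",
              sum(x$exonic), sum(x$intronic)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) c(length(x$genes), length(x$samples))

#' Subset an ExpressionMatrix
#'
#' @param x an [expression_matrix()].
#' @param i,j gene and sample indices (numeric, logical or names).
#' @param ... ignored.
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$genes)
  if (missing(j)) j <- seq_along(x$samples)
  expression_matrix(x$exonic[i, j, drop = FALSE], x$intronic[i, j, drop = FALSE],
                    gene_length = if (!is.null(x$gene_length)) x$gene_length[i])
}

layer_counts <- function(x, reads = c("both", "exonic", "intronic")) {
  reads <- match.arg(reads)
  switch(reads,
         both = x$exonic + x$intronic,
         exonic = x$exonic,
         intronic = x$intronic)
}

#' Counts-per-million normalization
#'
#' Normalizes the selected read layer(s) so every sample sums to one million.
#' With `reads = "both"` the exonic and intronic layers are summed before
#' normalization, the convention used for all expression values in this
#' pipeline; `reads = "exonic"` ignores the intronic layer entirely.
#' Samples with zero total in the selected layer(s) are flagged with a
#' warning and their CPM defined as 0.
#'
#' @param x an [expression_matrix()].
#' @param reads which read layer(s) to use: `"both"` (default), `"exonic"`,
#'   or `"intronic"`.
#' @return gene x sample numeric matrix of CPM values.
#' @export
compute_cpm <- function(x, reads = c("both", "exonic", "intronic")) {
  counts <- layer_counts(x, reads)
  totals <- colSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    warning(sprintf("%d sample(s) with zero total counts; CPM set to 0", sum(zero)))
    totals[zero] <- 1
  }
  sweep(counts, 2, totals, "/") * 1e6
}

#' log2(CPM + 1) expression
#'
#' @inheritParams compute_cpm
#' @return gene x sample matrix of log2(CPM + 1) values.
#' @export
log_cpm <- function(x, reads = c("both", "exonic", "intronic")) {
  log2(compute_cpm(x, reads) + 1)
}

# Exonic counts per million of the TOTAL (exonic + intronic) library. This is
# the "expression (CPM) using only exonic reads" view used by the
# nuclear-fraction estimators: the numerator is restricted to exonic reads but
# the sequencing depth is the whole library, so per-transcript exonic yield is
# comparable between compartments.
cpm_exonic_of_total <- function(x) {
  totals <- colSums(x$exonic + x$intronic)
  totals[totals == 0] <- 1
  sweep(x$exonic, 2, totals, "/") * 1e6
}

#' FPKM from exonic reads
#'
#' Fragments per kilobase per million computed from exonic reads only, using
#' annotated transcript lengths. Intron retention varies across genes, so no
#' intron-inclusive effective length is attempted.
#'
#' @param x an [expression_matrix()] with `gene_length` present.
#' @return gene x sample matrix of FPKM values.
#' @export
compute_fpkm <- function(x) {
  if (is.null(x$gene_length)) {
    stop("gene lengths are required for FPKM; supply gene_length")
  }
  cpm <- compute_cpm(x, reads = "exonic")
  sweep(cpm, 1, x$gene_length / 1e3, "/")
}

#' Per-sample gene detection
#'
#' Number of genes detected (CPM > 0) in each sample under the chosen read
#' layer(s).
#'
#' @inheritParams compute_cpm
#' @return named integer vector, one entry per sample.
#' @export
gene_detection <- function(x, reads = c("both", "exonic", "intronic")) {
  cpm <- suppressWarnings(compute_cpm(x, reads))
  colSums(cpm > 0)
}

#' Write a two-layer expression matrix to disk
#'
#' Writes `matrix_exonic.mtx`, `matrix_intronic.mtx` (MatrixMarket),
#' `genes.tsv` and `samples.tsv` into `dir`, or dense CSV files
#' (`exonic.csv`, `intronic.csv`) with `format = "csv"`. Gene rows x sample
#' columns in all files.
#'
#' @param x an [expression_matrix()].
#' @param dir output directory (created if needed).
#' @param format `"mtx"` (default) or `"csv"`.
#' @return `dir`, invisibly.
#' @export
write_expression <- function(x, dir, format = c("mtx", "csv")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- data.frame(gene_id = x$genes)
  if (!is.null(x$gene_length)) genes$length <- x$gene_length
  utils::write.table(genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = x$samples),
                     file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(x$exonic, sparse = TRUE), "generalMatrix"),
                    file.path(dir, "matrix_exonic.mtx"))
    Matrix::writeMM(methods::as(Matrix::Matrix(x$intronic, sparse = TRUE), "generalMatrix"),
                    file.path(dir, "matrix_intronic.mtx"))
  } else {
    utils::write.csv(as.data.frame(x$exonic), file.path(dir, "exonic.csv"))
    utils::write.csv(as.data.frame(x$intronic), file.path(dir, "intronic.csv"))
  }
  invisible(dir)
}

#' Read a two-layer expression matrix from disk
#'
#' Counterpart of [write_expression()]; round-trips are bit-exact on the
#' integer count layers. Dimensions of the MTX files must agree with the
#' annotation tables.
#'
#' @param dir directory containing the files written by [write_expression()].
#' @param format `"mtx"` (default) or `"csv"`.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(dir, format = c("mtx", "csv")) {
  format <- match.arg(format)
  genes <- utils::read.delim(file.path(dir, "genes.tsv"), stringsAsFactors = FALSE)
  samples <- utils::read.delim(file.path(dir, "samples.tsv"), stringsAsFactors = FALSE)
  as_count_matrix <- function(m) {
    m <- as.matrix(m)
    if (all(m == round(m)) && max(m) < .Machine$integer.max) {
      storage.mode(m) <- "integer"
    }
    m
  }
  if (format == "mtx") {
    exonic <- as_count_matrix(Matrix::readMM(file.path(dir, "matrix_exonic.mtx")))
    intronic <- as_count_matrix(Matrix::readMM(file.path(dir, "matrix_intronic.mtx")))
  } else {
    exonic <- as.matrix(utils::read.csv(file.path(dir, "exonic.csv"), row.names = 1,
                                        check.names = FALSE))
    intronic <- as.matrix(utils::read.csv(file.path(dir, "intronic.csv"), row.names = 1,
                                          check.names = FALSE))
  }
  if (nrow(exonic) != nrow(genes) || ncol(exonic) != nrow(samples)) {
    stop(sprintf("matrix is %d x %d but annotations describe %d genes and %d samples",
                 nrow(exonic), ncol(exonic), nrow(genes), nrow(samples)))
  }
  expression_matrix(exonic, intronic, genes = genes$gene_id,
                    samples = samples$sample_id,
                    gene_length = genes$length)
}
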