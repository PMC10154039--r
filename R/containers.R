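# Coerce dense or sparse numeric input to dgCMatrix.
as_dgc <- function(x) {
  if (methods::is(x, "sparseMatrix") || methods::is(x, "Matrix"))
    methods::as(methods::as(methods::as(x, "dMatrix"), "generalMatrix"),
                "CsparseMatrix")
  else
    methods::as(Matrix::Matrix(as.matrix(x), sparse = TRUE),
                "CsparseMatrix")
}

#' Sparse UMI count matrix with gene and cell annotations
#'
#' The central container for droplet-style single-cell data: a sparse
#' gene x cell matrix of nonnegative integer UMI counts, a gene annotation
#' table (id, chromosome, start, mitochondrial flag) and a cell annotation
#' table (barcode, sample, time point, reporter status, plus any extra
#' columns such as an embedding or cluster labels). Optional named layers
#' (e.g. `spliced`, `unspliced`) share the same dimensions.
#'
#' @param counts sparse or dense gene x cell matrix of nonnegative integers;
#'   coerced to `dgCMatrix`. Rownames are gene ids, colnames are barcodes.
#' @param gene_meta data.frame with at least a `gene` column matching
#'   `rownames(counts)`; typically also `chrom`, `start`, `mito`.
#' @param cell_meta data.frame with at least a `barcode` column matching
#'   `colnames(counts)`.
#' @param layers named list of matrices with the same dimnames as `counts`.
#' @return an object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, gene_meta = NULL, cell_meta = NULL,
                         layers = list()) {
  counts <- as_dgc(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and barcode colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell barcodes")
  if (any(counts@x < 0)) stop("counts must be nonnegative")
  if (is.null(gene_meta))
    gene_meta <- data.frame(gene = rownames(counts))
  if (is.null(cell_meta))
    cell_meta <- data.frame(barcode = colnames(counts))
  stopifnot(identical(gene_meta$gene, rownames(counts)),
            identical(cell_meta$barcode, colnames(counts)))
  for (nm in names(layers)) {
    stopifnot(identical(dim(layers[[nm]]), dim(counts)))
    layers[[nm]] <- as_dgc(layers[[nm]])
    dimnames(layers[[nm]]) <- dimnames(counts)
  }
  structure(list(counts = counts, gene_meta = gene_meta,
                 cell_meta = cell_meta, layers = layers),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells (%d nonzero)\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  if (length(x$layers))
    cat("layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Subset a CountMatrix by gene and/or cell
#'
#' @param x a `CountMatrix`.
#' @param genes,cells index vectors (logical, integer or character) into
#'   genes / cells; `NULL` keeps all.
#' @return the subsetted `CountMatrix`.
#' @export
subset_cm <- function(x, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- seq_len(nrow(x$counts))
  if (is.null(cells)) cells <- seq_len(ncol(x$counts))
  if (is.character(genes)) genes <- match(genes, rownames(x$counts))
  if (is.character(cells)) cells <- match(cells, colnames(x$counts))
  count_matrix(x$counts[genes, cells, drop = FALSE],
               x$gene_meta[genes, , drop = FALSE] |> `rownames<-`(NULL),
               x$cell_meta[cells, , drop = FALSE] |> `rownames<-`(NULL),
               lapply(x$layers, function(l) l[genes, cells, drop = FALSE]))
}

#' Log2 expression matrix
#'
#' Gene x cell matrix of `log2(1 + size-normalised counts)` values plus the
#' single scale factor used for every cell. All scoring operates on this.
#'
#' @param values sparse gene x cell matrix of nonnegative reals.
#' @param scale the counts-per-cell scale factor used during normalisation.
#' @param gene_meta,cell_meta annotation tables carried over from the counts.
#' @return an object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, scale, gene_meta = NULL,
                              cell_meta = NULL) {
  stopifnot(scale > 0)
  if (any(values < 0)) stop("log2 expression values must be nonnegative")
  structure(list(values = values, scale = scale,
                 gene_meta = gene_meta, cell_meta = cell_meta),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells (scale = %g)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene signature
#'
#' A named, unique set of gene ids, optionally with a per-gene sign.
#'
#' @param name signature name.
#' @param genes character vector of gene ids (non-empty, de-duplicated).
#' @param direction optional numeric vector of +1/-1 per gene.
#' @return an object of class `GeneSignature`.
#' @export
gene_signature <- function(name, genes, direction = NULL) {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("a gene signature needs at least one gene")
  if (!is.null(direction)) stopifnot(length(direction) == length(genes))
  structure(list(name = name, genes = genes, direction = direction),
            class = "GeneSignature")
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat(sprintf("GeneSignature '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}
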