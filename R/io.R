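#' Write a CountMatrix in the 10x triplet layout
#'
#' Writes `matrix.mtx`, `genes.tsv` (the full gene annotation table) and
#' `barcodes.tsv` (the full cell annotation table) into `dir`; each extra
#' layer goes to `<layer>.mtx`.
#'
#' @param x a `CountMatrix`.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_10x <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(x$gene_meta, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$cell_meta, file.path(dir, "barcodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(x$layers))
    Matrix::writeMM(x$layers[[nm]], file.path(dir, paste0(nm, ".mtx")))
  invisible(dir)
}

#' Read a CountMatrix from a 10x triplet directory
#'
#' Expects the layout written by [write_10x()]; any `<name>.mtx` file other
#' than `matrix.mtx` is read back as a layer.
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return a `CountMatrix`.
#' @export
read_10x <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  genes <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  cells <- utils::read.table(file.path(dir, "barcodes.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  dimnames(counts) <- list(genes$gene, cells$barcode)
  layer_files <- setdiff(list.files(dir, pattern = "\\.mtx$"), "matrix.mtx")
  layers <- lapply(layer_files, function(f) {
    m <- methods::as(Matrix::readMM(file.path(dir, f)), "CsparseMatrix")
    dimnames(m) <- dimnames(counts)
    m
  })
  names(layers) <- sub("\\.mtx$", "", layer_files)
  count_matrix(counts, genes, cells, layers)
}

#' Read a gene signature file
#'
#' Supports the GMT dialect (one signature per line: name, description,
#' genes, tab-separated) and plain two-column TSV (signature name, gene).
#'
#' @param path file path.
#' @param format `"gmt"` or `"tsv"`.
#' @return a list of `GeneSignature` objects keyed by name.
#' @export
read_signatures <- function(path, format = c("gmt", "tsv")) {
  format <- match.arg(format)
  if (format == "gmt") {
    lines <- readLines(path)
    sigs <- lapply(lines, function(l) {
      f <- strsplit(l, "\t", fixed = TRUE)[[1]]
      gene_signature(f[1], f[-(1:2)])
    })
  } else {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    sigs <- lapply(split(tab[[2]], tab[[1]]), function(g)
      gene_signature(NA_character_, g))
    for (nm in names(sigs)) sigs[[nm]]$name <- nm
  }
  stats::setNames(sigs, vapply(sigs, `[[`, "", "name"))
}

write_tsv <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
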