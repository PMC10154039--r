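#' Filter cells and genes by the standard droplet QC rules
#'
#' Cells are retained when their detected-gene count (genes with count > 0)
#' lies in `[min_genes, max_genes]` (both ends inclusive) and their
#' mitochondrial UMI fraction is strictly below `max_mito`. Genes are then
#' retained when detected in at least `min_cells` of the retained cells.
#' Cells are filtered on the unfiltered gene set first; a cell violating
#' several rules is attributed to the first rule in the order
#' gene-count range, then mitochondrial fraction.
#'
#' @param cm a `CountMatrix` whose `gene_meta` carries a logical `mito`
#'   column.
#' @param min_genes,max_genes detected-gene bounds per cell (default
#'   200 and 6000, inclusive).
#' @param max_mito mitochondrial fraction cutoff (default 0.10, strict).
#' @param min_cells minimum number of cells a gene must be detected in
#'   (default 5).
#' @return list with `counts` (filtered `CountMatrix`) and `report`, a
#'   one-row data.frame reconciling input = retained + removed per rule.
#' @export
filter_cells_genes <- function(cm, min_genes = 200, max_genes = 6000,
                               max_mito = 0.10, min_cells = 5) {
  if (is.null(cm$gene_meta$mito)) stop("gene_meta must carry a mito flag")
  cnt <- cm$counts
  detected <- Matrix::colSums(cnt > 0)
  tot <- Matrix::colSums(cnt)
  mito_frac <- Matrix::colSums(cnt[cm$gene_meta$mito, , drop = FALSE]) /
    pmax(tot, 1)
  bad_ngene <- detected < min_genes | detected > max_genes
  bad_mito <- !bad_ngene & mito_frac >= max_mito
  keep_cells <- !(bad_ngene | bad_mito)
  if (!any(keep_cells)) stop("no cells pass the QC filters")
  ncell_gene <- Matrix::rowSums(cnt[, keep_cells, drop = FALSE] > 0)
  keep_genes <- ncell_gene >= min_cells
  if (!any(keep_genes)) stop("no genes pass the QC filters")
  report <- data.frame(
    input_cells = ncol(cnt),
    removed_gene_count = sum(bad_ngene),
    removed_mito = sum(bad_mito),
    retained_cells = sum(keep_cells),
    input_genes = nrow(cnt),
    removed_low_detection = sum(!keep_genes),
    retained_genes = sum(keep_genes))
  list(counts = subset_cm(cm, genes = keep_genes, cells = keep_cells),
       report = report)
}

#' Log2 size-factor normalisation
#'
#' Every cell's counts are scaled to a common total of `scale` counts and
#' log-transformed: `value(g, c) = log2(1 + count(g, c) * scale /
#' library_size(c))`.
#'
#' @param cm a `CountMatrix`.
#' @param scale target counts per cell (default 10,000).
#' @return an `ExpressionMatrix` (sparse; zeros stay zero).
#' @export
normalize_log2 <- function(cm, scale = 1e4) {
  cnt <- cm$counts
  lib <- Matrix::colSums(cnt)
  if (any(lib == 0))
    stop("cells with zero library size: ",
         paste(colnames(cnt)[lib == 0], collapse = ", "))
  v <- cnt
  v@x <- log2(1 + v@x * scale / rep.int(lib, diff(v@p)))
  expression_matrix(v, scale, cm$gene_meta, cm$cell_meta)
}

#' Select highly variable genes
#'
#' Genes are ranked by a binned dispersion statistic: per-gene mean and
#' variance of the log2 values are computed, genes are split into 20
#' equal-frequency bins of mean expression, and the variance is z-scored
#' within each bin. Ties (including the all-equal case, where every z-score
#' is 0) are broken lexicographically by gene id.
#'
#' @param expr an `ExpressionMatrix`.
#' @param n number of genes to return (default 4000, capped at the gene
#'   count).
#' @param nbin number of mean-expression bins.
#' @return character vector of the top `n` gene ids.
#' @export
select_hvg <- function(expr, n = 4000, nbin = 20) {
  v <- expr$values
  if (n > nrow(v)) stop("n exceeds the number of genes")
  mu <- Matrix::rowMeans(v)
  m2 <- Matrix::rowMeans(v^2)
  va <- pmax(m2 - mu^2, 0) * ncol(v) / max(ncol(v) - 1, 1)
  bin <- cut(rank(mu, ties.method = "first"),
             breaks = min(nbin, nrow(v)), labels = FALSE)
  z <- stats::ave(va, bin, FUN = function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  ord <- order(-z, rownames(v))
  rownames(v)[ord[seq_len(n)]]
}
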