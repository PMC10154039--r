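# Small simulated datasets shared across test files; everything is built
# in code at test time.

small_config <- function(seed = 1L, n_genes = 400, cells = 60, ...) {
  simulation_config(
    n_genes = n_genes,
    n_cells_per_stage = c(T0 = cells, T1 = cells, T2 = cells, T3 = cells),
    program_specs = list(
      list(name = "tps", n_genes = 10, lineage = "differentiation",
           direction = "down", lfc_range = c(2, 2), shared_with = "tps"),
      list(name = "tps", n_genes = 10, lineage = "transformation",
           direction = "up", lfc_range = c(2, 2), shared_with = "tps"),
      list(name = "maturation", n_genes = 15, lineage = "differentiation",
           direction = "up", lfc_range = c(1.5, 2.5)),
      list(name = "stemness_loss", n_genes = 15, lineage = "transformation",
           direction = "down", lfc_range = c(1.5, 2.5)),
      list(name = "splicing_factor", n_genes = 12, lineage = "both",
           direction = "up", lfc_range = c(1.5, 1.5))),
    cc_spec = list(n_s_genes = 12, n_g2m_genes = 12, frac_s = 0.2,
                   frac_g2m = 0.2, effect = 1.5),
    seed = seed, ...)
}

flat_config <- function(seed = 1L, n_genes = 400, cells = 60) {
  cfg <- small_config(seed = seed, n_genes = n_genes, cells = cells)
  cfg$program_specs <- lapply(cfg$program_specs, function(p) {
    p$lfc_range <- c(0, 0)
    p
  })
  cfg$cc_spec <- list(n_s_genes = 0, n_g2m_genes = 0, frac_s = 0,
                      frac_g2m = 0, effect = 0)
  cfg
}

# A hand-buildable CountMatrix from a dense integer matrix.
toy_cm <- function(mat, mito = rep(FALSE, nrow(mat)), chrom = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("g%03d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("c%03d", seq_len(ncol(mat)))
  if (is.null(chrom)) chrom <- rep("1", nrow(mat))
  count_matrix(mat,
               data.frame(gene = rownames(mat), chrom = chrom,
                          start = seq_len(nrow(mat)) * 100, mito = mito),
               data.frame(barcode = colnames(mat)))
}

# Deterministic dense expression matrix wrapper.
toy_expr <- function(mat) {
  m <- methods::as(Matrix::Matrix(mat, sparse = TRUE), "CsparseMatrix")
  expression_matrix(m, scale = 1e4,
                    gene_meta = data.frame(gene = rownames(mat)),
                    cell_meta = data.frame(barcode = colnames(mat)))
}
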