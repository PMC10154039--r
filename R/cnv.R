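#' Infer per-cell CNV profiles by moving-average smoothing
#'
#' Genes are ordered by chromosome and position; each cell's log2
#' expression is expressed relative to the mean of the reference cells,
#' clipped to `±clip`, and smoothed with a centred moving average of `w`
#' consecutive genes within each chromosome (windows never span two
#' chromosomes; chromosomes with fewer than `w` genes are dropped with a
#' warning). Finally each cell's genome-wide mean is subtracted, so the
#' profile is invariant to adding a per-cell constant to the expression.
#'
#' @param expr an `ExpressionMatrix`.
#' @param gene_positions data.frame (gene, chrom, start); defaults to the
#'   matrix's `gene_meta`.
#' @param reference_cells barcodes of presumed-normal cells.
#' @param w odd window width in genes (default 101).
#' @param clip clipping bound on relative expression (default 3).
#' @return a `CNVProfile`: list with `matrix` (cell x window), `windows`
#'   (chrom, centre gene), `w`, `reference_cells`, `burden` (per-cell mean
#'   squared window value).
#' @export
infer_cnv_profile <- function(expr, gene_positions = NULL, reference_cells,
                              w = 101, clip = 3) {
  if (w %% 2 == 0) stop("window width w must be odd")
  if (!length(reference_cells)) stop("reference cell set is empty")
  v <- as.matrix(expr$values)
  if (is.null(gene_positions)) gene_positions <- expr$gene_meta
  stopifnot(all(reference_cells %in% colnames(v)),
            all(c("gene", "chrom", "start") %in% names(gene_positions)))
  gp <- gene_positions[match(rownames(v), gene_positions$gene), ]
  ord <- order(gp$chrom, gp$start)
  v <- v[ord, , drop = FALSE]
  gp <- gp[ord, ]
  rel <- v - rowMeans(v[, reference_cells, drop = FALSE])
  rel <- pmin(pmax(rel, -clip), clip)
  mats <- list(); wins <- list()
  for (chr in unique(gp$chrom)) {
    sel <- gp$chrom == chr
    if (sum(sel) < w) {
      warning("chromosome ", chr, " has fewer than ", w,
              " genes; excluded")
      next
    }
    sm <- zoo::rollmean(rel[sel, , drop = FALSE], w)
    mats[[chr]] <- sm
    centre <- gp$gene[sel][(1 + (w - 1) / 2):(sum(sel) - (w - 1) / 2)]
    wins[[chr]] <- data.frame(chrom = chr, centre_gene = centre)
  }
  if (!length(mats)) stop("no chromosome has at least w genes")
  prof <- t(do.call(rbind, mats))
  prof <- prof - rowMeans(prof)
  windows <- do.call(rbind, wins)
  rownames(windows) <- NULL
  colnames(prof) <- paste0(windows$chrom, ":", windows$centre_gene)
  structure(list(matrix = prof, windows = windows, w = w,
                 reference_cells = reference_cells,
                 burden = rowMeans(prof^2)),
            class = "CNVProfile")
}

#' Call malignant cells from a CNV profile
#'
#' Cells are clustered hierarchically on their CNV profiles (correlation
#' distance, average linkage). Cells sharing a CNV correlate strongly and
#' form a tight clade, while CNV-free cells are mutually uncorrelated and
#' only merge near the noise level (height about 1), so the dendrogram is
#' cut at `cut_height` rather than into a fixed number of groups. A
#' cluster of at least `min_cluster` cells is called malignant when its
#' mean burden (mean squared window value) exceeds `margin` times the mean
#' burden of the reference cells. With `k` set, a fixed k-way cut is used
#' instead of the height cut.
#'
#' @param profile a `CNVProfile`.
#' @param margin burden multiple of the reference required for a malignant
#'   call (default 1.5).
#' @param cut_height dendrogram cut height on the correlation-distance
#'   scale (default 0.6, i.e. clades tighter than a mean correlation of
#'   0.4).
#' @param min_cluster smallest cluster size eligible for a malignant call
#'   (default 10); guards against small chance clades of noise cells.
#' @param k optional fixed number of clusters overriding `cut_height`.
#' @return data.frame (barcode, cluster, burden, malignant).
#' @export
call_malignant <- function(profile, margin = 1.5, cut_height = 0.6,
                           min_cluster = 10, k = NULL) {
  m <- profile$matrix
  if (nrow(m) < 2) stop("need at least two cells to call malignant cells")
  cc <- suppressWarnings(stats::cor(t(m)))
  cc[!is.finite(cc)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  cl <- if (is.null(k)) stats::cutree(hc, h = cut_height)
        else stats::cutree(hc, k = k)
  burden <- profile$burden
  ref_burden <- mean(burden[rownames(m) %in% profile$reference_cells])
  if (!is.finite(ref_burden)) ref_burden <- mean(burden)
  cl_burden <- tapply(burden, cl, mean)
  cl_size <- table(cl)
  high <- cl_burden > margin * ref_burden & cl_size >= min_cluster
  malignant <- unname(high[as.character(cl)])
  data.frame(barcode = rownames(m), cluster = unname(cl),
             burden = unname(burden), malignant = malignant,
             row.names = NULL)
}
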