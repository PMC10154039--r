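#' Scoring configuration
#'
#' @param nbin number of average-expression bins used to match control
#'   genes (default 28).
#' @param nctrl control genes drawn per signature gene (default 100).
#' @param seed integer seed for the control draw.
#' @return a `ScoringConfig` list.
#' @export
scoring_config <- function(nbin = 28, nctrl = 100, seed = 1L) {
  if (nbin < 2) stop("nbin must be at least 2")
  structure(list(nbin = nbin, nctrl = nctrl, seed = as.integer(seed)),
            class = "ScoringConfig")
}

#' Mean-of-log2 signature score
#'
#' The per-cell score of a gene set is the mean of the log2 expression
#' values over the signature genes present in the matrix. Genes absent
#' from the matrix are dropped; their number is reported as a warning.
#'
#' @param expr an `ExpressionMatrix`.
#' @param sig a `GeneSignature` (or a plain character vector of gene ids).
#' @return named numeric vector of per-cell scores.
#' @export
signature_score <- function(expr, sig) {
  if (!inherits(sig, "GeneSignature")) sig <- gene_signature("sig", sig)
  present <- intersect(sig$genes, rownames(expr$values))
  if (!length(present))
    stop("no gene of signature '", sig$name, "' is present in the matrix")
  n_absent <- length(sig$genes) - length(present)
  if (n_absent > 0)
    warning(n_absent, " gene(s) of signature '", sig$name,
            "' absent from the matrix")
  Matrix::colMeans(expr$values[present, , drop = FALSE])
}

#' Module score against a binned expression-matched background
#'
#' Genes are binned into `nbin` equal-frequency bins of average expression
#' across cells; for every signature gene, `nctrl` control genes are drawn
#' (seeded) from the same bin, and the per-cell score is the mean over the
#' signature genes minus the mean over the pooled control genes. When a
#' bin holds fewer genes than requested, controls are drawn with
#' replacement and a warning is emitted.
#'
#' @param expr an `ExpressionMatrix`.
#' @param sig a `GeneSignature` or character vector.
#' @param config a [scoring_config()].
#' @return named numeric vector of per-cell scores.
#' @export
module_score_binned <- function(expr, sig, config = scoring_config()) {
  if (!inherits(sig, "GeneSignature")) sig <- gene_signature("sig", sig)
  v <- expr$values
  genes <- rownames(v)
  present <- intersect(sig$genes, genes)
  if (!length(present))
    stop("no gene of signature '", sig$name, "' is present in the matrix")
  if (length(genes) - length(present) < length(present))
    stop("fewer non-signature genes than signature genes; cannot draw a ",
         "background")
  avg <- Matrix::rowMeans(v)
  bin <- cut(rank(avg, ties.method = "first"),
             breaks = min(config$nbin, length(genes)), labels = FALSE)
  names(bin) <- genes
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  ctrl <- character(0)
  for (g in present) {
    pool <- genes[bin == bin[[g]]]
    if (length(pool) < config$nctrl) {
      warning("bin of gene ", g, " holds ", length(pool),
              " genes; sampling controls with replacement")
      ctrl <- c(ctrl, sample(pool, config$nctrl, replace = TRUE))
    } else {
      ctrl <- c(ctrl, sample(pool, config$nctrl))
    }
  }
  ctrl <- unique(ctrl)
  sig_mean <- Matrix::colMeans(v[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(v[ctrl, , drop = FALSE])
  sig_mean - ctrl_mean
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Derived G1 (quiescence) score
#'
#' Cells whose S or G2M score is positive are actively cycling and get a
#' G1 score of exactly 0; for the remaining cells the G1 score is
#' `-(S + G2M) / 2`, so the more negative both cycling scores are, the
#' higher the quiescence score.
#'
#' @param s,g2m numeric vectors of S and G2M scores (recycled together).
#' @return numeric vector of G1 scores.
#' @export
g1_score <- function(s, g2m) {
  ifelse(pmax(s, g2m) > 0, 0, -(s + g2m) / 2)
}

#' Cell-cycle scoring and phase assignment
#'
#' S and G2M scores come from [module_score_binned()]; a cell with a
#' positive maximum is assigned the argmax phase (ties go to G2M), all
#' other cells are G1. The G1 score follows [g1_score()].
#'
#' @param expr an `ExpressionMatrix`.
#' @param s_genes,g2m_genes S-phase and G2M-phase signatures.
#' @param config a [scoring_config()] (default `nbin = 28`).
#' @return a `CellScores` data.frame (barcode, SScore, G2MScore, G1Score,
#'   phase).
#' @export
cell_cycle_scores <- function(expr, s_genes, g2m_genes,
                              config = scoring_config()) {
  s <- module_score_binned(expr, s_genes, config)
  g2m <- module_score_binned(expr, g2m_genes, config)
  phase <- ifelse(pmax(s, g2m) > 0, ifelse(s > g2m, "S", "G2M"), "G1")
  data.frame(barcode = colnames(expr$values), SScore = s, G2MScore = g2m,
             G1Score = g1_score(s, g2m), phase = phase,
             row.names = NULL)
}

#' Bulk G1 score from TPM
#'
#' Per sample, the mean TPM over each cell-cycle signature is computed and
#' z-scored across samples; the bulk G1 score combines the two z-scores
#' with the same rule as the single-cell formula, `-(z_S + z_G2M) / 2`.
#'
#' @param tpm sample x gene numeric matrix of TPM values.
#' @param s_genes,g2m_genes signatures (`GeneSignature` or character).
#' @return data.frame (sample, z_s, z_g2m, G1Score).
#' @export
bulk_g1_score <- function(tpm, s_genes, g2m_genes) {
  if (nrow(tpm) < 2) stop("bulk G1 needs at least 2 samples")
  sig_mean <- function(sig) {
    if (inherits(sig, "GeneSignature")) sig <- sig$genes
    present <- intersect(sig, colnames(tpm))
    if (!length(present)) stop("signature has no gene in the TPM matrix")
    rowMeans(tpm[, present, drop = FALSE])
  }
  zs <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("zero variance across samples; z-score undefined")
    (x - mean(x)) / s
  }
  z_s <- zs(sig_mean(s_genes))
  z_g2m <- zs(sig_mean(g2m_genes))
  data.frame(sample = rownames(tpm), z_s = z_s, z_g2m = z_g2m,
             G1Score = -(z_s + z_g2m) / 2, row.names = NULL)
}
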