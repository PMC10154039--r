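#' Steady-state gamma for one gene
#'
#' Fits the steady-state ratio `gamma` of unspliced to spliced abundance on
#' the cells in the extreme quantiles of spliced expression (where cells
#' are assumed closest to steady state). The default is regression through
#' the origin; with `intercept = TRUE` an offset is estimated as well.
#'
#' @param spliced,unspliced numeric vectors over cells (already
#'   size-normalised).
#' @param quantile tail fraction on each side (default 0.02).
#' @param intercept estimate an offset (default `FALSE`).
#' @return list with `gamma` and `offset`, or `NULL` when the gene is
#'   degenerate (all-zero or constant spliced values).
#' @export
fit_steady_state_gamma <- function(spliced, unspliced, quantile = 0.02,
                                   intercept = FALSE) {
  ok <- is.finite(spliced) & is.finite(unspliced)
  s <- spliced[ok]; u <- unspliced[ok]
  if (sum(s != 0 | u != 0) < 20) return(NULL)
  if (stats::sd(s) == 0) return(NULL)
  qs <- stats::quantile(s, c(quantile, 1 - quantile))
  ext <- s <= qs[1] | s >= qs[2]
  if (sum(ext) < 2) ext <- rep(TRUE, length(s))
  s_e <- s[ext]; u_e <- u[ext]
  if (intercept) {
    if (stats::sd(s_e) == 0) return(NULL)
    fit <- stats::lm.fit(cbind(1, s_e), u_e)
    gamma <- fit$coefficients[2]
    offset <- fit$coefficients[1]
  } else {
    if (sum(s_e^2) == 0) return(NULL)
    gamma <- sum(u_e * s_e) / sum(s_e^2)
    offset <- 0
  }
  if (!is.finite(gamma) || gamma <= 0) return(NULL)
  list(gamma = unname(gamma), offset = unname(offset))
}

#' Fit the steady-state velocity model over all genes
#'
#' Spliced and unspliced layers are size-normalised per cell (to the
#' median spliced library size), gamma is fitted per gene on the extreme
#' quantiles of spliced expression, and the velocity residual of every
#' cell and gene is `u - (gamma * s + offset)`. Genes whose gamma cannot
#' be fitted are skipped and listed in `skipped`.
#'
#' @param cm a `CountMatrix` with `spliced` and `unspliced` layers.
#' @param quantile extreme-quantile fraction (default 0.02).
#' @param intercept per-gene offset (default `FALSE`).
#' @return a `VelocityModel`: list with `gamma`, `offset`, `residuals`
#'   (gene x cell), `s_norm`, `skipped`.
#' @export
fit_velocity <- function(cm, quantile = 0.02, intercept = FALSE) {
  stopifnot(all(c("spliced", "unspliced") %in% names(cm$layers)))
  s <- as.matrix(cm$layers$spliced)
  u <- as.matrix(cm$layers$unspliced)
  lib_s <- pmax(colSums(s), 1)
  lib_u <- pmax(colSums(u), 1)
  s_n <- sweep(s, 2, stats::median(lib_s) / lib_s, "*")
  u_n <- sweep(u, 2, stats::median(lib_u) / lib_u, "*")
  genes <- rownames(s)
  gamma <- offset <- stats::setNames(rep(NA_real_, length(genes)), genes)
  for (g in genes) {
    fit <- fit_steady_state_gamma(s_n[g, ], u_n[g, ], quantile, intercept)
    if (!is.null(fit)) {
      gamma[g] <- fit$gamma
      offset[g] <- fit$offset
    }
  }
  keep <- !is.na(gamma)
  resid <- u_n[keep, , drop = FALSE] -
    (s_n[keep, , drop = FALSE] * gamma[keep] + offset[keep])
  structure(list(gamma = gamma[keep], offset = offset[keep],
                 residuals = resid, s_norm = s_n[keep, , drop = FALSE],
                 skipped = genes[!keep]),
            class = "VelocityModel")
}

#' Project velocities onto a 2-D embedding
#'
#' Each cell's velocity vector is the weighted mean of the unit directions
#' toward its `k` nearest embedding neighbours, weighted by the Pearson
#' correlation between the cell's velocity residual profile and the
#' spliced-expression difference toward that neighbour (positive when the
#' neighbour lies where the cell's expression is heading). Weights are
#' normalised by their absolute sum, so flipping the sign of the residuals
#' negates every vector. Cells with negligible residuals get a zero
#' vector.
#'
#' @param model a `VelocityModel`.
#' @param embedding cell x 2 matrix, columns in the model's cell order.
#' @param k neighbour count (default 30; capped at n-1).
#' @param eps residual-norm threshold below which a cell's vector is 0.
#' @return cell x 2 matrix of velocity vectors.
#' @export
velocity_vectors <- function(model, embedding, k = 30, eps = 1e-8) {
  embedding <- as.matrix(embedding)
  n <- ncol(model$residuals)
  stopifnot(nrow(embedding) == n)
  k <- min(k, n - 1)
  d <- as.matrix(stats::dist(embedding))
  out <- matrix(0, n, 2, dimnames = list(rownames(embedding),
                                         c("v1", "v2")))
  V <- model$residuals
  S <- model$s_norm
  for (i in seq_len(n)) {
    v <- V[, i]
    if (sqrt(sum(v^2)) < eps) next
    nb <- order(d[i, ])[2:(k + 1)]
    dS <- S[, nb, drop = FALSE] - S[, i]
    vc <- v - mean(v)
    w <- vapply(seq_along(nb), function(j) {
      x <- dS[, j]
      xs <- stats::sd(x)
      if (!is.finite(xs) || xs == 0) return(0)
      stats::cor(v, x)
    }, 0)
    dirs <- sweep(embedding[nb, , drop = FALSE], 2, embedding[i, ])
    len <- sqrt(rowSums(dirs^2))
    ok <- len > 0 & is.finite(w)
    if (!any(ok) || sum(abs(w[ok])) == 0) next
    unit <- dirs[ok, , drop = FALSE] / len[ok]
    out[i, ] <- colSums(unit * w[ok]) / sum(abs(w[ok]))
  }
  out
}

#' Directed-flow statistic between two cell groups
#'
#' Measures whether velocity vectors of group A point toward group B more
#' than the reverse: the mean cosine between each A cell's vector and the
#' unit direction toward B's centroid, minus the same quantity for B
#' toward A. Swapping the groups negates the statistic. Significance is
#' assessed by permuting group labels.
#'
#' @param vectors cell x 2 velocity vectors.
#' @param embedding cell x 2 embedding (same row order).
#' @param groupA,groupB row indices (logical or integer) of the two
#'   groups.
#' @param n_permutations label permutations for the p-value (default 499).
#' @param seed permutation seed.
#' @return a `FlowScore` list (`score` in [-1, 1], `p`, group sizes).
#' @export
flow_direction_score <- function(vectors, embedding, groupA, groupB,
                                 n_permutations = 499, seed = 1L) {
  embedding <- as.matrix(embedding)
  idxA <- which(as.logical(seq_len(nrow(embedding)) %in%
                             to_idx(groupA, nrow(embedding))))
  idxB <- which(as.logical(seq_len(nrow(embedding)) %in%
                             to_idx(groupB, nrow(embedding))))
  if (!length(idxA) || !length(idxB)) stop("both groups must be non-empty")
  centA <- colMeans(embedding[idxA, , drop = FALSE])
  centB <- colMeans(embedding[idxB, , drop = FALSE])
  if (sqrt(sum((centA - centB)^2)) < 1e-12)
    stop("group centroids coincide; flow direction undefined")
  stat_fn <- function(ia, ib) {
    ca <- colMeans(embedding[ia, , drop = FALSE])
    cb <- colMeans(embedding[ib, , drop = FALSE])
    mean_cos <- function(idx, target) {
      v <- vectors[idx, , drop = FALSE]
      dirs <- sweep(-embedding[idx, , drop = FALSE], 2, target, "+")
      num <- rowSums(v * dirs)
      den <- sqrt(rowSums(v^2)) * sqrt(rowSums(dirs^2))
      mean(ifelse(den > 0, num / den, 0))
    }
    mean_cos(ia, cb) - mean_cos(ib, ca)
  }
  obs <- stat_fn(idxA, idxB)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pool <- c(idxA, idxB)
  nA <- length(idxA)
  perm <- replicate(n_permutations, {
    sh <- sample(pool)
    stat_fn(sh[seq_len(nA)], sh[-seq_len(nA)])
  })
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_permutations + 1)
  structure(list(score = obs, p = p, nA = length(idxA), nB = length(idxB)),
            class = "FlowScore")
}

to_idx <- function(x, n) {
  if (is.logical(x)) which(x) else as.integer(x)
}
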