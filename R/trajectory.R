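#' Fit principal curves for a two-lineage bifurcating trajectory
#'
#' For each terminal cluster, the path of clusters from the root to that
#' terminal is found on the minimum-spanning tree of cluster centroids in
#' the 2-D embedding. A principal curve is fitted through the cells of the
#' path's clusters by iterative projection-smoothing: cells are projected
#' orthogonally onto the current polyline, each embedding coordinate is
#' smoothed against arc length, and the curve is re-discretised to 300
#' fixed points, until the total projection distance changes by less than
#' 1e-4 (relative) or 50 iterations. Pseudotime is the normalised
#' arc-length of each cell's projection, 0 at the root. Cells whose
#' clusters lie on both lineages' paths are labelled `trunk` and belong to
#' both lineages.
#'
#' @param embedding cell x 2 numeric matrix (rownames = barcodes).
#' @param clusters cluster label per cell.
#' @param root root cluster label.
#' @param terminals named character vector of two terminal cluster labels;
#'   the names become the lineage names (defaults `differentiation`,
#'   `transformation` when unnamed).
#' @param n_points number of fixed points per curve (default 300).
#' @return a `TrajectoryFit`: list with `cells` (barcode, lineage label,
#'   one pseudotime column per lineage, NA outside the lineage) and
#'   `curves` (one `n_points` x 2 matrix per lineage).
#' @export
fit_lineage_curve <- function(embedding, clusters, root, terminals,
                              n_points = 300) {
  embedding <- as.matrix(embedding)
  stopifnot(ncol(embedding) == 2, length(clusters) == nrow(embedding))
  if (is.null(rownames(embedding)))
    rownames(embedding) <- as.character(seq_len(nrow(embedding)))
  if (is.null(names(terminals)))
    names(terminals) <- c("differentiation", "transformation")[
      seq_along(terminals)]
  cl_levels <- unique(as.character(clusters))
  stopifnot(root %in% cl_levels, all(terminals %in% cl_levels))
  cent <- do.call(rbind, lapply(cl_levels, function(cl)
    colMeans(embedding[clusters == cl, , drop = FALSE])))
  rownames(cent) <- cl_levels

  # cluster-centroid MST; lineage = path root -> terminal on the tree
  d <- as.matrix(stats::dist(cent))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g)
  paths <- lapply(terminals, function(tm) {
    p <- igraph::shortest_paths(mst, from = root, to = tm)$vpath[[1]]
    if (!length(p)) stop("cluster graph is disconnected")
    igraph::as_ids(p)
  })

  shared <- if (length(paths) == 2) intersect(paths[[1]], paths[[2]])
            else character(0)
  curves <- list()
  pt_tab <- matrix(NA_real_, nrow(embedding), length(terminals),
                   dimnames = list(rownames(embedding), names(terminals)))
  for (lin in names(terminals)) {
    path <- paths[[lin]]
    sel <- clusters %in% path
    if (sum(sel) < 50) stop("fewer than 50 cells on lineage ", lin)
    fit <- principal_curve_2d(embedding[sel, , drop = FALSE],
                              cent[path, , drop = FALSE], n_points)
    # orient 0 at the root cluster
    root_pt <- mean(fit$lambda[clusters[sel] == root])
    term_pt <- mean(fit$lambda[clusters[sel] == terminals[[lin]]])
    lambda <- if (root_pt > term_pt) 1 - fit$lambda else fit$lambda
    curve <- if (root_pt > term_pt) fit$curve[rev(seq_len(n_points)), ]
             else fit$curve
    curves[[lin]] <- curve
    pt_tab[sel, lin] <- lambda
  }
  label <- rep(NA_character_, length(clusters))
  for (i in seq_along(paths))
    label[clusters %in% setdiff(paths[[i]], shared)] <- names(terminals)[i]
  label[clusters %in% shared] <- "trunk"
  cells <- data.frame(barcode = rownames(embedding), lineage = label,
                      pt_tab, check.names = FALSE, row.names = NULL)
  structure(list(cells = cells, curves = curves,
                 root = root, terminals = terminals),
            class = "TrajectoryFit")
}

# Iterative projection-smoothing principal curve through an ordered
# centroid path. Returns the discretised curve and each cell's normalised
# arc-length position.
principal_curve_2d <- function(points, centroid_path, n_points,
                               max_iter = 50, tol = 1e-4, df = 8) {
  curve <- resample_polyline(centroid_path, n_points)
  prev_d <- Inf
  for (it in seq_len(max_iter)) {
    proj <- project_polyline(points, curve)
    total_d <- sum(proj$dist2)
    if (is.finite(prev_d) && abs(prev_d - total_d) / max(prev_d, 1e-12) < tol)
      break
    prev_d <- total_d
    lam <- proj$lambda
    ord <- order(lam)
    eff_df <- min(df, max(2, length(unique(lam)) - 1))
    sx <- stats::smooth.spline(lam[ord], points[ord, 1], df = eff_df)
    sy <- stats::smooth.spline(lam[ord], points[ord, 2], df = eff_df)
    grid <- seq(min(lam), max(lam), length.out = n_points)
    curve <- cbind(stats::predict(sx, grid)$y, stats::predict(sy, grid)$y)
    curve <- resample_polyline(curve, n_points)
  }
  proj <- project_polyline(points, curve)
  rng <- range(proj$lambda)
  lambda <- if (diff(rng) > 0) (proj$lambda - rng[1]) / diff(rng)
            else rep(0, length(proj$lambda))
  list(curve = curve, lambda = lambda)
}

# Re-discretise a polyline to n points equally spaced in arc length.
resample_polyline <- function(poly, n) {
  seg <- sqrt(rowSums(diff(poly)^2))
  cum <- c(0, cumsum(seg))
  if (max(cum) == 0) return(matrix(poly[1, ], n, 2, byrow = TRUE))
  grid <- seq(0, max(cum), length.out = n)
  cbind(stats::approx(cum, poly[, 1], grid, ties = "ordered")$y,
        stats::approx(cum, poly[, 2], grid, ties = "ordered")$y)
}

# Orthogonal projection of points onto a polyline: per point, the nearest
# location over all segments; lambda is its arc length along the polyline.
project_polyline <- function(points, poly) {
  n <- nrow(points)
  m <- nrow(poly) - 1
  seg_len <- sqrt(rowSums((poly[-1, , drop = FALSE] -
                             poly[-(m + 1), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg_len))
  best_d <- rep(Inf, n)
  best_l <- numeric(n)
  for (j in seq_len(m)) {
    a <- poly[j, ]
    v <- poly[j + 1, ] - a
    vv <- sum(v^2)
    if (vv == 0) next
    t <- ((points[, 1] - a[1]) * v[1] + (points[, 2] - a[2]) * v[2]) / vv
    t <- pmin(pmax(t, 0), 1)
    dx <- points[, 1] - (a[1] + t * v[1])
    dy <- points[, 2] - (a[2] + t * v[2])
    d2 <- dx * dx + dy * dy
    upd <- d2 < best_d
    best_d[upd] <- d2[upd]
    best_l[upd] <- cum[j] + t[upd] * seg_len[j]
  }
  list(lambda = best_l, dist2 = best_d)
}

#' Pseudotime-dynamic gene test along one lineage
#'
#' Per gene, a natural cubic regression spline of expression on pseudotime
#' (5 degrees of freedom) is compared with a constant model by an F test;
#' p-values are Benjamini-Hochberg adjusted across genes. A significant
#' gene's direction is the sign of the fitted value at the end of the
#' lineage minus the fitted value at the start; non-significant and
#' constant genes are `flat`. Trunk cells are included: they define the
#' shared start of both lineages.
#'
#' @param expr an `ExpressionMatrix`.
#' @param fit a `TrajectoryFit`.
#' @param lineage lineage name in `fit`.
#' @param df spline degrees of freedom (default 5).
#' @param q_threshold FDR threshold used to call a direction (default
#'   0.05).
#' @return a `DynamicGeneResult` data.frame (gene, statistic, p, q,
#'   delta_end_start, direction).
#' @export
pseudotime_dynamic_genes <- function(expr, fit, lineage, df = 5,
                                     q_threshold = 0.05) {
  stopifnot(lineage %in% names(fit$curves))
  pt <- fit$cells[[lineage]]
  sel <- !is.na(pt)
  if (sum(sel) < 100) stop("fewer than 100 cells on lineage ", lineage)
  pt <- pt[sel]
  barcodes <- fit$cells$barcode[sel]
  Y <- t(as.matrix(expr$values[, barcodes, drop = FALSE]))
  n <- nrow(Y)
  B <- splines::ns(pt, df = df)
  X <- cbind(1, B)
  qrX <- qr(X)
  coef <- qr.coef(qrX, Y)
  res <- Y - X %*% coef
  rss1 <- colSums(res^2)
  rss0 <- colSums(scale(Y, center = TRUE, scale = FALSE)^2)
  df1 <- df
  df2 <- n - df - 1
  fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  constant <- rss0 <= .Machine$double.eps * n
  p[constant] <- 1
  fstat[constant] <- 0
  ends <- stats::predict(B, c(min(pt), max(pt)))
  delta <- as.numeric(cbind(1, ends[2, , drop = FALSE]) %*% coef -
                        cbind(1, ends[1, , drop = FALSE]) %*% coef)
  q <- stats::p.adjust(p, "BH")
  direction <- ifelse(q < q_threshold & !constant,
                      ifelse(delta > 0, "up", "down"), "flat")
  data.frame(gene = colnames(Y), statistic = fstat, p = p, q = q,
             delta_end_start = delta, direction = direction,
             row.names = NULL)
}

#' Classify dynamic genes into the four lineage gene sets
#'
#' Set 1 / set 2 are the genes rising / falling along the differentiation
#' lineage at `q < q_threshold`; set 3 / set 4 the genes falling / rising
#' along the transformation lineage.
#'
#' @param diff_results,transf_results `DynamicGeneResult` tables over the
#'   same gene universe.
#' @param q_threshold FDR threshold (default 0.05).
#' @return a `LineageGeneSets` list (`set1`..`set4`, `q_threshold`).
#' @export
classify_gene_sets <- function(diff_results, transf_results,
                               q_threshold = 0.05) {
  stopifnot(setequal(diff_results$gene, transf_results$gene))
  pick <- function(res, dir)
    res$gene[res$q < q_threshold & res$direction == dir]
  structure(list(set1 = pick(diff_results, "up"),
                 set2 = pick(diff_results, "down"),
                 set3 = pick(transf_results, "down"),
                 set4 = pick(transf_results, "up"),
                 q_threshold = q_threshold),
            class = "LineageGeneSets")
}

#' Extract the tipping-point signature
#'
#' The tipping-point signature is the intersection of set 2 (genes falling
#' along the differentiation lineage) and set 4 (genes rising along the
#' transformation lineage): genes that the committing progenitor sheds on
#' the normal route but amplifies on the malignant route.
#'
#' @param sets a `LineageGeneSets`.
#' @return a `TippingPointSignature`: list with `genes` and `provenance`
#'   (parent set sizes and threshold).
#' @export
tipping_point_signature <- function(sets) {
  stopifnot(inherits(sets, "LineageGeneSets"))
  genes <- intersect(sets$set2, sets$set4)
  if (!length(genes)) warning("tipping-point signature is empty")
  structure(list(genes = genes,
                 provenance = list(n_set2 = length(sets$set2),
                                   n_set4 = length(sets$set4),
                                   q_threshold = sets$q_threshold)),
            class = "TippingPointSignature")
}

#' @export
print.TippingPointSignature <- function(x, ...) {
  cat(sprintf("TippingPointSignature: %d genes (set2 n=%d, set4 n=%d, q<%g)\n",
              length(x$genes), x$provenance$n_set2, x$provenance$n_set4,
              x$provenance$q_threshold))
  invisible(x)
}
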