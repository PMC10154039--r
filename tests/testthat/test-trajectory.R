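# Shared bifurcation fixture for the trajectory tests.
traj_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_bifurcation(small_config(seed = 13, n_genes = 600,
                                               cells = 120))
      emb <- as.matrix(sim$counts$cell_meta[, c("dim1", "dim2")])
      rownames(emb) <- sim$counts$cell_meta$barcode
      fit <- fit_lineage_curve(emb, sim$counts$cell_meta$cluster,
                               sim$truth$root_cluster,
                               sim$truth$terminal_clusters)
      cache <<- list(sim = sim, emb = emb, fit = fit,
                     expr = normalize_log2(sim$counts))
    }
    cache
  }
})

test_that("cells on a straight line get pseudotime equal to position", {
  set.seed(1)
  n <- 120
  x <- sort(runif(n, 0, 10))
  emb <- cbind(x, rnorm(n, 0, 1e-3))
  rownames(emb) <- sprintf("c%03d", seq_len(n))
  cl <- paste0("k", cut(x, 4, labels = FALSE))
  fit <- fit_lineage_curve(emb, cl, root = "k1", terminals = c(lin = "k4"))
  pt <- fit$cells$lin
  expect_gt(cor(pt, x, method = "spearman"), 0.999)
  expect_equal(range(pt), c(0, 1))
  expect_equal(nrow(fit$curves$lin), 300)
  # reversing root and terminal reverses the map
  fit_r <- fit_lineage_curve(emb, cl, root = "k4", terminals = c(lin = "k1"))
  expect_gt(cor(fit_r$cells$lin, 1 - pt), 0.999)
})

test_that("pseudotime is invariant to rigid rotation of the embedding", {
  fx <- traj_fixture()
  th <- pi / 3
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  emb_rot <- fx$emb %*% R
  fit_rot <- fit_lineage_curve(emb_rot, fx$sim$counts$cell_meta$cluster,
                               fx$sim$truth$root_cluster,
                               fx$sim$truth$terminal_clusters)
  for (lin in c("differentiation", "transformation")) {
    a <- fx$fit$cells[[lin]]
    b <- fit_rot$cells[[lin]]
    sel <- !is.na(a)
    expect_gt(cor(a[sel], b[sel]), 0.999)
  }
})

test_that("fitted pseudotime tracks the latent pseudotime on both lineages", {
  fx <- traj_fixture()
  truth_pt <- fx$sim$truth$pseudotime
  for (lin in c("differentiation", "transformation")) {
    pt <- fx$fit$cells[[lin]]
    sel <- !is.na(pt)
    rho <- cor(pt[sel], truth_pt[fx$fit$cells$barcode[sel]],
               method = "spearman")
    expect_gt(rho, 0.9)
  }
  # trunk cells are shared by both lineages, branch cells by one
  lab <- fx$fit$cells$lineage
  both <- !is.na(fx$fit$cells$differentiation) &
    !is.na(fx$fit$cells$transformation)
  expect_true(all(lab[both] == "trunk"))
})

test_that("dynamic-gene test flags planted trends and spares constants", {
  fx <- traj_fixture()
  res <- pseudotime_dynamic_genes(fx$expr, fx$fit, "differentiation")
  truth <- fx$sim$truth
  up_genes <- truth$programs$gene[truth$programs$lineage == "differentiation" &
                                    truth$programs$direction == "up"]
  down_genes <- truth$programs$gene[
    truth$programs$lineage == "differentiation" &
      truth$programs$direction == "down"]
  expect_gte(mean(res$direction[match(up_genes, res$gene)] == "up"), 0.9)
  expect_gte(mean(res$direction[match(down_genes, res$gene)] == "down"), 0.9)
  # a constant gene gets p = 1 and direction flat
  ex2 <- fx$expr
  ex2$values[1, ] <- 1
  res2 <- pseudotime_dynamic_genes(ex2, fx$fit, "differentiation")
  expect_equal(res2$p[1], 1)
  expect_equal(res2$direction[1], "flat")
  expect_true(all(res$q >= res$p))
})

test_that("spline F-test p-values agree with a GAM oracle on sample genes", {
  fx <- traj_fixture()
  res <- pseudotime_dynamic_genes(fx$expr, fx$fit, "transformation")
  pt <- fx$fit$cells$transformation
  sel <- !is.na(pt)
  barcodes <- fx$fit$cells$barcode[sel]
  set.seed(2)
  genes <- sample(res$gene, 25)
  for (g in genes) {
    y <- as.numeric(fx$expr$values[g, barcodes])
    gp <- tryCatch({
      gm <- mgcv::gam(y ~ s(x, k = 6), data = data.frame(y = y, x = pt[sel]))
      summary(gm)$s.table[1, "p-value"]
    }, error = function(e) NA)
    if (is.na(gp)) next
    mine <- res$p[res$gene == g]
    # agreement on the significance call at a threshold away from both
    expect_equal(mine < 1e-4, gp < 1e-4)
  }
})

test_that("permuting pseudotime kills discoveries among flat genes", {
  fx <- traj_fixture()
  fit_perm <- fx$fit
  set.seed(99)
  sel <- !is.na(fit_perm$cells$differentiation)
  fit_perm$cells$differentiation[sel] <-
    sample(fit_perm$cells$differentiation[sel])
  res <- pseudotime_dynamic_genes(fx$expr, fit_perm, "differentiation")
  expect_lt(mean(res$q < 0.05), 0.02)
  expect_lt(mean(res$p < 0.05), 0.10)
})

test_that("gene-set classification and the TPS intersection are set algebra", {
  mk <- function(genes, dirs, qs) data.frame(gene = genes, statistic = 1,
                                             p = qs, q = qs,
                                             delta_end_start = 0,
                                             direction = dirs)
  genes <- c("a", "b", "c", "d", "e")
  diff_res <- mk(genes, c("down", "down", "down", "up", "flat"),
                 c(0.01, 0.01, 0.01, 0.01, 0.9))
  transf_res <- mk(genes, c("up", "up", "flat", "up", "down"),
                   c(0.01, 0.01, 0.9, 0.01, 0.01))
  sets <- classify_gene_sets(diff_res, transf_res, 0.05)
  expect_setequal(sets$set2, c("a", "b", "c"))
  expect_setequal(sets$set4, c("a", "b", "d"))
  expect_length(intersect(sets$set1, sets$set2), 0)
  tps <- tipping_point_signature(sets)
  expect_setequal(tps$genes, c("a", "b"))
  # empty intersection warns but does not error
  sets$set2 <- character(0)
  expect_warning(tipping_point_signature(sets), "empty")
  # no significant genes -> four empty sets
  none <- mk(genes, rep("flat", 5), rep(0.9, 5))
  expect_true(all(lengths(classify_gene_sets(none, none)[1:4]) == 0))
})

test_that("the planted tipping-point signature is recovered end to end", {
  fx <- traj_fixture()
  dg_d <- pseudotime_dynamic_genes(fx$expr, fx$fit, "differentiation")
  dg_t <- pseudotime_dynamic_genes(fx$expr, fx$fit, "transformation")
  sets <- classify_gene_sets(dg_d, dg_t, 0.05)
  tps <- tipping_point_signature(sets)
  truth_tps <- fx$sim$truth$tps_genes
  expect_true(all(tps$genes %in% sets$set2))
  expect_true(all(tps$genes %in% sets$set4))
  expect_gte(mean(truth_tps %in% tps$genes), 0.9)
})
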