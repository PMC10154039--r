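test_that("signature score is the mean of log2 values over present genes", {
  mat <- matrix(c(1, 3, 5,
                  2, 2, 2), 3, 2,
                dimnames = list(c("a", "b", "c"), c("c1", "c2")))
  ex <- toy_expr(mat)
  expect_equal(unname(signature_score(ex, gene_signature("s", c("a", "b")))),
               c((1 + 3) / 2, (2 + 2) / 2))
  # degenerate signature of all genes equals the column means
  expect_equal(unname(signature_score(ex, rownames(mat))),
               unname(colMeans(mat)))
  # absent genes warn; fully absent signature errors with its name
  expect_warning(signature_score(ex, gene_signature("s", c("a", "zz"))),
                 "absent")
  expect_error(signature_score(ex, gene_signature("ghost", "zz")), "ghost")
})

test_that("signature score is linear over disjoint sub-signatures", {
  set.seed(7)
  mat <- matrix(abs(rnorm(200 * 5, 3)), 200, 5,
                dimnames = list(sprintf("g%03d", 1:200),
                                sprintf("c%d", 1:5)))
  ex <- toy_expr(mat)
  g1 <- rownames(mat)[1:30]
  g2 <- rownames(mat)[31:50]
  s_all <- signature_score(ex, c(g1, g2))
  s1 <- signature_score(ex, g1)
  s2 <- signature_score(ex, g2)
  expect_equal(s_all, (30 * s1 + 20 * s2) / 50)
})

test_that("binned module score vanishes when controls equal the signature", {
  # a bin whose genes are exactly the signature genes: score must be 0
  set.seed(3)
  base <- matrix(abs(rnorm(60 * 8, 2, 0.2)), 60, 8,
                 dimnames = list(sprintf("g%02d", 1:60),
                                 sprintf("c%d", 1:8)))
  # 30 signature genes at a much higher level: they fill the top bin(s)
  sig_genes <- rownames(base)[1:30]
  base[sig_genes, ] <- base[sig_genes, ] + 50
  ex <- toy_expr(base)
  sc <- suppressWarnings(
    module_score_binned(ex, gene_signature("s", sig_genes),
                        scoring_config(nbin = 2, nctrl = 50, seed = 1)))
  expect_equal(unname(sc), rep(0, 8), tolerance = 1e-12)
})

test_that("a shift of the signature against its bin-mates is recovered", {
  # two clean expression tiers so the 2-bin cut is unambiguous: 200 genes
  # near 1 and 200 near 5, with the 30 signature genes in the high tier
  # shifted by +1. The control pool is the (de-duplicated) high bin, so
  # the analytic score is 6 - (170*5 + 30*6)/200 = 0.85.
  set.seed(8)
  n_cells <- 10
  low <- matrix(1, 200, n_cells)
  high <- matrix(5, 200, n_cells)
  mat <- rbind(low, high)
  dimnames(mat) <- list(sprintf("g%03d", 1:400), sprintf("c%02d", 1:n_cells))
  sig <- sample(rownames(mat)[201:400], 30)
  mat[sig, ] <- mat[sig, ] + 1
  ex <- toy_expr(mat)
  sc <- suppressWarnings(
    module_score_binned(ex, gene_signature("s", sig),
                        scoring_config(nbin = 2, nctrl = 200, seed = 2)))
  expect_equal(unname(sc), rep(0.85, n_cells), tolerance = 0.05)
  # determinism under the same seed
  sc2 <- suppressWarnings(
    module_score_binned(ex, gene_signature("s", sig),
                        scoring_config(nbin = 2, nctrl = 200, seed = 2)))
  expect_identical(sc, sc2)
})

test_that("G1 score follows the published formula exactly", {
  expect_equal(g1_score(-0.4, -0.2), 0.3)
  expect_equal(g1_score(0.5, -0.1), 0)
  expect_equal(g1_score(0, 0), 0)
  expect_equal(g1_score(-0.1, 0.2), 0)
  s <- c(-1, -0.5, 0.3, 0)
  g <- c(-2, 0.1, -0.3, 0)
  expect_equal(g1_score(s, g), c(1.5, 0, 0, 0))
})

test_that("phase assignment uses the argmax rule with G2M tie-break", {
  set.seed(5)
  sim <- simulate_bifurcation(small_config(seed = 5, n_genes = 300,
                                           cells = 60))
  expr <- normalize_log2(sim$counts)
  cc <- suppressWarnings(cell_cycle_scores(
    expr, gene_signature("S", sim$truth$s_genes),
    gene_signature("G2M", sim$truth$g2m_genes),
    scoring_config(seed = 5)))
  # the partition property: every cell gets exactly one phase
  expect_true(all(cc$phase %in% c("G1", "S", "G2M")))
  # positive max -> argmax phase; non-positive -> G1
  expect_true(all(cc$phase[pmax(cc$SScore, cc$G2MScore) <= 0] == "G1"))
  pos <- pmax(cc$SScore, cc$G2MScore) > 0
  expect_true(all(cc$phase[pos & cc$SScore > cc$G2MScore] == "S"))
  expect_true(all(cc$phase[pos & cc$SScore <= cc$G2MScore] == "G2M"))
  # G1 score positive only in G1 cells
  expect_true(all(cc$G1Score[cc$phase != "G1"] == 0))
  expect_true(all(cc$G1Score[cc$phase == "G1"] >= 0))
  # planted phases recovered
  expect_gt(mean(cc$phase == sim$truth$phase[cc$barcode]), 0.9)
})

test_that("bulk G1 combines sample-level z-scores like the cell formula", {
  tpm <- matrix(c(50, 40, 30, 20, 10,
                  5, 4, 3, 3, 1,
                  7, 7, 7, 7, 7), 5, 3,
                dimnames = list(paste0("s", 1:5), c("sg", "gg", "flat")))
  res <- bulk_g1_score(tpm, s_genes = "sg", g2m_genes = "gg")
  z1 <- (tpm[, "sg"] - mean(tpm[, "sg"])) / sd(tpm[, "sg"])
  z2 <- (tpm[, "gg"] - mean(tpm[, "gg"])) / sd(tpm[, "gg"])
  expect_equal(res$G1Score, unname(-(z1 + z2) / 2))
  # the sample lowest in both signatures has the highest bulk G1
  expect_equal(which.max(res$G1Score), 5L)
  # zero-variance signature across samples errors
  expect_error(bulk_g1_score(tpm, s_genes = "flat", g2m_genes = "gg"),
               "variance")
  expect_error(bulk_g1_score(tpm[1, , drop = FALSE], "sg", "gg"), "2 samples")
})
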