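test_that("same config and seed reproduce the dataset exactly", {
  s1 <- simulate_bifurcation(small_config(seed = 42))
  s2 <- simulate_bifurcation(small_config(seed = 42))
  expect_identical(as.matrix(s1$counts$counts), as.matrix(s2$counts$counts))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_bifurcation(small_config(seed = 43))
  expect_false(identical(as.matrix(s1$counts$counts),
                         as.matrix(s3$counts$counts)))
})

test_that("counts are nonnegative integers and metadata is consistent", {
  sim <- simulate_bifurcation(small_config(seed = 3))
  cm <- sim$counts
  expect_true(all(cm$counts@x >= 0))
  expect_true(all(cm$counts@x == round(cm$counts@x)))
  expect_identical(cm$gene_meta$gene, rownames(cm$counts))
  expect_identical(cm$cell_meta$barcode, colnames(cm$counts))
  expect_setequal(unique(cm$cell_meta$time_point), c("T0", "T1", "T2", "T3"))
  # mito genes flagged and named mt-
  expect_true(all(grepl("^mt-", cm$gene_meta$gene[cm$gene_meta$mito])))
  # trunk cells sit before the branch point in latent pseudotime
  pt <- sim$truth$pseudotime
  expect_true(all(pt[sim$truth$lineage == "trunk"] <= sim$truth$branch_point))
})

test_that("zero effect sizes give flat genes with stage-independent means", {
  sim <- simulate_bifurcation(flat_config(seed = 9, cells = 120))
  cm <- sim$counts
  expr <- normalize_log2(cm)
  tp <- cm$cell_meta$time_point
  mean_by_tp <- vapply(c("T0", "T3"), function(t)
    mean(Matrix::colMeans(expr$values[, tp == t])), 0)
  expect_lt(abs(mean_by_tp[1] - mean_by_tp[2]), 0.05)
  expect_length(sim$truth$tps_genes, 10)  # truth still records membership
})

test_that("config validation rejects bad branch points and empty programs", {
  expect_error(small_config(branch_point = 0), "branch_point")
  expect_error(small_config(branch_point = 1.2), "branch_point")
  bad <- list(list(name = "p", n_genes = 0, lineage = "both",
                   direction = "up", lfc_range = c(1, 1)))
  expect_error(simulation_config(program_specs = bad), "empty program")
})

test_that("spliced/unspliced layers obey the steady-state construction", {
  sim <- simulate_bifurcation(small_config(seed = 5))
  cm <- sim$counts
  # exact, noise-free steady state at integer gamma
  cme <- simulate_spliced_unspliced(cm, gamma_true = 2, noise = "none")
  expect_identical(as.matrix(cme$layers$unspliced),
                   2 * as.matrix(cme$layers$spliced))
  # overlapping gene sets rejected
  g <- rownames(cm$counts)[1:5]
  expect_error(simulate_spliced_unspliced(cm, g, g[3:5]), "disjoint")
  # layers are nonnegative integers under Poisson noise
  cmp <- simulate_spliced_unspliced(cm, induced_genes = g, gamma_true = 0.5)
  u <- cmp$layers$unspliced
  expect_true(all(u@x >= 0) && all(u@x == round(u@x)))
})

test_that("CNV planting scales segment means and ratio 1 is the identity", {
  sim <- simulate_bifurcation(flat_config(seed = 11, cells = 100))
  cm <- sim$counts
  spec1 <- list(list(chrom = "1", start_gene = 1, n_genes = 15,
                     copy_ratio = 1, frac_cells = 0.2))
  cm1 <- simulate_cnv_cells(cm, spec1, seed = 2)
  expect_identical(as.matrix(cm1$counts), as.matrix(cm$counts))

  spec2 <- list(list(chrom = "1", start_gene = 1, n_genes = 15,
                     copy_ratio = 2, frac_cells = 0.2),
                list(chrom = "2", start_gene = 1, n_genes = 15,
                     copy_ratio = 3, frac_cells = 0.2))
  cm2 <- simulate_cnv_cells(cm, spec2, seed = 2)
  truth <- attr(cm2, "cnv_truth")
  aff <- truth$malignant_cells
  ref <- setdiff(colnames(cm$counts), aff)
  for (i in 1:2) {
    seg_genes <- truth$segments$genes[[i]]
    ratio <- spec2[[i]]$copy_ratio
    m_aff <- mean(as.matrix(cm2$counts[seg_genes, aff]))
    m_ref <- mean(as.matrix(cm2$counts[seg_genes, ref]))
    expect_lt(abs(m_aff / m_ref - ratio), 0.25 * ratio)
  }
  expect_error(
    simulate_cnv_cells(cm, list(list(chrom = "1", start_gene = 1,
                                     n_genes = 5, copy_ratio = 0,
                                     frac_cells = 0.1))),
    "copy ratio")
})

test_that("junction counts respect degenerate PSI and store the truth", {
  spec <- data.frame(event_id = c("a", "b"), type = c("SE", "RI"),
                     psi = c(1, 0), coverage = 40)
  ev <- simulate_junction_counts(spec, groups = c("A", "B"), seed = 4)
  expect_true(all(ev$E[ev$event_id == "a"] == 0))
  expect_true(all(ev$I[ev$event_id == "b"] == 0))
  expect_equal(attr(ev, "psi_truth")$A, c(a = 1, b = 0))
  # SE effective lengths default to (2, 1)
  expect_true(all(ev$lI[ev$event_id == "a"] == 2))
  expect_true(all(ev$lE[ev$event_id == "a"] == 1))
})

test_that("survival cohort respects censoring extremes and the hazard model", {
  spec <- list(n_patients = 150, baseline_hazard = 0.002, beta = 1.5,
               censoring_rate = 1)
  coh <- simulate_survival_cohort(spec, seed = 6)
  expect_true(all(coh$event == 0))
  spec$censoring_rate <- 0
  coh0 <- simulate_survival_cohort(spec, seed = 6)
  expect_true(all(coh0$event == 1))
  # larger scores die sooner under beta > 0
  hi <- coh0$score > stats::median(coh0$score)
  expect_lt(stats::median(coh0$time_days[hi]),
            stats::median(coh0$time_days[!hi]))
  expect_error(simulate_survival_cohort(list(n_patients = 5,
                                             baseline_hazard = 0.001,
                                             beta = 0, censoring_rate = 0)),
               "10 patients")
})
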