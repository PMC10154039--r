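test_that("ortholog collapse renames, averages and duplicates correctly", {
  expr <- matrix(c(2, 4, 6,
                   4, 8, 12,
                   1, 1, 1), 3, 3, byrow = FALSE,
                 dimnames = list(c("s1", "s2", "s3"),
                                 c("HGA", "HGB", "HGC")))
  # identity-style 1:1 map leaves values unchanged
  map11 <- data.frame(human = c("HGA", "HGB", "HGC"),
                      mouse = c("Mga", "Mgb", "Mgc"))
  out11 <- collapse_orthologs(expr, map11, "mouse")
  expect_equal(unname(out11), unname(expr), ignore_attr = TRUE)
  expect_identical(colnames(out11), c("Mga", "Mgb", "Mgc"))
  # many:1 collapses by the mean
  map21 <- data.frame(human = c("HGA", "HGB"), mouse = c("Mg", "Mg"))
  out21 <- collapse_orthologs(expr, map21, "mouse")
  expect_equal(out21[, "Mg"], rowMeans(expr[, c("HGA", "HGB")]))
  expect_equal(attr(out21, "n_dropped"), 1L)
  # 1:many duplicates
  map12 <- data.frame(human = c("HGA", "HGA"), mouse = c("Mg1", "Mg2"))
  out12 <- collapse_orthologs(expr, map12, "mouse")
  expect_equal(out12[, "Mg1"], out12[, "Mg2"])
  expect_error(collapse_orthologs(expr, map11[0, ], "mouse"), "empty")
  expect_error(collapse_orthologs(
    expr, data.frame(human = "ZZ", mouse = "Mz"), "mouse"), "overlap")
})

test_that("cross-species matching recovers identity and permutations", {
  set.seed(41)
  g <- 60
  centroids <- matrix(rnorm(4 * g, 5, 2), 4, g,
                      dimnames = list(c("HSPC", "GMP", "GMPlike", "Mono"),
                                      sprintf("g%02d", 1:g)))
  # identical sets: diagonal correlation 1, namesake best matches
  res <- cross_species_cluster(centroids, centroids,
                               species = c("mmu", "hsa"))
  expect_true(all(res$best_match$correlation == 1))
  expect_identical(sub("hsa:", "", res$best_match$best_match[1:4]),
                   rownames(centroids))
  # small noise keeps all best matches correct
  noisy <- centroids + rnorm(length(centroids), 0, 0.1)
  res2 <- cross_species_cluster(centroids, noisy, c("mmu", "hsa"))
  expect_identical(sub("^(mmu|hsa):", "", res2$best_match$best_match),
                   rep(rownames(centroids), 2))
  # permuted subtype labels are recovered
  perm <- c(3, 1, 4, 2)
  permuted <- noisy[perm, ]
  rownames(permuted) <- paste0("sub", 1:4)
  res3 <- cross_species_cluster(centroids, permuted, c("mmu", "hsa"))
  got <- sub("hsa:", "", res3$best_match$best_match[1:4])
  expect_identical(got, paste0("sub", order(perm)))
  # constant rows are named in the error
  bad <- centroids
  bad["GMP", ] <- 1
  expect_error(cross_species_cluster(bad, noisy), "GMP")
})

test_that("DEG signatures honour the fold-change and p thresholds", {
  set.seed(43)
  n <- 10
  g <- 300
  counts <- matrix(rnbinom(n * g, mu = 50, size = 10), n, g,
                   dimnames = list(sprintf("s%d", 1:n),
                                   sprintf("g%03d", 1:g)))
  groups <- rep(c("normal", "case"), each = 5)
  # identical groups: empty signature
  sig0 <- deg_signature(counts, groups, lfc_cutoff = 1, case = "case")
  expect_length(sig0$genes, 0)
  # one planted 16-fold gene passes log2FC > 3, nulls do not
  counts2 <- counts
  counts2[groups == "case", "g001"] <- rnbinom(5, mu = 1600, size = 10)
  counts2[groups == "normal", "g001"] <- rnbinom(5, mu = 100, size = 10)
  sig <- deg_signature(counts2, groups, lfc_cutoff = 3, case = "case")
  expect_identical(sig$genes, "g001")
  expect_error(deg_signature(counts[1:3, ], c("a", "a", "b"), 1), "2 samples")
})

test_that("survival cutpoint maximises separation within minprop bounds", {
  # two perfectly separated score groups: simultaneous early events
  # below, censored late observations above; the cutpoint must fall
  # between the ranges
  coh <- data.frame(
    patient_id = sprintf("p%02d", 1:20),
    time_days = c(rep(10, 10), rep(1000, 10)),
    event = c(rep(1, 10), rep(0, 10)),
    score = c(seq(5, 6, length.out = 10), seq(9, 10, length.out = 10)))
  cut <- survival_cutpoint(coh, minprop = 0.1)
  expect_gt(cut$cutpoint, 6)
  expect_lt(cut$cutpoint, 9)
  # brute force over every admissible split agrees on the maximum
  brute <- max(cut$candidates$chisq)
  expect_equal(cut$statistic, brute)
  # minprop = 0.5 with even n leaves only the median split
  cut2 <- survival_cutpoint(coh, minprop = 0.5)
  expect_equal(nrow(cut2$candidates), 1)
  expect_equal(cut2$cutpoint, (6 + 9) / 2)
  expect_error(survival_cutpoint(transform(coh, score = 1)), "equal")
})

test_that("log-rank matches a hand-computed risk table and is null-calibrated", {
  # duplicated cohort: statistic 0, p 1
  coh <- data.frame(time_days = c(5, 8, 12, 20), event = c(1, 1, 0, 1))
  dup <- rbind(coh, coh)
  lr0 <- logrank_test(dup, rep(c("a", "b"), each = 4))
  expect_lt(lr0$chisq, 1e-10)
  expect_equal(lr0$p, 1, tolerance = 1e-6)

  # 6-patient toy: independent risk-table computation
  toy <- data.frame(time_days = c(1, 2, 3, 4, 5, 6),
                    event = c(1, 1, 1, 1, 0, 1),
                    group = c("a", "b", "a", "b", "a", "b"))
  obs_exp <- local({
    o_a <- 0; e_a <- 0; v <- 0
    for (t in sort(unique(toy$time_days[toy$event == 1]))) {
      at_risk <- toy$time_days >= t
      d <- sum(toy$time_days == t & toy$event == 1)
      n <- sum(at_risk)
      n_a <- sum(at_risk & toy$group == "a")
      o_a <- o_a + sum(toy$time_days == t & toy$event == 1 &
                         toy$group == "a")
      e_a <- e_a + d * n_a / n
      if (n > 1)
        v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
    }
    (o_a - e_a)^2 / v
  })
  lr <- logrank_test(toy[, 1:2], toy$group)
  expect_equal(lr$chisq, obs_exp, tolerance = 1e-8)
  expect_equal(lr$p, pchisq(obs_exp, 1, lower.tail = FALSE))
  expect_error(logrank_test(toy[, 1:2], rep("a", 6)), "two non-empty")

  # null calibration: rejection rate near 5%
  set.seed(47)
  rej <- replicate(300, {
    ch <- simulate_survival_cohort(
      list(n_patients = 100, baseline_hazard = 0.002, beta = 0,
           censoring_rate = 0.3), seed = sample.int(2^30, 1))
    logrank_test(ch, rep(c("x", "y"), 50))$p < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("Kaplan-Meier estimate matches the hand-computed product", {
  # 4 patients: events at 2 and 6, censor at 4, event at 9
  coh <- data.frame(time_days = c(2, 4, 6, 9), event = c(1, 0, 1, 1))
  km <- km_estimate(coh)
  # S(2) = 3/4; S(6) = 3/4 * 1/2 = 3/8; S(9) = 0
  expect_equal(km$surv[km$time == 0], 1)
  expect_equal(km$surv[km$time == 2], 3 / 4)
  expect_equal(km$surv[km$time == 6], 3 / 8)
  expect_equal(km$surv[km$time == 9], 0)
  expect_true(all(diff(km$surv) <= 1e-12))
  # no events: survival stays at 1
  none <- data.frame(time_days = c(3, 7), event = c(0, 0))
  expect_true(all(km_estimate(none)$surv == 1))
  # single patient with an event drops to 0
  one <- km_estimate(data.frame(time_days = 5, event = 1))
  expect_equal(one$surv[one$time == 5], 0)
  # no censoring: KM equals the empirical survival function
  ec <- data.frame(time_days = c(1, 2, 3, 4), event = 1)
  kme <- km_estimate(ec)
  expect_equal(kme$surv[-1], c(3, 2, 1, 0) / 4)
  expect_error(km_estimate(data.frame(time_days = numeric(0),
                                      event = integer(0))), "empty")
})
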