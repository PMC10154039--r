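#' Pipeline configuration
#'
#' Central place for every stage's parameters and toggles. Accepts a
#' nested list (or a YAML/JSON file path) and fills in defaults; unknown
#' stage names are rejected.
#'
#' @param config list or path to a YAML/JSON file; `NULL` gives the
#'   default configuration.
#' @param seed integer seed propagated to every stochastic stage.
#' @return a validated `PipelineConfig` list.
#' @export
pipeline_config <- function(config = NULL, seed = 1L) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs needs the yaml package")
      yaml::read_yaml(config)
    }
  }
  defaults <- list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, qc = TRUE, scoring = TRUE,
                  trajectory = TRUE, velocity = TRUE, cnv = TRUE,
                  splicing = TRUE, cohort = TRUE),
    qc = list(min_genes = 200, max_genes = 6000, max_mito = 0.10,
              min_cells = 5, scale = 1e4),
    scoring = list(nbin = 28, nctrl = 100),
    trajectory = list(q_threshold = 0.05, df = 5, n_points = 300),
    velocity = list(quantile = 0.02, k = 30, n_induced = 50,
                    gamma_true = 0.5),
    cnv = list(w = 101, clip = 3, margin = 1.5),
    splicing = list(n_events = 500, coverage = 50, dpsi = 0.3,
                    frac_differential = 0.1, q_threshold = 0.05,
                    dpsi_threshold = 0.1),
    cohort = list(minprop = 0.1))
  cfg <- utils::modifyList(defaults, if (is.null(config)) list() else config)
  bad <- setdiff(names(cfg$stages), names(defaults$stages))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "PipelineConfig")
}

#' CNV-focused companion configuration
#'
#' A patient-style dataset for malignant-cell calling: same gene universe,
#' depth and dispersion as the base configuration, 500 cells, but no
#' planted expression programs or cell-cycle structure, so inferred-CNV
#' profiles reflect copy number alone.
#'
#' @param base a [simulation_config()] supplying gene count, depth and
#'   dispersion.
#' @param seed integer seed.
#' @param n_cells total cells (default 500).
#' @return a `SimulationConfig`.
#' @export
cnv_simulation_config <- function(base = simulation_config(), seed = 1L,
                                  n_cells = 500) {
  flat <- lapply(base$program_specs, function(p) {
    p$lfc_range <- c(0, 0)
    p
  })
  simulation_config(
    n_genes = base$n_genes,
    n_cells_per_stage = c(T0 = n_cells),
    n_samples_per_stage = 1,
    branch_point = base$branch_point,
    program_specs = flat,
    cc_spec = list(n_s_genes = 0, n_g2m_genes = 0, frac_s = 0,
                   frac_g2m = 0, effect = 0),
    nb_dispersion = base$nb_dispersion,
    library_size_mean = base$library_size_mean,
    library_size_sdlog = base$library_size_sdlog,
    mito_frac = base$mito_frac,
    cnv_spec = base$cnv_spec,
    survival_spec = base$survival_spec,
    seed = seed)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Simulates a bifurcating leukemogenesis time course and pushes it
#' through QC, signature and cell-cycle scoring, trajectory and
#' tipping-point extraction, RNA velocity, CNV-based malignant calling,
#' differential splicing and survival stratification, collecting one
#' structured report. Stages run in dependency order; turning a stage off
#' removes its block from the report. When `out_dir` is given, stage
#' artifacts are written as TSV and the report as JSON.
#'
#' @param config a [pipeline_config()] (or list / file path coerced to
#'   one).
#' @param out_dir optional output directory for artifacts.
#' @param sim_config optional [simulation_config()] overriding the default
#'   synthetic dataset (its seed is taken from the pipeline config).
#' @return the report list, invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         sim_config = NULL) {
  if (!inherits(config, "PipelineConfig")) config <- pipeline_config(config)
  report <- list(seed = config$seed, parameters = config[
    setdiff(names(config), c("stages", "seed"))])
  on_stage <- function(nm) isTRUE(config$stages[[nm]])
  stage <- "simulate"
  result <- tryCatch({
    # --- simulate -------------------------------------------------------
    if (is.null(sim_config))
      sim_config <- simulation_config(seed = config$seed)
    sim <- simulate_bifurcation(sim_config)
    cm <- sim$counts
    truth <- sim$truth
    report$simulate <- list(n_genes = nrow(cm$counts),
                            n_cells = ncol(cm$counts),
                            n_tps_genes = length(truth$tps_genes))

    # --- qc -------------------------------------------------------------
    stage <- "qc"
    if (on_stage("qc")) {
      qc <- filter_cells_genes(cm, config$qc$min_genes, config$qc$max_genes,
                               config$qc$max_mito, config$qc$min_cells)
      cm <- qc$counts
      report$qc <- as.list(qc$report)
    }
    expr <- normalize_log2(cm, config$qc$scale)

    # --- scoring --------------------------------------------------------
    stage <- "scoring"
    if (on_stage("scoring")) {
      sc_cfg <- scoring_config(config$scoring$nbin, config$scoring$nctrl,
                               seed = config$seed)
      sf_genes <- truth$programs$gene[
        truth$programs$program == "splicing_factor"]
      sf_genes <- intersect(sf_genes, rownames(expr$values))
      sf_block <- NULL
      if (length(sf_genes)) {
        sf_score <- signature_score(expr, gene_signature("splicing_factor",
                                                         sf_genes))
        sf_trend <- tapply(sf_score, expr$cell_meta$time_point, mean)
        sf_block <- as.list(sf_trend)
      }
      cc <- NULL
      if (length(truth$s_genes) && length(truth$g2m_genes)) {
        cc <- cell_cycle_scores(expr,
                                gene_signature("S", truth$s_genes),
                                gene_signature("G2M", truth$g2m_genes),
                                sc_cfg)
        phase_acc <- mean(cc$phase == truth$phase[cc$barcode])
      } else phase_acc <- NA
      report$scoring <- list(splicing_factor_trend = sf_block,
                             phase_accuracy = phase_acc)
    }

    # --- trajectory / TPS ----------------------------------------------
    stage <- "trajectory"
    if (on_stage("trajectory")) {
      emb <- as.matrix(cm$cell_meta[, c("dim1", "dim2")])
      rownames(emb) <- cm$cell_meta$barcode
      fit <- fit_lineage_curve(emb, cm$cell_meta$cluster,
                               truth$root_cluster,
                               truth$terminal_clusters,
                               n_points = config$trajectory$n_points)
      dg_d <- pseudotime_dynamic_genes(expr, fit, "differentiation",
                                       df = config$trajectory$df,
                                       q_threshold = config$trajectory$q_threshold)
      dg_t <- pseudotime_dynamic_genes(expr, fit, "transformation",
                                       df = config$trajectory$df,
                                       q_threshold = config$trajectory$q_threshold)
      sets <- classify_gene_sets(dg_d, dg_t, config$trajectory$q_threshold)
      tps <- tipping_point_signature(sets)
      tp_truth <- intersect(truth$tps_genes, rownames(expr$values))
      report$trajectory <- list(
        tps_genes = tps$genes,
        set_sizes = lengths(sets[c("set1", "set2", "set3", "set4")]),
        tps_sensitivity = if (length(tp_truth))
          mean(tp_truth %in% tps$genes) else NA,
        tps_fdr = if (length(tps$genes))
          mean(!tps$genes %in% tp_truth) else 0)
    } else fit <- NULL

    # --- velocity -------------------------------------------------------
    stage <- "velocity"
    if (on_stage("velocity")) {
      tot <- Matrix::rowSums(cm$counts)
      cand <- setdiff(rownames(cm$counts),
                      c(truth$programs$gene, truth$s_genes, truth$g2m_genes))
      vg <- cand[order(-tot[cand])][seq_len(config$velocity$n_induced)]
      set.seed(config$seed + 1L)
      cmv <- simulate_spliced_unspliced(cm, induced_genes = vg,
                                        gamma_true = config$velocity$gamma_true)
      model <- fit_velocity(cmv, quantile = config$velocity$quantile)
      induced_fit <- intersect(vg, names(model$gamma))
      sign_rec <- mean(model$residuals[induced_fit, , drop = FALSE] > 0)
      report$velocity <- list(n_genes_fit = length(model$gamma),
                              induced_positive_rate = sign_rec)
    }

    # --- cnv ------------------------------------------------------------
    stage <- "cnv"
    if (on_stage("cnv")) {
      # malignant-cell calling targets its own patient-style dataset, a
      # mixture of CNV-bearing and normal cells without lineage programs
      cnv_sim <- simulate_bifurcation(cnv_simulation_config(
        base = sim_config, seed = config$seed + 2L))
      cm_cnv <- simulate_cnv_cells(cnv_sim$counts, sim_config$cnv_spec,
                                   seed = config$seed + 2L)
      cnv_truth <- attr(cm_cnv, "cnv_truth")
      expr_cnv <- normalize_log2(cm_cnv, config$qc$scale)
      ref <- setdiff(colnames(cm_cnv$counts), cnv_truth$malignant_cells)
      prof <- infer_cnv_profile(expr_cnv, cm_cnv$gene_meta, ref,
                                w = config$cnv$w, clip = config$cnv$clip)
      calls <- call_malignant(prof, margin = config$cnv$margin)
      truth_mal <- calls$barcode %in% cnv_truth$malignant_cells
      report$cnv <- list(
        confusion = as.list(table(called = calls$malignant,
                                  truth = truth_mal) |> as.vector() |>
                              stats::setNames(c("tn", "fp", "fn", "tp"))),
        sensitivity = if (any(truth_mal))
          mean(calls$malignant[truth_mal]) else NA,
        specificity = mean(!calls$malignant[!truth_mal]))
    }

    # --- splicing -------------------------------------------------------
    stage <- "splicing"
    if (on_stage("splicing")) {
      sp <- config$splicing
      n_ev <- sp$n_events
      types <- sample(c("SE", "A3SS", "A5SS", "RI", "MXE"), n_ev,
                      replace = TRUE, prob = c(0.6, 0.1, 0.1, 0.1, 0.1))
      psi <- stats::runif(n_ev, 0.2, 0.8)
      n_diff <- round(sp$frac_differential * n_ev)
      psi_b <- psi
      psi_b[seq_len(n_diff)] <- pmin(1, psi[seq_len(n_diff)] + sp$dpsi)
      spec <- data.frame(event_id = sprintf("ev%04d", seq_len(n_ev)),
                         type = types, psi_A = psi, psi_B = psi_b,
                         coverage = sp$coverage)
      ev <- simulate_junction_counts(spec, groups = c("A", "B"),
                                     seed = config$seed + 3L)
      res <- differential_psi(ev[ev$group == "A", ], ev[ev$group == "B", ])
      counts_by_type <- count_event_types(res, sp$q_threshold,
                                          sp$dpsi_threshold)
      truly_diff <- res$event_id %in% spec$event_id[seq_len(n_diff)]
      sig <- !is.na(res$q) & res$q < sp$q_threshold
      report$splicing <- list(
        table = res[sig, ],
        events_per_type = as.list(counts_by_type),
        differential_sensitivity = mean(sig[truly_diff]))
    }

    # --- cohort ---------------------------------------------------------
    stage <- "cohort"
    if (on_stage("cohort")) {
      scores <- stats::rnorm(sim_config$survival_spec$n_patients)
      coh <- simulate_survival_cohort(sim_config$survival_spec, scores,
                                      seed = config$seed + 4L)
      cut <- survival_cutpoint(coh, minprop = config$cohort$minprop)
      groups <- ifelse(coh$score > cut$cutpoint, "high", "low")
      lr <- logrank_test(coh, groups)
      med <- stats::median(coh$score)
      lr_med <- logrank_test(coh, ifelse(coh$score > med, "high", "low"))
      report$cohort <- list(
        cutpoint = cut$cutpoint,
        logrank_p_cutpoint = lr$p,
        logrank_p_cutpoint_note = paste(
          "exploratory: the cutpoint was selected to maximise group",
          "separation, which inflates the naive log-rank p-value"),
        logrank_p_median_split = lr_med$p)
    }
    report
  }, error = function(e) {
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(result, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    if (!is.null(result$splicing))
      write_tsv(result$splicing$table,
                file.path(out_dir, "differential_splicing.tsv"))
    if (!is.null(result$trajectory))
      write_tsv(data.frame(gene = result$trajectory$tps_genes),
                file.path(out_dir, "tps_genes.tsv"))
    return(invisible(result))
  }
  result
}
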