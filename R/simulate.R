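#' Configuration for the bifurcating-trajectory simulator
#'
#' Describes a stepwise-leukemogenesis experiment: bone-marrow samples at
#' consecutive time points (T0 = pre-leukemic through T3 = overt leukemia),
#' in which a progenitor population splits at a branch point into a normal
#' differentiation lineage and a transformation lineage. Gene programs are
#' planted as monotone log-linear trends along a lineage; a tipping-point
#' program is planted by listing the same genes as falling along the
#' differentiation lineage and rising along the transformation lineage.
#'
#' @param n_genes total gene count.
#' @param n_cells_per_stage named integer vector of cells per time point;
#'   names become the time-point labels.
#' @param n_samples_per_stage replicate samples per time point.
#' @param branch_point pseudotime fraction in (0,1) where the lineages split.
#' @param program_specs list of program definitions, each a list with
#'   `name`, `n_genes` (or explicit `genes`), `lineage` (one of
#'   `"differentiation"`, `"transformation"`, `"both"`), `direction`
#'   (`"up"`/`"down"`) and `lfc_range`, a length-2 log2 fold-change range
#'   from which per-gene effects are drawn (equal endpoints give a fixed
#'   effect). Programs on a specific lineage ramp up only after the branch
#'   point, so the two lineages share identical means along the trunk.
#' @param cc_spec cell-cycle plant: list with `n_s_genes`, `n_g2m_genes`,
#'   `frac_s`, `frac_g2m`, `effect` (log2 shift in cycling cells).
#' @param nb_dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`), shared across genes.
#' @param library_size_mean,library_size_sdlog per-cell library sizes are
#'   drawn log-normal with this mean and sdlog.
#' @param mito_frac fraction of genes labelled mitochondrial (`mt-` prefix).
#' @param trend shape of planted trends along pseudotime: `"linear"`
#'   (log-linear in the mean) or `"sigmoid"`.
#' @param cnv_spec list of CNV segments, each a list with `chrom`,
#'   `start_gene` (index within the chromosome's gene list), `n_genes`,
#'   `copy_ratio` (> 0) and `frac_cells`.
#' @param splice_spec data.frame of alternative-splicing events
#'   (`event_id`, `type`, `psi`, `coverage`), see
#'   [simulate_junction_counts()].
#' @param survival_spec list with `n_patients`, `baseline_hazard` (events
#'   per day), `beta` (log hazard ratio per score unit), `censoring_rate`.
#' @param seed integer seed; the same config and seed reproduce the same
#'   dataset byte for byte.
#' @return a validated `SimulationConfig` list.
#' @export
simulation_config <- function(
    n_genes = 2000,
    n_cells_per_stage = c(T0 = 375, T1 = 375, T2 = 375, T3 = 375),
    n_samples_per_stage = 2,
    branch_point = 0.35,
    program_specs = default_programs(),
    cc_spec = list(n_s_genes = 40, n_g2m_genes = 40,
                   frac_s = 0.2, frac_g2m = 0.2, effect = 1.5),
    nb_dispersion = 0.1,
    library_size_mean = 10000,
    library_size_sdlog = 0.25,
    mito_frac = 0.02,
    trend = c("linear", "sigmoid"),
    cnv_spec = list(list(chrom = "1", start_gene = 1, n_genes = 100,
                         copy_ratio = 2, frac_cells = 0.1)),
    splice_spec = NULL,
    survival_spec = list(n_patients = 200, baseline_hazard = 0.002,
                         beta = 1, censoring_rate = 0.3),
    seed = 1L) {
  trend <- match.arg(trend)
  if (!(branch_point > 0 && branch_point < 1))
    stop("branch_point must lie strictly inside (0, 1)")
  if (n_genes < 1 || any(n_cells_per_stage < 1))
    stop("gene and cell counts must be positive")
  for (p in program_specs) {
    if (is.null(p$genes) && (is.null(p$n_genes) || p$n_genes < 1))
      stop("empty program: ", p$name)
    stopifnot(p$lineage %in% c("differentiation", "transformation", "both"),
              p$direction %in% c("up", "down"),
              length(p$lfc_range) == 2, all(p$lfc_range >= 0))
  }
  for (s in cnv_spec) if (s$copy_ratio <= 0) stop("copy ratio must be > 0")
  if (!is.null(survival_spec) && survival_spec$baseline_hazard < 0)
    stop("baseline hazard must be nonnegative")
  structure(list(
    n_genes = n_genes, n_cells_per_stage = n_cells_per_stage,
    n_samples_per_stage = n_samples_per_stage, branch_point = branch_point,
    program_specs = program_specs, cc_spec = cc_spec,
    nb_dispersion = nb_dispersion, library_size_mean = library_size_mean,
    library_size_sdlog = library_size_sdlog, mito_frac = mito_frac,
    trend = trend, cnv_spec = cnv_spec, splice_spec = splice_spec,
    survival_spec = survival_spec, seed = as.integer(seed)),
    class = "SimulationConfig")
}

#' Default planted gene programs
#'
#' Four programs covering the structure the analysis stages look for: a
#' 40-gene tipping-point program (down along differentiation, up along
#' transformation, fixed 4-fold range), maturation genes rising along the
#' differentiation lineage, genes silenced along the transformation
#' lineage, and a splicing-factor program rising with time in every cell.
#'
#' @return a list of program specifications for [simulation_config()].
#' @export
default_programs <- function() {
  list(
    list(name = "tps", n_genes = 40, lineage = "differentiation",
         direction = "down", lfc_range = c(2, 2), shared_with = "tps"),
    list(name = "tps", n_genes = 40, lineage = "transformation",
         direction = "up", lfc_range = c(2, 2), shared_with = "tps"),
    list(name = "maturation", n_genes = 60, lineage = "differentiation",
         direction = "up", lfc_range = c(1.5, 2.5)),
    list(name = "stemness_loss", n_genes = 60, lineage = "transformation",
         direction = "down", lfc_range = c(1.5, 2.5)),
    list(name = "splicing_factor", n_genes = 50, lineage = "both",
         direction = "up", lfc_range = c(1.5, 1.5))
  )
}

ramp_after <- function(pt, from) pmax(0, (pt - from) / (1 - from))

#' Simulate a bifurcating single-cell time course
#'
#' Draws latent pseudotime and lineage for every cell, builds per-cell gene
#' means from the planted programs (identical means on the shared trunk, so
#' the bifurcation is identifiable only after the branch), samples UMI
#' counts from a negative binomial, and attaches a Y-shaped 2-D embedding,
#' cluster labels, time point, sample and reporter status to the cell
#' metadata. Everything needed to score downstream stages is returned in
#' the ground-truth record.
#'
#' @param config a [simulation_config()].
#' @return a list with `counts` (a `CountMatrix`) and `truth` (latent
#'   pseudotime, lineage, planted program table, tipping-gene set, true
#'   cell-cycle phase, cluster/root/terminal labels).
#' @export
simulate_bifurcation <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  G <- config$n_genes
  stages <- names(config$n_cells_per_stage)
  K <- length(stages)
  n_cells <- sum(config$n_cells_per_stage)

  genes <- sprintf("gene%04d", seq_len(G))
  n_mt <- round(config$mito_frac * G)
  if (n_mt > 0) {
    mt_idx <- (G - n_mt + 1):G
    genes[mt_idx] <- sprintf("mt-gene%04d", mt_idx)
  } else mt_idx <- integer(0)
  # genes laid on 19 autosomes in blocks, ordered by index
  chrom <- as.character(rep_len(rep(1:19, each = ceiling(G / 19)), G))
  chrom <- chrom[order(as.integer(chrom))]
  start <- stats::ave(seq_len(G), chrom, FUN = seq_along) * 10000L
  gene_meta <- data.frame(gene = genes, chrom = chrom, start = start,
                          strand = "+", mito = seq_len(G) %in% mt_idx)

  # --- latent cell state ------------------------------------------------
  stage <- rep(stages, config$n_cells_per_stage)
  stage_idx <- rep(seq_len(K), config$n_cells_per_stage) - 1L
  pt <- stats::runif(n_cells, stage_idx / K, (stage_idx + 1) / K)
  bp <- config$branch_point
  lineage <- ifelse(pt <= bp, "trunk",
                    sample(c("differentiation", "transformation"),
                           n_cells, replace = TRUE))
  barcodes <- sprintf("cell%05d", seq_len(n_cells))
  sample_id <- paste0(stage, "_rep",
                      sample.int(config$n_samples_per_stage, n_cells,
                                 replace = TRUE))

  # --- planted programs -------------------------------------------------
  free <- setdiff(seq_len(G), mt_idx)
  assigned <- list()
  programs <- list()
  for (p in config$program_specs) {
    key <- if (!is.null(p$shared_with)) p$shared_with else p$name
    if (!is.null(p$genes)) {
      idx <- match(p$genes, genes)
    } else if (!is.null(assigned[[key]]) && !is.null(p$shared_with)) {
      idx <- assigned[[key]]
    } else {
      # scatter program genes across the genome, as real programs are
      idx <- sort(sample(free, p$n_genes))
      free <- setdiff(free, idx)
      assigned[[key]] <- idx
    }
    eff <- stats::runif(length(idx), p$lfc_range[1], p$lfc_range[2])
    programs[[length(programs) + 1L]] <- data.frame(
      program = p$name, gene = genes[idx], gene_idx = idx,
      lineage = p$lineage, direction = p$direction,
      lfc = eff * ifelse(p$direction == "up", 1, -1))
  }
  program_tab <- do.call(rbind, programs)

  cc <- config$cc_spec
  s_idx <- g2m_idx <- integer(0)
  phase <- rep("G1", n_cells)
  if (!is.null(cc) && (cc$n_s_genes > 0 || cc$n_g2m_genes > 0)) {
    s_idx <- sort(sample(free, cc$n_s_genes))
    free <- setdiff(free, s_idx)
    g2m_idx <- sort(sample(free, cc$n_g2m_genes))
    free <- setdiff(free, g2m_idx)
    phase <- sample(c("G1", "S", "G2M"), n_cells, replace = TRUE,
                    prob = c(1 - cc$frac_s - cc$frac_g2m, cc$frac_s,
                             cc$frac_g2m))
  }

  # --- per-cell log2 shifts --------------------------------------------
  delta <- matrix(0, G, n_cells)
  shape <- if (config$trend == "linear") identity else
    function(x) stats::plogis(10 * (x - 0.5))
  for (i in seq_len(nrow(program_tab))) {
    g <- program_tab$gene_idx[i]
    lin <- program_tab$lineage[i]
    r <- if (lin == "both") shape(pt)
         else shape(ramp_after(pt, bp)) *
              (lineage == lin | lineage == "trunk")
    delta[g, ] <- delta[g, ] + program_tab$lfc[i] * r
  }
  # cycle markers are phase-specific: at +effect in their phase and
  # repressed (-effect) outside it, as for canonical markers (Mki67, Ccnb1)
  if (length(s_idx))
    delta[s_idx, ] <- delta[s_idx, ] +
      cc$effect * rep(ifelse(phase == "S", 1, -1), each = length(s_idx))
  if (length(g2m_idx))
    delta[g2m_idx, ] <- delta[g2m_idx, ] +
      cc$effect * rep(ifelse(phase == "G2M", 1, -1), each = length(g2m_idx))

  # --- counts -----------------------------------------------------------
  base <- stats::rlnorm(G, meanlog = 0, sdlog = 1)
  rel <- base * 2^delta
  rel <- sweep(rel, 2, colSums(rel), "/")
  libsize <- stats::rlnorm(n_cells, log(config$library_size_mean) -
                             config$library_size_sdlog^2 / 2,
                           config$library_size_sdlog)
  mu <- sweep(rel, 2, libsize, "*")
  size <- 1 / config$nb_dispersion
  cnt <- matrix(stats::rnbinom(G * n_cells, mu = mu, size = size),
                G, n_cells, dimnames = list(genes, barcodes))

  # --- embedding: Y-shaped layout from latent state ---------------------
  ang <- ifelse(lineage == "differentiation", pi / 6,
                ifelse(lineage == "transformation", -pi / 6, 0))
  r_trunk <- pmin(pt, bp) * 10
  r_arm <- pmax(pt - bp, 0) * 10
  emb <- cbind(dim1 = r_trunk + r_arm * cos(ang) + stats::rnorm(n_cells, 0, 0.25),
               dim2 = r_arm * sin(ang) + stats::rnorm(n_cells, 0, 0.25))

  # clusters: trunk split in 2 bins, each arm in 3 bins along pseudotime
  cl <- character(n_cells)
  trunkish <- lineage == "trunk"
  cl[trunkish] <- paste0("trunk", 1L + (pt[trunkish] > bp / 2))
  for (lin in c("differentiation", "transformation")) {
    sel <- lineage == lin
    if (any(sel))
      cl[sel] <- paste0(substr(lin, 1, 5),
                        cut(pt[sel], seq(bp, 1, length.out = 4),
                            labels = FALSE, include.lowest = TRUE))
  }

  cell_meta <- data.frame(barcode = barcodes, sample = sample_id,
                          time_point = stage,
                          reporter = lineage == "transformation",
                          cluster = cl, dim1 = emb[, 1], dim2 = emb[, 2])
  cm <- count_matrix(cnt, gene_meta, cell_meta)
  truth <- list(
    pseudotime = stats::setNames(pt, barcodes),
    lineage = stats::setNames(lineage, barcodes),
    phase = stats::setNames(phase, barcodes),
    programs = program_tab[, setdiff(names(program_tab), "gene_idx")],
    tps_genes = intersect(
      program_tab$gene[program_tab$lineage == "differentiation" &
                         program_tab$direction == "down"],
      program_tab$gene[program_tab$lineage == "transformation" &
                         program_tab$direction == "up"]),
    s_genes = genes[s_idx], g2m_genes = genes[g2m_idx],
    root_cluster = "trunk1",
    terminal_clusters = c(differentiation = "diffe3",
                          transformation = "trans3"),
    branch_point = bp, seed = config$seed)
  list(counts = cm, truth = truth)
}

#' Add spliced/unspliced layers under the steady-state kinetic model
#'
#' The existing counts become the spliced layer; unspliced counts are drawn
#' so that genes at steady state satisfy `E[u] = gamma * E[s]`, induced
#' genes exceed that ratio and repressed genes fall below it.
#'
#' @param cm a `CountMatrix`.
#' @param induced_genes,repressed_genes disjoint gene-id sets.
#' @param gamma_true per-gene steady-state ratio; a single value is
#'   recycled.
#' @param induction_factor,repression_factor multiplicative offsets from
#'   steady state applied to induced / repressed genes.
#' @param steady_tail for induced/repressed genes, the fraction of cells
#'   with the highest spliced abundance that have already reached the new
#'   steady state (their unspliced mean stays at `gamma * s`); this is the
#'   kinetic lag the extreme-quantile gamma fit relies on.
#' @param noise `"poisson"` draws `u ~ Poisson(gamma * f * s)`; `"none"`
#'   sets `u = round(gamma * f * s)` exactly.
#' @return the `CountMatrix` with `spliced` and `unspliced` layers and a
#'   `velocity_truth` attribute recording gamma and the gene classes.
#' @export
simulate_spliced_unspliced <- function(cm, induced_genes = character(0),
                                       repressed_genes = character(0),
                                       gamma_true = 0.5,
                                       induction_factor = 3,
                                       repression_factor = 0.3,
                                       steady_tail = 0.02,
                                       noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  if (length(intersect(induced_genes, repressed_genes)))
    stop("induced and repressed gene sets must be disjoint")
  genes <- rownames(cm$counts)
  stopifnot(all(induced_genes %in% genes), all(repressed_genes %in% genes))
  gamma <- rep_len(gamma_true, length(genes))
  names(gamma) <- genes
  s <- as.matrix(cm$counts)
  # kinetic state depends on relative abundance, not sequencing depth
  lib <- pmax(colSums(s), 1)
  s_rel <- sweep(s, 2, stats::median(lib) / lib, "*")
  f <- matrix(1, nrow(s), ncol(s), dimnames = dimnames(s))
  for (g in c(induced_genes, repressed_genes)) {
    fac <- if (g %in% induced_genes) induction_factor else repression_factor
    # cells above the upper spliced quantile have settled at steady state
    thr <- stats::quantile(s_rel[g, ], 1 - steady_tail)
    f[g, s_rel[g, ] < thr] <- fac
  }
  mu_u <- s * gamma * f
  u <- if (noise == "poisson")
    matrix(stats::rpois(length(mu_u), mu_u), nrow(s), ncol(s)) else
    round(mu_u)
  dimnames(u) <- dimnames(s)
  cm$layers$spliced <- cm$counts
  cm$layers$unspliced <- as_dgc(u)
  attr(cm, "velocity_truth") <- list(
    gamma = gamma, induced = induced_genes, repressed = repressed_genes)
  cm
}

#' Plant copy-number segments into a count matrix
#'
#' For each CNV segment, the counts of the segment's genes are rescaled by
#' the copy ratio in a random subset of cells and re-sampled from a Poisson
#' with that rescaled mean. A copy ratio of exactly 1 leaves the matrix
#' untouched.
#'
#' @param cm a `CountMatrix` whose `gene_meta` has `chrom` and `start`.
#' @param cnv_spec list of segments as in [simulation_config()].
#' @param seed integer seed.
#' @param cells optional explicit barcode set to affect (overrides
#'   `frac_cells`; the same cells get every segment).
#' @return the modified `CountMatrix`; the affected barcodes and segment
#'   table are stored in the `cnv_truth` attribute.
#' @export
simulate_cnv_cells <- function(cm, cnv_spec, seed = 1L, cells = NULL) {
  set.seed(seed)
  gm <- cm$gene_meta
  cnt <- as.matrix(cm$counts)
  if (is.null(cells)) {
    n_aff <- round(cnv_spec[[1]]$frac_cells * ncol(cnt))
    cells <- sample(colnames(cnt), n_aff)
  }
  seg_tab <- list()
  for (sg in cnv_spec) {
    if (sg$copy_ratio <= 0) stop("copy ratio must be > 0")
    on_chr <- which(gm$chrom == sg$chrom)
    on_chr <- on_chr[order(gm$start[on_chr])]
    if (sg$start_gene + sg$n_genes - 1 > length(on_chr))
      stop("CNV segment exceeds chromosome ", sg$chrom)
    idx <- on_chr[sg$start_gene:(sg$start_gene + sg$n_genes - 1)]
    if (sg$copy_ratio != 1) {
      mu <- cnt[idx, cells, drop = FALSE] * sg$copy_ratio
      cnt[idx, cells] <- stats::rpois(length(mu), mu)
    }
    seg_tab[[length(seg_tab) + 1L]] <- data.frame(
      chrom = sg$chrom, genes = I(list(gm$gene[idx])),
      copy_ratio = sg$copy_ratio)
  }
  out <- count_matrix(cnt, cm$gene_meta, cm$cell_meta, cm$layers)
  attr(out, "cnv_truth") <- list(malignant_cells = cells,
                                 segments = do.call(rbind, seg_tab))
  out
}

#' Simulate junction counts for alternative-splicing events
#'
#' For each event and group, total junction reads are drawn Poisson around
#' the event's mean coverage and split between inclusion and exclusion
#' junctions. The inclusion-read probability accounts for the effective
#' junction lengths (2 inclusion junctions vs 1 exclusion junction for a
#' skipped exon), so the length-normalised PSI estimator is consistent for
#' the planted PSI.
#'
#' @param splice_spec data.frame with columns `event_id`, `type` (one of
#'   SE, A3SS, A5SS, RI, MXE) and either a single `psi` column (same PSI in
#'   every group) or one `psi_<group>` column per group, plus `coverage`.
#' @param groups character vector of group labels.
#' @param seed integer seed.
#' @param fixed_coverage if `TRUE` use `coverage` reads exactly instead of
#'   Poisson totals.
#' @return a data.frame of `SpliceEvent` rows (event_id, type, group, I, E,
#'   lI, lE) with the true group PSIs attached as the `psi_truth` attribute.
#' @export
simulate_junction_counts <- function(splice_spec, groups = c("A", "B"),
                                     seed = 1L, fixed_coverage = FALSE) {
  set.seed(seed)
  el <- effective_lengths(splice_spec$type)
  rows <- list()
  truth <- list()
  for (g in groups) {
    psi <- if (paste0("psi_", g) %in% names(splice_spec))
      splice_spec[[paste0("psi_", g)]] else splice_spec$psi
    stopifnot(all(psi >= 0 & psi <= 1), all(splice_spec$coverage >= 0))
    n <- if (fixed_coverage) splice_spec$coverage else
      stats::rpois(nrow(splice_spec), splice_spec$coverage)
    theta <- el$lI * psi / (el$lI * psi + el$lE * (1 - psi))
    I <- stats::rbinom(nrow(splice_spec), n, theta)
    rows[[g]] <- data.frame(event_id = splice_spec$event_id,
                            type = splice_spec$type, group = g,
                            I = I, E = n - I, lI = el$lI, lE = el$lE)
    truth[[g]] <- stats::setNames(psi, splice_spec$event_id)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "psi_truth") <- truth
  out
}

effective_lengths <- function(type) {
  lI <- ifelse(type == "SE", 2L, ifelse(type == "MXE", 2L, 1L))
  lE <- ifelse(type == "MXE", 2L, 1L)
  list(lI = lI, lE = lE)
}

#' Simulate a survival cohort with a score-dependent hazard
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(beta * score)`; censoring is independent, with a
#' censoring hazard chosen to give approximately the requested censoring
#' fraction (rate 0 disables censoring, rate 1 censors every patient).
#'
#' @param survival_spec list with `n_patients`, `baseline_hazard`, `beta`,
#'   `censoring_rate`.
#' @param scores per-patient score; defaults to standard normal draws.
#' @param seed integer seed.
#' @return a `SurvivalCohort` data.frame (patient_id, time_days, event,
#'   score) with the true `beta` attached as attribute `beta_truth`.
#' @export
simulate_survival_cohort <- function(survival_spec, scores = NULL,
                                     seed = 1L) {
  set.seed(seed)
  sp <- survival_spec
  if (sp$baseline_hazard < 0) stop("baseline hazard must be nonnegative")
  if (sp$n_patients < 10) stop("need at least 10 patients")
  if (is.null(scores)) scores <- stats::rnorm(sp$n_patients)
  stopifnot(length(scores) == sp$n_patients)
  haz <- sp$baseline_hazard * exp(sp$beta * scores)
  t_event <- stats::rexp(sp$n_patients, haz)
  q <- sp$censoring_rate
  if (q >= 1) {
    time <- t_event
    event <- rep(0L, sp$n_patients)
  } else if (q <= 0) {
    time <- t_event
    event <- rep(1L, sp$n_patients)
  } else {
    cens_haz <- sp$baseline_hazard * exp(sp$beta * mean(scores)) * q / (1 - q)
    t_cens <- stats::rexp(sp$n_patients, cens_haz)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  }
  out <- data.frame(patient_id = sprintf("P%04d", seq_len(sp$n_patients)),
                    time_days = time, event = event, score = scores)
  attr(out, "beta_truth") <- sp$beta
  out
}
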