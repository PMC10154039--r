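#' Map an expression matrix into another species' gene space
#'
#' Columns (genes) are translated through an ortholog table: 1:1 pairs are
#' renamed, several source genes mapping to one target gene are collapsed
#' by their mean, and a source gene with several targets is duplicated
#' into each. Unmapped genes are dropped; their number is attached as the
#' `n_dropped` attribute.
#'
#' @param expr sample/subtype x gene numeric matrix.
#' @param ortholog_map data.frame with columns `human` and `mouse` (no
#'   duplicate pairs).
#' @param target `"mouse"` or `"human"`: the gene space to map into.
#' @return matrix in the target gene space.
#' @export
collapse_orthologs <- function(expr, ortholog_map,
                               target = c("mouse", "human")) {
  target <- match.arg(target)
  source <- setdiff(c("mouse", "human"), target)
  if (!nrow(ortholog_map)) stop("ortholog map is empty")
  if (anyDuplicated(ortholog_map)) stop("duplicate ortholog pairs")
  map <- ortholog_map[ortholog_map[[source]] %in% colnames(expr), ]
  if (!nrow(map)) stop("no overlap between the map and the matrix genes")
  tgt_genes <- unique(map[[target]])
  out <- vapply(tgt_genes, function(g) {
    src <- map[[source]][map[[target]] == g]
    rowMeans(expr[, src, drop = FALSE])
  }, numeric(nrow(expr)))
  out <- matrix(out, nrow = nrow(expr),
                dimnames = list(rownames(expr), tgt_genes))
  attr(out, "n_dropped") <- sum(!colnames(expr) %in% map[[source]])
  out
}

#' Hierarchical matching of subtypes across species
#'
#' Subtype centroids of the two species (already in a shared gene space)
#' are stacked and clustered hierarchically with 1 - Spearman correlation
#' distance and average linkage; each subtype's best match is the
#' cross-species subtype with the highest correlation.
#'
#' @param cent_a,cent_b subtype x gene centroid matrices (rownames are
#'   subtype names); species tags are taken from `species` or default to
#'   `"a"`/`"b"`.
#' @param species length-2 character of species tags.
#' @return list with `hclust` (the dendrogram), `correlations` and
#'   `best_match` (subtype, species, best cross-species match,
#'   correlation).
#' @export
cross_species_cluster <- function(cent_a, cent_b, species = c("a", "b")) {
  shared <- intersect(colnames(cent_a), colnames(cent_b))
  if (length(shared) < 3) stop("fewer than 3 shared genes")
  if (nrow(cent_a) < 2 || nrow(cent_b) < 2)
    stop("need at least 2 subtypes per species")
  comb <- rbind(cent_a[, shared, drop = FALSE],
                cent_b[, shared, drop = FALSE])
  tag <- rep(species, c(nrow(cent_a), nrow(cent_b)))
  const <- apply(comb, 1, function(x) stats::sd(x) == 0)
  if (any(const))
    stop("constant centroid row(s): ",
         paste(rownames(comb)[const], collapse = ", "))
  rownames(comb) <- paste(tag, rownames(comb), sep = ":")
  cc <- stats::cor(t(comb), method = "spearman")
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  best <- do.call(rbind, lapply(seq_len(nrow(comb)), function(i) {
    other <- which(tag != tag[i])
    j <- other[which.max(cc[i, other])]
    data.frame(subtype = rownames(comb)[i], species = tag[i],
               best_match = rownames(comb)[j], correlation = cc[i, j])
  }))
  list(hclust = hc, correlations = cc, best_match = best)
}

#' Threshold-defined differential-expression signature from bulk counts
#'
#' Counts are library-size normalised (counts per median library); the
#' log2 fold change of a gene is the difference of group means of
#' `log2(normalised + 1)`, and the p-value comes from a two-sample test on
#' those log2 values (Welch t by default, Wilcoxon optionally), adjusted
#' by Benjamini-Hochberg. The signature is the set of genes exceeding the
#' fold-change cutoff in the case group at the adjusted-p cutoff.
#'
#' @param counts sample x gene matrix of bulk counts.
#' @param groups factor/character per sample with exactly two levels; the
#'   second level (or `case`) is the case group.
#' @param lfc_cutoff log2 fold-change cutoff (e.g. 3, 4 or 1.5).
#' @param padj_cutoff BH-adjusted p cutoff (default 0.05).
#' @param case the case group label (default: second level).
#' @param test `"t"` or `"wilcox"`.
#' @return a `DEGSignature`: list with `genes`, `table` (per-gene log2FC,
#'   p, padj) and the thresholds used.
#' @export
deg_signature <- function(counts, groups, lfc_cutoff, padj_cutoff = 0.05,
                          case = NULL, test = c("t", "wilcox")) {
  test <- match.arg(test)
  groups <- as.character(groups)
  lev <- unique(groups)
  stopifnot(length(lev) == 2)
  if (is.null(case)) case <- lev[2]
  ctrl <- setdiff(lev, case)
  if (min(table(groups)) < 2) stop("each group needs at least 2 samples")
  lib <- rowSums(counts)
  norm <- counts / lib * stats::median(lib)
  lg <- log2(norm + 1)
  is_case <- groups == case
  lfc <- colMeans(lg[is_case, , drop = FALSE]) -
    colMeans(lg[!is_case, , drop = FALSE])
  p <- apply(lg, 2, function(x) {
    if (stats::sd(x) == 0) return(1)
    if (test == "t")
      tryCatch(stats::t.test(x[is_case], x[!is_case])$p.value,
               error = function(e) 1)
    else stats::wilcox.test(x[is_case], x[!is_case], exact = FALSE)$p.value
  })
  padj <- stats::p.adjust(p, "BH")
  tab <- data.frame(gene = colnames(counts), log2fc = lfc, p = p,
                    padj = padj, row.names = NULL)
  genes <- tab$gene[tab$log2fc > lfc_cutoff & tab$padj < padj_cutoff]
  structure(list(genes = genes, table = tab,
                 lfc_cutoff = lfc_cutoff, padj_cutoff = padj_cutoff,
                 contrast = paste(case, "vs", ctrl)),
            class = "DEGSignature")
}

#' Validate and clean a survival cohort table
#'
#' Drops patients with unknown follow-up (missing or nonpositive time,
#' missing event indicator) before any fit.
#'
#' @param cohort data.frame with `time_days`, `event` and a score column.
#' @return the filtered cohort.
#' @export
clean_cohort <- function(cohort) {
  keep <- !is.na(cohort$time_days) & cohort$time_days > 0 &
    !is.na(cohort$event)
  cohort[keep, , drop = FALSE]
}

#' Maximally selected survival cutpoint
#'
#' Scans the midpoints between consecutive distinct score values that
#' leave at least `minprop` of the patients on each side and returns the
#' cutpoint maximising the two-group log-rank chi-square; ties are broken
#' toward the median score. P-values computed downstream of this selection
#' are exploratory: maximising over splits makes the naive log-rank p
#' anti-conservative.
#'
#' @param cohort a `SurvivalCohort` data.frame (time_days, event, score).
#' @param minprop minimum fraction of patients per side, in (0, 0.5].
#' @param score_col score column name (default `"score"`).
#' @return list with `cutpoint`, `statistic` and the scanned `candidates`.
#' @export
survival_cutpoint <- function(cohort, minprop = 0.1,
                              score_col = "score") {
  cohort <- clean_cohort(cohort)
  n <- nrow(cohort)
  if (n < 10) stop("need at least 10 patients")
  if (!(minprop > 0 && minprop <= 0.5)) stop("minprop must be in (0, 0.5]")
  score <- cohort[[score_col]]
  if (length(unique(score)) < 2) stop("all scores are equal")
  s <- sort(unique(score))
  mids <- (s[-1] + s[-length(s)]) / 2
  ok <- vapply(mids, function(m)
    min(sum(score <= m), sum(score > m)) >= ceiling(minprop * n), TRUE)
  mids <- mids[ok]
  if (!length(mids)) stop("no candidate split satisfies minprop")
  stat <- vapply(mids, function(m) {
    g <- score > m
    sd <- survival::survdiff(
      survival::Surv(cohort$time_days, cohort$event) ~ g)
    sd$chisq
  }, 0)
  best <- which(stat == max(stat))
  if (length(best) > 1)
    best <- best[which.min(abs(mids[best] - stats::median(score)))]
  list(cutpoint = mids[best], statistic = stat[best],
       candidates = data.frame(cutpoint = mids, chisq = stat))
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic on one degree of freedom with the
#' chi-squared upper-tail p-value (no continuity correction).
#'
#' @param cohort a `SurvivalCohort` data.frame (time_days, event).
#' @param groups two-level group label per patient.
#' @return list with `chisq`, `p`, `n` per group.
#' @export
logrank_test <- function(cohort, groups) {
  stopifnot(length(groups) == nrow(cohort))
  cohort$.group <- groups
  cohort <- clean_cohort(cohort)
  groups <- cohort$.group
  tab <- table(groups)
  if (length(tab) != 2 || any(tab == 0))
    stop("log-rank needs two non-empty groups")
  sd <- survival::survdiff(
    survival::Surv(cohort$time_days, cohort$event) ~ groups)
  chisq <- unname(sd$chisq)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       n = as.integer(tab))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param cohort a `SurvivalCohort` data.frame (time_days, event).
#' @return data.frame (time, n_risk, n_event, surv): a right-continuous
#'   step function starting at S(0) = 1.
#' @export
km_estimate <- function(cohort) {
  cohort <- clean_cohort(cohort)
  if (!nrow(cohort)) stop("empty cohort")
  sf <- survival::survfit(survival::Surv(time_days, event) ~ 1,
                          data = cohort)
  data.frame(time = c(0, sf$time), n_risk = c(nrow(cohort), sf$n.risk),
             n_event = c(0, sf$n.event), surv = c(1, sf$surv))
}
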