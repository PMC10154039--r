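#' Percent spliced in from junction counts
#'
#' `PSI = (I/lI) / (I/lI + E/lE)`: the length-normalised fraction of reads
#' supporting inclusion. For a skipped exon the inclusion form spans two
#' junctions and the exclusion form one, hence the default effective
#' lengths (2, 1). PSI is missing (`NA`) when both normalised counts are
#' zero.
#'
#' @param I,E inclusion and exclusion junction read counts (vectors).
#' @param lI,lE positive effective lengths.
#' @return numeric vector of PSI values in [0, 1] (NA where undefined).
#' @export
compute_psi <- function(I, E, lI = 2, lE = 1) {
  if (any(lI <= 0) || any(lE <= 0)) stop("effective lengths must be positive")
  if (any(I < 0) || any(E < 0)) stop("junction counts must be nonnegative")
  ni <- I / lI
  ne <- E / lE
  ifelse(ni + ne == 0, NA_real_, ni / (ni + ne))
}

#' Skipping ratio (PSI complement)
#'
#' @inheritParams compute_psi
#' @return `1 - PSI`.
#' @export
skip_ratio <- function(I, E, lI = 2, lE = 1) 1 - compute_psi(I, E, lI, lE)

#' Differential PSI between two cell groups
#'
#' Events are matched by id; junction counts are pooled within each group
#' (pseudobulk). The p-value is a two-proportion score test on the raw
#' inclusion-read fraction (under equal PSI the inclusion-read probability
#' is the same monotone function of PSI in both groups, so the null is
#' preserved); delta PSI is reported on the length-normalised scale as
#' `PSI(B) - PSI(A)`. Events missing from one group are excluded and
#' counted in the `n_excluded` attribute.
#'
#' @param eventsA,eventsB `SpliceEvent` tables (event_id, type, I, E, lI,
#'   lE), possibly one row per cell.
#' @return a `DifferentialSpliceResult` data.frame (event_id, type, psi_a,
#'   psi_b, dpsi, p, q).
#' @export
differential_psi <- function(eventsA, eventsB) {
  pool <- function(ev) {
    agg <- stats::aggregate(cbind(I, E) ~ event_id + type + lI + lE,
                            data = ev, FUN = sum)
    agg
  }
  a <- pool(eventsA); b <- pool(eventsB)
  common <- intersect(a$event_id, b$event_id)
  n_excluded <- length(union(a$event_id, b$event_id)) - length(common)
  a <- a[match(common, a$event_id), ]
  b <- b[match(common, b$event_id), ]
  psi_a <- compute_psi(a$I, a$E, a$lI, a$lE)
  psi_b <- compute_psi(b$I, b$E, b$lI, b$lE)
  na_ <- a$I + a$E
  nb_ <- b$I + b$E
  phat <- (a$I + b$I) / (na_ + nb_)
  se <- sqrt(phat * (1 - phat) * (1 / na_ + 1 / nb_))
  z <- (a$I / na_ - b$I / nb_) / se
  p <- ifelse(is.finite(z), 2 * stats::pnorm(-abs(z)), 1)
  p[na_ == 0 | nb_ == 0] <- NA
  out <- data.frame(event_id = common, type = a$type,
                    psi_a = psi_a, psi_b = psi_b, dpsi = psi_b - psi_a,
                    p = p, q = stats::p.adjust(p, "BH"), row.names = NULL)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Tally significant events per splicing type
#'
#' @param results a `DifferentialSpliceResult`.
#' @param q_threshold FDR cutoff (default 0.05).
#' @param dpsi_threshold minimum absolute delta PSI (default 0.1).
#' @return named integer vector over SE, A3SS, A5SS, RI, MXE.
#' @export
count_event_types <- function(results, q_threshold = 0.05,
                              dpsi_threshold = 0.1) {
  types <- c("SE", "A3SS", "A5SS", "RI", "MXE")
  sig <- !is.na(results$q) & results$q < q_threshold &
    !is.na(results$dpsi) & abs(results$dpsi) >= dpsi_threshold
  table(factor(results$type[sig], levels = types)) |> c()
}
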