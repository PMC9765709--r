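# Export-signal characterization across propeptides: alignment logo counts,
# KK-duplet frequency, hydrophobicity profiles, conserved post-h-region
# residues, and the MGE enrichment test.

#' Observed residue counts for the first columns of a propeptide alignment
#'
#' Raw counts (no pseudocounts); gaps are excluded from the per-column totals.
#'
#' @param alignment Character vector of aligned sequences (equal widths).
#' @param n_cols Number of leading columns to tally (default 40); shorter
#'   alignments use all columns and are flagged.
#' @return List with `counts` (20 x n matrix over [aa_alphabet()]),
#'   `totals` (non-gap count per column) and `truncated`.
#' @export
logo_counts <- function(alignment, n_cols = 40) {
  if (length(alignment) == 0L) stop("empty alignment", call. = FALSE)
  widths <- unique(nchar(alignment))
  if (length(widths) != 1L) stop("alignment rows have unequal widths", call. = FALSE)
  truncated <- widths < n_cols
  use <- min(widths, n_cols)
  chars <- do.call(rbind, strsplit(substr(alignment, 1L, use), "", fixed = TRUE))
  ab <- aa_alphabet()
  counts <- vapply(seq_len(use), function(j)
    tabulate(match(chars[, j], ab), nbins = 20L), integer(20L))
  rownames(counts) <- ab
  colnames(counts) <- seq_len(use)
  list(counts = counts, totals = colSums(counts), truncated = truncated)
}

#' Fraction of propeptides carrying a KK duplet
#'
#' Reports the fraction with `KK` inside the n-region (the first `n_region`
#' residues, matching the fallback used by the signal heuristic when no
#' cleavage is predicted) and, since the original survey does not state which
#' region was counted, also the fraction with `KK` anywhere in the propeptide.
#'
#' @param propeptides Character vector of propeptide sequences.
#' @param n_region n-region length (default 12).
#' @return List with `fraction` (n-region), `fraction_anywhere`, `n_with_kk`,
#'   and `n_total`.
#' @export
kk_duplet_frequency <- function(propeptides, n_region = 12) {
  if (length(propeptides) == 0L) stop("empty propeptide set", call. = FALSE)
  in_n <- grepl("KK", substr(propeptides, 1L, n_region), fixed = TRUE)
  anywhere <- grepl("KK", propeptides, fixed = TRUE)
  list(fraction = mean(in_n), fraction_anywhere = mean(anywhere),
       n_with_kk = sum(in_n), n_total = length(propeptides))
}

#' Sliding-window mean hydropathy profile
#'
#' Centered Kyte-Doolittle window means; edge positions use the truncated
#' window.  Proteins shorter than the window collapse to a single flagged
#' global mean.
#'
#' @param protein Character scalar.
#' @param window Odd window width (default 7).
#' @return List with `profile` (numeric, one value per residue) and `flagged`.
#' @export
hydrophobicity_profile <- function(protein, window = 7) {
  kd <- kyte_doolittle()[aa_chars(protein)]
  n <- length(kd)
  if (n < window)
    return(list(profile = mean(kd), flagged = TRUE))
  half <- window %/% 2L
  prof <- vapply(seq_len(n), function(i)
    mean(kd[max(1L, i - half):min(n, i + half)]), 0)
  list(profile = prof, flagged = FALSE)
}

#' Residue frequencies at the first position after the h-region
#'
#' For each sequence the h-region end is located with
#' [score_signal_peptide()]; the residue immediately following it is tallied.
#' Sequences without a detectable h-region are skipped; an empty result is
#' flagged.
#'
#' @param propeptides Character vector.
#' @param params [signal_params()].
#' @return List with `frequencies` (named counts, decreasing), `n_used`, and
#'   `flagged` (TRUE when no sequence had a detectable h-region).
#' @export
conserved_position_check <- function(propeptides, params = signal_params()) {
  res <- character()
  for (p in propeptides) {
    sg <- score_signal_peptide(p, params)
    if (!is.na(sg$h_end) && sg$h_end < nchar(p))
      res <- c(res, substr(p, sg$h_end + 1L, sg$h_end + 1L))
  }
  if (length(res) == 0L)
    return(list(frequencies = integer(), n_used = 0L, flagged = TRUE))
  tab <- sort(table(res), decreasing = TRUE)
  list(frequencies = tab, n_used = length(res), flagged = FALSE)
}

#' One-degree-of-freedom enrichment chi-square test
#'
#' Two-cell goodness-of-fit of an observed in-class count against an expected
#' fraction: `chi2 = (O - E)^2 / E + ((T - O) - (T - E))^2 / (T - E)` with
#' `E = T * expected_fraction`, compared to a chi-square with 1 df.
#'
#' @param observed_in_class Observed count in the class of interest.
#' @param total Total count.
#' @param expected_fraction Expected class fraction, in (0, 1).
#' @return List with `chi2`, `p`, `expected`, and `valid` (FALSE with a
#'   warning when an expected cell count is below 5).
#' @export
enrichment_chi_square <- function(observed_in_class, total, expected_fraction) {
  if (expected_fraction <= 0 || expected_fraction >= 1)
    stop("expected_fraction must lie strictly in (0,1)", call. = FALSE)
  if (total <= 0) stop("total must be positive", call. = FALSE)
  if (observed_in_class > total)
    stop("observed count exceeds total", call. = FALSE)
  E <- total * expected_fraction
  E2 <- total - E
  valid <- TRUE
  if (min(E, E2) < 5) {
    warning("expected cell count below 5; chi-square approximation is weak")
    valid <- FALSE
  }
  chi2 <- (observed_in_class - E)^2 / E + ((total - observed_in_class) - E2)^2 / E2
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE),
       expected = E, valid = valid)
}

#' Summarize export pathways and MGE enrichment over propeptide calls
#'
#' Counts SPI / SPII / unassigned calls, splits them by MGE vs non-MGE
#' context, and runs [enrichment_chi_square()] for SPII calls in MGEs against
#' the overall MGE fraction of the input systems.
#'
#' @param pathways Character vector (`"SPI"`, `"SPII"`, anything else counts
#'   as unassigned).
#' @param in_mge Logical vector, parallel to `pathways`.
#' @param expected_fraction Expected MGE fraction; defaults to `mean(in_mge)`.
#' @return List with `counts`, `mge_counts`, and `spii_enrichment`.
#' @export
pathway_summary <- function(pathways, in_mge,
                            expected_fraction = mean(in_mge)) {
  stopifnot(length(pathways) == length(in_mge))
  cls <- ifelse(pathways %in% c("SPI", "SPII"), pathways, "unassigned")
  counts <- c(SPI = sum(cls == "SPI"), SPII = sum(cls == "SPII"),
              unassigned = sum(cls == "unassigned"))
  mge_counts <- table(factor(cls, c("SPI", "SPII", "unassigned")),
                      factor(in_mge, c(FALSE, TRUE), c("non_mge", "mge")))
  enr <- NULL
  if (counts["SPII"] > 0 && expected_fraction > 0 && expected_fraction < 1)
    enr <- enrichment_chi_square(sum(cls == "SPII" & in_mge), counts[["SPII"]],
                                 expected_fraction)
  list(counts = counts, mge_counts = mge_counts, spii_enrichment = enr)
}
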