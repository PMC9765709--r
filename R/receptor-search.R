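# Per-subfamily position-specific scoring models, proteome scanning and
# subfamily assignment.
#
# Models are position-specific log-odds matrices built from gapless-column
# seed alignments, scored against proteins by local dynamic programming with
# uniform affine gap penalties.  This is deliberately simpler than a full
# profile-HMM: there are no position-specific insert/delete states, and the
# extreme-value calibration fitted on random decoys absorbs the difference.

#' Build a position-specific scoring model from a seed alignment
#'
#' Columns whose gap fraction exceeds `max_gap_fraction` are dropped.  For a
#' retained column, the log-odds of residue *a* is
#' `log((p_a + w * bg_a) / (1 + w) / bg_a)` where `p_a` is the weight-normalized
#' observed frequency among non-gap residues, `bg_a` the background frequency
#' and `w` the pseudocount weight.
#'
#' @param alignment Named character vector of aligned sequences (equal widths,
#'   `-` for gaps).
#' @param family Family label stored on the model.
#' @param background Named background frequencies over [aa_alphabet()].
#' @param pseudocount Pseudocount weight `w` (default 1).
#' @param max_gap_fraction Columns with a larger gap fraction are dropped.
#' @param gap_open,gap_extend Affine gap penalties (log-odds units) used when
#'   the model is aligned to proteins.
#' @return An object of class `qs_profile`.
#' @export
build_profile <- function(alignment, family = "unnamed",
                          background = aa_background(), pseudocount = 1,
                          max_gap_fraction = 0.5,
                          gap_open = 11, gap_extend = 1) {
  if (length(alignment) == 0L) stop("empty alignment", call. = FALSE)
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1L)
    stop("alignment rows have unequal widths", call. = FALSE)
  ab <- aa_alphabet()
  bg <- background[ab]
  if (anyNA(bg)) stop("background must cover the 20-residue alphabet", call. = FALSE)
  chars <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  is_gap <- chars == "-" | chars == "."
  bad <- !is_gap & !(chars %in% ab)
  if (any(bad))
    stop("unknown residue symbol '", chars[which(bad)[1]], "' in alignment",
         call. = FALSE)
  gap_frac <- colMeans(is_gap)
  keep <- which(gap_frac <= max_gap_fraction & gap_frac < 1)
  if (length(keep) == 0L)
    stop("alignment has zero retained columns after gap filtering", call. = FALSE)

  L <- length(keep)
  scores <- matrix(NA_real_, L, 20L, dimnames = list(NULL, ab))
  for (k in seq_len(L)) {
    col <- chars[, keep[k]]
    col <- col[!is_gap[, keep[k]]]
    p <- tabulate(match(col, ab), nbins = 20L) / length(col)
    scores[k, ] <- log((p + pseudocount * bg) / (1 + pseudocount) / bg)
  }
  structure(list(family = family, scores = scores, length = L,
                 background = bg, gap_open = gap_open, gap_extend = gap_extend,
                 calibration = NULL),
            class = "qs_profile")
}

#' @export
print.qs_profile <- function(x, ...) {
  cat("qs_profile:", x$family, "-", x$length, "columns,",
      if (is.null(x$calibration)) "uncalibrated" else "calibrated", "\n")
  invisible(x)
}

#' Consensus sequence of a scoring model (argmax residue per column)
#' @param model A `qs_profile`.
#' @return Character scalar.
#' @export
profile_consensus <- function(model) {
  ab <- aa_alphabet()
  paste(ab[apply(model$scores, 1L, which.max)], collapse = "")
}

#' Calibrate a scoring model against random decoys
#'
#' Draws `n_decoys` i.i.d. decoy proteins from the model's background
#' frequencies, records the best local-alignment score of the model on each,
#' and fits a Gumbel (extreme-value) distribution to those maxima by maximum
#' likelihood.  E-values reported by [scan_proteome()] are
#' `P(S >= s) * n_database` under this fit.
#'
#' @param model A `qs_profile`.
#' @param n_decoys Number of decoys (must be at least `min_decoys`).
#' @param decoy_length Decoy protein length.
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param min_decoys Minimum admissible `n_decoys`.
#' @return The model with a `calibration` component.
#' @export
calibrate_profile <- function(model, n_decoys = 500, decoy_length = 350,
                              seed = 1L, min_decoys = 500) {
  stopifnot(inherits(model, "qs_profile"))
  if (n_decoys < min_decoys)
    stop("n_decoys (", n_decoys, ") below configured minimum (", min_decoys, ")",
         call. = FALSE)
  scores <- with_seed(child_seed(seed, paste0("cal", model$family)), {
    decoys <- lapply(seq_len(n_decoys), function(i)
      encode_aa(random_protein(decoy_length, model$background)))
    as.numeric(profile_best_scores_cpp(model$scores, decoys,
                                       model$gap_open, model$gap_extend))
  })
  if (stats::sd(scores) < 1e-9)
    stop("degenerate decoy score variance; cannot calibrate", call. = FALSE)
  fit <- fit_gumbel(scores)
  model$calibration <- list(mu = fit$mu, beta = fit$beta,
                            n_decoys = n_decoys, decoy_length = decoy_length)
  model
}

# Gumbel maximum-likelihood fit via the standard one-dimensional profile
# likelihood in beta (Lawless), solved with uniroot.
fit_gumbel <- function(x) {
  xbar <- mean(x)
  g <- function(beta) {
    w <- exp(-(x - max(x)) / beta) # stabilized
    beta - xbar + sum(x * w) / sum(w)
  }
  s <- stats::sd(x)
  lo <- s / 50
  hi <- s * 50
  beta <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
  mu <- -beta * log(mean(exp(-(x - max(x)) / beta))) + max(x)
  list(mu = mu, beta = beta)
}

# Gumbel upper-tail probability P(S >= s)
gumbel_tail <- function(s, mu, beta) {
  p <- -expm1(-exp(-(s - mu) / beta))
  pmax(p, .Machine$double.xmin)
}

#' Default hit-filtering thresholds
#'
#' The per-family numeric thresholds used in the original survey are not
#' published; the defaults here (E-value at most 1e-5, coverage at least 0.6,
#' identical for all families) are this package's own design choice and can be
#' overridden per family.
#'
#' @param max_evalue,min_coverage Global defaults.
#' @param per_family Optional named list of per-family overrides, each a list
#'   with elements `max_evalue` and/or `min_coverage`.
#' @return A `qs_thresholds` list.
#' @export
default_thresholds <- function(max_evalue = 1e-5, min_coverage = 0.6,
                               per_family = list()) {
  stopifnot(min_coverage >= 0, min_coverage <= 1)
  structure(list(max_evalue = max_evalue, min_coverage = min_coverage,
                 per_family = per_family), class = "qs_thresholds")
}

threshold_for <- function(thresholds, family) {
  out <- list(max_evalue = thresholds$max_evalue,
              min_coverage = thresholds$min_coverage)
  ov <- thresholds$per_family[[family]]
  if (!is.null(ov)) out[names(ov)] <- ov
  out
}

#' Scan a proteome with one calibrated scoring model
#'
#' Each protein is aligned locally to the model; coverage is the number of
#' model columns consumed by match states divided by the model length, and the
#' E-value is the calibrated tail probability times `n_database`.  Hits are
#' filtered by the family's thresholds (pass `thresholds = NULL` to keep all
#' proteins) and sorted by increasing E-value.
#'
#' @param proteins Named character vector of protein sequences.
#' @param model Calibrated `qs_profile`.
#' @param thresholds A `qs_thresholds` object, or `NULL` for no filtering.
#' @param n_database Effective database size for E-values (defaults to the
#'   number of proteins scanned).
#' @return data.frame with columns protein_id, family, score, coverage,
#'   evalue, protein_start, protein_end.
#' @export
scan_proteome <- function(proteins, model, thresholds = default_thresholds(),
                          n_database = length(proteins)) {
  stopifnot(inherits(model, "qs_profile"))
  if (is.null(model$calibration))
    stop("model is uncalibrated; run calibrate_profile() first", call. = FALSE)
  if (length(proteins) == 0L)
    return(empty_hits())
  if (is.null(names(proteins))) names(proteins) <- paste0("protein_", seq_along(proteins))
  enc <- lapply(proteins, encode_aa)
  m <- profile_scan_cpp(model$scores, enc, model$gap_open, model$gap_extend)
  p <- gumbel_tail(m[, "score"], model$calibration$mu, model$calibration$beta)
  hits <- data.frame(protein_id = names(proteins),
                     family = model$family,
                     score = m[, "score"],
                     coverage = m[, "matched_cols"] / model$length,
                     evalue = p * n_database,
                     protein_start = m[, "protein_start"],
                     protein_end = m[, "protein_end"],
                     stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(thresholds)) {
    th <- threshold_for(thresholds, model$family)
    hits <- hits[hits$evalue <= th$max_evalue & hits$coverage >= th$min_coverage, ,
                 drop = FALSE]
  }
  hits[order(hits$evalue, hits$protein_id), , drop = FALSE]
}

empty_hits <- function() {
  data.frame(protein_id = character(), family = character(), score = numeric(),
             coverage = numeric(), evalue = numeric(),
             protein_start = integer(), protein_end = integer(),
             stringsAsFactors = FALSE)
}

#' Assign a single subfamily to each protein from multi-model hits
#'
#' Applies the survey's disambiguation rules: a protein passing both the Rap
#' and NprR thresholds is classed as NprR (with `reassigned_from = "Rap"`),
#' because the Rap model matches the shared 3HB/TPR core of NprR proteins
#' while the reverse does not hold.  Rgg assignments additionally require a
#' confirmed nearby propeptide (the Rgg model also matches MutR/GadR-like
#' non-QS regulators); when `confirmed_propeptide_ids` is supplied,
#' unconfirmed Rgg candidates are dropped, otherwise they are retained with
#' `needs_propeptide_confirmation = TRUE`.  Remaining multi-family proteins
#' take the passing family with the lowest E-value (ties broken by family
#' name).
#'
#' @param hits data.frame of threshold-passing hits from [scan_proteome()]
#'   across all family models (row-bound).
#' @param confirmed_propeptide_ids Optional character vector of protein ids
#'   with a confirmed QS propeptide nearby.
#' @return data.frame of assigned hits, one row per protein, with extra
#'   columns `reassigned_from` and `needs_propeptide_confirmation`.
#' @export
assign_family <- function(hits, confirmed_propeptide_ids = NULL) {
  out <- cbind(empty_hits(),
               data.frame(reassigned_from = character(),
                          needs_propeptide_confirmation = logical()))
  if (is.null(hits) || nrow(hits) == 0L) return(out)
  rows <- lapply(split(hits, hits$protein_id), function(h) {
    fams <- h$family
    if (all(c("Rap", "NprR") %in% fams)) {
      r <- h[h$family == "NprR", , drop = FALSE][1, ]
      r$reassigned_from <- "Rap"
    } else {
      h <- h[order(h$evalue, h$family), , drop = FALSE]
      r <- h[1, ]
      r$reassigned_from <- NA_character_
    }
    r$needs_propeptide_confirmation <- identical(r$family, "Rgg")
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(confirmed_propeptide_ids)) {
    drop <- out$needs_propeptide_confirmation &
      !(out$protein_id %in% confirmed_propeptide_ids)
    out <- out[!drop, , drop = FALSE]
    out$needs_propeptide_confirmation <- out$needs_propeptide_confirmation &
      !(out$protein_id %in% confirmed_propeptide_ids)
  }
  out[order(out$evalue, out$protein_id), , drop = FALSE]
}
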