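# Locating candidate pheromone precursor genes in the flanks of receptor
# genes: strand-aware 50 + 1,000 nt windows, small-ORF detection with
# alternative start codons, a heuristic signal-peptide score, the SHP
# six-frame fallback for Rgg/ComR, and the plasmid-wide mode for PrgX.

make_window <- function(replicon_id, side, seq, positions, flipped, gene_strand) {
  structure(list(replicon_id = replicon_id, side = side, seq = seq,
                 positions = positions, flipped = flipped,
                 gene_strand = gene_strand),
            class = "flank_window")
}

#' @export
print.flank_window <- function(x, ...) {
  cat("flank_window:", x$side, "of gene on", x$replicon_id,
      sprintf("(%d nt, %s)\n", nchar(x$seq), if (x$flipped) "revcomp" else "forward"))
  invisible(x)
}

#' Build the upstream and downstream flank windows of a gene
#'
#' Each window concatenates the 50 terminal bases of the gene with 1,000
#' additional bases beyond it, in the gene's transcription direction: for a
#' `-` strand gene "downstream" precedes the gene on the forward strand and
#' the window sequence is reverse-complemented.  Windows are truncated at the
#' ends of linear replicons and wrap on circular ones.  Genes shorter than
#' 50 nt contribute their whole length (with a warning).
#'
#' @param gene List or one-row data.frame with `start`, `end` (0-based,
#'   half-open, forward strand) and `strand` (`"+"`/`"-"`).
#' @param replicon Character scalar replicon sequence.
#' @param replicon_id Replicon identifier stored on the windows.
#' @param circular Is the replicon circular?
#' @param terminal Bases of the gene included (default 50).
#' @param flank Bases beyond the gene included (default 1000).
#' @return List with elements `downstream` and `upstream`, each a
#'   `flank_window` whose `positions` element maps window positions back to
#'   0-based replicon coordinates.
#' @export
build_flank_windows <- function(gene, replicon, replicon_id = "replicon",
                                circular = FALSE, terminal = 50, flank = 1000) {
  L <- nchar(replicon)
  s <- as.integer(gene$start); e <- as.integer(gene$end)
  if (s < 0 || e > L || s >= e) stop("gene coordinates outside replicon", call. = FALSE)
  glen <- e - s
  if (glen < terminal) {
    warning("gene shorter than ", terminal, " nt; using the whole gene")
    terminal <- glen
  }
  clip <- function(pos) {
    if (circular) pos %% L else pos[pos >= 0 & pos < L]
  }
  # forward-strand position vectors of the "after gene end" and "before gene
  # start" windows
  after  <- clip(seq.int(e - terminal, e + flank - 1L))
  before <- clip(seq.int(s - flank, s + terminal - 1L))
  chars <- strsplit(replicon, "", fixed = TRUE)[[1]]
  seq_of <- function(pos) paste(chars[pos + 1L], collapse = "")
  if (identical(gene$strand, "-")) {
    dn <- make_window(replicon_id, "downstream", revcomp(seq_of(before)),
                      rev(before), TRUE, "-")
    up <- make_window(replicon_id, "upstream", revcomp(seq_of(after)),
                      rev(after), TRUE, "-")
  } else {
    dn <- make_window(replicon_id, "downstream", seq_of(after), after, FALSE, "+")
    up <- make_window(replicon_id, "upstream", seq_of(before), before, FALSE, "+")
  }
  list(downstream = dn, upstream = up)
}

#' Find small ORFs in a flank window
#'
#' Scans all six frames of the window for open reading frames starting at
#' ATG, GTG or TTG (alternative starts translated as Met) and ending at an
#' in-window stop codon, reporting for each stop the longest ORF (earliest
#' admissible start after the previous in-frame stop) whose translated length
#' falls in `[min_aa, max_aa]`.  Coordinates are mapped back to the replicon
#' through the window's position map.
#'
#' @param window A `flank_window`.
#' @param min_aa,max_aa Translated length bounds (stop codon excluded).
#' @return data.frame with window coordinates (`win_start`, `win_end`,
#'   `win_strand`, 0-based half-open, stop codon included), replicon
#'   coordinates (`rep_start`, `rep_end`, `rep_strand`, `wrapped`) and the
#'   translated `protein`.
#' @export
find_orfs <- function(window, min_aa = 20, max_aa = 120) {
  stopifnot(inherits(window, "flank_window"))
  n <- nchar(window$seq)
  out <- list()
  for (str in c("+", "-")) {
    S <- if (str == "+") window$seq else revcomp(window$seq)
    for (f in 0:2) {
      ncf <- (nchar(S) - f) %/% 3L
      if (ncf < 1L) next
      codons <- substring(S, f + 3L * seq_len(ncf) - 2L, f + 3L * seq_len(ncf))
      starts <- which(codons %in% c("ATG", "GTG", "TTG"))
      stops  <- which(codons %in% c("TAA", "TAG", "TGA"))
      if (length(stops) == 0L || length(starts) == 0L) next
      prev <- c(0L, stops[-length(stops)])
      for (k in seq_along(stops)) {
        cand <- starts[starts > prev[k] & starts < stops[k]]
        if (length(cand) == 0L) next
        st <- cand[1]
        len_aa <- stops[k] - st
        if (len_aa < min_aa || len_aa > max_aa) next
        a <- f + 3L * (st - 1L)            # 0-based nt start on strand S
        b <- f + 3L * stops[k]             # 0-based nt end (incl stop)
        if (str == "-") { tmp <- a; a <- n - b; b <- n - tmp }
        orf_nt <- substr(window$seq, a + 1L, b)
        if (str == "-") orf_nt <- revcomp(orf_nt)
        prot <- substr(translate_dna(orf_nt, start_as_met = TRUE), 1L, len_aa)
        out[[length(out) + 1L]] <- data.frame(
          win_start = a, win_end = b, win_strand = str, protein = prot,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(empty_orfs())
  orfs <- do.call(rbind, out)
  map <- map_window_span(window, orfs$win_start, orfs$win_end, orfs$win_strand)
  orfs <- cbind(orfs, map)
  orfs[order(orfs$win_start, orfs$win_strand), , drop = FALSE]
}

empty_orfs <- function() {
  data.frame(win_start = integer(), win_end = integer(), win_strand = character(),
             protein = character(), rep_start = integer(), rep_end = integer(),
             rep_strand = character(), wrapped = logical(),
             stringsAsFactors = FALSE)
}

# map window spans [a, b) (+ window-relative strand) to replicon coordinates
map_window_span <- function(window, a, b, strand) {
  P <- window$positions
  n <- length(P)
  rep_start <- integer(length(a)); rep_end <- integer(length(a))
  wrapped <- logical(length(a)); rep_strand <- character(length(a))
  for (i in seq_along(a)) {
    pos <- P[(a[i] + 1L):b[i]]
    lo <- min(pos); hi <- max(pos)
    wrapped[i] <- (hi - lo + 1L) != length(pos)
    if (!wrapped[i]) { rep_start[i] <- lo; rep_end[i] <- hi + 1L }
    else {
      # wrapped span on a circular replicon: report the transcription-order
      # first and last positions
      rep_start[i] <- pos[1]; rep_end[i] <- pos[length(pos)] + 1L
    }
    fwd <- !window$flipped
    rep_strand[i] <- if (xor(strand[i] == "-", !fwd)) "-" else "+"
  }
  data.frame(rep_start = rep_start, rep_end = rep_end, rep_strand = rep_strand,
             wrapped = wrapped, stringsAsFactors = FALSE)
}

#' Parameters of the heuristic signal-peptide score
#'
#' The neural predictors used in large surveys are replaced here by a
#' documented heuristic over the classic n/h/c signal-peptide architecture:
#' a positively charged n-region carrying the KK duplet, a hydrophobic
#' h-region (Kyte-Doolittle window mean), and a small-residue (A-X-A style)
#' cleavage region, with a lipobox + invariant Cys overriding to the SPII
#' (lipoprotein) pathway.  Scores lie in [0, 1]; `fallback_cutoff` mirrors the
#' 0.25 secondary-predictor cutoff of the original procedure, applied to this
#' package's own score.
#'
#' @param n_max n-region length searched for the KK duplet.
#' @param h_window Hydropathy window width.
#' @param h_gate Minimum window-mean hydropathy for any signal at all.  The
#'   default (3.0 on the Kyte-Doolittle scale) is deliberately strict: ORFs
#'   translated from random DNA are hydrophobic-rich (about a third of sense
#'   codons encode F/L/I/V/M/A), so a permissive gate floods eavesdropper
#'   flanks with spurious calls.  Strongly hydrophobic h-regions (Leu/Ile
#'   runs) score well above the gate.
#' @param h_scale Scale from gated hydropathy to score contribution.
#' @param c_search Residues after the h-region searched for a cleavage motif.
#' @param small_residues c-region small-residue set.
#' @param lipobox Lipobox regular expression (must end at the invariant Cys).
#' @param primary_cutoff,fallback_cutoff Score cutoffs used by
#'   [call_propeptides()]; the fallback must not exceed the primary.
#' @param w_n,w_h,w_c Component weights.
#' @return List of parameters.
#' @export
signal_params <- function(n_max = 12, h_window = 8, h_gate = 3.0, h_scale = 1.0,
                          c_search = 10, small_residues = c("A", "G", "S"),
                          lipobox = "[LVI][ASTG][GA]C",
                          primary_cutoff = 0.6, fallback_cutoff = 0.25,
                          w_n = 0.4, w_h = 0.4, w_c = 0.2) {
  stopifnot(fallback_cutoff <= primary_cutoff)
  list(n_max = n_max, h_window = h_window, h_gate = h_gate, h_scale = h_scale,
       c_search = c_search, small_residues = small_residues, lipobox = lipobox,
       primary_cutoff = primary_cutoff, fallback_cutoff = fallback_cutoff,
       w_n = w_n, w_h = w_h, w_c = w_c)
}

#' Score a protein for an N-terminal export signal
#'
#' @param protein Character scalar (must be at least 15 aa for a non-zero
#'   score).
#' @param params See [signal_params()].
#' @return List with `score` in [0, 1], `cleavage` (1-based position of the
#'   last signal residue; mature region starts at `cleavage + 1`), `pathway`
#'   (`"SPI"`, `"SPII"` or `"none"`), and `h_end` (1-based end of the
#'   h-region, `NA` when no hydrophobic region passes the gate).
#' @export
score_signal_peptide <- function(protein, params = signal_params()) {
  len <- nchar(protein)
  none <- list(score = 0, cleavage = NA_integer_, pathway = "none",
               h_end = NA_integer_)
  if (len < 15) return(none)
  ch <- aa_chars(protein)
  kd <- kyte_doolittle()[ch]
  W <- params$h_window
  wins <- vapply(seq_len(len - W + 1L), function(i) mean(kd[i:(i + W - 1L)]), 0)
  maxwin <- max(wins)
  if (maxwin < params$h_gate) return(none)
  h_end <- which.max(wins) + W - 1L
  h_score <- clamp01((maxwin - params$h_gate) / params$h_scale)
  n_score <- as.numeric(grepl("KK", substr(protein, 1, params$n_max), fixed = TRUE))

  # SPII: lipobox with invariant Cys around the end of the h-region
  lo <- max(1L, h_end - 3L)
  hi <- min(len, h_end + 8L)
  m <- regexpr(params$lipobox, substr(protein, lo, hi), perl = TRUE)
  spii <- m[1] != -1L
  c_score <- 0; cleavage <- NA_integer_
  if (spii) {
    cys <- lo + m[1] - 1L + attr(m, "match.length") - 1L  # position of Cys
    cleavage <- cys - 1L
    c_score <- 1
  } else {
    for (q in (h_end + 1L):min(len - 2L, h_end + params$c_search)) {
      if (q < 1L || q + 2L > len) next
      if (ch[q] %in% params$small_residues && ch[q + 2L] %in% params$small_residues) {
        c_score <- 1; cleavage <- q + 2L; break
      }
    }
    if (is.na(cleavage)) cleavage <- min(h_end + 6L, len)
  }
  score <- params$w_n * n_score + params$w_h * h_score + params$w_c * c_score
  pathway <- if (score < params$fallback_cutoff) "none" else if (spii) "SPII" else "SPI"
  list(score = score, cleavage = as.integer(cleavage), pathway = pathway,
       h_end = as.integer(h_end))
}

# translate all six frames of a window into between-stop peptide segments
# (with their coordinate bookkeeping); used by the SHP fallback
six_frame_segments <- function(window, min_len = 10) {
  n <- nchar(window$seq)
  segs <- list()
  for (str in c("+", "-")) {
    S <- if (str == "+") window$seq else revcomp(window$seq)
    for (f in 0:2) {
      ncf <- (nchar(S) - f) %/% 3L
      if (ncf < 1L) next
      aa <- translate_dna(substr(S, f + 1L, f + 3L * ncf))
      parts <- strsplit(aa, "*", fixed = TRUE)[[1]]
      c0 <- 0L # codon offset of current part within the frame
      for (p in parts) {
        if (nchar(p) > min_len) {
          a <- f + 3L * c0
          b <- f + 3L * (c0 + nchar(p))
          aa0 <- a; bb0 <- b
          if (str == "-") { aa0 <- n - b; bb0 <- n - a }
          segs[[length(segs) + 1L]] <- list(peptide = p, win_start = aa0,
                                            win_end = bb0, win_strand = str,
                                            frame = f, codon0 = c0)
        }
        c0 <- c0 + nchar(p) + 1L
      }
    }
  }
  segs
}

#' Six-frame fallback search for SHP-like propeptides
#'
#' Translates all six frames of the window, keeps peptides longer than 10 aa
#' between stop codons, and aligns each against each known mature peptide by
#' exact dynamic programming.  Matches with identity > 80% over an aligned
#' span covering > 85% of the known peptide are returned as propeptide calls
#' (`predictor = "shp_match"`, `pathway = "none"`).
#'
#' @param window A `flank_window` (or whole-replicon pseudo-window).
#' @param known_peptides Character vector of known mature peptides.
#' @param min_identity,min_coverage Retention thresholds (strict inequalities).
#' @param predictor Predictor label stored on the calls.
#' @return data.frame of propeptide calls (possibly empty).
#' @export
shp_fallback_search <- function(window, known_peptides,
                                min_identity = 0.8, min_coverage = 0.85,
                                predictor = "shp_match") {
  if (length(known_peptides) == 0L) return(empty_calls())
  segs <- six_frame_segments(window, min_len = 10)
  out <- list()
  for (sg in segs) {
    enc_c <- encode_aa(sg$peptide)
    for (kp in known_peptides) {
      al <- pair_align_cpp(enc_c, encode_aa(kp), 1, -1, 2, 1, TRUE)
      span_known <- al$b_end - al$b_start + 1L
      if (span_known <= 0) next
      identity <- al$n_ident / span_known
      coverage <- span_known / nchar(kp)
      if (identity > min_identity && coverage > min_coverage) {
        # nt coords of the matched candidate segment
        a_cod <- sg$codon0 + al$a_start - 1L
        b_cod <- sg$codon0 + al$a_end
        a <- sg$frame + 3L * a_cod
        b <- sg$frame + 3L * b_cod
        n <- nchar(window$seq)
        if (sg$win_strand == "-") { tmp <- a; a <- n - b; b <- n - tmp }
        map <- map_window_span(window, a, b, sg$win_strand)
        out[[length(out) + 1L]] <- cbind(
          data.frame(side = window$side, protein = sg$peptide,
                     score = identity, cleavage = NA_integer_,
                     pathway = "none", predictor = predictor,
                     mature = substr(sg$peptide, al$a_start, al$a_end),
                     matched_known = kp, stringsAsFactors = FALSE),
          map)
        break
      }
    }
  }
  if (length(out) == 0L) return(empty_calls())
  calls <- do.call(rbind, out)
  calls[order(-calls$score, calls$rep_start), , drop = FALSE]
}

empty_calls <- function() {
  data.frame(side = character(), protein = character(), score = numeric(),
             cleavage = integer(), pathway = character(), predictor = character(),
             mature = character(), matched_known = character(),
             rep_start = integer(), rep_end = integer(), rep_strand = character(),
             wrapped = logical(), stringsAsFactors = FALSE)
}

#' Plasmid-wide SHP search
#'
#' Applies the six-frame known-peptide search to an entire plasmid replicon,
#' used for PrgX whose pheromone genes are usually not adjacent to the
#' receptor gene.
#'
#' @param replicon Character scalar replicon sequence.
#' @param known_peptides Known mature peptides.
#' @param replicon_type Replicon context label; must be `"plasmid"` or
#'   `"phage_plasmid"`.
#' @param replicon_id Identifier stored on the calls.
#' @return data.frame of propeptide calls (`predictor = "plasmid_wide"`).
#' @export
plasmid_wide_search <- function(replicon, known_peptides,
                                replicon_type = "plasmid",
                                replicon_id = "plasmid") {
  if (!replicon_type %in% c("plasmid", "phage_plasmid"))
    stop("plasmid-wide search requires a plasmid or phage-plasmid replicon, got '",
         replicon_type, "'", call. = FALSE)
  win <- make_window(replicon_id, "plasmid_wide", replicon,
                     seq.int(0L, nchar(replicon) - 1L), FALSE, "+")
  shp_fallback_search(win, known_peptides, predictor = "plasmid_wide")
}

#' Call candidate propeptides around one receptor gene
#'
#' Implements the full decision cascade: score all small ORFs of the
#' downstream then upstream flank windows with the primary signal cutoff; if
#' none passes, retry at the 0.25 fallback cutoff.  For the SHP-class
#' families the known-peptide route additionally always runs: the upstream
#' six-frame search for Rgg/ComR and the plasmid-wide search for PrgX on
#' plasmid replicons (their peptides carry no canonical signal, so a spurious
#' signal-based call must not mask them).  ORFs overlapping the receptor gene
#' by more than the shared 50 nt are discarded, and calls are deduplicated by
#' coordinates.
#'
#' @param receptor List/row with `protein_id`, `family`, `replicon`, `start`,
#'   `end`, `strand`.
#' @param replicons Named character vector of replicon sequences.
#' @param params [signal_params()].
#' @param known_peptides Optional data.frame with columns `family`, `peptide`.
#' @param replicon_types Named character vector of replicon context labels
#'   (`"chromosome"`, `"plasmid"`, `"phage_plasmid"`); defaults to chromosome.
#' @param circular Named logical vector (or single value) marking circular
#'   replicons.
#' @return data.frame of propeptide calls with a `receptor_id` column.
#' @export
call_propeptides <- function(receptor, replicons, params = signal_params(),
                             known_peptides = NULL, replicon_types = NULL,
                             circular = FALSE) {
  rid <- receptor$replicon
  if (!rid %in% names(replicons))
    stop("receptor replicon '", rid, "' not found", call. = FALSE)
  repl <- replicons[[rid]]
  if (receptor$start < 0 || receptor$end > nchar(repl))
    stop("receptor coordinates outside replicon", call. = FALSE)
  circ <- if (length(circular) > 1L) isTRUE(circular[[rid]]) else isTRUE(circular)
  wins <- build_flank_windows(receptor, repl, replicon_id = rid, circular = circ)

  fam_known <- character()
  if (!is.null(known_peptides) && nrow(known_peptides) > 0L)
    fam_known <- unique(known_peptides$peptide[known_peptides$family == receptor$family])

  score_window <- function(win, cutoff) {
    orfs <- find_orfs(win)
    if (nrow(orfs) == 0L) return(empty_calls())
    # discard ORFs overlapping the receptor gene beyond the shared 50 nt
    ov <- pmin(orfs$rep_end, receptor$end) - pmax(orfs$rep_start, receptor$start)
    orfs <- orfs[ov <= 50, , drop = FALSE]
    if (nrow(orfs) == 0L) return(empty_calls())
    res <- lapply(orfs$protein, score_signal_peptide, params = params)
    keep <- vapply(res, function(r) r$score >= cutoff, TRUE)
    if (!any(keep)) return(empty_calls())
    orfs <- orfs[keep, , drop = FALSE]
    res <- res[keep]
    data.frame(side = win$side, protein = orfs$protein,
               score = vapply(res, `[[`, 0, "score"),
               cleavage = vapply(res, `[[`, 0L, "cleavage"),
               pathway = vapply(res, `[[`, "", "pathway"),
               predictor = NA_character_,
               mature = substr(orfs$protein,
                               pmax(1L, nchar(orfs$protein) - 6L),
                               nchar(orfs$protein)),
               matched_known = NA_character_,
               rep_start = orfs$rep_start, rep_end = orfs$rep_end,
               rep_strand = orfs$rep_strand, wrapped = orfs$wrapped,
               stringsAsFactors = FALSE)
  }

  calls <- empty_calls()
  for (pass in c("primary", "fallback")) {
    cutoff <- if (pass == "primary") params$primary_cutoff else params$fallback_cutoff
    calls <- rbind(score_window(wins$downstream, cutoff),
                   score_window(wins$upstream, cutoff))
    if (nrow(calls) > 0L) { calls$predictor <- pass; break }
  }
  # The SHP-class families (Rgg, ComR, PrgX) encode peptides without a
  # canonical export signal, so the known-peptide route always runs for them:
  # a spurious signal-based fallback call must not mask the real pheromone.
  if (receptor$family %in% c("Rgg", "ComR")) {
    calls <- rbind(calls, shp_fallback_search(wins$upstream, fam_known))
  }
  if (receptor$family == "PrgX") {
    rtype <- if (!is.null(replicon_types) && rid %in% names(replicon_types))
      replicon_types[[rid]] else "chromosome"
    if (rtype %in% c("plasmid", "phage_plasmid"))
      calls <- rbind(calls, plasmid_wide_search(repl, fam_known, rtype, rid))
  }
  if (nrow(calls) > 0L) {
    key <- paste(calls$rep_start, calls$rep_end, calls$rep_strand)
    calls <- calls[!duplicated(key), , drop = FALSE]
    calls <- calls[order(-calls$score, calls$rep_start), , drop = FALSE]
  }
  cbind(data.frame(receptor_id = if (nrow(calls)) receptor$protein_id else character(),
                   family = if (nrow(calls)) receptor$family else character(),
                   stringsAsFactors = FALSE),
        calls)
}
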