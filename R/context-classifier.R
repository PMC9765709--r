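# Genomic context assignment (chromosome / prophage / plasmid /
# phage-plasmid), signaling-role classification (eavesdropper / single /
# chatterer / multi-message), and the family-by-context summary table.

#' Assign the genomic context of a receptor gene
#'
#' Plasmid and phage-plasmid labels come from replicon-level rows of the MGE
#' table; a gene is in a prophage only when fully contained in a retained
#' prophage interval; everything else is chromosome.  Prophage intervals on
#' one replicon must not overlap.
#'
#' @param gene List/row with `replicon`, `start`, `end`.
#' @param mge data.frame with columns replicon, type
#'   (`"prophage"`/`"plasmid"`/`"phage_plasmid"`), start, end (0-based,
#'   half-open; interval ignored for replicon-level types).
#' @param known_replicons Optional character vector of valid replicon ids;
#'   genes on unknown replicons raise an error when it is supplied.
#' @return One of `"chromosome"`, `"prophage"`, `"plasmid"`, `"phage_plasmid"`.
#' @export
assign_context <- function(gene, mge, known_replicons = NULL) {
  if (!is.null(known_replicons) && !gene$replicon %in% known_replicons)
    stop("gene on unknown replicon '", gene$replicon, "'", call. = FALSE)
  m <- mge[mge$replicon == gene$replicon, , drop = FALSE]
  if (nrow(m) == 0L) return("chromosome")
  lev <- m$type[m$type %in% c("plasmid", "phage_plasmid")]
  if (length(lev)) return(lev[1])
  ph <- m[m$type == "prophage", , drop = FALSE]
  if (nrow(ph) > 1L) {
    ph <- ph[order(ph$start), , drop = FALSE]
    if (any(ph$start[-1] < ph$end[-nrow(ph)]))
      stop("overlapping prophage intervals on replicon '", gene$replicon, "'",
           call. = FALSE)
  }
  contained <- ph$start <= gene$start & gene$end <= ph$end
  if (any(contained)) "prophage" else "chromosome"
}

#' Classify the signaling role of one system
#'
#' A system with no propeptide call is an eavesdropper.  A system producing
#' at least two identical copies of a mature peptide (within one propeptide
#' or across sibling genes) is a chatterer; chatterer takes precedence over
#' multi-message when both identical copies and a distinct variant exist.  A
#' system with at least two distinct mature peptides is multi-message;
#' otherwise it is single.
#'
#' @param mature_lists List with one character vector of mature-peptide
#'   copies per propeptide call (e.g. from [detect_repeats()] positions, or
#'   the planted truth); empty list means no calls.
#' @return One of `"eavesdropper"`, `"chatterer"`, `"multi_message"`,
#'   `"single"`.
#' @export
classify_role <- function(mature_lists) {
  if (length(mature_lists) == 0L) return("eavesdropper")
  all_m <- unlist(mature_lists)
  if (length(all_m) == 0L) return("eavesdropper")
  if (any(table(all_m) >= 2L)) return("chatterer")
  if (length(unique(all_m)) >= 2L) return("multi_message")
  "single"
}

#' Family-by-context summary of classified systems
#'
#' @param systems data.frame with columns `family`, `context`, `role`, and
#'   `n_propeptides`; optional `genus` column enables equal-weight-per-genus
#'   normalization.
#' @param normalize_genus Average per-genus instead of pooling, giving each
#'   genus equal weight (labelled in the output).
#' @return data.frame per family and context: n, pct_with_propeptide,
#'   pct_eavesdropper, and the normalization mode used.
#' @export
summarize_systems <- function(systems, normalize_genus = FALSE) {
  cols <- c("family", "context", "role", "n_propeptides")
  if (nrow(systems) == 0L)
    return(data.frame(family = character(), context = character(), n = integer(),
                      pct_with_propeptide = numeric(), pct_eavesdropper = numeric(),
                      normalization = character(), stringsAsFactors = FALSE))
  stopifnot(all(cols %in% names(systems)))
  key <- interaction(systems$family, systems$context, drop = TRUE)
  rows <- lapply(split(systems, key), function(s) {
    stat <- function(v) {
      if (normalize_genus && "genus" %in% names(s)) {
        mean(tapply(v, s$genus, mean))
      } else mean(v)
    }
    data.frame(family = s$family[1], context = s$context[1], n = nrow(s),
               pct_with_propeptide = 100 * stat(s$n_propeptides > 0),
               pct_eavesdropper = 100 * stat(s$role == "eavesdropper"),
               normalization = if (normalize_genus) "equal_weight_per_genus" else "pooled",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$family, out$context), , drop = FALSE]
}
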