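# End-to-end orchestration: profile building and calibration, proteome
# scanning, family assignment with the Rap/NprR and Rgg rules, propeptide
# calling, repeat analysis, and context/role classification.

#' Build and calibrate scoring models for a set of families
#'
#' Uses the package's synthetic seed alignments; for real analyses pass your
#' own alignments to [build_profile()] and calibrate them directly.
#'
#' @param families Families to model.
#' @param seed Integer seed for seed-alignment generation and calibration.
#' @param n_decoys,decoy_length Calibration parameters.
#' @return Named list of calibrated `qs_profile` objects.
#' @export
build_family_profiles <- function(families = qs_families(), seed = 1L,
                                  n_decoys = 500, decoy_length = 350) {
  profs <- lapply(families, function(f) {
    m <- build_profile(family_seed_alignment(f, seed = seed), family = f)
    calibrate_profile(m, n_decoys = n_decoys, decoy_length = decoy_length,
                      seed = child_seed(seed, f))
  })
  stats::setNames(profs, families)
}

#' Run the full receptor-pheromone discovery pipeline on a genome bundle
#'
#' Scans the proteome with every family model, assigns subfamilies (Rap hits
#' also passing NprR become NprR; Rgg hits without a confirmed propeptide are
#' dropped), calls propeptides around every receptor via the window/ORF/
#' signal cascade, runs repeat detection on the calls, and classifies genomic
#' context and signaling role per system.
#'
#' @param bundle Genome bundle ([generate_genome()] / [read_genome_bundle()]).
#' @param profiles Named list of calibrated models; built from the synthetic
#'   seed alignments when `NULL`.
#' @param thresholds [default_thresholds()].
#' @param params [signal_params()].
#' @param seed Seed used when `profiles` is `NULL`.
#' @return List with `hits` (all threshold-passing model hits), `receptors`
#'   (assigned, with coordinates), `calls` (propeptide calls), `systems`
#'   (one row per receptor with context and role) and `summary`
#'   (family-by-context table).
#' @export
run_qs_pipeline <- function(bundle, profiles = NULL,
                            thresholds = default_thresholds(),
                            params = signal_params(), seed = 1L) {
  families <- if (!is.null(profiles)) names(profiles) else
    unique(if (!is.null(bundle$config)) bundle$config$families else qs_families())
  if (is.null(profiles)) profiles <- build_family_profiles(families, seed = seed)

  hits <- do.call(rbind, lapply(profiles, function(m)
    scan_proteome(bundle$proteome, m, thresholds)))
  rownames(hits) <- NULL

  provisional <- assign_family(hits)
  genes <- bundle$genes
  idx <- match(provisional$protein_id, genes$locus_tag)
  provisional$replicon <- genes$replicon[idx]
  provisional$start <- genes$start[idx]
  provisional$end <- genes$end[idx]
  provisional$strand <- genes$strand[idx]
  provisional <- provisional[!is.na(provisional$start), , drop = FALSE]

  replicon_types <- replicon_type_map(bundle$mge, names(bundle$replicons))

  calls <- lapply(seq_len(nrow(provisional)), function(i) {
    r <- provisional[i, ]
    call_propeptides(list(protein_id = r$protein_id, family = r$family,
                          replicon = r$replicon, start = r$start, end = r$end,
                          strand = r$strand),
                     bundle$replicons, params = params,
                     known_peptides = bundle$known_peptides,
                     replicon_types = replicon_types,
                     circular = bundle$circular)
  })
  calls <- do.call(rbind, calls)
  confirmed <- unique(calls$receptor_id)

  receptors <- assign_family(hits, confirmed_propeptide_ids = confirmed)
  idx <- match(receptors$protein_id, genes$locus_tag)
  receptors$replicon <- genes$replicon[idx]
  receptors$start <- genes$start[idx]
  receptors$end <- genes$end[idx]
  receptors$strand <- genes$strand[idx]
  receptors <- receptors[!is.na(receptors$start), , drop = FALSE]
  calls <- calls[calls$receptor_id %in% receptors$protein_id, , drop = FALSE]

  systems <- lapply(seq_len(nrow(receptors)), function(i) {
    r <- receptors[i, ]
    cc <- calls[calls$receptor_id == r$protein_id, , drop = FALSE]
    mature_lists <- lapply(seq_len(nrow(cc)), function(k)
      call_mature_copies(cc[k, ]))
    data.frame(receptor_id = r$protein_id, family = r$family,
               replicon = r$replicon, start = r$start, end = r$end,
               strand = r$strand,
               context = assign_context(list(replicon = r$replicon,
                                             start = r$start, end = r$end),
                                        bundle$mge),
               role = classify_role(mature_lists),
               n_propeptides = nrow(cc),
               reassigned_from = r$reassigned_from,
               stringsAsFactors = FALSE)
  })
  systems <- if (length(systems)) do.call(rbind, systems) else
    data.frame(receptor_id = character(), family = character(),
               replicon = character(), start = integer(), end = integer(),
               strand = character(), context = character(), role = character(),
               n_propeptides = integer(), reassigned_from = character(),
               stringsAsFactors = FALSE)
  rownames(systems) <- NULL
  list(hits = hits, receptors = receptors, calls = calls, systems = systems,
       summary = summarize_systems(systems))
}

# replicon-level context labels from the MGE table
replicon_type_map <- function(mge, replicon_ids) {
  types <- stats::setNames(rep("chromosome", length(replicon_ids)), replicon_ids)
  lev <- mge[mge$type %in% c("plasmid", "phage_plasmid"), , drop = FALSE]
  types[lev$replicon] <- lev$type
  types
}

# mature-peptide copies implied by one propeptide call: the repeat-detector
# copies when the call carries >= 2, else the call's mature peptide
call_mature_copies <- function(call) {
  if (call$predictor %in% c("shp_match", "plasmid_wide") || nchar(call$protein) < 10L)
    return(call$mature)
  rep_report <- detect_repeats(call$protein)
  if (rep_report$copy_count >= 2L) {
    vapply(rep_report$positions, function(p)
      substr(call$protein, p, p + nchar(rep_report$seed) - 1L), "")
  } else call$mature
}
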