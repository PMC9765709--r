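# Synthetic genomes with planted RRNPPA systems.
#
# Each planted system occupies a self-contained 7 kb "slot": the receptor
# gene sits at a fixed offset with its propeptide gene(s) planted inside the
# 50 + 1,000 nt flank windows that the finder will later reconstruct, so every
# plant is recoverable in principle.  Slots are assembled on the forward
# strand and reverse-complemented wholesale for '-' strand systems, which
# keeps the coordinate bookkeeping honest on both strands.  Background DNA is
# i.i.d. uniform over ACGT; all coordinates are 0-based, half-open.

SLOT_NT <- 7000L
RECEPTOR_AT <- 2500L
PLASMID_NT <- 20000L

# residues used for planted mature peptides: polar-biased so that a mature
# region can never out-score the planted hydrophobic h-region (max KD 1.8,
# below the 2.0 gate)
mature_alphabet <- function() strsplit("ADEGHKNPQRSTWY", "")[[1]]

#' Configuration of a synthetic genome simulation
#'
#' Defaults describe the package's stated simulation world: 7 families times
#' 20 systems at receptor mutation rate 0.1, with 20% eavesdroppers, 10%
#' sibling propeptide pairs, 10% SPII (lipoprotein-type) export, 20% of
#' chromosomal systems inside planted prophages and 15% of systems on
#' plasmid-type replicons (a quarter of which are labeled phage-plasmids).
#'
#' @param n_replicons Number of chromosomal replicons.
#' @param replicon_length Chromosomal replicon length (nt); must be at least
#'   twice the planted-system slot span.
#' @param families Families to plant (subset of [qs_families()]).
#' @param systems_per_family Systems planted per family.
#' @param eavesdropper_fraction Probability a system lacks propeptide genes
#'   (never applied to Rgg, whose family definition requires a pheromone).
#' @param repeat_copy_range Integer interval within \[1, 6\] for mature-peptide
#'   copy numbers of multi-copy plants.
#' @param sibling_gene_probability Probability of a second propeptide gene.
#' @param spii_fraction Probability of SPII (lipobox) export for
#'   signal-bearing families.
#' @param mutation_rate Receptor substitutions per residue vs the family
#'   consensus.
#' @param prophage_fraction Probability a chromosomal system lies inside a
#'   planted prophage interval.
#' @param plasmid_fraction Probability a system sits on its own plasmid
#'   replicon (PrgX systems are always plasmid-borne).
#' @param multi_copy_fraction Probability a propeptide carries more than one
#'   mature copy; copy number then drawn uniformly from `repeat_copy_range`
#'   above 1.
#' @param variant_fraction Probability a multi-copy propeptide carries one
#'   pseudorepeated (single-mismatch) copy.
#' @param n_decoy_rgg Number of planted MutR/GadR-like decoy receptors
#'   (Rgg-model hits without any QS propeptide).
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_replicons = 20, replicon_length = 60000,
                       families = qs_families(), systems_per_family = 20,
                       eavesdropper_fraction = 0.2,
                       repeat_copy_range = c(1L, 6L),
                       sibling_gene_probability = 0.1,
                       spii_fraction = 0.1, mutation_rate = 0.1,
                       prophage_fraction = 0.2, plasmid_fraction = 0.15,
                       multi_copy_fraction = 0.3, variant_fraction = 0.3,
                       n_decoy_rgg = 2, seed = 1L) {
  probs <- c(eavesdropper_fraction, sibling_gene_probability, spii_fraction,
             prophage_fraction, plasmid_fraction, multi_copy_fraction,
             variant_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]", call. = FALSE)
  if (mutation_rate < 0 || mutation_rate > 1)
    stop("mutation_rate must lie in [0,1]", call. = FALSE)
  rr <- as.integer(repeat_copy_range)
  if (length(rr) != 2L || rr[1] < 1L || rr[2] > 6L || rr[1] > rr[2])
    stop("repeat_copy_range must be an integer interval within [1,6]", call. = FALSE)
  if (!all(families %in% qs_families()))
    stop("unknown family in `families`", call. = FALSE)
  if (replicon_length < 2L * SLOT_NT)
    stop("replicon_length (", replicon_length, ") below twice the planted-gene span (",
         2L * SLOT_NT, " nt)", call. = FALSE)
  structure(list(n_replicons = as.integer(n_replicons),
                 replicon_length = as.integer(replicon_length),
                 families = families,
                 systems_per_family = as.integer(systems_per_family),
                 eavesdropper_fraction = eavesdropper_fraction,
                 repeat_copy_range = rr,
                 sibling_gene_probability = sibling_gene_probability,
                 spii_fraction = spii_fraction, mutation_rate = mutation_rate,
                 prophage_fraction = prophage_fraction,
                 plasmid_fraction = plasmid_fraction,
                 multi_copy_fraction = multi_copy_fraction,
                 variant_fraction = variant_fraction,
                 n_decoy_rgg = as.integer(n_decoy_rgg),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate one synthetic pheromone precursor
#'
#' Builds a propeptide with the planted n/h/c export-signal architecture:
#' `MKK` + polar n-region, an 8-residue hydrophobic h-region, a conserved
#' post-h residue (V for Rap, G otherwise), then either an `AQA` cleavage
#' motif (SPI) or a `LAGC` lipobox ending at the invariant Cys (SPII),
#' followed by `n_copies` tandem copies of the mature peptide, the last one
#' forming the C terminus.  `pathway = "none"` instead yields a short
#' SHP-style peptide (start codon + polar body + C-terminal mature) with no
#' canonical signal, emulating the Rgg/ComR/PrgX peptide class.
#'
#' @param family Family name (drives the conserved post-h residue).
#' @param n_copies Mature-peptide copies, in \[1, 6\].
#' @param variant_position Optional 1-based position within the mature
#'   peptide; when given (requires `n_copies >= 2`) the first copy carries a
#'   single substitution there, creating a pseudorepeat.
#' @param pathway `"SPI"`, `"SPII"` or `"none"`.
#' @param seed Integer seed.
#' @param mature Optional mature peptide; drawn from the polar mature
#'   alphabet when `NULL` (7 aa, or 8 aa for the SHP class).
#' @return List with `dna` (ORF including the stop codon), `protein`,
#'   `matures` (copies in order), `mature` (the canonical last copy),
#'   `cleavage` (1-based last signal residue, `NA` for SHP) and `pathway`.
#' @export
generate_propeptide <- function(family, n_copies = 1, variant_position = NULL,
                                pathway = c("SPI", "SPII", "none"), seed = 1L,
                                mature = NULL) {
  pathway <- match.arg(pathway)
  n_copies <- as.integer(n_copies)
  if (n_copies < 1L || n_copies > 6L)
    stop("n_copies must lie in [1,6]", call. = FALSE)
  if (!is.null(variant_position) && n_copies < 2L)
    stop("variant_position requires n_copies >= 2", call. = FALSE)
  with_seed(child_seed(seed, paste0("prop", family, pathway, n_copies)), {
    ma <- mature_alphabet()
    if (pathway == "none") {
      if (is.null(mature)) mature <- paste(sample(ma, 8, replace = TRUE), collapse = "")
      body <- paste(sample(c("S", "T", "N", "Q", "G", "P", "H", "Y", "D", "E"),
                           12, replace = TRUE), collapse = "")
      protein <- paste0("M", body, mature)
      matures <- mature
      cleavage <- NA_integer_
    } else {
      if (is.null(mature)) mature <- paste(sample(ma, 7, replace = TRUE), collapse = "")
      matures <- rep(mature, n_copies)
      if (!is.null(variant_position)) {
        vp <- as.integer(variant_position)
        if (vp < 1L || vp > nchar(mature))
          stop("variant_position outside the mature peptide", call. = FALSE)
        ch <- aa_chars(mature)
        ch[vp] <- sample(setdiff(ma, ch[vp]), 1L)
        matures[1] <- paste(ch, collapse = "")
      }
      nreg <- paste0("MKK", paste(sample(c("S", "T", "N", "Q"), 3, replace = TRUE),
                                  collapse = ""))
      hreg <- if (family == "Rap") strrep("I", 8)
              else paste(sample(c("I", "L"), 8, replace = TRUE), collapse = "")
      post_h <- if (family == "Rap") "V" else "G"
      if (pathway == "SPI") {
        signal <- paste0(nreg, hreg, post_h, "AQA")
        cleavage <- nchar(signal)
      } else {
        signal <- paste0(nreg, hreg, "LAGC")
        cleavage <- nchar(signal) - 1L # cleaved before the invariant Cys
      }
      protein <- paste0(signal, paste(matures, collapse = ""))
    }
    if (nchar(protein) > 120L)
      stop("propeptide length ", nchar(protein),
           " aa exceeds the 120 aa budget (n_copies x mature length too large)",
           call. = FALSE)
    if (nchar(protein) < 20L && pathway != "none")
      stop("propeptide shorter than 20 aa", call. = FALSE)
    list(dna = paste0(reverse_translate(protein), "TAA"), protein = protein,
         matures = matures, mature = matures[length(matures)],
         cleavage = cleavage, pathway = pathway)
  })
}

# splice `insert` into `dna` replacing [at, at + nchar(insert)) (0-based)
splice_dna <- function(dna, at, insert) {
  paste0(substr(dna, 1L, at), insert, substr(dna, at + nchar(insert) + 1L, nchar(dna)))
}

# draw per-system architecture; the first five uniforms are, in order:
# strand, context, phage-plasmid split, eavesdropper, sibling (documented so
# tests can replay the stream)
draw_system <- function(config, family, i) {
  with_seed(child_seed(config$seed, paste0("sys_", family, "_", i)), {
    u <- stats::runif(5)
    strand <- if (u[1] < 0.5) "+" else "-"
    if (family == "PrgX") {
      context <- if (u[3] < 0.25) "phage_plasmid" else "plasmid"
    } else if (u[2] < config$plasmid_fraction) {
      context <- if (u[3] < 0.25) "phage_plasmid" else "plasmid"
    } else if (u[2] < config$plasmid_fraction + config$prophage_fraction) {
      context <- "prophage"
    } else context <- "chromosome"
    eaves <- u[4] < config$eavesdropper_fraction && family != "Rgg"
    sibling <- !eaves && u[5] < config$sibling_gene_probability &&
      family %in% c("Rap", "NprR", "PlcR", "AimR")
    multi <- stats::runif(1) < config$multi_copy_fraction
    n_copies <- if (multi && config$repeat_copy_range[2] > 1L)
      sample(seq.int(max(2L, config$repeat_copy_range[1]),
                     config$repeat_copy_range[2]), 1L) else 1L
    variant <- multi && n_copies >= 2L && stats::runif(1) < config$variant_fraction
    spii <- stats::runif(1) < config$spii_fraction
    pathway <- if (family %in% c("Rgg", "ComR", "PrgX")) "none"
               else if (spii) "SPII" else "SPI"
    side <- if (stats::runif(1) < 0.5) "downstream" else "upstream"
    if (family %in% c("Rgg", "ComR")) side <- "upstream"
    list(strand = strand, context = context, eavesdropper = eaves,
         sibling = sibling, n_copies = if (pathway == "none") 1L else n_copies,
         variant = variant && pathway != "none", spii = spii,
         pathway = pathway, side = side)
  })
}

# assemble one system slot on the forward strand, then flip if needed
build_slot <- function(config, family, i, arch, sys_id) {
  with_seed(child_seed(config$seed, paste0("slot_", family, "_", i)), {
    rec_prot <- mutate_protein(family_consensus(family), config$mutation_rate)
    rec_dna <- paste0(reverse_translate(rec_prot), "TAA")
    rec_start <- RECEPTOR_AT
    rec_end <- rec_start + nchar(rec_dna)
    slot <- random_dna(SLOT_NT)
    slot <- splice_dna(slot, rec_start, rec_dna)

    props <- list()
    place <- function(pp, side) {
      orf_nt <- nchar(pp$dna)
      dmax <- 1000L - orf_nt - 30L
      d <- sample(seq.int(60L, dmax), 1L)
      if (side == "downstream") start <- rec_end + d
      else start <- rec_start - d - orf_nt
      # in-frame stop immediately before the start codon pins the ORF start
      slot <<- splice_dna(slot, start - 3L, paste0("TAA", pp$dna))
      c(list(start = start, end = start + orf_nt, side = side), pp)
    }
    if (!arch$eavesdropper && family != "PrgX") {
      pp <- generate_propeptide(family, arch$n_copies,
                                variant_position = if (arch$variant) 5L else NULL,
                                pathway = arch$pathway,
                                seed = child_seed(config$seed, paste0("pp_", sys_id)))
      props[[1]] <- place(pp, arch$side)
      if (arch$sibling) {
        sib_identical <- stats::runif(1) < 0.2
        mat2 <- if (sib_identical) pp$mature else {
          ch <- aa_chars(pp$mature)
          vp <- sample(c(5L, 6L), 1L)
          ch[vp] <- sample(setdiff(mature_alphabet(), ch[vp]), 1L)
          paste(ch, collapse = "")
        }
        pp2 <- generate_propeptide(family, 1L, pathway = arch$pathway,
                                   seed = child_seed(config$seed, paste0("ppb_", sys_id)),
                                   mature = mat2)
        other <- if (arch$side == "downstream") "upstream" else "downstream"
        props[[2]] <- place(pp2, other)
      }
    }
    bg_prot <- random_protein(150)
    bg_dna <- paste0(reverse_translate(bg_prot), "TAA")
    slot <- splice_dna(slot, 5200L, bg_dna)
    genes <- data.frame(start = c(rec_start, 5200L),
                        end = c(rec_end, 5200L + nchar(bg_dna)),
                        strand = "+", protein = c(rec_prot, bg_prot),
                        role = c("receptor", "background"),
                        stringsAsFactors = FALSE)
    if (identical(arch$strand, "-")) {
      slot <- revcomp(slot)
      flip <- function(s, e) c(SLOT_NT - e, SLOT_NT - s)
      for (k in seq_len(nrow(genes))) {
        fe <- flip(genes$start[k], genes$end[k])
        genes$start[k] <- fe[1]; genes$end[k] <- fe[2]
      }
      genes$strand <- "-"
      props <- lapply(props, function(p) {
        fe <- flip(p$start, p$end); p$start <- fe[1]; p$end <- fe[2]; p
      })
    }
    list(dna = slot, genes = genes, props = props, strand = arch$strand)
  })
}

truth_role <- function(arch, props) {
  if (length(props) == 0L) return("eavesdropper")
  all_matures <- unlist(lapply(props, `[[`, "matures"))
  counts <- table(all_matures)
  if (any(counts >= 2L)) return("chatterer")
  if (length(unique(all_matures)) >= 2L) return("multi_message")
  "single"
}

#' Generate a synthetic genome bundle with planted ground truth
#'
#' Emits replicon sequences, a CDS gene table (receptor and background genes;
#' propeptide ORFs are deliberately left unannotated, as in real genomes), a
#' proteome, an MGE label table (prophage intervals, plasmid and
#' phage-plasmid replicon labels), a known-mature-peptide table for the
#' SHP-class families, and the planted truth.
#'
#' @param config A [sim_config()].
#' @return A list (`qs_genome` bundle) with elements `replicons`, `genes`,
#'   `proteome`, `mge`, `known_peptides`, `truth` (list of data.frames
#'   `systems`, `propeptides`, `decoys`), `circular`, and `config`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  # last slot-width stretch of each chromosome is reserved for decoy genes
  capacity <- config$replicon_length %/% SLOT_NT - 1L
  chrom_ids <- paste0("chrom_", sprintf("%02d", seq_len(config$n_replicons)))

  systems <- list()
  for (family in config$families) {
    for (i in seq_len(config$systems_per_family)) {
      sys_id <- paste0(family, "_", sprintf("%03d", i))
      arch <- draw_system(config, family, i)
      slot <- build_slot(config, family, i, arch, sys_id)
      systems[[sys_id]] <- list(id = sys_id, family = family, arch = arch,
                                slot = slot)
    }
  }

  chrom_sys <- Filter(function(s) s$arch$context %in% c("chromosome", "prophage"),
                      systems)
  plas_sys <- Filter(function(s) s$arch$context %in% c("plasmid", "phage_plasmid"),
                     systems)
  if (length(chrom_sys) > capacity * config$n_replicons)
    stop("replicons too short for requested systems: need ",
         length(chrom_sys), " chromosomal slots but capacity is ",
         capacity * config$n_replicons, call. = FALSE)

  replicons <- list(); mge <- list(); genes <- list(); truth_sys <- list()
  truth_prop <- list(); known <- list(); decoys <- list()

  chrom_dna <- with_seed(child_seed(config$seed, "chromdna"),
                         lapply(chrom_ids, function(id) random_dna(config$replicon_length)))
  names(chrom_dna) <- chrom_ids

  # pack chromosomal systems round-robin into slot positions
  slot_of <- seq_along(chrom_sys) - 1L
  for (k in seq_along(chrom_sys)) {
    s <- chrom_sys[[k]]
    rid <- chrom_ids[(slot_of[k] %% config$n_replicons) + 1L]
    off <- (slot_of[k] %/% config$n_replicons) * SLOT_NT
    chrom_dna[[rid]] <- splice_dna(chrom_dna[[rid]], off, s$slot$dna)
    systems[[s$id]]$placement <- list(replicon = rid, offset = off)
    if (s$arch$context == "prophage")
      mge[[length(mge) + 1L]] <- data.frame(replicon = rid, type = "prophage",
                                            start = off + 500L, end = off + 6500L,
                                            stringsAsFactors = FALSE)
  }
  replicons <- chrom_dna

  for (s in plas_sys) {
    rid <- paste0("p_", s$id)
    dna <- with_seed(child_seed(config$seed, paste0("plasdna_", s$id)),
                     random_dna(PLASMID_NT))
    off <- 2000L
    dna <- splice_dna(dna, off, s$slot$dna)
    if (s$family == "PrgX" && !s$arch$eavesdropper) {
      pp <- generate_propeptide("PrgX", 1L, pathway = "none",
                                seed = child_seed(config$seed, paste0("pp_", s$id)))
      pos <- with_seed(child_seed(config$seed, paste0("ppX_", s$id)),
                       12000L + sample.int(3000L, 1L))
      dna <- splice_dna(dna, pos - 3L, paste0("TAA", pp$dna))
      systems[[s$id]]$distant <- c(list(start = pos, end = pos + nchar(pp$dna),
                                        side = "plasmid_wide"), pp)
    }
    replicons[[rid]] <- dna
    systems[[s$id]]$placement <- list(replicon = rid, offset = off)
    mge[[length(mge) + 1L]] <- data.frame(
      replicon = rid,
      type = if (s$arch$context == "phage_plasmid") "phage_plasmid" else "plasmid",
      start = 0L, end = nchar(dna), stringsAsFactors = FALSE)
  }

  # decoy Rgg-like receptors without propeptides (MutR/GadR analogues)
  if (config$systems_per_family > 0L && config$n_decoy_rgg > 0L) {
    for (j in seq_len(config$n_decoy_rgg)) {
      prot <- with_seed(child_seed(config$seed, paste0("decoy", j)),
                        mutate_protein(family_consensus("MutR_decoy"),
                                       config$mutation_rate))
      dna <- paste0(reverse_translate(prot), "TAA")
      rid <- chrom_ids[((j - 1L) %% config$n_replicons) + 1L]
      at <- config$replicon_length - SLOT_NT + 1500L
      replicons[[rid]] <- splice_dna(replicons[[rid]], at, dna)
      decoys[[j]] <- data.frame(replicon = rid, start = at, end = at + nchar(dna),
                                strand = "+", protein = prot,
                                stringsAsFactors = FALSE)
    }
  }

  # assemble gene table, truth and known peptides
  for (s in systems) {
    pl <- s$placement
    g <- s$slot$genes
    g$start <- g$start + pl$offset; g$end <- g$end + pl$offset
    g$replicon <- pl$replicon
    g$system_id <- ifelse(g$role == "receptor", s$id, NA_character_)
    genes[[length(genes) + 1L]] <- g

    props <- lapply(s$slot$props, function(p) {
      p$start <- p$start + pl$offset; p$end <- p$end + pl$offset; p
    })
    if (!is.null(s$distant)) props <- c(props, list(s$distant))
    role <- truth_role(s$arch, props)
    rec <- g[g$role == "receptor", ]
    truth_sys[[length(truth_sys) + 1L]] <- data.frame(
      system_id = s$id, family = s$family, replicon = pl$replicon,
      strand = s$arch$strand, rec_start = rec$start, rec_end = rec$end,
      context = s$arch$context, role = role,
      n_propeptides = length(props),
      pathway = if (length(props)) props[[1]]$pathway else "none",
      stringsAsFactors = FALSE)
    for (p in props) {
      truth_prop[[length(truth_prop) + 1L]] <- data.frame(
        system_id = s$id, family = s$family, replicon = pl$replicon,
        start = p$start, end = p$end,
        strand = if (p$side == "plasmid_wide") "+" else s$arch$strand,
        side = p$side, protein = p$protein, pathway = p$pathway,
        copy_count = length(p$matures),
        matures = paste(p$matures, collapse = ";"),
        mature = p$mature, cleavage = p$cleavage,
        stringsAsFactors = FALSE)
      if (s$family %in% c("Rgg", "ComR", "PrgX"))
        known[[length(known) + 1L]] <- data.frame(family = s$family,
                                                  peptide = p$mature,
                                                  stringsAsFactors = FALSE)
    }
  }

  genes_df <- if (length(genes)) do.call(rbind, genes) else
    data.frame(start = integer(), end = integer(), strand = character(),
               protein = character(), role = character(), replicon = character(),
               system_id = character(), stringsAsFactors = FALSE)
  if (length(decoys)) {
    dd <- do.call(rbind, decoys)
    genes_df <- rbind(genes_df,
                      data.frame(start = dd$start, end = dd$end, strand = dd$strand,
                                 protein = dd$protein, role = "decoy",
                                 replicon = dd$replicon, system_id = NA_character_,
                                 stringsAsFactors = FALSE))
  }
  genes_df <- genes_df[order(genes_df$replicon, genes_df$start), , drop = FALSE]
  if (nrow(genes_df)) {
    genes_df$locus_tag <- sprintf("cds_%04d", seq_len(nrow(genes_df)))
  } else genes_df$locus_tag <- character()
  rownames(genes_df) <- NULL
  proteome <- stats::setNames(genes_df$protein, genes_df$locus_tag)

  truth_systems <- if (length(truth_sys)) do.call(rbind, truth_sys) else
    data.frame(system_id = character(), family = character(), replicon = character(),
               strand = character(), rec_start = integer(), rec_end = integer(),
               context = character(), role = character(), n_propeptides = integer(),
               pathway = character(), stringsAsFactors = FALSE)
  # attach receptor locus tags to truth
  if (nrow(truth_systems)) {
    key <- paste(genes_df$replicon, genes_df$start, genes_df$end)
    tkey <- paste(truth_systems$replicon, truth_systems$rec_start, truth_systems$rec_end)
    truth_systems$receptor_id <- genes_df$locus_tag[match(tkey, key)]
  } else truth_systems$receptor_id <- character()

  list(replicons = unlist(replicons),
       genes = genes_df,
       proteome = proteome,
       mge = if (length(mge)) do.call(rbind, mge) else
         data.frame(replicon = character(), type = character(),
                    start = integer(), end = integer(), stringsAsFactors = FALSE),
       known_peptides = if (length(known)) unique(do.call(rbind, known)) else
         data.frame(family = character(), peptide = character(),
                    stringsAsFactors = FALSE),
       truth = list(systems = truth_systems,
                    propeptides = if (length(truth_prop)) do.call(rbind, truth_prop) else
                      data.frame(system_id = character(), family = character(),
                                 replicon = character(), start = integer(),
                                 end = integer(), strand = character(),
                                 side = character(), protein = character(),
                                 pathway = character(), copy_count = integer(),
                                 matures = character(), mature = character(),
                                 cleavage = integer(), stringsAsFactors = FALSE),
                    decoys = if (length(decoys)) do.call(rbind, decoys) else
                      data.frame(replicon = character(), start = integer(),
                                 end = integer(), strand = character(),
                                 protein = character(), stringsAsFactors = FALSE)),
       circular = stats::setNames(rep(FALSE, length(replicons)), names(replicons)),
       config = config)
}
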