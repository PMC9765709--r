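# small sequence utilities shared across modules

#' Reverse complement of a DNA string
#' @param dna Character scalar over ACGT (case-insensitive).
#' @return Character scalar.
#' @export
revcomp <- function(dna) {
  x <- chartr("ACGTacgt", "TGCAtgca", dna)
  paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Translate a DNA string (first frame)
#'
#' Standard genetic code; trailing partial codons dropped; stops rendered as
#' `*`. When `start_as_met = TRUE` the first codon is translated as M if it is
#' one of the accepted start codons (ATG, GTG, TTG), mirroring how
#' alternative-start ORFs are translated by prokaryotic gene callers.
#'
#' @param dna Character scalar.
#' @param start_as_met Treat an alternative start codon as Met.
#' @return Character scalar amino-acid sequence.
#' @export
translate_dna <- function(dna, start_as_met = FALSE) {
  dna <- toupper(dna)
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  codons <- substring(dna, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  if (start_as_met && codons[1] %in% c("ATG", "GTG", "TTG")) aa[1] <- "M"
  paste(aa, collapse = "")
}

# run code with a temporary RNG state seeded by `seed`; restores the caller's
# RNG stream afterwards so library code never perturbs user simulations
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# random DNA / protein draws (use the current RNG stream)
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

random_protein <- function(n, freqs = aa_background()) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

# substitute residues at rate `rate`, always to a different residue
mutate_protein <- function(protein, rate) {
  if (rate <= 0) return(protein)
  ch <- aa_chars(protein)
  hit <- which(stats::runif(length(ch)) < rate)
  ab <- aa_alphabet()
  for (i in hit) ch[i] <- sample(setdiff(ab, ch[i]), 1L)
  paste(ch, collapse = "")
}

# deterministic reverse translation: one fixed codon per amino acid
aa_codon_table <- function() {
  c(A = "GCT", C = "TGC", D = "GAT", E = "GAA", F = "TTC",
    G = "GGT", H = "CAT", I = "ATC", K = "AAA", L = "CTG",
    M = "ATG", N = "AAC", P = "CCG", Q = "CAG", R = "CGT",
    S = "TCT", T = "ACC", V = "GTT", W = "TGG", Y = "TAC")
}

reverse_translate <- function(protein) {
  ch <- aa_chars(protein)
  paste(aa_codon_table()[ch], collapse = "")
}

# derive a child seed (< 2^31) from a base seed and a tag
child_seed <- function(seed, tag) {
  (as.numeric(seed) * 7919 + sum(utf8ToInt(as.character(tag)))) %% 2147483629
}
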