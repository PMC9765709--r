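#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard residues, in the fixed order used by profile matrices and
#' the integer encoding passed to the compiled alignment kernels.
#'
#' @return Character vector of 20 one-letter residue codes.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Background amino-acid frequencies
#'
#' Robinson-Robinson style average composition of bacterial proteins, used as
#' the null model for profile log-odds scores and for sampling decoy proteins
#' during E-value calibration.
#'
#' @return Named numeric vector over [aa_alphabet()], summing to 1.
#' @export
aa_background <- function() {
  f <- c(A = 0.078, C = 0.019, D = 0.054, E = 0.063, F = 0.039,
         G = 0.074, H = 0.022, I = 0.051, K = 0.057, L = 0.090,
         M = 0.022, N = 0.045, P = 0.052, Q = 0.043, R = 0.051,
         S = 0.071, T = 0.058, V = 0.066, W = 0.013, Y = 0.032)
  f / sum(f)
}

#' Kyte-Doolittle hydropathy scale
#'
#' @return Named numeric vector of hydropathy values over [aa_alphabet()].
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8,
    G = -0.4, H = -3.2, I = 4.5, K = -3.9, L = 3.8,
    M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
    S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
}

# integer-encode a protein string (0-based indices into aa_alphabet());
# errors on unknown symbols, naming the first offender
encode_aa <- function(protein) {
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  idx <- match(ch, aa_alphabet())
  if (anyNA(idx)) {
    bad <- ch[which(is.na(idx))[1]]
    stop("unknown residue symbol '", bad, "' in protein sequence", call. = FALSE)
  }
  as.integer(idx - 1L)
}

aa_chars <- function(protein) strsplit(protein, "", fixed = TRUE)[[1]]
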