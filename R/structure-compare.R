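# Structural comparison of receptor TPR blocks: Kabsch superposition, RMSD
# matrices, interaction networks, UPGMA/NJ dendrograms, and the greedy
# identity/coverage clustering used to de-redundify sequence sets.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of `coordsB`
#' onto `coordsA`.
#'
#' @param coordsA,coordsB n x 3 matrices with matched rows (n >= 3).
#' @return List with `rotation` (3 x 3, determinant +1), `translation`
#'   (length 3; `B %*% rotation + translation` superposes onto A), and `rmsd`.
#' @export
kabsch_superpose <- function(coordsA, coordsB) {
  A <- as.matrix(coordsA); B <- as.matrix(coordsB)
  if (nrow(A) != nrow(B) || ncol(A) != 3L || ncol(B) != 3L)
    stop("coordinate sets must be n x 3 with matched point counts", call. = FALSE)
  if (nrow(A) < 3L) stop("need at least 3 points", call. = FALSE)
  if (!all(is.finite(A)) || !all(is.finite(B)))
    stop("coordinates must be finite", call. = FALSE)
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- t(B0) %*% A0
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("degenerate (collinear) coordinate set; superposition undefined",
         call. = FALSE)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  Brot <- B0 %*% R
  rmsd <- sqrt(mean(rowSums((A0 - Brot)^2)))
  list(rotation = R, translation = as.numeric(ca - cb %*% R), rmsd = rmsd)
}

#' Pairwise RMSD matrix over structure selections
#'
#' @param selections Named list of n x 3 coordinate matrices (equal point
#'   counts after range trimming).
#' @return Symmetric `dist`-compatible matrix with zero diagonal.
#' @export
rmsd_matrix <- function(selections) {
  n <- length(selections)
  stopifnot(n >= 2L)
  labs <- names(selections)
  if (is.null(labs)) labs <- paste0("s", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (nrow(selections[[i]]) != nrow(selections[[j]]))
      stop("selections '", labs[i], "' and '", labs[j],
           "' have different point counts and cannot be compared", call. = FALSE)
    r <- kabsch_superpose(selections[[i]], selections[[j]])$rmsd
    m[i, j] <- m[j, i] <- r
  }
  m
}

#' Threshold an RMSD matrix into an interaction network
#'
#' Undirected edges connect pairs at distance at most `threshold` (default:
#' the median off-diagonal distance, reported in the result).
#'
#' @param matrix Symmetric distance matrix with labels.
#' @param threshold Positive distance cutoff.
#' @return List with `edges` (data.frame from, to, weight) and `threshold`.
#' @export
build_network <- function(matrix, threshold = NULL) {
  off <- matrix[upper.tri(matrix)]
  if (is.null(threshold)) threshold <- stats::median(off)
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  labs <- rownames(matrix)
  idx <- which(upper.tri(matrix) & matrix <= threshold, arr.ind = TRUE)
  edges <- data.frame(from = labs[idx[, 1]], to = labs[idx[, 2]],
                      weight = matrix[idx], stringsAsFactors = FALSE)
  list(edges = edges[order(edges$weight), , drop = FALSE], threshold = threshold)
}

#' Build a dendrogram from a distance matrix
#'
#' UPGMA (average-linkage agglomeration) or neighbor joining, with optional
#' midpoint rooting.  Labels are sorted lexicographically before clustering so
#' the result is invariant to input order even under ties.
#'
#' @param matrix Symmetric distance matrix with labels (n >= 3).
#' @param method `"upgma"` or `"nj"`.
#' @param rooting `"midpoint"` or `"none"`.
#' @return An [ape::as.phylo] tree; serialize with [ape::write.tree].
#' @export
build_dendrogram <- function(matrix, method = c("upgma", "nj"),
                             rooting = c("none", "midpoint")) {
  method <- match.arg(method); rooting <- match.arg(rooting)
  if (nrow(matrix) < 3L) stop("need at least 3 structures", call. = FALSE)
  ord <- order(rownames(matrix))
  m <- matrix[ord, ord]
  tree <- if (method == "upgma") {
    ape::as.phylo(stats::hclust(stats::as.dist(m), method = "average"))
  } else {
    ape::nj(stats::as.dist(m))
  }
  if (rooting == "midpoint") tree <- phangorn::midpoint(tree)
  tree
}

#' Greedy identity/coverage clustering of sequences
#'
#' Sequences are sorted by decreasing length (ties broken by name); each joins
#' the first existing representative it matches at `identity` or higher over
#' `coverage` or more (global dynamic-programming alignment; identity is
#' identities over alignment columns, coverage is the shorter over the longer
#' length), otherwise it becomes a new representative.
#'
#' @param sequences Named character vector.
#' @param identity,coverage Thresholds in \[0, 1\] (default 0.95 each).
#' @return List with `representatives` (names) and `membership` (named by
#'   sequence, value is its representative).
#' @export
greedy_cluster <- function(sequences, identity = 0.95, coverage = 0.95) {
  stopifnot(length(sequences) > 0L)
  if (is.null(names(sequences))) names(sequences) <- paste0("seq", seq_along(sequences))
  ord <- order(-nchar(sequences), names(sequences))
  sequences <- sequences[ord]
  reps <- character()
  membership <- character(length(sequences))
  names(membership) <- names(sequences)
  enc <- lapply(sequences, encode_aa)
  for (i in seq_along(sequences)) {
    placed <- FALSE
    for (r in reps) {
      cov <- min(nchar(sequences[[i]]), nchar(sequences[[r]])) /
             max(nchar(sequences[[i]]), nchar(sequences[[r]]))
      if (cov < coverage) next
      al <- pair_align_cpp(enc[[i]], enc[[r]], 1, -1, 5, 1, FALSE)
      if (al$n_ident / al$n_aligned >= identity) {
        membership[i] <- r; placed <- TRUE; break
      }
    }
    if (!placed) { reps <- c(reps, names(sequences)[i]); membership[i] <- names(sequences)[i] }
  }
  list(representatives = reps, membership = membership)
}

#' Read C-alpha coordinates from a PDB file
#'
#' Minimal fixed-width parser for `ATOM` records: keeps `CA` atoms of the
#' requested chain, first altloc only, optionally restricted to residue
#' ranges.  (No mature R PDB parser is available in this package's dependency
#' set, and only CA traces are needed for superposition.)
#'
#' @param path PDB file path.
#' @param chain Chain identifier (default first chain seen).
#' @param residues Optional integer vector of residue numbers to keep, in
#'   the given order.
#' @return n x 3 matrix of CA coordinates with residue numbers as rownames.
#' @export
read_ca_coords <- function(path, chain = NULL, residues = NULL) {
  lines <- readLines(path)
  atoms <- lines[startsWith(lines, "ATOM")]
  name <- trimws(substr(atoms, 13, 16))
  alt <- substr(atoms, 17, 17)
  keep <- name == "CA" & alt %in% c(" ", "A")
  atoms <- atoms[keep]
  if (length(atoms) == 0L) stop("no CA atoms found in ", path, call. = FALSE)
  ch <- substr(atoms, 22, 22)
  if (is.null(chain)) chain <- ch[1]
  atoms <- atoms[ch == chain]
  resno <- as.integer(substr(atoms, 23, 26))
  xyz <- cbind(x = as.numeric(substr(atoms, 31, 38)),
               y = as.numeric(substr(atoms, 39, 46)),
               z = as.numeric(substr(atoms, 47, 54)))
  rownames(xyz) <- resno
  if (!is.null(residues)) {
    idx <- match(residues, resno)
    if (anyNA(idx)) stop("residues missing from chain ", chain, ": ",
                         paste(residues[is.na(idx)], collapse = ","), call. = FALSE)
    xyz <- xyz[idx, , drop = FALSE]
  }
  xyz
}

#' Write a minimal CA-only PDB file (synthetic structures for tests)
#'
#' @param coords n x 3 coordinate matrix.
#' @param path Output path.
#' @param chain Chain id.
#' @return `path`, invisibly.
#' @export
write_ca_pdb <- function(coords, path, chain = "A") {
  lines <- vapply(seq_len(nrow(coords)), function(i)
    sprintf("ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, chain, i, coords[i, 1], coords[i, 2], coords[i, 3]), "")
  writeLines(c(lines, "END"), path)
  invisible(path)
}
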