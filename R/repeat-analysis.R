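# Propeptide length distributions, atypically large propeptides, and
# mature-peptide (pseudo)repeat detection.

#' Flag atypically large (or small) propeptides per family
#'
#' Tukey fences on type-7 (linear interpolation) quartiles:
#' `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR`.  Families with fewer than 4 values get
#' undefined fences, are flagged, and contribute no outliers.
#'
#' @param lengths Numeric vector of propeptide lengths.
#' @param family Character vector of family labels, parallel to `lengths`.
#' @param ids Optional identifiers, parallel to `lengths`.
#' @return List with `summary` (per family: n, quartiles, fences, fences_defined)
#'   and `outliers` (data.frame id, family, length).
#' @export
length_outliers <- function(lengths, family, ids = NULL) {
  stopifnot(length(lengths) == length(family))
  if (is.null(ids)) ids <- as.character(seq_along(lengths))
  fams <- sort(unique(family))
  rows <- list(); outs <- list()
  for (f in fams) {
    x <- lengths[family == f]
    xi <- ids[family == f]
    if (length(x) < 4L) {
      rows[[f]] <- data.frame(family = f, n = length(x), q1 = NA_real_,
                              median = stats::median(x), q3 = NA_real_,
                              lower_fence = NA_real_, upper_fence = NA_real_,
                              fences_defined = FALSE, n_outliers = 0L,
                              stringsAsFactors = FALSE)
      next
    }
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo <- q[1] - 1.5 * iqr; hi <- q[3] + 1.5 * iqr
    is_out <- x < lo | x > hi
    rows[[f]] <- data.frame(family = f, n = length(x), q1 = q[1], median = q[2],
                            q3 = q[3], lower_fence = lo, upper_fence = hi,
                            fences_defined = TRUE, n_outliers = sum(is_out),
                            stringsAsFactors = FALSE)
    if (any(is_out))
      outs[[f]] <- data.frame(id = xi[is_out], family = f, length = x[is_out],
                              stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       outliers = if (length(outs)) do.call(rbind, c(outs, list(make.row.names = FALSE)))
                  else data.frame(id = character(), family = character(),
                                  length = numeric(), stringsAsFactors = FALSE))
}

#' Detect (pseudo)repeated mature-peptide copies in a propeptide
#'
#' Takes the C-terminal 5-mer as the mature-peptide seed and scans the
#' protein left to right for non-overlapping occurrences with at most
#' `mismatch_tolerance` mismatches.  A propeptide whose copies all match the
#' seed exactly is classed `identical`; if at least one copy carries a
#' mismatch it is `pseudorepeated`; a single occurrence is `single`.
#'
#' @param protein Character scalar, at least 10 aa.
#' @param mismatch_tolerance Maximum mismatches per copy (default 1 of 5).
#' @param seed_length Length of the C-terminal seed (default 5).
#' @return List with `seed`, `copy_count`, `classification`, `positions`
#'   (1-based start of each copy) and `variants` (data.frame of copy index and
#'   mismatch positions within the seed).
#' @export
detect_repeats <- function(protein, mismatch_tolerance = 1, seed_length = 5) {
  n <- nchar(protein)
  if (n < 10L) stop("protein must be at least 10 aa", call. = FALSE)
  seed <- substr(protein, n - seed_length + 1L, n)
  sch <- aa_chars(seed)
  ch <- aa_chars(protein)
  positions <- integer(); mism <- list()
  i <- 1L
  while (i <= n - seed_length + 1L) {
    d <- which(ch[i:(i + seed_length - 1L)] != sch)
    if (length(d) <= mismatch_tolerance) {
      positions <- c(positions, i)
      mism[[length(mism) + 1L]] <- d
      i <- i + seed_length # greedy non-overlapping
    } else i <- i + 1L
  }
  k <- length(positions)
  cls <- if (k <= 1L) "single"
         else if (any(lengths(mism) > 0L)) "pseudorepeated" else "identical"
  variants <- if (k)
    data.frame(copy = rep(seq_len(k), lengths(mism)),
               seed_position = unlist(mism), stringsAsFactors = FALSE)
  else data.frame(copy = integer(), seed_position = integer())
  list(seed = seed, copy_count = k, classification = cls,
       positions = positions, variants = variants)
}

#' Compare the mature peptides of two sibling propeptide genes
#'
#' @param matureA,matureB Mature peptide sequences.
#' @return List with `classification` (`"identical"`/`"variant"`),
#'   `positions` (1-based differing positions; `NA` when lengths differ) and
#'   `length_mismatch`.
#' @export
compare_sibling_propeptides <- function(matureA, matureB) {
  if (nchar(matureA) != nchar(matureB))
    return(list(classification = "variant", positions = NA_integer_,
                length_mismatch = TRUE))
  d <- which(aa_chars(matureA) != aa_chars(matureB))
  list(classification = if (length(d)) "variant" else "identical",
       positions = d, length_mismatch = FALSE)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' k - 1 degrees of freedom.  When every value is identical across all groups
#' the statistic is defined as 0 with p = 1.
#'
#' @param groups List of numeric vectors (at least two non-empty groups).
#' @return List with `H`, `p`, and `df`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L, all(lengths(groups) > 0L))
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  if (length(unique(x)) == 1L)
    return(list(H = 0, p = 1, df = length(groups) - 1L))
  r <- rank(x)
  Rj <- tapply(r, g, sum)
  nj <- tabulate(g)
  H <- 12 / (n * (n + 1)) * sum(Rj^2 / nj) - 3 * (n + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H <- H / C
  df <- length(groups) - 1L
  list(H = H, p = stats::pchisq(H, df, lower.tail = FALSE), df = df)
}
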