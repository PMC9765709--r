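# shared lazy fixtures: built once per test run, on first use

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# calibrated model for one family (synthetic seed alignment, fixed seed)
test_model <- function(family) {
  cached(paste0("model_", family), function() {
    calibrate_profile(build_profile(family_seed_alignment(family, seed = 101),
                                    family = family),
                      seed = 101)
  })
}

# small planted genome used across propeptide / context tests
small_bundle <- function() {
  cached("small_bundle", function()
    generate_genome(sim_config(systems_per_family = 3, seed = 11)))
}

# the default-scale synthetic run of the acceptance criteria:
# 7 families x 20 systems, mutation_rate 0.1, fixed seed
default_run <- function() {
  cached("default_run", function() {
    bundle <- generate_genome(sim_config(seed = 2024))
    list(bundle = bundle,
         result = run_qs_pipeline(bundle, seed = 7))
  })
}

# uniform random window of DNA as a flank window
random_window <- function(n = 1050) {
  rrnppa:::make_window("w", "downstream",
                       paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""),
                       seq.int(0L, n - 1L), FALSE, "+")
}

# brute-force six-frame ORF oracle: enumerate every (start, stop) codon pair
# with no intervening stop, keep the earliest start per stop, bound lengths
brute_force_orfs <- function(window, min_aa = 20, max_aa = 120) {
  n <- nchar(window$seq)
  rows <- list()
  for (str in c("+", "-")) {
    S <- if (str == "+") window$seq else revcomp(window$seq)
    for (f in 0:2) {
      ncf <- (nchar(S) - f) %/% 3
      if (ncf < 1) next
      codons <- substring(S, f + 3 * seq_len(ncf) - 2, f + 3 * seq_len(ncf))
      is_start <- codons %in% c("ATG", "GTG", "TTG")
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      for (k in which(is_stop)) {
        # earliest start with no stop strictly between it and this stop
        found <- NA
        for (st in seq_len(k - 1)) {
          if (is_stop[st]) { found <- NA; next }
          if (is_start[st] && is.na(found)) found <- st
        }
        # reject if a stop sits between found and k
        if (!is.na(found) && any(is_stop[found:(k - 1)])) found <- NA
        if (is.na(found)) next
        len_aa <- k - found
        if (len_aa < min_aa || len_aa > max_aa) next
        a <- f + 3 * (found - 1); b <- f + 3 * k
        if (str == "-") { tmp <- a; a <- n - b; b <- n - tmp }
        orf_nt <- substr(window$seq, a + 1, b)
        if (str == "-") orf_nt <- revcomp(orf_nt)
        prot <- substr(translate_dna(orf_nt, start_as_met = TRUE), 1, len_aa)
        rows[[length(rows) + 1]] <- data.frame(win_start = a, win_end = b,
                                               win_strand = str, protein = prot,
                                               stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(win_start = integer(), win_end = integer(),
                      win_strand = character(), protein = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$win_start, out$win_strand), , drop = FALSE]
}

# random proper rotation matrix
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# numerical RMSD minimization over rotations (Euler angles, multi-start);
# independent oracle for the Kabsch solution
numeric_min_rmsd <- function(A, B, n_starts = 8) {
  A0 <- sweep(A, 2, colMeans(A)); B0 <- sweep(B, 2, colMeans(B))
  rot <- function(th) {
    cx <- cos(th[1]); sx <- sin(th[1]); cy <- cos(th[2]); sy <- sin(th[2])
    cz <- cos(th[3]); sz <- sin(th[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(th) sqrt(mean(rowSums((A0 - B0 %*% rot(th))^2)))
  best <- Inf
  for (s in seq_len(n_starts)) {
    th0 <- stats::runif(3, -pi, pi)
    o <- stats::optim(th0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    if (o$value < best) best <- o$value
  }
  best
}
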