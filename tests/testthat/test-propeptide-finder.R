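# flank windows, ORF finding, signal scoring, SHP and plasmid-wide search

test_that("flank windows use the 50 + 1000 nt geometry", {
  withr::with_seed(1, repl <- rrnppa:::random_dna(10000))
  w <- build_flank_windows(list(start = 100, end = 400, strand = "+"), repl)
  expect_equal(w$downstream$positions, 350:1399)
  expect_equal(w$downstream$seq, substr(repl, 351, 1400))
  # upstream truncated at the origin
  expect_equal(w$upstream$positions, 0:149)
  expect_equal(w$upstream$seq, substr(repl, 1, 150))

  # '-' strand gene: transcriptional downstream precedes the gene, revcomp
  wm <- build_flank_windows(list(start = 5000, end = 5300, strand = "-"), repl)
  expect_equal(wm$downstream$seq, revcomp(substr(repl, 4001, 5050)))
  expect_equal(wm$downstream$positions, rev(4000:5049))
  expect_true(wm$downstream$flipped)

  # gene ending at the replicon end: downstream is the 50 terminal bases only
  we <- build_flank_windows(list(start = 9700, end = 10000, strand = "+"), repl)
  expect_equal(we$downstream$positions, 9950:9999)

  # short gene triggers a warning and uses the whole gene
  expect_warning(build_flank_windows(list(start = 100, end = 130, strand = "+"),
                                     repl), "whole gene")
  expect_error(build_flank_windows(list(start = -5, end = 100, strand = "+"), repl),
               "outside replicon")
})

test_that("circular windows are rotation invariant", {
  withr::with_seed(2, repl <- rrnppa:::random_dna(3000))
  rot <- 2000L
  repl_rot <- paste0(substr(repl, rot + 1, 3000), substr(repl, 1, rot))
  # gene near the end of the original replicon
  w1 <- build_flank_windows(list(start = 2800, end = 2950, strand = "+"), repl,
                            circular = TRUE)
  w2 <- build_flank_windows(list(start = 800, end = 950, strand = "+"), repl_rot,
                            circular = TRUE)
  expect_equal(w1$downstream$seq, w2$downstream$seq)
  expect_equal(w1$upstream$seq, w2$upstream$seq)
  # position maps correspond modulo the rotation
  expect_equal((w1$downstream$positions - rot) %% 3000, w2$downstream$positions)
})

test_that("find_orfs equals the brute-force six-frame oracle", {
  withr::with_seed(33, {
    for (i in 1:50) {
      w <- random_window(1050)
      got <- find_orfs(w)
      want <- brute_force_orfs(w)
      expect_equal(got[, c("win_start", "win_end", "win_strand", "protein")],
                   want, ignore_attr = TRUE)
    }
  })
})

test_that("ORF length bounds are inclusive at 20 and 120 aa", {
  mk <- function(n_sense) {
    # poly-C background carries no start/stop codons in any frame
    # GAC codons: neither strand of poly-GAC contains starts or stops
    orf <- paste0("ATG", strrep("GAC", n_sense), "TAA")
    rrnppa:::make_window("w", "downstream",
                         paste0(strrep("C", 30), "TAA", orf, strrep("C", 30)),
                         seq.int(0L, 30 + 3 + nchar(orf) + 30 - 1L), FALSE, "+")
  }
  expect_equal(nrow(find_orfs(mk(18))), 0L)  # 19 aa: excluded
  o20 <- find_orfs(mk(19))                   # 20 aa: included
  expect_equal(nrow(o20), 1L)
  expect_equal(nchar(o20$protein), 20L)
  expect_equal(nrow(find_orfs(mk(119))), 1L) # 120 aa: included
  expect_equal(nrow(find_orfs(mk(120))), 0L) # 121 aa: excluded
  # no start codon anywhere: empty
  none <- rrnppa:::make_window("w", "downstream", strrep("C", 300),
                               seq.int(0L, 299L), FALSE, "+")
  expect_equal(nrow(find_orfs(none)), 0L)
})

test_that("signal scoring recognises the planted architectures", {
  # featureless protein: no signal
  r <- score_signal_peptide(strrep("A", 40))
  expect_equal(r$score, 0)
  expect_equal(r$pathway, "none")
  # too short: zero score
  expect_equal(score_signal_peptide("MKKLLII")$score, 0)

  # hand-built canonical SPI signal: MKK + Leu block + AQA + mature
  p <- paste0("MKKTSN", strrep("L", 10), "AQA", "SWNQTDE")
  r <- score_signal_peptide(p)
  expect_equal(r$pathway, "SPI")
  expect_equal(r$cleavage, 19L) # cleaved after the AQA motif
  expect_gte(r$score, 0.6)

  # generator truth: cleavage and pathway recovered for every family/pathway
  for (fam in c("Rap", "NprR", "PlcR", "AimR")) {
    for (pw in c("SPI", "SPII")) {
      for (k in c(1, 3)) {
        pp <- generate_propeptide(fam, k, pathway = pw,
                                  seed = rrnppa:::child_seed(17, paste0(fam, pw, k)))
        r <- score_signal_peptide(pp$protein)
        expect_equal(r$pathway, pw, info = paste(fam, pw, k))
        expect_equal(r$cleavage, pp$cleavage, info = paste(fam, pw, k))
        expect_gte(r$score, 0.6)
      }
    }
  }
  # SHP-class peptides stay signal-less
  shp <- generate_propeptide("Rgg", 1, pathway = "none", seed = 18)
  expect_equal(score_signal_peptide(shp$protein)$pathway, "none")
})

test_that("shp_fallback_search applies the identity/coverage gates", {
  embed <- function(peptide) {
    orf <- paste0(rrnppa:::reverse_translate(peptide), "TAA")
    seqn <- paste0(strrep("C", 60), "TAA", orf, strrep("C", 60))
    rrnppa:::make_window("w", "upstream", seqn, seq.int(0L, nchar(seqn) - 1L),
                         FALSE, "+")
  }
  known <- c("LTSWWGL", "AIFILAS")
  hit <- shp_fallback_search(embed("MNNSTLTSWWGLQDNS"), known)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$mature, "LTSWWGL")
  expect_equal(hit$matched_known, "LTSWWGL")
  expect_equal(hit$score, 1)

  # empty known set: no matches, not an error
  expect_equal(nrow(shp_fallback_search(embed("MNNSTLTSWWGLQDNS"), character())), 0L)

  # 6/7 internal mismatch (85.7% identity, full coverage): retained
  hit67 <- shp_fallback_search(embed("MNNSTLTSWAGLQDNS"), "LTSWWGL")
  expect_equal(nrow(hit67), 1L)
  # 5/7 (71.4%): rejected
  expect_equal(nrow(shp_fallback_search(embed("MNNSTLTAWAGLQDNS"), "LTSWWGL")), 0L)
})

test_that("plasmid-wide search finds distant peptides and guards context", {
  b <- small_bundle()
  prgx <- b$truth$propeptides[b$truth$propeptides$side == "plasmid_wide", ]
  expect_gt(nrow(prgx), 0L)
  p <- prgx[1, ]
  res <- plasmid_wide_search(b$replicons[[p$replicon]], p$mature,
                             "plasmid", p$replicon)
  expect_true(any(res$matched_known == p$mature))
  # peptide absent: empty
  res0 <- plasmid_wide_search(b$replicons[[p$replicon]], "WWWWWWWW", "plasmid")
  expect_equal(nrow(res0), 0L)
  expect_error(plasmid_wide_search(b$replicons[[1]], p$mature, "chromosome"),
               "plasmid")
})

test_that("call_propeptides recovers planted systems", {
  b <- small_bundle()
  ts <- b$truth$systems
  tp <- b$truth$propeptides
  rt <- rrnppa:::replicon_type_map(b$mge, names(b$replicons))
  call_for <- function(s)
    call_propeptides(list(protein_id = s$receptor_id, family = s$family,
                          replicon = s$replicon, start = s$rec_start,
                          end = s$rec_end, strand = s$strand),
                     b$replicons, known_peptides = b$known_peptides,
                     replicon_types = rt)

  # a canonical signal-bearing plant comes back with exact coordinates
  can <- ts[ts$pathway %in% c("SPI", "SPII") & ts$n_propeptides == 1, ][1, ]
  pp <- tp[tp$system_id == can$system_id, ]
  calls <- call_propeptides(list(protein_id = can$receptor_id, family = can$family,
                                 replicon = can$replicon, start = can$rec_start,
                                 end = can$rec_end, strand = can$strand),
                            b$replicons)
  expect_true(any(calls$rep_start == pp$start & calls$rep_end == pp$end &
                    calls$rep_strand == pp$strand))
  expect_equal(calls$predictor[1], "primary")

  # sibling plants: both genes returned
  sib <- ts[ts$n_propeptides == 2 & ts$pathway %in% c("SPI", "SPII"), ]
  if (nrow(sib)) {
    s <- sib[1, ]
    pps <- tp[tp$system_id == s$system_id, ]
    calls <- call_for(s)
    for (k in seq_len(nrow(pps)))
      expect_true(any(calls$rep_start == pps$start[k] & calls$rep_end == pps$end[k]))
  }

  # coordinates outside the replicon error
  expect_error(call_propeptides(list(protein_id = "x", family = "Rap",
                                     replicon = names(b$replicons)[1],
                                     start = 10, end = 1e7, strand = "+"),
                                b$replicons), "outside replicon")

  # windows of pure poly-C background yield no calls at all
  polyc <- stats::setNames(strrep("C", 8000), "bare")
  expect_equal(nrow(call_propeptides(list(protein_id = "x", family = "Rap",
                                          replicon = "bare", start = 3000,
                                          end = 4200, strand = "+"), polyc)), 0L)
})

test_that("calls are strand symmetric under replicon reverse-complement", {
  b <- small_bundle()
  ts <- b$truth$systems
  s <- ts[ts$pathway == "SPI", ][1, ]
  L <- nchar(b$replicons[[s$replicon]])
  rec1 <- list(protein_id = "r", family = s$family, replicon = s$replicon,
               start = s$rec_start, end = s$rec_end, strand = s$strand)
  calls1 <- call_propeptides(rec1, b$replicons)
  flipped <- b$replicons
  flipped[[s$replicon]] <- revcomp(flipped[[s$replicon]])
  rec2 <- list(protein_id = "r", family = s$family, replicon = s$replicon,
               start = L - s$rec_end, end = L - s$rec_start,
               strand = if (s$strand == "+") "-" else "+")
  calls2 <- call_propeptides(rec2, flipped)
  expect_equal(nrow(calls1), nrow(calls2))
  k1 <- sort(paste(calls1$rep_start, calls1$rep_end, calls1$rep_strand))
  k2 <- sort(paste(L - calls2$rep_end, L - calls2$rep_start,
                   ifelse(calls2$rep_strand == "+", "-", "+")))
  expect_equal(k1, k2)
  expect_setequal(calls1$protein, calls2$protein)
})
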