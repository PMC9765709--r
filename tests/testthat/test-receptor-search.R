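# profile building, calibration, scanning and family assignment

uniform_bg <- stats::setNames(rep(0.05, 20), aa_alphabet())

test_that("build_profile matches the closed-form log-odds", {
  # single sequence, uniform background, vanishing pseudocount
  m <- build_profile(c(s1 = "ACD"), background = uniform_bg, pseudocount = 1e-12)
  expect_equal(m$length, 3L)
  expect_equal(unname(m$scores[1, "A"]), log(20), tolerance = 1e-6)
  expect_equal(unname(m$scores[2, "C"]), log(20), tolerance = 1e-6)
  expect_equal(unname(m$scores[3, "D"]), log(20), tolerance = 1e-6)

  # polymorphic column, pseudocount weight w
  for (w in c(0.5, 1, 2)) {
    m2 <- build_profile(c(a = "AC", b = "AD"), background = uniform_bg,
                        pseudocount = w)
    expect_equal(unname(m2$scores[2, "C"]), log((0.5 + w * 0.05) / (1 + w) / 0.05),
                 tolerance = 1e-12)
    expect_equal(unname(m2$scores[1, "A"]), log((1 + w * 0.05) / (1 + w) / 0.05),
                 tolerance = 1e-12)
  }
})

test_that("gap columns are dropped and bad input errors", {
  m <- build_profile(c("A-C", "A-C"))
  expect_equal(m$length, 2L)
  # a column at exactly the max gap fraction is retained
  m2 <- build_profile(c("A-C", "AGC"), max_gap_fraction = 0.5)
  expect_equal(m2$length, 3L)
  expect_error(build_profile(c("--", "--")), "zero retained columns")
  expect_error(build_profile(character()), "empty")
  expect_error(build_profile(c("AB")), "unknown residue symbol 'B'")
  expect_error(build_profile(c("AC", "ACD")), "unequal widths")
})

test_that("consensus self-match has coverage 1 and the column-max score", {
  m <- test_model("Rap")
  cons <- profile_consensus(m)
  h <- scan_proteome(c(self = cons), m, thresholds = NULL, n_database = 1)
  expect_equal(h$coverage, 1)
  expect_equal(h$score, sum(apply(m$scores, 1, max)), tolerance = 1e-8)

  # local alignment: leading random residues leave score and coverage intact
  withr::with_seed(5, {
    padded <- paste0(rrnppa:::random_protein(10), cons)
  })
  h2 <- scan_proteome(c(pad = padded), m, thresholds = NULL, n_database = 1)
  expect_equal(h2$score, h$score)
  expect_equal(h2$coverage, 1)
})

test_that("calibration is deterministic, validated, and E-values behave", {
  m0 <- build_profile(family_seed_alignment("PlcR", seed = 101), family = "PlcR")
  expect_error(scan_proteome(c(a = "ACDEF"), m0), "uncalibrated")
  expect_error(calibrate_profile(m0, n_decoys = 100), "below configured minimum")

  m1 <- calibrate_profile(m0, seed = 42)
  m2 <- calibrate_profile(m0, seed = 42)
  expect_identical(m1$calibration, m2$calibration)

  # doubling the database size doubles the E-value at fixed score
  p <- profile_consensus(m1)
  h1 <- scan_proteome(c(x = p), m1, thresholds = NULL, n_database = 500)
  h2 <- scan_proteome(c(x = p), m1, thresholds = NULL, n_database = 1000)
  expect_equal(h2$evalue, 2 * h1$evalue)

  # E-values are monotone decreasing in score
  withr::with_seed(7, {
    prots <- vapply(1:20, function(i) rrnppa:::random_protein(150), "")
  })
  names(prots) <- paste0("d", 1:20)
  h <- scan_proteome(prots, m1, thresholds = NULL)
  ord <- order(h$score)
  expect_true(all(diff(h$evalue[ord]) <= 0))
})

test_that("fitted tail probability at the decoy 95th percentile is near 0.05", {
  m <- test_model("ComR")
  cal <- m$calibration
  # fresh decoys from a different stream
  withr::with_seed(77, {
    dec <- lapply(1:400, function(i)
      rrnppa:::encode_aa(rrnppa:::random_protein(cal$decoy_length, m$background)))
  })
  sc <- as.numeric(rrnppa:::profile_best_scores_cpp(m$scores, dec,
                                                    m$gap_open, m$gap_extend))
  q95 <- stats::quantile(sc, 0.95, names = FALSE)
  p <- -expm1(-exp(-(q95 - cal$mu) / cal$beta))
  expect_gt(p, 0.03)
  expect_lt(p, 0.07)
})

test_that("assign_family applies the Rap/NprR and Rgg rules", {
  hit <- function(id, fam, e) data.frame(protein_id = id, family = fam,
                                         score = 100, coverage = 0.9, evalue = e,
                                         protein_start = 1L, protein_end = 50L,
                                         stringsAsFactors = FALSE)
  hits <- rbind(hit("p1", "Rap", 1e-40),
                hit("p2", "Rap", 1e-40), hit("p2", "NprR", 1e-30),
                hit("p3", "Rgg", 1e-20),
                hit("p4", "PlcR", 1e-9), hit("p4", "AimR", 1e-12))
  out <- assign_family(hits)
  get <- function(id) out[out$protein_id == id, ]
  expect_equal(get("p1")$family, "Rap")
  expect_true(is.na(get("p1")$reassigned_from))
  # passes both Rap and NprR -> NprR, even though Rap E-value is lower
  expect_equal(get("p2")$family, "NprR")
  expect_equal(get("p2")$reassigned_from, "Rap")
  # lowest E-value wins otherwise
  expect_equal(get("p4")$family, "AimR")
  # Rgg flagged without confirmation info, dropped when unconfirmed
  expect_true(get("p3")$needs_propeptide_confirmation)
  out2 <- assign_family(hits, confirmed_propeptide_ids = "p1")
  expect_false("p3" %in% out2$protein_id)
  out3 <- assign_family(hits, confirmed_propeptide_ids = c("p3"))
  expect_true("p3" %in% out3$protein_id)
  expect_false(out3[out3$protein_id == "p3", ]$needs_propeptide_confirmation)
  # empty input -> empty output
  expect_equal(nrow(assign_family(hits[0, ])), 0L)
})

test_that("family models separate the subfamilies as designed", {
  rap <- test_model("Rap")
  all7 <- vapply(qs_families(), family_consensus, "")
  h <- scan_proteome(all7, rap, thresholds = default_thresholds())
  # the Rap model hits Rap and (through the shared core) NprR, nothing else
  expect_setequal(h$protein_id, c("Rap", "NprR"))
  nprr <- test_model("NprR")
  h2 <- scan_proteome(all7, nprr, thresholds = default_thresholds())
  # the reverse confusion does not pass the coverage gate
  expect_identical(h2$protein_id, "NprR")
})
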