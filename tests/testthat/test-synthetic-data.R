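# synthetic genome generator: determinism, geometry, planted truth

test_that("config validation catches bad inputs", {
  expect_error(sim_config(eavesdropper_fraction = 1.2), "probabilities")
  expect_error(sim_config(repeat_copy_range = c(0, 6)), "repeat_copy_range")
  expect_error(sim_config(repeat_copy_range = c(1, 7)), "repeat_copy_range")
  expect_error(sim_config(replicon_length = 10000), "twice the planted-gene span")
  expect_error(sim_config(families = c("Rap", "Nope")), "unknown family")
})

test_that("zero systems gives empty truth over background replicons", {
  b <- generate_genome(sim_config(systems_per_family = 0, n_replicons = 2,
                                  replicon_length = 14000, seed = 3))
  expect_equal(nrow(b$truth$systems), 0L)
  expect_equal(nrow(b$truth$propeptides), 0L)
  expect_equal(length(b$replicons), 2L)
  expect_true(all(nchar(b$replicons) == 14000))
  expect_equal(nrow(b$genes), 0L)
})

test_that("generation is deterministic for a fixed seed", {
  cfg <- sim_config(systems_per_family = 2, seed = 99)
  b1 <- generate_genome(cfg)
  b2 <- generate_genome(cfg)
  expect_identical(b1, b2)
  b3 <- generate_genome(sim_config(systems_per_family = 2, seed = 100))
  expect_false(identical(b1$replicons, b3$replicons))
})

test_that("too many systems for the replicons raises a sizing error", {
  cfg <- sim_config(n_replicons = 1, replicon_length = 14000,
                    families = c("Rap", "NprR", "PlcR"), systems_per_family = 5,
                    plasmid_fraction = 0, seed = 1)
  expect_error(generate_genome(cfg), "too short for requested systems")
})

test_that("eavesdropper draws replay from the documented RNG stream", {
  cfg <- sim_config(families = "Rap", systems_per_family = 5,
                    eavesdropper_fraction = 0.4, n_decoy_rgg = 0, seed = 31)
  b <- generate_genome(cfg)
  ts <- b$truth$systems
  expect_equal(nrow(ts), 5L)
  expect_true(all(ts$family == "Rap"))
  # oracle: replay the per-system seeded stream; the 4th uniform drives the
  # eavesdropper draw
  replay <- vapply(1:5, function(i)
    rrnppa:::with_seed(rrnppa:::child_seed(31, paste0("sys_Rap_", i)), {
      u <- stats::runif(5)
      u[4] < 0.4
    }), TRUE)
  expect_equal(sum(ts$role == "eavesdropper"), sum(replay))
  expect_equal(ts$n_propeptides == 0, replay)
})

test_that("planted propeptides lie inside the finder's flank windows", {
  b <- small_bundle()
  ts <- b$truth$systems
  tp <- b$truth$propeptides
  for (i in seq_len(nrow(tp))) {
    p <- tp[i, ]
    if (p$side == "plasmid_wide") next
    s <- ts[ts$system_id == p$system_id, ]
    wins <- build_flank_windows(list(start = s$rec_start, end = s$rec_end,
                                     strand = s$strand),
                                b$replicons[[s$replicon]], s$replicon)
    pos <- wins[[p$side]]$positions
    expect_true(all(seq.int(p$start, p$end - 1L) %in% pos),
                info = p$system_id)
  }
})

test_that("truth context labels are consistent with the MGE table", {
  b <- small_bundle()
  ts <- b$truth$systems
  for (i in seq_len(nrow(ts))) {
    s <- ts[i, ]
    ctx <- assign_context(list(replicon = s$replicon, start = s$rec_start,
                               end = s$rec_end), b$mge)
    expect_equal(ctx, s$context, info = s$system_id)
  }
})

test_that("generate_propeptide builds the stated architectures", {
  # single copy: the protein ends with the mature peptide
  pp <- generate_propeptide("Rap", 1, pathway = "SPI", seed = 5)
  m <- nchar(pp$mature)
  expect_equal(substr(pp$protein, nchar(pp$protein) - m + 1, nchar(pp$protein)),
               pp$mature)
  expect_true(grepl("KK", substr(pp$protein, 1, 12)))
  expect_gte(nchar(pp$protein), 20)
  expect_lte(nchar(pp$protein), 120)
  # the ORF round-trips through translation
  expect_equal(translate_dna(pp$dna), paste0(pp$protein, "*"))

  # six copies: naive substring scan finds exactly 6 occurrences
  pp6 <- generate_propeptide("NprR", 6, pathway = "SPI", seed = 6)
  hits <- gregexpr(pp6$mature, pp6$protein, fixed = TRUE)[[1]]
  expect_length(hits, 6L)

  # SPII carries a lipobox with invariant Cys at the cleavage point
  ppl <- generate_propeptide("PlcR", 1, pathway = "SPII", seed = 7)
  expect_equal(substr(ppl$protein, ppl$cleavage + 1, ppl$cleavage + 1), "C")
  expect_true(grepl("[LVI][ASTG][GA]C", ppl$protein))

  # sibling-style variant: copies differ only at the requested position
  ppv <- generate_propeptide("AimR", 2, variant_position = 5,
                             pathway = "SPI", seed = 8)
  a <- rrnppa:::aa_chars(ppv$matures[1])
  b <- rrnppa:::aa_chars(ppv$matures[2])
  expect_equal(which(a != b), 5L)
})

test_that("generate_propeptide validates sizes", {
  expect_error(generate_propeptide("Rap", 7), "n_copies")
  expect_error(generate_propeptide("Rap", 0), "n_copies")
  expect_error(generate_propeptide("Rap", 6, pathway = "SPI", seed = 1,
                                   mature = strrep("Q", 20)),
               "120 aa budget")
  expect_error(generate_propeptide("Rap", 1, variant_position = 3), "n_copies >= 2")
})
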