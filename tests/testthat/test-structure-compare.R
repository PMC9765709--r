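# Kabsch superposition, RMSD matrices, networks, dendrograms, clustering

test_that("kabsch_superpose is exact on rigid copies and validates input", {
  withr::with_seed(21, A <- matrix(stats::rnorm(30), 10, 3))
  expect_equal(kabsch_superpose(A, A)$rmsd, 0, tolerance = 1e-12)
  withr::with_seed(22, {
    for (i in 1:10) {
      R <- random_rotation()
      B <- A %*% R + matrix(rep(stats::rnorm(3), each = 10), 10)
      r <- kabsch_superpose(A, B)
      expect_lt(r$rmsd, 1e-8)
      expect_equal(det(r$rotation), 1, tolerance = 1e-8)
      # returned transform actually superposes B onto A
      expect_lt(max(abs(sweep(B %*% r$rotation, 2, -r$translation) - A)), 1e-6)
    }
  })
  expect_error(kabsch_superpose(A, A[1:5, ]), "matched point counts")
  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("kabsch RMSD equals numerical minimization over rotations", {
  withr::with_seed(23, {
    for (i in 1:10) {
      A <- matrix(stats::rnorm(30), 10, 3)
      B <- matrix(stats::rnorm(30), 10, 3)
      got <- kabsch_superpose(A, B)$rmsd
      expect_equal(got, numeric_min_rmsd(A, B), tolerance = 1e-6)
    }
  })
})

test_that("kabsch RMSD is invariant to rigid pre-transformations", {
  withr::with_seed(24, {
    A <- matrix(stats::rnorm(24), 8, 3)
    B <- matrix(stats::rnorm(24), 8, 3)
    base <- kabsch_superpose(A, B)$rmsd
    for (i in 1:5) {
      B2 <- B %*% random_rotation() + matrix(rep(stats::rnorm(3), each = 8), 8)
      expect_equal(kabsch_superpose(A, B2)$rmsd, base, tolerance = 1e-9)
    }
  })
})

test_that("rmsd_matrix is symmetric with informative errors", {
  withr::with_seed(25, {
    A <- matrix(stats::rnorm(30), 10, 3)
    B <- A + 0.1 * matrix(stats::rnorm(30), 10, 3)
    C <- matrix(stats::rnorm(30), 10, 3)
  })
  m <- rmsd_matrix(list(a = A, b = B, dup = A, c = C))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 4))
  expect_lt(m["a", "dup"], 1e-10)
  # noisy copy of the same template is closer than an unrelated cloud
  expect_lt(m["a", "b"], m["a", "c"])
  expect_error(rmsd_matrix(list(a = A, short = A[1:5, ])),
               "'a' and 'short'")
})

test_that("build_network thresholds distances into edges", {
  d <- matrix(c(0, 1, 5, 1, 0, 6, 5, 6, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(nrow(build_network(d, threshold = 0.5)$edges), 0L)
  expect_equal(nrow(build_network(d, threshold = 10)$edges), 3L)
  # planted two-cluster matrix: within < threshold < between
  labs <- c("a1", "a2", "b1", "b2")
  d2 <- matrix(4, 4, 4, dimnames = list(labs, labs))
  diag(d2) <- 0
  d2["a1", "a2"] <- d2["a2", "a1"] <- 1
  d2["b1", "b2"] <- d2["b2", "b1"] <- 1
  net <- build_network(d2, threshold = 2)
  expect_equal(nrow(net$edges), 2L)
  # exactly two connected components (tiny union-find)
  parent <- stats::setNames(labs, labs)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (k in seq_len(nrow(net$edges)))
    parent[find(net$edges$from[k])] <- find(net$edges$to[k])
  expect_equal(length(unique(vapply(labs, find, ""))), 2L)
  # default threshold is the median off-diagonal
  expect_equal(build_network(d2)$threshold, stats::median(d2[upper.tri(d2)]))
})

test_that("UPGMA recovers ultrametric trees and NJ recovers additive trees", {
  labs <- c("A", "B", "C", "D")
  # ultrametric: (A,B) at height 1, (C,D) at height 2, root at height 3
  du <- matrix(6, 4, 4, dimnames = list(labs, labs))
  diag(du) <- 0
  du["A", "B"] <- du["B", "A"] <- 2
  du["C", "D"] <- du["D", "C"] <- 4
  tu <- build_dendrogram(du, method = "upgma")
  expect_setequal(tu$tip.label, labs)
  expect_equal(as.matrix(stats::cophenetic(tu))[labs, labs], du)

  # additive: A:1,B:2 off one node, C:3,D:4 off the other, internal edge 5
  da <- matrix(0, 4, 4, dimnames = list(labs, labs))
  da["A", "B"] <- 3; da["C", "D"] <- 7
  da["A", "C"] <- 9; da["A", "D"] <- 10
  da["B", "C"] <- 10; da["B", "D"] <- 11
  da <- da + t(da)
  ta <- build_dendrogram(da, method = "nj")
  expect_equal(as.matrix(stats::cophenetic(ta))[labs, labs], da, tolerance = 1e-12)

  # label-order invariance (lexicographic pre-sort)
  perm <- c(3, 1, 4, 2)
  tp <- build_dendrogram(du[perm, perm], method = "upgma")
  expect_equal(ape::write.tree(tp), ape::write.tree(tu))

  # newick round-trip
  nw <- ape::write.tree(ta)
  back <- ape::read.tree(text = nw)
  expect_equal(as.matrix(stats::cophenetic(back))[labs, labs], da,
               tolerance = 1e-6)

  # midpoint rooting places the root halfway along the longest path
  tm <- build_dendrogram(da, method = "nj", rooting = "midpoint")
  cm <- as.matrix(stats::cophenetic(tm))
  expect_equal(cm[labs, labs], da, tolerance = 1e-12)
  depths <- ape::node.depth.edgelength(tm)[seq_len(4)]
  names(depths) <- tm$tip.label
  # deepest two tips straddle the midpoint of the B-D path (length 11)
  expect_equal(unname(depths["B"]), 5.5, tolerance = 1e-12)
  expect_equal(unname(depths["D"]), 5.5, tolerance = 1e-12)

  expect_error(build_dendrogram(du[1:2, 1:2]), "at least 3")
})

test_that("greedy_cluster applies identity and coverage gates", {
  s1 <- "MKTAYIAKQRQISFVKSHFSR"
  expect_equal(greedy_cluster(c(a = s1))$representatives, "a")
  r <- greedy_cluster(c(a = s1, b = s1))
  expect_equal(length(r$representatives), 1L)
  expect_equal(unname(r$membership["b"]), r$representatives[1])

  # 20-mer pair differing at 2 positions = 90% identity: split at 0.95
  x <- "ACDEFGHIKLMNPQRSTVWY"
  y <- "ACDEFGHIKLMNPQRSTAWA"  # differs at positions 18 and 20
  r2 <- greedy_cluster(c(x = x, y = y), identity = 0.95)
  expect_equal(length(r2$representatives), 2L)
  r3 <- greedy_cluster(c(x = x, y = y), identity = 0.85)
  expect_equal(length(r3$representatives), 1L)

  # coverage gate: a short perfect fragment stays separate at 0.95 coverage
  frag <- substr(s1, 1, 10)
  r4 <- greedy_cluster(c(a = s1, f = frag))
  expect_equal(length(r4$representatives), 2L)

  # one-pass property on random families: members match their representative
  withr::with_seed(31, {
    fam <- c(vapply(1:6, function(i) rrnppa:::random_protein(30), ""),
             vapply(1:6, function(i) rrnppa:::random_protein(30), ""))
    names(fam) <- paste0("s", 1:12)
    fam[7:12] <- fam[1:6] # exact duplicates join their template
  })
  r5 <- greedy_cluster(fam)
  expect_equal(length(r5$representatives), 6L)
  expect_true(all(fam[names(r5$membership)] == fam[r5$membership]))
})

test_that("CA PDB round-trip preserves coordinates", {
  withr::with_seed(41, coords <- matrix(round(stats::rnorm(30, sd = 10), 3), 10, 3))
  f <- tempfile(fileext = ".pdb")
  write_ca_pdb(coords, f)
  back <- read_ca_coords(f, chain = "A")
  expect_equal(unname(back), unname(coords), tolerance = 1e-9)
  sel <- read_ca_coords(f, residues = c(3, 1, 5))
  expect_equal(unname(sel), unname(coords[c(3, 1, 5), ]), tolerance = 1e-9)
  expect_error(read_ca_coords(f, residues = 99), "missing from chain")
})
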