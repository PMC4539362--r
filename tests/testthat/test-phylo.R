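test_that("T92 distance: zero on identity, closed form to 1e-12, K2P at theta 0.5", {
  expect_equal(t92_distance("ACGTACGT", "ACGTACGT"), 0)
  # 20 columns, theta = 0.5 in both sequences, P = 2/20, Q = 1/20
  x <- "AAAAAAAAAACCCCCCCCCC"
  y <- paste0("G", "AAAAAAAA", "T", "TCCCCCCCC", "C")  # A>G ts, A>T tv, C>T ts
  cmp_manual <- -0.5 * log(1 - 2 * 0.1 - 0.05) - 0.25 * log(1 - 2 * 0.05)
  expect_equal(t92_distance(x, y), cmp_manual, tolerance = 1e-12)
  # with theta forced to 0.5 the formula is exactly Kimura's 2-parameter
  k2p <- function(P, Q) -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  expect_equal(t92_distance(x, y, theta = 0.5), k2p(0.1, 0.05),
               tolerance = 1e-12)
})

test_that("T92 agrees with an independent implementation on simulated alignments", {
  tr <- random_tree(5, seed = 3, min_bl = 0.02, max_bl = 0.1)
  aln <- simulate_alignment(tr, length = 2000, seed = 3)$alignment
  mine <- t92_distance_matrix(aln, theta_mode = "alignment")
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(aln$seq), "")))
  rownames(bin) <- aln$id
  ref <- as.matrix(ape::dist.dna(bin, model = "T92"))
  expect_equal(mine, ref[rownames(mine), colnames(mine)], tolerance = 1e-12)
})

test_that("transversion-only divergence is corrected upwards and errors flag saturation", {
  x <- strrep("A", 50)
  y <- paste0(strrep("C", 10), strrep("A", 40))   # Q = 0.2, P = 0
  d <- t92_distance(x, y)
  expect_gt(d, 0.2)
  expect_error(t92_distance(strrep("A", 10), strrep("C", 10)), "saturated")
  expect_error(t92_distance("----", "ACGT"), "valid")
  # gap/N columns are excluded pairwise
  expect_equal(t92_distance("ACGT-N", "ACGTAC"), 0)
})

test_that("NJ solves the three-taxon case by the three-point formulas", {
  dm <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm)
  expect_equal(ape::Ntip(tr), 3L)
  pd <- ape::cophenetic.phylo(tr)
  expect_equal(pd[rownames(dm), colnames(dm)], dm, tolerance = 1e-9)
})

test_that("NJ recovers the generating topology and lengths from additive matrices", {
  for (seed in 1:12) {
    ntip <- sample(4:8, 1)
    tr <- random_tree(ntip, seed = 1000 + seed)
    dm <- ape::cophenetic.phylo(tr)
    est <- nj_tree(dm)
    expect_equal(rf_distance(est, tr), 0L, info = paste("seed", seed))
    pd <- ape::cophenetic.phylo(est)
    expect_equal(pd[rownames(dm), colnames(dm)], dm, tolerance = 1e-8)
  }
})

test_that("NJ topology matches the exhaustive least-squares search on 5 taxa", {
  skip_if_not_installed("phangorn")
  for (seed in 1:5) {
    tr <- random_tree(5, seed = 2000 + seed)
    dm <- ape::cophenetic.phylo(tr)
    best <- ls_best_topology(dm)
    expect_equal(rf_distance(nj_tree(dm), best), 0L)
  }
})

test_that("NJ validates its input", {
  m <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(nj_tree(m), "at least 3")
  bad <- matrix(c(0, 1, 2, 1, 0, 3, 2.5, 3, 0), 3, 3)
  expect_error(nj_tree(bad), "symmetric")
})

test_that("RF distance: zero on identical trees, 2 between the 4-taxon topologies", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 2L)
  t3 <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(rf_distance(t1, t3), "leaf")
})

test_that("RF equals the independent bipartition implementation on random 6-taxon pairs", {
  skip_if_not_installed("phangorn")
  for (seed in 1:25) {
    t1 <- random_tree(6, seed = 3000 + seed)
    t2 <- random_tree(6, seed = 4000 + seed)
    t2$tip.label <- t1$tip.label
    expect_equal(rf_distance(t1, t2),
                 as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2))))
  }
})

test_that("clade membership follows bipartitions", {
  tr <- ape::read.tree(text = "((A,B),((C,D),(E,F)));")
  out <- clade_membership(tr, list(ab = c("A", "B"), cdef = c("C", "D", "E", "F"),
                                   ac = c("A", "C"), solo = "A"))
  expect_equal(out$monophyletic, c(TRUE, TRUE, FALSE, TRUE))
  expect_match(out$note[4], "vacuously")
  t4 <- ape::read.tree(text = "((A,B),(C,D));")
  expect_false(clade_membership(t4, list(x = c("A", "C")))$monophyletic)
})

test_that("congruence scan is quiet on single-history alignments and flags conversions", {
  nwk <- "((A:0.05,B:0.05):0.06,(C:0.05,D:0.05):0.06,(E:0.05,F:0.05):0.06);"
  part <- tibble::tibble(
    label = c("exon1", "intron1", "exon2", "intron2", "exon3",
              "intron3_5prime", "three_prime_region"),
    start = seq(1, by = 600, length.out = 7),
    end = seq(600, by = 600, length.out = 7))
  sim0 <- simulate_alignment(nwk, length = 4200, seed = 21)
  r0 <- congruence_scan(sim0$alignment, part)
  expect_equal(nrow(r0$flags), 0L)
  expect_true(all(r0$rf == 0))
  expect_true(all(r0$rf %% 2 == 0))

  sim1 <- simulate_alignment(nwk, length = 4200, seed = 22,
                             conversion = list(donor = "A", recipient = "C",
                                               start = 1, end = 2400,
                                               gc_bias = 0.7))
  r1 <- congruence_scan(sim1$alignment, part)
  expect_gt(nrow(r1$flags), 0L)
  # flagged at the conversion edge (intron2 | exon3 boundary, column 2400),
  # allowing one segment of slack
  expect_true(any(abs(r1$flags$boundary_column - 2400) <= 600))
})

test_that("three-taxon scans return trees but can flag nothing", {
  nwk <- "(A:0.1,B:0.1,C:0.1);"
  part <- tibble::tibble(label = c("s1", "s2"), start = c(1, 501),
                         end = c(500, 1000))
  sim <- simulate_alignment(nwk, length = 1000, seed = 5)
  r <- congruence_scan(sim$alignment, part)
  expect_equal(length(r$trees), 2L)
  expect_equal(nrow(r$flags), 0L)
})

test_that("short or saturated segments are skipped with a warning", {
  nwk <- "((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05);"
  part <- tibble::tibble(label = c("tiny", "main"), start = c(1, 31),
                         end = c(30, 1000))
  sim <- simulate_alignment(nwk, length = 1000, seed = 6)
  expect_warning(r <- congruence_scan(sim$alignment, part), "tiny")
  expect_equal(names(r$trees), "main")
  expect_equal(r$skipped, "tiny")
})

test_that("segment trees serialise to a Newick bundle", {
  nwk <- "((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05);"
  part <- tibble::tibble(label = c("s1", "s2"), start = c(1, 501),
                         end = c(500, 1000))
  sim <- simulate_alignment(nwk, length = 1000, seed = 7)
  r <- congruence_scan(sim$alignment, part)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_trees_newick(r, path)
  trees <- ape::read.tree(path)
  expect_equal(length(trees), 2L)
})
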