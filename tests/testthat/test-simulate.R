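test_that("zero-rate single-block config reproduces flank + block + flank exactly", {
  cfg <- sim_config(seed = 2, n_blocks = 1, block_divergence = 0,
                    flank_length = 1500, block_length = 3000)
  h <- simulate_haplotype(cfg)
  expect_equal(h$seq$length, 1500L + 3000L + 1500L)
  expect_equal(nrow(h$truth$blocks), 1L)
  expect_equal(h$truth$blocks$start, 1501L)
  expect_equal(h$truth$blocks$end, 4500L)
  # a zero-divergence pair shares the block region byte for byte
  p <- simulate_haplotype_pair(sim_config(seed = 2, n_blocks = 2,
                                          block_divergence = 0,
                                          flank_divergence = 0,
                                          flank_length = 1000))
  expect_equal(substr(p$a$seq$seq, 1, 1000), substr(p$b$seq$seq, 1, 1000))
})

test_that("the same seed reproduces haplotypes byte for byte", {
  cfg <- sim_config(seed = 77, n_blocks = 3, block_divergence = 0.04,
                    inversion = list(position = 2000, length = 300))
  h1 <- simulate_haplotype(cfg)
  h2 <- simulate_haplotype(cfg)
  expect_identical(h1$seq$seq, h2$seq$seq)
  expect_identical(h1$truth$blocks, h2$truth$blocks)
  h3 <- simulate_haplotype(sim_config(seed = 78, n_blocks = 3,
                                      block_divergence = 0.04))
  expect_false(identical(h1$seq$seq, h3$seq$seq))
})

test_that("realised substitution fraction stays within 3 SD of the binomial expectation", {
  p <- 0.05
  cfg <- sim_config(seed = 9, n_blocks = 2, block_divergence = p,
                    gene_spacing_range = c(8000, 8000))
  h <- simulate_haplotype(cfg)
  # copies 1 and 2 both derive from the ancestor: pairwise mismatch fraction
  # approximately 2p(1 - p) (minus coincident hits)
  b <- h$truth$blocks
  c1 <- substr(h$seq$seq, b$start[1], b$start[1] + 7999)
  c2 <- substr(h$seq$seq, b$start[2], b$start[2] + 7999)
  mm <- mean(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  # expectation: 2p(1-p) + p^2 * 5/8 (both-hit collisions under kappa = 2)
  exp_mm <- 2 * p * (1 - p) + p^2 * 5 / 8
  expect_lt(abs(mm - exp_mm), 3 * sqrt(exp_mm * (1 - exp_mm) / 8000))
})

test_that("truth features are internally consistent with the emitted sequence", {
  cfg <- sim_config(seed = 30, n_blocks = 3)
  h <- simulate_haplotype(cfg)
  f <- h$truth$features
  expect_true(all(f$end <= h$seq$length))
  expect_true(all(f$start >= 1))
  cds <- dplyr::filter(f, kind == "CDS")
  expect_equal(sum(cds$end - cds$start + 1) %% 3, 0)
  expect_equal(sum(f$kind == "gene"), 3L)
  # genes fall inside their blocks
  g <- dplyr::filter(f, kind == "gene")
  expect_true(all(g$start >= h$truth$blocks$start &
                    g$end <= h$truth$blocks$end))
})

test_that("conversion tracts raise recipient GC under full bias and are recorded", {
  cfg <- sim_config(seed = 41, n_blocks = 2, block_divergence = 0.15,
                    gene_spacing_range = c(6000, 6000), gc = 0.5,
                    conversion = list(donor = 1, recipient = 2,
                                      tract_length = 800, gc_bias = 1))
  h <- simulate_haplotype(cfg)
  tr <- h$truth$conversion
  expect_equal(tr$end - tr$start + 1L, 800L)
  tract <- substr(h$seq$seq, tr$start, tr$end)
  don <- substr(h$seq$seq,
                h$truth$blocks$start[1] + 500L,
                h$truth$blocks$start[1] + 500L + 799L)
  gc_of <- function(x) mean(strsplit(x, "")[[1]] %in% c("G", "C"))
  # with gc_bias = 1 every GC/AT difference resolves to GC
  expect_gte(gc_of(tract), gc_of(don))
  # tract exceeding the block errors
  expect_error(simulate_haplotype(sim_config(
    seed = 41, n_blocks = 2, gene_spacing_range = c(6000, 6000),
    conversion = list(donor = 1, recipient = 2, tract_length = 7000))),
    "tract exceeds")
})

test_that("alignment simulation: zero branch lengths give identical sequences", {
  nwk <- "((A:0,B:0):0,(C:0,D:0):0);"
  sim <- simulate_alignment(nwk, length = 500, seed = 3)
  expect_equal(length(unique(sim$alignment$seq)), 1L)
  dm <- t92_distance_matrix(sim$alignment)
  expect_true(all(dm == 0))
})

test_that("alignment simulation respects theta and records conversion truth", {
  nwk <- "((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);"
  sim <- simulate_alignment(nwk, length = 4000, theta = 0.7, seed = 8)
  gc <- mean(strsplit(paste0(sim$alignment$seq, collapse = ""), "")[[1]] %in%
               c("G", "C"))
  expect_equal(gc, 0.7, tolerance = 0.03)
  sim2 <- simulate_alignment(nwk, length = 1000, seed = 9,
                             conversion = list(donor = "A", recipient = "D",
                                               start = 101, end = 400,
                                               gc_bias = 1))
  expect_equal(sim2$truth$start, 101)
  a <- strsplit(sim2$alignment$seq[sim2$alignment$id == "A"], "")[[1]]
  d <- strsplit(sim2$alignment$seq[sim2$alignment$id == "D"], "")[[1]]
  inside <- mean(a[101:400] == d[101:400])
  outside <- mean(a[-(101:400)] == d[-(101:400)])
  expect_gt(inside, outside)
  expect_error(simulate_alignment(nwk, length = 100, seed = 1,
                                  conversion = list(donor = "A",
                                                    recipient = "B",
                                                    start = 50, end = 200)),
               "outside")
})

test_that("clone simulation with no implants reproduces substrings and truth is empty", {
  h <- simulate_haplotype(sim_config(seed = 12, n_blocks = 1,
                                     block_divergence = 0))
  lay <- tibble::tibble(id = c("x", "y"), start = c(1L, 4001L),
                        end = c(9000L, h$seq$length))
  cl <- simulate_clones(h$seq, lay)
  expect_equal(cl$clones$seq[1], substr(h$seq$seq, 1, 9000))
  expect_equal(nrow(cl$truth), 0L)
})

test_that("fragmentation truth tiles the reference with the requested gaps", {
  s <- random_seq(30000, seed = 14)
  gaps <- c(10, 1000, 250)
  fr <- fragment_sequence(s, gaps = gaps, min_piece = 5000, seed = 15)
  tr <- fr$truth
  expect_equal(nrow(tr), 4L)
  expect_equal(tr$ref_start[-1] - tr$ref_end[-4] - 1L, gaps)
  expect_equal(tr$ref_end[4], 30000L)
  # emitted contig sequences match their recorded placements
  for (i in seq_len(4)) {
    emitted <- fr$contigs$seq[fr$contigs$id == tr$contig_id[i]]
    want <- substr(s, tr$ref_start[i], tr$ref_end[i])
    if (tr$orientation[i] == "reverse") want <- reverse_complement(want)
    expect_identical(emitted, want)
  }
})

test_that("truth records serialise to JSON", {
  skip_if_not_installed("jsonlite")
  h <- simulate_haplotype(sim_config(seed = 1, n_blocks = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_json(h$truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(back$blocks), 2)
})
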