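test_that("self-overlap of an identical sequence is full-length, identity 1, no variants", {
  s <- seq_tbl(c("a", "b"), rep(random_seq(50000, seed = 2), 2))
  ov <- find_end_overlap(s)
  expect_s3_class(ov, "overlap_alignment")
  expect_equal(ov$a_start, 1L); expect_equal(ov$a_end, 50000L)
  expect_equal(ov$b_start, 1L); expect_equal(ov$b_end, 50000L)
  expect_identical(ov$identity, 1)
  expect_equal(nrow(call_overlap_variants(ov)), 0L)
})

test_that("suffix/prefix overlap is recovered exactly by construction", {
  a <- random_seq(30000, seed = 3)
  b <- paste0(substr(a, 20001, 30000), random_seq(5000, seed = 4))
  s <- seq_tbl(c("a", "b"), c(a, b))
  ov <- find_end_overlap(s)
  expect_equal(ov$b_start, 1L)
  expect_equal(ov$a_end - ov$a_start + 1L, 10000L)
  expect_equal(ov$a_start, 20001L)
  expect_identical(substr(a, ov$a_start, ov$a_end),
                   substr(b, ov$b_start, ov$b_end))
  expect_equal(ov$orientation, "forward")
})

test_that("reverse-orientation overlaps are detected and reported in original coordinates", {
  a <- random_seq(20000, seed = 6)
  b_fwd <- paste0(substr(a, 12001, 20000), random_seq(3000, seed = 7))
  s <- seq_tbl(c("a", "b"), c(a, reverse_complement(b_fwd)))
  ov <- find_end_overlap(s)
  expect_equal(ov$orientation, "reverse")
  expect_equal(ov$a_start, 12001L)
  nb <- nchar(b_fwd)
  expect_equal(ov$b_end, nb)        # prefix of b_fwd = suffix of stored rc
  expect_identical(ov$identity, 1)
})

test_that("sequences shorter than min_overlap give NULL, not an error", {
  s <- seq_tbl(c("a", "b"), c(random_seq(500, seed = 1), random_seq(500, seed = 2)))
  expect_null(find_end_overlap(s, min_overlap = 1000))
})

test_that("implanted SNPs and indels are recovered exactly", {
  fx <- make_clone_pair(seed = 42, overlap = 8000,
                        variants = list(list(pair = c("cA", "cB"), snps = 5,
                                             indels = c(-10))))
  ov <- find_end_overlap(fx$clones)
  v <- call_overlap_variants(ov)
  expect_equal(sum(v$kind == "SNP"), 5L)
  expect_equal(sum(v$kind == "deletion"), 1L)
  expect_equal(v$length[v$kind == "deletion"], 10L)
  expect_equal(sort(v$pos_a[v$kind == "SNP"]),
               sort(fx$truth$pos_a[fx$truth$kind == "SNP"]))
})

test_that("an implanted 514-bp inverted segment yields one inversion call of exact length", {
  fx <- make_clone_pair(seed = 13, overlap = 6000,
                        variants = list(list(pair = c("cA", "cB"),
                                             inversion = 514)))
  ov <- find_end_overlap(fx$clones, min_identity = 0.85)
  v <- call_overlap_variants(ov, min_inversion = 100)
  inv <- v[v$kind == "inversion", ]
  expect_equal(nrow(inv), 1L)
  expect_equal(inv$length, 514L)
  expect_equal(inv$pos_a, fx$truth$pos_a[fx$truth$kind == "inversion"])
  # re-labelling does not change the alignment itself
  expect_equal(ov$aligned_length, nchar(ov$a_aln))
})

test_that("variant positions are strictly increasing and confined to the overlap", {
  for (seed in c(3, 17, 29)) {
    fx <- make_clone_pair(seed = seed, overlap = 9000,
                          variants = list(list(pair = c("cA", "cB"), snps = 12,
                                               indels = c(25, -40))),
                          variant_seed = seed + 1)
    ov <- find_end_overlap(fx$clones)
    v <- call_overlap_variants(ov)
    expect_true(all(diff(v$pos_a) > 0))
    expect_true(all(v$pos_a >= ov$a_start & v$pos_a <= ov$a_end))
  }
})

test_that("variant counts equal the implant record across seeded replicates", {
  for (seed in 1:6) {
    fx <- make_clone_pair(seed = 100 + seed, overlap = 10000,
                          variants = list(list(pair = c("cA", "cB"), snps = 10,
                                               indels = c(60, -35, 12))),
                          variant_seed = seed)
    ov <- find_end_overlap(fx$clones)
    v <- call_overlap_variants(ov)
    expect_equal(sum(v$kind == "SNP"), 10L, info = paste("seed", seed))
    expect_equal(sum(v$kind == "insertion"), 2L, info = paste("seed", seed))
    expect_equal(sum(v$kind == "deletion"), 1L, info = paste("seed", seed))
  }
})

test_that("all-pairs overlap table matches the tiling-path layout", {
  h <- simulate_haplotype(sim_config(seed = 31, n_blocks = 1,
                                     block_divergence = 0,
                                     flank_length = 12000))
  n <- h$seq$length
  lay <- tibble::tibble(id = c("c1", "c2", "c3"),
                        start = c(1L, 8001L, 18001L),
                        end = c(12000L, 22000L, n))
  cl <- simulate_clones(h$seq, lay)
  ovs <- find_all_overlaps(cl$clones, min_overlap = 2000)
  expect_setequal(paste(ovs$id_a, ovs$id_b),
                  c("c1 c2", "c2 c3"))
  expect_true(all(ovs$identity == 1))
})

test_that("variants export as minimal VCF with symbolic inversions", {
  v <- tibble::tibble(kind = c("SNP", "deletion", "inversion"),
                      pos_a = c(10L, 50L, 200L), pos_b = c(10L, 50L, 200L),
                      length = c(1L, 3L, 514L),
                      allele_a = c("A", "TTT", "X"), allele_b = c("G", "", ""))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_variants_vcf(v, "cloneA", path)
  lines <- readLines(path)
  expect_true(any(grepl("^##fileformat=VCF", lines)))
  expect_true(any(grepl("cloneA\t200\t.\tN\t<INV>\t.\t.\tEND=713;SVLEN=514",
                        lines, fixed = TRUE)))
})
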