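test_that("degenerate compositions give the exact expected profiles", {
  all_gc <- strrep("GC", 500)
  sc <- gc_profile(all_gc, window = 100)
  expect_true(all(sc$windows$gc == 1))
  expect_equal(sc$sd, 0)
  half <- strrep("ATGC", 250)
  sc2 <- gc_profile(half, window = 100)
  expect_true(all(sc2$windows$gc == 0.5))
})

test_that("random sequence has mean GC near one half", {
  sc <- gc_profile(random_seq(10000, seed = 3), window = 100, step = 10)
  expect_equal(sc$mean, 0.5, tolerance = 0.02)
})

test_that("N bases drop out of the denominator and all-N windows are missing", {
  s <- paste0(strrep("G", 50), strrep("N", 200), strrep("A", 50))
  sc <- gc_profile(s, window = 100)
  expect_true(any(is.na(sc$windows$gc)))
  expect_equal(sc$windows$gc[1], 1)        # 50 G + 50 N: GC = 50/50
  expect_false(is.na(sc$mean))
})

test_that("an implanted high-GC tract is flagged as one anomaly covering the tract", {
  s <- paste0(random_seq(4000, gc = 0.40, seed = 9),
              random_seq(300, gc = 0.80, seed = 10),
              random_seq(5700, gc = 0.40, seed = 11))
  sc <- gc_profile(s, window = 100)
  an <- flag_anomalies(sc, z_cutoff = 2.5)
  expect_equal(nrow(an), 1L)
  expect_lte(an$start, 4001)
  expect_gte(an$end, 4300)
  expect_lte(4001 - an$start, 100)
  expect_lte(an$end - 4300, 100)
  expect_gt(an$peak_z, 2.5)
})

test_that("a constant scan warns and flags nothing; zero cutoff floods", {
  sc <- gc_profile(strrep("GC", 300), window = 100)
  expect_warning(an <- flag_anomalies(sc), "no variation")
  expect_equal(nrow(an), 0L)
  s <- paste0(random_seq(2000, gc = 0.4, seed = 1),
              random_seq(200, gc = 0.9, seed = 2),
              random_seq(2000, gc = 0.4, seed = 3))
  sc2 <- gc_profile(s, window = 100)
  an0 <- flag_anomalies(sc2, z_cutoff = 0, min_windows = 1)
  # every window at or above the mean qualifies
  expect_equal(sum(an0$n_windows),
               sum(sc2$windows$gc >= sc2$mean, na.rm = TRUE))
})

test_that("the number of flagged windows is non-increasing in the z cut-off", {
  s <- paste0(random_seq(3000, gc = 0.4, seed = 5),
              random_seq(250, gc = 0.85, seed = 6),
              random_seq(3000, gc = 0.4, seed = 7))
  sc <- gc_profile(s, window = 100)
  counts <- vapply(c(0.5, 1, 1.5, 2, 2.5, 3, 4),
                   function(z) sum(flag_anomalies(sc, z)$n_windows),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("anomaly intervals are disjoint and maximal", {
  s <- paste0(random_seq(2000, gc = 0.4, seed = 12),
              random_seq(200, gc = 0.9, seed = 13),
              random_seq(1500, gc = 0.4, seed = 14),
              random_seq(200, gc = 0.9, seed = 15),
              random_seq(2000, gc = 0.4, seed = 16))
  an <- flag_anomalies(gc_profile(s, window = 100), 2.5)
  expect_equal(nrow(an), 2L)
  expect_true(all(an$start[-1] > an$end[-nrow(an)]))
})

test_that("window-partition mean equals whole-interval GC when step = window", {
  s <- random_seq(5000, gc = 0.55, seed = 20)
  sc <- gc_profile(s, window = 100, step = 100)
  whole <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
  expect_equal(mean(sc$windows$gc), whole, tolerance = 1e-12)
})

test_that("anomalies associate with the nearest exon boundary within range", {
  feats <- feature_tbl("g", "exon", c(1001, 2001, 3001), c(1100, 2100, 3100),
                       name = paste0("exon", 1:3))
  an <- tibble::tibble(start = c(950L, 2500L), end = c(1050L, 2600L),
                       peak_z = c(3, 3), peak_gc = c(0.8, 0.8),
                       n_windows = c(10L, 10L))
  out <- associate_boundaries(an, feats, max_dist = 200)
  expect_equal(out$boundary_name[1], "exon1_start")
  expect_equal(out$boundary_dist[1], 0L)        # boundary inside interval
  expect_true(is.na(out$boundary_name[2]))      # 400 bp away from any boundary
})

test_that("GC tracts implanted at three 5' junctions associate with the right boundaries", {
  set.seed(31)
  low <- function(n) random_seq(n, gc = 0.35)
  hot <- function(n) random_seq(n, gc = 0.90)
  # exon starts at 501, 1501, 2501; 120-bp hot tract straddles each start
  s <- paste0(low(440), hot(120), low(940), hot(120), low(940), hot(120),
              low(940))
  feats <- feature_tbl("g", "exon", c(501, 1501, 2501), c(800, 1800, 2800),
                       name = paste0("exon", 1:3))
  an <- flag_anomalies(gc_profile(s, window = 100), 2.5)
  out <- associate_boundaries(an, feats, max_dist = 200)
  expect_setequal(setdiff(out$boundary_name, NA),
                  paste0("exon", 1:3, "_start"))
})

test_that("BED and bedGraph exports convert to 0-based half-open intervals", {
  an <- tibble::tibble(start = 101L, end = 200L, peak_z = 3.21,
                       peak_gc = 0.9, n_windows = 5L)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_anomalies_bed(an, "chr", bed)
  expect_equal(readLines(bed), "chr\t100\t200\tgc_anomaly_1\t321\t.")
  sc <- gc_profile(strrep("ATGC", 100), window = 100, step = 100)
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  write_gc_bedgraph(sc, bg)
  lines <- readLines(bg)
  expect_match(lines[2], "^seq\t0\t100\t0\\.5$")
})
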