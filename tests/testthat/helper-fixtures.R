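# Shared fixture builders. Everything is generated in code; no binary data.

# a clone pair cut from one haplotype with a known overlap interval
make_clone_pair <- function(seed = 11, hap_len_flank = 20000, overlap = 10000,
                            variants = NULL, variant_seed = 5) {
  cfg <- sim_config(seed = seed, n_blocks = 1, block_divergence = 0,
                    flank_length = hap_len_flank)
  h <- simulate_haplotype(cfg)
  n <- h$seq$length
  lay <- tibble::tibble(id = c("cA", "cB"),
                        start = c(1L, n - overlap - 4000L + 1L),
                        end = c(n - 4000L, n))
  lay$end[1] <- lay$start[2] + overlap - 1L
  cl <- simulate_clones(h$seq, lay, variants = variants, seed = variant_seed)
  list(hap = h, layout = lay, clones = cl$clones, truth = cl$truth)
}

# brute-force maximum matching size between two fragment multisets under the
# package's tolerance rule (oracle for the greedy matcher, <= 8 fragments)
bf_max_matching <- function(fa, fb, rel_tol = 0.05, abs_tol = 50) {
  ok <- function(x, y) abs(x - y) <= max(abs_tol, rel_tol * max(x, y))
  best <- 0L
  recur <- function(ia, used_b, count) {
    best <<- max(best, count)
    if (ia > length(fa)) return()
    recur(ia + 1L, used_b, count)          # leave fa[ia] unmatched
    for (j in seq_along(fb)) {
      if (!used_b[j] && ok(fa[ia], fb[j])) {
        used_b[j] <- TRUE
        recur(ia + 1L, used_b, count + 1L)
        used_b[j] <- FALSE
      }
    }
  }
  recur(1L, rep(FALSE, length(fb)), 0L)
  best
}

# all unrooted topologies over the given taxa (via phangorn), for the
# least-squares NJ oracle
ls_best_topology <- function(dm) {
  taxa <- rownames(dm)
  trees <- phangorn::allTrees(length(taxa), rooted = FALSE, tip.label = taxa)
  rss <- vapply(trees, function(tr) {
    tr$edge.length <- rep(1, nrow(tr$edge))
    # design matrix: path incidence of each edge for each taxon pair
    n <- length(taxa)
    pairs <- utils::combn(n, 2)
    A <- matrix(0, ncol(pairs), nrow(tr$edge))
    for (pi in seq_len(ncol(pairs))) {
      p <- ape::nodepath(tr, pairs[1, pi], pairs[2, pi])
      for (e in seq_len(nrow(tr$edge))) {
        for (s in seq_len(length(p) - 1)) {
          if (all(sort(c(p[s], p[s + 1])) == sort(tr$edge[e, ]))) A[pi, e] <- 1
        }
      }
    }
    y <- dm[t(pairs)]
    fit <- stats::lm.fit(A, y)
    sum(fit$residuals^2)
  }, numeric(1))
  trees[[which.min(rss)]]
}

random_tree <- function(ntip, seed, min_bl = 0.02, max_bl = 0.3) {
  with_seed_test(seed, {
    tr <- ape::rtree(ntip, rooted = FALSE,
                     br = function(n) stats::runif(n, min_bl, max_bl))
    tr
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
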