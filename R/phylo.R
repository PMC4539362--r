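# Segment-partitioned phylogenetics: Tamura three-parameter distances,
# neighbor-joining, Robinson-Foulds incongruence and breakpoint flagging.
#
# The T92 distance corrects the raw transition (P) and transversion (Q)
# proportions for transition bias and GC content theta:
#   h = 2 * theta * (1 - theta)
#   d = -h * ln(1 - P/h - Q) - (1 - h)/2 * ln(1 - 2Q)
# Trees are ape::phylo objects; NJ and RF are implemented here and
# cross-checked against ape/phangorn in the test suite.

PURINES <- c("A", "G"); PYRIMIDINES <- c("C", "T")

t92_components <- function(a, b) {
  av <- strsplit(toupper(a), "")[[1]]; bv <- strsplit(toupper(b), "")[[1]]
  if (length(av) != length(bv)) abort("aligned sequences differ in length")
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n == 0) abort("no valid (gap/N-free) columns")
  av <- av[ok]; bv <- bv[ok]
  diff <- av != bv
  ts <- diff & ((av %in% PURINES & bv %in% PURINES) |
                  (av %in% PYRIMIDINES & bv %in% PYRIMIDINES))
  theta <- mean(c(av, bv) %in% c("G", "C"))
  list(P = sum(ts) / n, Q = sum(diff & !ts) / n, theta = theta, n = n)
}

#' Tamura three-parameter (T92) distance
#'
#' Pairwise nucleotide distance under Tamura's 1992 model, which accounts
#' for transition/transversion bias and deviation of GC content from 0.5.
#' Columns containing a gap or N in either sequence are excluded (pairwise
#' deletion); theta is estimated from the two sequences over the included
#' columns. At theta = 0.5 the distance reduces to Kimura's two-parameter
#' formula.
#'
#' @param a,b Equal-length aligned sequences (strings).
#' @param theta Optional fixed GC fraction; default estimates it per pair.
#' @return The distance (substitutions per site).
#' @export
t92_distance <- function(a, b, theta = NULL) {
  cmp <- t92_components(a, b)
  th <- theta %||% cmp$theta
  h <- 2 * th * (1 - th)
  arg1 <- if (cmp$P == 0) 1 - cmp$Q else 1 - cmp$P / h - cmp$Q
  arg2 <- 1 - 2 * cmp$Q
  if (arg1 <= 0 || arg2 <= 0)
    abort("t92_distance: saturated pair (log argument <= 0)")
  term1 <- if (cmp$P == 0 && h == 0) -cmp$Q * 0 else -h * log(arg1)
  term1 - 0.5 * (1 - h) * log(arg2)
}

#' T92 distance matrix for an alignment
#'
#' @param aln Alignment as a sequence tibble (equal-length `seq` strings) or
#'   a named character vector.
#' @param theta_mode `"pairwise"` (theta per pair, default) or
#'   `"alignment"` (one theta over the whole alignment).
#' @return A symmetric matrix with taxa as dimnames. Errors on saturated
#'   pairs, naming them.
#' @export
t92_distance_matrix <- function(aln, theta_mode = c("pairwise", "alignment")) {
  theta_mode <- match.arg(theta_mode)
  if (is.data.frame(aln)) aln <- setNames(aln$seq, aln$id)
  n <- length(aln)
  theta <- NULL
  if (theta_mode == "alignment") {
    all_b <- strsplit(toupper(paste0(aln, collapse = "")), "")[[1]]
    all_b <- all_b[all_b %in% c("A", "C", "G", "T")]
    theta <- mean(all_b %in% c("G", "C"))
  }
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dij <- tryCatch(t92_distance(aln[[i]], aln[[j]], theta = theta),
                    error = function(e) abort(sprintf(
                      "pair %s / %s: %s", names(aln)[i], names(aln)[j],
                      conditionMessage(e))))
    d[i, j] <- d[j, i] <- dij
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with the canonical Q-criterion. Ties on Q are
#' broken by the lowest taxon-index pair, making the result deterministic;
#' negative branch lengths are clamped to zero. On an additive distance
#' matrix the generating tree is recovered exactly.
#'
#' @param dm Symmetric non-negative distance matrix with taxa dimnames (at
#'   least 3 taxa).
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3) abort("nj_tree: need at least 3 taxa")
  if (any(dm < 0) || any(abs(dm - t(dm)) > 1e-9))
    abort("nj_tree: distance matrix must be symmetric and non-negative")
  labels <- rownames(dm) %||% paste0("t", seq_len(n))
  # each active node is a Newick fragment; join events nest them
  frag <- labels
  D <- dm
  while (length(frag) > 2) {
    m <- length(frag)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    vi <- max(vi, 0); vj <- max(vj, 0)
    new_frag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], vi, frag[j], vj)
    du <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    frag <- c(frag[keep], new_frag)
    D <- D2
  }
  bl <- max(D[1, 2], 0)
  nwk <- sprintf("(%s:%.10g,%s:0);", frag[1], bl, frag[2])
  tr <- ape::read.tree(text = nwk)
  ape::unroot(tr)
}

# non-trivial bipartitions of an unrooted tree as canonical strings
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  ntip <- length(tree$tip.label)
  desc <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(purrr::map(kids, function(k)
      if (k <= ntip) tree$tip.label[k] else desc(k)))
  }
  internal <- unique(tree$edge[, 2][tree$edge[, 2] > ntip])
  parts <- purrr::map_chr(internal, function(node) {
    side <- sort(desc(node))
    if (length(side) < 2 || length(side) > ntip - 2) return(NA_character_)
    if (tips[1] %in% side) side <- setdiff(tips, side)  # canonical side
    paste(sort(side), collapse = "|")
  })
  unique(parts[!is.na(parts)])
}

#' Robinson-Foulds distance
#'
#' Size of the symmetric difference between the non-trivial bipartition sets
#' of two unrooted trees over the same taxa. Always an even number for
#' binary trees; zero iff the topologies are identical.
#'
#' @param t1,t2 `ape::phylo` trees with identical leaf sets.
#' @return Integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    abort("rf_distance: trees have different leaf sets")
  b1 <- tree_bipartitions(t1); b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Test monophyly of labelled groups
#'
#' A group is monophyletic on an unrooted tree iff some bipartition equals
#' the group. Groups of fewer than two taxa are vacuously monophyletic
#' (noted).
#'
#' @param tree An `ape::phylo` tree.
#' @param groups Named list of taxon-label vectors.
#' @return A tibble: `group`, `n_taxa`, `monophyletic`, `note`.
#' @export
clade_membership <- function(tree, groups) {
  parts <- tree_bipartitions(tree)
  tips <- sort(tree$tip.label)
  purrr::imap_dfr(groups, function(taxa, nm) {
    if (length(taxa) < 2)
      return(tibble(group = nm, n_taxa = length(taxa), monophyletic = TRUE,
                    note = "fewer than 2 taxa: vacuously monophyletic"))
    side <- sort(taxa)
    if (tips[1] %in% side) side <- sort(setdiff(tips, side))
    key <- paste(side, collapse = "|")
    # splits separating <=1 taxon exist on every unrooted tree
    hit <- key %in% parts || length(side) <= 1 ||
      length(side) >= length(tips) - 1
    tibble(group = nm, n_taxa = length(taxa), monophyletic = hit,
           note = NA_character_)
  })
}

#' Read a segment partition file
#'
#' TSV with columns label, start, end (1-based inclusive alignment columns).
#'
#' @param path Input file.
#' @return A tibble `label`, `start`, `end`.
#' @export
read_partition <- function(path) {
  readr::read_tsv(path, col_names = c("label", "start", "end"),
                  col_types = "cii", comment = "#", progress = FALSE)
}

#' Segment-partitioned congruence scan
#'
#' For each alignment segment, builds the T92 distance matrix and a
#' neighbor-joining tree, then computes pairwise Robinson-Foulds distances
#' between all segment trees. Adjacent segments with RF > 0 are flagged as
#' candidate gene-conversion breakpoints at their shared boundary. Segments
#' with fewer than `min_columns` gap/N-free columns, or containing a
#' saturated pair, are skipped with a warning.
#'
#' @param aln Alignment (sequence tibble or named character vector), at
#'   least 4 taxa for breakpoint flagging (3 accepted: single topology, no
#'   flags possible).
#' @param partition Tibble `label`, `start`, `end` of alignment-column
#'   intervals (1-based inclusive), in 5' to 3' order.
#' @param min_columns Minimum valid columns per segment (default 50).
#' @param theta_mode Passed to [t92_distance_matrix()].
#' @return An `incongruence_report`: list with `trees` (named list of
#'   `phylo`), `rf` (matrix of even integers), `flags` (tibble of adjacent
#'   incongruent segment pairs with the shared boundary column) and
#'   `skipped`.
#' @export
congruence_scan <- function(aln, partition, min_columns = 50L,
                            theta_mode = "pairwise") {
  if (is.data.frame(aln)) aln <- setNames(aln$seq, aln$id)
  if (length(aln) < 3) abort("congruence_scan: need at least 3 taxa")
  trees <- list(); skipped <- character(0)
  for (i in seq_len(nrow(partition))) {
    lab <- partition$label[i]
    seg <- substr(aln, partition$start[i], partition$end[i])
    nvalid <- tryCatch(
      min(utils::combn(length(seg), 2, function(p)
        t92_components(seg[[p[1]]], seg[[p[2]]])$n)),
      error = function(e) 0L)
    if (nvalid < min_columns) {
      warn(sprintf("segment '%s': fewer than %d valid columns; skipped",
                   lab, min_columns))
      skipped <- c(skipped, lab); next
    }
    dm <- tryCatch(t92_distance_matrix(seg, theta_mode = theta_mode),
                   error = function(e) {
                     warn(sprintf("segment '%s': %s; skipped", lab,
                                  conditionMessage(e)))
                     NULL
                   })
    if (is.null(dm)) { skipped <- c(skipped, lab); next }
    trees[[lab]] <- nj_tree(dm)
  }
  labs <- names(trees)
  rf <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
  if (length(labs) > 1) {
    for (i in seq_len(length(labs) - 1)) for (j in (i + 1):length(labs)) {
      rf[i, j] <- rf[j, i] <- rf_distance(trees[[i]], trees[[j]])
    }
  }
  flags <- tibble(segment_a = character(), segment_b = character(),
                  boundary_column = integer(), rf = integer())
  kept <- partition[partition$label %in% labs, , drop = FALSE]
  if (nrow(kept) > 1) {
    for (i in seq_len(nrow(kept) - 1)) {
      la <- kept$label[i]; lb <- kept$label[i + 1]
      r <- rf[la, lb]
      if (r > 0) {
        flags <- bind_rows(flags, tibble(
          segment_a = la, segment_b = lb,
          boundary_column = kept$end[i], rf = as.integer(r)))
      }
    }
  }
  structure(list(trees = trees, rf = rf, flags = flags, skipped = skipped,
                 partition = partition),
            class = "incongruence_report")
}

#' @export
print.incongruence_report <- function(x, ...) {
  cat(sprintf("<incongruence_report> %d segment trees, %d skipped, %d flagged breakpoints\n",
              length(x$trees), length(x$skipped), nrow(x$flags)))
  if (nrow(x$flags) > 0) print(x$flags)
  invisible(x)
}

#' @export
tidy.incongruence_report <- function(x, ...) {
  if (length(x$trees) < 2)
    return(tibble(segment_a = character(), segment_b = character(),
                  rf = integer()))
  idx <- which(upper.tri(x$rf), arr.ind = TRUE)
  tibble(segment_a = rownames(x$rf)[idx[, 1]],
         segment_b = colnames(x$rf)[idx[, 2]],
         rf = as.integer(x$rf[idx]))
}

#' @export
glance.incongruence_report <- function(x, ...) {
  tibble(n_segments = length(x$trees), n_skipped = length(x$skipped),
         n_flags = nrow(x$flags),
         max_rf = if (length(x$trees) > 1) max(x$rf) else NA_integer_)
}

#' Write segment trees as a Newick bundle
#'
#' @param report An `incongruence_report`.
#' @param path Output path; one labelled Newick line per segment tree.
#' @return `path`, invisibly.
#' @export
write_trees_newick <- function(report, path) {
  lines <- purrr::imap_chr(report$trees, function(tr, lab)
    paste0(ape::write.tree(tr)))
  writeLines(lines, path)
  invisible(path)
}
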