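# Sliding-window identity matrices and tandem duplication-block detection.
#
# The dot-matrix comparison is ungapped: cell (i, j) is the exact-match
# fraction of window i of sequence a against window j of sequence b, with N
# bases excluded from both numerator and denominator. Because windows start
# on a common step grid, every cell lies on a diagonal with offset a multiple
# of the step, and the whole matrix is computed from per-diagonal cumulative
# sums in O(n^2 / step) time.

#' Sliding-window identity matrix
#'
#' @param a First sequence (one-row sequence tibble or string).
#' @param b Second sequence; omit (`NULL`) for a self-comparison.
#' @param window Window size in bp (default 200).
#' @param step Step between window starts (default `window / 4`).
#' @param max_windows Cap on windows per axis; if exceeded, the step is
#'   enlarged (with a message) to stay at desk scale (default 2000).
#' @return An `identity_matrix`: list with `values` (windows-in-a by
#'   windows-in-b matrix of identity fractions, NA where no comparable
#'   bases), window start vectors `a_starts`/`b_starts`, `window`, `step`,
#'   ids and a `self` flag.
#' @export
identity_matrix <- function(a, b = NULL, window = 200L, step = NULL,
                            max_windows = 2000L) {
  xa <- as_seq1(a, "a")
  self <- is.null(b)
  xb <- if (self) xa else as_seq1(b, "b")
  na <- nchar(xa$seq); nb <- nchar(xb$seq)
  if (window > na || window > nb) abort("window larger than sequence")
  step <- as.integer(step %||% max(1L, window %/% 4L))
  need <- ceiling(max(na, nb) / step)
  if (need > max_windows) {
    step <- as.integer(ceiling(max(na, nb) / max_windows))
    inform(sprintf("identity_matrix: step enlarged to %d bp (max_windows)", step))
  }
  ia <- seq_to_int(xa$seq); ib <- seq_to_int(xb$seq)
  a_starts <- seq.int(1L, na - window + 1L, by = step)
  b_starts <- seq.int(1L, nb - window + 1L, by = step)
  nwa <- length(a_starts); nwb <- length(b_starts)
  vals <- matrix(NA_real_, nwa, nwb)
  for (dj in seq.int(-(nwa - 1L), nwb - 1L)) {   # diagonal: j - i = dj
    d <- dj * step                               # offset in bp
    t0 <- max(1L, 1L - d); t1 <- min(na, nb - d)
    if (t1 - t0 + 1L < window) next
    av <- ia[t0:t1]; bv <- ib[(t0 + d):(t1 + d)]
    ok <- av != 0L & bv != 0L
    eq <- (av == bv) & ok
    ceq <- c(0, cumsum(eq)); cok <- c(0, cumsum(ok))
    i_idx <- seq.int(max(1L, 1L - dj), min(nwa, nwb - dj))
    p <- a_starts[i_idx] - t0 + 1L               # window start within diagonal
    keep <- p + window - 1L <= (t1 - t0 + 1L)
    i_idx <- i_idx[keep]; p <- p[keep]
    den <- cok[p + window] - cok[p]
    num <- ceq[p + window] - ceq[p]
    vals[cbind(i_idx, i_idx + dj)] <- ifelse(den == 0, NA_real_, num / den)
  }
  structure(list(id_a = xa$id, id_b = xb$id, window = as.integer(window),
                 step = step, a_starts = a_starts, b_starts = b_starts,
                 values = vals, self = self, ia = ia, ib = ib),
            class = "identity_matrix")
}

#' @export
tidy.identity_matrix <- function(x, min_identity = 0, ...) {
  idx <- which(!is.na(x$values) & x$values >= min_identity, arr.ind = TRUE)
  tibble(a_start = x$a_starts[idx[, 1]], b_start = x$b_starts[idx[, 2]],
         identity = x$values[idx])
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat(sprintf("<identity_matrix> %s vs %s: %d x %d windows (%d bp, step %d)\n",
              x$id_a, x$id_b, length(x$a_starts), length(x$b_starts),
              x$window, x$step))
  invisible(x)
}

#' Dot-plot of an identity matrix
#'
#' @param object An `identity_matrix`.
#' @param min_identity Cells below this identity are not drawn (default 0.5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.identity_matrix <- function(object, min_identity = 0.5, ...) {
  df <- tidy(object, min_identity = min_identity)
  ggplot2::ggplot(df, ggplot2::aes(.data$a_start, .data$b_start,
                                   fill = .data$identity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "grey85", high = "black",
                                 limits = c(min_identity, 1)) +
    ggplot2::labs(x = object$id_a, y = object$id_b, fill = "identity") +
    ggplot2::theme_minimal()
}

#' Export high-identity cells as TSV
#'
#' @param m An `identity_matrix`.
#' @param path Output path.
#' @param min_identity Threshold for exported cells (default 0.7).
#' @return `path`, invisibly.
#' @export
write_identity_cells <- function(m, path, min_identity = 0.7) {
  readr::write_tsv(tidy(m, min_identity = min_identity), path, progress = FALSE)
  invisible(path)
}

#' Detect tandem duplication blocks from an identity matrix
#'
#' Candidate diagonal offsets are located by exact k-mer co-occurrence
#' voting (duplicated sequence at any realistic identity shares abundant
#' exact 31-mers at its true offset, whereas unrelated sequence shares
#' none), so blocks are found at 1-bp offset resolution rather than only on
#' the window grid. Along each supported diagonal, windowed identity is
#' computed at the matrix step; cells at or above `threshold` form runs,
#' runs on offsets within one step of each other are merged, and merged
#' runs spanning less than `min_block` bp are discarded. In self-comparison
#' mode the main diagonal is excluded and each mirror-image pair is
#' reported once (the copy with `a_start < b_start`).
#'
#' @param m An `identity_matrix`.
#' @param threshold Identity threshold (default 0.7).
#' @param min_block Minimum block span in bp (default 5000).
#' @param k Seed k-mer size for offset discovery (default 31).
#' @param min_seeds Minimum k-mer votes for a candidate offset (default 3).
#' @return A tibble of blocks: `a_start`, `a_end`, `b_start`, `b_end`,
#'   `offset` (b_start - a_start), `length`, `mean_identity`, `n_cells`;
#'   carries the matrix step in attribute `"step"` for [estimate_period()].
#' @export
detect_blocks <- function(m, threshold = 0.7, min_block = 5000L, k = 31L,
                          min_seeds = 3L) {
  out <- tibble(a_start = integer(), a_end = integer(), b_start = integer(),
                b_end = integer(), offset = integer(), length = integer(),
                mean_identity = double(), n_cells = integer())
  offs <- candidate_offsets(m, k, min_seeds)
  if (length(offs) == 0) return(structure(out, step = m$step))

  window <- m$window; step <- m$step
  na <- length(m$ia); nb <- length(m$ib)
  runs <- purrr::map_dfr(offs, function(d) {
    t0 <- max(1L, 1L - d); t1 <- min(na, nb - d)
    if (t1 - t0 + 1L < window) return(NULL)
    av <- m$ia[t0:t1]; bv <- m$ib[(t0 + d):(t1 + d)]
    ok <- av != 0L & bv != 0L
    eq <- (av == bv) & ok
    ceq <- c(0, cumsum(eq)); cok <- c(0, cumsum(ok))
    p <- seq.int(1L, t1 - t0 + 2L - window, by = step)
    den <- cok[p + window] - cok[p]
    val <- ifelse(den == 0, NA_real_, (ceq[p + window] - ceq[p]) / den)
    hit <- !is.na(val) & val >= threshold
    if (!any(hit)) return(NULL)
    r <- rle(hit); e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    purrr::map_dfr(which(r$values), function(ri) {
      rows <- s[ri]:e[ri]
      tibble(d = d, a0 = t0 + p[s[ri]] - 1L,
             a1 = t0 + p[e[ri]] - 1L + window - 1L,
             val = sum(val[rows]), n = length(rows))
    })
  })
  if (nrow(runs) == 0) return(structure(out, step = m$step))

  # merge runs whose offsets are within one step and whose a-extents touch
  nr <- nrow(runs)
  parent <- seq_len(nr)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (u in seq_len(nr)) {
    close_d <- which(abs(runs$d - runs$d[u]) <= step &
                       seq_len(nr) != u)
    for (v in close_d) {
      if (runs$a0[v] <= runs$a1[u] + step && runs$a1[v] >= runs$a0[u] - step)
        parent[find(u)] <- find(v)
    }
  }
  comp <- vapply(seq_len(nr), find, integer(1))
  blocks <- runs |>
    mutate(comp = comp) |>
    group_by(.data$comp) |>
    summarise(a_start = min(.data$a0), a_end = max(.data$a1),
              b_start = min(.data$a0 + .data$d),
              b_end = max(.data$a1 + .data$d),
              offset = as.integer(round(stats::weighted.mean(.data$d, .data$n))),
              mean_identity = sum(.data$val) / sum(.data$n),
              n_cells = sum(.data$n), .groups = "drop") |>
    mutate(length = .data$a_end - .data$a_start + 1L) |>
    filter(.data$length >= min_block) |>
    select("a_start", "a_end", "b_start", "b_end", "offset", "length",
           "mean_identity", "n_cells") |>
    arrange(.data$a_start, .data$b_start)
  structure(blocks, step = m$step)
}

# candidate diagonal offsets by exact k-mer co-occurrence voting
candidate_offsets <- function(m, k = 31L, min_seeds = 3L, max_offsets = 500L) {
  chr <- c("A", "C", "G", "T")
  sa <- paste0(c("N", chr)[m$ia + 1L], collapse = "")
  sb <- if (m$self) sa else paste0(c("N", chr)[m$ib + 1L], collapse = "")
  na <- nchar(sa); nb <- nchar(sb)
  if (na < k || nb < k) return(integer(0))
  ka <- substring(sa, seq_len(na - k + 1L), seq_len(na - k + 1L) + k - 1L)
  keep_a <- !grepl("N", ka, fixed = TRUE)
  da <- tibble(kmer = ka[keep_a], pa = which(keep_a))
  db <- if (m$self) dplyr::rename(da, pb = "pa") else {
    kb <- substring(sb, seq_len(nb - k + 1L), seq_len(nb - k + 1L) + k - 1L)
    keep_b <- !grepl("N", kb, fixed = TRUE)
    tibble(kmer = kb[keep_b], pb = which(keep_b))
  }
  pairs <- dplyr::inner_join(da, db, by = "kmer",
                             relationship = "many-to-many")
  d <- pairs$pb - pairs$pa
  if (m$self) d <- d[d > 0L] else d <- d
  if (length(d) == 0) return(integer(0))
  votes <- sort(table(d), decreasing = TRUE)
  cand <- as.integer(names(votes)[votes >= min_seeds])
  utils::head(cand, max_offsets)
}

#' Estimate the tandem repeat period from duplication blocks
#'
#' Block offsets are clustered single-linkage with the given tolerance; the
#' most populous cluster (ties: smallest offsets) gives the period as its
#' median, and copy number follows from the largest offset.
#'
#' @param blocks Block tibble from [detect_blocks()].
#' @param tolerance Offset clustering tolerance in bp; defaults to twice the
#'   matrix step recorded on `blocks`, else 500.
#' @return A list with `period` (bp), `n_copies` and `support` (the offsets
#'   contributing to the period cluster).
#' @export
estimate_period <- function(blocks, tolerance = NULL) {
  if (nrow(blocks) == 0) abort("no duplication detected")
  step <- attr(blocks, "step")
  tolerance <- tolerance %||% if (!is.null(step)) 2L * step else 500L
  offs <- sort(abs(blocks$offset))
  grp <- cumsum(c(1L, diff(offs) > tolerance))
  sizes <- table(grp)
  best <- as.integer(names(sizes)[sizes == max(sizes)])[1]  # ties: smallest
  period <- median(offs[grp == best])
  n_copies <- 1L + as.integer(round(max(offs) / period))
  list(period = period, n_copies = n_copies, support = offs[grp == best])
}

#' Start-to-start spacing of consecutive genes
#'
#' Distances between consecutive features (sorted by start, per sequence)
#' after filtering to the requested kinds. Start-to-start spacing equals the
#' duplication period when the genes sit in tandem blocks; end-to-start
#' distances are also reported for transparency.
#'
#' @param features A feature tibble.
#' @param kinds Feature kinds to keep (default `"gene"`).
#' @return A tibble: `seq_id`, `gene_a`, `gene_b`, `start_to_start`,
#'   `end_to_start` (bp). Empty when fewer than two features survive the
#'   filter.
#' @export
gene_spacing <- function(features, kinds = "gene") {
  f <- features |>
    filter(.data$kind %in% kinds) |>
    arrange(.data$seq_id, .data$start)
  f |>
    group_by(.data$seq_id) |>
    mutate(gene_a = .data$name, gene_b = lead(.data$name),
           start_to_start = lead(.data$start) - .data$start,
           end_to_start = lead(.data$start) - .data$end) |>
    ungroup() |>
    filter(!is.na(.data$gene_b)) |>
    select("seq_id", "gene_a", "gene_b", "start_to_start", "end_to_start")
}
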