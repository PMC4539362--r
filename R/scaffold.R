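# Reference-guided contig ordering with gap estimation.

# best placement of one contig on one reference (both orientations)
place_contig <- function(contig_seq, ref_seq, k, band) {
  best <- NULL
  for (ori in c("forward", "reverse")) {
    cs <- if (ori == "reverse") reverse_complement(contig_seq) else contig_seq
    chain <- chain_seeds(kmer_seeds(ref_seq, cs, k), k, band = band)
    if (nrow(chain) == 0) next
    first <- chain[1, ]; last <- chain[nrow(chain), ]
    nc <- nchar(cs); nr <- nchar(ref_seq)
    ref_start <- max(1L, first$pa - (first$pb - 1L))
    ref_end <- min(nr, last$pa + k - 1L + (nc - (last$pb + k - 1L)))
    anchor <- last$pb + k - first$pb          # contig span covered by seeds
    cand <- list(orientation = ori, ref_start = ref_start, ref_end = ref_end,
                 score = nrow(chain), anchor = anchor)
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  best
}

#' Order contigs against reference sequences
#'
#' Anchors each contig to its best-matching reference by shared k-mer seeds,
#' orients it, orders placed contigs by reference midpoint, and estimates the
#' gap between consecutive contigs as the distance between the projected
#' reference coordinates of their facing ends (floored at zero; projected
#' overlaps are annotated). Contigs without a seed anchor spanning at least
#' `min_anchor` bp are reported unplaced; when two placements conflict
#' (majority overlap on the reference) the lower-scoring contig is demoted
#' to unplaced with a warning.
#'
#' @param contigs Sequence tibble of contigs.
#' @param references Sequence tibble of one or more reference sequences.
#' @param min_anchor Minimum anchored contig span in bp (default 500).
#' @param k,band Seeding parameters as in [find_end_overlap()].
#' @return A `scaffold_layout`: list with `placements` (tibble sorted by
#'   reference and midpoint, with `gap_after` in bp and `overlaps_next`
#'   flags) and `unplaced` (tibble of contig ids and reasons).
#' @export
scaffold_contigs <- function(contigs, references, min_anchor = 500L,
                             k = 31L, band = 2000L) {
  rows <- purrr::map(seq_len(nrow(contigs)), function(i) {
    cands <- purrr::map(seq_len(nrow(references)), function(j) {
      p <- place_contig(contigs$seq[i], references$seq[j], k, band)
      if (is.null(p)) return(NULL)
      tibble(contig_id = contigs$id[i], ref_id = references$id[j],
             orientation = p$orientation, ref_start = p$ref_start,
             ref_end = p$ref_end, score = p$score, anchor = p$anchor)
    })
    cands <- bind_rows(purrr::compact(cands))
    if (nrow(cands) == 0) return(NULL)
    cands[which.max(cands$score), ]
  })
  placements <- bind_rows(purrr::compact(rows))
  placed_ids <- character(0)
  unplaced <- tibble(contig_id = character(), reason = character())

  no_hit <- setdiff(contigs$id, placements$contig_id)
  if (length(no_hit) > 0)
    unplaced <- bind_rows(unplaced, tibble(contig_id = no_hit,
                                           reason = "no anchor"))
  weak <- placements$anchor < min_anchor
  if (any(weak)) {
    unplaced <- bind_rows(unplaced, tibble(
      contig_id = placements$contig_id[weak], reason = "anchor below minimum"))
    placements <- placements[!weak, , drop = FALSE]
  }

  placements <- arrange(placements, .data$ref_id,
                        (.data$ref_start + .data$ref_end) / 2)
  # demote majority-overlapping placements (keep higher score)
  drop <- logical(nrow(placements))
  if (nrow(placements) > 1) {
    for (i in seq_len(nrow(placements) - 1)) {
      j <- i + 1
      while (j <= nrow(placements) && !drop[i] &&
             placements$ref_id[j] == placements$ref_id[i]) {
        if (drop[j]) { j <- j + 1; next }
        ov <- min(placements$ref_end[i], placements$ref_end[j]) -
          max(placements$ref_start[i], placements$ref_start[j]) + 1L
        shorter <- min(placements$ref_end[i] - placements$ref_start[i],
                       placements$ref_end[j] - placements$ref_start[j]) + 1L
        if (ov > shorter / 2) {
          loser <- if (placements$score[i] >= placements$score[j]) j else i
          warn(sprintf("conflicting placement: contig '%s' demoted to unplaced",
                       placements$contig_id[loser]))
          drop[loser] <- TRUE
        }
        j <- j + 1
      }
    }
  }
  if (any(drop)) {
    unplaced <- bind_rows(unplaced, tibble(
      contig_id = placements$contig_id[drop], reason = "conflicting placement"))
    placements <- placements[!drop, , drop = FALSE]
  }

  placements <- placements |>
    group_by(.data$ref_id) |>
    mutate(gap_after = pmax(0L, as.integer(lead(.data$ref_start) -
                                             .data$ref_end - 1L)),
           overlaps_next = (lead(.data$ref_start) - .data$ref_end - 1L) < 0L) |>
    ungroup()
  structure(list(placements = placements, unplaced = unplaced),
            class = "scaffold_layout")
}

#' @export
tidy.scaffold_layout <- function(x, ...) x$placements

#' @export
glance.scaffold_layout <- function(x, ...) {
  tibble(n_placed = nrow(x$placements), n_unplaced = nrow(x$unplaced),
         total_gap = sum(x$placements$gap_after, na.rm = TRUE),
         max_gap = if (nrow(x$placements) > 1)
           max(x$placements$gap_after, na.rm = TRUE) else NA_integer_)
}

#' @export
print.scaffold_layout <- function(x, ...) {
  cat(sprintf("<scaffold_layout> %d placed, %d unplaced\n",
              nrow(x$placements), nrow(x$unplaced)))
  print(x$placements)
  invisible(x)
}

#' Write a scaffold layout as an AGP-like TSV
#'
#' Alternating contig (`W`) and gap (`N`) rows in reference order.
#'
#' @param layout A `scaffold_layout` from [scaffold_contigs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scaffold_agp <- function(layout, path) {
  p <- layout$placements
  lines <- character(0); part <- 0L
  for (i in seq_len(nrow(p))) {
    part <- part + 1L
    lines <- c(lines, sprintf("%s\t%d\t%d\t%d\tW\t%s\t1\t%d\t%s",
                              p$ref_id[i], p$ref_start[i], p$ref_end[i], part,
                              p$contig_id[i], p$ref_end[i] - p$ref_start[i] + 1L,
                              if (p$orientation[i] == "forward") "+" else "-"))
    if (!is.na(p$gap_after[i]) && p$gap_after[i] > 0) {
      part <- part + 1L
      lines <- c(lines, sprintf("%s\t%d\t%d\t%d\tN\t%d\tscaffold\tyes\talign_genus",
                                p$ref_id[i], p$ref_end[i] + 1L,
                                p$ref_end[i] + p$gap_after[i], part,
                                p$gap_after[i]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
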