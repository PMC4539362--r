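# Clone end-overlap detection and variant calling.
#
# Overlaps between near-identical clones are found by exact k-mer seeding on
# the dominant alignment diagonal, chaining colinear seeds, and closing the
# inter-anchor gaps with global alignment (Biostrings). Variant calls are read
# off the stitched alignment columns; a low-identity stretch whose reverse
# complement aligns back at high identity is re-labelled as one inversion.

ALN_MATCH <- 1; ALN_MISMATCH <- -2; ALN_GAP_OPEN <- 4; ALN_GAP_EXT <- 1

sub_matrix <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = ALN_MATCH,
                                           mismatch = ALN_MISMATCH,
                                           baseOnly = FALSE)
}

# exact shared k-mers: tibble(pa, pb), first occurrence in `a` per b position
kmer_seeds <- function(sa, sb, k = 31L) {
  na <- nchar(sa); nb <- nchar(sb)
  if (na < k || nb < k) return(tibble(pa = integer(), pb = integer()))
  ka <- substring(sa, seq_len(na - k + 1L), seq_len(na - k + 1L) + k - 1L)
  kb <- substring(sb, seq_len(nb - k + 1L), seq_len(nb - k + 1L) + k - 1L)
  hit <- match(kb, ka)
  keep <- !is.na(hit) & !grepl("N", kb, fixed = TRUE)
  tibble(pa = hit[keep], pb = which(keep))
}

# dominant-diagonal seed chain: strictly colinear, non-overlapping anchors
chain_seeds <- function(seeds, k, band = 2000L, bin = 250L) {
  if (nrow(seeds) == 0) return(seeds)
  d <- seeds$pa - seeds$pb
  centre <- as.integer(names(sort(table(round(d / bin)), decreasing = TRUE))[1]) * bin
  s <- seeds[abs(d - centre) <= band, , drop = FALSE]
  s <- s[order(s$pa, s$pb), , drop = FALSE]
  keep <- logical(nrow(s)); last_a <- -Inf; last_b <- -Inf
  for (i in seq_len(nrow(s))) {
    if (s$pa[i] >= last_a + k && s$pb[i] >= last_b + k) {
      keep[i] <- TRUE; last_a <- s$pa[i]; last_b <- s$pb[i]
    }
  }
  s[keep, , drop = FALSE]
}

# align two (possibly empty) segments globally; returns list(a=, b=) aligned
align_piece <- function(pa, pb) {
  if (nchar(pa) == 0 && nchar(pb) == 0) return(list(a = "", b = ""))
  if (nchar(pa) == 0) return(list(a = strrep("-", nchar(pb)), b = pb))
  if (nchar(pb) == 0) return(list(a = pa, b = strrep("-", nchar(pa))))
  # a large length difference means the piece holds a long indel: raise the
  # opening cost so the gap stays contiguous instead of being scattered
  open_cost <- if (abs(nchar(pa) - nchar(pb)) >= 50) 100 else ALN_GAP_OPEN
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(pa), Biostrings::DNAString(pb),
    type = "global", substitutionMatrix = sub_matrix(),
    gapOpening = open_cost, gapExtension = ALN_GAP_EXT)
  list(a = as.character(Biostrings::alignedPattern(al)),
       b = as.character(Biostrings::alignedSubject(al)))
}

# stitch anchors + aligned gap pieces over spans [a0,a1] x [b0,b1]
stitch_alignment <- function(sa, sb, chain, k, a0, a1, b0, b1) {
  apieces <- character(); bpieces <- character()
  cur_a <- a0; cur_b <- b0
  for (i in seq_len(nrow(chain))) {
    pa <- chain$pa[i]; pb <- chain$pb[i]
    gp <- align_piece(substr(sa, cur_a, pa - 1L), substr(sb, cur_b, pb - 1L))
    anchor <- substr(sa, pa, pa + k - 1L)
    apieces <- c(apieces, gp$a, anchor)
    bpieces <- c(bpieces, gp$b, anchor)
    cur_a <- pa + k; cur_b <- pb + k
  }
  gp <- align_piece(substr(sa, cur_a, a1), substr(sb, cur_b, b1))
  list(a = paste0(c(apieces, gp$a), collapse = ""),
       b = paste0(c(bpieces, gp$b), collapse = ""))
}

aln_stats <- function(a_aln, b_aln) {
  ac <- strsplit(a_aln, "")[[1]]; bc <- strsplit(b_aln, "")[[1]]
  valid <- ac != "N" & bc != "N"           # N columns excluded from identity
  match <- ac == bc & ac != "-" & valid
  mism <- ac != bc & ac != "-" & bc != "-" & valid
  gap_runs_a <- rle(ac == "-"); gap_runs_b <- rle(bc == "-")
  n_open <- sum(gap_runs_a$values) + sum(gap_runs_b$values)
  n_gap <- sum(ac == "-") + sum(bc == "-")
  score <- ALN_MATCH * sum(match) + ALN_MISMATCH * sum(mism) -
    ALN_GAP_OPEN * n_open - ALN_GAP_EXT * n_gap
  list(identity = if (sum(valid) == 0) NA_real_ else sum(match) / sum(valid),
       score = score, columns = length(ac))
}

find_end_overlap_oriented <- function(sa, sb, k, min_overlap, band) {
  na <- nchar(sa); nb <- nchar(sb)
  chain <- chain_seeds(kmer_seeds(sa, sb, k), k, band = band)
  if (nrow(chain) == 0) return(NULL)
  first <- chain[1, ]; last <- chain[nrow(chain), ]
  a0 <- max(1L, first$pa - (first$pb - 1L))
  b0 <- max(1L, first$pb - (first$pa - 1L))
  a1 <- min(na, last$pa + k - 1L + (nb - (last$pb + k - 1L)))
  b1 <- min(nb, last$pb + k - 1L + (na - (last$pa + k - 1L)))
  if (min(a1 - a0, b1 - b0) + 1L < min_overlap) return(NULL)
  aln <- stitch_alignment(sa, sb, chain, k, a0, a1, b0, b1)
  st <- aln_stats(aln$a, aln$b)
  list(a_start = a0, a_end = a1, b_start = b0, b_end = b1,
       identity = st$identity, score = st$score,
       aligned_length = st$columns, a_aln = aln$a, b_aln = aln$b)
}

#' Find the maximal end-overlap between two sequences
#'
#' Detects a suffix/prefix (tiling-path) overlap between two clone or
#' haplotype sequences, trying both orientations of the second sequence.
#' Candidate overlaps are seeded by shared k-mers on the dominant alignment
#' diagonal, chained, and the chained span is aligned end to end; the
#' highest-scoring overlap with identity at least `min_identity` is returned.
#'
#' @param seqs A sequence tibble holding the two records (or more; then
#'   `id_a`/`id_b` select the pair).
#' @param id_a,id_b Record ids; default the first two rows.
#' @param min_overlap Minimum overlap span in bp (default 1000).
#' @param min_identity Minimum alignment identity (default 0.9).
#' @param k Seed k-mer size (default 31).
#' @param band Diagonal band half-width in bp, sized to the indel budget
#'   (default 2000).
#' @return An `overlap_alignment` object, or `NULL` when no qualifying
#'   overlap exists. Fields include the overlap intervals on each sequence
#'   (1-based inclusive, `b` in original coordinates), `orientation`
#'   (`"forward"`/`"reverse"`), `identity`, `aligned_length` and the stitched
#'   alignment used by [call_overlap_variants()].
#' @seealso [call_overlap_variants()], [glance.overlap_alignment()]
#' @export
find_end_overlap <- function(seqs, id_a = NULL, id_b = NULL,
                             min_overlap = 1000L, min_identity = 0.9,
                             k = 31L, band = 2000L) {
  if (is.null(id_a)) id_a <- seqs$id[1]
  if (is.null(id_b)) id_b <- seqs$id[2]
  sa <- seqs$seq[match(id_a, seqs$id)]
  sb <- seqs$seq[match(id_b, seqs$id)]
  if (is.na(sa) || is.na(sb)) abort("id_a/id_b not found in `seqs`")
  if (min(nchar(sa), nchar(sb)) < min_overlap) return(NULL)
  nb <- nchar(sb)
  cands <- list()
  fwd <- find_end_overlap_oriented(sa, sb, k, min_overlap, band)
  if (!is.null(fwd)) { fwd$orientation <- "forward"; cands <- c(cands, list(fwd)) }
  rev <- find_end_overlap_oriented(sa, reverse_complement(sb), k, min_overlap, band)
  if (!is.null(rev)) {
    rev$orientation <- "reverse"
    rc_start <- rev$b_start; rc_end <- rev$b_end
    rev$b_start <- nb - rc_end + 1L; rev$b_end <- nb - rc_start + 1L
    cands <- c(cands, list(rev))
  }
  cands <- purrr::keep(cands, ~ !is.na(.x$identity) && .x$identity >= min_identity)
  if (length(cands) == 0) return(NULL)
  # best score; ties: longer alignment, then forward orientation
  ord <- order(purrr::map_dbl(cands, "score"),
               purrr::map_int(cands, "aligned_length"),
               purrr::map_chr(cands, "orientation") == "forward",
               decreasing = TRUE)
  best <- cands[[ord[1]]]
  structure(c(list(id_a = id_a, id_b = id_b), best,
              list(len_a = nchar(sa), len_b = nb)),
            class = "overlap_alignment")
}

#' All-pairs end-overlaps within a clone set
#'
#' @inheritParams find_end_overlap
#' @return A tibble with one row per qualifying pair (id_a, id_b, overlap
#'   coordinates, orientation, identity, aligned_length) and the
#'   `overlap_alignment` objects in a list-column `overlap`.
#' @export
find_all_overlaps <- function(seqs, min_overlap = 1000L, min_identity = 0.9,
                              k = 31L, band = 2000L) {
  pairs <- utils::combn(seqs$id, 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(p) {
    ov <- find_end_overlap(seqs, p[1], p[2], min_overlap = min_overlap,
                           min_identity = min_identity, k = k, band = band)
    if (is.null(ov)) return(NULL)
    mutate(glance(ov), overlap = list(ov))
  })
  bind_rows(purrr::compact(rows))
}

#' @export
glance.overlap_alignment <- function(x, ...) {
  tibble(id_a = x$id_a, id_b = x$id_b, a_start = x$a_start, a_end = x$a_end,
         b_start = x$b_start, b_end = x$b_end, orientation = x$orientation,
         identity = x$identity, aligned_length = x$aligned_length,
         score = x$score)
}

#' @export
print.overlap_alignment <- function(x, ...) {
  cat(sprintf(
    "<overlap_alignment> %s[%d-%d] ~ %s[%d-%d] (%s)\n  identity %.4f over %d aligned columns\n",
    x$id_a, x$a_start, x$a_end, x$id_b, x$b_start, x$b_end, x$orientation,
    x$identity, x$aligned_length))
  invisible(x)
}

empty_variants <- function() {
  tibble(kind = character(), pos_a = integer(), pos_b = integer(),
         length = integer(), allele_a = character(), allele_b = character())
}

#' Call SNPs, indels and inversions within an end-overlap
#'
#' Reads variants off the stitched overlap alignment: mismatch columns become
#' SNPs, gap runs become insertions (sequence present only in `b`) or
#' deletions (present only in `a`). A low-identity stretch whose reverse
#' complement re-aligns locally at >= 90% identity and spans at least
#' `min_inversion` bp is re-labelled as a single inversion; SNP/indel calls
#' inside it are dropped so its internal mismatches are not double-counted.
#'
#' @param ov An `overlap_alignment` from [find_end_overlap()].
#' @param min_inversion Minimum inversion length in bp (default 100).
#' @return A tibble of variant calls sorted by `pos_a`: columns `kind`
#'   (SNP/insertion/deletion/inversion), `pos_a`, `pos_b` (1-based, original
#'   coordinates), `length`, `allele_a`, `allele_b`.
#' @export
call_overlap_variants <- function(ov, min_inversion = 100L) {
  stopifnot(inherits(ov, "overlap_alignment"))
  ac <- strsplit(ov$a_aln, "")[[1]]; bc <- strsplit(ov$b_aln, "")[[1]]
  agap <- ac == "-"; bgap <- bc == "-"
  # original coordinates per column (gap columns anchored to preceding base)
  pos_a <- ov$a_start - 1L + pmax(cumsum(!agap), 1L)
  pb_off <- cumsum(!bgap)
  if (ov$orientation == "forward") pos_b <- ov$b_start - 1L + pmax(pb_off, 1L)
  else pos_b <- ov$b_end + 1L - pmax(pb_off, 1L)

  snp <- which(!agap & !bgap & ac != bc & ac != "N" & bc != "N")
  vars <- tibble(kind = rep("SNP", length(snp)), pos_a = pos_a[snp],
                 pos_b = pos_b[snp], length = 1L,
                 allele_a = ac[snp], allele_b = bc[snp])

  state <- ifelse(agap, "ins", ifelse(bgap, "del", "m"))
  r <- rle(state)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in which(r$values != "m")) {
    cols <- starts[i]:ends[i]
    if (r$values[i] == "ins") {
      vars <- bind_rows(vars, tibble(
        kind = "insertion", pos_a = pos_a[starts[i]], pos_b = pos_b[starts[i]],
        length = length(cols), allele_a = "",
        allele_b = paste0(bc[cols], collapse = "")))
    } else {
      vars <- bind_rows(vars, tibble(
        kind = "deletion", pos_a = pos_a[starts[i]], pos_b = pos_b[starts[i]],
        length = length(cols),
        allele_a = paste0(ac[cols], collapse = ""), allele_b = ""))
    }
  }

  inv <- detect_inversions(ov, ac, bc, agap, bgap, pos_a, pos_b, min_inversion)
  if (nrow(inv) > 0) {
    for (j in seq_len(nrow(inv))) {
      # drop calls whose a- or b-extent touches the re-labelled segment
      # (alignment structure inside an inversion is meaningless)
      ia <- c(inv$pos_a[j] - 1L, inv$pos_a[j] + inv$length[j])
      ib <- range(inv$pos_b[j], inv$pos_b[j] + inv$length[j] - 1L) + c(-1L, 1L)
      va1 <- vars$pos_a + ifelse(vars$kind == "deletion", vars$length - 1L, 0L)
      vb1 <- vars$pos_b + ifelse(vars$kind == "insertion", vars$length - 1L,
                                 ifelse(vars$kind == "SNP", 0L, 0L))
      hit_a <- vars$pos_a <= ia[2] & va1 >= ia[1]
      hit_b <- pmin(vars$pos_b, vb1) <= ib[2] & pmax(vars$pos_b, vb1) >= ib[1]
      vars <- vars[!(hit_a | hit_b), , drop = FALSE]
    }
    vars <- bind_rows(vars, inv)
  }
  arrange(vars, .data$pos_a, .data$kind)
}

# find low-identity alignment stretches that are reverse-complement matches
detect_inversions <- function(ov, ac, bc, agap, bgap, pos_a, pos_b,
                              min_inversion, window = 50L, low = 0.75,
                              min_rc_identity = 0.9) {
  out <- empty_variants()
  n <- length(ac)
  if (n < window || min_inversion <= 0) return(out)
  m <- as.numeric(ac == bc & !agap)
  roll <- cumsum(m); roll <- (roll[window:n] - c(0, roll)[1:(n - window + 1)]) / window
  lowpos <- which(roll < low)                        # window start columns
  if (length(lowpos) == 0) return(out)
  covered <- logical(n)
  for (p in lowpos) covered[p:(p + window - 1L)] <- TRUE
  r <- rle(covered); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    if (r$lengths[i] < max(window, min_inversion %/% 2)) next
    c0 <- max(1L, starts[i] - window); c1 <- min(n, ends[i] + window)
    a_seg <- paste0(ac[c0:c1][!agap[c0:c1]], collapse = "")
    b_seg <- paste0(bc[c0:c1][!bgap[c0:c1]], collapse = "")
    if (min(nchar(a_seg), nchar(b_seg)) < min_inversion) next
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a_seg),
      Biostrings::reverseComplement(Biostrings::DNAString(b_seg)),
      type = "local", substitutionMatrix = sub_matrix(),
      gapOpening = ALN_GAP_OPEN, gapExtension = ALN_GAP_EXT)
    pa_rng <- c(Biostrings::start(Biostrings::pattern(al)),
                Biostrings::end(Biostrings::pattern(al)))
    inv_len <- pa_rng[2] - pa_rng[1] + 1L
    if (inv_len < min_inversion) next
    ident <- Biostrings::nmatch(al) / Biostrings::nchar(al)
    if (is.na(ident) || ident < min_rc_identity) next
    seg_a_start <- pos_a[which(!agap & seq_len(n) >= c0)[1]]
    inv_a_start <- seg_a_start + pa_rng[1] - 1L
    rc_rng <- c(Biostrings::start(Biostrings::subject(al)),
                Biostrings::end(Biostrings::subject(al)))
    b_seg_start <- min(pos_b[c0:c1][!bgap[c0:c1]])
    inv_b_start <- b_seg_start + (nchar(b_seg) - rc_rng[2])
    out <- bind_rows(out, tibble(
      kind = "inversion", pos_a = inv_a_start, pos_b = as.integer(inv_b_start),
      length = inv_len,
      allele_a = substr(a_seg, pa_rng[1], pa_rng[2]), allele_b = ""))
  }
  out
}

#' Write overlap variants as a minimal VCF
#'
#' SNPs and indels are written with explicit REF/ALT; inversions as symbolic
#' `<INV>` records with `END` and `SVLEN` INFO keys. Positions are 1-based on
#' the first partner of the overlap.
#'
#' @param variants A variant tibble from [call_overlap_variants()].
#' @param chrom CHROM value (typically the id of sequence a).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, chrom, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of SV\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
           "##ALT=<ID=INV,Description=\"Inversion\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- purrr::pmap_chr(variants, function(kind, pos_a, pos_b, length,
                                             allele_a, allele_b, ...) {
    if (kind == "SNP") {
      sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", chrom, pos_a, allele_a, allele_b)
    } else if (kind == "inversion") {
      sprintf("%s\t%d\t.\tN\t<INV>\t.\t.\tEND=%d;SVLEN=%d",
              chrom, pos_a, pos_a + length - 1L, length)
    } else if (kind == "deletion") {
      sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tSVLEN=-%d",
              chrom, pos_a, paste0("N", allele_a), "N", length)
    } else {
      sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tSVLEN=%d",
              chrom, pos_a, "N", paste0("N", allele_b), length)
    }
  })
  writeLines(c(hdr, rows), path)
  invisible(path)
}
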