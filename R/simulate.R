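# Synthetic haplotypes, clone sets and alignments with truth records.
#
# The generator emulates the structure the analysis assumes: a haplotype of
# tandemly duplicated blocks, one class I-like gene per block (3 exons / 2
# introns and a 3' region), start-to-start gene spacing equal to the block
# period, conserved flanks, optional inversion and GC-biased conversion
# tracts, plus clone fragmentation with gaps. Default scale is 1:10 relative
# to the locus it emulates (8-kb blocks for ~80-kb blocks) so end-to-end
# runs take seconds. One integer seed governs all randomness.

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random nucleotide sequence
#'
#' @param n Length in bp.
#' @param gc Target GC fraction (default 0.5).
#' @param seed Optional seed for a self-contained draw.
#' @return A nucleotide string.
#' @export
random_seq <- function(n, gc = 0.5, seed = NULL) {
  draw <- function() paste0(sample(BASES, n, replace = TRUE,
                                   prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                            (1 - gc) / 2)), collapse = "")
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# per-site substitutions: prob p; transition with prob kappa/(kappa+2)
mutate_sites <- function(seq, p, kappa = 2) {
  if (p <= 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(v)) < p & v != "N")
  if (length(hit) == 0) return(seq)
  is_ts <- runif(length(hit)) < kappa / (kappa + 2)
  v[hit[is_ts]] <- TRANSITION[v[hit[is_ts]]]
  tv <- hit[!is_ts]
  if (length(tv) > 0)
    v[tv] <- purrr::map_chr(v[tv], ~ sample(TRANSVERSIONS[[.x]], 1))
  paste0(v, collapse = "")
}

#' Simulation configuration
#'
#' Defaults describe the emulated locus at 1:10 scale: 8-kb duplication
#' blocks (for ~80 kb), gene spacing drawn from 6.3-6.8 kb (for 63-68 kb),
#' one 3-exon gene per block. The drawn gene spacing is the tandem period:
#' each copy is truncated (or padded with random spacer) to its drawn
#' spacing, so start-to-start gene distances equal the period by
#' construction.
#'
#' @param seed Integer seed; the same seed reproduces outputs byte for byte.
#' @param block_length Ancestral block length in bp (default 8000).
#' @param n_blocks Number of tandem copies (default 4).
#' @param block_divergence Per-site substitution probability applied to each
#'   copy (default 0.05).
#' @param flank_length Conserved flank length either side in bp (default 5000).
#' @param flank_divergence Per-site substitution probability for flanks when
#'   two haplotypes are generated (default 0.002).
#' @param indel_rate Per-site indel probability outside exons (default 0).
#' @param indel_length_p Geometric length parameter for indels (default 0.2).
#' @param gene_spacing_range Range the per-junction gene spacing (= block
#'   period) is drawn from, in bp (default c(6300, 6800)).
#' @param kappa Transition/transversion weight (default 2).
#' @param gc Base composition of ancestral sequence (default 0.5).
#' @param inversion Optional `list(position =, length =)` applied to the
#'   final haplotype.
#' @param conversion Optional `list(donor =, recipient =, tract_length =,
#'   gc_bias = 0.7, offset =)`: copies a tract (at `offset` bp into the
#'   block, default the gene start) from one copy into another, choosing the
#'   GC-bearing allele at differing sites with probability `gc_bias`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, block_length = 8000L, n_blocks = 4L,
                       block_divergence = 0.05, flank_length = 5000L,
                       flank_divergence = 0.002, indel_rate = 0,
                       indel_length_p = 0.2,
                       gene_spacing_range = c(6300L, 6800L), kappa = 2,
                       gc = 0.5, inversion = NULL, conversion = NULL) {
  stopifnot(block_length >= 2000, n_blocks >= 1,
            block_divergence >= 0, block_divergence <= 1,
            all(gene_spacing_range >= 1600))
  structure(list(seed = as.integer(seed), block_length = as.integer(block_length),
                 n_blocks = as.integer(n_blocks),
                 block_divergence = block_divergence,
                 flank_length = as.integer(flank_length),
                 flank_divergence = flank_divergence, indel_rate = indel_rate,
                 indel_length_p = indel_length_p,
                 gene_spacing_range = as.integer(gene_spacing_range),
                 kappa = kappa, gc = gc, inversion = inversion,
                 conversion = conversion),
            class = "sim_config")
}

# gene model relative to the block start: 3 exons / 2 introns; CDS = exons
# (total 618 bp, divisible by 3), then a 3' region to the block end
gene_model_rel <- function(block_length) {
  gene_start <- 501L
  lens <- c(exon1 = 72L, intron1 = 130L, exon2 = 270L, intron2 = 230L,
            exon3 = 276L)
  ends <- gene_start - 1L + cumsum(lens)
  starts <- ends - lens + 1L
  tibble(part = names(lens), start = starts, end = ends)
}

copy_features <- function(copy_idx, copy_start, model, seq_id) {
  parts <- mutate(model, start = .data$start + copy_start - 1L,
                  end = .data$end + copy_start - 1L)
  ex <- filter(parts, startsWith(.data$part, "exon"))
  intr <- filter(parts, startsWith(.data$part, "intron"))
  g <- sprintf("gene%d", copy_idx)
  bind_rows(
    feature_tbl(seq_id, "gene", min(parts$start), max(parts$end),
                name = g),
    feature_tbl(seq_id, "exon", ex$start, ex$end,
                name = paste0(g, "_", ex$part)),
    feature_tbl(seq_id, "intron", intr$start, intr$end,
                name = paste0(g, "_", intr$part)),
    feature_tbl(seq_id, "CDS", ex$start, ex$end, name = g, phase = 0L))
}

# build one haplotype from shared ancestral material (RNG state advances)
build_haplotype <- function(id, anc_block, flank_l, flank_r, cfg,
                            n_blocks = cfg$n_blocks,
                            flank_divergence = 0) {
  model <- gene_model_rel(cfg$block_length)
  gene_end_rel <- max(model$end)
  spacing_vals <- seq.int(cfg$gene_spacing_range[1], cfg$gene_spacing_range[2])
  periods <- if (n_blocks > 1)
    spacing_vals[sample.int(length(spacing_vals), n_blocks - 1, replace = TRUE)]
  else integer(0)
  fl <- mutate_sites(flank_l, flank_divergence, cfg$kappa)
  fr <- mutate_sites(flank_r, flank_divergence, cfg$kappa)
  pieces <- fl
  pos <- nchar(fl) + 1L
  blocks <- tibble(copy = integer(), start = integer(), end = integer(),
                   period = integer())
  feats <- NULL
  copies <- character(n_blocks)
  copy_starts <- integer(n_blocks)
  for (i in seq_len(n_blocks)) {
    s <- mutate_sites(anc_block, cfg$block_divergence, cfg$kappa)
    if (cfg$indel_rate > 0) s <- apply_indels(s, gene_end_rel, cfg)
    target <- if (i < n_blocks) periods[i] else nchar(s)
    if (nchar(s) >= target) s <- substr(s, 1L, target)
    else s <- paste0(s, random_seq(target - nchar(s), cfg$gc))
    copies[i] <- s
    copy_starts[i] <- pos
    blocks <- bind_rows(blocks, tibble(copy = i, start = pos,
                                       end = pos + nchar(s) - 1L,
                                       period = target))
    feats <- bind_rows(feats, copy_features(i, pos, model, id))
    pieces <- c(pieces, s)
    pos <- pos + nchar(s)
  }
  conv_truth <- NULL
  if (!is.null(cfg$conversion)) {
    cv <- cfg$conversion
    offset <- cv$offset %||% 501L
    gc_bias <- cv$gc_bias %||% 0.7
    if (offset + cv$tract_length - 1L > min(nchar(copies)))
      abort("conversion tract exceeds block")
    don <- strsplit(copies[[cv$donor]], "")[[1]][offset:(offset + cv$tract_length - 1L)]
    rec_seq <- strsplit(copies[[cv$recipient]], "")[[1]]
    rec <- rec_seq[offset:(offset + cv$tract_length - 1L)]
    new <- converted_tract(don, rec, gc_bias)
    rec_seq[offset:(offset + cv$tract_length - 1L)] <- new
    copies[[cv$recipient]] <- paste0(rec_seq, collapse = "")
    pieces <- c(fl, copies)
    conv_truth <- tibble(
      donor = cv$donor, recipient = cv$recipient,
      start = copy_starts[cv$recipient] + offset - 1L,
      end = copy_starts[cv$recipient] + offset + cv$tract_length - 2L,
      gc_bias = gc_bias)
  }
  hap <- paste0(paste0(pieces, collapse = ""), fr)
  inv_truth <- NULL
  if (!is.null(cfg$inversion)) {
    iv <- cfg$inversion
    v <- strsplit(hap, "")[[1]]
    rng <- iv$position:(iv$position + iv$length - 1L)
    v[rng] <- rev(COMPLEMENT[v[rng]])
    hap <- paste0(v, collapse = "")
    inv_truth <- tibble(start = iv$position, end = max(rng),
                        length = iv$length)
  }
  list(seq = seq_tbl(id, hap),
       truth = list(blocks = blocks, features = feats,
                    conversion = conv_truth, inversion = inv_truth,
                    periods = periods))
}

# donor tract copied in; GC-bearing allele kept with probability gc_bias
converted_tract <- function(donor, recipient, gc_bias) {
  out <- donor
  diff <- which(donor != recipient)
  for (i in diff) {
    d_gc <- donor[i] %in% c("G", "C"); r_gc <- recipient[i] %in% c("G", "C")
    if (d_gc == r_gc) next                   # no GC asymmetry: keep donor
    take_gc <- runif(1) < gc_bias
    out[i] <- if (take_gc) (if (d_gc) donor[i] else recipient[i])
              else (if (d_gc) recipient[i] else donor[i])
  }
  out
}

apply_indels <- function(s, gene_end_rel, cfg) {
  n <- nchar(s)
  if (n <= gene_end_rel + 10L) return(s)
  region <- (gene_end_rel + 1L):n
  k <- rbinom(1, length(region), cfg$indel_rate)
  if (k == 0) return(s)
  pos <- sort(sample(region, k), decreasing = TRUE)
  for (p in pos) {
    len <- 1L + stats::rgeom(1, cfg$indel_length_p)
    if (runif(1) < 0.5) {                    # deletion
      s <- paste0(substr(s, 1, p - 1L), substr(s, min(p + len, nchar(s) + 1L),
                                               nchar(s)))
    } else {                                 # insertion
      s <- paste0(substr(s, 1, p), random_seq(len, cfg$gc),
                  substr(s, p + 1L, nchar(s)))
    }
  }
  s
}

#' Simulate a tandemly duplicated haplotype
#'
#' Builds an ancestral block carrying a three-exon gene model, tandem-copies
#' it with per-junction spacing drawn from `gene_spacing_range` (the drawn
#' spacing is the realised period), mutates each copy at `block_divergence`
#' under a kappa-weighted substitution scheme, adds flanks, and applies the
#' optional inversion/conversion. With all rates zero and one block the
#' output is the ancestral block plus flanks exactly.
#'
#' @param cfg A [sim_config()].
#' @param id Sequence id for the haplotype (default "hap1").
#' @return A list: `seq` (one-row sequence tibble) and `truth` (block
#'   layout, feature tibble for every copy, conversion/inversion intervals,
#'   drawn periods).
#' @export
simulate_haplotype <- function(cfg, id = "hap1") {
  with_seed(cfg$seed, {
    anc <- random_seq(cfg$block_length, cfg$gc)
    fl <- random_seq(cfg$flank_length, cfg$gc)
    fr <- random_seq(cfg$flank_length, cfg$gc)
    build_haplotype(id, anc, fl, fr, cfg)
  })
}

#' Simulate a pair of haplotypes sharing ancestry
#'
#' Both haplotypes derive from the same ancestral block and flanks;
#' divergence is concentrated in the block region (`block_divergence` per
#' copy per haplotype) while flanks diverge at `flank_divergence` only —
#' the conserved-flank / variable-core structure of the emulated locus.
#' Copy number may differ between the haplotypes.
#'
#' @param cfg A [sim_config()].
#' @param n_blocks_b Copy number of the second haplotype (default as first).
#' @param ids Sequence ids.
#' @return A list with elements `a` and `b`, each as [simulate_haplotype()].
#' @export
simulate_haplotype_pair <- function(cfg, n_blocks_b = cfg$n_blocks,
                                    ids = c("hapA", "hapB")) {
  with_seed(cfg$seed, {
    anc <- random_seq(cfg$block_length, cfg$gc)
    fl <- random_seq(cfg$flank_length, cfg$gc)
    fr <- random_seq(cfg$flank_length, cfg$gc)
    a <- build_haplotype(ids[1], anc, fl, fr, cfg,
                         flank_divergence = cfg$flank_divergence)
    b <- build_haplotype(ids[2], anc, fl, fr, cfg, n_blocks = n_blocks_b,
                         flank_divergence = cfg$flank_divergence)
    list(a = a, b = b)
  })
}

# place `k` intervals of lengths `lens` in [lo, hi] with pairwise margin
place_intervals <- function(lo, hi, lens, margin, occupied = NULL) {
  out <- list()
  for (len in lens) {
    placed <- FALSE
    for (try in 1:100) {
      if (hi - len + 1L < lo) break
      p <- sample.int(hi - len + 1L - lo + 1L, 1L) + lo - 1L
      iv <- c(p - margin, p + len - 1L + margin)
      clash <- any(purrr::map_lgl(c(out, occupied), function(o)
        iv[1] <= o[2] && iv[2] >= o[1]))
      if (!clash) { out <- c(out, list(c(p, p + len - 1L))); placed <- TRUE; break }
    }
    if (!placed) abort("could not place implants without collision after 100 draws")
  }
  out
}

#' Simulate overlapping clones from a haplotype
#'
#' Cuts clones out of a haplotype as the given intervals and implants the
#' requested variants into the *second* clone of each named pair, only
#' inside the pair's overlap region; every implant is recorded in the truth
#' table. Implants keep a minimum spacing (default 50 bp) so recovered
#' counts can be compared exactly to truth; inversion placements whose
#' flanking bases would extend the reverse-complement match are re-drawn.
#'
#' @param hap A one-row sequence tibble (e.g. from [simulate_haplotype()]).
#' @param layout Tibble `id`, `start`, `end` of clone intervals on `hap`.
#' @param variants Optional list of implant specs, each
#'   `list(pair = c(id_a, id_b), snps = 0, indels = integer(),
#'   inversion = NULL)`; positive indels insert into clone b, negative
#'   delete from it; `inversion` is a length in bp.
#' @param min_spacing Minimum distance between implants in bp (default 50).
#' @param margin Keep implants this far from the overlap ends (default 100).
#' @param seed Seed for implant placement (default 1).
#' @return A list: `clones` (sequence tibble) and `truth` (tibble of
#'   implanted variants with haplotype and clone-a coordinates).
#' @export
simulate_clones <- function(hap, layout, variants = NULL, min_spacing = 50L,
                            margin = 100L, seed = 1L) {
  s <- as_seq1(hap)$seq
  clones <- setNames(substring(s, layout$start, layout$end), layout$id)
  truth <- tibble(pair_a = character(), pair_b = character(),
                  kind = character(), pos_hap = integer(), pos_a = integer(),
                  length = integer())
  with_seed(seed, for (spec in (variants %||% list())) {
    ida <- spec$pair[1]; idb <- spec$pair[2]
    ia <- match(ida, layout$id); ib <- match(idb, layout$id)
    lo <- max(layout$start[ia], layout$start[ib]) + margin
    hi <- min(layout$end[ia], layout$end[ib]) - margin
    if (hi <= lo) abort("designated clones do not overlap")
    snps <- spec$snps %||% 0L
    indels <- spec$indels %||% integer(0)
    inv_len <- spec$inversion

    occupied <- list()
    implants <- list()
    if (!is.null(inv_len)) {
      repeat {
        iv <- place_intervals(lo, hi, inv_len, min_spacing, occupied)[[1]]
        # reject placements whose flanks would extend the reverse-complement
        # match (score-positive extension needs a hit at +-1 or +-2)
        l1 <- substr(s, iv[1] - 1L, iv[1] - 1L)
        l2 <- substr(s, iv[1] - 2L, iv[1] - 2L)
        r1 <- substr(s, iv[2] + 1L, iv[2] + 1L)
        r2 <- substr(s, iv[2] + 2L, iv[2] + 2L)
        if (COMPLEMENT[[r1]] != l1 && COMPLEMENT[[r2]] != l2) break
      }
      occupied <- c(occupied, list(iv))
      implants <- c(implants, list(list(kind = "inversion", pos = iv[1],
                                        len = inv_len)))
    }
    for (ind in indels) {
      iv <- place_intervals(lo, hi, abs(ind), min_spacing, occupied)[[1]]
      occupied <- c(occupied, list(iv))
      implants <- c(implants, list(list(
        kind = if (ind > 0) "insertion" else "deletion",
        pos = iv[1], len = abs(ind))))
    }
    if (snps > 0) {
      ivs <- place_intervals(lo, hi, rep(1L, snps), min_spacing, occupied)
      occupied <- c(occupied, ivs)
      implants <- c(implants, purrr::map(ivs, ~ list(kind = "SNP",
                                                     pos = .x[1], len = 1L)))
    }
    # apply right-to-left on clone b so earlier positions stay valid
    implants <- implants[order(purrr::map_int(implants, "pos"),
                               decreasing = TRUE)]
    cb <- clones[[idb]]
    off_b <- layout$start[ib] - 1L
    for (im in implants) {
      p <- im$pos - off_b
      if (im$kind == "SNP") {
        ref <- substr(cb, p, p)
        alt <- sample(setdiff(BASES, ref), 1)
        substr(cb, p, p) <- alt
      } else if (im$kind == "deletion") {
        cb <- paste0(substr(cb, 1, p - 1L), substr(cb, p + im$len, nchar(cb)))
      } else if (im$kind == "insertion") {
        cb <- paste0(substr(cb, 1, p - 1L), random_seq(im$len),
                     substr(cb, p, nchar(cb)))
      } else {
        seg <- substr(cb, p, p + im$len - 1L)
        substr(cb, p, p + im$len - 1L) <- reverse_complement(seg)
      }
      truth <- bind_rows(truth, tibble(
        pair_a = ida, pair_b = idb, kind = im$kind, pos_hap = im$pos,
        pos_a = im$pos - layout$start[ia] + 1L, length = im$len))
    }
    clones[[idb]] <- cb
  })
  list(clones = seq_tbl(layout$id, unname(clones[layout$id])),
       truth = arrange(truth, .data$pos_hap))
}

#' Fragment a sequence into ordered contigs with gaps
#'
#' Deletes `gaps` spacers from the sequence and returns the remaining pieces
#' as contigs (optionally shuffled and reverse-complemented), emulating an
#' unordered draft assembly; the truth records order, orientation and gap
#' sizes for scaffold-recovery checks.
#'
#' @param seq One-row sequence tibble or string.
#' @param gaps Integer vector of spacer lengths (bp) deleted between
#'   consecutive contigs; `length(gaps) + 1` contigs result.
#' @param min_piece Minimum contig length in bp (default 2000).
#' @param shuffle Shuffle contig order and randomly flip orientations
#'   (default TRUE).
#' @param seed Seed (default 1).
#' @return A list: `contigs` (sequence tibble, ids `ctg01`...) and `truth`
#'   (tibble `contig_id`, `ref_start`, `ref_end`, `orientation`,
#'   `gap_after`).
#' @export
fragment_sequence <- function(seq, gaps, min_piece = 2000L, shuffle = TRUE,
                              seed = 1L) {
  x <- as_seq1(seq)
  n <- nchar(x$seq)
  k <- length(gaps) + 1L
  total_piece <- n - sum(gaps)
  if (total_piece < k * min_piece) abort("sequence too short for requested pieces")
  with_seed(seed, {
    extra <- total_piece - k * min_piece
    cuts <- sort(sample.int(extra + k - 1L, k - 1L))
    lens <- diff(c(0L, cuts, extra + k)) - 1L + min_piece
    starts <- cumsum(c(1L, head(lens, -1L) + gaps))
    ends <- starts + lens - 1L
    ids <- sprintf("ctg%02d", seq_len(k))
    ori <- rep("forward", k)
    seqs <- substring(x$seq, starts, ends)
    if (shuffle) {
      flip <- which(runif(k) < 0.5)
      if (length(flip) > 0) {
        seqs[flip] <- purrr::map_chr(seqs[flip], reverse_complement)
        ori[flip] <- "reverse"
      }
    }
    truth <- tibble(contig_id = ids, ref_start = starts, ref_end = ends,
                    orientation = ori,
                    gap_after = c(as.integer(gaps), NA_integer_))
    ord <- if (shuffle) sample.int(k) else seq_len(k)
    list(contigs = seq_tbl(ids[ord], seqs[ord]), truth = truth)
  })
}

#' Simulate an alignment evolved down a tree
#'
#' Columns evolve independently under a process compatible with the T92
#' model: the root is drawn from the stationary composition (GC = `theta`),
#' each branch substitutes sites with probability `1 - exp(-b)` for branch
#' length `b`, choosing a transition with probability `kappa / (kappa + 2)`
#' and otherwise a transversion partner weighted by stationary frequency.
#' An optional gene-conversion event then copies a column interval from the
#' donor tip into the recipient tip, keeping the GC-bearing allele at
#' differing sites with probability `gc_bias`.
#'
#' @param tree An `ape::phylo` with branch lengths (expected substitutions
#'   per site), or a Newick string.
#' @param length Alignment length in columns (default 1200).
#' @param theta Stationary GC content (default 0.5).
#' @param kappa Transition/transversion weight (default 2).
#' @param conversion Optional `list(donor =, recipient =, start =, end =,
#'   gc_bias = 0.7)` with tip labels and column interval.
#' @param seed Seed (default 1).
#' @return A list: `alignment` (sequence tibble over the tip labels) and
#'   `truth` (the conversion interval, or NULL).
#' @export
simulate_alignment <- function(tree, length = 1200L, theta = 0.5, kappa = 2,
                               conversion = NULL, seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!is.null(conversion) &&
      (conversion$start < 1 || conversion$end > length))
    abort("conversion interval outside alignment length")
  ntip <- length(tree$tip.label)
  stat <- c((1 - theta) / 2, theta / 2, theta / 2, (1 - theta) / 2)
  with_seed(seed, {
    root <- ntip + 1L
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[root]] <- sample(BASES, length, replace = TRUE, prob = stat)
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      par <- ord$edge[e, 1]; child <- ord$edge[e, 2]
      bl <- ord$edge.length[e]
      v <- seqs[[par]]
      p <- 1 - exp(-max(bl, 0))
      hit <- which(runif(length) < p)
      if (length(hit) > 0) {
        # reversible kernel: target weights kappa*pi for the transition
        # partner, pi for each transversion partner; stationary GC = theta
        for (b in BASES) {
          idx <- hit[v[hit] == b]
          if (length(idx) == 0) next
          targets <- c(TRANSITION[[b]], TRANSVERSIONS[[b]])
          w <- c(kappa * stat[match(targets[1], BASES)],
                 stat[match(targets[2:3], BASES)])
          v[idx] <- sample(targets, length(idx), replace = TRUE, prob = w)
        }
      }
      seqs[[child]] <- v
    }
    tips <- purrr::map_chr(seq_len(ntip), ~ paste0(seqs[[.x]], collapse = ""))
    names(tips) <- tree$tip.label
    truth <- NULL
    if (!is.null(conversion)) {
      cv <- conversion
      don <- strsplit(tips[[cv$donor]], "")[[1]][cv$start:cv$end]
      rec_full <- strsplit(tips[[cv$recipient]], "")[[1]]
      rec <- rec_full[cv$start:cv$end]
      rec_full[cv$start:cv$end] <- converted_tract(don, rec,
                                                   cv$gc_bias %||% 0.7)
      tips[[cv$recipient]] <- paste0(rec_full, collapse = "")
      truth <- tibble(donor = cv$donor, recipient = cv$recipient,
                      start = cv$start, end = cv$end)
    }
    list(alignment = seq_tbl(names(tips), unname(tips)),
         truth = truth)
  })
}

#' Write a truth record as JSON
#'
#' @param truth A truth list/tibble from a simulator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    abort("write_truth_json requires the jsonlite package")
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
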