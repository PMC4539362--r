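# Orchestration of the two workflows: clone-set validation and haplotype
# comparison. Both return structured report objects whose every number
# traces to a stage result stored in the object.

#' Validate a clone set as a single haplotype
#'
#' Runs all-pairs end-overlap detection, calls variants within each overlap,
#' digests every clone in silico, optionally matches digests against
#' experimental size lists, and optionally scaffolds extra contigs. The
#' verdict is "single haplotype consistent" when every detected overlap has
#' identity at or above `consistency_identity` once `terminal_window` bp at
#' each overlap end are set aside (clone ends are where miscalled bases
#' accumulate).
#'
#' @param clones Sequence tibble of clone inserts (>= 2 rows).
#' @param expected_profiles Optional named list of `fragment_profile`
#'   objects (names = clone ids) from gel sizing.
#' @param enzyme Restriction enzyme for digestion (default HindIII).
#' @param min_overlap,min_identity Overlap detection parameters.
#' @param consistency_identity Core-identity threshold for the verdict
#'   (default 0.999).
#' @param terminal_window Bp excluded at each overlap end when computing
#'   core identity (default 200).
#' @param contigs,references Optional inputs forwarded to
#'   [scaffold_contigs()].
#' @return A `clone_validation_report`: overlaps, per-pair variant tibble,
#'   digest profiles, profile matches, scaffold layout and `verdict`
#'   ("single_haplotype_consistent", "discordant" or "no_overlaps").
#' @export
run_clone_validation <- function(clones, expected_profiles = NULL,
                                 enzyme = "HindIII", min_overlap = 1000L,
                                 min_identity = 0.9,
                                 consistency_identity = 0.999,
                                 terminal_window = 200L,
                                 contigs = NULL, references = NULL) {
  if (nrow(clones) < 2) abort("clone validation needs at least 2 sequences")
  overlaps <- find_all_overlaps(clones, min_overlap = min_overlap,
                                min_identity = min_identity)
  variants <- empty_variants() |> mutate(id_a = character(), id_b = character())
  core_identity <- double(0)
  if (nrow(overlaps) > 0) {
    vlist <- purrr::map(overlaps$overlap, call_overlap_variants)
    variants <- purrr::map2_dfr(vlist, seq_len(nrow(overlaps)), function(v, i)
      mutate(v, id_a = overlaps$id_a[i], id_b = overlaps$id_b[i]))
    core_identity <- purrr::map_dbl(overlaps$overlap, overlap_core_identity,
                                    terminal_window = terminal_window)
    overlaps$core_identity <- core_identity
  }
  profiles <- purrr::map(seq_len(nrow(clones)), function(i)
    digest(clones[i, ], enzyme = enzyme))
  names(profiles) <- clones$id
  matches <- NULL
  if (!is.null(expected_profiles)) {
    matches <- purrr::imap(expected_profiles, function(exp_p, id) {
      if (!id %in% names(profiles)) return(NULL)
      match_profiles(profiles[[id]], exp_p)
    })
  }
  scaffold <- NULL
  if (!is.null(contigs)) {
    scaffold <- scaffold_contigs(contigs, references %||% clones)
  }
  verdict <- if (nrow(overlaps) == 0) "no_overlaps"
  else if (all(core_identity >= consistency_identity))
    "single_haplotype_consistent"
  else "discordant"
  if (verdict == "no_overlaps") warn("no qualifying overlaps between clones")
  structure(list(overlaps = select(overlaps, -dplyr::any_of("overlap")),
                 overlap_objects = if (nrow(overlaps)) overlaps$overlap else list(),
                 variants = variants, profiles = profiles, matches = matches,
                 scaffold = scaffold, verdict = verdict,
                 parameters = list(enzyme = enzyme, min_overlap = min_overlap,
                                   min_identity = min_identity,
                                   consistency_identity = consistency_identity,
                                   terminal_window = terminal_window)),
            class = "clone_validation_report")
}

# identity over alignment columns excluding `terminal_window` bp at each end
overlap_core_identity <- function(ov, terminal_window = 200L) {
  ac <- strsplit(ov$a_aln, "")[[1]]; bc <- strsplit(ov$b_aln, "")[[1]]
  n <- length(ac)
  keep <- seq_len(n) > terminal_window & seq_len(n) <= n - terminal_window
  if (!any(keep)) keep <- rep(TRUE, n)
  valid <- keep & ac != "N" & bc != "N"
  if (sum(valid) == 0) return(NA_real_)
  sum(ac[valid] == bc[valid] & ac[valid] != "-") / sum(valid)
}

#' @export
print.clone_validation_report <- function(x, ...) {
  cat(sprintf("<clone_validation_report> verdict: %s\n", x$verdict))
  cat(sprintf("  %d overlap pair(s), %d variant call(s), %d digest profile(s)\n",
              nrow(x$overlaps), nrow(x$variants), length(x$profiles)))
  invisible(x)
}

#' @export
glance.clone_validation_report <- function(x, ...) {
  tibble(verdict = x$verdict, n_pairs = nrow(x$overlaps),
         n_variants = nrow(x$variants),
         min_core_identity = if (nrow(x$overlaps))
           min(x$overlaps$core_identity) else NA_real_)
}

#' Compare two haplotypes structurally
#'
#' Builds the self- and cross-identity matrices, detects duplication blocks
#' and estimates the tandem period for each haplotype, computes gene
#' spacings from the annotation, scans each annotated gene for GC anomalies
#' (associating them with exon boundaries), and, when an alignment and
#' segment partition are supplied, runs the segment-tree congruence scan.
#'
#' @param hap_a,hap_b One-row sequence tibbles.
#' @param features Optional feature tibble for both haplotypes; without it
#'   the gene-spacing and GC-boundary stages are skipped with a warning.
#' @param alignment,partition Optional inputs for [congruence_scan()].
#' @param window Identity-matrix window in bp (default 200).
#' @param block_threshold,min_block Block detection parameters.
#' @param gc_window GC scan window in bp (default 100).
#' @param z_cutoff GC anomaly cut-off in standard deviations (default 2.5).
#' @return A `haplotype_comparison_report` with elements `self_a`, `self_b`,
#'   `cross` (identity matrices), `blocks_a`, `blocks_b`, `period_a`,
#'   `period_b`, `spacing`, `gc_anomalies`, `congruence`.
#' @export
run_haplotype_comparison <- function(hap_a, hap_b, features = NULL,
                                     alignment = NULL, partition = NULL,
                                     window = 200L, block_threshold = 0.7,
                                     min_block = 5000L, gc_window = 100L,
                                     z_cutoff = 2.5) {
  self_a <- identity_matrix(hap_a, window = window)
  self_b <- identity_matrix(hap_b, window = window)
  cross <- identity_matrix(hap_a, hap_b, window = window)
  blocks_a <- detect_blocks(self_a, threshold = block_threshold,
                            min_block = min_block)
  blocks_b <- detect_blocks(self_b, threshold = block_threshold,
                            min_block = min_block)
  period_a <- if (nrow(blocks_a)) estimate_period(blocks_a) else NULL
  period_b <- if (nrow(blocks_b)) estimate_period(blocks_b) else NULL
  spacing <- NULL; gc_anoms <- NULL
  if (is.null(features)) {
    warn("no annotation supplied: gene spacing and GC-boundary stages skipped")
  } else {
    spacing <- gene_spacing(features)
    ids <- c(as_seq1(hap_a)$id, as_seq1(hap_b)$id)
    genes <- filter(features, .data$kind == "gene", .data$seq_id %in% ids)
    gc_anoms <- purrr::pmap_dfr(
      genes[, c("seq_id", "start", "end", "name")],
      function(seq_id, start, end, name) {
        hap <- if (seq_id == ids[1]) hap_a else hap_b
        pad <- 200L
        lo <- max(1L, start - pad)
        hi <- min(nchar(as_seq1(hap)$seq), end + pad)
        scan <- gc_profile(hap, lo, hi, window = gc_window)
        an <- suppressWarnings(flag_anomalies(scan, z_cutoff = z_cutoff))
        if (nrow(an) == 0) return(NULL)
        an <- associate_boundaries(
          an, filter(features, .data$seq_id == seq_id,
                     .data$name == name | startsWith(.data$name, name)))
        mutate(an, seq_id = seq_id, gene = name, .before = 1)
      })
  }
  congruence <- NULL
  if (!is.null(alignment) && !is.null(partition)) {
    congruence <- congruence_scan(alignment, partition)
  }
  structure(list(self_a = self_a, self_b = self_b, cross = cross,
                 blocks_a = blocks_a, blocks_b = blocks_b,
                 period_a = period_a, period_b = period_b,
                 spacing = spacing, gc_anomalies = gc_anoms,
                 congruence = congruence,
                 parameters = list(window = window,
                                   block_threshold = block_threshold,
                                   min_block = min_block,
                                   gc_window = gc_window,
                                   z_cutoff = z_cutoff)),
            class = "haplotype_comparison_report")
}

#' @export
print.haplotype_comparison_report <- function(x, ...) {
  cat("<haplotype_comparison_report>\n")
  cat(sprintf("  blocks: %d (a), %d (b)", nrow(x$blocks_a), nrow(x$blocks_b)))
  if (!is.null(x$period_a))
    cat(sprintf("; period a: %.0f bp x %d copies", x$period_a$period,
                x$period_a$n_copies))
  if (!is.null(x$period_b))
    cat(sprintf("; period b: %.0f bp x %d copies", x$period_b$period,
                x$period_b$n_copies))
  cat("\n")
  if (!is.null(x$spacing) && nrow(x$spacing) > 0)
    cat(sprintf("  gene spacings (start-to-start): %s bp\n",
                paste(x$spacing$start_to_start, collapse = ", ")))
  if (!is.null(x$gc_anomalies))
    cat(sprintf("  GC anomalies: %d\n", nrow(x$gc_anomalies)))
  if (!is.null(x$congruence))
    cat(sprintf("  congruence: %d segment trees, %d flagged breakpoint(s)\n",
                length(x$congruence$trees), nrow(x$congruence$flags)))
  invisible(x)
}

#' Write report tables to a directory
#'
#' Emits one TSV per stage result (plus Newick trees for the congruence
#' stage) so every reported number is traceable to a file.
#'
#' @param report A `clone_validation_report` or
#'   `haplotype_comparison_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(df, name) {
    if (!is.null(df) && is.data.frame(df) && nrow(df) > 0)
      readr::write_tsv(df, file.path(dir, paste0(name, ".tsv")),
                       progress = FALSE)
  }
  if (inherits(report, "clone_validation_report")) {
    emit(report$overlaps, "overlaps")
    emit(report$variants, "variants")
    emit(purrr::map_dfr(report$profiles, tidy), "digest_profiles")
    if (!is.null(report$matches))
      emit(purrr::imap_dfr(report$matches, function(m, id)
        mutate(glance(m), clone = id, .before = 1)), "profile_matches")
    if (!is.null(report$scaffold)) emit(tidy(report$scaffold), "scaffold")
    writeLines(report$verdict, file.path(dir, "verdict.txt"))
  } else if (inherits(report, "haplotype_comparison_report")) {
    emit(report$blocks_a, "blocks_a")
    emit(report$blocks_b, "blocks_b")
    emit(report$spacing, "gene_spacing")
    emit(report$gc_anomalies, "gc_anomalies")
    if (!is.null(report$congruence)) {
      emit(tidy(report$congruence), "segment_rf")
      emit(report$congruence$flags, "breakpoint_flags")
      write_trees_newick(report$congruence,
                         file.path(dir, "segment_trees.nwk"))
    }
  } else abort("unknown report type")
  invisible(dir)
}
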