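# Coding-effect classification of overlap variants against a CDS gene model.

#' Classify coding effects of overlap variants
#'
#' Each SNP falling inside a CDS is translated in both alleles with the
#' standard genetic code: an unchanged amino acid is synonymous, a changed one
#' nonsynonymous. Indels inside a CDS whose length is not a multiple of three
#' are frameshifts. Variants inside the gene span but outside its CDS are
#' intronic; all others intergenic.
#'
#' @param variants Variant tibble from [call_overlap_variants()]; positions
#'   (`pos_a`) are interpreted on `seq`.
#' @param features Feature tibble containing the `CDS` rows of one or more
#'   gene models (grouped by `name`); minus-strand models are supported.
#' @param seq The sequence carrying `allele_a` at `pos_a` (one-row sequence
#'   tibble or string).
#' @return The variant tibble with columns `gene`, `region`
#'   (CDS/intron/intergenic) and `effect`
#'   (synonymous/nonsynonymous/frameshift/not_applicable) appended.
#' @export
classify_coding_effects <- function(variants, features, seq) {
  s <- as_seq1(seq)$seq
  cds <- filter(features, .data$kind == "CDS")
  if (nrow(cds) == 0) abort("`features` contains no CDS rows")
  models <- split(cds, cds$name)
  for (g in names(models)) {
    if (sum(models[[g]]$end - models[[g]]$start + 1L) %% 3L != 0L)
      abort(sprintf("CDS model of gene '%s' is not a multiple of 3", g))
  }
  gene_span <- purrr::map(models, ~ c(min(.x$start), max(.x$end)))

  classify_one <- function(kind, pos_a, length, allele_a, allele_b, ...) {
    for (g in names(models)) {
      m <- arrange(models[[g]], .data$start)
      in_cds <- any(pos_a >= m$start & pos_a <= m$end)
      if (in_cds) {
        if (kind == "SNP") {
          eff <- snp_effect(s, m, pos_a, allele_b)
          return(tibble(gene = g, region = "CDS", effect = eff))
        }
        if (kind %in% c("insertion", "deletion")) {
          eff <- if (length %% 3L != 0L) "frameshift" else "not_applicable"
          return(tibble(gene = g, region = "CDS", effect = eff))
        }
        return(tibble(gene = g, region = "CDS", effect = "not_applicable"))
      }
      sp <- gene_span[[g]]
      if (pos_a >= sp[1] && pos_a <= sp[2])
        return(tibble(gene = g, region = "intron", effect = "not_applicable"))
    }
    tibble(gene = NA_character_, region = "intergenic",
           effect = "not_applicable")
  }
  if (nrow(variants) == 0) {
    return(mutate(variants, gene = character(), region = character(),
                  effect = character()))
  }
  dplyr::bind_cols(variants, purrr::pmap_dfr(variants, classify_one))
}

# translate the codon containing genomic position `pos` with ref and alt base
snp_effect <- function(s, cds_sorted, pos, alt) {
  strand <- cds_sorted$strand[1]
  segs <- purrr::map2(cds_sorted$start, cds_sorted$end, ~ .x:.y)
  genome_pos <- unlist(segs)                 # 5'->3' on + strand
  if (strand == "-") genome_pos <- rev(genome_pos)
  cds_idx <- match(pos, genome_pos)
  bases <- strsplit(s, "")[[1]][genome_pos]
  if (strand == "-") bases <- chartr("ACGTN", "TGCAN", bases)
  alt_base <- if (strand == "-") chartr("ACGTN", "TGCAN", alt) else alt
  codon_i <- (cds_idx - 1L) %/% 3L
  cpos <- codon_i * 3L + 1:3
  ref_codon <- paste0(bases[cpos], collapse = "")
  alt_bases <- bases; alt_bases[cds_idx] <- alt_base
  alt_codon <- paste0(alt_bases[cpos], collapse = "")
  aa <- function(codon) {
    if (grepl("N", codon)) return(NA_character_)
    Biostrings::GENETIC_CODE[[codon]]
  }
  ref_aa <- aa(ref_codon); alt_aa <- aa(alt_codon)
  if (is.na(ref_aa) || is.na(alt_aa)) return("not_applicable")
  if (ref_aa == alt_aa) "synonymous" else "nonsynonymous"
}
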