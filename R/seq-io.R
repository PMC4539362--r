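# Sequence records are plain tibbles: one row per sequence with columns
# id, description, seq, length. All coordinates in the package are 1-based
# inclusive (GenBank convention); exporters to BED/bedGraph convert.

VALID_BASES <- c("A", "C", "G", "T", "N")

#' Build a sequence tibble
#'
#' Constructs the tabular sequence container used throughout the package:
#' one row per record with columns `id`, `description`, `seq` and `length`.
#' Sequences are uppercased and `U` is mapped to `T` on ingestion.
#'
#' @param id Character vector of record identifiers (non-empty).
#' @param seq Character vector of nucleotide sequences over A, C, G, T, N.
#' @param description Optional character vector of free-text descriptions.
#' @return A tibble with columns `id`, `description`, `seq`, `length`.
#' @examples
#' seq_tbl("x", "acgt")
#' @export
seq_tbl <- function(id, seq, description = "") {
  if (any(!nzchar(id))) abort("sequence ids must be non-empty")
  id <- unname(id); seq <- unname(seq); description <- unname(description)
  seq <- toupper(seq)
  seq <- gsub("U", "T", seq, fixed = TRUE)
  bad <- stringr::str_locate(seq, sprintf("[^%s]", paste(VALID_BASES, collapse = "")))[, 1]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    abort(sprintf("invalid character in record '%s' at position %d", id[i], bad[i]))
  }
  tibble(
    id = as.character(id),
    description = rep_len(as.character(description), length(id)),
    seq = seq,
    length = nchar(seq)
  )
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A sequence tibble (see [seq_tbl()]); one row per header, in file
#'   order. Lowercase (soft-masked) residues are uppercased; `U` becomes `T`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) abort(sprintf("no records in '%s'", path))
  nm <- names(x)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  seq_tbl(id = id, seq = as.character(x), description = desc)
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs A sequence tibble.
#' @param path Output path. Lines are wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs$seq)
  names(x) <- ifelse(nzchar(seqs$description),
                     paste(seqs$id, seqs$description), seqs$id)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' An involution over the alphabet A, C, G, T, N (`N` maps to `N`).
#'
#' @param seq A single nucleotide string.
#' @return The reverse-complemented string.
#' @examples
#' reverse_complement("AAGCTT") # HindIII site is palindromic
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) abort("reverse_complement: alphabet is {A,C,G,T,N}")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

FEATURE_KINDS <- c("gene", "pseudogene", "exon", "intron", "CDS", "region")

#' Build a feature tibble
#'
#' Features (genes, exons, CDS parts, ...) are tibbles with 1-based inclusive
#' coordinates on the forward strand, regardless of feature strand.
#'
#' @param seq_id Sequence the feature lies on.
#' @param kind One of gene, pseudogene, exon, intron, CDS, region.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param name Feature name.
#' @param phase CDS phase (0-2) or `NA`.
#' @return A tibble with columns seq_id, kind, start, end, strand, name, phase.
#' @export
feature_tbl <- function(seq_id, kind, start, end, strand = "+", name = "",
                        phase = NA_integer_) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(end < start)) abort("feature end < start")
  unknown <- !kind %in% FEATURE_KINDS
  if (any(unknown)) {
    warn(sprintf("unknown feature kind(s) %s; recorded as 'region'",
                 paste(unique(kind[unknown]), collapse = ", ")))
    kind[unknown] <- "region"
  }
  tibble(seq_id = as.character(seq_id), kind = kind, start = start, end = end,
         strand = strand, name = as.character(name),
         phase = as.integer(phase))
}

#' Read gene annotations
#'
#' Reads features from GFF3 or from a 5-column tab table
#' (name, kind, start, end, strand). Both dialects use 1-based inclusive
#' coordinates, which is also the package's internal convention.
#'
#' @param path Input file.
#' @param dialect `"gff3"` or `"table"`.
#' @param seq_id Sequence id to assign for the `table` dialect (which carries
#'   none); ignored for GFF3.
#' @return A feature tibble (see [feature_tbl()]).
#' @export
read_features <- function(path, dialect = c("gff3", "table"),
                          seq_id = NA_character_) {
  dialect <- match.arg(dialect)
  if (dialect == "gff3") {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    f <- readr::read_tsv(I(lines), col_names = c(
      "seqid", "source", "type", "start", "end", "score", "strand", "phase",
      "attributes"), col_types = "ccciicccc", progress = FALSE)
    name <- stringr::str_match(f$attributes, "(?:Name|ID)=([^;]+)")[, 2]
    feature_tbl(seq_id = f$seqid, kind = f$type, start = f$start, end = f$end,
                strand = ifelse(f$strand %in% c("+", "-"), f$strand, "+"),
                name = ifelse(is.na(name), "", name),
                phase = suppressWarnings(as.integer(f$phase)))
  } else {
    f <- readr::read_tsv(path, col_names = c("name", "kind", "start", "end",
                                             "strand"),
                         col_types = "cciic", comment = "#", progress = FALSE)
    feature_tbl(seq_id = seq_id, kind = f$kind, start = f$start, end = f$end,
                strand = f$strand, name = f$name)
  }
}

#' Write features as GFF3
#'
#' @param features A feature tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  lines <- c("##gff-version 3", sprintf(
    "%s\thaploblock\t%s\t%d\t%d\t.\t%s\t%s\t%s",
    features$seq_id, features$kind, features$start, features$end,
    features$strand,
    ifelse(is.na(features$phase), ".", as.character(features$phase)),
    ifelse(nzchar(features$name), paste0("Name=", features$name), ".")))
  writeLines(lines, path)
  invisible(path)
}

# integer encoding used by windowed scans: A=1 C=2 G=3 T=4, N/other = 0
seq_to_int <- function(seq) {
  code <- integer(256)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  code[utf8ToInt(seq)]
}

# accept a one-row sequence tibble, a named/plain string; return list(id, seq)
as_seq1 <- function(x, default_id = "seq") {
  if (is.data.frame(x)) {
    if (nrow(x) != 1) abort("expected a single sequence record")
    list(id = x$id, seq = x$seq)
  } else if (is.character(x) && length(x) == 1) {
    list(id = if (!is.null(names(x))) names(x) else default_id,
         seq = toupper(x))
  } else {
    abort("expected a one-row sequence tibble or a single string")
  }
}
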