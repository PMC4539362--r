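# In-silico restriction digestion and gel-profile matching.

#' Built-in restriction enzymes
#'
#' A small table of common enzymes; `cut_offset` is the cut position within
#' the recognition site on the top strand (HindIII cuts A^AGCTT).
#'
#' @return A tibble with columns `name`, `site`, `cut_offset`.
#' @export
restriction_enzymes <- function() {
  tibble(name = c("HindIII", "EcoRI", "BamHI"),
         site = c("AAGCTT", "GAATTC", "GGATCC"),
         cut_offset = c(1L, 1L, 1L))
}

resolve_enzyme <- function(enzyme) {
  if (is.data.frame(enzyme)) return(enzyme[1, ])
  e <- filter(restriction_enzymes(), .data$name == enzyme)
  if (nrow(e) == 0) abort(sprintf("unknown enzyme '%s'", enzyme))
  e
}

#' In-silico restriction digest
#'
#' Finds every occurrence of the recognition site (occurrences containing `N`
#' are conservatively not called; overlapping occurrences are all counted)
#' and derives fragment lengths from the sorted cut positions. A linear
#' molecule with k sites yields k+1 fragments; a circular one yields
#' max(k, 1), with sites spanning the origin detected.
#'
#' Cuts are accounted on the top strand at `cut_offset`. For palindromic
#' sites this makes circular digests exactly invariant under reverse
#' complement; on linear molecules the internal fragments are invariant but
#' the two terminal fragments shift by the overhang length (site length
#' minus twice the offset), reflecting the staggered duplex cut.
#'
#' @param seq One-row sequence tibble or string.
#' @param enzyme Enzyme name from [restriction_enzymes()] or a one-row tibble
#'   with `name`, `site`, `cut_offset`.
#' @param topology `"linear"` (default; clone inserts are linear) or
#'   `"circular"`.
#' @return A `fragment_profile`: list with `source`, sorted integer
#'   `fragments` (bp) and `topology`. Fragments always sum to the sequence
#'   length.
#' @export
digest <- function(seq, enzyme = "HindIII", topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  x <- as_seq1(seq)
  e <- resolve_enzyme(enzyme)
  n <- nchar(x$seq)
  site_len <- nchar(e$site)
  search_seq <- x$seq
  if (topology == "circular" && n >= site_len)
    search_seq <- paste0(x$seq, substr(x$seq, 1L, site_len - 1L))
  hits <- Biostrings::start(Biostrings::matchPattern(
    e$site, Biostrings::DNAString(search_seq), fixed = TRUE))
  cuts <- hits + e$cut_offset - 1L          # bases before the cut
  if (topology == "linear") {
    cuts <- sort(unique(cuts[cuts >= 1L & cuts < n]))
    frags <- diff(c(0L, cuts, n))
  } else {
    cuts <- sort(unique(((cuts - 1L) %% n) + 1L))
    frags <- if (length(cuts) == 0) n
             else if (length(cuts) == 1) n
             else c(diff(cuts), n - cuts[length(cuts)] + cuts[1])
  }
  structure(list(source = x$id, fragments = sort(as.integer(frags)),
                 topology = topology, enzyme = e$name),
            class = "fragment_profile")
}

#' Create a fragment profile from a size list
#'
#' @param fragments Integer vector of fragment sizes in bp.
#' @param source Label for the profile (e.g. "gel: clone 251E3").
#' @param topology Molecule topology.
#' @return A `fragment_profile`.
#' @export
fragment_profile <- function(fragments, source = "profile",
                             topology = "linear") {
  structure(list(source = source, fragments = sort(as.integer(fragments)),
                 topology = topology, enzyme = NA_character_),
            class = "fragment_profile")
}

#' Read an experimental fragment-size list
#'
#' Plain text, one integer size (bp) per line; `#` starts a comment.
#'
#' @param path Input file.
#' @param source Profile label (defaults to the file name).
#' @return A `fragment_profile`.
#' @export
read_fragment_profile <- function(path, source = basename(path)) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  fragment_profile(as.integer(lines), source = source)
}

#' @export
print.fragment_profile <- function(x, ...) {
  cat(sprintf("<fragment_profile> %s (%s%s): %d fragments, %d bp total\n",
              x$source, x$topology,
              if (is.na(x$enzyme)) "" else paste0(", ", x$enzyme),
              length(x$fragments), sum(x$fragments)))
  invisible(x)
}

#' @export
tidy.fragment_profile <- function(x, ...) {
  tibble(source = x$source, fragment = x$fragments)
}

#' Match two fragment profiles at gel resolution
#'
#' Greedy largest-first matching: repeatedly takes the largest unmatched
#' fragment from either profile and pairs it with the closest unmatched
#' fragment of the other profile within tolerance
#' `|x - y| <= max(abs_tol, rel_tol * max(x, y))`. Fragments below
#' `min_fragment` (typically unresolved on gels) are excluded from matching.
#'
#' @param a,b `fragment_profile` objects.
#' @param rel_tol Relative size tolerance (default 0.05).
#' @param abs_tol Absolute tolerance in bp (default 50, gel sizing error).
#' @param min_fragment Fragments below this size are ignored (default 500).
#' @return A `profile_match`: list with `matched` (tibble of size pairs),
#'   `unmatched_a`, `unmatched_b` (integer vectors) and `concordant`
#'   (TRUE iff both unmatched sets are empty).
#' @export
match_profiles <- function(a, b, rel_tol = 0.05, abs_tol = 50,
                           min_fragment = 500L) {
  fa <- sort(a$fragments[a$fragments >= min_fragment], decreasing = TRUE)
  fb <- sort(b$fragments[b$fragments >= min_fragment], decreasing = TRUE)
  used_a <- logical(length(fa)); used_b <- logical(length(fb))
  pairs <- list()
  repeat {
    ia <- which(!used_a); ib <- which(!used_b)
    if (length(ia) == 0 && length(ib) == 0) break
    top_a <- if (length(ia)) fa[ia[1]] else -Inf
    top_b <- if (length(ib)) fb[ib[1]] else -Inf
    if (top_a >= top_b) {
      i <- ia[1]
      cand <- ib[abs(fb[ib] - fa[i]) <= pmax(abs_tol, rel_tol * pmax(fb[ib], fa[i]))]
      if (length(cand) == 0) { used_a[i] <- TRUE; next }
      j <- cand[which.min(abs(fb[cand] - fa[i]))]
      pairs <- c(pairs, list(c(fa[i], fb[j])))
      used_a[i] <- TRUE; used_b[j] <- TRUE
    } else {
      j <- ib[1]
      cand <- ia[abs(fa[ia] - fb[j]) <= pmax(abs_tol, rel_tol * pmax(fa[ia], fb[j]))]
      if (length(cand) == 0) { used_b[j] <- TRUE; next }
      i <- cand[which.min(abs(fa[cand] - fb[j]))]
      pairs <- c(pairs, list(c(fa[i], fb[j])))
      used_a[i] <- TRUE; used_b[j] <- TRUE
    }
  }
  matched <- if (length(pairs))
    tibble(size_a = purrr::map_int(pairs, ~ as.integer(.x[1])),
           size_b = purrr::map_int(pairs, ~ as.integer(.x[2])))
  else tibble(size_a = integer(), size_b = integer())
  unmatched_a <- sort(setdiff_multiset(fa, matched$size_a))
  unmatched_b <- sort(setdiff_multiset(fb, matched$size_b))
  structure(list(matched = arrange(matched, dplyr::desc(.data$size_a)),
                 unmatched_a = unmatched_a, unmatched_b = unmatched_b,
                 concordant = length(unmatched_a) == 0 &&
                   length(unmatched_b) == 0),
            class = "profile_match")
}

# multiset difference (removes one occurrence per match)
setdiff_multiset <- function(x, y) {
  for (v in y) {
    i <- match(v, x)
    if (!is.na(i)) x <- x[-i]
  }
  x
}

#' @export
print.profile_match <- function(x, ...) {
  cat(sprintf("<profile_match> %d pairs, %d+%d unmatched, concordant: %s\n",
              nrow(x$matched), length(x$unmatched_a), length(x$unmatched_b),
              x$concordant))
  invisible(x)
}

#' @export
glance.profile_match <- function(x, ...) {
  tibble(n_matched = nrow(x$matched), n_unmatched_a = length(x$unmatched_a),
         n_unmatched_b = length(x$unmatched_b), concordant = x$concordant)
}
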