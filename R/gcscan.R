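# Windowed GC-content profiling and z-score anomaly flagging.

#' Sliding-window GC profile
#'
#' GC fraction per window, `(G + C) / (A + C + G + T)` with N excluded from
#' the denominator; all-N windows are recorded as missing and excluded from
#' the scan mean and standard deviation. The baseline mean/sd are computed
#' over the scanned interval (typically one gene), not genome-wide.
#'
#' @param seq One-row sequence tibble or string.
#' @param start,end Scanned interval (1-based inclusive; default the whole
#'   sequence).
#' @param window Window size in bp (default 100).
#' @param step Step between window starts in bp (default 1, a true sliding
#'   window; increase for speed).
#' @return A `gc_scan`: list with `windows` (tibble `start`, `end`, `gc`),
#'   `mean`, `sd`, `window`, `step`, `seq_id` and the scanned interval.
#' @export
gc_profile <- function(seq, start = NULL, end = NULL, window = 100L,
                       step = 1L) {
  x <- as_seq1(seq)
  n <- nchar(x$seq)
  start <- as.integer(start %||% 1L); end <- as.integer(end %||% n)
  stopifnot(start >= 1, end <= n, start <= end)
  if (window > end - start + 1L) abort("window larger than scanned interval")
  v <- seq_to_int(substr(x$seq, start, end))
  gcb <- as.integer(v == 2L | v == 3L)
  valid <- as.integer(v != 0L)
  cg <- c(0L, cumsum(gcb)); cv <- c(0L, cumsum(valid))
  p <- seq.int(1L, length(v) - window + 1L, by = step)
  den <- cv[p + window] - cv[p]
  num <- cg[p + window] - cg[p]
  gc <- ifelse(den == 0L, NA_real_, num / den)
  w_start <- start + p - 1L
  structure(list(
    windows = tibble(start = w_start, end = w_start + window - 1L, gc = gc),
    mean = mean(gc, na.rm = TRUE), sd = sd(gc, na.rm = TRUE),
    window = as.integer(window), step = as.integer(step),
    seq_id = x$id, from = start, to = end), class = "gc_scan")
}

#' @export
tidy.gc_scan <- function(x, ...) {
  mutate(x$windows, z = (.data$gc - x$mean) / x$sd)
}

#' @export
glance.gc_scan <- function(x, ...) {
  tibble(seq_id = x$seq_id, from = x$from, to = x$to, window = x$window,
         step = x$step, n_windows = nrow(x$windows),
         mean_gc = x$mean, sd_gc = x$sd)
}

#' @export
print.gc_scan <- function(x, ...) {
  cat(sprintf("<gc_scan> %s [%d-%d], %d-bp window step %d: mean GC %.3f, sd %.3f\n",
              x$seq_id, x$from, x$to, x$window, x$step, x$mean, x$sd))
  invisible(x)
}

#' GC profile track with anomaly cut-off
#'
#' @param object A `gc_scan`.
#' @param z_cutoff Cut-off line to draw (default 2.5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gc_scan <- function(object, z_cutoff = 2.5, ...) {
  df <- object$windows
  ggplot2::ggplot(df, ggplot2::aes(.data$start, .data$gc)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_hline(yintercept = object$mean, linetype = 2) +
    ggplot2::geom_hline(yintercept = object$mean + z_cutoff * object$sd,
                        colour = "firebrick") +
    ggplot2::labs(x = "position (bp)", y = "GC fraction") +
    ggplot2::theme_minimal()
}

#' Flag GC anomalies by z-score
#'
#' Windows whose GC z-score meets the cut-off are merged into maximal runs;
#' each run becomes one anomaly interval (union of qualifying window spans).
#'
#' @param scan A `gc_scan` from [gc_profile()].
#' @param z_cutoff Standard-deviation cut-off (default 2.5).
#' @param direction `"high"` (default; GC-biased conversion leaves elevated
#'   GC), `"low"`, or `"both"`.
#' @param min_windows Minimum number of consecutive qualifying windows for a
#'   run to be reported (default 25): a genuine GC tract sustains the
#'   excursion across many overlapping windows, whereas single-window spikes
#'   on random sequence do not. Runs whose intervals still overlap (possible
#'   when the step is smaller than the window) are merged.
#' @return A tibble of anomalies: `start`, `end`, `peak_z`, `peak_gc`,
#'   `n_windows`, plus empty association columns filled by
#'   [associate_boundaries()]. Empty (with a warning) when the scan has no
#'   variation.
#' @export
flag_anomalies <- function(scan, z_cutoff = 2.5,
                           direction = c("high", "low", "both"),
                           min_windows = 25L) {
  direction <- match.arg(direction)
  empty <- tibble(start = integer(), end = integer(), peak_z = double(),
                  peak_gc = double(), n_windows = integer())
  if (is.na(scan$sd) || scan$sd == 0) {
    warn("flag_anomalies: GC scan has no variation (sd = 0)")
    return(empty)
  }
  w <- scan$windows
  z <- (w$gc - scan$mean) / scan$sd
  hit <- switch(direction,
                high = z >= z_cutoff,
                low = z <= -z_cutoff,
                both = abs(z) >= z_cutoff)
  hit[is.na(hit)] <- FALSE
  if (!any(hit)) return(empty)
  r <- rle(hit); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- purrr::map_dfr(which(r$values), function(i) {
    rows <- starts[i]:ends[i]
    peak <- rows[which.max(abs(z[rows]))]
    tibble(start = w$start[rows[1]], end = w$end[rows[length(rows)]],
           peak_z = z[peak], peak_gc = w$gc[peak],
           n_windows = length(rows))
  })
  runs <- filter(runs, .data$n_windows >= min_windows)
  if (nrow(runs) <= 1) return(runs)
  # with step < window, spans of nearby runs can overlap: merge them
  grp <- cumsum(c(1L, runs$start[-1] > cummax(runs$end)[-nrow(runs)]))
  runs |>
    mutate(grp = grp) |>
    group_by(.data$grp) |>
    summarise(start = min(.data$start), end = max(.data$end),
              peak_gc = .data$peak_gc[which.max(abs(.data$peak_z))],
              peak_z = .data$peak_z[which.max(abs(.data$peak_z))],
              n_windows = sum(.data$n_windows), .groups = "drop") |>
    select("start", "end", "peak_z", "peak_gc", "n_windows")
}

#' Associate GC anomalies with exon boundaries
#'
#' For each anomaly, finds the closest exon start or end within `max_dist`
#' bp (distance zero when the boundary falls inside the anomaly interval).
#'
#' @param anomalies Anomaly tibble from [flag_anomalies()].
#' @param features Feature tibble including `exon` rows.
#' @param max_dist Maximum association distance in bp (default 200).
#' @return The anomaly tibble with `boundary_name`, `boundary_pos` and
#'   `boundary_dist` columns (NA where no boundary is within range).
#' @export
associate_boundaries <- function(anomalies, features, max_dist = 200L) {
  ex <- filter(features, .data$kind == "exon")
  bnd <- bind_rows(
    tibble(name = paste0(ex$name, "_start"), pos = ex$start),
    tibble(name = paste0(ex$name, "_end"), pos = ex$end))
  fill <- purrr::pmap_dfr(
    anomalies[, c("start", "end")], function(start, end) {
      if (nrow(bnd) == 0)
        return(tibble(boundary_name = NA_character_,
                      boundary_pos = NA_integer_, boundary_dist = NA_integer_))
      d <- pmax(0L, pmax(bnd$pos - end, start - bnd$pos))
      i <- which.min(d)
      if (d[i] <= max_dist)
        tibble(boundary_name = bnd$name[i], boundary_pos = bnd$pos[i],
               boundary_dist = as.integer(d[i]))
      else
        tibble(boundary_name = NA_character_, boundary_pos = NA_integer_,
               boundary_dist = NA_integer_)
    })
  dplyr::bind_cols(anomalies, fill)
}

#' Export anomalies as BED
#'
#' BED is 0-based half-open; intervals are converted from the package's
#' 1-based inclusive convention. The score column carries the peak z-score
#' scaled by 100.
#'
#' @param anomalies Anomaly tibble from [flag_anomalies()].
#' @param seq_id Chromosome/sequence name.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_anomalies_bed <- function(anomalies, seq_id, path) {
  lines <- sprintf("%s\t%d\t%d\tgc_anomaly_%d\t%d\t.",
                   seq_id, anomalies$start - 1L, anomalies$end,
                   seq_len(nrow(anomalies)),
                   as.integer(round(anomalies$peak_z * 100)))
  writeLines(lines, path)
  invisible(path)
}

#' Export a GC profile as bedGraph
#'
#' @param scan A `gc_scan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gc_bedgraph <- function(scan, path) {
  w <- scan$windows[!is.na(scan$windows$gc), ]
  lines <- c(sprintf("track type=bedGraph name=\"GC %s\"", scan$seq_id),
             sprintf("%s\t%d\t%d\t%.6g", scan$seq_id, w$start - 1L, w$end,
                     w$gc))
  writeLines(lines, path)
  invisible(path)
}
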