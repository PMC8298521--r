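#' Per-SNP Gd allele-depth fraction
#'
#' The bulked-segregant statistic: `gd / (gd + vx)`, the fraction of reads
#' carrying the mutant-parent (Gd) allele at a marker. In a bulk selected
#' for the mutant phenotype the fraction is 0.5 at unlinked markers and
#' approaches 1.0 at the causal locus, so "the ratio approaching 1.0" flags
#' the candidate region. Undefined (NA) when both depths are zero; such
#' markers are dropped from the ratio track.
#'
#' @param gd_depth,vx_depth Non-negative integer read depths (vectorised).
#' @return Numeric in `[0, 1]`, NA where total depth is zero.
#' @examples
#' snp_ratio(10, 10)  # 0.5
#' snp_ratio(20, 0)   # 1
#' @export
snp_ratio <- function(gd_depth, vx_depth) {
  if (any(gd_depth < 0) || any(vx_depth < 0))
    stop("read depths must be non-negative")
  total <- gd_depth + vx_depth
  ifelse(total == 0, NA_real_, gd_depth / total)
}

#' Per-marker ratio track from a bulk depth table
#'
#' @param depths Bulk depth table (see [simulate_pool_depths()]).
#' @return Data frame `chrom, pos_bp, id, ratio`, markers with zero total
#'   depth removed, sorted by `(chrom, pos_bp)`.
#' @export
ratio_track <- function(depths) {
  r <- snp_ratio(depths$gd_depth, depths$vx_depth)
  out <- data.frame(chrom = depths$chrom, pos_bp = depths$pos_bp,
                    id = depths$id, ratio = r, stringsAsFactors = FALSE)
  out <- out[!is.na(out$ratio), , drop = FALSE]
  out <- out[order(out$chrom, out$pos_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sliding-window means of the ratio track
#'
#' Windows are bp-anchored and half-open, `[k*step, k*step + window)` for
#' k = 0, 1, ... per chromosome (the package's one departure from 1-based
#' inclusive coordinates): a marker at 1-based position p falls in the
#' window when `start < p <= start + window`. The defaults are a 0.5 Mb
#' window advanced in 0.25 Mb steps. A window containing fewer than
#' `min_markers` markers with a defined ratio is masked: reported with
#' `mean_ratio = NA`, never as 0.
#'
#' @param track Ratio track from [ratio_track()].
#' @param genome Optional `toy_genome` supplying chromosome lengths;
#'   when absent the last marker position is used as the chromosome end.
#' @param window Window width in bp (default 5e5).
#' @param step Step in bp (default 2.5e5); `0 < step <= window`.
#' @param min_markers Minimum defined ratios per reported window (default 5).
#' @return Data frame `chrom, win_start, win_end, n_markers, mean_ratio`
#'   with `win_start`/`win_end` the half-open bounds; attribute
#'   `chrom_lengths` records the lengths used, attribute `step` the step.
#' @export
window_means <- function(track, genome = NULL, window = 5e5, step = 2.5e5,
                         min_markers = 5) {
  if (window <= 0 || step <= 0) stop("window and step must be positive")
  if (step > window) stop("step must not exceed window")
  lens <- if (!is.null(genome)) chrom_lengths(genome) else
    tapply(track$pos_bp, track$chrom, max)
  parts <- lapply(unique(track$chrom), function(ch) {
    len <- lens[[ch]]
    pos <- track$pos_bp[track$chrom == ch]
    val <- track$ratio[track$chrom == ch]
    starts <- seq(0, len - 1e-9, by = step)
    means <- n <- numeric(length(starts))
    for (k in seq_along(starts)) {
      inside <- pos > starts[k] & pos <= starts[k] + window
      n[k] <- sum(inside)
      means[k] <- if (n[k] >= min_markers) mean(val[inside]) else NA_real_
    }
    data.frame(chrom = ch, win_start = starts, win_end = starts + window,
               n_markers = as.integer(n), mean_ratio = means,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "chrom_lengths") <- lens
  attr(out, "step") <- step
  out
}

#' Detect mapping peaks in a windowed ratio track
#'
#' A peak is a maximal run of at least `min_run` contiguous unmasked windows
#' whose mean ratio is at or above `threshold` (masked windows break runs).
#' Each run yields one peak whose interval spans the run (clipped to the
#' chromosome end, converted back to 1-based inclusive coordinates) and
#' whose `peak_window` is the run's maximum-mean window, leftmost on ties.
#' Peaks are returned sorted by `peak_value` descending.
#'
#' @param windows Output of [window_means()].
#' @param threshold Detection threshold in `(0.5, 1]` (default 0.9).
#' @param min_run Minimum run length in windows (default 1).
#' @return List of `mapping_peak` objects: `interval` (a
#'   `genomic_interval`), `peak_value`, `peak_window` (list with
#'   `win_start`, `win_end`).
#' @export
detect_peaks <- function(windows, threshold = 0.9, min_run = 1) {
  if (threshold <= 0.5 || threshold > 1)
    stop("threshold must lie in (0.5, 1]")
  if (min_run < 1) stop("min_run must be >= 1")
  lens <- attr(windows, "chrom_lengths")
  step <- attr(windows, "step")
  peaks <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    w <- w[order(w$win_start), , drop = FALSE]
    above <- !is.na(w$mean_ratio) & w$mean_ratio >= threshold
    # contiguity additionally requires consecutive window starts
    r <- rle(above)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    for (j in which(r$values & r$lengths >= min_run)) {
      rows <- idx_start[j]:idx_end[j]
      if (!is.null(step) &&
          any(diff(w$win_start[rows]) > step + 1e-9)) next
      best <- rows[which.max(w$mean_ratio[rows])]
      end_bp <- max(w$win_end[rows])
      if (!is.null(lens) && !is.null(lens[[ch]]))
        end_bp <- min(end_bp, lens[[ch]])
      peaks[[length(peaks) + 1L]] <- structure(
        list(interval = genomic_interval(ch, min(w$win_start[rows]) + 1,
                                         end_bp),
             peak_value = w$mean_ratio[best],
             peak_window = list(win_start = w$win_start[best],
                                win_end = w$win_end[best])),
        class = "mapping_peak")
    }
  }
  peaks[order(vapply(peaks, `[[`, 0, "peak_value"), decreasing = TRUE)]
}

#' @export
print.mapping_peak <- function(x, ...) {
  cat(sprintf("mapping_peak: %s:%s-%s  peak mean ratio %.3f in window [%s, %s)\n",
              x$interval$chrom, format(x$interval$start, big.mark = ","),
              format(x$interval$end, big.mark = ","), x$peak_value,
              format(x$peak_window$win_start, big.mark = ","),
              format(x$peak_window$win_end, big.mark = ",")))
  invisible(x)
}

#' Write detected peaks as BED
#'
#' @param peaks List of `mapping_peak`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  if (length(peaks) == 0L) {
    cat("", file = path)
    return(invisible(path))
  }
  write_bed(lapply(peaks, `[[`, "interval"), path,
            names = sprintf("peak%d_ratio%.3f", seq_along(peaks),
                            vapply(peaks, `[[`, 0, "peak_value")))
}
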