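#' Circular summary of bending angles
#'
#' Summarises protonema bending angles (measured relative to the original
#' growth axis, reported in degrees on `[0, 360)`): a circular histogram,
#' the circular mean direction and the mean resultant length. Angles are
#' reduced modulo 360 first, so the summary is invariant to adding full
#' turns and equivariant under global rotation (the mean rotates, the
#' resultant length does not).
#'
#' @param angles Numeric angles in degrees, `n >= 1`.
#' @param bin_width Histogram bin width in degrees; must divide 360
#'   (default 30).
#' @return List with `counts` (named by bin start, over
#'   `[k*bin, (k+1)*bin)`), `mean_angle` (degrees in `[0, 360)`, NA when the
#'   resultant length is numerically zero, e.g. antipodal pairs), `rbar`
#'   (mean resultant length in `[0, 1]`) and `n`.
#' @examples
#' circular_summary(c(0, 90))  # mean 45, rbar cos(pi/4)
#' @export
circular_summary <- function(angles, bin_width = 30) {
  if (length(angles) < 1L) stop("empty angle sample")
  if (bin_width <= 0 || 360 %% bin_width != 0)
    stop("bin_width must be a positive divisor of 360")
  a <- angles %% 360
  nbins <- 360 / bin_width
  bin <- floor(a / bin_width) + 1L
  counts <- tabulate(bin, nbins)
  names(counts) <- seq(0, 360 - bin_width, by = bin_width)
  rad <- a * pi / 180
  s <- mean(sin(rad)); c <- mean(cos(rad))
  rbar <- sqrt(s^2 + c^2)
  mean_angle <- if (rbar < 1e-12) NA_real_ else
    (atan2(s, c) * 180 / pi) %% 360
  list(counts = counts, mean_angle = mean_angle, rbar = rbar,
       n = length(a))
}

#' Per-timepoint mean, sd and n of angle time series
#'
#' Summarises kinetic bending curves (one series per filament) as the
#' arithmetic mean and sample standard deviation at each timepoint over the
#' filaments present there; missing values are skipped and `n` is reported
#' per timepoint. The linear (not circular) mean is used, appropriate while
#' the angles stay well within one cycle.
#'
#' @param series A numeric matrix (rows = timepoints, columns = filaments),
#'   or a list of equal-indexing numeric vectors (shorter series are padded
#'   with NA).
#' @param timepoints Optional timepoint labels (default row index).
#' @return Data frame `timepoint, mean, sd, n`; `sd` is NA where `n < 2`.
#' @export
kinetic_summary <- function(series, timepoints = NULL) {
  if (is.list(series) && !is.data.frame(series)) {
    if (length(series) < 1L) stop("need at least one series")
    len <- max(vapply(series, length, 0L))
    series <- vapply(series, function(x) c(x, rep(NA_real_, len - length(x))),
                     numeric(len))
    series <- matrix(series, nrow = len)
  }
  series <- as.matrix(series)
  if (ncol(series) < 1L) stop("need at least one series")
  n <- apply(series, 1L, function(x) sum(!is.na(x)))
  m <- apply(series, 1L, function(x) mean(x, na.rm = TRUE))
  s <- apply(series, 1L, function(x)
    if (sum(!is.na(x)) >= 2L) stats::sd(x, na.rm = TRUE) else NA_real_)
  m[n == 0L] <- NA_real_
  if (is.null(timepoints)) timepoints <- seq_len(nrow(series))
  data.frame(timepoint = timepoints, mean = m, sd = s, n = n)
}
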