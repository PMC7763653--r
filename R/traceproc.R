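#' Detect peaks in an electropherogram
#'
#' The trace is detrended with a rolling-median baseline (window much wider
#' than a peak) and the noise level is estimated as the scaled median absolute
#' deviation of the detrended signal. Local maxima of the detrended signal
#' exceeding \code{min_snr * noise} and \code{min_height_fu} are reported,
#' ordered by time; apex times are refined by a three-point parabolic fit so
#' sizing is not limited by the sampling grid. Peak areas are Gaussian
#' estimates (height x fitted sigma x sqrt(2*pi)).
#'
#' @param trace an \code{"electropherogram"}.
#' @param min_snr detection threshold in noise standard deviations.
#' @param min_height_fu absolute height floor, FU.
#' @param min_sep_s minimum separation between reported apexes, seconds;
#'   candidates closer than this are merged keeping the tallest.
#' @param baseline_window_s rolling-median window, seconds.
#' @return data.frame of class \code{"chip_peaks"} with columns
#'   \code{time_s}, \code{height_fu}, \code{area}, \code{is_internal_marker}
#'   (all \code{FALSE}; markers are identified later, positionally).
#' @export
detect_peaks <- function(trace, min_snr = 5, min_height_fu = 0,
                         min_sep_s = 0.15, baseline_window_s = 2) {
  dt <- stats::median(diff(trace$time_s))
  k <- max(3L, as.integer(round(baseline_window_s / dt)))
  if (k %% 2L == 0L) k <- k + 1L
  baseline <- stats::runmed(trace$fu, k, endrule = "median")
  y <- as.numeric(trace$fu - baseline)
  noise <- stats::mad(y)
  thr <- max(min_snr * noise, min_height_fu, .Machine$double.eps)
  pk <- pracma::findpeaks(y, minpeakheight = thr,
                          minpeakdistance = max(1L, as.integer(round(min_sep_s / dt))))
  if (is.null(pk))
    return(empty_peaks())
  pk <- pk[order(pk[, 2]), , drop = FALSE]
  # prominence filter: a peak must rise by the threshold above its connecting
  # saddle, which rejects noise wiggles riding on the tail of a larger peak
  prom <- vapply(pk[, 2], function(i) peak_prominence(y, i), numeric(1))
  pk <- pk[prom >= thr, , drop = FALSE]
  if (nrow(pk) == 0L)
    return(empty_peaks())
  apex_t <- numeric(nrow(pk)); height <- numeric(nrow(pk))
  area <- numeric(nrow(pk))
  for (r in seq_len(nrow(pk))) {
    i <- pk[r, 2]
    delta <- 0; h <- y[i]; sigma <- dt
    if (i > 1L && i < length(y)) {
      # parabola through the apex sample and its neighbours; for a Gaussian
      # the curvature also yields the width, hence the area estimate
      a <- (y[i - 1] + y[i + 1] - 2 * y[i]) / 2
      b <- (y[i + 1] - y[i - 1]) / 2
      if (a < 0) {
        delta <- max(-1, min(1, -b / (2 * a)))
        h <- y[i] + b * delta + a * delta^2
        sigma <- sqrt(max(h, .Machine$double.eps) / (-2 * a)) * dt
      }
    }
    apex_t[r] <- trace$time_s[i] + delta * dt
    height[r] <- h
    area[r] <- h * sigma * sqrt(2 * pi)
  }
  structure(data.frame(time_s = apex_t, height_fu = height, area = area,
                       is_internal_marker = FALSE),
            class = c("chip_peaks", "data.frame"))
}

# topographic prominence of the local maximum at index i: height above the
# higher of the two minima separating it from the nearest taller point (or
# trace end) on each side
peak_prominence <- function(y, i) {
  n <- length(y)
  left_min <- y[i]; j <- i
  while (j > 1L && y[j - 1L] <= y[i]) {
    j <- j - 1L
    if (y[j] < left_min) left_min <- y[j]
  }
  right_min <- y[i]; j <- i
  while (j < n && y[j + 1L] <= y[i]) {
    j <- j + 1L
    if (y[j] < right_min) right_min <- y[j]
  }
  y[i] - max(left_min, right_min)
}

empty_peaks <- function() {
  structure(data.frame(time_s = numeric(0), height_fu = numeric(0),
                       area = numeric(0), is_internal_marker = logical(0)),
            class = c("chip_peaks", "data.frame"))
}

#' Fit the time-to-size calibration from a ladder well
#'
#' Detects the ladder peaks, takes the first and last as the lower/upper
#' internal markers, and pairs the remaining peaks in time order with the
#' known rung sizes (their counts must agree). The calibration is a strictly
#' monotone piecewise-linear interpolation of log10(size) against apex time,
#' exact at every rung, with linear extrapolation beyond the outer rungs.
#'
#' @param ladder_trace ladder-well \code{"electropherogram"}.
#' @param ladder_sizes ascending rung sizes, bp.
#' @param min_snr,min_height_fu passed to \code{\link{detect_peaks}}.
#' @return An object of class \code{"chip_calibration"} with fields
#'   \code{anchor_time_s}, \code{anchor_size_bp}, \code{marker_time_s}
#'   (lower, upper).
#' @export
fit_calibration <- function(ladder_trace, ladder_sizes, min_snr = 5,
                            min_height_fu = 0) {
  pk <- detect_peaks(ladder_trace, min_snr = min_snr,
                     min_height_fu = min_height_fu)
  if (nrow(pk) < 4L)
    stop("ladder well: only ", nrow(pk),
         " peaks detected; need 2 markers + >= 2 rungs", call. = FALSE)
  rung_t <- pk$time_s[-c(1L, nrow(pk))]
  if (length(rung_t) != length(ladder_sizes))
    stop("ladder calibration: ", length(rung_t),
         " non-marker peaks detected but ", length(ladder_sizes),
         " rung sizes expected", call. = FALSE)
  if (is.unsorted(ladder_sizes, strictly = TRUE))
    stop("ladder sizes must be strictly ascending", call. = FALSE)
  cal <- structure(list(anchor_time_s = rung_t,
                        anchor_size_bp = as.numeric(ladder_sizes),
                        marker_time_s = pk$time_s[c(1L, nrow(pk))]),
                   class = "chip_calibration")
  # monotonicity assertion over the anchored interval
  grid <- seq(min(rung_t), max(rung_t), length.out = 512L)
  est <- time_to_size(cal, grid)
  if (any(diff(est) <= 0))
    stop("fitted calibration map is not strictly increasing", call. = FALSE)
  cal
}

#' @export
print.chip_calibration <- function(x, ...) {
  cat(sprintf("Chip calibration: %d rungs (%g-%g bp), markers at %.2f / %.2f s\n",
              length(x$anchor_size_bp), min(x$anchor_size_bp),
              max(x$anchor_size_bp), x$marker_time_s[1], x$marker_time_s[2]))
  invisible(x)
}

#' Map migration times to fragment sizes under a calibration
#'
#' Piecewise-linear in log10(size) between rung anchors; linear continuation
#' with the terminal segment slopes outside the anchored interval.
#'
#' @param calibration a \code{"chip_calibration"}.
#' @param time_s migration times, seconds.
#' @return Estimated sizes, bp.
#' @export
time_to_size <- function(calibration, time_s) {
  x <- calibration$anchor_time_s
  y <- log10(calibration$anchor_size_bp)
  n <- length(x)
  yi <- stats::approx(x, y, xout = pmin(pmax(time_s, x[1]), x[n]),
                      ties = "ordered")$y
  lo <- time_s < x[1]; hi <- time_s > x[n]
  if (any(lo))
    yi[lo] <- y[1] + (time_s[lo] - x[1]) * (y[2] - y[1]) / (x[2] - x[1])
  if (any(hi))
    yi[hi] <- y[n] + (time_s[hi] - x[n]) * (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  10^yi
}

#' Align a sample well to the ladder via the internal markers
#'
#' Every well carries the same lower and upper marker fragments; the affine
#' time transform that maps the sample's two marker apexes onto the ladder's
#' removes well-to-well migration drift. The transform is the identity when
#' the marker times already coincide.
#'
#' @param sample_trace sample-well \code{"electropherogram"}.
#' @param calibration a \code{"chip_calibration"} (supplies the ladder marker
#'   times).
#' @param min_snr,min_height_fu passed to \code{\link{detect_peaks}}.
#' @return The trace with transformed \code{time_s}, plus attributes
#'   \code{align_scale} and \code{align_shift}.
#' @export
align_internal_markers <- function(sample_trace, calibration, min_snr = 5,
                                   min_height_fu = 0) {
  pk <- detect_peaks(sample_trace, min_snr = min_snr,
                     min_height_fu = min_height_fu)
  if (nrow(pk) < 2L)
    stop("sample well '", sample_trace$label, "': fewer than two peaks; ",
         "internal markers not detectable", call. = FALSE)
  smk <- pk$time_s[c(1L, nrow(pk))]
  lmk <- calibration$marker_time_s
  scale <- (lmk[2] - lmk[1]) / (smk[2] - smk[1])
  shift <- lmk[1] - scale * smk[1]
  out <- sample_trace
  out$time_s <- scale * sample_trace$time_s + shift
  attr(out, "align_scale") <- scale
  attr(out, "align_shift") <- shift
  out
}

#' Size the fragments of a sample well
#'
#' Detect peaks, align the well to the ladder via its internal markers, drop
#' the two marker peaks, and convert the remaining apex times to fragment
#' sizes; sizes outside the chip's 25-1000 bp sizing range are flagged.
#'
#' @inheritParams align_internal_markers
#' @param sizing_range_bp the chip's validated sizing range, bp.
#' @return data.frame of class \code{"sized_peaks"} with columns
#'   \code{time_s}, \code{height_fu}, \code{area}, \code{size_bp},
#'   \code{in_sizing_range}.
#' @export
size_peaks <- function(sample_trace, calibration, min_snr = 5,
                       min_height_fu = 0, sizing_range_bp = c(25, 1000)) {
  aligned <- align_internal_markers(sample_trace, calibration,
                                    min_snr = min_snr,
                                    min_height_fu = min_height_fu)
  pk <- detect_peaks(aligned, min_snr = min_snr,
                     min_height_fu = min_height_fu)
  if (nrow(pk) >= 2L) pk <- pk[-c(1L, nrow(pk)), , drop = FALSE]
  size <- time_to_size(calibration, pk$time_s)
  structure(data.frame(time_s = pk$time_s, height_fu = pk$height_fu,
                       area = pk$area, size_bp = size,
                       in_sizing_range = size >= sizing_range_bp[1] &
                         size <= sizing_range_bp[2]),
            class = c("sized_peaks", "data.frame"))
}
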