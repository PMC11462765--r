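#' Detect R peaks in an ECG trace
#'
#' Threshold-plus-refractory local-maxima detector. A sample is a candidate
#' peak if it is a strict local maximum and exceeds
#' `baseline + threshold_frac * (max - baseline)` where the baseline is the
#' median amplitude. Candidates closer together than the refractory period
#' are merged, keeping the larger one (physiologically, a second QRS cannot
#' occur within ~200 ms of the last).
#'
#' @param ecg An [ecg_trace()].
#' @param threshold_frac Fraction of the baseline-to-max range a peak must
#'   exceed (default 0.5).
#' @param refractory_ms Minimum gap between reported peaks in ms (default 200).
#' @return List of class `r_peaks` with `times` (ms, strictly increasing, in
#'   the clip time base) and the parameters used.
#' @export
detect_r_peaks <- function(ecg, threshold_frac = 0.5, refractory_ms = 200) {
  stopifnot(inherits(ecg, "ecg_trace"))
  x <- ecg$samples
  if (anyNA(x)) em_stop("em_input_error", "ECG contains NA/NaN samples")
  if (max(x) == min(x)) em_stop("em_no_peaks_error", "constant ECG trace: no peaks")
  baseline <- stats::median(x)
  thr <- baseline + threshold_frac * (max(x) - baseline)
  n <- length(x)
  # strict local maxima (plateaus: first sample of the plateau wins);
  # boundary samples count as peaks when they exceed their single neighbour
  left <- c(-Inf, x[-n])
  right <- c(x[-1], -Inf)
  cand <- which(x >= thr & x > left & x >= right)
  if (length(cand) == 0L) em_stop("em_no_peaks_error", "no samples exceed R-peak threshold")
  dt_ms <- 1000 / ecg$sampling_rate
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) == 0L || (i - keep[length(keep)]) * dt_ms >= refractory_ms) {
      keep <- c(keep, i)
    } else if (x[i] > x[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  structure(
    list(times = ecg$t0 + (keep - 1) * dt_ms,
         threshold_frac = threshold_frac, refractory_ms = refractory_ms),
    class = "r_peaks"
  )
}

#' Fractional R-R landmark times for a montage
#'
#' The montage formats sample the cardiac cycle at fixed fractions of the
#' R-R interval: the single-cycle format (Type 1) takes the R peak, one third
#' (approximate end of the T wave), one half (mid T-P segment) and two thirds
#' (approximate P-wave onset) of the first complete R-R interval; the
#' two-cycle format (Type 2) takes the R peak and one third of the R-R from
#' each of the first two consecutive cycles. When more peaks are available
#' than needed, the earliest complete cycle(s) are used.
#'
#' @param r_peaks An `r_peaks` object or a numeric vector of peak times (ms).
#' @param montage_type 1 or 2.
#' @return List of class `landmark_set`: `montage_type`, `times` (4 ms
#'   values, non-decreasing), and `fractions` (data.frame of cycle, fraction).
#' @export
landmark_times <- function(r_peaks, montage_type = 1) {
  if (inherits(r_peaks, "r_peaks")) r_peaks <- r_peaks$times
  stopifnot(is.numeric(r_peaks), montage_type %in% c(1, 2))
  r_peaks <- sort(r_peaks)
  need <- if (montage_type == 2) 3L else 2L
  if (length(r_peaks) < need)
    em_stop("em_insufficient_cycles_error",
            "montage type %d needs >= %d R peaks, got %d (single cardiac cycle)",
            montage_type, need, length(r_peaks))
  if (montage_type == 1) {
    rr <- r_peaks[2] - r_peaks[1]
    times <- r_peaks[1] + rr * c(0, 1 / 3, 1 / 2, 2 / 3)
    fractions <- data.frame(cycle = c(1, 1, 1, 1), fraction = c(0, 1 / 3, 1 / 2, 2 / 3))
  } else {
    rr1 <- r_peaks[2] - r_peaks[1]
    rr2 <- r_peaks[3] - r_peaks[2]
    times <- c(r_peaks[1], r_peaks[1] + rr1 / 3, r_peaks[2], r_peaks[2] + rr2 / 3)
    fractions <- data.frame(cycle = c(1, 1, 2, 2), fraction = c(0, 1 / 3, 0, 1 / 3))
  }
  structure(list(montage_type = montage_type, times = times, fractions = fractions),
            class = "landmark_set")
}

#' Map landmark times to frame indices
#'
#' Each landmark maps to the frame whose acquisition time is nearest; exact
#' ties break toward the earlier frame so results are reproducible across
#' frame rates. Indices are 1-based (R convention). Repeated indices can only
#' occur when the frame rate is lower than the landmark spacing; this is
#' flagged in the `repeated` attribute.
#'
#' @param landmarks A `landmark_set` or numeric vector of times (ms).
#' @param frame_times Strictly increasing frame times (ms) spanning the landmarks.
#' @return Integer vector of frame indices (1-based), with attribute
#'   `repeated` (logical).
#' @export
landmark_frame_indices <- function(landmarks, frame_times) {
  if (inherits(landmarks, "landmark_set")) landmarks <- landmarks$times
  stopifnot(is.numeric(landmarks), is.numeric(frame_times))
  if (any(diff(frame_times) <= 0))
    em_stop("em_input_error", "frame_times must be strictly increasing")
  span <- range(frame_times)
  # half-quantum slack: a landmark within half a frame period of the last
  # frame still maps to it
  slack <- stats::median(diff(frame_times)) / 2
  if (any(landmarks < span[1] - slack | landmarks > span[2] + slack))
    em_stop("em_out_of_span_error",
            "landmark outside frame-time span [%.1f, %.1f] ms", span[1], span[2])
  idx <- vapply(landmarks, function(tm) {
    d <- abs(frame_times - tm)
    which(d <= min(d) + 1e-9)[1]  # earlier frame on ties
  }, integer(1))
  attr(idx, "repeated") <- anyDuplicated(idx) > 0L
  idx
}
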