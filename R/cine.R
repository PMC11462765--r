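#' ECG trace attached to a cine clip
#'
#' A lightweight container for an ECG recording synchronized to a cine loop.
#' Amplitudes are in arbitrary units; what matters downstream is the position
#' of the R peaks in the clip time base.
#'
#' @param samples Numeric vector of ECG amplitudes (>= 2 samples).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in milliseconds, relative to the first
#'   frame of the accompanying clip.
#' @return An object of class `ecg_trace`.
#' @export
ecg_trace <- function(samples, sampling_rate, t0 = 0) {
  if (!is.numeric(samples) || length(samples) < 2L)
    em_stop("em_input_error", "ECG trace needs at least 2 numeric samples")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0)
    em_stop("em_input_error", "sampling_rate must be a positive scalar (Hz)")
  structure(
    list(samples = as.numeric(samples),
         sampling_rate = as.numeric(sampling_rate),
         t0 = as.numeric(t0)),
    class = "ecg_trace"
  )
}

#' Sample times of an ECG trace in clip milliseconds
#' @param ecg An `ecg_trace`.
#' @return Numeric vector of per-sample times (ms).
#' @export
ecg_times <- function(ecg) {
  ecg$t0 + (seq_along(ecg$samples) - 1) / ecg$sampling_rate * 1000
}

#' Multiframe echocardiogram cine clip
#'
#' The unit of raw input: a stack of frames, their acquisition times, an
#' optional synchronized ECG, and identifiers. Frames are numeric matrices
#' (grayscale, 0-255) or `h x w x 3` arrays (color), all sharing dimensions;
#' the image origin is top-left.
#'
#' @param frames List of frames (matrices or 3-channel arrays).
#' @param frame_times Strictly increasing acquisition times in ms, one per frame.
#' @param ecg Optional [ecg_trace()].
#' @param color_space One of `"grayscale"`, `"rgb"`, `"sepia"`.
#' @param patient_id,study_id,clip_id Opaque identifier strings.
#' @param view_tag Free-text view label (e.g. `"PSAX"`).
#' @return An object of class `cine_clip`.
#' @export
cine_clip <- function(frames, frame_times, ecg = NULL,
                      color_space = c("grayscale", "rgb", "sepia"),
                      patient_id = "P0", study_id = "S0", clip_id = "C0",
                      view_tag = "PSAX") {
  color_space <- match.arg(color_space)
  if (!is.list(frames) || length(frames) == 0L)
    em_stop("em_input_error", "frames must be a non-empty list")
  if (length(frames) != length(frame_times))
    em_stop("em_input_error", "one frame_time per frame required (%d frames, %d times)",
            length(frames), length(frame_times))
  if (any(diff(frame_times) <= 0))
    em_stop("em_input_error", "frame_times must be strictly increasing")
  d1 <- dim(frames[[1]])
  for (f in frames) {
    if (!identical(dim(f)[1:2], d1[1:2]))
      em_stop("em_input_error", "all frames must share height and width")
  }
  if (!is.null(ecg)) {
    stopifnot(inherits(ecg, "ecg_trace"))
    tt <- ecg_times(ecg)
    if (tt[1] > frame_times[1] + 1e-6 || tt[length(tt)] < frame_times[length(frame_times)] - 1e-6)
      em_stop("em_ecg_mismatch_error",
              "ECG span [%.1f, %.1f] ms does not cover frame span [%.1f, %.1f] ms",
              tt[1], tt[length(tt)], frame_times[1], frame_times[length(frame_times)])
  }
  structure(
    list(frames = frames, frame_times = as.numeric(frame_times), ecg = ecg,
         color_space = color_space, patient_id = patient_id,
         study_id = study_id, clip_id = clip_id, view_tag = view_tag),
    class = "cine_clip"
  )
}

#' @export
print.cine_clip <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<cine_clip %s> %d frames %dx%d (%s), %.0f-%.0f ms, ECG %s\n",
              x$clip_id, length(x$frames), d[2], d[1], x$color_space,
              x$frame_times[1], x$frame_times[length(x$frame_times)],
              if (is.null(x$ecg)) "absent" else "present"))
  invisible(x)
}

#' Clip-level quality control
#'
#' Applies the study's inclusion rules: a clip is unusable when its ECG is
#' absent or uninterpretable, when it covers only a single cardiac cycle
#' (fewer R peaks than the montage format needs), when a human reviewer
#' flagged obscuring overlays, or when the view label is off the accept list.
#' Poor image quality is deliberately *not* a failure code: low-quality but
#' valid clips stay in, mirroring real-world surveillance data.
#'
#' @param clip A [cine_clip()].
#' @param r_peaks Optional pre-computed R-peak times (ms); when `NULL` peaks
#'   are detected from the clip's ECG with [detect_r_peaks()] defaults.
#' @param montage_type 1 (needs >= 2 R peaks) or 2 (needs >= 3).
#' @param accept_views Optional character vector of acceptable `view_tag`s.
#' @param obscured Logical human-review flag for overlays obscuring anatomy.
#' @return A `clip_qc` report: list with `clip_id`, `usable`, `reasons`
#'   (subset of `NO_ECG`, `UNINTERPRETABLE_ECG`, `SINGLE_CYCLE`, `OBSCURED`,
#'   `WRONG_VIEW`).
#' @export
validate_clip <- function(clip, r_peaks = NULL, montage_type = 1,
                          accept_views = NULL, obscured = FALSE) {
  stopifnot(inherits(clip, "cine_clip"), montage_type %in% c(1, 2))
  reasons <- character(0)
  need <- if (montage_type == 2) 3L else 2L
  if (is.null(clip$ecg) && is.null(r_peaks)) {
    reasons <- c(reasons, "NO_ECG")
  } else {
    if (is.null(r_peaks)) {
      r_peaks <- tryCatch(detect_r_peaks(clip$ecg)$times, em_error = function(e) NULL)
    }
    if (is.null(r_peaks)) {
      reasons <- c(reasons, "UNINTERPRETABLE_ECG")
    } else if (length(r_peaks) < need) {
      reasons <- c(reasons, "SINGLE_CYCLE")
    }
  }
  if (isTRUE(obscured)) reasons <- c(reasons, "OBSCURED")
  if (!is.null(accept_views) && !(clip$view_tag %in% accept_views))
    reasons <- c(reasons, "WRONG_VIEW")
  structure(
    list(clip_id = clip$clip_id, usable = length(reasons) == 0L, reasons = reasons),
    class = "clip_qc"
  )
}

#' @export
print.clip_qc <- function(x, ...) {
  cat(sprintf("<clip_qc %s> usable=%s%s\n", x$clip_id, x$usable,
              if (length(x$reasons)) paste0(" [", paste(x$reasons, collapse = ","), "]") else ""))
  invisible(x)
}

#' Serialize QC reports as JSON lines
#' @param reports List of `clip_qc` reports.
#' @param path Output file; one JSON object per line.
#' @export
write_qc_reports <- function(reports, path) {
  lines <- vapply(reports, function(r) {
    jsonlite::toJSON(list(clip_id = r$clip_id, usable = r$usable,
                          reasons = r$reasons), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an ECG sidecar CSV
#'
#' Sidecar format: header `time_ms,amplitude`, one sample per row, uniform
#' sampling assumed (rate inferred from the median timestamp increment).
#'
#' @param path CSV path.
#' @return An [ecg_trace()] with `t0` equal to the first timestamp.
#' @export
read_ecg_sidecar <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_ms", "amplitude") %in% names(df)))
    em_stop("em_input_error", "ECG sidecar must have columns time_ms,amplitude")
  if (nrow(df) < 2L)
    em_stop("em_input_error", "ECG sidecar needs >= 2 samples")
  dt <- stats::median(diff(df$time_ms))
  if (!is.finite(dt) || dt <= 0)
    em_stop("em_input_error", "ECG sidecar timestamps must increase")
  ecg_trace(df$amplitude, sampling_rate = 1000 / dt, t0 = df$time_ms[1])
}

#' Write an ECG sidecar CSV
#' @param ecg An [ecg_trace()].
#' @param path Output CSV path.
#' @export
write_ecg_sidecar <- function(ecg, path) {
  utils::write.csv(
    data.frame(time_ms = ecg_times(ecg), amplitude = ecg$samples),
    path, row.names = FALSE)
  invisible(path)
}
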