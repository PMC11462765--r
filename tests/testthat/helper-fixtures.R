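# Shared fixtures, generated in code. Small phantom clips keep the suite fast.

tiny_phantom <- function(seed = 7, colorize = "grayscale", ...) {
  generate_phantom_clip(phantom_params(image_dims = c(160, 120), seed = seed,
                                       colorize = colorize, ...))
}

# A minimal hand-built clip: constant-dimension frames with explicit times.
manual_clip <- function(frames, fps = 30, ecg = NULL, ...) {
  cine_clip(frames, frame_times = (seq_along(frames) - 1) * 1000 / fps,
            ecg = ecg, ...)
}

# ECG trace with clean unit spikes at the given times (ms)
spike_ecg <- function(spike_times, fs = 500, duration = NULL, t0 = 0) {
  duration <- duration %||% (max(spike_times) + 200)
  t <- seq(0, duration, by = 1000 / fs)
  a <- numeric(length(t))
  for (tp in spike_times) a[which.min(abs(t - tp))] <- 1
  ecg_trace(a, sampling_rate = fs, t0 = t0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rec.601 luminance, reimplemented for comparisons
to_gray_ref <- function(f) {
  if (is.matrix(f)) f else 0.299 * f[, , 1] + 0.587 * f[, , 2] + 0.114 * f[, , 3]
}
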