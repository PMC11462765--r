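# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers can dispatch on failure kind.
em_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "em_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

em_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x) && x > 0

# 8-bit clamp; images are numeric matrices [row, col] in 0..255, origin top-left.
clamp8 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

#' @importFrom EBImage resize
resize_gray <- function(img, out_h, out_w) {
  stopifnot(is.matrix(img), out_h >= 1, out_w >= 1)
  if (nrow(img) == out_h && ncol(img) == out_w) return(img)
  # EBImage's first dimension maps to our rows.
  out <- EBImage::resize(img, w = out_h, h = out_w, filter = "bilinear")
  matrix(as.numeric(out), nrow = out_h, ncol = out_w)
}

# Symmetric zero-pad to exact output dims; odd remainders give the extra
# pixel to the bottom/right edge.
pad_symmetric <- function(img, out_h, out_w, value = 0) {
  h <- nrow(img); w <- ncol(img)
  stopifnot(out_h >= h, out_w >= w)
  if (out_h == h && out_w == w) return(img)
  out <- matrix(value, nrow = out_h, ncol = out_w)
  top <- (out_h - h) %/% 2
  left <- (out_w - w) %/% 2
  out[top + seq_len(h), left + seq_len(w)] <- img
  out
}

# Rec.601 luminance conversion; pass-through for matrices.
to_gray <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (length(dim(frame)) == 3L && dim(frame)[3] == 3L) {
    return(0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3])
  }
  em_stop("em_input_error", "frame must be a matrix or an h x w x 3 array")
}
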