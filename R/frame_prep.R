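#' Estimate the imaging-sector mask of a cine clip
#'
#' Burned-in annotations (text, scale bars) are static while insonated tissue
#' moves and its speckle decorrelates, so the per-pixel temporal variance
#' across frames separates the fan-shaped imaging sector from overlays and
#' background. The variance map is thresholded, small connected components
#' are dropped, the largest component is kept, and its convex hull is taken
#' as the sector (a circular sector with opening angle below 180 degrees is
#' convex). Moving overlays such as an ECG sweep form their own components
#' and are discarded with the small/non-largest ones.
#'
#' @param clip A [cine_clip()] with at least 2 frames.
#' @param var_frac Variance threshold as a fraction of the maximum per-pixel
#'   variance.
#' @param max_frames Cap on the number of frames used (evenly subsampled).
#' @return A `sector_mask`: list with logical `mask` and `method`.
#' @export
compute_sector_mask <- function(clip, var_frac = 0.002, max_frames = 24) {
  stopifnot(inherits(clip, "cine_clip"))
  if (length(clip$frames) < 2)
    em_stop("em_input_error", "sector estimation needs >= 2 frames")
  idx <- unique(round(seq(1, length(clip$frames),
                          length.out = min(max_frames, length(clip$frames)))))
  M <- vapply(clip$frames[idx], function(f) as.numeric(to_gray(f)),
              numeric(length(to_gray(clip$frames[[1]]))))
  v <- rowMeans(M^2) - rowMeans(M)^2
  if (max(v) <= 1e-9)
    em_stop("em_no_sector_error", "clip has no temporal variance anywhere")
  h <- nrow(to_gray(clip$frames[[1]])); w <- ncol(to_gray(clip$frames[[1]]))
  fg <- matrix(v > var_frac * max(v), h, w)

  lab <- EBImage::bwlabel(fg)
  sizes <- tabulate(lab[lab > 0])
  min_size <- max(9, round(5e-4 * h * w))
  big <- which(sizes >= min_size)
  if (length(big) == 0L)
    em_stop("em_no_sector_error", "no connected moving region found")
  keep <- big[which.max(sizes[big])]
  comp <- lab == keep

  mask <- fill_convex_hull(comp) | comp
  frac <- mean(mask)
  if (frac < 0.05 || frac > 0.95)
    em_stop("em_no_sector_error",
            "sector covers %.1f%% of the image; outside the plausible 5-95%% range",
            100 * frac)
  structure(list(mask = mask, method = "threshold-hull"), class = "sector_mask")
}

#' Wrap a user-provided sector mask
#' @param mask Logical matrix (TRUE inside the imaging sector).
#' @return A `sector_mask` with method `"provided"`.
#' @export
sector_mask <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  structure(list(mask = mask, method = "provided"), class = "sector_mask")
}

# Rasterize the convex hull of the TRUE pixels of a logical matrix
# (even-odd crossing test against the hull polygon, at pixel centers).
fill_convex_hull <- function(comp) {
  pts <- which(comp, arr.ind = TRUE)
  hull <- pts[grDevices::chull(pts[, 2], pts[, 1]), , drop = FALSE]
  if (nrow(hull) < 3) return(comp)
  h <- nrow(comp); w <- ncol(comp)
  ry <- rep(seq_len(h), times = w)
  cx <- rep(seq_len(w), each = h)
  inside <- rep(FALSE, h * w)
  n <- nrow(hull)
  j <- n
  for (i in seq_len(n)) {
    y1 <- hull[i, 1]; x1 <- hull[i, 2]
    y2 <- hull[j, 1]; x2 <- hull[j, 2]
    cross <- ((y1 > ry) != (y2 > ry)) &
      (cx < (x2 - x1) * (ry - y1) / (y2 - y1) + x1)
    inside <- xor(inside, cross)
    j <- i
  }
  matrix(inside, h, w)
}

#' Mask and grayscale a single frame
#'
#' Converts color frames to single-channel by Rec.601 luminance
#' (0.299 R + 0.587 G + 0.114 B), zeroes every pixel outside the sector
#' mask, and returns an 8-bit grayscale matrix of the same dimensions.
#' Idempotent on its own output.
#'
#' @param frame Matrix or `h x w x 3` array, values 0-255.
#' @param mask A `sector_mask` or logical matrix matching the frame.
#' @return Numeric matrix (0-255 integers).
#' @export
prepare_frame <- function(frame, mask) {
  if (inherits(mask, "sector_mask")) mask <- mask$mask
  g <- to_gray(frame)
  if (!all(dim(mask) == dim(g)))
    em_stop("em_input_error", "mask dimensions %dx%d do not match frame %dx%d",
            nrow(mask), ncol(mask), nrow(g), ncol(g))
  g[!mask] <- 0
  clamp8(g)
}
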