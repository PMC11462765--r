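# 2x2 montage assembly and standardization. Grid layout is row-major in
# landmark order: position 1 = top-left = first landmark, position 2 =
# top-right, position 3 = bottom-left, position 4 = bottom-right.

fit_to_tile <- function(frame, tile_h, tile_w) {
  h <- nrow(frame); w <- ncol(frame)
  s <- min(tile_w / w, tile_h / h)
  if (abs(s - 1) > 1e-12) {
    frame <- resize_gray(frame, max(1, round(h * s)), max(1, round(w * s)))
  }
  pad_symmetric(frame, tile_h, tile_w)
}

#' Assemble four prepared frames into a 2x2 montage
#'
#' Frames are placed row-major in landmark order. If input dimensions differ,
#' each frame is first fit to a common tile (the max width and height among
#' inputs) by aspect-preserving scaling plus symmetric zero-padding.
#'
#' @param frames List of exactly 4 grayscale matrices (prepared frames).
#' @param montage_type 1 or 2.
#' @param provenance List with `patient_id`, `study_id`, `clip_id`, and
#'   `frames` (data.frame with columns `position`, `frame_index`, `cycle`,
#'   `fraction`, `time_ms`).
#' @return An object of class `echo_montage` (pre-standardization).
#' @export
assemble_montage <- function(frames, montage_type = 1, provenance = NULL) {
  if (!is.list(frames) || length(frames) != 4L)
    em_stop("em_input_error", "a montage needs exactly 4 frames, got %d", length(frames))
  stopifnot(montage_type %in% c(1, 2))
  frames <- lapply(frames, to_gray)
  tile_h <- max(vapply(frames, nrow, 1L))
  tile_w <- max(vapply(frames, ncol, 1L))
  tiles <- lapply(frames, fit_to_tile, tile_h = tile_h, tile_w = tile_w)
  image <- rbind(cbind(tiles[[1]], tiles[[2]]),
                 cbind(tiles[[3]], tiles[[4]]))
  if (!is.null(provenance) && !is.null(provenance$frames) &&
      nrow(provenance$frames) != 4L)
    em_stop("em_input_error", "provenance must describe exactly 4 frames")
  structure(
    list(image = clamp8(image), montage_type = montage_type,
         provenance = provenance, target_dims = c(ncol(image), nrow(image))),
    class = "echo_montage"
  )
}

#' Standardize montage dimensions
#'
#' Scales by `min(target_w / w, target_h / h)` (aspect-preserving, bilinear)
#' and symmetrically zero-pads to exactly `target_dims`. The study-standard
#' input dimension is 1200 x 900 pixels.
#'
#' @param montage An `echo_montage`.
#' @param target_dims `c(width, height)` in pixels.
#' @return The montage with `image` of exactly `target_dims`.
#' @export
standardize_montage <- function(montage, target_dims = c(1200, 900)) {
  stopifnot(inherits(montage, "echo_montage"))
  if (length(target_dims) != 2 || any(target_dims <= 0))
    em_stop("em_config_error", "target_dims must be two positive pixel counts")
  tw <- target_dims[1]; th <- target_dims[2]
  img <- montage$image
  h <- nrow(img); w <- ncol(img)
  if (h == th && w == tw) {
    montage$target_dims <- target_dims
    return(montage)
  }
  s <- min(tw / w, th / h)
  img <- resize_gray(img, max(1, round(h * s)), max(1, round(w * s)))
  img <- pad_symmetric(img, th, tw)
  montage$image <- clamp8(img)
  montage$target_dims <- target_dims
  montage
}

#' @export
print.echo_montage <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<echo_montage type %d> %dx%d%s\n", x$montage_type,
              ncol(x$image), nrow(x$image),
              if (!is.null(p)) sprintf(" (%s/%s/%s)", p$patient_id, p$study_id, p$clip_id) else ""))
  invisible(x)
}

montage_sidecar_path <- function(png_path) sub("\\.png$", ".json", png_path)

#' Save a montage as PNG plus JSON sidecar
#'
#' Written under `dir/<patient>/<study>/type<k>.png` with a sidecar carrying
#' the montage type, dimensions, and frame provenance.
#'
#' @param montage An `echo_montage` (with provenance identifiers).
#' @param dir Output root directory.
#' @return The PNG path, invisibly.
#' @export
save_montage <- function(montage, dir) {
  p <- montage$provenance
  if (is.null(p) || is.null(p$patient_id) || is.null(p$study_id))
    em_stop("em_input_error", "montage provenance with patient/study ids required to save")
  out_dir <- file.path(dir, p$patient_id, p$study_id)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  png_path <- file.path(out_dir, sprintf("type%d.png", montage$montage_type))
  png::writePNG(montage$image / 255, png_path)
  meta <- list(montage_type = montage$montage_type,
               patient_id = p$patient_id, study_id = p$study_id,
               clip_id = p$clip_id %||% NA,
               width = ncol(montage$image), height = nrow(montage$image),
               target_dims = montage$target_dims,
               frames = p$frames)
  jsonlite::write_json(meta, montage_sidecar_path(png_path),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(png_path)
}

#' Load a montage saved by [save_montage()]
#' @param png_path Path to the montage PNG.
#' @return An `echo_montage` equal to the one saved.
#' @export
load_montage <- function(png_path) {
  sc <- montage_sidecar_path(png_path)
  if (!file.exists(png_path))
    em_stop("em_input_error", "no montage image at %s", png_path)
  if (!file.exists(sc))
    em_stop("em_integrity_error", "montage sidecar %s is missing", sc)
  img <- clamp8(png::readPNG(png_path) * 255)
  if (length(dim(img)) == 3L) img <- to_gray(255 * png::readPNG(png_path))
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (meta$width != ncol(img) || meta$height != nrow(img))
    em_stop("em_integrity_error",
            "sidecar dims %dx%d disagree with PNG %dx%d",
            meta$width, meta$height, ncol(img), nrow(img))
  structure(
    list(image = img, montage_type = meta$montage_type,
         provenance = list(patient_id = meta$patient_id, study_id = meta$study_id,
                           clip_id = meta$clip_id,
                           frames = as.data.frame(meta$frames)),
         target_dims = as.numeric(meta$target_dims)),
    class = "echo_montage"
  )
}

#' Build a standardized montage straight from a cine clip
#'
#' Runs the full extraction chain: R-peak detection, fractional R-R
#' landmarks, nearest-frame mapping, sector masking, per-frame preparation,
#' 2x2 assembly, and standardization.
#'
#' @param clip A [cine_clip()] with an ECG (or supply `r_peaks`).
#' @param montage_type 1 or 2.
#' @param mask Optional precomputed `sector_mask` (default: estimated).
#' @param r_peaks Optional R-peak times in ms (default: detected).
#' @param target_dims Final dimensions, `c(width, height)`.
#' @return A standardized `echo_montage`.
#' @export
montage_from_clip <- function(clip, montage_type = 1, mask = NULL,
                              r_peaks = NULL, target_dims = c(1200, 900)) {
  stopifnot(inherits(clip, "cine_clip"))
  if (is.null(r_peaks)) {
    if (is.null(clip$ecg)) em_stop("em_input_error", "clip has no ECG and no r_peaks given")
    r_peaks <- detect_r_peaks(clip$ecg)$times
  }
  lm <- landmark_times(r_peaks, montage_type)
  idx <- landmark_frame_indices(lm, clip$frame_times)
  if (is.null(mask)) mask <- compute_sector_mask(clip)
  prepared <- lapply(idx, function(i) prepare_frame(clip$frames[[i]], mask))
  prov <- list(
    patient_id = clip$patient_id, study_id = clip$study_id, clip_id = clip$clip_id,
    frames = data.frame(position = 1:4, frame_index = as.integer(idx),
                        cycle = lm$fractions$cycle, fraction = lm$fractions$fraction,
                        time_ms = lm$times)
  )
  standardize_montage(assemble_montage(prepared, montage_type, prov), target_dims)
}

#' Create an empty montage registry
#'
#' The registry enforces the study rule that each patient contributes at most
#' one montage of each type per echocardiogram study.
#'
#' @return A zero-row data.frame with the registry columns.
#' @export
montage_registry <- function() {
  data.frame(patient_id = character(), study_id = character(),
             clip_id = character(), montage_type = integer(),
             echo_date = as.Date(character()), label = character(),
             stringsAsFactors = FALSE)
}

#' Register a montage, enforcing one per patient/study/type
#' @param registry A registry data.frame from [montage_registry()].
#' @param montage An `echo_montage` with provenance.
#' @param echo_date Optional echo date for subset filtering.
#' @param label Optional `"CASE"`/`"NON_CASE"` label.
#' @return The registry with one row appended.
#' @export
register_montage <- function(registry, montage, echo_date = as.Date(NA), label = NA_character_) {
  p <- montage$provenance
  dup <- registry$patient_id == p$patient_id & registry$study_id == p$study_id &
    registry$montage_type == montage$montage_type
  if (any(dup))
    em_stop("em_integrity_error",
            "duplicate montage for %s/%s type %d: each study contributes one montage per type",
            p$patient_id, p$study_id, montage$montage_type)
  rbind(registry, data.frame(
    patient_id = p$patient_id, study_id = p$study_id,
    clip_id = p$clip_id %||% NA_character_,
    montage_type = as.integer(montage$montage_type),
    echo_date = as.Date(echo_date), label = label, stringsAsFactors = FALSE))
}
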