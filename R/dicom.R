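# Minimal DICOM support: explicit-VR little-endian Part-10 files carrying
# uncompressed 8-bit multiframe ultrasound, plus a simplified waveform
# sequence for the ECG. This is a deliberately small subset — enough to
# round-trip the clips this package produces and to ingest files written in
# the same dialect — not a conformant general-purpose DICOM implementation.

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_element <- function(group, elem, vr, value) {
  if (length(value) %% 2 == 1) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0) else charToRaw(" ")
    value <- c(value, pad)
  }
  hdr <- c(raw_u16(group), raw_u16(elem), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(hdr, raw(2), raw_u32(length(value)), value)
  } else {
    if (length(value) > 65534) em_stop("em_input_error", "value too long for short VR")
    c(hdr, raw_u16(length(value)), value)
  }
}

dcm_str <- function(group, elem, vr, s) dcm_element(group, elem, vr, charToRaw(as.character(s)))
dcm_ds <- function(group, elem, x) dcm_str(group, elem, "DS",
                                           paste(formatC(x, digits = 10, format = "g"), collapse = "\\"))
dcm_us <- function(group, elem, x) dcm_element(group, elem, "US", raw_u16(x))
dcm_ul <- function(group, elem, x) dcm_element(group, elem, "UL", raw_u32(x))

#' Write a cine clip as a DICOM multiframe file
#'
#' Explicit-VR little-endian, uncompressed 8-bit pixels. The ECG, when
#' present, is embedded as a waveform sequence (sampling frequency, sample
#' count, trigger-time offset, float32 samples).
#'
#' @param clip A [cine_clip()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dicom_clip <- function(clip, path) {
  stopifnot(inherits(clip, "cine_clip"))
  h <- dim(clip$frames[[1]])[1]; w <- dim(clip$frames[[1]])[2]
  rgb <- !is.matrix(clip$frames[[1]])
  n <- length(clip$frames)

  px <- vector("list", n)
  for (k in seq_len(n)) {
    f <- clip$frames[[k]]
    px[[k]] <- if (rgb) as.raw(as.integer(clamp8(aperm(f, c(3, 2, 1)))))
               else as.raw(as.integer(clamp8(t(f))))
  }
  px <- do.call(c, px)

  el <- list(
    dcm_str(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.3.1"),
    dcm_str(0x0008, 0x0018, "UI", paste0("1.2.826.0.1.", abs(sum(utf8ToInt(clip$clip_id))))),
    dcm_str(0x0008, 0x0060, "CS", "US"),
    dcm_str(0x0008, 0x103E, "LO", clip$view_tag),
    dcm_str(0x0010, 0x0020, "LO", clip$patient_id),
    dcm_str(0x0018, 0x1030, "LO", clip$clip_id),
    dcm_str(0x0020, 0x0010, "SH", clip$study_id),
    dcm_str(0x0020, 0x4000, "LT", clip$color_space),
    dcm_us(0x0028, 0x0002, if (rgb) 3 else 1),
    dcm_str(0x0028, 0x0004, "CS", if (rgb) "RGB" else "MONOCHROME2"),
    dcm_str(0x0028, 0x0008, "IS", as.character(n)),
    dcm_us(0x0028, 0x0010, h),
    dcm_us(0x0028, 0x0011, w),
    dcm_us(0x0028, 0x0100, 8), dcm_us(0x0028, 0x0101, 8),
    dcm_us(0x0028, 0x0102, 7), dcm_us(0x0028, 0x0103, 0)
  )
  if (rgb) el <- c(el, list(dcm_us(0x0028, 0x0006, 0)))

  ft <- clip$frame_times
  if (n >= 2 && max(abs(diff(ft) - (ft[2] - ft[1]))) < 1e-6) {
    el <- c(el, list(dcm_ds(0x0018, 0x1063, ft[2] - ft[1])))
  } else {
    el <- c(el, list(dcm_ds(0x0018, 0x1065, c(ft[1], diff(ft)))))
  }

  if (!is.null(clip$ecg)) {
    item <- c(
      dcm_ds(0x0018, 0x1060, clip$ecg$t0),
      dcm_ds(0x003A, 0x001A, clip$ecg$sampling_rate),
      dcm_ul(0x003A, 0x0010, length(clip$ecg$samples)),
      dcm_element(0x5400, 0x1010, "OF",
                  writeBin(as.numeric(clip$ecg$samples), raw(), size = 4, endian = "little"))
    )
    sq_val <- c(raw_u16(0xFFFE), raw_u16(0xE000), raw_u32(length(item)), item)
    el <- c(el, list(dcm_element(0x5400, 0x0100, "SQ", sq_val)))
  }

  el <- c(el, list(dcm_element(0x7FE0, 0x0010, "OB", px)))
  body <- do.call(c, el)

  meta_el <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_str(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.3.1"),
    dcm_str(0x0002, 0x0003, "UI", "1.2.826.0.1.1"),
    dcm_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  )
  meta <- c(dcm_ul(0x0002, 0x0000, length(meta_el)), meta_el)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

read_u16 <- function(buf, pos) readBin(buf[pos:(pos + 1)], "integer", size = 2,
                                       endian = "little", signed = FALSE)
read_u32 <- function(buf, pos) readBin(buf[pos:(pos + 3)], "integer", size = 4,
                                       endian = "little")

# Parse an explicit-VR little-endian element stream into a flat named list
# keyed "GGGG,EEEE"; sequences become nested lists of items.
parse_elements <- function(buf, pos, end) {
  out <- list()
  while (pos <= end - 7) {
    group <- read_u16(buf, pos); elem <- read_u16(buf, pos + 2)
    vr <- rawToChar(buf[(pos + 4):(pos + 5)])
    if (vr %in% LONG_VRS) {
      len <- read_u32(buf, pos + 8); vpos <- pos + 12
    } else {
      len <- read_u16(buf, pos + 6); vpos <- pos + 8
    }
    if (len < 0 || vpos + len - 1 > end)
      em_stop("em_input_error", "corrupt DICOM element at offset %d", pos)
    key <- sprintf("%04X,%04X", group, elem)
    if (vr == "SQ") {
      items <- list(); ip <- vpos
      while (ip <= vpos + len - 8) {
        ilen <- read_u32(buf, ip + 4)
        items[[length(items) + 1]] <- parse_elements(buf, ip + 8, ip + 7 + ilen)
        ip <- ip + 8 + ilen
      }
      out[[key]] <- list(vr = vr, items = items)
    } else {
      out[[key]] <- list(vr = vr, value = if (len > 0) buf[vpos:(vpos + len - 1)] else raw(0))
    }
    pos <- vpos + len
  }
  out
}

dcm_get_str <- function(el, key) {
  if (is.null(el[[key]])) return(NULL)
  v <- el[[key]]$value
  trimws(rawToChar(v[v != as.raw(0)]))  # drop UI nul padding
}
dcm_get_num <- function(el, key) {
  s <- dcm_get_str(el, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
dcm_get_u16 <- function(el, key) {
  if (is.null(el[[key]])) return(NULL)
  readBin(el[[key]]$value, "integer", size = 2, endian = "little", signed = FALSE)
}
dcm_get_u32 <- function(el, key) {
  if (is.null(el[[key]])) return(NULL)
  readBin(el[[key]]$value, "integer", size = 4, endian = "little")
}

#' Read a multiframe DICOM cine clip
#'
#' Reads files in the explicit-VR little-endian dialect written by
#' [write_dicom_clip()]. Frame times come from the frame-time vector when
#' present, otherwise from uniform spacing by the frame-time tag. The ECG is
#' taken from embedded waveform data when present, else from a sidecar CSV
#' (`time_ms,amplitude`), else left absent.
#'
#' @param path DICOM file path.
#' @param ecg_sidecar Optional CSV path supplying the ECG when the file
#'   carries none.
#' @return A [cine_clip()].
#' @export
read_dicom_clip <- function(path, ecg_sidecar = NULL) {
  if (!file.exists(path)) em_stop("em_input_error", "cannot read %s", path)
  buf <- readBin(path, raw(), file.info(path)$size)
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM")
    em_stop("em_input_error", "%s is not a DICOM Part-10 file", path)
  el <- parse_elements(buf, 133, length(buf))
  ts <- dcm_get_str(el, "0002,0010")
  if (!is.null(ts) && ts != "1.2.840.10008.1.2.1")
    em_stop("em_input_error", "unsupported transfer syntax %s", ts)

  n <- dcm_get_num(el, "0028,0008") %||% 1
  if (n < 2) em_stop("em_not_a_cine_error", "single-frame object is not a cine clip")
  h <- dcm_get_u16(el, "0028,0010"); w <- dcm_get_u16(el, "0028,0011")
  spp <- dcm_get_u16(el, "0028,0002") %||% 1
  px <- el[["7FE0,0010"]]
  if (is.null(px) || is.null(h) || is.null(w))
    em_stop("em_input_error", "missing pixel data or dimensions")
  need <- n * h * w * spp
  if (length(px$value) < need)
    em_stop("em_input_error", "pixel data truncated (%d < %d bytes)", length(px$value), need)
  vals <- as.integer(px$value[seq_len(need)])

  frames <- vector("list", n)
  fsz <- h * w * spp
  for (k in seq_len(n)) {
    fr <- vals[((k - 1) * fsz + 1):(k * fsz)]
    if (spp == 1) {
      frames[[k]] <- t(matrix(fr, nrow = w, ncol = h))
    } else {
      a <- array(fr, dim = c(3, w, h))        # channel-fastest, row-major
      frames[[k]] <- aperm(a, c(3, 2, 1))
    }
  }

  ftv <- dcm_get_num(el, "0018,1065")
  if (!is.null(ftv)) {
    frame_times <- cumsum(ftv)
  } else {
    ft <- dcm_get_num(el, "0018,1063")
    if (is.null(ft)) em_stop("em_input_error", "no frame timing tags present")
    frame_times <- (seq_len(n) - 1) * ft
  }

  ecg <- NULL
  wf <- el[["5400,0100"]]
  if (!is.null(wf) && length(wf$items) >= 1) {
    it <- wf$items[[1]]
    fs <- dcm_get_num(it, "003A,001A")
    t0 <- dcm_get_num(it, "0018,1060") %||% 0
    ns <- dcm_get_u32(it, "003A,0010")
    samples <- readBin(it[["5400,1010"]]$value, "numeric", n = ns, size = 4,
                       endian = "little")
    ecg <- ecg_trace(samples, sampling_rate = fs, t0 = t0)
  } else if (!is.null(ecg_sidecar)) {
    ecg <- read_ecg_sidecar(ecg_sidecar)
  }

  cs <- dcm_get_str(el, "0020,4000")
  if (is.null(cs) || !(cs %in% c("grayscale", "rgb", "sepia")))
    cs <- if (spp == 3) "rgb" else "grayscale"

  cine_clip(frames, frame_times, ecg = ecg, color_space = cs,
            patient_id = dcm_get_str(el, "0010,0020") %||% "unknown",
            study_id = dcm_get_str(el, "0020,0010") %||% "unknown",
            clip_id = dcm_get_str(el, "0018,1030") %||% basename(path),
            view_tag = dcm_get_str(el, "0008,103E") %||% "")
}
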