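test_that("DICOM round trip preserves frames, times, and identifiers", {
  for (col in c("grayscale", "sepia")) {
    ph <- tiny_phantom(seed = 3, colorize = col)
    f <- withr::local_tempfile(fileext = ".dcm")
    write_dicom_clip(ph$clip, f)
    clip2 <- read_dicom_clip(f)
    expect_equal(length(clip2$frames), length(ph$clip$frames))
    expect_equal(dim(clip2$frames[[1]])[1:2], dim(ph$clip$frames[[1]])[1:2])
    # times to within one timestamp quantum
    expect_lt(max(abs(clip2$frame_times - ph$clip$frame_times)), 1000 / 30)
    # 8-bit storage: within half a gray level
    expect_lte(max(abs(to_gray_ref(clip2$frames[[1]]) - to_gray_ref(ph$clip$frames[[1]]))), 0.5)
    expect_equal(clip2$patient_id, ph$clip$patient_id)
    expect_equal(clip2$study_id, ph$clip$study_id)
    expect_equal(clip2$clip_id, ph$clip$clip_id)
    expect_equal(clip2$view_tag, ph$clip$view_tag)
    expect_equal(clip2$color_space, ph$clip$color_space)
    # embedded ECG restored (float32 precision)
    expect_lt(max(abs(clip2$ecg$samples - ph$clip$ecg$samples)), 1e-6)
    expect_equal(clip2$ecg$sampling_rate, ph$clip$ecg$sampling_rate)
  }
})

test_that("uniform frame timing reconstructs from the frame-rate tag", {
  frames <- replicate(60, matrix(0, 20, 24), simplify = FALSE)
  clip <- manual_clip(frames, fps = 30)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_clip(clip, f)
  clip2 <- read_dicom_clip(f)
  expect_equal(clip2$frame_times, (0:59) * 1000 / 30, tolerance = 1e-9)
  expect_equal(clip2$frame_times[60], 1966.667, tolerance = 1e-4)
})

test_that("ECG sidecar supplies the trace when the file has none", {
  frames <- replicate(10, matrix(0, 10, 12), simplify = FALSE)
  clip <- manual_clip(frames, fps = 30)  # no ECG embedded
  f <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_clip(clip, f)

  side <- withr::local_tempfile(fileext = ".csv")
  ecg <- spike_ecg(c(50, 250), duration = 400, t0 = 0)
  write_ecg_sidecar(ecg, side)
  clip2 <- read_dicom_clip(f, ecg_sidecar = side)
  expect_false(is.null(clip2$ecg))
  expect_equal(clip2$ecg$t0, 0)
  expect_equal(clip2$ecg$sampling_rate, 500)

  # sidecar starting after the first frame cannot cover the clip
  short <- withr::local_tempfile(fileext = ".csv")
  write_ecg_sidecar(ecg_trace(c(0, 1, 0), 500, t0 = 100), short)
  expect_error(read_dicom_clip(f, ecg_sidecar = short), class = "em_ecg_mismatch_error")
})

test_that("still images and unreadable files are rejected", {
  f <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_clip(manual_clip(list(matrix(0, 8, 8))), f)
  expect_error(read_dicom_clip(f), class = "em_not_a_cine_error")
  expect_error(read_dicom_clip(file.path(tempdir(), "nope.dcm")),
               class = "em_input_error")
  junk <- withr::local_tempfile(fileext = ".dcm")
  writeBin(raw(200), junk)
  expect_error(read_dicom_clip(junk), class = "em_input_error")
})

test_that("clip QC applies the inclusion rules", {
  ph <- tiny_phantom(seed = 5)  # 3 cycles -> 3 R peaks
  qc <- validate_clip(ph$clip)
  expect_true(qc$usable)
  expect_length(qc$reasons, 0)

  no_ecg <- ph$clip; no_ecg$ecg <- NULL
  qc <- validate_clip(no_ecg)
  expect_false(qc$usable)
  expect_equal(qc$reasons, "NO_ECG")

  # a single detected R peak is a single-cycle clip
  one <- manual_clip(replicate(30, matrix(0, 10, 10), simplify = FALSE),
                     ecg = spike_ecg(200, duration = 1100))
  expect_equal(validate_clip(one)$reasons, "SINGLE_CYCLE")

  # two peaks are enough for Type 1 but not Type 2
  two <- manual_clip(replicate(30, matrix(0, 10, 10), simplify = FALSE),
                     ecg = spike_ecg(c(100, 800), duration = 1100))
  expect_true(validate_clip(two, montage_type = 1)$usable)
  expect_equal(validate_clip(two, montage_type = 2)$reasons, "SINGLE_CYCLE")

  # flat ECG is uninterpretable
  flat <- manual_clip(replicate(30, matrix(0, 10, 10), simplify = FALSE),
                      ecg = ecg_trace(numeric(600), 500))
  expect_equal(validate_clip(flat)$reasons, "UNINTERPRETABLE_ECG")

  qc <- validate_clip(ph$clip, accept_views = "A4C", obscured = TRUE)
  expect_setequal(qc$reasons, c("OBSCURED", "WRONG_VIEW"))

  # purity: identical input, identical report
  expect_identical(validate_clip(ph$clip), validate_clip(ph$clip))
})

test_that("QC reports serialize as JSON lines", {
  ph <- tiny_phantom(seed = 5)
  no_ecg <- ph$clip; no_ecg$ecg <- NULL
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_qc_reports(list(validate_clip(ph$clip), validate_clip(no_ecg)), f)
  lines <- readLines(f)
  expect_length(lines, 2)
  parsed <- jsonlite::fromJSON(lines[2])
  expect_false(parsed$usable)
  expect_equal(parsed$reasons, "NO_ECG")
})

test_that("an independent DICOM reader agrees on structure and pixels", {
  ph <- tiny_phantom(seed = 11)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_clip(ph$clip, f)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys, pydicom",
    "ds = pydicom.dcmread(sys.argv[1])",
    "px = ds.pixel_array",
    "print(ds.Rows, ds.Columns, ds.NumberOfFrames, ds.PatientID,",
    "      px.shape[0], int(px[0].sum()))"
  ), script)
  out <- system2("python", c(script, f), stdout = TRUE)
  parts <- strsplit(trimws(out[length(out)]), "\\s+")[[1]]
  expect_equal(as.integer(parts[1]), 120)
  expect_equal(as.integer(parts[2]), 160)
  expect_equal(as.integer(parts[3]), length(ph$clip$frames))
  expect_equal(parts[4], ph$clip$patient_id)
  expect_equal(as.integer(parts[5]), length(ph$clip$frames))
  expect_equal(as.numeric(parts[6]), sum(round(ph$clip$frames[[1]])))
})
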