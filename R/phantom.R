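# Synthetic parasternal short-axis phantom: a contracting ring-shaped
# ventricle (bright myocardium around a dark cavity) inside a fan-shaped
# imaging sector, with papillary bumps, multiplicative speckle, optional
# burned-in overlays, and a synchronized ECG with sharp R deflections.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Parameters for the short-axis phantom
#'
#' @param image_dims `c(width, height)` in pixels.
#' @param frame_rate Frames per second; must give >= 4 frames per cardiac cycle.
#' @param heart_rate Beats per minute.
#' @param n_cycles Number of cardiac cycles in the clip (>= 1).
#' @param r_ed End-diastolic cavity radius in pixels (default scaled to image).
#' @param fractional_shortening Ground-truth (r_ED - r_ES) / r_ED, in (0, 0.6).
#' @param wall_thickness Myocardial wall thickness in pixels.
#' @param papillary_amp Radius of the two papillary-muscle bumps in pixels.
#' @param speckle_scale Relative standard deviation of the multiplicative
#'   gamma speckle (0 disables it).
#' @param colorize `"grayscale"` or `"sepia"` (monotone sepia color map).
#' @param annotations Burn in a static text block and a moving ECG strip.
#' @param ecg_noise Additive Gaussian noise SD on the ECG (amplitude units).
#' @param seed Integer seed; clips are bitwise-reproducible given the seed.
#' @return A validated list of class `phantom_params`.
#' @export
phantom_params <- function(image_dims = c(320, 240), frame_rate = 30,
                           heart_rate = 75, n_cycles = 3, r_ed = NULL,
                           fractional_shortening = 0.35, wall_thickness = NULL,
                           papillary_amp = NULL, speckle_scale = 0.15,
                           colorize = c("grayscale", "sepia"),
                           annotations = TRUE, ecg_noise = 0, seed = 1) {
  colorize <- match.arg(colorize)
  if (fractional_shortening <= 0 || fractional_shortening >= 0.6)
    em_stop("em_config_error", "fractional_shortening must be in (0, 0.6)")
  if (!is_count(n_cycles))
    em_stop("em_config_error", "n_cycles must be a positive integer")
  if (frame_rate < heart_rate / 60 * 4)
    em_stop("em_config_error",
            "frame_rate %.1f gives < 4 frames per cycle at %.0f bpm", frame_rate, heart_rate)
  h <- image_dims[2]
  r_ed <- r_ed %||% round(0.18 * h)
  wall_thickness <- wall_thickness %||% max(3, round(0.5 * r_ed))
  papillary_amp <- papillary_amp %||% max(2, round(0.3 * wall_thickness))
  structure(
    list(image_dims = image_dims, frame_rate = frame_rate, heart_rate = heart_rate,
         n_cycles = n_cycles, r_ed = r_ed,
         fractional_shortening = fractional_shortening,
         wall_thickness = wall_thickness, papillary_amp = papillary_amp,
         speckle_scale = speckle_scale, colorize = colorize,
         annotations = annotations, ecg_noise = ecg_noise, seed = seed),
    class = "phantom_params"
  )
}

# Smooth unimodal contraction pulse over cycle phase, peaking at phase 1/3 so
# that end-systole coincides with the approximate end-of-T-wave landmark.
contraction_pulse <- function(phase, width = 0.12) {
  exp(-(phase - 1 / 3)^2 / (2 * width^2))
}

phantom_ecg <- function(params) {
  period <- 60000 / params$heart_rate
  duration <- params$n_cycles * period
  fs <- 500
  t <- seq(0, duration, by = 1000 / fs)
  r_times <- (seq_len(params$n_cycles) - 1) * period
  a <- numeric(length(t))
  for (rp in r_times) {
    a <- a + pmax(0, 1 - abs(t - rp) / 25)              # triangular QRS, 50 ms base
    a <- a + 0.18 * exp(-(t - (rp + period / 3))^2 / (2 * 40^2))  # T wave
    a <- a + 0.10 * exp(-(t - (rp + 2 * period / 3))^2 / (2 * 30^2))  # P wave
  }
  if (params$ecg_noise > 0) a <- a + stats::rnorm(length(a), 0, params$ecg_noise)
  list(ecg = ecg_trace(a, sampling_rate = fs, t0 = 0), r_times = r_times,
       period = period, duration = duration)
}

#' Generate a synthetic short-axis cine clip with ground truth
#'
#' Produces a [cine_clip()] plus a truth record carrying everything tests
#' need: true R-peak times, the imaging-sector mask, burned-in annotation
#' pixels, the per-frame cavity radius, and the ground-truth fractional
#' shortening.
#'
#' @param params A [phantom_params()] object (or arguments forwarded to it).
#' @param patient_id,study_id,clip_id Identifiers stamped on the clip.
#' @param view_tag View label (default `"PSAX"`).
#' @return List with elements `clip` ([cine_clip()]) and `truth` (list with
#'   `r_peak_times`, `sector` logical matrix, `annotation_pixels` logical
#'   matrix, `radius_px`, `fractional_shortening`, `intensity` list of
#'   pre-colorization frames).
#' @export
generate_phantom_clip <- function(params = phantom_params(),
                                  patient_id = "P0", study_id = "S0",
                                  clip_id = "C0", view_tag = "PSAX") {
  if (!inherits(params, "phantom_params")) params <- do.call(phantom_params, params)
  with_seed(params$seed, {
    w <- params$image_dims[1]; h <- params$image_dims[2]
    eg <- phantom_ecg(params)
    dt <- 1000 / params$frame_rate
    n_frames <- floor(eg$duration / dt)
    frame_times <- (seq_len(n_frames) - 1) * dt

    # geometry: fan apex at top center, ventricle centered along the beam
    apex <- c(x = w / 2, y = 4)
    fan_half <- 35 * pi / 180
    fan_r <- 0.82 * h
    X <- matrix(rep(seq_len(w), each = h), nrow = h)
    Y <- matrix(rep(seq_len(h), times = w), nrow = h)
    dxa <- X - apex["x"]; dya <- Y - apex["y"]
    dist_apex <- sqrt(dxa^2 + dya^2)
    ang <- atan2(dxa, dya)  # 0 points straight down
    sector <- dya >= 0 & dist_apex <= fan_r & abs(ang) <= fan_half

    cy <- apex["y"] + 0.55 * fan_r
    cx <- apex["x"]
    D <- sqrt((X - cx)^2 + (Y - cy)^2)

    r_ed <- params$r_ed
    r_es <- r_ed * (1 - params$fractional_shortening)
    phase <- (frame_times %% eg$period) / eg$period
    radius <- r_ed - (r_ed - r_es) * contraction_pulse(phase)

    ann <- matrix(FALSE, h, w)
    if (params$annotations) {
      ann[3:10, 3:70] <- TRUE            # static text / scale block (top-left)
      ann[(h - 14):(h - 4), ] <- TRUE    # ECG strip band (bottom)
    }
    text_px <- matrix(FALSE, h, w)
    if (params$annotations) {
      blk <- outer(seq(3, 10) %% 4 < 2, seq(3, 70) %% 5 < 3, "&")
      text_px[3:10, 3:70] <- blk
    }

    pap_ang <- c(-0.9, 0.9)  # radians from the downward beam axis
    shape <- if (params$speckle_scale > 0) 1 / params$speckle_scale^2 else Inf

    frames <- vector("list", n_frames)
    intensity <- vector("list", n_frames)
    for (k in seq_len(n_frames)) {
      r_k <- radius[k]
      img <- matrix(0, h, w)
      img[sector] <- 110
      img[sector & D < r_k + params$wall_thickness] <- 200
      img[sector & D < r_k] <- 25
      for (a in pap_ang) {
        px <- cx + r_k * sin(a); py <- cy + r_k * cos(a)
        bump <- (X - px)^2 + (Y - py)^2 <= params$papillary_amp^2
        img[bump & sector] <- 190
      }
      if (params$speckle_scale > 0) {
        g <- matrix(1, h, w)
        g[sector] <- stats::rgamma(sum(sector), shape = shape, rate = shape)
        img <- img * g
      }
      if (params$annotations) {
        img[text_px] <- 255
        # ECG strip: static trace plus a per-frame sweep cursor
        strip_base <- h - 6
        cols <- seq_len(w)
        tt <- (cols - 1) / (w - 1) * eg$duration
        amp <- stats::approx(ecg_times(eg$ecg), eg$ecg$samples, xout = tt, rule = 2)$y
        rows <- pmin(h - 4, pmax(h - 14, round(strip_base - amp * 7)))
        img[(h - 14):(h - 4), ] <- 10
        img[cbind(rows, cols)] <- 230
        cur <- min(w, 1 + round(frame_times[k] / eg$duration * (w - 1)))
        img[(h - 14):(h - 4), cur] <- 255
      }
      img <- clamp8(img)
      intensity[[k]] <- img
      if (params$colorize == "sepia") {
        frames[[k]] <- array(c(img, 0.80 * img, 0.55 * img), dim = c(h, w, 3))
      } else {
        frames[[k]] <- img
      }
    }

    clip <- cine_clip(frames, frame_times, ecg = eg$ecg,
                      color_space = if (params$colorize == "sepia") "sepia" else "grayscale",
                      patient_id = patient_id, study_id = study_id,
                      clip_id = clip_id, view_tag = view_tag)
    truth <- list(r_peak_times = eg$r_times, sector = sector,
                  annotation_pixels = ann, radius_px = radius,
                  fractional_shortening = params$fractional_shortening,
                  intensity = intensity, params = params)
    list(clip = clip, truth = truth)
  })
}

#' Generate a synthetic survivor cohort with clips, CSV tables, and truth
#'
#' Builds a full, self-consistent test bed: per-patient clinical tables that
#' the cohort-labeling rules classify exactly as intended, and one phantom
#' clip per echo study. Case patients' diagnostic (qualifying) echoes record
#' SF in the case band (15-28%); their rendered clips always carry low
#' fractional shortening, including pre-diagnosis studies, encoding the
#' premise that the imaging signature precedes the measured SF decline.
#' Non-case studies record and render SF in 32-45%. The deliberate 28/32 gap
#' keeps labels unambiguous.
#'
#' @param n_patients Number of patients (>= 4).
#' @param case_fraction Fraction of patients that are cardiomyopathy cases,
#'   in (0, 1).
#' @param echoes_per_patient Length-2 integer range; echo studies per patient
#'   are drawn uniformly from it. With >= 4 echoes per case, every case has
#'   at least one echo in each of the four timing subsets.
#' @param seed Integer seed.
#' @param clip_params Named list of overrides passed to [phantom_params()]
#'   for every clip (e.g. smaller `image_dims` for fast tests).
#' @param generate_clips Set `FALSE` to produce only tables and truth.
#' @param write_dir Optional directory; when given, writes `patients.csv`,
#'   `exposures.csv`, `echoes.csv`, `truth.csv`, and DICOM clips under
#'   `clips/`.
#' @return List with `patients`, `exposures`, `echoes`, `truth` data frames
#'   and `clips` (named list of [cine_clip()] by study id, or `NULL`).
#' @export
generate_phantom_cohort <- function(n_patients, case_fraction = 0.4,
                                    echoes_per_patient = c(2, 5), seed = 1,
                                    clip_params = list(), generate_clips = TRUE,
                                    write_dir = NULL) {
  if (n_patients < 4) em_stop("em_config_error", "need n_patients >= 4")
  if (case_fraction <= 0 || case_fraction >= 1)
    em_stop("em_config_error", "case_fraction must be in (0, 1)")
  if (length(echoes_per_patient) != 2 || echoes_per_patient[1] > echoes_per_patient[2] ||
      echoes_per_patient[1] < 1)
    em_stop("em_config_error", "echoes_per_patient must be a valid range c(lo, hi)")
  with_seed(seed, {
    n_cases <- max(1, round(n_patients * case_fraction))
    is_case <- c(rep(TRUE, n_cases), rep(FALSE, n_patients - n_cases))
    pid <- sprintf("P%04d", seq_len(n_patients))

    patients <- data.frame(
      patient_id = pid,
      cancer_dx_date = as.Date("2006-01-01") + sample(0:2500, n_patients, TRUE),
      chest_rt = stats::runif(n_patients) < 0.42,
      stringsAsFactors = FALSE
    )
    patients$therapy_end_date <- patients$cancer_dx_date + 365
    patients$hf_therapy_start_date <- as.Date(NA)
    patients$excluded_flag <- FALSE

    exposures <- list(); echoes <- list(); truth <- list()
    for (i in seq_len(n_patients)) {
      dox <- if (is_case[i]) stats::rnorm(1, 300, 70) else stats::rnorm(1, 200, 60)
      exposures[[length(exposures) + 1]] <- data.frame(
        patient_id = pid[i], agent = "doxorubicin",
        dose_mg_m2 = round(min(500, max(80, dox)), 1))
      if (stats::runif(1) < 0.3)
        exposures[[length(exposures) + 1]] <- data.frame(
          patient_id = pid[i], agent = "daunorubicin",
          dose_mg_m2 = round(stats::runif(1, 60, 150), 1))

      m <- sample(seq(echoes_per_patient[1], echoes_per_patient[2]), 1)
      if (is_case[i]) {
        # index (first qualifying) echo well past therapy end; earlier echoes
        # pre-diagnosis, spread to populate the four timing subsets
        index_date <- patients$therapy_end_date[i] + sample(900:2000, 1)
        # pre-diagnosis echoes fill the timing subsets first (>= 4 echoes
        # populate all four); a confirmatory qualifying echo after the index
        # comes fifth, so smaller case records use the HF-therapy pathway
        deltas <- 0
        if (m >= 2) deltas <- c(deltas, sample(180:364, 1))
        if (m >= 3) deltas <- c(deltas, sample(365:729, 1))
        if (m >= 4) deltas <- c(deltas, sample(730:1100, 1))
        if (m >= 5) deltas <- c(deltas, -60)
        if (m > 5) deltas <- c(deltas, sample(31:1100, m - 5))
        qualifying <- deltas <= 0
        sf <- ifelse(qualifying, stats::runif(m, 15, 28), stats::runif(m, 31, 45))
        if (sum(qualifying) < 2) patients$hf_therapy_start_date[i] <- index_date + 30
        dates <- index_date - deltas
        fs_true <- stats::runif(m, 0.15, 0.28)  # imaging signature on all case clips
      } else {
        first <- patients$therapy_end_date[i] + sample(30:365, 1)
        dates <- sort(first + c(0, cumsum(sample(180:540, m, TRUE)))[seq_len(m)])
        sf <- stats::runif(m, 32, 45)
        fs_true <- sf / 100
        deltas <- rep(NA_real_, m)
      }
      ord <- order(dates)
      for (j in seq_len(m)) {
        k <- ord[j]
        sid <- sprintf("%s-S%02d", pid[i], j)
        echoes[[length(echoes) + 1]] <- data.frame(
          patient_id = pid[i], study_id = sid, echo_date = dates[k],
          sf_pct = round(sf[k], 1), ef_pct = NA_real_,
          qualitative_concern = FALSE, stringsAsFactors = FALSE)
        truth[[length(truth) + 1]] <- data.frame(
          patient_id = pid[i], study_id = sid, echo_date = dates[k],
          fs_true = fs_true[k],
          intended_label = if (is_case[i]) "CASE" else "NON_CASE",
          clip_seed = sample.int(2^31 - 2, 1), stringsAsFactors = FALSE)
      }
    }
    exposures <- do.call(rbind, exposures)
    echoes <- do.call(rbind, echoes)
    truth <- do.call(rbind, truth)

    clips <- NULL
    if (generate_clips) {
      clips <- vector("list", nrow(truth))
      names(clips) <- truth$study_id
      for (k in seq_len(nrow(truth))) {
        cp <- utils::modifyList(
          list(fractional_shortening = truth$fs_true[k],
               heart_rate = sample(60:110, 1), seed = truth$clip_seed[k]),
          clip_params)
        ph <- generate_phantom_clip(do.call(phantom_params, cp),
                                    patient_id = truth$patient_id[k],
                                    study_id = truth$study_id[k],
                                    clip_id = paste0(truth$study_id[k], "-C1"))
        clips[[k]] <- ph$clip
      }
    }

    out <- list(patients = patients, exposures = exposures, echoes = echoes,
                truth = truth, clips = clips, seed = seed)
    if (!is.null(write_dir)) {
      dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(patients, file.path(write_dir, "patients.csv"), row.names = FALSE)
      utils::write.csv(exposures, file.path(write_dir, "exposures.csv"), row.names = FALSE)
      utils::write.csv(echoes, file.path(write_dir, "echoes.csv"), row.names = FALSE)
      utils::write.csv(truth, file.path(write_dir, "truth.csv"), row.names = FALSE)
      if (!is.null(clips)) {
        dir.create(file.path(write_dir, "clips"), showWarnings = FALSE)
        for (sid in names(clips))
          write_dicom_clip(clips[[sid]], file.path(write_dir, "clips", paste0(sid, ".dcm")))
      }
    }
    out
  })
}
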