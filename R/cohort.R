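# Clinical labeling rules: case/non-case classification from serial SF/EF
# measurements, timing-based case subsets, and anthracycline dose conversion.

DOX_FACTORS <- c(doxorubicin = 1.0, daunorubicin = 0.5, idarubicin = 3.0,
                 epirubicin = 0.67, mitoxantrone = 10.0)

#' Doxorubicin-equivalent cumulative anthracycline/anthraquinone dose
#'
#' Sums agent doses weighted by the standard conversion factors:
#' doxorubicin 1.0, daunorubicin 0.5, idarubicin 3.0, epirubicin 0.67,
#' mitoxantrone 10.0.
#'
#' @param exposures A data.frame with columns `agent` and `dose_mg_m2`, or a
#'   named numeric vector of doses by agent.
#' @return Total dose in mg/m2 doxorubicin equivalents.
#' @export
doxorubicin_equivalent_dose <- function(exposures) {
  if (is.numeric(exposures)) {
    exposures <- data.frame(agent = names(exposures) %||% character(0),
                            dose_mg_m2 = as.numeric(exposures))
  }
  if (nrow(exposures) == 0L) return(0)
  agent <- tolower(exposures$agent)
  unknown <- setdiff(unique(agent), names(DOX_FACTORS))
  if (length(unknown))
    em_stop("em_unknown_agent_error", "unknown agent(s): %s", paste(unknown, collapse = ", "))
  if (any(exposures$dose_mg_m2 < 0))
    em_stop("em_input_error", "doses must be non-negative")
  sum(exposures$dose_mg_m2 * DOX_FACTORS[agent])
}

sf_qualifies <- function(sf, ef) {
  (!is.na(sf) & sf <= 28) | (!is.na(ef) & ef <= 50)
}

#' Classify a survivor as case, non-case, or indeterminate
#'
#' A survivor is a cardiomyopathy CASE with SF <= 28% or EF <= 50% on at
#' least two echocardiograms, at least one of them after completion of
#' cancer therapy — or with those criteria met once if chronic heart-failure
#' therapy was subsequently started. The cardiomyopathy index date is the
#' date of the earliest qualifying echo. A NON_CASE has SF >= 30% and
#' EF >= 55% (where measured) on every echo and no qualitative concern.
#' Survivors matching neither definition (e.g. a single SF of 29%) are
#' INDETERMINATE and excluded from modeling.
#'
#' @param rec A survivor record: list/data.frame with `therapy_end_date`,
#'   optional `hf_therapy_start_date`, and `echoes` (data.frame with
#'   `echo_date`, `sf_pct`, `ef_pct`, `qualitative_concern`).
#' @return List with `label` (`"CASE"`, `"NON_CASE"`, `"INDETERMINATE"`) and
#'   `cm_dx_date` (Date, `NA` unless CASE).
#' @export
classify_survivor <- function(rec) {
  e <- rec$echoes
  if (is.null(e) || nrow(e) == 0L || all(is.na(e$sf_pct) & is.na(e$ef_pct)))
    em_stop("em_input_error", "survivor has no echo with SF or EF measured")
  e <- e[order(as.Date(e$echo_date)), , drop = FALSE]
  q <- sf_qualifies(e$sf_pct, e$ef_pct)
  post <- as.Date(e$echo_date) > as.Date(rec$therapy_end_date)
  hf <- !is.null(rec$hf_therapy_start_date) && !is.na(rec$hf_therapy_start_date)
  # HF-therapy path: criteria met on exactly one occasion, therapy started
  # any time on/after that echo
  hf_path <- sum(q) == 1 && hf &&
    as.Date(rec$hf_therapy_start_date) >= as.Date(e$echo_date[which(q)[1]])

  is_case <- (sum(q) >= 2 && any(q & post)) || hf_path
  if (is_case) {
    return(list(label = "CASE", cm_dx_date = as.Date(e$echo_date[which(q)[1]])))
  }
  sf_ok <- is.na(e$sf_pct) | e$sf_pct >= 30
  ef_ok <- is.na(e$ef_pct) | e$ef_pct >= 55
  concern <- isTRUE(any(e$qualitative_concern))
  if (all(sf_ok) && all(ef_ok) && !concern)
    return(list(label = "NON_CASE", cm_dx_date = as.Date(NA)))
  list(label = "INDETERMINATE", cm_dx_date = as.Date(NA))
}

#' Classify every patient in a cohort
#'
#' @param cohort List with `patients` and `echoes` data frames (the layout
#'   written by [generate_phantom_cohort()] / read by [read_cohort()]).
#' @return Data.frame with `patient_id`, `label`, `cm_dx_date`.
#' @export
classify_cohort <- function(cohort) {
  out <- lapply(seq_len(nrow(cohort$patients)), function(i) {
    p <- cohort$patients[i, ]
    rec <- list(therapy_end_date = p$therapy_end_date,
                hf_therapy_start_date = p$hf_therapy_start_date,
                echoes = cohort$echoes[cohort$echoes$patient_id == p$patient_id, ])
    cl <- classify_survivor(rec)
    data.frame(patient_id = p$patient_id, label = cl$label,
               cm_dx_date = cl$cm_dx_date, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

CASE_SUBSETS <- c("AT_DX_AND_PRE", "PRE_ONLY", "GE_1Y_PRE", "GE_2Y_PRE")

#' Filter a montage registry by case-echo timing subset
#'
#' Case montages are kept by the lead time `delta = cm_dx_date - echo_date`
#' (days): `AT_DX_AND_PRE` keeps `delta >= 0`; `PRE_ONLY` keeps
#' `delta > at_dx_days` (the at-diagnosis window, 0 by default, commonly set
#' to 30); `GE_1Y_PRE` keeps `delta >= 365`; `GE_2Y_PRE` keeps
#' `delta >= 730` (inclusive boundaries). Non-case montages are always
#' retained. The four subsets are nested for case montages.
#'
#' @param registry Montage registry data.frame with `label`, `echo_date`,
#'   and `cm_dx_date` columns (see [register_montage()]).
#' @param subset One of `"AT_DX_AND_PRE"`, `"PRE_ONLY"`, `"GE_1Y_PRE"`,
#'   `"GE_2Y_PRE"`.
#' @param at_dx_days Width of the at-diagnosis window in days.
#' @return The filtered registry.
#' @export
select_case_subset <- function(registry, subset = CASE_SUBSETS, at_dx_days = 0) {
  subset <- match.arg(subset)
  is_case <- registry$label == "CASE"
  if (any(is_case & is.na(registry$cm_dx_date)))
    em_stop("em_integrity_error", "case montage without cm_dx_date in registry")
  delta <- as.numeric(as.Date(registry$cm_dx_date) - as.Date(registry$echo_date))
  keep <- switch(subset,
    AT_DX_AND_PRE = delta >= 0,
    PRE_ONLY = delta > at_dx_days,
    GE_1Y_PRE = delta >= 365,
    GE_2Y_PRE = delta >= 730)
  registry[!is_case | (is_case & keep), , drop = FALSE]
}

#' Read cohort CSV tables
#'
#' Expects `patients.csv` (patient_id, cancer_dx_date, therapy_end_date,
#' chest_rt, hf_therapy_start_date, excluded_flag), `exposures.csv`
#' (patient_id, agent, dose_mg_m2), and `echoes.csv` (patient_id, study_id,
#' echo_date, sf_pct, ef_pct, qualitative_concern), with ISO-8601 dates.
#'
#' @param dir Directory containing the three CSVs.
#' @return List with `patients`, `exposures`, `echoes` data frames.
#' @export
read_cohort <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  patients <- rd("patients.csv")
  for (col in c("cancer_dx_date", "therapy_end_date", "hf_therapy_start_date"))
    patients[[col]] <- as.Date(patients[[col]])
  echoes <- rd("echoes.csv")
  echoes$echo_date <- as.Date(echoes$echo_date)
  list(patients = patients, exposures = rd("exposures.csv"), echoes = echoes)
}
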