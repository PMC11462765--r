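mk_rec <- function(sf, dates, therapy_end = as.Date("2010-01-01"),
                   ef = rep(NA_real_, length(sf)), hf = as.Date(NA),
                   concern = rep(FALSE, length(sf))) {
  list(therapy_end_date = therapy_end, hf_therapy_start_date = hf,
       echoes = data.frame(echo_date = as.Date(dates), sf_pct = sf, ef_pct = ef,
                           qualitative_concern = concern))
}

test_that("case classification follows the two-echo rule", {
  # two qualifying echoes after therapy completion
  r <- classify_survivor(mk_rec(c(27, 26), c("2012-01-01", "2012-06-01")))
  expect_equal(r$label, "CASE")
  expect_equal(r$cm_dx_date, as.Date("2012-01-01"))

  # qualifying by EF alone
  r <- classify_survivor(mk_rec(c(35, 33), c("2012-01-01", "2012-06-01"),
                                ef = c(48, 50)))
  expect_equal(r$label, "CASE")

  # two qualifying echoes but none post-therapy: not a case, not a non-case
  r <- classify_survivor(mk_rec(c(27, 26), c("2008-01-01", "2009-06-01")))
  expect_equal(r$label, "INDETERMINATE")
})

test_that("one qualifying echo plus subsequent HF therapy is a case", {
  r <- classify_survivor(mk_rec(27, "2012-01-01", hf = as.Date("2012-03-01")))
  expect_equal(r$label, "CASE")
  expect_equal(r$cm_dx_date, as.Date("2012-01-01"))

  # HF therapy predating the qualifying echo does not count
  r <- classify_survivor(mk_rec(27, "2012-01-01", hf = as.Date("2011-01-01")))
  expect_equal(r$label, "INDETERMINATE")

  # one qualifying echo, no HF therapy
  r <- classify_survivor(mk_rec(27, "2012-01-01"))
  expect_equal(r$label, "INDETERMINATE")
})

test_that("non-case requires normal function and no qualitative concern", {
  r <- classify_survivor(mk_rec(c(35, 33), c("2012-01-01", "2012-06-01"),
                                ef = c(60, 58)))
  expect_equal(r$label, "NON_CASE")
  expect_true(is.na(r$cm_dx_date))

  # SF 29 sits in the indeterminate band (28 < 29 < 30)
  expect_equal(classify_survivor(mk_rec(29, "2012-01-01"))$label, "INDETERMINATE")

  r <- classify_survivor(mk_rec(c(35, 33), c("2012-01-01", "2012-06-01"),
                                concern = c(FALSE, TRUE)))
  expect_equal(r$label, "INDETERMINATE")

  expect_error(classify_survivor(mk_rec(NA_real_, "2012-01-01")),
               class = "em_input_error")
})

test_that("phantom cohort labels are recovered exactly", {
  co <- generate_phantom_cohort(40, 0.4, echoes_per_patient = c(1, 6), seed = 1,
                                generate_clips = FALSE)
  cl <- classify_cohort(co)
  intended <- unique(co$truth[, c("patient_id", "intended_label")])
  merged <- merge(cl, intended)
  expect_equal(nrow(merged), 40)
  expect_true(all(merged$label == merged$intended_label))
})

toy_registry <- function(deltas = c(0, 180, 545, 912)) {
  cm <- as.Date("2015-01-01")
  rbind(
    data.frame(patient_id = "P1", study_id = paste0("S", seq_along(deltas)),
               clip_id = NA, montage_type = 1L, echo_date = cm - deltas,
               label = "CASE", cm_dx_date = cm),
    data.frame(patient_id = "P2", study_id = c("T1", "T2"), clip_id = NA,
               montage_type = 1L, echo_date = as.Date(c("2014-01-01", "2015-06-01")),
               label = "NON_CASE", cm_dx_date = as.Date(NA))
  )
}

test_that("timing subsets keep the documented case echoes", {
  reg <- toy_registry()
  sizes <- vapply(c("AT_DX_AND_PRE", "PRE_ONLY", "GE_1Y_PRE", "GE_2Y_PRE"),
                  function(s) sum(select_case_subset(reg, s)$label == "CASE"), 1)
  expect_equal(unname(sizes), c(4, 3, 2, 1))
  # non-case montages present in all four subsets, unchanged
  for (s in c("AT_DX_AND_PRE", "PRE_ONLY", "GE_1Y_PRE", "GE_2Y_PRE"))
    expect_equal(sum(select_case_subset(reg, s)$label == "NON_CASE"), 2)

  # inclusive year boundary
  reg365 <- toy_registry(deltas = 365)
  expect_equal(sum(select_case_subset(reg365, "GE_1Y_PRE")$label == "CASE"), 1)

  # configurable at-diagnosis window
  reg20 <- toy_registry(deltas = c(0, 20, 200))
  expect_equal(sum(select_case_subset(reg20, "PRE_ONLY")$label == "CASE"), 2)
  expect_equal(sum(select_case_subset(reg20, "PRE_ONLY", at_dx_days = 30)$label == "CASE"), 1)

  bad <- toy_registry(); bad$cm_dx_date[1] <- NA
  expect_error(select_case_subset(bad, "PRE_ONLY"), class = "em_integrity_error")
})

test_that("subset registries are nested on the phantom cohort", {
  co <- generate_phantom_cohort(30, 0.5, echoes_per_patient = c(4, 6), seed = 3,
                                generate_clips = FALSE)
  cl <- classify_cohort(co)
  reg <- merge(co$echoes[, c("patient_id", "study_id", "echo_date")], cl)
  reg$montage_type <- 1L; reg$clip_id <- NA
  prev <- NULL
  for (s in c("AT_DX_AND_PRE", "PRE_ONLY", "GE_1Y_PRE", "GE_2Y_PRE")) {
    cur <- select_case_subset(reg, s)
    cur_cases <- cur$study_id[cur$label == "CASE"]
    if (!is.null(prev)) expect_true(all(cur_cases %in% prev))
    prev <- cur_cases
  }
  # every case patient with >= 4 echoes appears in every subset
  counts <- table(co$echoes$patient_id)
  deep <- select_case_subset(reg, "GE_2Y_PRE")
  cases <- unique(reg$patient_id[reg$label == "CASE"])
  for (p in cases[counts[cases] >= 4])
    expect_true(p %in% deep$patient_id)
})

test_that("doxorubicin-equivalent doses use the standard factors", {
  ex <- function(agent, dose) data.frame(agent = agent, dose_mg_m2 = dose)
  expect_equal(doxorubicin_equivalent_dose(ex(c("doxorubicin", "daunorubicin"),
                                              c(100, 100))), 150)
  expect_equal(doxorubicin_equivalent_dose(ex("mitoxantrone", 40)), 400)
  expect_equal(doxorubicin_equivalent_dose(ex(c("idarubicin", "epirubicin"),
                                              c(10, 100))), 97)
  expect_equal(doxorubicin_equivalent_dose(ex(character(0), numeric(0))), 0)
  expect_error(doxorubicin_equivalent_dose(ex("cisplatin", 50)),
               class = "em_unknown_agent_error")
  expect_error(doxorubicin_equivalent_dose(ex("doxorubicin", -5)),
               class = "em_input_error")
})

test_that("cohort CSV round trip preserves tables and dates", {
  co <- generate_phantom_cohort(8, 0.5, echoes_per_patient = c(1, 3), seed = 5,
                                generate_clips = FALSE,
                                write_dir = withr::local_tempdir())
  dir <- withr::local_tempdir()
  co2 <- generate_phantom_cohort(8, 0.5, echoes_per_patient = c(1, 3), seed = 5,
                                 generate_clips = FALSE, write_dir = dir)
  back <- read_cohort(dir)
  expect_equal(back$patients$patient_id, co$patients$patient_id)
  expect_equal(back$patients$therapy_end_date, co$patients$therapy_end_date)
  expect_equal(back$echoes$sf_pct, co$echoes$sf_pct)
  expect_identical(class(back$echoes$echo_date), "Date")
})
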