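# Builds a small labeled registry in code: P1 enrolled twice, P2 opt-out,
# P3 never approached, P4 enrolled late in the window.
window_fixture <- function() {
  dem <- make_demographics(paste0("P", 1:4))
  epi <- make_episodes(
    episode_id = paste0("E", 1:5),
    patient_id = c("P1", "P1", "P2", "P3", "P4"),
    eligibility = c("2011-04-01", "2013-01-01", "2011-04-01", "2011-04-01",
                    "2011-04-01"),
    start = c("2011-04-11", "2013-01-15", "2011-04-05", NA, "2011-05-01"),
    end = c("2011-07-30", "2013-06-01", "2011-05-01", "2011-10-01",
            "2012-06-01"))
  ct <- make_contacts(c("P1", "P1", "P4"),
                      c("2011-05-01", "2013-02-01", "2011-06-01"),
                      c(30, 30, 30))
  q <- make_phq9(paste0("P", 1:4), rep("2011-04-01", 4), rep(14, 4))
  b <- registry_bundle(dem, epi, ct, q)
  labels <- classify_all(b)
  list(bundle = b, labels = labels)
}

test_that("the mean eligibility-to-enrollment lag is the arithmetic mean in days", {
  fx <- window_fixture()
  # enrolled episodes: E1 (lag 10), E2 (lag 14), E5 (lag 30)
  expect_equal(mean_eligibility_to_enrollment_lag(fx$labels,
                                                  fx$bundle$episodes),
               (10 + 14 + 30) / 3)

  two <- make_episodes(c("E1", "E2"), c("P1", "P2"),
                       c("2010-01-01", "2010-01-01"),
                       c("2010-01-11", "2010-01-21"),
                       c("2010-06-01", "2010-06-01"))
  ct <- make_contacts(c("P1", "P2"), c("2010-02-01", "2010-02-01"), c(9, 9))
  b <- registry_bundle(make_demographics(c("P1", "P2")), two, ct,
                       empty_phq9())
  lb <- classify_all(b)
  expect_equal(mean_eligibility_to_enrollment_lag(lb, b$episodes), 15.0)

  b0 <- registry_bundle(
    make_demographics("P1"),
    make_episodes("E1", "P1", "2010-01-01", "2010-01-01", "2010-06-01"),
    make_contacts("P1", "2010-02-01", 9), empty_phq9())
  zero <- classify_all(b0)
  expect_equal(mean_eligibility_to_enrollment_lag(zero, b0$episodes), 0.0)

  # undefined without enrolled episodes
  opt <- window_fixture()
  opt$labels$labels <- opt$labels$labels[
    opt$labels$labels$status != "enrolled", ]
  expect_error(mean_eligibility_to_enrollment_lag(opt$labels,
                                                  opt$bundle$episodes),
               "undefined")
})

test_that("index strategies anchor patients as documented", {
  fx <- window_fixture()
  epi <- fx$bundle$episodes

  idx1 <- assign_index_dates(fx$labels, epi, "first_eligibility")
  # P1 has eligibility dates 2011-04-01 and 2013-01-01: earliest wins for
  # every arm under the common-index special case
  expect_equal(idx1$index_date[idx1$patient_id == "P1"],
               as.Date("2011-04-01"))
  expect_true(all(idx1$index_date == as.Date("2011-04-01")))

  idx2 <- assign_index_dates(fx$labels, epi, "enrollment_linked")
  expect_equal(idx2$index_date[idx2$patient_id == "P1"],
               as.Date("2011-04-11"))  # start of first enrolled episode
  expect_equal(idx2$arm[idx2$patient_id == "P2"], "comparison")
  expect_equal(idx2$index_date[idx2$patient_id == "P2"],
               as.Date("2011-04-01"))

  # shifted eligibility: comparison index = eligibility + rounded mean lag
  lag <- round(mean_eligibility_to_enrollment_lag(fx$labels, epi))
  idx3 <- assign_index_dates(fx$labels, epi, "shifted_eligibility")
  expect_equal(idx3$index_date[idx3$patient_id == "P2"],
               as.Date("2011-04-01") + lag)
  expect_equal(idx3$index_date[idx3$patient_id == "P1"],
               as.Date("2011-04-11"))

  # hand-checked: mean lag 14 on a two-episode fixture shifts 2012-01-01
  # to 2012-01-15
  two <- make_episodes(c("E1", "E2"), c("P1", "P2"),
                       c("2011-01-01", "2012-01-01"),
                       c("2011-01-15", NA),
                       c("2011-06-01", "2012-06-01"))
  ct <- make_contacts("P1", "2011-02-01", 30)
  b <- registry_bundle(make_demographics(c("P1", "P2")), two, ct,
                       empty_phq9())
  lb <- classify_all(b)
  # P2 recovered? no contacts, stays not_approached (comparison arm)
  idx <- assign_index_dates(lb, b$episodes, "shifted_eligibility")
  expect_equal(idx$index_date[idx$patient_id == "P2"],
               as.Date("2012-01-15"))
})

test_that("window cohorts classify completed, incomplete, opt-out and not-approached", {
  fx <- window_fixture()
  idx <- assign_index_dates(fx$labels, fx$bundle$episodes,
                            "first_eligibility")
  coh <- build_cross_sectional_cohorts(fx$labels, fx$bundle$episodes, idx,
                                       window_days = 183)
  got <- setNames(as.character(coh$cohort), coh$patient_id)
  # P1: first enrolled episode starts day 10, ends day 120 < 183: completed
  expect_equal(got[["P1"]], "completed_enrollment_6m")
  # P4: starts day 30, ends day 427 >= 183: incomplete
  expect_equal(got[["P4"]], "incomplete_enrollment_6m")
  expect_equal(got[["P2"]], "opt_out_6m")
  expect_equal(got[["P3"]], "not_approached_6m")
  # exactly one cohort per patient
  expect_equal(anyDuplicated(coh$patient_id), 0L)
})

test_that("enlarging the window can only promote incomplete to completed", {
  for (seed in 1:10) {
    synth <- generate_registry(registry_config(n_episodes = 40), seed = 300 + seed)
    cleaned <- clean_missing(synth$bundle)$bundle
    labels <- classify_all(cleaned)
    idx <- assign_index_dates(labels, cleaned$episodes, "first_eligibility")
    small <- build_cross_sectional_cohorts(labels, cleaned$episodes, idx,
                                           window_days = 183)
    large <- build_cross_sectional_cohorts(labels, cleaned$episodes, idx,
                                           window_days = 366)
    both <- merge(small, large, by = "patient_id")
    demoted <- both$cohort.x == "completed_enrollment_6m" &
      both$cohort.y == "incomplete_enrollment_6m"
    expect_false(any(demoted))
  }
})

test_that("window-cohort assignment agrees with the brute-force enumerator", {
  for (seed in 1:15) {
    synth <- generate_registry(registry_config(n_episodes = 30), seed = 400 + seed)
    cleaned <- clean_missing(synth$bundle)$bundle
    labels <- classify_all(cleaned)
    idx <- assign_index_dates(labels, cleaned$episodes, "first_eligibility")
    coh <- build_cross_sectional_cohorts(labels, cleaned$episodes, idx)
    expect_equal(as.character(coh$cohort),
                 bf_window_cohorts(labels, cleaned$episodes, idx))
  }
})

test_that("window record extraction uses half-open intervals around the index", {
  dem <- make_demographics("P1")
  epi <- make_episodes("E1", "P1", "2011-04-01", "2011-04-01", "2012-06-01")
  ct <- make_contacts(rep("P1", 3),
                      c("2011-03-31", "2011-04-01", "2011-09-30"),
                      c(10, 20, 30))
  b <- registry_bundle(dem, epi, ct, empty_phq9())
  lb <- classify_all(b)
  idx <- assign_index_dates(lb, b$episodes, "first_eligibility")
  sl <- extract_window_records(b, idx, observation_days = 183,
                               outcome_days = 183)
  p1 <- sl[["P1"]]
  # contact exactly at the index date lands in the outcome window
  expect_equal(p1$observation$contacts$contact_date, as.Date("2011-03-31"))
  expect_setequal(format(p1$outcome$contacts$contact_date),
                  c("2011-04-01", "2011-09-30"))
  # zero-length outcome window is empty
  sl0 <- extract_window_records(b, idx, outcome_days = 0)
  expect_equal(nrow(sl0[["P1"]]$outcome$contacts), 0L)
})
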