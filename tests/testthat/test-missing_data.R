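test_that("episode metrics implement the derived-variable definitions", {
  b <- clinic_fixture()
  m <- episode_metrics(b)
  rownames(m) <- m$episode_id

  # activation time = end - start in days; 0 is legal (same-day episodes)
  expect_equal(m["E5", "activation_time_days"], 90L)
  epi0 <- make_episodes("E1", "P1", "2010-05-01", "2010-05-01", "2010-05-01")
  b0 <- registry_bundle(make_demographics("P1"), epi0, empty_contacts(),
                        empty_phq9())
  expect_equal(episode_metrics(b0)$activation_time_days, 0L)

  # missing start: eligibility time defined instead; contact metrics from
  # attributable dated contacts only
  epi1 <- make_episodes("E1", "P1", "2010-01-01", NA, "2010-04-01")
  ct1 <- make_contacts(c("P1", "P1"), c("2010-02-01", "2010-03-01"),
                       c(30, 15))
  b1 <- registry_bundle(make_demographics("P1"), epi1, ct1, empty_phq9())
  m1 <- episode_metrics(b1)
  expect_equal(m1$eligibility_time_days, 90L)
  expect_true(is.na(m1$activation_time_days))
  expect_equal(m1$contact_frequency, 2L)
  expect_equal(m1$total_time_spent_min, 45)

  # single-episode wrapper agrees
  single <- compute_episode_metrics(b$episodes[b$episodes$episode_id == "E5", ],
                                    b)
  expect_equal(single$activation_time_days, 90L)

  # an undropped missing end date is an upstream ordering error
  epi_bad <- make_episodes("E1", "P1", "2010-01-01", "2010-01-05", NA)
  b_bad <- registry_bundle(make_demographics("P1"), epi_bad,
                           empty_contacts(), empty_phq9())
  expect_error(episode_metrics(b_bad), "drop_incomplete_episodes")
})

test_that("complete-case drop removes exactly the start-without-end episodes", {
  epi <- make_episodes(paste0("E", 1:3), rep("P1", 3),
                       c("2010-01-01", "2011-01-01", "2012-01-01"),
                       c("2010-01-05", "2011-01-05", NA),
                       c("2010-06-01", NA, "2012-06-01"))
  b <- registry_bundle(make_demographics("P1"), epi, empty_contacts(),
                       empty_phq9())
  res <- drop_incomplete_episodes(b)
  expect_equal(nrow(res$bundle$episodes), 2L)
  expect_equal(res$report$dropped, 1L)
  expect_equal(res$report$dropped_keys, "E2")

  # identity transform when nothing is missing
  res2 <- drop_incomplete_episodes(res$bundle)
  expect_equal(res2$report$dropped, 0L)
  expect_equal(res2$bundle$episodes, res$bundle$episodes)
})

test_that("planted missing-end instances are exactly the rows dropped", {
  cfg <- registry_config(n_episodes = 1000, missing_end_rate = 0.005)
  synth <- generate_registry(cfg, seed = 11)
  planted <- synth$truth$episodes$episode_id[synth$truth$episodes$planted_drop]
  expect_length(planted, 5L)
  res <- drop_incomplete_episodes(synth$bundle)
  expect_setequal(res$report$dropped_keys, planted)
  expect_equal(res$report$dropped, 5L)
})

test_that("start-date recovery takes the first in-window contact when eligibility time is positive", {
  epi <- make_episodes("E1", "P1", "2020-01-01", NA, "2020-06-01")
  ct <- make_contacts(c("P1", "P1"), c("2020-02-01", "2020-03-01"), c(10, 10))
  b <- registry_bundle(make_demographics("P1"), epi, ct, empty_phq9())
  res <- recover_start_dates(b)
  expect_equal(res$bundle$episodes$start_date, as.Date("2020-02-01"))
  expect_equal(res$bundle$episodes$start_provenance, "recovered")
  expect_equal(res$report$recovered_ids, "E1")

  # zero eligibility time: the guard forbids recovery
  epi0 <- make_episodes("E1", "P1", "2020-06-01", NA, "2020-06-01")
  ct0 <- make_contacts("P1", "2020-06-01", 10)
  b0 <- registry_bundle(make_demographics("P1"), epi0, ct0, empty_phq9())
  res0 <- recover_start_dates(b0)
  expect_true(is.na(res0$bundle$episodes$start_date))
  expect_equal(res0$report$untouched, 1L)
})

test_that("planted recoverable and unrecoverable episodes separate exactly", {
  # 10 recoverable (positive eligibility time, in-window contacts) and
  # 7 unrecoverable (no contacts, or zero eligibility time)
  rec_elig <- sprintf("2020-%02d-01", 1:10)
  rec_end <- sprintf("2020-%02d-20", 3:12)
  unrec_elig <- c(sprintf("2021-%02d-01", 1:4), sprintf("2021-%02d-05", 5:7))
  unrec_end <- c(sprintf("2021-%02d-25", 1:4), sprintf("2021-%02d-05", 5:7))
  epi <- make_episodes(
    episode_id = sprintf("E%02d", 1:17),
    patient_id = sprintf("P%02d", 1:17),
    eligibility = c(rec_elig, unrec_elig),
    start = rep(NA_character_, 17),
    end = c(rec_end, unrec_end))
  true_start <- as.Date(sprintf("2020-%02d-10", 1:10))
  ct <- make_contacts(
    patient_id = rep(sprintf("P%02d", 1:10), each = 2),
    contact_date = as.character(rbind(format(true_start),
                                      format(true_start + 5))),
    time_spent = rep(15, 20))
  b <- registry_bundle(make_demographics(sprintf("P%02d", 1:17)), epi, ct,
                       empty_phq9())
  res <- recover_start_dates(b)
  expect_setequal(res$report$recovered_ids, sprintf("E%02d", 1:10))
  expect_equal(res$report$untouched, 7L)
  got <- res$bundle$episodes
  rec <- got[got$start_provenance == "recovered", ]
  expect_equal(rec$start_date, true_start)
  expect_true(all(rec$start_date >= rec$eligibility_date &
                    rec$start_date <= rec$end_date))
})

test_that("recovery report partitions the episodes it examined", {
  synth <- generate_registry(registry_config(n_episodes = 400), seed = 5)
  res <- clean_missing(synth$bundle)
  n_missing_start <- sum(is.na(synth$bundle$episodes$start_date) &
                           !is.na(synth$bundle$episodes$end_date))
  expect_equal(res$report$recovered + res$report$untouched, n_missing_start)
  expect_equal(res$report$examined, nrow(synth$bundle$episodes))
  expect_length(intersect(res$report$recovered_ids,
                          res$report$untouched_ids), 0L)
})

test_that("adding an earlier in-window contact never delays the recovered start", {
  base_epi <- make_episodes("E1", "P1", "2020-01-01", NA, "2020-06-01")
  dem <- make_demographics("P1")
  for (k in 1:20) {
    set.seed(k)
    dates <- as.Date("2020-01-02") + sample(0:120, 3)
    ct <- make_contacts(rep("P1", 3), format(dates), rep(10, 3))
    b <- registry_bundle(dem, base_epi, ct, empty_phq9())
    s1 <- recover_start_dates(b)$bundle$episodes$start_date
    earlier <- min(dates) - sample(1:20, 1)
    ct2 <- rbind(ct, data.frame(patient_id = "P1",
                                contact_date = format(earlier),
                                time_spent = 10))
    b2 <- registry_bundle(dem, base_epi, ct2, empty_phq9())
    s2 <- recover_start_dates(b2)$bundle$episodes$start_date
    expect_true(s2 <= s1)
    in_window <- earlier >= as.Date("2020-01-01")
    expect_equal(s2, if (in_window) earlier else s1)
  }
})

test_that("metrics agree with the brute-force re-derivation on small random bundles", {
  for (seed in 1:25) {
    n <- 1 + (seed %% 20)
    synth <- generate_registry(registry_config(n_episodes = n,
                                               missing_end_rate = 0),
                               seed = 100 + seed)
    cleaned <- clean_missing(synth$bundle)$bundle
    m <- episode_metrics(cleaned)
    bf <- bf_metrics(cleaned)
    expect_equal(m$activation_time_days, bf$activation_time_days)
    expect_equal(m$eligibility_time_days, bf$eligibility_time_days)
    expect_equal(m$ce_time_days, bf$ce_time_days)
    expect_equal(m$contact_frequency, bf$contact_frequency)
    expect_equal(m$total_time_spent_min, bf$total_time_spent_min)
  }
})
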