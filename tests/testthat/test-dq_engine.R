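test_that("attribute domain rules flag out-of-range items and normalize free text", {
  q <- make_phq9(c("P1", "P1"), c("2010-01-05", "2010-01-06"), c(12, 9))
  q$item_1[1] <- 4   # outside 0-3
  q$total[1] <- 15   # keep total = sum to isolate the domain rule
  b <- registry_bundle(make_demographics("P1"),
                       make_episodes("E1", "P1", "2010-01-01", "2010-01-10",
                                     "2010-06-01"),
                       empty_contacts(), q)
  res <- check_attribute_domain(b)
  expect_equal(res$violations$rule_id, "phq9_item_domain")
  expect_equal(res$violations$action, "set_missing")
  expect_true(is.na(res$bundle$questionnaires$item_1[1]))
  # boundary value 0 stays silent
  expect_false("Q000002" %in% res$violations$row_id)

  dem <- make_demographics(c("P1", "P2", "P3"))
  dem$employment_status <- c("I am looking for a job", "I am employed",
                             "whatever")
  b2 <- registry_bundle(dem, make_episodes("E1", "P1", "2010-01-01", NA,
                                           "2010-06-01"),
                        empty_contacts(), empty_phq9())
  res2 <- check_attribute_domain(b2)
  v <- res2$violations
  expect_equal(v$action[v$row_id == "P1"], "normalized")
  expect_equal(res2$bundle$demographics$employment_status[1:2],
               c("no", "yes"))
  expect_equal(v$action[v$row_id == "P3"], "set_missing")
  expect_true(is.na(res2$bundle$demographics$employment_status[3]))
})

test_that("relational integrity flags duplicates and orphans, silent on clean data", {
  # duplicate composite key via distinct episode ids
  epi <- make_episodes(c("E1", "E2"), c("P1", "P1"),
                       c("2010-01-01", "2010-01-01"),
                       c("2010-01-05", "2010-01-05"),
                       c("2010-06-01", "2010-07-01"))
  b <- registry_bundle(make_demographics("P1"), epi, empty_contacts(),
                       empty_phq9())
  v <- check_relational_integrity(b)$violations
  expect_equal(v$rule_id, "episode_key_unique")
  expect_equal(v$dimension, "uniqueness")
  expect_equal(v$row_id, "E2")

  ct <- make_contacts("PX", "2010-02-01", 5)
  b2 <- registry_bundle(make_demographics("P1"),
                        make_episodes("E1", "P1", "2010-01-01", NA,
                                      "2010-06-01"), ct, empty_phq9())
  v2 <- check_relational_integrity(b2)$violations
  expect_equal(v2$rule_id, "orphan_child_rows")
  expect_equal(v2$dimension, "consistency")

  expect_equal(nrow(check_relational_integrity(clinic_fixture())$violations),
               0L)
})

test_that("historical rules order birth, start and end dates", {
  dem <- make_demographics("P1", birth_date = "2015-01-01")
  b <- registry_bundle(dem, make_episodes("E1", "P1", "2010-01-01", NA,
                                          "2010-06-01"),
                       empty_contacts(), empty_phq9())
  v <- check_historical_rules(b)$violations
  expect_equal(v$rule_id, "birth_before_events")
  expect_equal(v$row_id, "P1")

  epi <- make_episodes("E1", "P1", "2010-01-01", "2010-06-01", "2010-05-01")
  b2 <- registry_bundle(make_demographics("P1"), epi, empty_contacts(),
                        empty_phq9())
  v2 <- check_historical_rules(b2)$violations
  expect_true("start_before_end" %in% v2$rule_id)

  # same-day start and end is legal: the minimum activation time is 0 days
  epi3 <- make_episodes("E1", "P1", "2010-05-01", "2010-05-01", "2010-05-01")
  b3 <- registry_bundle(make_demographics("P1"), epi3, empty_contacts(),
                        empty_phq9())
  expect_equal(nrow(check_historical_rules(b3)$violations), 0L)

  # a recorded-enrolled episode without any contact has its contact date
  # labeled missing
  epi4 <- make_episodes("E1", "P1", "2010-01-01", "2010-01-05", "2010-06-01",
                        recorded_status = "enrolled")
  b4 <- registry_bundle(make_demographics("P1"), epi4, empty_contacts(),
                        empty_phq9())
  v4 <- check_historical_rules(b4)$violations
  expect_equal(v4$rule_id, "enrolled_has_contact")
  expect_equal(v4$column, "contact_date")
})

test_that("state-dependent rules tie end dates to eligibility and baselines to enrollment", {
  epi <- make_episodes("E1", "P1", NA, "2010-01-05", "2010-06-01")
  b <- registry_bundle(make_demographics("P1"), epi, empty_contacts(),
                       empty_phq9())
  v <- check_state_dependent(b)$violations
  expect_equal(v$rule_id, "end_requires_eligibility")
  expect_equal(v$dimension, "completeness")
  expect_equal(v$column, "eligibility_date")

  # questionnaire exactly on the enrollment date: allowed
  epi2 <- make_episodes("E1", "P1", "2010-01-01", "2010-01-10", "2010-06-01")
  q_on <- make_phq9("P1", "2010-01-10", 12)
  b2 <- registry_bundle(make_demographics("P1"), epi2, empty_contacts(), q_on)
  expect_equal(nrow(check_state_dependent(b2)$violations), 0L)

  # GAD-7 recorded 10 days after enrollment: flagged
  q_late <- make_phq9("P1", "2010-01-20", 12, instrument = "GAD7")
  b3 <- registry_bundle(make_demographics("P1"), epi2, empty_contacts(),
                        q_late)
  v3 <- check_state_dependent(b3)$violations
  expect_equal(v3$rule_id, "baseline_before_enrollment")
})

test_that("attribute dependency enforces total = sum of items with configurable repair", {
  # maximal consistent row and all-zero row: silent
  q <- make_phq9(c("P1", "P1"), c("2010-01-01", "2010-01-02"), c(27, 0),
                 items = rbind(rep(3L, 9), rep(0L, 9)))
  b <- registry_bundle(make_demographics("P1"),
                       make_episodes("E1", "P1", "2010-01-01", NA,
                                     "2010-06-01"),
                       empty_contacts(), q)
  expect_equal(nrow(check_attribute_dependency(b)$violations), 0L)

  # items sum to 13, recorded total 15: flagged and recomputed
  items <- matrix(c(3, 3, 3, 2, 2, 0, 0, 0, 0), nrow = 1)
  q2 <- make_phq9("P1", "2010-01-01", 15, items = items)
  b2 <- registry_bundle(make_demographics("P1"),
                        make_episodes("E1", "P1", "2010-01-01", NA,
                                      "2010-06-01"),
                        empty_contacts(), q2)
  res <- check_attribute_dependency(b2)
  expect_equal(res$violations$action, "normalized")
  expect_equal(res$bundle$questionnaires$total, 13)

  res2 <- check_attribute_dependency(
    b2, default_ruleset(total_repair = "set_missing"))
  expect_equal(res2$violations$action, "set_missing")
  expect_true(is.na(res2$bundle$questionnaires$total))
})

test_that("full assessment reports per family, keeps dimension bookkeeping, and is idempotent", {
  synth <- generate_registry(registry_config(n_episodes = 300), seed = 3)
  expect_equal(nrow(run_quality_assessment(synth$bundle)$violations), 0L)

  corrupted <- inject_errors(synth, seed = 3)
  res <- run_quality_assessment(corrupted$bundle)
  # one injection per type: every family shows at least one finding and the
  # two attribute-domain types land in the same family
  fam <- res$report$by_family
  expect_equal(unname(fam["attribute_domain"]), 2L)
  expect_true(all(fam[c("relational_integrity", "historical_data",
                        "state_dependent", "attribute_dependency")] == 1L))
  expect_equal(sum(fam), nrow(corrupted$truth$injections))

  # per-dimension totals equal the sum over rules tagged with the dimension
  rules <- default_ruleset()
  dims <- vapply(rules, `[[`, "", "dimension")
  for (d in names(res$report$by_dimension)) {
    expect_equal(res$report$by_dimension[[d]],
                 sum(res$report$by_rule[dims == d]))
  }

  # second run on the cleaned output performs zero repairs
  res2 <- run_quality_assessment(res$bundle)
  expect_equal(n_repairs(res2), 0L)
})

test_that("a ruleset read from YAML reproduces the default assessment", {
  path <- system.file("extdata", "default_rules.yaml", package = "regforge")
  rs <- read_ruleset(path)
  expect_setequal(names(rs), names(default_ruleset()))
  synth <- generate_registry(registry_config(n_episodes = 150), seed = 9)
  corrupted <- inject_errors(synth, seed = 9)
  a <- run_quality_assessment(corrupted$bundle, default_ruleset())
  b <- run_quality_assessment(corrupted$bundle, rs)
  expect_equal(a$violations, b$violations)
})
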