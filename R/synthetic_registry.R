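# Synthetic four-table registry bundles with planted ground truth. The
# generator emulates the structural and statistical features the pipeline
# consumes -- multi-episode patients, the enrolled/opt-out/not-approached
# status mixture, missing start dates (structural for never-approached
# episodes, recoverable for enrolled episodes whose activation was only
# captured in the contact log), contact-log marginals, and PHQ-9 severity
# strata -- and returns a ledger of every planted fact so downstream
# stages can be tested against known truth. Bundles are clean by
# construction: the full data-quality ruleset finds nothing until
# inject_errors() plants violations.

#' Configuration for the synthetic registry generator
#'
#' Defaults encode the registry profile the package emulates: a
#' three-way status mixture of 44.3% enrolled / 33.3% opt-out / 22.4%
#' never approached, about 2.3% of enrolled episodes with a start date
#' recoverable only from the contact log (so that roughly 23.4% of all
#' episodes lack a recorded start date), about 0.5% of instances missing
#' an end date (data-entry error, dropped by complete-case analysis),
#' and eligibility dates spanning March 2008 to May 2018.
#'
#' @param n_episodes Number of status-bearing patient instances.
#' @param episodes_per_patient Named numeric vector of probabilities for
#'   1, 2, 3, ... episodes per patient.
#' @param status_mix Named proportions for `enrolled`, `opt_out`,
#'   `not_approached`; must sum to 1.
#' @param allocation `"exact"` (deterministic rounded quotas) or
#'   `"stochastic"` (per-episode multinomial draw).
#' @param recoverable_fraction Fraction of enrolled episodes generated
#'   with a missing (but contact-log-recoverable) start date.
#' @param missing_end_rate Fraction (of `n_episodes`) of additional
#'   instances planted with a start date but no end date.
#' @param subthreshold_fraction Fraction of enrolled episodes with a
#'   screening PHQ-9 below 10 (provider-discretion inclusions).
#' @param missing_contact_date_rate Fraction of extra contact rows with a
#'   missing contact date (retained, excluded from computation).
#' @param severity_mix Proportions of eligibility-date PHQ-9 totals in the
#'   bands 10-14, 15-19, 20-27.
#' @param date_range Two dates bounding eligibility dates.
#' @param max_contacts Cap on contacts per episode.
#' @param max_minutes Cap on minutes per contact.
#' @param female_rate,race_mix,marital_mix Demographic category
#'   frequencies.
#' @param age_mean,age_sd Age distribution at first eligibility (years,
#'   truncated to 18-90).
#' @return A list of class `generator_config`.
#' @export
registry_config <- function(
    n_episodes = 1000,
    episodes_per_patient = c("1" = 0.80, "2" = 0.15, "3" = 0.05),
    status_mix = c(enrolled = 0.443, opt_out = 0.333, not_approached = 0.224),
    allocation = c("exact", "stochastic"),
    recoverable_fraction = 0.023,
    missing_end_rate = 0.005,
    subthreshold_fraction = 0.0096,
    missing_contact_date_rate = 0.0017,
    severity_mix = c("10-14" = 0.486, "15-19" = 0.337, "20-27" = 0.177),
    date_range = as.Date(c("2008-03-03", "2018-05-17")),
    max_contacts = 123,
    max_minutes = 990,
    female_rate = 0.715,
    race_mix = c(White = 0.9198, Black = 0.0227, Asian = 0.0168,
                 `Native American` = 0.0040, Others = 0.0288,
                 Unknown = 0.0079),
    marital_mix = c(Married = 0.4894, Single = 0.3046, Divorced = 0.1571,
                    Widowed = 0.0463, Unknown = 0.0026),
    age_mean = 41.3, age_sd = 16.2) {
  allocation <- match.arg(allocation)
  cfg <- structure(list(
    n_episodes = n_episodes, episodes_per_patient = episodes_per_patient,
    status_mix = status_mix, allocation = allocation,
    recoverable_fraction = recoverable_fraction,
    missing_end_rate = missing_end_rate,
    subthreshold_fraction = subthreshold_fraction,
    missing_contact_date_rate = missing_contact_date_rate,
    severity_mix = severity_mix, date_range = as.Date(date_range),
    max_contacts = max_contacts, max_minutes = max_minutes,
    female_rate = female_rate, race_mix = race_mix,
    marital_mix = marital_mix, age_mean = age_mean, age_sd = age_sd),
    class = "generator_config")
  validate_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' @param config A `generator_config`.
#' @return The config, invisibly; errors name the offending field.
#' @export
validate_config <- function(config) {
  chk_rate <- function(field) {
    v <- config[[field]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop(sprintf("config field '%s' must be a rate in [0, 1]", field),
           call. = FALSE)
    }
  }
  if (!is.numeric(config$n_episodes) || config$n_episodes < 0) {
    stop("config field 'n_episodes' must be a non-negative count",
         call. = FALSE)
  }
  if (abs(sum(config$status_mix) - 1) > 1e-9) {
    stop("config field 'status_mix' must sum to 1", call. = FALSE)
  }
  if (!setequal(names(config$status_mix),
                c("enrolled", "opt_out", "not_approached"))) {
    stop("config field 'status_mix' must name enrolled, opt_out, ",
         "not_approached", call. = FALSE)
  }
  for (f in c("recoverable_fraction", "missing_end_rate",
              "subthreshold_fraction", "missing_contact_date_rate")) {
    chk_rate(f)
  }
  if (abs(sum(config$episodes_per_patient) - 1) > 1e-9) {
    stop("config field 'episodes_per_patient' must sum to 1", call. = FALSE)
  }
  if (abs(sum(config$severity_mix) - 1) > 1e-9) {
    stop("config field 'severity_mix' must sum to 1", call. = FALSE)
  }
  if (length(config$date_range) != 2L ||
      config$date_range[1] > config$date_range[2]) {
    stop("config field 'date_range' must be two ordered dates",
         call. = FALSE)
  }
  invisible(config)
}

#' Registry profile emulating a large collaborative-care depression registry
#'
#' Returns a [registry_config()] scaled to 15,576 eligible patient
#' instances with status mixture (44.30%, 33.30%, 22.40%), an overall
#' missing-start-date rate of 23.42% (22.40% structural from
#' never-approached instances plus recoverable enrolled instances),
#' eligibility dates spanning 2008-03-03 to 2018-05-17, at most 123
#' contacts per instance, and at most 990 minutes per contact. Allocation
#' is stochastic: empirical proportions converge to the configured mixture
#' as n grows.
#'
#' @return A `generator_config`.
#' @export
depression_profile_config <- function() {
  registry_config(
    n_episodes = 15576,
    status_mix = c(enrolled = 0.4430, opt_out = 0.3330,
                   not_approached = 0.2240),
    allocation = "stochastic",
    # overall missing-start target 0.2342 = 0.2240 structural
    # + 0.4430 * recoverable_fraction
    recoverable_fraction = (0.2342 - 0.2240) / 0.4430,
    missing_end_rate = 0.0048,
    date_range = as.Date(c("2008-03-03", "2018-05-17")),
    max_contacts = 123,
    max_minutes = 990)
}

# Compose a questionnaire total into k items each in 0..cap, uniformly at
# random among the feasible slot allocations.
.compose_items <- function(total, k = 9L, cap = 3L) {
  slots <- rep(seq_len(k), each = cap)
  tabulate(sample(slots, total), nbins = k)
}

.seed_guard <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      abs(seed) > 2^31 - 100) {
    stop("seed must be a single integer below 2^31 - 100", call. = FALSE)
  }
  as.integer(seed)
}

#' Generate a synthetic registry bundle with planted ground truth
#'
#' Deterministic given `(config, seed)`. Enrolled episodes get a recorded
#' start date and at least one positive-duration contact; opt-out episodes
#' get a start date and no contacts; never-approached episodes lack both.
#' Recoverable episodes are planted enrolled with the start date withheld
#' from the episode table but present as the earliest in-window contact.
#' All planted values satisfy the full data-quality ruleset.
#'
#' @param config A `generator_config`.
#' @param seed Integer seed (< 2^31).
#' @return List of class `synthetic_registry` with `bundle`
#'   (a `registry_bundle`) and `truth` (a `ground_truth`: per-episode
#'   planted status/recoverability/true start date, per-record injection
#'   ledger, empty until [inject_errors()]).
#' @export
generate_registry <- function(config = registry_config(), seed = 1L) {
  validate_config(config)
  seed <- .seed_guard(seed)
  n <- as.integer(config$n_episodes)

  # --- patient skeleton -------------------------------------------------
  set.seed(seed + 1L)
  kmax <- length(config$episodes_per_patient)
  if (n > 0L) {
    draws <- sample(as.integer(names(config$episodes_per_patient)),
                    size = n, replace = TRUE,
                    prob = config$episodes_per_patient)
    csum <- cumsum(draws)
    n_pat <- which(csum >= n)[1]
    draws <- draws[seq_len(n_pat)]
    draws[n_pat] <- draws[n_pat] - (csum[n_pat] - n)
  } else {
    draws <- integer(0)
    n_pat <- 0L
  }
  patient_id <- sprintf("P%06d", seq_len(n_pat))
  epi_patient <- rep(patient_id, times = draws)
  epi_index <- sequence(draws)

  # --- status allocation ------------------------------------------------
  set.seed(seed + 2L)
  statuses <- names(config$status_mix)
  if (n > 0L) {
    if (config$allocation == "exact") {
      quota <- round(n * config$status_mix)
      quota[1] <- n - sum(quota[-1])
      planted <- sample(rep(statuses, times = quota))
    } else {
      planted <- sample(statuses, n, replace = TRUE,
                        prob = config$status_mix)
    }
    enrolled_idx <- which(planted == "enrolled")
    n_recover <- if (config$allocation == "exact") {
      round(length(enrolled_idx) * config$recoverable_fraction)
    } else {
      sum(stats::runif(length(enrolled_idx)) < config$recoverable_fraction)
    }
    recoverable <- rep(FALSE, n)
    if (n_recover > 0L) {
      recoverable[sample(enrolled_idx, n_recover)] <- TRUE
    }
  } else {
    planted <- character(0)
    recoverable <- logical(0)
  }

  # --- episode dates ----------------------------------------------------
  set.seed(seed + 3L)
  d0 <- as.numeric(config$date_range[1])
  d1 <- as.numeric(config$date_range[2])
  elig <- numeric(n)
  start_true <- rep(NA_real_, n)
  end <- numeric(n)
  # Per-patient sequential, non-overlapping episode windows so contact
  # attribution is unambiguous.
  first_elig <- numeric(n_pat)
  if (n > 0L) {
    lag <- sample(0:60, n, replace = TRUE)          # eligibility -> offer
    act <- sample(30:365, n, replace = TRUE)        # activation time
    elig_time_na <- sample(0:300, n, replace = TRUE)  # never-approached span
    first_elig <- round(stats::runif(n_pat, d0, max(d0, d1 - 1500)))
    cursor <- first_elig
    ord <- order(epi_patient, epi_index)
    for (j in ord) {
      p <- match(epi_patient[j], patient_id)
      e <- cursor[p]
      elig[j] <- e
      if (planted[j] == "not_approached") {
        end[j] <- e + elig_time_na[j]
      } else if (planted[j] == "opt_out") {
        start_true[j] <- e + lag[j]
        end[j] <- start_true[j] + sample(0:200, 1)
      } else {
        start_true[j] <- e + max(1L, lag[j])  # recoverable needs elig_time > 0
        end[j] <- start_true[j] + act[j]
      }
      cursor[p] <- end[j] + sample(30:400, 1)
    }
  }
  episode_id <- sprintf("E%06d", seq_len(n))
  start_recorded <- start_true
  start_recorded[recoverable] <- NA_real_
  start_recorded[planted == "not_approached"] <- NA_real_

  # --- extra instances missing an end date (complete-case fodder) ------
  n_drop <- round(config$missing_end_rate * n)
  if (n_drop > 0L) {
    set.seed(seed + 4L)
    drop_pat <- sprintf("P%06d", n_pat + seq_len(n_drop))
    drop_elig <- round(stats::runif(n_drop, d0, d1 - 100))
    drop_start <- drop_elig + sample(0:60, n_drop, replace = TRUE)
    drop_id <- sprintf("E%06d", n + seq_len(n_drop))
  } else {
    drop_pat <- character(0); drop_elig <- numeric(0)
    drop_start <- numeric(0); drop_id <- character(0)
  }

  episodes <- data.frame(
    episode_id = c(episode_id, drop_id),
    patient_id = c(epi_patient, drop_pat),
    eligibility_date = as.Date(c(elig, drop_elig), origin = "1970-01-01"),
    start_date = as.Date(c(start_recorded, drop_start),
                         origin = "1970-01-01"),
    end_date = as.Date(c(end, rep(NA_real_, n_drop)), origin = "1970-01-01"),
    recorded_status = rep(NA_character_, n + n_drop),
    stringsAsFactors = FALSE)

  # --- contacts ---------------------------------------------------------
  set.seed(seed + 5L)
  is_contactful <- planted == "enrolled"
  n_contacts <- integer(n)
  n_contacts[is_contactful] <- pmin(
    1L + stats::rpois(sum(is_contactful), 3), config$max_contacts)
  ci <- rep(seq_len(n), times = n_contacts)
  if (length(ci)) {
    span <- pmax(end[ci] - start_true[ci], 0)
    offs <- floor(stats::runif(length(ci)) * (span + 1))
    # The first contact of each episode is pinned to the true start date:
    # for recoverable episodes it is the recovery target.
    first_of_epi <- !duplicated(ci)
    offs[first_of_epi] <- 0
    contact_date <- start_true[ci] + offs
    time_spent <- pmin(5 + stats::rpois(length(ci), 15), config$max_minutes)
  } else {
    contact_date <- numeric(0)
    time_spent <- numeric(0)
  }
  n_missing_date <- round(config$missing_contact_date_rate * length(ci))
  if (n_missing_date > 0L) {
    md_pat <- sample(patient_id, n_missing_date, replace = TRUE)
    contacts <- data.frame(
      patient_id = c(epi_patient[ci], md_pat),
      contact_date = as.Date(c(contact_date,
                               rep(NA_real_, n_missing_date)),
                             origin = "1970-01-01"),
      time_spent = c(time_spent,
                     pmin(5 + stats::rpois(n_missing_date, 15),
                          config$max_minutes)),
      stringsAsFactors = FALSE)
  } else {
    contacts <- data.frame(
      patient_id = epi_patient[ci],
      contact_date = as.Date(contact_date, origin = "1970-01-01"),
      time_spent = time_spent,
      stringsAsFactors = FALSE)
  }

  # --- demographics -----------------------------------------------------
  set.seed(seed + 6L)
  all_pat <- c(patient_id, drop_pat)
  np <- length(all_pat)
  first_elig_all <- c(first_elig, drop_elig)
  age <- pmin(pmax(round(stats::rnorm(np, config$age_mean, config$age_sd)),
                   18), 90)
  # margin of at least 2 days keeps the completed-years age at the first
  # eligibility date from ever falling below the drawn age
  birth <- as.Date(first_elig_all, origin = "1970-01-01") - age * 365.25 -
    sample(2:200, np, replace = TRUE)
  sex <- ifelse(stats::runif(np) < config$female_rate, "female", "male")
  demographics <- data.frame(
    patient_id = all_pat,
    birth_date = as.Date(round(as.numeric(birth)), origin = "1970-01-01"),
    sex = sex,
    race = sample(names(config$race_mix), np, replace = TRUE,
                  prob = config$race_mix),
    marital_status = sample(names(config$marital_mix), np, replace = TRUE,
                            prob = config$marital_mix),
    employment_status = sample(c("yes", "no"), np, replace = TRUE,
                               prob = c(0.6, 0.4)),
    consent = rep(TRUE, np),
    bipolar_history = rep(FALSE, np),
    depression_diagnosis = rep(TRUE, np),
    stringsAsFactors = FALSE)

  # --- questionnaires ---------------------------------------------------
  set.seed(seed + 7L)
  band_lo <- c(10L, 15L, 20L)
  band_hi <- c(14L, 19L, 27L)
  draw_totals <- function(m) {
    if (m == 0L) return(integer(0))
    b <- sample(seq_along(config$severity_mix), m, replace = TRUE,
                prob = config$severity_mix)
    band_lo[b] + floor(stats::runif(m) * (band_hi[b] - band_lo[b] + 1))
  }
  elig_total <- draw_totals(n)
  if (n > 0L) {
    enrolled_idx <- which(planted == "enrolled")
    n_sub <- round(length(enrolled_idx) * config$subthreshold_fraction)
    if (n_sub > 0L) {
      sub_idx <- sample(enrolled_idx, n_sub)
      elig_total[sub_idx] <- sample(3:9, n_sub, replace = TRUE)
    }
  }
  # A PHQ-9 at every eligibility date; a second PHQ-9 at the recorded
  # start date of offered episodes; a GAD-7 at eligibility for enrolled.
  with_start <- which(!is.na(start_recorded[seq_len(n)]))
  start_total <- draw_totals(length(with_start))
  q_pid <- c(epi_patient, epi_patient[with_start])
  q_date <- c(elig, start_recorded[with_start])
  q_total <- c(elig_total, start_total)
  items <- t(vapply(q_total, .compose_items, integer(9)))
  enr_gad <- which(planted == "enrolled" & !recoverable)
  gad_total <- if (length(enr_gad)) {
    sample(5:18, length(enr_gad), replace = TRUE)
  } else integer(0)
  questionnaires <- data.frame(
    patient_id = c(q_pid, epi_patient[enr_gad]),
    instrument = c(rep("PHQ9", length(q_pid)),
                   rep("GAD7", length(enr_gad))),
    stringsAsFactors = FALSE)
  item_mat <- rbind(items,
                    matrix(NA_integer_, nrow = length(enr_gad), ncol = 9))
  colnames(item_mat) <- paste0("item_", 1:9)
  questionnaires <- cbind(questionnaires, as.data.frame(item_mat))
  questionnaires$total <- c(q_total, gad_total)
  questionnaires$recording_date <- as.Date(c(q_date, elig[enr_gad]),
                                           origin = "1970-01-01")

  bundle <- registry_bundle(demographics, episodes, contacts, questionnaires)
  truth <- structure(list(
    episodes = data.frame(
      episode_id = c(episode_id, drop_id),
      planted_status = c(planted, rep(NA_character_, n_drop)),
      recoverable = c(recoverable, rep(NA, n_drop)),
      true_start_date = as.Date(c(start_true, drop_start),
                                origin = "1970-01-01"),
      planted_drop = c(rep(FALSE, n), rep(TRUE, n_drop)),
      stringsAsFactors = FALSE),
    injections = .empty_injections(),
    config = config, seed = seed), class = "ground_truth")
  structure(list(bundle = bundle, truth = truth),
            class = "synthetic_registry")
}

#' @export
print.synthetic_registry <- function(x, ...) {
  cat("<synthetic_registry> seed", x$truth$seed, "\n")
  print(x$bundle)
  tab <- table(x$truth$episodes$planted_status, useNA = "no")
  cat("  planted statuses:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (nrow(x$truth$injections)) {
    cat("  injected errors:", nrow(x$truth$injections), "\n")
  }
  invisible(x)
}

.empty_injections <- function() {
  data.frame(injection_id = character(0), type = character(0),
             family = character(0), table = character(0),
             row_id = character(0), column = character(0),
             original = character(0), injected = character(0),
             stringsAsFactors = FALSE)
}

.INJECTION_TYPES <- c(
  phq_item_domain = "attribute_domain",
  employment_free_text = "attribute_domain",
  duplicate_episode_key = "relational_integrity",
  date_inversion = "historical_data",
  missing_eligibility = "state_dependent",
  phq_total_mismatch = "attribute_dependency")

#' Inject data-quality violations into a clean bundle
#'
#' Plants a configured number of violations of each type -- out-of-domain
#' PHQ-9 item, free-text employment answer, duplicate composite episode
#' key, start/end date inversion, end date without an eligibility date,
#' and total-not-equal-to-item-sum -- and returns the corrupted bundle
#' with a ledger holding every original value. Injections never collide
#' on the same cell, and targets are chosen so one planted fault triggers
#' exactly one rule.
#'
#' @param synth A `synthetic_registry` (or a bare `registry_bundle`).
#' @param counts Named integer vector: injections per type (defaults to 1
#'   of each; names as in the description).
#' @param seed Integer seed.
#' @return A `synthetic_registry` with the corrupted bundle and the
#'   injection ledger appended to the truth.
#' @export
inject_errors <- function(synth, counts = NULL, seed = 1L) {
  if (inherits(synth, "registry_bundle")) {
    synth <- structure(list(
      bundle = synth,
      truth = structure(list(episodes = NULL,
                             injections = .empty_injections(),
                             config = NULL, seed = NA),
                        class = "ground_truth")),
      class = "synthetic_registry")
  }
  default <- stats::setNames(rep(1L, length(.INJECTION_TYPES)),
                             names(.INJECTION_TYPES))
  if (!is.null(counts)) {
    bad <- setdiff(names(counts), names(default))
    if (length(bad)) {
      stop("unknown injection type(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    default[names(counts)] <- counts
  }
  counts <- default
  seed <- .seed_guard(seed)
  set.seed(seed + 11L)
  bundle <- synth$bundle
  ledger <- list()
  inj_n <- 0L
  add <- function(type, table, row_id, column, original, injected) {
    inj_n <<- inj_n + 1L
    ledger[[inj_n]] <<- data.frame(
      injection_id = sprintf("I%04d", inj_n), type = type,
      family = unname(.INJECTION_TYPES[[type]]), table = table,
      row_id = row_id, column = column,
      original = as.character(original), injected = as.character(injected),
      stringsAsFactors = FALSE)
  }
  pick <- function(pool, k, what) {
    if (length(pool) < k) {
      stop(sprintf("not enough rows to inject %d '%s' errors (have %d)",
                   k, what, length(pool)), call. = FALSE)
    }
    if (k == 0L) return(integer(0))
    sample(pool, k)
  }

  q <- bundle$questionnaires
  items_ok <- q$instrument == "PHQ9" &
    rowSums(is.na(q[, paste0("item_", 1:9)])) == 0 & !is.na(q$total)
  used_q <- rep(FALSE, nrow(q))

  # 1. out-of-domain PHQ-9 item (item set to a value outside 0-3)
  k <- counts[["phq_item_domain"]]
  rows <- pick(which(items_ok & !used_q), k, "phq_item_domain")
  used_q[rows] <- TRUE
  for (r in rows) {
    col <- paste0("item_", sample(1:9, 1))
    bad_val <- sample(c(-1, 4, 5), 1)
    add("phq_item_domain", "questionnaires", q$response_id[r], col,
        q[[col]][r], bad_val)
    q[[col]][r] <- bad_val
  }

  # 6. total != sum of items (kept inside the 0-27 domain)
  k <- counts[["phq_total_mismatch"]]
  rows <- pick(which(items_ok & !used_q), k, "phq_total_mismatch")
  used_q[rows] <- TRUE
  for (r in rows) {
    delta <- if (q$total[r] <= 25) 2 else -2
    add("phq_total_mismatch", "questionnaires", q$response_id[r], "total",
        q$total[r], q$total[r] + delta)
    q$total[r] <- q$total[r] + delta
  }
  bundle$questionnaires <- q

  # 2. free-text employment answer (normalized by the domain rule)
  dem <- bundle$demographics
  k <- counts[["employment_free_text"]]
  rows <- pick(which(dem$employment_status %in% c("yes", "no")), k,
               "employment_free_text")
  for (r in rows) {
    txt <- sample(c("I am employed", "I am looking for a job"), 1)
    add("employment_free_text", "demographics", dem$patient_id[r],
        "employment_status", dem$employment_status[r], txt)
    dem$employment_status[r] <- txt
  }
  bundle$demographics <- dem

  epi <- bundle$episodes
  used_e <- rep(FALSE, nrow(epi))
  attributed <- attribute_contacts(bundle)
  has_contact <- epi$episode_id %in%
    attributed$episode_id[!is.na(attributed$episode_id)]

  # 3. duplicate composite episode key (appended twin row, fresh id)
  k <- counts[["duplicate_episode_key"]]
  pool <- which(!has_contact & !used_e)   # contact-free: no attribution churn
  rows <- pick(pool, k, "duplicate_episode_key")
  used_e[rows] <- TRUE
  if (k > 0L) {
    twins <- epi[rows, , drop = FALSE]
    twins$episode_id <- sprintf("EDUP%03d", seq_len(k))
    for (i in seq_len(k)) {
      add("duplicate_episode_key", "episodes", twins$episode_id[i],
          "episode_key", epi$episode_id[rows[i]],
          composite_episode_key(twins[i, , drop = FALSE]))
    }
    epi <- rbind(epi, twins)
    used_e <- c(used_e, rep(TRUE, k))
    has_contact <- c(has_contact, rep(FALSE, k))
  }

  # 4. date inversion: end date moved before the start date (but not
  # before eligibility, so only the start/end ordering rule fires)
  k <- counts[["date_inversion"]]
  pool <- which(!used_e & !is.na(epi$start_date) & !is.na(epi$end_date) &
                  !is.na(epi$eligibility_date) &
                  epi$start_date >= epi$eligibility_date + 2)
  rows <- pick(pool, k, "date_inversion")
  used_e[rows] <- TRUE
  for (r in rows) {
    new_end <- epi$start_date[r] - 1
    add("date_inversion", "episodes", epi$episode_id[r], "end_date",
        format(epi$end_date[r]), format(new_end))
    epi$end_date[r] <- new_end
  }

  # 5. end date without an eligibility date (targets with a start date, so
  # the blanked composite keys cannot collide)
  k <- counts[["missing_eligibility"]]
  pool <- which(!used_e & !is.na(epi$end_date) &
                  !is.na(epi$eligibility_date) & !is.na(epi$start_date))
  rows <- pick(pool, k, "missing_eligibility")
  used_e[rows] <- TRUE
  for (r in rows) {
    add("missing_eligibility", "episodes", epi$episode_id[r],
        "eligibility_date", format(epi$eligibility_date[r]), NA)
    epi$eligibility_date[r] <- as.Date(NA)
  }
  bundle$episodes <- epi
  bundle <- link_records(bundle)

  synth$bundle <- bundle
  synth$truth$injections <- rbind(synth$truth$injections,
                                  .bind_violations(ledger))
  synth
}

#' Write a synthetic registry (tables + truth ledger) to a directory
#'
#' @param synth A `synthetic_registry`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_synthetic_registry <- function(synth, dir) {
  paths <- write_registry(synth$bundle, dir)
  truth_path <- file.path(dir, "ground_truth.json")
  truth <- synth$truth
  jsonlite::write_json(list(
    seed = truth$seed,
    episodes = truth$episodes,
    injections = truth$injections), truth_path, auto_unbox = TRUE,
    dataframe = "rows", na = "null", digits = NA)
  invisible(c(paths, ground_truth = truth_path))
}
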