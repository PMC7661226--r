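# Episode status classification (enrolled / opt-out / not-approached) via
# the two derivation algorithms -- A for episodes with a start date (zero
# contact frequency or zero total time spent means not enrolled), B for
# episodes whose start date was missing (recovered from the contact log
# means enrolled, otherwise never approached) -- plus the study eligibility
# filter and PHQ-9 severity banding.

.STATUS_LEVELS <- c("enrolled", "opt_out", "not_approached")
.EXCLUSION_REASONS <- c("no_consent", "age_below_18", "bipolar_history",
                        "phq_below_10", "fewer_than_two_phq9",
                        "no_depression_diagnosis")

#' Study eligibility criteria
#'
#' The registry eligibility screen: research consent, age at least 18 at
#' the eligibility date, a clinical depression diagnosis, no history of
#' bipolar disorder, and a screening PHQ-9 of at least 10. Enrolled
#' episodes below the PHQ-9 threshold may be retained at the providers'
#' discretion (`subthreshold_override`, default on). The requirement of at
#' least two completed PHQ-9 questionnaires belongs to the cross-sectional
#' study pathway only and is off by default.
#'
#' @param min_age Minimum age in whole years at the eligibility date.
#' @param min_phq9 Minimum screening PHQ-9 total.
#' @param require_consent Exclude patients without research consent.
#' @param require_depression_dx Require a depression diagnosis flag.
#' @param exclude_bipolar Exclude patients with a bipolar history.
#' @param min_phq9_count Minimum number of PHQ-9 responses per patient
#'   (`NULL` disables the check).
#' @param subthreshold_override Retain enrolled episodes with a screening
#'   PHQ-9 below `min_phq9`.
#' @return A list of class `eligibility_criteria`.
#' @export
eligibility_criteria <- function(min_age = 18, min_phq9 = 10,
                                 require_consent = TRUE,
                                 require_depression_dx = TRUE,
                                 exclude_bipolar = TRUE,
                                 min_phq9_count = NULL,
                                 subthreshold_override = TRUE) {
  structure(list(min_age = min_age, min_phq9 = min_phq9,
                 require_consent = require_consent,
                 require_depression_dx = require_depression_dx,
                 exclude_bipolar = exclude_bipolar,
                 min_phq9_count = min_phq9_count,
                 subthreshold_override = subthreshold_override),
            class = "eligibility_criteria")
}

# Age in completed years at a reference date.
.age_at <- function(birth, ref) {
  b <- as.POSIXlt(birth)
  r <- as.POSIXlt(ref)
  age <- r$year - b$year
  before_birthday <- (r$mon < b$mon) | (r$mon == b$mon & r$mday < b$mday)
  age - as.integer(before_birthday)
}

# Screening PHQ-9: total of the latest PHQ-9 recorded on or before the
# anchor date, per patient. Returns NA where no such response exists.
.phq9_at <- function(bundle, patient_id, anchor) {
  q <- bundle$questionnaires
  q <- q[q$instrument == "PHQ9" & !is.na(q$recording_date) &
           !is.na(q$total), , drop = FALSE]
  out <- rep(NA_real_, length(patient_id))
  if (nrow(q) == 0L) return(out)
  cand <- merge(
    data.frame(idx = seq_along(patient_id), patient_id = patient_id,
               anchor = anchor, stringsAsFactors = FALSE),
    q[, c("patient_id", "recording_date", "total", "response_id")],
    by = "patient_id")
  cand <- cand[!is.na(cand$anchor) &
                 cand$recording_date <= cand$anchor, , drop = FALSE]
  if (nrow(cand) == 0L) return(out)
  cand <- cand[order(cand$idx, cand$recording_date, cand$response_id,
                     decreasing = c(FALSE, TRUE, FALSE),
                     method = "radix"), , drop = FALSE]
  cand <- cand[!duplicated(cand$idx), , drop = FALSE]
  out[cand$idx] <- cand$total
  out
}

#' Apply the study eligibility filter
#'
#' Evaluates every episode against the criteria in a fixed order: research
#' consent first, then the inclusion criteria (age, depression diagnosis,
#' bipolar history, screening PHQ-9, optionally a minimum PHQ-9 count).
#' Enrolled episodes failing only the PHQ-9 threshold are retained with
#' `subthreshold_override = TRUE` when the override is enabled.
#'
#' @param bundle A cleaned `registry_bundle`.
#' @param criteria An [eligibility_criteria()] object.
#' @return List with `decisions` (data frame: `episode_id`, `eligible`,
#'   `exclusion_reasons` as a `;`-joined string, `subthreshold_override`)
#'   and `tally` (named integer vector of exclusion counts per reason,
#'   plus `eligible`).
#' @export
apply_eligibility_filter <- function(bundle, criteria = eligibility_criteria()) {
  if (!inherits(criteria, "eligibility_criteria")) {
    stop("criteria must be an eligibility_criteria object", call. = FALSE)
  }
  epi <- bundle$episodes
  dem <- bundle$demographics
  di <- match(epi$patient_id, dem$patient_id)

  reasons <- vector("list", nrow(epi))
  add_reason <- function(reasons, which_bad, reason) {
    for (i in which_bad) reasons[[i]] <- c(reasons[[i]], reason)
    reasons
  }

  # Consent is evaluated first, mirroring the study's exclusion order.
  if (criteria$require_consent) {
    bad <- which(is.na(dem$consent[di]) | !dem$consent[di])
    reasons <- add_reason(reasons, bad, "no_consent")
  }
  age <- .age_at(dem$birth_date[di], epi$eligibility_date)
  bad <- which(!is.na(age) & age < criteria$min_age)
  reasons <- add_reason(reasons, bad, "age_below_18")
  if (criteria$exclude_bipolar) {
    bad <- which(!is.na(dem$bipolar_history[di]) & dem$bipolar_history[di])
    reasons <- add_reason(reasons, bad, "bipolar_history")
  }
  if (criteria$require_depression_dx) {
    bad <- which(is.na(dem$depression_diagnosis[di]) |
                   !dem$depression_diagnosis[di])
    reasons <- add_reason(reasons, bad, "no_depression_diagnosis")
  }
  phq <- .phq9_at(bundle, epi$patient_id, epi$eligibility_date)
  low_phq <- which(!is.na(phq) & phq < criteria$min_phq9)
  reasons <- add_reason(reasons, low_phq, "phq_below_10")
  if (!is.null(criteria$min_phq9_count)) {
    q <- bundle$questionnaires
    counts <- table(q$patient_id[q$instrument == "PHQ9" & !is.na(q$total)])
    npq <- as.integer(counts[epi$patient_id])
    npq[is.na(npq)] <- 0L
    bad <- which(npq < criteria$min_phq9_count)
    reasons <- add_reason(reasons, bad, "fewer_than_two_phq9")
  }

  # Provider-discretion override: an episode that fails only the PHQ-9
  # threshold but is (derivably) enrolled stays in the study sample.
  override <- rep(FALSE, nrow(epi))
  if (criteria$subthreshold_override && length(low_phq)) {
    metrics <- episode_metrics(bundle)
    mi <- match(epi$episode_id, metrics$episode_id)
    enrolled_like <- (!is.na(epi$recorded_status) &
                        epi$recorded_status == "enrolled") |
      (is.na(epi$recorded_status) & !is.na(epi$start_date) &
         metrics$contact_frequency[mi] > 0 &
         metrics$total_time_spent_min[mi] > 0)
    for (i in low_phq) {
      if (identical(reasons[[i]], "phq_below_10") && enrolled_like[i]) {
        override[i] <- TRUE
        reasons[i] <- list(NULL)
      }
    }
  }

  reason_str <- vapply(reasons, function(r) {
    if (is.null(r)) "" else paste(r, collapse = ";")
  }, "")
  eligible <- reason_str == ""
  tally <- vapply(.EXCLUSION_REASONS, function(r) {
    sum(vapply(reasons, function(x) r %in% x, logical(1)))
  }, integer(1))
  tally <- c(tally, eligible = sum(eligible),
             subthreshold_override = sum(override))

  list(decisions = data.frame(episode_id = epi$episode_id,
                              eligible = eligible,
                              exclusion_reasons = reason_str,
                              subthreshold_override = override,
                              stringsAsFactors = FALSE),
       tally = tally)
}

.classify_vec <- function(has_start, recovered, recorded_status,
                          contact_frequency, total_time_spent) {
  n <- length(has_start)
  status <- character(n)
  provenance <- character(n)
  recorded <- !is.na(recorded_status) & recorded_status %in% .STATUS_LEVELS
  status[recorded] <- recorded_status[recorded]
  provenance[recorded] <- "recorded"

  todo <- !recorded
  # Algorithm B: start date missing after recovery was attempted.
  b_unapp <- todo & !has_start
  status[b_unapp] <- "not_approached"
  provenance[b_unapp] <- "derived_B_unapproached"
  b_rec <- todo & has_start & recovered
  status[b_rec] <- "enrolled"
  provenance[b_rec] <- "derived_B_recovered"
  # Algorithm A: start date present; zero frequency or zero total time
  # means the patient was offered the intervention but never received it.
  a <- todo & has_start & !recovered
  a_opt <- a & (contact_frequency == 0 | total_time_spent == 0)
  status[a_opt] <- "opt_out"
  provenance[a_opt] <- "derived_A"
  a_enr <- a & contact_frequency > 0 & total_time_spent > 0
  status[a_enr] <- "enrolled"
  provenance[a_enr] <- "derived_A"
  list(status = status, provenance = provenance)
}

#' Classify a single episode
#'
#' A recorded status always takes precedence (provenance `"recorded"`).
#' Otherwise algorithm A applies when a start date is present: positive
#' contact frequency and positive total time spent mean enrolled, zero of
#' either means opt-out. Algorithm B applies when the start date was
#' missing: a start date recovered from the contact log means enrolled,
#' a start date still missing means the patient was never approached.
#'
#' @param episode One-row slice of an episode table (after start-date
#'   recovery).
#' @param metrics The matching one-row slice of [episode_metrics()].
#' @return List with `status` and `provenance`.
#' @export
classify_episode <- function(episode, metrics) {
  if (nrow(metrics) != 1L || metrics$episode_id != episode$episode_id) {
    stop("metrics row does not match the episode", call. = FALSE)
  }
  res <- .classify_vec(!is.na(episode$start_date),
                       identical(episode$start_provenance, "recovered"),
                       episode$recorded_status,
                       metrics$contact_frequency,
                       metrics$total_time_spent_min)
  list(status = res$status, provenance = res$provenance)
}

#' Classify every eligible episode
#'
#' @param bundle A cleaned `registry_bundle` (incomplete episodes dropped,
#'   start-date recovery attempted).
#' @param decisions Optional `decisions` data frame from
#'   [apply_eligibility_filter()]; when given, only eligible episodes are
#'   labeled.
#' @return An object of class `cohort_labels`: `$labels` (data frame
#'   `episode_id`, `patient_id`, `status`, `provenance`), `$counts`
#'   (named integer vector per status), `$provenance_counts`.
#'   The statuses partition the labeled set.
#' @export
classify_all <- function(bundle, decisions = NULL) {
  epi <- bundle$episodes
  if (!is.null(decisions)) {
    keep <- epi$episode_id %in%
      decisions$episode_id[decisions$eligible]
    epi <- epi[keep, , drop = FALSE]
  }
  metrics <- episode_metrics(bundle)
  mi <- match(epi$episode_id, metrics$episode_id)
  res <- .classify_vec(!is.na(epi$start_date),
                       epi$start_provenance == "recovered",
                       epi$recorded_status,
                       metrics$contact_frequency[mi],
                       metrics$total_time_spent_min[mi])
  labels <- data.frame(episode_id = epi$episode_id,
                       patient_id = epi$patient_id,
                       status = res$status,
                       provenance = res$provenance,
                       stringsAsFactors = FALSE)
  counts <- vapply(.STATUS_LEVELS, function(s) sum(labels$status == s),
                   integer(1))
  prov <- table(labels$provenance)
  structure(list(labels = labels, counts = counts,
                 provenance_counts = prov, n = nrow(labels)),
            class = "cohort_labels")
}

#' @export
print.cohort_labels <- function(x, ...) {
  cat("<cohort_labels>", x$n, "episodes\n")
  for (s in names(x$counts)) {
    pct <- if (x$n > 0) 100 * x$counts[[s]] / x$n else 0
    cat(sprintf("  %-15s %6d (%.2f%%)\n", s, x$counts[[s]], pct))
  }
  invisible(x)
}

#' Band a PHQ-9 total into severity categories
#'
#' The banding used in subgroup summary tables: `<=5`, `>5,<10`,
#' `>=10,<15`, `>=15,<20`, `>=20` (severe depression), plus `missing`.
#' Bands are exhaustive and mutually exclusive over the valid 0-27 range.
#'
#' @param score Integer vector of PHQ-9 totals (`NA` allowed).
#' @return Factor with the six band levels.
#' @export
band_phq9 <- function(score) {
  if (any(!is.na(score) & (score < 0 | score > 27))) {
    stop("PHQ-9 total outside the 0-27 domain; run the data-quality ",
         "assessment first", call. = FALSE)
  }
  levels <- c("<=5", ">5,<10", ">=10,<15", ">=15,<20", ">=20", "missing")
  out <- rep("missing", length(score))
  ok <- !is.na(score)
  out[ok & score <= 5] <- "<=5"
  out[ok & score > 5 & score < 10] <- ">5,<10"
  out[ok & score >= 10 & score < 15] <- ">=10,<15"
  out[ok & score >= 15 & score < 20] <- ">=15,<20"
  out[ok & score >= 20] <- ">=20"
  factor(out, levels = levels)
}
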