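# Missing-data procedures: complete-case dropping of episodes that have a
# start date but no end date, and recovery of missing start dates from the
# contact log (first attributable contact date becomes the start date when
# the eligibility time is positive). Derived per-episode metrics live here
# too, since every downstream stage consumes them.

#' Compute derived metrics for every episode
#'
#' Per episode: activation time (end minus start, in days, defined when the
#' start date is present), eligibility time (end minus eligibility, defined
#' when the start date is missing), CE time (end minus first attributable
#' contact date, defined when the start date was recovered from the contact
#' log), contact frequency, and total contact minutes. Contacts with a
#' missing date, or falling outside the episode's
#' `[eligibility_date, end_date]` window, are excluded from frequency and
#' duration.
#'
#' @param bundle A `registry_bundle` whose episodes all have an end date
#'   (drop incomplete episodes first).
#' @return Data frame with one row per episode: `episode_id`, `patient_id`,
#'   `activation_time_days`, `eligibility_time_days`, `ce_time_days`,
#'   `contact_frequency`, `total_time_spent_min`, `first_contact_date`.
#' @export
episode_metrics <- function(bundle) {
  epi <- bundle$episodes
  if (any(is.na(epi$end_date))) {
    stop("episodes with a missing end date present; run ",
         "drop_incomplete_episodes() first", call. = FALSE)
  }
  contacts <- attribute_contacts(bundle)
  usable <- contacts[!is.na(contacts$episode_id) &
                       !is.na(contacts$contact_date), , drop = FALSE]

  freq <- integer(nrow(epi))
  minutes <- numeric(nrow(epi))
  first_contact <- rep(as.Date(NA), nrow(epi))
  if (nrow(usable)) {
    idx <- match(usable$episode_id, epi$episode_id)
    agg_n <- tapply(rep(1L, nrow(usable)), idx, sum)
    agg_min <- tapply(ifelse(is.na(usable$time_spent), 0,
                             usable$time_spent), idx, sum)
    agg_first <- tapply(as.numeric(usable$contact_date), idx, min)
    pos <- as.integer(names(agg_n))
    freq[pos] <- as.integer(agg_n)
    minutes[pos] <- as.numeric(agg_min)
    first_contact[pos] <- as.Date(as.numeric(agg_first),
                                  origin = "1970-01-01")
  }

  has_start <- !is.na(epi$start_date)
  recovered <- epi$start_provenance == "recovered"
  data.frame(
    episode_id = epi$episode_id,
    patient_id = epi$patient_id,
    activation_time_days = ifelse(
      has_start, as.integer(epi$end_date - epi$start_date), NA_integer_),
    eligibility_time_days = ifelse(
      !has_start, as.integer(epi$end_date - epi$eligibility_date),
      NA_integer_),
    ce_time_days = ifelse(
      recovered & !is.na(first_contact),
      as.integer(epi$end_date - first_contact), NA_integer_),
    contact_frequency = freq,
    total_time_spent_min = minutes,
    first_contact_date = first_contact,
    stringsAsFactors = FALSE)
}

#' Compute derived metrics for one episode
#'
#' Single-episode convenience wrapper over [episode_metrics()].
#'
#' @param episode One-row slice of an episode table.
#' @param bundle The `registry_bundle` the episode belongs to (supplies the
#'   contact log for attribution).
#' @return One-row metrics data frame.
#' @export
compute_episode_metrics <- function(episode, bundle) {
  m <- episode_metrics(bundle)
  out <- m[m$episode_id == episode$episode_id, , drop = FALSE]
  if (nrow(out) != 1L) {
    stop("episode not found in bundle: ", episode$episode_id, call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

.recovery_report <- function(examined, dropped_keys, recovered_ids,
                             untouched_ids, provenance) {
  structure(list(
    examined = examined,
    dropped = length(dropped_keys),
    recovered = length(recovered_ids),
    untouched = length(untouched_ids),
    dropped_keys = dropped_keys,
    recovered_ids = recovered_ids,
    untouched_ids = untouched_ids,
    provenance = provenance,
    mechanism = NULL
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  cat(sprintf("  episodes examined:        %d\n", x$examined))
  cat(sprintf("  dropped (no end date):    %d\n", x$dropped))
  cat(sprintf("  start dates recovered:    %d\n", x$recovered))
  cat(sprintf("  still missing start date: %d\n", x$untouched))
  if (!is.null(x$mechanism)) {
    cat(sprintf("  missingness mechanism (annotation): %s\n", x$mechanism))
  }
  invisible(x)
}

#' Drop episodes with a start date but no end date (complete-case)
#'
#' Episodes carrying a start date but no end date are incomplete records
#' (the registry guideline requires enrolled instances to have eligibility,
#' start and end dates) and are removed; all other rows are untouched. The
#' removal is performed at the episode (patient-instance) level: other
#' episodes of the same patient survive.
#'
#' @param bundle A `registry_bundle`.
#' @param mechanism Optional missingness-mechanism annotation (e.g.
#'   `"MCAR"`) attached to the report; never inferred.
#' @return List with `bundle` (filtered) and `report`
#'   (a `recovery_report`; `report$dropped` counts removals).
#' @export
drop_incomplete_episodes <- function(bundle, mechanism = "MCAR") {
  epi <- bundle$episodes
  drop <- !is.na(epi$start_date) & is.na(epi$end_date)
  report <- .recovery_report(
    examined = nrow(epi),
    dropped_keys = epi$episode_id[drop],
    recovered_ids = character(0),
    untouched_ids = character(0),
    provenance = data.frame(
      episode_id = epi$episode_id[drop],
      action = if (any(drop)) "dropped" else character(0),
      stringsAsFactors = FALSE))
  report$mechanism <- mechanism
  bundle$episodes <- epi[!drop, , drop = FALSE]
  rownames(bundle$episodes) <- NULL
  bundle <- link_records(bundle)
  list(bundle = bundle, report = report)
}

#' Recover missing start dates from the contact log
#'
#' For each episode with a missing start date: compute the eligibility time
#' (end date minus eligibility date); if it is positive, gather the
#' contacts attributable to the episode; if any exist, the first (earliest)
#' contact date becomes the start date with provenance `"recovered"`.
#' Episodes with zero eligibility time or no attributable contacts are left
#' untouched. A recovered start date always lies within
#' `[eligibility_date, end_date]` by construction of the attribution
#' window.
#'
#' @param bundle A `registry_bundle` from which end-date-incomplete
#'   episodes have already been dropped.
#' @return List with `bundle` (start dates filled in, provenance updated)
#'   and `report` (a `recovery_report`; dropped/recovered/untouched
#'   partition the episodes examined).
#' @export
recover_start_dates <- function(bundle) {
  epi <- bundle$episodes
  if (any(is.na(epi$end_date))) {
    stop("run drop_incomplete_episodes() before start-date recovery",
         call. = FALSE)
  }
  missing_start <- which(is.na(epi$start_date))
  contacts <- attribute_contacts(bundle)
  usable <- contacts[!is.na(contacts$episode_id) &
                       !is.na(contacts$contact_date), , drop = FALSE]
  first_contact <- tapply(as.numeric(usable$contact_date),
                          usable$episode_id, min)

  recovered_ids <- character(0)
  for (i in missing_start) {
    elig_time <- as.integer(epi$end_date[i] - epi$eligibility_date[i])
    if (is.na(elig_time) || elig_time <= 0L) next
    fc <- unname(first_contact[epi$episode_id[i]])
    if (length(fc) == 0L || is.na(fc)) next
    epi$start_date[i] <- as.Date(fc, origin = "1970-01-01")
    epi$start_provenance[i] <- "recovered"
    recovered_ids <- c(recovered_ids, epi$episode_id[i])
  }
  untouched_ids <- setdiff(epi$episode_id[missing_start], recovered_ids)

  report <- .recovery_report(
    examined = length(missing_start),
    dropped_keys = character(0),
    recovered_ids = recovered_ids,
    untouched_ids = untouched_ids,
    provenance = data.frame(
      episode_id = c(recovered_ids, untouched_ids),
      action = c(rep("recovered", length(recovered_ids)),
                 rep("untouched", length(untouched_ids))),
      stringsAsFactors = FALSE))
  bundle$episodes <- epi
  bundle <- link_records(bundle)
  list(bundle = bundle, report = report)
}

#' Complete-case drop followed by start-date recovery
#'
#' Convenience wrapper running [drop_incomplete_episodes()] then
#' [recover_start_dates()] and merging the two reports.
#'
#' @inheritParams drop_incomplete_episodes
#' @return List with `bundle` and a merged `recovery_report`.
#' @export
clean_missing <- function(bundle, mechanism = "MCAR") {
  d <- drop_incomplete_episodes(bundle, mechanism = mechanism)
  r <- recover_start_dates(d$bundle)
  report <- .recovery_report(
    examined = d$report$examined,
    dropped_keys = d$report$dropped_keys,
    recovered_ids = r$report$recovered_ids,
    untouched_ids = r$report$untouched_ids,
    provenance = rbind(d$report$provenance, r$report$provenance))
  report$mechanism <- mechanism
  list(bundle = r$bundle, report = report)
}
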