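# Index-date strategies and cross-sectional window cohorts. Three index
# strategies are supported: a common first-eligibility date, an
# enrollment-linked date (intent-to-treat), and a shifted eligibility date
# for the comparison arm (eligibility plus the mean eligibility-to-
# enrollment lag of the treatment arm). Under the first-eligibility special
# case the registry yields four window cohorts: not approached, opt-out,
# completed enrollment, and incomplete enrollment.

.INDEX_STRATEGIES <- c("first_eligibility", "enrollment_linked",
                       "shifted_eligibility")
.WINDOW_COHORTS <- c("not_approached_6m", "opt_out_6m",
                     "completed_enrollment_6m", "incomplete_enrollment_6m")

# First enrolled episode per patient: minimum start date, ties broken by
# minimum eligibility date then episode id.
.first_enrolled <- function(labels, episodes) {
  enr <- labels$labels[labels$labels$status == "enrolled", , drop = FALSE]
  epi <- episodes[episodes$episode_id %in% enr$episode_id, , drop = FALSE]
  epi <- epi[!is.na(epi$start_date), , drop = FALSE]
  if (nrow(epi) == 0L) return(epi)
  epi <- epi[order(epi$patient_id, epi$start_date, epi$eligibility_date,
                   epi$episode_id), , drop = FALSE]
  epi[!duplicated(epi$patient_id), , drop = FALSE]
}

#' Mean eligibility-to-enrollment lag in the treatment arm
#'
#' Arithmetic mean of (start date minus eligibility date), in days, over
#' enrolled episodes carrying both dates. Used by the shifted-eligibility
#' index strategy to give the comparison arm an equivalent follow-up
#' window.
#'
#' @param labels A `cohort_labels` object.
#' @param episodes The episode table.
#' @return Mean lag in days (numeric scalar).
#' @export
mean_eligibility_to_enrollment_lag <- function(labels, episodes) {
  enr <- labels$labels[labels$labels$status == "enrolled", , drop = FALSE]
  epi <- episodes[episodes$episode_id %in% enr$episode_id, , drop = FALSE]
  lags <- as.numeric(epi$start_date - epi$eligibility_date)
  lags <- lags[!is.na(lags)]
  if (length(lags) == 0L) {
    stop("no enrolled episode with both eligibility and start dates; ",
         "the mean lag is undefined", call. = FALSE)
  }
  mean(lags)
}

#' Assign per-patient index dates
#'
#' Strategies:
#' * `first_eligibility` -- every patient is indexed at their earliest
#'   eligibility date, identically in both arms (the common-window special
#'   case).
#' * `enrollment_linked` -- patients with any enrolled episode
#'   (intervention arm) are indexed at the start date of their first
#'   enrolled episode; comparison patients at their configured eligibility
#'   pick (first by default).
#' * `shifted_eligibility` -- intervention patients as under
#'   `enrollment_linked`; comparison patients at their eligibility pick
#'   plus the mean eligibility-to-enrollment lag of the treatment arm,
#'   rounded to the nearest whole day.
#'
#' @param labels A `cohort_labels` object.
#' @param episodes The episode table.
#' @param strategy One of `"first_eligibility"`, `"enrollment_linked"`,
#'   `"shifted_eligibility"`.
#' @param comparison_pick Which eligibility date anchors comparison-arm
#'   patients under the second and third strategies: `"first"` (default)
#'   or `"last"`.
#' @return Data frame of class `index_assignment`: `patient_id`,
#'   `index_date`, `strategy`, `arm`. Patients without a qualifying
#'   episode are excluded (attribute `excluded` lists them).
#' @export
assign_index_dates <- function(labels, episodes,
                               strategy = c("first_eligibility",
                                            "enrollment_linked",
                                            "shifted_eligibility"),
                               comparison_pick = c("first", "last")) {
  strategy <- match.arg(strategy)
  comparison_pick <- match.arg(comparison_pick)
  lab <- labels$labels
  epi <- episodes[episodes$episode_id %in% lab$episode_id, , drop = FALSE]
  patients <- unique(lab$patient_id)
  enrolled_patients <- unique(lab$patient_id[lab$status == "enrolled"])
  arm <- ifelse(patients %in% enrolled_patients, "intervention",
                "comparison")

  safe_agg <- function(fun) {
    agg <- suppressWarnings(
      tapply(as.numeric(epi$eligibility_date), epi$patient_id, fun,
             na.rm = TRUE))
    agg[!is.finite(agg)] <- NA_real_   # patients with no eligibility date
    agg
  }
  pick_elig <- function(pids) {
    agg <- safe_agg(if (comparison_pick == "first") min else max)
    as.Date(as.numeric(agg[pids]), origin = "1970-01-01")
  }

  if (strategy == "first_eligibility") {
    agg <- safe_agg(min)
    index <- as.Date(as.numeric(agg[patients]), origin = "1970-01-01")
  } else {
    fe <- .first_enrolled(labels, episodes)
    start_idx <- fe$start_date[match(patients, fe$patient_id)]
    comp_idx <- pick_elig(patients)
    if (strategy == "shifted_eligibility") {
      lag <- round(mean_eligibility_to_enrollment_lag(labels, episodes))
      comp_idx <- comp_idx + lag
    }
    index <- as.Date(ifelse(arm == "intervention", start_idx, comp_idx),
                     origin = "1970-01-01")
  }

  excluded <- patients[is.na(index)]
  keep <- !is.na(index)
  out <- data.frame(patient_id = patients[keep], index_date = index[keep],
                    strategy = strategy, arm = arm[keep],
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  class(out) <- c("index_assignment", "data.frame")
  out
}

#' Build the four cross-sectional window cohorts
#'
#' Under the first-eligibility index (the special case in which the index
#' date is identical across arms), each patient falls into exactly one of
#' four cohorts over the half-open window `[index, index + window_days)`:
#' completed enrollment (first enrolled episode starts in-window and ends
#' before the window closes), incomplete enrollment (starts in-window,
#' still open at the window close), opt-out (no enrolled episode in-window
#' but an opt-out episode anchored in-window), and not approached
#' (everything else). Enrollment is intent-to-treat: enrolled patients are
#' counted regardless of completing, dropping out, or reaching remission.
#'
#' @param labels A `cohort_labels` object.
#' @param episodes The episode table.
#' @param index An `index_assignment` (strategy `first_eligibility`).
#' @param window_days Window length in days (default 183, i.e. 6 months).
#' @return Data frame of class `window_cohorts`: `patient_id`, `cohort`,
#'   `window_start`, `window_end` (exclusive).
#' @export
build_cross_sectional_cohorts <- function(labels, episodes, index,
                                          window_days = 183) {
  lab <- labels$labels
  missing_idx <- setdiff(unique(lab$patient_id), index$patient_id)
  if (length(missing_idx)) {
    stop("no index date for labeled patient(s): ",
         paste(utils::head(missing_idx, 5), collapse = ", "), call. = FALSE)
  }
  epi <- episodes[match(lab$episode_id, episodes$episode_id), , drop = FALSE]
  epi$status <- lab$status
  idx <- index$index_date[match(epi$patient_id, index$patient_id)]
  wend <- idx + window_days
  # An episode is anchored in-window by its start date when present,
  # otherwise by its eligibility date.
  anchor <- as.Date(ifelse(is.na(epi$start_date),
                           as.numeric(epi$eligibility_date),
                           as.numeric(epi$start_date)),
                    origin = "1970-01-01")
  in_window <- !is.na(anchor) & anchor >= idx & anchor < wend

  cohort <- rep("not_approached_6m", nrow(index))
  names(cohort) <- index$patient_id

  enr <- which(epi$status == "enrolled" & in_window & !is.na(epi$start_date))
  if (length(enr)) {
    e <- epi[enr, , drop = FALSE]
    e$wend <- wend[enr]
    e <- e[order(e$patient_id, e$start_date, e$eligibility_date,
                 e$episode_id), , drop = FALSE]
    first <- e[!duplicated(e$patient_id), , drop = FALSE]
    completed <- !is.na(first$end_date) & first$end_date < first$wend
    cohort[first$patient_id] <- ifelse(completed, "completed_enrollment_6m",
                                       "incomplete_enrollment_6m")
  }
  opt <- unique(epi$patient_id[epi$status == "opt_out" & in_window])
  still_na <- names(cohort)[cohort == "not_approached_6m"]
  cohort[intersect(opt, still_na)] <- "opt_out_6m"

  out <- data.frame(patient_id = index$patient_id,
                    cohort = factor(unname(cohort), levels = .WINDOW_COHORTS),
                    window_start = index$index_date,
                    window_end = index$index_date + window_days,
                    stringsAsFactors = FALSE)
  class(out) <- c("window_cohorts", "data.frame")
  out
}

#' Extract per-patient observation- and outcome-window record slices
#'
#' Returns, for each indexed patient, the episodes, contacts and
#' questionnaire responses falling inside the observation window
#' `[index - observation_days, index)` and the outcome window
#' `[index, index + outcome_days)`. Both windows are half-open: a record
#' dated exactly at the index date belongs to the outcome window.
#' Episodes are anchored by eligibility date, contacts by contact date,
#' questionnaires by recording date.
#'
#' @param bundle A `registry_bundle`.
#' @param index An `index_assignment`.
#' @param observation_days,outcome_days Window lengths in days.
#' @return Named list (one element per patient), each with `observation`
#'   and `outcome` sublists of `episodes`, `contacts`, `questionnaires`.
#' @export
extract_window_records <- function(bundle, index, observation_days = 183,
                                   outcome_days = 183) {
  slice <- function(df, date_col, lo, hi) {
    d <- df[[date_col]]
    df[!is.na(d) & d >= lo & d < hi, , drop = FALSE]
  }
  out <- lapply(seq_len(nrow(index)), function(i) {
    pid <- index$patient_id[i]
    idx <- index$index_date[i]
    epi <- bundle$episodes[bundle$episodes$patient_id == pid, , drop = FALSE]
    con <- bundle$contacts[bundle$contacts$patient_id == pid, , drop = FALSE]
    que <- bundle$questionnaires[bundle$questionnaires$patient_id == pid, ,
                                 drop = FALSE]
    list(
      observation = list(
        episodes = slice(epi, "eligibility_date", idx - observation_days, idx),
        contacts = slice(con, "contact_date", idx - observation_days, idx),
        questionnaires = slice(que, "recording_date",
                               idx - observation_days, idx)),
      outcome = list(
        episodes = slice(epi, "eligibility_date", idx, idx + outcome_days),
        contacts = slice(con, "contact_date", idx, idx + outcome_days),
        questionnaires = slice(que, "recording_date", idx,
                               idx + outcome_days)))
  })
  names(out) <- index$patient_id
  out
}
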