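# Hand-built fixtures and independent brute-force oracles. The oracles
# deliberately use naive per-row loops so they share no code with the
# vectorized implementations they check.

d <- function(x) as.Date(x)

make_demographics <- function(patient_id,
                              birth_date = rep("1980-01-01",
                                               length(patient_id)),
                              consent = TRUE, bipolar = FALSE) {
  data.frame(patient_id = patient_id, birth_date = birth_date,
             sex = "female", race = "White", marital_status = "Married",
             employment_status = "yes", consent = consent,
             bipolar_history = bipolar, depression_diagnosis = TRUE,
             stringsAsFactors = FALSE)
}

make_episodes <- function(episode_id, patient_id, eligibility, start, end,
                          recorded_status = NA_character_) {
  data.frame(episode_id = episode_id, patient_id = patient_id,
             eligibility_date = eligibility, start_date = start,
             end_date = end, recorded_status = recorded_status,
             stringsAsFactors = FALSE)
}

make_contacts <- function(patient_id = character(0),
                          contact_date = character(0),
                          time_spent = numeric(0)) {
  data.frame(patient_id = patient_id, contact_date = contact_date,
             time_spent = time_spent, stringsAsFactors = FALSE)
}

make_phq9 <- function(patient_id, recording_date, total,
                      items = NULL, instrument = "PHQ9") {
  n <- length(patient_id)
  if (is.null(items)) {
    items <- t(vapply(total, function(t) {
      v <- integer(9)
      while (sum(v) < t) {
        i <- which(v < 3)[1]
        v[i] <- v[i] + 1L
      }
      v
    }, integer(9)))
  }
  df <- data.frame(patient_id = patient_id,
                   instrument = rep(instrument, length.out = n),
                   stringsAsFactors = FALSE)
  colnames(items) <- paste0("item_", 1:9)
  df <- cbind(df, as.data.frame(items))
  df$total <- total
  df$recording_date <- recording_date
  df
}

empty_contacts <- function() make_contacts()
empty_phq9 <- function() {
  make_phq9(character(0), character(0), integer(0),
            items = matrix(integer(0), ncol = 9))
}

# A five-patient clinic fixture exercising every status pathway.
clinic_fixture <- function() {
  demographics <- make_demographics(paste0("P", 1:5))
  episodes <- make_episodes(
    episode_id = paste0("E", 1:6),
    patient_id = c("P1", "P1", "P2", "P3", "P4", "P5"),
    eligibility = c("2010-01-01", "2012-01-01", "2011-04-01", "2013-01-01",
                    "2010-03-01", "2014-01-01"),
    start = c("2010-01-10", "2012-01-05", NA, NA, "2010-03-01", NA),
    end = c("2010-06-01", "2012-03-01", "2011-10-01", "2013-05-01",
            "2010-05-30", "2014-06-01"))
  contacts <- make_contacts(
    patient_id = c("P1", "P1", "P2", "P2", "P4"),
    contact_date = c("2010-02-01", "2010-03-01", "2011-05-01", "2011-06-01",
                     "2010-04-01"),
    time_spent = c(30, 15, 20, 10, 45))
  questionnaires <- make_phq9(
    patient_id = paste0("P", c(1, 1, 2, 3, 4, 5)),
    recording_date = c("2010-01-01", "2012-01-01", "2011-04-01",
                       "2013-01-01", "2010-03-01", "2014-01-01"),
    total = c(12, 15, 11, 20, 14, 10))
  registry_bundle(demographics, episodes, contacts, questionnaires)
}

# --- brute-force oracles ------------------------------------------------

# Episode a dated record belongs to: scan the patient's episodes one by
# one, keep those whose closed window covers the date, take the one with
# the greatest eligibility date (first episode id on ties).
bf_attribute_one <- function(episodes, pid, date) {
  best <- NA_character_
  best_elig <- as.Date(NA)
  if (is.na(date)) return(best)
  for (i in seq_len(nrow(episodes))) {
    if (episodes$patient_id[i] != pid) next
    elig <- episodes$eligibility_date[i]
    end <- episodes$end_date[i]
    if (is.na(elig) || is.na(end)) next
    if (date < elig || date > end) next
    better <- is.na(best_elig) || elig > best_elig ||
      (elig == best_elig && episodes$episode_id[i] < best)
    if (better) {
      best <- episodes$episode_id[i]
      best_elig <- elig
    }
  }
  best
}

# Full metric re-derivation scanning all contacts per patient.
bf_metrics <- function(bundle) {
  epi <- bundle$episodes
  ct <- bundle$contacts
  out <- data.frame(episode_id = epi$episode_id,
                    activation_time_days = NA_integer_,
                    eligibility_time_days = NA_integer_,
                    ce_time_days = NA_integer_,
                    contact_frequency = 0L,
                    total_time_spent_min = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(epi))) {
    if (!is.na(epi$start_date[i])) {
      out$activation_time_days[i] <-
        as.integer(epi$end_date[i] - epi$start_date[i])
    } else {
      out$eligibility_time_days[i] <-
        as.integer(epi$end_date[i] - epi$eligibility_date[i])
    }
    first <- as.Date(NA)
    for (j in seq_len(nrow(ct))) {
      if (ct$patient_id[j] != epi$patient_id[i]) next
      owner <- bf_attribute_one(epi, ct$patient_id[j], ct$contact_date[j])
      if (is.na(owner) || owner != epi$episode_id[i]) next
      out$contact_frequency[i] <- out$contact_frequency[i] + 1L
      if (!is.na(ct$time_spent[j])) {
        out$total_time_spent_min[i] <-
          out$total_time_spent_min[i] + ct$time_spent[j]
      }
      if (is.na(first) || ct$contact_date[j] < first) {
        first <- ct$contact_date[j]
      }
    }
    if (identical(epi$start_provenance[i], "recovered") && !is.na(first)) {
      out$ce_time_days[i] <- as.integer(epi$end_date[i] - first)
    }
  }
  out
}

# Window-cohort assignment by scanning each patient's episodes.
bf_window_cohorts <- function(labels, episodes, index, window_days = 183) {
  lab <- labels$labels
  out <- character(nrow(index))
  for (k in seq_len(nrow(index))) {
    pid <- index$patient_id[k]
    idx <- index$index_date[k]
    hi <- idx + window_days
    rows <- which(lab$patient_id == pid)
    best_enr <- NULL
    has_opt <- FALSE
    for (r in rows) {
      e <- episodes[episodes$episode_id == lab$episode_id[r], ]
      anchor <- if (is.na(e$start_date)) e$eligibility_date else e$start_date
      inw <- !is.na(anchor) && anchor >= idx && anchor < hi
      if (!inw) next
      if (lab$status[r] == "enrolled" && !is.na(e$start_date)) {
        if (is.null(best_enr) ||
            e$start_date < best_enr$start_date ||
            (e$start_date == best_enr$start_date &&
               e$eligibility_date < best_enr$eligibility_date) ||
            (e$start_date == best_enr$start_date &&
               e$eligibility_date == best_enr$eligibility_date &&
               e$episode_id < best_enr$episode_id)) {
          best_enr <- e
        }
      } else if (lab$status[r] == "opt_out") {
        has_opt <- TRUE
      }
    }
    out[k] <- if (!is.null(best_enr)) {
      if (!is.na(best_enr$end_date) && best_enr$end_date < hi) {
        "completed_enrollment_6m"
      } else "incomplete_enrollment_6m"
    } else if (has_opt) "opt_out_6m" else "not_approached_6m"
  }
  out
}
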