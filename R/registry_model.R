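# Column contracts for the four linked registry tables. Loading is strict
# about mandatory columns and lenient about values: unparseable dates become
# NA (and are logged on the bundle), no row is ever dropped at load time.

.REGISTRY_TABLES <- c("demographics", "episodes", "contacts", "questionnaires")

.MANDATORY_COLUMNS <- list(
  demographics = c("patient_id", "birth_date", "sex", "race", "marital_status",
                   "employment_status", "consent", "bipolar_history",
                   "depression_diagnosis"),
  episodes = c("episode_id", "patient_id", "eligibility_date", "start_date",
               "end_date", "recorded_status"),
  contacts = c("patient_id", "contact_date", "time_spent"),
  questionnaires = c("patient_id", "instrument", paste0("item_", 1:9),
                     "total", "recording_date")
)

.DATE_COLUMNS <- list(
  demographics = "birth_date",
  episodes = c("eligibility_date", "start_date", "end_date"),
  contacts = "contact_date",
  questionnaires = "recording_date"
)

# Sentinel used when a missing start date participates in the composite
# episode key (patient_id, eligibility_date, start_date).
.KEY_SENTINEL <- "<missing>"

#' Delimited-text dialect for registry tables
#'
#' @param sep Field separator (default comma).
#' @param date_format Date format string understood by [base::as.Date()]
#'   (default ISO-8601, `"%Y-%m-%d"`).
#' @param na_strings Strings read as missing values.
#' @return A list of class `registry_dialect`.
#' @export
registry_dialect <- function(sep = ",", date_format = "%Y-%m-%d",
                             na_strings = c("", "NA")) {
  structure(list(sep = sep, date_format = date_format,
                 na_strings = na_strings),
            class = "registry_dialect")
}

.parse_dates <- function(df, cols, fmt, table) {
  log <- list()
  for (col in cols) {
    if (inherits(df[[col]], "Date")) next
    raw <- as.character(df[[col]])
    parsed <- as.Date(raw, format = fmt)
    bad <- !is.na(raw) & raw != "" & is.na(parsed)
    if (any(bad)) {
      log[[length(log) + 1L]] <- data.frame(
        table = table, column = col, row = which(bad),
        value = raw[bad], stringsAsFactors = FALSE)
    }
    df[[col]] <- parsed
  }
  list(df = df, log = log)
}

.as_logical_col <- function(x) {
  if (is.logical(x)) return(x)
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "t", "yes", "1")] <- TRUE
  out[lx %in% c("false", "f", "no", "0")] <- FALSE
  out
}

#' Construct a registry bundle from the four tables
#'
#' A `registry_bundle` holds the four linked tables of a collaborative-care
#' registry (demographics, care-episode table, contact log, questionnaires)
#' plus a linkage map over the composite episode key
#' `(patient_id, eligibility_date, start_date)`. Construction validates
#' structure only; value-level problems are the business of the
#' data-quality engine, never fatal here.
#'
#' @param demographics,episodes,contacts,questionnaires Data frames with the
#'   documented columns. Date columns may be `Date` or character in the
#'   dialect's format.
#' @param dialect A [registry_dialect()].
#' @return An object of class `registry_bundle`.
#' @export
registry_bundle <- function(demographics, episodes, contacts, questionnaires,
                            dialect = registry_dialect()) {
  tables <- list(demographics = demographics, episodes = episodes,
                 contacts = contacts, questionnaires = questionnaires)
  parse_log <- list()
  for (tab in .REGISTRY_TABLES) {
    df <- as.data.frame(tables[[tab]], stringsAsFactors = FALSE)
    missing_cols <- setdiff(.MANDATORY_COLUMNS[[tab]], names(df))
    if (length(missing_cols) > 0L) {
      stop(sprintf("table '%s' is missing mandatory column(s): %s",
                   tab, paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    res <- .parse_dates(df, .DATE_COLUMNS[[tab]], dialect$date_format, tab)
    df <- res$df
    parse_log <- c(parse_log, res$log)
    tables[[tab]] <- df
  }

  epi <- tables$episodes
  if (anyDuplicated(epi$episode_id)) {
    stop("duplicate episode_id in episode table: ",
         paste(unique(epi$episode_id[duplicated(epi$episode_id)]),
               collapse = ", "), call. = FALSE)
  }
  for (col in c("consent", "bipolar_history", "depression_diagnosis")) {
    tables$demographics[[col]] <- .as_logical_col(tables$demographics[[col]])
  }
  tables$contacts$time_spent <- as.numeric(tables$contacts$time_spent)
  for (col in c(paste0("item_", 1:9), "total")) {
    tables$questionnaires[[col]] <- suppressWarnings(
      as.numeric(tables$questionnaires[[col]]))
  }
  rs <- as.character(tables$episodes$recorded_status)
  rs[!is.na(rs) & (rs == "" | tolower(rs) == "none")] <- NA_character_
  tables$episodes$recorded_status <- rs
  if (!"start_provenance" %in% names(tables$episodes)) {
    tables$episodes$start_provenance <-
      ifelse(is.na(tables$episodes$start_date), "missing", "recorded")
  }
  # Stable per-row identifiers for the child tables (used by the violation
  # ledger); synthesised when absent, preserved when present.
  if (!"contact_id" %in% names(tables$contacts)) {
    tables$contacts$contact_id <-
      sprintf("C%06d", seq_len(nrow(tables$contacts)))
  }
  if (!"response_id" %in% names(tables$questionnaires)) {
    tables$questionnaires$response_id <-
      sprintf("Q%06d", seq_len(nrow(tables$questionnaires)))
  }
  rownames(tables$demographics) <- NULL
  rownames(tables$episodes) <- NULL
  rownames(tables$contacts) <- NULL
  rownames(tables$questionnaires) <- NULL

  bundle <- structure(list(
    demographics = tables$demographics,
    episodes = tables$episodes,
    contacts = tables$contacts,
    questionnaires = tables$questionnaires,
    linkage = NULL,
    orphans = NULL,
    dialect = dialect,
    parse_log = if (length(parse_log)) do.call(rbind, parse_log) else NULL
  ), class = "registry_bundle")
  link_records(bundle)
}

#' @export
print.registry_bundle <- function(x, ...) {
  cat("<registry_bundle>\n")
  cat(sprintf("  demographics:   %6d patients\n", nrow(x$demographics)))
  cat(sprintf("  episodes:       %6d patient instances\n", nrow(x$episodes)))
  cat(sprintf("  contacts:       %6d contact records\n", nrow(x$contacts)))
  cat(sprintf("  questionnaires: %6d responses\n", nrow(x$questionnaires)))
  if (!is.null(x$orphans) && nrow(x$orphans) > 0L) {
    cat(sprintf("  orphans:        %6d unlinked rows\n", nrow(x$orphans)))
  }
  invisible(x)
}

#' Load a registry bundle from delimited-text files
#'
#' @param paths Either a directory containing `demographics.csv`,
#'   `episodes.csv`, `contacts.csv` and `questionnaires.csv`, or a named
#'   list/character vector with one path per table.
#' @param dialect A [registry_dialect()].
#' @return A `registry_bundle`. Row counts equal the file row counts:
#'   loading never drops records; unparseable dates become `NA` and are
#'   recorded in the bundle's `parse_log`.
#' @export
load_registry <- function(paths, dialect = registry_dialect()) {
  if (is.character(paths) && length(paths) == 1L && dir.exists(paths)) {
    paths <- file.path(paths, paste0(.REGISTRY_TABLES, ".csv"))
    names(paths) <- .REGISTRY_TABLES
  }
  paths <- as.list(paths)
  missing_tabs <- setdiff(.REGISTRY_TABLES, names(paths))
  if (length(missing_tabs)) {
    stop("no path given for table(s): ", paste(missing_tabs, collapse = ", "),
         call. = FALSE)
  }
  tables <- lapply(.REGISTRY_TABLES, function(tab) {
    path <- paths[[tab]]
    if (!file.exists(path)) {
      stop(sprintf("registry file not found: %s (%s table)", path, tab),
           call. = FALSE)
    }
    utils::read.table(path, header = TRUE, sep = dialect$sep,
                      na.strings = dialect$na_strings,
                      colClasses = "character", stringsAsFactors = FALSE,
                      check.names = FALSE, quote = "\"", comment.char = "")
  })
  names(tables) <- .REGISTRY_TABLES
  registry_bundle(tables$demographics, tables$episodes, tables$contacts,
                  tables$questionnaires, dialect = dialect)
}

#' Write a registry bundle to delimited-text files
#'
#' Inverse of [load_registry()]: on a clean bundle the round trip is
#' lossless row-for-row and value-for-value.
#'
#' @param bundle A `registry_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_registry <- function(bundle, dir) {
  stopifnot(inherits(bundle, "registry_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- bundle$dialect$date_format
  out <- character(0)
  for (tab in .REGISTRY_TABLES) {
    df <- bundle[[tab]]
    for (col in .DATE_COLUMNS[[tab]]) df[[col]] <- format(df[[col]], fmt)
    path <- file.path(dir, paste0(tab, ".csv"))
    utils::write.table(df, path, sep = bundle$dialect$sep, na = "",
                       row.names = FALSE, quote = TRUE)
    out[tab] <- path
  }
  invisible(out)
}

#' Resolve cross-table linkage and report orphans
#'
#' Builds the linkage map from composite episode keys
#' `(patient_id, eligibility_date, start_date)` to episode ids, and lists
#' rows that cannot be attached to a demographics patient. Orphans are
#' reported, never dropped.
#'
#' @param bundle A `registry_bundle`.
#' @return The bundle with `$linkage` (data frame of composite keys) and
#'   `$orphans` (data frame `table`, `row_id`, `patient_id`) populated.
#' @export
link_records <- function(bundle) {
  epi <- bundle$episodes
  key <- composite_episode_key(epi)
  bundle$linkage <- data.frame(
    patient_id = epi$patient_id,
    eligibility_date = epi$eligibility_date,
    start_date = epi$start_date,
    key = key,
    episode_id = epi$episode_id,
    stringsAsFactors = FALSE)

  known <- unique(bundle$demographics$patient_id)
  orphan <- function(df, table, row_id) {
    bad <- !(df$patient_id %in% known)
    if (!any(bad)) return(NULL)
    data.frame(table = table, row_id = row_id[bad],
               patient_id = df$patient_id[bad], stringsAsFactors = FALSE)
  }
  orphans <- rbind(
    orphan(bundle$episodes, "episodes", bundle$episodes$episode_id),
    orphan(bundle$contacts, "contacts", bundle$contacts$contact_id),
    orphan(bundle$questionnaires, "questionnaires",
           bundle$questionnaires$response_id))
  bundle$orphans <- if (is.null(orphans)) {
    data.frame(table = character(0), row_id = character(0),
               patient_id = character(0), stringsAsFactors = FALSE)
  } else orphans
  bundle
}

#' Composite episode key
#'
#' The episode identifier triplet used for relational mapping across tables:
#' patient id, eligibility date, start date. A missing start date is a legal
#' key component, encoded by a sentinel.
#'
#' @param episodes The episode table of a bundle.
#' @return Character vector of keys, one per episode row.
#' @export
composite_episode_key <- function(episodes) {
  sd <- ifelse(is.na(episodes$start_date), .KEY_SENTINEL,
               format(episodes$start_date, "%Y-%m-%d"))
  ed <- ifelse(is.na(episodes$eligibility_date), .KEY_SENTINEL,
               format(episodes$eligibility_date, "%Y-%m-%d"))
  paste(episodes$patient_id, ed, sd, sep = "|")
}

# Attribute child rows (contacts / questionnaires) to episodes.
# A row belongs to an episode when its date falls inside the closed
# interval [eligibility_date, end_date]; when several episodes of one
# patient qualify, the episode with the latest eligibility_date not after
# the row's date wins (ties broken by episode_id order).
.attribute_rows <- function(episodes, df, id_col, date_col) {
  out <- rep(NA_character_, nrow(df))
  if (nrow(df) == 0L || nrow(episodes) == 0L) return(out)
  ok <- !is.na(df[[date_col]]) & !is.na(df$patient_id)
  epi <- episodes[!is.na(episodes$eligibility_date) &
                    !is.na(episodes$end_date), , drop = FALSE]
  if (!any(ok) || nrow(epi) == 0L) return(out)
  cand <- merge(
    data.frame(idx = which(ok), patient_id = df$patient_id[ok],
               date = df[[date_col]][ok], stringsAsFactors = FALSE),
    epi[, c("patient_id", "episode_id", "eligibility_date", "end_date")],
    by = "patient_id")
  cand <- cand[cand$date >= cand$eligibility_date &
                 cand$date <= cand$end_date, , drop = FALSE]
  if (nrow(cand) == 0L) return(out)
  cand <- cand[order(cand$idx, cand$eligibility_date, cand$episode_id,
                     decreasing = c(FALSE, TRUE, FALSE),
                     method = "radix"), , drop = FALSE]
  cand <- cand[!duplicated(cand$idx), , drop = FALSE]
  out[cand$idx] <- cand$episode_id
  out
}

#' Attribute contact records to episodes
#'
#' A contact belongs to an episode when its date lies in the closed window
#' `[eligibility_date, end_date]`; among overlapping episodes of the same
#' patient the one with the latest eligibility date not after the contact
#' wins. Contacts with a missing date are never attributed (they are
#' retained in the table but excluded from frequency/duration computation).
#'
#' @param bundle A `registry_bundle`.
#' @return The contact table with an `episode_id` column (`NA` where no
#'   episode window covers the contact).
#' @export
attribute_contacts <- function(bundle) {
  contacts <- bundle$contacts
  contacts$episode_id <- .attribute_rows(bundle$episodes, contacts,
                                         "contact_id", "contact_date")
  contacts
}

#' Attribute questionnaire responses to episodes
#'
#' Same attribution policy as [attribute_contacts()], keyed on the
#' recording date.
#'
#' @param bundle A `registry_bundle`.
#' @return The questionnaire table with an `episode_id` column.
#' @export
attribute_questionnaires <- function(bundle) {
  q <- bundle$questionnaires
  q$episode_id <- .attribute_rows(bundle$episodes, q, "response_id",
                                  "recording_date")
  q
}
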