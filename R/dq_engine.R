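# Declarative data-quality engine organised around five rule families:
# attribute domain constraints, relational integrity, historical data rules,
# state-dependent object rules, and attribute dependency rules. Each family
# maps to a fixed subset of the quality dimensions (accuracy, completeness,
# consistency, validity, uniqueness); timeliness is deliberately out of
# scope. Every value the engine changes is traceable to exactly one entry
# in the violation ledger.

.DQ_FAMILIES <- c("attribute_domain", "relational_integrity",
                  "historical_data", "state_dependent",
                  "attribute_dependency")

.FAMILY_DIMENSIONS <- list(
  attribute_domain     = c("accuracy", "consistency", "validity", "completeness"),
  relational_integrity = c("consistency", "uniqueness", "completeness"),
  historical_data      = c("accuracy", "consistency", "validity", "completeness"),
  state_dependent      = c("completeness", "consistency", "uniqueness", "accuracy"),
  attribute_dependency = "accuracy"
)

.DQ_DIMENSIONS <- c("accuracy", "completeness", "consistency", "validity",
                    "uniqueness")

#' Default free-text normalization dictionary for employment status
#'
#' Maps free-text answers about current employment status onto the
#' normalized yes/no domain. User-extensible; unknown free text is set to
#' missing with a flag.
#'
#' @return Named character vector: names are lower-cased free-text answers,
#'   values are the normalized codes.
#' @export
employment_normalization <- function() {
  c("yes" = "yes", "no" = "no",
    "i am employed" = "yes",
    "i am looking for a job" = "no")
}

.new_rule <- function(rule_id, family, dimension, table, column,
                      params = list()) {
  stopifnot(family %in% .DQ_FAMILIES,
            dimension %in% .FAMILY_DIMENSIONS[[family]])
  structure(list(rule_id = rule_id, family = family, dimension = dimension,
                 table = table, column = column, params = params),
            class = "quality_rule")
}

#' Default data-quality ruleset
#'
#' The shipped rules instantiate all five rule families on the
#' depression-registry schema: questionnaire item/total domains,
#' employment free-text normalization, composite-key uniqueness and
#' cross-table orphan checks, date-ordering rules (birth before all
#' events, start before end), state-dependent checks (an end date implies
#' an eligibility date; baseline questionnaires precede enrollment), and
#' the aggregate-consistency rule that a PHQ-9 total equals the sum of its
#' nine items.
#'
#' @param phq_item_repair Action for an out-of-domain questionnaire item:
#'   `"set_missing"` (default) or `"flag"` only.
#' @param total_repair Action when a PHQ-9 total disagrees with the item
#'   sum: `"recompute"` (default, total recomputed from items) or
#'   `"set_missing"`.
#' @param normalization Free-text normalization dictionary, as returned by
#'   [employment_normalization()].
#' @return A list of class `quality_ruleset`.
#' @export
default_ruleset <- function(phq_item_repair = c("set_missing", "flag"),
                            total_repair = c("recompute", "set_missing"),
                            normalization = employment_normalization()) {
  phq_item_repair <- match.arg(phq_item_repair)
  total_repair <- match.arg(total_repair)
  rules <- list(
    .new_rule("phq9_item_domain", "attribute_domain", "validity",
              "questionnaires", paste0("item_", 1:9),
              list(domain = 0:3, instrument = "PHQ9",
                   repair = phq_item_repair)),
    .new_rule("phq9_total_domain", "attribute_domain", "validity",
              "questionnaires", "total",
              list(domain = 0:27, instrument = "PHQ9", repair = "flag")),
    .new_rule("time_spent_domain", "attribute_domain", "validity",
              "contacts", "time_spent",
              list(min = 0, repair = "set_missing")),
    .new_rule("employment_domain", "attribute_domain", "consistency",
              "demographics", "employment_status",
              list(dictionary = normalization)),
    .new_rule("episode_key_unique", "relational_integrity", "uniqueness",
              "episodes", "episode_key", list()),
    .new_rule("demographics_unique", "relational_integrity", "uniqueness",
              "demographics", "patient_id", list()),
    .new_rule("orphan_child_rows", "relational_integrity", "consistency",
              c("contacts", "questionnaires"), "patient_id", list()),
    .new_rule("episode_has_patient", "relational_integrity", "completeness",
              "episodes", "patient_id", list()),
    .new_rule("birth_before_events", "historical_data", "accuracy",
              "demographics", "birth_date", list()),
    .new_rule("start_before_end", "historical_data", "consistency",
              "episodes", c("start_date", "end_date"), list()),
    .new_rule("eligibility_before_end", "historical_data", "consistency",
              "episodes", c("eligibility_date", "end_date"), list()),
    .new_rule("enrolled_has_contact", "historical_data", "completeness",
              "episodes", "episode_id", list()),
    .new_rule("end_requires_eligibility", "state_dependent", "completeness",
              "episodes", "eligibility_date", list()),
    .new_rule("baseline_before_enrollment", "state_dependent", "consistency",
              "questionnaires", "recording_date", list()),
    .new_rule("phq9_total_equals_items", "attribute_dependency", "accuracy",
              "questionnaires", "total", list(repair = total_repair))
  )
  names(rules) <- vapply(rules, `[[`, "", "rule_id")
  structure(rules, class = "quality_ruleset")
}

#' Read a ruleset from a YAML file
#'
#' The file holds one entry per rule with fields `rule_id`, `family`,
#' `dimension`, `table`, `column` and optional `params` (domain bounds,
#' repair action, normalization dictionary). See
#' `system.file("extdata", "default_rules.yaml", package = "regforge")`.
#'
#' @param path Path to a YAML ruleset.
#' @return A `quality_ruleset`.
#' @export
read_ruleset <- function(path) {
  raw <- yaml::read_yaml(path)
  rules <- lapply(raw$rules, function(r) {
    params <- if (is.null(r$params)) list() else r$params
    if (!is.null(params$domain)) params$domain <- as.numeric(params$domain)
    if (!is.null(params$dictionary)) {
      params$dictionary <- unlist(params$dictionary)
    }
    .new_rule(r$rule_id, r$family, r$dimension, unlist(r$table),
              unlist(r$column), params)
  })
  names(rules) <- vapply(rules, `[[`, "", "rule_id")
  structure(rules, class = "quality_ruleset")
}

.empty_violations <- function() {
  data.frame(rule_id = character(0), family = character(0),
             dimension = character(0), table = character(0),
             row_id = character(0), column = character(0),
             observed = character(0), action = character(0),
             message = character(0), stringsAsFactors = FALSE)
}

.violation <- function(rule, table, row_id, column, observed, action,
                       message) {
  n <- length(row_id)
  if (n == 0L) return(NULL)
  data.frame(rule_id = rule$rule_id, family = rule$family,
             dimension = rule$dimension, table = table,
             row_id = as.character(row_id), column = column,
             observed = as.character(observed), action = action,
             message = message, stringsAsFactors = FALSE)
}

.bind_violations <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (length(lst) == 0L) return(.empty_violations())
  do.call(rbind, lst)
}

#' Check attribute domain constraints
#'
#' Flags values outside their declared domains (questionnaire items 0-3,
#' totals 0-27, non-negative contact minutes) and normalizes free-text
#' categorical answers (employment status) through the configured
#' dictionary. Out-of-domain questionnaire items are set to missing by
#' default; unknown free text is set to missing with a flag.
#'
#' @param bundle A `registry_bundle`.
#' @param ruleset A `quality_ruleset` (default [default_ruleset()]).
#' @return List with `bundle` (normalized) and `violations` (ledger rows).
#' @export
check_attribute_domain <- function(bundle, ruleset = default_ruleset()) {
  v <- list()
  q <- bundle$questionnaires

  rule <- ruleset$phq9_item_domain
  if (!is.null(rule)) {
    for (col in rule$column) {
      if (!col %in% names(q)) {
        stop(sprintf("rule '%s' targets absent column '%s'",
                     rule$rule_id, col), call. = FALSE)
      }
      is_phq <- q$instrument == rule$params$instrument
      bad <- which(is_phq & !is.na(q[[col]]) &
                     !(q[[col]] %in% rule$params$domain))
      if (length(bad)) {
        act <- if (rule$params$repair == "set_missing") "set_missing" else "flagged"
        v[[length(v) + 1L]] <- .violation(
          rule, "questionnaires", q$response_id[bad], col, q[[col]][bad],
          act, "questionnaire item outside domain 0-3")
        if (rule$params$repair == "set_missing") q[[col]][bad] <- NA_real_
      }
    }
  }

  rule <- ruleset$phq9_total_domain
  if (!is.null(rule)) {
    is_phq <- q$instrument == rule$params$instrument
    bad <- which(is_phq & !is.na(q$total) &
                   !(q$total %in% rule$params$domain))
    v[[length(v) + 1L]] <- .violation(
      rule, "questionnaires", q$response_id[bad], "total", q$total[bad],
      "flagged", "questionnaire total outside domain 0-27")
  }
  bundle$questionnaires <- q

  rule <- ruleset$time_spent_domain
  if (!is.null(rule)) {
    ct <- bundle$contacts
    bad <- which(!is.na(ct$time_spent) & ct$time_spent < rule$params$min)
    if (length(bad)) {
      v[[length(v) + 1L]] <- .violation(
        rule, "contacts", ct$contact_id[bad], "time_spent",
        ct$time_spent[bad], "set_missing", "negative contact duration")
      ct$time_spent[bad] <- NA_real_
      bundle$contacts <- ct
    }
  }

  rule <- ruleset$employment_domain
  if (!is.null(rule)) {
    dict <- rule$params$dictionary
    dem <- bundle$demographics
    raw <- dem$employment_status
    key <- tolower(trimws(as.character(raw)))
    needs <- !is.na(raw) & !(raw %in% c("yes", "no"))
    mapped <- unname(dict[key])
    norm <- which(needs & !is.na(mapped))
    unk <- which(needs & is.na(mapped))
    if (length(norm)) {
      v[[length(v) + 1L]] <- .violation(
        rule, "demographics", dem$patient_id[norm], "employment_status",
        raw[norm], "normalized",
        sprintf("free-text employment answer normalized to '%s'",
                mapped[norm]))
      dem$employment_status[norm] <- mapped[norm]
    }
    if (length(unk)) {
      v[[length(v) + 1L]] <- .violation(
        rule, "demographics", dem$patient_id[unk], "employment_status",
        raw[unk], "set_missing", "unrecognized employment answer")
      dem$employment_status[unk] <- NA_character_
    }
    bundle$demographics <- dem
  }

  list(bundle = bundle, violations = .bind_violations(v))
}

#' Check relational integrity
#'
#' Flags duplicate composite episode keys and duplicated demographics
#' patients (uniqueness), orphan contact/questionnaire rows (consistency),
#' and episodes lacking a demographics row (completeness). Nothing is
#' repaired; relational defects require human review.
#'
#' @inheritParams check_attribute_domain
#' @return List with `bundle` (unchanged, linkage refreshed) and
#'   `violations`.
#' @export
check_relational_integrity <- function(bundle, ruleset = default_ruleset()) {
  bundle <- link_records(bundle)
  v <- list()

  rule <- ruleset$episode_key_unique
  if (!is.null(rule)) {
    key <- bundle$linkage$key
    dup <- which(duplicated(key))
    v[[length(v) + 1L]] <- .violation(
      rule, "episodes", bundle$linkage$episode_id[dup], "episode_key",
      key[dup], "flagged", "duplicate composite episode key")
  }

  rule <- ruleset$demographics_unique
  if (!is.null(rule)) {
    pid <- bundle$demographics$patient_id
    dup <- which(duplicated(pid))
    v[[length(v) + 1L]] <- .violation(
      rule, "demographics", pid[dup], "patient_id", pid[dup], "flagged",
      "patient duplicated in demographics")
  }

  rule <- ruleset$orphan_child_rows
  if (!is.null(rule) && nrow(bundle$orphans)) {
    orp <- bundle$orphans[bundle$orphans$table %in%
                            c("contacts", "questionnaires"), , drop = FALSE]
    v[[length(v) + 1L]] <- .violation(
      rule, orp$table, orp$row_id, "patient_id", orp$patient_id, "flagged",
      "row references a patient absent from demographics")
  }

  rule <- ruleset$episode_has_patient
  if (!is.null(rule) && nrow(bundle$orphans)) {
    orp <- bundle$orphans[bundle$orphans$table == "episodes", , drop = FALSE]
    v[[length(v) + 1L]] <- .violation(
      rule, "episodes", orp$row_id, "patient_id", orp$patient_id, "flagged",
      "episode has no demographics row")
  }

  list(bundle = bundle, violations = .bind_violations(v))
}

#' Check historical data rules
#'
#' Date-ordering rules: a birth date must precede every event recorded for
#' the same patient; an episode's start date must not follow its end date,
#' nor its eligibility date its end date (equality is legal: the minimum
#' observed activation time is 0 days). Episodes explicitly recorded as
#' enrolled must have at least one attributable contact, otherwise the
#' contact date is labeled missing.
#'
#' @inheritParams check_attribute_domain
#' @return List with `bundle` (unchanged) and `violations`.
#' @export
check_historical_rules <- function(bundle, ruleset = default_ruleset()) {
  v <- list()
  epi <- bundle$episodes
  dem <- bundle$demographics

  rule <- ruleset$birth_before_events
  if (!is.null(rule)) {
    events <- rbind(
      data.frame(patient_id = epi$patient_id, date = epi$eligibility_date),
      data.frame(patient_id = epi$patient_id, date = epi$start_date),
      data.frame(patient_id = epi$patient_id, date = epi$end_date),
      data.frame(patient_id = bundle$contacts$patient_id,
                 date = bundle$contacts$contact_date),
      data.frame(patient_id = bundle$questionnaires$patient_id,
                 date = bundle$questionnaires$recording_date))
    events <- events[!is.na(events$date), , drop = FALSE]
    if (nrow(events)) {
      first_event <- tapply(events$date, events$patient_id, min)
      fe <- as.Date(as.numeric(first_event), origin = "1970-01-01")
      idx <- match(dem$patient_id, names(first_event))
      bad <- which(!is.na(dem$birth_date) & !is.na(idx) &
                     dem$birth_date > fe[idx])
      v[[length(v) + 1L]] <- .violation(
        rule, "demographics", dem$patient_id[bad], "birth_date",
        format(dem$birth_date[bad]), "flagged",
        "birth date after an event recorded for the patient")
    }
  }

  rule <- ruleset$start_before_end
  if (!is.null(rule)) {
    bad <- which(!is.na(epi$start_date) & !is.na(epi$end_date) &
                   epi$start_date > epi$end_date)
    v[[length(v) + 1L]] <- .violation(
      rule, "episodes", epi$episode_id[bad], "start_date",
      format(epi$start_date[bad]), "flagged",
      "start date after end date (negative activation time)")
  }

  rule <- ruleset$eligibility_before_end
  if (!is.null(rule)) {
    bad <- which(!is.na(epi$eligibility_date) & !is.na(epi$end_date) &
                   epi$eligibility_date > epi$end_date)
    v[[length(v) + 1L]] <- .violation(
      rule, "episodes", epi$episode_id[bad], "eligibility_date",
      format(epi$eligibility_date[bad]), "flagged",
      "eligibility date after end date")
  }

  rule <- ruleset$enrolled_has_contact
  if (!is.null(rule)) {
    attributed <- attribute_contacts(bundle)
    with_contact <- unique(attributed$episode_id[
      !is.na(attributed$episode_id) & !is.na(attributed$contact_date)])
    bad <- which(!is.na(epi$recorded_status) &
                   epi$recorded_status == "enrolled" &
                   !(epi$episode_id %in% with_contact))
    v[[length(v) + 1L]] <- .violation(
      rule, "episodes", epi$episode_id[bad], "contact_date", NA, "flagged",
      "enrolled episode without any contact date; contact date labeled missing")
  }

  list(bundle = bundle, violations = .bind_violations(v))
}

#' Check state-dependent object rules
#'
#' Events whose occurrence depends on other events: an episode with an end
#' date must also carry an eligibility date (otherwise the eligibility date
#' is labeled a missing value), and the baseline questionnaire of an
#' episode (the earliest attributable response per instrument) must be
#' recorded before or on the enrollment (start) date.
#'
#' @inheritParams check_attribute_domain
#' @return List with `bundle` (unchanged) and `violations`.
#' @export
check_state_dependent <- function(bundle, ruleset = default_ruleset()) {
  v <- list()
  epi <- bundle$episodes

  rule <- ruleset$end_requires_eligibility
  if (!is.null(rule)) {
    bad <- which(!is.na(epi$end_date) & is.na(epi$eligibility_date))
    v[[length(v) + 1L]] <- .violation(
      rule, "episodes", epi$episode_id[bad], "eligibility_date", NA,
      "flagged", "episode has an end date but no eligibility date")
  }

  rule <- ruleset$baseline_before_enrollment
  if (!is.null(rule)) {
    q <- attribute_questionnaires(bundle)
    q <- q[!is.na(q$episode_id) & !is.na(q$recording_date), , drop = FALSE]
    if (nrow(q)) {
      q <- q[order(q$episode_id, q$instrument, q$recording_date,
                   q$response_id), , drop = FALSE]
      baseline <- q[!duplicated(paste(q$episode_id, q$instrument)), ,
                    drop = FALSE]
      start <- epi$start_date[match(baseline$episode_id, epi$episode_id)]
      bad <- which(!is.na(start) & baseline$recording_date > start)
      v[[length(v) + 1L]] <- .violation(
        rule, "questionnaires", baseline$response_id[bad], "recording_date",
        format(baseline$recording_date[bad]), "flagged",
        "baseline questionnaire recorded after the enrollment date")
    }
  }

  list(bundle = bundle, violations = .bind_violations(v))
}

#' Check attribute dependency rules
#'
#' Aggregate consistency: a PHQ-9 total must equal the sum of its nine
#' items. Rows with any missing item are skipped (the sum is undefined).
#' The repair policy is configurable: recompute the total from the items
#' (default) or set the total to missing.
#'
#' @inheritParams check_attribute_domain
#' @return List with `bundle` (repaired per policy) and `violations`.
#' @export
check_attribute_dependency <- function(bundle, ruleset = default_ruleset()) {
  v <- list()
  rule <- ruleset$phq9_total_equals_items
  if (!is.null(rule)) {
    q <- bundle$questionnaires
    items <- as.matrix(q[, paste0("item_", 1:9)])
    sums <- rowSums(items)
    is_phq <- q$instrument == "PHQ9"
    bad <- which(is_phq & !is.na(sums) & !is.na(q$total) & q$total != sums)
    if (length(bad)) {
      action <- if (rule$params$repair == "recompute") "normalized" else "set_missing"
      v[[length(v) + 1L]] <- .violation(
        rule, "questionnaires", q$response_id[bad], "total", q$total[bad],
        action, sprintf("total %s does not equal item sum %s",
                        q$total[bad], sums[bad]))
      q$total[bad] <- if (rule$params$repair == "recompute") sums[bad] else NA_real_
      bundle$questionnaires <- q
    }
  }
  list(bundle = bundle, violations = .bind_violations(v))
}

#' Run the full data-quality assessment
#'
#' Executes the five rule families in a fixed order -- attribute domain
#' first (so downstream rules see normalized values), then relational
#' integrity, historical, state-dependent, and attribute dependency rules.
#' Returns the cumulative violation ledger, a quality report with per-rule
#' and per-dimension counts, and the cleaned bundle reflecting all repairs.
#' The assessment is idempotent: re-running it on its own cleaned output
#' performs zero repair actions.
#'
#' @inheritParams check_attribute_domain
#' @return An object of class `dq_result` with elements `bundle` (cleaned),
#'   `violations` (the ledger) and `report` (a `quality_report`).
#' @export
run_quality_assessment <- function(bundle, ruleset = default_ruleset()) {
  steps <- list(check_attribute_domain, check_relational_integrity,
                check_historical_rules, check_state_dependent,
                check_attribute_dependency)
  violations <- list()
  for (step in steps) {
    res <- step(bundle, ruleset)
    bundle <- res$bundle
    violations[[length(violations) + 1L]] <- res$violations
  }
  violations <- .bind_violations(violations)
  structure(list(bundle = bundle, violations = violations,
                 report = quality_report(violations, bundle, ruleset)),
            class = "dq_result")
}

#' Build a quality report from a violation ledger
#'
#' @param violations Violation ledger data frame.
#' @param bundle The assessed `registry_bundle`.
#' @param ruleset The `quality_ruleset` used.
#' @return A `quality_report`: per-rule violation counts, per-dimension
#'   totals (each equal to the sum of counts of rules tagged with that
#'   dimension), per-table completeness rates, and repair-action counts.
#' @export
quality_report <- function(violations, bundle, ruleset = default_ruleset()) {
  rule_ids <- vapply(ruleset, `[[`, "", "rule_id")
  by_rule <- vapply(rule_ids, function(id) {
    sum(violations$rule_id == id)
  }, integer(1))
  rule_dim <- vapply(ruleset, `[[`, "", "dimension")
  by_dimension <- vapply(.DQ_DIMENSIONS, function(d) {
    sum(by_rule[rule_dim == d])
  }, integer(1))
  by_family <- vapply(.DQ_FAMILIES, function(f) {
    sum(violations$family == f)
  }, integer(1))
  actions <- c(flagged = 0L, normalized = 0L, set_missing = 0L, dropped = 0L)
  tab <- table(violations$action)
  actions[names(tab)] <- as.integer(tab)

  completeness <- vapply(.REGISTRY_TABLES, function(tab) {
    df <- bundle[[tab]][, .MANDATORY_COLUMNS[[tab]], drop = FALSE]
    if (nrow(df) == 0L) return(1)
    1 - sum(vapply(df, function(col) sum(is.na(col)), integer(1))) /
      (nrow(df) * ncol(df))
  }, numeric(1))

  structure(list(by_rule = by_rule, by_dimension = by_dimension,
                 by_family = by_family, actions = actions,
                 n_violations = nrow(violations),
                 completeness = completeness),
            class = "quality_report")
}

#' Number of repair actions recorded in a data-quality result
#'
#' Repairs are the violations whose action changed a value
#' (`normalized`, `set_missing`, `dropped`); `flagged` findings are not
#' repairs.
#'
#' @param x A `dq_result` or `quality_report`.
#' @return Integer count.
#' @export
n_repairs <- function(x) {
  if (inherits(x, "dq_result")) x <- x$report
  sum(x$actions[c("normalized", "set_missing", "dropped")])
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n")
  cat(sprintf("  violations: %d (repairs: %d)\n", x$n_violations,
              sum(x$actions[c("normalized", "set_missing", "dropped")])))
  cat("  by dimension:\n")
  for (d in names(x$by_dimension)) {
    cat(sprintf("    %-12s %d\n", d, x$by_dimension[[d]]))
  }
  cat("  by family:\n")
  for (f in names(x$by_family)) {
    cat(sprintf("    %-22s %d\n", f, x$by_family[[f]]))
  }
  cat("  completeness:\n")
  for (t in names(x$completeness)) {
    cat(sprintf("    %-15s %.4f\n", t, x$completeness[[t]]))
  }
  invisible(x)
}

#' @export
print.dq_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}
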