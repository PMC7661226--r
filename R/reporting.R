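# Summary artifacts: subgroup summary tables (counts, demographics and
# PHQ-9 severity bands per status column) and the patient flow summary in
# DOT form, with flow conservation checked at every split. Percentages are
# printed to two decimals, rounding half-up; the age SD uses the sample
# (n - 1) convention.

.round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Subgroup summary table per status
#'
#' For each cohort status: number and percentage of instances, age mean
#' and sample SD at the eligibility date, sex/race/marital frequency
#' blocks with explicit missing rows, and PHQ-9 severity-band counts both
#' at the start date and at the eligibility date. For the never-approached
#' column the start-date block is reported as not available (no start date
#' exists).
#'
#' @param labels A `cohort_labels` object.
#' @param bundle The `registry_bundle` the labels were derived from.
#' @return An object of class `cohort_summary`.
#' @export
summarize_cohorts <- function(labels, bundle) {
  lab <- labels$labels
  epi <- bundle$episodes[match(lab$episode_id, bundle$episodes$episode_id), ,
                         drop = FALSE]
  dem <- bundle$demographics[match(lab$patient_id,
                                   bundle$demographics$patient_id), ,
                             drop = FALSE]
  age <- .age_at(dem$birth_date, epi$eligibility_date)
  phq_start <- .phq9_at(bundle, lab$patient_id, epi$start_date)
  phq_elig <- .phq9_at(bundle, lab$patient_id, epi$eligibility_date)

  freq_block <- function(x, sel) {
    x <- as.character(x[sel])
    x[is.na(x)] <- "missing"
    tab <- table(x)
    n <- sum(sel)
    data.frame(level = names(tab), n = as.integer(tab),
               pct = if (n > 0) .round_half_up(100 * as.integer(tab) / n)
                     else rep(0, length(tab)),
               stringsAsFactors = FALSE)
  }

  total <- nrow(lab)
  out <- lapply(.STATUS_LEVELS, function(s) {
    sel <- lab$status == s
    n <- sum(sel)
    a <- age[sel]
    a <- a[!is.na(a)]
    res <- list(
      status = s, n = n,
      pct = if (total > 0) .round_half_up(100 * n / total) else 0,
      age_mean = if (length(a)) mean(a) else NA_real_,
      age_sd = if (length(a) > 1) stats::sd(a) else NA_real_,
      sex = freq_block(dem$sex, sel),
      race = freq_block(dem$race, sel),
      marital_status = freq_block(dem$marital_status, sel))
    if (s == "not_approached") {
      res$phq9_at_start <- "No start date is available"
    } else {
      res$phq9_at_start <- as.data.frame(table(band_phq9(phq_start[sel])),
                                         responseName = "n")
      names(res$phq9_at_start)[1] <- "band"
    }
    res$phq9_at_eligibility <- as.data.frame(table(band_phq9(phq_elig[sel])),
                                             responseName = "n")
    names(res$phq9_at_eligibility)[1] <- "band"
    res
  })
  names(out) <- .STATUS_LEVELS
  structure(list(by_status = out, total = total), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>", x$total, "instances\n")
  for (s in names(x$by_status)) {
    b <- x$by_status[[s]]
    cat(sprintf("  %-15s n=%d (%.2f%%)  age %.2f (SD %.2f)\n", s, b$n,
                b$pct, b$age_mean, b$age_sd))
  }
  invisible(x)
}

#' Build a patient flow summary with conservation checks
#'
#' Nodes follow the registry flow: registry total splits into
#' consent-excluded and consented; consented splits into criteria-excluded
#' and eligible; eligible splits into enrolled, opt-out and not-approached;
#' optionally enrolled splits into drop-out / remitted / discharged
#' outcomes. Child counts must sum to their parent's count at every split,
#' otherwise the failing split is named in an error.
#'
#' @param tallies Named list/vector with `registry_total`,
#'   `consent_excluded`, `criteria_excluded`, `eligible`, `enrolled`,
#'   `opt_out`, `not_approached`, and optionally `drop_out`, `remitted`,
#'   `discharged`.
#' @return An object of class `flow_summary` with `nodes` (data frame
#'   `node`, `count`) and `edges` (data frame `from`, `to`, `count`).
#' @export
flow_summary <- function(tallies) {
  t <- as.list(tallies)
  req <- c("registry_total", "consent_excluded", "criteria_excluded",
           "eligible", "enrolled", "opt_out", "not_approached")
  missing_nodes <- setdiff(req, names(t))
  if (length(missing_nodes)) {
    stop("flow tallies missing: ", paste(missing_nodes, collapse = ", "),
         call. = FALSE)
  }
  consented <- t$registry_total - t$consent_excluded
  check <- function(parent, total, parts) {
    if (total != sum(unlist(parts))) {
      stop(sprintf(
        "flow conservation violated at '%s': %d != %s = %d", parent, total,
        paste(unlist(parts), collapse = " + "), sum(unlist(parts))),
        call. = FALSE)
    }
  }
  check("registry_total", t$registry_total,
        list(t$consent_excluded, consented))
  check("consented", consented, list(t$criteria_excluded, t$eligible))
  check("eligible", t$eligible,
        list(t$enrolled, t$opt_out, t$not_approached))

  nodes <- data.frame(
    node = c("registry_total", "consent_excluded", "consented",
             "criteria_excluded", "eligible", "enrolled", "opt_out",
             "not_approached"),
    count = c(t$registry_total, t$consent_excluded, consented,
              t$criteria_excluded, t$eligible, t$enrolled, t$opt_out,
              t$not_approached),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    from = c("registry_total", "registry_total", "consented", "consented",
             "eligible", "eligible", "eligible"),
    to = c("consent_excluded", "consented", "criteria_excluded", "eligible",
           "enrolled", "opt_out", "not_approached"),
    stringsAsFactors = FALSE)

  outcomes <- intersect(c("drop_out", "remitted", "discharged"), names(t))
  if (length(outcomes)) {
    check("enrolled", t$enrolled, t[outcomes])
    nodes <- rbind(nodes, data.frame(node = outcomes,
                                     count = unlist(t[outcomes]),
                                     stringsAsFactors = FALSE))
    edges <- rbind(edges, data.frame(from = "enrolled", to = outcomes,
                                     stringsAsFactors = FALSE))
  }
  edges$count <- nodes$count[match(edges$to, nodes$node)]
  structure(list(nodes = nodes, edges = edges), class = "flow_summary")
}

#' Emit a flow summary as DOT digraph text
#'
#' One node per flow stage labeled `"name\\n(count)"`; layout is left to
#' any DOT renderer.
#'
#' @param flow A `flow_summary` (or tallies accepted by [flow_summary()]).
#' @param file Optional path; when given the text is also written there.
#' @return The DOT text, invisibly when `file` is given.
#' @export
emit_flow_summary <- function(flow, file = NULL) {
  if (!inherits(flow, "flow_summary")) flow <- flow_summary(flow)
  lines <- c("digraph patient_flow {", "  rankdir=TB;",
             "  node [shape=box];")
  for (i in seq_len(nrow(flow$nodes))) {
    lines <- c(lines, sprintf('  %s [label="%s\\n(%d)"];',
                              flow$nodes$node[i], flow$nodes$node[i],
                              flow$nodes$count[i]))
  }
  for (i in seq_len(nrow(flow$edges))) {
    lines <- c(lines, sprintf("  %s -> %s;", flow$edges$from[i],
                              flow$edges$to[i]))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' @export
print.flow_summary <- function(x, ...) {
  cat("<flow_summary>\n")
  for (i in seq_len(nrow(x$nodes))) {
    cat(sprintf("  %-18s %d\n", x$nodes$node[i], x$nodes$count[i]))
  }
  invisible(x)
}

#' Run the full registry curation pipeline
#'
#' Data-quality assessment, complete-case drop, start-date recovery,
#' eligibility filtering, status classification, index-date assignment,
#' window-cohort construction, flow summary and subgroup summary, in
#' order. Every stage's row counts are retained so the flow summary is
#' reconstructable.
#'
#' @param bundle A `registry_bundle`.
#' @param ruleset A `quality_ruleset`.
#' @param criteria An [eligibility_criteria()].
#' @param strategy Index-date strategy (see [assign_index_dates()]).
#' @param window_days Cross-sectional window length in days.
#' @param registry_total Optional total registry size for the flow
#'   summary's root node (defaults to the episode count before cleaning).
#' @return A list of class `registry_pipeline` with elements `dq`,
#'   `recovery`, `decisions`, `tally`, `labels`, `index`, `cohorts`,
#'   `flow`, `summary`, and the cleaned `bundle`.
#' @export
run_pipeline <- function(bundle, ruleset = default_ruleset(),
                         criteria = eligibility_criteria(),
                         strategy = "first_eligibility",
                         window_days = 183,
                         registry_total = NULL) {
  n0 <- nrow(bundle$episodes)
  dq <- run_quality_assessment(bundle, ruleset)
  cleaned <- clean_missing(dq$bundle)
  filt <- apply_eligibility_filter(cleaned$bundle, criteria)
  labels <- classify_all(cleaned$bundle, filt$decisions)
  index <- assign_index_dates(labels, cleaned$bundle$episodes,
                              strategy = strategy)
  # Patients excluded at indexing (no usable anchor date, e.g. an
  # unrepairable missing eligibility date) are excluded from cohorting;
  # assign_index_dates() logs them on the `excluded` attribute.
  cohortable <- labels
  cohortable$labels <- labels$labels[
    labels$labels$patient_id %in% index$patient_id, , drop = FALSE]
  cohorts <- build_cross_sectional_cohorts(cohortable,
                                           cleaned$bundle$episodes,
                                           index, window_days = window_days)
  # The flow root is the set of instances entering the eligibility screen
  # (post-cleaning); cleaning drops are reported in `recovery`, not here.
  if (is.null(registry_total)) registry_total <- nrow(filt$decisions)
  n_excluded <- sum(!filt$decisions$eligible)
  n_consent <- sum(grepl("no_consent", filt$decisions$exclusion_reasons))
  extra <- registry_total - nrow(filt$decisions)
  flow <- flow_summary(list(
    registry_total = registry_total,
    consent_excluded = n_consent + max(extra, 0),
    criteria_excluded = n_excluded - n_consent,
    eligible = labels$n,
    enrolled = labels$counts[["enrolled"]],
    opt_out = labels$counts[["opt_out"]],
    not_approached = labels$counts[["not_approached"]]))
  structure(list(dq = dq, recovery = cleaned$report,
                 decisions = filt$decisions, tally = filt$tally,
                 labels = labels, index = index, cohorts = cohorts,
                 flow = flow, summary = summarize_cohorts(labels,
                                                          cleaned$bundle),
                 bundle = cleaned$bundle),
            class = "registry_pipeline")
}

#' @export
print.registry_pipeline <- function(x, ...) {
  cat("<registry_pipeline>\n")
  print(x$flow)
  invisible(x)
}
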