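#' Cohort selection rules
#'
#' Defines which trainees enter the analysis cohort and how far they are
#' followed: the entry level (CT1), the inclusive entry-year window, the
#' study horizon (last observed calendar year), an optional restriction on
#' region of primary medical qualification for graduate subcohorts, and
#' the number of annual transitions under study.
#'
#' @param entry_window Inclusive entry-year range, length-2 integer vector.
#' @param horizon_year Last observed calendar year; periods falling after
#'   it are administratively censored.
#' @param entry_level Level whose first appearance defines cohort entry.
#' @param restrict_pmq Optional value of `pmq_region` (e.g. `"UK"`) to
#'   restrict the cohort to, applied at selection time.
#' @param max_time Number of transitions; must equal the number of levels
#'   minus one.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(entry_window = c(2012L, 2017L),
                        horizon_year = 2018L,
                        entry_level = "CT1",
                        restrict_pmq = NULL,
                        max_time = n_transitions()) {
  entry_window <- as.integer(entry_window)
  if (length(entry_window) != 2 || entry_window[1] > entry_window[2]) {
    stop("entry_window must be an inclusive year range c(first, last)",
         call. = FALSE)
  }
  if (entry_window[2] > horizon_year - 1L) {
    stop("entry_window must end no later than horizon_year - 1",
         call. = FALSE)
  }
  if (max_time != n_transitions()) {
    stop("max_time must equal the number of training levels minus one",
         call. = FALSE)
  }
  if (!entry_level %in% training_levels()) {
    stop("unknown entry_level: ", entry_level, call. = FALSE)
  }
  structure(
    list(entry_window = entry_window,
         horizon_year = as.integer(horizon_year),
         entry_level = entry_level,
         restrict_pmq = restrict_pmq,
         max_time = as.integer(max_time)),
    class = "cohort_spec"
  )
}

## Structural validation of raw records: unique (person, year) keys,
## covariates constant within person, levels non-decreasing and climbing
## at most one level per elapsed year.
validate_records <- function(records) {
  required <- c("person_id", "year", "level")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("records are missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  key <- paste(records$person_id, records$year)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicate (person_id, year) rows: ",
         paste(utils::head(dup, 10), collapse = ", "), call. = FALSE)
  }
  ord <- order(records$person_id, records$year)
  pid <- records$person_id[ord]
  yr <- records$year[ord]
  lv <- as.integer(factor(records$level[ord], levels = training_levels()))
  same <- pid[-1] == pid[-length(pid)]
  dy <- diff(yr)
  dl <- diff(lv)
  bad <- same & (dl < 0 | dl > dy)
  if (any(bad)) {
    stop("records violate level-trajectory invariants (regression or ",
         "skipped level) at rows: ",
         paste(utils::head(ord[-1][bad], 10), collapse = ", "),
         call. = FALSE)
  }
  covs <- setdiff(names(records), required)
  for (nm in covs) {
    v <- records[[nm]][ord]
    differs <- same & (is.na(v[-1]) != is.na(v[-length(v)]) |
                         (!is.na(v[-1]) & !is.na(v[-length(v)]) &
                            v[-1] != v[-length(v)]))
    if (any(differs)) {
      stop("covariate '", nm, "' varies within person for: ",
           paste(utils::head(unique(pid[-1][differs]), 5), collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(records)
}

#' Select the entry cohort
#'
#' Keeps one entry per person whose *first* appearance at the entry level
#' falls inside the entry window ("first attempt to progress": later
#' same-level rows of a stayer never create a second entry, and a person
#' first seen at the entry level before the window is excluded outright
#' rather than re-admitted via a later duplicate row).  Persons never
#' observed at the entry level are excluded.  The optional `restrict_pmq`
#' filter is applied here, before person-period construction, so subcohort
#' risk tables match a standalone run.
#'
#' @param records Observation records (validated against the structural
#'   invariants; malformed records raise an error listing offending rows).
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per selected person: `person_id`,
#'   `entry_year`, and the person-level covariates.
#' @export
select_entry_cohort <- function(records, spec = cohort_spec()) {
  validate_records(records)
  at_entry <- records[records$level == spec$entry_level, , drop = FALSE]
  first_entry <- tapply(at_entry$year, at_entry$person_id, min)
  in_window <- first_entry >= spec$entry_window[1] &
    first_entry <= spec$entry_window[2]
  keep <- names(first_entry)[in_window]
  cohort <- tibble::tibble(person_id = keep,
                           entry_year = as.integer(first_entry[keep]))
  covs <- setdiff(names(records), c("person_id", "year", "level"))
  if (length(covs) > 0) {
    first_rows <- records[!duplicated(records$person_id),
                          c("person_id", covs), drop = FALSE]
    cohort <- merge(cohort, first_rows, by = "person_id", sort = FALSE)
    cohort <- tibble::as_tibble(cohort)
  }
  if (!is.null(spec$restrict_pmq)) {
    if (!"pmq_region" %in% names(cohort)) {
      stop("restrict_pmq set but records carry no pmq_region column",
           call. = FALSE)
    }
    cohort <- cohort[!is.na(cohort$pmq_region) &
                       cohort$pmq_region == spec$restrict_pmq, , drop = FALSE]
  }
  cohort <- cohort[order(cohort$person_id), , drop = FALSE]
  if (nrow(cohort) == 0) {
    warning("entry cohort is empty for the given window", call. = FALSE)
  }
  cohort
}

#' Build the person-period dataset
#'
#' One row per person per annual transition at risk.  Walking years
#' `entry_year + 1, entry_year + 2, ...`: a person observed at the expected
#' next level contributes an event-free row (`event = 0`); a person absent
#' or observed below the expected level contributes a final row with
#' `event = 1` ("did not progress", covering drop-out, repeats, breaks and
#' slower-than-minimum progression alike); periods falling after the
#' horizon year are simply not emitted (right censoring).  A person
#' observed *above* the expected level indicates corrupt data and raises
#' an error.  A person with five event-free rows is a six-year completer.
#'
#' @param records Observation records.
#' @param cohort Output of [select_entry_cohort()].
#' @param spec The same [cohort_spec()].
#' @return A tibble with columns `person_id`, `time` (1..5), `event`,
#'   `entry_year` and the person-level covariates.
#' @export
build_person_period <- function(records, cohort, spec = cohort_spec()) {
  tmax <- spec$max_time
  n <- nrow(cohort)
  if (n == 0) {
    return(tibble::tibble(person_id = character(), time = integer(),
                          event = integer(), entry_year = integer()))
  }
  lvl_idx <- as.integer(factor(records$level, levels = training_levels()))
  key <- paste(records$person_id, records$year)

  entry <- cohort$entry_year
  ## years at which transition t = 1..tmax resolves, per person
  yr_mat <- outer(entry, seq_len(tmax), `+`)
  obs <- matrix(lvl_idx[match(paste(rep(cohort$person_id, tmax),
                                    as.vector(yr_mat)), key)],
                nrow = n)
  expected <- matrix(rep(seq_len(tmax) + 1L, each = n), nrow = n)
  if (any(obs > expected, na.rm = TRUE)) {
    bad <- which(apply(obs > expected, 1L, any, na.rm = TRUE))
    stop("persons observed above their expected level (corrupt records): ",
         paste(utils::head(cohort$person_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  ok <- !is.na(obs) & obs == expected
  in_frame <- yr_mat <= spec$horizon_year
  t_avail <- pmin(tmax, spec$horizon_year - entry)  # periods inside horizon

  fail_mat <- !ok & in_frame
  n_periods <- integer(n)
  event_last <- integer(n)
  for (i in seq_len(n)) {
    f <- which(fail_mat[i, seq_len(t_avail[i])])
    if (length(f) > 0) {
      n_periods[i] <- f[1L]
      event_last[i] <- 1L
    } else {
      n_periods[i] <- t_avail[i]
      event_last[i] <- 0L
    }
  }
  keep <- n_periods > 0
  idx <- rep(seq_len(n)[keep], n_periods[keep])
  time <- unlist(lapply(seq_len(n)[keep],
                        function(i) seq_len(n_periods[i])), use.names = FALSE)
  event <- integer(length(time))
  last <- cumsum(n_periods[keep])
  event[last] <- event_last[keep]

  pp <- tibble::tibble(person_id = cohort$person_id[idx],
                       time = as.integer(time),
                       event = event,
                       entry_year = cohort$entry_year[idx])
  covs <- setdiff(names(cohort), c("person_id", "entry_year"))
  for (nm in covs) pp[[nm]] <- cohort[[nm]][idx]
  pp
}

#' Per-period risk table
#'
#' Counts, for each transition time, the persons at risk, the events
#' (non-progressions) and the persons administratively censored after that
#' period.  Persons are conserved: events plus censored plus six-year
#' completers equals the cohort size, and
#' `n[t+1] = n[t] - events[t] - censored[t]`.
#'
#' @param person_periods Output of [build_person_period()].
#' @return A tibble with columns `time`, `n_risk`, `events`, `censored`
#'   and an attribute `completers` (persons surviving all transitions).
#' @export
risk_table <- function(person_periods) {
  tmax <- n_transitions()
  times <- seq_len(tmax)
  n_risk <- vapply(times, function(t) sum(person_periods$time == t),
                   integer(1))
  events <- vapply(times, function(t) {
    sum(person_periods$event[person_periods$time == t])
  }, integer(1))
  ## last observed period per person, with its event flag
  if (nrow(person_periods) > 0) {
    last_t <- tapply(person_periods$time, person_periods$person_id, max)
    ord <- paste(person_periods$person_id, person_periods$time)
    last_ev <- person_periods$event[match(paste(names(last_t), last_t), ord)]
    censored <- vapply(times, function(t) {
      sum(last_t == t & last_ev == 0 & t < tmax)
    }, integer(1))
    completers <- sum(last_t == tmax & last_ev == 0)
  } else {
    censored <- integer(tmax)
    completers <- 0L
  }
  out <- tibble::tibble(time = times, n_risk = n_risk,
                        events = events, censored = censored)
  attr(out, "completers") <- as.integer(completers)
  out
}
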