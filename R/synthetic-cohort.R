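#' Configuration for the synthetic training-registry cohort generator
#'
#' Bundles and validates everything [generate_cohort()] needs: the cohort
#' size, the distribution of entry years, the five per-transition baseline
#' hazards (probability of *not* progressing at transitions CT1-CT2 through
#' ST5-ST6 for the reference covariate pattern), covariate prevalences and
#' their log-odds effects on the hazard logit, the stayer probability, the
#' per-covariate missingness rates, the administrative censoring year and
#' the master seed.
#'
#' @param n_trainees Number of trainees to simulate.
#' @param entry_year_weights Named numeric vector of entry-year
#'   probabilities (names are calendar years, e.g. `"2012"`); must sum to 1.
#' @param baseline_hazards Numeric vector of length 5: per-transition
#'   probability of not progressing for the reference pattern.  Values of 0
#'   and 1 are allowed as degenerate limits.
#' @param covariate_specs Data frame with columns `name`, `prevalence`
#'   (probability of the non-reference category) and `effect` (additive
#'   shift on the per-period hazard logit for the non-reference category),
#'   or `NULL` for a covariate-free cohort.
#' @param stayer_prob Probability that a non-progressor reappears at the
#'   same level in later years (at most two extra same-level records)
#'   instead of vanishing from the record stream.
#' @param missing_rates Named numeric vector of per-covariate
#'   missing-completely-at-random rates, applied person-wise.
#' @param censor_year Study horizon: records after this calendar year are
#'   never emitted (administrative right censoring).
#' @param seed Master seed; all randomness is drawn from purpose-specific
#'   substreams derived from it, so e.g. adding covariates does not shift
#'   the transition draws.
#'
#' @return An object of class `cohort_config`.
#' @seealso [training_scenario()] for a documented realistic preset.
#' @export
cohort_config <- function(n_trainees,
                          entry_year_weights,
                          baseline_hazards,
                          covariate_specs = NULL,
                          stayer_prob = 0,
                          missing_rates = NULL,
                          censor_year = 2018L,
                          seed = 1L) {
  if (is.null(covariate_specs)) {
    covariate_specs <- tibble::tibble(name = character(),
                                      prevalence = numeric(),
                                      effect = numeric())
  }
  covariate_specs <- tibble::as_tibble(covariate_specs)
  config <- structure(
    list(
      n_trainees = as.integer(n_trainees),
      entry_year_weights = entry_year_weights,
      baseline_hazards = as.numeric(baseline_hazards),
      covariate_specs = covariate_specs,
      stayer_prob = stayer_prob,
      missing_rates = missing_rates %||% numeric(),
      censor_year = as.integer(censor_year),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
  validate_cohort_config(config)
  config
}

#' @rdname cohort_config
#' @param config A `cohort_config` object.
#' @export
validate_cohort_config <- function(config) {
  stop_config <- function(field, msg) {
    stop(sprintf("invalid cohort configuration: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (!is.numeric(config$n_trainees) || length(config$n_trainees) != 1 ||
      is.na(config$n_trainees) || config$n_trainees < 1) {
    stop_config("n_trainees", "must be a positive count")
  }
  w <- config$entry_year_weights
  if (is.null(names(w)) || anyNA(suppressWarnings(as.integer(names(w))))) {
    stop_config("entry_year_weights", "must be named by calendar year")
  }
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop_config("entry_year_weights", "must be nonnegative and sum to 1")
  }
  h <- config$baseline_hazards
  if (length(h) != n_transitions()) {
    stop_config("baseline_hazards",
                sprintf("must have exactly %d entries (one per transition)",
                        n_transitions()))
  }
  if (anyNA(h) || any(h < 0) || any(h > 1)) {
    stop_config("baseline_hazards", "must be probabilities in [0, 1]")
  }
  cs <- config$covariate_specs
  if (!all(c("name", "prevalence", "effect") %in% names(cs))) {
    stop_config("covariate_specs",
                "must have columns name, prevalence and effect")
  }
  if (anyDuplicated(cs$name)) {
    stop_config("covariate_specs", "has duplicated covariate names")
  }
  if (nrow(cs) > 0 && (any(cs$prevalence < 0) || any(cs$prevalence > 1))) {
    stop_config("covariate_specs", "prevalences must be in [0, 1]")
  }
  if (length(config$stayer_prob) != 1 ||
      config$stayer_prob < 0 || config$stayer_prob > 1) {
    stop_config("stayer_prob", "must be a probability in [0, 1]")
  }
  mr <- config$missing_rates
  if (length(mr) > 0) {
    if (is.null(names(mr)) || any(mr < 0) || any(mr > 1)) {
      stop_config("missing_rates", "must be named probabilities in [0, 1]")
    }
    if (!all(names(mr) %in% cs$name)) {
      stop_config("missing_rates",
                  "names unknown covariates (not in covariate_specs)")
    }
  }
  entry_years <- as.integer(names(w))
  if (any(entry_years >= config$censor_year + 1L)) {
    stop_config("censor_year", "must not precede every entry year")
  }
  invisible(config)
}

## Purpose-specific substream seeds derived from the master seed.  Each
## generator phase re-seeds from its own substream, so the transition draws
## for trainee i are identical whether or not covariates or missingness are
## configured.
substream_seeds <- function(seed) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 5L)
  names(s) <- c("entry", "covariates", "transitions", "stayers", "missingness")
  s
}

#' Generate synthetic annual observation records
#'
#' Simulates one trainee trajectory per person: an entry year drawn from
#' `entry_year_weights`, then, at each of the five annual transitions, the
#' trainee fails to progress with probability
#' `plogis(qlogis(h_t) + sum(effects * covariates))`.  Progression emits a
#' record at the next level in the next calendar year; failure either ends
#' the record stream or -- with probability `stayer_prob` -- emits one or
#' two further records at the same level ("stayers", exercising downstream
#' de-duplication).  No record is ever emitted for a year after
#' `censor_year`.  Deterministic given the config seed.
#'
#' @param config A [cohort_config()].
#' @return A tibble of observation records: `person_id`, `year`, `level`
#'   (factor over CT1..ST6) plus one two-level factor column per configured
#'   covariate (reference category first).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  seeds <- substream_seeds(config$seed)
  n <- config$n_trainees
  levels_all <- training_levels()
  tmax <- n_transitions()

  entry_years <- as.integer(names(config$entry_year_weights))
  set.seed(seeds[["entry"]])
  entry <- entry_years[sample.int(length(entry_years), n, replace = TRUE,
                                  prob = unname(config$entry_year_weights))]

  specs <- config$covariate_specs
  k <- nrow(specs)
  set.seed(seeds[["covariates"]])
  X <- if (k > 0) {
    vapply(seq_len(k), function(j) stats::rbinom(n, 1L, specs$prevalence[j]),
           integer(n))
  } else {
    matrix(0L, n, 0L)
  }
  if (n == 1) X <- matrix(X, nrow = 1)

  ## Per-person, per-transition event probabilities on the logit scale.
  offset <- if (k > 0) as.numeric(X %*% specs$effect) else rep(0, n)
  eta <- outer(offset, stats::qlogis(config$baseline_hazards), `+`)
  p_event <- stats::plogis(eta)

  set.seed(seeds[["transitions"]])
  U <- matrix(stats::runif(n * tmax), n, tmax)
  ev <- U < p_event
  ## first failed transition; Inf = completer
  first_event <- apply(ev, 1L, function(z) {
    w <- which(z)
    if (length(w)) w[1L] else Inf
  })

  set.seed(seeds[["stayers"]])
  u_stay <- stats::runif(n)
  extra_years <- 1L + (stats::runif(n) < 0.5)  # 1 or 2 extra same-level years

  ## Highest level attained: level t for an event at transition t, else ST6.
  top_level <- ifelse(is.finite(first_event), first_event, tmax + 1L)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    yrs <- entry[i] + seq_len(top_level[i]) - 1L
    lev <- seq_len(top_level[i])
    if (is.finite(first_event[i]) && u_stay[i] < config$stayer_prob) {
      t_ev <- first_event[i]
      stay_years <- entry[i] + t_ev - 1L + seq_len(extra_years[i])
      yrs <- c(yrs, stay_years)
      lev <- c(lev, rep(t_ev, length(stay_years)))
    }
    keep <- yrs <= config$censor_year
    rows[[i]] <- list(year = yrs[keep], level = lev[keep])
  }
  n_rows <- vapply(rows, function(r) length(r$year), integer(1))
  idx <- rep(seq_len(n), n_rows)

  records <- tibble::tibble(
    person_id = sprintf("P%06d", idx),
    year = unlist(lapply(rows, `[[`, "year"), use.names = FALSE),
    level = factor(levels_all[unlist(lapply(rows, `[[`, "level"),
                                     use.names = FALSE)],
                   levels = levels_all)
  )
  for (j in seq_len(k)) {
    lab <- covariate_labels(specs$name[j])
    records[[specs$name[j]]] <- factor(lab[X[idx, j] + 1L], levels = lab)
  }

  if (length(config$missing_rates) > 0) {
    records <- inject_missingness(records, config$missing_rates,
                                  seed = seeds[["missingness"]])
  }
  records
}

#' Blank out covariate values completely at random
#'
#' Sets each person's value for each covariate to missing independently
#' with the stated rate; a person's missingness is identical across all of
#' their records (missingness lives at the person level, as in a registry).
#'
#' @param records Observation records as produced by [generate_cohort()].
#' @param missing_rates Named numeric vector of rates in `[0, 1]`.
#' @param seed Seed for the missingness draws.
#' @return The records with `NA`s injected.
#' @export
inject_missingness <- function(records, missing_rates, seed) {
  if (length(missing_rates) == 0) return(records)
  if (any(missing_rates < 0) || any(missing_rates > 1)) {
    stop("missing_rates must be probabilities in [0, 1]", call. = FALSE)
  }
  unknown <- setdiff(names(missing_rates), names(records))
  if (length(unknown) > 0) {
    stop("missing_rates names unknown covariates: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  persons <- unique(records$person_id)
  set.seed(seed)
  for (nm in names(missing_rates)) {
    hit <- persons[stats::runif(length(persons)) < missing_rates[[nm]]]
    records[[nm]][records$person_id %in% hit] <- NA
  }
  records
}

#' A realistic national-registry scenario
#'
#' A documented preset emulating annual registry data on UK psychiatry
#' training progression: entry cohorts 2012--2017, administrative
#' censoring at 2018, a pronounced bottleneck at the third transition
#' (core to specialty training, where open competition for posts and
#' membership examinations concentrate non-progression), modest hazards
#' elsewhere, and hazard-logit effects for the usual demographic and
#' socioeconomic dichotomies (gender, region of primary medical
#' qualification, ethnicity, disability, school type, graduate entry,
#' free school meals, parental degree, area deprivation).  Positive
#' effects raise the per-period probability of not progressing.  Roughly
#' a quarter of trainees carry at least one missing socioeconomic value,
#' and about one non-progressor in ten reappears at the same level
#' ("stayer").
#'
#' @param n_trainees Cohort size; defaults to 2820.
#' @param seed Master seed.
#' @return A [cohort_config()].
#' @export
training_scenario <- function(n_trainees = 2820L, seed = 20120601L) {
  cohort_config(
    n_trainees = n_trainees,
    entry_year_weights = c("2012" = 0.17, "2013" = 0.17, "2014" = 0.165,
                           "2015" = 0.165, "2016" = 0.165, "2017" = 0.165),
    ## reference-pattern probabilities of not progressing, t = 1..5,
    ## calibrated by simulation so the cohort-level hazards come out near
    ## (0.20, 0.21, 0.571, 0.21, 0.21) once the covariate effects act --
    ## a pronounced core-to-specialty bottleneck and a six-year completion
    ## probability of about 17%
    baseline_hazards = c(0.097, 0.106, 0.417, 0.130, 0.131),
    covariate_specs = tibble::tibble(
      name = c("gender", "pmq_region", "ethnicity", "school_type",
               "graduate_entry", "disability", "free_school_meals",
               "parents_degree", "imd_most_deprived"),
      prevalence = c(0.596, 0.324, 0.25, 0.25,
                     0.30, 0.08, 0.08,
                     0.55, 0.20),
      effect = c(0.40, 0.77, 0.26, 0.05,
                 0.05, 1.02, 0.66,
                 -0.05, 0.39)
    ),
    stayer_prob = 0.10,
    ## person-level rates whose union loses about a quarter of the cohort
    ## to complete-case exclusion, as socioeconomic registry fields do
    missing_rates = c(ethnicity = 0.05, school_type = 0.05,
                      graduate_entry = 0.02, disability = 0.02,
                      free_school_meals = 0.05, parents_degree = 0.05,
                      imd_most_deprived = 0.05),
    censor_year = 2018L,
    seed = seed
  )
}

#' Read and write observation-record tables
#'
#' Records are exchanged as headered CSV, one row per person-year, missing
#' values encoded as empty fields.  Column order and types follow
#' [generate_cohort()].
#'
#' @param records A records tibble.
#' @param path File path.
#' @return `read_records_csv()` returns a records tibble with `level` and
#'   covariate columns restored to their factor codings.
#' @export
write_records_csv <- function(records, path) {
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  records <- readr::read_csv(path, na = "", show_col_types = FALSE,
                             progress = FALSE)
  records$year <- as.integer(records$year)
  records$level <- factor(records$level, levels = training_levels())
  covs <- setdiff(names(records), c("person_id", "year", "level"))
  for (nm in covs) {
    records[[nm]] <- factor(records[[nm]], levels = covariate_labels(nm))
  }
  records
}
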