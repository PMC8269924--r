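# Hand-written ten-person fixture exercising every selection and
# censoring rule.  Window 2012-2017, horizon 2018.  By hand:
#   selected (7): p01 completer; p02 stayer, entry 2013, event t1;
#     p03 stayer, events t3; p06 entry 2017, event t1; p07 entry 2016,
#     censored after t2; p08 event t2; p10 entry 2014, censored after t4.
#   excluded (3): p04 first seen at CT2; p05 first CT1 in 2011 (before
#     window, later duplicate row must not re-admit); p09 first seen ST4.
# Risk table: t (n, d, c) = 1:(7,2,0) 2:(5,1,1) 3:(3,1,0) 4:(2,0,1)
#   5:(1,0,0); one completer.  KM survival: 5/7, 4/7, 8/21, 8/21, 8/21.
fixture_records <- function() {
  rows <- list(
    p01 = list(years = 2012:2017, levels = c("CT1","CT2","CT3","ST4","ST5","ST6"),
               gender = "male", pmq = "UK"),
    p02 = list(years = 2013:2014, levels = c("CT1","CT1"),
               gender = "female", pmq = "UK"),
    p03 = list(years = 2012:2015, levels = c("CT1","CT2","CT3","CT3"),
               gender = "female", pmq = "UK"),
    p04 = list(years = 2014:2015, levels = c("CT2","CT3"),
               gender = "male", pmq = "non-UK"),
    p05 = list(years = 2011:2012, levels = c("CT1","CT1"),
               gender = "male", pmq = "UK"),
    p06 = list(years = 2017, levels = "CT1",
               gender = "male", pmq = "UK"),
    p07 = list(years = 2016:2018, levels = c("CT1","CT2","CT3"),
               gender = "female", pmq = "non-UK"),
    p08 = list(years = 2012:2013, levels = c("CT1","CT2"),
               gender = "male", pmq = "non-UK"),
    p09 = list(years = 2015:2016, levels = c("ST4","ST5"),
               gender = "female", pmq = "UK"),
    p10 = list(years = 2014:2018, levels = c("CT1","CT2","CT3","ST4","ST5"),
               gender = "female", pmq = "non-UK")
  )
  tibble::tibble(
    person_id = rep(names(rows), vapply(rows, function(r) length(r$years), 1L)),
    year = as.integer(unlist(lapply(rows, `[[`, "years"))),
    level = factor(unlist(lapply(rows, `[[`, "levels")),
                   levels = c("CT1","CT2","CT3","ST4","ST5","ST6")),
    gender = factor(rep(vapply(rows, `[[`, "", "gender"),
                        vapply(rows, function(r) length(r$years), 1L)),
                    levels = c("male", "female")),
    pmq_region = factor(rep(vapply(rows, `[[`, "", "pmq"),
                            vapply(rows, function(r) length(r$years), 1L)),
                        levels = c("UK", "non-UK"))
  )
}

fixture_risk <- function() {
  tibble::tibble(time = 1:5,
                 n_risk = c(7L, 5L, 3L, 2L, 1L),
                 events = c(2L, 1L, 1L, 0L, 0L),
                 censored = c(0L, 1L, 0L, 1L, 0L))
}

fixture_km_survival <- function() c(5/7, 4/7, 8/21, 8/21, 8/21)

# A small covariate scenario used across model tests: two real effects and
# one null, no missingness, entry spread over the full window.
test_scenario <- function(n = 5000L, seed = 1L,
                          effects = c(0.40, 0.77, 0)) {
  cohort_config(
    n_trainees = n,
    entry_year_weights = c("2012" = 0.2, "2013" = 0.2, "2014" = 0.2,
                           "2015" = 0.2, "2016" = 0.1, "2017" = 0.1),
    baseline_hazards = c(0.22, 0.21, 0.571, 0.19, 0.18),
    covariate_specs = tibble::tibble(
      name = c("gender", "pmq_region", "school_type"),
      prevalence = c(0.6, 0.32, 0.25),
      effect = effects
    ),
    seed = seed
  )
}

# generate -> select -> person-period in one step
build_pp <- function(config, spec = cohort_spec()) {
  records <- generate_cohort(config)
  cohort <- select_entry_cohort(records, spec)
  build_person_period(records, cohort, spec)
}

# A 21-row toy person-period table with events and non-events at every
# transition time and a dichotomous covariate, small enough for direct
# likelihood evaluation with optim().
toy_person_periods <- function() {
  mk <- function(id, x, times, events) {
    tibble::tibble(person_id = id, time = times, event = events,
                   entry_year = 2012L,
                   x = factor(rep(x, length(times)), levels = c("no", "yes")))
  }
  rbind(
    mk("A", "no",  1:5, c(0, 0, 0, 0, 0)),
    mk("C", "no",  1,   1),
    mk("D", "yes", 1:2, c(0, 1)),
    mk("G", "no",  1:3, c(0, 0, 1)),
    mk("H", "yes", 1:4, c(0, 0, 0, 1)),
    mk("F", "yes", 1:5, c(0, 0, 0, 0, 1))
  )
}
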