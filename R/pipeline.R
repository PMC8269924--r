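#' Read and write person-period tables
#'
#' Person-period datasets are exchanged as headered CSV with missing
#' covariates encoded as empty fields, so any pipeline stage can be rerun
#' from the serialized output of the previous one.
#'
#' @param person_periods A person-period tibble.
#' @param path File path.
#' @export
write_person_period_csv <- function(person_periods, path) {
  readr::write_csv(person_periods, path, na = "")
  invisible(path)
}

#' @rdname write_person_period_csv
#' @export
read_person_period_csv <- function(path) {
  pp <- readr::read_csv(path, na = "", show_col_types = FALSE,
                        progress = FALSE)
  pp$time <- as.integer(pp$time)
  pp$event <- as.integer(pp$event)
  if ("entry_year" %in% names(pp)) pp$entry_year <- as.integer(pp$entry_year)
  covs <- setdiff(names(pp), c("person_id", "time", "event", "entry_year"))
  for (nm in covs) {
    pp[[nm]] <- factor(pp[[nm]], levels = covariate_labels(nm))
  }
  pp
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> cohort build -> discrete-time model
#' -> sensitivity estimators -> disclosure-controlled report as a single
#' configured run.  Every stage consumes only the previous stage's
#' serialized CSV output, so any stage can be rerun independently; every
#' output file is listed in the returned manifest with an md5 content
#' hash, and a rerun with the same configuration and seed reproduces
#' identical hashes.
#'
#' @param config A configuration list, or the path of a YAML file holding
#'   one.  Recognised entries:
#'   \describe{
#'     \item{records_csv}{Path of an existing observation-record CSV; if
#'       absent, records are simulated from [training_scenario()].}
#'     \item{n_trainees}{Cohort size for simulation (default 2820).}
#'     \item{entry_window, horizon_year, restrict_pmq}{Cohort selection,
#'       see [cohort_spec()].}
#'     \item{covariates, interactions, patterns}{Model specification;
#'       `patterns` is a list of named covariate assignments to curve.}
#'     \item{disclosure}{Logical: emit the disclosure-controlled report
#'       (default `TRUE`).}
#'     \item{out_dir}{Output directory (created if needed).}
#'     \item{seed}{Master seed for the simulation.}
#'   }
#' @param seed Overrides `config$seed` when non-`NULL`.
#' @return The run manifest (invisibly): configuration echo, package
#'   version, and per-file md5 hashes.  Also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config = list(), seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% tempfile("dtprog_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  stage <- "simulate"
  outputs <- character()
  emit <- function(name) {
    outputs[[length(outputs) + 1]] <<- file.path(out_dir, name)
    file.path(out_dir, name)
  }
  run <- function(expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s (partial outputs in %s)",
                   stage, conditionMessage(e), out_dir), call. = FALSE)
    })
  }

  ## stage 1: simulate or load records
  records_path <- emit("records.csv")
  run({
    if (!is.null(config$records_csv)) {
      if (!file.exists(config$records_csv)) {
        stop("input records file does not exist: ", config$records_csv)
      }
      records <- read_records_csv(config$records_csv)
    } else {
      sim <- training_scenario(n_trainees = config$n_trainees %||% 2820L,
                               seed = seed)
      records <- generate_cohort(sim)
    }
    write_records_csv(records, records_path)
  })

  ## stage 2: cohort + person-period construction (reads records.csv)
  stage <- "build"
  pp_path <- emit("person_periods.csv")
  risk_path <- emit("risk_table.csv")
  spec <- run(cohort_spec(
    entry_window = config$entry_window %||% c(2012L, 2017L),
    horizon_year = config$horizon_year %||% 2018L,
    restrict_pmq = config$restrict_pmq
  ))
  run({
    records <- read_records_csv(records_path)
    cohort <- select_entry_cohort(records, spec)
    pp <- build_person_period(records, cohort, spec)
    write_person_period_csv(pp, pp_path)
    risk <- risk_table(pp)
    readr::write_csv(
      cbind(risk, completers = attr(risk, "completers")), risk_path)
  })

  ## stage 3: discrete-time model (reads person_periods.csv)
  stage <- "fit"
  fit_path <- emit("fit.json")
  base_curve_path <- emit("baseline_curve.csv")
  run({
    pp <- read_person_period_csv(pp_path)
    covariates <- config$covariates %||% character()
    fit <- fit_hazard_model(pp, covariates = covariates,
                            interactions = config$interactions %||% list())
    est <- effect_estimates(fit)
    r2 <- pseudo_r2(fit)
    base <- baseline_hazards(fit)
    readr::write_csv(base, base_curve_path)
    curves <- list()
    for (pat in config$patterns %||% list()) {
      cv <- pattern_curve(fit, pat)
      cv$pattern <- paste(names(pat), unlist(pat), sep = "=",
                          collapse = ";")
      curves[[length(curves) + 1]] <- cv
    }
    if (length(curves) > 0) {
      readr::write_csv(do.call(rbind, curves), emit("pattern_curves.csv"))
    }
    jsonlite::write_json(
      list(
        time_coefficients = as.list(fit$time_coefficients),
        covariate_coefficients = as.list(fit$covariate_coefficients),
        se = as.list(sqrt(diag(fit$vcov))),
        effects = est,
        minus2LL = fit$minus2LL,
        null_minus2LL = fit$null_minus2LL,
        pseudo_r2 = r2,
        n_rows = fit$n_rows,
        n_persons = fit$n_persons,
        n_dropped_persons = fit$n_dropped_persons,
        converged = fit$converged
      ),
      fit_path, auto_unbox = TRUE, digits = NA)
  })

  ## stage 4: sensitivity estimators (reads person_periods.csv)
  stage <- "sensitivity"
  lt_path <- emit("life_table.csv")
  km_path <- emit("km_curve.csv")
  agree_path <- emit("estimator_agreement.csv")
  run({
    pp <- read_person_period_csv(pp_path)
    risk <- risk_table(pp)
    lt <- life_table(risk)
    km <- km_estimate(pp)
    base_fit <- fit_hazard_model(pp)  # intercepts-only
    agree <- compare_estimators(baseline_hazards(base_fit), km, lt)
    readr::write_csv(lt, lt_path)
    readr::write_csv(km, km_path)
    readr::write_csv(agree, agree_path)
  })

  ## stage 5: disclosure-controlled report (reads risk_table.csv)
  stage <- "report"
  if (isTRUE(config$disclosure %||% TRUE)) {
    run({
      risk <- readr::read_csv(risk_path, show_col_types = FALSE,
                              progress = FALSE)
      disclosed <- disclose_table(risk[, c("time", "n_risk", "events",
                                           "censored", "completers")])
      disclosed$time <- as.character(risk$time)  # time index, not a count
      readr::write_csv(disclosed, emit("disclosed_risk_table.csv"))
    })
  }

  manifest <- list(
    package = "dtprog",
    version = as.character(utils::packageVersion("dtprog")),
    seed = seed,
    config = config[setdiff(names(config), "out_dir")],
    outputs = lapply(stats::setNames(outputs, basename(unlist(outputs))),
                     function(f) list(path = basename(f),
                                      md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
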