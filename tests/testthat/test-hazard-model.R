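test_that("intercepts-only hazards equal the empirical event proportions", {
  pp <- build_pp(test_scenario(n = 1500, seed = 7))
  fit <- fit_hazard_model(pp)
  rt <- risk_table(pp)
  expect_equal(unname(stats::plogis(fit$time_coefficients)),
               rt$events / rt$n_risk, tolerance = 1e-8)
  expect_true(fit$converged)
  expect_lt(fit$max_score, 1e-8)
  ## sign convention: positive time coefficient iff hazard above one half
  expect_equal(unname(fit$time_coefficients > 0),
               rt$events / rt$n_risk > 0.5)
})

test_that("coefficients and standard errors agree with an independent fit", {
  pp <- build_pp(test_scenario(n = 2000, seed = 13))
  fit <- fit_hazard_model(pp, covariates = c("gender", "pmq_region"))
  ref <- stats::glm(event ~ 0 + factor(time) + gender + pmq_region,
                    family = stats::binomial(),
                    data = pp,
                    control = stats::glm.control(epsilon = 1e-12))
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)),
               tolerance = 1e-7)
  expect_equal(unname(sqrt(diag(fit$vcov))),
               unname(sqrt(diag(stats::vcov(ref)))), tolerance = 1e-5)
  expect_equal(fit$minus2LL, -2 * as.numeric(stats::logLik(ref)),
               tolerance = 1e-8)
})

test_that("the likelihood never worsens when covariates are added", {
  pp <- build_pp(test_scenario(n = 1500, seed = 19))
  fit <- fit_hazard_model(pp, covariates = c("gender", "pmq_region"))
  expect_lte(fit$minus2LL, fit$null_minus2LL)
  expect_true(isSymmetric(fit$vcov, tol = 1e-10))
  expect_true(all(diag(fit$vcov) >= 0))
})

test_that("degenerate designs are detected, not silently fitted", {
  pp <- build_pp(test_scenario(n = 800, seed = 5))
  ## constant covariate: collinear with the time dummies
  pp$flat <- factor("yes", levels = c("no", "yes"))
  expect_error(fit_hazard_model(pp, covariates = "flat"), "flat")
  ## duplicated covariate
  pp$gender2 <- factor(as.character(pp$gender), levels = c("male", "female"))
  expect_error(
    fit_hazard_model(pp, covariates = c("gender", "gender2")),
    "rank-deficient")
  ## >2 categories
  pp$multi <- factor(sample(c("a", "b", "c"), nrow(pp), TRUE))
  expect_error(fit_hazard_model(pp, covariates = "multi"), "dichotomous")
  ## unknown covariate
  expect_error(fit_hazard_model(pp, covariates = "nope"), "nope")
})

test_that("complete separation is flagged with a warning", {
  pp <- build_pp(cohort_config(300, c("2012" = 1), rep(0.3, 5), seed = 2))
  ## covariate equal to the outcome separates perfectly
  pp$oracle <- factor(ifelse(pp$event == 1, "yes", "no"),
                      levels = c("no", "yes"))
  expect_warning(fit_hazard_model(pp, covariates = "oracle"), "separation")
})

test_that("complete-case exclusion is per model and counted", {
  cfg <- test_scenario(n = 2000, seed = 3)
  rec <- generate_cohort(cfg)
  rec <- inject_missingness(rec, c(school_type = 0.3), seed = 99)
  spec <- cohort_spec()
  pp <- build_person_period(rec, select_entry_cohort(rec, spec), spec)
  n_na <- length(unique(pp$person_id[is.na(pp$school_type)]))
  fit <- fit_hazard_model(pp, covariates = "school_type")
  expect_equal(fit$n_dropped_persons, n_na)
  ## a model not using the covariate keeps everyone
  fit0 <- fit_hazard_model(pp, covariates = "gender")
  expect_equal(fit0$n_dropped_persons, 0L)
  ## aligning rows via drop_missing_on allows a nested comparison
  red <- fit_hazard_model(pp, covariates = "gender",
                          drop_missing_on = c("gender", "school_type"))
  full <- fit_hazard_model(pp, covariates = c("gender", "school_type"))
  expect_equal(red$n_rows, full$n_rows)
  expect_silent(lr_test(full, red))
})

test_that("survival curves obey the product formula and never cross", {
  pp <- build_pp(test_scenario(n = 3000, seed = 29))
  fit <- fit_hazard_model(pp, covariates = c("gender", "pmq_region"))
  base <- baseline_hazards(fit)
  expect_equal(base$survival, cumprod(1 - base$hazard), tolerance = 1e-12)
  expect_true(all(diff(base$survival) <= 0))
  ## reference pattern reproduces the baseline exactly
  ref_curve <- pattern_curve(fit, list(gender = "male", pmq_region = "UK"))
  expect_equal(ref_curve$hazard, base$hazard)
  ## a positive-coefficient pattern sits above the baseline hazard always
  fem <- pattern_curve(fit, list(gender = "female", pmq_region = "UK"))
  expect_true(fit$covariate_coefficients[["gender=female"]] > 0)
  expect_true(all(fem$hazard > base$hazard))
  ## survival curves of patterns differing in one covariate never cross
  expect_true(all(fem$survival < ref_curve$survival))
  ## proportionality by construction: per-period odds ratio identical in t
  or_t <- (fem$hazard / (1 - fem$hazard)) /
    (ref_curve$hazard / (1 - ref_curve$hazard))
  expect_equal(or_t, rep(exp(fit$covariate_coefficients[["gender=female"]]), 5),
               tolerance = 1e-10)
})

test_that("pattern assignment is validated", {
  pp <- build_pp(test_scenario(n = 800, seed = 29))
  fit <- fit_hazard_model(pp, covariates = "gender")
  expect_error(pattern_curve(fit, list()), "assign every")
  expect_error(pattern_curve(fit, list(gender = "male", nope = 1)), "nope")
  expect_error(pattern_curve(fit, list(gender = "other")), "category")
})

test_that("odds ratios invert under reference recoding and CIs are
           log-symmetric", {
  pp <- build_pp(test_scenario(n = 2000, seed = 37))
  fit <- fit_hazard_model(pp, covariates = "gender")
  flip <- fit_hazard_model(pp, covariates = "gender",
                           reference = list(gender = "female"))
  e <- effect_estimates(fit)
  ef <- effect_estimates(flip)
  expect_equal(ef$odds_ratio, 1 / e$odds_ratio, tolerance = 1e-8)
  ## recoding swaps and inverts the CI endpoints too
  expect_equal(ef$ci_low, 1 / e$ci_high, tolerance = 1e-8)
  ## Wald CI is symmetric on the log scale
  expect_equal(e$ci_high / e$odds_ratio, e$odds_ratio / e$ci_low,
               tolerance = 1e-10)
  expect_true(e$ci_low <= e$odds_ratio && e$odds_ratio <= e$ci_high)
})

test_that("likelihood-ratio test identities", {
  pp <- build_pp(test_scenario(n = 1500, seed = 41))
  full <- fit_hazard_model(pp, covariates = c("gender", "pmq_region"))
  red <- fit_hazard_model(pp, covariates = "gender",
                          drop_missing_on = c("gender", "pmq_region"))
  out <- lr_test(full, red)
  expect_gte(out$chi2, 0)
  expect_equal(out$df, 1)
  ## identical models: chi2 = 0, p = 1
  same <- lr_test(full, full)
  expect_equal(same$chi2, 0)
  expect_equal(same$p_value, 1)
  ## non-nested models refuse
  other <- fit_hazard_model(pp, covariates = "school_type")
  expect_error(lr_test(full, other), "nested")
})

test_that("pseudo R-squared matches a direct likelihood evaluation", {
  pp <- toy_person_periods()
  fit <- fit_hazard_model(pp, covariates = "x")
  ## independent oracle: minimise -2LL over the 6 parameters directly
  X <- cbind(outer(pp$time, 1:5, `==`) * 1, x = as.numeric(pp$x == "yes"))
  nll <- function(b) {
    mu <- stats::plogis(drop(X %*% b))
    -2 * sum(pp$event * log(mu) + (1 - pp$event) * log(1 - mu))
  }
  opt <- stats::optim(rep(0, 6), nll, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 1000))
  opt_null <- stats::optim(rep(0, 5), function(b) nll(c(b, 0)),
                           method = "BFGS",
                           control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(fit$minus2LL, opt$value, tolerance = 1e-6)
  expect_equal(fit$null_minus2LL, opt_null$value, tolerance = 1e-6)
  r2 <- pseudo_r2(fit)
  n <- nrow(pp)
  cs_direct <- 1 - exp((opt$value - opt_null$value) / n)
  expect_equal(r2$cox_snell, cs_direct, tolerance = 1e-6)
  expect_equal(r2$nagelkerke, cs_direct / (1 - exp(-opt_null$value / n)),
               tolerance = 1e-6)
  expect_gte(r2$nagelkerke, r2$cox_snell)
  ## covariate-free fit: both zero
  r20 <- pseudo_r2(fit_hazard_model(pp))
  expect_equal(r20$cox_snell, 0)
  expect_equal(r20$nagelkerke, 0)
})

test_that("interaction decisions follow the significance-or-deltaLL rule", {
  ## bare rule: boundary inclusive on the -2LL improvement
  expect_false(interaction_rule(p_value = 0.850, delta_minus2LL = 0))
  expect_true(interaction_rule(p_value = 0.850, delta_minus2LL = 4.0))
  expect_true(interaction_rule(p_value = 0.01, delta_minus2LL = 0))
  expect_false(interaction_rule(p_value = 0.06, delta_minus2LL = 3.99))
  ## a strong simulated interaction (log-odds 1.0) is included; simulated
  ## directly on the person-period scale, independent of the generator
  sim_pp <- function(n, b_int, seed) {
    set.seed(seed)
    x1 <- stats::rbinom(n, 1, 0.5)
    x2 <- stats::rbinom(n, 1, 0.5)
    eta0 <- stats::qlogis(c(0.2, 0.2, 0.5, 0.2, 0.2))
    alive <- rep(TRUE, n)
    out <- list()
    for (t in 1:5) {
      idx <- which(alive)
      p <- stats::plogis(eta0[t] + 0.3 * x1[idx] + 0.3 * x2[idx] +
                           b_int * x1[idx] * x2[idx])
      ev <- stats::rbinom(length(idx), 1, p)
      out[[t]] <- tibble::tibble(
        person_id = sprintf("S%05d", idx), time = t, event = ev,
        entry_year = 2012L,
        g1 = factor(c("no", "yes")[x1[idx] + 1], levels = c("no", "yes")),
        g2 = factor(c("no", "yes")[x2[idx] + 1], levels = c("no", "yes")))
      alive[idx[ev == 1]] <- FALSE
    }
    do.call(rbind, out)
  }
  pp <- sim_pp(20000, b_int = 1.0, seed = 77)
  with_int <- fit_hazard_model(pp, covariates = c("g1", "g2"),
                               interactions = list(c("g1", "g2")))
  without <- fit_hazard_model(pp, covariates = c("g1", "g2"))
  expect_true(interaction_decision(with_int, without)$include)
  ## rows mismatch refuses
  pp2 <- pp[pp$person_id != "S00001", ]
  other <- fit_hazard_model(pp2, covariates = c("g1", "g2"))
  expect_error(interaction_decision(with_int, other), "row sets")
})
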