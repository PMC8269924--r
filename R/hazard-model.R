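#' Fit the discrete-time logistic hazard model
#'
#' Maximum-likelihood fit of the Bernoulli likelihood
#' `sum(y*log(mu) + (1-y)*log(1-mu))` with
#' `mu = plogis(sum(beta_t * 1[time == t]) + sum(beta_k * x_k))`:
#' the five time dummies are entered as intercepts (no global intercept --
#' the dummies span it, and a global-intercept parameterisation is refused
#' by construction), and each dichotomous covariate contributes a single
#' 0/1 column for its non-reference category.  Because covariates are
#' time-constant, their per-period odds ratio is identical across
#' transitions (the proportional-odds structure holds by construction).
#'
#' Rows with a missing value on any covariate in `drop_missing_on`
#' (default: the requested covariates) are removed before fitting and the
#' dropped person count is recorded; passing a superset allows a reduced
#' model to be fitted on exactly the rows of a larger model, as the
#' likelihood-ratio test requires.
#'
#' Estimation is damped Newton (iteratively reweighted least squares with
#' step halving), converged when the largest score component falls below
#' `1e-8` or the relative change in -2 log likelihood falls below `1e-10`,
#' capped at 100 iterations.  The covariance matrix is the inverse observed
#' information at the optimum.  A rank-deficient design (e.g. a constant or
#' duplicated covariate) is an error naming the offending columns; apparent
#' complete separation is flagged with a warning, not silently returned.
#'
#' @param person_periods Person-period tibble from [build_person_period()].
#' @param covariates Character vector of covariate column names (2-level
#'   factors or logicals); empty for the intercepts-only model, whose
#'   fitted hazards equal the empirical event proportions `d_t / n_t`.
#' @param interactions List of character pairs of covariate names; each
#'   adds the product of the two 0/1 codes.
#' @param reference Named list overriding the reference category of a
#'   covariate (recoding flips the sign of its coefficient, i.e. inverts
#'   its odds ratio).
#' @param drop_missing_on Covariate names whose missingness defines the
#'   complete-case row set.
#' @return An object of class `hazard_fit` with elements
#'   `time_coefficients`, `covariate_coefficients`, `coefficients`,
#'   `vcov`, `minus2LL`, `null_minus2LL`, `n_rows`, `n_persons`,
#'   `n_dropped_persons`, `converged`, `coding`.
#' @export
fit_hazard_model <- function(person_periods,
                             covariates = character(),
                             interactions = list(),
                             reference = list(),
                             drop_missing_on = covariates) {
  tmax <- n_transitions()
  pp <- person_periods
  stopifnot(all(c("person_id", "time", "event") %in% names(pp)))
  missing_cov <- setdiff(union(covariates, drop_missing_on), names(pp))
  if (length(missing_cov) > 0) {
    stop("unknown covariate(s): ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }

  ## complete-case handling, per model: drop every row of a person with a
  ## missing value on any covariate in drop_missing_on
  n_persons_all <- length(unique(pp$person_id))
  if (length(drop_missing_on) > 0) {
    has_na <- Reduce(`|`, lapply(drop_missing_on, function(nm) is.na(pp[[nm]])))
    drop_persons <- unique(pp$person_id[has_na])
    pp <- pp[!pp$person_id %in% drop_persons, , drop = FALSE]
  }
  n_persons <- length(unique(pp$person_id))

  y <- pp$event
  if (sum(y) == 0 || sum(y) == length(y)) {
    stop("model requires at least one event and one non-event", call. = FALSE)
  }

  ## design: 5 time dummies, then one 0/1 column per covariate/interaction
  Xt <- vapply(seq_len(tmax), function(t) as.numeric(pp$time == t),
               numeric(nrow(pp)))
  colnames(Xt) <- paste0("t", seq_len(tmax))
  coding <- list()
  Xc_cols <- list()
  for (nm in covariates) {
    code <- code_covariate(pp[[nm]], nm, reference[[nm]])
    coding[[nm]] <- code$coding
    Xc_cols[[code$label]] <- code$x
  }
  for (pair in interactions) {
    if (length(pair) != 2 || !all(pair %in% covariates)) {
      stop("each interaction must be a pair of fitted covariate names",
           call. = FALSE)
    }
    lab <- vapply(pair, function(nm) coding[[nm]]$label, character(1))
    Xc_cols[[paste(lab, collapse = ":")]] <-
      Xc_cols[[lab[1]]] * Xc_cols[[lab[2]]]
  }
  Xc <- if (length(Xc_cols) > 0) do.call(cbind, Xc_cols) else
    matrix(0, nrow(pp), 0)
  X <- cbind(Xt, Xc)

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient design; offending column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }

  fit <- irls_logit(X, y)
  null_fit <- if (ncol(Xc) > 0) irls_logit(Xt, y) else fit

  if (fit$converged && any(abs(fit$beta) > 12)) {
    warning("very large coefficient(s); possible complete separation: ",
            paste(names(fit$beta)[abs(fit$beta) > 12], collapse = ", "),
            call. = FALSE)
  }
  if (!fit$converged) {
    warning("hazard model did not converge within the iteration cap ",
            "(max |score| = ", format(fit$max_score), ")", call. = FALSE)
  }

  structure(
    list(
      time_coefficients = fit$beta[seq_len(tmax)],
      covariate_coefficients = fit$beta[-seq_len(tmax)],
      coefficients = fit$beta,
      vcov = fit$vcov,
      minus2LL = fit$minus2LL,
      null_minus2LL = null_fit$minus2LL,
      n_rows = nrow(pp),
      n_persons = n_persons,
      n_dropped_persons = n_persons_all - n_persons,
      converged = fit$converged,
      max_score = fit$max_score,
      iterations = fit$iterations,
      coding = coding,
      covariates = covariates,
      interactions = interactions
    ),
    class = "hazard_fit"
  )
}

## 0/1 coding of a dichotomous covariate; reference category coded 0.
code_covariate <- function(col, name, reference = NULL) {
  if (is.logical(col)) {
    ref <- if (is.null(reference)) FALSE else reference
    x <- as.numeric(col != ref)
    alt <- !ref
  } else {
    lv <- if (is.factor(col)) levels(col) else sort(unique(as.character(col)))
    if (length(lv) != 2) {
      stop("covariate '", name, "' must be dichotomous; levels: ",
           paste(lv, collapse = ", "), call. = FALSE)
    }
    ref <- if (is.null(reference)) lv[1] else reference
    if (!ref %in% lv) {
      stop("reference category '", ref, "' not a level of '", name, "'",
           call. = FALSE)
    }
    alt <- setdiff(lv, ref)
    x <- as.numeric(as.character(col) == alt)
  }
  list(x = x,
       label = paste0(name, "=", alt),
       coding = list(reference = ref, coded = alt,
                     label = paste0(name, "=", alt)))
}

## One extra full Newton step from an (almost) converged point: quadratic
## convergence squares the residual, pushing fitted hazards to machine
## precision.  Declined if it would not keep the -2LL non-increasing.
polish_newton <- function(X, y, beta, cur, m2ll) {
  mu <- stats::plogis(drop(X %*% beta))
  score <- drop(crossprod(X, y - mu))
  H <- crossprod(X, X * (mu * (1 - mu)))
  delta <- tryCatch(solve(H, score), error = function(e) NULL)
  if (!is.null(delta)) {
    cand <- beta + delta
    new <- m2ll(cand)
    if (is.finite(new) && new <= cur + 1e-12) {
      beta <- cand
      cur <- new
      mu <- stats::plogis(drop(X %*% beta))
      score <- drop(crossprod(X, y - mu))
      H <- crossprod(X, X * (mu * (1 - mu)))
    }
  }
  list(beta = beta, m2ll = cur, score = score,
       max_score = max(abs(score)), H = H)
}

## Damped Newton / IRLS for the Bernoulli log-likelihood with logit link.
irls_logit <- function(X, y, tol_score = 1e-8, tol_rel = 1e-10,
                       maxit = 100L) {
  beta <- rep(0, ncol(X))
  names(beta) <- colnames(X)
  m2ll <- function(b) {
    mu <- stats::plogis(drop(X %*% b))
    -2 * sum(stats::dbinom(y, 1L, mu, log = TRUE))
  }
  cur <- m2ll(beta)
  converged <- FALSE
  max_score <- Inf
  it <- 0L
  H <- NULL
  while (it < maxit) {
    it <- it + 1L
    mu <- stats::plogis(drop(X %*% beta))
    score <- drop(crossprod(X, y - mu))
    max_score <- max(abs(score))
    w <- mu * (1 - mu)
    H <- crossprod(X, X * w)
    if (max_score < tol_score) {
      st <- polish_newton(X, y, beta, cur, m2ll)
      beta <- st$beta; cur <- st$m2ll; score <- st$score
      max_score <- st$max_score; H <- st$H
      converged <- TRUE
      break
    }
    delta <- tryCatch(solve(H, score), error = function(e) {
      solve(H + diag(1e-10, ncol(X)), score)
    })
    step <- 1
    repeat {
      cand <- beta + step * delta
      new <- m2ll(cand)
      if (is.finite(new) && new <= cur + 1e-12) break
      step <- step / 2
      if (step < 2^-30) break
    }
    beta <- beta + step * delta
    new <- m2ll(beta)
    if (abs(cur - new) < tol_rel * (abs(new) + 1)) {
      st <- polish_newton(X, y, beta, new, m2ll)
      beta <- st$beta; cur <- st$m2ll; score <- st$score
      max_score <- st$max_score; H <- st$H
      converged <- TRUE
      break
    }
    cur <- new
  }
  vcov <- tryCatch(solve(H), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  dimnames(vcov) <- list(names(beta), names(beta))
  list(beta = beta, vcov = vcov, minus2LL = cur, converged = converged,
       max_score = max_score, iterations = it)
}

#' @export
print.hazard_fit <- function(x, ...) {
  cat("Discrete-time logistic hazard model\n")
  cat(sprintf("  person-period rows: %d  persons: %d (dropped: %d)\n",
              x$n_rows, x$n_persons, x$n_dropped_persons))
  cat(sprintf("  -2LL: %.3f  (intercepts-only: %.3f)  converged: %s\n",
              x$minus2LL, x$null_minus2LL, x$converged))
  se <- sqrt(diag(x$vcov))
  tab <- data.frame(estimate = x$coefficients, se = se)
  print(round(tab, 4))
  invisible(x)
}

#' Baseline hazards and survival for the reference pattern
#'
#' Per-transition hazard `h_t = plogis(beta_t)` and cumulative survival
#' `S_t = prod(1 - h_j, j <= t)` at the reference covariate pattern (all
#' covariates at their reference category).  A positive time coefficient
#' means more trainees do not progress than do (`h_t > 0.5`).
#'
#' @param fit A converged [fit_hazard_model()] result.
#' @return A `survival_curve`: tibble with columns `time`, `hazard`,
#'   `survival`, plus a `pattern` attribute.
#' @export
baseline_hazards <- function(fit) {
  ref <- lapply(fit$coding, function(cd) cd$reference)
  pattern_curve(fit, ref)
}

#' Hazard and survival curve for a covariate pattern
#'
#' `h_t(pattern) = plogis(beta_t + sum(beta_k * x_k))`, survival by the
#' product formula.  Two patterns differing in one covariate yield curves
#' that never cross: the log-odds shift is constant over time.
#'
#' @param fit A converged [fit_hazard_model()] result.
#' @param pattern Named list assigning every fitted covariate a category.
#' @return A `survival_curve` tibble (`time`, `hazard`, `survival`).
#' @export
pattern_curve <- function(fit, pattern = list()) {
  missing_assign <- setdiff(fit$covariates, names(pattern))
  if (length(missing_assign) > 0) {
    stop("pattern must assign every fitted covariate; missing: ",
         paste(missing_assign, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(pattern), fit$covariates)
  if (length(unknown) > 0) {
    stop("pattern names covariates not in the fit: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  offset <- 0
  xvals <- list()
  for (nm in fit$covariates) {
    cd <- fit$coding[[nm]]
    val <- pattern[[nm]]
    x <- if (identical(val, cd$coded) ||
             identical(as.character(val), as.character(cd$coded))) 1 else
      if (identical(val, cd$reference) ||
          identical(as.character(val), as.character(cd$reference))) 0 else
        stop("pattern value '", val, "' is not a category of '", nm, "'",
             call. = FALSE)
    xvals[[cd$label]] <- x
    offset <- offset + fit$covariate_coefficients[[cd$label]] * x
  }
  for (pair in fit$interactions) {
    labs <- vapply(pair, function(nm) fit$coding[[nm]]$label, character(1))
    ilab <- paste(labs, collapse = ":")
    offset <- offset +
      fit$covariate_coefficients[[ilab]] * xvals[[labs[1]]] * xvals[[labs[2]]]
  }
  hazard <- stats::plogis(fit$time_coefficients + offset)
  curve <- tibble::tibble(time = seq_along(hazard),
                          hazard = unname(hazard),
                          survival = cumprod(1 - unname(hazard)))
  attr(curve, "pattern") <- pattern
  class(curve) <- c("survival_curve", class(curve))
  curve
}

#' Odds ratios with Wald confidence intervals
#'
#' For every covariate and interaction term: `OR = exp(beta)`,
#' 95% CI `exp(beta +/- z * SE)` with the 0.975 normal quantile, and a
#' two-sided Wald p-value.  On the event scale (event = did not progress)
#' an OR above 1 means higher per-period odds of not progressing, i.e.
#' lower odds of completing in the minimum time; recoding the reference
#' category inverts the OR.
#'
#' @param fit A converged [fit_hazard_model()] result.
#' @param level Confidence level (default 0.95).
#' @return A tibble: `term`, `estimate`, `se`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
effect_estimates <- function(fit, level = 0.95) {
  terms <- names(fit$covariate_coefficients)
  if (length(terms) == 0) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          se = numeric(), odds_ratio = numeric(),
                          ci_low = numeric(), ci_high = numeric(),
                          p_value = numeric()))
  }
  beta <- fit$covariate_coefficients
  se <- sqrt(diag(fit$vcov))[terms]
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    term = terms,
    estimate = unname(beta),
    se = unname(se),
    odds_ratio = exp(unname(beta)),
    ci_low = exp(unname(beta) - z * unname(se)),
    ci_high = exp(unname(beta) + z * unname(se)),
    p_value = 2 * stats::pnorm(-abs(unname(beta) / unname(se)))
  )
}

#' Likelihood-ratio test between nested hazard models
#'
#' `chi2 = reduced$minus2LL - full$minus2LL` on the difference in
#' parameter count, with both models fitted on identical rows (use
#' `drop_missing_on` in [fit_hazard_model()] to align complete-case sets).
#'
#' @param fit Full model.
#' @param reduced_fit Nested reduced model.
#' @return A list with `chi2`, `df`, `p_value`.
#' @export
lr_test <- function(fit, reduced_fit) {
  full_terms <- names(fit$coefficients)
  red_terms <- names(reduced_fit$coefficients)
  if (!all(red_terms %in% full_terms)) {
    stop("models are not nested: reduced model has terms absent from the ",
         "full model", call. = FALSE)
  }
  if (fit$n_rows != reduced_fit$n_rows) {
    stop("models were fitted on different row sets (", fit$n_rows, " vs ",
         reduced_fit$n_rows, " rows); refit with a common drop_missing_on",
         call. = FALSE)
  }
  chi2 <- reduced_fit$minus2LL - fit$minus2LL
  df <- length(full_terms) - length(red_terms)
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p_value = p)
}

#' Cox-Snell and Nagelkerke pseudo R-squared
#'
#' Computed against the intercepts-only (time-dummies-only) model on the
#' same rows: Cox-Snell `1 - exp((minus2LL - null_minus2LL) / n_rows)`,
#' Nagelkerke rescales it by its attainable maximum
#' `1 - exp(-null_minus2LL / n_rows)`.  Both are reported because common
#' software prints both and published values rarely say which.
#'
#' @param fit A converged [fit_hazard_model()] result.
#' @return A list with `cox_snell` and `nagelkerke`.
#' @export
pseudo_r2 <- function(fit) {
  cs <- 1 - exp((fit$minus2LL - fit$null_minus2LL) / fit$n_rows)
  max_cs <- 1 - exp(-fit$null_minus2LL / fit$n_rows)
  list(cox_snell = cs, nagelkerke = cs / max_cs)
}

#' Decide whether an interaction term enters the final model
#'
#' The interaction is included when its Wald test is significant at
#' `alpha` *or* the -2 log likelihood improves by at least
#' `delta_threshold` (inclusive at the boundary).
#'
#' @param fit_with Model including the interaction term(s).
#' @param fit_without The same model without them (same rows).
#' @param alpha Significance level for the Wald test (default 0.05).
#' @param delta_threshold Required -2LL improvement (default 4).
#' @return A list: `include`, `p_value` (Wald, for the added terms),
#'   `delta_minus2LL`, `rationale`.
#' @export
interaction_decision <- function(fit_with, fit_without,
                                 alpha = 0.05, delta_threshold = 4) {
  added <- setdiff(names(fit_with$coefficients),
                   names(fit_without$coefficients))
  if (length(added) == 0 ||
      !all(names(fit_without$coefficients) %in%
             names(fit_with$coefficients))) {
    stop("fit_with must nest fit_without plus the interaction term(s)",
         call. = FALSE)
  }
  if (fit_with$n_rows != fit_without$n_rows) {
    stop("models were fitted on different row sets", call. = FALSE)
  }
  ## Wald test of the added terms (chi-squared on their joint estimate)
  b <- fit_with$coefficients[added]
  V <- fit_with$vcov[added, added, drop = FALSE]
  w <- drop(t(b) %*% solve(V) %*% b)
  p <- stats::pchisq(w, df = length(added), lower.tail = FALSE)
  delta <- fit_without$minus2LL - fit_with$minus2LL
  include <- interaction_rule(p, delta, alpha, delta_threshold)
  rationale <- sprintf(
    "Wald p = %.4g (alpha = %g); delta -2LL = %.4g (threshold %g): %s",
    p, alpha, delta, delta_threshold,
    if (include) "include" else "exclude")
  list(include = include, p_value = p, delta_minus2LL = delta,
       rationale = rationale)
}

#' @rdname interaction_decision
#' @param p_value Significance of the interaction term(s).
#' @param delta_minus2LL Improvement in -2 log likelihood from adding them.
#' @details `interaction_rule()` is the bare decision rule on an already
#'   computed p-value and -2LL improvement; `interaction_decision()`
#'   computes both from a pair of nested fits and applies it.
#' @export
interaction_rule <- function(p_value, delta_minus2LL,
                             alpha = 0.05, delta_threshold = 4) {
  (p_value < alpha) || (delta_minus2LL >= delta_threshold)
}
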