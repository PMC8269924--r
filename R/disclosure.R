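#' Statistical disclosure control rules for published figures
#'
#' The rounding and suppression policy applied to every published count,
#' percentage and average when reporting registry-derived statistics:
#' counts of 0, 1 or 2 are published as 0 and all other counts are rounded
#' to the nearest multiple of 5; percentages based on fewer than 22.5
#' individuals are suppressed; averages based on seven or fewer
#' individuals are suppressed.  Suppression thresholds apply to the
#' *unrounded* base, and disclosure is applied only at the reporting
#' boundary -- every internal computation uses raw values.
#'
#' @param rounding_base Multiple to which counts are rounded.
#' @param small_values Counts published as 0.
#' @param percentage_suppression_threshold Minimum base for a percentage.
#' @param average_suppression_threshold Bases of at most this many values
#'   have their average suppressed.
#' @return An object of class `disclosure_rules`.
#' @export
disclosure_rules <- function(rounding_base = 5L,
                             small_values = c(0L, 1L, 2L),
                             percentage_suppression_threshold = 22.5,
                             average_suppression_threshold = 7L) {
  stopifnot(rounding_base >= 1,
            percentage_suppression_threshold > 0,
            average_suppression_threshold > 0)
  structure(
    list(rounding_base = as.integer(rounding_base),
         small_values = as.integer(small_values),
         percentage_suppression_threshold = percentage_suppression_threshold,
         average_suppression_threshold = as.integer(
           average_suppression_threshold)),
    class = "disclosure_rules"
  )
}

#' Round a count for publication
#'
#' Counts in the small-value set map to 0; every other count maps to the
#' nearest multiple of the rounding base (integer counts have a unique
#' nearest multiple of 5, so no tie-break is ever needed).  Non-integer or
#' negative inputs are rejected.
#'
#' @param n Vector of nonnegative integer counts.
#' @param rules A [disclosure_rules()] object.
#' @return Integer vector of disclosed counts.
#' @export
round_count <- function(n, rules = disclosure_rules()) {
  if (any(n < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(n != as.integer(n))) {
    stop("counts must be integers", call. = FALSE)
  }
  n <- as.integer(n)
  out <- as.integer(rules$rounding_base * round(n / rules$rounding_base))
  out[n %in% rules$small_values] <- 0L
  out
}

#' Disclose a percentage
#'
#' Suppressed (returned as `NA`) when the unrounded base is below the
#' threshold; otherwise the percentage rounded to one decimal place.
#' A zero denominator yields suppression, not a division error.
#'
#' @param numerator,denominator Raw (unrounded) counts.
#' @param rules A [disclosure_rules()] object.
#' @return Numeric vector of percentages, `NA` where suppressed.
#' @export
disclose_percentage <- function(numerator, denominator,
                                rules = disclosure_rules()) {
  if (any(denominator < 0)) stop("denominator must be nonnegative",
                                 call. = FALSE)
  pct <- ifelse(denominator > 0,
                round(100 * numerator / denominator, 1), NA_real_)
  pct[denominator < rules$percentage_suppression_threshold] <- NA_real_
  pct
}

#' Disclose an average
#'
#' Suppressed (returned as `NA`) when based on at most the threshold
#' number of individuals; otherwise the arithmetic mean.
#'
#' @param values Raw values.
#' @param rules A [disclosure_rules()] object.
#' @return The mean, or `NA` if suppressed.
#' @export
disclose_average <- function(values, rules = disclosure_rules()) {
  if (length(values) <= rules$average_suppression_threshold) return(NA_real_)
  mean(values)
}

#' Apply disclosure control to a counts table
#'
#' Rounds every numeric column of integer counts and marks suppressed
#' cells with `"~"`.  Columns named in `percentage_cols` are treated as
#' percentages with their base taken from `base_col` and suppressed below
#' the percentage threshold.
#'
#' @param counts A data frame of counts (and optionally percentages).
#' @param rules A [disclosure_rules()] object.
#' @param percentage_cols Character vector of percentage column names.
#' @param base_col Name of the column holding each row's unrounded base.
#' @return A tibble of the same shape with character columns: disclosed
#'   counts, percentages to one decimal, `"~"` for suppressed cells.
#' @export
disclose_table <- function(counts, rules = disclosure_rules(),
                           percentage_cols = character(),
                           base_col = NULL) {
  out <- tibble::as_tibble(counts)
  for (nm in names(out)) {
    col <- out[[nm]]
    if (!is.numeric(col)) next
    if (nm %in% percentage_cols) {
      base <- if (is.null(base_col)) rep(Inf, nrow(out)) else counts[[base_col]]
      disclosed <- ifelse(base < rules$percentage_suppression_threshold,
                          "~", sprintf("%.1f", col))
      out[[nm]] <- disclosed
    } else {
      out[[nm]] <- as.character(round_count(col, rules))
    }
  }
  out
}
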