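#' Ordinary least-squares fit of a marker against age
#'
#' Fits `value ~ age` by OLS and reports the two-sided Pearson correlation
#' p-value, matching the convention of reporting regression lines with
#' Pearson-test P values.
#'
#' @param age Numeric vector, years.
#' @param value Numeric vector, marker values (same length).
#' @return An object of class `linear_age_fit`: list with `slope`,
#'   `intercept`, `r_squared`, `pearson_p`, `n`.
#' @export
fit_linear_vs_age <- function(age, value) {
  ok <- is.finite(age) & is.finite(value)
  age <- age[ok]; value <- value[ok]
  if (length(age) < 3L) stop("need at least 3 finite (age, value) pairs")
  if (length(unique(age)) < 2L) stop("degenerate ages: all equal")
  fit <- stats::lm.fit(cbind(1, age), value)
  slope <- unname(fit$coefficients[2])
  intercept <- unname(fit$coefficients[1])
  ssr <- sum(fit$residuals^2)
  sst <- sum((value - mean(value))^2)
  r2 <- if (sst == 0) 0 else 1 - ssr / sst
  p <- if (sst == 0 || stats::sd(value) == 0) NA_real_ else
    stats::cor.test(age, value)$p.value
  structure(list(slope = slope, intercept = intercept,
                 r_squared = max(0, min(1, r2)), pearson_p = p,
                 n = length(age)),
            class = "linear_age_fit")
}

#' Pseudo-first-order exponential decay fit of a marker against age
#'
#' Assumes `Activity(t) = Activity0 * exp(-k * t)` and fits by OLS on the
#' natural-log-transformed values (the log-linear form), as is standard for
#' pseudo-first-order kinetics. Non-positive values are excluded (their
#' count is recorded) rather than offset-shifted. If the fitted slope is
#' non-negative the marker shows no decline: `k` is reported as the fitted
#' value and `half_life` as `Inf`, with `declining = FALSE`.
#'
#' @param age Numeric vector, years.
#' @param value Numeric vector, marker values; only positive values enter
#'   the log-space fit.
#' @return An object of class `decay_fit`: list with `k` (per year),
#'   `activity0` (units at age 0), `half_life` (years, `ln(2)/k`),
#'   `r_squared`, `pearson_p`, `n`, `n_excluded`, `declining`.
#' @export
fit_exponential_decay <- function(age, value) {
  ok <- is.finite(age) & is.finite(value)
  n_excluded <- sum(ok & value <= 0)
  use <- ok & value > 0
  if (sum(use) < 3L) stop("fewer than 3 usable (age, positive value) pairs")
  lin <- fit_linear_vs_age(age[use], log(value[use]))
  k <- -lin$slope
  declining <- k > 1e-12  # guard against numerically-zero slopes
  structure(list(k = k,
                 activity0 = exp(lin$intercept),
                 half_life = if (declining) log(2) / k else Inf,
                 r_squared = lin$r_squared,
                 pearson_p = lin$pearson_p,
                 n = lin$n, n_excluded = n_excluded,
                 declining = declining),
            class = "decay_fit")
}

#' Age-normalize marker values against a cohort regression
#'
#' Default (`mode = "ratio"`): the observed value divided by the cohort
#' regression prediction at that age — dimensionless and centered at 1, so a
#' point exactly on the regression line maps to 1. The alternative
#' (`mode = "residual"`) returns `1 + (observed - predicted)/mean(predicted)`,
#' a residual rescaled to the same unit-centered scale.
#'
#' @param value Observed marker value(s).
#' @param age Age(s) in years.
#' @param fit A `linear_age_fit` for this marker over the cohort.
#' @param mode `"ratio"` (default) or `"residual"`.
#' @param mean_predicted Cohort mean of predicted values; required for
#'   `"residual"` mode.
#' @return Dimensionless normalized value(s).
#' @export
age_normalize <- function(value, age, fit, mode = c("ratio", "residual"),
                          mean_predicted = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "linear_age_fit"))
  pred <- fit$intercept + fit$slope * age
  if (mode == "ratio") {
    if (any(pred <= 0, na.rm = TRUE)) {
      stop("regression predicts non-positive values in the observed age ",
           "range; unusable for ratio normalization")
    }
    value / pred
  } else {
    if (is.null(mean_predicted)) stop("mean_predicted required for residual mode")
    1 + (value - pred) / mean_predicted
  }
}

#' @export
print.linear_age_fit <- function(x, ...) {
  cat(sprintf("Linear age fit: value = %.4g %+.4g*age (n=%d, R2=%.3f, P=%.3g)\n",
              x$intercept, x$slope, x$n, x$r_squared, x$pearson_p))
  invisible(x)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "Pseudo-first-order decay: k=%.4g /y, half-life=%.3g y (n=%d, R2=%.3f, P=%.3g)\n",
    x$k, x$half_life, x$n, x$r_squared, x$pearson_p))
  if (!x$declining) cat("  [no decline: slope >= 0]\n")
  invisible(x)
}

#' Serialize age-model fits to JSON for provenance
#'
#' @param fits Named list of `linear_age_fit` / `decay_fit` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fits_json <- function(fits, path) {
  payload <- lapply(fits, function(f) unclass(f))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
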