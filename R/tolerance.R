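#' Tolerance specification
#'
#' A one-sided tolerance limit bounds at least a proportion `content` of the
#' population with confidence `confidence`. Defaults follow the common
#' clinical-chemistry choice: 90 % content at 95 % confidence.
#'
#' @param content Population proportion P in (0, 1); default 0.90.
#' @param confidence Confidence gamma in (0, 1); default 0.95.
#' @param side `"lower"` or `"upper"`.
#' @return List of class `tolerance_spec`.
#' @export
tolerance_spec <- function(content = 0.90, confidence = 0.95,
                           side = c("upper", "lower")) {
  side <- match.arg(side)
  stopifnot(content > 0, content < 1, confidence > 0, confidence < 1)
  structure(list(content = content, confidence = confidence, side = side),
            class = "tolerance_spec")
}

#' Exact k factor for a one-sided normal tolerance limit
#'
#' `k = qt(gamma, df = n - 1, ncp = z_P * sqrt(n)) / sqrt(n)` — the exact
#' noncentral-t construction, not Howe's approximation.
#'
#' @param n Sample size, >= 2.
#' @param content Population proportion P.
#' @param confidence Confidence gamma.
#' @return The k factor.
#' @export
normal_k_factor <- function(n, content = 0.90, confidence = 0.95) {
  if (n < 2) stop("n must be >= 2")
  zp <- stats::qnorm(content)
  stats::qt(confidence, df = n - 1, ncp = zp * sqrt(n)) / sqrt(n)
}

#' One-sided parametric-normal tolerance limit
#'
#' @param mean,sd Sample mean and (n-1 denominator) standard deviation.
#' @param n Sample size.
#' @param spec A [tolerance_spec()].
#' @return List of class `tolerance_limit` with `value`, `spec`, `n_obs`,
#'   `k_factor`, `method = "parametric_normal"`.
#' @export
normal_one_sided_limit <- function(mean, sd, n, spec = tolerance_spec()) {
  if (n < 2) stop("n must be >= 2")
  if (!is.finite(sd) || sd <= 0) stop("sd must be positive")
  k <- normal_k_factor(n, spec$content, spec$confidence)
  value <- if (spec$side == "upper") mean + k * sd else mean - k * sd
  structure(list(value = value, spec = spec, n_obs = n, k_factor = k,
                 order_index = NA_integer_, achieved_confidence = NA_real_,
                 method = "parametric_normal"),
            class = "tolerance_limit")
}

#' Minimum sample size for a nonparametric one-sided limit
#'
#' Smallest n whose extreme order statistic attains the stated confidence:
#' `1 - content^n >= confidence`, i.e. `n >= log(1 - confidence)/log(content)`.
#'
#' @param spec A [tolerance_spec()].
#' @return Integer minimum n.
#' @export
nonparametric_min_n <- function(spec = tolerance_spec()) {
  as.integer(ceiling(log(1 - spec$confidence) / log(spec$content)))
}

#' One-sided nonparametric (order-statistic) tolerance limit
#'
#' For an upper limit, returns the m-th order statistic where m is the
#' smallest integer with `pbinom(m - 1, n, content) >= confidence`; the
#' lower limit uses the reflected index `n - m + 1`. The returned value is
#' always an observed data point, so the limit is equivariant under any
#' strictly monotone transform of the data.
#'
#' @param data Numeric sample.
#' @param spec A [tolerance_spec()].
#' @return List of class `tolerance_limit` with `value`, `order_index`
#'   (1-based from the smallest observation), `achieved_confidence`.
#' @export
nonparametric_one_sided_limit <- function(data, spec = tolerance_spec()) {
  data <- data[is.finite(data)]
  n <- length(data)
  min_n <- nonparametric_min_n(spec)
  if (n < min_n) {
    stop(sprintf(paste0(
      "n = %d below nonparametric minimum %d for P=%g, gamma=%g ",
      "(extreme order statistic achieves only %.4f confidence)"),
      n, min_n, spec$content, spec$confidence,
      1 - spec$content^n))
  }
  m_candidates <- which(stats::pbinom(0:(n - 1), n, spec$content) >=
                          spec$confidence)
  m <- m_candidates[1]  # smallest m with BinomCDF(m-1; n, P) >= gamma
  achieved <- stats::pbinom(m - 1, n, spec$content)
  idx <- if (spec$side == "upper") m else n - m + 1L
  sorted <- sort(data)
  structure(list(value = sorted[idx], spec = spec, n_obs = n,
                 k_factor = NA_real_, order_index = as.integer(idx),
                 achieved_confidence = achieved,
                 method = "nonparametric"),
            class = "tolerance_limit")
}

#' Select the tolerance-limit method from the best-fitting family
#'
#' Parametric-normal when the AICc winner is Normal; otherwise the
#' distribution-free order-statistic limit.
#'
#' @param best_fit_family Family name from [select_best()].
#' @return `"parametric_normal"` or `"nonparametric"`.
#' @export
choose_method <- function(best_fit_family) {
  if (identical(best_fit_family, "Normal")) "parametric_normal"
  else "nonparametric"
}

#' Compute a one-sided tolerance limit with the method chosen by fit
#'
#' @param data Numeric sample.
#' @param method `"parametric_normal"` or `"nonparametric"`.
#' @param spec A [tolerance_spec()].
#' @return A `tolerance_limit`.
#' @export
tolerance_limit <- function(data, method, spec = tolerance_spec()) {
  data <- data[is.finite(data)]
  if (method == "parametric_normal") {
    normal_one_sided_limit(mean(data), stats::sd(data), length(data), spec)
  } else {
    nonparametric_one_sided_limit(data, spec)
  }
}

#' @export
print.tolerance_limit <- function(x, ...) {
  cat(sprintf("One-sided %s tolerance limit (%s): %.6g (P=%g, gamma=%g, n=%d)\n",
              x$spec$side, x$method, x$value, x$spec$content,
              x$spec$confidence, x$n_obs))
  invisible(x)
}
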