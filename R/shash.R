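#' The sinh-arcsinh (SHASH) distribution
#'
#' Density, distribution function, quantile function, random generation and
#' maximum-likelihood fitting for the four-parameter sinh-arcsinh family in
#' the Jones-Pewsey parameterization:
#' `X = xi + eta * sinh((asinh(Z) + eps) / delta)`, `Z ~ N(0,1)`.
#' `xi` is location, `eta > 0` scale, `eps` controls skewness (positive =
#' right skew) and `delta > 0` tail weight (`delta < 1` heavier than
#' normal). With `eps = 0, delta = 1` the family reduces exactly to
#' `Normal(xi, eta)`.
#'
#' @param x,q Vector of quantiles.
#' @param p Vector of probabilities.
#' @param n Number of draws.
#' @param xi Location.
#' @param eta Scale, > 0.
#' @param eps Skewness.
#' @param delta Tail weight, > 0.
#' @param log Logical; return log-density.
#' @name shash
NULL

# standard-normal transform of x under the SHASH map
shash_z <- function(x, xi, eta, eps, delta) {
  r <- (x - xi) / eta
  sinh(delta * asinh(r) - eps)
}

#' @rdname shash
#' @export
dshash <- function(x, xi = 0, eta = 1, eps = 0, delta = 1, log = FALSE) {
  stopifnot(eta > 0, delta > 0)
  r <- (x - xi) / eta
  w <- delta * asinh(r) - eps
  z <- sinh(w)
  # log |dz/dx| = log(delta * cosh(w)) - log(eta * sqrt(1 + r^2))
  ld <- stats::dnorm(z, log = TRUE) + log(delta) + log(cosh(w)) -
    log(eta) - 0.5 * log1p(r^2)
  if (log) ld else exp(ld)
}

#' @rdname shash
#' @export
pshash <- function(q, xi = 0, eta = 1, eps = 0, delta = 1) {
  stopifnot(eta > 0, delta > 0)
  stats::pnorm(shash_z(q, xi, eta, eps, delta))
}

#' @rdname shash
#' @export
qshash <- function(p, xi = 0, eta = 1, eps = 0, delta = 1) {
  stopifnot(eta > 0, delta > 0)
  xi + eta * sinh((asinh(stats::qnorm(p)) + eps) / delta)
}

#' @rdname shash
#' @export
rshash <- function(n, xi = 0, eta = 1, eps = 0, delta = 1) {
  stopifnot(eta > 0, delta > 0)
  qshash(stats::runif(n), xi, eta, eps, delta)
}

shash_negloglik <- function(theta, x) {
  # theta = (xi, log eta, eps, log delta)
  nll <- suppressWarnings(
    -sum(dshash(x, theta[1], exp(theta[2]), theta[3], exp(theta[4]),
                log = TRUE)))
  if (!is.finite(nll)) .Machine$double.xmax else nll
}

#' Maximum-likelihood SHASH fit
#'
#' Multi-start quasi-Newton optimization on `(xi, log eta, eps, log delta)`.
#' Starts are built from sample moments (a normal start `eps=0, delta=1`)
#' plus skew-tilted variants; the best converged optimum is returned.
#'
#' @param x Numeric data, length >= 8.
#' @param n_starts Number of optimizer starts (default 6).
#' @return List with `params` (named: xi, eta, eps, delta), `loglik`,
#'   `converged`.
#' @export
fit_shash <- function(x, n_starts = 6) {
  if (length(x) < 8L) stop("need at least 8 observations")
  m <- stats::median(x)
  s <- stats::mad(x)
  if (s == 0) s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("degenerate sample: zero spread")
  sk <- mean(((x - mean(x)) / stats::sd(x))^3)
  starts <- list(
    c(m, log(s), 0, 0),
    c(m, log(s), 0.5 * sign(sk), log(1.2)),
    c(m, log(s), -0.5 * sign(sk), log(0.8)),
    c(mean(x), log(stats::sd(x)), 0, 0),
    c(m, log(s * 1.5), sk, 0),
    c(m, log(s / 1.5), 0, log(1.5))
  )[seq_len(max(1, n_starts))]
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      stats::optim(st, shash_negloglik, x = x, method = "BFGS",
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    return(list(params = c(xi = NA, eta = NA, eps = NA, delta = NA),
                loglik = -Inf, converged = FALSE))
  }
  th <- best$par
  list(params = c(xi = th[1], eta = exp(th[2]), eps = th[3],
                  delta = exp(th[4])),
       loglik = -best$value,
       converged = best$convergence == 0)
}
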