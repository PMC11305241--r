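#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2*loglik + 2*k + 2*k*(k+1)/(n - k - 1)`.
#'
#' @param loglik Maximized log-likelihood in nats.
#' @param n_params Number of free parameters `k`.
#' @param n_obs Number of observations `n`; must exceed `n_params + 1`.
#' @return The AICc value.
#' @export
aicc <- function(loglik, n_params, n_obs) {
  if (n_obs <= n_params + 1) {
    stop("AICc requires n_obs > n_params + 1")
  }
  -2 * loglik + 2 * n_params + 2 * n_params * (n_params + 1) /
    (n_obs - n_params - 1)
}

#' Distribution catalog for marker fitting
#'
#' The eight families considered when selecting a marker's distribution:
#' Normal, LogNormal, Exponential, Gamma, Weibull, SHASH, and 2- and
#' 3-component normal mixtures. Positive-support families are skipped
#' (with a recorded reason) when the data contain non-positive values.
#'
#' @return Character vector of family names in catalog order.
#' @export
dist_catalog <- function() {
  c("Normal", "LogNormal", "Exponential", "Gamma", "Weibull", "SHASH",
    "NormalMixture2", "NormalMixture3")
}

dist_n_params <- function(family) {
  switch(family,
    Normal = 2L, LogNormal = 2L, Exponential = 1L, Gamma = 2L,
    Weibull = 2L, SHASH = 4L,
    NormalMixture2 = 5L, NormalMixture3 = 8L,
    stop("unknown family: ", family))
}

# ML fit of a two-parameter positive-support family by direct optimization
# on log-parameters (no closed form for Gamma/Weibull shape).
fit_positive_2par <- function(x, dens, start) {
  nll <- function(th) {
    v <- suppressWarnings(-sum(dens(x, exp(th[1]), exp(th[2]), log = TRUE)))
    if (!is.finite(v)) .Machine$double.xmax else v
  }
  opt <- stats::optim(log(start), nll, method = "BFGS",
                      control = list(maxit = 500))
  list(par = unname(exp(opt$par)), loglik = -opt$value,
       converged = opt$convergence == 0)
}

mixture_loglik <- function(x, w, mu, sigma) {
  m <- length(w)
  comp <- vapply(seq_len(m), function(j)
    log(w[j]) + stats::dnorm(x, mu[j], sigma[j], log = TRUE),
    numeric(length(x)))
  mx <- apply(comp, 1, max)
  sum(mx + log(rowSums(exp(comp - mx))))
}

#' Univariate Gaussian mixture fit by EM
#'
#' EM with k-means initialization plus random restarts; convergence when
#' the log-likelihood improves by less than `tol`. Components collapsing
#' below a floor of `1e-4 * sd(x)` are rejected and the restart discarded.
#'
#' @param x Data vector.
#' @param m Number of components (2 or 3).
#' @param n_starts Restarts (default 20); first uses k-means, the rest
#'   random responsibilities.
#' @param tol Log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter EM iteration cap per start.
#' @return List with `params` (weights, means, sds sorted by mean),
#'   `loglik`, `converged`.
#' @export
fit_normal_mixture <- function(x, m, n_starts = 20, tol = 1e-8,
                               max_iter = 500) {
  n <- length(x)
  sd_floor <- 1e-4 * stats::sd(x)
  run_em <- function(mu, sigma, w) {
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      comp <- vapply(seq_len(m), function(j)
        log(w[j]) + stats::dnorm(x, mu[j], sigma[j], log = TRUE), numeric(n))
      mx <- apply(comp, 1, max)
      lse <- mx + log(rowSums(exp(comp - mx)))
      ll <- sum(lse)
      resp <- exp(comp - lse)
      nk <- colSums(resp)
      if (any(nk < 1e-8)) return(NULL)
      w <- nk / n
      mu <- colSums(resp * x) / nk
      sigma <- sqrt(colSums(resp * outer(x, mu, "-")^2) / nk)
      if (any(sigma < sd_floor)) return(NULL)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    list(w = w, mu = mu, sigma = sigma,
         loglik = mixture_loglik(x, w, mu, sigma))
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    if (s == 1L) {
      km <- tryCatch(stats::kmeans(x, centers = m, nstart = 3),
                     error = function(e) NULL)
      if (is.null(km)) next
      mu <- as.numeric(km$centers)
      sigma <- vapply(seq_len(m), function(j) {
        s0 <- stats::sd(x[km$cluster == j])
        if (!is.finite(s0) || s0 < sd_floor) stats::sd(x) / m else s0
      }, numeric(1))
      w <- pmax(km$size, 1) / n
      w <- w / sum(w)
    } else {
      mu <- sample(x, m)
      sigma <- rep(stats::sd(x) * stats::runif(1, 0.3, 1.2), m)
      w <- rep(1 / m, m)
    }
    fit <- run_em(mu, sigma, w)
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) {
    return(list(params = NULL, loglik = -Inf, converged = FALSE))
  }
  o <- order(best$mu)
  list(params = list(weights = best$w[o], means = best$mu[o],
                     sds = best$sigma[o]),
       loglik = best$loglik, converged = TRUE)
}

#' Maximum-likelihood fit of one catalog family
#'
#' Closed-form MLE for Normal, LogNormal and Exponential (variance uses the
#' 1/n ML convention); numerical optimization for Gamma and Weibull;
#' multi-start optimization for SHASH; EM for normal mixtures.
#'
#' @param x Data vector, length >= 8.
#' @param family One of [dist_catalog()].
#' @param mixture_starts Restarts for mixture EM (default 20).
#' @return An object of class `distribution_fit`: list with `family`,
#'   `params`, `loglik`, `n_params`, `n_obs`, `aicc`, `converged`,
#'   `skip_reason` (NA unless the family was skipped).
#' @export
fit_family <- function(x, family, mixture_starts = 20) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("need at least 8 finite observations")
  positive_only <- family %in% c("LogNormal", "Exponential", "Gamma", "Weibull")
  make <- function(params, loglik, converged = TRUE, skip = NA_character_) {
    k <- dist_n_params(family)
    structure(list(
      family = family, params = params, loglik = loglik, n_params = k,
      n_obs = n,
      aicc = if (is.finite(loglik) && n > k + 1) aicc(loglik, k, n) else Inf,
      converged = converged && is.finite(loglik),
      skip_reason = skip), class = "distribution_fit")
  }
  if (positive_only && any(x <= 0)) {
    return(make(NULL, -Inf, FALSE, "non-positive data for positive-support family"))
  }
  switch(family,
    Normal = {
      mu <- mean(x); s <- sqrt(mean((x - mu)^2))
      if (s == 0) return(make(NULL, -Inf, FALSE, "zero variance"))
      make(c(mean = mu, sd = s), sum(stats::dnorm(x, mu, s, log = TRUE)))
    },
    LogNormal = {
      lm_ <- mean(log(x)); ls <- sqrt(mean((log(x) - lm_)^2))
      if (ls == 0) return(make(NULL, -Inf, FALSE, "zero log-variance"))
      make(c(meanlog = lm_, sdlog = ls),
           sum(stats::dlnorm(x, lm_, ls, log = TRUE)))
    },
    Exponential = {
      rate <- 1 / mean(x)
      make(c(rate = rate), sum(stats::dexp(x, rate, log = TRUE)))
    },
    Gamma = {
      mu <- mean(x); v <- stats::var(x)
      st <- c(shape = max(mu^2 / v, 1e-2), rate = max(mu / v, 1e-6))
      f <- fit_positive_2par(x, function(x, a, b, log) stats::dgamma(x, a, rate = b, log = log), st)
      make(c(shape = f$par[1], rate = f$par[2]), f$loglik, f$converged)
    },
    Weibull = {
      st <- c(shape = 1.2, scale = mean(x))
      f <- fit_positive_2par(x, function(x, a, b, log) stats::dweibull(x, a, b, log = log), st)
      make(c(shape = f$par[1], scale = f$par[2]), f$loglik, f$converged)
    },
    SHASH = {
      f <- tryCatch(fit_shash(x), error = function(e) NULL)
      if (is.null(f)) return(make(NULL, -Inf, FALSE, "optimizer failure"))
      make(f$params, f$loglik, f$converged)
    },
    NormalMixture2 = {
      f <- fit_normal_mixture(x, 2, n_starts = mixture_starts)
      make(f$params, f$loglik, f$converged)
    },
    NormalMixture3 = {
      f <- fit_normal_mixture(x, 3, n_starts = mixture_starts)
      make(f$params, f$loglik, f$converged)
    },
    stop("unknown family: ", family)
  )
}

#' Fit a catalog of families and rank by AICc
#'
#' Fits each requested family by maximum likelihood and returns the fits
#' sorted by ascending AICc. Ties are broken by fewer parameters, then by
#' catalog order. Failed or skipped fits are excluded from the ranking but
#' reported in the `skipped` attribute.
#'
#' @param x Data vector.
#' @param families Subset of [dist_catalog()] (default: full catalog).
#' @param mixture_starts Restarts for mixture EM.
#' @return List with `best` (the winning `distribution_fit`) and `ranking`
#'   (list of successful fits, ascending AICc); attribute `skipped` names
#'   failures and reasons.
#' @export
select_best <- function(x, families = dist_catalog(), mixture_starts = 20) {
  stopifnot(all(families %in% dist_catalog()))
  fits <- lapply(families, function(f) fit_family(x, f, mixture_starts))
  ok <- vapply(fits, function(f) f$converged && is.finite(f$aicc), logical(1))
  skipped <- vapply(fits[!ok], function(f)
    paste0(f$family, ": ", ifelse(is.na(f$skip_reason), "non-convergence",
                                  f$skip_reason)), character(1))
  fits <- fits[ok]
  if (!length(fits)) {
    stop("all distribution fits failed: ", paste(skipped, collapse = "; "))
  }
  cat_order <- match(vapply(fits, `[[`, "", "family"), dist_catalog())
  o <- order(vapply(fits, `[[`, 0, "aicc"),
             vapply(fits, `[[`, 0L, "n_params"),
             cat_order)
  fits <- fits[o]
  structure(list(best = fits[[1]], ranking = fits), skipped = skipped)
}

#' @export
print.distribution_fit <- function(x, ...) {
  cat(sprintf("%s fit: loglik=%.4f, k=%d, n=%d, AICc=%.4f\n",
              x$family, x$loglik, x$n_params, x$n_obs, x$aicc))
  invisible(x)
}

#' Export a distribution ranking as a CSV table
#'
#' @param selection Result of [select_best()].
#' @param path Output CSV path.
#' @return The table, invisibly.
#' @export
write_ranking_csv <- function(selection, path) {
  rk <- selection$ranking
  tab <- data.frame(
    family = vapply(rk, `[[`, "", "family"),
    params = vapply(rk, function(f)
      paste(sprintf("%s=%.6g", names(unlist(f$params)), unlist(f$params)),
            collapse = ";"), character(1)),
    loglik = vapply(rk, `[[`, 0, "loglik"),
    aicc = vapply(rk, `[[`, 0, "aicc"),
    converged = vapply(rk, `[[`, TRUE, "converged")
  )
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
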