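# Shared fixtures: everything is generated in code at test time.

# small, fast default config for pipeline-level tests
fast_cohort <- function(seed = 11, n = 60, mode = "activities", ...) {
  generate_cohort(cohort_config(n_animals = n, seed = seed, mode = mode, ...))
}

# marker table straight from a generated cohort (activities mode), with
# age-normalized columns appended the same way the pipeline does
marker_table <- function(cohort, age_norm_mode = "ratio") {
  idx <- cohort_indices(cohort)
  markers <- idx[, c("cat_id", "sex", "age_years", "bcs",
                     "par", "latency", "far", "sar", "sad")]
  cols <- c(stkt = "stkt_u_mg", tkt_tdp = "tkt_tdp03_u_mg", gr = "gr_u_mg")
  for (nm in names(cols)) {
    lin <- fit_linear_vs_age(idx$age_years, idx[[cols[[nm]]]])
    pred <- lin$intercept + lin$slope * idx$age_years
    markers[[paste0("agenorm_", nm)]] <- age_normalize(
      idx[[cols[[nm]]]], idx$age_years, lin, mode = age_norm_mode,
      mean_predicted = mean(pred))
  }
  markers
}

# brute-force order-statistic index for an upper nonparametric limit:
# smallest m with sum_{i=0}^{m-1} C(n,i) P^i (1-P)^(n-i) >= gamma,
# accumulated term by term (independent of the package's pbinom route)
bruteforce_upper_index <- function(n, P, gamma) {
  acc <- 0
  for (m in 1:n) {
    acc <- acc + choose(n, m - 1) * P^(m - 1) * (1 - P)^(n - m + 1)
    if (acc >= gamma) return(m)
  }
  NA_integer_
}

# hand-constructed threshold_set from explicit per-marker limits, for
# classifier tests that must not depend on distribution fitting
manual_thresholds <- function(limits, sides = default_marker_sides()) {
  out <- lapply(marker_set(), function(mk) {
    list(limit = list(value = limits[[mk]],
                      spec = tolerance_spec(side = sides[[mk]])),
         family = "manual", method = "manual", side = sides[[mk]],
         n = NA_integer_)
  })
  names(out) <- marker_set()
  structure(out, class = "threshold_set")
}
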