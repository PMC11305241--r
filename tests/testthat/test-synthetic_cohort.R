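test_that("config validation lists every offending field", {
  expect_s3_class(cohort_config(), "cohort_config")
  err <- tryCatch(cohort_config(n_animals = 10,
                                half_lives = c(stkt = -1, tkt_tdp = 10.7,
                                               gr = 43.3)),
                  error = conditionMessage)
  expect_match(err, "half_lives")
  expect_match(err, "exceed n_animals")  # 16 planted > 10
  expect_error(cohort_config(age_mixture = list(weights = c(0.5, 0.4, 0.2),
                                                means = 1:3, sds = rep(1, 3))),
               "sum to 1")
})

test_that("same seed gives a byte-identical cohort; seeds differ", {
  a <- generate_cohort(cohort_config(seed = 42))
  b <- generate_cohort(cohort_config(seed = 42))
  expect_identical(a, b)
  c_ <- generate_cohort(cohort_config(seed = 43))
  expect_false(identical(a$age_years, c_$age_years))
  # schema matches the assay-core reader in both modes
  for (mode in c("raw", "activities")) {
    coh <- generate_cohort(cohort_config(seed = 1, mode = mode))
    path <- withr::local_tempfile(fileext = ".csv")
    write.csv(coh, path, row.names = FALSE)
    expect_equal(attr(read_cohort_csv(path), "assay_mode"), mode)
  }
})

test_that("covariate laws: ages in range, BCS discrete 1-9, sex ratio", {
  coh <- generate_cohort(cohort_config(n_animals = 2000, seed = 7,
                                       mode = "activities"))
  expect_true(all(coh$age_years >= 1 & coh$age_years <= 17))
  expect_true(all(coh$bcs %in% 1:9))
  expect_equal(median(coh$bcs), 5)
  expect_lt(abs(sd(coh$bcs) - 1), 0.5)
  # female fraction ~ 44/60 (binomial expectation, n = 2000)
  expect_lt(abs(mean(coh$sex == "F") - 44 / 60), 3 * sqrt(44 / 60 * 16 / 60 / 2000))
})

test_that("noiseless generator recovers the configured half-lives exactly", {
  cfg <- cohort_config(n_animals = 200, seed = 9, noise_sigma_log = 0,
                       assay_sigma_log = 0, far_sigma_log = 0,
                       deficiency_plan = c(b1_low_tdp = 0, b1_high_tdp = 0,
                                           b2 = 0),
                       mode = "activities")
  coh <- generate_cohort(cfg)
  for (pair in list(c("stkt_u_mg", "stkt"), c("tkt_tdp03_u_mg", "tkt_tdp"),
                    c("gr_u_mg", "gr"))) {
    fit <- fit_exponential_decay(coh$age_years, coh[[pair[1]]])
    expect_equal(fit$half_life, cohort_config()$half_lives[[pair[2]]],
                 tolerance = 1e-4)  # >= 4 significant digits
  }
})

test_that("default plan plants exactly 8 + 7 + 1 truth-labeled animals", {
  coh <- generate_cohort(cohort_config(seed = 13))
  expect_equal(sum(coh$truth_status != "not_deficient"), 16)
  expect_equal(sum(coh$truth_subtype == "low_TDP"), 8)
  expect_equal(sum(coh$truth_subtype == "high_TDP"), 7)
  expect_equal(sum(coh$truth_status == "B2_deficient"), 1)
})

test_that("planted effects shift the intended indices", {
  cfg <- cohort_config(seed = 17, mode = "activities")
  coh <- generate_cohort(cfg)
  idx <- cohort_indices(coh)
  low <- coh$truth_subtype == "low_TDP"
  high <- coh$truth_subtype == "high_TDP"
  healthy <- coh$truth_status == "not_deficient"
  expect_gt(min(idx$par[low]), max(idx$par[healthy]) * 0.8)
  expect_gt(mean(idx$par[low]), 2 * mean(idx$par[healthy]))
  expect_gt(mean(idx$far[high]), 1.5 * mean(idx$far[healthy]))
  expect_lt(coh$gr_u_mg[coh$truth_status == "B2_deficient"],
            min(coh$gr_u_mg[healthy]))
  # healthy index baselines sit in the configured physiological ranges
  expect_lt(abs(median(idx$par[healthy]) - 1.3), 0.25)
  expect_lt(abs(median(idx$far[healthy]) - 1.12), 0.1)
})

test_that("generated ages prefer the 3-component mixture over one normal", {
  wins <- 0
  for (s in 1:5) {
    coh <- generate_cohort(cohort_config(n_animals = 300, seed = 100 + s,
                                         mode = "activities"))
    fits <- list(fit_family(coh$age_years, "Normal"),
                 fit_family(coh$age_years, "NormalMixture3",
                            mixture_starts = 5))
    if (fits[[2]]$aicc <= fits[[1]]$aicc) wins <- wins + 1
  }
  expect_gt(wins / 5, 0.5)
})

test_that("truth_evaluation computes confusion summaries and checks ids", {
  coh <- generate_cohort(cohort_config(seed = 19, mode = "activities"))
  perfect <- data.frame(cat_id = coh$cat_id, status = coh$truth_status,
                        subtype = coh$truth_subtype)
  ev <- truth_evaluation(perfect, coh)
  expect_equal(ev$overall$sensitivity, 1)
  expect_equal(ev$overall$specificity, 1)
  expect_equal(ev$low_TDP$sensitivity, 1)
  none <- data.frame(cat_id = coh$cat_id, status = "not_deficient",
                     subtype = "none")
  ev0 <- truth_evaluation(none, coh)
  expect_equal(ev0$overall$sensitivity, 0)
  expect_equal(ev0$overall$specificity, 1)
  bad <- perfect; bad$cat_id[1] <- "nope"
  expect_error(truth_evaluation(bad, coh), "mismatch")
})

test_that("detection rate rises with planted effect size (sweep)", {
  rate_at <- function(a0_factor) {
    hits <- 0; total <- 0
    for (s in 1:6) {
      cfg <- cohort_config(seed = 300 + s, mode = "activities",
                           effects = c(a0_factor = a0_factor,
                                       a3_factor = 2, gr_factor = 0.4))
      coh <- generate_cohort(cfg)
      mk <- marker_table(coh)
      th <- derive_thresholds(mk, families = c("Normal", "Weibull"),
                              mixture_starts = 2)
      calls <- classify_cohort(mk, thresholds = th)
      hits <- hits + sum(calls$subtype == "low_TDP" &
                           coh$truth_subtype == "low_TDP")
      total <- total + sum(coh$truth_subtype == "low_TDP")
    }
    hits / total
  }
  weak <- rate_at(0.9)    # nearly no effect
  strong <- rate_at(0.3)  # strong PAR elevation
  expect_gte(strong, weak)
  expect_gt(strong, 0)
})
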