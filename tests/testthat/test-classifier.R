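test_that("derive_thresholds: parametric limit on normal marker, errors", {
  set.seed(71)
  mk <- as.data.frame(matrix(rlnorm(60 * 8, 0, 0.2), 60,
                             dimnames = list(NULL, marker_set())))
  mk$agenorm_stkt <- rnorm(60, 1, 0.1)
  th <- derive_thresholds(mk, families = c("Normal", "Weibull", "SHASH"),
                          mixture_starts = 3)
  expect_s3_class(th, "threshold_set")
  expect_setequal(names(th), marker_set())
  if (th$agenorm_stkt$method == "parametric_normal") {
    x <- mk$agenorm_stkt
    expect_equal(th$agenorm_stkt$limit$value,
                 mean(x) - normal_k_factor(60) * sd(x), tolerance = 1e-10)
  }
  # every threshold carries provenance
  for (mk_ in marker_set()) {
    expect_true(th[[mk_]]$family %in% dist_catalog())
    expect_true(th[[mk_]]$method %in% c("parametric_normal", "nonparametric"))
  }
  # constant marker -> error naming the marker
  mk$sad <- 1
  expect_error(derive_thresholds(mk, families = "Normal"), "sad")
  # insufficient n propagates with marker name
  expect_error(derive_thresholds(mk[1:20, ]), "agenorm_stkt")
})

test_that("classify applies the subtype rules deterministically", {
  lims <- as.list(c(agenorm_stkt = 0.5, agenorm_tkt_tdp = 2, agenorm_gr = 0.5,
                    par = 2, latency = 100, far = 2, sar = 2, sad = 1))
  th <- manual_thresholds(lims)
  base <- list(agenorm_stkt = 1, agenorm_tkt_tdp = 1, agenorm_gr = 1,
               par = 1.3, latency = 30, far = 1.1, sar = 0.9, sad = -0.2)
  expect_equal(classify(base, th)$status, "not_deficient")
  hi_par <- base; hi_par$par <- 3
  call <- classify(hi_par, th)
  expect_equal(call$status, "B1_deficient")
  expect_equal(call$subtype, "low_TDP")
  expect_equal(call$markers_triggered, "par")
  hi_far <- base; hi_far$far <- 2.5; hi_far$sad <- 1.4
  call <- classify(hi_far, th)
  expect_equal(call$subtype, "high_TDP")
  expect_setequal(call$markers_triggered, c("far", "sad"))
  lo_gr <- base; lo_gr$agenorm_gr <- 0.3
  expect_equal(classify(lo_gr, th)$status, "B2_deficient")
  # B1 takes precedence over a GR co-flag
  both <- lo_gr; both$par <- 3
  call <- classify(both, th)
  expect_equal(call$status, "B1_deficient")
  expect_true(call$gr_co_flag)
  # ties at the limit are NOT flagged (strict comparison)
  at_limit <- base; at_limit$par <- 2
  expect_equal(classify(at_limit, th)$status, "not_deficient")
  # missing markers degrade to fewer testable markers
  miss <- base; miss$far <- NA
  call <- classify(miss, th)
  expect_equal(call$n_missing, 1)
  expect_equal(call$status, "not_deficient")
})

test_that("classification is invariant under monotone marker re-scaling", {
  lims <- as.list(c(agenorm_stkt = 0.5, agenorm_tkt_tdp = 2, agenorm_gr = 0.5,
                    par = 2, latency = 100, far = 2, sar = 2, sad = 1))
  set.seed(72)
  for (i in 1:20) {
    vals <- lapply(lims, function(l) l * runif(1, 0.5, 2))
    call1 <- classify(vals, manual_thresholds(lims))
    # exp() both values and limits for the upper-side markers: order preserved
    lims2 <- lapply(lims, exp)
    vals2 <- lapply(vals, exp)
    call2 <- classify(vals2, manual_thresholds(lims2))
    expect_identical(call1$flags, call2$flags)
  }
})

test_that("summarize_calls counts statuses, subtypes and top markers", {
  calls <- data.frame(
    cat_id = sprintf("c%02d", 1:6),
    status = c("not_deficient", "B1_deficient", "B1_deficient",
               "B1_deficient", "B2_deficient", "not_deficient"),
    subtype = c("none", "low_TDP", "low_TDP", "high_TDP", "none", "none"),
    markers_triggered = c("", "par", "par;latency", "far", "agenorm_gr", ""),
    sex = c("F", "F", "M", "F", "F", "M"),
    age_years = c(2, 8, 9, 4, 6, 3), bcs = c(5, 5, 4, 6, 5, 5),
    stringsAsFactors = FALSE)
  s <- summarize_calls(calls)
  expect_equal(s$n_deficient, 4)
  expect_equal(s$status_counts$B1_deficient, 3)
  expect_equal(s$status_counts$B2_deficient, 1)
  expect_equal(s$subtype_counts$low_TDP, 2)
  expect_equal(s$top_marker$low_TDP$marker, "par")
  expect_equal(s$top_marker$low_TDP$count, 2)
  expect_equal(s$top_marker$high_TDP$marker, "far")
  expect_equal(s$flagged_demographics$n_female, 3)
  # zero flagged
  none <- calls[calls$status == "not_deficient", ]
  s0 <- summarize_calls(none)
  expect_equal(s0$n_deficient, 0)
  expect_null(s0$top_marker$low_TDP)
  # single B2 call
  one <- calls[5, ]
  expect_equal(summarize_calls(one)$status_counts$B2_deficient, 1)
})

test_that("sensitivity of low_TDP detection is monotone in effect size", {
  # planted-PAR-effect sweep on a common baseline cohort
  detect_rate <- sapply(c(1.5, 3, 6), function(effect) {
    hits <- 0
    for (s in 1:15) {
      set.seed(700 + s)
      mk <- as.data.frame(matrix(rlnorm(60 * 8, 0, 0.15), 60,
                                 dimnames = list(NULL, marker_set())))
      planted <- sample(60, 1)
      mk$par[planted] <- mk$par[planted] * effect
      th <- derive_thresholds(mk, families = c("Normal", "Weibull"),
                              mixture_starts = 2)
      call <- classify(mk[planted, ], th)
      if (call$subtype == "low_TDP") hits <- hits + 1
    }
    hits / 15
  })
  expect_true(all(diff(detect_rate) >= 0))
  expect_gt(detect_rate[3], detect_rate[1])
})

test_that("thresholds export to CSV with full provenance", {
  set.seed(73)
  mk <- as.data.frame(matrix(rlnorm(40 * 8, 0, 0.2), 40,
                             dimnames = list(NULL, marker_set())))
  th <- derive_thresholds(mk, families = c("Normal", "Weibull"),
                          mixture_starts = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- write_thresholds_csv(th, path)
  expect_equal(nrow(tab), 8)
  expect_setequal(tab$marker, marker_set())
  expect_true(all(c("method", "side", "limit", "achieved_confidence") %in%
                    names(tab)))
})
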