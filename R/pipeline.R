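#' Pipeline configuration
#'
#' Validated settings for the end-to-end analysis; every setting in effect
#' is serialized into the output directory for provenance.
#'
#' @param input Path to a cohort CSV, or NULL to generate a synthetic
#'   cohort.
#' @param synthetic A [cohort_config()] used when `input` is NULL.
#' @param content,confidence Tolerance content P and confidence gamma.
#' @param sides Named per-marker side map (see [default_marker_sides()]).
#' @param latency_formula `"par-based"` or `"stimulated-based"`.
#' @param age_norm_mode `"ratio"` or `"residual"`.
#' @param k_range Candidate cluster counts.
#' @param leave_one_out Classify each animal against thresholds derived
#'   without it (default FALSE).
#' @param mixture_starts EM restarts for mixture fits.
#' @param seed Seed used for any stochastic step (mixture/SHASH restarts).
#' @param out Output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, synthetic = cohort_config(),
                            content = 0.90, confidence = 0.95,
                            sides = default_marker_sides(),
                            latency_formula = "par-based",
                            age_norm_mode = "ratio",
                            k_range = 2:10, leave_one_out = FALSE,
                            mixture_starts = 20, seed = 1,
                            out = "thiastat_out") {
  stopifnot(content > 0, content < 1, confidence > 0, confidence < 1)
  stopifnot(latency_formula %in% c("par-based", "stimulated-based"))
  stopifnot(age_norm_mode %in% c("ratio", "residual"))
  stopifnot(all(marker_set() %in% names(sides)))
  if (!is.null(input) && !file.exists(input)) {
    stop("input file not found: ", input)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full thiamine-status pipeline
#'
#' Stage order: activation indices -> age-decay models -> age
#' normalization -> distribution fits -> tolerance cutoffs -> deficiency
#' classification -> endophenotype clustering. Writes `indices.csv`,
#' `fits.json`, `ranking_<marker>.csv`, `thresholds.csv`, `calls.csv`,
#' `clusters.csv`, `ccc_curve.csv`, `cluster_summary.csv`, `summary.md`
#' and `config.json` under `config$out`. Re-running with the same inputs
#' and config reproduces all outputs exactly.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all intermediate objects (`cohort`,
#'   `indices`, `age_fits`, `markers`, `thresholds`, `calls`, `summary`,
#'   `clusters`, `truth` when available).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)

  cohort <- if (is.null(config$input)) {
    generate_cohort(config$synthetic)
  } else {
    read_cohort_csv(config$input)
  }

  set.seed(config$seed)  # governs optimizer restarts downstream
  indices <- cohort_indices(cohort, latency_formula = config$latency_formula)
  write_table(indices, file.path(config$out, "indices.csv"))

  # age models for the three age-dependent activities
  activity_cols <- c(stkt = "stkt_u_mg", tkt_tdp = "tkt_tdp03_u_mg",
                     gr = "gr_u_mg")
  age_fits <- list()
  markers <- indices[, c("cat_id", "sex", "age_years", "bcs",
                         "par", "latency", "far", "sar", "sad")]
  for (nm in names(activity_cols)) {
    v <- indices[[activity_cols[[nm]]]]
    lin <- fit_linear_vs_age(indices$age_years, v)
    dec <- fit_exponential_decay(indices$age_years, v)
    age_fits[[paste0("linear_", nm)]] <- lin
    age_fits[[paste0("decay_", nm)]] <- dec
    pred <- lin$intercept + lin$slope * indices$age_years
    markers[[paste0("agenorm_", nm)]] <- age_normalize(
      v, indices$age_years, lin, mode = config$age_norm_mode,
      mean_predicted = mean(pred, na.rm = TRUE))
  }
  write_fits_json(age_fits, file.path(config$out, "fits.json"))

  thresholds <- derive_thresholds(
    markers, content = config$content, confidence = config$confidence,
    sides = config$sides, mixture_starts = config$mixture_starts)
  write_thresholds_csv(thresholds, file.path(config$out, "thresholds.csv"))
  for (mk in marker_set()) {
    write_ranking_csv(thresholds[[mk]]$selection,
                      file.path(config$out, paste0("ranking_", mk, ".csv")))
  }

  calls <- classify_cohort(markers, thresholds = thresholds,
                           leave_one_out = config$leave_one_out,
                           content = config$content,
                           confidence = config$confidence,
                           sides = config$sides,
                           mixture_starts = config$mixture_starts)
  write_table(calls, file.path(config$out, "calls.csv"))
  call_summary <- summarize_calls(calls)

  clusters <- cluster_endophenotypes(markers, calls,
                                     k_range = config$k_range)
  write_table(data.frame(cat_id = markers$cat_id[
                           stats::complete.cases(markers[, c("age_years",
                             "bcs", "par", "far", "sex")])],
                         cluster = clusters$assignments),
              file.path(config$out, "clusters.csv"))
  write_table(data.frame(k = as.integer(names(clusters$ccc_by_k)),
                         ccc = unname(clusters$ccc_by_k)),
              file.path(config$out, "ccc_curve.csv"))
  write_table(clusters$summary, file.path(config$out, "cluster_summary.csv"))

  truth <- NULL
  if ("truth_status" %in% names(cohort)) {
    truth <- truth_evaluation(calls, cohort)
  }
  write_summary_md(file.path(config$out, "summary.md"),
                   call_summary, thresholds, clusters, age_fits, truth)
  serializable <- config
  serializable$sides <- as.list(config$sides)
  serializable$synthetic <- lapply(unclass(config$synthetic), function(v)
    if (is.numeric(v) || is.list(v)) v else as.character(v))
  jsonlite::write_json(unclass(serializable),
                       file.path(config$out, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(cohort = cohort, indices = indices, age_fits = age_fits,
                 markers = markers, thresholds = thresholds, calls = calls,
                 summary = call_summary, clusters = clusters, truth = truth))
}

# deterministic CSV writer (fixed 15-significant-digit format so reruns
# are byte-identical across platforms)
write_table <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 15,
                                                 format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

write_summary_md <- function(path, call_summary, thresholds, clusters,
                             age_fits, truth) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# Thiamine status report")
  w("")
  w("## Age-decay models")
  for (nm in grep("^decay_", names(age_fits), value = TRUE)) {
    f <- age_fits[[nm]]
    w("- %s: k = %.4g /y, half-life = %.3g y (R2 = %.3f, P = %.3g)",
      sub("decay_", "", nm), f$k, f$half_life, f$r_squared, f$pearson_p)
  }
  w("")
  w("## Cutoffs (one-sided tolerance limits)")
  w("")
  w("| marker | family | method | side | limit |")
  w("|---|---|---|---|---|")
  for (mk in names(thresholds)) {
    th <- thresholds[[mk]]
    w("| %s | %s | %s | %s | %.4g |", mk, th$family, th$method, th$side,
      th$limit$value)
  }
  w("")
  w("## Deficiency calls")
  w("- animals: %d; flagged deficient: %d", call_summary$n,
    call_summary$n_deficient)
  w("- B1 deficient: %d (low-TDP %d, high-TDP %d); B2 deficient: %d",
    call_summary$status_counts$B1_deficient,
    call_summary$subtype_counts$low_TDP,
    call_summary$subtype_counts$high_TDP,
    call_summary$status_counts$B2_deficient)
  for (st in names(call_summary$top_marker)) {
    tm <- call_summary$top_marker[[st]]
    if (!is.null(tm)) {
      w("- most frequent %s trigger: %s (%d animals)", st, tm$marker,
        tm$count)
    }
  }
  if (!is.null(truth)) {
    w("")
    w("## Recovery of planted truth (synthetic cohort)")
    w("- overall sensitivity %.2f, specificity %.2f",
      truth$overall$sensitivity, truth$overall$specificity)
  }
  w("")
  w("## Endophenotype clustering")
  w("- chosen k = %d (CCC argmax over %s)", clusters$chosen_k,
    paste(range(as.integer(names(clusters$ccc_by_k))), collapse = "-"))
  invisible(path)
}
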