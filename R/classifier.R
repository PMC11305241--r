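#' Marker set used for deficiency classification
#'
#' Eight markers: three age-normalized activities and five activation
#' indices. `low_TDP` markers respond to the 0-0.3 mM TDP contrast
#' (marginal/acute B1 deficiency); `high_TDP` markers respond at 3 mM TDP
#' (low-TDP-affinity enzyme forms, chronic deficiency); `agenorm_gr` is the
#' riboflavin (B2) control.
#'
#' @return Character vector of the eight marker names.
#' @export
marker_set <- function() {
  c("agenorm_stkt", "agenorm_tkt_tdp", "agenorm_gr",
    "par", "latency", "far", "sar", "sad")
}

b1_low_tdp_markers <- function() c("agenorm_stkt", "agenorm_tkt_tdp", "par", "latency")
b1_high_tdp_markers <- function() c("far", "sar", "sad")

#' Default cutoff side per marker
#'
#' Deficiency lowers age-normalized STKT and GR (lower limits) and raises
#' the activation indices (upper limits). The age-normalized TKT+TDP cutoff
#' is an upper limit, following the published convention for that marker.
#'
#' @return Named character vector, `"lower"` or `"upper"` per marker.
#' @export
default_marker_sides <- function() {
  c(agenorm_stkt = "lower", agenorm_tkt_tdp = "upper", agenorm_gr = "lower",
    par = "upper", latency = "upper", far = "upper", sar = "upper",
    sad = "upper")
}

#' Derive tolerance cutoffs for all markers of a cohort
#'
#' For each marker: fit the distribution catalog, pick the AICc winner,
#' choose parametric-normal vs nonparametric accordingly, and compute the
#' one-sided limit on the configured side. Full provenance (winning family,
#' method, n) is retained per marker.
#'
#' @param cohort_markers Data.frame with (at least) the [marker_set()]
#'   columns, one row per animal.
#' @param content,confidence Tolerance content P and confidence gamma.
#' @param sides Named vector overriding [default_marker_sides()].
#' @param families Distribution catalog subset to consider.
#' @param mixture_starts EM restarts passed down to mixture fits.
#' @return An object of class `threshold_set`: named list per marker with
#'   `limit` (a `tolerance_limit`), `family`, `method`, `side`.
#' @export
derive_thresholds <- function(cohort_markers, content = 0.90,
                              confidence = 0.95,
                              sides = default_marker_sides(),
                              families = dist_catalog(),
                              mixture_starts = 20) {
  markers <- marker_set()
  missing_cols <- setdiff(markers, names(cohort_markers))
  if (length(missing_cols)) {
    stop("cohort_markers missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- lapply(markers, function(mk) {
    x <- cohort_markers[[mk]]
    x <- x[is.finite(x)]
    spec <- tolerance_spec(content, confidence, sides[[mk]])
    if (length(x) < nonparametric_min_n(spec)) {
      stop("marker '", mk, "': only ", length(x),
           " complete values; need >= ", nonparametric_min_n(spec))
    }
    sel <- tryCatch(select_best(x, families, mixture_starts),
                    error = function(e) stop("marker '", mk, "': ",
                                             conditionMessage(e)))
    method <- choose_method(sel$best$family)
    lim <- tryCatch(tolerance_limit(x, method, spec),
                    error = function(e) stop("marker '", mk, "': ",
                                             conditionMessage(e)))
    list(limit = lim, family = sel$best$family, method = method,
         side = sides[[mk]], n = length(x), selection = sel)
  })
  names(out) <- markers
  structure(out, class = "threshold_set",
            content = content, confidence = confidence)
}

# strict inequality: the cutoff point itself (an observed datum for
# nonparametric limits) is never self-flagged
marker_abnormal <- function(value, threshold) {
  if (!is.finite(value)) return(NA)
  if (threshold$side == "upper") value > threshold$limit$value
  else value < threshold$limit$value
}

#' Classify one animal against a threshold set
#'
#' Flags each marker beyond its one-sided limit (strict inequality).
#' Status logic: any abnormal B1 marker makes the animal `B1_deficient`
#' (subtype `low_TDP` if a 0-0.3 mM marker triggered, `high_TDP` if only
#' 3 mM markers did; a low-TDP trigger takes precedence if both families
#' trigger, with all triggering markers recorded). An animal abnormal only
#' in `agenorm_gr` is `B2_deficient`; a GR flag alongside B1 flags is kept
#' as a co-flag note. Missing markers are non-informative and recorded.
#'
#' @param animal_markers Named list / one-row data.frame with marker values.
#' @param thresholds A `threshold_set`.
#' @return List of class `deficiency_call` with `flags` (named logical,
#'   `NA` = untestable), `status`, `subtype`, `markers_triggered`,
#'   `gr_co_flag`, `n_missing`.
#' @export
classify <- function(animal_markers, thresholds) {
  markers <- marker_set()
  flags <- vapply(markers, function(mk)
    marker_abnormal(as.numeric(animal_markers[[mk]]), thresholds[[mk]]),
    logical(1))
  triggered <- markers[which(flags %in% TRUE)]
  b1_low <- any(flags[b1_low_tdp_markers()] %in% TRUE)
  b1_high <- any(flags[b1_high_tdp_markers()] %in% TRUE)
  gr_flag <- isTRUE(flags[["agenorm_gr"]])
  if (b1_low || b1_high) {
    status <- "B1_deficient"
    subtype <- if (b1_low) "low_TDP" else "high_TDP"
  } else if (gr_flag) {
    status <- "B2_deficient"
    subtype <- "none"
  } else {
    status <- "not_deficient"
    subtype <- "none"
  }
  structure(list(flags = flags, status = status, subtype = subtype,
                 markers_triggered = triggered,
                 gr_co_flag = gr_flag && (b1_low || b1_high),
                 n_missing = sum(is.na(flags))),
            class = "deficiency_call")
}

#' Classify a whole cohort
#'
#' @param cohort_markers Data.frame with [marker_set()] columns plus
#'   `cat_id` and optionally `sex`, `age_years`, `bcs`.
#' @param thresholds A `threshold_set`; derived from `cohort_markers` when
#'   NULL. With `leave_one_out = TRUE` each animal is classified against
#'   thresholds re-derived from the other animals (off by default: the
#'   standard reference-interval practice classifies contributors against
#'   the cohort cutoffs).
#' @param leave_one_out Logical, default FALSE.
#' @param ... Passed to [derive_thresholds()].
#' @return Data.frame, one row per animal: per-marker flags
#'   (`flag_<marker>`), `status`, `subtype`, `markers_triggered`
#'   (semicolon-joined), plus the covariate columns present.
#' @export
classify_cohort <- function(cohort_markers, thresholds = NULL,
                            leave_one_out = FALSE, ...) {
  if (is.null(thresholds) && !leave_one_out) {
    thresholds <- derive_thresholds(cohort_markers, ...)
  }
  rows <- lapply(seq_len(nrow(cohort_markers)), function(i) {
    th <- if (leave_one_out) {
      derive_thresholds(cohort_markers[-i, , drop = FALSE], ...)
    } else thresholds
    call <- classify(cohort_markers[i, ], th)
    fl <- as.list(call$flags)
    names(fl) <- paste0("flag_", names(call$flags))
    c(list(cat_id = cohort_markers$cat_id[i]), fl,
      list(status = call$status, subtype = call$subtype,
           markers_triggered = paste(call$markers_triggered, collapse = ";"),
           gr_co_flag = call$gr_co_flag))
  })
  calls <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  for (cov in c("sex", "age_years", "bcs")) {
    if (cov %in% names(cohort_markers)) calls[[cov]] <- cohort_markers[[cov]]
  }
  calls
}

#' Summarize deficiency calls over a cohort
#'
#' @param calls Data.frame from [classify_cohort()].
#' @return List with `n`, `n_deficient`, counts by `status` and `subtype`,
#'   `top_marker` (most frequent triggering marker per subtype with its
#'   count), and `flagged_demographics` (mean age, BCS, female count of the
#'   flagged group, when covariates are present).
#' @export
summarize_calls <- function(calls) {
  stopifnot(nrow(calls) >= 1)
  flagged <- calls$status != "not_deficient"
  status_counts <- table(factor(calls$status,
    levels = c("not_deficient", "B1_deficient", "B2_deficient")))
  subtype_counts <- table(factor(calls$subtype[calls$status == "B1_deficient"],
    levels = c("low_TDP", "high_TDP")))
  top_marker <- lapply(c(low_TDP = "low_TDP", high_TDP = "high_TDP"),
    function(st) {
      mks <- unlist(strsplit(
        calls$markers_triggered[calls$subtype == st & flagged], ";"))
      allowed <- if (st == "low_TDP") b1_low_tdp_markers() else b1_high_tdp_markers()
      mks <- mks[mks %in% allowed]
      if (!length(mks)) return(NULL)
      tb <- sort(table(mks), decreasing = TRUE)
      list(marker = names(tb)[1], count = as.integer(tb[1]))
    })
  demo <- NULL
  if (any(flagged) && all(c("age_years", "sex", "bcs") %in% names(calls))) {
    demo <- list(
      mean_age = mean(calls$age_years[flagged], na.rm = TRUE),
      sd_age = stats::sd(calls$age_years[flagged]),
      mean_bcs = mean(calls$bcs[flagged], na.rm = TRUE),
      n_female = sum(calls$sex[flagged] == "F", na.rm = TRUE),
      n_male = sum(calls$sex[flagged] == "M", na.rm = TRUE))
  }
  list(n = nrow(calls), n_deficient = sum(flagged),
       status_counts = as.list(status_counts),
       subtype_counts = as.list(subtype_counts),
       top_marker = top_marker,
       flagged_demographics = demo)
}

#' Export a threshold set as a CSV table
#'
#' @param thresholds A `threshold_set`.
#' @param path Output CSV path.
#' @return The table, invisibly.
#' @export
write_thresholds_csv <- function(thresholds, path) {
  tab <- do.call(rbind, lapply(names(thresholds), function(mk) {
    th <- thresholds[[mk]]
    data.frame(marker = mk, method = th$method, side = th$side,
               family = th$family,
               content = th$limit$spec$content,
               confidence = th$limit$spec$confidence,
               n = th$n, limit = th$limit$value,
               k_factor = th$limit$k_factor,
               order_index = th$limit$order_index,
               achieved_confidence = th$limit$achieved_confidence)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
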