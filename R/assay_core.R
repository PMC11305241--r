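#' Specific enzymatic activity from a kinetic rate
#'
#' Converts a spectrophotometric rate (change in absorbance at 340 nm per
#' minute) into a specific activity in U/mg protein, using the NADH/NADPH
#' extinction coefficient 6.22 mM^-1 cm^-1 and an assumed 1 cm path length.
#' 1 U = 1 umol substrate converted per minute.
#'
#' @param rate Kinetic rate, delta A340 per minute. May be negative (drifting
#'   baseline); negative rates are kept and flagged via a warning unless
#'   `clamp_negative = TRUE`.
#' @param protein_conc Protein concentration of the assayed hemolysate,
#'   mg/ml. Must be positive.
#' @param dilution_factor Dimensionless dilution factor (>= 1 nominally)
#'   applied to the hemolysate before assay.
#' @param extinction Molar extinction coefficient in mM^-1 cm^-1
#'   (default 6.22, NAD(P)H at 340 nm).
#' @param path_cm Cuvette path length in cm (default 1).
#' @param clamp_negative If TRUE, negative rates are clamped to 0; default
#'   FALSE keeps them so QC failures stay visible downstream.
#' @return Specific activity in U/mg.
#' @examples
#' specific_activity(0.0622, protein_conc = 1)   # 0.01 U/mg
#' specific_activity(0.311, protein_conc = 2.5)  # 0.02 U/mg
#' @export
specific_activity <- function(rate, protein_conc, dilution_factor = 1,
                              extinction = 6.22, path_cm = 1,
                              clamp_negative = FALSE) {
  if (any(!is.finite(rate))) stop("rate must be finite")
  if (any(!is.finite(protein_conc)) || any(protein_conc <= 0)) {
    stop("protein_conc must be positive and finite")
  }
  if (any(dilution_factor < 1)) stop("dilution_factor must be >= 1")
  if (any(rate < 0)) {
    if (clamp_negative) {
      rate <- pmax(rate, 0)
    } else {
      warning("negative kinetic rate retained; check baseline drift")
    }
  }
  (rate / (extinction * path_cm)) * dilution_factor / protein_conc
}

#' Aggregate technical replicates of a kinetic rate
#'
#' Returns the arithmetic mean and the coefficient of variation (CV, %) of
#' replicate kinetic readings, plus a QC flag when the CV exceeds a
#' threshold. The CV is reported as `NA` for a single replicate or a zero
#' mean (undefined).
#'
#' @param rates Numeric vector of replicate rates (nominally technical
#'   triplicates); at least one finite value required.
#' @param cv_threshold QC threshold on CV in percent (default 15).
#' @return A list with `mean`, `cv` (percent, `NA` if undefined), and
#'   `qc_pass` (logical; `NA` when CV undefined).
#' @export
aggregate_replicates <- function(rates, cv_threshold = 15) {
  rates <- rates[!is.na(rates)]
  if (length(rates) == 0L) stop("no replicate rates supplied")
  if (any(!is.finite(rates))) stop("replicate rates must be finite")
  m <- mean(rates)
  cv <- if (length(rates) < 2L || m == 0) NA_real_ else 100 * stats::sd(rates) / abs(m)
  list(mean = m, cv = cv, qc_pass = if (is.na(cv)) NA else cv <= cv_threshold)
}

#' Thiamine (B1) activation indices from a transketolase activity profile
#'
#' From specific transketolase activities measured without added thiamine
#' diphosphate (`a0`, STKT), with 0.3 mM TDP (`a03`) and with 3 mM TDP
#' (`a3`), computes:
#' \describe{
#'   \item{PAR}{primary activation ratio, a03/a0 — the classic "TDP effect"
#'     detecting marginal thiamine deficiency}
#'   \item{FAR}{further activation ratio, a3/a03 — sensitive to enzyme forms
#'     with low TDP affinity (chronic deficiency)}
#'   \item{SAR}{selective activation ratio, FAR/PAR}
#'   \item{SAD}{selective activation difference, FAR - PAR}
#'   \item{latency}{percent stimulation by 0.3 mM TDP (see Details)}
#' }
#'
#' @details The latency index is not given a formula in the clinical
#' literature this pipeline follows; two conventional forms are provided.
#' The default, `"par-based"`, is the classic TDP-effect percentage
#' `100 * (a03 - a0) / a0` (monotone in PAR); `"stimulated-based"` is
#' `100 * (a03 - a0) / a03`.
#'
#' @param a0,a03,a3 Specific TKT activities (U/mg) at 0, 0.3 and 3 mM TDP.
#' @param latency_formula `"par-based"` (default) or `"stimulated-based"`.
#' @return A list with `par`, `far`, `sar`, `sad`, `latency` (all `NA` with
#'   a `reason` attribute when `a0` or `a03` is non-positive).
#' @examples
#' compute_b1_indices(0.2, 0.26, 0.65)
#' @export
compute_b1_indices <- function(a0, a03, a3,
                               latency_formula = c("par-based", "stimulated-based")) {
  latency_formula <- match.arg(latency_formula)
  if (!is.finite(a0) || !is.finite(a03) || !is.finite(a3) ||
      a0 <= 0 || a03 <= 0) {
    out <- list(par = NA_real_, far = NA_real_, sar = NA_real_,
                sad = NA_real_, latency = NA_real_)
    attr(out, "reason") <- "non-positive or missing baseline activity"
    return(out)
  }
  par <- a03 / a0
  far <- a3 / a03
  latency <- switch(latency_formula,
    "par-based" = 100 * (a03 - a0) / a0,
    "stimulated-based" = 100 * (a03 - a0) / a03
  )
  list(par = par, far = far, sar = far / par, sad = far - par,
       latency = latency)
}

# Raw-kinetics column layout of the input CSV (versioned schema v1).
tkt_rate_cols <- function() {
  c(outer(c("tkt_rate_0_rep", "tkt_rate_03_rep", "tkt_rate_3_rep"),
          1:3, paste0))
}

#' Read a cohort CSV in the raw-kinetics or precomputed-activity schema
#'
#' Schema v1: columns `cat_id`, `sex` (F/M), `age_years`, `bcs` (1-9), then
#' either raw-mode columns `tkt_rate_{0|03|3}_rep{1..3}`, `gr_rate_rep{1..3}`,
#' `protein_mg_ml`, `dilution`, or activity-mode columns `stkt_u_mg`,
#' `tkt_tdp03_u_mg`, `tkt_tdp3_u_mg`, `gr_u_mg`. Empty cells are missing
#' values.
#'
#' @param path CSV path.
#' @return A data.frame with an attribute `assay_mode` of `"raw"` or
#'   `"activities"`.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  base_cols <- c("cat_id", "sex", "age_years", "bcs")
  missing_base <- setdiff(base_cols, names(df))
  if (length(missing_base)) {
    stop("cohort CSV missing required column(s): ",
         paste(missing_base, collapse = ", "))
  }
  raw_cols <- c(tkt_rate_cols(), paste0("gr_rate_rep", 1:3),
                "protein_mg_ml", "dilution")
  act_cols <- c("stkt_u_mg", "tkt_tdp03_u_mg", "tkt_tdp3_u_mg", "gr_u_mg")
  if (all(act_cols %in% names(df))) {
    attr(df, "assay_mode") <- "activities"
  } else if (all(raw_cols %in% names(df))) {
    attr(df, "assay_mode") <- "raw"
  } else {
    stop("cohort CSV matches neither schema; raw mode needs: ",
         paste(setdiff(raw_cols, names(df)), collapse = ", "),
         "; activity mode needs: ",
         paste(setdiff(act_cols, names(df)), collapse = ", "))
  }
  if (!all(df$sex %in% c("F", "M", NA))) stop("sex must be 'F' or 'M'")
  df
}

#' Compute per-animal activities and B1 indices for a cohort table
#'
#' Replicates are aggregated by mean first, then converted to specific
#' activities, then indices are computed — the order of operations is fixed
#' so that index computation on aggregated replicates equals index
#' computation on replicate means.
#'
#' @param cohort A data.frame from [read_cohort_csv()] or
#'   [generate_cohort()]; either schema accepted.
#' @param cv_threshold Replicate CV QC threshold, percent.
#' @param latency_formula Passed to [compute_b1_indices()].
#' @return A data.frame with one row per animal: covariates, specific
#'   activities (`stkt_u_mg`, `tkt_tdp03_u_mg`, `tkt_tdp3_u_mg`, `gr_u_mg`),
#'   the five indices, and a `qc_flag` column (TRUE when any replicate CV
#'   exceeded the threshold or a rate was negative).
#' @export
cohort_indices <- function(cohort, cv_threshold = 15,
                           latency_formula = "par-based") {
  mode <- attr(cohort, "assay_mode")
  if (is.null(mode)) {
    mode <- if (all(c("stkt_u_mg", "tkt_tdp03_u_mg") %in% names(cohort)))
      "activities" else "raw"
  }
  n <- nrow(cohort)
  out <- cohort[, c("cat_id", "sex", "age_years", "bcs")]
  acts <- matrix(NA_real_, n, 4,
                 dimnames = list(NULL, c("stkt_u_mg", "tkt_tdp03_u_mg",
                                         "tkt_tdp3_u_mg", "gr_u_mg")))
  qc <- logical(n)
  if (mode == "activities") {
    acts[, 1] <- cohort$stkt_u_mg
    acts[, 2] <- cohort$tkt_tdp03_u_mg
    acts[, 3] <- cohort$tkt_tdp3_u_mg
    acts[, 4] <- cohort$gr_u_mg
  } else {
    groups <- list(
      stkt_u_mg = paste0("tkt_rate_0_rep", 1:3),
      tkt_tdp03_u_mg = paste0("tkt_rate_03_rep", 1:3),
      tkt_tdp3_u_mg = paste0("tkt_rate_3_rep", 1:3),
      gr_u_mg = paste0("gr_rate_rep", 1:3)
    )
    for (i in seq_len(n)) {
      for (g in names(groups)) {
        rates <- as.numeric(cohort[i, groups[[g]]])
        rates <- rates[!is.na(rates)]
        if (!length(rates)) next
        agg <- aggregate_replicates(rates, cv_threshold)
        if (isFALSE(agg$qc_pass) || agg$mean < 0) qc[i] <- TRUE
        acts[i, g] <- suppressWarnings(specific_activity(
          agg$mean, cohort$protein_mg_ml[i], cohort$dilution[i]))
      }
    }
  }
  out <- cbind(out, as.data.frame(acts))
  idx <- t(vapply(seq_len(n), function(i) {
    v <- compute_b1_indices(acts[i, 1], acts[i, 2], acts[i, 3],
                            latency_formula = latency_formula)
    unlist(v)
  }, c(par = 0, far = 0, sar = 0, sad = 0, latency = 0)))
  out <- cbind(out, as.data.frame(idx))
  out$qc_flag <- qc
  out
}
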