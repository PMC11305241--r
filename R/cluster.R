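#' Robust column standardization (median / MAD)
#'
#' Each column is centered at its median and scaled by 1.4826 * MAD (the
#' normal-consistent MAD). Zero-MAD columns fall back to an IQR-based scale
#' (IQR / 1.349); columns with both zero are dropped with a warning. The
#' centers and scales are recorded for the inverse transform.
#'
#' @param m Numeric matrix (animals x features).
#' @return List of class `cluster_input`: `x` (standardized matrix),
#'   `center`, `scale`, `dropped` (names of dropped columns).
#' @export
robust_standardize <- function(m) {
  m <- as.matrix(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  center <- apply(m, 2, stats::median)
  scale_ <- apply(m, 2, stats::mad)  # 1.4826 * raw MAD
  iqr_scale <- apply(m, 2, stats::IQR) / (2 * stats::qnorm(0.75))
  fallback <- scale_ == 0 & iqr_scale > 0
  scale_[fallback] <- iqr_scale[fallback]
  dropped <- colnames(m)[scale_ == 0]
  if (length(dropped)) {
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
  }
  keep <- scale_ > 0
  if (!any(keep)) stop("no usable columns after standardization")
  x <- sweep(sweep(m[, keep, drop = FALSE], 2, center[keep]), 2,
             scale_[keep], "/")
  structure(list(x = x, center = center[keep], scale = scale_[keep],
                 dropped = dropped),
            class = "cluster_input")
}

#' Ward minimum-variance agglomeration
#'
#' Lance-Williams recurrence on the merge cost `d^2/2` between singletons
#' (the increase in within-cluster error sum of squares), so two points at
#' Euclidean distance d merge at height d^2/2. Ties are broken by the
#' lowest pair index, making the tree deterministic given input order.
#' Returns a standard `hclust` object (usable with [stats::cutree()] and
#' `plot()`).
#'
#' @param x Numeric matrix or a `cluster_input`.
#' @return An `hclust` object; heights are cumulative-ESS increments and
#'   are monotone non-decreasing.
#' @export
ward_linkage <- function(x) {
  if (inherits(x, "cluster_input")) x <- x$x
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 observations")
  D <- as.matrix(stats::dist(x))^2 / 2  # delta-ESS between singletons
  diag(D) <- Inf
  size <- rep(1L, n)
  id <- -(1:n)           # hclust convention: negative = singleton
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    # first index pair (column-major over i<j) attaining the minimum
    best <- which(sub == min(sub), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- idx[best[1]]; j <- idx[best[2]]
    height[step] <- D[i, j]
    pair <- sort(c(id[i], id[j]))
    # hclust orders: singletons (negative) before clusters (positive)
    merge[step, ] <- if (pair[1] < 0 && pair[2] < 0) c(pair[1], pair[2])
      else if (pair[1] < 0) c(pair[1], pair[2])
      else c(pair[1], pair[2])
    ni <- size[i]; nj <- size[j]
    others <- setdiff(idx, c(i, j))
    for (k in others) {
      nk <- size[k]
      D[i, k] <- D[k, i] <-
        ((ni + nk) * D[i, k] + (nj + nk) * D[j, k] - nk * D[i, j]) /
        (ni + nj + nk)
    }
    size[i] <- ni + nj
    active[j] <- FALSE
    id[i] <- step
    D[j, ] <- D[, j] <- Inf
  }
  order_ <- tree_order(merge, n)
  structure(list(merge = merge, height = height, order = order_,
                 labels = rownames(x), method = "ward",
                 call = match.call(), dist.method = "squared euclidean / 2"),
            class = "hclust")
}

# leaf order by recursive traversal of the merge matrix
tree_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(n - 1)
}

#' Cubic clustering criterion (Sarle's approximation)
#'
#' Compares the observed proportion of variance explained by a partition
#' (R^2) against its expectation under a uniform-hypercube null, with the
#' hypercube aligned to the data's principal axes (Sarle's SAS technical
#' report A-108 approximation). Positive values indicate clustering
#' stronger than the null; values near 0 are null-like.
#'
#' @param x Numeric matrix or `cluster_input` (animals x features).
#' @param assignments Integer cluster assignments of length `nrow(x)`.
#' @return The CCC value.
#' @export
cubic_clustering_criterion <- function(x, assignments) {
  if (inherits(x, "cluster_input")) x <- x$x
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  q <- length(unique(assignments))
  if (q < 2 || q > n / 2) stop("number of clusters must be in [2, n/2]")
  xc <- scale(x, center = TRUE, scale = FALSE)
  tss <- sum(xc^2)
  wss <- 0
  for (g in unique(assignments)) {
    xg <- x[assignments == g, , drop = FALSE]
    wss <- wss + sum(scale(xg, center = TRUE, scale = FALSE)^2)
  }
  r2 <- 1 - wss / tss
  ev <- eigen(crossprod(xc) / (n - 1), symmetric = TRUE,
              only.values = TRUE)$values
  s <- sqrt(pmax(ev, 0))
  s[s == 0] <- 1          # null directions contribute unit edge lengths
  # hypercube edges proportional to s; sub-boxes cut along at most q-1
  # dimensions whose scaled edge u_j exceeds 1 (Sarle's rule)
  c0 <- (prod(s) / q)^(1 / p)
  u0 <- s / c0
  pstar <- min(sum(u0 >= 1), q - 1)
  if (pstar > 0 && pstar < p) {
    cstar <- (prod(s[1:pstar]) / q)^(1 / pstar)
    u <- s / cstar
    jj <- (pstar + 1):p
    num <- sum(1 / (n + u[1:pstar])) + sum(u[jj]^2 / (n + u[jj]))
    dims <- pstar
  } else {
    u <- u0
    num <- sum(1 / (n + u))
    dims <- p
  }
  e_r2 <- 1 - (num / sum(u^2)) * ((n - q)^2 / n) * (1 + 4 / n)
  e_r2 <- min(max(e_r2, 1e-12), 1 - 1e-12)
  if (r2 >= 1) return(Inf)
  log((1 - e_r2) / (1 - r2)) * sqrt(n * dims / 2) / (0.001 + e_r2)^1.2
}

# canonical labels: clusters numbered by their smallest member index
canonical_labels <- function(assignments) {
  firsts <- vapply(split(seq_along(assignments), assignments),
                   min, integer(1))
  ranks <- rank(firsts)
  out <- ranks[as.character(assignments)]
  as.integer(unname(out))
}

#' Endophenotype clustering of a cohort
#'
#' Builds the feature matrix {age, BCS, PAR, FAR, sex(0/1)}, robustly
#' standardizes it, runs Ward agglomeration, scores each candidate k with
#' the cubic clustering criterion, and summarizes the chosen partition per
#' cluster: mean (SD) of age/BCS/PAR/FAR, % female, and — when deficiency
#' calls are supplied — % deficient and % triggering low-TDP / high-TDP
#' markers.
#'
#' @param cohort Data.frame with `age_years`, `bcs`, `par`, `far`, `sex`.
#' @param calls Optional data.frame from [classify_cohort()] (matched by
#'   `cat_id` when present, else by row order).
#' @param k_range Candidate cluster counts (default 2:10, capped at n/2).
#' @return List of class `cluster_result`: `tree` (hclust), `chosen_k`,
#'   `ccc_by_k` (named numeric), `assignments` (canonical labels),
#'   `summary` (data.frame, one row per cluster), `input`.
#' @export
cluster_endophenotypes <- function(cohort, calls = NULL, k_range = 2:10) {
  feat <- data.frame(
    age = cohort$age_years,
    bcs = cohort$bcs,
    par = cohort$par,
    far = cohort$far,
    sex = as.numeric(cohort$sex == "F")
  )
  complete <- stats::complete.cases(feat)
  if (!all(complete)) {
    warning(sum(!complete), " animal(s) with missing features excluded ",
            "from clustering")
  }
  feat <- feat[complete, , drop = FALSE]
  n <- nrow(feat)
  k_range <- k_range[k_range >= 2 & k_range <= n / 2]
  if (!length(k_range)) stop("no valid k in range for n = ", n)
  input <- robust_standardize(as.matrix(feat))
  tree <- ward_linkage(input)
  ccc_by_k <- vapply(k_range, function(k)
    cubic_clustering_criterion(input, stats::cutree(tree, k)), numeric(1))
  names(ccc_by_k) <- k_range
  chosen_k <- k_range[which.max(ccc_by_k)]
  assignments <- canonical_labels(stats::cutree(tree, chosen_k))
  cohort_cc <- cohort[complete, , drop = FALSE]
  calls_cc <- NULL
  if (!is.null(calls)) {
    calls_cc <- if ("cat_id" %in% names(calls) && "cat_id" %in% names(cohort)) {
      calls[match(cohort_cc$cat_id, calls$cat_id), , drop = FALSE]
    } else calls[complete, , drop = FALSE]
  }
  msd <- function(v) sprintf("%.2f (%.2f)", mean(v), stats::sd(v))
  summary_ <- do.call(rbind, lapply(sort(unique(assignments)), function(g) {
    in_g <- assignments == g
    row <- data.frame(
      cluster = g, n = sum(in_g),
      age = msd(cohort_cc$age_years[in_g]),
      bcs = msd(cohort_cc$bcs[in_g]),
      par = msd(cohort_cc$par[in_g]),
      far = msd(cohort_cc$far[in_g]),
      pct_female = 100 * mean(cohort_cc$sex[in_g] == "F"))
    if (!is.null(calls_cc)) {
      row$pct_deficient <- 100 * mean(calls_cc$status[in_g] != "not_deficient")
      row$pct_low_tdp <- 100 * mean(calls_cc$subtype[in_g] == "low_TDP")
      row$pct_high_tdp <- 100 * mean(calls_cc$subtype[in_g] == "high_TDP")
    }
    row
  }))
  structure(list(tree = tree, chosen_k = chosen_k, ccc_by_k = ccc_by_k,
                 assignments = assignments, summary = summary_,
                 input = input),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Ward clustering: chosen k = %d (CCC = %.3f)\n",
              x$chosen_k, max(x$ccc_by_k)))
  print(x$summary)
  invisible(x)
}
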