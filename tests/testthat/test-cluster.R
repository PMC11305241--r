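test_that("robust standardization matches hand arithmetic", {
  ci <- robust_standardize(cbind(a = c(1, 2, 3), b = c(10, 20, 40)))
  # column a: median 2, MAD (x1.4826) = 1.4826 -> 1/1.4826 = 0.67449
  expect_equal(ci$x[, "a"], c(-1, 0, 1) / 1.4826, tolerance = 1e-6)
  expect_equal(median(ci$x[, "a"]), 0)
  expect_equal(median(ci$x[, "b"]), 0)
  # constant column dropped with warning
  expect_warning(ci2 <- robust_standardize(cbind(a = 1:5, c = rep(2, 5))),
                 "constant")
  expect_equal(ci2$dropped, "c")
  expect_error(suppressWarnings(robust_standardize(matrix(1, 4, 2))),
               "no usable columns")
  # zero MAD but positive IQR falls back to the IQR scale
  v <- c(0, 0, 0, 0, 0, 0, 1, 2, 3, 4)  # > half identical: MAD = 0
  ci3 <- robust_standardize(cbind(v = v))
  expect_true(all(is.finite(ci3$x)))
})

test_that("ward linkage: two-point height, duplicates, tie-breaking", {
  # two points at distance d merge at ESS increment d^2/2
  tr <- ward_linkage(rbind(c(0, 0), c(3, 4)))  # d = 5
  expect_equal(tr$height, 12.5)
  # duplicated points merge first at height 0
  tr2 <- ward_linkage(rbind(c(0, 0), c(1, 0), c(0, 0)))
  expect_equal(tr2$height[1], 0)
  expect_equal(sort(tr2$merge[1, ]), c(-3, -1))
  # three collinear equidistant points: closest pair merges first,
  # lowest-pair-index tie break
  tr3 <- ward_linkage(cbind(c(0, 1, 2), 0))
  expect_equal(sort(tr3$merge[1, ]), c(-2, -1))
})

test_that("ward heights are monotone and agree with hclust on ward costs", {
  set.seed(81)
  for (i in 1:5) {
    x <- matrix(rnorm(40 * 3), 40)
    tr <- ward_linkage(x)
    expect_false(is.unsorted(tr$height))
    hc <- hclust(dist(x)^2 / 2, method = "ward.D")
    expect_equal(tr$height, hc$height, tolerance = 1e-10)
    expect_equal(cutree(tr, 4), cutree(hc, 4))
  }
})

test_that("assignments are permutation-invariant up to canonical labels", {
  set.seed(82)
  x <- matrix(rnorm(30 * 3), 30)
  rownames(x) <- NULL
  perm <- sample(30)
  a1 <- cutree(ward_linkage(x), 4)
  a2 <- cutree(ward_linkage(x[perm, ]), 4)
  # same partition after inverting the permutation
  part1 <- unname(lapply(split(seq_len(30), a1), sort))
  part2 <- unname(lapply(split(perm, a2), sort))
  expect_setequal(part1, part2)
})

test_that("CCC recovers planted k and stays sub-critical on uniform null", {
  gen3 <- function(seed) {
    set.seed(seed)
    rbind(cbind(rnorm(50), rnorm(50)),
          cbind(rnorm(50, 10), rnorm(50, 10)),
          cbind(rnorm(50, 0), rnorm(50, 10)))
  }
  hits <- 0
  for (s in 1:25) {
    x <- gen3(s)
    tr <- ward_linkage(x)
    ccc <- sapply(2:6, function(k)
      cubic_clustering_criterion(x, cutree(tr, k)))
    if ((2:6)[which.max(ccc)] == 3) hits <- hits + 1
  }
  expect_gte(hits / 25, 0.8)
  # uniform hypercube: no spurious strong clustering signal (CCC < 2)
  for (s in 1:5) {
    set.seed(100 + s)
    x <- matrix(runif(150 * 4), ncol = 4)
    tr <- ward_linkage(x)
    ccc <- sapply(2:8, function(k)
      cubic_clustering_criterion(x, cutree(tr, k)))
    expect_true(all(ccc < 2))
  }
  expect_error(cubic_clustering_criterion(matrix(rnorm(16), 8),
                                          c(1, 1, 2, 2, 3, 3, 4, 5)),
               "clusters")
})

test_that("cluster_endophenotypes recovers planted endophenotype groups", {
  make_cohort <- function(seed) {
    set.seed(seed)
    n_per <- 20
    data.frame(
      cat_id = sprintf("c%03d", 1:(3 * n_per)),
      sex = sample(c("F", "M"), 3 * n_per, replace = TRUE),
      age_years = c(rnorm(n_per, 2, 0.3), rnorm(n_per, 8, 0.3),
                    rnorm(n_per, 14, 0.3)),
      bcs = rep(5, 3 * n_per),
      par = c(rnorm(n_per, 1.2, 0.05), rnorm(n_per, 3.5, 0.05),
              rnorm(n_per, 1.2, 0.05)),
      far = c(rnorm(n_per, 1.1, 0.05), rnorm(n_per, 1.1, 0.05),
              rnorm(n_per, 2.8, 0.05)))
  }
  hits <- 0
  for (s in 1:10) {
    res <- suppressWarnings(
      cluster_endophenotypes(make_cohort(s), k_range = 2:8))
    if (res$chosen_k == 3) hits <- hits + 1
  }
  expect_gt(hits / 10, 0.5)
  res <- suppressWarnings(cluster_endophenotypes(make_cohort(1)))
  expect_equal(length(res$assignments), 60)
  expect_equal(sort(unique(res$assignments)), seq_len(res$chosen_k))
  # canonical labeling: cluster 1 contains animal 1
  expect_equal(res$assignments[1], 1L)
  expect_true(all(res$summary$pct_female >= 0 & res$summary$pct_female <= 100))
})

test_that("cluster summaries incorporate deficiency calls", {
  set.seed(83)
  cohort <- data.frame(
    cat_id = sprintf("c%02d", 1:40), sex = rep(c("F", "M"), 20),
    age_years = runif(40, 1, 17), bcs = sample(3:7, 40, TRUE),
    par = c(rnorm(36, 1.3, 0.1), rnorm(4, 4, 0.1)),
    far = rnorm(40, 1.1, 0.1))
  calls <- data.frame(
    cat_id = cohort$cat_id,
    status = c(rep("not_deficient", 36), rep("B1_deficient", 4)),
    subtype = c(rep("none", 36), rep("low_TDP", 4)))
  res <- suppressWarnings(cluster_endophenotypes(cohort, calls))
  expect_true(all(c("pct_deficient", "pct_low_tdp") %in% names(res$summary)))
  expect_true(all(res$summary$pct_deficient >= 0 &
                    res$summary$pct_deficient <= 100))
  # the planted high-PAR animals concentrate their cluster's deficiency
  expect_gte(max(res$summary$pct_deficient), 50)
})
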