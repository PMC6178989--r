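# brute-force joint histogram oracle: per-voxel tally with explicit loops
brute_histogram <- function(a, b, bins) {
  rng <- function(x) stats::quantile(x, c(0.01, 0.99), names = FALSE)
  ra <- rng(a); rb <- rng(b)
  cls <- function(x, r) min(max(floor((x - r[1]) / (r[2] - r[1]) * bins) + 1,
                                1), bins)
  counts <- matrix(0, bins, bins)
  for (i in seq_along(a)) {
    ia <- cls(a[i], ra); ib <- cls(b[i], rb)
    counts[ia, ib] <- counts[ia, ib] + 1
  }
  counts
}

# entropy/MI by direct formula evaluation on counts
brute_mi <- function(counts) {
  p <- counts / sum(counts)
  pa <- rowSums(p); pb <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (pa[i] * pb[j]))
  s
}

brute_entropy <- function(counts) {
  p <- counts / sum(counts)
  -sum(ifelse(p > 0, p * log(p), 0))
}

test_that("joint histogram matches an exhaustive per-voxel tally", {
  set.seed(11)
  a <- array(rnorm(64), c(4, 4, 4))
  b <- array(rnorm(64), c(4, 4, 4))
  h <- joint_histogram(a, b, bins = 8)
  expect_equal(h$n, 64)
  expect_equal(sum(h$counts), 64)
  expect_equal(h$counts, brute_histogram(as.numeric(a), as.numeric(b), 8))
})

test_that("identical two-valued images fill only the histogram diagonal", {
  a <- array(rep(c(0, 1), 32), c(4, 4, 4))
  h <- joint_histogram(a, a, bins = 2)
  expect_equal(sum(h$counts) , 64)
  expect_equal(h$counts[1, 2] + h$counts[2, 1], 0)
})

test_that("histogram respects the mask and rejects empty masks", {
  set.seed(2)
  a <- array(rnorm(216), c(6, 6, 6))
  b <- array(rnorm(216), c(6, 6, 6))
  m <- array(runif(216) > 0.4, c(6, 6, 6))
  h <- joint_histogram(a, b, mask = m, bins = 16)
  expect_equal(sum(h$counts), sum(m))
  expect_error(joint_histogram(a, b, mask = array(FALSE, c(6, 6, 6))),
               "empty mask")
})

test_that("MI, NMI and FSE agree with brute-force evaluation to 1e-10", {
  set.seed(12)
  a <- array(rnorm(64), c(4, 4, 4))
  b <- array(0.5 * as.numeric(a) + rnorm(64), c(4, 4, 4))
  h <- joint_histogram(a, b, bins = 6)
  bc <- brute_histogram(as.numeric(a), as.numeric(b), 6)
  expect_lt(abs(mutual_information(h) - brute_mi(bc)), 1e-10)
  expect_lt(abs(feature_space_entropy(h) - brute_entropy(bc)), 1e-10)
  marg_h <- brute_entropy(matrix(rowSums(bc))) +
    brute_entropy(matrix(colSums(bc)))
  expect_lt(abs(normalized_mutual_information(h) -
                  marg_h / brute_entropy(bc)), 1e-10)
})

test_that("MI of an image with itself is its marginal entropy; constants give 0", {
  set.seed(13)
  a <- array(sample(1:5, 64, TRUE) + 0, c(4, 4, 4))
  h <- joint_histogram(a, a, bins = 8)
  expect_equal(mutual_information(h),
               brute_entropy(matrix(rowSums(h$counts))), tolerance = 1e-12)
  hc <- joint_histogram(a, array(1, c(4, 4, 4)), bins = 8)
  expect_equal(mutual_information(hc), 0)
})

test_that("hand-evaluated 2x2 joint counts give the expected MI", {
  h <- structure(list(counts = rbind(c(2, 1), c(1, 2)),
                      edges_a = 0:2, edges_b = 0:2, n = 6),
                 class = "histogram2d")
  # direct evaluation of sum p log(p / (pa pb)) for counts [[2,1],[1,2]]
  p <- rbind(c(2, 1), c(1, 2)) / 6
  expected <- sum(p * log(p / (rowSums(p) %o% colSums(p))))
  expect_equal(mutual_information(h), expected, tolerance = 1e-12)
})

test_that("NMI spans [1, 2] between independence and identity", {
  set.seed(14)
  a <- array(rnorm(512), c(8, 8, 8))
  expect_equal(normalized_mutual_information(joint_histogram(a, a, bins = 16)),
               2, tolerance = 1e-12)
  # exactly independent marginals: a varies along x only, b along y only
  g <- expand.grid(i = 1:8, j = 1:8, k = 1:8)
  ai <- array(g$i %% 2, c(8, 8, 8))
  bj <- array(g$j %% 2, c(8, 8, 8))
  expect_equal(normalized_mutual_information(
    joint_histogram(ai, bj, bins = 4)), 1, tolerance = 1e-12)
  expect_error(normalized_mutual_information(
    joint_histogram(array(1, c(4, 4, 4)), array(2, c(4, 4, 4)), bins = 4)),
    "constant")
})

test_that("MI is non-negative and FSE bounded by the marginal entropies", {
  set.seed(15)
  for (i in 1:10) {
    a <- array(rnorm(216), c(6, 6, 6))
    b <- array(rnorm(216) + 0.3 * as.numeric(a), c(6, 6, 6))
    h <- joint_histogram(a, b, bins = 12)
    ha <- brute_entropy(matrix(rowSums(h$counts)))
    hb <- brute_entropy(matrix(colSums(h$counts)))
    expect_gte(mutual_information(h), -1e-12)
    expect_lte(feature_space_entropy(h), ha + hb + 1e-12)
  }
})

test_that("metrics are invariant to bin-preserving linear intensity rescaling", {
  set.seed(16)
  a <- array(rnorm(216), c(6, 6, 6))
  b <- array(rnorm(216), c(6, 6, 6))
  h1 <- joint_histogram(a, b, bins = 16)
  h2 <- joint_histogram(a * 3 + 7, b, bins = 16)
  expect_equal(mutual_information(h1), mutual_information(h2),
               tolerance = 1e-12)
  expect_equal(feature_space_entropy(h1), feature_space_entropy(h2),
               tolerance = 1e-12)
  expect_equal(normalized_mutual_information(h1),
               normalized_mutual_information(h2), tolerance = 1e-12)
})

test_that("cross-correlation matches the textbook Pearson formula", {
  a <- array(rnorm(216, 10, 2), c(6, 6, 6))
  expect_equal(cross_correlation(a, 2 * a + 3), 1, tolerance = 1e-12)
  expect_equal(cross_correlation(a, -a), -1, tolerance = 1e-12)
  x <- c(1, 2, 4, 5, 9); y <- c(2, 1, 5, 4, 8)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  av <- array(0, c(5, 1, 1)); bv <- array(0, c(5, 1, 1))
  av[] <- x; bv[] <- y
  expect_error(cross_correlation(av, bv), NA)
  # dims >= 2 per axis not required for bare arrays passed directly
  expect_equal(cross_correlation(av, bv), num / den, tolerance = 1e-12)
  expect_error(cross_correlation(a, array(5, c(6, 6, 6))), "constant")
})

test_that("fse of degenerate histograms behaves as declared", {
  one <- structure(list(counts = matrix(c(9, 0, 0, 0), 2), n = 9),
                   class = "histogram2d")
  expect_equal(feature_space_entropy(one), 0)
  four <- structure(list(counts = matrix(c(3, 3, 3, 3), 2), n = 12),
                    class = "histogram2d")
  expect_equal(feature_space_entropy(four), log(4), tolerance = 1e-12)
})
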