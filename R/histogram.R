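#' Joint intensity histogram of two volumes
#'
#' Bins the in-mask intensities of two volumes on the same grid into a B x B
#' joint histogram. Bin edges are linear between each volume's robust
#' intensity range (1st-99th percentile within the mask, guarding against hot
#' voxels); values outside the range are clipped into the end bins so counts
#' always sum to the mask size. A constant image occupies a single bin.
#'
#' @param a,b [volume3d] objects on the same grid, or bare arrays.
#' @param mask logical/0-1 array; `NULL` uses all voxels.
#' @param bins number of bins per axis (>= 2).
#' @param probs robust range percentiles.
#' @return An object of class `histogram2d` with fields `counts`, `edges_a`,
#'   `edges_b`, `n`.
#' @export
joint_histogram <- function(a, b, mask = NULL, bins = 64,
                            probs = c(0.01, 0.99)) {
  av <- if (inherits(a, "volume3d")) a$data else a
  bv <- if (inherits(b, "volume3d")) b$data else b
  assert_that(all(dim(av) == dim(bv)), "volumes must share a grid")
  assert_that(bins >= 2, "bins must be >= 2")
  if (is.null(mask)) mask <- rep(TRUE, length(av))
  m <- as.logical(mask)
  assert_that(any(m), "empty mask")
  x <- as.numeric(av)[m]
  y <- as.numeric(bv)[m]
  bx <- bin_index(x, bins, probs)
  by <- bin_index(y, bins, probs)
  counts <- matrix(tabulate(bx$idx + bins * (by$idx - 1), nbins = bins * bins),
                   nrow = bins)
  structure(list(counts = counts, edges_a = bx$edges, edges_b = by$edges,
                 n = length(x)),
            class = "histogram2d")
}

bin_index <- function(x, bins, probs) {
  rng <- stats::quantile(x, probs, names = FALSE, type = 7)
  if (diff(rng) <= 0) {
    # constant (or near-constant) image: everything in one bin
    return(list(idx = rep(1L, length(x)),
                edges = seq(rng[1], rng[1] + 1, length.out = bins + 1)))
  }
  idx <- floor((x - rng[1]) / diff(rng) * bins) + 1
  idx <- pmin(pmax(idx, 1L), bins)
  list(idx = as.integer(idx), edges = seq(rng[1], rng[2], length.out = bins + 1))
}

hist_probs <- function(h) {
  assert_that(h$n > 0, "empty histogram")
  h$counts / h$n
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Similarity measures on a joint intensity histogram
#'
#' `mutual_information()` returns MI = sum p(a,b) ln(p(a,b) / (p(a) p(b))) in
#' nats (zero-count cells skipped; MI >= 0 up to floating point).
#' `normalized_mutual_information()` returns NMI = (H(A) + H(B)) / H(A, B),
#' in `[1, 2]`, the similarity maximized by the coregistration stage.
#' `feature_space_entropy()` returns the joint entropy H(A, B) in nats.
#'
#' @param h a `histogram2d` from [joint_histogram()].
#' @return A scalar.
#' @export
mutual_information <- function(h) {
  p <- hist_probs(h)
  pa <- rowSums(p)
  pb <- colSums(p)
  idx <- which(p > 0, arr.ind = TRUE)
  sum(p[idx] * log(p[idx] / (pa[idx[, 1]] * pb[idx[, 2]])))
}

#' @rdname mutual_information
#' @export
normalized_mutual_information <- function(h) {
  p <- hist_probs(h)
  hab <- entropy_nats(p)
  if (hab <= 0)
    stop_pq("NMI undefined: both images constant (zero joint entropy)")
  (entropy_nats(rowSums(p)) + entropy_nats(colSums(p))) / hab
}

#' @rdname mutual_information
#' @export
feature_space_entropy <- function(h) {
  entropy_nats(hist_probs(h))
}

#' Cross-correlation of two volumes within a mask
#'
#' Pearson correlation coefficient of the in-mask intensities.
#'
#' @param a,b [volume3d] objects or arrays on the same grid.
#' @param mask logical/0-1 array; `NULL` uses all voxels.
#' @return Correlation in `[-1, 1]`.
#' @export
cross_correlation <- function(a, b, mask = NULL) {
  av <- if (inherits(a, "volume3d")) a$data else a
  bv <- if (inherits(b, "volume3d")) b$data else b
  assert_that(all(dim(av) == dim(bv)), "volumes must share a grid")
  if (is.null(mask)) mask <- rep(TRUE, length(av))
  m <- as.logical(mask)
  assert_that(any(m), "empty mask")
  x <- as.numeric(av)[m]
  y <- as.numeric(bv)[m]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_pq("undefined correlation: constant input inside mask")
  stats::cor(x, y)
}
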