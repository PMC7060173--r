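#' Cross-channel (k-)nearest-neighbor distances
#'
#' For each localization of `query`, the plain Euclidean distance to its
#' nearest neighbor in `reference` (`k = 1`), or the arithmetic mean of
#' the distances to its `k` nearest reference localizations (`k > 1`).
#' This is the raw material of the 2-CLASTA test statistic: clustering of
#' the underlying molecules shortens cross-channel distances.
#'
#' @param query,reference [LocalizationSet-class] objects (e.g. the red
#'   and blue color channels).
#' @param k Neighbor order (>= 1); `reference` must contain at least `k`
#'   records.
#' @return Numeric vector of distances (nm), one per query record.
#' @examples
#' red <- LocalizationSet(0, 0)
#' blue <- LocalizationSet(3, 4)
#' crossNNDistances(red, blue)  # 5
#' @export
crossNNDistances <- function(query, reference, k = 1L) {
  stopifnot(is(query, "LocalizationSet"), is(reference, "LocalizationSet"))
  .assertNonEmpty(query, "query set")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (nLocalizations(reference) < k)
    stop(sprintf("insufficient data: reference has %d record(s), need >= k = %d",
                 nLocalizations(reference), k))
  cpp_cross_knn(query@coords[, 1], query@coords[, 2],
                reference@coords[, 1], reference@coords[, 2], k)
}

#' Empirical cumulative distribution function
#'
#' Right-continuous step ecdf of a sample of statistic values (built on
#' [stats::ecdf()]).
#'
#' @param values Non-empty numeric vector of finite values.
#' @return A function of class `"ecdf"`.
#' @export
empiricalCdf <- function(values) {
  if (length(values) == 0L)
    stop("insufficient data: empirical cdf of an empty sample")
  if (!all(is.finite(values)))
    stop("values must be finite")
  stats::ecdf(values)
}

#' Integral of an empirical cdf over `[0, rMax]`
#'
#' The 2-CLASTA test statistic `g = integral of cdf(r) dr from 0 to rMax`.
#' For a step ecdf of values `v_i` this equals the closed form
#' `rMax - mean(min(v_i, rMax))`, which is evaluated exactly. Large `g`
#' means the cdf rises early, i.e. short cross-channel distances.
#'
#' @param values Numeric vector of statistic values (nm), or an `"ecdf"`
#'   object produced by [empiricalCdf()].
#' @param rMax Upper integration limit (nm), > 0.
#' @return The statistic `g` in `[0, rMax]` (nm).
#' @examples
#' cdfIntegral(c(0.2, 0.6, 1.0), 1)  # 0.4
#' @export
cdfIntegral <- function(values, rMax) {
  stopifnot(is.numeric(rMax), length(rMax) == 1L, rMax > 0)
  if (inherits(values, "ecdf")) {
    env <- environment(values)
    # knots and multiplicities reconstruct the sample exactly
    kx <- stats::knots(values)
    n <- env$nobs
    cnt <- round(diff(c(0, values(kx))) * n)
    values <- rep(kx, cnt)
  }
  if (length(values) == 0L) stop("insufficient data: empty sample")
  rMax - mean(pmin(values, rMax))
}

#' Per-point cross-type L function at a fixed radius
#'
#' For each query localization `i`, counts the reference localizations
#' within distance `rStar` (no edge correction) and transforms the count
#' to the L scale: `L_i = sqrt(K_i / pi)` with
#' `K_i = (area / nReference) * count_i`. Under cross-channel independence
#' `L_i` is on the order of `rStar`; co-clustering inflates it.
#'
#' @param query,reference [LocalizationSet-class] objects.
#' @param rStar Disc radius (nm); the conventional default is 50 nm.
#' @param area Observation-window area (nm^2); defaults to the area of the
#'   reference set's ROI.
#' @return Numeric vector of L values (nm), one per query record.
#' @export
lcrossValues <- function(query, reference, rStar = 50, area = NULL) {
  stopifnot(is(query, "LocalizationSet"), is(reference, "LocalizationSet"))
  .assertNonEmpty(query, "query set")
  .assertNonEmpty(reference, "reference set")
  if (rStar <= 0) stop("rStar must be positive")
  if (is.null(area)) area <- roiArea(reference@roi)
  if (area <= 0) stop("area must be positive")
  counts <- cpp_disc_counts(query@coords[, 1], query@coords[, 2],
                            reference@coords[, 1], reference@coords[, 2],
                            rStar)
  sqrt((area / nLocalizations(reference)) * counts / pi)
}
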