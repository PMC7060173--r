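#' Toroidal shift of a localization set
#'
#' Translates every localization by `v` and wraps coordinates back into
#' the ROI by modular arithmetic (periodic boundary conditions). The shift
#' breaks cross-channel correlations while conserving each channel's
#' internal structure — including the localization clusters produced by
#' blinking — which is what makes the randomized controls a valid null
#' model. Frames are unchanged.
#'
#' @param points A [LocalizationSet-class].
#' @param v Numeric 2-vector, shift in nm.
#' @param roi [RegionOfInterest-class] defining the torus; defaults to the
#'   set's own ROI.
#' @return A shifted [LocalizationSet-class] with all coordinates in
#'   `[min, max)`.
#' @examples
#' roi <- RegionOfInterest(0, 0, 10000, 10000)
#' ls <- LocalizationSet(9000, 9000, roi = roi)
#' coords(toroidalShift(ls, c(2000, 3000)))  # (1000, 2000)
#' @export
toroidalShift <- function(points, v, roi = NULL) {
  stopifnot(is(points, "LocalizationSet"), length(v) == 2L,
            all(is.finite(v)))
  if (is.null(roi)) roi <- points@roi
  w <- roiWidth(roi); h <- roiHeight(roi)
  x <- (points@coords[, 1] - roi@xMin + v[1]) %% w + roi@xMin
  y <- (points@coords[, 2] - roi@yMin + v[2]) %% h + roi@yMin
  initialize(points, coords = cbind(x = x, y = y), roi = roi)
}

#' Run the 2-CLASTA significance test
#'
#' Tests the null hypothesis that the two color channels are spatially
#' uncorrelated (as produced by a random distribution of biomolecules),
#' using a rank-based Monte-Carlo test that is immune to blinking and
#' overcounting:
#'
#' 1. Compute per-localization statistic values for the observed pair
#'    (nearest-neighbor distances, mean k-NN distances, or per-point
#'    `L_cross(rStar)` values, depending on `statistic`).
#' 2. Repeat `nControls` times with the query channel toroidally shifted
#'    by a vector drawn uniformly over the ROI, yielding randomized
#'    controls that retain each channel's univariate structure.
#' 3. With `rMax = "auto"`, set the integration limit to the maximum value
#'    occurring in the observed data *or any control*, so every cdf
#'    reaches 1 inside `[0, rMax]`; a numeric `rMax` overrides (useful
#'    when prior knowledge restricts the analysis to short distances).
#' 4. Summarize each cdf by `g = integral of cdf over [0, rMax]` and rank
#'    the observed `g` among the pooled `nControls + 1` values. For
#'    distance statistics and `direction = "clustering"`, the rank is
#'    taken in descending order (clustering shortens distances so inflates
#'    `g`); for `"lcross"` in ascending order (clustering inflates L);
#'    `direction = "repulsion"` reverses the order. Ties take the worst
#'    rank (conservative).
#' 5. `p = rank / (nControls + 1)`: one-sided, exact, and uniform on the
#'    discrete grid `{1/(N+1), ..., 1}` under the null. The smallest
#'    attainable p-value is `1/(nControls + 1)` (0.01 at the default
#'    `nControls = 99`).
#'
#' @param query,reference [LocalizationSet-class] objects sharing the same
#'   ROI; `query` is the channel that gets shifted (conventionally red).
#' @param statistic `"nn"`, `"knn"` or `"lcross"`.
#' @param k Neighbor order for `"knn"` (conventional values 3, 5, 10);
#'   forced to 1 for `"nn"`.
#' @param rStar Disc radius (nm) for `"lcross"`.
#' @param rMax `"auto"` or a positive number (nm).
#' @param nControls Number of randomized controls `N` (default 99).
#' @param direction `"clustering"` or `"repulsion"`.
#' @param seed Optional integer seed; if supplied the result is bit-exactly
#'   reproducible and the session RNG state is left untouched.
#' @param keepControls Keep the per-localization values of every control
#'   (memory-heavy; off by default).
#' @param keepCurves Record the observed cdf and the mean control cdf on a
#'   256-point grid for plotting.
#' @return A [ClastaResult-class].
#' @examples
#' roi <- RegionOfInterest(0, 0, 2000, 2000)
#' set.seed(1)
#' red <- LocalizationSet(runif(150, 0, 2000), runif(150, 0, 2000),
#'                        channelId = "red", roi = roi)
#' blue <- LocalizationSet(runif(150, 0, 2000), runif(150, 0, 2000),
#'                         channelId = "blue", roi = roi)
#' res <- runClastaTest(red, blue, nControls = 19, seed = 7)
#' pValue(res)
#' @export
runClastaTest <- function(query, reference,
                          statistic = c("nn", "knn", "lcross"),
                          k = 1L, rStar = 50, rMax = "auto",
                          nControls = 99L,
                          direction = c("clustering", "repulsion"),
                          seed = NULL, keepControls = FALSE,
                          keepCurves = FALSE) {
  statistic <- match.arg(statistic)
  direction <- match.arg(direction)
  stopifnot(is(query, "LocalizationSet"), is(reference, "LocalizationSet"))
  .assertNonEmpty(query, "query channel")
  .assertNonEmpty(reference, "reference channel")
  if (!.sameRoi(query@roi, reference@roi))
    stop("configuration error: query and reference must share the same ROI")
  # the analysis region is the ROI: records outside it (e.g. pushed across
  # the boundary by localization error or drift) are excluded, exactly as
  # when an ROI is drawn on experimental data. This keeps the observed and
  # toroidally shifted configurations exchangeable under the null.
  query <- query[.inRoi(query@coords[, 1], query@coords[, 2], query@roi)]
  reference <- reference[.inRoi(reference@coords[, 1],
                                reference@coords[, 2], reference@roi)]
  .assertNonEmpty(query, "query channel (within ROI)")
  .assertNonEmpty(reference, "reference channel (within ROI)")
  nControls <- as.integer(nControls)
  if (nControls < 1L) stop("nControls must be >= 1")
  k <- if (statistic == "nn") 1L else as.integer(k)
  if (statistic == "knn" && k < 1L) stop("k must be >= 1")
  if (statistic != "lcross" && nLocalizations(reference) < k)
    stop(sprintf("insufficient data: reference has %d record(s), need >= k = %d",
                 nLocalizations(reference), k))

  roi <- query@roi
  w <- roiWidth(roi); h <- roiHeight(roi)

  valueLists <- .withSeed(seed, {
    sx <- stats::runif(nControls, 0, w)
    sy <- stats::runif(nControls, 0, h)
    vl <- if (statistic == "lcross") {
      counts <- cpp_clasta_disc(query@coords[, 1], query@coords[, 2],
                                reference@coords[, 1], reference@coords[, 2],
                                rStar, sx, sy,
                                roi@xMin, roi@yMin, roi@xMax, roi@yMax)
      scale <- roiArea(roi) / nLocalizations(reference) / pi
      lapply(counts, function(cc) sqrt(scale * cc))
    } else {
      cpp_clasta_knn(query@coords[, 1], query@coords[, 2],
                     reference@coords[, 1], reference@coords[, 2], k,
                     sx, sy, roi@xMin, roi@yMin, roi@xMax, roi@yMax)
    }
    list(values = vl, sx = sx, sy = sy)
  })
  sx <- valueLists$sx; sy <- valueLists$sy
  values <- valueLists$values

  rMaxUsed <- if (identical(rMax, "auto")) {
    max(vapply(values, max, numeric(1)))
  } else {
    rMax <- as.numeric(rMax)
    if (!is.finite(rMax) || rMax <= 0) stop("rMax must be 'auto' or > 0")
    rMax
  }
  if (rMaxUsed <= 0) rMaxUsed <- .Machine$double.eps  # degenerate: all values 0

  g <- vapply(values, cdfIntegral, numeric(1), rMax = rMaxUsed)
  gData <- g[1L]
  gCtrl <- g[-1L]

  # descending rank rewards large g (short distances); lcross flips because
  # clustering inflates L, pushing its cdf right and deflating g
  descending <- (statistic != "lcross")
  if (direction == "repulsion") descending <- !descending
  rank <- if (descending) 1L + sum(gCtrl >= gData) else 1L + sum(gCtrl <= gData)
  p <- rank / (nControls + 1L)

  curves <- matrix(numeric(0), 0, 3,
                   dimnames = list(NULL, c("r", "cdfData", "cdfControlMean")))
  if (keepCurves) {
    r <- seq(0, rMaxUsed, length.out = 256L)
    cdfData <- empiricalCdf(values[[1L]])(r)
    ctrl <- vapply(values[-1L], function(v) empiricalCdf(v)(r),
                   numeric(length(r)))
    curves <- cbind(r = r, cdfData = cdfData,
                    cdfControlMean = rowMeans(ctrl))
  }

  new("ClastaResult", pValue = p, gData = gData, gControls = gCtrl,
      rMaxUsed = rMaxUsed, nControls = nControls, direction = direction,
      statistic = statistic, k = k, rStar = as.numeric(rStar),
      shiftVectors = cbind(x = sx, y = sy),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      dataValues = values[[1L]],
      controlValues = if (keepControls) values[-1L] else list(),
      curves = curves)
}

#' Decide rejection of the null hypothesis
#'
#' Rejects iff `p <= alpha`. Because the p-value lives on the grid
#' `{1/(N+1), ..., 1}` and is uniform under the null, the boundary-inclusive
#' rule gives a false-positive rate exactly equal to `alpha` whenever
#' `alpha` is a multiple of `1/(N+1)` (e.g. 0.05 at N = 99).
#'
#' @param pValue P-value or [ClastaResult-class].
#' @param alpha Significance level in `(0, 1]` (default 0.05).
#' @return Logical: reject the null of a random molecular distribution?
#' @export
rejectNull <- function(pValue, alpha = 0.05) {
  if (is(pValue, "ClastaResult")) pValue <- pValue@pValue
  stopifnot(alpha > 0, alpha <= 1)
  pValue <= alpha
}

#' @rdname clasta-accessors
#' @export
setMethod("pValue", "ClastaResult", function(object, ...) object@pValue)

#' @rdname clasta-accessors
#' @export
setMethod("gData", "ClastaResult", function(object, ...) object@gData)

#' @rdname clasta-accessors
#' @export
setMethod("gControls", "ClastaResult", function(object, ...) object@gControls)

#' @rdname clasta-accessors
#' @export
setMethod("rMaxUsed", "ClastaResult", function(object, ...) object@rMaxUsed)

setMethod("show", "ClastaResult", function(object) {
  cat("2-CLASTA significance test\n")
  statLabel <- switch(object@statistic,
    nn = "nearest-neighbor distance",
    knn = sprintf("mean %d-nearest-neighbor distance", object@k),
    lcross = sprintf("L_cross(r* = %g nm)", object@rStar))
  cat(sprintf("  statistic: %s, direction: %s\n",
              statLabel, object@direction))
  cat(sprintf("  g_data = %.4g nm, %d controls in [%.4g, %.4g] nm, r_max = %.4g nm\n",
              object@gData, object@nControls, min(object@gControls),
              max(object@gControls), object@rMaxUsed))
  cat(sprintf("  p-value = %.4g (grid step 1/%d)\n",
              object@pValue, object@nControls + 1L))
})

# evaluate expr under a temporary seed, restoring the session RNG state
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hadSeed) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(expr))
}

# counter-based sub-seed: identical (seed, index) -> identical sub-seed,
# independent of execution order; kept inside the 32-bit integer range
.subSeed <- function(seed, index) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + index * 16807) %%
               2147483647)
}
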