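#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib clasta, .registration = TRUE
NULL

#' Axis-aligned rectangular region of interest
#'
#' A `RegionOfInterest` defines the rectangle (in nanometers) on which an
#' analysis operates. It fixes both the coordinate frame of a
#' [LocalizationSet] and the torus used for toroidal-shift randomization:
#' membership is half-open, `[xMin, xMax) x [yMin, yMax)`, so wrap-around
#' under modular arithmetic is a bijection.
#'
#' @slot xMin,yMin,xMax,yMax Rectangle bounds in nm; `xMax > xMin` and
#'   `yMax > yMin`, all finite.
#'
#' @seealso [RegionOfInterest()], [toroidalShift()]
#' @export
setClass("RegionOfInterest",
  representation(xMin = "numeric", yMin = "numeric",
                 xMax = "numeric", yMax = "numeric"))

setValidity("RegionOfInterest", function(object) {
  b <- c(object@xMin, object@yMin, object@xMax, object@yMax)
  if (length(b) != 4L || !all(is.finite(b)))
    return("all four bounds must be single finite numbers")
  if (object@xMax <= object@xMin) return("xMax must exceed xMin")
  if (object@yMax <= object@yMin) return("yMax must exceed yMin")
  TRUE
})

#' Two-dimensional localizations of one color channel
#'
#' A `LocalizationSet` holds the fitted 2D positions (in nm) of all
#' single-molecule detections of one color channel, together with their
#' acquisition-frame indices and the [RegionOfInterest] they were recorded
#' in. Positions are continuous; frame indices are 1-based. Coordinates may
#' lie slightly outside the ROI (localization error, drift and chromatic
#' aberration can push detections across the boundary); operations that
#' need the torus wrap them by modular arithmetic.
#'
#' @slot channelId Character label, e.g. `"red"` or `"blue"`.
#' @slot coords Numeric matrix with columns `x`, `y` (nm).
#' @slot frames Integer vector of 1-based frame indices, one per row of
#'   `coords`.
#' @slot roi A [RegionOfInterest].
#'
#' @seealso [LocalizationSet()], [readLocalizations()], [runClastaTest()]
#' @export
setClass("LocalizationSet",
  representation(channelId = "character", coords = "matrix",
                 frames = "integer", roi = "RegionOfInterest"))

setValidity("LocalizationSet", function(object) {
  if (length(object@channelId) != 1L || is.na(object@channelId))
    return("channelId must be a single non-NA string")
  if (!is.numeric(object@coords) || ncol(object@coords) != 2L)
    return("coords must be a numeric matrix with two columns (x, y)")
  if (nrow(object@coords) > 0L && !all(is.finite(object@coords)))
    return("all coordinates must be finite")
  if (length(object@frames) != nrow(object@coords))
    return("frames must have one entry per localization")
  if (length(object@frames) > 0L &&
      (anyNA(object@frames) || any(object@frames < 1L)))
    return("frame indices must be positive integers")
  TRUE
})

#' Result of a 2-CLASTA significance test
#'
#' Container for everything [runClastaTest()] computes: the observed
#' statistic, the Monte-Carlo control statistics from toroidal-shift
#' randomization, the `rMax` convention actually used, and the rank-based
#' p-value. The p-value lives on the discrete grid
#' `{1/(N+1), 2/(N+1), ..., 1}` where `N` is the number of controls.
#'
#' @slot pValue One-sided p-value.
#' @slot gData Test statistic of the observed data (nm).
#' @slot gControls Numeric vector of `N` control statistics.
#' @slot rMaxUsed Upper integration limit actually used (nm).
#' @slot nControls Number of randomized controls `N`.
#' @slot direction `"clustering"` or `"repulsion"`.
#' @slot statistic `"nn"`, `"knn"` or `"lcross"`.
#' @slot k Neighbor order for the knn statistic.
#' @slot rStar Disc radius for the lcross statistic (nm).
#' @slot shiftVectors `N x 2` matrix of toroidal shift vectors (nm).
#' @slot seed Integer seed used, or `NA` if the session RNG was used.
#' @slot dataValues Per-localization statistic values of the observed pair
#'   (NN distances, mean k-NN distances, or L values).
#' @slot controlValues List of `N` control value vectors (empty unless
#'   `keepControls = TRUE`).
#' @slot curves Matrix with columns `r`, `cdfData`, `cdfControlMean`
#'   (empty unless `keepCurves = TRUE`).
#'
#' @seealso [runClastaTest()], [pValue()], [rejectNull()]
#' @export
setClass("ClastaResult",
  representation(pValue = "numeric", gData = "numeric",
                 gControls = "numeric", rMaxUsed = "numeric",
                 nControls = "integer", direction = "character",
                 statistic = "character", k = "integer", rStar = "numeric",
                 shiftVectors = "matrix", seed = "integer",
                 dataValues = "numeric", controlValues = "list",
                 curves = "matrix"))

setValidity("ClastaResult", function(object) {
  N <- object@nControls
  if (length(object@gControls) != N)
    return("gControls must have length nControls")
  if (nrow(object@shiftVectors) != N)
    return("shiftVectors must have nControls rows")
  r <- object@pValue * (N + 1L)
  if (abs(r - round(r)) > 1e-8 || round(r) < 1 || round(r) > N + 1L)
    return("pValue * (nControls + 1) must be an integer in [1, N + 1]")
  if (object@rMaxUsed <= 0) return("rMaxUsed must be positive")
  TRUE
})

#' Spatial pattern of the simulated molecules
#'
#' Describes the ground-truth molecular distribution of one simulated
#' experiment: complete spatial randomness (`"random"`), randomly placed
#' n-mers (`"oligomer"`, all n protomers at the n-mer position by default),
#' or areas of enrichment/depletion (`"circular_domains"`,
#' `"rectangular_domains"`).
#'
#' @slot kind Pattern kind.
#' @slot nMer Oligomer order (1-4) for `"oligomer"`.
#' @slot protomerOffset Standard deviation (nm) of an optional Gaussian
#'   scatter of protomers about the n-mer position; 0 by default.
#' @slot domainRadius Radius of circular domains (nm).
#' @slot rectSize Width and height of rectangular domains (nm).
#' @slot domainDensity Domains per um^2.
#' @slot fractionInDomains Fraction of molecules placed inside domains.
#' @slot moleculeDensity Molecules per um^2.
#'
#' @seealso [PatternSpec()], [placeMolecules()]
#' @export
setClass("PatternSpec",
  representation(kind = "character", nMer = "integer",
                 protomerOffset = "numeric", domainRadius = "numeric",
                 rectSize = "numeric", domainDensity = "numeric",
                 fractionInDomains = "numeric", moleculeDensity = "numeric"))

setValidity("PatternSpec", function(object) {
  kinds <- c("random", "oligomer", "circular_domains", "rectangular_domains")
  if (!(object@kind %in% kinds))
    return(sprintf("kind must be one of %s", paste(kinds, collapse = ", ")))
  if (object@nMer < 1L || object@nMer > 4L)
    return("nMer must be an integer between 1 and 4")
  if (object@moleculeDensity < 0) return("moleculeDensity must be >= 0")
  if (object@fractionInDomains < 0 || object@fractionInDomains > 1)
    return("fractionInDomains must lie in [0, 1]")
  if (object@domainDensity < 0) return("domainDensity must be >= 0")
  if (object@kind == "circular_domains" && object@domainRadius <= 0)
    return("domainRadius must be positive for circular domains")
  if (object@kind == "rectangular_domains" &&
      (length(object@rectSize) != 2L || any(object@rectSize <= 0)))
    return("rectSize must be two positive lengths (nm)")
  TRUE
})

#' Stochastic labeling of molecules
#'
#' Each molecule independently carries a label with probability
#' `efficiency`; a labeled molecule is red with probability `ratio`, blue
#' otherwise (binomial statistics). Each molecule contributes to at most
#' one color channel.
#'
#' @slot efficiency Probability a molecule carries any label (in `[0, 1]`).
#' @slot ratio Probability a labeled molecule is red (in `[0, 1]`).
#'
#' @seealso [LabelingSpec()], [assignLabels()]
#' @export
setClass("LabelingSpec",
  representation(efficiency = "numeric", ratio = "numeric"))

setValidity("LabelingSpec", function(object) {
  if (object@efficiency < 0 || object@efficiency > 1)
    return("efficiency must lie in [0, 1]")
  if (object@ratio < 0 || object@ratio > 1)
    return("ratio must lie in [0, 1]")
  TRUE
})

#' Blinking model: detections per label and frame assignment
#'
#' Each fluorescent label produces a random number of detections
#' ("blinking"/overcounting); this class holds the distribution of
#' detections per label (always >= 1) and the rule assigning each
#' detection to an acquisition frame.
#'
#' @slot family `"lognormal"` (ceiling of a log-normal draw),
#'   `"geometric"` (support 1, 2, ...), `"fixed"`, or `"empirical"`
#'   (user-supplied histogram over positive integers).
#' @slot meanlog,sdlog Log-normal parameters.
#' @slot mean Mean of the geometric variant.
#' @slot m Detection count of the fixed variant.
#' @slot table Named numeric vector: probabilities (or weights) indexed by
#'   the detection count, for the empirical variant.
#' @slot frameAssignment `"uniform"` (i.i.d. uniform frames) or `"burst"`
#'   (geometric on-times separated by geometric off-times).
#' @slot burstOn,burstOff Mean on-/off-times (frames) of the burst model.
#' @slot nFrames Total number of acquisition frames.
#'
#' @seealso [BlinkModel()], [simulateBlinking()]
#' @export
setClass("BlinkModel",
  representation(family = "character", meanlog = "numeric", sdlog = "numeric",
                 mean = "numeric", m = "integer", table = "numeric",
                 frameAssignment = "character", burstOn = "numeric",
                 burstOff = "numeric", nFrames = "integer"))

setValidity("BlinkModel", function(object) {
  fams <- c("lognormal", "geometric", "fixed", "empirical")
  if (!(object@family %in% fams))
    return(sprintf("family must be one of %s", paste(fams, collapse = ", ")))
  if (object@family == "geometric" && object@mean < 1)
    return("geometric mean must be >= 1 (every label blinks at least once)")
  if (object@family == "fixed" && object@m < 1L)
    return("fixed detection count must be >= 1")
  if (object@family == "empirical") {
    if (length(object@table) == 0L || is.null(names(object@table)))
      return("empirical family needs a named probability table")
    counts <- suppressWarnings(as.integer(names(object@table)))
    if (anyNA(counts) || any(counts < 1L))
      return("empirical table must be indexed by positive integer counts")
    if (any(object@table < 0) || sum(object@table) <= 0)
      return("empirical table weights must be non-negative, not all zero")
  }
  if (!(object@frameAssignment %in% c("uniform", "burst")))
    return("frameAssignment must be 'uniform' or 'burst'")
  if (object@nFrames < 1L) return("nFrames must be >= 1")
  TRUE
})

#' Imaging and sample artifacts applied to simulated localizations
#'
#' @slot localizationErrorSigma Gaussian localization error (standard
#'   deviation, nm), applied independently in x and y.
#' @slot unspecificLabelDensity Unspecifically bound labels per um^2 and
#'   channel; blinked with the channel's own [BlinkModel].
#' @slot backgroundDensityRed,backgroundDensityBlue False-positive
#'   background signals per um^2, blinked with `backgroundBlink`.
#' @slot backgroundBlink [BlinkModel] of the background signals.
#' @slot driftTotal Total linear stage drift (nm in x and y) accumulated
#'   over `nFrames`, applied identically to both channels.
#' @slot aberrationBeta Dimensionless gain of the residual chromatic
#'   aberration field applied to the red channel.
#' @slot aberrationCenter Fixed point (nm) of the aberration field.
#'
#' @seealso [ArtifactSpec()], [simulateExperiment()]
#' @export
setClass("ArtifactSpec",
  representation(localizationErrorSigma = "numeric",
                 unspecificLabelDensity = "numeric",
                 backgroundDensityRed = "numeric",
                 backgroundDensityBlue = "numeric",
                 backgroundBlink = "BlinkModel",
                 driftTotal = "numeric",
                 aberrationBeta = "numeric",
                 aberrationCenter = "numeric"))

setValidity("ArtifactSpec", function(object) {
  if (object@localizationErrorSigma < 0) return("sigma must be >= 0")
  if (object@unspecificLabelDensity < 0 ||
      object@backgroundDensityRed < 0 || object@backgroundDensityBlue < 0)
    return("densities must be >= 0")
  if (length(object@driftTotal) != 2L || !all(is.finite(object@driftTotal)))
    return("driftTotal must be a finite 2-vector (nm)")
  if (object@aberrationBeta < 0) return("aberrationBeta must be >= 0")
  if (length(object@aberrationCenter) != 2L)
    return("aberrationCenter must be a 2-vector (nm)")
  TRUE
})

#' Full parameterization of one simulated two-color experiment
#'
#' @slot roi [RegionOfInterest] of the simulated field.
#' @slot pattern [PatternSpec] of the ground-truth molecules.
#' @slot labeling [LabelingSpec].
#' @slot blinkRed,blinkBlue [BlinkModel] of each channel.
#' @slot artifacts [ArtifactSpec].
#'
#' @seealso [Scenario()], [idealScenario()], [realisticScenario()],
#'   [simulateExperiment()]
#' @export
setClass("Scenario",
  representation(roi = "RegionOfInterest", pattern = "PatternSpec",
                 labeling = "LabelingSpec", blinkRed = "BlinkModel",
                 blinkBlue = "BlinkModel", artifacts = "ArtifactSpec"))

#' Sensitivity estimate for one scenario
#'
#' @slot scenario The [Scenario] evaluated.
#' @slot alpha Significance level.
#' @slot nSims Number of replicate simulations.
#' @slot nRejections Number of replicates with `p <= alpha`.
#' @slot sensitivity `nRejections / nSims`.
#' @slot pValues All replicate p-values.
#'
#' @seealso [estimateSensitivity()], [runGrid()]
#' @export
setClass("PowerResult",
  representation(scenario = "Scenario", alpha = "numeric",
                 nSims = "integer", nRejections = "integer",
                 sensitivity = "numeric", pValues = "numeric"))

setValidity("PowerResult", function(object) {
  if (length(object@pValues) != object@nSims)
    return("pValues must have one entry per replicate")
  if (object@sensitivity < 0 || object@sensitivity > 1)
    return("sensitivity must lie in [0, 1]")
  TRUE
})
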