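#' Construct a molecular pattern specification
#'
#' @param kind `"random"`, `"oligomer"`, `"circular_domains"` or
#'   `"rectangular_domains"`. `"random"` is equivalent to monomers
#'   (`"oligomer"` with `nMer = 1`).
#' @param nMer Oligomer order (1-4).
#' @param protomerOffset Gaussian scatter (sd, nm) of protomers about the
#'   n-mer position; the default 0 puts all n protomers at one point.
#' @param domainRadius Circular-domain radius (nm); studied values span
#'   20-150 nm.
#' @param rectSize Rectangular-domain width and height (nm); the studied
#'   geometry is 80 x 400 nm^2.
#' @param domainDensity Domains per um^2 (studied range 3-25).
#' @param fractionInDomains Fraction of molecules inside domains (0-1).
#' @param moleculeDensity Molecules per um^2 (default 75).
#' @return A [PatternSpec-class].
#' @export
PatternSpec <- function(kind = c("random", "oligomer", "circular_domains",
                                 "rectangular_domains"),
                        nMer = 1L, protomerOffset = 0,
                        domainRadius = 100, rectSize = c(80, 400),
                        domainDensity = 10, fractionInDomains = 1,
                        moleculeDensity = 75) {
  kind <- match.arg(kind)
  new("PatternSpec", kind = kind, nMer = as.integer(nMer),
      protomerOffset = as.numeric(protomerOffset),
      domainRadius = as.numeric(domainRadius),
      rectSize = as.numeric(rectSize),
      domainDensity = as.numeric(domainDensity),
      fractionInDomains = as.numeric(fractionInDomains),
      moleculeDensity = as.numeric(moleculeDensity))
}

#' Construct a labeling specification
#'
#' @param efficiency Probability a molecule carries any label (1.0 in the
#'   ideal scenario, 0.4 in the realistic one).
#' @param ratio Probability a labeled molecule is red (0.5 = balanced).
#' @return A [LabelingSpec-class].
#' @export
LabelingSpec <- function(efficiency = 1, ratio = 0.5) {
  new("LabelingSpec", efficiency = as.numeric(efficiency),
      ratio = as.numeric(ratio))
}

#' Construct a blinking model
#'
#' @param family Distribution of detections per label: `"lognormal"`
#'   (ceiling of a log-normal draw, always >= 1), `"geometric"` (support
#'   1, 2, ...), `"fixed"`, or `"empirical"` (histogram).
#' @param meanlog,sdlog Log-normal parameters. The defaults give a mean of
#'   about 5 detections per label with a heavy right tail, the regime of
#'   typical SNAP-tag dSTORM labels.
#' @param mean Mean of the geometric variant (>= 1).
#' @param m Count of the fixed variant.
#' @param table Named numeric vector of weights indexed by detection count
#'   (e.g. `c("1" = 0.5, "2" = 0.3, "5" = 0.2)`).
#' @param frameAssignment `"uniform"` or `"burst"`.
#' @param burstOn,burstOff Mean on-/off-times in frames for `"burst"`.
#' @param nFrames Total acquisition frames per channel (default 10000).
#' @return A [BlinkModel-class].
#' @export
BlinkModel <- function(family = c("lognormal", "geometric", "fixed",
                                  "empirical"),
                       meanlog = log(3.2), sdlog = 0.8,
                       mean = 2, m = 1L, table = numeric(0),
                       frameAssignment = c("uniform", "burst"),
                       burstOn = 2, burstOff = 50, nFrames = 10000L) {
  family <- match.arg(family)
  frameAssignment <- match.arg(frameAssignment)
  new("BlinkModel", family = family, meanlog = as.numeric(meanlog),
      sdlog = as.numeric(sdlog), mean = as.numeric(mean), m = as.integer(m),
      table = table, frameAssignment = frameAssignment,
      burstOn = as.numeric(burstOn), burstOff = as.numeric(burstOff),
      nFrames = as.integer(nFrames))
}

#' Construct an artifact specification
#'
#' @param localizationErrorSigma Gaussian localization error (sd, nm);
#'   default 30 nm, typical of SMLM experiments.
#' @param unspecificLabelDensity Unspecifically bound labels per um^2 and
#'   channel (realistic value 5).
#' @param backgroundDensityRed,backgroundDensityBlue False-positive
#'   background signals per um^2 (realistic values 1 and 2).
#' @param backgroundBlink [BlinkModel-class] of background signals;
#'   defaults to a geometric model with mean 2 detections.
#' @param driftTotal Total linear stage drift over the acquisition (nm in
#'   x and y), applied identically to both channels.
#' @param aberrationBeta Gain of the residual chromatic-aberration field
#'   (0-0.06 studied).
#' @param aberrationCenter Fixed point of the aberration field (nm);
#'   default (2500, 2500).
#' @return An [ArtifactSpec-class].
#' @export
ArtifactSpec <- function(localizationErrorSigma = 30,
                         unspecificLabelDensity = 0,
                         backgroundDensityRed = 0,
                         backgroundDensityBlue = 0,
                         backgroundBlink = BlinkModel("geometric", mean = 2),
                         driftTotal = c(0, 0),
                         aberrationBeta = 0,
                         aberrationCenter = c(2500, 2500)) {
  new("ArtifactSpec",
      localizationErrorSigma = as.numeric(localizationErrorSigma),
      unspecificLabelDensity = as.numeric(unspecificLabelDensity),
      backgroundDensityRed = as.numeric(backgroundDensityRed),
      backgroundDensityBlue = as.numeric(backgroundDensityBlue),
      backgroundBlink = backgroundBlink,
      driftTotal = as.numeric(driftTotal),
      aberrationBeta = as.numeric(aberrationBeta),
      aberrationCenter = as.numeric(aberrationCenter))
}

#' Construct a scenario
#'
#' @param roi [RegionOfInterest-class]; default 10 x 10 um^2.
#' @param pattern [PatternSpec-class].
#' @param labeling [LabelingSpec-class].
#' @param blinkRed,blinkBlue [BlinkModel-class] per channel.
#' @param artifacts [ArtifactSpec-class].
#' @return A [Scenario-class].
#' @seealso [idealScenario()], [realisticScenario()]
#' @export
Scenario <- function(roi = RegionOfInterest(0, 0, 10000, 10000),
                     pattern = PatternSpec(),
                     labeling = LabelingSpec(),
                     blinkRed = BlinkModel(),
                     blinkBlue = BlinkModel(),
                     artifacts = ArtifactSpec()) {
  new("Scenario", roi = roi, pattern = pattern, labeling = labeling,
      blinkRed = blinkRed, blinkBlue = blinkBlue, artifacts = artifacts)
}

#' Preset scenarios
#'
#' `idealScenario()`: 100% labeling efficiency, no unspecific labels, no
#' background, 30 nm localization error, 75 molecules/um^2 on a
#' 10 x 10 um^2 field. `realisticScenario()`: 40% labeling efficiency,
#' 5 unspecific labels/um^2 per channel, 1 (red) and 2 (blue) background
#' signals/um^2, otherwise identical.
#'
#' @param pattern [PatternSpec-class] to embed (default monomers).
#' @param ... Further arguments passed to [Scenario()].
#' @return A [Scenario-class].
#' @export
idealScenario <- function(pattern = PatternSpec("random"), ...) {
  Scenario(pattern = pattern, labeling = LabelingSpec(efficiency = 1),
           artifacts = ArtifactSpec(), ...)
}

#' @rdname idealScenario
#' @export
realisticScenario <- function(pattern = PatternSpec("random"), ...) {
  Scenario(pattern = pattern, labeling = LabelingSpec(efficiency = 0.4),
           artifacts = ArtifactSpec(unspecificLabelDensity = 5,
                                    backgroundDensityRed = 1,
                                    backgroundDensityBlue = 2), ...)
}

setMethod("show", "Scenario", function(object) {
  p <- object@pattern
  cat(sprintf("Scenario: %s pattern, %g molecules/um^2 on %.3g um^2\n",
              p@kind, p@moleculeDensity, roiArea(object@roi) / 1e6))
  cat(sprintf("  labeling: efficiency %.2f, red ratio %.2f\n",
              object@labeling@efficiency, object@labeling@ratio))
  a <- object@artifacts
  cat(sprintf("  error sigma %g nm, unspecific %g/um^2, bg %g|%g/um^2, drift (%g, %g) nm, beta %g\n",
              a@localizationErrorSigma, a@unspecificLabelDensity,
              a@backgroundDensityRed, a@backgroundDensityBlue,
              a@driftTotal[1], a@driftTotal[2], a@aberrationBeta))
})

#' Place ground-truth molecules
#'
#' Stage 1 of the generative model. `"random"` scatters molecules
#' uniformly (equivalently, monomers); `"oligomer"` scatters
#' `floor(total / n)` n-mer positions uniformly and puts n molecules at
#' each; the domain kinds scatter `round(domainDensity * area)` domain
#' centers uniformly, draw per-domain molecule counts i.i.d. Poisson with
#' mean `total * fractionInDomains / nDomains`, place those molecules
#' uniformly within their domain (wrapped toroidally into the ROI when a
#' domain overhangs the edge), and scatter the remaining
#' `(1 - fractionInDomains) * total` molecules uniformly outside all
#' domains by rejection sampling.
#'
#' @param pattern [PatternSpec-class].
#' @param roi [RegionOfInterest-class].
#' @return Numeric matrix of molecule positions with columns `x`, `y`
#'   (nm). Uses the session RNG.
#' @export
placeMolecules <- function(pattern, roi) {
  stopifnot(is(pattern, "PatternSpec"), is(roi, "RegionOfInterest"))
  areaUm2 <- roiArea(roi) / 1e6
  total <- round(pattern@moleculeDensity * areaUm2)
  runifRoi <- function(n) {
    cbind(x = stats::runif(n, roi@xMin, roi@xMax),
          y = stats::runif(n, roi@yMin, roi@yMax))
  }
  kind <- pattern@kind
  if (kind == "random" || (kind == "oligomer" && pattern@nMer == 1L)) {
    return(runifRoi(total))
  }
  if (kind == "oligomer") {
    n <- pattern@nMer
    centers <- runifRoi(total %/% n)
    mol <- centers[rep(seq_len(nrow(centers)), each = n), , drop = FALSE]
    if (pattern@protomerOffset > 0) {
      mol <- mol + matrix(stats::rnorm(2 * nrow(mol), 0,
                                       pattern@protomerOffset),
                          ncol = 2)
    }
    return(mol)
  }
  # domain kinds
  nDomains <- round(pattern@domainDensity * areaUm2)
  frac <- pattern@fractionInDomains
  if (nDomains == 0L && frac > 0)
    stop("configuration error: fractionInDomains > 0 requires at least one domain")
  centers <- runifRoi(nDomains)
  nInside <- if (nDomains > 0L)
    stats::rpois(nDomains, total * frac / nDomains) else integer(0)
  inDomain <- function(px, py) {
    # membership of points (in ROI coordinates) in any domain, on the torus
    if (nDomains == 0L) return(rep(FALSE, length(px)))
    w <- roiWidth(roi); h <- roiHeight(roi)
    hit <- rep(FALSE, length(px))
    for (d in seq_len(nDomains)) {
      dx <- abs(px - centers[d, 1]); dx <- pmin(dx, w - dx)
      dy <- abs(py - centers[d, 2]); dy <- pmin(dy, h - dy)
      hit <- hit | if (kind == "circular_domains") {
        dx * dx + dy * dy <= pattern@domainRadius^2
      } else {
        dx <= pattern@rectSize[1] / 2 & dy <= pattern@rectSize[2] / 2
      }
    }
    hit
  }
  wrapRoi <- function(m) {
    cbind(x = (m[, 1] - roi@xMin) %% roiWidth(roi) + roi@xMin,
          y = (m[, 2] - roi@yMin) %% roiHeight(roi) + roi@yMin)
  }
  inside <- lapply(seq_len(nDomains), function(d) {
    ni <- nInside[d]
    if (ni == 0L) return(NULL)
    if (kind == "circular_domains") {
      rr <- pattern@domainRadius * sqrt(stats::runif(ni))
      th <- stats::runif(ni, 0, 2 * pi)
      cbind(centers[d, 1] + rr * cos(th), centers[d, 2] + rr * sin(th))
    } else {
      cbind(centers[d, 1] + stats::runif(ni, -0.5, 0.5) * pattern@rectSize[1],
            centers[d, 2] + stats::runif(ni, -0.5, 0.5) * pattern@rectSize[2])
    }
  })
  inside <- do.call(rbind, inside)
  if (!is.null(inside)) inside <- wrapRoi(inside)
  nOutside <- round(total * (1 - frac))
  outside <- NULL
  if (nOutside > 0L) {
    acc <- matrix(numeric(0), 0, 2)
    while (nrow(acc) < nOutside) {
      cand <- runifRoi(max(nOutside - nrow(acc), 16L) * 2L)
      keep <- !inDomain(cand[, 1], cand[, 2])
      acc <- rbind(acc, cand[keep, , drop = FALSE])
    }
    outside <- acc[seq_len(nOutside), , drop = FALSE]
  }
  mol <- rbind(inside, outside)
  colnames(mol) <- c("x", "y")
  mol
}

#' Assign color labels to molecules
#'
#' Stage 2: each molecule independently carries a label with probability
#' `efficiency`; a labeled molecule is red with probability `ratio`, blue
#' otherwise, so every molecule contributes to at most one channel.
#'
#' @param molecules Numeric matrix of positions (columns x, y, nm).
#' @param labeling [LabelingSpec-class].
#' @return List with matrices `red` and `blue` of label positions.
#' @export
assignLabels <- function(molecules, labeling) {
  stopifnot(is(labeling, "LabelingSpec"))
  n <- nrow(molecules)
  u <- stats::runif(n)
  labeled <- u < labeling@efficiency
  red <- labeled & (stats::runif(n) < labeling@ratio)
  blue <- labeled & !red
  list(red = molecules[red, , drop = FALSE],
       blue = molecules[blue, , drop = FALSE])
}

# detections per label, always >= 1
.drawDetections <- function(nLabels, blink) {
  switch(blink@family,
    lognormal = pmax(1L, as.integer(ceiling(
      stats::rlnorm(nLabels, blink@meanlog, blink@sdlog)))),
    geometric = 1L + stats::rgeom(nLabels, prob = 1 / blink@mean),
    fixed = rep(blink@m, nLabels),
    empirical = {
      counts <- as.integer(names(blink@table))
      sample(counts, nLabels, replace = TRUE,
             prob = blink@table / sum(blink@table))
    })
}

.drawFrames <- function(mPerLabel, blink) {
  total <- sum(mPerLabel)
  if (blink@frameAssignment == "uniform") {
    return(sample.int(blink@nFrames, total, replace = TRUE))
  }
  # burst: first frame uniform, then alternating geometric on/off runs
  unlist(lapply(mPerLabel, function(m) {
    f <- integer(m)
    t <- sample.int(blink@nFrames, 1L)
    i <- 1L
    while (i <= m) {
      on <- 1L + stats::rgeom(1L, 1 / blink@burstOn)
      for (j in seq_len(min(on, m - i + 1L))) {
        f[i] <- min(t, blink@nFrames)
        t <- t + 1L
        i <- i + 1L
      }
      t <- t + 1L + stats::rgeom(1L, 1 / blink@burstOff)
      if (t > blink@nFrames) t <- sample.int(blink@nFrames, 1L)
    }
    f
  }), use.names = FALSE)
}

#' Simulate blinking of a set of labels
#'
#' Stage 3a: each label yields `m >= 1` detections at the label position,
#' with `m` drawn from the model's detections-per-label distribution and
#' frames assigned per its frame-assignment rule. Localization error is
#' applied separately ([applyLocalizationError()]).
#'
#' @param labels Numeric matrix of label positions (columns x, y, nm).
#' @param blink [BlinkModel-class].
#' @param roi [RegionOfInterest-class] to attach to the result.
#' @param channelId Channel label.
#' @return A [LocalizationSet-class] with one record per detection.
#' @export
simulateBlinking <- function(labels, blink, roi, channelId = "points") {
  stopifnot(is(blink, "BlinkModel"))
  nLabels <- nrow(labels)
  if (nLabels == 0L) {
    return(new("LocalizationSet", channelId = channelId,
               coords = cbind(x = numeric(0), y = numeric(0)),
               frames = integer(0), roi = roi))
  }
  m <- .drawDetections(nLabels, blink)
  idx <- rep(seq_len(nLabels), m)
  LocalizationSet(labels[idx, 1], labels[idx, 2],
                  frames = .drawFrames(m, blink),
                  channelId = channelId, roi = roi)
}

#' Apply Gaussian localization error
#'
#' Stage 3b: displaces each detection by independent Gaussian noise of
#' standard deviation `sigma` in x and y.
#'
#' @param ls A [LocalizationSet-class].
#' @param sigma Localization error (sd, nm), >= 0.
#' @return The displaced [LocalizationSet-class]; records pushed across
#'   the ROI boundary are kept as-is.
#' @export
applyLocalizationError <- function(ls, sigma) {
  stopifnot(is(ls, "LocalizationSet"), sigma >= 0)
  n <- nLocalizations(ls)
  if (sigma == 0 || n == 0L) return(ls)
  initialize(ls, coords = cbind(
    x = ls@coords[, 1] + stats::rnorm(n, 0, sigma),
    y = ls@coords[, 2] + stats::rnorm(n, 0, sigma)))
}

#' Add unspecific labels and false-positive background
#'
#' Stage 4: per channel, `Poisson(density * area)` unspecifically bound
#' labels are scattered uniformly and blinked with the channel's own
#' blinking model; false-positive background signals likewise, but with
#' the dedicated background blinking model. Both are spread with the
#' localization error.
#'
#' @param channels List with [LocalizationSet-class] elements `red` and
#'   `blue`.
#' @param artifacts [ArtifactSpec-class].
#' @param roi [RegionOfInterest-class].
#' @param blinkRed,blinkBlue Channel [BlinkModel-class] objects used for
#'   the unspecific labels.
#' @return The augmented `channels` list.
#' @export
addUnspecificAndBackground <- function(channels, artifacts, roi,
                                       blinkRed, blinkBlue) {
  stopifnot(is(artifacts, "ArtifactSpec"))
  areaUm2 <- roiArea(roi) / 1e6
  addPoints <- function(ls, density, blink) {
    nPts <- stats::rpois(1L, density * areaUm2)
    if (nPts == 0L) return(ls)
    pos <- cbind(stats::runif(nPts, roi@xMin, roi@xMax),
                 stats::runif(nPts, roi@yMin, roi@yMax))
    extra <- simulateBlinking(pos, blink, roi, channelId(ls))
    extra <- applyLocalizationError(extra, artifacts@localizationErrorSigma)
    initialize(ls, coords = rbind(ls@coords, extra@coords),
               frames = c(ls@frames, extra@frames))
  }
  if (artifacts@unspecificLabelDensity > 0) {
    channels$red <- addPoints(channels$red, artifacts@unspecificLabelDensity,
                              blinkRed)
    channels$blue <- addPoints(channels$blue, artifacts@unspecificLabelDensity,
                               blinkBlue)
  }
  if (artifacts@backgroundDensityRed > 0)
    channels$red <- addPoints(channels$red, artifacts@backgroundDensityRed,
                              artifacts@backgroundBlink)
  if (artifacts@backgroundDensityBlue > 0)
    channels$blue <- addPoints(channels$blue, artifacts@backgroundDensityBlue,
                               artifacts@backgroundBlink)
  channels
}

#' Apply linear stage drift
#'
#' Stage 5: with alternating laser excitation both channels share the
#' stage, so the same linear drift law applies to both: a record acquired
#' at frame `t` is displaced by `driftTotal * t / nFrames`.
#'
#' @param channels List with [LocalizationSet-class] elements `red`, `blue`.
#' @param driftTotal Total drift (nm in x and y) over `nFrames`.
#' @param nFrames Total acquisition frames.
#' @return The drifted `channels` list.
#' @export
applyDrift <- function(channels, driftTotal, nFrames) {
  stopifnot(length(driftTotal) == 2L, nFrames >= 1L)
  if (all(driftTotal == 0)) return(channels)
  shift1 <- function(ls) {
    frac <- ls@frames / nFrames
    initialize(ls, coords = cbind(x = ls@coords[, 1] + driftTotal[1] * frac,
                                  y = ls@coords[, 2] + driftTotal[2] * frac))
  }
  channels$red <- shift1(channels$red)
  channels$blue <- shift1(channels$blue)
  channels
}

#' Apply residual chromatic aberration to the red channel
#'
#' Stage 6: each red record at `(x, y)` is displaced by the linear radial
#' field `beta * (x - x0, y - y0)`; the blue channel is the registration
#' reference and stays put.
#'
#' @param redChannel A [LocalizationSet-class].
#' @param beta Dimensionless gain (>= 0; 0-0.06 studied).
#' @param center Fixed point `(x0, y0)` of the field (nm).
#' @return The displaced red [LocalizationSet-class].
#' @export
applyChromaticAberration <- function(redChannel, beta,
                                     center = c(2500, 2500)) {
  stopifnot(is(redChannel, "LocalizationSet"), beta >= 0,
            length(center) == 2L)
  if (beta == 0) return(redChannel)
  initialize(redChannel, coords = cbind(
    x = redChannel@coords[, 1] + beta * (redChannel@coords[, 1] - center[1]),
    y = redChannel@coords[, 2] + beta * (redChannel@coords[, 2] - center[2])))
}

#' Simulate a full two-color SMLM experiment
#'
#' Composes the six generative stages in order: molecule placement,
#' stochastic labeling, blinking, Gaussian localization error, unspecific
#' labels and false-positive background, stage drift, and chromatic
#' aberration (red channel only). Deterministic given `seed`.
#'
#' The final coordinates are wrapped toroidally into the ROI, so the
#' simulated field is stationary on the torus the significance test uses.
#' This makes the observed pair and its toroidally shifted controls
#' exactly exchangeable under the null, which is what gives the test its
#' exact size; leaving boundary spill-over in place instead induces a
#' small systematic edge bias between data and controls.
#'
#' @param scenario A [Scenario-class].
#' @param seed Optional integer seed (session RNG state preserved).
#' @return List with elements `red` and `blue` ([LocalizationSet-class])
#'   and `truth` (matrix of ground-truth molecule positions, nm).
#' @examples
#' sc <- idealScenario(PatternSpec("oligomer", nMer = 2,
#'                                 moleculeDensity = 50),
#'                     roi = RegionOfInterest(0, 0, 2000, 2000))
#' sim <- simulateExperiment(sc, seed = 1)
#' nLocalizations(sim$red)
#' @export
simulateExperiment <- function(scenario, seed = NULL) {
  stopifnot(is(scenario, "Scenario"))
  .withSeed(seed, {
    roi <- scenario@roi
    truth <- placeMolecules(scenario@pattern, roi)
    labels <- assignLabels(truth, scenario@labeling)
    sigma <- scenario@artifacts@localizationErrorSigma
    channels <- list(
      red = applyLocalizationError(
        simulateBlinking(labels$red, scenario@blinkRed, roi, "red"), sigma),
      blue = applyLocalizationError(
        simulateBlinking(labels$blue, scenario@blinkBlue, roi, "blue"),
        sigma))
    channels <- addUnspecificAndBackground(channels, scenario@artifacts, roi,
                                           scenario@blinkRed,
                                           scenario@blinkBlue)
    channels <- applyDrift(channels, scenario@artifacts@driftTotal,
                           scenario@blinkRed@nFrames)
    channels$red <- applyChromaticAberration(
      channels$red, scenario@artifacts@aberrationBeta,
      scenario@artifacts@aberrationCenter)
    # close the torus: wrap boundary spill-over back into the ROI
    list(red = toroidalShift(channels$red, c(0, 0)),
         blue = toroidalShift(channels$blue, c(0, 0)),
         truth = truth)
  })
}
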