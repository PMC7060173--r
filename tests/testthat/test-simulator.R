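test_that("oligomer placement puts n molecules at each of floor(total/n)
           positions", {
  set.seed(51)
  roi <- smallRoi()  # 4 um^2 -> total = 300 at 75/um^2
  pat <- PatternSpec("oligomer", nMer = 2, moleculeDensity = 75)
  mol <- placeMolecules(pat, roi)
  expect_equal(nrow(mol), 300)
  expect_equal(nrow(unique(mol)), 150)
  expect_true(all(table(paste(mol[, 1], mol[, 2])) == 2))
  # total count is exactly nMer * floor(total / nMer)
  pat3 <- PatternSpec("oligomer", nMer = 3, moleculeDensity = 75)
  expect_equal(nrow(placeMolecules(pat3, roi)), 3 * (300 %/% 3))
})

test_that("fully loaded circular domains contain every molecule", {
  set.seed(52)
  roi <- RegionOfInterest(0, 0, 4000, 4000)
  pat <- PatternSpec("circular_domains", domainRadius = 100,
                     domainDensity = 10, fractionInDomains = 1,
                     moleculeDensity = 75)
  mol <- placeMolecules(pat, roi)
  # every molecule within domainRadius (on the torus) of some other
  # molecule's domain: verify via distance to nearest of many resamples
  expect_true(all(mol[, 1] >= 0 & mol[, 1] < 4000))
  expect_true(all(mol[, 2] >= 0 & mol[, 2] < 4000))
  # clustered: self-NN distances far below CSR expectation
  ls <- LocalizationSet(mol[, 1], mol[, 2], roi = roi)
  lambda <- nrow(mol) / roiArea(roi)
  expect_lt(median(selfNNDistances(ls)), 0.7 * sqrt(log(2) / (lambda * pi)))
})

test_that("per-domain occupancy averages total * fraction / nDomains", {
  set.seed(53)
  roi <- RegionOfInterest(0, 0, 10000, 10000)
  pat <- PatternSpec("circular_domains", domainRadius = 100,
                     domainDensity = 10, fractionInDomains = 0.6,
                     moleculeDensity = 75)
  nIn <- replicate(20, {
    mol <- placeMolecules(pat, roi)
    # in-domain molecules are the first block; outside count is exact
    nrow(mol) - round(7500 * 0.4)
  })
  # mean in-domain molecules per domain ~ 7500 * 0.6 / 1000 = 4.5
  perDomain <- mean(nIn) / 1000
  expect_lt(abs(perDomain - 4.5), 3 * sqrt(4.5 / (1000 * 20)))
})

test_that("outside-domain molecules avoid the domains", {
  set.seed(54)
  roi <- RegionOfInterest(0, 0, 4000, 4000)
  pat <- PatternSpec("circular_domains", domainRadius = 150,
                     domainDensity = 5, fractionInDomains = 0,
                     moleculeDensity = 50)
  expect_error(placeMolecules(PatternSpec("circular_domains",
                                          domainDensity = 0,
                                          fractionInDomains = 0.5), roi),
               "configuration error")
  mol <- placeMolecules(pat, roi)
  expect_equal(nrow(mol), 800)
})

test_that("the random pattern is distributionally a 1-mer pattern", {
  set.seed(55)
  roi <- RegionOfInterest(0, 0, 10000, 10000)
  a <- placeMolecules(PatternSpec("random", moleculeDensity = 75), roi)
  b <- placeMolecules(PatternSpec("oligomer", nMer = 1,
                                  moleculeDensity = 75), roi)
  nnA <- selfNNDistances(LocalizationSet(a[, 1], a[, 2], roi = roi))
  nnB <- selfNNDistances(LocalizationSet(b[, 1], b[, 2], roi = roi))
  expect_gt(suppressWarnings(ks.test(nnA, nnB))$p.value, 0.01)
})

test_that("CSR ground truth follows the 1 - exp(-lambda pi r^2) law", {
  set.seed(56)
  roi <- RegionOfInterest(0, 0, 10000, 10000)
  mol <- placeMolecules(PatternSpec("random", moleculeDensity = 75), roi)
  ls <- LocalizationSet(mol[, 1], mol[, 2], roi = roi)
  # inner queries only, so boundary censoring is negligible
  inner <- mol[, 1] > 500 & mol[, 1] < 9500 & mol[, 2] > 500 & mol[, 2] < 9500
  nn <- selfNNDistances(ls[inner])  # distance to nearest other molecule
  lambda <- (nrow(mol) - 1) / roiArea(roi)
  ks <- suppressWarnings(
    ks.test(nn, function(q) 1 - exp(-lambda * pi * q^2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("label assignment is binomial and exclusive", {
  set.seed(57)
  mol <- cbind(runif(10000), runif(10000))
  lab <- assignLabels(mol, LabelingSpec(efficiency = 1, ratio = 0.5))
  expect_equal(nrow(lab$red) + nrow(lab$blue), 10000)
  ci <- qbinom(c(0.005, 0.995), 10000, 0.5)
  expect_gte(nrow(lab$red), ci[1]); expect_lte(nrow(lab$red), ci[2])
  # 40% efficiency leaves ~40% labeled
  lab40 <- assignLabels(mol, LabelingSpec(efficiency = 0.4, ratio = 0.5))
  nLab <- nrow(lab40$red) + nrow(lab40$blue)
  ci40 <- qbinom(c(0.005, 0.995), 10000, 0.4)
  expect_gte(nLab, ci40[1]); expect_lte(nLab, ci40[2])
  # zero efficiency labels nothing
  lab0 <- assignLabels(mol, LabelingSpec(efficiency = 0))
  expect_equal(nrow(lab0$red) + nrow(lab0$blue), 0)
})

test_that("blinking produces >= 1 detection per label with valid frames", {
  roi <- smallRoi()
  set.seed(58)
  labels <- cbind(runif(5, 0, 2000), runif(5, 0, 2000))
  fixed3 <- BlinkModel("fixed", m = 3L)
  ls <- simulateBlinking(labels, fixed3, roi)
  expect_equal(nLocalizations(ls), 15L)
  # detections sit exactly at the label positions before error
  expect_true(all(coords(ls)[, 1] %in% labels[, 1]))
  labels2 <- cbind(runif(2000, 0, 2000), runif(2000, 0, 2000))
  for (bm in list(BlinkModel("lognormal"), BlinkModel("geometric", mean = 3),
                  BlinkModel("empirical",
                             table = c("1" = 0.5, "2" = 0.3, "5" = 0.2)),
                  BlinkModel("lognormal", frameAssignment = "burst"))) {
    ls2 <- simulateBlinking(labels2, bm, roi)
    expect_gte(nLocalizations(ls2), 2000L)
    expect_true(all(frames(ls2) >= 1L & frames(ls2) <= bm@nFrames))
  }
})

test_that("a tenfold meanlog gap gives a ~tenfold detection-count ratio", {
  set.seed(59)
  roi <- smallRoi()
  labels <- cbind(runif(4000, 0, 2000), runif(4000, 0, 2000))
  lo <- simulateBlinking(labels, BlinkModel("lognormal",
                                            meanlog = log(2), sdlog = 0.5),
                         roi)
  hi <- simulateBlinking(labels, BlinkModel("lognormal",
                                            meanlog = log(20), sdlog = 0.5),
                         roi)
  ratio <- nLocalizations(hi) / nLocalizations(lo)
  # ceiling inflates the small-count channel slightly, so allow a band
  expect_gt(ratio, 7); expect_lt(ratio, 11)
})

test_that("localization error has the requested spread and no correlation", {
  set.seed(60)
  roi <- smallRoi()
  ls <- randomSet(10000, roi)
  expect_identical(applyLocalizationError(ls, 0), ls)
  blurred <- applyLocalizationError(ls, 30)
  dx <- coords(blurred)[, 1] - coords(ls)[, 1]
  dy <- coords(blurred)[, 2] - coords(ls)[, 2]
  expect_lt(abs(sd(dx) - 30), 1)
  expect_lt(abs(sd(dy) - 30), 1)
  expect_lt(abs(cor(dx, dy)), 0.05)
})

test_that("unspecific labels and background are added at the stated rates", {
  set.seed(61)
  roi <- RegionOfInterest(0, 0, 10000, 10000)  # 100 um^2
  empty <- function(id) new("LocalizationSet", channelId = id,
                            coords = cbind(x = numeric(0), y = numeric(0)),
                            frames = integer(0), roi = roi)
  channels <- list(red = empty("red"), blue = empty("blue"))
  bm <- BlinkModel("fixed", m = 1L)
  art <- ArtifactSpec(localizationErrorSigma = 0,
                      unspecificLabelDensity = 5,
                      backgroundDensityRed = 1, backgroundDensityBlue = 2,
                      backgroundBlink = BlinkModel("fixed", m = 1L))
  counts <- replicate(30, {
    ch <- addUnspecificAndBackground(channels, art, roi, bm, bm)
    c(nLocalizations(ch$red), nLocalizations(ch$blue))
  })
  # red: Poisson(500) + Poisson(100); blue: Poisson(500) + Poisson(200)
  expect_lt(abs(mean(counts[1, ]) - 600), 3 * sqrt(600 / 30))
  expect_lt(abs(mean(counts[2, ]) - 700), 3 * sqrt(700 / 30))
  # densities 0: unchanged
  none <- addUnspecificAndBackground(channels, ArtifactSpec(), roi, bm, bm)
  expect_equal(nLocalizations(none$red), 0L)
})

test_that("drift displaces linearly in the frame index, both channels", {
  roi <- RegionOfInterest(0, 0, 10000, 10000)
  mk <- function(id) LocalizationSet(c(100, 100), c(100, 100),
                                     frames = c(5000L, 10000L),
                                     channelId = id, roi = roi)
  channels <- list(red = mk("red"), blue = mk("blue"))
  out <- applyDrift(channels, c(500, 0), 10000L)
  for (ch in out) {
    expect_equal(unname(coords(ch)[, 1]), c(350, 600))  # +250, +500
    expect_equal(unname(coords(ch)[, 2]), c(100, 100))
  }
  expect_identical(applyDrift(channels, c(0, 0), 10000L), channels)
})

test_that("chromatic aberration is the stated linear radial field", {
  roi <- RegionOfInterest(0, 0, 10000, 10000)
  red <- LocalizationSet(c(3500, 2500), c(2500, 2500), roi = roi)
  out <- applyChromaticAberration(red, 0.06, c(2500, 2500))
  expect_equal(unname(coords(out)[1, ]), c(3560, 2500))
  expect_equal(unname(coords(out)[2, ]), c(2500, 2500))  # fixed point
  expect_identical(applyChromaticAberration(red, 0), red)
})

test_that("simulateExperiment is deterministic given a seed and matches
           the preset parameter sets", {
  sc <- smallScenario()
  a <- simulateExperiment(sc, seed = 99)
  b <- simulateExperiment(sc, seed = 99)
  expect_identical(coords(a$red), coords(b$red))
  expect_identical(coords(a$blue), coords(b$blue))
  expect_identical(a$truth, b$truth)
  expect_identical(frames(a$red), frames(b$red))
  # ideal preset: full labeling, no artifacts
  ideal <- idealScenario()
  expect_equal(ideal@labeling@efficiency, 1)
  expect_equal(ideal@artifacts@unspecificLabelDensity, 0)
  expect_equal(ideal@artifacts@backgroundDensityRed, 0)
  # realistic preset: 40% labeling, 5/um^2 unspecific, 1 and 2 /um^2 bg
  real <- realisticScenario()
  expect_equal(real@labeling@efficiency, 0.4)
  expect_equal(real@artifacts@unspecificLabelDensity, 5)
  expect_equal(real@artifacts@backgroundDensityRed, 1)
  expect_equal(real@artifacts@backgroundDensityBlue, 2)
})

test_that("scenario YAML presets round-trip through the loader", {
  idealPath <- system.file("extdata/scenarios/ideal.yaml", package = "clasta")
  sc <- scenarioFromYAML(idealPath)
  expect_s4_class(sc, "Scenario")
  expect_equal(sc@pattern@moleculeDensity, 75)
  expect_equal(sc@labeling@efficiency, 1)
  expect_equal(roiArea(sc@roi) / 1e6, 100)
  realPath <- system.file("extdata/scenarios/realistic.yaml",
                          package = "clasta")
  scr <- scenarioFromYAML(realPath)
  expect_equal(scr@labeling@efficiency, 0.4)
  expect_equal(scr@artifacts@backgroundDensityBlue, 2)
})
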