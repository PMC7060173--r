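#' Estimate the sensitivity of the test for a scenario
#'
#' Runs `nSims` independent replicates of simulate-then-test and reports
#' the fraction rejected at level `alpha` (`sensitivity = tp / (tp + fn)`
#' for truly clustered scenarios; for null scenarios the same quantity is
#' the false-positive rate). Each replicate gets a counter-based sub-seed,
#' so identical `(seed, scenario, replicate index)` give identical
#' p-values regardless of execution order.
#'
#' @param scenario A [Scenario-class].
#' @param alpha Significance level (default 0.05).
#' @param nSims Number of replicates (the conventional figure-of-merit
#'   uses 100).
#' @param nControls Randomized controls per test (default 99).
#' @param seed Master integer seed.
#' @param statistic,k,rStar,rMax,direction Passed to [runClastaTest()].
#' @return A [PowerResult-class].
#' @export
estimateSensitivity <- function(scenario, alpha = 0.05, nSims = 100L,
                                nControls = 99L, seed = 1L,
                                statistic = "nn", k = 1L, rStar = 50,
                                rMax = "auto", direction = "clustering") {
  stopifnot(is(scenario, "Scenario"), nSims >= 1L)
  nSims <- as.integer(nSims)
  p <- vapply(seq_len(nSims), function(i) {
    .replicatePValue(scenario, .subSeed(seed, i), nControls,
                     statistic, k, rStar, rMax, direction)
  }, numeric(1))
  nRej <- sum(p <= alpha)
  new("PowerResult", scenario = scenario, alpha = alpha, nSims = nSims,
      nRejections = as.integer(nRej), sensitivity = nRej / nSims,
      pValues = p)
}

# one simulate-then-test replicate under a single sub-seed
.replicatePValue <- function(scenario, subSeed, nControls, statistic, k,
                             rStar, rMax, direction) {
  .withSeed(subSeed, {
    sim <- simulateExperiment(scenario)
    res <- runClastaTest(sim$red, sim$blue, statistic = statistic, k = k,
                         rStar = rStar, rMax = rMax, nControls = nControls,
                         direction = direction)
    res@pValue
  })
}

#' @rdname clasta-accessors
#' @export
setMethod("sensitivity", "PowerResult",
          function(object, ...) object@sensitivity)

#' @rdname clasta-accessors
#' @export
setMethod("pValues", "PowerResult", function(object, ...) object@pValues)

setMethod("show", "PowerResult", function(object) {
  se <- sqrt(object@sensitivity * (1 - object@sensitivity) /
               max(object@nSims, 1L))
  cat(sprintf("PowerResult: sensitivity %.3f (%d/%d rejected at alpha = %g, SE %.3f)\n",
              object@sensitivity, object@nRejections, object@nSims,
              object@alpha, se))
})

# named axes a grid can sweep; each entry rewrites one scenario field
.gridAxes <- list(
  molecule_density = function(sc, v) {
    sc@pattern@moleculeDensity <- v; sc },
  labeling_efficiency = function(sc, v) {
    sc@labeling@efficiency <- v; sc },
  labeling_ratio = function(sc, v) {
    sc@labeling@ratio <- v; sc },
  drift = function(sc, v) {
    sc@artifacts@driftTotal <- c(v, 0); sc },
  n_mer = function(sc, v) {
    sc@pattern@kind <- "oligomer"; sc@pattern@nMer <- as.integer(v); sc },
  domain_density = function(sc, v) {
    sc@pattern@domainDensity <- v; sc },
  fraction_in_domains = function(sc, v) {
    sc@pattern@fractionInDomains <- v; sc },
  domain_radius = function(sc, v) {
    sc@pattern@domainRadius <- v; sc },
  localization_error = function(sc, v) {
    sc@artifacts@localizationErrorSigma <- v; sc },
  aberration_beta = function(sc, v) {
    sc@artifacts@aberrationBeta <- v; sc })

#' Sweep one scenario parameter and estimate sensitivity at each value
#'
#' @param baseScenario The [Scenario-class] to modify.
#' @param axis Parameter to sweep; one of `molecule_density`,
#'   `labeling_efficiency`, `labeling_ratio`, `drift`, `n_mer`,
#'   `domain_density`, `fraction_in_domains`, `domain_radius`,
#'   `localization_error`, `aberration_beta`.
#' @param values Numeric vector of axis values.
#' @param alpha,nSims,nControls,seed,... Passed to
#'   [estimateSensitivity()]; each grid cell derives its own sub-seed from
#'   `seed` and its position, so results are reproducible and
#'   order-independent.
#' @return List with `table` (tidy `data.frame`: axis, value, sensitivity,
#'   nRejections, nSims) and `results` (list of [PowerResult-class]).
#' @export
runGrid <- function(baseScenario, axis, values, alpha = 0.05,
                    nSims = 100L, nControls = 99L, seed = 1L, ...) {
  if (!(axis %in% names(.gridAxes)))
    stop(sprintf("configuration error: unknown axis '%s'; choose one of %s",
                 axis, paste(names(.gridAxes), collapse = ", ")))
  modify <- .gridAxes[[axis]]
  results <- lapply(seq_along(values), function(j) {
    estimateSensitivity(modify(baseScenario, values[j]), alpha = alpha,
                        nSims = nSims, nControls = nControls,
                        seed = .subSeed(seed, 100000 + j), ...)
  })
  table <- data.frame(
    axis = axis, value = values,
    sensitivity = vapply(results, function(r) r@sensitivity, numeric(1)),
    nRejections = vapply(results, function(r) r@nRejections, integer(1)),
    nSims = nSims, alpha = alpha)
  list(table = table, results = results)
}
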