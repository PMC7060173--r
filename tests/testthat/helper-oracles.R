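# Brute-force oracles and small fixture builders shared across tests.

# O(n * m) exhaustive mean-of-k-nearest distances
bruteKnn <- function(qxy, rxy, k = 1L) {
  apply(qxy, 1L, function(q) {
    d <- sqrt((rxy[, 1] - q[1])^2 + (rxy[, 2] - q[2])^2)
    mean(sort(d)[seq_len(k)])
  })
}

# O(n * m) disc counts within radius rstar
bruteDiscCounts <- function(qxy, rxy, rstar) {
  apply(qxy, 1L, function(q) {
    sum((rxy[, 1] - q[1])^2 + (rxy[, 2] - q[2])^2 <= rstar^2)
  })
}

# exact integral of the step ecdf of `values` over [0, rmax], summed
# interval by interval over the knots (independent of the closed form)
stepIntegral <- function(values, rmax) {
  f <- stats::ecdf(values)
  kx <- sort(unique(c(0, stats::knots(f), rmax)))
  kx <- kx[kx <= rmax]
  heights <- f(kx)
  widths <- diff(c(kx, rmax))
  sum(heights * widths)
}

# uniform random localization set on an ROI
randomSet <- function(n, roi, channelId = "pts", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  LocalizationSet(runif(n, roi@xMin, roi@xMax),
                  runif(n, roi@yMin, roi@yMax),
                  channelId = channelId, roi = roi)
}

# small field used by fast unit tests: 2 x 2 um^2 at 75 molecules/um^2
smallRoi <- function() RegionOfInterest(0, 0, 2000, 2000)

smallScenario <- function(pattern = PatternSpec("random"), ...) {
  idealScenario(pattern = pattern, roi = smallRoi(), ...)
}

# nearest-neighbor distances within one set: the self-distance 0 makes the
# mean of the 2 smallest equal to half the true NN distance
selfNNDistances <- function(ls) {
  2 * crossNNDistances(ls, ls, k = 2L)
}
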