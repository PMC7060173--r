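test_that("toroidal shift wraps by modular arithmetic", {
  roi <- RegionOfInterest(0, 0, 10000, 10000)
  ls <- LocalizationSet(9000, 9000, roi = roi)
  expect_equal(unname(coords(toroidalShift(ls, c(2000, 3000)))[1, ]),
               c(1000, 2000))
  # zero shift is the identity
  set.seed(41)
  many <- randomSet(200, roi)
  expect_equal(coords(toroidalShift(many, c(0, 0))), coords(many))
})

test_that("toroidal shift keeps points in the ROI and preserves the
           multiset of coordinates modulo the period", {
  set.seed(42)
  roi <- RegionOfInterest(100, -50, 1100, 450)
  ls <- randomSet(300, roi)
  for (i in 1:10) {
    v <- runif(2, -3000, 3000)
    sh <- toroidalShift(ls, v)
    expect_true(all(coords(sh)[, 1] >= 100 & coords(sh)[, 1] < 1100))
    expect_true(all(coords(sh)[, 2] >= -50 & coords(sh)[, 2] < 450))
    expect_identical(frames(sh), frames(ls))
    # x mod width shifted back must reproduce the original multiset
    xBack <- (coords(sh)[, 1] - 100 - v[1]) %% 1000 + 100
    expect_equal(sort(xBack), sort(coords(ls)[, 1]), tolerance = 1e-9)
  }
})

test_that("perfect co-localization yields the minimal p-value", {
  set.seed(43)
  roi <- smallRoi()
  red <- randomSet(300, roi, "red")
  blue <- initialize(red, channelId = "blue")
  res <- runClastaTest(red, blue, nControls = 99, seed = 7)
  expect_equal(pValue(res), 0.01)
  expect_true(rejectNull(res))
  # with all distances zero, repulsion puts the data at the other extreme
  resRep <- runClastaTest(red, blue, nControls = 99, seed = 7,
                          direction = "repulsion")
  expect_equal(pValue(resRep), 1)
})

test_that("p-values sit on the 1/(N+1) grid and are seed-reproducible", {
  set.seed(44)
  roi <- smallRoi()
  red <- randomSet(250, roi, "red")
  blue <- randomSet(250, roi, "blue")
  for (N in c(3L, 19L, 99L)) {
    res <- runClastaTest(red, blue, nControls = N, seed = 11)
    expect_equal(pValue(res) * (N + 1), round(pValue(res) * (N + 1)))
    expect_gte(pValue(res), 1 / (N + 1))
    expect_lte(pValue(res), 1)
  }
  a <- runClastaTest(red, blue, nControls = 49, seed = 123)
  b <- runClastaTest(red, blue, nControls = 49, seed = 123)
  expect_identical(pValue(a), pValue(b))
  expect_identical(gControls(a), gControls(b))
  expect_identical(a@shiftVectors, b@shiftVectors)
})

test_that("clustering and repulsion ranks are complementary without ties", {
  set.seed(45)
  roi <- smallRoi()
  red <- randomSet(200, roi, "red")
  blue <- randomSet(200, roi, "blue")
  for (seed in c(3, 17, 91)) {
    pc <- pValue(runClastaTest(red, blue, nControls = 19, seed = seed))
    pr <- pValue(runClastaTest(red, blue, nControls = 19, seed = seed,
                               direction = "repulsion"))
    expect_equal(pc + pr, 21 / 20)
  }
})

test_that("auto r_max covers every distance over data and controls", {
  set.seed(46)
  roi <- smallRoi()
  red <- randomSet(150, roi, "red")
  blue <- randomSet(150, roi, "blue")
  res <- runClastaTest(red, blue, nControls = 19, seed = 2,
                       keepControls = TRUE)
  allMax <- max(vapply(c(list(res@dataValues), res@controlValues),
                       max, numeric(1)))
  expect_equal(rMaxUsed(res), allMax)
  # a user-supplied r_max overrides and caps the statistic
  res2 <- runClastaTest(red, blue, nControls = 19, seed = 2, rMax = 80)
  expect_equal(rMaxUsed(res2), 80)
  expect_lte(gData(res2), 80)
})

test_that("the knn and lcross statistic variants detect co-localization", {
  set.seed(47)
  roi <- smallRoi()
  red <- randomSet(300, roi, "red")
  # blue at red positions + small jitter: strong cross-channel correlation
  blue <- LocalizationSet(coords(red)[, 1] + rnorm(300, 0, 20),
                          coords(red)[, 2] + rnorm(300, 0, 20),
                          channelId = "blue", roi = roi)
  for (stat in c("knn", "lcross")) {
    res <- runClastaTest(red, blue, statistic = stat, k = 3L,
                         nControls = 99, seed = 5)
    expect_equal(pValue(res), 0.01, info = stat)
  }
})

test_that("the rejection rule is boundary-inclusive", {
  expect_true(rejectNull(0.01, 0.05))
  expect_true(rejectNull(0.05, 0.05))
  expect_false(rejectNull(0.06, 0.05))
})

test_that("mismatched ROIs and empty channels are configuration errors", {
  roiA <- RegionOfInterest(0, 0, 1000, 1000)
  roiB <- RegionOfInterest(0, 0, 2000, 2000)
  a <- randomSet(10, roiA, seed = 48)
  b <- randomSet(10, roiB, seed = 49)
  expect_error(runClastaTest(a, b), "same ROI")
})
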