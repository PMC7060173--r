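test_that("nearest-neighbor distances match hand-computed cases", {
  expect_equal(crossNNDistances(LocalizationSet(0, 0),
                                LocalizationSet(3, 4)), 5)
  # mean of the two smallest distances (1 and 2)
  q <- LocalizationSet(0, 0)
  r <- LocalizationSet(c(1, 0, 3), c(0, 2, 0))
  expect_equal(crossNNDistances(q, r, k = 2), 1.5)
  expect_error(crossNNDistances(q, r, k = 4), "insufficient data")
})

test_that("grid k-NN equals the exhaustive-scan oracle", {
  set.seed(31)
  roi <- RegionOfInterest(0, 0, 1000, 1000)
  q <- randomSet(200, roi, "q")
  r <- randomSet(300, roi, "r")
  for (k in c(1L, 3L, 5L, 10L)) {
    expect_equal(crossNNDistances(q, r, k = k),
                 bruteKnn(coords(q), coords(r), k), tolerance = 1e-12)
  }
  # queries far outside the reference bounding box
  qFar <- LocalizationSet(c(-5000, 9000), c(-5000, -2000), roi = roi)
  expect_equal(crossNNDistances(qFar, r, k = 3),
               bruteKnn(coords(qFar), coords(r), 3), tolerance = 1e-12)
})

test_that("k = 1 distances never exceed the distance to any named point", {
  set.seed(32)
  roi <- RegionOfInterest(0, 0, 500, 500)
  q <- randomSet(50, roi); r <- randomSet(80, roi)
  d <- crossNNDistances(q, r)
  probe <- coords(r)[17, ]
  dProbe <- sqrt((coords(q)[, 1] - probe[1])^2 +
                 (coords(q)[, 2] - probe[2])^2)
  expect_true(all(d <= dProbe + 1e-12))
})

test_that("k-NN distances are permutation- and translation-invariant", {
  set.seed(33)
  roi <- RegionOfInterest(0, 0, 800, 800)
  q <- randomSet(60, roi); r <- randomSet(90, roi)
  d0 <- crossNNDistances(q, r, k = 3)
  permQ <- sample(60); permR <- sample(90)
  dPerm <- crossNNDistances(q[permQ], r[permR], k = 3)
  expect_equal(dPerm, d0[permQ], tolerance = 1e-12)
  shift <- c(123.4, -56.7)
  qs <- LocalizationSet(coords(q)[, 1] + shift[1], coords(q)[, 2] + shift[2])
  rs <- LocalizationSet(coords(r)[, 1] + shift[1], coords(r)[, 2] + shift[2])
  expect_equal(crossNNDistances(qs, rs, k = 3), d0, tolerance = 1e-9)
})

test_that("empirical cdf steps and ties behave as a right-continuous ecdf", {
  f1 <- empiricalCdf(5.0)
  expect_equal(f1(4.9), 0); expect_equal(f1(5.0), 1)
  f2 <- empiricalCdf(c(1, 1, 3))
  expect_equal(f2(1), 2 / 3); expect_equal(f2(2), 2 / 3)
  expect_equal(f2(3), 1)
  expect_error(empiricalCdf(numeric(0)), "insufficient data")
})

test_that("ecdf of uniforms stays within the 99% DKW band", {
  set.seed(34)
  u <- runif(1000)
  f <- empiricalCdf(u)
  grid <- seq(0, 1, length.out = 2001)
  eps <- sqrt(log(2 / 0.01) / (2 * 1000))
  expect_lt(max(abs(f(grid) - grid)), eps)
})

test_that("cdf integral matches its closed form and exact step integration", {
  expect_equal(cdfIntegral(0, 1), 1)       # cdf is 1 on all of [0, 1]
  expect_equal(cdfIntegral(c(1, 1), 1), 0) # step at the right edge
  expect_equal(cdfIntegral(c(0.2, 0.6, 1.0), 1), 0.4)
  set.seed(35)
  for (i in 1:20) {
    v <- rexp(sample(1:200, 1), rate = 1 / 50)
    rmax <- runif(1, 1, 200)
    g <- cdfIntegral(v, rmax)
    expect_equal(g, stepIntegral(v, rmax), tolerance = 1e-9)
    expect_equal(g, rmax - mean(pmin(v, rmax)), tolerance = 1e-12)
    expect_gte(g, 0); expect_lte(g, rmax)
    # ecdf-object input agrees with raw values
    expect_equal(cdfIntegral(empiricalCdf(v), rmax), g, tolerance = 1e-9)
  }
})

test_that("cdf integral agrees with fine-grid Riemann integration", {
  set.seed(36)
  v <- runif(500, 0, 100); rmax <- 80
  ngrid <- 2^20
  grid <- (seq_len(ngrid) - 0.5) / ngrid * rmax
  riemann <- mean(empiricalCdf(v)(grid)) * rmax
  expect_equal(cdfIntegral(v, rmax), riemann, tolerance = 2 * rmax / ngrid)
})

test_that("lcross values follow the closed form and brute-force counts", {
  # empty disc
  q <- LocalizationSet(0, 0, roi = RegionOfInterest(0, 0, 1e4, 1e4))
  r <- LocalizationSet(5e3, 5e3, roi = RegionOfInterest(0, 0, 1e4, 1e4))
  expect_equal(lcrossValues(q, r, rStar = 50), 0)
  # one point in the disc, area 100 um^2, n_ref = 1
  r2 <- LocalizationSet(10, 0, roi = RegionOfInterest(0, 0, 1e4, 1e4))
  expect_equal(lcrossValues(q, r2, rStar = 50), sqrt(1e8 / pi),
               tolerance = 1e-9)
  # random instance: counts equal brute force for every point
  set.seed(37)
  roi <- RegionOfInterest(0, 0, 1000, 1000)
  qq <- randomSet(100, roi); rr <- randomSet(100, roi)
  got <- lcrossValues(qq, rr, rStar = 75)
  cnt <- bruteDiscCounts(coords(qq), coords(rr), 75)
  expect_equal(got, sqrt((roiArea(roi) / 100) * cnt / pi), tolerance = 1e-12)
})
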