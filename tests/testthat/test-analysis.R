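test_that("VOI statistics follow hand arithmetic", {
  m <- array(88, c(4, 4, 2)); mask <- array(TRUE, c(4, 4, 2))
  st <- voiStats(m, mask)
  expect_equal(st$mean, 88); expect_equal(st$sd, 0)
  expect_equal(st$min, 88); expect_equal(st$max, 88)
  two <- array(c(20, 30), c(2, 1, 1)); mk2 <- array(TRUE, c(2, 1, 1))
  st2 <- voiStats(two, mk2)
  expect_equal(st2$mean, 25)
  expect_equal(st2$sd, sqrt(50))        # sample convention (n - 1)
  expect_equal(st2$min, 20); expect_equal(st2$max, 30)
  stp <- voiStats(two, mk2, sdType = "population")
  expect_equal(stp$sd, 5)
  expect_error(voiStats(m, array(FALSE, c(4, 4, 2))), "empty VOI")
  # invalid voxels are excluded, not counted
  valid <- mk2; valid[2, 1, 1] <- FALSE
  expect_equal(voiStats(two, mk2, valid = valid)$n, 1L)
})

test_that("central-slice restriction centers on the occupied slab extent", {
  mask <- array(TRUE, c(2, 2, 10))
  out <- centralSliceMask(mask, 4)
  kept <- which(apply(out, 3, any))
  expect_identical(kept, 4:7)            # 0-based slices 3..6
  # full extent requested: identity
  expect_identical(centralSliceMask(mask, 10), mask)
  # odd leftover resolves toward the lower index
  m9 <- array(FALSE, c(2, 2, 12)); m9[, , 2:10] <- TRUE  # 9 occupied
  kept9 <- which(apply(centralSliceMask(m9, 4), 3, any))
  expect_identical(kept9, 4:7)
  # occupancy away from the volume center is respected
  mOff <- array(FALSE, c(2, 2, 15)); mOff[, , 10:15] <- TRUE
  keptOff <- which(apply(centralSliceMask(mOff, 4), 3, any))
  expect_identical(keptOff, 11:14)
  expect_error(centralSliceMask(mask, 0), "positive")
})

test_that("PDFF histogram conventions: conservation and closed last bin", {
  mask <- array(TRUE, c(5, 5, 2))
  all100 <- array(100, c(5, 5, 2))
  h <- pdffHistogram(all100, mask, binWidthPct = 1)
  expect_equal(h$count[100], 50L)
  expect_equal(sum(h$count), 50L)
  set.seed(2)
  m <- array(runif(50, 0, 100), c(5, 5, 2))
  h2 <- pdffHistogram(m, mask, binWidthPct = 5)
  expect_equal(sum(h2$count), 50L)
  expect_error(pdffHistogram(m, mask, binWidthPct = 3), "divide")
})

test_that("threshold volume matches a brute-force voxel count", {
  set.seed(4)
  m <- array(runif(200, 0, 100), c(10, 10, 2))
  mask <- array(runif(200) > 0.3, c(10, 10, 2))
  vv <- 0.002662
  for (t in c(0, 37.5, 50, 100)) {
    brute <- 0
    for (i in seq_along(m)) if (mask[i] && m[i] <= t) brute <- brute + 1
    expect_equal(volUnderThreshold(m, mask, t, vv), brute * vv)
  }
  # inclusive threshold: a voxel exactly at the cutoff counts
  one <- array(50, c(1, 1, 1)); mk1 <- array(TRUE, c(1, 1, 1))
  expect_equal(volUnderThreshold(one, mk1, 50, 1), 1)
  # all-fat map has zero volume below 0
  fat <- array(100, c(2, 2, 1)); mkf <- array(TRUE, c(2, 2, 1))
  expect_equal(volUnderThreshold(fat, mkf, 0, vv), 0)
})

test_that("volume curve is monotone, conserving, and histogram-consistent", {
  set.seed(6)
  m <- array(runif(300, 0, 100), c(10, 10, 3))
  mask <- array(runif(300) > 0.4, c(10, 10, 3))
  vv <- 0.001
  cv <- volumeCurve(m, mask, vv)
  expect_true(all(diff(cv@volumeCm3) >= 0))
  expect_equal(cv@volumeCm3[length(cv@volumeCm3)], cv@totalVolumeCm3)
  expect_equal(cv@totalVolumeCm3, sum(mask) * vv)
  # cross-module identity: curve at bin edges = cumulative histogram x volume
  h <- pdffHistogram(m, mask, binWidthPct = 1)
  atEdges <- cv@volumeCm3[match(h$hi, cv@thresholdsPct)]
  expect_equal(atEdges, cumsum(h$count) * vv)
})

test_that("aggregation over acquisitions computes mean/SD and envelopes", {
  mkStats <- function(mean) structure(list(mean = mean, sd = 0, min = mean,
                                           max = mean, n = 10,
                                           voxelVolumeCm3 = 1),
                                      class = "VOIStats")
  # four identical inputs collapse
  cv <- new("VolumeCurve", thresholdsPct = c(0, 50, 100),
            volumeCm3 = c(0, 0.3, 0.6), totalVolumeCm3 = 0.6)
  agg0 <- aggregateAcquisitions(rep(list(mkStats(50)), 4), rep(list(cv), 4))
  expect_equal(agg0$sdOfMeans, 0)
  expect_equal(agg0$curveMin, agg0$curveMax)
  # hand arithmetic on {51, 52, 74, 70}
  agg <- aggregateAcquisitions(lapply(c(51, 52, 74, 70), mkStats))
  expect_equal(agg$meanOfMeans, 61.75)
  expect_equal(agg$sdOfMeans, 11.954776, tolerance = 1e-6)
  # envelope ordering holds pointwise for heterogeneous curves
  cv2 <- new("VolumeCurve", thresholdsPct = c(0, 50, 100),
             volumeCm3 = c(0, 0.5, 0.6), totalVolumeCm3 = 0.6)
  agg2 <- aggregateAcquisitions(rep(list(mkStats(1)), 2), list(cv, cv2))
  expect_true(all(agg2$curveMin <= agg2$curveMean + 1e-12))
  expect_true(all(agg2$curveMean <= agg2$curveMax + 1e-12))
  # mismatched grids are rejected
  cv3 <- new("VolumeCurve", thresholdsPct = c(0, 100),
             volumeCm3 = c(0, 0.6), totalVolumeCm3 = 0.6)
  expect_error(aggregateAcquisitions(rep(list(mkStats(1)), 2),
                                     list(cv, cv3)), "mismatched")
  expect_error(aggregateAcquisitions(list(mkStats(1))), "2")
})
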