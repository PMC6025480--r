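test_that("experiment phantoms carry the right tubes and labels", {
  gt1 <- buildPhantom(experimentPhantomSpec(1, "small"), seed = 5)
  # exactly three codes present: background, BAT, perigonadal WAT
  codes <- sort(unique(as.vector(gt1@labels)))
  expect_identical(codes, c(0L, which(gt1@labelNames == "BAT"),
                            which(gt1@labelNames == "WAT_peri")))
  # experiment 3: three tubes with the graded compositions
  spec3 <- experimentPhantomSpec(3, "small")
  expect_length(spec3@tubes, 3L)
  expect_equal(spec3@tubes[[1]]@composition, c(BAT = 0.6, WAT_peri = 0.4))
  expect_equal(spec3@tubes[[2]]@composition, c(BAT = 0.4, WAT_peri = 0.6))
  expect_equal(spec3@tubes[[3]]@composition, c(WAT_sub = 1.0))
})

test_that("phantom build is deterministic per seed", {
  spec <- experimentPhantomSpec(1, "small")
  a <- buildPhantom(spec, seed = 11)
  b <- buildPhantom(spec, seed = 11)
  expect_identical(a@labels, b@labels)
  expect_identical(a@rhoF, b@rhoF)
  expect_identical(a@psi, b@psi)
  # pure tubes have seed-independent labels; the drawn fields must differ
  c <- buildPhantom(spec, seed = 12)
  expect_false(identical(a@rhoF, c@rhoF))
  spec3 <- experimentPhantomSpec(3, "small")
  expect_false(identical(buildPhantom(spec3, seed = 11)@labels,
                         buildPhantom(spec3, seed = 12)@labels))
})

test_that("packed volume fractions match the target within 1 pp", {
  spec <- experimentPhantomSpec(3, "small")
  tissues <- defaultTissueModels()
  for (seed in c(2, 9)) {
    gt <- buildPhantom(spec, tissues, seed = seed)
    for (ti in 1:2) {
      tube <- spec@tubes[[ti]]
      target <- tube@composition
      inTube <- gt@labels > 0L &
        tubeMaskOracle(gt, tube)
      lb <- gt@labels[inTube]
      for (nm in names(target)) {
        achieved <- mean(lb == which(gt@labelNames == nm))
        expect_lt(abs(achieved - target[[nm]]), 0.01)
      }
    }
  }
})

test_that("packMixture handles degenerate and layered cases", {
  coords <- as.matrix(expand.grid(x = seq(0.25, 10, 0.5),
                                  y = seq(0.25, 10, 0.5),
                                  z = seq(0.25, 5, 0.5)))
  lab <- packMixture(coords, c(WAT_peri = 1), 1.5, seed = 1,
                     fineSpacingMm = 0.5)
  expect_true(all(lab == 1L))
  expect_error(packMixture(coords, c(a = 0.5, b = 0.5), 0.2, seed = 1,
                           fineSpacingMm = 0.5), "clump")
  # layered packing splits along the axis
  lab2 <- packMixture(coords, c(a = 0.5, b = 0.5), 1.5, seed = 1,
                      fineSpacingMm = 0.5, packing = "layered", axis = "y")
  y1 <- coords[lab2 == 1L, "y"]
  y2 <- coords[lab2 == 2L, "y"]
  expect_lte(max(y1), min(y2))
})

test_that("larger clump scale produces larger contiguous pieces", {
  coords <- as.matrix(expand.grid(x = seq(0.15, 12, 0.3),
                                  y = seq(0.15, 12, 0.3),
                                  z = seq(0.15, 3, 0.3)))
  comp <- c(BAT = 0.6, WAT_peri = 0.4)
  sizes <- vapply(c(0.3, 1.5), function(scale) {
    lab <- packMixture(coords, comp, scale, seed = 3, fineSpacingMm = 0.3)
    # mean connected-component size of the BAT phase on the central slice
    d <- c(40, 40, 10)
    arr <- array(lab == 1L, dim = d)
    slice <- arr[, , 5]
    cc <- EBImage::bwlabel(slice * 1)
    mean(tabulate(cc[cc > 0]))
  }, numeric(1))
  expect_gt(sizes[2], sizes[1])
})

test_that("tissue field assignment reproduces the tissue distributions", {
  tissues <- defaultTissueModels()
  # zero variance: every cell exactly at the mean
  labs <- rep(3L, 500)  # WAT_peri
  tis0 <- tissues
  tis0$WAT_peri <- tissueModel("WAT_peri", 88, 0, 35, 0)
  f0 <- assignTissueFields(labs, tis0, seed = 4)
  expect_equal(pdffPercent(f0$rhoW, f0$rhoF), rep(88, 500))
  # BAT 23 +/- 6: sample mean over 1e4 cells within 0.5 pp
  labsB <- rep(2L, 10000)
  fB <- assignTissueFields(labsB, tissues, seed = 8)
  pd <- pdffPercent(fB$rhoW, fB$rhoF)
  expect_lt(abs(mean(pd) - 23), 0.5)
  expect_lt(abs(sd(pd) - 6), 0.5)
  # density conservation
  expect_equal(fB$rhoW + fB$rhoF,
               rep(tissues$BAT@totalDensity, 10000))
  expect_true(all(fB$r2s >= 0))
  expect_error(assignTissueFields(rep(9L, 5), tissues, 1), "missing tissue")
})

test_that("smooth field map respects amplitude and gradient bounds", {
  dims <- c(60, 60, 20); sp <- rep(0.5, 3); or <- c(0, 0, 0)
  zero <- smoothFieldMap(dims, sp, or,
                         defaultFieldMapParams(poly = c(0, 0, 0, 0),
                                               rippleHz = 0), seed = 1)
  expect_true(all(zero == 0))
  psi <- smoothFieldMap(dims, sp, or, defaultFieldMapParams(), seed = 1)
  expect_lte(max(abs(psi)), 60)
  # smoothness: finite-difference gradient below 5 Hz/mm along each axis
  d <- dims
  gx <- abs(psi[-1, , ] - psi[-d[1], , ]) / sp[1]
  gy <- abs(psi[, -1, ] - psi[, -d[2], ]) / sp[2]
  gz <- abs(psi[, , -1] - psi[, , -d[3]]) / sp[3]
  expect_lt(max(gx, gy, gz), 5)
})

test_that("ground-truth VOI mean of a pure tube matches its tissue model", {
  spec <- experimentPhantomSpec(1, "small")
  tissues <- defaultTissueModels()
  gt <- buildPhantom(spec, tissues, seed = 21)
  for (ti in 1:2) {
    tube <- spec@tubes[[ti]]
    m <- tubeMaskOracle(gt, tube) & gt@labels > 0L
    pd <- pdffPercent(gt@rhoW[m], gt@rhoF[m])
    tm <- tissues[[names(tube@composition)]]
    # expectation of the [0, 100]-truncated normal the cells are drawn from
    a <- (0 - tm@pdffMeanPct) / tm@pdffSdPct
    b <- (100 - tm@pdffMeanPct) / tm@pdffSdPct
    truncMean <- tm@pdffMeanPct + tm@pdffSdPct *
      (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
    se <- tm@pdffSdPct / sqrt(sum(m))
    expect_lt(abs(mean(pd) - truncMean), 3 * se + 0.05)
  }
})

test_that("phantom spec validity catches geometry errors", {
  tube <- tubeSpec(4, 30, c(10, 37.5, 20), composition = c(BAT = 1))
  overl <- tubeSpec(4, 30, c(12, 37.5, 20), composition = c(BAT = 1))
  expect_error(phantomSpec(tubes = list(tube, overl)), "overlap")
  outside <- tubeSpec(4, 30, c(54, 37.5, 20), composition = c(BAT = 1))
  expect_error(phantomSpec(tubes = list(outside)), "outside the box")
  expect_error(tubeSpec(4, 30, c(10, 37.5, 20),
                        composition = c(BAT = 0.7, WAT_peri = 0.2)),
               "sum to 1")
  expect_error(tubeSpec(1, 5, c(10, 10, 10), composition = c(BAT = 1),
                        analyzedVolumeCm3 = 1), "exceeds")
})
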