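test_that("constant grids give a flat profile equal to the constant", {
  grid <- discGrid(function(d) 7.5, extent = 30, px = 0.5)
  prof <- crossSectionProfiles(grid, c(0, 0))
  expect_true(all(abs(prof@meanIntensity - 7.5) < 1e-12))
  expect_equal(prof@distances[1], 0)
  expect_equal(diff(prof@distances), rep(0.5, length(prof@distances) - 1))
})

test_that("radially symmetric grids give near-identical sections", {
  f <- function(d) 10 * exp(-d^2 / (2 * 15^2))
  grid <- discGrid(f, extent = 30, px = 0.25)
  prof <- crossSectionProfiles(grid, c(0, 0), profileConfig(nSections = 36L))
  inner <- prof@distances <= 20
  spread <- apply(prof@sectionMatrix[, inner], 2,
                  function(x) diff(range(x, na.rm = TRUE)))
  expect_lt(max(spread), 1e-3 * 10)  # bilinear error at this pixel size
  expect_equal(prof@meanIntensity[inner], f(prof@distances[inner]),
               tolerance = 1e-3)
})

test_that("a doubled-intensity wedge lifts the mean profile by its angular
          fraction", {
  px <- 0.5; base <- 10
  xs <- seq(-30, 30, by = px)
  v <- outer(xs, xs, function(y, x) {
    az <- atan2(y, x)
    base * ifelse(az >= 0 & az < (36 / 180) * pi, 2, 1)
  })
  grid <- SurfaceGrid(v, px, c(-30, -30))
  prof <- crossSectionProfiles(grid, c(0, 0))
  mid <- prof@distances > 5 & prof@distances < 20
  ## 36/360 of all half-sections hit the wedge: mean = base * 1.1
  expect_equal(mean(prof@meanIntensity[mid]), base * 1.1,
               tolerance = 0.01)
  ## brute-force pixel-space oracle
  oracle <- radialAverageOracle(grid, 20)
  keep <- prof@distances > 5 & prof@distances < 20
  expect_equal(as.numeric(prof@meanIntensity[keep]),
               as.numeric(oracle[as.character(round(prof@distances[keep] /
                                                      px))]),
               tolerance = 0.02)
})

test_that("profile preconditions are enforced", {
  grid <- discGrid(function(d) 1 + d, extent = 10, px = 1)
  expect_error(crossSectionProfiles(grid, c(50, 0)), "outside")
  expect_error(profileConfig(nSections = 100L, sectionStep = 3.5),
               "360")
})

test_that("alignment pads shorter profiles with NA, never extrapolates", {
  mk <- function(n) new("RadialProfile", distances = (0:(n - 1)) * 1,
                        meanIntensity = rep(2, n),
                        sectionMatrix = matrix(2, 4, n), pixelSize = 1)
  single <- centerAndAlign(list(mk(30)))
  expect_equal(single[[1]]@meanIntensity, rep(2, 30))
  pair <- centerAndAlign(list(mk(30), mk(40)))
  expect_equal(length(pair[[1]]@distances), 40)
  expect_true(all(is.na(pair[[1]]@meanIntensity[31:40])))
  expect_equal(pair[[2]]@meanIntensity, rep(2, 40))
  short <- mk(30); short@pixelSize <- 2
  short@distances <- short@distances * 2
  expect_error(centerAndAlign(list(mk(30), short)), "pixel sizes")
})

test_that("threshold distance matches closed forms", {
  ## linear ramp I(d) = 10 (1 + d / 100): 120% of center at d = 20
  ramp <- discGrid(function(d) 10 * (1 + d / 100), extent = 40, px = 0.5)
  prof <- crossSectionProfiles(ramp, c(0, 0))
  td <- thresholdDistance(prof)
  expect_equal(td$distance, 20, tolerance = 0.1)
  expect_false(td$censored)

  ## inverted-Gaussian well: crossing at 20 sqrt(2 ln 1.25) = 13.36 um
  well <- discGrid(function(d) 5 * (2 - exp(-d^2 / (2 * 20^2))),
                   extent = 40, px = 0.5)
  td2 <- thresholdDistance(crossSectionProfiles(well, c(0, 0)))
  expect_equal(td2$distance, 20 * sqrt(2 * log(1.25)), tolerance = 0.1)

  ## constant profile never reaches 120%: censored at max distance
  flat <- discGrid(function(d) 3, extent = 20, px = 1)
  pf <- crossSectionProfiles(flat, c(0, 0))
  td3 <- thresholdDistance(pf)
  expect_true(td3$censored)
  expect_equal(td3$distance, max(pf@distances))

  zero <- discGrid(function(d) ifelse(d < 2, 0, 1), extent = 20, px = 1)
  expect_error(thresholdDistance(crossSectionProfiles(zero, c(0, 0))),
               "zero")
})

test_that("threshold distance is monotone in the threshold factor", {
  ramp <- discGrid(function(d) 10 * (1 + d / 100), extent = 40, px = 0.5)
  prof <- crossSectionProfiles(ramp, c(0, 0))
  ds <- vapply(c(1.05, 1.1, 1.2, 1.3),
               function(f) thresholdDistance(
                 prof, profileConfig(backgroundThresholdFactor = f))$distance,
               0)
  expect_true(all(diff(ds) >= 0))
})

test_that("planted central-minimum radius is recovered through the full
          pipeline to within one pixel", {
  est <- vapply(1:9, function(s) {
    spec <- samSpec(seed = s, dr5CentralMinFactor = 0.6,
                    dr5WedgeAmplitude = 0, noiseMultSigma = 0.1,
                    noiseAddSigma = 2)
    sam <- generateSam(spec, gridMode = "field")
    l1 <- layers(sam$nuclei) == "L1"
    fit <- fitSphere(nucleusCoords(sam$nuclei)[l1, , drop = FALSE])
    mc <- sphericalCenter(sam$truth@trueSeeds, fit)
    prof <- crossSectionProfiles(sam$grids$DR5, pCenter(mc)[1:2])
    thresholdDistance(prof, backgroundHalfwidth = 3)$distance
  }, 0)
  expect_lt(abs(median(est) - 10), 1)  # planted radius 10, 1 um pixels
})
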