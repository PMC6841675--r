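unitSphereFit <- function(r = 40) {
  fitSphere(r * rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                      c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
}

test_that("symmetric seeds at equal colatitude put P_center at the pole", {
  fit <- unitSphereFit()
  th <- pi / 6
  az <- c(0, 2 * pi / 3, 4 * pi / 3)
  seeds <- 40 * cbind(sin(th) * cos(az), sin(th) * sin(az),
                      rep(cos(th), 3))
  mc <- sphericalCenter(seeds, fit, summitHint = c(0, 0, 40))
  expect_equal(pCenter(mc), c(0, 0, 40), tolerance = 1e-9)
  expect_equal(centralAxis(mc)@direction, c(0, 0, 1), tolerance = 1e-9)
})

test_that("equatorial seeds: summit hint picks the north pole, antipode kept", {
  fit <- unitSphereFit()
  az <- c(0.3, 1.9, 4.0)
  seeds <- 40 * cbind(cos(az), sin(az), 0)
  mc <- sphericalCenter(seeds, fit, summitHint = c(0, 0, 40))
  expect_equal(pCenter(mc), c(0, 0, 40), tolerance = 1e-9)
  expect_equal(discardedCandidate(mc), c(0, 0, -40), tolerance = 1e-9)
})

test_that("P_center is geodesically equidistant to the projected seeds", {
  fit <- unitSphereFit()
  withr::with_seed(11, {
    for (i in 1:50) {
      seeds <- spherePoints(3, c(0, 0, 0), 40, seed = NULL) +
        matrix(rnorm(9, 0, 2), 3, 3)  # near, not on, the sphere
      mc <- sphericalCenter(seeds, fit, summitHint = c(0, 0, 40))
      gd <- apply(projectedSeeds(mc), 1, function(s)
        geodesicDistance(pCenter(mc), s, fit))
      expect_lt(diff(range(gd)), 1e-9 * sphereRadius(fit))
    }
  })
})

test_that("degenerate seed configurations error", {
  fit <- unitSphereFit()
  same <- rbind(c(0, 0, 40), c(0, 0, 40), c(40, 0, 0))
  expect_error(sphericalCenter(same, fit), "degenerate")
})

test_that("distance to the central axis matches the projection oracle", {
  ax <- Axis(c(0, 0, 0), c(0, 0, 1))
  expect_equal(distanceToAxis(c(0, 0, 17), ax), 0)
  expect_equal(distanceToAxis(c(3, 4, 17), ax), 5)
  withr::with_seed(3, {
    for (i in 1:20) {
      anchor <- rnorm(3, 0, 10); dir <- rnorm(3)
      axis <- Axis(anchor, dir)
      p <- rnorm(3, 0, 10)
      ## oracle: distance to the orthogonal projection onto the line
      tpar <- sum((p - anchor) * axis@direction)
      proj <- anchor + tpar * axis@direction
      expect_equal(distanceToAxis(p, axis), sqrt(sum((p - proj)^2)),
                   tolerance = 1e-12)
    }
  })
  ## matrix input agrees with pointwise evaluation
  pts <- matrix(rnorm(30), 10, 3)
  expect_equal(distanceToAxis(pts, ax),
               apply(pts, 1, distanceToAxis, axis = ax))
})

test_that("reporter-weighted center: point mass and symmetric cases", {
  fit <- unitSphereFit()
  coords <- 40 * rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0),
                       c(0, -1, 0))
  nt <- NucleusTable(letters[1:5], coords, rep("L1", 5),
                     cbind(CLV3 = c(0, 7, 0, 0, 0)))
  expect_equal(clv3Center(nt, "CLV3", fit), coords[2, ], tolerance = 1e-9)
  ## intensity symmetric about the pole -> the pole
  th <- pi / 5; az <- seq(0, 2 * pi, length.out = 9)[-9]
  ring <- 40 * cbind(sin(th) * cos(az), sin(th) * sin(az),
                     rep(cos(th), 8))
  nt2 <- NucleusTable(letters[1:8], ring, rep("L1", 8),
                      cbind(CLV3 = rep(3, 8)))
  expect_equal(clv3Center(nt2, "CLV3", fit), c(0, 0, 40),
               tolerance = 1e-9)
  expect_error(clv3Center(nt2, "DR5", fit), "not present")
  nt3 <- NucleusTable(letters[1:8], ring, rep("L1", 8),
                      cbind(CLV3 = rep(0, 8)))
  expect_error(clv3Center(nt3, "CLV3", fit), "zero")
})

test_that("estimated and reporter-derived centers agree within one cell
          diameter on nine synthetic meristems", {
  errs <- vapply(1:9, function(s) {
    sam <- generateSam(samSpec(seed = s), makeGrids = FALSE)
    l1 <- layers(sam$nuclei) == "L1"
    fit <- fitSphere(nucleusCoords(sam$nuclei)[l1, , drop = FALSE])
    mc <- sphericalCenter(sam$truth@trueSeeds, fit)
    cc <- clv3Center(sam$nuclei, "CLV3", fit)
    geodesicDistance(cc, pCenter(mc), fit)
  }, 0)
  expect_true(all(errs < 5))  # one cell diameter, all nine meristems
})
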