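## Synthetic meristem generator: a hemispherical dome of cells with planted
## stem-cell (central Gaussian) and auxin-output (central minimum + wedge
## maxima) reporter fields, fully determined by a SamSpec and its seed.

## Fibonacci lattice on a spherical cap (colatitude <= thetaMax). z is
## spaced uniformly over the cap (equal-area), azimuths advance by the
## golden angle, giving near-uniform geodesic spacing ~= `spacing`.
.capLattice <- function(radius, thetaMaxDeg, spacing) {
  zmin <- cos(.degToRad(thetaMaxDeg))
  area <- 2 * pi * radius^2 * (1 - zmin)
  n <- max(4L, as.integer(round(area / (sqrt(3) / 2 * spacing^2))))
  k <- seq_len(n)
  z <- 1 - (1 - zmin) * (k - 0.5) / n
  phi <- (k * pi * (3 - sqrt(5))) %% (2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(x = s * cos(phi), y = s * sin(phi), z = z)  # unit directions
}

#' Number of lattice cells implied by a SamSpec
#'
#' Per-layer cell counts of the Fibonacci cap lattice; the generator emits
#' exactly these counts (no silent drops).
#'
#' @param spec a [SamSpec-class].
#' @return Named integer vector, one count per layer (L1 outward-in).
#' @export
latticeCellCount <- function(spec) {
  radii <- spec@domeRadius - (0:spec@nLayers) * spec@cellDiameter
  radii <- radii[radii > spec@cellDiameter]
  counts <- vapply(radii, function(r)
    nrow(.capLattice(r, spec@summitColatitude, spec@cellDiameter)), 0L)
  names(counts) <- c("L1", "L2", rep("inner", 8L))[seq_along(counts)]
  counts
}

#' Generate a synthetic meristem with planted ground truth
#'
#' Places cell nuclei on a Fibonacci lattice over a spherical cap (L1 on
#' the dome sphere, optional sub-epidermal layers one cell diameter
#' deeper), plants a central stem-cell reporter field
#' `CLV3 = A exp(-g^2 / (2 sigma^2))` of geodesic distance `g` from the
#' true apex, and an auxin-output field `DR5` with a sharp central minimum
#' (scaled to `dr5CentralMinFactor` of baseline inside
#' `dr5CentralMinRadius`) and azimuthal wedge maxima at the primordium
#' positions. Intensity noise is `I * LogNormal(0, noiseMultSigma) +
#' Normal(0, noiseAddSigma)`, clipped at zero. The surface grids are the
#' top-view radial max-projection of the L1 intensities resampled onto
#' isotropic pixels.
#'
#' The sphere center is at the origin and the true apex at
#' `(0, 0, domeRadius)`; the true central axis is `+z`.
#'
#' @param spec a [SamSpec-class]; `spec@seed` fully determines the output.
#' @param makeGrids set `FALSE` to skip the surface grids (faster when only
#'   the nucleus table is needed).
#' @param gridMode `"cells"` (default): each pixel takes the intensity of
#'   its nearest L1 cell, i.e. the max-projection of the segmented per-cell
#'   means, carrying the granularity of the cell lattice. `"field"`: the
#'   planted analytic field is rasterized directly at pixel centers (with
#'   the same intensity noise per pixel), emulating an idealized,
#'   segmentation-free surface projection whose transitions are sharp at
#'   the pixel scale.
#' @return A list with elements `nuclei` ([NucleusTable-class]), `grids`
#'   (named list of [SurfaceGrid-class], one per channel, or `NULL`), and
#'   `truth` ([SamGroundTruth-class]).
#' @examples
#' sam <- generateSam(samSpec(seed = 1L), makeGrids = FALSE)
#' sam$nuclei
#' @export
generateSam <- function(spec, makeGrids = TRUE,
                        gridMode = c("cells", "field")) {
  stopifnot(is(spec, "SamSpec"))
  gridMode <- match.arg(gridMode)
  validObject(spec)
  withSeed(spec@seed, {
    R <- spec@domeRadius
    d <- spec@cellDiameter
    radii <- R - (0:spec@nLayers) * d
    radii <- radii[radii > d]
    layerName <- c("L1", "L2", rep("inner", 8L))[seq_along(radii)]

    dirs <- NULL; layer <- character(); shellR <- numeric()
    for (i in seq_along(radii)) {
      u <- .capLattice(radii[i], spec@summitColatitude, d)
      dirs <- rbind(dirs, u)
      layer <- c(layer, rep(layerName[i], nrow(u)))
      shellR <- c(shellR, rep(radii[i], nrow(u)))
    }
    n <- nrow(dirs)

    ## radial centroid jitter, truncated so L1 stays within d/4 of the
    ## true sphere
    jit <- pmin(pmax(rnorm(n, 0, spec@posJitterSigma), -d / 4), d / 4)
    if (spec@posJitterSigma == 0) jit <- rep(0, n)
    coords <- dirs * (shellR + jit)

    ## planted fields as functions of geodesic distance from the apex and
    ## azimuth (both from the unit directions, i.e. noise-free geometry)
    g <- R * acos(pmin(1, pmax(-1, dirs[, 3L])))
    az <- atan2(dirs[, 2L], dirs[, 1L]) * 180 / pi
    fields <- .samFields(spec, g, az)
    clv3 <- fields$clv3
    dr5 <- fields$dr5

    noisy <- function(x) {
      if (spec@noiseMultSigma > 0)
        x <- x * rlnorm(length(x), 0, spec@noiseMultSigma)
      if (spec@noiseAddSigma > 0)
        x <- x + rnorm(length(x), 0, spec@noiseAddSigma)
      pmax(x, 0)
    }
    intens <- cbind(CLV3 = noisy(clv3), DR5 = noisy(dr5))

    nuclei <- NucleusTable(sprintf("cell_%04d", seq_len(n)), coords,
                           layer, intens)

    thetaP <- .degToRad(spec@primordiumColatitude)
    azP <- .degToRad(spec@primordiumAzimuths)
    seeds <- R * cbind(sin(thetaP) * cos(azP), sin(thetaP) * sin(azP),
                       rep(cos(thetaP), length(azP)))
    truth <- new("SamGroundTruth", sphereCenter = c(0, 0, 0), radius = R,
                 trueCenter3d = c(0, 0, R), trueAxis = c(0, 0, 1),
                 trueSeeds = seeds, spec = spec)

    grids <- NULL
    if (makeGrids) {
      if (gridMode == "cells") {
        l1 <- layer == "L1"
        grids <- lapply(colnames(intens), function(ch)
          .rasterizeL1(coords[l1, 1:2, drop = FALSE], intens[l1, ch],
                       R, spec@gridPixelSize, d))
      } else {
        grids <- .rasterizeField(spec, noisy)
      }
      names(grids) <- c("CLV3", "DR5")
    }
    list(nuclei = nuclei, grids = grids, truth = truth)
  })
}

## planted reporter fields as functions of geodesic distance g (um) from
## the apex and azimuth (degrees)
.samFields <- function(spec, g, az) {
  clv3 <- spec@clv3Amplitude * exp(-g^2 / (2 * spec@clv3Sigma^2))
  wedgeSigma <- 15  # azimuthal width (degrees) of a primordium wedge
  wedge <- rep(0, length(g))
  for (a in spec@primordiumAzimuths) {
    da <- (az - a + 180) %% 360 - 180
    wedge <- wedge + exp(-da^2 / (2 * wedgeSigma^2))
  }
  dr5 <- spec@dr5Base *
    ifelse(g < spec@dr5CentralMinRadius, spec@dr5CentralMinFactor,
           1 + spec@dr5WedgeAmplitude * wedge)
  list(clv3 = clv3, dr5 = dr5)
}

## Direct rasterization of the planted fields at pixel centers (idealized
## surface projection). Pixels outside the dome footprint are 0.
.rasterizeField <- function(spec, noisy) {
  R <- spec@domeRadius
  px <- spec@gridPixelSize
  xs <- seq(-R, R, by = px)
  gx <- rep(xs, each = length(xs))
  gy <- rep(xs, times = length(xs))
  rho <- sqrt(gx^2 + gy^2)
  g <- R * asin(pmin(1, rho / R))       # planar radius -> geodesic
  az <- atan2(gy, gx) * 180 / pi
  fields <- .samFields(spec, g, az)
  inside <- rho <= R * sin(.degToRad(spec@summitColatitude))
  lapply(fields[c("clv3", "dr5")], function(v) {
    v <- noisy(v)
    v[!inside] <- 0
    SurfaceGrid(matrix(v, length(xs), length(xs)), px, c(-R, -R))
  })
}

## Top-view rasterization: each pixel takes the intensity of its nearest L1
## cell in the xy-plane (a Voronoi raster, i.e. the radial max-projection of
## per-cell mean intensities); pixels farther than one cell diameter from
## every cell are outside the dome footprint and set to 0.
.rasterizeL1 <- function(xy, values, radius, px, cellDiameter) {
  xs <- seq(-radius, radius, by = px)
  gx <- rep(xs, each = length(xs))   # column-major: y varies fastest
  gy <- rep(xs, times = length(xs))
  d2 <- outer(gx, xy[, 1L], "-")^2 + outer(gy, xy[, 2L], "-")^2
  nn <- max.col(-d2, ties.method = "first")
  val <- values[nn]
  val[sqrt(d2[cbind(seq_along(nn), nn)]) > cellDiameter] <- 0
  SurfaceGrid(matrix(val, nrow = length(xs), ncol = length(xs)),
              pixelSize = px, origin = c(-radius, -radius))
}
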