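## Rotated cross-section profiles, profile alignment and the
## threshold-distance ("central minimum size") metric.

## vectorized bilinear interpolation on a SurfaceGrid; xs/ys in um.
## Returns NA outside the grid.
.bilinear <- function(grid, xs, ys) {
  px <- grid@pixelSize
  v <- grid@values
  cj <- (xs - grid@origin[1L]) / px  # 0-based column coordinate
  ri <- (ys - grid@origin[2L]) / px  # 0-based row coordinate
  nr <- nrow(v); nc <- ncol(v)
  ok <- cj >= 0 & cj <= nc - 1 & ri >= 0 & ri <= nr - 1
  out <- rep(NA_real_, length(xs))
  if (!any(ok)) return(out)
  cj <- cj[ok]; ri <- ri[ok]
  j0 <- pmin(floor(cj), nc - 2); j0[j0 < 0] <- 0
  i0 <- pmin(floor(ri), nr - 2); i0[i0 < 0] <- 0
  tx <- cj - j0; ty <- ri - i0
  i0 <- i0 + 1L; j0 <- j0 + 1L  # to 1-based
  out[ok] <-
    v[cbind(i0, j0)] * (1 - tx) * (1 - ty) +
    v[cbind(i0, j0 + 1L)] * tx * (1 - ty) +
    v[cbind(i0 + 1L, j0)] * (1 - tx) * ty +
    v[cbind(i0 + 1L, j0 + 1L)] * tx * ty
  out
}

#' Rotated cross-section intensity profiles around a center
#'
#' Samples the surface grid by bilinear interpolation along `nSections`
#' lines through `center2d`, rotated successively by `sectionStep` degrees
#' (defaults: 100 sections, 3.6 degrees), at one-pixel spacing out to the
#' grid edge. Signed positions along each line are folded to radial
#' distance and all samples are averaged into one mean intensity per
#' distance bin (bin width = one pixel).
#'
#' @param grid a [SurfaceGrid-class] (isotropic pixels).
#' @param center2d um coordinates (x, y) of the center; must lie inside
#'   the grid.
#' @param cfg a [ProfileConfig-class].
#' @return A [RadialProfile-class]; its `sectionMatrix` keeps the
#'   per-section profiles (section x distance bin) for audit.
#' @export
crossSectionProfiles <- function(grid, center2d, cfg = profileConfig()) {
  stopifnot(is(grid, "SurfaceGrid"), is(cfg, "ProfileConfig"))
  validObject(cfg)
  px <- grid@pixelSize
  xmax <- grid@origin[1L] + (ncol(grid@values) - 1L) * px
  ymax <- grid@origin[2L] + (nrow(grid@values) - 1L) * px
  cx <- center2d[1L]; cy <- center2d[2L]
  if (cx < grid@origin[1L] || cx > xmax || cy < grid@origin[2L] || cy > ymax)
    stop("'center2d' lies outside the grid")

  tmax <- sqrt((xmax - grid@origin[1L])^2 + (ymax - grid@origin[2L])^2)
  tvals <- seq(-floor(tmax / px), floor(tmax / px)) * px
  bins <- abs(round(tvals / px)) + 1L  # distance-bin index per sample
  nb <- max(bins)
  angles <- .degToRad((seq_len(cfg@nSections) - 1L) * cfg@sectionStep)

  secmat <- matrix(NA_real_, cfg@nSections, nb)
  sums <- counts <- rep(0, nb)
  for (k in seq_len(cfg@nSections)) {
    vals <- .bilinear(grid, cx + tvals * cos(angles[k]),
                      cy + tvals * sin(angles[k]))
    ok <- !is.na(vals)
    if (!any(ok)) next
    s <- vapply(split(vals[ok], bins[ok]), sum, 0)
    cnt <- vapply(split(vals[ok], bins[ok]), length, 0L)
    idx <- as.integer(names(s))
    secmat[k, idx] <- s / cnt
    sums[idx] <- sums[idx] + s
    counts[idx] <- counts[idx] + cnt
  }
  keep <- counts > 0
  lastKeep <- max(which(keep))
  mi <- ifelse(counts > 0, sums / counts, NA_real_)[seq_len(lastKeep)]
  new("RadialProfile", distances = (seq_len(lastKeep) - 1L) * px,
      meanIntensity = mi,
      sectionMatrix = secmat[, seq_len(lastKeep), drop = FALSE],
      pixelSize = px)
}

#' Align radial profiles onto a common distance grid
#'
#' Profiles (which all start at distance 0 and share one pixel size) are
#' padded with `NA` to the longest profile; values are never extrapolated.
#'
#' @param profiles list of [RadialProfile-class] with a common pixel size.
#' @return List of aligned [RadialProfile-class] objects of equal length.
#' @export
centerAndAlign <- function(profiles) {
  if (!length(profiles)) stop("need at least one profile")
  pxs <- vapply(profiles, function(p) p@pixelSize, 0)
  if (diff(range(pxs)) > 1e-12)
    stop("profiles have mixed pixel sizes: ",
         paste(unique(signif(pxs, 6)), collapse = ", "))
  nb <- max(vapply(profiles, function(p) length(p@distances), 0L))
  px <- pxs[1L]
  lapply(profiles, function(p) {
    pad <- nb - length(p@distances)
    if (pad == 0L) return(p)
    new("RadialProfile", distances = (seq_len(nb) - 1L) * px,
        meanIntensity = c(p@meanIntensity, rep(NA_real_, pad)),
        sectionMatrix = cbind(p@sectionMatrix,
                              matrix(NA_real_, nrow(p@sectionMatrix), pad)),
        pixelSize = px)
  })
}

#' Distance at which the signal reaches a multiple of the center background
#'
#' The center background is the intensity of the distance-0 bin of the
#' averaged radial profile. The function returns the smallest distance at
#' which the mean intensity first reaches
#' `backgroundThresholdFactor * background` (linear interpolation between
#' bins). If the threshold is never reached the maximal measured distance
#' is returned, flagged censored. This is the metric used for the size of
#' a central signal minimum (in um).
#'
#' @param profile a [RadialProfile-class].
#' @param cfg a [ProfileConfig-class] (uses `backgroundThresholdFactor`).
#' @param backgroundHalfwidth um; with the default 0 the background is the
#'   distance-0 bin alone, a positive value averages all bins within that
#'   distance (more robust when single bins are noisy).
#' @return List with `distance` (um), `censored` (logical), `background`
#'   and `threshold` intensities.
#' @export
thresholdDistance <- function(profile, cfg = profileConfig(),
                              backgroundHalfwidth = 0) {
  stopifnot(is(profile, "RadialProfile"))
  m <- profile@meanIntensity
  d <- profile@distances
  if (!length(m)) stop("empty profile")
  bg <- if (backgroundHalfwidth > 0)
    mean(m[d <= backgroundHalfwidth], na.rm = TRUE) else m[1L]
  if (!is.finite(bg) || bg == 0)
    stop("center background signal is zero: threshold ratio undefined")
  thr <- cfg@backgroundThresholdFactor * bg
  ok <- which(is.finite(m))
  m <- m[ok]; d <- d[ok]
  hit <- which(m >= thr)
  if (!length(hit))
    return(list(distance = d[length(d)], censored = TRUE,
                background = bg, threshold = thr))
  i <- hit[1L]
  dist <- if (i == 1L) d[1L] else
    d[i - 1L] + (thr - m[i - 1L]) / (m[i] - m[i - 1L]) * (d[i] - d[i - 1L])
  list(distance = dist, censored = FALSE, background = bg, threshold = thr)
}

#' Mean intensity of a profile within the central window
#'
#' @param profile a [RadialProfile-class].
#' @param halfwidth window half-width in um (default 12.5).
#' @return Mean intensity over distance bins `<= halfwidth`.
#' @export
centralMean <- function(profile, halfwidth = 12.5) {
  sel <- profile@distances <= halfwidth & is.finite(profile@meanIntensity)
  if (!any(sel)) stop("no profile bins within the central window")
  mean(profile@meanIntensity[sel])
}
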