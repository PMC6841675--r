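## Meristem-center geometry: least-squares sphere fit through L1 nuclei,
## projection onto the sphere, the three-seed spherical circumcenter
## (spherical Voronoi vertex) and distances to the central axis.

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

## great-circle distance between two points near a sphere (both are first
## radially normalized); used for all on-sphere distances
.geodesic <- function(p, q, center, radius) {
  u <- (p - center) / sqrt(sum((p - center)^2))
  v <- (q - center) / sqrt(sum((q - center)^2))
  radius * acos(min(1, max(-1, sum(u * v))))
}

#' Geodesic (great-circle) distance on a fitted sphere
#'
#' @param p,q 3D points (radially projected onto the sphere first).
#' @param fit a [SphereFit-class].
#' @return Distance in um along the sphere surface.
#' @export
geodesicDistance <- function(p, q, fit) {
  .geodesic(as.numeric(p), as.numeric(q), fit@center, fit@radius)
}

#' Fit a sphere to 3D points by least squares
#'
#' Solves the algebraic (linearized) least-squares problem: with
#' `|p|^2 = 2 c . p + (r^2 - |c|^2)`, the center and radius follow from one
#' linear solve. With `refine = TRUE` (default) a single Gauss-Newton step
#' on the geometric residuals `|p - c| - r` follows; the reported RMS
#' residual is always geometric.
#'
#' @param points n x 3 matrix (or data.frame) of points, n >= 4.
#' @param refine apply the Gauss-Newton refinement step.
#' @return A [SphereFit-class].
#' @examples
#' pts <- rbind(c(40, 0, 0), c(-40, 0, 0), c(0, 40, 0),
#'              c(0, -40, 0), c(0, 0, 40), c(0, 0, -40))
#' fitSphere(pts)
#' @export
fitSphere <- function(points, refine = TRUE) {
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3L) stop("'points' must have three columns (x, y, z)")
  if (!all(is.finite(pts))) stop("'points' must be finite")
  n <- nrow(pts)
  if (n < 4L) stop("sphere fitting needs at least 4 points, got ", n)
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  qrA <- qr(A)
  if (qrA$rank < 4L)
    stop("degenerate point configuration: points are coplanar ",
         "(design-matrix rank ", qrA$rank, " < 4)")
  sol <- qr.coef(qrA, b)
  center <- sol[1:3]
  r2 <- sol[4L] + sum(center^2)
  if (r2 <= 0) stop("degenerate point configuration: non-positive radius")
  radius <- sqrt(r2)
  if (refine) {
    d <- sqrt(rowSums(sweep(pts, 2L, center)^2))
    if (all(d > 0)) {
      J <- cbind(-sweep(pts, 2L, center) / d, -1)
      delta <- tryCatch(qr.coef(qr(J), -(d - radius)),
                        error = function(e) rep(0, 4L))
      if (all(is.finite(delta))) {
        center <- center + delta[1:3]
        radius <- radius + delta[4L]
      }
    }
  }
  d <- sqrt(rowSums(sweep(pts, 2L, center)^2))
  new("SphereFit", center = as.numeric(center), radius = radius,
      rmsResidual = sqrt(mean((d - radius)^2)), nPointsUsed = n,
      pointsCentroid = as.numeric(colMeans(pts)))
}

#' Radially project a point onto a fitted sphere
#'
#' @param point 3D point (must differ from the sphere center).
#' @param fit a [SphereFit-class].
#' @return The point `center + r * (point - center) / |point - center|`.
#' @export
projectToSphere <- function(point, fit) {
  v <- as.numeric(point) - fit@center
  nv <- sqrt(sum(v^2))
  if (nv == 0)
    stop("cannot project the sphere center itself: direction undefined")
  fit@center + fit@radius * v / nv
}

#' Meristem center from three primordium seeds (spherical Voronoi vertex)
#'
#' Projects the three seed points onto the fitted sphere and computes the
#' two antipodal spherical circumcenters (the normalized cross product of
#' the two chord-difference vectors, scaled to the sphere). The candidate
#' closer to `summitHint` becomes `P_center` -- the point equidistant to
#' all three projected seeds and the vertex of their spherical Voronoi
#' tessellation; the antipodal solution is retained for audit. The central
#' axis runs from the sphere center through `P_center`.
#'
#' @param seeds 3 x 3 matrix of seed points (rows), picked close to the
#'   sphere surface; they are always projected first.
#' @param fit a [SphereFit-class].
#' @param summitHint 3D point used to resolve the antipodal ambiguity;
#'   defaults to the centroid of the fitted points projected onto the
#'   sphere (the dome summit).
#' @return A [MeristemCenter-class].
#' @examples
#' fit <- fitSphere(rbind(c(40, 0, 0), c(-40, 0, 0), c(0, 40, 0),
#'                        c(0, -40, 0), c(0, 0, 40), c(0, 0, -40)))
#' seeds <- 40 * rbind(c(sin(pi / 6), 0, cos(pi / 6)),
#'                     c(-sin(pi / 6) / 2,  sin(pi / 6) * sqrt(3) / 2, cos(pi / 6)),
#'                     c(-sin(pi / 6) / 2, -sin(pi / 6) * sqrt(3) / 2, cos(pi / 6)))
#' pCenter(sphericalCenter(seeds, fit, summitHint = c(0, 0, 40)))
#' @export
sphericalCenter <- function(seeds, fit, summitHint = NULL) {
  seeds <- as.matrix(seeds)
  if (!all(dim(seeds) == c(3L, 3L)))
    stop("'seeds' must be a 3 x 3 matrix (one seed per row)")
  proj <- t(apply(seeds, 1L, projectToSphere, fit = fit))
  v1 <- proj[2L, ] - proj[1L, ]
  v2 <- proj[3L, ] - proj[1L, ]
  nrm <- .cross3(v1, v2)
  nn <- sqrt(sum(nrm^2))
  if (nn < 1e-9 * fit@radius^2)
    stop("degenerate seeds: projections are coincident or collinear ",
         "on the sphere")
  nrm <- nrm / nn
  cand1 <- fit@center + fit@radius * nrm
  cand2 <- fit@center - fit@radius * nrm
  if (is.null(summitHint)) summitHint <- fit@pointsCentroid
  summitHint <- projectToSphere(summitHint, fit)
  d1 <- sum((cand1 - summitHint)^2)
  d2 <- sum((cand2 - summitHint)^2)
  pc <- if (d1 <= d2) cand1 else cand2
  other <- if (d1 <= d2) cand2 else cand1
  new("MeristemCenter", pCenter = pc, seedsProjected = proj,
      axis = Axis(fit@center, pc - fit@center),
      candidateDiscarded = other, fit = fit)
}

#' Distance from a point to a line (the central axis)
#'
#' @param point 3D point (or n x 3 matrix of points).
#' @param axis an [Axis-class].
#' @return Perpendicular distance(s) `|(point - anchor) x direction|` in um.
#' @export
distanceToAxis <- function(point, axis) {
  if (is.matrix(point)) {
    v <- sweep(point, 2L, axis@anchor)
    d <- axis@direction
    cx <- cbind(v[, 2L] * d[3L] - v[, 3L] * d[2L],
                v[, 3L] * d[1L] - v[, 1L] * d[3L],
                v[, 1L] * d[2L] - v[, 2L] * d[1L])
    sqrt(rowSums(cx^2))
  } else {
    sqrt(sum(.cross3(as.numeric(point) - axis@anchor, axis@direction)^2))
  }
}

#' Reference center from a stem-cell reporter channel
#'
#' The intensity-weighted centroid of the L1 cell positions, projected onto
#' the fitted sphere. Used to validate the geometric `P_center` against the
#' center defined by stem-cell reporter expression.
#'
#' @param cells a [NucleusTable-class].
#' @param channel name of the reporter channel.
#' @param fit a [SphereFit-class].
#' @return A 3D point on the sphere surface.
#' @export
clv3Center <- function(cells, channel, fit) {
  if (!channel %in% colnames(cells@intensities))
    stop("channel '", channel, "' not present in the nucleus table")
  l1 <- cells@layer == "L1"
  w <- cells@intensities[l1, channel]
  if (sum(w) <= 0)
    stop("total '", channel, "' intensity in L1 is zero: centroid undefined")
  centroid <- colSums(cells@coords[l1, , drop = FALSE] * w) / sum(w)
  projectToSphere(centroid, fit)
}
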