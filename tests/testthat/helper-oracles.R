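## Shared fixtures and independent oracles, built in code.

library(GenomicRanges)

## points on a sphere with optional radial Gaussian noise (sigma in um)
spherePoints <- function(n, center, radius, sigma = 0, seed = NULL) {
  gen <- function() {
    u <- matrix(rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    r <- if (sigma > 0) radius + rnorm(n, 0, sigma) else rep(radius, n)
    matrix(center, n, 3, byrow = TRUE) + r * u
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

## a random rigid transform (rotation matrix + translation)
randomRigid <- function(seed) {
  withr::with_seed(seed, {
    M <- matrix(rnorm(9), 3, 3)
    Q <- qr.Q(qr(M))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    list(R = Q, t = rnorm(3, 0, 20))
  })
}
applyRigid <- function(pts, rg) {
  if (is.matrix(pts)) sweep(pts %*% t(rg$R), 2, -rg$t)
  else as.numeric(rg$R %*% pts + rg$t)
}

## radially symmetric / analytic disc grids (fun maps distance -> value)
discGrid <- function(fun, extent, px) {
  xs <- seq(-extent, extent, by = px)
  d <- sqrt(outer(xs^2, xs^2, "+"))
  vals <- fun(d)
  if (length(vals) == 1L) vals <- array(vals, dim(d))
  SurfaceGrid(matrix(vals, nrow(d)), px, c(-extent, -extent))
}

## brute-force pixel-space radial average (oracle for cross-section means)
radialAverageOracle <- function(grid, maxDist) {
  px <- pixelSize(grid)
  v <- gridValues(grid)
  xs <- gridOrigin(grid)[1] + (seq_len(ncol(v)) - 1) * px
  ys <- gridOrigin(grid)[2] + (seq_len(nrow(v)) - 1) * px
  d <- sqrt(outer(ys^2, xs^2, "+"))
  bin <- round(d / px)
  keep <- bin * px <= maxDist
  tapply(v[keep], bin[keep], mean)
}

## Nadaraya-Watson by explicit loops (independent of the matrix path)
nwOracle <- function(x, y, h, at) {
  vapply(at, function(a) {
    w <- exp(-0.5 * ((a - x) / h)^2)
    sum(w * y) / sum(w)
  }, 0)
}

## Fisher two-sided p by full enumeration over tables with fixed margins,
## probabilities from products of binomial coefficients
fisherEnumOracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  denom <- choose(n, c1)
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x)
    choose(r1, x) * choose(r2, c1 - x) / denom, 0)
  pObs <- choose(r1, a) * choose(r2, c1 - a) / denom
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

## per-base boolean-array reduction oracle
reduceOracle <- function(starts, ends, genomeLen) {
  covered <- logical(genomeLen)
  for (i in seq_along(starts)) covered[starts[i]:ends[i]] <- TRUE
  r <- rle(covered)
  stops <- cumsum(r$lengths)
  begins <- stops - r$lengths + 1L
  keep <- r$values
  list(starts = begins[keep], ends = stops[keep],
       coveredBases = sum(covered))
}

## random interval set on one chromosome
randomIntervals <- function(n, genomeLen, maxw = 40, seed = 1) {
  withr::with_seed(seed, {
    s <- sample.int(genomeLen - maxw, n, replace = TRUE)
    w <- sample.int(maxw, n, replace = TRUE)
    GRanges("chr1", IRanges(s, s + w - 1L))
  })
}

## a minimal single-gene GeneModels fixture on the + or - strand
oneGeneModels <- function(start = 5001L, end = 8000L, strand = "+",
                          withFeatures = FALSE) {
  g <- GRanges("chr1", IRanges(start, end), strand = strand,
               gene_id = "g1")
  if (!withFeatures) return(geneModels(g))
  u <- 300L
  f <- GRanges("chr1",
               IRanges(c(start, start + u, end - 2L * u + 1L, end - u + 1L),
                       c(start + u - 1L, start + 2L * u - 1L,
                         end - u, end)),
               type = c("five_prime_UTR", "exon", "exon",
                        "three_prime_UTR"),
               gene_id = "g1")
  if (strand == "-")
    f$type[c(1L, 4L)] <- c("three_prime_UTR", "five_prime_UTR")
  geneModels(g, f)
}
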