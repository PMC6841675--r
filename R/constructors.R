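## User-facing constructors with defaults, plus accessors and show methods.

#' Construct a NucleusTable
#'
#' @param cellId character vector of unique cell ids.
#' @param coords n x 3 numeric matrix (or data.frame) of centroids in um.
#' @param layer layer labels (`"L1"`, `"L2"`, `"inner"`).
#' @param intensities n x channels numeric matrix with channel column names
#'   (may have zero columns).
#' @return A [NucleusTable-class].
#' @examples
#' nt <- NucleusTable(c("a", "b", "c", "d"),
#'                    cbind(x = c(40, -40, 0, 0), y = c(0, 0, 40, -40),
#'                          z = c(0, 0, 0, 0)),
#'                    layer = rep("L1", 4),
#'                    intensities = cbind(CLV3 = c(1, 2, 3, 4)))
#' nCells(nt)
#' @export
NucleusTable <- function(cellId, coords, layer,
                         intensities = matrix(numeric(), length(cellId), 0)) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y", "z")
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  new("NucleusTable", cellId = as.character(cellId), coords = coords,
      layer = as.character(layer), intensities = intensities)
}

#' @describeIn NucleusTable number of cells.
#' @param x a `NucleusTable`.
#' @export
nCells <- function(x) length(x@cellId)

#' @describeIn NucleusTable cell identifiers.
#' @export
cellIds <- function(x) x@cellId

#' @describeIn NucleusTable n x 3 centroid matrix (um).
#' @export
nucleusCoords <- function(x) x@coords

#' @describeIn NucleusTable layer labels.
#' @export
layers <- function(x) x@layer

#' @describeIn NucleusTable per-cell channel intensity matrix.
#' @export
intensities <- function(x) x@intensities

#' @describeIn NucleusTable coerce to a plain data.frame (one row per cell).
#' @export
nucleusTableAsDataFrame <- function(x) {
  data.frame(cell_id = x@cellId, x_um = x@coords[, 1L],
             y_um = x@coords[, 2L], z_um = x@coords[, 3L],
             layer = x@layer, x@intensities,
             check.names = FALSE, row.names = NULL)
}

setMethod("show", "NucleusTable", function(object) {
  cat(sprintf("NucleusTable with %d cells (%s), %d channel(s)%s\n",
              nCells(object),
              paste(sprintf("%s: %d", names(table(object@layer)),
                            as.integer(table(object@layer))),
                    collapse = ", "),
              ncol(object@intensities),
              if (ncol(object@intensities))
                paste0(": ", paste(colnames(object@intensities),
                                   collapse = ", "))
              else ""))
})

#' Construct a SurfaceGrid
#'
#' @param values numeric intensity matrix.
#' @param pixelSize pixel edge in um (isotropic).
#' @param origin um coordinates of pixel `(1, 1)`.
#' @return A [SurfaceGrid-class].
#' @export
SurfaceGrid <- function(values, pixelSize, origin = c(0, 0)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("SurfaceGrid", values = values, pixelSize = as.numeric(pixelSize),
      origin = as.numeric(origin))
}

#' @describeIn SurfaceGrid the intensity matrix.
#' @param x a `SurfaceGrid`.
#' @export
gridValues <- function(x) x@values

#' @describeIn SurfaceGrid pixel edge length in um.
#' @export
pixelSize <- function(x) x@pixelSize

#' @describeIn SurfaceGrid um coordinates of pixel (1, 1).
#' @export
gridOrigin <- function(x) x@origin

setMethod("show", "SurfaceGrid", function(object) {
  cat(sprintf("SurfaceGrid %d x %d px, %.3g um/px, origin (%.3g, %.3g) um\n",
              nrow(object@values), ncol(object@values), object@pixelSize,
              object@origin[1L], object@origin[2L]))
})

#' @describeIn fitSphere fitted sphere center (um).
#' @param fit a `SphereFit`.
#' @export
sphereCenter <- function(fit) fit@center

#' @describeIn fitSphere fitted radius `rad_sphere` (um).
#' @export
sphereRadius <- function(fit) fit@radius

#' @describeIn fitSphere RMS geometric residual (um).
#' @export
sphereResidual <- function(fit) fit@rmsResidual

setMethod("show", "SphereFit", function(object) {
  cat(sprintf(paste0("SphereFit: center (%.3f, %.3f, %.3f) um, ",
                     "rad_sphere %.3f um, rms residual %.3g um (n = %d)\n"),
              object@center[1L], object@center[2L], object@center[3L],
              object@radius, object@rmsResidual, object@nPointsUsed))
})

#' Construct an Axis
#'
#' @param anchor point on the line (um).
#' @param direction direction vector (normalized internally).
#' @return An [Axis-class].
#' @export
Axis <- function(anchor, direction) {
  nd <- sqrt(sum(direction^2))
  if (nd == 0) stop("axis direction must be non-zero")
  new("Axis", anchor = as.numeric(anchor),
      direction = as.numeric(direction) / nd)
}

#' @describeIn sphericalCenter the center point on the sphere surface.
#' @param x a `MeristemCenter`.
#' @export
pCenter <- function(x) x@pCenter

#' @describeIn sphericalCenter the central [Axis-class] of the meristem.
#' @export
centralAxis <- function(x) x@axis

#' @describeIn sphericalCenter seeds projected onto the sphere (3 x 3).
#' @export
projectedSeeds <- function(x) x@seedsProjected

#' @describeIn sphericalCenter the discarded antipodal candidate.
#' @export
discardedCandidate <- function(x) x@candidateDiscarded

setMethod("show", "MeristemCenter", function(object) {
  cat(sprintf("MeristemCenter: P_center (%.3f, %.3f, %.3f) um on sphere r = %.3f um\n",
              object@pCenter[1L], object@pCenter[2L], object@pCenter[3L],
              object@fit@radius))
})

#' Radial-quantification configuration
#'
#' See [ProfileConfig-class] for the meaning and provenance of each
#' parameter.
#'
#' @param nSections number of rotated cross-sections.
#' @param sectionStep rotation step in degrees.
#' @param centralHalfwidth central-window half-width in um.
#' @param backgroundThresholdFactor threshold as a multiple of the center
#'   background signal.
#' @param stemCellRadiusFraction stem-cell gate as a fraction of
#'   `rad_sphere`.
#' @param bootstrapIterations bootstrap replicates for confidence bands.
#' @param kernelBandwidth Gaussian bandwidth in um, or `"auto"`/`NA` for
#'   Silverman's rule.
#' @return A [ProfileConfig-class].
#' @export
profileConfig <- function(nSections = 100L, sectionStep = 360 / nSections,
                          centralHalfwidth = 12.5,
                          backgroundThresholdFactor = 1.2,
                          stemCellRadiusFraction = 0.25,
                          bootstrapIterations = 10000L,
                          kernelBandwidth = NA_real_) {
  if (identical(kernelBandwidth, "auto")) kernelBandwidth <- NA_real_
  new("ProfileConfig", nSections = as.integer(nSections),
      sectionStep = as.numeric(sectionStep),
      centralHalfwidth = as.numeric(centralHalfwidth),
      backgroundThresholdFactor = as.numeric(backgroundThresholdFactor),
      stemCellRadiusFraction = as.numeric(stemCellRadiusFraction),
      bootstrapIterations = as.integer(bootstrapIterations),
      kernelBandwidth = as.numeric(kernelBandwidth))
}

setMethod("show", "ProfileConfig", function(object) {
  cat(sprintf(paste0("ProfileConfig: %d sections x %.2f deg; central window ",
                     "+/- %.1f um;\n  threshold %.0f%% of center background; ",
                     "stem-cell gate %.2f * rad_sphere; B = %d\n"),
              object@nSections, object@sectionStep, object@centralHalfwidth,
              100 * object@backgroundThresholdFactor,
              object@stemCellRadiusFraction, object@bootstrapIterations))
})

#' Synthetic-meristem specification
#'
#' See [SamSpec-class] for parameter semantics. Defaults describe a 40 um
#' dome of 5 um cells with two sub-epidermal layers, a central stem-cell
#' reporter Gaussian and a peripheral auxin-output field with a 10 um
#' central minimum and wedge maxima at golden-angle primordium positions.
#'
#' @param domeRadius,cellDiameter,nLayers,summitColatitude dome geometry.
#' @param primordiumAzimuths,primordiumColatitude primordium placement
#'   (degrees).
#' @param clv3Amplitude,clv3Sigma central reporter field.
#' @param dr5Base,dr5WedgeAmplitude,dr5CentralMinRadius,dr5CentralMinFactor
#'   auxin-output field.
#' @param posJitterSigma radial centroid jitter SD (um).
#' @param noiseMultSigma,noiseAddSigma intensity noise.
#' @param gridPixelSize surface-grid pixel size (um).
#' @param seed integer seed; the spec plus seed fully determine the output.
#' @return A [SamSpec-class].
#' @export
samSpec <- function(domeRadius = 40, cellDiameter = 5, nLayers = 2L,
                    summitColatitude = 75,
                    primordiumAzimuths = c(0, 137.5, 275),
                    primordiumColatitude = 65,
                    clv3Amplitude = 100, clv3Sigma = 10,
                    dr5Base = 100, dr5WedgeAmplitude = 1,
                    dr5CentralMinRadius = 10, dr5CentralMinFactor = 0.2,
                    posJitterSigma = 0.5,
                    noiseMultSigma = 0.2, noiseAddSigma = 5,
                    gridPixelSize = 1, seed = 1L) {
  new("SamSpec", domeRadius = as.numeric(domeRadius),
      cellDiameter = as.numeric(cellDiameter), nLayers = as.integer(nLayers),
      summitColatitude = as.numeric(summitColatitude),
      primordiumAzimuths = as.numeric(primordiumAzimuths),
      primordiumColatitude = as.numeric(primordiumColatitude),
      clv3Amplitude = as.numeric(clv3Amplitude),
      clv3Sigma = as.numeric(clv3Sigma), dr5Base = as.numeric(dr5Base),
      dr5WedgeAmplitude = as.numeric(dr5WedgeAmplitude),
      dr5CentralMinRadius = as.numeric(dr5CentralMinRadius),
      dr5CentralMinFactor = as.numeric(dr5CentralMinFactor),
      posJitterSigma = as.numeric(posJitterSigma),
      noiseMultSigma = as.numeric(noiseMultSigma),
      noiseAddSigma = as.numeric(noiseAddSigma),
      gridPixelSize = as.numeric(gridPixelSize), seed = as.integer(seed))
}

setMethod("show", "SamSpec", function(object) {
  cat(sprintf(paste0("SamSpec: dome r = %.1f um, cells %.1f um, %d layer(s) ",
                     "below L1, seed %d\n"),
              object@domeRadius, object@cellDiameter, object@nLayers,
              object@seed))
})

#' Synthetic interval-world specification
#'
#' See [IntervalWorldSpec-class]. Defaults give a 4 Mb chromosome with 200
#' genes (~2 kb), 300 promoter-proximal binding sites (sigma 600 bp around
#' the TSS), a 60% chance of a linked deacetylation interval per site, and
#' 120 background acetylation intervals.
#'
#' @param genomeLength,nGenes,geneLengthMeanlog,geneLengthSdlog genome and
#'   gene-model structure.
#' @param nBindingSites,bindingOffsetSigma,bindingWidthMeanlog,bindingWidthSdlog
#'   binding-site placement and widths.
#' @param pLink,linkOffsetSigma,acetWidthMeanlog,acetWidthSdlog linked
#'   acetylation intervals.
#' @param posteriorShape1,posteriorShape2 Beta posterior-score parameters.
#' @param nBackgroundUp,nBackgroundDown unlinked background intervals.
#' @param openChromatinFraction fraction of genes in the open-chromatin set.
#' @param seed integer seed.
#' @return An [IntervalWorldSpec-class].
#' @export
intervalWorldSpec <- function(genomeLength = 4e6, nGenes = 200L,
                              geneLengthMeanlog = log(2000),
                              geneLengthSdlog = 0.3,
                              nBindingSites = 300L, bindingOffsetSigma = 600,
                              pLink = 0.6, linkOffsetSigma = 150,
                              bindingWidthMeanlog = log(250),
                              bindingWidthSdlog = 0.3,
                              acetWidthMeanlog = log(600),
                              acetWidthSdlog = 0.3,
                              posteriorShape1 = 9, posteriorShape2 = 1,
                              nBackgroundUp = 60L, nBackgroundDown = 60L,
                              openChromatinFraction = 0.8, seed = 1L) {
  new("IntervalWorldSpec", genomeLength = as.integer(genomeLength),
      nGenes = as.integer(nGenes),
      geneLengthMeanlog = as.numeric(geneLengthMeanlog),
      geneLengthSdlog = as.numeric(geneLengthSdlog),
      nBindingSites = as.integer(nBindingSites),
      bindingOffsetSigma = as.numeric(bindingOffsetSigma),
      pLink = as.numeric(pLink), linkOffsetSigma = as.numeric(linkOffsetSigma),
      bindingWidthMeanlog = as.numeric(bindingWidthMeanlog),
      bindingWidthSdlog = as.numeric(bindingWidthSdlog),
      acetWidthMeanlog = as.numeric(acetWidthMeanlog),
      acetWidthSdlog = as.numeric(acetWidthSdlog),
      posteriorShape1 = as.numeric(posteriorShape1),
      posteriorShape2 = as.numeric(posteriorShape2),
      nBackgroundUp = as.integer(nBackgroundUp),
      nBackgroundDown = as.integer(nBackgroundDown),
      openChromatinFraction = as.numeric(openChromatinFraction),
      seed = as.integer(seed))
}

#' Construct a GeneModels object
#'
#' @param genes stranded GRanges of gene spans with a `gene_id` column.
#' @param features optional GRanges of sub-features with `type` and
#'   `gene_id` columns.
#' @return A [GeneModels-class].
#' @export
geneModels <- function(genes, features = GRanges()) {
  new("GeneModels", genes = genes, features = features)
}

#' @describeIn geneModels gene spans as GRanges.
#' @param x a `GeneModels`.
#' @export
genes <- function(x) x@genes

#' @describeIn geneModels sub-feature GRanges.
#' @export
geneFeatures <- function(x) x@features

#' @describeIn geneModels strand-aware TSS positions as width-1 GRanges.
#' @export
tssPositions <- function(x) {
  g <- x@genes
  pos <- ifelse(as.character(strand(g)) == "+", start(g), end(g))
  GRanges(seqnames(g), IRanges(pos, width = 1L), strand = strand(g),
          gene_id = mcols(g)$gene_id)
}

setMethod("show", "GeneModels", function(object) {
  cat(sprintf("GeneModels: %d gene(s), %d sub-feature(s)\n",
              length(object@genes), length(object@features)))
})

setMethod("show", "SamGroundTruth", function(object) {
  cat(sprintf(paste0("SamGroundTruth: apex (%.2f, %.2f, %.2f) um on sphere ",
                     "r = %.2f um\n"),
              object@trueCenter3d[1L], object@trueCenter3d[2L],
              object@trueCenter3d[3L], object@radius))
})
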