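## Core S4 classes. Validity checks enforce the structural invariants that
## downstream operations rely on (unique cell ids, finite coordinates,
## positive pixel sizes, sphere geometry consistency).

#' NucleusTable: per-nucleus centroids and channel intensities
#'
#' Holds one segmented meristem: cell identifiers, 3D nuclear centroids in
#' micrometers, a cell-layer label (`"L1"`, `"L2"` or `"inner"`), and one
#' mean intensity (arbitrary units, non-negative) per fluorescence channel.
#'
#' @slot cellId character vector of unique cell identifiers.
#' @slot coords numeric matrix (n x 3, columns x/y/z) of centroids in um.
#' @slot layer character vector of layer labels.
#' @slot intensities numeric matrix (n x channels) of per-cell mean
#'   intensities; column names are channel names.
#' @exportClass NucleusTable
setClass("NucleusTable",
  representation(cellId = "character", coords = "matrix",
                 layer = "character", intensities = "matrix"),
  validity = function(object) {
    n <- length(object@cellId)
    msg <- character()
    if (anyDuplicated(object@cellId)) msg <- c(msg, "cell ids must be unique")
    if (!is.numeric(object@coords) || ncol(object@coords) != 3L ||
        nrow(object@coords) != n)
      msg <- c(msg, "'coords' must be a numeric n x 3 matrix")
    else if (!all(is.finite(object@coords)))
      msg <- c(msg, "coordinates must be finite")
    if (length(object@layer) != n)
      msg <- c(msg, "'layer' length must match number of cells")
    if (!all(object@layer %in% c("L1", "L2", "inner")))
      msg <- c(msg, "layer labels must be 'L1', 'L2' or 'inner'")
    if (nrow(object@intensities) != n)
      msg <- c(msg, "'intensities' rows must match number of cells")
    else if (ncol(object@intensities) > 0 &&
             (!all(is.finite(object@intensities)) ||
              any(object@intensities < 0)))
      msg <- c(msg, "intensities must be finite and >= 0")
    if (length(msg)) msg else TRUE
  })

#' SurfaceGrid: a top-view surface-projected intensity image
#'
#' A 2D grid of intensities on isotropic square pixels, as produced by
#' surface projection of a confocal stack. `values[i, j]` sits at physical
#' position `origin + (j - 1, i - 1) * pixelSize` (x along columns, y along
#' rows).
#'
#' @slot values numeric matrix of intensities (finite, >= 0).
#' @slot pixelSize positive pixel edge length in um.
#' @slot origin numeric length-2, um position of pixel (1, 1).
#' @exportClass SurfaceGrid
setClass("SurfaceGrid",
  representation(values = "matrix", pixelSize = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
      msg <- c(msg, "'pixelSize' must be a single positive number")
    if (length(object@origin) != 2L || !all(is.finite(object@origin)))
      msg <- c(msg, "'origin' must be two finite numbers")
    if (!all(is.finite(object@values)) || any(object@values < 0))
      msg <- c(msg, "grid intensities must be finite and >= 0")
    if (length(msg)) msg else TRUE
  })

#' SphereFit: a least-squares sphere through L1 nuclei
#'
#' @slot center numeric length-3, sphere center in um.
#' @slot radius positive radius (`rad_sphere`) in um.
#' @slot rmsResidual root-mean-square geometric residual in um.
#' @slot nPointsUsed number of points fitted (>= 4).
#' @slot pointsCentroid centroid of the fitted points; used as the default
#'   summit hint when resolving the antipodal circumcenter ambiguity.
#' @exportClass SphereFit
setClass("SphereFit",
  representation(center = "numeric", radius = "numeric",
                 rmsResidual = "numeric", nPointsUsed = "integer",
                 pointsCentroid = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@center) != 3L || !all(is.finite(object@center)))
      msg <- c(msg, "'center' must be three finite numbers")
    if (!is.finite(object@radius) || object@radius <= 0)
      msg <- c(msg, "'radius' must be positive")
    if (!is.finite(object@rmsResidual) || object@rmsResidual < 0)
      msg <- c(msg, "'rmsResidual' must be >= 0")
    if (object@nPointsUsed < 4L)
      msg <- c(msg, "at least 4 points are needed for a sphere fit")
    if (length(msg)) msg else TRUE
  })

#' Axis: a line in 3D (anchor point + unit direction)
#'
#' @slot anchor numeric length-3 point on the line (um).
#' @slot direction numeric length-3 unit vector.
#' @exportClass Axis
setClass("Axis",
  representation(anchor = "numeric", direction = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@anchor) != 3L || !all(is.finite(object@anchor)))
      msg <- c(msg, "'anchor' must be three finite numbers")
    if (length(object@direction) != 3L ||
        abs(sqrt(sum(object@direction^2)) - 1) > 1e-8)
      msg <- c(msg, "'direction' must be a 3D unit vector")
    if (length(msg)) msg else TRUE
  })

#' MeristemCenter: the spherical-Voronoi vertex used as meristem center
#'
#' `pCenter` is the point on the fitted sphere equidistant (geodesically) to
#' the three projected primordium seeds; `axisDirection` points from the
#' sphere center through `pCenter` and defines the central axis of the
#' meristem. The discarded antipodal circumcenter is retained for audit.
#'
#' @slot pCenter numeric length-3 point on the sphere surface (um).
#' @slot seedsProjected 3 x 3 matrix, the seeds projected onto the sphere.
#' @slot axis [Axis-class] through the sphere center and `pCenter`.
#' @slot candidateDiscarded numeric length-3, the antipodal candidate.
#' @slot fit the [SphereFit-class] the construction is based on.
#' @exportClass MeristemCenter
setClass("MeristemCenter",
  representation(pCenter = "numeric", seedsProjected = "matrix",
                 axis = "Axis", candidateDiscarded = "numeric",
                 fit = "SphereFit"),
  validity = function(object) {
    msg <- character()
    fit <- object@fit
    r <- fit@radius
    if (abs(sqrt(sum((object@pCenter - fit@center)^2)) - r) > 1e-6 * max(1, r))
      msg <- c(msg, "'pCenter' must lie on the fitted sphere")
    if (!all(dim(object@seedsProjected) == c(3L, 3L)))
      msg <- c(msg, "'seedsProjected' must be a 3 x 3 matrix")
    else {
      gd <- apply(object@seedsProjected, 1L, function(s)
        .geodesic(object@pCenter, s, fit@center, r))
      if (diff(range(gd)) > 1e-6 * r)
        msg <- c(msg, "'pCenter' must be equidistant to the projected seeds")
    }
    if (length(msg)) msg else TRUE
  })

#' RadialProfile: mean signal intensity versus distance from the center
#'
#' Produced by [crossSectionProfiles()]. Distance bins are spaced by one
#' pixel starting at 0; the per-section profile matrix is retained for
#' audit (rows = sections, columns = distance bins; NA where a section left
#' the grid).
#'
#' @slot distances ascending bin-center distances in um, starting at 0.
#' @slot meanIntensity mean intensity per bin across all sections.
#' @slot sectionMatrix per-section x per-bin intensity matrix.
#' @slot pixelSize um per bin.
#' @exportClass RadialProfile
setClass("RadialProfile",
  representation(distances = "numeric", meanIntensity = "numeric",
                 sectionMatrix = "matrix", pixelSize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@distances) != length(object@meanIntensity))
      msg <- c(msg, "'distances' and 'meanIntensity' lengths differ")
    if (is.unsorted(object@distances, strictly = TRUE))
      msg <- c(msg, "'distances' must be strictly increasing")
    ok <- is.finite(object@meanIntensity)
    if (any(object@meanIntensity[ok] < 0))
      msg <- c(msg, "intensities must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' ProfileConfig: tunable parameters of the radial quantification
#'
#' Defaults encode the standard analysis settings: 100 cross-sections
#' rotated by 3.6 degrees, a +/- 12.5 um central comparison window, the
#' 120%-of-center-background threshold for the size of the central signal
#' minimum, the `dist <= rad_sphere / 4` stem-cell gate, and 10000
#' bootstrap iterations for kernel-regression confidence bands.
#'
#' @slot nSections number of cross-sections (default 100).
#' @slot sectionStep rotation step between sections in degrees (3.6);
#'   `nSections * sectionStep` must equal 360.
#' @slot centralHalfwidth half-width of the central window in um (12.5).
#' @slot backgroundThresholdFactor multiple of the center background signal
#'   defining the threshold crossing (1.2).
#' @slot stemCellRadiusFraction fraction of `rad_sphere` within which cells
#'   count as stem cells (0.25).
#' @slot bootstrapIterations bootstrap replicates for confidence bands
#'   (10000).
#' @slot kernelBandwidth Gaussian kernel bandwidth in um, or `NA` for
#'   Silverman's rule-of-thumb on the distances.
#' @exportClass ProfileConfig
setClass("ProfileConfig",
  representation(nSections = "integer", sectionStep = "numeric",
                 centralHalfwidth = "numeric",
                 backgroundThresholdFactor = "numeric",
                 stemCellRadiusFraction = "numeric",
                 bootstrapIterations = "integer",
                 kernelBandwidth = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nSections < 1L)
      msg <- c(msg, "'nSections' must be >= 1")
    if (abs(object@nSections * object@sectionStep - 360) > 1e-9)
      msg <- c(msg, "nSections * sectionStep must equal 360 degrees")
    if (object@centralHalfwidth <= 0)
      msg <- c(msg, "'centralHalfwidth' must be > 0")
    if (object@backgroundThresholdFactor <= 0)
      msg <- c(msg, "'backgroundThresholdFactor' must be > 0")
    if (object@stemCellRadiusFraction <= 0 ||
        object@stemCellRadiusFraction > 1)
      msg <- c(msg, "'stemCellRadiusFraction' must be in (0, 1]")
    if (object@bootstrapIterations < 1L)
      msg <- c(msg, "'bootstrapIterations' must be >= 1")
    if (!is.na(object@kernelBandwidth) && object@kernelBandwidth <= 0)
      msg <- c(msg, "'kernelBandwidth' must be > 0 or NA for automatic")
    if (length(msg)) msg else TRUE
  })

#' SamSpec: parameters of the synthetic meristem generator
#'
#' Describes the hemispherical cell dome and the planted reporter fields
#' emitted by [generateSam()]. All lengths in um, angles in degrees,
#' intensities in arbitrary units.
#'
#' @slot domeRadius radius of the dome sphere (40).
#' @slot cellDiameter target geodesic spacing between neighbouring cells
#'   (5).
#' @slot nLayers cell layers below L1 (2).
#' @slot summitColatitude colatitude extent of the populated cap (75).
#' @slot primordiumAzimuths azimuths of the young primordia, degrees in
#'   [0, 360) (0, 137.5, 275 -- successive golden-angle positions).
#' @slot primordiumColatitude colatitude of the primordium centers (65).
#' @slot clv3Amplitude,clv3Sigma peak intensity and geodesic width of the
#'   central stem-cell reporter Gaussian.
#' @slot dr5Base,dr5WedgeAmplitude,dr5CentralMinRadius auxin-output field:
#'   baseline intensity, relative amplitude of the primordium wedges, and
#'   radius of the central minimum inside which the signal drops to
#'   `dr5CentralMinFactor` of baseline.
#' @slot dr5CentralMinFactor depth of the central minimum (0.2).
#' @slot posJitterSigma radial jitter SD of L1 centroids around the true
#'   sphere, truncated at `cellDiameter / 4` (0.5).
#' @slot noiseMultSigma lognormal sigma of multiplicative intensity noise.
#' @slot noiseAddSigma SD of additive Gaussian intensity noise (clipped at
#'   zero).
#' @slot gridPixelSize pixel size of the emitted surface grids (1).
#' @slot seed integer seed; together with the spec it fully determines the
#'   output.
#' @exportClass SamSpec
setClass("SamSpec",
  representation(domeRadius = "numeric", cellDiameter = "numeric",
                 nLayers = "integer", summitColatitude = "numeric",
                 primordiumAzimuths = "numeric",
                 primordiumColatitude = "numeric",
                 clv3Amplitude = "numeric", clv3Sigma = "numeric",
                 dr5Base = "numeric", dr5WedgeAmplitude = "numeric",
                 dr5CentralMinRadius = "numeric",
                 dr5CentralMinFactor = "numeric",
                 posJitterSigma = "numeric",
                 noiseMultSigma = "numeric", noiseAddSigma = "numeric",
                 gridPixelSize = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!(object@domeRadius > object@cellDiameter &&
          object@cellDiameter > 0))
      msg <- c(msg, "'domeRadius' > 'cellDiameter' > 0 is required")
    angs <- c(object@primordiumAzimuths)
    if (any(angs < 0 | angs >= 360))
      msg <- c(msg, "'primordiumAzimuths' must lie in [0, 360)")
    if (object@summitColatitude <= 0 || object@summitColatitude > 90)
      msg <- c(msg, "'summitColatitude' must be in (0, 90]")
    if (object@primordiumColatitude <= 0 ||
        object@primordiumColatitude > 90)
      msg <- c(msg, "'primordiumColatitude' must be in (0, 90]")
    for (fld in c("clv3Amplitude", "clv3Sigma", "dr5Base",
                  "dr5CentralMinRadius", "gridPixelSize"))
      if (slot(object, fld) <= 0)
        msg <- c(msg, sprintf("'%s' must be > 0", fld))
    for (fld in c("dr5WedgeAmplitude", "posJitterSigma",
                  "noiseMultSigma", "noiseAddSigma"))
      if (slot(object, fld) < 0)
        msg <- c(msg, sprintf("'%s' must be >= 0", fld))
    if (object@dr5CentralMinFactor <= 0 || object@dr5CentralMinFactor >= 1)
      msg <- c(msg, "'dr5CentralMinFactor' must be in (0, 1)")
    if (object@nLayers < 0L) msg <- c(msg, "'nLayers' must be >= 0")
    if (is.na(object@seed)) msg <- c(msg, "'seed' must be an integer")
    if (length(msg)) msg else TRUE
  })

#' IntervalWorldSpec: parameters of the synthetic genomic-interval world
#'
#' Describes the toy genome emitted by [generateIntervalWorld()]: gene
#' models on one chromosome, transcription-factor binding sites whose
#' midpoints are drawn Normal(TSS, `bindingOffsetSigma`), linked
#' "acetylation-change" intervals spawned near binding sites with
#' probability `pLink` (direction "down"), independent background
#' acetylation intervals of both directions, and an open-chromatin
#' background set around a random subset of genes.
#'
#' @slot genomeLength chromosome length in bp.
#' @slot nGenes number of genes.
#' @slot geneLengthMeanlog,geneLengthSdlog lognormal gene-length parameters.
#' @slot nBindingSites number of binding sites.
#' @slot bindingOffsetSigma SD (bp) of binding midpoints around the TSS.
#' @slot pLink probability a binding site spawns a linked acetylation
#'   interval.
#' @slot linkOffsetSigma SD (bp) of the linked interval midpoint around its
#'   parent binding site.
#' @slot bindingWidthMeanlog,bindingWidthSdlog,acetWidthMeanlog,acetWidthSdlog
#'   lognormal width parameters of binding / acetylation intervals.
#' @slot posteriorShape1,posteriorShape2 Beta parameters of the posterior
#'   scores attached to intervals.
#' @slot nBackgroundUp,nBackgroundDown counts of unlinked background
#'   acetylation intervals per direction.
#' @slot openChromatinFraction fraction of genes contributing to the
#'   open-chromatin background set.
#' @slot seed integer seed.
#' @exportClass IntervalWorldSpec
setClass("IntervalWorldSpec",
  representation(genomeLength = "integer", nGenes = "integer",
                 geneLengthMeanlog = "numeric", geneLengthSdlog = "numeric",
                 nBindingSites = "integer", bindingOffsetSigma = "numeric",
                 pLink = "numeric", linkOffsetSigma = "numeric",
                 bindingWidthMeanlog = "numeric", bindingWidthSdlog = "numeric",
                 acetWidthMeanlog = "numeric", acetWidthSdlog = "numeric",
                 posteriorShape1 = "numeric", posteriorShape2 = "numeric",
                 nBackgroundUp = "integer", nBackgroundDown = "integer",
                 openChromatinFraction = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@genomeLength <= 0L || object@nGenes <= 0L ||
        object@nBindingSites <= 0L)
      msg <- c(msg, "genome length and entity counts must be > 0")
    if (object@pLink < 0 || object@pLink > 1)
      msg <- c(msg, "'pLink' must be in [0, 1]")
    if (object@bindingOffsetSigma <= 0 || object@linkOffsetSigma < 0)
      msg <- c(msg, "offset sigmas must be positive")
    if (object@posteriorShape1 <= 0 || object@posteriorShape2 <= 0)
      msg <- c(msg, "posterior Beta parameters must be > 0")
    if (object@nBackgroundUp < 0L || object@nBackgroundDown < 0L)
      msg <- c(msg, "background counts must be >= 0")
    if (object@openChromatinFraction < 0 || object@openChromatinFraction > 1)
      msg <- c(msg, "'openChromatinFraction' must be in [0, 1]")
    if (is.na(object@seed)) msg <- c(msg, "'seed' must be an integer")
    if (length(msg)) msg else TRUE
  })

#' GeneModels: gene spans plus optional sub-features
#'
#' Gene spans are a stranded GRanges with a `gene_id` metadata column;
#' `features` optionally carries sub-spans (`five_prime_UTR`, `exon`,
#' `three_prime_UTR`) with `type` and `gene_id` columns, nested within
#' their gene. The TSS of a gene is its start on `+` and its end on `-`.
#'
#' @slot genes GRanges of gene spans.
#' @slot features GRanges of sub-features (possibly empty).
#' @exportClass GeneModels
setClass("GeneModels",
  representation(genes = "GRanges", features = "GRanges"),
  validity = function(object) {
    msg <- character()
    if (is.null(mcols(object@genes)$gene_id))
      msg <- c(msg, "'genes' must carry a 'gene_id' metadata column")
    if (any(!as.character(strand(object@genes)) %in% c("+", "-")))
      msg <- c(msg, "gene strands must be '+' or '-'")
    if (length(object@features)) {
      fm <- mcols(object@features)
      if (is.null(fm$type) || is.null(fm$gene_id))
        msg <- c(msg, "'features' must carry 'type' and 'gene_id' columns")
      else if (!all(fm$gene_id %in% mcols(object@genes)$gene_id))
        msg <- c(msg, "feature gene_ids must match a gene")
    }
    if (length(msg)) msg else TRUE
  })

#' SamGroundTruth: planted parameters of a synthetic meristem
#'
#' Written alongside every generated dataset; round-trips losslessly
#' through the JSON sidecar ([writeGroundTruth()]/[readGroundTruth()]).
#'
#' @slot sphereCenter true dome-sphere center (um).
#' @slot radius true dome radius (um).
#' @slot trueCenter3d the true apex (meristem center) on the sphere.
#' @slot trueAxis unit vector of the true central axis.
#' @slot trueSeeds 3 x 3 matrix of the true primordium seed points.
#' @slot spec the [SamSpec-class] that generated the data.
#' @exportClass SamGroundTruth
setClass("SamGroundTruth",
  representation(sphereCenter = "numeric", radius = "numeric",
                 trueCenter3d = "numeric", trueAxis = "numeric",
                 trueSeeds = "matrix", spec = "SamSpec"))
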