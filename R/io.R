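## Readers and writers for the package's plain-text interchange formats:
## nucleus tables (TSV), surface grids (TSV matrix or 32-bit TIFF), BED6
## interval sets, GFF3 gene models and JSON ground-truth sidecars. All
## round-trip losslessly for in-range values.

#' Write / read a NucleusTable as TSV
#'
#' Columns: `cell_id`, `x_um`, `y_um`, `z_um`, `layer`, then one column
#' per channel. Units are micrometers, as the header names state.
#'
#' @param x a [NucleusTable-class].
#' @param path file path.
#' @return `writeNucleusTable` returns `path` invisibly;
#'   `readNucleusTable` returns a [NucleusTable-class].
#' @export
writeNucleusTable <- function(x, path) {
  stopifnot(is(x, "NucleusTable"))
  df <- nucleusTableAsDataFrame(x)
  ## full double precision so the table round-trips losslessly
  for (cl in names(df))
    if (is.numeric(df[[cl]])) df[[cl]] <- sprintf("%.17g", df[[cl]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeNucleusTable
#' @export
readNucleusTable <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("cell_id", "x_um", "y_um", "z_um", "layer")
  if (!all(need %in% names(df)))
    stop("nucleus table '", path, "' is missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  bad <- which(!complete.cases(df[, c("x_um", "y_um", "z_um")]))
  if (length(bad))
    stop("non-numeric coordinates in '", path, "' at data line(s) ",
         paste(head(bad, 5L), collapse = ", "))
  chans <- setdiff(names(df), need)
  NucleusTable(df$cell_id, as.matrix(df[, c("x_um", "y_um", "z_um")]),
               df$layer,
               if (length(chans)) as.matrix(df[, chans, drop = FALSE])
               else matrix(numeric(), nrow(df), 0))
}

#' Write / read a SurfaceGrid
#'
#' TSV format: two header comment lines carrying `pixel_size_um` and
#' `origin_um`, then the intensity matrix. TIFF format: single-page
#' 32-bit float image (pixel size and origin go in the JSON sidecar the
#' pipeline writes, since TIFF carries no physical calibration here).
#'
#' @param x a [SurfaceGrid-class].
#' @param path file path; format chosen by extension (`.tsv` or `.tif`).
#' @param pixelSizeUm,originUm calibration used when reading a TIFF.
#' @return `writeSurfaceGrid` returns `path` invisibly; `readSurfaceGrid`
#'   a [SurfaceGrid-class].
#' @export
writeSurfaceGrid <- function(x, path) {
  stopifnot(is(x, "SurfaceGrid"))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    v <- x@values
    tiff::writeTIFF(v / max(v, 1), path, bits.per.sample = 32L)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# pixel_size_um=%.17g", x@pixelSize),
                 sprintf("# origin_um=%.17g,%.17g",
                         x@origin[1L], x@origin[2L])), con)
    write.table(matrix(sprintf("%.17g", x@values), nrow(x@values)),
                con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname writeSurfaceGrid
#' @export
readSurfaceGrid <- function(path, pixelSizeUm = 1, originUm = c(0, 0)) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    v <- tiff::readTIFF(path)
    return(SurfaceGrid(v, pixelSizeUm, originUm))
  }
  hdr <- readLines(path, n = 2L)
  px <- as.numeric(sub("# pixel_size_um=", "", hdr[1L], fixed = TRUE))
  org <- as.numeric(strsplit(sub("# origin_um=", "", hdr[2L],
                                 fixed = TRUE), ",")[[1L]])
  if (is.na(px) || length(org) != 2L || anyNA(org))
    stop("malformed surface-grid header in '", path, "'")
  v <- as.matrix(read.table(path, sep = "\t", skip = 2L, header = FALSE))
  dimnames(v) <- NULL
  SurfaceGrid(v, px, org)
}

#' Write / read posterior-scored intervals as BED6
#'
#' The BED score column carries the posterior probability, the name
#' column the direction label (`up`, `down` or `none`). Coordinates are
#' converted between BED's 0-based half-open convention and GRanges'
#' 1-based closed convention by rtracklayer.
#'
#' @param gr GRanges with optional `score`/`direction` metadata.
#' @param path file path.
#' @return `writeBedIntervals` returns `path` invisibly;
#'   `readBedIntervals` a GRanges with `score` and `direction` columns.
#' @export
writeBedIntervals <- function(gr, path) {
  out <- granges(gr)
  mcols(out)$name <- if (is.null(mcols(gr)$direction)) "none"
                     else mcols(gr)$direction
  mcols(out)$score <- if (is.null(mcols(gr)$score)) 0
                      else mcols(gr)$score
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' @rdname writeBedIntervals
#' @export
readBedIntervals <- function(path) {
  ## validate coordinates before handing to the importer, so malformed
  ## rows are reported with their line number
  lines <- readLines(path)
  dat <- strsplit(lines, "\t")
  for (i in seq_along(dat)) {
    f <- dat[[i]]
    if (length(f) < 3L)
      stop("BED line ", i, ": fewer than 3 fields")
    s <- suppressWarnings(as.numeric(f[2L]))
    e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e) || s >= e)
      stop("BED line ", i, ": invalid interval [", f[2L], ", ", f[3L], ")")
  }
  gr <- rtracklayer::import(path, format = "BED")
  names(mcols(gr))[names(mcols(gr)) == "name"] <- "direction"
  gr
}

#' Read gene models from GFF3
#'
#' Imports `gene` records (and `five_prime_UTR`/`exon`/`three_prime_UTR`
#' sub-features when present) into a [GeneModels-class]. GFF3's 1-based
#' closed coordinates map directly onto GRanges.
#'
#' @param path GFF3 file.
#' @return A [GeneModels-class].
#' @export
readGeneModels <- function(path) {
  gff <- rtracklayer::import(path, format = "GFF3")
  isGene <- mcols(gff)$type == "gene"
  g <- granges(gff[isGene])
  mcols(g)$gene_id <- mcols(gff)$ID[isGene]
  fsel <- mcols(gff)$type %in% c("five_prime_UTR", "exon", "three_prime_UTR")
  f <- granges(gff[fsel])
  if (length(f)) {
    par <- mcols(gff)$Parent[fsel]
    mcols(f)$type <- as.character(mcols(gff)$type[fsel])
    mcols(f)$gene_id <- vapply(par, function(p)
      if (length(p)) as.character(p[[1L]]) else NA_character_, "")
  }
  geneModels(g, f)
}

#' Write gene models to GFF3
#'
#' @param models a [GeneModels-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(models, path) {
  g <- models@genes
  mcols(g) <- DataFrame(type = "gene", ID = mcols(g)$gene_id)
  out <- g
  f <- models@features
  if (length(f)) {
    ff <- granges(f)
    mcols(ff) <- DataFrame(type = mcols(f)$type, ID = NA_character_,
                           Parent = as.character(mcols(f)$gene_id))
    GenomeInfoDb::seqlevels(ff) <- GenomeInfoDb::seqlevels(g)
    suppressWarnings(out <- c(out, ff))
  }
  rtracklayer::export(out, path, format = "GFF3")
  invisible(path)
}

#' Write / read a ground-truth sidecar as JSON
#'
#' The sidecar records the planted sphere geometry, axis, primordium
#' seeds and the full generator spec, and round-trips losslessly.
#'
#' @param truth a [SamGroundTruth-class].
#' @param path JSON file path.
#' @return `writeGroundTruth` returns `path` invisibly;
#'   `readGroundTruth` a [SamGroundTruth-class].
#' @export
writeGroundTruth <- function(truth, path) {
  stopifnot(is(truth, "SamGroundTruth"))
  sp <- truth@spec
  specList <- lapply(slotNames(sp), function(s) slot(sp, s))
  names(specList) <- slotNames(sp)
  jsonlite::write_json(
    list(sphere_center = truth@sphereCenter, radius = truth@radius,
         true_center_3d = truth@trueCenter3d, true_axis = truth@trueAxis,
         true_seeds = truth@trueSeeds, spec = specList),
    path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- do.call(samSpec, j$spec)
  seeds <- as.matrix(j$true_seeds)
  storage.mode(seeds) <- "double"
  new("SamGroundTruth", sphereCenter = as.numeric(j$sphere_center),
      radius = as.numeric(j$radius),
      trueCenter3d = as.numeric(j$true_center_3d),
      trueAxis = as.numeric(j$true_axis),
      trueSeeds = seeds, spec = sp)
}
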