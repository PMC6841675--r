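## End-to-end pipeline orchestration: simulate -> fit-center -> radial
## quantification -> stats, and simulate -> interval post-processing ->
## enrichment, driven by one config, with a manifest of output hashes so
## a re-run with the same config is verifiably identical.

#' Default pipeline configuration
#'
#' @param outDir output directory.
#' @param seed master integer seed; per-stage seeds are derived from it
#'   deterministically.
#' @param stages subset of `c("sam", "intervals")`.
#' @param sam a [SamSpec-class] (its own seed is overridden by the derived
#'   stage seed).
#' @param profile a [ProfileConfig-class].
#' @param world an [IntervalWorldSpec-class] (seed likewise overridden).
#' @param annotation an [annotationConfig()] list.
#' @return A pipeline config list, serializable with
#'   [writePipelineConfig()].
#' @export
pipelineConfig <- function(outDir, seed = 1L,
                           stages = c("sam", "intervals"),
                           sam = samSpec(), profile = profileConfig(),
                           world = intervalWorldSpec(),
                           annotation = annotationConfig()) {
  stopifnot(all(stages %in% c("sam", "intervals")))
  list(out_dir = outDir, seed = as.integer(seed), stages = stages,
       sam = sam, profile = profile, world = world, annotation = annotation)
}

#' Write / read a pipeline config as JSON (lossless round-trip)
#'
#' @param config a [pipelineConfig()] list.
#' @param path JSON file path.
#' @return `writePipelineConfig` returns `path` invisibly;
#'   `readPipelineConfig` the config list.
#' @export
writePipelineConfig <- function(config, path) {
  s4ToList <- function(x) {
    out <- lapply(slotNames(x), function(s) slot(x, s))
    names(out) <- slotNames(x)
    out
  }
  jsonlite::write_json(
    list(out_dir = config$out_dir, seed = config$seed,
         stages = as.list(config$stages), sam = s4ToList(config$sam),
         profile = s4ToList(config$profile),
         world = s4ToList(config$world), annotation = config$annotation),
    path, digits = I(17), auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  prof <- j$profile
  pipelineConfig(
    outDir = j$out_dir, seed = j$seed, stages = unlist(j$stages),
    sam = do.call(samSpec, j$sam),
    profile = profileConfig(
      nSections = prof$nSections, sectionStep = prof$sectionStep,
      centralHalfwidth = prof$centralHalfwidth,
      backgroundThresholdFactor = prof$backgroundThresholdFactor,
      stemCellRadiusFraction = prof$stemCellRadiusFraction,
      bootstrapIterations = prof$bootstrapIterations,
      kernelBandwidth = if (is.null(prof$kernelBandwidth)) NA_real_
                        else prof$kernelBandwidth),
    world = do.call(intervalWorldSpec, j$world),
    annotation = annotationConfig(j$annotation$upstream,
                                  j$annotation$downstream))
}

.stageSeed <- function(master, stage) {
  ## deterministic per-stage seed, kept within 32-bit integer range
  (as.integer(master) * 2654435L + match(stage, c("sam", "intervals",
                                                  "bootstrap")) * 97L) %%
    2147483647L
}

#' Run the full analysis pipeline from one config
#'
#' Stage `"sam"`: generate a synthetic meristem, write the nucleus table,
#' surface grids and ground-truth sidecar, fit the sphere to L1 nuclei,
#' compute `P_center` from the planted primordium seeds, write a center
#' report (JSON), radial profiles (TSV) and the gated, normalized
#' per-cell records (TSV). Stage `"intervals"`: generate an interval
#' world, write gene models (GFF3) and interval sets (BED6), run
#' posterior filtering, reduction, conflict removal, annotation, Venn
#' overlaps, the TSS metaprofile and the enrichment test, and write their
#' reports. A manifest (JSON) records package version, config hash, seeds
#' and the MD5 of every output; re-running the same config reproduces
#' identical hashes. On stage failure, that stage's partial outputs are
#' removed.
#'
#' @param config a [pipelineConfig()] list.
#' @return The manifest, invisibly (also written to
#'   `manifest.json`).
#' @export
runPipeline <- function(config) {
  outDir <- config$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  addFile <- function(path) files <<- c(files, path)

  runStage <- function(stage, fun) {
    before <- files
    tryCatch(fun(), error = function(e) {
      new <- setdiff(files, before)
      unlink(new)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if ("sam" %in% config$stages) runStage("sam", function() {
    spec <- config$sam
    spec@seed <- .stageSeed(config$seed, "sam")
    sam <- generateSam(spec)
    addFile(writeNucleusTable(sam$nuclei, file.path(outDir, "nuclei.tsv")))
    for (ch in names(sam$grids))
      addFile(writeSurfaceGrid(sam$grids[[ch]],
                               file.path(outDir,
                                         sprintf("grid_%s.tsv", ch))))
    addFile(writeGroundTruth(sam$truth,
                             file.path(outDir, "ground_truth.json")))

    l1 <- layers(sam$nuclei) == "L1"
    fit <- fitSphere(nucleusCoords(sam$nuclei)[l1, , drop = FALSE])
    mc <- sphericalCenter(sam$truth@trueSeeds, fit)
    rep <- list(center = sphereCenter(fit), rad_sphere = sphereRadius(fit),
                rms_residual = sphereResidual(fit),
                p_center = pCenter(mc),
                axis_direction = centralAxis(mc)@direction)
    jsonlite::write_json(rep, file.path(outDir, "center.json"),
                         digits = NA, auto_unbox = TRUE)
    addFile(file.path(outDir, "center.json"))

    center2d <- pCenter(mc)[1:2]
    for (ch in names(sam$grids)) {
      prof <- crossSectionProfiles(sam$grids[[ch]], center2d,
                                   config$profile)
      pf <- file.path(outDir, sprintf("profile_%s.tsv", ch))
      write.table(data.frame(distance_um = prof@distances,
                             mean_intensity = prof@meanIntensity),
                  pf, sep = "\t", quote = FALSE, row.names = FALSE)
      addFile(pf)
    }
    rec <- gateStemCells(sam$nuclei, fit, centralAxis(mc),
                         config$profile)
    rec <- minmaxNormalize(rec)
    rf <- file.path(outDir, "cell_records.tsv")
    write.table(rec, rf, sep = "\t", quote = FALSE, row.names = FALSE)
    addFile(rf)
  })

  if ("intervals" %in% config$stages) runStage("intervals", function() {
    spec <- config$world
    spec@seed <- .stageSeed(config$seed, "intervals")
    w <- generateIntervalWorld(spec)
    addFile(writeGeneModels(w$models, file.path(outDir, "genes.gff3")))
    addFile(writeBedIntervals(w$binding, file.path(outDir, "binding.bed")))
    addFile(writeBedIntervals(w$acetUp, file.path(outDir, "acet_up.bed")))
    addFile(writeBedIntervals(w$acetDown,
                              file.path(outDir, "acet_down.bed")))
    addFile(writeBedIntervals(w$openChromatin,
                              file.path(outDir, "open_chromatin.bed")))

    bind <- reduceIntervals(filterPosterior(w$binding))
    up <- reduceIntervals(filterPosterior(w$acetUp))
    down <- reduceIntervals(filterPosterior(w$acetDown))
    cf <- conflictFilter(up, down)
    ann <- annotateIntervals(bind, w$models, config$annotation)
    af <- file.path(outDir, "binding_annotation.tsv")
    write.table(ann, af, sep = "\t", quote = FALSE, row.names = FALSE)
    addFile(af)
    venn <- overlapSets(bind, cf$up, cf$down,
                        setNames = c("binding", "acet_up", "acet_down"))
    meta <- tssMetaprofile(bind, w$models,
                           seed = .stageSeed(config$seed, "bootstrap"))
    boundGenes <- unique(ann$gene_id[ann$category %in%
                                       c("upstream", "five_prime_UTR")])
    boundGenes <- boundGenes[!is.na(boundGenes)]
    bg <- unique(mcols(genes(w$models))$gene_id)
    enr <- enrichment2x2(intersect(boundGenes, bg),
                         intersect(w$truth$open_genes, bg), bg)
    sf <- file.path(outDir, "interval_stats.json")
    jsonlite::write_json(
      list(n_binding_filtered = length(bind),
           n_up_kept = length(cf$up), n_down_kept = length(cf$down),
           n_removed = length(cf$removed),
           venn = venn, metaprofile = meta,
           enrichment = list(table = enr$table,
                             odds_ratio = enr$odds_ratio, p = enr$p)),
      sf, digits = NA)
    addFile(sf)
  })

  cfgFile <- file.path(outDir, "config.json")
  writePipelineConfig(config, cfgFile)
  files <- unique(files)
  manifest <- list(
    package = "samq",
    version = as.character(utils::packageVersion("samq")),
    seed = config$seed,
    stage_seeds = list(sam = .stageSeed(config$seed, "sam"),
                       intervals = .stageSeed(config$seed, "intervals"),
                       bootstrap = .stageSeed(config$seed, "bootstrap")),
    config_md5 = unname(tools::md5sum(cfgFile)),
    outputs = lapply(sort(basename(files)), function(f)
      list(file = f, md5 = unname(tools::md5sum(file.path(outDir, f))))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(manifest)
}
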