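## Synthetic genomic-interval world: a toy chromosome with gene models,
## promoter-proximal binding sites, linked "acetylation-change" intervals
## and an open-chromatin background, with recorded ground truth.

#' Generate a synthetic genomic-interval world
#'
#' Places `nGenes` non-overlapping genes (lognormal lengths, random
#' strand, simple 5'UTR/exon/intron/3'UTR structure) on one chromosome,
#' draws `nBindingSites` transcription-factor binding sites whose
#' midpoints are `Normal(TSS, bindingOffsetSigma)` around the TSS of a
#' random gene, spawns for each site with probability `pLink` a linked
#' acetylation-change interval (direction `"down"`) at
#' `Normal(site, linkOffsetSigma)`, adds independent background
#' acetylation intervals of both directions at uniform positions, and
#' builds an open-chromatin background from a random gene subset
#' (gene span plus 1 kb of promoter, reduced). Posterior scores are
#' Beta-distributed. All intervals are sorted GRanges within
#' `[1, genomeLength]`.
#'
#' @param spec an [IntervalWorldSpec-class]; its seed fully determines the
#'   output.
#' @return A list: `models` ([GeneModels-class]), `binding`, `acetUp`,
#'   `acetDown`, `openChromatin` (GRanges; interval sets carry `score`
#'   and `direction` metadata, binding additionally `parent_gene`;
#'   linked acetylation intervals carry `parent_site`), and `truth`
#'   (a list of the planted assignments).
#' @export
generateIntervalWorld <- function(spec) {
  stopifnot(is(spec, "IntervalWorldSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    L <- spec@genomeLength
    nG <- spec@nGenes
    margin <- 3000L  # room for promoter windows and binding offsets
    slot <- L %/% nG
    lens <- pmax(300L, as.integer(round(
      rlnorm(nG, spec@geneLengthMeanlog, spec@geneLengthSdlog))))
    if (any(lens + 2L * margin >= slot))
      stop("genome too short for ", nG, " genes of the requested lengths")
    offs <- vapply(seq_len(nG), function(i)
      as.integer(runif(1, margin, slot - margin - lens[i])), 0L)
    starts <- (seq_len(nG) - 1L) * slot + offs + 1L
    strands <- sample(c("+", "-"), nG, replace = TRUE)
    gid <- sprintf("gene_%03d", seq_len(nG))
    genesGr <- GRanges("chrS", IRanges(starts, width = lens),
                       strand = strands, gene_id = gid)

    ## simple gene structure: 10% UTRs at the ends, body split into two
    ## exons separated by one intron
    featList <- lapply(seq_len(nG), function(i) {
      s <- starts[i]; e <- s + lens[i] - 1L
      u <- max(50L, as.integer(0.1 * lens[i]))
      innerS <- s + u; innerE <- e - u
      third <- (innerE - innerS + 1L) %/% 3L
      utr5 <- if (strands[i] == "+") c(s, s + u - 1L) else c(e - u + 1L, e)
      utr3 <- if (strands[i] == "+") c(e - u + 1L, e) else c(s, s + u - 1L)
      GRanges("chrS", IRanges(
        c(utr5[1L], innerS, innerE - third + 1L, utr3[1L]),
        c(utr5[2L], innerS + third - 1L, innerE, utr3[2L])),
        type = c("five_prime_UTR", "exon", "exon", "three_prime_UTR"),
        gene_id = gid[i])
    })
    models <- geneModels(genesGr, do.call(c, featList))

    tssPos <- ifelse(strands == "+", starts, starts + lens - 1L)
    nB <- spec@nBindingSites
    parent <- sample.int(nG, nB, replace = TRUE)
    bMid <- as.integer(round(tssPos[parent] +
                               rnorm(nB, 0, spec@bindingOffsetSigma)))
    bW <- pmax(50L, as.integer(round(
      rlnorm(nB, spec@bindingWidthMeanlog, spec@bindingWidthSdlog))))
    bS <- pmax(1L, bMid - bW %/% 2L)
    bE <- pmin(L, bS + bW - 1L)
    binding <- GRanges("chrS", IRanges(bS, bE),
                       score = rbeta(nB, spec@posteriorShape1,
                                     spec@posteriorShape2),
                       direction = "none",
                       parent_gene = gid[parent])

    linked <- runif(nB) < spec@pLink
    nLk <- sum(linked)
    acetDown <- GRanges()
    linkOffsets <- integer()
    if (nLk > 0L) {
      linkOffsets <- as.integer(round(rnorm(nLk, 0, spec@linkOffsetSigma)))
      aMid <- bMid[linked] + linkOffsets
      aW <- pmax(100L, as.integer(round(
        rlnorm(nLk, spec@acetWidthMeanlog, spec@acetWidthSdlog))))
      aS <- pmax(1L, aMid - aW %/% 2L)
      acetDown <- GRanges("chrS", IRanges(aS, pmin(L, aS + aW - 1L)),
                          score = rbeta(nLk, spec@posteriorShape1,
                                        spec@posteriorShape2),
                          direction = "down",
                          parent_site = which(linked))
    }
    bgInterval <- function(nBg, dir) {
      if (nBg == 0L) return(GRanges())
      w <- pmax(100L, as.integer(round(
        rlnorm(nBg, spec@acetWidthMeanlog, spec@acetWidthSdlog))))
      s <- as.integer(runif(nBg, 1, L - max(w)))
      GRanges("chrS", IRanges(s, s + w - 1L),
              score = rbeta(nBg, spec@posteriorShape1, spec@posteriorShape2),
              direction = dir, parent_site = NA_integer_)
    }
    acetUp <- GenomicRanges::sort(bgInterval(spec@nBackgroundUp, "up"))
    acetDown <- GenomicRanges::sort(c(acetDown,
                                      bgInterval(spec@nBackgroundDown,
                                                 "down")))

    openGenes <- sort(sample.int(nG, round(spec@openChromatinFraction * nG)))
    openChromatin <- reduce(GRanges("chrS", IRanges(
      pmax(1L, starts[openGenes] - 1000L),
      starts[openGenes] + lens[openGenes] - 1L + 1000L)))

    list(models = models,
         binding = GenomicRanges::sort(binding),
         acetUp = acetUp, acetDown = acetDown,
         openChromatin = openChromatin,
         truth = list(spec = spec, tss = tssPos, parent_gene = gid[parent],
                      binding_midpoints = bMid, linked = linked,
                      link_offsets = linkOffsets,
                      open_genes = gid[openGenes]))
  })
}
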