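## Post-processing of posterior-scored ChIP-derived intervals on GRanges:
## strict posterior filtering, reduction, opposite-direction conflict
## removal, promoter-window annotation, three-set Venn overlaps,
## strand-aware TSS metaprofiles and 2x2 enrichment.

.checkReduced <- function(gr, what) {
  if (!identical(unname(as.data.frame(granges(reduceIntervals(gr)))),
                 unname(as.data.frame(granges(GenomicRanges::sort(gr))))))
    stop("'", what, "' must be reduced (disjoint, sorted, non-adjacent); ",
         "run reduceIntervals() first")
  invisible(TRUE)
}

#' Keep intervals with posterior probability strictly above a threshold
#'
#' Retains intervals whose `score` (the domain caller's posterior
#' probability) is strictly greater than `threshold` -- a score exactly at
#' the threshold is dropped.
#'
#' @param gr GRanges with a numeric `score` metadata column in `[0, 1]`.
#' @param threshold posterior cutoff (default 0.9).
#' @return The filtered GRanges.
#' @export
filterPosterior <- function(gr, threshold = 0.9) {
  sc <- mcols(gr)$score
  if (length(gr) && (is.null(sc) || anyNA(sc)))
    stop("posterior scores are missing from the 'score' column")
  gr[which(sc > threshold)]
}

#' Reduce intervals by merging overlapping or adjacent regions
#'
#' Merges intervals that overlap or abut (zero gap); the result is
#' disjoint, sorted and non-adjacent. Metadata columns are dropped.
#'
#' @param gr GRanges.
#' @return Reduced GRanges.
#' @export
reduceIntervals <- function(gr) {
  reduce(GenomicRanges::sort(granges(gr)))
}

#' Remove opposite-direction intervals closer than a minimum gap
#'
#' For every pair of one "up" and one "down" interval whose gap is
#' strictly smaller than `minGap` (overlap counts as gap 0), both members
#' are removed; a pair at exactly `minGap` is kept. Such conflicting calls
#' of opposite direction within less than ~half a nucleosome of each other
#' are treated as unreliable. With `symmetric = FALSE` only the `down`
#' member of each conflicting pair is removed.
#'
#' @param up,down reduced GRanges of direction-labelled intervals.
#' @param minGap minimum tolerated gap in bp (default 73).
#' @param symmetric remove both members of a conflicting pair (default)
#'   or only the `down` member.
#' @return List with the filtered `up`, `down`, and `removed` (a GRanges
#'   of all removed intervals with a `direction` column).
#' @export
conflictFilter <- function(up, down, minGap = 73, symmetric = TRUE) {
  .checkReduced(up, "up")
  .checkReduced(down, "down")
  ## gap < minGap <=> distance <= minGap - 1 <=> findOverlaps maxgap
  hits <- findOverlaps(up, down, maxgap = minGap - 1L)
  badUp <- unique(queryHits(hits))
  badDown <- unique(subjectHits(hits))
  if (!symmetric) badUp <- integer()
  removed <- c(
    `if`(length(badUp), {
      g <- granges(up[badUp]); mcols(g)$direction <- "up"; g
    }, GRanges()),
    `if`(length(badDown), {
      g <- granges(down[badDown]); mcols(g)$direction <- "down"; g
    }, GRanges()))
  list(up = up[setdiff(seq_along(up), badUp)],
       down = down[setdiff(seq_along(down), badDown)],
       removed = removed)
}

#' Annotation window configuration
#'
#' @param upstream bp upstream of the TSS counted as promoter-proximal
#'   (default 2500).
#' @param downstream bp downstream of the gene end (default 1000).
#' @return A list used by [annotateIntervals()].
#' @export
annotationConfig <- function(upstream = 2500, downstream = 1000) {
  stopifnot(upstream >= 0, downstream >= 0)
  list(upstream = as.integer(upstream), downstream = as.integer(downstream))
}

## category priority: smaller wins
.annCategories <- c(upstream = 1L, five_prime_UTR = 2L, exon = 3L,
                    intron = 4L, three_prime_UTR = 5L, downstream = 6L)

#' Annotate intervals by position relative to gene models
#'
#' Each interval is represented by its midpoint and assigned one category
#' by priority `upstream > 5'UTR > exon > intron > 3'UTR > downstream >
#' intergenic`. Windows are strand-aware: the upstream window of a `-`
#' strand gene extends rightward of its TSS. Genes without recorded
#' sub-features count as exon over their whole span. Ties within a
#' category are broken by nearest TSS. The signed distance to the nearest
#' TSS (negative = upstream of it) is reported for every interval.
#'
#' @param gr GRanges of intervals.
#' @param models a [GeneModels-class].
#' @param cfg an [annotationConfig()] list.
#' @return A data.frame with one row per interval: `chrom`, `start`,
#'   `end`, `midpoint`, `category`, `gene_id`, `tss_distance`.
#' @export
annotateIntervals <- function(gr, models, cfg = annotationConfig()) {
  stopifnot(is(models, "GeneModels"))
  g <- models@genes
  if (!length(gr))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), midpoint = integer(),
                      category = character(), gene_id = character(),
                      tss_distance = integer()))
  mids <- start(gr) + (width(gr) - 1L) %/% 2L
  mp <- GRanges(seqnames(gr), IRanges(mids, width = 1L))

  plus <- as.character(strand(g)) == "+"
  tssPos <- ifelse(plus, start(g), end(g))
  win <- list()
  ## upstream / downstream flanks (strand-aware), clipped at 1
  upS <- ifelse(plus, pmax(1L, start(g) - cfg$upstream), end(g) + 1L)
  upE <- ifelse(plus, start(g) - 1L, end(g) + cfg$upstream)
  dnS <- ifelse(plus, end(g) + 1L, pmax(1L, start(g) - cfg$downstream))
  dnE <- ifelse(plus, end(g) + cfg$downstream, start(g) - 1L)
  okUp <- upE >= upS
  okDn <- dnE >= dnS
  win$upstream <- GRanges(seqnames(g)[okUp], IRanges(upS[okUp], upE[okUp]),
                          gene_id = mcols(g)$gene_id[okUp])
  win$downstream <- GRanges(seqnames(g)[okDn], IRanges(dnS[okDn], dnE[okDn]),
                            gene_id = mcols(g)$gene_id[okDn])

  feats <- models@features
  if (length(feats)) {
    for (type in c("five_prime_UTR", "exon", "three_prime_UTR")) {
      f <- feats[mcols(feats)$type == type]
      if (length(f))
        win[[type]] <- GRanges(seqnames(f), IRanges(start(f), end(f)),
                               gene_id = mcols(f)$gene_id)
    }
    ## introns: gene span minus recorded sub-features, per gene
    ## (computed unstranded; sub-feature GRanges often carry '*')
    featUn <- GRanges(seqnames(feats), IRanges(start(feats), end(feats)))
    featByGene <- split(featUn, mcols(feats)$gene_id)
    hasFeat <- mcols(g)$gene_id %in% names(featByGene)
    intronList <- lapply(which(hasFeat), function(i) {
      gid <- mcols(g)$gene_id[i]
      span <- GRanges(seqnames(g[i]), IRanges(start(g[i]), end(g[i])))
      GenomicRanges::setdiff(span, reduce(featByGene[[gid]]))
    })
    introns <- do.call(c, c(intronList, list(GRanges())))
    if (length(introns)) {
      mcols(introns)$gene_id <- rep(mcols(g)$gene_id[hasFeat],
                                    lengths(intronList))
      win$intron <- introns
    }
    ## genes without features: whole span counts as exon
    noFeat <- g[!hasFeat]
  } else {
    noFeat <- g
  }
  if (length(noFeat)) {
    body <- GRanges(seqnames(noFeat), IRanges(start(noFeat), end(noFeat)),
                    gene_id = mcols(noFeat)$gene_id)
    win$exon <- if (is.null(win$exon)) body else c(win$exon, body)
  }

  allWin <- GRanges()
  for (nm in names(win)) {
    w <- win[[nm]]
    if (!length(w)) next
    mcols(w)$category <- nm
    mcols(w)$priority <- .annCategories[[nm]]
    allWin <- c(allWin, w)
  }

  tss <- GRanges(seqnames(g), IRanges(tssPos, width = 1L))
  category <- rep("intergenic", length(gr))
  geneId <- rep(NA_character_, length(gr))
  tssDist <- rep(NA_integer_, length(gr))

  if (!all(as.character(seqnames(gr)) %in%
           as.character(GenomeInfoDb::seqlevels(g))))
    warning("intervals on chromosomes absent from the gene models are ",
            "classified intergenic")

  hits <- suppressWarnings(findOverlaps(mp, allWin))
  if (length(hits)) {
    gidOfWin <- mcols(allWin)$gene_id[subjectHits(hits)]
    prio <- mcols(allWin)$priority[subjectHits(hits)]
    tssOfGene <- setNames(tssPos, mcols(g)$gene_id)
    dTss <- abs(mids[queryHits(hits)] - tssOfGene[gidOfWin])
    ord <- order(queryHits(hits), prio, dTss)
    first <- ord[!duplicated(queryHits(hits)[ord])]
    q <- queryHits(hits)[first]
    category[q] <- mcols(allWin)$category[subjectHits(hits)[first]]
    geneId[q] <- gidOfWin[first]
  }

  nh <- suppressWarnings(nearest(mp, tss))
  okN <- !is.na(nh)
  signed <- mids[okN] - tssPos[nh[okN]]
  neg <- !plus[nh[okN]]
  signed[neg] <- -signed[neg]  # on '-' genes, rightward of TSS is upstream
  tssDist[okN] <- as.integer(signed)

  data.frame(chrom = as.character(seqnames(gr)), start = start(gr),
             end = end(gr), midpoint = mids, category = category,
             gene_id = geneId, tss_distance = tssDist,
             row.names = NULL)
}

#' Three-set Venn overlap counts
#'
#' Counts, for each set, how many of its elements overlap (by at least one
#' bp) elements of the other two sets, keyed by membership pattern.
#' Element counts, not base-pair counts: each set's rows sum to that set's
#' size.
#'
#' @param a,b,c reduced GRanges.
#' @param setNames labels for the three sets.
#' @return A data.frame with columns `set`, `pattern` (e.g. `"A"`,
#'   `"A+B"`, `"A+B+C"`), `count`.
#' @export
overlapSets <- function(a, b, c, setNames = c("A", "B", "C")) {
  sets <- list(a, b, c)
  for (i in 1:3) .checkReduced(sets[[i]], setNames[i])
  out <- NULL
  for (i in 1:3) {
    others <- setdiff(1:3, i)
    member <- cbind(TRUE,
                    countOverlaps(sets[[i]], sets[[others[1L]]]) > 0,
                    countOverlaps(sets[[i]], sets[[others[2L]]]) > 0)
    colnames(member) <- setNames[c(i, others)]
    pattern <- apply(member, 1L, function(m) {
      nm <- colnames(member)[m]
      paste(setNames[sort(match(nm, setNames))], collapse = "+")
    })
    if (length(pattern) == 0L) pattern <- character()
    tab <- table(pattern)
    out <- rbind(out, data.frame(set = setNames[i],
                                 pattern = names(tab),
                                 count = as.integer(tab),
                                 row.names = NULL))
  }
  out
}

#' Strand-aware TSS metaprofile with bootstrap confidence band
#'
#' Histograms interval midpoints by signed distance to the nearest TSS
#' (negative = upstream of the TSS, strand-aware), normalized to a
#' density over `[-window, window]`; the 95% band is a percentile
#' bootstrap over intervals.
#'
#' @param gr GRanges of intervals.
#' @param models a [GeneModels-class].
#' @param window half-width of the profile in bp (default 3000).
#' @param bins number of distance bins (default 60).
#' @param B bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return A data.frame with `mid` (bin center, bp), `density`, `lower`,
#'   `upper`; attribute `"n"` is the number of intervals within the
#'   window.
#' @export
tssMetaprofile <- function(gr, models, window = 3000L, bins = 60L,
                           B = 1000L, level = 0.95, seed = 1L) {
  stopifnot(is(models, "GeneModels"))
  g <- models@genes
  plus <- as.character(strand(g)) == "+"
  tssPos <- ifelse(plus, start(g), end(g))
  tss <- GRanges(seqnames(g), IRanges(tssPos, width = 1L))
  mids <- start(gr) + (width(gr) - 1L) %/% 2L
  mp <- GRanges(seqnames(gr), IRanges(mids, width = 1L))
  nh <- suppressWarnings(nearest(mp, tss))
  ok <- !is.na(nh)
  signed <- mids[ok] - tssPos[nh[ok]]
  neg <- !plus[nh[ok]]
  signed[neg] <- -signed[neg]
  signed <- signed[abs(signed) <= window]
  n <- length(signed)
  if (n == 0L) stop("no interval midpoints within ", window, " bp of a TSS")
  breaks <- seq(-window, window, length.out = bins + 1L)
  bw <- diff(breaks)[1L]
  binOf <- pmin(pmax(findInterval(signed, breaks, rightmost.closed = TRUE),
                     1L), bins)
  dens <- tabulate(binOf, bins) / (n * bw)
  boot <- withSeed(seed, {
    W <- rmultinom(B, n, rep(1 / n, n))  # n x B resampling counts
    M <- matrix(0, bins, B)
    for (i in seq_len(n)) M[binOf[i], ] <- M[binOf[i], ] + W[i, ]
    M / (n * bw)
  })
  alpha <- (1 - level) / 2
  ci <- apply(boot, 1L, quantile, probs = c(alpha, 1 - alpha))
  res <- data.frame(mid = (breaks[-1L] + breaks[-(bins + 1L)]) / 2,
                    density = dens, lower = ci[1L, ], upper = ci[2L, ])
  attr(res, "n") <- n
  res
}

#' 2 x 2 enrichment of a target gene set within a class, against a
#' background universe
#'
#' Builds the contingency table (in class vs not) x (target vs not) within
#' the background gene universe (typically genes in open chromatin) and
#' applies [fisherExact2x2()].
#'
#' @param targets character vector of target gene ids (subset of
#'   `background`).
#' @param classMembers character vector of class gene ids (subset of
#'   `background`).
#' @param background character vector: the gene universe.
#' @return List with `table` (2 x 2 matrix), `odds_ratio`, `p`.
#' @export
enrichment2x2 <- function(targets, classMembers, background) {
  targets <- unique(targets); classMembers <- unique(classMembers)
  background <- unique(background)
  if (!all(targets %in% background))
    stop("'targets' must be a subset of 'background'")
  if (!all(classMembers %in% background))
    stop("'classMembers' must be a subset of 'background'")
  a <- length(intersect(classMembers, targets))
  b <- length(setdiff(classMembers, targets))
  c <- length(setdiff(targets, classMembers))
  d <- length(background) - a - b - c
  tab <- matrix(c(a, c, b, d), 2L, 2L,
                dimnames = list(class = c("in_class", "not_in_class"),
                                target = c("target", "not_target")))
  ft <- fisherExact2x2(tab)
  list(table = tab, odds_ratio = ft$odds_ratio, p = ft$p)
}
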