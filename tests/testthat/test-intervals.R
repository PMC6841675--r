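test_that("posterior filter is strictly greater-than", {
  gr <- GRanges("chr1", IRanges(c(1, 100, 200), width = 50),
                score = c(0.89, 0.90, 0.91))
  kept <- filterPosterior(gr, 0.9)
  expect_identical(length(kept), 1L)
  expect_identical(start(kept), 200L)
  expect_identical(length(filterPosterior(GRanges(), 0.9)), 0L)
  all3 <- filterPosterior(gr, 0)
  expect_identical(length(all3), 3L)
  noScore <- GRanges("chr1", IRanges(1, 10))
  expect_error(filterPosterior(noScore), "missing")
})

test_that("reduction merges overlap and abutment but not 1-bp gaps", {
  ## BED [0,10) + [10,20) are GRanges [1,10] + [11,20]: abutting, merged
  ab <- GRanges("chr1", IRanges(c(1, 11), c(10, 20)))
  expect_identical(as.data.frame(reduceIntervals(ab))$start, 1L)
  expect_identical(as.data.frame(reduceIntervals(ab))$end, 20L)
  gap <- GRanges("chr1", IRanges(c(1, 12), c(10, 20)))
  expect_identical(length(reduceIntervals(gap)), 2L)
})

test_that("reduction matches the per-base boolean oracle on random sets", {
  for (s in 1:25) {
    gr <- randomIntervals(200, 2000, maxw = 40, seed = s)
    red <- reduceIntervals(gr)
    or <- reduceOracle(start(gr), end(gr), 2000L)
    expect_identical(start(red), or$starts)
    expect_identical(end(red), or$ends)
    expect_identical(sum(width(red)), or$coveredBases)
    ## idempotence
    expect_identical(as.data.frame(reduceIntervals(red)),
                     as.data.frame(red))
  }
})

test_that("opposite-direction conflicts closer than the minimum gap are
          removed symmetrically, strict at the boundary", {
  ## BED [1000,1100) vs [1150,1200): gap 50 < 73 -> both removed
  up <- reduceIntervals(GRanges("chr1", IRanges(1001, 1100)))
  down <- reduceIntervals(GRanges("chr1", IRanges(1151, 1200)))
  r <- conflictFilter(up, down)
  expect_identical(length(r$up), 0L)
  expect_identical(length(r$down), 0L)
  expect_identical(length(r$removed), 2L)

  ## gap exactly 73 -> both kept ("closer than" is strict)
  down73 <- reduceIntervals(GRanges("chr1", IRanges(1174, 1200)))
  r73 <- conflictFilter(up, down73)
  expect_identical(length(r73$up), 1L)
  expect_identical(length(r73$down), 1L)

  ## overlapping pair: gap 0 -> removed
  downOv <- reduceIntervals(GRanges("chr1", IRanges(1050, 1200)))
  rOv <- conflictFilter(up, downOv)
  expect_identical(length(rOv$up), 0L)

  ## asymmetric mode keeps the up member
  rAs <- conflictFilter(up, downOv, symmetric = FALSE)
  expect_identical(length(rAs$up), 1L)
  expect_identical(length(rAs$down), 0L)

  unred <- GRanges("chr1", IRanges(c(1, 5), c(10, 20)))
  expect_error(conflictFilter(unred, down), "reduced")
})

test_that("surviving up/down sets have min pairwise gap >= 73 by brute
          force", {
  for (s in 1:10) {
    up <- reduceIntervals(randomIntervals(40, 20000, maxw = 120,
                                          seed = s))
    down <- reduceIntervals(randomIntervals(40, 20000, maxw = 120,
                                            seed = s + 100))
    r <- conflictFilter(up, down)
    if (length(r$up) && length(r$down)) {
      gaps <- outer(seq_along(r$up), seq_along(r$down),
                    Vectorize(function(i, j)
                      GenomicRanges::distance(r$up[i], r$down[j])))
      expect_gte(min(gaps), 73)
    }
  }
})

test_that("promoter-window annotation follows the window arithmetic", {
  models <- oneGeneModels(5001L, 8000L, "+")
  cfg <- annotationConfig()
  mkIv <- function(mid) GRanges("chr1", IRanges(mid - 10L, mid + 10L))
  ## midpoint at 2600 (0-based in BED terms): inside [start-2500, start)
  expect_identical(annotateIntervals(mkIv(2601L), models,
                                     cfg)$category, "upstream")
  expect_identical(annotateIntervals(mkIv(8101L), models,
                                     cfg)$category, "downstream")
  expect_identical(annotateIntervals(mkIv(6000L), models,
                                     cfg)$category, "exon")
  far <- annotateIntervals(mkIv(100L), models, cfg)
  expect_identical(far$category, "intergenic")

  ## signed TSS distance: negative upstream
  expect_lt(annotateIntervals(mkIv(2601L), models, cfg)$tss_distance, 0)
  expect_gt(annotateIntervals(mkIv(6000L), models, cfg)$tss_distance, 0)

  ## on the minus strand the upstream window extends rightward
  mm <- oneGeneModels(5001L, 8000L, "-")
  expect_identical(annotateIntervals(mkIv(9000L), mm, cfg)$category,
                   "upstream")
  expect_identical(annotateIntervals(mkIv(4500L), mm, cfg)$category,
                   "downstream")
  expect_lt(annotateIntervals(mkIv(9000L), mm, cfg)$tss_distance, 0)
})

test_that("sub-features are classified by priority with intron fallback", {
  models <- oneGeneModels(5001L, 8000L, "+", withFeatures = TRUE)
  mkIv <- function(mid) GRanges("chr1", IRanges(mid - 5L, mid + 5L))
  expect_identical(annotateIntervals(mkIv(5100L), models)$category,
                   "five_prime_UTR")
  expect_identical(annotateIntervals(mkIv(5400L), models)$category,
                   "exon")
  expect_identical(annotateIntervals(mkIv(6500L), models)$category,
                   "intron")
  expect_identical(annotateIntervals(mkIv(7900L), models)$category,
                   "three_prime_UTR")
})

test_that("annotation assigns exactly one category per interval", {
  w <- generateIntervalWorld(intervalWorldSpec(seed = 6L))
  ann <- annotateIntervals(w$binding, w$models)
  expect_identical(nrow(ann), length(w$binding))
  cats <- c("upstream", "five_prime_UTR", "exon", "intron",
            "three_prime_UTR", "downstream", "intergenic")
  expect_true(all(ann$category %in% cats))
  expect_false(anyNA(ann$category))
})

test_that("three-set Venn counts: identical, disjoint and random sets", {
  a <- reduceIntervals(GRanges("chr1", IRanges(c(1, 100), c(10, 120))))
  vSame <- overlapSets(a, a, a)
  expect_true(all(vSame$pattern == "A+B+C"))
  expect_true(all(vSame$count == 2))

  b <- reduceIntervals(GRanges("chr1", IRanges(c(200, 300),
                                               c(210, 320))))
  cc <- reduceIntervals(GRanges("chr1", IRanges(400, 410)))
  vDis <- overlapSets(a, b, cc)
  expect_identical(sort(unique(vDis$pattern)), c("A", "B", "C"))
  expect_identical(vDis$count[vDis$set == "A"], 2L)

  for (s in 1:8) {
    x <- reduceIntervals(randomIntervals(30, 3000, seed = s))
    y <- reduceIntervals(randomIntervals(30, 3000, seed = s + 50))
    z <- reduceIntervals(randomIntervals(30, 3000, seed = s + 90))
    v <- overlapSets(x, y, z)
    ## conservation: each set's cells sum to its size
    sizes <- c(A = length(x), B = length(y), C = length(z))
    for (nm in names(sizes))
      expect_identical(sum(v$count[v$set == nm]),
                       as.integer(sizes[[nm]]))
    ## brute-force membership of the first set's elements
    inY <- vapply(seq_along(x), function(i)
      any(start(y) <= end(x)[i] & end(y) >= start(x)[i]), TRUE)
    expect_identical(sum(v$count[v$set == "A" &
                                   grepl("B", v$pattern)]),
                     as.integer(sum(inY)))
  }
})

test_that("TSS metaprofile: point mass at zero, bootstrap-size invariance
          and planted-offset recovery", {
  models <- oneGeneModels(5001L, 8000L, "+")
  atTss <- GRanges("chr1", IRanges(rep(4996L, 20), rep(5006L, 20)))
  mp <- tssMetaprofile(atTss, models, window = 1000L, bins = 20L,
                       B = 100L)
  expect_identical(attr(mp, "n"), 20L)
  zeroBin <- which(mp$mid == min(abs(mp$mid)) | mp$mid ==
                     -min(abs(mp$mid)))
  expect_equal(sum(mp$density) * diff(mp$mid)[1], 1, tolerance = 1e-9)
  expect_true(all(mp$density[-zeroBin] == 0))

  w <- generateIntervalWorld(intervalWorldSpec(seed = 9L))
  m1 <- tssMetaprofile(w$binding, w$models, B = 200L, seed = 1L)
  m2 <- tssMetaprofile(w$binding, w$models, B = 400L, seed = 1L)
  expect_identical(m1$density, m2$density)  # B affects the band only

  ## planted Normal(0, 600) offsets: compare bin masses analytically
  m3 <- tssMetaprofile(w$binding, w$models, window = 3000L, bins = 12L,
                       B = 100L, seed = 1L)
  bw <- diff(m3$mid)[1]
  pTot <- pnorm(3000, 0, 600) - pnorm(-3000, 0, 600)
  expected <- (pnorm(m3$mid + bw / 2, 0, 600) -
                 pnorm(m3$mid - bw / 2, 0, 600)) / pTot
  observed <- m3$density * bw
  n <- attr(m3, "n")
  se <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(observed - expected) < 4 * se + 3 / n))

  none <- GRanges("chr1", IRanges(100000L, 100100L))
  expect_error(tssMetaprofile(none, models, window = 1000L), "TSS")
})

test_that("gene-set enrichment builds the right table and detects planted
          signal", {
  bg <- sprintf("g%03d", 1:100)
  cls <- bg[1:40]
  tg <- bg[c(1:25, 90:95)]  # mostly inside the class
  r <- enrichment2x2(tg, cls, bg)
  expect_identical(r$table[1, 1], 25L)  # class & target
  expect_identical(sum(r$table), 100L)
  expect_gt(r$odds_ratio, 1)
  expect_lt(r$p, 0.01)
  expect_error(enrichment2x2(c(tg, "zzz"), cls, bg), "subset")

  deg <- enrichment2x2(bg, bg, bg)
  expect_identical(deg$odds_ratio, Inf)

  ## independent random labels keep the rejection rate at or below alpha
  withr::with_seed(31, {
    rej <- 0
    for (i in 1:200) {
      tgr <- sample(bg, 30)
      clr <- sample(bg, 40)
      if (enrichment2x2(tgr, clr, bg)$p < 0.05) rej <- rej + 1
    }
  })
  expect_lte(rej / 200, 0.05 + 0.03)
})
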