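## helper: constant CG methylation track with chosen values over regions
methTrackWith <- function(grid, base = 0.8, low = NULL, lowLevel = 0.02) {
  v <- rep(base, nBins(grid))
  if (!is.null(low))
    v[unique(queryHits(findOverlaps(binRanges(grid), low)))] <- lowLevel
  new("BinnedTrack", grid = grid, values = v)
}

test_that("FAIRE peaks classify into PRE, DRE and unclassified", {
  genome <- tinyGenome()
  grid <- makeBins(genome, 200)
  gm <- fixtureGenes()
  peaks <- GRanges("chr1", IRanges(c(801, 3050, 8000, 8500),
                                   c(950, 3250, 8200, 8700)))
  lowRegion <- GRanges("chr1", IRanges(8000, 8200))
  mt <- methTrackWith(grid, base = 0.4, low = lowRegion)
  cls <- classifyFaire(peaks, gm, mt)
  expect_equal(cls$class, c("PRE", "unclassified", "DRE", "unclassified"))
  ## peak near the TSS is proximal; distal one needs low methylation
  expect_equal(cls$reason[2], "genic")         # overlaps gB body
  expect_equal(cls$reason[4], "high_methylation")
  expect_lte(cls$mean_cg[3], 0.1)
  ## DRE and PRE sets are disjoint and no DRE touches a gene body
  expect_false(any(cls$class == "DRE" & cls$class == "PRE"))
  dre <- cls[cls$class == "DRE"]
  expect_false(any(overlapsAny(dre, geneRanges(gm), ignore.strand = TRUE)))
  ## missing methylation data flagged, not classified
  mtNA <- new("BinnedTrack", grid = grid,
              values = rep(NA_real_, nBins(grid)))
  clsNA <- classifyFaire(peaks[3], gm, mtNA)
  expect_equal(clsNA$class, "unclassified")
  expect_equal(clsNA$reason, "no_methylation_data")
})

test_that("planted elements are recovered with clean margins", {
  cfg <- simConfig(genome = c(chr1 = 2e6, chr2 = 2e6), nStates = 5,
                   emission = defaultEmission(5))
  ann <- simulateAnnotation(cfg, 41)
  els <- simulateElements(ann, cfg, 41)
  grid <- makeBins(genomeIndex(cfg$genome), 200)
  mt <- methTrackWith(grid, base = 0.5, low = els$lowMethRegions)
  cls <- classifyFaire(els$peaks, ann$genes, mt)
  for (what in c("DRE", "PRE")) {
    called <- cls$class == what
    truth <- els$peaks$true_class == what
    expect_gte(sum(called & truth) / sum(called), 0.95)  # precision
    expect_gte(sum(called & truth) / sum(truth), 0.95)   # recall
  }
})

test_that("DRE target linking is nearest-TSS with deterministic ties", {
  genome <- tinyGenome()
  gm <- geneModels(chrom = c("chr1", "chr1"), start = c(101, 1101),
                   end = c(500, 1500), strand = c("+", "+"),
                   gene_id = c("gNear", "gFar"), genome = genome)
  ## element at 701-800: 300-ish bp from TSS 1101, ~200 from TSS 101? no:
  ## distances: |101 - 701| vs |1101 - 800|; nearest is gFar (300 vs 599)
  dre <- GRanges("chr1", IRanges(701, 800))
  lk <- linkDreTargets(dre, gm)
  expect_equal(lk$gene_id, "gFar")
  ## exact equidistance: lexicographically smaller id wins
  gmT <- geneModels(chrom = c("chr1", "chr1"), start = c(101, 1100),
                    end = c(300, 1500), strand = c("+", "+"),
                    gene_id = c("gB", "gA"), genome = genome)
  mid <- GRanges("chr1", IRanges(501, 700))  # 199 bp to both TSSs
  expect_equal(linkDreTargets(mid, gmT)$gene_id, "gA")
  ## unlinked on a geneless chromosome
  expect_false(linkDreTargets(GRanges("chr2", IRanges(1, 50)), gm)$linked)
  set.seed(37)
  for (i in 1:10) {
    gmr <- randomGeneModels(10)
    q <- randomIntervals(20)
    expect_equal(linkDreTargets(q, gmr)$gene_id,
                 bruteNearestTss(q, gmr)$gene_id)
  }
})

test_that("tissue-specific DRE clusters recover planted structure", {
  cfg <- simConfig(genome = c(chr1 = 2e6, chr2 = 2e6), nStates = 5,
                   emission = defaultEmission(5))
  ann <- simulateAnnotation(cfg, 43)
  els <- simulateElements(ann, cfg, 43)
  isTs <- !is.na(els$peaks$true_tissue)
  sig <- els$signal[isTs, , drop = FALSE]
  truth <- els$peaks$true_tissue[isTs]
  cl <- clusterTissueDres(sig, k = 3, seed = 3)
  expect_gte(ari(cl$cluster, truth), 0.9)
  ## each cluster's maximal tissue is its planted tissue
  lab <- vapply(1:3, function(cc)
    names(which.max(table(truth[cl$cluster == cc]))), character(1))
  expect_equal(cl$maxTissue, lab)
  ## planted expression coupling: linked genes peak in the matching tissue
  segs <- simulateStates(cfg, ann, 43)
  fpkm <- simulateExpression(segs, ann$genes, cfg, 43,
                             boost = els$expressionBoost)
  links <- linkDreTargets(els$peaks[isTs], ann$genes)
  cl2 <- clusterTissueDres(sig, k = 3, seed = 3, fpkm = fpkm, links = links)
  for (cc in 1:3)
    expect_equal(names(which.max(cl2$linkedExpression[cc, ])),
                 cl2$maxTissue[cc])
  ## singleton clustering at k = rows
  few <- sig[1:4, ]
  expect_equal(sort(unname(table(clusterTissueDres(few, 4)$cluster))),
               rep(1L, 4), ignore_attr = TRUE)
})

test_that("the six loop/PRE categories follow the decision table", {
  genome <- tinyGenome()
  gm <- geneModels(chrom = rep("chr1", 4),
                   start = c(1001, 3001, 5001, 7001),
                   end = c(1800, 3800, 5800, 7800),
                   strand = "+", gene_id = c("g1", "g2", "g3", "g4"),
                   genome = genome)
  prom <- promoterWindows(gm)
  pres <- prom[c(1, 2)]  # g1 and g2 promoters carry PREs
  ## loops: g1 <-> g2 (both PRE), g3 <-> g2 (partner PRE); g4 untouched
  loops <- S4Vectors::Pairs(c(granges(prom[1]), granges(prom[3])),
                            c(granges(prom[2]), granges(prom[2])))
  res <- geneLoopCategories(gm, loops, pres)
  expect_equal(res$category[res$gene_id == "g1"], 1L)
  expect_equal(res$category[res$gene_id == "g2"], 1L)
  expect_equal(res$category[res$gene_id == "g3"], 3L)
  expect_equal(res$category[res$gene_id == "g4"], 6L)
  ## no loops at all: PRE promoters are category 5, others 6
  res5 <- geneLoopCategories(gm, loops[0], pres)
  expect_equal(res5$category, c(5L, 5L, 6L, 6L))
  ## property: category is a pure function of the three predicates
  set.seed(41)
  for (i in 1:20) {
    gmr <- randomGeneModels(8)
    promR <- promoterWindows(gmr)
    presR <- promR[runif(8) < 0.5]
    pick <- replicate(4, sample.int(8, 2), simplify = FALSE)
    loopsR <- S4Vectors::Pairs(
      do.call(c, lapply(pick, function(p) granges(promR[p[1]]))),
      do.call(c, lapply(pick, function(p) granges(promR[p[2]]))))
    resR <- geneLoopCategories(gmr, loopsR, presR)
    want <- with(resR, ifelse(looped,
                              ifelse(own_pre, ifelse(partner_pre, 1L, 2L),
                                     ifelse(partner_pre, 3L, 4L)),
                              ifelse(own_pre, 5L, 6L)))
    expect_identical(resR$category, want)
    ## the two impossible combinations never occur
    expect_false(any(resR$partner_pre & !resR$looped))
  }
})
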