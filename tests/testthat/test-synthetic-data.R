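smallCfg <- function(...) simConfig(genome = c(chr1 = 4e5, chr2 = 2e5),
                                    nStates = 5,
                                    emission = defaultEmission(5),
                                    annotation = modifyList(
                                      simConfig()$annotation,
                                      list(nGenes = 80L, nTEs = 80L)), ...)

test_that("the generator is deterministic under the master seed", {
  cfg <- smallCfg()
  a1 <- simulateAnnotation(cfg, 42); a2 <- simulateAnnotation(cfg, 42)
  expect_equal(geneRanges(a1$genes), geneRanges(a2$genes))
  expect_equal(a1$tes, a2$tes)
  s1 <- simulateStates(cfg, a1, 42); s2 <- simulateStates(cfg, a2, 42)
  expect_identical(stateLabels(s1[[2]]), stateLabels(s2[[2]]))
  t1 <- simulateTracks(s1[[1]], cfg, 42); t2 <- simulateTracks(s2[[1]], cfg, 42)
  expect_identical(binMatrix(t1$counts), binMatrix(t2$counts))
  ## a different seed changes the outputs
  expect_false(identical(stateLabels(simulateStates(cfg, a1, 43)[[1]]),
                         stateLabels(s1[[1]])))
  ## named substreams: adding a downstream component does not perturb others
  m1 <- simulateMethylome(s1[[1]], cfg, 42)
  expect_identical(binMatrix(simulateTracks(s1[[1]], cfg, 42)$counts),
                   binMatrix(t1$counts))
  expect_identical(simulateMethylome(s1[[1]], cfg, 42)$callsA, m1$callsA)
})

test_that("annotation respects density, non-overlap and class counts", {
  cfg <- smallCfg()
  ann <- simulateAnnotation(cfg, 7)
  g <- geneRanges(ann$genes)
  expect_equal(length(g), cfg$annotation$nGenes)
  ## pairwise non-overlapping by interval scan
  byChrom <- split(g, seqnames(g))
  for (ch in names(byChrom)) {
    x <- byChrom[[ch]]
    o <- order(start(x))
    expect_true(all(start(x)[o][-1] > end(x)[o][-length(x)]))
  }
  ## TSS upstream of ATG in transcription orientation
  neg <- as.character(strand(g)) == "-"
  expect_true(all(ifelse(neg, g$tss > g$atg, g$tss < g$atg)))
  ## zero density gives zero genes
  cfg0 <- simConfig(genome = c(chr1 = 4e5),
                    annotation = modifyList(simConfig()$annotation,
                                            list(nGenes = 0L)))
  expect_equal(length(simulateAnnotation(cfg0, 1)$genes), 0L)
  ## infeasible density errors
  cfgBad <- simConfig(genome = c(chr1 = 1e5),
                      annotation = modifyList(simConfig()$annotation,
                                              list(nGenes = 300L)))
  expect_error(simulateAnnotation(cfgBad, 1), "infeasible")
})

test_that("state paths honour stickiness, absorbing and switch-rate limits", {
  cfg <- simConfig(genome = c(chr1 = 2e6), nStates = 5,
                   emission = defaultEmission(5), stickiness = 0.9)
  segs <- simulateStates(cfg, NULL, 3)
  st <- stateLabels(segs[[1]])
  expect_equal(mean(st[-1] == st[-length(st)]), 0.9, tolerance = 0.02)
  ## absorbing chain: one state per chromosome
  cfg1 <- simConfig(genome = c(chr1 = 1e5, chr2 = 1e5), nStates = 5,
                    emission = defaultEmission(5), stickiness = 1)
  st1 <- stateLabels(simulateStates(cfg1, NULL, 3)[[1]])
  expect_equal(length(unique(st1[1:500])), 1L)
  expect_equal(length(unique(st1[501:1000])), 1L)
  ## zero tissue-switch rate: identical tissues
  cfg0 <- simConfig(genome = c(chr1 = 2e5), nStates = 5,
                    emission = defaultEmission(5), tissueSwitchRate = 0)
  s0 <- simulateStates(cfg0, NULL, 5)
  expect_identical(stateLabels(s0[[1]]), stateLabels(s0[[2]]))
  expect_error(simulateStates(simConfig(stickiness = 0), NULL, 1),
               "stickiness")
})

test_that("track counts follow the emission model and are recoverable", {
  cfg <- smallCfg()
  segs <- simulateStates(cfg, NULL, 9)
  ## all-zero emissions give pure background
  cfg0 <- smallCfg()
  cfg0$emission[] <- 0
  tr0 <- simulateTracks(segs[[1]], cfg0, 9)
  expect_true(all(binMatrix(tr0$presence) == 0))
  expect_lt(mean(binMatrix(tr0$counts)), 3 * 30 / 21)
  ## fg/bg 20 at depth 30: binarization recovers the recorded presence truth
  tr <- simulateTracks(segs[[1]], cfg, 9)
  B <- binarizeMatrix(tr$counts, tr$input)
  expect_gte(mean(binMatrix(B) == binMatrix(tr$presence)), 0.98)
})

test_that("methylome marginals match the configuration", {
  cfg <- smallCfg()
  segs <- simulateStates(cfg, NULL, 15)
  sim <- simulateMethylome(segs[[1]], cfg, 15, nDMR = 0)
  tab <- table(sim$callsA$context) / nrow(sim$callsA)
  want <- cfg$methylome$density / sum(cfg$methylome$density)
  expect_equal(as.numeric(tab[names(want)]), as.numeric(want),
               tolerance = 0.02)
  expect_equal(mean(sim$callsA$total), cfg$methylome$coverage,
               tolerance = 0.05)
  ## zero planted delta: empty truth
  expect_equal(nrow(sim$truth), 0L)
  expect_equal(nrow(simulateMethylome(segs[[1]], cfg, 15,
                                      dmrDelta = 0)$truth), 0L)
  ## all-zero density errors
  cfgz <- smallCfg()
  cfgz$methylome$density[] <- 0
  expect_error(simulateMethylome(segs[[1]], cfgz, 1), "density")
})

test_that("expression follows promoter-state categories", {
  cfg <- simConfig(genome = c(chr1 = 2e6), nStates = 5,
                   emission = defaultEmission(5),
                   annotation = modifyList(simConfig()$annotation,
                                           list(nGenes = 500L)))
  ann <- simulateAnnotation(cfg, 31)
  segs <- simulateStates(cfg, ann, 31)
  fpkm <- simulateExpression(segs, ann$genes, cfg, 31)
  expect_equal(dim(fpkm), c(500L, 3L))
  g <- geneRanges(ann$genes)
  grid <- binGrid(segs[[1]])
  cats <- stateCategories(cfg$emission)
  tssCat <- cats[stateLabels(segs[[1]])[
    globalBinIndex(grid, as.character(seqnames(g)), g$tss)]]
  med <- tapply(fpkm[, 1], tssCat, median)
  ## category medians preserve the configured ordering
  expect_gt(med["active"], med["Quies"])
  expect_gt(med["Quies"], med["inactive"])
  ## repressed and heterochromatic genes are mostly unexpressed
  expect_gt(mean(fpkm[tssCat == "inactive", 1] < 1), 0.9)
  ## determinism
  expect_identical(fpkm, simulateExpression(segs, ann$genes, cfg, 31))
})

test_that("panel divergence rates and planted differences behave", {
  cfg <- smallCfg()
  segs <- simulateStates(cfg, NULL, 23)
  ## zero rates and no planting: all varieties identical
  cfg0 <- smallCfg(panel = modifyList(simConfig()$panel,
                                      list(withinRate = 0, betweenRate = 0,
                                           nFixedDiff = 0L)))
  p0 <- simulatePanel(segs[[1]], cfg0, 23)
  for (v in names(p0$segs))
    expect_identical(stateLabels(p0$segs[[v]]), stateLabels(segs[[1]]))
  ## planted fixed differences are exactly recoverable at zero divergence
  cfgF <- smallCfg(panel = modifyList(simConfig()$panel,
                                      list(withinRate = 0, betweenRate = 0,
                                           nFixedDiff = 50L)))
  pf <- simulatePanel(segs[[1]], cfgF, 23)
  expect_equal(nrow(pf$truth), 50L)
  groups <- split(names(pf$subgroup), pf$subgroup)
  ss <- subgroupSwitch(pf$segs, groups$Xian, groups$Geng)
  expect_identical(ss$bins$bin, pf$truth$bin)
  expect_identical(ss$bins$state_A, pf$truth$state_A)
  expect_identical(ss$bins$state_B, pf$truth$state_B)
  ## SNP flank enrichment: flanks of heterochromatin runs are densest
  cfgS <- smallCfg()
  ps <- simulatePanel(segs[[1]], cfgS, 23)
  expect_true(all(lengths(ps$snps) > 0))
})
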