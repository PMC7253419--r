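mkSegP <- function(states, K, grid) new("Segmentation", grid = grid,
                                        states = as.integer(states),
                                        K = as.integer(K))

test_that("conserved fractions are exact for identical and relabeled panels", {
  grid <- makeBins(genomeIndex(c(chr1 = 20000)), 200)
  set.seed(51)
  st <- sample.int(3L, nBins(grid), replace = TRUE)
  panel <- list(a = mkSegP(st, 3, grid), b = mkSegP(st, 3, grid),
                c = mkSegP(st, 3, grid))
  expect_equal(unname(conservedFraction(panel)), rep(1, 3))
  ## one variety fully relabeled (cyclic shift): nothing is conserved
  panel$c <- mkSegP(st %% 3L + 1L, 3, grid)
  expect_equal(unname(conservedFraction(panel)), rep(0, 3))
  ## independent random panel at K = 3, n = 3: closed form K^-(n-1) per state
  grid2 <- makeBins(genomeIndex(c(chr1 = 2e7)), 200)  # 1e5 bins
  big <- lapply(1:3, function(i)
    mkSegP(sample.int(3L, nBins(grid2), replace = TRUE), 3, grid2))
  got <- conservedFraction(big)
  want <- 1 / 9  # P(two other varieties match) given the first
  sdPois <- sqrt((1e5 / 3) * want) / (1e5 / 3)  # ~3 sigma binomial bound
  expect_true(all(abs(got - want) < 3 * sdPois))
  expect_error(conservedFraction(big[1]), "at least 2")
})

test_that("subgroup switches recover planted differences and similarities", {
  cfg <- simConfig(genome = c(chr1 = 4e5, chr2 = 2e5), nStates = 5,
                   emission = defaultEmission(5),
                   annotation = modifyList(simConfig()$annotation,
                                           list(nGenes = 60L, nTEs = 50L)),
                   panel = modifyList(simConfig()$panel,
                                      list(withinRate = 0, betweenRate = 0,
                                           nFixedDiff = 50L)))
  segs <- simulateStates(cfg, NULL, 53)
  panel <- simulatePanel(segs[[1]], cfg, 53)
  groups <- split(names(panel$subgroup), panel$subgroup)
  ss <- subgroupSwitch(panel$segs, groups$Xian, groups$Geng,
                       otherGroups = groups[c("Aus", "aromatic")])
  ## exact set equality with the planted truth
  expect_identical(ss$bins$bin, panel$truth$bin)
  expect_identical(ss$bins$state_A, panel$truth$state_A)
  ## the normalized matrix counts each planted cell over fraction x bins
  K <- 5; n <- nBins(binGrid(segs[[1]]))
  fr <- tabulate(unlist(lapply(panel$segs, stateLabels)), K) /
    (n * length(panel$segs))
  cnt <- table(factor(panel$truth$state_A, 1:K),
               factor(panel$truth$state_B, 1:K))
  expect_equal(unname(ss$matrix), unname(cnt / (fr * n)), tolerance = 1e-12)
  ## other groups still carry the base state: similarity is computable
  expect_true(all(ss$similarity[, "A"] + ss$similarity[, "B"] <= 1 + 1e-12))
  ## a third group identical to A scores similarity 1 vs 0
  ssA <- subgroupSwitch(panel$segs, groups$Xian, groups$Geng,
                        otherGroups = list(XianCopy = groups$Xian))
  expect_equal(unname(ssA$similarity["XianCopy", ]), c(1, 0))
  ## identical groups produce no consensus bins, not an error
  ss0 <- subgroupSwitch(panel$segs, groups$Aus, groups$aromatic)
  expect_equal(nrow(ss0$bins), 0L)
  expect_error(subgroupSwitch(panel$segs, groups$Xian, groups$Xian),
               "disjoint")
})

test_that("SNP profiles measure densities in flanks, body and boundary mode", {
  set.seed(55)
  peaks <- GRanges("chr1", IRanges(c(5001, 12001), c(6000, 13500)))
  ## SNPs only inside peaks: flank units are zero
  inPos <- c(5100, 5500, 5900, 12100, 13000)
  snpsIn <- GRanges("chr1", IRanges(inPos, width = 1))
  profIn <- snpProfile(snpsIn, peaks)
  expect_true(all(profIn$density[profIn$zone != "body"] == 0))
  expect_true(sum(profIn$density[profIn$zone == "body"]) > 0)
  ## uniform random SNPs: densities fluctuate around the global rate
  rate <- 0.02
  pos <- sort(sample.int(40000, round(40000 * rate)))
  snps <- GRanges("chr1", IRanges(pos, width = 1))
  prof <- snpProfile(snps, peaks, flank = 2000, unit = 10)
  ## Poisson 3-sigma band per unit: unit bp = 10 x 2 peaks
  sigma <- sqrt(rate / 20)
  expect_true(mean(abs(prof$density - rate) < 3 * sigma) > 0.98)
  ## boundary mode: 20 units over 1 kb before the peak
  bd <- snpProfile(snps, peaks, boundaryMode = TRUE)
  expect_equal(nrow(bd), 20L)
  expect_true(all(bd$zone == "upstream"))
  expect_error(snpProfile(snps, peaks[0]), "non-empty")
})

test_that("SNP flank enrichment around heterochromatin is detectable", {
  cfg <- simConfig(genome = c(chr1 = 2e6), nStates = 5,
                   emission = defaultEmission(5))
  segs <- simulateStates(cfg, NULL, 57)
  panel <- simulatePanel(segs[[1]], cfg, 57)
  v <- names(panel$segs)[1]
  prof <- snpProfile(panel$snps[[v]], panel$regions$H3K9me2[[v]],
                     boundaryMode = TRUE)
  ## density rises toward the peak boundary (monotone trend, positive slope)
  fit <- lm(density ~ unit, data = prof)
  expect_gt(unname(coef(fit)[2]), 0)
})

test_that("saturation curves are monotone and flat for identical varieties", {
  genome <- genomeIndex(c(chr1 = 1e5))
  rset <- GRanges("chr1", IRanges(c(1, 50001), c(10000, 60000)))
  same <- list(a = rset, b = rset, c = rset)
  sat <- saturationCurve(same, genome, nOrders = 5, seed = 1)
  expect_equal(sat$accumulation_mean, rep(0.2, 3))
  expect_equal(sat$accumulation_sd, rep(0, 3))
  ## disjoint region sets accumulate linearly
  disj <- list(a = GRanges("chr1", IRanges(1, 10000)),
               b = GRanges("chr1", IRanges(20001, 30000)),
               c = GRanges("chr1", IRanges(40001, 50000)))
  satD <- saturationCurve(disj, genome, nOrders = 4, seed = 2)
  expect_equal(satD$accumulation_mean, c(0.1, 0.2, 0.3))
  ## pairwise differential fractions averaged over prefix pairs
  pd <- matrix(0.4, 3, 3, dimnames = list(names(disj), names(disj)))
  diag(pd) <- 0
  satP <- saturationCurve(disj, genome, pairwiseDiff = pd, nOrders = 3,
                          seed = 3)
  expect_true(is.na(satP$differential_mean[1]))
  expect_equal(satP$differential_mean[2:3], c(0.4, 0.4))
  expect_error(saturationCurve(disj, genome, nOrders = 0), "nOrders")
  ## monotone accumulation on simulated shared-core + private regions
  set.seed(5)
  core <- GRanges("chr1", IRanges(1, 20000))
  rl <- lapply(1:5, function(i)
    c(core, GRanges("chr1", IRanges(sample(60000:90000, 1), width = 5000))))
  names(rl) <- paste0("v", 1:5)
  satC <- saturationCurve(rl, genome, nOrders = 10, seed = 4)
  expect_true(all(diff(satC$accumulation_mean) >= 0))
})

test_that("epigenome distances separate planted subgroups", {
  ## identical tracks: all distances zero
  sig <- matrix(rpois(400, 10), 100, 4,
                dimnames = list(NULL, paste0("v", 1:4)))
  same <- cbind(v1 = sig[, 1], v2 = sig[, 1], v3 = sig[, 1])
  expect_true(all(epigenomeDistance(same)$dist == 0))
  ## Bray-Curtis of disjoint indicator vectors is 1
  d2 <- epigenomeDistance(cbind(a = c(1, 0), b = c(0, 1)))$dist
  expect_equal(as.numeric(d2), 1)
  ## planted 2-subgroup panel: within < between distances
  cfg <- simConfig(genome = c(chr1 = 4e5), nStates = 5,
                   emission = defaultEmission(5),
                   panel = modifyList(simConfig()$panel,
                                      list(withinRate = 0.02,
                                           betweenRate = 0.25)))
  segs <- simulateStates(cfg, NULL, 59)
  panel <- simulatePanel(segs[[1]], cfg, 59)
  dm <- as.matrix(epigenomeDistance(panel$signal$H3K9me2)$dist)
  sub <- panel$subgroup[colnames(dm)]
  withinM <- mean(dm[outer(sub, sub, "==") & upper.tri(dm)])
  betweenM <- mean(dm[outer(sub, sub, "!=") & upper.tri(dm)])
  expect_lt(withinM, betweenM)
  ## the spearman variant is symmetric with zero diagonal
  ds <- as.matrix(epigenomeDistance(sig, metric = "1-spearman")$dist)
  expect_equal(ds, t(ds))
  expect_true(all(diag(ds) == 0))
  expect_error(epigenomeDistance(sig, metric = "euclid"), "arg")
})

test_that("core/distributed proportions conserve counts", {
  tab <- rbind(g1 = c(TRUE, TRUE), g2 = c(TRUE, FALSE), g3 = c(FALSE, TRUE),
               g4 = c(TRUE, TRUE), g5 = c(FALSE, FALSE),
               g6 = c(TRUE, FALSE), g7 = c(TRUE, TRUE), g8 = c(FALSE, TRUE),
               g9 = c(TRUE, FALSE), g10 = c(TRUE, TRUE))
  colnames(tab) <- c("H3K4me3", "H3K27me3")
  lab <- setNames(rep(c("core", "distributed"), c(6, 4)), rownames(tab))
  got <- coreVsDistributed(tab, lab)
  ## manual tally: 7 H3K4me3-marked genes; 4 core (g1,g2,g4,g6), 3 distributed
  expect_equal(unname(got["H3K4me3", ]), c(4, 3) / 7)
  expect_equal(rowSums(got), c(H3K4me3 = 1, H3K27me3 = 1))
  ## all-core input gives proportions (1, 0)
  labC <- setNames(rep("core", 10), rownames(tab))
  expect_equal(unname(coreVsDistributed(tab, labC)[, "core"]), c(1, 1))
  expect_error(coreVsDistributed(tab, lab[-1]), "unlabeled")
})
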