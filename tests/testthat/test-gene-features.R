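test_that("peak-to-gene assignment follows the 1-bp overlap rule", {
  gm <- fixtureGenes()
  ## half-open-adjacent peak (ends where the gene starts) is not assigned
  peaks <- GRanges("chr1", IRanges(c(801, 900, 1990, 2500),
                                   c(1000, 1001, 3100, 2600)))
  asg <- assignPeaksToGenes(peaks, gm)
  expect_false(any(asg$peak_index == 1 & asg$gene_id == "gA"))
  ## 1-bp overlap assigns; a peak spanning two genes is assigned to both
  expect_true(any(asg$peak_index == 2 & asg$gene_id == "gA"))
  expect_setequal(asg$gene_id[asg$peak_index == 3], c("gA", "gB"))
  ## random instance vs brute force
  set.seed(17)
  for (i in 1:20) {
    gmr <- randomGeneModels(12)
    pk <- randomIntervals(20)
    got <- assignPeaksToGenes(pk, gmr)
    want <- bruteOverlap(granges(geneRanges(gmr)), pk)
    expect_equal(got$gene_id, geneRanges(gmr)$gene_id[want$a_index])
    expect_equal(got$peak_index, want$b_index)
  }
})

test_that("mark combination classes are the exact present subset", {
  tab <- rbind(g1 = c(TRUE, FALSE, FALSE),
               g2 = c(TRUE, TRUE, TRUE),
               g3 = c(FALSE, FALSE, FALSE))
  colnames(tab) <- c("H3K4me3", "H3K27ac", "RNAPII")
  cls <- markCombinationClass(tab)
  expect_equal(unname(cls), c("H3K4me3", "H3K4me3+H3K27ac+RNAPII", "none"))
  expect_equal(unname(markCombinationClass(tab, c("H3K27ac", "RNAPII"))["g2"]),
               "H3K27ac+RNAPII")
  expect_error(markCombinationClass(tab, "absent"), "missing")
})

test_that("summit position classes follow transcription orientation", {
  gm <- fixtureGenes()  # gA: + 1001..2000 tss 1001 atg 1101; gB: - tss 4500 atg 4400
  pk <- GRanges("chr1", IRanges(c(901, 1020, 1500, 4420), width = 100))
  pk$summit <- c(951, 1050, 1550, 4450)
  pk$score <- c(5, 9, 2, 4)
  cls <- summitPositionClass(gm, pk)
  expect_equal(unname(cls["gA"]), "tss_atg")   # strongest peak summit 1050
  expect_equal(unname(cls["gC"]), "unmarked")
  ## on the minus strand, summit between tss (4500) and atg (4400) is tss_atg
  expect_equal(unname(cls["gB"]), "tss_atg")
  ## upstream case: summit 5-prime of the TSS
  pk2 <- GRanges("chr1", IRanges(901, 1000))
  pk2$summit <- 951; pk2$score <- 1
  expect_equal(unname(summitPositionClass(gm, pk2)["gA"]), "upstream")
  ## brute-force agreement on random instances (midpoint summits)
  set.seed(23)
  for (i in 1:10) {
    gmr <- randomGeneModels(10)
    pkr <- randomIntervals(15)
    pkr$score <- runif(15)
    got <- summitPositionClass(gmr, pkr, upstreamWindow = 500L)
    g <- geneRanges(gmr)
    summit <- (start(pkr) + end(pkr)) %/% 2L
    for (gi in seq_along(g)) {
      neg <- as.character(strand(g))[gi] == "-"
      lo <- if (neg) start(g)[gi] else start(g)[gi] - 500L
      hi <- if (neg) end(g)[gi] + 500L else end(g)[gi]
      cand <- which(as.character(seqnames(pkr)) ==
                      as.character(seqnames(g))[gi] &
                    start(pkr) <= hi & end(pkr) >= lo)
      wantCls <- "unmarked"
      if (length(cand)) {
        best <- cand[order(-pkr$score[cand],
                           abs(summit[cand] - g$tss[gi]))][1]
        rel <- if (neg) g$tss[gi] - summit[best] else summit[best] - g$tss[gi]
        relAtg <- if (neg) g$tss[gi] - g$atg[gi] else g$atg[gi] - g$tss[gi]
        wantCls <- if (rel < 0) "upstream"
                   else if (rel > relAtg) "downstream" else "tss_atg"
      }
      expect_equal(unname(got[g$gene_id[gi]]), wantCls)
    }
  }
})

test_that("expression breadth counts strict threshold crossings", {
  fp <- rbind(g1 = c(1.0, 1.0001, 5), g2 = c(0, 0, 0), g3 = c(2, 3, 4))
  colnames(fp) <- c("t1", "t2", "t3")
  br <- expressionBreadth(fp)
  expect_equal(unname(br), c(2L, 0L, 3L))
  ## conservation: histogram total equals gene count
  expect_equal(sum(table(br)), nrow(fp))
  expect_error(expressionBreadth(rbind(c(-1, 2))), "negative")
  set.seed(3)
  big <- matrix(rexp(200 * 20), 200, 20,
                dimnames = list(sprintf("g%03d", 1:200), NULL))
  expect_equal(unname(expressionBreadth(big)),
               unname(apply(big, 1, function(r) sum(r > 1))))
})

test_that("promoter profiles have the declared geometry and cluster", {
  gm <- fixtureGenes()
  ## flat unit tracks: profile is 401 positions per mark, all ratio 1
  genome <- tinyGenome()
  flat <- GRanges(rep(c("chr1", "chr2"), c(1, 1)),
                  IRanges(1, c(10000, 4000)), score = 1)
  prof <- promoterProfiles(gm, list(H3K4me3 = flat, FAIRE = flat), flat)
  expect_equal(dim(prof), c(4L, 2L * 401L))
  expect_true(all(prof == 1))
  ## planted archetypes recovered at k = 3
  set.seed(29)
  npos <- 401
  arch <- function(kind, n) {
    t(vapply(seq_len(n), function(i) {
      x <- rnorm(npos, 0.2, 0.05)
      if (kind == "active") x[150:250] <- rnorm(101, 8, 0.5)
      if (kind == "flank") x[1:120] <- rnorm(120, 6, 0.5)
      pmax(x, 0)
    }, numeric(npos)))
  }
  mat <- rbind(arch("active", 60), arch("flank", 60), arch("blank", 60))
  rownames(mat) <- sprintf("g%03d", seq_len(nrow(mat)))
  truth <- rep(1:3, each = 60)
  cl <- promoterProfileClusters(mat, k = 3, minCluster = 10, seed = 2)
  expect_gte(ari(cl$cluster, truth), 0.9)
  expect_length(cl$smallClusters, 0)
  ## identical profiles: degenerate flag
  same <- matrix(1, 10, npos)
  expect_true(promoterProfileClusters(same, 2, minCluster = 2)$degenerate)
})

test_that("TE insertion classes let exon dominate intron", {
  genome <- tinyGenome()
  ## gene with two exons 1001-1200 and 1801-2000 (intron between)
  gm <- geneModels("chr1", 1001, 2000, "+", "gX", atg = 1051,
                   exons = list(gX = GRanges("chr1", IRanges(c(1001, 1801),
                                                             c(1200, 2000)))),
                   genome = genome)
  tes <- GRanges("chr1", IRanges(c(1150, 1300, 3000), c(1350, 1500, 3100)))
  tes$family <- c("Copia", "Copia", "Gypsy")
  cls <- teInsertionClass(gm, tes)
  ## TE spanning the exon-intron junction counts as exon
  expect_equal(unname(cls["gX", "Copia"]), "exon")
  expect_equal(unname(cls["gX", "Gypsy"]), "none")
  tesIn <- GRanges("chr1", IRanges(1300, 1500))
  tesIn$family <- "Copia"
  expect_equal(unname(teInsertionClass(gm, tesIn)["gX", "Copia"]), "intron")
  ## brute-force agreement on random instances
  set.seed(31)
  for (i in 1:10) {
    gmr <- randomGeneModels(8)
    ter <- randomIntervals(12)
    ter$family <- sample(c("Copia", "Gypsy"), 12, TRUE)
    got <- teInsertionClass(gmr, ter)
    g <- geneRanges(gmr)
    for (gi in seq_along(g)) for (fam in c("Copia", "Gypsy")) {
      sub <- ter[ter$family == fam]
      ov <- bruteOverlap(granges(g[gi]), sub)
      want <- "none"
      if (nrow(ov)) {
        ex <- geneExons(gmr)[[g$gene_id[gi]]]
        hitsExon <- any(vapply(ov$b_index, function(j)
          nrow(bruteOverlap(ex, sub[j])) > 0, logical(1)))
        want <- if (hitsExon) "exon" else "intron"
      }
      expect_equal(unname(got[g$gene_id[gi], fam]), want)
    }
  }
})
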