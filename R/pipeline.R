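#' @include AllGenerics.R
NULL

.writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = TRUE,
              col.names = NA)
  path
}

.writeTsvPlain <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-epigenome analysis pipeline
#'
#' Generates a synthetic multi-tissue, multi-variety epigenome under one
#' seed, then runs every analysis stage of the package over it - state
#' segmentation (binarize, fit, decode, annotate), DMR calling and
#' state-switch coupling, tissue-pair switching matrices, a differential
#' mark comparison, mark/expression fold-change correlation, DRE/PRE
#' classification with loop gene categories, and the variety-panel
#' statistics - writing every declared output file under \code{outDir}.
#'
#' @param outDir output directory (created if absent).
#' @param seed master seed driving all randomness.
#' @param config a \code{\link{simConfig}}.
#' @param hmmInit,hmmMaxIter EM effort knobs passed to
#'   \code{\link{fitStateHMM}}.
#' @return invisibly, a list of the in-memory results plus \code{files},
#'   the manifest of written paths.
#' @export
runPipeline <- function(outDir, seed = 1L, config = simConfig(),
                        hmmInit = 3L, hmmMaxIter = 100L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outDir, paste0(...))
  files <- character()
  addf <- function(path) files <<- c(files, path)
  grid <- .simGrid(config)
  tissues <- config$tissues

  ## ---- simulate ------------------------------------------------------
  ann <- simulateAnnotation(config, seed)
  addf(writeGffGenes(ann$genes, p("genes.gff3")))
  te <- ann$tes; te$name <- te$family
  addf(writeBed(te, p("tes.bed")))
  segs <- simulateStates(config, ann, seed)
  els <- simulateElements(ann, config, seed)
  addf(writeBedpe(els$loops, p("loops.bedpe")))
  tracks <- lapply(tissues, function(tt)
    simulateTracks(segs[[tt]], config, seed, stream = tt))
  names(tracks) <- tissues
  for (tt in tissues) {
    addf(writeBedGraph(tracks[[tt]]$input, p("input_", tt, ".bedGraph")))
    for (mk in config$marks)
      addf(writeBedGraph(
        .BinnedTrack(grid, binMatrix(tracks[[tt]]$counts)[, mk]),
        p(mk, "_", tt, ".bedGraph")))
  }
  meth <- simulateMethylome(segs[[1L]], config, seed,
                            lowMethRegions = els$lowMethRegions)
  addf(writeMethCalls(meth$callsA, p("meth_sampleA.tsv")))
  addf(writeMethCalls(meth$callsB, p("meth_sampleB.tsv")))
  fpkm <- simulateExpression(segs, ann$genes, config, seed,
                             boost = els$expressionBoost)
  addf(writeFpkm(fpkm, p("fpkm.tsv")))

  ## ---- segmentation --------------------------------------------------
  binarized <- lapply(tissues, function(tt)
    binarizeMatrix(tracks[[tt]]$counts, tracks[[tt]]$input))
  names(binarized) <- tissues
  model <- fitStateHMM(binarized, config$nStates, seed = seed,
                       nInit = hmmInit, maxIter = hmmMaxIter)
  addf(.writeTsv(emissionProbs(model), p("emissions.tsv")))
  addf(.writeTsv(transitionProbs(model), p("transitions.tsv")))
  decoded <- lapply(binarized, function(b) decodeStates(model, b))
  for (tt in tissues) {
    br <- binRanges(grid)
    br$name <- paste0("S", stateLabels(decoded[[tt]]))
    addf(writeBed(br, p("segmentation_", tt, ".bed")))
  }
  annot <- annotateStates(decoded[[1L]], model, ann$genes, ann$tes)
  addf(.writeTsv(data.frame(coverage = annot$coverage,
                            category = annot$categories),
                 p("state_annotation.tsv")))
  addf(.writeTsv(annot$enrichment, p("state_enrichment.tsv")))

  ## ---- methylation ---------------------------------------------------
  dmrs <- callDMRs(meth$callsA, meth$callsB, grid,
                   context = config$methylome$dmrContext)
  dmrBed <- dmrs
  if (length(dmrBed)) {
    dmrBed$name <- paste0("DMR_", dmrBed$direction)
    dmrBed$score <- abs(dmrBed$delta)
  }
  addf(writeBed(dmrBed, p("dmrs.bed")))
  coupling <- dmrStateCoupling(dmrs, decoded[[1L]], decoded[[2L]])
  addf(.writeTsv(coupling$log10, p("dmr_coupling_log10.tsv")))
  addf(.writeTsv(coupling$counts, p("dmr_coupling_counts.tsv")))

  ## ---- state dynamics ------------------------------------------------
  pairs <- utils::combn(tissues, 2L, simplify = FALSE)
  sw <- lapply(pairs, function(pr)
    switchMatrix(decoded[[pr[1L]]], decoded[[pr[2L]]]))
  pooled <- combineSwitchMatrices(sw)
  addf(.writeTsv(switchCounts(pooled), p("switch_counts.tsv")))
  addf(.writeTsv(switchProbs(pooled), p("switch_probabilities.tsv")))
  addf(.writeTsv(pooled@log10Enrichment, p("switch_log10_enrichment.tsv")))

  ## differential H3K27ac between the first two tissues over merged peaks
  mk <- "H3K27ac"
  peakOf <- function(tt) reduce(binRanges(grid)[
    binMatrix(binarized[[tt]])[, mk] == 1], ignore.strand = TRUE)
  regions <- reduce(c(peakOf(tissues[1L]), peakOf(tissues[2L])),
                    ignore.strand = TRUE)
  diffres <- differentialRegions(
    .BinnedTrack(grid, binMatrix(tracks[[tissues[1L]]]$counts)[, mk]),
    .BinnedTrack(grid, binMatrix(tracks[[tissues[2L]]]$counts)[, mk]),
    regions)
  addf(.writeTsvPlain(diffres, p("differential_", mk, ".tsv")))

  ## promoter H3K4me3 fold-change vs expression fold-change
  prom <- promoterWindows(ann$genes)
  promCounts <- function(tt) {
    v <- binMatrix(tracks[[tt]]$counts)[, "H3K4me3"]
    hits <- findOverlaps(prom, binRanges(grid))
    out <- rowsum(v[subjectHits(hits)], queryHits(hits))
    res <- setNames(numeric(length(prom)), prom$gene_id)
    res[as.integer(rownames(out))] <- out[, 1L]
    res
  }
  fcp <- foldChangePairs(promCounts(tissues[1L]), promCounts(tissues[2L]),
                         fpkm[, tissues[1L]], fpkm[, tissues[2L]])
  fcc <- fcCorrelation(fcp)
  addf(.writeTsvPlain(data.frame(r = fcc$r, slope = fcc$slope, n = fcc$n),
                      p("fc_correlation.tsv")))
  breadth <- expressionBreadth(fpkm)
  addf(.writeTsvPlain(data.frame(gene_id = names(breadth),
                                 breadth = breadth), p("breadth.tsv")))

  ## ---- regulatory elements -------------------------------------------
  cgTrack <- methylationTrack(meth$callsA, grid, "CG")
  cls <- classifyFaire(els$peaks, ann$genes, cgTrack)
  clsBed <- cls; clsBed$name <- cls$class
  addf(writeBed(clsBed, p("elements.bed")))
  links <- linkDreTargets(cls[cls$class == "DRE"], ann$genes)
  addf(.writeTsvPlain(links, p("dre_links.tsv")))
  dreSignal <- els$signal[els$peaks$true_class == "DRE" &
                            !is.na(els$peaks$true_tissue), , drop = FALSE]
  dcl <- clusterTissueDres(dreSignal, k = length(tissues), seed = seed)
  addf(.writeTsv(dcl$centers, p("dre_cluster_centers.tsv")))
  glc <- geneLoopCategories(ann$genes, els$loops,
                            cls[cls$class == "PRE"])
  addf(.writeTsvPlain(glc, p("gene_loop_categories.tsv")))

  ## ---- variety panel -------------------------------------------------
  panel <- simulatePanel(segs[[1L]], config, seed)
  cons <- conservedFraction(panel$segs)
  addf(.writeTsvPlain(data.frame(state = names(cons), conserved = cons),
                      p("conserved_fraction.tsv")))
  groups <- split(names(panel$subgroup), panel$subgroup)
  ss <- subgroupSwitch(panel$segs, groups$Xian, groups$Geng,
                       otherGroups = groups[setdiff(names(groups),
                                                    c("Xian", "Geng"))])
  addf(.writeTsv(ss$matrix, p("subgroup_switch_matrix.tsv")))
  if (!is.null(ss$similarity))
    addf(.writeTsv(ss$similarity, p("subgroup_similarity.tsv")))
  v1 <- names(panel$segs)[1L]
  addf(writeBed(panel$snps[[v1]], p("snps_", v1, ".bed")))
  prof <- snpProfile(panel$snps[[v1]], panel$regions$H3K9me2[[v1]])
  addf(.writeTsvPlain(prof, p("snp_profile_H3K9me2.tsv")))
  sat <- saturationCurve(panel$regions$H3K4me1, grid@seqinfo,
                         nOrders = 10L, seed = seed)
  addf(.writeTsvPlain(sat, p("saturation_H3K4me1.tsv")))
  dist <- epigenomeDistance(panel$signal$H3K9me2)
  addf(.writeTsv(as.matrix(dist$dist), p("epigenome_distance_H3K9me2.tsv")))

  invisible(list(config = config, annotation = ann, states = segs,
                 tracks = tracks, binarized = binarized, model = model,
                 decoded = decoded, stateAnnotation = annot, meth = meth,
                 dmrs = dmrs, coupling = coupling, switch = pooled,
                 differential = diffres, fcCorrelation = fcc, fpkm = fpkm,
                 elements = cls, loopCategories = glc, panel = panel,
                 conserved = cons, subgroupSwitch = ss,
                 snpProfile = prof, saturation = sat, distance = dist,
                 files = files))
}
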