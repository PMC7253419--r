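#' @include AllGenerics.R
NULL

#' Classify open-chromatin peaks into DRE and PRE
#'
#' Proximal regulatory elements (PRE) are peaks whose nearest TSS lies
#' within \code{preDistance} bp or which overlap a promoter window.  Distal
#' regulatory elements (DRE) are peaks overlapping neither a gene body nor a
#' promoter window whose mean CG methylation is at most \code{lowmethMax}
#' (low or no methylation); intergenic peaks with higher methylation, or
#' without methylation data, remain unclassified with a reason, as do genic
#' peaks beyond the proximal distance.
#'
#' @param peaks GRanges of open-chromatin peaks.
#' @param genes a \linkS4class{GeneModels}.
#' @param methylBins a \linkS4class{BinnedTrack} of mean CG methylation
#'   (see \code{\link{methylationTrack}}).
#' @param promoterUp,promoterDown promoter window around the TSS (defaults
#'   1000 and 500 bp).
#' @param preDistance maximum TSS distance for a PRE (default 1000 bp).
#' @param lowmethMax maximum mean CG methylation for a DRE (default 0.1).
#' @return GRanges of the peaks with mcols \code{class} ("DRE", "PRE" or
#'   "unclassified"), \code{reason}, \code{mean_cg}, \code{tss_distance},
#'   \code{gene_id} (nearest-TSS gene).
#' @export
classifyFaire <- function(peaks, genes, methylBins, promoterUp = 1000L,
                          promoterDown = 500L, preDistance = 1000L,
                          lowmethMax = 0.1) {
  prom <- promoterWindows(genes, promoterUp, promoterDown)
  nt <- nearestTss(peaks, genes)
  grid <- binGrid(methylBins)
  mv <- trackValues(methylBins)
  br <- binRanges(grid)
  hits <- findOverlaps(peaks, br)
  ow <- width(pintersect(peaks[queryHits(hits)], br[subjectHits(hits)],
                         ignore.strand = TRUE))
  v <- mv[subjectHits(hits)]
  ok <- !is.na(v)
  meanCg <- rep(NA_real_, length(peaks))
  num <- rowsum((v * ow)[ok], queryHits(hits)[ok])
  den <- rowsum(ow[ok], queryHits(hits)[ok])
  meanCg[as.integer(rownames(num))] <- num[, 1L] / den[, 1L]
  inProm <- overlapsAny(peaks, prom, ignore.strand = TRUE)
  inGene <- overlapsAny(peaks, geneRanges(genes), ignore.strand = TRUE)
  isPre <- inProm | (!is.na(nt$distance) & abs(nt$distance) <= preDistance)
  cls <- rep("unclassified", length(peaks))
  reason <- rep(NA_character_, length(peaks))
  cls[isPre] <- "PRE"
  distal <- !isPre & !inGene & !inProm
  cls[distal & !is.na(meanCg) & meanCg <= lowmethMax] <- "DRE"
  reason[distal & is.na(meanCg)] <- "no_methylation_data"
  reason[distal & !is.na(meanCg) & meanCg > lowmethMax] <- "high_methylation"
  reason[!isPre & (inGene | inProm)] <- "genic"
  out <- granges(peaks)
  mcols(out) <- DataFrame(class = cls, reason = reason, mean_cg = meanCg,
                          tss_distance = nt$distance, gene_id = nt$gene_id)
  out
}

#' Link DREs to putative target genes
#'
#' Each distal element is linked to the gene with the nearest TSS;
#' equidistant ties break to the lexicographically smaller gene id.
#' Elements on chromosomes without genes are flagged unlinked.
#'
#' @param dres GRanges of DREs.
#' @param genes a \linkS4class{GeneModels}.
#' @return data.frame with columns dre_index, gene_id, distance, linked.
#' @export
linkDreTargets <- function(dres, genes) {
  nt <- nearestTss(dres, genes)
  data.frame(dre_index = seq_along(dres), gene_id = nt$gene_id,
             distance = nt$distance, linked = !is.na(nt$gene_id))
}

#' Cluster tissue-specific DREs by signal intensity
#'
#' Element rows are z-scaled across tissues and clustered with seeded
#' k-means; per cluster, the mean signal per tissue is reported, and when
#' expression and element-gene links are supplied, the mean expression of
#' linked genes per tissue as well.
#'
#' @param signal elements x tissues numeric matrix of open-chromatin signal.
#' @param k number of clusters (default 9).
#' @param seed RNG seed.
#' @param fpkm optional gene x tissue matrix (columns matching signal).
#' @param links optional data.frame from \code{\link{linkDreTargets}}.
#' @param nstart k-means restarts.
#' @return list with \code{cluster}, \code{centers}, \code{maxTissue} and
#'   optional \code{linkedExpression} (cluster x tissue mean FPKM).
#' @export
clusterTissueDres <- function(signal, k = 9L, seed = 1L, fpkm = NULL,
                              links = NULL, nstart = 10L) {
  if (k > nrow(signal)) stop("k exceeds the number of elements")
  if (is.null(rownames(signal))) rownames(signal) <- seq_len(nrow(signal))
  cl <- tissueSpecificClusters(signal, k, seed, nstart)
  out <- cl[c("cluster", "centers", "maxTissue")]
  if (!is.null(fpkm) && !is.null(links)) {
    common <- intersect(colnames(signal), colnames(fpkm))
    le <- matrix(NA_real_, k, length(common),
                 dimnames = list(NULL, common))
    for (cc in seq_len(k)) {
      idx <- as.integer(names(out$cluster)[out$cluster == cc])
      gid <- links$gene_id[match(idx, links$dre_index)]
      gid <- gid[!is.na(gid) & gid %in% rownames(fpkm)]
      if (length(gid)) le[cc, ] <- colMeans(fpkm[gid, common, drop = FALSE])
    }
    out$linkedExpression <- le
  }
  out
}

#' Six loop/PRE gene categories
#'
#' Each gene is scored on three predicates: \emph{own} - its promoter
#' overlaps a PRE; \emph{looped} - a loop anchor maps to its promoter;
#' \emph{partnerPRE} - some loop partner's promoter carries a PRE.  The
#' category is 1 = own & looped & partnerPRE, 2 = own & looped &
#' !partnerPRE, 3 = !own & looped & partnerPRE, 4 = !own & looped &
#' !partnerPRE, 5 = own & !looped, 6 = !own & !looped.  (The two remaining
#' predicate combinations - partnerPRE without a loop - are unreachable by
#' construction.)  This decision table is an interpretation reconstructed
#' from the published category contrasts; it is not enumerated in the
#' original description.
#'
#' @param genes a \linkS4class{GeneModels}.
#' @param loops a \link[S4Vectors]{Pairs} of anchor GRanges (see
#'   \code{\link{readBedpe}}).
#' @param pres GRanges of proximal regulatory elements.
#' @param promoterUp,promoterDown promoter window (defaults 1000/500 bp).
#' @return data.frame with gene_id, own_pre, looped, partner_pre, category.
#' @export
geneLoopCategories <- function(genes, loops, pres, promoterUp = 1000L,
                               promoterDown = 500L) {
  prom <- promoterWindows(genes, promoterUp, promoterDown)
  ids <- prom$gene_id
  own <- overlapsAny(prom, pres, ignore.strand = TRUE)
  names(own) <- ids
  ## anchor -> promoter mapping; anchors overlapping several promoters keep all
  a1 <- first(loops); a2 <- second(loops)
  h1 <- findOverlaps(a1, prom, ignore.strand = TRUE)
  h2 <- findOverlaps(a2, prom, ignore.strand = TRUE)
  looped <- setNames(rep(FALSE, length(ids)), ids)
  partnerPre <- setNames(rep(FALSE, length(ids)), ids)
  for (l in seq_along(loops)) {
    g1 <- ids[subjectHits(h1)[queryHits(h1) == l]]
    g2 <- ids[subjectHits(h2)[queryHits(h2) == l]]
    looped[c(g1, g2)] <- TRUE
    if (length(g1) && length(g2)) {
      if (any(own[g2])) partnerPre[g1] <- TRUE
      if (any(own[g1])) partnerPre[g2] <- TRUE
    }
  }
  stopifnot(!any(partnerPre & !looped))  # unreachable by construction
  category <- ifelse(looped,
                     ifelse(own, ifelse(partnerPre, 1L, 2L),
                            ifelse(partnerPre, 3L, 4L)),
                     ifelse(own, 5L, 6L))
  data.frame(gene_id = ids, own_pre = unname(own), looped = unname(looped),
             partner_pre = unname(partnerPre), category = unname(category))
}
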