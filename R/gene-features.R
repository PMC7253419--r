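#' @include AllGenerics.R
NULL

#' Assign peaks to genes by minimum overlap
#'
#' A gene corresponds to a peak when they share at least \code{minBp} bp of
#' overlap (default 1); a peak overlapping several genes is assigned to all
#' of them.  The \code{scope} selects whether the gene body or a promoter
#' window is the assignment target.
#'
#' @param peaks GRanges of peaks.
#' @param genes a \linkS4class{GeneModels}.
#' @param minBp minimum overlap in bp (default 1).
#' @param scope "body" (default) or "promoter".
#' @param promoterUp,promoterDown promoter window extent when
#'   \code{scope = "promoter"} (defaults 1000 and 500 bp around the TSS).
#' @return data.frame with columns gene_id, peak_index, overlap_bp.
#' @export
assignPeaksToGenes <- function(peaks, genes, minBp = 1L,
                               scope = c("body", "promoter"),
                               promoterUp = 1000L, promoterDown = 500L) {
  scope <- match.arg(scope)
  target <- if (scope == "body") geneRanges(genes)
            else promoterWindows(genes, promoterUp, promoterDown)
  op <- overlapPairs(target, peaks, minBp)
  data.frame(gene_id = target$gene_id[op$a_index],
             peak_index = op$b_index, overlap_bp = op$overlap_bp)
}

#' Per-gene mark presence table
#'
#' @param peakSets named list of GRanges, one per mark.
#' @param genes a \linkS4class{GeneModels}.
#' @param ... passed to \code{\link{assignPeaksToGenes}}.
#' @return logical matrix genes x marks (TRUE iff >= 1 assigned peak).
#' @export
geneMarkTable <- function(peakSets, genes, ...) {
  ids <- geneRanges(genes)$gene_id
  out <- matrix(FALSE, length(ids), length(peakSets),
                dimnames = list(ids, names(peakSets)))
  for (mk in names(peakSets)) {
    asg <- assignPeaksToGenes(peakSets[[mk]], genes, ...)
    out[unique(asg$gene_id), mk] <- TRUE
  }
  out
}

#' Mark-combination class of each gene
#'
#' The class label is the exact subset of requested marks present on the
#' gene, written as \code{mark1+mark2}; genes with none of the marks are
#' labeled \code{"none"}.
#'
#' @param table logical gene x mark matrix (see \code{\link{geneMarkTable}}).
#' @param marks ordered subset of column names to classify on.
#' @return named character vector of class labels per gene.
#' @export
markCombinationClass <- function(table, marks = colnames(table)) {
  if (!all(marks %in% colnames(table)))
    stop("requested marks missing from table")
  sub <- table[, marks, drop = FALSE]
  lab <- apply(sub, 1L, function(r)
    if (any(r)) paste(marks[r], collapse = "+") else "none")
  setNames(lab, rownames(table))
}

#' Classify genes by H3K4me3 summit position
#'
#' Genes are classed by where the summit of their strongest assigned peak
#' falls in transcription orientation: upstream of the TSS, between TSS and
#' ATG, or downstream of the ATG; genes without an assigned peak are
#' "unmarked".  Peaks are assigned by overlap with the gene body extended
#' upstream by \code{upstreamWindow} bp; among several peaks the one with
#' the largest score wins (ties: summit nearest the TSS).
#'
#' @param genes a \linkS4class{GeneModels} (needs \code{atg}).
#' @param peaks GRanges with optional \code{summit} (1-based bp) and
#'   \code{score} mcols; missing summits default to the peak midpoint.
#' @param upstreamWindow upstream extension for assignment (default 1000 bp).
#' @return named character vector with values "upstream", "tss_atg",
#'   "downstream", "unmarked".
#' @export
summitPositionClass <- function(genes, peaks, upstreamWindow = 1000L) {
  g <- geneRanges(genes)
  summit <- peaks$summit
  if (is.null(summit)) summit <- (start(peaks) + end(peaks)) %/% 2L
  score <- peaks$score
  if (is.null(score)) score <- rep(0, length(peaks))
  neg <- as.character(strand(g)) == "-"
  ext <- GRanges(seqnames(g),
                 IRanges(pmax(start(g) - ifelse(neg, 0L, upstreamWindow), 1L),
                         end(g) + ifelse(neg, upstreamWindow, 0L)))
  hits <- findOverlaps(ext, peaks)
  out <- setNames(rep("unmarked", length(g)), g$gene_id)
  for (i in unique(queryHits(hits))) {
    pk <- subjectHits(hits)[queryHits(hits) == i]
    best <- pk[order(-score[pk], abs(summit[pk] - g$tss[i]))][1L]
    s <- summit[best]
    ## project onto transcription orientation
    rel <- if (neg[i]) g$tss[i] - s else s - g$tss[i]
    relAtg <- if (neg[i]) g$tss[i] - g$atg[i] else g$atg[i] - g$tss[i]
    out[i] <- if (rel < 0) "upstream"
              else if (!is.na(relAtg) && rel > relAtg) "downstream"
              else "tss_atg"
  }
  out
}

#' Expression breadth per gene
#'
#' The number of tissues in which the gene is expressed, with "expressed"
#' meaning FPKM strictly above \code{threshold} (default 1).
#'
#' @param fpkm gene x tissue numeric matrix.
#' @param threshold expression threshold (default 1).
#' @return named integer vector of breadth counts.
#' @export
expressionBreadth <- function(fpkm, threshold = 1) {
  if (any(fpkm < 0)) stop("negative FPKM values")
  setNames(as.integer(rowSums(fpkm > threshold)), rownames(fpkm))
}

#' Signal profiles around TSSs
#'
#' For each gene, samples each mark's ratio signal (mark track over input
#' track, missing input imputed as the genome background rate) every
#' \code{step} bp across TSS +/- \code{window}, oriented so that position 1
#' is the most upstream point.  With the defaults (2 kb, 10 bp) each mark
#' contributes 401 positions.
#'
#' @param genes a \linkS4class{GeneModels}.
#' @param trackList named list of GRanges with \code{score} (step tracks),
#'   one per mark.
#' @param input GRanges step track of input signal.
#' @param window half-width in bp (default 2000).
#' @param step sampling step in bp (default 10).
#' @return numeric matrix genes x (marks * positions); columns named
#'   \code{mark.position}.
#' @export
promoterProfiles <- function(genes, trackList, input, window = 2000L,
                             step = 10L) {
  g <- geneRanges(genes)
  offs <- seq(-window, window, by = step)
  npos <- length(offs)
  neg <- as.character(strand(g)) == "-"
  pos <- outer(g$tss, rep(1, npos)) +
    outer(ifelse(neg, -1, 1), offs)  # genes x positions, oriented
  chrom <- rep(as.character(seqnames(g)), npos)
  flat <- GRanges(chrom, IRanges(pmax(as.vector(pos), 1L),
                                 width = 1L))
  sampleTrack <- function(tr) {
    v <- rep(NA_real_, length(flat))
    hits <- findOverlaps(flat, tr)
    v[queryHits(hits)] <- tr$score[subjectHits(hits)]
    matrix(v, nrow = length(g))
  }
  bg <- sum(as.numeric(input$score) * width(input)) /
    sum(as.numeric(width(input)))
  iv <- sampleTrack(input)
  iv[is.na(iv) | iv == 0] <- bg
  out <- lapply(names(trackList), function(mk) {
    mv <- sampleTrack(trackList[[mk]])
    mv[is.na(mv)] <- 0
    r <- mv / iv
    colnames(r) <- paste0(mk, ".", offs)
    r
  })
  res <- do.call(cbind, out)
  rownames(res) <- g$gene_id
  res
}

#' Cluster promoter profiles
#'
#' Profiles are log2(ratio + 1) transformed and clustered with seeded
#' k-means; clusters smaller than \code{minCluster} are flagged in the QC
#' report (not merged).
#'
#' @param profiles matrix from \code{\link{promoterProfiles}}.
#' @param k number of clusters (default 15).
#' @param minCluster minimum cluster size to pass QC (default 2000, meant
#'   for genome-scale runs; set lower on small inputs).
#' @param seed RNG seed.
#' @param nstart k-means restarts.
#' @return list with \code{cluster} (per gene), \code{sizes},
#'   \code{smallClusters} (ids failing \code{minCluster}), \code{degenerate}
#'   flag (all profiles identical).
#' @export
promoterProfileClusters <- function(profiles, k = 15L, minCluster = 2000L,
                                    seed = 1L, nstart = 10L) {
  if (k > nrow(profiles)) stop("k exceeds the number of genes")
  x <- log2(profiles + 1)
  if (all(apply(x, 2L, sd) == 0)) {
    return(list(cluster = setNames(rep(1L, nrow(x)), rownames(x)),
                sizes = nrow(x), smallClusters = integer(),
                degenerate = TRUE))
  }
  set.seed(seed)
  km <- kmeans(x, centers = k, nstart = nstart)
  sizes <- tabulate(km$cluster, k)
  list(cluster = setNames(km$cluster, rownames(profiles)), sizes = sizes,
       smallClusters = which(sizes < minCluster), degenerate = FALSE)
}

#' TE insertion location class per gene
#'
#' For each gene and TE family: "exon" when any TE of the family overlaps an
#' exon of the gene (exon dominates when both exon and intron are hit),
#' "intron" when only intronic sequence is hit, "none" otherwise.  An
#' overall column uses all families together.
#'
#' @param genes a \linkS4class{GeneModels}.
#' @param tes GRanges of TEs with a \code{family} mcol.
#' @return character matrix genes x (families + "any").
#' @export
teInsertionClass <- function(genes, tes) {
  g <- geneRanges(genes)
  ex <- geneExons(genes)
  fams <- unique(tes$family)
  out <- matrix("none", length(g), length(fams) + 1L,
                dimnames = list(g$gene_id, c(fams, "any")))
  classify <- function(teSub) {
    res <- rep("none", length(g))
    bodyHit <- overlapPairs(granges(g), teSub)
    for (i in unique(bodyHit$a_index)) {
      exi <- ex[[g$gene_id[i]]]
      teHit <- teSub[bodyHit$b_index[bodyHit$a_index == i]]
      res[i] <- if (length(exi) && any(overlapsAny(teHit, exi,
                                                   ignore.strand = TRUE)))
        "exon" else "intron"
    }
    res
  }
  for (fam in fams) out[, fam] <- classify(tes[tes$family == fam])
  out[, "any"] <- classify(tes)
  out
}
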