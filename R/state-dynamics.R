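#' @include AllGenerics.R
NULL

.newSwitchMatrix <- function(counts, fractions, nbins) {
  K <- nrow(counts)
  nm <- paste0("S", seq_len(K))
  dimnames(counts) <- list(nm, nm)
  symmetrized <- counts + t(counts)
  probabilities <- .rowNormalize(symmetrized)
  enrichment <- sweep(probabilities, 2L, fractions, "/")
  enrichment[, fractions == 0] <- NA_real_
  l10 <- suppressWarnings(log10(enrichment))
  l10[!is.finite(l10)] <- NA_real_
  names(fractions) <- nm
  new("SwitchMatrix", counts = counts, symmetrized = symmetrized,
      probabilities = probabilities, enrichment = enrichment,
      log10Enrichment = l10, stateFractions = fractions,
      nBins = as.integer(nbins))
}

#' Chromatin-state switching matrix between two conditions
#'
#' Counts bins labeled s1 in A and s2 in B, symmetrizes by adding the
#' transpose, row-normalizes the symmetric matrix into switching
#' probabilities, and computes the enrichment transform: each probability
#' divided by the genome fraction of the target state (pooled across the
#' two inputs), with log10 reported alongside (zeros and masked cells NA).
#'
#' @param segA,segB \linkS4class{Segmentation}s on the same grid.
#' @param stateFractions optional per-state genome fractions to normalize
#'   the enrichment by; defaults to the fractions pooled over both inputs.
#' @return a \linkS4class{SwitchMatrix}.
#' @export
switchMatrix <- function(segA, segB, stateFractions = NULL) {
  if (!identical(binGrid(segA)@binsPerChrom, binGrid(segB)@binsPerChrom))
    stop("segmentations must share one grid")
  K <- max(nStates(segA), nStates(segB))
  lv <- seq_len(K)
  sA <- stateLabels(segA); sB <- stateLabels(segB)
  counts <- unclass(table(factor(sA, lv), factor(sB, lv)))
  if (is.null(stateFractions))
    stateFractions <- (tabulate(sA, K) + tabulate(sB, K)) / (2 * length(sA))
  .newSwitchMatrix(counts, stateFractions, length(sA))
}

#' Pool switching matrices over several condition pairs
#'
#' Element-wise sum of the raw counts of each pair, then re-symmetrization,
#' re-normalization and re-computation of the enrichment using the pooled
#' state fractions (weighted by bins compared).
#'
#' @param matrices list of \linkS4class{SwitchMatrix} objects with the same
#'   number of states.
#' @return a \linkS4class{SwitchMatrix}.
#' @export
combineSwitchMatrices <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  K <- nrow(switchCounts(matrices[[1L]]))
  for (m in matrices)
    if (nrow(switchCounts(m)) != K) stop("state label sets differ")
  counts <- Reduce(`+`, lapply(matrices, switchCounts))
  w <- vapply(matrices, function(m) m@nBins, integer(1))
  fr <- rowSums(vapply(matrices, function(m) m@stateFractions * m@nBins,
                       numeric(K))) / sum(w)
  .newSwitchMatrix(counts, fr, sum(w))
}

#' Differential mark signal over regions
#'
#' A documented substitute for a full negative-binomial differential test:
#' per-region counts are normalized with median-of-ratios size factors and
#' the two conditions are compared with the exact conditional test of two
#' Poisson rates (the observed count of A out of the regional total is
#' binomial with success probability equal to A's share of the size
#' factors).  BH adjustment is applied across regions; a region is called
#' iff its fold-change exceeds \code{minFc} (in either direction) and its
#' q-value is at most \code{qMax}.
#'
#' @param countsA,countsB \linkS4class{BinnedTrack}s of read counts per bin
#'   for the mark in the two conditions.
#' @param regions GRanges of regions (conventionally the merged peak union
#'   of the two conditions).
#' @param minFc fold-change threshold (default 1.5), interpreted on the
#'   natural scale unless \code{fcScale = "log2"}.
#' @param qMax q-value cutoff (default 0.01).
#' @param fcScale "natural" (default) or "log2": scale on which
#'   \code{minFc} is read.
#' @param pseudocount added to normalized counts before fold-change
#'   (default 1).
#' @return data.frame with one row per region: counts, normalized means,
#'   log2 fold-change, p, q, call flag and a skip flag for regions with no
#'   counts in either condition.
#' @export
differentialRegions <- function(countsA, countsB, regions, minFc = 1.5,
                                qMax = 0.01, fcScale = c("natural", "log2"),
                                pseudocount = 1) {
  fcScale <- match.arg(fcScale)
  grid <- binGrid(countsA)
  if (!identical(grid@binsPerChrom, binGrid(countsB)@binsPerChrom))
    stop("count tracks must share one grid")
  br <- binRanges(grid)
  hits <- findOverlaps(regions, br)
  sumOver <- function(v) {
    out <- numeric(length(regions))
    acc <- rowsum(v[subjectHits(hits)], queryHits(hits))
    out[as.integer(rownames(acc))] <- acc[, 1L]
    out
  }
  kA <- sumOver(trackValues(countsA))
  kB <- sumOver(trackValues(countsB))
  sf <- sizeFactors(cbind(A = kA, B = kB))
  nA <- kA / sf[1L]; nB <- kB / sf[2L]
  skip <- kA + kB == 0
  shareA <- (1 / sf[1L]) / (1 / sf[1L] + 1 / sf[2L])
  p <- rep(NA_real_, length(regions))
  p[!skip] <- binomExactP(kA[!skip], kA[!skip] + kB[!skip], shareA)
  q <- rep(NA_real_, length(regions))
  q[!skip] <- p.adjust(p[!skip], "BH")
  l2fc <- log2((nA + pseudocount) / (nB + pseudocount))
  fcPass <- if (fcScale == "natural")
    pmax((nA + pseudocount) / (nB + pseudocount),
         (nB + pseudocount) / (nA + pseudocount)) > minFc
  else abs(l2fc) > minFc
  data.frame(chrom = as.character(seqnames(regions)),
             start = start(regions), end = end(regions),
             count_A = kA, count_B = kB, norm_A = nA, norm_B = nB,
             log2fc = l2fc, p = p, q = q,
             call = !skip & fcPass & !is.na(q) & q <= qMax,
             skipped = skip)
}

#' Fold-change pairs for a mark and expression
#'
#' Builds per-gene pairs of log2 fold-changes: the mark's promoter signal
#' and the gene's expression between two conditions, with pseudocounts
#' applied before the log so all values are finite.
#'
#' @param markA,markB named numeric vectors of promoter mark signal per gene.
#' @param exprA,exprB named numeric vectors of FPKM per gene.
#' @param pseudoMark,pseudoExpr pseudocounts (defaults 1 and 0.01).
#' @return data.frame with columns gene_id, mark_l2fc, expr_l2fc.
#' @export
foldChangePairs <- function(markA, markB, exprA, exprB,
                            pseudoMark = 1, pseudoExpr = 0.01) {
  genes <- Reduce(intersect, list(names(markA), names(markB),
                                  names(exprA), names(exprB)))
  data.frame(gene_id = genes,
             mark_l2fc = log2((markA[genes] + pseudoMark) /
                                (markB[genes] + pseudoMark)),
             expr_l2fc = log2((exprA[genes] + pseudoExpr) /
                                (exprB[genes] + pseudoExpr)),
             row.names = NULL)
}

#' Correlation of mark and expression fold-changes
#'
#' @param pairs data.frame from \code{\link{foldChangePairs}} (columns
#'   mark_l2fc, expr_l2fc).
#' @return list with Pearson \code{r}, fitted \code{slope}, \code{n}, and a
#'   \code{degenerate} flag set when either vector has zero variance.
#' @export
fcCorrelation <- function(pairs) {
  x <- pairs$mark_l2fc; y <- pairs$expr_l2fc
  if (length(x) < 3L) stop("need at least 3 fold-change pairs")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, slope = NA_real_, n = length(x),
                degenerate = TRUE))
  list(r = cor(x, y), slope = unname(coef(lm(y ~ x))[2L]), n = length(x),
       degenerate = FALSE)
}

#' Tissue-specific clustering of differential regions
#'
#' Rows (regions) are standardized to zero mean and unit variance (constant
#' rows are dropped and flagged) and clustered with seeded k-means; clusters
#' are reported ordered by the tissue of their maximal mean signal.
#'
#' @param signal regions x tissues numeric matrix.
#' @param k number of clusters.
#' @param seed RNG seed.
#' @param nstart k-means restarts (default 10).
#' @return list with \code{cluster} (per retained row), \code{centers}
#'   (cluster x tissue profile of scaled signal), \code{maxTissue} (tissue
#'   of maximal mean signal per cluster), \code{dropped} (indices of
#'   constant rows).
#' @export
tissueSpecificClusters <- function(signal, k, seed = 1L, nstart = 10L) {
  if (k > nrow(signal)) stop("k exceeds the number of regions")
  rsd <- apply(signal, 1L, sd)
  dropped <- which(rsd == 0)
  keep <- signal[rsd > 0, , drop = FALSE]
  if (k == 1L) {
    return(list(cluster = setNames(rep(1L, nrow(keep)), rownames(keep)),
                centers = matrix(colMeans(keep), 1L,
                                 dimnames = list(NULL, colnames(signal))),
                maxTissue = colnames(signal)[which.max(colMeans(keep))],
                dropped = dropped))
  }
  z <- t(scale(t(keep)))
  if (k == nrow(z)) {
    ## one cluster per row; no need to iterate
    km <- list(cluster = seq_len(k), centers = z)
  } else {
    set.seed(seed)
    km <- kmeans(z, centers = k, nstart = nstart)
  }
  maxT <- colnames(signal)[apply(km$centers, 1L, which.max)]
  ord <- order(match(maxT, colnames(signal)))
  relabel <- match(seq_len(k), ord)
  list(cluster = setNames(relabel[km$cluster], rownames(keep)),
       centers = km$centers[ord, , drop = FALSE],
       maxTissue = maxT[ord], dropped = dropped)
}
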