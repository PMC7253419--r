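#' @include AllGenerics.R
NULL

.checkPanel <- function(segList) {
  if (length(segList) < 2L) stop("need at least 2 varieties")
  K <- nStates(segList[[1L]])
  g <- binGrid(segList[[1L]])@binsPerChrom
  for (s in segList) {
    if (nStates(s) != K) stop("state label sets differ across varieties")
    if (!identical(binGrid(s)@binsPerChrom, g))
      stop("all varieties must share one grid")
  }
  K
}

#' Conserved chromatin-state fraction per state
#'
#' A bin is conserved for state s when every variety labels it s.  The
#' reported value normalizes the conserved count by the state's abundance:
#' conserved bins divided by the mean per-variety bin count of s, so an
#' identical panel scores exactly 1 for every occupied state.
#'
#' @param segList named list of \linkS4class{Segmentation}s, one per variety.
#' @return numeric vector, one (possibly NA for absent states) value per state.
#' @export
conservedFraction <- function(segList) {
  K <- .checkPanel(segList)
  mat <- vapply(segList, stateLabels, integer(nBins(segList[[1L]])))
  allSame <- rowSums(mat == mat[, 1L]) == ncol(mat)
  conserved <- tabulate(mat[allSame, 1L], K)
  meanCount <- rowMeans(vapply(segList, function(s)
    tabulate(stateLabels(s), K), numeric(K)))
  out <- conserved / meanCount
  out[meanCount == 0] <- NA_real_
  setNames(out, paste0("S", seq_len(K)))
}

#' Fixed inter-subgroup chromatin-state differences
#'
#' A consensus-different bin requires every variety of group A to share one
#' state sA, every variety of group B to share another state sB, and sA !=
#' sB.  The switch matrix counts those bins per (sA, sB) cell, normalized by
#' the genome proportion of the source state (cell count divided by
#' fraction(sA) x total bins).  The similarity of any third group to A
#' versus B is the fraction of consensus bins where the group's majority
#' state matches sA (resp. sB).
#'
#' @param segList named list of \linkS4class{Segmentation}s.
#' @param groupA,groupB character vectors of variety names (disjoint).
#' @param stateFractions optional per-state genome fractions for the
#'   normalization; defaults to the pooled fractions over all varieties.
#' @param otherGroups optional named list of variety-name vectors whose
#'   similarity to A/B over the consensus bins is reported.
#' @return list with \code{bins} (data.frame bin, state_A, state_B),
#'   \code{matrix} (K x K normalized counts), \code{similarity}
#'   (group x c(A, B) matrix or NULL).
#' @export
subgroupSwitch <- function(segList, groupA, groupB, stateFractions = NULL,
                           otherGroups = NULL) {
  K <- .checkPanel(segList)
  if (length(intersect(groupA, groupB)))
    stop("groups must be disjoint")
  if (!all(c(groupA, groupB) %in% names(segList)))
    stop("unknown variety names")
  matOf <- function(g) vapply(segList[g], stateLabels,
                              integer(nBins(segList[[1L]])))
  mA <- matOf(groupA); mB <- matOf(groupB)
  consA <- rowSums(mA == mA[, 1L]) == ncol(mA)
  consB <- rowSums(mB == mB[, 1L]) == ncol(mB)
  hit <- which(consA & consB & mA[, 1L] != mB[, 1L])
  bins <- data.frame(bin = hit, state_A = mA[hit, 1L], state_B = mB[hit, 1L])
  if (is.null(stateFractions)) {
    allStates <- unlist(lapply(segList, stateLabels), use.names = FALSE)
    stateFractions <- tabulate(allStates, K) / length(allStates)
  }
  n <- nBins(segList[[1L]])
  lv <- seq_len(K)
  counts <- unclass(table(factor(bins$state_A, lv), factor(bins$state_B, lv)))
  norm <- counts / (stateFractions * n)
  norm[stateFractions == 0, ] <- NA_real_
  dimnames(norm) <- list(paste0("S", lv), paste0("S", lv))
  similarity <- NULL
  if (!is.null(otherGroups) && nrow(bins)) {
    similarity <- t(vapply(otherGroups, function(g) {
      mg <- matOf(g)[bins$bin, , drop = FALSE]
      maj <- apply(mg, 1L, function(r)
        as.integer(names(which.max(table(r)))))
      c(A = mean(maj == bins$state_A), B = mean(maj == bins$state_B))
    }, numeric(2)))
  }
  list(bins = bins, matrix = norm, similarity = similarity)
}

#' SNP density profile around peaks
#'
#' Strandless density of SNPs per bp in fixed-width units across the peak
#' flanks plus a body scaled to a fixed number of units; density in a unit
#' is the total SNP count over all peaks divided by the total bp the unit
#' spans.  The boundary mode instead profiles only the 1-kb region before
#' each peak in 20 units, which removes peak-length interference.
#'
#' @param snps GRanges of SNP positions (width 1).
#' @param peaks GRanges of peak regions (non-empty).
#' @param flank flank extent in bp (default 2000).
#' @param unit flank unit width in bp (default 10).
#' @param bodyUnits number of units the peak body is scaled to (default 20).
#' @param boundaryMode when TRUE, profile only the \code{boundaryFlank} bp
#'   upstream (left) of each peak in \code{boundaryUnits} units.
#' @param boundaryFlank,boundaryUnits boundary-mode extent (1000 bp / 20).
#' @return data.frame with columns zone ("upstream", "body", "downstream"),
#'   unit index and \code{density} (SNPs per bp per peak).
#' @export
snpProfile <- function(snps, peaks, flank = 2000L, unit = 10L,
                       bodyUnits = 20L, boundaryMode = FALSE,
                       boundaryFlank = 1000L, boundaryUnits = 20L) {
  if (length(peaks) == 0L) stop("peaks must be non-empty")
  spos <- start(snps)
  sch <- as.character(seqnames(snps))
  countIn <- function(chrom, s, e) {
    ## total SNPs in [s, e] per element; s/e equal-length vectors
    n <- numeric(length(s))
    for (ch in unique(chrom)) {
      i <- chrom == ch
      p <- sort(spos[sch == ch])
      n[i] <- findInterval(e[i], p) - findInterval(s[i] - 1L, p)
    }
    n
  }
  chrom <- as.character(seqnames(peaks))
  if (boundaryMode) {
    uw <- boundaryFlank / boundaryUnits
    dens <- vapply(seq_len(boundaryUnits), function(u) {
      s <- start(peaks) - boundaryFlank + (u - 1L) * uw
      e <- s + uw - 1L
      sum(countIn(chrom, pmax(s, 1L), pmax(e, 0L))) /
        (length(peaks) * uw)
    }, numeric(1))
    return(data.frame(zone = "upstream", unit = seq_len(boundaryUnits),
                      density = dens))
  }
  nUnits <- flank %/% unit
  up <- vapply(seq_len(nUnits), function(u) {
    s <- start(peaks) - flank + (u - 1L) * unit
    e <- s + unit - 1L
    sum(countIn(chrom, pmax(s, 1L), pmax(e, 0L))) / (length(peaks) * unit)
  }, numeric(1))
  dn <- vapply(seq_len(nUnits), function(u) {
    s <- end(peaks) + 1L + (u - 1L) * unit
    e <- s + unit - 1L
    sum(countIn(chrom, s, e)) / (length(peaks) * unit)
  }, numeric(1))
  body <- vapply(seq_len(bodyUnits), function(u) {
    w <- width(peaks)
    s <- start(peaks) + floor((u - 1L) * w / bodyUnits)
    e <- start(peaks) + ceiling(u * w / bodyUnits) - 1L
    sum(countIn(chrom, s, e)) / sum(e - s + 1)
  }, numeric(1))
  rbind(data.frame(zone = "upstream", unit = seq_len(nUnits), density = up),
        data.frame(zone = "body", unit = seq_len(bodyUnits), density = body),
        data.frame(zone = "downstream", unit = seq_len(nUnits), density = dn))
}

#' Saturation curves over random variety orderings
#'
#' For each of \code{nOrders} random orderings of the varieties and each
#' prefix size k, the accumulation score is the fraction of genome bp
#' covered by the union of the mark's regions over the first k varieties;
#' when a matrix of pairwise differential fractions is supplied, the
#' differential proportion is the mean over the pairs within the prefix.
#'
#' @param regionsList named list of GRanges, one region set per variety.
#' @param genome a Seqinfo giving the genome size.
#' @param pairwiseDiff optional symmetric variety x variety matrix of
#'   pairwise differential fractions (dimnames = variety names).
#' @param nOrders number of random orderings (default 10).
#' @param seed RNG seed.
#' @return data.frame with columns k, accumulation_mean, accumulation_sd,
#'   differential_mean, differential_sd.
#' @export
saturationCurve <- function(regionsList, genome, pairwiseDiff = NULL,
                            nOrders = 10L, seed = 1L) {
  if (nOrders < 1L) stop("nOrders must be >= 1")
  if (length(regionsList) < 3L) stop("need at least 3 varieties")
  nv <- length(regionsList)
  genomeBp <- sum(as.numeric(seqlengths(genome)))
  set.seed(seed)
  acc <- diffp <- matrix(NA_real_, nOrders, nv)
  for (o in seq_len(nOrders)) {
    ord <- sample(names(regionsList))
    un <- GRanges()
    for (k in seq_len(nv)) {
      un <- reduce(c(un, granges(regionsList[[ord[k]]])),
                   ignore.strand = TRUE)
      acc[o, k] <- sum(as.numeric(width(un))) / genomeBp
      if (!is.null(pairwiseDiff) && k >= 2L) {
        pr <- utils::combn(ord[seq_len(k)], 2L)
        diffp[o, k] <- mean(pairwiseDiff[cbind(pr[1L, ], pr[2L, ])])
      }
    }
    if (any(diff(acc[o, ]) < 0)) stop("accumulation must be non-decreasing")
  }
  data.frame(k = seq_len(nv),
             accumulation_mean = colMeans(acc),
             accumulation_sd = apply(acc, 2L, sd),
             differential_mean = colMeans(diffp),
             differential_sd = apply(diffp, 2L, sd))
}

#' Epigenome distance matrix across varieties
#'
#' Pairwise distances between per-variety binned signal vectors, by
#' Bray-Curtis dissimilarity or 1 - Spearman correlation, optionally with a
#' seeded 2-D non-metric MDS ordination.
#'
#' @param signal bins x varieties numeric matrix.
#' @param metric "bray-curtis" (default) or "1-spearman".
#' @param ordinate when TRUE, also return a 2-D ordination.
#' @param seed RNG seed for the ordination.
#' @return list with \code{dist} (a dist) and \code{points} (varieties x 2
#'   matrix or NULL).
#' @export
epigenomeDistance <- function(signal, metric = c("bray-curtis", "1-spearman"),
                              ordinate = FALSE, seed = 1L) {
  metric <- match.arg(metric)
  d <- if (metric == "bray-curtis") {
    vegan::vegdist(t(signal), method = "bray")
  } else {
    stats::as.dist(1 - cor(signal, method = "spearman"))
  }
  pts <- NULL
  if (ordinate) {
    set.seed(seed)
    ## non-metric MDS from a metric start; flagged stochastic, hence the seed
    pts <- MASS::isoMDS(stats::as.dist(as.matrix(d) +
                                         1e-9 * (1 - diag(ncol(signal)))),
                        k = 2, trace = FALSE)$points
    rownames(pts) <- colnames(signal)
  }
  list(dist = d, points = pts)
}

#' Core versus distributed gene proportions per mark
#'
#' For each mark, among the genes carrying it, the proportion labeled core
#' (pan-genome presence above 99\% of accessions) versus distributed.
#'
#' @param markTable logical gene x mark matrix (\code{\link{geneMarkTable}}).
#' @param labels named character vector ("core"/"distributed") per gene.
#' @return matrix marks x c(core, distributed); rows sum to 1 (NA when no
#'   gene carries the mark).
#' @export
coreVsDistributed <- function(markTable, labels) {
  missing <- setdiff(rownames(markTable), names(labels))
  if (length(missing))
    stop("unlabeled genes: ", paste(missing, collapse = ", "))
  lab <- labels[rownames(markTable)]
  if (!all(lab %in% c("core", "distributed")))
    stop("labels must be 'core' or 'distributed'")
  out <- t(vapply(colnames(markTable), function(mk) {
    g <- lab[markTable[, mk]]
    if (!length(g)) return(c(core = NA_real_, distributed = NA_real_))
    c(core = mean(g == "core"), distributed = mean(g == "distributed"))
  }, numeric(2)))
  out
}
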