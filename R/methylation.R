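#' @include AllGenerics.R
NULL

#' Filter cytosine calls by coverage and compute levels
#'
#' Cytosines with total coverage below \code{minCoverage} (default 3) are
#' removed; the methylation level of the rest is methylated / total.
#'
#' @param calls data.frame with columns chrom, pos, strand, context, meth,
#'   total (see \code{\link{readMethCalls}}).
#' @param minCoverage minimum total read coverage (default 3).
#' @return the filtered data.frame with an added \code{level} column.
#' @export
cytosineLevels <- function(calls, minCoverage = 3L) {
  if (any(calls$meth > calls$total) || any(calls$meth < 0))
    stop("methylated counts must satisfy 0 <= meth <= total")
  out <- calls[calls$total >= minCoverage, , drop = FALSE]
  out$level <- out$meth / out$total
  rownames(out) <- NULL
  out
}

#' Aggregate cytosine levels into grid bins
#'
#' The bin level is the unweighted mean of the qualifying per-cytosine
#' levels (the region-averaging convention used throughout); pooled
#' methylated/total counts are also recorded for count-based testing.
#' Coverage weighting is available as an alternative.  Bins without
#' qualifying cytosines are flagged missing.
#'
#' @param calls filtered calls from \code{\link{cytosineLevels}}.
#' @param grid a \linkS4class{BinGrid}.
#' @param context one of "CG", "CHG", "CHH".
#' @param weighting "unweighted" (default) or "coverage".
#' @return data.frame with columns bin, n_cytosines, mean_level, meth, total.
#' @export
binMethylation <- function(calls, grid, context = c("CG", "CHG", "CHH"),
                           weighting = c("unweighted", "coverage")) {
  context <- match.arg(context)
  weighting <- match.arg(weighting)
  cc <- calls[calls$context == context, , drop = FALSE]
  if (nrow(cc) == 0L)
    return(data.frame(bin = integer(), n_cytosines = integer(),
                      mean_level = numeric(), meth = numeric(),
                      total = numeric()))
  bin <- globalBinIndex(grid, cc$chrom, cc$pos)
  f <- factor(bin)
  mean_level <- if (weighting == "unweighted")
    tapply(cc$level, f, mean) else
    tapply(cc$level * cc$total, f, sum) / tapply(cc$total, f, sum)
  data.frame(bin = as.integer(levels(f)),
             n_cytosines = as.integer(table(f)),
             mean_level = as.numeric(mean_level),
             meth = as.numeric(tapply(cc$meth, f, sum)),
             total = as.numeric(tapply(cc$total, f, sum)))
}

#' A per-context bin methylation track
#'
#' Convenience wrapper putting the mean bin levels of
#' \code{\link{binMethylation}} onto the grid as a
#' \linkS4class{BinnedTrack} (missing bins NA), as consumed by
#' \code{\link{classifyFaire}}.
#'
#' @inheritParams binMethylation
#' @param minCoverage minimum per-cytosine coverage.
#' @return a \linkS4class{BinnedTrack} of mean levels.
#' @export
methylationTrack <- function(calls, grid, context = "CG", minCoverage = 3L) {
  mb <- binMethylation(cytosineLevels(calls, minCoverage), grid, context)
  v <- rep(NA_real_, nBins(grid))
  v[mb$bin] <- mb$mean_level
  .BinnedTrack(grid, v)
}

#' Call differentially methylated regions (200-bp bins)
#'
#' For every bin with at least \code{minCytosines} qualifying cytosines in
#' both samples, the pooled counts of sample A are tested against sample B's
#' pooled level with an exact two-sided binomial test; p-values are BH
#' adjusted across the tested bins of the context.  A bin is a DMR iff the
#' absolute difference of the unweighted mean levels is at least
#' \code{deltaMin} (default 0.6) and the adjusted q-value is at most
#' \code{qMax} (default 0.05).  A symmetric test (B against A's pooled
#' level) is reported in a QC column.
#'
#' @param callsA,callsB raw cytosine call data.frames for the two samples.
#' @param grid a \linkS4class{BinGrid} (conventionally 200 bp).
#' @param context methylation context to test.
#' @param deltaMin minimum |level_A - level_B| (default 0.6).
#' @param qMax maximum BH-adjusted q (default 0.05).
#' @param minCytosines minimum qualifying cytosines per sample per bin
#'   (default 2).
#' @param minCoverage per-cytosine coverage filter (default 3).
#' @return GRanges of DMR bins with mcols context, delta, p, q, direction,
#'   p_symmetric.  The full table of tested bins is attached as
#'   \code{metadata(x)$tested}.
#' @export
callDMRs <- function(callsA, callsB, grid, context = "CG", deltaMin = 0.6,
                     qMax = 0.05, minCytosines = 2L, minCoverage = 3L) {
  a <- binMethylation(cytosineLevels(callsA, minCoverage), grid, context)
  b <- binMethylation(cytosineLevels(callsB, minCoverage), grid, context)
  tab <- merge(a, b, by = "bin", suffixes = c("_A", "_B"))
  tab <- tab[tab$n_cytosines_A >= minCytosines &
               tab$n_cytosines_B >= minCytosines, , drop = FALSE]
  gr <- GRanges(seqinfo = grid@seqinfo)
  if (nrow(tab)) {
    clamp <- function(m, n) pmin(pmax(m / n, 1 / (n + 2)), 1 - 1 / (n + 2))
    pB <- clamp(tab$meth_B, tab$total_B)
    pA <- clamp(tab$meth_A, tab$total_A)
    tab$delta <- tab$mean_level_A - tab$mean_level_B
    tab$p <- binomExactP(tab$meth_A, tab$total_A, pB)
    tab$p_symmetric <- binomExactP(tab$meth_B, tab$total_B, pA)
    tab$q <- p.adjust(tab$p, "BH")
    hit <- abs(tab$delta) >= deltaMin & tab$q <= qMax
    if (any(hit)) {
      gr <- binRanges(grid)[tab$bin[hit]]
      mcols(gr) <- DataFrame(bin = tab$bin[hit], context = context,
                             delta = tab$delta[hit], p = tab$p[hit],
                             q = tab$q[hit],
                             direction = ifelse(tab$delta[hit] > 0,
                                                "hyper_A", "hypo_A"),
                             p_symmetric = tab$p_symmetric[hit])
    }
  }
  metadata(gr)$tested <- tab
  metadata(gr)$context <- context
  gr
}

#' Couple DMRs to chromatin-state switches
#'
#' Counts DMR bins by the (state in A, state in B) cell, divides each cell
#' by the genome-wide number of bins making that state transition (relative
#' DMR switching counts; cells with no transitions are masked), row-
#' normalizes the relative matrix, and reports its log10 (masked and zero
#' cells NA).
#'
#' @param dmrs GRanges from \code{\link{callDMRs}} (needs the \code{bin} mcol).
#' @param segA,segB \linkS4class{Segmentation}s of the two conditions on the
#'   same grid.
#' @return list with matrices \code{counts}, \code{transitions},
#'   \code{relative}, \code{probabilities}, \code{log10} (all K x K).
#' @export
dmrStateCoupling <- function(dmrs, segA, segB) {
  if (!identical(binGrid(segA)@binsPerChrom, binGrid(segB)@binsPerChrom))
    stop("segmentations must share one grid")
  K <- max(nStates(segA), nStates(segB))
  lv <- seq_len(K)
  sA <- stateLabels(segA); sB <- stateLabels(segB)
  transitions <- unclass(table(factor(sA, lv), factor(sB, lv)))
  bins <- if (length(dmrs)) dmrs$bin else integer()
  counts <- unclass(table(factor(sA[bins], lv), factor(sB[bins], lv)))
  relative <- counts / transitions
  relative[transitions == 0] <- NA_real_
  rs <- rowSums(relative, na.rm = TRUE)
  probabilities <- relative / rs
  probabilities[rs == 0, ] <- NA_real_
  l10 <- suppressWarnings(log10(probabilities))
  l10[!is.finite(l10)] <- NA_real_
  nm <- paste0("S", lv)
  out <- lapply(list(counts = counts, transitions = transitions,
                     relative = relative, probabilities = probabilities,
                     log10 = l10),
                function(m) { dimnames(m) <- list(nm, nm); m })
  out
}
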