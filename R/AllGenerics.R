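#' @include AllClasses.R
NULL

#' Number of bins in a grid-backed object
#' @param x a BinGrid, BinnedTrack, BinMatrix or Segmentation.
#' @return integer(1)
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' Bin width accessor
#' @param x a BinGrid or grid-backed object.
#' @return integer(1), bin width in bp.
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' Bin ranges of a grid as GRanges
#' @param x a BinGrid or grid-backed object.
#' @return a GRanges with one range per bin, in global bin order.
#' @export
setGeneric("binRanges", function(x) standardGeneric("binRanges"))

#' Grid accessor
#' @param x a grid-backed object.
#' @return the underlying \linkS4class{BinGrid}.
#' @export
setGeneric("binGrid", function(x) standardGeneric("binGrid"))

#' Per-bin values of a track
#' @param x a BinnedTrack.
#' @return numeric vector, one value per bin (NA = missing).
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' Bins x marks matrix accessor
#' @param x a BinMatrix.
#' @return the numeric matrix (marks as column names).
#' @export
setGeneric("binMatrix", function(x) standardGeneric("binMatrix"))

#' Mark names of a model or matrix
#' @param x a BinMatrix or StateHMM.
#' @return character vector of mark names.
#' @export
setGeneric("markNames", function(x) standardGeneric("markNames"))

#' Number of hidden states
#' @param x a StateHMM or Segmentation.
#' @return integer(1)
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' Emission probabilities of a StateHMM
#' @param x a StateHMM.
#' @return K x M matrix of Bernoulli emission probabilities.
#' @export
setGeneric("emissionProbs", function(x) standardGeneric("emissionProbs"))

#' Transition matrix of a StateHMM
#' @param x a StateHMM.
#' @return K x K row-stochastic matrix.
#' @export
setGeneric("transitionProbs", function(x) standardGeneric("transitionProbs"))

#' Initial state distribution of a StateHMM
#' @param x a StateHMM.
#' @return length-K probability vector.
#' @export
setGeneric("initialProbs", function(x) standardGeneric("initialProbs"))

#' Training log-likelihood trace
#' @param x a StateHMM.
#' @return numeric vector, one entry per EM iteration.
#' @export
setGeneric("logLikTrace", function(x) standardGeneric("logLikTrace"))

#' Per-bin state labels
#' @param x a Segmentation.
#' @return integer vector of state ids.
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' Switch-count accessors
#' @param x a SwitchMatrix.
#' @return a K x K matrix.
#' @export
setGeneric("switchCounts", function(x) standardGeneric("switchCounts"))

#' @rdname switchCounts
#' @export
setGeneric("switchProbs", function(x) standardGeneric("switchProbs"))

#' @rdname switchCounts
#' @export
setGeneric("switchEnrichment", function(x) standardGeneric("switchEnrichment"))

#' Gene body ranges of a GeneModels object
#' @param x a GeneModels.
#' @return GRanges with mcols gene_id, tss, atg, gene_class.
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' Exon structure of a GeneModels object
#' @param x a GeneModels.
#' @return GRangesList named by gene id.
#' @export
setGeneric("geneExons", function(x) standardGeneric("geneExons"))

## ---- methods ----------------------------------------------------------

#' @rdname nBins
setMethod("nBins", "BinGrid", function(x) sum(x@binsPerChrom))
#' @rdname nBins
setMethod("nBins", "BinnedTrack", function(x) nBins(x@grid))
#' @rdname nBins
setMethod("nBins", "BinMatrix", function(x) nBins(x@grid))
#' @rdname nBins
setMethod("nBins", "Segmentation", function(x) nBins(x@grid))

#' @rdname binWidth
setMethod("binWidth", "BinGrid", function(x) x@binWidth)

#' @rdname binGrid
setMethod("binGrid", "BinnedTrack", function(x) x@grid)
#' @rdname binGrid
setMethod("binGrid", "BinMatrix", function(x) x@grid)
#' @rdname binGrid
setMethod("binGrid", "Segmentation", function(x) x@grid)

#' @rdname binRanges
setMethod("binRanges", "BinGrid", function(x) {
  sl <- seqlengths(x@seqinfo)
  w <- x@binWidth
  starts <- unlist(lapply(sl, function(L) seq.int(1L, L, by = w)),
                   use.names = FALSE)
  chrom <- rep(names(sl), x@binsPerChrom)
  ends <- pmin(starts + w - 1L, rep(unname(sl), x@binsPerChrom))
  GRanges(chrom, IRanges(starts, ends), seqinfo = x@seqinfo)
})
#' @rdname binRanges
setMethod("binRanges", "BinnedTrack", function(x) binRanges(x@grid))
#' @rdname binRanges
setMethod("binRanges", "Segmentation", function(x) binRanges(x@grid))

#' @rdname trackValues
setMethod("trackValues", "BinnedTrack", function(x) x@values)

#' @rdname binMatrix
setMethod("binMatrix", "BinMatrix", function(x) x@mat)

#' @rdname markNames
setMethod("markNames", "BinMatrix", function(x) colnames(x@mat))
#' @rdname markNames
setMethod("markNames", "StateHMM", function(x) colnames(x@emission))

#' @rdname nStates
setMethod("nStates", "StateHMM", function(x) x@K)
#' @rdname nStates
setMethod("nStates", "Segmentation", function(x) x@K)

#' @rdname emissionProbs
setMethod("emissionProbs", "StateHMM", function(x) x@emission)
#' @rdname transitionProbs
setMethod("transitionProbs", "StateHMM", function(x) x@transition)
#' @rdname initialProbs
setMethod("initialProbs", "StateHMM", function(x) x@initProb)
#' @rdname logLikTrace
setMethod("logLikTrace", "StateHMM", function(x) x@logLik)

#' @rdname stateLabels
setMethod("stateLabels", "Segmentation", function(x) x@states)

#' @rdname switchCounts
setMethod("switchCounts", "SwitchMatrix", function(x) x@counts)
#' @rdname switchCounts
setMethod("switchProbs", "SwitchMatrix", function(x) x@probabilities)
#' @rdname switchCounts
setMethod("switchEnrichment", "SwitchMatrix", function(x) x@enrichment)

#' @rdname geneRanges
setMethod("geneRanges", "GeneModels", function(x) x@genes)
#' @rdname geneExons
setMethod("geneExons", "GeneModels", function(x) x@exons)

setMethod("length", "GeneModels", function(x) length(x@genes))

#' @importMethodsFrom GenomeInfoDb seqinfo
setMethod("seqinfo", "BinGrid", function(x) x@seqinfo)

setMethod("show", "BinGrid", function(object) {
  cat("BinGrid:", length(object@binsPerChrom), "chromosome(s),",
      nBins(object), "bins of", object@binWidth, "bp\n")
})

setMethod("show", "BinnedTrack", function(object) {
  v <- object@values
  cat("BinnedTrack:", length(v), "bins;",
      sum(is.na(v)), "missing; mean =",
      signif(mean(v, na.rm = TRUE), 4), "\n")
})

setMethod("show", "BinMatrix", function(object) {
  cat("BinMatrix:", nrow(object@mat), "bins x", ncol(object@mat),
      "marks (", paste(colnames(object@mat), collapse = ", "), ")\n")
})

setMethod("show", "StateHMM", function(object) {
  cat("StateHMM:", object@K, "states,", ncol(object@emission), "marks;",
      "logLik =", signif(tail(object@logLik, 1), 8), "after",
      length(object@logLik), "EM iterations\n")
})

setMethod("show", "Segmentation", function(object) {
  tab <- tabulate(object@states, object@K)
  cat("Segmentation:", length(object@states), "bins,", object@K, "states;",
      "occupancy:", paste(signif(tab / sum(tab), 2), collapse = " "), "\n")
})

setMethod("show", "SwitchMatrix", function(object) {
  cat("SwitchMatrix:", nrow(object@counts), "states,",
      object@nBins, "bins compared\n")
})

setMethod("show", "GeneModels", function(object) {
  cls <- table(object@genes$gene_class)
  cat("GeneModels:", length(object@genes), "genes (",
      paste(names(cls), cls, sep = ":", collapse = ", "), ")\n")
})
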