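#' @import methods
#' @importClassesFrom GenomeInfoDb Seqinfo
#' @importClassesFrom GenomicRanges GRanges GRangesList
#' @importFrom GenomicRanges GRangesList
#' @importFrom GenomeInfoDb Seqinfo seqnames seqlengths seqinfo seqinfo<- seqlevels
#' @importFrom GenomicRanges GRanges granges mcols mcols<- findOverlaps pintersect
#'   reduce width start end strand seqnames gaps
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom S4Vectors queryHits subjectHits Pairs first second metadata metadata<-
#'   DataFrame mcols runValue Rle
#' @importFrom stats ppois rpois rbinom rbeta rlnorm runif rnorm kmeans p.adjust
#'   dbinom cor cor.test lm coef median sd quantile cmdscale complete.cases setNames
#' @importFrom utils head tail read.delim write.table modifyList
NULL

#' BinGrid: a fixed-width tiling of a genome
#'
#' A \code{BinGrid} partitions every chromosome of a genome into consecutive
#' bins of a fixed width (default 200 bp); the last bin of a chromosome may be
#' shorter.  All state, methylation and switching analyses in this package
#' operate at bin resolution, with bins indexed chromosome-major from 1.
#'
#' @slot seqinfo a \link[GenomeInfoDb]{Seqinfo} describing the genome.
#' @slot binWidth integer(1), bin width in bp.
#' @slot binsPerChrom named integer, number of bins per chromosome.
#'
#' @seealso \code{\link{makeBins}}, \code{\link{binRanges}}
#' @export
setClass("BinGrid",
  slots = c(seqinfo = "Seqinfo", binWidth = "integer",
            binsPerChrom = "integer"))

setValidity("BinGrid", function(object) {
  msg <- character()
  sl <- seqlengths(object@seqinfo)
  if (length(sl) == 0L) msg <- c(msg, "genome has no chromosomes")
  if (anyNA(sl) || any(sl < 1L)) msg <- c(msg, "chromosome lengths must be >= 1")
  if (anyDuplicated(names(sl))) msg <- c(msg, "chromosome names must be unique")
  if (length(object@binWidth) != 1L || is.na(object@binWidth) ||
      object@binWidth < 1L)
    msg <- c(msg, "binWidth must be a single positive integer")
  if (!identical(names(object@binsPerChrom), names(sl)))
    msg <- c(msg, "binsPerChrom names must match the genome")
  if (!all(object@binsPerChrom == as.integer(ceiling(sl / object@binWidth))))
    msg <- c(msg, "binsPerChrom inconsistent with lengths and binWidth")
  if (length(msg)) msg else TRUE
})

#' BinnedTrack: one value per genome bin
#'
#' Holds one numeric value (real, count, binary or \code{NA} for missing) for
#' every bin of a \code{\link{BinGrid}}.
#'
#' @slot grid the \code{BinGrid}.
#' @slot values numeric vector, one entry per bin.
#' @export
setClass("BinnedTrack", slots = c(grid = "BinGrid", values = "numeric"))

setValidity("BinnedTrack", function(object) {
  if (length(object@values) != nBins(object@grid))
    "length(values) must equal the number of bins" else TRUE
})

#' BinMatrix: a bins x marks matrix on a BinGrid
#'
#' Used both for per-mark read counts and for binarized presence calls
#' (entries in \{0,1\}).  Columns are named by mark.
#'
#' @slot grid the \code{BinGrid}.
#' @slot mat numeric matrix with \code{nBins(grid)} rows and one column per mark.
#' @export
setClass("BinMatrix", slots = c(grid = "BinGrid", mat = "matrix"))

setValidity("BinMatrix", function(object) {
  msg <- character()
  if (nrow(object@mat) != nBins(object@grid))
    msg <- c(msg, "matrix rows must equal the number of bins")
  if (is.null(colnames(object@mat)))
    msg <- c(msg, "matrix columns must be named by mark")
  if (length(msg)) msg else TRUE
})

#' StateHMM: a multivariate-Bernoulli hidden Markov model
#'
#' A K-state HMM over binarized mark presence: each state emits each mark
#' independently with a Bernoulli probability, states follow a first-order
#' Markov chain along the bins of each chromosome.
#'
#' @slot K integer(1), number of states.
#' @slot emission K x M matrix, \code{emission[k, m]} = P(mark m present | state k).
#' @slot transition K x K row-stochastic transition matrix.
#' @slot initProb length-K initial state distribution.
#' @slot logLik numeric, training log-likelihood trace (one entry per EM
#'   iteration of the winning restart).
#' @export
setClass("StateHMM",
  slots = c(K = "integer", emission = "matrix", transition = "matrix",
            initProb = "numeric", logLik = "numeric"))

setValidity("StateHMM", function(object) {
  msg <- character()
  K <- object@K
  if (nrow(object@emission) != K) msg <- c(msg, "emission must have K rows")
  if (any(object@emission < 0 | object@emission > 1))
    msg <- c(msg, "emission entries must lie in [0, 1]")
  if (!all(dim(object@transition) == c(K, K)))
    msg <- c(msg, "transition must be K x K")
  if (any(abs(rowSums(object@transition) - 1) > 1e-9))
    msg <- c(msg, "transition rows must sum to 1")
  if (length(object@initProb) != K || abs(sum(object@initProb) - 1) > 1e-9)
    msg <- c(msg, "initProb must be a length-K distribution")
  if (length(object@logLik) > 1 &&
      any(diff(object@logLik) < -1e-6 * pmax(1, abs(object@logLik[-1]))))
    msg <- c(msg, "log-likelihood trace must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' Segmentation: per-bin chromatin state labels
#'
#' @slot grid the \code{BinGrid}.
#' @slot states integer vector of state ids in 1..K, one per bin.
#' @slot K integer(1), number of states of the generating model.
#' @export
setClass("Segmentation",
  slots = c(grid = "BinGrid", states = "integer", K = "integer"))

setValidity("Segmentation", function(object) {
  msg <- character()
  if (length(object@states) != nBins(object@grid))
    msg <- c(msg, "states must label every bin")
  if (anyNA(object@states) || any(object@states < 1L) ||
      any(object@states > object@K))
    msg <- c(msg, "state ids must lie in 1..K")
  if (length(msg)) msg else TRUE
})

#' SwitchMatrix: chromatin-state switching between two conditions
#'
#' Raw K x K counts of bins labeled (s1 in A, s2 in B), the symmetrized
#' counts (counts + transpose), row-normalized switching probabilities, and
#' an enrichment transform (probability divided by the genome fraction of the
#' target state) with its log10.
#'
#' @slot counts K x K raw switch counts.
#' @slot symmetrized counts + t(counts).
#' @slot probabilities row-normalized symmetrized matrix (empty rows NA).
#' @slot enrichment probabilities divided by target-state genome fraction.
#' @slot log10Enrichment log10 of enrichment, zeros/masked cells NA.
#' @slot stateFractions genome fraction per state pooled over the two inputs.
#' @slot nBins integer(1), number of bins compared.
#' @export
setClass("SwitchMatrix",
  slots = c(counts = "matrix", symmetrized = "matrix",
            probabilities = "matrix", enrichment = "matrix",
            log10Enrichment = "matrix", stateFractions = "numeric",
            nBins = "integer"))

setValidity("SwitchMatrix", function(object) {
  msg <- character()
  if (sum(object@counts) != object@nBins)
    msg <- c(msg, "raw counts must sum to the number of bins compared")
  if (!isTRUE(all.equal(object@symmetrized, t(object@symmetrized))))
    msg <- c(msg, "symmetrized matrix must equal its transpose")
  rs <- rowSums(object@probabilities)
  ok <- !is.na(rs)
  if (any(abs(rs[ok] - 1) > 1e-9))
    msg <- c(msg, "probability rows must sum to 1")
  if (length(msg)) msg else TRUE
})

#' GeneModels: gene annotations with transcript landmarks
#'
#' Gene bodies as a \link[GenomicRanges]{GRanges} carrying per-gene metadata
#' (\code{gene_id}, \code{tss}, \code{atg}, \code{gene_class}), plus the exon
#' structure as a \link[GenomicRanges]{GRangesList} named by gene id.  TSS and
#' ATG are stored as 1-based positions; the TSS is the first transcribed base
#' and the ATG the first base of the CDS, both in transcription orientation.
#'
#' @slot genes GRanges of gene bodies with mcols gene_id, tss, atg, gene_class.
#' @slot exons GRangesList of exons, named by gene id (possibly empty per gene).
#' @export
setClass("GeneModels",
  slots = c(genes = "GRanges", exons = "GRangesList"))

setValidity("GeneModels", function(object) {
  msg <- character()
  need <- c("gene_id", "tss", "atg", "gene_class")
  if (!all(need %in% colnames(mcols(object@genes))))
    msg <- c(msg, paste("genes must carry mcols:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@genes$gene_id))
      msg <- c(msg, "gene ids must be unique")
    if (!all(names(object@exons) %in% object@genes$gene_id))
      msg <- c(msg, "exon list names must be gene ids")
  }
  if (length(msg)) msg else TRUE
})
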