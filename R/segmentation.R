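#' @include AllGenerics.R
NULL

#' Binarize mark counts against an input track
#'
#' A bin is called present (1) when its read count is improbably high under
#' a Poisson background whose local expectation is the mark's global
#' background rate scaled by the local input enrichment, \code{lambda_b =
#' bg_rate * max(input_b / mean(input), 1)}; the floor at the global
#' background rate prevents low-input bins from inflating significance.
#' The background rate is estimated robustly by iterative Poisson trimming
#' (bins above the 99.9\% quantile of the current estimate are discarded and
#' the mean recomputed), so enriched bins do not contaminate the
#' expectation.  Presence requires the upper tail probability
#' \code{P(X >= c | lambda_b)} to be at most \code{pThreshold}.
#'
#' @param counts a \linkS4class{BinnedTrack} of mark read counts.
#' @param input a \linkS4class{BinnedTrack} of input (control) read counts on
#'   the same grid.
#' @param pThreshold Poisson upper-tail threshold (default 1e-4).
#' @return a binary \linkS4class{BinnedTrack}.
#' @export
binarizeTrack <- function(counts, input, pThreshold = 1e-4) {
  if (!identical(binGrid(counts)@binsPerChrom, binGrid(input)@binsPerChrom))
    stop("counts and input must be on the same grid")
  cv <- trackValues(counts)
  iv <- trackValues(input)
  rate <- .backgroundRate(cv)
  if (all(iv == 0)) {
    warning("all-zero input track; falling back to the global background rate")
    lambda <- rep(rate, length(cv))
  } else {
    lambda <- rate * pmax(iv / mean(iv), 1)
  }
  p <- ppois(cv - 1, lambda, lower.tail = FALSE)
  .BinnedTrack(binGrid(counts), as.numeric(p <= pThreshold & cv > 0))
}

## global background rate by iterative Poisson trimming of enriched bins
.backgroundRate <- function(cv) {
  bg <- mean(cv)
  if (bg == 0) return(0)
  for (i in 1:4) {
    keep <- cv <= stats::qpois(0.999, bg)
    newbg <- mean(cv[keep])
    if (abs(newbg - bg) < 1e-8) break
    bg <- newbg
  }
  bg
}

#' Binarize a full bins x marks count matrix
#'
#' @param counts a \linkS4class{BinMatrix} of read counts.
#' @param input a \linkS4class{BinnedTrack} of input counts.
#' @param pThreshold Poisson upper-tail threshold.
#' @return a binary \linkS4class{BinMatrix}.
#' @export
binarizeMatrix <- function(counts, input, pThreshold = 1e-4) {
  grid <- binGrid(counts)
  m <- binMatrix(counts)
  out <- vapply(colnames(m), function(mk)
    trackValues(binarizeTrack(.BinnedTrack(grid, m[, mk]), input, pThreshold)),
    numeric(nrow(m)))
  .BinMatrix(grid, out)
}

.logEmissionMatrix <- function(B, emission) {
  E <- pmin(pmax(emission, 1e-10), 1 - 1e-10)
  B %*% t(log(E)) + (1 - B) %*% t(log1p(-E))
}

.seqIndex <- function(grid) {
  n <- unname(grid@binsPerChrom)
  list(start = as.integer(cumsum(c(1L, head(n, -1L)))), len = as.integer(n))
}

#' Fit a multivariate-Bernoulli hidden Markov model
#'
#' Baum-Welch EM over a binarized bins x marks matrix.  Each state emits
#' each mark independently with a Bernoulli probability; chromosomes are
#' treated as independent sequences.  Several random restarts are run and
#' the model with the best log-likelihood is returned; the log-likelihood is
#' asserted non-decreasing at every iteration.
#'
#' @param B a binary \linkS4class{BinMatrix}, or a list of them (e.g. one per
#'   tissue) for concatenated training: the matrices are stacked and every
#'   chromosome of every matrix is an independent sequence.
#' @param K number of states.
#' @param seed RNG seed for the restarts.
#' @param nInit number of random restarts (default 5).
#' @param maxIter maximum EM iterations (default 200).
#' @param tol relative log-likelihood gain below which EM stops (default 1e-4).
#' @return a \linkS4class{StateHMM}.
#' @export
fitStateHMM <- function(B, K, seed = 1L, nInit = 5L, maxIter = 200L,
                        tol = 1e-4) {
  K <- as.integer(K)
  if (is.list(B)) {
    mats <- lapply(B, binMatrix)
    mat <- do.call(rbind, mats)
    sqs <- lapply(B, function(b) .seqIndex(binGrid(b)))
    off <- cumsum(c(0L, vapply(mats, nrow, integer(1))))
    sq <- list(
      start = unlist(lapply(seq_along(sqs), function(i)
        sqs[[i]]$start + off[i])),
      len = unlist(lapply(sqs, `[[`, "len")))
  } else {
    mat <- binMatrix(B)
    sq <- .seqIndex(binGrid(B))
  }
  if (!all(mat %in% c(0, 1))) stop("input matrix must be binary")
  if (K < 1L) stop("K must be >= 1")
  if (K > nrow(mat)) stop("K exceeds the number of bins")
  M <- ncol(mat)
  cm <- colMeans(mat)
  best <- NULL
  for (i in seq_len(nInit)) {
    set.seed(substreamSeed(seed, paste0("hmm-init-", i)))
    E <- matrix(pmin(pmax(rep(cm, each = K) +
                            runif(K * M, -0.4, 0.4), 0.02), 0.98), K, M)
    A <- matrix((1 - 0.9) / max(1, K - 1), K, K)
    diag(A) <- if (K == 1L) 1 else 0.9
    pi0 <- rep(1 / K, K)
    trace <- numeric()
    for (it in seq_len(maxIter)) {
      fb <- cpp_forward_backward(.logEmissionMatrix(mat, E), A, pi0,
                                 sq$start, sq$len)
      ll <- fb$logLik
      if (length(trace) &&
          ll < tail(trace, 1) - 1e-6 * max(1, abs(tail(trace, 1))))
        stop("EM log-likelihood decreased; numerical failure")
      converged <- length(trace) &&
        (ll - tail(trace, 1)) < tol * abs(tail(trace, 1))
      trace <- c(trace, ll)
      gamma <- fb$gamma
      gs <- colSums(gamma)
      E <- (t(gamma) %*% mat) / gs
      if (K > 1L) {
        xi <- fb$xiSum
        rs <- rowSums(xi)
        A <- xi / ifelse(rs > 0, rs, 1)
        A[rs == 0, ] <- 1 / K
      }
      pi0 <- fb$initGamma / sum(fb$initGamma)
      if (converged) break
    }
    if (is.null(best) || tail(trace, 1) > tail(best$trace, 1))
      best <- list(E = E, A = A, pi0 = pi0, trace = trace)
  }
  dimnames(best$E) <- list(paste0("S", seq_len(K)), colnames(mat))
  dimnames(best$A) <- list(paste0("S", seq_len(K)), paste0("S", seq_len(K)))
  new("StateHMM", K = K, emission = best$E, transition = best$A,
      initProb = best$pi0, logLik = best$trace)
}

#' Decode a segmentation from a fitted model
#'
#' The default posterior rule labels each bin with the state maximizing the
#' forward-backward posterior (ties broken by the lower state id); the
#' viterbi rule returns the jointly most probable path.
#'
#' @param model a \linkS4class{StateHMM}.
#' @param B a binary \linkS4class{BinMatrix} with the model's marks.
#' @param rule "posterior" (default) or "viterbi".
#' @return a \linkS4class{Segmentation}.
#' @export
decodeStates <- function(model, B, rule = c("posterior", "viterbi")) {
  rule <- match.arg(rule)
  mat <- binMatrix(B)
  if (!identical(colnames(mat), markNames(model)))
    stop("mark names of matrix and model differ")
  sq <- .seqIndex(binGrid(B))
  le <- .logEmissionMatrix(mat, emissionProbs(model))
  states <- if (rule == "posterior") {
    fb <- cpp_forward_backward(le, transitionProbs(model),
                               initialProbs(model), sq$start, sq$len)
    max.col(fb$gamma, ties.method = "first")
  } else {
    cpp_viterbi(le, transitionProbs(model), initialProbs(model),
                sq$start, sq$len)
  }
  .Segmentation(binGrid(B), states, nStates(model))
}

#' Posterior state probabilities per bin
#'
#' @param model a \linkS4class{StateHMM}.
#' @param B a binary \linkS4class{BinMatrix}.
#' @return bins x K matrix of forward-backward posteriors.
#' @export
statePosteriors <- function(model, B) {
  mat <- binMatrix(B)
  sq <- .seqIndex(binGrid(B))
  cpp_forward_backward(.logEmissionMatrix(mat, emissionProbs(model)),
                       transitionProbs(model), initialProbs(model),
                       sq$start, sq$len)$gamma
}

#' Default chromatin-state category rules
#'
#' A state is Quies when every emission probability is below
#' \code{quiesMax}; repressive when the H3K27me3 emission is the state's
#' maximum and at least \code{reprMin}; inactive when the H3K9me2 emission
#' is at least \code{inactMin} (flagged bivalent when H3K4me1 is also at
#' least \code{bivMin}); active otherwise.
#'
#' @param quiesMax,reprMin,inactMin,bivMin thresholds on emission
#'   probabilities.
#' @param reprMark,inactMark,bivMark mark names used by the rules.
#' @return a named list of rules for \code{\link{stateCategories}}.
#' @export
stateCategoryRules <- function(quiesMax = 0.1, reprMin = 0.3, inactMin = 0.3,
                               bivMin = 0.3, reprMark = "H3K27me3",
                               inactMark = "H3K9me2", bivMark = "H3K4me1") {
  list(quiesMax = quiesMax, reprMin = reprMin, inactMin = inactMin,
       bivMin = bivMin, reprMark = reprMark, inactMark = inactMark,
       bivMark = bivMark)
}

#' Assign categories to states from their emission profiles
#'
#' @param emission K x M emission matrix with mark column names.
#' @param rules a rule list from \code{\link{stateCategoryRules}}.
#' @return character vector of categories ("active", "repressive",
#'   "inactive", "Quies") with a logical \code{bivalent} attribute.
#' @export
stateCategories <- function(emission, rules = stateCategoryRules()) {
  marks <- colnames(emission)
  getcol <- function(mk) if (mk %in% marks) emission[, mk] else
    rep(0, nrow(emission))
  repr <- getcol(rules$reprMark)
  inact <- getcol(rules$inactMark)
  biv <- getcol(rules$bivMark)
  mx <- apply(emission, 1L, max)
  cat <- ifelse(mx < rules$quiesMax, "Quies",
         ifelse(inact >= rules$inactMin, "inactive",
         ifelse(repr == mx & repr >= rules$reprMin, "repressive", "active")))
  attr(cat, "bivalent") <- inact >= rules$inactMin & biv >= rules$bivMin
  cat
}

#' Annotate a segmentation with coverage, enrichments and categories
#'
#' Computes per-state genome coverage, bp-based fold enrichment over feature
#' classes, and (when a model is supplied) the emission-based category of
#' each state.  Fold enrichment of state s over feature f is
#' \code{(bp(s & f) / bp(s)) / (bp(f) / genome bp)}.
#'
#' @param seg a \linkS4class{Segmentation}.
#' @param model optional \linkS4class{StateHMM} for category calls.
#' @param genes optional \linkS4class{GeneModels}; contributes TSS, TTS,
#'   exon, intron and intergenic feature classes.
#' @param tes optional GRanges of transposable elements with a \code{family}
#'   mcol; contributes one feature class per family.
#' @param features optional named list of GRanges overriding/extending the
#'   derived feature classes.
#' @param rules category rules (see \code{\link{stateCategoryRules}}).
#' @param landmarkWindow half-width in bp of the TSS/TTS feature windows
#'   (default 200).
#' @return list with elements \code{coverage} (per-state genome fraction),
#'   \code{enrichment} (states x features matrix), \code{categories}
#'   (or NULL).
#' @export
annotateStates <- function(seg, model = NULL, genes = NULL, tes = NULL,
                           features = NULL, rules = stateCategoryRules(),
                           landmarkWindow = 200L) {
  states <- stateLabels(seg)
  if (length(states) == 0L) stop("empty segmentation")
  K <- nStates(seg)
  br <- binRanges(seg)
  genomeBp <- sum(as.numeric(width(br)))
  coverage <- tabulate(states, K) / length(states)
  names(coverage) <- paste0("S", seq_len(K))
  feats <- list()
  if (!is.null(genes)) {
    g <- geneRanges(genes)
    neg <- as.character(strand(g)) == "-"
    tts <- ifelse(neg, start(g), end(g))
    mkwin <- function(pos) {
      sl <- seqlengths(seqinfo(br))
      GRanges(seqnames(g),
              IRanges(pmax(pos - landmarkWindow, 1L),
                      pmin(pos + landmarkWindow,
                           sl[as.character(seqnames(g))])))
    }
    ex <- unlist(geneExons(genes), use.names = FALSE)
    feats$TSS <- mkwin(g$tss)
    feats$TTS <- mkwin(tts)
    feats$exon <- reduce(ex)
    feats$intron <- GenomicRanges::setdiff(reduce(granges(g)), reduce(ex),
                                           ignore.strand = TRUE)
    feats$intergenic <- gaps(reduce(granges(g), ignore.strand = TRUE))
    feats$intergenic <-
      feats$intergenic[strand(feats$intergenic) == "*"]
  }
  if (!is.null(tes)) {
    for (fam in unique(tes$family))
      feats[[fam]] <- reduce(tes[tes$family == fam])
  }
  if (!is.null(features)) feats[names(features)] <- features
  enrichment <- NULL
  if (length(feats)) {
    enrichment <- matrix(NA_real_, K, length(feats),
                         dimnames = list(names(coverage), names(feats)))
    stateRegions <- lapply(seq_len(K), function(k)
      reduce(br[states == k], ignore.strand = TRUE))
    for (f in seq_along(feats)) {
      fr <- reduce(feats[[f]], ignore.strand = TRUE)
      fbp <- sum(as.numeric(width(fr)))
      for (k in seq_len(K)) {
        sbp <- sum(as.numeric(width(stateRegions[[k]])))
        if (sbp == 0 || fbp == 0) next
        ibp <- sum(as.numeric(width(GenomicRanges::intersect(
          stateRegions[[k]], fr, ignore.strand = TRUE))))
        enrichment[k, f] <- (ibp / sbp) / (fbp / genomeBp)
      }
    }
  }
  categories <- if (!is.null(model))
    stateCategories(emissionProbs(model), rules) else NULL
  list(coverage = coverage, enrichment = enrichment, categories = categories)
}
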