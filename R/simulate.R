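#' @include AllGenerics.R
NULL

#' Canonical 15-state emission matrix
#'
#' A structured multivariate-Bernoulli emission matrix over the seven
#' default marks, with rows for the recurrent chromatin-state archetypes of
#' a plant epigenome: weak/strong/poised promoter states, a bivalent
#' promoter, promoter-flanking and transcription states, an active TTS
#' state, intergenic active and open-chromatin states, a Polycomb state, an
#' H3K4me1+H3K9me2 bivalent heterochromatin state, canonical
#' heterochromatin, and a quiescent state.  For \code{K < 15} a
#' representative subset of rows is returned (most distinct archetypes
#' first).
#'
#' @param K number of states (1..15).
#' @param marks mark names (subset/order of the seven defaults).
#' @return K x length(marks) emission matrix.
#' @export
defaultEmission <- function(K = 15L,
                            marks = c("H3K4me3", "H3K27ac", "H3K4me1",
                                      "H3K27me3", "H3K9me2", "RNAPII",
                                      "FAIRE")) {
  full <- rbind(
    TssWk     = c(0.50, 0.05, 0.10, 0.05, 0.02, 0.10, 0.30),
    TssA      = c(0.90, 0.30, 0.10, 0.02, 0.02, 0.30, 0.60),
    TssAP     = c(0.90, 0.80, 0.10, 0.02, 0.02, 0.80, 0.70),
    TssBiv    = c(0.45, 0.05, 0.05, 0.50, 0.02, 0.10, 0.20),
    TssAFlnk1 = c(0.50, 0.50, 0.60, 0.02, 0.02, 0.30, 0.20),
    TssAFlnk2 = c(0.40, 0.20, 0.70, 0.02, 0.02, 0.30, 0.10),
    TxWk      = c(0.05, 0.05, 0.60, 0.02, 0.02, 0.10, 0.05),
    Tx        = c(0.05, 0.05, 0.80, 0.02, 0.02, 0.70, 0.05),
    TtsAFlnk  = c(0.10, 0.10, 0.40, 0.02, 0.02, 0.80, 0.10),
    IntA      = c(0.05, 0.60, 0.10, 0.02, 0.02, 0.10, 0.30),
    OpenChr   = c(0.05, 0.10, 0.05, 0.02, 0.05, 0.05, 0.80),
    ReprPC    = c(0.05, 0.02, 0.05, 0.70, 0.05, 0.02, 0.05),
    Copia     = c(0.02, 0.02, 0.50, 0.05, 0.60, 0.02, 0.02),
    Het       = c(0.02, 0.02, 0.05, 0.05, 0.80, 0.02, 0.02),
    Quies     = c(0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02))
  colnames(full) <- c("H3K4me3", "H3K27ac", "H3K4me1", "H3K27me3",
                      "H3K9me2", "RNAPII", "FAIRE")
  priority <- c("TssAP", "Tx", "ReprPC", "Het", "Quies", "TssA", "TxWk",
                "IntA", "OpenChr", "Copia", "TssBiv", "TssAFlnk1",
                "TtsAFlnk", "TssWk", "TssAFlnk2")
  stopifnot(K >= 1L, K <= 15L, all(marks %in% colnames(full)))
  rows <- priority[seq_len(K)]
  rows <- rows[order(match(rows, rownames(full)))]
  full[rows, marks, drop = FALSE]
}

#' Simulation configuration
#'
#' Assembles the full parameter set of the synthetic-epigenome generator;
#' any element can be overridden by name.  The defaults describe a compact
#' desk-scale study: a 2 x 2 Mb genome at 200-bp bins, a 15-state model
#' over five histone marks plus RNAPII occupancy and open chromatin
#' (FAIRE), three tissues, and a 20-variety panel structured into the five
#' rice subpopulation groups (9 Xian/Indica, 2 Geng/Japonica, 2 Aus, 2
#' aromatic, 5 intermediate).  All randomness derives from the master seed
#' through named substreams.
#'
#' @param ... named overrides of any default element.
#' @return a list of class \code{SimConfig}.
#' @export
simConfig <- function(...) {
  marks <- c("H3K4me3", "H3K27ac", "H3K4me1", "H3K27me3", "H3K9me2",
             "RNAPII", "FAIRE")
  cfg <- list(
    genome = c(chr1 = 2e6, chr2 = 2e6),
    binWidth = 200L,
    marks = marks,
    nStates = 15L,
    emission = defaultEmission(15L, marks),
    stickiness = 0.95,
    stateWeights = NULL,  # derived: Quies-heavy genome, see .stateWeights
    tissues = c("young_leaf", "mature_leaf", "panicle"),
    tissueSwitchRate = 0.1,
    depth = 30,
    fgBgRatio = 20,
    inputDepthFactor = 1,
    overdispersion = 0,
    annotationBias = list(promoter = 0.9, gypsyHet = 0.9, copiaBiv = 0.7),
    annotation = list(
      nGenes = 300L, geneLengthRange = c(1000, 4000), exonsPerGene = 1:3,
      teGeneFraction = 0.1, nTEs = 250L, teLengthRange = c(200, 2000),
      teFamilies = c("Copia", "Gypsy", "LINE", "SINE", "hAT", "CACTA",
                     "Mariner", "Mutator", "Harbinger", "Helitron"),
      teFamilyWeights = c(4, 6, 2, 1, 1, 1, 1, 1, 1, 1)),
    methylome = list(
      density = c(CG = 0.05, CHG = 0.03, CHH = 0.10),
      coverage = 20, levelSd = 0.03,
      levelByCategory = rbind(
        active     = c(CG = 0.05, CHG = 0.02, CHH = 0.01),
        repressive = c(CG = 0.40, CHG = 0.20, CHH = 0.05),
        inactive   = c(CG = 0.90, CHG = 0.60, CHH = 0.15),
        Quies      = c(CG = 0.50, CHG = 0.30, CHH = 0.05)),
      nDMR = 100L, dmrDelta = 0.7, dmrContext = "CG"),
    expression = list(
      meanlog = c(active = 3, repressive = 0, inactive = -3, Quies = -1.5),
      sdlog = 1),
    elements = list(
      nPRE = 60L, nDRE = 60L, preWidth = 400L, dreWidth = 400L,
      dreMinTssDist = 3000L, tissueSpecificFraction = 0.6,
      signalHigh = 10, signalLow = 1, signalConstitutive = 8,
      signalNoiseSd = 0.15, nLoops = 30L),
    panel = list(
      varieties = sprintf("var%02d", 1:20),
      subgroup = rep(c("Xian", "Geng", "Aus", "aromatic", "intermediate"),
                     c(9, 2, 2, 2, 5)),
      withinRate = 0.02, betweenRate = 0.1, nFixedDiff = 50L,
      snpRate = c(active = 0.002, repressive = 0.003, inactive = 0.010,
                  Quies = 0.005),
      flankBoost = 3, flankBins = 2L),
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, over)
  names(cfg$panel$subgroup) <- cfg$panel$varieties
  stopifnot(all(cfg$emission >= 0 & cfg$emission <= 1),
            cfg$tissueSwitchRate >= 0, cfg$tissueSwitchRate <= 1,
            cfg$panel$withinRate >= 0, cfg$panel$withinRate <= 1,
            cfg$panel$betweenRate >= 0, cfg$panel$betweenRate <= 1)
  structure(cfg, class = c("SimConfig", "list"))
}

.simGrid <- function(config) makeBins(genomeIndex(config$genome),
                                      config$binWidth)

.simCategories <- function(config)
  as.character(stateCategories(config$emission))

## state weights of the jump chain: genomes are mostly quiescent and
## heterochromatic, so the inactive archetypes carry the bulk of the mass
## and each mark's genome-wide presence stays realistic (roughly 10-20%)
.stateWeights <- function(config) {
  if (!is.null(config$stateWeights)) return(config$stateWeights)
  cats <- .simCategories(config)
  w <- c(active = 0.5, repressive = 0.8, inactive = 1.5, Quies = 3)[cats]
  unname(w / sum(w))
}

## run-length Markov path: self-transition = stickiness, next state drawn
## by weight among the others
.markovPath <- function(n, K, stickiness, weights = rep(1 / K, K)) {
  if (stickiness >= 1 || K == 1L)
    return(rep(sample.int(K, 1L, prob = weights), n))
  out <- integer(n)
  pos <- 1L
  s <- sample.int(K, 1L, prob = weights)
  while (pos <= n) {
    len <- 1L + stats::rgeom(1L, 1 - stickiness)
    idx <- pos:min(n, pos + len - 1L)
    out[idx] <- s
    pos <- pos + len
    s <- sample(seq_len(K)[-s], 1L, prob = weights[-s])
  }
  out
}

## redraw whole runs of a path with the given probability
.redrawSegments <- function(states, rate, K) {
  if (rate <= 0) return(states)
  r <- rle(states)
  flip <- runif(length(r$values)) < rate
  newv <- vapply(which(flip), function(i)
    sample(seq_len(K)[-r$values[i]], 1L), integer(1))
  r$values[flip] <- newv
  inverse.rle(r)
}

#' Simulate a gene and TE annotation
#'
#' Places non-overlapping genes (with exon structure and an ATG inside the
#' first exon) by random stick-breaking of the inter-gene space, and TE
#' intervals with family labels drawn by weight.  A configured fraction of
#' genes is labeled TE-gene.
#'
#' @param config a \code{\link{simConfig}}.
#' @param seed master seed (default from config).
#' @return list with \code{genes} (a \linkS4class{GeneModels}) and
#'   \code{tes} (GRanges with a \code{family} mcol).
#' @export
simulateAnnotation <- function(config, seed = config$seed) {
  set.seed(substreamSeed(seed, "annotation"))
  an <- config$annotation
  genome <- genomeIndex(config$genome)
  sl <- seqlengths(genome)
  nG <- an$nGenes
  if (nG * mean(an$geneLengthRange) >= 0.9 * sum(as.numeric(sl)))
    stop("infeasible gene density for this genome")
  perChrom <- diff(round(c(0, cumsum(as.numeric(sl)) / sum(as.numeric(sl)) * nG)))
  geneGr <- GRanges(seqinfo = genome)
  exonList <- list()
  meta <- list()
  gid <- 0L
  for (ci in seq_along(sl)) {
    n <- perChrom[ci]
    if (n == 0L) next
    L <- sl[ci]
    len <- round(runif(n, an$geneLengthRange[1L], an$geneLengthRange[2L]))
    gapTotal <- L - sum(len)
    if (gapTotal <= n) stop("infeasible gene density for this genome")
    cuts <- sort(sample.int(gapTotal - 1L, n))
    gaps <- diff(c(0L, cuts))
    starts <- cumsum(gaps) + c(0L, cumsum(len[-n]))
    strands <- sample(c("+", "-"), n, replace = TRUE)
    for (i in seq_len(n)) {
      gid <- gid + 1L
      id <- sprintf("g%04d", gid)
      gs <- starts[i] + 1L
      ge <- starts[i] + len[i]
      nEx <- sample(an$exonsPerGene, 1L)
      ## alternate exon/intron widths summing to the gene length
      parts <- 2L * nEx - 1L
      w <- as.vector(stats::rmultinom(1L, len[i] - parts, rep(1, parts))) + 1L
      bnd <- gs + cumsum(c(0L, head(w, -1L)))
      exs <- bnd[seq(1L, parts, by = 2L)]
      exe <- exs + w[seq(1L, parts, by = 2L)] - 1L
      tss <- if (strands[i] == "-") ge else gs
      off <- sample(30:150, 1L)
      atg <- if (strands[i] == "-") ge - off else gs + off
      geneGr <- c(geneGr, GRanges(names(sl)[ci], IRanges(gs, ge),
                                  strand = strands[i], seqinfo = genome))
      exonList[[id]] <- GRanges(names(sl)[ci], IRanges(exs, exe),
                                strand = strands[i], seqinfo = genome)
      meta[[id]] <- data.frame(gene_id = id, tss = tss, atg = atg)
    }
  }
  md <- do.call(rbind, meta)
  if (is.null(md)) {
    g <- GRanges(seqinfo = genome)
    mcols(g) <- DataFrame(gene_id = character(), tss = integer(),
                          atg = integer(), gene_class = character())
    genes <- new("GeneModels", genes = g,
                 exons = GenomicRanges::GRangesList())
  } else {
    md$gene_class <- ifelse(runif(nrow(md)) < an$teGeneFraction,
                            "TE-gene", "gene")
    mcols(geneGr) <- DataFrame(md)
    genes <- new("GeneModels", genes = geneGr,
                 exons = GenomicRanges::GRangesList(exonList))
  }
  nT <- an$nTEs
  teChrom <- sample(names(sl), nT, replace = TRUE,
                    prob = as.numeric(sl) / sum(as.numeric(sl)))
  teLen <- round(runif(nT, an$teLengthRange[1L], an$teLengthRange[2L]))
  teStart <- vapply(seq_len(nT), function(i)
    sample.int(sl[teChrom[i]] - teLen[i], 1L), integer(1))
  tes <- GRanges(teChrom, IRanges(teStart, width = teLen), seqinfo = genome)
  tes$family <- sample(an$teFamilies, nT, replace = TRUE,
                       prob = an$teFamilyWeights)
  list(genes = genes, tes = tes)
}

#' Simulate per-tissue true chromatin-state paths
#'
#' The base tissue's path is a first-order Markov chain over the bins of
#' each chromosome with self-transition probability \code{stickiness}.
#' When an annotation is given, bins at gene TSSs are biased toward the
#' strongest-H3K4me3 state, Gypsy TE bins toward the strongest-H3K9me2
#' state, and Copia TE bins toward the bivalent H3K4me1+H3K9me2 state.
#' Each further tissue is derived by re-drawing whole segments of the base
#' path with probability \code{tissueSwitchRate}.
#'
#' @param config a \code{\link{simConfig}}.
#' @param annotation optional output of \code{\link{simulateAnnotation}}.
#' @param seed master seed.
#' @return named list of \linkS4class{Segmentation}s, one per tissue.
#' @export
simulateStates <- function(config, annotation = NULL, seed = config$seed) {
  K <- config$nStates
  if (K < 2L) stop("need K >= 2 states")
  if (config$stickiness <= 0 || config$stickiness > 1)
    stop("stickiness must lie in (0, 1]")
  set.seed(substreamSeed(seed, "states"))
  grid <- .simGrid(config)
  n <- unname(grid@binsPerChrom)
  base <- unlist(lapply(n, .markovPath, K = K,
                        stickiness = config$stickiness,
                        weights = .stateWeights(config)))
  if (!is.null(annotation)) {
    E <- config$emission
    bias <- config$annotationBias
    promState <- which.max(E[, "H3K4me3"])
    hetState <- which.max(E[, "H3K9me2"])
    ## Copia TEs go to the H3K4me1+H3K9me2 bivalent state when the model has
    ## one, otherwise to plain heterochromatin
    bivScore <- pmin(E[, "H3K9me2"], E[, "H3K4me1"])
    bivState <- if (max(bivScore) >= 0.3) which.max(bivScore) else hetState
    g <- geneRanges(annotation$genes)
    if (length(g)) {
      tssBin <- globalBinIndex(grid, as.character(seqnames(g)), g$tss)
      pick <- runif(length(tssBin)) < bias$promoter
      base[tssBin[pick]] <- promState
    }
    applyTe <- function(fam, state, p) {
      te <- annotation$tes[annotation$tes$family == fam]
      if (!length(te)) return()
      hits <- findOverlaps(binRanges(grid), te)
      b <- unique(queryHits(hits))
      pick <- runif(length(b)) < p
      base[b[pick]] <<- state
    }
    applyTe("Gypsy", hetState, bias$gypsyHet)
    applyTe("Copia", bivState, bias$copiaBiv)
  }
  segs <- list(.Segmentation(grid, base, K))
  for (t in seq_along(config$tissues)[-1L])
    segs[[t]] <- .Segmentation(grid,
                               .redrawSegments(base, config$tissueSwitchRate, K),
                               K)
  names(segs) <- config$tissues
  segs
}

#' Simulate mark read-count tracks from a state path
#'
#' For every mark, bin presence is Bernoulli with the state's emission
#' probability, and the read count Poisson with mean \code{depth * (bg + fg
#' * present)} where \code{fg/bg = fgBgRatio}; the input (control) track is
#' Poisson at \code{depth * inputDepthFactor}, emulating an input library
#' sequenced to comparable depth.  An optional negative-binomial overdispersion
#' knob replaces the Poisson draws.
#'
#' @param seg a \linkS4class{Segmentation} (a true state path).
#' @param config a \code{\link{simConfig}}.
#' @param seed master seed.
#' @param stream substream suffix so different tissues get independent draws.
#' @return list with \code{counts} (\linkS4class{BinMatrix}), \code{input}
#'   (\linkS4class{BinnedTrack}), \code{presence} (binary
#'   \linkS4class{BinMatrix}, the recorded truth).
#' @export
simulateTracks <- function(seg, config, seed = config$seed, stream = "") {
  if (config$depth <= 0) stop("depth must be positive")
  set.seed(substreamSeed(seed, paste0("tracks", stream)))
  E <- config$emission
  states <- stateLabels(seg)
  n <- length(states)
  bg <- 1 / (1 + config$fgBgRatio)
  fg <- 1 - bg
  draw <- function(mu) {
    if (config$overdispersion > 0)
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$overdispersion)
    else rpois(length(mu), mu)
  }
  marks <- config$marks
  presence <- counts <- matrix(0, n, length(marks),
                               dimnames = list(NULL, marks))
  for (m in seq_along(marks)) {
    pr <- rbinom(n, 1L, E[states, marks[m]])
    presence[, m] <- pr
    counts[, m] <- draw(config$depth * (bg + fg * pr))
  }
  input <- draw(rep(config$depth * config$inputDepthFactor, n))
  grid <- binGrid(seg)
  list(counts = .BinMatrix(grid, counts),
       input = .BinnedTrack(grid, input),
       presence = .BinMatrix(grid, presence))
}

#' Simulate a two-sample methylome with planted DMRs
#'
#' Cytosines are placed per context at the configured density; each
#' cytosine's true level is its bin's state-category level for that context
#' plus jitter.  Both samples draw coverage Poisson and methylated counts
#' binomial around the same levels, except in the planted DMR bins where
#' sample B's level is shifted by the planted delta.  Optional low-
#' methylation regions (e.g. planted distal elements) override the level.
#'
#' @param seg a \linkS4class{Segmentation}.
#' @param config a \code{\link{simConfig}}.
#' @param seed master seed.
#' @param lowMethRegions optional GRanges forced to near-zero CG/CHG/CHH
#'   levels.
#' @param nDMR,dmrDelta override the configured planting.
#' @return list with \code{callsA}, \code{callsB} (data.frames in the
#'   methylation-call layout), \code{truth} (data.frame bin, context,
#'   delta), \code{sites} (per-cytosine truth).
#' @export
simulateMethylome <- function(seg, config, seed = config$seed,
                              lowMethRegions = NULL,
                              nDMR = config$methylome$nDMR,
                              dmrDelta = config$methylome$dmrDelta) {
  me <- config$methylome
  if (all(me$density <= 0)) stop("cytosine density must be positive")
  grid <- binGrid(seg)
  states <- stateLabels(seg)
  cats <- .simCategories(config)
  sl <- seqlengths(grid@seqinfo)

  set.seed(substreamSeed(seed, "meth-sites"))
  sites <- do.call(rbind, lapply(names(me$density), function(ctx) {
    do.call(rbind, lapply(names(sl), function(ch) {
      nc <- round(me$density[[ctx]] * sl[[ch]])
      if (nc == 0L) return(NULL)
      data.frame(chrom = ch, pos = sort(sample.int(sl[[ch]], nc)),
                 strand = sample(c("+", "-"), nc, replace = TRUE),
                 context = ctx)
    }))
  }))
  sites$bin <- globalBinIndex(grid, sites$chrom, sites$pos)
  cat_of <- cats[states[sites$bin]]
  base <- me$levelByCategory[cbind(cat_of, sites$context)]
  base <- pmin(pmax(base + rnorm(nrow(sites), 0, me$levelSd), 0.01), 0.99)
  if (!is.null(lowMethRegions)) {
    pt <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L))
    base[overlapsAny(pt, lowMethRegions, ignore.strand = TRUE)] <- 0.02
  }
  sites$levelA <- base
  sites$levelB <- base
  truth <- data.frame(bin = integer(), context = character(),
                      delta = numeric())
  if (nDMR > 0L && dmrDelta != 0) {
    ctx <- me$dmrContext
    ctxSites <- sites$context == ctx
    perBin <- table(sites$bin[ctxSites])
    binLevel <- tapply(base[ctxSites], sites$bin[ctxSites], mean)
    eligible <- as.integer(names(perBin))[perBin >= 2L &
                                            binLevel <= 1 - abs(dmrDelta) - 0.05]
    if (is.null(lowMethRegions) == FALSE) {
      br <- binRanges(grid)
      eligible <- eligible[!overlapsAny(br[eligible], lowMethRegions,
                                        ignore.strand = TRUE)]
    }
    planted <- sample(eligible, min(nDMR, length(eligible)))
    hit <- ctxSites & sites$bin %in% planted
    sites$levelB[hit] <- pmin(sites$levelA[hit] + abs(dmrDelta), 0.99)
    truth <- data.frame(bin = sort(planted), context = ctx,
                        delta = -abs(dmrDelta))  # delta = A - B
  }
  drawSample <- function(stream, level) {
    set.seed(substreamSeed(seed, stream))
    cov <- rpois(nrow(sites), me$coverage)
    meth <- rbinom(nrow(sites), cov, level)
    data.frame(chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
               context = sites$context, meth = meth, total = cov)
  }
  list(callsA = drawSample("meth-A", sites$levelA),
       callsB = drawSample("meth-B", sites$levelB),
       truth = truth, sites = sites)
}

#' Simulate a gene x tissue FPKM table
#'
#' Each gene's FPKM per tissue is log-normal with the mean set by the
#' category of the chromatin state at its TSS bin in that tissue, so active
#' promoters express highly and repressed/heterochromatic ones mostly below
#' 1 FPKM.  An optional boost table multiplies selected gene/tissue cells
#' (used to couple tissue-specific distal elements to expression).
#'
#' @param segs named list of per-tissue \linkS4class{Segmentation}s.
#' @param genes a \linkS4class{GeneModels}.
#' @param config a \code{\link{simConfig}}.
#' @param seed master seed.
#' @param boost optional data.frame (gene_id, tissue, factor).
#' @return numeric matrix genes x tissues.
#' @export
simulateExpression <- function(segs, genes, config, seed = config$seed,
                               boost = NULL) {
  set.seed(substreamSeed(seed, "expression"))
  ex <- config$expression
  cats <- .simCategories(config)
  g <- geneRanges(genes)
  grid <- binGrid(segs[[1L]])
  tssBin <- globalBinIndex(grid, as.character(seqnames(g)), g$tss)
  out <- vapply(names(segs), function(tt) {
    cat_of <- cats[stateLabels(segs[[tt]])[tssBin]]
    rlnorm(length(tssBin), ex$meanlog[cat_of], ex$sdlog)
  }, numeric(length(g)))
  rownames(out) <- g$gene_id
  if (!is.null(boost))
    out[cbind(match(boost$gene_id, rownames(out)),
              match(boost$tissue, colnames(out)))] <-
      out[cbind(match(boost$gene_id, rownames(out)),
                match(boost$tissue, colnames(out)))] * boost$factor
  out
}

#' Simulate planted regulatory elements and loops
#'
#' Plants proximal elements (PRE) at the TSS of a random subset of genes
#' and distal elements (DRE) in intergenic space at least
#' \code{dreMinTssDist} bp from every TSS, with clean margins.  A fraction
#' of DREs is tissue-specific with high open-chromatin signal only in its
#' tissue; loops connect random promoter pairs.  The DRE footprints are
#' returned as low-methylation regions so the methylome simulation can
#' honor them.
#'
#' @param annotation output of \code{\link{simulateAnnotation}}.
#' @param config a \code{\link{simConfig}}.
#' @param seed master seed.
#' @return list with \code{peaks} (GRanges with \code{true_class} and
#'   \code{true_tissue} mcols), \code{signal} (elements x tissues matrix),
#'   \code{loops} (Pairs), \code{lowMethRegions} (GRanges),
#'   \code{expressionBoost} (data.frame for
#'   \code{\link{simulateExpression}}).
#' @export
simulateElements <- function(annotation, config, seed = config$seed) {
  set.seed(substreamSeed(seed, "elements"))
  el <- config$elements
  genes <- annotation$genes
  g <- geneRanges(genes)
  genome <- seqinfo(g)
  sl <- seqlengths(genome)
  nP <- min(el$nPRE, length(g))
  preGenes <- sort(sample.int(length(g), nP))
  neg <- as.character(strand(g)) == "-"
  preStart <- ifelse(neg[preGenes], g$tss[preGenes] - el$preWidth %/% 4L,
                     g$tss[preGenes] - 3L * el$preWidth %/% 4L)
  preStart <- pmax(preStart, 1L)
  preEnd <- pmin(preStart + el$preWidth - 1L,
                 sl[as.character(seqnames(g))[preGenes]])
  pre <- GRanges(seqnames(g)[preGenes], IRanges(preStart, preEnd),
                 seqinfo = genome)
  ## distal placements by rejection sampling against TSS distance and genes
  chrom <- as.character(seqnames(g))
  D <- el$dreMinTssDist
  expand <- function(s, e) GRanges(chrom, IRanges(pmax(s - D, 1L),
                                                  pmin(e + D, sl[chrom])),
                                   seqinfo = genome)
  avoid <- reduce(c(expand(start(g), end(g)), expand(g$tss, g$tss)),
                  ignore.strand = TRUE)
  allowed <- gaps(avoid)
  allowed <- allowed[strand(allowed) == "*" &
                       width(allowed) >= el$dreWidth + 2L]
  if (length(allowed) == 0L) stop("no intergenic space left for distal elements")
  pick <- sample.int(length(allowed), el$nDRE, replace = TRUE,
                     prob = width(allowed) - el$dreWidth + 1)
  off <- vapply(pick, function(i)
    sample.int(width(allowed)[i] - el$dreWidth + 1L, 1L), integer(1))
  dre <- GRanges(as.character(seqnames(allowed))[pick],
                 IRanges(start(allowed)[pick] + off - 1L,
                         width = el$dreWidth), seqinfo = genome)
  dre <- dre[!duplicated(dre)]
  peaks <- c(pre, dre)
  peaks$true_class <- rep(c("PRE", "DRE"), c(length(pre), length(dre)))
  peaks$true_gene <- c(g$gene_id[preGenes], rep(NA, length(dre)))
  tissues <- config$tissues
  nEl <- length(peaks)
  ts <- rep(NA_character_, nEl)
  isDre <- peaks$true_class == "DRE"
  nTs <- round(sum(isDre) * el$tissueSpecificFraction)
  ts[which(isDre)[seq_len(nTs)]] <- rep_len(tissues, nTs)
  peaks$true_tissue <- ts
  signal <- matrix(el$signalConstitutive, nEl, length(tissues),
                   dimnames = list(NULL, tissues))
  for (i in which(!is.na(ts)))
    signal[i, ] <- ifelse(tissues == ts[i], el$signalHigh, el$signalLow)
  signal <- signal * exp(rnorm(length(signal), 0, el$signalNoiseSd))
  ## loops between random promoter pairs (enriched for PRE promoters)
  prom <- promoterWindows(genes)
  nL <- min(el$nLoops, length(g) %/% 2L)
  cand <- unique(c(preGenes, sample.int(length(g))))
  pairIdx <- matrix(cand[seq_len(2L * nL)], ncol = 2L)
  a1 <- prom[pairIdx[, 1L]]; a2 <- prom[pairIdx[, 2L]]
  swap <- as.character(seqnames(a1)) > as.character(seqnames(a2)) |
    (as.character(seqnames(a1)) == as.character(seqnames(a2)) &
       start(a1) > start(a2))
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  loops <- Pairs(granges(a1), granges(a2))
  mcols(loops)$score <- round(runif(nL, 5, 50))
  boost <- data.frame(gene_id = character(), tissue = character(),
                      factor = numeric())
  linked <- linkDreTargets(peaks[isDre], genes)
  tsIdx <- which(!is.na(ts[isDre]))
  if (length(tsIdx))
    boost <- data.frame(gene_id = linked$gene_id[tsIdx],
                        tissue = ts[isDre][tsIdx],
                        factor = 8)
  ## hypomethylated valleys extend past the element so that bin-level
  ## methylation over the peak is uncontaminated by flanking heterochromatin
  lowMeth <- GRanges(seqnames(dre),
                     IRanges(pmax(start(dre) - config$binWidth, 1L),
                             pmin(end(dre) + config$binWidth,
                                  sl[as.character(seqnames(dre))])),
                     seqinfo = genome)
  list(peaks = peaks, signal = signal, loops = loops,
       lowMethRegions = lowMeth, expressionBoost = boost)
}

#' Simulate a multi-variety panel
#'
#' Every subgroup's consensus path diverges from the base path by segment
#' re-draws at the between-subgroup rate; each variety diverges from its
#' subgroup consensus at the within rate.  A configured number of bins is
#' planted as fixed Xian-vs-Geng state differences.  Per variety, SNPs are
#' placed with a per-bin rate set by the state category, boosted in the
#' flanking bins of heterochromatin runs; per mark, the modified regions
#' (bins whose state emits the mark at probability >= 0.5) and a Poisson
#' signal track are derived.
#'
#' @param baseSeg a \linkS4class{Segmentation} (the reference tissue path).
#' @param config a \code{\link{simConfig}}.
#' @param seed master seed.
#' @param groupA,groupB subgroup names carrying the planted fixed
#'   differences (defaults "Xian", "Geng").
#' @return list with \code{segs} (named list of Segmentations),
#'   \code{subgroup} (named character), \code{snps} (named list of GRanges),
#'   \code{regions} (mark -> variety -> GRanges), \code{signal} (mark ->
#'   bins x varieties matrix), \code{truth} (data.frame bin, state_A,
#'   state_B of the planted differences).
#' @export
simulatePanel <- function(baseSeg, config, seed = config$seed,
                          groupA = "Xian", groupB = "Geng") {
  pa <- config$panel
  if (length(pa$varieties) < 2L) stop("need at least 2 varieties")
  set.seed(substreamSeed(seed, "panel"))
  K <- nStates(baseSeg)
  grid <- binGrid(baseSeg)
  base <- stateLabels(baseSeg)
  n <- length(base)
  groups <- unique(pa$subgroup)
  consensus <- lapply(groups, function(gp)
    .redrawSegments(base, pa$betweenRate, K))
  names(consensus) <- groups
  truth <- data.frame(bin = integer(), state_A = integer(),
                      state_B = integer())
  if (pa$nFixedDiff > 0L && all(c(groupA, groupB) %in% groups)) {
    bins <- sort(sample.int(n, pa$nFixedDiff))
    sA <- sample.int(K, pa$nFixedDiff, replace = TRUE)
    sB <- vapply(sA, function(s) sample(seq_len(K)[-s], 1L), integer(1))
    consensus[[groupA]][bins] <- sA
    consensus[[groupB]][bins] <- sB
    truth <- data.frame(bin = bins, state_A = sA, state_B = sB)
  }
  segs <- lapply(pa$varieties, function(v)
    .Segmentation(grid,
                  .redrawSegments(consensus[[pa$subgroup[[v]]]],
                                  pa$withinRate, K),
                  K))
  names(segs) <- pa$varieties
  cats <- .simCategories(config)
  E <- config$emission
  bg <- 1 / (1 + config$fgBgRatio)
  fg <- 1 - bg
  br <- binRanges(grid)
  snps <- lapply(segs, function(sg) {
    st <- stateLabels(sg)
    rate <- pa$snpRate[cats[st]] * binWidth(grid)
    inact <- cats[st] == "inactive"
    nearInact <- rep(FALSE, n)
    for (d in seq_len(pa$flankBins)) {
      nearInact <- nearInact | c(inact[-seq_len(d)], rep(FALSE, d)) |
        c(rep(FALSE, d), head(inact, -d))
    }
    rate[!inact & nearInact] <- rate[!inact & nearInact] * pa$flankBoost
    cnt <- rpois(n, rate)
    keep <- which(cnt > 0)
    if (!length(keep)) return(GRanges(seqinfo = grid@seqinfo))
    pos <- unlist(lapply(keep, function(b)
      start(br)[b] + sample.int(width(br)[b], cnt[b], replace = TRUE) - 1L))
    ch <- rep(as.character(seqnames(br))[keep], cnt[keep])
    sort(GRanges(ch, IRanges(pos, width = 1L), seqinfo = grid@seqinfo))
  })
  regions <- lapply(config$marks, function(mk) {
    lapply(segs, function(sg)
      reduce(br[E[stateLabels(sg), mk] >= 0.5], ignore.strand = TRUE))
  })
  names(regions) <- config$marks
  signal <- lapply(config$marks, function(mk) {
    vapply(segs, function(sg)
      rpois(n, config$depth * (bg + fg * E[stateLabels(sg), mk])),
      numeric(n))
  })
  names(signal) <- config$marks
  list(segs = segs, subgroup = pa$subgroup, snps = snps,
       regions = regions, signal = signal, truth = truth)
}
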