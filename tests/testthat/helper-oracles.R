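## Shared fixtures and independent brute-force oracles.

suppressMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

tinyGenome <- function() genomeIndex(c(chr1 = 10000, chr2 = 4000))

randomIntervals <- function(n, genome = tinyGenome(), maxLen = 500) {
  sl <- GenomeInfoDb::seqlengths(genome)
  chrom <- sample(names(sl), n, replace = TRUE)
  len <- sample.int(maxLen, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample.int(sl[[chrom[i]]] - len[i], 1L), integer(1))
  GRanges(chrom, IRanges(start, width = len), seqinfo = genome)
}

## quadratic overlap oracle
bruteOverlap <- function(a, b, minBp = 1L) {
  rows <- list()
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (as.character(seqnames(a))[i] != as.character(seqnames(b))[j]) next
    ov <- min(end(a)[i], end(b)[j]) - max(start(a)[i], start(b)[j]) + 1L
    if (ov >= minBp)
      rows[[length(rows) + 1L]] <- data.frame(a_index = i, b_index = j,
                                              overlap_bp = ov)
  }
  if (!length(rows))
    return(data.frame(a_index = integer(), b_index = integer(),
                      overlap_bp = integer()))
  out <- do.call(rbind, rows)
  out[order(out$a_index, out$b_index), , drop = FALSE]
}

## quadratic nearest-TSS oracle (shares only the distance definition)
bruteNearestTss <- function(x, gm) {
  g <- geneRanges(gm)
  out <- data.frame(gene_id = rep(NA_character_, length(x)),
                    distance = rep(NA_real_, length(x)))
  for (q in seq_along(x)) {
    ch <- as.character(seqnames(x))[q]
    cand <- which(as.character(seqnames(g)) == ch)
    if (!length(cand)) next
    best <- NULL
    for (k in cand) {
      tss <- g$tss[k]
      gap <- if (tss > end(x)[q]) tss - end(x)[q] - 1L
             else if (tss < start(x)[q]) start(x)[q] - tss - 1L else 0L
      if (is.null(best) || gap < best$gap ||
          (gap == best$gap && g$gene_id[k] < best$id))
        best <- list(gap = gap, id = g$gene_id[k], k = k)
    }
    d <- best$gap
    if (d > 0) {
      rightOf <- g$tss[best$k] > end(x)[q]
      upstream <- if (as.character(strand(g))[best$k] == "-") !rightOf
                  else rightOf
      d <- if (upstream) -d else d
    }
    out$gene_id[q] <- best$id
    out$distance[q] <- d
  }
  out
}

## exact HMM posterior by exhaustive path enumeration (K^T paths)
brutePosterior <- function(E, A, piv, obs) {
  K <- nrow(E); Tn <- nrow(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  probs <- apply(paths, 1L, function(st) {
    p <- piv[st[1L]]
    for (t in seq_len(Tn)) {
      e <- prod(E[st[t], ]^obs[t, ] * (1 - E[st[t], ])^(1 - obs[t, ]))
      p <- p * e
      if (t < Tn) p <- p * A[st[t], st[t + 1L]]
    }
    p
  })
  gamma <- matrix(0, Tn, K)
  for (t in seq_len(Tn)) for (k in seq_len(K))
    gamma[t, k] <- sum(probs[paths[, t] == k])
  gamma / rowSums(gamma)
}

## simple gene fixture: 4 genes on two chromosomes, both strands
fixtureGenes <- function(genome = tinyGenome()) {
  geneModels(chrom = c("chr1", "chr1", "chr1", "chr2"),
             start = c(1001, 3001, 6001, 501),
             end = c(2000, 4500, 7000, 1500),
             strand = c("+", "-", "+", "-"),
             gene_id = c("gA", "gB", "gC", "gD"),
             atg = c(1101, 4400, 6151, 1301),
             genome = genome)
}

randomGeneModels <- function(n, genome = tinyGenome(), minLen = 200,
                             maxLen = 800) {
  sl <- GenomeInfoDb::seqlengths(genome)
  chrom <- sample(names(sl), n, replace = TRUE)
  len <- sample(minLen:maxLen, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample.int(sl[[chrom[i]]] - len[i] - 1L, 1L), integer(1))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  end <- start + len
  atg <- ifelse(strand == "-", end - 50L, start + 50L)
  geneModels(chrom, start, end, strand, sprintf("rg%03d", seq_len(n)),
             atg = atg, genome = genome)
}

## adjusted Rand index (independent of any clustering implementation)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
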