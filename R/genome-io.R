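#' @include AllGenerics.R
NULL

#' Build a genome index
#'
#' @param lengths named numeric/integer vector of chromosome lengths (bp).
#' @return a \link[GenomeInfoDb]{Seqinfo}.
#' @examples
#' genomeIndex(c(chr1 = 1e6, chr2 = 4e5))
#' @export
genomeIndex <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(lengths)))
    stop("chromosome names must be unique")
  if (anyNA(lengths) || any(lengths < 1))
    stop("chromosome lengths must be >= 1")
  Seqinfo(seqnames = names(lengths), seqlengths = as.integer(lengths))
}

#' Tile a genome into fixed-width bins
#'
#' Every chromosome is cut into consecutive bins of \code{width} bp; the last
#' bin of a chromosome may be shorter (partial bins are kept so that the bins
#' partition the genome exactly).  Bins are indexed chromosome-major starting
#' at 1.
#'
#' @param genome a Seqinfo (see \code{\link{genomeIndex}}) or named length vector.
#' @param width bin width in bp (default 200).
#' @return a \linkS4class{BinGrid}.
#' @examples
#' makeBins(genomeIndex(c(chr1 = 1000)), 200)
#' @export
makeBins <- function(genome, width = 200L) {
  if (!is(genome, "Seqinfo")) genome <- genomeIndex(genome)
  width <- as.integer(width)
  if (length(width) != 1L || is.na(width) || width < 1L)
    stop("bin width must be a single positive integer")
  sl <- seqlengths(genome)
  new("BinGrid", seqinfo = genome, binWidth = width,
      binsPerChrom = setNames(as.integer(ceiling(sl / width)), names(sl)))
}

## cumulative bin offset per chromosome (0 for the first)
.binOffsets <- function(grid) {
  n <- grid@binsPerChrom
  setNames(cumsum(c(0L, unname(head(n, -1L)))), names(n))
}

#' Global bin index of genomic positions
#'
#' @param grid a \linkS4class{BinGrid}.
#' @param chrom character vector of chromosome names.
#' @param pos 1-based positions.
#' @return integer vector of global (chromosome-major) bin indices.
#' @export
globalBinIndex <- function(grid, chrom, pos) {
  sl <- seqlengths(grid@seqinfo)
  bad <- setdiff(unique(chrom), names(sl))
  if (length(bad))
    stop("chromosomes absent from genome: ", paste(bad, collapse = ", "))
  if (any(pos < 1) || any(pos > sl[chrom]))
    stop("positions outside chromosome bounds")
  off <- .binOffsets(grid)
  as.integer(off[chrom] + (pos - 1L) %/% grid@binWidth + 1L)
}

.checkGenomeMembership <- function(chrom, genome, what = "interval") {
  if (is.null(genome)) return(invisible())
  sl <- seqlengths(genome)
  bad <- setdiff(unique(chrom), names(sl))
  if (length(bad))
    stop(what, " file uses chromosomes absent from genome: ",
         paste(bad, collapse = ", "))
  invisible()
}

## ---- BED --------------------------------------------------------------

#' Read a BED3-BED6 file
#'
#' BED coordinates (0-based half-open) are converted to the 1-based closed
#' convention of GRanges at the boundary.  Malformed lines raise an error
#' naming the line number; if \code{genome} is supplied, chromosomes absent
#' from it are rejected.
#'
#' @param path file path.
#' @param genome optional Seqinfo for validation and seqinfo annotation.
#' @return a GRanges with optional \code{name} and \code{score} mcols.
#' @export
readBed <- function(path, genome = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineNo <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (length(fields) == 0L)
    return(GRanges(seqinfo = genome))
  if (any(ncols < 3L))
    stop("malformed BED line ", lineNo[which(ncols < 3L)[1L]],
         ": fewer than 3 fields")
  n <- min(ncols)
  m <- do.call(rbind, lapply(fields, `[`, seq_len(min(n, 6L))))
  start0 <- suppressWarnings(as.numeric(m[, 2L]))
  end0 <- suppressWarnings(as.numeric(m[, 3L]))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stop("malformed BED line ", lineNo[bad[1L]], ": non-numeric coordinates")
  bad <- which(start0 >= end0 | start0 < 0)
  if (length(bad))
    stop("malformed BED line ", lineNo[bad[1L]],
         ": start must satisfy 0 <= start < end")
  .checkGenomeMembership(m[, 1L], genome, "BED")
  gr <- GRanges(m[, 1L], IRanges(start0 + 1, end0),
                seqinfo = genome)
  if (ncol(m) >= 4L) gr$name <- m[, 4L]
  if (ncol(m) >= 5L) gr$score <- suppressWarnings(as.numeric(m[, 5L]))
  if (ncol(m) >= 6L) {
    st <- m[, 6L]
    bad <- which(!st %in% c("+", "-", "."))
    if (length(bad))
      stop("malformed BED line ", lineNo[bad[1L]], ": bad strand")
    strand(gr) <- st
  }
  gr
}

#' Write intervals as BED
#'
#' Intervals are sorted by (chromosome, start) and written 0-based half-open.
#' With \code{name} and \code{score} mcols present a BED6 file is produced,
#' otherwise BED3.
#'
#' @param gr a GRanges.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeBed <- function(gr, path) {
  o <- order(as.character(seqnames(gr)), start(gr))
  gr <- gr[o]
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  if (!is.null(gr$name) || !is.null(gr$score) ||
      any(strand(gr) != "*")) {
    df$name <- if (is.null(gr$name)) "." else gr$name
    df$score <- if (is.null(gr$score)) 0 else gr$score
    df$strand <- sub("\\*", ".", as.character(strand(gr)))
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- bedGraph ---------------------------------------------------------

#' Read a bedGraph file
#' @param path file path.
#' @param genome optional Seqinfo.
#' @return GRanges with a \code{score} mcol.
#' @export
readBedGraph <- function(path, genome = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineNo <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(fields) == 0L) return(GRanges(seqinfo = genome, score = numeric()))
  bad <- which(lengths(fields) < 4L)
  if (length(bad))
    stop("malformed bedGraph line ", lineNo[bad[1L]], ": fewer than 4 fields")
  m <- do.call(rbind, lapply(fields, `[`, 1:4))
  start0 <- suppressWarnings(as.numeric(m[, 2L]))
  end0 <- suppressWarnings(as.numeric(m[, 3L]))
  val <- suppressWarnings(as.numeric(m[, 4L]))
  bad <- which(is.na(start0) | is.na(end0) | is.na(val) | start0 >= end0)
  if (length(bad))
    stop("malformed bedGraph line ", lineNo[bad[1L]])
  .checkGenomeMembership(m[, 1L], genome, "bedGraph")
  GRanges(m[, 1L], IRanges(start0 + 1, end0), score = val, seqinfo = genome)
}

#' Write a bedGraph file
#' @param gr GRanges with a \code{score} mcol, or a \linkS4class{BinnedTrack}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeBedGraph <- function(gr, path) {
  if (is(gr, "BinnedTrack")) {
    br <- binRanges(gr)
    br$score <- trackValues(gr)
    gr <- br[!is.na(br$score)]
  }
  o <- order(as.character(seqnames(gr)), start(gr))
  gr <- gr[o]
  df <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                   gr$score)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- GFF3 genes -------------------------------------------------------

#' Read gene models from GFF3
#'
#' Parses \code{gene}, \code{exon} and \code{CDS} features (exons/CDS may be
#' attached to the gene directly or through one level of mRNA).  The TSS is
#' the first transcribed base (gene start on +, gene end on -) and the ATG
#' the first CDS base in transcription orientation.  Genes without exon or
#' CDS children are kept with an empty exon list, with a warning.
#'
#' @param path GFF3 file path.
#' @param genome optional Seqinfo.
#' @return a \linkS4class{GeneModels}.
#' @export
readGffGenes <- function(path, genome = NULL) {
  gff <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gff$type)
  genes <- gff[typ == "gene"]
  if (length(genes) == 0L) stop("no gene features in ", path)
  .checkGenomeMembership(as.character(seqnames(genes)), genome, "GFF3")
  ids <- genes$ID
  if (is.null(ids) || anyNA(ids)) stop("gene features must carry ID attributes")
  ## map child Parent -> gene id (flatten one mRNA level)
  parentOf <- function(x) vapply(as.list(x$Parent), function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1))
  mrna <- gff[typ == "mRNA"]
  mrnaParent <- setNames(parentOf(mrna), mrna$ID)
  toGene <- function(p) ifelse(p %in% ids, p, unname(mrnaParent[p]))
  exons <- gff[typ == "exon"]
  cds <- gff[typ == "CDS"]
  exonGene <- toGene(parentOf(exons))
  cdsGene <- toGene(parentOf(cds))
  exonList <- S4Vectors::split(granges(exons), factor(exonGene, levels = ids))
  tss <- ifelse(as.character(strand(genes)) == "-", end(genes), start(genes))
  atg <- rep(NA_integer_, length(genes))
  if (length(cds)) {
    cdsStartTx <- ifelse(as.character(strand(cds)) == "-", end(cds), start(cds))
    neg <- as.character(strand(cds)) == "-"
    for (i in seq_along(ids)) {
      j <- which(cdsGene == ids[i])
      if (length(j))
        atg[i] <- if (as.character(strand(genes))[i] == "-")
          max(end(cds)[j]) else min(start(cds)[j])
    }
  }
  noChild <- lengths(exonList) == 0L & is.na(atg)
  if (any(noChild))
    warning(sum(noChild), " gene(s) without exon/CDS features kept with ",
            "empty exon list")
  cls <- genes$gene_class
  if (is.null(cls)) cls <- rep("gene", length(genes))
  cls[is.na(cls)] <- "gene"
  g <- granges(genes)
  if (!is.null(genome)) seqinfo(g) <- genome
  mcols(g) <- DataFrame(gene_id = ids, tss = as.integer(tss),
                        atg = as.integer(atg), gene_class = cls)
  new("GeneModels", genes = g,
      exons = exonList[ids])
}

#' Write gene models as GFF3
#' @param gm a \linkS4class{GeneModels}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGffGenes <- function(gm, path) {
  g <- geneRanges(gm)
  ex <- geneExons(gm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_along(g)) {
    id <- g$gene_id[i]
    ch <- as.character(seqnames(g))[i]
    st <- as.character(strand(g))[i]
    writeLines(sprintf("%s\tchromdyn\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_class=%s",
                       ch, start(g)[i], end(g)[i], st, id, g$gene_class[i]), con)
    exi <- ex[[id]]
    if (length(exi))
      writeLines(sprintf("%s\tchromdyn\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                         ch, start(exi), end(exi), st, id), con)
    if (!is.na(g$atg[i])) {
      ## minimal CDS row from ATG to gene end (transcription orientation)
      cs <- if (st == "-") start(g)[i] else g$atg[i]
      ce <- if (st == "-") g$atg[i] else end(g)[i]
      writeLines(sprintf("%s\tchromdyn\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                         ch, cs, ce, st, id), con)
    }
  }
  invisible(path)
}

## ---- BEDPE loops ------------------------------------------------------

#' Read chromatin loops from BEDPE
#'
#' Anchors are ordered so that anchor 1 precedes anchor 2 (by chromosome,
#' then start).
#'
#' @param path BEDPE file path.
#' @param genome optional Seqinfo.
#' @return a \link[S4Vectors]{Pairs} of GRanges with a \code{score} mcol.
#' @export
readBedpe <- function(path, genome = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track)", lines) & nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 6L)
  if (length(bad))
    stop("malformed BEDPE line ", which(keep)[bad[1L]], ": fewer than 6 fields")
  m <- do.call(rbind, lapply(fields, `[`, seq_len(min(lengths(fields), 8L))))
  a1 <- GRanges(m[, 1L], IRanges(as.numeric(m[, 2L]) + 1, as.numeric(m[, 3L])),
                seqinfo = genome)
  a2 <- GRanges(m[, 4L], IRanges(as.numeric(m[, 5L]) + 1, as.numeric(m[, 6L])),
                seqinfo = genome)
  .checkGenomeMembership(c(m[, 1L], m[, 4L]), genome, "BEDPE")
  swap <- as.character(seqnames(a1)) > as.character(seqnames(a2)) |
    (as.character(seqnames(a1)) == as.character(seqnames(a2)) &
       start(a1) > start(a2))
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  p <- Pairs(a1, a2)
  mcols(p)$score <- if (ncol(m) >= 8L)
    suppressWarnings(as.numeric(m[, 8L])) else rep(NA_real_, length(a1))
  p
}

#' Write chromatin loops as BEDPE
#' @param loops a Pairs of GRanges.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeBedpe <- function(loops, path) {
  a1 <- first(loops); a2 <- second(loops)
  sc <- mcols(loops)$score
  if (is.null(sc)) sc <- rep(".", length(loops))
  df <- data.frame(as.character(seqnames(a1)), start(a1) - 1L, end(a1),
                   as.character(seqnames(a2)), start(a2) - 1L, end(a2),
                   paste0("loop", seq_along(a1)), sc)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- tabular formats --------------------------------------------------

#' Read per-cytosine methylation calls
#'
#' Tab-delimited with columns chrom, pos (1-based), strand, context
#' (CG/CHG/CHH), methylated count, total count - the common
#' bisulfite-extractor layout.
#'
#' @param path file path.
#' @return data.frame with those six columns.
#' @export
readMethCalls <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "strand", "context", "meth", "total")
  if (!all(need %in% names(df)))
    stop("methylation table must have columns: ", paste(need, collapse = ", "))
  if (any(df$meth > df$total) || any(df$meth < 0))
    stop("methylated counts must satisfy 0 <= meth <= total")
  df[need]
}

#' Write per-cytosine methylation calls
#' @param calls data.frame as returned by \code{\link{readMethCalls}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMethCalls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a gene x tissue FPKM table
#' @param path TSV path (first column gene id, remaining columns tissues).
#' @return numeric matrix, genes as rownames.
#' @export
readFpkm <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' @rdname readFpkm
#' @param fpkm numeric matrix of FPKM values.
#' @export
writeFpkm <- function(fpkm, path) {
  df <- data.frame(gene_id = rownames(fpkm), fpkm, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- binning and interval operations ---------------------------------

#' Aggregate a step track onto a bin grid
#'
#' Each bin receives the reducer applied to the bp-weighted values of the
#' bedGraph intervals overlapping it.  \code{sum} accumulates value x
#' overlap-bp (empty bins 0); \code{mean} is the bp-weighted mean over
#' covered bp (empty bins missing); \code{max} is the maximum value observed
#' (empty bins missing).  Overlapping input intervals are ambiguous and
#' rejected.
#'
#' @param track GRanges with a \code{score} mcol (or a bedGraph path).
#' @param grid a \linkS4class{BinGrid}.
#' @param reducer one of "mean", "sum", "max".
#' @return a \linkS4class{BinnedTrack}.
#' @export
trackToBins <- function(track, grid, reducer = c("mean", "sum", "max")) {
  reducer <- match.arg(reducer)
  if (is.character(track)) track <- readBedGraph(track, grid@seqinfo)
  if (is.null(track$score)) stop("track must carry a score column")
  self <- findOverlaps(track, track)
  if (length(self) > length(track))
    stop("overlapping bedGraph intervals are ambiguous")
  br <- binRanges(grid)
  hits <- findOverlaps(br, track)
  q <- queryHits(hits); s <- subjectHits(hits)
  ow <- width(pintersect(br[q], track[s]))
  val <- track$score[s]
  n <- nBins(grid)
  out <- switch(reducer,
    sum = {
      v <- numeric(n)
      acc <- rowsum(val * ow, q)
      v[as.integer(rownames(acc))] <- acc[, 1L]
      v
    },
    mean = {
      v <- rep(NA_real_, n)
      num <- rowsum(val * ow, q)
      den <- rowsum(as.numeric(ow), q)
      v[as.integer(rownames(num))] <- num[, 1L] / den[, 1L]
      v
    },
    max = {
      v <- rep(NA_real_, n)
      mx <- vapply(split(val, q), max, numeric(1))
      v[as.integer(names(mx))] <- mx
      v
    })
  new("BinnedTrack", grid = grid, values = out)
}

#' All sufficiently-overlapping interval pairs
#'
#' @param a,b GRanges on the same genome.
#' @param minBp minimum overlap in bp (default 1).
#' @return data.frame with columns \code{a_index}, \code{b_index},
#'   \code{overlap_bp}, ordered a-major then b.
#' @export
overlapPairs <- function(a, b, minBp = 1L) {
  hits <- findOverlaps(a, b, minoverlap = minBp)
  q <- queryHits(hits); s <- subjectHits(hits)
  ow <- width(pintersect(a[q], b[s], ignore.strand = TRUE))
  o <- order(q, s)
  data.frame(a_index = q[o], b_index = s[o], overlap_bp = ow[o])
}

#' Nearest TSS and signed distance
#'
#' For each query interval, finds the gene whose TSS is closest.  The
#' distance is 0 when the interval covers the TSS; otherwise it is the gap
#' in bp, signed negative when the interval lies upstream of the TSS in the
#' gene's orientation.  Ties (equidistant TSSs) are broken by the
#' lexicographically smaller gene id.
#'
#' @param x GRanges of query intervals.
#' @param genes a \linkS4class{GeneModels}.
#' @return data.frame with columns \code{gene_id}, \code{distance}
#'   (NA for queries on chromosomes without genes).
#' @export
nearestTss <- function(x, genes) {
  g <- geneRanges(genes)
  tssCh <- as.character(seqnames(g))
  tss <- g$tss
  neg <- as.character(strand(g)) == "-"
  out <- data.frame(gene_id = rep(NA_character_, length(x)),
                    distance = rep(NA_real_, length(x)))
  xs <- start(x); xe <- end(x); xc <- as.character(seqnames(x))
  for (ch in unique(xc)) {
    gi <- which(tssCh == ch)
    qi <- which(xc == ch)
    if (length(gi) == 0L) next
    ## order candidate genes by tss then id for deterministic ties
    gi <- gi[order(tss[gi], g$gene_id[gi])]
    tpos <- tss[gi]
    for (q in qi) {
      ## gap = bases strictly between interval and TSS (covering = 0)
      gap <- ifelse(tpos > xe[q], tpos - xe[q] - 1L,
             ifelse(tpos < xs[q], xs[q] - tpos - 1L, 0L))
      best <- which(gap == min(gap))
      if (length(best) > 1L)
        best <- best[order(g$gene_id[gi[best]])][1L]
      k <- gi[best]
      d <- gap[best]
      if (d > 0) {
        rightOf <- tss[k] > xe[q]
        upstream <- if (neg[k]) !rightOf else rightOf
        d <- if (upstream) -d else d
      }
      out$gene_id[q] <- g$gene_id[k]
      out$distance[q] <- d
    }
  }
  out
}

#' Construct gene models directly
#'
#' Builds a \linkS4class{GeneModels} from per-gene vectors.  The TSS is
#' derived from the strand (start on +, end on -) unless given; a gene's
#' exons default to its whole body.
#'
#' @param chrom,start,end,strand per-gene coordinates (1-based closed).
#' @param gene_id unique gene identifiers.
#' @param atg optional ATG positions (1-based; NA if unknown).
#' @param gene_class "gene" or "TE-gene", recycled.
#' @param exons optional named list (by gene id) of GRanges of exons.
#' @param genome optional Seqinfo.
#' @param tss optional TSS positions overriding the strand-derived default.
#' @return a \linkS4class{GeneModels}.
#' @export
geneModels <- function(chrom, start, end, strand, gene_id, atg = NA_integer_,
                       gene_class = "gene", exons = NULL, genome = NULL,
                       tss = NULL) {
  strand <- rep_len(strand, length(chrom))
  g <- GRanges(chrom, IRanges(start, end), strand = strand, seqinfo = genome)
  if (is.null(tss)) tss <- ifelse(strand == "-", end, start)
  mcols(g) <- DataFrame(gene_id = gene_id, tss = as.integer(tss),
                        atg = as.integer(rep_len(atg, length(g))),
                        gene_class = rep_len(gene_class, length(g)))
  ex <- lapply(gene_id, function(id) {
    if (!is.null(exons) && !is.null(exons[[id]])) granges(exons[[id]])
    else granges(g[match(id, gene_id)])
  })
  names(ex) <- gene_id
  new("GeneModels", genes = g, exons = GRangesList(ex))
}

#' Promoter windows of genes
#'
#' The promoter of a gene is the window from \code{upstream} bp before to
#' \code{downstream} bp after its TSS, in transcription orientation, clipped
#' to the chromosome.
#'
#' @param genes a \linkS4class{GeneModels}.
#' @param upstream,downstream window extent in bp (defaults 1000 and 500).
#' @return GRanges with a \code{gene_id} mcol.
#' @export
promoterWindows <- function(genes, upstream = 1000L, downstream = 500L) {
  g <- geneRanges(genes)
  neg <- as.character(strand(g)) == "-"
  tss <- g$tss
  s <- ifelse(neg, tss - downstream, tss - upstream)
  e <- ifelse(neg, tss + upstream, tss + downstream)
  sl <- seqlengths(seqinfo(g))
  chrom <- as.character(seqnames(g))
  s <- pmax(s, 1L)
  if (!anyNA(sl)) e <- pmin(e, sl[chrom])
  out <- GRanges(chrom, IRanges(s, e), strand = strand(g),
                 seqinfo = seqinfo(g))
  out$gene_id <- g$gene_id
  out
}
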