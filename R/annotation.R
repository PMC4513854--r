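#' @include AllClasses.R formats.R
NULL

# Signed TSS distance of one summit to every TSS on its chromosome, in
# transcript orientation (negative = upstream). Returns the nearest
# distance (smallest absolute value; ties resolved to the first gene in
# table order) and the gene index.
nearestTssDistance <- function(summit, chrom, genes) {
  idx <- which(genes$chrom == chrom)
  if (length(idx) == 0L) return(list(dist = NA_real_, gene = NA_integer_))
  tss <- genes$tss[idx]
  d <- ifelse(genes$strand[idx] == "+", summit - tss, tss - summit)
  k <- which.min(abs(d))
  list(dist = d[k], gene = idx[k])
}

#' Signed distances of peak summits to the nearest TSS
#'
#' The distance is measured in transcript orientation: negative values lie
#' upstream of the TSS, positive values downstream; the nearest TSS over
#' all transcripts (smallest absolute distance) is used. The histogram is
#' binned at `binWidth` with bin `[0, binWidth)` containing distance 0.
#'
#' @param peaks `GRanges` with a `summit` metadata column.
#' @param genes gene table from [readGeneTable()] / [generateGenome()].
#' @param binWidth histogram bin width in bp (the TSS-distance profiles use
#'   50-bp bins genome-wide and 20-bp bins for the promoter close-up).
#' @return A list with `distances` (numeric, one per peak, with the nearest
#'   gene name as names), and `histogram` (data.frame `binStart`, `count`;
#'   `binStart` is the inclusive left edge of each `binWidth`-bp bin).
#' @export
tssDistances <- function(peaks, genes, binWidth = 50L) {
  stopf(nrow(genes) > 0L, "gene table is empty")
  if (length(peaks) == 0L) {
    return(list(distances = numeric(0),
                histogram = data.frame(binStart = integer(0),
                                       count = integer(0))))
  }
  chrom <- as.character(seqnames(peaks))
  res <- lapply(seq_along(peaks), function(i) {
    nearestTssDistance(peaks$summit[i], chrom[i], genes)
  })
  d <- vapply(res, function(x) x$dist, numeric(1))
  names(d) <- genes$name[vapply(res, function(x) x$gene, integer(1))]
  dd <- d[!is.na(d)]
  bins <- floor(dd / binWidth)
  tab <- table(bins)
  hist <- data.frame(binStart = as.integer(names(tab)) * as.integer(binWidth),
                     count = as.integer(tab))
  list(distances = d, histogram = hist)
}

# Category of one summit relative to one containing transcript.
insideCategory <- function(summit, gene) {
  exS <- gene$exonStarts[[1L]]
  exE <- gene$exonEnds[[1L]]
  inExon <- any(summit >= exS & summit <= exE)
  if (!inExon) return("intron")
  if (is.na(gene$cdsStart)) return("exon")
  if (gene$strand == "+") {
    if (summit < gene$cdsStart) return("utr5")
    if (summit > gene$cdsEnd) return("utr3")
  } else {
    if (summit > gene$cdsEnd) return("utr5")
    if (summit < gene$cdsStart) return("utr3")
  }
  "exon"
}

#' Classify peak summits into nine gene-feature categories
#'
#' Classification is by the summit position (a point), which makes the nine
#' categories mutually exclusive. A summit inside a transcript is classified
#' with precedence 5' UTR > 3' UTR > exon > intron across all containing
#' transcripts (UTRs from the CDS bounds; transcripts without a CDS
#' contribute only exon/intron). A summit outside every transcript is a
#' proximal promoter within 1 kb upstream of a TSS, a distal promoter within
#' 1-3 kb upstream, proximal/distal downstream within 1 kb / 1-3 kb past the
#' gene's downstream reference, else distal intergenic; among multiple
#' qualifying transcripts the nearest TSS wins.
#'
#' The downstream reference is the transcript end (`downstreamOf =
#' "txEnd"`, default). The literal alternative, windows downstream of the
#' TSS (`downstreamOf = "tss"`), is available but overlaps the gene body
#' and is not the default.
#'
#' @param peaks `GRanges` with a `summit` metadata column.
#' @param genes gene table.
#' @param downstreamOf `"txEnd"` (default) or `"tss"`.
#' @return A factor over [featureCategories()], one value per peak.
#' @export
classifyLocations <- function(peaks, genes, downstreamOf = c("txEnd", "tss")) {
  downstreamOf <- match.arg(downstreamOf)
  cats <- featureCategories()
  if (length(peaks) == 0L) return(factor(character(), levels = cats))
  prec <- c(utr5 = 1L, utr3 = 2L, exon = 3L, intron = 4L)
  chrom <- as.character(seqnames(peaks))
  out <- character(length(peaks))
  for (i in seq_along(peaks)) {
    s <- peaks$summit[i]
    g <- genes[genes$chrom == chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) { out[i] <- "distal_intergenic"; next }
    inside <- which(s >= g$txStart & s <= g$txEnd)
    if (length(inside) > 0L) {
      cand <- vapply(inside, function(j) insideCategory(s, g[j, ]),
                     character(1))
      out[i] <- names(prec)[min(prec[cand])]
      next
    }
    # outside all transcripts: promoter / downstream windows
    dTss <- ifelse(g$strand == "+", s - g$tss, g$tss - s)
    dsRef <- if (downstreamOf == "txEnd") {
      ifelse(g$strand == "+", s - g$txEnd, g$txStart - s)
    } else {
      dTss
    }
    cat_g <- rep(NA_character_, nrow(g))
    cat_g[dTss >= -1000 & dTss < 0] <- "proximal_promoter"
    cat_g[dTss >= -3000 & dTss < -1000] <- "distal_promoter"
    down <- is.na(cat_g) & dsRef >= 0 & dsRef <= 1000
    cat_g[down] <- "proximal_downstream"
    down2 <- is.na(cat_g) & dsRef > 1000 & dsRef <= 3000
    cat_g[down2] <- "distal_downstream"
    ok <- which(!is.na(cat_g))
    if (length(ok) == 0L) { out[i] <- "distal_intergenic"; next }
    out[i] <- cat_g[ok[which.min(abs(dTss[ok]))]]
  }
  factor(out, levels = cats)
}

#' Tabulate a feature classification
#'
#' @param categories factor from [classifyLocations()].
#' @return A [FeatureDistribution-class].
#' @export
featureDistribution <- function(categories) {
  categories <- factor(categories, levels = featureCategories())
  counts <- as.integer(table(categories))
  names(counts) <- featureCategories()
  new("FeatureDistribution", counts = counts,
      total = as.integer(sum(counts)))
}

#' Random-location control intervals sampled from input tags
#'
#' Control interval `i` is centred on a uniformly sampled (without
#' replacement) input-tag 5' position and given the width of a randomly
#' paired real peak; intervals are clipped to chromosome bounds when
#' `seqlens` is provided. A `summit` metadata column (the sampled tag
#' position) is included so controls can be annotated exactly like peaks.
#'
#' @param inputTags width-1 `GRanges` of input tags.
#' @param peaks `GRanges` of real peaks (width donor).
#' @param n number of controls; `n <= length(inputTags)`.
#' @param seed RNG seed.
#' @param seqlens optional named chromosome lengths for clipping.
#' @return `GRanges` of `n` control intervals.
#' @export
randomControl <- function(inputTags, peaks, n, seed = NULL, seqlens = NULL) {
  n <- as.integer(n)
  stopf(n <= length(inputTags),
        "n = %d exceeds the %d available input tags", n, length(inputTags))
  stopf(length(peaks) > 0L, "need at least one real peak as width donor")
  withSeed(seed, {
    pick <- sample.int(length(inputTags), n)
    w <- width(peaks)[sample.int(length(peaks), n, replace = TRUE)]
    centers <- start(inputTags)[pick]
    chrom <- as.character(seqnames(inputTags))[pick]
    s <- centers - w %/% 2L
    e <- s + w - 1L
    s <- pmax(s, 1L)
    if (!is.null(seqlens)) e <- pmin(e, seqlens[chrom])
    gr <- GRanges(chrom, IRanges(s, pmax(e, s)))
    gr$summit <- centers
    gr$name <- sprintf("control_%d", seq_len(n))
    gr
  })
}

#' Per-category log2 enrichment between two feature distributions
#'
#' `log2(percentA / percentB)` per category. A category with zero control
#' percentage but nonzero peak percentage yields `Inf`; both zero yields
#' `NaN`.
#'
#' @param distA,distB [FeatureDistribution-class] objects over the same
#'   categories (peaks vs random control, typically).
#' @return Named numeric vector of log2 ratios.
#' @examples
#' # the hallmark promoter enrichment: 25% of peaks vs 2% of controls
#' log2(25 / 2)  # ~3.64
#' @export
enrichmentLog2 <- function(distA, distB) {
  stopf(identical(names(distA@counts), names(distB@counts)),
        "distributions must cover identical categories")
  pa <- categoryPercent(distA)
  pb <- categoryPercent(distB)
  r <- suppressWarnings(log2(pa / pb))
  r[pa == 0 & pb == 0] <- NaN
  r
}

#' Count peaks overlapping a repeat track
#'
#' @param peaks `GRanges`.
#' @param repeatTrack `GRanges` (BED3-style intervals).
#' @return Named integer vector `c(nOverlapping, nTotal)`: peaks overlapping
#'   at least one repeat interval by >= 1 bp, and total peaks.
#' @export
repeatOverlap <- function(peaks, repeatTrack) {
  hits <- countOverlaps(granges(peaks), granges(repeatTrack),
                        ignore.strand = TRUE)
  c(nOverlapping = sum(hits > 0L), nTotal = length(peaks))
}
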