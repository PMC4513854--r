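#' @include AllClasses.R signal-map.R
NULL

# Running mean of x over a centered window of w bins; windows are clamped at
# the array edges and divided by the actual number of bins covered.
runningMean <- function(x, w) {
  n <- length(x)
  if (w >= n) return(rep(mean(x), n))
  h <- w %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Per-bin lambda: max over the genome-wide input rate and the local-window
# input rates (each window's mean bin count, i.e. already "per bin").
localLambda <- function(inp, globalRate, localWindows, binWidth) {
  lam <- rep(globalRate, length(inp))
  for (w in localWindows) {
    wBins <- max(1L, as.integer(round(w / binWidth)))
    lam <- pmax(lam, runningMean(inp, wBins))
  }
  lam
}

#' Call peaks from ChIP and input signal maps
#'
#' A transparent local-Poisson enrichment caller: for every bin, the
#' background rate lambda is the maximum of the genome-wide input rate per
#' bin and the mean input rate in each local window centred on the bin
#' (default 1, 5 and 10 kb). A bin is significant when its Poisson
#' upper-tail probability `P(X >= count)` is at most `pCutoff` *and*
#' `count / lambda >= minFold`. Significant bins separated by at most
#' `mergeGap` non-significant bins are merged into peaks; the summit is the
#' centre of the maximum-count bin (leftmost on ties), the peak p-value the
#' minimum bin p-value, and the fold enrichment the maximum bin-level
#' `count / lambda` among the peak's significant bins.
#'
#' @param chipMap,inputMap [SignalMap-class] objects with identical bin
#'   width and chromosome set. Depth-match the input first (see
#'   [downsampleTags()]); an all-zero input map triggers a warning and the
#'   ChIP genome-wide rate is used as background.
#' @param config a [PeakCallConfig-class].
#' @param chipTags optional `GRanges` of the ChIP tags; when given, exact
#'   per-peak tag counts are computed via [countTagsInRegion()], otherwise
#'   the count is estimated from bin sums.
#' @return A coordinate-sorted `GRanges` with metadata columns `name`,
#'   `summit` (bp), `tagCount`, `foldEnrichment` and `pValue`.
#' @export
callPeaks <- function(chipMap, inputMap, config = peakCallConfig(),
                      chipTags = NULL) {
  stopf(chipMap@binWidth == inputMap@binWidth,
        "bin width mismatch: %d vs %d", chipMap@binWidth, inputMap@binWidth)
  stopf(identical(sort(names(chipMap@counts)), sort(names(inputMap@counts))),
        "chip and input maps must cover the same chromosomes")
  bw <- chipMap@binWidth
  totalBins <- sum(vapply(chipMap@counts, length, integer(1)))
  inputTotal <- sum(vapply(inputMap@counts, sum, numeric(1)))
  chipTotal <- sum(vapply(chipMap@counts, sum, numeric(1)))
  if (inputTotal == 0 && chipTotal > 0) {
    warning("input map is empty; using genome-wide ChIP rate as background")
    globalRate <- chipTotal / totalBins
  } else {
    globalRate <- inputTotal / totalBins
  }
  peaks <- list()
  for (chrom in names(chipMap@counts)) {
    cnt <- chipMap@counts[[chrom]]
    inp <- if (inputTotal == 0) rep(globalRate, length(cnt))
           else inputMap@counts[[chrom]]
    lam <- localLambda(inp, globalRate, config@localWindows, bw)
    lam <- pmax(lam, .Machine$double.eps)
    # clamp at the smallest normal double so reported p-values stay in (0,1]
    pv <- pmax(ppois(cnt - 1L, lam, lower.tail = FALSE),
               .Machine$double.xmin)
    sig <- which(pv <= config@pCutoff & cnt >= config@minFold * lam &
                   cnt > 0L)
    if (length(sig) == 0L) next
    grp <- cumsum(c(1L, diff(sig) > config@mergeGap + 1L))
    chromLen <- chipMap@seqlens[[chrom]]
    for (g in split(sig, grp)) {
      b1 <- g[1L]; b2 <- g[length(g)]
      maxBin <- g[which.max(cnt[g])]  # which.max: leftmost on ties
      summit <- (maxBin - 1L) * bw + as.integer(ceiling(bw / 2))
      startBp <- (b1 - 1L) * bw + 1L
      endBp <- min(b2 * bw, chromLen)
      allBins <- b1:b2
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = chrom, start = startBp, end = endBp, summit = summit,
        binSum = sum(cnt[allBins]),
        foldEnrichment = max(cnt[g] / lam[g]),
        pValue = min(pv[g]))
    }
  }
  if (length(peaks) == 0L) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(name = character(), summit = integer(),
                           tagCount = numeric(), foldEnrichment = numeric(),
                           pValue = numeric())
    return(gr)
  }
  df <- do.call(rbind, peaks)
  ord <- order(match(df$chrom, names(chipMap@counts)), df$start)
  df <- df[ord, , drop = FALSE]
  gr <- GRanges(df$chrom, IRanges(df$start, df$end))
  tagCount <- if (!is.null(chipTags)) {
    countTagsInRegion(chipTags, gr, fragLen = chipMap@fragLen)
  } else {
    # a fragment of length f overlaps (f + bw - 1)/bw bins on average
    round(df$binSum * bw / (chipMap@fragLen + bw - 1L))
  }
  mcols(gr) <- DataFrame(name = sprintf("peak_%d", seq_along(gr)),
                         summit = as.integer(df$summit),
                         tagCount = as.numeric(tagCount),
                         foldEnrichment = df$foldEnrichment,
                         pValue = df$pValue)
  gr
}

#' Empirical FDR by treatment/control swap
#'
#' Calls peaks twice — ChIP vs input, then input vs ChIP — and returns the
#' ratio (swapped peak count) / (real peak count).
#'
#' @inheritParams callPeaks
#' @return A single number: 0 when both counts are zero; `Inf` (with a
#'   warning) when no real peaks exist but swapped peaks do.
#' @export
empiricalFdr <- function(chipMap, inputMap, config = peakCallConfig()) {
  nReal <- length(callPeaks(chipMap, inputMap, config))
  nSwap <- length(callPeaks(inputMap, chipMap, config))
  if (nReal == 0L) {
    if (nSwap == 0L) return(0)
    warning("no real peaks but swapped peaks found; empirical FDR undefined")
    return(Inf)
  }
  nSwap / nReal
}

# ---------------------------------------------------------------------------
# Peak I/O (BED6+4)
# ---------------------------------------------------------------------------

#' Write peaks as BED6+4
#'
#' Columns: chrom, start (0-based), end, name, score (`-10*log10(p)`,
#' capped at 10000), strand (`.`), then summit (0-based), tagCount,
#' foldEnrichment, pValue. Pass `narrowPeak = TRUE` for the
#' narrowPeak-compatible column order (signalValue, pValue as -log10,
#' qValue -1, relative summit offset).
#'
#' @param peaks `GRanges` from [callPeaks()].
#' @param path output path.
#' @param narrowPeak logical.
#' @return `path`, invisibly.
#' @export
writePeaksBed <- function(peaks, path, narrowPeak = FALSE) {
  score <- pmin(round(-10 * log10(pmax(peaks$pValue, 1e-1000))), 10000)
  if (narrowPeak) {
    df <- data.frame(
      chrom = as.character(seqnames(peaks)), start = start(peaks) - 1L,
      end = end(peaks), name = peaks$name, score = score, strand = ".",
      signalValue = peaks$foldEnrichment,
      pValue = -log10(pmax(peaks$pValue, 1e-1000)), qValue = -1,
      peak = peaks$summit - start(peaks))
  } else {
    df <- data.frame(
      chrom = as.character(seqnames(peaks)), start = start(peaks) - 1L,
      end = end(peaks), name = peaks$name, score = score, strand = ".",
      summit = peaks$summit - 1L, tagCount = peaks$tagCount,
      foldEnrichment = peaks$foldEnrichment, pValue = peaks$pValue)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read peaks written by [writePeaksBed()] (default column order)
#'
#' @param path path to the BED6+4 file.
#' @return `GRanges` with the same metadata columns as [callPeaks()].
#' @export
readPeaksBed <- function(path) {
  stopf(file.exists(path), "no such file: %s", path)
  df <- read.delim(path, header = FALSE,
                   col.names = c("chrom", "start", "end", "name", "score",
                                 "strand", "summit", "tagCount",
                                 "foldEnrichment", "pValue"))
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
  mcols(gr) <- DataFrame(name = df$name, summit = as.integer(df$summit + 1L),
                         tagCount = df$tagCount,
                         foldEnrichment = df$foldEnrichment,
                         pValue = df$pValue)
  gr
}
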