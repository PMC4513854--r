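#' @include AllClasses.R signal-map.R formats.R
NULL

#' Two-way peak overlap
#'
#' Counts, for each peak set, how many of its peaks overlap (>= 1 bp, same
#' chromosome) at least one peak of the other set. Each peak is counted
#' once regardless of how many partners it overlaps.
#'
#' @param peaksA,peaksB `GRanges`.
#' @return A list with `nA`, `nB`, `nAWithB`, `nBWithA`.
#' @export
peakOverlap <- function(peaksA, peaksB) {
  a <- granges(peaksA)
  b <- granges(peaksB)
  list(nA = length(a), nB = length(b),
       nAWithB = sum(countOverlaps(a, b, ignore.strand = TRUE) > 0L),
       nBWithA = sum(countOverlaps(b, a, ignore.strand = TRUE) > 0L))
}

#' Two-factor tag-count scatter table
#'
#' One row per factor-A peak (locations with only a factor-B peak are, by
#' construction, excluded): the tag counts of both factors in the peak
#' region (fragment-overlap counting, see [countTagsInRegion()]) and the
#' peak's motif class.
#'
#' @param peaksA `GRanges` of factor-A peaks with `name` metadata.
#' @param tagsA,tagsB width-1 `GRanges` of the two factors' tags.
#' @param classes factor from [classifyPeaks()], named by peak name and
#'   covering every peak in `peaksA`.
#' @param fragLen fragment extension length for counting.
#' @return A `data.frame` with columns `peak`, `tagsA`, `tagsB`, `class`.
#' @export
scatterTable <- function(peaksA, tagsA, tagsB, classes, fragLen = 150L) {
  stopf(all(peaksA$name %in% names(classes)),
        "every peak needs a motif class")
  data.frame(
    peak = peaksA$name,
    tagsA = countTagsInRegion(tagsA, peaksA, fragLen = fragLen),
    tagsB = countTagsInRegion(tagsB, peaksA, fragLen = fragLen),
    class = as.character(classes[peaksA$name]),
    stringsAsFactors = FALSE)
}

#' Per-class linear regression of the tag-count scatter
#'
#' Ordinary least squares of `tagsA` on `tagsB` for the points of one motif
#' class, with the Pearson correlation.
#'
#' @param points data.frame from [scatterTable()].
#' @param class motif class to fit (`NULL`: all points).
#' @return A list with `slope`, `intercept`, `r`, `n`, `defined`. With
#'   fewer than 2 points or zero variance in `tagsB` the fit is undefined
#'   (`defined = FALSE`, numeric fields `NA`).
#' @export
classRegression <- function(points, class = NULL) {
  if (!is.null(class)) points <- points[points$class == class, , drop = FALSE]
  n <- nrow(points)
  if (n < 2L || var(points$tagsB) == 0 || var(points$tagsA) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                n = n, defined = FALSE))
  }
  fit <- lm(tagsA ~ tagsB, data = points)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r = cor(points$tagsA, points$tagsB), n = n, defined = TRUE)
}

#' Fraction of peaks with a summit within a window of any TSS
#'
#' @param peaks `GRanges` with a `summit` metadata column.
#' @param genes gene table.
#' @param window half-window in bp (default 3000: the promoter-region
#'   statistic "within 3000 bp of TSS").
#' @return Fraction in `[0, 1]`; `NA` for an empty peak list.
#' @export
promoterFraction <- function(peaks, genes, window = 3000L) {
  stopf(nrow(genes) > 0L, "gene table is empty")
  if (length(peaks) == 0L) return(NA_real_)
  chrom <- as.character(seqnames(peaks))
  near <- vapply(seq_along(peaks), function(i) {
    tss <- genes$tss[genes$chrom == chrom[i]]
    length(tss) > 0L && min(abs(peaks$summit[i] - tss)) <= window
  }, logical(1))
  mean(near)
}

#' Cross-dataset conservation of sampled peaks
#'
#' Uniformly samples `nSample` peaks without replacement and counts how many
#' overlap (>= 1 bp) at least one peak in *every* provided set — the
#' "k out of n randomly selected peaks conserved in all datasets" statistic.
#'
#' @param peaks `GRanges` to sample from (pre-filter to a promoter subset if
#'   desired; the sampler takes any subset as given).
#' @param otherPeakSets non-empty list of `GRanges`.
#' @param nSample sample size (default 100).
#' @param seed RNG seed.
#' @param minOverlapFraction optional minimum fraction of the sampled peak's
#'   width that must be covered by a partner (0 = any 1-bp overlap).
#' @return Named integer vector `c(k, n)`; attribute `flags` holds the
#'   per-sample, per-set overlap logical matrix.
#' @export
conservationFraction <- function(peaks, otherPeakSets, nSample = 100L,
                                 seed = NULL, minOverlapFraction = 0) {
  stopf(length(otherPeakSets) > 0L, "otherPeakSets must be non-empty")
  nSample <- as.integer(nSample)
  stopf(nSample <= length(peaks),
        "nSample = %d exceeds the %d available peaks", nSample,
        length(peaks))
  idx <- withSeed(seed, sort(sample.int(length(peaks), nSample)))
  sel <- granges(peaks[idx])
  flags <- vapply(otherPeakSets, function(set) {
    if (minOverlapFraction <= 0) {
      countOverlaps(sel, granges(set), ignore.strand = TRUE) > 0L
    } else {
      hits <- findOverlaps(sel, granges(set), ignore.strand = TRUE)
      cov <- rep(0, length(sel))
      if (length(hits) > 0L) {
        ow <- width(pintersect(sel[queryHits(hits)],
                               granges(set)[subjectHits(hits)]))
        best <- tapply(ow, queryHits(hits), max)
        cov[as.integer(names(best))] <- best
      }
      cov / width(sel) >= minOverlapFraction
    }
  }, logical(nSample))
  flags <- matrix(flags, nrow = nSample)
  k <- sum(rowSums(flags) == length(otherPeakSets))
  out <- c(k = as.integer(k), n = nSample)
  attr(out, "flags") <- flags
  out
}
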