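#' @include AllClasses.R
NULL

#' Accessors for SignalMap and motif objects
#'
#' @param x object.
#' @param chrom optional chromosome name; if omitted, `binCounts` returns the
#'   full named list.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname accessors
#' @export
setGeneric("fragLen", function(x) standardGeneric("fragLen"))

#' @rdname accessors
#' @export
setGeneric("nTags", function(x) standardGeneric("nTags"))

#' @rdname accessors
#' @export
setGeneric("binCounts", function(x, chrom = NULL) standardGeneric("binCounts"))

#' @rdname accessors
#' @export
setGeneric("motifWidth", function(x) standardGeneric("motifWidth"))

#' @rdname accessors
#' @export
setGeneric("categoryCounts", function(x) standardGeneric("categoryCounts"))

#' @rdname accessors
#' @export
setGeneric("categoryPercent", function(x) standardGeneric("categoryPercent"))

#' @rdname accessors
#' @export
setMethod("binWidth", "SignalMap", function(x) x@binWidth)

#' @rdname accessors
#' @export
setMethod("fragLen", "SignalMap", function(x) x@fragLen)

#' @rdname accessors
#' @export
setMethod("nTags", "SignalMap", function(x) x@nTags)

#' @rdname accessors
#' @export
setMethod("binCounts", "SignalMap", function(x, chrom = NULL) {
  if (is.null(chrom)) return(x@counts)
  stopf(chrom %in% names(x@counts), "unknown chromosome '%s'", chrom)
  x@counts[[chrom]]
})

#' @rdname accessors
#' @export
setMethod("seqlengths", "SignalMap", function(x) x@seqlens)

#' @rdname accessors
#' @export
setMethod("motifWidth", "ConsensusMotif", function(x) nchar(x@iupac))

#' @rdname accessors
#' @export
setMethod("motifWidth", "PWMotif", function(x) ncol(x@mat))

#' @rdname accessors
#' @export
setMethod("motifWidth", "DimericMotif", function(x) {
  # width of the canonical arrangement at the minimum spacer
  2L * motifWidth(x@half) + x@spacerMin
})

#' @rdname accessors
#' @export
setMethod("categoryCounts", "FeatureDistribution", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("categoryPercent", "FeatureDistribution", function(x) {
  if (x@total == 0L) return(setNames(rep(NaN, length(x@counts)), names(x@counts)))
  100 * x@counts / x@total
})

#' Reverse complement of a consensus motif
#'
#' @param x a [ConsensusMotif-class].
#' @param ... ignored.
#' @export
setMethod("reverseComplement", "ConsensusMotif", function(x, ...) {
  consensusMotif(revcompChar(x@iupac), paste0(x@name, "_rc"))
})

setMethod("show", "SignalMap", function(object) {
  cat(sprintf("SignalMap: %d chromosome(s), binWidth=%d, fragLen=%d, nTags=%d\n",
              length(object@counts), object@binWidth, object@fragLen,
              object@nTags))
  for (chrom in names(object@counts)) {
    cnt <- object@counts[[chrom]]
    cat(sprintf("  %s: %d bins (length %d), total count %.0f\n",
                chrom, length(cnt), object@seqlens[[chrom]], sum(cnt)))
  }
})

setMethod("show", "ConsensusMotif", function(object) {
  cat(sprintf("ConsensusMotif '%s': %s (width %d)\n", object@name,
              object@iupac, nchar(object@iupac)))
})

setMethod("show", "DimericMotif", function(object) {
  cat(sprintf("DimericMotif '%s': %s + spacer %d-%d bp + revcomp\n",
              object@name, object@half@iupac, object@spacerMin,
              object@spacerMax))
})

setMethod("show", "PWMotif", function(object) {
  cat(sprintf("PWMotif '%s': width %d, background %s\n", object@name,
              ncol(object@mat),
              paste(sprintf("%.2f", object@background), collapse = "/")))
})

setMethod("show", "FeatureDistribution", function(object) {
  cat(sprintf("FeatureDistribution over %d peaks\n", object@total))
  pct <- categoryPercent(object)
  for (k in names(object@counts)) {
    cat(sprintf("  %-20s %6d  %6.2f%%\n", k, object@counts[[k]], pct[[k]]))
  }
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0(
    "SimulationConfig: %.0f bp / %d chrom(s), gc=%.2f, %d genes ",
    "(%d CCAAT promoters), %d SOX + %d dimeric sites\n",
    "  fragLen=%d readLen=%d chipTags=%d inputTags=%d enrichment=%.2f seed=%d\n"),
    object@genomeLength, object@nChroms, object@gc, object@nGenes,
    object@nCcaatPromoters, object@nSoxSites, object@nDimericSites,
    object@fragLen, object@readLen, object@nChipTags, object@nInputTags,
    object@enrichment, object@seed))
})

setMethod("show", "PeakCallConfig", function(object) {
  cat(sprintf(
    "PeakCallConfig: pCutoff=%g, minFold=%g, mergeGap=%d, localWindows=%s\n",
    object@pCutoff, object@minFold, object@mergeGap,
    paste(object@localWindows, collapse = "/")))
})
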