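#' @include utils.R
NULL

# ---------------------------------------------------------------------------
# SignalMap
# ---------------------------------------------------------------------------

#' Binned genomic signal map
#'
#' Per-chromosome counts of extended sequencing fragments in fixed-width bins
#' (default 32 nt). A fragment increments every bin it overlaps by at least
#' one base, so bin counts are a coverage surrogate: the number of fragments
#' touching the bin.
#'
#' @slot binWidth integer, bin width in bp.
#' @slot fragLen integer, in-silico fragment extension length in bp.
#' @slot counts named list of integer vectors, one per chromosome; element
#'   `i` of a vector is the fragment count of bin `i` (bin `i` covers bases
#'   `(i-1)*binWidth + 1 ... i*binWidth`, 1-based closed).
#' @slot seqlens named integer vector of chromosome lengths.
#' @slot nTags integer, number of tags that contributed.
#'
#' @seealso [buildSignalMap()], [writeSignalMap()], [readSignalMap()]
#' @exportClass SignalMap
setClass("SignalMap",
  representation(
    binWidth = "integer",
    fragLen = "integer",
    counts = "list",
    seqlens = "integer",
    nTags = "integer"
  )
)

setValidity("SignalMap", function(object) {
  msgs <- character()
  if (length(object@binWidth) != 1L || object@binWidth < 1L)
    msgs <- c(msgs, "binWidth must be a single positive integer")
  if (length(object@fragLen) != 1L || object@fragLen < 1L)
    msgs <- c(msgs, "fragLen must be a single positive integer")
  if (is.null(names(object@counts)) ||
      !identical(names(object@counts), names(object@seqlens)))
    msgs <- c(msgs, "counts and seqlens must share chromosome names")
  for (chrom in names(object@counts)) {
    cnt <- object@counts[[chrom]]
    if (any(cnt < 0L))
      msgs <- c(msgs, sprintf("negative bin count on %s", chrom))
    expBins <- as.integer(ceiling(object@seqlens[[chrom]] / object@binWidth))
    if (length(cnt) != expBins)
      msgs <- c(msgs, sprintf("%s: expected %d bins, got %d",
                              chrom, expBins, length(cnt)))
  }
  if (length(msgs) > 0L) msgs else TRUE
})

# ---------------------------------------------------------------------------
# Peak-calling configuration
# ---------------------------------------------------------------------------

#' Peak caller configuration
#'
#' @slot pCutoff numeric, Poisson upper-tail p-value cutoff per bin
#'   (default 1e-7, the cutoff used for the original MACS run this caller
#'   stands in for).
#' @slot minFold numeric, minimum ChIP/local-lambda fold enrichment.
#' @slot mergeGap integer, maximum number of non-significant bins allowed
#'   between significant bins merged into one peak.
#' @slot localWindows numeric vector of window sizes (bp) over which the
#'   local input rate (lambda) is estimated; the per-bin lambda is the
#'   maximum of the genome-wide rate and all local-window rates.
#'
#' @exportClass PeakCallConfig
setClass("PeakCallConfig",
  representation(
    pCutoff = "numeric",
    minFold = "numeric",
    mergeGap = "integer",
    localWindows = "numeric"
  )
)

setValidity("PeakCallConfig", function(object) {
  msgs <- character()
  if (!(object@pCutoff > 0 && object@pCutoff < 1))
    msgs <- c(msgs, "pCutoff must lie in (0, 1)")
  if (object@minFold < 1)
    msgs <- c(msgs, "minFold must be >= 1")
  if (object@mergeGap < 0L)
    msgs <- c(msgs, "mergeGap must be >= 0")
  if (any(object@localWindows <= 0))
    msgs <- c(msgs, "localWindows must be positive")
  if (length(msgs) > 0L) msgs else TRUE
})

#' Create a peak caller configuration
#'
#' @param pCutoff per-bin Poisson upper-tail p-value cutoff.
#' @param minFold minimum per-bin fold enrichment over local lambda.
#' @param mergeGap maximum number of non-significant bins bridged when
#'   merging significant bins into peaks.
#' @param localWindows window sizes (bp) for local lambda estimation.
#' @return A [PeakCallConfig-class] object.
#' @examples
#' peakCallConfig()
#' peakCallConfig(minFold = 16)  # the stricter mfold-like setting
#' @export
peakCallConfig <- function(pCutoff = 1e-7, minFold = 5, mergeGap = 1L,
                           localWindows = c(1000, 5000, 10000)) {
  new("PeakCallConfig", pCutoff = pCutoff, minFold = as.numeric(minFold),
      mergeGap = as.integer(mergeGap), localWindows = as.numeric(localWindows))
}

# ---------------------------------------------------------------------------
# Simulation configuration
# ---------------------------------------------------------------------------

#' Synthetic ChIP-seq simulation configuration
#'
#' Defines the study conditions the simulator emulates: a small genome with
#' genes whose proximal promoters carry a planted CCAAT-box (Motif 1) bound
#' by both factors, plus intergenic SOX-consensus (Motif 2) and dimeric
#' inverted-repeat (Motif 3) sites bound by factor A only; 150-bp fragments
#' sequenced as 50-nt single-end tags, with a uniform-background input track
#' at more than twice the ChIP depth.
#'
#' @slot genomeLength total genome length (bp).
#' @slot nChroms number of chromosomes (genomeLength split evenly).
#' @slot gc background G+C fraction.
#' @slot nGenes number of gene models.
#' @slot nCcaatPromoters genes receiving a Motif-1 instance in the proximal
#'   promoter.
#' @slot nSoxSites,nDimericSites counts of intergenic Motif-2 / Motif-3 sites.
#' @slot fragLen fragment length (bp, default 150).
#' @slot readLen read length (bp, default 50).
#' @slot nChipTags,nInputTags tag counts per ChIP factor / for input.
#' @slot enrichment fraction of ChIP tags drawn from planted sites.
#' @slot siteOffsetUpstream bp between the promoter Motif-1 instance and the
#'   TSS (site ends this many bp upstream; default 106, the TSS offset of the
#'   validated TOP2A CCAAT box).
#' @slot jitterSd sd (bp) of the normal jitter of fragment centers around the
#'   site center.
#' @slot repeatFraction fraction of the genome covered by the random repeat
#'   track.
#' @slot strengthSdLog sdlog of the log-normal per-site binding strength.
#' @slot seed RNG seed.
#'
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    genomeLength = "numeric",
    nChroms = "integer",
    gc = "numeric",
    nGenes = "integer",
    nCcaatPromoters = "integer",
    nSoxSites = "integer",
    nDimericSites = "integer",
    fragLen = "integer",
    readLen = "integer",
    nChipTags = "integer",
    nInputTags = "integer",
    enrichment = "numeric",
    siteOffsetUpstream = "integer",
    jitterSd = "numeric",
    repeatFraction = "numeric",
    strengthSdLog = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  counts <- c(object@nGenes, object@nCcaatPromoters, object@nSoxSites,
              object@nDimericSites, object@nChipTags, object@nInputTags)
  if (any(counts < 0L)) msgs <- c(msgs, "all counts must be >= 0")
  if (object@gc < 0 || object@gc > 1) msgs <- c(msgs, "gc must be in [0, 1]")
  if (object@enrichment < 0 || object@enrichment > 1)
    msgs <- c(msgs, "enrichment must be in [0, 1]")
  if (object@nCcaatPromoters > object@nGenes)
    msgs <- c(msgs, "nCcaatPromoters must be <= nGenes")
  if (object@genomeLength < 1) msgs <- c(msgs, "genomeLength must be positive")
  if (object@nChroms < 1L) msgs <- c(msgs, "nChroms must be >= 1")
  if (length(msgs) > 0L) msgs else TRUE
})

#' Create a simulation configuration
#'
#' Defaults describe the toy-scale study conditions: one 2-Mb chromosome,
#' 60 genes of which 30 carry a promoter CCAAT box, 15 SOX-consensus and 15
#' dimeric intergenic sites, 40,000 ChIP tags per factor at 50% site-derived
#' enrichment, and 100,000 input tags (> 2x ChIP depth).
#'
#' @param genomeLength,nChroms,gc,nGenes,nCcaatPromoters,nSoxSites,nDimericSites
#'   see [SimulationConfig-class].
#' @param fragLen,readLen,nChipTags,nInputTags,enrichment,siteOffsetUpstream
#'   see [SimulationConfig-class].
#' @param jitterSd,repeatFraction,strengthSdLog,seed
#'   see [SimulationConfig-class].
#' @return A [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(genomeLength = 2e5, nGenes = 10,
#'                         nCcaatPromoters = 6, seed = 1)
#' @export
simulationConfig <- function(genomeLength = 2e6, nChroms = 1L, gc = 0.41,
                             nGenes = 60L, nCcaatPromoters = 30L,
                             nSoxSites = 15L, nDimericSites = 15L,
                             fragLen = 150L, readLen = 50L,
                             nChipTags = 40000L, nInputTags = 100000L,
                             enrichment = 0.5, siteOffsetUpstream = 106L,
                             jitterSd = 30, repeatFraction = 0.1,
                             strengthSdLog = 0.5, seed = 1L) {
  new("SimulationConfig",
      genomeLength = as.numeric(genomeLength), nChroms = as.integer(nChroms),
      gc = gc, nGenes = as.integer(nGenes),
      nCcaatPromoters = as.integer(nCcaatPromoters),
      nSoxSites = as.integer(nSoxSites),
      nDimericSites = as.integer(nDimericSites),
      fragLen = as.integer(fragLen), readLen = as.integer(readLen),
      nChipTags = as.integer(nChipTags), nInputTags = as.integer(nInputTags),
      enrichment = enrichment,
      siteOffsetUpstream = as.integer(siteOffsetUpstream),
      jitterSd = jitterSd, repeatFraction = repeatFraction,
      strengthSdLog = strengthSdLog, seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# Motif models
# ---------------------------------------------------------------------------

#' IUPAC consensus motif
#'
#' @slot iupac consensus string over IUPAC nucleotide codes.
#' @slot name motif name.
#' @exportClass ConsensusMotif
setClass("ConsensusMotif",
  representation(iupac = "character", name = "character")
)

setValidity("ConsensusMotif", function(object) {
  if (length(object@iupac) != 1L || nchar(object@iupac) == 0L)
    return("iupac must be a single non-empty string")
  chars <- strsplit(toupper(object@iupac), "", fixed = TRUE)[[1L]]
  bad <- setdiff(chars, names(IUPAC_MAP))
  if (length(bad) > 0L)
    return(sprintf("invalid IUPAC code(s): %s", paste(unique(bad), collapse = ", ")))
  TRUE
})

#' Create a consensus motif
#'
#' Two motifs ship as package defaults: the NF-Y CCAAT-box motif
#' (`AGCCAATSR`: the CCAAT core with its preferred 5' AG and 3' CA/GG
#' flanks) and the classical SOX heptamer (`WWCAAWG`).
#'
#' @param iupac consensus string over IUPAC codes.
#' @param name motif name.
#' @return A [ConsensusMotif-class].
#' @examples
#' motifCcaatFull()
#' consensusMotif("WWCAAWG", "SOX_consensus")
#' @export
consensusMotif <- function(iupac, name = iupac) {
  new("ConsensusMotif", iupac = toupper(iupac), name = name)
}

#' @rdname consensusMotif
#' @export
motifCcaatFull <- function() consensusMotif("AGCCAATSR", "M1_CCAAT_flanked")

#' @rdname consensusMotif
#' @export
motifCcaatCore <- function() consensusMotif("CCAAT", "M1_CCAAT_core")

#' @rdname consensusMotif
#' @export
motifSoxConsensus <- function() consensusMotif("WWCAAWG", "M2_SOX_consensus")

#' Dimeric inverted-repeat motif
#'
#' A half-site consensus followed, after a spacer, by its reverse complement.
#' The canonical dimeric SOX site uses the 7-bp heptamer half with a 4-bp
#' spacer; an exploratory wider spacer range (2-14 bp) can be requested.
#'
#' @slot half [ConsensusMotif-class] half-site.
#' @slot spacerMin,spacerMax spacer range in bp.
#' @slot name motif name.
#' @exportClass DimericMotif
setClass("DimericMotif",
  representation(half = "ConsensusMotif", spacerMin = "integer",
                 spacerMax = "integer", name = "character")
)

setValidity("DimericMotif", function(object) {
  if (object@spacerMin < 0L || object@spacerMin > object@spacerMax)
    return("need 0 <= spacerMin <= spacerMax")
  TRUE
})

#' Create a dimeric inverted-repeat motif
#'
#' @param half half-site [ConsensusMotif-class].
#' @param spacerMin,spacerMax spacer range in bp (canonical site: both 4).
#' @param name motif name.
#' @return A [DimericMotif-class].
#' @examples
#' motifSoxDimeric()                       # canonical 4-bp spacer
#' motifSoxDimeric(spacerMin = 2, spacerMax = 14)  # exploratory range
#' @export
dimericMotif <- function(half = motifSoxConsensus(), spacerMin = 4L,
                         spacerMax = 4L, name = "dimeric") {
  new("DimericMotif", half = half, spacerMin = as.integer(spacerMin),
      spacerMax = as.integer(spacerMax), name = name)
}

#' @rdname dimericMotif
#' @param ... passed on to `dimericMotif()`.
#' @export
motifSoxDimeric <- function(...) {
  dimericMotif(half = motifSoxConsensus(), name = "M3_SOX_dimeric", ...)
}

#' Position weight matrix motif
#'
#' Column-stochastic base probabilities with a background model; scores are
#' log2 odds against the background, and p-values are computed exactly on a
#' discretized score grid (see [pwmPvalue()]).
#'
#' @slot mat 4 x width probability matrix, rows A, C, G, T.
#' @slot background length-4 background probabilities (A, C, G, T).
#' @slot granularity score discretization step in bits.
#' @slot name motif name.
#' @exportClass PWMotif
setClass("PWMotif",
  representation(mat = "matrix", background = "numeric",
                 granularity = "numeric", name = "character")
)

setValidity("PWMotif", function(object) {
  msgs <- character()
  if (nrow(object@mat) != 4L || !identical(rownames(object@mat), DNA_BASES))
    msgs <- c(msgs, "mat must have rows A, C, G, T")
  if (any(abs(colSums(object@mat) - 1) > 1e-9))
    msgs <- c(msgs, "each PWM column must sum to 1")
  if (length(object@background) != 4L || abs(sum(object@background) - 1) > 1e-9)
    msgs <- c(msgs, "background must be 4 probabilities summing to 1")
  if (object@granularity <= 0)
    msgs <- c(msgs, "granularity must be positive")
  if (length(msgs) > 0L) msgs else TRUE
})

# ---------------------------------------------------------------------------
# Feature distribution (nine-category annotation)
# ---------------------------------------------------------------------------

#' The nine gene-feature categories
#'
#' Order used in all distributions: distal promoter (-3 to -1 kb of TSS),
#' proximal promoter (-1 to 0 kb), 5' UTR, exon, intron, 3' UTR, proximal
#' downstream (0-1 kb past the annotated end), distal downstream (1-3 kb),
#' distal intergenic (everything else).
#'
#' @return Character vector of the nine category names.
#' @examples
#' featureCategories()
#' @export
featureCategories <- function() {
  c("distal_promoter", "proximal_promoter", "utr5", "exon", "intron",
    "utr3", "proximal_downstream", "distal_downstream", "distal_intergenic")
}

#' Distribution of peaks over gene-feature categories
#'
#' @slot counts named integer vector over the nine categories.
#' @slot total total number of classified peaks.
#' @exportClass FeatureDistribution
setClass("FeatureDistribution",
  representation(counts = "integer", total = "integer")
)

setValidity("FeatureDistribution", function(object) {
  msgs <- character()
  if (!identical(names(object@counts), featureCategories()))
    msgs <- c(msgs, "counts must be named by the nine feature categories")
  if (any(object@counts < 0L)) msgs <- c(msgs, "counts must be >= 0")
  if (sum(object@counts) != object@total)
    msgs <- c(msgs, "counts must sum to total")
  if (length(msgs) > 0L) msgs else TRUE
})
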