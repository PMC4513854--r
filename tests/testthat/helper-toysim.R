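# Shared fixtures, built in code. The default toy simulation (2 Mb, 60
# genes, ~140k tags) is expensive enough to cache per (seed, enrichment).

.simCache <- new.env(parent = emptyenv())

# Full toy run: simulate, deduplicate, depth-match input, build maps, call
# peaks for both factors.
toyRun <- function(seed = 1L, enrichment = 0.5) {
  key <- sprintf("s%d_e%g", seed, enrichment)
  if (!is.null(.simCache[[key]])) return(.simCache[[key]])
  cfg <- simulationConfig(seed = as.integer(seed), enrichment = enrichment)
  sim <- generateGenome(cfg)
  tagsA <- deduplicateTags(simulateTags(sim, "A"))
  tagsB <- deduplicateTags(simulateTags(sim, "B"))
  tagsInput <- deduplicateTags(simulateTags(sim, "input"))
  seqlens <- setNames(width(sim$genome), names(sim$genome))
  inputMatched <- downsampleTags(tagsInput,
                                 max(length(tagsA), length(tagsB)),
                                 seed = seed + 7L)
  mapA <- buildSignalMap(tagsA, seqlens)
  mapB <- buildSignalMap(tagsB, seqlens)
  mapInput <- buildSignalMap(inputMatched, seqlens)
  peaksA <- callPeaks(mapA, mapInput, chipTags = tagsA)
  peaksB <- callPeaks(mapB, mapInput, chipTags = tagsB)
  res <- list(sim = sim, tagsA = tagsA, tagsB = tagsB,
              tagsInput = tagsInput, inputMatched = inputMatched,
              seqlens = seqlens, mapA = mapA, mapB = mapB,
              mapInput = mapInput, peaksA = peaksA, peaksB = peaksB)
  .simCache[[key]] <- res
  res
}

# A small, fast simulation for structural tests.
smallSim <- function(seed = 1L, ...) {
  generateGenome(simulationConfig(
    genomeLength = 4e5, nGenes = 10L, nCcaatPromoters = 6L,
    nSoxSites = 4L, nDimericSites = 3L, nChipTags = 8000L,
    nInputTags = 20000L, seed = as.integer(seed), ...))
}

# Build a one-row gene table the way readGeneTable() would return it
# (1-based closed coordinates, list columns, tss).
makeGene <- function(name, chrom, strand, txStart, txEnd,
                     cdsStart = NA_integer_, cdsEnd = NA_integer_,
                     exonStarts = NULL, exonEnds = NULL) {
  if (is.null(exonStarts)) { exonStarts <- txStart; exonEnds <- txEnd }
  g <- data.frame(name = name, chrom = chrom, strand = strand,
                  txStart = txStart, txEnd = txEnd,
                  cdsStart = cdsStart, cdsEnd = cdsEnd,
                  stringsAsFactors = FALSE)
  g$exonStarts <- list(as.integer(exonStarts))
  g$exonEnds <- list(as.integer(exonEnds))
  g$tss <- if (strand == "+") txStart else txEnd
  g
}

# Peaks GRanges with the metadata columns the annotation/motif modules use.
makePeaks <- function(chrom, start, end, summit, tagCount = 10,
                      pValue = 1e-9) {
  gr <- GRanges(chrom, IRanges(start, end))
  mcols(gr) <- S4Vectors::DataFrame(
    name = sprintf("peak_%d", seq_along(gr)),
    summit = as.integer(summit),
    tagCount = rep_len(as.numeric(tagCount), length(gr)),
    foldEnrichment = rep_len(10, length(gr)),
    pValue = rep_len(pValue, length(gr)))
  gr
}

# Random DNA string (optionally with N), seeded.
randomSeq <- function(n, seed = NULL, withN = FALSE) {
  bases <- c("A", "C", "G", "T", if (withN) "N")
  probs <- if (withN) c(rep(0.24, 4), 0.04) else rep(0.25, 4)
  if (!is.null(seed)) set.seed(seed)
  paste(sample(bases, n, replace = TRUE, prob = probs), collapse = "")
}

# Independent oracle for consensus scanning: overlap-safe regular
# expression with each IUPAC code expanded to its base class. Classes
# contain only A/C/G/T, so an N in the sequence matches nothing.
oracleConsensusStarts <- function(seq, iupac) {
  classes <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
               S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
               B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
               N = "[ACGT]")
  rx <- paste0("(?=", paste(classes[strsplit(iupac, "")[[1]]],
                            collapse = ""), ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (length(m) == 1 && m[1] == -1) integer(0) else as.integer(m)
}
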