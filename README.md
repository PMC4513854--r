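# ChIPcooc

Two-factor co-occupancy analysis for ChIP-seq, as a tested, reusable R
package.

## The problem

Genome-wide binding studies of a transcription factor sometimes find that
its strongest peaks sit on another factor's motif. The motivating case is a
SOX-family HMG-box protein whose ChIP-seq peaks in colorectal cancer cells
fall precisely on CCAAT boxes — the element of the heterotrimeric NF-Y
factor — in the proximal promoters of cell-cycle genes, in addition to the
classical SOX consensus <sup>A</sup>/<sub>T</sub><sup>A</sup>/<sub>T</sub>CAA<sup>A</sup>/<sub>T</sub>G
and its dimeric inverted-repeat form. Establishing such co-occupancy
computationally takes a chain of steps: aligned tags → binned signal maps →
peaks with an input-controlled background model → TSS/feature annotation
against a resampled random control → motif scanning and four-way peak
classification → per-class tag-count regressions of one factor against the
other. ChIPcooc implements that chain end to end, along with the
quantification arithmetic of the usual validation assays (ChIP-qPCR percent
input, 2^(−ΔΔCt) expression, unpaired t tests), and ships a synthetic-genome
simulator with planted binding sites so every stage is benchmarked against a
known truth.

The statistical core:

* **Signal maps** — tags deduplicated, input downsampled to ChIP depth,
  fragments extended 3′ to 150 bp, counted in 32-nt bins (a fragment
  increments every bin it overlaps).
* **Peak calling** — per-bin Poisson test against a local background rate
  λ = max(genome-wide input rate, 1/5/10-kb local input rates), requiring
  `P(X ≥ count) ≤ 1e-7` and fold ≥ 5; swap-based empirical FDR.
* **Motif scanning** — exact IUPAC consensus matching (`AGCCAATSR`,
  `WWCAAWG`), PWM scanning with exact DP p-values (1e-3-bit grid, FIMO-style
  p ≤ 1e-4 default), and dimeric inverted-repeat scanning
  (half + spacer + reverse complement; canonical spacer 4 bp, exploratory
  range 2–14 bp).
* **Co-occupancy** — one scatter point per factor-A peak: tag counts of both
  factors in the peak region, classed `M1_ONLY` / `M1_AND_SOX` / `SOX_ONLY`
  / `NONE`; unweighted OLS and Pearson r per class.

## Worked example

Simulate the default toy study — one 2-Mb chromosome, 60 genes (30 with a
promoter CCAAT box 106 bp upstream of the TSS), 15 SOX-consensus and 15
dimeric intergenic sites, 40,000 tags per ChIP factor at 50% enrichment,
100,000 input tags — then call, classify and correlate:

```r
library(ChIPcooc)
library(GenomicRanges)

sim   <- generateGenome(simulationConfig(seed = 1))
tagsA <- deduplicateTags(simulateTags(sim, "A"))     # binds all site classes
tagsB <- deduplicateTags(simulateTags(sim, "B"))     # binds CCAAT sites only
tagsI <- deduplicateTags(simulateTags(sim, "input"))

seqlens <- setNames(width(sim$genome), names(sim$genome))
inp  <- downsampleTags(tagsI, length(tagsA), seed = 8)
mapA <- buildSignalMap(tagsA, seqlens)
mapI <- buildSignalMap(inp, seqlens)

peaks <- callPeaks(mapA, mapI, chipTags = tagsA)
length(peaks)                      # 60
empiricalFdr(mapA, mapI)           # 0

cls <- classifyPeaks(peaks, sim$genome)
table(cls)
#>    M1_ONLY M1_AND_SOX   SOX_ONLY       NONE
#>         20         10         30          0

sc <- scatterTable(peaks, tagsA, tagsB, cls)
classRegression(sc[sc$class %in% c("M1_ONLY", "M1_AND_SOX"), ])$r  # 0.975
classRegression(sc[sc$class == "SOX_ONLY", ])$r                    # 0.121
promoterFraction(peaks, sim$genes)                                 # 0.5
```

Every planted site is covered by a called peak (sensitivity 1.0 at these
settings), the swap FDR is 0, and the co-occupancy signature is the r = 0.97
versus r = 0.12 contrast: factor-B tag counts track factor-A tag counts only
at peaks carrying the CCAAT motif, because only those sites are co-bound.

The classifier is the same machinery used on printed sequences; the
validated promoter oligo yields its single CCAAT box (as ATTGG on the minus
strand):

```r
scanConsensus("TCCCGCCTCCCTAACCTGATTGGTTTATTCAAACAAACC", motifCcaatCore())
#> GRanges: seq 19-23 -  | M1_CCAAT_core  score 1  match ATTGG
translateDna("CCCAAGAAGAAGCGGAAGGTG")
#> [1] "PKKKRKV"
```

`runPipeline(pipelineConfig(outdir = "out"))` runs the whole chain
(simulate → signal → callpeaks → annotate → scanmotifs → cooccupancy) with
per-stage seeds and writes TSV/BED/bedGraph/JSON outputs plus a run
manifest; reruns are byte-identical.

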