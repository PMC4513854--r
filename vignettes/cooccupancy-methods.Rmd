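---
title: "Methods: two-factor ChIP-seq co-occupancy analysis with ChIPcooc"
author: "ChIPcooc maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-factor ChIP-seq co-occupancy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

ChIPcooc implements the computational core of a two-factor ChIP-seq
co-occupancy study: one factor (here called factor A, modelled on a SOX-family
HMG-box protein) binds both its classical consensus sites and CCAAT-box
promoter elements; a second factor (factor B, modelled on the NF-Y
heterotrimer, whose NF-YA subunit contacts DNA) binds the CCAAT boxes only.
The pipeline takes aligned tags — reads reduced to a (chromosome, 5'
position, strand) triple — and produces binned signal maps, enriched peaks,
TSS-relative and gene-feature annotation, motif-based peak classes, and the
tag-count scatter with per-class regressions that exposes the co-occupancy
structure. The arithmetic of the validation assays (ChIP-qPCR percent input,
2^(-ddCt) expression, pooled-variance t tests with star annotation) is
included so that bench-side quantification uses the same tested code.

All coordinates inside the package are 1-based closed (`GRanges`); BED,
bedGraph and refFlat-style files keep their native 0-based half-open
semantics, converted at input/output. This is the single-convention rule that
avoids off-by-one drift, expressed in the container convention of the
Bioconductor ecosystem the package lives in.

## Signal maps

Tags are deduplicated per (chromosome, position, strand); the deeper input
library is downsampled to the ChIP alignment count; each tag is extended at
its 3' end to the library's average fragment length (150 bp by default) and
assigned to 32-nt bins. A fragment increments *every* bin it overlaps by at
least one base, so a bin count is the number of fragments touching the bin —
a true coverage surrogate that we verify against a per-base brute-force
oracle in the test suite. Fragments are clipped at chromosome edges and the
clipped lengths are used in the conservation checks. Region tag counts use
the same fragment-overlap rule by default; a `fivePrime` flag switches to
raw 5'-position counting for sensitivity analysis.

## Peak calling

The original study called peaks with MACS (cutoff p = 1e-7, mfold 16) and
treated it as an external tool. ChIPcooc instead ships a transparent
local-Poisson caller operating directly on the signal maps: for every bin,
the background rate lambda is the maximum of the genome-wide input rate per
bin and the mean input rate in 1-, 5- and 10-kb windows centred on the bin
(the genome-wide floor prevents zero-lambda divisions in input deserts). A
bin is significant when its exact Poisson upper tail `P(X >= count)` is at
most `pCutoff` (default 1e-7, matching the study's cutoff) *and* its fold
enrichment `count / lambda` is at least `minFold`. Significant bins at most
`mergeGap` non-significant bins apart merge into a peak; the summit is the
centre of the maximum-count bin, leftmost on ties.

`minFold` defaults to 5, not 16: MACS's mfold parameter governs
model-building candidate selection rather than final peak filtering, so 16
as a hard final filter would be far stricter than the original pipeline's
behaviour; users mirroring the original setting can pass 16. The caller
deliberately omits MACS's shift model: the upstream 3'-extension already
produces strand-symmetric coverage, and the simulator emits fragments with
no strand asymmetry, so a shift stage would have nothing to estimate.

The swap-based empirical FDR is the peak count obtained after exchanging
treatment and control maps, divided by the real peak count (0 when both are
zero; infinite, with a warning, in the pathological zero-real case).

## Annotation

Peaks are annotated by their summit — a point, which keeps the nine
gene-feature categories mutually exclusive and their percentages additive:
distal promoter (−3 to −1 kb of the TSS), proximal promoter (−1 to 0 kb),
5' UTR, exon, intron, 3' UTR, proximal downstream (0–1 kb), distal
downstream (1–3 kb), distal intergenic. Inside a transcript the precedence
is 5' UTR > 3' UTR > exon > intron (UTRs from the CDS bounds; non-coding
transcripts contribute only exon/intron), so the UTR categories are never
swallowed by the exon bar. The "downstream" windows are measured from the
transcript end by default; the literal alternative — windows downstream of
the TSS itself, which overlaps the gene body — is available behind
`downstreamOf = "tss"` because the category's verbal definition admits both
readings and we did not want to guess silently.

The random-location control re-samples input-tag 5' positions without
replacement and gives each control interval the width of a randomly paired
real peak (the construction specifies the sampling of locations but not
widths; inheriting real widths keeps the width distribution matched).
Per-category enrichment is `log2(peak% / control%)`, with explicit `Inf` /
`NaN` sentinels for empty denominators.

## Motif models and scanning

Three motif models drive classification:

* **Motif 1** — the CCAAT box with its preferred flanks, IUPAC `AGCCAATSR`.
  The exact column frequencies of the discovered logo are not numerically
  published, so the consensus string is the model; a `CCAAT`-core-only mode
  exists for scanning the pentanucleotide alone (it is what the worked
  promoter-oligo example uses, where the box appears as `ATTGG` on the
  minus strand).
* **Motif 2** — the classical SOX heptamer `WWCAAWG`.
* **Motif 3** — a dimeric site: the heptamer half, a spacer, and the
  reverse complement of the half. The canonical spacer is 4 bp;
  classification uses the fixed 4-bp spacer, and the wider 2–14 bp range is
  a separate exploratory mode because only the canonical spacing is an
  established binding architecture.

The consensus scanner reports every exact IUPAC match on both strands, with
coordinates always on the forward strand; an `N` in the sequence matches
nothing. It is property-tested against an independent regular-expression
oracle. PWMs derived from a consensus spread a `certainty` mass (default
0.9) over the allowed bases per column. PWM scanning is thresholded on the
exact p-value of the log2-odds score, computed by dynamic programming over
a discretized score grid (10^-3 bits per step; zero-probability cells are
clamped at −100 bits, far below any attainable threshold). The DP is exact
for the discretized scores and is tested against complete enumeration for
widths up to 6. The default hit threshold is p ≤ 1e-4, the standard
default of FIMO-style scanners. Because scores are discrete the achieved
tail probability at the cutoff can be smaller than the nominal threshold;
scanners return it as the `achievedP` attribute and the distributional
tests use it. Note that maximally degenerate short consensi can be
unreachable at a strict PWM threshold (for `WWCAAWG`, the exact-consensus
words already carry 8/4^7 ≈ 4.9e-4 of background mass), which is why
classification scans consensi exactly rather than through the PWM route.

Peak classification scans each peak's full interval sequence (a
summit-window mode is available behind a flag) and assigns one of four
classes: `M1_ONLY`, `M1_AND_SOX` (Motif 1 plus Motif 2 and/or 3),
`SOX_ONLY`, `NONE`.

## The synthetic-data generator

The simulator is first-class, tested code: it defines the study conditions
under which every downstream stage is benchmarked. Defaults: one 2-Mb
chromosome of i.i.d. background at GC 0.41 (the human genome-wide value);
60 genes with 2–5 exons and short (30–80 nt) UTRs, placed at least 4 kb
apart; 30 genes receive a Motif-1 instance whose TSS-proximal edge sits 106
bp upstream of the TSS (the offset of the experimentally validated promoter
CCAAT box); 15 exact Motif-2 heptamers and 15 Motif-3 instances
(half + 4 bp + reverse complement) in intergenic space; a random repeat
track covering 10% of the genome; per-site binding strengths drawn
log-normal (sdlog 0.5) so that the two factors' tag counts co-vary at
co-bound sites. Tags: 40,000 per ChIP factor, of which a fraction
`enrichment` (default 0.5) is site-derived — each site tag picks a bound
site proportionally to strength, jitters the fragment centre with normal
noise (sd 30 bp; the paper is silent on fragment placement, and unimodal
jitter gives well-defined summits), picks a strand uniformly and places the
tag at the fragment's 5' end. The input track is 100,000 tags of pure
background (more than twice the ChIP depth, as in the study). Everything is
reproducible bit-for-bit from the seed.

What the simulator does *not* emulate: mappability structure, PCR
duplicates, sequencing errors, strand-shift asymmetry, diploidy, and any
correlation between repeats and binding. Passing tests therefore certify
the algorithms under clean assumptions, not performance on real libraries.
The fraction of peaks with no motif at all is left as a free parameter
(zero by default) because the in-vivo value is unknown.

One measurement choice deserves emphasis. The classification-recovery
statistic asks whether the class assigned to a peak containing exactly one
planted site *detects* that site's motif class (an M1 site yields
`M1_ONLY` or `M1_AND_SOX`; an M2/M3 site yields `SOX_ONLY` or
`M1_AND_SOX`). Strict four-way identity is not a meaningful target on
i.i.d. background: the degenerate heptamer `WWCAAWG` occurs spuriously
about once per kilobase per strand, so a 300–500 bp peak interval has a
20–40% chance of containing a background SOX-consensus match, and even
summit windows retain a few percent. The pipeline reports the strict class
table as well, but the recovery assertion — and what a synthetic benchmark
can honestly certify — is detection of the planted signal.

## Co-occupancy statistics

The scatter table has one point per factor-A peak (locations with only a
factor-B peak are excluded by construction): tag counts of both factors in
the peak region, raw (a per-million flag is unnecessary here because the
simulator emits equal depths; counts deliberately follow the "number of
tags" convention), plus the peak's motif class. Per-class fits are
unweighted ordinary least squares of A-counts on B-counts with the Pearson
correlation. Overlap statistics count each peak once regardless of partner
multiplicity; "precisely overlapping" conservation across datasets is
operationalized as ≥ 1 bp overlap (no bp threshold is published), with a
`minOverlapFraction` option for stricter readings. The promoter statistic
is the fraction of summits within ±3 kb of any TSS. The conservation
sampler takes whatever peak subset it is given (proximal-promoter category
or 3-kb window — the filter is the caller's choice, since the published
phrasing admits both).

## qPCR arithmetic

Percent input adjusts the input Ct for the input dilution
(`adjusted = mean(ctInput) − log2(1/inputFraction)`; the dilution fraction
is a required argument because no standard value exists) and reports
`100 × 2^(adjusted − mean(ctIp))`, with the replicate SD propagated through
the exponent by the first-order delta method. Relative expression follows
the Livak convention `2^(−ddCt)`; the sign is worth stating because the
shorthand "2^ddCt" that often appears in methods sections would invert
every fold change. The t test is the classic pooled-variance unpaired test
(Welch behind a flag), with stars at p < 0.05 / 0.01 / 0.001; two identical
constant groups return the defined limit t = 0, p = 1.

## Problem sizes, tolerances, degenerate inputs

The test suite and the acceptance script run the default toy scale — 2 Mb,
~140,000 tags per full run, a few seeds — which completes in about two
minutes on one CPU; the simulation sizes were chosen as the smallest at
which every planted site is comfortably detectable (several hundred
site-derived tags per site over a background bin rate of ~3–4). Numerical
choices: Poisson p-values are exact tails clamped below at the smallest
normal double so reported values stay in (0, 1]; PWM p-value discretization
is 1e-3 bits; regression fits with fewer than two points or zero variance
return an explicit undefined sentinel rather than NaN arithmetic; empty
peak lists propagate as empty outputs or NA fractions. Summit ties break
leftmost; top-N peak ranking ties break by p-value, then coordinate.

## Known limitations

The caller has no broad-peak mode, no duplicate-aware lambda correction and
no paired-end support; motif discovery (as opposed to scanning with fixed
models) and motif-to-motif comparison are out of scope; the gene-feature
annotation assumes a flat transcript table rather than a full TxDb; and the
simulator's clean background means measured error rates (e.g. the swap FDR)
are optimistic relative to real chromatin input.
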