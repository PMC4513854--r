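#' @include AllClasses.R motifs.R formats.R
NULL

# Place intervals of the given widths uniformly on the chromosomes, keeping
# `margin` bp clear of every interval in `occupied` (a data.frame with
# chrom/start/end columns) and of the chromosome ends. Plain-vector
# bookkeeping: placement runs in tight loops. Errors when the genome is too
# crowded.
placeIntervals <- function(widths, chromLens, occupied, margin,
                           what = "interval") {
  chromNames <- names(chromLens)
  probs <- chromLens / sum(chromLens)
  oChrom <- occupied$chrom
  oStart <- occupied$start
  oEnd <- occupied$end
  pChrom <- character(length(widths))
  pStart <- integer(length(widths))
  for (k in seq_along(widths)) {
    w <- widths[k]
    placed <- FALSE
    for (attempt in seq_len(200L)) {
      chrom <- if (length(chromNames) == 1L) chromNames
               else sample(chromNames, 1L, prob = probs)
      L <- chromLens[[chrom]]
      if (L < w + 2 * margin + 2) next
      s <- sample.int(L - w - 2L * margin, 1L) + margin
      e <- s + w - 1L
      clash <- any(oChrom == chrom & oStart <= e + margin &
                     oEnd >= s - margin)
      if (!clash) {
        pChrom[k] <- chrom
        pStart[k] <- s
        oChrom <- c(oChrom, chrom)
        oStart <- c(oStart, s)
        oEnd <- c(oEnd, e)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(
        "genome too small to place the requested %ss without overlap", what),
        call. = FALSE)
    }
  }
  list(placed = data.frame(chrom = pChrom, start = pStart,
                           end = pStart + widths - 1L),
       occupied = data.frame(chrom = oChrom, start = oStart, end = oEnd))
}

# Build one random gene model (exon/intron structure + short UTRs) whose
# total genomic length is returned before placement.
randomGeneStructure <- function() {
  nE <- sample(2:5, 1L)
  exLens <- sample(120:400, nE, replace = TRUE)
  inLens <- if (nE > 1L) sample(100:1500, nE - 1L, replace = TRUE)
            else integer(0)
  utr5 <- sample(30:80, 1L)
  utr3 <- sample(30:80, 1L)
  list(exLens = exLens, inLens = inLens, utr5 = utr5, utr3 = utr3,
       totalLen = sum(exLens) + sum(inLens))
}

# Materialize a gene structure at genomic position txStart (1-based) on
# `strand`; returns the gene-table row fields.
materializeGene <- function(struct, chrom, txStart, strand) {
  nE <- length(struct$exLens)
  exS <- integer(nE); exE <- integer(nE)
  pos <- txStart
  for (j in seq_len(nE)) {
    exS[j] <- pos
    exE[j] <- pos + struct$exLens[j] - 1L
    pos <- exE[j] + 1L
    if (j < nE) pos <- pos + struct$inLens[j]
  }
  txEnd <- exE[nE]
  exonic <- unlist(mapply(seq.int, exS, exE, SIMPLIFY = FALSE))
  tot <- length(exonic)
  if (strand == "+") {
    cdsStart <- exonic[struct$utr5 + 1L]
    cdsEnd <- exonic[tot - struct$utr3]
  } else {
    cdsStart <- exonic[struct$utr3 + 1L]
    cdsEnd <- exonic[tot - struct$utr5]
  }
  list(chrom = chrom, strand = strand, txStart = txStart, txEnd = txEnd,
       cdsStart = cdsStart, cdsEnd = cdsEnd, exonStarts = exS,
       exonEnds = exE)
}

#' Generate a synthetic genome with planted binding sites
#'
#' Builds an i.i.d. background genome at the configured GC content, places
#' non-overlapping gene models, plants a CCAAT-box (Motif 1) instance in
#' the proximal promoter of `nCcaatPromoters` genes (the instance ends
#' `siteOffsetUpstream` bp upstream of the TSS, on the gene's strand),
#' plants exact SOX-consensus 7-mers (Motif 2) and dimeric
#' half-site + 4 bp + reverse-complement instances (Motif 3) in intergenic
#' space, and lays down a random repeat track. Motif-1 sites are bound by
#' both factors; Motif-2/3 sites by factor A only. Identical seeds
#' reproduce identical output.
#'
#' @param config a [SimulationConfig-class].
#' @return A list with `genome` (named `DNAStringSet`), `genes` (gene
#'   table), `repeats` (`GRanges`), `truth` (`GRanges` with metadata
#'   `class` in M1/M2/M3, `boundA`, `boundB`, `strength`, `name`) and
#'   `config`.
#' @export
generateGenome <- function(config) {
  validObject(config)
  withSeed(config@seed, {
    baseLen <- floor(config@genomeLength / config@nChroms)
    chromLens <- setNames(rep(as.integer(baseLen), config@nChroms),
                          sprintf("chr%d", seq_len(config@nChroms)))
    chromLens[config@nChroms] <- chromLens[config@nChroms] +
      as.integer(config@genomeLength - baseLen * config@nChroms)
    pBase <- c((1 - config@gc) / 2, config@gc / 2, config@gc / 2,
               (1 - config@gc) / 2)
    chars <- lapply(chromLens, function(L) {
      sample(DNA_BASES, L, replace = TRUE, prob = pBase)
    })

    # --- genes -----------------------------------------------------------
    structs <- lapply(seq_len(config@nGenes), function(i) {
      randomGeneStructure()
    })
    strands <- sample(c("+", "-"), config@nGenes, replace = TRUE)
    margin <- 4000L
    noOcc <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0))
    geneRows <- list()
    if (config@nGenes > 0L) {
      pl <- placeIntervals(vapply(structs,
                                  function(s) as.integer(s$totalLen),
                                  integer(1)),
                           chromLens, noOcc, margin, what = "gene")
      for (i in seq_len(config@nGenes)) {
        geneRows[[i]] <- materializeGene(structs[[i]],
                                         pl$placed$chrom[i],
                                         pl$placed$start[i], strands[i])
      }
    }
    genes <- data.frame(
      name = sprintf("gene_%d", seq_along(geneRows)),
      chrom = vapply(geneRows, `[[`, character(1), "chrom"),
      strand = vapply(geneRows, `[[`, character(1), "strand"),
      txStart = vapply(geneRows, `[[`, integer(1), "txStart"),
      txEnd = vapply(geneRows, `[[`, integer(1), "txEnd"),
      cdsStart = vapply(geneRows, `[[`, integer(1), "cdsStart"),
      cdsEnd = vapply(geneRows, `[[`, integer(1), "cdsEnd"),
      stringsAsFactors = FALSE)
    genes$exonStarts <- lapply(geneRows, `[[`, "exonStarts")
    genes$exonEnds <- lapply(geneRows, `[[`, "exonEnds")
    genes$tss <- ifelse(genes$strand == "+", genes$txStart, genes$txEnd)

    # --- planted sites ---------------------------------------------------
    siteChrom <- character(0); siteStart <- integer(0)
    siteSeq <- character(0); siteStrand <- character(0)
    siteClass <- character(0)
    m1 <- motifCcaatFull()
    m2 <- motifSoxConsensus()
    m3 <- motifSoxDimeric()
    d <- config@siteOffsetUpstream
    if (config@nCcaatPromoters > 0L) {
      pick <- sort(sample.int(nrow(genes), config@nCcaatPromoters))
      for (i in pick) {
        inst <- consensusInstance(m1)
        w <- nchar(inst)
        if (genes$strand[i] == "+") {
          s <- genes$tss[i] - d - w + 1L  # last base d bp upstream of TSS
          planted <- inst
        } else {
          s <- genes$tss[i] + d           # first base d bp upstream (right)
          planted <- revcompChar(inst)
        }
        siteChrom <- c(siteChrom, genes$chrom[i])
        siteStart <- c(siteStart, s)
        siteSeq <- c(siteSeq, planted)
        siteStrand <- c(siteStrand, genes$strand[i])
        siteClass <- c(siteClass, "M1")
      }
    }
    nOther <- config@nSoxSites + config@nDimericSites
    if (nOther > 0L) {
      otherSeqs <- c(
        vapply(seq_len(config@nSoxSites),
               function(i) consensusInstance(m2), character(1)),
        vapply(seq_len(config@nDimericSites),
               function(i) dimericInstance(m3, spacer = 4L), character(1)))
      otherClass <- c(rep("M2", config@nSoxSites),
                      rep("M3", config@nDimericSites))
      # keep clear of genes (plus promoter space) and of other sites
      occ <- data.frame(
        chrom = c(genes$chrom, siteChrom),
        start = c(pmax(genes$txStart - 3000L, 1L), siteStart),
        end = c(genes$txEnd + 3000L,
                siteStart + nchar(siteSeq) - 1L))
      pl <- placeIntervals(nchar(otherSeqs), chromLens, occ, 100L,
                           what = "binding site")
      strandPick <- sample(c("+", "-"), nOther, replace = TRUE)
      for (k in seq_len(nOther)) {
        planted <- if (strandPick[k] == "+") otherSeqs[k]
                   else revcompChar(otherSeqs[k])
        siteChrom <- c(siteChrom, pl$placed$chrom[k])
        siteStart <- c(siteStart, pl$placed$start[k])
        siteSeq <- c(siteSeq, planted)
        siteStrand <- c(siteStrand, strandPick[k])
        siteClass <- c(siteClass, otherClass[k])
      }
    }
    # patch the planted sequences into the background
    for (k in seq_along(siteStart)) {
      idx <- siteStart[k]:(siteStart[k] + nchar(siteSeq[k]) - 1L)
      chars[[siteChrom[k]]][idx] <-
        strsplit(siteSeq[k], "", fixed = TRUE)[[1L]]
    }

    # --- repeat track ----------------------------------------------------
    # random intervals drawn in batches and merged until the requested
    # genome fraction is covered
    repTarget <- config@repeatFraction * sum(chromLens)
    repGr <- GRanges()
    covered <- 0
    while (covered < repTarget && config@repeatFraction > 0) {
      nDraw <- max(5L, as.integer(ceiling((repTarget - covered) / 1100)))
      lens <- sample(200:2000, nDraw, replace = TRUE)
      chrom <- if (length(chromLens) == 1L) rep(names(chromLens), nDraw)
               else sample(names(chromLens), nDraw, replace = TRUE,
                           prob = chromLens / sum(chromLens))
      maxStart <- chromLens[chrom] - lens
      if (any(maxStart < 1L)) { lens <- pmin(lens, chromLens[chrom] - 1L)
                                maxStart <- chromLens[chrom] - lens }
      starts <- floor(runif(nDraw, 1, maxStart + 1))
      batch <- GRanges(chrom, IRanges(as.integer(starts),
                                      width = as.integer(lens)))
      repGr <- reduce(suppressWarnings(c(repGr, batch)))
      covered <- sum(width(repGr))
    }

    # --- assemble --------------------------------------------------------
    genome <- DNAStringSet(vapply(chars, paste, character(1), collapse = ""))
    names(genome) <- names(chromLens)
    si <- Seqinfo(names(chromLens), unname(chromLens))
    truth <- GRanges(siteChrom,
                     IRanges(siteStart, width = nchar(siteSeq)),
                     strand = siteStrand, seqinfo = si)
    truth$class <- siteClass
    truth$boundA <- TRUE
    truth$boundB <- siteClass == "M1"
    truth$strength <- rlnorm(length(truth), 0, config@strengthSdLog)
    truth$name <- sprintf("site_%d", seq_along(truth))
    seqlevels(repGr) <- seqlevels(si)
    seqinfo(repGr) <- si
    list(genome = genome, genes = genes, repeats = repGr, truth = truth,
         config = config)
  })
}

#' Simulate ChIP or input tags over a synthetic genome
#'
#' ChIP factors draw `round(enrichment * n)` tags from planted sites
#' (choosing a site proportionally to its strength among sites bound by the
#' factor), with fragment centres jittered around the site centre by normal
#' noise (`jitterSd`), uniform strand, and the tag placed at the fragment's
#' 5' end (left end for `+`, right end for `-`). Remaining tags — and all
#' input tags — are uniform background with fragments fully inside the
#' chromosome. Deterministic under the per-factor seed.
#'
#' @param sim result of [generateGenome()].
#' @param factor `"A"` (binds all site classes), `"B"` (binds Motif-1 sites
#'   only) or `"input"` (background only).
#' @param n tag count; defaults to the config's `nChipTags`
#'   (`nInputTags` for input).
#' @param seed RNG seed; defaults to the config seed plus a per-factor
#'   offset so the three tracks are independent.
#' @return A width-1 stranded `GRanges` of tags carrying the genome's
#'   seqinfo.
#' @export
simulateTags <- function(sim, factor = c("A", "B", "input"), n = NULL,
                         seed = NULL) {
  factor <- match.arg(factor)
  config <- sim$config
  if (is.null(n)) {
    n <- if (factor == "input") config@nInputTags else config@nChipTags
  }
  n <- as.integer(n)
  if (is.null(seed)) {
    seed <- config@seed + c(A = 101L, B = 202L, input = 303L)[[factor]]
  }
  chromLens <- setNames(width(sim$genome), names(sim$genome))
  si <- Seqinfo(names(chromLens), unname(chromLens))
  fragLen <- config@fragLen
  withSeed(seed, {
    nSite <- if (factor == "input") 0L
             else as.integer(round(config@enrichment * n))
    bound <- if (factor == "B") sim$truth[sim$truth$boundB]
             else sim$truth
    if (nSite > 0L && length(bound) == 0L) {
      stop(sprintf("no sites bound by factor %s", factor), call. = FALSE)
    }
    posList <- list(); strandList <- list(); chromList <- list()
    if (nSite > 0L) {
      pick <- sample.int(length(bound), nSite, replace = TRUE,
                         prob = bound$strength)
      center <- (start(bound) + end(bound)) / 2
      fragCenter <- center[pick] + rnorm(nSite, 0, config@jitterSd)
      l <- round(fragCenter - (fragLen - 1) / 2)
      chrom <- as.character(seqnames(bound))[pick]
      l <- pmin(pmax(l, 1L), chromLens[chrom] - fragLen + 1L)
      strand <- sample(c("+", "-"), nSite, replace = TRUE)
      pos <- ifelse(strand == "+", l, l + fragLen - 1L)
      posList[[1L]] <- as.integer(pos)
      strandList[[1L]] <- strand
      chromList[[1L]] <- chrom
    }
    nBg <- n - nSite
    if (nBg > 0L) {
      chrom <- sample(names(chromLens), nBg, replace = TRUE,
                      prob = chromLens / sum(chromLens))
      l <- floor(runif(nBg, 1, chromLens[chrom] - fragLen + 2))
      strand <- sample(c("+", "-"), nBg, replace = TRUE)
      pos <- ifelse(strand == "+", l, l + fragLen - 1L)
      posList[[length(posList) + 1L]] <- as.integer(pos)
      strandList[[length(strandList) + 1L]] <- strand
      chromList[[length(chromList) + 1L]] <- chrom
    }
    if (n == 0L) {
      return(GRanges(seqinfo = si))
    }
    GRanges(unlist(chromList),
            IRanges(unlist(posList), width = 1L),
            strand = unlist(strandList), seqinfo = si)
  })
}

#' Write a simulation to disk
#'
#' Writes the genome FASTA, gene table TSV, repeat BED3, truth-site TSV and
#' a JSON manifest recording the configuration and all file paths.
#'
#' @param sim result of [generateGenome()].
#' @param dir output directory (created if needed).
#' @param tags optional named list of tag `GRanges` (e.g. `list(A = ...,
#'   B = ..., input = ...)`) written as BED6.
#' @return Named character vector of written paths, invisibly.
#' @export
writeSimulation <- function(sim, dir, tags = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.tsv"),
    repeats = file.path(dir, "repeats.bed"),
    truth = file.path(dir, "truth_sites.tsv"))
  writeGenomeFasta(sim$genome, paths[["genome"]])
  writeGeneTable(sim$genes, paths[["genes"]])
  writeRepeatBed(sim$repeats, paths[["repeats"]])
  writeTruthTable(sim$truth, paths[["truth"]])
  for (nm in names(tags)) {
    p <- file.path(dir, sprintf("tags_%s.bed", nm))
    writeTagsBed(tags[[nm]], p)
    paths[[paste0("tags_", nm)]] <- p
  }
  cfg <- sim$config
  manifest <- list(
    config = list(
      genomeLength = cfg@genomeLength, nChroms = cfg@nChroms, gc = cfg@gc,
      nGenes = cfg@nGenes, nCcaatPromoters = cfg@nCcaatPromoters,
      nSoxSites = cfg@nSoxSites, nDimericSites = cfg@nDimericSites,
      fragLen = cfg@fragLen, readLen = cfg@readLen,
      nChipTags = cfg@nChipTags, nInputTags = cfg@nInputTags,
      enrichment = cfg@enrichment,
      siteOffsetUpstream = cfg@siteOffsetUpstream, jitterSd = cfg@jitterSd,
      repeatFraction = cfg@repeatFraction,
      strengthSdLog = cfg@strengthSdLog, seed = cfg@seed),
    paths = as.list(paths))
  manifestPath <- file.path(dir, "simulation_manifest.json")
  write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA,
             pretty = TRUE)
  paths[["manifest"]] <- manifestPath
  invisible(paths)
}

#' Write / read the truth-site table
#'
#' TSV with 1-based closed coordinates: chrom, start, end, strand, class,
#' boundA, boundB, strength, name.
#'
#' @param truth `GRanges` from [generateGenome()].
#' @param path file path.
#' @return `path` invisibly (writer); `GRanges` (reader).
#' @export
writeTruthTable <- function(truth, path) {
  df <- data.frame(chrom = as.character(seqnames(truth)),
                   start = start(truth), end = end(truth),
                   strand = as.character(strand(truth)),
                   class = truth$class, boundA = truth$boundA,
                   boundB = truth$boundB, strength = truth$strength,
                   name = truth$name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruthTable
#' @export
readTruthTable <- function(path) {
  stopf(file.exists(path), "no such file: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
  gr$class <- df$class
  gr$boundA <- df$boundA
  gr$boundB <- df$boundB
  gr$strength <- df$strength
  gr$name <- df$name
  gr
}
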