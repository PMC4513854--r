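#' @include simulate.R signal-map.R peak-calling.R annotation.R motifs.R
#' @include cooccupancy.R
NULL

PIPELINE_STAGES <- c("simulate", "signal", "callpeaks", "annotate",
                     "scanmotifs", "cooccupancy")

#' Create a pipeline configuration
#'
#' @param outdir output directory.
#' @param sim a [SimulationConfig-class] (used by the `simulate` stage).
#' @param peak a [PeakCallConfig-class].
#' @param motif1,motif2,motif3 motif models used for classification.
#' @param seeds named list of per-stage seeds (`simulate`, `signal`,
#'   `annotate`, `cooccupancy`); stages draw no shared RNG state.
#' @param paths named list of input paths (`genome`, `genes`, `repeats`,
#'   `tagsA`, `tagsB`, `tagsInput`) for runs that start downstream of
#'   `simulate`.
#' @param topN number of top peaks for summit-window extraction.
#' @return A list with class `PipelineConfig`.
#' @export
pipelineConfig <- function(outdir, sim = simulationConfig(),
                           peak = peakCallConfig(),
                           motif1 = motifCcaatFull(),
                           motif2 = motifSoxConsensus(),
                           motif3 = motifSoxDimeric(),
                           seeds = list(simulate = 1L, signal = 2L,
                                        annotate = 3L, cooccupancy = 4L),
                           paths = list(), topN = 1200L) {
  structure(list(outdir = outdir, sim = sim, peak = peak, motif1 = motif1,
                 motif2 = motif2, motif3 = motif3, seeds = seeds,
                 paths = paths, topN = as.integer(topN)),
            class = "PipelineConfig")
}

# Deterministic digest of the scalar configuration (for the manifest).
configDigest <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  sim <- config$sim
  pk <- config$peak
  obj <- list(
    sim = list(sim@genomeLength, sim@nChroms, sim@gc, sim@nGenes,
               sim@nCcaatPromoters, sim@nSoxSites, sim@nDimericSites,
               sim@fragLen, sim@readLen, sim@nChipTags, sim@nInputTags,
               sim@enrichment, sim@siteOffsetUpstream, sim@jitterSd,
               sim@repeatFraction, sim@strengthSdLog, sim@seed),
    peak = list(pk@pCutoff, pk@minFold, pk@mergeGap, pk@localWindows),
    motifs = c(config$motif1@iupac, config$motif2@iupac,
               config$motif3@half@iupac),
    seeds = config$seeds, topN = config$topN)
  writeLines(toJSON(obj, auto_unbox = TRUE, digits = NA), tmp)
  unname(md5sum(tmp))
}

needState <- function(state, keys, stage) {
  for (k in keys) {
    if (!exists(k, envir = state, inherits = FALSE) ||
        is.null(get(k, envir = state))) {
      stop(sprintf(
        "stage '%s' is missing input '%s'; run the earlier stages or provide it via config$paths",
        stage, k), call. = FALSE)
    }
  }
}

# Load whatever inputs config$paths provides into the state.
loadProvidedPaths <- function(state, config) {
  p <- config$paths
  if (!is.null(p$genome) && is.null(state$genome))
    state$genome <- readGenomeFasta(p$genome)
  if (!is.null(p$genes) && is.null(state$genes))
    state$genes <- readGeneTable(p$genes)
  if (!is.null(p$repeats) && is.null(state$repeats))
    state$repeats <- readRepeatBed(p$repeats)
  if (!is.null(p$truth) && is.null(state$truth))
    state$truth <- readTruthTable(p$truth)
  for (nm in c("tagsA", "tagsB", "tagsInput")) {
    if (!is.null(p[[nm]]) && is.null(state[[nm]]))
      state[[nm]] <- readTagsBed(p[[nm]])
  }
  state
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order (`simulate`, `signal`,
#' `callpeaks`, `annotate`, `scanmotifs`, `cooccupancy`); any contiguous
#' suffix can start from files provided in `config$paths`. All results are
#' written under `config$outdir` as TSV/BED/bedGraph/JSON; a JSON run
#' manifest records the configuration digest, seeds and per-stage outputs.
#' Reruns with the same configuration produce byte-identical outputs.
#'
#' @param config a [pipelineConfig()] object.
#' @param stages character vector, an ordered subset of the stage names.
#' @return The manifest (a list), invisibly; written as
#'   `run_manifest.json`.
#' @export
runPipeline <- function(config, stages = PIPELINE_STAGES) {
  stopf(all(stages %in% PIPELINE_STAGES), "unknown stage name")
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  state <- loadProvidedPaths(new.env(parent = emptyenv()), config)
  outputs <- list()
  fragLen <- config$sim@fragLen

  for (stage in stages) {
    message(sprintf("[ChIPcooc] stage: %s", stage))
    t0 <- proc.time()[["elapsed"]]
    switch(stage,
      simulate = {
        simCfg <- config$sim
        if (!is.null(config$seeds$simulate)) {
          simCfg@seed <- as.integer(config$seeds$simulate)
        }
        sim <- generateGenome(simCfg)
        state$genome <- sim$genome
        state$genes <- sim$genes
        state$repeats <- sim$repeats
        state$truth <- sim$truth
        state$tagsA <- simulateTags(sim, "A")
        state$tagsB <- simulateTags(sim, "B")
        state$tagsInput <- simulateTags(sim, "input")
        outputs$simulate <- as.list(writeSimulation(
          sim, file.path(outdir, "simulate"),
          tags = list(A = state$tagsA, B = state$tagsB,
                      input = state$tagsInput)))
      },
      signal = {
        needState(state, c("genome", "tagsA", "tagsB", "tagsInput"),
                  "signal")
        seqlens <- setNames(width(state$genome), names(state$genome))
        state$tagsA <- deduplicateTags(state$tagsA)
        state$tagsB <- deduplicateTags(state$tagsB)
        inp <- deduplicateTags(state$tagsInput)
        nChip <- max(length(state$tagsA), length(state$tagsB))
        if (length(inp) > nChip) {
          inp <- downsampleTags(inp, nChip,
                                seed = config$seeds$signal)
        }
        state$tagsInputMatched <- inp
        state$mapA <- buildSignalMap(state$tagsA, seqlens, fragLen)
        state$mapB <- buildSignalMap(state$tagsB, seqlens, fragLen)
        state$mapInput <- buildSignalMap(inp, seqlens, fragLen)
        dir.create(file.path(outdir, "signal"), showWarnings = FALSE)
        outputs$signal <- list(
          mapA = writeSignalMap(state$mapA,
                                file.path(outdir, "signal", "A.bedGraph")),
          mapB = writeSignalMap(state$mapB,
                                file.path(outdir, "signal", "B.bedGraph")),
          mapInput = writeSignalMap(
            state$mapInput, file.path(outdir, "signal", "input.bedGraph")))
      },
      callpeaks = {
        needState(state, c("mapA", "mapB", "mapInput"), "callpeaks")
        state$peaksA <- callPeaks(state$mapA, state$mapInput, config$peak,
                                  chipTags = state$tagsA)
        state$peaksB <- callPeaks(state$mapB, state$mapInput, config$peak,
                                  chipTags = state$tagsB)
        fdr <- empiricalFdr(state$mapA, state$mapInput, config$peak)
        dir.create(file.path(outdir, "callpeaks"), showWarnings = FALSE)
        pA <- file.path(outdir, "callpeaks", "peaks_A.bed")
        pB <- file.path(outdir, "callpeaks", "peaks_B.bed")
        writePeaksBed(state$peaksA, pA)
        writePeaksBed(state$peaksB, pB)
        statsPath <- file.path(outdir, "callpeaks", "stats.json")
        write_json(list(nPeaksA = length(state$peaksA),
                        nPeaksB = length(state$peaksB),
                        empiricalFdrA = fdr),
                   statsPath, auto_unbox = TRUE, digits = NA)
        outputs$callpeaks <- list(peaksA = pA, peaksB = pB,
                                  stats = statsPath)
      },
      annotate = {
        needState(state, c("peaksA", "genes", "tagsInput", "genome"),
                  "annotate")
        dir.create(file.path(outdir, "annotate"), showWarnings = FALSE)
        td50 <- tssDistances(state$peaksA, state$genes, binWidth = 50L)
        td20 <- tssDistances(state$peaksA, state$genes, binWidth = 20L)
        cats <- classifyLocations(state$peaksA, state$genes)
        dist <- featureDistribution(cats)
        ctrl <- randomControl(
          deduplicateTags(state$tagsInput), state$peaksA,
          n = length(state$peaksA), seed = config$seeds$annotate,
          seqlens = setNames(width(state$genome), names(state$genome)))
        ctrlCats <- classifyLocations(ctrl, state$genes)
        ctrlDist <- featureDistribution(ctrlCats)
        enr <- enrichmentLog2(dist, ctrlDist)
        repPk <- if (!is.null(state$repeats))
          repeatOverlap(state$peaksA, state$repeats) else NULL
        repCt <- if (!is.null(state$repeats))
          repeatOverlap(ctrl, state$repeats) else NULL
        annPath <- file.path(outdir, "annotate", "peak_annotation.tsv")
        write.table(
          data.frame(peak = state$peaksA$name,
                     category = as.character(cats),
                     nearestGene = names(td50$distances),
                     tssDistance = unname(td50$distances)),
          annPath, sep = "\t", quote = FALSE, row.names = FALSE)
        histPath <- file.path(outdir, "annotate", "tss_histogram_50bp.tsv")
        write.table(td50$histogram, histPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        hist20Path <- file.path(outdir, "annotate",
                                "tss_histogram_20bp.tsv")
        write.table(td20$histogram, hist20Path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        distPath <- file.path(outdir, "annotate", "feature_distribution.json")
        enrJson <- lapply(as.list(enr),
                          function(v) if (is.finite(v)) v else NA)
        write_json(list(
          peaks = as.list(categoryCounts(dist)),
          control = as.list(categoryCounts(ctrlDist)),
          log2Enrichment = enrJson,
          repeatOverlapPeaks = as.list(repPk),
          repeatOverlapControl = as.list(repCt)),
          distPath, auto_unbox = TRUE, digits = NA)
        outputs$annotate <- list(annotation = annPath, hist50 = histPath,
                                 hist20 = hist20Path,
                                 distribution = distPath)
        state$controls <- ctrl
      },
      scanmotifs = {
        needState(state, c("peaksA", "genome"), "scanmotifs")
        dir.create(file.path(outdir, "scanmotifs"), showWarnings = FALSE)
        windows <- extractSummitWindows(
          state$peaksA, state$genome,
          topN = min(config$topN, length(state$peaksA)))
        state$classes <- classifyPeaks(state$peaksA, state$genome,
                                       config$motif1, config$motif2,
                                       config$motif3)
        clsPath <- file.path(outdir, "scanmotifs", "peak_classes.tsv")
        write.table(
          data.frame(peak = names(state$classes),
                     class = as.character(state$classes)),
          clsPath, sep = "\t", quote = FALSE, row.names = FALSE)
        winPath <- file.path(outdir, "scanmotifs", "summit_windows.tsv")
        write.table(
          data.frame(peak = mcols(windows)$peak,
                     start = mcols(windows)$start,
                     end = mcols(windows)$end,
                     clipped = mcols(windows)$clipped,
                     sequence = as.character(windows)),
          winPath, sep = "\t", quote = FALSE, row.names = FALSE)
        outputs$scanmotifs <- list(classes = clsPath, windows = winPath)
      },
      cooccupancy = {
        needState(state, c("peaksA", "peaksB", "tagsA", "tagsB", "classes",
                           "genes"), "cooccupancy")
        dir.create(file.path(outdir, "cooccupancy"), showWarnings = FALSE)
        ov <- peakOverlap(state$peaksA, state$peaksB)
        sc <- scatterTable(state$peaksA, state$tagsA, state$tagsB,
                           state$classes, fragLen = fragLen)
        regs <- lapply(levels(state$classes), function(cl) {
          classRegression(sc, cl)
        })
        names(regs) <- levels(state$classes)
        pf <- promoterFraction(state$peaksA, state$genes)
        cons <- conservationFraction(
          state$peaksA, list(state$peaksB),
          nSample = min(100L, length(state$peaksA)),
          seed = config$seeds$cooccupancy)
        scPath <- file.path(outdir, "cooccupancy", "scatter.tsv")
        write.table(sc, scPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        statsPath <- file.path(outdir, "cooccupancy", "stats.json")
        write_json(list(overlap = ov, regressions = regs,
                        promoterFraction = pf,
                        conservation = list(k = unname(cons[["k"]]),
                                            n = unname(cons[["n"]]))),
                   statsPath, auto_unbox = TRUE, digits = NA)
        outputs$cooccupancy <- list(scatter = scPath, stats = statsPath)
      })
    message(sprintf("[ChIPcooc] stage %s done in %.1fs", stage,
                    proc.time()[["elapsed"]] - t0))
  }
  manifest <- list(package = "ChIPcooc",
                   version = as.character(utils::packageVersion("ChIPcooc")),
                   configDigest = configDigest(config),
                   seeds = config$seeds,
                   stages = stages,
                   outputs = outputs)
  write_json(manifest, file.path(outdir, "run_manifest.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
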