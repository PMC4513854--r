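# The synthetic-genome simulator: planted sites, truth table, tag model.

test_that("planted CCAAT promoters appear once per selected gene, bound by both factors", {
  sim <- smallSim(seed = 1)
  m1 <- sim$truth[sim$truth$class == "M1"]
  expect_equal(length(m1), 6L)
  expect_true(all(m1$boundA))
  expect_true(all(m1$boundB))
  # M2/M3 sites are factor-A only
  other <- sim$truth[sim$truth$class != "M1"]
  expect_true(all(other$boundA))
  expect_false(any(other$boundB))
})

test_that("every M1 site sequence contains CCAAT on one strand and sits at the configured TSS offset", {
  sim <- smallSim(seed = 2)
  m1 <- sim$truth[sim$truth$class == "M1"]
  for (i in seq_along(m1)) {
    s <- as.character(subseq(sim$genome[[as.character(seqnames(m1))[i]]],
                             start(m1)[i], end(m1)[i]))
    expect_gte(length(scanConsensus(s, motifCcaatCore())), 1L)
  }
  # offset: nearest site edge is siteOffsetUpstream bp from the TSS
  d <- sim$config@siteOffsetUpstream
  tss <- sim$genes$tss
  names(tss) <- sim$genes$chrom
  for (i in seq_along(m1)) {
    gch <- as.character(seqnames(m1))[i]
    near <- min(abs(outer(c(start(m1)[i], end(m1)[i]),
                          sim$genes$tss[sim$genes$chrom == gch], "-")))
    expect_equal(near, d)
  }
})

test_that("identical seeds reproduce identical genome and truth table", {
  a <- smallSim(seed = 3)
  b <- smallSim(seed = 3)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth, b$truth)
  expect_identical(a$genes, b$genes)
  c <- smallSim(seed = 4)
  expect_false(identical(as.character(a$genome), as.character(c$genome)))
})

test_that("overcrowded genomes are rejected", {
  expect_error(generateGenome(simulationConfig(
    genomeLength = 3e4, nGenes = 20L, nCcaatPromoters = 5L, seed = 1)),
    "too small")
})

test_that("emitted tag counts equal requested counts exactly", {
  sim <- smallSim(seed = 1)
  expect_equal(length(simulateTags(sim, "A")), sim$config@nChipTags)
  expect_equal(length(simulateTags(sim, "B")), sim$config@nChipTags)
  expect_equal(length(simulateTags(sim, "input")), sim$config@nInputTags)
  expect_equal(length(simulateTags(sim, "A", n = 123)), 123L)
})

test_that("enrichment = 0 yields pure background at the exact count", {
  sim0 <- generateGenome(simulationConfig(
    genomeLength = 4e5, nGenes = 10L, nCcaatPromoters = 6L,
    nSoxSites = 4L, nDimericSites = 3L, nChipTags = 5000L,
    enrichment = 0, seed = 5))
  tags <- simulateTags(sim0, "A")
  expect_equal(length(tags), 5000L)
  # no excess density at sites: site-window tag fraction consistent with
  # the window's genome fraction
  win <- suppressWarnings(resize(granges(sim0$truth), 400, fix = "center"))
  inWin <- sum(countOverlaps(tags, win, ignore.strand = TRUE) > 0)
  pWin <- sum(width(reduce(win))) / sum(width(sim0$genome))
  expect_gt(binom.test(inWin, 5000, pWin)$p.value, 1e-4)
})

test_that("factor B errors when no B-bound sites exist", {
  simNoM1 <- generateGenome(simulationConfig(
    genomeLength = 3e5, nGenes = 5L, nCcaatPromoters = 0L,
    nSoxSites = 3L, nDimericSites = 2L, seed = 6))
  expect_error(simulateTags(simNoM1, "B"), "no sites bound")
})

test_that("fragment midpoints concentrate on the site center (law of large numbers)", {
  sim1 <- generateGenome(simulationConfig(
    genomeLength = 1e5, nGenes = 1L, nCcaatPromoters = 1L,
    nSoxSites = 0L, nDimericSites = 0L, nChipTags = 10000L,
    enrichment = 1, seed = 7))
  tags <- simulateTags(sim1, "A")
  expect_equal(length(tags), 10000L)
  frag <- sim1$config@fragLen
  mid <- ifelse(as.character(strand(tags)) == "+",
                start(tags) + (frag - 1) / 2,
                start(tags) - (frag - 1) / 2)
  center <- (start(sim1$truth) + end(sim1$truth)) / 2
  expect_lt(abs(mean(mid) - center), 3 * sim1$config@jitterSd / sqrt(10000))
})

test_that("ChIP tag density at sites exceeds background density", {
  run <- toyRun(1)
  sim <- run$sim
  win <- suppressWarnings(resize(granges(sim$truth), 400, fix = "center"))
  nA <- length(run$tagsA)
  inWin <- sum(countOverlaps(run$tagsA, win, ignore.strand = TRUE) > 0)
  pWin <- sum(width(reduce(win))) / sum(width(sim$genome))
  bt <- binom.test(inWin, nA, pWin, alternative = "greater")
  expect_lt(bt$p.value, 0.01)
  # input is background only: its window fraction matches the genome
  # fraction
  nI <- length(run$tagsInput)
  inWinI <- sum(countOverlaps(run$tagsInput, win, ignore.strand = TRUE) > 0)
  expect_gt(binom.test(inWinI, nI, pWin)$p.value, 1e-4)
})

test_that("planted motif instances are rediscovered at exact coordinates by the scanners", {
  run <- toyRun(1)
  sim <- run$sim
  h1 <- scanConsensus(sim$genome, motifCcaatFull())
  h2 <- scanConsensus(sim$genome, motifSoxConsensus())
  h3 <- scanDimeric(sim$genome, motifSoxDimeric())
  for (cls in c("M1", "M2", "M3")) {
    tr <- sim$truth[sim$truth$class == cls]
    hits <- switch(cls, M1 = h1, M2 = h2, M3 = h3)
    found <- countOverlaps(tr, hits, type = "equal",
                           ignore.strand = TRUE) > 0
    expect_true(all(found), label = sprintf("class %s round trip", cls))
  }
})

test_that("writeSimulation round-trips genome, genes, truth and tags", {
  sim <- smallSim(seed = 1)
  tags <- simulateTags(sim, "A", n = 500)
  dir <- withr::local_tempdir()
  paths <- writeSimulation(sim, dir, tags = list(A = tags))
  g <- readGenomeFasta(paths[["genome"]])
  expect_identical(as.character(g), as.character(sim$genome))
  genes <- readGeneTable(paths[["genes"]])
  expect_equal(genes$tss, sim$genes$tss)
  truth <- readTruthTable(paths[["truth"]])
  expect_equal(start(truth), start(sim$truth))
  expect_equal(truth$class, sim$truth$class)
  tagsBack <- readTagsBed(paths[["tags_A"]])
  expect_equal(start(tagsBack), start(tags))
  expect_equal(as.character(strand(tagsBack)), as.character(strand(tags)))
  expect_true(file.exists(paths[["manifest"]]))
})
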