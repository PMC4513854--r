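# TSS distances, nine-category classification, random control, enrichment.

test_that("TSS distances are signed in transcript orientation", {
  genes <- rbind(makeGene("gp", "chr1", "+", 10000, 12000),
                 makeGene("gm", "chr2", "-", 8000, 10000))
  pk <- makePeaks(c("chr1", "chr2"), c(9900, 10000), c(9999, 10100),
                  summit = c(9950, 10050))
  d <- tssDistances(pk, genes)$distances
  expect_equal(unname(d[1]), -50)  # upstream of a + TSS
  expect_equal(unname(d[2]), -50)  # + strand coordinate 10050, - gene TSS 10000
  expect_equal(names(d), c("gp", "gm"))
})

test_that("TSS-distance histogram bins follow the [0, binWidth) convention", {
  genes <- makeGene("g", "chr1", "+", 1000, 3000)
  pk <- makePeaks("chr1", c(985, 965, 965), c(995, 975, 975),
                  summit = c(990, 970, 970))  # distances -10, -30, -30
  h <- tssDistances(pk, genes, binWidth = 20L)$histogram
  expect_equal(h$count[h$binStart == -40], 2L)
  expect_equal(h$count[h$binStart == -20], 1L)
  # empty peak list gives empty outputs
  e <- tssDistances(makePeaks(character(0), integer(0), integer(0),
                              integer(0)), genes)
  expect_equal(length(e$distances), 0L)
  expect_equal(nrow(e$histogram), 0L)
})

test_that("summit classification matches the nine-category definitions", {
  # + gene 5000..9000, exons [5000,5500] and [8500,9000], CDS 5200..8800
  genes <- makeGene("g", "chr1", "+", 5000, 9000, 5200, 8800,
                    exonStarts = c(5000, 8500), exonEnds = c(5500, 9000))
  classify1 <- function(summit) {
    as.character(classifyLocations(
      makePeaks("chr1", summit - 10, summit + 10, summit), genes))
  }
  expect_equal(classify1(4500), "proximal_promoter")   # 500 bp upstream
  expect_equal(classify1(3500), "distal_promoter")     # 1.5 kb upstream
  expect_equal(classify1(5100), "utr5")                # exon, before CDS
  expect_equal(classify1(5300), "exon")                # inside CDS exon
  expect_equal(classify1(7000), "intron")
  expect_equal(classify1(8900), "utr3")                # exon, past CDS
  expect_equal(classify1(9500), "proximal_downstream") # 500 bp past end
  expect_equal(classify1(11000), "distal_downstream")  # 2 kb past end
  expect_equal(classify1(14000), "distal_intergenic")
})

test_that("minus-strand genes mirror the classification and the literal TSS-downstream flag works", {
  genes <- makeGene("g", "chr1", "-", 5000, 9000, 5200, 8800,
                    exonStarts = c(5000, 8500), exonEnds = c(5500, 9000))
  classify1 <- function(summit, ...) {
    as.character(classifyLocations(
      makePeaks("chr1", summit - 10, summit + 10, summit), genes, ...))
  }
  expect_equal(classify1(9500), "proximal_promoter")  # upstream = right side
  expect_equal(classify1(8900), "utr5")
  expect_equal(classify1(5100), "utr3")
  expect_equal(classify1(4500), "proximal_downstream")
  # literal reading: windows downstream of the TSS itself
  expect_equal(classify1(4500, downstreamOf = "tss"), "distal_intergenic")
})

test_that("classification is total and distributions are consistent", {
  run <- toyRun(1)
  cats <- classifyLocations(run$peaksA, run$sim$genes)
  expect_false(any(is.na(cats)))
  dist <- featureDistribution(cats)
  expect_equal(sum(categoryCounts(dist)), length(run$peaksA))
  expect_equal(sum(categoryPercent(dist)), 100, tolerance = 0.01)
})

test_that("random controls resample input-tag positions with peak widths", {
  run <- toyRun(1)
  ctrl <- randomControl(run$tagsInput, run$peaksA, n = 200, seed = 1,
                        seqlens = run$seqlens)
  expect_equal(length(ctrl), 200L)
  expect_true(all(ctrl$summit %in% start(run$tagsInput)))
  expect_true(all(width(ctrl) %in% width(run$peaksA)))
  # deterministic under seed
  ctrl2 <- randomControl(run$tagsInput, run$peaksA, n = 200, seed = 1,
                         seqlens = run$seqlens)
  expect_identical(start(ctrl), start(ctrl2))
  expect_error(randomControl(run$tagsInput, run$peaksA,
                             n = length(run$tagsInput) + 1),
               "exceeds")
  # on this gene-sparse genome uniform controls are mostly intergenic
  cats <- classifyLocations(ctrl, run$sim$genes)
  expect_equal(names(which.max(table(cats))), "distal_intergenic")
})

test_that("log2 enrichment reproduces the hallmark promoter and UTR ratios", {
  mk <- function(counts) {
    x <- setNames(integer(9), featureCategories())
    x[names(counts)] <- counts
    new("FeatureDistribution", counts = x, total = sum(x))
  }
  # 25% vs 2% proximal promoter
  a <- mk(c(proximal_promoter = 250L, distal_intergenic = 750L))
  b <- mk(c(proximal_promoter = 20L, distal_intergenic = 980L))
  enr <- enrichmentLog2(a, b)
  expect_equal(unname(enr["proximal_promoter"]), log2(25 / 2),
               tolerance = 1e-12)
  expect_equal(round(unname(enr["proximal_promoter"]), 2), 3.64)
  # 10% vs 0.2% 5' UTR
  a2 <- mk(c(utr5 = 100L, distal_intergenic = 900L))
  b2 <- mk(c(utr5 = 2L, distal_intergenic = 998L))
  expect_equal(round(unname(enrichmentLog2(a2, b2)["utr5"]), 2), 5.64)
  # identical distributions are flat
  expect_true(all(enrichmentLog2(a, a)[categoryCounts(a) > 0] == 0))
  # sentinels
  z <- enrichmentLog2(a, mk(c(distal_intergenic = 1000L)))
  expect_true(is.infinite(z["proximal_promoter"]))
  expect_true(is.nan(z["utr5"]))
})

test_that("repeat overlap counts respect interval boundaries", {
  rep1 <- GRanges("chr1", IRanges(151, 160))
  pk <- makePeaks("chr1", 101, 200, 150)
  expect_equal(unname(repeatOverlap(pk, rep1)["nOverlapping"]), 1L)
  # abutting interval (starts where the peak ends + 1) does not overlap
  rep2 <- GRanges("chr1", IRanges(201, 210))
  expect_equal(unname(repeatOverlap(pk, rep2)["nOverlapping"]), 0L)
})

test_that("control repeat-overlap fractions are reproducible across draws", {
  run <- toyRun(1)
  frac <- function(seed) {
    ctrl <- randomControl(run$tagsInput, run$peaksA, n = 1000, seed = seed,
                          seqlens = run$seqlens)
    ov <- repeatOverlap(ctrl, run$sim$repeats)
    ov[["nOverlapping"]] / ov[["nTotal"]]
  }
  f1 <- frac(1); f2 <- frac(2)
  p <- (f1 + f2) / 2
  sigma <- sqrt(2 * p * (1 - p) / 1000)
  expect_lt(abs(f1 - f2), 4 * sigma)
})

test_that("a random control is not enriched against an independent control", {
  run <- toyRun(1)
  n <- 5000L
  d1 <- featureDistribution(classifyLocations(
    randomControl(run$tagsInput, run$peaksA, n, seed = 11,
                  seqlens = run$seqlens), run$sim$genes))
  d2 <- featureDistribution(classifyLocations(
    randomControl(run$tagsInput, run$peaksA, n, seed = 22,
                  seqlens = run$seqlens), run$sim$genes))
  enr <- enrichmentLog2(d1, d2)
  expected <- (categoryCounts(d1) + categoryCounts(d2)) / 2
  keep <- expected >= 20
  expect_gt(sum(keep), 0)
  expect_true(all(abs(enr[keep]) <= 0.5))
})
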