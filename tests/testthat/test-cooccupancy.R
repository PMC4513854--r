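# Two-factor overlap, tag-count scatter, per-class regression, conservation.

grOf <- function(start, end, chrom = "chr1") {
  GRanges(chrom, IRanges(start, end))
}

test_that("peak overlap follows closed-interval intersection rules", {
  r <- peakOverlap(grOf(101, 200), grOf(151, 250))
  expect_equal(r$nAWithB, 1L)
  expect_equal(r$nBWithA, 1L)
  # abutting intervals (B starts right after A ends) do not overlap
  r2 <- peakOverlap(grOf(101, 200), grOf(201, 300))
  expect_equal(r2$nAWithB, 0L)
  expect_equal(r2$nBWithA, 0L)
  # one A peak spanning two B peaks counts once on the A side
  r3 <- peakOverlap(grOf(101, 400), grOf(c(120, 300), c(160, 350)))
  expect_equal(r3$nAWithB, 1L)
  expect_equal(r3$nBWithA, 2L)
})

test_that("peak overlap is symmetric under argument swap", {
  set.seed(21)
  sa <- sort(sample.int(9000, 40))
  sb <- sort(sample.int(9000, 30))
  a <- grOf(sa, sa + 150)
  b <- grOf(sb, sb + 200)
  r <- peakOverlap(a, b)
  rs <- peakOverlap(b, a)
  expect_equal(r$nAWithB, rs$nBWithA)
  expect_equal(r$nBWithA, rs$nAWithB)
})

test_that("scatter table has one point per factor-A peak", {
  pk <- makePeaks("chr1", c(100, 500, 900), c(200, 600, 1000),
                  summit = c(150, 550, 950))
  tagsA <- GRanges("chr1", IRanges(c(120, 520, 920), width = 1),
                   strand = "+")
  classes <- factor(setNames(c("M1_ONLY", "SOX_ONLY", "NONE"), pk$name),
                    levels = c("M1_ONLY", "M1_AND_SOX", "SOX_ONLY", "NONE"))
  # no factor-B tags anywhere: tagsB all zero
  sc <- scatterTable(pk, tagsA, GRanges(), classes)
  expect_equal(nrow(sc), 3L)
  expect_true(all(sc$tagsB == 0))
  expect_equal(sc$tagsA, c(1L, 1L, 1L))
  # a peak without a class is rejected
  expect_error(scatterTable(pk, tagsA, GRanges(), classes[1:2]), "class")
})

test_that("regression matches the closed-form least squares", {
  # exact line y = 2x + 1
  pts <- data.frame(peak = letters[1:4], tagsA = c(3, 5, 7, 9),
                    tagsB = c(1, 2, 3, 4), class = "M1_ONLY")
  fit <- classRegression(pts, "M1_ONLY")
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  # closed form on a hand-built 3-point case
  x <- c(1, 4, 6); y <- c(2, 3, 9)
  pts2 <- data.frame(peak = letters[1:3], tagsA = y, tagsB = x,
                     class = "C")
  fit2 <- classRegression(pts2, "C")
  slopeCF <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit2$slope, slopeCF, tolerance = 1e-12)
  expect_equal(fit2$intercept, mean(y) - slopeCF * mean(x),
               tolerance = 1e-12)
  rCF <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(fit2$r, rCF, tolerance = 1e-12)
  # undefined-fit sentinels
  expect_false(classRegression(pts2[1, ], "C")$defined)
  pts3 <- pts2; pts3$tagsB <- 5
  expect_false(classRegression(pts3, "C")$defined)
})

test_that("regression recovers a planted slope and rejects spurious correlation", {
  set.seed(1)
  n <- 500
  x <- runif(n, 0, 100)
  yNull <- runif(n, 0, 100)
  ptsNull <- data.frame(peak = seq_len(n), tagsA = yNull, tagsB = x,
                        class = "C")
  expect_lt(abs(classRegression(ptsNull, "C")$r), 0.15)
  y <- 1.5 * x + rnorm(n, 0, 0.1 * 150)
  pts <- data.frame(peak = seq_len(n), tagsA = y, tagsB = x, class = "C")
  fit <- classRegression(pts, "C")
  expect_gte(fit$slope, 1.35)
  expect_lte(fit$slope, 1.65)
})

test_that("promoter fraction counts summits near any TSS", {
  genes <- rbind(makeGene("g1", "chr1", "+", 10000, 15000),
                 makeGene("g2", "chr1", "-", 30000, 35000))
  pk <- makePeaks("chr1", c(8000, 9500, 11000, 20000),
                  c(8200, 9700, 11200, 20200),
                  summit = c(8100, 9600, 11100, 20100))
  expect_equal(promoterFraction(pk, genes, window = 3000), 0.75)
  # window 0: only a summit exactly at a TSS counts
  pk0 <- makePeaks("chr1", c(9990, 9995), c(10010, 10005),
                   summit = c(10000, 10002))
  expect_equal(promoterFraction(pk0, genes, window = 0), 0.5)
  # window spanning the genome: everything counts
  expect_equal(promoterFraction(pk, genes, window = 1e9), 1)
  expect_true(is.na(promoterFraction(makePeaks(character(0), integer(0),
                                               integer(0), integer(0)),
                                     genes)))
})

test_that("conservation sampling counts peaks overlapping every provided set", {
  pk <- makePeaks("chr1", seq(1000, 10000, by = 1000),
                  seq(1200, 10200, by = 1000),
                  summit = seq(1100, 10100, by = 1000))
  r <- conservationFraction(pk, list(pk, pk), nSample = 5, seed = 1)
  expect_equal(unname(r["k"]), 5L)
  expect_equal(unname(r["n"]), 5L)
  # one empty set: nothing is conserved
  r0 <- conservationFraction(pk, list(pk, GRanges()), nSample = 5,
                             seed = 1)
  expect_equal(unname(r0["k"]), 0L)
  expect_error(conservationFraction(pk, list(), nSample = 5), "non-empty")
  expect_error(conservationFraction(pk, list(pk), nSample = 100), "exceeds")
  # the stricter minimum-overlap-fraction reading
  shifted <- GenomicRanges::shift(pk, 190)  # ~5% overlap of each 201-bp peak
  rLoose <- conservationFraction(pk, list(shifted), nSample = 10, seed = 1)
  rStrict <- conservationFraction(pk, list(shifted), nSample = 10, seed = 1,
                                  minOverlapFraction = 0.5)
  expect_equal(unname(rLoose["k"]), 10L)
  expect_equal(unname(rStrict["k"]), 0L)
})

test_that("co-bound sites make factor-A peaks conserved across B-like replicates", {
  run <- toyRun(1)
  sim <- run$sim
  seqlens <- run$seqlens
  # three replicate factor-B datasets: same genome, fresh tag draws
  repSets <- lapply(c(31L, 32L, 33L), function(s) {
    tb <- deduplicateTags(simulateTags(sim, "B", seed = s))
    mb <- buildSignalMap(tb, seqlens)
    callPeaks(mb, run$mapInput, chipTags = tb)
  })
  # restrict to factor-A peaks at co-bound (M1) sites
  m1sites <- sim$truth[sim$truth$boundB]
  aAtM1 <- run$peaksA[countOverlaps(run$peaksA, m1sites,
                                    ignore.strand = TRUE) > 0]
  expect_gt(length(aAtM1), 10L)
  r <- conservationFraction(aAtM1, repSets,
                            nSample = min(25L, length(aAtM1)), seed = 1)
  expect_gte(r[["k"]] / r[["n"]], 0.9)
})
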