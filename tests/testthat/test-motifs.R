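# Consensus / PWM / dimeric motif scanning and peak classification.

test_that("consensus scanning matches the exhaustive oracle on the validated promoter oligos", {
  wt <- "TCCCGCCTCCCTAACCTGATTGGTTTATTCAAACAAACC"
  mut <- "TCCCGCCTCCCTAACCTGTTTGGTTTATTCAAACAAACC"
  # the two oligos differ at exactly one position
  expect_equal(sum(strsplit(wt, "")[[1]] != strsplit(mut, "")[[1]]), 1L)
  h <- scanConsensus(wt, motifCcaatCore())
  expect_equal(length(h), 1L)
  expect_equal(as.character(strand(h)), "-")
  expect_equal(start(h), 19L)  # 0-based 18..22: the ATTGG box
  expect_equal(end(h), 23L)
  expect_equal(h$match, "ATTGG")
  expect_equal(length(scanConsensus(mut, motifCcaatCore())), 0L)
  # oracle: all 5-mers compared by hand against CCAAT/ATTGG
  k <- nchar(wt) - 5L + 1L
  fwd <- vapply(seq_len(k), function(i) substr(wt, i, i + 4L) == "CCAAT",
                logical(1))
  rvs <- vapply(seq_len(k), function(i) substr(wt, i, i + 4L) == "ATTGG",
                logical(1))
  expect_equal(sum(fwd) + sum(rvs), 1L)
  expect_equal(which(rvs), 19L)
})

test_that("direct consensus instances are found with documented coordinates", {
  h <- scanConsensus("AACAATG", motifSoxConsensus(), bothStrands = FALSE)
  expect_equal(length(h), 1L)
  expect_equal(start(h), 1L)
  expect_equal(as.character(strand(h)), "+")
  expect_error(scanConsensus("ACGT", consensusMotif("AXC")), "IUPAC")
})

test_that("consensus scanner agrees with Biostrings matchPattern on random sequences", {
  set.seed(101)
  motifs <- c("CCAAT", "WWCAAWG", "AGCCAATSR", "RYSWKM", "ACGT", "NNCGNN")
  for (rep in seq_len(200)) {
    seq <- randomSeq(sample(50:300, 1), withN = rep %% 3 == 0)
    iupac <- sample(motifs, 1)
    mine <- scanConsensus(seq, consensusMotif(iupac))
    fwdOracle <- oracleConsensusStarts(seq, iupac)
    rvsOracle <- oracleConsensusStarts(
      seq, as.character(reverseComplement(DNAString(iupac))))
    expect_identical(start(mine[strand(mine) == "+"]), fwdOracle)
    expect_identical(start(mine[strand(mine) == "-"]), rvsOracle)
  }
})

test_that("reverse-complement symmetry: forward hits mirror on the reverse complement", {
  set.seed(102)
  for (rep in seq_len(20)) {
    seq <- randomSeq(200)
    n <- nchar(seq)
    motif <- consensusMotif("WWCAAWG")
    w <- motifWidth(motif)
    h <- scanConsensus(seq, motif)
    hRc <- scanConsensus(as.character(reverseComplement(DNAString(seq))),
                         motif)
    plus <- start(h[strand(h) == "+"])
    minusOnRc <- start(hRc[strand(hRc) == "-"])
    expect_setequal(plus, sort(n - w + 2L - minusOnRc))
  }
})

test_that("PWM construction from consensus distributes certainty mass", {
  expect_equal(unname(pwmFromConsensus(consensusMotif("A"),
                                       certainty = 1)@mat[, 1]),
               c(1, 0, 0, 0))
  expect_equal(unname(pwmFromConsensus(consensusMotif("W"),
                                       certainty = 0.9)@mat[, 1]),
               c(0.45, 0.05, 0.05, 0.45))
  expect_equal(unname(pwmFromConsensus(consensusMotif("N"),
                                       certainty = 0.7)@mat[, 1]),
               rep(0.25, 4))
  expect_true(all(abs(colSums(pwmFromConsensus(
    motifCcaatFull())@mat) - 1) < 1e-12))
})

test_that("pwmPvalue closed forms hold at width 1 and for uniform PWMs", {
  m <- pwmFromConsensus(consensusMotif("A"), certainty = 1)
  expect_equal(pwmPvalue(m, log2(1 / 0.25)), 0.25)
  u <- pwmFromConsensus(consensusMotif("NNN"), certainty = 0.5)
  expect_equal(pwmPvalue(u, 0), 1)
})

test_that("pwmPvalue equals brute-force enumeration for widths <= 6", {
  bases <- c("A", "C", "G", "T")
  gran <- 1e-3
  cases <- list(
    list(iupac = "CCAAT", certainty = 0.9),   # the CCAAT-derived PWM
    list(iupac = "WWCA", certainty = 0.85),
    list(iupac = "RYSWKM", certainty = 0.8),
    list(iupac = "ACG", certainty = 1.0),
    list(iupac = "NWSA", certainty = 0.75))
  for (cs in cases) {
    pwm <- pwmFromConsensus(consensusMotif(cs$iupac),
                            certainty = cs$certainty)
    w <- motifWidth(pwm)
    words <- as.matrix(do.call(expand.grid,
                               c(rep(list(bases), w),
                                 stringsAsFactors = FALSE)))
    # independent enumeration over all 4^w words on the same score grid
    # the DP uses (scores rounded to 1e-3 bits, zero columns clamped)
    S <- log2(pwm@mat / pwm@background)
    S[!is.finite(S)] <- -100
    S <- round(S / gran)
    wordScore <- vapply(seq_len(nrow(words)), function(i) {
      sum(vapply(seq_len(w), function(j) S[words[i, j], j], numeric(1)))
    }, numeric(1))
    pWord <- 0.25^w
    thr <- unique(quantile(wordScore, c(0, 0.25, 0.5, 0.9, 1), type = 1))
    for (t in thr) {
      brute <- sum(pWord * (wordScore >= t))
      expect_equal(pwmPvalue(pwm, t * gran), brute, tolerance = 1e-6)
    }
    # and the exhaustive tail at the exact-consensus (maximum) score
    expect_equal(pwmPvalue(pwm, max(wordScore) * gran),
                 mean(wordScore == max(wordScore)), tolerance = 1e-6)
  }
})

test_that("scanPwm finds planted instances and saturates at p = 1", {
  set.seed(104)
  bg <- randomSeq(400)
  inst <- consensusInstance(motifSoxConsensus(), seed = 9)
  seq <- paste0(substr(bg, 1, 200), inst, substr(bg, 201, 400))
  pwm <- pwmFromConsensus(motifSoxConsensus(), certainty = 0.9)
  hits <- scanPwm(seq, pwm, pThreshold = 5e-4)
  expect_true(201L %in% start(hits))
  # p = 1: a hit at every N-free position on each strand
  short <- "ACGTACGTAC"
  all1 <- scanPwm(short, pwm, pThreshold = 1)
  expect_equal(length(all1), 2L * (nchar(short) - motifWidth(pwm) + 1L))
  # N windows are skipped
  withN <- scanPwm("ACGNACGTACGT", pwm, pThreshold = 1)
  expect_true(all(start(withN) > 4L))
})

test_that("scanPwm hit counts on background follow the achieved p-value", {
  set.seed(105)
  seq <- randomSeq(100000)
  pwm <- pwmFromConsensus(motifSoxConsensus(), certainty = 0.9)
  hits <- scanPwm(seq, pwm, pThreshold = 1e-4)
  pAch <- attr(hits, "achievedP")
  expect_lte(pAch, 1e-4)
  nPos <- nchar(seq) - motifWidth(pwm) + 1L
  expected <- 2 * pAch * nPos
  expect_lt(abs(length(hits) - expected), 4 * sqrt(expected) + 1)
})

test_that("dimeric scanning requires the inverted repeat at an allowed spacer", {
  site <- paste0("AACAATG", "GGGG", "CATTGTT")
  h <- scanDimeric(site, motifSoxDimeric(spacerMin = 2, spacerMax = 14))
  expect_equal(length(h), 1L)
  expect_equal(h$spacer, 4L)
  expect_equal(start(h), 1L)
  expect_equal(width(h), 18L)
  # a 15-bp spacer falls outside the 2-14 range
  far <- paste0("AACAATG", strrep("G", 15), "CATTGTT")
  expect_equal(length(scanDimeric(
    far, motifSoxDimeric(spacerMin = 2, spacerMax = 14))), 0L)
  # the half-site alone is not a dimeric hit
  expect_equal(length(scanDimeric("AACAATG", motifSoxDimeric())), 0L)
})

test_that("summit windows are 50 bp, clipped at edges, and ranked by tag count", {
  genome <- DNAStringSet(c(chr1 = randomSeq(2000, seed = 106)))
  pk <- makePeaks("chr1", c(900, 1, 300, 500, 700),
                  c(1100, 60, 400, 600, 800),
                  summit = c(1000, 11, 350, 550, 750),
                  tagCount = c(50, 10, 40, 30, 20))
  win <- extractSummitWindows(pk, genome)
  expect_equal(width(win)[1], 50L)
  expect_equal(mcols(win)$start[1], 975L)  # 0-based [975, 1025)
  expect_equal(mcols(win)$end[1], 1024L)
  expect_false(mcols(win)$clipped[1])
  # summit near the edge: clipped to 35 bases
  expect_equal(width(win)[2], 35L)
  expect_equal(mcols(win)$start[2], 1L)
  expect_true(mcols(win)$clipped[2])
  # the window sequence is the genomic subsequence
  expect_equal(as.character(win[[1]]),
               as.character(subseq(genome[[1]], 975, 1024)))
  # topN keeps the highest-count peaks
  top <- extractSummitWindows(pk, genome, topN = 3)
  expect_equal(mcols(top)$peak, pk$name[order(-pk$tagCount)][1:3])
})

test_that("peak classification assigns the four classes by motif content", {
  # scaffold built from an ACG repeat, which provably contains none of the
  # motifs (no CCAAT/ATTGG, no CAA preceded by two A/T, no TT at all)
  pad <- function(n) substr(strrep("ACG", ceiling(n / 3) + 1L), 1L, n)
  m1i <- "AGCCAATCA"
  m2i <- "AACAATG"
  chr <- paste0(pad(50), m1i,                  # 51-59:   peak 1, M1 only
                pad(90), m1i, "GGGG", m2i,     # 150-169: peak 2, M1 + SOX
                pad(90), m2i,                  # 260-266: peak 3, SOX only
                pad(145))                      # tail:    peak 4, none
  genome <- DNAStringSet(c(chr1 = chr))
  pk <- makePeaks("chr1", c(41, 141, 251, 321), c(80, 180, 290, 345),
                  summit = c(55, 160, 260, 330))
  cls <- classifyPeaks(pk, genome)
  expect_equal(as.character(cls),
               c("M1_ONLY", "M1_AND_SOX", "SOX_ONLY", "NONE"))
  expect_equal(names(cls), pk$name)
  # summit-window mode classifies the same construction
  cls2 <- classifyPeaks(pk, genome, region = "summit")
  expect_equal(as.character(cls2)[c(1, 4)], c("M1_ONLY", "NONE"))
})

test_that("MEME minimal format round-trips PWMs", {
  pwms <- list(pwmFromConsensus(motifCcaatFull(), certainty = 0.9),
               pwmFromConsensus(motifSoxConsensus(), certainty = 0.85))
  f <- withr::local_tempfile(fileext = ".meme")
  writeMemeMotif(pwms, f)
  back <- readMemeMotif(f)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]@mat, pwms[[1]]@mat, tolerance = 1e-5)
  expect_equal(back[[2]]@mat, pwms[[2]]@mat, tolerance = 1e-5)
  expect_equal(names(back), c(pwms[[1]]@name, pwms[[2]]@name))
})

test_that("motif instance samplers produce matching instances", {
  set.seed(108)
  for (i in 1:20) {
    inst <- consensusInstance(motifCcaatFull())
    expect_equal(length(scanConsensus(inst, motifCcaatFull(),
                                      bothStrands = FALSE)), 1L)
    di <- dimericInstance(motifSoxDimeric(), spacer = 4)
    expect_equal(nchar(di), 18L)
    h <- scanDimeric(di, motifSoxDimeric())
    expect_gte(length(h), 1L)
    expect_true(4L %in% h$spacer)
  }
})
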