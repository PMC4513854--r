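#' @include AllClasses.R AllGenerics.R
NULL

# Positions (1-based) where an IUPAC consensus matches the encoded sequence
# exactly. `enc` is the integer encoding from encodeDNA(); NA (N or other)
# never matches.
consensusPositions <- function(enc, iupacChars) {
  w <- length(iupacChars)
  n <- length(enc)
  if (n < w) return(integer(0))
  allowed <- lapply(iupacChars, function(ch) {
    DNA_BASES %in% IUPAC_MAP[[ch]]
  })
  ok <- rep(TRUE, n - w + 1L)
  for (j in seq_len(w)) {
    bases <- enc[j:(n - w + j)]
    okj <- allowed[[j]][bases]   # NA base -> NA
    okj[is.na(okj)] <- FALSE
    ok <- ok & okj
  }
  which(ok)
}

# Accept either a DNAStringSet/named character vector of sequences, or a
# single string; normalize to a named character vector.
asSeqSet <- function(seq) {
  if (is(seq, "DNAStringSet")) {
    out <- as.character(seq)
    if (is.null(names(out))) names(out) <- sprintf("seq%d", seq_along(out))
    return(out)
  }
  if (is(seq, "DNAString")) seq <- as.character(seq)
  out <- toupper(as.character(seq))
  if (is.null(names(out))) names(out) <- if (length(out) == 1L) "seq"
                                         else sprintf("seq%d", seq_along(out))
  out
}

emptyHits <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(motif = character(), score = numeric(),
                         spacer = integer(), match = character())
  gr
}

makeHits <- function(seqname, starts, width, strands, motifName, scores,
                     spacers, seqChars) {
  if (length(starts) == 0L) return(emptyHits())
  gr <- GRanges(seqname, IRanges(starts, width = width), strand = strands)
  match <- substring(paste(seqChars, collapse = ""), starts,
                     starts + width - 1L)
  mcols(gr) <- DataFrame(motif = motifName, score = scores,
                         spacer = spacers, match = match)
  gr
}

# ---------------------------------------------------------------------------
# Consensus scanning
# ---------------------------------------------------------------------------

#' Scan sequences for exact IUPAC consensus matches
#'
#' Reports every position where the consensus matches exactly on the `+`
#' strand and, if `bothStrands`, on the `-` strand (via the
#' reverse-complemented pattern matched against the forward sequence, so
#' coordinates always refer to the forward strand). An `N` in the sequence
#' never matches any code. Hits are sorted by sequence, position, then
#' strand (`+` first).
#'
#' @param seq a `DNAStringSet`, named character vector, or single string.
#' @param motif a [ConsensusMotif-class].
#' @param bothStrands scan the reverse strand too (default TRUE).
#' @return A `GRanges` (1-based coordinates on the forward strand) with
#'   metadata columns `motif`, `score` (1 for an exact consensus match),
#'   `spacer` (NA here) and `match` (forward-strand sequence of the hit).
#' @examples
#' scanConsensus("AACAATGAA", motifSoxConsensus())
#' @export
scanConsensus <- function(seq, motif, bothStrands = TRUE) {
  seqs <- asSeqSet(seq)
  fwdChars <- checkIupac(motif@iupac, sprintf("motif '%s'", motif@name))
  revChars <- strsplit(revcompChar(motif@iupac), "", fixed = TRUE)[[1L]]
  w <- length(fwdChars)
  out <- list()
  for (nm in names(seqs)) {
    chars <- strsplit(seqs[[nm]], "", fixed = TRUE)[[1L]]
    enc <- match(chars, DNA_BASES)
    pos <- consensusPositions(enc, fwdChars)
    strands <- rep("+", length(pos))
    if (bothStrands) {
      rpos <- consensusPositions(enc, revChars)
      pos <- c(pos, rpos)
      strands <- c(strands, rep("-", length(rpos)))
    }
    ord <- order(pos, strands)  # "+" < "-" lexicographically
    out[[nm]] <- makeHits(nm, pos[ord], w, strands[ord], motif@name,
                          rep(1, length(pos)), rep(NA_integer_, length(pos)),
                          chars)
  }
  suppressWarnings(do.call(c, unname(out)))
}

# ---------------------------------------------------------------------------
# PWM construction, p-values, scanning
# ---------------------------------------------------------------------------

#' Build a PWM from an IUPAC consensus
#'
#' At each position the bases allowed by the IUPAC code share `certainty`
#' probability mass equally; disallowed bases share the remainder. A fully
#' degenerate position (N) is uniform regardless of `certainty`.
#'
#' @param motif a [ConsensusMotif-class].
#' @param certainty probability mass on allowed bases, in `[0.25, 1]`.
#' @param background length-4 background probabilities (A, C, G, T).
#' @param granularity score discretization step in bits used by
#'   [pwmPvalue()] (default 1e-3).
#' @return A [PWMotif-class].
#' @examples
#' pwmFromConsensus(consensusMotif("W"), certainty = 0.9)@mat  # 0.45/0.05
#' @export
pwmFromConsensus <- function(motif, certainty = 0.9,
                             background = rep(0.25, 4),
                             granularity = 1e-3) {
  stopf(certainty >= 0.25 && certainty <= 1,
        "certainty must lie in [0.25, 1]")
  chars <- checkIupac(motif@iupac)
  mat <- vapply(chars, function(ch) {
    allowed <- DNA_BASES %in% IUPAC_MAP[[ch]]
    k <- sum(allowed)
    if (k == 4L) return(rep(0.25, 4))
    col <- numeric(4)
    col[allowed] <- certainty / k
    col[!allowed] <- (1 - certainty) / (4 - k)
    col
  }, numeric(4))
  rownames(mat) <- DNA_BASES
  colnames(mat) <- NULL
  new("PWMotif", mat = mat, background = background,
      granularity = granularity, name = motif@name)
}

# Discretized integer log2-odds score matrix (4 x w). -Inf columns (zero
# probability under the PWM) are clamped far below any attainable threshold.
pwmIntScores <- function(pwm) {
  s <- log2(pwm@mat / pwm@background)
  clamp <- -100  # bits; well below any realistic score
  s[!is.finite(s)] <- clamp
  round(s / pwm@granularity)
}

# Exact distribution of the discretized score of a background-distributed
# random w-mer: list(offset = minimum achievable integer score, probs =
# vector of probabilities for scores offset, offset+1, ...).
pwmScoreDistribution <- function(pwm) {
  S <- pwmIntScores(pwm)
  bg <- pwm@background
  probs <- 1
  offset <- 0L
  for (j in seq_len(ncol(S))) {
    sj <- S[, j]
    mn <- min(sj); mx <- max(sj)
    newLen <- length(probs) + (mx - mn)
    newProbs <- numeric(newLen)
    for (b in 1:4) {
      sh <- sj[b] - mn
      idx <- seq_along(probs) + sh
      newProbs[idx] <- newProbs[idx] + bg[b] * probs
    }
    probs <- newProbs
    offset <- offset + mn
  }
  list(offset = offset, probs = probs)
}

#' Exact PWM score p-value
#'
#' `P(score >= threshold)` for a random `w`-mer drawn from the PWM's
#' background model, computed by dynamic programming over the discretized
#' score distribution (granularity `pwm@granularity` bits). Exact for the
#' discretized scores.
#'
#' @param pwm a [PWMotif-class].
#' @param threshold log2-odds score threshold in bits.
#' @return The upper-tail probability.
#' @examples
#' m <- pwmFromConsensus(consensusMotif("A"), certainty = 1)
#' pwmPvalue(m, log2(1 / 0.25))  # 0.25: only A scores 2 bits
#' @export
pwmPvalue <- function(pwm, threshold) {
  dist <- pwmScoreDistribution(pwm)
  tInt <- round(threshold / pwm@granularity)
  if (tInt <= dist$offset) return(1)
  maxInt <- dist$offset + length(dist$probs) - 1L
  if (tInt > maxInt) return(0)
  sum(dist$probs[(tInt - dist$offset + 1L):length(dist$probs)])
}

# Smallest integer score s* whose upper-tail probability is <= p; returns
# list(intScore, achievedP) or NULL when even the maximum score has p > p.
pwmScoreThreshold <- function(pwm, p) {
  dist <- pwmScoreDistribution(pwm)
  surv <- rev(cumsum(rev(dist$probs)))
  ok <- which(surv <= p)
  if (length(ok) == 0L) return(NULL)
  list(intScore = dist$offset + ok[1L] - 1L, achievedP = surv[ok[1L]])
}

# Integer scores of all w-windows of enc under S (4 x w integer matrix);
# windows containing NA bases get NA.
windowScores <- function(enc, S) {
  w <- ncol(S)
  n <- length(enc)
  if (n < w) return(numeric(0))
  total <- rep(0, n - w + 1L)
  for (j in seq_len(w)) {
    total <- total + S[, j][enc[j:(n - w + j)]]
  }
  total
}

#' Scan sequences with a PWM at a p-value threshold
#'
#' Reports positions whose log2-odds score has an exact background p-value
#' at most `pThreshold` (the FIMO-default threshold 1e-4 is the default
#' here). Windows containing `N` are skipped. Because scores are discrete,
#' the achieved p-value at the score cutoff can be smaller than
#' `pThreshold`; it is returned in the `achievedP` attribute.
#'
#' @param seq a `DNAStringSet`, named character vector, or single string.
#' @param pwm a [PWMotif-class].
#' @param pThreshold hit p-value threshold in (0, 1).
#' @param bothStrands scan the reverse strand too.
#' @return A `GRanges` of hits (forward-strand coordinates) with `motif`,
#'   `score` (bits), `spacer` (NA) and `match` columns; attribute
#'   `achievedP` carries the exact tail probability at the score cutoff.
#' @export
scanPwm <- function(seq, pwm, pThreshold = 1e-4, bothStrands = TRUE) {
  stopf(pThreshold > 0 && pThreshold <= 1, "pThreshold must be in (0, 1]")
  seqs <- asSeqSet(seq)
  thr <- pwmScoreThreshold(pwm, pThreshold)
  if (is.null(thr)) {
    out <- emptyHits()
    attr(out, "achievedP") <- 0
    return(out)
  }
  Sf <- pwmIntScores(pwm)
  # reverse strand: reverse the columns and complement the rows
  Sr <- Sf[c(4L, 3L, 2L, 1L), rev(seq_len(ncol(Sf))), drop = FALSE]
  rownames(Sr) <- DNA_BASES
  w <- ncol(Sf)
  gran <- pwm@granularity
  out <- list()
  for (nm in names(seqs)) {
    chars <- strsplit(seqs[[nm]], "", fixed = TRUE)[[1L]]
    enc <- match(chars, DNA_BASES)
    sc <- windowScores(enc, Sf)
    pos <- which(!is.na(sc) & sc >= thr$intScore)
    scores <- sc[pos] * gran
    strands <- rep("+", length(pos))
    if (bothStrands) {
      scR <- windowScores(enc, Sr)
      posR <- which(!is.na(scR) & scR >= thr$intScore)
      pos <- c(pos, posR)
      scores <- c(scores, scR[posR] * gran)
      strands <- c(strands, rep("-", length(posR)))
    }
    ord <- order(pos, strands)
    out[[nm]] <- makeHits(nm, pos[ord], w, strands[ord], pwm@name,
                          scores[ord], rep(NA_integer_, length(pos)), chars)
  }
  res <- suppressWarnings(do.call(c, unname(out)))
  attr(res, "achievedP") <- thr$achievedP
  res
}

# ---------------------------------------------------------------------------
# Dimeric inverted-repeat scanning
# ---------------------------------------------------------------------------

#' Scan for dimeric inverted-repeat sites
#'
#' A hit is reported wherever the half-site consensus matches at position
#' `i` (on either strand) and its reverse complement matches at
#' `i + halfWidth + s` for some spacer `s` in the motif's range. The hit
#' interval spans both half-sites and the spacer; the spacer length is
#' recorded. Overlapping hits are all reported.
#'
#' @param seq a `DNAStringSet`, named character vector, or single string.
#' @param motif a [DimericMotif-class].
#' @return A `GRanges` of hits with `motif`, `score` (1), `spacer` and
#'   `match` metadata columns.
#' @examples
#' scanDimeric(paste0("AACAATG", "GGGG", "CATTGTT"), motifSoxDimeric())
#' @export
scanDimeric <- function(seq, motif) {
  seqs <- asSeqSet(seq)
  halfChars <- checkIupac(motif@half@iupac)
  rcChars <- strsplit(revcompChar(motif@half@iupac), "", fixed = TRUE)[[1L]]
  w <- length(halfChars)
  out <- list()
  for (nm in names(seqs)) {
    chars <- strsplit(seqs[[nm]], "", fixed = TRUE)[[1L]]
    enc <- match(chars, DNA_BASES)
    fwd <- consensusPositions(enc, halfChars)   # half on + strand
    rvs <- consensusPositions(enc, rcChars)     # half on - strand
    starts <- integer(0); strands <- character(0); spacers <- integer(0)
    for (s in motif@spacerMin:motif@spacerMax) {
      # + orientation: half ... spacer ... revcomp(half)
      hitP <- fwd[(fwd + w + s) %in% rvs]
      # - orientation: revcomp(half) ... spacer ... half (the same
      # arrangement read on the minus strand)
      hitM <- rvs[(rvs + w + s) %in% fwd]
      starts <- c(starts, hitP, hitM)
      strands <- c(strands, rep("+", length(hitP)), rep("-", length(hitM)))
      spacers <- c(spacers, rep(s, length(hitP) + length(hitM)))
    }
    ord <- order(starts, strands, spacers)
    widths <- 2L * w + spacers[ord]
    if (length(starts) == 0L) {
      out[[nm]] <- emptyHits()
    } else {
      gr <- GRanges(nm, IRanges(starts[ord], width = widths),
                    strand = strands[ord])
      mcols(gr) <- DataFrame(
        motif = motif@name, score = 1,
        spacer = spacers[ord],
        match = substring(seqs[[nm]], starts[ord],
                          starts[ord] + widths - 1L))
      out[[nm]] <- gr
    }
  }
  suppressWarnings(do.call(c, unname(out)))
}

# ---------------------------------------------------------------------------
# Summit windows & peak classification
# ---------------------------------------------------------------------------

#' Extract summit-centred sequence windows from peaks
#'
#' Window `[summit - halfWidth, summit + halfWidth - 1]` (1-based closed;
#' 50 bp at the default `halfWidth = 25`), clipped at chromosome edges with
#' a `clipped` flag. With `topN`, peaks are first ranked by `tagCount`
#' (descending; ties by `pValue` ascending then coordinate) and the first
#' `topN` taken.
#'
#' @param peaks `GRanges` with `summit`, `tagCount`, `pValue` metadata.
#' @param genome named `DNAStringSet`.
#' @param halfWidth half window width in bp (default 25).
#' @param topN optional number of top peaks to keep.
#' @return A `DNAStringSet` named by peak name with metadata columns
#'   `peak`, `start`, `end`, `clipped`.
#' @export
extractSummitWindows <- function(peaks, genome, halfWidth = 25L,
                                 topN = NULL) {
  halfWidth <- as.integer(halfWidth)
  if (!is.null(topN)) {
    ord <- order(-peaks$tagCount, peaks$pValue,
                 match(as.character(seqnames(peaks)), names(genome)),
                 start(peaks))
    peaks <- peaks[ord[seq_len(min(topN, length(peaks)))]]
  }
  if (length(peaks) == 0L) {
    out <- DNAStringSet()
    mcols(out) <- DataFrame(peak = character(), start = integer(),
                            end = integer(), clipped = logical())
    return(out)
  }
  chromLen <- setNames(width(genome), names(genome))
  s <- peaks$summit
  chrom <- as.character(seqnames(peaks))
  start <- s - halfWidth
  end <- s + halfWidth - 1L
  clipStart <- pmax(start, 1L)
  clipEnd <- pmin(end, chromLen[chrom])
  seqs <- DNAStringSet(vapply(seq_along(peaks), function(i) {
    as.character(subseq(genome[[chrom[i]]], clipStart[i], clipEnd[i]))
  }, character(1)))
  names(seqs) <- peaks$name
  mcols(seqs) <- DataFrame(peak = peaks$name, start = as.integer(clipStart),
                           end = as.integer(clipEnd),
                           clipped = clipStart != start | clipEnd != end)
  seqs
}

#' Classify peaks by motif content
#'
#' Scans each peak's sequence (full interval by default, or the
#' summit-centred window with `region = "summit"`) for the CCAAT-box motif
#' (M1), the SOX consensus (M2) and the dimeric inverted repeat (M3), and
#' assigns one of four classes: `M1_ONLY`, `M1_AND_SOX` (M1 plus M2 and/or
#' M3), `SOX_ONLY` (M2/M3 without M1) or `NONE`.
#'
#' @param peaks `GRanges` with `name` and `summit` metadata.
#' @param genome named `DNAStringSet`.
#' @param motif1 CCAAT-box [ConsensusMotif-class] (default
#'   [motifCcaatFull()]).
#' @param motif2 SOX consensus [ConsensusMotif-class].
#' @param motif3 dimeric [DimericMotif-class].
#' @param region `"interval"` (default) scans the full peak interval;
#'   `"summit"` scans the `summit +/- halfWidth` window.
#' @param halfWidth half window width for `region = "summit"`.
#' @return A factor named by peak name with levels `M1_ONLY`, `M1_AND_SOX`,
#'   `SOX_ONLY`, `NONE`.
#' @export
classifyPeaks <- function(peaks, genome, motif1 = motifCcaatFull(),
                          motif2 = motifSoxConsensus(),
                          motif3 = motifSoxDimeric(),
                          region = c("interval", "summit"),
                          halfWidth = 25L) {
  region <- match.arg(region)
  lv <- c("M1_ONLY", "M1_AND_SOX", "SOX_ONLY", "NONE")
  if (length(peaks) == 0L) {
    return(factor(character(), levels = lv))
  }
  if (region == "summit") {
    seqs <- extractSummitWindows(peaks, genome, halfWidth = halfWidth)
  } else {
    chrom <- as.character(seqnames(peaks))
    seqs <- DNAStringSet(vapply(seq_along(peaks), function(i) {
      as.character(subseq(genome[[chrom[i]]], start(peaks)[i],
                          end(peaks)[i]))
    }, character(1)))
    names(seqs) <- peaks$name
  }
  cls <- vapply(seq_along(seqs), function(i) {
    s <- as.character(seqs[[i]])
    hasM1 <- length(scanConsensus(s, motif1, bothStrands = TRUE)) > 0L
    hasSox <- length(scanConsensus(s, motif2, bothStrands = TRUE)) > 0L ||
      length(scanDimeric(s, motif3)) > 0L
    if (hasM1 && hasSox) "M1_AND_SOX"
    else if (hasM1) "M1_ONLY"
    else if (hasSox) "SOX_ONLY"
    else "NONE"
  }, character(1))
  factor(setNames(cls, names(seqs)), levels = lv)
}

# ---------------------------------------------------------------------------
# MEME minimal text format
# ---------------------------------------------------------------------------

#' Write PWMs in MEME minimal text format
#'
#' @param pwms a [PWMotif-class] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMemeMotif <- function(pwms, path) {
  if (is(pwms, "PWMotif")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  bg <- pwms[[1L]]@background
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -",
               "",
               "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1], bg[2], bg[3],
                       bg[4]), ""), con)
  for (pwm in pwms) {
    writeLines(sprintf("MOTIF %s", pwm@name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      ncol(pwm@mat)), con)
    for (j in seq_len(ncol(pwm@mat))) {
      writeLines(sprintf(" %.6f %.6f %.6f %.6f", pwm@mat[1, j],
                         pwm@mat[2, j], pwm@mat[3, j], pwm@mat[4, j]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read PWMs from MEME minimal text format
#'
#' @param path path to a MEME minimal-format file.
#' @param granularity score discretization for the returned PWMs.
#' @return A named list of [PWMotif-class] objects.
#' @export
readMemeMotif <- function(path, granularity = 1e-3) {
  stopf(file.exists(path), "no such file: %s", path)
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgAt <- grep("^Background letter frequencies", lines)
  if (length(bgAt) > 0L) {
    nums <- as.numeric(regmatches(
      lines[bgAt[1L] + 1L],
      gregexpr("[0-9]*\\.?[0-9]+", lines[bgAt[1L] + 1L]))[[1L]])
    if (length(nums) == 4L && abs(sum(nums) - 1) < 0.01) bg <- nums
  }
  motifAt <- grep("^MOTIF ", lines)
  out <- list()
  for (k in seq_along(motifAt)) {
    name <- sub("^MOTIF\\s+(\\S+).*$", "\\1", lines[motifAt[k]])
    hdr <- motifAt[k] + 1L
    while (hdr <= length(lines) &&
           !grepl("letter-probability matrix", lines[hdr])) hdr <- hdr + 1L
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    mat <- t(vapply(rows, function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
    }, numeric(4)))
    mat <- t(mat)  # 4 x w
    mat <- apply(mat, 2L, function(col) col / sum(col))
    dimnames(mat) <- list(DNA_BASES, NULL)
    out[[name]] <- new("PWMotif", mat = mat, background = bg,
                       granularity = granularity, name = name)
  }
  out
}

#' Write motif hits as GFF3-flavoured TSV
#'
#' Columns: seqid, source, type, start (1-based), end, score, strand,
#' frame (`.`), attributes (`Motif=...;Spacer=...`).
#'
#' @param hits `GRanges` from a scan function.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMotifHits <- function(hits, path) {
  attr <- sprintf("Motif=%s%s", hits$motif,
                  ifelse(is.na(hits$spacer), "",
                         sprintf(";Spacer=%d", hits$spacer)))
  df <- data.frame(seqid = as.character(seqnames(hits)), source = "ChIPcooc",
                   type = "motif_hit", start = start(hits), end = end(hits),
                   score = hits$score, strand = as.character(strand(hits)),
                   frame = ".", attributes = attr)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Motif instance sampling (used by the simulator and benchmarks)
# ---------------------------------------------------------------------------

#' Sample a concrete instance of a consensus motif
#'
#' Each degenerate position is resolved uniformly among its allowed bases.
#'
#' @param motif a [ConsensusMotif-class].
#' @param seed optional RNG seed.
#' @return A character string matching the consensus.
#' @export
consensusInstance <- function(motif, seed = NULL) {
  chars <- checkIupac(motif@iupac)
  withSeed(seed, paste(vapply(chars, function(ch) {
    opts <- IUPAC_MAP[[ch]]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = ""))
}

#' Sample a concrete dimeric inverted-repeat instance
#'
#' Half-site instance + random spacer + reverse complement of the half-site.
#'
#' @param motif a [DimericMotif-class].
#' @param spacer spacer length in bp (default 4, the canonical spacing).
#' @param seed optional RNG seed.
#' @return A character string.
#' @export
dimericInstance <- function(motif, spacer = 4L, seed = NULL) {
  withSeed(seed, {
    half <- consensusInstance(motif@half)
    sp <- paste(sample(DNA_BASES, spacer, replace = TRUE), collapse = "")
    paste0(half, sp, revcompChar(half))
  })
}
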