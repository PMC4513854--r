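#' @include AllClasses.R AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# Tag processing
# ---------------------------------------------------------------------------

#' Remove duplicate tags
#'
#' Keeps at most one tag per (chromosome, 5'-position, strand) triple,
#' preserving the input order of first occurrences. Tags on opposite strands
#' at the same position are both kept.
#'
#' @param tags width-1 stranded `GRanges`.
#' @return Deduplicated `GRanges`.
#' @export
deduplicateTags <- function(tags) {
  tags[!duplicated(tags)]
}

#' Downsample tags to a target count
#'
#' Uniform random subset without replacement, deterministic under `seed`;
#' the relative order of retained tags is preserved. Used to adjust the
#' deeper input library to the ChIP alignment number before peak calling.
#'
#' @param tags `GRanges` of tags.
#' @param n target count, `n <= length(tags)`.
#' @param seed RNG seed (NULL: use current RNG stream).
#' @return `GRanges` with exactly `n` tags.
#' @export
downsampleTags <- function(tags, n, seed = NULL) {
  n <- as.integer(n)
  stopf(n <= length(tags),
        "cannot downsample %d tags to %d", length(tags), n)
  if (n == length(tags)) return(tags)
  idx <- withSeed(seed, sort(sample.int(length(tags), n)))
  tags[idx]
}

# Strand-aware 3'-extension of width-1 tags to fragments, clipped to
# chromosome bounds. Errors on tags beyond the chromosome end.
extendTags <- function(tags, seqlens, fragLen) {
  stopf(all(as.character(seqnames(tags)) %in% names(seqlens)),
        "tags on chromosomes absent from seqlens")
  len <- seqlens[as.character(seqnames(tags))]
  bad <- which(start(tags) < 1L | start(tags) > len)
  if (length(bad) > 0L) {
    stop(sprintf("tag %d (%s:%d:%s) lies outside its chromosome (length %d)",
                 bad[1L], as.character(seqnames(tags))[bad[1L]],
                 start(tags)[bad[1L]], as.character(strand(tags))[bad[1L]],
                 len[bad[1L]]), call. = FALSE)
  }
  # drop seqinfo so out-of-bound intermediate ranges raise no warnings,
  # then extend 3'-wards (strand-aware) and clip at chromosome edges
  frags <- GRanges(as.character(seqnames(tags)), ranges(tags), strand(tags))
  frags <- resize(frags, fragLen, fix = "start")
  newStart <- pmax(start(frags), 1L)
  newEnd <- pmin(end(frags), unname(len))
  ranges(frags) <- IRanges(newStart, newEnd)
  frags
}

# ---------------------------------------------------------------------------
# SignalMap construction
# ---------------------------------------------------------------------------

#' Build a binned signal map from tags
#'
#' Each tag is extended in silico at its 3' end to `fragLen` bp (clipped at
#' chromosome edges) and every `binWidth`-sized bin the fragment overlaps by
#' at least one base is incremented by one.
#'
#' @param tags width-1 stranded `GRanges` (deduplicate first; not enforced).
#' @param seqlens named integer vector of chromosome lengths.
#' @param fragLen fragment length in bp (default 150).
#' @param binWidth bin width in bp (default 32).
#' @return A [SignalMap-class].
#' @examples
#' tags <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1), "+")
#' map <- buildSignalMap(tags, c(chr1 = 1000L))
#' binCounts(map, "chr1")[1:6]  # fragment [1,150] touches bins 1..5
#' @export
buildSignalMap <- function(tags, seqlens, fragLen = 150L, binWidth = 32L) {
  fragLen <- as.integer(fragLen)
  binWidth <- as.integer(binWidth)
  seqlens <- setNames(as.integer(seqlens), names(seqlens))
  frags <- extendTags(tags, seqlens, fragLen)
  counts <- lapply(names(seqlens), function(chrom) {
    nbins <- as.integer(ceiling(seqlens[[chrom]] / binWidth))
    f <- frags[as.character(seqnames(frags)) == chrom]
    if (length(f) == 0L) return(integer(nbins))
    b1 <- (start(f) - 1L) %/% binWidth + 1L
    b2 <- (end(f) - 1L) %/% binWidth + 1L
    idx <- sequence(b2 - b1 + 1L, from = b1)
    tabulate(idx, nbins)
  })
  names(counts) <- names(seqlens)
  new("SignalMap", binWidth = binWidth, fragLen = fragLen, counts = counts,
      seqlens = seqlens, nTags = length(tags))
}

#' Count tags whose fragments overlap regions
#'
#' A tag counts for a region when its 3'-extended fragment overlaps the
#' region by at least one base (matching the signal-map semantics used for
#' peak metrics). Set `fivePrime = TRUE` to count raw 5' tag positions
#' instead (sensitivity analysis).
#'
#' @param tags width-1 stranded `GRanges`.
#' @param regions `GRanges` of query regions.
#' @param fragLen fragment extension length in bp.
#' @param fivePrime logical; count unextended 5' positions only.
#' @return Integer vector of counts, one per region.
#' @export
countTagsInRegion <- function(tags, regions, fragLen = 150L,
                              fivePrime = FALSE) {
  frags <- GRanges(as.character(seqnames(tags)), ranges(tags), strand(tags))
  if (!fivePrime) {
    frags <- resize(frags, as.integer(fragLen), fix = "start")
    # clip below 1 so widths stay valid near the left edge
    ranges(frags) <- IRanges(pmax(start(frags), 1L), end(frags))
  }
  q <- GRanges(as.character(seqnames(regions)), ranges(regions))
  countOverlaps(q, frags, ignore.strand = TRUE)
}

# ---------------------------------------------------------------------------
# bedGraph serialization
# ---------------------------------------------------------------------------

#' Write a signal map as bedGraph
#'
#' One record per maximal run of equal-count bins (zero runs included, so the
#' reader reconstructs bin arrays exactly). The map's bin width, fragment
#' length and tag count travel in `#` header comments.
#'
#' @param map a [SignalMap-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSignalMap <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# binWidth=%d fragLen=%d nTags=%d", map@binWidth, map@fragLen,
            map@nTags),
    paste0("# seqlens=", paste(sprintf("%s:%d", names(map@seqlens),
                                       map@seqlens), collapse = ",")),
    "track type=bedGraph"), con)
  bw <- map@binWidth
  for (chrom in names(map@counts)) {
    cnt <- map@counts[[chrom]]
    r <- rle(cnt)
    endBin <- cumsum(r$lengths)
    startBin <- endBin - r$lengths + 1L
    start0 <- (startBin - 1L) * bw
    end0 <- pmin(endBin * bw, map@seqlens[[chrom]])
    writeLines(sprintf("%s\t%d\t%d\t%d", chrom, start0, end0, r$values), con)
  }
  invisible(path)
}

#' Read a signal map written by [writeSignalMap()]
#'
#' @param path path to the bedGraph file.
#' @return A [SignalMap-class] identical to the one written.
#' @export
readSignalMap <- function(path) {
  stopf(file.exists(path), "no such file: %s", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  meta <- regmatches(hdr[1L],
                     regexec("binWidth=(\\d+) fragLen=(\\d+) nTags=(\\d+)",
                             hdr[1L]))[[1L]]
  stopf(length(meta) == 4L, "missing signal-map header in '%s'", path)
  binWidth <- as.integer(meta[2L])
  fragLen <- as.integer(meta[3L])
  nTags <- as.integer(meta[4L])
  slStr <- sub("^# seqlens=", "", hdr[2L])
  slParts <- strsplit(strsplit(slStr, ",", fixed = TRUE)[[1L]], ":",
                      fixed = TRUE)
  seqlens <- setNames(vapply(slParts, function(p) as.integer(p[2L]),
                             integer(1)),
                      vapply(slParts, `[`, character(1), 1L))
  body <- lines[!startsWith(lines, "#") & !startsWith(lines, "track")]
  rec <- read.delim(text = body, header = FALSE,
                    col.names = c("chrom", "start0", "end0", "count"))
  counts <- lapply(names(seqlens), function(chrom) {
    nbins <- as.integer(ceiling(seqlens[[chrom]] / binWidth))
    cnt <- integer(nbins)
    r <- rec[rec$chrom == chrom, , drop = FALSE]
    if (nrow(r) > 0L) {
      b1 <- r$start0 %/% binWidth + 1L
      b2 <- (r$end0 - 1L) %/% binWidth + 1L
      cnt[sequence(b2 - b1 + 1L, from = b1)] <-
        rep.int(r$count, b2 - b1 + 1L)
    }
    cnt
  })
  names(counts) <- names(seqlens)
  new("SignalMap", binWidth = binWidth, fragLen = fragLen, counts = counts,
      seqlens = seqlens, nTags = nTags)
}
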