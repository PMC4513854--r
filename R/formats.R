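#' @include utils.R
NULL

# ---------------------------------------------------------------------------
# FASTA
# ---------------------------------------------------------------------------

#' Read a genome FASTA file
#'
#' Sequence names are taken from headers up to the first whitespace;
#' sequences are upper-cased and must be over the alphabet ACGTN.
#'
#' @param path path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 toy", "ACGTACGT"), fa)
#' readGenomeFasta(fa)
#' @export
readGenomeFasta <- function(path) {
  stopf(file.exists(path), "no such file: %s", path)
  x <- tryCatch(readDNAStringSet(path),
                error = function(e) stop(sprintf("malformed FASTA '%s': %s",
                                                 path, conditionMessage(e)),
                                         call. = FALSE))
  stopf(length(x) > 0L, "FASTA '%s' contains no sequences", path)
  names(x) <- sub("\\s.*$", "", names(x))
  stopf(!anyDuplicated(names(x)), "duplicate sequence names in '%s'", path)
  x <- DNAStringSet(toupper(x))
  letters <- colSums(alphabetFrequency(x))
  extra <- letters[!(names(letters) %in% c("A", "C", "G", "T", "N"))]
  stopf(all(extra == 0), "FASTA '%s' contains letters outside ACGTN", path)
  x
}

#' Write a genome FASTA file
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
  writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Tags (BED6)
# ---------------------------------------------------------------------------

#' Read aligned tags from a BED6 file
#'
#' Each record is one uniquely mapped read; the tag is reduced to the
#' 1-based coordinate of its 5' base: the BED start + 1 for `+` records and
#' the BED end for `-` records (the 5' end of a minus-strand read is its
#' rightmost base). Records must carry a `+`/`-` strand.
#'
#' @param path path to a BED6 file.
#' @return A width-1 `GRanges` with strand; metadata column `name`.
#' @export
readTagsBed <- function(path) {
  stopf(file.exists(path), "no such file: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop(sprintf("malformed BED '%s': %s",
                                                  path, conditionMessage(e)),
                                          call. = FALSE))
  stopf(all(width(gr) >= 1L), "BED '%s': records with start >= end", path)
  stopf(all(as.character(strand(gr)) %in% c("+", "-")),
        "BED '%s': every tag record needs strand '+' or '-'", path)
  tags <- resize(gr, 1L, fix = "start")  # strand-aware: 5' base
  keep <- intersect(c("name"), colnames(mcols(tags)))
  mcols(tags) <- mcols(tags)[, keep, drop = FALSE]
  tags
}

#' Write tags to a BED6 file
#'
#' Inverse of [readTagsBed()]: a width-1 record is written per tag, so the
#' (chrom, 5'-position, strand) triple round-trips exactly.
#'
#' @param tags width-1 `GRanges` with `+`/`-` strand.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTagsBed <- function(tags, path) {
  stopf(all(width(tags) == 1L), "tags must have width 1")
  stopf(all(as.character(strand(tags)) %in% c("+", "-")),
        "tags must be stranded (+/-)")
  out <- tags
  if (is.null(mcols(out)$name)) {
    mcols(out)$name <- sprintf("tag_%d", seq_along(out))
  }
  mcols(out)$score <- 0L
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Read a BED3 interval track (e.g. a repeat mask)
#'
#' @param path path to a BED file (first three columns used).
#' @return An unstranded `GRanges`.
#' @export
readRepeatBed <- function(path) {
  stopf(file.exists(path), "no such file: %s", path)
  gr <- rtracklayer::import(path, format = "BED")
  strand(gr) <- "*"
  mcols(gr) <- NULL
  gr
}

#' Write a BED3 interval track
#'
#' @param regions `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRepeatBed <- function(regions, path) {
  out <- granges(regions)
  strand(out) <- "*"
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Gene models (refFlat-style TSV)
# ---------------------------------------------------------------------------

GENE_TABLE_COLS <- c("name", "chrom", "strand", "txStart", "txEnd",
                     "cdsStart", "cdsEnd", "exonStarts", "exonEnds")

#' Read gene models from a refFlat-style TSV
#'
#' Columns: name, chrom, strand, txStart, txEnd, cdsStart, cdsEnd,
#' exonStarts, exonEnds. Coordinates in the file are 0-based half-open
#' (UCSC convention); exon lists are comma-separated with an optional
#' trailing comma. A record with `cdsStart == cdsEnd` has no coding region.
#' Internally everything is converted to 1-based closed coordinates.
#'
#' Records violating the gene-model invariants (exons sorted,
#' non-overlapping, inside the transcript; CDS inside the transcript) are
#' rejected with their line number.
#'
#' @param path path to the TSV (with header).
#' @return A `data.frame` with 1-based closed `txStart`, `txEnd`,
#'   `cdsStart`, `cdsEnd` (NA when absent), list columns `exonStarts`,
#'   `exonEnds`, and a `tss` column (1-based TSS: `txStart` for `+` genes,
#'   `txEnd` for `-` genes).
#' @export
readGeneTable <- function(path) {
  stopf(file.exists(path), "no such file: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopf(all(GENE_TABLE_COLS %in% colnames(df)),
        "gene table '%s' must have columns: %s", path,
        paste(GENE_TABLE_COLS, collapse = ", "))
  parseList <- function(x) {
    lapply(strsplit(as.character(x), ",", fixed = TRUE),
           function(v) as.integer(v[nzchar(v)]))
  }
  exonS0 <- parseList(df$exonStarts)
  exonE0 <- parseList(df$exonEnds)
  for (i in seq_len(nrow(df))) {
    line <- i + 1L  # header is line 1
    s0 <- exonS0[[i]]; e0 <- exonE0[[i]]
    stopf(length(s0) == length(e0) && length(s0) >= 1L,
          "gene table line %d: exon start/end lists differ in length", line)
    stopf(all(s0 < e0), "gene table line %d: exon with start >= end", line)
    stopf(!is.unsorted(s0, strictly = TRUE) && all(diff(e0) > 0) &&
            all(utils::head(e0, -1L) <= utils::tail(s0, -1L)),
          "gene table line %d: exons must be sorted and non-overlapping", line)
    stopf(s0[1L] >= df$txStart[i] && utils::tail(e0, 1L) <= df$txEnd[i],
          "gene table line %d: exon outside transcript bounds", line)
    stopf(df$txStart[i] < df$txEnd[i],
          "gene table line %d: txStart must be < txEnd", line)
    stopf(df$strand[i] %in% c("+", "-"),
          "gene table line %d: strand must be + or -", line)
    if (df$cdsStart[i] != df$cdsEnd[i]) {
      stopf(df$cdsStart[i] < df$cdsEnd[i] &&
              df$cdsStart[i] >= df$txStart[i] && df$cdsEnd[i] <= df$txEnd[i],
            "gene table line %d: CDS outside transcript bounds", line)
    }
  }
  hasCds <- df$cdsStart != df$cdsEnd
  out <- data.frame(
    name = df$name, chrom = df$chrom, strand = df$strand,
    txStart = df$txStart + 1L, txEnd = df$txEnd,
    cdsStart = ifelse(hasCds, df$cdsStart + 1L, NA_integer_),
    cdsEnd = ifelse(hasCds, df$cdsEnd, NA_integer_),
    stringsAsFactors = FALSE
  )
  out$exonStarts <- lapply(exonS0, function(v) v + 1L)
  out$exonEnds <- exonE0
  out$tss <- ifelse(out$strand == "+", out$txStart, out$txEnd)
  out
}

#' Write gene models to a refFlat-style TSV
#'
#' Inverse of [readGeneTable()] (file coordinates 0-based half-open).
#'
#' @param genes data.frame as returned by [readGeneTable()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(genes, path) {
  hasCds <- !is.na(genes$cdsStart)
  df <- data.frame(
    name = genes$name, chrom = genes$chrom, strand = genes$strand,
    txStart = genes$txStart - 1L, txEnd = genes$txEnd,
    cdsStart = ifelse(hasCds, genes$cdsStart - 1L, genes$txStart - 1L),
    cdsEnd = ifelse(hasCds, genes$cdsEnd, genes$txStart - 1L),
    exonStarts = vapply(genes$exonStarts,
                        function(v) paste0(paste(v - 1L, collapse = ","), ","),
                        character(1)),
    exonEnds = vapply(genes$exonEnds,
                      function(v) paste0(paste(v, collapse = ","), ","),
                      character(1)),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' TSS positions of a gene table
#'
#' @param genes data.frame from [readGeneTable()] / [generateGenome()].
#' @return A width-1 stranded `GRanges` of TSS positions, named by gene.
#' @export
geneTss <- function(genes) {
  GRanges(genes$chrom, IRanges(genes$tss, width = 1L), strand = genes$strand,
          name = genes$name)
}

# ---------------------------------------------------------------------------
# Translation
# ---------------------------------------------------------------------------

#' Translate a DNA sequence
#'
#' Standard genetic code, one letter per codon, stop codons rendered `*`.
#'
#' @param seq DNA string over ACGT with length divisible by 3.
#' @return Peptide string.
#' @examples
#' translateDna("CCCAAGAAGAAGCGGAAGGTG")  # "PKKKRKV", an SV40-type NLS
#' @export
translateDna <- function(seq) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  stopf(n > 0L && n %% 3L == 0L,
        "sequence length (%d) must be a positive multiple of 3", n)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  stopf(all(chars %in% DNA_BASES), "sequence must be over ACGT")
  codons <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(GENETIC_CODE[codons], collapse = "")
}
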