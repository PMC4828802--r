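# Readers and writers for the standard interchange formats used by the
# pipeline: FASTA/FASTQ (Biostrings), collapsed FASTA with count headers,
# GFF3/BED (rtracklayer), and plain TSV truth/report tables (readr).

#' Read and write FASTA
#'
#' @param x named character vector of sequences.
#' @param path file path.
#' @return `read_fasta()` returns a named character vector.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Read and write collapsed read libraries
#'
#' Collapsed FASTA uses headers of the form `seq_<N> x<count>`; FASTQ
#' (detected by extension .fq/.fastq) stores one record per read with
#' constant phred+33 quality.
#'
#' @param lib data frame with `seq`, `count`.
#' @param path output path.
#' @param qual_char quality character for FASTQ output (default "I", Q40).
#' @return `read_reads()` returns a tibble `seq`, `count` (and `qual` for
#'   FASTQ input).
#' @export
write_reads <- function(lib, path, qual_char = "I") {
  lib <- as_tibble(lib)
  if (grepl("\\.(fq|fastq)$", path)) {
    n <- rep(seq_len(nrow(lib)), lib$count)
    seqs <- lib$seq[n]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("@read_", seq_along(seqs), "\n", seqs, "\n+\n",
                      strrep(qual_char, nchar(seqs))), con)
  } else {
    headers <- sprintf("seq_%d x%d", seq_len(nrow(lib)), lib$count)
    write_fasta(setNames(lib$seq, headers), path)
  }
  invisible(path)
}

#' @rdname write_reads
#' @export
read_reads <- function(path) {
  if (grepl("\\.(fq|fastq)$", path)) {
    x <- Biostrings::readQualityScaledDNAStringSet(path)
    tibble(seq = as.character(x), qual = as.character(Biostrings::quality(x)),
           count = 1L)
  } else {
    x <- read_fasta(path)
    counts <- suppressWarnings(
      as.integer(sub(".*x(\\d+)\\s*$", "\\1", names(x))))
    counts[is.na(counts)] <- 1L
    tibble(seq = unname(x), count = counts)
  }
}

#' Read and write genomic feature tables
#'
#' Gene models round-trip through GFF3 and repeat intervals through BED
#' (rtracklayer handles the 0-based half-open BED convention); in-memory
#' tables are 1-based inclusive tibbles.
#'
#' @param features tibble `scaffold`, `start`, `end`, `strand`, `type`,
#'   `gene`.
#' @param path file path.
#' @return readers return tibbles mirroring the writer input.
#' @export
write_gff3 <- function(features, path) {
  gr <- GenomicRanges::GRanges(
    features$scaffold,
    IRanges::IRanges(features$start, features$end),
    strand = features$strand)
  gr$type <- features$type
  gr$ID <- sprintf("%s_%s_%d", features$gene, features$type,
                   seq_len(nrow(features)))
  gr$gene <- features$gene
  gr$phase <- ifelse(features$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  tibble(scaffold = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
         strand = as.character(GenomicRanges::strand(gr)),
         type = as.character(gr$type),
         gene = as.character(gr$gene))
}

#' @rdname write_gff3
#' @param intervals tibble `scaffold`, `start`, `end` (1-based inclusive).
#' @export
write_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    intervals$scaffold, IRanges::IRanges(intervals$start, intervals$end))
  gr$name <- if (!is.null(intervals[["repeat_id"]])) intervals$repeat_id else
    sprintf("interval_%d", seq_len(nrow(intervals)))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble(repeat_id = as.character(gr$name),
         scaffold = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr), end = GenomicRanges::end(gr))
}
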