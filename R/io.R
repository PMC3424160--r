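#' Read a FASTQ file into a reads data frame
#'
#' Validates the 4-line record layout first so that a malformed record is
#' reported with its record index, then parses through Biostrings.
#'
#' @param path FASTQ file (Phred+33).
#' @return data frame with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ: truncated record ", length(lines) %/% 4 + 1,
         " in ", path)
  }
  n <- length(lines) %/% 4
  for (r in seq_len(n)) {
    b <- lines[(r - 1) * 4 + 1:4]
    if (!startsWith(b[1], "@") || !startsWith(b[3], "+") ||
        nchar(b[2]) != nchar(b[4])) {
      stop("malformed FASTQ record ", r, " in ", path)
    }
  }
  if (n == 0) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' Write a reads data frame as FASTQ (Phred+33)
#'
#' @param reads data frame with `id`, `seq`, `qual`.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  out <- character(4 * nrow(reads))
  idx <- seq_len(nrow(reads))
  out[4 * idx - 3] <- paste0("@", reads$id)
  out[4 * idx - 2] <- reads$seq
  out[4 * idx - 1] <- "+"
  out[4 * idx] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(stats::setNames(as.character(seqs), names(seqs))),
    path)
  invisible(path)
}

#' Write collapsed tags as a count-annotated FASTA
#'
#' Headers carry the per-library copy counts:
#' `>tag<k> count_a=<n> count_b=<n>`.
#'
#' @param tags collapsed tag table from [collapse_tags()].
#' @param path output file.
#' @export
write_tag_fasta <- function(tags, path) {
  hdr <- sprintf("tag%d count_a=%d count_b=%d", seq_len(nrow(tags)),
                 tags$count_a, tags$count_b)
  write_fasta(stats::setNames(tags$sequence, hdr), path)
}

#' Write genome annotation as BED-like TSV
#'
#' Standard BED convention: 0-based half-open coordinates, columns chrom,
#' start, end, name, score, strand plus a `kind` column.
#'
#' @param genome a [make_genome()] object.
#' @param path output file.
#' @export
write_annotation_bed <- function(genome, path) {
  f <- genome$features
  df <- data.frame(chrom = "chr",
                   start = GenomicRanges::start(f) - 1L,
                   end = GenomicRanges::end(f),
                   name = f$name, score = 0,
                   strand = as.character(GenomicRanges::strand(f)),
                   kind = f$kind)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write genome annotation as GFF3
#'
#' @param genome a [make_genome()] object.
#' @param path output file.
#' @export
write_annotation_gff3 <- function(genome, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required for GFF3 export")
  }
  f <- genome$features
  gr <- GenomicRanges::GRanges("chr", IRanges::IRanges(
    GenomicRanges::start(f), GenomicRanges::end(f)),
    strand = GenomicRanges::strand(f))
  gr$type <- ifelse(f$kind == "intergenic", "region", f$kind)
  gr$ID <- f$name
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write the genome sequence as FASTA
#'
#' @param genome a [make_genome()] object.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  write_fasta(c(chr = genome$sequence), path)
}
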