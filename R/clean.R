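#' Default adapter pair
#'
#' @param adapter3,adapter5 adapter sequences.
#' @return named list with `adapter3`, `adapter5`.
#' @export
default_adapters <- function(adapter3 = "TGGAATTCTCGG",
                             adapter5 = "GTTCAGAGTTCT") {
  list(adapter3 = dna_norm(adapter3), adapter5 = dna_norm(adapter5))
}

#' Quality rule for read filtering
#'
#' A read is low quality when its mean Phred score falls below
#' `min_mean_phred` or it contains more than `max_n` ambiguous bases.
#'
#' @param min_mean_phred minimum mean Phred score (default 20).
#' @param max_n maximum tolerated N bases (default 0).
#' @return named list.
#' @export
quality_rule <- function(min_mean_phred = 20, max_n = 0) {
  list(min_mean_phred = min_mean_phred, max_n = max_n)
}

#' Classify raw small-RNA reads into cleaning categories
#'
#' Assigns every read exactly one category, evaluated in the fixed order
#' low_quality, adapter3_null, insert_null, adapter5_contaminant,
#' too_short, polyA, clean (the column order of the cleaning summary):
#' a read is low quality per the [quality_rule()]; then it must contain
#' the 3' adapter (otherwise `adapter3_null`; an insert longer than
#' `max_len` is treated the same way, as the adapter was not found inside
#' the size-selected window); an empty insert is an adapter dimer
#' (`insert_null`); an insert containing the 5' adapter is a 5'
#' contaminant; inserts shorter than `min_len` are `too_short`; inserts of
#' at least 90% A are `polyA`; the rest are clean.
#'
#' @param seqs,quals character vectors of read sequences and Phred+33
#'   quality strings (equal lengths per read).
#' @param adapters a [default_adapters()] list.
#' @param quality a [quality_rule()].
#' @param min_len,max_len clean insert length window (default 18-44 nt).
#' @param polyA_frac minimum A fraction for the polyA call (default 0.9).
#' @return data frame with `category` and the trimmed `insert`.
#' @export
classify_reads <- function(seqs, quals, adapters = default_adapters(),
                           quality = quality_rule(), min_len = 18,
                           max_len = 44, polyA_frac = 0.9) {
  stopifnot(length(seqs) == length(quals))
  if (any(nchar(seqs) != nchar(quals))) {
    stop("sequence and quality strings must have equal length")
  }
  n <- length(seqs)
  if (n == 0) {
    return(data.frame(category = character(0), insert = character(0),
                      stringsAsFactors = FALSE))
  }
  seqs <- toupper(seqs)
  mean_phred <- vapply(quals, function(q) {
    if (!nzchar(q)) return(0)
    mean(utf8ToInt(q)) - 33
  }, numeric(1), USE.NAMES = FALSE)
  n_count <- nchar(seqs) - nchar(gsub("N", "", seqs, fixed = TRUE))
  low <- mean_phred < quality$min_mean_phred | n_count > quality$max_n

  pos <- regexpr(adapters$adapter3, seqs, fixed = TRUE)
  insert <- ifelse(pos > 0, substr(seqs, 1, pos - 1), seqs)
  ilen <- nchar(insert)
  a_frac <- ifelse(ilen > 0,
                   (ilen - nchar(gsub("A", "", insert, fixed = TRUE))) / ilen,
                   0)
  has_a5 <- grepl(adapters$adapter5, insert, fixed = TRUE)

  category <- rep("clean", n)
  category[a_frac >= polyA_frac] <- "polyA"
  category[ilen < min_len] <- "too_short"
  category[has_a5] <- "adapter5_contaminant"
  category[pos > 0 & ilen == 0] <- "insert_null"
  category[nchar(seqs) > 0 & pos < 0] <- "adapter3_null"
  category[nchar(seqs) > 0 & ilen > max_len] <- "adapter3_null"
  category[low] <- "low_quality"
  # an empty read has, by definition, no insert
  category[nchar(seqs) == 0] <- "insert_null"
  data.frame(category = category, insert = insert, stringsAsFactors = FALSE)
}

#' Classify a single read
#'
#' @inheritParams classify_reads
#' @param seq,qual one read's sequence and quality string.
#' @return the category string.
#' @export
classify_read <- function(seq, qual, adapters = default_adapters(),
                          quality = quality_rule(), min_len = 18,
                          max_len = 44) {
  classify_reads(seq, qual, adapters, quality, min_len, max_len)$category
}

#' Cleaning summary in the style of the published accounting table
#'
#' Builds the category accounting from component counts: high-quality
#' reads are the sum of the six post-quality categories, and each category
#' percentage is taken of the high-quality total, half-up rounded to two
#' decimals.
#'
#' @param total_reads raw read count.
#' @param adapter3_null,insert_null,adapter5_contaminant,too_short,polyA,clean_reads
#'   category counts among high-quality reads.
#' @return object of class `cleaning_summary`: `counts` (named, including
#'   `high_quality` and `low_quality`) and `percentages` (of high-quality).
#' @export
cleaning_summary <- function(total_reads, adapter3_null, insert_null,
                             adapter5_contaminant, too_short, polyA,
                             clean_reads) {
  counts <- c(adapter3_null = adapter3_null, insert_null = insert_null,
              adapter5_contaminant = adapter5_contaminant,
              too_short = too_short, polyA = polyA,
              clean_reads = clean_reads)
  high_quality <- sum(counts)
  if (total_reads < high_quality) {
    stop("total_reads is smaller than the sum of high-quality categories")
  }
  structure(list(
    counts = c(total_reads = total_reads, high_quality = high_quality,
               low_quality = total_reads - high_quality, counts),
    percentages = c(high_quality = if (high_quality > 0) 100 else 0,
                    pct_of(counts, high_quality))),
    class = "cleaning_summary")
}

#' @export
print.cleaning_summary <- function(x, ...) {
  cat("Small-RNA cleaning summary\n")
  cat(sprintf("  total reads   %12d\n", x$counts[["total_reads"]]))
  cat(sprintf("  high quality  %12d (100)\n", x$counts[["high_quality"]]))
  for (k in c("adapter3_null", "insert_null", "adapter5_contaminant",
              "too_short", "polyA", "clean_reads")) {
    cat(sprintf("  %-20s %10d (%.2f)\n", k, x$counts[[k]], x$percentages[[k]]))
  }
  invisible(x)
}

#' Clean one small-RNA library
#'
#' Classifies every read, discards the contaminant categories and returns
#' the clean trimmed inserts together with the accounting summary.
#'
#' @param fastq path to a FASTQ file, or a reads data frame
#'   (`id`, `seq`, `qual`) as produced by [simulate_srna_library()].
#' @inheritParams classify_reads
#' @return list with `tags` (data frame: id, insert) and `summary`
#'   (a [cleaning_summary()]).
#' @export
clean_library <- function(fastq, adapters = default_adapters(),
                          quality = quality_rule(), min_len = 18,
                          max_len = 44) {
  reads <- if (is.character(fastq)) read_fastq(fastq) else fastq
  cl <- classify_reads(reads$seq, reads$qual, adapters, quality,
                       min_len, max_len)
  tab <- function(k) sum(cl$category == k)
  summ <- cleaning_summary(nrow(reads), tab("adapter3_null"),
                           tab("insert_null"), tab("adapter5_contaminant"),
                           tab("too_short"), tab("polyA"), tab("clean"))
  keep <- cl$category == "clean"
  list(tags = data.frame(id = reads$id[keep], insert = cl$insert[keep],
                         stringsAsFactors = FALSE),
       summary = summ, categories = cl$category)
}

#' Insert length histogram over the sequencing size window
#'
#' @param lengths integer insert lengths (or a character vector of
#'   sequences, whose nchar is used).
#' @param range (min, max) length window, default the 10-44 nt gel window.
#' @return object of class `length_histogram`: named `counts` per length
#'   and `total`.
#' @export
length_histogram <- function(lengths, range = c(10, 44)) {
  if (is.character(lengths)) lengths <- nchar(lengths)
  lengths <- lengths[lengths >= range[1] & lengths <= range[2]]
  bins <- range[1]:range[2]
  counts <- stats::setNames(tabulate(factor(lengths, levels = bins),
                                     nbins = length(bins)), bins)
  structure(list(counts = counts, total = sum(counts)),
            class = "length_histogram")
}

#' Compare two length distributions by Pearson chi-square
#'
#' Contingency-table analysis of two insert-length histograms: bins with
#' zero combined count are dropped, the remaining 2 x K table is tested
#' without continuity correction.
#'
#' @param hist_a,hist_b [length_histogram()] objects (or named count
#'   vectors over identical bins).
#' @return list with `statistic` (X^2), `df`, and `p.value`.
#' @export
chi2_length_test <- function(hist_a, hist_b) {
  ca <- if (inherits(hist_a, "length_histogram")) hist_a$counts else hist_a
  cb <- if (inherits(hist_b, "length_histogram")) hist_b$counts else hist_b
  stopifnot(length(ca) == length(cb))
  if (sum(ca) == 0 || sum(cb) == 0) {
    stop("both histograms must contain at least one tag")
  }
  keep <- (ca + cb) > 0
  if (sum(keep) < 2) stop("need at least 2 bins with nonzero combined counts")
  m <- rbind(ca[keep], cb[keep])
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = unname(ht$p.value))
}
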