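#' Collapse clean reads to unique tags with per-library counts
#'
#' One tag per distinct insert sequence, carrying its copy number in each
#' library; tags whose total copy number across both libraries falls below
#' `min_count` (singletons, at the default of 2) are discarded.
#'
#' @param reads_a,reads_b character vectors of clean insert sequences (one
#'   entry per read) for the two libraries.
#' @param min_count minimum total copies to keep a tag (default 2; use 1
#'   to keep singletons).
#' @return data frame ordered by sequence: `sequence`, `count_a`,
#'   `count_b`, `total`.
#' @export
collapse_tags <- function(reads_a, reads_b = character(0), min_count = 2) {
  seqs <- sort(unique(c(reads_a, reads_b)))
  ca <- table(factor(reads_a, levels = seqs))
  cb <- table(factor(reads_b, levels = seqs))
  out <- data.frame(sequence = seqs, count_a = as.integer(ca),
                    count_b = as.integer(cb), stringsAsFactors = FALSE)
  out$total <- out$count_a + out$count_b
  out[out$total >= min_count, , drop = FALSE]
}

#' Map tags to the genome allowing at most one mismatch
#'
#' Both strands are searched with Biostrings substitution-only matching;
#' when a tag has any perfect locus, its 1-mismatch loci are suppressed
#' (best-stratum reporting). Every locus is re-verified by direct sequence
#' comparison.
#'
#' @param tags collapsed tag table from [collapse_tags()] (or any data
#'   frame with a `sequence` column).
#' @param genome a [make_genome()] object or a single genome string.
#' @param max_mismatch maximum substitutions (default 1).
#' @return the tag table with added columns `mapped`, `best_mm`, `n_loci`
#'   and a list-column `loci` of per-tag data frames (`start`, `end`,
#'   `strand`, `mismatches`, 1-based).
#' @export
map_tags <- function(tags, genome, max_mismatch = 1) {
  gseq <- if (inherits(genome, "GenomeModel")) genome$sequence else genome
  assert_dna(tags$sequence, allow_n = TRUE, what = "tag")
  subject <- Biostrings::DNAString(gseq)
  loci <- vector("list", nrow(tags))
  for (r in seq_len(nrow(tags))) {
    tag <- toupper(tags$sequence[r])
    hits <- list()
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") tag else revcomp(tag)
      m <- Biostrings::matchPattern(pat, subject, max.mismatch = max_mismatch,
                                    with.indels = FALSE)
      m <- m[Biostrings::start(m) >= 1 &
               Biostrings::end(m) <= length(subject)]
      if (length(m) == 0) next
      mm <- vapply(seq_along(m), function(k) {
        sum(strsplit(as.character(m[[k]]), "")[[1]] !=
              strsplit(pat, "")[[1]])
      }, integer(1))
      ok <- mm <= max_mismatch
      if (!any(ok)) next
      hits[[strand]] <- data.frame(start = Biostrings::start(m)[ok],
                                   end = Biostrings::end(m)[ok],
                                   strand = strand, mismatches = mm[ok],
                                   stringsAsFactors = FALSE)
    }
    h <- do.call(rbind, hits)
    if (!is.null(h) && nrow(h)) {
      best <- min(h$mismatches)
      h <- h[h$mismatches == best, , drop = FALSE]
      h <- h[order(h$start, h$strand), , drop = FALSE]
      rownames(h) <- NULL
      loci[[r]] <- h
    } else {
      loci[[r]] <- data.frame(start = integer(0), end = integer(0),
                              strand = character(0), mismatches = integer(0),
                              stringsAsFactors = FALSE)
    }
  }
  tags$loci <- loci
  tags$n_loci <- vapply(loci, nrow, integer(1))
  tags$mapped <- tags$n_loci > 0
  tags$best_mm <- vapply(loci, function(h) {
    if (nrow(h)) min(h$mismatches) else NA_integer_
  }, integer(1))
  tags
}

#' Annotate mapped tags into small-RNA classes
#'
#' Class precedence is miRNA > rRNAetc > unann: a tag whose sequence
#' matches a catalog mature sequence (T/U-insensitive, exact) is miRNA; a
#' tag with a best locus overlapping an rRNA feature is rRNAetc; remaining
#' tags are unannotated (`unann`), with unmapped tags flagged separately.
#'
#' @param tags mapped tag table from [map_tags()].
#' @param features `GRanges` annotation with a `kind` column (as in a
#'   [make_genome()] object).
#' @param catalog named character vector of known mature sequences.
#' @return list with `tags` (the table plus an `annotation` column) and
#'   `summary` (a [class_summary()] over unique tags and read totals,
#'   unmapped counted with `unann`).
#' @export
annotate_tags <- function(tags, features, catalog = character(0)) {
  ann <- rep("unann", nrow(tags))
  ann[!tags$mapped] <- "unmapped"
  if (length(catalog)) {
    is_mir <- dna_norm(tags$sequence) %in% dna_norm(catalog)
  } else is_mir <- rep(FALSE, nrow(tags))
  rrna <- features[features$kind == "rRNA"]
  hits_rrna <- vapply(seq_len(nrow(tags)), function(r) {
    h <- tags$loci[[r]]
    if (!nrow(h)) return(FALSE)
    q <- GenomicRanges::GRanges("chr", IRanges::IRanges(h$start, h$end))
    length(GenomicRanges::findOverlaps(q, rrna)) > 0
  }, logical(1))
  ann[hits_rrna] <- "rRNAetc"
  ann[is_mir] <- "miRNA"
  tags$annotation <- ann
  grp <- ifelse(ann == "unmapped", "unann", ann)
  uniq <- vapply(c("miRNA", "rRNAetc", "unann"),
                 function(k) sum(grp == k), numeric(1))
  tot <- vapply(c("miRNA", "rRNAetc", "unann"),
                function(k) sum(tags$total[grp == k]), numeric(1))
  list(tags = tags, summary = class_summary(uniq, tot))
}

#' Small-RNA class summary table
#'
#' Formats unique-tag and total-read counts per class with percentages of
#' their respective totals, two decimals, half-up — the layout of the
#' published class table.
#'
#' @param unique_counts,total_counts named numeric vectors of per-class
#'   counts (unique tags, total reads).
#' @param unique_total,total_total optional denominators; default the
#'   column sums.
#' @return data frame with class, unique count/pct, total count/pct, and
#'   a leading `Total sRNAs` row.
#' @export
class_summary <- function(unique_counts, total_counts,
                          unique_total = sum(unique_counts),
                          total_total = sum(total_counts)) {
  stopifnot(length(unique_counts) == length(total_counts))
  data.frame(
    class = c("Total sRNAs", names(unique_counts)),
    unique = c(unique_total, unname(unique_counts)),
    unique_pct = c(pct_of(unique_total, unique_total),
                   pct_of(unname(unique_counts), unique_total)),
    total = c(total_total, unname(total_counts)),
    total_pct = c(pct_of(total_total, total_total),
                  pct_of(unname(total_counts), total_total)),
    stringsAsFactors = FALSE)
}

#' Shared and library-specific tag summary
#'
#' A tag is shared when it has copies in both libraries; the unique-tag
#' and read-count partitions are reported with percentages of their
#' totals, the layout of the published common/specific table.
#'
#' @param tags collapsed tag table with `count_a`, `count_b`.
#' @return data frame from [overlap_table()].
#' @export
overlap_summary <- function(tags) {
  a_spec <- tags$count_a > 0 & tags$count_b == 0
  b_spec <- tags$count_b > 0 & tags$count_a == 0
  shared <- tags$count_a > 0 & tags$count_b > 0
  overlap_table(
    unique_counts = c(a_specific = sum(a_spec), b_specific = sum(b_spec),
                      shared = sum(shared)),
    read_counts = c(a_specific = sum(tags$count_a[a_spec]),
                    b_specific = sum(tags$count_b[b_spec]),
                    shared = sum(tags$count_a[shared] + tags$count_b[shared])))
}

#' Format shared/specific counts with percentages
#'
#' @param unique_counts,read_counts named numeric vectors with entries
#'   `a_specific`, `b_specific`, `shared`.
#' @return data frame with a `Total` row and percentage columns (two
#'   decimals, half-up).
#' @export
overlap_table <- function(unique_counts, read_counts) {
  ut <- sum(unique_counts); rt <- sum(read_counts)
  data.frame(
    set = c("Total", "a_specific", "b_specific", "shared"),
    unique = c(ut, unname(unique_counts)),
    unique_pct = c(pct_of(ut, ut), pct_of(unname(unique_counts), ut)),
    reads = c(rt, unname(read_counts)),
    reads_pct = c(pct_of(rt, rt), pct_of(unname(read_counts), rt)),
    stringsAsFactors = FALSE)
}
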