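#' Minimum-free-energy secondary structure of a short sequence
#'
#' Exact dynamic program over all non-crossing structures under the
#' simplified nearest-neighbour model of [energy_model()]. Every base pair
#' must enclose at least `min_loop` bases; hairpin loops, bulges, internal
#' loops and multiloops are charged as documented there. The empty
#' structure has energy 0, so the reported MFE is never positive.
#'
#' @param seq nucleotide sequence (ACGU/ACGT, case-insensitive), at most
#'   100 nt by convention of the 100-nt discovery windows (longer input is
#'   allowed but quartic in length).
#' @param model an [energy_model()].
#' @return list with `structure` (dot-bracket) and `mfe` (kcal/mol).
#' @export
fold_mfe <- function(seq, model = energy_model()) {
  if (length(seq) != 1 || !nzchar(seq)) stop("seq must be a single non-empty string")
  assert_dna(seq)
  res <- fold_mfe_cpp(seq, unname(model$stack), model$hairpin_loop,
                      model$bulge_per_nt, model$internal_per_nt,
                      model$min_loop)
  list(structure = res$structure, mfe = res$mfe)
}

#' Extract the genomic window around a mapped tag
#'
#' Takes the (up to) `window` nt of genomic sequence centred on a mapped
#' tag, truncating at contig ends, and translates the tag's span into
#' window coordinates. Minus-strand loci are reverse-complemented so the
#' returned window reads 5' to 3' on the tag's strand.
#'
#' @param genome a [make_genome()] object or a single genome string.
#' @param start,end 1-based inclusive genomic span of the mapped tag.
#' @param strand `"+"` or `"-"`.
#' @param window window length in nt (default 100).
#' @return list with `seq`, `mature_span` (1-based within the window),
#'   `genome_start`, `genome_end`.
#' @export
extract_window <- function(genome, start, end, strand = "+", window = 100) {
  gseq <- if (inherits(genome, "GenomeModel")) genome$sequence else genome
  n <- nchar(gseq)
  if (start < 1 || end > n || start > end) stop("locus outside genome bounds")
  pad <- window - (end - start + 1)
  if (pad < 0) stop("tag longer than the requested window")
  left <- pad %/% 2
  ws <- max(1, start - left)
  we <- min(n, ws + window - 1)
  ws <- max(1, we - window + 1)
  seq <- substr(gseq, ws, we)
  span <- c(start - ws + 1, end - ws + 1)
  if (strand == "-") {
    seq <- revcomp(seq)
    L <- we - ws + 1
    span <- c(L - span[2] + 1, L - span[1] + 1)
  }
  list(seq = seq, mature_span = span, genome_start = ws, genome_end = we)
}

#' Build a hairpin candidate from a window
#'
#' Folds the window and assembles the candidate record used by
#' [criteria_check()]: MFE structure, the arm carrying the putative mature
#' sequence (5p if it ends before the terminal loop, 3p if it starts after
#' it), and the genomic location class.
#'
#' @param window_seq window sequence (<= 100 nt).
#' @param mature_span 1-based (start, end) of the mature sequence within
#'   the window.
#' @param location_class one of `"intergenic"`, `"intron"`, `"exon"`,
#'   `"rRNA"`.
#' @param model an [energy_model()].
#' @return list of class `hairpin_candidate`.
#' @export
hairpin_candidate <- function(window_seq, mature_span, location_class,
                              model = energy_model()) {
  if (nchar(window_seq) > 100) stop("window exceeds 100 nt")
  stopifnot(length(mature_span) == 2, mature_span[1] >= 1,
            mature_span[2] <= nchar(window_seq))
  f <- fold_mfe(window_seq, model)
  loops <- hairpin_loops(f$structure)
  # the arm is judged against the terminal loop of the mature's own
  # stem-loop — the nearest hairpin loop — so that small independent folds
  # in the window flanks do not obscure a clean 5p/3p placement
  arm <- "none"
  if (nrow(loops)) {
    dist <- ifelse(loops$start > mature_span[2], loops$start - mature_span[2],
                   ifelse(loops$end < mature_span[1],
                          mature_span[1] - loops$end, 0L))
    nearest <- loops[which.min(dist), ]
    if (mature_span[2] < nearest$start) arm <- "5p"
    if (mature_span[1] > nearest$end) arm <- "3p"
  }
  structure(list(window_seq = window_seq, structure = f$structure,
                 mfe = f$mfe, mature_span = mature_span, arm = arm,
                 location_class = location_class),
            class = "hairpin_candidate")
}

# hairpin (terminal) loops of a dot-bracket structure: maximal unpaired
# runs directly closed by a pair with no nested pair
hairpin_loops <- function(structure) {
  pairs <- db_pairs(structure)
  out <- data.frame(start = integer(0), end = integer(0))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    inside <- pairs[, 1] > i & pairs[, 2] < j
    if (!any(inside)) out <- rbind(out, data.frame(start = i + 1, end = j - 1))
  }
  out
}

#' Apply the three miRNA-candidate criteria to a hairpin
#'
#' A candidate passes when all of: (a) the mature sequence lies entirely on
#' one arm of the hairpin (5' or 3' of the terminal loop) and contains no
#' unpaired run longer than `max_unpaired_run` (no large internal loops or
#' bulges within the mature span); (b) the fold is steady, with MFE
#' strictly below `mfe_cutoff` kcal/mol; (c) the hairpin lies in an
#' intergenic region or an intron.
#'
#' @param candidate a [hairpin_candidate()].
#' @param mfe_cutoff free-energy threshold, default -20 kcal/mol.
#' @param max_unpaired_run longest tolerated unpaired run inside the
#'   mature span, default 4 nt.
#' @return list with `pass` (logical) and `failed` (character vector among
#'   `"a"`, `"b"`, `"c"`).
#' @export
criteria_check <- function(candidate, mfe_cutoff = -20, max_unpaired_run = 4) {
  stopifnot(inherits(candidate, "hairpin_candidate"))
  failed <- character(0)
  sp <- candidate$mature_span
  chars <- strsplit(candidate$structure, "")[[1]]
  mat <- chars[sp[1]:sp[2]]
  runs <- rle(mat == ".")
  longest_unpaired <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0
  if (candidate$arm == "none" || longest_unpaired > max_unpaired_run) {
    failed <- c(failed, "a")
  }
  if (!(candidate$mfe < mfe_cutoff)) failed <- c(failed, "b")
  if (!candidate$location_class %in% c("intergenic", "intron")) {
    failed <- c(failed, "c")
  }
  list(pass = length(failed) == 0, failed = failed)
}

#' Match a mature sequence against a known-miRNA catalog
#'
#' Exact (default) sequence identity against the catalog's mature
#' sequences, T/U-insensitive; with `max_mismatch > 0`, equal-length
#' Hamming matching. Ties are broken lexicographically by name.
#'
#' @param mature_seq the candidate mature sequence.
#' @param catalog named character vector of catalog mature sequences (e.g.
#'   from [read_fasta()]).
#' @param max_mismatch maximum substitutions tolerated (default 0).
#' @return the catalog name, or `"novel"`.
#' @export
match_catalog <- function(mature_seq, catalog, max_mismatch = 0) {
  q <- dna_norm(mature_seq)
  cat_seqs <- dna_norm(catalog)
  same_len <- nchar(cat_seqs) == nchar(q)
  if (!any(same_len)) return("novel")
  dists <- rep(NA_integer_, length(catalog))
  qs <- strsplit(q, "")[[1]]
  dists[same_len] <- vapply(strsplit(cat_seqs[same_len], ""),
                            function(s) sum(s != qs), integer(1))
  hit <- which(!is.na(dists) & dists <= max_mismatch)
  if (!length(hit)) return("novel")
  sort(names(catalog)[hit])[1]
}

#' Shared and specific known-miRNA inventories of two libraries
#'
#' @param known_a,known_b character vectors of known-miRNA names observed
#'   in each library.
#' @return list with the three name sets (`a_specific`, `b_specific`,
#'   `shared`) and a named count vector `counts` including the per-library
#'   totals.
#' @export
inventory_overlap <- function(known_a, known_b) {
  a <- unique(known_a); b <- unique(known_b)
  shared <- intersect(a, b)
  a_spec <- setdiff(a, b); b_spec <- setdiff(b, a)
  list(a_specific = sort(a_spec), b_specific = sort(b_spec),
       shared = sort(shared),
       counts = c(a_specific = length(a_spec), b_specific = length(b_spec),
                  shared = length(shared),
                  total_a = length(a_spec) + length(shared),
                  total_b = length(b_spec) + length(shared)))
}

#' Discover miRNA hairpin candidates from mapped tags
#'
#' For every mapped tag of mature-miRNA length, extracts the 100-nt window
#' around its best locus, folds it, applies the three candidate criteria
#' and reconciles the mature sequence against the known catalog.
#'
#' @param tags mapped tag table from [map_tags()].
#' @param genome a [make_genome()] object.
#' @param catalog named character vector of known mature sequences.
#' @param model an [energy_model()].
#' @param window window length (default 100).
#' @param mature_len_range tag lengths considered as putative matures
#'   (default 20-22 nt).
#' @param mfe_cutoff,max_unpaired_run criteria thresholds, see
#'   [criteria_check()].
#' @return data frame of candidates: sequence, window coordinates,
#'   structure, mfe, arm, location class, verdict, failed criteria, and
#'   catalog name.
#' @export
discover_hairpins <- function(tags, genome, catalog = character(0),
                              model = energy_model(), window = 100,
                              mature_len_range = c(20, 22),
                              mfe_cutoff = -20, max_unpaired_run = 4) {
  rows <- list()
  for (r in seq_len(nrow(tags))) {
    seq <- tags$sequence[r]
    L <- nchar(seq)
    if (L < mature_len_range[1] || L > mature_len_range[2]) next
    loci <- tags$loci[[r]]
    if (is.null(loci) || nrow(loci) == 0) next
    loc <- loci[1, ]
    win <- extract_window(genome, loc$start, loc$end, loc$strand, window)
    lc <- location_class(genome$features, loc$start, loc$end)
    cand <- hairpin_candidate(win$seq, win$mature_span, lc, model)
    v <- criteria_check(cand, mfe_cutoff, max_unpaired_run)
    rows[[length(rows) + 1]] <- data.frame(
      sequence = seq, window_start = win$genome_start,
      window_end = win$genome_end, strand = loc$strand,
      structure = cand$structure, mfe = cand$mfe, arm = cand$arm,
      location_class = lc, pass = v$pass,
      failed = paste(v$failed, collapse = ","),
      catalog_name = if (length(catalog)) match_catalog(seq, catalog) else "novel",
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(sequence = character(0), window_start = integer(0),
                      window_end = integer(0), strand = character(0),
                      structure = character(0), mfe = numeric(0),
                      arm = character(0), location_class = character(0),
                      pass = logical(0), failed = character(0),
                      catalog_name = character(0)))
  }
  do.call(rbind, rows)
}

# genomic location class of a span: the finest feature kind it overlaps,
# with exon > intron > rRNA > intergenic precedence so that anything
# touching an exon is called exonic
location_class <- function(features, start, end) {
  q <- GenomicRanges::GRanges("chr", IRanges::IRanges(start, end))
  hits <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(q, features))
  kinds <- unique(features$kind[hits])
  for (k in c("exon", "rRNA", "intron", "intergenic")) {
    if (k %in% kinds) return(k)
  }
  "intergenic"
}
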