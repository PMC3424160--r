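#' Configuration for a synthetic genome
#'
#' Describes the layout the generator packs into one contig: genes made of
#' exons and introns, standalone rRNA features, the intergenic gaps between
#' them, and hairpin loci carrying planted mature miRNAs.
#'
#' @param genome_length contig length in nt.
#' @param n_genes number of genes.
#' @param exons_per_gene exons per gene (introns fill between them).
#' @param exon_len,intron_len (min, max) nt ranges for exon and intron
#'   lengths.
#' @param n_rrna number of rRNA features.
#' @param rrna_len (min, max) nt range for rRNA lengths.
#' @param n_hairpins number of planted miRNA hairpins.
#' @param hairpin_in feature kinds eligible to host hairpins; the legal
#'   locations are `"intergenic"` and `"intron"`, but `"exon"` is accepted
#'   so that illegally placed hairpins can be generated for negative
#'   controls.
#' @param mature_len (min, max) planted mature miRNA length (20-22 nt).
#' @param stem_pairs,loop_len hairpin geometry passed to [make_hairpin()].
#' @param min_gap minimum intergenic gap flanking each feature block.
#' @return list of class `genome_config`.
#' @export
genome_config <- function(genome_length = 10000, n_genes = 3,
                          exons_per_gene = 2, exon_len = c(200, 400),
                          intron_len = c(80, 150), n_rrna = 1,
                          rrna_len = c(100, 150), n_hairpins = 2,
                          hairpin_in = "intergenic", mature_len = c(20, 22),
                          stem_pairs = 26, loop_len = 8, min_gap = 60) {
  stopifnot(genome_length > 0, n_genes >= 0, exons_per_gene >= 1,
            n_rrna >= 0, n_hairpins >= 0)
  if (!all(hairpin_in %in% c("intergenic", "intron", "exon"))) {
    stop("hairpin_in must be among intergenic, intron, exon")
  }
  structure(as.list(environment()), class = "genome_config")
}

#' Build a hairpin precursor around a mature miRNA
#'
#' Constructs a perfect stem-loop: the 5' arm is the mature sequence
#' extended by a G/C clamp to `stem_pairs` positions, the 3' arm is its
#' reverse complement, and an unpaired A-loop of `loop_len` nt joins them.
#' The mature strand therefore sits verbatim and fully paired on the 5'
#' arm.
#'
#' @param mature mature miRNA sequence, 20-22 nt (ACGU/ACGT).
#' @param stem_pairs number of stem base pairs (>= nchar(mature)).
#' @param loop_len terminal loop length (>= 3).
#' @return list with `precursor` (DNA string), `mature_start`,
#'   `mature_end` (1-based within the precursor).
#' @export
make_hairpin <- function(mature, stem_pairs = 26, loop_len = 8) {
  mature <- dna_norm(mature)
  assert_dna(mature, what = "mature")
  L <- nchar(mature)
  if (L < 20 || L > 22) stop("mature must be 20-22 nt")
  if (stem_pairs < L) stop("stem_pairs must be >= the mature length")
  if (loop_len < 3) stop("loop_len must be >= 3")
  total <- 2 * stem_pairs + loop_len
  if (total > 100) {
    stop("hairpin of ", total, " nt exceeds the 100 nt discovery window")
  }
  clamp <- paste(rep(c("G", "C"), length.out = stem_pairs - L), collapse = "")
  arm5 <- paste0(mature, clamp)
  precursor <- paste0(arm5, strrep("A", loop_len), revcomp(arm5))
  list(precursor = precursor, mature_start = 1L, mature_end = L)
}

#' Generate a synthetic genome with annotated features and planted hairpins
#'
#' Packs the configured gene, rRNA and hairpin features into one contig of
#' random sequence, with explicit intergenic features filling the gaps.
#' Deterministic given `seed`.
#'
#' @param config a [genome_config()].
#' @param seed integer seed.
#' @return object of class `GenomeModel`: list with `sequence` (character),
#'   `features` (`GRanges` with a `kind` column among gene/exon/intron/
#'   rRNA/intergenic and per-feature `name`), and `hairpins` (data frame of
#'   planted hairpin loci with mature coordinates and sequences).
#' @export
make_genome <- function(config = genome_config(), seed = 1) {
  stopifnot(inherits(config, "genome_config"))
  withr::with_seed(seed, make_genome_impl(config))
}

make_genome_impl <- function(cfg) {
  runi <- function(r, n = 1) if (r[1] >= r[2]) rep(r[1], n) else sample(r[1]:r[2], n, replace = TRUE)
  blocks <- list()
  for (g in seq_len(cfg$n_genes)) {
    ex <- runi(cfg$exon_len, cfg$exons_per_gene)
    intr <- if (cfg$exons_per_gene > 1) runi(cfg$intron_len, cfg$exons_per_gene - 1) else integer(0)
    blocks[[length(blocks) + 1]] <- list(type = "gene", name = paste0("gene", g),
                                         exons = ex, introns = intr,
                                         len = sum(ex) + sum(intr))
  }
  for (r in seq_len(cfg$n_rrna)) {
    blocks[[length(blocks) + 1]] <- list(type = "rRNA", name = paste0("rRNA", r),
                                         len = runi(cfg$rrna_len))
  }
  nb <- length(blocks)
  total_blocks <- sum(vapply(blocks, `[[`, numeric(1), "len"))
  slack <- cfg$genome_length - total_blocks - cfg$min_gap * (nb + 1)
  if (slack < 0) {
    stop("genome_length ", cfg$genome_length, " cannot hold ", nb,
         " features of total length ", total_blocks,
         " with minimum gaps; increase genome_length")
  }
  blocks <- blocks[sample.int(nb)]
  extra <- if (nb >= 0 && slack > 0) {
    as.vector(stats::rmultinom(1, slack, rep(1, nb + 1)))
  } else rep(0L, nb + 1)
  gaps <- cfg$min_gap + extra

  kind <- character(0); starts <- integer(0); ends <- integer(0); fname <- character(0)
  pos <- 1L
  add_feat <- function(k, s, e, nm) {
    kind <<- c(kind, k); starts <<- c(starts, s); ends <<- c(ends, e)
    fname <<- c(fname, nm)
  }
  for (b in seq_len(nb)) {
    gap <- gaps[b]
    add_feat("intergenic", pos, pos + gap - 1L, paste0("ig", b))
    pos <- pos + gap
    blk <- blocks[[b]]
    if (blk$type == "gene") {
      gstart <- pos
      for (e in seq_along(blk$exons)) {
        add_feat("exon", pos, pos + blk$exons[e] - 1L,
                 paste0(blk$name, "_exon", e))
        pos <- pos + blk$exons[e]
        if (e <= length(blk$introns)) {
          add_feat("intron", pos, pos + blk$introns[e] - 1L,
                   paste0(blk$name, "_intron", e))
          pos <- pos + blk$introns[e]
        }
      }
      add_feat("gene", gstart, pos - 1L, blk$name)
    } else {
      add_feat("rRNA", pos, pos + blk$len - 1L, blk$name)
      pos <- pos + blk$len
    }
  }
  add_feat("intergenic", pos, cfg$genome_length, paste0("ig", nb + 1))

  sequence <- rand_dna(cfg$genome_length)
  features <- GenomicRanges::GRanges("chr", IRanges::IRanges(starts, ends),
                                     strand = "+", kind = kind, name = fname)

  hairpins <- data.frame(name = character(0), start = integer(0),
                         end = integer(0), strand = character(0),
                         mature_start = integer(0), mature_end = integer(0),
                         mature_seq = character(0), kind = character(0),
                         stringsAsFactors = FALSE)
  used <- IRanges::IRanges()
  host_idx <- which(kind %in% cfg$hairpin_in)
  for (h in seq_len(cfg$n_hairpins)) {
    mat_len <- runi(cfg$mature_len)
    hp <- make_hairpin(rand_dna(mat_len), cfg$stem_pairs, cfg$loop_len)
    hp_len <- nchar(hp$precursor)
    placed <- FALSE
    for (try in 1:200) {
      fi <- host_idx[sample.int(length(host_idx), 1)]
      room <- ends[fi] - starts[fi] + 1L - hp_len - 2L
      if (room < 1) next
      s <- starts[fi] + sample.int(room, 1)
      cand <- IRanges::IRanges(s, s + hp_len - 1L)
      if (length(IRanges::findOverlaps(cand, used))) next
      used <- c(used, cand)
      substr(sequence, s, s + hp_len - 1L) <- hp$precursor
      hairpins <- rbind(hairpins, data.frame(
        name = paste0("syn-mir-", h), start = s, end = s + hp_len - 1L,
        strand = "+", mature_start = s + hp$mature_start - 1L,
        mature_end = s + hp$mature_end - 1L,
        mature_seq = substr(hp$precursor, hp$mature_start, hp$mature_end),
        kind = kind[fi], stringsAsFactors = FALSE))
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place hairpin ", h,
                      " in the requested feature kinds; enlarge the genome")
  }
  structure(list(sequence = sequence, features = features,
                 hairpins = hairpins, config = cfg),
            class = "GenomeModel")
}

#' Planted mature miRNA catalog of a synthetic genome
#'
#' @param genome a [make_genome()] object.
#' @return named character vector of mature sequences.
#' @export
mirna_catalog <- function(genome) {
  stopifnot(inherits(genome, "GenomeModel"))
  stats::setNames(genome$hairpins$mature_seq, genome$hairpins$name)
}

#' Small-RNA library profile
#'
#' The per-read class mix and read geometry of one simulated library. The
#' default mix follows the rates observed in a deep royal-jelly small-RNA
#' library: a fraction of a percent of reads lost to quality, empty or
#' missing adapters and 5' contamination, roughly 12% inserts below 18 nt,
#' and the clean remainder split between rRNA fragments, degradation
#' products and a small mature-miRNA fraction.
#'
#' @param n_reads number of reads.
#' @param class_mix named proportions over the nine read classes
#'   (normalised internally): `mature_miRNA`, `rRNA_fragment`,
#'   `degradation`, `adapter3_null`, `insert_null`,
#'   `adapter5_contaminant`, `too_short`, `polyA`, `low_quality`.
#' @param length_range (min, max) insert length for the clean insert
#'   classes, within 10-44 nt.
#' @param read_length raw read length (>= max insert + 3' adapter).
#' @param adapter3,adapter5 adapter sequences (arbitrary fixed 12-mers by
#'   default).
#' @param seed integer seed.
#' @return list of class `library_profile`.
#' @export
library_profile <- function(n_reads = 10000,
                            class_mix = c(mature_miRNA = 0.00068,
                                          rRNA_fragment = 0.33558,
                                          degradation = 0.53601,
                                          adapter3_null = 0.00495,
                                          insert_null = 0.00019,
                                          adapter5_contaminant = 0.00091,
                                          too_short = 0.11814,
                                          polyA = 0.00003,
                                          low_quality = 0.00351),
                            length_range = c(18, 44), read_length = 60,
                            adapter3 = "TGGAATTCTCGG",
                            adapter5 = "GTTCAGAGTTCT", seed = 1) {
  classes <- c("mature_miRNA", "rRNA_fragment", "degradation",
               "adapter3_null", "insert_null", "adapter5_contaminant",
               "too_short", "polyA", "low_quality")
  if (!all(names(class_mix) %in% classes)) {
    stop("unknown class in class_mix: ",
         paste(setdiff(names(class_mix), classes), collapse = ", "))
  }
  mix <- stats::setNames(rep(0, length(classes)), classes)
  mix[names(class_mix)] <- class_mix
  if (any(mix < 0) || sum(mix) <= 0) stop("class_mix must be non-negative and not all zero")
  mix <- mix / sum(mix)
  if (length_range[1] < 10 || length_range[2] > 44 ||
      length_range[1] > length_range[2]) {
    stop("length_range must lie within [10, 44]")
  }
  if (read_length < length_range[2] + nchar(adapter3)) {
    stop("read_length must cover the longest insert plus the 3' adapter")
  }
  structure(list(n_reads = as.integer(n_reads), class_mix = mix,
                 length_range = as.integer(length_range),
                 read_length = as.integer(read_length),
                 adapter3 = dna_norm(adapter3), adapter5 = dna_norm(adapter5),
                 seed = as.integer(seed)),
            class = "library_profile")
}

#' Simulate one small-RNA sequencing library
#'
#' Draws read classes from the profile mix and emits Phred+33 reads with a
#' full truth table. Clean-insert classes (mature miRNA, rRNA fragment,
#' degradation product) are genuine genomic subsequences followed by the 3'
#' adapter and random fill; the contaminant classes reproduce the standard
#' cleaning failure modes (missing 3' adapter, adapter dimer, 5' adapter
#' carried into the insert, insert below 18 nt, poly(A), low quality).
#'
#' @param genome a [make_genome()] object.
#' @param profile a [library_profile()].
#' @return list with `reads` (data frame: id, seq, qual) and `truth`
#'   (data frame: read id, generating class, the cleaning category it must
#'   be assigned, insert sequence and length).
#' @export
simulate_srna_library <- function(genome, profile) {
  stopifnot(inherits(genome, "GenomeModel"), inherits(profile, "library_profile"))
  withr::with_seed(profile$seed, simulate_srna_impl(genome, profile))
}

simulate_srna_impl <- function(genome, pr) {
  n <- pr$n_reads
  empty <- data.frame(id = character(0), seq = character(0), qual = character(0),
                      stringsAsFactors = FALSE)
  etruth <- data.frame(read_id = character(0), class = character(0),
                       expected_category = character(0), insert = character(0),
                       insert_len = integer(0), stringsAsFactors = FALSE)
  if (n == 0) return(list(reads = empty, truth = etruth))
  classes <- sample(names(pr$class_mix), n, replace = TRUE, prob = pr$class_mix)
  lr <- c(max(18L, pr$length_range[1]), pr$length_range[2])
  feats <- genome$features
  exon_rows <- which(feats$kind == "exon")
  rrna_rows <- which(feats$kind == "rRNA")
  matures <- genome$hairpins$mature_seq

  frag_from <- function(rows, L) {
    fi <- rows[sample.int(length(rows), 1)]
    s <- GenomicRanges::start(feats)[fi]
    e <- GenomicRanges::end(feats)[fi]
    L <- min(L, e - s + 1)
    off <- s + sample.int(e - s + 2 - L, 1) - 1L
    substr(genome$sequence, off, off + L - 1L)
  }

  inserts <- character(n)
  cat_map <- c(mature_miRNA = "clean", rRNA_fragment = "clean",
               degradation = "clean", adapter3_null = "adapter3_null",
               insert_null = "insert_null",
               adapter5_contaminant = "adapter5_contaminant",
               too_short = "too_short", polyA = "polyA",
               low_quality = "low_quality")
  for (r in seq_len(n)) {
    cl <- classes[r]
    inserts[r] <- switch(cl,
      mature_miRNA = {
        if (!length(matures)) stop("profile requests mature_miRNA reads but the genome has no hairpins")
        matures[sample.int(length(matures), 1)]
      },
      rRNA_fragment = {
        if (!length(rrna_rows)) stop("profile requests rRNA_fragment reads but the genome has no rRNA features")
        frag_from(rrna_rows, sample(lr[1]:lr[2], 1))
      },
      degradation = {
        if (!length(exon_rows)) stop("profile requests degradation reads but the genome has no exons")
        frag_from(exon_rows, sample(lr[1]:lr[2], 1))
      },
      adapter3_null = rand_dna(pr$read_length),
      insert_null = "",
      adapter5_contaminant = paste0(pr$adapter5, rand_dna(sample(8:12, 1))),
      too_short = rand_dna(sample(10:17, 1)),
      polyA = strrep("A", sample(lr[1]:lr[2], 1)),
      low_quality = rand_dna(sample(lr[1]:lr[2], 1))
    )
  }
  seqs <- character(n)
  no_adapter <- classes == "adapter3_null"
  seqs[no_adapter] <- inserts[no_adapter]
  if (any(!no_adapter)) {
    body <- paste0(inserts[!no_adapter], pr$adapter3)
    fill_len <- pmax(0L, pr$read_length - nchar(body))
    fill <- vapply(fill_len, function(L) if (L > 0) rand_dna(L) else "", character(1))
    seqs[!no_adapter] <- substr(paste0(body, fill), 1L, pr$read_length)
  }
  quals <- ifelse(classes == "low_quality",
                  strrep("#", nchar(seqs)), strrep("I", nchar(seqs)))
  ids <- sprintf("read%06d", seq_len(n))
  list(reads = data.frame(id = ids, seq = seqs, qual = quals,
                          stringsAsFactors = FALSE),
       truth = data.frame(read_id = ids, class = classes,
                          expected_category = unname(cat_map[classes]),
                          insert = inserts, insert_len = nchar(inserts),
                          stringsAsFactors = FALSE))
}

#' Expression ground truth for two transcriptome samples
#'
#' The generative model behind [simulate_counts()]: per-gene baseline mean
#' counts at the sample-1 sequencing depth, planted log2 fold changes (0
#' for null genes), the two library sizes, and a common overdispersion.
#'
#' @param n_genes number of genes (used when lengths/means are not given).
#' @param gene_lengths nt per gene; default uniform 500-3000.
#' @param baseline_means expected sample-1 counts per gene; default
#'   log-normal around a few hundred reads, the scale of a deeply
#'   sequenced library.
#' @param log2_fold planted per-gene log2 fold change (sample 2 over
#'   sample 1 at equal depth); default all 0.
#' @param library_sizes total clean reads (N1, N2).
#' @param dispersion negative-binomial overdispersion; 0 gives Poisson
#'   counts.
#' @param seed integer seed.
#' @return list of class `expression_truth`.
#' @export
expression_truth <- function(n_genes = 2000, gene_lengths = NULL,
                             baseline_means = NULL, log2_fold = NULL,
                             library_sizes = c(1e7, 1e7), dispersion = 0.05,
                             seed = 1) {
  if (dispersion < 0) stop("dispersion must be non-negative")
  if (any(library_sizes <= 0)) stop("library_sizes must be positive")
  withr::with_seed(seed, {
    if (is.null(gene_lengths)) gene_lengths <- sample(500:3000, n_genes, replace = TRUE)
    if (is.null(baseline_means)) baseline_means <- stats::rlnorm(n_genes, log(500), 0.7)
  })
  if (is.null(log2_fold)) log2_fold <- rep(0, length(gene_lengths))
  stopifnot(length(baseline_means) == length(gene_lengths),
            length(log2_fold) == length(gene_lengths))
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  if (any(baseline_means < 0)) stop("baseline means must be non-negative")
  structure(list(gene_lengths = as.integer(gene_lengths),
                 baseline_means = baseline_means, log2_fold = log2_fold,
                 library_sizes = library_sizes, dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "expression_truth")
}

#' Simulate two per-gene count vectors
#'
#' Counts are negative binomial around the truth means, with the sample-2
#' mean scaled by `2^log2_fold` and by the depth ratio N2/N1; dispersion 0
#' degenerates to Poisson.
#'
#' @param truth an [expression_truth()].
#' @return list with `counts` (data frame: gene_id, length, count_1,
#'   count_2), `truth` (planted fold changes with a `is_de` flag), and
#'   `library_sizes`.
#' @export
simulate_counts <- function(truth) {
  stopifnot(inherits(truth, "expression_truth"))
  n <- length(truth$gene_lengths)
  N <- truth$library_sizes
  mu1 <- truth$baseline_means
  mu2 <- truth$baseline_means * 2^truth$log2_fold * N[2] / N[1]
  withr::with_seed(truth$seed + 1L, {
    if (truth$dispersion == 0) {
      c1 <- stats::rpois(n, mu1); c2 <- stats::rpois(n, mu2)
    } else {
      size <- 1 / truth$dispersion
      c1 <- stats::rnbinom(n, mu = mu1, size = size)
      c2 <- stats::rnbinom(n, mu = mu2, size = size)
    }
  })
  ids <- sprintf("gene%05d", seq_len(n))
  list(counts = data.frame(gene_id = ids, length = truth$gene_lengths,
                           count_1 = c1, count_2 = c2,
                           stringsAsFactors = FALSE),
       truth = data.frame(gene_id = ids, log2_fold = truth$log2_fold,
                          is_de = truth$log2_fold != 0,
                          stringsAsFactors = FALSE),
       library_sizes = N)
}

#' Plant miRNA target sites into gene 3' regions
#'
#' Embeds, for each (gene, miRNA) pairing, either the full reverse
#' complement of the mature sequence (`perfect`) or the reverse complement
#' of the seed region only, positions 2-8 (`seed_only`), into the 3' end
#' of the gene's last exon; `none` leaves the genome untouched.
#'
#' @param genome a [make_genome()] object.
#' @param mirnas named character vector of mature miRNA sequences.
#' @param gene_subset gene names (as in the annotation) to receive sites;
#'   miRNAs are recycled over the subset.
#' @param site_type one of `"perfect"`, `"seed_only"`, `"none"`.
#' @return list with the modified `genome` and a `truth` data frame
#'   (gene_id, mirna, site start/end on the genome, site_type).
#' @export
plant_target_sites <- function(genome, mirnas, gene_subset,
                               site_type = c("perfect", "seed_only", "none")) {
  stopifnot(inherits(genome, "GenomeModel"))
  site_type <- match.arg(site_type)
  feats <- genome$features
  gene_names <- feats$name[feats$kind == "gene"]
  missing <- setdiff(gene_subset, gene_names)
  if (length(missing)) {
    stop("genes not in genome: ", paste(missing, collapse = ", "))
  }
  truth <- data.frame(gene_id = character(0), mirna = character(0),
                      start = integer(0), end = integer(0),
                      site_type = character(0), stringsAsFactors = FALSE)
  if (!length(gene_subset) || site_type == "none") {
    return(list(genome = genome, truth = truth))
  }
  mir_idx <- rep_len(seq_along(mirnas), length(gene_subset))
  for (k in seq_along(gene_subset)) {
    g <- gene_subset[k]
    mature <- dna_norm(mirnas[[mir_idx[k]]])
    site <- if (site_type == "perfect") revcomp(mature) else revcomp(substr(mature, 2, 8))
    ex <- which(feats$kind == "exon" & startsWith(feats$name, paste0(g, "_exon")))
    last_ex <- ex[which.max(GenomicRanges::end(feats)[ex])]
    e <- GenomicRanges::end(feats)[last_ex]
    s <- e - 10L - nchar(site) + 1L
    if (s < GenomicRanges::start(feats)[last_ex]) {
      stop("last exon of ", g, " too short to hold a target site")
    }
    substr(genome$sequence, s, s + nchar(site) - 1L) <- site
    truth <- rbind(truth, data.frame(
      gene_id = g, mirna = names(mirnas)[mir_idx[k]], start = s,
      end = s + nchar(site) - 1L, site_type = site_type,
      stringsAsFactors = FALSE))
  }
  list(genome = genome, truth = truth)
}

#' Spliced transcript sequences of a synthetic genome
#'
#' @param genome a [make_genome()] object.
#' @return named character vector, one concatenated-exon sequence per gene.
#' @export
get_transcripts <- function(genome) {
  stopifnot(inherits(genome, "GenomeModel"))
  feats <- genome$features
  genes <- feats$name[feats$kind == "gene"]
  out <- vapply(genes, function(g) {
    ex <- which(feats$kind == "exon" & startsWith(feats$name, paste0(g, "_exon")))
    ex <- ex[order(GenomicRanges::start(feats)[ex])]
    paste(substring(genome$sequence, GenomicRanges::start(feats)[ex],
                    GenomicRanges::end(feats)[ex]), collapse = "")
  }, character(1))
  stats::setNames(out, genes)
}
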