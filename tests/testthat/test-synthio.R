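test_that("genome generation is deterministic and satisfies its invariants", {
  cfg <- genome_config(genome_length = 10000, n_genes = 3, n_hairpins = 2)
  g1 <- make_genome(cfg, seed = 1)
  g2 <- make_genome(cfg, seed = 1)
  expect_identical(g1, g2)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(g1, f1); write_genome_fasta(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
  a1 <- tempfile(); a2 <- tempfile()
  write_annotation_bed(g1, a1); write_annotation_bed(g2, a2)
  expect_identical(readLines(a1), readLines(a2))
  expect_false(identical(g1$sequence, make_genome(cfg, seed = 2)$sequence))

  # coordinates within bounds; gene-level tiling covers the contig
  f <- g1$features
  expect_true(all(GenomicRanges::start(f) >= 1))
  expect_true(all(GenomicRanges::end(f) <= nchar(g1$sequence)))
  top <- f[f$kind %in% c("gene", "rRNA", "intergenic")]
  top <- top[order(GenomicRanges::start(top))]
  expect_equal(GenomicRanges::start(top)[1], 1)
  expect_equal(GenomicRanges::end(top)[length(top)], nchar(g1$sequence))
  expect_true(all(diff(GenomicRanges::start(top)) > 0))
  gaps <- GenomicRanges::start(top)[-1] -
    GenomicRanges::end(top)[-length(top)]
  expect_true(all(gaps == 1))

  # both hairpins sit wholly inside an intergenic feature
  expect_equal(nrow(g1$hairpins), 2)
  expect_true(all(g1$hairpins$kind == "intergenic"))
  for (h in seq_len(nrow(g1$hairpins))) {
    host <- f[f$kind == "intergenic" &
                GenomicRanges::start(f) <= g1$hairpins$start[h] &
                GenomicRanges::end(f) >= g1$hairpins$end[h]]
    expect_equal(length(host), 1)
  }
  # the recorded mature sequence is really in the genome
  expect_identical(
    substring(g1$sequence, g1$hairpins$mature_start, g1$hairpins$mature_end),
    g1$hairpins$mature_seq)
})

test_that("infeasible genome packing raises a sizing error", {
  expect_error(
    make_genome(genome_config(genome_length = 1000, n_genes = 50,
                              exon_len = c(100, 100), exons_per_gene = 1),
                seed = 1),
    "genome_length")
})

test_that("constructed hairpins fold as designed", {
  hp <- make_hairpin(substr(strrep("ACGGT", 5), 1, 22), 26, 8)
  expect_equal(nchar(hp$precursor), 60)
  f <- fold_mfe(hp$precursor)
  expect_lt(f$mfe, -20)
  # all-A mature with a GC clamp still folds well below the cutoff
  hpA <- make_hairpin(strrep("A", 22), 26, 8)
  expect_lt(fold_mfe(hpA$precursor)$mfe, -20)
  # the mature strand sits verbatim at the 5' arm
  expect_identical(substr(hpA$precursor, hpA$mature_start, hpA$mature_end),
                   strrep("A", 22))
  expect_error(make_hairpin(strrep("A", 22), 50, 20), "100 nt")
  expect_error(make_hairpin(strrep("A", 19), 26, 8), "20-22")
  expect_error(make_hairpin(strrep("A", 22), 20, 8), "stem_pairs")
})

test_that("library simulation hits the requested class mix and is reproducible", {
  g <- make_genome(genome_config(genome_length = 20000, n_genes = 4,
                                 n_rrna = 2, n_hairpins = 3), seed = 5)
  pr <- library_profile(n_reads = 10000,
                        class_mix = c(mature_miRNA = 0.2, degradation = 0.5,
                                      too_short = 0.1, rRNA_fragment = 0.1,
                                      low_quality = 0.1), seed = 9)
  lib <- simulate_srna_library(g, pr)
  expect_equal(nrow(lib$reads), 10000)
  # truth-table conservation: every read appears exactly once
  expect_identical(sort(lib$truth$read_id), sort(lib$reads$id))
  expect_false(any(duplicated(lib$truth$read_id)))
  # class counts within 3 binomial sigmas
  for (cl in names(pr$class_mix)[pr$class_mix > 0]) {
    p <- pr$class_mix[[cl]]
    sd3 <- 3 * sqrt(10000 * p * (1 - p))
    expect_lt(abs(sum(lib$truth$class == cl) - 10000 * p), sd3 + 1)
  }
  # determinism / seed sensitivity
  lib2 <- simulate_srna_library(g, pr)
  expect_identical(lib, lib2)
  pr2 <- library_profile(n_reads = 10000,
                         class_mix = pr$class_mix, seed = 10)
  lib3 <- simulate_srna_library(g, pr2)
  expect_false(identical(lib$reads$seq, lib3$reads$seq))
  mix3 <- prop.table(table(lib3$truth$class))
  for (cl in names(pr$class_mix)[pr$class_mix > 0]) {
    expect_lt(abs(mix3[[cl]] - pr$class_mix[[cl]]), 0.02)
  }
})

test_that("a pure mature-miRNA library reads back the planted sequences", {
  g <- make_genome(genome_config(genome_length = 15000, n_hairpins = 3),
                   seed = 2)
  pr <- library_profile(n_reads = 300, class_mix = c(mature_miRNA = 1),
                        seed = 3)
  lib <- simulate_srna_library(g, pr)
  matures <- g$hairpins$mature_seq
  expect_true(all(lib$truth$insert %in% matures))
  # each read is the planted mature followed by the 3' adapter
  expect_true(all(startsWith(lib$reads$seq,
                             paste0(lib$truth$insert, pr$adapter3))))
})

test_that("an empty library is valid and empty", {
  g <- make_genome(seed = 1)
  lib <- simulate_srna_library(g, library_profile(n_reads = 0, seed = 1))
  expect_equal(nrow(lib$reads), 0)
  f <- tempfile(fileext = ".fq")
  write_fastq(lib$reads, f)
  expect_identical(read_fastq(f), lib$reads)
})

test_that("simulated counts follow the planted truth", {
  # null genes centre on ratio 0
  tr <- expression_truth(n_genes = 1000, baseline_means = rep(1000, 1000),
                         gene_lengths = rep(1000, 1000), seed = 4)
  sim <- simulate_counts(tr)
  lr <- log2(sim$counts$count_1 / sim$counts$count_2)
  expect_lt(abs(mean(lr)), 0.05)
  # a strongly planted gene lands near its fold change
  tr2 <- expression_truth(n_genes = 3, baseline_means = rep(1e5, 3),
                          gene_lengths = rep(1000, 3),
                          log2_fold = c(0, 2, 0), dispersion = 0, seed = 5)
  sim2 <- simulate_counts(tr2)
  expect_lt(abs(log2(sim2$counts$count_2[2] / sim2$counts$count_1[2]) - 2),
            0.1)
  expect_true(all(sim2$truth$is_de == c(FALSE, TRUE, FALSE)))
  # zero baseline means zero counts in both samples
  tr3 <- expression_truth(n_genes = 2, baseline_means = c(0, 10),
                          gene_lengths = c(500, 500), seed = 6)
  sim3 <- simulate_counts(tr3)
  expect_equal(sim3$counts$count_1[1], 0)
  expect_equal(sim3$counts$count_2[1], 0)
  # depth imbalance scales sample 2
  tr4 <- expression_truth(n_genes = 2000, baseline_means = rep(500, 2000),
                          gene_lengths = rep(1000, 2000),
                          library_sizes = c(1e7, 2e7), dispersion = 0,
                          seed = 7)
  sim4 <- simulate_counts(tr4)
  expect_lt(abs(mean(sim4$counts$count_2) / mean(sim4$counts$count_1) - 2),
            0.05)
  expect_error(expression_truth(dispersion = -1), "dispersion")
})

test_that("target-site planting modifies only the designated genes", {
  g <- make_genome(genome_config(genome_length = 20000, n_genes = 5,
                                 n_hairpins = 2), seed = 8)
  cat <- mirna_catalog(g)
  genes <- g$features$name[g$features$kind == "gene"]
  res <- plant_target_sites(g, cat, genes[1:2], "perfect")
  expect_equal(nrow(res$truth), 2)
  site <- substring(res$genome$sequence, res$truth$start[1], res$truth$end[1])
  expect_identical(site, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(cat[[1]]))))
  # planted sites land inside the gene's transcript
  tx <- get_transcripts(res$genome)
  expect_true(grepl(site, tx[[res$truth$gene_id[1]]], fixed = TRUE))
  # empty subset leaves the genome byte-identical
  res0 <- plant_target_sites(g, cat, character(0), "perfect")
  expect_identical(res0$genome$sequence, g$sequence)
  expect_error(plant_target_sites(g, cat, "nonexistent", "perfect"),
               "not in genome")
})
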