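#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study material — a genome with annotated
# features and planted miRNA hairpins, two small-RNA libraries with truth
# tables, and a two-sample gene count table with planted fold changes.

source("analysis/00_config.R")

message("simulating genome (", GENOME_CFG$genome_length, " nt, ",
        GENOME_CFG$n_hairpins, " hairpins) ...")
genome <- make_genome(GENOME_CFG, seed = SEED)
write_genome_fasta(genome, file.path(RESULTS, "genome.fa"))
write_annotation_bed(genome, file.path(RESULTS, "annotation.bed"))
write_fasta(mirna_catalog(genome), file.path(RESULTS, "mirna_catalog.fa"))
write_tsv(genome$hairpins, "hairpin_truth.tsv")

message("simulating small-RNA libraries (", N_READS, " reads each) ...")
lib_a <- simulate_srna_library(genome, library_profile(
  n_reads = N_READS, class_mix = MIX_A, seed = SEED + 1L))
lib_b <- simulate_srna_library(genome, library_profile(
  n_reads = N_READS, class_mix = MIX_B, seed = SEED + 2L))
write_fastq(lib_a$reads, file.path(RESULTS, "library_A.fastq"))
write_fastq(lib_b$reads, file.path(RESULTS, "library_B.fastq"))
write_tsv(lib_a$truth, "library_A_truth.tsv")
write_tsv(lib_b$truth, "library_B_truth.tsv")

message("simulating gene counts (", N_GENES, " genes) ...")
lfc <- rep(0, N_GENES)
lfc[seq_len(N_GENES * 0.025)] <- 2
lfc[N_GENES * 0.025 + seq_len(N_GENES * 0.025)] <- -2
truth <- expression_truth(n_genes = N_GENES, log2_fold = lfc,
                          seed = SEED + 3L)
sim <- simulate_counts(truth)
write_tsv(sim$counts, "gene_counts.tsv")
write_tsv(sim$truth, "gene_truth.tsv")

message("library A class mix observed:")
print(round(prop.table(table(lib_a$truth$class)), 3))
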