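# Shared settings for the analysis drivers. Every script sources this
# file, so the whole workflow is reproducible from one seed.

library(jellymir)

SEED <- 1L
RESULTS <- "results"
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

# one synthetic genome stands in for the honey bee assembly: 6 genes with
# introns, 2 rRNA features, and 4 miRNA hairpins planted in legal
# (intergenic/intronic) locations
GENOME_CFG <- genome_config(genome_length = 40000, n_genes = 6,
                            n_rrna = 2, n_hairpins = 4,
                            hairpin_in = c("intergenic", "intron"))

# the two royal-jelly small-RNA libraries ("A" plays RJM, "B" plays RJC):
# identical contaminant structure, different miRNA content
N_READS <- 20000
MIX_A <- c(mature_miRNA = 0.08, rRNA_fragment = 0.32, degradation = 0.42,
           adapter3_null = 0.01, insert_null = 0.003,
           adapter5_contaminant = 0.005, too_short = 0.12, polyA = 0.002,
           low_quality = 0.04)
MIX_B <- c(mature_miRNA = 0.03, rRNA_fragment = 0.36, degradation = 0.43,
           adapter3_null = 0.01, insert_null = 0.003,
           adapter5_contaminant = 0.005, too_short = 0.13, polyA = 0.002,
           low_quality = 0.04)

# the two transcriptome samples: 2000 genes, 5% planted at |log2 fold| = 2
N_GENES <- 2000L

write_tsv <- function(df, name) {
  utils::write.table(df, file.path(RESULTS, name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  message("  wrote ", file.path(RESULTS, name))
}
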