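#!/usr/bin/env Rscript
# Stage 2: clean both small-RNA libraries, compare their insert-length
# distributions, collapse to unique tags, map to the genome (<= 1
# mismatch), and annotate tags into miRNA / rRNAetc / unann classes —
# the accounting of the published Tables 1-3, on synthetic data.

source("analysis/00_config.R")
genome <- make_genome(GENOME_CFG, seed = SEED)
catalog <- mirna_catalog(genome)

message("cleaning libraries ...")
clean_a <- clean_library(file.path(RESULTS, "library_A.fastq"))
clean_b <- clean_library(file.path(RESULTS, "library_B.fastq"))
print(clean_a$summary)
print(clean_b$summary)

summ_df <- function(s, lib) {
  data.frame(library = lib, category = names(s$counts),
             count = unname(s$counts),
             pct_of_high_quality = c(NA, 100, NA, unname(s$percentages[-1])))
}
write_tsv(rbind(summ_df(clean_a$summary, "A"), summ_df(clean_b$summary, "B")),
          "cleaning_summary.tsv")

message("comparing length distributions ...")
chi <- chi2_length_test(length_histogram(clean_a$tags$insert),
                        length_histogram(clean_b$tags$insert))
message(sprintf("  X^2 = %.1f on %d df, p = %.3g",
                chi$statistic, chi$df, chi$p.value))
write_tsv(data.frame(statistic = chi$statistic, df = chi$df,
                     p_value = chi$p.value), "length_chi2.tsv")

message("collapsing and mapping tags ...")
tags <- collapse_tags(clean_a$tags$insert, clean_b$tags$insert,
                      min_count = 2)
tags <- map_tags(tags, genome)
message("  ", nrow(tags), " tags kept, ",
        sum(tags$mapped), " mapped (<= 1 mismatch)")
write_tag_fasta(tags, file.path(RESULTS, "tags.fa"))

ann <- annotate_tags(tags, genome$features, catalog)
write_tsv(ann$summary, "class_summary.tsv")
write_tsv(overlap_summary(tags), "overlap_summary.tsv")
print(ann$summary)
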