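#!/usr/bin/env Rscript
# Stage 4: digital gene expression between the two transcriptome samples —
# RPKM, log2 ratio, the Audic-Claverie equal-expression probability,
# Benjamini-Hochberg FDR, and calls at FDR < 0.001 and |log2 ratio| > 1,
# checked against the planted truth.

source("analysis/00_config.R")

counts <- read.delim(file.path(RESULTS, "gene_counts.tsv"))
truth <- read.delim(file.path(RESULTS, "gene_truth.tsv"))
truth_obj <- expression_truth(n_genes = N_GENES, seed = SEED + 3L)
N <- truth_obj$library_sizes

message("testing ", nrow(counts), " genes ...")
dge <- dge_table(counts$count_1, counts$count_2, counts$length,
                 N[1], N[2], gene_id = counts$gene_id)
message(sprintf("  %d up, %d down, %d total DEGs",
                dge$summary[["n_up"]], dge$summary[["n_down"]],
                dge$summary[["total"]]))
write_tsv(dge$results, "dge_results.tsv")
write_tsv(data.frame(as.list(dge$summary)), "dge_summary.tsv")

called <- dge$results$gene_id[dge$results$call != "ns"]
planted <- truth$gene_id[truth$is_de]
message(sprintf("  recovery: %d/%d planted DEGs called; %d false calls",
                sum(planted %in% called), length(planted),
                sum(!called %in% planted)))
write_tsv(data.frame(planted = length(planted),
                     recovered = sum(planted %in% called),
                     false_calls = sum(!called %in% planted)),
          "dge_recovery.tsv")
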