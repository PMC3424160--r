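#!/usr/bin/env Rscript
# Stage 3: miRNA discovery and comparison — fold 100-nt windows around
# mapped tags of mature length, apply the three candidate criteria
# (one-arm placement, MFE < -20 kcal/mol, intergenic/intronic location),
# reconcile against the known catalog, and apply the altered-miRNA rule
# (>= 10 copies in both libraries and a two-fold difference).

source("analysis/00_config.R")
genome <- make_genome(GENOME_CFG, seed = SEED)
catalog <- mirna_catalog(genome)

clean_a <- clean_library(file.path(RESULTS, "library_A.fastq"))
clean_b <- clean_library(file.path(RESULTS, "library_B.fastq"))
tags <- map_tags(collapse_tags(clean_a$tags$insert, clean_b$tags$insert),
                 genome)

message("folding candidate windows ...")
cand <- discover_hairpins(tags, genome, catalog)
message("  ", nrow(cand), " candidate windows, ", sum(cand$pass),
        " pass all three criteria")
write_tsv(cand, "hairpin_candidates.tsv")

# per-library known-miRNA inventories: a miRNA is observed in a library
# when its mature tag has copies there
mir <- merge(data.frame(sequence = unname(catalog), name = names(catalog),
                        stringsAsFactors = FALSE),
             tags[, c("sequence", "count_a", "count_b")], by = "sequence",
             all.x = TRUE)
mir$count_a[is.na(mir$count_a)] <- 0L
mir$count_b[is.na(mir$count_b)] <- 0L
inv <- inventory_overlap(mir$name[mir$count_a > 0], mir$name[mir$count_b > 0])
message(sprintf("  known miRNAs: %d in A, %d in B, %d shared",
                inv$counts[["total_a"]], inv$counts[["total_b"]],
                inv$counts[["shared"]]))
write_tsv(data.frame(set = names(inv$counts), n = unname(inv$counts)),
          "mirna_inventory.tsv")

message("altered-miRNA calls ...")
alt <- altered_mirna(mir$count_a, mir$count_b, name = mir$name,
                     totals = c(sum(tags$count_a), sum(tags$count_b)))
print(alt[, c("name", "copies_a", "copies_b", "fold_change", "call")])
write_tsv(alt, "altered_mirna.tsv")
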