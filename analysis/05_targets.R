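#!/usr/bin/env Rscript
# Stage 5: miRNA target prediction — plant perfect target sites for the
# genome's miRNAs into the 3' regions of half the genes, predict targets
# by duplex minimum free energy over the spliced transcripts, and report
# the planted-gene/target overlap in the style of the DEG/target share.

source("analysis/00_config.R")
genome <- make_genome(GENOME_CFG, seed = SEED)
catalog <- mirna_catalog(genome)
genes <- genome$features$name[genome$features$kind == "gene"]
targeted <- genes[seq_len(length(genes) %/% 2)]

message("planting perfect sites in ", length(targeted), " of ",
        length(genes), " genes ...")
planted <- plant_target_sites(genome, catalog, targeted, "perfect")
write_tsv(planted$truth, "target_truth.tsv")

message("predicting targets over ", length(genes), " transcripts ...")
tx <- get_transcripts(planted$genome)
tmap <- predict_target_map(catalog, tx, energy_cutoff = -20)
write_tsv(tmap, "target_sites.tsv")

rep <- overlap_report(targeted, tmap)
message(sprintf("  %d/%d planted genes recovered as targets (%.1f%%)",
                rep$n_deg_targets, rep$n_deg, rep$proportion))
rep_all <- overlap_report(genes, tmap)
message(sprintf("  %d/%d of all genes called targets (%.1f%%); untargeted genes: %d called",
                rep_all$n_deg_targets, rep_all$n_deg, rep_all$proportion,
                sum(setdiff(genes, targeted) %in% tmap$transcript_id)))
write_tsv(data.frame(n_planted = rep$n_deg,
                     n_recovered = rep$n_deg_targets,
                     pct_recovered = rep$proportion,
                     n_untargeted_called = sum(setdiff(genes, targeted) %in%
                                                 tmap$transcript_id)),
          "target_overlap.tsv")
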