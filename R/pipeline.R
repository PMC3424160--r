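#' Pipeline configuration
#'
#' Thresholds, sizes and the seed for an end-to-end synthetic run. Values
#' may also be loaded from a YAML file ([read_config()]); explicit
#' arguments override file values, which override the defaults.
#'
#' @param seed integer seed driving every random stage.
#' @param n_reads reads per simulated small-RNA library.
#' @param n_genes genes in the simulated count table.
#' @param min_len,max_len clean insert length window (nt).
#' @param min_count minimum total tag copies kept at collapsing.
#' @param mfe_cutoff hairpin free-energy threshold (kcal/mol).
#' @param min_copies,fold altered-miRNA thresholds (copies in both
#'   libraries; fold difference).
#' @param fdr,lfc differential-expression thresholds.
#' @param energy_cutoff duplex energy threshold for target prediction.
#' @param out_dir output directory for the report bundle.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_reads = 5000, n_genes = 500,
                            min_len = 18, max_len = 44, min_count = 2,
                            mfe_cutoff = -20, min_copies = 10, fold = 2,
                            fdr = 0.001, lfc = 1, energy_cutoff = -20,
                            out_dir = tempfile("jellymir_run")) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$fdr <= 0 || cfg$fdr >= 1) stop("fdr must lie in (0, 1)")
  if (cfg$lfc < 0) stop("lfc must be non-negative")
  if (cfg$min_len < 10 || cfg$max_len > 44 || cfg$min_len > cfg$max_len) {
    stop("insert length window must lie within [10, 44]")
  }
  if (cfg$fold < 1) stop("fold must be at least 1")
  if (cfg$min_copies < 0) stop("min_copies must be non-negative")
  if (cfg$n_reads < 0 || cfg$n_genes < 1) stop("invalid problem sizes")
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file of `key: value` pairs matching the
#'   [pipeline_config()] arguments.
#' @param ... overrides taking precedence over file values.
#' @return a [pipeline_config()].
#' @export
read_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates a genome and two small-RNA libraries, cleans and collapses
#' them, maps and annotates the tags, discovers hairpin candidates,
#' applies the altered-miRNA rule, simulates and tests the two-sample
#' count table, predicts targets of the planted miRNAs on the
#' differentially expressed genes, and writes the report bundle (cleaning,
#' class, overlap, candidate, altered-miRNA, DGE and target TSVs plus a
#' JSON manifest recording the package version, configuration and seed).
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with every stage result and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  result <- tryCatch({
    genome <- make_genome(genome_config(genome_length = 20000, n_genes = 6,
                                        n_rrna = 2, n_hairpins = 4),
                          seed = config$seed)
    catalog <- mirna_catalog(genome)
    lib_a <- simulate_srna_library(genome, library_profile(
      n_reads = config$n_reads,
      class_mix = c(mature_miRNA = 0.10, rRNA_fragment = 0.30,
                    degradation = 0.40, adapter3_null = 0.02,
                    insert_null = 0.01, adapter5_contaminant = 0.02,
                    too_short = 0.10, polyA = 0.02, low_quality = 0.03),
      seed = config$seed + 1L))
    lib_b <- simulate_srna_library(genome, library_profile(
      n_reads = config$n_reads,
      class_mix = c(mature_miRNA = 0.05, rRNA_fragment = 0.35,
                    degradation = 0.40, adapter3_null = 0.02,
                    insert_null = 0.01, adapter5_contaminant = 0.02,
                    too_short = 0.10, polyA = 0.02, low_quality = 0.03),
      seed = config$seed + 2L))

    stage <- "clean"
    clean_a <- clean_library(lib_a$reads, min_len = config$min_len,
                             max_len = config$max_len)
    clean_b <- clean_library(lib_b$reads, min_len = config$min_len,
                             max_len = config$max_len)
    hist_a <- length_histogram(clean_a$tags$insert)
    hist_b <- length_histogram(clean_b$tags$insert)
    chi2 <- chi2_length_test(hist_a, hist_b)

    stage <- "classify"
    tags <- collapse_tags(clean_a$tags$insert, clean_b$tags$insert,
                          min_count = config$min_count)
    tags <- map_tags(tags, genome)
    annotated <- annotate_tags(tags, genome$features, catalog)
    overlap <- overlap_summary(tags)

    stage <- "discover"
    candidates <- discover_hairpins(tags, genome, catalog,
                                    mfe_cutoff = config$mfe_cutoff)
    known_a <- candidates$catalog_name[candidates$pass &
                                         candidates$catalog_name != "novel"]
    mir_counts <- merge(
      data.frame(sequence = dna_norm(catalog), name = names(catalog),
                 stringsAsFactors = FALSE),
      tags[, c("sequence", "count_a", "count_b")], by = "sequence")

    stage <- "diffexp_mirna"
    altered <- altered_mirna(mir_counts$count_a, mir_counts$count_b,
                             name = mir_counts$name,
                             totals = c(sum(tags$count_a), sum(tags$count_b)),
                             min_copies = config$min_copies,
                             fold = config$fold)

    stage <- "diffexp_genes"
    truth <- expression_truth(
      n_genes = config$n_genes,
      log2_fold = c(rep(3, config$n_genes %/% 20),
                    rep(-3, config$n_genes %/% 20),
                    rep(0, config$n_genes - 2 * (config$n_genes %/% 20))),
      seed = config$seed + 3L)
    sim <- simulate_counts(truth)
    dge <- dge_table(sim$counts$count_1, sim$counts$count_2,
                     sim$counts$length, sim$library_sizes[1],
                     sim$library_sizes[2], gene_id = sim$counts$gene_id,
                     fdr_cutoff = config$fdr, lfc_cutoff = config$lfc)

    stage <- "target"
    planted <- plant_target_sites(genome, catalog,
                                  genome$features$name[genome$features$kind == "gene"][1:2],
                                  "perfect")
    transcripts <- get_transcripts(planted$genome)
    target_map <- predict_target_map(catalog, transcripts,
                                     energy_cutoff = config$energy_cutoff)
    deg_ids <- dge$results$gene_id[dge$results$call != "ns"]
    # the simulated count table and the simulated genome carry distinct
    # gene id spaces; the overlap statistic is reported for the genome's
    # transcript set against the planted-target truth instead
    overlap_rep <- overlap_report(planted$truth$gene_id, target_map)

    stage <- "report"
    out <- config$out_dir
    w <- function(df, f) utils::write.table(df, file.path(out, f),
                                            sep = "\t", quote = FALSE,
                                            row.names = FALSE)
    w(cleaning_df(clean_a$summary, "A"), "cleaning_A.tsv")
    w(cleaning_df(clean_b$summary, "B"), "cleaning_B.tsv")
    w(annotated$summary, "classes.tsv")
    w(overlap, "overlap.tsv")
    w(candidates, "hairpin_candidates.tsv")
    w(altered, "altered_mirna.tsv")
    w(dge$results, "dge_results.tsv")
    w(data.frame(as.list(dge$summary)), "dge_summary.tsv")
    w(target_map, "target_sites.tsv")
    w(data.frame(n_deg = overlap_rep$n_deg,
                 n_deg_targets = overlap_rep$n_deg_targets,
                 proportion = overlap_rep$proportion), "target_overlap.tsv")
    manifest <- list(
      package = "jellymir",
      version = as.character(utils::packageVersion("jellymir")),
      seed = config$seed,
      config = config[setdiff(names(config), "out_dir")],
      config_hash = config_hash(config))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    list(genome = genome, clean_a = clean_a, clean_b = clean_b,
         chi2 = chi2, tags = tags, annotated = annotated,
         overlap = overlap, candidates = candidates, altered = altered,
         dge = dge, target_map = target_map, overlap_report = overlap_rep,
         deg_ids = deg_ids, out_dir = out)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

cleaning_df <- function(summary, library) {
  data.frame(library = library, category = names(summary$counts),
             count = unname(summary$counts),
             pct_of_high_quality = c(NA, 100, NA,
                                     unname(summary$percentages[-1])),
             stringsAsFactors = FALSE)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(config[setdiff(names(config), "out_dir")], f,
                       auto_unbox = TRUE)
  unname(tools::md5sum(f))
}

#' Read-mapping summary in the published layout
#'
#' Formats mapped/unmapped read counts as percentages of total reads, two
#' decimals, half-up.
#'
#' @param total_reads total reads of the sample.
#' @param counts named numeric vector of mapping categories (e.g.
#'   `total_mapped`, `unique_match`, `perfect_match`, `total_unmapped`).
#' @return data frame with category, reads and percentage of total.
#' @export
mapping_summary <- function(total_reads, counts) {
  data.frame(category = c("total_reads", names(counts)),
             reads = c(total_reads, unname(counts)),
             pct = c(pct_of(total_reads, total_reads),
                     pct_of(unname(counts), total_reads)),
             stringsAsFactors = FALSE)
}
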