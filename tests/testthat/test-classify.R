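test_that("tag collapsing counts multiplicities and drops singletons", {
  a <- c(rep("ACGTACGTACGTACGTAA", 3), "TTTTGGGGCCCCAAAATT")
  t1 <- collapse_tags(a, min_count = 2)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$count_a, 3)
  expect_equal(t1$count_b, 0)
  # order invariance
  t2 <- collapse_tags(rev(a), min_count = 2)
  expect_identical(t1, t2)
  # per-library counts and shared tags
  b <- c(rep("ACGTACGTACGTACGTAA", 2), rep("GGGGTTTTAAAACCCCGG", 2))
  t3 <- collapse_tags(a, b, min_count = 2)
  expect_equal(t3$count_a[t3$sequence == "ACGTACGTACGTACGTAA"], 3)
  expect_equal(t3$count_b[t3$sequence == "ACGTACGTACGTACGTAA"], 2)
  # a simulated library collapses to its truth multiplicities
  g <- make_genome(genome_config(genome_length = 15000, n_hairpins = 3),
                   seed = 21)
  lib <- simulate_srna_library(g, library_profile(
    n_reads = 2000, class_mix = c(mature_miRNA = 0.5, degradation = 0.5),
    seed = 22))
  cl <- clean_library(lib$reads)
  tags <- collapse_tags(cl$tags$insert, min_count = 1)
  truth_tab <- table(lib$truth$insert[lib$truth$expected_category == "clean"])
  expect_equal(sum(tags$count_a), sum(truth_tab))
  m <- match(tags$sequence, names(truth_tab))
  expect_false(anyNA(m))
  expect_equal(tags$count_a, as.integer(truth_tab[m]))
})

test_that("tag mapping equals an exhaustive Hamming scan", {
  set.seed(31)
  g <- make_genome(genome_config(genome_length = 8000, n_hairpins = 2),
                   seed = 31)
  gseq <- g$sequence
  mutate1 <- function(s, k = 1) {
    pos <- sample(nchar(s), k)
    for (p in pos) {
      cur <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    }
    s
  }
  exact <- vapply(1:6, function(i) {
    o <- sample(nchar(gseq) - 22, 1); substr(gseq, o, o + 21)
  }, character(1))
  tags <- data.frame(
    sequence = c(exact,
                 vapply(exact[1:3], mutate1, character(1)),
                 vapply(exact[1:3], mutate1, character(1), k = 2),
                 vapply(1:6, function(i) rand_seq(22), character(1)),
                 oracle_revcomp(exact[4])),
    stringsAsFactors = FALSE)
  tags$count_a <- 2L; tags$count_b <- 0L; tags$total <- 2L
  mapped <- map_tags(tags, g)
  for (r in seq_len(nrow(mapped))) {
    want <- brute_map(mapped$sequence[r], gseq)
    got <- mapped$loci[[r]]
    expect_equal(got, want, info = mapped$sequence[r])
  }
  # exact tags map with zero mismatches; 2-substitution variants are unmapped
  expect_true(all(mapped$best_mm[1:6] == 0))
  expect_false(any(mapped$mapped[10:12]))
  expect_error(map_tags(data.frame(sequence = "ACGTXX", count_a = 1,
                                   count_b = 0, total = 1), g),
               "invalid")
})

test_that("tags are annotated with miRNA > rRNAetc > unann precedence", {
  g <- make_genome(genome_config(genome_length = 20000, n_genes = 3,
                                 n_rrna = 2, rrna_len = c(200, 200),
                                 n_hairpins = 2), seed = 41)
  cat <- mirna_catalog(g)
  f <- g$features
  rrna <- f[f$kind == "rRNA"][1]
  rrna_frag <- substr(g$sequence, GenomicRanges::start(rrna) + 5,
                      GenomicRanges::start(rrna) + 30)
  tags <- data.frame(
    sequence = c(unname(cat[1]), rrna_frag, rand_seq(24)),
    count_a = c(5L, 4L, 3L), count_b = c(1L, 0L, 0L),
    total = c(6L, 4L, 3L), stringsAsFactors = FALSE)
  tags <- map_tags(tags, g)
  ann <- annotate_tags(tags, g$features, cat)
  expect_equal(ann$tags$annotation, c("miRNA", "rRNAetc", "unmapped"))
  # summary partitions unique tags and read totals
  s <- ann$summary
  expect_equal(s$unique[s$class == "Total sRNAs"], 3)
  expect_equal(sum(s$unique[s$class != "Total sRNAs"]), 3)
  expect_equal(s$total[s$class == "Total sRNAs"], 13)
  expect_equal(sum(s$total[s$class != "Total sRNAs"]), 13)
})

test_that("class summary reproduces the published miRNA percentage", {
  tab2 <- read.delim(system.file("extdata", "printed_table2.tsv",
                                 package = "jellymir"))
  cls <- tab2[tab2$class != "Total", ]
  tot <- tab2[tab2$class == "Total", ]
  s <- class_summary(stats::setNames(cls$unique_RJM, cls$class),
                     stats::setNames(cls$total_RJM, cls$class),
                     unique_total = tot$unique_RJM,
                     total_total = tot$total_RJM)
  expect_equal(s$unique_pct[s$class == "miRNA"], 0.04)
  expect_equal(s$total_pct[s$class == "unann"], 61.47)
})

test_that("overlap summaries partition tags and reproduce the published shares", {
  # disjoint sets: no shared tags
  tags <- data.frame(sequence = c("AAAA", "CCCC", "GGGG"),
                     count_a = c(2L, 3L, 0L), count_b = c(0L, 0L, 4L))
  ov <- overlap_summary(tags)
  expect_equal(ov$unique[ov$set == "shared"], 0)
  expect_equal(ov$unique[ov$set == "a_specific"], 2)
  expect_equal(ov$reads[ov$set == "Total"], 9)
  # identical sets with equal counts: 100% shared on both measures
  tags2 <- data.frame(sequence = c("AAAA", "CCCC"),
                      count_a = c(2L, 2L), count_b = c(2L, 2L))
  ov2 <- overlap_summary(tags2)
  expect_equal(ov2$unique_pct[ov2$set == "shared"], 100)
  expect_equal(ov2$reads_pct[ov2$set == "shared"], 100)
  # symmetry: swapping libraries exchanges the specific labels
  tags3 <- data.frame(sequence = c("AAAA", "CCCC", "GGGG"),
                      count_a = c(2L, 0L, 1L), count_b = c(0L, 5L, 3L))
  ov3 <- overlap_summary(tags3)
  tags3s <- tags3; names(tags3s)[2:3] <- c("count_b", "count_a")
  ov3s <- overlap_summary(tags3s)
  expect_equal(ov3$unique[ov3$set == "a_specific"],
               ov3s$unique[ov3s$set == "b_specific"])
  expect_equal(ov3$reads[ov3$set == "shared"],
               ov3s$reads[ov3s$set == "shared"])
  # published common/specific table reproduces exactly
  tab3 <- read.delim(system.file("extdata", "printed_table3.tsv",
                                 package = "jellymir"))
  t3 <- overlap_table(stats::setNames(tab3$unique, tab3$set),
                      stats::setNames(tab3$reads, tab3$set))
  expect_equal(t3$unique[t3$set == "Total"], 2222699)
  expect_equal(t3$reads[t3$set == "Total"], 19811504)
  expect_equal(t3$reads_pct, c(100, 8.76, 9.45, 81.79))
  expect_equal(t3$unique_pct, c(100, 47.07, 41.03, 11.90))
})
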