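test_that("unpairable sequences fold to the empty structure", {
  f <- fold_mfe(strrep("A", 30))
  expect_equal(f$structure, strrep(".", 30))
  expect_equal(f$mfe, 0)
  expect_error(fold_mfe("ACGX"), "invalid")
  # T and U are synonyms; the structure annotates the input as given
  expect_equal(fold_mfe("GGGAAAACCC")$mfe, fold_mfe("GGGAAAACCC")$mfe)
  expect_equal(fold_mfe(chartr("T", "U", "GGGTTTTCCC"))$mfe,
               fold_mfe("GGGTTTTCCC")$mfe)
})

test_that("the folding DP matches exhaustive enumeration and audits its own structure", {
  set.seed(51)
  for (i in 1:40) {
    s <- rand_seq(sample(5:22, 1))
    f <- fold_mfe(s)
    expect_equal(f$mfe, brute_fold_mfe(s), info = s)
    # the reported dot-bracket scores exactly its reported energy
    expect_equal(structure_energy(s, f$structure), f$mfe, info = s)
  }
})

test_that("flanking a sequence with a complementary pair never raises the MFE", {
  set.seed(52)
  for (i in 1:25) {
    s <- rand_seq(sample(8:20, 1))
    expect_lte(fold_mfe(paste0("G", s, "C"))$mfe, fold_mfe(s)$mfe)
  }
})

test_that("window extraction centres, truncates and reverse-complements", {
  g <- make_genome(genome_config(), seed = 61)
  w <- extract_window(g, 500, 521, "+", window = 100)
  expect_equal(nchar(w$seq), 100)
  expect_equal(w$mature_span[2] - w$mature_span[1], 21)
  expect_identical(substr(w$seq, w$mature_span[1], w$mature_span[2]),
                   substr(g$sequence, 500, 521))
  # near the contig start the window truncates but keeps the span valid
  wt <- extract_window(g, 10, 31, "+", window = 100)
  expect_equal(w2 <- nchar(wt$seq), 100)
  expect_equal(wt$genome_start, 1)
  expect_identical(substr(wt$seq, wt$mature_span[1], wt$mature_span[2]),
                   substr(g$sequence, 10, 31))
  short <- extract_window(substr(g$sequence, 1, 60), 10, 31, "+", window = 100)
  expect_equal(nchar(short$seq), 60)
  # minus strand equals the reverse complement of the plus-strand slice
  wm <- extract_window(g, 500, 521, "-", window = 100)
  expect_identical(wm$seq, oracle_revcomp(substr(g$sequence, wm$genome_start,
                                                 wm$genome_end)))
  expect_identical(substr(wm$seq, wm$mature_span[1], wm$mature_span[2]),
                   oracle_revcomp(substr(g$sequence, 500, 521)))
  expect_error(extract_window(g, -5, 20), "bounds")
})

test_that("the three candidate criteria are applied independently", {
  # a well-formed planted hairpin in intergenic space passes
  hp <- make_hairpin("TGAGGTAGTAGGTTGTATAGTT", 26, 8)
  cand <- hairpin_candidate(hp$precursor, c(1, 22), "intergenic")
  v <- criteria_check(cand)
  expect_true(v$pass)
  expect_equal(cand$arm, "5p")
  # the same hairpin inside an exon fails only criterion (c)
  cand_ex <- hairpin_candidate(hp$precursor, c(1, 22), "exon")
  v_ex <- criteria_check(cand_ex)
  expect_false(v_ex$pass)
  expect_equal(v_ex$failed, "c")
  # a weak 6-pair stem fails the energy criterion
  weak <- paste0("GCGCGC", "AAAA", "GCGCGC")
  cand_w <- hairpin_candidate(weak, c(1, 6), "intergenic")
  expect_gte(cand_w$mfe, -20)
  expect_true("b" %in% criteria_check(cand_w)$failed)
  # a mature spanning the terminal loop fails criterion (a)
  cand_loop <- hairpin_candidate(hp$precursor, c(20, 41), "intergenic")
  expect_true("a" %in% criteria_check(cand_loop)$failed)
})

test_that("catalog matching is exact by default with lexicographic ties", {
  cat <- c(`mir-b` = "TGAGGTAGTAGGTTGTATAGTT",
           `mir-a` = "TGAGGTAGTAGGTTGTATAGTT",
           `mir-c` = "ACCCGTAGATCCGAACTTGTGA")
  expect_equal(match_catalog("TGAGGTAGTAGGTTGTATAGTT", cat), "mir-a")
  expect_equal(match_catalog(chartr("T", "U", "TGAGGTAGTAGGTTGTATAGTT"), cat),
               "mir-a")
  variant <- "TGAGGTAGTAGGTTGTATAGTA"
  expect_equal(match_catalog(variant, cat), "novel")
  expect_equal(match_catalog(variant, cat, max_mismatch = 1), "mir-a")
  expect_equal(match_catalog("ACGT", cat), "novel")
})

test_that("known-miRNA inventories follow set arithmetic", {
  # the published worked example: 23 library-A-specific plus 46 shared
  a <- c(sprintf("mirA%02d", 1:23), sprintf("mirS%02d", 1:46))
  b <- c(sprintf("mirB%02d", 1:2), sprintf("mirS%02d", 1:46))
  inv <- inventory_overlap(a, b)
  expect_equal(unname(inv$counts["total_a"]), 69)
  expect_equal(unname(inv$counts["total_b"]), 48)
  expect_equal(unname(inv$counts["shared"]), 46)
  # disjoint and identical sets
  inv2 <- inventory_overlap(c("x", "y"), c("z"))
  expect_equal(length(inv2$shared), 0)
  inv3 <- inventory_overlap(c("x", "y"), c("y", "x"))
  expect_equal(inv3$shared, c("x", "y"))
  expect_equal(unname(inv3$counts["a_specific"]), 0)
})

test_that("hairpin discovery recovers planted miRNAs and rejects exonic ones", {
  g <- make_genome(genome_config(genome_length = 30000, n_genes = 5,
                                 n_rrna = 1, n_hairpins = 6,
                                 hairpin_in = c("intergenic", "intron")),
                   seed = 71)
  cat <- mirna_catalog(g)
  tags <- data.frame(sequence = unname(cat), count_a = 5L, count_b = 5L,
                     total = 10L, stringsAsFactors = FALSE)
  tags <- map_tags(tags, g)
  cand <- discover_hairpins(tags, g, cat)
  expect_equal(nrow(cand), 6)
  expect_true(all(cand$pass))
  expect_true(all(cand$location_class %in% c("intergenic", "intron")))
  expect_identical(sort(cand$catalog_name), sort(names(cat)))
  # exon-planted hairpins all fail, and only on location
  ge <- make_genome(genome_config(genome_length = 30000, n_genes = 5,
                                  exon_len = c(250, 400), n_hairpins = 4,
                                  hairpin_in = "exon"), seed = 72)
  ce <- mirna_catalog(ge)
  te <- map_tags(data.frame(sequence = unname(ce), count_a = 5L,
                            count_b = 5L, total = 10L,
                            stringsAsFactors = FALSE), ge)
  cande <- discover_hairpins(te, ge, ce)
  expect_equal(nrow(cande), 4)
  expect_false(any(cande$pass))
  expect_true(all(vapply(strsplit(cande$failed, ","),
                         function(f) "c" %in% f, logical(1))))
})
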