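ad <- default_adapters()
hq <- function(s) strrep("I", nchar(s))

test_that("reads are classified into the documented categories", {
  mk <- function(insert, tail = "CCCC") paste0(insert, ad$adapter3, tail)
  cases <- list(
    # a read that is exactly the 3' adapter has an empty insert
    list(seq = mk(""), qual = NULL, want = "insert_null"),
    list(seq = "", qual = "", want = "insert_null"),
    # no 3' adapter anywhere in the read
    list(seq = strrep("ACGT", 15), qual = NULL, want = "adapter3_null"),
    list(seq = mk(paste0(ad$adapter5, "ACGTACGTAC")), qual = NULL,
         want = "adapter5_contaminant"),
    list(seq = mk("ACGTACGTACGTACGT"), qual = NULL, want = "too_short"),
    list(seq = mk(strrep("A", 20)), qual = NULL, want = "polyA"),
    # 19 A's and one G is 95% A
    list(seq = mk(paste0(strrep("A", 19), "G")), qual = NULL, want = "polyA"),
    list(seq = mk("ACGTTGCAACGTTGCAACGT"), qual = NULL, want = "clean"),
    list(seq = mk("ACGTTGCAACGTTGCAACGT"),
         qual = strrep("#", nchar(mk("ACGTTGCAACGTTGCAACGT"))),
         want = "low_quality"),
    list(seq = mk("ACGTTGCAACGNTGCAACGT"), qual = NULL, want = "low_quality"))
  for (cs in cases) {
    q <- if (is.null(cs$qual)) hq(cs$seq) else cs$qual
    expect_equal(classify_read(cs$seq, q, ad), cs$want, info = cs$seq)
  }
  # a 16 nt insert falls below the 18 nt floor
  expect_equal(classify_read(mk("ACGTACGTACGTACGT"), hq(mk("ACGTACGTACGTACGT")), ad),
               "too_short")
  expect_error(classify_reads("ACGT", "II"), "equal length")
})

test_that("the cleaning summary reproduces the published accounting", {
  tab1 <- read.delim(system.file("extdata", "printed_table1.tsv",
                                 package = "jellymir"))
  for (r in seq_len(nrow(tab1))) {
    s <- cleaning_summary(tab1$total_reads[r], tab1$adapter3_null[r],
                          tab1$insert_null[r], tab1$adapter5_contaminant[r],
                          tab1$too_short[r], tab1$polyA[r],
                          tab1$clean_reads[r])
    if (tab1$library[r] == "RJM") {
      expect_equal(s$counts[["high_quality"]], 11787392)
      expect_equal(unname(s$percentages[c("adapter3_null", "insert_null",
                                          "adapter5_contaminant", "too_short",
                                          "polyA", "clean_reads")]),
                   c(0.50, 0.02, 0.09, 11.86, 0.00, 87.54))
    } else {
      expect_equal(s$counts[["high_quality"]], 10247413)
      expect_equal(unname(s$percentages[c("adapter3_null", "insert_null",
                                          "adapter5_contaminant", "too_short",
                                          "polyA", "clean_reads")]),
                   c(0.63, 0.02, 0.05, 6.66, 0.00, 92.64))
    }
    # categories partition the high-quality reads and percentages close
    expect_equal(sum(s$counts[c("adapter3_null", "insert_null",
                                "adapter5_contaminant", "too_short",
                                "polyA", "clean_reads")]),
                 s$counts[["high_quality"]])
    expect_lt(abs(sum(s$percentages[-1]) - 100), 0.03)
  }
})

test_that("cleaning a simulated library reproduces its truth table exactly", {
  g <- make_genome(genome_config(genome_length = 20000, n_genes = 4,
                                 n_rrna = 2, n_hairpins = 3), seed = 11)
  lib <- simulate_srna_library(g, library_profile(n_reads = 4000, seed = 12))
  cl <- clean_library(lib$reads)
  truth_counts <- table(lib$truth$expected_category)
  for (k in c("adapter3_null", "insert_null", "adapter5_contaminant",
              "too_short", "polyA", "low_quality")) {
    want <- if (k %in% names(truth_counts)) truth_counts[[k]] else 0
    expect_equal(unname(cl$summary$counts[[if (k == "low_quality") "low_quality" else k]]),
                 want, info = k)
  }
  expect_equal(unname(cl$summary$counts[["clean_reads"]]),
               sum(lib$truth$expected_category == "clean"))
  # round trip through FASTQ on disk gives the same summary
  f <- tempfile(fileext = ".fq")
  write_fastq(lib$reads, f)
  cl2 <- clean_library(f)
  expect_identical(cl$summary, cl2$summary)
})

test_that("an empty library yields an all-zero summary", {
  cl <- clean_library(data.frame(id = character(0), seq = character(0),
                                 qual = character(0)))
  expect_equal(unname(cl$summary$counts[["total_reads"]]), 0)
  expect_true(all(cl$summary$percentages == 0))
  expect_false(anyNA(cl$summary$percentages))
})

test_that("malformed FASTQ is reported with its record index", {
  f <- tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "BAD", "IIII"), f)
  expect_error(read_fastq(f), "record 2")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+"), f)
  expect_error(read_fastq(f), "record 2")
})

test_that("length histograms count only the 10-44 nt window", {
  h <- length_histogram(rep(22L, 5))
  expect_equal(h$total, 5)
  expect_equal(unname(h$counts[["22"]]), 5)
  expect_true(all(h$counts[names(h$counts) != "22"] == 0))
  h2 <- length_histogram(c(9L, 10L, 44L, 45L))
  expect_equal(h2$total, 2)
  h0 <- length_histogram(integer(0))
  expect_equal(h0$total, 0)
  expect_true(all(h0$counts == 0))
  # a planted 20/33 mix is recovered within 3 sigmas
  set.seed(1)
  lens <- sample(c(20L, 33L), 10000, replace = TRUE, prob = c(0.7, 0.3))
  h3 <- length_histogram(lens)
  expect_lt(abs(h3$counts[["20"]] - 7000), 3 * sqrt(10000 * 0.7 * 0.3))
})

test_that("the length-distribution chi-square behaves like Pearson's test", {
  hA <- length_histogram(rep(c(20L, 33L), c(10, 20)))
  hB <- length_histogram(rep(c(20L, 33L), c(20, 10)))
  res <- chi2_length_test(hA, hB)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-9)
  expect_equal(res$df, 1)
  # identical distributions give statistic 0, p 1
  same <- chi2_length_test(hA, hA)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # proportional tables carry no signal
  hB3 <- length_histogram(rep(c(20L, 33L), c(30, 60)))
  expect_equal(chi2_length_test(hA, hB3)$statistic, 0, tolerance = 1e-9)
  # swapping the libraries leaves the statistic unchanged
  expect_equal(chi2_length_test(hB, hA)$statistic, res$statistic)
  expect_error(chi2_length_test(length_histogram(integer(0)), hA),
               "at least one tag")
})
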