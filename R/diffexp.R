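#' Altered-miRNA call from per-library copy numbers
#'
#' A miRNA is evaluable only when it has at least `min_copies` copies in
#' both libraries; among evaluable miRNAs, a `fold`-fold (default
#' two-fold) difference in copy numbers in either direction is called
#' up/down in library A, anything smaller is called equal. Raw copy
#' numbers are compared by default; `normalize = TRUE` compares
#' copies-per-million when the library totals are supplied.
#'
#' @param copies_a,copies_b raw copy numbers in the two libraries
#'   (vectorised).
#' @param name optional miRNA names.
#' @param totals optional `(total_a, total_b)` library sizes for
#'   per-million normalisation.
#' @param normalize compare per-million values instead of raw copies.
#' @param min_copies evaluability floor, default 10 copies in both.
#' @param fold fold-change threshold, default 2.
#' @return data frame: name, copies, per-million values (when totals are
#'   given), `fold_change` (A over B on the compared scale) and `call`
#'   among `up_in_A`, `down_in_A`, `equal`, `not_evaluable`.
#' @export
altered_mirna <- function(copies_a, copies_b, name = NULL, totals = NULL,
                          normalize = FALSE, min_copies = 10, fold = 2) {
  stopifnot(length(copies_a) == length(copies_b))
  if (any(copies_a < 0 | copies_b < 0)) stop("copy numbers must be non-negative")
  if (normalize && is.null(totals)) {
    stop("normalize = TRUE requires library totals")
  }
  norm_a <- if (!is.null(totals)) 1e6 * copies_a / totals[1] else NA_real_
  norm_b <- if (!is.null(totals)) 1e6 * copies_b / totals[2] else NA_real_
  va <- if (normalize) norm_a else copies_a
  vb <- if (normalize) norm_b else copies_b
  evaluable <- pmin(copies_a, copies_b) >= min_copies
  call <- rep("equal", length(copies_a))
  call[va >= fold * vb] <- "up_in_A"
  call[vb >= fold * va] <- "down_in_A"
  call[!evaluable] <- "not_evaluable"
  data.frame(name = if (is.null(name)) sprintf("mir%d", seq_along(copies_a)) else name,
             copies_a = copies_a, copies_b = copies_b,
             norm_a = norm_a, norm_b = norm_b,
             fold_change = ifelse(evaluable & vb > 0, va / vb, NA_real_),
             call = call, stringsAsFactors = FALSE)
}

#' Reads per kilobase per million mapped reads
#'
#' @param count mapped read count(s).
#' @param gene_length_nt transcript length(s) in nt (> 0).
#' @param library_total total reads of the library (> 0).
#' @return `1e9 * count / (library_total * gene_length_nt)`.
#' @export
rpkm <- function(count, gene_length_nt, library_total) {
  if (any(gene_length_nt <= 0)) stop("gene length must be positive")
  if (any(library_total <= 0)) stop("library total must be positive")
  1e9 * count / (library_total * gene_length_nt)
}

#' log2 expression ratio
#'
#' @param rpkm_a,rpkm_b RPKM values (> 0).
#' @return `log2(rpkm_a / rpkm_b)`.
#' @export
log2_ratio <- function(rpkm_a, rpkm_b) {
  if (any(rpkm_a <= 0 | rpkm_b <= 0)) {
    stop("log2_ratio requires positive RPKM values")
  }
  log2(rpkm_a / rpkm_b)
}

#' Probability of equal expression for one gene in two pooled samples
#'
#' The Audic-Claverie conditional count model: given `x` reads in sample 1
#' (depth N1), the count `y` in sample 2 (depth N2) under equal expression
#' follows `p(y|x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1))`, a
#' negative binomial with size `x+1` and success probability
#' `N1/(N1+N2)`; tails are accumulated in log space through `pnbinom`. The
#' two-sided p-value doubles the smaller of the two directional depletion
#' tails, `P(Y <= y | x)` and `P(X <= x | y)` (each taken from the
#' conditional model in its own direction), capped at 1 — a construction
#' that is symmetric under exchanging `(x, N1)` with `(y, N2)`.
#'
#' @param x,y non-negative integer read counts in the two samples
#'   (vectorised).
#' @param N1,N2 total clean reads of the two libraries.
#' @return two-sided p-value(s) in `[0, 1]`.
#' @export
p_equal <- function(x, y, N1, N2) {
  if (any(x < 0 | y < 0)) stop("counts must be non-negative")
  if (any(x != floor(x) | y != floor(y))) stop("counts must be integers")
  if (N1 <= 0 || N2 <= 0) stop("library totals must be positive")
  lower_yx <- stats::pnbinom(y, size = x + 1, prob = N1 / (N1 + N2))
  lower_xy <- stats::pnbinom(x, size = y + 1, prob = N2 / (N1 + N2))
  pmin(1, 2 * pmin(lower_yx, lower_xy))
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjusted q-values.
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @return q-values in `[0, 1]`, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

#' Differential-expression call for one gene
#'
#' @param log2_ratio log2 expression ratio.
#' @param fdr Benjamini-Hochberg adjusted p-value.
#' @param fdr_cutoff,lfc_cutoff thresholds (defaults 0.001 and 1).
#' @return `"up"`, `"down"`, or `"ns"` (vectorised).
#' @export
dge_call <- function(log2_ratio, fdr, fdr_cutoff = 0.001, lfc_cutoff = 1) {
  out <- rep("ns", length(log2_ratio))
  out[fdr < fdr_cutoff & log2_ratio > lfc_cutoff] <- "up"
  out[fdr < fdr_cutoff & log2_ratio < -lfc_cutoff] <- "down"
  out
}

#' Digital gene expression table for two pooled samples
#'
#' Per gene: RPKM in both samples, log2 ratio (with a 0.5-count
#' pseudo-offset only where one sample has zero reads; the p-value always
#' uses the raw integers), the Audic-Claverie equal-expression p-value,
#' Benjamini-Hochberg FDR, and the significance call at FDR < 0.001 and
#' |log2 ratio| > 1. Genes with zero counts in both samples are excluded.
#'
#' @param counts_1,counts_2 per-gene read counts.
#' @param lengths per-gene transcript lengths (nt).
#' @param N1,N2 library totals (clean reads).
#' @param gene_id optional gene identifiers.
#' @param fdr_cutoff,lfc_cutoff call thresholds.
#' @return list with `results` (data frame of per-gene statistics and
#'   calls) and `summary` (a [dge_summary()]).
#' @export
dge_table <- function(counts_1, counts_2, lengths, N1, N2, gene_id = NULL,
                      fdr_cutoff = 0.001, lfc_cutoff = 1) {
  stopifnot(length(counts_1) == length(counts_2),
            length(lengths) == length(counts_1))
  if (is.null(gene_id)) gene_id <- sprintf("gene%05d", seq_along(counts_1))
  keep <- counts_1 + counts_2 > 0
  gene_id <- gene_id[keep]
  c1 <- counts_1[keep]; c2 <- counts_2[keep]; len <- lengths[keep]
  r1 <- rpkm(c1, len, N1)
  r2 <- rpkm(c2, len, N2)
  off1 <- ifelse(c1 == 0 | c2 == 0, 0.5, 0)
  lr <- log2(rpkm(c1 + off1, len, N1) / rpkm(c2 + off1, len, N2))
  p <- p_equal(c1, c2, N1, N2)
  q <- bh_fdr(p)
  call <- dge_call(lr, q, fdr_cutoff, lfc_cutoff)
  res <- data.frame(gene_id = gene_id, length = len, count_1 = c1,
                    count_2 = c2, rpkm_1 = r1, rpkm_2 = r2,
                    log2_ratio = lr, p_equal = p, fdr = q, call = call,
                    stringsAsFactors = FALSE)
  list(results = res,
       summary = dge_summary(sum(call == "up"), sum(call == "down")))
}

#' Differential-expression summary counts
#'
#' @param n_up,n_down numbers of up- and down-regulated genes.
#' @return named vector with `n_up`, `n_down`, and their `total`.
#' @export
dge_summary <- function(n_up, n_down) {
  c(n_up = n_up, n_down = n_down, total = n_up + n_down)
}
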