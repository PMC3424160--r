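#' Minimum-free-energy miRNA:target duplex for one window
#'
#' Exact dynamic program over all monotone antiparallel intermolecular
#' pairings of the miRNA against the window under the shared
#' [energy_model()] (intramolecular pairing forbidden); bulges and
#' internal loops between consecutive pairs are penalised per nucleotide,
#' and the empty duplex defines energy 0.
#'
#' @param mirna miRNA sequence, 5' to 3' (ACGU/ACGT).
#' @param window target window sequence, 5' to 3'.
#' @param model an [energy_model()].
#' @return list with `energy` (kcal/mol, <= 0), `mirna_pos`/`window_pos`
#'   (1-based positions of the paired bases, by increasing miRNA
#'   position), and `pairing` (three-line alignment string).
#' @export
duplex_mfe <- function(mirna, window, model = energy_model()) {
  assert_dna(mirna, what = "mirna"); assert_dna(window, what = "window")
  if (!nzchar(mirna) || !nzchar(window)) stop("sequences must be non-empty")
  res <- duplex_mfe_cpp(mirna, window, unname(model$stack),
                        model$bulge_per_nt, model$internal_per_nt)
  list(energy = res$energy, mirna_pos = res$mirna_pos,
       window_pos = res$window_pos,
       pairing = format_duplex(mirna, window, res$mirna_pos, res$window_pos))
}

# compact alignment rendering: miRNA 5'->3' over pairing bars over the
# window 3'->5'
format_duplex <- function(mirna, window, mirna_pos, window_pos) {
  if (!length(mirna_pos)) return("(no duplex)")
  m <- strsplit(toupper(mirna), "")[[1]]
  w <- strsplit(toupper(window), "")[[1]]
  top <- character(0); mid <- character(0); bot <- character(0)
  emit <- function(a, b, bar) {
    top <<- c(top, a); mid <<- c(mid, bar); bot <<- c(bot, b)
  }
  # leading unpaired miRNA 5' end
  for (i in seq_len(mirna_pos[1] - 1)) emit(m[i], " ", " ")
  for (k in seq_along(mirna_pos)) {
    emit(m[mirna_pos[k]], w[window_pos[k]], "|")
    if (k < length(mirna_pos)) {
      gi <- (mirna_pos[k] + 1):(mirna_pos[k + 1] - 1)
      gj <- if (window_pos[k] - 1 >= window_pos[k + 1] + 1) {
        (window_pos[k] - 1):(window_pos[k + 1] + 1)
      } else integer(0)
      gi <- gi[gi <= mirna_pos[k + 1] - 1 & gi >= mirna_pos[k] + 1]
      L <- max(length(gi), length(gj))
      for (g in seq_len(L)) {
        emit(if (g <= length(gi)) m[gi[g]] else "-",
             if (g <= length(gj)) w[gj[g]] else "-", " ")
      }
    }
  }
  for (i in seq_len(length(m) - mirna_pos[length(mirna_pos)])) {
    emit(m[mirna_pos[length(mirna_pos)] + i], " ", " ")
  }
  paste0("miRNA  5' ", paste(top, collapse = ""), " 3'\n",
         "          ", paste(mid, collapse = ""), "\n",
         "target 3' ", paste(bot, collapse = ""), " 5'")
}

#' Best predicted target site of a miRNA on one transcript
#'
#' Scans the transcript in overlapping windows, computes the duplex MFE in
#' each, and reports the single lowest-energy site passing the cutoff
#' (ties broken by leftmost transcript position). With `seed_required`,
#' sites must pair every miRNA seed position (2-8) contiguously.
#'
#' @param mirna mature miRNA sequence, 5' to 3'.
#' @param transcript transcript sequence, 5' to 3'.
#' @param model an [energy_model()].
#' @param energy_cutoff report only sites with energy strictly below this
#'   (default -20 kcal/mol).
#' @param seed_required require contiguous pairing of miRNA positions 2-8.
#' @param window,step scan window length and step (defaults 60/30 nt).
#' @param mirna_name,transcript_id identifiers carried into the result.
#' @return one-row data frame (`DuplexSite`: site_start, site_end on the
#'   transcript, energy, pairing, rank 1), or `NULL` when no site passes.
#' @export
predict_targets <- function(mirna, transcript, model = energy_model(),
                            energy_cutoff = -20, seed_required = FALSE,
                            window = 60, step = 30, mirna_name = "mirna",
                            transcript_id = "transcript") {
  n <- nchar(transcript)
  last <- max(1, n - window + 1)
  starts <- unique(c(seq(1, last, by = step), last))
  best <- NULL
  for (ws in starts) {
    wseq <- substr(transcript, ws, min(n, ws + window - 1))
    d <- duplex_mfe(mirna, wseq, model)
    if (!length(d$mirna_pos)) next
    if (seed_required && !seed_paired(d$mirna_pos, d$window_pos)) next
    site_start <- ws + min(d$window_pos) - 1
    site_end <- ws + max(d$window_pos) - 1
    if (d$energy < energy_cutoff &&
        (is.null(best) || d$energy < best$energy ||
         (d$energy == best$energy && site_start < best$site_start))) {
      best <- data.frame(mirna_name = mirna_name,
                         transcript_id = transcript_id,
                         site_start = site_start, site_end = site_end,
                         energy = d$energy, pairing = d$pairing, rank = 1L,
                         stringsAsFactors = FALSE)
    }
  }
  best
}

# contiguous pairing of miRNA positions 2-8 against consecutive window
# positions
seed_paired <- function(mirna_pos, window_pos) {
  idx <- match(2:8, mirna_pos)
  if (anyNA(idx)) return(FALSE)
  all(diff(window_pos[idx]) == -1)
}

#' Predict targets of a miRNA set across a transcript set
#'
#' @param mirnas named character vector of mature sequences.
#' @param transcripts named character vector of transcript sequences.
#' @inheritParams predict_targets
#' @return data frame of best sites, one row per (miRNA, transcript) pair
#'   with a reported site.
#' @export
predict_target_map <- function(mirnas, transcripts, model = energy_model(),
                               energy_cutoff = -20, seed_required = FALSE,
                               window = 60, step = 30) {
  rows <- list()
  for (m in seq_along(mirnas)) {
    for (t in seq_along(transcripts)) {
      s <- predict_targets(mirnas[[m]], transcripts[[t]], model,
                           energy_cutoff, seed_required, window, step,
                           mirna_name = names(mirnas)[m],
                           transcript_id = names(transcripts)[t])
      if (!is.null(s)) rows[[length(rows) + 1]] <- s
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna_name = character(0), transcript_id = character(0),
                      site_start = integer(0), site_end = integer(0),
                      energy = numeric(0), pairing = character(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Overlap between differentially expressed genes and predicted targets
#'
#' @param deg_ids identifiers of the differentially expressed genes.
#' @param target_map target table (any data frame with a `transcript_id`
#'   column, e.g. from [predict_target_map()]), or a character vector of
#'   targeted gene identifiers.
#' @return list with `n_deg`, `n_deg_targets` and `proportion` (percent,
#'   one decimal, half-up).
#' @export
overlap_report <- function(deg_ids, target_map) {
  targets <- if (is.data.frame(target_map)) {
    unique(target_map$transcript_id)
  } else unique(target_map)
  deg_ids <- unique(deg_ids)
  n_deg <- length(deg_ids)
  n_hit <- sum(deg_ids %in% targets)
  list(n_deg = n_deg, n_deg_targets = n_hit,
       proportion = if (n_deg > 0) pct_of(n_hit, n_deg, 1) else 0)
}
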