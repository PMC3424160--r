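# Independent brute-force oracles used to verify the dynamic programs and
# statistics. They share only the energy *definition* (via the exported
# structure/duplex evaluators) with the implementation, never its
# minimisation or tail algorithms.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]),
        collapse = "")
}

# all non-crossing structures of a sequence respecting min_loop
enumerate_structures <- function(seq, min_loop = 3) {
  b <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  n <- length(b)
  can <- function(a, c) paste0(b[a], b[c]) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > j) return(list(matrix(integer(0), ncol = 2)))
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- rec(i + 1, j)
    if (i + min_loop + 1 <= j) {
      for (k in (i + min_loop + 1):j) {
        if (!can(i, k)) next
        inner <- rec(i + 1, k - 1)
        outer <- rec(k + 1, j)
        for (A in inner) for (B in outer) {
          out[[length(out) + 1]] <- rbind(c(i, k), A, B)
        }
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1, n)
}

# exhaustive MFE over all enumerated structures, scored independently of
# the folding DP by the explicit loop-decomposition evaluator
brute_fold_mfe <- function(seq, model = jellymir::energy_model()) {
  structs <- enumerate_structures(seq, model$min_loop)
  min(vapply(structs, function(p) {
    jellymir::structure_energy(seq, p, model)
  }, numeric(1)))
}

# all monotone antiparallel intermolecular matchings (miRNA position
# increasing, window position decreasing), complementary pairs only
enumerate_duplexes <- function(mirna, window) {
  m <- strsplit(chartr("Tt", "Uu", toupper(mirna)), "")[[1]]
  w <- strsplit(chartr("Tt", "Uu", toupper(window)), "")[[1]]
  can <- function(a, c) paste0(m[a], w[c]) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  out <- list()
  rec <- function(i, jmin, acc) {
    if (i > length(m)) {
      out[[length(out) + 1]] <<- acc
      return(invisible())
    }
    rec(i + 1, jmin, acc)
    if (jmin > 1) {
      for (j in seq_len(jmin - 1)) {
        if (can(i, j)) rec(i + 1, j, rbind(acc, c(i, j)))
      }
    }
  }
  rec(1, length(w) + 1, matrix(integer(0), ncol = 2))
  out
}

brute_duplex_mfe <- function(mirna, window, model = jellymir::energy_model()) {
  min(vapply(enumerate_duplexes(mirna, window), function(p) {
    jellymir::duplex_energy(mirna, window, p, model)
  }, numeric(1)))
}

# exhaustive all-window Hamming scan on both strands with best-stratum
# reporting, for checking map_tags
brute_map <- function(tag, genome_seq, max_mismatch = 1) {
  g <- strsplit(toupper(genome_seq), "")[[1]]
  L <- nchar(tag)
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") toupper(tag) else oracle_revcomp(toupper(tag))
    t <- strsplit(pat, "")[[1]]
    no <- length(g) - L + 1
    if (no < 1) next
    idx <- outer(seq_len(L), 0:(no - 1), "+")
    mm <- colSums(matrix(g[idx], nrow = L) != t)
    sel <- which(mm <= max_mismatch)
    if (length(sel)) {
      hits[[strand]] <- data.frame(start = sel, end = sel + L - 1,
                                   strand = strand, mismatches = mm[sel],
                                   stringsAsFactors = FALSE)
    }
  }
  h <- do.call(rbind, hits)
  if (is.null(h) || !nrow(h)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  }
  h <- h[h$mismatches == min(h$mismatches), , drop = FALSE]
  h <- h[order(h$start, h$strand), , drop = FALSE]
  rownames(h) <- NULL
  h
}

# direct log-space summation of the Audic-Claverie conditional terms
brute_p_equal <- function(x, y, N1, N2) {
  r <- N2 / N1
  lterm <- function(k, xx, rr) {
    k * log(rr) + lgamma(xx + k + 1) - lgamma(xx + 1) - lgamma(k + 1) -
      (xx + k + 1) * log(1 + rr)
  }
  lower_yx <- sum(exp(lterm(0:y, x, r)))
  lower_xy <- sum(exp(lterm(0:x, y, 1 / r)))
  min(1, 2 * min(lower_yx, lower_xy))
}

# step-up definition of Benjamini-Hochberg: q_(k) = min_{j >= k} p_(j) n / j
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (k in seq_len(n)) {
    q[k] <- min(1, min(ps[k:n] * n / (k:n)))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# deterministic random DNA for test fixtures
rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
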