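#' Simplified nearest-neighbour RNA energy model
#'
#' A desk-scale surrogate for a full thermodynamic parameter set, shared by
#' the hairpin folding and the miRNA:target duplex prediction. Helix
#' stability comes from stacking energies keyed by the 5'-most pair of each
#' stack (Watson-Crick plus the G:U wobble); destabilising loops are charged
#' flat (hairpin loops) or per unpaired nucleotide (bulges and internal
#' loops). Multi-branched loops are charged as internal loops. All energies
#' are in kcal/mol.
#'
#' @param stack named numeric of stacking energies for pair types
#'   `AU, UA, GC, CG, GU, UG` (all negative).
#' @param hairpin_loop flat hairpin-loop penalty (>= 0).
#' @param bulge_per_nt per-nucleotide bulge penalty (>= 0).
#' @param internal_per_nt per-nucleotide internal-loop penalty (>= 0);
#'   also the per-nucleotide charge inside multiloops.
#' @param min_loop minimum number of unpaired bases in a hairpin loop
#'   (>= 3).
#' @return an object of class `energy_model`.
#' @export
energy_model <- function(stack = c(AU = -2, UA = -2, GC = -3, CG = -3,
                                   GU = -1, UG = -1),
                         hairpin_loop = 4, bulge_per_nt = 3,
                         internal_per_nt = 2, min_loop = 3) {
  types <- c("AU", "UA", "GC", "CG", "GU", "UG")
  if (!all(types %in% names(stack))) {
    stop("stack must name all of ", paste(types, collapse = ", "))
  }
  stack <- stack[types]
  if (any(stack >= 0)) stop("stack energies must be negative")
  if (hairpin_loop < 0 || bulge_per_nt < 0 || internal_per_nt < 0) {
    stop("loop penalties must be non-negative")
  }
  if (min_loop < 3) stop("min_loop must be at least 3")
  structure(list(stack = stack, hairpin_loop = hairpin_loop,
                 bulge_per_nt = bulge_per_nt,
                 internal_per_nt = internal_per_nt,
                 min_loop = as.integer(min_loop)),
            class = "energy_model")
}

# pair type of two bases ("A","C","G","U"/"T"), NA if not pairable
pair_type <- function(a, b) {
  key <- paste0(chartr("T", "U", a), chartr("T", "U", b))
  ok <- c("AU", "UA", "GC", "CG", "GU", "UG")
  ifelse(key %in% ok, key, NA_character_)
}

#' Parse a dot-bracket string into base-pair indices
#'
#' @param structure dot-bracket string.
#' @return two-column integer matrix (`i`, `j`), 1-based, `i < j`.
#' @export
db_pairs <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  open <- integer(0)
  out <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  for (p in seq_along(chars)) {
    if (chars[p] == "(") {
      open <- c(open, p)
    } else if (chars[p] == ")") {
      if (!length(open)) stop("unbalanced brackets in structure")
      out <- rbind(out, c(open[length(open)], p))
      open <- open[-length(open)]
    } else if (chars[p] != ".") {
      stop("invalid character in dot-bracket string: ", chars[p])
    }
  }
  if (length(open)) stop("unbalanced brackets in structure")
  out[order(out[, 1]), , drop = FALSE]
}

#' Energy of a given secondary structure
#'
#' Evaluates the loop-decomposition energy of an explicit structure under
#' the model, independently of the folding dynamic program. Used both to
#' audit folds and as the scoring half of the exhaustive test oracle.
#'
#' @param seq nucleotide sequence (ACGU/ACGT).
#' @param structure dot-bracket string, or a two-column pair matrix as
#'   returned by [db_pairs()].
#' @param model an [energy_model()].
#' @return energy in kcal/mol.
#' @export
structure_energy <- function(seq, structure, model = energy_model()) {
  assert_dna(seq)
  b <- strsplit(toupper(seq), "")[[1]]
  pairs <- if (is.character(structure)) db_pairs(structure) else structure
  if (nrow(pairs) == 0) return(0)
  if (any(is.na(pair_type(b[pairs[, 1]], b[pairs[, 2]])))) {
    stop("structure contains a non-complementary pair")
  }
  if (any(pairs[, 2] - pairs[, 1] - 1 < model$min_loop)) {
    stop("structure violates the minimum hairpin loop length")
  }
  # parent of each pair = smallest enclosing pair
  n <- nrow(pairs)
  span <- pairs[, 2] - pairs[, 1]
  parent <- rep(NA_integer_, n)
  for (k in seq_len(n)) {
    enclosing <- which(pairs[, 1] < pairs[k, 1] & pairs[, 2] > pairs[k, 2])
    if (length(enclosing)) parent[k] <- enclosing[which.min(span[enclosing])]
  }
  e <- 0
  for (k in seq_len(n)) {
    kids <- which(!is.na(parent) & parent == k)
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (length(kids) == 0) {
      e <- e + model$hairpin_loop
    } else if (length(kids) == 1) {
      ci <- pairs[kids, 1]; cj <- pairs[kids, 2]
      u1 <- ci - i - 1; u2 <- j - cj - 1
      if (u1 == 0 && u2 == 0) {
        e <- e + model$stack[[pair_type(b[i], b[j])]]
      } else if (u1 == 0 || u2 == 0) {
        e <- e + model$bulge_per_nt * (u1 + u2)
      } else {
        e <- e + model$internal_per_nt * (u1 + u2)
      }
    } else {
      u <- (j - i - 1) - sum(pairs[kids, 2] - pairs[kids, 1] + 1)
      e <- e + model$internal_per_nt * u
    }
  }
  unname(e)
}

#' Energy of an explicit miRNA:target duplex
#'
#' Scores a monotone antiparallel matching between a miRNA and a target
#' window under the model: gap-free steps are stacks (keyed by the
#' 5'-miRNA-side pair), one-sided gaps bulges, two-sided gaps internal
#' loops. The empty duplex scores 0.
#'
#' @param mirna miRNA sequence, 5' to 3'.
#' @param window target window sequence, 5' to 3'.
#' @param pairs two-column matrix: miRNA position, window position. miRNA
#'   positions must increase while window positions decrease (antiparallel).
#' @param model an [energy_model()].
#' @return energy in kcal/mol.
#' @export
duplex_energy <- function(mirna, window, pairs, model = energy_model()) {
  assert_dna(mirna); assert_dna(window)
  if (nrow(pairs) == 0) return(0)
  m <- strsplit(toupper(mirna), "")[[1]]
  w <- strsplit(toupper(window), "")[[1]]
  o <- order(pairs[, 1])
  pairs <- pairs[o, , drop = FALSE]
  if (nrow(pairs) > 1 && any(diff(pairs[, 2]) >= 0)) {
    stop("duplex pairs must be antiparallel (window positions decreasing)")
  }
  if (any(is.na(pair_type(m[pairs[, 1]], w[pairs[, 2]])))) {
    stop("duplex contains a non-complementary pair")
  }
  e <- 0
  for (k in seq_len(nrow(pairs) - 1)) {
    a <- pairs[k + 1, 1] - pairs[k, 1] - 1
    bgap <- pairs[k, 2] - pairs[k + 1, 2] - 1
    if (a == 0 && bgap == 0) {
      e <- e + model$stack[[pair_type(m[pairs[k, 1]], w[pairs[k, 2]])]]
    } else if (a == 0 || bgap == 0) {
      e <- e + model$bulge_per_nt * (a + bgap)
    } else {
      e <- e + model$internal_per_nt * (a + bgap)
    }
  }
  unname(e)
}
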