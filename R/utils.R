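#' Round half away from zero
#'
#' Fixed-point rounding in the "half-up" convention used by the printed
#' summary tables (base R's `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a total, half-up rounded
#'
#' @param count numeric numerator(s).
#' @param total denominator.
#' @param digits decimal places (default 2, the printed-table style).
#' @return `100 * count / total` rounded; 0 where `total` is 0.
#' @export
pct_of <- function(count, total, digits = 2) {
  if (length(total) == 1 && total == 0) return(rep(0, length(count)))
  round_half_up(100 * count / total, digits)
}

# reverse complement of plain DNA character vectors (T alphabet)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# normalise RNA-style sequences to the DNA alphabet used internally
dna_norm <- function(x) chartr("Uu", "Tt", toupper(x))

# random DNA of given lengths (uses the current RNG stream)
rand_dna <- function(lengths) {
  vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

assert_dna <- function(x, allow_n = FALSE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTUNacgtun]*$" else "^[ACGTUacgtu]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(what, " contains invalid characters: ",
         paste(utils::head(x[bad], 3), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}
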