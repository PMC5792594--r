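#' The 20 standard amino acids
#'
#' Single-letter codes, alphabetical, used as the residue alphabet for all
#' simulated sequences and profile columns.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# split a sequence string into residue characters
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# 0-based integer codes for the C scanner; errors on non-standard residues
seq_codes <- function(x) {
  codes <- match(seq_chars(x), AA_ALPHABET) - 1L
  if (anyNA(codes)) {
    stop("sequence contains non-amino-acid characters: ",
         paste(unique(setdiff(seq_chars(x), AA_ALPHABET)), collapse = ", "))
  }
  codes
}

assert_aa <- function(x, what = "sequence") {
  bad <- setdiff(unique(seq_chars(x)), AA_ALPHABET)
  if (length(bad) > 0) {
    stop(what, " contains non-amino-acid characters: ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

random_aa_seq <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

# uniform random replacement over the 20 residues at the given positions
# (a draw may coincide with the current residue; identity arithmetic
# accounts for this)
mutate_positions <- function(seq, positions) {
  if (length(positions) == 0) return(seq)
  ch <- seq_chars(seq)
  ch[positions] <- sample(AA_ALPHABET, length(positions), replace = TRUE)
  paste(ch, collapse = "")
}
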