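DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
rev_comp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Hamming distance between equal-length strings
#'
#' @param a,b character vectors (recycled); all strings in a pair must have
#'   equal length.
#' @return integer vector of per-pair mismatch counts.
#' @export
hamming <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  mapply(function(x, y) {
    if (nchar(x) != nchar(y)) stop("hamming(): strings differ in length")
    sum(utf8ToInt(x) != utf8ToInt(y))
  }, a, b, USE.NAMES = FALSE)
}

# split sequences into a character matrix (rows = positions); all equal length
seq_char_matrix <- function(seqs, width) {
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = width)
}

round1 <- function(x) round(x, 1)

# collapse a character vector of flags to a single comma-separated field
flag_str <- function(...) {
  f <- c(...)
  f <- f[nzchar(f)]
  if (length(f) == 0L) "" else paste(f, collapse = ",")
}

has_flag <- function(flags, flag) {
  vapply(strsplit(flags, ",", fixed = TRUE), function(f) flag %in% f, logical(1))
}
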