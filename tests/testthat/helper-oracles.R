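# Independent oracles used to cross-check the package's implementations.

# Plain-R local alignment score (Gotoh affine gaps; a gap of length k costs
# gap_open + (k - 1) * gap_extend). Score only, no traceback; written
# independently of the compiled aligner.
sw_score_oracle <- function(read, ref, match = 1, mismatch = -1,
                            gap_open = -2, gap_extend = -1) {
  a <- strsplit(read, "")[[1]]
  b <- strsplit(ref, "")[[1]]
  m <- length(a); n <- length(b)
  NEG <- -1e18
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] + gap_open, E[i + 1, j] + gap_extend)
      F[i + 1, j + 1] <- max(H[i, j + 1] + gap_open, F[i, j + 1] + gap_extend)
      d <- H[i, j] + if (a[i] == b[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, d, E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# Pair-by-pair concordance count over two genotype tables.
concordance_oracle <- function(a, b) {
  fold <- function(g) {
    g[g == "hemi_ref"] <- "hom_ref"
    g[g == "hemi_alt"] <- "hom_alt"
    g
  }
  n <- 0L; nd <- 0L
  for (i in seq_len(nrow(a))) {
    ga <- fold(a$genotype[i])
    if (ga == "no_call") next
    j <- which(b$sample_id == a$sample_id[i] & b$site_key == a$site_key[i])
    if (length(j) == 0L) next
    gb <- fold(b$genotype[j[1]])
    if (gb == "no_call") next
    n <- n + 1L
    if (ga != gb) nd <- nd + 1L
  }
  list(n_compared = n, n_discordant = nd)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}
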