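#' Build a dual 8-bp index scheme
#'
#' Generates `n_fwd` forward and `n_rev` reverse indices of the given length
#' by randomized-greedy sampling, enforcing a minimum pairwise Hamming
#' distance within each list. The valid sample pairs are all (forward,
#' reverse) rank combinations; with `exclude_same_rank` (the default) pairs
#' where the forward and reverse index have the same rank are excluded as an
#' anti-contamination safeguard, so a 10 x 10 design yields 90 usable
#' combinations rather than 100.
#'
#' @param n_fwd,n_rev number of forward/reverse indices.
#' @param length index length in bases (default 8).
#' @param min_hamming minimum pairwise Hamming distance within each list
#'   (default 3, making 1-mismatch demultiplexing unambiguous).
#' @param exclude_same_rank drop (i, i) pairs from the valid set.
#' @param seed integer seed.
#' @param max_attempts sampling attempts before giving up.
#' @return object of class `index_scheme`.
#' @export
build_index_scheme <- function(n_fwd, n_rev, length = 8L, min_hamming = 3L,
                               exclude_same_rank = TRUE, seed = 1L,
                               max_attempts = 20000L) {
  stopifnot(n_fwd >= 1, n_rev >= 1, length >= min_hamming)
  set.seed(seed)
  gen <- function(n) {
    acc <- character(0)
    attempts <- 0L
    while (base::length(acc) < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop(sprintf(
          "could not generate %d indices of length %d at min Hamming %d",
          n, length, min_hamming))
      cand <- paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
      if (base::length(acc) == 0L || all(hamming(cand, acc) >= min_hamming))
        acc <- c(acc, cand)
    }
    acc
  }
  fwd <- gen(n_fwd)
  rev <- gen(n_rev)
  pairs <- expand.grid(fwd_rank = seq_len(n_fwd), rev_rank = seq_len(n_rev),
                       KEEP.OUT.ATTRS = FALSE)
  if (exclude_same_rank)
    pairs <- pairs[pairs$fwd_rank != pairs$rev_rank, , drop = FALSE]
  pairs <- pairs[order(pairs$fwd_rank, pairs$rev_rank), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs$fwd <- fwd[pairs$fwd_rank]
  pairs$rev <- rev[pairs$rev_rank]
  structure(list(forward_indices = fwd, reverse_indices = rev,
                 valid_pairs = pairs, min_pairwise_hamming = min_hamming,
                 index_length = as.integer(length),
                 exclude_same_rank = exclude_same_rank, seed = seed),
            class = "index_scheme")
}

#' @export
print.index_scheme <- function(x, ...) {
  cat(sprintf(
    "index_scheme: %d fwd x %d rev (%d bp, min Hamming %d), %d valid pairs\n",
    length(x$forward_indices), length(x$reverse_indices), x$index_length,
    x$min_pairwise_hamming, nrow(x$valid_pairs)))
  invisible(x)
}

#' Build a sample sheet from an index scheme
#'
#' Assigns valid index pairs to samples in scheme order; index combinations
#' are conserved per sample across all amplicons.
#'
#' @param scheme an `index_scheme`.
#' @param sample_ids character vector of sample ids.
#' @param sexes "male"/"female" per sample.
#' @return data.frame (sample_id, fwd_index, rev_index, sex).
#' @export
make_sample_sheet <- function(scheme, sample_ids, sexes) {
  n <- length(sample_ids)
  if (n > nrow(scheme$valid_pairs))
    stop(sprintf("%d samples exceed the %d valid index pairs of the scheme",
                 n, nrow(scheme$valid_pairs)))
  stopifnot(length(sexes) == n, all(sexes %in% c("male", "female")))
  data.frame(sample_id = sample_ids,
             fwd_index = scheme$valid_pairs$fwd[seq_len(n)],
             rev_index = scheme$valid_pairs$rev[seq_len(n)],
             sex = sexes, stringsAsFactors = FALSE)
}

#' Check a pooling plan
#'
#' Warns when a pool would contain more than `max_per_pool` amplicon
#' products (samples x amplicons), the operational ceiling used to guarantee
#' sufficient per-product coverage.
#'
#' @param n_samples samples in the pool.
#' @param n_amplicons amplicons per sample.
#' @param max_per_pool maximum amplicon products per pool (default 200).
#' @return list with `total_products`, `max_per_pool`, `pools_needed`,
#'   invisibly.
#' @export
check_pool_plan <- function(n_samples, n_amplicons, max_per_pool = 200L) {
  total <- n_samples * n_amplicons
  if (total > max_per_pool)
    warning(sprintf(
      "pooling plan has %d amplicon products, exceeding %d per pool; split into %d pools",
      total, max_per_pool, ceiling(total / max_per_pool)))
  invisible(list(total_products = total, max_per_pool = max_per_pool,
                 pools_needed = as.integer(ceiling(total / max_per_pool))))
}

# per-position Hamming distances of a vector of strings against one string
.dist_to <- function(obs_mat, target) {
  tc <- strsplit(target, "", fixed = TRUE)[[1]]
  colSums(obs_mat != tc)
}

#' Demultiplex a pooled read set by dual indices
#'
#' Reads carry an 8-base forward index as a literal 5' prefix and the
#' reverse index reverse-complemented as a 3' suffix (the simulator
#' contract). A read is assigned to a sample iff both observed indices are
#' within `max_mismatch` of that sample's pair, and to exactly one sample;
#' ambiguous or unmatched reads go to the unassigned bin. Index bases are
#' trimmed from assigned reads.
#'
#' @param reads data.frame (id, seq, qual) as from [simulate_reads()] or
#'   [read_fastq()].
#' @param scheme optional `index_scheme`; when given, sheet pairs are checked
#'   against its valid pairs.
#' @param sheet sample sheet data.frame (sample_id, fwd_index, rev_index,
#'   sex).
#' @param max_mismatch maximum Hamming mismatches tolerated per index
#'   (default 0, exact matching).
#' @return list with `assignments` (read_id, sample_id, reason),
#'   `reads_by_sample` (named list of trimmed read data.frames),
#'   `unassigned` (untrimmed reads), and `stats`.
#' @export
demultiplex <- function(reads, scheme = NULL, sheet, max_mismatch = 0L) {
  if (anyDuplicated(paste(sheet$fwd_index, sheet$rev_index)))
    stop("sample sheet index pairs are not unique")
  if (!is.null(scheme)) {
    ok <- paste(sheet$fwd_index, sheet$rev_index) %in%
      paste(scheme$valid_pairs$fwd, scheme$valid_pairs$rev)
    if (!all(ok))
      stop("sample sheet uses index pairs outside the scheme's valid set: ",
           paste(sheet$sample_id[!ok], collapse = ", "))
  }
  ilen <- nchar(sheet$fwd_index[1])
  n <- nrow(reads)
  len <- nchar(reads$seq)
  sample_id <- rep(NA_character_, n)
  reason <- rep("no_match", n)

  usable <- len >= 2L * ilen
  reason[!usable] <- "too_short"
  if (any(usable)) {
    u <- which(usable)
    obs_fwd <- substr(reads$seq[u], 1L, ilen)
    obs_rev <- rev_comp(substr(reads$seq[u], len[u] - ilen + 1L, len[u]))
    if (max_mismatch == 0L) {
      key <- paste(obs_fwd, obs_rev)
      skey <- paste(sheet$fwd_index, sheet$rev_index)
      hit <- match(key, skey)
      ok <- !is.na(hit)
      sample_id[u[ok]] <- sheet$sample_id[hit[ok]]
      reason[u[ok]] <- "assigned"
    } else {
      fwd_mat <- seq_char_matrix(obs_fwd, ilen)
      rev_mat <- seq_char_matrix(obs_rev, ilen)
      n_hit <- integer(length(u))
      last_hit <- integer(length(u))
      for (j in seq_len(nrow(sheet))) {
        dj <- .dist_to(fwd_mat, sheet$fwd_index[j]) <= max_mismatch &
          .dist_to(rev_mat, sheet$rev_index[j]) <= max_mismatch
        n_hit <- n_hit + dj
        last_hit[dj] <- j
      }
      one <- n_hit == 1L
      sample_id[u[one]] <- sheet$sample_id[last_hit[one]]
      reason[u[one]] <- "assigned"
      reason[u[n_hit > 1L]] <- "ambiguous"
    }
  }

  assignments <- data.frame(read_id = reads$id, sample_id = sample_id,
                            reason = reason, stringsAsFactors = FALSE)
  assigned <- which(reason == "assigned")
  trimmed <- reads[assigned, , drop = FALSE]
  if (nrow(trimmed) > 0L) {
    tl <- nchar(trimmed$seq)
    trimmed$seq <- substr(trimmed$seq, ilen + 1L, tl - ilen)
    trimmed$qual <- substr(trimmed$qual, ilen + 1L, tl - ilen)
  }
  reads_by_sample <- split(trimmed, factor(sample_id[assigned],
                                           levels = sheet$sample_id))
  counts <- vapply(reads_by_sample, nrow, integer(1))
  stats <- list(
    per_sample = data.frame(sample_id = names(counts), n_reads = counts,
                            row.names = NULL, stringsAsFactors = FALSE),
    n_input = n, n_assigned = length(assigned),
    n_unassigned = n - length(assigned),
    unassigned_fraction = if (n > 0) (n - length(assigned)) / n else 0,
    reasons = table(reason))
  list(assignments = assignments, reads_by_sample = reads_by_sample,
       unassigned = reads[reason != "assigned", , drop = FALSE],
       stats = stats)
}
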