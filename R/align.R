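#' Default alignment scoring
#'
#' Match +1, mismatch -1, gap open -2 (first gapped base), gap extend -1.
#' @return named list of scoring parameters.
#' @export
default_scoring <- function() {
  list(match = 1, mismatch = -1, gap_open = -2, gap_extend = -1)
}

#' Align one read locally against a set of amplicon references
#'
#' Smith-Waterman local alignment with affine gaps against every reference;
#' the best-scoring alignment is returned. Alignments whose identity
#' (matches / alignment columns) falls below `min_identity`, or whose
#' reference span is shorter than `min_span` bases, are marked rejected.
#'
#' @param read read sequence (character scalar).
#' @param references named character vector of amplicon sequences.
#' @param scoring scoring list, see [default_scoring()].
#' @param min_identity minimum identity over the aligned span (default 0.8).
#' @param min_span minimum aligned reference span in bases (default 50).
#' @param read_id optional read identifier carried into the result.
#' @return object of class `amp_alignment`: amplicon_id, score, 0-based
#'   `ref_start`/`read_start`, aligned column vectors `ref_pos`/`read_pos`
#'   (0-based) with `read_bases`, mismatch/identity/span statistics, and
#'   `rejected`/`reason`.
#' @export
align_read <- function(read, references, scoring = default_scoring(),
                       min_identity = 0.8, min_span = 50L, read_id = NA) {
  if (length(references) == 0L) stop("references must be non-empty")
  if (is.na(read) || nchar(read) == 0L) {
    return(structure(list(read_id = read_id, amplicon_id = NA_character_,
                          score = 0, rejected = TRUE, reason = "empty_read"),
                     class = "amp_alignment"))
  }
  best <- NULL; best_name <- NA_character_
  for (nm in names(references)) {
    a <- cpp_sw_align(read, references[[nm]], scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend)
    if (is.null(best) || a$score > best$score) { best <- a; best_name <- nm }
  }
  align_len <- best$n_match + best$n_mismatch + best$n_gap_cols
  identity <- if (align_len > 0) best$n_match / align_len else 0
  span <- best$ref_end - best$ref_start + 1L
  rejected <- FALSE; reason <- NA_character_
  if (best$score <= 0) { rejected <- TRUE; reason <- "no_alignment" }
  else if (span < min_span) { rejected <- TRUE; reason <- "short_span" }
  else if (identity < min_identity) { rejected <- TRUE; reason <- "low_identity" }
  structure(list(
    read_id = read_id, amplicon_id = best_name, score = best$score,
    ref_start = best$ref_start, read_start = best$read_start,
    ref_end = best$ref_end, read_end = best$read_end,
    ref_pos = best$ref_pos, read_pos = best$read_pos,
    read_bases = substring(read, best$read_pos + 1L, best$read_pos + 1L),
    n_match = best$n_match, n_mismatch = best$n_mismatch,
    n_gap_cols = best$n_gap_cols, align_len = align_len,
    identity = identity, span = span, rejected = rejected, reason = reason),
    class = "amp_alignment")
}

#' @export
print.amp_alignment <- function(x, ...) {
  if (isTRUE(x$rejected))
    cat(sprintf("amp_alignment (rejected: %s)\n", x$reason))
  else
    cat(sprintf(
      "amp_alignment to %s: score %.0f, ref %d-%d, %d mm, identity %.3f\n",
      x$amplicon_id, x$score, x$ref_start, x$ref_end, x$n_mismatch,
      x$identity))
  invisible(x)
}

#' Batch-align reads and collect variant-site bases
#'
#' Aligns each read to its best-matching amplicon (shared 11-mer screening
#' followed by full Smith-Waterman) and records the read base observed at
#' every variant-site offset of that amplicon. This is the workhorse behind
#' [pileup()] for whole read sets.
#'
#' @param reads data.frame (id, seq, qual) of index-trimmed reads.
#' @param references named character vector of amplicon sequences (names must
#'   match panel amplicon ids).
#' @param panel an `amp_panel`.
#' @inheritParams align_read
#' @param kmer k-mer size used for candidate screening (default 11).
#' @return data.frame with one row per read: `read_id`, `amplicon_id`,
#'   `score`, `ref_start`, `span`, `n_mismatch`, `identity`, `rejected`,
#'   `reason`, and `site_bases` (one character per site of the amplicon, "."
#'   where the alignment does not cover the site).
#' @export
align_reads <- function(reads, references, panel,
                        scoring = default_scoring(), min_identity = 0.8,
                        min_span = 50L, kmer = 11L) {
  sites <- panel_sites(panel)
  offs <- lapply(names(references), function(a)
    as.integer(sites$local_offset[sites$amplicon_id == a]))
  res <- cpp_align_batch(reads$seq, unname(references), offs,
                         scoring$match, scoring$mismatch, scoring$gap_open,
                         scoring$gap_extend, as.integer(kmer), min_identity)
  identity <- ifelse(res$align_len > 0, res$n_match / res$align_len, 0)
  rejected <- is.na(res$ref_index) | res$span < min_span |
    identity < min_identity
  reason <- rep(NA_character_, nrow(reads))
  reason[is.na(res$ref_index)] <- "no_alignment"
  reason[!is.na(res$ref_index) & res$span < min_span] <- "short_span"
  reason[!is.na(res$ref_index) & res$span >= min_span &
           identity < min_identity] <- "low_identity"
  data.frame(
    read_id = reads$id,
    amplicon_id = names(references)[res$ref_index],
    score = res$score, ref_start = res$ref_start, span = res$span,
    n_mismatch = res$n_mismatch, identity = identity,
    rejected = rejected, reason = reason, site_bases = res$site_bases,
    stringsAsFactors = FALSE)
}

#' Zero-depth pileup scaffold for a panel
#'
#' One row per variant site with all base counts at zero; useful as the
#' pileup of a sample that produced no usable reads.
#'
#' @param panel an `amp_panel`.
#' @return pileup data.frame (see [pileup()]).
#' @export
empty_pileup <- function(panel) {
  s <- panel_sites(panel)
  data.frame(amplicon_id = s$amplicon_id, site_key = s$site_key,
             chrom = s$chrom, pos = s$pos, local_offset = s$local_offset,
             A = 0L, C = 0L, G = 0L, T = 0L, N = 0L, depth = 0L,
             stringsAsFactors = FALSE)
}

#' Pileup of variant-site base counts
#'
#' Tallies, for every variant site of the panel, the base contributed by each
#' (non-rejected) alignment whose span covers the site. Gapped positions
#' contribute nothing; N bases are tallied in the N column, which counts
#' toward depth but never toward ref or alt alleles.
#'
#' @param alignments either a list of `amp_alignment` objects from
#'   [align_read()] or a batch data.frame from [align_reads()] /
#'   [read_sam()].
#' @param panel an `amp_panel`.
#' @param min_base_quality reserved for quality-aware inputs; base counting
#'   is unfiltered when per-base qualities are unavailable (default 0).
#' @return data.frame with one row per panel site: base counts A/C/G/T/N and
#'   total `depth`.
#' @export
pileup <- function(alignments, panel, min_base_quality = 0) {
  out <- empty_pileup(panel)
  sites <- panel_sites(panel)
  tally <- function(amplicon_id, offset, base) {
    i <- which(out$amplicon_id == amplicon_id & out$local_offset == offset)
    if (length(i) == 0L) return()
    col <- if (base %in% DNA_BASES) base else "N"
    out[i, col] <<- out[i, col] + 1L
  }
  if (is.data.frame(alignments)) {
    keep <- !alignments$rejected & !is.na(alignments$amplicon_id)
    al <- alignments[keep, , drop = FALSE]
    for (a in unique(al$amplicon_id)) {
      offs <- sites$local_offset[sites$amplicon_id == a]
      if (length(offs) == 0L) next
      bases <- al$site_bases[al$amplicon_id == a]
      bm <- seq_char_matrix(bases, length(offs))
      for (k in seq_along(offs)) {
        i <- which(out$amplicon_id == a & out$local_offset == offs[k])
        tab <- table(factor(bm[k, ], levels = c(DNA_BASES, "N", ".")))
        out[i, DNA_BASES] <- out[i, DNA_BASES] + as.integer(tab[DNA_BASES])
        out[i, "N"] <- out[i, "N"] +
          as.integer(tab[["N"]]) + sum(!bm[k, ] %in% c(DNA_BASES, "N", "."))
      }
    }
  } else {
    for (aln in alignments) {
      if (isTRUE(aln$rejected)) next
      hit <- sites$amplicon_id == aln$amplicon_id
      for (k in which(hit)) {
        m <- match(sites$local_offset[k], aln$ref_pos)
        if (!is.na(m)) tally(aln$amplicon_id, sites$local_offset[k],
                             aln$read_bases[m])
      }
    }
  }
  out$depth <- out$A + out$C + out$G + out$T + out$N
  out
}

# base at each requested 0-based reference offset from a SAM record,
# walking the CIGAR; returns one character per offset ('.' if uncovered)
cigar_site_bases <- function(pos0, cigar, seq, offsets) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[MIDNSHP=X]", "", ops))
  op <- sub("\\d+", "", ops)
  bases <- rep(".", length(offsets))
  rcur <- pos0  # ref cursor, 0-based
  qcur <- 1L    # read cursor, 1-based
  for (k in seq_along(op)) {
    if (op[k] %in% c("M", "=", "X")) {
      hit <- which(offsets >= rcur & offsets < rcur + n[k])
      if (length(hit) > 0L) {
        qpos <- qcur + (offsets[hit] - rcur)
        bases[hit] <- substring(seq, qpos, qpos)
      }
      rcur <- rcur + n[k]; qcur <- qcur + n[k]
    } else if (op[k] %in% c("I", "S")) {
      qcur <- qcur + n[k]
    } else if (op[k] %in% c("D", "N")) {
      rcur <- rcur + n[k]
    }
  }
  bases
}

#' Ingest externally mapped reads from SAM/BAM
#'
#' Reads a SAM or BAM file and converts each mapped primary record into the
#' same per-read site-base representation produced by [align_reads()], so
#' externally mapped data feeds [pileup()] identically. Reference names may
#' be amplicon ids (positions local to the amplicon) or genomic chromosome
#' names (positions translated through the panel's amplicon intervals).
#' Unmapped, secondary and supplementary records are skipped and counted.
#'
#' @param path SAM or BAM file.
#' @param panel an `amp_panel`.
#' @return batch alignment data.frame (see [align_reads()]) with an
#'   attribute `skipped` giving skip counts by reason.
#' @export
read_sam <- function(path, panel) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("read_sam() requires the Rsamtools package")
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  b <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq")))[[1]]
  flag <- b$flag
  unmapped <- bitwAnd(flag, 4L) != 0L
  secondary <- bitwAnd(flag, 256L) != 0L
  suppl <- bitwAnd(flag, 2048L) != 0L
  keep <- !(unmapped | secondary | suppl)
  skipped <- c(unmapped = sum(unmapped), secondary = sum(secondary),
               supplementary = sum(suppl), off_panel = 0L)

  sites <- panel_sites(panel)
  amp <- panel$amplicons
  rows <- vector("list", sum(keep))
  ki <- 0L
  for (i in which(keep)) {
    rname <- as.character(b$rname[i])
    if (rname %in% amp$amplicon_id) {
      aid <- rname
      pos0 <- b$pos[i] - 1L
    } else {
      hit <- which(amp$chrom == rname & amp$start <= b$pos[i] &
                     amp$end >= b$pos[i])
      if (length(hit) == 0L) { skipped["off_panel"] <- skipped[["off_panel"]] + 1L; next }
      aid <- amp$amplicon_id[hit[1L]]
      pos0 <- b$pos[i] - amp$start[hit[1L]]
    }
    offs <- sites$local_offset[sites$amplicon_id == aid]
    bases <- cigar_site_bases(pos0, b$cigar[i], as.character(b$seq[i]), offs)
    ki <- ki + 1L
    rows[[ki]] <- data.frame(
      read_id = b$qname[i], amplicon_id = aid, score = NA_real_,
      ref_start = pos0, span = NA_integer_, n_mismatch = NA_integer_,
      identity = NA_real_, rejected = FALSE, reason = NA_character_,
      site_bases = paste(bases, collapse = ""), stringsAsFactors = FALSE)
  }
  out <- if (ki > 0L) do.call(rbind, rows[seq_len(ki)]) else
    data.frame(read_id = character(0), amplicon_id = character(0),
               score = numeric(0), ref_start = integer(0), span = integer(0),
               n_mismatch = integer(0), identity = numeric(0),
               rejected = logical(0), reason = character(0),
               site_bases = character(0), stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

# CIGAR string from an alignment's aligned column vectors
cigar_from_pairs <- function(aln, read_len) {
  runs <- character(0)
  push <- function(n, op) if (n > 0L) runs <<- c(runs, sprintf("%d%s", n, op))
  push(aln$read_start, "S")
  rp <- aln$ref_pos; qp <- aln$read_pos
  k <- 1L
  while (k <= length(rp)) {
    j <- k
    while (j < length(rp) && rp[j + 1L] == rp[j] + 1L &&
           qp[j + 1L] == qp[j] + 1L) j <- j + 1L
    push(j - k + 1L, "M")
    if (j < length(rp)) {
      push(qp[j + 1L] - qp[j] - 1L, "I")
      push(rp[j + 1L] - rp[j] - 1L, "D")
    }
    k <- j + 1L
  }
  push(read_len - aln$read_end - 1L, "S")
  paste(runs, collapse = "")
}

#' Write alignments to SAM
#'
#' Exports [align_read()] alignments as a minimal SAM file with the amplicon
#' references as sequence dictionary, for interoperability checks against
#' external mappers.
#'
#' @param alignments list of `amp_alignment` objects.
#' @param reads data.frame (id, seq, qual) the alignments came from.
#' @param references named amplicon reference sequences.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reads, references, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(references),
                   nchar(references)))
  recs <- vapply(alignments, function(a) {
    i <- match(a$read_id, reads$id)
    seq <- reads$seq[i]
    qual <- if (!is.null(reads$qual)) reads$qual[i] else "*"
    if (isTRUE(a$rejected))
      return(sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s",
                     a$read_id, seq, qual))
    sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
            a$read_id, a$amplicon_id, a$ref_start + 1L,
            cigar_from_pairs(a, nchar(seq)), seq, qual)
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}
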