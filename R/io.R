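#' Write reads to FASTQ
#'
#' @param reads data.frame (id, seq, qual).
#' @param path output path; a `.gz` suffix enables gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  qs <- Biostrings::QualityScaledDNAStringSet(
    x, Biostrings::PhredQuality(reads$qual))
  Biostrings::writeQualityScaledXStringSet(
    qs, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path (optionally gzipped).
#' @return data.frame (id, seq, qual).
#' @export
read_fastq <- function(path) {
  # metadata columns (none are written) are dropped on read
  qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = sub("\\s.*$", "", names(qs)),
             seq = as.character(qs),
             qual = as.character(Biostrings::quality(qs)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write/read a sample sheet TSV
#'
#' Columns: sample_id, fwd_index, rev_index, sex.
#' @param sheet sample sheet data.frame.
#' @param path TSV path.
#' @return `path` / the sheet.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

#' Write cohort truth genotypes to TSV
#'
#' @param truth a `cohort_truth`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth$genotypes, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write genotype calls to TSV
#'
#' @param calls genotype-call data.frame.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype table (TSV or VCF) for concordance comparison
#'
#' TSV tables need columns sample_id, site_key and genotype (or call). VCF
#' input is converted via GT fields: 0/0 -> hom_ref, 0/1 or 1/0 -> het,
#' 1/1 -> hom_alt, haploid 0/1 -> hemi classes, ./. -> no_call.
#'
#' @param path input path.
#' @return data.frame (sample_id, site_key, genotype).
#' @export
read_genotype_table <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "##")]
    hdr <- strsplit(sub("^#", "", body[1]), "\t")[[1]]
    rec <- strsplit(body[-1], "\t")
    samples <- hdr[-(1:9)]
    out <- list()
    for (r in rec) {
      key <- site_key(r[1], as.integer(r[2]))
      fmt <- strsplit(r[9], ":")[[1]]
      gi <- match("GT", fmt)
      for (si in seq_along(samples)) {
        gt <- strsplit(r[9 + si], ":")[[1]][gi]
        g <- switch(gt,
                    "0/0" = "hom_ref", "0/1" = "het", "1/0" = "het",
                    "1/1" = "hom_alt", "0" = "hemi_ref", "1" = "hemi_alt",
                    "no_call")
        out[[length(out) + 1L]] <- data.frame(
          sample_id = samples[si], site_key = key, genotype = g,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  } else {
    x <- read.delim(path, stringsAsFactors = FALSE)
    if (!"genotype" %in% names(x) && "call" %in% names(x))
      x$genotype <- x$call
    x[, c("sample_id", "site_key", "genotype")]
  }
}

gt_string <- function(call) {
  switch(call,
         hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
         hemi_ref = "0", hemi_alt = "1", "./.")
}

#' Write genotype calls as minimal VCF 4.2
#'
#' One row per panel site, samples as columns, FORMAT `GT:DP:AD`. With a
#' single sample the FILTER column carries `low_depth` for withheld calls
#' and `PASS` otherwise; with several samples FILTER is `.` and the
#' per-sample flags remain in the TSV output.
#'
#' @param calls genotype-call data.frame (one or more samples).
#' @param panel an `amp_panel`.
#' @param path output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, panel, path) {
  samples <- unique(calls$sample_id)
  sites <- panel$sites
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=malamp",
    "##FILTER=<ID=low_depth,Description=\"Site depth below the calling threshold\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Ref,alt read depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  rows <- vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    sc <- calls[calls$site_key == s$site_key, , drop = FALSE]
    cols <- vapply(samples, function(sid) {
      r <- sc[sc$sample_id == sid, , drop = FALSE]
      if (nrow(r) == 0L) return("./.:0:0,0")
      sprintf("%s:%d:%d,%d", gt_string(r$call[1]), r$depth[1],
              r$ref_count[1], r$alt_count[1])
    }, character(1))
    filter <- if (length(samples) == 1L) {
      r <- sc[sc$sample_id == samples[1], , drop = FALSE]
      if (nrow(r) == 1L && r$call[1] == "no_call" &&
          has_flag(r$flags[1], "low_depth")) "low_depth" else "PASS"
    } else "."
    paste(c(s$chrom, s$pos, ifelse(s$rsid == "NA", ".", s$rsid), s$ref,
            s$alt, ".", filter, ".", "GT:DP:AD", cols), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
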