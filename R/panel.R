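#' Amplicon panel objects
#'
#' A panel bundles a set of amplicon targets (genomic intervals, 1-based
#' inclusive, GRCh38 coordinates) with the variant sites they cover.
#' Ref/alt alleles are stored as plus-strand genomic bases even for
#' minus-strand genes (HBB, G6PD); cDNA-style labels such as "202 C>T" are
#' metadata only. Amplicon-local offsets are 0-based (`pos - start`).
#'
#' @param name panel name.
#' @param amplicons data.frame with columns `amplicon_id`, `gene`, `chrom`,
#'   `start`, `end`.
#' @param sites data.frame with columns `amplicon_id`, `gene`, `chrom`,
#'   `pos`, `rsid`, `ref`, `alt`, `label`.
#' @param reference_sequences optional named character vector of plus-strand
#'   amplicon sequences keyed by `amplicon_id`, each of length
#'   `end - start + 1`.
#' @return an object of class `amp_panel`.
#' @export
new_panel <- function(name, amplicons, sites, reference_sequences = NULL) {
  amplicons <- as.data.frame(amplicons, stringsAsFactors = FALSE)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  sites$chrom <- as.character(sites$chrom)
  amplicons$chrom <- as.character(amplicons$chrom)
  sites$x_linked <- sites$chrom == "X"
  sites$site_key <- site_key(sites$chrom, sites$pos)
  ord <- order(match(sites$amplicon_id, amplicons$amplicon_id), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  rownames(amplicons) <- NULL
  structure(
    list(name = name, amplicons = amplicons, sites = sites,
         reference_sequences = reference_sequences),
    class = "amp_panel")
}

#' Canonical site key
#'
#' Sites are keyed as `"chrom:pos"` throughout the package.
#' @param chrom chromosome name.
#' @param pos 1-based position.
#' @return character vector.
#' @export
site_key <- function(chrom, pos) paste0(chrom, ":", pos)

#' @export
print.amp_panel <- function(x, ...) {
  cat(sprintf("amp_panel '%s': %d amplicons, %d sites, %d loci\n",
              x$name, nrow(x$amplicons), nrow(x$sites),
              length(unique(x$amplicons$gene))))
  cat(sprintf("  reference sequences: %s\n",
              if (is.null(x$reference_sequences)) "none" else "attached"))
  invisible(x)
}

#' Variant sites of a panel
#'
#' @param panel an `amp_panel`.
#' @return data.frame of sites with amplicon assignment, 0-based local
#'   offsets and site keys.
#' @export
panel_sites <- function(panel) {
  s <- panel$sites
  s$local_offset <- s$pos -
    panel$amplicons$start[match(s$amplicon_id, panel$amplicons$amplicon_id)]
  s
}

#' Validate a panel
#'
#' Checks every structural invariant of a panel and returns a report instead
#' of failing: unique amplicon ids, single-base ref != alt alleles over
#' A/C/G/T, positive positions, each site inside exactly one amplicon (its
#' own), sites sorted by position within amplicon, and — when reference
#' sequences are attached — sequence lengths matching the intervals and the
#' reference base at each site offset matching the site's ref allele.
#' Amplicon lengths outside 400-600 bp produce warnings in the report, not
#' errors, for user-supplied panels.
#'
#' @param panel an `amp_panel`.
#' @return data.frame with columns `severity` ("error"/"warning"), `where`,
#'   `message`; zero rows iff the panel is valid.
#' @export
validate_panel <- function(panel) {
  viol <- function(severity, where, message)
    data.frame(severity = severity, where = where, message = message,
               stringsAsFactors = FALSE)
  out <- list()
  amp <- panel$amplicons
  sites <- panel$sites

  dup <- amp$amplicon_id[duplicated(amp$amplicon_id)]
  for (d in unique(dup))
    out[[length(out) + 1L]] <- viol("error", d, "duplicate amplicon_id")

  len <- amp$end - amp$start + 1L
  bad_len <- which(len < 400L | len > 600L)
  for (i in bad_len)
    out[[length(out) + 1L]] <- viol("warning", amp$amplicon_id[i],
      sprintf("amplicon length %d outside 400-600 bp", len[i]))

  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    where <- sprintf("%s (%s)", s$site_key, s$rsid)
    if (!(s$ref %in% DNA_BASES) || !(s$alt %in% DNA_BASES))
      out[[length(out) + 1L]] <- viol("error", where,
        "ref/alt alleles must be single bases in A/C/G/T")
    if (identical(s$ref, s$alt))
      out[[length(out) + 1L]] <- viol("error", where, "ref_allele == alt_allele")
    if (s$pos <= 0)
      out[[length(out) + 1L]] <- viol("error", where, "pos must be positive")
    hit <- amp$chrom == s$chrom & amp$start <= s$pos & amp$end >= s$pos
    if (sum(hit) == 0L)
      out[[length(out) + 1L]] <- viol("error", where,
        "site position falls in no amplicon interval")
    else if (sum(hit) > 1L)
      out[[length(out) + 1L]] <- viol("error", where,
        "site position falls in more than one amplicon interval")
    else if (amp$amplicon_id[hit] != s$amplicon_id)
      out[[length(out) + 1L]] <- viol("error", where,
        "site assigned to an amplicon that does not contain it")
  }

  for (a in unique(sites$amplicon_id)) {
    p <- sites$pos[sites$amplicon_id == a]
    if (is.unsorted(p))
      out[[length(out) + 1L]] <- viol("error", a, "sites not sorted by pos")
  }

  refs <- panel$reference_sequences
  if (!is.null(refs)) {
    for (a in names(refs)) {
      i <- match(a, amp$amplicon_id)
      if (is.na(i)) {
        out[[length(out) + 1L]] <- viol("error", a,
          "reference sequence for unknown amplicon_id")
        next
      }
      expect_len <- amp$end[i] - amp$start[i] + 1L
      if (nchar(refs[[a]]) != expect_len) {
        out[[length(out) + 1L]] <- viol("error", a, sprintf(
          "reference sequence length %d != interval length %d",
          nchar(refs[[a]]), expect_len))
        next
      }
      ss <- sites[sites$amplicon_id == a, , drop = FALSE]
      off <- ss$pos - amp$start[i] + 1L
      base <- substring(refs[[a]], off, off)
      bad <- which(base != ss$ref)
      for (j in bad)
        out[[length(out) + 1L]] <- viol("error", ss$site_key[j], sprintf(
          "reference base '%s' at site offset != ref allele '%s'",
          base[j], ss$ref[j]))
    }
  }

  if (length(out) == 0L)
    data.frame(severity = character(0), where = character(0),
               message = character(0), stringsAsFactors = FALSE)
  else do.call(rbind, out)
}

#' Load a panel
#'
#' Loads the built-in panel (`"malaria_host_v1"`), a JSON panel file, or a
#' flat TSV site list (columns gene, chrom, pos, rsid, ref, alt, label; the
#' importer derives ~500 bp amplicon windows around proximity-grouped sites).
#' The loaded panel is validated; errors in the validation report abort.
#'
#' @param source built-in panel name or path to a `.json` / `.tsv` file.
#' @return an `amp_panel`.
#' @export
load_panel <- function(source) {
  if (identical(source, "malaria_host_v1")) {
    panel <- builtin_panel()
  } else if (!file.exists(source)) {
    stop(sprintf("panel source '%s' is neither a built-in name nor a file",
                 source))
  } else if (grepl("\\.json$", source, ignore.case = TRUE)) {
    panel <- panel_from_json(source)
  } else {
    panel <- panel_from_site_tsv(source)
  }
  rep <- validate_panel(panel)
  errs <- rep[rep$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0L)
    stop("invalid panel:\n", paste(sprintf("  [%s] %s", errs$where,
                                           errs$message), collapse = "\n"))
  panel
}

panel_from_json <- function(path) {
  j <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                error = function(e) stop("malformed panel JSON: ",
                                         conditionMessage(e)))
  if (is.null(j$name) || is.null(j$amplicons))
    stop("malformed panel JSON: missing 'name' or 'amplicons'")
  amp <- do.call(rbind, lapply(j$amplicons, function(a)
    data.frame(amplicon_id = a$amplicon_id, gene = a$gene,
               chrom = as.character(a$chrom), start = as.integer(a$start),
               end = as.integer(a$end), stringsAsFactors = FALSE)))
  sites <- do.call(rbind, lapply(j$amplicons, function(a)
    do.call(rbind, lapply(a$sites, function(s)
      data.frame(amplicon_id = a$amplicon_id, gene = a$gene,
                 chrom = as.character(s$chrom), pos = as.integer(s$pos),
                 rsid = s$rsid, ref = s$ref, alt = s$alt, label = s$label,
                 stringsAsFactors = FALSE)))))
  refs <- NULL
  if (!is.null(j$reference_sequences))
    refs <- unlist(j$reference_sequences)
  new_panel(j$name, amp, sites, refs)
}

#' Write a panel to JSON
#'
#' Inverse of [load_panel()] for JSON sources; the built-in panel round-trips
#' through write -> load identically.
#'
#' @param panel an `amp_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  amps <- lapply(seq_len(nrow(panel$amplicons)), function(i) {
    a <- panel$amplicons[i, ]
    ss <- panel$sites[panel$sites$amplicon_id == a$amplicon_id, , drop = FALSE]
    list(amplicon_id = a$amplicon_id, gene = a$gene, chrom = a$chrom,
         start = a$start, end = a$end,
         sites = lapply(seq_len(nrow(ss)), function(k) {
           s <- ss[k, ]
           list(chrom = s$chrom, pos = s$pos, rsid = s$rsid, ref = s$ref,
                alt = s$alt, label = s$label)
         }))
  })
  obj <- list(name = panel$name, amplicons = amps)
  if (!is.null(panel$reference_sequences))
    obj$reference_sequences <- as.list(panel$reference_sequences)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# flat site-list TSV importer: groups sites per (gene, chrom) into clusters
# whose span fits a 500 bp window, then centres a window on each cluster
panel_from_site_tsv <- function(path, window = 500L, margin = 40L) {
  s <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("gene", "chrom", "pos", "rsid", "ref", "alt", "label")
  if (!all(need %in% names(s)))
    stop("malformed panel TSV: need columns ", paste(need, collapse = ", "))
  s$pos <- as.integer(s$pos)
  amps <- list(); rows <- list()
  for (g in unique(paste(s$gene, s$chrom))) {
    ss <- s[paste(s$gene, s$chrom) == g, , drop = FALSE]
    ss <- ss[order(ss$pos), , drop = FALSE]
    cl <- cumsum(c(1L, diff(ss$pos) > (window - 2L * margin)))
    for (k in unique(cl)) {
      sk <- ss[cl == k, , drop = FALSE]
      mid <- floor((min(sk$pos) + max(sk$pos)) / 2)
      start <- mid - floor(window / 2) + 1L
      end <- start + window - 1L
      id <- sprintf("%s_%d", sk$gene[1], k)
      amps[[length(amps) + 1L]] <- data.frame(
        amplicon_id = id, gene = sk$gene[1], chrom = sk$chrom[1],
        start = start, end = end, stringsAsFactors = FALSE)
      sk$amplicon_id <- id
      rows[[length(rows) + 1L]] <- sk
    }
  }
  new_panel(tools::file_path_sans_ext(basename(path)),
            do.call(rbind, amps), do.call(rbind, rows))
}

#' Locate a genomic position on the panel
#'
#' @param panel an `amp_panel`.
#' @param chrom chromosome name.
#' @param pos 1-based genomic position.
#' @return list with `amplicon` (one-row data.frame) and `local_offset`
#'   (0-based, `pos - start`).
#' @export
locate_site <- function(panel, chrom, pos) {
  amp <- panel$amplicons
  hit <- which(amp$chrom == as.character(chrom) & amp$start <= pos &
                 amp$end >= pos)
  if (length(hit) == 0L)
    stop(sprintf("position %s:%d is not covered by any panel amplicon",
                 chrom, pos))
  a <- amp[hit[1L], , drop = FALSE]
  list(amplicon = a, local_offset = as.integer(pos - a$start))
}

#' Attach amplicon reference sequences to a panel
#'
#' @param panel an `amp_panel`.
#' @param refs named character vector keyed by amplicon_id, or a path to a
#'   FASTA file whose record names are amplicon ids.
#' @return the panel with `reference_sequences` set (validated).
#' @export
attach_references <- function(panel, refs) {
  if (is.character(refs) && length(refs) == 1L && file.exists(refs)) {
    dss <- Biostrings::readDNAStringSet(refs)
    refs <- setNames(as.character(dss), sub("\\s.*$", "", names(dss)))
  }
  panel$reference_sequences <- refs
  rep <- validate_panel(panel)
  errs <- rep[rep$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0L)
    stop("reference sequences inconsistent with panel:\n",
         paste(sprintf("  [%s] %s", errs$where, errs$message), collapse = "\n"))
  panel
}
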