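#' Alternate-allele fraction of a pileup column
#'
#' The fraction is computed over ref + alt counts only, so sequencing-error
#' bases at a third allele do not depress it; a `third_allele` flag is raised
#' when non-ref/non-alt A/C/G/T bases exceed 10% of total depth. N bases
#' count toward depth but never toward any allele.
#'
#' @param column one-row pileup data.frame (or named count vector with
#'   entries A/C/G/T/N) for the site.
#' @param site one-row site data.frame with `ref` and `alt`.
#' @return list with `fraction`, `ref_count`, `alt_count`, `third_allele`.
#' @export
allele_fraction <- function(column, site) {
  cnt <- if (is.data.frame(column))
    setNames(as.integer(column[1, c("A", "C", "G", "T", "N")]),
             c("A", "C", "G", "T", "N"))
  else {
    v <- setNames(rep(0L, 5L), c("A", "C", "G", "T", "N"))
    v[names(column)] <- as.integer(column)
    v
  }
  depth <- sum(cnt)
  if (depth == 0L) stop("allele fraction undefined at depth 0")
  ref_count <- cnt[[site$ref]]
  alt_count <- cnt[[site$alt]]
  other <- sum(cnt[DNA_BASES]) - ref_count - alt_count
  third <- other / depth > 0.10
  frac <- if (ref_count + alt_count > 0L)
    alt_count / (ref_count + alt_count) else NA_real_
  list(fraction = frac, ref_count = ref_count, alt_count = alt_count,
       depth = depth, third_allele = third)
}

#' Call a genotype from a pileup column
#'
#' Threshold-based diploid calling: sites with depth below `min_depth`
#' (default 30) are withheld as `no_call`; otherwise the alt fraction `f`
#' classifies the genotype as `hom_ref` (f < `lower`), `het`
#' (`lower` <= f <= `upper`; the boundaries belong to the heterozygous
#' class) or `hom_alt` (f > `upper`). For males at X-linked sites the
#' diploid call collapses to a hemizygous call; a diploid `het` collapses to
#' the majority allele (`hemi_ref` when f <= 0.5) and is flagged
#' `male_het_anomaly`.
#'
#' @inheritParams allele_fraction
#' @param sex "male" or "female".
#' @param min_depth minimum total depth to emit a call (default 30; depth
#'   exactly `min_depth` is retained).
#' @param lower,upper alt-fraction thresholds (defaults 0.20 and 0.80).
#' @return one-row data.frame: `depth`, `ref_count`, `alt_count`,
#'   `alt_fraction`, `call`, `flags`.
#' @export
call_genotype <- function(column, site, sex, min_depth = 30L, lower = 0.20,
                          upper = 0.80) {
  if (!sex %in% c("male", "female"))
    stop("sex must be 'male' or 'female'")
  res <- data.frame(depth = 0L, ref_count = 0L, alt_count = 0L,
                    alt_fraction = NA_real_, call = "no_call", flags = "",
                    stringsAsFactors = FALSE)
  depth <- if (is.data.frame(column)) {
    cnt <- as.integer(column[1, c("A", "C", "G", "T", "N")])
    sum(cnt)
  } else sum(column)
  if (depth < min_depth) {
    res$depth <- depth
    res$flags <- "low_depth"
    return(res)
  }
  af <- allele_fraction(column, site)
  res$depth <- af$depth
  res$ref_count <- af$ref_count
  res$alt_count <- af$alt_count
  flags <- character(0)
  if (af$third_allele) flags <- c(flags, "third_allele")
  if (is.na(af$fraction)) {
    # depth carried entirely by third alleles / N: no interpretable genotype
    res$call <- "no_call"
    res$flags <- flag_str(flags)
    return(res)
  }
  f <- af$fraction
  res$alt_fraction <- f
  call <- if (f < lower) "hom_ref" else if (f > upper) "hom_alt" else "het"
  if (sex == "male" && isTRUE(site$x_linked)) {
    if (call == "het") {
      call <- if (f <= 0.5) "hemi_ref" else "hemi_alt"
      flags <- c(flags, "male_het_anomaly")
    } else {
      call <- c(hom_ref = "hemi_ref", hom_alt = "hemi_alt")[[call]]
    }
  }
  res$call <- call
  res$flags <- flag_str(flags)
  res
}

#' Call all panel sites for one sample
#'
#' Emits one genotype call per panel site; sites absent from the pileup are
#' depth-0 `no_call`s.
#'
#' @param pileup_df pileup data.frame from [pileup()] for one sample.
#' @param panel an `amp_panel`.
#' @param sex "male" or "female".
#' @param sample_id sample identifier carried into the output.
#' @inheritParams call_genotype
#' @param depth_scope `"site"` applies `min_depth` per site (default);
#'   `"amplicon"` withholds every site of an amplicon whose mean site depth
#'   falls below `min_depth`.
#' @return data.frame with one row per panel site: sample_id, site_key,
#'   chrom, pos, rsid, ref, alt, depth, ref_count, alt_count, alt_fraction,
#'   call, flags.
#' @export
call_sample <- function(pileup_df, panel, sex, sample_id = NA_character_,
                        min_depth = 30L, lower = 0.20, upper = 0.80,
                        depth_scope = c("site", "amplicon")) {
  depth_scope <- match.arg(depth_scope)
  sites <- panel_sites(panel)
  amp_low <- character(0)
  if (depth_scope == "amplicon" && nrow(pileup_df) > 0L) {
    md <- tapply(pileup_df$depth, pileup_df$amplicon_id, mean)
    amp_low <- names(md)[md < min_depth]
  }
  rows <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    col <- pileup_df[pileup_df$site_key == s$site_key, , drop = FALSE]
    if (nrow(col) == 0L)
      col <- data.frame(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L)
    g <- if (s$amplicon_id %in% amp_low)
      data.frame(depth = sum(as.integer(col[1, c("A","C","G","T","N")])),
                 ref_count = 0L, alt_count = 0L, alt_fraction = NA_real_,
                 call = "no_call", flags = "low_depth",
                 stringsAsFactors = FALSE)
    else
      call_genotype(col, s, sex,
                    min_depth = if (depth_scope == "amplicon") 1L else
                      min_depth,
                    lower = lower, upper = upper)
    rows[[i]] <- cbind(
      data.frame(sample_id = sample_id, site_key = s$site_key,
                 chrom = s$chrom, pos = s$pos, rsid = s$rsid, ref = s$ref,
                 alt = s$alt, stringsAsFactors = FALSE),
      g)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fold hemizygous calls onto homozygous classes
#'
#' Tabulation and concordance compare genotypes on the folded classes
#' (`hemi_ref` -> `hom_ref`, `hemi_alt` -> `hom_alt`).
#'
#' @param call character vector of genotype classes.
#' @return character vector.
#' @export
fold_call <- function(call) {
  out <- call
  out[out == "hemi_ref"] <- "hom_ref"
  out[out == "hemi_alt"] <- "hom_alt"
  out
}
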