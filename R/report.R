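#' Per-site genotype distribution summary
#'
#' Tabulates one site's genotype calls across a cohort: `no_call`s are
#' excluded from counts and mean depth, hemizygous classes are folded into
#' the homozygous classes, and the carrier percentage is the share of
#' genotyped samples carrying at least one variant allele (1 decimal).
#'
#' @param calls genotype-call data.frame covering one or more sites.
#' @param site_key the site to summarise (default: the only site present).
#' @return one-row data.frame: site_key, rsid, n_genotyped, hom_ref, het,
#'   hom_alt, mean_depth, carrier_pct (NA when no sample is genotyped).
#' @export
site_summary <- function(calls, site_key = NULL) {
  if (is.null(site_key)) {
    site_key <- unique(calls$site_key)
    if (length(site_key) != 1L)
      stop("calls cover several sites; give site_key explicitly")
  }
  sc <- calls[calls$site_key == site_key, , drop = FALSE]
  called <- sc[sc$call != "no_call", , drop = FALSE]
  cls <- fold_call(called$call)
  n <- nrow(called)
  counts <- table(factor(cls, levels = c("hom_ref", "het", "hom_alt")))
  data.frame(
    site_key = site_key,
    rsid = if ("rsid" %in% names(sc) && nrow(sc) > 0L) sc$rsid[1] else NA,
    n_genotyped = n,
    hom_ref = as.integer(counts[["hom_ref"]]),
    het = as.integer(counts[["het"]]),
    hom_alt = as.integer(counts[["hom_alt"]]),
    mean_depth = if (n > 0L) mean(called$depth) else NA_real_,
    carrier_pct = if (n > 0L)
      round1(100 * (counts[["het"]] + counts[["hom_alt"]]) / n) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Genotype distribution summaries for every panel site
#'
#' @param calls genotype-call data.frame over a cohort.
#' @param panel an `amp_panel`.
#' @return data.frame with one [site_summary()] row per panel site.
#' @export
cohort_site_summaries <- function(calls, panel) {
  out <- do.call(rbind, lapply(panel$sites$site_key, function(k)
    site_summary(calls, k)))
  out$rsid <- panel$sites$rsid[match(out$site_key, panel$sites$site_key)]
  out
}

as_counts <- function(counts) {
  if (is.data.frame(counts))
    counts <- setNames(as.numeric(counts[1, c("hom_ref", "het", "hom_alt")]),
                       c("hom_ref", "het", "hom_alt"))
  if (is.null(names(counts)) && length(counts) == 3L)
    names(counts) <- c("hom_ref", "het", "hom_alt")
  stopifnot(all(c("hom_ref", "het", "hom_alt") %in% names(counts)),
            all(counts >= 0))
  counts
}

#' Carrier frequency from genotype counts
#'
#' Percentage of genotyped participants carrying at least one variant allele
#' (heterozygous or homozygous positive), rounded to 1 decimal.
#'
#' @param counts counts for hom_ref, het, hom_alt (named vector, plain
#'   length-3 vector, or one-row data.frame).
#' @return percentage (1 decimal).
#' @export
carrier_frequency <- function(counts) {
  counts <- as_counts(counts)
  total <- sum(counts)
  if (total == 0) stop("carrier frequency undefined for empty counts")
  round1(100 * (counts[["het"]] + counts[["hom_alt"]]) / total)
}

#' Homozygote frequency from genotype counts
#'
#' Percentage of genotyped participants homozygous for the variant allele,
#' rounded to 1 decimal.
#'
#' @inheritParams carrier_frequency
#' @return percentage (1 decimal).
#' @export
homozygote_frequency <- function(counts) {
  counts <- as_counts(counts)
  total <- sum(counts)
  if (total == 0) stop("homozygote frequency undefined for empty counts")
  round1(100 * counts[["hom_alt"]] / total)
}

#' Allele-count frequency from genotype counts
#'
#' True allele frequency (variant alleles over all alleles), as opposed to
#' the per-participant [carrier_frequency()]; rounded to 1 decimal.
#'
#' @inheritParams carrier_frequency
#' @return percentage (1 decimal).
#' @export
allele_count_frequency <- function(counts) {
  counts <- as_counts(counts)
  total <- sum(counts)
  if (total == 0) stop("allele frequency undefined for empty counts")
  round1(100 * (counts[["het"]] + 2 * counts[["hom_alt"]]) / (2 * total))
}

#' Genotype concordance between two call tables
#'
#' Compares genotype classes pairwise over the (sample, site) pairs where
#' both tables carry a determinate genotype (no_call and missing entries are
#' excluded); hemizygous classes are compared on the folded homozygous
#' classes. The overall discordance percentage is reported to 2 decimals and
#' the rate per 1000 genotypes to 1 decimal; the comparison is symmetric in
#' its two arguments.
#'
#' @param called,reference data.frames with columns `sample_id`, `site_key`,
#'   and a genotype class column named `call` or `genotype`.
#' @return list with `overall` (n_compared, n_discordant, concordance_pct,
#'   discordance_pct, discordance_per_1000) and `per_site` data.frame.
#' @export
concordance <- function(called, reference) {
  norm <- function(x) {
    g <- if ("call" %in% names(x)) x$call else x$genotype
    d <- data.frame(sample_id = x$sample_id, site_key = x$site_key,
                    genotype = fold_call(g), stringsAsFactors = FALSE)
    d[!is.na(d$genotype) & d$genotype != "no_call", , drop = FALSE]
  }
  a <- norm(called); b <- norm(reference)
  m <- merge(a, b, by = c("sample_id", "site_key"),
             suffixes = c("_a", "_b"))
  if (nrow(m) == 0L) stop("no comparable genotype pairs")
  m$discordant <- m$genotype_a != m$genotype_b
  n <- nrow(m); nd <- sum(m$discordant)
  per_site <- do.call(rbind, lapply(split(m, m$site_key), function(s)
    data.frame(site_key = s$site_key[1], n_compared = nrow(s),
               n_discordant = sum(s$discordant),
               concordance_pct = round1(100 * mean(!s$discordant)),
               stringsAsFactors = FALSE)))
  rownames(per_site) <- NULL
  list(overall = list(
         n_compared = n, n_discordant = nd,
         concordance_pct = round(100 * (1 - nd / n), 2),
         discordance_pct = round(100 * nd / n, 2),
         discordance_per_1000 = round1(1000 * nd / n)),
       per_site = per_site,
       pairs = m)
}

#' Profiling completeness per sample
#'
#' Counts, per sample, the amplicons for which every variant site received a
#' determinate call, and buckets samples by their number of failed
#' amplicons.
#'
#' @param calls genotype-call data.frame over a cohort.
#' @param panel an `amp_panel`.
#' @return list with `per_sample` (sample_id, n_amplicons_called, n_failed),
#'   `buckets` (named counts by number of failed amplicons), and
#'   `n_fully_profiled`.
#' @export
completeness <- function(calls, panel) {
  n_amp <- nrow(panel$amplicons)
  amp_of <- setNames(panel$sites$amplicon_id, panel$sites$site_key)
  per <- do.call(rbind, lapply(split(calls, calls$sample_id), function(sc) {
    ok <- tapply(sc$call != "no_call", amp_of[sc$site_key], all)
    called <- sum(ok[panel$amplicons$amplicon_id], na.rm = TRUE)
    data.frame(sample_id = sc$sample_id[1], n_amplicons_called = called,
               n_failed = n_amp - called, stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  buckets <- table(factor(per$n_failed, levels = 0:n_amp))
  list(per_sample = per, buckets = buckets,
       n_fully_profiled = sum(per$n_failed == 0L))
}

#' Sex-stratified G6PD class distribution
#'
#' Tabulates G6PD classes within each sex with within-sex percentages
#' (1 decimal) and the overall severe-deficiency percentage (A- hemizygotes
#' plus A-A- homozygotes over all classified samples). Undetermined and
#' non-canonical records are excluded.
#'
#' @param phenotypes per-sample phenotype data.frame (columns `sex` and
#'   `g6pd_class`), or a pre-tabulated count table with columns `sex`,
#'   `class`, `n`.
#' @return list with `by_sex` (sex, class, n, pct), `n_classified`,
#'   `n_severe`, `overall_severe_pct`.
#' @export
g6pd_distribution <- function(phenotypes) {
  if ("n" %in% names(phenotypes)) {
    cls_col <- if ("class" %in% names(phenotypes)) "class" else "g6pd_class"
    phenotypes <- data.frame(
      sex = rep(phenotypes$sex, phenotypes$n),
      g6pd_class = rep(phenotypes[[cls_col]], phenotypes$n),
      stringsAsFactors = FALSE)
  }
  keep <- phenotypes$g6pd_class %in% c(G6PD_MALE_CLASSES,
                                       G6PD_FEMALE_CLASSES)
  p <- phenotypes[keep, , drop = FALSE]
  if (nrow(p) == 0L) stop("no classified G6PD records")
  by_sex <- do.call(rbind, lapply(c("male", "female"), function(sx) {
    ps <- p[p$sex == sx, , drop = FALSE]
    if (nrow(ps) == 0L) return(NULL)
    lev <- if (sx == "male") G6PD_MALE_CLASSES else G6PD_FEMALE_CLASSES
    tab <- table(factor(ps$g6pd_class, levels = lev))
    data.frame(sex = sx, class = names(tab), n = as.integer(tab),
               pct = round1(100 * as.integer(tab) / nrow(ps)),
               stringsAsFactors = FALSE)
  }))
  rownames(by_sex) <- NULL
  n_severe <- sum(p$g6pd_class %in% G6PD_SEVERE_CLASSES)
  list(by_sex = by_sex, n_classified = nrow(p), n_severe = n_severe,
       overall_severe_pct = round1(100 * n_severe / nrow(p)))
}

#' Truth-versus-call genotype recovery
#'
#' Fraction of simulated truth genotypes whose call matches the truth class
#' exactly (a `no_call` never matches). Used to benchmark the end-to-end
#' pipeline on synthetic data.
#'
#' @param calls genotype-call data.frame over the cohort.
#' @param truth a `cohort_truth` from [simulate_cohort()].
#' @return list with `n_truth`, `n_recovered`, `recovery` (fraction), and
#'   the merged `pairs` table.
#' @export
genotype_recovery <- function(calls, truth) {
  m <- merge(truth$genotypes, calls[, c("sample_id", "site_key", "call")],
             by = c("sample_id", "site_key"), all.x = TRUE)
  m$call[is.na(m$call)] <- "no_call"
  m$recovered <- m$call == m$truth_class
  list(n_truth = nrow(m), n_recovered = sum(m$recovered),
       recovery = mean(m$recovered), pairs = m)
}
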