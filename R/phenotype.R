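G6PD_MALE_CLASSES <- c("B", "A+", "A-")
G6PD_FEMALE_CLASSES <- c("BB", "BA+", "BA-", "A+A+", "A+A-", "A-A-")
G6PD_SEVERE_CLASSES <- c("A-", "A-A-")

# alt dose of a genotype class; hemizygous dose is on a single allele
call_alt_dose <- function(call) {
  switch(call,
         hom_ref = 2L * 0L, het = 1L, hom_alt = 2L,
         hemi_ref = 0L, hemi_alt = 1L,
         no_call = NA_integer_,
         stop("unknown genotype class: ", call))
}

#' Infer the G6PD A-deficiency class from the 202 and 376 calls
#'
#' Allele-level rule on the two classifying positions (cDNA 202, rs1050828;
#' cDNA 376, rs1050829): the B allele carries neither variant, the A+ allele
#' carries the 376 variant only, and the A- allele carries both. Males get a
#' single-allele class from their hemizygous calls; females get a diplotype
#' under the canonical phasing assumption that every 202-variant allele lies
#' on a 376-variant background (the haplotype structure the A-/A+/B
#' nomenclature presupposes). A 202-variant dose exceeding the 376-variant
#' dose is inconsistent with that structure and is reported as
#' `non_canonical` rather than forced into a class. `severe_deficiency` is
#' true exactly for the A- hemizygote and A-A- homozygote.
#'
#' @param call_202 genotype class at the 202 site (rs1050828).
#' @param call_376 genotype class at the 376 site (rs1050829).
#' @param sex "male" or "female".
#' @return list with `class` (one of B/A+/A- for males, BB/BA+/BA-/A+A+/
#'   A+A-/A-A- for females, or "undetermined"), `severe_deficiency`, and
#'   `flag` ("" or "non_canonical"/"male_het_anomaly").
#' @export
infer_g6pd <- function(call_202, call_376, sex) {
  stopifnot(sex %in% c("male", "female"))
  und <- function(flag = "")
    list(class = "undetermined", severe_deficiency = FALSE, flag = flag)
  if (call_202 == "no_call" || call_376 == "no_call") return(und())

  if (sex == "male") {
    # accept diploid-style calls (e.g. from external tables) as hemizygous
    d202 <- call_alt_dose(call_202)
    d376 <- call_alt_dose(call_376)
    if (call_202 == "het" || call_376 == "het")
      return(und("male_het_anomaly"))
    a202 <- as.integer(d202 > 0L)
    a376 <- as.integer(d376 > 0L)
    if (a202 == 1L && a376 == 0L) return(und("non_canonical"))
    cls <- if (a202 == 1L) "A-" else if (a376 == 1L) "A+" else "B"
    return(list(class = cls, severe_deficiency = cls == "A-", flag = ""))
  }

  d202 <- call_alt_dose(call_202)
  d376 <- call_alt_dose(call_376)
  if (d202 > d376) return(und("non_canonical"))
  n_aminus <- d202
  n_aplus <- d376 - d202
  n_b <- 2L - d376
  alleles <- c(rep("B", n_b), rep("A+", n_aplus), rep("A-", n_aminus))
  cls <- paste0(alleles[1], alleles[2])
  list(class = cls, severe_deficiency = cls == "A-A-", flag = "")
}

#' Infer the haemoglobin genotype from the HBB variant calls
#'
#' Composes the beta-globin genotype label from the variant-allele doses at
#' rs334 (HbS), rs33930165 (HbC) and rs33950507 (HbE): no variant alleles
#' gives HbAA, one or two variant alleles give the usual trait/disease
#' labels (HbAS, HbSS, HbSC, ...). More than two variant alleles across the
#' three sites is biologically impossible for one diploid locus and raises
#' an error.
#'
#' @param call_rs334,call_rs33930165,call_rs33950507 genotype classes.
#' @return haemoglobin label, or "undetermined" when any call is `no_call`.
#' @export
infer_hbb <- function(call_rs334, call_rs33930165, call_rs33950507) {
  calls <- c(call_rs334, call_rs33930165, call_rs33950507)
  if (any(calls == "no_call")) return("undetermined")
  dose <- vapply(calls, call_alt_dose, integer(1))
  if (sum(dose) > 2L)
    stop(sprintf(
      "inconsistent HBB calls: %d variant alleles across rs334/rs33930165/rs33950507",
      sum(dose)))
  letters <- c(rep("S", dose[1]), rep("C", dose[2]), rep("E", dose[3]))
  alleles <- c(rep("A", 2L - length(letters)), letters)
  ord <- order(match(alleles, c("A", "S", "C", "E")))
  paste0("Hb", paste(alleles[ord], collapse = ""))
}

#' Infer Duffy antigen status from the rs2814778 call
#'
#' The rs2814778 promoter variant ablates erythroid ACKR1 expression;
#' homozygotes are Duffy-negative and refractory to Plasmodium vivax
#' invasion.
#'
#' @param call genotype class at rs2814778.
#' @return one of "Fy_negative", "Fy_heterozygous", "Fy_positive",
#'   "undetermined".
#' @export
infer_duffy <- function(call) {
  switch(fold_call(call),
         hom_alt = "Fy_negative", het = "Fy_heterozygous",
         hom_ref = "Fy_positive", no_call = "undetermined",
         stop("unknown genotype class: ", call))
}

#' Infer Dantu blood-group carrier status from the rs186873296 call
#'
#' @param call genotype class at rs186873296.
#' @return one of "non_carrier", "heterozygous", "homozygous",
#'   "undetermined".
#' @export
infer_dantu <- function(call) {
  switch(fold_call(call),
         hom_ref = "non_carrier", het = "heterozygous",
         hom_alt = "homozygous", no_call = "undetermined",
         stop("unknown genotype class: ", call))
}

#' Phenotype records for a called cohort
#'
#' Translates per-sample genotype calls into clinically interpretable
#' labels: the G6PD A-/A+/B class (from the 202/376 calls; the secondary
#' G6PD variants are reported as raw calls and do not alter the class), the
#' haemoglobin genotype, Duffy status, and Dantu carrier status. A record is
#' undetermined for a phenotype whenever one of its required sites is
#' `no_call`; inconsistent HBB call combinations yield "inconsistent".
#'
#' @param calls data.frame of genotype calls (as from [call_sample()],
#'   possibly row-bound over samples).
#' @param panel an `amp_panel`; rsids identify the classifying sites.
#' @param sexes named character vector sample_id -> sex, or a data.frame
#'   with `sample_id` and `sex` columns.
#' @return data.frame with one row per sample: sample_id, sex, g6pd_class,
#'   g6pd_severe, g6pd_flag, hbb, duffy, dantu.
#' @export
phenotype_cohort <- function(calls, panel, sexes) {
  if (is.data.frame(sexes))
    sexes <- setNames(sexes$sex, sexes$sample_id)
  key_of <- function(rsid) {
    k <- panel$sites$site_key[panel$sites$rsid == rsid]
    if (length(k) == 0L) NA_character_ else k[1]
  }
  keys <- vapply(c("rs1050828", "rs1050829", "rs334", "rs33930165",
                   "rs33950507", "rs2814778", "rs186873296"), key_of,
                 character(1))
  get_call <- function(sc, key) {
    if (is.na(key)) return("no_call")
    v <- sc$call[sc$site_key == key]
    if (length(v) == 0L) "no_call" else v[1]
  }
  samples <- unique(calls$sample_id)
  rows <- lapply(samples, function(sid) {
    sc <- calls[calls$sample_id == sid, , drop = FALSE]
    sex <- sexes[[sid]]
    g6 <- infer_g6pd(get_call(sc, keys[["rs1050828"]]),
                     get_call(sc, keys[["rs1050829"]]), sex)
    hbb <- tryCatch(
      infer_hbb(get_call(sc, keys[["rs334"]]),
                get_call(sc, keys[["rs33930165"]]),
                get_call(sc, keys[["rs33950507"]])),
      error = function(e) "inconsistent")
    data.frame(sample_id = sid, sex = sex, g6pd_class = g6$class,
               g6pd_severe = g6$severe_deficiency, g6pd_flag = g6$flag,
               hbb = hbb,
               duffy = infer_duffy(get_call(sc, keys[["rs2814778"]])),
               dantu = infer_dantu(get_call(sc, keys[["rs186873296"]])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
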