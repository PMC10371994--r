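#' The built-in malaria host-genetics panel
#'
#' Seven amplicons across four loci associated with malaria disease severity:
#' one amplicon on HBB (chr11; sickle-cell HbS rs334, HbC, HbE and several
#' thalassaemia-linked variants), four on G6PD (chrX; the deficiency variants
#' at cDNA positions 202/376/542/680/968 plus benign and off-target sites),
#' one on ACKR1 (chr1; the Duffy-null rs2814778 promoter variant), and one on
#' the intergenic Dantu blood-group region (chr4; rs186873296). Coordinates
#' are 1-based GRCh38. Amplicon windows are ~500 bp, within the 400-600 bp
#' product-size range the assay targets; the exact primer footprints are not
#' part of the computational model. The panel ships without reference
#' sequences; attach real ones with [attach_references()] or generate
#' synthetic ones with [simulate_references()].
#'
#' @return an `amp_panel` with 7 amplicons and 25 variant sites.
#' @seealso [load_panel()], [builtin_cohort_counts()]
#' @export
builtin_panel <- function() {
  amplicons <- data.frame(
    amplicon_id = c("G6PD_1", "G6PD_2", "G6PD_3", "G6PD_4",
                    "HBB_1", "ACKR1_1", "DANTU_1"),
    gene  = c("G6PD", "G6PD", "G6PD", "G6PD", "HBB", "ACKR1",
              "Dantu_intergenic"),
    chrom = c("X", "X", "X", "X", "11", "1", "4"),
    start = c(154532700L, 154534050L, 154535200L, 154535800L,
              5226720L, 159204520L, 143781082L),
    end   = c(154533199L, 154534599L, 154535699L, 154536299L,
              5227219L, 159205019L, 143781581L),
    stringsAsFactors = FALSE)

  S <- function(amp, gene, chrom, pos, rsid, ref, alt, label)
    data.frame(amplicon_id = amp, gene = gene, chrom = chrom, pos = pos,
               rsid = rsid, ref = ref, alt = alt, label = label,
               stringsAsFactors = FALSE)
  sites <- rbind(
    S("G6PD_1", "G6PD", "X", 154532738L, "rs2230036",   "C", "T", "benign"),
    S("G6PD_1", "G6PD", "X", 154533025L, "rs76723693",  "A", "G", "968"),
    S("G6PD_1", "G6PD", "X", 154533122L, "rs137852327", "C", "T", "NA"),
    S("G6PD_2", "G6PD", "X", 154534125L, "rs137852328", "C", "A", "680"),
    S("G6PD_2", "G6PD", "X", 154534177L, "rs5986875",   "G", "A", "benign"),
    S("G6PD_2", "G6PD", "X", 154534440L, "rs5030872",   "T", "A", "542"),
    S("G6PD_2", "G6PD", "X", 154534527L, "NA",          "T", "C", "NA"),
    S("G6PD_3", "G6PD", "X", 154535277L, "rs1050829",   "T", "C", "376"),
    S("G6PD_3", "G6PD", "X", 154535443L, "NA",          "G", "A", "NA"),
    S("G6PD_3", "G6PD", "X", 154535468L, "NA",          "G", "T", "NA"),
    S("G6PD_4", "G6PD", "X", 154536002L, "rs1050828",   "C", "T", "202"),
    S("HBB_1", "HBB", "11", 5226867L, "NA",          "C", "G", "NA"),
    S("HBB_1", "HBB", "11", 5226925L, "rs33915217",  "C", "A", "beta_thal"),
    S("HBB_1", "HBB", "11", 5226932L, "rs35578002",  "G", "T", "NA"),
    S("HBB_1", "HBB", "11", 5226943L, "rs33950507",  "C", "T", "HbE"),
    S("HBB_1", "HBB", "11", 5226963L, "rs33972047",  "T", "C", "beta_thal"),
    S("HBB_1", "HBB", "11", 5226966L, "rs35382661",  "A", "C", "NA"),
    S("HBB_1", "HBB", "11", 5227002L, "rs334",       "T", "A", "HbS"),
    S("HBB_1", "HBB", "11", 5227003L, "rs33930165",  "C", "T", "HbC"),
    S("HBB_1", "HBB", "11", 5227013L, "rs713040",    "A", "G", "beta_thal;HPFH"),
    S("HBB_1", "HBB", "11", 5227072L, "rs386134236", "A", "G", "NA"),
    S("ACKR1_1", "ACKR1", "1", 159204646L, "NA",        "A", "C", "NA"),
    S("ACKR1_1", "ACKR1", "1", 159204893L, "rs2814778", "T", "C", "Fy(a-b-)"),
    S("DANTU_1", "Dantu_intergenic", "4", 143781321L, "rs186873296", "A", "G",
      "Dantu"),
    S("DANTU_1", "Dantu_intergenic", "4", 143781342L, "NA", "G", "T", "NA"))

  new_panel("malaria_host_v1", amplicons, sites)
}

#' Reference cohort genotype tallies for the built-in panel
#'
#' Per-site genotype counts observed in the 100-child severe-malaria cohort
#' from Muheza, Northeast Tanzania, for which the built-in panel was
#' designed, bundled as worked-example input data. Hemizygous genotypes are
#' folded into the homozygous classes, and per-site denominators differ
#' because samples below the 30x depth threshold drop out site by site.
#'
#' @return data.frame with columns `site_key`, `rsid`, `hom_ref`, `het`,
#'   `hom_alt`, `mean_depth`.
#' @export
builtin_cohort_counts <- function() {
  C <- function(key, rsid, hr, het, ha, dp)
    data.frame(site_key = key, rsid = rsid, hom_ref = hr, het = het,
               hom_alt = ha, mean_depth = dp, stringsAsFactors = FALSE)
  rbind(
    C("X:154532738", "rs2230036",    87L, 6L,  6L,  803L),
    C("X:154533025", "rs76723693",   99L, 0L,  0L,  798L),
    C("X:154533122", "rs137852327",  99L, 0L,  0L,  798L),
    C("X:154534125", "rs137852328",  99L, 0L,  0L,  629L),
    C("X:154534177", "rs5986875",    98L, 1L,  0L,  629L),
    C("X:154534440", "rs5030872",    99L, 0L,  0L,  622L),
    C("X:154534527", "NA",           86L, 1L,  0L,  622L),
    C("X:154535277", "rs1050829",    48L, 16L, 23L, 956L),
    C("X:154535443", "NA",           86L, 1L,  0L,  622L),
    C("X:154535468", "NA",           86L, 1L,  0L,  622L),
    C("X:154536002", "rs1050828",    71L, 8L,  8L,  530L),
    C("11:5226867",  "NA",           98L, 1L,  0L,  1020L),
    C("11:5226925",  "rs33915217",   99L, 0L,  0L,  1020L),
    C("11:5226932",  "rs35578002",   98L, 1L,  0L,  1020L),
    C("11:5226943",  "rs33950507",   99L, 0L,  0L,  1020L),
    C("11:5226963",  "rs33972047",   99L, 0L,  0L,  1020L),
    C("11:5226966",  "rs35382661",   97L, 2L,  0L,  1118L),
    C("11:5227002",  "rs334",        90L, 4L,  5L,  2003L),
    C("11:5227003",  "rs33930165",   99L, 0L,  0L,  2003L),
    C("11:5227013",  "rs713040",     4L,  27L, 65L, 2002L),
    C("11:5227072",  "rs386134236",  98L, 1L,  0L,  984L),
    C("1:159204646", "NA",           76L, 19L, 0L,  644L),
    C("1:159204893", "rs2814778",    0L,  0L,  95L, 623L),
    C("4:143781321", "rs186873296",  95L, 3L,  0L,  132L),
    C("4:143781342", "NA",           98L, 1L,  0L,  184L))
}

#' Reference cohort G6PD class tallies
#'
#' Sex-stratified G6PD genotype-class counts for the 83 cohort members with
#' determinate calls at both the 202 and 376 positions, bundled as
#' worked-example input data for [g6pd_distribution()].
#'
#' @return data.frame with columns `sex`, `class`, `n`.
#' @export
builtin_g6pd_counts <- function() {
  data.frame(
    sex = c(rep("male", 3L), rep("female", 6L)),
    class = c("B", "A+", "A-", "BB", "BA+", "BA-", "A+A+", "A+A-", "A-A-"),
    n = c(25L, 13L, 5L, 21L, 6L, 2L, 7L, 1L, 3L),
    stringsAsFactors = FALSE)
}
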