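calls_from_counts <- function(site_key, hom_ref, het, hom_alt,
                              depth = 100) {
  n <- hom_ref + het + hom_alt
  data.frame(
    sample_id = sprintf("P%03d", seq_len(n)),
    site_key = site_key,
    rsid = site_key,
    depth = depth,
    call = c(rep("hom_ref", hom_ref), rep("het", het),
             rep("hom_alt", hom_alt)),
    stringsAsFactors = FALSE)
}

test_that("site summaries reproduce the reference cohort percentages", {
  # sickle-cell rs334: 90/4/5 -> 9.1% carriers
  s <- site_summary(calls_from_counts("11:5227002", 90, 4, 5))
  expect_equal(s$n_genotyped, 99L)
  expect_equal(s$carrier_pct, 9.1)
  # Duffy rs2814778: all 95 homozygous positive -> 100%
  s2 <- site_summary(calls_from_counts("1:159204893", 0, 0, 95))
  expect_equal(s2$carrier_pct, 100.0)
  # all no_call -> undefined
  nc <- data.frame(sample_id = "P1", site_key = "k", rsid = "k",
                   depth = 0, call = "no_call", stringsAsFactors = FALSE)
  s3 <- site_summary(nc)
  expect_equal(s3$n_genotyped, 0L)
  expect_true(is.na(s3$carrier_pct))
  # hemizygous calls fold into the homozygous classes
  hemi <- calls_from_counts("X:1", 3, 0, 0)
  hemi$call <- c("hemi_ref", "hemi_alt", "hom_ref")
  s4 <- site_summary(hemi)
  expect_equal(s4$hom_ref, 2L)
  expect_equal(s4$hom_alt, 1L)
})

test_that("carrier and homozygote frequencies match the worked examples", {
  expect_equal(carrier_frequency(c(71, 8, 8)), 18.4)     # G6PD 202
  expect_equal(carrier_frequency(c(48, 16, 23)), 44.8)   # G6PD 376
  expect_equal(homozygote_frequency(c(48, 16, 23)), 26.4)
  expect_equal(homozygote_frequency(c(4, 27, 65)), 67.7) # rs713040
  expect_equal(carrier_frequency(c(95, 3, 0)), 3.1)      # Dantu
  expect_equal(carrier_frequency(c(87, 6, 6)), 12.1)     # rs2230036
  expect_equal(carrier_frequency(c(10, 0, 0)), 0.0)
  expect_equal(homozygote_frequency(c(5, 5, 0)), 0.0)
  expect_error(carrier_frequency(c(0, 0, 0)), "undefined")
  # allele-count frequency is the distinct, true allele frequency
  expect_equal(allele_count_frequency(c(71, 8, 8)), 13.8)  # 24/174
})

test_that("concordance reproduces the printed overall discordance", {
  # 962 comparable genotypes with 4 mismatches
  a <- data.frame(sample_id = sprintf("P%04d", 1:962),
                  site_key = "s", genotype = "hom_ref",
                  stringsAsFactors = FALSE)
  b <- a
  b$genotype[1:4] <- "het"
  cc <- concordance(a, b)
  expect_equal(cc$overall$n_compared, 962L)
  expect_equal(cc$overall$n_discordant, 4L)
  expect_equal(cc$overall$discordance_pct, 0.42)
  expect_equal(cc$overall$discordance_per_1000, 4.2)
  expect_equal(cc$overall$concordance_pct + cc$overall$discordance_pct, 100)
  # identical tables are fully concordant
  cc2 <- concordance(a, a)
  expect_equal(cc2$overall$n_discordant, 0L)
  expect_equal(cc2$overall$concordance_pct, 100)
  # symmetric in its arguments
  cc3 <- concordance(b, a)
  expect_equal(cc3$overall, cc$overall)
})

test_that("concordance equals a brute-force pair count on random tables", {
  set.seed(71)
  classes <- c("hom_ref", "het", "hom_alt", "hemi_ref", "hemi_alt",
               "no_call")
  mk <- function() data.frame(
    sample_id = rep(sprintf("P%02d", 1:20), each = 10),
    site_key = rep(sprintf("s%02d", 1:10), times = 20),
    genotype = sample(classes, 200, replace = TRUE,
                      prob = c(0.4, 0.2, 0.2, 0.05, 0.05, 0.1)),
    stringsAsFactors = FALSE)
  for (rep_i in 1:5) {
    a <- mk(); b <- mk()
    got <- concordance(a, b)$overall
    want <- concordance_oracle(a, b)
    expect_equal(got$n_compared, want$n_compared)
    expect_equal(got$n_discordant, want$n_discordant)
  }
})

test_that("completeness buckets samples by failed amplicons", {
  p <- tiny_panel()
  mk_calls <- function(sid, failed_amp) {
    s <- panel_sites(p)
    data.frame(sample_id = sid, site_key = s$site_key, depth = 100,
               call = ifelse(s$amplicon_id %in% failed_amp, "no_call",
                             "hom_ref"),
               stringsAsFactors = FALSE)
  }
  calls <- rbind(mk_calls("S1", character(0)),
                 mk_calls("S2", "AMP_A"),
                 mk_calls("S3", c("AMP_A", "AMP_X")))
  comp <- completeness(calls, p)
  expect_equal(comp$n_fully_profiled, 1L)
  expect_equal(as.integer(comp$buckets), c(1L, 1L, 1L))
  expect_equal(comp$per_sample$n_failed[comp$per_sample$sample_id == "S3"],
               2L)
  # one no_call site fails the whole amplicon
  partial <- mk_calls("S4", character(0))
  partial$call[1] <- "no_call"
  comp2 <- completeness(partial, p)
  expect_equal(comp2$per_sample$n_failed, 1L)
})

test_that("G6PD distribution reproduces the reference cohort percentages", {
  d <- g6pd_distribution(builtin_g6pd_counts())
  m <- d$by_sex[d$by_sex$sex == "male", ]
  expect_equal(m$pct[m$class == "B"], 58.1)
  expect_equal(m$pct[m$class == "A+"], 30.2)
  expect_equal(m$pct[m$class == "A-"], 11.6)
  f <- d$by_sex[d$by_sex$sex == "female", ]
  expect_equal(f$pct[f$class == "BB"], 52.5)
  expect_equal(f$pct[f$class == "A-A-"], 7.5)
  expect_equal(d$n_classified, 83L)
  expect_equal(d$n_severe, 8L)
  expect_equal(d$overall_severe_pct, 9.6)
  # per-sex percentages sum to 100 within rounding
  for (sx in c("male", "female")) {
    tot <- sum(d$by_sex$pct[d$by_sex$sex == sx])
    expect_lt(abs(tot - 100), 0.1 * sum(d$by_sex$sex == sx))
  }
  expect_error(g6pd_distribution(data.frame(sex = "male",
                                            g6pd_class = "undetermined")),
               "no classified")
})

test_that("summaries agree with truth counts on error-free cohorts", {
  pool <- tiny_pool(n_samples = 10, mean_depth = 60, error_rate = 0,
                    seed = 90)
  dm <- demultiplex(pool$reads, pool$scheme, pool$sheet)
  calls <- do.call(rbind, lapply(pool$sheet$sample_id, function(sid) {
    pp <- pileup(align_reads(dm$reads_by_sample[[sid]], pool$refs,
                             pool$panel), pool$panel)
    call_sample(pp, pool$panel, pool$sheet$sex[pool$sheet$sample_id == sid],
                sample_id = sid)
  }))
  sums <- cohort_site_summaries(calls, pool$panel)
  truth <- pool$truth$genotypes
  for (k in pool$panel$sites$site_key) {
    tt <- table(factor(fold_call(truth$truth_class[truth$site_key == k]),
                       levels = c("hom_ref", "het", "hom_alt")))
    row <- sums[sums$site_key == k, ]
    expect_equal(c(row$hom_ref, row$het, row$hom_alt), as.integer(tt))
  }
})
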