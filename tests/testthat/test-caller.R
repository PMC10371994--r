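site_auto <- function() {
  s <- tiny_panel()$sites[1, ]   # 2:1100 T>A, autosomal
  s$x_linked <- FALSE
  s
}
site_x <- function() {
  p <- tiny_panel()
  s <- p$sites[3, ]              # X:5200 C>T
  s$x_linked <- TRUE
  s
}

test_that("allele_fraction uses the ref+alt denominator and flags third alleles", {
  s <- site_auto()
  af <- allele_fraction(count_row(T = 80, A = 20), s)
  expect_equal(af$fraction, 0.20)
  af0 <- allele_fraction(count_row(T = 100), s)
  expect_equal(af0$fraction, 0.0)
  af3 <- allele_fraction(count_row(T = 50, A = 45, G = 5), s)
  expect_equal(af3$fraction, 45 / 95, tolerance = 1e-12)
  expect_false(af3$third_allele)           # 5/100 is not > 10%
  af4 <- allele_fraction(count_row(T = 50, A = 39, G = 11), s)
  expect_true(af4$third_allele)            # 11/100 > 10%
  expect_error(allele_fraction(count_row(), s), "depth 0")
  # N bases count toward depth but not the fraction
  afn <- allele_fraction(count_row(T = 40, A = 40, N = 20), s)
  expect_equal(afn$fraction, 0.5)
  expect_false(afn$third_allele)
})

test_that("genotype thresholds partition the alt-fraction axis", {
  s <- site_auto()
  cases <- list(
    list(T = 90, A = 10, call = "hom_ref"),    # 10%
    list(T = 10, A = 90, call = "hom_alt"),    # 90%
    list(T = 50, A = 50, call = "het"),        # 50%
    list(T = 80, A = 20, call = "het"),        # exactly 20% -> het
    list(T = 20, A = 80, call = "het"))        # exactly 80% -> het
  for (cs in cases) {
    g <- call_genotype(count_row(T = cs$T, A = cs$A), s, "female")
    expect_equal(g$call, cs$call,
                 info = sprintf("T=%d A=%d", cs$T, cs$A))
  }
  # depth below 30 is withheld, depth exactly 30 retained
  g29 <- call_genotype(count_row(T = 29), s, "female")
  expect_equal(g29$call, "no_call")
  expect_true(grepl("low_depth", g29$flags))
  g30 <- call_genotype(count_row(T = 30), s, "female")
  expect_equal(g30$call, "hom_ref")
  g0 <- call_genotype(count_row(), s, "male")
  expect_equal(g0$call, "no_call")
  expect_error(call_genotype(count_row(T = 50), s, "unknown"), "sex")
})

test_that("male X-linked calls collapse to hemizygous classes", {
  s <- site_x()
  g <- call_genotype(count_row(C = 2, T = 98), s, "male")
  expect_equal(g$call, "hemi_alt")
  g2 <- call_genotype(count_row(C = 98, T = 2), s, "male")
  expect_equal(g2$call, "hemi_ref")
  # diploid-looking het in a male collapses to majority allele with a flag
  g3 <- call_genotype(count_row(C = 60, T = 40), s, "male")
  expect_equal(g3$call, "hemi_ref")
  expect_true(grepl("male_het_anomaly", g3$flags))
  g4 <- call_genotype(count_row(C = 40, T = 60), s, "male")
  expect_equal(g4$call, "hemi_alt")
  # females on X stay diploid
  g5 <- call_genotype(count_row(C = 60, T = 40), s, "female")
  expect_equal(g5$call, "het")
})

test_that("classification is a partition and monotone in alt fraction", {
  s <- site_auto()
  sx <- site_x()
  rank_of <- c(hom_ref = 1, hemi_ref = 1, het = 2, hom_alt = 3, hemi_alt = 3)
  for (sex in c("female", "male")) {
    last_rank_auto <- 0; last_rank_x <- 0
    for (a in 0:100) {
      g <- call_genotype(count_row(T = 100 - a, A = a), s, sex)
      expect_true(g$call %in% c("hom_ref", "het", "hom_alt"))
      expect_gte(rank_of[[g$call]], last_rank_auto)
      last_rank_auto <- rank_of[[g$call]]
      gx <- call_genotype(count_row(C = 100 - a, T = a), sx, sex)
      if (sex == "male") expect_false(gx$call == "het")
      expect_gte(rank_of[[gx$call]], last_rank_x)
      last_rank_x <- rank_of[[gx$call]]
    }
  }
})

test_that("call_sample emits one call per panel site", {
  pool <- tiny_pool(n_samples = 2, mean_depth = 80, error_rate = 0, seed = 19)
  dm <- demultiplex(pool$reads, pool$scheme, pool$sheet)
  sid <- pool$sheet$sample_id[1]
  pp <- pileup(align_reads(dm$reads_by_sample[[sid]], pool$refs, pool$panel),
               pool$panel)
  calls <- call_sample(pp, pool$panel, pool$sheet$sex[1], sample_id = sid)
  expect_equal(nrow(calls), nrow(pool$panel$sites))
  truth <- pool$truth$genotypes
  tc <- truth[truth$sample_id == sid, ]
  m <- merge(calls, tc, by = "site_key")
  expect_equal(m$call, m$truth_class)

  # an entirely missing amplicon leaves its sites no_call, others intact
  pp_drop <- pp[pp$amplicon_id != "AMP_X", ]
  calls2 <- call_sample(pp_drop, pool$panel, pool$sheet$sex[1],
                        sample_id = sid)
  expect_equal(calls2$call[calls2$site_key == "X:5200"], "no_call")
  expect_equal(calls2$call[calls2$site_key != "X:5200"],
               calls$call[calls$site_key != "X:5200"])

  # an empty pileup yields all no_call
  calls3 <- call_sample(empty_pileup(pool$panel), pool$panel, "female",
                        sample_id = "none")
  expect_true(all(calls3$call == "no_call"))
})

test_that("per-amplicon depth scope withholds whole amplicons", {
  p <- tiny_panel()
  pp <- empty_pileup(p)
  pp[pp$site_key == "2:1100", c("T", "depth")] <- c(100L, 100L)
  pp[pp$site_key == "2:1300", c("C", "depth")] <- c(10L, 10L)
  pp[pp$site_key == "X:5200", c("C", "depth")] <- c(50L, 50L)
  # site scope: only the 10x site is withheld
  cs <- call_sample(pp, p, "female", depth_scope = "site")
  expect_equal(cs$call[cs$site_key == "2:1100"], "hom_ref")
  expect_equal(cs$call[cs$site_key == "2:1300"], "no_call")
  # amplicon scope: mean depth (100+10)/2 = 55 >= 30 keeps both
  ca <- call_sample(pp, p, "female", depth_scope = "amplicon")
  expect_equal(ca$call[ca$site_key == "2:1300"], "hom_ref")
})

test_that("no male X heterozygote survives randomized calling", {
  s <- site_x()
  set.seed(4242)
  depth <- sample(30:500, 2000, replace = TRUE)
  alt <- vapply(depth, function(d) rbinom(1, d, runif(1)), integer(1))
  for (i in seq_along(depth)) {
    g <- call_genotype(count_row(C = depth[i] - alt[i], T = alt[i]), s,
                       "male")
    expect_false(g$call %in% c("het", "hom_ref", "hom_alt"))
  }
})
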