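test_that("simulated references honour length, site bases and the seed", {
  p <- load_panel("malaria_host_v1")
  refs1 <- simulate_references(p, 1)
  expect_named(refs1, p$amplicons$amplicon_id, ignore.order = TRUE)
  expect_equal(unname(nchar(refs1[p$amplicons$amplicon_id])),
               p$amplicons$end - p$amplicons$start + 1)
  sites <- panel_sites(p)
  base_at <- function(refs, s)
    substr(refs[[s$amplicon_id]], s$local_offset + 1, s$local_offset + 1)
  for (i in seq_len(nrow(sites)))
    expect_equal(base_at(refs1, sites[i, ]), sites$ref[i])

  expect_identical(simulate_references(p, 1), refs1)
  refs2 <- simulate_references(p, 2)
  expect_false(all(refs2 == refs1))
  for (i in seq_len(nrow(sites)))
    expect_equal(base_at(refs2, sites[i, ]), sites$ref[i])
})

test_that("cohort truth follows the configured allele frequencies", {
  p <- tiny_panel()
  freqs0 <- setNames(c(0, 1, 0.5), p$sites$site_key)
  cfg <- sim_config(n_samples = 40, alt_freq = freqs0, seed = 3)
  truth <- simulate_cohort(p, cfg)
  g <- truth$genotypes
  k <- p$sites$site_key
  expect_true(all(g$truth_class[g$site_key == k[1]] == "hom_ref"))
  expect_true(all(g$truth_class[g$site_key == k[2]] == "hom_alt"))

  # male X genotypes are single-allele
  males <- truth$samples$sample_id[truth$samples$sex == "male"]
  gx <- g[g$site_key == "X:5200" & g$sample_id %in% males, ]
  expect_true(all(is.na(gx$allele2)))
  expect_true(all(gx$truth_class %in% c("hemi_ref", "hemi_alt")))
})

test_that("allele frequency at 0.5 matches a binomial oracle at n = 10000", {
  p <- tiny_panel()
  freqs <- setNames(c(0.5, 0, 0), p$sites$site_key)
  cfg <- sim_config(n_samples = 10000, sex_ratio = 0, alt_freq = freqs,
                    seed = 5)
  truth <- simulate_cohort(p, cfg)
  g <- truth$genotypes[truth$genotypes$site_key == p$sites$site_key[1], ]
  n_alleles <- 2 * nrow(g)
  n_alt <- sum(g$allele1 == "A") + sum(g$allele2 == "A")
  se <- sqrt(0.25 / n_alleles)
  expect_lt(abs(n_alt / n_alleles - 0.5), 3 * se)
})

test_that("simulated reads reproduce haplotype fractions and error rates", {
  p <- tiny_panel()
  # single female sample, forced heterozygous at site A1 via freq 0.5 retry
  cfg <- sim_config(n_samples = 1, sex_ratio = 0,
                    alt_freq = setNames(c(1, 0, 0), p$sites$site_key),
                    mean_depth = 200, error_rate = 0, seed = 9)
  refs <- simulate_references(p, cfg$seed)
  truth <- simulate_cohort(p, cfg)
  # make the sample het at site 1 by hand: allele1 ref, allele2 alt
  i <- truth$genotypes$site_key == p$sites$site_key[1]
  truth$genotypes$allele1[i] <- p$sites$ref[1]
  truth$genotypes$allele2[i] <- p$sites$alt[1]
  truth$genotypes$truth_class[i] <- "het"
  scheme <- build_index_scheme(2, 2, seed = 1)
  sheet <- make_sample_sheet(scheme, truth$samples$sample_id, "female")
  sim <- simulate_reads(truth, refs, p, cfg, sheet)

  # error-free reads: index-trimmed read equals one of the haplotypes
  dm <- demultiplex(sim$reads, scheme, sheet)
  rd <- dm$reads_by_sample[[1]]
  aln <- align_reads(rd, refs, p)
  pp <- pileup(aln, p)
  col <- pp[pp$site_key == p$sites$site_key[1], ]
  f <- col$A / (col$A + col$T)
  n <- col$A + col$T
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / n))
  # hom-ref site is pure ref
  col3 <- pp[pp$site_key == p$sites$site_key[2], ]
  expect_equal(col3$T, 0)

  # hom-alt sample at error 0 gives alt fraction exactly 1
  cfg2 <- sim_config(n_samples = 1, sex_ratio = 0,
                     alt_freq = setNames(c(1, 0, 0), p$sites$site_key),
                     mean_depth = 100, error_rate = 0, seed = 10)
  truth2 <- simulate_cohort(p, cfg2)
  sim2 <- simulate_reads(truth2, refs, p, cfg2, sheet)
  dm2 <- demultiplex(sim2$reads, scheme, sheet)
  pp2 <- pileup(align_reads(dm2$reads_by_sample[[1]], refs, p), p)
  col2 <- pp2[pp2$site_key == p$sites$site_key[1], ]
  expect_gt(col2$depth, 0)
  expect_equal(col2$A / (col2$A + col2$T), 1.0)
})

test_that("per-base substitution errors occur at the configured rate", {
  p <- tiny_panel()
  cfg <- sim_config(n_samples = 1, sex_ratio = 0,
                    alt_freq = setNames(c(0, 0, 0), p$sites$site_key),
                    mean_depth = 60, error_rate = 0.01, seed = 12)
  refs <- simulate_references(p, cfg$seed)
  truth <- simulate_cohort(p, cfg)
  scheme <- build_index_scheme(2, 2, seed = 1)
  sheet <- make_sample_sheet(scheme, truth$samples$sample_id, "female")
  sim <- simulate_reads(truth, refs, p, cfg, sheet)
  # hom-ref everywhere: every non-reference base is an error
  full_ref <- paste0(sheet$fwd_index[1], refs[["AMP_A"]],
                     rev_comp(sheet$rev_index[1]))
  amp_a <- sim$log$read_id[sim$log$amplicon_id == "AMP_A"]
  seqs <- sim$reads$seq[sim$reads$id %in% amp_a]
  mm <- sum(hamming(seqs, full_ref))
  n_bases <- sum(nchar(seqs))
  se <- sqrt(0.01 * 0.99 / n_bases)
  expect_lt(abs(mm / n_bases - 0.01), 3 * se)
})

test_that("read counts per sample x amplicon are Poisson distributed", {
  p <- tiny_panel()
  cfg <- sim_config(n_samples = 250, sex_ratio = 0.5,
                    alt_freq = setNames(rep(0.3, 3), p$sites$site_key),
                    mean_depth = 20, error_rate = 0, seed = 21)
  refs <- simulate_references(p, cfg$seed)
  truth <- simulate_cohort(p, cfg)
  scheme <- build_index_scheme(17, 17, seed = 2)
  sheet <- make_sample_sheet(scheme, truth$samples$sample_id,
                             truth$samples$sex)
  sim <- simulate_reads(truth, refs, p, cfg, sheet)
  counts <- table(factor(paste(sim$log$sample_id, sim$log$amplicon_id),
                         levels = as.vector(outer(sheet$sample_id,
                                                  p$amplicons$amplicon_id,
                                                  paste))))
  # 500 draws; chi-square GOF against Poisson(20), pooling tails
  lambda <- 20
  breaks <- c(-Inf, 12:28, Inf)
  obs <- table(cut(as.integer(counts), breaks))
  pr <- diff(ppois(c(-Inf, 12:28, Inf), lambda))
  gof <- suppressWarnings(chisq.test(as.integer(obs), p = pr,
                                     rescale.p = TRUE))
  expect_gt(gof$p.value, 0.01)
})

test_that("the whole simulation is reproducible from (config, seed)", {
  a <- tiny_pool(n_samples = 4, seed = 33)
  b <- tiny_pool(n_samples = 4, seed = 33)
  expect_identical(a$refs, b$refs)
  expect_identical(a$truth$genotypes, b$truth$genotypes)
  expect_identical(a$reads, b$reads)
  c <- tiny_pool(n_samples = 4, seed = 34)
  expect_false(identical(a$reads$seq, c$reads$seq))
})

test_that("unknown samples in the truth set are rejected", {
  pool <- tiny_pool(n_samples = 3, seed = 1)
  sheet <- pool$sheet[-1, ]
  expect_error(simulate_reads(pool$truth, pool$refs, pool$panel,
                              pool$config, sheet), "absent")
})
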