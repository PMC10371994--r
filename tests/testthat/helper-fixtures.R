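# Small in-code fixtures shared across test files.

tiny_panel <- function() {
  amp <- data.frame(
    amplicon_id = c("AMP_A", "AMP_X"),
    gene = c("GENE_A", "GENE_X"),
    chrom = c("2", "X"),
    start = c(1000L, 5000L),
    end = c(1449L, 5449L),
    stringsAsFactors = FALSE)
  sites <- data.frame(
    amplicon_id = c("AMP_A", "AMP_A", "AMP_X"),
    gene = c("GENE_A", "GENE_A", "GENE_X"),
    chrom = c("2", "2", "X"),
    pos = c(1100L, 1300L, 5200L),
    rsid = c("rsA1", "rsA2", "rsX1"),
    ref = c("T", "C", "C"),
    alt = c("A", "T", "T"),
    label = c("siteA1", "siteA2", "siteX1"),
    stringsAsFactors = FALSE)
  new_panel("tiny_test_panel", amp, sites)
}

# deterministic small simulated pool built through the package's own
# generator, returned with all intermediates
tiny_pool <- function(n_samples = 6, mean_depth = 50, error_rate = 0,
                      seed = 42, panel = tiny_panel(), alt_freq = NULL) {
  if (is.null(alt_freq))
    alt_freq <- setNames(rep(0.4, nrow(panel$sites)), panel$sites$site_key)
  cfg <- sim_config(n_samples = n_samples, alt_freq = alt_freq,
                    mean_depth = mean_depth, error_rate = error_rate,
                    seed = seed)
  refs <- simulate_references(panel, cfg$seed)
  truth <- simulate_cohort(panel, cfg)
  scheme <- build_index_scheme(ceiling(sqrt(n_samples)) + 1L,
                               ceiling(sqrt(n_samples)) + 1L, seed = seed)
  sheet <- make_sample_sheet(scheme, truth$samples$sample_id,
                             truth$samples$sex)
  sim <- simulate_reads(truth, refs, panel, cfg, sheet)
  list(panel = panel, config = cfg, refs = refs, truth = truth,
       scheme = scheme, sheet = sheet, reads = sim$reads, log = sim$log)
}

# pileup count row helper
count_row <- function(A = 0, C = 0, G = 0, T = 0, N = 0)
  data.frame(A = A, C = C, G = G, T = T, N = N)
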