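#' Run the full synthetic-to-report pipeline
#'
#' Chains every stage on synthetic data: reference simulation, cohort truth
#' simulation, index-scheme and sample-sheet construction, pooled read
#' simulation, demultiplexing, amplicon-local alignment and pileup,
#' threshold genotype calling, phenotype inference, and cohort summaries.
#' Entirely deterministic given `config$seed`.
#'
#' @param panel an `amp_panel` (default: the built-in panel).
#' @param config a [sim_config()].
#' @param scheme optional `index_scheme`; by default one large enough for
#'   the cohort is built from `config$seed`.
#' @param max_mismatch index mismatches tolerated during demultiplexing.
#' @param min_depth,lower,upper genotype-calling thresholds.
#' @param out_dir optional directory; when given, FASTQ, truth, sample
#'   sheet, per-sample genotype TSV, phenotype TSV and a multi-sample VCF
#'   are written there.
#' @return list with `panel`, `config`, `refs`, `truth`, `scheme`, `sheet`,
#'   `reads`, `demux`, `pileups`, `calls`, `phenotypes`, `summaries`
#'   (site summaries, completeness, g6pd distribution), and `recovery`.
#' @export
run_pipeline <- function(panel = load_panel("malaria_host_v1"),
                         config = sim_config(n_samples = 20),
                         scheme = NULL, max_mismatch = 0L, min_depth = 30L,
                         lower = 0.20, upper = 0.80, out_dir = NULL) {
  refs <- simulate_references(panel, config$seed)
  truth <- simulate_cohort(panel, config)
  n <- config$n_samples
  if (is.null(scheme)) {
    k <- ceiling(sqrt(n)) + 1L
    scheme <- build_index_scheme(k, k, seed = config$seed)
  }
  sheet <- make_sample_sheet(scheme, truth$samples$sample_id,
                             truth$samples$sex)
  sim <- simulate_reads(truth, refs, panel, config, sheet)
  dm <- demultiplex(sim$reads, scheme, sheet, max_mismatch = max_mismatch)

  pileups <- list(); call_rows <- list()
  for (sid in sheet$sample_id) {
    rd <- dm$reads_by_sample[[sid]]
    pp <- if (is.null(rd) || nrow(rd) == 0L) empty_pileup(panel) else
      pileup(align_reads(rd, refs, panel), panel)
    pileups[[sid]] <- pp
    call_rows[[sid]] <- call_sample(
      pp, panel, sheet$sex[sheet$sample_id == sid], sample_id = sid,
      min_depth = min_depth, lower = lower, upper = upper)
  }
  calls <- do.call(rbind, call_rows)
  rownames(calls) <- NULL
  phenotypes <- phenotype_cohort(calls, panel, sheet)
  summaries <- list(
    sites = cohort_site_summaries(calls, panel),
    completeness = completeness(calls, panel),
    g6pd = tryCatch(g6pd_distribution(phenotypes), error = function(e) NULL))
  recov <- genotype_recovery(calls, truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fastq(sim$reads, file.path(out_dir, "pool.fastq"))
    write_truth_tsv(truth, file.path(out_dir, "truth.tsv"))
    write_sample_sheet(sheet, file.path(out_dir, "sample_sheet.tsv"))
    write_genotype_tsv(calls, file.path(out_dir, "genotypes.tsv"))
    write.table(phenotypes, file.path(out_dir, "phenotypes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_vcf(calls, panel, file.path(out_dir, "genotypes.vcf"))
  }

  list(panel = panel, config = config, refs = refs, truth = truth,
       scheme = scheme, sheet = sheet, reads = sim$reads, read_log = sim$log,
       demux = dm, pileups = pileups, calls = calls,
       phenotypes = phenotypes, summaries = summaries, recovery = recov)
}
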