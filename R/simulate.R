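#' Simulation configuration
#'
#' Bundles the knobs of the synthetic cohort/read generator. Defaults model
#' the kind of MiSeq amplicon pool the panel was designed for: ~100x mean
#' depth per sample and amplicon, a small iid per-base substitution error
#' rate, and per-site alt-allele frequencies estimated from the bundled
#' reference-cohort tallies (for the built-in panel) or 0.1 otherwise.
#'
#' @param n_samples number of samples in the cohort.
#' @param sex_ratio proportion of males (default 0.5).
#' @param alt_freq named numeric vector of per-site alt-allele frequencies
#'   keyed by site key; `NULL` uses [default_alt_freqs()].
#' @param mean_depth mean reads per sample x amplicon (Poisson mean).
#' @param error_rate iid per-base substitution probability in `[0, 0.5)`,
#'   applied over the whole read including the index bases.
#' @param depth_multipliers optional named vector of per-amplicon depth
#'   multipliers (amplicons not named get 1); designating an amplicon as
#'   low-coverage with [low_coverage_amplicon()] applies 0.15.
#' @param alt_haplotype_bias optional named per-amplicon probability of a
#'   read originating from the second (alt-carrying, for heterozygotes)
#'   haplotype; default 0.5 models unbiased amplification, lower values model
#'   allele-biased amplification.
#' @param seed integer random seed recorded in all outputs.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_samples, sex_ratio = 0.5, alt_freq = NULL,
                       mean_depth = 100, error_rate = 0.005,
                       depth_multipliers = NULL, alt_haplotype_bias = NULL,
                       seed = 1L) {
  stopifnot(n_samples >= 1, sex_ratio >= 0, sex_ratio <= 1,
            mean_depth > 0, error_rate >= 0, error_rate < 0.5)
  if (!is.null(alt_freq) && (any(alt_freq < 0) || any(alt_freq > 1)))
    stop("alt_freq values must lie in [0, 1]")
  structure(list(n_samples = as.integer(n_samples), sex_ratio = sex_ratio,
                 alt_freq = alt_freq, mean_depth = mean_depth,
                 error_rate = error_rate,
                 depth_multipliers = depth_multipliers,
                 alt_haplotype_bias = alt_haplotype_bias,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Designate a low-coverage amplicon
#'
#' Returns a depth-multiplier vector marking one amplicon as low-coverage
#' (multiplier 0.15), emulating the coverage deficit of an amplicon with
#' poor primer binding affinity such as the intergenic Dantu target.
#'
#' @param amplicon_id amplicon to mark.
#' @param multiplier depth multiplier for the designated amplicon.
#' @return named numeric vector usable as `depth_multipliers`.
#' @export
low_coverage_amplicon <- function(amplicon_id, multiplier = 0.15) {
  setNames(multiplier, amplicon_id)
}

#' Default per-site alt-allele frequencies
#'
#' For the built-in panel, allele frequencies are estimated from the bundled
#' reference-cohort genotype tallies as `(het + 2 hom_alt) / (2 n)`; for
#' other panels every site defaults to 0.1.
#'
#' @param panel an `amp_panel`.
#' @return named numeric vector keyed by site key.
#' @export
default_alt_freqs <- function(panel) {
  sites <- panel$sites
  if (identical(panel$name, "malaria_host_v1")) {
    cc <- builtin_cohort_counts()
    n <- cc$hom_ref + cc$het + cc$hom_alt
    p <- (cc$het + 2 * cc$hom_alt) / (2 * n)
    freqs <- setNames(p, cc$site_key)
    out <- setNames(rep(0.1, nrow(sites)), sites$site_key)
    out[names(freqs)] <- freqs
    out
  } else {
    setNames(rep(0.1, nrow(sites)), sites$site_key)
  }
}

#' Simulate amplicon reference sequences
#'
#' Generates a uniform-random sequence of the correct length for each panel
#' amplicon, then overwrites the base at every variant-site offset with the
#' site's ref allele, so the simulated references are consistent with the
#' panel by construction. Deterministic given the seed.
#'
#' @param panel an `amp_panel`.
#' @param seed integer seed.
#' @return named character vector keyed by amplicon_id.
#' @export
simulate_references <- function(panel, seed = 1L) {
  set.seed(seed)
  amp <- panel$amplicons
  sites <- panel_sites(panel)
  refs <- character(nrow(amp))
  names(refs) <- amp$amplicon_id
  for (i in seq_len(nrow(amp))) {
    len <- amp$end[i] - amp$start[i] + 1L
    chars <- sample(DNA_BASES, len, replace = TRUE)
    ss <- sites[sites$amplicon_id == amp$amplicon_id[i], , drop = FALSE]
    chars[ss$local_offset + 1L] <- ss$ref
    refs[i] <- paste(chars, collapse = "")
  }
  refs
}

#' Simulate cohort truth genotypes
#'
#' Draws per-sample diploid genotypes under Hardy-Weinberg equilibrium: each
#' allele is an independent Bernoulli(alt-frequency) draw. Males carry a
#' single haploid allele at X-linked sites. Heterozygous genotypes store the
#' ref allele as `allele1` and the alt allele as `allele2`, so the simulator's
#' haplotype-bias knob has a well-defined direction.
#'
#' @param panel an `amp_panel`.
#' @param config a [sim_config()].
#' @return list of class `cohort_truth` with `samples` (sample_id, sex) and
#'   `genotypes` (sample_id, site_key, allele1, allele2 — `NA` for male X —
#'   and `truth_class`).
#' @export
simulate_cohort <- function(panel, config) {
  set.seed(config$seed + 1L)
  n <- config$n_samples
  sample_id <- sprintf("S%03d", seq_len(n))
  sex <- ifelse(runif(n) < config$sex_ratio, "male", "female")
  sites <- panel_sites(panel)
  freqs <- config$alt_freq
  if (is.null(freqs)) freqs <- default_alt_freqs(panel)

  gts <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    p <- freqs[[s$site_key]]
    if (is.null(p) || is.na(p)) p <- 0
    a1 <- ifelse(rbinom(n, 1L, p) == 1L, s$alt, s$ref)
    a2 <- ifelse(rbinom(n, 1L, p) == 1L, s$alt, s$ref)
    haploid <- s$x_linked & sex == "male"
    a2[haploid] <- NA_character_
    # order het genotypes ref-first
    swap <- !haploid & a1 == s$alt & a2 == s$ref
    a1[swap] <- s$ref; a2[swap] <- s$alt
    cls <- ifelse(haploid,
                  ifelse(a1 == s$alt, "hemi_alt", "hemi_ref"),
                  ifelse(a1 == s$alt & a2 == s$alt, "hom_alt",
                         ifelse(a1 == s$ref & a2 == s$ref, "hom_ref", "het")))
    gts[[i]] <- data.frame(sample_id = sample_id, site_key = s$site_key,
                           allele1 = a1, allele2 = a2, truth_class = cls,
                           stringsAsFactors = FALSE)
  }
  structure(list(samples = data.frame(sample_id = sample_id, sex = sex,
                                      stringsAsFactors = FALSE),
                 genotypes = do.call(rbind, gts),
                 seed = config$seed),
            class = "cohort_truth")
}

#' Simulate a dual-indexed pooled read set
#'
#' For every sample x amplicon, draws Poisson(mean depth x multiplier) reads.
#' Each read is a full-length copy of one of the sample's haplotypes (chosen
#' with probability `alt_haplotype_bias` for the second haplotype, default
#' 0.5, so a heterozygote's expected alt fraction is the bias), prefixed with
#' the sample's forward index and suffixed with the reverse-complemented
#' reverse index, then subjected to iid per-base substitution errors over the
#' whole construct. Qualities are constant Q30.
#'
#' @param truth a `cohort_truth` from [simulate_cohort()].
#' @param refs named amplicon reference sequences (see
#'   [simulate_references()]).
#' @param panel an `amp_panel`.
#' @param config a [sim_config()].
#' @param sample_sheet data.frame (sample_id, fwd_index, rev_index, sex);
#'   every truth sample must appear with a unique index pair.
#' @return list with `reads` (data.frame id, seq, qual) and `log`
#'   (data.frame read_id, sample_id, amplicon_id, haplotype).
#' @export
simulate_reads <- function(truth, refs, panel, config, sample_sheet) {
  missing <- setdiff(truth$samples$sample_id, sample_sheet$sample_id)
  if (length(missing) > 0L)
    stop("samples absent from sample sheet: ", paste(missing, collapse = ", "))
  if (anyDuplicated(paste(sample_sheet$fwd_index, sample_sheet$rev_index)))
    stop("sample sheet index pairs are not unique")
  set.seed(config$seed + 2L)

  amp <- panel$amplicons
  sites <- panel_sites(panel)
  mult <- setNames(rep(1, nrow(amp)), amp$amplicon_id)
  if (!is.null(config$depth_multipliers)) {
    dm <- config$depth_multipliers
    mult[names(dm)] <- dm
  }
  bias <- setNames(rep(0.5, nrow(amp)), amp$amplicon_id)
  if (!is.null(config$alt_haplotype_bias)) {
    hb <- config$alt_haplotype_bias
    bias[names(hb)] <- hb
  }
  rc_rev <- setNames(rev_comp(sample_sheet$rev_index),
                     sample_sheet$sample_id)
  fwd <- setNames(sample_sheet$fwd_index, sample_sheet$sample_id)

  gt <- truth$genotypes
  seq_chunks <- list(); log_chunks <- list()
  counter <- 0L
  for (si in seq_len(nrow(truth$samples))) {
    sid <- truth$samples$sample_id[si]
    sex <- truth$samples$sex[si]
    g <- gt[gt$sample_id == sid, , drop = FALSE]
    for (ai in seq_len(nrow(amp))) {
      aid <- amp$amplicon_id[ai]
      n_reads <- rpois(1L, config$mean_depth * mult[[aid]])
      if (n_reads == 0L) next
      ref_chars <- strsplit(refs[[aid]], "", fixed = TRUE)[[1]]
      L <- length(ref_chars)
      ss <- sites[sites$amplicon_id == aid, , drop = FALSE]
      ga <- g[match(ss$site_key, g$site_key), , drop = FALSE]
      hap1 <- ref_chars; hap2 <- ref_chars
      if (nrow(ss) > 0L) {
        hap1[ss$local_offset + 1L] <- ga$allele1
        a2 <- ifelse(is.na(ga$allele2), ga$allele1, ga$allele2)
        hap2[ss$local_offset + 1L] <- a2
      }
      choice <- rbinom(n_reads, 1L, bias[[aid]])
      m <- matrix(hap1, nrow = L, ncol = n_reads)
      if (any(choice == 1L)) m[, choice == 1L] <- hap2
      fwd_chars <- strsplit(fwd[[sid]], "", fixed = TRUE)[[1]]
      rev_chars <- strsplit(rc_rev[[sid]], "", fixed = TRUE)[[1]]
      m <- rbind(matrix(fwd_chars, nrow = length(fwd_chars), ncol = n_reads),
                 m,
                 matrix(rev_chars, nrow = length(rev_chars), ncol = n_reads))
      if (config$error_rate > 0) {
        total <- length(m)
        n_err <- rbinom(1L, total, config$error_rate)
        if (n_err > 0L) {
          idx <- sample.int(total, n_err)
          cur <- match(m[idx], DNA_BASES)
          shift <- sample.int(3L, n_err, replace = TRUE)
          m[idx] <- DNA_BASES[(cur - 1L + shift) %% 4L + 1L]
        }
      }
      ids <- sprintf("r%07d", counter + seq_len(n_reads))
      counter <- counter + n_reads
      seq_chunks[[length(seq_chunks) + 1L]] <- data.frame(
        id = ids, seq = do.call(paste0, asplit(m, 1L)),
        qual = strrep("?", nrow(m)), stringsAsFactors = FALSE)
      log_chunks[[length(log_chunks) + 1L]] <- data.frame(
        read_id = ids, sample_id = sid, amplicon_id = aid,
        haplotype = choice + 1L, stringsAsFactors = FALSE)
    }
  }
  reads <- if (length(seq_chunks)) do.call(rbind, seq_chunks) else
    data.frame(id = character(0), seq = character(0), qual = character(0))
  lg <- if (length(log_chunks)) do.call(rbind, log_chunks) else
    data.frame(read_id = character(0), sample_id = character(0),
               amplicon_id = character(0), haplotype = integer(0))
  list(reads = reads, log = lg, seed = config$seed)
}
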