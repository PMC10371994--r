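---
title: "Amplicon genotyping of malaria host-susceptibility variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amplicon genotyping of malaria host-susceptibility variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(malamp)
```

## The problem

Human polymorphisms shaped by malaria's selective pressure — the sickle-cell
allele on *HBB*, the G6PD-deficiency variants on the X chromosome, the
Duffy-null promoter variant on *ACKR1*, and the intergenic Dantu blood-group
variant — determine disease severity, treatment safety (primaquine and G6PD
deficiency), and parasite invasion biology. Whole-genome approaches are
expensive and ethically heavy for the populations that need this information
most. Targeted amplicon sequencing with custom dual indices offers a cheap,
pooled alternative: each sample's amplicons carry a unique (forward,
reverse) 8-bp index pair, hundreds of samples are sequenced in one run, and
genotypes are read off per-site base counts.

`malamp` implements that workflow end to end: panel definition, dual-index
demultiplexing, amplicon-local alignment and pileup, threshold genotype
calling with X-chromosome hemizygote handling, phenotype inference (G6PD
A−/A+/B classes, haemoglobin type, Duffy and Dantu status), and cohort
reporting with concordance against prior genotyping. A synthetic read
generator makes every stage testable without any sequence download.

## The panel model

A panel is a set of amplicon targets (1-based inclusive GRCh38 intervals)
and the variant sites they cover. The built-in `malaria_host_v1` panel has
7 amplicons over 4 loci and 25 SNP sites: one *HBB* amplicon (HbS rs334,
HbC, HbE, and several thalassaemia-associated and off-target sites), four
*G6PD* amplicons covering the deficiency variants at cDNA positions
202/376/542/680/968 plus benign and unnamed sites, one *ACKR1* amplicon
(rs2814778), and one amplicon for the intergenic Dantu region
(rs186873296).

Two conventions matter:

* **Strand.** Ref/alt alleles are stored as plus-strand genomic bases even
  for minus-strand genes (*HBB*, *G6PD*). The cDNA-style labels ("202 C>T")
  are metadata; all counting is plus-strand.
* **Coordinates.** Site positions are 1-based genomic; amplicon-local
  offsets are 0-based (`pos - start`), the usual pileup convention.

The assay targets products of 400–600 bp, but exact primer footprints are a
wet-lab property with no computational consequence here. The built-in panel
therefore assigns each amplicon a ~500 bp window: centred on the site
cluster for *HBB*, *ACKR1* and Dantu, and four non-overlapping windows
grouping the *G6PD* sites by proximity. `validate_panel()` enforces the
structural invariants (each site inside exactly one amplicon, single-base
ref ≠ alt, sorted sites, reference-sequence consistency) and treats window
lengths outside 400–600 bp as warnings for user panels.

## Dual indexing and demultiplexing

Indices are 8 bp with a minimum pairwise Hamming distance of 3 within each
of the forward and reverse lists (`build_index_scheme()`, randomized-greedy
generation). The distance-3 floor is chosen so that one-mismatch
demultiplexing is provably unambiguous (two distinct indices cannot share a
read within one substitution). A 10 × 10 design yields 90 usable pairs
under the default `exclude_same_rank = TRUE`, which drops the ten (i, i)
pairs as an anti-contamination safeguard; setting it to `FALSE` restores
the full 100. Index pairs are conserved per sample across all amplicons,
and a pooling check warns above 200 amplicon products per pool.

Reads carry the forward index literally at the 5′ end and the
reverse-complemented reverse index at the 3′ end; the demultiplexer and the
simulator share this contract. The default matching is exact
(`max_mismatch = 0`) — the conservative choice given that no tolerance is
standard — with a 1-mismatch mode available. A read is assigned only when
exactly one sample matches both indices; ambiguous, unmatched and
shorter-than-16-bp reads are set aside with reasons, so the output bins
always partition the input.

## Alignment and pileup

Reads are aligned locally against the panel's amplicon references (a closed
universe of 7 sequences), which is equivalent to genome mapping for pileup
purposes and removes any reference-genome dependency. Two routes exist:

* `align_read()` — exact Smith–Waterman with affine gaps (match +1,
  mismatch −1, gap open −2 for the first gapped base, extend −1), full
  traceback, best reference wins. This is the reference implementation the
  test suite checks against an independent brute-force dynamic program.
* `align_reads()` — the batch workhorse: shared 11-mer seeding picks the
  candidate amplicon and its best-supported diagonal, and the read is
  aligned along that diagonal (the exact gap-free Smith–Waterman solution
  on it, found by maximum-sum segment). When the seeded alignment's
  identity falls below the acceptance threshold — the signature of an
  indel or a junk read — the batch path falls back to full Smith–Waterman.
  Ties between references go to the first in panel order; diagonal ties go
  to the smaller diagonal.

Alignments are rejected below 0.8 identity over the aligned span or under a
50-bp span; neither value is assay-derived, both are conventional defaults
exposed in the API. Pileup counts, per variant site, the read base aligned
to the site offset; gapped positions contribute nothing and N bases count
toward depth but never toward an allele. Externally mapped SAM/BAM is
ingested through `read_sam()` (amplicon-local or genomic coordinates,
CIGAR-aware), producing pileups identical to the internal route on the same
alignments. Base qualities are not filtered by default — the simulator
emits constant Q30 — and the `min_base_quality` knob is reserved for
quality-carrying inputs.

## Genotype calling

Calling is deliberately simple and transparent — fixed depth and
allele-fraction thresholds rather than genotype likelihoods:

* depth < 30 → `no_call` (`low_depth` flag); depth exactly 30 is retained;
* alt fraction f < 0.20 → homozygous reference;
* f > 0.80 → homozygous alternate;
* 0.20 ≤ f ≤ 0.80 → heterozygous.

The boundary points 0.20 and 0.80 are assigned to the heterozygous class
(closed interval): the heterozygous rule is the entry condition at its open
edges, and both cut-points are configurable. The alt fraction is computed
over ref + alt counts only, so error bases at a third allele do not depress
it; when non-ref/non-alt bases exceed 10% of depth a `third_allele` flag is
raised (a data-quality signal, not a calling rule). If ref + alt counts are
zero at adequate depth — a column swamped by third alleles or Ns — the call
is withheld, the one situation where `no_call` does not mean low depth.

Males at X-linked sites are hemizygous: homozygous-style calls collapse to
`hemi_ref`/`hemi_alt`, and a diploid-looking heterozygote (contamination,
mis-sexing) collapses to the majority allele with a `male_het_anomaly`
flag. This collapsing rule is this package's convention; the class labels
follow the standard hemizygote nomenclature. A female heterozygote is never
collapsed. The 30× filter applies per site by default
(`depth_scope = "site"`); a per-amplicon mode is provided because
"coverage at positions of interest" can be read either way.

## Phenotype inference

**G6PD.** The A−/A+/B nomenclature encodes haplotypes of the 202
(rs1050828) and 376 (rs1050829) variants: B carries neither, A+ carries 376
only, A− carries both. Male classes come directly from the hemizygous
calls. Female diplotypes require a phasing assumption for the double
heterozygote: `malamp` resolves 202-het/376-het as B/A− because the
nomenclature itself presupposes that 202-variant alleles occur on the
376-variant background — there is no "202-only" allele class. Combinations
that violate this structure (202-variant dose exceeding 376-variant dose)
are reported as `non_canonical` and left unclassified rather than forced.
Severe deficiency is exactly {A−, A−A−}. The remaining G6PD panel sites
(542, 680, 968, and the benign rs2230036/rs5986875) are reported as raw
genotype calls and never alter the class.

**Haemoglobin.** The label composes from variant-allele doses at rs334
(S), rs33930165 (C) and rs33950507 (E); more than two variant alleles
across the three sites is impossible for one diploid locus and raises an
inconsistency error. **Duffy** and **Dantu** map directly from their single
sites; rs713040 and other off-target sites are carried as annotations with
no phenotype label.

## The synthetic-data generator

The generator emulates the study design the panel was built for: a pooled
MiSeq run of dual-indexed amplicons over a paediatric severe-malaria
cohort.

* **Truth genotypes** are Hardy–Weinberg draws per site (two independent
  Bernoulli alleles; one for males on X). Default alt-allele frequencies
  are estimated from the bundled reference-cohort tallies
  (`builtin_cohort_counts()`), so simulated cohorts resemble the Northeast
  Tanzanian population the assay was validated in.
* **Reads** are full-length single-end amplicon copies: per sample ×
  amplicon the read count is Poisson with mean `mean_depth` (default 100,
  a typical per-product target for this pool size), each read picks a
  haplotype uniformly (a heterozygote's expected alt fraction is 0.5), and
  iid substitution errors at `error_rate` hit every base including the
  index bases — which is what a per-base error model means for an indexed
  construct. The default 0.005 is a plausible post-filter Illumina
  substitution rate; it is a free parameter of the simulation, not a
  measured property of any particular run.
* **Depth heterogeneity** is available via per-amplicon multipliers;
  `low_coverage_amplicon("DANTU_1")` marks an amplicon as low-coverage
  (multiplier 0.15) to mimic the Dantu amplicon's primer-affinity deficit.
  No amplicon is designated by default, so the headline simulation
  conditions keep all amplicons at the configured mean depth.
* **Allele-biased amplification** is modelled by `alt_haplotype_bias`: at
  bias 0.15 a true heterozygote's expected alt fraction sits below the 20%
  threshold and the caller classifies it homozygous reference — the exact
  mechanism behind the known Dantu heterozygote misclassification, which
  the test suite reproduces.

What the generator does **not** model: linkage between sites (each site is
drawn independently, so e.g. non-canonical G6PD 202/376 combinations arise
far more often than in real cohorts, where the two variants are in strong
LD); realistic quality-score profiles; indel errors (the panel sites are
SNPs and the caller does not call indels); PCR chimeras; and index hopping.
Passing end-to-end tests therefore demonstrates the correctness of the
pipeline's logic under its stated error model, not robustness to every
artefact of real amplicon data.

Reads are full-length single-end rather than paired 2×150 because the
analysis is pileup-based and the fragment is the amplicon; paired reads
would exercise no additional downstream logic.

## Determinism and numerical conventions

Every stochastic stage takes the seed from `sim_config()`; the three
simulation stages use fixed offsets of it (references +0, cohort +1, reads
+2) so each stage is independently reproducible. Reported percentages
follow the field's printing conventions: frequencies and per-1000 rates to
1 decimal, overall discordance to 2 decimals. Concordance folds hemizygous
onto homozygous classes and compares only pairs determinate on both sides;
per-site denominators therefore vary, and nothing is imputed. Carrier
frequency is per-participant (share with ≥1 variant allele) — the
convention used in the assay's validation cohort — while
`allele_count_frequency()` provides the true allele-count frequency under a
distinct name.

The test suite runs the full pipeline at 50 samples × 7 amplicons × 100×
mean depth with error 0.005 (~35,000 reads), a size chosen to exercise
every rule with tight statistical margins while keeping the default test
run fast; the acceptance script uses the same conditions.

## Known limitations

* The threshold caller has no notion of genotype likelihood or allele
  balance priors; borderline fractions near 0.2/0.8 flip classes with no
  uncertainty estimate.
* Indels are neither simulated nor called; the batch aligner handles them
  (via its Smith–Waterman fallback) only well enough to keep pileups
  honest.
* The G6PD phasing assumption is a population-genetics convention, not an
  observation of any individual's haplotypes; true 202-only chromosomes
  would be reported `non_canonical`.
* Real-data coverage phenomena (per-amplicon coverage spread, sample
  dropout patterns) are only qualitatively reproducible via the depth
  multipliers.
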