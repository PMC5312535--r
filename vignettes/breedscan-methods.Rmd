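---
title: "Methods: statistics, locus selection and the simulation harness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistics, locus selection and the simulation harness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

breedscan implements the bespoke computational stages of a breed-origin
population-genomics analysis: sliding-window diversity, a windowed
F~ST~/PBS selection scan with dual-scan intersection, LD decay profiling,
neutral RAD-locus selection for sequence-based demographic inference, and
the conversion of mutation-scaled coalescent estimates into natural units.
This vignette explains each model, the parameters that matter, the
numerical conventions, and what the simulation harness does and does not
establish.

## Data model and coordinates

All coordinates inside the package are 0-based half-open. VCF (1-based)
and GFF3 (1-based inclusive) are converted at the readers, and a property
test asserts that the same physical interval encoded as BED and as GFF3
compares equal after reading. One convention everywhere removes the
off-by-one class of bugs that plagues mixed-coordinate pipelines.

Genotypes are alternate-allele counts in {0, 1, 2} with `NA` for missing.
Multi-allelic and non-SNP records are dropped (with a reported count), not
split: every statistic below is defined on biallelic SNPs. Missing
genotypes are never imputed; each estimator defines its own handling. No
minor-allele-frequency filter is applied anywhere by default — the source
analyses do not state one, so the package does not invent one.

## Windowed heterozygosity

Per sample and window, diversity is the fraction of heterozygous genotypes
among usable sites. The default grid is 1 Mb windows stepped every 200 kb.
For RAD data, whose coverage is concentrated at restriction sites, a site
is usable for a sample only when its depth is at least `min_depth`
(default 5, inclusive: depth exactly 5 passes, a literal reading of
"coverage less than five times" as the exclusion rule). Windows with zero
usable sites are undefined (`NA`), never zero — a zero would be a strong
biological claim the data cannot support.

## Weir–Cockerham F~ST~ and PBS

Per-window F~ST~ between two populations is the Weir & Cockerham (1984)
"weighted" estimate: the per-SNP among-population variance component *a*
and total *a + b + c* are summed over the SNPs in the window and the ratio
of sums is reported. This is the standard windowed form and the behaviour
of the windowed mode of the common VCF toolkit. Sites need at least two
genotyped individuals per population and a polymorphic pooled sample;
windows with fewer than `min_snps` usable SNPs (default 10) are flagged
undefined and excluded from quantile ranking, preventing single-SNP
outlier windows. The raw estimate (which can be slightly negative) is kept
alongside a copy clamped to [0, 1 − 10⁻⁹]; the clamp keeps the
branch-length transform finite and non-negative.

The population branch statistic for a focal population against a sister
and an outgroup is

    PBS = (T_fs + T_fo − T_so) / 2,   T = −log(1 − F_ST)   (natural log),

computed per window from the three pairwise windowed estimates on a shared
grid (default 100 kb windows, 20 kb step). A window is defined only where
all three pairwise values are. The identity
`PBS_focal + PBS_sister = T_fs` is exact algebra and is property-tested to
10⁻¹².

## LD decay and the H statistic

r² is the composite (Rogers–Huff style) genotype correlation: the squared
Pearson correlation of alternate-allele-count vectors over the samples
non-missing at both sites. Phase is unavailable in this design, so the
phase-free estimator is the appropriate one; it differs from EM-haplotype
r² of phased tools, and pairs involving a monomorphic site are undefined
and skipped. All same-chromosome pairs up to 500 kb are binned into 100
five-kb bins; bins are left-open right-closed, so a pair at exactly 5 kb
falls in bin 1 (an arbitrary but fixed and documented tie-break). The H
statistic is the sum of per-bin mean r² — an area-under-the-curve analogue
of the decay profile, bounded by the bin count (100 at defaults); empty
bins contribute 0 and are flagged by their zero pair count.

## Candidate regions from two scans

The selection procedure takes the top 3% of the PBS windows and the top 3%
of an independent sweep-scan track, intersects them at base-pair level,
merges the result, and reports the covered length and genome fraction
(denominator: the sum of chromosome lengths). Quantile selection uses the
empirical order statistic: with n defined windows the threshold is the
⌈qn⌉-th largest score and ties at the threshold are all included —
deterministic, conservative, and monotone in q. The quantile is taken over
windows, not merged regions (the source is silent; windows are the ranked
unit). The second track is *ingested*, not computed: the
composite-likelihood sweep statistic belongs to a published external tool,
and the package only grids its per-position scores (window maximum by
default). Gene overlap is by at least one base pair, deduplicated and
sorted; the optional enrichment against user-supplied gene lists is a
plain hypergeometric tail test, deliberately not a re-implementation of
external GO services.

## The RAD locus-selection cascade

The neutral-locus pipeline runs in a fixed order: digest → extract →
annotation filters → coverage filter → spacing thinning. The order of the
annotation predicates among themselves is immaterial (they are independent),
and thinning runs last so that a locus rejected earlier cannot shadow a
passing neighbour; the source order is ambiguous, so this order is a
documented choice, not an inference.

* **Digest.** All forward-strand occurrences of the SpeI motif `ACTAGT`;
  the motif is its own reverse complement, so one strand suffices.
  Ambiguity codes never match.
* **Extraction.** 100 bp flanks joined around the motif, 3 bp trimmed from
  each end: 2·100 + 6 − 2·3 = 200 bp loci. Loci whose full untrimmed
  footprint crosses a contig edge or touches an N run are rejected with
  reason `edge`; N-run rejection is logged separately from the gap-track
  filter, since either path may apply.
* **Annotation.** Rejection on ≥ 1 bp overlap with CpG/repeat/gap tracks;
  "at least 10 kb from exons" is inclusive (distance ≥ 10,000 passes) while
  "more than 100 bp from CNEs" is exclusive (distance 100 is rejected) —
  the two phrasings differ and the package preserves the distinction.
  Distance is the end-gap on the half-open system, 0 when overlapping.
* **Coverage.** Every base of both full 100 bp flanks must reach depth ≥ 5
  in every listed individual (inclusive bound, universal quantifier);
  positions absent from the depth table count as zero.
* **Thinning.** "One locus every 100 kb" is a greedy left-to-right walk
  keeping a passing locus only when its cut site is ≥ 100 kb beyond the
  last kept one. The greedy walk guarantees the independence property the
  coalescent sampler needs (no two retained loci closer than the spacing);
  fixed 100 kb bins would not.

Every digested site appears exactly once in the audit table with exactly
one terminal status, and the whole cascade is checked against an
independent brute-force evaluator (plain string slicing and O(n²) interval
loops) on 100 random toy genomes.

## Demographic-unit scaling and trace summaries

Sequence-based coalescent samplers report θ (4N~e~μ per site), τ
(divergence in expected mutations per site) and mutation-scaled migration
rates. With the calibrated dog-lineage mutation rate μ = 2.2×10⁻⁹ per site
per year and generation time g = 3 years:

    T_years = τ / μ        N_e = θ / (4 μ g)        2Nm = m · θ_target / 2

The 2Nm conversion follows the sampler-manual convention (band rate scaled
by the per-generation mutation rate); the convention string travels with
the output because published reports rarely state theirs, and ours is an
explicit choice, not an inference about any particular study's formula.
Scaling is linear and exactly invertible (`unscale_estimates`), which is
property-tested to 10⁻¹² relative error.

Trace files are read per replicate, burn-in iterations are removed before
pooling (default 200,000 of 5,200,000 iterations, one row per 10
iterations; a flag supports thinning raw files on load, since samplers
differ in whether files are pre-thinned). Summaries report the posterior
mean and the central 95% interval using the median-unbiased empirical
quantile (R's type 8) — fixed so documented examples are exact. Replicate
consistency uses a potential-scale-reduction statistic over replicates
(between-replicate variance of means against mean within-replicate
variance); values above 1.1 are flagged. A pooled-interval rule was
rejected because a bimodal pool widens its own interval and defeats the
check.

## What the simulator emulates — and what it does not

`simulate_panel` runs a structured coalescent for the three-population
history the demographic stage infers: the breed splits from the indigenous
dogs 8,300 years ago, dogs split from wolves 31,700 years ago (converted
to generations with g = 3, the same constant the scaling stage uses, so
simulation truth and conversions are mutually consistent), a small
ancestral dog population between the splits, rapid indigenous expansion
after the breed split, a mild breed reduction, and symmetric low migration
(2Nm = 0.5 per band) on the wolf–indigenous and indigenous–breed bands.
The absolute sizes (wolf 20,000; indigenous 30,000; breed 3,000; ancestral
dog 4,000; root 20,000) are plausible placeholders chosen once to give
dog-like nucleotide diversity (~10⁻³/bp in the indigenous population);
graphical sources report no exact values, and these numbers are not
anyone's published estimates.

Numerical design of the simulator:

* Genealogies are simulated per sequence block (default 10 kb): free
  recombination between blocks, complete linkage within. This keeps runs
  deterministic and fast and is adequate for frequency-based statistics
  (F~ST~, PBS, heterozygosity) and for qualitative LD structure; it does
  *not* reproduce a realistic continuous LD decay curve, so decay-shape
  assertions are made only on constructed pair lists, never on simulated
  panels.
* Within an epoch sizes are constant; epoch boundaries are the two split
  times, where lineages are relabelled pastward. Mutations are
  infinite-sites, Poisson on total branch length, at distinct integer
  positions.
* Sweep planting is a frequency transform of neutral output, not a
  forward selection simulation: at each SNP within 100 kb of the target, a
  swept allele is drawn with probability equal to its current frequency in
  the target population (the allele one hitchhiking haplotype would
  carry), and each target genotype becomes the swept homozygote with
  probability `strength` (plateau to 50 kb, then linear decay to zero at
  100 kb). The shipped default `strength = 1` is the completed-hard-sweep
  fixation limit; at that calibration the top-ranked PBS window contains
  the planted sweep in ≥ 90% of 50-replicate batches (measured at 48–50/50
  across three independent seed batches). The transform leaves other
  populations untouched and is the identity at strength 0.
* Depth tables draw one negative-binomial depth per locus and sample
  (mean 36, dispersion 30) and use it for every flank base — RAD coverage
  at the anchored end is locus-level, roughly uniform within a locus —
  with optional per-locus dropout. Synthetic MCMC traces are stationary
  AR(1) deviations around the truth (relative SD `noise`, autocorrelation
  0.9); with `noise = 0` every row equals the truth, so burn-in handling
  is exercised purely by the loader arithmetic.

Passing tests on this harness show that the estimators and the cascade
compute what they claim on data with the assumed structure. They do not
show robustness to properties the generator omits: genotyping error,
array-ascertainment bias of merged SNP-chip data, within-block
recombination, background selection, or non-equilibrium base composition.

## Problem sizes

The shipped tests and the acceptance script use desk-scale problem sizes
chosen as the package's own validation budget: 1–2 Mb single-chromosome
panels with 4–8 diploids per population for simulation-based checks, 50
replicates for sweep power, 100 random toy genomes for the cascade oracle,
500 random instances for the F~ST~ oracle, and 52,000-iteration synthetic
traces in 5 replicates for parameter recovery. All run in a few minutes on
one core; every generator is a pure function of its seed, so results are
exactly reproducible.
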