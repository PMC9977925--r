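---
title: "Models and methods behind the rrhp pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the rrhp pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical model and the procedural choices
behind each stage of the package, in the spirit of the methods sections of
count-based differential-analysis packages. It also documents the design
decisions that were genuinely open, and what the simulation-based tests do
and do not establish about real data.

## The assay and its count model

RRHP measures 5-hydroxymethylcytosine (5hmC) at MspI recognition sites
(CCGG). After a first MspI digestion and adapter ligation, 5hmC at a
junction is glucosylated; glucosyl-5hmC blocks the second MspI digestion,
so only hydroxymethylated junctions keep amplifiable adapters. A sequenced
junction read therefore begins with CCGG, on either strand (the motif is
its own reverse complement), and the read count at a junction is an
abundance measure of hydroxymethylation — which is why libraries are
sequenced at equal volume rather than equal molarity, and why the analysis
treats the data exactly like RNA-seq counts.

Coordinates are 0-based half-open throughout the package; SAM input is
converted from 1-based on entry and BED output is 0-based. The two
junctions of a site are kept as separate analysis units keyed by
`(contig, site_start, strand)`: the plus junction's read starts on the
first C (`five_prime = site_start`), the minus junction's biological 5′
base is the last G (`five_prime = site_start + 3`).

## Quantification rules

A mapped read increments a junction if and only if

* its biological 5′ base is aligned (no soft/hard clip on that side of the
  CIGAR) and coincides exactly with the junction's `five_prime` coordinate,
  and
* its biological first four bases are CCGG, with zero mismatches — the
  junction is adapter-reconstituted sequence, so a mismatch means
  mis-assignment rather than a sequencing-error-tolerant match.

Duplicates are counted, not removed, because abundance at the junction *is*
the signal. Multi-mapper policy is delegated to the aligner; every mapped
record presented is counted at most once. Unmapped, clipped and
non-CCGG-start reads count only toward the raw-read total, giving the
per-library audit trail (raw reads, junction-assigned reads, covered
sites).

## The two-step abundance filter

Sites are removed (1) when at least `max_zero_samples` (default 6) of the
ten biological samples have zero counts, then (2) when at least
`max_below_median` (default 6) samples have counts strictly below *Ymax*,
the median over every remaining entry of the matrix. Three choices here
were open and are now fixed, with the parameters exposed:

* **Controls are excluded** from both filters and from *Ymax*: the control
  library (second digestion omitted) measures library complexity, not
  5hmC, and the filter thresholds are defined against the biological
  design.
* **"Below the median" is strict (`<`)**, the plain reading of the rule;
  the boundary case is covered by tests.
* ***Ymax* is computed after the first filter, zeros included**, because it
  exists for the second filtering step and should describe the matrix that
  step sees. When a previously realised threshold must be imposed (e.g. a
  published *Ymax* of 19), `filter_params(median_override = )` bypasses the
  computation.

Both filters are idempotent and monotone in their thresholds, and each
stage only ever subsets rows — survivor counts are bit-identical. These are
tested properties, not just intentions.

## The moderated differential test

The test is implemented in the package rather than delegated. Counts `c`
in a library of size `L` (column sum) become
`log2((c + 0.5) / (L + 1) * 1e6)`. An unweighted per-site linear fit of the
two-group design (intercept + indicator, large = 1; controls never enter
the design) gives residual standard deviations whose square roots are
regressed on average log2 count by lowess (span 0.5 by default, exposed).
Each observation then receives precision weight `predicted_sd^-4`
evaluated at its fitted log2 count. A degenerate trend (constant counts,
zero residual SD) yields weights at a configurable ceiling (default `1e6`)
instead of infinities.

Weighted least squares per site gives the group log fold change, its
unscaled standard deviation, and `s²` on `d = n − 2` degrees of freedom.
The empirical-Bayes step estimates the prior `(d₀, s₀²)` by method of
moments on `log s²`, matching the mean and variance of the log chi-square
distribution through digamma/trigamma; the single root-find (inverse
trigamma) uses a monotone Newton iteration. When the observed variance of
`log s²` does not exceed its sampling expectation the prior degrees of
freedom are infinite and the prior variance is the arithmetic mean of the
`s²`. Posterior variances are `s̃² = (d₀s₀² + d·s²)/(d₀ + d)`; moderated
`t = logFC / (s̃ · stdev_unscaled)` is referred to a t distribution on
`d₀ + d` degrees of freedom, capped at the pooled residual degrees of
freedom across sites. Two-sided p values are adjusted by the
Benjamini–Hochberg step-up rule (implemented directly; the test suite
cross-checks it against `p.adjust` and the whole chain against an
independent moderated-statistics implementation at `1e-8`). DhmCs are the
sites with `q < 0.05`, strictly — no fold-change threshold is applied.

The MDS diagnostic computes, for each library pair, the root-mean-square of
the 500 largest absolute log2-CPM differences ("leading" fold changes) and
projects the distance matrix with classical metric scaling. Control
libraries appear in the plot — overlapping controls indicate absence of
flow-cell effects — but never in the design matrix.

## The simulator: what it emulates, and what it does not

The generator reproduces the statistical structure the analysis assumes,
under the profiled study's design:

* two groups of five libraries plus one 5hmC-irrelevant control;
* 75 bp single-end reads beginning with CCGG, emitted in biological
  orientation with constant Phred 35 qualities (an optional uniform
  substitution rate exists; base-calling fidelity is not the validation
  surface);
* per-library depth multipliers proportional to the study's raw-read
  depths, which span roughly 7–65 million reads, with the control at about
  double the biological mean — the "equal volume, not equal molarity"
  imbalance;
* per-site hydroxymethylation `π ~ Beta(a, b)` shared by both junctions of
  a site (glucosylation protects the CCGG duplex, not a strand);
* junction counts `NB(mean = multiplier · depth_factor · π, dispersion φ)`
  — a Gamma–Poisson law, matching the RNA-seq analogy of count-based RRHP
  data rather than a binomial thinning of fragment copies; the control
  library uses `mean = multiplier · depth_factor` regardless of `π`;
* reads extend from the junction into their fragment and are truncated at
  the neighbouring cut (natural fragment length, minimum 20 bp) rather
  than padded with invented chimeric sequence.

Defaults are fixed once: `depth_factor = 60` expected reads at a fully
hydroxymethylated junction (giving site-level counts in the tens, the
regime the published filter thresholds imply), baseline `Beta(2, 2)` (a
broad, symmetric level distribution), `φ = 0.3` (the study does not report
a dispersion; this is a typical between-animal value for count assays and
is exposed in the configuration), `diff_fraction = 0.1`,
`effect_logit_shift = log 4`, and a direction mix `diff_up_fraction =
2237/2677` matching the direction split of the study's DhmC calls. A
single integer seed fans out to fixed per-stage streams, so a configuration
reproduces byte-identical FASTQ/SAM/tables, and stages rerun in isolation
reproduce their outputs.

The simulator does **not** emulate adapter read-through, PCR duplicates,
per-cycle quality decay, PhiX spike-ins, mappability or alignment error,
CpG-density structure along the genome, or methylation-sensitivity of the
first digestion (assumed complete, as the protocol intends). Passing the
simulation-based tests therefore demonstrates correctness of the counting,
filtering and inference machinery under the stated count model — not
robustness to alignment artefacts or to misspecified dispersion in real
libraries.

## Validation scenarios and problem sizes

Two seeded scenarios, each ~2,000 planted recognition sites (~400 kb of
genome, a size chosen so the full suite runs in minutes), probe the
operating characteristics of the test:

* **Null calibration** — no planted effects, otherwise default study-like
  parameters: the fraction of sites with `p < 0.05` must lie within three
  binomial standard errors of 0.05, and `q < 0.05` calls must be
  essentially absent.
* **Planted effects** — 10% of sites differential with a four-fold odds
  shift on `π`, balanced between directions, baseline `Beta(2, 18)` (mean
  `π ≈ 0.1`, where a four-fold odds shift is approximately a four-fold
  level change and cannot saturate at 1), `φ = 0.1` and `depth_factor =
  500`, i.e. a moderately dispersed, adequately powered design chosen by a
  power calculation rather than tuned on outcomes. Observed false
  discovery proportion among calls must not exceed 0.10 and sensitivity
  among differential sites present in the analysed (post-filter) set must
  reach 0.8. Sensitivity is scoped to the analysed set deliberately: the
  abundance filter removes weak sites by design, and its subsetting
  behaviour is tested separately.

The direction mix matters more than it may appear: with all effects in one
direction, library-size (CPM) normalisation absorbs the global 5hmC shift
and biases null log fold changes — a genuine property of library-size-only
normalisation that users should keep in mind when one group is globally
hypo- or hyper-hydroxymethylated. The pipeline deliberately performs no
TMM/quantile normalisation, mirroring the published analysis.

## Annotation choices

Categories follow the fixed priority promoter-TSS > TTS > exon > intron >
intergenic, each site receiving exactly one. The promoter window is
(−1000, +100) bp and the TTS window (−100, +1000) bp, strand-relative
around the TSS/TES; the reference tool's defaults are not printed in its
output, so the windows are explicit, configurable parameters here, and the
published category tallies are consequently not treated as reproduction
targets. The nearest gene is the one with the closest TSS on the same
contig (ties broken lexicographically by gene id, for determinism);
distances to the TSS are signed, negative upstream in the gene's
orientation. Overlapping genes are resolved by the same nearest-TSS rule.
Gene models come from GFF3 via standard import; exonless transcripts are
treated as a single exon spanning the transcript.

## Degenerate inputs and numerical corners

* Empty matrices propagate through the filter cascade and return zero-row
  reports rather than erroring.
* A library with zero total counts is an error in the transform (its CPM is
  undefined).
* Sites with non-finite or zero residual variance are excluded from
  hyperparameter estimation but still moderated (their posterior variance
  is the shrunk prior).
* `trigamma⁻¹` falls back to asymptotic forms outside `[1e-6, 1e7]`.
* BED strand codes `0`/`1` are accepted on input and normalised to `+`/`-`.
* The global median of an even number of entries is the mean of the two
  central order statistics (the standard definition), so *Ymax* need not be
  an observed count.

## Known limitations

Single-factor two-group designs only (no blocking or covariates);
library-size normalisation only; annotation is a simplified
re-implementation, not full feature parity with HOMER (no CpG islands,
repeats, or motif analysis); the genome-scale published counts (millions of
sites from tens of millions of reads) require the deposited sequencing data
and reference assembly and are documented as external checks rather than
recomputed at desk scale.
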