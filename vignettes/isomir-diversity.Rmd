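---
title: "IsomiR diversity analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IsomiR diversity analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomirdiv)
```

This vignette is the package's own account of the statistical procedures it
implements, the assumptions they rest on, and the choices made where a
published analysis of this kind typically leaves the details open.

## The analysis in one paragraph

IsomiRs — terminal sequence variants of a mature miRNA — are identified by
signed 5'/3' offsets from the archetype. After discarding isomiRs that never
exceed 100 raw reads in any sample (about 12 reads per million at a typical
8.9-million-read library), the number of distinct isomiRs of each miRNA in
each sample is treated as a per-sample *diversity* statistic. Diversity is
compared between tissue groups (tumor vs normal) and, within tumors, between
histology groups (unfavorable vs favorable); miRNAs significant in both
comparisons with a two-fold change in either direction are the candidate
prognostic markers. Candidates stratify patients by median diversity for
Kaplan–Meier/log-rank analysis and Cox regression adjusted for histology.
Finally, candidate archetypes and isoforms are compared as targeting agents
by scanning 3'UTRs for seed-complementary sites.

## Nomenclature and sequence reconstruction

Coordinates are 1-based inclusive on the precursor hairpin, the convention
miRBase uses for hairpin-relative annotation. Offsets are differences of
read and archetype termini; positive means downstream on the precursor. Only
*templated* variants are modelled: an isomiR sequence is always a precursor
substring, and offsets that would run past the hairpin are rejected loudly
rather than silently mis-sequenced. Non-templated 3' additions (e.g.
post-transcriptional uridylation) and internal editing variants are out of
scope — count tables containing them should be reduced to templated
coordinates upstream.

The package ships a worked-example record for miR-455-5p. Its mature 5p arm
(`UAUGUGCCUUUGGACUACAUCG`) and the uridine immediately 3' of it are genuine
(they are pinned down by the published hybridization probe for the `0|1`
isoform, `TATGTGCCTTTGGACTACATCGT`); the flanking hairpin context in the
FASTA is synthetic, which the file name and header state explicitly. Every
offset computation exercised by the package depends only on the mature arm
and that +1 base.

## Filtering and diversity

* `min_reads = 100`, strict inequality, in `min_samples = 1` sample: the
  filter is deliberately permissive — one strongly expressed sample rescues
  an isomiR — because diversity counting downstream uses per-sample presence
  (count ≥ 1) anyway. The per-sample presence threshold is exposed
  (`presence_min`) since no universal convention exists.
* Pooled categories use bands {1}, {2–9}, {≥10}. Published category labels
  of this kind are often ambiguous about the value 10; the bands here are
  exhaustive and mutually exclusive, so category counts always partition the
  per-tissue miRNA total, and the chi-square on the 2×k table is well
  defined whenever all expected cells are positive (the function refuses
  otherwise and suggests merging).
* Eligibility (`min_median = 3`) keeps miRNAs whose across-sample median
  diversity is at least 3; below that, "diversity" is dominated by
  presence/absence noise.
* Group comparison uses Welch's t-test by default. A pooled-variance option
  exists, but group sizes in tumor/normal designs are typically very
  unbalanced (e.g. 127 vs 5), exactly the situation where the equal-variance
  assumption does the most damage. With zero variance in both groups and
  equal means the p-value is defined as 1 (no evidence), a convention needed
  because diversity rows can be constant.
* Fold change is mean(numerator)/mean(denominator) and the selection band is
  two-sided (> 2 or < 0.5): prognostic hits of this kind can have *fewer*
  isoforms in the tumor group, so a one-sided band would discard the
  biologically expected direction.
* Raw p-value thresholds (0.01 for tumor/normal, 0.05 for the histology
  comparison) are the default to match how such analyses are usually
  reported; Benjamini–Hochberg adjustment is available via `p_adjust` and is
  flagged in the output attributes when used.
* Median splits assign ties to the "less"/"low" group. Ties are real in
  small-count data; sending them to the putatively unprotected group is the
  conservative choice for a "more diversity is protective" claim, and the
  rule is configurable.

## Survival

Kaplan–Meier, log-rank and Cox fits delegate to the `survival` package
(`survfit`, `survdiff`, `coxph`), with Efron tie handling — the
least-biased common default when event times tie. The test suite
deliberately re-derives all three from first principles (hand product-limit,
observed-minus-expected log-rank, grid-free partial-likelihood
maximisation) so the package's contract does not depend on the library.
Separation and collinearity are turned into errors naming the offending
term; `run_pipeline()` reports an inestimable Cox fit as a message rather
than aborting, since small-cohort separation is a data property, not a user
error. An optional administrative `horizon` (e.g. 5 × 365 days) censors
long follow-up to mirror 5-year event-free survival analyses.

## Target scanning

The seed is miRNA positions 2–8 (7-mer), the convention of RNA22-class
scanners; a site is any sense-strand UTR window equal to the seed's reverse
complement up to `max_mismatch` mismatches, with G:U wobble counting as a
mismatch *inside* the seed (standard seed stringency) but scoring 0.5 in the
extended-duplex pairing score (Watson–Crick = 1), a crude but monotone proxy
for duplex stability. Matching uses `Biostrings::matchPattern`; the brute
force window scan lives in the tests as the independent oracle.

A pure 3'-extension isoform such as `0|1` has the same seed as its
archetype, so its seed-site list is *identical* — an invariant the package
asserts. Any archetype/isoform difference in site counts must therefore come
from the extended duplex: `compare_site_counts()` reports plain seed counts
and, when `min_score` is given, "effective" counts thresholded on the
pairing score, and flags the seed-identical case explicitly so users can see
which counting reproduces a reported pattern (e.g. 5 isoform vs 4 archetype
sites). The empirical null for scores is built from dinucleotide-preserving
Altschul–Erickson shuffles of the UTR (1000 by default), scored at every
alignment window; p is the upper-tail rank with the +1 correction.

## IHC scores

The proportion ordinal is 0 (0%), 1 (1–25%], 2 (26–50%], 3 (51–75%],
4 (76–100%]; fractional percentages round half-up to integer percent before
binning because the bins are integer-valued. IRS is the plain product
(0–12). The H-score uses the standard Σ intensity × percent definition
(0–300), stated here because published methods sections frequently cite the
score without the formula. Two raters' tables are merged case by case —
ordinals are never averaged; discordant cases are flagged and, by default,
left unresolved (consensus required).

## The synthetic cohort

The generator's defaults describe the study conditions the pipeline targets:
127 tumor and 5 adjacent normal samples, mean depth 8.9 million reads
(coefficient of variation 0.1 — depth variance is a free parameter since no
per-sample figure is published), negative-binomial counts with dispersion
0.2 (typical for bulk count data), about 30% unfavorable histology, 75%
censoring (most pediatric patients remain event-free), and hazard ratios of
2 (low diversity) and 3 (unfavorable histology).

Per-miRNA, per-sample isoform counts are zero-truncated Poisson with the
rate solved numerically so the *mean* equals its target — the simplest
positive count model with a controllable mean, which makes the planted
fold change exact in expectation. Signal miRNAs order their group means
unfavorable < favorable < normal such that both the unfavorable/favorable
and the tumor-average/normal mean ratios equal `diversity_fc` exactly; the
default `diversity_fc = 3` reflects that reported hits of this kind clear
the two-fold selection threshold with margin. (At exactly 2.0 the sampled
fold change straddles the strict threshold and per-miRNA recovery is a coin
flip — the package's tests assert recovery at 2.5 and above for this
reason.) Isoform identities come from a fixed plausibility-ranked offset
pool with 5' offsets concentrated at 0 and 3' offsets dispersed, mirroring
the precision asymmetry of Drosha vs Dicer cleavage; abundance decays
geometrically along the ranks (ratio 0.65), with the `0|1` isoform promoted
to the top rank for signal miRNAs.

Survival times are exponential (Weibull optional) under a proportional
hazards model with baseline fixed at 30% cumulative event probability over
five years. Censoring is independent exponential with its rate calibrated
against the cohort-average hazard so the expected censored fraction equals
`censor_rate`; with covariates the realised fraction deviates by a few
percentage points, which is accepted as the price of keeping censoring
independent.

Planted UTR sites are exact (or single-mismatch) seed complements inserted
at recorded positions into background sequence that is rejection-sampled to
be free of accidental sites for the planted miRNAs, and re-verified after
insertion — so the manifest is exact ground truth for any scanner.

What the generator does *not* emulate: read-level artifacts (adapters,
sequencing error), non-templated additions, multi-mapping, compositional
biases of real UTRs, correlated miRNA expression, and informative
censoring. Passing tests therefore demonstrate the statistical machinery
and its calibration under the stated model, not robustness to those
real-data complications.

## Problem sizes and reproducibility

All randomness flows from one seed per generator call (internal stream
offsets +1 and +2 separate the clinical and sequence modules), and the
caller's RNG state is saved and restored, so identical configs give
byte-identical outputs. The test suite and the acceptance script use desk
scale problems chosen to make their checks well-powered but quick: 60 + 60
samples for end-to-end planted-truth runs, n = 500 with 50 replicates for
Cox recovery (Monte-Carlo SE of the mean log-HR ≈ 0.02, comfortably below
the 10% bias bound), and ~2000 eligible null miRNAs for the type-I error
check (binomial 99% band of ±0.006 around 0.01).

## Interfaces

The package is a library, not a shell tool: the exported functions are the
stable interface, `run_pipeline()` orchestrates them end to end from a
single seeded configuration, and all tables read and write plain
tab-separated text (FASTA for sequences) so the stages can be driven from
any workflow system. Each pipeline run echoes every threshold into its
result object and run log.

## Known limitations

* Diversity is a raw count of present isomiRs; it is not adjusted for
  library depth beyond the global abundance filter, so depth-confounded
  diversity differences are possible in strongly unbalanced designs
  (RPM-based presence is available via `presence_min` on RPM-transformed
  tables, but no TMM/size-factor normalisation is included by design).
* The pairing score is positional complementarity, not a thermodynamic
  model; it ranks duplexes sensibly but its absolute values have no free
  energy interpretation.
* The Cox machinery assumes proportional hazards and a single composite
  event; competing risks and time-dependent covariates are out of scope.
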