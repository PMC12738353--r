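# isomirdiv

Most mature microRNAs are not a single sequence but a population of isoforms
(isomiRs) whose 5' and 3' termini vary by a few nucleotides around the
canonical ("archetype") form, mainly through imprecise Drosha/Dicer cleavage.
In Wilms' tumor (nephroblastoma), the *diversity* of that population — how
many distinct isomiRs of a miRNA a sample expresses — carries prognostic
information: tumors, and especially unfavorable-histology tumors, express
fewer isoforms of certain miRNAs, and patients with higher isoform diversity
have better event-free survival. `isomirdiv` implements the full analysis
pipeline behind that observation for anyone working with isomiR-level small
RNA-seq count tables (e.g. GDC-style isomiR quantification files), plus a
seeded synthetic-data generator so that every stage can be exercised and
validated without access to patient data.

## What the package computes

**Nomenclature.** An isomiR is identified as `<miRNA> <o5>|<o3>`, where the
signed offsets are distances of its termini from the archetype's on the
precursor: `o5 = read_start - archetype_start`, `o3 = read_end -
archetype_end`, positive downstream. `miR-455-5p 0|0` is the archetype;
`miR-455-5p 0|1` carries one templated extra 3' base.

**Diversity statistics.** After an abundance filter (keep isomiRs with
> 100 reads in at least one sample, about 12 RPM at typical depth), the
per-miRNA, per-sample count of distinct isomiRs forms a diversity matrix
D(m, s). miRNAs are tabulated into pooled categories (1, 2–9, ≥ 10 distinct
isoforms per tissue; compared by Pearson chi-square), restricted to those
with median diversity ≥ 3, and tested for group differences by Welch's
t-test with a two-sided fold-change band (FC > 2 or < 0.5). Candidates from
the tumor/normal and unfavorable/favorable comparisons are intersected.

**Survival.** Samples are split at the median of any marker (diversity or
expression) into more/less (or high/low) groups; groups are compared by
Kaplan–Meier curves and the log-rank test, and hazard ratios come from Cox
proportional-hazards models (Efron ties), univariate or adjusted for tumor
histology.

**Target scanning.** 3'UTRs are scanned for reverse complements of the
miRNA seed (positions 2–8) with up to one mismatch (G:U wobble counts as a
mismatch in the seed). Each hit gets an extended-duplex pairing score
(Watson–Crick +1, wobble +0.5) over the full antiparallel miRNA:UTR duplex,
so a pure 3'-extension isoform — whose seed sites are provably identical to
the archetype's — can still gain "effective" sites through 3'-supplementary
pairing. An empirical null from dinucleotide-preserving (Altschul–Erickson)
UTR shuffles converts scores to p-values.

**IHC quantification.** Immunoreactivity score (intensity 0–3 × proportion
category 0–4, range 0–12) and H-score (Σ intensity × percent, range 0–300),
with two-rater merging and one-way ANOVA / t-test group comparisons.

## Worked example

```r
library(isomirdiv)

# the published 2x3 isoform-category table: tumor vs normal tissue
category_chisq(c("1" = 195, "2-9" = 1742, ">=10" = 53),
               c("1" = 287, "2-9" = 842, ">=10" = 2))
#> $statistic    153.5239
#> $df           2
#> $p_value      4.5995e-34        (reported as P < 0.001)

# the 0|1 isoform of miR-455-5p from the shipped fixture
fx <- mir455_fixture()
isomir_sequence(fx$precursor, fx$annotation, isomir_id("miR-455-5p", 0, 1))
#> "UAUGUGCCUUUGGACUACAUCGU"   # = probe TATGTGCCTTTGGACTACATCGT in DNA letters

# a full synthetic run with two planted signal miRNAs
cfg <- sim_config(n_tumor = 60, n_normal = 60, n_mirnas = 60, n_signal = 2,
                  seed = 37)
run_pipeline(sim = cfg, scan = TRUE)
#> isomiR diversity pipeline run
#>   input: 462 isomiRs, 450 after abundance filter (> 100 reads in >= 1 sample(s))
#>   pooled categories (tumor):  1: 0, 2-9: 50, >=10: 10 of 60 miRNAs
#>   pooled categories (normal): 1: 0, 2-9: 50, >=10: 10 of 60 miRNAs
#>   category chi-square p = NA
#>   eligible miRNAs (median >= 3): 24
#>   candidates tumor/normal: 2; unfavorable/favorable: 2; shared: miR-sim-001-5p, miR-sim-002-5p
#>   survival (marker miR-sim-001-5p): log-rank p = 0.121; univariate HR(less) = 2.70
```

The two planted miRNAs are exactly the candidate intersection. The category
chi-square is `NA` here because this small simulated cohort has empty
single-isoform cells (the function refuses a chi-square with zero expected
counts); at realistic cohort scale the category test is well defined. The
survival stage stratifies tumors by the leading candidate's diversity; with
60 tumors the planted hazard ratio of 2 is detectable but not always
significant, which is the honest behaviour at that sample size.

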