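---
title: "Methods: hotspot screening, consensus filtering and clinical statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hotspot screening, consensus filtering and clinical statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jakscreen)
```

## The problem

Targeted amplicon deep sequencing of kinase hotspot exons (here the four
JAK2 hotspot exons 16, 20, 21 and 23 screened in childhood B-cell
precursor ALL) can detect subclonal point mutations down to a few percent
variant allele frequency (VAF), but only behind an aggressive filtering
wall: amplicon data are rife with caller-specific artifacts, PCR errors,
run-restricted batch effects, germline polymorphisms and poorly covered
positions. `jakscreen` packages the complete analysis path — multi-caller
VCF ingestion, variant normalization, consensus merging, a ten-rule
cohort-level filter cascade, detection-limit accounting, and the
downstream clinical statistics — together with a synthetic-cohort
generator, so the entire pipeline is testable end to end without any
patient-level data.

## Variant identity and merging

All operations join on a normalized variant key (chromosome, 1-based
position, REF, ALT): alleles are trimmed to minimal representation and
indels are left-aligned against the packaged reference, so two callers
reporting the same deletion at the two ends of a repeat compare equal.
Tests verify sequence-equivalence of normalization with a
haplotype-substitution oracle.

Four caller dialects are supported, emulating the tag conventions of
common tools: FORMAT `DP`/`AO` (freebayes-like, per-alt counts), FORMAT
`DP`/scalar `AD` (varscan-like), INFO `DP4` (bcftools-like, strand-split
counts, not per-allele), and FORMAT `AD` = ref,alt with `DP` (GATK-like).
Per sample, calls are grouped by key; the consensus depth and alt count
are the **medians** across reporting callers (even counts: mean of the
central pair, rounded half up), and VAF is their ratio. Median-of-callers
was chosen (the source study does not state its aggregation) because it
is robust to one caller's miscount and symmetric in the callers; the VAF
is a single consistent ratio rather than a mean of per-caller VAFs, so
every downstream threshold acts on one number.

## The filter cascade

Ten rules, all evaluated for every occurrence (no short-circuiting, so
the audit trail attributes every exclusion):

| rule | fails when | boundary |
|------|------------|----------|
| REGION | variant outside the targeted BED regions | 1-based pos in 0-based half-open [start, end) |
| MULTICALLER | reported by only one caller | 2 callers pass |
| DEPTH | aggregated coverage < 100 reads | 100 passes |
| ALTREADS | < 10 reads support the allele | 10 passes |
| VAFPRESENCE | no sample carries the key at VAF > 2% | 2.0% exactly fails |
| RUNBALANCE | carriers unequally distributed over runs (Pearson chi-square vs run sizes, df = runs−1, p < 0.05) | single run or < 2 carriers: not evaluated |
| COSMIC | key absent from the hotspot whitelist | exact normalized match |
| AACHANGE | effect is synonymous or noncoding | frameshift/in-frame indels count as changing |
| SNP | mean of the three population AFs ≥ 5% | 5% exactly fails |
| GERMLINE | ≥ 10 carriers with mean **and** median VAF > 40% | 40% exactly passes, 10 carriers flag |

Boundary semantics are fixed exactly as printed in the source criteria
(`< 100`, `< 10`, "above 2%" strict, "≥ 5%" inclusive, "> 40%" strict)
and pinned by a dedicated boundary test suite. The SNP rule averages the
three databases (most literal reading of "mean population frequency
across"); requiring each database individually to reach 5% is available
as `snp_rule = "each"`. The germline heuristic is implemented exactly as
the two stated rules (population-frequency table plus the cohort
mean/median signature) and nothing more, because no further criterion is
stated. The run-balance test compares carrier counts (not read-level
support — unstated in the source; carrier counts chosen and documented).
A brute-force re-evaluation of all ten predicates serves as the oracle
for the cascade on hundreds of random small cohorts.

## Detection limits

The deterministic rule ties detectability to the cascade's own
thresholds: a VAF v at depth d is detectable iff d ≥ 100 and v·d ≥ 10
expected alt reads. At the deepest exon's median of 944 reads, a 1%
variant expects 9.44 alt reads — under the pipeline's own rules it cannot
be called, which is exactly why 1% detection was described as limited in
the source study. Alongside, `detection_probability()` gives the exact
binomial tail P(X ≥ 10), X ~ Bin(d, v), with no normal approximation;
a grid test checks monotonicity in both arguments and that the
deterministic rule is the large-depth 0.5-probability boundary.

## Clinical statistics

**CRLF2 classification.** "High" is strictly above the cohort's 90th
percentile of probe intensity, computed with the type-7
linear-interpolation quantile (configurable); on values 1..10 the
threshold is 9.1 and only 10 is high.

**Relative expression** is the comparative-Ct method,
2^−(Ct_target − Ct_reference) × 100%.

**Fisher's exact test** (two-sided) uses the probability-ordering
definition: sum the hypergeometric probabilities of all margin-fixed
tables no more probable than the observed one (relative tie tolerance
1e−7). The 4/0/0/5 high-vs-low-MRD table gives p = 1/126 ≈ 0.0079 ≈
0.008. An enumeration oracle over all tables with margins ≤ 12 pins the
implementation.

**Cumulative incidence** under competing risks uses the Aalen–Johansen
estimator: at each event time, cause k's incidence jumps by
S(t−)·d_k(t)/n(t) with S the all-cause Kaplan–Meier survivor; tied event
types share one risk set, censoring at a tied time is removed after the
events. Non-response is encoded as an event of type 1 at day 79
(79/365.25 years — the day-to-year convention is ours; the source does
not state one). With no competing events the estimator reduces to
1 − KM exactly (tested to 1e−12), and ΣCIF + S = 1 everywhere.

**Gray's K-sample test** (ρ = 0) compares cause-1 subdistribution
hazards. The score compares each group's events at every cause-1 event
time with its share of the weighted risk set
R_g(t) = Y_g(t)·(1 − F₁g(t−))/S_g(t−), which keeps prior competing-event
subjects at risk. Because those weights are estimated, the variance must
carry correction terms: we derive them by the counting-process delta
method — the influence of group g's cause-1 and cause-2 martingales on
log w_g(t) has coefficients F₂g(u−)/[(1−F₁g(t−))Y_g(u)] and
(1−F₁g(u−))/[(1−F₁g(t−))Y_g(u)] — and plug in the pooled subdistribution
hazard under the null. During development the statistic was checked
against the reference implementation in the `cmprsk` package: relative
agreement ~3% at n = 80 shrinking to ~1% at n = 3200, i.e. the two
variance estimators are asymptotically identical but not bit-identical
in finite samples (`cmprsk` is not a dependency; it is absent from the
test environment). The packaged validation is therefore behavioural: an
exhaustive permutation oracle on ≤ 8 subjects (asymptotic and
permutation p within 0.25 and agreeing at the 0.05 level — chi-square
asymptotics are crude at n = 8, hence the wide band), exact symmetry and
degeneracy properties, and an empirical type-I error of 0.048–0.06 over
500 seeded null simulations against the acceptance band [0.03, 0.08].

## Drug-response normalization

Viability is 100 × signal / mean(vehicle wells), uncapped by default
(ratios above 100% retain information; capping is an option). Group
summaries collapse technical replicates within sample before computing
the group mean and SEM over sample-level means, so biological n is the
number of samples. Group comparisons use the two-sided independent-sample
t-test, pooled-variance by default (the source says only "independent
sample T-test"; Welch is a switch).

## The synthetic cohort: what it emulates and what it does not

The generator's defaults state the emulated world: 461 samples in the
seven major cytogenetic subtypes at the study's exact proportions
(79/67/124/15/26/124/26), four sequencing runs (116/115/115/115 — run
structure is unstated in the source and configurable), per-exon depths
negative-binomial with medians 673/577/711/944, 16 somatic hotspot
carriers (11 R683G, 2 R683T, 1 R867Q, 2 R923H; VAF uniform on 1–56%)
restricted to the three subtypes that carry mutations, one common
germline SNP (carrier rate 0.35, VAF ~ Beta(200,200), i.e. tightly
heterozygous), and one artifact confined to run 1. Callers miss variants
with probability logistic in log-VAF around a per-caller v50 (1–2.5%),
inject false positives per region, and jitter depth and alt counts; alt
reads are binomial draws at the true VAF from the sample's exon depth.
One master seed is split hierarchically per sample/caller/stage, so
output is bit-identical across runs and independent of iteration order.

Numerical choices made once, a priori: depth dispersion (NB size) 3,
giving a depth CV ≈ 0.6 as is typical of equimolar amplicon pools — the
source anchors only the medians. Under this world ~95% of sample-exon
pairs can detect 5% VAF and ~28% can detect 1%, near but not equal to
the study's printed 91%/26%; the gap simply reflects that the real depth
distribution is unknown, and we do not tune the dispersion to match.

What a green test establishes: the cascade recovers exactly the planted
somatic variants and attributes the plants' exclusions to the right
rules, on data with the configured statistical structure. What it does
not establish: performance on real chemistry (UMI/PCR error profiles,
alignment artifacts, strand bias — none are modelled; simulation starts
at caller output counts), nor the study's patient-level results, which
depend on unreleased data.

The clinical generator links relapse hazard to high MRD (rates 0.45 vs
0.05 per year, death 0.03, administrative censoring at 3–10 years, 2%
non-responders at day 79, 30% missing MRD), which reproduces the
qualitative MRD–relapse association; the expression generator makes
CRLF2-high status likely (87.5%) in mutated samples; the assay generator
gives mutated samples a sigmoid dose response (IC50 0.3 µM, floor 20%)
and wildtype a shallow one (floor 85%). These are stated-world constants,
not estimates.

## Degenerate inputs and tie-breaks

Single run or fewer than two carriers: run-balance is `not_evaluated`
and passes (cannot assess). Zero aggregated depth: VAF 0. Records with
unextractable counts: kept, flagged, depth 0 (so they fail DEPTH rather
than vanish). Even-caller medians round half up to stay integral. All
CRLF2 intensities equal: everything is "low" (nothing strictly above the
percentile). Fisher on an all-zero table: error; degenerate margins give
p = 1.

## Known limitations

- Gray's test variance is asymptotically, not exactly, the classical
  estimator; small-sample p-values can differ by a few percent relative.
- Multi-allelic DP4 records cannot attribute strand-split counts per
  allele; the total alt support is assigned to each split allele.
- Effect annotation handles substitutions and indel frame logic within
  single exons of the packaged model; splice-site prediction and
  cross-exon substitutions are out of scope.
- Viability SEM is undefined (reported NA) for single-sample
  concentrations.
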