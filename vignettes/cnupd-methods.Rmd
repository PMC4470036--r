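---
title: "Allele-specific copy number, LOH and UPD analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific copy number, LOH and UPD analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnupd)
```

## The measurement model

High-density SNP arrays report two quantities per probe: the **LogR ratio**,
log2 of the sample's total intensity over a reference pool's mean intensity,
which is ~0 at two copies and log2(c/2) at c copies; and the **B-allele
frequency (BAF)**, the fraction of signal attributable to the B allele,
which sits near 0, 0.5 or 1 for diploid AA/AB/BB genotypes and at b/c for a
locus carrying b of c copies. Together they resolve states that total copy
number alone cannot: a region with LogR ~0 but no heterozygous BAF is
**copy-neutral LOH (uniparental disomy, UPD)** — both homologs from one
parent; a region with collapsed LogR and *noise* BAF (no allele present) is
a **homozygous deletion (HD)**; collapsed LogR with railed BAF is hemizygous
loss with LOH.

cnupd implements this reasoning as a pipeline aimed at near-pure tumor
samples such as cancer cell lines, where discrete copy levels are separable
because there is no stromal dilution. The package was built around a
bladder-cancer cell line panel study design; a transcribed curated
mutation/copy-status table for 49 such lines ships as a fixture
(`load_table1_fixture()`), preserving conflicting multi-source reports
verbatim so that counting policies (`any_source` vs `own_data_precedence`)
remain explicit choices of the analysis, not of the data container.

## Normalization and genotype calling

The reference-pool normalization is deliberately simple: multiplicative
median scaling so a sample's median autosomal intensity equals the pool's
(`normalize_R()`), then `logR = log2(R / mean_R)` per probe. Downstream
stages depend only on LogR being centered at 0 for two copies; any
finer-grained intensity normalization can be applied upstream. Genotypes are
called from BAF with two windows (`call_genotypes()`): homozygous rails at
`hom_window = 0.05`, a heterozygous band of half-width `het_window = 0.15`,
`NC` (no call) between. Sex is inferred from Y-probe dosage: mean Y LogR
against the mixed-sex pool above `-1` (one Y copy lands near 0 on that
scale, zero copies near -3) calls a male; Y evidence overrides declared
metadata because residual Y signal is the more reliable indicator. X
chromosome LogR is then computed against the sex-matched pool.

## Segmentation and categorical calls

`segment_logR()` is a circular-binary-segmentation variant: each segment is
scanned for the contiguous arc (including prefixes/suffixes, i.e. plain
splits) maximizing

$$U(i, d) = \frac{\left| \sum_{j=i+1}^{i+d} x_j - \tfrac{d}{m}\sum_j x_j \right|}
{\sqrt{d(m-d)/m}},$$

the likelihood-ratio statistic for a mean shift on the arc with variance
held global. Significance is assessed by permutation (default 1000
permutations, `alpha = 0.01`): permuting the segment makes the test exact
without any distributional assumption on the noise. Acceptance cuts the
segment at the arc ends and recurses. Three numerical choices matter:

* **Arc grid.** Arc lengths are scanned exhaustively up to 50 probes and on
  a 10% geometric grid beyond, which bounds the scan at O(m log m) per
  evaluation while locating any arc within a few percent of its true
  length; the accepted arc is then refined by an exact local re-scan, and
  the recursion sharpens boundaries further. The scan kernel is compiled
  (Rcpp), as is usual for segmentation codes.
* **Early stopping.** The permutation loop aborts once enough exceedances
  have accumulated that p < alpha is impossible, so null split tests cost a
  small fraction of significant ones.
* **Minimum segment size.** Cuts closer than `min_probes = 5` to a segment
  edge are discarded and undersized segments are merged into the
  neighbor with the closer mean (ties to the left, for determinism).

Calls are assigned by thresholds on segment mean LogR rather than a mixture
model: loss at or below -0.3, gain at or above +0.3, amplification at or
above log2(5/2) ≈ 1.32 — the LogR of five copies, the conventional
amplification definition for this assay; no ploidy correction is applied.
The ±0.3 defaults are conventional for near-pure samples, where one-copy
changes shift LogR by ±0.58/±1; all thresholds are config-exposed
(`run_config()`). Each altered segment is scoped as whole-chromosome,
whole-arm (≥ 90% of an arm's probes, by default) or focal.

## Allelic states and UPD

Probe-level allelic states (`call_allelic_state()`) quantify the published
decision rule: LOH requires a homozygous call, BAF within 0.05 of a rail,
and a *decline* in segment LogR — quantified as mean LogR ≤ -0.1, since the
source rule names the decline but not its size; HD requires an NC call, BAF
farther than 0.1 from each of {0, 0.5, 1} (the no-allele signal is uniform
noise), and segment LogR ≤ -1. Both cutoffs are parameters.

UPD detection (`detect_upd()`) looks for maximal runs of informative probes
without heterozygous calls whose LogR is compatible with ≥ 2 copies (every
rolling 50-probe mean at or above -0.15; amplified UPD sits above the band,
hemizygous deletions fall below and are excluded). Isolated heterozygous
calls are absorbed as genotyping error only when flanked on both sides by
at least half a window of homozygous probes and while the run's
heterozygous fraction stays ≤ 0.02. Runs must span ≥ 2 Mb **and** ≥ 50
probes. The probe guard is what controls the false-positive rate: with
heterozygous fraction h = 0.3, a chance homozygous run of k probes has
probability 0.7^k per position, so k = 50 pushes the expected genome-wide
false count below 10^-3 even for a 20-sample cohort, whereas a 2 Mb bp
threshold alone would admit hundreds of chance runs on a sparse probe grid.
The flip side is honest too: on a sparse grid (the packaged 20,000-probe
default spans ~2.9 Gb, ~145 kb per probe) a 2 Mb event covers ~14 probes
and is *undetectable by design*; resolving few-Mb UPD requires probe
spacing in the tens of kb, which is why the recovery tests run on a denser
desk-scale annotation (~31 kb spacing) emulating the density regime of a
million-probe array.

Detected events are classified into six categories (`classify_upd()`):
whole chromosome (1), whole arm (2), focal (3), focal with segmental
duplication (4, overlapping a +1 segment), with segmental amplification (5,
overlapping +2), and near-whole chromosome with a combined focal deletion
(6, run covering ≥ 80% of the chromosome on a chromosome carrying a focal
loss). Two interpretation choices are documented rather than inherited: the
+1 → category 4 / +2 → category 5 mapping, and evaluation order — the
near-whole-plus-deletion signature is tested before the single-arm rule,
because a 90% run whose remainder is deleted is the combined-deletion
pattern, not an arm event.

## Recurrence: minimal common regions

`mcr_permutation_test()` asks which probes are altered across samples more
often than random placement explains. Each permutation relocates every
sample's altered segments (probe lengths preserved) uniformly — genome-wide
by default, per-chromosome as an option — rejecting within-sample overlaps.
Per-probe p-values are computed against the **pooled** null: the frequency
distribution aggregated over permutations *and* probes, exchangeable under
uniform relocation. Pooling is the package's key resolution choice: a
per-probe exceedance p-value has floor 1/(n_perm + 1), and after FDR
correction across tens of thousands of probes no probe could ever reach
significance at practical permutation counts; the pooled null has
resolution 1/(n_perm × n_probes), so a 500-permutation run resolves
adjusted p-values far below 0.05. The per-probe formula remains available
(`p_method = "per_probe"`). Benjamini-Hochberg adjustment is applied across
all probes of a direction, and maximal runs of consecutive significant
probes become MCRs. A +1 pseudo-count keeps p-values off zero, standard
permutation practice.

Amplification recurrence (`recurrent_amplifications()`) is simpler: maximal
probe runs carrying a +2 call in at least 3 samples. The arm/chromosome
alteration table counts whole-chromosome events exclusively — never
double-counted as two arm events.

## Instability, statistics, expression

Per-sample instability is measured three ways (Mb altered from segment
extents; fraction of probes altered; altered-segment count) and summarized
by cohort tertiles cut at the empirical 1/3 and 2/3 quantiles (type-1, so
cuts land on observed values; boundary ties go low, deterministically).
Associations use the Wilcoxon **rank-sum** test (the two-group form matches
mutant-vs-wild-type comparisons of independent lines): exact when combined
n ≤ 20 without ties, normal approximation with continuity correction
otherwise; fully tied data returns p = 1. Frequency comparisons use the 2×2
chi-square without continuity correction by default (a Yates flag exists);
degenerate margins return statistic 0 with a warning. Both delegate to the
standard R tests; the package's own test suite checks them against full
rank enumeration and the textbook formula.

Expression integration collapses probe-level matrices to genes by maximum,
classifies samples by Pearson correlation to class centroids over the
shared-gene intersection (≥ 10 genes enforced; ties reported, never
silently broken), and orders samples by complete-linkage hierarchical
clustering of their correlation vectors (Euclidean distance; linkage and
distance are documented defaults, config-switchable, since the upstream
tooling never specified them). Copy-number/expression comparisons report a
linear-scale fold change and the rank-sum p-value.

## The synthetic-data generator

`simulate_sample()` emulates Illumina-style allele-specific signals: for a
probe at c copies with b B-alleles, LogR is log2(c/2) + N(0, 0.15) and BAF
is b/c plus noise, clipped to [0, 1]; c = 0 draws LogR around -3 (arrays
saturate, they do not reach -infinity) and uniform BAF. Germline genotypes
are drawn with heterozygous fraction 0.3; 0.5% of probes drop out. BAF
noise is 0.03 at balanced heterozygotes and half that on the homozygous
rails — on real arrays the allele-ratio transform compresses noise near 0
and 1, and this is also what keeps the genotype caller's no-call rate below
1% at the default windows. Events are encoded as (total, minor-allele)
copy pairs, which spans the whole vocabulary: (2,1) normal, (2,0) UPD,
(1,0) hemizygous loss, (0,0) HD, (6,1) amplification. Cohorts plant a
shared event in round(penetrance × n) samples and add Poisson background
events sized log-uniformly between 1 Mb and a chromosome arm.

What the generator does **not** emulate: GC waves and batch structure in
LogR, BAF asymmetry/compression differences between platforms, subclonal
mixtures, and linkage between neighboring probes' genotypes. Passing
recovery tests therefore demonstrate algorithmic correctness under the
stated signal model, not robustness to every artifact of production array
data.

## Problem sizes used by tests and the acceptance script

All checks are desk-scale by choice: segmentation recovery uses 400-probe
step series over 50 seeds; call correctness uses a 4,000-probe two-
chromosome genome at near-zero noise; UPD recovery plants 60 events
(2-50 Mb; categories 1-3) across 20 samples on a 13,000-probe four-
chromosome annotation (~31 kb spacing) plus a 20-sample diploid null; MCR
calibration and power use 10 replicate 20-sample cohorts each (10,000-probe
genome, 2 background events/sample, 500 relocation permutations, cohort
segmentation at 200 permutations per split — the minimum attainable p,
1/201, still resolves alpha = 0.01); the classifier runs 200 samples
against 4 random centroids at noise 25% of centroid spread. The curated-
table counts are computed from the packaged fixture directly.

## Known limitations

* Threshold calling presumes near-pure samples; contaminated or polyploid
  genomes shift LogR levels off the log2(c/2) grid and need re-tuned
  thresholds.
* UPD resolution is bounded by probe density and heterozygosity, as
  quantified above; events below ~50 informative probes are invisible.
* The relocation null treats the concatenated probe grid as homogeneous;
  genome-wide relocation can move segments across chromosome ends (the
  per-chromosome mode avoids this at some power cost for large events).
* Sex inference requires Y probes; without them the declared metadata is
  trusted, and without either the X chromosome is skipped.
* The curated fixture transcribes a published table whose print form is
  imperfect (a handful of cells lack source tags); those entries carry an
  explicit "unspecified" source rather than a guess.
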