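---
title: "Methods: antibody performance metrics for paired-end ChIP-seq"
author: "chipab authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: antibody performance metrics for paired-end ChIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipab)
```

## The problem

Two ChIP-seq libraries made with different antibodies against the same
histone modification cannot be compared naively. Two technical artefacts
confound any comparison:

1. **Depth.** More read pairs mean more power to call peaks, so the deeper
   library looks "better" regardless of antibody quality.
2. **Shearing bias.** Chromatin shears into shorter fragments in open
   chromatin than in closed chromatin. Combined with library size
   selection, this couples the fragment-length distribution of a library
   to the *regional* allocation of its reads: a library with more short
   inserts places proportionally more reads at transcription start sites,
   mimicking signal.

`chipab` addresses both. It normalizes paired-end alignment sets so that
every member of a comparison group has the same depth *and* the same
insert-size distribution, and it provides the downstream metrics on which
antibody comparisons rest: peak-base saturation, base-level
sensitivity/specificity against a reference genome segmentation, SPOT
scores, region-level enrichment over a whole-cell-extract (WCE) control,
binned genome-wide correlation, and replicate-level quality control.

All coordinates in the package are 0-based and half-open (the BED
convention). The unit of counting everywhere is the *fragment*: one
sequenced read pair, represented by the interval from the leftmost mate's
start over the absolute template length. The insert size of a fragment is
its interval length.

## Insert-size-matched normalization

Given a group of libraries to be compared, the algorithm is:

1. count read pairs per insert size in each library
   (`insert_histogram()`);
2. for each insert size present in **all** libraries, take the minimum
   count across the group (`groupwise_insert_target()`); sizes missing
   from any one library are dropped;
3. sample each library, uniformly without replacement within each
   insert-size stratum, down to that common histogram
   (`downsample_to_histogram()`).

After step 3 every library in the group has an identical insert-size
histogram — the elementwise minimum — which is also the deepest common
histogram achievable. We implement the per-stratum quota as *exactly* the
minimum rather than an approximate binomial thinning: exactness makes the
contract testable (`normalize_group()` output histograms are asserted
identical, not merely close) and is strictly stronger than approximate
matching. Strata are processed in ascending insert-size order under a
seeded generator, so results are reproducible across platforms.

WCE controls are deliberately *not* insert-normalized: they serve as the
fixed background that everything else is measured against.

Grouping is the caller's responsibility: libraries should be normalized
as a group only when they are meant to be compared (e.g. all replicates
of both antibodies against one modification).

## The shearing-bias diagnostic

`fragment_bias()` quantifies the coupling between insert size and
regional read allocation, typically on a WCE library:

* fragments are binned by insert size into half-open 50-bp bins spanning
  70–700 bp by default — the insert range a standard Illumina flow cell
  retains; the named 50-bp endpoints of that window motivate the bin
  width, and all three are configurable;
* within each bin, each fragment is assigned to exactly one segmentation
  label by its **midpoint**, with an explicit `unannotated` bucket, so the
  per-bin fractions partition to 1 (midpoint assignment avoids the double
  counting that any-overlap assignment would introduce);
* per focal label, the per-bin fraction is regressed on the bin midpoint
  by ordinary least squares, reporting the slope sign, the coefficient of
  determination, and the first-bin/last-bin fold change.

In a library with shearing bias the TSS fraction falls with insert size
(negative slope, fold change above 1) while the repressed-region fraction
rises. The R² of a zero-variance response is defined as 0 rather than
NaN, and a zero last-bin fraction yields an infinite fold change rather
than an error.

## Peak-level metrics

`call_peaks_simple()` is intentionally minimal plumbing: it tiles the
genome in fixed windows, counts fragment midpoints in sample and control,
scales the control by the depth ratio, and keeps windows with
`count >= min_count` and `count / (1 + scaled control) >= fold_threshold`,
merging adjacent positive windows. It exists so that the peak-dependent
statistics can be exercised end-to-end on simulated data; it is not a
model-based caller, applies no FDR control, and should not ground claims
about real data — real peak sets (e.g. HOMER output) enter as BED3 via
`read_peaks()`.

On top of a peak set:

* `saturation_curve()` downsamples to a ladder of depths (depth *i* uses
  seed `seed + i`), calls peaks at each, and records total peak bases; a
  plateau means further sequencing would not enlarge the called
  territory.
* `sensitivity_specificity()` works at single-base resolution against
  the seven-label segmentation, **restricted to annotated bases**:
  sensitivity is the fraction of expected-label bases inside peaks;
  specificity is the fraction of annotated peak bases carrying the
  expected label. Both are invariant to how peak intervals are split.
* `peak_base_overlap()` partitions the union of two peak sets into
  only-A / only-B / both at base level.
* `spot_score()` is the fraction of fragments overlapping any peak base
  by at least 1 bp. We use any-overlap rather than midpoint here because
  that is the established SPOT/FRiP convention.

Whether "reads" means single ends or pairs is a recurring ambiguity in
QC metrics; this package standardizes on fragments (pairs) throughout,
including SPOT denominators.

## Coverage and region statistics

`binned_counts()` tiles chromosomes in 2000-bp bins by default, keeping
partial terminal bins (dropping them would bias short chromosomes), and
assigns fragments by midpoint. `loglog_correlation()` is the Pearson
correlation of `log(count + 1)` between two samples over identical bins —
the statistic summarized by genome-wide log-log scatter plots; the
pseudocount handles empty bins and the statistic is invariant to depth
rescaling.

`region_allocation()` tallies fragments per segmentation label (again by
midpoint, with the unannotated bucket reported explicitly, so both
"fraction of all reads" and "fraction of annotated reads" can be
recovered). `enrichment_over_wce()` divides a sample's per-label read
fractions by the WCE's — the "enrichment over input" column of standard
antibody comparisons. `region_scatter_stats()` counts fragments per
annotated interval in two samples and summarizes each label by the
least-squares slope through the origin and squared Pearson correlation;
an antibody that pulls down relatively more enhancer than TSS chromatin
shows an enhancer slope well above its TSS slope.

## Replicate quality control

`flag_outlier_replicates()` operationalizes the observation that a bad
replicate betrays itself through its regional read allocation. For each
replicate and label it computes the leave-one-out mean and standard
deviation of the other replicates' fractions and flags when the
deviation exceeds `k * sd` **and** an absolute floor `min_abs`
(defaults 3 and 0.02). The floor is essential with 3–4 replicates:
automated protocols produce such tight groups that a pure z-rule would
flag meaningless differences. No multiple-testing correction is applied
across labels; the rule is a screen, not a test. `group_compare()` is a
two-sided Welch t test (the safer default when variances may differ
between antibody groups), with a documented convention for degenerate
zero-variance inputs: equal constant groups give p = 1, separated
constant groups give p = 0.

## The synthetic-data generator

`sim_config()` + `simulate_experiment()` generate data with exactly the
structure the analyses assume, so the whole pipeline is testable without
external data:

* **Genome.** Alternating labelled segments; types drawn with probability
  proportional to `proportion / mean segment length` (so realized base
  fractions converge to the requested proportions) and exponential
  lengths. Default composition: R 0.84, T 0.08, E 0.03, WE 0.02,
  PF 0.015, TSS 0.01, CTCF 0.005 — a repressed-dominated genome with ~1%
  TSS, matching combined ChromHMM/Segway segmentations of differentiated
  human cell lines. The non-R, non-TSS split is plausible rather than
  load-bearing, and configurable.
* **Fragments.** A fragment picks a label (probability ∝ base fraction ×
  enrichment weight; all weights 1 in WCE mode), an interval of that
  label (probability ∝ length), a uniform start within it, and a length
  from the label's truncated log-normal. Defaults place the TSS location
  (meanlog 5.1) half a log-unit below repressed regions (5.6), giving the
  monotone open-vs-closed shearing trend; the 70–700 bp truncation
  mirrors the flow-cell window. Real fragment-length distributions per
  region are not published quantitatively, so only the direction and
  rough magnitude of the bias are modelled.
* **Enrichment.** The default ChIP weight vector (TSS 20, PF 4, E 2,
  others 1) emulates a sharp TSS-centred mark like H3K4me3.
* **Replicates.** Per-replicate, per-label weights are jittered by a
  gamma variate with mean 1 and variance `(replicate_noise − 1)/10` —
  the simplest overdispersion mechanism; the default `replicate_noise = 1`
  reproduces pure resampling noise, appropriate for tightly automated
  technical replicates.
* **Antibody shift.** `antibody_shift` multiplies the weights of chosen
  labels, emulating an immunogen-dependent region preference (e.g.
  `c(E = 2)` for an antibody with stronger enhancer pull-down).

What the generator does **not** model: sequence content, mappability, GC
bias, duplicated reads, strand structure, or inter-chromosomal
differences. Tests passing on simulated data therefore demonstrate the
correctness of the *computations* and the recoverability of the modelled
effects — not robustness to every artefact of real libraries.

## Numerical choices and degenerate inputs

* Fragments that would overhang a chromosome end are shifted left, never
  truncated, so simulated insert sizes are exactly the drawn lengths.
* `downsample_to_histogram()` errors, naming the insert size, if a target
  exceeds availability; it never silently truncates.
* Empty samples: an empty sample yields an empty peak set (not an error),
  but SPOT and region allocation on empty/ungrounded subsets are analysis
  errors because their ratios are undefined.
* Records on chromosomes missing from `chrom_sizes` are a hard error, not
  a silent drop — silent drops would corrupt SPOT denominators.
* Annotation overlap validation names the offending interval pair.

## Problem sizes used in the shipped checks

The package's end-to-end checks simulate at sizes chosen so each effect
is comfortably detectable while the whole suite stays quick on a laptop:
bias-sign recovery uses 20 seeds of 10^6 fragments on the default 10^7 bp
genome; the no-bias control uses 10^7 fragments so the Monte Carlo error
of the TSS first/last-bin fold (~4%) is small against its ±10% acceptance
band; saturation uses 2×10^5 fragments with 20-fold TSS enrichment over
1% of a 10^7 bp genome, with caller settings (500-bp windows, fold ≥ 3,
min count 20) that make detection depth-limited across the ladder rather
than instantaneous; replicate-correlation and antibody-shift checks use
10^6 fragments; QC recovery uses 100 seeds of 4×3×10^4 fragments; the
Welch size check uses 10^4 simulated null comparisons.

## Known limitations

* The simple caller's windowed fold rule has no statistical calibration;
  its peaks are fixtures, not discoveries.
* Midpoint assignment differs from the any-overlap counting used by some
  coverage tools; for intervals much longer than fragments the
  difference is negligible, but single-fragment-scale intervals can
  differ by one count.
* The leave-one-out QC rule assumes at least three replicates and a
  single outlier; two simultaneous outliers in a group of four can mask
  each other.
* Insert-size matching equalizes distributions *within* a comparison
  group only; nothing is claimed across groups normalized separately.
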