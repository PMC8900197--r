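---
title: "Copy-number screening of embryo liquid biopsies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number screening of embryo liquid biopsies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicscreen)
```

## The problem

Non-invasive pre-implantation genetic testing for aneuploidies (niPGT-A)
infers an embryo's chromosome constitution from cell-free DNA shed into
the spent culture medium (SCM) or aspirated with the blastocoel fluid
(BF), instead of biopsying cells. After whole-genome amplification and
shallow sequencing (~2 million reads), reads are counted in 1 Mb genome
bins, normalized, segmented, and converted into per-chromosome
copy-number calls; calls are then scored against a gold-standard
reference (inner cell mass or whole-blastocyst biopsy) with the standard
diagnostic statistics. `nicscreen` implements that entire analysis,
together with a read-count simulator that provides ground truth for
validating it.

## The dosage model

Everything rests on linearity of coverage in copy number: a bin present
at $c$ copies contributes expected reads proportional to $c/2$. A gain
from two to three copies raises expected counts by 50%, a loss to one
copy lowers them by 50%. A mosaic event carried by a cell fraction $m$
has effective copy number $2 + m\,(c - 2)$, so a single-copy mosaic
gain/loss shifts the copy ratio to $r = 1 \pm m/2$, and conversely
$m = 2\,|r - 1|$ (`mosaic_fraction()`). This inversion is exact only
under the linear model; uniform whole-genome scaling (triploidy,
haploidy) is invisible to ratio-based methods and is out of scope.

## The simulator

`simulate_sample()` draws counts by gamma–multinomial sampling: the
expected bin weight

$$w_b \propto \Big[(1-c)\,\tfrac{\mathrm{cn}_{\mathrm{embryo}}(b)}{2} +
  c\,\tfrac{\mathrm{cn}_{XX}(b)}{2}\Big]\cdot
  e^{\beta\,(\mathrm{gc}_b - 0.41)}\cdot \mathrm{usable}_b$$

is multiplied by a per-bin gamma factor with unit mean and variance
equal to the `dispersion` parameter, a `dropout_rate` fraction of bins
is zeroed, and the profile's `total_reads` are then allocated
multinomially. Marginally the counts are negative-binomial-like
(per-bin CV $\approx \sqrt{\mathrm{dispersion} + 1/\mu}$) while the
total is conserved exactly. The $c$ term mixes in a 46,XX contaminant
(maternal cumulus-cell DNA); it defaults to 0 because sex-chromosome
concordance observed in SCM validation cohorts indicates contamination
is usually minor, but it is a first-class knob for sensitivity studies.

Source presets encode the biology qualitatively: SCM yields several-fold
more cell-free DNA than BF, so SCM uses `dispersion = 0.005` (bin-level
CV ≈ 9% at 2M reads, typical of good-quality WGA) and 1% dropout, while
BF uses `dispersion = 0.04` (CV ≈ 21%) with 8% dropout; biopsy
references (ICM/WB) are cleaner still. These BF/SCM noise levels are
plausible settings chosen once for this package — published cohorts
report DNA content and success rates, not bin-level dispersions — so BF
results here characterize "a noisier, droppier source", not a fitted
instrument model.

The genome is a fixed built-in table of 24 human-like chromosome lengths
(3086 Mb total; 3086 bins at the default 1 Mb bin width), with a `scale`
argument that shrinks all chromosomes proportionally for fast tests. GC
content per bin is a seeded AR(1) walk (mean 0.41, autocorrelation 0.9,
innovation sd 0.03, clipped to [0.2, 0.8]). The short correlation length
matters: every chromosome then samples the full GC range, so GC
correction cannot confound with chromosome dosage. The walk emulates
isochore-like heterogeneity only; it is not the real genome's GC track,
and mappability or blacklist structure is not modelled.

`simulate_cohort()` reproduces the shape of a published 148-embryo
SCM/BF validation cohort by default: aneuploidy rate 47/148 ≈ 31.8%,
single random whole-chromosome autosomal events, gain or loss with equal
probability, 30% of events mosaic with fraction uniform on [0.5, 1] (the
assay's reportable range). Real cohorts also contain segmental and
sub-threshold-mosaic abnormalities; the generator supports them per
sample (arbitrary event lists) but does not include them in the default
cohort mix, so cohort-level accuracy estimates apply to whole-chromosome
events.

## Normalization

`filter_bins()` masks unusable, GC-extreme, zero-count and
low-panel-median bins, and rejects a sample as *not analyzable* when
more than half its autosomal bins are masked — the analogue of a
technical failure (no reliable sequencing data, hence a `no_result`
classification rather than an error).

`gc_correct()` fits a loess trend (span 0.3, robust symmetric family) of
log depth against GC over valid autosomal bins and divides it out,
preserving mean autosomal depth. The fit is two-pass: residual
chromosome-median log-shifts larger than 0.15 (dosage-sized — a
reportable event shifts a chromosome by at least $\log 1.25 \approx
0.22$) are subtracted before refitting, so an aneuploid chromosome
cannot drag the trend toward itself. The 0.15 guard deliberately leaves
genuinely GC-driven chromosome offsets (which are much smaller) inside
the fit.

`build_panel()` scales each euploid reference sample to autosomal median
1 and stores per-bin medians on a *diploid scale*: autosomes over all
panel samples, X over the 46,XX samples, and Y as twice the 46,XY
median (one Y copy observed, two-copy scale stored). Bins with panel
coefficient of variation above 0.3 are masked; sex-chromosome CVs are
computed within the matching sex. `reference_normalize()` divides the
corrected depths by the panel and anchors the median of valid autosomal
bins at exactly 1. The median anchor is robust: a single trisomic
chromosome (~8% of autosomal bins) shifts it by only ~1%, which is why
package checks measure event dosage against the *disomic* autosomal
baseline. On this diploid-female scale an XY sample reads X ≈ 0.5 and
Y ≈ 0.5, which is exactly what the sex caller consumes.

## Segmentation

Circular binary segmentation is implemented from scratch (C++ core).
`max_t_arc()` maximizes the pooled-variance two-sample t statistic
between every circular arc and its complement; enumerating the
non-wrapping arcs covers all circular partitions, ties keep the smallest
start then smallest end, and a zero-variance vector returns $T = 0$.
Significance comes from within-chromosome permutations,
$p = (1 + \#\{|T^*| \ge |T|\})/(n_{\mathrm{perm}} + 1)$; permuting
within the chromosome preserves its noise scale. `segment_chromosome()`
recurses on significant splits ($\alpha = 0.01$, 1000 permutations,
minimum segment width 3 bins — none of these are published values; they
are this package's defaults) and `merge_segments()` re-joins adjacent
segments whose means differ by less than 0.1 ratio units, weighting
means by bin count. During recursion the permutation loop stops early
once the p-value provably exceeds $\alpha$; the split decision is
unchanged and seeded, so results stay deterministic. Segmentation runs
on linear-scale ratios, which makes the 50%-shift calling rules literal;
log-scale segmentation would be equally defensible and slightly more
variance-stabilized, but the linear contract was chosen so ratios map
to mosaic fractions without transformation.

## Calling

`call_chromosome()` takes the dominant deviating segment (largest
$|r - 1|$ among segments of ≥ 10 bins). If it spans ≥ 80% of the
chromosome it is a whole-chromosome event: $m \ge 0.8$ prints as a full
integer-copy gain/loss, $0.5 \le m < 0.8$ as a mosaic call with its
fraction, and $m < 0.5$ is *below the reporting floor* — mosaicism is
only reported above 50%, so the chromosome is called euploid. Smaller
deviating segments become `segmental` calls. The 0.5 floor is the
assay's published reporting rule; the 0.8 full cutoff and 80% span
fraction are this package's conventions (some band is required to print
integer copy numbers, and chromosome-level reporting needs a span rule),
both configurable.

`call_sex()` uses dosage windows on the diploid-female scale: X in
[0.8, 1.2] with Y ≤ 0.2 is XX; X in [0.35, 0.65] with Y in [0.3, 0.7]
is XY; anything else is indeterminate rather than guessed. After an XY
call the sex-chromosome ratios are doubled to per-copy-pair units before
chromosome calling so a normal X or Y reads 1. A sample classifies as
aneuploid/mosaic if any chromosome call is non-euploid — the
two-category grouping used for concordance — and karyotype strings
follow ISCN-like conventions (`47,XY,+21`, `45,XX,-16`,
`46,XX,+16[0.6]`, `46,XY,del(5)[0.8]`).

## Diagnostics

`diagnostic_metrics()` computes sensitivity TP/(TP+FN), specificity
TN/(TN+FP), NPV TN/(TN+FN), PPV TP/(TP+FP) and concordance (TP+TN)/n
with aneuploid/mosaic as the positive class; zero-denominator metrics
are undefined (NA), never 0. `no_result` samples leave the denominators,
mirroring how unevaluable samples are excluded in validation studies.
Display percentages round half *up* to one decimal (41/80 → 51.3%),
matching printed clinical tables, while exact fractions are always
carried alongside. Subgroup matrices pool cellwise
(`pool_matrices()`), and 2×2 comparisons are Pearson chi-square with
the Yates correction on by default — published tables do not always
state which convention produced each P value, so both are exposed and no
particular P value should be treated as canonical.

The package bundles plain-text fixtures with the summary counts of a
published 148-embryo SCM/BF validation cohort (`fixture_path()`): the
per-assay confusion counts by reference subgroup, a per-sample sheet
realizing those counts (synthetic reconstruction — marginals exact, row
pairings arbitrary), the 212-embryo IVF/ICSI ploidy and sex sheet, and
the 64-pair WB–SCM counts. They let the diagnostic layer be verified
against printed arithmetic with no simulation.

## Numerical and testing choices

Test problem sizes are a deliberate trade-off: module tests run on a
10%-scale genome (~312 bins), while the recovery guarantees that are
quantitative — full events within 2% of the 50% dosage shift, GC
invariance $|r| < 0.05$, null false-split rate ≤ 2α over 100 euploid
chromosomes, ≥95% cohort classification accuracy and mosaic-fraction
MAE ≤ 0.1 on a 148-embryo cohort — run at full scale (3086 bins,
2 × 10⁶ reads, 20-sample panel). At these sizes the standard error of a
large chromosome's mean ratio is ≈ 1%, so the 2% dosage tolerance is a
~2σ statement per seed, not a certainty; seeds are fixed in the tests.

Degenerate inputs are handled explicitly: constant GC skips correction;
zero-variance vectors return an unsplit segment; vectors shorter than
twice the minimum width are never split; all-zero or mostly-masked
samples become `no_result`; panel construction requires ≥ 3 samples
(median robustness) and a CV cutoff of 0 masks everything, which
downstream reports as an error rather than silently passing.

## Known limitations

* Amplification artifacts are reduced to dispersion + dropout; real WGA
  shows wave-like correlated bias along the genome that is not
  simulated, so passing tests bound performance under the stated noise
  model, not under every real amplification pathology.
* The reference normalization is contract-level (GC + panel medians);
  commercial pipelines' proprietary internals may differ bit-for-bit
  while satisfying the same contract.
* Polyploidy/haploidy and copy-neutral events are undetectable by
  design; segmental calls report bin-resolution boundaries (±1 Mb), not
  base-pair breakpoints.
* BF noise parameters are plausible, not fitted; conclusions about BF
  from simulation are qualitative.
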