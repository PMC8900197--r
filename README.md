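# nicscreen

Copy-number screening of embryo liquid biopsies from shallow
whole-genome sequencing bin counts.

## What this is for

Non-invasive pre-implantation genetic testing for aneuploidies
(niPGT-A) screens IVF embryos using cell-free DNA from the spent
culture medium (SCM) or blastocoel fluid (BF) instead of an embryo
biopsy. The assay is low-pass WGS (~2 × 10⁶ reads/sample): reads are
counted in 1 Mb genome bins, normalized by GC content and a euploid
reference panel, segmented by circular binary segmentation (CBS), and
converted into per-chromosome copy-number and mosaicism calls; the
calls are then validated against a gold-standard reference (inner cell
mass or whole-blastocyst biopsy) with the usual diagnostic statistics.

`nicscreen` is for people building or validating such pipelines: it
provides the complete analysis plus a ground-truth read-count
simulator, so every stage can be tested quantitatively without access
to restricted patient data.

## The model in brief

Coverage is linear in copy number: a bin at $c$ copies draws reads
$\propto c/2$, so a trisomy raises a chromosome's normalized copy
ratio $r$ to 1.5 (+50%) and a monosomy lowers it to 0.5 (−50%). A
mosaic event in cell fraction $m$ gives $r = 1 \pm m/2$, inverted as
$m = 2\,|r-1|$; mosaicism is reported only above $m = 0.5$. Bin counts
are simulated gamma–multinomially (negative-binomial-like marginals,
exact read total), with GC bias $e^{\beta(\mathrm{gc}-0.41)}$, bin
dropout, and optional 46,XX (maternal) contamination. Segmentation is
canonical CBS: the maximal circular-arc two-sample t statistic with
within-chromosome permutation p-values, recursive splitting and
weighted-mean merging. Diagnostic scoring uses aneuploid/mosaic as the
positive class: sensitivity TP/(TP+FN), specificity TN/(TN+FP), NPV
TN/(TN+FN), PPV TP/(TP+FP), concordance (TP+TN)/n, plus ploidy/sex
concordance and 2×2 χ² comparisons.

See `vignettes/niPGTA-screening.Rmd` for the full account of the
methods, defaults and limitations.

## Worked example

Simulate a trisomy-21 embryo's SCM sample at full scale, call it
against a 20-sample euploid panel, and score the published summary
counts of a 148-embryo SCM validation cohort:

```r
library(nicscreen)

genome <- build_genome(bin_width = 1e6, scale = 1)   # 3086 x 1 Mb bins
ref    <- simulate_reference_panel(20, source_profile("SCM"), genome,
                                   seed = 101)
panel  <- build_panel_from_counts(ref$samples, genome, sexes = ref$sexes)

truth <- karyotype("XY", whole_chromosome_event("21", 3, m = 1, genome))
scm   <- simulate_sample(truth, source_profile("SCM"), genome,
                         seed = 2024, sample_id = "embryo01")
call  <- analyze_sample(scm, genome, panel, seed = 7)
print(call)
#> ploidy_call 'embryo01': aneuploid (47,XY,+21), sex XY

subset(attr(call, "segments"), chrom == "21")
#>    chrom start end n_bins     mean p genome_start genome_end
#> 23    21     0  47     47 1.495674 1         2775       2822

diagnostic_metrics(confusion_counts(TP = 43, FP = 20, TN = 81, FN = 4))
#> sensitivity  91.5% (43/47)
#> specificity  80.2% (81/101)
#> npv          95.3% (81/85)
#> ppv          68.3% (43/63)
#> concordance  83.8% (124/148)
```

The trisomic chromosome comes back as a single 47-bin segment with
mean ratio 1.496 — the expected +50% dosage shift — and the sample is
classified aneuploid with karyotype `47,XY,+21`. The confusion-count
fixture bundled in `inst/extdata/` (see `?fixture_path`) carries the
same published counts used above, broken down by reference subgroup.

A thin command-line wrapper over these functions ships in
`inst/cli/nicscreen.R` with subcommands `simulate`, `normalize`,
`segment`, `call`, `evaluate` and `run-all`.

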