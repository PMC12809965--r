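# polybench

Dosage-aware benchmarking of polyploid small-variant calls.

## The problem

In polyploid genomes (tetraploid potato, hexaploid wheat, synthetic
polyploids built from pooled human samples) a heterozygous site carries an
**allelic dosage**: the number of copies of each allele among the ploidy
haplotypes (`AAAa` = dosage 1 of 4, a *simplex* genotype). Variant callers
that reliably **detect** a non-reference allele still frequently mis-assign
its copy number, so detection and genotyping accuracy must be measured
separately:

* **detection** — site-level TP iff truth and query share ≥ 1 ALT allele
  with dosage ≥ 1 on both sides;
* **genotyping** — TP iff the full genotype multisets are identical after
  allele harmonization (allelic composition *and* copy number).

With `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)` and
`F1 = 2PR/(P+R)` (0 when a denominator is 0), a matched site with the
wrong genotype counts as FP *and* FN, so detection metrics always bound
genotyping metrics from above; the gap is pure dosage error.

`polybench` provides, as pipeable data-frame-first functions:

* **Truth synthesis** — `merge_truth()` unions per-sample diploid truth
  VCFs (GIAB-style VCF+BED pairs) into a polyploid truth set: confident
  regions intersected, normalized sites unioned, per-allele dosages summed,
  absence inside confident regions counted as hom-ref.
* **Confidence regions** — `derive_confidence_regions()` computes the
  reference intervals uniquely covered by every haplotype's
  assembly-to-reference alignments (PAF/BED in, BED out), the dipcall-style
  mask generalized to any haplotype count; plus region algebra
  (`region_set()`, `region_intersect_all()`, `region_subtract()`,
  `filter_by_regions()`).
* **Normalization** — `normalize_variants()` (minimal representation,
  left-aligned indels, apply-to-sequence tested) and `harmonize_sites()`
  for co-located records spelled over different footprints.
* **Evaluation** — `evaluate_calls()` scores both modes at once, stratified
  by variant type × genotype class × annotation stratum, with
  `dosage_confusion()` (truth vs called dosage per truth allele) and
  `simplex_fp_fraction()` (share of FPs called as simplex, the
  low-allele-fraction indel artifact diagnostic); results carry
  `tidy()`/`glance()`/`autoplot()` methods.
* **Filters** — `qd_filter()` (per-type QD hard thresholds: drop SNVs and
  > 1 bp indels at QD < 2, 1-bp indels at QD < 5, strict inequalities),
  configurable `freebayes_filter()` policies, and `reliable_read_filter()`
  (keep a read iff strictly more than 50% of its bases fall in reliable
  regions, exact integer arithmetic at the boundary).
* **Synthetic benchmarks** — `fixture_spec()` / `simulate_benchmark()`
  generate reference, haplotypes, diploid truth samples, PAV-defected
  alignment blocks, corrupted callsets and read placements, all
  deterministic per seed and fully bookkept, so every evaluation count can
  be predicted exactly.

## Worked example

```r
library(polybench)
library(dplyr)

spec  <- fixture_spec(seed = 42, chrom_len = 50000, n_haplotypes = 4)
ref   <- gen_reference(spec)
hs    <- gen_haplotypes(ref$sequences, spec)
truth <- merge_truth(hs$samples, ref$sequences)
glance(truth)
#>   n_sites ploidy confident_bases n_hom_ref_dropped
#> 1     387      4           49600                 0

corr <- corrupt_callset(truth, spec, ref$sequences)
ev   <- evaluate_calls(truth, corr$query, reference = ref$sequences)
glance(ev) %>% select(starts_with("detection"))
#>   detection_TP detection_FP detection_FN detection_precision detection_recall
#> 1          375           19           12               0.952            0.969
glance(ev) %>% select(starts_with("genotyping"))
#>   genotyping_TP genotyping_FP genotyping_FN genotyping_precision
#> 1           368            26            19                0.934
```

Two diploid truth samples merged at ploidy 4 give 387 truth sites inside
the jointly confident 49.6 kb. The corrupted callset drops ~3% of sites,
shifts ~2% of dosages by one copy and adds ~5% spurious simplex calls; the
evaluation recovers exactly those injections: 12 detection FNs (the drops)
versus 19 genotyping FNs (drops + dosage shifts) — the 7-site gap is pure
dosage error, visible on the confusion matrix off-diagonals:

```r
dosage_confusion(ev)
#>    truth_dosage called_dosage     n
#>  1            1             0     6
#>  2            1             1   114
#>  3            1             2     1
#>  4            2             2   139
#>  ...
```

`autoplot(ev)` draws precision/recall/F1 by mode and variant type;
`plot_dosage_confusion(ev)` draws the matrix above.

A thin command-line wrapper over these functions ships in
`inst/scripts/polybench.R` (subcommands `simulate`, `derive-regions`,
`merge-truth`, `evaluate`, `filter-vcf`, `filter-reads`).

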