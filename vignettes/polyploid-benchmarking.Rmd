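---
title: "Dosage-aware benchmarking of polyploid small-variant calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosage-aware benchmarking of polyploid small-variant calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polybench)
library(dplyr)
```

## The problem

Variant calling in polyploids has to answer two different questions. The
first is *detection*: is there a non-reference allele at this site at all?
The second is *genotyping*: what is the exact allelic composition and copy
number — the **allelic dosage** — under the declared ploidy? A tetraploid
site may carry one, two, or three copies of an alternative allele
(`0/0/0/1`, `0/0/1/1`, `0/1/1/1`), and callers that reliably detect the
allele still frequently mis-assign its copy number, because each haplotype
is covered by fewer reads as ploidy rises. Evaluating the two questions
separately is what this package is for: `evaluate_calls()` scores a
polyploid callset against a truth set under both semantics at once, so the
gap between its detection and genotyping rows is precisely the
dosage-assignment error.

A second obstacle is that curated polyploid truth sets barely exist. Two
constructions are supported here:

* **Synthetic polyploid truth** (`merge_truth()`): several diploid samples
  with trusted truth VCFs and confident-region BEDs are merged into one
  virtual polyploid. The confident regions are intersected; the site set is
  the union of the samples' normalized sites; at each site, every sample
  contributes its allele dosages, and a sample with no record inside the
  jointly confident region contributes dosage zero (hom-ref) — which is
  exactly the assertion its confident regions license. Two diploids give a
  tetraploid truth set, three give a hexaploid.
* **Assembly-based confidence regions** (`derive_confidence_regions()`):
  given per-haplotype assembly-to-reference alignment blocks (PAF), the
  reference positions covered by *exactly one* retained block per
  haplotype, intersected across all haplotypes, delimit where every
  haplotype is uniquely and consistently represented. Evaluation is
  restricted to these regions so callers are not penalized for sites that
  are unresolvable or absent from the truth.

## Evaluation semantics

Both callsets are normalized (minimal representation, left-aligned indels)
and restricted to the confidence regions. Records whose footprints overlap
at a harmonizable locus are paired 1:1; ties are broken by nearest start,
then lexicographically smallest ALT, deterministically.

* **Detection**: a pair is a TP iff truth and query share at least one ALT
  allele with dosage ≥ 1 on both sides.
* **Genotyping**: a TP additionally requires the full genotype multisets to
  be identical after the two records' alleles are re-spelled over a common
  REF footprint.

A matched pair that fails the criterion counts as FP *and* FN
simultaneously — the convention of haplotype-replay evaluators, stated here
explicitly because different accountings change precision and recall.
Unmatched truth records are FNs; unmatched query records asserting an ALT
are FPs. Query records asserting nothing (hom-ref genotype or missing GT)
are no-calls: they are ignored entirely, so they are never FPs, and a truth
site covered only by one scores as FN. From these rules it follows that
genotyping TPs are a subset of detection TPs, so detection precision and
recall bound the genotyping values from above on any input — a property the
test suite asserts on every fixture.

`eval_metrics()` uses `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
`F1 = 2PR/(P+R)`, each defined as 0 when its denominator is 0.

Beyond the scalar metrics, `dosage_confusion()` tabulates, for the ALT
allele of every truth site, the truth dosage against the called dosage
(0 = missed or called hom-ref). The diagonal is exact dosage concordance;
the `called = 0` column isolates the failure mode where low-dosage
(simplex) variants are dismissed as noise. `simplex_fp_fraction()`
computes the complementary diagnostic: the share of false-positive calls
of a given type whose *called* genotype is simplex, which flags
low-allele-fraction indel artifacts.

## Normalization and harmonization

Unions and matching are only well-defined if the same edit has one
spelling. `normalize_variants()` implements the standard trim/extend
algorithm: shared trailing bases are trimmed (extending left with the
preceding reference base whenever an allele would empty, which keeps the
VCF anchor base), then shared leading bases are trimmed while every allele
retains two bases. The result is minimal and left-aligned; SNVs are fixed
points; the operation is idempotent. Correctness is asserted not against
hand-picked examples but against an apply-to-sequence oracle: a
representation is accepted iff substituting it into the reference yields
the same sequence as the original record, for thousands of randomized
spellings.

When co-located records spell alleles over different footprints (an SNV
inside a deletion's span, say), `harmonize_sites()` pads every REF to the
union footprint with reference bases and re-spells the ALTs against it;
duplicate spellings collapse to one allele index and ALTs are ordered
lexicographically, which makes `merge_truth()` invariant to sample order.
Same-sample overlapping records whose summed dosage exceeds the sample's
ploidy are genuinely contradictory and abort with a diagnostic naming the
site. Sites whose harmonized genotype ends up all-reference are dropped
and counted (`n_hom_ref_dropped`).

## Filters

`qd_filter()` applies the community-style per-type quality-by-depth hard
thresholds: SNVs, MNVs and indels longer than 1 bp are dropped iff
`QD < 2`; 1-bp indels iff `QD < 5`. The inequalities are strict (a 1-bp
indel at exactly `QD = 5.0` survives), and a multiallelic record uses the
most stringent threshold applicable to any of its alleles. Records lacking
QD are kept with a warning by default — QD is only emitted for variant
sites, and failing absence would silently drop valid records —
`missing_fails = TRUE` reverses this.

`freebayes_filter()` evaluates an ordered minimum-threshold policy over
`QUAL`, `MQM`, `DP` (or any annotation). The shipped `minimal` and
`strict` presets live in an editable YAML
(`inst/extdata/freebayes_filters.yaml`) and are labelled there as
reconstructions of common post hoc practice rather than authoritative
values; the policy object is fully configurable precisely because this
step is under-specified in the literature.

`reliable_read_filter()` implements the reliable-region read-retention
rule: a read is kept iff strictly more than `min_frac` (default 50%) of
its bases derive from reliable regions. Two numerical choices matter.
First, base accounting uses reference-projected aligned blocks only: read
insertions and clipped bases count toward read length but can never count
as overlap — a deterministic rule derivable from standard alignment
records. Second, the comparison is done by integer cross-multiplication
(`overlap * den > num * read_length`), so a read with exactly half its
bases inside is dropped with no floating-point ambiguity at the boundary.

## The synthetic benchmark generator

`fixture_spec()` + `simulate_benchmark()` produce a complete, fully
bookkept benchmark: reference FASTA, per-haplotype sequences, per-sample
diploid truth VCF/BED pairs, alignment blocks with presence/absence-like
defects, the merged polyploid truth, a corrupted query callset, and read
placements. Everything downstream of a spec (including its seed) is
deterministic to the byte.

The generator is site-based: candidate sites are placed at density
`snv_rate + indel_rate` per base (defaults 0.008 and 0.002, an SNV:indel
ratio of 4:1), and each haplotype then carries the ALT with probability
`carrier_prob = 0.5`, conditioned on at least one carrier. This produces
the full dosage spectrum at every ploidy — simplex through hom-alt — which
is the regime the evaluator must distinguish. The default density of
0.01/bp is an order of magnitude above typical human heterozygosity
(~0.001/bp); it is chosen so that the small genomes used for testing
(100–150 kb) still yield > 1000 truth sites, giving the count-recovery
properties statistical teeth. Sites are spaced ≥ 30 bp apart and
re-checked after normalization so truth footprints never interact.
Insertion/deletion lengths are `1 + Geometric(p = 0.5)`, capped at 10 bp —
small variants only. A configurable fraction of SNV sites
(`multiallelic_rate = 0.02`) carries two distinct ALT bases.

`corrupt_callset()` injects the three error modes the evaluator measures,
each independently bookkept: sites dropped at `fn_rate` (default 0.03),
dosage shifts of ±1 copy at `dosage_err_rate` (default 0.02), and spurious
records at `fp_rate` × truth count (default 0.05) placed disjoint from
truth footprints inside the confidence regions, with configurable type mix
and called dosage (default simplex, the empirically dominant FP genotype
class for indels). Dosage shifts stay within `[1, ploidy − 1]` by default
so that every shifted site remains a detection TP and the
detection/genotyping divergence is attributable purely to dosage;
`dosage_to_zero = TRUE` instead allows shifts to hom-ref — the
simplex-to-hom-ref failure mode of diploid-trained callers — which the
ledger then books as an FN, not an FP, in both modes (such shifts are
restricted to single-ALT records so the bookkeeping stays exact). The
ledger suffices to predict every TP/FP/FN cell exactly, and the test suite
asserts that equality across ploidies 2/4/6 and dozens of seeds.

`gen_alignment_blocks()` starts from one full-length alignment block per
haplotype per chromosome and injects `pav_events` defects: a *gap* removes
a segment from one haplotype's block (a reference-only segment — coverage
0) and a *dup* adds a duplicated block (a sample-side repeat — coverage 2).
Either way the segment leaves the joint confidence region, so the expected
region set is available in closed form for testing.

What the generator deliberately does **not** emulate: sequencing errors and
base qualities (read placements are geometry only), alignment artifacts,
clustered errors near structural variants, reference-biased spurious
calls, caller-specific biases, and linked errors across nearby sites.
Passing fixtures therefore demonstrates that the *accounting machinery* —
merging, normalization, matching, counting, stratification — is exact, not
that any particular caller performs well on real data.

## Worked example

```{r pipeline}
spec <- fixture_spec(seed = 42, chrom_len = 50000, n_haplotypes = 4)
ref <- gen_reference(spec)
hs <- gen_haplotypes(ref$sequences, spec)
truth <- merge_truth(hs$samples, ref$sequences)
glance(truth)

corr <- corrupt_callset(truth, spec, ref$sequences)
ev <- evaluate_calls(truth, corr$query, reference = ref$sequences)
glance(ev) %>% select(dplyr::starts_with("detection"))
glance(ev) %>% select(dplyr::starts_with("genotyping"))
dosage_confusion(ev)
```

```{r plot, fig.width = 6, fig.height = 3.5}
autoplot(ev)
```

## Design choices on open points

* **Multiallelic sites** are compared jointly by default (the whole-site
  genotype multiset must match); `split_multiallelic = TRUE` decomposes
  biallelic MNVs into SNVs first via `decompose_mnv()`, for callers that
  emit composite substitutions. Joint comparison is the stricter, less
  assumption-laden default.
* **Detection requires a shared ALT allele**, not merely any non-reference
  call at the locus: a query calling the wrong ALT at a truth site is an
  FP+FN, the stricter of the two defensible readings.
* **Genotypes are unphased multisets** even when the input uses `|`:
  dosage, not phase, is what is being evaluated.
* **Site-level matching** after normalization/harmonization replaces full
  haplotype-replay comparison. Representation differences spanning
  *several* nearby records (one caller's complex substitution vs.
  another's two adjacent indels) can therefore score differently than a
  replay evaluator would — a documented limitation accepted in exchange
  for determinism and oracle-testability.
* **Ploidies above 6** are rejected rather than silently mislabelled; the
  genotype-class scale (`simplex` … `sextuplex`) covers the supported
  designs.

## Problem sizes used by the test suite

Unit tests run on 1–10 kb toy genomes. The end-to-end property tests use
150 kb single-chromosome fixtures with ≥ 1000 truth sites each, 20 random
seeds per ploidy in {2, 4, 6}; the interval-algebra and normalization
oracles each run 1000 randomized trials (100 kb chromosomes, 1 kb
references). These sizes make every probabilistic property effectively
certain while keeping a full run in a few minutes on one core.
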