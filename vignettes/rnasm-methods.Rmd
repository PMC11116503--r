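---
title: "Detecting somatic mutations from tumor RNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting somatic mutations from tumor RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnasm)
library(dplyr)
```

## The problem

Tumor RNA-seq is abundant where matched DNA sequencing often is not, and in
expressed regions it can reach depths that rescue mutations invisible to
exome capture. Calling somatic mutations from RNA, however, is dominated by
three artifact classes that DNA pipelines never see:

* **reverse-transcription (RT) errors** introduced during library
  construction, which surface as low-allele-fraction, low-base-quality
  calls;
* **alignment errors near splice junctions and in soft-clipped read ends**,
  where spliced aligners place mismatched bases;
* **A-to-I RNA editing**, an enzymatic deamination of adenosine that is real
  RNA signal but absent from the genome, observed as A>G changes
  (pyrimidine-collapsed T>C).

`rnasm` takes the candidate output of a somatic caller plus per-site read
evidence and removes these artifact classes in two stages: a bank of
eighteen rule filters, then a stacking classifier that scores each surviving
candidate as DNA-backed versus RNA-only. Downstream helpers compute
substitution spectra, fit reference mutational-signature exposures, and
validate calls against DNA-derived mutation sets.

The package deliberately consumes caller output; it does not run aligners or
callers. Evidence from a second aligner and a second caller enters as
columns of the evidence table, so the dual-concordance filters work from any
tooling (or run inert when those columns are absent).

## The filter bank

Every filter is a named predicate over one row of site evidence; the bank
evaluates all enabled filters for every candidate. Two tallies are
reported, because they answer different questions:

* **independent** — how many candidates each filter would reject if applied
  alone (the per-filter percentages one typically plots);
* **attributed** — the first failing filter in a fixed canonical order
  (germline → depth → low-alt → base quality → mapping → strand bias →
  multimap → read position → soft-clip → junction → uneven coverage →
  homopolymer → cluster → editing → population AF → dual-aligner →
  dual-caller → no-evidence), which partitions the rejected set exactly:
  passes + attributed rejections = inputs.

Default thresholds (all exposed in `filter_config()`):

| filter | rule | default |
|---|---|---|
| germline | allele-exact match in matched-normal VCF | — |
| depth | total depth < `min_depth` | 10 reads |
| low_alt | alt reads < `min_alt_reads` or VAF < `min_vaf` | 3 reads / 0.05 |
| base_quality | median alt base quality < floor | 20 |
| mapping_quality | median alt MQ < floor, or mean mismatches > cap | 20 / 5 |
| strand_bias | two-sided Fisher exact on stranded 2×2, tested when alt ≥ 5 | p < 0.001 |
| multimap | fraction of MQ-0/secondary alt reads | > 0.5 |
| read_position | mean fractional variant position in alt reads | outside [0.1, 0.9] |
| soft_clip | fraction of alt reads clipped within 10 bp | > 0.3 |
| junction | distance to an annotated exon boundary | ≤ 5 bp |
| uneven_coverage | site depth / median flank depth | < 0.5 |
| homopolymer | longest run in ±5 bp window | > 6 bp |
| cluster | ≥ 3 same-class T>C/A>G candidates within 150 bp | — |
| editing | A>G / T>C at a known editing site | window 0 bp |
| population_af | population allele frequency (when resource given) | > 0.001 |
| dual_aligner | alt reads after second-aligner realignment | < 2 |
| dual_caller | alt reads in the second caller's pileup | < 2 |
| no_evidence | candidate with no evidence row | — |

Choices worth explaining:

* **Fisher's exact test** for strand bias: counts at a single site are
  small, so an exact test is preferred over a chi-square approximation; the
  test only runs with at least five alt reads because below that it has
  essentially no power and would reject nothing anyway.
* **Flank definition** for uneven coverage: the median depth over 25 bp on
  each side, excluding the site column. The median (not the mean) is robust
  to the depth cliffs that exon boundaries produce in RNA-seq coverage.
* **The mismatch cap** lives inside the mapping-quality filter: evidence
  carries the mean per-read mismatch count of alt reads only, so an absolute
  cap (default 5) is used rather than an alt-versus-ref margin.
* **Indels** are exempt from the editing and cluster filters (both are
  defined on substitution classes) and subject to all others.
* **Inert behavior**: the concordance filters pass, with a log message,
  for candidates whose second-aligner/second-caller columns are missing.
  This keeps the bank usable on plain single-caller evidence.

Tightening any single threshold can only shrink the pass set; this
monotonicity is enforced by tests.

## Site evidence

Evidence can be summarized from an indexed BAM (`summarize_site()`) or read
from a tab-delimited table whose header matches `evidence_schema()` — four
key columns plus 22 evidence fields. Both routes are tested to drive
identical filter outcomes. Counting conventions in `summarize_site()`:

* bases inside soft-clipped segments never support the variant;
* duplicate-flagged reads contribute only to `dup_frac`;
* reads with base quality below 10 at the site are excluded from allele
  counts but remain in `depth_total`;
* reads whose deletion spans the site count toward depth only;
* secondary and supplementary alignments are ignored.

## The stacking classifier

Each surviving candidate is described by 26 features (`feature_names()`):
allele-fraction and depth terms, quality deltas between alt and ref reads,
strand-bias statistic, soft-clip/multimap/mismatch fractions, junction
distance, flank unevenness, GC of the surrounding 100 bp, homopolymer run,
trinucleotide channel and substitution class, a T>C indicator, distance to
the nearest known editing site, the local density of same-class T>C
candidates, caller quality, the VAF shift under the second aligner, the
second caller's alt count, and log1p gene TPM. Missing optional evidence is
imputed with documented sentinels (1e4 bp distance caps, zero counts), so
vectors are always finite.

Three base learners — a random forest (`ranger`), gradient-boosted trees
(`xgboost`) and a single-hidden-layer neural network (`nnet`, with an
internal standardizing scaler) — are tuned over small fixed grids by 5-fold
cross-validation maximizing ROC-AUC. A logistic meta-learner is then fitted
on the base learners' *out-of-fold* probabilities only; a dedicated test
shows that on label-shuffled noise the honest meta-learner stays at chance
while in-fold probabilities would look wildly optimistic. Class imbalance
is handled with case weights (not resampling) to keep training
deterministic; all randomness derives from one integer seed, and a saved
bundle reproduces probabilities to 1e-9.

Training labels mirror the intended workflow: candidates that survive the
filter bank are labelled positive when they match a DNA-derived somatic
mutation set and negative (RNA-only) otherwise. Training on filter-bank
survivors matters in practice — on raw candidate sets the loss is dominated
by artifact classes the filters already remove, and the decision boundary
around novel editing sites is noticeably worse. The classifier is applied
to all post-filter candidates, not only to T>C calls: RNA-only variants are
not limited to editing.

Support-vector and plain logistic learners are implemented behind the same
learner interface for comparison but are excluded from the default stack.

## Spectra and signatures

SNVs are collapsed to the six pyrimidine-reference substitution classes and
the 96 trinucleotide channels in COSMIC SBS order (class-major, then 5',
then 3' base); purine-reference changes are reverse-complemented together
with their context, so every channel assignment is strand-collapse
invariant. Channel sums per sample equal SNV counts exactly; indels are
skipped and counted.

Signature exposures are fitted per sample by non-negative least squares
against a fixed reference matrix (any 96×K table in COSMIC layout). The
residual is reported for the least-squares solution itself; exposures are
then rescaled to the sample's mutation count for interpretability. This
supervised refit is deterministic; de novo signature discovery (Bayesian
NMF and friends) is out of scope. Per-mutation assignment uses the
posterior ratio for a mutation in channel c:
`P(k | c) = e_k S[c,k] / Σ_j e_j S[c,j]`, assigning the argmax signature
only when its likelihood exceeds 0.75 (strictly), otherwise "unassigned".
Channels with zero fitted intensity are flagged rather than silently
assigned. An optional backward-elimination sparsity step was considered and
left out of the default path: with a handful of reference signatures it
changes nothing, and with 60+ it belongs to an explicit model-selection
decision by the user.

## Validation harness

`validate_calls()` compares predictions with one or more DNA-derived
reference sets under the coverage-exclusion rule: any site with fewer than
10 reads in *any* platform's depth lookup is excluded from both numerator
and denominator before precision (validated / compared) and sensitivity
(adequately covered reference mutations recovered) are computed. Matching
is allele-exact by default; a positions-only mode exists for sensitivity
analyses. Cohort summaries use the lower median (for an even number of
patients, the lower of the two middle values). `binned_validation()`
reports validated fractions by depth or GC bins, flagging bins with under
five sites; the size-weighted bin fractions recompose the overall fraction
exactly. `fdr_by_transition()` reports per-class FDR with empty classes as
undefined, never zero. `smg_input_table()` gates the per-gene mutation
table to genes with mean TPM ≥ 1 — lowly expressed genes lack the RNA
coverage for selection inference and would otherwise be misread as
negatively selected by dN/dS tools; the dN/dS model itself is external.

## The synthetic benchmark

`make_benchmark()` generates, from one seed, a miniature genome (2 × 100 kb
with alternating GC-rich/GC-poor 10 kb blocks), 40 genes of 2–8 exons,
and a truth-labelled candidate set with per-site evidence. Default
conditions (all config keys):

* 2,000 sites split 45% somatic, 15% germline, 20% editing, 10% RT error,
  5% soft-clip artifact, 5% junction artifact, across 4 samples;
* coverage negative-binomial with mean 100 and dispersion 10;
* true VAFs: somatic Beta(2, 5); RT error Beta(1, 20) (the low-frequency
  artifact regime); editing Beta(3, 3); germline 0.5 or 1.0;
* a candidate-emission floor of 3 alt reads for every class except RT
  errors: a caller does not emit a site with fewer supporting reads, while
  permissive low-VAF emission is precisely the RT-error mode;
* class-specific evidence signatures: RT errors get low base quality and
  zero second-caller support; soft-clip artifacts get ≥ 0.8 clipped alt
  fraction and zero second-aligner support; junction artifacts sit within
  5 bp of an exon boundary with zero second-aligner support; somatic,
  germline and editing sites carry platform-consistent counts;
* editing sites are placed inside exons on the transcript strand (A>G on
  "+", T>C on "−") in pairs: one site present in the known-editing BED and
  one *novel* partner 20–80 bp away that is absent from it. Pairs of two
  keep the hyper-editing cluster rule (≥ 3 in 150 bp) from firing, so
  catching novel editing is genuinely the classifier's job, and the
  proximity feature has realistic signal (real editing clusters around
  known sites);
* somatic and germline sites are placed at least 10 bp from exon
  boundaries and never at editing positions, so truth classes are
  unambiguous by construction;
* DNA reference sets emulate exome-like (95% of somatic truths, depth mean
  80) and genome-like (98%, depth mean 40) platforms, giving the coverage
  rule something to exclude.

What the generator does **not** emulate: per-cycle base-quality error
profiles, realistic read-level alignment (evidence is simulated at the
site-summary level; a small SAM writer exists solely to test
`summarize_site()`), transcript-abundance-driven coverage, subclonal
structure, and mutational hotspots. Tests passing on this benchmark
therefore demonstrate the correctness and discriminative machinery of the
pipeline under separable-by-construction conditions — an upper bound, not a
clinical performance claim.

## Problem sizes and numerical choices

The test suite and the acceptance script run benchmarks of 400–2,000 sites
and train the stack on roughly 1,000–1,700 rows with two parameter sets per
learner — sizes chosen so a full run stays comfortable on a single CPU
while every stage (including 5-fold CV across five seeds) is exercised.
Signature fits use `pracma::lsqnonneg` (exact active-set NNLS); a
multiplicative-update oracle in the tests confirms the residual to 1e-4.
Ties in ROC ranking count 0.5; PR-AUC uses step-wise interpolation
(average-precision form). Medians of even-length patient vectors take the
lower middle value. All derived seeds stay below 2^31.

## Known limitations

* The 18 filter IDs and the 26-feature manifest are concrete, documented
  instantiations; both are config-visible so an alternative set can be
  swapped in without code changes.
* The editing filter ignores strand (the editing-site input carries strand,
  but membership is tested on position); a strand-aware mode would need
  stranded library information that plain evidence tables lack.
* `summarize_site()` handles SNVs fully and indels by exact-CIGAR matching;
  complex/multi-part indels are not resolved.
* Population allele-frequency filtering is inert unless a resource table is
  supplied; no bundled population database exists at this scale.
* Exposure fitting against highly collinear signature references is
  ill-conditioned like any NNLS refit; with the bundled low-overlap
  synthetic references recovery is within ±0.05 at n = 2,000 draws.
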