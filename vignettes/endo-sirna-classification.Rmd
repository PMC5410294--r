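---
title: "Classifying endogenous siRNAs from small-RNA libraries"
author: "endosirna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying endogenous siRNAs from small-RNA libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endosirna)
```

## The problem

Gametes and early embryos carry, besides microRNAs (miRNAs) and
Piwi-interacting RNAs (piRNAs), a third small-RNA class: endogenous small
interfering RNAs (endo-siRNAs), 18–24 nt DICER products of double-stranded RNA
precursors. Given small-RNA sequencing libraries from stages such as sperm,
oocyte and zygote, the questions this package answers are:

1. which sequenced tags are miRNAs, piRNAs, structural-ncRNA fragments,
   endo-siRNAs, or unknown;
2. which structural precursor each endo-siRNA comes from — a transposable
   element (TE-siRNA), a long-hairpin locus (Lhp-siRNA), or an
   inverted-complement region of an mRNA (IC-siRNA);
3. which endo-siRNAs are enriched in one stage (typically the zygote) relative
   to the others; and
4. whether LINE-1 (L1)-derived siRNAs can be explained by a double-stranded
   RNA formed between the L1 transcript and an antisense noncoding transcript
   (asL1) driven by the antisense promoter (ASP) in the L1 5'UTR.

No public data accompany the study system this pipeline models, so the package
ships a first-class synthetic-data module: toy genomes with planted features
and simulated libraries with known truth labels. Every downstream stage is
validated by planted-truth recovery and by brute-force oracles.

## The classification procedure and its assumptions

**Preprocessing** (`filter_and_collapse()`). Reads containing unknown
nucleotides are removed; the 3' adapter is trimmed (leftmost occurrence of a
≥ 6 nt adapter prefix; exact match — the original trimmer and its parameters
are unstated, so the simplest deterministic rule is used); trimmed reads
outside 18–30 nt are discarded; identical sequences collapse into tags with
per-library counts; tags with total count ≤ 2 are removed. The count filter's
scope (total across libraries vs per library) is a configuration switch,
`count_filter_scope`, defaulting to `total`: the filter description applies to
reads per sequencing run, and collapsing first keeps the bookkeeping exact.

**Mapping** (`build_index()`, `map_tags()`). Tags are placed on the genome by
perfect match only, reproducing a `bowtie -k1 -n0` contract. `-k1` reports one
alignment whose choice is implementation-defined, so this package makes the
choice total and reproducible: the minimal hit under (chromosome name
lexicographic, start ascending, + before −). Tags without a perfect match are
discarded. `N` in the genome never matches anything.

**Tier annotation** (`annotate_tiers()`). Tiers apply in order, first match
wins: structural ncRNA (tRNA/rRNA/snRNA/snoRNA references), then miRNA
(length 21–24 nt and reference homology), then piRNA (reference homology or
length 25–30 nt), then endo-siRNA candidate (18–24 nt). "Homologous" is
operationalised as exact substring containment on either strand (a mismatch
tolerance exists but defaults to 0); the tier precedence when a tag matches
several reference kinds is this package's decision — the source procedure does
not state one — and it is pinned by a test.

**Subclassification** (`classify_te()`, `find_clusters()`, `fold_region()`,
`classify_lhp()`, `find_inverted_complement()`, `assign_ic()`,
`finalize_labels()`).

* TE-siRNAs: perfect match (either strand) to any record of a repeat library
  whose headers carry `family=` tags (LTR/SINE/L1/ERV); ties resolve to the
  first record in file order.
* Lhp-siRNAs: genomic clusters are maximal greedy left-to-right runs of hits
  with span strictly under 10 kb containing at least 16 distinct tag sequences
  ("more than 15 unique ... within less than 10 kb"). Each cluster region is
  folded; candidates whose hits lie entirely within a hairpin arm are called.
* IC-siRNAs: each mRNA is searched for inverted-complement arm pairs;
  candidates placed (perfect match, mRNA coordinates) entirely inside an arm
  are called.
* A candidate with several calls takes the subclass priority TE > Lhp > IC
  (TE matching is the most specific sequence-level evidence); candidates with
  no call revert to unknown.

**Enrichment screen** (`select_enriched()`). Counts are normalised to CPM with
a 0.5 pseudocount on count and total, so fold differences are always finite.
The test is a two-sided Fisher exact test on the tag-vs-rest 2×2 table; a tag
is selected iff against *every* comparator the fold difference strictly
exceeds 2 and p is strictly below 0.01. The test, the normalisation and the
both-comparators conjunction are this package's choices where the screen's
description states only "FD > 2, P value < 0.01"; all are configuration keys,
and no multiple-testing correction is applied by default (a BH switch exists).

**L1 antisense-promoter model** (`extract_upstream()`, `find_homology()`,
`build_duplex()`, `assign_l1_sirnas()`). Promoter coordinates are signed
integers without a zero: +1 is the first transcribed base at the TSS, −1 the
first base upstream. 3000 nt upstream windows of annotated L1 copies are
locally aligned against the reverse complement of the L1 ORF2 (or 3'UTR)
sequence; blocks of aligned length ≥ 50 at identity ≥ 0.8 become antisense
homology blocks. The dsRNA duplex length is the promoter-coordinate
intersection of a block with the asL1 span (an input, e.g. +93..−490, taken
from a RACE result; "ends at −490" is read as inclusive). Candidate tags whose
placement on the L1 element lies entirely within the duplex's sense-side
interval are the L1-siRNAs, labelled sense/antisense by hit strand. Both ORF2
and 3'UTR blocks are handled by the same code via `target_offset`; the
reference copy must be annotated on the + strand (the toy worlds are; a −
strand reference would need transcript-coordinate reflection, a known
limitation). Small assay arithmetic is included: `spliced_product_length()`
(intron-containing PCR product minus intron) and `fold_change_ddct()`
(2^−ΔΔCt).

## Folding: why base-pair maximization

The long-hairpin decision needs only "does this cluster region fold back on
itself with long, mostly-paired arms". The package folds with Nussinov
base-pair maximization (Watson–Crick plus G·U wobble, minimum loop 3,
nested structures only) in compiled code, not with a thermodynamic
free-energy model: it removes an external-binary dependency, is exactly
testable against exhaustive structure enumeration for short sequences, and
preserves the qualitative decision. The traceback prefers closing the
outermost pair, so a planted inverted repeat is recovered as one long helix.
Arms are the two strands of the largest helix group after merging adjacent
helices separated by ≤ 4 unpaired positions on both strands; a region
qualifies as a long hairpin iff its paired fraction (2·pairs/length) is
≥ 0.5 and both arms are ≥ 20 nt (`lhp.min_paired_fraction`, `lhp.min_arm`;
the source procedure never defines "long hairpin", so the thresholds are
explicit configuration). The O(n³) dynamic program is practical to a few kb
(a 1.6 kb region folds in seconds); regions above `fold_max_len` (default
5 kb) are skipped with a warning, and 8 kb is a hard guard. Maximal pairing
on *random* sequence is dense, so the paired-fraction threshold alone does
not separate hairpins from chance structure in very short regions — the arm
length and containment rules carry that weight.

## The inverted-complement search

Aligning an mRNA against its own reverse complement with one best-local-
alignment call fails on the most important edge case: for a perfect
palindrome the optimal alignment is the full-length self-alignment, whose two
projections coincide — it would be discarded by the arm-overlap rule even
though the true answer is two adjacent arms. The search therefore seeds with
exact inverted 12-mer matches grouped by antidiagonal (a property of
inverted repeats: arm extension keeps i+j constant), merges seed runs
(bridging gaps from isolated mismatches), and then rescans or realigns:

* non-overlapping arm candidates are refined by local alignment of arm 1
  against the reverse complement of arm 2 with blastn-like scores
  (+2/−3, gap open 5, gap extend 2), keeping pairs with aligned length ≥ 30
  and identity ≥ 0.8;
* a self-overlapping (palindromic) candidate is split at its centre into two
  adjacent arms and its identity recomputed gaplessly.

Overlapping reported regions collapse to the higher-scoring one. All scores
and thresholds are configuration keys.

## The synthetic worlds

`toy_genome_spec()`/`build_toy_genome()` construct one random chromosome with
non-overlapping planted features; every planted tag is an exact substring of
its feature, so perfect-match mappability is guaranteed, and the truth table
records the intended final label. `simulate_libraries()` draws reads per
library by multinomial sampling of the intended abundances plus a configurable
background fraction sampled from random genome positions with lengths from
0.5·N(23, 1) + 0.5·N(27.5, 0.8), discretised and clipped to 18–30 nt — the
bimodal tag-length pattern of gamete/zygote libraries, with the miRNA/endo-
siRNA peak at 23 nt and the piRNA peak at 27–28 nt (the mixture weights are
this package's choice; the source reports only the peak positions). Quality
strings are constant `I`; quality is never used.

Three construction details matter and are deliberate:

* **Hairpin loci are near-perfect inverted repeats.** An exact inverted
  repeat makes every 3'-arm tag equal the reverse complement of a 5'-arm
  substring, so the deterministic mapper places all tags on the 5' arm and
  the cluster collapses. Real long hairpins are imperfect; the generator
  substitutes one base per 20 nt of the 3' arm (the mirror base, which can
  never pair, not even by wobble), making every 21-nt tag's placement unique
  while keeping the region a long hairpin. Tags also avoid the innermost 15%
  of each arm: base-pair maximization can trade the bubble-weakened helix
  ends nearest the loop for denser loop-internal pairings, so detected arms
  may fall slightly short of the planted ones there.
* **Homology-arm edges are guarded.** Just outside each planted arm pair
  (IC arms, the L1 upstream block) the generator forces eight positions to
  equal their would-be partners — equal bases never complement — so local
  alignment cannot profitably extend a planted 217 nt or 365 nt block by
  chance flanking matches, and the planted lengths are recovered exactly for
  any seed.
* **Worlds that would corrupt truth are rejected, not patched.** If a planted
  tag happens to contain the adapter's first 6 nt the trimmer would truncate
  it; `simulate_libraries()` refuses such a world with a named error instead
  of silently changing the truth.

The packaged fixtures (`fixture_fig1c()`, `fixture_fig2c()`,
`fixture_plce1()`, `fixture_full()`) fix their generator seeds: they are
calibrated worlds whose expected outputs are exact counts (17 Lhp-siRNAs over
a 1612 nt cluster built as 700/212/700 arm/loop/arm — the published account
states only the tag count and region size, the split is this package's
choice; a 365 bp duplex with 9 assigned tags and 4 ORF2 decoys; a 217 nt IC
region with 2 in-arm tags and 2 spacer decoys). Library depths (800–5000
reads) keep every planted tag far above the count filter under multinomial
sampling. What a green fixture test establishes: the rules recover planted
structure exactly in a noise-free world. What it does not establish:
performance on imperfect repeats at genome scale, on sequencing errors, or on
multi-mapping ambiguity beyond the deterministic tie-break — all out of scope
here.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally and in BED output;
  promoter coordinates have no zero and are linearised (−1 → 0) for interval
  arithmetic, making the duplex-length computation a plain intersection.
* Percentages in class summaries round half away from zero (a 0.5% share
  prints as 1, a 6.63% read share prints as 7), matching how the published
  class table prints.
* Cluster building is greedy left-to-right with disjoint runs. Adversarial
  hit layouts where a qualifying window straddles two runs can disagree with
  exhaustive window enumeration; the tests bound this by checking agreement
  on layouts with inter-cluster gaps above the window span (the realistic
  case of discrete loci) plus the exact boundary cases (16 distinct tags over
  9,999 nt: cluster; over exactly 10,000 nt: none).
* Fisher's exact p is delegated to `stats::fisher.test` and cross-checked in
  tests against direct hypergeometric summation to 1e-10.
* Zero-depth libraries yield empty FASTQ without error; empty reference sets
  warn and skip their tier; an empty genome, a malformed FASTQ record
  (named by index) or a malformed BED line (named by line number) reject.

## Known limitations

* Folding is O(n³) in time and O(n²) in memory: clusters beyond a few kb are
  skipped (configurable), and regions over 8 kb are refused.
* One reported placement per tag: multi-mapping tags contribute one location,
  chosen by the deterministic order, not by abundance-aware assignment.
* The L1 scan models one reference copy on the + strand and one best homology
  block per upstream sequence.
* The simulator has no sequencing-error or UMI model and no piRNA ping-pong
  structure; piRNA annotation leans on the length rule plus user-supplied
  references.
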