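---
title: "Comparative plastome analysis with plastomer: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome analysis with plastomer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomer)
```

This vignette is the package's account of the science it implements: the
models and procedures, the tunable parameters and why their defaults are
what they are, what the synthetic-data generator does and does not emulate,
and the numerical design choices made where the field's conventions leave
room.

## 1. Quadripartite architecture

A plastome is modelled as a circular molecule with layout
LSC | IRa | SSC | IRb, where IRb is the reverse complement of IRa.
`detect_inverted_repeat()` finds the longest pair of non-overlapping
segments, one the exact reverse complement of the other, each at least
`min_ir_len` bases. Detection is seed-based: exact k-mer matches (k = 21)
between the sequence and its reverse complement are merged into maximal
runs per diagonal and extended exactly at the ends. For circular records
the search runs on the doubled sequence so origin-spanning placements are
found, and the result is reported on the canonical rotation that starts at
the LSC start (the rotation offset relative to the input is returned;
`canonical_rotation()` applies it, preferring a feature named *trnH* as the
start when one is annotated, which is the conventional linearization).

Parameters:

* `min_ir_len` (bp, default 10 000). Real legume IRs are ~25 kb;
  10 kb sits far above chance matches and far below real IRs. Genomes with
  no qualifying pair raise a *no IR found* error — the inverted-repeat-loss
  situation, which is a biological result, not a failure.
* `max_mismatch` (default 0). Exact matching is the default contract:
  within-genome IR copies are homogenized in vivo and clean duplications
  give a crisp, testable definition (detected partition = planted
  partition, exactly). Setting `max_mismatch > 0` enables a
  mismatch-tolerant mode for diverged or error-containing sequences:
  exact seeds of at least `min_ir_len/(max_mismatch+1)` bases (the
  pigeonhole bound) are extended by X-drop (+1 match, −3 mismatch,
  drop-off 12, capped at `max_mismatch` total mismatches). The X-drop
  score decays in unrelated flanking sequence, so extension self-terminates
  at the IR junctions; in the panel workflow this recovers the planted IR
  length exactly on tips carrying ~100 substitutions inside the IR.
* Tie-breaking: among equal-length candidates, the pair minimizing the
  first copy's start coordinate wins — determinism over optimality, since
  ties essentially only occur between shifted listings of the same IR.

LSC vs SSC assignment is by length (the longer single-copy segment is the
LSC). `gc_content()` is (G+C)/(A+C+G+T) with ambiguity codes and N excluded
from numerator and denominator; `ir_overlap_extent()` counts the bases of a
feature interval inside IRa ∪ IRb, origin-aware for circular records.
Coordinates are 1-based closed intervals throughout the R API (the
R/Bioconductor convention); GFF3 I/O is 1-based inclusive and BED output
0-based half-open, as those formats require.

## 2. Repeat detection

`find_maximal_repeats()` reports direct and palindromic (reverse-
complement) repeat pairs of at least `min_len` bases within `max_mismatch`
Hamming distance. The defaults — 30 bp and 3 mismatches, i.e. ≥ 90%
identity — are the criterion used throughout the comparative plastome
literature. Ambiguity codes never match anything, including themselves:
conservative, and it prevents spurious pairs through N runs.

**Maximality and locus canonicalization.** On a given diagonal (direct:
copy offset; palindromic: antidiagonal against the reverse complement),
for every budget b in 0..`max_mismatch` a *candidate window* is a segment
pair that cannot be extended at either end without exceeding b mismatches
or leaving the sequence. Enumerating all budgets reproduces the nested
same-locus listings of suffix-tree repeat finders (a 36-bp entry alongside
a 30-bp entry at the same position); reporting all of them would inflate
counts with staggered variants of one locus. The reported set is therefore
*locus-canonical*: per diagonal, candidates are ranked by (fewest
mismatches, then longest, then leftmost) and greedily selected, suppressing
any candidate that overlaps an already selected window. Consequences worth
knowing:

* An exact repeat copy is reported exactly once, with `mismatches = 0`,
  even though the budget would allow longer degenerate extensions.
* A family planted at k dispersed locations yields exactly C(k, 2) raw
  pairs — the combinatorial identity the consolidation stage then deflates.
* The tie-break is chiral: mirrored inputs can shift a reported locus by
  up to 2·`max_mismatch` bases between equally scoring staggered windows.
  Lengths, orientations and mismatch counts are mirror-invariant.

The search is seed-and-extend with exact k-mer seeds of length
`floor(min_len / (max_mismatch + 1))` (pigeonhole: every qualifying window
contains such a seed, so discovery is complete), merged into maximal exact
runs per diagonal before window enumeration. The test suite verifies the
whole contract against an independent exhaustive diagonal-sweep oracle on
hundreds of random and adversarial sequences (planted copies, N runs,
self-overlapping tandem arrays, both orientations).

The genome is treated as linear for the repeat search, matching the cited
tools' behaviour; the IR detector is the component that is origin-aware.

## 3. Repeat consolidation

Raw pair listings inflate repeat counts in two ways: a repeat at k
locations appears as C(k, 2) pairs, and near-identical sequences recur
across loci. The consolidation stage implements the deflation procedure:

* `classify_tandem()` — a pair is tandem when the gap from the end of the
  first copy to the start of the second is under 1000 bp (the strictest
  reading of "within 1000 bp of each other"; overlapping copies have
  gap ≤ 0 and are tandem).
* `filter_ir_duplicates()` — dispersed pairs whose two copies both lie
  entirely inside IRa ∪ IRb are expected consequences of the IR duplication
  and are dropped; pairs with at least one copy touching a single-copy
  region are kept. The structural IRa/IRb pair itself (the full-length
  palindromic match any whole-genome search necessarily reports) is
  excluded from all tallies by `drop_structural_ir_pair()` — it is the
  genome architecture, not a small repeat.
* `cluster_families()` — two stages. (i) Same-locus merge: instances whose
  intervals are nested or overlap by ≥ 80% of the shorter are one location
  (this absorbs the nested-length listings and 1–2 bp end jitter from
  flank extension). (ii) Single-linkage clustering at ≥ 90% ungapped
  identity over the shorter member, all offsets including dangling ends
  (overhangs count as mismatches, so 90% still requires 90% of the shorter
  sequence aligned and matching), reverse-complement aware. The 0.90
  threshold mirrors the search identity; the original analyses used
  interactive assembly software for this step, so the threshold is exposed
  as a parameter rather than claimed as the historical value.
* Family representatives are majority consensus over members aligned to
  the longest member, with IUPAC codes on ties (printed repeat consensus
  sequences in the literature carry such codes, e.g. M for an A/C tie).
  This consensus-calling is a reasonable reconstruction, not validated
  against the original software.

`summarize_repeats()` reports the Table-2-style row: raw pairs, tandem
pairs, dispersed unique sequences and unique locations.

## 4. Diversity and rates

`count_pairwise_snps()` uses pairwise deletion: a column counts for a pair
only when both rows carry an unambiguous base. This excludes indel
polymorphisms from the counts (plastome comparisons treat indels
separately) and makes π = S/L exact for two sequences.
`nucleotide_diversity()` is the average of per-pair π over all unordered
pairs, without finite-sample corrections (recorded in output metadata by
being the only definition in the package).

`substitution_rate()` is r = S / (L · T). The default divides by T, not 2T:
back-calculation from published rate tables (≈2000 SNPs, T = 5.25 × 10⁶
years, r ≈ 2.5 × 10⁻⁹ implies L ≈ 158 kb — a plastome alignment length,
whereas 2T would imply ~79 kb) shows the convention treats the calibration
date as measuring the whole tip-to-tip path. `per_lineage = TRUE` gives the
2T convention. Calibration dates are explicit caller input
(`calibration_table()`), because the mapping of node dates to taxon pairs
is a scientific choice, not something the package should guess.

`rate_matrix()` lays out SNPs above and rates below the diagonal and flags
cells whose rate falls below `flag_factor` (default 0.5) times the median
off-diagonal rate of their row. A rate far below its row's typical value
means the calibration date overestimates the plastome divergence — the
chloroplast-capture signature. The 0.5 default separates the ~3.5-fold
depressions seen in captured-plastome comparisons from ordinary rate noise
(tens of percent); it is a reporting aid, not a test statistic.

`windowed_identity()` is the sliding-window identity series behind
percent-identity plots: per non-reference row, matching unambiguous columns
/ comparable columns per window (default 100 columns, step 25), NA where a
window has no comparable column. `drop_second_ir()` removes the IRb columns
before rate computation, the convention for plastome-wide statistics (the
second IR is a duplication, not independent evidence).

## 5. The synthetic-plastome generator

`generate_plastome()` emits LSC | IRa | SSC | IRb with i.i.d. background at
`gc_target` (default 0.353, the legume plastome value), planted repeat
families, border genes, and a truth record containing the partition, every
planted instance (position, strand, mismatches, realized sequence — IR
mirrors included and flagged), and a config echo including the seed.
Determinism is a contract: same config and seed, byte-identical output.

What it emulates, and what it does not:

* The i.i.d. background is the simplest model that makes planted structure
  detectable and accidental structure negligible: at 10⁻⁵ the probability
  of an accidental exact ≥ 30-bp repeat in a 50-kb genome. A
  post-generation scan rejects (and regenerates under a new attempt) any
  accidental exact 30-mer duplication, direct or palindromic, not explained
  by planted copies; near-exact accidental pairs (1–3 mismatches) are not
  scanned for — probability ~10⁻³ per genome — so fixed-seed tests are
  deterministic and unaffected. Real plastomes are not i.i.d.: they carry
  genes, codon structure, and AT-rich spacers. Passing tests on synthetic
  genomes therefore validates the *algorithms' contracts*, not their
  behaviour on low-complexity regions, which real data would exercise
  harder.
* Junction bases are resampled so the planted IR cannot extend by chance
  reverse-complementarity at its boundaries, and planted copies keep 1 bp
  clear of region ends: the planted partition is exactly the maximal IR,
  which is what makes "detected = truth, exactly" a fair assertion.
* Mismatch edits across copies of a family are drawn from disjoint
  position pools when possible, so pairwise copy distances are exactly
  m_i + m_j and detectability under the Hamming budget is predictable.
* Border genes are annotations only (they do not change the sequence) and
  alternate between the LSC/IRa and SSC/IRb junctions.
* Not modelled: real gene content (111 genes), introns, codon models,
  rate heterogeneity among sites, indels, IR expansion/contraction.

`evolve_sequences()` evolves an ancestor along an `ape` tree with branch
lengths in years: per branch of t years, Binomial(L, r·t) sites are drawn
without replacement and each receives one of the three other bases
uniformly. This keeps realized per-branch substitution counts unbiased in
the small-divergence regime the package targets (r·t well below 0.1;
the constructor rejects r·t > 1). Multiple hits within a branch are not
modelled, and coincident hits on two lineages shrink pairwise differences
by ~0.3% at the simulated divergences — well inside the 3-standard-error
bands the recovery tests use. There are no indels, so tip sets are aligned
by construction. For two-taxon rate recovery, `two_taxon_tree(T)` builds
two branches of T/2: the calibration time measures the tip-to-tip path,
matching the divide-by-T rate convention above.

## 6. Problem sizes and runtimes

The shipped tests and workflow run at deliberately scaled sizes: panel
genomes of ~20–37.5 kb (¼ of a real plastome), oracle-equivalence sweeps on
hundreds of sequences of 0.12–2 kb, IR-detection sweeps over 50 genomes of
36 kb, and 50-replicate rate recovery at L = 50 kb over T = 5.25 × 10⁶
years at r = 2.7 × 10⁻⁹. These sizes exercise every code path (including
full-scale detection on one 152,794-bp synthetic genome with the published
architecture) while keeping the whole suite in the minutes range; all
algorithms are linear or near-linear in genome length and run comfortably
at real plastome scale.

## 7. Known limitations

* The locus-canonical repeat report is a deliberate deviation from "list
  every maximal window": it trades the inflated nested listings for a
  deterministic one-pair-per-locus contract. Raw REPuter-style totals are
  therefore not digit-for-digit reproducible from real genomes, and are
  not claimed to be; the consolidation-level quantities are the stable
  comparison points.
* Tie-break chirality (Section 2) means mirrored inputs can report a locus
  shifted by a few bases.
* `cluster_families()` is O(m²) in instances with O(len²) identity
  scoring — fine for plastome repeat counts (tens of instances), wrong
  tool for repeat-dense nuclear genomes.
* The mismatch-tolerant IR mode's X-drop parameters (+1/−3, drop 12) are
  conventional seed-extension values, validated on simulated divergence,
  not fitted.
* Real-data validation of Table-1-style numbers uses a synthetic genome
  built to the published architecture (the package ships no real GenBank
  sequence); lengths and border-gene extents are deterministic and exact,
  realized GC is binomial around its target.
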