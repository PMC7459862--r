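---
title: "Alignment-free degenerate primer design from k-mer frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free degenerate primer design from k-mer frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerprimer)
```

## The idea

Degenerate PCR primers for functional genes are conventionally designed on a
multiple sequence alignment: conserved columns become primer positions, and
column variability becomes degeneracy. Alignment is the bottleneck — its
cost grows steeply with database size, and misalignment silently destroys
conservation signal. `kmerprimer` uses a different observable: if a region
of length *k* is conserved across a database, the *same k-mer* must occur in
many sequences, so conserved loci are exactly the high-frequency entries of
a k-mer count table. Counting k-mers is linear in total database size and
needs no alignment at all.

The pipeline is a composition of small, individually testable operations:

1. **Preprocessing** (`load_fasta()`, `trim_by_length()`, `dedupe_exact()`):
   sequences are upper-cased, U→T, ambiguity codes other than N collapsed to
   N; exact duplicates are removed so highly resequenced strains do not
   inflate frequencies.
2. **Counting** (`count_kmers()`): for each k in the primer length range,
   every N-free window is tabulated with its total occurrence count and its
   *per-sequence hit fraction* (`seq_fraction`), the fraction of sequences
   containing it at least once. Counting is strand-specific; reverse primers
   arise later by explicit reverse complementation.
3. **Merging** (`merge_overlapping()`): two high-frequency k-mers that
   overlap by more than *x* bases are assumed to be offset reads of the same
   conserved locus and are grouped transitively; the group survivor is the
   highest-count k-mer (ties: longer, then lexicographically smaller, so the
   output is byte-deterministic).
4. **Degenerate combination** (`combine_variants()`): every k-mer at Hamming
   distance exactly 1 from a surviving seed whose `seq_fraction` reaches the
   variant floor is folded into the seed as an IUPAC code — the base set at
   the differing position becomes the union. Absorption runs in descending
   `seq_fraction` order and stops before the degeneracy cap would be
   exceeded, so the most informative variants are folded in first.
5. **Assessment** (`primer_coverage()`, `pair_and_report()`,
   `specificity()`, `breakdown_by_rank()`, `breakdown_by_phenotype()`).

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `primer_len_min/max` | 18–20 bp | k-mer (primer) length range |
| `product_min/max` | 200–500 bp | accepted amplicon length, primers inclusive |
| `min_coverage` | 0.2 | floor on the emitted primer's database coverage, also used as the frequency floor during candidate selection |
| `overlap` | 10 bases | merge k-mers overlapping by more than this |
| `variant_min_fraction` | 0.01 | `seq_fraction` floor for Hamming-1 variant absorption |
| `max_degeneracy` | 64 | cap on expansions per primer |
| `top_n` | 30 | high-frequency ranks considered per k |
| `max_mismatches` | 0 | matcher mismatch budget |
| `fold_temp`, `mg`, `na` | 57 °C, 20 mM, 0 mM | folding conditions for ΔG |

Notes on the less obvious choices:

* **`min_coverage` in selection.** A seed whose own hit fraction is already
  below the acceptable output coverage can only cross the floor through
  degeneracy; in practice conserved loci present a dominant consensus, so
  filtering candidates at the same floor prunes the search drastically
  without losing designs, and the realized (post-combination) coverage is
  re-checked before a primer is emitted.
* **`max_degeneracy` = 64.** The degeneracy cap keeps GC%/Tm ranges
  informative (a primer of unbounded degeneracy has vacuous property
  ranges), keeps expansion-based computations cheap, and matches the
  degeneracy scale of published functional-gene primers. Absorption simply
  stops at the cap; it never emits a partially widened position.
* **Tm at exactly 20 bp.** The two Tm rules leave 20 bp to convention; the
  Wallace rule is used for L ≤ 20, which reproduces the published property
  tables for every 20-bp primer we checked.
* **Mismatch budget default 0.** Coverage is then a statement about exact
  IUPAC-set membership, which is what degeneracy is meant to buy; a nonzero
  budget is available for sensitivity analyses and can only increase
  coverage (a tested invariant).

## The in-silico matcher

Binding sites are found by a deterministic window scan: sequence bases are
bit-encoded (A/C/G/T/N one bit each), primer positions carry the bitmask of
their IUPAC set, and a window matches when every position has a non-empty
intersection, up to the mismatch budget. Two semantic decisions are explicit
and tested:

* a database N matches only a primer N — an unknown base is never evidence
  for a binding site;
* a reverse primer is stored 5'→3' as synthesized and its binding site is
  located by matching its reverse complement on the sense strand.
  `pair_and_report(rev_sense = TRUE)` handles the designed-primer case where
  both pair members are sense-strand k-mers, reporting the synthesized
  (reverse-complemented) sequence for the reverse member.

Amplicon arithmetic: for a forward site starting at *s* and a reverse site
ending at *e* (1-based, inclusive), the product length is *e* − *s* + 1,
primers included. Per covered sequence the shortest in-range product is
recorded; the reported mode is the most frequent recorded length with ties
going to the smallest, so reports are deterministic.

## Self-folding ΔG

Hairpin free energy is computed with a transparent nearest-neighbor model:
all structures with a Watson–Crick stem of ≥ 3 pairs and a loop of ≥ 3
bases are enumerated, scored as the sum of SantaLucia unified stack energies
ΔG = ΔH − TΔS at the folding temperature plus a tabulated hairpin-loop
penalty (Jacobson–Stockmayer extrapolation between tabulated sizes; the
loop term is treated as entropic and scaled with absolute temperature), and
the minimum is returned (0 when no qualifying hairpin exists). Ionic
conditions enter as the standard sodium-equivalent entropy correction of
0.368·ln[Na⁺eq] cal mol⁻¹ K⁻¹ per stack, with Na⁺eq = [Na⁺] + 120·√[Mg²⁺]
(mM). The Mg²⁺/Na⁺ inputs are interpreted as mM. This model is deliberately
simple — no bulges, internal loops, dangling ends or partition function —
and its values are indicative screening numbers, not mfold-compatible ones.
The tests pin it to an independent exhaustive stem/loop enumeration oracle
on short sequences.

## The synthetic-data generator

`generate_database()` produces uniform-ACGT background sequences with
planted motifs and returns an exact manifest (carrier, coordinate, variant)
as ground truth. Design choices:

* carrier counts are deterministic (`round(fraction × n)`), so recovered
  coverage can be asserted exactly;
* variant carrier sets are disjoint — each carrier differs from the
  consensus at no more than one position — so the planted truth is exactly
  recoverable under the Hamming-1 absorption rule and planted coverage
  equals the carrier fraction;
* paired motifs plant the reverse complement of a given reverse-primer
  sequence at an exact amplicon spacing, giving a known product-length mode;
* all randomness is seeded and confined to the generator; the analysis path
  is RNG-free, which is what makes whole-pipeline reruns byte-identical.

What the generator does **not** emulate: phylogenetic correlation between
sequences, indels and alignment ambiguity, GC-content skew, sequencing
error, or partial gene fragments. Passing the recovery tests therefore
demonstrates correctness of the counting/merging/absorption machinery under
the stated model, not performance on real gene databases, where conserved
regions are shaped by selection rather than planted verbatim.

Validation-suite problem sizes were chosen to exercise every code path at
desk scale: recovery runs use 20 databases of 100 sequences × 600–800 bp
with the primer length fixed to the planted motif length (20 bp; with mixed
k, sub-k-mers of the motif are equally frequent and tie in coverage, which
only obscures the assertion), matcher and property oracles use hundreds of
randomized cases, and the folding oracle uses sequences up to 30 bp.

## Numerical conventions

* Reported percentages and property ranges are rounded half away from zero
  to 2 decimals, matching fixed-point table style; internal computations are
  unrounded.
* GC%/Tm ranges are computed from per-position set membership (minimum =
  positions forced G/C, maximum = positions that can be G/C); this equals
  brute-force extremes over expansions (tested) at any degeneracy.
* Every ordering in the pipeline is a total order (count → length →
  lexicographic; coverage → IUPAC string), so outputs carry no hidden
  platform or hash-order dependence.
* Coordinates are 1-based inclusive in all user-facing structures.

## Known limitations

* Coverage is exact-match (IUPAC-set) based, not thermodynamic: a primer
  with one terminal mismatch may amplify in practice but counts as a miss at
  `max_mismatches = 0`; conversely 3'-end mismatches are not penalized
  extra.
* Only Hamming-distance-1 variants of the seed are folded in; a conserved
  locus whose variation is spread over two positions in the same molecule is
  represented only up to the variants' marginal frequencies.
* The overlap-merge heuristic can, in principle, chain distinct loci that
  share long repeats; the transitive grouping is deliberate (it mirrors how
  offset k-mers tile one locus) but repetitive gene families deserve a check
  of the emitted seeds.
* The ΔG model's scope is stated above; use a full secondary-structure
  package where accurate folding energies matter.
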