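---
title: "Closing scaffold gaps through a Bloom filter de Bruijn graph"
author: "gapclosr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closing scaffold gaps through a Bloom filter de Bruijn graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapclosr)
```

## The problem

Short-read assemblers order and orient contigs into scaffolds, but the
sequence between contigs often cannot be resolved and is written as a run
of `N` characters whose length is only an estimate from the fragment-size
distribution. Much of that missing sequence is nevertheless present in the
raw reads: it simply was not assembled, typically because of locally low
coverage or repeats. gapclosr re-assembles each gap locally, directly from
the reads, and splices successful reconstructions back into the scaffolds.

The design goal inherited from the tools this package emulates is
scalability: the only genome-wide data structure is a Bloom filter over
k-mers, a few bits per k-mer, so the approach extends to very large read
sets. Everything else is per-gap work.

## The graph: a multiplicity-thresholded Bloom filter

All k-mers of the reads are inserted, in *canonical* form (the
lexicographically smaller of a k-mer and its reverse complement, so both
strands index the same node), into a cascading Bloom filter with
`threshold` levels. Each occurrence of a k-mer advances it by one level; a
k-mer present in every level is *solid*. With the default `threshold = 2`,
k-mers seen once — which is what most sequencing-error k-mers are — never
become solid and are invisible to the traversal. The filter has one-sided
error: no false negatives, and a false-positive rate per level of
approximately `fill_ratio ^ num_hashes`.

The solid set is queried as an *implicit de Bruijn graph*: the neighbors
of k-mer `x` are the solid k-mers `x[2:k] + c` (right) and `c + x[1:k-1]`
(left) for `c` in A, C, G, T. No adjacency is ever stored.

Two hashing details matter for correctness and reproducibility:

* **Double hashing.** Bit positions are `h1 + i * h2` for `i` in
  `0..num_hashes-1`, with `h1`, `h2` derived from the canonical k-mer
  string and a fixed recorded seed, so identical inputs give identical
  filters on any platform.
* **Per-level seeds.** Each cascade level hashes with its own derived
  seed. If the levels shared one hash family, a top-level hit would imply
  hits in every lower level (same bit positions, superset content) and the
  cascade's false-positive rate would collapse to that of a single level;
  with independent per-level hashing the solid-query estimate is the
  product of the per-level rates, which is what `bloom_fpr()` reports and
  what the package's randomized tests verify empirically.

## Connecting a gap

For each gap the pipeline extracts the `min_flank` (default 100 bp) clean
bases on each side and then:

1. **Anchoring** (`find_anchor()`): scan candidate k-mers from the gap
   edge inward and take the first solid one on each side. The bases
   between the anchor and the gap edge (`trim`) are *replaced* by
   assembled sequence, which lets the connection correct
   micro-misassemblies at the flank tip.
2. **Path enumeration** (`enumerate_paths()`): a depth-limited,
   bidirectional, breadth-first search. One frontier extends rightward
   from the left anchor, the other leftward from the right anchor,
   alternating one level at a time (left first). Every walk endpoint is
   recorded per depth together with its predecessors, and complete paths
   are assembled wherever the two search DAGs share a k-mer at compatible
   depths. All distinct paths within the depth limit are enumerated. A
   path may not visit the same k-mer twice in the same orientation — this
   bounds walks through tandem repeats while still allowing a path to
   traverse both arms of an inverted repeat.
3. **Consensus** (`consensus_paths()`): a single path is reported
   verbatim (`unique`); 2 to `max_paths` paths of equal length are merged
   column-wise, writing the IUPAC code of the observed bases at
   mismatching columns (`consensus`) — a heterozygous site inside a gap
   becomes a single ambiguity column rather than an arbitrary choice of
   haplotype.

The search is fail-closed, with one status per failure mode: exceeding the
live-branch cap `B` aborts the whole gap (`branch_limit`); more than
`max_paths` distinct paths is `too_many_paths`; frontiers that exhaust
without meeting give `no_path`; hitting the depth limit everywhere gives
`length_limit`. Output is all-or-none: a gap is either replaced by a
complete N-free product or left untouched.

### Search limits and their meaning

| parameter | default | meaning |
|---|---|---|
| `k` | sweep 90..40 | k-mer length (bp) per pass |
| `threshold` | 2 | k-mer multiplicity required for solidity |
| `min_flank` (`L`) | 100 bp | required clean flank; also the extracted flank length |
| `max_paths` (`P`) | 2 | maximum path multiplicity reported as a connection |
| `max_branches` (`B`) | 3000 | cap on live branches, summed over both frontiers |
| `max_frag` (`F`) | 5000 bp | cap on the full product, anchor to anchor inclusive |
| `bloom_size` | "16M" | total filter memory, split equally across levels |

`F` caps the *product* (kept flanks plus interior), mirroring the maximum
fragment-length semantics of paired-read connection; the search depth
limit is derived from it as `F - kept_left - kept_right + k` edges. `B`
counts branches summed over both frontiers; the alternative (per
frontier) is not distinguishable from the outside and the total is the
fail-safe reading.

## The k sweep

Gap-closing yield depends on k in two opposing ways: long k-mers span and
disambiguate repeats but need high coverage to be observed `threshold`
times; short k-mers tolerate low coverage but tangle the graph. The
pipeline therefore runs a sweep of k values, by default descending from
90 to 40 in steps of 10 (40 bp being a practical lower bound below which
random k-mer collisions make traversal unreliable, and large-k-first
being preferred since it resolves repeats). After each pass the closed
gaps are removed from the open set (*subtractive* iteration) and the
filter is discarded, so exactly one Bloom filter is in memory at any
time; reads given as files are re-streamed for each k.

## Updating the scaffolds

Replacement products are spliced over the window spanning the gap and
both extracted flanks, processing gaps within a scaffold from 3' to 5'
(right-most first) so that length changes never shift the coordinates of
gaps still to be processed. Length disagreements between the N-run and
the product are ignored by design — gap lengths are estimates. When two
gaps sit closer than `2 * min_flank` their windows can overlap; the
right-most closure wins and the conflicting one is dropped and logged.
Coordinates are 0-based and half-open everywhere, stated in the headers
of the TSV outputs.

## The synthetic-data generator

`simulate_dataset()` produces the package's study conditions: an i.i.d.
random genome at a configurable GC fraction (optionally with planted
exact repeats), paired-end reads with Gaussian fragment lengths and
i.i.d. per-base substitution errors, and a draft in which known windows
are masked by N-runs whose written lengths mis-state the truth by a
configurable signed fraction. The defaults are the reference validation
scenario used throughout the tests: a 100 kbp non-repetitive genome,
2 x 100 bp pairs at 50-fold coverage, no errors, and 20 gaps of 50-500 bp
with the written N-run length off by a uniform factor in ±20 % — the kind
of mis-estimation that fragment-library-derived gap sizes show in
practice. Each operation draws from its own RNG stream derived from
`(seed, operation name)`, so genome, reads and draft are individually
reproducible.

What the generator deliberately does **not** model: indels and
platform-specific error profiles (the multiplicity threshold, which is
what the fixtures exercise, acts on substitution-dominated error k-mers);
coverage biases; diploidy beyond the two-haplotype consensus fixture; and
real repeat landscapes (planted repeats are exact copies). Passing tests
on these fixtures therefore demonstrate the correctness of the machinery
— graph construction, search, consensus, splicing, accounting — under the
stated statistical assumptions, not closure rates on real genomes, where
repeat structure dominates the failure modes.

## Assessment

`count_gaps()` counts maximal N-runs (ambiguity codes are not N).
`extract_inserted()` recovers what was placed into each gap without
trusting the pipeline's own records: the 100 bp flanks of each original
gap are located in the filled scaffold — exactly at their draft
coordinates first, then scaffold-wide, allowing progressively more
gap-facing flank bases to have been corrected — and the bases strictly
between the unique anchoring are reported; ambiguous anchorings are
counted as unassessable rather than guessed. `seq_similarity()` scores a
query against the truth by global alignment with unit scoring (gaps cost
nothing, so the optimum is the maximum number of matching bases), where a
query ambiguity code aligned to any base of its IUPAC set counts as a
match — ambiguity is not penalized; the reported value is
`100 * matches / nchar(query)`. The alignment itself is delegated to
`Biostrings::pairwiseAlignment()` with a 0/1 IUPAC-compatibility
substitution matrix. An *exact* match means some IUPAC-consistent
resolution of the insert equals the truth. A 95 % similarity threshold,
often used as a reporting cutoff in assembly evaluation, is available as
an optional summary field, not a hard filter.

## Numerical and design choices

* **Canonical form** is the lexicographic minimum of the two strands:
  deterministic, strand-neutral, standard.
* **Consensus is restricted to equal-length path sets.** Column-wise
  IUPAC merging is only well defined for equal lengths;
  alignment-based merging of unequal paths would introduce arbitrary gap
  placement into reported sequence. Unequal-length path sets leave the
  gap open, reported under `too_many_paths` (the set is too ambiguous to
  merge) since the status vocabulary is fixed.
* **Zero-length connections** (`start == goal`, overlapping flanks) are
  legal and yield the anchor k-mer itself as the path.
* **Within-read duplicate k-mers** count as separate occurrences; the
  threshold is about coverage, and per-read deduplication would
  complicate streaming for no modelled benefit.
* **Degenerate inputs:** flanks shorter than k give `no_anchor`;
  `max_frag` smaller than the kept flanks gives `length_limit`; a
  scaffold whose N-runs touch its ends yields no gap records; ambiguity
  codes in scaffolds (e.g. from a previous closing pass) are treated
  like N for flank validity and k-mer extraction — they are not solid
  bases.
* **Tie-breaks:** neighbor expansion and path discovery use the fixed
  base order A < C < G < T; identical spelled sequences found via
  different meeting points are collapsed before counting against
  `max_paths`.
* **Filter sizing:** the constructor warns when the top level's
  estimated false-positive rate exceeds 5 %. For desk-scale work the
  defaults are generous; for real read sets, size the filter to a few
  bits per expected distinct k-mer per level.

## Validation scale

The test suite validates the search against an exhaustive depth-first
enumeration over an exactly counted k-mer set (an independent
implementation kept deliberately free of Bloom filters and bidirectional
logic) on 20 random 2-5 kbp genomes, 100 flank pairs in all, and runs the
reference scenarios end to end: the 100 kbp error-free dataset described
above, the same genome at 60-fold coverage with 1 % substitution errors
(with threshold 1 as a contrast, showing the multiplicity filter is what
absorbs the errors), a two-haplotype consensus fixture, and a
100,000-insertion Bloom filter contract check. These sizes keep the whole
suite within a few minutes on one core while leaving every moving part
exercised; closure rates on the error-free scenario are expected to be at
or near 100 %, with every closed gap restoring the masked sequence
exactly.

## Limitations

* Only substitution-style variation can be expressed in a consensus;
  indel-divergent alleles fail the gap (by design, all-or-none).
* A Bloom false positive can in principle admit a spurious path; the
  probability is controlled by filter sizing and reported by
  `bloom_fpr()`, and the product-level soundness (every reported k-mer
  solid) is still guaranteed, but solidity itself is probabilistic.
* Gaps whose flanks are themselves repetitive may anchor ambiguously at
  assessment time and are reported unassessable rather than scored.
* The pipeline trusts gap coordinates within a single run; it does not
  re-validate that flanks still match the scaffold at apply time.
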