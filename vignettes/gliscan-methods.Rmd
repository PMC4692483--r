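---
title: "Methods: homotypic Ci/Gli cluster detection with a GC-preserving background"
author: "gliscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homotypic Ci/Gli cluster detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliscan)
```

## The problem

Ci/Gli transcription factors mediate Hedgehog signaling by binding a
GC-rich ~9 bp motif. Enhancers that respond to Hedgehog often carry
several such sites within a short span, so homotypic clustering is a
usable signal for enhancer nomination. The statistical difficulty is the
motif's GC richness: the consensus site is 6/9 (67%) GC while a typical
fly genome is well under 50% GC, so apparent "clusters" arise by chance in
any GC-rich stretch. A sound enrichment test therefore needs a null model
that preserves the genome's local GC landscape, and a correction for the
fact that randomized sequence systematically carries fewer motif matches
than real sequence.

## Site model

A position weight matrix is reduced to three ingredients:

* **CIV (consensus index vector)** — per-position preference strength,
  `civ(i) = (100/ln K) · Σ_b f(i,b) ln(K f(i,b))` with `0·ln 0 := 0` and
  `K = 4` by default. This anchors a uniform row at 0 and a single-base
  row at 100, and increases strictly from uniform toward degenerate. A
  5-letter normalization (`K = 5`, the gap-inclusive convention of some
  matrix suites) is available via `alphabet_size`; it shifts the zero
  point upward and is provided only for compatibility.
* **Core positions** — the leftmost maximal contiguous run of positions
  with CIV > `civ_min` (default 70). The run length is the scan width; for
  the Ci matrix this is the first nine of eleven positions. When several
  runs tie, taking the leftmost one is a determinism choice; the motif
  model assumes a single informative core, and a matrix with several
  separated informative blocks is outside this model.
* **MSS (matrix similarity score)** — the CIV-weighted match score of a
  core-width sequence normalized by the consensus score, so
  `MSS(consensus) = 1` and `MSS ∈ [0, 1]`. MSS is invariant to positive
  rescaling of the CIV weights.

The **site vocabulary** enumerates all `4^w` core-width k-mers and keeps
those with `MSS ≥ min_mss` (default 0.75) that carry identical C/C or G/G
bases at core positions 4 and 6 — positions critical for Ci binding — plus
the exact reverse complements, which inherit their sense partner's MSS.
Scanning is an exact dictionary match (Aho–Corasick via
`Biostrings::matchPDict`) of this fixed vocabulary; windows containing N
never match. A window whose string matches in both orientations is
reported once with the higher-MSS orientation (`+` on ties); the
alternative of double-counting such windows is available via
`merge_duplicates = FALSE` because the original convention is not
documented, and the choice shifts cluster site counts only in the rare
dual-match case.

## Background model and composition correction

Three randomizations are implemented; only the third is used for
inference:

1. `bg_random` — every base redrawn uniformly. Destroys composition
   entirely.
2. `bg_shuffle3mer` — the sequence is cut into contiguous non-overlapping
   3-mers which are shuffled; a trailing remainder of 1–2 bases stays in
   place (the simplest rule consistent with parsing into contiguous
   3-mers). Preserves global 3-mer and mononucleotide composition but
   homogenizes it locally.
3. `bg_flip_gc_at` — every base independently becomes itself or its
   complement with probability 1/2. This preserves the GC/AT identity of
   every position, hence the GC content of every window of every width,
   exactly. The flip probability is exactly 1/2 with no bias, the
   maximum-entropy choice given the constraint.

Profiling flank GC around site coordinates (`gc_context_profile`, 50 bp
per side, site bases excluded) shows why: the flip model reproduces the
native flank GC per site exactly by construction, while models 1 and 2
pull it toward a genome-wide average. Since Ci/Gli sites live
preferentially in GC-rich context, a homogenizing null would overstate
enrichment in GC-rich regions and understate it elsewhere.

Flipped chromosomes still carry fewer vocabulary matches than native
sequence wherever the native genome is motif-enriched. Left uncorrected
this would inflate every cluster's enrichment, so the expected counts are
computed from **composition-corrected** replicates: `n_raw` raw flipped
genomes (default 1000) are scanned and every hit pooled into a master
list of possible site positions (duplicates retained; sampling is uniform
over pool entries); then `n_replicates` background site maps (default
100) are rebuilt by drawing, per k-mer, exactly the native count of
positions from that k-mer's pool. The per-k-mer equality is exact in
every replicate, not approximate — this is asserted exhaustively in the
test suite. Numerical details:

* Within-replicate coordinate collisions are resolved by rejection
  resampling (up to 1000 attempts per site, then an error advising a
  larger `n_raw`). Site maps must have unique intervals.
* If a k-mer's native count exceeds its distinct pooled positions, the
  missing positions are borrowed from pooled sites of the same MSS class
  (MSS rounded to 0.01) and relabeled with the native k-mer, with a
  warning. Relabeling keeps the composition invariant exact; the borrowed
  positions are equivalent under the null in affinity class, which is what
  the expected count integrates over.
* The corrected statistic is insensitive to `n_raw` because the pool only
  needs to cover position diversity; the test suite and the examples use
  10–150 raw replicates, and a deeper pool is only needed when rare
  k-mers are native.

## Cluster statistic and filter cascade

Candidate clusters are windows of `min_sites`–`max_sites` (3–10)
consecutive sites whose end-to-end span (outside ends) is at most
`max_span` (1000 bp, boundary inclusive — a span of exactly 1000 passes).
For each window,

* `expected` = mean, across ensemble replicates, of background sites
  **fully contained** in the window interval (containment is symmetric
  with the span definition, which also uses outside ends);
* `CC = n_sites / max(expected, expected_floor)` with
  `expected_floor = 1/n_replicates` — the smallest observable nonzero
  expectation. The floor keeps CC finite and monotone when no background
  site falls in the window; CC is never defined by division by zero.

Filters (flag order is cosmetic; the pass decision is a conjunction):
`CC ≥ 4`; best member site `MSS ≥ 0.81` (drops clusters made entirely of
weak sites); no member site overlapping an exon or repeat interval by
≥ 1 bp; member-site bases ≤ 25% of the span, with overlapping site bases
counted once (union) — windows denser than that are dominated by
repetitive sequence. Failed windows are retained with per-filter flags so
stage counts always reconcile.

Passing windows that share at least one member site are merged into one
reported cluster: the representative is the window with the most sites,
ties broken by higher average MSS, then leftmost start. Groups with
disjoint site sets stay separate, so adjacent clusters split by a span gap
are reported individually. The merge rule is a reporting decision — all
candidate windows are preserved in the verbose window table. Reported
clusters are ranked by average MSS (descending), then site count, then
coordinate; average MSS favors clusters whose every site is plausibly
bound, whereas CC is used strictly as a filter, not a ranking key.

## Annotation and orthology

refFlat gene models give nearest-transcript annotation: distance is the
unsigned gap between interval hulls (0 when overlapping), ties broken by
transcript name order; the feature label is exon/intron/upstream/
downstream relative to transcript strand. Gene-body (hull) distance is
used rather than TSS distance; the TSS convention can be recovered by
collapsing models to 1 bp starts if needed. Locus assignment splits each
intergenic gap at its midpoint; a site exactly on a boundary goes to the
lower-coordinate locus (deterministic tie). CTCF boundaries are consumed
as a plain interval set and annotated by nearest distance only.

The orthology filter consumes cluster intervals already lifted into the
analysis assembly's coordinates and keeps clusters with ≥ 1 bp positional
overlap, ignoring sequence identity; coordinate mapping between
assemblies is out of scope.

## Synthetic fixtures

`simulate_genome` draws background bases segment by segment at requested
GC fractions, plants vocabulary k-mers at fixed offsets (minus-strand
plants store the reverse complement), and can scrub decoys by
re-randomizing any unplanted vocabulary match (touching only non-planted
bases, bounded retries). Scrubbed fixtures give exact ground truth for
unit tests; unscrubbed ones give realistic chance-hit rates for
statistical tests. The generator emulates a piecewise-constant GC
landscape and motif enrichment; it does not emulate repeat families,
dinucleotide structure, chromatin, or evolutionary divergence (the
orthology filter needs only intervals), so passing tests demonstrate
correctness of the algorithms, not biological performance on real
genomes.

Default study-scale choices used across tests and the acceptance script:
100 kb chromosomes at 43–45% GC (a realistic fly-genome GC), planted
clusters of 3–5 sites within 800 bp spans, 50 raw / 20 corrected
background replicates for recovery experiments and 100 corrected
replicates where the composition invariant itself is under test. These
sizes keep the full pipeline in the seconds range while leaving every
statistic at its default threshold.

## Reproducibility

All generators consume R's global RNG; the pipeline wrappers accept an
explicit `seed` applied with `withr::with_seed` so a run is a pure
function of (inputs, seed). Derived stage seeds are small fixed offsets
of the run seed. Two runs with the same seed are bit-identical; runs with
different seeds share the native scan and, on strongly planted fixtures,
the reported cluster set.

## Known limitations

* CC is a ratio against a Monte-Carlo expectation, not a calibrated
  p-value; no multiplicity control is attempted.
* The exact CIV normalization of the original matrix software is not
  public; the `K = 4` entropy form used here matches its documented
  endpoints but reproducing a published vocabulary exactly also requires
  the original (proprietary) matrix.
* Enumerating the vocabulary is `4^w` and is refused above width 12 by
  default.
* Background generation is single-threaded; full-genome analyses with
  1000 raw replicates are batch jobs, not interactive calls.
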