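---
title: "Comparing, benchmarking and merging structural variants with svmatchr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing, benchmarking and merging structural variants with svmatchr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svmatchr)
```

## The problem

Two callsets rarely describe the same structural variant (SV) with the same
VCF record. Alignment ambiguity in and around repeats shifts breakpoints,
assemblers disagree on insertion lengths by a few bases, and the same allele
can be left- or right-shifted by hundreds of base pairs while producing an
identical sample haplotype. Any analysis that needs to decide whether two SV
records are "the same variant" — benchmarking a caller against a truth set,
or merging per-sample callsets into a project-level VCF — therefore needs a
quantitative notion of SV similarity and a deterministic procedure for
turning pairwise similarities into matches. svmatchr implements such an
engine for sequence-resolved deletions and insertions (inversions and
duplications pass through the same machinery; unresolved breakends are
excluded).

## Record model and coordinates

Internally every record is normalized to 0-based half-open coordinates:

* a deletion's `start` is its first deleted base and `end - start` equals
  its length, so the deleted interval is exactly `[start, end)`;
* an insertion spans only its anchor base, `end = start + 1`. This
  convention is deliberate: the reference-distance test below is a *strict*
  inequality, and a true zero-width insertion interval would make it fail
  even for identical records.

Records must carry one ALT allele each; multiallelic rows are rejected with
a pointer to upstream splitting (`bcftools norm -m-any`). Left-alignment and
indel normalization are likewise upstream concerns.

## The four similarity metrics

For records with spans `[S1, E1)` and `[S2, E2)` and lengths `L1`, `L2`:

* **Reference distance.** The pair is positionally comparable when
  `max(S1 - refdist, S2) < min(E1 + refdist, E2)`. Note this is a
  span-based test: two long deletions shifted by more than `refdist` can
  still be comparable while their spans overlap; for insertions (1 bp
  spans) it reduces to an anchor-distance test.
* **Reciprocal overlap.** Shared bases divided by the larger span.
  Insertions have no physical reference span, so each insertion's span is
  first expanded by half its length upstream and downstream. The
  denominator is the maximum *span length* — the corresponding printed
  expression is a coordinate, but a coordinate is not a length and the
  accompanying prose ("over the maximum variant span") decides the reading.
* **Size similarity.** `min(L1, L2) / max(L1, L2)`.
* **Sequence similarity.** Both variants are applied to the shared
  reference context `[min(S1,S2), max(E1,E2))`, giving two local haplotypes
  `H1`, `H2`; the score is `1 - ed(H1, H2) / (|H1| + |H2|)` with `ed` the
  Levenshtein distance (computed by `utils::adist`, and checked against an
  independent dynamic-programming oracle in the test suite). Identical —
  including empty — haplotypes score 1.

The `1 - ed/totlen` normalization has a documented quirk: because `totlen`
sums *both* haplotype lengths, two completely unrelated equal-length
insertions score about `0.75` on DNA (random 4-letter strings have an edit
distance near half their length), comfortably above a 0.70 threshold. The
formula is kept exactly as defined because it is the field's established
definition; an alternative normalization `1 - 2*ed/totlen`, which maps
unrelated strings to ~0.5, is available via
`match_params(seqsim_symmetric = TRUE)` and is off by default.

A second consequence of the haplotype construction is worth knowing: for a
*deletion*, the local haplotypes contain only the sequence that remains
after deletion. In non-repetitive sequence, perturbing a deletion's
breakpoints even slightly leaves two short, unrelated residual strings, so
sequence similarity collapses towards 0/0.75 rather than degrading
smoothly. High cross-caller similarity for shifted deletions is a repeat
phenomenon: if the context has period p and the shift is a multiple of p,
the haplotypes are literally identical. The synthetic perturbation model
reflects this — shifts, size jitter and base errors act on insertions,
while deletions are only shifted (used to exercise distance violations).

## TruScore and match assignment

The fractional metrics are averaged into a TruScore in [0, 100]
(`100 * mean(recovl, sizesim, seqsim)`). When sequence comparison is
disabled (`pctseq = 0`, e.g. for non-sequence-resolved callsets) the mean is
taken over the two remaining metrics rather than penalizing the pair.
Positionally incomparable pairs skip the haplotype comparison entirely
(they can never be reported as matches), and their TruScore likewise falls
back to the two cheap metrics.

Within a *chunk* (see below) all base x comp pairs form a matrix. The
default single-best assignment ravels the matrix and sweeps it greedily,
passing pairs first in descending TruScore, ties broken by (base start,
comp start) for determinism; a pair is emitted if neither member has been
consumed, and leftover records become FN (base) or FP (comp). Sorting
passing pairs ahead of failing ones is a deliberate choice: a
threshold-failing pair with a high TruScore (say, a type mismatch between
two colocated same-size variants) must not consume records that still have
a genuine passing partner. Greedy assignment — not optimal bipartite
matching — is the described algorithm and is kept; the exhaustive optimum
exists in the test suite as an oracle on instances where the two provably
coincide. With `multimatch = TRUE` each row and column instead reports its
best passing partner, so one record may participate in several matches.

## Streaming: zipper and chunker

Sorted callsets are merged into one position-ordered stream (stable:
earlier inputs win ties) and grouped into chunks: a new chunk opens when the
next record's start exceeds the running maximum end of the current chunk by
more than `chunksize`. The default `chunksize = max(1000, refdist + 1)`
guarantees no cross-chunk pair can pass the reference-distance gate, so
chunked evaluation is exact, not an approximation — the suite verifies
chunked results equal a single whole-matrix comparison. Filtering (size
bounds, PASS-only, region restriction by start position, genotype presence)
happens in the chunker; filtered comparison calls are counted separately
and excluded from the call count, mirroring the distinction between a
discovery set and an evaluation set. The paper-side convention for whether
such calls should instead count against precision is unstated; reporting
them as `filtered` keeps both readings computable.

## Benchmarking

`sv_bench()` classifies every filtered record into exactly one of TP-base,
TP-comp, FP, FN and derives `precision = TP-comp / call cnt`,
`recall = TP-base / base cnt`, `F1 = 2pr/(p+r)`, and genotype concordance
(fraction of TP pairs whose designated samples carry the same
phase-insensitive genotype; first sample per file by default).
Zero-denominator rates are reported as missing (`NA`), never as 0. Default
thresholds are 70% sequence and size similarity, 500 bp reference distance,
type matching, 0% reciprocal overlap. An empty baseline after filtering is
an error (recall would be undefined).

## Collapsing

`sv_collapse()` reuses the same machinery on an NxN matrix of all calls in
a chunk, at stricter defaults (95%/95%/500 bp) appropriate for
representations of the *same* allele from a harmonized pipeline. Clustering
without `chain` is a position-ordered seed scan: each unconsumed record
gathers the later records that directly match it. This makes `keep =
"first"` idempotent by construction (the kept representatives pairwise fail
to match), which the suite property-tests; a global pair-ordered variant
would not be, since representatives of two separately grown clusters can
still match each other. With `chain = TRUE`, clusters are connected
components of the passing-match graph, so transitively linked variants
merge; components are independent of ordering, making chain-mode collapse
idempotent under every keep strategy.

Representatives are chosen by `first` (most upstream), `maxqual`, or
`common` (highest ALT-allele count across samples; "minor allele count" is
read as ALT count, the paper's exact definition being unstated). Ties break
by (start, input order); `maxqual` with all-missing QUAL falls back to
`first`.

Genotypes consolidate per sample: the representative's ALT count becomes
`min(2, sum of members' ALT counts)` — two hets become a hom — with a
warning counting genotypes saturated at the diploid limit (the 0/1 + 1/1
case is undefined upstream; capping at 2 is the only representable
diploid choice). Consolidation also runs in `--hap` mode: there the
genotype-compatibility gate (`gt_compatible`) already blocks merges that
would claim overlapping haplotype slots (hom-ALT against any ALT carrier,
two phased hets on the same haplotype), and the remaining legal merges —
e.g. `1|0` with `0|1` — are precisely the ones that *should* produce a
homozygous diploid genotype when two haplotype callsets are combined.

A "naive" overlap-based merge is a parameterization, not a code path:
`pctseq = 0, pctovl = 0.5, refdist = 500` with the built-in insertion span
expansion reproduces it.

## Annotation and the tandem-repeat audit

`num_neighbors()` counts, per record, the other records within a distance
measured between closest span edges (a multi-kb deletion's neighborhood
should extend from its ends, not its start) and assigns transitive
proximity-group identifiers. `breakpoint_overlap()` intersects breakpoints
with annotation intervals via interval trees (IRanges), labeling hits as
`start_bnd`, `end_bnd`, `contained_within` or `completely_overlaps`;
insertions, spanning only an anchor, always report `start_bnd`.

The tandem-repeat audit consumes (motif, copy-number-difference)
annotations from a 5-column sidecar TSV — the interface where a
TandemRepeatFinder-style annotator would plug in; running such external
binaries is out of scope. Within a locus, alleles sharing an annotation key
are redundant representations of one expansion/contraction;
`audit_merge()` compares a merged locus against the all-representations
baseline and counts missing keys (over-merging) and surviving duplicates
(under-merging). `audit_cohort()` applies this across merges and drops loci
with identical outcomes everywhere, since those say nothing about merging
strategy. Motifs are keyed literally; rotated motif phases (ACG vs CGA) are
treated as distinct keys — a known limitation.

## The synthetic fixtures

Everything above is testable offline through the generator:

* `make_reference()` — uniform random contigs, optionally with planted
  motif arrays at recorded coordinates; byte-identical per seed. Random
  sequence is deliberately the *hard* case for SV comparison (no repeat
  homology to forgive breakpoint wobble); what passing tests do not show is
  behavior on realistic human repeat landscapes, segmental duplications or
  GC bias.
* `implant_svs()` — non-overlapping anchored DEL/INS truth records with
  genotypes over a configurable sample count. Footprints are spaced (1.5 kb
  by default) so truth loci fall into separate chunks at default
  parameters.
* `perturb_callset()` — positional shift, size jitter, per-base errors,
  drops and novel insertions, with every action written to a ledger so
  expected TP/FP/FN counts are computed, not guessed. An adversarial
  `seq_replace` mode (same-length homopolymer) exists because, per the
  normalization quirk above, random substitutions alone cannot push
  equal-length insertion similarity below ~0.75.
* `make_fig4a_locus()` — the worked audit example: one 29 bp motif array
  carrying eight insertion alleles (+2, +3, +4, +5 copies, two
  representations each) across 10 samples. Pair members carry identical
  inserted sequence at anchors one motif period apart inside the array, so
  their haplotypes are provably identical (similarity 1 >= 0.95), while
  distinct copy numbers differ in size by at least a factor 4/5 < 0.95.
  Collapse at defaults must therefore keep exactly one allele per copy
  number, and the audit must report 0 missing and 0 redundant — which is
  what `scripts/acceptance.R` recomputes.

## Numerical choices and problem sizes

Tolerances: metric agreement with the independent DP oracle is exact (same
floating-point expression); empty-haplotype similarity is defined as 1;
similarity values are clamped to [0, 1]; INFO metrics are emitted with 4
decimals. Breakpoint distances are signed, base minus comp. The suite runs
on deliberately modest problem sizes — 100-record callsets for the
chunking-equivalence checks (50 seeds), 1000 random pairs for the metric
oracle, 500 planted instances for the assignment oracle, 20-50 seeds for
the perturbation, collapse and hap-contract properties — chosen so the
whole suite completes in about a minute while still exercising every code
path; all sizes scale up by changing the loop constants.
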