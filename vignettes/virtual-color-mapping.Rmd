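---
title: "Virtual-color pseudoalignment for scATAC-seq: model, parameters, and design notes"
author: "vcatac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual-color pseudoalignment for scATAC-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcatac)
library(data.table)
```

## The problem

Pseudoalignment decides which references a read is compatible with from
k-mer membership alone, without base-level alignment. On short references
(transcripts, microbial genomes) this is nearly as accurate as alignment
and much faster. Applied directly to a genome it breaks down: a chromosome
is one enormous "color", so a read's k-mers can be supported by matches
scattered tens of megabases apart, and a k-mer that recurs within the
chromosome drags the reported position to the smallest coordinate. The
result is both spurious positions and lost reads, which matters for
assays such as single-cell ATAC-seq whose downstream analysis (peak
calling, clustering) starts from genomic fragment coordinates.

`vcatac` restores positional locality by projecting each reference onto
*virtual colors*: overlapping bins of fixed maximal extent that the
pseudoalignment algorithm treats as distinct colors, while the k-mer index
itself is left untouched. Reads are resolved to a bin, and hence to a
position, at bin-stride resolution before the usual threshold test is
applied.

## The index

The package builds a compacted de Bruijn graph over the reference set:

* k-mers are canonicalized (lexicographic minimum of the k-mer and its
  reverse complement; k must be odd so no k-mer is self-complementary);
* unitigs are maximal non-branching paths in the node-centric graph,
  additionally split wherever a reference contig (a maximal non-N stretch)
  starts or ends mid-path. The extra splits make every reference the exact
  concatenation of complete, oriented unitig occurrences, which is what
  the position lookup relies on. Hairpin adjacencies (a k-mer whose sole
  neighbor is its own reverse complement) also terminate unitigs, since a
  simple path cannot continue through them;
* the K→U table maps each canonical k-mer to its unique
  (unitig, offset, orientation) triplet, and the U→R table inverts the
  tiling, so K→U ∘ U→R yields every genomic position and strand of a
  k-mer.

Construction is in-memory and single-pass per stage, targeted at
references up to the ~100 Mb scale; no compressed-index machinery is
used. The index serializes to a small versioned binary container
(`save_index()` / `load_index()` round trips are bit-exact).

## Virtual colors

For bin stride $\ell_{vcol}$ and overlap $ov$, a reference of length $L$
carries $B = \lceil L / \ell_{vcol} \rceil$ bins. Bin $b$ covers
$[\max(0, b\,\ell_{vcol} - ov),\ \min(L, (b+1)\,\ell_{vcol}))$: the
leftmost bin spans $\ell_{vcol}$ bases, interior bins $ov + \ell_{vcol}$,
and the rightmost $ov + r_l$ where $(B-1)\,\ell_{vcol} + r_l = L$. Bin ids
are global and 0-based via the cumulative offsets $CB$; bins never span
two references. A position carries its base bin and, when it lies within
$ov$ of the next bin boundary, the next bin too — never more, which is why
`build_scheme()` requires $ov \le \ell_{vcol}$ (overlap is defined only
with the left neighbor, and the dedup stage relies on duplicate groups of
size at most two).

Two anchoring decisions were genuinely open and are fixed here:

* the position used for color assignment is the *k-mer start* on the
  forward strand, which turns the overlap test into a pure modulus and is
  stable under canonicalization;
* the extra color is suppressed at the last bin of a reference, since no
  bin may cross a reference boundary.

A consequence of start-anchoring is an exact boundary law with disjoint
bins ($ov = 0$): a read is lost iff it extends at least $k$ bases past a
bin boundary (with $k-1$ bases past it, no k-mer starts in the next bin).
With $ov \ge$ read length no read is lost at all; both laws are asserted
exhaustively in the test suite.

## Mapping

For a mate $Q$, $K(Q)$ is the set of its k-mers with an index entry
(non-ACGT k-mers and error-derived k-mers that do not occur in the genome
are excluded — so the threshold is relative to *matched* k-mers). Every
occurrence of every matched k-mer is expanded to its virtual color id(s),
support is tallied per (color, read orientation) counting each read k-mer
once, and colors with support $\ge \tau\,|K(Q)|$ survive. The reported
position anchors on the leftmost-in-read supporting k-mer, taking the
smallest reference coordinate within the bin when it recurs, and
subtracting the k-mer's read offset (for reverse-orientation mappings the
symmetric expression `refpos - (rl - k - off)` is used, so the reported
value is always the reference start of the mate's span; the merge
example intervals force this reading). Positions clamp at 0.

Mate hits are then deduplicated (overlap twins keep the smaller color
id), merged under the paired-end criteria — same reference, color ids
within 1, opposite orientations, and a start-position gap in
$[-dovetail_{max}, ins_{max}]$ oriented by mate 1's strand — and filtered
to the largest combined support fraction $\tau'$. A pair produces a
fragment only when exactly one merged mapping survives; ties are reported
as multimapped and discarded, matching standard practice.

Defaults ($k = 25$, $\tau = 0.7$, $\ell_{vcol} = 1000$,
$dovetail_{max} = 20$, $ins_{max} = 1000$) are the best-performing
setting for ATAC-scale short reads. When `ov_length` is not given, the
mapper uses `max(150, 2 * max observed read length)`, which always meets
the "overlap at least the read length" requirement with slack. Numerical
tie-breaks: the threshold comparison uses a $10^{-9}$ slack so
$\tau = 1$ means exact equality of support and $|K(Q)|$; equal-position
merged ends take mate 1's read length.

### Streaming queries and the terminal k-mer cache

Consecutive read k-mers usually extend along one unitig, and a k-mer
occurs at most once in the graph, so after one successful lookup the next
k-mer can be verified by comparing a single unitig nucleotide — no index
access. A state variable carries the previous k-mer's unitig, orientation,
offset and distance-to-end; it empties at read start and when the
previous k-mer sat at the unitig end. Queries made in that latter,
*terminal* situation consult a fixed-capacity (default 5,000,000 entries)
write-once cache keyed by canonical k-mer; entries are never replaced and
insertion stops at capacity, so correctness never depends on insertion
order. Both mechanisms are pure optimizations: the test suite asserts
byte-identical mapping output with streaming and cache independently
toggled. Because terminal-ness is defined through the streaming state,
the cache is inert when streaming is disabled.

### Optional pre-mapping mate merge

`merge_overlapping_mates()` can join a pair into a unified fragment
before mapping (3'-overlap of at least 20 bases, at most 2 mismatches —
parameters chosen here). It is off by default and excluded from the
package's accuracy properties, because the upstream procedure it mirrors
is not specified in enough detail to commit to; the stage is provided as
an explicitly separate, documented step.

## Fragment processing

Mapped fragments flow through barcode correction, sorting and
deduplication into the standard five-column fragment BED (reference name,
start, end, cell barcode, duplicate count *including the fragment
itself*; 0-based half-open intervals):

* **Barcode correction** keeps permit-list members and otherwise accepts
  a unique Hamming-distance-1 neighbor; zero or several candidates drop
  the fragment. "Nearest neighbor" admits several readings — distance-1
  uniqueness is the conservative deterministic one; an opt-in
  `"frequency"` policy breaks multi-candidate ties by the highest
  exact-match count observed in the run.
* **Sorting** uses (FASTA reference order, start, end, barcode). Above a
  chunk-size threshold, sorted key runs spill to temporary files and are
  k-way merged; the merged permutation carries an input-row tiebreak, so
  the result is identical — ties included — to one in-memory stable sort
  for any chunk size (asserted down to chunk size 1).
* **Dedup** collapses consecutive equal (reference, start, end, barcode)
  records, so counts sum to the number of input records — the
  conservation identity `fragments_in = kept + dropped` and
  `sum(counts) = kept` is asserted end to end.
* No Tn5 +4/−5 shift is applied by default (the upstream description
  does not mention one); `tn5_shift = TRUE` applies it before sorting.

## The synthetic-data generator

`make_genome()` / `simulate_pairs()` define the conditions everything is
tested under: an i.i.d. uniform ACGT background; optional repeat
families (first copy is the consensus, later copies diverge by i.i.d.
substitution); optional N gaps to exercise contig splitting; fragments
sampled uniformly proportional to reference length with normal lengths
(mean 250, sd 60, floored at the read length — droplet ATAC libraries
are dominated by sub-nucleosomal fragments of roughly this scale);
FR-oriented 100-base mates from the fragment ends with a random sequenced
strand; i.i.d. per-base substitutions (default 0.005, a typical
short-read scale; the upstream simulation's "probability mismatch"
parameter is ambiguous as a per-base rate, so the rate is exposed rather
than fixed); barcodes drawn uniformly from a generated 500 x 16-base
permit list with a single-base error on 2% of observations; optional
exact-duplicate injection to exercise dedup counts. Everything is
deterministic under the seed.

What this emulates — and does not: real ATAC data has non-uniform
coverage (peaks), quality-correlated and indel errors, skewed cells per
barcode, and genome-scale repeat families (SINE/LINE content far above
10%). Passing tests therefore demonstrate the *method's* correctness and
its qualitative behavior (boundary completeness, the accuracy drop
without virtual colors, τ monotonicity), not a performance forecast for
human data. Indels are deliberately absent from the default error model
so that start/end coordinates have exact ground truth and accuracy can be
scored at tolerance 0.

## Problem sizes used by the checks

The packaged checks run, among others: oracle equivalence of the mapper
against a literal brute-force threshold-union implementation on 20 random
genomes of 6–15 kb (mixed repeat content) across
$\tau \in \{0.6, 0.7, 0.8, 1.0\}$ and
$\ell_{vcol} \in \{500, 1000, 5000\}$; optimization transparency on
50,000 pairs from a 200 kb genome; parameter recovery (accuracy and
mapping rate $\ge 0.99$ at tolerance 0) on a 1 Mb repeat-free genome with
20,000 pairs; and the virtual-color ablation on a 300 kb genome with 10%
duplicated content, where accuracy is monotone non-increasing over
$\ell_{vcol} \in \{1000, 10^5, \text{whole reference}\}$. These sizes
were chosen as the smallest at which each property is sharply testable.

## A worked miniature

```{r example}
sp <- sim_params(genome_length = 100000, n_pairs = 1000, seed = 7)
g <- make_genome(sp)
sim <- simulate_pairs(g, sp)
idx <- build_index(g$refs, k = 25)
res <- map_pairs(idx, sim$r1, sim$r3, barcodes = sim$r2)
res
evaluate_mapping(res$fragments, sim$truth, stats = res$stats)
pr <- process_fragments(res$fragments, sim$permit)
head(pr$bed)
```

## Known limitations

* k is capped at 31 (2-bit packing into one machine word), and the index
  is uncompressed in memory; multi-gigabase genomes are out of scope.
* Only substitutions are modeled by the mapper's accuracy guarantees;
  indel-containing reads lose the k-mers that span the indel and may
  shift or drop.
* Multimapped pairs are discarded rather than resolved probabilistically.
* Barcode correction considers Hamming distance 1 only; indel barcode
  errors are not corrected.
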