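---
title: "Heuristic-free alignment and aligner auditing with goldalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heuristic-free alignment and aligner auditing with goldalign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goldalign)
```

## Why exhaustive alignment

Heuristic read aligners optimize a well-defined objective — an alignment
scoring function — but do not guarantee they find its optimum.  `goldalign`
computes that optimum exactly, by filling every cell of the affine-gap
dynamic program for every read, against either a linear reference or a
directed acyclic variation graph.  The point is not throughput but
*auditability*: with the true optimum in hand, a heuristic alignment can be
classified as correct-by-score (its reported score equals the optimum),
suboptimal, or missing, read by read, on real data, with the heuristics
isolated from the scoring function.

## The reference graph

`build_graph()` turns a reference sequence plus variant records into a DAG:

- Substitutions fork the graph into parallel branch nodes; multi-allelic
  records get one alternate node per allele.
- A deletion becomes a *bypass edge* around the deleted reference node.  No
  node is ever empty, so every DP column carries a character.
- An insertion becomes an off-reference node plus a bypass edge for the
  reference path.
- Maximal unbranched runs of reference sequence are merged into single nodes.

Alleles are first normalized by trimming the shared prefix/suffix bases that
VCF records carry (the indel anchor base).  Records whose normalized
reference spans *coincide* are merged into one multi-allelic fork site — this
is what makes a SNP and a deletion at the same position compose into a single
fork with three outgoing paths.  Records whose spans overlap only partially
are rejected with a diagnostic naming both records: nested or staggered
variants have no canonical composition into a DAG path set, and silently
merging them would make the path set (and hence "the optimum") ill-defined.
Rejection keeps the contract crisp; the simulator never emits such pairs.

Coordinates are 1-based and fully closed, as in SAM and VCF.  Every node
records the reference coordinate of its last base (`ref_end`); alternate
nodes are right-aligned against the span they replace, so an alignment ending
on an alternate allele still reports a reference-anchored position.  Columns
of an insertion node all share the anchor coordinate of the adjacent
reference base.  `min_af` filters on the VCF `INFO/AF` field; records without
a frequency are kept only at `min_af = 0`, on the view that an unknown-
frequency variant should not survive an explicit frequency cut.

## The scoring model

`scoring_model()` carries:

| field | default | meaning |
|---|---|---|
| `mode` | `semiglobal` | `semiglobal` consumes every read base, reference flanks free; `local` aligns any read substring, cells floored at 0 |
| `match` | 0 | per-base match bonus (points) |
| `mismatch_min`, `mismatch_max` | 2, 6 | penalty magnitudes at Phred 0 and at/above the ceiling |
| `quality_ceiling` | 40 | Phred value where the mismatch penalty saturates |
| `gap_open` | 5 | extra penalty on a gap's first base |
| `gap_extend` | 3 | penalty per gap base |
| `ambig_penalty` | 1 | penalty whenever an `N` is involved; `N` never matches |

The quality interpolation is
`mn + floor((mx - mn) * min(q, ceiling) / ceiling)` — the convention of the
end-to-end aligner family the `sg-default` preset mimics.  The presets
(`sg-default`, `local-default`, `local-flat`) are this package's documented
defaults for the three common scoring families (end-to-end with
quality-scaled mismatches, local with quality-scaled mismatches, local with a
flat mismatch cost); they are deliberately *not* claimed to equal any
specific tool's constants, and every field can be overridden.

Penalties are stored as non-negative magnitudes; alignment scores are signed.
Local mode requires `match > 0`, since otherwise nothing can rise above the
zero floor.

## The engine

Columns are the graph's node characters in topological order.  The recurrence
is the standard three-state Gotoh DP; at a node's first column the carried-in
`H` and `E` vectors are elementwise maxima over the final columns of all
in-neighbours.  Source nodes are seeded with the textbook column 0: in
semiglobal mode a leading read-gap chain `-(gap_open + i*gap_extend)` (so an
optimal alignment may begin with an insertion at the very start of the
reference), in local mode zeros.

The batch dimension is query-parallel: each `(row, column)` cell is computed
for all reads at once, and cells are mutually independent, so results are
invariant to how the read set is partitioned into batches (a tested
contract).

**Cell widths.**  `select_cell_width()` implements the strict rule: if
`max_score - min_score > 255` for the read length and model, wide (16-bit
representable) cells are used, else narrow biased 8-bit cells.  Both widths
are realized as a saturating window anchored at the score-range lower bound
`-L * max(mx, gap_open + gap_extend)`.  Bottom saturation is safe: the bound
is also a lower bound on the true optimum (every consumed read base costs at
most a maximal mismatch or a fresh gap base), and any path that saturates can
be dominated by an alignment that restarts behind the saturation point, so a
clamped value can never overstate the optimum.  This is verified empirically
by the narrow-vs-wide and engine-vs-oracle suites rather than assumed.

**Optimum tracking.**  Per read, the best stratum is the maximum
alignment-ending score over all columns (`H[m, j]` in semiglobal mode, the
column maximum in local mode), reported with the smallest anchored coordinate
attaining it and the count of co-optimal locations at least one read-length
apart (greedy left-to-right clustering; a separation of exactly one
read-length counts as apart).  Columns anchored to the same coordinate — an
alternate allele and the reference base it parallels — collapse to one
location.  The second stratum is the best score at columns at least one
read-length from *every* best coordinate; restricting the runner-up this way
avoids reporting a trivial 1 bp shift of the best alignment as "second best",
which would make score-gap-based MAPQ features meaningless.  It is `NA` when
no qualifying column exists.

**Ties and degenerate inputs.**  Reported positions prefer the smallest
anchored coordinate.  The linear-reference traceback prefers diagonal over
vertical over horizontal moves, and the longest aligned read suffix among
end-column ties in local mode.  Empty batches, mixed-length batches and
non-`{A,C,G,T,N}` characters are rejected with diagnostics naming the read;
an empty FASTQ aligns to an empty result, successfully.

**Traceback** is supported for single-node (linear) references only, where
the full matrices fit comfortably; on graphs only scores and anchored
positions are reported.  Every emitted CIGAR is re-scoreable:
`score_cigar()` replays it and must reproduce `best_score` exactly (a tested
invariant).  Semiglobal CIGARs never contain soft clips; local CIGARs
soft-clip the unaligned read prefix/suffix.

## SAM dialect

`write_sam()` emits `AS:i` (optimal score) plus the custom tags `mp:i`
(anchored position of the rightmost aligned base), `mc:i` (co-optimal count),
and `ss:i`/`sp:i`/`sc:i` for the second stratum, omitted when unset.  Without
a traceback the CIGAR is `*` and POS carries the `mp` anchor.  Local-mode
reads with no positive-scoring cell are written unaligned (flag 4, POS 0);
semiglobal reads always have a score, and `min_score` controls whether very
negative ones are flagged unaligned.  Phred+33 is the only quality encoding
handled.  `read_sam()` parses the dialect back with typed tags and flags
secondary/supplementary records so audits can keep primaries only.

## The evaluation definitions

- **correct-by-score**: aligned and `heuristic score == optimal score`.
  A heuristic score *above* the optimum is impossible under a matched scoring
  function, so it raises a scoring-mismatch error naming the read instead of
  being binned — making the optimality guarantee observable.
- **correct-by-location**: aligned to the expected sequence within a
  tolerance (default 5 bp).  Truth coordinates anchor the rightmost aligned
  base; leftmost SAM POS values are converted via the CIGAR's reference span
  before comparison.
- **MAPQ calibration**: group by reported MAPQ, compare
  `-10*log10(incorrect fraction)` with the nominal value.  Zero-incorrect
  bins report a cap of 60 with an explicit flag rather than infinity.
- **sweep reports**: per parameter setting, ratios against a baseline of
  % aligned, % correct-by-score, mean score deficit (optimal − heuristic)
  over aligned reads, the same over incorrect-by-score reads, and wall time.
  Score-deficit statistics exclude unaligned reads.  Score bins default to
  width 10.

## The synthetic generator and the oracle

`simulate_genome()` draws uniform i.i.d. bases; `simulate_variants()` plants
SNPs (default rate 1e-3 per base) and 1–3 bp indels (2e-4 per base) with at
least one untouched base between reference spans and uniform allele
frequencies — densities chosen to mirror common-variant density in human
resequencing, and spacing that guarantees `build_graph()` accepts every
emitted set.  `simulate_reads()` samples windows from random source-to-sink
paths (so alternate alleles are exercised), injects substitution errors
(default 0.5% per base, typical of short-read data) and draws qualities from
a flat Phred 30–40 profile.  The truth table records the rightmost-base
anchor of each window — the same anchoring the engine reports, so
simulate → align → evaluate closes without coordinate conversion — plus the
planted score implied by the injected errors.

What the generator does *not* model: sequence-dependent error modes, indel
sequencing errors, coverage or GC bias, paired-end fragments.  Passing tests
therefore demonstrate algorithmic correctness of the alignment and auditing
machinery on statistically structured data, not performance claims about any
real instrument's error profile.

`oracle_align()` is the package's independent referee: it enumerates every
source-to-sink path (refusing above 10⁴ paths) and runs a plain scalar
full-matrix affine DP against each, sharing no recurrence code with the
batched engine — in particular none of the join-carry logic, which is exactly
the part most worth distrusting.  The test suite additionally checks the
oracle itself against a memoized recursion written directly from the
recurrence definition on linear references.

## Problem sizes and numerical checks

The shipped suites use sizes chosen to exercise every code path while staying
desk-sized: oracle-equivalence on 200 random (graph ≤ 30 columns, read ≤ 10
bp, random model) instances per mode; narrow/wide agreement on 50 random
batches; a 1200 bp / 150-read self-audit; 10⁴ reads per MAPQ bin for
calibration recovery.  All randomized tests fix seeds.

## Limitations

- No paired-end concordance; mates are aligned independently if at all.
- No spliced alignment and no dual-affine (two-piece) gap functions.
- Variation graphs must be acyclic; structural variants, phased-haplotype
  restrictions and multi-chromosome graphs are out of scope.
- Traceback (CIGAR/POS) is linear-reference only.
- Exhaustive DP in R is for audit-scale inputs (thousands of reads against
  kilobase–megabase references), not production alignment throughput.
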