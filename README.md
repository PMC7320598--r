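# goldalign

Heuristic-free optimal read alignment to linear and variation-graph
references, and an auditing toolkit that uses those guaranteed optima as a
*computational gold standard* for evaluating heuristic read aligners.

## The problem

Short-read aligners (Bowtie 2, BWA-MEM, HISAT2, vg, ...) accelerate alignment
with seed-and-extend heuristics.  Those heuristics can miss the optimal
alignment of a read — the alignment maximizing the very scoring function the
aligner itself defines — or fail to report any alignment at all.  Simulated
reads don't resolve this: the simulated location need not be the (only)
location of the optimal alignment.  What does resolve it is computing, for
every read, the provably optimal alignment score by exhaustive dynamic
programming under the *same* mode, scoring function and reference as the tool
under audit.  `goldalign` does exactly that, for:

- **linear references** (a FASTA sequence), and
- **directed acyclic variation graphs** built from a reference plus a VCF:
  variants induce forks and joins; alternate nodes are right-aligned so every
  dynamic-programming (DP) column carries an anchored reference coordinate.

## The model

Alignment is affine-gap Gotoh DP.  For read row *i* and DP column *j*:

```
E[i,j] = max( H[i,j-1] - (g_o + g_e),  E[i,j-1] - g_e )        (gap in read,  D)
F[i,j] = max( H[i-1,j] - (g_o + g_e),  F[i-1,j] - g_e )        (gap in ref,   I)
H[i,j] = max( H[i-1,j-1] + s(r_i, c_j),  E[i,j],  F[i,j] [, 0] )
```

with the zero floor in local (Smith–Waterman) mode only.  Semiglobal
("fitting") mode consumes every read base with free reference flanks
(`H[0,j] = 0` for all *j*).  At a join, a column takes elementwise maxima of
`H` and `E` carried from the final columns of *all* its in-neighbours, in
topological order.  The substitution score `s` rewards a match and charges a
quality-scaled mismatch penalty interpolated between `mn` (Phred 0) and `mx`
(Phred ≥ ceiling, default 40):

```
penalty(q) = mn + floor((mx - mn) * min(q, 40) / 40)
```

Batches are processed *query-parallel*: one `(row, column)` cell is filled for
every read in the batch at once, so cell values are independent and results
never depend on how reads are batched.  If the possible score range
`max - min` exceeds 255 for a read length and scoring function, 16-bit score
cells are selected at run time, otherwise biased 8-bit cells suffice; the two
widths give bit-identical results whenever the narrow width is legal.

Reported per read: the optimal score (`AS`), the anchored reference position
of the rightmost aligned base (`mp`), the count of equally scoring locations
at least one read-length apart (`mc`), and the second-best stratum at least
one read-length away from every best location (`ss`/`sp`/`sc`) — all in
custom SAM tags.  For linear references a traceback can populate CIGAR/POS.

The evaluation module then audits any aligner's SAM against these optima:
**correct-by-score** (reported score equals the optimum), **correct-by-
location** (coordinate within a tolerance of the truth, default 5 bp),
score-binned accuracy tables, MAPQ calibration
(`MAPQ = -10·log10 Pr[incorrectly mapped]` vs. the empirical error rate per
MAPQ bin), and parameter-sweep ratio tables against a baseline setting.

## Worked example

```r
library(goldalign)

# A SNP (pos 5, A>T) and a 1 bp deletion (pos 4, TA>T) fork the reference:
v <- data.frame(pos = c(4, 5), ref = c("TA", "A"), alt = c("T", "T"))
g <- build_graph("ACGTACGT", v)
g
#> <ref_graph> ref: 8 bp reference, 4 nodes, 5 edges, 9 DP columns
g$nodes
#>   id ref_end span is_ref  seq
#> 1  1       4    4   TRUE ACGT
#> 2  2       5    1   TRUE    A
#> 3  3       5    1  FALSE    T
#> 4  4       8    3   TRUE  CGT

# Three 3-mers, one per haplotype, all align perfectly (score 0 under the
# end-to-end preset, match bonus 0), each anchored at reference coordinate 6:
m <- scoring_preset("sg-default")
align_batch(g, read_batch(c("TAC", "TTC", "GTC")), m)
#>      id aligned best_score best_pos best_count second_score second_pos second_count
#> 1 read1    TRUE          0        6          1           -8          2            1
#> 2 read2    TRUE          0        6          1          -11          2            1
#> 3 read3    TRUE          0        6          1          -11          2            1

# Linear-reference traceback: deleting one base costs gap_open + gap_extend = 8
traceback_linear("ACGTACGT", "ACGTCGT", model = m)[c("cigar", "pos", "score")]
#> $cigar "4M1D3M"   $pos 1   $score -8
```

`best_pos` anchors the rightmost aligned read base; `best_count` counts
co-optimal locations at least one read-length apart; the `second_*` columns
describe the best alignment at least one read-length away from every optimum
(the score/position pair MAPQ estimators lean on).

Auditing an aligner (here its input is fabricated by damaging three scores of
the optimal result set):

```r
set.seed(99)
genome <- simulate_genome(2000)
vars   <- simulate_variants(genome, snp_rate = 0.005, indel_rate = 0.001)
graph  <- build_graph(genome, vars, min_af = 0.1)
sim    <- simulate_reads(graph, n_reads = 50, read_length = 60,
                         error_rate = 0.01, seed = 100)
opt    <- align_batch(graph, read_batch(sim$seqs, sim$quals, sim$ids), m)

heur <- data.frame(qname = opt$id, score = opt$best_score, unaligned = FALSE)
heur$score[1:3] <- heur$score[1:3] - 2L   # a heuristic that missed 3 optima
score_audit(heur, opt)
#> <score_audit> 50 reads: 94.0% correct-by-score, 6.0% incorrect, 0.0% unaligned
#>  bin  n frac_correct frac_incorrect frac_unaligned
#>  -20  3    1.0000000     0.00000000              0
#>  -10 25    0.9600000     0.04000000              0
#>    0 22    0.9090909     0.09090909              0
```

## Command line

A thin CLI ships at `inst/cli/goldalign`
(`Rscript $(Rscript -e 'cat(system.file("cli","goldalign",package="goldalign"))') ...`):

```sh
goldalign simulate --length 10000 --reads 100 --read-length 100 --seed 1 --out-prefix sim
goldalign build    --fasta sim.fasta --vcf sim.vcf --min-af 0.1 --out sim.gg
goldalign align    --graph sim.gg --reads sim.fastq --preset sg-default --out opt.sam
goldalign evaluate score    --heuristic theirs.sam --optimal opt.sam --bins 10
goldalign evaluate location --heuristic theirs.sam --truth sim.truth.tsv --tolerance 5
```

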