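# vdjpartition

Partitioning of rearranged human immunoglobulin heavy-chain sequences
into their V, D and J gene segments and N-addition junctions, built
around a **motif-anchored approximate backwards dynamic-programming
algorithm** that handles somatic point mutations *and* indels at a small
fraction of the cost of exhaustive DP.

## Who this is for

Immunologists and repertoire-sequencing bioinformaticians who need to
annotate heavy-chain VDJ rearrangements (gene assignment, segment
boundaries, CDR3 junction composition) at scale, and methods developers
who want reference implementations of the underlying alignment engines
together with a ground-truthed rearrangement simulator.

## The method

VDJ rearrangements carry two near-invariant anchors: the `TAT TAC TGT`
motif (Tyr–Tyr–Cys, codons 102–104) ending the V framework and `C TGG
GG` inside J. Pinning the query–germline DP matrix at the motif, the V
alignment starts there with score 0 and *walks the diagonal 3'→5'*.
Scoring is +5 match, −4 mismatch, affine gaps at −30 for the first gap
base and −1 per additional base. On a mismatch the walk steps forward 10
bases and solves a 40 × 40 Needleman–Wunsch block whose best first-row/
first-column entry tells it whether the mismatch was a mutation (resume
on the diagonal) or an indel (resume displaced by the gap); the walk
ends at either 5' terminus. Whenever edits are isolated by more than a
block of matches this reproduces the exhaustive overlap-DP score
exactly, and it can never exceed it.

Around that core: a small anchored DP finds the 3' V end (maximum score
anywhere in the matrix); the J start is aligned backwards from the J
motif; the D segment is matched by a gapless run-length scorer (+1 per
match, reset on mismatch, a mismatch bridged as a mutation only when
flanked by ≥ 3 consecutive matches and a pre-mismatch run score > 3),
reported at score ≥ 9. A V score below 3.1 per aligned base triggers a
fallback ladder ending in exhaustive overlap DP; a J motif absent from
the query triggers Smith–Waterman. Leftover junction bases become the
VD / DJ N regions. All assignment is reported with full tie sets.

The package also ships the rearrangement **simulator** (normal excision
and N-addition models, iid substitution, indel count
P(n) = c·n·e^(−3(n−1)) with c = (1−e^(−3))², zero-truncated-Poisson
lengths) and an **evaluation** layer (gene-level success rates, score-
binned success curves, approximate-vs-exhaustive score differences,
outside-genotype rates).

## Worked example

```r
library(vdjpartition)

db    <- make_fixture_db(12, 8, 4, seed = 1)      # synthetic germline set
sim   <- simulate_rearrangements(
           db, simulation_params(mutation_probability = 0.035),
           n = 200, seed = 42)                    # 3.5% mutation + indels
parts <- partition_sequences(sim, db)

partition_sequence(sim$sequence[1], db, query_name = sim$id[1])
#> <vdj_partition: sim000001 (341 nt, strand +)>
#>   V: IGHV1-S1*01 [0, 286) score 1236 (4.32/base)
#>   D: IGHD1-S5*01 [289, 310) score 21
#>   J: IGHJ1*01 [310, 341) score 146 (4.71/base)
#>   VD N: 'CGG'  DJ N: ''
#>   flags: v_motif_inferred

glance(evaluate_success(parts, sim))
#> # A tibble: 1 × 5
#>   v_success d_success j_success all_success n_records
#>       <dbl>     <dbl>     <dbl>       <dbl>     <int>
#> 1         1     0.745         1       0.745       200
```

Record `sim000001`'s truth is `IGHV1-S1*01` / `IGHD1-S5*01` /
`IGHJ1*01` — all three recovered. The V spans query positions
[0, 286) (coordinates are 0-based, half-open throughout), scoring 1236,
i.e. 4.32 per aligned base, comfortably above the 3.1 acceptance
threshold; this record's V motif carried mutations, so the anchor was
inferred through the fallback ladder (`v_motif_inferred`). The three
bases `CGG` between the V end and D start are the VD N addition; the DJ
junction is empty. V and J genes are recovered for all 200 records;
the D segment — short, heavily excised and buried in the junction — is
recovered for 74.5%, and is the limiting factor for whole-rearrangement
success, as expected. `autoplot(evaluate_success(...))` draws the
score-binned success curves.

A command-line interface wrapping the same functions is installed as
`exec/vdjpartition` (`partition`, `simulate`, `evaluate`, `score-diff`,
`make-fixtures`).

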