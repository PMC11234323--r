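# rnacov

Evidence for evolutionarily conserved RNA secondary structure from
alignment covariation.

## The problem

A conserved RNA structure leaves a fingerprint in a multiple sequence
alignment: base-paired columns accumulate compensatory substitutions
(AU→GC, and half-compensatory changes through G:U) that preserve pairing.
Measuring covariation between columns is easy; concluding *conserved
structure* from it is not, because homologous sequences covary for other
reasons — above all their shared phylogeny (two substitutions on one
branch are co-inherited by a whole clade) — and because a conserved
alignment without variation says nothing either way.  `rnacov` is for
anyone asking whether an RNA alignment (an lncRNA candidate, a predicted
structural region, an Rfam-style seed) actually supports a conserved
structure.

Two quantities per column pair (i, j):

* **Significance.**  The G-test
  `G(i,j) = 2 Σ_ab Obs_ij^ab ln(Obs_ij^ab / (Obs_i^a Obs_j^b / N))`
  (or MI on frequencies), with the average product correction, is compared
  with the same statistic on *phylogenetic null alignments*: each null
  replays the per-branch substitution events of a Fitch-parsimony ancestral
  sample of the input at random sequence positions, preserving phylogenetic
  covariation, per-sequence composition and (by default) gap structure,
  while destroying site-specific covariation.  The E-value of a pair is the
  expected number of null pairs scoring at least as high; pairs with
  E < 0.05 are called significantly covarying.
* **Power.**  The probability that a pair *would* covary significantly
  given its observed substitution count (summed per-column, or
  simultaneous double substitutions per branch), from an isotonic
  calibration shipped with the package.

Observed vs expected covariation classifies the alignment:
**STRUCTURAL** (≥ 3 covarying pairs), **CANNOT_TELL** (no covariation, no
power), **NEGATIVE** (no covariation despite high double-subs power),
**INCONSISTENT_POWER** (single- but not double-subs power), or
INCONCLUSIVE.  A codon-evolution model
(`P(c1c2c3|a,t) = Σ_b P(c1c2c3|b) P(b|a,t)`, BLOSUM62-derived rates ×
codon biases) explains the within-codon covariation of protein-coding
exons, a structure-independent covariation source.  Synthetic-data
generators reproduce the classic artifacts (occupancy bias under legacy
nulls, conserved-column traps with RAF-style statistics, pseudogene
dilution, shifted-helix misalignment), so the whole pipeline is testable
without external data.

## Worked example

Simulate an alignment with 10 conserved pairs on a balanced 32-leaf tree
at high divergence, then analyze it:

```r
library(rnacov)
sim <- simulate_structural_alignment(32, 80, pairs = 10, divergence = 1.6,
                                     tree = balanced_tree(32, 1.6), seed = 7)
res <- analyze(sim$alignment, n_nulls = 20, seed = 8)
res
#> rnacov analysis (gtest, E < 0.05, 20 nulls)
#>   10 significant non-adjacent pair(s)
#> STRUCTURAL (observed 10 covarying pairs; expected 9.9 single-subs / 9.6 double-subs)

head(subset(res$pairs, significant,
            select = c(i, j, score, evalue, subs_single, power_single)), 5)
#>   i  j score    evalue subs_single power_single
#> 1 4 77 62.98 1.167e-06          30            1
#> 2 7 74 57.38 9.474e-06          27            1
#> 3 5 76 54.96 2.349e-05          27            1
#> 4 8 73 53.02 4.852e-05          24            1
#> 5 3 78 49.52 1.796e-04          34            1
```

All 10 planted pairs are recovered (columns are 1-based; pair 4:77 scores
G = 63 after APC, far beyond anything the 20 phylogenetic nulls produce,
hence E ≈ 10⁻⁶ by the fitted tail).  The observed count (10) matches the
power-based expectation (9.9), the ~1:1 relationship that holds when an
alignment's variation is genuinely shared across the proposed pairs —
so the call is STRUCTURAL.

Within-codon covariation of the codon model (serine, positions c1–c2),
decaying with divergence as synonymous 6-box covariation is diluted:

```r
mi_trajectory("S", "c1c2", c(0.05, 0.2, 0.5, 1, 2))
#>      t         mi
#> 1 0.05 0.86156196
#> 2 0.20 0.68929907
#> 3 0.50 0.42879025
#> 4 1.00 0.19412529
#> 5 2.00 0.06087768
```

Real alignments come in through `read_alignment()` (Stockholm with
`#=GC SS_cons` in WUSS notation, or aligned FASTA), and a CLI wraps the
same pipeline:

```sh
Rscript inst/cli/rnacov analyze --in my.sto --nulls 20 --seed 1 \
    --out-tsv pairs.tsv --out-json call.json
Rscript inst/cli/rnacov codon-mi --aa S --pair c1c3
Rscript inst/cli/rnacov simulate --n-seq 20 --length 100 --pairs 10 --out sim.sto
```

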