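---
title: "Covariation evidence for conserved RNA structure: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariation evidence for conserved RNA structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnacov)
```

## The question

Given a multiple sequence alignment of homologous RNAs, does the alignment
carry evidence that a *secondary structure* has been conserved by
selection?  This is not structure prediction: the question is whether any
conserved structure exists at all.  The observable is covariation between
alignment columns — conserved base pairs accumulate compensatory double
substitutions (AU→GC) and half-compensatory changes through G:U — but
covariation alone is not enough, because two other forces produce it too:

* **Phylogeny.**  Two independent substitutions on the same branch are
  co-inherited by the whole descendant clade and look like pairwise
  covariation to any statistic that treats sequences as independent.
* **Too little variation.**  A perfectly conserved alignment shows no
  covariation whether or not a structure is conserved; absence of
  covariation is evidence against structure only when the alignment had
  enough variation to reveal it (*covariation power*).

`rnacov` implements both halves: significance of covariation against a
phylogenetic null, and power from substitution counts, combined into a
four-way alignment-level call.

## Covariation statistics

For columns $i, j$ with joint residue counts $\mathrm{Obs}_{ij}^{ab}$ over
the rows occupying both columns ($N$ of them), the package scores

$$\mathrm{G}(i,j) = 2 \sum_{a,b} \mathrm{Obs}_{ij}^{ab}
  \ln \frac{\mathrm{Obs}_{ij}^{ab}}
           {\mathrm{Obs}_i^{a}\,\mathrm{Obs}_j^{b} / N},
\qquad
\mathrm{MI}(i,j) = \sum_{a,b} p_{ij}^{ab}
  \log_2 \frac{p_{ij}^{ab}}{p_i^a p_j^b}.$$

On gap-free data $\mathrm{G} = 2 N \ln(2)\, \mathrm{MI}$.  The difference
matters with gaps: MI on frequencies is occupancy-agnostic, the G-test
grows with the number of observed symbols.  The G-test with the average
product correction (APC, $\mathrm{corr}_{ij} = \mathrm{raw}_{ij} -
\bar r_i \bar r_j / \bar r$, means excluding the diagonal) is the default.
Rows gapped at either column are excluded pair by pair; IUPAC ambiguity
codes and lowercase are treated as missing, because the statistics are
defined on A, C, G, U only.

RAF-style scores, which add conservation and Watson-Crick-consistency
terms to covariation, are implemented only as a *diagnostic*
(`raf`, `raf_diagnostic`) and are refused by the significance machinery:
the null model destroys per-column conservation, so a statistic that
rewards conservation scores conserved, zero-covariation pairs above its
own null — the "conserved-column" artifact reproduced by
`make_conserved_column_trap()`.

## The phylogenetic null

A neighbor-joining tree (Jukes–Cantor distances, midpoint-rooted) is built
from the alignment; users may supply a Newick tree instead.  Ancestral
sequences are sampled by five-state Fitch parsimony (gap is a fifth
character), with uniform random tie-breaking in the down-pass, and each
parent/child difference is recorded as a substitution event on its branch.

Each null alignment redraws the ancestral sample, then replays evolution
from the root with **the same events on the same branches**, but each
residue substitution $x \to y$ is re-placed at a position chosen uniformly
among positions of the evolving sequence currently holding $x$.  Placed
substitutions are inherited by descendants, so clade-level (phylogenetic)
covariation survives; site-specific covariation is destroyed; per-sequence
base composition is preserved exactly; per-column conservation is *not*
preserved (deliberately).

**Gap handling.**  In gap-preserving mode (default), columns with any gap
anywhere in the sampled tree history keep their sampled content verbatim,
and re-placement happens among the tree-wide resident columns.  This makes
three invariants hold exactly — per-branch event counts, per-sequence
composition, and bit-identical gap masks — at the cost of not randomizing
the gappy columns themselves, a slightly conservative choice for very
gappy alignments.  (The obvious alternative, re-placing residue events
among the non-gap positions of each lineage, cannot satisfy all three
invariants at once: a deletion column whose content was changed by an
earlier re-placement forces either a composition error or an extra
parent/child difference.)  Legacy mode re-places every event, indels
included; it exists to reproduce the occupancy-bias artifact
(`make_gap_bias_scenario()`), where the G-test scores high-occupancy pairs
against occupancy-scrambled nulls.

Within a branch, events are applied in random order at positions not yet
touched on that branch, so recounting parent/child differences on the null
reproduces the per-branch event totals exactly; when no eligible position
holds the from-residue the event falls back to a random eligible position
and is flagged (`fallback_events`).

## E-values

Scores of all column pairs of $M$ null alignments are pooled.  The E-value
of a score $s$ is the expected number of null pairs per alignment scoring
at least $s$: empirically $\#\{\text{pooled} \ge s\}/M$.  Below the
resolution $1/M$ an exponential tail is used, **anchored at the pooled
maximum** where $E = 1/M$ by construction, with decay rate fitted by least
squares to the log-survival of the top 1% of pooled scores.  A
maximum-likelihood mean-excess fit on a wider slice (e.g. the top 10%) was
tried first and rejected: the null G-test tail is lighter than exponential
until far out, the bulk near the threshold biases the rate low by ~1.6×,
and the resulting E-values were ~10× too large at the pooled maximum,
breaking E-value calibration.  With the anchored tail, a pair is
significant at $E < 0.05$ with $M = 20$ exactly when it outscores every
pooled null pair, which makes the false-positive calibration at the 0.05
default nearly exchangeability-exact.  Calibration is verified on 200
structure-free star-topology alignments (S = 20, L = 100, divergence 0.3)
in the acceptance suite; the measured rate (~0.02–0.05 per alignment) is
slightly conservative, a known property of parsimony-based nulls (the
randomized replay is marginally over-dispersed relative to the
parsimony-minimal source).

## Power and the four-way call

The power of a base pair is the probability it would covary significantly
given its observed variation, measured either as the summed residue
substitutions of its two columns (*single-subs*) or as the number of
branches substituting at both columns simultaneously (*double-subs*;
double-subs power implies single-subs power, not conversely).  Power
curves are isotonic regressions of significance outcome on substitution
count, forced to 0 at 0 substitutions.  The shipped default
(`inst/extdata/power_default.tsv`, rebuilt by
`scripts/calibrate_power.R`) is calibrated on this package's own
structure-constrained simulations — balanced 32-leaf trees, 80 columns, 10
nested pairs, root-to-tip divergences 0.2–1.6, the default G-test+APC
pipeline with 20 nulls.  It is *not* numerically comparable to power
calibrated on curated structural families; users with a trusted collection
should refit via `fit_power_curve()`.

The alignment-level call compares the observed number of significantly
covarying proposed pairs with the expected number (sum of per-pair
powers): `STRUCTURAL` at ≥ 3 observed; otherwise `CANNOT_TELL` when the
single-subs expectation is ≤ 5; otherwise `NEGATIVE` when the double-subs
expectation is ≥ 8; `INCONSISTENT_POWER` when single-subs power is high
(≥ 8) but double-subs power low (≤ 5), the signature of an alignment whose
variation is not actually shared between the two columns of the proposed
pairs; `INCONCLUSIVE` otherwise.  The ≤ 5 / ≥ 8 thresholds follow the
published screening convention; whether they refer to single- or
double-subs power is not specified there, and this package resolves the
ambiguity as just described.  Pairs closer than four columns are excluded
from the structure-level summary (helical pairs require at least three
unpaired nucleotides between them) but are retained in the pair table,
where they carry the within-codon signal of protein-coding exons.

## The codon model

Within-codon covariation in coding alignments arises from the genetic
code, not from RNA structure or phylogeny.  The model: an ancestral amino
acid $a$ evolves for time $t$ under an amino-acid chain, and the resulting
amino acid emits a codon from its (stationary) codon bias,

$$P(c_1 c_2 c_3 \mid a, t) = \sum_{b} P(c_1 c_2 c_3 \mid b)\, P(b \mid a, t).$$

Expected within-codon covariation is the MI of the two-position marginals.
The amino-acid chain is derived from BLOSUM62: joint frequencies are
reconstructed from the half-bit scores and the standard background
frequencies ($q_{ab} \propto p_a p_b 2^{s_{ab}/2}$ — the exact target
frequencies are not shipped with any pre-installed component, and integer
score rounding makes this reconstruction approximate), the conditional
matrix is log-mapped through its symmetrized eigendecomposition (tiny
eigenvalues clamped at $10^{-6}$, negative off-diagonal rates zeroed — the
`projected` flag records this), and rates are rescaled to one expected
substitution per site at $t = 1$.  Stop codons are outside the state
space; indels are ignored; sequences descend independently from the
ancestor (star topology).  Codon biases default to uniform over synonymous
codons; per-amino-acid normalized count tables can be supplied.

Consequences checked by the tests: only the three 6-codon amino acids
(Ser, Arg, Leu) can covary within-codon through synonymous change alone,
so their MI starts high and decays monotonically with divergence (to
numerical resolution ~10⁻³; around $t \approx 2$ nonsynonymous mixing adds
back MI at the 10⁻⁴ level), while single-codon amino acids (Met, Trp)
start at exactly 0 and rise.  The observed-vs-expected comparison
(`observed_within_codon()`) conditions on the encoded amino acid:
each amino acid's codon columns are analyzed as their own sub-alignment
against their own null, mirroring how the per-amino-acid observed
fractions are defined, and keeping the null pool of each test at a scale
where mid-range MI (~0.2 bits) is detectable at desk-scale sequence
numbers (150 in the acceptance run).

## Synthetic data: what it emulates and what it does not

`simulate_structural_alignment()` evolves a root sequence down a tree;
paired columns propose 80% double-compensatory, 15% half-compensatory and
5% pair-breaking changes (weights configurable; the qualitative structure
is what matters, no published quantitative kernel exists), with Poisson
event counts per branch at one event per unpaired site (per pair for
paired sites) per unit branch length.  Artifact generators build on it:
occupancy gradients, conserved-column traps, pseudogene mixtures (a
fraction of terminal branches evolve unconstrained at twice the rate —
dead copies keep accumulating substitutions), and shifted-helix
misalignments (the 5' strand moves right, the 3' strand left, preserving
interior pairing while destroying column conservation).

Simulated worlds in the acceptance suite are stated once and fixed:
star topologies for calibration (no true phylogenetic covariation, so the
E-value null is exercised at its cleanest), balanced trees for power and
recovery (coalescent trees concentrate divergence in a few deep branches
and make per-pair substitution counts erratic — realistic, but a
low-variance scaffold is the right instrument for measuring recovery and
the ~1:1 observed-vs-expected growth), root-to-tip divergence 1.6
("high divergence", ~30% average pairwise identity) for recovery, 0.5 for
the pseudogene direction test (mid-curve power, so the expected count has
room to rise).  What a green test does **not** establish: behaviour on
real alignments with alignment errors, non-homologs, rate heterogeneity
across sites or lineages, or base composition bias — none of which the
generators model.

## Numerical and degenerate-input choices

* Jukes–Cantor p-distances are capped at 0.70 before correction; NJ
  branch lengths are clamped at 0; midpoint rooting falls back to rooting
  at the first leaf for degenerate (all-zero) distance matrices.
* An all-identical alignment yields zero-cost Fitch samples, nulls equal
  to the input, all-zero score matrices (APC skipped, flagged), and E-values
  equal to the pair count — nothing is ever significant.
* `gtest` on zero joint support returns 0 with a `zero_support` flag;
  MI of an empty distribution is an error.
* Ties everywhere are broken by fixed rules (lexicographic names in
  trees, `(i, j)` order in pair tables) so identical seeds give identical
  output.

## Limitations

* The null is mildly conservative (see above); at `M = 20` nulls the
  E-value floor above the pooled maximum means single very strong pairs
  are the only route to E < 0.05 — raise `n_nulls` for finer resolution.
* Power is calibrated on simulations, not on curated families; absolute
  expected-covarying counts are comparable only within this package.
* The BLOSUM62 rate derivation is one defensible reading of "derived from
  BLOSUM62"; it is not claimed identical to any published tool's.
* Stockholm support covers the sequence lines and `#=GC SS_cons`; other
  annotations are ignored on input.
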