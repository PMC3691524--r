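---
title: "Phylogeny-aware consensus RNA structure prediction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-aware consensus RNA structure prediction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylocofold)
```

## The problem

Functional RNAs conserve their secondary structure far more strongly
than their sequence.  Given a multiple alignment of homologous RNA
sequences, a *consensus* structure -- one set of base-paired column
pairs shared by all rows -- can be predicted by combining a
thermodynamic folding model with *covariation* evidence: when two
columns repeatedly swap one canonical base pair for another (say
`GC` for `AU`) across the alignment, the pairing of those columns is
conserved even though the sequence is not.

Covariance scores computed column-by-column treat the rows of the
alignment as exchangeable: every pair of sequences contributes equally,
as if the sequences were related by a complete graph.  That discards
the phylogeny.  Two compensatory configurations with identical column
compositions can require very different numbers of independent
mutation events on the tree, and more independent events are stronger
evidence of selective pressure to maintain pairing.  This package
scores that difference explicitly: it counts covarying mutations on a
rooted binary tree with a gap-aware parsimony pass and scales the
covariance reward accordingly.

## Covariance scoring

Let the alignment hold $N$ sequences and $L$ columns, with $s_{ik}$ the
symbol at column $i$ of row $k$, and let
$B = \{AU, UA, CG, GC, GU, UG\}$ be the canonical (Watson-Crick plus
wobble) pairs.  For a column pair $(i, j)$:

**Conservation** rewards covariation between rows whose symbols can
pair:

$$V_{ij} = \frac{1}{N} \sum_{1 \le k < l \le N} t(k, l), \qquad
t(k,l) = \begin{cases}
h(s_{ik}, s_{il}) + h(s_{jk}, s_{jl}) & (s_{ik},s_{jk}) \in B \text{ and } (s_{il},s_{jl}) \in B\\
0 & \text{otherwise}
\end{cases}$$

with $h$ the Hamming distance on bases, so a pair of rows contributes
0, 1 or 2 according to whether their base pairs differ at zero, one or
both partners.  In RIBOSUM mode the Hamming sum is replaced by the
entry $R(s_{ik}s_{jk}, s_{il}s_{jl})$ of a base-pair substitution
matrix.  The leading factor is $1/N$, exactly as in the scoring scheme
this package follows; some folding-program releases normalize by the
number of sequence pairs instead, so a constant-factor difference in
$V$ against other software is expected and harmless (the pairing
threshold is calibrated for the $1/N$ convention).

**Penalty** charges rows that cannot pair:
$Q_{ij} = \sum_k q_k$ with $q_k = 0$ for a canonical pair, $0.25$ when
both symbols are gaps, and $1$ otherwise.  IUPAC ambiguity codes are
retained on input but can never pair, so they always fall into the
penalty branch; this is a documented convention of this package.

The baseline covariance score is $\gamma_{ij} = V_{ij} - \phi_1
Q_{ij}$, and columns with $\gamma_{ij} > \gamma_t$ (default $-2$) are
candidate pairing columns.

## The phylogenetic factor

Let $m_{ij}$ be the minimum number of covarying mutations on the tree
for column pair $(i, j)$, and $b_{ij}$ the number of rows whose symbols
at $(i, j)$ form a canonical pair.  Since a tree with $b$ pair-carrying
leaves can force at most $b - 1$ mutations, $m/(b-1)$ normalizes the
count to $[0, 1]$, and the scaled score is

$$\varepsilon_{ij} = 1 + \beta\,\frac{m_{ij}}{b_{ij} - 1}, \qquad
\gamma^p_{ij} = \varepsilon_{ij} V_{ij} - \phi_1 Q_{ij}.$$

At $b \le 1$ the normalizer is undefined but $m = 0$ is forced, and we
define $\varepsilon = 1$ (no bonus), continuous with the $m = 0$ case.
In Hamming mode $V \ge 0$, so $\gamma^p \ge \gamma$ always: every
column pair that passes the threshold under the baseline score also
passes under the scaled score, and the phylogeny can only *add*
candidate pairing columns.  The candidate mask is computed from
$\gamma^p$.  In RIBOSUM mode $V$ can be negative and the dominance
guarantee lapses; the package asserts it only in Hamming mode.

$m_{ij}$ is computed with the forward phase of the Fitch
small-parsimony algorithm on the rooted binary tree, over the
six-letter alphabet $B$.  Each leaf is labelled with its row's ordered
base pair at $(i,j)$; any non-pairing observation (gap, one-sided gap,
non-canonical pair, ambiguity code) is replaced by a single gap
sentinel.  Internal nodes follow the usual rule -- intersection of the
children's label sets if non-empty, otherwise union with one mutation
charged -- with two gap-aware modifications: a sentinel child is
transparent (the parent inherits the other child's label set and
accumulated cost), and when *both* children are sentinels the parent is
a sentinel with cost 0.  The both-sentinel rule is forced by
consistency: a sentinel subtree contains no pairing information at all,
so it must propagate transparently upward.  Only the forward
(bottom-up) phase is needed because the mutation count, not the
internal labels, enters the score.  Two distinct canonical pairs always
count as one event under set logic -- `GC` at one leaf and `CG` at its
sibling is a mutation.  Branch lengths are ignored throughout: the
count is pure parsimony, which is all the scaled score consumes.

### Default parameters

| parameter | default | meaning |
|---|---|---|
| $\beta$ | 10 | weight of the normalized mutation count in $\varepsilon \in [1, 1+\beta]$ |
| $\phi_1$ | 1 (Hamming), 0.6 (RIBOSUM) | penalty weight in $\gamma^p$ |
| $\phi_2$ | 1 (Hamming), 0.5 (RIBOSUM) | weight of $\gamma^p$ as folding pseudo-energy |
| $\gamma_t$ | $-2$ | pairing-candidate threshold on $\gamma^p$ |
| min. hairpin | 3 columns | steric constraint: pairs need $j - i > 3$ |

$\beta = 10$ is the value at which the phylogenetic scaling helps most
across a published benchmark sweep ($\beta$ from 1 to 15); $\beta = 0$
switches the factor off and recovers the baseline method exactly (a
property the test suite asserts bit-for-bit).  The RIBOSUM-mode
$\phi_1, \phi_2$ follow the defaults of the RIBOSUM-scored variant of
the baseline method.

### The bundled RIBOSUM-style matrix

The genuine RIBOSUM85-60 matrix is not distributable as text here, so
the package ships `extdata/ribosum_synthetic.tsv`, a *synthetic*
16x16 matrix with the qualitative log-odds structure of the RIBOSUM
family: conserved canonical pairs positive, compensatory double
substitutions highest, non-canonical dinucleotides negative.  All
correctness guarantees are established against oracles under the same
matrix and therefore hold for any user-supplied matrix
(`read_ribosum()`); for production RIBOSUM scoring, drop in the real
matrix.

## Consensus folding

The optimal structure minimizes the summed per-sequence loop energies
plus the covariance pseudo-energies, via the standard four-table
interval recursion: $F$ (unconstrained region), $C$ (region closed by a
pair), $FM$ (multiloop region with at least one branch), $FM1$
(multiloop region with exactly one branch at its left edge).  A pair
may close a region only where the $\gamma^p$ mask allows it, and its
closing contribution includes the pseudo-energy term.

Two points in the recursion as conventionally written down are
underdetermined, and this package resolves them explicitly:

* **Sign of the covariance term.**  Written as a closing-pair
  term $+\phi_2\gamma_{ij}$, positive covariance would *raise* the
  energy of conserved pairs, contradicting the intent and the behaviour of
  the folding programs it extends (where covariance enters as a
  pseudo-energy bonus).  The default here is $-\phi_2\gamma^p_{ij}$,
  so that covariation lowers the energy; `cov_sign = "literal"` flips
  the sign for strict-literal replication.
* **The single-branch recursion.**  The printed $FM1$ line references
  an undefined index and omits the branch term.  We implement the
  standard Zuker-style decomposition
  $FM1_{i,j} = \min(FM1_{i,j-1} + M_c,\; C_{i,j} + M_b)$, which is the
  decomposition the surrounding recursion follows.

### Energy model

The bundled model is a simplified nearest-neighbour table: a 6x6
stacking matrix over canonical pairs, logarithmic initiation for
hairpins ($5.6 + 1.7\ln(n/3)$ kcal/mol) and interior/bulge loops
($1.1 + 1.1\ln n$), and an affine multiloop score
($M_a = 3.4$ closing, $M_b = 0.4$ per branch, $M_c = 0.1$ per unpaired
column).  Magnitudes are Turner-like but the table is deliberately
small; full published parameter sets (dangling ends, coaxial stacking,
tetraloop bonuses, sequence-dependent mismatches) are out of scope.
Folding correctness is tested against a brute-force enumeration oracle
under the *same* model, so the guarantees are independent of the table
values, and `read_energy_model()` accepts any table in the documented
text format.

Alignment-specific conventions (the model's "dialect", documented
because alignment folding programs differ here):

* A sequence contributes loop energy for a loop only when its own
  bases at the closing columns form a canonical pair; rows that cannot
  pair there are already penalized through $Q$ inside $\gamma^p$, so
  charging them loop energy would double-count.
* Per-sequence loop sizes are measured in that sequence's gap-stripped
  coordinates; a gap-shortened hairpin below 3 nt costs a fixed finite
  penalty (6.0) instead of the logarithmic term.
* Multiloop terms are column-level and applied once per sequence
  (multiplied by $N$), so the reported per-sequence-normalized energy
  does not dilute with alignment depth.
* Interior loops are capped at 30 unpaired columns total (the standard
  folding-program restriction); wider interior loops are disallowed in
  both the recursion and the re-scorer.
* Lonely pairs are permitted; dangling ends and coaxial stacks are not
  modelled.

The reported energy is the total divided by $N$, and it is computed by
*re-scoring the traced structure* with the independent loop
decomposition in `score_structure()`, never taken from the DP tables;
an internal check requires the two to agree within $10^{-9}$
(tolerance for the different floating-point summation orders).  Ties
inside the recursion are broken deterministically: hairpin before
interior before multiloop, and smaller indices first; the brute-force
oracle breaks ties toward fewer pairs, then the lexicographically
smallest pair list.  Optimal energies are compared exactly through the
shared scorer; at exact ties the two tie-breaking rules may return
different (equally optimal) structures.

Degenerate inputs fold to the open chain: alignments shorter than the
minimal hairpin span, or whose mask admits no pair, return the empty
structure with energy 0.

## Tree handling

The parsimony pass requires a rooted, strictly binary tree whose
leaves match the alignment rows.  Multifurcations are rejected with an
explicit message rather than silently resolved -- resolution changes
parsimony counts -- unless `binarize = TRUE`, which applies a
deterministic caterpillar resolution with zero-length branches.

Trees are an *input*: any construction method may be used.  For
convenience the package bundles Jukes-Cantor distances plus UPGMA so
the pipeline runs end to end without external programs.  Distances are
computed over columns where neither row has a gap or ambiguity code;
p-distances above 0.75, where the JC69 logarithm diverges, and pairs
with no comparable columns are set to the finite sentinel 1000 (large
against any realistic tree scale, mirroring the saturation convention
of classical distance programs, whose "-1 = infinity" output must be
replaced before rooted-tree estimation).  UPGMA is average-linkage
`hclust` with its deterministic merge order.

## Evaluation conventions

Predicted pairs are compared to a reference consensus structure at
base-pair level.  A predicted pair absent from the reference is
*compatible* when it could be inserted into the reference without
breaking pairing rules (no shared endpoint, no crossing) and
*contradictory* otherwise; only contradictory pairs count as false
positives.  Compatible pairs are excluded from the true negatives as
well -- neither rewarded nor punished -- which is the common convention
in the RNA-structure literature; `compatible_as_tn = TRUE` switches to
counting them as true negatives.  True negatives are counted over the
universe of all column pairs obeying the hairpin separation.

MCC is the Matthews correlation coefficient with the convention that a
zero factor under the root yields 0.  "Specificity" is reported as
$TP/(TP+FP)$ (positive predictive value): with the quadratic
true-negative universe, TN-based specificity saturates at 1.000 and
carries no information, which is also why published per-family tables
report uniform TN-based specificity across methods.  Both ratios define
$0/0 = 1$.

## The synthetic generator

`simulate_alignment()` evolves a root sequence down a rooted binary
tree under a *coupled-switch* model: at columns paired in the true
structure, a mutation replaces the whole canonical pair with a
different canonical pair at both partners in one event; unpaired
columns substitute independently; gaps are inserted at leaves, at
unpaired columns only.  Branch lengths are ignored -- rates are per
branch -- because the parsimony count the generator exercises is itself
branch-length-blind.  Defaults, chosen once as representative of a
moderately diverged structural-RNA alignment: substitution rate 0.15
and switch rate 0.30 per branch, gap probability 0.05.

This model directly controls the number of covarying mutations, which
is what the scoring machinery consumes, at the price of realism: there
is no reversible substitution process, no rate heterogeneity across
sites, no indel evolution (gaps never hit paired columns, so the true
structure is always attainable), and no alignment error.  Passing
tests on simulated data therefore demonstrate correctness of the
*computation* -- scores, parsimony counts, folding optima, evaluation
statistics -- not predictive accuracy on real alignments, which
depends on alignment quality and energy-parameter fidelity that the
simulation does not emulate.

The recovery fixture used in the acceptance suite places one 4-pair
helix in a 30-column alignment of 10 sequences at switch rate 1.0 (the
maximal compensatory signal) with no gaps.  Note that the theoretical
ceiling $m = b - 1$ is unattainable at $b = 10$: every internal node
of the tree would need disjoint child label sets, which forces all
leaf labels in any subtree to be distinct -- impossible with only six
canonical pairs.  The fixture therefore attains the maximal *feasible*
parsimony count, which the suite verifies against exhaustive
enumeration.

## Problem sizes and numerical choices in the test suite

The suite enumerates all 13 unlabeled rooted binary tree shapes with
2-6 leaves crossed with every 4-symbol leaf labelling (28,240
instances) for the parsimony oracle; Fitch cost is invariant under
leaf renaming (asserted separately by a permutation property), so this
covers all labeled trees of those sizes.  Parsimony oracles enumerate
internal labelings over the *observed* label set only -- an optimal
unit-cost labeling never needs an unobserved label (exchange
argument).  Folding oracles enumerate all structures for alignments of
10-14 columns and 2-4 rows, 100 seeded instances per scoring mode.
Floating-point comparisons between the DP and its oracle use the
shared re-scorer and a $10^{-9}$ tolerance.

## Known limitations

* The bundled energy table is simplified; absolute energies are not
  publication-grade thermodynamics, though optimality under the model
  is exact.
* The RIBOSUM-style matrix shipped is synthetic (see above).
* No partition-function or base-pair-probability output; a single MFE
  structure is returned.
* Pseudoknots are out of scope throughout (structures are strictly
  nested).
* UPGMA assumes a molecular clock; for real data supply a tree from a
  dedicated phylogeny program.
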