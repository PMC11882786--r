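---
title: "Energy profiles for alignment-free protein comparison: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy profiles for alignment-free protein comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enerprof)
```

## The model

`enerprof` represents a protein by a 210-dimensional vector of pairwise
amino-acid interaction energies and compares proteins by the Manhattan
distance between these vectors. This vignette explains the statistical
model behind the vectors, the conventions and tunable parameters, what the
synthetic-data generators do and do not emulate, and the design decisions
taken where more than one reasonable choice existed.

### The distance-dependent knowledge-based potential

The potential is an empirical energy function estimated from observed
atomic contacts in a training set of structures. Every heavy atom is typed
by its residue and PDB atom name; the 20 standard residues contribute 167
types in total (glycine's 4 backbone atoms up to tryptophan's 14 heavy
atoms). Contacts are the edges of the 3-D Delaunay tessellation of the
structure's typed heavy atoms — two atoms are "in contact" when no other
atom shields them — and each contact distance is binned into one of 30
half-open shells of width 0.5 &Aring; starting at 0.75 &Aring; (upper edge
15.75 &Aring;).

With $M_{ij}(d)$ the pooled count of type pair $(i,j)$ in shell $d$,
$M_{ij} = \sum_d M_{ij}(d)$, $f_{ij}(d) = M_{ij}(d)/M_{ij}$ and
$f_{xx}(d)$ the pooled frequency of shell $d$ over all pairs (the
*reference state*), the energy of a contact is

$$\Delta E^{ij}(d) = RT\left[\ln(1 + M_{ij}\sigma) -
  \ln\!\left(1 + M_{ij}\sigma\,\frac{f_{ij}(d)}{f_{xx}(d)}\right)\right].$$

The formula is an inverse-Boltzmann ratio with a sparse-data correction:
for abundant pairs ($M_{ij}\sigma \gg 1$) it approaches
$-RT\ln(f_{ij}/f_{xx})$, while rarely observed pairs are shrunk toward 0.
Shells observed more often than the background get negative (favourable)
energies; the function is strictly decreasing in the ratio
$f_{ij}/f_{xx}$.

Parameters, with units and defaults:

| parameter | default | meaning |
|---|---|---|
| `RT` | 0.582 kcal/mol | energy scale of the log-ratio |
| `sigma` | 0.02 | weight of a single observation in the shrinkage term |
| shell start | 0.75 &Aring; | lower edge of the first distance shell |
| shell width | 0.5 &Aring; | resolution of the distance dependence |
| shell count | 30 | upper range 15.75 &Aring; |

Where the formula is undefined the package returns exactly 0: pairs never
observed ($M_{ij}=0$) and shells empty across the whole database
($f_{xx}(d)=0$). Zero is the information-free value and the continuous
limit of the expression.

Counts are pooled over the entire training set before the formula is
applied — the frequencies are database frequencies, not averages of
per-structure frequencies. The classical training-set filters (sequence
identity, resolution, R-factor, length 40–1000) describe how a production
training list should be curated; the package trains on whatever manifest
it is given, records the manifest digest as provenance, and re-checks only
the length bound (warning, not error), because the other criteria are
properties of the source database that cannot be verified from coordinates
alone.

### Structural profile of energy (SPE)

The interaction energy of residues $A$ and $B$ is the sum of
$\Delta E^{ij}(d)$ over their contacting atom pairs. Aggregating over all
residue pairs by unordered amino-acid *type* pair gives the 210-entry SPE
(pair order fixed: lexicographic over `ACDEFGHIKLMNPQRSTVWY`, `AA` first,
`YY` last). By construction the un-normalized entries sum to the total
contact energy of the structure — an identity the tests verify to 1e-9
against an independent accumulation path.

By default SPE entries are divided by the residue count $L$ so that
structures of different sizes are comparable and live on the same scale
as the composition-based profile below; `normalize = FALSE` retains raw
sums.

### Predictor matrix and compositional profile (CPE)

Many proteins have no solved structure. The package therefore fits a
20×20 predictor matrix $P$ mapping amino-acid composition to energy: for
a training structure $S$ with composition counts $N_i$ and fractions
$n_j = N_j/L$, the per-type energy (the energy of all interactions
involving residues of type $i$) is modelled as
$\hat e_i = N_i \sum_j P_{ij} n_j$, and each row of $P$ is obtained by
minimizing $Z_i = \sum_S (e_i^S - \hat e_i^S)^2$ via its normal equations
— 20 independent linear least-squares problems in 20 unknowns. The fit is
exact on data generated from the model itself, which is the package's
parameter-recovery oracle (planted $P^*$ recovered to 1e-8).

The CPE of a sequence is then
$E_{ij} = n_i P_{ij} n_j + n_j P_{ji} n_i$ for $i \ne j$ and
$E_{ii} = n_i P_{ii} n_i$: because $P$ is not constrained to be symmetric,
the symmetrized form makes the profile well defined on unordered pairs
(a flag switches to $(P+P^\top)/2$ instead; the two agree whenever the
profile is all that is consumed downstream). Composition fractions are
already length-invariant, so no further division by $L$ is applied —
this is the sense in which the CPE is "normalized by protein length",
and it is why the SPE default normalization is on.

### Comparison tools

All comparisons run on the Manhattan ($L_1$) distance between profiles.
The toolkit mirrors standard practice: 1-nearest-neighbour classification
evaluated by leave-one-out cross-validation (each sample predicted as the
class of its nearest other sample), adjusted Rand index for clustering
agreement, Spearman rank correlation for branching-order comparison,
group-average distance matrices, neighbour-joining and UPGMA trees, and
the separation measure
$E_{AB} = \langle d_{AB}\rangle - (\langle d_{AA}\rangle +
\langle d_{BB}\rangle)/2$ built from closest-neighbour set distances.

## Conventions and tie-breaks

Deterministic behaviour took precedence wherever an arbitrary choice was
needed:

* **1-NN ties** are broken by the smallest sample index.
* **Within-set closest distances** $\langle d_{AA}\rangle$ exclude the
  self term (otherwise they are trivially 0 because $d(a,a)=0$); a
  singleton set has within-set distance 0 by convention. Cross-set
  distances do not exclude shared members, so $E_{AB} \le 0$ when
  $A = B$.
* **Per-type energies** count the $\{i,i\}$ profile entry twice (an
  $i$–$i$ interaction involves two residues of type $i$); a flag selects
  the once convention. Under the default, summing the per-type energies
  counts every interaction exactly twice:
  $\sum_i e_i = 2\sum_{\text{pairs}} \mathrm{SPE}$, an identity the tests
  assert exactly.
* **Negative NJ branch lengths** (possible on non-additive input) are
  clamped to 0, with pre-clamp values retained in an attribute.
* **Macro-F1** is reported alongside per-class F1 when a single number is
  needed; F1 of an empty class is defined as 0.
* **Branching order** relative to an anchor leaf: the tree is rooted on
  the anchor's edge and the remaining leaves are sorted by the
  topological depth of their parent node, ties broken alphabetically.
  This is an explicit operationalization of "which lineage splits off
  first"; it is rotation-invariant and reproduces the ladder order of a
  caterpillar tree. Other operationalizations exist; this one is simple
  and deterministic.
* **Bootstrap resampling unit** is the 210 profile coordinates (sampled
  with replacement per replicate), the analogue of site resampling in
  sequence phylogenetics. Replicate trees are exposed so alternative
  schemes can be evaluated.

## Structure parsing policy

PDB files are read with bio3d and normalized as follows: hydrogens
dropped; altloc `' '`/`'A'` kept, otherwise the highest-occupancy
conformer per residue; `HETATM` excluded except MSE→MET (on by default,
`SE` renamed `SD`); non-standard residue names dropped with a warning;
first model only. OXT and any other atom name outside the 167-type scheme
survive parsing but are excluded from the tessellation point set, since
the potential is only defined on the scheme. Intra-residue tessellation
edges are excluded by default (the profile aggregates *inter*-residue
interactions); a policy flag re-admits them. Delaunay edges shorter than
0.75 &Aring; or at/beyond 15.75 &Aring; cannot be binned and are dropped,
with a counter kept on the contact set.

## Numerical choices

* The tessellation is an incremental Bowyer–Watson construction over
  points rescaled to a unit box inside a large enclosing tetrahedron,
  with cached circumspheres and a small relative tolerance in the
  in-sphere test. Degenerate inputs (collinear/cospherical points) are
  handled by a deterministic uniform jitter of magnitude 1e-6 &Aring;
  from a seeded generator, with one retry; contact distances are always
  recomputed from the unjittered coordinates. Tests verify the
  nearest-neighbour-graph and Gabriel-graph subgraph properties (both are
  provable subsets of the Delaunay edges) and invariance under rigid
  motion.
* Least squares uses the normal equations with an explicit rank check;
  rank deficiency with `lambda = 0` is an error naming the deficient row
  and suggesting ridge regularization, which adds `lambda` to the
  normal-equation diagonal (`lambda = 0` default, as the plain fit is the
  reference behaviour).
* Serialized floating point uses 17 significant digits, which
  reconstructs IEEE doubles exactly; every writer/reader pair is a value
  round-trip, and tests assert it.
* Newick branch lengths are written with 6 decimals.

## What the synthetic data does and does not emulate

The generators produce *geometric toys*: random sequences, residue
centers on a seeded self-avoiding walk with 3.8 &Aring; steps (the
C&alpha; virtual bond length) and full heavy-atom complements at small
random offsets (0.3–1.5 &Aring;) around each center. They guarantee what
the code paths need — valid atom names resolving in the 167-type scheme,
non-degenerate geometry, every distance shell of the reference state
populated, exact planted parameters for the predictor fit, known cluster
structure, additive tree metrics — and each generator asserts its own
construction guarantees.

They do **not** emulate real protein physics: no backbone dihedral
statistics, no rotamers, no secondary structure, no packing density
gradient. Consequently, green tests demonstrate that the machinery is
correct (formulas, conservation identities, recovery of planted
structure, determinism), not that the potential trained on toys carries
biological signal. Reproducing the discriminative results on real fold
and family benchmarks requires training on a curated non-redundant PDB
list and the corresponding external datasets, which this package's tests
deliberately do not download. Problem sizes in tests and the acceptance
script (training sets of 6–12 structures of 20–60 residues, 1000 random
count tensors, 100 randomized oracle trials, 8-leaf trees, 24-point
cluster sets) were chosen as the smallest sizes that exercise every
branch of the code while keeping the default runs quick on a laptop.

## Known limitations

* Single-conformer, first-model parsing discards NMR ensembles and
  alternate conformations beyond the occupancy rule.
* The potential carries no explicit solvation, dihedral or multi-body
  terms; the reference state is the pooled shell distribution.
* CPE quality is bounded by the composition model: it cannot distinguish
  sequence permutations by construction. That is also its speed
  advantage.
* The NJ/UPGMA implementations delegate to ape/stats; trees on highly
  non-additive input inherit those methods' behaviour (with negative
  branch clamping as documented).
* The within-set self-exclusion and tie-break conventions are documented
  choices; other conventions change $E_{AB}$ and classification reports
  in edge cases with exact ties or duplicated profiles.
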