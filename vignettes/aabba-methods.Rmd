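---
title: "Autocorrelation fingerprints for attributed molecular graphs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autocorrelation fingerprints for attributed molecular graphs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aabba)
```

## The model

A molecular graph here is an undirected, connected graph whose nodes
(atoms) carry a table of real-valued atomic properties and whose edges
(bonds) carry a table of bond properties; at most one node is flagged as
the metal center. Fixed-length fingerprints are built from Moreau–Broto
style autocorrelations: sums, over pairs of graph elements at a given
topological distance ("depth"), of an arithmetic combination of their
property values. The classical form correlates atoms with atoms; this
package extends it with bond–bond and bond–atom terms, which bring bond
properties (distances, orders, orbital descriptors) into the
representation — the feature that matters most for transition-metal
complexes, where reactivity is dominated by the metal–ligand bonds.

Four elementary kernels are provided. Writing $p_i$ for an atomic
property value, $q_e$ for a bond property value, and $\hat{O}$ for one of
the four operators (product $a\,b$, deltametric $a-b$, ratiometric $a/b$,
summetric $a+b$), the entry at depth $d$ of each profile is:

* **AA** — over atom pairs with shortest-path distance $d$:
  $\sum \hat{O}(p_i, p_j)$.
* **BB** — over bond pairs with line-graph distance $d$:
  $\sum \hat{O}(q_{e_1}, q_{e_2})$.
* **BB̄ / BB (metal-centered)** — the properties of all metal–ligand
  bonds are first merged into a single *super-bond* by averaging (BB̄) or
  summation (BB); depth 0 is the super-bond self-term and a non-metal
  bond contributes at the line-graph distance to its nearest metal–ligand
  bond.
* **BA** — over (bond, atom) pairs whose bond–atom distance
  (the smaller endpoint distance) is $d$: $\sum \hat{O}(q_e, p_j)$, the
  bond value always first.

Each kernel runs with a *full* origin (all atoms/bonds) or a
*metal-centered* origin (only the metal atom, the super-bond, or the
metal–ligand bonds). Profiles over depths $0..D$ are concatenated per
property into labeled blocks; the **AABBA(I)** vector is the
concatenation of such blocks, and **AABBA(II)** instead merges endpoint
atomic properties and bond properties into a per-edge vector and
autocorrelates that vector exactly like BB, producing a compact
fingerprint directly.

## Depth and counting conventions

The published description leaves the pair-counting and the bond-depth
arithmetic open; the package fixes them as follows and uses the same
conventions in its brute-force test oracle:

* Distances: atom–atom depth is the shortest-path bond count; bond–bond
  depth is the shortest-path distance in the line graph (same bond = 0,
  bonds sharing an atom = 1); bond–atom depth is the minimum over the
  bond's endpoints of the atom distance (own endpoint = 0). For the
  metal-centered BB kernel, metal–ligand bonds form the depth-0
  super-bond and a non-metal bond sits at the line-graph distance to the
  nearest metal–ligand bond, i.e. the first ligand shell is depth 1.
* Full-origin pair counting: each unordered pair contributes once; depth
  0 collects one self-term per origin element. Counting each pair twice
  would only scale the symmetric operators by 2, but would cancel the
  deltametric identically to zero.
* Ordered operators in full scope use a canonical operand order — the
  element earlier in node (or edge) file order is the origin side. This
  preserves information at the cost of depending on the stored element
  order; the permutation-invariance guarantee therefore covers the
  product and summetric operators everywhere and the ordered operators in
  metal-centered scope, where the origin is intrinsic.
* Empty sums (depths beyond the diameter, or no pair at a depth) are
  exactly 0, not missing.
* A ratiometric term with a zero divisor is an error by default; an
  opt-in `on_zero_division = "skip"` mode contributes 0 instead. Silent
  skipping can mask a broken property table, so it is never the default.

Every dimension is labeled `<prop>-<depth>_<origin><op>_<kernel>`
(e.g. `Z-2_FA_AA`), with `BBm` as the ASCII name of the averaged
super-bond kernel and `<bond>.<atom>` as the property field of bond–atom
blocks; `parse_label()` inverts `format_label()` exactly.

## The maximal vector and redundancy removal

`maximal_vector()` concatenates every kernel × origin × operator block at
depths 0–6, in a deterministic order (kernel, origin, operator, property,
depth), so saved models remain valid across runs. Across a dataset,
`remove_redundant()` drops columns that are constant and columns that are
exact duplicates of an earlier column, after canonical rounding to 12
significant digits. Exact duplication is the conservative reading of
"redundant": dropped columns are recoverable from kept ones with zero
error, and the operation is idempotent. Correlated-but-not-identical
columns are deliberately kept — separating them is the job of the
relevance-based reduction, not of preprocessing.

## Model harnesses

Three regression harnesses evaluate the fingerprints; all report MAE and
the coefficient of determination $r^2 = 1 - SS_{res}/SS_{tot}$ (not
squared Pearson; the mean predictor scores exactly 0, and a zero-variance
target yields `NaN` with a warning) over repeated
train/validation/test splits (default 80:10:10, ten repeats, per-repeat
derived seeds; 20:40:40 is the small-data setting).

* **MLP**: two ReLU hidden layers of 128 units, Adam on MSE, features
  z-scored on the training set. Epoch budget (2000), early-stopping
  patience (50 on validation MSE) and batch size (`min(64, n/10)`) are
  package defaults, configurable; the architecture convention does not
  fix them. Implemented in package code because no suitable
  deep-learning backend is part of the package's dependency set.
* **GBM**: 1000 regression trees of depth 5, learning rate 0.05, 5-fold
  cross-validation (xgboost backend). Feature relevance is the fraction
  of total split gain — the squared-error impurity reduction (Friedman
  MSE criterion) — attributed to each feature, averaged over folds and
  normalized to sum to 1. Trees are scale-invariant, so features are not
  standardized for the GBM. One caveat documented here because it is
  easy to trip over: impurity relevance divides credit arbitrarily among
  features that are exact monotone transforms of one another, and a
  maximal autocorrelation vector contains such twins (e.g. the product
  and summetric self-terms $s^2$ and $2s$ of the same super-bond).
  Recovery claims about specific columns are therefore only meaningful
  against independent (noise) alternatives, or at the level of
  descriptor families.
* **GP**: zero-mean Gaussian-process regression with the multiplied
  Linear × RBF kernel
  $k(x,x') = \sigma^2_{lin}\langle x,x'\rangle \cdot \sigma^2_{rbf}
  \exp(-\lVert x-x'\rVert^2/2\lambda^2)$
  plus Gaussian noise. The two variances enter only through their
  product, so the optimizer works on the combined amplitude (reported
  split evenly between the two factors). Amplitude, length-scale and
  noise are fitted on train+validation by marginal-likelihood
  maximization: L-BFGS on log-parameters with analytic gradients, three
  restarts by default, and an escalating diagonal jitter
  ($10^{-10}$–$10^{-4}$ of the mean diagonal) before declaring a
  covariance matrix numerically indefinite. Features are z-scored on the
  training split; duplicate rows are handled by the jitter. The dense
  Cholesky solver targets datasets up to a few thousand rows.

## Accumulated-relevance reduction

`prune_by_accumulated_relevance()` keeps the smallest prefix of the
relevance ranking whose cumulative relevance reaches a threshold (ties
broken by original column order; the kept set is reported in column
order, so threshold 1 is the identity). `reduce_scan()` tabulates MAE
against reduced dimensionality over a descending threshold grid, always
including the full-dimensional baseline. The relevance ranking is
computed once from the full data, not re-estimated per threshold, and by
default the GP kernel hyperparameters are also fitted once per repeat on
the full-dimensional data and reused across thresholds
(`refit = "per_threshold"` re-optimizes them). Fixed hyperparameters
make the scan cheap (one Cholesky per threshold and repeat) and make the
threshold-1 row reproduce the baseline exactly; the cost is that
length-scales tuned at full dimensionality are long relative to pruned
subspaces, where the kernel degenerates gracefully toward its linear
factor.

## The synthetic generator

`generate_graphs()` emulates the star-of-subtrees topology of a
mononuclear complex: one metal hub whose neighbors are the roots of 4–6
random ligand trees of 1–6 atoms, each atom within 3 bonds of its root.
Properties are drawn independently per element from configurable
distributions; the shipped catalog (`znum`, `eneg`, `radius`; `blen`,
`border`) mimics the *shape* of a generic chemistry property set —
an integer-valued size property, positive reals elsewhere — and is
explicitly a synthetic stand-in, not chemistry. All values are strictly
positive so every operator (including ratiometric) is defined on every
graph. `generate_targets()` plants a linear target on named fingerprint
dimensions plus Gaussian noise and records the noiseless signal; the
default recipe weights its two terms (`znum-1_MA_AA`, `blen-0_MS_BBm`,
weights 0.001 and 3) so both contribute comparable variance under the
default distributions. A single seed drives generation through a
save/restore wrapper around R's Mersenne–Twister stream, so datasets are
byte-reproducible and the session RNG is never disturbed.

What the generator does *not* emulate: electronic-structure physics,
correlated property tables (real atomic numbers, radii and
electronegativities co-vary strongly), discrete ligand chemistry, or
rings within ligands. Passing tests on this generator demonstrates the
correctness of the featurization arithmetic and the recoverability of
planted statistical structure — not predictive accuracy on real
complexes.

## Problem sizes used in the shipped checks

The test suite verifies the kernels against an independent brute-force
enumeration oracle (Floyd–Warshall distances, explicit line graphs) on
200 random graphs of up to 10 nodes at depths 0–4 and 10⁻¹² relative
tolerance. The planted-recovery benchmark uses 1000 graphs, the 2
planted dimensions plus 480 independent noise dimensions, and noise at
10% of the signal's standard deviation; the reduction scan runs the GP
over a seven-point threshold grid with two split repeats. The
acceptance script runs the full pipeline at 500 graphs with three GP
repeats. These sizes were chosen as the smallest at which the
statistical claims are stable across seeds.

## Known limitations

* Full-scope deltametric/ratiometric blocks depend on the stored node
  order (documented above); graphs serialized and re-read keep their
  order, but reordering nodes changes those blocks.
* The GP is dense $O(n^3)$; no sparse/inducing-point approximation.
* AABBA(II) variant recipes II1–II5 are shipped defaults (package
  conventions), configurable through `merge_recipe()`; they are not a
  published standard.
* Whole-graph descriptors (`wg_*`) are a minimal optional block (counts
  and property sums).
* No SMILES/xyz or electronic-structure parsing: graphs enter as JSON or
  GML with properties already attached.
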