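---
title: "Methods: classifying and mapping green odorants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and mapping green odorants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

"Green odor" is the grassy smell of freshly cut leaves, classically
attributed to a small family of C6 alcohols and aldehydes (the hexenols and
hexenals). Whether an arbitrary small molecule smells "green" is a binary
molecular-property prediction problem: given a SMILES string, output the
probability that the molecule belongs to the green-odor class. greenodor
implements the full workflow around that question — dataset curation,
fingerprint featurization, three classical classifiers under one prediction
contract, repeated cross-validated evaluation, chemical-space clustering of
the positive class, and a descriptor-level statistical contrast between the
two classes.

## Representation

Molecules are represented as binary Morgan (circular, ECFP-style)
fingerprints of radius 2 folded to 2048 bits. Every atom receives an initial
invariant hashed from (atomic number, heavy-atom degree, implicit hydrogen
count, formal charge, ring membership); each iteration re-hashes the
invariant together with the sorted (bond order, neighbour invariant) pairs,
so after $r$ iterations an identifier encodes the full bonded environment up
to $r$ bonds. Environments whose bond set duplicates one already emitted are
dropped (so a methane molecule contributes exactly one environment no matter
the radius), and surviving identifiers are folded modulo 2048. Bit
collisions from folding are accepted as-is; that is the standard behaviour
of fixed-length fingerprints. On reference molecules the per-heavy-atom
distinct-environment counts (`FpDensityMorgan1`–`3`) agree exactly with the
widely used cheminformatics toolkit values (ethanol 2/2/2, hexane
0.833/1.167/1.333, benzene 0.333/0.5/0.667).

Similarity between fingerprints is the Dice coefficient
$\mathrm{DSC}(A,B) = 2|X \cap Y| / (|X| + |Y|)$ over the on-bit sets. Two
empty fingerprints are defined to have similarity 0 (not 1) so featureless
inputs are never spuriously identical.

SMILES parsing, canonicalization and bulk physicochemical properties go
through OpenBabel (via ChemmineOB). The molecular graph layer reads
OpenBabel's V2000 output directly because the higher-level SDF container in
the R toolchain mis-handles single-heavy-atom molecules. Implicit hydrogens
are inferred from standard valences with charge adjustment; ring membership
comes from bridge detection on the bond graph.

## The descriptor battery

`compute_descriptors()` always contains the nine descriptors used by the
factor screening — `FpDensityMorgan1`–`3`, `NumValenceElectrons`, `MolWt`,
`PSA`, `pyLabuteASA`, `HeavyAtomMolWt`, `TPSA` — plus standard extras (logP,
molar refractivity, H-bond donor/acceptor counts, ring/rotatable-bond
counts, heteroatom count, fraction of sp³ carbons). Two deliberate choices:

* `PSA` and `TPSA` are both topological polar surface areas and are kept as
  two named entries, because descriptor batteries conventionally list both
  labels and the screening table has nine rows. They are perfectly
  collinear; the factor-analysis gates treat that case explicitly (see
  below).
* `pyLabuteASA` is computed in-package as Labute's approximate accessible
  surface area: one van der Waals sphere per atom (Bondi radii, implicit
  hydrogens as explicit spheres), minus one spherical cap per bonded
  neighbour at the idealised bond length. Values are in Å² of van der Waals
  surface; they are strongly rank-correlated with other implementations but
  not numerically identical, which is all the downstream factor analysis
  needs (it standardizes every variable).

## Classifiers

All three models consume the same 2048-bit fingerprints and expose
`predict_scores()` (green-class probability) and `predict_labels()`
(threshold 0.5). `predict_scores` is a generic, so any external model
honouring the contract can be plugged into the evaluation harness.

* **MLP** — 2048 → 256 → 256 → 2 with ReLU and dropout 0.1 between layers,
  softmax cross-entropy, Adam at learning rate 0.001, batch size 1/16 of
  the training set (`ceil(n/16)`, final short batch kept). Early stopping
  monitors the epoch-mean *training* loss (no inner validation split is
  held out): when the loss has failed to improve its running best by more
  than 1e-6 for 7 consecutive epochs, training stops; `max_epochs`
  (default 500) is a safety bound. The training loop is compiled
  (RcppArmadillo) with a single Mersenne-Twister stream for weight
  initialization, batch order and dropout masks, so a fit is bit-for-bit
  reproducible given its seed. The green class is the second output
  neuron.
* **SVM** — RBF kernel with C = 1, gamma = 0.1, Platt-scaled
  probabilities (e1071).
* **Random forest** — 100 trees, depth ≤ 6, `floor(log2(p))` features per
  split, terminal nodes ≥ 50 samples (ranger). The `min_samples_split = 2`
  convention of the reference configuration is the splitting default and
  has no separate knob.

A plain grid search (`grid_search()`) scores candidates by stratified
5-fold CV accuracy; ties break by grid order and failed candidates score
−∞ with a note in the audit table.

## Evaluation

`run_repeated_cv()` performs stratified 5-fold cross-validation repeated 10
times (50 evaluation folds; every molecule is a test item exactly 10
times). Per fold it reports the confusion counts and precision, accuracy,
recall, F1, MCC — exactly the textbook count formulas — plus AUC and
average precision. AUC is computed by Mann–Whitney pair counting (ties
count half), which matches the probabilistic definition directly rather
than integrating an ROC curve. Average precision is the non-interpolated
step sum $\sum_k (R_k - R_{k-1}) P_k$. Zero-denominator metrics degrade to
0 with a warning so degenerate folds never crash the harness, and a fold
whose training fails is recorded and excluded from the means. The mean
confusion matrix is the element-wise mean of the per-fold count matrices.
Green is the positive class throughout.

## Chemical-space clustering

The positive class is embedded in 2-D and clustered with a distance-cutoff
rule: two molecules join the same group when their embedded Euclidean
distance is strictly less than 1/24 of the largest pairwise distance in the
set; groups are the connected components of that proximity graph
(equivalently, single-linkage clusters cut at the cutoff — the package
verifies this equivalence against `hclust` in its tests). Strictness
matters at the degenerate extreme: if all points coincide the cutoff is 0
and the rule would make every point a singleton, so that case is
special-cased to a single cluster with a warning. Cluster ids are ordered
by decreasing size. Groups smaller than `min_major_size` (default 30, the
reference threshold on a 587-molecule positive class; scale it with your
class size) are dropped from the major-cluster summary; the display
threshold of 7 molecules affects only plotting/export tags.

Two embeddings satisfy the `embed_2d()` contract (deterministic under a
seed): an exact O(n²) t-SNE implemented in-package (perplexity default 30,
early exaggeration 12 for 100 of 500 iterations, learning rate 200,
adaptive gains) and classical metric MDS (`cmdscale`). t-SNE is the default
and matches the reference workflow. One practical caveat found during
development and worth knowing: t-SNE equalizes within-cluster density, so
on small synthetic sets the fixed 1/24 cutoff tends to fragment chemotype
blobs into sub-cutoff islands; metric MDS preserves the global distance
scale and recovers chemotype-level major clusters much more stably. The
multi-chemotype recovery checks in the test suite therefore run on the MDS
embedding; with several hundred molecules per chemotype the t-SNE route
behaves comparably.

The chemical space network (CSN) has molecules as nodes at their embedded
coordinates and an edge for every pair within the cutoff, weighted by the
Dice similarity of the two fingerprints; network components coincide with
the cluster labels by construction. Each cluster's representative molecule
is the member maximising closeness centrality on the cluster's unweighted
subgraph, using the Wasserman–Faust composite
$C(v) = \frac{r_v}{n-1}\,\frac{r_v}{\sum_{u} d(v,u)}$ (sums over nodes
reachable from $v$), which degrades gracefully on disconnected subgraphs; a
singleton is its own representative with score 0. An alternative rule —
highest mean Dice similarity to the other members — is available because
the two formulations ("most central" vs "most similar") are both natural
readings of representativeness; printed centralities from the reference
workflow are not reproduction targets because the exact graph underlying
them is not fully specified.

## Descriptor statistics

Factor screening: variables are standardized, factors extracted from the
correlation matrix by the principal-component method, and rotated with
varimax. Two numerical choices matter. First, the battery legitimately
contains a perfectly collinear pair (PSA/TPSA), which makes the correlation
matrix singular; eigendecomposition is unaffected, but KMO and Bartlett's
test need the inverse, so the gates are reported as not computable in that
case (and `kmo()` itself names the collinear pair in its error). Second,
the varimax iteration in base R can stall in a local optimum (or a saddle,
for symmetric two-block loading geometries — observed on exact two-factor
simulations), so the rotation is restarted from eight fixed orthogonal
starts and the solution with the largest varimax criterion is kept; the
restarts are seeded constants, so results are deterministic. Each factor is
signed so its largest-magnitude loading is positive. Screening retains
descriptors whose maximum absolute loading is *strictly* greater than 0.75.

Difference analysis follows a normality-gated decision tree per
descriptor: Shapiro–Wilk on each sample at α; if either sample rejects
normality (or is constant, where Shapiro–Wilk is inapplicable), the
two-sided Mann–Whitney U test is used; otherwise Levene's test
(median-centred, the robust Brown–Forsythe form — the gate is unnamed in
the reference description, so the robust default was chosen) routes to
Welch's t-test (heteroscedastic) or the pooled t-test. α defaults to 0.05
with 0.01 available as the stricter preset, because the source workflow
uses both thresholds in different places. No multiple-testing correction is
applied across the nine descriptors, matching the reference procedure; a
BH/Bonferroni option exists but defaults off. Direction is the sign of
median(green) − median(non-green).

## The synthetic data generator

`generate_synthetic()` builds the two classes from enumerated template
families. The green class emulates the leaf-volatile chemotype: C4–C10
aliphatic alcohols, aldehydes, methyl ketones and esters, saturated or with
one E/Z double bond at each interior position (245 distinct structures; the
classic hexenols/hexenals are members). The non-green class is
tri-substituted benzenes and di-substituted fused heterocycles
(naphthalene, quinoline, benzofuran, benzothiophene) carrying polar
substituents (~1250 distinct structures). Draws are without replacement,
deduplicated on canonical SMILES, and deterministic given the seed; a
`green_families` argument restricts the green draw to chosen chemotypes in
equal proportion for cluster-recovery experiments.

The generator plants the contrasts the difference analysis is expected to
find: at the default templates the realized gaps are ≈70 mass units in
MolWt and ≈50 Å² in TPSA (well above the ≥60 / ≥15 design floors), with
NumValenceElectrons, HeavyAtomMolWt, PSA and pyLabuteASA moving with them.
What the generator does *not* emulate: fingerprint density. Real non-green
odorants are structurally simple aromatics, so real green molecules have
*higher* FpDensityMorgan1–3; the synthetic non-green class is heavily
substituted and environment-dense, so that particular contrast runs in the
opposite direction here. Tests therefore assert the planted mass/surface
contrasts, not the fingerprint-density direction — a passing suite says the
machinery recovers planted effects, not that the synthetic classes are
chemically exchangeable with curated odorant databases. Odor plausibility
of individual synthetic molecules is likewise out of scope.

`generate_separable_fingerprints()` is the classifier test fixture: class
"nongreen" draws its on-bits from the lower half of bit positions, "green"
from the upper half, each class with one always-on anchor bit; at zero
noise a single-bit rule is perfect, and a `noise` parameter relocates
non-anchor bits into the wrong half with the given probability.

## Problem sizes and determinism

The test-suite and acceptance workloads use: 1,000 random confusion tables
and 200 random score vectors for the metric oracles; 100 random 200-point
instances for the clustering oracle; 200 + 200 synthetic molecules for the
difference analysis; an n = 1000 exact two-factor simulation for loading
recovery; 2,000 null simulations (n = 30 per sample) for the type-I check;
and 5×10-fold CV of the MLP on 400 separable 2048-bit fingerprints, each
fold trained with an epoch budget of 20 — on this benchmark the trainer
reaches separation within a few epochs, so the budget is a cost choice, not
a convergence compromise. Every random stage derives its own seed from the
global seed via a stage-name hash (`derive_seed()`), so stages are
independently reproducible and re-running any command with the same
configuration reproduces its CSV outputs byte-for-byte.

## Known limitations

* The fingerprint implementation is ECFP-style but not bit-compatible with
  any specific external toolkit; cross-toolkit comparisons should go
  through similarities, not raw bit positions.
* OpenBabel is the single chemistry authority: molecules it cannot parse
  are dropped in cleaning, and its TPSA/logP conventions are inherited.
* The cleaning step deduplicates on exact canonical SMILES, so
  stereoisomers and tautomers with distinct canonical forms are kept as
  distinct molecules.
* t-SNE is exact O(n²): comfortable to a few thousand molecules, not
  intended beyond that.
* The difference analysis treats descriptors marginally (no multivariate
  test), mirroring the reference procedure.
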