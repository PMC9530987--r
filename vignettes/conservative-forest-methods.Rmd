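---
title: "Conservative random forests for endocrine-activity screening: models, parameters and design choices"
author: "ConservativeRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conservative random forests for endocrine-activity screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ConservativeRF)
```

## Scope and model

`ConservativeRF` trains random-forest (Q)SAR classifiers for endocrine
receptor activity from molecular fingerprints: a mostly-binary vector of
substructure indicators plus a handful of continuous physical-chemical
properties per substance, labelled either Inactive/Active or on the
ordered potency scale Inactive < Very Weak < Weak < Moderate < Strong.
The datasets this method targets are severely imbalanced and the
screening context is asymmetric: a missed active is costlier than a false
alarm. Three design commitments follow and run through every component:

1. **Balanced accuracy** — the mean of per-class recalls — is the central
   statistic, because it is insensitive to imbalance and extends
   unambiguously to multi-class problems (a constant predictor scores
   exactly $1/n$ for $n$ classes).
2. **Conservatism**: every tie, anywhere in the pipeline, resolves toward
   the stronger activity class.
3. **Auditability**: every stage is deterministic given a seed, and every
   model serializes to JSON that round-trips bit-exactly.

## The decision-tree learner

Trees are grown on random subsets of the training substances (75% drawn
without replacement per tree, 101 trees per forest by default). At each
node a random subset of descriptors is considered — default
$\lceil\sqrt{d}\rceil$ of the post-pruning descriptors, the canonical
random-forest heuristic; the size is configurable
(`treeConfig(nFeatureSubset=)`).

**Binning.** At the start of each tree, every continuous descriptor is
discretized into twenty equal-width bins over *that tree's* sample range;
the 19 internal boundaries are the only thresholds tested. A molar-mass
range of 50–250 yields boundaries 60, 70, …, 240. "Equal-sized" here means
equal-width: only that reading produces evenly spaced boundaries like
these. Because each tree sees a different subsample, bin spacing varies
across trees, which adds the same kind of de-correlation that feature
subsetting does. Binary descriptors have the single candidate threshold
0.5.

**Split costs.** Four costs are selectable. Gini impurity is scored as the
weighted mean of child impurities (lower is better; the implementation
negates it so that all costs are maximized). The metric costs — balanced
accuracy, Matthews correlation, macro F — are evaluated on the labelling
induced by the candidate split: each child's samples are assigned that
child's conservative-majority class and the metric of this two-child
labelling against the observed classes is the score. This is the minimal
construction that makes a classification metric well-defined at a single
node. One practical consequence, visible in the test suite: on strongly
imbalanced nodes a single split often cannot change any child's majority
class, so BA/MCC/F-driven trees may stop early (sometimes as depth-0
stumps) where Gini's concavity always finds gradient. The protocol
therefore trains one forest per requested cost and lets the fitness
selection pick the representative; in practice Gini usually wins on the
synthetic benchmarks.

**Stopping and ties.** A node becomes a leaf on purity, at `maxDepth`
(default 20 — deliberately generous, since the genetic optimizer caps
depths afterwards), below `minNodeSize` (default 2), or when no candidate
strictly improves on the unsplit node's score. Exact score ties break to
the lowest descriptor column index, then the lowest threshold, making
training order-deterministic. Every node stores its class-count vector,
so prediction can stop at any depth cap and return that node's
conservative majority.

## Forest prediction and the conservative vote

A forest prediction tallies the enabled trees' votes (each tree read at
its depth cap) and returns the class with the maximum tally, resolving
ties toward the strongest class: equal Inactive/Active votes give Active;
a Weak/Moderate tie gives Moderate. The same rule labels tree nodes. The
test suite verifies by exhaustive enumeration (all tallies over up to 5
classes summing to ≤ 9) that this vote never returns a weaker class than
a weakest-wins tie-break would.

## Genetic optimization

After training, a genetic algorithm searches the space of per-tree
(enabled, depth-cap) assignments. The published description of this step
defers its exact scoring equations to supplementary material that is not
available; the package therefore defines its own documented fitness

$$F = \frac{BA_{train} + BA_{test}}{2} - \lambda\,|BA_{train} - BA_{test}|,
\qquad \lambda = 0.5,$$

which matches the stated intent — improving the balanced accuracy of both
the training and the testing data — while explicitly penalizing the
train/test gap that signals overfitting. $\lambda = 0$ recovers the plain
mean; the parameter is exposed in `gaConfig()`. GA hyperparameters
(population 50, 100 generations, crossover 0.8, mutation 0.05/gene,
elitism 2, tournament 3) are standard small-GA settings, all
configurable. Two structural guarantees matter more than the exact
settings: the identity chromosome (all trees enabled, uncapped) is seeded
into generation 0, so the optimized forest can never score below the
unoptimized one; and elitism makes the best-ever fitness non-decreasing.
On a 3-tree forest the chromosome space is small enough to enumerate, and
the test suite checks the GA reaches the exhaustive optimum there.

## Applicability domain

The AD answers "is this query chemically similar enough to the training
set for the prediction to be trusted?". The pruned training fingerprints
are embedded by PCA keeping the smallest number of components whose
cumulative explained variance reaches 95% (component signs are fixed by
making the largest-magnitude loading positive, for determinism). Each
training point receives an admission radius equal to its mean Euclidean
distance to its $k = 5$ nearest training neighbours — small in dense
regions, large in sparse ones, the density-kNN idea. A query is in-domain
if it falls within the (capped) radius of at least one training point, so
a training point is always in-domain with respect to itself.

The threshold rule is parameterized by $n^{1/m}$, with $n$ the number of
training points. The published account states the expression but not the
quantity it cuts; this package applies it as a quantile index: the radius
cap is the $\lceil n^{1/m}\rceil$-th *smallest* per-point radius, and all
radii are truncated to it. At $m = 1$ the index is $n$ (no capping, the
loosest domain); as $m \to \infty$ the index tends to 1 and every radius
collapses to the smallest — so larger $m$ monotonically tightens the
domain, the direction the optimization below relies on. This reading is
the package's own and is not asserted to be the original authors'; the
alternative ("$n^{1/m}$-th largest") reverses the direction and would make
the tuning loop inconsistent.

`optimizeM` scans a grid of $m$ (default 1–10 by 0.5) and picks the value
maximizing in-domain balanced accuracy subject to coverage ≥ 0.85 —
i.e. removing at most roughly 15% of the data; ties prefer higher
coverage. When no grid value reaches the coverage floor, the BA-improving
value with the highest coverage is taken instead. Note a geometric
caveat: for high-dimensional, mostly-binary fingerprints, pairwise
distances concentrate, and even the uncapped domain ($m = 1$) can cover
less than 85% of held-out data; in that regime the fallback rule governs
and coverage should be read from the reported metrics table rather than
assumed.

## Fingerprint assembly and pruning

Computing PubChem/MACCS/FP2-style bits is external-tool territory; the
package defines only the adapter contract (a function mapping structure
strings to a fixed-width numeric block) and the assembly step, which
concatenates adapter outputs in declared order and drops — never
zero-fills — substances any adapter fails on. The bundled hash-bit
adapter generates deterministic pseudo-random bits from the structure
string so the contract is testable offline.

Pruning is two deterministic passes: descriptors with no variance are
removed, then descriptors are scanned left-to-right and any later
descriptor with Pearson $|r| > 0.98$ against a kept one is dropped (the
earlier, i.e. first-declared, descriptor survives). Absolute correlation
is the default because an anti-correlated binary bit is exactly as
redundant as a correlated one; `absolute = FALSE` restores the literal
signed reading. Pruning is fitted on training data only and the learned
keep-list is re-applied to test or new data, avoiding leakage. Both
passes are idempotent.

## Data handling rules

* **75/25 split, stratified.** With potency classes holding only tens of
  substances, an unstratified split can leave a class empty and make
  per-class test metrics incomputable. Each class contributes
  `floor(n_c × fraction)` substances to training, remainders assigned by
  largest fractional part; a singleton class goes to training with a
  warning.
* **Missing values.** The CSV loader rejects rows with missing
  descriptors by default; an explicit flag median-imputes continuous
  columns instead. Silent imputation has no place in a screening tool.
* **Duplicates.** Exact duplicate structure strings are removed keeping
  the first occurrence; when duplicates disagree on the label, the kept
  substance takes the *strongest* label — the conservative resolution.
* **Source counts.** Literature-derived calls become more reliable with
  more independent sources; `filterMinSources` implements the ≥ 4-sources
  restriction used for receptor-binding data.

## The synthetic-data generator

No real dataset ships with the package; the generator
(`generatorSpec()` / `generateFingerprintData()`) emulates the structure
the method assumes. Its defaults mirror the binary estrogen-agonism
condition: 6,319 substances with class priors (0.945, 0.055) — the
roughly 5,969:350 Inactive:Active imbalance of the curated evaluation
data — and 2,456 descriptors before pruning (2,435 informative-or-noise
bits, 3 all-zero columns, 15 continuous properties, 3 exact duplicate
columns). Informative bits shift their Bernoulli success probability
linearly across the class range by ±`bitEffect` (default 0.4, a value at
which forests learn reliably without making the problem trivial; 50
informative bits by default); continuous descriptors are unit-variance
Gaussians whose means shift by 2·`bitEffect`·σ across the class range;
source counts are 1 + Poisson(3), centring the distribution on the
≥ 4-sources threshold. The optional contaminant block gives each
contaminated substance a random label and its own ~5σ offset in the
continuous coordinates, isolating it from the data density — the
situation an applicability domain exists to catch.

The five-class benchmark uses priors (0.745, 0.101, 0.132, 0.011, 0.011),
the multi-class receptor-binding composition. What the generator does
*not* emulate: real substructure-bit correlation structure (bits are
independent given the class), chemically meaningful descriptor scales,
and label noise. Passing tests therefore demonstrate that the algorithms
are implemented correctly and recover planted structure; they do not
certify accuracy on real chemistry.

## Problem sizes and numerical choices

The test and benchmark sizes are chosen so the full suite runs in about a
minute on one core while still being statistically meaningful: the
separable benchmark is 2,000 substances × 200 descriptors with a 101-tree
forest; the GA-optimality check uses a 3-tree forest whose chromosome
space is enumerable; split-search equivalence is checked against a
brute-force oracle on 50 × 10 instances for all four costs; the
protocol-determinism check runs the full pipeline twice on a 350-substance
fixture. Numerical tie tolerance in split search is $10^{-12}$ (scores
closer than that are treated as ties and broken positionally). Model JSON
is written with 17 significant digits so thresholds round-trip
bit-exactly. All randomness flows from user-supplied integer seeds;
per-tree and per-stage streams are derived as
`(seed × 10007 + index) mod (2³¹ − 1)`.

## Known limitations

* The GA fitness is a documented stand-in for unavailable reference
  equations; results may differ from the original implementation even on
  identical data.
* Metric-based split costs frequently stall on imbalanced nodes (see
  above); they are faithful options, not recommendations.
* The $n^{1/m}$ rule's target quantity is this package's interpretation.
* Multi-class errors are all weighted equally; misclassifying Strong as
  Moderate costs as much as Strong as Inactive, although the screening
  consequences differ.
* The pipeline does not calibrate probabilities, weight votes, or model
  descriptor noise; predictions are class labels only.
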