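---
title: "Counter-propagation neural networks for multiclass QSAR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counter-propagation neural networks for multiclass QSAR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpann)
```

## The modelling problem

P-glycoprotein (P-gp, ABCB1) is an ATP-driven efflux transporter that pumps
a remarkably diverse range of compounds out of cells, and it shapes the
ADMET profile of many drugs. Compounds interacting with it fall into three
classes: *substrates* (transported), *inhibitors* (block transport) and
*non-active* compounds. Given a table of numeric 2D molecular descriptors
for a curated compound set, the package builds a three-class classifier
with a counter-propagation artificial neural network (CP-ANN) and supplies
the full workflow around it: structure-driven dataset splitting, descriptor
reduction, genetic-algorithm (GA) descriptor selection, class-balanced
evaluation, and a distance-based applicability domain.

Descriptor computation itself (e.g. Dragon) is out of scope: the input is
always a compounds-by-descriptors CSV with a class label column.

## The CP-ANN model

The network has two layers of identical grid shape. The Kohonen layer is a
self-organizing map: neuron $j$ holds a weight vector $w_j \in
\mathbb{R}^m$ over the $m$ descriptors, and an input $x_s$ is assigned to
the *winning* (central) neuron $c$ minimizing the Euclidean distance
$d_j = \sum_i (x_{si} - w_{ji})^2$. During training, epoch $t$ presents
every training compound once in a seeded random order; the winner's
neighbourhood moves toward the input,

$$\Delta w_{ji} = \eta(t)\, a(D_c - D_j)\, (x_i - w_{ji}^{old}),$$

with the linear learning-rate schedule

$$\eta(t) = (a_{max} - a_{min}) \frac{t_{max} - t}{t_{max} - 1} + a_{min},$$

so $\eta(1) = a_{max}$ and $\eta(t_{max}) = a_{min}$. The output layer
holds, per neuron, one weight $u_{kj}$ per class. Targets are one-hot
vectors $y \in \{0,1\}^G$; after each winner search the output weights of
the same neighbourhood are corrected by
$\Delta u_{kj} = \eta(t)\, a(D_c - D_j)\, (y_k - u_{kj}^{old})$, i.e. with
exactly the same factor as the Kohonen update of that step. Because every
update is a convex pull toward a value in $[0,1]$ and weights initialize
uniformly in $[0,1]$, output weights stay in $[0,1]$ and read as bounded
class indicators.

Prediction finds the winner from the descriptors alone and reads off the
winner's output-weight vector as class scores. A score above 0.5 counts as
predicted class membership; the single assigned class is the argmax. Rows
where no class, or more than one, clears 0.5 are flagged
(`below-threshold` / `multiple-above`): the per-class threshold semantics
and single-label confusion matrices can only be reconciled by argmax, so
the flag preserves the information that the winner neuron was ambiguous.

### Grid topology and neighbourhood

The grid is square and non-toroidal; topological distance is the Chebyshev
ring distance (the eight surrounding neurons are ring 1). The
neighbourhood function is triangular, $a(d) = 1 - d/(r_t + 1)$ inside the
radius and 0 outside: value 1 at the winner, linearly decaying, the
simplest shape consistent with a "triangular" kernel. Two choices the
source material leaves open are declared here as design decisions, not
inferences: the radius shrinks linearly from $\max(\text{rows},
\text{cols}) - 1$ at $t = 1$ to 0 at $t = t_{max}$ (standard Kohonen
practice), and weights initialize uniformly in $[0,1]$ per component from
the run's seed. Winner ties break to the first neuron in row-major order.
Kohonen and output layers are updated within the same pass; a two-phase
variant (map first, then outputs) was considered and rejected because the
single-pass form needs no second schedule and reproduces the same
fixed-point behaviour.

## Preprocessing

The canonical reduction chain, in order:

1. **Variance filter** — descriptors with sample SD below $10^{-4}$ carry
   no information and are dropped.
2. **Correlation filter** — descriptors are scanned in column order; a
   descriptor with $|r| \ge 0.95$ (Pearson) against an already retained
   one is removed and its surviving partner recorded. Scanning in input
   order makes the filter deterministic and idempotent where "keep only
   one of the pair" alone would leave the survivor unspecified.
3. **Autoscaling** — $x^{norm} = (x - \bar{x})/s_x$ with the sample SD
   ($n-1$). The fitted means and SDs are stored and re-applied to test,
   validation and new compounds. By default the statistics are fitted on
   the entire dataset before splitting (the convention of the original
   workflow this package follows); `scale_on = "train"` fits them on the
   training partition only, which is the leak-free choice when the split
   precedes preprocessing in an external protocol. Both are exposed
   because the two conventions disagree in exactly the situations where
   the model is audited.
4. **SOM descriptor reduction** — the *transposed* autoscaled matrix is
   mapped onto a small grid (default 7×7), so descriptors that behave
   alike across compounds share neurons. From each occupied neuron the
   descriptor nearest to and the descriptor farthest from the neuron's
   weight vector are kept: the nearest is the neuron's best
   representative, the farthest preserves within-neuron diversity. The
   retained count is $\sum_j \min(2, \text{occupancy}_j)$, at most twice
   the occupied-neuron count. Whether the reduction map should share the
   splitting map's learning parameters is unstated in the source
   workflow; the package defaults the reduction map to the same
   0.5→0.01, 100-epoch schedule and exposes it via `som_config`.

## Dataset splitting

Training/test/validation (TR/TE/V) partitions are drawn from clusters on
a Kohonen top-map (default 20×20, 100 epochs, learning rate 0.5→0.01) so
that each partition covers the whole descriptor space: within each
occupied neuron, compounds are taken in seeded random order; the first
goes to TR (every cluster is represented in training), each later one
joins the partition furthest below its target fraction, with ties broken
TR, TE, V. This weighted round-robin is one consistent reading of
"cluster-based selection spanning the whole map" — the exact allocation
rule of the original workflow is not recorded — and it guarantees global
sizes within a couple of compounds of the requested fractions (the
defaults 0.711/0.136/0.153 turn 2512 compounds into 1786/341/385). The
split is structure-driven only; labels play no role, and V is fixed
before any model construction.

## GA descriptor selection

Chromosomes are binary inclusion vectors over the preprocessed
descriptors. Fitness is $MCC_{TR} \times MCC_{TE}$ of a CP-ANN trained on
the selected columns, each factor the arithmetic mean of the per-class
one-vs-rest Matthews correlation coefficients. The mean is used because
the multiclass aggregation of per-class MCCs is not otherwise defined in
the source workflow, and the arithmetic mean is symmetric in the classes;
the product rewards subsets that perform on *both* sets, penalizing
memorization. The search is steady-state with elitism: per generation two
parents are drawn by rank-proportional roulette (rank weighting stays
well-defined when MCC products go negative), recombined by uniform
crossover, mutated bitwise (rate 0.02), and the offspring replaces the
weakest non-elite member unconditionally. Fitness values are memoized by
bit pattern, and every fitness network trains from the same derived seed,
so a chromosome scores identically wherever it reappears and reruns are
exactly reproducible. Default search parameters: 95 chromosomes, 150
generations, 20 survivors, learning rates 0.6/0.001; the fitness networks
default to a reduced 20×20/150-epoch configuration, with the full-size
network refit once on the winning subset.

## Evaluation

All per-class measures are one-vs-rest from TP/FP/FN/TN counts:
sensitivity $100 \cdot TP/(TP+FN)$, specificity $100 \cdot TN/(TN+FP)$,
precision $100 \cdot TP/(TP+FP)$, and
$MCC = (TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}$
with the standard 0 convention for a degenerate denominator. The global
indices are class-balanced: NER (non error rate) is the mean per-class
sensitivity and AvPr the mean per-class precision. Overall accuracy is
computed but never used for selection — with class imbalance of roughly
1178/477/857 it rewards majority-class bias. Undefined measures (zero
denominators, e.g. a class absent from the truth vector) propagate as
`NA` and are excluded from the averages with a warning.

The package ships the published external-validation confusion matrices of
the P-gp CP-ANN classifier (385 compounds) as fixtures
(`validation_confusion_fixtures()`); feeding them through the metrics
module reproduces the published validation-set metrics to within the
printing convention (the source tables appear to truncate rather than
round, e.g. a computed 75.98 printed as 75.9). One published cell — the
inhibitor validation MCC, printed 0.63 — is inconsistent with its own
confusion matrix, which yields 0.59 by the MCC formula; the package
documents the discrepancy and makes no attempt to reconcile it.

## Applicability domain

Reliability is judged in the model's own geometry: the Euclidean distance
(ED) between a compound's autoscaled descriptor vector and its winning
neuron's weight vector. The domain boundary is the maximum ED observed on
a reference partition, by convention the test set, and the boundary is
inclusive — a compound exactly at the reference distance is in-domain.
Predictions whose class scores fall within ±0.1 of the 0.5 threshold are
flagged uncertain; the half-width is configurable because the source
workflow defines the uncertainty zone qualitatively, without a width.
Flags are advisory only: an out-of-domain compound may still show the
modelled response through mechanisms the model does not capture, so
nothing is rejected outright. For labelled data the assessment also emits
per-class residuals $y_{target} - y_{predicted}$, the ordinate of the
standard ED-versus-residual domain plots (`plot()` on the assessment
draws them).

## Synthetic data: what it emulates and what it does not

`generate_dataset()` draws three-class descriptor tables with the
statistical structure the pipeline assumes: informative descriptors
(class-conditional normal with identity within-class covariance; per
descriptor the three class means are a random permutation of
$(-s, 0, +s)$, so neighbouring class means differ by `separation` $= s$
within-class SDs), pure-noise descriptors, redundant descriptors (affine
copies of informative ones plus noise at $|r| \approx 0.98$, half
sign-flipped to exercise the absolute-value correlation filter), and
constant columns. The default class sizes 1178/477/857 mirror the P-gp
dataset's imbalance. What the generator deliberately does *not* emulate:
heavy-tailed and discrete descriptor distributions (functional-group
counts), correlation *blocks* larger than pairs, label noise, and
activity cliffs. Tests passing on this generator therefore demonstrate
the correctness of the machinery and its behaviour under the assumed
structure — not the accuracy of any particular chemistry model.

## Problem sizes and numerical choices in the test material

The shipped tests and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which each property is identifiable:

* CP-ANN generalization uses 255 compounds (100/70/85), separation 3, a
  12×12 map and 200 epochs — enough map for ~180 training compounds at
  roughly 1.4 neurons per compound, matching the density of the original
  43×43 map for 1786 compounds.
* The GA recovery experiment uses 8 informative + 40 noise descriptors on
  370 compounds (150/100/120) at separation 1 with 20 chromosomes, 30
  generations and 20×20 fitness networks. The weak per-descriptor signal
  is essential: at separation 3 a handful of informative columns already
  drives $MCC_{TR} \times MCC_{TE}$ to 1 and the remaining informative
  columns become invisible to any wrapper selection. The test partition
  (~50 compounds) keeps the $MCC_{TE}$ fitness estimate stable enough
  that rank selection orders chromosomes by subset quality rather than
  noise. The elite is 5 of 20, preserving the 20/95 ratio of the
  full-scale search.
* The full-scale split check maps 2512 synthetic compounds on the
  20×20/100-epoch splitting map and requires the 1786/341/385 sizes
  within ±2.

Degenerate inputs are handled explicitly rather than silently: constant
descriptors raise an error in `autoscale()` (they must be filtered
first), an empty chromosome scores $-\infty$ rather than erroring inside
the GA loop, zero-denominator measures are `NA` (percentages) or 0
(MCC), and winner ties break row-major. Single-epoch maps train at
$a_{max}$ with a zero radius, since the schedule is undefined at
$t_{max} = 1$.

## Known limitations

* The original model's headline numbers (TR/TE NER and AvPr, the
  26-descriptor selection, the 96-descriptor reduction, the AD boundary
  5.45) depend on the undeposited Dragon descriptor matrix of the 2512
  curated compounds and cannot be recomputed from published material;
  the package reproduces what is recomputable (the validation-set
  metrics from the printed confusion matrices) and validates everything
  else by construction on synthetic data.
* Hexagonal grids, toroidal boundaries and batch-SOM training are not
  implemented; square/non-toroidal/triangular is the only topology.
* The GA is single-objective and steady-state; no parallel islands.
* Scores are bounded class indicators, not calibrated probabilities.

## A worked run

```{r, eval = FALSE}
d <- generate_dataset(synthetic_spec(n_per_class = c(80, 55, 65),
                                     separation = 3, seed = 301))
cfg <- pipeline_config(
  split_som = som_config(8, 8, 30, 0.5, 0.01),
  som_grid = c(5, 5),
  ga = ga_config(population_size = 20, generations = 30, survivors = 5,
                 grid_rows = 8, grid_cols = 8, epochs = 60),
  final_som = som_config(12, 12, 200, 0.6, 0.001),
  seed = 301)
run <- run_pipeline(d, cfg)
print(run)
summary(run$model)
plot(run$ad, class = "inhibitor")
```
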