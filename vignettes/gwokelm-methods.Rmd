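---
title: "Genetic-seeded grey wolf optimization of kernel extreme learning machines: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gwokelm methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwokelm)
```

This vignette is the package's own account of the methods it implements:
the classifier and its closed-form solve, the optimizer and its fusion with
a genetic seeding phase, the wrapper fitness, the architecture-search
encoding and its surrogate, the imaging pipeline, and — throughout — the
numerical and design choices that were genuinely open and how we settled
them.

## The kernel extreme learning machine

An extreme learning machine is a single-hidden-layer network whose output
weights are obtained in closed form. In the kernel variant the hidden
feature map is never materialized: with training inputs $x_1,\dots,x_N$,
one-hot target matrix $T \in \{0,1\}^{N\times m}$ and Gram matrix
$\Omega_{ij} = K(x_i, x_j)$, training solves the single ridge system

$$(\Omega + I/C)\,\beta = T,$$

and a query $x$ is scored by $f(x) = [K(x,x_1),\dots,K(x,x_N)]\,\beta$ and
decoded by argmax (exact ties resolve to the first class in sorted order,
a deterministic rule that makes predictions permutation-invariant). The
kernel is the Gaussian
$K(x,y) = \exp(-\lVert x-y\rVert^2 / 2\gamma^2)$.

Parameters, with defaults and units:

* `c_reg` ($C$, default 32, dimensionless): ridge trade-off. Larger $C$
  means a *weaker* penalty, so training scores approach the one-hot
  targets as $C \to \infty$ on distinct points. We read the regularizer as
  $I/C$, not $I\cdot C$: the alternative would make a "larger $C$ for
  stronger regularization" reading inconsistent with $C$ as a capacity
  knob, and only $I/C$ yields the interpolation limit the tests verify.
* `gamma` ($\gamma$, default 0.5, in feature units): RBF width. The
  package uses the $2\gamma^2$ denominator form; the alternative
  $\exp(-\gamma\lVert x-y\rVert^2)$ parameterization is not exposed.
  Rescaling all features by $s$ while multiplying $\gamma$ by $s$ leaves
  every kernel value, hence every prediction, unchanged (tested).

Numerics: $\Omega + I/C$ is symmetric positive definite for any $C > 0$
(the Gram matrix is PSD), so the solve uses a Cholesky factorization with
a `qr.solve` least-squares fallback for the near-singular factorizations
that arise at extreme widths (e.g. $\gamma \to 0$ makes $\Omega \to I$,
harmless; $\gamma \to \infty$ makes $\Omega$ nearly rank one). One-hot
coding uses 1/0 rather than $\pm 1$; under argmax decoding the two are
affinely equivalent, and 1/0 reads directly as class membership. A linear
kernel is provided mainly so the implementation can be cross-checked
against explicit-feature ridge regression, which the test suite does to
$10^{-8}$.

## Grey wolf optimization and genetic seeding

GWO is a population metaheuristic in which the three best solutions found
so far — alpha, beta, delta — steer all others. Per leader $M_\ell$ a wolf
at $M$ computes, with fresh uniform draws $l_1, l_2$ per dimension,

$$N = 2a\,l_1 - a, \quad Q = 2\,l_2, \quad
  Y_\ell = |Q \circ M_\ell - M|, \quad M_\ell' = M_\ell - N \circ Y_\ell,$$

and moves to the mean of the three candidates, clamped to the search box.
The control parameter $a = 2(1 - t/T)$ decays linearly from 2 to 0, moving
the swarm from exploration ($|N|$ up to 2, steps can overshoot leaders) to
exploitation ($a = 0$ collapses every wolf onto the leaders' mean).

Design choices on points the method description leaves open:

* **Absolute value.** The per-leader distances carry the absolute-value
  bars of the canonical encircling equation; dropping them (as some
  restatements do) makes the update direction-unstable.
* **Elitist leaders.** Alpha/beta/delta are the best three *ever
  evaluated*, not the best of the current population; this makes the
  best-so-far history non-increasing by construction, which the tests
  assert on every run.
* **Boundary handling.** Per-dimension clamping after each update.
* **Budget accounting.** Evaluations are exactly
  `pop_size * (max_iter + 1)` plus any seeding-phase evaluations, so
  algorithm comparisons can be made at equal budgets.

G-GWO replaces uniform random initialization with the final population of
a short binary genetic algorithm: 16 bits per coordinate with an affine
fixed-point decode onto the box, roulette selection on *rank* weights
(best rank weight $P$, worst 1 — the objective is minimized, and raw
fitness roulette is undefined for negative or zero-sum values), single-
point crossover (rate 0.8), uniform per-bit mutation (rate 0.01), elitism
of one, 10 generations. Crossover and mutation rates follow the study
configuration; bits per gene, generations and elitism are package choices.

**What seeding buys — and does not.** GA seeding provably starts the swarm
at a better median initial fitness than uniform sampling (tested, paired
seeds). It does not follow that the *final* result is better at an equal
total budget: on 5-D Rastrigin the seeded variant's median final fitness
is worse than plain GWO's in our runs, because the concentrated initial
swarm gives up exploration in a highly multimodal landscape. The
acceptance suite computes this paired comparison and reports it rather
than asserting a direction; users should treat seeding as most useful when
evaluations are expensive and early quality matters.

## Wrapper feature selection and hyperparameter tuning

Feature subsets are searched in a continuous relaxation: one coordinate
per feature on $[-1, 2]$, binarized at each evaluation by comparing
against fresh uniform draws (a coordinate at 2 is always selected, at
$-1$ never). The asymmetric box biases the search toward inclusion early
on. Each candidate's fitness is

$$\alpha P + (1-\alpha)\frac{N - L}{N}, \qquad \alpha = 0.99,$$

with $P$ the holdout score, $L$ the selected-feature count and $N$ the
total. $P$ is validation *accuracy* by default: the fitness is described
both as precision- and accuracy-balancing in different places, and
accuracy matches the "classification accuracy versus subset size" framing;
a `fitness_measure = "precision"` switch uses positive-class (or macro)
precision instead. Candidates with $L = 0$ receive a worst-case sentinel
instead of raising, so the swarm can move back into feasible space.

Note one algebraic subtlety: the subset bonus is normalized by $N$, so
adding or removing a column (even an exact duplicate) shifts the bonus
mechanically. The meaningful invariant — a duplicate column can never
improve the *achievable validation accuracy* — holds and is tested with
$\alpha = 1$.

The validation protocol is a single stratified holdout (train fraction
0.7). The split seed is deliberately separate from the optimizer seed and
is consumed in an isolated RNG scope, so the same split is scored for
every candidate and the optimizer's stream is untouched; k-fold validation
was considered and left out to keep the evaluation cost of each of the
~1,700 candidate evaluations per run at one fit. Hyperparameters are
searched as $(\log_2 C, \log_2\gamma)$ over $[-5, 15] \times [-10, 5]$:
the log scale makes the usual exponential grid a box that GWO's linear
updates move through sensibly. `mode = "joint"` appends these two
coordinates to the $N$ flag coordinates.

Because binarization is stochastic, a position does not determine a flag
vector; the fitted object therefore records the best-ever *evaluated*
flags and parameters, which are refitted on the training side to produce
the returned model and holdout metrics.

An SVD reduction step (`svd_reduce`) is provided for upstream feature
tables: column-centered projection onto the top right singular directions,
with the centers and rotation kept so new data can be projected
identically.

## Architecture search with a smoothed Jaccard objective

The segmentation network's architecture is encoded as a fixed 22-field
vector — per-layer kernel counts in $[20, 200]$, kernel sizes in
$\{3, 5\}$, pooling/upsampling sizes in $\{2, 3\}$, dropout rates in
$[0.2, 0.4]$ — in a fixed order (4 conv, 2 max-pool, 2 dropout, 2
upsampling, 4 transposed-conv; the last two transposed-conv layers list
size before count). Decoding rounds and clamps counts, snaps discrete
sizes to the nearest allowed value (ties to the smaller), and clamps
rates; `decode(encode(hp))` is the identity on valid configurations, and
decode is idempotent. A variable-depth search (layer counts 2–10 are the
stated architectural limits) would change the vector length and is not
part of the fixed 22-field encoding; the package keeps the fixed-topology
reading.

Candidate quality is the mean smoothed Jaccard coefficient over mask
pairs:

$$\frac{1}{\mathrm{tim}} \sum_m
  \frac{\varepsilon + |y_m \cap \hat y_m|}
       {(\varepsilon + |y_m|) + (\varepsilon + |\hat y_m|)
        - (\varepsilon + |y_m \cap \hat y_m|)}.$$

$\varepsilon$ is a fixed configuration value (default 1) rather than a
per-evaluation random draw: a randomized objective makes the search
non-deterministic in a way that cannot be controlled by the run seed and
destroys the comparability of fitness values across iterations. As
$\varepsilon \to 0$ the measure approaches classical
intersection-over-union; at $\varepsilon = 1$ it is defined for empty
masks and rewards exact agreement with exactly 1.

**The surrogate.** Training the actual encoder-decoder per candidate is
out of scope at desk scale, so the search is exercised against a
deterministic surrogate: a task draws a hidden optimal architecture
$hp^\ast$ and a set of synthetic truth masks; a candidate's predicted
masks are the truths with a fraction $d^2$ of their pixels removed, where
$d$ is the candidate's range-normalized RMS distance from $hp^\ast$ in
encoded space. The decay is quadratic so the objective stays smooth and
informative near the optimum, and so a single mis-snapped discrete field
(which contributes a fixed quantum to $d$) does not flatten the landscape.
The surrogate is pixel-deterministic given `(hp, task)`, peaks at exactly
1 at $hp^\ast$, and decays monotonically along any ray from it — all
tested. It emulates the *shape* of an architecture-quality landscape, not
its content: passing the search on the surrogate shows the loop optimizes
a 22-dimensional mixed box reliably, not that any particular architecture
segments real fundus images well.

## Imaging pipeline

Preprocessing applies, in order: bilinear resize (default 256×256 — the
target size is a package default, chosen as the usual encoder-decoder
input scale), a 3×3 median filter, and CLAHE (clip 2.0, 8×8 tiles; both
standard defaults). Resize uses pixel-center alignment
(`src = (dst + 0.5)·scale − 0.5`), under which a 2× downsample is exactly
the mean of each aligned 2×2 block — the property the tests pin down. The
median filter and CLAHE are delegated to EBImage.

The augmentation catalogue holds exactly 30 operations: sharpen and emboss
at levels 0.5/1/1.5/2, Gaussian blur at scales 0.25/0.5/1/2, rotations of
45/90/135/180°, edge enhancement at 0.25/0.5/0.75/1, skews left/right/
forward/backward, flips left/right/top/bottom, and 10° shears along each
axis. Filter "levels" blend between the identity image and the
unit-strength filtered image (`out = img + level·(filtered − img)`), so
level 1 is the pure filter and level 2 over-drives then clips. Skew
magnitudes are ±10°, borrowed from the shear's stated angle (their own
magnitude is unstated). Geometric operations keep the input canvas with
reflect-101 padding; flips and 180° rotations are exact index
permutations (hence exact involutions), 90° rotations are exact on square
canvases, and 45°/135° rotations and skews resample bilinearly.

The sevenfold expansion keeps each source image and adds six operations
sampled per image without replacement from the catalogue (seeded). This
reconciles a 30-variant catalogue with an exactly sevenfold growth:
2055 sources become 14,385 images, and the per-class and per-source
counts scale by exactly 7. Whether the six operations should be the same
for every image is unspecified; per-image sampling was adopted as the
variant that actually diversifies the dataset. Split accounting defaults
to `test = floor(0.3 · count)` per class, with explicit per-class test
overrides available to reproduce published split tables whose rounding is
not recoverable from a fraction (note the published test total, 4,316,
exceeds its own per-class sum by one; the per-class values are treated as
authoritative).

## Synthetic data: what it emulates, what it does not

`make_classification_data` emulates the feature tables a CNN feature
extractor would produce: class-conditional Gaussian informative columns
(adjacent class means separated by `class_sep` standard deviations per
column) plus independent standard-normal noise columns, balanced classes,
with the informative index set recorded for exact recovery scoring. It
does not emulate feature correlation, heavy tails, or label noise — so
feature-recovery results here bound what to expect on real CNN features
from above. `make_segmentation_data` produces unions of random disks over
a low-frequency sinusoidal background; at zero pixel noise foreground and
background bands are disjoint by construction, so midpoint thresholding
recovers the truth exactly (a generator self-check, not a claim about
fundus lesions, which have vastly more structure).

The optimizer benchmark catalogue (sphere, Schwefel 2.22, Rosenbrock,
Rastrigin, Ackley, Griewank with their standard literature boxes) is a
package choice: the study's own benchmark set is unnamed, and these six
are the conventional unimodal/multimodal split.

## Problem sizes and reproducibility

The study configuration (population 8, 200 iterations, domain $[-1,2]$,
crossover 0.8, mutation 0.01, $\alpha = 0.99$, $C = 32$, $\gamma = 0.5$)
is the package default throughout. The test and acceptance suites run the
searches at the sizes a closed-form-classifier loop handles comfortably:
the exhaustive-enumeration check on 8 features × 60 samples with
40-iteration searches over 30 seeds; feature recovery on 5 informative +
15 noise features × 200 samples (`class_sep = 1.5`, chosen so each
informative feature is individually weak but jointly needed — the regime
in which recovering all of them is actually demanded) with 100-iteration
searches over 30 seeds; sphere calibration at the full 8 × 200
configuration over 20 seeds; architecture search at 50 iterations.

Every entry point takes a `seed`; one master seed fans out to named child
seeds (`derive_seed`) for the GA phase, wolf updates, splits and
augmentation sampling, so sub-systems are independently reproducible and
the same seed yields bit-identical results (asserted in the tests). Data
splits consume their seed inside an isolated RNG scope that restores the
caller's `.Random.seed`.

## Known limitations

* The wrapper fitness evaluates one stratified holdout; subset choices can
  overfit that split on small data (use the k-fold-style workaround of
  comparing fits across `split_seed`s if this matters).
* The stochastic binarization means the reported flags are the best
  *sampled* subset; on tiny feature sets exhaustive enumeration (which the
  tests use as the oracle) is preferable outright.
* The surrogate architecture search validates the optimizer loop, not real
  segmentation quality; plugging a genuine training harness into
  `search_architecture`'s evaluator is the intended path to real use.
* Augmentation geometry (reflection padding, canvas-preserving warps) is
  one reasonable convention; published pipelines differ in their borders
  and crops, and downstream results can be sensitive to that choice.
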