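---
title: "Selecting features from sparse streams: model, algorithm and design notes"
author: "streamFS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting features from sparse streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamFS)
```

## The problem

In many applied settings — microarray panels assembled probe by probe,
sensor fleets reporting asynchronously, clinical registries accumulating
variables — *features* arrive over time while the set of samples stays
fixed. A selector must maintain a small, discriminative feature subset
online, without ever seeing the full feature matrix. On top of that,
arriving columns are often incomplete: a fraction $\rho$ of entries is
missing because of dropouts, equipment failures, or unasked questions.

streamFS addresses this *online sparse streaming feature selection*
problem in three stages per buffered block of arriving features:

1. **Completion.** The $M \times H$ block $B_t$ is completed by a rank-$L$
   latent-factor model trained only on the observed cells $\Lambda$.
2. **Selection.** A genetic algorithm (GA) with elitism searches binary
   inclusion vectors over the candidate pool — the features already
   selected plus the $H$ new arrivals — scoring each subset by the
   validation error of an actual classifier (a wrapper objective).
3. **Pruning.** The GA winner is screened by conditional-independence
   tests: features independent of the label under every conditioning
   subset are dropped as irrelevant, and a Markov-blanket style
   redundancy pass removes features rendered conditionally independent
   of the label by some subset of the others.

## The latent-factor completion model

For a block $B_t$ with observed cells $\Lambda$, factors $U \in
\mathbb{R}^{M\times L}$ and $V \in \mathbb{R}^{H\times L}$ minimize

$$\varepsilon(U, V) \;=\; \sum_{(m,j)\in\Lambda}\Big(\tfrac12\big(f_{m,j}
- u_m^\top v_j\big)^2 \;+\; \tfrac{\lambda}{2}\big(\lVert u_m\rVert^2 +
\lVert v_j\rVert^2\big)\Big),$$

i.e. squared reconstruction error with an $\ell_2$ penalty charged *per
observed cell*. Charging the penalty per cell (rather than once per row
as in the matrix-global Frobenius form) means frequently observed rows
are shrunk harder; we keep this form because it is the objective whose
per-cell gradient the SGD update uses, and the two differ only in the
effective per-row regularization weight. Training is plain SGD: each
epoch visits every observed cell once in a shuffled order and updates
both factor rows simultaneously from the same residual,

$$u_{m,k} \leftarrow u_{m,k} + \eta\,(v_{j,k}\,\mathrm{err}_{m,j} -
\lambda u_{m,k}), \qquad
v_{j,k} \leftarrow v_{j,k} + \eta\,(u_{m,k}\,\mathrm{err}_{m,j} -
\lambda v_{j,k}).$$

Unobserved cells are then filled with $u_m^\top v_j$; observed cells are
always copied through unchanged, so a fully observed block passes
through the imputation stage bit-identically.

Numerical choices worth knowing about:

* **Initialization** is uniform on $[0, 0.004)$: small positive values
  so the multiplicative dynamics can escape zero in either direction.
  We use a continuous uniform rather than a scaled random permutation
  grid of step 1/1000 — same support and intent, no quantization
  artifact.
* **Stopping.** Training stops at `maxEpochs` (default 500) or when the
  relative loss change per epoch falls below `relTol` (default 1e-5) —
  but the relative-change test is only armed once the loss has dropped
  below 99% of its starting value. With the tiny initialization the
  first epochs sit on a near-flat plateau (gradients are proportional
  to the factor entries, which start at $\sim 10^{-3}$); without the
  guard the stopping rule fires on the plateau before descent begins.
* **Divergence.** A non-finite epoch loss aborts with an error that
  names the learning rate, the parameter to reduce.
* **Defaults** $\eta = 0.01$, $\lambda = 0.05$, $L = 5$: chosen to
  converge reliably on blocks of a few thousand observed cells; on a
  noiseless rank-1 $50\times20$ block with 30% of cells hidden they
  recover the hidden cells about an order of magnitude better than
  column-mean imputation.
* The factors are fit **independently per block**; completion is a
  per-buffer operation and no factor state crosses block boundaries.

## The genetic-algorithm wrapper

Subsets are binary chromosomes $b \in \{0,1\}^n$ scored by

$$J(b) \;=\; \alpha\,\varepsilon\big(X_{:,\,b}\,, y\big) \;+\;
\beta\,\frac{\lVert b\rVert_0}{n},$$

where $\varepsilon$ is the wrapped classifier's validation error. The
defaults $\alpha = 1$, $\beta = 0.01$ keep classification error the
dominant term; the sparsity term breaks ties toward smaller subsets.
The all-zero chromosome is scored with the majority-class error so the
empty set never looks like a perfect classifier.

One generation consists of: roulette selection with weights $1/(f +
\iota)$ (lower error, higher weight; $\iota = 10^{-6}$ guards the
division) into a mating pool of size $N$; single-point crossover of
consecutive pool pairs with probability $p_c = 0.8$ (an odd final
individual passes through uncrossed); independent bit flips with
probability $p_m = 0.05$; offspring evaluation; and elitist replacement
of the worst offspring by the best chromosome found so far. Elitism
makes the best-fitness sequence non-increasing by construction, which
is also a property every run is tested for. A `mutation strength`
parameter is accepted and recorded for interface compatibility but has
no role in the binary bit-flip operator.

In streaming runs the initial population is **warm-started**: its first
chromosome is the incumbent selected set $S_{t-1}$ (with the new block's
features off); the other $N-1$ chromosomes are the usual Bernoulli$(p_0)$
draws. Combined with elitism this guarantees the block winner never
scores worse than the incumbent, so a carried-over feature is only
dropped when the measured objective genuinely prefers dropping it. The
guarantee matters because the candidate pool has no recall: a feature
whose value only becomes visible once its co-informative partners
arrive in later blocks would otherwise be discarded on fitness noise
mid-stream and lost for good. Standalone `runGA()` calls are not
warm-started unless a `warmStart` chromosome is passed explicitly.

Fitness evaluations are **pure functions of the bit pattern**: the
validation splits are derived from the protocol seed only, never from
the chromosome or the evaluation order, so results are identical
however evaluations are scheduled, and a per-run memo table serves
repeated patterns. On an eight-feature task this cache means the GA
evaluates at most all $2^8$ patterns no matter how many generations it
runs.

### Which classifier drives the fitness?

Any of the four wrapped classifiers (3-nearest-neighbours, random
forest with 6 trees, CART, linear SVM) can be plugged in. The streaming
pipeline defaults to the **linear SVM**: on block-level pools its error
responds sharply (ten points or more) to the loss of a genuinely
informative feature, while 3-NN error is nearly flat to single-feature
changes and its ranking is then dominated by split noise. The SVM is
fit without internal rescaling — standard libsvm practice when inputs
are on comparable scales, which completed feature streams are; callers
with heterogeneous units should standardize first. The fitness protocol
default for streaming runs is stratified two-fold cross-validation:
every sample is validated exactly once (error resolution $1/M$) at two
classifier fits per evaluation; the module-level default for standalone
use is the cheaper single stratified 70/30 hold-out (`k = 0`), and any
stratified `k`-fold is available.

## Relevance and redundancy pruning

The pruning stage uses conditional-independence (CI) tests at level
$\alpha = 0.05$. For continuous features and binary labels (numerically
encoded) the test is Fisher's z on the partial correlation, computed
from QR regression residuals — this degrades gracefully when the
conditioning set contains a near-copy of the tested feature: a residual
with negligible variance is reported as conditional independence, which
is exactly the Markov-blanket verdict for a duplicated feature. Labels
with three or more classes use a G² contingency test on
tertile-discretized values.

* **Irrelevance screen.** Each feature in the GA winner is tested
  against the label conditioned on every subset (up to size $d = 3$) of
  the other winners; a feature independent under *all* subsets is
  dropped. (The exported `classifyRelevance()` refines this into
  strong / weak / irrelevant; the pipeline only needs the
  irrelevant-or-not decision and exits early at the first dependence.)
* **Redundancy pass.** Features are revisited in ascending order of
  unconditional label association — weakest first — and removed if some
  subset of the remaining features renders them conditionally
  independent of the label. Weakest-first ordering makes the pass
  deterministic and biases removal toward noisy duplicates rather than
  their cleaner parents. The pass is idempotent: survivors were
  dependent under every subset of a larger pool, so a second pass
  removes nothing.
* **Exchangeable pairs.** A feature and a near-duplicate of it are
  *mutually* removable — each renders the other conditionally
  independent of the label — and their sampled marginal associations
  differ by less than sampling noise, so examination order alone would
  decide the pair by coin flip. Mutual removals are therefore resolved
  by conditional retention: before a feature is removed through a
  blanket, each blanket member is tested with the feature swapped into
  its place, and if some member is itself removable there with weaker
  retention (a larger p-value), the feature is spared — the weaker
  member falls when its own turn comes. The parent of a noisy
  duplicate genuinely retains signal beyond the copy, so this
  comparison prefers the parent far more reliably than the marginal
  ordering.

Conditioning subsets are restricted to the current selected set with
$d \le 3$: an unrestricted subset search over the whole stream is
unbounded online, and each additional conditioning variable costs a
degree of freedom in the test. Features rejected in earlier blocks are
not recalled; the candidate pool at block $t$ is exactly
$S_{t-1} \cup B_t$, which also bounds the GA's search dimension by
$|S_{t-1}| + H$.

## The synthetic stream generator

Real sparse-stream benchmarks are external downloads; the generator
instead plants known structure so every claim is testable in code:

* A latent sample matrix $A \in \mathbb{R}^{M \times L_{\text{true}}}$
  (standard normal), default rank 10. Every feature is $A w + $ noise,
  so the full matrix is approximately low-rank — the premise the
  completion model relies on.
* **Informative** features load on distinct latents (the first
  $n_{\text{inf}}$); labels are the sign of a weighted sum of the
  informative *columns* (weights $\sim U(0.8, 1.2)$), or the
  exclusive-or of two thresholded columns for a deliberately
  non-linear variant.
* **Redundant** features are noisy scaled duplicates of single
  informative columns. A duplicate is conditionally independent of the
  label given its parent by construction, so it is precisely what the
  redundancy pass should remove; its extra noise also makes its label
  association strictly weaker than its parent's, which is what makes
  "keep the parent, drop the copy" a well-posed expectation.
* **Noise** features load only on latents *beyond* the informative
  subspace. Orthogonality to the label direction alone is not enough:
  if noise weights merely avoided the label direction inside the
  informative latent span, a handful of such features plus one
  informative column would jointly reconstruct the label score
  exactly, and planted "noise" would secretly be informative. Keeping
  noise in a complementary latent subspace makes it label-independent
  individually *and* jointly.
* An MCAR mask hides each cell independently with probability $\rho$,
  and the columns are streamed in a shuffled arrival order.

`noiseSd` defaults to 0.5 — a 4:1 signal-to-noise variance ratio,
typical of biomedical assay noise. The value also controls how
distinguishable a duplicate is from its parent: as `noiseSd`
approaches 0 a copy becomes statistically interchangeable with its
parent and *no* method can be expected to prefer the original, so
ground-truth role recovery is only a meaningful benchmark away from
that degenerate corner.

What passing tests on this generator do **not** show: robustness to
distribution shift or concept drift, to informatively missing data
(the mask is MCAR only), to heavy-tailed or discrete features, or to
label noise. The generator is a controlled instrument for validating
the mechanics, not a simulation of any particular assay.

## The comparison protocol

`crossValidatedAccuracy()` reports mean ± sd accuracy (percent) over
repeated stratified five-fold cross-validation (default 10 repeats with
re-randomized splits, sd across repeat means). Method-by-dataset tables
are compared with the Friedman rank test (rank 1 = best per dataset,
average ranks on ties, $\chi^2_{k-1}$ reference), and pairwise with the
**exact** Wilcoxon signed-rank test: zero differences dropped, average
ranks on ties, and the p-value computed from the full null distribution
over all $2^n$ sign assignments (by convolution over the doubled rank
values, so tied average ranks stay exact). For six all-positive paired
differences the one-sided p is $1/64 \approx 0.0156$ regardless of the
magnitudes — a useful analytic anchor that the bundled example table
reproduces.

## Problem sizes used by the tests and acceptance script

The shipped tests validate on deliberately small instances: rank-1
$50\times20$ completion blocks; GA tasks with 8-12 features where
exhaustive enumeration over all subsets is the oracle; CI-test
calibration at $M$ = 300-1000 with hundreds of null replicates; and
end-to-end streams with $M = 200$ samples, $T = 100$ features
($5$ informative, $5$ redundant), $\rho = 0.1$ and buffer width
$H = 20$ — five blocks per run. The per-block GA budget in the
streaming default is 50 generations with a population of 30; block
pools are at most a few dozen features and the convergence curves
plateau well before that.

## Known limitations

* The completion model is linear; strongly non-linear feature
  dependences are captured only through the classifier wrapper, not
  the imputation.
* The Fisher-z test assumes approximately Gaussian continuous margins;
  heavily skewed features should be transformed first.
* With duplicated features whose noise is negligible, parent-vs-copy
  choices are arbitrary coin flips for any statistical criterion (see
  the generator notes above).
* The stream has no forgetting mechanism: a feature once pruned is
  never recalled, and drifting label relationships are out of scope.
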