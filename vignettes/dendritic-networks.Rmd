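---
title: "Dendritic networks: model, training, and analysis methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dendritic networks: model, training, and analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrann)
```

## The model

Biological neurons integrate inputs on dendrites before the soma fires; each
dendrite sees only a restricted patch of the sensory input, and each dendrite
belongs to exactly one neuron. `dendrann` builds image classifiers with this
wiring: a standard two-hidden-layer network in which the first hidden layer
plays the role of dendrites, the second of somata, and the wiring between
layers is constrained by boolean masks.

For a network with `S` somata and `D` dendrites per soma there are
`S * D` dendritic units. Two masks define the architecture:

* the **input mask** `M1` (`n_features x S*D`) says which pixels each
  dendrite samples;
* the **structure mask** `M2` (`S*D x S`) wires rows `[(s-1)D+1, sD]` to
  column `s` only — each dendrite belongs to exactly one soma.

Masks enter in three places. At initialization the weights are multiplied
elementwise by their mask (`Wk <- Wk * Mk`). During backpropagation every
gradient of a non-existent connection is zeroed (`dWk <- dWk * Mk`). After
every optimizer update the weights are re-masked. Either of the last two
steps alone would suffice for plain gradient descent, but Adam carries
internal state, so the package applies both; together they make the support
invariant *exact*: an off-mask weight is `0.0` bit-for-bit at every step,
which the tests assert with `identical()`, not with a tolerance.

The forward pass is the usual

```
A1 = f(X W1 + b1),  A2 = f(A1 W2 + b2),  Yhat = softmax(A2 W3 + b3)
```

with `f` the leaky rectifier with negative slope 0.1 on both hidden layers.
The output layer is dense: the architectural claim is about hidden wiring,
not the readout.

### Input sampling schemes

* **R** (random): each dendrite samples `synapses_per_dendrite` (default 16)
  pixel locations uniformly without replacement from the whole image.
* **LRF** (local receptive fields): each dendrite samples one contiguous
  window (default 4x4, i.e. the full 16 synapses) at a uniformly drawn
  location.
* **GRF** (global receptive fields): one window location per *soma*; each of
  its dendrites jitters that location by up to `grf_spread` pixels
  (Chebyshev) before cutting its window.
* **F**: all-to-all input sampling with the structured second layer kept.
* **sparse** (sANN comparator): both masks filled uniformly at random at a
  chosen density, typically matched to a dendritic network's nonzero counts
  via `matched_densities()`; no structural constraint.
* **dense** (vANN comparator): all-true masks — an ordinary MLP.

Two geometric choices deserve a note. A 4x4 window has no center pixel, so
"the window around a drawn center" is implemented by drawing the window's
top-left **anchor** uniformly over all positions where the window fits
entirely inside the image. This is equivalent to center-drawing up to a
half-window shift at the borders, and it guarantees exactly 16 in-image
pixels — no wrap-around, no zero-padding, no short windows. For GRF, the
jitter radius around the somatic anchor is not dictated by the architecture;
it is exposed as `grf_spread` (default 2 pixels) and dendrite anchors are
clipped back into the valid anchor range, so border somata keep full
windows. For multi-channel images a sampled pixel location contributes all
of its channels (16 locations = 48 features for RGB); sampling individual
features instead is a deliberate non-default because "a synapse" is a
spatial contact, not a color channel.

## Training

Adam with learning rate 0.001, betas 0.9/0.999, epsilon 1e-8 (a config
field; the published description fixes only the rate and betas), minibatch
128, categorical cross-entropy, and a stratified 90/10 train/validation
split. Stratification is this package's choice: at desk-scale sample sizes
an unstratified 10% split can starve a class, and balance is the property
the split is supposed to preserve. The training split is reshuffled every
epoch; all epoch permutations are drawn up front from one seeded stream so a
run is a pure function of `(spec, data, config)` — bit-reproducible on fixed
hardware and thread count. Per-epoch train loss/accuracy are the
batch-weighted running averages; validation metrics are computed at each
epoch end, and `epochs_to_min_val_loss()` takes the first minimum (ties go
to the earlier epoch).

Epoch presets follow the benchmark budgets (15 MNIST, 20 FMNIST/KMNIST, 50
EMNIST/CIFAR10/sequential); the synthetic task uses 15, the MNIST-scale
budget, since it is an easy 10-class task of MNIST geometry.

Numerical choices: softmax and cross-entropy are computed through a
max-subtracted log-sum-exp, finite for logits up to about ±1e3; the leaky
rectifier's derivative at exactly 0 is taken on the negative branch (slope
0.1), an event of measure zero that only matters for exactly-zero
pre-activations; biases are never masked (a fully masked-out unit keeps a
trainable bias, and such biases are included in parameter counts); Glorot
uniform initialization with zero biases matches the common framework
default, with masking applied immediately after.

## Efficiency scores

Comparing a 5,000-parameter network with a 200,000-parameter one on accuracy
alone hides the cost. For each model in an explicitly given cohort, let
`k = trainable parameters x epochs to minimum validation loss`. The
efficiency factor is

```
f = log10(k_model) / min_m log10(k_m)
```

so the cheapest model in the cohort has `f = 1` and everything else `f > 1`.
The accuracy efficiency score is `aes = accuracy / f` (bounded in [0, 100])
and the loss efficiency score is `les = loss * f`. `f` is undefined for
`k <= 1`, which the code rejects. Because `log10` is monotone, taking the
minimum of the logs equals the log of the minimum `k`; the code evaluates
the expression as printed above. A score is meaningless outside its cohort,
so the cohort is an argument, never global state, and `efficiency_report()`
records cohort membership in one table.

Trainable parameters are counted as: on-mask entries of the two hidden-layer
masks, plus the full output matrix, plus all biases (`dendrann::count_trainable_params`).
The canonical example — 10 somata, 8 dendrites each, 16 synapses, 10
classes — gives 1280 + 80 + 100 (output weights) + 100 (biases) = 1560
parameters; a 512–256
vANN on the same task needs 535,818.

## Interpretability

All node-level analyses start from the **hit matrix**: for each hidden node,
the count of test images of each class on which its activation was strictly
positive, plus one extra row counting the images on which it stayed
inactive, so every column sums to the test-set size. "Active" is judged on
the post-activation value; with a leaky rectifier this coincides with the
pre-activation sign except exactly at zero.

* **Entropy** (bits): `H = -sum p log2 p` over the hit-matrix column divided
  by the number of test images, with `0 log 0 = 0`. The sum runs over all
  `n_classes + 1` rows, including the inactive row, so `H` is bounded by
  `log2(n_classes + 1)`. Nodes that never activate are flagged silent and
  excluded from distributions. High entropy = mixed selectivity.
* **Selectivity index**: the number of classes for which a node is active on
  strictly more than `threshold` test images. The canonical threshold of 400
  images corresponds to 40% of a 1000-per-class test set;
  `selectivity_threshold()` scales the rule as `round(0.4 x per-class test
  count)` for other sizes — that scaling is this package's convention. The
  index is by construction in `[1, n_classes]` for threshold-crossing nodes;
  nodes that never cross carry no index, and summary statistics here are
  taken over the crossing nodes, mirroring the silent-node exclusion of the
  entropy analysis.
* **Weight statistics**: excess kurtosis, Fisher–Pearson skewness and range
  of the learned weights, computed on raw values (kernel-density smoothing is
  a presentation device, never the statistic), and a 20-bin equal-width
  histogram helper.

## Embedding quality

`embed_activations()` projects a seeded random subset (default 2000 test
observations) of a hidden layer's activations to 2-D with t-SNE
(perplexity 50), via the Rtsne package. Three scores quantify the
projection, all with Euclidean distances, self-exclusion, and distance ties
broken by ascending point index so results are deterministic:

* **silhouette** — global class separation, mean of `(b - a)/max(a, b)`; a
  sample whose class has a single member scores 0 by convention (configurable
  to an error);
* **neighborhood hit** — local separation: mean fraction of the `k = 11`
  nearest neighbors sharing the point's label;
* **trustworthiness** — `T(k) = 1 - 2/(nk(2n-3k-1)) sum_i sum_{j in N_i^k}
  max(0, r(i,j) - k)`, penalizing low-dimensional neighbors that were not
  high-dimensional neighbors by their high-dimensional rank. It is computed
  between the raw activations and the embedding (no preprocessing of the
  activations).

Each score is verified in the test suite against an independent brute-force
`O(n^2)` implementation to 1e-12, and silhouette additionally against
`cluster::silhouette`.

## The synthetic task

Real MNIST-family archives cannot ship with the package, so experiments run
on a generated stand-in designed to preserve the one property the
architecture banks on: *class information that lives in compact image
regions*. Each of the 10 classes owns a fixed center on a grid over the
28x28 canvas; a sample is a Gaussian intensity blob (sd 2.5 px) at that
center, shifted by an integer jitter uniform in ±2 px per axis, plus
N(0, 0.1^2) pixel noise, clipped to [0, 1]. Defaults are 200 training and
100 test images per class. The task is learnable (a 1-nearest-neighbor
baseline exceeds 90% test accuracy) and genuinely localized (masking the
8x8 region at a class's center collapses that class's 1-NN recall), both
asserted in the tests.

What the generator does *not* emulate: multi-scale shape structure, within-
class style variation, correlated background clutter, or heavy class overlap
of real benchmarks. Passing results on this task show that the machinery
works and that the efficiency/selectivity directions hold where local
structure exists; they do not certify benchmark accuracy on FMNIST-scale
data, for which the IDX reader and the CLI provide a direct path.

## Difficulty manipulations

Two dataset transforms raise task difficulty without touching the trainer:

* `add_gaussian_noise()` adds i.i.d. zero-mean pixel noise of chosen sigma
  (on the [0, 1] intensity scale, which is also why images are normalized to
  that range) and clips back to [0, 1]. By default noise is applied to the
  split it is given — the "new dataset" reading in which models are retrained
  on noisy data; evaluating a clean-trained model on noisy tests is the same
  call applied to the test set only.
* `sequential_batches()` reorders an epoch so every minibatch contains one
  class and classes appear in a fixed order (ascending by default, fixed
  across epochs, configurable). It plugs into `train()` through the
  `batch_stream` argument; nothing else changes.

## Desk-scale study and problem sizes

The packaged study (also what `scripts/acceptance.R` reruns) compares a
dANN-LRF with 32 somata x 8 dendrites (4,970 parameters) against the
node-matched 256–32 vANN (209,514 parameters) on the default synthetic task,
15 epochs, three seeds. Typical behavior: the dendritic model concedes about
one to two accuracy points (~89.5% vs ~91.6%) while using 42x fewer
parameters, hence a far higher accuracy efficiency score (~90 vs ~70), and
its first-layer threshold-crossing nodes are more mixed-selective (mean
selectivity ~9.1 vs ~8.0). These sizes keep the full suite and study in the
minutes range on one CPU core; all sizes are arguments, so nothing prevents
running the same harness at benchmark scale.

## Known limitations

* Masked-dense storage: sparsity saves parameters, not FLOPs; each step
  still multiplies full matrices and adds a mask product.
* Gradients of non-existent connections are computed and then discarded —
  information from those directions is lost by design, the price of training
  structured sparsity with standard backpropagation.
* Cable (dendrite-to-soma) weights are unconstrained in sign; biologically
  they might be restricted to positive values.
* Two hidden layers only; deeper dendritic stacks and convolutional or
  transformer hybrids are out of scope.
* The 90/10 split and per-epoch reshuffling are reproducible but
  thread-count-dependent BLAS reductions can perturb the last bits across
  machines; exactness contracts (mask support, serialization round-trips)
  are unaffected.
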