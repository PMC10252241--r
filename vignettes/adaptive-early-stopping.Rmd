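---
title: "Adaptive early stopping and gradual cross-entropy for ordinal radiograph grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive early stopping and gradual cross-entropy for ordinal radiograph grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(koadapt)
```

## The problem

Kellgren–Lawrence (KL) grading assigns an ordinal severity score 0–4 to a
knee radiograph, reading three features: joint-space narrowing (the dark gap
between femur and tibia), subchondral sclerosis (bone densification at the
joint margins) and osteophytes (bony outgrowths). Deep classifiers for this
task are trained on small, imbalanced image sets and overfit readily, so the
number of training epochs matters, and a fixed "patience" epoch count is a
blunt instrument: set too high it overfits, set too low it underfits.

`koadapt` implements, end to end and at desk scale, a pipeline built around
two ideas: an **adaptive patience threshold** for early stopping, and a
**gradual cross-entropy (GCE)** loss for epochs that are cut short.

## The adaptive patience rule

Let $t_i$ be the monitored measure (validation loss) at observation $i$ and
$\varepsilon_i = t_i - t_{i-1}$ its successive difference. The patience
threshold is the running average of the differences observed so far. An
observation is a *stall* when its difference fails to beat the threshold as
it stood before the observation,
$\varepsilon_i \ge \bar\varepsilon_{i-1}$; otherwise the stall counter
resets. Training stops after `window` consecutive stalls (default 3).

Two threshold modes exist. The default maintains the exact arithmetic mean
incrementally, $A_k = A_{k-1} + (\varepsilon_k - A_{k-1})/k$. An alternative
`"literal"` mode uses $(A_{k-1} + \varepsilon_k)/(i+1)$ — a printed form
that divides a sum of two terms by the observation count and is therefore
*not* a self-consistent running mean; it is retained for comparison, the
incremental mean is the default, and the `running_avg_diff` field is the
true mean in both modes (property-tested against `mean(diff(x))`).

The comparison direction is a design choice the source material leaves
open: here *improvement* means improving **faster than one's own history**
($\varepsilon$ strictly below the running average). Consequences worth
understanding before reading a green test:

* a loss curve that keeps falling at an *accelerating* rate never stalls;
* a *plateau* after improvement stalls immediately (differences of zero
  against a negative average) and stops the run exactly `window`
  evaluations after it begins;
* a curve that still falls but *decelerates* accumulates stalls — the rule
  reads "improvement has leveled off relative to its history" as a stop
  signal. A constant-rate improvement sits exactly on the threshold and
  counts as a stall. This is the intended adaptive behaviour, and it is why
  the property tests exercise accelerating traces for the never-stop case.

The rule runs at two levels. The **macro controller** observes the
full-validation loss once per epoch and aborts the whole run; it is guarded
by `min_epochs` (default 3) to avoid immature stops, and the best
full-validation checkpoint is restored afterwards (standard practice; the
alternative would return a degraded model). The **micro controller**
observes the loss on a fixed held-out validation mini-batch every
`micro_check_every` training batches (default 10) and aborts only the
current epoch; its state is reset at each epoch start and kept separate
from the macro state. Both windows default to 3 and all cadences are
configurable — the source material fixes none of them.

## Gradual cross-entropy

The usual epoch loss is $J(w) = -\frac{1}{N}\sum_{i=1}^{N}\log
p_{\text{model}}(y_i)$ over the $N$ examples allocated to the epoch. When
the micro controller aborts after $l < N$ examples, dividing by $N$ would
understate the loss of the consumed portion. GCE rescales by
$\delta = N/l$:

$$J(w) = -\frac{\delta}{N}\sum_{i=1}^{l}\log p_{\text{model}}(y_i),$$

which is algebraically the mean cross-entropy of the consumed examples — an
aborted epoch is scored as if the consumed portion were the whole epoch.
The summation runs over the $l$ consumed examples only (the only reading
under which the rescaled form is consistent with "loss from consumed data
only"). True-class probabilities are clamped at $10^{-12}$ before the
logarithm so degenerate predictions yield finite losses. The trainer logs
each epoch's loss in exactly this form, and the identity
`gce(batch) == mean per-example CE of the consumed subset` is
property-tested to $10^{-10}$ against a brute-force oracle.

## The network plan

The classifier follows the DenseNet-169 stack: a 7×7 stride-2 stem
convolution, a 3×3 stride-2 max-pool, four dense blocks (6/12/32/32
composite layers, dropout 0.2) separated by transition layers (1×1
convolution at 0.5 compression plus 2×2 stride-2 average-pool), and a
global-average-pool softmax head sized to the task (5, 3 or 2 classes
rather than the stock 1000). `build_layer_plan()` emits this as a symbolic
ten-row table with computed spatial sizes; for a 224×224 input the column
is 112, 56, 56, 28, 28, 14, 14, 7, 7, 1.

Two size conventions coexist deliberately. The textbook formulas — valid
convolution $l - m + 1$ and the pooled element count
$n_c(n_h-f+1)(n_w-f+1)/s^2$ — are exposed as standalone calculators
(`conv_output_size()` with $s{=}1, p{=}0$, and `maxpool_size_literal()`); the
literal pool formula on a 112×112 map with $f{=}3, s{=}2$ gives 55×55-ish
counts, while the canonical table prints 56×56. The reference sizes require
"same"-style padding ($p=3$ for the stem, $p=1$ for the pool), so the model
builder uses the padded convention and the discrepancy is surfaced in the
documentation and tests rather than hidden.

`instantiate_network()` builds a runnable model from the plan in pure R
(im2col convolutions over BLAS, sparse-matrix col2im for the backward
pass). Composites use the standard pre-activation BN-ReLU-Conv ordering
with optional 1×1 bottlenecks; batch normalisation is included because
without it the deep unnormalised stack collapses inter-example variance at
the pooled features and plain SGD cannot escape the class prior (observed
directly during development). Weights are He-uniform, seeded; grayscale
images are replicated to three channels; training is from scratch — no
pretrained weights, since the source never parameterises its fine-tuning.
The optimiser is the plain SGD rule $\phi \leftarrow \phi - \alpha\,d\phi$
(`sgd_update()`, used verbatim by the training loop); the learning rate is
explicitly an "arbitrary, configurable" quantity (default 0.001; the test
harness uses 0.1 for its small reduced models). Analytic gradients for
every layer type are tested against central finite differences.

A ViT-style patching path (`extract_patches()`, $N = WH/P^2$, linear +
positional embedding, default $P = 16$) is provided as an off-by-default
auxiliary representation: the source text claims patching replaces
convolutions yet classifies with a convolutional network, a contradiction
we flag rather than resolve — the default pipeline feeds images directly to
the convolutional plan.

## Data pipeline

Augmentation draws a flip, a rotation (±25°), shifts (±22%/±23% of the
side) and a zoom (±25%) uniformly within the policy ranges — the tuned
values of the reference experiment — and applies them as one inverse-mapped
affine transform with bilinear interpolation and nearest-edge fill (both
fill and interpolation are our choices; the source is silent).

Balancing brings every class to exactly 500 training records: classes under
the target are topped up with augmented copies of randomly chosen
same-class originals, classes over it are subsampled without replacement —
the only reading that yields exactly 500 per class and a 2500-image
training set from the 604/275/403/200/44 distribution. Augmented records
are confined to the training split by construction and by container
invariant, so no leakage into validation or test is possible.

Splitting is a single stratified random assignment at the reference
proportions (≈0.50/0.17/0.33). The reference's validation/test counts
(826/1656) cannot be reconstructed from its 1526 raw images, so the
proportions, not the absolute counts, are replicated. Grade regrouping maps
{0,1}→healthy for both coarser tasks (grade 1 is only "doubtful"
narrowing), {2,3}→moderate and {4}→severe for the 3-class task,
{2,3,4}→unhealthy for the binary task; the mapping is configurable since
the source never states it.

## Metrics

`micro_metrics()` pools one-vs-rest TP/TN/FP/FN counts across classes
before forming accuracy $(\Sigma TP+\Sigma TN)/(\Sigma TP+\Sigma TN+\Sigma
FP+\Sigma FN)$, recall, precision, and F1 as the harmonic mean of the
pooled precision and recall — the summed forms. `macro_metrics()` averages
per-class ratios unweighted. Whether the reference's reported numbers are
micro or macro averages is unstated, so both are always reported with the
micro form as canonical. Note that for $C > 2$ the pooled accuracy includes
true negatives and exceeds the plain diagonal fraction; comparisons across
tasks with different class counts (such as the ordinal-difficulty test)
therefore use the plain diagonal fraction. Zero denominators yield 0 with a
warning; an all-zero matrix is an error.

## The synthetic world

`generate_knee_image()` draws a stylised anterior-posterior knee: two
bright horizontal bone bands separated by a dark joint-space gap of width
`base_gap − grade × gap_decay` (defaults 14 px and 3 px at 64 px
resolution) with ±1 px jitter, margins that brighten with grade
(sclerosis), per-grade bright ellipses at the lateral joint margins
(osteophytes), and additive Gaussian noise (σ = 0.08). The per-grade counts
default to the reference distribution 604/275/403/200/44. Images are
written as plain-text PGM (P2) files — the pre-installed R stack has no
PNG/JPEG codec, and the portable graymap keeps every artifact diffable.

What the generator emulates: the ordinal gap/sclerosis/osteophyte structure,
class imbalance, and overlap between adjacent grades (via jitter and
noise), so that the 5-class problem has nonzero Bayes error while the
binary split stays easy. What it does not: anatomical realism, acquisition
physics, pose variation, or the pixel statistics of real radiographs. A
green ordinal-difficulty test therefore establishes that the pipeline
learns and that coarser tasks are no harder than finer ones *in this
world*; it says nothing about clinical performance, and the reference's
headline accuracies on the real dataset are deliberately not targets.

## Numerical and scale choices

* Probability floor $10^{-12}$ before logarithms; batch-norm ε $10^{-5}$,
  running-statistic momentum 0.1.
* Stall comparison is non-strict (`eps >= threshold`); ties with the
  running average count as stalls.
* Max-pool backward routes gradients to the first maximum on ties.
* Rounding in stratified splits resolves per class as
  `round(f_train·n)`, `round(f_val·n)`, remainder to test.
* The acceptance tests scale the world down to fit a 1-CPU budget: the
  ordinal-difficulty run uses counts ≈ 1/12 of the reference distribution,
  64 px images, a reduced plan (growth 6, blocks 2/2/2/2, no bottleneck),
  learning rate 0.1 and 8 epochs over 3 seeds; the balancing targets use
  32 px images because they count records, not pixels. Epoch reshuffling
  re-randomises the full training set each epoch; unconsumed examples from
  an aborted epoch are not carried over.

## Known limitations

Pure-R training is slow beyond the reduced plan; the full 6/12/32/32
configuration at 224 px is instantiable and probe-able but not practically
trainable here. The micro controller's cadence interacts with batch size
(few checks per epoch make micro stops rare at the defaults). The literal
threshold mode is provided for comparison only and has no recommended use.
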