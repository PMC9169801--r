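---
title: "Explanation-guided training: model, penalty, and what the simulator can show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explanation-guided training: model, penalty, and what the simulator can show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rightreasons)
```

## The problem

Convolutional classifiers for plant-leaf tasks routinely reach high accuracy
while attending to the wrong evidence — backgrounds, watermarks, acquisition
artifacts.  This package implements a four-step improvement loop: train a
baseline classifier; explain its decisions with Grad-CAM; encode expertise
as per-image binary *annotation matrices* that mark pixels known to be
useless for the task; and retrain with a right-for-the-right-reasons (RRR)
penalty that suppresses the model's sensitivity to those pixels.  A
synthetic leaf-scene simulator with exact ground-truth masks makes the whole
loop testable end to end without any external imagery.

## Grad-CAM

For input $X \in \mathbb{R}^{U\times V\times B}$, last-convolutional-stage
feature maps $A^1,\dots,A^K$ of size $P\times Q$, and pre-softmax class
score $y^c$, the channel weights are the spatially averaged gradients

$$w_k^c \;=\; \frac{1}{PQ}\sum_{i,j}\frac{\partial y^c}{\partial A^k_{ij}},$$

and the explanation is
$G = \mathrm{Trans}\!\left(\mathrm{ReLU}\!\left(\sum_k w_k^c A^k\right)\right)$,
where $\mathrm{Trans}$ upsamples from $P\times Q$ to $U\times V$.  Choices
fixed in this implementation:

* gradients are taken on the **pre-softmax** score, never on probabilities;
* $\mathrm{Trans}$ is corner-aligned bilinear interpolation (constant maps
  are preserved exactly; outputs stay within the input range);
* heatmaps are stored **unnormalized**; max-normalization happens only
  inside the assessment metrics, because Grad-CAM magnitudes are
  scale-arbitrary and the metrics need a bounded scale;
* assessment explains the sample's **true** class by default
  (`class_choice = "predicted"` is available).  A model can have an
  identically zero heatmap for a class — typical for "absence" classes
  whose score decreases in every feature — and such samples are excluded
  from cosine means (below) rather than imputed.

## The right-reason penalty

With softmax probabilities $\hat y$, the guided quantity is the input
gradient of the log-transformed output,
$\mathrm{Grad}_X = \partial \sum_c \log(\hat y_c + 1) / \partial X$.
The probabilities (not the raw scores) are used inside the logarithm so the
argument is always in $[1, 2]$ and the expression is defined everywhere.
The per-sample penalty masks this gradient with the annotation matrix $A$
(1 = useless pixel, replicated across the colour bands) and sums; the
default variant squares the masked entries first,

$$\mathrm{RLoss} = \mathrm{Sum}(A \cdot \mathrm{Grad}_X^2),$$

which guarantees nonnegativity — required by the magnitude balancing below.
A signed `literal_sum` variant (no squaring) is selectable.

The combined objective is

$$\mathrm{NLoss} = \mathrm{CLoss} + \lambda\,
\mathrm{Balance}(\mathrm{RLoss}, \mathrm{CLoss}), \qquad
\mathrm{Balance}(l_1, l_2) = 10^{\lceil \log_{10}(l_2/l_1)\rceil}\, l_1,$$

so the penalty always enters in the decade of the classification loss:
$l_2 \le \mathrm{Balance}(l_1,l_2) < 10\,l_2$.  A batch whose raw penalty
falls below $10^{-12}$ (all-zero annotation matrices, or a model whose
guided gradients have vanished) skips the penalty term entirely; training
with all-zero annotations is therefore *bit-identical* to plain
cross-entropy training.

### Differentiating the balanced penalty

The Balance factor is piecewise constant (a ceiling of a logarithm), so it
contributes no gradient of its own; within a batch it is a constant
multiplier on $\nabla_\theta \mathrm{RLoss}$.  $\nabla_\theta \mathrm{RLoss}$
itself requires double backpropagation: the penalty is a function of a
gradient, so its parameter gradient sweeps the backward graph a second time.
The implementation does this explicitly (conv and dense backward nodes
contribute weight-adjoint terms; ReLU masks and pooling argmaxes are
piecewise constant; the softmax head contributes a Hessian–vector product of
$\sum_c \log(\hat y_c + 1)$) and is pinned by finite-difference tests at
every level.

### Why the penalty gradient is trust-region capped

Balancing by *value* makes the penalty's *gradient* pressure scale-free:
$\lambda f\,\lVert\nabla \mathrm{RLoss}\rVert \approx \lambda\,
\mathrm{CLoss}\,\lVert\nabla \log \mathrm{RLoss}\rVert$, independent of how
small the raw penalty is.  On a small network this pressure measures tens of
times the classification gradient, and a handful of such steps destroys the
model.  The update therefore caps the balanced penalty contribution at
`grad_cap` times the classification-gradient norm per batch (the reported
loss value is always the exact combined loss).  The default `grad_cap = 1`
keeps the two influences within the same order of magnitude — the stated
intent of Balance itself.

Two regimes matter in practice, and the experiment defaults reflect them:

* **Sparse masks** (e.g. a corner watermark; a few percent of the pixels):
  full-strength guidance (`grad_cap = 1`) is required — it must beat the
  classification gradient on the mask-reading weights while learning is
  happening.  Note the guided quantity's gradient vanishes at full
  confidence, so guidance can only redirect learning *while the model is
  still uncertain*; it cannot unlearn a feature the model has already
  memorized to confidence.
* **Dense masks** (e.g. everything outside the lesions; most of the image):
  the penalty then opposes the classification computation itself on a small
  network, and full-strength guidance collapses the model toward the
  uniform-output state where all guided gradients vanish.  Here guidance
  must remain a mild bias; the `fake_vs_real` experiment defaults to
  `grad_cap = 0.1`.  Per-task strengths mirror the per-task penalty weights
  $\lambda$ (1.5 for fake-vs-real, 2 otherwise), which are likewise
  task-tuned config values.

### Retraining semantics

`run_framework()` retrains **the explained baseline model** with the
combined loss (`retrain_from = "baseline"`).  This matches the improvement
loop's reading — guidance refines the model whose explanations were just
inspected — and it is also the regime in which the balanced penalty is well
behaved, because the classification loss is already low when guidance
starts.  Training the second model from a fresh identically-seeded
initialization (`retrain_from = "fresh"`) is available; at small scale a
fresh start under a dense-mask penalty tends to collapse to chance accuracy
before the classifier can establish itself.  Both models always share the
train data, the architecture, the per-phase epoch count, and the minibatch
order.

## Explanation assessment

Explanations are flattened, max-normalized to $[0,1]$, and compared with the
*assessment mask* $B$ (1 = useful-region pixel, the elementwise complement
of the annotation matrix):

* $\mathrm{RMSE} = \sqrt{\sum_i (a_i-b_i)^2 / N}$ — absolute difference;
* $\mathrm{CosineS} = \sum_i a_i b_i / (\lVert a\rVert\,\lVert b\rVert)$ —
  relative difference; undefined for zero-norm inputs, which are excluded
  from means and counted (`n_cosine_excluded`);
* $\mathrm{PIP}$ — the fraction of the $\lceil N\,p/100\rceil$ highest-valued
  pixels (ties broken by lowest flat index, column-major) that land inside
  the mask region, reported in percent at $p \in \{1, 5, 10\}$ by default.

One geometric caveat worth knowing when reading reports: against a small
binary region, the cosine rewards *diffuse* maps (a uniform map scores
$\sqrt{|RM|/N}$, a single spike inside the region only $1/\sqrt{|RM|}$), so
a retraining that sharpens saliency into the region can raise PIP and lower
RMSE while leaving the cosine flat or slightly down.  The three metrics are
deliberately complementary.

## The simulator and what it does (not) show

`build_dataset()` generates three task designs with pixel-exact masks:

* **fake_vs_real** — a pool of `n_base = 8` base scenes reused across
  samples (emulating a design where a few leaf photographs are augmented
  many times), small per-sample photometric jitter (global brightness shift,
  sd 0.02, plus iid pixel noise, sd 0.01), and transparent circles blended
  toward the background colour in the fake half ("thinning" lesions).
  Fake samples are annotated outside their circles; unmodified samples
  carry the zero matrix (no guidance), the documented opt-out.
* **diseased_vs_healthy** — per-sample unique scenes, brown blotches inside
  the leaf for the diseased class; annotation = exact background.
* **species** — 2–4 procedurally distinct silhouettes (broad / narrow /
  lobed / round ellipse unions) with equal class counts; annotation =
  outside the minimum bounding rectangle, preserving shape information.

Scene parameters the source imagery does not determine were fixed once:
1–5 circles per fake image, radii 5–15% of the short image side, opacity
0.3–0.7, circles allowed in the background (where they are nearly
invisible — an intended source of task difficulty and an irreducible error
floor, since a fake whose circles all fall in the background is almost
indistinguishable from its base scene).  Coordinates are 1-based row/column
with pixel centres at integers; a pixel belongs to a circle iff
$(r-c_r)^2 + (c-c_c)^2 \le \rho^2$.

The simulator gives exact masks and full determinism (every dataset is a
pure function of its configuration and one integer seed), which is what the
correctness and direction tests need.  It does **not** emulate specular
highlights, occlusion, camera optics, label noise, or the long-tailed
appearance variation of field photographs; passing tests on the simulator
demonstrate that the machinery is correct and that guidance moves models in
the expected direction at small scale, not that any particular accuracy
will transfer to real imagery.

## Networks and training

Two architectures share one engine (batched im2col convolution with C
gather/scatter kernels, max pooling, ReLU, dense layers, softmax
cross-entropy, Adam):

* `tiny` — per-image mean removal, conv 3×3/stride 2 (16), pool 2, conv 3×3
  (32, the Grad-CAM stage), pool 2, dense 64, dense $n$; sized so a full
  experiment (dataset, two 15-epoch trainings, assessment) runs in about a
  minute on one CPU core.
* `alexnet_like` — the classic 5-conv + 3-dense stack for paper-scale runs.

Training defaults for `tiny`: Adam, learning rate $2\times10^{-3}$, batch
16, 3-epoch linear warmup, $\beta_2 = 0.99$.  The warmup and the faster
second-moment decay were chosen for stability of short small-batch runs —
without warmup a minority of runs never escapes chance level — and all of
them are plain `train_config()` arguments.  Initialization is He-scaled
Gaussian from the model seed; no pretrained weights are used anywhere.  The
per-image mean removal is implemented as a true network layer so that input
gradients (and their double-backprop) account for it exactly.

Desk-scale experiment defaults (`experiment_config`): 500 samples at
64×64 (300 train / 100 validation / 100 test, stratified 60/20/20),
15 epochs for `fake_vs_real`; the cross-validation harness drops the
validation split and stratifies folds by class.

## Numerical choices

* Balance's decade exponent uses `ceiling(log10(ratio) - 1e-9)`; the small
  guard keeps exact powers of ten from being bumped a decade up by
  floating-point noise in `log10`.
* The penalty's zero guard is $10^{-12}$; skipped batches are counted per
  epoch in the training history (`n_rloss_skipped`).
* PIP ties break by lowest flat index; `k = ceiling(N * percent / 100)`.
  Both are documented because PIP is discontinuous in ties.
* Max pooling resolves ties by first window offset; pooling argmaxes and
  ReLU masks are treated as locally constant in all gradient passes, which
  is exact away from measure-zero kink points.
* Non-finite losses abort training immediately, naming the offending
  component.

## Limitations

* The guided gradient $\partial\sum_c\log(\hat y_c+1)/\partial X$ vanishes
  at maximal uncertainty and at full confidence; guidance is therefore only
  active in the mid-confidence band, and cannot repair a model that has
  already memorized a spurious cue to confidence.
* Dense annotation masks on small networks constrain the same weights the
  classifier needs; expect an accuracy/explanation trade governed by
  `grad_cap` rather than a free improvement.
* Cosine similarity against small regions structurally favours diffuse
  explanations (see above).
* The engine is CPU-only and sized for desk-scale experiments; the
  `alexnet_like` variant is provided for fidelity of architecture, not for
  speed.
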