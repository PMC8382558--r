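---
title: "Classifying metabolomic feature tables with a Hessian-free sparse stacked autoencoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying metabolomic feature tables with a Hessian-free sparse stacked autoencoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabsae)
```

## The problem

Untargeted LC-MS metabolomics yields feature tables with thousands of
detected peaks (p, often several thousand) measured on a handful of samples
(n, often tens): nonnegative, sparse, strongly right-skewed intensities with
p >> n. `metabsae` classifies such tables with a deep model tailored to this
regime: a sparse stacked autoencoder (SAE) that learns a low-dimensional
representation without labels, topped by a softmax classifier, with the
whole stack fine-tuned by Hessian-free (HF) second-order optimization. The
package also carries the two standard baselines used to benchmark it (KNN
and a kernel SVM), SMOTE augmentation, and a leakage-safe cross-validation
harness.

## The model

Every layer computes a weighted sum of its inputs,
$z^{l+1} = X W^l + b^{l+1}$, followed by the rectifier $a = \max(0, z)$.
ReLU is used throughout because its gradient does not saturate, which
matters when the stack is deep and the data sparse; the subgradient at 0 is
taken as 0 so backpropagation is deterministic.

Training has three stages.

**1. Layer-wise pretraining.** Each pair of adjacent layer sizes forms an
autoencoder. Its encoder weights are first initialized by training a
restricted Boltzmann machine with one-step contrastive divergence (CD-1),
full batch, on the layer's input; with min-max-normalized inputs in
$[0, 1]$ the visible units are Bernoulli and the inputs act as activation
probabilities. (Deeper layers see unbounded ReLU activations, so the stack
switches those RBMs to Gaussian visible units automatically.) The encoder is
then refined by full-batch gradient descent on the sparse autoencoder cost

$$J = \frac{1}{m}\sum_{k=1}^m \tfrac12\lVert \hat x^{(k)} - x^{(k)}\rVert^2
      + \beta \sum_j \mathrm{KL}(\rho \,\|\, \hat\rho_j),$$

where $\hat\rho_j$ is the mean activation of hidden unit $j$ over the batch
and $\mathrm{KL}(\rho\|\hat\rho) = \rho\log(\rho/\hat\rho) +
(1-\rho)\log\big((1-\rho)/(1-\hat\rho)\big)$ is the Bernoulli KL divergence
that pushes each unit's mean activation toward the small target $\rho$. The
hidden activations of the trained layer become the next layer's input; the
decoders are discarded.

**2. Head training.** A softmax output layer is trained by full-batch
gradient descent with the encoder frozen.

**3. Fine-tuning.** All parameters move jointly against the supervised loss
$J(w,b) = \frac{1}{m}\sum_k \tfrac12 \lVert a(x^{(k)}) - y^{(k)}\rVert^2$
on softmax outputs versus one-hot targets — either by plain gradient descent
(`gd_finetune()`, the GD-SAE variant) or by Hessian-free optimization
(`hf_finetune()`, HF-SAE). MSE is the default fine-tuning loss because it is
the one cost the training traces track; cross-entropy is available via the
model's `loss` field, with matched gradients and curvature.

## Hessian-free internals

HF never forms a curvature matrix. Each outer iteration solves the damped
Gauss-Newton system $(G + \lambda I)\,d = -g$ approximately by conjugate
gradients, where $G = \frac{1}{m}J^\top H_L J$ with $J$ the Jacobian of the
network outputs and $H_L$ the loss Hessian at the outputs (the identity for
MSE). $Gv$ is computed matrix-free by a forward R-operator pass (propagating
directional derivatives of every activation) followed by a backward pass,
at the cost of roughly two gradient evaluations; `gauss_newton_product()` is
verified in the tests against an explicitly assembled finite-difference
Jacobian and is positive semidefinite by construction.

The surrounding heuristics follow the standard HF recipe, with every
constant exposed in `hf_config()`:

* **CG budget and tolerance** — at most `cg_max_iters` (default 100) inner
  iterations, stopping early at relative residual `cg_tol` (5e-4).
* **Warm start** — CG starts from the previous outer step scaled by
  `cg_warm_start_decay` (0.95), which transfers curvature information
  between outer iterations.
* **CG backtracking** — the true loss is evaluated at geometrically spaced
  stored CG iterates and the best one is kept; CG optimizes the quadratic
  model, which can overshoot the true loss late in the solve.
* **Levenberg-Marquardt damping** — the reduction ratio
  $\rho = (J(\theta) - J(\theta + d)) / (-g^\top d - \tfrac12 d^\top (G +
  \lambda I) d)$ compares achieved and model-predicted reduction (the
  predicted reduction uses the damped curvature); $\rho < 0.25$ multiplies
  $\lambda$ by 1.5, $\rho > 0.75$ by 1/1.5.
* **Acceptance** — a step is applied only if it does not increase the
  training loss, so the accepted-step loss sequence is non-increasing by
  construction; after 25 consecutive rejections the run aborts with a
  diagnostic rather than spinning.

Both fine-tuners are full-batch: at these sample sizes mini-batching buys
nothing and full batches make the Gauss-Newton model exact for the data
actually optimized.

On a convex problem (a single linear output layer under MSE), one HF outer
iteration with $\lambda \to 0$ and CG run to convergence is an exact Newton
step and lands on the closed-form least-squares optimum; the test suite
asserts this to 1e-6, which pins down the whole gradient → curvature → CG
→ update chain.

## Parameters that matter

| parameter | where | default | why |
|---|---|---|---|
| architecture | `run_crossval()` / `new_sae_model()` | 4573-1000-500-100-5 full scale | input width = p, three encoder layers, K = 5 classes |
| learning rate $\alpha$ | `pretrain_config()`, `train_config()` | 0.01 | full-batch stable step for normalized inputs |
| RBM sweeps | `pretrain_config()` | 500 | full-batch CD-1 budget per layer |
| fine-tuning iterations | `train_config()` | 4000 | outer-iteration budget (GD steps or HF outer steps) |
| sparsity target $\rho$ | `sparse_config()` | 0.05 | mean activation pushed near zero |
| penalty weight $\beta$ | `sparse_config()` | 3 | balance of reconstruction vs sparsity |
| KL clamp $\varepsilon$ | `sparse_config()` | 1e-6 | see below |
| SMOTE factor / k | `smote_expand()` | 8 / 5 | 40 samples → 320; 5 same-class neighbors |
| damping $\lambda_0$ | `hf_config()` | 1 | conservative first HF step |

## Numerical choices and degenerate inputs

* **KL clamping.** With ReLU activations the mean activation $\hat\rho_j$
  is unbounded and can hit 0 or exceed 1, where the Bernoulli KL is
  undefined. $\hat\rho$ is clamped into $[\varepsilon, 1-\varepsilon]$,
  $\varepsilon = 10^{-6}$, before the penalty; where the clamp is active the
  penalty is locally constant, so its gradient contribution there is exactly
  zero — the analytic gradient of the clamped cost, which is what the
  finite-difference tests verify.
* **Softmax overflow.** Logits are max-shifted per row before
  exponentiation; rows sum to 1 within 1e-12.
* **Prediction ties** break to the lowest class index; KNN vote ties
  likewise, and KNN distance ties to the earliest training row — all
  deterministic.
* **Constant features** map to 0 under min-max normalization instead of
  erroring: near-constant features are common in sparse peak tables.
  Held-out values falling outside a fold's training range are preserved
  (no clipping) unless explicitly requested.
* **Zero-range CG right-hand side** returns the zero step immediately;
  non-finite values inside CG raise a typed error that callers treat as
  divergence.
* **Missing cells** in input tables are a hard error unless the explicit
  fill-with-zero policy is chosen (absence is often encoded as zero in
  LC-MS tables).

## The synthetic-data generator

Real serum LC-MS data of the study design this package targets (five
treatment groups of eight animals, ~4500 features) are not publicly
deposited, so `simulate_metabolome()` emulates the shape: per-feature
log-normal baselines (multiplicative intensities), a disjoint block of 25
discriminative features per class up-shifted by `effect_size` on the log
scale, log-scale noise of SD 1, and 30% random zeroes for sparsity. These
defaults are the package's fixed reference conditions: an effect of two
noise SDs makes classes nearly (not trivially) linearly separable, which is
the regime where the published protocol operates — its baselines score
75–85%, so the real classes are largely but not perfectly separable.

What the generator does **not** emulate: retention-time drift, batch
effects, correlated features within metabolite adducts/isotopes, and
heteroscedastic technical noise. Passing tests therefore demonstrate that
the algorithms are implemented correctly and rank as published on data of
the stated shape — not that the exact published accuracies transfer to any
real cohort.

## Protocol choices where the design was open

* **Normalization** is per-feature min-max to $[0, 1]$ (bounded inputs suit
  Bernoulli-visible RBMs); z-scoring is available. It is always fitted on
  the training partition of each fold and applied to the test partition.
* **Pipeline order.** The default applies SMOTE inside each training fold
  only, so no synthetic point derived from a test sample can leak into
  training. The published protocol appears to expand first and split the
  320 expanded samples afterwards; `paper_order = TRUE` reproduces that
  order for comparison.
* **Pretraining** is RBM initialization *followed by* sparse-autoencoder
  refinement; either stage can be disabled (`rbm_iters = 0`,
  `ae_iters = 0`).
* **Untied decoders**: pretraining decoders are independent parameters.
* **Parameter flattening order** (for the optimizers) is encoder layers in
  order then the head, each layer's `W` in column-major order followed by
  `b`.
* **Kappa** is computed from the confusion matrix pooled over folds, giving
  one value per method.
* **Compute-matched comparison.** One HF outer iteration spends up to
  `cg_max_iters` curvature products, each costing about two gradient
  evaluations, so benchmark configurations give plain GD a proportionally
  larger iteration budget (`gd_iterations`) than HF's outer count.

## Problem sizes used by the tests and the acceptance script

The full-scale protocol (p = 4573, architecture 4573-1000-500-100-5, 500
RBM sweeps, 4000 fine-tuning iterations) is a configuration choice, not a
constant. The shipped tests and `scripts/acceptance.R` run the identical
code paths at the package's reduced reference scale: p = 200, architecture
200-32-16-5, 20 CD-1 sweeps and 30 sparse-AE steps per layer, 300-step head
training, 30 HF outer iterations against 300 GD iterations, SMOTE 40 → 320
inside each training fold, 3–5 seeds for medians. At this scale the
qualitative findings reproduce: HF fine-tuning descends monotonically over
accepted steps, reaches any loss level plain GD attains in far fewer outer
iterations, and tops the cross-validated ranking, while KNN/SVM baselines
sit below it.

## Known limitations

* Full-batch training is O(n·p) per gradient; very large expanded datasets
  would need the mini-batch HF variants deliberately left out of scope.
* The KL penalty on ReLU mean activations is a pragmatic carry-over from
  sigmoid autoencoders; the clamp keeps it defined but units whose mean
  activation exceeds 1 receive no sparsity gradient.
* Kappa's published range is quoted as $[0, 1]$; the statistic itself can
  be negative for worse-than-chance agreement, and the implementation
  returns such values honestly.
* No feature-importance or biomarker-selection machinery: classification
  only.
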