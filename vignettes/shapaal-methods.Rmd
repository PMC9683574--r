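---
title: "Shapley-attributed ablation with augmented learning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shapley-attributed ablation with augmented learning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapaal)
```

## The problem

Time-series classification in sensing applications — electrocardiogram
screening being the motivating case — often has to work from a few dozen
labelled recordings, because annotation requires expert time. Deep
classifiers that excel with thousands of examples degrade sharply in this
regime, and any individual bad training sample (noisy, atypical, or plainly
mislabeled) carries a large weight. `shapaal` implements a three-stage
answer:

1. **Learn.** Fit a residual network whose input — and therefore whose
   identity (shortcut) connections — carries a small, controlled additive
   Gaussian perturbation. The perturbation synthesises neighbours of the
   seen examples, compensating for the small sample.
2. **Unlearn.** Treat every training sample as a player in a
   transferable-utility coalition game, compute its Shapley value, and
   discard samples whose value is non-positive: by the null-player axiom
   these contribute nothing (or harm).
3. **Re-learn.** Fit a fresh network, again with perturbation, on the
   retained subset, and classify with that model.

## The augmented training objective

The base model minimizes the empirical cross-entropy risk over the training
set. Under augmentation, each input $x$ is replaced by $x + \delta$ with
$\delta \sim \alpha \times \mathcal N(\mu, \sigma^2)$, where $\mu$ and
$\sigma^2$ are the pooled mean and variance of the raw training matrix and
$\alpha$ (default **0.020**) keeps the signal-to-noise ratio high. The
worst-case (adversarial, max-over-$\delta$) form of this objective is
intractable and is *not* what is optimized; the fitted objective is the
sampled-noise surrogate: draw $\delta$ once per training instance (default;
a per-epoch resampling policy is available) and minimize the empirical risk
on the perturbed inputs. With $\alpha = 0$ the pipeline is bit-identical to
an unperturbed run at the same seeds — a property the test suite asserts.

The order of operations is fixed: perturb first ($x + \delta$), z-normalize
second. Normalization uses a *single pooled mean and standard deviation over
all entries of the raw training matrix* (population convention, divide by
$NT$), and the same pair is applied to the test set — test statistics are
never consulted. Two readings of the printed statistics were possible
(pooled scalars vs. per-timestamp vectors); the scalar reading matches the
shape of the formula and keeps the train-to-test carry-over well defined, so
it is the implemented path. All four ablation variants share the statistics
of the *raw* full training matrix, so their evaluations are strictly
comparable. Constant training matrices (std below $10^{-12}$) are refused
rather than silently divided.

## The network

The univariate series of length $T$ enters as a $T \times 1$ single-channel
plane, so the convolutions are $k \times 1$ kernels of a two-dimensional
operator. Each of the $\chi$ residual blocks stacks three
convolution/batch-norm/ReLU stages with kernel lengths 8/5/3 and 64 filters
by default — the community time-series residual-network baseline — with a
$1 \times 1$ projection on the shortcut only where channel counts differ.
After the last block: global average pooling over time, then a dense softmax
over the $C$ classes, trained with cross-entropy.

Hyper-parameters follow the small-sample recipe:

* **Batch size** is `min(ceiling(N/10), 16)`, with batch 2 when
  $N \le 10$ — a pure function tested against an independent oracle on an
  exhaustive sweep.
* **Learning rate** is fixed at $10^{-3}$. That value is the framework
  default of the Adam optimizer, and the trainer accordingly takes Adam
  steps (a fixed-rate mini-batch gradient-descent variant); no schedulers.
* **Depth** $\chi \in [2, 10]$ adapts to the training set. The published
  distribution-aware depth estimator is external to this package, so a
  documented stand-in maps the complexity score
  $C \cdot \log_2(\text{distinct instances})$ linearly from the score range
  $[2, 24]$ onto $[2, 10]$. It is deterministic, duplication-invariant and
  monotone in the score, and an explicit `n_blocks` overrides it. No claim
  of equivalence with the original estimator is made.
* **Epochs** default to 500 with best-training-loss checkpoint restore;
  epoch count and early-stopping policy are not pinned down by the recipe,
  and small $N$ makes a generous fixed budget cheap and reproducible.

The network, including backpropagation, is implemented in R directly
(im2col convolutions over BLAS, standard batch-norm gradients). Every
random draw — initialization, batch shuffling, noise — is tied to an
explicit seed of R's default Mersenne-Twister generator, so fits are
bit-reproducible; a numerical gradient check validated all analytic
gradients during development.

## Valuing training samples

The coalition game is defined by Definition-style contracts: a value
function $v$ over subsets of the $N$ training samples with
$v(\emptyset) = 0$ (enforced by shifting every evaluation by the raw
empty-set value), the marginal contribution
$\Delta_v(n, \psi) = v(\psi \cup \{n\}) - v(\psi)$, and the Shapley value as
the permutation-averaged marginal. Two exact estimators (subset-formula
enumeration over $2^N$ coalitions, and full permutation enumeration) agree
to $10^{-9}$ and satisfy efficiency ($\sum_n \varphi(n) = v(N)$),
null-player ($\varphi = 0$ exactly for a constructed non-contributor),
symmetry and linearity — the test suite checks all four axioms. Beyond
$N \approx 12$ exact enumeration is infeasible and a seeded Monte-Carlo
permutation estimator with per-player standard errors takes over.

Two *value-function* routes are shipped, because the published pipeline
leaves the bridge between feature attribution and per-sample valuation
unstated:

* **Retraining game** (`estimator = "retrain_mc"` / `"retrain_exact"`): the
  worth of a coalition is the accuracy of a surrogate classifier trained on
  exactly those samples. The default surrogate is 1-nearest-neighbour — fast
  enough to evaluate thousands of coalitions — with the full residual
  network available as an expensive option. When the evaluation set reuses
  the training set (the default inside the pipeline, flagged as such),
  matching is leave-one-out: a sample can never validate its own label,
  otherwise a mislabeled sample would trivially appear valuable.
* **Model attribution** (`estimator = "model_attribution"`, the pipeline
  default): the practical shortcut that values sample $i$ as the signed sum
  over its time steps of a gradient-based attribution of the fitted
  augmented model's true-class logit, computed against the mean of a seeded
  background set of `min(N, 50)` training instances. This mirrors the
  fast attribution route of the original pipeline; the signed sum preserves
  the sign that the non-positive-discard rule needs.

For the synthetic benchmark studies in this package (and in the
reproduction script) the retraining game with Monte-Carlo estimation is
used: it is the construction the axioms actually govern, it is cheap at
$N \le 200$ with the 1-NN surrogate, and its behaviour on ground-truth
mislabels is directly testable. The attribution route remains the pipeline
default for fidelity to the original design.

## Discarding and re-learning

Samples with $\varphi(n) \le 0$ are discarded (the printed selection rule
includes the boundary; a strict-inequality variant sits behind
`discard_rule = "lt"`). If *every* sample would be discarded, a guard keeps
the highest-valued sample per class and flags the run loudly — a trainable
dataset must remain; this guard is an artifact of the implementation, not
of the method. Re-learning always builds a fresh, re-initialized network
(same seeded initialization, fresh noise draws) on the retained subset — no
warm start — with the full-train normalization statistics carried over.

## The synthetic benchmark

Real benchmark archives require downloads, so the generator produces
UCR-dialect datasets with known ground truth: class-specific templates
(sinusoids with class-dependent frequency/phase, or localized Gaussian
bumps), i.i.d. additive Gaussian noise, and a controllable fraction $\rho$
of training labels flipped to a uniformly chosen wrong class, with the
flipped indices recorded. Mislabels are the quantitative stand-in for
"negatively contributing" samples: the precision of the discarded set
against the recorded mislabels measures enrichment, with $\rho$ itself as
the random-discard baseline.

The study conditions are fixed once: 60 training and 100 test instances
(training-insufficiency factor 0.6), series length 48, two classes,
noise standard deviation 0.5, $\rho = 0.2$ where mislabels are studied, and
a reduced network ($\chi = 2$, 8 filters, 100 epochs) so ten-seed studies
complete in minutes on one CPU. Mode-over-seeds aggregation (round to 4
decimals, count, break ties toward the larger value) reproduces the
many-seed reporting convention at a desk-friendly 8-10 seeds.

What passing these studies shows — and what it does not: the synthetic
templates are far cleaner than real physiological waveforms (no baseline
wander, no class overlap structure, no autocorrelated noise), so success
here validates the *mechanics* (the valuation identifies planted
non-contributors; ablation plus augmentation does not hurt, and typically
helps, the mode accuracy) rather than any clinical-grade claim.

## Numerical choices

* Population (divide-by-$N$) convention for every standard deviation, so
  tests are bit-stable; degenerate-scale floor $10^{-12}$.
* Batch-norm $\varepsilon = 10^{-3}$, running-stat momentum 0.9; a batch of
  one falls back to running statistics.
* Softmax is computed with row-max subtraction; training aborts with the
  epoch index if the loss turns non-finite.
* Mode ties break toward the larger accuracy; valuation ties at exactly
  zero are discarded (boundary belongs to the discard side).
* Derived seeds use modular arithmetic below $2^{31}$; the temporary-seed
  helper restores the caller's RNG state, so library calls never clobber a
  user's random stream.

## Limitations

Univariate, fixed-length series only; no missing values. The depth
heuristic is a declared proxy, not the published estimator. The adversarial
max-over-perturbations objective is represented by its sampled surrogate,
as in the original pipeline. Exact valuation is limited to a dozen players;
Monte-Carlo error decreases as $1/\sqrt{\text{permutations}}$ and the
reported standard errors should be consulted before trusting a sign near
zero. Real-archive evaluation is supported through the UCR-dialect reader
and the command line but is deliberately outside the test suite.
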