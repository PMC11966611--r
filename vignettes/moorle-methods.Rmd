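---
title: "Entropy-regularized multi-objective training for drug response prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-regularized multi-objective training for drug response prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moorle)
```

## The problem

Cell-line drug screens are pair-input datasets: each record is a
(cell line, drug) combination with a continuous response, typically the
area under the dose-response curve (AUC). Public screens are strongly
imbalanced at the drug level — a few compounds are screened against
nearly every cell line while a long tail is screened far less. A
regressor trained by pooled mean squared error is free to buy overall
accuracy on the heavily screened drugs at the cost of the tail. That
trade is invisible in bulk metrics but dominates the *drug-averaged*
view (compute the metric within each drug, then average with equal
weight per drug), which is the view that matters when the model's job is
virtual screening: predicting responses for compounds it has never seen.

## The MOORLE loss

Training is reframed as a multi-objective problem with one objective per
drug. For a batch with drug set $D$, per-drug mean squared errors

$$\mathrm{MSE}_{d} = \frac{1}{n_d}\sum_{i \in d}(f(x_i) - y_i)^2$$

are softmax-normalized into a distribution
$p_d = \exp(\mathrm{MSE}_d) / \sum_{j} \exp(\mathrm{MSE}_j)$ with entropy
$H(P) = -\sum_d p_d \ln p_d$, and the loss is

$$L = \frac{1}{|D|}\sum_{d \in D} \mathrm{MSE}_d
      + a\,\bigl(\ln|D| - H(P)\bigr).$$

$H(P)$ is maximized at $\ln|D|$ exactly when all per-drug losses are
equal, so the penalty $\ln|D| - H(P)$ is non-negative, zero if and only
if the per-drug losses are equal, and pushes training toward balanced
per-drug performance. With a single drug in the batch the penalty is
identically zero and $L$ is that drug's MSE; at $a = 0$, $L$ is the
unweighted mean of per-drug MSEs. Both identities are asserted in the
test suite to $10^{-12}$.

```{r loss-example}
pred <- c(0.2, 0.5, 0.9, 0.4)
obs  <- c(0.1, 0.5, 0.5, 0.5)
moorle_loss(pred, obs, groups = c("A", "A", "B", "B"), a = 3)
```

### Differentiation

The distribution $P$ is a function of the model, and we do **not**
detach it: gradients flow through the softmax and entropy terms. With
$m$ the vector of per-drug MSEs,

$$\frac{\partial L}{\partial m_k} = \frac{1}{|D|}
  + a\,p_k\,\bigl(\ln p_k + H(P)\bigr), \qquad
  \frac{\partial m_k}{\partial f(x_i)} = \frac{2\,(f(x_i)-y_i)}{n_k}
  \;\; (i \in k).$$

The alternative — treating $P$ as a constant — would make the penalty
gradient vanish entirely (only $1/|D|$ survives), so the regularization
weight would have no effect on training; the loss is optimized as a
whole. `batch_loss_gradient()` implements the expression above and is
checked against central-difference numerical gradients to $10^{-5}$
relative error.

Note the sign structure: drugs whose loss is above the batch average
have $\ln p_k + H > 0$ and receive extra gradient weight; drugs below
average receive less, and for large $a$ the weight can cross zero —
the penalty is then actively willing to worsen a well-fit drug to buy
balance. This matters for choosing $a$ (below).

### Numerical choices

* $|D|$ is the set of drugs **present in the current batch**: minibatch
  training never sees the global drug set, and $\ln|D|$ must bound the
  entropy actually computed.
* The softmax subtracts the maximum per-drug loss before
  exponentiation — mathematically identical, finite up to arbitrarily
  large losses (tested at $10^6$).
* Entropy uses natural logarithms and the convention $0 \ln 0 = 0$; the
  distribution-sum validation tolerance is $10^{-9}$.
* A drug with one pair contributes a valid (possibly zero) MSE; there is
  no minimum group size at loss time.
* The base loss enters `per_group_mse()` through a single `base`
  argument, so the squared-error kernel can be swapped for any other
  non-negative pairwise loss without touching the aggregation path.

## Samplers

`sequential_shuffled()` is the deep-learning default: one seeded
permutation per epoch, every record exactly once. Under long-tailed
counts, rare drugs then appear in few batches. The *mixed* sampler draws
records with replacement from the blend

$$w(d) \propto (1-\lambda)\,\frac{1}{N} + \lambda\,\frac{1}{|D|\,c_d},$$

where $c_d$ is drug $d$'s record count: $\lambda = 0$ is uniform record
sampling and $\lambda = 1$ gives every drug equal expected mass
(default $\lambda = 0.5$). Epochs under the mixed sampler draw exactly
$N$ records so the per-epoch gradient-step count matches the sequential
sampler's — the two strategies are then comparable in an ablation.
Expected per-drug inclusion is
$(1-\lambda)\,c_d/N + \lambda/|D|$ by construction; the test suite
verifies empirical frequencies at $10^4$ draws within three binomial
standard errors.

## Split plans

* **Random-pair folds** hold out combinations; a drug may appear on both
  sides (the drug-repurposing evaluation).
* **Drug-blind folds** partition drugs, and records inherit their drug's
  fold, so no compound ever spans train and test (the virtual-screening
  evaluation). Fold pair-counts are balanced greedily: drugs in
  decreasing count order (ties broken by a seeded shuffle) go to the
  currently lightest fold. Balancing pair counts rather than drug counts
  keeps test sizes comparable under long-tailed profiles.
* `validation_holdout()` carves a tuning set out of a fold's training
  portion; in drug-blind mode it holds out whole drugs, so tuning the
  regularization weight sees the same blindness as the test fold.
* `validate_plan()` re-checks every generated plan (exact partition, no
  drug spanning folds) and is itself exercised on one thousand random
  plans in the acceptance suite. Plans serialize to two-column text so a
  fixed split can be shared across all configurations being compared.

## Reference model and training

The regressor is a small fully connected network (default hidden layers
64 and 32, ReLU, dropout 0.1) trained by minibatch Adam (default
learning rate $10^{-3}$, batch 64, 40 epochs). Features are standardized
to zero mean and unit variance using training-portion statistics only,
stored in the model and re-applied at prediction time. All randomness —
initialization, batch order, weighted draws, dropout masks — is scoped
by explicit seeds, and retraining with identical seeds reproduces every
number exactly. The loss enters the backward pass only through its
gradient with respect to the batch predictions, which is the single
point where the MSE and MOORLE objectives differ; with one drug in the
dataset the two training trajectories are verified to be identical step
for step.

These training defaults are the package's own choices; the experiments
this package scales down do not publish their optimizer settings.

## The synthetic screen generator

`generate_dataset()` produces a pair-input screen with known ground
truth so every component is testable without downloads:

* **Count profiles** (`imbalance_profile()`): `ccle_like` reproduces the
  mildly imbalanced small-panel regime (12.5% of drugs below 90% of the
  maximum count); `ctrp_like` the strongly imbalanced regime (17.2%
  below half the maximum, a further 19.6% between 50% and 90%). Bucket
  membership is exact by construction; within-bucket counts are uniform
  draws, and one drug always sits exactly at the maximum.
* **Response surface**: sample features are standard normal; drugs sit
  in mechanism-of-action (MOA) clusters in feature space. The noiseless
  response is a logistic squash of an additive-plus-bilinear form in the
  two feature vectors, with Gaussian noise added. The squash is
  calibrated (shift 1.0, scale 0.5) so responses look like AUC screens:
  mean about 0.7, spread about 0.14, most pairs weakly responsive. With
  the default noise (`noise_sd = 0.05`) the best achievable per-drug
  R² — computable exactly via `oracle_metrics()` — is about 0.89.
* Because responses depend on drugs only through their features, a
  drug-blind model can generalize in principle; the suite verifies that
  a model trained with one whole MOA cluster held out predicts it above
  chance, and that a linear reader of the features transfers.

What the generator does **not** emulate: real expression covariance and
pathway structure, dose-response curve fitting (responses are generated
directly at the AUC level), assay batch effects, non-Gaussian and
heteroscedastic measurement error, and the chemical-similarity structure
of real compound libraries. Passing tests on this generator demonstrate
that the machinery is correct and that effects propagate as designed —
not that any particular effect size carries over to real screens.

## Choosing the regularization weight

The weight $a$ trades mean per-drug loss against balance and must be
tuned per dataset on a validation split that mirrors the evaluation
blindness (`sweep_regularization()`, default grid 0–6;
`compare_tuned_moorle()` for the tuned-versus-baseline comparison). Two
properties of the loss make this tuning genuinely necessary rather than
cosmetic:

1. The softmax of per-drug MSEs is not scale-invariant: the same $a$
   that is a gentle nudge when losses live at $10^{-3}$–$10^{-2}$ (the
   AUC regime) is a strong force when transient losses are of order 1.
2. Equalizing *raw* per-drug MSEs is not the same objective as
   maximizing drug-averaged R², which implicitly weights each drug's
   error by its response variance. Drugs with little response variance
   can have their error pulled *up* toward the common loss level,
   making their R² arbitrarily negative.

In this package's own scaled-down experiments (the acceptance script,
about 5,000 pairs, 60 drugs, a two-hidden-layer network), weights in
the 2–4 range consistently reduced drug-averaged R² relative to the
plain-MSE baseline for exactly these reasons — the validation sweep
prefers the smallest weight offered, and the effect weakens as $a \to
0$. At this problem size the per-batch per-drug losses are single
squared errors, so the entropy term partly chases noise. The
regularizer's published benefits were obtained with full-scale deep
models on screens with two orders of magnitude more data; reproducing
them is outside what a desk-scale synthetic study can show, and users
should treat $a$ as a parameter to be swept — including values well
below 1 — not copied.

## Problem sizes used by the tests

The unit suite runs on datasets of tens to hundreds of pairs; the
end-to-end acceptance checks use the generator's default screen (60
drugs, about 5,100 pairs) with 5-fold drug-blind cross-validation and a
handful of replicate seeds. These sizes were chosen as the smallest at
which drug-level effects are measurable while keeping the whole suite
runnable on a laptop CPU in minutes.

## Limitations

* No GPU path and no autodiff: the network is intentionally small, and
  architectures beyond a fully connected regressor are out of scope.
* Per-drug priority weights (skewing balance toward drugs of interest)
  are an extension point of the aggregation path, not implemented.
* Statistical significance testing of ablation effects (repeated
  measures ANOVA and friends) is left to general-purpose packages;
  reports carry raw metrics only.
* Undersampling and oversampling are deliberately absent: the first
  discards scarce screen data, the second inflates the importance of
  duplicated pairs.
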