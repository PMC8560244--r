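---
title: "Joint tree and network models for mental-health assessment records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint tree and network models for mental-health assessment records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mheval)
```

# The problem

Screening instruments for mental health produce tabular records: batteries
of Likert-style questionnaire items together with continuous behavioral
features such as posting frequency or session duration, labeled with an
assessed risk class. `mheval` implements and compares two classifier
families for such records — a C4.5 decision tree and a small multilayer
perceptron — together with two specific accelerations: a
logarithm-free polynomial scoring rule for the tree's split criterion, and
Levenberg–Marquardt (LM) training for the network. A soft-vote
combination of the two fitted models serves as the joint classifier.

# The tree and its polynomial scoring rule

## Gain ratio

C4.5 grows a tree by maximizing the *information gain ratio*. For a node
holding class counts $s_1,\dots,s_m$ (total $s$) the class entropy is
$\mathrm{Info}(S) = -\sum_i (s_i/s)\log_2(s_i/s)$; a candidate partition
into branches $S_1,\dots,S_k$ is scored by

$$\mathrm{GainRatio}(A) \;=\;
\frac{\mathrm{Info}(S) - \sum_j (s_j/s)\,\mathrm{Info}(S_j)}
     {-\sum_j (s_j/s)\log_2(s_j/s)},$$

the denominator (split information) penalizing many-valued attributes.
Categorical attributes propose their multiway partition into levels;
continuous attributes propose binary splits at *equal-division points*:
with observed extremes $\mathrm{MIN}, \mathrm{MAX}$ and $N$ candidate
points (default $N = 10$),

$$A_i = \mathrm{MIN} + i\,\frac{\mathrm{MAX}-\mathrm{MIN}}{N+1},
\qquad i = 1,\dots,N,$$

each inducing the partition $\{x \le A_i\}$ / $\{x > A_i\}$. The divisor
$N+1$ places every candidate strictly inside the observed range; a
divisor-free reading would put every candidate at or beyond
$\mathrm{MAX}$, leaving nothing to compare. All $N$ interior candidates
are evaluated, ties going to the smaller threshold. The classic
midpoints-between-sorted-values candidate set is available behind the
`midpoints` flag of `tree_params()`, off by default.

At a node, every available attribute is scored, candidates whose gain
ratio reaches the mean over valid candidates are retained (the maximum
always does, so this filter never empties a non-empty candidate set), and
the best retained candidate splits the node. Remaining ties break
lexicographically by attribute name and then by threshold, so builds are
bit-reproducible. Categorical attributes are consumed along a path;
continuous attributes may be reused deeper with different thresholds.

## The Maclaurin (TAM) surrogate

Scoring every candidate calls `log` many times. The TAM variant replaces
$\ln x$ on $(0,1]$ with its third-order Maclaurin expansion about 1,

$$\ln x \approx (x-1) - \tfrac{(x-1)^2}{2} + \tfrac{(x-1)^3}{3},$$

which turns every $p\ln p$ term with $p = a/b$ into the closed polynomial

$$\frac{a\,(a-b)\,(2a^2 - 7ab + 11b^2)}{6\,b^4},$$

evaluated with arithmetic only (`approx_plogp()`). All three entropy
terms of the gain ratio — class entropy, conditional entropy and split
information — use the surrogate, so the per-candidate scoring path
performs *zero* transcendental-log calls; an instrumented counter
(`log_call_count()`) verifies this during whole-tree builds. The constant
prefactor $1/\ln 2$ is retained so entropies stay in bits; since the gain
ratio is a quotient, any common positive prefactor cancels and cannot
reorder candidates.

## Accuracy of the surrogate

The cubic surrogate is exact at $p = 1$ and degrades as $p \to 0$. Two
consequences matter in practice and are measured by the test suite:

* the *relative* entropy error at a balanced 2-class table is
  $1 - (2/3)/\ln 2 \approx 3.8\%$, stays below 5% while class
  proportions remain within $[0.4, 0.6]$, and grows to $\approx 12.8\%$
  at a 20/80 table — skewed tables are where the surrogate is weakest;
* what the tree needs is not absolute accuracy but *ranking* accuracy:
  over seeded random candidate sets with branch proportions in
  $[0.2, 0.8]$, the attribute ranked best by the surrogate agrees with
  the exact ranking in well over 95% of draws, and exact-mode and
  TAM-mode trees built on the same data agree on almost all test
  predictions.

## Numerical choices

$0\log 0 := 0$ throughout. A candidate is invalid when its split
information is below $10^{-12}$ (all records in one branch) — invalid
candidates are flagged, not raised. Candidates whose gain is below
$10^{-12}$ are also discarded: a zero-information split cannot improve
the tree, and discarding it guarantees termination when continuous
attributes are reused. No pruning is applied (depth and node-size limits,
defaults 25 and 2, are the only regularizers); an empty categorical
branch becomes a leaf carrying its parent's class distribution, which is
also what an unseen level receives at prediction time. Records with a
value equal to a threshold route left (`<=`).

# The perceptron and its two trainers

The network is a fully connected perceptron with sigmoid
($1/(1+e^{-z})$) hidden units — one hidden layer by default — and two
output heads over the same final pre-activation: a softmax head for
classification training and a sigmoid head for squared-error training.
Weights initialize uniformly on $[-r, r]$, $r = \sqrt{6/(f_{in}+f_{out})}$,
biases at zero, deterministically per seed.

**Gradient descent** minimizes the summed classification cross-entropy
$-\sum_i \sum_k y_{ik}\ln \hat y_{ik} + \frac{\lambda}{2m}\sum\theta^2$
(softmax head, predictions clipped to $[10^{-12}, 1-10^{-12}]$, L2 over
weights only — the bias-free convention). The output-layer error
simplifies to $\hat y - y$; hidden layers propagate through
$a(1-a)$. Because the loss is summed rather than averaged, a sensible
step size scales like $1/m$; the comparison harness uses $10/m$.

**Levenberg–Marquardt** minimizes the sum-squared error
$E = \frac12\sum (d - y)^2$ of the sigmoid head, the objective for which
a residual vector exists. Each iteration assembles the residual Jacobian
$J$ (one row per sample × output, one column per parameter; per-output
reverse-mode passes, batched over samples for single-hidden-layer
networks) and solves

$$\Delta = -(J^\top J + \mu I)^{-1} J^\top e$$

as a linear system. An improving candidate is accepted and $\mu$ divided
by 10; otherwise $\mu$ is multiplied by 10 and the step retried, up to
$\mu = 10^{12}$ (then the run stops with a warning status). The accepted
trace is strictly decreasing by construction. $\mu \to 0$ recovers
Gauss–Newton (exact in one step for linear residuals); large $\mu$
approaches a small gradient step $-(1/\mu)J^\top e$. Defaults:
$\mu_0 = 10^{-3}$, factor 10 — the method is famously insensitive to
these.

The two trainers deliberately optimize *different* objectives — the
cross-entropy/softmax pairing is the natural gradient-descent loss, while
classic LM requires squared-error residuals. For convergence
comparisons, both report a per-iteration squared-error trace
$\frac12\sum(\hat p - y)^2$ computed from each model's own probability
head, so "iterations to error $< 0.01$" is comparable across trainers.
On the four-point XOR task the LM median is an order of magnitude below
the gradient-descent median; note that a 2-2-2 sigmoid network has
well-known local minima on XOR, so a minority of initializations (4 of
the first 10 seeds here) plateau above zero error under either trainer.

# The joint model

The combination rule is a convex soft vote,
$p = w_t\,p_{tree} + (1-w_t)\,p_{net}$, the simplest rule that strictly
generalizes both members ($w_t \in \{0,1\}$ reproduces them
bit-for-bit). `weight_mode = "equal"` fixes $w_t = 0.5$;
`"validation_grid"` picks $w_t \in \{0, 0.1, \dots, 1\}$ to maximize
accuracy on a held-out fifth of the training data, with members
refitted on the remaining four fifths for the selection and the final
members trained on all of it. The comparison harness defaults to the
validation grid: when one member clearly dominates, an equal vote would
pull the ensemble below it, which is not what a "joint" model should do.

For the network member, continuous features are standardized (train-set
mean/sd) and categorical features one-hot encoded; the tree consumes the
raw typed columns.

# Evaluation

Accuracy and per-class recall (macro-averaged when a scalar is needed)
use the argmax rule. The four error metrics

$$\mathrm{MAE} = \tfrac1n\sum|P_i - T_i|,\quad
  \mathrm{MSE} = \tfrac1n\sum(P_i - T_i)^2,\quad
  \mathrm{RMSE} = \sqrt{\mathrm{MSE}},\quad
  \mathrm{MAPE} = \tfrac1n\sum\frac{|P_i - T_i|}{|T_i|}$$

need a numeric prediction $P_i$; for classifiers this package defines
$P_i$ as the predicted probability of record $i$'s *true* class and
$T_i = 1$. This makes all four metrics well defined, bounded and
sensitive to calibration, not just to the argmax. MAPE is reported as
`NA` whenever some $T_i = 0$ (never under this convention, since
$T_i \equiv 1$). `rmse` $= \sqrt{\texttt{mse}}$ and
`mae` $\le$ `rmse` hold by construction and are asserted over random
vectors.

# The synthetic generator

`generate_dataset()` stands in for questionnaire-plus-activity corpora.
Each record draws a latent class from `class_weights`; continuous
activity features come from class-conditional unit-variance Gaussians
whose means sit `separation` within-class standard deviations apart
(axis-aligned unit directions scaled by $\mathrm{sep}/\sqrt2$); Likert
items come from class-conditional multinomials over levels 1–5 whose
probabilities decay geometrically (rate $e^{-0.5\,\mathrm{sep}}$ per
level) away from a class-specific modal level. At `separation = 0` both
blocks are pure noise, so the best achievable accuracy is the largest
class weight; at `separation = 6` the classes are essentially separable.
Finally each label is replaced with probability `label_noise` by a
different, uniformly chosen class.

The default benchmark — **the study conditions for every comparison in
this package** — is 2000 records, 3 balanced classes, 6 Likert items, 4
continuous features, `separation = 2.5`, `label_noise = 0.05`, divided
into 10 equal parts with six concatenated for training (1200) and four
for testing (800). Likert items are generated and modeled as unordered
categoricals to exercise multiway splits; an ordinal-as-continuous
treatment can be emulated by declaring the column continuous in the
schema. What the generator does *not* emulate: text features, temporal
structure within respondents, missing values, ordinal dependence between
items, or covariate shift between train and test — so passing tests
bound behavior on this family of distributions only, and say nothing
about any particular real corpus.

# Experiment design and problem sizes

The five-model harness (`compare_models()`) fits, per seed: DT (exact
C4.5), IDT (TAM-C4.5), ANN (gradient descent), IANN (LM) and the joint
model, all on the same split. Harness choices, fixed once:

* tree depth 15, minimum node size 5 — mild regularization for noisy
  data at this scale;
* hidden width 3 for both networks. This width matters for fairness: at
  larger widths a fully converged LM fit memorizes the 5% label noise
  that an early-stopped gradient-descent fit never reaches, and the
  comparison measures implicit regularization rather than optimizers;
* gradient descent: step $10/m$, 600 iterations; LM: 40 iterations —
  both near their plateau on the benchmark;
* dominance and monotonicity experiments average 10 seeds; monotonicity
  grids (separation 0/2/6 at noise 0.05, noise 0/0.1/0.2 at separation
  2.5) use 600-record datasets so the full grid stays inexpensive.

Expected qualitative behavior, verified by the acceptance suite: the
joint model's mean accuracy is not below its best member's by more than
noise; TAM scoring does not degrade the tree; LM does not degrade the
network; accuracy rises with separation and falls with label noise for
every model.

# Known limitations

* The Maclaurin surrogate's entropy error exceeds 5% outside roughly the
  $[0.4, 0.6]$ proportion band (measured: 12.8% at 20/80); its fitness
  for tree induction rests on rank agreement, not on absolute accuracy.
* LM assembles a dense $nK \times W$ Jacobian: memory grows linearly in
  samples × outputs × parameters, which is fine at questionnaire scale
  and wrong for large corpora.
* No pruning, no missing-value handling, no ordinal split types; class
  probabilities at leaves are unsmoothed empirical frequencies.
* A 2-2-2 network cannot always escape XOR's local minima; neither
  trainer is restarted automatically.
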