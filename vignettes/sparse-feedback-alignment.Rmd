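---
title: "Training with sparse direct feedback alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training with sparse direct feedback alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsefa)
```

## The credit-assignment problem this package addresses

Backpropagation computes the error signal of a hidden layer from the
transposed forward weights of every deeper layer. On distributed or
near-memory hardware — and in any biologically motivated reading of learning —
this is the *weight transport problem*: a synapse's update depends on weights
stored arbitrarily far away, forcing global data movement on every training
step.

Feedback alignment replaces the transposed weights with *fixed random*
feedback; direct feedback alignment (DFA) goes further and delivers the
output-layer error `e` straight to each hidden layer through one fixed random
matrix `B_l`. This package implements the sparse extension: the feedback
matrix is constrained to have a prescribed **rank** and **sparsity**
(fraction of exactly-zero entries), down to the extreme of a *single* nonzero
per row (SSDFA), where the error of neuron `i` in layer `l` is literally a
product of three scalars:

```
delta_li = B_lij * e_j * f'(a_li)
```

so one error word per neuron is all the backward pass ever moves.

## Model and update rules

The forward pass is a plain fully connected network without biases,

```
y_l = W_l a_{l-1},   a_l = f(y_l),   a_0 = x,
```

with elementwise activations (`tanh`, `relu`, `sigmoid`, `linear`) whose
derivatives are evaluated from the activation output `a` (for tanh,
`1 - a^2`; the relu derivative at exactly 0 is taken to be 0). The output
layer is linear and paired with softmax cross-entropy, so the output error is

```
e = softmax(y_n) - target,
```

which is exactly the loss gradient at the output pre-activations; no
activation-derivative gate is applied at the output layer under any rule.
The hidden-layer error signals are

```
BP:        delta_l = W_{l+1}^T delta_{l+1} * f'(a_l)
DFA/SDFA:  delta_l = B_l e * f'(a_l)
```

and every rule shares the outer-product weight gradient
`dW_l = delta_l a_{l-1}^T` and plain SGD,
`W_l <- W_l - lr * decay^epoch * dW_l`. Mini-batch gradients are averaged
over the batch, which keeps the learning-rate semantics independent of batch
size. Feedback matrices are fixed at generation time and never updated.

With a single hidden layer and `B_1 = W_2^T`, DFA and BP coincide exactly;
the test suite asserts this to `1e-12`, and checks the full BP gradient
against central finite differences to `1e-6` on randomly drawn small
networks (depth at most 3, widths at most 6).

## Constructing feedback matrices with prescribed rank and sparsity

`generate_feedback()` builds an `N x M` matrix with rank `R` and sparsity
`S`, where `M` is the number of output errors. The per-row support size is
`k = round(M (1 - S))`, held constant across rows (the stricter reading of a
fixed per-neuron fan-in). The construction:

1. `R` base rows each receive `k` nonzeros drawn uniform on
   `[-b, b]`. Their supports are dealt round-robin over a random column
   order, so together they cover all `M` columns whenever `R * k >= M`.
2. The remaining `N - R` rows are uniform-random nonzero scalar multiples
   (`sign * U(0.1, 1)`) of randomly chosen base rows. A linearly dependent
   row must share its parent's zero pattern, so per-row sparsity is
   preserved exactly.
3. Row order is shuffled, and the realized rank is verified by SVD. In the
   measure-zero event that the sampled base rows are rank deficient, they
   are resampled with an incremented seed (at most 100 attempts, then a
   hard error) — deterministic behavior with a loud failure mode rather
   than silent deficiency.

Feasibility requires `R (1 - S) >= 1`. Below that product some error column
is necessarily all zero, meaning that class's error could never propagate
backwards; such specs raise at construction and sweep cells are recorded as
skipped, never trained. The comparison carries a `1e-9` tolerance so that
decimal sparsities such as 0.9 are not rejected by float representation.

`generate_ssdfa()` is the single-connection special case: one nonzero per
row, columns dealt round-robin so every error is covered and each column
receives at least `floor(N/M)` connections; rank is `M` and sparsity
`(M-1)/M` by construction.

**Initialization bounds.** Forward weights default to
`U(-1/sqrt(fan_out), 1/sqrt(fan_out))`; a literal `1/fan_out` rule is also
built in (`init = "inv_fan_out"`) because the two readings differ only by a
radical and both are defensible — no test depends on which is active.
Feedback values default to half-width `1/sqrt(k)`: with `k` nonzeros per
row this keeps the variance of `B_l e` invariant as sparsity changes, so
sweeps compare sparsity patterns rather than feedback gain. Both bounds are
explicit arguments for users who want other conventions.

## The alignment-angle diagnostic

For hidden layer `l` the diagnostic compares the fixed feedback `B_l`
against the product of all downstream forward weights
`P = W_n ... W_{l+1}`; `alignment_angle()` vectorizes `t(P)` and `B_l` and
returns the angle between them in degrees. For random initial weights the
angle starts near 90°; as training proceeds the forward weights drift into
alignment with the feedback, which is the mechanism by which a fixed random
backward channel comes to deliver gradient-like directions. `train_network()`
records the angle per hidden layer each epoch, and the sweep runner records
its final value per cell.

## The hardware cost model

`layer_costs()` accounts reads, writes, multiply-accumulates and *data
movement* — defined as the words a neuron must send or receive per weight
update — per training example, in words (no byte widths are assumed):

| rule | reads | writes | MACs | movement |
|------|-------|--------|------|----------|
| BP   | \|W\|+\|A\| | \|W\| | 2\|W\| | \|W\|+\|A\|+\|E_next\| |
| DFA  | \|W\|+\|B\| | \|W\| | \|W\|+\|B\| | \|A\| × \|E\| |
| SDFA | \|W\|+\|b\| | \|W\| | \|W\|+\|b\| | \|A\| × \|e\| |

BP movement is read in the von Neumann sense (weights and activations
shuttle to and from main memory, plus the downstream error vector); DFA and
SDFA movement is read per neuron — each neuron receives the full error
vector (`|E|` words) under dense feedback and only its `|e| = k` connected
errors under sparse feedback — multiplied by the neuron count. This reading
makes dense SDFA (`k = M`) equal the DFA accounting exactly and reproduces
both headline figures for the 9216-4096-4096-1000 fully connected stack:
movement falls by exactly the class count (1000×) from DFA to SSDFA and by
about 6,400× from BP to SSDFA, while the MAC reduction `2|W|/(|W|+|b|)` is
bounded above by 2 and approaches it as weights dominate feedback nonzeros.
Non-FC layers can be costed by passing a hand-built counts table to
`layer_costs()`; the bundled derivation covers fully connected stacks only.

## Synthetic tasks: what they emulate and what they do not

`make_cluster_task()` is the package's default test surface: `n_classes`
Gaussian clusters whose means sit on scaled orthonormal directions, with
isotropic noise. **`margin` is the distance from a class mean to its nearest
midpoint decision boundary** (so pairwise mean distances are `2 * margin`);
at `margin/noise_scale = 6` a typical sample sits six noise standard
deviations from the boundary, and a linear softmax reliably exceeds 95%
test accuracy — the calibration the bundled defaults are built around. The
default dimensions (784 features, 10 classes, hidden width 400) mirror the
classic handwritten-digit fully connected setting so that sweep outputs have
the familiar shape. `make_teacher_task()` labels uniform inputs by a frozen
random teacher network, guaranteeing a realizable boundary; argmax labels of
a random teacher cannot be exactly balanced, so only class *coverage* is
guaranteed there (with input resampling up to a retry bound), whereas
cluster tasks are balanced within one sample.

Passing on these tasks shows that the credit-assignment machinery works —
gradients are correct, feedback delivers usable error directions, sparsity
does not break learning. It does not show image-scale behavior: the clusters
are unimodal and linearly separable, with none of the within-class structure
of real images, and accuracy differences between rules are compressed at
this difficulty. Expect larger BP-versus-DFA gaps on hard real datasets than
on these tasks.

`read_idx()` reads MNIST-style IDX files (big-endian magic 2051/2049,
bytes scaled to `[0, 1]`) for users who want a scaled-down replication on
real digits; no dataset is bundled or downloaded, and nothing in the test
suite depends on one.

## Training driver and sweeps

`train_network()` is the single driver for all three rules; it validates
shapes and feedback feasibility up front, warns if any error column of a
supplied feedback matrix is entirely unconnected (a confound that would
silently hide classes from the backward pass), and returns a tibble history
(epoch 0 is the pre-training evaluation) plus the final parameters. The
whole run is a pure function of the configuration and root seed: histories
reproduce bitwise, and `run_experiment()` writes timestamp-free CSVs so
reruns are byte-identical. `sweep_rank_sparsity()` enumerates a rank ×
sparsity grid, trains `repeats` seeds per feasible cell (default 3 for fast
iteration; 10 matches the convention of averaging ten simulations per cell),
and `aggregate_sweep()` reduces to per-cell means and standard deviations.

Default optimizer settings (`learning_rate = 0.05`, `decay = 1`,
`batch_size = 50`) were chosen by a small sweep on the bundled cluster task,
mirroring how such hyperparameters are normally tuned per task; they are
arguments, not constants.

## Numerical choices and edge conventions

* 64-bit floats throughout; softmax is computed with max subtraction, and
  test-time log-loss through a log-sum-exp, so saturated logits do not
  overflow.
* The relu derivative at exactly 0 is 0, shared by the forward and backward
  paths.
* `measure_rank()` counts singular values above
  `max(dim) * eps * max(sv)`, the standard SVD rank tolerance.
* Sparsity counts exact structural zeros only; generated nonzero values are
  never thresholded (the single-connection generator draws magnitudes in
  `[0.1, 1]`, bounded away from zero).
* Ties in argmax classification resolve to the first class, fixed so that
  histories are reproducible.
* Degenerate inputs fail loudly: non-finite inputs or gradients,
  non-chaining layer specs, non-one-hot targets, infeasible feedback specs
  and unreadable IDX headers all raise with the offending object named.

## Problem sizes used by the test suite

The suite exercises full-scale feedback construction (400 × 10 over the
complete feasible rank/sparsity grid) but trains at deliberately modest
sizes: the behavioral checks train 784-400-10 networks for 5 epochs on
6,000-sample tasks across 5 seeds per rule, and the sweep-trend checks use
16-to-20-dimensional tasks with hidden widths of 20–24. These sizes are the
package's own choice of a desk-scale experiment: large enough that BP, DFA
and SSDFA all clear 95% test accuracy and the alignment angle visibly falls
from initialization, small enough to iterate on quickly.

## Known limitations

* Fully connected networks only: no convolutional, pooling or normalization
  layers, and no momentum/adaptive optimizers — plain SGD with
  multiplicative decay is the only update rule.
* Direct feedback variants are known to degrade on deep convolutional
  stacks; nothing here contradicts that, since the package does not train
  them.
* The cost model is analytic word counting, not a cache- or cycle-accurate
  simulation, and deliberately reports no absolute megabyte figures (word
  size is presentation-level: `word_bytes` would be a display choice, not a
  model input).
* Feedback is fixed by design; learned or sign-symmetric feedback is out of
  scope.
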