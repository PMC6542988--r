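# sparsefa

Training fully connected neural networks **without weight transport**:
backpropagation (BP), direct feedback alignment (DFA), and its sparse
variants (SDFA / SSDFA), together with the generator for rank- and
sparsity-constrained random feedback matrices, the feedback-alignment angle
diagnostic, and an analytic hardware cost model of reads, writes,
multiply-accumulates (MACs) and data movement per training example.

## Who this is for

Researchers in bio-plausible learning and neuromorphic hardware who want a
small, fully tested reference implementation of sparse direct feedback
alignment: every backward-pass rule is hand-written, checked against
finite-difference oracles, and instrumented so that the locality and cost
claims of local learning can be measured rather than asserted.

## The algorithm

The forward pass is the usual `y_l = W_l a_{l-1}`, `a_l = f(y_l)` without
biases; the output layer is linear under softmax cross-entropy, so the
output error is `e = softmax(y_n) − target`. The three credit-assignment
rules differ only in the hidden-layer error signal:

```
BP:         δ_l = W_{l+1}ᵀ δ_{l+1} ⊙ f′(a_l)      (weight transport)
DFA/SDFA:   δ_l = B_l e ⊙ f′(a_l)                 (fixed random feedback)
```

Under SDFA the fixed feedback matrix `B_l` is sparse with prescribed rank
`R` and sparsity `S` (fraction of zeros); feasibility requires
`R (1 − S) ≥ 1`, otherwise some error signal could never reach the layer.
In the single-connection extreme (SSDFA, one nonzero per row) the error of
each neuron is a product of three scalars `B_lij · e_j · f′(a_li)` — one
error word per neuron is all the backward pass moves. All rules share the
outer-product gradient `δW_l = δ_l a_{l−1}ᵀ` and SGD with multiplicative
learning-rate decay.

The alignment angle between a layer's feedback matrix and the product of
its downstream forward weights (`∠(B_l, ∏ W_i)`, vectorized, in degrees)
starts near 90° at initialization and falls as the forward weights align to
the fixed feedback — the mechanism that makes random feedback deliver
gradient-like directions.

## Worked example

Train a 784-400-10 tanh network on the bundled Gaussian-cluster task
(10 classes, margin-to-noise ratio 6, 6,000 samples) with single-connection
sparse feedback:

```r
library(sparsefa)

task <- make_cluster_task(6000, 784, 10, margin = 6, noise_scale = 1, seed = 1)
fit  <- train_network(task, network_spec(c(784, 400, 10)), rule = "SDFA",
                      cfg = update_config(0.05), epochs = 5, seed = 1)
tidy(fit)
#> # A tibble: 6 × 6
#>   epoch train_accuracy test_accuracy train_loss mean_angle angle_1
#>   <int>          <dbl>         <dbl>      <dbl>      <dbl>   <dbl>
#> 1     0         0.0932         0.089    3.93          90.0    90.0
#> 2     1         0.997          0.992    0.0461        77.9    77.9
#> 3     2         1              0.996    0.0172        76.5    76.5
#> 4     3         1              0.998    0.0104        75.8    75.8
#> 5     4         1              0.999    0.00749       75.4    75.4
#> 6     5         1              0.999    0.00585       75.1    75.1
```

Epoch 0 is the pre-training evaluation: chance accuracy (~0.09 on 10
classes) and a 90° alignment angle, as expected for random feedback against
random weights. By epoch 5 the network classifies 99.9% of held-out samples
while each hidden neuron received exactly **one** error scalar per update,
and the alignment angle has dropped by ~15°. `autoplot(fit)` draws the
curves; `glance(fit)` gives the one-row summary.

The cost model for the same architecture:

```r
report_costs(network_spec(c(784, 400, 10)))
#> Per-example cost totals (words):
#> # A tibble: 3 × 5
#>   rule   reads writes   macs movement
#>   <chr>  <dbl>  <dbl>  <dbl>    <dbl>
#> 1 BP    318010 317600 635200   318030
#> 2 DFA   321600 317600 321600     4100
#> 3 SDFA  318000 317600 318000      410
```

Movement under BP is dominated by shuttling the 317,600 weights; under
SSDFA it is 410 words — one error per neuron. On a 9216-4096-4096-1000
stack the same accounting yields the headline factors: 1000× movement
reduction from DFA to SSDFA and ≈6,400× from BP to SSDFA, with the MAC
reduction bounded by 2.

Feedback matrices with controlled rank and sparsity:

```r
B <- generate_ssdfa(25, 10, seed = 1)   # one nonzero per row
glance(B)
#> # A tibble: 1 × 6
#>   n_rows n_cols  rank sparsity   nnz  seed
#>    <int>  <int> <int>    <dbl> <int> <int>
#> 1     25     10    10      0.9    25     1

generate_feedback(feedback_spec(400, 10, rank = 5, sparsity = 0.5, seed = 3))
#> <feedback_matrix> 400 x 10, rank 5, sparsity 0.500
```

`sweep_rank_sparsity()` runs the full rank × sparsity grid (skipping
infeasible cells with the reason recorded), `aggregate_sweep()` reduces it
to per-cell means ± sd, and `autoplot()` plots accuracy against rank by
sparsity. A thin command-line front end over these functions lives in
`inst/cli/sparsefa.R` (verbs `train`, `sweep`, `cost`, `gen-feedback`,
`gen-task`, driven by YAML configs).

## Scope

Fully connected networks and plain SGD only: no convolutional layers, no
adaptive optimizers, no learned feedback. The methods vignette
(`vignettes/sparse-feedback-alignment.Rmd`) documents the model,
the feedback-matrix construction, the cost-model semantics, all numerical
conventions, and known limitations.
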