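---
title: "Models and methods: graph-aware forecasting of brain-network signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: graph-aware forecasting of brain-network signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(graphbold)
```

## The problem

Resting-state fMRI yields, after parcellation, one band-limited and
temporally autocorrelated time series per brain region — a data matrix
$X \in \mathbb{R}^{N\times T}$ sampled every TR $= 0.72$ s. Diffusion MRI
yields a weighted, symmetric structural adjacency $A_w$ between the same
regions. graphbold asks how well the *future* activity of all regions,
$[x^{(T_p+1)},\dots,x^{(T_p+T_f)}]$, can be predicted from a window of past
activity $[x^{(1)},\dots,x^{(T_p)}]$ when the forecaster is allowed to move
information along the graph — and what the trained forecaster then implies
about directed region-to-region influence.

## Spatial coupling

All spatial mixing is built from the random-walk transition operator
$T = D^{-1}A_w$ with $D = \mathrm{diag}(A_w \mathbf{1})$. A graph filter of
walk order $K$ is the truncated power series

$$y^q = \sum_{m}\sum_{k=0}^{K} \theta_k^{qm}\, T^k x^m,$$

applied by $k$ repeated operator products (powers of $T$ are never
materialized). Three couplings are available through `spatial_spec()`:

* **operator** — $T$ built from a structural adjacency (`SC`) or from the
  Pearson similarity of node2vec connectome embeddings (`CE`);
* **adaptive** — a learned $A_{\mathrm{adap}} = \tanh(V)/N$ with $V$ free
  and zero-initialized, so every entry stays strictly inside $(-1/N, 1/N)$;
* **hybrid** — the sum of both power series;
* **none** — $K = 0$, the spatially decoupled null model.

Correlation-based CE adjacencies can carry negative entries; these are
clipped to zero before row normalization (an absolute-value option exists).
The diagonal of the CE similarity is zeroed: self-influence is carried by
the $k = 0$ term. Zero-degree nodes keep an all-zero transition row rather
than an invented self-loop.

## Connectome embeddings

`connectome_embedding()` runs second-order biased random walks (100 walks
of length 80 per node; return parameter $p = 2$, in-out parameter $q = 1$)
and trains 64-dimensional skip-gram vectors with negative sampling. The
walk generator and the SGNS trainer are compiled code with a private RNG,
so a seed fully determines the embedding. The skip-gram context window
(10), epochs (5) and negative samples (5) are not dictated by the walk
construction; they are standard word2vec defaults and are exposed in
`embedding_config()`. Isolated nodes emit length-1 walks and receive a
zero similarity row instead of failing, since random synthetic graphs may
contain them.

## Forecasters

**DCRNN** (`dcrnn()`): an encoder–decoder of diffusion-convolution GRU
cells. Each gate replaces the dense matrix product of a GRU with the graph
filter above applied to $[x \,\|\, h]$:
$r = \sigma(\mathcal{G}_C(\Theta_r)[x\|h] + b_r)$, likewise $u$, and a
candidate $c = \tanh(\mathcal{G}_C(\Theta_c)[x \,\|\, r \odot h] + b_c)$,
with the convex update $h' = u \odot h + (1-u)\odot c$. The decoder starts
from a zero GO vector; during training it consumes the true previous value
with probability $\epsilon_i = \tau/(\tau + e^{i/\tau})$ (one Bernoulli
draw per decoder step per sample; $\tau$ defaults to 2000 iterations) and
its own prediction otherwise; in validation and test mode $\epsilon = 0$
strictly. The output head is an affine map from the final hidden state to
one feature per node per step.

**GWN** (`gwn()`): blocks of gated dilated causal convolutions
$h = \tanh(\mathcal{D}_C(\Theta_1)x + b_1)\odot\sigma(\mathcal{D}_C(\Theta_2)x + b_2)$
interleaved with graph convolutions (applied independently at each time
index), residual connections, and skip branches taken after the graph
convolution; the summed skips pass through two dense layers that emit all
$T_f$ steps at once. The dilation schedule is $(1, 2)$ within each block,
repeated across blocks; the kernel width defaults to $R = 2$, giving a
receptive field $1 + (R-1)\sum d$. Whether the skip branch should be taken
before or after the graph convolution is not forced by the architecture;
taking it after keeps the skip path spatially informed and is the choice
made here.

**TAtt** (`tatt()`): stacked causal temporal-attention layers with no
spatial mixing. Queries/keys/values share one projection
$g(x) = \mathrm{ReLU}(Wx + b)$ per head; scores are inner products divided
by the head width $D$; the softmax runs over $t_j \le t_i$. Strictly
$t_j < t_i$ leaves the first row empty, so the mask is relaxed to include
the current step — an implementation choice, flagged here. Heads act on
disjoint $D = M/\mathrm{heads}$ slices and are concatenated; each layer
adds a residual connection and batch normalization (training-mode batch
statistics, evaluation-mode running averages, momentum 0.1). The horizon
is emitted jointly by a learned affine map over the time axis.

**VAR** (`fit_var()`): the pooled least-squares vector autoregression
$x^{(t)} = b + \sum_{l=1}^{p} A_l x^{(t-l)} + u^{(t)}$, forecasting
recursively on its own predictions. One model is fitted across all
training windows of all sessions; the regression rows come from each
session's contiguous training stretch, so session boundaries are never
crossed. `select_order()` scans $p$ in steps of five and keeps the order
with the lowest test MAE. `adf_fraction()` reports (never blocks on) the
share of region series failing an augmented Dickey–Fuller screen at
$\alpha = 0.01$; the test regression uses AIC lag selection up to the
Schwert bound and MacKinnon response-surface critical values, implemented
in the package because no unit-root package is among its dependencies.

## Training

All neural models are trained by Adam on the MAE objective through a small
reverse-mode automatic-differentiation engine written for this package
(matrix-valued nodes; verified against central finite differences in the
test suite). Family presets in `train_schedule()` follow the published
regimes — DCRNN: 70 epochs, batch 16, learning rate 0.1 decayed by 0.1 at
epochs 20/40/60 with gradient-norm clipping at 5; GWN: 30 epochs, batch 8,
rate $10^{-4}$ decayed at 10/20; TAtt: 40 epochs, batch 16, rate 0.1
decayed at 10/20/30. If validation MAE fails to improve for more than 10
epochs, the best weights are restored and the next decay fires early; the
returned model is always the best-validation checkpoint. A small-cohort
preset doubles the epoch budget and shifts the decays accordingly. Session
signals are min-max scaled to $[0,1]$ before training using full-session
statistics; that choice leaks the test range into the scaling (two
scalars) and is retained deliberately as the conventional protocol — a
strict train-only variant sits behind `scale_train_only`. Z-scoring with
region-wise statistics pooled over the dataset is applied only at
evaluation time, to report scale-free errors.

## Directed influence

For a trained forecaster $h(\cdot)$ on standardized data, silencing region
$n'$ means zeroing its input window (zero is the sample mean). The
influence of $n'$ on $n$ is

$$I_n(n') = \frac{1}{S}\sum_s \frac{1}{T_f}\sum_t
 \left| \hat{x}_n^{(t)}(s) - \hat{x}_n'^{(t)}(s) \right|,$$

evaluated over the test split. Targets are never modified. The diagonal is
computed but excluded from the 0–100 rescaling and from edge-recovery
ranking, since self-influence is trivially large. On a path graph, a
1-layer DCGRU with $K = 1$ propagates at most three hops per
encoder+decoder step pair (the reset gate adds one hop before the
candidate's graph convolution), and influence beyond that radius is
exactly zero — a property the tests probe directly.

## The synthetic generator

`make_benchmark()` draws a symmetric random graph (edge probability 0.2,
uniform $(0,1]$ weights) and simulates

$$x^{(t)} = \gamma\, x^{(t-1)} + \beta\, T x^{(t-1)} + \varepsilon^{(t)},
\qquad \gamma = 0.5,\ \beta = 0.4,\ \varepsilon \sim
\mathcal{N}(0, 1),$$

with a 200-step burn-in, i.e. exactly a VAR(1) with coefficient
$\gamma I + \beta T$ and spectral radius below one by construction. This
emulates the two features of parcellated BOLD that matter for the methods
— temporal autocorrelation and graph-mediated coupling — and deliberately
omits hemodynamic convolution, scanner drift and physiological noise, so
green tests certify the machinery, not fMRI realism. An optional band-pass
on the innovations is off by default to keep the VAR(1) identity exact for
the oracle tests.

An important property of this process: because coupled signals are
spatially smooth, a region's own history already predicts much of its
future. The exact linear analysis (fit a full VAR versus a per-region AR
on the same windows) shows the spatial information gain is only a few
percent of MAE and grows as the input window shortens. The training-based
checks therefore use short windows ($T_p = T_f = 3$), one 500-step
session, and deliberately small models (DCRNN hidden 16, 1 layer, 8
epochs; GWN 8 channels, 2 blocks, 8 epochs at rate $3\times 10^{-3}$) —
sizes at which both the graph-aware model and its $K=0$ null converge to
their respective optima within CPU minutes and the paired comparison is
decided by the spatial margin rather than by optimization noise. The VAR
recovery check uses $T = 5000$ so that OLS noise sits well inside the
0.05 entrywise band.

## Numerical choices and degenerate inputs

* Band-pass filtering uses an order-5 Butterworth applied
  forward-backward (zero phase); phase distortion would corrupt lag-based
  modeling. The band must lie strictly inside $(0, \mathrm{Nyquist})$.
* Min-max scaling of a constant session, Pearson similarity of a constant
  embedding row, FC states of constant regions, and rescaling of a
  constant influence matrix are all refused with specific errors rather
  than returning NaN.
* Chronological splits use floor rounding for validation and test with
  the remainder to training (a 1,081-pair session yields 108 test pairs);
  windows never cross session boundaries.
* Weight initialization is Glorot-uniform with the full power series
  treated as one layer (effective fan-in $c_{in}(K{+}1)\cdot$branches);
  biases start at zero; the adaptive $V$ starts at zero so
  $A_\mathrm{adap}$ starts as the zero matrix.
* Non-finite training losses abort with a diagnostic rather than
  continuing.
* Training is bit-reproducible under a fixed seed and single-threaded
  BLAS; the test suite asserts equality of history curves at $10^{-6}$.

## Known limitations

* The engine is plain R matrix algebra: fine for tens of regions and
  CPU-minute training budgets, far from GPU-framework scale (hundreds of
  regions at full session counts).
* The eigenbasis (spectral) formulation of the graph convolution is
  intentionally not implemented; the power series is the computational
  route throughout.
* Influence is a property of the fitted predictive model, not a causal
  claim about the underlying system; hemodynamics and sampling-rate
  limits apply to any lag-based method.
* TAtt is included for completeness of the comparison; on
  low-data regimes it is expected to trail the recurrent and
  convolutional families.
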