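# graphbold

Forecasting brain-network activity with graph neural networks, and turning
the trained forecasters into a directed-connectivity probe.

## The problem

After parcellation, a resting-state fMRI session is a matrix
`X ∈ R^{N×T}` of region-averaged BOLD signals (TR = 0.72 s), and diffusion
tractography gives a weighted symmetric structural adjacency `A_w` between
the same `N` regions. The scientific question is twofold: how much better
can the future activity of every region,
`[x^(Tp+1), …, x^(Tp+Tf)]`, be predicted from a window of past activity
when the forecaster is allowed to propagate information along the
anatomical graph — and, given a trained forecaster, which regions carry
predictive information about which others (directed influence)?

## What is in the package

All spatial mixing uses the random-walk transition operator
`T = D⁻¹ A_w`, `D = diag(A_w 1)`, inside truncated power-series graph
filters `y = Σ_k θ_k T^k x` (walk order `K`; `K = 0` is the spatially
decoupled null). Three coupling substrates are supported: a structural
adjacency, the Pearson similarity of node2vec connectome embeddings
(biased walks + skip-gram, implemented in compiled code), and a learned
adaptive adjacency `tanh(V)/N`.

On top of these, three forecaster families and a baseline:

* `dcrnn()` — encoder–decoder of diffusion-convolution GRU cells with
  scheduled sampling `ε_i = τ/(τ + e^{i/τ})`;
* `gwn()` — graph WaveNet: gated dilated causal convolutions interleaved
  with graph convolutions, residual/skip connections, one-shot
  multi-horizon head;
* `tatt()` — stacked causal temporal-attention layers (no spatial
  mixing), residual connections and batch normalization;
* `fit_var()` — pooled ordinary-least-squares VAR(p) with order selection
  in steps of five and an augmented Dickey–Fuller stationarity screen.

Models train with Adam on the mean-absolute-error objective through the
package's own reverse-mode autodiff engine (no GPU framework needed), with
the published learning-rate schedules as presets. `influence_matrix()`
silences one region's input window at a time and records the mean absolute
change of every region's forecast — a directed `N×N` influence matrix,
rescalable to 0–100. A synthetic generator
(`make_benchmark()`) produces graph-coupled VAR(1) signals with known
ground truth so that every claim is testable without imaging data.

## Worked example

Twenty regions, known coupling `x_t = 0.5 x_{t-1} + 0.4 T x_{t-1} + ε`,
one 500-step session, 3-step input and forecast windows:

```r
library(graphbold)

cfg   <- synthetic_config(n = 20, t_len = 500, sessions = 1, seed = 1)
bench <- make_benchmark(cfg)
prep  <- prepare_data(bench$sessions, t_p = 3, t_f = 3)

sp    <- spatial_spec("operator", operator = bench$operator, k = 1)
model <- dcrnn(sp, t_p = 3, t_f = 3, hidden = 16, layers = 1, seed = 101)
fit   <- train_model(model, prep$splits,
                     train_schedule("dcrnn", epochs = 8, batch_size = 16,
                                    decay_epochs = c(4, 6), seed = 101))

evaluate_model(fit$model, prep$splits$test)[c("mae", "r2")]
im <- rescale_0_100(influence_matrix(fit$model, prep$splits$test))
influence_edge_auc(im, bench$graph)
```

This prints (seed 101):

```
test MAE: 0.0821   R2: 0.362
influence edge-recovery AUC: 0.998
```

The test MAE of 0.082 sits essentially on the linear-optimal floor for
this process, about 3–5 % below the same model trained with `K = 0`
(no spatial mixing) — the spatial benefit the package is built to
measure. The influence matrix ranks true graph edges above non-edges
almost perfectly (AUC 0.998). FC-state similarity (`fc_similarity`) is
also reported by `evaluate_model()`, but correlation states over 3-step
horizons are noisy; use longer forecast windows when that metric matters.

## Command line

A thin wrapper over the same functions lives in `inst/cli/graphbold.R`:

```sh
Rscript inst/cli/graphbold.R simulate --n 20 --t 2000 --sessions 3 --seed 1 --out sim/
Rscript inst/cli/graphbold.R embed --adjacency sim/adjacency.tsv --seed 1 --out ace.tsv
Rscript inst/cli/graphbold.R fit --sessions sim/ --adjacency sim/adjacency.tsv \
        --model dcrnn --space operator --k 1 --tp 10 --tf 10 --epochs 8 --out model.dir
Rscript inst/cli/graphbold.R evaluate --model model.dir --out report.json
Rscript inst/cli/graphbold.R influence --model model.dir --rescale --out influence.tsv
```
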