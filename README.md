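# flowdock

Generative rigid-body protein–protein docking by conditional flow matching,
at desk scale. Given two monomer backbones, flowdock samples candidate bound
complexes by integrating a learned denoising flow over the ligand pose and
ranks them with a trained confidence readout — the sample-and-rank scheme of
structure-based docking, with every stage (data, training, sampling,
evaluation) runnable and verifiable on synthetic toy complexes on one CPU.

## The model

The state of a two-chain complex is decomposed after a receptor-anchored
superposition into the ligand center `c ∈ R³`, the ligand orientation
`R ∈ SO(3)` relative to a reference conformation, and per-chain internal
coordinates `x̄`. A prior `p₀` — Gaussian translation
`c₀ ~ N(c_rec, σ_tr² I)`, Haar-uniform rotation, and unbound conformers
(holo / apo-like / predicted-like) for `x̄₀` — is transported to the data
distribution along conditional optimal-transport paths:

```
c_t = (1−t) c₀ + t c₁          (straight line in R³)
R_t = R₁ exp((1−t) log(R₁ᵀR₀))  (SO(3) geodesic)
x̄_t = (1−t) x̄₀ + t x̄₁          (per chain, individually superposed)
```

A pair-representation network — structure and conditioning embedders
(triangle multiplicative updates, triangle attention, pair transitions) and
a 4-block AdaLN-conditioned pair denoiser — predicts the fully denoised
state `x̂₁(x_t, t)`; sampling re-interpolates toward `x̂₁` over a uniform
time grid, which is algebraically identical to an Euler step on the
reparametrized velocity `v_t = (x̂₁ − x_t)/(1−t)`. Predictions are scored by
DockQ (`(fnat + 1/(1+(iRMSD/1.5)²) + 1/(1+(LRMSD/8.5)²))/3`, classes
acceptable > 0.23, medium > 0.49, high > 0.80), and benchmark statistics
(top-1/top-5/oracle success with 10,000-resample percentile bootstrap CIs,
per-subunit interface RMSD, one-sided Wilcoxon tests) are built in.

A synthetic-data module generates self-avoiding toy chains with a
composition-biased interface patch (the learnable docking signal), clash-free
bound poses, and perturbed unbound conformers emulating the holo/apo/predicted
input distinction; `baseline_dock()` is the model-free control showing the
planted signal is recoverable.

There is no deep-learning framework dependency: the network and its training
run on a small reverse-mode autodiff engine written for this package, with
C++ kernels for the heavy pair operations and finite-difference-verified
gradients.

## A worked example

```r
library(flowdock)

# a bound toy complex and its unbound monomers
recs <- make_toy_records(1, seed = 42)
native <- recs[[1]]$x1
native
#> ComplexConformation: 2 chains (R:18, L:24), provenance=holo
#>   receptor=R ligand=L

# the model-free patch-matching baseline
bp <- baseline_dock(native, seed = 1)
dockq(bp, native)
#> DockQ 0.297 (acceptable): fnat 0.611, iRMSD 4.98 A, LRMSD 17.19 A

# an untrained model is the identity flow: samples stay at the prior
model <- init_denoiser(denoiser_config(), seed = 1)
res <- dock_complex(model, native, n_samples = 3, steps = 10, seed = 7)
round(sapply(res$predictions, function(p) dockq(p, native)$dockq), 3)
#> [1] 0.027 0.006 0.028

# train on a generated dataset and redock (sizes in the methods vignette)
train_recs <- make_toy_records(400, seed = 1)
fit <- run_stages(train_recs, train_config(seed = 1))
res <- dock_complex(fit$model, native, n_samples = 20, steps = 10, seed = 7)
```

DockQ near zero for the untrained model is expected: its zero-initialized
readout makes sampling a no-op on the prior draw. The training-recovery test
in `tests/testthat/test-acceptance.R` trains the default model on 400
synthetic complexes and measures held-out oracle success.

The command-line surface wraps the same functions:

```sh
inst/exec/flowdock generate --n 50 --seed 7 --out toy_dataset
inst/exec/flowdock train --manifest toy_dataset/manifest.jsonl --out run
inst/exec/flowdock dock --checkpoint run/checkpoint_stage3.rds \
    --receptor toy_dataset/cx0001_R_holo.pdb \
    --ligand toy_dataset/cx0001_L_holo.pdb --out preds
inst/exec/flowdock evaluate --native toy_dataset/cx0001_bound.pdb \
    --predictions preds --out eval.json
```

## Scope

Bi-protein complexes, backbone + CB only, toy scale (chains of tens of
residues). See `vignettes/flowdock-methods.Rmd` for the model, the design
choices and their rationale, and known limitations.
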