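---
title: "Generative rigid-body docking by conditional flow matching: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative rigid-body docking by conditional flow matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

flowdock samples bound protein--protein complex structures given the two
monomer structures, without evolutionary information. The generative model is
conditional flow matching (CFM): a prior distribution $p_0$ over poses is
transported to the data distribution $p_1$ along a probability path $p_t$,
and a neural network is trained to predict, from a noisy intermediate state
$x_t$ and the path time $t$, the fully denoised sample
$\hat{x}_1(x_t, t)$. Sampling integrates the induced velocity field
$v_t = (\hat{x}_1 - x_t)/(1 - t)$ from $t = 0$ to $t = 1$.

The state is decomposed after a global superposition anchored on the
receptor: the ligand's rigid-body pose splits into its CA centroid
$c \in \mathbb{R}^3$ and its orientation $R \in SO(3)$ relative to the
reference ligand conformation, and each chain additionally carries internal
coordinates $\bar{x}$ obtained by superposing that chain individually onto
the reference. The conditional paths are straight (conditional optimal
transport) in $c$ and $\bar{x}$,

$$c_t = (1-t)\,c_0 + t\,c_1, \qquad \bar{x}_t = (1-t)\,\bar{x}_0 + t\,\bar{x}_1,$$

and geodesic on the rotation group,

$$R_t = R_1 \exp\!\big((1-t)\log(R_1^{\top} R_0)\big),$$

with priors $c_0 \sim \mathcal{N}(c_{\mathrm{rec}}, \sigma_{tr}^2 I_3)$
(centered on the receptor CA centroid), $R_0 \sim \mathcal{U}(SO(3))$ (Haar),
and $\bar{x}_0$ drawn from a library of unbound conformers per chain
(holo / apo-like / predicted-like). The rotation path is implemented in the
right-translated convention shown above; the exponential-map notation does
not by itself fix left versus right translation, and either choice satisfies
the endpoint identities — the package pins the convention and tests it
through the endpoint and equivariance properties.

Two algebraic facts organize the implementation and its tests. First, the
translation velocity along its own conditional path is constant and equals
$c_1 - c_0$. Second, an Euler step with the reparametrized velocity is
*identical* to re-interpolating the current state toward the prediction with
effective ratio $(t_{k+1} - t_k)/(1 - t_k)$; the sampler uses the
re-interpolation form, the velocity form is exposed separately, and a test
pins their agreement to $10^{-9}$. A consequence, also tested: with an
oracle denoiser that always returns the true bound state, the sampler ends
exactly at the bound pose for any step count and any prior draw.

## The denoiser network

The network operates on an $L \times L$ pair representation of the current
(noisy) complex:

* **Features.** CB-distogram (38 one-hot bins, 3.25--50.75 Å, AF-template
  convention), inter-residue unit vectors expressed in each residue's
  backbone frame (Gram--Schmidt over N/CA/C), CB and frame masks, one-hot
  residue-pair identities (toggleable — the structure-only ablation),
  clipped relative sequence offsets (±32) with a same-chain flag. Inter-chain
  entries are computed, never masked. All geometric features are invariant
  under global rigid motions; the pair conditioning adds 16 Fourier features
  of $t$.
* **Structure embedder.** Linear embedding followed by two pair-stack
  blocks (triangle multiplicative update outgoing/incoming, triangle
  attention over starting and ending nodes, 4x pair transition).
* **Conditioning embedder.** A linear embedding of the same positional
  features plus the time embedding; it modulates the denoiser through AdaLN
  and is deliberately kept shallow — the conditioning is generated from the
  features, not processed through the pair stack.
* **Pair denoiser.** Four blocks; triangle multiplicative updates are plain
  residual sublayers, while triangle attention and the transition are
  wrapped in adaptive layer normalization (AdaLN): element-wise scale and
  shift predicted from the conditioning modulate the normalized input, and a
  predicted gate rescales each residual delta. Scale and gate biases start
  at one, so AdaLN is an ordinary layer norm at initialization.
* **Pose readout (anchor voting).** Three body anchors of the ligand — its
  internal CA centroid and two points offset 8 Å along the conformer's
  principal axes, with axis signs fixed by intrinsic chain geometry — have
  receptor-determined images under the bound pose. Every receptor residue
  votes for each image as $\mathrm{CA}_i + F_i d_{ik}$ (local-frame offsets
  decoded from the pooled receptor-to-ligand block of the pair
  representation, output-scaled so the zero-initialized head can reach tens
  of Ångströms), the votes are combined under softmax attention weights, and
  two learned scalar gates mix the absolute estimates with the anchors'
  current images. The centroid gives the denoised center; differentiable
  two-vector Gram--Schmidt over the gated anchor displacements gives the
  denoised orientation, and is non-degenerate because the closed-gate
  anchors reproduce the current pose exactly. Gates and head are
  zero-initialized, so the untrained network is exactly the identity on the
  state and sampling is a no-op — a tested contract. This gated-absolute
  form was chosen over a pure update parametrization after the latter proved
  hard to optimize: on bound complexes the target pose is a function of the
  receptor geometry alone, and position voting turns orientation regression
  into the same, easier, point-regression problem as translation.
* **Confidence readout.** A per-pair scorer: every inter-chain entry of the
  *predicted* structure — its raw positional pair features concatenated with
  the corresponding embedded pair-representation row — passes through a
  small MLP, the per-pair scores are averaged and squashed through a
  sigmoid. Scoring before pooling matters: the ranking signal is a
  conjunction ("interface-type residue pair in contact") that mean-pooled
  channels cannot express, and probes on pooled features confirmed this
  empirically. The head regresses the DockQ of the model's own prediction
  and plays the role of the ranking confidence in sample-and-rank
  inference.

Everything runs on a small reverse-mode autodiff tape written for this
package (dense-array operations with hand-derived backward rules; the hot
kernels — layer normalization, broadcasts, triangle multiplication and
attention — are C++). Every backward rule is verified against finite
differences in the test suite, including end-to-end through the full network
and structure loss.

## Training

Each training step samples $t \sim \mathcal{U}[0, 0.99)$, draws a prior
state (monomer provenance per the stage's probabilities), interpolates to
$x_t$, runs the network, and applies one Adam update (learning rate decayed
linearly from $5\times10^{-3}$ to $10^{-3}$). Three stages mirror a staged
curriculum: stages 1 and 2 train the docking module (embedders, pair
denoiser, pose readout) and differ only in monomer sampling — stage 1
holo-only, stage 2 mixed 20%/40%/40% holo/apo-like/predicted-like; stage 3
trains all parameters under the same sampling, and the confidence head
trains through both mixed stages. The pose readout is trainable from stage
1 because it is freshly
initialized here — there is no pretrained folding trunk to freeze around —
so freezing it would leave the early stages with nothing to move the pose.

Two auxiliary signals stabilize optimization, both internal to training and
absent at inference: dense deep supervision of the anchor votes (every
receptor residue's vote for every ligand anchor regresses onto that
anchor's image under the native pose, giving direct credit assignment
regardless of the attention weights and gate state), and, in the mixed
stages, the confidence head regressing the DockQ of six structures per step
— the model's prediction, the noisy state itself, and four rigid jitters of
the bound pose that cover the quality bands where ranking matters. The
confidence regression is applied through a stop-gradient on the trunk — it
trains only the head, at its own constant learning rate since it starts
mid-schedule — because joint training measurably disturbed the pose
features at this scale.

The structure objective defaults to the plain coordinate MSE of the denoised
prediction, unweighted in $t$ (`mse`). The $(1-t)^{-2}$-weighted coordinate
MSE of the CFM objective (`weighted_mse`) and the clamped cross-chain
frame-aligned point error (`fape_like`, 10 Å clamp) are implemented and
tested, but neither is the training default: the CFM weight concentrates
gradient mass on $t \to 1$ samples, for which the best prediction is already
the input state, and the 10 Å clamp silences exactly the far-from-native
samples that carry the pose signal — in this small-data regime both
measurably stall the pose gates, which was verified empirically before
fixing the default. All modes satisfy the same zero-at-truth and invariance
tests.

Determinism: every stochastic component (chain generation, pose search,
prior draws, $t$, Adam data order) derives its own substream from one root
seed, and training histories are bitwise reproducible in single-threaded R.

## Synthetic data: what it emulates and what it does not

`toygen` generates self-avoiding smoothed random-walk backbones (3.8 Å
virtual bonds, ideal-geometry N/C/O/CB) with one contiguous interface patch
per chain whose residues are drawn from a distinct composition
(W/Y/F/M against a background of the remaining amino acids) — the learnable
docking signal. Bound poses place the patches face to face, require at least
`contact_target` CB--CB contacts under 8 Å and no inter-chain atoms closer
than `clash_floor` (2.5 Å), and select, among clash-free patch-facing
placements, the pose optimizing a registered patch-contact score (receptor
patch residue $k$ pairs with reversed ligand patch residue $w{+}1{-}k$); the
registration pins a unique preferred orientation so the planted pose is
recoverable from sequence and geometry alone. `baseline_dock()` — a
model-free search over the same score, knowing only the biased residue set —
reaches acceptable DockQ on the large majority of complexes, which is the
package's learnability control.

Unbound (apo-like / predicted-like) conformers apply smoothed correlated
backbone noise plus one interior hinge rotation, then re-idealize bond
lengths; defaults (apo: $\sigma = 0.65$ Å, hinge 0.05 rad; predicted:
$\sigma = 1.2$ Å, hinge 0.10 rad) were calibrated once so apo-like CA-RMSD
to the bound conformation falls in 0.3--2.0 Å, mimicking the typical
accuracy ordering of experimental apo structures versus predicted monomers.

What the toy data does *not* emulate: sidechain packing and chemistry,
realistic secondary structure, binding energetics, size and composition
diversity of real interfaces, or crystallographic artifacts. Passing the
training-recovery test therefore shows that the flow, the architecture and
the optimization can extract a planted structural signal end to end — not
that the model would dock real proteins.

## Numerical choices

* SO(3) exponential/logarithm switch to series limits below $10^{-7}$;
  near-$\pi$ logarithms use the symmetric-part eigenvector branch; geodesics
  through an exact half-turn pick the principal branch with a warning.
* Haar rotations come from normalized 4D Gaussian quaternions.
* Kabsch superposition excludes reflections (determinant forced to $+1$) and
  refuses fewer than three or near-collinear points.
* Distogram underflow goes to the first bin, overflow to the last, the
  diagonal to the first; masked pairs are all-zero rows.
* The time grid is uniform, $t_k = k/K$, and $t = 1$ is never fed to the
  network — the final update jumps to the last prediction. This is the
  simplest scheme consistent with a 10-step default and the
  $(1-t)^{-1}$ singularity.
* Translation prior $\sigma_{tr}$ defaults to 15 Å, comparable to toy
  complex diameters so that prior draws cover distinct binding sites.
* Internal coordinates default to the rigid mode (the prediction keeps the
  input monomer conformation); a bounded per-residue deformation head
  (≤ ~3 Å) exists behind `readout = "rigid_deform"`, mirroring the
  observation that rigid-internal sampling dominates at this scale.
* PDB I/O is fixed-column, 3-decimal, one TER per chain, 1-based contiguous
  numbering; alternate locations, insertion codes and multi-model files are
  rejected loudly. Per-residue scalars ride in the B-factor column.

## Problem sizes used by the checks

The package's verification suite runs at desk scale, chosen once: geometry
and path algebra at $n \le 10^5$ samples; bootstrap calibration with 1,000
replicates of 180 Bernoulli targets at 10,000 resamples; and a
training-recovery study with 400 training and 50 held-out complexes (chains
16--24 residues), the default 4-block model at channel width 16 with 2
attention heads, the default 1700/400/400-step stage schedule, and 20
samples per held-out target with 2 integration steps at evaluation (the
open-gate denoiser does most of its work in the first call, so short grids
lose little; the sampling default elsewhere remains 10 steps). Channel
width, head count, stage lengths and the evaluation step count are the
package's toy-scale defaults; they keep a full train-and-evaluate cycle in
the tens of minutes on one CPU core while leaving the architecture (block
structure, feature set, flow) exactly as described above.

## Known limitations

* Rigid-internal sampling: the model does not explore subunit flexibility
  effectively; apo-like and predicted-like inputs carry their conformational
  error into the prediction. The deformation head is bounded and off by
  default.
* The confidence head shares the failure mode of sample-and-rank ranking
  generally: it can be overconfident on wrong poses; oracle success exceeds
  top-1 success.
* Bi-protein scope only; no tri-chain complexes, no heteroatoms, no mmCIF.
* The autodiff engine is single-threaded and dense; it is sized for
  $L \lesssim 100$ pairs, not for real protein lengths.
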