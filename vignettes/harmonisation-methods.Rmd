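---
title: "Cross-scanner diffusion MRI harmonisation: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-scanner diffusion MRI harmonisation: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Diffusion-weighted MRI (dMRI) signals measured on different scanners — or
with different protocols on the same scanner — are not directly
comparable: hardware (gradient strength, coils), sequence timing (TE/TR)
and reconstruction all imprint systematic differences on the signal, and
therefore on every quantity derived from it (diffusion-tensor metrics,
spherical-harmonic energies). *Harmonisation* learns a mapping that makes
data acquired under a "source" protocol statistically comparable to data
acquired under a "target" protocol. The gold-standard evaluation design is
a *travelling-subject* study: the same subjects are scanned everywhere, so
inter-scanner differences are not confounded by inter-subject variation.

`dwiharm` implements such a toolkit end to end:

* a real, even-order spherical-harmonic (SH) representation with
  Laplace–Beltrami (LB) regularisation (`sh_fit()`, `sh_resample()`);
* evaluation features: weighted-linear-least-squares (WLLS) diffusion
  tensor with FA and MD maps (`fit_wlls()`, `fa_map()`, `md_map()`), and
  the rotationally invariant SH energies R0 and R2 (`rish()`,
  `rish_maps()`);
* three harmonisers: a non-learning *reference* (trilinear + SH
  interpolation, `predict_reference()`), a sparse-dictionary-learning
  harmoniser (SDL; `sdl_train()`, `harmonise_matched()`,
  `harmonise_superres()`), and a voxel-wise SH network (`shnet_train()`,
  `shnet_harmonise_matched()`, `shnet_harmonise_superres()`);
* a three-scale evaluation protocol — global, regional, local — on
  ME/MNE/MSE errors with poor-region flagging
  (`evaluate_harmonisation()`, `flag_poor_regions()`);
* a synthetic travelling-subject phantom (`make_subject()`,
  `render_acquisition()`, `make_benchmark()`) so everything above is
  testable without access to restricted human data.

Two tasks are distinguished throughout, mirroring the standard benchmark
design: **matched-resolution scanner-to-scanner mapping** (same voxel size
and direction count on both sides) and **spatial/angular resolution
enhancement** ("super-resolution": predicting a finer-grid,
higher-angular-resolution acquisition from the standard one).

# The spherical-harmonic representation

Single-shell dMRI signals live on the sphere of gradient directions, with
antipodal symmetry ($S(g) = S(-g)$). We use the real, symmetric
(even-order) SH basis in the Descoteaux convention: for order $l$ and
$m<0$ the $\sqrt{2}$-scaled cosine harmonic, $m=0$ the zonal harmonic,
$m>0$ the $\sqrt{2}$-scaled sine harmonic; basis functions are ordered by
increasing $l$, then $m=-l,\dots,l$ (`sh_index_table()`). An order-$L$
truncation has $(L+1)(L+2)/2$ coefficients: 15 at order 4, 28 at order 6,
45 at order 8 (hence "29/46 channels" when a $b=0$ channel is appended).

Fitting solves a damped least-squares problem per voxel,

$$\hat c = (B^\top B + \lambda_{LB} L)^{-1} B^\top s,\qquad
L = \mathrm{diag}\,l^2(l+1)^2,$$

where $B$ is the basis evaluated at the scheme's directions and the
penalty spectrum $l^2(l+1)^2$ is the Laplace–Beltrami operator on SH. The
default weight $\lambda_{LB} = 0.006$ (unitless) is the value used
throughout the harmonisation literature this package follows; it
stabilises order-8 fits from 30 directions (45 unknowns, underdetermined
without regularisation — `sh_fit()` refuses $\lambda_{LB}=0$ there) and
barely perturbs well-determined fits. Signals are always divided by the
voxel's mean $b=0$ intensity before fitting; the SH field therefore
represents the normalised signal shape, and every harmoniser re-applies a
$b=0$ scale on output.

`hemisphere_dirs()` generates direction schemes by electrostatic-repulsion
descent with antipodal charge pairs from a seeded random start. The
construction is deterministic given the seed; different protocols use
different seeds so that angular resampling paths are genuinely exercised.

# Evaluation features

**WLLS tensor.** The diffusion tensor is estimated from
$\ln S = \ln S_0 - b\, g^\top D g$ by ordinary least squares on the
log-signal followed by one re-weighted pass with weights equal to the
squared predicted signals — the standard WLLS estimator (the single
re-weighting pass is configurable). Non-positive signals are clamped to a
small positive fraction of the voxel's maximum before the log (the count
is reported). FA and MD are computed from the eigenvalues, with negative
eigenvalues from noisy fits clamped to zero and FA clipped to $[0,1]$; a
zero tensor has FA defined as 0. $b=0$ volumes are included in the fit for
predicted stacks as for acquired ones (a switch exists).

**RISH.** The order-$l$ rotationally invariant SH energy is
$R_l = \sum_m c_{l,m}^2$ of the $b_0$-normalised signal's SH coefficients
— no $2l+1$ normalisation, matching the feature's original definition.
R0 captures isotropic signal magnitude, R2 angular contrast. Fits default
to order 4 with $\lambda_{LB}=0.006$; voxels whose mean $b=0$ signal is
below a small epsilon are excluded and counted.

# The three-scale error protocol

For each feature map (FA, MD, R0, R2), predicted vs acquired:

* per-voxel errors: ME $= p - a$ (signed accuracy), MNE $= (p-a)/a$
  (relative accuracy; voxels with $|a| < 10^{-6}$ in feature units are
  excluded and counted), MSE $= (p-a)^2$;
* **global**: the mean over the evaluation mask;
* **regional**: per-ROI mean within subject, then the median across
  subjects per ROI;
* **local**: means over sliding fully-in-mask $3^3$ neighbourhoods
  (stride 1), pooled across subjects and summarised by the median and the
  95th percentile (type-7, linear-interpolation quantiles).

Brain-edge voxels are removed by one 6-connected morphological erosion of
the mask (width configurable). An exclusion ledger accounts for every
masked voxel, so the evaluated set plus exclusions always sums to the full
mask.

**Poor-region flagging.** With several algorithms evaluated, a ROI is
flagged when its median MSE lies in the 90th percentile of its tissue
class (WM or GM separately) for at least 3 algorithms in at least one
feature. We evaluate "in the 90th percentile" strictly
(value $>$ threshold): with an inclusive rule a degenerate class in which
all ROIs tie would flag everything, which contradicts the rule's purpose
of isolating *systematically poor* regions. Tissue classes are supplied as
a two-column table (label → WM/GM); no parcellation is performed by this
package. Final comparisons can be restricted to WM with flagged ROIs
excluded, mirroring the restricted analysis the protocol prescribes.

# The reference predictor

The non-learning baseline resamples the $b_0$-normalised source signals
trilinearly at the target voxel centres (edge-value extension outside the
source box, counted in QC), fits SH at the source directions — order 6 for
matched-resolution targets, order 8 for the high-angular targets — and
evaluates at the target directions, re-scaling by the trilinearly
interpolated mean $b=0$. Operating on normalised signals makes the spatial
and angular steps commute with global gain. Because an order-8 fit from 30
directions is underdetermined, that path requires $\lambda_{LB}>0$
(default 0.006). The reference corrects geometry and sampling but not the
scanner effect — it is the floor every learning method must beat.

# The sparse-dictionary harmoniser (SDL)

**Patches and channels.** The harmoniser works on vectorised
spatio-angular patches $X_n \in \mathbb{R}^m$: a $3\times3\times3$ spatial
window by $k=5$ angular channels ($m=135$). Since raw direction schemes
differ across scanners, the 5 channels are the $b_0$-normalised signal
SH-resampled onto 5 fixed representative directions shared by all
acquisitions (`sdl_channel_dirs()`, a seeded electrostatic design). Images
are standardised per image and per channel (mean/SD over in-mask voxels)
before patch extraction; the model records the average target-image
statistics. At prediction the source is standardised with its *own*
statistics and reconstructions are un-standardised with the *target*
statistics — this is what maps per-channel offsets and gains between
scanners, and it is why a pure intensity offset between scanners is
removed exactly.

**Dictionary learning.** The model is an over-complete dictionary
$D \in \mathbb{R}^{m \times p}$, $p = 2m$, with unit-norm atoms and
non-negative sparse codes, minimising
$\sum_n \|X_n - D\alpha_n\|_2^2 + \lambda\|\alpha_n\|_1$ s.t.
$\|d_j\|_2 = 1,\ \alpha \ge 0$. Optimisation alternates a code step
(non-negative lasso by cyclic coordinate descent with an active-set
strategy; C++ inner loop) and a dictionary step, for a default of 1000
iterations on random batches of 128 patches, initialised from randomly
drawn patches. Design choices worth recording:

* *Mini-batch dictionary step*: blockwise-optimal unit-norm column
  updates driven by accumulated sufficient statistics
  ($A=\sum\alpha\alpha^\top$, $B=\sum X\alpha^\top$, exponential
  forgetting 0.98), the online dictionary-learning scheme. The statistics
  are accumulated from *support-refitted* (debiased) codes — non-negative
  least squares restricted to the lasso support — so atom directions are
  not dragged toward zero by the $\ell_1$ shrinkage.
* *Exploration vs stabilisation*: during the first 75% of iterations,
  unused atoms and near-duplicate atoms (|correlation| > 0.99, checked
  every 5 iterations) are re-seeded from the worst-reconstructed patches
  of the current batch and their statistics reset; the final quarter runs
  with plain accumulation and no replacement so the dictionary settles.
* *Full-batch mode* (`batch = N`) switches to exact alternating
  minimisation with warm-started codes, which makes the objective provably
  non-increasing across alternations — used by the tests as an oracle
  property.
* *$\lambda$ selection*: grid search scored by
  $\mathrm{AIC} = Nm\,\ln(\mathrm{RSS}/(Nm)) + 2\,\mathrm{nnz}$ — a
  Gaussian log-likelihood with the number of non-zero code entries as the
  degrees of freedom (the likelihood form is the natural choice for a
  squared-error model; nothing else is printed in the source literature).
  Ties break toward the larger (sparser) $\lambda$; an RSS of exactly 0
  returns the largest $\lambda$ achieving it.

**Matched-resolution prediction.** Source patches are coded on the target
dictionary and reconstructed as $D\alpha$; overlapping patch predictions
are averaged per voxel. The corrected 5-channel values then update the
source's order-4 SH field by the *minimum-norm coefficient update*
$c' = c + B^\top(BB^\top)^{-1}(y - Bc)$ (with $B$ the basis at the channel
directions), i.e. the smallest coefficient change consistent with the
predicted channels; the updated field is resampled at the target
directions and re-scaled by the source mean $b=0$. Voxels covered by no
complete patch fall back to the channel-statistics mapping alone (counted
in QC). The minimum-norm closure is this package's answer to an
under-specified step — 5 channel values cannot determine 15 coefficients,
and the update uses the source's angular detail everywhere the dictionary
is silent.

**Super-resolution.** The dictionary is learned on high-resolution target
patches ($6^3$ spatial, the low-resolution $3^3$ patch times the
resolution factor 2; incompatible size pairs are refused). Codes for a
source patch are computed on the *block-average-downsampled* dictionary
$PD$ and the reconstruction uses the original $D$, yielding
high-resolution patches that are overlap-averaged on the upsampled grid.
Direction matching again goes through the truncated SH basis: the source
SH field is trilinearly upsampled, min-norm-updated to the predicted
channels, and resampled at the target directions.

# The voxel-wise SH network (SHNet)

**Architecture** (fixed): BatchNorm → FC(15→150)+ReLU → BatchNorm →
FC(150→150)+ReLU → BatchNorm → FC(150→150)+ReLU → BatchNorm → FC(150→15),
operating on order-4 SH coefficient vectors of $b_0$-normalised signals
($\lambda_{LB}=0.006$), voxels restricted to the brain mask. The loss is
the mean squared coefficient error, equally weighted — the natural match
to the evaluation family. Input and target coefficients are z-scored with
training-set statistics recorded in the model (the network trains in
standardised space; predictions are un-standardised).

**Training schedule** (fixed where published, chosen where not): Adam
(lr 0.001, batch 128) for the first five epochs, then plain SGD; the
learning rate is multiplied by 0.9 when the validation loss fails to
improve by at least 0.1% for more than five consecutive epochs (with
cool-down after each decay). Nine of ten training subjects train the
weights; the tenth is the validation subject, and the best-validation
weights are deployed. Published sources name the optimiser switch but no
SGD hyper-parameters; we use lr 0.1 with heavy-ball momentum 0.9, which a
batch-normalised network tolerates and needs — Adam's 0.001 is far too
small a step for plain SGD on this loss surface.

Three deterministic post-processing steps address a structural property of
BatchNorm training that matters at this package's precision targets:
training-mode BN uses *batch* statistics (noisy at batch 128, width 150)
while prediction uses *population* statistics, so the stochastically
trained weights are biased away from the population-statistics optimum.

1. *Exact BN recalibration*: population means/variances are recomputed
   over the full training set with frozen weights (the EMA running
   estimates are themselves noisy).
2. *Frozen-BN fine-tuning*: with BN statistics frozen, the deployed
   function is an ordinary smooth MLP; a short full-batch L-BFGS phase
   (validated between chunks, best kept) optimises exactly the function
   that will be used at prediction.
3. *Readout refit*: the final linear layer is re-solved in closed form by
   least squares on the training set — one exact block-coordinate step.

All three optimise the same training objective on the same data; they
remove optimisation noise, not add capacity. Training is bit-reproducible
given the seed (a package-internal Lehmer RNG drives initialisation and
shuffling, leaving R's global RNG untouched).

**Prediction.** Matched: per-voxel SH vectors are mapped by the network,
resampled at the target directions, and re-scaled by the source mean
$b=0$ (the network predicts normalised signal shape only; FA/MD/RISH are
invariant to that scale). Super-resolution: coefficient channels and the
mean $b=0$ map are interpolated by separable cubic convolution
(Catmull–Rom, $a=-0.5$) onto the target grid before the voxel-wise map.
BatchNorm runs in population-statistics mode at prediction, making
prediction purely voxel-wise and permutation-equivariant.

# The synthetic phantom

`make_subject()` builds a spherical "brain" on a high-resolution grid
(default $24^3$ at 1.2 mm): a CSF core (isotropic,
$3.0\times10^{-3}$ mm²/s), a WM shell with single-fibre sectors (along x
or y; axial/radial diffusivities $1.7/0.3\times10^{-3}$) and
crossing-fibre wedges (two populations at 90°), and a GM rim (90%
isotropic at $0.8\times10^{-3}$). Mixture fractions sum to one per voxel;
each subject's seed jitters radii, diffusivities and fractions by a few
percent. The layout deliberately contains single-fibre, crossing and
isotropic regions plus sharp WM/GM edges, because anisotropy features (FA,
R2) fail precisely at such edges. Nine ROI labels (1 CSF, 4 WM, 4 GM) and
a label→tissue-class table support the regional protocol.

`render_acquisition()` computes the noise-free multi-tensor signal
$S = S_0\sum_i f_i e^{-b\,g^\top D_i g}$, applies the **scanner effect in
SH space** — per-order attenuation $(a_0, a_2, a_4)$ of the normalised
signal, then a global gain, then an optional Gaussian blur — samples the
protocol's direction set, block-averages to the protocol grid (2.4 mm
standard, 1.2 mm high-resolution), and adds Rician noise: each measurement
becomes $|(S+n_1, n_2)|$ with $\sigma = S_{0,\mathrm{ref}}/\mathrm{SNR}$
(default SNR 30; magnitude data is Rician, not Gaussian). Per-order
attenuation plus gain is the *minimal* effect family that shifts all four
evaluation features between scanners; the default target effect is gain
1.05 with $(a_0,a_2,a_4) = (0.95, 0.80, 0.70)$. The manifest of a
generated benchmark records every seed and effect parameter, so the
ground-truth transform is explicit — `apply_scanner_effect()` /
`invert_scanner_effect()` implement the oracle harmoniser whose residual
(noise + SH truncation) lower-bounds every learned method — and
regeneration from the manifest is bit-identical.

The default benchmark is 14 subjects (10 train / 4 test) with one source
protocol (30 directions, 2.4 mm, unit effect) and two targets
(matched-resolution 30-direction, and 60-direction 1.2 mm, both with the
non-trivial effect), all at $b = 1200$ s/mm² with one $b=0$ volume.

**Two oracles.** `apply_scanner_effect()` / `invert_scanner_effect()`
apply the recorded transform to *measured* (noisy) data — useful for
verifying that the transform is recoverable. The `"oracle"` method of
`run_benchmark()` is the *noise floor*: the ground-truth transform applied
to the noise-free signal (a noise-free rendering of the target protocol).
The distinction matters for squared-energy features such as R0: input
noise inflates the noisy-input oracle's error by an independent variance
term that a learned conditional-mean predictor does not pay, so only the
noise-free-truth oracle is a genuine lower bound. Every predictor's error
then decomposes into method error plus this floor.

**What the phantom does and does not emulate.** It reproduces the
*structure* of a travelling-subject study — per-subject anatomy, protocol
grids and schemes, a systematic inter-scanner transform, magnitude noise —
at desk scale. It does not contain realistic head anatomy, spatially
varying scanner effects, registration error, eddy/EPI distortion or
multi-shell data. Passing tests therefore demonstrate correctness of the
algorithms and the recoverability of a known transform, not clinical
performance on real scanners; the real inter-scanner transform is unknown
and possibly spatially varying, which the manifest makes explicit rather
than claiming realism.

# Problem sizes used in tests and the acceptance script

The bundled analyses run the full pipeline at reduced scale, chosen so a
laptop core reproduces them in minutes: anatomy $24^3$ at 1.2 mm (matched
protocols at $12^3$, 2.4 mm), 14 subjects, SNR 30; SDL with $m=135$,
$p=270$, batch 128 (1000 iterations for the benchmark, 200 for the
generative-recovery check, which uses about 90 patches per atom); the
network trained on all in-mask voxels of the ten training subjects
(~5,600) for up to 40 epochs, with the deterministic fine-tuning phase
capped at 4,000 rows. The dictionary-recovery check codes with a small $\lambda$
($10^{-3}$) plus support refit, since reconstruction — not sparsity — is
what it measures. These sizes are statements of the reproducible study
design, and the vignette's numbers are whatever the tests and
`scripts/acceptance.R` actually compute at those sizes.

# Numerical choices and degenerate inputs

* $b=0$ identification: b-values below 50 s/mm² count as $b=0$
  (configurable); gradient vectors for such volumes may be zero.
* Voxels are 0-based in continuous coordinates (0 = first voxel centre);
  world coordinates go through the stored affine; no reorientation is
  performed — inputs are assumed co-registered.
* Trilinear/tricubic sampling outside the source volume clamps to edge
  values and reports the count.
* MNE denominators below $10^{-6}$, mean-$b_0$ below $10^{-8}$, and
  non-positive signals before a log are excluded/clamped and always
  counted in QC fields.
* Coordinate descent stops at relative change $10^{-7}$ or 200 sweeps;
  ties in AIC break toward sparsity; quantiles are type 7 throughout.
* All stochastic components (direction design, phantom, dictionary
  batches, network shuffling) draw from explicit integer seeds through a
  package-internal generator, so no call disturbs R's global RNG state
  and every run is reproducible.

# Known limitations

* Single-shell only; multi-shell joint bases and higher-order RISH (R4+)
  are out of scope.
* Held-out precision of the voxel-wise network is bounded at desk scale
  by a subject-level distribution gap, not by optimisation: with the
  bundled phantom the network fits the training subjects' identity map to
  well under 0.1% of the coefficient variance, but a held-out subject's
  coefficient distribution differs enough (anatomy jitter, independent
  noise) that its error settles near 0.2–0.3% and does not shrink with
  more training voxels. Studies with realistic voxel counts and more
  subjects sit in a different regime; the tests report the desk-scale
  numbers as they are.
* The SDL channel definition (5 fixed directions) and the min-norm SH
  closure are this package's documented choices for steps the method
  family leaves unspecified; alternatives (more channels, paired
  dictionaries) are exposed as configuration or extension points.
* The SHNet family's convolutional relatives (residual, spherical and
  fully convolutional variants) are documented extension points, not
  implementations; `run_benchmark()`'s method registry is where such
  harmonisers would plug in.
* Preprocessing (motion/eddy/susceptibility correction, registration,
  parcellation) is consumed, never performed.
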