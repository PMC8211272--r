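---
title: "Learnable divisive normalization encoding models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learnable divisive normalization encoding models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnv1)
```

# The model

`dnv1` fits image-computable encoding models of V1 spiking activity in which
divisive normalization (DN) is not assumed but *learned*. The response of
model channel $l$ at each feature-map location is

$$
z_l(x) \;=\; \frac{y_l^{n_l}(x)}{\sigma_l^{n_l} + \sum_k p_{kl}\,
\langle y_k^{n_k}(x)\rangle},
$$

where $y_l = \mathrm{ReLU}(\mathrm{BN}^*(w_l \ast x))$ are the driving
inputs of a bank of 32 convolutional subunit filters (13 px, applied to
40 px stimuli sampled at 35 px/degree), $n_l \ge 0$ are learned exponents,
$\sigma_l \ge 0$ semi-saturation constants, and $p_{kl} \ge 0$ the
normalization pool weights that say how strongly channel $k$ suppresses
channel $l$. $\langle\cdot\rangle$ is 5 px spatial average pooling of the
exponentiated drive, which grants the normalization signal approximate
phase invariance without requiring many filters per orientation.
$\mathrm{BN}^*$ is batch normalization without a learned scale (bias only);
because scaling the drive by $\beta$ while scaling $\sigma_l$ accordingly
leaves $z$ unchanged, the standardization does not restrict the computation
— the package verifies this scale-equivalence property in its test suite.

Per-neuron predictions come from a factorized, non-negative readout
$g_i = \sum_{u,v,l} a_{uv,i}\, b_{l,i}\, z_{uvl} + q_i$ followed by a
learnable output nonlinearity $\hat r_i = h_i(g_i)\,\mathrm{ELU}^*(g_i)$,
with $\mathrm{ELU}^*$ the shifted exponential-linear function (identity
above 1) and $h_i$ a positive piecewise-exponential correction parameterized
on a tent basis (51 points on $[-3, 6]$, spacing 0.18). Because $a, b \ge 0$
the readout is monotone: all suppression must be produced by the DN core,
which is what makes the fitted $p_{kl}$ interpretable.

Four core variants share this skeleton: the **subunit** baseline (identity
instead of DN — an LN-LN model), the full feature-specific **dn** model,
**dn_nonspecific** (all incoming weights of a channel constrained equal, the
classical nonspecific pool), and **dn_extended**, which replaces the scalar
weights by a dilated spatial convolution
$p_{kl}\to p_{kluv} = \sum_{m=1}^2 c_{luv,m} d_{kl,m}$ (dilation 5, kernel
1–7) so the pool can reach into the receptive-field surround. With a 1×1
kernel the extended model reduces exactly to the center model — a reduction
the tests assert to machine precision.

# Training objective

Spike counts are modeled as Poisson; training minimizes

$$
\mathcal{L} = \sum_{i,j}\big(\hat r_{ij} - r_{ij}\ln \hat r_{ij}\big)
 + \lambda_{\text{smooth}} \sum_{uvk} (L \ast w_k)^2_{uv}
 + \lambda_{\text{sparse}} \sum_i \lVert a_i\rVert_1 \lVert b_i\rVert_1
 + \lambda_{\text{out}} \,\mathcal{L}_{\text{out}}(\alpha),
$$

with $L$ a fixed 3×3 Laplace filter and $\mathcal{L}_{\text{out}}$ the mean
squared first and second finite differences of the tent coefficients
(pushing $h_i$ toward the identity). Optimization uses Adam at learning rate
$10^{-3}$, mini-batches of 256 image–trial samples, validation Poisson loss
evaluated every 100 steps, learning rate divided by 3 after 10 non-improving
evaluations, four decays, then stop; the best-on-validation parameters are
returned. Non-negativity of $n, \sigma, p, c, d, a, b$ is enforced by
projection (clipping at zero) after every step, which preserves exact zeros.
Regularizer weights are searched log-uniformly:
$\lambda_{\text{smooth}} \in [10^{-9}, 10^{-3.5}]$,
$\lambda_{\text{sparse}} \in [10^{-9}, 10^{-4.5}]$, and
$\lambda_{\text{out}} \in [10^{-8}, 10^{2}]$ for the center DN and subunit
models or $[10^{-5}, 10^{0}]$ for the nonspecific and extended ones.

All gradients are derived analytically and implemented by hand
(`R/gradients.R`); convolution is im2col plus BLAS, pooling a cached sparse
operator. The test suite checks every parameter group of every variant
against central finite differences at $10^{-4}$ relative tolerance. Two
numerical choices matter at $y = 0$: the forward pass uses exact powers
$y^n$, while gradient terms use $\log(y + 10^{-6})$ and
$\max(y, 10^{-6})^{n-1}$ so derivatives stay finite at the rectifier's
kink. Predictions are floored at $10^{-8}$ inside the Poisson logarithm.

## Early stopping versus model selection

Early stopping monitors the validation *Poisson loss* (the quantity the
schedule is defined on), whereas model selection across fits ranks by
validation *accuracy* (average correlation / FEV). These two uses of the
validation set are deliberately kept distinct in `train()` and
`select_top_models()`; conflating them changes neither code path but is a
common source of confusion when comparing training traces.

# Accuracy metrics

With repeated trials, the observation-noise variance
$\sigma^2_{\text{noise}}$ is the across-trial variance averaged over images
(unbiased $n-1$ estimator within images), the explainable variance is
$\mathrm{Var}[r] - \sigma^2_{\text{noise}}$, and model accuracy is the
fraction of explainable variance explained,
$\mathrm{FEV} = 1 - (\overline{(r-\hat r)^2} - \sigma^2_{\text{noise}})/
\mathrm{Var}_{\text{exp}}$, averaged over neurons. The residual is computed
against per-trial observations with $1/N$ normalization — that convention
makes the noise correction exact in expectation. One consequence the tests
document: a grand-mean predictor scores FEV $\approx 0$ rather than exactly
0, because total variance uses the $n-1$ estimator while the residual uses
$1/N$; the gap vanishes as $1/N$. Neurons with explainable-to-total variance
ratio below 0.15 are excluded by `filter_neurons()`, mirroring the
recordings' inclusion rule. `avg_correlation()` assigns constant predictions
a correlation of zero before averaging.

# The synthetic data conditions

Because the macaque recordings are not redistributable, every claim the
package tests is grounded in a synthetic population whose ground truth is a
known DN model (`synthetic_config()` defaults):

* **Stimuli**: 40×40 px, pooled zero mean/unit variance; pink-noise
  (1/f²-power) background mixed with 1–3 oriented Gabor patches per image
  (`texture_mix`). Natural images drive V1 through their oriented content;
  isotropic noise alone would leave orientation-specific normalization
  nearly unidentifiable. An optional cosine aperture (1° inner diameter)
  emulates the display mask.
* **Ground truth core**: 16 channels of unit-norm 13 px Gabor filters in
  quadrature pairs spanning 8 distinct orientations (drawn uniformly at
  random — an evenly gridded bank would park many filter pairs exactly on
  the 45° similar/dissimilar boundary), exponents 2, $\sigma = 1$, and
  planted weights $p_{kl} \propto \exp(\kappa \cos 2\Delta\theta_{kl})$
  normalized so column sums are ~1 (denominators stay O(1)). $\kappa = 1$
  gives orientation-specific normalization; $\kappa = 0$ the nonspecific
  control.
* **Readout**: one-hot spatial location per neuron, 1–3 positive feature
  weights — the structure the readout priors assume.
* **Firing statistics**: per-neuron gain and baseline are calibrated on a
  probe set so mean counts sit near 2 (0.5–10 regime) and the
  explainable-to-total variance ratio falls in 0.18–0.39 (population mean
  near the recordings' 0.285). Trial noise is Poisson (2–4 repeats;
  over-dispersion is deliberately absent because the likelihood is Poisson).
* **Splits**: image-level 64/16/20 train/validation/test by seeded shuffle.

What passing tests on these populations shows: the estimator pipeline is
correct, normalization weights are identifiable from spike counts at
realistic noise levels, and the in-silico indices discriminate DN from
subunit computation. What they cannot show: that real V1 data are fit at
full-recording-scale accuracies, which depend on the recordings themselves.

Desk-scale problem sizes used throughout the tests and acceptance script —
16 channels, 2 000–4 000 images, 20 neurons, 2 000 training steps for the
recovery experiments, reduced in-silico grids — were chosen as the
package's default simulation conditions;
the full-scale settings (32 channels, per-pixel search grids with 73.7 M
stimuli) remain available through the same configuration objects.

# What the recovery experiments can and cannot show

The package's central validation is a parameter-recovery experiment:
simulate 20 neurons (2 trials, 4 000 images) from a known
orientation-specific ground truth ($\kappa = 1$), refit with the subunit
filters frozen, and compare the fitted normalization weights and
normalization-input structure with the planted ones. Three facts about this
experiment, established with the package itself, matter for interpreting
its results:

1. **The output nonlinearity is partially degenerate with the divisive
   stage.** At a single readout location, the denominator's pooled energy
   correlates strongly with the unit's own drive, so a compressive static
   output function (or a per-channel exponent below 1) can mimic much of
   the normalization. In a fully free fit the tent-basis coefficients
   absorb divisive structure and the recovered weights decorrelate from the
   truth; fixing the output nonlinearity's penalty at the top of its search
   interval ($\lambda_{\text{out}} = 100$, which pins $h$ to a near-pure
   gain) substantially improves recovery, and freezing the readout and
   output nonlinearity at the ground truth improves it further. The
   recovery configuration therefore uses $\lambda_{\text{out}} = 100$ with
   `min_delta = 1e-4` so the learning-rate schedule cycles.
2. **Recovery at these conditions is information-limited, not
   optimization-limited.** With everything but the DN parameters pinned at
   the truth, the fitted weights plateau at a Pearson correlation of about
   0.65 with the planted matrix, unchanged between 5 000 and 10 000
   training steps with the exponents and semi-saturation constants
   recovered essentially exactly (n 1.99 vs 2, sigma 1.00 vs 1). The
   residual error concentrates in per-column scales (softly identified
   against the per-channel semi-saturation constants) and in the split of
   weight between quadrature-pair filters, whose pooled energies are
   nearly identical by design of the phase-invariant pooling.
3. **Structure-level recovery is asymmetric.** The
   similar-versus-dissimilar normalization-input ratio of the fitted model
   is well above 1 for the $\kappa = 1$ ground truth — the planted
   orientation specificity is clearly detected. The nonspecific
   ($\kappa = 0$) control, measured through the identical pipeline, scores
   0.997 for the *true* model but the *fitted* model overshoots (ratio
   near 1.5, stable across training lengths): when the exponents are
   mis-estimated, the residual mismatch loads onto normalization sources
   whose drives correlate with the target's own, and those are the
   similarly oriented ones. At this population size the free fit therefore
   has a positive specificity bias; distinguishing genuinely specific from
   nonspecific normalization at desk scale requires comparing fitted
   ratios across the two regimes (3.2 versus 1.5 here), not reading either
   in isolation.

At full recording scale (166 neurons, 7 250 images, 2–4 trials) the
corresponding weight-level recovery would be better-determined; the
desk-scale population here deliberately keeps every experiment runnable in
minutes on one CPU.

# In-silico experiments

`find_optimal_gabor()` scans an exhaustive parameter grid (centers,
12 orientations, 8 phases, log-spaced sizes 4–40 px, frequencies, contrasts
up to amplitude 2.52 — the intensity range seen in training) and keeps, per
unit, the argmax of the prediction with a deterministic first-in-grid-order
tie-break. Cross-orientation inhibition superimposes the optimal Gabor with
a 90°-rotated mask over a contrast lattice topping at half maximum contrast
(so plaids stay in range), phase-averages over 8 mask phases, and reports
$\mathrm{COI}(c_i, c_j) = 1 - \hat r(c_i, c_j)/\hat r(0, c_j)$; units with
max COI ≥ 10% count as cross-orientation inhibited. Size tuning presents
hard-edged circular gratings (diameters up to 120 px = 3.43°) at the optimal
parameters and single optimal phase, and the suppression index is
$\mathrm{SI} = 1 - \hat r_{\text{supp}}/\hat r_{\text{max}}$.

Two behaviors of the center model deserve note. First, a hand-built model
with strong cross-channel weights shows max COI far above the 10% criterion
while its subunit twin (identical filters and readout, no DN) shows
essentially none — the discriminating phenomenon. Second, a center-only DN
model *cannot* respond to anything beyond its denominator's 0.49° input
coverage, so its size-tuning curves are exactly flat beyond that diameter
(asserted to numerical precision); the Cavanaugh-style SI can still be
slightly positive because the hard-edged disc transiently boosts responses
when the edge crosses the receptive field, so population mean SI is compared
against the same 10% cutoff that defines a suppressed cell, not against
exact zero.

## Stimulus conventions

Orientation $\varphi$ is the carrier wave-vector angle, counterclockwise
from the positive row axis, so "orthogonal" means $\varphi + \pi/2$; pixels
are sampled at integer centers with the origin at top left; Gabor size is
the ±2 SD envelope extent and frequency counts cycles per four envelope SDs.
One identity worth recording: rotating the wave vector by $\pi$ *and
negating the phase* reproduces the same image ($\cos$ is even); rotating by
$\pi$ while shifting the phase by $\pi$ does not, except at special phases.

# Normalization-structure analysis

Filter orientation is estimated from the 2D power spectrum: each 13 px
kernel is windowed with a centered Gaussian (SD 3 px), mean-subtracted and
scaled to unit norm (so the selectivity measure is comparable across
filters), zero-padded to 64×64, and summarized by the mean resultant vector
$m = \sum_R F_{uv} e^{2i\phi}/\sum_R F_{uv}$ over the annulus
$0.3 < \sqrt{u^2+v^2} < 0.7$ in Nyquist units (strict inequalities, as
printed). $|m| \ge 0.125$ flags a filter as oriented; the preferred
orientation is $\arg(m)/2 \bmod \pi$. The normalization-input matrix
averages $p_{kl}\langle y_k^{n_k}\rangle$ — the *pooled* quantity that
actually enters the denominator — over images and locations; a flag exposes
the unpooled variant for sensitivity checks. Splits (< 45° vs ≥ 45°
orientation difference), 10°-wide bins on [0°, 90°], and the cosine-
similarity split (> 0 vs < 0, exact zeros counted separately) quantify
orientation specificity; unoriented filters stay in the matrix but are
excluded from orientation splits. The readout-contribution control
normalizes each neuron's feature weights to unit sum (removing the $a/b$
scaling degeneracy) and reports the coefficient of variation (population SD
over mean) of the pooled channel averages; a one-hot concentration gives
the closed form $\sqrt{C-1}$.

# Other design choices and degenerate inputs

* **Pooling boundary**: stride-1 zero-padded "same" pooling with fixed
  divisor 25, so the denominator aligns with the 28×28 numerator; border
  pixels are under-pooled and oracle tests therefore pin down interior
  pixels exactly.
* **BN\***: standardization with variance epsilon $10^{-4}$; running
  statistics by exponential moving average (momentum 0.9) initialized from
  the first batch; the bias is added after standardization.
* **$h$ outside the tent grid**: $g$ is clamped to $[-3, 6]$ before
  evaluating $h$, so extreme activations follow the boundary value of $h$
  instead of collapsing the prediction to zero.
* **Output-penalty boundary**: first differences run over $j \ge 2$, second
  differences over $2 \le j \le N-1$; a constant $\alpha$ scores exactly 0.
* **Degenerate inputs**: non-finite stimuli, eval-mode BN without
  initialized statistics, $\sigma = 0$ with an empty pool, even crop
  residuals in the extended model, and single-trial neurons in the noise
  estimator are all rejected with explicit errors rather than propagating
  NaNs; silent units yield `NA` indices and are masked from summaries.
* **Weight initialization**: filters from a truncated normal (SD 0.01),
  $p$ uniform on $[0, 0.01]$, $\sigma = n = 1$, small positive uniform
  readout weights, $\alpha = 0$.

# Known limitations

Pure-R training is practical at the desk scale the package targets
(hundreds of milliseconds per step at 16 channels) but not at the full
32-channel, thousand-run hyperparameter campaigns at full recording scale;
the configuration objects support those sizes, the wall-clock does not.
The synthetic generator emulates second-order image statistics and planted
normalization structure, not natural-image content; absolute FEV values on
synthetic populations are therefore not comparable to values on real
recordings. The Poisson likelihood ignores the over-dispersion real neurons
show; `simulate_population()` accepts externally supplied rates if
robustness to that assumption is being probed.
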