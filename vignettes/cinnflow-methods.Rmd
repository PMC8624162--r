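---
title: "Conditional invertible networks for imaging inverse problems: models and methods"
author: "cinnflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional invertible networks for imaging inverse problems: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The statistical model

An imaging inverse problem observes noisy linear measurements
$y^\delta = A x^\dagger + \epsilon$ of an unknown image $x^\dagger$.
Point reconstructions discard the uncertainty that matters most when
the problem is ill-posed, so `cinnflow` instead learns the full
posterior $p(x \mid y^\delta)$ with a *conditional normalizing flow*: an
invertible map $T_\theta(\,\cdot\,; y)$ from a simple base density
$p_z$ to image space, conditioned on features of the measurements. The
change-of-variables formula gives the exact model density

$$
p_\theta(x \mid y) \;=\; p_z\!\big(T_\theta^{-1}(x; y)\big)\,
\big|\det J_{T_\theta^{-1}}(x; y)\big|,
$$

which is trained by maximizing the exact log-likelihood of paired
$(x, y)$ data — no adversarial game, no variational bound. Posterior
moments follow by Monte Carlo: draw $z_i \sim p_z$, map
$x_i = T_\theta(z_i; y)$, and report the pixelwise sample mean
(reconstruction) and standard deviation (uncertainty map). Following
the printed estimator, the variance uses the divisor-$N$ (biased) form.

# Invertible building blocks

Every layer returns its output together with its exact per-sample
log-Jacobian-determinant; the composed log-determinant is the sum over
layers, and it is always accumulated in double precision.

* **Coupling layers** split the channels into $(c_1, c_2)$ with
  $c_1 = \lceil c/2 \rceil$ (first channels form the untouched group —
  a deterministic convention shared with common flow implementations).
  Additive couplings translate the second group by a subnetwork of the
  first and have unit Jacobian determinant. Affine couplings also
  rescale, $y_2 = x_2 \odot e^{s} + t$, with log-determinant
  $\sum_i s_i$. Conditional couplings concatenate conditioning features
  to the subnetwork input.
* **Scale clamping.** Unbounded log-scales make the inverse pass
  numerically explosive. The raw scale passes through
  $s = \gamma \tanh(\hat s/\gamma)$ with $\gamma = 2$ by default,
  bounding every singular value of the coupling in
  $[e^{-\gamma}, e^{\gamma}]$ while keeping the log-determinant exact.
  The forward pass reports the largest $|s|$ seen (`max_log_scale`) as
  a stability monitor; it is identically zero for additive couplings.
* **Coupling subnetworks** are 3-layer convolutions (kernel 3, hidden
  width 64 by default, leaky-ReLU) with a zero-initialized final layer,
  so every coupling starts as the identity and early training is
  stable. The initialization scheme is the package's own choice.
* **Channel mixing** after every coupling uses a fixed random
  orthogonal matrix (a fixed $1\times 1$ convolution, $|\det Q| = 1$);
  a plain random permutation is available as an ablation switch. The
  matrices are frozen at initialization and never trained.
* **Invertible downsampling**: checkerboard (space-to-depth, a pure
  permutation) or the orthonormal 2-D Haar transform (average /
  horizontal / vertical / diagonal per $2\times2$ block). Both map
  $(c, h, w) \to (4c, h/2, w/2)$ with zero log-determinant. Odd spatial
  sizes are rejected, never padded silently — invertibility must be
  exact; `pad_to_multiple()` is the explicit utility for callers.

# Base distributions

Two latent densities over $\mathbb{R}^n$ are provided:

* the standard normal,
  $\log p_z(z) = -\tfrac12\|z\|^2 - \tfrac n2 \log 2\pi$;
* a **radial Gaussian** whose radius is half-normal ($r = |\hat r|$,
  $\hat r \sim N(0,1)$) and whose direction is uniform on the sphere:
  $$
  \log p_z(z) = \log\frac{2}{\sqrt{2\pi}\,S_n}
  - (n-1)\log\|z\| - \tfrac12\|z\|^2,
  \qquad S_n = \frac{2\pi^{n/2}}{\Gamma(n/2)}.
  $$
  In high dimension the standard normal's density mode sits far from
  its typical set; the radial density concentrates where its samples
  actually live, which can improve single-sample reconstruction
  quality.

The normalization constant above is re-derived from the half-normal
radius law divided by the sphere area element $r^{n-1} S_n$, and the
test suite confirms by quadrature that the density integrates to one
for $n \in \{1,2,3\}$; for $n = 1$ it coincides with the standard
normal exactly. Log-densities are always reported fully normalized —
nothing constant is dropped — so validation NLLs are comparable across
base distributions. For $n \ge 2$ the density is singular at the
origin: evaluation at $\|z\| = 0$ raises an error rather than clamping,
because a silent clamp would corrupt the likelihood bookkeeping.
$S_n$ is computed in log space to avoid overflow at large $n$.

# Conditioning

The conditioning network never needs to be invertible. Because CNNs
exploit local structure while CT sinograms and MRI k-space encode
global relationships, measurements first pass through a **model-based
inversion layer** $A^\dagger$ into image space:

* Moore–Penrose pseudo-inverse (dense operators; equals the adjoint
  for the orthonormal masked Fourier operator),
* TV-regularized inverse
  $(A^TA + \lambda_{\mathrm{tv}} \nabla^T\nabla)^{-1}A^T$ with
  $\lambda_{\mathrm{tv}} = 0.02$ by default; $\nabla$ is the discrete
  forward-difference gradient with zero-flux boundaries, which keeps
  $\nabla^T\nabla$ symmetric positive semidefinite,
* filtered back-projection with the Ram-Lak filter (discrete
  band-limited ramp, optional frequency cutoff),
* zero-filled inverse FFT (magnitude image; the magnitude is the
  package's choice for handling the complex output of non-Hermitian
  masking, and it is positively homogeneous rather than fully linear).

A feature network then produces one array per flow scale with halving
spatial sizes. Four variants of strictly increasing capacity:
`avg_pool` (one learned convolution + average pooling), `cnn` (a small
fully convolutional stack + pooling), `resnet` (residual blocks with
strided convolutions in place of pooling; widths double per scale,
capped at 256), and `unet` (encoder-decoder whose per-scale encoder and
decoder activations feed the invertible UNet's two paths, with a
zero-initialized head producing an image-space output). The head
enables the optional conditional loss
$-\log p_\theta(x|y) + \alpha\,\mathrm{MSE}(H(y), x)$ with
$\alpha = 1$ as the ablation default. Conditioning is trained jointly
with the flow by default; a freeze flag supports pre-trained
conditioning networks.

# Architectures

**Multi-scale flow.** Per scale: coupling block → downsampling →
coupling block → split, with half the channels exiting to the latent
output at each scale and the final scale being a coupling block. The
split-off proportion (one half) is the standard Real-NVP convention;
couplings before a downsampling consume the conditioning features of
their resolution, couplings after it the next scale's features.

**Invertible UNet.** The down path applies coupling → downsampling →
split per scale, stashing half the channels at each coarse resolution;
after the coarsest coupling block, the up path re-concatenates each
stash, upsamples invertibly and applies couplings, so the latent lives
at the input resolution. With the down-path order as stated, the stash
lives at the coarse resolution, and channel counts only close if the
deep output and the stash are concatenated *before* the invertible
upsampling; the package therefore implements the up step as
concat → upsample → coupling, preserving the step-by-step
re-concatenation of the splits. Additive couplings are the default for
this architecture — affine invertible UNets are prone to the
"exploding inverse" failure at test time — while the multi-scale
default is affine.

**Single-channel inputs** cannot be channel-split, so coupling blocks
are skipped wherever only one channel is present (before the first
downsampling, and at the full-resolution end of the invertible UNet's
up path). The transformation there is carried by the downsampled
scales.

**Latent serialization.** Latent chunks serialize in scale order, each
chunk in R's native column-major layout — deterministic and
reproducible across runs, which is what sampling with fixed seeds
requires.

Checkpoints are single versioned JSON files (configuration plus all
weights at full precision); models are rebuilt from the configuration
(mixing matrices reproduced from stored seeds) and weights injected.

# Training

All layers have hand-derived analytic backward passes, verified
end-to-end against finite differences in the test suite; no
automatic-differentiation framework is involved. Optimization is Adam
at learning rate $10^{-4}$ by default (the benchmarks below use larger
rates suited to their tiny models), with the learning rate multiplied
by 0.8 when the validation NLL fails to improve for 5 validation
rounds (floor $10^{-6}$); patience and floor are package choices. The
returned model is the epoch with minimal validation NLL. The
train/validation split is 90/10 by index before shuffling. Optional
dequantization-style training noise adds fresh $N(0, 0.005)$ per pixel
each epoch. NLL is averaged per sample (nats), so values are comparable
across resolutions and base distributions. Gradient clipping is off by
default but available, since affine flows can spike. A NaN loss aborts
training and returns the last best checkpoint.

# Sample refinement

A drawn sample has no guarantee of data consistency. `refine_sample()`
descends on

$$
\|A x - y\|_2^2 \;-\; \lambda \log p_\theta(x \mid y)
$$

with plain gradient descent (100 iterations, step $10^{-4}$ by
default), initialized at a flow sample; the gradient of the log-density
term is obtained by the same exact backward pass used in training. The
$\lambda$ grid explored in the package's experiments is
$\{0, 0.01, 0.1, 1, 10\}$; $\lambda = 0$ is pure data fidelity and, on
a well-conditioned operator at the default step, provably never
increases it.

# Metrics

PSNR is $10\log_{10}(\mathrm{range}^2/\mathrm{MSE})$; identical inputs
report an infinite PSNR, capped at 99.99 dB with a flag column in CSV
output so aggregates stay finite. SSIM uses the Gaussian-weighted
$11\times11$ window ($\sigma = 1.5$, $K_1 = 0.01$, $K_2 = 0.03$)
averaged over the valid interior, matching the standard reference
implementation to $10^{-4}$ on frozen fixtures; for images smaller
than the window, the window shrinks to the largest odd size that fits.
The dynamic-range policy is selectable: per-image maximum (CT-style
slice evaluation) or a global/volume maximum (MRI-style evaluation) —
the two conventions give incomparable absolute numbers.

# Synthetic data and what the tests do (and do not) show

The generator produces random ellipse superpositions (anatomy-like CT
slices) and sparse stroke patterns (digit-like images), both in
$[0,1]$, plus measurement simulation for three operators: dense
Gaussian compressed sensing (entries $N(0, 1/m)$, default
$m/n = 196/784$), the discrete parallel-beam Radon transform
(ray-driven via exact-transpose rotation, angles uniform on $[0,\pi)$,
detector count $\lceil\sqrt2\,\mathrm{side}\rceil$ covering the
diagonal), and the masked centered orthonormal Fourier transform
(column masks: 1-D Cartesian phase-encode undersampling, acceleration
4, 8% center fraction, zero frequency at the array center).
"10% relative noise" is implemented as noise whose expected norm is
10% of $\|Ax\|$ per sample; Poisson noise uses a single-parameter
photon-count model on exponentiated line integrals (a simplification
of realistic low-dose pipelines). Datasets regenerate bit-identically
from their seed; serialization is plain text (JSON + TSV).

Synthetic phantoms lack the texture, artifacts and acquisition quirks
of clinical data, and the toy problem sizes are far below clinical
resolution, so green tests here demonstrate *correctness of the
machinery and of the probabilistic calibration* — exact invertibility,
exact log-determinants, recovery of a known posterior — not clinical
reconstruction quality.

# Benchmark problem sizes and numerical choices

The package's validation experiments use sizes chosen to make the
mathematics decisive:

* *Density sanity*: unconditional flow on 20,000 2-D standard-normal
  samples; the best validation NLL must sit within 0.05 nats of the
  analytic $\log 2\pi + 1 \approx 2.8379$.
* *Posterior recovery*: $4\times4$ images under a squared-exponential
  Gaussian prior (correlation length 1.5 px, marginal sd 0.3, mean
  0.5), $m = 8$ Gaussian measurements, noise sd 0.05; 8,000 training
  pairs, 40 epochs. The conditional mean over 100 samples is compared
  with the closed-form posterior mean on 20 held-out measurements
  (target: within 10% relative $L_2$), and the pointwise std must
  rank-correlate positively with the analytic posterior std.
* *Conditioning ablation*: $16\times16$ digit-like phantoms, $m/n =
  1/4$ Gaussian measurements, 10% relative noise; identical flows
  trained for 20 epochs conditioned on the TV-regularized versus the
  pseudo-inverse reconstruction, 3 seeds. The quantity of interest is
  the *ordering* of mean test PSNR, not its magnitude.
* The finite-difference Jacobian oracle uses central differences at
  $\varepsilon = 10^{-6}$ on inputs of at most 256 elements.

Degenerate inputs are handled by validation errors, not silent fixes:
channel counts must match coupling splits, spatial sizes must be even
for downsampling and divisible by $2^{L-1}$ for pyramids, singular
mixing matrices and infeasible mask fractions are rejected, and
non-finite inputs fail fast.

# Known limitations

Training runs on a single CPU in plain R; it is intended for method
study at toy scale, not for full-resolution clinical datasets.
Conditional base distributions, Gaussian-mixture bases, learnable
invertible downsampling and fan-beam/helical CT geometries are out of
scope. The MRI path models the discrete masked Fourier operator only,
not continuous k-space trajectories, and the single-coil magnitude
convention discards phase. MAP estimation without a data-fidelity
penalty is intentionally not exposed; the refinement objective covers
the practically useful regime.
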