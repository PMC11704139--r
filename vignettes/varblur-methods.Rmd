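---
title: "Blur-operator families, blind identification and unrolled deblurring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blur-operator families, blind identification and unrolled deblurring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varblur)
```

## The problem

A microscope observes a blurred, noisy version of the true specimen
intensity $u$:

$$ b \;=\; N\!\big(H(\gamma)\,u\big), $$

where $H(\gamma)$ is a linear blur operator drawn from a known
*low-dimensional family* parameterized by $\gamma \in \mathbb{R}^p$
(typically $p < 20$), and $N$ adds heteroscedastic noise.  Blind
restoration then splits into two learnable sub-problems:

1. **identification** — estimate $\hat\gamma$ from the single observation
   $b$ with a convolutional encoder, and
2. **deblurring** — restore $u$ with an unrolled Douglas–Rachford scheme
   whose data steps use $H(\hat\gamma)$ and whose regularization steps are
   learned image-to-image proximal maps.

Constraining the operator to a physical family is what makes the blind
problem well posed: instead of estimating a whole kernel (or a huge
operator matrix), only a handful of physically meaningful coefficients
must be recovered.

## Operator families

### Zernike-pupil diffraction PSFs

Under scalar (Fresnel/Fraunhofer) diffraction, a focal slice of the
incoherent point spread function is

$$ k \;=\; \big|\,\mathcal{F}^{-1}\!\big[\rho\big]\,\big|^2 ,
\qquad
\rho(f) \;=\; \mathbf{1}_{\{\|f\|\le f_c\}}
\exp\!\Big(2\pi i \sum_j c_j Z_j\big(\|f\|/f_c,\angle f\big)\Big)
\exp\!\Big(2\pi i z \sqrt{(n_i/\lambda)^2-\|f\|^2}\Big), $$

with cutoff frequency $f_c = \mathrm{NA}/\lambda$, immersion index $n_i$
and defocus $z$.  The pupil phase is expanded in Noll-indexed Zernike
polynomials; piston, tip and tilt (Noll 1–3) are excluded because they do
not change the shape of the kernel.  Coefficients are expressed in
**waves** (one wave of a mode adds a $2\pi$ phase excursion); the
radians-per-mode alternative would only rescale the coefficient ranges, and
the waves convention makes the documented amplitude bound 0.15 produce a
visibly rich variety of kernels.  Kernels are normalized to unit sum, so
blurring preserves total flux and the mean intensity of the image.

Numerically, the pupil is sampled on an odd oversampled frequency grid
(default $4\times$ the kernel grid, rounded to odd) so that every discrete
frequency has its negative counterpart; the kernel is cropped to
`psf_grid_size` and renormalized.  The default constants
($\lambda = 0.5\,\mu m$, NA $=1.49$, $n_i = 1.515$, pixel pitch
$0.065\,\mu m$, grid $31\times 31$) describe a high-NA oil objective and
satisfy the Nyquist condition $1/(2\,\mathrm{pitch}) \ge f_c$, which the
constructor enforces.

### A parity caveat: which modes are identifiable from one image?

A fact with practical consequences for small families: if the pupil phase
contains only *even-parity* modes (defocus, astigmatism, spherical — even
radial order), the phase is an even function of the frequency, every PSF is
centrally symmetric, and
$k(-\gamma)$ equals $k(\gamma)$ **exactly**.  The observation is then
identical for $\gamma$ and $-\gamma$, no estimator can do better than
predicting the posterior mean $0$, and a least-squares-trained network
dutifully converges to exactly that.  Odd-parity modes (coma, trefoil)
break the symmetry: a global sign flip then *reflects* the kernel instead
of fixing it, which image content disambiguates.  For this reason
`zernike_family()` defaults to coma/trefoil modes (Noll 7–10) for
$p \le 4$ and to the full 4–10 set (where the odd modes resolve the even
ones' signs) for larger $p$.  The scaled-down experiments below use
$p = 3$ with Noll (7, 8, 9).

### Eigen-PSF subspaces and product-convolution operators

When PSFs are measured (or simulated) rather than modeled, a family of
sample kernels is compressed by an *uncentered* PCA into an orthonormal
eigen-PSF basis $e_1,\dots,e_M$ (`build_basis_pca`); uncentered because
PSFs are nonnegative and their mean — the dominant diffraction pattern —
belongs in the basis, as the leading singular vector.  A space-invariant
operator is then $k = \sum_m \gamma_m e_m$.

Space-varying blur is represented by the product-convolution expansion

$$ H(\gamma)\,u \;=\; \sum_{m=1}^{p} \gamma_m\; e_m \star (v_m \odot u), $$

with smooth space-variation maps $v_m$; the local impulse response at $x$
is $\sum_m \gamma_m v_m(x) e_m$, so the PSF varies continuously across the
field of view.  The implementation pairs one $\gamma_m$ with one
$(e_m, v_m)$ pair — the simplest linear-subspace reading of the expansion;
a fully bilinear pairing ($M_e \times M_v$ coefficients) can be expressed
in the same interface by repeating basis elements.

All convolutions are **circular**: operators diagonalize exactly in the
Fourier basis, adjoints are exact (`adjoint_operator` satisfies
$\langle Hu, w\rangle = \langle u, H^T w\rangle$ to machine precision), and
the regularized inverse of the solver has a closed form for
space-invariant operators.  The price is a wrap-around artifact near the
boundary, which is why observations are boundary-cropped before
identification (below).  Images use R's 1-based row/column indexing;
kernels are centered at the middle pixel of their (odd-sized) grid.

## Degradation model

Noise is the Gaussian approximation of Poisson shot noise plus read noise:
each pixel of $z = H(\gamma)u$ receives independent noise of variance
$\eta_1 \max(z,0) + \eta_2^2$.  Negative values (possible only through
noise itself, since blurred images of nonnegative specimens are
nonnegative) are clamped *inside the variance term only*; the observation
is not clipped, so the forward model stays linear.  Training ranges default
to $\eta_1 \in [0, 0.01]$, $\eta_2 \in [0, 0.05]$ for images in $[0,1]$,
and the noise-robustness sweeps use $\eta_2 \in \{0, 0.05, 0.1\}$ as the
noiseless / medium / high-noise regimes.  These ranges are package
defaults chosen to bracket realistic fluorescence SNRs; all are
configurable.

## The identification network

`init_identification_model()` builds a residual convolutional encoder:
stem convolution, then stages that halve the resolution with a strided
convolution and apply residual blocks, each convolution followed by batch
normalization and ReLU, ending in adaptive average pooling to a fixed
$2\times 2$ spatial grid and a linear head of size $p$.  Batch normalization matters here and not only for speed: the
blur signature is a small perturbation riding on large content variance,
and without normalization the optimization sits on the trivial
mean-predictor plateau for a very long time.  Adaptive pooling makes the
encoder size-agnostic: any input whose four-times-halved side still covers
the pooling grid (17 pixels and up for the 4-stage presets) maps to a
length-$p$ output.  The
`full` preset is an 18-layer-class encoder (widths 64–512, two blocks per
stage); the `tiny` preset (widths 16–64, one block per stage, about
1.5e5 weights) trains in minutes on one CPU.

Training (`train_identification`) minimizes the empirical risk
$\mathbb{E}\,\|IN(b) - \gamma\|^2$ over fresh (image, operator, noise)
triples; a fresh operator is drawn for every presentation so the network
cannot associate content with a kernel.  Targets are rescaled
per-coordinate to $[-1,1]$ by the family ranges (the inverse scaling is
applied at prediction), observations are cropped by the PSF half-width so
the network never sees the circular wrap-around, and the optimizer is Adam
with learning rate $10^{-3}$, betas $(0.9, 0.999)$, $\varepsilon=10^{-8}$
and no weight decay as the defaults.  An optional weight
exponential-moving-average (`ema`) returns Polyak-averaged weights, which
are noticeably less noisy than the final iterate at small batch sizes.

**Symmetry augmentation.**  Zernike-pupil kernels obey exact reflection
laws: reflecting the kernel about an image axis multiplies each pupil
coefficient by a sign fixed by the mode's azimuthal structure (sine modes
negate under the vertical reflection; a mode of azimuthal order $m$ picks
up $(-1)^m$ or $-(-1)^m$ under the horizontal one), and composing both
reflections gives the 180-degree rotation, whose label map coincides with
the global sign flip on odd-parity families.  For Zernike families the
trainer therefore presents each sample under one of the four transforms
(identity, two reflections, rotation) with the correspondingly transformed
label, and `predict_params` averages the four equivariant estimates at
test time.  A related exact fact worth knowing: flipping the signs of all
*even-parity* modes (defocus, astigmatism, spherical) leaves every kernel
unchanged — such sign combinations are fundamentally unrecoverable from a
single image, which is another reason the small families here use
odd-parity modes.

## The deblurring network

For the quadratic data term $f(x)=\tfrac12\|Hx-b\|^2$, the proximal map at
$z$ with scale $\sigma$ is the regularized inverse

$$ \mathrm{prox}(z) \;=\; (H^TH + \sigma I)^{-1}(H^Tb + \sigma z), $$

computed in closed form in Fourier space for convolution operators, or by
conjugate gradient on the normal equations otherwise.  The unrolled
Douglas–Rachford network runs, from the CG initial guess
$x_0 = z_0 \approx (H^TH+\sigma I)^{-1}H^Tb$ (20 CG iterations by
default),

$$ x_{k+1} = (H^TH+\sigma I)^{-1}(H^Tb+\sigma z_k), \qquad
   z_{k+1} = z_k + \mathrm{Prox}_k(2x_{k+1}-z_k) - x_{k+1}, $$

for $k = 0,\dots,K-1$ and returns the final data-consistency iterate
$x_K$ (default $K=4$).  With identity proximal maps the recursion
contracts to the least-squares solution; with the proximal map of
$\tfrac{\lambda}{2}\|x\|^2$ it converges to the ridge/Tikhonov solution —
both limits are verified against closed forms in the test suite.  Two
consequences of returning $x_K$ are worth stating: the $K$-th proximal map
does not influence the output (it would only affect $z_K$), so effectively
$K-1$ proximal networks shape the restoration; `output = "prox"` returns
the last proximal image instead.  $\sigma$ defaults to $10^{-3}$; a good
noise-adapted choice is $\max(\eta_2^2, 10^{-4})$.

Proximal networks are small residual two-scale U-Nets (`tiny_unet`:
widths 16/32; `drunet_like`: widths 32/64) whose final convolution is
initialized near zero — an untrained network starts at the identity, so
training starts from the Tikhonov baseline and can only refine it.
`classical_denoiser` (fixed Gaussian smoothing) and `identity` provide
non-learned plug-in baselines, and any R function can be used as a
proximal map.

Training (`train_deblurring`) follows the sequential procedure: the
identification network is trained first, then the proximal weights
minimize $\mathbb{E}\,\|DN(b,\hat\gamma) - u\|^2$ with
$\hat\gamma = IN(b)$ — the *estimated* parameters, so the deblurring
network learns to absorb identification errors (training against the true
$\gamma$ is available as an ablation flag).  Gradients flow exactly
through the unrolled recursion: the regularized inverse is linear in $z$,
with $\partial x_{k+1}/\partial z_k = \sigma (H^TH+\sigma I)^{-1}$,
applied in Fourier space; only the proximal weights are trainable, so no
gradient with respect to $\gamma$ is needed.  This exact-differentiation
path requires a space-invariant (Fourier-diagonal) family, which is also
the setting of the convolution experiments; space-varying operators are
supported at inference through CG.  The loss is squared error (an L1
option would be a one-line change; squared error matches the
minimum-mean-square-error interpretation of both networks).

## Synthetic phantoms

The phantom generator replaces a natural-image corpus at desk scale with
four content classes chosen to span the regimes that matter for blur
identification: `beads` (sparse Gaussian point sources, Poisson-scattered
— the classical PSF-calibration content), `filaments` (smoothed
random-walk curves), `blobs` (thresholded smoothed noise, piecewise
smooth) and `texture` (band-limited random fields), plus a `mixture`
class superimposing random pairs.  All are rescaled to $[0,1]$ and are
reproducible from a seed.  What the phantoms do *not* emulate: the
intensity statistics, anisotropy and correlated background of real
micrographs, and the scale/diversity of a 118k-image natural corpus.
Passing the scaled-down tests therefore demonstrates that the pipeline's
mechanics and optimization work end to end — not that the tiny networks
transfer to arbitrary real specimens.

## Scaled-down study conditions

The package's own experiments (test suite and `scripts/acceptance.R`) run
on one CPU in minutes, with sizes chosen once:

* identification: `tiny` encoder, $p=3$ Zernike family (Noll 7–9,
  $c_{\max} = 0.15$), 2,000 bead phantoms of $64\times 64$ (boundary-cropped
  to $34\times 34$ observations), noiseless training, 10 epochs at batch
  size 2 with symmetry augmentation and weight averaging, Adam learning
  rate decaying $3\times 10^{-3} \to 2\times 10^{-4}$ (a batch-normalized
  network at desk-scale batch sizes trains reliably above the full-scale
  default $10^{-3}$, which remains the package default).  Bead phantoms
  are used for this protocol because content-generic identification — the
  full-scale study's point — needs corpus sizes and network capacity far
  beyond desk scale; point-source content is the standard calibration
  regime in microscopy and exercises the same estimator.
* evaluation: 200 held-out phantoms with fresh operators, scored by the
  relative kernel error $\|k(\hat\gamma)-k(\gamma)\|_2/\|k(\gamma)\|_2$
  (equivalently the PSF SNR in dB) and the relative parameter error; the
  noise sweep over $\eta_2 \in \{0, 0.05, 0.1\}$ uses 400 phantoms per
  noisy level.  At these sizes the trained encoder reaches median relative
  kernel errors slightly above twenty percent in the noiseless regime
  (a full-scale encoder trained on a hundred thousand natural images
  reaches a few percent); a noiseless-trained encoder saturates (relative
  error near 1) at the two higher noise levels, so the sweep mainly
  checks the ordering — and because both noisy levels sit at saturation,
  their ordering is dominated by sampling noise and can invert across
  training seeds, which is why the sweep uses the larger per-level sample.
* deblurring: $K = 4$ untied `tiny_unet` proximal networks,
  $\sigma = 10^{-3}$, 300 training phantoms, 3 epochs at batch size 4,
  estimated $\hat\gamma$ from the trained encoder; compared by SSIM
  against both the observation and the identity-proximal (Tikhonov)
  baseline on held-out phantoms at test noise $\eta_2 = 0.02$.  The
  identity-proximal baseline amplifies noise at this small $\sigma$, so
  the learned proximal maps improve on it by a wide margin, and on the
  observation by a clear one.

## Numerical choices and degenerate inputs

* PSF normalization: unit sum to $10^{-12}$; an all-zero pupil raises an
  error rather than returning a degenerate kernel.
* Orthonormality of bases is enforced at construction to $10^{-10}$
  (Gram deviation); deliberately non-orthonormal variation maps must be
  flagged.
* CG runs on the normal equations with a fixed iteration budget; the
  regularized inverse warns and returns the best iterate if the residual
  stays large.
* SSIM uses the canonical constants ($K_1=0.01$, $K_2=0.03$), an
  $11\times 11$ Gaussian window ($\sigma=1.5$), valid-region windowing and
  uncorrected (population) local variances.
* PSF SNR is $-20\log_{10}(\|\hat k - k\|_2/\|k\|_2)$ — the relative-error
  form consistent with a 0-SNR reading for a doubled kernel; an exact
  estimate returns `Inf`.
* Determinism: every stochastic component draws from R's global RNG;
  seeded runs are bit-reproducible, and batch normalization uses running
  statistics at inference so prediction is deterministic.

## Known limitations

* The learned components are deliberately small; their accuracy on
  content-generic corpora and real micrographs is out of scope at desk
  scale.
* Training the deblurring network differentiates the Fourier-diagonal
  inverse and therefore requires space-invariant families; product-
  convolution operators are supported for simulation, identification and
  CG-based restoration, but not for proximal-weight training.
* Circular boundary handling trades boundary realism for exact linear
  algebra; real acquisitions should be windowed or cropped accordingly.
* The operator-family container stores bases as JSON arrays — convenient
  and dependency-free for families up to a few megabytes, not intended for
  very large basis stacks.
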