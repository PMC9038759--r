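---
title: "Phase retrieval for grating-interferometry phase-stepping data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase retrieval for grating-interferometry phase-stepping data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gipret)
```

## The measurement model

A Talbot–Lau grating interferometer converts refraction and small-angle
scattering by a sample into intensity modulation on the detector. During
*phase stepping*, one grating is scanned through its period in `M`
discrete steps, and each detector pixel traces a sinusoid

$$I_k = a_0 + a_1 \sin\!\left(\frac{2\pi (k + \eta_k)}{M} + \theta\right),
\qquad k = 1, \dots, M,$$

where $a_0$ is the DC offset (counts), $a_1$ the modulation amplitude,
$\theta$ the fringe phase, and $\eta_k$ a mechanical stepping error in
units of one step. `forward_stepping()` implements this model;
`fit_sinusoid()` solves the per-pixel least-squares problem in closed
form by the linear reparameterisation $(a_0, a_1\cos\theta,
a_1\sin\theta)$ — the harmonic regression is exactly linear, so the fit
is deterministic, vectorised over all pixels, and needs no iteration.
The fit deliberately assumes ideal step positions ($\eta = 0$): the
stepping error is unknown at analysis time, and its effect surfaces as
the spatially structured moiré residual that the retrieval methods
downstream are designed to remove.

Comparing a sample scan with a reference (air) scan yields three
contrast channels (`extract_contrast()`):

* transmission $T = a_{0,s}/a_{0,r}$,
* differential phase contrast (DPCI)
  $\varphi = \mathrm{wrap}(\theta_s - \theta_r) \in [-\pi, \pi)$,
* dark-field $V = (a_{1,s}/a_{0,s})\,/\,(a_{1,r}/a_{0,r})$, the
  visibility ratio.

The dark-field defaults to the conventional visibility ratio. An
alternative form, $(a_{1,s}/a_{0,r})/(a_{0,s}/a_{1,r})$, circulates in
the literature but is dimensionally inconsistent with the visibility
definition (it scales with the square of the amplitudes rather than
their ratio); it is available behind
`extract_contrast(..., darkfield_form = "literal")` so both conventions
can be compared. No published numeric dark-field values we are aware of
disambiguate the two on real data.

### Angular and derivative conventions

All phases are wrapped to the half-open interval $[-\pi, \pi)$
(`wrap_angle()`), and the DPCI is wrapped after the subtraction. The
discrete x-derivative `diff_x()` is the per-row first difference with a
replicate left boundary (first column zero); `cumsum_x()` is its exact
inverse up to the per-row constant. This pairing is what makes the
integration round trip exact to machine precision and is used
*everywhere* a derivative appears: the simulator's ground truth, the
integration model, the TV operator, and the network loss. Pixel
coordinates are 0-based, x running left to right along columns and y
down the rows; all derivatives and integrations act along x.

## The simulation protocol

`make_phantom()` prepares a normalised test image (the ten-ellipse
Shepp–Logan head phantom rasterised from its ellipse table, a
procedurally generated high-frequency texture, or any user image),
zero-pads it 32 pixels on the left and right, and attaches a
closed-form carrier-phase pattern
$\theta(x, y) = \sqrt{(x/10 - 20)^2 + (-y/5 + 70)^2} \bmod 2\pi$
(a "peppers" variant with gentler gradients is selectable). The sample
coefficients follow an attenuation/visibility model driven by the
normalised image $I$:

$$a_{0,s} = a_{0,r}\bigl(1 - (I/4)^{0.7}\bigr), \qquad
  a_{1,s} = a_{1,r}\bigl(1 - (I/1.5)^{0.5}\bigr), \qquad
  \theta_s = \theta_r + s\,\partial I/\partial x,$$

with reference values $a_{0,r} = 70{,}000$ and $a_{1,r} = 30{,}000$
counts. Two modelling choices deserve comment. First, the sample phase
is the carrier *plus* the image derivative: only a carrier common to
both scans makes the extracted DPCI equal the intended derivative
image, since the DPCI is the difference of the two phase maps. Second,
the scale $s$ between the normalised-image gradient and radians is an
instrument property with no canonical value; it defaults to 1.0 (which
keeps the phase shift well within one fringe period for images in
$[0, 1]$) and is exposed as `deriv_scale`.

`simulate_acquisition()` draws an independent stepping error
$\eta_k \sim \mathcal U(-0.05, 0.05)$ per step *and per scan* — the
independence between the reference and sample realisations is what
produces the moiré residual — and optionally replaces every frame by an
independent Poisson draw with the noise-free frame as its mean. At
$a_0 = 70{,}000$ counts the relative shot noise per frame is about
0.4%, so the DPCI noise is dominated by the stepping error and the
phase-fit noise floor, as in a well-exposed acquisition.

What the generator deliberately does *not* emulate: wave-optical
(Fresnel) propagation, polychromatic spectra, detector point-spread and
flat-field structure, and scatter. Passing tests on this generator
therefore demonstrate correctness of the analysis chain under the
stated signal model, not robustness to every instrumental effect in
measured data.

## Classical retrieval

The DPCI is a noisy derivative; the phase image (PCI) follows by
integration, $\phi(x, y) = c\int_0^x \varphi(x', y)\,dx'$, with $c$ an
instrument constant (1 throughout the synthetic work).
`direct_integration()` is the cumulative-sum counterpart. Because every
error accumulates along x, its output exhibits the characteristic
horizontal stripes; the per-row integration constant is fixed so that
air pixels average to zero when a mask is available (rows without air
fall back to a zero first column).

`wf_destripe()` implements wavelet-Fourier destriping: the image is
decomposed with an orthogonal periodized DWT (implemented in the
package, since the filter needs direct access to the per-level detail
bands); at each level the band that condenses horizontal-stripe energy
(high-pass along y, low-pass along x) is Fourier-transformed along the
stripe axis and damped by $1 - e^{-f^2/2\sigma^2}$. Defaults — `db4`,
4 levels, $\sigma = 2$ frequency bins — were chosen so that a
row-constant stripe field loses more than 90% of its energy while a
smooth stripe-free image changes by less than 1%, and are exposed in
the configuration. Images whose sides are not divisible by
$2^{\text{levels}}$ are reflect-padded and cropped back.

`admm_retrieval()` minimises the regularised objective

$$\lVert D_x \hat x - \varphi\rVert_2^2
  + \lambda_1 \lVert \mathrm{TV}\,\hat x\rVert_1
  + \lambda_2 \lVert M \hat x\rVert_2^2,
\qquad \lambda_1 = 0.001,\ \lambda_2 = 1,$$

where $M$ is the binary air mask built by thresholding the three
contrast channels (`make_mask()`; each threshold can be disabled, and
with no active test the mask is empty — the regime for objects larger
than the field of view). The solver is ADMM with splitting on the
anisotropic TV gradients $z = (D_x \hat x, D_y \hat x)$: anisotropic TV
was chosen because it gives a separable soft-threshold z-update; the
x-update solves the regularised normal equations by warm-started
conjugate gradients, because the replicate-boundary difference
operators are not circulant and the mask is not translation invariant,
so no FFT diagonalisation exists. Defaults $\rho = 1$, 200 iterations,
relative-change tolerance $10^{-5}$, 15 CG steps per outer iteration.
The iteration starts from the direct-integration estimate — a cheap
warm start that also anchors the objective-decrease test. On 16×16
instances the final objective agrees with an independent primal-dual
(Chambolle–Pock) solver of the same objective to within 1% (see the
test suite).

## Self-supervised retrieval

The key observation for learning-based retrieval without clean targets
is that a DPCI can be fitted from any subset of at least three stepping
frames (`subset_dpci()`). Subsets keep their true step indices in the
model phase, so the angular sampling stays faithful. On noiseless data
every subset reproduces the full-data DPCI; on noisy data, two
independently drawn subsets give two noisy realisations of the same
image whose paired noise is approximately zero-mean — the premise of
Noise2Noise training. The pairing is only approximate for small M
(overlapping subsets share frames, so the paired noises are correlated);
the correlation decays as M grows, which is the usual dose/quality
trade-off of phase stepping. We draw the input and target subsets
independently (sizes uniform between $\lceil M/2\rceil$ and $M$,
subsets uniform without replacement) rather than disjointly: with
$M = 8$ disjoint pairs of at least 3 frames barely exist, and
independence is what the zero-mean argument actually needs.

`draw_training_batch()` samples one subset pair per training iteration
and cuts random square patches, all channels jointly; a random
horizontal mirror negates the DPCI channels, because an x-derivative
changes sign under x-reflection — without the sign flip the
augmentation would poison the derivative loss.

### Network

`build_network()` assembles a dual-stream architecture: a *base* stream
conditioned on transmission and dark-field (images that are not
differentiated and share the object's shape) and a *detail* stream fed
with the DPCI (scaled by $1/\pi$ into roughly $[-1, 1]$; the loss is
always computed against the unscaled target). Each stream is a small
U-net: 3×3 same-padding convolutions with ReLU, features starting at 64
and doubling once per level (depth 2 = one 2×2 max-pooling stage), a
channel-reducing convolution followed by nearest-neighbour upsampling
on the way up, and additive skip connections. The stream outputs are
added and passed through three convolution blocks, the last being the
linear 1-channel output layer. Additive merging (for the skips and the
stream fusion alike) keeps the channel counts — and with them the
single-CPU training cost — at half of what concatenation skips would
require, while the element-wise addition of the two streams is the
fusion rule the architecture is built around. With the default
configuration the network has 371,585 parameters.

The training loss is the retrieval objective with the network output
$f$ in place of $\hat x$ (per-pixel means rather than sums, for
scale-stable gradients):

$$\mathcal L = \overline{(D_x f - \varphi_{\text{target}})^2}
  + \lambda_1\bigl(\overline{|D_x f|} + \overline{|D_y f|}\bigr)
  + \lambda_2\,\overline{M f^2}.$$

$D_x$ and the TV operator are the same discrete operators as in the
classical solvers, so a network that outputs the exact integral of its
target has zero data term. When no air prior exists, $\lambda_2 = 0$
disables the mask term. The optimiser is ADAM at initial rate $10^{-4}$
decayed per epoch as $1/\sqrt{t}$ (the per-epoch reading of the decay;
a per-iteration decay would freeze learning within the first epoch at
these schedule lengths). The reference schedule is 100 epochs × 100
iterations with 64 patches of 64²; the package's tests and the
acceptance script run a reduced schedule (10 × 50 iterations, 16
patches of 48²) that completes in a few minutes on one CPU and already
beats direct integration by a wide margin (about +15 dB PSNR on the
noisy Shepp–Logan phantom).

The network itself is implemented in the package's compiled code
(single-precision, guard-padded layout, convolutions as nine
row-shifted SGEMM accumulations) with forward and backward passes
verified in the test suite against a naive R implementation of the same
topology; training is single-threaded and bit-reproducible from the
seed pair (initialisation + sampling share one seed).

Transmission and dark-field conditioning channels come from the
*full-data* fit rather than from subsets: they carry no derivative
information, so their noise does not bias the N2N expectation, and the
full fit is their lowest-noise estimate.

## Numerical and design notes

* **Degenerate inputs.** An all-zero pixel fits to
  $a_0 = a_1 = 0, \theta = 0$ by convention; amplitude-sign ambiguity is
  resolved by $a_1 \ge 0$ (adding $\pi$ to $\theta$); division by a zero
  reference coefficient fills the affected pixels with a configurable
  value and counts them in a diagnostic.
* **Ties and thresholds.** Max-pooling ties take the first candidate in
  column-major order; the TV subgradient uses $\mathrm{sign}(0) = 0$.
* **Stopping.** ADMM stops on relative iterate change below `tol` or at
  `max_iter`; training aborts if the loss exceeds 1000× its initial
  value for 50 consecutive iterations.
* **Problem sizes.** The test suite exercises 64²–256² phantoms, the
  reduced training schedule above, and 16² instances for the
  solver-oracle comparison; these sizes were chosen so the full chain
  (including three independent seeded trainings) runs comfortably on a
  single CPU while leaving every conclusion scale-independent.
* **Storage.** Stacks and images are stored as float32 TIFF with YAML
  sidecars (the package writes IEEE-float TIFFs itself, since the
  available TIFF writer only emits integer samples; files are read back
  through `tiff::readTIFF`). Integer counts below $2^{24}$ round trip
  exactly; 16-bit files are exact up to 65,535. Display windows are
  applied only at PNG export, never to stored data, so metrics never
  depend on visualisation choices.

## Known limitations

* The signal model is monochromatic and geometric; no wave-optics, no
  detector PSF, no flat-field structure.
* Phase unwrapping beyond the fixed $[-\pi, \pi)$ convention is out of
  scope; samples inducing phase steps beyond one fringe period alias.
* Retrieval is one-directional (x only); two-directional variants that
  combine orthogonal DPCIs are not implemented.
* The Noise2Noise pairing is only approximately independent at small M;
  the residual correlation leaves some artifact energy in the learned
  reconstruction, consistent with the method's published behaviour.
* The reduced-scale training demonstrates the mechanism, not the
  ceiling: longer schedules and larger patch budgets improve the
  learned reconstruction further.
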