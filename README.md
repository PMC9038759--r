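# gipret — phase retrieval for grating-interferometry phase-stepping data

X-ray and neutron Talbot–Lau grating interferometers measure three
images at once — transmission, differential phase contrast (DPCI) and
dark-field — by scanning a grating through its period in `M` steps and
fitting the per-pixel intensity sinusoid

    I_k = a0 + a1 * sin(2*pi*(k + eta_k)/M + theta),   k = 1..M.

The DPCI `wrap(theta_sam - theta_ref)` is the *x-derivative* of the
phase image that users actually want; integrating it accumulates
stepping-motor error (`eta_k`) and counting noise into severe
horizontal stripe artifacts. `gipret` is a toolkit for everyone working
with phase-stepping data who needs to get from raw stepping stacks to a
clean integrated phase image (PCI). It provides:

* the forward stepping model, a closed-form per-pixel harmonic
  least-squares fit, and contrast extraction
  (transmission `a0s/a0r`, DPCI, dark-field visibility ratio
  `(a1s/a0s)/(a1r/a0r)`);
* a synthetic-acquisition generator (padded Shepp–Logan or texture
  phantoms, carrier-phase patterns, sample coefficients
  `a0s = a0r(1-(I/4)^0.7)`, `a1s = a1r(1-(I/1.5)^0.5)`,
  `theta_s = theta_r + dI/dx`, uniform stepping error, Poisson noise);
* three classical retrieval routes: direct 1-D integration,
  wavelet-Fourier destriping, and ADMM minimisation of
  `||Dx x - dpci||^2 + 0.001 ||TV x||_1 + ||M x||^2` with a
  threshold-built air mask `M`;
* a self-supervised (Noise2Noise) route: DPCI training *pairs* are
  fitted from independent random subsets of the stepping frames — no
  clean targets needed — and a dual-stream convolutional network
  (transmission/dark-field conditioning stream + DPCI detail stream,
  depth-2 U-nets, 64 base features, additive fusion) is trained with
  the physics loss
  `mean((Dx f - dpci)^2) + 0.001 TV(f) + mean(M f^2)` under ADAM with
  a `1/sqrt(epoch)` learning-rate decay. The network and its training
  loop are implemented in the package's own compiled code and run on a
  single CPU;
* PSNR/SSIM evaluation, float32-TIFF stack/image I/O with YAML
  sidecars, a strict-YAML pipeline runner with checksummed run
  manifests, and a CLI (`exec/gipret`) with `simulate`, `fit`,
  `retrieve`, `make-pairs`, `train`, `predict`, `evaluate` and
  `pipeline` subcommands.

## Worked example

Simulate a noisy acquisition at the stated study settings
(`a0 = 70,000`, `a1 = 30,000`, `M = 8`, stepping error ±0.05 steps,
Poisson noise), fit it, and compare direct integration with the
regularised solver:

```r
library(gipret)

phantom <- make_phantom("shepp_logan", size = 128)
acq  <- simulate_acquisition(phantom, noisy = TRUE, seed = 1)
trip <- extract_contrast(fit_sinusoid(acq$ref), fit_sinusoid(acq$sam))
trip
#> <contrast_triplet> 128 x 192
#>   transmission in [0.616, 1.01], dpci in [-1.04, 1.04] rad, darkfield in [0.28, 1.04]

mask     <- make_mask(trip)              # air prior from the three channels
pci_int  <- direct_integration(trip$dpci, mask = mask)
pci_admm <- admm_retrieval(trip$dpci, mask = mask)

clip <- function(x) pmin(pmax(x, 0), 1)
ev_int  <- evaluate_pci(clip(pci_int),      phantom$gt$pci)
ev_admm <- evaluate_pci(clip(pci_admm$pci), phantom$gt$pci)
cat(sprintf("integration: PSNR %.1f dB, SSIM %.3f\n", ev_int$psnr, ev_int$ssim))
cat(sprintf("ADMM:        PSNR %.1f dB, SSIM %.3f\n", ev_admm$psnr, ev_admm$ssim))
#> integration: PSNR 5.6 dB, SSIM 0.371
#> ADMM:        PSNR 30.9 dB, SSIM 0.912
```

The integration result at 5.6 dB is dominated by the accumulated stripe
artifacts; the TV/air-mask solver removes them almost entirely. The
learned route goes further on structure preservation — train it on the
same acquisition without any clean target:

```r
st <- train_n2n(list(list(ref = acq$ref, sam = acq$sam,
                          triplet = trip, mask = mask)),
                pair_sampler_config(M = 8, patch_size = 48,
                                    patches_per_iteration = 16),
                cfg = train_config(epochs = 10, iterations_per_epoch = 50),
                seed = 1)
pci_n2n <- predict_pci(st, trip)
```

On a 256² phantom this reduced schedule (a few minutes on one CPU)
lifts the retrieval from 4.0 dB PSNR / 0.34 SSIM (direct integration)
to 19.1 dB / 0.66, with the loss trace available in
`st$loss_history`. The methods vignette
(`vignettes/phase-retrieval-methods.Rmd`) explains the signal model,
the solvers, the Noise2Noise pairing argument and every default.

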