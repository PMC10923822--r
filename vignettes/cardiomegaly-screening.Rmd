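---
title: "Segmentation-based cardiomegaly screening: models, training and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmentation-based cardiomegaly screening: models, training and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The screening model

Cardiomegaly — pathological enlargement of the heart — is screened on a
posteroanterior chest radiograph through the cardiothoracic ratio

$$\mathrm{CTR} = \frac{\text{maximum horizontal cardiac diameter}}
                     {\text{maximum horizontal thoracic diameter}},$$

with the decision rule

$$\text{output} = \begin{cases}
  \text{cardiomegaly} & \mathrm{CTR} > \pi\\
  \text{normal} & \text{otherwise,}
\end{cases}$$

where $\pi = 0.50$ is the common screening threshold and $\pi = 0.55$ a
stricter protocol used by some annotators. `ctrseg` estimates both
diameters from two independent binary segmentation networks — one for the
cardiac silhouette, one for the two lung fields. Each predicted
probability map is thresholded at 0.5, cleaned by connected-component
selection (largest component for the heart, union of the two largest for
the lungs, components under 0.1% of the image area discarded), and reduced
to a tight axis-aligned bounding box; the CTR is the ratio of the two box
widths. Boxes are 0-based and inclusive, so a box spanning columns
$x_{\min}..x_{\max}$ has width $x_{\max}-x_{\min}+1$. An empty mask makes
the image *indeterminate* rather than silently classified.

# Networks

Both organs use the same encoder–decoder architecture built from a
*convolutional block*: 3×3 convolution (stride 1, shape-preserving
padding), batch normalization, ReLU, then CBAM attention (channel
attention: a shared two-layer MLP over the per-channel average and maximum
descriptors, reduction ratio 16; spatial attention: a 7×7 convolution over
the channel-wise average/max planes; both gates sigmoid). The encoder
stacks five stages of three blocks (16, 32, 64, 128, 256 filters) each
followed by 2×2 max pooling, so a 299×299×3 input becomes a 9×9×256 latent
(299→149→74→37→18→9). The decoder mirrors this with three blocks per stage
and stride-2 3×3 transposed convolutions whose padding alternates
same/valid/same/valid/valid to reproduce exactly the encoder's size chain
(9→18→37→74→149→299), ending in a 3×3 convolution to one channel, batch
normalization, and a sigmoid. The batch normalization placed immediately
before the output sigmoid is unusual but implemented as designed.

For other input sizes the padding pattern is derived automatically from
the encoder chain: a pooled size $s$ came from either $2s$ ("same") or
$2s+1$ ("valid"), so the inversion is always well defined; inputs below 32
pixels are rejected because the fifth pooling would leave nothing.

No deep-learning framework is involved: convolutions run through
im2col/GEMM kernels (Rcpp + BLAS) with hand-derived backward passes for
every layer, including CBAM's argmax routing and the batch-norm coupling
across the batch. A finite-difference test in the suite compares analytic
gradients of the full encoder–decoder against central differences.

# Supervised and semi-supervised training

The supervised loss on a labeled batch of size $bs^l$ is the mean of
binary cross-entropy plus Dice loss per pair,

$$\mathcal{L}_S = \frac{1}{bs^l}\sum_i \left[H(y_i, \hat y_i) +
  \mathrm{dice}(y_i, \hat y_i)\right],$$

with BCE reduced as a pixel mean (clipping at $10^{-7}$) and
$\mathrm{dice} = 1 - (2\sum y\hat y + \varepsilon) / (\sum y + \sum \hat y
+ \varepsilon)$, $\varepsilon = 10^{-6}$.

Semi-supervised training adds an auxiliary decoder fed *perturbed* latent
representations of unlabeled images. Each unlabeled latent $z$ is
perturbed $k = 3$ ways:

* **F-Noise** — $z' = z + z \odot N$, $N \sim U(-0.3, 0.3)$ elementwise;
* **F-Drop** — the channel-mean map of $z$ is min–max normalized to
  $[0,1]$; positions whose normalized mean does not exceed a threshold
  $\gamma \sim U(0.6, 0.9)$ are zeroed across channels. As printed, this
  *keeps* the most active regions; the reference cross-consistency
  formulation drops them instead, and a configuration switch
  (`fdrop_invert`) exposes that variant. A constant latent, for which
  min–max normalization is undefined, drops everything.
* **Dropout** — elementwise zeroing at rate $r \sim U(0.1, 0.7)$,
  survivors unscaled by default (a rescaling flag exists).

The consistency loss is the mean over the $k \cdot bs^u$
(target, auxiliary) pairs of the per-pair pixel *sum* of squared error,
with the main-decoder outputs treated as fixed targets — no gradient flows
into them. Because the literal pixel sum exceeds the pixel-mean supervised
loss by a factor of roughly $W \times H$, the default configuration
normalizes the per-pair error by the pixel count
(`unsup_pixel_mean = TRUE`); the literal sum remains available. Its weight
follows the Gaussian ramp-up $\omega(t) = \exp(-5(1 - t/L)^2)$ for
$t < L$ and 1 afterwards (default $L = 50$, half of the default 100
epochs). Gradient routing: $\mathcal{L}_S$ updates the main decoder and
encoder; $\omega\,\mathcal{L}_U$ updates the auxiliary decoder and
encoder. One auxiliary decoder serves all $k$ perturbations.

Mini-batches mix the pools proportionally:
$\delta = (n+m)/bs$, $bs^l = \lfloor n/\delta \rfloor$,
$bs^u = \lceil m/\delta \rceil$, which always sum to $bs$. In heavily
unlabeled regimes the floor can reach zero (with $n = 247$, $m = 9763$,
$bs = 16$: $\delta = 625.625$, $bs^l = 0$); a clamp raises $bs^l$ to 1 and
reduces $bs^u$ accordingly, and the plan records that it fired. An epoch
is one pass over the unlabeled training pool; the labeled pool cycles with
reshuffling. 20% of labeled and 10% of unlabeled samples are held out for
validation (rounded half away from zero; stratified by image label when
available), and the checkpoint with the best labeled-validation Jaccard is
retained. Optimisation uses Adam (learning rate $10^{-3}$, moments 0.9 /
0.999). Every random decision — initialization, splits, shuffling,
augmentation, perturbations — derives from the single configured seed, so
two runs with the same configuration produce identical histories.

# Preprocessing and augmentation

Standardization applies, in order: resize to 299×299 (bilinear),
grayscale conversion (luminance weights for RGB), Contrast Limited
Adaptive Histogram Equalization, replication to three identical channels,
and scaling by the 8-bit maximum into $[0,1]$. CLAHE parameters are not
dictated by the protocol; the defaults are clip limit 2.0 with an 8×8
tile grid (both configurable). The tile decomposition requires the side
to divide evenly, so images are edge-padded to the next multiple and
cropped back; constant images bypass equalization. Labeled training pairs
are augmented on the fly with random horizontal/vertical flips, rotation
drawn uniformly from $[0°, 10°]$ with random sign (zero fill), and a 10%
zoom-in (center crop to 90% of each side, resized back) applied with
probability one half. Masks are always resampled nearest-neighbour so
they stay binary. Unlabeled images are never augmented. Note that the
zoom-in changes the foreground area by about $1/0.9^2 \approx 1.23$; only
the rotation approximately preserves it.

# The synthetic phantom generator

Clinical radiographs with pixel-level annotation are scarce, so the test
bed is a phantom generator that emulates exactly the features the method
consumes: two dark elliptical lung fields on a brighter body, a bright
cardiac ellipse centered between them, a diagonal intensity gradient,
additive Gaussian noise, optional rib-like bands, and pixel-exact masks.
The heart's horizontal pixel extent is constructed as
$\mathrm{round}(\mathrm{CTR}_{\text{target}} \times W_{\text{lungs}})$,
so the mask-derived CTR matches the requested one to within pixelization
($\pm 2/\text{size}$), and the generator reports the exact mask-derived
value as ground truth. Masks are a deterministic function of the geometry;
noise only ever touches the image. Dataset generation jitters lung
centers (±0.015 of the image in x, ±0.02 in y), semi-axes (±8%) and heart
height (±0.02) between phantoms, draws target CTRs from a clamped normal
law centered at 0.50 with standard deviation 0.08 (roughly the clinical
spread, and roughly class-balanced at $\pi = 0.50$), and writes 8-bit PNGs
plus a manifest CSV. Defaults are noise SD 0.05 and gradient amplitude
0.1; "noiseless" phantoms set both to zero.

What the phantoms deliberately do not model: ribs' overlap with the
mediastinum, clavicles and scapulae, rotation/inspiration variability,
pathology other than heart width, scanner post-processing, and any
texture realism. Passing the phantom suites therefore demonstrates that
the pipeline's geometry, losses, optimisation and evaluation machinery
are correct and that the networks can learn this family of shapes — not
that the trained weights transfer to clinical radiographs.

# Desk-scale experiment sizes

The full-scale protocol (299-pixel inputs, 16/32/64/128/256 filters, 100
epochs, batch 16) is GPU-scale; the package's own experiments run at desk
scale, chosen once as: 64-pixel phantoms, filter widths 8/16/16/24/32,
batch size 2 (supervised) or 4 (semi-supervised, giving a 1 labeled + 3
unlabeled mix per step), batch-norm momentum 0.9 (the default 0.99 tracks
too slowly when an epoch holds only a handful of optimisation steps), 60
supervised epochs, and for the semi-supervised comparison 10 labeled +
60 unlabeled noisy phantoms for 15 epochs with ramp-up length 8 —
keeping the protocol's ratio of ramp length to epoch count. The
supervised learnability check uses 40 noiseless phantoms and requires a
median validation Jaccard above 0.8 over three seeds for the lung
fields; the semi-supervised
check trains on the same 10 labeled phantoms with and without the
unlabeled pool across three seeds and compares median best-validation
Jaccard for the heart (the harder organ at this scale), requiring
non-inferiority within 0.02. These sizes are the package's choices for a
CPU-sized, deterministic test bed; nothing about the method depends on
them.

# Numerical choices and edge cases

* Binarization threshold 0.5, minimum component area 0.1%, all
  configurable; empty masks propagate as "indeterminate".
* BCE clipping $10^{-7}$; Dice smoothing $10^{-6}$; batch-norm
  $\varepsilon = 10^{-3}$, momentum 0.99 (configurable).
* He-uniform weight initialization, zero biases, fully seeded.
* Max pooling uses valid 2×2 windows (odd sizes drop the last row/column,
  e.g. 299 → 149); ties take the first maximum in column-major order, as
  do the CBAM argmax descriptors.
* The hard-prediction AUC of a thresholded CTR classifier is
  $(\mathrm{Sens}+\mathrm{Spec})/2$ (two-point trapezoid); this is the
  reported AUC column, because the reported evaluation tables are
  consistent with exactly that formula on every dataset. A rank-based
  (midrank-tied) AUC over continuous CTR scores is also provided.
* Report tables round half away from zero to two decimals; raw values are
  kept internally.
* Divergent training (non-finite loss) aborts with epoch/step context
  rather than continuing.

# Known limitations

* The from-scratch CNN engine is single-threaded per BLAS call and meant
  for desk-scale experiments; full-scale training of the 299-pixel
  architecture is out of its intended range.
* CLAHE here is EBImage's implementation; bit-exact agreement with other
  libraries' CLAHE is not a goal.
* The CTR uses the lungs-union bounding box as the thoracic diameter, not
  an anatomical inner-rib-cage measure, and assumes a frontal view.
* Two independent binary models are trained; no joint multi-class head is
  provided.
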