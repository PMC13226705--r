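---
title: "Universal adversarial perturbations against frozen image encoders: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Universal adversarial perturbations against frozen image encoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The threat model

Digital-pathology pipelines increasingly route image patches through a large
*frozen* feature extractor (typically a vision transformer) and train only a
light linear classifier — a "linear probe" — on the extracted CLS features.
`utapr` implements the attacker's and defender's sides of this arrangement:

* a **universal adversarial perturbation**: a single, fixed noise pattern
  `p` with `max|p| <= epsilon/255`, added to *any* input patch, optimised so
  that the encoder's feature representation of the attacked patch decorrelates
  from that of the clean patch;
* **patch-specific** and **class-specific** perturbations, which instead
  maximise the cross-entropy of the downstream probe for one image or one
  class;
* a single-step **gradient-sign baseline**;
* a **Fourier low-pass-filter defense**, its physical cost expressed as an
  effective numerical aperture, and the **adaptive attack** that trains
  through the filter;
* a convolutional **attack detector**; and
* the **linear-probing evaluation harness** (accuracy drops, cross-encoder
  transfer matrices, CLS-to-token attention heatmaps, PCA/UMAP projections).

## The universal attack

With a frozen encoder $\mathcal{M}$, preprocessing $\mathcal{T}$ and clean
patches $I$, the attack minimises the batch-mean cosine similarity

$$\mathrm{CosSim}(f_\mathrm{ori}, f_\mathrm{atk})
  = \frac{f_\mathrm{ori}\cdot f_\mathrm{atk}}
         {\lVert f_\mathrm{ori}\rVert\,\lVert f_\mathrm{atk}\rVert},
  \qquad
  f_\mathrm{atk} = \mathcal{M}(\mathcal{T}(I + p \odot M)),$$

by projected sign-gradient descent with step size

$$\alpha = \frac{\epsilon\,\theta\,B}{255\,L\,N},$$

clamping $p$ to $[-\epsilon/255, +\epsilon/255]$ after every step. Over the
$LN/B$ steps of a full run the updates sum to $\theta$ times the bound, so
$\theta$ controls how hard the pattern is driven into the box: large
$\theta$ produces a bimodal pattern saturated at $\pm\epsilon$ and strong
same-encoder attacks; intermediate $\theta$ transfers better to other
encoders. Defaults are $\epsilon = 20$ (8-bit units), $\theta = 10$,
$L = 10$ epochs, $B = 5$, $N = 900$, giving $\alpha = 4.35\times10^{-4}$.

Two regularisers improve transfer to encoders never seen during training:

* **Random tile masking.** Each step draws a fresh binary mask `M` activating
  `n_mask` of the encoder's non-overlapping patch-embedding tiles (default
  130 of 256, about 51%); only masked pixels receive an update that step.
* **Attention-gradient bypass.** During the attacked branch's backward pass
  the post-softmax attention weights are treated as constants: gradients flow
  through the value path and every other layer, but not through the
  query/key attention-weight computation. Forward values are untouched. This
  steers the pattern toward local, tile-level features rather than
  model-specific token-coupling patterns. The contract stops differentiation
  exactly at the post-softmax attention-weight tensor; gradients through
  LayerNorm and the softmax temperature elsewhere are unaffected, which is
  one of several defensible readings of "zero the self-attention gradient" —
  it is the one that keeps the value path exact, and it is frozen here as the
  package's convention and verified against a frozen-attention
  finite-difference oracle.

Perturbations live in normalised `[0, 1]` intensity space; `epsilon` is
user-facing in 8-bit units and converted as `epsilon/255`. During training
the attacked intensities are continuous and unrounded; only evaluation-time
application (`apply_perturbation()`) clips to `[0, 255]` and quantises to
8 bits, rounding half-to-even. Clean-branch features are computed once per
image and cached — they cannot change, since the encoder is frozen.
`sign(0)` is defined as 0 (no update where a gradient is exactly zero), and
batches are drawn as seeded epoch-wise permutations, which makes a full
training run bit-reproducible from its configuration in single-threaded BLAS.

The printed step-size formula is implemented as a constant per-run $\alpha$;
a per-step schedule would be an easy extension, but nothing in the method
requires one, and the constant form is what makes the printed
$\alpha = 4.35\times 10^{-4}$ dimensionally meaningful.

### Specialised attacks

`psap_train()` (one image) and `csap_train()` (one class) run signed
gradient *ascent* on the probe's cross-entropy, clamped to an L-infinity
bound each step (100 steps of 0.01 by default). Their default bound is 4
(8-bit units), not the universal attack's 20: a bespoke attack on a known
patch needs only the smallest budget that defeats that patch, and on the
bundled encoder budgets far beyond it make the "specialised" pattern behave
like a weak universal attack — which contradicts its defining property. The
bound is exposed for users who want to study that crossover; the
specialisation analysis in the tests is sensitive to it.

`fgsm()` moves every pixel once by `magnitude * sign(dCE/dI)`; its default
magnitude `20/255` matches the universal budget for a fair baseline
comparison.

## The bundled encoder

`build_tiny_vit()` constructs a frozen, seeded, randomly initialised vision
transformer: 14-pixel patch embedding, learned CLS token and positional
embeddings, two pre-norm transformer blocks (3-head self-attention via
query/key/value projections, 4x GELU MLP, LayerNorm, residuals) and a final
LayerNorm; default width 192 at 224-pixel input. Both the forward pass and
the input-gradient backward pass (with and without the attention bypass) are
written out explicitly and checked against central finite differences to
about `1e-6` relative error.

One deliberate departure from a textbook random initialisation: the patch
embedding is followed by a GELU evaluated at gain 8
(`gelu(8 * (XW + b))`), placing the embedding units in their saturating
regime. A purely linear random embedding gives every tile the same input
Jacobian regardless of content, which makes *any* optimised pattern act
universally — unlike trained transformers, whose sensitivity is strongly
input-selective. The gated embedding restores content-dependent tile
Jacobians at negligible cost and is part of the frozen encoder definition.

External encoders plug in by implementing the same contract: an object of
class `encoder` with `patch_size`, `input_size`, `feature_dim`,
`norm_mean`/`norm_sd`, an `enc_forward()` method returning CLS and patch
tokens, and an `enc_backward()` method exposing input gradients with the
optional attention bypass. No third-party weights ship with the package.

## The synthetic testbed

`generate_synthetic_patches()` renders labelled, H&E-flavoured texture
patches: a per-class background colour (classes spread over the hue circle
with alternating saturation/lightness, so class means are pairwise well
separated), a Poisson number of soft-edged dark elliptical "nuclei" whose
density and size grow with the class index, a per-patch RGB colour jitter
(sd 5 in 8-bit units) emulating staining variability between specimens, and
i.i.d. Gaussian pixel noise (sd 3). Blob centres are placed with a
minimum-separation rejection rule so rendered blob counts are checkable by
connected-component labelling. Generation is a pure function of its
configuration, seed included.

What the generator emulates — and what it does not. It reproduces the
*statistical situation* of tissue-type classification: strongly separable
classes with non-trivial within-class diversity, discriminative structure at
both low (colour) and mid (blob texture) spatial frequencies, and robustness
of a linear probe to unstructured noise. It does not reproduce stain
physics, spatial tissue architecture, scanner artifacts, or the learned
(rather than random) feature geometry of production encoders. Passing tests
on this testbed therefore demonstrate correctness and the *direction* of
every effect (attackability, transfer, defense, adaptive bypass, detection),
not clinical effect sizes.

A known limitation follows from the random encoder: its high-gain
adversarial directions are weight-dominated and shared across images, so a
patch-specific pattern at its flip budget still transfers to other images of
the *same class* much more readily than for trained encoders, whose local
sensitivity is image-specific. The within-class specialisation gap on this
testbed is correspondingly narrower than the published behaviour of
production models; the hierarchy (patch-specific < class-specific <
universal) is still reproduced.

## The defense loop

`fourier_lpf()` zeroes, per channel, every centred-spectrum coefficient
whose horizontal or vertical frequency index exceeds `k/2`, then inverts and
clips. "Kernel size" is the side of the *retained frequency window* — under
this reading the quoted effective numerical apertures for windows of 50, 20
and 10 pixels (0.123, 0.0491, 0.0246) all follow from a single illumination
wavelength via `NA = lambda * (k/2) / (H * dx)`. The wavelength default is
0.55 um (visible mid-band) and is exposed in `lpf_config()` since it is an
assumption, not a measurement. The retained window is symmetric about DC
(`|f| <= k/2`, i.e. k+1 bins per axis for even k) rather than a literal
k-bin half-open slice: symmetry makes the filtered image exactly real and
the pre-clip filter an exact idempotent, self-adjoint spectral projection —
which is also what makes gradients through the in-loop filter exact (the
projection is its own adjoint).

`lpf_resilient_utap()` is the adaptive attack: identical training with the
filter inserted before preprocessing in the attacked branch, so the
optimisation concentrates its budget in the retained band and survives the
deployed defense.

The desk-scale tests transport the reference 50-pixel window on a 224-pixel
field to the 56-pixel test field by preserving the effective NA:
`k = round(50 * 56/224) = 13`.

## The detector

`detector_train()` fits a plain convolutional stack (stride-2 3x3
convolutions + ReLU, global average pooling, linear head) with binary
cross-entropy, Adam, a validation split and best-weights early stopping.
Two variants are sized to parameter budgets — "light" (679,553 parameters,
under 0.70M) and "large" (about 16.9M, under 17.5M) — the budgets, not a
specific architecture, being the design constraint. Convolutions are im2col
matrix products; parameter counts are exact (`count_params()`).

## Linear probing and reporting

`train_linear_probe()` minimises mean cross-entropy plus an L2 penalty
`l2_strength * ||W||^2` by L-BFGS (R's `optim`) from a zero initialisation,
capped at 100 iterations, making fits deterministic. The default
`l2_strength = 1/n` keeps the penalty's share of the objective stable across
sample sizes; the reference protocol does not print its constant, so the
value is exposed. Probes are always trained on clean features only. Argmax
ties break to the lowest class index. Accuracy is reported in percent and
attack efficacy as `drop = original - attacked`; `transfer_matrix()`
evaluates every (training encoder, attacked encoder) pair on patches unseen
by both probe and attack training. The mean silhouette width over class
labels (`silhouette_score()`) quantifies the "cluster collapse" of attacked
feature spaces that the PCA/UMAP projections show qualitatively.

## Numerical conventions and problem sizes

All computation is double precision; determinism claims assume
single-threaded BLAS. Images are row-major with origin top-left; tiles are
ordered row-major on the grid. The test suite exercises the full pipeline at
a reduced problem size chosen as the package's own benchmark geometry:
56-pixel patches (a 4x4 tile grid at patch size 14), a width-96 two-block
encoder, nine classes, 225 attack-training patches (25 per class, the same
100-per-class balance as the reference protocol at desk scale), 180 probe
patches and 270 held-out patches; masks activate 8 of 16 tiles (~51%,
matching the reference coverage). The published budget constants
(`epsilon = 20`, `theta = 10`, `L = 10`, `B = 5`) are used unchanged; with
them the attack saturates its bound regardless of `N`, so the reduced image
count changes runtime, not the attack's operating regime.
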