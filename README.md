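# utapr

Universal adversarial perturbations for frozen image feature extractors, in R.

## The problem

Computational-pathology pipelines increasingly consist of a large **frozen
feature extractor** (a vision transformer trained on millions of slides) plus
a light **linear probe** trained on its CLS features. This architecture has a
system-level weakness: a single, fixed, visually imperceptible noise pattern
— a *universal adversarial perturbation* — can be optimised so that adding it
to **any** input patch corrupts the encoder's feature representation, and the
same pattern keeps working on images and even on encoders it never saw.

`utapr` is a toolkit for studying this threat and its countermeasures. It is
aimed at researchers evaluating the adversarial robustness of frozen image
encoders ("ethical hacking" of their own pipelines), and it is fully testable
on a laptop: it bundles a deterministic tiny vision transformer and a
synthetic generator of H&E-like textured patches, so no proprietary weights
or datasets are required. External encoders plug in through a documented
contract.

## The method

The universal attack optimises a pattern `p` with `max|p| <= eps/255` by
projected sign-gradient descent, minimising the cosine similarity

    CosSim(f_ori, f_atk) = (f_ori . f_atk) / (||f_ori|| ||f_atk||)

between clean and attacked CLS features over a training set, with step size

    alpha = eps * theta * B / (255 * L * N)

(defaults `eps = 20`, `theta = 10`, `B = 5`, `L = 10`, `N = 900`, i.e.
`alpha = 4.35e-4`), a fresh random tile mask per step (130 of 256 tiles,
about 51%), and an attention-gradient bypass in the attacked branch's
backward pass ("pay no attention"): post-softmax attention weights are
treated as constants so the pattern targets local, transferable features.

Around this core the package provides patch-specific (`psap_train()`) and
class-specific (`csap_train()`) cross-entropy attacks, the FGSM baseline
(`fgsm()`), a Fourier low-pass-filter defense with effective numerical
aperture accounting (`fourier_lpf()`, `effective_na()`), the adaptive
filter-resilient attack (`lpf_resilient_utap()`), a convolutional attack
detector (`detector_train()`), and a linear-probing evaluation harness
(`train_linear_probe()`, `transfer_matrix()`, `attention_heatmap()`,
`project_features()`).

## Worked example

A complete attack-and-evaluate loop on the bundled testbed (about a minute
on one CPU):

```r
library(utapr)

make <- function(seed, per_class)
  generate_synthetic_patches(synthesis_config(
    n_classes = 9, per_class = per_class, image_size = 56, seed = seed))

train_set <- make(101, 25)   # 225 patches to optimise the attack on
probe_set <- make(102, 20)   # 180 patches to fit the linear probe
test_set  <- make(103, 30)   # 270 held-out patches

encoder <- build_tiny_vit(seed = 7, input_size = 56, width = 96, heads = 3)
probe   <- train_linear_probe(feature_matrix(encoder, probe_set),
                              probe_set$labels)

clean_acc <- evaluate_probe(probe, feature_matrix(encoder, test_set),
                            test_set$labels)

fit <- utap_train(train_set, encoder,
                  attack_config(n_train = 225, n_mask = 8, seed = 11))
attacked <- apply_perturbation(test_set, fit$perturbation)
atk_acc  <- evaluate_probe(probe, feature_matrix(encoder, attacked),
                           test_set$labels)

cat(sprintf("clean %.2f%%  attacked %.2f%%  drop %.2f points\n",
            clean_acc, atk_acc, accuracy_drop(clean_acc, atk_acc)))
#> clean 100.00%  attacked 27.41%  drop 72.59 points
```

The probe classifies the nine synthetic texture classes perfectly from the
frozen features; adding the single fixed pattern (bounded at ±20 of 255
intensity levels, visually negligible) to every held-out patch collapses
accuracy to 27%. A matched *random* pattern at the same bound changes
accuracy by less than a point — the potency comes from the optimised
structure, not the energy:

```r
noise <- perturbation(array(runif(56 * 56 * 3, -20/255, 20/255),
                            c(56, 56, 3)), 20)
evaluate_probe(probe, feature_matrix(encoder,
               apply_perturbation(test_set, noise)), test_set$labels)
#> [1] 100
```

Defending with a low-pass filter restores accuracy but costs optical
resolution — a window of 13 frequency bins on this 56-pixel field has the
resolution of a 0.13-NA objective (`effective_na(lpf_config(13), 56)`) —
and an adaptive attacker who trains through the filter
(`lpf_resilient_utap()`) breaks the defense again. See the methods vignette
(`vignettes/adversarial-perturbations.Rmd`) for the full story.

A command-line wrapper over the same functions is installed with the
package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "utapr-cli.R", package = "utapr"))')" \
    synth --seed 3 --out data --n-classes 9 --per-class 25 --image-size 56
```

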