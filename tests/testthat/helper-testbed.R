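# Shared desk-scale testbed, built lazily and cached for the whole run.
#
# Nine texture classes at 56x56 pixels (4x4 tile grid at patch size 14), a
# frozen tiny ViT of width 96, a linear probe fit on clean features of a
# disjoint patch set, and cached universal-attack runs. The universal attack
# uses the published budget (epsilon 20, theta 10, L 10, B 5, about 51% of
# tiles masked per step) on 225 training patches.

tb_cache <- new.env(parent = emptyenv())

tb_get <- function(name, builder) {
  if (!exists(name, envir = tb_cache)) assign(name, builder(), envir = tb_cache)
  get(name, envir = tb_cache)
}

tb_synth <- function(seed, per_class) {
  generate_synthetic_patches(synthesis_config(
    n_classes = 9L, per_class = per_class, image_size = 56L, seed = seed))
}

tb_sets <- function() tb_get("sets", function() {
  list(train = tb_synth(101, 25),   # universal-attack training patches (225)
       probe = tb_synth(102, 20),   # probe training patches
       test  = tb_synth(103, 30),   # held-out evaluation patches
       extra = tb_synth(104, 30))   # second held-out pool (pairing controls)
})

tb_encoder <- function() tb_get("enc", function()
  build_tiny_vit(seed = 7, input_size = 56, width = 96, heads = 3))

tb_encoder2 <- function() tb_get("enc2", function()
  build_tiny_vit(seed = 8, input_size = 56, width = 96, heads = 3))

tb_probe <- function() tb_get("probe", function()
  train_linear_probe(feature_matrix(tb_encoder(), tb_sets()$probe),
                     tb_sets()$probe$labels))

tb_probe2 <- function() tb_get("probe2", function()
  train_linear_probe(feature_matrix(tb_encoder2(), tb_sets()$probe),
                     tb_sets()$probe$labels))

tb_test_features <- function() tb_get("test_features", function()
  feature_matrix(tb_encoder(), tb_sets()$test))

tb_attack_cfg <- function(...) attack_config(n_train = 225, n_mask = 8,
                                             seed = 11, ...)

tb_utap <- function() tb_get("utap", function()
  utap_train(tb_sets()$train, tb_encoder(), tb_attack_cfg()))

tb_utap2 <- function() tb_get("utap2", function()
  utap_train(tb_sets()$train, tb_encoder2(), tb_attack_cfg()))

# Low-pass window matching the effective numerical aperture of the reference
# 50-pixel window on a 224-pixel field (0.123), transported to the 56-pixel
# desk-scale field: k = round(50 * 56 / 224) = 13.
tb_lpf <- function() lpf_config(13)

tb_resilient <- function() tb_get("resilient", function()
  lpf_resilient_utap(tb_sets()$train, tb_encoder(),
                     tb_attack_cfg(lpf_in_loop = tb_lpf())))

tb_accuracy <- function(ps, encoder = tb_encoder(), probe = tb_probe()) {
  evaluate_probe(probe, feature_matrix(encoder, ps), ps$labels)
}

# small encoder for gradient-oracle tests: 28x28 input, 4 patch tokens
tb_small_vit <- function(heads = 3, width = 24) {
  build_tiny_vit(seed = 1, input_size = 28, width = width, heads = heads)
}

# central finite differences of f at x (array), all entries
fd_gradient <- function(f, x, h = 1e-3) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}
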