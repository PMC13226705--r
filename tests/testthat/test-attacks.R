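# Attack primitives and optimisers: step size, masking, losses, perturbation
# application, and gradient-oracle checks of the update rules.

test_that("the PGD step size follows the published budget formula", {
  expect_equal(compute_step_size(20, 10, 5, 10, 900), 1000 / 2295000)
  expect_equal(compute_step_size(0, 10, 5, 10, 900), 0)
  expect_equal(compute_step_size(255, 1, 1, 1, 1), 1)
  expect_error(compute_step_size(20, 10, 5, 0, 900), "positive")
})

test_that("random tile masks have exact tile and pixel counts", {
  m0 <- random_tile_mask(0)
  expect_true(all(m0$grid == 0) && all(m0$pixels == 0))
  m_full <- random_tile_mask(256)
  expect_true(all(m_full$grid == 1))
  p <- perturbation(array(runif(224 * 224 * 3, -0.05, 0.05), c(224, 224, 3)), 20)
  img <- array(100, c(224, 224, 3))
  expect_equal(apply_perturbation(img, p, m_full), apply_perturbation(img, p))
  expect_error(random_tile_mask(257), "\\[0, 256\\]")
  for (n_mask in c(1, 64, 130, 200)) {
    m <- random_tile_mask(n_mask)
    expect_equal(sum(m$grid), n_mask)
    expect_equal(sum(m$pixels), n_mask * 14^2)
    expect_equal(dim(m$pixels), c(224L, 224L))
    # pixel map is the exact tile expansion of the grid
    expect_equal(m$pixels, m$grid[rep(1:16, each = 14), rep(1:16, each = 14)])
  }
})

test_that("cosine similarity matches hand arithmetic and rejects zero vectors", {
  f <- rnorm(10)
  expect_equal(cosine_similarity(f, f), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2, 3), c(4, 5, 6)),
               32 / (sqrt(14) * sqrt(77)), tolerance = 1e-12)
  expect_equal(round(cosine_similarity(c(1, 2, 3), c(4, 5, 6)), 6), 0.974632)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero")
  # symmetry and scale invariance
  a <- rnorm(8); b <- rnorm(8)
  expect_equal(cosine_similarity(a, b), cosine_similarity(b, a))
  expect_equal(cosine_similarity(3.7 * a, b), cosine_similarity(a, b))
})

test_that("one-hot cross-entropy uses the stable closed forms", {
  expect_equal(cross_entropy_onehot(c(1, rep(0, 8)), rep(0.3, 9)), log(9))
  expect_equal(cross_entropy_onehot(c(1, 0), c(1, 0)), log(1 + exp(-1)))
  z <- rnorm(5); gt <- c(0, 0, 1, 0, 0)
  expect_equal(cross_entropy_onehot(gt, z), cross_entropy_onehot(gt, z + 17))
  # CE decreases monotonically as the true-class margin grows
  ces <- vapply(c(0, 1, 2, 4), function(m)
    cross_entropy_onehot(c(1, 0, 0), c(m, 0, 0)), numeric(1))
  expect_true(all(diff(ces) < 0))
  expect_error(cross_entropy_onehot(c(1, 1, 0), rnorm(3)), "one-hot")
  expect_error(cross_entropy_onehot(c(1, 0), c(Inf, 0)), "finite")
})

test_that("perturbation application clips, rounds half-to-even and masks", {
  img <- array(100, c(28, 28, 3))
  p0 <- perturbation(array(0, c(28, 28, 3)), 20)
  expect_equal(apply_perturbation(img, p0), img)
  p <- perturbation(array(20 / 255, c(28, 28, 3)), 20)
  expect_true(all(apply_perturbation(img, p) == 120))
  expect_true(all(apply_perturbation(array(255, c(28, 28, 3)), p) == 255))
  # round-half-to-even at the 8-bit quantisation step
  ph <- perturbation(array(0.5 / 255, c(28, 28, 3)), 20)
  expect_true(all(apply_perturbation(array(100, c(28, 28, 3)), ph) == 100))
  expect_true(all(apply_perturbation(array(101, c(28, 28, 3)), ph) == 102))
  expect_error(apply_perturbation(array(1, c(14, 14, 3)), p), "match")
})

test_that("a single universal-attack step equals the finite-difference oracle", {
  # toy linear encoder on 8x8 single-channel images: the whole input is one
  # tile, so the mask is the identity. The logit objective is used because
  # the cosine objective is stationary at p = 0 (attacked and clean features
  # coincide at the cosine maximum), making a single-step oracle ill-posed;
  # the cosine *gradient machinery* is finite-difference-checked at
  # non-degenerate points in the encoder tests.
  enc <- build_linear_encoder(seed = 3, input_size = 8, channels = 1,
                              feature_dim = 16,
                              norm_mean = 0.5, norm_sd = 0.5)
  set.seed(7)
  imgs <- lapply(1:2, function(i) array(runif(64) * 255, c(8, 8, 1)))
  ps <- structure(list(images = imgs, labels = c(0L, 1L),
                       class_names = c("a", "b"), ids = c("i1", "i2")),
                  class = "image_patch_set")
  probe <- train_linear_probe(matrix(rnorm(40 * 16), 40), rep(0:3, 10))
  cfg <- attack_config(theta = 0.5, epochs = 1, batch = 2, n_train = 2,
                       n_mask = 1, seed = 1, objective = "cross_entropy")
  res <- utap_train(ps, enc, cfg, probe = probe)
  alpha <- compute_step_size(20, 0.5, 2, 1, 2)
  mean_ce <- function(pvec) {
    p <- array(pvec, c(8, 8, 1))
    mean(vapply(1:2, function(i) {
      f <- enc_forward(enc, utapr:::normalize01(imgs[[i]] / 255 + p, enc))$cls
      cross_entropy_onehot(as.numeric(seq_len(4) == ps$labels[i] + 1),
                           as.vector(utapr:::probe_logits(probe, f)))
    }, numeric(1)))
  }
  fd <- fd_gradient(mean_ce, numeric(64), h = 1e-4)
  # cross-entropy is maximised: one step of +alpha * sign(d mean-CE / dp)
  expect_equal(as.vector(res$perturbation$values),
               as.vector(alpha * sign(fd)), tolerance = 1e-9)
  expect_equal(nrow(res$trace), 1L)
})

test_that("universal training obeys budget, masking locality and determinism", {
  ps <- tb_synth(41, 4)                      # 36 patches at 56x56
  enc <- build_tiny_vit(seed = 2, input_size = 56, width = 48, heads = 3)
  cfg <- attack_config(epochs = 2, batch = 6, n_train = 36, n_mask = 5,
                       seed = 9)
  res <- utap_train(ps, enc, cfg)
  # trace length L*N/B and per-step bound conservation
  expect_equal(nrow(res$trace), 2 * 36 / 6)
  expect_true(all(res$trace$max_abs_p <= 20 / 255 + 1e-15))
  expect_lte(max(abs(res$perturbation$values)), 20 / 255)
  # masking locality: after one step only masked tiles can be non-zero
  cfg1 <- attack_config(epochs = 1, batch = 36, n_train = 36, n_mask = 5,
                        seed = 9)
  res1 <- utap_train(ps, enc, cfg1)
  tile_nonzero <- vapply(1:16, function(t) {
    r <- (t - 1) %/% 4; c <- (t - 1) %% 4
    any(res1$perturbation$values[r * 14 + 1:14, c * 14 + 1:14, ] != 0)
  }, logical(1))
  expect_lte(sum(tile_nonzero), 5)
  # objective decreases from its p = 0 starting value (cosine of 1)
  expect_lt(mean(utils::tail(res$trace$objective, 3)),
            mean(utils::head(res$trace$objective, 3)))
  expect_gt(res$trace$objective[1], 0.9)
  # bit-identical reproducibility for an identical config
  res_b <- utap_train(ps, enc, cfg)
  expect_identical(res$perturbation$values, res_b$perturbation$values)
  expect_identical(res$trace, res_b$trace)
})

test_that("large step-size scaling saturates the perturbation at the bound", {
  ps <- tb_synth(42, 3)[1:20]
  enc <- build_tiny_vit(seed = 2, input_size = 56, width = 48, heads = 3)
  cfg <- attack_config(theta = 100, epochs = 5, batch = 5, n_train = 20,
                       n_mask = 16, seed = 2)
  res <- utap_train(ps, enc, cfg)
  at_bound <- mean(abs(abs(res$perturbation$values) - 20 / 255) < 1e-6)
  expect_gte(at_bound, 0.8)
})

test_that("multi-source training switches encoders at the configured cadence", {
  ps <- tb_synth(43, 4)                      # 36 patches
  encs <- list(a = build_tiny_vit(seed = 2, input_size = 56, width = 48,
                                  heads = 3, name = "a"),
               b = build_tiny_vit(seed = 3, input_size = 56, width = 48,
                                  heads = 3, name = "b"))
  cfg <- attack_config(epochs = 3, batch = 3, n_train = 36, n_mask = 8,
                       seed = 4, switch_interval = 8)
  res <- utap_train(ps, encs, cfg)
  runs <- rle(res$trace$encoder)
  expect_true(all(runs$lengths %% 8 == 0 | cumsum(runs$lengths) == nrow(res$trace)))
  expect_setequal(unique(res$trace$encoder), c("a", "b"))
  expect_lte(max(abs(res$perturbation$values)), 20 / 255)
})

test_that("patch-specific ascent increases cross-entropy within its bound", {
  sets <- tb_sets(); enc <- tb_encoder(); probe <- tb_probe()
  img <- sets$test$images[[1]]; lab <- sets$test$labels[1]
  pt <- psap_train(img, lab, enc, probe, steps = 40)
  expect_lte(max(abs(pt$values)), 4 / 255)
  ce_of <- function(im) {
    f <- feature_matrix(enc, list(im))
    cross_entropy_onehot(as.numeric(seq_len(9) == lab + 1),
                         as.vector(utapr:::probe_logits(probe, f)))
  }
  expect_gt(ce_of(apply_perturbation(img, pt)), ce_of(img))
})

test_that("a single patch-specific step matches the finite-difference oracle", {
  enc <- build_linear_encoder(seed = 5, input_size = 8, channels = 1,
                              feature_dim = 12,
                              norm_mean = 0.5, norm_sd = 0.5)
  set.seed(8)
  feats <- matrix(rnorm(40 * 12), 40)
  labs <- rep(0:3, 10)
  probe <- train_linear_probe(feats, labs)
  img <- array(runif(64) * 255, c(8, 8, 1))
  pt <- psap_train(img, 2L, enc, probe, steps = 1, step_size = 0.007,
                   bound = 20)
  ce_of <- function(v) {
    f <- enc_forward(enc, utapr:::normalize01(img / 255 + array(v, c(8, 8, 1)),
                                              enc))$cls
    cross_entropy_onehot(as.numeric(seq_len(4) == 3),
                         as.vector(utapr:::probe_logits(probe, f)))
  }
  fd <- fd_gradient(ce_of, numeric(64), h = 1e-4)
  expect_equal(as.vector(pt$values), as.vector(0.007 * sign(fd)),
               tolerance = 1e-9)
})

test_that("class-specific training reduces to patch-specific on one image", {
  sets <- tb_sets(); enc <- tb_encoder(); probe <- tb_probe()
  img <- sets$test$images[[2]]; lab <- sets$test$labels[2]
  one <- sets$test[2]
  p_ps <- psap_train(img, lab, enc, probe, steps = 15)
  p_cs <- csap_train(one, lab, enc, probe, steps = 15, batch = 1, seed = 1)
  expect_equal(p_cs$values, p_ps$values)
  expect_lte(max(abs(p_cs$values)), 4 / 255)
  expect_error(csap_train(list(), 0L, enc, probe), "empty")
  expect_error(csap_train(sets$test[1:3], 99L, enc, probe), "share")
})

test_that("the gradient-sign baseline has exact single-step structure", {
  sets <- tb_sets(); enc <- tb_encoder(); probe <- tb_probe()
  img <- sets$test$images[[3]]; lab <- sets$test$labels[3]
  expect_equal(fgsm(img, lab, enc, probe, magnitude = 0), img)
  mag <- 8 / 255
  atk <- fgsm(img, lab, enc, probe, magnitude = mag)
  delta <- atk / 255 - img / 255
  interior <- img > 16 & img < 239 & abs(delta) > 1e-9
  expect_true(all(abs(abs(delta[interior]) * 255 - 8) <= 0.5 + 1e-9))
  expect_true(all(atk >= 0 & atk <= 255))
})

test_that("the gradient-sign pattern matches finite differences on the toy encoder", {
  enc <- build_linear_encoder(seed = 6, input_size = 8, channels = 1,
                              feature_dim = 12,
                              norm_mean = 0.5, norm_sd = 0.5)
  set.seed(9)
  feats <- matrix(rnorm(40 * 12), 40)
  probe <- train_linear_probe(feats, rep(0:3, 10))
  img <- array(runif(64) * 255, c(8, 8, 1))
  gi <- utapr:::ce_input_gradient(enc, probe, img / 255, 1L)
  ce_of <- function(v) {
    f <- enc_forward(enc, utapr:::normalize01(img / 255 + array(v, c(8, 8, 1)),
                                              enc))$cls
    cross_entropy_onehot(as.numeric(seq_len(4) == 2),
                         as.vector(utapr:::probe_logits(probe, f)))
  }
  fd <- fd_gradient(ce_of, numeric(64), h = 1e-4)
  tied <- abs(fd) < 1e-10
  expect_gte(mean(sign(gi$grad[!tied]) == sign(fd[!tied])), 0.99)
})
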