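# Linear probing, transfer reporting, heatmaps, projections and perturbation
# rendering.

test_that("the probe solves a symmetric separable problem deterministically", {
  feats <- matrix(c(-1, 1), 2, 1)
  probe <- train_linear_probe(feats, c(0L, 1L), l2_strength = 1e-6)
  expect_equal(evaluate_probe(probe, feats, c(0L, 1L)), 100)
  # decision boundary: z0(x) = z1(x) at x*
  x_star <- -(probe$bias[1] - probe$bias[2]) /
    (probe$weights[1, 1] - probe$weights[2, 1])
  expect_lt(abs(x_star), 0.1)
  probe_b <- train_linear_probe(feats, c(0L, 1L), l2_strength = 1e-6)
  expect_identical(probe$weights, probe_b$weights)   # zero-init determinism
  expect_identical(probe$bias, probe_b$bias)
  # the optimised objective improves on the zero-initialisation value log(C)
  expect_lt(probe$objective, log(2))
  expect_error(train_linear_probe(feats, c(1L, 1L)), "2 classes")
  expect_error(train_linear_probe(matrix(c(NaN, 1), 2, 1), c(0L, 1L)),
               "finite")
})

test_that("the quasi-Newton fit matches a slow gradient-descent oracle", {
  set.seed(20)
  n <- 200; d <- 4; C <- 4
  centers <- matrix(rnorm(C * d, sd = 2), C)
  labs <- rep(0:(C - 1), each = n / C)
  feats <- centers[labs + 1, ] + matrix(rnorm(n * d, sd = 0.8), n)
  l2 <- 1 / n
  probe <- train_linear_probe(feats, labs, l2_strength = l2)
  # full-batch plain gradient descent, 10k small steps, shared objective
  Y <- matrix(0, n, C); Y[cbind(1:n, labs + 1)] <- 1
  W <- matrix(0, C, d); b <- rep(0, C)
  obj <- function(W, b) {
    Z <- feats %*% t(W) + rep(b, each = n)
    m <- apply(Z, 1, max)
    mean(m + log(rowSums(exp(Z - m))) - Z[cbind(1:n, labs + 1)]) +
      l2 * sum(W^2)
  }
  for (it in 1:10000) {
    Z <- feats %*% t(W) + rep(b, each = n)
    P <- exp(Z - apply(Z, 1, max)); P <- P / rowSums(P)
    R <- P - Y
    W <- W - 0.5 * (crossprod(R, feats) / n + 2 * l2 * W)
    b <- b - 0.5 * colMeans(R)
  }
  expect_equal(probe$objective, obj(W, b), tolerance = 1e-4)
})

test_that("accuracy and drop arithmetic follow the reporting conventions", {
  feats <- diag(3)
  probe <- train_linear_probe(rbind(feats, feats), rep(0:2, 2))
  expect_equal(evaluate_probe(probe, feats, 0:2), 100)
  expect_equal(accuracy_drop(97.37, 12.27), 85.10)
  expect_equal(accuracy_drop(50, 50), 0)
  expect_equal(accuracy_drop(90, 70) + accuracy_drop(70, 30),
               accuracy_drop(90, 30))
  expect_error(evaluate_probe(probe, feats[0, , drop = FALSE], integer(0)),
               "empty")
})

test_that("argmax prediction breaks ties toward the lowest class index", {
  probe <- structure(list(weights = matrix(0, 3, 2), bias = c(1, 1, 0),
                          n_classes = 3L), class = "probe_model")
  expect_equal(predict_probe(probe, matrix(rnorm(10), 5, 2)), rep(0L, 5))
})

test_that("the transfer matrix honours its indexing and zero-attack contracts", {
  sets <- tb_sets()
  test_small <- sets$test[1:45]
  encs <- list(`tiny-vit-7` = tb_encoder(), `tiny-vit-8` = tb_encoder2())
  probes <- list(`tiny-vit-7` = tb_probe(), `tiny-vit-8` = tb_probe2())
  zero <- perturbation(array(0, c(56, 56, 3)), 20)
  rep0 <- transfer_matrix(list(`tiny-vit-7` = zero, `tiny-vit-8` = zero),
                          encs, test_small, probes)
  expect_equal(rep0$attacked_acc, rep0$original_acc)
  expect_true(all(rep0$drop == 0))
  expect_equal(rownames(rep0$drop), names(encs))
  expect_equal(colnames(rep0$drop), names(encs))
  expect_error(transfer_matrix(list(`tiny-vit-7` = zero), encs, test_small,
                               probes["tiny-vit-7"]), "tiny-vit-8")
})

test_that("internal attacks dominate external transfer on the testbed", {
  sets <- tb_sets()
  encs <- list(`tiny-vit-7` = tb_encoder(), `tiny-vit-8` = tb_encoder2())
  probes <- list(`tiny-vit-7` = tb_probe(), `tiny-vit-8` = tb_probe2())
  perts <- list(`tiny-vit-7` = tb_utap()$perturbation,
                `tiny-vit-8` = tb_utap2()$perturbation)
  rep <- transfer_matrix(perts, encs, sets$test, probes)
  expect_true(all(rep$original_acc >= 0 & rep$original_acc <= 100))
  expect_true(all(rep$attacked_acc >= 0 & rep$attacked_acc <= 100))
  expect_equal(rep$drop, rep$original_acc - rep$attacked_acc)
  for (s in rownames(rep$drop))
    expect_gte(rep$drop[s, s], max(rep$drop[s, colnames(rep$drop) != s]))
  # external transfer still degrades the victim (direction-only claim)
  expect_gt(min(rep$drop), 0)
})

test_that("attention heatmaps have the token-grid shape and cosine bounds", {
  sets <- tb_sets()
  hm <- attention_heatmap(sets$test$images[[1]], tb_encoder())
  expect_equal(dim(unclass(hm)), c(4L, 4L))
  expect_true(all(hm >= -1 & hm <= 1))
  enc224 <- build_tiny_vit(seed = 0)
  img224 <- array(rep(sets$test$images[[2]], 16)[1:(224 * 224 * 3)],
                  c(224, 224, 3))
  hm224 <- attention_heatmap(img224, enc224)
  expect_equal(dim(unclass(hm224)), c(16L, 16L))
})

test_that("heatmaps are exact for a stub encoder and scale-invariant", {
  stub <- structure(list(input_size = 28L, patch_size = 14L,
                         norm_mean = c(0.5, 0.5, 0.5),
                         norm_sd = c(0.5, 0.5, 0.5), feature_dim = 4L),
                    class = c("stub_encoder", "encoder"))
  registerS3method("enc_forward", "stub_encoder",
                   function(encoder, xnorm, want_cache = FALSE,
                            fixed_attention = NULL) {
                     cls <- c(1, 2, 3, 4)
                     list(cls = cls,
                          patch_tokens = matrix(rep(cls, each = 4), 4))
                   }, envir = asNamespace("utapr"))
  img <- array(100, c(28, 28, 3))
  hm <- attention_heatmap(img, stub)
  expect_equal(unclass(hm), matrix(1, 2, 2))
  registerS3method("enc_forward", "stub_encoder",
                   function(encoder, xnorm, want_cache = FALSE,
                            fixed_attention = NULL) {
                     cls <- c(1, 2, 3, 4)
                     list(cls = cls,
                          patch_tokens = 7.3 * matrix(rep(cls, each = 4), 4))
                   }, envir = asNamespace("utapr"))
  expect_equal(unclass(attention_heatmap(img, stub)), matrix(1, 2, 2))
})

test_that("feature projections are deterministic with fixed conventions", {
  set.seed(30)
  line <- outer(seq(-2, 2, length.out = 20), c(1, 2, -1))
  pc <- project_features(line, "pca")
  expect_equal(dim(pc), c(20L, 2L))
  expect_lt(stats::var(pc[, 2]) / stats::var(pc[, 1]), 1e-10)
  expect_identical(pc, project_features(line, "pca"))
  expect_error(project_features(line[1:2, ], "pca"), ">= 3")
})

test_that("the seeded nonlinear embedding is reproducible", {
  set.seed(31)
  feats <- rbind(matrix(rnorm(60, 0), 15),
                 matrix(rnorm(60, 6), 15))
  u1 <- project_features(feats, "umap", seed = 5, n_neighbors = 5)
  u2 <- project_features(feats, "umap", seed = 5, n_neighbors = 5)
  expect_equal(dim(u1), c(30L, 2L))
  expect_equal(unname(as.matrix(u1)), unname(as.matrix(u2)))
})

test_that("perturbation rendering follows the gray-background convention", {
  p0 <- perturbation(array(0, c(28, 28, 3)), 20)
  r0 <- render_perturbation(p0)
  expect_true(all(r0$image == 128))
  pe <- perturbation(array(20 / 255, c(28, 28, 3)), 20)
  re <- render_perturbation(pe)
  expect_true(all(re$image == 148))
  set.seed(8)
  pr <- perturbation(array(runif(28 * 28 * 3, -20 / 255, 20 / 255),
                           c(28, 28, 3)), 20)
  rr <- render_perturbation(pr)
  expect_true(all(rr$values_8bit >= -20 & rr$values_8bit <= 20))
  expect_s3_class(rr$histogram, "histogram")
})

test_that("mean silhouette width behaves as a separability index", {
  set.seed(40)
  tight <- rbind(matrix(rnorm(40, 0, 0.1), 20),
                 matrix(rnorm(40, 5, 0.1), 20))
  labs <- rep(0:1, each = 20)
  expect_gt(silhouette_score(tight, labs), 0.9)
  mixed <- matrix(rnorm(80), 40)
  expect_lt(silhouette_score(mixed, labs), 0.3)
  expect_error(silhouette_score(tight, rep(0, 40)), "2 classes")
})
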