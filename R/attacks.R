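# Adversarial perturbation attacks on frozen encoders.
#
# The universal attack optimises a single L-infinity-bounded pattern by
# sign-gradient projected descent on the cosine similarity between clean and
# attacked CLS features, with a fresh random tile mask each step and the
# attention-gradient bypass active on the attacked branch's backward pass.
# Patch- and class-specific attacks instead *maximise* the cross-entropy of a
# pretrained linear probe; the fast gradient-sign method is the single-step
# baseline.

#' PGD step size from the attack budget
#'
#' `alpha = epsilon * theta * B / (255 * L * N)`, in normalised intensity
#' units per step. With the default budget (`epsilon = 20`, `theta = 10`,
#' `B = 5`, `L = 10`, `N = 900`) this is 4.35e-4, and the `L * N / B = 1800`
#' optimisation steps sum to `theta` times the bound, guaranteeing the bound
#' can saturate.
#'
#' @param epsilon_8bit perturbation bound in 8-bit units.
#' @param theta dimensionless step-size scaling factor.
#' @param batch batch size `B`.
#' @param epochs number of passes `L` over the training images.
#' @param n_train number of training images `N`.
#' @return step size `alpha` (numeric scalar).
#' @export
compute_step_size <- function(epsilon_8bit, theta, batch, epochs, n_train) {
  if (epochs <= 0 || n_train <= 0) stop("epochs and n_train must be positive")
  epsilon_8bit * theta * batch / (255 * epochs * n_train)
}

#' Random tile mask
#'
#' Partitions a `grid_size * tile_size` square image into non-overlapping
#' `tile_size x tile_size` tiles (the encoder's patch grid) and activates
#' `n_mask` tiles chosen uniformly without replacement. Used to regularise
#' the universal attack: each optimisation step only updates the pixels of
#' the active tiles.
#'
#' @param n_mask number of active tiles, `0 <= n_mask <= grid_size^2`.
#' @param grid_size tiles per side (default 16, i.e. 224/14).
#' @param tile_size tile side in pixels (default 14).
#' @return object of class `tile_mask` with fields `grid` (binary
#'   `grid_size x grid_size`) and `pixels` (binary `H x W`).
#' @export
random_tile_mask <- function(n_mask, grid_size = 16L, tile_size = 14L) {
  n_tiles <- grid_size^2
  if (n_mask < 0L || n_mask > n_tiles)
    stop(sprintf("n_mask must lie in [0, %d]", n_tiles))
  grid <- matrix(0L, grid_size, grid_size)
  if (n_mask > 0L) grid[sample.int(n_tiles, n_mask)] <- 1L
  pixels <- grid[rep(seq_len(grid_size), each = tile_size),
                 rep(seq_len(grid_size), each = tile_size)]
  structure(list(grid = grid, pixels = pixels,
                 n_mask = as.integer(n_mask),
                 tile_size = as.integer(tile_size)),
            class = "tile_mask")
}

#' Cosine similarity of two feature vectors
#'
#' `CosSim(f1, f2) = (f1 . f2) / (||f1|| ||f2||)`, the attack objective that
#' is minimised to decorrelate attacked features from clean ones.
#'
#' @param f1,f2 non-zero numeric vectors of equal length.
#' @return scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(f1, f2) {
  n1 <- sqrt(sum(f1^2)); n2 <- sqrt(sum(f2^2))
  if (n1 == 0 || n2 == 0) stop("cosine similarity is undefined for zero vectors")
  sum(f1 * f2) / (n1 * n2)
}

# Gradient of CosSim(f_ori, f) w.r.t. f (f_ori treated as constant).
#' @keywords internal
cosine_grad <- function(f_ori, f) {
  n1 <- sqrt(sum(f_ori^2)); n2 <- sqrt(sum(f^2))
  cs <- sum(f_ori * f) / (n1 * n2)
  f_ori / (n1 * n2) - cs * f / n2^2
}

#' Cross-entropy of logits against a one-hot label
#'
#' `CE(gt, logits) = -sum_i gt_i log(Softmax(logits)_i)`, computed in the
#' numerically stable log-sum-exp form. Invariant to adding a constant to all
#' logits.
#'
#' @param gt one-hot numeric vector of length `C`.
#' @param logits finite numeric vector of length `C`.
#' @return scalar `>= 0`.
#' @export
cross_entropy_onehot <- function(gt, logits) {
  if (length(gt) != length(logits)) stop("gt and logits must have equal length")
  if (!all(gt %in% c(0, 1)) || sum(gt) != 1) stop("gt must be one-hot")
  if (!all(is.finite(logits))) stop("logits must be finite")
  logsumexp(logits) - logits[which(gt == 1)]
}

#' Attack configuration
#'
#' Bundles the optimisation budget of the universal attack. Defaults are the
#' published operating point: `epsilon = 20`, `theta = 10`, `L = 10` epochs,
#' batch `B = 5`, `N = 900` training images, `n_mask = 130` active tiles
#' (about 51% of the 256-tile grid).
#'
#' @param epsilon_8bit L-infinity bound in 8-bit units.
#' @param theta step-size scaling factor.
#' @param epochs passes over the training images.
#' @param batch images per optimisation step.
#' @param n_train number of training images used (`<=` dataset size).
#' @param n_mask active tiles per step (`<=` tile count).
#' @param seed RNG seed for batch order, masks and pool switching.
#' @param objective `"cosine"` (feature decorrelation) or `"cross_entropy"`
#'   (probe-logit attack; requires a probe at train time).
#' @param lpf_in_loop optional [lpf_config()]: pass each attacked batch
#'   through the low-pass filter inside the forward pass, producing a
#'   filter-resilient perturbation.
#' @param pool optional character vector naming the encoders when training
#'   against a pool; the active encoder is redrawn uniformly every
#'   `switch_interval` steps.
#' @param switch_interval steps between pool redraws (default 8).
#' @return object of class `attack_config`.
#' @export
attack_config <- function(epsilon_8bit = 20, theta = 10, epochs = 10L,
                          batch = 5L, n_train = 900L, n_mask = 130L,
                          seed = 1L, objective = c("cosine", "cross_entropy"),
                          lpf_in_loop = NULL, pool = NULL,
                          switch_interval = 8L) {
  objective <- match.arg(objective)
  if (any(c(epsilon_8bit < 0, theta <= 0, epochs < 1, batch < 1, n_train < 1,
            n_mask < 0)))
    stop("attack budget parameters must be positive")
  if (batch > n_train) stop("batch must not exceed n_train")
  structure(list(epsilon_8bit = epsilon_8bit, theta = theta,
                 epochs = as.integer(epochs), batch = as.integer(batch),
                 n_train = as.integer(n_train), n_mask = as.integer(n_mask),
                 seed = as.integer(seed), objective = objective,
                 lpf_in_loop = lpf_in_loop, pool = pool,
                 switch_interval = as.integer(switch_interval)),
            class = "attack_config")
}

#' Train a universal adversarial perturbation
#'
#' Projected sign-gradient descent on the batch-mean cosine similarity
#' between clean and attacked CLS features of a frozen encoder (or a pool of
#' encoders). Per optimisation step: draw the next batch of `B` images from
#' the epoch's random permutation, draw a fresh random tile mask, form the
#' attacked intensities `I/255 + p (*) M` (continuous, unrounded), extract
#' clean features (cached; no bypass) and attacked features (bypass active on
#' the backward pass), then update
#' `p <- Clamp(p - alpha * sign(grad), -eps/255, +eps/255)`. Pixels outside
#' the step's mask receive a zero gradient and hence no update.
#'
#' @param dataset an [image_patch_set()] with at least `n_train` images.
#' @param encoders a single encoder or a named list of encoders (the pool).
#' @param config an [attack_config()].
#' @param probe optional [train_linear_probe()] model, required for the
#'   `"cross_entropy"` objective (maximised, logit-level attack ablation).
#' @return list with `perturbation` (a [perturbation()]) and `trace` (a
#'   data.frame with per-step objective, `max|p|` and active encoder).
#' @export
utap_train <- function(dataset, encoders, config = attack_config(),
                       probe = NULL) {
  stopifnot(inherits(dataset, "image_patch_set"),
            inherits(config, "attack_config"))
  if (inherits(encoders, "encoder")) encoders <- list(encoders)
  if (is.null(names(encoders)) || any(names(encoders) == ""))
    names(encoders) <- vapply(encoders, function(e) e$name, character(1))
  if (n_patches(dataset) < config$n_train)
    stop("dataset smaller than n_train")
  if (config$objective == "cross_entropy" && is.null(probe))
    stop("the cross_entropy objective requires a pretrained probe")
  e1 <- encoders[[1L]]
  S <- e1$input_size
  chan <- dim(dataset$images[[1L]])[3L]
  grid_size <- S %/% e1$patch_size
  if (config$n_mask > grid_size^2)
    stop(sprintf("n_mask exceeds the %d-tile grid", grid_size^2))
  eps01 <- config$epsilon_8bit / 255
  alpha <- compute_step_size(config$epsilon_8bit, config$theta, config$batch,
                             config$epochs, config$n_train)
  lpf <- config$lpf_in_loop
  x01 <- lapply(dataset$images[seq_len(config$n_train)], function(im) im / 255)
  # clean CLS features, cached per encoder (forward values never change)
  f_ori_cache <- lapply(encoders, function(enc) {
    xin <- if (is.null(lpf)) x01 else lapply(x01, lpf_apply_linear, cfg = lpf)
    lapply(xin, function(x) enc_forward(enc, normalize01(x, enc))$cls)
  })
  p <- array(0, c(S, S, chan))
  steps_per_epoch <- config$n_train %/% config$batch
  total_steps <- config$epochs * steps_per_epoch
  tr_obj <- numeric(total_steps); tr_max <- numeric(total_steps)
  tr_enc <- character(total_steps)
  with_seed(config$seed, {
    active <- 1L
    step <- 0L
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(config$n_train)
      for (b in seq_len(steps_per_epoch)) {
        step <- step + 1L
        if (length(encoders) > 1L &&
            (step - 1L) %% config$switch_interval == 0L)
          active <- sample.int(length(encoders), 1L)
        enc <- encoders[[active]]
        mask <- random_tile_mask(config$n_mask, grid_size, e1$patch_size)
        mpix <- array(mask$pixels, c(S, S, chan))
        ids <- perm[((b - 1L) * config$batch + 1L):(b * config$batch)]
        g <- array(0, c(S, S, chan))
        obj <- 0
        for (i in ids) {
          atk01 <- x01[[i]] + p * mpix
          xin <- if (is.null(lpf)) atk01 else lpf_apply_linear(atk01, lpf)
          fw <- enc_forward(enc, normalize01(xin, enc), want_cache = TRUE)
          if (config$objective == "cosine") {
            f_ori <- f_ori_cache[[active]][[i]]
            obj <- obj + cosine_similarity(f_ori, fw$cls)
            d_cls <- cosine_grad(f_ori, fw$cls)           # minimised
          } else {
            lab <- dataset$labels[i]
            sm <- probe_softmax(probe, fw$cls)
            onehot <- as.numeric(seq_along(sm) == lab + 1L)
            obj <- obj - (-log(sm[lab + 1L]))              # CE, maximised
            d_cls <- -as.vector(crossprod(probe$weights, sm - onehot))
          }
          gi <- input_gradient01(enc, fw$cache, d_cls,
                                 bypass_attention_grad = TRUE)
          if (!is.null(lpf)) gi <- lpf_apply_linear(gi, lpf)  # self-adjoint
          g <- g + gi * mpix
        }
        p <- clamp(p - alpha * sign0(g / config$batch), -eps01, eps01)
        tr_obj[step] <- obj / config$batch
        tr_max[step] <- max(abs(p))
        tr_enc[step] <- enc$name
      }
    }
  })
  prov <- list(kind = "utap", encoders = names(encoders),
               config_hash = config_hash(config[setdiff(names(config), "lpf_in_loop")]),
               seed = config$seed,
               lpf_in_loop = if (is.null(lpf)) NULL else lpf$kernel_size)
  list(perturbation = perturbation(p, config$epsilon_8bit, prov, tol = 0),
       trace = data.frame(step = seq_len(total_steps), objective = tr_obj,
                          max_abs_p = tr_max, encoder = tr_enc))
}

# One signed-gradient ascent step on probe cross-entropy; shared by the
# patch-/class-specific attacks and the FGSM baseline.
#' @keywords internal
ce_input_gradient <- function(encoder, probe, x01, label,
                              bypass_attention_grad = FALSE) {
  fw <- enc_forward(encoder, normalize01(x01, encoder), want_cache = TRUE)
  sm <- probe_softmax(probe, fw$cls)
  onehot <- as.numeric(seq_along(sm) == label + 1L)
  d_cls <- as.vector(crossprod(probe$weights, sm - onehot))  # dCE/d_cls
  list(grad = input_gradient01(encoder, fw$cache, d_cls, bypass_attention_grad),
       ce = -log(max(sm[label + 1L], 1e-300)))
}

#' Patch-specific adversarial perturbation
#'
#' Signed gradient *ascent* on the cross-entropy of a pretrained linear probe
#' for one specific image, clamped to the L-infinity bound after every step.
#' Highly effective on the optimised image, by construction non-universal.
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param label integer class id in `[0, C)`.
#' @param encoder frozen encoder.
#' @param probe [train_linear_probe()] model fit on clean features.
#' @param steps optimisation steps (default 100).
#' @param step_size ascent step in normalised intensity units (default 0.01).
#' @param bound L-infinity bound in 8-bit units. The default (4) is the
#'   minimal budget at which the attack reliably defeats its target patch on
#'   the bundled encoder; a bespoke single-patch attack has no reason to
#'   spend more, and larger budgets make the pattern behave like a weak
#'   universal attack instead of a specialised one.
#' @return a [perturbation()].
#' @export
psap_train <- function(image, label, encoder, probe, steps = 100L,
                       step_size = 0.01, bound = 4) {
  x01 <- image / 255
  eps01 <- bound / 255
  p <- array(0, dim(x01))
  for (s in seq_len(steps)) {
    gi <- ce_input_gradient(encoder, probe, x01 + p, label)
    p <- clamp(p + step_size * sign0(gi$grad), -eps01, eps01)
  }
  perturbation(p, bound,
               list(kind = "psap", encoder = encoder$name, label = label),
               tol = 0)
}

#' Class-specific adversarial perturbation
#'
#' One shared perturbation maximising the mean probe cross-entropy over all
#' images of a single class, batch-iterated with the same signed-ascent
#' update and bound as [psap_train()].
#'
#' @param class_images an [image_patch_set()] (or list of arrays) all sharing
#'   `class_label`.
#' @param class_label the common integer class id.
#' @param encoder frozen encoder.
#' @param probe pretrained linear probe.
#' @param steps total optimisation steps.
#' @param batch images per step.
#' @param step_size ascent step in normalised intensity units.
#' @param bound L-infinity bound in 8-bit units.
#' @param seed RNG seed for batch sampling.
#' @return a [perturbation()].
#' @export
csap_train <- function(class_images, class_label, encoder, probe,
                       steps = 100L, batch = 5L, step_size = 0.01,
                       bound = 4, seed = 1L) {
  imgs <- if (inherits(class_images, "image_patch_set")) {
    if (!all(class_images$labels == class_label))
      stop("all images must share class_label")
    class_images$images
  } else class_images
  if (length(imgs) == 0L) stop("empty class set")
  x01 <- lapply(imgs, function(im) im / 255)
  eps01 <- bound / 255
  p <- array(0, dim(x01[[1L]]))
  with_seed(seed, {
    for (s in seq_len(steps)) {
      ids <- if (length(x01) <= batch) seq_along(x01)
             else sample.int(length(x01), batch)
      g <- array(0, dim(p))
      for (i in ids)
        g <- g + ce_input_gradient(encoder, probe, x01[[i]] + p,
                                   class_label)$grad
      p <- clamp(p + step_size * sign0(g / length(ids)), -eps01, eps01)
    }
  })
  perturbation(p, bound,
               list(kind = "csap", encoder = encoder$name,
                    label = class_label, seed = seed),
               tol = 0)
}

#' Fast gradient-sign attack (single-step baseline)
#'
#' `attacked = clamp(I/255 + magnitude * sign(dCE/dI), 0, 1)`, returned on
#' the 8-bit scale. The default magnitude matches the universal attack's
#' budget (`20/255`) for a fair comparison.
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param label integer class id.
#' @param encoder frozen encoder.
#' @param probe pretrained linear probe.
#' @param magnitude perturbation magnitude in normalised intensity units.
#' @return attacked 8-bit image array.
#' @export
fgsm <- function(image, label, encoder, probe, magnitude = 20 / 255) {
  x01 <- image / 255
  gi <- ce_input_gradient(encoder, probe, x01, label)
  round(clamp(x01 + magnitude * sign0(gi$grad), 0, 1) * 255)
}
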