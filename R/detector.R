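# Attack-detection network: a plain convolutional stack (strided 3x3
# convolutions + ReLU, global average pooling, linear head) trained with
# binary cross-entropy to separate clean from perturbed images. Two variants
# are sized to fixed parameter budgets: "light" (<= 0.70M parameters) and
# "large" (<= 17.5M parameters). Convolutions are implemented as im2col
# matrix products.

detector_channels <- list(light = c(48L, 96L, 192L, 272L),
                          large = c(96L, 192L, 384L, 768L, 896L, 896L))

#' Build an attack detector
#'
#' @param variant `"light"` or `"large"`.
#' @param input_size image side in pixels the detector operates on.
#' @param seed RNG seed for the (He-scaled) weight initialisation.
#' @return object of class `detector_model` (untrained).
#' @export
build_detector <- function(variant = c("light", "large"), input_size = 56L,
                           seed = 0L) {
  variant <- match.arg(variant)
  chans <- detector_channels[[variant]]
  ins <- c(3L, chans[-length(chans)])
  weights <- with_seed(seed, lapply(seq_along(chans), function(i) {
    fan_in <- 9L * ins[i]
    list(W = matrix(stats::rnorm(fan_in * chans[i], 0, sqrt(2 / fan_in)),
                    fan_in, chans[i]),
         b = rep(0, chans[i]))
  }))
  head <- with_seed(seed + 1L,
                    list(w = stats::rnorm(chans[length(chans)], 0,
                                          1 / sqrt(chans[length(chans)])),
                         b = 0))
  structure(list(variant = variant, input_size = as.integer(input_size),
                 channels = chans, weights = weights, head = head,
                 trained = FALSE, metadata = list(seed = seed)),
            class = "detector_model")
}

#' Exact parameter count of a detector
#'
#' @param model a `detector_model`.
#' @return integer number of trainable parameters.
#' @export
count_params <- function(model) {
  n <- sum(vapply(model$weights,
                  function(l) length(l$W) + length(l$b), numeric(1)))
  as.integer(n + length(model$head$w) + 1L)
}

# im2col index table for a 3x3 stride-2 pad-1 convolution on an n x n
# single-channel image (indices into the zero-padded (n+2)^2 plane).
#' @keywords internal
conv_index <- function(n) {
  np <- n + 2L
  no <- (n - 1L) %/% 2L + 1L
  centers_y <- seq(2L, by = 2L, length.out = no)
  pos <- as.matrix(expand.grid(y = centers_y, x = centers_y))
  off <- as.matrix(expand.grid(dy = -1:1, dx = -1:1))
  idx <- matrix(0L, no * no, 9L)
  for (j in seq_len(9L))
    idx[, j] <- (pos[, 2L] + off[j, 2L] - 1L) * np + (pos[, 1L] + off[j, 1L])
  list(idx = idx, n_out = no, n_pad = np)
}

# Batched im2col: X is (n*n*C) x B (columns = images, channel-major planes).
# Returns (B*no^2) x (9*C).
#' @keywords internal
im2col_batch <- function(X, n, C, B, ci) {
  np <- ci$n_pad
  plane <- np * np
  Xp <- matrix(0, plane * C, B)
  src <- as.vector(outer(2:(n + 1L), (1:(n + 1L))[2:(n + 1L)] - 1L,
                         function(y, x) (x) * np + y))  # padded positions
  for (ch in seq_len(C))
    Xp[src + (ch - 1L) * plane, ] <- X[((ch - 1L) * n * n + 1L):(ch * n * n), ]
  no2 <- ci$n_out^2
  IM <- matrix(0, B * no2, 9L * C)
  for (ch in seq_len(C)) for (j in seq_len(9L)) {
    IM[, (ch - 1L) * 9L + j] <-
      as.vector(Xp[ci$idx[, j] + (ch - 1L) * plane, ])
  }
  IM
}

# Adjoint of im2col_batch: scatter-add dIM back to (n*n*C) x B.
#' @keywords internal
col2im_batch <- function(dIM, n, C, B, ci) {
  np <- ci$n_pad
  plane <- np * np
  dXp <- matrix(0, plane * C, B)
  no2 <- ci$n_out^2
  for (ch in seq_len(C)) for (j in seq_len(9L)) {
    rows <- ci$idx[, j] + (ch - 1L) * plane
    dXp[rows, ] <- dXp[rows, ] + matrix(dIM[, (ch - 1L) * 9L + j], no2, B)
  }
  src <- as.vector(outer(2:(n + 1L), (1:(n + 1L))[2:(n + 1L)] - 1L,
                         function(y, x) (x) * np + y))
  dX <- matrix(0, n * n * C, B)
  for (ch in seq_len(C))
    dX[((ch - 1L) * n * n + 1L):(ch * n * n), ] <-
      dXp[src + (ch - 1L) * plane, ]
  dX
}

# Forward pass over a batch. X: (S*S*3) x B matrix of intensities already
# normalised to x/255 - 0.5. Returns logits and (optionally) caches.
#' @keywords internal
detector_forward <- function(model, X, want_cache = FALSE) {
  B <- ncol(X)
  n <- model$input_size
  C <- 3L
  caches <- if (want_cache) vector("list", length(model$weights)) else NULL
  for (li in seq_along(model$weights)) {
    ci <- conv_index(n)
    IM <- im2col_batch(X, n, C, B, ci)
    Z <- IM %*% model$weights[[li]]$W +
      rep(model$weights[[li]]$b, each = nrow(IM))
    Y <- pmax(Z, 0)
    if (want_cache) caches[[li]] <- list(IM = IM, Z = Z, ci = ci, n = n, C = C)
    # to column-per-image layout for the next layer
    Cout <- model$channels[li]
    no <- ci$n_out
    X <- matrix(aperm(array(Y, c(no * no, B, Cout)), c(1L, 3L, 2L)),
                no * no * Cout, B)
    n <- no; C <- Cout
  }
  feat <- matrix(colSums(matrix(X, n * n, C * B)), C, B) / 1  # per-image sums
  feat <- feat / (n * n)                                      # global avg pool
  logits <- as.vector(crossprod(feat, model$head$w)) + model$head$b
  list(logits = logits, feat = feat, caches = caches,
       last = list(n = n, C = C, B = B))
}

# Backward pass: returns gradients for every conv layer and the head.
#' @keywords internal
detector_backward <- function(model, fw, dlogits) {
  B <- fw$last$B; n <- fw$last$n; C <- fw$last$C
  gh_w <- as.vector(fw$feat %*% dlogits)
  gh_b <- sum(dlogits)
  dfeat <- outer(model$head$w, dlogits)            # C x B
  dX <- matrix(rep(dfeat / (n * n), each = n * n), n * n * C, B)
  grads <- vector("list", length(model$weights))
  for (li in rev(seq_along(model$weights))) {
    cc <- fw$caches[[li]]
    Cout <- model$channels[li]
    no <- cc$ci$n_out
    dY <- matrix(aperm(array(dX, c(no * no, Cout, B)), c(1L, 3L, 2L)),
                 B * no * no, Cout)
    dZ <- dY * (cc$Z > 0)
    grads[[li]] <- list(W = crossprod(cc$IM, dZ), b = colSums(dZ))
    if (li > 1L)
      dX <- col2im_batch(dZ %*% t(model$weights[[li]]$W), cc$n, cc$C, B, cc$ci)
  }
  list(conv = grads, head = list(w = gh_w, b = gh_b))
}

#' @keywords internal
patchset_to_cols <- function(ps) {
  vapply(ps$images, function(im) as.vector(im) / 255 - 0.5,
         numeric(length(ps$images[[1L]])))
}

#' Train an attack detector
#'
#' Binary cross-entropy training (clean = negative, attacked = positive) with
#' the Adam optimiser on mini-batches, a held-out validation split and
#' best-weights early stopping. Inputs must be balanced or
#' weight-compensated; this implementation requires both classes present.
#'
#' @param clean an [image_patch_set()] of clean images.
#' @param attacked an [image_patch_set()] of attacked images (same size).
#' @param variant `"light"` or `"large"`.
#' @param epochs maximum training epochs.
#' @param lr Adam learning rate.
#' @param batch mini-batch size.
#' @param val_frac fraction held out for validation-based early stopping.
#' @param seed RNG seed (initialisation, shuffling, split).
#' @param patience epochs without validation improvement before stopping.
#' @return a trained `detector_model`.
#' @export
detector_train <- function(clean, attacked, variant = c("light", "large"),
                           epochs = 15L, lr = 1e-3, batch = 16L,
                           val_frac = 0.15, seed = 0L, patience = 3L) {
  variant <- match.arg(variant)
  if (n_patches(clean) == 0L || n_patches(attacked) == 0L)
    stop("detector training needs both clean and attacked examples")
  model <- build_detector(variant, dim(clean$images[[1L]])[1L], seed)
  X <- cbind(patchset_to_cols(clean), patchset_to_cols(attacked))
  y <- c(rep(0, n_patches(clean)), rep(1, n_patches(attacked)))
  n <- length(y)
  with_seed(seed, {
    ord <- sample.int(n)
    X <- X[, ord, drop = FALSE]; y <- y[ord]
    n_val <- max(2L, round(val_frac * n))
    vi <- seq_len(n_val)
    Xv <- X[, vi, drop = FALSE]; yv <- y[vi]
    Xt <- X[, -vi, drop = FALSE]; yt <- y[-vi]
    nt <- length(yt)
    # Adam state
    ms <- list(); vs <- list(); t <- 0
    upd <- function(key, par, g) {
      t_loc <- t
      if (is.null(ms[[key]])) { ms[[key]] <<- 0 * g; vs[[key]] <<- 0 * g }
      ms[[key]] <<- 0.9 * ms[[key]] + 0.1 * g
      vs[[key]] <<- 0.999 * vs[[key]] + 0.001 * g^2
      mhat <- ms[[key]] / (1 - 0.9^t_loc)
      vhat <- vs[[key]] / (1 - 0.999^t_loc)
      par - lr * mhat / (sqrt(vhat) + 1e-8)
    }
    best <- list(loss = Inf, weights = model$weights, head = model$head,
                 stale = 0L)
    for (ep in seq_len(epochs)) {
      perm <- sample.int(nt)
      for (bs in split(perm, ceiling(seq_along(perm) / batch))) {
        t <- t + 1
        fw <- detector_forward(model, Xt[, bs, drop = FALSE], want_cache = TRUE)
        z <- fw$logits
        dlog <- (1 / (1 + exp(-z)) - yt[bs]) / length(bs)
        gr <- detector_backward(model, fw, dlog)
        for (li in seq_along(model$weights)) {
          model$weights[[li]]$W <- upd(paste0("W", li),
                                       model$weights[[li]]$W, gr$conv[[li]]$W)
          model$weights[[li]]$b <- upd(paste0("b", li),
                                       model$weights[[li]]$b, gr$conv[[li]]$b)
        }
        model$head$w <- upd("hw", model$head$w, gr$head$w)
        model$head$b <- upd("hb", model$head$b, gr$head$b)
      }
      zv <- detector_forward(model, Xv)$logits
      vloss <- mean(pmax(zv, 0) - zv * yv + log1p(exp(-abs(zv))))
      if (vloss < best$loss - 1e-6) {
        best <- list(loss = vloss, weights = model$weights,
                     head = model$head, stale = 0L)
      } else best$stale <- best$stale + 1L
      vacc <- mean((zv > 0) == (yv > 0.5))
      if (vacc == 1 && vloss < 0.01) break
      if (best$stale >= patience) break
    }
    model$weights <- best$weights
    model$head <- best$head
  })
  model$trained <- TRUE
  model$metadata <- list(seed = seed, epochs = epochs, lr = lr,
                         n_clean = n_patches(clean),
                         n_attacked = n_patches(attacked))
  model
}

#' Detector probabilities for a patch set
#'
#' @param model a trained `detector_model`.
#' @param ps an [image_patch_set()].
#' @return vector of attack probabilities (sigmoid of the logit).
#' @export
detector_predict <- function(model, ps) {
  X <- patchset_to_cols(ps)
  1 / (1 + exp(-detector_forward(model, X)$logits))
}

#' Evaluate a detector on labelled clean/attacked sets
#'
#' Clean images are the negative class, attacked images the positive class.
#'
#' @param model a trained `detector_model`.
#' @param clean clean [image_patch_set()].
#' @param attacked attacked [image_patch_set()].
#' @param threshold decision threshold on the attack probability.
#' @return list with the 2x2 `confusion` matrix (counts), `tnr = TN/(TN+FP)`
#'   and `tpr = TP/(TP+FN)`, both in percent.
#' @export
detector_eval <- function(model, clean, attacked, threshold = 0.5) {
  pc <- detector_predict(model, clean) >= threshold
  pa <- detector_predict(model, attacked) >= threshold
  tn <- sum(!pc); fp <- sum(pc); tp <- sum(pa); fn <- sum(!pa)
  confusion <- matrix(c(tn, fp, fn, tp), 2L, 2L, byrow = TRUE,
                      dimnames = list(truth = c("clean", "attacked"),
                                      predicted = c("clean", "attacked")))
  list(confusion = confusion,
       tnr = 100 * tn / (tn + fp),
       tpr = 100 * tp / (tp + fn))
}

#' @export
print.detector_model <- function(x, ...) {
  cat(sprintf("<detector_model> %s, %s, %d parameters, input %dx%d\n",
              x$variant, if (x$trained) "trained" else "untrained",
              count_params(x), x$input_size, x$input_size))
  invisible(x)
}
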