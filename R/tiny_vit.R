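# Bundled tiny vision transformer.
#
# A structurally faithful, frozen, randomly initialised ViT: patch embedding,
# learned CLS token and positional embeddings, >= 2 pre-norm transformer
# blocks of multi-head self-attention (query/key/value projections) and an
# MLP, each with LayerNorm and residual connections, and a final LayerNorm.
# Forward and backward passes are written out explicitly so that the backward
# pass can optionally treat the post-softmax attention weights as constants
# (the transferability regularisation used during attack training).

#' Build the bundled tiny vision transformer
#'
#' Weights are drawn once from a seeded Gaussian (sd 0.02) and frozen; the
#' encoder is a deterministic pure function of its inputs thereafter. The
#' default geometry (input 224, patch 14, width 192, 2 blocks, 3 heads)
#' mirrors a production ViT's structure at desk scale.
#'
#' @param seed integer seed determining the frozen weights.
#' @param input_size input image side in pixels (divisible by `patch_size`).
#' @param patch_size tile side in pixels (default 14).
#' @param width token dimensionality (divisible by `heads`).
#' @param depth number of transformer blocks (>= 2).
#' @param heads number of attention heads.
#' @param mlp_ratio hidden width of the MLP as a multiple of `width`.
#' @param embed_gain gain applied inside the GELU nonlinearity that follows
#'   the patch embedding (`gelu(gain * (X W + b))`). At the default gain the
#'   embedding units operate in their saturating regime, so each tile's
#'   Jacobian depends on the tile's content — the input-selective behaviour
#'   trained transformers exhibit. Set to `0` for a purely linear embedding.
#' @param norm_mean,norm_sd per-channel preprocessing constants.
#' @param name encoder registry name.
#' @return An encoder object of class `c("tiny_vit", "encoder")`.
#' @export
build_tiny_vit <- function(seed = 0L, input_size = 224L, patch_size = 14L,
                           width = 192L, depth = 2L, heads = 3L,
                           mlp_ratio = 4L, embed_gain = 8,
                           norm_mean = c(0.5, 0.5, 0.5),
                           norm_sd = c(0.5, 0.5, 0.5),
                           name = sprintf("tiny-vit-%d", seed)) {
  if (input_size %% patch_size != 0L)
    stop("input_size must be divisible by patch_size")
  if (width %% heads != 0L) stop("width must be divisible by heads")
  if (depth < 2L) stop("at least 2 transformer blocks are required")
  n_side <- input_size %/% patch_size
  n_tok <- n_side^2
  d_in <- patch_size^2 * 3L
  w <- with_seed(seed, {
    g <- function(...) array(stats::rnorm(prod(c(...)), 0, 0.02), c(...))
    blocks <- lapply(seq_len(depth), function(b) list(
      g1 = rep(1, width), b1 = rep(0, width),
      Wq = g(width, width), bq = rep(0, width),
      Wk = g(width, width), bk = rep(0, width),
      Wv = g(width, width), bv = rep(0, width),
      Wo = g(width, width), bo = rep(0, width),
      g2 = rep(1, width), b2 = rep(0, width),
      W1 = g(width, width * mlp_ratio), b1m = rep(0, width * mlp_ratio),
      W2 = g(width * mlp_ratio, width), b2m = rep(0, width)))
    list(Wp = g(d_in, width), bp = rep(0, width),
         cls = as.vector(g(width, 1L)),
         pos = g(n_tok + 1L, width),
         blocks = blocks, gf = rep(1, width), bf = rep(0, width))
  })
  structure(list(name = name, patch_size = as.integer(patch_size),
                 input_size = as.integer(input_size),
                 channels = 3L,
                 feature_dim = as.integer(width),
                 depth = as.integer(depth), heads = as.integer(heads),
                 embed_gain = embed_gain,
                 norm_mean = norm_mean, norm_sd = norm_sd,
                 deterministic = TRUE, weights = w,
                 patch_index = patch_index_map(input_size, patch_size),
                 seed = as.integer(seed)),
            class = c("tiny_vit", "encoder"))
}

# Index map sending flattened image positions to the rows of the patch
# matrix: tiles ordered row-major over the grid (origin top-left), each tile
# flattened in R's column-major order over (y, x, channel).
#' @keywords internal
patch_index_map <- function(S, ps) {
  n_side <- S %/% ps
  arr <- array(seq_len(S * S * 3L), c(S, S, 3L))
  idx <- matrix(0L, n_side^2, ps^2 * 3L)
  t <- 0L
  for (r in seq_len(n_side)) for (c in seq_len(n_side)) {
    t <- t + 1L
    ys <- ((r - 1L) * ps + 1L):(r * ps)
    xs <- ((c - 1L) * ps + 1L):(c * ps)
    idx[t, ] <- as.vector(arr[ys, xs, ])
  }
  idx
}

#' @keywords internal
ln_fwd <- function(x, g, b, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(y = xhat * rep(g, each = nrow(x)) + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

#' @keywords internal
ln_bwd <- function(dy, xhat, inv, g) {
  dxhat <- dy * rep(g, each = nrow(dy))
  (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
}

#' @keywords internal
gelu <- function(u) u * stats::pnorm(u)

#' @keywords internal
gelu_grad <- function(u) stats::pnorm(u) + u * stats::dnorm(u)

#' @keywords internal
addb <- function(M, b) M + rep(b, each = nrow(M))

#' @export
enc_forward.tiny_vit <- function(encoder, xnorm, want_cache = FALSE,
                                 fixed_attention = NULL) {
  w <- encoder$weights
  heads <- encoder$heads
  d <- encoder$feature_dim
  dh <- d %/% heads
  if (!identical(dim(xnorm), c(encoder$input_size, encoder$input_size, 3L)) &&
      !identical(as.integer(dim(xnorm)), c(encoder$input_size, encoder$input_size, 3L)))
    stop("input shape mismatch: expected ",
         encoder$input_size, "x", encoder$input_size, "x3")
  X0 <- matrix(as.vector(xnorm)[as.vector(encoder$patch_index)],
               nrow(encoder$patch_index))
  E_pre <- addb(X0 %*% w$Wp, w$bp)
  E <- if (encoder$embed_gain > 0) gelu(encoder$embed_gain * E_pre)
       else E_pre
  H <- rbind(w$cls, E) + w$pos
  nt <- nrow(H)
  cache <- if (want_cache) list(blocks = vector("list", encoder$depth)) else NULL
  for (bi in seq_len(encoder$depth)) {
    bw <- w$blocks[[bi]]
    l1 <- ln_fwd(H, bw$g1, bw$b1)
    Q <- addb(l1$y %*% bw$Wq, bw$bq)
    K <- addb(l1$y %*% bw$Wk, bw$bk)
    V <- addb(l1$y %*% bw$Wv, bw$bv)
    O <- matrix(0, nt, d)
    As <- vector("list", heads)
    for (h in seq_len(heads)) {
      ix <- ((h - 1L) * dh + 1L):(h * dh)
      if (is.null(fixed_attention)) {
        S <- tcrossprod(Q[, ix, drop = FALSE], K[, ix, drop = FALSE]) / sqrt(dh)
        A <- softmax_rows(S)
      } else A <- fixed_attention[[bi]][[h]]
      As[[h]] <- A
      O[, ix] <- A %*% V[, ix, drop = FALSE]
    }
    At <- addb(O %*% bw$Wo, bw$bo)
    H1 <- H + At
    l2 <- ln_fwd(H1, bw$g2, bw$b2)
    U <- addb(l2$y %*% bw$W1, bw$b1m)
    H <- H1 + addb(gelu(U) %*% bw$W2, bw$b2m)
    if (want_cache)
      cache$blocks[[bi]] <- list(xhat1 = l1$xhat, inv1 = l1$inv,
                                 Q = Q, K = K, V = V, A = As,
                                 xhat2 = l2$xhat, inv2 = l2$inv, U = U)
  }
  lf <- ln_fwd(H, w$gf, w$bf)
  if (!all(is.finite(lf$y))) stop("non-finite activations in encoder forward")
  out <- list(cls = lf$y[1L, ], patch_tokens = lf$y[-1L, , drop = FALSE])
  if (want_cache) {
    cache$xhatF <- lf$xhat; cache$invF <- lf$inv
    cache$E_pre <- E_pre
    out$cache <- cache
  }
  out
}

#' @export
enc_backward.tiny_vit <- function(encoder, cache, d_cls,
                                  bypass_attention_grad = FALSE) {
  w <- encoder$weights
  heads <- encoder$heads
  d <- encoder$feature_dim
  dh <- d %/% heads
  nt <- nrow(cache$xhatF)
  dHf <- matrix(0, nt, d)
  dHf[1L, ] <- d_cls
  dH <- ln_bwd(dHf, cache$xhatF, cache$invF, w$gf)
  for (bi in rev(seq_len(encoder$depth))) {
    bw <- w$blocks[[bi]]
    cb <- cache$blocks[[bi]]
    # MLP branch
    dG <- dH %*% t(bw$W2)
    dU <- dG * gelu_grad(cb$U)
    dmy <- dU %*% t(bw$W1)
    dH1 <- dH + ln_bwd(dmy, cb$xhat2, cb$inv2, bw$g2)
    # attention branch
    dO <- dH1 %*% t(bw$Wo)
    dQ <- matrix(0, nt, d); dK <- matrix(0, nt, d); dV <- matrix(0, nt, d)
    for (h in seq_len(heads)) {
      ix <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cb$A[[h]]
      dV[, ix] <- crossprod(A, dO[, ix, drop = FALSE])
      if (!bypass_attention_grad) {
        dA <- tcrossprod(dO[, ix, drop = FALSE], cb$V[, ix, drop = FALSE])
        dS <- A * (dA - rowSums(dA * A))
        dQ[, ix] <- dS %*% cb$K[, ix, drop = FALSE] / sqrt(dh)
        dK[, ix] <- crossprod(dS, cb$Q[, ix, drop = FALSE]) / sqrt(dh)
      }
    }
    day <- dQ %*% t(bw$Wq) + dK %*% t(bw$Wk) + dV %*% t(bw$Wv)
    dH <- dH1 + ln_bwd(day, cb$xhat1, cb$inv1, bw$g1)
  }
  dE <- dH[-1L, , drop = FALSE]
  if (encoder$embed_gain > 0)
    dE <- dE * gelu_grad(encoder$embed_gain * cache$E_pre) * encoder$embed_gain
  dX0 <- dE %*% t(w$Wp)
  S <- encoder$input_size
  dx <- numeric(S * S * 3L)
  dx[as.vector(encoder$patch_index)] <- as.vector(dX0)
  array(dx, c(S, S, 3L))
}
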