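# Frozen feature-extractor contract.
#
# An encoder is an S3 object carrying its spec fields (name, patch_size,
# input_size, feature_dim, per-channel normalisation) and implementing the
# generics below. Forward passes are pure functions of (weights, input);
# weights are frozen at construction. Gradients of scalar functions of the
# output features with respect to the *input pixels* are exposed through
# enc_backward(); the `bypass_attention_grad` flag switches the backward pass
# to treat post-softmax self-attention weights as constants ("pay no
# attention" regularisation) without ever changing forward values.

#' Per-channel preprocessing applied before an encoder
#'
#' Computes `((pixels / 255) - mean) / scale` channel-wise, the standard
#' normalisation contract of frozen feature extractors.
#'
#' @param images an [image_patch_set()], a list of `H x W x C` arrays, or a
#'   single array with pixel values in `[0, 255]`.
#' @param encoder an encoder object (supplies `norm_mean`, `norm_sd`).
#' @return Normalised array(s) with shape preserved.
#' @export
preprocess <- function(images, encoder) {
  if (any(encoder$norm_sd == 0)) stop("zero normalisation scale")
  f <- function(x) {
    r <- range(x)
    if (r[1L] < 0 || r[2L] > 255) stop("pixels must lie in [0, 255]")
    normalize01(x / 255, encoder)
  }
  if (inherits(images, "image_patch_set")) lapply(images$images, f)
  else if (is.list(images)) lapply(images, f)
  else f(images)
}

# Normalisation from [0,1] intensities (used internally by attacks, where
# perturbed intensities are continuous and may transiently leave [0,1]).
#' @keywords internal
normalize01 <- function(x01, encoder) {
  d <- dim(x01)
  C <- d[3L]
  out <- x01
  for (ch in seq_len(C))
    out[, , ch] <- (x01[, , ch] - encoder$norm_mean[ch]) / encoder$norm_sd[ch]
  out
}

#' Forward pass of an encoder
#'
#' @param encoder encoder object.
#' @param xnorm normalised input array (output of [preprocess()]).
#' @param want_cache keep intermediates for a subsequent [enc_backward()].
#' @param fixed_attention internal: list (per block) of lists (per head) of
#'   attention-weight matrices to use in place of the softmax output; used to
#'   build independent value-path-only gradient oracles.
#' @return list with `cls` (length `feature_dim` vector), `patch_tokens`
#'   (token-count x token-dim matrix) and, if requested, `cache`.
#' @export
enc_forward <- function(encoder, xnorm, want_cache = FALSE,
                        fixed_attention = NULL) UseMethod("enc_forward")

#' Backward pass: gradient of a feature functional w.r.t. the input
#'
#' Given the cotangent `d_cls` (gradient of some scalar loss with respect to
#' the CLS feature vector), returns the gradient with respect to the
#' *normalised* input array.
#'
#' @param encoder encoder object.
#' @param cache cache returned by [enc_forward()] with `want_cache = TRUE`.
#' @param d_cls numeric vector of length `feature_dim`.
#' @param bypass_attention_grad if `TRUE`, post-softmax attention weights are
#'   treated as constants during differentiation: gradients flow through the
#'   value path and all other layers, but not through the attention-weight
#'   computation (query/key path).
#' @return gradient array with the shape of the normalised input.
#' @export
enc_backward <- function(encoder, cache, d_cls,
                         bypass_attention_grad = FALSE) UseMethod("enc_backward")

#' Extract feature bundles from images
#'
#' Runs [preprocess()] and the encoder forward pass over a batch. The
#' `bypass_attention_grad` flag is accepted for contract symmetry; it has no
#' effect on forward values.
#'
#' @param encoder encoder object.
#' @param images an [image_patch_set()], list of arrays, or one array
#'   (8-bit pixel scale).
#' @param bypass_attention_grad ignored in the forward direction.
#' @return list with `cls`: an `n x feature_dim` matrix, and `patch_tokens`:
#'   a list of token matrices (one per image).
#' @export
extract_features <- function(encoder, images, bypass_attention_grad = FALSE) {
  xs <- preprocess(images, encoder)
  if (!is.list(xs)) xs <- list(xs)
  cls <- matrix(NA_real_, length(xs), encoder$feature_dim)
  toks <- vector("list", length(xs))
  for (i in seq_along(xs)) {
    fb <- enc_forward(encoder, xs[[i]])
    if (!all(is.finite(fb$cls))) stop("encoder produced non-finite features")
    cls[i, ] <- fb$cls
    toks[[i]] <- fb$patch_tokens
  }
  list(cls = cls, patch_tokens = toks)
}

#' CLS feature matrix of a patch set
#'
#' Convenience wrapper around [extract_features()] returning only the
#' `n x feature_dim` CLS matrix.
#'
#' @inheritParams extract_features
#' @export
feature_matrix <- function(encoder, images) extract_features(encoder, images)$cls

# Gradient of a scalar loss w.r.t. [0,1]-scale intensities, chaining the
# preprocessing through enc_backward().
#' @keywords internal
input_gradient01 <- function(encoder, cache, d_cls, bypass_attention_grad = FALSE) {
  g <- enc_backward(encoder, cache, d_cls, bypass_attention_grad)
  for (ch in seq_len(dim(g)[3L])) g[, , ch] <- g[, , ch] / encoder$norm_sd[ch]
  g
}

#' @export
print.encoder <- function(x, ...) {
  cat(sprintf("<encoder:%s> '%s' input %dx%d, patch %d, %d tokens, feature_dim %d\n",
              class(x)[1L], x$name, x$input_size, x$input_size, x$patch_size,
              (x$input_size / x$patch_size)^2, x$feature_dim))
  invisible(x)
}

#' Toy linear encoder
#'
#' A deterministic "encoder" computing `f(x) = W vec(x)` on the normalised
#' input. It satisfies the encoder contract (single patch token equal to the
#' CLS vector) and exists to make gradient oracles computable in closed form
#' or by cheap finite differences.
#'
#' @param seed RNG seed for the random projection `W`.
#' @param input_size image side in pixels.
#' @param channels number of channels.
#' @param feature_dim output dimensionality.
#' @param norm_mean,norm_sd per-channel normalisation (length `channels`).
#' @return An encoder object of class `c("linear_encoder", "encoder")`.
#' @export
build_linear_encoder <- function(seed = 0L, input_size = 8L, channels = 1L,
                                 feature_dim = 16L,
                                 norm_mean = rep(0.5, channels),
                                 norm_sd = rep(0.5, channels)) {
  W <- with_seed(seed, matrix(stats::rnorm(feature_dim * input_size^2 * channels),
                              feature_dim))
  structure(list(name = sprintf("linear-%d", seed), W = W,
                 patch_size = as.integer(input_size),
                 input_size = as.integer(input_size),
                 channels = as.integer(channels),
                 feature_dim = as.integer(feature_dim),
                 norm_mean = norm_mean, norm_sd = norm_sd,
                 deterministic = TRUE),
            class = c("linear_encoder", "encoder"))
}

#' @export
enc_forward.linear_encoder <- function(encoder, xnorm, want_cache = FALSE,
                                       fixed_attention = NULL) {
  cls <- as.vector(encoder$W %*% as.vector(xnorm))
  out <- list(cls = cls, patch_tokens = matrix(cls, 1L))
  if (want_cache) out$cache <- list(dim = dim(xnorm))
  out
}

#' @export
enc_backward.linear_encoder <- function(encoder, cache, d_cls,
                                        bypass_attention_grad = FALSE) {
  array(as.vector(crossprod(encoder$W, d_cls)), cache$dim)
}
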