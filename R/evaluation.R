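# Linear probing of frozen features and attack-efficacy reporting.

#' Train a multinomial logistic probe on frozen features
#'
#' Minimises `mean cross-entropy + l2_strength * ||W||^2` by quasi-Newton
#' (L-BFGS) optimisation with line search, capped at 100 iterations, from a
#' zero initialisation — making the fit deterministic. The probe is the
#' downstream "linear probing" classifier: the encoder stays frozen and only
#' this linear head is ever trained, always on clean features.
#'
#' @param features `n x d` numeric matrix of CLS features.
#' @param labels integer class ids in `[0, C)`, at least two classes present.
#' @param l2_strength ridge penalty on the weights (not the bias). The
#'   default `1 / n` keeps the penalty's share of the objective constant as
#'   the sample size grows.
#' @param max_iter optimiser iteration cap (default 100).
#' @return object of class `probe_model` with fields `weights` (`C x d`),
#'   `bias` (length `C`), `l2_strength`, `converged`, `n_iters`.
#' @export
train_linear_probe <- function(features, labels, l2_strength = NULL,
                               max_iter = 100L) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) stop("non-finite features")
  labels <- as.integer(labels)
  n <- nrow(features); d <- ncol(features)
  C <- max(labels) + 1L
  if (length(unique(labels)) < 2L) stop("probe training needs >= 2 classes")
  if (is.null(l2_strength)) l2_strength <- 1 / n
  Y <- matrix(0, n, C); Y[cbind(seq_len(n), labels + 1L)] <- 1
  unpack <- function(par) list(W = matrix(par[seq_len(C * d)], C, d),
                               b = par[C * d + seq_len(C)])
  fn <- function(par) {
    th <- unpack(par)
    Z <- features %*% t(th$W) + rep(th$b, each = n)
    m <- apply(Z, 1L, max)
    lse <- m + log(rowSums(exp(Z - m)))
    ce <- mean(lse - Z[cbind(seq_len(n), labels + 1L)])
    ce + l2_strength * sum(th$W^2)
  }
  gr <- function(par) {
    th <- unpack(par)
    Z <- features %*% t(th$W) + rep(th$b, each = n)
    P <- softmax_rows(Z)
    R <- P - Y
    gW <- crossprod(R, features) / n + 2 * l2_strength * th$W
    gb <- colMeans(R)
    c(as.vector(gW), gb)
  }
  fit <- stats::optim(rep(0, C * d + C), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_iter, factr = 1e4))
  th <- unpack(fit$par)
  structure(list(weights = th$W, bias = th$b, l2_strength = l2_strength,
                 converged = fit$convergence == 0L,
                 n_iters = unname(fit$counts["function"]),
                 objective = fit$value, n_classes = C),
            class = "probe_model")
}

#' @keywords internal
probe_logits <- function(probe, features) {
  if (is.null(dim(features))) features <- matrix(features, 1L)
  features %*% t(probe$weights) + rep(probe$bias, each = nrow(features))
}

# Softmax class probabilities for a single feature vector.
#' @keywords internal
probe_softmax <- function(probe, f) {
  z <- as.vector(probe_logits(probe, f))
  e <- exp(z - max(z))
  e / sum(e)
}

#' Predict class ids with a probe
#'
#' Argmax over logits; ties break to the lowest class index.
#'
#' @param probe a `probe_model`.
#' @param features `n x d` feature matrix.
#' @return integer class ids in `[0, C)`.
#' @export
predict_probe <- function(probe, features) {
  Z <- probe_logits(probe, features)
  apply(Z, 1L, which.max) - 1L
}

#' Classification accuracy of a probe, in percent
#'
#' @param probe a `probe_model`.
#' @param features `n x d` feature matrix.
#' @param labels integer class ids.
#' @return accuracy `100 * correct / total`.
#' @export
evaluate_probe <- function(probe, features, labels) {
  if (length(labels) == 0L) stop("empty evaluation set")
  100 * mean(predict_probe(probe, features) == as.integer(labels))
}

#' Accuracy drop caused by an attack
#'
#' @param original_acc,attacked_acc accuracies in percent.
#' @return `original_acc - attacked_acc`.
#' @export
accuracy_drop <- function(original_acc, attacked_acc) original_acc - attacked_acc

#' Cross-encoder transfer matrix
#'
#' Evaluates each source-encoder perturbation against every target encoder:
#' rows index the encoder the perturbation was trained on, columns the
#' encoder being attacked. Diagonal entries are internal attacks, off-
#' diagonal entries are black-box external attacks. All evaluation uses
#' patches unseen by both probe training and perturbation training, with
#' perturbations applied at the 8-bit evaluation convention (full pattern,
#' overflow-clipped).
#'
#' @param perturbations named list of [perturbation()]s, one per source
#'   encoder.
#' @param encoders named list of encoders (targets).
#' @param test_set held-out [image_patch_set()].
#' @param probes named list of `probe_model`s, one per target encoder,
#'   trained on clean features.
#' @return object of class `transfer_report` with matrices `original_acc`,
#'   `attacked_acc`, `drop` (percent; rows = sources, cols = targets).
#' @export
transfer_matrix <- function(perturbations, encoders, test_set, probes) {
  src <- names(perturbations); tgt <- names(encoders)
  missing_probe <- setdiff(tgt, names(probes))
  if (length(missing_probe))
    stop("missing probe for encoder(s): ", paste(missing_probe, collapse = ", "))
  orig <- numeric(length(tgt)); names(orig) <- tgt
  clean_feats <- list()
  for (e in tgt) {
    clean_feats[[e]] <- feature_matrix(encoders[[e]], test_set)
    orig[e] <- evaluate_probe(probes[[e]], clean_feats[[e]], test_set$labels)
  }
  atk <- matrix(NA_real_, length(src), length(tgt), dimnames = list(src, tgt))
  for (s in src) {
    attacked <- apply_perturbation(test_set, perturbations[[s]])
    for (e in tgt)
      atk[s, e] <- evaluate_probe(probes[[e]],
                                  feature_matrix(encoders[[e]], attacked),
                                  test_set$labels)
  }
  orig_m <- matrix(orig, length(src), length(tgt), byrow = TRUE,
                   dimnames = list(src, tgt))
  structure(list(original_acc = orig_m, attacked_acc = atk,
                 drop = orig_m - atk), class = "transfer_report")
}

#' @export
print.transfer_report <- function(x, ...) {
  cat("<transfer_report> accuracy drop (percent), rows = trained on, cols = attacked:\n")
  print(round(x$drop, 2))
  invisible(x)
}

#' CLS-to-patch-token attention heatmap
#'
#' Cosine similarity between the CLS token and every patch token, arranged
#' row-major on the token grid. High values mark regions the encoder's global
#' feature attends to; a coherent map disintegrates under a successful
#' feature-space attack.
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param encoder encoder exposing patch tokens.
#' @return `(input_size/patch_size)` square matrix of values in `[-1, 1]`
#'   (class `heatmap_grid`). Zero-norm tokens map to 0 with a warning.
#' @export
attention_heatmap <- function(image, encoder) {
  fb <- enc_forward(encoder, preprocess(image, encoder))
  side <- encoder$input_size %/% encoder$patch_size
  cn <- sqrt(sum(fb$cls^2))
  vals <- apply(fb$patch_tokens, 1L, function(tk) {
    tn <- sqrt(sum(tk^2))
    if (tn == 0 || cn == 0) { warning("zero-norm token in heatmap"); return(0) }
    sum(fb$cls * tk) / (cn * tn)
  })
  structure(matrix(vals, side, side, byrow = TRUE), class = "heatmap_grid")
}

#' 2-D projection of a feature matrix
#'
#' PCA (deterministic; sign fixed so each component's largest-magnitude
#' loading is positive) or UMAP (delegated to the standard `umap-learn`
#' implementation through a Python subprocess, seeded).
#'
#' @param features `n x d` matrix, `n >= 3`.
#' @param method `"pca"` or `"umap"`.
#' @param seed RNG seed (UMAP only).
#' @param n_neighbors UMAP neighbourhood size.
#' @return `n x 2` coordinate matrix.
#' @export
project_features <- function(features, method = c("pca", "umap"), seed = 1L,
                             n_neighbors = 15L) {
  method <- match.arg(method)
  features <- as.matrix(features)
  if (nrow(features) < 3L) stop("need >= 3 samples to project")
  if (method == "pca") {
    pc <- stats::prcomp(features, center = TRUE, scale. = FALSE, rank. = 2L)
    rot <- pc$rotation
    for (j in seq_len(ncol(rot))) {
      k <- which.max(abs(rot[, j]))
      if (rot[k, j] < 0) { rot[, j] <- -rot[, j] }
    }
    sweep(features, 2L, pc$center) %*% rot
  } else {
    fin <- tempfile(fileext = ".csv"); fout <- tempfile(fileext = ".csv")
    on.exit(unlink(c(fin, fout)))
    utils::write.table(features, fin, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    code <- sprintf(paste0(
      "import numpy, umap; x = numpy.loadtxt(%s, delimiter=','); ",
      "e = umap.UMAP(n_components=2, n_neighbors=%d, random_state=%d, n_jobs=1).fit_transform(x); ",
      "numpy.savetxt(%s, e, delimiter=',')"),
      deparse(fin), as.integer(n_neighbors), as.integer(seed), deparse(fout))
    status <- suppressWarnings(system2("python", c("-c", shQuote(code)),
                                       stdout = FALSE, stderr = FALSE))
    if (!identical(status, 0L) || !file.exists(fout))
      stop("umap projection requires a python interpreter with umap-learn on the PATH")
    as.matrix(utils::read.table(fout, sep = ","))
  }
}

#' Visualise a perturbation on a neutral gray background
#'
#' The pattern is superimposed on a uniform `[128, 128, 128]` background:
#' `clamp(128 + p * 255, 0, 255)` per channel. For the histogram the RGB
#' channels are averaged into a single intensity map reported in 8-bit units,
#' whose support lies within `[-epsilon, +epsilon]`.
#'
#' @param p a [perturbation()].
#' @param breaks histogram breaks (passed to [graphics::hist()]).
#' @return list with `image` (8-bit RGB array), `values_8bit` (channel-mean
#'   intensity map in 8-bit units) and `histogram` (a `histogram` object,
#'   not plotted).
#' @export
render_perturbation <- function(p, breaks = 64L) {
  stopifnot(inherits(p, "perturbation"))
  img <- round(clamp(128 + p$values * 255, 0, 255))
  v8 <- apply(p$values, c(1L, 2L), mean) * 255
  h <- graphics::hist(as.vector(v8), breaks = breaks, plot = FALSE)
  list(image = img, values_8bit = v8, histogram = h)
}
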