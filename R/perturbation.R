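# The trainable noise pattern.

#' Adversarial perturbation container
#'
#' An additive noise pattern in normalised intensity units (pixel/255 scale)
#' with an L-infinity bound expressed in 8-bit units: every entry satisfies
#' `|value| <= epsilon_8bit / 255`.
#'
#' @param values numeric `H x W x 3` array in normalised intensity units.
#' @param epsilon_8bit L-infinity bound in 8-bit intensity units (the paper
#'   convention for reporting perturbation budgets).
#' @param provenance optional list recording how the pattern was produced
#'   (config hash, encoder name(s), seed).
#' @param tol numeric slack allowed on the bound check, to absorb 32-bit
#'   storage rounding; exact in-memory training updates clamp hard.
#' @return An object of class `perturbation`.
#' @export
perturbation <- function(values, epsilon_8bit, provenance = list(), tol = 1e-6) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("perturbation values must be an H x W x C array")
  if (max(abs(values)) > epsilon_8bit / 255 + tol)
    stop(sprintf("perturbation violates its bound: max|p| = %.6g > %.6g",
                 max(abs(values)), epsilon_8bit / 255))
  structure(list(values = values, epsilon_8bit = epsilon_8bit,
                 provenance = provenance),
            class = "perturbation")
}

#' @export
print.perturbation <- function(x, ...) {
  cat(sprintf("<perturbation> %s, epsilon = %g/255, max|p| = %.5f\n",
              paste(dim(x$values), collapse = "x"), x$epsilon_8bit,
              max(abs(x$values))))
  invisible(x)
}

#' Apply a perturbation to 8-bit images
#'
#' Evaluation-time application: `attacked = clamp(I/255 + p (*) M, 0, 1) * 255`
#' rounded to 8 bits (round-half-to-even). During attack training the
#' continuous, unrounded intensities are used instead; this function is the
#' evaluation convention with overflow clipping.
#'
#' @param images an [image_patch_set()] or a single `H x W x 3` array in
#'   `[0, 255]`.
#' @param p a [perturbation()].
#' @param mask optional [tile_mask()]; by default the full pattern is applied.
#' @return Same container as `images`, with attacked 8-bit pixel values.
#' @export
apply_perturbation <- function(images, p, mask = NULL) {
  stopifnot(inherits(p, "perturbation"))
  pv <- p$values
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "tile_mask"))
    pv <- pv * array(mask$pixels, dim(pv))
  }
  f <- function(im) {
    if (!identical(dim(im)[1:2], dim(pv)[1:2]))
      stop("image and perturbation shapes do not match")
    round(clamp(im / 255 + pv, 0, 1) * 255)
  }
  if (inherits(images, "image_patch_set")) {
    images$images <- lapply(images$images, f)
    images
  } else f(images)
}
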