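# Fourier low-pass-filter defense and its physical-optics bookkeeping.
#
# "Kernel size" k is the side of the retained central frequency window: per
# channel the centred 2-D spectrum is computed, every coefficient whose
# horizontal or vertical frequency index exceeds k/2 in magnitude is zeroed,
# and the image is inverted. The retained window is symmetric about DC, which
# makes the filtered image exactly real and the (pre-clip) filter an exact
# spectral projection — applying it twice equals applying it once.

#' Low-pass-filter configuration
#'
#' @param kernel_size retained-frequency window size `k` in frequency-grid
#'   units (reference values 50, 20, 10 on a 224-pixel field).
#' @param pixel_size_um physical pixel pitch in micrometres (default 0.5,
#'   i.e. a 20x scan).
#' @param wavelength_um assumed illumination wavelength in micrometres
#'   (default 0.55, visible mid-band).
#' @param window_shape only `"square"` windows are implemented.
#' @return object of class `lpf_config`.
#' @export
lpf_config <- function(kernel_size, pixel_size_um = 0.5, wavelength_um = 0.55,
                       window_shape = "square") {
  if (kernel_size <= 0) stop("kernel_size must be positive")
  if (pixel_size_um <= 0 || wavelength_um <= 0)
    stop("physical parameters must be positive")
  window_shape <- match.arg(window_shape, "square")
  structure(list(kernel_size = kernel_size, pixel_size_um = pixel_size_um,
                 wavelength_um = wavelength_um, window_shape = window_shape),
            class = "lpf_config")
}

# Binary retained-frequency mask in *unshifted* FFT index order, for an n-point
# axis: frequency f (in [-n/2, n/2)) is kept iff |f| <= k/2.
#' @keywords internal
lpf_axis_keep <- function(n, k) {
  f <- c(0:(ceiling(n / 2) - 1L), -(floor(n / 2):1))
  abs(f) <= k / 2
}

# Linear (no clipping) spectral projection of an H x W x C array; exactly
# real, exactly idempotent, self-adjoint. Gradients of any loss through the
# filter are obtained by applying the same projection to the cotangent.
#' @keywords internal
lpf_apply_linear <- function(x, cfg) {
  d <- dim(x)
  k <- cfg$kernel_size
  if (k >= max(d[1L], d[2L])) return(x)
  keep_r <- lpf_axis_keep(d[1L], k)
  keep_c <- lpf_axis_keep(d[2L], k)
  out <- x
  for (ch in seq_len(d[3L])) {
    F <- stats::fft(x[, , ch])
    F[!keep_r, ] <- 0
    F[, !keep_c] <- 0
    out[, , ch] <- Re(stats::fft(F, inverse = TRUE)) / (d[1L] * d[2L])
  }
  out
}

#' Fourier low-pass filter of an 8-bit image
#'
#' Per channel: centred 2-D discrete Fourier transform, zero all coefficients
#' outside the central `k x k` retained window (symmetric about DC), invert,
#' clip to `[0, 255]`. The DC coefficient is always retained, so channel
#' means are preserved (pre-clip).
#'
#' @param image `H x W x 3` (or `H x W`) array in `[0, 255]`.
#' @param cfg an [lpf_config()]; `kernel_size <= min(H, W)` required.
#' @return filtered image, clipped to `[0, 255]` (not re-quantised).
#' @export
fourier_lpf <- function(image, cfg) {
  stopifnot(inherits(cfg, "lpf_config"))
  was_2d <- length(dim(image)) == 2L
  if (was_2d) image <- array(image, c(dim(image), 1L))
  if (cfg$kernel_size > min(dim(image)[1:2]))
    stop("kernel_size must not exceed the image size")
  out <- clamp(lpf_apply_linear(image, cfg), 0, 255)
  if (was_2d) out[, , 1L] else out
}

#' Effective numerical aperture of a low-pass filter
#'
#' The resolution cut-off of retaining a `k`-wide frequency window on an
#' `field_pixels`-wide field sampled at `pixel_size_um` equals that of a
#' microscope with `NA = wavelength * (k/2) / (field_pixels * pixel_size)`.
#' Reported rounded to three significant figures. NA is linear in `k`:
#' windows of 50, 20 and 10 pixels on a 224-pixel field at 0.5 um/pixel give
#' 0.123, 0.0491 and 0.0246.
#'
#' @param cfg an [lpf_config()].
#' @param field_pixels field width in pixels (default 224).
#' @return effective numerical aperture (3 significant figures).
#' @export
effective_na <- function(cfg, field_pixels = 224L) {
  stopifnot(inherits(cfg, "lpf_config"))
  signif(cfg$wavelength_um * (cfg$kernel_size / 2) /
           (field_pixels * cfg$pixel_size_um), 3L)
}

#' Train a low-pass-filter-resilient universal perturbation
#'
#' Identical to [utap_train()] except that every attacked batch passes
#' through the (linear, self-adjoint) low-pass filter before preprocessing
#' and feature extraction, so the optimisation concentrates the attack in the
#' retained frequency band and the resulting perturbation survives the
#' filter deployed as a defense.
#'
#' @param dataset an [image_patch_set()].
#' @param encoder a frozen encoder (or pool, as in [utap_train()]).
#' @param config an [attack_config()] whose `lpf_in_loop` is an
#'   [lpf_config()].
#' @return as [utap_train()].
#' @export
lpf_resilient_utap <- function(dataset, encoder, config) {
  if (is.null(config$lpf_in_loop))
    stop("config$lpf_in_loop must be an lpf_config")
  stopifnot(inherits(config$lpf_in_loop, "lpf_config"))
  utap_train(dataset, encoder, config)
}

#' Apply the low-pass filter to a whole patch set
#'
#' @param ps an [image_patch_set()].
#' @param cfg an [lpf_config()].
#' @return the filtered set, re-quantised to 8 bits.
#' @export
lpf_patchset <- function(ps, cfg) {
  ps$images <- lapply(ps$images, function(im) round(fourier_lpf(im, cfg)))
  ps
}
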