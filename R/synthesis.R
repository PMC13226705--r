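# Synthetic histology-like image patches.
#
# The generator emulates the texture statistics that make H&E tissue classes
# separable for a feature extractor: each class has a characteristic
# background colour (stroma/eosin tone) and a characteristic density and size
# of dark nucleus-like elliptical blobs, plus i.i.d. Gaussian pixel noise.
# It makes no attempt at histological realism beyond class-separable texture.

#' Image patch set container
#'
#' Holds a list of 8-bit RGB image patches together with integer class labels
#' (0-based, in `[0, C)`), class names and unique string identifiers.
#'
#' @param images list of `H x W x 3` numeric arrays with values in `[0, 255]`.
#' @param labels integer vector of class ids, one per image, each in `[0, C)`.
#' @param class_names character vector of length `C`.
#' @param ids character vector of unique per-patch identifiers.
#' @return An object of class `image_patch_set`.
#' @export
image_patch_set <- function(images, labels, class_names, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("img_%05d", seq_along(images))
  obj <- structure(list(images = images, labels = as.integer(labels),
                        class_names = as.character(class_names),
                        ids = as.character(ids)),
                   class = "image_patch_set")
  validate_patchset(obj)
  obj
}

#' @keywords internal
validate_patchset <- function(ps) {
  stopifnot(inherits(ps, "image_patch_set"))
  n <- length(ps$images)
  if (length(ps$labels) != n) stop("labels length must equal number of images")
  if (length(ps$ids) != n) stop("ids length must equal number of images")
  if (anyDuplicated(ps$ids)) stop("patch ids must be unique")
  C <- length(ps$class_names)
  if (n > 0L) {
    if (any(ps$labels < 0L) || any(ps$labels >= C))
      stop("labels must lie in [0, C)")
    d <- dim(ps$images[[1L]])
    for (im in ps$images) {
      if (!identical(dim(im), d)) stop("all patches must share identical dimensions")
      r <- range(im)
      if (r[1L] < 0 || r[2L] > 255) stop("pixel values must lie in [0, 255]")
    }
  }
  invisible(ps)
}

#' @export
print.image_patch_set <- function(x, ...) {
  d <- if (length(x$images)) paste(dim(x$images[[1L]]), collapse = "x") else "empty"
  cat(sprintf("<image_patch_set> %d patches (%s), %d classes\n",
              length(x$images), d, length(x$class_names)))
  invisible(x)
}

#' Number of patches in a set
#' @param ps an `image_patch_set`.
#' @export
n_patches <- function(ps) length(ps$images)

#' Subset an image patch set
#' @param x an `image_patch_set`.
#' @param i index vector.
#' @param ... unused.
#' @export
`[.image_patch_set` <- function(x, i, ...) {
  image_patch_set(x$images[i], x$labels[i], x$class_names, x$ids[i])
}

#' Synthesis configuration for the synthetic patch generator
#'
#' Defines a multi-class textured-patch testbed: per-class background colour,
#' nucleus-like blob density (expected blob count per patch), blob radius
#' range and blob colour, with additive Gaussian pixel noise. Defaults follow
#' the scale of the colorectal-tissue benchmark the toolkit is modelled on:
#' nine classes, 100 patches per class, 224x224 pixels.
#'
#' @param n_classes number of classes `C`.
#' @param per_class patches generated per class.
#' @param image_size side length in pixels; must be divisible by `patch_size`.
#' @param patch_size encoder tile size the image must align to (default 14).
#' @param blob_density_range list of `C` numeric pairs `c(lo, hi)`: the range
#'   the expected blob count per patch is drawn from for each class (counts
#'   are scaled to `image_size` relative to the 224-pixel reference field).
#' @param blob_radius_range list of `C` numeric pairs: blob semi-axis range in
#'   pixels at the 224-pixel reference field (scaled with `image_size`).
#' @param background_color_per_class `C x 3` matrix of 8-bit RGB backgrounds.
#' @param blob_color_per_class `C x 3` matrix of 8-bit RGB blob colours.
#' @param noise_sd standard deviation of additive Gaussian pixel noise, in
#'   8-bit intensity units.
#' @param color_jitter_sd standard deviation of the per-patch RGB offset
#'   applied to the background and blob colours, in 8-bit units. Emulates
#'   staining variability between specimens: patches of one class share a
#'   colour band but are not identical, so within-class diversity is
#'   substantial relative to pixel noise.
#' @param seed integer RNG seed; generation is a pure function of this config.
#' @return An object of class `synthesis_config`.
#' @export
synthesis_config <- function(n_classes = 9L, per_class = 100L,
                             image_size = 224L, patch_size = 14L,
                             blob_density_range = NULL,
                             blob_radius_range = NULL,
                             background_color_per_class = NULL,
                             blob_color_per_class = NULL,
                             noise_sd = 3, color_jitter_sd = 5, seed = 1L) {
  n_classes <- as.integer(n_classes)
  per_class <- as.integer(per_class)
  image_size <- as.integer(image_size)
  if (n_classes < 1L) stop("n_classes must be >= 1")
  if (per_class < 1L) stop("per_class must be >= 1")
  if (image_size %% patch_size != 0L)
    stop(sprintf("image_size (%d) must be divisible by the encoder patch size (%d)",
                 image_size, patch_size))
  if (is.null(blob_density_range))
    blob_density_range <- lapply(seq_len(n_classes), function(c)
      c(10 + 22 * (c - 1), 16 + 22 * (c - 1)))
  if (is.null(blob_radius_range))
    blob_radius_range <- lapply(seq_len(n_classes), function(c)
      c(3 + 0.45 * (c - 1), 5 + 0.45 * (c - 1)))
  if (is.null(background_color_per_class))
    background_color_per_class <- default_background_palette(n_classes)
  if (is.null(blob_color_per_class))
    blob_color_per_class <- default_blob_palette(n_classes)
  background_color_per_class <- as.matrix(background_color_per_class)
  blob_color_per_class <- as.matrix(blob_color_per_class)
  for (nm in c("blob_density_range", "blob_radius_range")) {
    v <- get(nm)
    if (length(v) != n_classes)
      stop(sprintf("%s must have length n_classes", nm))
  }
  if (nrow(background_color_per_class) != n_classes ||
      nrow(blob_color_per_class) != n_classes)
    stop("per-class colour matrices must have n_classes rows")
  structure(list(n_classes = n_classes, per_class = per_class,
                 image_size = image_size, patch_size = as.integer(patch_size),
                 blob_density_range = blob_density_range,
                 blob_radius_range = blob_radius_range,
                 background_color_per_class = background_color_per_class,
                 blob_color_per_class = blob_color_per_class,
                 noise_sd = noise_sd, color_jitter_sd = color_jitter_sd,
                 seed = as.integer(seed)),
            class = "synthesis_config")
}

# Background palette: classes spread across the full hue circle with
# alternating saturation and lightness, so class mean colours are pairwise
# strongly separated (the role played by tissue-type appearance in stained
# slides). Blob colours are dark purple-to-blue, haematoxylin-like.
#' @keywords internal
default_background_palette <- function(C) {
  h <- (seq(0, C - 1) / C) %% 1
  s <- rep(c(0.45, 0.30), length.out = C)
  v <- rep(c(0.92, 0.70), length.out = C)
  t(sapply(seq_len(C), function(i) grDevices::col2rgb(grDevices::hsv(h[i], s[i], v[i]))[, 1L]))
}

#' @keywords internal
default_blob_palette <- function(C) {
  h <- seq(0.62, 0.80, length.out = C)
  t(sapply(seq_len(C), function(i) grDevices::col2rgb(grDevices::hsv(h[i], 0.65, 0.38))[, 1L]))
}

#' Generate a synthetic labelled patch set
#'
#' Renders `n_classes * per_class` textured RGB patches. Each patch gets its
#' class background colour, a Poisson-distributed number of soft-edged
#' elliptical blobs (centres placed with a minimum-separation rejection rule
#' so blobs rarely merge), and additive Gaussian noise, then is quantised to
#' 8 bits. The returned set is shuffled, but patch ids record the class of
#' origin. Generation is deterministic for a fixed config (seed included).
#'
#' @param config a [synthesis_config()].
#' @return An [image_patch_set()].
#' @export
generate_synthetic_patches <- function(config) {
  stopifnot(inherits(config, "synthesis_config"))
  with_seed(config$seed, {
    S <- config$image_size
    scale_area <- (S / 224)^2
    scale_len <- S / 224
    class_names <- sprintf("class%02d", seq_len(config$n_classes))
    images <- list(); labels <- integer(0); ids <- character(0)
    for (cl in seq_len(config$n_classes)) {
      dr <- config$blob_density_range[[cl]] * scale_area
      rr <- config$blob_radius_range[[cl]] * scale_len
      bg <- config$background_color_per_class[cl, ]
      fg <- config$blob_color_per_class[cl, ]
      for (k in seq_len(config$per_class)) {
        lambda <- stats::runif(1, dr[1L], dr[2L])
        n_blob <- stats::rpois(1, lambda)
        jbg <- clamp(bg + stats::rnorm(3L, 0, config$color_jitter_sd), 0, 255)
        jfg <- clamp(fg + stats::rnorm(3L, 0, config$color_jitter_sd), 0, 255)
        im <- render_blob_patch(S, jbg, jfg, n_blob, rr)
        if (config$noise_sd > 0)
          im <- im + array(stats::rnorm(length(im), 0, config$noise_sd), dim(im))
        images[[length(images) + 1L]] <- round(clamp(im, 0, 255))
        labels <- c(labels, cl - 1L)
        ids <- c(ids, sprintf("%s_%04d", class_names[cl], k))
      }
    }
    ord <- sample(length(images))
    image_patch_set(images[ord], labels[ord], class_names, ids[ord])
  })
}

# Render one patch: background colour plus n_blob soft-edged ellipses.
# Centres are drawn with rejection (up to 40 tries) against a minimum
# separation of the sum of radii, so the rendered blob count matches the
# requested count closely enough for connected-component checks.
#' @keywords internal
render_blob_patch <- function(S, bg, fg, n_blob, radius_range) {
  im <- array(rep(bg, each = S * S), c(S, S, 3L))
  if (n_blob == 0L) return(im)
  centers <- matrix(NA_real_, 0L, 2L)
  radii <- numeric(0)
  for (b in seq_len(n_blob)) {
    r <- stats::runif(1, radius_range[1L], radius_range[2L])
    for (try in 1:40) {
      cx <- stats::runif(1, r + 1, S - r)
      cy <- stats::runif(1, r + 1, S - r)
      if (nrow(centers) == 0L ||
          all(sqrt((centers[, 1L] - cy)^2 + (centers[, 2L] - cx)^2) >
              radii + r + 2)) break
    }
    centers <- rbind(centers, c(cy, cx))
    radii <- c(radii, r)
    b_ratio <- stats::runif(1, 0.6, 1)
    ang <- stats::runif(1, 0, pi)
    im <- draw_soft_ellipse(im, cy, cx, r, r * b_ratio, ang, fg)
  }
  im
}

#' @keywords internal
draw_soft_ellipse <- function(im, cy, cx, a, b, ang, color) {
  S <- dim(im)[1L]
  pad <- ceiling(a) + 3L
  ys <- max(1L, floor(cy - pad)):min(S, ceiling(cy + pad))
  xs <- max(1L, floor(cx - pad)):min(S, ceiling(cx + pad))
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- dy * cos(ang) + dx * sin(ang)
  v <- -dy * sin(ang) + dx * cos(ang)
  q <- sqrt((u / a)^2 + (v / b)^2)
  alpha <- 1 / (1 + exp((q - 1) / 0.08))   # soft, Gaussian-like edge
  for (ch in 1:3)
    im[ys, xs, ch] <- im[ys, xs, ch] * (1 - alpha) + color[ch] * alpha
  im
}
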