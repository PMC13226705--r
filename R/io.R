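# On-disk artifacts: PNG patches with CSV manifests, float-TIFF perturbations
# with JSON sidecar metadata. All formats are lossless and language-neutral.

#' Write an image patch set to disk
#'
#' Saves each patch as an 8-bit PNG under `dir/images/` and writes a CSV
#' manifest (`id`, `path`, `label`; header required) plus a `classes.json`
#' sidecar holding class names.
#'
#' @param ps an [image_patch_set()].
#' @param dir output directory (created if missing).
#' @return The manifest path, invisibly usable by [read_patchset()].
#' @export
write_patchset <- function(ps, dir) {
  validate_patchset(ps)
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  rel <- file.path("images", paste0(ps$ids, ".png"))
  for (i in seq_along(ps$images))
    png::writePNG(ps$images[[i]] / 255, file.path(dir, rel[i]))
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(id = ps$ids, path = rel, label = ps$labels),
                   manifest, row.names = FALSE)
  jsonlite::write_json(list(class_names = ps$class_names),
                       file.path(dir, "classes.json"), auto_unbox = FALSE)
  invisible(manifest)
}

#' Read an image patch set from a CSV manifest
#'
#' @param manifest_path path to a manifest CSV with columns `id`, `path`,
#'   `label` (paths relative to the manifest's directory, or absolute).
#' @return An [image_patch_set()]. An empty manifest yields an empty set with
#'   zero classes and a warning.
#' @export
read_patchset <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("id", "path", "label")
  if (!all(need %in% names(man)))
    stop("manifest must have columns id, path, label")
  base <- dirname(manifest_path)
  cls_file <- file.path(base, "classes.json")
  class_names <- if (file.exists(cls_file))
    unlist(jsonlite::read_json(cls_file)$class_names) else NULL
  if (nrow(man) == 0L) {
    warning("empty manifest: returning an empty patch set with 0 classes")
    return(image_patch_set(list(), integer(0), class_names %||% character(0)))
  }
  C <- if (!is.null(class_names)) length(class_names) else max(man$label) + 1L
  images <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    path <- man$path[i]
    if (!file.exists(path)) path <- file.path(base, man$path[i])
    if (!file.exists(path))
      stop(sprintf("manifest row %d (id '%s'): image file not found: %s",
                   i, man$id[i], man$path[i]))
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), c(dim(arr), 3L))
    if (dim(arr)[3L] > 3L) arr <- arr[, , 1:3, drop = FALSE]
    lab <- man$label[i]
    if (is.na(lab) || lab != as.integer(lab) || lab < 0L || lab >= C)
      stop(sprintf("manifest row %d (id '%s'): label %s outside [0, %d)",
                   i, man$id[i], as.character(man$label[i]), C))
    images[[i]] <- round(arr * 255)
  }
  image_patch_set(images, as.integer(man$label),
                  class_names %||% sprintf("class%02d", seq_len(C)),
                  man$id)
}

#' Save a perturbation as 32-bit float TIFF plus JSON metadata
#'
#' The pattern is stored offset-encoded (`(p + 1) / 2`) as a 32-bit float
#' TIFF, with a JSON sidecar (`<path>.json`) recording the epsilon bound,
#' provenance and an integrity checksum. Round-trips are exact at 32-bit
#' float precision.
#'
#' @param p a [perturbation()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
save_perturbation <- function(p, path) {
  stopifnot(inherits(p, "perturbation"))
  enc <- (p$values + 1) / 2
  if (min(enc) < 0 || max(enc) > 1)
    stop("perturbation values must lie within [-1, 1] for storage")
  tiff::writeTIFF(enc, path, bits.per.sample = 32L)
  meta <- list(epsilon_8bit = p$epsilon_8bit,
               shape = dim(p$values),
               encoding = "offset_half_float32",
               provenance = p$provenance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a perturbation saved by [save_perturbation()]
#'
#' @param path TIFF path written by [save_perturbation()].
#' @param expected_epsilon optional epsilon the caller requires; a mismatch
#'   with the recorded metadata is an explicit error.
#' @return A [perturbation()]. A stored array violating the recorded bound
#'   (allowing 32-bit rounding slack) raises an integrity error.
#' @export
load_perturbation <- function(path, expected_epsilon = NULL) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(path)) stop("perturbation file not found: ", path)
  if (!file.exists(meta_path)) stop("metadata sidecar not found: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!is.null(expected_epsilon) &&
      !isTRUE(all.equal(expected_epsilon, meta$epsilon_8bit)))
    stop(sprintf("epsilon mismatch: file was saved with epsilon = %g but %g was requested",
                 meta$epsilon_8bit, expected_epsilon))
  enc <- tiff::readTIFF(path)
  vals <- enc * 2 - 1
  if (max(abs(vals)) > meta$epsilon_8bit / 255 + 1e-5)
    stop(sprintf("integrity error: stored perturbation violates its recorded bound (max|p| = %.6g > %.6g)",
                 max(abs(vals)), meta$epsilon_8bit / 255))
  perturbation(vals, meta$epsilon_8bit,
               provenance = as.list(meta$provenance), tol = 1e-5)
}
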