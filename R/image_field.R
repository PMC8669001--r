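#' Calibrated multi-channel image field
#'
#' Container for a single microscopy field of view: one or more named
#' intensity arrays sharing a common shape, plus the physical pixel (or
#' voxel) size. Arrays are indexed `[y, x]` in 2D and `[y, x, z]` in 3D;
#' pixel `i` along an axis has its center at `(i - 0.5) * pixel_size` in
#' micrometres, so all exported coordinates are in physical units.
#'
#' @param channels named list of numeric arrays (all the same shape,
#'   finite, non-negative). Typical roles: `"dna"`, `"marker"`, `"fish"`,
#'   `"body"`, `"adhesion"`.
#' @param pixel_size physical pixel size in micrometres; either a single
#'   number (isotropic) or one value per axis.
#' @param condition optional condition label attached to the field
#'   (e.g. `"control"` / `"perturbed"`).
#' @param field_id optional identifier used in measurement tables.
#'
#' @return An object of class `ImageField`: a list with elements
#'   `channels`, `pixel_size` (per-axis, micrometres), `dim`, `ndim`,
#'   `condition`, `field_id`.
#' @examples
#' img <- matrix(runif(64 * 64), 64, 64)
#' fld <- image_field(list(dna = img), pixel_size = 0.2)
#' fld
#' @export
image_field <- function(channels, pixel_size, condition = NA_character_,
                        field_id = "field_1") {
  if (!is.list(channels) || length(channels) == 0 ||
      is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("'channels' must be a non-empty named list of arrays")
  dims <- dim(channels[[1]]) %||% length(channels[[1]])
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.numeric(ch))
      stop("channel '", nm, "' is not numeric")
    if (!identical(dim(ch) %||% length(ch), dims))
      stop("channel '", nm, "' does not share the common shape")
    if (any(!is.finite(ch)) || any(ch < 0))
      stop("channel '", nm, "' has non-finite or negative intensities")
  }
  ndim <- length(dims)
  if (!ndim %in% c(2L, 3L))
    stop("channels must be 2D or 3D arrays")
  pixel_size <- as.numeric(pixel_size)
  if (length(pixel_size) == 1L) pixel_size <- rep(pixel_size, ndim)
  if (length(pixel_size) != ndim || any(!is.finite(pixel_size)) ||
      any(pixel_size <= 0))
    stop("'pixel_size' must be positive, one value per axis (or scalar)")
  structure(list(channels = channels, pixel_size = pixel_size,
                 dim = dims, ndim = ndim, condition = condition,
                 field_id = field_id),
            class = "ImageField")
}

#' @export
print.ImageField <- function(x, ...) {
  cat("ImageField '", x$field_id, "': ",
      paste(x$dim, collapse = " x "), " px, ",
      paste(signif(x$pixel_size, 3), collapse = " x "), " um/px\n",
      sep = "")
  cat("  channels: ", paste(names(x$channels), collapse = ", "), "\n",
      sep = "")
  if (!is.na(x$condition))
    cat("  condition: ", x$condition, "\n", sep = "")
  invisible(x)
}

#' Integer-labeled segmentation map
#'
#' Wraps an integer array of object labels (`0` = background, objects
#' numbered `1..N` with no id skipped) together with the provenance of the
#' segmentation. Connectivity is 8-connected in 2D and 26-connected in 3D.
#'
#' @param labels integer array of labels.
#' @param provenance character note on which channel/operation produced
#'   the map.
#' @param host optional named integer vector mapping each object id to a
#'   parent object (e.g. focus to host nucleus).
#' @return An object of class `LabelMap` with elements `labels`,
#'   `n`, `provenance`, `host`.
#' @export
label_map <- function(labels, provenance = "unknown", host = NULL) {
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers")
  labels <- array(as.integer(labels), dim = dim(labels) %||% length(labels))
  ids <- sort(unique(labels[labels > 0]))
  n <- length(ids)
  if (n > 0 && !identical(ids, seq_len(n)))
    stop("object ids must be consecutive 1..N with none skipped")
  structure(list(labels = labels, n = n, provenance = provenance,
                 host = host),
            class = "LabelMap")
}

#' @export
print.LabelMap <- function(x, ...) {
  cat("LabelMap: ", x$n, " object(s), ",
      paste(dim(x$labels), collapse = " x "), " px (", x$provenance,
      ")\n", sep = "")
  invisible(x)
}

# Relabel an integer array so retained ids become consecutive 1..N.
# `keep` is the sorted vector of ids to retain.
relabel <- function(labels, keep) {
  out <- array(0L, dim = dim(labels))
  for (i in seq_along(keep)) out[labels == keep[i]] <- i
  out
}

# Pixel-center coordinates (micrometres) for every pixel of an array
# shape; returns a matrix with one column per axis in (y, x[, z]) order.
pixel_centers <- function(dims, pixel_size, which = NULL) {
  idx <- if (is.null(which)) seq_len(prod(dims)) else which
  arr_idx <- arrayInd(idx, dims)
  sweep(arr_idx - 0.5, 2, pixel_size, `*`)
}

#' Write an image field to disk
#'
#' Writes each channel as one page of a multi-page 32-bit float TIFF, and a
#' YAML sidecar (`<path>.meta.yaml`) recording channel names, pixel size,
#' condition and field id so the field round-trips losslessly through
#' [read_field()].
#'
#' @param field an [image_field()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "ImageField"))
  if (field$ndim != 2L)
    stop("TIFF export currently supports 2D fields")
  mx <- max(1, vapply(field$channels, max, numeric(1)))
  pages <- lapply(field$channels, function(ch) ch / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(channels = as.list(names(field$channels)),
               pixel_size_um = as.list(field$pixel_size),
               intensity_scale = mx,
               condition = field$condition,
               field_id = field$field_id)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read an image field from disk
#'
#' Reads a multi-page TIFF written by [write_field()] (or any multi-page
#' TIFF plus a channel map). Pixel size comes from the YAML sidecar when
#' present and can be overridden.
#'
#' @param path TIFF path.
#' @param channel_map optional character vector naming the pages to load,
#'   in page order; pages beyond its length are ignored with a warning.
#'   Defaults to the sidecar's channel names.
#' @param pixel_size optional micrometre pixel-size override; required if
#'   no sidecar exists.
#' @return An [image_field()].
#' @export
read_field <- function(path, channel_map = NULL, pixel_size = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else NULL
  if (is.null(channel_map))
    channel_map <- as.character(unlist(meta$channels))
  if (length(channel_map) == 0)
    stop("no channel map: pass 'channel_map' or provide a metadata sidecar")
  if (length(channel_map) < length(pages))
    warning(length(pages) - length(channel_map),
            " page(s) beyond the channel map were ignored")
  if (length(channel_map) > length(pages))
    stop("channel map names ", length(channel_map), " roles but the file has ",
         length(pages), " page(s)")
  scale <- meta$intensity_scale %||% 1
  channels <- lapply(pages[seq_along(channel_map)], function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # tolerate RGB pages
    p * scale
  })
  names(channels) <- channel_map
  px <- pixel_size %||% unlist(meta$pixel_size_um)
  if (is.null(px))
    stop("pixel size not recorded in metadata; pass 'pixel_size'")
  image_field(channels, pixel_size = px,
              condition = meta$condition %||% NA_character_,
              field_id = meta$field_id %||% basename(path))
}
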