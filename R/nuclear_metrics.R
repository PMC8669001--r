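#' Periphery/total mean-intensity ratio
#'
#' Mean fluorescence intensity of `channel` over the peripheral band
#' divided by its mean over the full nuclear area — the readout used to
#' detect redistribution of chromatin marks (H3.1/3.2, H3K27me3, ...)
#' away from the nuclear periphery. A spatially uniform nucleus gives
#' exactly 1; band-enriched signal gives values above 1.
#'
#' @param field an [image_field()].
#' @param channel marker channel name.
#' @param partition a `NuclearPartition` from [partition_periphery()].
#' @return Dimensionless ratio (single number).
#' @examples
#' ph <- generate_nucleus_phantom(phantom_spec(n_nuclei = 1, seed = 2,
#'   noise = list(photon_scale = 0, sigma = 0)))
#' p <- ph$truth$partitions[[1]]
#' periphery_total_ratio(ph$field, "marker", p)
#' @export
periphery_total_ratio <- function(field, channel, partition) {
  stopifnot(inherits(field, "ImageField"),
            inherits(partition, "NuclearPartition"))
  if (partition$degenerate)
    stop("degenerate partition for nucleus ", partition$nucleus_id,
         ": band covers the whole nucleus")
  img <- get_channel(field, channel)
  total_mean <- mean(img[partition$full])
  if (!is.finite(total_mean) || total_mean <= 0)
    stop("undefined ratio: zero total mean intensity in nucleus ",
         partition$nucleus_id)
  mean(img[partition$band]) / total_mean
}

#' Heterochromatic-foci/total mean-intensity ratio
#'
#' Mean intensity of `channel` over the union of a nucleus's
#' heterochromatic foci divided by the mean over the full nucleus.
#' Returns `NA` (metric absent, not zero) when the nucleus has no
#' segmented focus.
#'
#' @param field an [image_field()].
#' @param channel marker channel name.
#' @param foci focus [label_map()] (with `host` nucleus mapping).
#' @param partition the nucleus's `NuclearPartition` (or any object with
#'   a `full` mask and `nucleus_id`).
#' @return Dimensionless ratio, or `NA_real_` if the nucleus has no foci.
#' @export
foci_total_ratio <- function(field, channel, foci, partition) {
  stopifnot(inherits(field, "ImageField"), inherits(foci, "LabelMap"))
  img <- get_channel(field, channel)
  ids <- which((foci$host %||% integer(0)) == partition$nucleus_id)
  if (length(ids) == 0) return(NA_real_)
  fm <- array(foci$labels %in% ids, dim = dim(foci$labels)) &
    partition$full
  if (!any(fm)) return(NA_real_)
  total_mean <- mean(img[partition$full])
  if (!is.finite(total_mean) || total_mean <= 0)
    stop("undefined ratio: zero total mean intensity in nucleus ",
         partition$nucleus_id)
  mean(img[fm]) / total_mean
}

#' Nucleus size in physical units
#'
#' Pixel count times pixel area (2D, um^2) or voxel volume (3D, um^3).
#'
#' @param mask logical mask array, or a `NuclearPartition` (its `full`
#'   mask is used).
#' @param pixel_size micrometres per pixel (scalar or per axis).
#' @return Area (um^2) or volume (um^3).
#' @export
nucleus_size <- function(mask, pixel_size) {
  if (inherits(mask, "NuclearPartition")) mask <- mask$full
  n <- sum(mask)
  if (n == 0) stop("empty mask")
  nd <- length(dim(mask) %||% 1)
  pixel_size <- if (length(pixel_size) == 1L) rep(pixel_size, nd)
                else as.numeric(pixel_size)
  n * prod(pixel_size)
}

#' Per-nucleus intensity-ratio measurements for a field
#'
#' Runs [periphery_total_ratio()] (and, when a focus map is supplied,
#' [foci_total_ratio()]) for every non-degenerate nucleus and every
#' requested channel, returning one tidy row per (nucleus, channel).
#' Nuclei failing preconditions (degenerate band, zero total intensity)
#' are excluded and counted in the `qc` attribute rather than silently
#' dropped.
#'
#' @param field an [image_field()].
#' @param channels character vector of marker channel names.
#' @param partitions list from [partition_periphery()].
#' @param foci optional focus [label_map()].
#' @return A data frame with columns `field_id`, `condition`,
#'   `nucleus_id`, `channel`, `periphery_total_ratio`,
#'   `foci_total_ratio`, `total_mean`, `band_mean`, `foci_mean`,
#'   `nucleus_area_um2`; attribute `qc` lists excluded nuclei.
#' @export
measure_nuclei <- function(field, channels, partitions, foci = NULL) {
  rows <- list()
  qc <- character(0)
  for (p in partitions) {
    for (ch in channels) {
      img <- get_channel(field, ch)
      total_mean <- mean(img[p$full])
      if (p$degenerate || !is.finite(total_mean) || total_mean <= 0) {
        qc <- c(qc, sprintf("nucleus %d / channel %s excluded (%s)",
                            p$nucleus_id, ch,
                            if (p$degenerate) "degenerate band"
                            else "zero total intensity"))
        next
      }
      ptr <- periphery_total_ratio(field, ch, p)
      ftr <- if (is.null(foci)) NA_real_
             else foci_total_ratio(field, ch, foci, p)
      fm_mean <- if (is.na(ftr)) NA_real_ else ftr * total_mean
      rows[[length(rows) + 1L]] <- data.frame(
        field_id = field$field_id, condition = field$condition,
        nucleus_id = p$nucleus_id, channel = ch,
        periphery_total_ratio = ptr, foci_total_ratio = ftr,
        total_mean = total_mean, band_mean = ptr * total_mean,
        foci_mean = fm_mean, nucleus_area_um2 = p$area_um2)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(field_id = character(0), condition = character(0),
               nucleus_id = integer(0), channel = character(0),
               periphery_total_ratio = numeric(0),
               foci_total_ratio = numeric(0), total_mean = numeric(0),
               band_mean = numeric(0), foci_mean = numeric(0),
               nucleus_area_um2 = numeric(0))
  attr(out, "qc") <- qc
  out
}
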