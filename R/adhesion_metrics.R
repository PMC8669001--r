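#' Difference-of-Gaussian band-pass filter
#'
#' `Gaussian(sigma_low) * I - Gaussian(sigma_high) * I`: suppresses both
#' pixel noise (below `sigma_low`) and diffuse background (above
#' `sigma_high`), isolating punctate structures such as focal adhesions.
#' The response is identically zero on constant images and linear in the
#' input.
#'
#' @param field an [image_field()].
#' @param adhesion_channel channel to filter.
#' @param sigma_low,sigma_high Gaussian sigmas in micrometres,
#'   `0 < sigma_low < sigma_high`.
#' @return Numeric array of the filtered response (same shape).
#' @export
dog_bandpass <- function(field, adhesion_channel = "adhesion",
                         sigma_low = 0.2, sigma_high = 1.0) {
  stopifnot(inherits(field, "ImageField"))
  if (sigma_low <= 0 || sigma_low >= sigma_high)
    stop("need 0 < sigma_low < sigma_high")
  img <- get_channel(field, adhesion_channel)
  px <- field$pixel_size[1]
  EBImage::gblur(img, sigma = sigma_low / px) -
    EBImage::gblur(img, sigma = sigma_high / px)
}

#' Segment focal adhesions from a band-pass-filtered image
#'
#' Per cell, the threshold is `mean + k_threshold x SD` of the filtered
#' response inside that cell (adaptive, so per-cell background
#' differences do not bias counts); connected regions above threshold
#' and at least `min_area` become adhesions assigned to the cell. A cell
#' whose response has zero variance yields zero adhesions.
#'
#' The default `k_threshold = 1.5` is deliberate: the per-cell SD of the
#' band-pass response is inflated by the puncta themselves, so larger
#' multipliers cut far above the half-maximum of each punctum and
#' shrink recovered areas by 40% and more, while 1.5 keeps counts exact
#' and areas close to truth on noiseless and moderately noisy phantoms.
#'
#' @param filtered response array from [dog_bandpass()].
#' @param cells cell [label_map()].
#' @param k_threshold SD multiplier (default 1.5).
#' @param min_area minimum adhesion area (um^2).
#' @param pixel_size micrometres per pixel.
#' @return A list with `adhesions` (a [label_map()] with `host` cell
#'   mapping) and `records` (data frame: `cell_id`, `adhesion_id`,
#'   `area_um2`, `mean_response`, `centroid_y_um`, `centroid_x_um`).
#' @export
segment_adhesions <- function(filtered, cells, k_threshold = 1.5,
                              min_area = 0.1, pixel_size = 1) {
  stopifnot(inherits(cells, "LabelMap"))
  dims <- dim(filtered)
  pixel_size <- if (length(pixel_size) == 1L) rep(pixel_size, 2)
                else as.numeric(pixel_size)
  out <- array(0L, dim = dims)
  host <- integer(0)
  rows <- list()
  na <- 0L
  for (id in seq_len(cells$n)) {
    m <- cells$labels == id
    vals <- filtered[m]
    s <- sd(vals)
    if (!is.finite(s) || s == 0) next
    thr <- mean(vals) + k_threshold * s
    am <- array(FALSE, dim = dims)
    am[m] <- vals > thr
    lab <- label_mask(am)
    lab <- drop_small_objects(lab, min_area, pixel_size)
    ids <- sort(unique(lab[lab > 0]))
    for (k in ids) {
      sel <- lab == k
      na <- na + 1L
      out[sel] <- na
      host[na] <- id
      cc <- colMeans(pixel_centers(dims, pixel_size, which = which(sel)))
      rows[[na]] <- data.frame(cell_id = id, adhesion_id = na,
                               area_um2 = sum(sel) * prod(pixel_size),
                               mean_response = mean(filtered[sel]),
                               centroid_y_um = cc[1], centroid_x_um = cc[2])
    }
  }
  records <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = integer(0), adhesion_id = integer(0),
               area_um2 = numeric(0), mean_response = numeric(0),
               centroid_y_um = numeric(0), centroid_x_um = numeric(0))
  list(adhesions = label_map(out, provenance = "segment_adhesions",
                             host = if (length(host)) host else NULL),
       records = records)
}

#' Per-cell focal-adhesion summaries
#'
#' Counts and quantifies segmented adhesions on a per-cell basis:
#' adhesion count, total and mean adhesion area, and the cell-spreading
#' area (cell-mask area). A cell with no adhesions contributes a valid
#' row with zero count and areas.
#'
#' @param adhesion_records data frame from [segment_adhesions()].
#' @param cells cell [label_map()].
#' @param pixel_size micrometres per pixel.
#' @param condition optional condition label copied onto every row.
#' @return A `CellSummary` data frame: `cell_id`, `adhesion_count`,
#'   `total_adhesion_area_um2`, `mean_adhesion_area_um2`,
#'   `spreading_area_um2`, `condition`.
#' @export
summarize_cells <- function(adhesion_records, cells, pixel_size = 1,
                            condition = NA_character_) {
  stopifnot(inherits(cells, "LabelMap"))
  pixel_size <- if (length(pixel_size) == 1L) rep(pixel_size, 2)
                else as.numeric(pixel_size)
  px_area <- prod(pixel_size)
  cell_ids <- seq_len(cells$n)
  spread <- tabulate(cells$labels[cells$labels > 0], cells$n) * px_area
  count <- total <- meanarea <- numeric(length(cell_ids))
  for (i in cell_ids) {
    rec <- adhesion_records[adhesion_records$cell_id == i, , drop = FALSE]
    count[i] <- nrow(rec)
    total[i] <- sum(rec$area_um2)
    meanarea[i] <- if (nrow(rec)) mean(rec$area_um2) else 0
  }
  data.frame(cell_id = cell_ids, adhesion_count = as.integer(count),
             total_adhesion_area_um2 = total,
             mean_adhesion_area_um2 = meanarea,
             spreading_area_um2 = spread, condition = condition)
}
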