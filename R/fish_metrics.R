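#' Detect FISH spots inside nuclei
#'
#' Laplacian-of-Gaussian blob detection at `spot_scale`, restricted to the
#' nuclear masks. Local maxima of the scale-normalized LoG response are
#' kept when their response exceeds `snr_min` times the robust noise
#' level (1.4826 x MAD of the intranuclear response); centers are refined
#' to subpixel precision by an intensity-weighted centroid in a small
#' window of the raw channel. Spots outside any nucleus are discarded.
#'
#' @param field an [image_field()].
#' @param fish_channel FISH channel name.
#' @param nuclei nucleus [label_map()].
#' @param spot_scale expected spot Gaussian radius (um).
#' @param snr_min minimum response-to-noise ratio.
#' @return A `SpotSet` data frame: `field_id`, `condition`, `nucleus_id`,
#'   `y_um`, `x_um`, `response`, `snr`. Empty when nothing is detected.
#' @export
detect_spots <- function(field, fish_channel = "fish", nuclei,
                         spot_scale = 0.3, snr_min = 3) {
  stopifnot(inherits(field, "ImageField"), inherits(nuclei, "LabelMap"))
  if (field$ndim != 2L) stop("spot detection operates on 2D fields")
  if (spot_scale <= 0) stop("'spot_scale' must be positive")
  img <- get_channel(field, fish_channel)
  px <- field$pixel_size[1]
  sig <- max(spot_scale / px, 0.8)
  # scale-normalized LoG via difference of Gaussians (DoG ~ sigma^2 LoG)
  resp <- EBImage::gblur(img, sigma = sig) -
    EBImage::gblur(img, sigma = 1.6 * sig)
  inside <- nuclei$labels > 0
  empty <- spot_set_empty(field)
  if (!any(inside)) return(empty)
  noise <- 1.4826 * stats::mad(resp[inside], center = 0)
  if (noise <= 0) noise <- .Machine$double.eps
  peaks <- local_maxima(resp)
  keep <- which(peaks & inside & (resp / noise >= snr_min))
  if (length(keep) == 0) return(empty)
  ij <- arrayInd(keep, dim(resp))
  ord <- order(resp[keep], decreasing = TRUE)
  ij <- ij[ord, , drop = FALSE]
  rows <- list()
  taken <- array(FALSE, dim = dim(resp))
  w <- max(2L, as.integer(ceiling(sig)))
  for (k in seq_len(nrow(ij))) {
    i <- ij[k, 1]; j <- ij[k, 2]
    if (taken[i, j]) next
    ys <- max(1, i - w):min(dim(img)[1], i + w)
    xs <- max(1, j - w):min(dim(img)[2], j + w)
    taken[ys, xs] <- TRUE
    patch <- img[ys, xs, drop = FALSE]
    patch <- pmax(patch - min(patch), 0)
    tot <- sum(patch)
    cy <- if (tot > 0) sum((ys - 0.5) * rowSums(patch)) / tot else i - 0.5
    cx <- if (tot > 0) sum((xs - 0.5) * colSums(patch)) / tot else j - 0.5
    nid <- nuclei$labels[min(max(round(cy + 0.5), 1), dim(img)[1]),
                         min(max(round(cx + 0.5), 1), dim(img)[2])]
    if (nid == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      field_id = field$field_id, condition = field$condition,
      nucleus_id = as.integer(nid), y_um = cy * px,
      x_um = cx * field$pixel_size[2], response = resp[i, j],
      snr = resp[i, j] / noise)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  class(out) <- c("SpotSet", class(out))
  out
}

spot_set_empty <- function(field) {
  out <- data.frame(field_id = character(0), condition = character(0),
                    nucleus_id = integer(0), y_um = numeric(0),
                    x_um = numeric(0), response = numeric(0),
                    snr = numeric(0))
  class(out) <- c("SpotSet", class(out))
  out
}

# local maxima over the 8-neighborhood; plateaus count (a blob centered
# between pixel centers ties across neighbors), duplicates are removed
# later by the window suppression in detect_spots
local_maxima <- function(x) {
  d <- dim(x)
  pad <- matrix(-Inf, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- x
  res <- x > 0
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    res <- res & (x >= pad[(2 + dy):(d[1] + 1 + dy),
                           (2 + dx):(d[2] + 1 + dx)])
  }
  res
}

# Distance (physical units) from `centroid` to the first mask boundary
# crossing along the ray through `point`, by 0.1-px ray marching with
# linear interpolation at the exit. Works in 2D and 3D.
ray_exit_distance <- function(mask, centroid, point, pixel_size, dims) {
  dirv <- point - centroid
  len <- sqrt(sum(dirv^2))
  if (len == 0) return(0)
  u <- dirv / len
  step <- 0.1 * min(pixel_size)
  t_max <- sqrt(sum((dims * pixel_size)^2))
  ts <- seq(0, t_max, by = step)
  inside_at <- function(tv) {
    pts <- outer(tv, u)
    pts <- sweep(pts, 2, centroid, `+`)
    idx <- round(sweep(pts, 2, pixel_size, `/`) + 0.5)
    ok <- rep(TRUE, nrow(idx))
    for (a in seq_along(dims))
      ok <- ok & idx[, a] >= 1 & idx[, a] <= dims[a]
    res <- rep(FALSE, nrow(idx))
    if (any(ok)) {
      flat <- idx[ok, 1, drop = TRUE]
      mult <- 1
      for (a in seq_along(dims)[-1]) {
        mult <- mult * dims[a - 1]
        flat <- flat + (idx[ok, a] - 1) * mult
      }
      res[ok] <- mask[flat]
    }
    res
  }
  # march in chunks so long rays stop at the first boundary crossing
  chunk <- 256L
  if (!inside_at(0)) return(len)  # centroid itself outside (non-convex)
  for (start in seq(1L, length(ts), by = chunk)) {
    block <- ts[start:min(start + chunk - 1L, length(ts))]
    ins <- inside_at(block)
    first_out <- which(!ins)[1]
    if (!is.na(first_out)) {
      # linear interpolation between last inside and first outside sample
      return(block[first_out] - step / 2)
    }
  }
  ts[length(ts)]
}

#' Size-normalized relative radial position of a FISH spot
#'
#' The shortest distance from the spot to the nuclear centroid divided by
#' the length of the three-point line encompassing centroid, spot and
#' nuclear periphery — i.e. the distance from the centroid to the first
#' boundary crossing of the ray through the spot. The result is 0 at the
#' centroid, 1 on the nuclear edge, and invariant under uniform scaling
#' of the nucleus, which removes nuclear-size differences between cells.
#'
#' @param spot_um spot coordinates in micrometres (`(y, x)` or
#'   `(y, x, z)`), pixel-center convention.
#' @param mask logical nucleus mask.
#' @param centroid nucleus centroid in micrometres; computed from the
#'   mask when `NULL`.
#' @param pixel_size micrometres per pixel (scalar or per axis).
#' @return Relative position in `[0, 1]` (clamped after subpixel
#'   boundary interpolation).
#' @export
relative_radial_position <- function(spot_um, mask, centroid = NULL,
                                     pixel_size = 1) {
  dims <- dim(mask)
  nd <- length(dims)
  pixel_size <- if (length(pixel_size) == 1L) rep(pixel_size, nd)
                else as.numeric(pixel_size)
  idx <- pmin(pmax(round(spot_um / pixel_size + 0.5), 1), dims)
  flat <- idx[1]
  mult <- 1
  for (a in seq_len(nd)[-1]) {
    mult <- mult * dims[a - 1]
    flat <- flat + (idx[a] - 1) * mult
  }
  if (!mask[flat])
    stop("spot at (", paste(signif(spot_um, 4), collapse = ", "),
         ") um lies outside the nucleus mask")
  if (is.null(centroid))
    centroid <- colMeans(pixel_centers(dims, pixel_size,
                                       which = which(mask)))
  d_spot <- sqrt(sum((spot_um - centroid)^2))
  if (d_spot == 0) return(0)
  d_edge <- ray_exit_distance(mask, centroid, spot_um, pixel_size, dims)
  min(max(d_spot / d_edge, 0), 1)
}

#' Distance from a FISH spot to the nearest heterochromatic focus
#'
#' Euclidean distance (anisotropy-weighted in 3D) from the spot to the
#' nearest focus pixel, read off the distance transform of the focus-mask
#' complement; 0 when the spot lies inside a focus. Absent (`NA`) when
#' the field has no focus at all.
#'
#' @param spot_um spot coordinates in micrometres.
#' @param foci focus [label_map()] (or logical mask).
#' @param pixel_size micrometres per pixel (scalar or per axis).
#' @return Distance in micrometres, or `NA_real_` with a warning if the
#'   field contains no focus.
#' @export
distance_to_nearest_focus <- function(spot_um, foci, pixel_size = 1) {
  fm <- if (inherits(foci, "LabelMap")) foci$labels > 0 else foci > 0
  dims <- dim(fm)
  nd <- length(dims)
  pixel_size <- if (length(pixel_size) == 1L) rep(pixel_size, nd)
                else as.numeric(pixel_size)
  if (!any(fm)) {
    warning("no heterochromatic focus in the field; distance undefined")
    return(NA_real_)
  }
  dmap <- distance_transform(fm, spacing = pixel_size)
  idx <- pmin(pmax(round(spot_um / pixel_size + 0.5), 1), dims)
  flat <- idx[1]
  mult <- 1
  for (a in seq_len(nd)[-1]) {
    mult <- mult * dims[a - 1]
    flat <- flat + (idx[a] - 1) * mult
  }
  dmap[flat]
}

#' Measure positional metrics for a set of detected spots
#'
#' Applies [relative_radial_position()] and (when a focus map is given)
#' [distance_to_nearest_focus()] to every spot of a `SpotSet`, using the
#' partitions' masks and centroids.
#'
#' @param spots a `SpotSet` from [detect_spots()].
#' @param partitions list from [partition_periphery()].
#' @param foci optional focus [label_map()].
#' @param pixel_size micrometres per pixel.
#' @return The `SpotSet` with added columns `relative_position` and
#'   `distance_to_focus_um`. Spots that fall outside their nucleus after
#'   refinement are dropped.
#' @export
measure_spots <- function(spots, partitions, foci = NULL, pixel_size = 1) {
  if (nrow(spots) == 0) {
    spots$relative_position <- numeric(0)
    spots$distance_to_focus_um <- numeric(0)
    return(spots)
  }
  dmap_ready <- !is.null(foci) &&
    any(if (inherits(foci, "LabelMap")) foci$labels > 0 else foci > 0)
  rel <- dist_f <- rep(NA_real_, nrow(spots))
  keep <- rep(TRUE, nrow(spots))
  for (k in seq_len(nrow(spots))) {
    p <- partitions[[spots$nucleus_id[k]]]
    coord <- c(spots$y_um[k], spots$x_um[k])
    rel[k] <- tryCatch(
      relative_radial_position(coord, p$full, p$centroid, pixel_size),
      error = function(e) NA_real_)
    if (is.na(rel[k])) { keep[k] <- FALSE; next }
    if (dmap_ready)
      dist_f[k] <- distance_to_nearest_focus(coord, foci, pixel_size)
  }
  spots$relative_position <- rel
  spots$distance_to_focus_um <- dist_f
  spots[keep, , drop = FALSE]
}

#' Empirical CDF of relative radial positions, per condition
#'
#' Cumulative distribution frequencies of the relative position `r`,
#' computed per condition on sorted unique values (ties share a step) —
#' the standard presentation for locus-repositioning data.
#'
#' @param spots a `SpotSet` with a `relative_position` column.
#' @param by grouping column name (default `"condition"`).
#' @return A data frame with columns `condition` (or the `by` name),
#'   `r`, `F` (right-continuous, ending at 1). Empty groups are omitted
#'   with a warning.
#' @export
position_ecdf <- function(spots, by = "condition") {
  if (!by %in% names(spots)) stop("grouping column '", by, "' not present")
  groups <- split(spots$relative_position, spots[[by]], drop = TRUE)
  out <- list()
  for (g in names(groups)) {
    r <- groups[[g]][!is.na(groups[[g]])]
    if (length(r) == 0) {
      warning("group '", g, "' has no spots; omitted")
      next
    }
    Fn <- stats::ecdf(r)
    u <- sort(unique(r))
    df <- data.frame(u, Fn(u))
    names(df) <- c("r", "F")
    df[[by]] <- g
    out[[g]] <- df[, c(by, "r", "F")]
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
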