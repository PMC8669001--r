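#' Specification of a synthetic microscopy phantom
#'
#' Collects every parameter of the synthetic-image generator: field
#' geometry, nuclear geometry, how the chromatin marker signal is split
#' between the peripheral band and the interior, heterochromatic foci,
#' FISH spots, cells and focal-adhesion puncta, and the noise model.
#' Defaults emulate a typical 60x confocal field of cultured mammalian
#' cells: 0.2 um pixels, nuclei of 3.5-5 um semi-axis, a 25% peripheral
#' band holding 60% of the marker signal in the control-like state,
#' chromocenter-like foci 3-fold over nucleoplasm, and a dozen
#' focal-adhesion puncta per cell at 5-fold over cytoplasm.
#'
#' Two independent RNG streams are derived from `seed`: one for geometry
#' (placement), one for noise, so geometry can be held fixed while the
#' noise realization varies (set `noise_seed` to change only the noise).
#'
#' @param field_shape pixels per axis `(y, x)`.
#' @param pixel_size micrometres per pixel.
#' @param n_nuclei nuclei per field.
#' @param nucleus_radii range (um) from which each elliptical nucleus's
#'   semi-axes are drawn.
#' @param peripheral_fraction fraction `f_p` in `[0, 1]` of the total
#'   marker signal emitted from the peripheral band.
#' @param band_fraction band depth as a fraction of the equivalent
#'   radius; the same value must be used at analysis time.
#' @param n_foci heterochromatic foci per nucleus.
#' @param focus_radius focus radius (um).
#' @param focus_gain fold-brightness of foci over nucleoplasm (>= 1) in
#'   the DNA channel.
#' @param spots `NULL`, or a data frame with columns `nucleus` (index),
#'   `r` (target relative radial position in `[0, 1]`) and `azimuth`
#'   (radians) describing FISH spots.
#' @param spot_sigma Gaussian radius of a rendered FISH spot (um).
#' @param spot_amplitude peak intensity of a FISH spot above background.
#' @param n_adhesions focal-adhesion puncta per cell.
#' @param adhesion_radius punctum radius (um).
#' @param punctum_gap minimum edge-to-edge separation (um) between
#'   placed foci and between placed adhesion puncta; keeps discrete
#'   objects resolvable so ground-truth counts are meaningful.
#' @param adhesion_gain fold-brightness of puncta over cytoplasm (>= 1).
#' @param cell_radius cell-body radius (um).
#' @param nucleoplasm_level,marker_level,cytoplasm_level,background_level
#'   base intensity levels (arbitrary units; background is outside all
#'   objects, the marker channel has zero background so signal totals are
#'   exactly conserved).
#' @param noise list with `photon_scale` (Poisson component: intensity is
#'   replaced by `Poisson(I * photon_scale) / photon_scale`; `0` disables)
#'   and `sigma` (additive Gaussian read noise SD; `0` disables).
#' @param seed master RNG seed.
#' @param noise_seed optional separate seed for the noise stream.
#' @return An object of class `PhantomSpec`.
#' @export
phantom_spec <- function(field_shape = c(256L, 256L),
                         pixel_size = 0.2,
                         n_nuclei = 4L,
                         nucleus_radii = c(3.5, 5),
                         peripheral_fraction = 0.6,
                         band_fraction = 0.25,
                         n_foci = 4L,
                         focus_radius = 0.8,
                         focus_gain = 3,
                         spots = NULL,
                         spot_sigma = 0.3,
                         spot_amplitude = 300,
                         n_adhesions = 12L,
                         adhesion_radius = 0.6,
                         adhesion_gain = 5,
                         punctum_gap = 1.0,
                         cell_radius = 10,
                         nucleoplasm_level = 100,
                         marker_level = 100,
                         cytoplasm_level = 100,
                         background_level = 10,
                         noise = list(photon_scale = 1, sigma = 2),
                         seed = 1L,
                         noise_seed = NULL) {
  spec <- list(field_shape = as.integer(field_shape),
               pixel_size = pixel_size, n_nuclei = as.integer(n_nuclei),
               nucleus_radii = nucleus_radii,
               peripheral_fraction = peripheral_fraction,
               band_fraction = band_fraction, n_foci = as.integer(n_foci),
               focus_radius = focus_radius, focus_gain = focus_gain,
               spots = spots, spot_sigma = spot_sigma,
               spot_amplitude = spot_amplitude,
               n_adhesions = as.integer(n_adhesions),
               adhesion_radius = adhesion_radius,
               adhesion_gain = adhesion_gain, punctum_gap = punctum_gap,
               cell_radius = cell_radius,
               nucleoplasm_level = nucleoplasm_level,
               marker_level = marker_level,
               cytoplasm_level = cytoplasm_level,
               background_level = background_level,
               noise = noise, seed = as.integer(seed),
               noise_seed = noise_seed)
  class(spec) <- "PhantomSpec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(field_shape) != 2L || any(field_shape < 16L))
      stop("field_shape must be two axis lengths of at least 16 px")
    if (peripheral_fraction < 0 || peripheral_fraction > 1)
      stop("peripheral_fraction must lie in [0, 1]")
    if (band_fraction <= 0 || band_fraction >= 1)
      stop("band_fraction must lie in (0, 1)")
    radii <- c(nucleus_radii, focus_radius, adhesion_radius, cell_radius,
               spot_sigma, pixel_size)
    if (any(radii <= 0)) stop("all radii and sizes must be positive")
    if (punctum_gap < 0) stop("punctum_gap must be non-negative")
    if (focus_gain < 1 || adhesion_gain < 1)
      stop("all gains must be >= 1")
    if (n_nuclei < 0 || n_foci < 0 || n_adhesions < 0)
      stop("counts must be non-negative")
    if (!is.null(spots)) {
      spots <- as.data.frame(spots)
      if (!all(c("nucleus", "r", "azimuth") %in% names(spots)))
        stop("'spots' needs columns nucleus, r, azimuth")
      if (any(spots$r < 0 | spots$r > 1))
        stop("spot relative positions must lie in [0, 1]")
      if (any(spots$nucleus < 1 | spots$nucleus > n_nuclei))
        stop("each spot's generating nucleus must exist")
    }
  })
  invisible(spec)
}

#' @export
print.PhantomSpec <- function(x, ...) {
  cat("PhantomSpec: ", paste(x$field_shape, collapse = " x "), " px @ ",
      x$pixel_size, " um/px, ", x$n_nuclei, " nuclei, f_p = ",
      x$peripheral_fraction, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# --- ellipse machinery (pixel units, pixel-center coordinates) ----------

rasterize_ellipse <- function(dims, cy, cx, a, b, theta) {
  y <- seq_len(dims[1]) - 0.5
  x <- seq_len(dims[2]) - 0.5
  dy <- matrix(y - cy, dims[1], dims[2])
  dx <- matrix(x - cx, dims[1], dims[2], byrow = TRUE)
  u <- dy * cos(theta) + dx * sin(theta)
  v <- -dy * sin(theta) + dx * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# Distance (pixels) from the ellipse center to its boundary along the unit
# direction (dy, dx); used to place FISH spots at an exact relative radius.
ellipse_ray_extent <- function(a, b, theta, dy, dx) {
  u <- dy * cos(theta) + dx * sin(theta)
  v <- -dy * sin(theta) + dx * cos(theta)
  1 / sqrt((u / a)^2 + (v / b)^2)
}

# Rejection-sample non-overlapping ellipses away from the field border.
# Returns a data frame (cy, cx, a, b, theta) in pixel units.
place_ellipses <- function(dims, n, radii_px, max_tries = 400L) {
  out <- data.frame(cy = numeric(0), cx = numeric(0), a = numeric(0),
                    b = numeric(0), theta = numeric(0))
  if (n == 0) return(out)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      ab <- sort(runif(2, radii_px[1], radii_px[2]), decreasing = TRUE)
      # border clearance includes room for analysis-time smoothing, so
      # a segmented object never touches the field border spuriously
      margin <- ab[1] + 5
      if (2 * margin >= min(dims)) next
      cy <- runif(1, margin, dims[1] - margin)
      cx <- runif(1, margin, dims[2] - margin)
      theta <- runif(1, 0, pi)
      ok <- TRUE
      if (nrow(out) > 0) {
        dist <- sqrt((out$cy - cy)^2 + (out$cx - cx)^2)
        # 8 px edge-to-edge clearance: close pairs would fuse into one
        # component once the channel is smoothed at analysis time
        ok <- all(dist > out$a + ab[1] + 8)
      }
      if (ok) {
        out[i, ] <- c(cy, cx, ab[1], ab[2], theta)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("placement failure: could not fit ", n,
           " non-overlapping nuclei/cells in the field")
  }
  out
}

# Place n disk centers inside an ellipse, pairwise separated by at least
# gap_px between disk edges so neighboring puncta stay resolvable, at
# normalized elliptical radius <= rho_max. Returns a (cy, cx) matrix.
place_inside_ellipse <- function(ell, n, r_px, rho_max = 0.7,
                                 max_tries = 200L, gap_px = 1,
                                 max_restarts = 50L) {
  out <- matrix(NA_real_, n, 2)
  if (n == 0) return(out)
  # greedy rejection sampling can paint itself into a corner in tight
  # configurations; restart the whole set when that happens
  for (restart in seq_len(max_restarts)) {
    out[] <- NA_real_
    done <- TRUE
    for (i in seq_len(n)) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        rho <- sqrt(runif(1)) * rho_max
        phi <- runif(1, 0, 2 * pi)
        u <- rho * ell$a * cos(phi)
        v <- rho * ell$b * sin(phi)
        cy <- ell$cy + u * cos(ell$theta) - v * sin(ell$theta)
        cx <- ell$cx + u * sin(ell$theta) + v * cos(ell$theta)
        ok <- TRUE
        if (i > 1) {
          d <- sqrt((out[seq_len(i - 1), 1] - cy)^2 +
                      (out[seq_len(i - 1), 2] - cx)^2)
          ok <- all(d > 2 * r_px + gap_px)
        }
        if (ok) {
          out[i, ] <- c(cy, cx)
          placed <- TRUE
          break
        }
      }
      if (!placed) { done <- FALSE; break }
    }
    if (done) return(out)
  }
  stop("placement failure: could not fit ", n,
       " non-overlapping puncta inside the object")
}

apply_noise <- function(img, noise) {
  ps <- noise$photon_scale %||% 0
  sg <- noise$sigma %||% 0
  if (ps > 0)
    img <- array(rpois(length(img), pmax(img, 0) * ps) / ps, dim = dim(img))
  if (sg > 0)
    img <- img + array(rnorm(length(img), 0, sg), dim = dim(img))
  pmax(img, 0)
}

noise_off <- function(noise) {
  (noise$photon_scale %||% 0) <= 0 && (noise$sigma %||% 0) <= 0
}

# Shared geometry synthesis: nuclei masks + label map + partitions + foci.
synth_nuclei <- function(spec) {
  dims <- spec$field_shape
  px <- spec$pixel_size
  ells <- place_ellipses(dims, spec$n_nuclei, spec$nucleus_radii / px)
  labels <- array(0L, dim = dims)
  for (i in seq_len(nrow(ells))) {
    m <- rasterize_ellipse(dims, ells$cy[i], ells$cx[i], ells$a[i],
                           ells$b[i], ells$theta[i])
    labels[m] <- i
  }
  nuclei <- label_map(labels, provenance = "phantom ground truth")
  parts <- partition_periphery(nuclei, band_fraction = spec$band_fraction,
                               pixel_size = px)
  foci_labels <- array(0L, dim = dims)
  host <- integer(0)
  if (spec$n_foci > 0 && spec$n_nuclei > 0) {
    r_px <- spec$focus_radius / px
    nf <- 0L
    for (i in seq_len(nrow(ells))) {
      centers <- place_inside_ellipse(ells[i, ], spec$n_foci, r_px,
                                      gap_px = spec$punctum_gap / px)
      for (k in seq_len(nrow(centers))) {
        m <- rasterize_ellipse(dims, centers[k, 1], centers[k, 2],
                               r_px, r_px, 0)
        nf <- nf + 1L
        foci_labels[m] <- nf
        host[nf] <- i
      }
    }
  }
  foci <- label_map(foci_labels, provenance = "phantom ground truth",
                    host = if (length(host)) host else NULL)
  list(ells = ells, nuclei = nuclei, partitions = parts, foci = foci)
}

render_dna <- function(spec, geom) {
  dna <- array(spec$background_level, dim = spec$field_shape)
  dna[geom$nuclei$labels > 0] <- spec$nucleoplasm_level +
    spec$background_level
  dna[geom$foci$labels > 0] <- spec$focus_gain * spec$nucleoplasm_level +
    spec$background_level
  dna
}

render_marker <- function(spec, geom) {
  marker <- array(0, dim = spec$field_shape)
  f_p <- spec$peripheral_fraction
  for (p in geom$partitions) {
    total <- spec$marker_level * sum(p$full)
    n_band <- sum(p$band)
    n_int <- sum(p$interior)
    if (n_int == 0) {
      marker[p$band] <- total / n_band
    } else {
      marker[p$band] <- f_p * total / n_band
      marker[p$interior] <- (1 - f_p) * total / n_int
    }
  }
  marker
}

#' Generate a nuclear-architecture phantom
#'
#' Builds a two-channel field: a DNA channel (nucleoplasm plus bright
#' heterochromatic foci) and a marker channel in which exactly
#' `peripheral_fraction` of each nucleus's integrated signal lies inside
#' the peripheral band. The band is produced by [partition_periphery()]
#' itself (same band fraction), so the noiseless band/total integral
#' recovers `f_p` exactly by construction; noise is applied last.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `field` (an [image_field()] with channels
#'   `dna` and `marker`) and `truth` (ground truth: `nuclei` and `foci`
#'   [label_map()]s, `partitions`, per-nucleus table `nuclei_table` with
#'   true `f_p`, and the noiseless channels).
#' @examples
#' ph <- generate_nucleus_phantom(phantom_spec(n_nuclei = 2, seed = 7))
#' ph$field
#' @export
generate_nucleus_phantom <- function(spec) {
  validate_phantom_spec(spec)
  set.seed(derive_seed(spec$seed, 1))
  geom <- synth_nuclei(spec)
  dna <- render_dna(spec, geom)
  marker <- render_marker(spec, geom)
  truth <- build_truth(spec, geom, clean = list(dna = dna, marker = marker))
  set.seed(derive_seed(spec$noise_seed %||% spec$seed, 2))
  field <- image_field(list(dna = apply_noise(dna, spec$noise),
                            marker = apply_noise(marker, spec$noise)),
                       pixel_size = spec$pixel_size)
  list(field = field, truth = truth)
}

build_truth <- function(spec, geom, clean, extra = list()) {
  px <- spec$pixel_size
  tab <- do.call(rbind, lapply(geom$partitions, function(p) {
    data.frame(nucleus_id = p$nucleus_id,
               centroid_y_um = p$centroid[1], centroid_x_um = p$centroid[2],
               area_um2 = sum(p$full) * prod(px),
               f_p = spec$peripheral_fraction)
  }))
  structure(c(list(nuclei = geom$nuclei, foci = geom$foci,
                   partitions = geom$partitions, nuclei_table = tab,
                   clean = clean, spec = spec),
              extra),
            class = "GroundTruth")
}

#' Generate a DNA-FISH phantom
#'
#' As [generate_nucleus_phantom()], plus a `fish` channel holding one
#' Gaussian blob per requested spot. Each blob is centered on the point of
#' the azimuth ray from the nucleus centroid at which the relative radial
#' position equals the requested `r` (computed analytically on the
#' generating ellipse), so ground-truth positions are exact.
#'
#' @param spec a [phantom_spec()] with a non-`NULL` `spots` entry.
#' @return A list `field` / `truth`; `truth$spots` holds exact centers
#'   (um) and target relative positions.
#' @export
generate_fish_phantom <- function(spec) {
  validate_phantom_spec(spec)
  if (is.null(spec$spots)) stop("'spots' must be given for a FISH phantom")
  spots <- as.data.frame(spec$spots)
  set.seed(derive_seed(spec$seed, 1))
  geom <- synth_nuclei(spec)
  dna <- render_dna(spec, geom)
  px <- spec$pixel_size
  dims <- spec$field_shape
  fish <- array(spec$background_level, dim = dims)
  yy <- matrix(seq_len(dims[1]) - 0.5, dims[1], dims[2])
  xx <- matrix(seq_len(dims[2]) - 0.5, dims[1], dims[2], byrow = TRUE)
  centers <- data.frame(nucleus_id = integer(0), y_um = numeric(0),
                        x_um = numeric(0), r_star = numeric(0),
                        azimuth = numeric(0))
  sig <- spec$spot_sigma / px
  for (k in seq_len(nrow(spots))) {
    ell <- geom$ells[spots$nucleus[k], ]
    dy <- cos(spots$azimuth[k])
    dx <- sin(spots$azimuth[k])
    ext <- ellipse_ray_extent(ell$a, ell$b, ell$theta, dy, dx)
    cy <- ell$cy + spots$r[k] * ext * dy
    cx <- ell$cx + spots$r[k] * ext * dx
    fish <- fish + spec$spot_amplitude *
      exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * sig^2))
    centers[k, ] <- c(spots$nucleus[k], cy * px, cx * px, spots$r[k],
                      spots$azimuth[k])
  }
  truth <- build_truth(spec, geom,
                       clean = list(dna = dna, fish = fish),
                       extra = list(spots = centers))
  set.seed(derive_seed(spec$noise_seed %||% spec$seed, 2))
  field <- image_field(list(dna = apply_noise(dna, spec$noise),
                            fish = apply_noise(fish, spec$noise)),
                       pixel_size = px)
  list(field = field, truth = truth)
}

#' Generate a focal-adhesion phantom
#'
#' Builds a `body` channel (smooth cytoplasm disk per cell) and an
#' `adhesion` channel: cytoplasmic background plus `n_adhesions`
#' non-overlapping disk puncta of radius `adhesion_radius` at
#' `adhesion_gain`-fold brightness, per cell.
#'
#' @param spec a [phantom_spec()].
#' @return A list `field` / `truth`; `truth$cells` and `truth$adhesions`
#'   are ground-truth [label_map()]s, `truth$adhesion_table` the per-punctum
#'   areas.
#' @export
generate_adhesion_phantom <- function(spec) {
  validate_phantom_spec(spec)
  px <- spec$pixel_size
  dims <- spec$field_shape
  r_cell <- spec$cell_radius / px
  r_adh <- spec$adhesion_radius / px
  if (spec$n_adhesions * pi * r_adh^2 >= 0.5 * pi * r_cell^2)
    stop("cell mask must be larger than the union of adhesions")
  set.seed(derive_seed(spec$seed, 1))
  n_cells <- max(1L, spec$n_nuclei)
  ells <- place_ellipses(dims, n_cells, c(r_cell, r_cell))
  cell_labels <- array(0L, dim = dims)
  adh_labels <- array(0L, dim = dims)
  host <- integer(0)
  body <- array(spec$background_level, dim = dims)
  adhesion <- array(spec$background_level, dim = dims)
  na <- 0L
  for (i in seq_len(nrow(ells))) {
    m <- rasterize_ellipse(dims, ells$cy[i], ells$cx[i], ells$a[i],
                           ells$b[i], ells$theta[i])
    cell_labels[m] <- i
    body[m] <- spec$cytoplasm_level + spec$background_level
    adhesion[m] <- spec$cytoplasm_level / 2 + spec$background_level
    if (spec$n_adhesions > 0) {
      centers <- place_inside_ellipse(ells[i, ], spec$n_adhesions, r_adh,
                                      rho_max = 0.85,
                                      gap_px = spec$punctum_gap / px)
      for (k in seq_len(nrow(centers))) {
        pm <- rasterize_ellipse(dims, centers[k, 1], centers[k, 2],
                                r_adh, r_adh, 0)
        na <- na + 1L
        adh_labels[pm] <- na
        host[na] <- i
        adhesion[pm] <- spec$adhesion_gain *
          (spec$cytoplasm_level / 2) + spec$background_level
      }
    }
  }
  cells <- label_map(cell_labels, provenance = "phantom ground truth")
  adhesions <- label_map(adh_labels, provenance = "phantom ground truth",
                         host = if (length(host)) host else NULL)
  adh_tab <- if (na > 0) {
    data.frame(adhesion_id = seq_len(na), cell_id = host,
               area_um2 = as.numeric(tabulate(adh_labels[adh_labels > 0],
                                              na)) * prod(px, px))
  } else {
    data.frame(adhesion_id = integer(0), cell_id = integer(0),
               area_um2 = numeric(0))
  }
  truth <- structure(list(cells = cells, adhesions = adhesions,
                          adhesion_table = adh_tab,
                          clean = list(body = body, adhesion = adhesion),
                          spec = spec),
                     class = "GroundTruth")
  set.seed(derive_seed(spec$noise_seed %||% spec$seed, 2))
  field <- image_field(list(body = apply_noise(body, spec$noise),
                            adhesion = apply_noise(adhesion, spec$noise)),
                       pixel_size = px)
  list(field = field, truth = truth)
}

#' Generate a two-condition phantom experiment
#'
#' Renders `n_fields` independent fields per condition, with per-field
#' seeds derived from the master seed, and attaches the condition label
#' and a field id to every field and ground truth. This is the entry
#' point for end-to-end control-vs-perturbed comparisons (e.g. reduced
#' peripheral fraction, or fewer/smaller adhesions, in the perturbed
#' condition).
#'
#' @param control_spec,perturbed_spec [phantom_spec()]s for the two
#'   conditions.
#' @param n_fields fields per condition (>= 1).
#' @param seed master seed; per-field seeds are derived from it.
#' @param kind which phantom type to render: `"nucleus"`, `"fish"` or
#'   `"adhesion"`.
#' @return A list of per-field lists, each with `field`, `truth`,
#'   `condition` (`"control"` / `"perturbed"`) and `field_id`.
#' @export
generate_two_condition_experiment <- function(control_spec, perturbed_spec,
                                              n_fields, seed = 1L,
                                              kind = c("nucleus", "fish",
                                                       "adhesion")) {
  kind <- match.arg(kind)
  if (n_fields < 1) stop("'n_fields' must be at least 1")
  gen <- switch(kind, nucleus = generate_nucleus_phantom,
                fish = generate_fish_phantom,
                adhesion = generate_adhesion_phantom)
  out <- list()
  conds <- c(control = list(control_spec), perturbed = list(perturbed_spec))
  for (ci in seq_along(conds)) {
    cond <- names(conds)[ci]
    validate_phantom_spec(conds[[ci]])
    for (f in seq_len(n_fields)) {
      sp <- conds[[ci]]
      sp$seed <- derive_seed(seed, ci * 100003L + f)
      sp$noise_seed <- NULL
      ph <- gen(sp)
      ph$condition <- cond
      ph$field_id <- sprintf("%s_%02d", cond, f)
      ph$field$condition <- cond
      ph$field$field_id <- ph$field_id
      out[[length(out) + 1L]] <- ph
    }
  }
  out
}
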