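#' Pipeline configuration
#'
#' Collects everything a reproducible run needs: the input fields (either
#' in-memory [image_field()]s or a manifest of TIFF paths with condition
#' labels), the channel-role mapping, every stage parameter, the RNG
#' seed and an optional output directory. `(config, seed)` fully
#' determines the outputs.
#'
#' @param fields list of [image_field()]s, or a data frame manifest with
#'   columns `path` and `condition` (optional `field_id`).
#' @param channels named list mapping roles to channel names: `dna`,
#'   `markers` (character vector), `fish`, `body`, `adhesion`. Roles set
#'   to `NULL` are skipped; a role naming a channel absent from a field
#'   is skipped for that field.
#' @param params named list of stage parameters; unset entries take the
#'   documented stage defaults. Recognized: `band_fraction`,
#'   `min_nucleus_area`, `smoothing_scale`, `focus_scale`,
#'   `min_focus_area`, `spot_scale`, `snr_min`, `sigma_low`,
#'   `sigma_high`, `k_threshold`, `min_adhesion_area`, `min_cell_area`.
#' @param seed RNG seed recorded with the run.
#' @param output_dir if non-`NULL`, CSV/JSON outputs and the run log are
#'   written there.
#' @return An object of class `PipelineConfig`.
#' @export
pipeline_config <- function(fields,
                            channels = list(dna = "dna",
                                            markers = "marker",
                                            fish = "fish",
                                            body = "body",
                                            adhesion = "adhesion"),
                            params = list(), seed = 1L,
                            output_dir = NULL) {
  defaults <- list(band_fraction = 0.25, min_nucleus_area = 20,
                   smoothing_scale = 0.5, focus_scale = 1,
                   min_focus_area = 0.2, spot_scale = 0.3, snr_min = 3,
                   sigma_low = 0.2, sigma_high = 1.0, k_threshold = 1.5,
                   min_adhesion_area = 0.1, min_cell_area = 50)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  params <- utils::modifyList(defaults, params)
  if (params$band_fraction <= 0 || params$band_fraction >= 1)
    stop("band_fraction must lie in (0, 1)")
  if (params$sigma_low <= 0 || params$sigma_low >= params$sigma_high)
    stop("need 0 < sigma_low < sigma_high")
  if (params$snr_min < 0 || params$k_threshold < 0)
    stop("snr_min and k_threshold must be non-negative")
  if (is.data.frame(fields)) {
    if (!all(c("path", "condition") %in% names(fields)))
      stop("a manifest needs 'path' and 'condition' columns")
  } else if (!is.list(fields) ||
             !all(vapply(fields, inherits, logical(1), "ImageField"))) {
    stop("'fields' must be ImageFields or a manifest data frame")
  }
  structure(list(fields = fields, channels = channels, params = params,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "PipelineConfig")
}

#' Read / write a pipeline configuration file
#'
#' Plain-text YAML round-trip of channel roles, stage parameters, seed
#' and the input manifest (in-memory fields are not serialized).
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "PipelineConfig"))
  manifest <- if (is.data.frame(config$fields))
    lapply(seq_len(nrow(config$fields)),
           function(i) as.list(config$fields[i, ])) else list()
  yaml::write_yaml(list(channels = config$channels,
                        params = config$params, seed = config$seed,
                        output_dir = config$output_dir,
                        manifest = manifest), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  fields <- if (length(y$manifest))
    do.call(rbind, lapply(y$manifest, as.data.frame)) else
      stop("config has no manifest; supply fields in code")
  pipeline_config(fields, channels = y$channels, params = y$params,
                  seed = y$seed, output_dir = y$output_dir)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(list(channels = config$channels,
                        params = config$params, seed = config$seed), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full quantification pipeline
#'
#' For every input field: segment nuclei, partition the periphery,
#' segment heterochromatic foci, measure periphery/total and foci/total
#' intensity ratios and nuclear areas for each marker channel; detect
#' and measure FISH spots when a FISH channel is present; band-pass
#' filter, segment and summarize focal adhesions when adhesion/body
#' channels are present. Per-field failures are isolated: the field is
#' logged and the run continues. Finally, every metric observed in two
#' or more conditions is compared with the appropriate nonparametric
#' test.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `PipelineResult`:
#'   `measurements` (long-format table: `field_id`, `object_type`,
#'   `object_id`, `metric`, `value`, `units`, `condition`,
#'   `config_hash`), `comparisons` (named list of `ComparisonResult`),
#'   `log` (character), `errors` (per-field error messages),
#'   `config_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  set.seed(config$seed)
  hash <- config_hash(config)
  p <- config$params
  roles <- config$channels
  log <- character(0)
  errors <- character(0)
  rows <- list()
  note <- function(...) log <<- c(log, sprintf(...))

  fields <- config$fields
  n_fields <- if (is.data.frame(fields)) nrow(fields) else length(fields)
  for (i in seq_len(n_fields)) {
    t0 <- proc.time()[["elapsed"]]
    fid <- if (is.data.frame(fields)) basename(fields$path[i]) else NULL
    res <- tryCatch({
      field <- if (is.data.frame(fields)) {
        f <- read_field(fields$path[i])
        f$condition <- fields$condition[i]
        if (!is.null(fields$field_id)) f$field_id <- fields$field_id[i]
        f
      } else fields[[i]]
      fid <- field$field_id
      process_field(field, roles, p)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      msg <- sprintf("field %s: %s", fid %||% as.character(i),
                     conditionMessage(res))
      errors <- c(errors, msg)
      note("ERROR %s", msg)
      next
    }
    rows[[length(rows) + 1L]] <- res
    note("field %s: %d measurement row(s) in %.2f s",
         fid, nrow(res), proc.time()[["elapsed"]] - t0)
  }
  measurements <- if (length(rows)) do.call(rbind, rows) else
    data.frame(field_id = character(0), object_type = character(0),
               object_id = integer(0), metric = character(0),
               value = numeric(0), units = character(0),
               condition = character(0))
  if (nrow(measurements))
    measurements$config_hash <- hash

  comparisons <- list()
  if (nrow(measurements)) {
    for (m in unique(measurements$metric)) {
      sub <- measurements[measurements$metric == m &
                            !is.na(measurements$value), , drop = FALSE]
      conds <- unique(sub$condition[!is.na(sub$condition)])
      if (length(conds) >= 2) {
        sub$value_num <- sub$value
        comparisons[[m]] <- summarize_metric(
          data.frame(value = sub$value, condition = sub$condition),
          "value", "condition")
        comparisons[[m]]$metric <- m
        note("compared '%s' across %d conditions (p = %.4g)", m,
             length(conds), comparisons[[m]]$p_value)
      }
    }
  }
  out <- structure(list(measurements = measurements,
                        comparisons = comparisons, log = log,
                        errors = errors, config_hash = hash),
                   class = "PipelineResult")
  if (!is.null(config$output_dir)) write_pipeline_outputs(out, config)
  out
}

# All measurements for one field, as long-format rows.
process_field <- function(field, roles, p) {
  rows <- list()
  add <- function(object_type, object_id, metric, value, units) {
    rows[[length(rows) + 1L]] <<- data.frame(
      field_id = field$field_id, object_type = object_type,
      object_id = as.integer(object_id), metric = metric,
      value = as.numeric(value), units = units,
      condition = field$condition)
  }
  has <- function(ch) !is.null(ch) && all(ch %in% names(field$channels))

  partitions <- NULL
  foci <- NULL
  if (has(roles$dna)) {
    nuclei <- segment_nuclei(field, roles$dna, p$min_nucleus_area,
                             p$smoothing_scale)
    if (nuclei$n > 0) {
      partitions <- partition_periphery(nuclei, p$band_fraction,
                                        field$pixel_size)
      foci <- segment_heterochromatic_foci(field, roles$dna, nuclei,
                                           p$focus_scale, p$min_focus_area)
      markers <- roles$markers[roles$markers %in% names(field$channels)]
      if (length(markers)) {
        tab <- measure_nuclei(field, markers, partitions, foci)
        for (k in seq_len(nrow(tab))) {
          add("nucleus", tab$nucleus_id[k],
              paste0("periphery_total_ratio_", tab$channel[k]),
              tab$periphery_total_ratio[k], "dimensionless")
          add("nucleus", tab$nucleus_id[k],
              paste0("foci_total_ratio_", tab$channel[k]),
              tab$foci_total_ratio[k], "dimensionless")
        }
      }
      for (q in partitions)
        if (!q$degenerate)
          add("nucleus", q$nucleus_id, "nucleus_area", q$area_um2, "um^2")
      if (has(roles$fish)) {
        spots <- detect_spots(field, roles$fish, nuclei, p$spot_scale,
                              p$snr_min)
        spots <- measure_spots(spots, partitions, foci, field$pixel_size)
        for (k in seq_len(nrow(spots))) {
          add("spot", k, "relative_position", spots$relative_position[k],
              "dimensionless")
          add("spot", k, "distance_to_focus",
              spots$distance_to_focus_um[k], "um")
        }
      }
    }
  }
  if (has(roles$body) && has(roles$adhesion)) {
    cells <- segment_cells(field, roles$body, p$min_cell_area,
                           p$smoothing_scale)
    if (cells$n > 0) {
      filt <- dog_bandpass(field, roles$adhesion, p$sigma_low,
                           p$sigma_high)
      seg <- segment_adhesions(filt, cells, p$k_threshold,
                               p$min_adhesion_area, field$pixel_size)
      summ <- summarize_cells(seg$records, cells, field$pixel_size,
                              field$condition)
      for (k in seq_len(nrow(summ))) {
        add("cell", summ$cell_id[k], "adhesion_count",
            summ$adhesion_count[k], "count")
        add("cell", summ$cell_id[k], "mean_adhesion_area",
            summ$mean_adhesion_area_um2[k], "um^2")
        add("cell", summ$cell_id[k], "total_adhesion_area",
            summ$total_adhesion_area_um2[k], "um^2")
        add("cell", summ$cell_id[k], "spreading_area",
            summ$spreading_area_um2[k], "um^2")
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(field_id = character(0), object_type = character(0),
                      object_id = integer(0), metric = character(0),
                      value = numeric(0), units = character(0),
                      condition = character(0)))
  do.call(rbind, rows)
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$measurements,
            file.path(config$output_dir, "measurements.csv"),
            row.names = FALSE)
  if (length(result$comparisons)) {
    cmp <- do.call(rbind, lapply(result$comparisons, as.data.frame))
    write.csv(cmp, file.path(config$output_dir, "comparisons.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      lapply(result$comparisons, function(x)
        list(metric = x$metric, groups = x$groups, n = x$n,
             median = unname(x$median), test = x$test,
             statistic = x$statistic, p_value = x$p_value)),
      file.path(config$output_dir, "comparisons.json"),
      auto_unbox = TRUE, digits = NA)
  }
  writeLines(result$log, file.path(config$output_dir, "run_log.txt"))
  invisible(NULL)
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("PipelineResult: ", nrow(x$measurements), " measurement row(s), ",
      length(x$comparisons), " comparison(s), ", length(x$errors),
      " field error(s)\n", sep = "")
  cat("  config hash: ", x$config_hash, "\n", sep = "")
  invisible(x)
}
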