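#' Pipeline configuration
#'
#' A single serializable configuration object driving the command-level
#' entry points. Unknown keys are rejected so a typo in a config file
#' fails loudly instead of being silently ignored.
#'
#' @param shape,spacing_um acquisition geometry (see
#'   \code{\link{acq_geometry}}).
#' @param background list: \code{filter_width_um}.
#' @param detect list: \code{spot_diameter_um}, \code{threshold},
#'   \code{min_component_voxels}.
#' @param null list: \code{n_sims}, \code{exclude_interior}.
#' @param bins \code{"fine"} or \code{"coarse"}.
#' @param alpha significance level.
#' @param seed integer seed.
#' @param simulate list of generator settings: \code{n_neurons},
#'   \code{n_spots}, \code{kernel_radius_um}, \code{kernel_amplitude},
#'   \code{kernel_profile}, \code{n_branches}, \code{branch_length_um},
#'   \code{soma_radius_um}, \code{tube_radius_um}.
#' @return An object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(shape = c(60L, 256L, 256L),
                            spacing_um = c(0.2, 0.299, 0.299),
                            background = list(filter_width_um = 46.2),
                            detect = list(spot_diameter_um = 0.723,
                                          threshold = 1,
                                          min_component_voxels = 10L),
                            null = list(n_sims = 1000L,
                                        exclude_interior = TRUE),
                            bins = "fine", alpha = 0.05, seed = 1L,
                            simulate = list(n_neurons = 5L, n_spots = 300L,
                                            kernel_radius_um = 7,
                                            kernel_amplitude = 1,
                                            kernel_profile = "flat",
                                            n_branches = 4L,
                                            branch_length_um = 25,
                                            soma_radius_um = 5,
                                            tube_radius_um = 0.75)) {
  cfg <- list(shape = as.integer(shape), spacing_um = as.numeric(spacing_um),
              background = background, detect = detect, null = null,
              bins = bins, alpha = alpha, seed = as.integer(seed),
              simulate = simulate)
  acq_geometry(cfg$shape, cfg$spacing_um)  # validates
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; top-level and nested keys must match
#'   \code{\link{pipeline_config}} arguments, unknown keys are an error.
#' @return A \code{"pipeline_config"}.
#' @export
read_config <- function(path) {
  raw <- suppressWarnings(yaml::read_yaml(path))
  if (is.null(names(raw)) || any(!nzchar(names(raw))))
    stop("config keys must be named (note: quote \"null\" in YAML, ",
         "unquoted it parses as the null value)")
  allowed <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  defaults <- formals(pipeline_config)
  for (nm in intersect(names(raw), c("background", "detect", "null",
                                     "simulate"))) {
    known <- names(eval(defaults[[nm]]))
    bad <- setdiff(names(raw[[nm]]), known)
    if (length(bad))
      stop(sprintf("unknown config keys under `%s`: %s", nm,
                   paste(bad, collapse = ", ")))
    merged <- eval(defaults[[nm]])
    merged[names(raw[[nm]])] <- raw[[nm]]
    raw[[nm]] <- merged
  }
  do.call(pipeline_config, raw)
}

.cfg_geom <- function(config) acq_geometry(config$shape, config$spacing_um)
.cfg_bins <- function(config) distance_bins(config$bins)

#' Simulate a synthetic cohort and write it to disk
#'
#' For each neuron: the ground-truth mask (8-bit TIFF), the exact spot
#' coordinates (CSV) and a parameters JSON are written under
#' \code{out_dir}, using per-neuron seeds derived from the config seed.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir output directory (created if missing).
#' @return Data frame listing the written files, invisibly.
#' @export
cmd_simulate <- function(config, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  geom <- .cfg_geom(config)
  sim <- config$simulate
  kern <- chemo_kernel(sim$kernel_radius_um, sim$kernel_amplitude,
                       sim$kernel_profile)
  rows <- vector("list", sim$n_neurons)
  for (i in seq_len(sim$n_neurons)) {
    sd_i <- config$seed + 1000L * i
    nm <- generate_neuron_mask(geom, n_branches = sim$n_branches,
                               branch_length_um = sim$branch_length_um,
                               soma_radius_um = sim$soma_radius_um,
                               tube_radius_um = sim$tube_radius_um,
                               seed = sd_i)
    spots <- sample_spots(nm$mask, sim$n_spots, kern, seed = sd_i + 1L,
                          diameter_um = config$detect$spot_diameter_um)
    mask_path <- file.path(out_dir, sprintf("neuron%03d_mask.tif", i))
    spot_path <- file.path(out_dir, sprintf("neuron%03d_spots.csv", i))
    write_mask(nm$mask, mask_path)
    write_spots(spots, spot_path)
    rows[[i]] <- data.frame(neuron = i, mask = mask_path, spots = spot_path)
  }
  jsonlite::write_json(list(seed = config$seed, shape = config$shape,
                            spacing_um = config$spacing_um,
                            simulate = sim),
                       file.path(out_dir, "parameters.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(do.call(rbind, rows))
}

#' Run the chemoattraction analysis over a simulated or detected cohort
#'
#' Reads mask/spot file pairs (as written by \code{\link{cmd_simulate}}
#' or by the detection stage), fits the per-neuron profiles and the
#' cohort model, and writes per-neuron profile CSVs plus a cohort
#' summary CSV.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param mask_paths,spot_paths parallel vectors of mask TIFF and spot
#'   CSV paths.
#' @param out_dir output directory.
#' @return The \code{"chemo_fit"} object, invisibly.
#' @export
cmd_chemoattract <- function(config, mask_paths, spot_paths, out_dir) {
  if (length(mask_paths) != length(spot_paths))
    stop("`mask_paths` and `spot_paths` must be parallel")
  missing <- c(mask_paths, spot_paths)[!file.exists(c(mask_paths, spot_paths))]
  if (length(missing))
    stop("input file not found: ", missing[1])
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  edges <- .cfg_bins(config)
  profiles <- vector("list", length(mask_paths))
  for (i in seq_along(mask_paths)) {
    mask <- read_mask(mask_paths[i])
    spots <- read_spots(spot_paths[i])
    profiles[[i]] <- chemo_profile(
      spots, mask, bin_edges = edges, n_sims = config$null$n_sims,
      seed = config$seed + i,
      exclude_interior = isTRUE(config$null$exclude_interior),
      neuron_id = sprintf("neuron%03d", i))
    df <- as.data.frame(profiles[[i]])
    df[] <- lapply(df, function(v) sprintf("%.9g", v))
    utils::write.csv(df,
                     file.path(out_dir, sprintf("profile%03d.csv", i)),
                     row.names = FALSE, quote = FALSE)
  }
  fit <- fit_chemoattraction(profiles, alpha = config$alpha)
  sm <- fit$bins
  sm[] <- lapply(sm, function(v) if (is.numeric(v)) sprintf("%.9g", v) else v)
  utils::write.csv(sm, file.path(out_dir, "cohort_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(radius_um = fit$radius_um,
                            interaction_p = fit$interaction_p,
                            n_neurons = fit$n_neurons,
                            seed = config$seed,
                            config = unclass(config)),
                       file.path(out_dir, "cohort_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(fit)
}

#' Colocalization over a list of ROI mask pairs
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param mask_a_paths,mask_b_paths parallel vectors of mask TIFF paths.
#' @param groups optional group labels per ROI.
#' @param out_dir output directory.
#' @return The \code{\link{aggregate_overlap}} summary, invisibly.
#' @export
cmd_coloc <- function(config, mask_a_paths, mask_b_paths, groups = NULL,
                      out_dir) {
  if (!length(mask_a_paths)) stop("empty ROI list")
  if (length(mask_a_paths) != length(mask_b_paths))
    stop("mask path lists must be parallel")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  res <- lapply(seq_along(mask_a_paths), function(i)
    overlap_fractions(read_mask(mask_a_paths[i]), read_mask(mask_b_paths[i]),
                      roi_id = sprintf("roi%03d", i),
                      group = if (is.null(groups)) NA else groups[i]))
  df <- do.call(rbind, res)
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.9g", v))
  utils::write.csv(out, file.path(out_dir, "overlap_per_roi.csv"),
                   row.names = FALSE, quote = FALSE)
  agg <- aggregate_overlap(df, by_group = !is.null(groups))
  jsonlite::write_json(agg, file.path(out_dir, "overlap_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(agg)
}

#' Volumetry over a list of two-marker ROI mask pairs
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param mask_1_paths,mask_2_paths parallel vectors of mask TIFF paths.
#' @param out_dir output directory.
#' @return The \code{\link{volume_fraction_cohort}} summary, invisibly.
#' @export
cmd_volumetry <- function(config, mask_1_paths, mask_2_paths, out_dir) {
  if (!length(mask_1_paths)) stop("empty ROI list")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  res <- lapply(seq_along(mask_1_paths), function(i)
    channel_volume_fraction(read_mask(mask_1_paths[i]),
                            read_mask(mask_2_paths[i]),
                            roi_id = sprintf("roi%03d", i)))
  coh <- volume_fraction_cohort(res)
  out <- coh$per_roi
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.9g", v))
  utils::write.csv(out, file.path(out_dir, "volume_fractions.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(coh)
}

#' Print the derived striatal geometry table
#'
#' @param constants a \code{\link{geometry_constants}} object or a path
#'   to a JSON file of constants.
#' @param out_path optional CSV output path.
#' @return The \code{\link{geometry_table}} data frame.
#' @export
cmd_geometry <- function(constants = geometry_constants(), out_path = NULL) {
  if (is.character(constants)) {
    vals <- jsonlite::read_json(constants, simplifyVector = TRUE)
    constants <- do.call(geometry_constants, vals)
  }
  tab <- geometry_table(constants)
  if (!is.null(out_path)) {
    out <- tab
    out$value <- sprintf("%.9g", out$value)
    utils::write.csv(out, out_path, row.names = FALSE, quote = FALSE)
  }
  tab
}
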