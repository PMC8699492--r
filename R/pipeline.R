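# Orchestration layer behind the command-line interface: a single run()
# entry point dispatching the analysis commands, with flat key-value config
# defaults, deterministic outputs, and a sidecar record of every tunable so
# any result is reproducible from its own files.

#' Default run configuration
#'
#' Every tunable of the analysis modules, as a flat named list. Values in a
#' user config file (YAML, flat keys) override these; command-line flags
#' override both.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() list(
  pixel_size_um = 1,
  threshold_method = "otsu",
  manual_threshold = NA,
  invert = FALSE,
  min_object_px = 0L,
  fill_holes = FALSE,
  connectivity = 8L,
  exclude_border = TRUE,
  min_rod_px = 25L,
  min_neurite_um = NA,       # NA: 5 px at the image calibration
  reference_axis_deg = 0,    # or "random"
  perimeter_method = "calibrated",
  fractal_mode = "silhouette",
  min_box_px = 2L,
  max_box_px = NA,           # NA: min(image dims) / 4
  n_offsets = 4L,
  glcm_levels = 16L,
  glcm_window_px = 64L,
  glcm_stride_px = 32L,
  seed = 1L
)

#' Merge configuration sources
#'
#' @param config_file optional YAML file of flat key-value overrides.
#' @param overrides named list of final overrides (e.g. parsed CLI flags).
#' @return Validated config list.
#' @export
load_config <- function(config_file = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) sq_input_error("config file not found: %s",
                                                  config_file)
    user <- yaml::read_yaml(config_file)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad)) sq_validation_error("unknown config key(s): %s",
                                         paste(bad, collapse = ", "))
    cfg[names(user)] <- user
  }
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad)) sq_validation_error("unknown config key(s): %s",
                                       paste(bad, collapse = ", "))
  cfg[names(overrides)] <- overrides
  cfg
}

resolve_reference_axis <- function(cfg) {
  if (identical(cfg$reference_axis_deg, "random"))
    with_seed(cfg$seed, runif(1L, 0, 180))
  else as.numeric(cfg$reference_axis_deg)
}

segment_from_config <- function(m, cfg) {
  mask <- binarize(m, cfg$threshold_method,
                   if (is.na(cfg$manual_threshold)) NULL else cfg$manual_threshold,
                   cfg$invert)
  mask <- clean_mask(mask, cfg$min_object_px, cfg$fill_holes, cfg$connectivity)
  cells <- label_instances(mask, cfg$connectivity, cfg$exclude_border)
  list(mask = mask, cells = cells)
}

#' Run an analysis command
#'
#' The programmatic equivalent of the command-line interface. Results are
#' deterministic given (input, config, seed); alongside every CSV a JSON
#' sidecar records the full configuration.
#'
#' @param command one of `"segment"`, `"measure-bacteria"`,
#'   `"measure-neurons"`, `"fractal"`, `"texture"`, `"synth"`.
#' @param input path to an image, or a [micrograph]/[binary_mask] object.
#' @param out_dir output directory (created if needed).
#' @param config config list from [load_config()].
#' @param synth_kind for `command = "synth"`: `"rods"`, `"neuron"`,
#'   `"fractal"`, or `"texture"`.
#' @return Invisibly, a list of the objects produced (also written to
#'   `out_dir`).
#' @export
run_command <- function(command, input = NULL, out_dir = ".",
                        config = default_config(), synth_kind = "rods") {
  commands <- c("segment", "measure-bacteria", "measure-neurons", "fractal",
                "texture", "synth")
  if (!command %in% commands)
    sq_validation_error("unknown command '%s' (expected one of: %s)", command,
                        paste(commands, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  get_micrograph <- function() {
    if (inherits(input, "micrograph")) input
    else load_micrograph(input, config$pixel_size_um)
  }
  result <- switch(command,
    "segment" = {
      seg <- segment_from_config(get_micrograph(), config)
      lab <- matrix(0L, nrow(seg$mask$pixels), ncol(seg$mask$pixels))
      for (cell in seg$cells)
        lab[cell$pixels] <- cell$cell_id
      write_micrograph(micrograph(seg$mask$pixels * 255, config$pixel_size_um,
                                  8L, "mask"),
                       file.path(out_dir, "mask.png"))
      tiff::writeTIFF(lab / max(1L, max(lab)), file.path(out_dir, "labels.tif"),
                      bits.per.sample = 16L)
      seg
    },
    "measure-bacteria" = {
      m <- get_micrograph()
      seg <- segment_from_config(m, config)
      pop <- measure_population(seg$cells, config$pixel_size_um,
                                config$min_rod_px, source_id = m$source_id)
      write_results(pop$table, file.path(out_dir, "bacteria.csv"))
      pop
    },
    "measure-neurons" = {
      m <- get_micrograph()
      seg <- segment_from_config(m, config)
      ref <- resolve_reference_axis(config)
      mnu <- if (is.na(config$min_neurite_um)) NULL else config$min_neurite_um
      pop <- measure_neuron_population(seg$cells, ref, mnu,
                                       config$perimeter_method,
                                       source_id = m$source_id)
      write_results(pop$table, file.path(out_dir, "neurons.csv"))
      pop
    },
    "fractal" = {
      obj <- if (inherits(input, "binary_mask")) input else get_micrograph()
      sizes <- fractal_sizes_from_config(obj, config)
      res <- silhouette_pipeline(obj, config$fractal_mode,
                                 config$threshold_method,
                                 if (is.na(config$manual_threshold)) NULL
                                 else config$manual_threshold,
                                 config$invert, config$min_object_px,
                                 config$fill_holes, sizes, config$n_offsets)
      df <- data.frame(cell_id = "field",
                       fractal_dimension = res$fractal$dimension_D,
                       fit_r2 = res$fractal$fit_r2,
                       mean_lacunarity = res$lacunarity$mean_lambda)
      write_results(as_result_table(df, "fractal"), file.path(out_dir, "fractal.csv"))
      res
    },
    "texture" = {
      m <- get_micrograph()
      cfgg <- glcm_config(levels = config$glcm_levels)
      tm <- texture_map(m, config$glcm_window_px, config$glcm_stride_px, cfgg)
      flat <- cbind(tm$origins,
                    do.call(cbind, lapply(tm$maps, as.vector)))
      utils::write.csv(flat, file.path(out_dir, "texture.csv"),
                       row.names = FALSE)
      tm
    },
    "synth" = {
      syn <- switch(synth_kind,
        rods = gen_rod_population(25L, pixel_size_um = 0.02,
                                  seed = config$seed),
        neuron = gen_neuron(6, list(c(length_um = 30, angle_deg = 0,
                                      tortuosity = 0),
                                    c(length_um = 40, angle_deg = 120,
                                      tortuosity = 0)),
                            seed = config$seed),
        fractal = gen_fractal("sierpinski", iterations = 8L),
        texture = gen_texture("checkerboard", seed = config$seed),
        sq_validation_error("unknown synth kind '%s'", synth_kind))
      if (!is.null(syn$micrograph))
        write_micrograph(syn$micrograph, file.path(out_dir, "image.png"))
      if (!is.null(syn$mask))
        write_micrograph(micrograph(syn$mask$pixels * 255,
                                    syn$mask$pixel_size_um, 8L, "mask"),
                         file.path(out_dir, "mask.png"))
      if (is.data.frame(syn$truth))
        utils::write.csv(syn$truth, file.path(out_dir, "truth.csv"),
                         row.names = FALSE)
      syn
    })
  jsonlite::write_json(c(list(command = command), config),
                       file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(result)
}

fractal_sizes_from_config <- function(obj, config) {
  dims <- if (inherits(obj, "binary_mask")) dim(obj$pixels)
          else dim(obj$pixels)
  maxb <- if (is.na(config$max_box_px)) floor(min(dims) / 4)
          else config$max_box_px
  minb <- config$min_box_px
  if (maxb < minb * 8L) return(NULL)  # fall back to defaults
  2^(ceiling(log2(minb)):floor(log2(maxb)))
}
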