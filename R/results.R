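#' Descriptor vocabulary
#'
#' The fixed set of descriptor names the package emits, with their units.
#' Result tables only accept names from this vocabulary so that downstream
#' consumers can rely on a stable schema.
#'
#' @return Named character vector mapping descriptor name to unit.
#' @export
descriptor_vocabulary <- function() c(
  length_um            = "um",
  width_um             = "um",
  aspect_ratio         = "dimensionless",
  projected_area_um2   = "um2",
  volume_um3           = "um3",
  surface_um2          = "um2",
  sv_ratio_per_um      = "per_um",
  feret_length_um      = "um",
  feret_width_um       = "um",
  soma_diameter_um     = "um",
  neurite_count        = "count",
  avg_neurite_length_um= "um",
  max_neurite_length_um= "um",
  neurite_length_um    = "um",
  radial_distance_um   = "um",
  straightness_um      = "um",
  tortuosity           = "dimensionless",
  chord_angle_deg      = "degrees",
  area_um2             = "um2",
  perimeter_um         = "um",
  circularity          = "dimensionless",
  n_parallel           = "count",
  n_intermediate       = "count",
  n_perpendicular      = "count",
  is_differentiated    = "flag",
  fractal_dimension    = "dimensionless",
  fit_r2               = "dimensionless",
  box_count            = "count",
  box_size_px          = "px",
  lacunarity           = "dimensionless",
  mean_lacunarity      = "dimensionless",
  asm                  = "dimensionless",
  entropy              = "nat",
  contrast             = "dimensionless",
  correlation          = "dimensionless",
  idm                  = "dimensionless"
)

#' Build a result table
#'
#' The long-format record of every measurement: one row per
#' (source, cell, descriptor) triple, units always recorded.
#'
#' @param source_id,cell_id,descriptor,value vectors of equal length (or
#'   length 1, recycled).
#' @return A `data.frame` of class `result_table` with columns
#'   `source_id, cell_id, descriptor, value, unit`.
#' @export
result_table <- function(source_id, cell_id, descriptor, value) {
  vocab <- descriptor_vocabulary()
  bad <- setdiff(unique(descriptor), names(vocab))
  if (length(bad))
    sq_validation_error("unknown descriptor(s): %s", paste(bad, collapse = ", "))
  out <- data.frame(source_id = as.character(source_id),
                    cell_id = as.character(cell_id),
                    descriptor = as.character(descriptor),
                    value = as.numeric(value),
                    unit = unname(vocab[descriptor]),
                    stringsAsFactors = FALSE)
  class(out) <- c("result_table", "data.frame")
  out
}

#' Convert a wide per-cell data frame to a result table
#'
#' Columns other than `cell_id` must be vocabulary descriptor names.
#'
#' @param df wide data frame with a `cell_id` column.
#' @param source_id provenance label for every row.
#' @return A [result_table].
#' @export
as_result_table <- function(df, source_id = "unknown") {
  stopifnot(is.data.frame(df), "cell_id" %in% names(df))
  desc <- setdiff(names(df), "cell_id")
  parts <- lapply(desc, function(d)
    result_table(source_id, df$cell_id, d, as.numeric(df[[d]])))
  out <- do.call(rbind, parts)
  out <- out[order(match(out$cell_id, df$cell_id)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("result_table", "data.frame")
  out
}

#' Write a result table to CSV
#'
#' UTF-8, comma-delimited, `.` decimal separator. Values are written with 12
#' significant digits so that numeric round-trips are lossless at that
#' precision. An optional JSON mirror of the same records can be written
#' alongside.
#'
#' @param table a [result_table] (non-empty).
#' @param path output CSV path.
#' @param json also write `<path>.json` with the same records.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, json = FALSE) {
  if (!inherits(table, "result_table") || nrow(table) == 0L)
    sq_validation_error("table must be a non-empty result_table")
  out <- table
  out$value <- formatC(out$value, digits = 12, format = "g")
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) sq_input_error("cannot write results to '%s'", path)
  if (json)
    jsonlite::write_json(as.data.frame(unclass(table)), paste0(path, ".json"),
                         digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a result table written by [write_results()]
#' @param path CSV path.
#' @return A [result_table].
#' @export
read_results <- function(path) {
  if (!file.exists(path)) sq_input_error("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$source_id <- as.character(df$source_id)
  df$cell_id <- as.character(df$cell_id)
  df$value <- as.numeric(df$value)
  class(df) <- c("result_table", "data.frame")
  df
}
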