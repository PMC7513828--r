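# Table and config I/O, run manifests.

cell_required_cols <- c("cell_id", "embryo_id", "litter_id", "z",
                        "nanog_raw", "gata6_raw", "ti_flag")
track_required_cols <- c("cell_id", "frame", "gfp")

#' Read a segmented-cell table from CSV
#'
#' Validates the cell-record schema (`cell_id`, `embryo_id`, `litter_id`,
#' `z`, `nanog_raw`, `gata6_raw`, `ti_flag`; `gfp_raw` and `identity`
#' optional). Unknown columns are preserved. Negative intensities are
#' rejected.
#'
#' @param path Path to a CSV file (UTF-8, header row, '.' decimal).
#' @return A validated tibble of cell records.
#' @export
read_cell_table <- function(path) {
  tb <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  missing <- setdiff(cell_required_cols, names(tb))
  if (length(missing)) {
    stop("cell table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("nanog_raw", "gata6_raw", "gfp_raw")) {
    if (col %in% names(tb) && any(tb[[col]] < 0, na.rm = TRUE)) {
      stop("negative intensities in column ", col, call. = FALSE)
    }
  }
  tb
}

#' Read a time-lapse track table from CSV
#'
#' Requires `cell_id`, `frame`, `gfp`; `event`, `smoothed_gfp`,
#' `identity_start` and any extra columns are preserved.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of track records.
#' @export
read_track_table <- function(path) {
  tb <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  missing <- setdiff(track_required_cols, names(tb))
  if (length(missing)) {
    stop("track table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tb
}

#' Write a table to CSV
#'
#' UTF-8, header row, '.' decimal, no row names: the package interchange
#' format.
#'
#' @param table A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a simulation configuration from a YAML file
#'
#' Top-level keys `circuit`, `mechanics` and any [embryo_config()] argument
#' are supported; unspecified values keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return An [embryo_config()] object.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path) %||% list()
  circuit <- do.call(circuit_params, y$circuit %||% list())
  mechanics <- do.call(mechanics_params, y$mechanics %||% list())
  rest <- y[setdiff(names(y), c("circuit", "mechanics"))]
  do.call(embryo_config,
          c(list(circuit = circuit, mechanics = mechanics), rest))
}

#' Write a run manifest
#'
#' Records what produced a set of outputs: the command, seed(s), a hash of
#' the configuration, package version, timestamp and output paths. One
#' manifest is written per CLI run.
#'
#' @param path Output JSON path.
#' @param command Command (or function) name.
#' @param seed Seed(s) used.
#' @param config The configuration object (hashed after serialisation).
#' @param outputs Character vector of output paths.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, seed = NULL, config = NULL,
                           outputs = character()) {
  manifest <- list(
    command = command,
    seed = seed,
    config_hash = if (is.null(config)) NA_character_ else
      paste0(sum(utf8ToInt(paste(deparse(config), collapse = ""))
                 * seq_len(1)), "-",
             nchar(paste(deparse(config), collapse = ""))),
    package_version = as.character(utils::packageVersion("icmfate")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# split one master seed into reproducible per-component streams
seed_for <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(master) * 7919 + h) %% .Machine$integer.max)
}
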