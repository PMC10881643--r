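# Observed time-course container. A dataset is a tidy tibble of records
# (one measurement per row) carrying, as attributes, the metadata that a
# record table cannot express: the normalization convention, the experiment
# geometry (needed to interpret concentrations), and the protocol that
# produced the data.

DATASET_UNITS <- c("fold_change", "ng_per_ml", "molecules_per_cell")
DATASET_COLUMNS <- c("experiment_id", "protocol", "time_h", "compartment",
                     "value", "unit", "replicate")

#' Construct a time-course dataset
#'
#' @param records A data frame with columns `experiment_id`, `protocol`
#'   (one of `"accumulation"`, `"pulse_chase"`, `"cell_free_decay"`),
#'   `time_h`, `compartment` (`"intracellular"` or `"extracellular"`),
#'   `value`, `unit` (`"fold_change"`, `"ng_per_ml"` or
#'   `"molecules_per_cell"`), `replicate`, and optionally `sigma`
#'   (per-point measurement uncertainty on the same scale as `value`).
#' @param normalization For fold-change data from accumulation or cell-free
#'   experiments: a list `list(mode = "ref_time", ref_time = 24)` or
#'   `list(mode = "max")` describing how raw intensities were normalized
#'   (per replicate). Ignored for absolute units.
#' @param geometry An [sflt_geometry()]; required when any unit is
#'   `"ng_per_ml"`.
#' @param protocol An [sflt_protocol] describing the experiment; if `NULL`,
#'   a default protocol of the declared kind is reconstructed when needed.
#' @return A tibble of class `sflt_dataset`.
#' @export
sflt_dataset <- function(records, normalization = NULL, geometry = NULL,
                         protocol = NULL) {
  records <- tibble::as_tibble(records)
  missing <- setdiff(DATASET_COLUMNS, names(records))
  if (length(missing) > 0) {
    stop("dataset is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0) stop("empty dataset", call. = FALSE)
  bad_t <- which(!is.finite(records$time_h) | records$time_h < 0)
  if (length(bad_t) > 0) {
    stop("negative or non-finite time_h at row ", bad_t[1], call. = FALSE)
  }
  bad_v <- which(!is.finite(records$value) | records$value < 0)
  if (length(bad_v) > 0) {
    stop("negative or non-finite value at row ", bad_v[1], call. = FALSE)
  }
  bad_u <- setdiff(unique(records$unit), DATASET_UNITS)
  if (length(bad_u) > 0) {
    stop("unknown unit '", bad_u[1], "'; valid units: ",
         paste(DATASET_UNITS, collapse = ", "), call. = FALSE)
  }
  bad_c <- setdiff(unique(records$compartment),
                   c("intracellular", "extracellular"))
  if (length(bad_c) > 0) {
    stop("unknown compartment '", bad_c[1], "'", call. = FALSE)
  }
  if (length(unique(records$unit)) > 1) {
    stop("mixed units within one dataset; split into separate datasets",
         call. = FALSE)
  }
  if (any(records$unit == "ng_per_ml")) {
    if (is.null(geometry)) {
      stop("unit 'ng_per_ml' requires an explicit geometry ",
           "(n_cells, media_volume_ml, molecular_weight_g_per_mol)",
           call. = FALSE)
    }
    stopifnot(inherits(geometry, "sflt_geometry"))
  }
  if (!"sigma" %in% names(records)) records$sigma <- NA_real_
  attr(records, "normalization") <- normalization
  attr(records, "geometry") <- geometry
  attr(records, "protocol") <- protocol
  class(records) <- c("sflt_dataset", class(records))
  records
}

dataset_normalization <- function(dataset) attr(dataset, "normalization")
dataset_geometry <- function(dataset) attr(dataset, "geometry")
dataset_protocol <- function(dataset) attr(dataset, "protocol")

#' Read a time-course dataset from CSV (+ YAML sidecar)
#'
#' The CSV must have the columns `experiment_id, protocol, time_h,
#' compartment, value, unit, replicate` (optionally `sigma`). Metadata that
#' does not fit a record table — normalization convention, experiment
#' geometry, protocol settings — lives in a YAML sidecar next to the CSV
#' (same name, `.yaml` extension) and is attached on read.
#'
#' @param path Path to the CSV file.
#' @return An `sflt_dataset`.
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(DATASET_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  side <- sidecar_path(path)
  normalization <- NULL
  geometry <- NULL
  protocol <- NULL
  if (file.exists(side)) {
    y <- yaml::read_yaml(side)
    normalization <- y$normalization
    if (!is.null(y$geometry)) {
      geometry <- sflt_geometry(
        n_cells = y$geometry$n_cells,
        media_volume_ml = y$geometry$media_volume_ml,
        molecular_weight_g_per_mol = y$geometry$molecular_weight_g_per_mol %||% 1e5
      )
    }
    if (!is.null(y$protocol)) protocol <- protocol_from_list(y$protocol)
  }
  sflt_dataset(df, normalization = normalization, geometry = geometry,
               protocol = protocol)
}

#' Write a time-course dataset to CSV (+ YAML sidecar)
#'
#' @param dataset An `sflt_dataset`.
#' @param path Output CSV path; metadata goes to the `.yaml` sidecar.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(dataset, path) {
  stopifnot(inherits(dataset, "sflt_dataset"))
  df <- as.data.frame(dataset)
  if (all(is.na(df$sigma))) df$sigma <- NULL
  readr::write_csv(df, path, progress = FALSE)
  meta <- list()
  if (!is.null(dataset_normalization(dataset))) {
    meta$normalization <- dataset_normalization(dataset)
  }
  g <- dataset_geometry(dataset)
  if (!is.null(g)) meta$geometry <- unclass(g)
  p <- dataset_protocol(dataset)
  if (!is.null(p)) meta$protocol <- protocol_to_list(p)
  if (length(meta) > 0) yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".yaml")
}

protocol_to_list <- function(protocol) {
  y <- unclass(protocol)
  if (!is.null(y$production_schedule)) {
    y$production_schedule <- purrr::pmap(y$production_schedule,
                                         function(time, value) {
                                           list(time = time, value = value)
                                         })
  }
  y[!vapply(y, is.null, logical(1))]
}

protocol_from_list <- function(y) {
  sched <- NULL
  if (!is.null(y$production_schedule)) {
    sched <- tibble::tibble(
      time = vapply(y$production_schedule, function(s) as.numeric(s$time), 1),
      value = vapply(y$production_schedule, function(s) as.numeric(s$value), 1)
    )
  }
  new_protocol(
    kind = y$kind, horizon = as.numeric(y$horizon),
    production_schedule = sched,
    media_events = as.numeric(unlist(y$media_events %||% list())),
    inhibitions = y$inhibitions %||% list(),
    history = y$history %||% "steady_state",
    sample_times = as.numeric(unlist(y$sample_times %||% list())),
    S_x0 = if (!is.null(y$S_x0)) as.numeric(y$S_x0),
    pulse_duration = if (!is.null(y$pulse_duration)) as.numeric(y$pulse_duration),
    normalization = y$normalization
  )
}
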