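#' Write a hemisphere partition to CSV
#'
#' Columns: `cell_id`, `azimuth_deg`, `elevation_deg`, `solid_angle_sr`.
#'
#' @param partition a `sphere_partition`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_partition_csv <- function(partition, path) {
  readr::write_csv(tibble::as_tibble(partition), path)
  invisible(path)
}

#' Read a hemisphere partition from CSV
#'
#' @param path a file written by [write_partition_csv()].
#' @return a `sphere_partition`.
#' @export
read_partition_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("cell_id", "azimuth_deg", "elevation_deg", "solid_angle_sr")
  if (!all(need %in% names(out))) {
    stop_bad_arg(paste("partition CSV must have columns:",
                       paste(need, collapse = ", ")))
  }
  attr(out, "n_cells") <- nrow(out)
  class(out) <- c("sphere_partition", class(out))
  out
}

#' Write a directional field to CSV
#'
#' One row per cell with the field metadata repeated in `frequency_khz` and
#' `role` columns, so a flat file round-trips the object.
#'
#' @param field a `directional_field`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "directional_field"))
  out <- tibble::as_tibble(field)
  out$frequency_khz <- field_frequency(field)
  out$role <- field_role(field)
  out$floor_db <- attr(field, "floor_db")
  readr::write_csv(out, path)
  invisible(path)
}

#' Import a directional field from CSV onto a partition
#'
#' Validates that the file provides a gain for every cell of the active
#' partition (by `cell_id`) and rebuilds the `directional_field`. Rows for
#' unknown cells are an error; a missing cell is reported by id.
#'
#' @param path CSV with columns `cell_id`, `gain_db`, `frequency_khz`,
#'   `role` (e.g. written by [write_field_csv()]).
#' @param partition the active `sphere_partition`.
#' @return a `directional_field`.
#' @export
import_directional_field <- function(path, partition) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("cell_id", "gain_db", "frequency_khz", "role")
  if (!all(need %in% names(raw))) {
    stop_bad_arg(paste("field CSV must have columns:",
                       paste(need, collapse = ", ")))
  }
  missing <- setdiff(partition$cell_id, raw$cell_id)
  if (length(missing) > 0) {
    stop_bad_arg(sprintf("field CSV is missing cell id(s): %s",
                         paste(head(missing, 5), collapse = ", ")))
  }
  raw <- raw[match(partition$cell_id, raw$cell_id), ]
  floor_db <- if ("floor_db" %in% names(raw)) raw$floor_db[1] else -60
  directional_field(partition, raw$gain_db, raw$frequency_khz[1],
                    role = raw$role[1], floor_db = floor_db)
}

#' Write a template set to CSV
#'
#' One row per cell: `cell_id`, `frequency_khz`, `rel_gain_db`, and
#' `element_1..element_2k` (the zero-mean template, left-ear positions
#' first).
#'
#' @param ts a `template_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_templates_csv <- function(ts, path) {
  stopifnot(inherits(ts, "template_set"))
  el <- tibble::as_tibble(ts$templates, .name_repair = ~ paste0(
    "element_", seq_along(.x)))
  out <- dplyr::bind_cols(
    tibble::tibble(cell_id = ts$partition$cell_id,
                   frequency_khz = ts$frequency_khz,
                   rel_gain_db = ts$rel_gain_db),
    el)
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a flutter covariance to CSV
#'
#' Long format: `row`, `col`, `value_db2`.
#'
#' @param cov a `flutter_covariance`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_covariance_csv <- function(cov, path) {
  stopifnot(inherits(cov, "flutter_covariance"))
  m <- cov$matrix
  out <- tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value_db2 = as.vector(m)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Write per-echo ensemble gains to CSV
#'
#' Serializes an echo ensemble as per-echo dB gains at its carrier
#' frequency (`echo`, `gain_db`), the form the covariance estimators
#' consume.
#'
#' @param ensemble an `echo_ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "echo_ensemble"))
  g <- ensemble_gains_db(ensemble, ensemble$carrier_khz)
  readr::write_csv(tibble::tibble(echo = seq_along(g), gain_db = g), path)
  invisible(path)
}
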