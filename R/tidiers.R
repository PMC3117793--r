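#' Tidy a template set
#'
#' Long format: one row per cell and template element, with the element's
#' ear and position and the cell's relative gain.
#'
#' @param x a `template_set`.
#' @param ... unused.
#' @return a tibble `(cell_id, azimuth_deg, elevation_deg, frequency_khz,
#'   rel_gain_db, element, ear, position, value_db)`.
#' @method tidy template_set
#' @export
tidy.template_set <- function(x, ...) {
  k <- ncol(x$templates) / 2
  base <- dplyr::mutate(x$partition[, c("cell_id", "azimuth_deg",
                                        "elevation_deg")],
                        frequency_khz = x$frequency_khz,
                        rel_gain_db = x$rel_gain_db)
  el <- tibble::as_tibble(x$templates)
  dplyr::bind_cols(base, el) |>
    tidyr::pivot_longer(dplyr::all_of(colnames(x$templates)),
                        names_to = "element", values_to = "value_db") |>
    dplyr::mutate(
      ear = ifelse(substr(.data$element, 1, 1) == "L", "left", "right"),
      position = as.integer(substring(.data$element, 2))
    )
}

#' One-row summary of a template set
#'
#' @param x a `template_set`.
#' @param ... unused.
#' @return a tibble with the frequency, number of cells and elements, the
#'   hemisphere-mean template gain and mean modulation interval.
#' @method glance template_set
#' @export
glance.template_set <- function(x, ...) {
  tibble::tibble(
    frequency_khz = x$frequency_khz,
    n_cells = nrow(x$templates),
    n_elements = ncol(x$templates),
    max_raw_gain_db = x$max_raw_gain_db,
    mean_gain_db = mean(template_gain(x)$gain_db),
    mean_modulation_db = mean(modulation_interval(x)$modulation_interval_db)
  )
}

#' Tidy an entropy map
#'
#' @param x an `entropy_map`.
#' @param ... unused.
#' @return the map as a plain tibble.
#' @method tidy entropy_map
#' @export
tidy.entropy_map <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of an entropy map
#'
#' @param x an `entropy_map`.
#' @param ... unused.
#' @return a tibble with the grid sizes, chance level and the grand-mean
#'   entropy.
#' @method glance entropy_map
#' @export
glance.entropy_map <- function(x, ...) {
  tibble::tibble(
    n_cells = attr(x, "n_cells"),
    n_frequencies = dplyr::n_distinct(x$frequency_khz),
    n_snr = dplyr::n_distinct(x$snr_db),
    n_realizations = attr(x, "n_realizations"),
    chance_bits = log2(attr(x, "n_cells")),
    mean_entropy_bits = mean(x$entropy_bits)
  )
}

#' Tidy a flutter covariance
#'
#' @param x a `flutter_covariance`.
#' @param ... unused.
#' @return a long tibble `(row, col, value_db2)`.
#' @method tidy flutter_covariance
#' @export
tidy.flutter_covariance <- function(x, ...) {
  m <- x$matrix
  tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value_db2 = as.vector(m)
  )
}
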