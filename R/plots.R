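#' Plot a directional field over the frontal hemisphere
#'
#' @param object a `directional_field`.
#' @param ... unused.
#' @return a ggplot: cell centres coloured by gain.
#' @method autoplot directional_field
#' @export
autoplot.directional_field <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$azimuth_deg, .data$elevation_deg,
                               colour = .data$gain_db)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c(name = "gain (dB)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%s field at %g kHz", field_role(object),
                      field_frequency(object)),
      x = "azimuth (deg)", y = "elevation (deg)") +
    ggplot2::theme_minimal()
}

#' Plot template gain and modulation interval over the hemisphere
#'
#' @param object a `template_set`.
#' @param ... unused.
#' @return a ggplot faceted by the two summaries.
#' @method autoplot template_set
#' @export
autoplot.template_set <- function(object, ...) {
  df <- dplyr::left_join(template_gain(object), modulation_interval(object),
                         by = c("cell_id", "azimuth_deg", "elevation_deg")) |>
    tidyr::pivot_longer(c("gain_db", "modulation_interval_db"),
                        names_to = "summary", values_to = "db")
  ggplot2::ggplot(df, ggplot2::aes(.data$azimuth_deg, .data$elevation_deg,
                                   colour = .data$db)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c(name = "dB") +
    ggplot2::facet_wrap(~summary) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("templates at %g kHz", object$frequency_khz),
                  x = "azimuth (deg)", y = "elevation (deg)") +
    ggplot2::theme_minimal()
}

#' Plot an entropy map
#'
#' Cell-centre maps of expected entropy, faceted by frequency (rows) and
#' echo strength (columns).
#'
#' @param object an `entropy_map`.
#' @param snr_db optional subset of echo strengths to show.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot entropy_map
#' @export
autoplot.entropy_map <- function(object, snr_db = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(snr_db)) df <- dplyr::filter(df, .data$snr_db %in% .env$snr_db)
  ggplot2::ggplot(df, ggplot2::aes(.data$azimuth_deg, .data$elevation_deg,
                                   colour = .data$entropy_bits)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::scale_colour_viridis_c(name = "bits", direction = -1) +
    ggplot2::facet_grid(frequency_khz ~ snr_db) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "azimuth (deg)", y = "elevation (deg)",
                  title = "expected localization entropy") +
    ggplot2::theme_minimal()
}

#' Plot a perch-hunting sweep
#'
#' Mean entropy versus frequency, one line per foraging radius.
#'
#' @param hunt a tibble from [perch_hunt()].
#' @return a ggplot.
#' @export
plot_perch_hunt <- function(hunt) {
  ggplot2::ggplot(hunt, ggplot2::aes(.data$frequency_khz,
                                     .data$mean_entropy_bits,
                                     colour = factor(.data$radius_m))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "frequency (kHz)", y = "mean entropy (bits)",
                  colour = "radius (m)",
                  title = "perch-hunting localization performance") +
    ggplot2::theme_minimal()
}
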