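#' Ear-sweep protocol
#'
#' The scanning movement of the pinnae during echo reception. The default is
#' a diagonal sweep from (-15, -15) to (+15, +15) degrees in steps of 5,
#' giving 7 ear positions; the right ear moves in anti-phase (negated
#' offsets), as one ear rocks forward while the other rocks back. Because a
#' measurement vector is indexed by time, the anti-phase convention only
#' decides which template element lands in which slot.
#'
#' @param extent_deg sweep half-range (degrees). Default 15.
#' @param step_deg step between ear positions (degrees). Default 5.
#' @param mode `"diagonal"` (azimuth and elevation move together),
#'   `"azimuth"` (elevation fixed at 0) or `"elevation"` (azimuth fixed).
#' @param antiphase if `TRUE` (default) the right ear uses negated offsets.
#' @return an `ear_sweep_protocol` with a tibble of `(daz_deg, del_deg)`
#'   offsets, one row per ear position.
#' @export
ear_sweep_protocol <- function(extent_deg = 15, step_deg = 5,
                               mode = c("diagonal", "azimuth", "elevation"),
                               antiphase = TRUE) {
  mode <- match.arg(mode)
  check_positive_scalar(step_deg, "step_deg")
  s <- seq(-extent_deg, extent_deg, by = step_deg)
  offsets <- switch(mode,
    diagonal  = tibble::tibble(daz_deg = s, del_deg = s),
    azimuth   = tibble::tibble(daz_deg = s, del_deg = 0),
    elevation = tibble::tibble(daz_deg = 0, del_deg = s)
  )
  structure(list(offsets = offsets, mode = mode, antiphase = antiphase),
            class = "ear_sweep_protocol")
}

#' Build binaural amplitude-modulation templates
#'
#' For every candidate direction (partition cell), the template is the
#' expected dB magnitude received at each ear position of the sweep: the
#' hearing field is rigidly rotated to each ear position (the right ear with
#' negated offsets when the protocol is anti-phase) while the emission field
#' stays fixed at the head pose, and the two are combined pointwise. Left-ear
#' values (positions 1..k) are concatenated before right-ear values, giving a
#' `2k`-element row per cell (14 with the default 7-position sweep).
#'
#' Raw rows are normalized per frequency so that the highest raw gain across
#' all templates is 0 dB, then each row is shifted to zero mean; the row mean
#' is stored as the position's relative gain. The mean echo strength and the
#' modulation shape thereby decompose orthogonally: the effective mean of a
#' measurement is `template + relative gain + echo strength`.
#'
#' @param emission,hearing_left,hearing_right `directional_field`s sharing
#'   one partition and frequency.
#' @param protocol an [ear_sweep_protocol()].
#' @return a `template_set` with elements `templates` (N x 2k matrix of
#'   zero-mean dB rows), `rel_gain_db` (row means after the per-frequency
#'   normalization), `max_raw_gain_db`, `partition`, `frequency_khz`,
#'   `protocol`.
#' @export
build_templates <- function(emission, hearing_left, hearing_right,
                            protocol = ear_sweep_protocol()) {
  stopifnot(inherits(protocol, "ear_sweep_protocol"))
  for (f in list(hearing_left, hearing_right)) {
    if (!same_partition(emission, f)) {
      stop_bad_arg("fields must share one partition")
    }
    if (abs(field_frequency(emission) - field_frequency(f)) > 1e-9) {
      stop_bad_arg("fields must share one frequency")
    }
  }
  off <- protocol$offsets
  k <- nrow(off)
  n <- nrow(emission)
  sgn <- if (protocol$antiphase) -1 else 1
  left <- vapply(seq_len(k), function(i) {
    rotate_field(hearing_left, off$daz_deg[i], off$del_deg[i])$gain_db +
      emission$gain_db
  }, numeric(n))
  right <- vapply(seq_len(k), function(i) {
    rotate_field(hearing_right, sgn * off$daz_deg[i], sgn * off$del_deg[i])$gain_db +
      emission$gain_db
  }, numeric(n))
  raw <- cbind(left, right)
  max_raw <- max(raw)
  raw <- raw - max_raw # highest raw gain across all templates sits at 0 dB
  rel_gain <- rowMeans(raw)
  templates <- raw - rel_gain
  colnames(templates) <- c(paste0("L", seq_len(k)), paste0("R", seq_len(k)))
  structure(
    list(
      templates = templates,
      rel_gain_db = rel_gain,
      max_raw_gain_db = max_raw,
      partition = tibble::as_tibble(emission)[, c("cell_id", "azimuth_deg",
                                                  "elevation_deg",
                                                  "solid_angle_sr")],
      frequency_khz = field_frequency(emission),
      protocol = protocol
    ),
    class = "template_set"
  )
}

# effective template: zero-mean modulation shape plus the position's
# relative gain, so adding an echo strength A gives the measurement mean
effective_templates <- function(ts) {
  ts$templates + ts$rel_gain_db
}

#' Per-position template gain
#'
#' Mean raw gain of each template relative to the per-frequency maximum of
#' the per-position means: 0 dB at the best-served position, negative
#' elsewhere. With the per-frequency normalization this is interpretable as
#' an inverse directivity index: the more the beam focuses, the more
#' negative the hemisphere average becomes.
#'
#' @param ts a `template_set`.
#' @return a tibble `(cell_id, azimuth_deg, elevation_deg, gain_db)`.
#' @export
template_gain <- function(ts) {
  stopifnot(inherits(ts, "template_set"))
  g <- ts$rel_gain_db - max(ts$rel_gain_db)
  dplyr::mutate(ts$partition[, c("cell_id", "azimuth_deg", "elevation_deg")],
                gain_db = g)
}

#' Per-position modulation interval
#'
#' Difference between the highest and lowest gain within each template (dB).
#' The interval is introduced solely by the moving ears: replacing the
#' emission field changes template gains but not the modulation interval,
#' because the static emission adds the same constant to every element of a
#' row and is removed by the zero-mean scaling.
#'
#' @param ts a `template_set`.
#' @return a tibble `(cell_id, azimuth_deg, elevation_deg,
#'   modulation_interval_db)`.
#' @export
modulation_interval <- function(ts) {
  stopifnot(inherits(ts, "template_set"))
  rng <- apply(ts$templates, 1, function(x) max(x) - min(x))
  dplyr::mutate(ts$partition[, c("cell_id", "azimuth_deg", "elevation_deg")],
                modulation_interval_db = rng)
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf(
    "<template_set> %d cells x %d elements at %g kHz (max raw gain %.2f dB)\n",
    nrow(x$templates), ncol(x$templates), x$frequency_khz, x$max_raw_gain_db))
  invisible(x)
}
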