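#' Construct a directional field on a hemisphere partition
#'
#' A directional field stores a gain (dB) for every cell of a
#' [partition_hemisphere()] partition at one frequency. Roles distinguish
#' the emission beam, per-ear hearing sensitivity, and the combined
#' emission-times-hearing field (the augmented head-related transfer
#' function, AHRTF).
#'
#' @param partition a `sphere_partition`.
#' @param gain_db numeric vector of per-cell gains (dB), one per cell.
#' @param frequency_khz frequency in kHz.
#' @param role one of `"emission"`, `"hearing_left"`, `"hearing_right"`,
#'   `"ahrtf_left"`, `"ahrtf_right"`.
#' @param floor_db gain floor (dB) used when rotations sample outside the
#'   stored domain. Default -60.
#' @return a `directional_field`: the partition tibble plus a `gain_db`
#'   column, carrying `frequency_khz`, `role` and `floor_db` attributes.
#' @export
directional_field <- function(partition, gain_db, frequency_khz,
                              role = c("emission", "hearing_left",
                                       "hearing_right", "ahrtf_left",
                                       "ahrtf_right"),
                              floor_db = -60) {
  role <- match.arg(role)
  stopifnot(inherits(partition, "sphere_partition"))
  if (length(gain_db) != nrow(partition)) {
    stop_bad_arg("`gain_db` must have one value per partition cell")
  }
  if (any(!is.finite(gain_db))) stop_bad_arg("gains must be finite")
  check_positive_scalar(frequency_khz, "frequency_khz")
  out <- tibble::as_tibble(partition)
  out$gain_db <- as.numeric(gain_db)
  attr(out, "n_cells") <- nrow(out)
  attr(out, "frequency_khz") <- frequency_khz
  attr(out, "role") <- role
  attr(out, "floor_db") <- floor_db
  class(out) <- c("directional_field", "sphere_partition", class(tibble::tibble()))
  out
}

field_frequency <- function(field) attr(field, "frequency_khz")
field_role <- function(field) attr(field, "role")

#' Synthetic head configuration
#'
#' Parameters of the synthetic directivity model that stands in for a
#' boundary-element-simulated head: a directional emission beam (or the
#' two-isotropic-source control emitter), and two hearing beams with
#' laterally offset axes and a bounded ear gain. The defaults emulate the
#' structural features the localization model exploits: beams narrow in
#' proportion to wavelength/aperture, the emission axis drifts to slightly
#' higher elevations with frequency, and the left/right ear axes are offset
#' to either side.
#'
#' @param variant `"focused"` (directional emission beam) or
#'   `"isotropic_pair"` (two omni-directional sources 4.2 mm apart, the
#'   control emitter that strips the facial morphology down to the nostril
#'   spacing).
#' @param emission_aperture_mm,hearing_aperture_mm effective radiator sizes
#'   (mm) controlling beamwidth.
#' @param ear_axis_az_deg,ear_axis_el_deg hearing-beam axis offsets: left ear
#'   at `(-az, +el)`, right ear at `(+az, +el)` degrees.
#' @param ear_gain_cap_db maximum hearing gain (dB). Default 12.
#' @param source_spacing_mm spacing of the isotropic source pair (mm).
#'   Default 4.2.
#' @param speed_of_sound_ms speed of sound (m/s). Default 343.
#' @param gain_floor_db floor applied to emission fields (dB).
#' @param null_depth_db depth cap (dB re. peak) of the interference nulls of
#'   the two-source control emitter. Default -15: idealized point-sampled
#'   nulls are unphysically deep; measured and simulated emission fields show
#'   null depths of one to a few tens of dB.
#' @param hearing_floor_db floor of the hearing beams (dB). Default -15,
#'   giving a 27 dB front-hemisphere directivity span with the default ear
#'   gain: pinna patterns are sidelobe-limited to a few tens of dB, much
#'   shallower than an emission beam's skirts.
#' @param emission_axis_el0_deg emission axis elevation at 20 kHz (degrees);
#'   the axis rises by `emission_axis_el_slope` degrees per kHz above that.
#' @param emission_axis_el_slope degrees of axis elevation per kHz.
#' @return a `synthetic_head` configuration list.
#' @export
synthetic_head <- function(variant = c("focused", "isotropic_pair"),
                           emission_aperture_mm = 9,
                           hearing_aperture_mm = 14,
                           ear_axis_az_deg = 15,
                           ear_axis_el_deg = 10,
                           ear_gain_cap_db = 12,
                           source_spacing_mm = 4.2,
                           speed_of_sound_ms = 343,
                           gain_floor_db = -60,
                           hearing_floor_db = -15,
                           null_depth_db = -15,
                           emission_axis_el0_deg = 5,
                           emission_axis_el_slope = 1 / 30) {
  variant <- match.arg(variant)
  check_positive_scalar(emission_aperture_mm, "emission_aperture_mm")
  check_positive_scalar(hearing_aperture_mm, "hearing_aperture_mm")
  if (ear_gain_cap_db < 0) stop_bad_arg("`ear_gain_cap_db` must be >= 0")
  structure(
    list(
      variant = variant,
      emission_aperture_mm = emission_aperture_mm,
      hearing_aperture_mm = hearing_aperture_mm,
      ear_axis_az_deg = ear_axis_az_deg,
      ear_axis_el_deg = ear_axis_el_deg,
      ear_gain_cap_db = ear_gain_cap_db,
      source_spacing_mm = source_spacing_mm,
      speed_of_sound_ms = speed_of_sound_ms,
      gain_floor_db = gain_floor_db,
      hearing_floor_db = hearing_floor_db,
      null_depth_db = null_depth_db,
      emission_axis_el0_deg = emission_axis_el0_deg,
      emission_axis_el_slope = emission_axis_el_slope
    ),
    class = "synthetic_head"
  )
}

# unnormalized two-monopole interference pattern in dB (max 0 at broadside)
two_source_pattern_db <- function(azimuth_deg, elevation_deg, spacing_mm,
                                  frequency_khz, speed_of_sound_ms = 343) {
  lambda_mm <- speed_of_sound_ms * 1000 / (frequency_khz * 1000)
  u_y <- cos(elevation_deg * DEG) * sin(azimuth_deg * DEG)
  # coherent sum of two unit monopoles at +/- spacing/2 on the interaural axis
  amp <- abs(2 * cos(pi * spacing_mm * u_y / lambda_mm))
  20 * log10(amp / 2)
}

#' Two-isotropic-source emission field
#'
#' The control emitter: two omni-directional point sources spaced
#' `source_spacing_mm` apart along the interaural axis, summed coherently in
#' the far field. Strips the emitter morphology down to the nostril spacing;
#' the pattern is symmetric about the midline with its global maximum
#' straight ahead. Interference nulls are capped at the configured null
#' depth (idealized nulls are unphysically deep), the result floored at the
#' gain floor and normalized to unit radiated power over the hemisphere.
#'
#' @param cfg a [synthetic_head()] configuration.
#' @param frequency_khz frequency in kHz.
#' @param partition a `sphere_partition`.
#' @return an emission `directional_field`.
#' @export
two_source_emission <- function(cfg, frequency_khz, partition) {
  check_positive_scalar(frequency_khz, "frequency_khz")
  g <- two_source_pattern_db(partition$azimuth_deg, partition$elevation_deg,
                             cfg$source_spacing_mm, frequency_khz,
                             cfg$speed_of_sound_ms)
  g <- pmax(g, cfg$null_depth_db, cfg$gain_floor_db)
  f <- directional_field(partition, g, frequency_khz, role = "emission",
                         floor_db = cfg$gain_floor_db)
  normalize_emission(f)
}

#' Gaussian-lobe parametric beam
#'
#' Synthetic stand-in for a simulated directivity pattern: a Gaussian main
#' lobe whose half-power beamwidth scales as wavelength over aperture
#' (`70 * lambda / aperture` degrees, the horn-antenna rule of thumb), so
#' the beam narrows in inverse proportion to frequency. Peak gain equals
#' `gain_cap_db` on the axis. Off the main lobe the pattern rolls into a
#' rippled sidelobe skirt: concentric rings `ripple_amp_db` deep riding on
#' the floor, spaced like the main lobe (sidelobe spacing scales with
#' wavelength over aperture). Simulated and measured directivity fields have
#' such texture everywhere; a perfectly flat skirt would make peripheral
#' directions mutually indistinguishable in a way real fields are not. Set
#' `ripple_amp_db = 0` for the bare floored Gaussian lobe.
#'
#' @param aperture_mm effective aperture (mm).
#' @param frequency_khz frequency (kHz).
#' @param axis_az_deg,axis_el_deg beam axis direction (degrees).
#' @param gain_cap_db peak gain (dB).
#' @param partition a `sphere_partition`.
#' @param floor_db gain floor (dB). Default -60.
#' @param ripple_amp_db peak-to-trough sidelobe ripple (dB). Default 6.
#' @param speed_of_sound_ms speed of sound (m/s).
#' @param role field role. Default `"hearing_left"`.
#' @return a `directional_field`.
#' @export
parametric_beam <- function(aperture_mm, frequency_khz, axis_az_deg,
                            axis_el_deg, gain_cap_db, partition,
                            floor_db = -60, ripple_amp_db = 6,
                            speed_of_sound_ms = 343,
                            role = "hearing_left") {
  check_positive_scalar(aperture_mm, "aperture_mm")
  check_positive_scalar(frequency_khz, "frequency_khz")
  lambda_mm <- speed_of_sound_ms * 1000 / (frequency_khz * 1000)
  hpbw_deg <- 70 * lambda_mm / aperture_mm
  ang <- angular_distance(partition$azimuth_deg, partition$elevation_deg,
                          axis_az_deg, axis_el_deg)
  # -3 dB at ang = hpbw/2 for a Gaussian lobe
  main <- gain_cap_db - 12 * (ang / hpbw_deg)^2
  skirt <- floor_db + ripple_amp_db *
    (0.5 + 0.5 * cos(2 * pi * (ang - hpbw_deg) / hpbw_deg))
  directional_field(partition, pmax(main, skirt, floor_db), frequency_khz,
                    role = role, floor_db = floor_db)
}

#' Normalize an emission field to unit radiated power
#'
#' Rescales the field so its linear power, weighted by the cell solid
#' angles, integrates to 1 over the frontal hemisphere (all emitted energy
#' is assumed to stay in front of the animal). The pattern shape is
#' unchanged; the operation is idempotent.
#'
#' @param field an emission `directional_field`.
#' @return the normalized field.
#' @export
normalize_emission <- function(field) {
  stopifnot(inherits(field, "directional_field"))
  if (field_role(field) != "emission") {
    stop_bad_arg("`normalize_emission()` applies to emission fields only")
  }
  p <- 10^(field$gain_db / 10)
  total <- sum(p * field$solid_angle_sr)
  if (!is.finite(total) || total <= 0) {
    abort("degenerate emission field: total radiated power is zero",
          class = "pinnasonar_degenerate_error")
  }
  out <- field
  out$gain_db <- field$gain_db - 10 * log10(total)
  out
}

#' Combine emission and hearing fields into an AHRTF
#'
#' The augmented head-related transfer function is the pointwise product of
#' the emission and hearing directivities: linear magnitudes multiply, so dB
#' gains add cell by cell.
#'
#' @param emission,hearing `directional_field`s on the same partition and
#'   frequency.
#' @return a `directional_field` with role `ahrtf_left`/`ahrtf_right`
#'   matching the hearing field's side.
#' @export
combine_ahrtf <- function(emission, hearing) {
  stopifnot(inherits(emission, "directional_field"),
            inherits(hearing, "directional_field"))
  if (!same_partition(emission, hearing)) {
    stop_bad_arg("emission and hearing fields are on different partitions")
  }
  if (abs(field_frequency(emission) - field_frequency(hearing)) > 1e-9) {
    stop_bad_arg("emission and hearing fields are at different frequencies")
  }
  role <- if (field_role(hearing) == "hearing_right") "ahrtf_right" else "ahrtf_left"
  directional_field(emission, emission$gain_db + hearing$gain_db,
                    field_frequency(emission), role = role,
                    floor_db = attr(hearing, "floor_db"))
}

#' Emission and hearing fields of the synthetic head at one frequency
#'
#' Builds the per-frequency triple the template stage consumes: an emission
#' field (directional beam or isotropic pair, per the configured variant,
#' normalized to unit radiated power) and left/right hearing beams with
#' offset axes capped at the ear gain.
#'
#' @param cfg a [synthetic_head()] configuration.
#' @param frequency_khz frequency (kHz).
#' @param partition a `sphere_partition`.
#' @return a list with elements `emission`, `hearing_left`, `hearing_right`.
#' @export
head_fields <- function(cfg, frequency_khz, partition) {
  stopifnot(inherits(cfg, "synthetic_head"))
  if (cfg$variant == "isotropic_pair") {
    emission <- two_source_emission(cfg, frequency_khz, partition)
  } else {
    el <- cfg$emission_axis_el0_deg +
      cfg$emission_axis_el_slope * (frequency_khz - 20)
    emission <- parametric_beam(cfg$emission_aperture_mm, frequency_khz,
                                axis_az_deg = 0, axis_el_deg = el,
                                gain_cap_db = 0, partition = partition,
                                floor_db = cfg$gain_floor_db,
                                speed_of_sound_ms = cfg$speed_of_sound_ms,
                                role = "emission")
    emission <- normalize_emission(emission)
  }
  list(
    emission = emission,
    hearing_left = parametric_beam(
      cfg$hearing_aperture_mm, frequency_khz,
      axis_az_deg = -cfg$ear_axis_az_deg, axis_el_deg = cfg$ear_axis_el_deg,
      gain_cap_db = cfg$ear_gain_cap_db, partition = partition,
      floor_db = cfg$hearing_floor_db,
      speed_of_sound_ms = cfg$speed_of_sound_ms,
      role = "hearing_left"),
    hearing_right = parametric_beam(
      cfg$hearing_aperture_mm, frequency_khz,
      axis_az_deg = cfg$ear_axis_az_deg, axis_el_deg = cfg$ear_axis_el_deg,
      gain_cap_db = cfg$ear_gain_cap_db, partition = partition,
      floor_db = cfg$hearing_floor_db,
      speed_of_sound_ms = cfg$speed_of_sound_ms,
      role = "hearing_right")
  )
}
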