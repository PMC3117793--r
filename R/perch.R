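#' Acoustic wavelength
#'
#' @param frequency_khz frequency (kHz).
#' @param speed_of_sound_ms speed of sound (m/s). Default 343.
#' @return wavelength in metres.
#' @export
wavelength_m <- function(frequency_khz, speed_of_sound_ms = 343) {
  speed_of_sound_ms / (frequency_khz * 1000)
}

#' Mesh nodes per wavelength
#'
#' Sampling density of a surface mesh relative to the acoustic wavelength;
#' boundary-element simulations need at least about 4 nodes per wavelength
#' for stable fields. Shared wavelength arithmetic with the two-source
#' emitter model.
#'
#' @param frequency_khz frequency (kHz).
#' @param edge_length_mm maximum mesh edge length (mm).
#' @param speed_of_sound_ms speed of sound (m/s).
#' @return nodes per wavelength.
#' @examples
#' nodes_per_wavelength(110, 0.5) # > 4
#' @export
nodes_per_wavelength <- function(frequency_khz, edge_length_mm,
                                 speed_of_sound_ms = 343) {
  check_positive_scalar(edge_length_mm, "edge_length_mm")
  wavelength_m(frequency_khz, speed_of_sound_ms) * 1000 / edge_length_mm
}

#' Call repetition rate from the interpulse interval
#'
#' @param interpulse_interval_ms interval between calls (ms).
#' @return repetition rate in Hz (a 6 ms interval gives about 166 Hz).
#' @export
repetition_rate_hz <- function(interpulse_interval_ms) {
  check_positive_scalar(interpulse_interval_ms, "interpulse_interval_ms")
  1000 / interpulse_interval_ms
}

#' Pure-tone atmospheric absorption (ISO 9613-1)
#'
#' Absorption coefficient of sound in air from the ISO 9613-1 closed form
#' (classical plus nitrogen/oxygen relaxation), in dB per metre.
#'
#' @param frequency_khz frequency in kHz, in `[1, 200]`.
#' @param temperature_c air temperature (deg C). Default 20.
#' @param rel_humidity relative humidity (percent). Default 50.
#' @param pressure_kpa ambient pressure (kPa). Default 101.325.
#' @return absorption in dB/m (strictly positive).
#' @examples
#' atmospheric_attenuation(80) > atmospheric_attenuation(40)
#' @export
atmospheric_attenuation <- function(frequency_khz, temperature_c = 20,
                                    rel_humidity = 50,
                                    pressure_kpa = 101.325) {
  if (any(frequency_khz < 1 | frequency_khz > 200)) {
    stop_bad_arg("`frequency_khz` must lie in [1, 200]")
  }
  if (rel_humidity < 0 || rel_humidity > 100 || pressure_kpa <= 0 ||
      temperature_c < -50 || temperature_c > 60) {
    stop_bad_arg("air condition outside the supported range")
  }
  f <- frequency_khz * 1000
  t_k <- temperature_c + 273.15
  t0 <- 293.15
  t01 <- 273.16
  pr <- 101.325
  p <- pressure_kpa / pr
  psat <- 10^(-6.8346 * (t01 / t_k)^1.261 + 4.6151)
  h <- rel_humidity * psat / p
  fr_o <- p * (24 + 4.04e4 * h * (0.02 + h) / (0.391 + h))
  fr_n <- p * (t_k / t0)^(-0.5) *
    (9 + 280 * h * exp(-4.170 * ((t_k / t0)^(-1 / 3) - 1)))
  8.686 * f^2 * (1.84e-11 / p * sqrt(t_k / t0) +
                   (t_k / t0)^(-2.5) *
                     (0.01275 * exp(-2239.1 / t_k) / (fr_o + f^2 / fr_o) +
                        0.1068 * exp(-3352.0 / t_k) / (fr_n + f^2 / fr_n)))
}

#' Perch-hunting scenario
#'
#' Parameters of the ambush-foraging Monte Carlo: prey appear at random
#' locations within a foraging radius; each distance converts to an echo
#' strength through the sonar equation (two-way spherical spreading from a
#' 0.1 m reference, atmospheric attenuation, target strength and ear gain).
#'
#' @param radius_m foraging radius (m).
#' @param n_prey prey locations per simulation. Default 1000.
#' @param call_spl_db call level (dB SPL) at the 0.1 m reference.
#'   Default 105.
#' @param target_strength_db echo level relative to the impinging sound at
#'   the target (dB). Default -40 (a small fluttering insect).
#' @param ear_gain_db maximum external-ear gain (dB). Default 12.
#' @param temperature_c,rel_humidity,pressure_kpa air condition.
#' @param ref_distance_m spreading reference distance (m). Default 0.1.
#' @param snr_range_db range of echo strengths the entropy curves cover;
#'   computed strengths are clamped to it. Default `c(0, 50)`.
#' @param ball `"volume"` (default; prey uniform in the ball, distance
#'   density proportional to r^2) or `"hemisphere"` (uniform in the upper
#'   half-ball; identical distance distribution, kept for explicitness).
#' @return a `hunt_scenario`.
#' @export
hunt_scenario <- function(radius_m = 3, n_prey = 1000, call_spl_db = 105,
                          target_strength_db = -40, ear_gain_db = 12,
                          temperature_c = 20, rel_humidity = 50,
                          pressure_kpa = 101.325, ref_distance_m = 0.1,
                          snr_range_db = c(0, 50),
                          ball = c("volume", "hemisphere")) {
  check_positive_scalar(radius_m, "radius_m")
  if (n_prey < 1) stop_bad_arg("`n_prey` must be >= 1")
  structure(
    list(radius_m = radius_m, n_prey = as.integer(n_prey),
         call_spl_db = call_spl_db, target_strength_db = target_strength_db,
         ear_gain_db = ear_gain_db, temperature_c = temperature_c,
         rel_humidity = rel_humidity, pressure_kpa = pressure_kpa,
         ref_distance_m = ref_distance_m, snr_range_db = snr_range_db,
         ball = match.arg(ball)),
    class = "hunt_scenario"
  )
}

#' Echo strength at the ear from the sonar equation
#'
#' `call level - 40 log10(d / ref) - 2 d alpha(f) + target strength +
#' ear gain`, clamped to the scenario's evaluated strength range so the
#' value can index the entropy-versus-strength curves.
#'
#' @param distance_m bat-to-prey distance(s), at least the reference
#'   distance.
#' @param frequency_khz call frequency (kHz).
#' @param scenario a [hunt_scenario()].
#' @param clamp clamp to `scenario$snr_range_db`? Default `TRUE`.
#' @return echo strength(s) in dB.
#' @export
echo_snr <- function(distance_m, frequency_khz, scenario = hunt_scenario(),
                     clamp = TRUE) {
  stopifnot(inherits(scenario, "hunt_scenario"))
  if (any(distance_m < scenario$ref_distance_m)) {
    stop_bad_arg("`distance_m` must be >= the reference distance")
  }
  alpha <- atmospheric_attenuation(frequency_khz, scenario$temperature_c,
                                   scenario$rel_humidity,
                                   scenario$pressure_kpa)
  snr <- scenario$call_spl_db -
    40 * log10(distance_m / scenario$ref_distance_m) -
    2 * distance_m * alpha +
    scenario$target_strength_db + scenario$ear_gain_db
  if (clamp) {
    snr <- pmin(pmax(snr, scenario$snr_range_db[1]), scenario$snr_range_db[2])
  }
  snr
}

#' Sample prey distances within the foraging radius
#'
#' Prey locations are uniform in the ball of the foraging radius, so the
#' distance density is proportional to r^2 (inverse-CDF sampling; the
#' median distance is `radius * 2^(-1/3)`).
#'
#' @param scenario a [hunt_scenario()].
#' @param seed optional seed.
#' @return a numeric vector of `n_prey` distances (m).
#' @export
sample_prey_distances <- function(scenario = hunt_scenario(), seed = NULL) {
  stopifnot(inherits(scenario, "hunt_scenario"))
  draw <- function() {
    d <- scenario$radius_m * stats::runif(scenario$n_prey)^(1 / 3)
    pmax(d, scenario$ref_distance_m)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Expected perch-hunting entropy at one frequency
#'
#' Monte Carlo mean over sampled prey of the expected localization entropy
#' at each prey's echo strength, obtained by linear interpolation of the
#' entropy-versus-strength curve for that frequency.
#'
#' @param frequency_khz call frequency (kHz); must appear in `curves`.
#' @param curves a tibble `(frequency_khz, snr_db, mean_entropy_bits)`,
#'   e.g. from [entropy_summary()].
#' @param scenario a [hunt_scenario()].
#' @param seed optional seed.
#' @param attenuation include atmospheric attenuation? Default `TRUE`
#'   (`FALSE` isolates the spreading-only ablation).
#' @return mean entropy in bits.
#' @export
perch_hunt_entropy <- function(frequency_khz, curves,
                               scenario = hunt_scenario(), seed = NULL,
                               attenuation = TRUE) {
  cv <- dplyr::filter(curves,
                      abs(.data$frequency_khz - .env$frequency_khz) < 1e-9)
  if (nrow(cv) < 2) {
    stop_bad_arg("`curves` must cover the requested frequency on a grid")
  }
  d <- sample_prey_distances(scenario, seed)
  snr <- if (attenuation) {
    echo_snr(d, frequency_khz, scenario)
  } else {
    s <- scenario$call_spl_db -
      40 * log10(d / scenario$ref_distance_m) +
      scenario$target_strength_db + scenario$ear_gain_db
    pmin(pmax(s, scenario$snr_range_db[1]), scenario$snr_range_db[2])
  }
  out_of_support <- snr < min(cv$snr_db) | snr > max(cv$snr_db)
  if (any(out_of_support)) {
    warn(sprintf("%d echo strengths outside the curve support were clamped",
                 sum(out_of_support)))
    snr <- pmin(pmax(snr, min(cv$snr_db)), max(cv$snr_db))
  }
  mean(approx(cv$snr_db, cv$mean_entropy_bits, xout = snr)$y)
}

#' Perch-hunting sweep over frequency and foraging radius
#'
#' Runs the Monte Carlo of [perch_hunt_entropy()] for every frequency in
#' the curves and every foraging radius, with fresh prey samples per cell
#' of the sweep.
#'
#' @param curves entropy-versus-strength curves, see [perch_hunt_entropy()].
#' @param radii_m foraging radii (m). Default 1 to 5.
#' @param scenario a [hunt_scenario()]; its radius is overridden by
#'   `radii_m`.
#' @param seed integer seed for the whole sweep.
#' @param attenuation include atmospheric attenuation? Default `TRUE`.
#' @return a tibble `(frequency_khz, radius_m, mean_entropy_bits)`.
#' @export
perch_hunt <- function(curves, radii_m = 1:5, scenario = hunt_scenario(),
                       seed = NULL, attenuation = TRUE) {
  freqs <- sort(unique(curves$frequency_khz))
  run <- function() {
    purrr::map_dfr(radii_m, function(r) {
      sc <- scenario
      sc$radius_m <- r
      purrr::map_dfr(freqs, function(f) {
        tibble::tibble(
          frequency_khz = f, radius_m = r,
          mean_entropy_bits = perch_hunt_entropy(f, curves, sc,
                                                 attenuation = attenuation))
      })
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
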