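test_that("two-source pattern matches direct phasor arithmetic everywhere", {
  p <- partition_hemisphere(256)
  for (f_khz in c(40, 80, 110)) {
    got <- pinnasonar:::two_source_pattern_db(
      p$azimuth_deg, p$elevation_deg, 4.2, f_khz)
    # oracle: coherent sum of two complex unit monopoles on the y axis
    lambda_mm <- 343e3 / (f_khz * 1e3)
    k <- 2 * pi / lambda_mm
    u_y <- cos(p$elevation_deg * pi / 180) * sin(p$azimuth_deg * pi / 180)
    amp <- Mod(exp(1i * k * 2.1 * u_y) + exp(-1i * k * 2.1 * u_y))
    expect_lt(max(abs(got - 20 * log10(amp / 2))), 1e-6)
  }
})

test_that("the two-source pattern peaks straight ahead with a null at the predicted azimuth", {
  az <- seq(-90, 90, by = 0.1)
  pat <- pinnasonar:::two_source_pattern_db(az, 0, 4.2, 80)
  expect_equal(pat[az == 0], max(pat))
  expect_equal(pat, rev(pat)) # azimuthal symmetry
  null_pred <- asin(343e3 / 80e3 / (2 * 4.2)) * 180 / pi # ~30.7 deg
  null_obs <- az[az > 0][which.min(pat[az > 0])]
  expect_lt(abs(null_obs - null_pred), 0.1)
})

test_that("coincident sources give an isotropic emission field", {
  p <- partition_hemisphere(128)
  cfg <- synthetic_head("isotropic_pair", source_spacing_mm = 1e-9)
  f <- two_source_emission(cfg, 80, p)
  expect_lt(max(f$gain_db) - min(f$gain_db), 1e-6)
})

test_that("two-source emission is normalized to unit radiated power", {
  p <- partition_hemisphere(256)
  cfg <- synthetic_head("isotropic_pair")
  for (f_khz in c(30, 80)) {
    f <- two_source_emission(cfg, f_khz, p)
    expect_equal(sum(10^(f$gain_db / 10) * f$solid_angle_sr), 1,
                 tolerance = 1e-9)
  }
  expect_error(two_source_emission(cfg, 0, p), class = "pinnasonar_arg_error")
})

test_that("parametric beams narrow in proportion to wavelength", {
  p <- partition_hemisphere(4096)
  ang <- angular_distance(p$azimuth_deg, p$elevation_deg, 0, 0)
  ord <- order(ang)
  # empirical half-power solid angle, interpolated from the sampled gains
  half_power_area <- function(f_khz) {
    b <- parametric_beam(14, f_khz, 0, 0, 12, p, ripple_amp_db = 0)
    g <- b$gain_db[ord]
    a <- ang[ord]
    keep <- g > -50 & !duplicated(g) # one sample per collar ring
    a3 <- stats::approx(rev(g[keep]), rev(a[keep]), xout = max(g) - 3)$y
    2 * pi * (1 - cos(a3 * pi / 180))
  }
  a40 <- half_power_area(40)
  a80 <- half_power_area(80)
  # halving the wavelength halves the beamwidth: area ratio ~ 4
  expect_gt(a40 / a80, 3.4)
  expect_lt(a40 / a80, 4.6)
  # -3 dB solid angle strictly decreases with frequency
  areas <- vapply(seq(20, 110, by = 10), half_power_area, numeric(1))
  expect_true(all(diff(areas) < 0))
})

test_that("beam peak sits at the cap on the axis and at the floor far off-axis", {
  p <- partition_hemisphere(256)
  b <- parametric_beam(10, 60, 0, 0, 12, p, ripple_amp_db = 0)
  expect_equal(b$gain_db[1], 12) # cell 1 is the polar cap at (0, 0)
  wide <- parametric_beam(1000, 80, 0, 0, 12, p, ripple_amp_db = 0)
  off <- angular_distance(p$azimuth_deg, p$elevation_deg, 0, 0) > 85
  expect_true(all(wide$gain_db[off] <= -60 + 1e-6))
})

test_that("emission normalization is exact, idempotent, and shape-preserving", {
  p <- partition_hemisphere(128)
  f <- directional_field(p, stats::rnorm(128, -10, 5), 60, role = "emission")
  n1 <- normalize_emission(f)
  expect_equal(sum(10^(n1$gain_db / 10) * n1$solid_angle_sr), 1,
               tolerance = 1e-9)
  n2 <- normalize_emission(n1)
  expect_equal(n2$gain_db, n1$gain_db, tolerance = 1e-12)
  expect_equal(diff(range(n1$gain_db - f$gain_db)), 0, tolerance = 1e-12)

  # uniform field: linear power 1/(2 pi) per steradian
  u <- normalize_emission(directional_field(p, rep(-7, 128), 60,
                                            role = "emission"))
  expect_equal(10^(u$gain_db[1] / 10), 1 / (2 * pi), tolerance = 1e-12)

  # two-cell hand normalization: linear powers (3, 1) -> (0.75, 0.25) / cell
  p2 <- partition_hemisphere(2)
  f2 <- normalize_emission(directional_field(p2, 10 * log10(c(3, 1)), 60,
                                             role = "emission"))
  expect_equal(10^(f2$gain_db / 10) * f2$solid_angle_sr, c(0.75, 0.25),
               tolerance = 1e-12)
})

test_that("degenerate and mis-typed fields are rejected", {
  p <- partition_hemisphere(8)
  f <- directional_field(p, rep(0, 8), 60, role = "emission")
  f$gain_db <- rep(-Inf, 8)
  expect_error(normalize_emission(f), class = "pinnasonar_degenerate_error")
  h <- directional_field(p, rep(0, 8), 60, role = "hearing_left")
  expect_error(normalize_emission(h), class = "pinnasonar_arg_error")
  expect_error(directional_field(p, rep(NA_real_, 8), 60, role = "emission"),
               class = "pinnasonar_arg_error")
})

test_that("combining fields adds dB gains cellwise", {
  p <- partition_hemisphere(64)
  e <- directional_field(p, rep(-3, 64), 60, role = "emission")
  h <- directional_field(p, rep(-4, 64), 60, role = "hearing_right")
  c1 <- combine_ahrtf(e, h)
  expect_equal(c1$gain_db, rep(-7, 64))
  expect_equal(attr(c1, "role"), "ahrtf_right")

  # identity element: 0 dB emission leaves the hearing field unchanged
  id <- directional_field(p, rep(0, 64), 60, role = "emission")
  hb <- directional_field(p, stats::rnorm(64), 60, role = "hearing_left")
  expect_equal(combine_ahrtf(id, hb)$gain_db, hb$gain_db)

  # commutative in the gains
  e2 <- directional_field(p, stats::rnorm(64), 60, role = "emission")
  h2 <- directional_field(p, stats::rnorm(64), 60, role = "hearing_left")
  swapped_e <- directional_field(p, h2$gain_db, 60, role = "emission")
  swapped_h <- directional_field(p, e2$gain_db, 60, role = "hearing_left")
  expect_equal(combine_ahrtf(e2, h2)$gain_db,
               combine_ahrtf(swapped_e, swapped_h)$gain_db)

  f2 <- directional_field(p, rep(0, 64), 80, role = "hearing_left")
  expect_error(combine_ahrtf(e, f2), class = "pinnasonar_arg_error")
})

test_that("narrower normalized beams trade hemisphere-average gain for peak gain", {
  p <- partition_hemisphere(1024)
  avg_rel_gain <- function(f_khz) {
    b <- parametric_beam(9, f_khz, 0, 0, 0, p, ripple_amp_db = 0)
    b <- normalize_emission(directional_field(p, b$gain_db, f_khz,
                                              role = "emission"))
    mean(b$gain_db - max(b$gain_db)) # template-style: peak at 0 dB
  }
  gains <- vapply(c(20, 40, 80), avg_rel_gain, numeric(1))
  expect_true(all(diff(gains) < 0))
})

test_that("the synthetic head produces the expected per-frequency triple", {
  p <- partition_hemisphere(128)
  cfg <- synthetic_head("focused")
  fl <- head_fields(cfg, 80, p)
  expect_named(fl, c("emission", "hearing_left", "hearing_right"))
  expect_equal(sum(10^(fl$emission$gain_db / 10) * p$solid_angle_sr), 1,
               tolerance = 1e-9)
  expect_lte(max(fl$hearing_left$gain_db), 12)
  expect_gt(max(fl$hearing_left$gain_db), 10) # axis nearly hits a cell
  # left/right beams point at the configured offset axes
  il <- which.max(fl$hearing_left$gain_db)
  ir <- which.max(fl$hearing_right$gain_db)
  expect_lt(angular_distance(p$azimuth_deg[il], p$elevation_deg[il], -15, 10),
            15)
  expect_lt(angular_distance(p$azimuth_deg[ir], p$elevation_deg[ir], 15, 10),
            15)
  expect_true(p$azimuth_deg[il] < 0 && p$azimuth_deg[ir] > 0)
})
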