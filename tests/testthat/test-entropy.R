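test_that("measurements are floored, noise-free in the zero-noise limit, and unbiased above floor", {
  cov <- build_covariance()
  tmpl <- c(seq(-3, 3, by = 1), seq(3, -3, by = -1))

  # deeply sub-floor strength: everything truncates to the floor
  expect_equal(simulate_measurement(tmpl, -1000, cov, seed = 1), rep(0, 14))

  # noiseless limit reproduces the floored mean exactly
  tiny <- build_covariance(sigma_db = 1e-6)
  expect_equal(simulate_measurement(tmpl, 30, tiny, seed = 2),
               pmax(tmpl + 30, 0), tolerance = 1e-4)

  # high strength, no flooring: sample mean converges on template + A
  b <- simulate_measurement(tmpl, 40, cov, n = 1e4, seed = 3)
  expect_lt(max(abs(colMeans(b) - (tmpl + 40))), 0.2)
  expect_true(all(b >= 0))
})

test_that("the likelihood is a multivariate normal about the floored mean", {
  tmpl <- rep(0, 14)
  cov <- build_covariance(5, 0, 0, 7)
  b <- rep(10, 14)
  # at the mean, the density is the bare normalizer (2 pi sigma^2)^(-M/2)
  expect_equal(likelihood(b, tmpl, 10, cov), (2 * pi * 25)^(-7),
               tolerance = 1e-12)
  # the mean is the mode in b
  expect_gt(likelihood(b, tmpl, 10, cov),
            likelihood(b + c(3, rep(0, 13)), tmpl, 10, cov))
  # indistinguishable positions: identical templates, identical likelihoods
  cov2 <- build_covariance()
  t2 <- c(seq(-3, 3, 1), seq(3, -3, -1))
  expect_equal(likelihood(b, t2, 12, cov2), likelihood(b, t2, 12, cov2))
})

test_that("the censored likelihood variant agrees with the default away from the floor", {
  cov <- build_covariance(5, 0, 0, 7) # diagonal: variants share the normalizer
  tmpl <- c(seq(-3, 3, 1), seq(3, -3, -1))
  b <- pmax(tmpl + 40, 0) + 1
  expect_equal(likelihood(b, tmpl, 40, cov, method = "censored", log = TRUE),
               likelihood(b, tmpl, 40, cov, log = TRUE), tolerance = 1e-9)
  # at the floor the censored variant accumulates mass, not density
  expect_gt(likelihood(rep(0, 14), tmpl, -50, cov, method = "censored",
                       log = TRUE), log(1e-3))
})

test_that("strength marginalization averages the likelihood over the prior grid", {
  cov <- build_covariance()
  tmpl <- c(seq(-3, 3, 1), seq(3, -3, -1))
  b <- simulate_measurement(tmpl, 25, cov, seed = 9)

  # point prior collapses to the plain likelihood
  pt <- strength_prior(25, 25, 1)
  expect_equal(marginal_likelihood(b, tmpl, cov, pt),
               likelihood(b, tmpl, 25, cov), tolerance = 1e-12)

  # an average can never exceed the best single strength
  pr <- strength_prior(0, 50, 1)
  best <- max(vapply(pr$grid, function(a) likelihood(b, tmpl, a, cov),
                     numeric(1)))
  expect_lte(marginal_likelihood(b, tmpl, cov, pr), best)

  # grid refinement changes the marginal by well under 1 percent
  m1 <- marginal_likelihood(b, tmpl, cov, strength_prior(0, 50, 1), log = TRUE)
  m05 <- marginal_likelihood(b, tmpl, cov, strength_prior(0, 50, 0.5),
                             log = TRUE)
  expect_lt(abs(exp(m1 - m05) - 1), 0.01)
})

test_that("posteriors normalize, and identical templates give a uniform posterior", {
  h <- small_head(n_cells = 32)
  cov <- build_covariance()
  teff <- pinnasonar:::effective_templates(h$ts)
  b <- simulate_measurement(teff[5, ], 30, cov, seed = 4)
  post <- posterior(b, h$ts, cov)
  expect_equal(sum(post$posterior), 1, tolerance = 1e-12)

  flat_ts <- manual_template_set(matrix(0, 16, 14))
  b2 <- simulate_measurement(rep(0, 14), 20, cov, seed = 5)
  post2 <- posterior(b2, flat_ts, cov)
  expect_equal(post2$posterior, rep(1 / 16, 16), tolerance = 1e-12)
})

test_that("the marginalized posterior matches exhaustive joint enumeration", {
  h <- small_head(n_cells = 16, frequency_khz = 80)
  cov <- build_covariance()
  prior <- strength_prior(0, 20, 5)
  teff <- pinnasonar:::effective_templates(h$ts)
  sigma <- cov$matrix
  set.seed(21)
  for (rep in 1:10) {
    cell <- sample(16, 1)
    b <- simulate_measurement(teff[cell, ], stats::runif(1, 5, 20), cov)
    post <- posterior(b, h$ts, cov, prior)$posterior
    # oracle: enumerate the joint (cell x strength) grid in linear space
    w <- c(0.5, 1, 1, 1, 0.5)
    joint <- outer(seq_len(16), seq_along(prior$grid),
                   Vectorize(function(c, a) {
      mu <- pmax(teff[c, ] + prior$grid[a], 0)
      q <- stats::mahalanobis(b, mu, sigma)
      w[a] * exp(-0.5 * q) / sqrt((2 * pi)^14 * det(sigma))
    }))
    oracle <- rowSums(joint) / sum(joint)
    expect_equal(post, oracle, tolerance = 1e-10)
  }
})

test_that("entropy follows the Shannon formula with its conventions", {
  expect_equal(shannon_entropy(rep(1 / 256, 256)), 8)
  expect_equal(shannon_entropy(c(1, rep(0, 99))), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1)
  expect_error(shannon_entropy(c(-0.2, 1.2)), class = "pinnasonar_arg_error")
  expect_error(shannon_entropy(c(0.4, 0.4)), class = "pinnasonar_arg_error")
})

test_that("the fast entropy engine agrees with the exact posterior path", {
  h <- small_head(n_cells = 48, frequency_khz = 70)
  cov <- build_covariance()
  eng <- pinnasonar:::posterior_engine(h$ts, cov)
  teff <- pinnasonar:::effective_templates(h$ts)
  set.seed(13)
  for (a in c(0, 10, 30, 50)) {
    cell <- sample(48, 1)
    b <- simulate_measurement(teff[cell, ], a, cov)
    h_slow <- shannon_entropy(posterior(b, h$ts, cov)$posterior)
    h_fast <- pinnasonar:::engine_entropies(eng, matrix(b, 1))
    expect_equal(h_fast, h_slow, tolerance = 1e-12)
  }
})

test_that("expected entropy is chance for uninformative templates and near zero when noiseless", {
  flat_ts <- manual_template_set(matrix(0, 64, 14))
  cov <- build_covariance()
  expect_equal(expected_entropy(3, flat_ts, cov, -1000, seed = 1), log2(64),
               tolerance = 1e-9)

  h <- small_head(n_cells = 64, frequency_khz = 60)
  tiny <- build_covariance(sigma_db = 0.01)
  central <- which.min(angular_distance(h$partition$azimuth_deg,
                                        h$partition$elevation_deg, 0, 5))
  expect_lt(expected_entropy(central, h$ts, tiny, 50, seed = 2), 0.5)
})

test_that("twenty realizations give stable expected entropies", {
  h <- small_head(n_cells = 64, frequency_khz = 60)
  cov <- build_covariance()
  h20 <- expected_entropy(10, h$ts, cov, 30, n_realizations = 20, seed = 1)
  h200 <- expected_entropy(10, h$ts, cov, 30, n_realizations = 200, seed = 2)
  expect_lt(abs(h20 - h200), 0.3)
})

test_that("entropy maps stay within bounds and are seed-reproducible", {
  h <- small_head(n_cells = 32, frequency_khz = 60)
  cov <- build_covariance()
  em <- entropy_map(h$ts, cov, snr_grid_db = c(0, 25, 50),
                    n_realizations = 5, seed = 77)
  expect_true(all(em$entropy_bits >= 0 & em$entropy_bits <= log2(32) + 1e-9))
  expect_equal(nrow(em), 32 * 3)
  em2 <- entropy_map(h$ts, cov, snr_grid_db = c(0, 25, 50),
                     n_realizations = 5, seed = 77)
  expect_identical(em$entropy_bits, em2$entropy_bits)
  sm <- entropy_summary(em)
  expect_equal(nrow(sm), 3)
  expect_true(all(sm$range_entropy_bits >= 0))
})

test_that("sub-floor strengths leave the map at chance", {
  flat_ts <- manual_template_set(matrix(0, 32, 14),
                                 rel_gain_db = rep(-2000, 32))
  cov <- build_covariance()
  em <- entropy_map(flat_ts, cov, snr_grid_db = 0, n_realizations = 5,
                    seed = 3)
  expect_equal(em$entropy_bits, rep(log2(32), 32), tolerance = 1e-9)
})

test_that("the focused view concentrates information centrally at high frequency", {
  p <- partition_hemisphere(256)
  cfg <- synthetic_head("focused")
  fl <- head_fields(cfg, 110, p)
  ts <- build_templates(fl$emission, fl$hearing_left, fl$hearing_right)
  cov <- build_covariance()
  em <- entropy_map(ts, cov, snr_grid_db = 15, n_realizations = 20, seed = 6)
  ang <- angular_distance(em$azimuth_deg, em$elevation_deg, 0, 8)
  expect_gte(min(em$entropy_bits[ang > 60]), 7.5) # periphery at chance
  expect_lt(mean(em$entropy_bits[ang < 20]), 5)   # centre informative
})

test_that("angular resolution maps entropy to an equivalent solid angle", {
  expect_equal(angular_resolution(8, 256), 2 * pi)
  expect_equal(angular_resolution(0, 256), 2 * pi / 256)
  expect_equal(angular_resolution(1, 256), 4 * pi / 256)
  p <- partition_hemisphere(64)
  expect_equal(angular_resolution(log2(64), p), 2 * pi)
  expect_error(angular_resolution(9, 256), class = "pinnasonar_arg_error")
  expect_error(angular_resolution(-1, 256), class = "pinnasonar_arg_error")
})
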