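#' Uniform prior over echo strength
#'
#' The mean received echo strength is unknown to the animal and is
#' marginalized out as a nuisance parameter over a uniform grid of dB
#' values. The default grid spans 0 to 50 dB in 1 dB steps; the grid is
#' averaged with trapezoid end weights.
#'
#' @param a_min_db,a_max_db grid limits (dB). Defaults 0 and 50.
#' @param step_db grid step (dB). Default 1.
#' @return a `strength_prior`.
#' @export
strength_prior <- function(a_min_db = 0, a_max_db = 50, step_db = 1) {
  if (a_min_db > a_max_db) stop_bad_arg("`a_min_db` must be <= `a_max_db`")
  check_positive_scalar(step_db, "step_db")
  grid <- seq(a_min_db, a_max_db, by = step_db)
  if (length(grid) == 0) stop_bad_arg("empty strength grid")
  w <- rep(1, length(grid))
  if (length(grid) > 1) w[c(1, length(grid))] <- 0.5
  structure(list(a_min_db = a_min_db, a_max_db = a_max_db,
                 step_db = step_db, grid = grid, log_w = log(w / sum(w))),
            class = "strength_prior")
}

#' Simulate a floored binaural measurement
#'
#' Draws the measured magnitude vector for an echo of mean strength
#' `a_db` from a direction with the given template: correlated Gaussian
#' flutter noise is added to `template + a_db` and the result is clipped
#' from below at the 0 dB detection floor (system noise acts as a maximum
#' operator on the dB scale).
#'
#' @param template numeric template vector (dB). Pass the effective
#'   template (zero-mean shape plus relative gain) for a physical cell.
#' @param a_db echo strength (dB).
#' @param cov a [build_covariance()] object.
#' @param n number of independent realizations. Default 1.
#' @param seed optional seed.
#' @return a length-`length(template)` vector (`n = 1`) or an
#'   `n x length(template)` matrix; every element is `>= 0`.
#' @export
simulate_measurement <- function(template, a_db, cov, n = 1, seed = NULL) {
  stopifnot(inherits(cov, "flutter_covariance"))
  m <- length(template)
  if (m != nrow(cov$matrix)) {
    stop_bad_arg("template length must match the covariance dimension")
  }
  cov <- covariance_chol(cov)
  draw <- function() matrix(rnorm(n * m), n, m) %*% cov$chol
  eps <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  b <- pmax(sweep(eps, 2, template + a_db, "+"), 0)
  if (n == 1) drop(b) else b
}

loglik_single <- function(b, template, a_db, cov,
                          method = c("floored_mean", "censored")) {
  method <- match.arg(method)
  cov <- covariance_chol(cov)
  m <- length(b)
  if (method == "floored_mean") {
    mu <- pmax(template + a_db, 0)
    d <- b - mu
    q <- drop(crossprod(d, cov$inv %*% d))
    -0.5 * (q + m * log(2 * pi) + cov$log_det)
  } else {
    # diagonal censored approximation: Gaussian mass below the floor for
    # floored elements, marginal densities elsewhere
    mu <- template + a_db
    s <- sqrt(diag(cov$matrix))
    floored <- b <= 0
    sum(ifelse(floored,
               pnorm(0, mean = mu, sd = s, log.p = TRUE),
               dnorm(b, mean = mu, sd = s, log = TRUE)))
  }
}

#' Likelihood of a measurement given direction and strength
#'
#' Multivariate normal density of the measurement about the floored mean
#' `max(template + a_db, 0)`, with the flutter covariance. The number of
#' template elements enters through the Gaussian normalizer. A censored
#' variant (`method = "censored"`) instead assigns floored elements the
#' Gaussian mass below the detection floor, using the marginal variances;
#' it serves sensitivity analysis of the flooring approximation.
#'
#' @inheritParams simulate_measurement
#' @param b measurement vector (dB, floored at 0).
#' @param method `"floored_mean"` (default) or `"censored"`.
#' @param log return the log density? Default `FALSE`.
#' @return the (log) density.
#' @export
likelihood <- function(b, template, a_db, cov,
                       method = c("floored_mean", "censored"), log = FALSE) {
  ll <- loglik_single(b, template, a_db, cov, method)
  if (log) ll else exp(ll)
}

#' Marginal likelihood over echo strength
#'
#' Averages [likelihood()] over the uniform strength grid of the prior with
#' trapezoid end weights, accumulating in log space.
#'
#' @inheritParams likelihood
#' @param prior a [strength_prior()].
#' @return the (log) marginal density.
#' @export
marginal_likelihood <- function(b, template, cov, prior = strength_prior(),
                                method = c("floored_mean", "censored"),
                                log = FALSE) {
  stopifnot(inherits(prior, "strength_prior"))
  ll <- vapply(prior$grid, function(a) {
    loglik_single(b, template, a, cov, method)
  }, numeric(1))
  lm <- log_sum_exp(ll + prior$log_w)
  if (log) lm else exp(lm)
}

#' Posterior over candidate directions
#'
#' Applies Bayes' rule with a uniform prior over the partition cells and
#' the strength-marginalized likelihood, in log space.
#'
#' @param b measurement vector.
#' @param ts a [build_templates()] template set.
#' @param cov a [build_covariance()] object.
#' @param prior a [strength_prior()].
#' @param method likelihood variant, see [likelihood()].
#' @return a tibble `(cell_id, azimuth_deg, elevation_deg, posterior)`
#'   summing to 1.
#' @export
posterior <- function(b, ts, cov, prior = strength_prior(),
                      method = c("floored_mean", "censored")) {
  stopifnot(inherits(ts, "template_set"))
  teff <- effective_templates(ts)
  lm <- vapply(seq_len(nrow(teff)), function(c) {
    marginal_likelihood(b, teff[c, ], cov, prior, method, log = TRUE)
  }, numeric(1))
  if (all(!is.finite(lm))) {
    abort("all log-likelihoods are -Inf; posterior undefined",
          class = "pinnasonar_degenerate_error")
  }
  lp <- lm - log_sum_exp(lm)
  dplyr::mutate(ts$partition[, c("cell_id", "azimuth_deg", "elevation_deg")],
                posterior = exp(lp))
}

#' Shannon entropy of a discrete distribution
#'
#' `-sum(p * log2(p))` with the `0 * log 0 = 0` convention. A uniform
#' posterior over 256 cells gives 8 bits (total ignorance); a point mass
#' gives 0 bits.
#'
#' @param p probability vector summing to 1.
#' @return entropy in bits.
#' @examples
#' shannon_entropy(rep(1 / 256, 256)) # 8
#' @export
shannon_entropy <- function(p) {
  if (any(p < -1e-12)) stop_bad_arg("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop_bad_arg("probabilities must sum to 1")
  p <- pmax(p, 0)
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

# --- batched posterior-entropy engine ---------------------------------------
# Precomputes, for one template set, the floored mean vectors over the joint
# (cell x strength-grid) lattice and the quadratic-form pieces, so posterior
# entropies for many echoes reduce to one BLAS product and one exp pass per
# chunk. Per-echo constants (the echo's own quadratic form and the Gaussian
# normalizer) cancel in the posterior and are dropped.
posterior_engine <- function(ts, cov, prior = strength_prior()) {
  cov <- covariance_chol(cov)
  teff <- effective_templates(ts)
  n_cells <- nrow(teff)
  m <- ncol(teff)
  grid <- prior$grid
  n_a <- length(grid)
  # rows ordered strength-fastest within cell: row = (c - 1) * n_a + a
  mu <- pmax(teff[rep(seq_len(n_cells), each = n_a), ] +
               rep(grid, times = n_cells), 0)
  p_mat <- mu %*% cov$inv
  list(mu_t = t(mu), half_m2 = 0.5 * rowSums(p_mat * mu),
       inv = cov$inv, n_cells = n_cells, n_a = n_a, m = m,
       w = exp(prior$log_w), chol = cov$chol, teff = teff)
}

# posterior entropies (bits) for echo rows `b_mat`; the heavy lattice loop
# lives in the C++ kernel
engine_entropies <- function(eng, b_mat, ...) {
  posterior_entropy_kernel(b_mat, eng$mu_t, eng$half_m2, eng$w, eng$inv)
}

#' Expected localization entropy at one position
#'
#' Monte Carlo average, over realizations of the flutter noise, of the
#' posterior entropy for echoes of strength `a_db` from one cell. Twenty
#' realizations per condition give stable averages.
#'
#' @param cell_id the true cell.
#' @param ts a `template_set`.
#' @param cov a `flutter_covariance`.
#' @param a_db echo strength (dB).
#' @param n_realizations Monte Carlo realizations. Default 20.
#' @param seed optional seed.
#' @param prior a [strength_prior()].
#' @return mean entropy in bits.
#' @export
expected_entropy <- function(cell_id, ts, cov, a_db, n_realizations = 20,
                             seed = NULL, prior = strength_prior()) {
  if (n_realizations < 1) stop_bad_arg("`n_realizations` must be >= 1")
  eng <- posterior_engine(ts, cov, prior)
  teff <- eng$teff[cell_id, ]
  b <- simulate_measurement(teff, a_db, cov, n = n_realizations, seed = seed)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  mean(engine_entropies(eng, b))
}

#' Expected-entropy map over position, frequency and echo strength
#'
#' The central product of the analysis: for every partition cell, frequency
#' and echo strength on the grid, the Monte Carlo expected entropy of the
#' localization posterior. Echo direction is informative where the entropy
#' falls below the chance level `log2(n_cells)`.
#'
#' @param template_sets list of `template_set`s (one per frequency).
#' @param cov a `flutter_covariance`.
#' @param snr_grid_db echo strengths to evaluate (dB). Default 0 to 50 in
#'   steps of 5.
#' @param n_realizations Monte Carlo realizations per condition. Default 20.
#' @param seed integer seed; the map is reproducible given the seed.
#' @param prior a [strength_prior()].
#' @return an `entropy_map` tibble `(cell_id, azimuth_deg, elevation_deg,
#'   frequency_khz, snr_db, entropy_bits)` with attributes `n_cells` and
#'   `n_realizations`.
#' @export
entropy_map <- function(template_sets, cov, snr_grid_db = seq(0, 50, by = 5),
                        n_realizations = 20, seed = NULL,
                        prior = strength_prior()) {
  if (inherits(template_sets, "template_set")) {
    template_sets <- list(template_sets)
  }
  if (length(snr_grid_db) == 0) stop_bad_arg("`snr_grid_db` is empty")
  run <- function() {
    purrr::map_dfr(template_sets, function(ts) {
      eng <- posterior_engine(ts, cov, prior)
      n_cells <- eng$n_cells
      purrr::map_dfr(snr_grid_db, function(a) {
        # all cells' echoes for this strength in one batch
        z <- matrix(rnorm(n_cells * n_realizations * eng$m),
                    n_cells * n_realizations, eng$m) %*% eng$chol
        mu <- eng$teff[rep(seq_len(n_cells), each = n_realizations), ] + a
        b <- pmax(mu + z, 0)
        h <- engine_entropies(eng, b)
        hbar <- colMeans(matrix(h, nrow = n_realizations))
        dplyr::mutate(
          ts$partition[, c("cell_id", "azimuth_deg", "elevation_deg")],
          frequency_khz = ts$frequency_khz, snr_db = a, entropy_bits = hbar)
      })
    })
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  attr(out, "n_cells") <- nrow(template_sets[[1]]$templates)
  attr(out, "n_realizations") <- n_realizations
  class(out) <- c("entropy_map", class(out))
  out
}

#' Summarize an entropy map over the hemisphere
#'
#' Per frequency and echo strength: the hemisphere-average expected entropy
#' (cells have equal solid angles, so the plain mean is the area-weighted
#' mean) and the worst-minus-best range across cells.
#'
#' @param em an [entropy_map()].
#' @return a tibble `(frequency_khz, snr_db, mean_entropy_bits,
#'   range_entropy_bits)`.
#' @export
entropy_summary <- function(em) {
  tibble::as_tibble(em) |>
    dplyr::group_by(.data$frequency_khz, .data$snr_db) |>
    dplyr::summarise(
      mean_entropy_bits = mean(.data$entropy_bits),
      range_entropy_bits = max(.data$entropy_bits) - min(.data$entropy_bits),
      .groups = "drop"
    )
}

#' Angular resolution implied by an entropy value
#'
#' Converts entropy to the solid angle of the equivalent set of
#' equiprobable cells: `(2 * pi / n_cells) * 2^H`. Chance-level entropy
#' maps to the whole hemisphere; zero entropy to a single cell.
#'
#' @param entropy_bits entropy value(s) in `[0, log2(n_cells)]`.
#' @param n_cells number of partition cells (or a `sphere_partition`).
#' @return solid angle(s) in steradians.
#' @examples
#' angular_resolution(8, 256) # 2 * pi
#' angular_resolution(0, 256) # one cell
#' @export
angular_resolution <- function(entropy_bits, n_cells) {
  if (inherits(n_cells, "sphere_partition")) n_cells <- nrow(n_cells)
  if (any(entropy_bits < 0 | entropy_bits > log2(n_cells) + 1e-9)) {
    stop_bad_arg("`entropy_bits` must lie in [0, log2(n_cells)]")
  }
  (2 * pi / n_cells) * 2^entropy_bits
}
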