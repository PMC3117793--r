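#' Structured flutter-noise covariance
#'
#' Covariance of the dB amplitude modulations a fluttering target imposes on
#' the binaural measurement vector. Three classes of entries fill the
#' matrix: the per-position variance `sigma^2` on the diagonal; within-ear
#' covariances decaying geometrically with the position (time) lag,
#' `sigma^2 * lag_corr^|i-j|`; and interaural covariances coupling the two
#' ears, `interaural_corr` times the corresponding within-ear entry (so
#' simultaneous left/right measurements have covariance
#' `interaural_corr * sigma^2`). The vector ordering is left-ear positions
#' `1..n` then right-ear positions `1..n`.
#'
#' @param sigma_db per-position standard deviation (dB). Default 5 (the
#'   medium noise level; 2.5 and 7.5 bracket it as low/high).
#' @param lag_corr within-ear lag-1 correlation in `[-1, 1]`. Default 0.2.
#' @param interaural_corr correlation between simultaneous left/right
#'   modulations in `[0, 1]`. Default 0.9 (the ears are close together
#'   relative to the target range).
#' @param n_positions ear positions per ear. Default 7.
#' @return a `flutter_covariance` with the `2 n_positions` square `matrix`
#'   and the generating parameters.
#' @examples
#' cov <- build_covariance(5, 0.2, 0.9, 7)
#' dim(cov$matrix) # 14 x 14
#' @export
build_covariance <- function(sigma_db = 5, lag_corr = 0.2,
                             interaural_corr = 0.9, n_positions = 7) {
  check_positive_scalar(sigma_db, "sigma_db")
  if (abs(lag_corr) > 1) stop_bad_arg("`lag_corr` must lie in [-1, 1]")
  if (interaural_corr < 0 || interaural_corr > 1) {
    stop_bad_arg("`interaural_corr` must lie in [0, 1]")
  }
  n <- as.integer(n_positions)
  if (n < 1) stop_bad_arg("`n_positions` must be >= 1")
  lags <- abs(outer(seq_len(n), seq_len(n), "-"))
  k <- sigma_db^2 * lag_corr^lags # lag_corr^0 = 1 covers the diagonal
  b <- matrix(c(1, interaural_corr, interaural_corr, 1), 2, 2)
  m <- kronecker(b, k)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev)) {
    abort(sprintf(
      "covariance parameters give a non-PSD matrix (smallest eigenvalue %.3g)",
      min(ev)), class = "pinnasonar_psd_error")
  }
  structure(
    list(sigma_db = sigma_db, lag_corr = lag_corr,
         interaural_corr = interaural_corr, n_positions = n, matrix = m),
    class = "flutter_covariance"
  )
}

# cache the Cholesky pieces the likelihood needs
covariance_chol <- function(cov) {
  if (!is.null(cov$chol)) return(cov)
  r <- tryCatch(chol(cov$matrix), error = function(e) {
    abort("flutter covariance is singular", class = "pinnasonar_psd_error")
  })
  cov$chol <- r
  cov$inv <- chol2inv(r)
  cov$log_det <- 2 * sum(log(diag(r)))
  cov
}

#' Simulate echoes from a fluttering target
#'
#' Synthetic stand-in for ensonifying a fluttering insect with a train of
#' calls: `n` short tone bursts whose log-amplitudes (dB) follow a
#' stationary AR(1) Gaussian sequence with standard deviation `sigma_db`
#' and lag-1 correlation `lag_corr`.
#'
#' @param n number of echoes (>= 2).
#' @param sigma_db log-amplitude standard deviation (dB).
#' @param lag_corr lag-1 correlation of consecutive echo amplitudes.
#' @param carrier_khz burst carrier frequency (kHz).
#' @param sampling_rate_khz sampling rate (kHz); must exceed twice the
#'   carrier.
#' @param duration_ms burst duration (ms). Default 1.5.
#' @param aspect aspect angle label carried as metadata (azimuth, elevation
#'   in degrees). Default `c(0, 0)`.
#' @param seed optional integer seed for reproducibility.
#' @return an `echo_ensemble`: list with `traces` (n x samples matrix),
#'   `gain_db` (the generating dB gains), `sampling_rate_khz`,
#'   `carrier_khz`, `aspect`.
#' @export
simulate_flutter_echoes <- function(n, sigma_db = 5, lag_corr = 0.2,
                                    carrier_khz = 40,
                                    sampling_rate_khz = 400,
                                    duration_ms = 1.5, aspect = c(0, 0),
                                    seed = NULL) {
  if (n < 2) stop_bad_arg("`n` must be >= 2")
  if (sampling_rate_khz <= 2 * carrier_khz) {
    stop_bad_arg("sampling rate must exceed twice the carrier (Nyquist)")
  }
  if (sigma_db < 0 || abs(lag_corr) >= 1) {
    stop_bad_arg("need `sigma_db` >= 0 and |lag_corr| < 1")
  }
  draw <- function() {
    g <- numeric(n)
    g[1] <- rnorm(1) * sigma_db
    if (n > 1) {
      innov <- rnorm(n - 1) * sigma_db * sqrt(1 - lag_corr^2)
      for (t in 2:n) g[t] <- lag_corr * g[t - 1] + innov[t - 1]
    }
    g
  }
  g <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  len <- max(2L, round(duration_ms / 1000 * sampling_rate_khz * 1000))
  tt <- (seq_len(len) - 1) / (sampling_rate_khz * 1000)
  carrier <- sin(2 * pi * carrier_khz * 1000 * tt)
  traces <- 10^(g / 20) %o% carrier
  structure(
    list(traces = traces, gain_db = g,
         sampling_rate_khz = sampling_rate_khz, carrier_khz = carrier_khz,
         aspect = aspect),
    class = "echo_ensemble"
  )
}

#' Single-bin spectral power by the Goertzel recursion
#'
#' Evaluates the squared magnitude of the discrete Fourier bin nearest the
#' target frequency using the Goertzel second-order recursion
#' `s[t] = x[t] + 2 cos(w) s[t-1] - s[t-2]`, run at C speed through a
#' recursive filter. Equivalent to `|fft(x)[k]|^2` at the selected bin.
#'
#' @param trace numeric sample vector (length >= 2).
#' @param target_khz analysis frequency (kHz); must be below Nyquist.
#' @param sampling_rate_khz sampling rate (kHz).
#' @return the spectral power at the nearest DFT bin.
#' @export
goertzel_power <- function(trace, target_khz, sampling_rate_khz) {
  len <- length(trace)
  if (len < 2) stop_bad_arg("`trace` must hold at least 2 samples")
  if (target_khz >= sampling_rate_khz / 2) {
    stop_bad_arg("`target_khz` must be below the Nyquist frequency")
  }
  k <- round(target_khz / sampling_rate_khz * len)
  w <- 2 * pi * k / len
  coeff <- 2 * cos(w)
  s <- stats::filter(trace, c(coeff, -1), method = "recursive")
  s1 <- s[len]
  s2 <- s[len - 1]
  s1^2 + s2^2 - coeff * s1 * s2
}

ensemble_gains_db <- function(ensemble, frequency_khz) {
  stopifnot(inherits(ensemble, "echo_ensemble"))
  p <- apply(ensemble$traces, 1, goertzel_power,
             target_khz = frequency_khz,
             sampling_rate_khz = ensemble$sampling_rate_khz)
  10 * log10(pmax(p, .Machine$double.xmin))
}

#' Estimate the flutter amplitude spread from an echo ensemble
#'
#' Standard deviation of the per-echo dB gains at the stated frequency,
#' extracted with [goertzel_power()]. Recovers the `sigma_db` of
#' [simulate_flutter_echoes()].
#'
#' @param ensemble an `echo_ensemble`.
#' @param frequency_khz analysis frequency (kHz).
#' @return standard deviation in dB.
#' @export
estimate_sigma <- function(ensemble, frequency_khz) {
  sd(ensemble_gains_db(ensemble, frequency_khz))
}

#' Estimate lag correlations of flutter modulations
#'
#' Pearson correlation between the dB-gain sequence and its lagged copy for
#' lags `1..max_lag`. A constant ensemble has no defined correlation and
#' yields `NA` with a warning.
#'
#' @param ensemble an `echo_ensemble`.
#' @param frequency_khz analysis frequency (kHz).
#' @param max_lag largest lag (calls) to report. Default 5.
#' @return a tibble `(lag, correlation)`.
#' @export
estimate_lag_correlation <- function(ensemble, frequency_khz, max_lag = 5) {
  g <- ensemble_gains_db(ensemble, frequency_khz)
  n <- length(g)
  if (n <= max_lag + 1) stop_bad_arg("need more echoes than `max_lag` + 1")
  if (sd(g) < 1e-12) {
    warn("constant ensemble: lag correlations are undefined")
    return(tibble::tibble(lag = seq_len(max_lag), correlation = NA_real_))
  }
  r <- vapply(seq_len(max_lag), function(l) {
    cor(g[seq_len(n - l)], g[seq_len(n - l) + l])
  }, numeric(1))
  tibble::tibble(lag = seq_len(max_lag), correlation = r)
}
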