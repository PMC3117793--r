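# internal numerics shared across modules

DEG <- pi / 180

#' Convert azimuth/elevation directions to unit vectors
#'
#' The package convention: azimuth is the horizontal angle (degrees, positive
#' to the bat's right), elevation the vertical angle (degrees, positive up);
#' `(0, 0)` is straight ahead. The frontal hemisphere is the set of
#' directions whose forward component is non-negative.
#'
#' @param azimuth_deg,elevation_deg numeric vectors of equal length.
#' @return a numeric matrix with one row per direction and columns
#'   `x` (forward), `y` (right), `z` (up).
#' @examples
#' direction_vector(0, 0)    # straight ahead
#' direction_vector(90, 0)   # hard right
#' @export
direction_vector <- function(azimuth_deg, elevation_deg) {
  n <- max(length(azimuth_deg), length(elevation_deg))
  az <- rep_len(azimuth_deg, n) * DEG
  el <- rep_len(elevation_deg, n) * DEG
  cbind(x = cos(el) * cos(az), y = cos(el) * sin(az), z = sin(el))
}

# inverse of direction_vector(); rows of `v` need not be normalized
vector_direction <- function(v) {
  v <- v / sqrt(rowSums(v^2))
  tibble::tibble(
    azimuth_deg   = atan2(v[, 2], v[, 1]) / DEG,
    elevation_deg = asin(pmin(1, pmax(-1, v[, 3]))) / DEG
  )
}

# column maxima of a matrix without apply() overhead; ties broken
# deterministically
col_maxs <- function(m) {
  idx <- max.col(t(m), ties.method = "first")
  m[cbind(idx, seq_len(ncol(m)))]
}

# log(sum(exp(x))) guarded against -Inf-only input
log_sum_exp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

# columnwise log-sum-exp of a matrix
col_log_sum_exp <- function(m) {
  mx <- col_maxs(m)
  finite <- is.finite(mx)
  out <- mx
  if (any(finite)) {
    sw <- exp(sweep(m[, finite, drop = FALSE], 2, mx[finite], "-"))
    out[finite] <- mx[finite] + log(colSums(sw))
  }
  out
}

stop_bad_arg <- function(msg) abort(msg, class = "pinnasonar_arg_error")

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_bad_arg(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}
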