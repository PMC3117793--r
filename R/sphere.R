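#' Partition the frontal hemisphere into equal-area directional cells
#'
#' Discretizes the frontal hemisphere (all directions within 90 degrees of
#' straight ahead) into `n_cells` cells of exactly equal solid angle using a
#' recursive zonal equal-area layout: a polar cap centred on the forward
#' axis, followed by collars of equal-area cells whose boundaries are placed
#' so that every cell covers `2 * pi / n_cells` steradians. The cells are the
#' discrete hypothesis space of candidate echo directions: with the default
#' 256 cells the chance-level entropy of a localization posterior is
#' `log2(256) = 8` bits.
#'
#' @param n_cells number of cells (positive integer). Default 256.
#' @return a `sphere_partition`: a tibble with columns `cell_id`,
#'   `azimuth_deg`, `elevation_deg` (cell centres) and `solid_angle_sr`
#'   (identical for all cells), plus an `n_cells` attribute.
#' @examples
#' p <- partition_hemisphere(256)
#' sum(p$solid_angle_sr) # 2 * pi
#' @export
partition_hemisphere <- function(n_cells = 256) {
  if (!is.numeric(n_cells) || length(n_cells) != 1L || !is.finite(n_cells) ||
      n_cells < 1 || n_cells != round(n_cells)) {
    stop_bad_arg("`n_cells` must be a single positive integer")
  }
  n_cells <- as.integer(n_cells)
  area <- 2 * pi / n_cells

  if (n_cells == 1L) {
    theta <- 0
    phi <- 0
  } else {
    # polar cap holding one cell: 2*pi*(1 - cos(theta_cap)) = area
    theta_cap <- acos(1 - 1 / n_cells)
    # ideal collar height ~ sqrt(cell area); round to an integer collar count
    n_collars <- max(1L, round((pi / 2 - theta_cap) / sqrt(area)))
    fitting <- (pi / 2 - theta_cap) / n_collars
    ideal <- vapply(seq_len(n_collars), function(j) {
      2 * pi * (cos(theta_cap + (j - 1) * fitting) -
                  cos(theta_cap + j * fitting)) / area
    }, numeric(1))
    # round cell counts per collar while conserving the running total
    m <- integer(n_collars)
    carry <- 0
    for (j in seq_len(n_collars)) {
      m[j] <- max(0L, as.integer(round(ideal[j] + carry)))
      carry <- carry + ideal[j] - m[j]
    }
    m[n_collars] <- m[n_collars] + (n_cells - 1L - sum(m))
    keep <- m > 0L
    m <- m[keep]
    # re-place collar boundaries so each collar's area is exactly m_j * area
    cos_bounds <- cos(theta_cap) - cumsum(m) * area / (2 * pi)
    cos_top <- c(cos(theta_cap), head(cos_bounds, -1))
    cos_mid <- (cos_top + cos_bounds) / 2 # area midpoint of each collar
    theta_mid <- acos(pmin(1, pmax(0, cos_mid)))
    theta <- c(0, rep(theta_mid, m))
    # equal azimuthal sectors per collar, staggered between collars
    phi <- c(0, unlist(lapply(seq_along(m), function(j) {
      2 * pi * (seq_len(m[j]) - 0.5) / m[j] + (j %% 2) * pi / m[j]
    })))
  }

  # polar angle theta measured from the forward axis; phi winds around it
  v <- cbind(cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
  dirs <- vector_direction(v)
  out <- tibble::tibble(
    cell_id = seq_len(n_cells),
    azimuth_deg = dirs$azimuth_deg,
    elevation_deg = dirs$elevation_deg,
    solid_angle_sr = area
  )
  attr(out, "n_cells") <- n_cells
  class(out) <- c("sphere_partition", class(out))
  out
}

#' Great-circle angle between directions
#'
#' @param az1,el1,az2,el2 directions in degrees (vectorized).
#' @return angle(s) in degrees in `[0, 180]`.
#' @examples
#' angular_distance(0, 0, 90, 0)   # 90
#' angular_distance(45, 0, -45, 0) # 90
#' @export
angular_distance <- function(az1, el1, az2, el2) {
  a <- direction_vector(az1, el1)
  b <- direction_vector(az2, el2)
  n <- max(nrow(a), nrow(b))
  a <- a[rep_len(seq_len(nrow(a)), n), , drop = FALSE]
  b <- b[rep_len(seq_len(nrow(b)), n), , drop = FALSE]
  acos(pmin(1, pmax(-1, rowSums(a * b)))) / DEG
}

# unit-vector matrix of the partition's cell centres (memoised per call site)
partition_vectors <- function(partition) {
  direction_vector(partition$azimuth_deg, partition$elevation_deg)
}

same_partition <- function(a, b, tol = 1e-9) {
  nrow(a) == nrow(b) &&
    max(abs(a$azimuth_deg - b$azimuth_deg)) < tol &&
    max(abs(a$elevation_deg - b$elevation_deg)) < tol
}

# rotation taking the forward axis to (daz, del): intrinsic azimuth-then-
# elevation. Columns act on unit-vector rows via v %*% t(R).
rotation_matrix <- function(daz_deg, del_deg) {
  a <- daz_deg * DEG
  b <- del_deg * DEG
  rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3)
  ry %*% rz
}

#' Rigidly rotate a directional field
#'
#' Models an ear movement as a rigid rotation of the hearing directionality:
#' the returned field, sampled at direction `d`, equals the input field at
#' the back-rotated direction. Rotations are intrinsic azimuth-then-elevation.
#' Directions whose back-rotation leaves the frontal hemisphere take the
#' field's gain floor.
#'
#' @param field a `directional_field` (see [directional_field()]).
#' @param daz_deg,del_deg rotation in degrees (positive azimuth rotates the
#'   field to the right, positive elevation up).
#' @param method `"nearest"` (default; nearest-cell lookup, deterministic) or
#'   `"idw"` (inverse-distance weights over the 3 nearest cell centres).
#' @return a `directional_field` on the same partition.
#' @examples
#' p <- partition_hemisphere(64)
#' f <- parametric_beam(10, 60, axis_az_deg = 0, axis_el_deg = 0,
#'                      gain_cap_db = 12, partition = p)
#' g <- rotate_field(f, 10, 0) # peak now near azimuth 10
#' @export
rotate_field <- function(field, daz_deg, del_deg, method = c("nearest", "idw")) {
  method <- match.arg(method)
  stopifnot(inherits(field, "directional_field"))
  floor_db <- attr(field, "floor_db")
  v <- partition_vectors(field)
  # back-rotate each centre and look the source value up in the input field
  rinv <- t(rotation_matrix(daz_deg, del_deg)) # orthonormal inverse
  vb <- v %*% t(rinv)
  outside <- vb[, 1] < 0
  dots <- vb %*% t(v) # cosine similarity back-rotated centres x cells
  gain <- field$gain_db
  if (method == "nearest") {
    idx <- max.col(dots, ties.method = "first")
    new_gain <- gain[idx]
  } else {
    new_gain <- vapply(seq_len(nrow(dots)), function(i) {
      ord <- order(dots[i, ], decreasing = TRUE)[1:3]
      ang <- acos(pmin(1, pmax(-1, dots[i, ord])))
      if (ang[1] < 1e-12) return(gain[ord[1]])
      w <- 1 / ang
      sum(w * gain[ord]) / sum(w)
    }, numeric(1))
  }
  new_gain[outside] <- floor_db
  out <- field
  out$gain_db <- new_gain
  out
}
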