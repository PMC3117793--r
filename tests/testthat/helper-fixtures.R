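# shared fixtures, built in code; small enough to rebuild per file

small_head <- function(n_cells = 64, frequency_khz = 60,
                       variant = "focused") {
  partition <- partition_hemisphere(n_cells)
  cfg <- synthetic_head(variant)
  fields <- head_fields(cfg, frequency_khz, partition)
  ts <- build_templates(fields$emission, fields$hearing_left,
                        fields$hearing_right)
  list(partition = partition, cfg = cfg, fields = fields, ts = ts)
}

# constant-gain field whose rotations stay constant (floor = the constant)
flat_field <- function(partition, gain_db = 0, role = "hearing_left",
                       frequency_khz = 60) {
  directional_field(partition, rep(gain_db, nrow(partition)), frequency_khz,
                    role = role, floor_db = gain_db)
}

# hand-built template set around an explicit template matrix
manual_template_set <- function(templates, rel_gain_db = NULL,
                                frequency_khz = 60) {
  n <- nrow(templates)
  partition <- partition_hemisphere(n)
  if (is.null(rel_gain_db)) rel_gain_db <- rep(0, n)
  structure(
    list(templates = templates, rel_gain_db = rel_gain_db,
         max_raw_gain_db = 0,
         partition = tibble::as_tibble(partition)[, c(
           "cell_id", "azimuth_deg", "elevation_deg", "solid_angle_sr")],
         frequency_khz = frequency_khz,
         protocol = ear_sweep_protocol()),
    class = "template_set"
  )
}

# nearest-neighbour distances between partition cell centres (degrees)
nn_distances_deg <- function(partition) {
  v <- direction_vector(partition$azimuth_deg, partition$elevation_deg)
  dots <- tcrossprod(v)
  dots <- pmax(pmin(dots, 1), -1)
  d <- acos(dots) * 180 / pi
  diag(d) <- Inf
  apply(d, 1, min)
}
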