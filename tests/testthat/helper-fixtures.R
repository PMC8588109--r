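# Small builders used across test files.

# Atom table (single frame) from raw vectors.
atoms_tbl <- function(x, y, z, mass = 1, charge = 0, element = "C",
                      atom_id = seq_along(x)) {
  tibble::tibble(atom_id = atom_id, x = x, y = y, z = z,
                 mass = rep_len(mass, length(x)),
                 charge = rep_len(charge, length(x)),
                 element = rep_len(element, length(x)))
}

# Single- or multi-frame trajectory from a list of n x 3 coordinate matrices.
traj_from_coords <- function(coords_list, topology = NULL, box_edge = NA,
                             frame_interval = 1, selections = list()) {
  if (is.matrix(coords_list)) coords_list <- list(coords_list)
  n <- nrow(coords_list[[1]])
  frames <- purrr::map2_dfr(coords_list, seq_along(coords_list), function(m, k) {
    tibble::tibble(frame = k, time = (k - 1) * frame_interval,
                   atom_id = seq_len(n), x = m[, 1], y = m[, 2], z = m[, 3])
  })
  new_trajectory(frames, topology, box_edge = box_edge,
                 frame_interval = frame_interval, selections = selections)
}

# Random rigid motion applied to an n x 3 coordinate matrix.
rigid_motion <- function(m, seed = 1) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  sweep(m %*% t(R), 2, runif(3, -5, 5), "+")
}

# Analytic linear charge density profile of a uniformly charged ball.
uniform_ball_qprofile <- function(Q, R, D, bw) {
  r_lo <- seq(0, D - bw + 1e-12, by = bw)
  r_hi <- r_lo + bw
  frac <- pmin(r_hi, R)^3 - pmin(r_lo, R)^3
  dendritrace:::new_profile(r_lo, r_hi, Q * frac / R^3 / bw, "charge_linear", bw)
}
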