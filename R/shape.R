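#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of a set of atoms from their
#' centre of mass:
#' \deqn{R_g = \left(\frac{1}{M}\sum_i m_i r_i^2\right)^{1/2}}
#' with \eqn{r_i} the distance of atom \eqn{i} from the centre of mass.
#'
#' @param atoms A data frame with columns `x`, `y`, `z` and optionally
#'   `mass` (defaults to equal masses).
#' @return Radius of gyration, nm.
#' @export
radius_of_gyration <- function(atoms) {
  com <- center_of_mass(atoms)
  m <- if ("mass" %in% names(atoms)) atoms$mass else rep(1, nrow(atoms))
  r2 <- (atoms$x - com[1])^2 + (atoms$y - com[2])^2 + (atoms$z - com[3])^2
  sqrt(sum(m * r2) / sum(m))
}

#' Asphericity (relative shape anisotropy)
#'
#' \deqn{\alpha = 1 - 3\,\frac{\lambda_x\lambda_y + \lambda_x\lambda_z +
#'   \lambda_y\lambda_z}{(\lambda_x+\lambda_y+\lambda_z)^2}}
#' where \eqn{\lambda_{x,y,z}} are the eigenvalues of the **mass-weighted
#' gyration tensor** \eqn{S = \frac{1}{M}\sum_i m_i\,\Delta r_i \Delta
#' r_i^T}. With gyration-tensor eigenvalues the stated limits hold exactly:
#' 0 for an ideal sphere, 1 for an infinitely elongated rod, and 0.25 for a
#' flat disc. (With true moment-of-inertia eigenvalues a rod would give
#' 0.25 instead of 1, so this implementation deliberately uses the gyration
#' tensor.) The result is clipped to `[0, 1]` against round-off.
#'
#' @inheritParams radius_of_gyration
#' @return Dimensionless asphericity in `[0, 1]`.
#' @export
asphericity <- function(atoms) {
  if (nrow(atoms) < 2) abort("asphericity needs at least 2 distinct atoms")
  com <- center_of_mass(atoms)
  m <- if ("mass" %in% names(atoms)) atoms$mass else rep(1, nrow(atoms))
  d <- cbind(atoms$x - com[1], atoms$y - com[2], atoms$z - com[3])
  if (all(rowSums(d^2) < 1e-24)) abort("all atoms coincide; shape undefined")
  S <- crossprod(d * sqrt(m / sum(m)))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  a <- 1 - 3 * (ev[1] * ev[2] + ev[1] * ev[3] + ev[2] * ev[3]) / sum(ev)^2
  min(max(a, 0), 1)
}

#' Kirkwood hydrodynamic radius
#'
#' Reciprocal of the mean reciprocal distance over all unordered atom pairs:
#' \deqn{R_h^{-1} = \langle r_{ij}^{-1} \rangle_{i \ne j}.}
#' Conventionally evaluated over heavy atoms only; pass a pre-filtered
#' table (e.g. `atoms[atoms$element != "H", ]`) or let [shape_summary()]
#' do the filtering. Pairs are accumulated in blocks so large selections
#' do not materialise the full distance matrix.
#'
#' @inheritParams radius_of_gyration
#' @param block Number of atoms per block in the pairwise accumulation.
#' @return Hydrodynamic radius, nm.
#' @export
kirkwood_rh <- function(atoms, block = 512) {
  n <- nrow(atoms)
  if (n < 2) abort("kirkwood_rh needs at least 2 atoms")
  xyz <- coords_matrix(atoms)
  s <- 0
  for (i0 in seq(1, n, by = block)) {
    i1 <- min(i0 + block - 1, n)
    d2 <- cross_dist2(xyz[i0:i1, , drop = FALSE], xyz)
    ## zero out self and lower-triangle duplicates: keep j > i only
    for (r in seq_len(i1 - i0 + 1)) {
      d2[r, seq_len(i0 + r - 1)] <- NA
    }
    d2v <- d2[!is.na(d2)]
    if (any(d2v == 0)) abort("coincident atom pair: 1/r diverges")
    s <- s + sum(1 / sqrt(d2v))
  }
  n_pairs <- n * (n - 1) / 2
  1 / (s / n_pairs)
}

#' RMS radial position of terminal groups
#'
#' Root-mean-square distance of the terminal-group nitrogen atoms from a
#' reference centre (normally the dendrimer centre of mass):
#' \deqn{R_e = \left(\frac{1}{N_t}\sum_i r_i^2\right)^{1/2}.}
#'
#' @param atoms Data frame of terminal atoms (`x`, `y`, `z`).
#' @param center Length-3 centre, nm; defaults to the origin.
#' @return `Re`, nm.
#' @export
terminal_radius <- function(atoms, center = c(0, 0, 0)) {
  if (nrow(atoms) == 0) abort("terminal selection is empty")
  r2 <- (atoms$x - center[1])^2 + (atoms$y - center[2])^2 + (atoms$z - center[3])^2
  sqrt(mean(r2))
}

#' Dense-sphere outer boundary
#'
#' Under the dense-sphere model the outer boundary of a uniform-density
#' molecule of gyration radius `Rg` lies at `sqrt(5/3) * Rg` (the radius
#' R of a uniform ball whose Rg equals the given value).
#'
#' @param Rg Radius of gyration, nm (>= 0).
#' @return Boundary radius, nm.
#' @export
dense_sphere_boundary <- function(Rg) {
  if (any(Rg < 0)) abort("Rg must be >= 0")
  sqrt(5 / 3) * Rg
}

#' Spacer length distribution
#'
#' Normalised histogram of the Euclidean distance between consecutive
#' branching points, pooled over all frames and all listed pairs.
#'
#' @param traj A `dendri_trajectory`.
#' @param branch_pairs List of 2-vectors of branch-point atom ids; defaults
#'   to `traj$selections$branch_pairs`.
#' @param bin_width Histogram bin width, nm.
#' @return A tibble (`d_lo`, `d_hi`, `d`, `density`) with
#'   `sum(density * bin_width) == 1`; class `spacer_histogram`.
#' @export
spacer_length_distribution <- function(traj, branch_pairs = NULL,
                                       bin_width = 0.02) {
  branch_pairs <- branch_pairs %||% traj$selections$branch_pairs
  if (is.null(branch_pairs) || length(branch_pairs) == 0) {
    abort("no branch-point pairs given")
  }
  ds <- c()
  for (k in frame_index(traj)) {
    fr <- frame_atoms(traj, k)
    for (p in branch_pairs) {
      a <- fr[match(p[1], fr$atom_id), ]
      b <- fr[match(p[2], fr$atom_id), ]
      if (anyNA(a$x) || anyNA(b$x)) abort("branch pair references missing atom")
      ds <- c(ds, sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2))
    }
  }
  edges <- seq(0, max(ds) + bin_width, by = bin_width)
  h <- graph_hist(ds, edges)
  out <- tibble(d_lo = edges[-length(edges)], d_hi = edges[-1],
                d = (edges[-1] + edges[-length(edges)]) / 2,
                density = h / (sum(h) * bin_width))
  class(out) <- c("spacer_histogram", class(out))
  out
}

graph_hist <- function(x, edges) {
  idx <- findInterval(x, edges, rightmost.closed = TRUE, left.open = FALSE)
  idx[idx == length(edges)] <- length(edges) - 1  # right edge inclusive
  tabulate(idx, nbins = length(edges) - 1)
}

#' Per-frame and averaged shape descriptors
#'
#' Computes, for every frame, the dendrimer radius of gyration, asphericity,
#' Kirkwood hydrodynamic radius (heavy atoms), terminal-group radius and the
#' dense-sphere boundary `sqrt(5/3) * Rg`. `tidy()` returns the per-frame
#' table; `glance()` the trajectory means plus the `Rh/Rg` ratio.
#'
#' @param traj A `dendri_trajectory` with roles attached.
#' @param selection Which atoms form the molecule (default the dendrimer
#'   selection, i.e. all-atom mass weighting).
#' @param heavy_only_rh Use only heavy atoms (element != `"H"`) for the
#'   Kirkwood sum.
#' @return An object of class `shape_summary`.
#' @export
shape_summary <- function(traj, selection = "dendrimer", heavy_only_rh = TRUE) {
  ids <- selection_ids(traj, selection)
  term_ids <- selection_ids(traj, "terminals")
  heavy_ids <- intersect(ids, selection_ids(traj, "heavy"))
  rows <- purrr::map_dfr(frame_index(traj), function(k) {
    fr <- frame_atoms(traj, k)
    sel <- fr[fr$atom_id %in% ids, ]
    com <- center_of_mass(sel)
    rh_sel <- if (heavy_only_rh) fr[fr$atom_id %in% heavy_ids, ] else sel
    tibble(
      frame = k, time = fr$time[1],
      Rg = radius_of_gyration(sel),
      alpha = asphericity(sel),
      Rh = if (nrow(rh_sel) >= 2) kirkwood_rh(rh_sel) else NA_real_,
      Re = if (length(term_ids) > 0)
        terminal_radius(fr[fr$atom_id %in% term_ids, ], com) else NA_real_
    )
  })
  rows$boundary <- dense_sphere_boundary(rows$Rg)
  structure(list(per_frame = rows), class = "shape_summary")
}

#' @export
print.shape_summary <- function(x, ...) {
  cat("<shape_summary>", nrow(x$per_frame), "frames\n")
  print(glance(x))
  invisible(x)
}

#' @rdname shape_summary
#' @param x A `shape_summary`.
#' @param ... Unused.
#' @export
tidy.shape_summary <- function(x, ...) x$per_frame

#' @rdname shape_summary
#' @export
glance.shape_summary <- function(x, ...) {
  pf <- x$per_frame
  tibble(
    Rg = mean(pf$Rg), alpha = mean(pf$alpha), Rh = mean(pf$Rh),
    ratio_Rh_Rg = mean(pf$Rh) / mean(pf$Rg),
    boundary = dense_sphere_boundary(mean(pf$Rg)),
    Re = mean(pf$Re), n_frames = nrow(pf)
  )
}

#' @export
autoplot.shape_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_frame, c("Rg", "alpha", "Rh", "Re"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "time (ps)", y = NULL)
}
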