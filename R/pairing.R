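#' Unit normal of a planar three-atom group
#'
#' The plane through three atoms has coefficients (A, B, C) equal to the
#' cross product of two edge vectors; the unit normal is returned with
#' arbitrary sign (a plane has no preferred side).
#'
#' @param atoms Atom table containing the triple.
#' @param triple Atom ids of the three plane-defining atoms.
#' @param area_tol Minimum triangle area, nm^2, below which the triple is
#'   rejected as collinear.
#' @return Unit length-3 vector.
#' @export
plane_normal <- function(atoms, triple, area_tol = 1e-6) {
  p <- as.matrix(atoms[match(triple, atoms$atom_id), c("x", "y", "z")])
  if (anyNA(p)) abort("triple references atoms missing from the frame")
  v <- cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])
  area <- 0.5 * sqrt(sum(v^2))
  if (area <= area_tol) {
    abort(sprintf("collinear triple (area %.2g nm^2 <= %.2g)", area, area_tol))
  }
  unit3(v)
}

#' Centre distance and inter-plane angle of two planar groups
#'
#' The distance r is between the group centres (centroids of each group's
#' `center_atoms`); the angle is
#' \eqn{\theta = \arccos|\hat n_1 \cdot \hat n_2|}, folded to `[0, 90]`
#' degrees because each normal's sign is arbitrary.
#'
#' @param atoms Atom table for one frame.
#' @param g1,g2 Lists (or one-row tibbles) with elements `triple` and
#'   `center_atoms`.
#' @return A tibble with columns `r` (nm) and `theta` (degrees).
#' @export
pair_geometry <- function(atoms, g1, g2) {
  grab <- function(g, field) {
    v <- g[[field]]
    if (is.list(v)) v <- v[[1]]
    as.integer(v)
  }
  cen <- function(ids) {
    p <- atoms[match(ids, atoms$atom_id), c("x", "y", "z")]
    if (anyNA(p$x)) abort("center_atoms reference atoms missing from the frame")
    colMeans(as.matrix(p))
  }
  n1 <- plane_normal(atoms, grab(g1, "triple"))
  n2 <- plane_normal(atoms, grab(g2, "triple"))
  c1 <- cen(grab(g1, "center_atoms"))
  c2 <- cen(grab(g2, "center_atoms"))
  tibble(r = sqrt(sum((c1 - c2)^2)),
         theta = rad2deg(acos(pmin(abs(sum(n1 * n2)), 1))))
}

## Per-frame geometry of all groups: centres (n x 3) and unit normals (n x 3).
group_frame_geometry <- function(atoms, groups) {
  n <- nrow(groups)
  centers <- matrix(0, n, 3)
  normals <- matrix(0, n, 3)
  for (j in seq_len(n)) {
    normals[j, ] <- plane_normal(atoms, groups$triple[[j]])
    ca <- groups$center_atoms[[j]]
    centers[j, ] <- colMeans(as.matrix(atoms[match(ca, atoms$atom_id),
                                             c("x", "y", "z")]))
  }
  list(centers = centers, normals = normals)
}

## Geometry of all unordered group pairs of one class in one frame.
frame_pair_geometries <- function(atoms, groups, class, r_cutoff = Inf) {
  geo <- group_frame_geometry(atoms, groups)
  n <- nrow(groups)
  if (n < 2) return(tibble(i = integer(), j = integer(), r = numeric(),
                           theta = numeric()))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- groups$spacer_id[idx[, 1]] == groups$spacer_id[idx[, 2]]
  keep <- if (class == "neighboring") same else !same
  idx <- idx[keep, , drop = FALSE]
  if (nrow(idx) == 0) return(tibble(i = integer(), j = integer(), r = numeric(),
                                    theta = numeric()))
  dvec <- geo$centers[idx[, 1], , drop = FALSE] - geo$centers[idx[, 2], , drop = FALSE]
  r <- sqrt(rowSums(dvec^2))
  cosang <- abs(rowSums(geo$normals[idx[, 1], , drop = FALSE] *
                          geo$normals[idx[, 2], , drop = FALSE]))
  th <- rad2deg(acos(pmin(cosang, 1)))
  ok <- r < r_cutoff
  tibble(i = groups$group_id[idx[ok, 1]], j = groups$group_id[idx[ok, 2]],
         r = r[ok], theta = th[ok])
}

#' Distance-angle pair matrix of planar groups
#'
#' Accumulates, per frame, every unordered pair of planar groups of the
#' requested class — `"neighboring"` (same `spacer_id`) or
#' `"non_neighboring"` (different) — with centre distance below `r_cutoff`
#' into a 2D histogram over (inter-plane angle, distance), then averages
#' over frames, giving mean pairs per frame per bin.
#'
#' @param traj A `dendri_trajectory` with `planar_groups` attached.
#' @param class `"neighboring"` or `"non_neighboring"`.
#' @param r_cutoff Distance cut-off, nm (default 1.8; neighbouring groups
#'   cannot exceed this by topology, and more distant pairs are not
#'   analysed).
#' @param theta_bin Angle bin width, degrees (grid spans 0-90).
#' @param r_bin Distance bin width, nm.
#' @return A long tibble (`theta_lo`, `theta_hi`, `theta`, `r_lo`, `r_hi`,
#'   `r`, `count`) of class `pair_matrix`.
#' @export
pair_matrix <- function(traj, class = c("non_neighboring", "neighboring"),
                        r_cutoff = 1.8, theta_bin = 2, r_bin = 0.05) {
  class <- match.arg(class)
  groups <- traj$selections$planar_groups
  if (is.null(groups) || nrow(groups) < 2) {
    abort("trajectory needs at least two planar groups")
  }
  th_edges <- seq(0, 90, by = theta_bin)
  if (th_edges[length(th_edges)] < 90) th_edges <- c(th_edges, 90)
  r_edges <- seq(0, r_cutoff, by = r_bin)
  if (r_edges[length(r_edges)] < r_cutoff) r_edges <- c(r_edges, r_cutoff)
  nth <- length(th_edges) - 1; nr <- length(r_edges) - 1
  acc <- matrix(0, nth, nr)
  frames <- frame_index(traj)
  any_pairs <- FALSE
  for (k in frames) {
    fr <- frame_atoms(traj, k)
    pg <- frame_pair_geometries(fr, groups, class, r_cutoff)
    if (nrow(pg) == 0) next
    any_pairs <- TRUE
    ti <- pmin(pmax(findInterval(pg$theta, th_edges, rightmost.closed = TRUE), 1), nth)
    ri <- pmin(pmax(findInterval(pg$r, r_edges, rightmost.closed = TRUE), 1), nr)
    for (p in seq_along(ti)) acc[ti[p], ri[p]] <- acc[ti[p], ri[p]] + 1
  }
  if (!any_pairs) warn(sprintf("no %s pairs within %.2f nm", class, r_cutoff))
  acc <- acc / length(frames)
  grid <- tidyr::expand_grid(ti = seq_len(nth), ri = seq_len(nr))
  out <- tibble(
    theta_lo = th_edges[grid$ti], theta_hi = th_edges[grid$ti + 1],
    theta = (th_edges[grid$ti] + th_edges[grid$ti + 1]) / 2,
    r_lo = r_edges[grid$ri], r_hi = r_edges[grid$ri + 1],
    r = (r_edges[grid$ri] + r_edges[grid$ri + 1]) / 2,
    count = acc[cbind(grid$ti, grid$ri)]
  )
  attr(out, "class_label") <- class
  attr(out, "r_cutoff") <- r_cutoff
  class(out) <- c("pair_matrix", class(out))
  out
}

#' Radial marginal of a pair matrix
#'
#' Integrates the pair matrix over all orientation angles (discrete sum of
#' the angle bins), leaving the mean number of pairs per frame per radial
#' bin.
#'
#' @param M A [pair_matrix()].
#' @return A tibble (`r_lo`, `r_hi`, `r`, `count`) of class
#'   `pair_marginal`; total count equals the matrix total.
#' @export
radial_marginal <- function(M) {
  out <- dplyr::summarise(
    dplyr::group_by(as_tibble(M), .data$r_lo, .data$r_hi, .data$r),
    count = sum(.data$count), .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$r_lo)
  attr(out, "class_label") <- attr(M, "class_label")
  class(out) <- c("pair_marginal", class(out))
  out
}

#' Mean number of close pairs (first-peak integral)
#'
#' Sums the radial marginal over the first-peak region `r < r_cut_peak`
#' (default 0.55 nm, bracketing the contact peak near 0.4 nm), giving the
#' average number of closest pairs per frame.
#'
#' @param npr A [radial_marginal()].
#' @param r_cut_peak Upper integration limit, nm.
#' @return Mean close-pair count `n_p`.
#' @export
first_peak_count <- function(npr, r_cut_peak = 0.55) {
  if (r_cut_peak > max(npr$r_hi) + 1e-9) {
    abort("r_cut_peak lies beyond the histogram grid")
  }
  sum(npr$count[npr$r < r_cut_peak])
}

#' Pair formation events over a trajectory
#'
#' Builds the per-pair boolean series feeding the pairing autocorrelation:
#' a pair of planar groups is "formed" in a frame when its centre distance
#' is below `form_cutoff` (the same first-peak threshold as
#' [first_peak_count()]).
#'
#' @param traj A `dendri_trajectory` with `planar_groups`.
#' @param class `"neighboring"`, `"non_neighboring"` or `"all"`.
#' @param form_cutoff Formation distance, nm.
#' @return A [bond_events()] object, one row per group pair.
#' @export
pairing_events <- function(traj, class = "all", form_cutoff = 0.55) {
  groups <- traj$selections$planar_groups
  if (is.null(groups) || nrow(groups) < 2) {
    abort("trajectory needs at least two planar groups")
  }
  n <- nrow(groups)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- groups$spacer_id[idx[, 1]] == groups$spacer_id[idx[, 2]]
  keep <- switch(class, neighboring = same, non_neighboring = !same,
                 all = rep(TRUE, nrow(idx)),
                 abort(sprintf("unknown class '%s'", class)))
  idx <- idx[keep, , drop = FALSE]
  frames <- frame_index(traj)
  pres <- matrix(FALSE, nrow(idx), length(frames))
  for (kk in seq_along(frames)) {
    fr <- frame_atoms(traj, frames[kk])
    geo <- group_frame_geometry(fr, groups)
    dvec <- geo$centers[idx[, 1], , drop = FALSE] - geo$centers[idx[, 2], , drop = FALSE]
    pres[, kk] <- sqrt(rowSums(dvec^2)) < form_cutoff
  }
  bond_events(pres, traj$frame_interval,
              pair_ids = tibble(pair = seq_len(nrow(idx)),
                                group_i = groups$group_id[idx[, 1]],
                                group_j = groups$group_id[idx[, 2]]))
}

## Autocorrelation sums S(t) = sum_k b_k b_{k+t} via FFT, per series.
acf_sums_fft <- function(b) {
  n <- length(b)
  m <- 2^ceiling(log2(2 * n))
  f <- fft(c(b, rep(0, m - n)))
  s <- Re(fft(f * Conj(f), inverse = TRUE)) / m
  s[1:n]
}

#' Intermittent pairing autocorrelation and relaxation time
#'
#' The structural relaxation of pairing (a pair may break and re-form) is
#' \deqn{C(t) = \frac{\langle b(0)\,b(t)\rangle}{\langle b \rangle}}
#' with b(t) the 0/1 pair-formation indicator, averaged over all pairs and
#' time origins; for a 0/1 signal `C(0) = 1` under this normalisation.
#' The relaxation time is extracted as
#' \deqn{\tau_{LF} = \int_0^{t^*} C(t)\,dt + C(t^*)\,t^*,}
#' where `t*` is the first crossing of `1/e` (linearly interpolated): the
#' integral up to the crossing plus a single-exponential tail closure with
#' decay time `t*`. For a pure exponential this returns the decay time
#' exactly. `method = "crossing"` instead reports `t*` itself.
#'
#' @param series A [bond_events()] object with at least one formed pair.
#' @param max_lag Largest lag (frames) to evaluate; defaults to half the
#'   series length.
#' @param method `"integral"` (default) or `"crossing"`.
#' @return A `pairing_acf` object: tibble of `time`, `C` plus `tau_LF`
#'   (attribute and `$tau_LF`); `Inf` when the correlation never decays
#'   below `1/e` (e.g. permanently formed pairs).
#' @export
pairing_acf <- function(series, max_lag = NULL,
                        method = c("integral", "crossing")) {
  method <- match.arg(method)
  b <- series$presence
  if (mean(b) == 0) abort("no formed pairs: autocorrelation undefined")
  n <- ncol(b)
  max_lag <- min(max_lag %||% (n %/% 2), n - 1)
  num <- numeric(max_lag + 1)
  for (i in seq_len(nrow(b))) {
    num <- num + acf_sums_fft(as.numeric(b[i, ]))[1:(max_lag + 1)]
  }
  norm <- nrow(b) * (n - 0:max_lag)       # origins available at each lag
  C <- (num / norm) / mean(b)
  tvals <- (0:max_lag) * series$frame_interval
  thr <- exp(-1)
  below <- which(C < thr)
  if (length(below) == 0) {
    tau <- Inf
  } else {
    k <- below[1]
    t_star <- tvals[k - 1] + (C[k - 1] - thr) / (C[k - 1] - C[k]) *
      (tvals[k] - tvals[k - 1])
    if (method == "crossing") {
      tau <- t_star
    } else {
      sel <- tvals <= t_star
      tt <- c(tvals[sel], t_star)
      cc <- c(C[sel], thr)
      tau <- trapz(tt, cc) + thr * t_star
    }
  }
  structure(list(acf = tibble(time = tvals, C = C), tau_LF = tau,
                 method = method),
            class = "pairing_acf")
}

#' @export
print.pairing_acf <- function(x, ...) {
  cat(sprintf("<pairing_acf> tau_LF = %.4g ps (%s method), %d lags\n",
              x$tau_LF, x$method, nrow(x$acf)))
  invisible(x)
}

#' @rdname pairing_acf
#' @param x A `pairing_acf`.
#' @param ... Unused.
#' @export
tidy.pairing_acf <- function(x, ...) x$acf

#' @rdname pairing_acf
#' @export
glance.pairing_acf <- function(x, ...) tibble(tau_LF = x$tau_LF, method = x$method)

#' Full pairing characterisation of a trajectory
#'
#' For each pair class (neighbouring/non-neighbouring) computes the
#' distance-angle matrix, its radial marginal, the first-peak pair count
#' `n_p`, and — when the trajectory has more than one frame — the pairing
#' autocorrelation time `tau_LF`.
#'
#' @param traj A `dendri_trajectory` with `planar_groups`.
#' @inheritParams pair_matrix
#' @param r_cut_peak First-peak integration limit, nm.
#' @return A `pairing_summary` object; `glance()` gives one row per class.
#' @export
pairing_summary <- function(traj, r_cutoff = 1.8, theta_bin = 2, r_bin = 0.05,
                            r_cut_peak = 0.55) {
  res <- list()
  for (cl in c("neighboring", "non_neighboring")) {
    M <- suppressWarnings(pair_matrix(traj, cl, r_cutoff, theta_bin, r_bin))
    npr <- radial_marginal(M)
    np <- first_peak_count(npr, r_cut_peak)
    tau <- NA_real_
    if (n_frames(traj) > 3) {
      ev <- pairing_events(traj, cl, form_cutoff = r_cut_peak)
      if (mean(ev$presence) > 0) tau <- pairing_acf(ev)$tau_LF
    }
    res[[cl]] <- list(matrix = M, marginal = npr, n_p = np, tau_LF = tau)
  }
  structure(res, class = "pairing_summary")
}

#' @export
print.pairing_summary <- function(x, ...) {
  cat("<pairing_summary>\n")
  print(glance(x))
  invisible(x)
}

#' @rdname pairing_summary
#' @param x A `pairing_summary`.
#' @param ... Unused.
#' @export
glance.pairing_summary <- function(x, ...) {
  purrr::map_dfr(names(x), function(cl)
    tibble(class = cl, n_p = x[[cl]]$n_p, tau_LF = x[[cl]]$tau_LF))
}

#' @export
autoplot.pair_matrix <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$r, .data$theta, fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "r (nm)", y = expression(theta ~ "(deg)"),
                  fill = "pairs/frame",
                  title = paste0(attr(object, "class_label"), " pairs"))
}

#' @export
autoplot.pair_marginal <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$r, .data$count)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "r (nm)", y = expression(n[pairs](r)))
}
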