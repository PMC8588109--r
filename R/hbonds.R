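#' Per-pair boolean event series
#'
#' Container for per-pair on/off time series (hydrogen bond or planar pair
#' present/absent per frame), the common input of the lifetime and
#' autocorrelation estimators.
#'
#' @param presence Logical matrix, pairs in rows, frames in columns.
#' @param frame_interval Frame spacing, ps.
#' @param pair_ids Optional tibble identifying the pairs (one row per row
#'   of `presence`).
#' @return A `bond_events` object.
#' @export
bond_events <- function(presence, frame_interval = 1, pair_ids = NULL) {
  presence <- as.matrix(presence)
  storage.mode(presence) <- "logical"
  structure(
    list(presence = presence, frame_interval = frame_interval,
         pair_ids = pair_ids %||% tibble(pair = seq_len(nrow(presence)))),
    class = "bond_events"
  )
}

#' @export
print.bond_events <- function(x, ...) {
  cat(sprintf("<bond_events> %d pairs x %d frames (dt = %g ps), mean occupancy %.4f\n",
              nrow(x$presence), ncol(x$presence), x$frame_interval,
              mean(x$presence)))
  invisible(x)
}

#' @export
tidy.bond_events <- function(x, ...) {
  tibble(
    pair = rep(x$pair_ids$pair, ncol(x$presence)),
    frame = rep(seq_len(ncol(x$presence)), each = nrow(x$presence)),
    time = (rep(seq_len(ncol(x$presence)), each = nrow(x$presence)) - 1) * x$frame_interval,
    on = as.vector(x$presence)
  )
}

## ---------------------------------------------------------------------------

#' Hydrogen-bond geometric criterion
#'
#' A donor-hydrogen-acceptor triple is bonded when the donor-acceptor
#' distance is below `d_max` and the bond is close to linear. Two angle
#' conventions are supported:
#'
#' * `"hda_deviation"` (default, the Gromacs convention): the angle at the
#'   donor between the D-H and D-A vectors is at most `angle_max` — small
#'   values mean a near-linear D-H...A arrangement;
#' * `"dha"`: the raw D-H-A angle itself must be below `angle_max` (a
#'   literal reading sometimes seen in print; note a linear bond has
#'   D-H-A close to 180 degrees, so this convention selects strongly bent
#'   geometries and is provided for comparison only).
#'
#' @param d_max Donor-acceptor distance cut-off, nm.
#' @param angle_max Angular cut-off, degrees, in (0, 90].
#' @param angle_def `"hda_deviation"` or `"dha"`.
#' @return An `hbond_criterion` list.
#' @export
hbond_criterion <- function(d_max = 0.35, angle_max = 30,
                            angle_def = c("hda_deviation", "dha")) {
  if (d_max <= 0) abort("d_max must be > 0")
  if (angle_max <= 0 || angle_max > 90) abort("angle_max must be in (0, 90]")
  structure(list(d_max = d_max, angle_max = angle_max,
                 angle_def = match.arg(angle_def)),
            class = "hbond_criterion")
}

#' Detect hydrogen bonds in one frame
#'
#' @param atoms One frame's atom table ([frame_atoms()]).
#' @param donors Donor atom ids.
#' @param hydrogens Tibble with columns `hydrogen`, `donor` mapping each
#'   polar hydrogen to its parent donor.
#' @param acceptors Acceptor atom ids.
#' @param crit An [hbond_criterion()].
#' @return Tibble of detected `(donor, hydrogen, acceptor)` triples with the
#'   measured distance (nm) and angle (degrees).
#' @export
detect_hbonds <- function(atoms, donors, hydrogens, acceptors,
                          crit = hbond_criterion()) {
  hydrogens <- as_tibble(hydrogens)
  if (!all(c("hydrogen", "donor") %in% names(hydrogens))) {
    abort("hydrogens needs columns 'hydrogen' and 'donor'")
  }
  if (!all(hydrogens$donor %in% donors)) {
    abort("every hydrogen must map to a listed donor")
  }
  xyz <- coords_matrix(atoms)
  rownames(xyz) <- atoms$atom_id
  get <- function(ids) xyz[as.character(ids), , drop = FALSE]
  out <- list()
  acc <- setdiff(acceptors, integer(0))
  A <- get(acc)
  for (h in seq_len(nrow(hydrogens))) {
    d_id <- hydrogens$donor[h]
    h_id <- hydrogens$hydrogen[h]
    D <- xyz[as.character(d_id), ]
    H <- xyz[as.character(h_id), ]
    a_ids <- acc[acc != d_id & acc != h_id]
    if (length(a_ids) == 0) next
    Am <- get(a_ids)
    da <- sweep(Am, 2, D)
    dist_da <- sqrt(rowSums(da^2))
    near <- dist_da < crit$d_max & dist_da > 0
    if (!any(near)) next
    a_ids <- a_ids[near]; Am <- Am[near, , drop = FALSE]
    da <- da[near, , drop = FALSE]; dist_da <- dist_da[near]
    if (crit$angle_def == "hda_deviation") {
      dh <- H - D
      cosang <- (da %*% dh) / (dist_da * sqrt(sum(dh^2)))
    } else {
      hd <- D - H
      ha <- sweep(Am, 2, H)
      cosang <- (ha %*% hd) / (sqrt(rowSums(ha^2)) * sqrt(sum(hd^2)))
    }
    ang <- rad2deg(acos(pmin(pmax(cosang, -1), 1)))
    ok <- as.vector(ang) <= crit$angle_max
    if (crit$angle_def == "dha") ok <- as.vector(ang) < crit$angle_max
    if (any(ok)) {
      out[[length(out) + 1]] <- tibble(
        donor = d_id, hydrogen = h_id, acceptor = a_ids[ok],
        distance = dist_da[ok], angle = as.vector(ang)[ok]
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(donor = integer(), hydrogen = integer(), acceptor = integer(),
                  distance = numeric(), angle = numeric()))
  }
  dplyr::bind_rows(out)
}

partition_roles <- function(partition) {
  switch(partition,
    intra_dendrimer = list(d = c("dendrimer", "terminal_N", "branch_point"),
                           a = c("dendrimer", "terminal_N", "branch_point")),
    dendrimer_water = list(d = c("dendrimer", "terminal_N", "branch_point", "solvent"),
                           a = c("dendrimer", "terminal_N", "branch_point", "solvent"),
                           cross = c("solvent")),
    dendrimer_guest = list(d = c("dendrimer", "terminal_N", "branch_point", "guest"),
                           a = c("dendrimer", "terminal_N", "branch_point", "guest"),
                           cross = c("guest")),
    abort(sprintf("unknown partition '%s'", partition))
  )
}

#' Hydrogen-bond count series over a trajectory
#'
#' Counts bonds per frame within a donor/acceptor partition:
#' `"intra_dendrimer"` (both partners on the dendrimer),
#' `"dendrimer_water"` or `"dendrimer_guest"` (one partner on the
#' dendrimer, the other in the named species, in either direction).
#'
#' @param traj A `dendri_trajectory` with `donors`, `hydrogens`,
#'   `acceptors` selections attached.
#' @param partition One of `"intra_dendrimer"`, `"dendrimer_water"`,
#'   `"dendrimer_guest"`.
#' @param crit An [hbond_criterion()].
#' @return An `hbond_series` object: per-frame tibble plus the mean;
#'   `tidy()` gives the series, `glance()` the mean count.
#' @export
hbond_count_series <- function(traj, partition = "intra_dendrimer",
                               crit = hbond_criterion()) {
  sel <- traj$selections
  if (is.null(sel$donors) || is.null(sel$hydrogens) || is.null(sel$acceptors)) {
    abort("trajectory needs donors/hydrogens/acceptors selections")
  }
  pr <- partition_roles(partition)
  topo <- traj$topology
  role_of <- setNames(topo$role, topo$atom_id)
  dend <- c("dendrimer", "terminal_N", "branch_point")
  rows <- purrr::map_dfr(frame_index(traj), function(k) {
    fr <- frame_atoms(traj, k)
    hb <- detect_hbonds(fr, sel$donors, sel$hydrogens, sel$acceptors, crit)
    if (nrow(hb) > 0) {
      dr <- role_of[as.character(hb$donor)]
      ar <- role_of[as.character(hb$acceptor)]
      keep <- if (is.null(pr$cross)) {
        dr %in% pr$d & ar %in% pr$a
      } else {
        (dr %in% dend & ar %in% pr$cross) | (dr %in% pr$cross & ar %in% dend)
      }
      n <- sum(keep)
    } else n <- 0L
    tibble(frame = k, time = fr$time[1], n = n)
  })
  structure(list(per_frame = rows, partition = partition, crit = crit),
            class = "hbond_series")
}

#' @export
print.hbond_series <- function(x, ...) {
  cat(sprintf("<hbond_series> %s: mean %.3f bonds over %d frames\n",
              x$partition, mean(x$per_frame$n), nrow(x$per_frame)))
  invisible(x)
}

#' @rdname hbond_count_series
#' @param x An `hbond_series`.
#' @param ... Unused.
#' @export
tidy.hbond_series <- function(x, ...) x$per_frame

#' @rdname hbond_count_series
#' @export
glance.hbond_series <- function(x, ...) {
  tibble(partition = x$partition, mean_n = mean(x$per_frame$n),
         n_frames = nrow(x$per_frame))
}

#' Mean continuous bond lifetime
#'
#' Average length (in ps) of maximal uninterrupted on-runs over all pairs.
#' Runs touching the first or last frame are excluded: their true duration
#' is censored by the observation window and including them would bias the
#' mean downward for long-lived bonds (and upward for a short window).
#'
#' @param series A [bond_events()] object.
#' @return Mean continuous lifetime, ps.
#' @export
continuous_lifetime <- function(series) {
  runs <- interior_run_lengths(series$presence)
  if (length(runs) == 0) {
    abort("no interior on-runs: lifetime undefined (all-off, or every run touches the series boundary)")
  }
  mean(runs) * series$frame_interval
}

## On-run lengths (frames) excluding runs touching either boundary.
interior_run_lengths <- function(presence) {
  out <- vector("list", nrow(presence))
  for (i in seq_len(nrow(presence))) {
    r <- rle(as.vector(presence[i, ]))
    if (length(r$lengths) == 0) next
    on <- which(r$values)
    on <- on[on != 1 & on != length(r$lengths)]
    out[[i]] <- r$lengths[on]
  }
  unlist(out)
}

#' Bonds per side group
#'
#' Average number of (dendrimer side group)-water hydrogen bonds divided by
#' the number of side groups.
#'
#' @param n_side_bonds Mean bond count involving the side groups.
#' @param n_groups Number of side groups (> 0).
#' @return Dimensionless ratio.
#' @export
per_side_group_ratio <- function(n_side_bonds, n_groups) {
  if (any(n_groups <= 0)) abort("n_groups must be > 0")
  n_side_bonds / n_groups
}
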