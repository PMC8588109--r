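#' Molecular trajectory container
#'
#' A `dendri_trajectory` bundles per-atom static attributes (the topology),
#' per-frame coordinates, and named selections used by the analysis stages.
#' Coordinates are always stored in nanometres; times in picoseconds; charges
#' in elementary charge units; masses in g/mol.
#'
#' @param frames A data frame with columns `frame`, `time`, `atom_id`,
#'   `x`, `y`, `z` (long format, one row per atom per frame).
#' @param topology A data frame with one row per atom: `atom_id`, `element`,
#'   `mass`, `charge`, `role`, `group_id`. Missing columns are filled with
#'   defaults (mass 1, charge 0, role `"other"`).
#' @param box_edge Cubic box edge length in nm (may be `NA` for open systems).
#' @param frame_interval Time between consecutive frames, ps.
#' @param selections A named list of selections; see [attach_topology()].
#'
#' @return An object of class `dendri_trajectory`.
#' @export
new_trajectory <- function(frames, topology = NULL, box_edge = NA_real_,
                           frame_interval = 1, selections = list()) {
  frames <- as_tibble(frames)
  need <- c("frame", "atom_id", "x", "y", "z")
  miss <- setdiff(need, names(frames))
  if (length(miss) > 0) {
    abort(paste0("frames is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"time" %in% names(frames)) {
    frames$time <- (frames$frame - 1) * frame_interval
  }
  if (!all(is.finite(frames$x) & is.finite(frames$y) & is.finite(frames$z))) {
    abort("all positions must be finite")
  }
  counts <- table(frames$frame)
  if (length(unique(as.integer(counts))) > 1) {
    abort("inconsistent atom counts across frames")
  }
  n_atoms <- as.integer(counts[1])
  if (is.null(topology)) {
    topology <- tibble(atom_id = sort(unique(frames$atom_id)))
  }
  topology <- as_tibble(topology)
  if (!"atom_id" %in% names(topology)) topology$atom_id <- seq_len(nrow(topology))
  if (!"element" %in% names(topology)) topology$element <- "X"
  if (!"mass" %in% names(topology)) topology$mass <- 1
  if (!"charge" %in% names(topology)) topology$charge <- 0
  if (!"role" %in% names(topology)) topology$role <- "other"
  if (!"group_id" %in% names(topology)) topology$group_id <- NA_integer_
  if (nrow(topology) != n_atoms) {
    abort(sprintf("topology has %d atoms but frames have %d", nrow(topology), n_atoms))
  }
  if (any(topology$mass < 0, na.rm = TRUE)) abort("atom masses must be >= 0")
  bad <- setdiff(unique(topology$role), atom_roles())
  if (length(bad) > 0) {
    abort(paste0("unknown role(s): ", paste(bad, collapse = ", ")))
  }
  structure(
    list(
      topology = topology[order(topology$atom_id), ],
      frames = frames[order(frames$frame, frames$atom_id), ],
      box_edge = box_edge,
      frame_interval = frame_interval,
      selections = selections
    ),
    class = "dendri_trajectory"
  )
}

#' Recognised atom roles
#' @return Character vector of the role labels understood by the package.
#' @export
atom_roles <- function() {
  c("dendrimer", "terminal_N", "branch_point", "counterion", "guest",
    "solvent", "other")
}

#' @export
print.dendri_trajectory <- function(x, ...) {
  cat(sprintf(
    "<dendri_trajectory> %d atoms x %d frames (dt = %g ps, box = %s nm)\n",
    n_atoms(x), n_frames(x), x$frame_interval,
    ifelse(is.na(x$box_edge), "?", format(x$box_edge))
  ))
  roles <- table(x$topology$role)
  cat("  roles:", paste(sprintf("%s=%d", names(roles), roles), collapse = " "), "\n")
  if (length(x$selections) > 0) {
    cat("  selections:", paste(names(x$selections), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname new_trajectory
#' @param x Object to test.
#' @export
is_trajectory <- function(x) inherits(x, "dendri_trajectory")

#' Number of frames / atoms in a trajectory
#' @param traj A `dendri_trajectory`.
#' @return Integer count.
#' @export
n_frames <- function(traj) length(unique(traj$frames$frame))

#' @rdname n_frames
#' @export
n_atoms <- function(traj) nrow(traj$topology)

#' Extract one frame as an atom table
#'
#' Returns the atoms of a single frame joined with the static topology,
#' ordered by `atom_id` — the tidy unit all low-level geometry functions
#' consume.
#'
#' @param traj A `dendri_trajectory`.
#' @param frame Frame index (values of the `frame` column).
#' @param ids Optional atom ids to restrict to.
#' @return A tibble with coordinates and per-atom attributes.
#' @export
frame_atoms <- function(traj, frame = 1, ids = NULL) {
  fr <- traj$frames[traj$frames$frame == frame, ]
  if (nrow(fr) == 0) abort(sprintf("no frame %s in trajectory", frame))
  out <- dplyr::left_join(fr, traj$topology, by = "atom_id")
  if (!is.null(ids)) out <- out[out$atom_id %in% ids, ]
  out
}

#' Frame indices present in a trajectory
#' @param traj A `dendri_trajectory`.
#' @export
frame_index <- function(traj) sort(unique(traj$frames$frame))

#' Atom ids of a named selection
#'
#' @param traj A `dendri_trajectory` with an attached topology.
#' @param which One of `"dendrimer"` (includes terminal and branch-point
#'   atoms), `"terminals"`, `"branch_points"`, `"counterions"`, `"guests"`
#'   (all guest atoms), `"solvent"`, `"heavy"` (element != H), or `"all"`.
#' @return Integer vector of atom ids.
#' @export
selection_ids <- function(traj, which = "dendrimer") {
  topo <- traj$topology
  switch(which,
    all = topo$atom_id,
    dendrimer = topo$atom_id[topo$role %in% c("dendrimer", "terminal_N", "branch_point")],
    terminals = topo$atom_id[topo$role == "terminal_N"],
    branch_points = topo$atom_id[topo$role == "branch_point"],
    counterions = topo$atom_id[topo$role == "counterion"],
    guests = topo$atom_id[topo$role == "guest"],
    solvent = topo$atom_id[topo$role == "solvent"],
    heavy = topo$atom_id[topo$element != "H"],
    abort(sprintf("unknown selection '%s'", which))
  )
}

#' Bare charge of the dendrimer
#'
#' Sum of all fixed charges on dendrimer atoms (terminal, branch-point and
#' other dendrimer roles) before counterion screening.
#'
#' @param traj A `dendri_trajectory`.
#' @return Net charge in e.
#' @export
q_bare <- function(traj) {
  ids <- selection_ids(traj, "dendrimer")
  sum(traj$topology$charge[traj$topology$atom_id %in% ids])
}

## ---------------------------------------------------------------------------
## Centre of mass

#' Mass-weighted centre of a set of atoms
#'
#' @param atoms A data frame with columns `x`, `y`, `z` and (optionally)
#'   `mass`; absent masses count as 1 (geometric centroid).
#' @return Named numeric vector `c(x, y, z)`, nm.
#' @export
center_of_mass <- function(atoms) {
  if (nrow(atoms) == 0) abort("selection is empty")
  m <- if ("mass" %in% names(atoms)) atoms$mass else rep(1, nrow(atoms))
  M <- sum(m)
  if (M <= 0) abort("total mass of selection is zero")
  c(x = sum(m * atoms$x) / M, y = sum(m * atoms$y) / M, z = sum(m * atoms$z) / M)
}
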