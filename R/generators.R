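## Synthetic-configuration generators with known ground truth.
##
## These emulate the statistical structure the analysis stages assume —
## a dense-sphere bead cloud for the dendrimer, a diffuse counterion cloud
## with a controllable condensed fraction, rigid planar triples at exact
## (distance, angle) pair geometry, two-state telegraph bond series, and
## guest molecules at controllable separation from the host — so every
## estimator can be validated against construction-time ground truth.

## Run code under a fixed seed without clobbering the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a dense-sphere dendrimer bead cloud
#'
#' Beads are sampled uniformly in a ball of radius `target_R` centred at the
#' origin; for large `n_beads` the empirical radius of gyration converges to
#' `sqrt(3/5) * target_R` and the asphericity to 0. `terminal_count` beads
#' are placed in the outer shell (radial distance in `[0.8, 1] * target_R`)
#' and flagged `terminal_N`; `spacer_charge_sites` further beads carry
#' `spacer_site_charge` each, emulating protonated spacer groups, so the bare
#' charge is `terminal_count * terminal_charge +
#' spacer_charge_sites * spacer_site_charge`.
#'
#' @param n_beads Number of beads.
#' @param target_R Outer radius of the uniform ball, nm.
#' @param bead_mass Mass per bead, g/mol.
#' @param terminal_count Number of terminal beads (<= `n_beads`).
#' @param terminal_charge Charge per terminal bead, e.
#' @param spacer_charge_sites Number of charged spacer beads.
#' @param spacer_site_charge Charge per spacer site, e.
#' @param box_edge Simulation-cell edge, nm.
#' @param seed RNG seed; the same seed reproduces the same configuration.
#' @return A single-frame [new_trajectory()] with roles and charges set.
#' @export
gen_dendrimer <- function(n_beads, target_R, bead_mass = 100,
                          terminal_count = 0, terminal_charge = 1,
                          spacer_charge_sites = 0, spacer_site_charge = 1,
                          box_edge = 4 * target_R, seed = 1) {
  if (target_R <= 0) abort("target_R must be > 0")
  if (terminal_count + spacer_charge_sites > n_beads) {
    abort("terminal_count + spacer_charge_sites exceeds n_beads")
  }
  with_seed(seed, {
    n_core <- n_beads - terminal_count
    core <- runif_ball(n_core, target_R)
    term <- if (terminal_count > 0) runif_ball(terminal_count, target_R, r_min = 0.8 * target_R)
            else matrix(0, 0, 3)
    xyz <- rbind(core, term)
    role <- c(rep("dendrimer", n_core), rep("terminal_N", terminal_count))
    charge <- rep(0, n_beads)
    if (terminal_count > 0) charge[(n_core + 1):n_beads] <- terminal_charge
    if (spacer_charge_sites > 0) {
      sites <- sample.int(n_core, spacer_charge_sites)
      charge[sites] <- charge[sites] + spacer_site_charge
    }
    topo <- tibble(atom_id = seq_len(n_beads), element = "C",
                   mass = bead_mass, charge = charge, role = role,
                   group_id = NA_integer_)
    frames <- tibble(frame = 1L, time = 0, atom_id = seq_len(n_beads),
                     x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    new_trajectory(frames, topo, box_edge = box_edge)
  })
}

#' Add a counterion cloud around a host configuration
#'
#' Places `round(condensed_fraction * n_ions)` ions inside
#' `condensed_radius` of the origin; of these, `round(pair_fraction *
#' n_ions)` sit at exactly `pair_distance` from a randomly chosen charged
#' host site (ion pairs). The remaining ions are uniform in the cubic box
#' outside the condensed region. When `n_ions * |ion_charge|` equals the
#' host's bare charge the resulting system is electroneutral by
#' construction.
#'
#' @param host A single-frame `dendri_trajectory` (the dendrimer).
#' @param n_ions Number of counterions.
#' @param ion_charge Charge per ion, e (typically -1).
#' @param condensed_fraction Fraction of ions inside `condensed_radius`.
#' @param condensed_radius Radius of the condensed region, nm.
#' @param pair_fraction Fraction of ions in direct ion pairs
#'   (must not exceed `condensed_fraction`).
#' @param pair_distance Ion-site contact distance, nm (the ion-pair peak).
#' @param exclusion Minimum distance of non-paired ions from any charged
#'   host site, nm, so only the constructed pairs fall under a contact
#'   cut-off between `pair_distance` and `exclusion`.
#' @param ion_mass Ion mass, g/mol.
#' @param seed RNG seed.
#' @return A single-frame trajectory containing host plus ions.
#' @export
gen_ion_cloud <- function(host, n_ions, ion_charge = -1,
                          condensed_fraction = 0.5, condensed_radius = 2,
                          pair_fraction = 0, pair_distance = 0.3,
                          exclusion = 0.5, ion_mass = 35.45, seed = 1) {
  box <- host$box_edge
  if (is.na(box) || box <= 2 * condensed_radius) {
    abort("host box_edge must exceed twice the condensed_radius")
  }
  if (pair_fraction > condensed_fraction) {
    abort("pair_fraction cannot exceed condensed_fraction")
  }
  n_cond <- round(condensed_fraction * n_ions)
  n_pair <- round(pair_fraction * n_ions)
  n_diff <- n_ions - n_cond
  host_atoms <- frame_atoms(host, frame_index(host)[1])
  charged <- host_atoms[host_atoms$charge != 0, ]
  if (n_pair > 0 && nrow(charged) == 0) {
    abort("host has no charged sites to form ion pairs with")
  }
  with_seed(seed, {
    pos <- matrix(0, n_ions, 3)
    if (n_pair > 0) {
      ## each paired ion sits at exactly pair_distance from its chosen site
      ## and no closer than `exclusion` to any OTHER charged site, so the
      ## nearest-site distance histogram has its spike exactly at
      ## pair_distance and contact counting is unambiguous
      site_xyz_all <- coords_matrix(charged)
      for (ii in seq_len(n_pair)) {
        placed <- FALSE
        for (attempt in 1:500) {
          j <- sample.int(nrow(charged), 1)
          cand <- site_xyz_all[j, ] + runif_sphere(1)[1, ] * pair_distance
          d_other <- sqrt(colSums((t(site_xyz_all[-j, , drop = FALSE]) - cand)^2))
          if (length(d_other) == 0 || min(d_other) > exclusion) {
            pos[ii, ] <- cand
            placed <- TRUE
            break
          }
        }
        if (!placed) abort("cannot place an ion pair clear of other charged sites")
      }
    }
    if (n_cond - n_pair > 0) {
      need <- n_cond - n_pair
      site_xyz <- coords_matrix(charged)
      got <- 0L
      buf <- matrix(0, need, 3)
      tries <- 0L
      while (got < need) {
        cand <- runif_ball(need, condensed_radius)
        keep <- if (nrow(charged) > 0) {
          sqrt(apply(cross_dist2(cand, site_xyz), 1, min)) > exclusion
        } else rep(TRUE, need)
        take <- min(sum(keep), need - got)
        if (take > 0) buf[got + seq_len(take), ] <- cand[keep, , drop = FALSE][seq_len(take), ]
        got <- got + take
        tries <- tries + 1L
        if (tries > 1000) abort("cannot place condensed ions outside the exclusion zone")
      }
      pos[(n_pair + 1):n_cond, ] <- buf
    }
    if (n_diff > 0) {
      got <- 0L
      tries_d <- 0L
      buf <- matrix(0, n_diff, 3)
      site_xyz_all <- coords_matrix(charged)
      while (got < n_diff) {
        tries_d <- tries_d + 1L
        if (tries_d > 2000) abort("cannot place diffuse ions outside the condensed/exclusion regions")
        cand <- matrix(stats::runif(3 * n_diff, -box / 2, box / 2), ncol = 3)
        keep <- sqrt(rowSums(cand^2)) > condensed_radius
        if (nrow(charged) > 0) {
          keep <- keep & sqrt(apply(cross_dist2(cand, site_xyz_all), 1, min)) > exclusion
        }
        take <- min(sum(keep), n_diff - got)
        if (take > 0) buf[got + seq_len(take), ] <- cand[keep, , drop = FALSE][seq_len(take), ]
        got <- got + take
      }
      pos[(n_cond + 1):n_ions, ] <- buf
    }
    n0 <- n_atoms(host)
    ion_ids <- n0 + seq_len(n_ions)
    topo <- dplyr::bind_rows(
      host$topology,
      tibble(atom_id = ion_ids, element = "Cl", mass = ion_mass,
             charge = ion_charge, role = "counterion", group_id = NA_integer_)
    )
    fr <- dplyr::bind_rows(
      host$frames,
      tibble(frame = 1L, time = 0, atom_id = ion_ids,
             x = pos[, 1], y = pos[, 2], z = pos[, 3])
    )
    new_trajectory(fr, topo, box_edge = box,
                   frame_interval = host$frame_interval,
                   selections = host$selections)
  })
}

#' Generate rigid planar three-atom groups at exact pair geometry
#'
#' Each group is an equilateral triangle of circumradius `ring_radius` (its
#' centroid is the group centre). For every requested pair, the second group
#' is displaced by `r` along the first group's plane and its plane tilted by
#' `theta` about the displacement axis, so the measured centre-centre
#' distance and inter-plane angle equal the request to machine precision.
#' Pair clusters and isolated groups are laid out on a coarse grid more than
#' 3 nm apart, so no unintended pair falls within the 1.8 nm analysis
#' cut-off.
#'
#' @param pairs A data frame with columns `r` (nm), `theta` (degrees, in
#'   `[0, 90]`) and logical `neighboring` (same spacer or not). May have
#'   zero rows.
#' @param n_isolated Number of additional isolated groups (no partner within
#'   the cut-off).
#' @param ring_radius Circumradius of the triangle, nm.
#' @param seed RNG seed (random in-plane orientations of the clusters).
#' @return A single-frame trajectory whose `selections$planar_groups` table
#'   records triples, centre atoms and spacer ids.
#' @export
gen_planar_groups <- function(pairs = NULL, n_isolated = 0, ring_radius = 0.12,
                              seed = 1) {
  pairs <- if (is.null(pairs)) tibble(r = numeric(), theta = numeric(),
                                      neighboring = logical())
           else as_tibble(pairs)
  if (nrow(pairs) > 0) {
    if (any(pairs$theta < 0 | pairs$theta > 90)) {
      abort("theta must lie in [0, 90] degrees (fold larger angles first)")
    }
    if (any(pairs$r <= 0)) abort("pair distance r must be > 0")
  }
  n_clusters <- nrow(pairs) + n_isolated
  if (n_clusters == 0) abort("nothing to generate")
  spacing <- 5
  side <- ceiling(n_clusters^(1 / 3))
  idx <- seq_len(n_clusters) - 1L
  origins <- cbind(idx %% side, (idx %/% side) %% side, idx %/% side^2) * spacing
  tri_local <- ring_radius * rbind(
    c(1, 0, 0),
    c(-0.5, sqrt(3) / 2, 0),
    c(-0.5, -sqrt(3) / 2, 0)
  )
  with_seed(seed, {
    atoms <- list(); groups <- list()
    gid <- 0L; spid <- 0L; aid <- 0L
    add_group <- function(center, Rmat, spacer) {
      gid <<- gid + 1L
      tri <- sweep(tri_local %*% t(Rmat), 2, center, "+")
      ids <- aid + 1:3
      aid <<- aid + 3L
      atoms[[gid]] <<- tibble(atom_id = ids, x = tri[, 1], y = tri[, 2], z = tri[, 3])
      groups[[gid]] <<- tibble(group_id = gid, spacer_id = spacer,
                               triple = list(ids), center_atoms = list(ids))
    }
    for (p in seq_len(nrow(pairs))) {
      o <- origins[p, ]
      spid <- spid + 1L
      sp1 <- spid
      if (pairs$neighboring[p]) sp2 <- sp1 else { spid <- spid + 1L; sp2 <- spid }
      add_group(o, diag(3), sp1)
      ## partner: displaced along x (in the first plane), tilted about x
      Rt <- rot_about(c(1, 0, 0), deg2rad(pairs$theta[p]))
      add_group(o + c(pairs$r[p], 0, 0), Rt, sp2)
    }
    for (k in seq_len(n_isolated)) {
      o <- origins[nrow(pairs) + k, ]
      spid <- spid + 1L
      axis <- runif_sphere(1)[1, ]
      add_group(o, rot_about(axis, stats::runif(1, 0, 2 * pi)), spid)
    }
    at <- dplyr::bind_rows(atoms)
    topo <- tibble(atom_id = at$atom_id, element = "C", mass = 12.01,
                   charge = 0, role = "dendrimer",
                   group_id = rep(seq_len(gid), each = 3))
    fr <- tibble(frame = 1L, time = 0, atom_id = at$atom_id,
                 x = at$x, y = at$y, z = at$z)
    new_trajectory(fr, topo, box_edge = side * spacing + 10,
                   selections = list(planar_groups = dplyr::bind_rows(groups)))
  })
}

#' Generate two-state telegraph bond series
#'
#' Each pair alternates between on and off sojourns with independent
#' exponential durations (means `mean_on`, `mean_off`, ps), sampled on a
#' regular frame grid. The initial state is drawn from the stationary
#' distribution, and by memorylessness the sampled process is exactly
#' stationary. This is the ground truth for the continuous-lifetime
#' estimator and for the pairing autocorrelation time
#' `tau_c = mean_on * mean_off / (mean_on + mean_off)`.
#'
#' @param n_pairs Number of independent pair series.
#' @param mean_on,mean_off Mean sojourn times, ps.
#' @param frame_interval Sampling interval, ps.
#' @param n_frames Number of sampled frames (>= 2).
#' @param seed RNG seed.
#' @return A `bond_events` object (see [bond_events()]).
#' @export
gen_telegraph_series <- function(n_pairs, mean_on, mean_off,
                                 frame_interval = 1, n_frames, seed = 1) {
  if (mean_on <= 0 || mean_off <= 0) abort("mean_on and mean_off must be > 0")
  if (n_frames < 2) abort("n_frames must be >= 2")
  if (frame_interval >= mean_on) {
    warn("frame_interval >= mean_on: on-lifetimes are undersampled")
  }
  total_t <- n_frames * frame_interval
  p_on <- mean_on / (mean_on + mean_off)
  t_frames <- (seq_len(n_frames) - 1) * frame_interval
  with_seed(seed, {
    pres <- matrix(FALSE, n_pairs, n_frames)
    for (i in seq_len(n_pairs)) {
      start_on <- stats::runif(1) < p_on
      n_guess <- max(16, ceiling(2.5 * total_t / (mean_on + mean_off)) + 16)
      repeat {
        k <- ceiling(n_guess / 2)
        on_d <- stats::rexp(k, 1 / mean_on)
        off_d <- stats::rexp(k, 1 / mean_off)
        dur <- if (start_on) as.vector(rbind(on_d, off_d)) else as.vector(rbind(off_d, on_d))
        ends <- cumsum(dur)
        if (ends[length(ends)] >= total_t) break
        n_guess <- n_guess * 2
      }
      seg <- findInterval(t_frames, ends) + 1L  # sojourn index per frame
      on_idx <- if (start_on) seg %% 2L == 1L else seg %% 2L == 0L
      pres[i, ] <- on_idx
    }
    bond_events(pres, frame_interval)
  })
}

#' Place guest molecules around a host at controlled separation
#'
#' Guests are rigid 4-bead clusters (elements C, N, O, C; net charge
#' `guest_charge` split evenly), emulating a small tetrapeptide.
#' `bound_count` guests are placed with exactly one bead at `contact_gap`
#' from a randomly chosen host atom (in contact under any reasonable local
#' criterion); the remaining guests are placed with every bead more than
#' 2 nm from every host atom.
#'
#' @param host A single-frame `dendri_trajectory`.
#' @param n_guests Total number of guest molecules.
#' @param bound_count Number of guests in contact (<= `n_guests`).
#' @param contact_gap Contact distance for bound guests, nm.
#' @param guest_charge Net charge per guest, e.
#' @param seed RNG seed.
#' @return A single-frame trajectory with `selections$guests` populated.
#' @export
gen_complex_scene <- function(host, n_guests, bound_count,
                              contact_gap = 0.25, guest_charge = -2, seed = 1) {
  if (bound_count > n_guests) abort("bound_count cannot exceed n_guests")
  host_atoms <- frame_atoms(host, frame_index(host)[1])
  ## separation is measured from the dendrimer, not from any counterion cloud
  dend <- host_atoms$role %in% c("dendrimer", "terminal_N", "branch_point")
  if (any(dend)) host_atoms <- host_atoms[dend, ]
  hxyz <- coords_matrix(host_atoms)
  r_host <- sqrt(rowSums(hxyz^2))
  far_radius <- max(r_host) + 2.6
  box <- host$box_edge
  if (!is.na(box) && n_guests > bound_count && box / 2 < far_radius + 0.5) {
    abort("host box too small to separate unbound guests by > 2 nm")
  }
  bead_local <- 0.15 * rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                             c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  with_seed(seed, {
    guest_atoms <- list(); guest_ids <- list()
    aid <- n_atoms(host)
    for (g in seq_len(n_guests)) {
      if (g <= bound_count) {
        j <- sample.int(nrow(hxyz), 1)
        dir <- unit3(if (sum(hxyz[j, ]^2) > 0) hxyz[j, ] else runif_sphere(1)[1, ])
        anchor <- hxyz[j, ] + dir * contact_gap
        beads <- sweep(bead_local %*% t(rot_about(runif_sphere(1)[1, ],
                                                  stats::runif(1, 0, 2 * pi))), 2,
                       anchor + dir * 0, "+")
        ## keep bead 1 exactly at the anchor
        beads <- sweep(beads, 2, beads[1, ] - anchor, "-")
        ## push remaining beads outward so none lands closer than bead 1
        shift <- dir * 0.02
        beads[-1, ] <- sweep(beads[-1, , drop = FALSE], 2, shift, "+")
      } else {
        dir <- runif_sphere(1)[1, ]
        center <- dir * (far_radius + stats::runif(1, 0, 0.4))
        beads <- sweep(bead_local, 2, center, "+")
      }
      ids <- aid + 1:4
      aid <- aid + 4L
      guest_ids[[g]] <- ids
      guest_atoms[[g]] <- tibble(atom_id = ids, x = beads[, 1], y = beads[, 2],
                                 z = beads[, 3])
    }
    ga <- dplyr::bind_rows(guest_atoms)
    topo <- dplyr::bind_rows(
      host$topology,
      tibble(atom_id = ga$atom_id,
             element = rep(c("C", "N", "O", "C"), n_guests),
             mass = rep(c(12.01, 14.01, 16.00, 12.01), n_guests),
             charge = guest_charge / 4, role = "guest",
             group_id = rep(seq_len(n_guests), each = 4))
    )
    fr <- dplyr::bind_rows(
      host$frames,
      tibble(frame = 1L, time = 0, atom_id = ga$atom_id,
             x = ga$x, y = ga$y, z = ga$z)
    )
    sels <- host$selections
    sels$guests <- guest_ids
    new_trajectory(fr, topo, box_edge = box,
                   frame_interval = host$frame_interval, selections = sels)
  })
}
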