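#' Local contact criterion for complexation
#'
#' A guest molecule is in complex with the host when at least one
#' guest-host atom pair is closer than `s * r_min(el_i, el_j)`, where
#' `r_min` is the separation at which the non-bonded pair potential is at
#' its minimum (strict inequality). The per-element-pair minima are
#' supplied as a symmetric table; [default_rmin_table()] ships
#' Lennard-Jones-style values (`2^(1/6)` times the pair sigma under
#' Lorentz combining) for H, C, N, O and Cl, typical of biomolecular force
#' fields.
#'
#' @param s Dimensionless contact factor (typically 1.0, 1.5 or 2.0).
#' @param r_min_table Data frame with columns `element_i`, `element_j`,
#'   `r_min` (nm); will be symmetrised.
#' @return A `contact_criterion` object.
#' @export
contact_criterion <- function(s = 1.5, r_min_table = default_rmin_table()) {
  if (s <= 0) abort("s must be > 0")
  tab <- as_tibble(r_min_table)
  if (!all(c("element_i", "element_j", "r_min") %in% names(tab))) {
    abort("r_min_table needs columns element_i, element_j, r_min")
  }
  sym <- dplyr::distinct(dplyr::bind_rows(
    tab,
    dplyr::rename(tab, element_i = "element_j", element_j = "element_i")
  ))
  structure(list(s = s, r_min_table = sym), class = "contact_criterion")
}

#' @rdname contact_criterion
#' @export
default_rmin_table <- function() {
  ## per-element r_min/2-style radii (nm); pair value via arithmetic mean
  base <- c(H = 0.12, C = 0.38, N = 0.365, O = 0.33, Cl = 0.44)
  els <- names(base)
  grid <- expand.grid(element_i = els, element_j = els,
                      stringsAsFactors = FALSE)
  tibble(element_i = grid$element_i, element_j = grid$element_j,
         r_min = (base[grid$element_i] + base[grid$element_j]) / 2)
}

rmin_lookup <- function(crit, el_i, el_j) {
  tab <- crit$r_min_table
  key <- paste(tab$element_i, tab$element_j)
  v <- setNames(tab$r_min, key)
  out <- v[paste(el_i, el_j)]
  if (anyNA(out)) {
    miss <- unique(paste(el_i, el_j)[is.na(out)])
    abort(paste0("element pair(s) missing from r_min table: ",
                 paste(head(miss, 5), collapse = "; ")))
  }
  unname(out)
}

#' Is a guest molecule in complex with the host?
#'
#' @param guest_atoms,host_atoms Atom tables with coordinates and
#'   `element`.
#' @param crit A [contact_criterion()].
#' @return `TRUE` iff some guest-host atom pair satisfies
#'   `r < s * r_min` (strict).
#' @export
guest_in_complex <- function(guest_atoms, host_atoms, crit = contact_criterion()) {
  if (nrow(guest_atoms) == 0 || nrow(host_atoms) == 0) {
    abort("guest and host selections must be non-empty")
  }
  d <- sqrt(cross_dist2(coords_matrix(guest_atoms), coords_matrix(host_atoms)))
  rm <- matrix(
    rmin_lookup(crit,
                rep(guest_atoms$element, times = nrow(host_atoms)),
                rep(host_atoms$element, each = nrow(guest_atoms))),
    nrow = nrow(guest_atoms)
  )
  any(d < crit$s * rm)
}

#' Guests-in-complex time series
#'
#' Counts, independently per frame (no hysteresis), the guest molecules
#' with at least one atom in contact with the host under the local
#' criterion.
#'
#' @param traj A `dendri_trajectory` with `guests` attached.
#' @param crit A [contact_criterion()].
#' @return A `complex_series` object; `tidy()` the per-frame counts,
#'   `glance()` the mean.
#' @export
complex_series <- function(traj, crit = contact_criterion()) {
  guests <- traj$selections$guests
  if (is.null(guests) || length(guests) == 0) {
    abort("trajectory has no guest molecules attached")
  }
  host_ids <- selection_ids(traj, "dendrimer")
  rows <- purrr::map_dfr(frame_index(traj), function(k) {
    fr <- frame_atoms(traj, k)
    host <- fr[fr$atom_id %in% host_ids, ]
    in_cx <- vapply(guests, function(g)
      guest_in_complex(fr[fr$atom_id %in% g, ], host, crit), TRUE)
    tibble(frame = k, time = fr$time[1], n_lc = sum(in_cx),
           bound = list(which(in_cx)))
  })
  structure(list(per_frame = rows, s = crit$s), class = "complex_series")
}

#' @export
print.complex_series <- function(x, ...) {
  cat(sprintf("<complex_series> s = %g: mean n_lc = %.3f over %d frames\n",
              x$s, mean(x$per_frame$n_lc), nrow(x$per_frame)))
  invisible(x)
}

#' @rdname complex_series
#' @param x A `complex_series`.
#' @param ... Unused.
#' @export
tidy.complex_series <- function(x, ...) x$per_frame[, c("frame", "time", "n_lc")]

#' @rdname complex_series
#' @export
glance.complex_series <- function(x, ...) {
  tibble(s = x$s, mean_n_lc = mean(x$per_frame$n_lc),
         n_frames = nrow(x$per_frame))
}

#' Radius of gyration of the host and of the complex
#'
#' Applies the mass-weighted radius of gyration to the host atoms alone and
#' to the union of host and currently bound guest atoms.
#'
#' @param atoms One frame's atom table.
#' @param host_ids Host atom ids.
#' @param bound_guest_ids Atom ids of guests currently in complex (may be
#'   empty, in which case both radii coincide).
#' @return A tibble with `Rg_dendrimer` and `Rg_complex` (nm).
#' @export
complex_size <- function(atoms, host_ids, bound_guest_ids = integer()) {
  host <- atoms[atoms$atom_id %in% host_ids, ]
  if (nrow(host) == 0) abort("host selection is empty")
  un <- atoms[atoms$atom_id %in% c(host_ids, bound_guest_ids), ]
  tibble(Rg_dendrimer = radius_of_gyration(host),
         Rg_complex = radius_of_gyration(un))
}

#' Full complexation characterisation
#'
#' For each contact factor `s`, computes the guests-in-complex series and,
#' per frame, the host and complex radii of gyration; the summary averages
#' over all frames.
#'
#' @param traj A `dendri_trajectory` with guests.
#' @param s_values Contact factors to evaluate (default `c(1.5, 2)`).
#' @param r_min_table Per-element-pair potential minima.
#' @return A `complex_summary` object; `glance()` gives one row per `s`.
#' @export
complex_summary <- function(traj, s_values = c(1.5, 2),
                            r_min_table = default_rmin_table()) {
  host_ids <- selection_ids(traj, "dendrimer")
  guests <- traj$selections$guests
  out <- purrr::map(s_values, function(s) {
    cs <- complex_series(traj, contact_criterion(s, r_min_table))
    sizes <- purrr::map_dfr(seq_len(nrow(cs$per_frame)), function(i) {
      k <- cs$per_frame$frame[i]
      fr <- frame_atoms(traj, k)
      bound_ids <- unlist(guests[cs$per_frame$bound[[i]]])
      complex_size(fr, host_ids, bound_ids)
    })
    list(series = cs, sizes = dplyr::bind_cols(
      cs$per_frame[, c("frame", "time", "n_lc")], sizes))
  })
  names(out) <- paste0("s_", s_values)
  structure(list(by_s = out, s_values = s_values), class = "complex_summary")
}

#' @export
print.complex_summary <- function(x, ...) {
  cat("<complex_summary>\n")
  print(glance(x))
  invisible(x)
}

#' @rdname complex_summary
#' @param x A `complex_summary`.
#' @param ... Unused.
#' @export
glance.complex_summary <- function(x, ...) {
  purrr::map_dfr(seq_along(x$s_values), function(i) {
    sz <- x$by_s[[i]]$sizes
    tibble(s = x$s_values[i], n_lc = mean(sz$n_lc),
           Rg_dendrimer = mean(sz$Rg_dendrimer),
           Rg_complex = mean(sz$Rg_complex))
  })
}

#' @rdname complex_summary
#' @export
tidy.complex_summary <- function(x, ...) {
  purrr::map_dfr(seq_along(x$s_values), function(i)
    dplyr::mutate(x$by_s[[i]]$sizes, s = x$s_values[i], .before = 1))
}
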