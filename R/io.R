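#' Read a molecular configuration or trajectory
#'
#' Dispatches on `format` (guessed from the file extension when omitted).
#' Supported dialects:
#'
#' * **xyz** — (extended) XYZ, possibly multi-frame. Per-atom lines are
#'   `element x y z [charge [mass]]`; coordinates are interpreted as nm
#'   (the package's native unit, also used by [write_xyz()]). The comment
#'   line may carry `time=<ps>` and `box=<nm>` tokens.
#' * **pdb** — fixed-column ATOM/HETATM records, multi-MODEL aware.
#'   PDB coordinates are in Angstrom and are converted to nm on read.
#' * **gro** — Gromacs fixed-column coordinate file (already in nm);
#'   multi-frame concatenated files are supported.
#'
#' @param path Path to the file.
#' @param format `"xyz"`, `"pdb"` or `"gro"`.
#' @param frame_interval Time between frames in ps (used when the file
#'   carries no time stamps).
#' @return A [new_trajectory()] object with a minimal topology (elements and,
#'   for extended XYZ, charges/masses); attach selections with
#'   [attach_topology()].
#' @export
read_configuration <- function(path, format = c("xyz", "pdb", "gro"),
                               frame_interval = 1) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (length(format) > 1) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xyz", "pdb", "gro")) ext else "xyz"
  }
  format <- match.arg(format, c("xyz", "pdb", "gro"))
  switch(format,
    xyz = read_xyz(path, frame_interval),
    pdb = read_pdb(path, frame_interval),
    gro = read_gro(path, frame_interval)
  )
}

read_xyz <- function(path, frame_interval = 1) {
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  times <- c()
  box <- NA_real_
  charges <- NULL
  masses <- NULL
  elements <- NULL
  k <- 0L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i])) {
      abort(sprintf("xyz parse error at line %d: expected atom count", i))
    }
    n <- as.integer(trimws(lines[i]))
    if (i + 1L + n > length(lines)) {
      abort(sprintf("xyz parse error at line %d: truncated frame", i))
    }
    comment <- lines[i + 1L]
    t_tok <- regmatches(comment, regexpr("time=\\S+", comment))
    b_tok <- regmatches(comment, regexpr("box=\\S+", comment))
    k <- k + 1L
    times[k] <- if (length(t_tok) == 1) as.numeric(sub("time=", "", t_tok)) else (k - 1) * frame_interval
    if (length(b_tok) == 1) box <- as.numeric(sub("box=", "", b_tok))
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "\\s+")
    nf <- lengths(toks)
    if (any(nf < 4)) {
      abort(sprintf("xyz parse error at line %d: fewer than 4 fields",
                    i + 1L + which(nf < 4)[1]))
    }
    el <- vapply(toks, `[[`, "", 1L)
    num <- function(j) suppressWarnings(vapply(toks, function(tk) as.numeric(tk[j]), 0))
    xyz <- cbind(num(2), num(3), num(4))
    if (anyNA(xyz)) {
      abort(sprintf("xyz parse error near line %d: non-numeric coordinate", i + 2L))
    }
    if (k == 1L) {
      elements <- el
      if (all(nf >= 5)) charges <- num(5)
      if (all(nf >= 6)) masses <- num(6)
    } else if (n != length(elements)) {
      abort("inconsistent atom counts across frames")
    }
    frames[[k]] <- xyz
    i <- i + 2L + n
  }
  build_traj_from_frames(frames, times, elements, box, frame_interval,
                         charges = charges, masses = masses)
}

read_pdb <- function(path, frame_interval = 1) {
  lines <- readLines(path)
  is_atom <- grepl("^(ATOM |HETATM)", lines)
  is_model_end <- grepl("^(ENDMDL|END\\s*$)", lines)
  frames <- list()
  cur <- list()
  elements_all <- list()
  flush_frame <- function() {
    if (length(cur) == 0) return(invisible(NULL))
    m <- do.call(rbind, cur)
    frames[[length(frames) + 1L]] <<- m / 10  # Angstrom -> nm
    cur <<- list()
  }
  el_cur <- character()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (is_atom[i]) {
      x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
      y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
      z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
      if (anyNA(c(x, y, z))) {
        abort(sprintf("pdb parse error at line %d: bad coordinates", i))
      }
      el <- trimws(substr(ln, 77, 78))
      if (el == "") el <- substr(trimws(substr(ln, 13, 16)), 1, 1)
      cur[[length(cur) + 1L]] <- c(x, y, z)
      el_cur <- c(el_cur, el)
    } else if (is_model_end[i] && length(cur) > 0) {
      elements_all[[length(elements_all) + 1L]] <- el_cur
      el_cur <- character()
      flush_frame()
    }
  }
  if (length(cur) > 0) {
    elements_all[[length(elements_all) + 1L]] <- el_cur
    flush_frame()
  }
  if (length(frames) == 0) abort("pdb file contains no ATOM records")
  n0 <- nrow(frames[[1]])
  if (any(vapply(frames, nrow, 0L) != n0)) {
    abort("inconsistent atom counts across frames")
  }
  times <- (seq_along(frames) - 1) * frame_interval
  build_traj_from_frames(frames, times, elements_all[[1]], NA_real_, frame_interval)
}

read_gro <- function(path, frame_interval = 1) {
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  elements <- NULL
  times <- c()
  box <- NA_real_
  k <- 0L
  while (i <= length(lines)) {
    if (i + 1L > length(lines)) break
    title <- lines[i]
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n)) abort(sprintf("gro parse error at line %d: expected atom count", i + 1L))
    if (i + 2L + n > length(lines)) abort(sprintf("gro parse error at line %d: truncated frame", i))
    body <- lines[(i + 2L):(i + 1L + n)]
    x <- suppressWarnings(as.numeric(substr(body, 21, 28)))
    y <- suppressWarnings(as.numeric(substr(body, 29, 36)))
    z <- suppressWarnings(as.numeric(substr(body, 37, 44)))
    if (anyNA(c(x, y, z))) {
      abort(sprintf("gro parse error near line %d: bad coordinates",
                    i + 1L + which(is.na(x + y + z))[1]))
    }
    el <- substr(trimws(substr(body, 11, 15)), 1, 1)
    boxline <- strsplit(trimws(lines[i + 2L + n]), "\\s+")[[1]]
    box <- suppressWarnings(as.numeric(boxline[1]))
    t_tok <- regmatches(title, regexpr("t=\\s*\\S+", title))
    k <- k + 1L
    times[k] <- if (length(t_tok) == 1) as.numeric(sub("t=\\s*", "", t_tok)) else (k - 1) * frame_interval
    if (k == 1L) {
      elements <- el
    } else if (n != length(elements)) {
      abort("inconsistent atom counts across frames")
    }
    frames[[k]] <- cbind(x, y, z)
    i <- i + 3L + n
  }
  if (length(frames) == 0) abort("gro file contains no frames")
  build_traj_from_frames(frames, times, elements, box, frame_interval)
}

build_traj_from_frames <- function(frames, times, elements, box, frame_interval,
                                   charges = NULL, masses = NULL) {
  n <- nrow(frames[[1]])
  long <- purrr::map2_dfr(frames, seq_along(frames), function(m, k) {
    tibble(frame = k, time = times[k], atom_id = seq_len(n),
           x = m[, 1], y = m[, 2], z = m[, 3])
  })
  topo <- tibble(atom_id = seq_len(n), element = elements,
                 mass = if (is.null(masses)) rep(1, n) else masses,
                 charge = if (is.null(charges)) rep(0, n) else charges,
                 role = "other", group_id = NA_integer_)
  new_trajectory(long, topo, box_edge = box, frame_interval = frame_interval)
}

#' Write a trajectory as extended XYZ
#'
#' One block per frame: atom count, a comment line carrying `time=` and
#' `box=` tokens, then `element x y z charge mass` per atom, in nm.
#'
#' @param traj A `dendri_trajectory`.
#' @param path Output path.
#' @param digits Coordinate precision (decimal places).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  topo <- traj$topology
  for (k in frame_index(traj)) {
    fr <- traj$frames[traj$frames$frame == k, ]
    writeLines(as.character(nrow(fr)), con)
    writeLines(sprintf("time=%g box=%g", fr$time[1],
                       ifelse(is.na(traj$box_edge), 0, traj$box_edge)), con)
    writeLines(sprintf("%s %.*f %.*f %.*f %.6g %.6g",
                       topo$element, digits, fr$x, digits, fr$y, digits, fr$z,
                       topo$charge, topo$mass), con)
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## Topology / selection specification

#' Read a topology/selection specification
#'
#' The spec is a YAML or JSON document with (all optional except `atoms`):
#'
#' * `atoms`: list of blocks, each with `ids` (vector or `"a-b"` range
#'   string) and any of `role`, `element`, `mass`, `charge`, `group`.
#' * `planar_groups`: list of `{group_id, triple, center_atoms, spacer_id}`.
#' * `guests`: list of atom-id vectors, one per guest molecule.
#' * `donors`, `acceptors`: atom-id vectors; `hydrogens`: list of
#'   `{hydrogen, donor}` pairs.
#' * `branch_pairs`: list of 2-vectors of branch-point atom ids
#'   (consecutive branching points defining a spacer).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A topology specification list for [attach_topology()].
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

parse_id_spec <- function(ids) {
  if (is.character(ids) && length(ids) == 1 && grepl("^\\s*\\d+\\s*-\\s*\\d+\\s*$", ids)) {
    ab <- as.integer(strsplit(ids, "-")[[1]])
    return(seq.int(ab[1], ab[2]))
  }
  as.integer(unlist(ids))
}

#' Attach topology attributes and selections to a trajectory
#'
#' Populates per-atom roles/masses/charges/groups from a specification (a
#' list as returned by [read_topology()], or the path to one), validates all
#' referenced atom ids and planar triples, and caches the named selections
#' used by downstream stages. The dendrimer bare charge is recomputed and
#' must equal the sum of terminal and inserted-group charges by construction.
#'
#' @param traj A `dendri_trajectory`.
#' @param topo_spec Specification list or file path.
#' @return The trajectory with topology and selections populated.
#' @export
attach_topology <- function(traj, topo_spec) {
  if (is.character(topo_spec)) topo_spec <- read_topology(topo_spec)
  topo <- traj$topology
  all_ids <- topo$atom_id
  check_ids <- function(ids, what) {
    bad <- setdiff(ids, all_ids)
    if (length(bad) > 0) {
      abort(sprintf("%s references unknown atom id(s): %s", what,
                    paste(head(bad, 5), collapse = ", ")))
    }
    ids
  }
  for (blk in topo_spec$atoms %||% list()) {
    ids <- check_ids(parse_id_spec(blk$ids), "atoms block")
    sel <- topo$atom_id %in% ids
    if (!is.null(blk$role)) {
      if (!blk$role %in% atom_roles()) abort(sprintf("unknown role '%s'", blk$role))
      topo$role[sel] <- blk$role
    }
    if (!is.null(blk$element)) topo$element[sel] <- blk$element
    if (!is.null(blk$mass)) topo$mass[sel] <- blk$mass
    if (!is.null(blk$charge)) topo$charge[sel] <- blk$charge
    if (!is.null(blk$group)) topo$group_id[sel] <- as.integer(blk$group)
  }
  sels <- traj$selections
  pg <- topo_spec$planar_groups %||% NULL
  if (!is.null(pg)) {
    pg_tbl <- purrr::map_dfr(pg, function(g) {
      tibble(group_id = as.integer(g$group_id),
             spacer_id = as.integer(g$spacer_id %||% g$group_id),
             triple = list(check_ids(as.integer(unlist(g$triple)), "planar triple")),
             center_atoms = list(check_ids(
               as.integer(unlist(g$center_atoms %||% g$triple)), "center_atoms")))
    })
    bad_triple <- vapply(pg_tbl$triple, function(tr) length(unique(tr)) != 3, TRUE)
    if (any(bad_triple)) abort("every planar triple needs 3 distinct atoms")
    fr1 <- frame_atoms(traj, frame_index(traj)[1])
    for (j in seq_len(nrow(pg_tbl))) {
      p <- as.matrix(fr1[match(pg_tbl$triple[[j]], fr1$atom_id), c("x", "y", "z")])
      a <- 0.5 * sqrt(sum(cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])^2))
      if (a < 1e-6) {
        abort(sprintf("planar triple of group %d is collinear (area %.2g nm^2)",
                      pg_tbl$group_id[j], a))
      }
    }
    sels$planar_groups <- pg_tbl
  }
  if (!is.null(topo_spec$guests)) {
    sels$guests <- lapply(topo_spec$guests, function(g)
      check_ids(as.integer(unlist(g)), "guest molecule"))
  }
  if (!is.null(topo_spec$donors)) {
    sels$donors <- check_ids(as.integer(unlist(topo_spec$donors)), "donors")
  }
  if (!is.null(topo_spec$acceptors)) {
    sels$acceptors <- check_ids(as.integer(unlist(topo_spec$acceptors)), "acceptors")
  }
  if (!is.null(topo_spec$hydrogens)) {
    hs <- topo_spec$hydrogens
    if (is.data.frame(hs)) {
      hy <- tibble(hydrogen = as.integer(hs$hydrogen), donor = as.integer(hs$donor))
    } else {
      hy <- purrr::map_dfr(hs, function(h)
        tibble(hydrogen = as.integer(h$hydrogen), donor = as.integer(h$donor)))
    }
    check_ids(hy$hydrogen, "hydrogens")
    check_ids(hy$donor, "hydrogen donors")
    sels$hydrogens <- hy
  }
  if (!is.null(topo_spec$branch_pairs)) {
    bp <- lapply(topo_spec$branch_pairs, function(p) {
      p <- as.integer(unlist(p))
      if (length(p) != 2) abort("each branch pair needs exactly 2 atom ids")
      check_ids(p, "branch pair")
    })
    sels$branch_pairs <- bp
  }
  ## role-disjointness the analyses rely on
  if (any(topo$role == "counterion" & topo$role %in% c("dendrimer", "terminal_N"))) {
    abort("an atom cannot be both counterion and dendrimer")  # unreachable by construction
  }
  traj$topology <- topo
  traj$selections <- sels
  traj
}
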