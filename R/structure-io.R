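#' Read a PDB structure
#'
#' Parses ATOM/HETATM records of a PDB file into an `arp_structure`: an atom
#' table plus an N x 3 coordinate matrix in angstroms. Alternate-location
#' conformers are reduced to the highest-occupancy one; insertion codes are
#' rejected (they do not occur in the coordinate models this package
#' targets).
#'
#' @param path path to a PDB file.
#' @param hetatm keep HETATM records (default `TRUE`).
#' @return an object of class `arp_structure` with elements
#'   * `atoms`: data.frame with columns `eleno`, `elety` (atom name),
#'     `resid` (residue name), `chain`, `resno`, `elesy` (element symbol);
#'   * `xyz`: numeric matrix with one row per atom, columns x, y, z (A).
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(c(
#'   "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
#'   "END"), pdb)
#' s <- read_structure(pdb)
#' s$xyz
#' @export
read_structure <- function(path, hetatm = TRUE) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, rm.alt = TRUE, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (!hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms found in '", path, "'")
  if (any(!is.na(at$insert) & nzchar(at$insert)))
    stop("insertion codes are not supported (file '", path, "')")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("non-finite coordinates in '", path, "'")
  new_structure(
    atoms = data.frame(
      eleno = at$eleno, elety = at$elety, resid = at$resid,
      chain = ifelse(is.na(at$chain), " ", at$chain), resno = at$resno,
      elesy = guess_element(at$elety, at$elesy),
      stringsAsFactors = FALSE),
    xyz = xyz)
}

new_structure <- function(atoms, xyz) {
  stopifnot(nrow(atoms) == nrow(xyz), ncol(xyz) == 3)
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, xyz = xyz), class = "arp_structure")
}

# Element symbol from the PDB element column when present, else from the
# leading letter of the atom name (adequate for protein heavy atoms + H).
guess_element <- function(elety, elesy = NULL) {
  if (!is.null(elesy)) {
    elesy <- toupper(trimws(elesy))
    bad <- is.na(elesy) | !nzchar(elesy)
  } else {
    elesy <- rep(NA_character_, length(elety))
    bad <- rep(TRUE, length(elety))
  }
  if (any(bad)) {
    nm <- gsub("[^A-Za-z].*$", "", trimws(elety[bad]))
    elesy[bad] <- toupper(substr(nm, 1, 1))
  }
  elesy
}

#' Write a structure (or trajectory) to a PDB file
#'
#' Single structures produce one MODEL; trajectories produce a multi-model
#' PDB readable by [read_trajectory()].
#'
#' @param x an `arp_structure` or `arp_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "arp_trajectory")) {
    top <- x$topology
    n <- n_frames(x)
    con <- file(path, "w")
    on.exit(close(con))
    for (f in seq_len(n)) {
      writeLines(sprintf("MODEL     %4d", f), con)
      writeLines(pdb_atom_lines(top$atoms, frame_xyz(x, f)), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    stopifnot(inherits(x, "arp_structure"))
    writeLines(c(pdb_atom_lines(x$atoms, x$xyz), "END"), path)
  }
  invisible(path)
}

pdb_atom_lines <- function(atoms, xyz) {
  nm <- trimws(atoms$elety)
  nm <- ifelse(nchar(nm) <= 3, paste0(" ", nm), nm)  # short names start col 14
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          atoms$eleno %% 100000, nm,
          atoms$resid, atoms$chain, atoms$resno,
          xyz[, 1], xyz[, 2], xyz[, 3], atoms$elesy)
}

#' Read a trajectory against a topology
#'
#' Supported containers: multi-model PDB and (CHARMM/NAMD) DCD. Several files
#' are concatenated in argument order. Frame coordinates are in angstroms.
#'
#' @param topology an `arp_structure` defining atom identities.
#' @param paths character vector of trajectory files (`.pdb` or `.dcd`).
#' @param dt_ps optional frame interval in picoseconds (> 0).
#' @return an `arp_trajectory`: list with `topology`, `coords` (array
#'   frames x atoms x 3) and `time_ps`.
#' @export
read_trajectory <- function(topology, paths, dt_ps = NULL) {
  stopifnot(inherits(topology, "arp_structure"))
  if (!is.null(dt_ps) && dt_ps <= 0) stop("dt_ps must be > 0")
  nat <- nrow(topology$atoms)
  frames <- list()
  for (p in paths) {
    if (!file.exists(p)) stop("trajectory file not found: ", p)
    if (grepl("\\.dcd$", p, ignore.case = TRUE)) {
      m <- bio3d::read.dcd(p, verbose = FALSE)   # nframe x 3N matrix
      if (ncol(m) != 3L * nat)
        stop("atom-count mismatch: topology has ", nat, " atoms, DCD '",
             p, "' has ", ncol(m) / 3L)
      frames <- c(frames, lapply(seq_len(nrow(m)), function(i)
        matrix(m[i, ], ncol = 3, byrow = TRUE)))
    } else {
      mods <- read_multimodel_pdb(p)
      for (m in mods) {
        if (nrow(m) != nat)
          stop("atom-count mismatch: topology has ", nat, " atoms, '",
               p, "' model has ", nrow(m))
        frames <- c(frames, list(m))
      }
    }
  }
  if (length(frames) == 0) stop("no frames read from ", paste(paths, collapse = ", "))
  new_trajectory(topology, frames, dt_ps)
}

# Multi-model PDB coordinate extraction (fixed-width columns per the PDB
# specification); returns a list of N x 3 matrices, one per MODEL.
read_multimodel_pdb <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_id <- cumsum(rec == "MODEL ")
  if (max(model_id) == 0) model_id <- rep(1L, length(lines))
  keep <- which(is_atom)
  if (length(keep) == 0) stop("no ATOM records in '", path, "'")
  xs <- suppressWarnings(as.numeric(substr(lines[keep], 31, 38)))
  ys <- suppressWarnings(as.numeric(substr(lines[keep], 39, 46)))
  zs <- suppressWarnings(as.numeric(substr(lines[keep], 47, 54)))
  bad <- which(!is.finite(xs) | !is.finite(ys) | !is.finite(zs))
  if (length(bad))
    stop("malformed ATOM record at line ", keep[bad[1]], " of '", path, "'")
  split_id <- model_id[keep]
  split_id[split_id == 0] <- 1L
  lapply(split(seq_along(keep), split_id), function(i)
    cbind(x = xs[i], y = ys[i], z = zs[i]))
}

new_trajectory <- function(topology, frames, dt_ps = NULL) {
  nat <- nrow(topology$atoms)
  coords <- array(NA_real_, dim = c(length(frames), nat, 3))
  for (i in seq_along(frames)) coords[i, , ] <- frames[[i]]
  time_ps <- if (is.null(dt_ps)) seq_along(frames) - 1
             else (seq_along(frames) - 1) * dt_ps
  structure(list(topology = topology, coords = coords, time_ps = time_ps),
            class = "arp_trajectory")
}

#' Number of frames in a trajectory (1 for a structure)
#' @param x an `arp_structure` or `arp_trajectory`.
#' @export
n_frames <- function(x) {
  if (inherits(x, "arp_trajectory")) dim(x$coords)[1] else 1L
}

#' Coordinates of one frame as an N x 3 matrix
#' @param x an `arp_structure` or `arp_trajectory`.
#' @param frame frame index (1-based).
#' @export
frame_xyz <- function(x, frame = 1L) {
  if (inherits(x, "arp_trajectory")) {
    m <- x$coords[frame, , , drop = FALSE]
    dim(m) <- dim(m)[2:3]
    colnames(m) <- c("x", "y", "z")
    m
  } else {
    stopifnot(frame == 1L)
    x$xyz
  }
}

#' Promote a structure to a one-frame trajectory
#' @param x an `arp_structure` (an `arp_trajectory` passes through).
#' @export
as_trajectory <- function(x) {
  if (inherits(x, "arp_trajectory")) return(x)
  stopifnot(inherits(x, "arp_structure"))
  new_trajectory(x, list(x$xyz))
}

topology_of <- function(x) if (inherits(x, "arp_trajectory")) x$topology else x

#' @export
print.arp_structure <- function(x, ...) {
  cat("arp_structure:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chains (",
      paste(sort(unique(x$atoms$chain)), collapse = " "), ")\n")
  invisible(x)
}

#' @export
print.arp_trajectory <- function(x, ...) {
  cat("arp_trajectory:", n_frames(x), "frames x",
      nrow(x$topology$atoms), "atoms\n")
  invisible(x)
}
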