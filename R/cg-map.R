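#' Center of geometry of an atom set
#'
#' Unweighted arithmetic mean of the selected atom coordinates, the bead
#' primitive behind every order parameter and the steering engine. By
#' construction it is equivariant under global translation and rotation.
#'
#' @param x an `arp_structure` or `arp_trajectory`.
#' @param atom_set integer atom indices (from [select_atoms()]).
#' @param frame frame index.
#' @return numeric length-3 vector (x, y, z) in angstroms.
#' @export
cog <- function(x, atom_set, frame = 1L) {
  if (length(atom_set) == 0) stop("cog() of an empty atom set")
  m <- frame_xyz(x, frame)
  colMeans(m[atom_set, , drop = FALSE])
}

#' Map atom selections to coarse-grained bead tracks
#'
#' Computes per-frame COG coordinates for a list of named atom selections
#' ("beads"). Subdomain beads use backbone atoms only, matching the
#' convention the order parameters are defined with.
#'
#' @param x an `arp_structure` or `arp_trajectory`.
#' @param bead_spec named list; each element an integer atom-index vector,
#'   or a list of arguments forwarded to [select_atoms()].
#' @param registry required when `bead_spec` entries are selection argument
#'   lists.
#' @return a `bead_mapping`: list with `labels`, `atom_sets`, and `coords`
#'   (array frames x beads x 3, angstrom).
#' @export
map_beads <- function(x, bead_spec, registry = NULL) {
  if (is.null(names(bead_spec)) || any(!nzchar(names(bead_spec))))
    stop("bead_spec must be a fully named list")
  if (anyDuplicated(names(bead_spec)))
    stop("bead labels must be unique")
  atom_sets <- lapply(names(bead_spec), function(lb) {
    sp <- bead_spec[[lb]]
    if (is.numeric(sp)) return(as.integer(sp))
    if (is.list(sp)) {
      if (is.null(registry)) stop("registry needed to resolve bead '", lb, "'")
      return(tryCatch(do.call(select_atoms, c(list(x, registry), sp)),
                      error = function(e) stop("bead '", lb, "' failed to resolve: ",
                                               conditionMessage(e), call. = FALSE)))
    }
    stop("bead '", lb, "' must be atom indices or a selection list")
  })
  names(atom_sets) <- names(bead_spec)
  if (any(lengths(atom_sets) == 0)) stop("beads must contain at least one atom")
  nf <- n_frames(x)
  coords <- array(NA_real_, dim = c(nf, length(atom_sets), 3),
                  dimnames = list(NULL, names(atom_sets), c("x", "y", "z")))
  for (f in seq_len(nf)) {
    m <- frame_xyz(x, f)
    for (b in seq_along(atom_sets))
      coords[f, b, ] <- colMeans(m[atom_sets[[b]], , drop = FALSE])
  }
  structure(list(labels = names(atom_sets), atom_sets = atom_sets,
                 coords = coords),
            class = "bead_mapping")
}

#' @export
print.bead_mapping <- function(x, ...) {
  cat("bead_mapping:", length(x$labels), "beads x", dim(x$coords)[1],
      "frames\n")
  invisible(x)
}

# the four subdomain backbone beads of an actin-fold subunit, in the
# torsion order subdomain 2, 1, 3, 4
subdomain_bead_spec <- function(subunit) {
  sets <- lapply(c(2L, 1L, 3L, 4L), function(s)
    list(subunit = subunit, subdomain = s, backbone = TRUE))
  names(sets) <- paste0(subunit, "_sd", c(2L, 1L, 3L, 4L))
  sets
}

# clamp Bead 1..4 atom-set spec from the registry definition
clamp_bead_spec <- function(registry) {
  cb <- registry$clamp_beads
  if (length(cb) != 4) stop("clamp definition must have exactly four beads")
  sets <- lapply(cb, function(b)
    list(subunit = b$subunit,
         resno = unlist(lapply(b$resno, function(ab) seq(ab[[1]], ab[[2]]))),
         backbone = TRUE))
  names(sets) <- paste0("clamp_bead", 1:4)
  sets
}
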