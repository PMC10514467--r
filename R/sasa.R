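#' Deterministic generalized-spiral points on the unit sphere
#'
#' The fixed point set used by the Shrake-Rupley sampler; deterministic so
#' that SASA values are bit-reproducible for a given point count.
#'
#' @param n number of points.
#' @return an n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  stopifnot(n >= 1)
  k <- seq_len(n)
  # generalized spiral (golden-angle) construction
  z <- (2 * k - 1) / n - 1
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

default_radii <- function(config = arptraj_config()) {
  unlist(config$sasa$radii)
}

atom_radii <- function(atoms, radii) {
  r <- radii[atoms$elesy]
  if (any(is.na(r))) {
    bad <- unique(atoms$elesy[is.na(r)])
    stop("no van der Waals radius configured for element(s): ",
         paste(bad, collapse = ", "))
  }
  unname(r)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by deterministic sphere-point sampling: each atom's van
#' der Waals sphere is expanded by the probe radius and covered with a
#' fixed generalized-spiral point set; points inside any neighbouring
#' expanded sphere are buried. Hydrogens are excluded by default (the
#' crystal/cryo-EM models this package targets carry none).
#'
#' @param x an `arp_structure` or `arp_trajectory`.
#' @param atom_set atoms forming the system (occluders + evaluated);
#'   default all atoms.
#' @param frame frame index.
#' @param probe probe radius in angstroms (default 1.4, a water molecule).
#' @param n_points sphere points per atom (default 960).
#' @param radii named vector of per-element radii (A); defaults from the
#'   shipped config.
#' @param include_h include hydrogen atoms.
#' @return a `sasa_result`: list with `area` (per-atom A^2, named by atom
#'   index), `atom_set`, `probe`, `n_points`.
#' @export
sasa <- function(x, atom_set = NULL, frame = 1L, probe = 1.4,
                 n_points = 960L, radii = default_radii(),
                 include_h = FALSE) {
  if (probe < 0) stop("probe radius must be >= 0")
  top <- topology_of(x)
  if (is.null(atom_set)) atom_set <- seq_len(nrow(top$atoms))
  if (!include_h)
    atom_set <- atom_set[top$atoms$elesy[atom_set] != "H"]
  if (length(atom_set) == 0) stop("sasa() of an empty atom set")
  m <- frame_xyz(x, frame)[atom_set, , drop = FALSE]
  r <- atom_radii(top$atoms[atom_set, , drop = FALSE], radii)
  a <- sasa_cpp(m, r, probe, sphere_points(n_points),
                seq_along(atom_set))
  structure(list(area = setNames(a, atom_set), atom_set = atom_set,
                 probe = probe, n_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat("sasa_result:", length(x$area), "atoms, total",
      round(sum(x$area), 1), "A^2 (probe", x$probe, "A,",
      x$n_points, "points)\n")
  invisible(x)
}

#' Buried surface area between two atom groups
#'
#' Computes BSA = (SASA1 + SASA2 - SASA12) / 2 per frame, where SASA1 and
#' SASA2 are the areas of each group computed with the other group absent
#' and SASA12 is the area of the combined system. Only the two groups are
#' present in any of the three calculations.
#'
#' @param x an `arp_structure` or `arp_trajectory`.
#' @param group1,group2 disjoint integer atom-index vectors.
#' @param frames frame indices (default all).
#' @inheritParams sasa
#' @return a `bsa_result`: data.frame with columns `frame`, `sasa1`,
#'   `sasa2`, `sasa12`, `bsa` (A^2).
#' @export
bsa <- function(x, group1, group2, frames = NULL, probe = 1.4,
                n_points = 960L, radii = default_radii(),
                include_h = FALSE) {
  if (length(intersect(group1, group2)))
    stop("group1 and group2 must be disjoint (",
         length(intersect(group1, group2)), " shared atoms)")
  if (is.null(frames)) frames <- seq_len(n_frames(x))
  group1 <- sort(group1); group2 <- sort(group2)
  both <- sort(c(group1, group2))   # fixed atom order: bsa(A,B) == bsa(B,A)
  rows <- lapply(frames, function(f) {
    s1 <- sum(sasa(x, group1, f, probe, n_points, radii, include_h)$area)
    s2 <- sum(sasa(x, group2, f, probe, n_points, radii, include_h)$area)
    s12 <- sum(sasa(x, both, f, probe, n_points, radii,
                    include_h)$area)
    data.frame(frame = f, sasa1 = s1, sasa2 = s2, sasa12 = s12,
               bsa = (s1 + s2 - s12) / 2)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bsa_result", "data.frame")
  out
}

#' BSA of the Arp2/3 complex with the mother filament
#'
#' Convenience wrapper applying the registry's exclusion list: mother
#' filament subunits marked non-interacting (by default MA1, MA0, MA5,
#' MA7, MA8) are dropped from the filament group before the BSA
#' computation, as is done when tracking the interface over trajectories.
#'
#' @inheritParams bsa
#' @param registry a `subunit_registry`.
#' @param complex_subunits canonical names of the complex group (default
#'   the seven Arp2/3 subunits present).
#' @param apply_exclusions drop the registry's `mf_excluded` subunits.
#' @return a `bsa_result` (see [bsa()]).
#' @export
mother_filament_bsa <- function(x, registry,
                                complex_subunits = NULL,
                                apply_exclusions = TRUE, frames = NULL,
                                probe = 1.4, n_points = 960L,
                                radii = default_radii()) {
  subs <- subunits(registry)
  if (is.null(complex_subunits))
    complex_subunits <- intersect(
      c("Arp2", "Arp3", paste0("ARPC", 1:5)), subs)
  mf <- grep("^MA", subs, value = TRUE)
  if (apply_exclusions) mf <- setdiff(mf, registry$mf_excluded)
  if (length(mf) == 0) stop("no mother-filament subunits in registry")
  g1 <- select_atoms(x, registry, subunit = complex_subunits)
  g2 <- select_atoms(x, registry, subunit = mf)
  bsa(x, g1, g2, frames = frames, probe = probe, n_points = n_points,
      radii = radii)
}
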