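#' @name synthetic-data
#' @title Synthetic pseudo-atomic systems with known ground truth
#'
#' @description
#' Generators for pseudo-atomic structures and trajectories whose
#' conformational order parameters are known exactly by construction, so
#' that every pipeline stage (PDB round trip, registry resolution, bead
#' mapping, order parameters, interfaces, steering) can be validated
#' without external data.
#'
#' Each pseudo-subunit is a rigid cluster of pseudo-residues (four
#' backbone atoms per residue, non-coplanar, zero-sum offsets) so that
#' subdomain COGs coincide exactly with prescribed subdomain centers. The
#' four subdomain centers of each Arp are placed by internal coordinates
#' with a prescribed torsion, so the twisting/flattening dihedral phi and
#' the Arp2-Arp3 inner-domain distance realize requested time courses
#' exactly; isotropic Gaussian positional noise (independent across atoms
#' and frames) is added on top.
NULL

## geometric constants of the synthetic subunit layout (angstrom)
.syn <- list(
  bond = 16, theta = 100 * pi / 180,   # subdomain-center chain geometry
  clamp_bond = 12, clamp_theta = 110 * pi / 180,
  spd_dir = c(cos(20 * pi / 180), sin(20 * pi / 180), 0))

# place D from A, B, C with |CD| = bond, angle(BCD) = theta and
# torsion(A,B,C,D) = phi (radians); standard internal-coordinate placement
place_dihedral <- function(A, B, C, bond, theta, phi) {
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + bond * (-cos(theta) * bc + sin(theta) * cos(phi) * m -
              sin(theta) * sin(phi) * n)
}

# zero-sum, non-coplanar backbone-atom offsets: 3 residues x (N, CA, C, O)
residue_offsets <- function() {
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * 0.7
  centers <- rbind(c(2.4, 0, 0), c(-1.2, 2.1, 0), c(-1.2, -2.1, 0))
  list(res_centers = centers, atom_offsets = tet,
       elety = c("N", "CA", "C", "O"))
}

# atoms of one subdomain cluster (3 residues) around a center point
cluster_atoms <- function(center, resno_base, chain) {
  off <- residue_offsets()
  rows <- list()
  for (r in 1:3) {
    pos <- matrix(rep(center + off$res_centers[r, ], each = 4), ncol = 3,
                  byrow = FALSE) + off$atom_offsets
    rows[[r]] <- list(
      atoms = data.frame(elety = off$elety, resid = "ALA", chain = chain,
                         resno = resno_base + r - 1L, elesy = "C",
                         stringsAsFactors = FALSE),
      xyz = pos)
  }
  list(atoms = do.call(rbind, lapply(rows, `[[`, "atoms")),
       xyz = do.call(rbind, lapply(rows, `[[`, "xyz")))
}

# one-residue bead (4 atoms, zero-sum) at an exact point
bead_residue <- function(center, resno, chain, elety = c("N", "CA", "C", "O")) {
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * 0.7
  list(atoms = data.frame(elety = elety, resid = "ALA", chain = chain,
                          resno = resno, elesy = "C",
                          stringsAsFactors = FALSE),
       xyz = sweep(tet, 2, center, `+`))
}

# a single anchor residue whose CA sits exactly at `ca_pos`
anchor_residue <- function(ca_pos, resno, chain) {
  off <- rbind(N = c(-1.4, 0.5, 0), CA = c(0, 0, 0),
               C = c(1.4, 0.4, 0.3), O = c(2.2, 1.3, 0.1))
  list(atoms = data.frame(elety = rownames(off), resid = "ALA",
                          chain = chain, resno = resno, elesy = "C",
                          stringsAsFactors = FALSE),
       xyz = sweep(off, 2, ca_pos, `+`))
}

# subdomain centers c1..c4 of an actin-fold subunit with torsion
# (c2, c1, c3, c4) = phi (degrees), in the subunit's local frame
subdomain_centers <- function(phi_deg) {
  b <- .syn$bond; th <- .syn$theta
  c1 <- c(0, 0, 0)
  c3 <- c(b, 0, 0)
  c2 <- b * c(cos(th), sin(th), 0)
  c4 <- place_dihedral(c2, c1, c3, b, th, phi_deg * pi / 180)
  rbind(c1 = c1, c2 = c2, c3 = c3, c4 = c4)
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
}

# coordinates of one synthetic frame (matrix only; block order fixed and
# shared with synthetic_atoms below).
# pars: list(short_pitch, phi_arp2, phi_arp3, clamp, dloop, wloop)
synthetic_xyz <- function(pars) {
  off <- residue_offsets()
  cluster_xyz <- function(center) {
    pos <- matrix(NA_real_, 12, 3)
    for (r in 1:3)
      pos[(4 * r - 3):(4 * r), ] <-
        sweep(off$atom_offsets, 2, center + off$res_centers[r, ], `+`)
    pos
  }
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * 0.7
  anchor_off <- rbind(c(-1.4, 0.5, 0), c(0, 0, 0), c(1.4, 0.4, 0.3),
                      c(2.2, 1.3, 0.1))
  parts <- list()
  add <- function(m) parts[[length(parts) + 1L]] <<- m

  ## Arp3 (chain A) at the origin
  cen3 <- subdomain_centers(pars$phi_arp3)
  for (sd in 1:4) add(cluster_xyz(cen3[sd, ]))
  inner3 <- (cen3["c3", ] + cen3["c4", ]) / 2

  ## Arp2 (chain B): built locally, rotated, translated so its inner-domain
  ## COG sits short_pitch angstroms from Arp3's along a fixed direction
  cen2 <- subdomain_centers(pars$phi_arp2) %*% t(rot_z(180))
  inner2_local <- (cen2[3, ] + cen2[4, ]) / 2
  shift <- inner3 + pars$short_pitch * .syn$spd_dir - inner2_local
  cen2 <- sweep(cen2, 2, shift, `+`)
  for (sd in 1:4) add(cluster_xyz(cen2[sd, ]))
  inner2 <- (cen2[3, ] + cen2[4, ]) / 2

  ## anchor residues on Arp2: D-loop anchor (resno 20) and the W-loop pair
  ## (resno 21/22) with the scheduled separations
  q_dloop <- inner2 + c(0, 18, 10)
  add(sweep(anchor_off, 2, q_dloop, `+`))
  w0 <- inner2 + c(0, -18, 8)
  add(sweep(anchor_off, 2, w0 + c(0, pars$wloop / 2, 0), `+`))
  add(sweep(anchor_off, 2, w0 - c(0, pars$wloop / 2, 0), `+`))

  ## ARPC3 (chain E): anchor residue 20 at the scheduled D-loop distance,
  ## plus a body cluster nearby
  q_c3 <- q_dloop + c(0, 0, pars$dloop)
  add(sweep(anchor_off, 2, q_c3, `+`))
  add(cluster_xyz(q_c3 + c(6, 0, 4)))

  ## clamp subunits ARPC2 (chain D) / ARPC4 (chain F): four one-residue
  ## beads on an internal-coordinate chain with torsion = clamp twist
  bc <- .syn$clamp_bond; tc <- .syn$clamp_theta
  b2 <- c(0, 0, -40)
  b3 <- b2 + c(bc, 0, 0)
  b1 <- b2 + bc * c(cos(tc), sin(tc), 0)
  b4 <- place_dihedral(b1, b2, b3, bc, tc, pars$clamp * pi / 180)
  for (b in list(b1, b2, b3, b4)) add(sweep(tet, 2, b, `+`))

  ## remaining complex subunits as compact bodies (keep the registry and
  ## subunit-level CG beads fully populated)
  add(cluster_xyz(c(-20, -25, -15)))   # ARPC1
  add(cluster_xyz(c(35, -25, -15)))    # ARPC5

  do.call(rbind, parts)
}

# atom table matching the block order of synthetic_xyz
synthetic_atoms <- function() {
  parts <- list()
  add <- function(p) parts[[length(parts) + 1L]] <<- p$atoms
  zero <- c(0, 0, 0)
  for (sd in 1:4) add(cluster_atoms(zero, c(1L, 4L, 7L, 10L)[sd], "A"))
  for (sd in 1:4) add(cluster_atoms(zero, c(1L, 4L, 7L, 10L)[sd], "B"))
  add(anchor_residue(zero, 20L, "B"))
  add(anchor_residue(zero, 21L, "B"))
  add(anchor_residue(zero, 22L, "B"))
  add(anchor_residue(zero, 20L, "E"))
  add(cluster_atoms(zero, 1L, "E"))
  add(bead_residue(zero, 1L, "D"))
  add(bead_residue(zero, 2L, "D"))
  add(bead_residue(zero, 1L, "F"))
  add(bead_residue(zero, 2L, "F"))
  add(cluster_atoms(zero, 1L, "C"))
  add(cluster_atoms(zero, 1L, "G"))
  atoms <- do.call(rbind, parts)
  atoms$eleno <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  atoms[, c("eleno", "elety", "resid", "chain", "resno", "elesy")]
}

# assemble one synthetic frame as a structure
synthetic_frame <- function(pars) {
  new_structure(synthetic_atoms(), synthetic_xyz(pars))
}

default_schedules <- function() list(
  short_pitch = c(42.7, 52.2),
  phi_arp2 = c(-3, -20), phi_arp3 = c(-3, -20),
  clamp = c(0, 30), dloop = c(6, 26), wloop = c(10, 6))

#' Specification for a synthetic trajectory
#'
#' @param n_frames number of frames.
#' @param noise_sd isotropic Gaussian positional noise per atom per frame
#'   (A); 0 for noise-free data.
#' @param seed RNG seed recorded in the ground truth.
#' @param schedules named list of metric time courses. Each entry is
#'   either a length-2 vector (linear start to end) or a data.frame with
#'   columns `at` (fractions in 0..1) and `value` (piecewise-linear
#'   breakpoints). Metrics: `short_pitch` (A), `phi_arp2`, `phi_arp3`,
#'   `clamp` (degrees), `dloop`, `wloop` (A).
#' @param dt_ps frame interval in ps.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_frames = 1000L, noise_sd = 0.5, seed = 1L,
                           schedules = list(), dt_ps = 100) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_frames < 1) stop("n_frames must be >= 1")
  sch <- modifyList(default_schedules(), schedules)
  for (m in names(sch)) {
    s <- sch[[m]]
    if (is.data.frame(s)) {
      if (!all(c("at", "value") %in% names(s)) || any(s$at < 0 | s$at > 1))
        stop("schedule '", m, "' breakpoints need columns at (0..1), value")
    } else if (length(s) != 2)
      stop("schedule '", m, "' must be length-2 or a breakpoint data.frame")
  }
  dist_vals <- unlist(lapply(sch[c("short_pitch", "dloop", "wloop")],
                             function(s) if (is.data.frame(s)) s$value else s))
  if (any(dist_vals <= 0)) stop("distance schedules must stay positive")
  structure(list(n_frames = as.integer(n_frames), noise_sd = noise_sd,
                 seed = as.integer(seed), schedules = sch, dt_ps = dt_ps),
            class = "synthetic_spec")
}

schedule_values <- function(sch, n) {
  fr <- if (n == 1) 0.5 else (seq_len(n) - 1) / (n - 1)
  vapply(names(sch), function(m) {
    s <- sch[[m]]
    if (is.data.frame(s)) approx(s$at, s$value, xout = fr, rule = 2)$y
    else if (n == 1) s[1] else approx(c(0, 1), s, xout = fr)$y
  }, numeric(n)) -> vals
  if (n == 1) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, names(sch)))
  as.data.frame(vals)
}

#' Generate active/inactive endpoint structures
#'
#' Two pseudo-atomic structures realizing the requested short-pitch
#' distances and twisting/flattening angles exactly (to construction
#' precision, < 1e-3 of the unit). Defaults correspond to the activation
#' endpoints: 42.7 A / flattened for the active (short-pitch) state and
#' 52.2 A / twisted for the inactive (splayed) state.
#'
#' @param short_pitch named or ordered length-2 vector
#'   `c(active, inactive)` of inner-domain distances (A).
#' @param phi length-2 vector `c(active, inactive)` of flattening
#'   dihedrals (degrees), applied to both Arps.
#' @param clamp,dloop,wloop endpoint values of the remaining metrics.
#' @return list with `active` and `inactive` `arp_structure`s.
#' @export
make_endpoints <- function(short_pitch = c(42.7, 52.2),
                           phi = c(-3, -20), clamp = c(0, 30),
                           dloop = c(6, 26), wloop = c(10, 6)) {
  if (any(short_pitch <= 0, dloop <= 0, wloop <= 0))
    stop("unrealizable geometry: distances must be positive")
  mk <- function(i) synthetic_frame(list(
    short_pitch = short_pitch[i], phi_arp2 = phi[i], phi_arp3 = phi[i],
    clamp = clamp[i], dloop = dloop[i], wloop = wloop[i]))
  list(active = mk(1), inactive = mk(2))
}

#' Generate a synthetic trajectory with recorded ground truth
#'
#' Frames realize the spec's metric schedules; independent isotropic
#' Gaussian noise (sd `noise_sd`) is added to every atom coordinate of
#' every frame. Regeneration with the same spec (including seed) is
#' bit-identical.
#'
#' @param spec a [synthetic_spec()].
#' @return a `synthetic_dataset`: list with `trajectory`
#'   (`arp_trajectory`), `ground_truth` (per-frame true metric values,
#'   with `noise_sd` and `seed` attributes) and `spec`.
#' @export
make_trajectory <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_frames
  gt <- schedule_values(spec$schedules, n)
  frames <- vector("list", n)
  for (f in seq_len(n)) {
    xyz <- synthetic_xyz(as.list(gt[f, , drop = FALSE]))
    if (spec$noise_sd > 0)
      xyz <- xyz + matrix(rnorm(length(xyz), sd = spec$noise_sd),
                          nrow(xyz), 3)
    frames[[f]] <- xyz
  }
  top <- new_structure(synthetic_atoms(), frames[[1]])
  gt <- cbind(frame = seq_len(n), gt)
  attr(gt, "noise_sd") <- spec$noise_sd
  attr(gt, "seed") <- spec$seed
  structure(list(trajectory = new_trajectory(top, frames, spec$dt_ps),
                 ground_truth = gt, spec = spec),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", x$spec$n_frames, "frames, noise sd",
      x$spec$noise_sd, "A, seed", x$spec$seed, "\n")
  invisible(x)
}

#' Two-cluster interface fixture
#'
#' A flat grid of carbon pseudo-atoms (group A, chain `A`) facing a
#' second grid (group B, chain `B`). Group B sits `separation` angstroms
#' away except for a designed contact patch of `patch_size` residues
#' protruding to `patch_gap` angstroms from group A. One atom per
#' residue; the designed patch residue numbers are recorded.
#'
#' @param nx,ny grid dimensions (atoms = residues per group).
#' @param spacing in-plane atom spacing (A).
#' @param separation A-to-B distance outside the patch (A).
#' @param patch_size number of contacting residues in the designed patch.
#' @param patch_gap atom-atom distance inside the patch (A); >= 0.
#' @return list with `structure` (an `arp_structure`), `group1`, `group2`
#'   (atom indices) and `patch_resno_b` (designed contact residues on the
#'   B side, which face patch residues 1..patch_size of A).
#' @export
make_interface_system <- function(nx = 6L, ny = 5L, spacing = 5,
                                  separation = 30, patch_size = 10L,
                                  patch_gap = 4) {
  if (patch_gap < 0) stop("patch_gap must be >= 0")
  n <- nx * ny
  if (patch_size > n) stop("patch_size exceeds grid size")
  gx <- rep(seq_len(nx), ny) * spacing
  gy <- rep(seq_len(ny), each = nx) * spacing
  a_xyz <- cbind(gx, gy, 0)
  b_z <- rep(separation, n)
  b_z[seq_len(patch_size)] <- patch_gap
  b_xyz <- cbind(gx, gy, b_z)
  atoms <- data.frame(
    eleno = seq_len(2 * n), elety = "C1", resid = "LIG",
    chain = rep(c("A", "B"), each = n),
    resno = rep(seq_len(n), 2), elesy = "C", stringsAsFactors = FALSE)
  list(structure = new_structure(atoms, rbind(a_xyz, b_xyz)),
       group1 = seq_len(n), group2 = n + seq_len(n),
       patch_resno_b = seq_len(patch_size))
}

#' Synthetic branch-junction stand-in
#'
#' A pseudo-atomic emulation of the branch-junction architecture: the
#' seven complex subunits as compact atom shells docked onto a 10-subunit
#' mother filament laid along x, arranged so that exactly the mother
#' subunits listed in `contact_subunits` touch the complex while the
#' registry's excluded subunits (MA1, MA0, MA5, MA7, MA8 by default) stay
#' clear of it. This object is a synthetic stand-in for a deposited
#' branch-junction coordinate model; its interface area is a property of
#' this construction, not of any deposited structure.
#'
#' @param subunit_radius shell radius of each pseudo-subunit (A).
#' @param n_shell atoms per subunit shell.
#' @param contact_subunits mother subunits designed to contact the
#'   complex.
#' @return an `arp_structure` using the `synthetic` dialect chain naming.
#' @export
make_branch_junction <- function(subunit_radius = 9, n_shell = 48L,
                                 contact_subunits = c("MA2", "MA3", "MA4",
                                                      "MA6", "MA9")) {
  syn_chains <- c(Arp3 = "A", Arp2 = "B", ARPC1 = "C", ARPC2 = "D",
                  ARPC3 = "E", ARPC4 = "F", ARPC5 = "G",
                  MA0 = "H", MA1 = "I", MA2 = "J", MA3 = "K", MA4 = "L",
                  MA5 = "M", MA6 = "N", MA7 = "O", MA8 = "P", MA9 = "Q",
                  DA1 = "R", DA2 = "S", DA3 = "T", DA4 = "U")
  shell <- function(center, chain) {
    pts <- sphere_points(n_shell) * subunit_radius
    xyz <- sweep(pts, 2, center, `+`)
    atoms <- data.frame(
      eleno = seq_len(n_shell), elety = "C1", resid = "SUB", chain = chain,
      resno = rep(seq_len(ceiling(n_shell / 4)), each = 4)[seq_len(n_shell)],
      elesy = "C", stringsAsFactors = FALSE)
    list(atoms = atoms, xyz = xyz)
  }
  ## mother filament: two-strand arrangement along x, complex side at y > 0
  d_axial <- 27.5
  mf_centers <- lapply(0:9, function(k)
    c(k * d_axial, ifelse(k %% 2 == 0, 0, 6), -2 * subunit_radius - 4))
  names(mf_centers) <- paste0("MA", 0:9)
  ## complex subunits above the filament; bodies above designed contacts
  touch_z <- -1   # shell gap ~2 A to a mother subunit directly below
  cplx <- list(
    Arp3  = c(2 * d_axial, 2, touch_z),                 # docks on MA2
    Arp2  = c(3 * d_axial, 8, touch_z),                 # docks on MA3
    ARPC3 = c(4 * d_axial, 2, touch_z),                 # docks on MA4
    ARPC2 = c(6 * d_axial, 8, touch_z),                 # arm onto MA6
    ARPC1 = c(9 * d_axial, 8, touch_z),                 # insert onto MA9
    ARPC4 = c(3.5 * d_axial, 4, touch_z + 2.2 * subunit_radius),
    ARPC5 = c(5.0 * d_axial, 4, touch_z + 2.2 * subunit_radius))
  ## daughter filament stubs pointing away from the mother filament
  da_centers <- lapply(1:4, function(k)
    c((2.5 + 0.4 * k) * d_axial, 10 + 2.2 * subunit_radius * k, touch_z))
  names(da_centers) <- paste0("DA", 1:4)

  centers <- c(cplx, mf_centers, da_centers)
  parts <- lapply(names(centers), function(su)
    shell(centers[[su]], syn_chains[[su]]))
  atoms <- do.call(rbind, lapply(parts, `[[`, "atoms"))
  xyz <- do.call(rbind, lapply(parts, `[[`, "xyz"))
  atoms$eleno <- seq_len(nrow(atoms))
  new_structure(atoms, xyz)
}
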