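#' @name order-parameters
#' @title Conformational order parameters of Arp2/3 complex activation
#'
#' @description
#' The activation pathway is tracked with a small set of scalar order
#' parameters, each computed per frame from coarse-grained beads (COGs of
#' backbone-atom selections):
#'
#' * **short-pitch distance** -- distance between the inner-domain
#'   (subdomains 3+4) COG of Arp2 and of Arp3. It contracts from about
#'   52 A (splayed, inactive) to about 43 A (short-pitch, filament-like)
#'   when the complex activates.
#' * **twisting/flattening dihedral** (phi) -- signed torsion of the four
#'   subdomain COGs of an actin-fold subunit, taken in the order
#'   subdomain 2, 1, 3, 4. Flattening moves the four subdomains toward a
#'   common plane.
#' * **clamp twist** -- torsion of four configured backbone bead sets on
#'   the clamp subunits ARPC2/ARPC4, tracking rotation of the bottom half
#'   of the complex.
#' * **named distances** -- Euclidean distances between configured residue
#'   anchors (e.g. the W-loop opening F173-I140 in Arp2, or the Arp2
#'   D-loop to ARPC3 distance I41-Y58).
#'
#' All return an `op_series`: a data.frame with columns `frame`, `time_ps`
#' and `value` plus `metric`/`units` attributes; [rolling_smooth()] adds
#' `smoothed` and `std` columns.
NULL

new_op_series <- function(values, x, metric, units) {
  tp <- if (inherits(x, "arp_trajectory")) x$time_ps else 0
  df <- data.frame(frame = seq_along(values), time_ps = tp, value = values)
  attr(df, "metric") <- metric
  attr(df, "units") <- units
  class(df) <- c("op_series", "data.frame")
  df
}

#' @export
print.op_series <- function(x, ...) {
  cat("op_series '", attr(x, "metric"), "' (", attr(x, "units"), "), ",
      nrow(x), " frames; mean ", signif(mean(x$value, na.rm = TRUE), 5),
      "\n", sep = "")
  invisible(x)
}

# signed IUPAC torsion (degrees) of four points given as frames x 3
# matrices; collinear triples yield NaN rather than an error.
torsion_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  b2n <- sqrt(rowSums(b2^2))
  m1 <- cross(n1, b2 / b2n)
  xx <- rowSums(n1 * n2)
  yy <- rowSums(m1 * n2)
  ang <- atan2(yy, xx) * 180 / pi
  bad <- rowSums(n1^2) < 1e-20 | rowSums(n2^2) < 1e-20
  ang[bad] <- NaN
  ang[ang <= -180] <- ang[ang <= -180] + 360   # range (-180, 180]
  ang
}

bead_frames <- function(bm, b) bm$coords[, b, , drop = FALSE][, 1, , drop = TRUE]

as_mat3 <- function(m) if (is.matrix(m)) m else matrix(m, ncol = 3)

#' Short-pitch (inner-domain) distance
#'
#' Per-frame distance between the COG of subdomains 3+4 of Arp2 and the
#' COG of subdomains 3+4 of Arp3, using backbone atoms. This is the metric
#' of the splayed-to-short-pitch conformational switch.
#'
#' @param x an `arp_structure` or `arp_trajectory`.
#' @param registry a `subunit_registry`.
#' @return an `op_series` in angstroms.
#' @export
short_pitch_distance <- function(x, registry) {
  spec <- list(
    arp2_inner = list(subunit = "Arp2", subdomain = c(3, 4), backbone = TRUE),
    arp3_inner = list(subunit = "Arp3", subdomain = c(3, 4), backbone = TRUE))
  bm <- map_beads(x, spec, registry)
  d <- sqrt(rowSums((as_mat3(bead_frames(bm, 1)) -
                     as_mat3(bead_frames(bm, 2)))^2))
  new_op_series(d, x, "short_pitch_distance", "angstrom")
}

#' Subunit twisting/flattening dihedral
#'
#' Signed torsion (degrees) of the four subdomain COG beads of an
#' actin-fold subunit, in the order subdomain 2, 1, 3, 4.
#'
#' @inheritParams short_pitch_distance
#' @param subunit `"Arp2"`, `"Arp3"`, or an actin subunit name (e.g.
#'   `"MA3"`, `"DA2"`).
#' @return an `op_series` in degrees on (-180, 180].
#' @export
flattening_dihedral <- function(x, registry, subunit = "Arp3") {
  bm <- map_beads(x, subdomain_bead_spec(subunit), registry)
  ang <- torsion_deg(as_mat3(bead_frames(bm, 1)), as_mat3(bead_frames(bm, 2)),
                     as_mat3(bead_frames(bm, 3)), as_mat3(bead_frames(bm, 4)))
  new_op_series(ang, x, paste0("flattening_", subunit), "degrees")
}

#' Clamp-twist dihedral
#'
#' Torsion of the four configured clamp beads (backbone-atom sets on
#' ARPC2/ARPC4), Bead 1-Bead 2-Bead 3-Bead 4.
#'
#' @inheritParams short_pitch_distance
#' @return an `op_series` in degrees.
#' @export
clamp_twist <- function(x, registry) {
  bm <- map_beads(x, clamp_bead_spec(registry), registry)
  ang <- torsion_deg(as_mat3(bead_frames(bm, 1)), as_mat3(bead_frames(bm, 2)),
                     as_mat3(bead_frames(bm, 3)), as_mat3(bead_frames(bm, 4)))
  new_op_series(ang, x, "clamp_twist", "degrees")
}

#' Distance between two named residue anchors
#'
#' @inheritParams short_pitch_distance
#' @param anchor_a,anchor_b anchor names defined in the registry (e.g.
#'   `"arp2_F173"`, `"arp2_I140"`).
#' @param elety atom name used for both anchors (default `"CA"`).
#' @return an `op_series` in angstroms.
#' @export
named_distance <- function(x, registry, anchor_a, anchor_b, elety = "CA") {
  ia <- anchor_atom(x, registry, anchor_a, elety)
  ib <- anchor_atom(x, registry, anchor_b, elety)
  nf <- n_frames(x)
  d <- vapply(seq_len(nf), function(f) {
    m <- frame_xyz(x, f)
    sqrt(sum((m[ia, ] - m[ib, ])^2))
  }, numeric(1))
  new_op_series(d, x, paste0("dist_", anchor_a, "_", anchor_b), "angstrom")
}

#' Rolling mean and standard deviation of an order-parameter series
#'
#' Centered rolling window with truncated windows at the edges; the std
#' band is the standard deviation over the same window. Frames whose value
#' is NaN (e.g. undefined torsions) propagate into every window that
#' contains them instead of being dropped.
#'
#' @param series an `op_series`.
#' @param window window width in frames (>= 1); the 50-frame default
#'   matches 5 ns at a 100 ps frame interval.
#' @return the series with `smoothed` and `std` columns added.
#' @export
rolling_smooth <- function(series, window = 50L) {
  stopifnot(inherits(series, "op_series"))
  if (window < 1) stop("window must be >= 1")
  n <- nrow(series)
  if (window > n) stop("window (", window, ") exceeds series length (", n, ")")
  v <- series$value
  series$smoothed <- zoo::rollapply(v, width = window, FUN = mean,
                                    align = "center", partial = TRUE)
  series$std <- zoo::rollapply(v, width = window,
                               FUN = function(w) if (length(w) > 1) sd(w) else 0,
                               align = "center", partial = TRUE)
  attr(series, "smooth_window") <- window
  series
}

#' Root-mean-square fluctuation from the initial frame
#'
#' Per-atom RMS displacement from the first frame, optionally after rigid
#' superposition of every frame onto the first using a stated alignment
#' selection; per-residue values are means over each residue's backbone
#' atoms.
#'
#' @param traj an `arp_trajectory` with at least two frames.
#' @param atom_set atoms to report RMSF for.
#' @param align_set atoms used for rigid-body superposition onto frame 1,
#'   or `NULL` to skip alignment.
#' @param per_residue aggregate to residue level (mean over backbone
#'   atoms of each residue present in `atom_set`).
#' @return a data.frame with `chain`, `resno`, `elety` (atom level) and
#'   `rmsf` (angstrom).
#' @export
rmsf <- function(traj, atom_set, align_set = NULL, per_residue = FALSE) {
  stopifnot(inherits(traj, "arp_trajectory"))
  if (length(atom_set) == 0) stop("rmsf() of an empty selection")
  nf <- n_frames(traj)
  if (nf < 2) stop("rmsf needs at least two frames")
  ref <- frame_xyz(traj, 1)
  sq <- matrix(0, nrow = nf - 1, ncol = length(atom_set))
  for (f in 2:nf) {
    m <- frame_xyz(traj, f)
    if (!is.null(align_set))
      m <- superpose_onto(m, ref, align_set)
    sq[f - 1, ] <- rowSums((m[atom_set, , drop = FALSE] -
                            ref[atom_set, , drop = FALSE])^2)
  }
  at <- traj$topology$atoms[atom_set, , drop = FALSE]
  out <- data.frame(chain = at$chain, resno = at$resno,
                    elety = trimws(at$elety),
                    rmsf = sqrt(colMeans(sq)))
  if (per_residue) {
    out <- aggregate(rmsf ~ chain + resno, data = out, FUN = mean)
    out <- out[order(out$chain, out$resno), ]
    rownames(out) <- NULL
  }
  out
}

# rigid-body least-squares superposition of mobile onto ref using the
# atoms in align_set (Kabsch via bio3d::fit.xyz)
superpose_onto <- function(mobile, ref, align_set) {
  fixed <- as.vector(t(ref))
  mob <- as.vector(t(mobile))
  idx <- as.vector(rbind(3 * align_set - 2, 3 * align_set - 1, 3 * align_set))
  fitted <- bio3d::fit.xyz(fixed = fixed, mobile = mob,
                           fixed.inds = idx, mobile.inds = idx)
  matrix(fitted, ncol = 3, byrow = TRUE)
}

#' Two-dimensional pseudo-free-energy basin extraction
#'
#' Bins two equal-length order-parameter series into a 2D histogram,
#' converts occupancies to a pseudo free energy E = -ln(p / p_max) (in kT
#' units; empty bins are infinite), and extracts the basin: the
#' 8-connected set of bins with E <= `depth` containing the minimum-energy
#' bin. This reproduces the "most probable conformations within a radius
#' of one free energy unit of the lowest energy conformation" construction
#' used to delimit conformational states in (phi, distance) planes.
#'
#' @param series_x,series_y `op_series` (or numeric vectors) of equal
#'   length.
#' @param bins number of bins per axis.
#' @param pad fractional range padding per side.
#' @param depth basin depth in energy units (default 1).
#' @return a `basin2d`: list with `x_edges`, `y_edges`, `counts`,
#'   `energy`, `basin` (logical matrix) and `min_bin` (i, j).
#' @export
basin_2d <- function(series_x, series_y, bins = 50L, pad = 0.05, depth = 1) {
  vx <- if (is.data.frame(series_x)) series_x$value else as.numeric(series_x)
  vy <- if (is.data.frame(series_y)) series_y$value else as.numeric(series_y)
  if (length(vx) != length(vy)) stop("series must have equal length")
  ok <- is.finite(vx) & is.finite(vy)
  vx <- vx[ok]; vy <- vy[ok]
  if (length(vx) == 0) stop("no finite frames to bin")
  edges <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    w <- diff(r)
    seq(r[1] - pad * w, r[2] + pad * w, length.out = bins + 1)
  }
  xe <- edges(vx); ye <- edges(vy)
  ix <- pmin(pmax(findInterval(vx, xe, rightmost.closed = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(vy, ye, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(0L, bins, bins)
  tab <- table(factor(ix, levels = 1:bins), factor(iy, levels = 1:bins))
  counts[] <- as.integer(tab)
  p <- counts / sum(counts)
  energy <- -log(p / max(p))          # min-energy bin at 0; empty bins Inf
  seeds <- which(energy == 0, arr.ind = TRUE)   # ties: every global minimum
  mi <- seeds[1, ]
  basin <- matrix(FALSE, bins, bins)
  for (s in seq_len(nrow(seeds)))
    basin <- basin | flood_fill_8(energy <= depth, seeds[s, 1], seeds[s, 2])
  structure(list(x_edges = xe, y_edges = ye, counts = counts,
                 energy = energy, basin = basin, min_bin = mi),
            class = "basin2d")
}

# 8-neighbor flood fill of TRUE cells from a seed
flood_fill_8 <- function(mask, i0, j0) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  stack <- list(c(i0, j0))
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- p[1]; j <- p[2]
    if (i < 1 || i > nr || j < 1 || j > nc) next
    if (out[i, j] || !mask[i, j]) next
    out[i, j] <- TRUE
    for (di in -1:1) for (dj in -1:1)
      if (di || dj) stack[[length(stack) + 1L]] <- c(i + di, j + dj)
  }
  out
}

#' @export
print.basin2d <- function(x, ...) {
  cat("basin2d:", sum(x$counts), "frames in", nrow(x$counts), "x",
      ncol(x$counts), "bins;", sum(x$basin), "bins in the 1-unit basin\n")
  invisible(x)
}

#' Basin area in metric units
#' @param b a `basin2d`.
#' @return basin area = number of basin bins x bin area.
#' @export
basin_area <- function(b) {
  dx <- diff(b$x_edges)[1]; dy <- diff(b$y_edges)[1]
  sum(b$basin) * dx * dy
}

#' Export order-parameter series as a tidy table
#'
#' @param series_list named list of `op_series`.
#' @param path optional TSV output path.
#' @return a long data.frame with columns `frame`, `time_ps`, `metric`,
#'   `units`, `value`, `smoothed`, `std`.
#' @export
op_table <- function(series_list, path = NULL) {
  rows <- lapply(series_list, function(s) {
    data.frame(frame = s$frame, time_ps = s$time_ps,
               metric = attr(s, "metric"), units = attr(s, "units"),
               value = s$value,
               smoothed = if ("smoothed" %in% names(s)) s$smoothed else NA_real_,
               std = if ("std" %in% names(s)) s$std else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path))
    write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  out
}
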