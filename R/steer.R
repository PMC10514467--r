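#' Build a coarse-grained elastic-network model
#'
#' Maps a structure to subunit- or subdomain-level COG beads joined by an
#' elastic network: every bead pair closer than `cutoff` gets a harmonic
#' edge whose rest length is the distance in the input conformation. The
#' model is the desk-scale stand-in for the all-atom system in the steered
#' protocol: the collective variables (pairwise subunit COG distances),
#' the moving-restraint structure and the endpoint definitions are
#' preserved while the forcefield is replaced by the network.
#'
#' @param x an `arp_structure`.
#' @param registry a `subunit_registry`.
#' @param level `"subunit"` (one backbone-COG bead per subunit) or
#'   `"subdomain"` (four beads for each Arp, one for every other subunit).
#' @param cutoff network edge cutoff in angstroms.
#' @param stiffness elastic-network spring constant (energy / A^2).
#' @return a `cg_model`: list with `labels`, `bead_spec`, `coords`
#'   (beads x 3), `edges` (data.frame `i`, `j`, `r0`, `k`).
#' @export
build_cg <- function(x, registry, level = c("subunit", "subdomain"),
                     cutoff = 60, stiffness = 50) {
  level <- match.arg(level)
  spec <- cg_bead_spec(registry, level)
  bm <- map_beads(x, spec, registry)
  coords <- as_mat3(bm$coords[1, , ])
  rownames(coords) <- bm$labels
  n <- nrow(coords)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- sqrt(rowSums((coords[pr[, 1], , drop = FALSE] -
                     coords[pr[, 2], , drop = FALSE])^2))
  keep <- d <= cutoff
  if (!any(keep))
    stop("no network edges at cutoff ", cutoff,
         " A; minimum bead distance is ", round(min(d), 1), " A")
  edges <- data.frame(i = pr[keep, 1], j = pr[keep, 2], r0 = d[keep],
                      k = stiffness)
  g <- igraph::graph_from_edgelist(as.matrix(edges[, c("i", "j")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  if (igraph::components(g)$no > 1)
    stop("elastic network is disconnected at cutoff ", cutoff,
         " A; increase the cutoff")
  structure(list(labels = bm$labels, bead_spec = spec, level = level,
                 coords = coords, edges = edges, cutoff = cutoff),
            class = "cg_model")
}

cg_bead_spec <- function(registry, level) {
  subs <- subunits(registry)
  if (level == "subunit") {
    spec <- lapply(subs, function(su) list(subunit = su, backbone = TRUE))
    names(spec) <- subs
    return(spec)
  }
  spec <- list()
  for (su in subs) {
    if (su %in% c("Arp2", "Arp3"))
      spec <- c(spec, subdomain_bead_spec(su))
    else {
      spec[[su]] <- list(subunit = su, backbone = TRUE)
    }
  }
  spec
}

#' @export
print.cg_model <- function(x, ...) {
  cat("cg_model (", x$level, " level): ", length(x$labels), " beads, ",
      nrow(x$edges), " network edges (cutoff ", x$cutoff, " A)\n", sep = "")
  invisible(x)
}

#' Moving-restraint schedule between two endpoint conformations
#'
#' One harmonic restraint per bead pair: the relaxed length starts at the
#' pair distance in the active (model-building) conformation and is
#' ramped linearly to the pair distance in the inactive conformation over
#' `ramp_steps` steps. The default restrains every bead pair, mirroring a
#' bias applied "between each COG"; `pairs` restricts the set.
#'
#' @param model a `cg_model` built from the active conformation.
#' @param inactive an `arp_structure` providing the target conformation,
#'   or a beads x 3 coordinate matrix with the model's bead labels.
#' @param registry registry used to map beads onto `inactive` (required
#'   when `inactive` is a structure).
#' @param k restraint spring constant (energy / A^2); default 10000.
#' @param ramp_steps number of steps over which targets are ramped.
#' @param pairs optional 2-column matrix of bead indices to restrain.
#' @return a `restraint_schedule`: data.frame `i`, `j`, `start`, `target`
#'   with attributes `k` and `ramp_steps`.
#' @export
schedule_from_endpoints <- function(model, inactive, registry = NULL,
                                    k = 10000, ramp_steps = 60000L,
                                    pairs = NULL) {
  stopifnot(inherits(model, "cg_model"))
  if (k < 0) stop("spring constant must be >= 0")
  if (inherits(inactive, "arp_structure")) {
    if (is.null(registry)) stop("registry required to map beads onto the ",
                                "inactive structure")
    bm <- map_beads(inactive, model$bead_spec, registry)
    tgt <- as_mat3(bm$coords[1, , ])
  } else {
    tgt <- as.matrix(inactive)
    if (nrow(tgt) != length(model$labels))
      stop("bead mismatch: model has ", length(model$labels),
           " beads, target has ", nrow(tgt))
  }
  n <- length(model$labels)
  if (is.null(pairs)) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  } else pairs <- as.matrix(pairs)
  pd <- function(m) sqrt(rowSums((m[pairs[, 1], , drop = FALSE] -
                                  m[pairs[, 2], , drop = FALSE])^2))
  sched <- data.frame(i = pairs[, 1], j = pairs[, 2],
                      start = pd(model$coords), target = pd(tgt))
  if (any(sched$target <= 0)) stop("restraint targets must be positive")
  attr(sched, "k") <- k
  attr(sched, "ramp_steps") <- as.integer(ramp_steps)
  class(sched) <- c("restraint_schedule", "data.frame")
  sched
}

#' Run the steered coarse-grained dynamics
#'
#' Overdamped (Brownian) Langevin dynamics of the bead network under the
#' moving harmonic restraints: each step
#' \deqn{x \leftarrow x + (F/\gamma)\,dt + \sqrt{2 k_B T\, dt/\gamma}\,\eta}
#' with restraint targets interpolated linearly over the ramp, followed by
#' `hold_steps` of unbiased network dynamics (the restraint released).
#' Euler integration is stable for `dt < 2 gamma / k_max`; the run aborts
#' if the configured step violates this bound or if any coordinate or
#' energy turns non-finite.
#'
#' @param model a `cg_model`.
#' @param schedule a `restraint_schedule`.
#' @param hold_steps unbiased steps appended after the ramp.
#' @param dt integration step.
#' @param gamma friction coefficient (energy * step / A^2).
#' @param kT thermal energy; 0 gives deterministic gradient dynamics.
#' @param seed mandatory RNG seed when `kT > 0`.
#' @param record_stride store bead coordinates every this many steps (CVs
#'   and energies are recorded every step).
#' @return a `cg_trajectory`: list with `coords` (recorded frames x beads
#'   x 3), `recorded_steps`, `cv` (steps x restrained pairs, realized
#'   distances), `target` (same shape, instantaneous targets; NA in the
#'   hold phase), `energy` (data.frame `step`, `network`, `restraint`),
#'   `phase`, `end_of_ramp` (bead coordinates), `seed`.
#' @export
run_steered <- function(model, schedule, hold_steps = 0L, dt = 1.0,
                        gamma = 1e6, kT = 2.5, seed = NULL,
                        record_stride = NULL) {
  stopifnot(inherits(model, "cg_model"),
            inherits(schedule, "restraint_schedule"))
  k_r <- attr(schedule, "k")
  ramp <- attr(schedule, "ramp_steps")
  k_max <- max(c(model$edges$k, k_r))
  if (dt >= 2 * gamma / k_max)
    stop("unstable step: dt = ", dt, " but stability requires dt < ",
         signif(2 * gamma / k_max, 4), " (= 2*gamma/k_max)")
  if (kT > 0) {
    if (is.null(seed)) stop("seed is mandatory for stochastic runs (kT > 0)")
    set.seed(seed)
  }
  total <- ramp + hold_steps
  if (is.null(record_stride)) record_stride <- max(1L, total %/% 1000L)
  n <- nrow(model$coords)
  X <- model$coords
  E <- model$edges
  inc_net <- incidence(n, E$i, E$j)
  inc_res <- incidence(n, schedule$i, schedule$j)
  noise_sd <- sqrt(2 * kT * dt / gamma)
  rec_steps <- unique(c(seq(0L, total, by = record_stride), total))
  coords <- array(NA_real_, dim = c(length(rec_steps), n, 3),
                  dimnames = list(NULL, model$labels, c("x", "y", "z")))
  coords[1, , ] <- X
  cv <- matrix(NA_real_, total, nrow(schedule))
  tgt <- matrix(NA_real_, total, nrow(schedule))
  en <- data.frame(step = seq_len(total), network = NA_real_,
                   restraint = NA_real_)
  ri <- 2L
  end_of_ramp <- X
  pair_delta <- function(idx_i, idx_j)
    X[idx_i, , drop = FALSE] - X[idx_j, , drop = FALSE]

  for (s in seq_len(total)) {
    # elastic network forces
    dn <- pair_delta(E$i, E$j)
    ln <- sqrt(rowSums(dn^2))
    coef_n <- -E$k * (ln - E$r0) / ln
    Fm <- inc_net %*% (coef_n * dn)
    u_net <- sum(0.5 * E$k * (ln - E$r0)^2)
    # moving restraints (ramp phase only)
    if (s <= ramp) {
      frac <- s / ramp
      r_t <- schedule$start + frac * (schedule$target - schedule$start)
      dr <- pair_delta(schedule$i, schedule$j)
      lr <- sqrt(rowSums(dr^2))
      coef_r <- -k_r * (lr - r_t) / lr
      Fm <- Fm + inc_res %*% (coef_r * dr)
      u_res <- sum(0.5 * k_r * (lr - r_t)^2)
      tgt[s, ] <- r_t
    } else u_res <- 0
    X <- X + as.matrix(Fm) * (dt / gamma)
    if (kT > 0)
      X <- X + matrix(rnorm(3 * n, sd = noise_sd), n, 3)
    if (!all(is.finite(X)) || !is.finite(u_net + u_res))
      stop("dynamics diverged at step ", s,
           " (non-finite coordinate or energy)")
    dcv <- pair_delta(schedule$i, schedule$j)
    cv[s, ] <- sqrt(rowSums(dcv^2))
    en$network[s] <- u_net; en$restraint[s] <- u_res
    if (s == ramp) end_of_ramp <- X
    if (s %in% rec_steps) { coords[ri, , ] <- X; ri <- ri + 1L }
  }
  rownames(end_of_ramp) <- model$labels
  structure(list(model = model, schedule = schedule,
                 coords = coords, recorded_steps = rec_steps,
                 cv = cv, target = tgt, energy = en,
                 phase = rep(c("ramp", "hold"), c(ramp, hold_steps)),
                 end_of_ramp = end_of_ramp,
                 dt = dt, gamma = gamma, kT = kT, seed = seed),
            class = "cg_trajectory")
}

incidence <- function(n, i, j) {
  m <- matrix(0, n, length(i))
  m[cbind(i, seq_along(i))] <- 1
  m[cbind(j, seq_along(j))] <- -1
  m
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("cg_trajectory:", length(x$phase), "steps (",
      sum(x$phase == "ramp"), "ramp +", sum(x$phase == "hold"),
      "hold ), kT =", x$kT, "\n")
  invisible(x)
}

#' Distance RMSD between two bead conformations
#'
#' Root-mean-square over a pair set of the difference between
#' intra-conformation pair distances -- rigid-motion invariant by
#' construction.
#'
#' @param frame_beads,reference_beads beads x 3 coordinate matrices with
#'   identical row labels (row order may differ when labelled).
#' @param pairs optional 2-column index matrix; default all bead pairs.
#' @return DRMSD in angstroms.
#' @export
drmsd <- function(frame_beads, reference_beads, pairs = NULL) {
  a <- as.matrix(frame_beads); b <- as.matrix(reference_beads)
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    if (!setequal(rownames(a), rownames(b)))
      stop("bead label mismatch between frame and reference")
    b <- b[rownames(a), , drop = FALSE]
  } else if (nrow(a) != nrow(b))
    stop("bead count mismatch: ", nrow(a), " vs ", nrow(b))
  n <- nrow(a)
  if (is.null(pairs))
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pd <- function(m) sqrt(rowSums((m[pairs[, 1], , drop = FALSE] -
                                  m[pairs[, 2], , drop = FALSE])^2))
  sqrt(mean((pd(a) - pd(b))^2))
}

#' Write a CG trajectory as a multi-model PDB plus a CV table
#'
#' Beads become CA pseudo-atoms (one residue per bead, chain `X`); the
#' per-step collective-variable table is written as TSV.
#'
#' @param ct a `cg_trajectory`.
#' @param prefix output path prefix; writes `<prefix>.pdb` and
#'   `<prefix>_cv.tsv`.
#' @return the two paths, invisibly.
#' @export
write_cg_trajectory <- function(ct, prefix) {
  stopifnot(inherits(ct, "cg_trajectory"))
  n <- length(ct$model$labels)
  atoms <- data.frame(eleno = seq_len(n), elety = "CA", resid = "BEA",
                      chain = "X", resno = seq_len(n), elesy = "C",
                      stringsAsFactors = FALSE)
  top <- new_structure(atoms, ct$coords[1, , ])
  traj <- new_trajectory(top, lapply(seq_len(dim(ct$coords)[1]),
                                     function(i) as_mat3(ct$coords[i, , ])))
  pdb_path <- paste0(prefix, ".pdb")
  write_structure(traj, pdb_path)
  lab <- paste0(ct$model$labels[ct$schedule$i], "-",
                ct$model$labels[ct$schedule$j])
  cvdf <- data.frame(step = seq_len(nrow(ct$cv)), phase = ct$phase,
                     setNames(as.data.frame(ct$cv), lab),
                     check.names = FALSE)
  cv_path <- paste0(prefix, "_cv.tsv")
  write.table(cvdf, cv_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(pdb_path, cv_path))
}
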