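# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# explicit normal-vector torsion: angle between the two bond planes, with
# the sign taken from the orientation of n1 x n2 against the central bond
oracle_torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  cosphi <- max(-1, min(1, cosphi))
  phi <- acos(cosphi) * 180 / pi
  # sign: positive when n1 x n2 points against the central bond (matches
  # the (0,0,0),(1,0,0),(1,1,0),(1,1,-1) -> +90 construction)
  if (sum(cr(n1, n2) * b2) > 0) phi <- -phi
  phi
}

# dense-quadrature SASA for small sphere systems: per-atom accessible area
# by uniform-spiral sampling with n_quad points (independent of the
# package's C++ sampler and usable as a brute-force reference)
oracle_sasa <- function(centers, radii, probe, n_quad = 2e5) {
  k <- seq_len(n_quad)
  z <- (2 * k - 1) / n_quad - 1
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  pts <- cbind(r * cos(k * golden), r * sin(k * golden), z)
  ex <- radii + probe
  vapply(seq_len(nrow(centers)), function(i) {
    p <- sweep(pts * ex[i], 2, centers[i, ], `+`)
    acc <- rep(TRUE, n_quad)
    for (j in seq_len(nrow(centers))) {
      if (j == i) next
      d2 <- (p[, 1] - centers[j, 1])^2 + (p[, 2] - centers[j, 2])^2 +
        (p[, 3] - centers[j, 3])^2
      acc <- acc & d2 >= ex[j]^2
    }
    4 * pi * ex[i]^2 * mean(acc)
  }, numeric(1))
}

# plain breadth-first connectivity check on an edge list
oracle_connected <- function(n, edges) {
  adj <- lapply(seq_len(n), function(i) integer())
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n); queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  all(seen)
}

# random rigid motion (rotation + translation) applied to an n x 3 matrix
random_rigid <- function(m, seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  sweep(m %*% q, 2, rnorm(3, sd = 20), `+`)
}

# a bare n-atom carbon structure from a coordinate matrix
carbon_structure <- function(xyz, chain = "A") {
  n <- nrow(xyz)
  arptraj:::new_structure(
    data.frame(eleno = seq_len(n), elety = "C1", resid = "LIG",
               chain = chain, resno = seq_len(n), elesy = "C",
               stringsAsFactors = FALSE),
    xyz)
}

# minimal CHARMM-format DCD writer (test fixture generator only)
write_test_dcd <- function(path, frames) {
  con <- file(path, "wb")
  on.exit(close(con))
  n_frames <- length(frames)
  natom <- nrow(frames[[1]])
  hdr <- raw(0)
  wint <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header block
  wint(84); writeChar("CORD", con, nchars = 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- n_frames; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- n_frames
  icntrl[20] <- 24L   # CHARMM version stamp
  wint(icntrl); wint(84)
  # title block
  wint(84); wint(1); writeChar(formatC("test dcd", width = 80), con,
                               nchars = 80, eos = NULL); wint(84)
  # natom block
  wint(4); wint(natom); wint(4)
  for (f in frames) {
    for (d in 1:3) {
      wint(4 * natom)
      writeBin(as.numeric(f[, d]), con, size = 4, endian = "little")
      wint(4 * natom)
    }
  }
  invisible(path)
}
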