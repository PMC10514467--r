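td <- function(a, b, c, d)
  arptraj:::torsion_deg(matrix(a, 1, 3), matrix(b, 1, 3),
                        matrix(c, 1, 3), matrix(d, 1, 3))

test_that("torsion handles planar and right-angle constructions exactly", {
  expect_equal(td(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)), 180)
  expect_equal(td(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)), 0)
  expect_equal(td(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)), -90)
  expect_equal(td(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, -1)), 90)
  # collinear triple: flagged, not a crash
  expect_true(is.nan(td(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))))
})

test_that("torsion satisfies its symmetries on random four-point sets", {
  set.seed(20)
  for (i in 1:50) {
    p <- matrix(rnorm(12, sd = 5), 4, 3)
    phi <- td(p[1, ], p[2, ], p[3, ], p[4, ])
    # independent normal-vector oracle
    expect_equal(phi, oracle_torsion(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
    # reversal symmetry ABCD = DCBA
    expect_equal(td(p[4, ], p[3, ], p[2, ], p[1, ]), phi, tolerance = 1e-9)
    # rigid-motion invariance
    q <- random_rigid(p, seed = i)
    expect_equal(td(q[1, ], q[2, ], q[3, ], q[4, ]), phi, tolerance = 1e-8)
    # mirror antisymmetry
    m <- p; m[, 1] <- -m[, 1]
    expect_equal(td(m[1, ], m[2, ], m[3, ], m[4, ]), -phi, tolerance = 1e-9)
  }
})

test_that("the activation metrics recover generator schedules", {
  sched <- list(short_pitch = c(45, 45), phi_arp2 = c(-25, 5),
                phi_arp3 = c(10, 170), clamp = c(0, 30),
                dloop = c(6, 26), wloop = c(10, 6))
  ds <- make_trajectory(synthetic_spec(n_frames = 200, noise_sd = 0,
                                       seed = 2, schedules = sched))
  tr <- ds$trajectory
  reg <- resolve_registry(tr, "synthetic")
  expect_equal(short_pitch_distance(tr, reg)$value,
               ds$ground_truth$short_pitch, tolerance = 1e-6)
  expect_equal(flattening_dihedral(tr, reg, "Arp2")$value,
               ds$ground_truth$phi_arp2, tolerance = 1e-6)
  expect_equal(flattening_dihedral(tr, reg, "Arp3")$value,
               ds$ground_truth$phi_arp3, tolerance = 1e-6)
  expect_equal(clamp_twist(tr, reg)$value,
               ds$ground_truth$clamp, tolerance = 1e-6)
  expect_equal(named_distance(tr, reg, "arp2_I41", "arpc3_Y58")$value,
               ds$ground_truth$dloop, tolerance = 1e-6)
  expect_equal(named_distance(tr, reg, "arp2_F173", "arp2_I140")$value,
               ds$ground_truth$wloop, tolerance = 1e-6)
})

test_that("named distances obey trivial identities", {
  ep <- make_endpoints()
  reg <- resolve_registry(ep$active, "synthetic")
  expect_equal(named_distance(ep$active, reg, "arp2_F173",
                              "arp2_F173")$value, 0)
  # 3-4-0 Pythagorean check on a bare two-atom system
  s <- carbon_structure(rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(sqrt(sum((frame_xyz(s)[1, ] - frame_xyz(s)[2, ])^2)), 5)
  expect_error(named_distance(ep$active, reg, "arp2_F173", "actinD2_M44"),
               "not present")
})

test_that("short-pitch directionality: active below inactive", {
  ep <- make_endpoints()
  reg <- resolve_registry(ep$active, "synthetic")
  expect_lt(short_pitch_distance(ep$active, reg)$value,
            short_pitch_distance(ep$inactive, reg)$value)
})

test_that("clamp twist is rigid-invariant and mirror-antisymmetric", {
  ep <- make_endpoints()
  reg <- resolve_registry(ep$active, "synthetic")
  base <- clamp_twist(ep$active, reg)$value
  moved <- ep$active
  moved$xyz <- random_rigid(moved$xyz, 31)
  expect_equal(clamp_twist(moved, reg)$value, base, tolerance = 1e-8)
  mirrored <- ep$active
  mirrored$xyz[, 3] <- -mirrored$xyz[, 3]
  expect_equal(clamp_twist(mirrored, reg)$value, -base, tolerance = 1e-9)
})

test_that("rolling smooth behaves on constants, window 1, and errors", {
  ds <- make_trajectory(synthetic_spec(n_frames = 60, noise_sd = 0, seed = 3,
    schedules = list(short_pitch = c(45, 45))))
  reg <- resolve_registry(ds$trajectory, "synthetic")
  s <- short_pitch_distance(ds$trajectory, reg)
  sm <- rolling_smooth(s, 10)
  expect_equal(sm$smoothed, rep(45, 60), tolerance = 1e-6)
  expect_equal(sm$std, rep(0, 60), tolerance = 1e-6)
  sm1 <- rolling_smooth(s, 1)
  expect_equal(sm1$smoothed, s$value)
  expect_error(rolling_smooth(s, 61), "exceeds")
  expect_error(rolling_smooth(s, 0), ">= 1")
})

test_that("NaN frames propagate through smoothing instead of dropping", {
  s <- arptraj:::new_op_series(c(1, 2, NaN, 4, 5, 6, 7), list(), "m", "u")
  sm <- rolling_smooth(s, 3)
  expect_true(all(is.na(sm$smoothed[2:4])))
  expect_false(anyNA(sm$smoothed[c(1, 5:7)]))
})

test_that("rmsf recovers closed-form fluctuation magnitudes", {
  # static trajectory: zero everywhere
  ep <- make_endpoints()
  s <- ep$active
  static <- arptraj:::new_trajectory(s, list(s$xyz, s$xyz, s$xyz))
  reg <- resolve_registry(s, "synthetic")
  sel <- select_atoms(static, reg, subunit = "Arp3", backbone = TRUE)
  expect_equal(rmsf(static, sel)$rmsf, rep(0, length(sel)))
  # one atom oscillating +/- d along x (alignment off): rmsf = d
  xyz <- matrix(0, 5, 3); xyz[, 1] <- 1:5
  d <- 0.8
  frames <- lapply(1:40, function(f) {
    m <- xyz; m[3, 1] <- m[3, 1] + d * (-1)^f; m
  })
  tr <- arptraj:::new_trajectory(carbon_structure(xyz), c(list(xyz), frames))
  r <- rmsf(tr, 1:5)
  expect_equal(r$rmsf[3], d, tolerance = 1e-9)
  expect_equal(r$rmsf[-3], rep(0, 4))
  # isotropic Gaussian jitter sigma about a fixed reference: rmsf -> sigma*sqrt(3)
  set.seed(9)
  sigma <- 0.5
  jit <- lapply(1:8000, function(f) xyz + matrix(rnorm(15, sd = sigma), 5, 3))
  trj <- arptraj:::new_trajectory(carbon_structure(xyz), c(list(xyz), jit))
  rj <- rmsf(trj, 1:5)
  expect_equal(mean(rj$rmsf), sigma * sqrt(3), tolerance = 0.05)
  expect_error(rmsf(trj, integer()), "empty")
  expect_error(rmsf(arptraj:::new_trajectory(carbon_structure(xyz),
                                             list(xyz)), 1:5), "two frames")
})

test_that("per-residue rmsf averages backbone atoms", {
  ds <- make_trajectory(synthetic_spec(n_frames = 30, noise_sd = 0.3,
                                       seed = 5,
    schedules = list(short_pitch = c(45, 45))))
  reg <- resolve_registry(ds$trajectory, "synthetic")
  sel <- select_atoms(ds$trajectory, reg, subunit = "Arp3", backbone = TRUE)
  per_atom <- rmsf(ds$trajectory, sel)
  per_res <- rmsf(ds$trajectory, sel, per_residue = TRUE)
  expect_equal(nrow(per_res), 12)   # 4 subdomains x 3 residues
  one <- per_atom[per_atom$resno == 7, ]
  expect_equal(per_res$rmsf[per_res$resno == 7], mean(one$rmsf))
})

test_that("basin extraction handles degenerate and bimodal inputs", {
  b1 <- basin_2d(rep(1, 100), rep(2, 100), bins = 10)
  expect_equal(sum(b1$basin), 1)
  expect_equal(sum(b1$counts), 100)
  # two equal, well-separated modes: both zero-energy bins in the basin set
  x <- rep(c(0, 10), each = 500)
  y <- rep(0, 1000)
  b2 <- basin_2d(x, y, bins = 20)
  expect_equal(sum(b2$energy == 0), 2)
  expect_true(all(b2$basin[b2$energy == 0]))
  expect_error(basin_2d(1:5, 1:6), "equal length")
})

test_that("the 1-unit basin of a bivariate Gaussian matches the analytic ellipse", {
  set.seed(13)
  n <- 50000
  sx <- 1; sy <- 2
  b <- basin_2d(rnorm(n, sd = sx), rnorm(n, sd = sy), bins = 50)
  analytic <- 2 * pi * sx * sy           # area inside -ln(p/pmax) <= 1
  dx <- diff(b$x_edges)[1]; dy <- diff(b$y_edges)[1]
  # binning error band: contour perimeter x bin diagonal
  a <- sqrt(2) * sx; bb <- sqrt(2) * sy
  perim <- pi * (3 * (a + bb) - sqrt((3 * a + bb) * (a + 3 * bb)))
  tol <- perim * sqrt(dx^2 + dy^2)
  expect_lt(abs(basin_area(b) - analytic), tol)
})
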