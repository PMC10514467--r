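make_cg_fixture <- function() {
  ep <- make_endpoints()
  reg <- resolve_registry(ep$active, "synthetic")
  model <- build_cg(ep$active, reg, level = "subunit", cutoff = 80)
  list(ep = ep, reg = reg, model = model)
}

test_that("build_cg wires rest lengths and rejects bad cutoffs", {
  fx <- make_cg_fixture()
  m <- fx$model
  expect_equal(nrow(m$coords), 7)
  # every edge's rest length equals the initial bead distance
  d <- sqrt(rowSums((m$coords[m$edges$i, ] - m$coords[m$edges$j, ])^2))
  expect_equal(m$edges$r0, unname(d), tolerance = 1e-12)
  # independent breadth-first connectivity oracle
  expect_true(oracle_connected(nrow(m$coords),
                               as.matrix(m$edges[, c("i", "j")])))
  expect_error(build_cg(fx$ep$active, fx$reg, cutoff = 1), "cutoff")
})

test_that("schedules interpolate between endpoint distances", {
  fx <- make_cg_fixture()
  # identical endpoints: a null pull
  null_sched <- schedule_from_endpoints(fx$model, fx$ep$active, fx$reg,
                                        ramp_steps = 100)
  expect_equal(null_sched$start, null_sched$target, tolerance = 1e-9)
  # real endpoints: the Arp2-Arp3 target exceeds the start (splaying
  # increases the separation)
  sched <- schedule_from_endpoints(fx$model, fx$ep$inactive, fx$reg,
                                   ramp_steps = 100)
  i <- which(fx$model$labels == "Arp2"); j <- which(fx$model$labels == "Arp3")
  row <- which(sched$i == min(i, j) & sched$j == max(i, j))
  expect_gt(sched$target[row], sched$start[row])
  # bead mismatch
  expect_error(schedule_from_endpoints(fx$model, matrix(0, 3, 3)),
               "mismatch")
})

test_that("zero-temperature, zero-bias dynamics hold the initial state", {
  fx <- make_cg_fixture()
  sched <- schedule_from_endpoints(fx$model, fx$ep$active, fx$reg,
                                   k = 0, ramp_steps = 50)
  run <- run_steered(fx$model, sched, kT = 0)
  expect_equal(unname(run$end_of_ramp), unname(fx$model$coords),
               tolerance = 1e-9)
})

test_that("a single stiff pair converges and tracks the quasi-static solution", {
  # two isolated beads, one restrained pair, T = 0
  coords <- rbind(a = c(0, 0, 0), b = c(10, 0, 0))
  model <- structure(list(labels = c("a", "b"), bead_spec = NULL,
                          level = "subunit", coords = coords,
                          edges = data.frame(i = 1L, j = 2L, r0 = 10, k = 0),
                          cutoff = 100),
                     class = "cg_model")
  sched <- data.frame(i = 1L, j = 2L, start = 10, target = 20)
  attr(sched, "k") <- 10000; attr(sched, "ramp_steps") <- 8000L
  class(sched) <- c("restraint_schedule", "data.frame")
  gamma <- 1e6
  run <- run_steered(model, sched, kT = 0, dt = 1, gamma = gamma)
  final <- run$cv[nrow(run$cv), 1]
  expect_lt(abs(final - 20), 0.1)   # stiff-limit convergence
  # overdamped tracking: d(t) = r(t) - v*tau*(1 - exp(-t/tau)),
  # tau = gamma / (2 k) for a symmetric pair
  tau <- gamma / (2 * 10000)
  v <- 10 / 8000
  steps <- seq_len(8000)
  analytic <- (10 + v * steps) - v * tau * (1 - exp(-steps / tau))
  expect_lt(max(abs(run$cv[, 1] - analytic) / analytic), 0.01)
})

test_that("instability and divergence are caught", {
  fx <- make_cg_fixture()
  sched <- schedule_from_endpoints(fx$model, fx$ep$inactive, fx$reg,
                                   ramp_steps = 10)
  expect_error(run_steered(fx$model, sched, dt = 1000, gamma = 1e6, kT = 0),
               "unstable")
  expect_error(run_steered(fx$model, sched, kT = 2.5), "seed")
})

test_that("steered runs are reproducible and reach the inactive state", {
  fx <- make_cg_fixture()
  sched <- schedule_from_endpoints(fx$model, fx$ep$inactive, fx$reg,
                                   ramp_steps = 3000)
  r1 <- run_steered(fx$model, sched, kT = 2.5, seed = 7)
  r2 <- run_steered(fx$model, sched, kT = 2.5, seed = 7)
  expect_identical(r1$cv, r2$cv)
  expect_identical(r1$coords, r2$coords)
  tgt <- arptraj:::bead_target(fx$model, fx$ep$inactive, fx$reg)
  expect_lt(drmsd(r1$end_of_ramp, tgt), drmsd(fx$model$coords, tgt))
})

test_that("with k = 0 the run reduces to unbiased network dynamics", {
  fx <- make_cg_fixture()
  sched0 <- schedule_from_endpoints(fx$model, fx$ep$inactive, fx$reg,
                                    k = 0, ramp_steps = 500)
  biased <- schedule_from_endpoints(fx$model, fx$ep$inactive, fx$reg,
                                    k = 10000, ramp_steps = 500)
  r0 <- run_steered(fx$model, sched0, kT = 2.5, seed = 11)
  rb <- run_steered(fx$model, biased, kT = 2.5, seed = 11)
  # same seed protocol: the unbiased run stays near the start while the
  # biased one moves; restraint energy is identically zero without bias
  expect_true(all(r0$energy$restraint == 0))
  i <- which(fx$model$labels == "Arp2"); j <- which(fx$model$labels == "Arp3")
  row <- which(sched0$i == min(i, j) & sched0$j == max(i, j))
  expect_lt(abs(r0$cv[500, row] - sched0$start[row]), 1)
  expect_gt(abs(rb$cv[500, row] - sched0$start[row]),
            abs(r0$cv[500, row] - sched0$start[row]))
})

test_that("drmsd obeys closed forms and matches brute force", {
  set.seed(40)
  a <- matrix(rnorm(30, sd = 10), 10, 3)
  expect_equal(drmsd(a, a), 0)
  # uniform scaling by (1+eps): drmsd = eps * rms of reference distances
  eps <- 0.03
  pr <- which(upper.tri(matrix(0, 10, 10)), arr.ind = TRUE)
  dref <- sqrt(rowSums((a[pr[, 1], ] - a[pr[, 2], ])^2))
  expect_equal(drmsd(a * (1 + eps), a), eps * sqrt(mean(dref^2)),
               tolerance = 1e-9)
  # random perturbation against direct summation
  b <- a + matrix(rnorm(30, sd = 0.5), 10, 3)
  dpert <- sqrt(rowSums((b[pr[, 1], ] - b[pr[, 2], ])^2))
  expect_equal(drmsd(b, a), sqrt(mean((dpert - dref)^2)), tolerance = 1e-12)
  # rigid motion invariance
  expect_equal(drmsd(random_rigid(b, 3), a), drmsd(b, a), tolerance = 1e-9)
  rownames(a) <- paste0("b", 1:10)
  bad <- a; rownames(bad) <- paste0("x", 1:10)
  expect_error(drmsd(a, bad), "label")
})

test_that("cg trajectories export beads and CVs to disk", {
  fx <- make_cg_fixture()
  sched <- schedule_from_endpoints(fx$model, fx$ep$inactive, fx$reg,
                                   ramp_steps = 200)
  run <- run_steered(fx$model, sched, kT = 0)
  prefix <- file.path(withr::local_tempdir(), "pull")
  paths <- write_cg_trajectory(run, prefix)
  expect_true(all(file.exists(paste0(prefix, c(".pdb", "_cv.tsv")))))
  cvtab <- read.delim(paste0(prefix, "_cv.tsv"), check.names = FALSE)
  expect_equal(nrow(cvtab), 200)
  top <- read_structure(paste0(prefix, ".pdb"))
  expect_equal(nrow(top$atoms), 7)
})
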