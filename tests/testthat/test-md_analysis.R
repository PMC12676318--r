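test_that("trajectory RMSD is zero for static or rigidly moving frames", {
  base <- matrix(rnorm(60), ncol = 3)
  static <- mk_traj(list(base, base, base))
  expect_true(all(traj_rmsd(static, selection = "CA")$rmsd < 1e-12))

  rigid <- mk_traj(list(base,
                        apply_rigid(base, rot_z(40), c(1, 2, 3)),
                        apply_rigid(base, rot_z(-10), c(-5, 0, 1))))
  expect_true(all(traj_rmsd(rigid, selection = "CA")$rmsd < 1e-9))
})

test_that("noisy-frame RMSD approaches sigma*sqrt(3)", {
  set.seed(71)
  n <- 2000
  base <- matrix(rnorm(3 * n, sd = 10), ncol = 3)
  sigma <- 0.4
  frames <- list(base, base + matrix(rnorm(3 * n, 0, sigma), ncol = 3))
  tr <- mk_traj(frames)
  rd <- traj_rmsd(tr, selection = "CA")
  expect_equal(rd$rmsd[2], sigma * sqrt(3), tolerance = 0.05)
  expect_error(traj_rmsd(tr, selection = "XX"), "no atoms")
})

test_that("RMSF recovers sigma*sqrt(3) within 3% at 10^4 frames", {
  st <- gen_trajectory(10000, 30, sigma_profile = 0.5, seed = 5)
  rmsf <- traj_rmsf(st$trajectory, selection = "CA", align = FALSE)
  rel <- abs(rmsf$rmsf - st$truth$rmsf) / st$truth$rmsf
  expect_lt(max(rel), 0.03)
})

test_that("a static trajectory has zero RMSF and one frame errors", {
  base <- matrix(rnorm(30), ncol = 3)
  tr <- mk_traj(list(base, base, base))
  expect_true(all(traj_rmsf(tr, selection = "CA")$rmsf < 1e-12))
  expect_error(traj_rmsf(mk_traj(list(base)), selection = "CA"), "2 frames")
})

test_that("a high-noise residue ranks first in RMSF", {
  sig <- rep(0.2, 15); sig[7] <- 2.0
  st <- gen_trajectory(500, 15, sigma_profile = sig, seed = 8)
  rmsf <- traj_rmsf(st$trajectory, selection = "CA", align = FALSE)
  expect_equal(rmsf$resid[which.max(rmsf$rmsf)], 7L)
})

test_that("RMSD and RMSF are invariant under one global rigid motion of all frames", {
  st <- gen_trajectory(50, 20, sigma_profile = 0.3, seed = 14)
  tr <- st$trajectory
  moved <- trajectory(lapply(tr$frames, apply_rigid, R = rot_z(77), t = c(4, 4, 4)),
                      tr$atoms, tr$times)
  expect_equal(traj_rmsd(moved, selection = "CA")$rmsd,
               traj_rmsd(tr, selection = "CA")$rmsd, tolerance = 1e-9)
  expect_equal(traj_rmsf(moved, selection = "CA", align = TRUE)$rmsf,
               traj_rmsf(tr, selection = "CA", align = TRUE)$rmsf,
               tolerance = 1e-9)
})

test_that("hydrogen-bond counting flips exactly at the 3.5 A boundary", {
  frames <- list(rbind(c(0, 0, 0), c(3.49, 0, 0)),
                 rbind(c(0, 0, 0), c(3.50, 0, 0)),
                 rbind(c(0, 0, 0), c(3.51, 0, 0)))
  tr <- mk_traj(frames, names = c("N", "O"))
  hb <- hbond_counts(tr, donors = 1L, acceptors = 2L)
  expect_equal(hb$n_hbonds, c(1L, 1L, 0L))
})

test_that("planted in-cutoff pairs are counted exactly and the count is cutoff-monotone", {
  set.seed(19)
  k <- 4
  donors <- 1:6
  acceptors <- 7:12
  frame <- matrix(runif(36, 0, 50), ncol = 3)
  # plant k donor/acceptor pairs at 2.9 A, push the rest far away
  for (i in seq_len(k)) frame[acceptors[i], ] <- frame[donors[i], ] + c(2.9, 0, 0)
  for (i in (k + 1):6) frame[acceptors[i], ] <- frame[donors[i], ] + c(30, 30, 30)
  tr <- mk_traj(list(frame, frame), names = rep(c("N", "O"), each = 6))
  hb <- hbond_counts(tr, donors, acceptors)
  expect_true(all(hb$n_hbonds >= k))   # planted pairs always counted

  cuts <- c(1, 2.5, 3.5, 5, 20, 100)
  counts <- vapply(cuts, function(cu) {
    hbond_counts(tr, donors, acceptors, hbond_criteria(max_distance = cu))$n_hbonds[1]
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[length(counts)], length(donors) * length(acceptors))

  expect_error(hbond_counts(tr, integer(0), acceptors), "non-empty")
})

test_that("the optional angle criterion rejects bent geometries", {
  # linear N-H...O (angle 180) vs bent (angle 90), both at 3.0 A
  linear <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0))
  bent <- rbind(c(1, 1, 0), c(1, 0, 0), c(3, 0, 0))    # D-H...A angle 90 deg
  tr <- mk_traj(list(linear, bent), names = c("N", "H", "O"))
  crit <- hbond_criteria(max_distance = 3.5, min_angle = 150)
  hb <- hbond_counts(tr, donors = 1L, acceptors = 3L, criteria = crit,
                     hydrogens = 2L)
  expect_equal(hb$n_hbonds, c(1L, 0L))
  expect_error(hbond_counts(tr, 1L, 3L, criteria = crit), "hydrogens")
})

test_that("energy summaries follow the stated arithmetic", {
  expect_equal(energy_summary(energy_series(rep(-10, 4), rep(-5, 4))), -15)
  expect_equal(energy_summary(energy_series(c(-3, 3), c(1, -1))), 0)

  set.seed(44)
  n <- 5000
  es <- energy_series(rnorm(n, -600000, 500), rnorm(n, -258600, 300))
  se <- sqrt(500^2 + 300^2) / sqrt(n)
  expect_lt(abs(energy_summary(es) - (-858600)), 4 * se)
})

test_that("energy ratios reproduce the published worked examples", {
  expect_identical(energy_ratio(-859009.6, -858589.2), 1.0005)
  expect_identical(energy_ratio(-859268.4, -858589.2), 1.0008)
  expect_identical(energy_ratio(-5, -5), 1)
  expect_error(energy_ratio(-1, 0), "nonzero")
  expect_error(energy_ratio(1, -1), "sign")

  set.seed(3)
  for (k in 1:20) {
    a <- -runif(1, 1e5, 1e6); b <- -runif(1, 1e5, 1e6)
    expect_equal(energy_ratio(a, b) * energy_ratio(b, a), 1, tolerance = 1e-3)
  }
})
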