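# One-particle-thick membrane: pair potential, patch building, equilibration.

test_that("pair energy has its -epsilon minimum at r_min with aligned normals", {
  mp <- membrane_params()
  up <- c(0, 0, 1)
  at_min <- membrane_pair_interaction(c(mp$r_min, 0, 0), up, up, mp)
  expect_equal(at_min$energy, -mp$epsilon, tolerance = 1e-12)
  expect_equal(at_min$force_j, c(0, 0, 0), tolerance = 1e-9)
  # perturbations in distance or alignment raise the energy
  expect_gt(membrane_pair_interaction(c(mp$r_min * 1.1, 0, 0), up, up,
                                      mp)$energy, -mp$epsilon)
  tilt <- c(sin(0.3), 0, cos(0.3))
  expect_gt(membrane_pair_interaction(c(mp$r_min, 0, 0), tilt, up,
                                      mp)$energy, -mp$epsilon)
})

test_that("interaction vanishes identically beyond the cutoff", {
  mp <- membrane_params()
  set.seed(7)
  for (i in 1:20) {
    r <- runit() * runif(1, mp$r_cut, 2 * mp$r_cut)
    out <- membrane_pair_interaction(r, runit(), runit(), mp)
    expect_identical(out$energy, 0)
    expect_identical(out$force_j, c(0, 0, 0))
    expect_identical(out$torque_i, c(0, 0, 0))
  }
  expect_error(membrane_pair_interaction(c(0, 0, 0), c(0, 0, 1), c(0, 0, 1)),
               "coincident")
})

test_that("forces and torques are exact gradients (finite-difference oracle)", {
  mp <- membrane_params()
  set.seed(21)
  h <- 1e-6
  worst <- 0
  for (i in 1:300) {
    r <- runit() * runif(1, 0.9, mp$r_cut - 0.05)
    ni <- runit(); nj <- runit()
    out <- membrane_pair_interaction(r, ni, nj, mp)
    for (k in 1:3) {
      rp <- r; rp[k] <- rp[k] + h
      rm <- r; rm[k] <- rm[k] - h
      fd <- -(membrane_pair_interaction(rp, ni, nj, mp)$energy -
              membrane_pair_interaction(rm, ni, nj, mp)$energy) / (2 * h)
      worst <- max(worst, abs(fd - out$force_j[k]) /
                     max(1, abs(out$force_j[k])))
      np <- ni; np[k] <- np[k] + h
      nm <- ni; nm[k] <- nm[k] - h
      fd_t <- -(membrane_pair_interaction(r, np, nj, mp)$energy -
                membrane_pair_interaction(r, nm, nj, mp)$energy) / (2 * h)
      worst <- max(worst, abs(fd_t - out$torque_i[k]) /
                     max(1, abs(out$torque_i[k])))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("flat patches have the closed-form lattice count and +z normals", {
  mp <- membrane_params()
  p <- build_flat_patch(40, 40, mp)
  a <- mp$r_min
  nx <- round(40 / a)
  ny <- 2 * round(40 / (a * sqrt(3)))
  expect_equal(nrow(p$pos), nx * ny)
  # count ~ area / triangular-lattice per-particle area
  expect_equal(nrow(p$pos), 40 * 40 / (a^2 * sqrt(3) / 2), tolerance = 0.06)
  expect_true(all(p$ornt[, 3] == 1))
  expect_true(all(p$pos[, 3] == 0))
  # determinism
  p2 <- build_flat_patch(40, 40, mp)
  expect_identical(p, p2)
  expect_error(build_flat_patch(10, 40), "box")
})

test_that("equilibrated patches stay flat, cohesive and fluid", {
  eq <- small_patch()
  nb <- neighbor_counts(eq, membrane_params()$r_cut)
  expect_true(all(nb >= 3))
  zc <- eq$pos[, 3] - mean(eq$pos[, 3])
  expect_lt(mean(abs(zc)), 1)
  expect_lt(abs(mean(zc)), 1e-9)
  # fluidity: in-plane diffusion measured from a short production run
  pr <- cached("patch_prod", {
    run_dynamics(eq, NULL, integrator_settings(seed = 12), n_steps = 12000,
                 obs_stride = 500, frame_stride = 300)
  })
  mm <- membrane_mechanics(pr$frames, pr$system$species, dt_frame = 3)
  expect_gt(mm$diffusion, 0.005)
})
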