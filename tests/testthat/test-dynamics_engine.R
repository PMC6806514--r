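# Langevin integrator: statics, equipartition, determinism, neighbour lists,
# checkpoint resume, blow-up reporting.

test_that("zero temperature and zero forces leave positions unchanged", {
  pos <- cbind(runif(5, 2, 18), runif(5, 2, 18), 0)
  sys <- particle_system(pos, rep(3L, 5), c(20, 20))  # no interactions apply
  out <- run_dynamics(sys, NULL, integrator_settings(temperature = 0),
                      n_steps = 100, obs_stride = 0,
                      tension = tension_settings(on = FALSE))
  expect_equal(out$system$pos, sys$pos, tolerance = 1e-14)
})

test_that("a tethered particle satisfies equipartition <x^2> = kT/k", {
  k <- 3
  topo <- structure(list(
    triplets = matrix(integer(0), 0, 3), n_triplets = 0,
    bonds = data.frame(i = integer(), j = integer(), r0 = numeric(),
                       k = numeric()),
    state = NULL, intra_factor = 1, self_exclusion = TRUE,
    tethers = data.frame(i = 1L, px = 10, py = 10, pz = 0, k = k)),
    class = "filament_topology")
  sys <- particle_system(matrix(c(10, 10, 0), 1), 3L, c(20, 20))
  out <- run_dynamics(sys, topo, integrator_settings(seed = 4),
                      n_steps = 3e5, obs_stride = 0, frame_stride = 20,
                      tension = tension_settings(on = FALSE))
  disp <- do.call(rbind, lapply(out$frames[-(1:500)], function(fr)
    fr$pos[1, ] - c(10, 10, 0)))
  expect_equal(mean(disp^2), 1 / k, tolerance = 0.05)
})

test_that("NVE dynamics conserves energy to 1e-4 over 1e4 steps at dt 0.01", {
  # bead-spring ring in vacuum: no orientational degrees of freedom, and
  # self-exclusion off so every interaction is a smooth harmonic bond (the
  # excluded-volume cutoff has a force-derivative kink that adds physical
  # discretisation noise unrelated to the integrator)
  ring <- build_target_ring(4.5, 30, 1)
  arc <- build_filament_arc(ring$n_triplets, ring, k_bond = 10,
                            intra_factor = 10, self_exclusion = FALSE)
  sys <- particle_system(arc$pos + rep(c(15, 15, 0), each = nrow(arc$pos)),
                         rep(c(3L, 3L, 4L), ring$n_triplets), c(30, 30))
  # thermalise velocities, then switch the thermostat off
  warm <- run_dynamics(sys, arc$topology, integrator_settings(seed = 2),
                       n_steps = 2000, obs_stride = 0,
                       tension = tension_settings(on = FALSE))
  nve <- run_dynamics(warm$system, arc$topology,
                      integrator_settings(gamma_t = 0, temperature = 0,
                                          dt = 0.01),
                      n_steps = 1e4, obs_stride = 100,
                      tension = tension_settings(on = FALSE))
  e <- nve$obs$e_total
  ekin <- mean(nve$obs$e_kin)
  # drift = secular trend over the run (a linear fit averages over the
  # bounded symplectic oscillation of the Verlet total energy)
  fit <- lm(e ~ nve$obs$step)
  drift <- abs(coef(fit)[2]) * 1e4
  expect_lt(drift / ekin, 1e-4)
})

test_that("thermostat holds the kinetic temperature within 2 percent", {
  eq <- small_patch()
  pr <- cached("patch_prod", {
    run_dynamics(eq, NULL, integrator_settings(seed = 12), n_steps = 12000,
                 obs_stride = 500, frame_stride = 300)
  })
  expect_equal(mean(pr$obs$temperature), 1, tolerance = 0.02)
})

test_that("identical settings and seed reproduce trajectories exactly", {
  sys <- small_patch()
  a <- run_dynamics(sys, NULL, integrator_settings(seed = 33), n_steps = 500,
                    obs_stride = 100)
  b <- run_dynamics(sys, NULL, integrator_settings(seed = 33), n_steps = 500,
                    obs_stride = 100)
  expect_identical(a$system$pos, b$system$pos)
  expect_identical(a$obs, b$obs)
  c <- run_dynamics(sys, NULL, integrator_settings(seed = 34), n_steps = 500,
                    obs_stride = 0)
  expect_false(identical(a$system$pos, c$system$pos))
})

test_that("neighbour-list forces equal the all-pairs reference", {
  # mixed membrane + filament + cargo system, < 500 particles
  ring <- build_target_ring(3.5, 0, 1)
  fil <- build_flat_spiral(2 * ring$n_triplets, ring, k_bond = 20)
  patch <- build_flat_patch(20, 20)
  sys <- add_cargo(patch, receptor_fraction = 1, seed = 5)
  merged <- add_filament(sys, fil)
  expect_lt(nrow(merged$system$pos), 500)
  nl <- energy_breakdown(merged$system, merged$topology, all_pairs = FALSE)
  ap <- energy_breakdown(merged$system, merged$topology, all_pairs = TRUE)
  expect_equal(nl$forces, ap$forces, tolerance = 1e-12)
  expect_equal(nl$torques, ap$torques, tolerance = 1e-12)
  expect_equal(nl$e_pot, ap$e_pot, tolerance = 1e-12)
})

test_that("resuming from a checkpoint reproduces the uninterrupted run", {
  sys <- small_patch()
  ck <- file.path(tempdir(), "resume_test.rds")
  full <- run_dynamics(sys, NULL, integrator_settings(seed = 8),
                       n_steps = 600, obs_stride = 0)
  part <- run_dynamics(sys, NULL, integrator_settings(seed = 8),
                       n_steps = 300, obs_stride = 0,
                       checkpoint_path = ck, checkpoint_every = 300)
  resumed <- resume_run(ck, n_steps = 300, obs_stride = 0)
  expect_identical(resumed$system$pos, full$system$pos)
  expect_identical(resumed$system$vel, full$system$vel)
  unlink(ck)
})

test_that("n_steps = 0 returns the initial frame only", {
  sys <- small_patch()
  out <- run_dynamics(sys, NULL, integrator_settings(), n_steps = 0)
  expect_length(out$frames, 1)
  expect_equal(out$frames[[1]]$pos, sys$pos)
  expect_equal(nrow(out$obs), 0)
})

test_that("blow-ups abort with the step and worst particle named", {
  # two strongly overlapping WCA beads launched at each other
  pos <- rbind(c(10, 10, 0), c(10.2, 10, 0))
  sys <- particle_system(pos, c(5L, 5L), c(20, 20))  # cargo pair, sigma 4
  expect_error(
    run_dynamics(sys, NULL, integrator_settings(temperature = 0),
                 n_steps = 10, obs_stride = 0,
                 tension = tension_settings(on = FALSE)),
    "blow-up at step")
})

test_that("recorded energy series matches recomputation from saved frames", {
  eq <- small_patch()
  out <- run_dynamics(eq, NULL, integrator_settings(seed = 13),
                      n_steps = 1000, obs_stride = 250, frame_stride = 250,
                      tension = tension_settings(on = FALSE))
  for (i in seq_along(out$frames)) {
    fr <- out$frames[[i]]
    sys_fr <- eq
    sys_fr$pos <- fr$pos
    sys_fr$ornt <- fr$ornt
    sys_fr$box <- fr$box
    eb <- energy_breakdown(sys_fr, NULL)
    expect_equal(eb$e_pot, out$obs$e_pot[i], tolerance = 1e-10)
  }
})
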