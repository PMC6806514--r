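# Protocol drivers: staging, series bookkeeping, sweep aggregation.
# (The physics of the scenarios is exercised at larger scale in
# test-acceptance.R; these tests check the drivers' contracts.)

tiny_params <- function(tau = 60, steps = 3000) {
  validate_config(list(
    geometry = list(R_nm = 11.5, tau_deg = tau, k_bond = 20),
    filament = list(n_turns = 1.5),
    membrane = list(box_x = 22, box_y = 22),
    run = list(steps = steps, seed = 2, equil_steps = 1000)))
}

test_that("presets encode the reference parameter sets", {
  expect_equal(preset_config("fig1c")$geometry$R_nm, 20.4)
  expect_equal(preset_config("fig2b")$geometry$R_nm, 15.3)
  expect_equal(preset_config("fig2b")$geometry$tau_deg, 60)
  expect_equal(preset_config("fig2c")$geometry$tau_deg, -40)
  expect_equal(preset_config("fig2c")$geometry$R_nm, 11.5)
  f4 <- preset_config("fig4a")
  expect_equal(f4$geometry$R_nm, 14.1)
  expect_true(f4$cargo$present)
  expect_equal(f4$interactions$receptor_fraction, 0.5)
  expect_equal(preset_config("fig4b")$interactions$receptor_fraction, 1.0)
  expect_error(preset_config("fig9"), "arg")
})

test_that("flat relaxation returns series, final state and report", {
  out <- cached("flat_tiny", run_flat_relaxation(tiny_params(0), n_frames = 10))
  expect_true(all(c("step", "depth", "planarity") %in% names(out$series)))
  expect_gt(nrow(out$series), 5)
  expect_s3_class(out$report, "deformation_report")
  expect_s3_class(out$final$system, "particle_system")
  # the spiral stays bound near the membrane plane
  expect_lt(abs(out$series$filament_z[nrow(out$series)]), 5)
})

test_that("tilt switch stages are ordered and the switch is recorded", {
  out <- cached("tilt_tiny",
                suppressWarnings(run_tilt_switch(tiny_params(60))))
  stages <- out$series$stage
  expect_true(all(stages[1:5] == "flat" | stages[1:5] == "tilted"))
  expect_equal(unique(stages), c("flat", "tilted"))
  # steps strictly increase across the stage boundary
  expect_true(all(diff(out$series$step) > 0))
  expect_equal(out$final$topology$state$tau, 60)
  expect_equal(out$tilted_state$tau, 60)
})

test_that("sweeps aggregate one row per grid point and survive failures", {
  grid <- data.frame(tau = c(60, -40, 60), R_nm = c(11.5, 11.5, 2.0))
  res <- suppressWarnings(run_sweep(grid, tiny_params(60, steps = 2000)))
  expect_equal(nrow(res), 3)
  expect_equal(res$tau, grid$tau)
  # the R = 2 nm point cannot fit 3 units and must fail gracefully
  expect_true(is.na(res$depth[3]))
  expect_match(res$error[3], ".+")
  expect_false(any(is.na(res$depth[1:2])))
})

test_that("cargo budding runs its four stages and the control runs none", {
  p <- validate_config(list(
    geometry = list(R_nm = 11.5, tau_deg = 60, k_bond = 20),
    filament = list(n_turns = 1.3),
    membrane = list(box_x = 24, box_y = 24),
    cargo = list(present = TRUE),
    run = list(steps = 4000, seed = 3, equil_steps = 1000)))
  out <- suppressWarnings(run_cargo_budding(p, "weak"))
  expect_equal(unique(out$series$stage),
               c("flat_corral", "tilted", "flat_release", "flat_final"))
  expect_s3_class(out$stage1_report, "deformation_report")
  expect_equal(out$final$topology$state$tau, 0)
  ctrl <- suppressWarnings(run_cargo_budding(p, "weak",
                                             with_filament = FALSE))
  expect_equal(unique(ctrl$series$stage), c("flat_corral", "control"))
  expect_false(any(ctrl$series$stage == "tilted"))
  # receptor labelling happened around the cargo
  expect_gt(sum(out$final$system$species == 2L), 3)
  expect_equal(sum(out$final$system$species == 5L), 1)
})

test_that("the strong preset labels receptors at double the weak density", {
  p <- validate_config(list(
    geometry = list(R_nm = 11.5, k_bond = 20),
    filament = list(n_turns = 1.3),
    membrane = list(box_x = 24, box_y = 24),
    cargo = list(present = TRUE),
    run = list(steps = 1000, seed = 3, equil_steps = 500)))
  patch <- build_flat_patch(24, 24)
  w <- add_cargo(patch, receptor_fraction = 0.5, seed = 3)
  s <- add_cargo(patch, receptor_fraction = 1.0, seed = 3)
  expect_gt(sum(s$species == 2L), sum(w$species == 2L))
  # fraction 1: every particle in the disc is a receptor
  expect_equal(sum(s$species == 2L),
               sum({
                 dx <- patch$pos[, 1] - 12; dy <- patch$pos[, 2] - 12
                 dx^2 + dy^2 < 9
               }))
})
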