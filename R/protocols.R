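# Scripted multi-stage protocols: the four scenarios of the two-state model
# (flat-spiral relaxation, tilt switch, parameter sweeps, cargo budding).

#' Named parameter presets
#'
#' Presets encode the model's reference parameter sets, one per headline
#' scenario: `fig1c` (flat spiral, R = 20.4 nm), `fig2b` (switch to tau = 60
#' deg at R = 15.3 nm), `fig2c` (tau = -40 deg, R = 11.5 nm), `fig4a` /
#' `fig4b` (cargo budding at R = 14.1 nm with low / high receptor density),
#' all with l_p = 1.8e3 nm, plus `ci-small`, a reduced-scale preset (smaller
#' box, shorter filament, softer bonds, fewer steps) for property tests and
#' desk-scale runs.
#'
#' @param name preset name
#' @return a validated `sim_params`
#' @export
preset_config <- function(name = c("fig1c", "fig2b", "fig2c", "fig4a",
                                   "fig4b", "ci-small")) {
  name <- match.arg(name)
  ov <- switch(name,
    "fig1c" = list(geometry = list(R_nm = 20.4, tau_deg = 0),
                   membrane = list(box_x = 48, box_y = 48),
                   run = list(steps = 2e6, scenario = "flat_relaxation")),
    "fig2b" = list(geometry = list(R_nm = 15.3, tau_deg = 60),
                   membrane = list(box_x = 48, box_y = 48),
                   run = list(steps = 2e6, scenario = "tilt_switch")),
    "fig2c" = list(geometry = list(R_nm = 11.5, tau_deg = -40),
                   membrane = list(box_x = 48, box_y = 48),
                   run = list(steps = 2e6, scenario = "tilt_switch")),
    "fig4a" = list(geometry = list(R_nm = 14.1, tau_deg = 60),
                   membrane = list(box_x = 40, box_y = 40),
                   cargo = list(present = TRUE),
                   interactions = list(receptor_fraction = 0.5),
                   run = list(steps = 2e6, scenario = "cargo_budding")),
    "fig4b" = list(geometry = list(R_nm = 14.1, tau_deg = 60),
                   membrane = list(box_x = 40, box_y = 40),
                   cargo = list(present = TRUE),
                   interactions = list(receptor_fraction = 1.0),
                   run = list(steps = 2e6, scenario = "cargo_budding")),
    "ci-small" = list(geometry = list(R_nm = 11.5, tau_deg = 60,
                                      k_bond = 40),
                      filament = list(n_turns = 2),
                      membrane = list(box_x = 26, box_y = 26),
                      run = list(steps = 4e4, scenario = "tilt_switch")))
  validate_config(ov)
}

# total unit count: explicit n_triplets override, else n_turns target turns
.filament_length <- function(params, ring) {
  n <- params$filament$n_triplets
  if (!is.na(n)) return(as.integer(n))
  as.integer(round(params$filament$n_turns * ring$n_triplets))
}

# membrane + flat spiral assembly shared by all scenarios
.assemble <- function(params, seed = params$run$seed, with_cargo = FALSE,
                      n_total = NULL, equil_steps = NULL) {
  mp <- membrane_params(params$membrane$epsilon, params$membrane$mu,
                        params$membrane$zeta, params$membrane$r_cut)
  ap <- adhesion_params(params$interactions$eps_binder,
                        params$interactions$eps_cargo,
                        params$interactions$adh_range,
                        params$interactions$receptor_fraction,
                        params$filament$bind_all3,
                        params$interactions$eps_rep)
  is <- integrator_settings(dt = params$units$timestep,
                            gamma_t = params$run$gamma_t,
                            gamma_r = params$run$gamma_r,
                            temperature = params$run$temperature,
                            seed = seed, skin = params$run$skin)
  tn <- tension_settings(params$tension$on, params$tension$coupling,
                         params$tension$target)
  if (is.null(equil_steps)) {
    equil_steps <- if (!is.na(params$run$equil_steps))
      as.integer(params$run$equil_steps)
    else max(10000L, as.integer(params$run$steps / 10))
  }
  patch <- build_flat_patch(params$membrane$box_x, params$membrane$box_y,
                            mp, params$membrane$density)
  # the lattice starts at r_min spacing, above the tensionless equilibrium
  # area; a stronger coupling during equilibration removes the excess area
  # quickly so production starts from a relaxed patch
  tn_eq <- tension_settings(tn$on, max(tn$coupling, 0.01), tn$target)
  patch <- equilibrate_patch(patch, steps = equil_steps, seed = seed,
                             params = mp, settings = is, tension = tn_eq)
  flat <- .state_from_params(params, tau = 0)
  ring <- build_target_ring(flat$R, 0, params$filament$spacing)
  if (is.null(n_total)) n_total <- .filament_length(params, ring)
  z_mem <- mean(patch$pos[patch$species <= 2L, 3])
  inner <- NULL
  sys <- patch
  if (with_cargo) {
    sys <- add_cargo(patch, receptor_disc = params$cargo$receptor_disc,
                     receptor_fraction = params$interactions$receptor_fraction,
                     seed = seed, diameter = params$cargo$diameter)
    inner <- (params$cargo$diameter + 1) / 2 + 0.6
  }
  fil <- build_flat_spiral(n_total, ring, min_gap = params$filament$gap,
                           k_bond = flat$k_bond,
                           intra_factor = params$filament$intra_factor,
                           center = sys$box / 2, z_binder = z_mem + 1.0,
                           inner_radius = inner,
                           self_exclusion = params$filament$self_exclusion)
  if (fil$outer_radius > min(sys$box) / 2 - 2)
    stop("initial spiral exceeds the box; enlarge the box or shorten the ",
         "filament", call. = FALSE)
  merged <- add_filament(sys, fil)
  # settle residual overlaps between the fresh spiral and the fluctuating
  # membrane with clamped displacements before free dynamics
  settled <- run_dynamics(merged$system, merged$topology, is,
                          n_steps = 1000, membrane = mp, adhesion = ap,
                          tension = tension_settings(on = FALSE),
                          obs_stride = 0, max_move = 0.05,
                          cargo_diam = params$cargo$diameter)
  list(system = settled$system, topology = merged$topology, mp = mp, ap = ap,
       is = is, tn = tn, flat_state = flat, ring = ring, n_total = n_total,
       cargo_diam = params$cargo$diameter)
}

# depth/planarity series from stored frames
.frame_series <- function(frames, species, topology) {
  rows <- lapply(frames, function(fr) {
    sys <- list(pos = fr$pos, ornt = fr$ornt, species = species,
                box = fr$box, images = fr$images, step = fr$step)
    class(sys) <- "particle_system"
    fm <- filament_metrics(sys, topology)
    c(step = fr$step, depth = deformation_depth(sys),
      planarity = fm$planarity, filament_z = fm$mean_z,
      mean_radius = fm$mean_radius)
  })
  as.data.frame(do.call(rbind, rows))
}

# plateau: |slope| of depth over the trailing 20% below 0.01 sigma / 1e3 steps
.plateau_reached <- function(series, frac = 0.2, slope_tol = 0.01) {
  n <- nrow(series)
  if (n < 5) return(NA)
  tail_rows <- series[series$step >= max(series$step) -
                        frac * diff(range(series$step)), ]
  if (nrow(tail_rows) < 3) return(NA)
  fit <- lm(depth ~ step, data = tail_rows)
  abs(coef(fit)[2]) * 1e3 < slope_tol
}

# plateau depth: time-average of the depth series over the trailing window
# (a single final frame samples the extremal-bin statistic, which is noisy;
# the depth-versus-time curve flattens to this average)
.plateau_depth <- function(series, frac = 0.2) {
  if (!nrow(series)) return(NA_real_)
  tail_rows <- series[series$step >= max(series$step) -
                        frac * diff(range(series$step)), ]
  mean(tail_rows$depth)
}

#' Flat-spiral relaxation on the membrane
#'
#' The null experiment: a pre-assembled planar spiral in the flat state is
#' placed on an equilibrated membrane and followed with no geometry switch.
#' The spiral densifies but its membrane-binding face stays trapped in a 2D
#' plane; only a shallow enveloping buckle (about -2 sigma, i.e. -5 nm)
#' develops.
#'
#' @param params a validated `sim_params` (e.g. `preset_config("fig1c")`)
#' @param seed RNG seed override
#' @param n_frames number of analysis snapshots across the run
#' @return list with `series` (depth/planarity time series), `final`
#'   (system + topology), `report` (a `deformation_report`)
#' @export
run_flat_relaxation <- function(params = preset_config("fig1c"),
                                seed = params$run$seed, n_frames = 40) {
  asm <- .assemble(params, seed)
  steps <- as.integer(params$run$steps)
  res <- run_dynamics(asm$system, asm$topology, asm$is, steps,
                      membrane = asm$mp, adhesion = asm$ap, tension = asm$tn,
                      obs_stride = max(1L, steps %/% 200),
                      frame_stride = max(1L, steps %/% n_frames))
  series <- .frame_series(res$frames, res$system$species, asm$topology)
  report <- deformation_report(res$system, asm$topology,
                               plateau_reached = .plateau_reached(series),
                               units = params$units)
  report$depth_plateau <- .plateau_depth(series)
  report$depth_plateau_nm <- to_nm(report$depth_plateau, params$units)
  list(series = series, obs = res$obs,
       final = list(system = res$system, topology = asm$topology),
       report = report)
}

#' Tilt-switch experiment
#'
#' Stage 1: flat-state equilibration of the spiral on the membrane. Stage 2:
#' the target geometry of every unit is switched instantly and globally to
#' the tilted state (R_target, tau_target); the membrane deformation depth
#' is tracked until it plateaus. Positive tilt buckles the membrane
#' downward, away from the cytoplasm; negative tilt upward.
#'
#' @param params a validated `sim_params`
#' @param tau_target tilt angle of the tilted state (degrees)
#' @param R_target ring radius of the tilted state (nm); default the flat
#'   state's radius
#' @param seed RNG seed override
#' @param flat_frac fraction of the step budget spent in stage 1
#' @param n_frames analysis snapshots per stage
#' @return list with `series`, `final`, `report`; `report$plateau_reached`
#'   is FALSE (with a warning flag) when no plateau developed within the
#'   step budget
#' @export
run_tilt_switch <- function(params = preset_config("fig2b"),
                            tau_target = params$geometry$tau_deg,
                            R_target = params$geometry$R_nm,
                            seed = params$run$seed, flat_frac = 0.25,
                            n_frames = 40) {
  asm <- .assemble(params, seed)
  steps <- as.integer(params$run$steps)
  s1 <- max(1L, as.integer(steps * flat_frac))
  s2 <- steps - s1
  r1 <- run_dynamics(asm$system, asm$topology, asm$is, s1,
                     membrane = asm$mp, adhesion = asm$ap, tension = asm$tn,
                     obs_stride = max(1L, s1 %/% 50),
                     frame_stride = max(1L, s1 %/% 10))
  tilted <- .state_from_params(params, tau = tau_target, R_nm = R_target)
  topo2 <- switch_geometry_state(asm$topology, tilted)
  # the switch changes every rest length instantly; a short clamped settle
  # absorbs the impulsive bond forces without ejecting membrane particles
  st <- run_dynamics(r1$system, topo2, asm$is, 500,
                     membrane = asm$mp, adhesion = asm$ap,
                     tension = tension_settings(on = FALSE),
                     obs_stride = 0, max_move = 0.05)
  r2 <- run_dynamics(st$system, topo2, asm$is, s2,
                     membrane = asm$mp, adhesion = asm$ap, tension = asm$tn,
                     obs_stride = max(1L, s2 %/% 100),
                     frame_stride = max(1L, s2 %/% n_frames))
  series1 <- .frame_series(r1$frames, r1$system$species, asm$topology)
  series2 <- .frame_series(r2$frames, r2$system$species, topo2)
  series1$stage <- "flat"
  series2$stage <- "tilted"
  series <- rbind(series1, series2)
  plateau <- .plateau_reached(series2)
  if (isFALSE(plateau))
    warning("run_tilt_switch: depth did not plateau within the step budget")
  report <- deformation_report(r2$system, topo2, plateau_reached = plateau,
                               units = params$units)
  report$depth_plateau <- .plateau_depth(series2)
  report$depth_plateau_nm <- to_nm(report$depth_plateau, params$units)
  list(series = series, obs = rbind(r1$obs, r2$obs),
       final = list(system = r2$system, topology = topo2),
       report = report, tilted_state = tilted)
}

#' Sweep the tilted-state parameters
#'
#' One tilt-switch run per grid point. Every run starts from the same
#' initial spiral: the flat state and the filament length are taken from
#' `params` and held fixed; only the tilted state differs.
#'
#' @param grid data.frame with columns `tau` (degrees) and `R_nm`, and
#'   optionally `l_p_nm`
#' @param params base `sim_params`
#' @param seed RNG seed used for every run
#' @return data.frame, one row per grid point, with the final depth, shape
#'   class and plateau flag; failed points carry NA and the error message
#' @export
run_sweep <- function(grid, params = preset_config("ci-small"),
                      seed = params$run$seed) {
  stopifnot(is.data.frame(grid), all(c("tau", "R_nm") %in% names(grid)))
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    pt <- grid[g, ]
    p <- params
    if ("l_p_nm" %in% names(pt) && is.finite(pt$l_p_nm)) {
      p$geometry$l_p_nm <- pt$l_p_nm
      p$geometry$k_bond <- NA
    }
    out <- tryCatch({
      r <- run_tilt_switch(p, tau_target = pt$tau, R_target = pt$R_nm,
                           seed = seed)
      data.frame(tau = pt$tau, R_nm = pt$R_nm,
                 l_p_nm = p$geometry$l_p_nm,
                 depth = r$report$depth, depth_nm = r$report$depth_nm,
                 shape_class = r$report$shape_class,
                 plateau = isTRUE(r$report$plateau_reached),
                 error = NA_character_)
    }, error = function(e)
      data.frame(tau = pt$tau, R_nm = pt$R_nm, l_p_nm = p$geometry$l_p_nm,
                 depth = NA_real_, depth_nm = NA_real_,
                 shape_class = NA_character_, plateau = NA,
                 error = conditionMessage(e)))
    out
  })
  do.call(rbind, rows)
}

#' Cargo-budding and scission experiment
#'
#' Stages: (1) a weakly membrane-bound cargo sphere is corralled by a flat
#' spiral polymerised around it and the assembly is equilibrated; (2) the
#' filament switches to the tilted state and is run to the depth plateau,
#' trapping the cargo in a conical buckle; (3) the filament switches back to
#' the flat state; (4) the neck destabilises, the cargo vesicle is released
#' and the filament returns to the membrane plane. The `weak` preset
#' (receptor fraction 0.5) gives a cargo that cannot bud on its own; the
#' `strong` preset (fraction 1.0) lets the cargo pre-deform the membrane.
#'
#' @param params a validated `sim_params` with `cargo$present`
#' @param preset `"weak"` or `"strong"` receptor density
#' @param seed RNG seed override
#' @param with_filament set FALSE for the no-filament control
#' @param stage_steps integer vector of 4 stage durations; default splits
#'   `params$run$steps` as 20/35/10/35 percent
#' @return list with `series` (per-stage), `final`, `report`,
#'   `stage1_report` (deformation before any switch)
#' @export
run_cargo_budding <- function(params = preset_config("fig4a"),
                              preset = c("weak", "strong"),
                              seed = params$run$seed,
                              with_filament = TRUE, stage_steps = NULL) {
  preset <- match.arg(preset)
  params$interactions$receptor_fraction <-
    if (preset == "weak") 0.5 else 1.0
  steps <- as.integer(params$run$steps)
  if (is.null(stage_steps))
    stage_steps <- pmax(1L, as.integer(steps * c(0.2, 0.35, 0.1, 0.35)))
  asm <- .assemble(params, seed, with_cargo = TRUE)
  topo <- asm$topology
  sys <- asm$system
  if (!with_filament) {
    keep <- sys$species <= 2L | sys$species == 5L
    sys$pos <- sys$pos[keep, , drop = FALSE]
    sys$vel <- sys$vel[keep, , drop = FALSE]
    sys$ornt <- sys$ornt[keep, , drop = FALSE]
    sys$images <- sys$images[keep, , drop = FALSE]
    sys$species <- sys$species[keep]
    topo <- NULL
  }
  run_stage <- function(system, topology, n, tag) {
    r <- run_dynamics(system, topology, asm$is, n, membrane = asm$mp,
                      adhesion = asm$ap, tension = asm$tn,
                      obs_stride = max(1L, n %/% 50),
                      frame_stride = max(1L, n %/% 15),
                      cargo_diam = asm$cargo_diam)
    if (!is.null(topology)) {
      ser <- .frame_series(r$frames, r$system$species, topology)
      ser$stage <- tag
    } else {
      ser <- data.frame(step = vapply(r$frames, `[[`, numeric(1), "step"),
                        depth = vapply(r$frames, function(fr) {
                          s2 <- system; s2$pos <- fr$pos; s2$box <- fr$box
                          deformation_depth(s2)
                        }, numeric(1)),
                        planarity = NA, filament_z = NA, mean_radius = NA,
                        stage = tag)
    }
    list(r = r, ser = ser)
  }
  st1 <- run_stage(sys, topo, stage_steps[1], "flat_corral")
  stage1_report <- deformation_report(st1$r$system, topo, NA, params$units)
  if (!with_filament) {
    # control: no geometry switching possible; just run the full budget
    st4 <- run_stage(st1$r$system, NULL,
                     sum(stage_steps[2:4]), "control")
    report <- deformation_report(st4$r$system, NULL, NA, params$units)
    return(list(series = rbind(st1$ser, st4$ser), final = list(
      system = st4$r$system, topology = NULL), report = report,
      stage1_report = stage1_report))
  }
  settle <- function(system, topology) {
    run_dynamics(system, topology, asm$is, 500, membrane = asm$mp,
                 adhesion = asm$ap, tension = tension_settings(on = FALSE),
                 obs_stride = 0, max_move = 0.05,
                 cargo_diam = asm$cargo_diam)$system
  }
  tilted <- .state_from_params(params, tau = params$geometry$tau_deg)
  topo_t <- switch_geometry_state(topo, tilted)
  st2 <- run_stage(settle(st1$r$system, topo_t), topo_t, stage_steps[2],
                   "tilted")
  flat <- .state_from_params(params, tau = 0)
  topo_f <- switch_geometry_state(topo_t, flat)
  st3 <- run_stage(settle(st2$r$system, topo_f), topo_f, stage_steps[3],
                   "flat_release")
  st4 <- run_stage(st3$r$system, topo_f, stage_steps[4], "flat_final")
  series <- rbind(st1$ser, st2$ser, st3$ser, st4$ser)
  report <- deformation_report(st4$r$system, topo_f,
                               plateau_reached = NA, units = params$units)
  list(series = series, final = list(system = st4$r$system,
                                     topology = topo_f),
       report = report, stage1_report = stage1_report)
}
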