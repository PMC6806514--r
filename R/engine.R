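# Langevin dynamics driver: settings, run loop, checkpointing.

#' Integrator settings
#'
#' Langevin velocity-Verlet integration for positions and velocities,
#' overdamped rotational Langevin updates (with re-normalisation) for the
#' membrane orientation vectors. Randomness is counter-based: every
#' (seed, step, particle) triple has its own stream, so a resumed run
#' reproduces an uninterrupted one exactly.
#'
#' @param dt timestep in reduced time
#' @param gamma_t translational friction
#' @param gamma_r rotational friction
#' @param temperature k_B T
#' @param seed integer random seed
#' @param skin neighbour-list skin distance in sigma
#' @return an object of class `integrator_settings`
#' @export
integrator_settings <- function(dt = 0.01, gamma_t = 1, gamma_r = 3,
                                temperature = 1, seed = 1, skin = 0.4) {
  stopifnot(dt > 0, gamma_t >= 0, gamma_r > 0, temperature >= 0, skin > 0)
  structure(list(dt = dt, gamma_t = gamma_t, gamma_r = gamma_r,
                 temperature = temperature, seed = as.numeric(seed),
                 skin = skin),
            class = "integrator_settings")
}

#' Lateral tension control
#'
#' Berendsen-style rescaling of the periodic box (and all lateral
#' coordinates) toward a target lateral tension, zero by default. Budding
#' and tubulation consume projected membrane area; without this coupling
#' deep deformations would be suppressed by the build-up of lateral tension.
#'
#' @param on logical
#' @param coupling dimensionless coupling strength
#' @param target target lateral pressure (kT/sigma^3), 0 for a tensionless
#'   membrane
#' @return an object of class `tension_settings`
#' @export
tension_settings <- function(on = TRUE, coupling = 0.002, target = 0) {
  structure(list(on = isTRUE(on), coupling = coupling, target = target),
            class = "tension_settings")
}

# flatten parameter objects into the list the C++ core expects
.cpp_params <- function(membrane, adhesion, settings, tension,
                        self_excl = TRUE) {
  # keep the timestep stable against the stiffest bond handled elsewhere
  list(eps_mem = membrane$epsilon, mu = membrane$mu, zeta = membrane$zeta,
       rmin = membrane$r_min, rcut = membrane$r_cut,
       eps_binder = adhesion$eps_binder, eps_cargo = adhesion$eps_cargo,
       adh_w = adhesion$adh_range, eps_rep = adhesion$eps_rep,
       bind_all3 = adhesion$bind_all3, self_excl = self_excl,
       tension_on = tension$on, tension_c = tension$coupling,
       tension_target = tension$target,
       dt = settings$dt, gamma_t = settings$gamma_t,
       gamma_r = settings$gamma_r, temperature = settings$temperature,
       skin = settings$skin, seed = settings$seed)
}

.bond_matrix <- function(topology) {
  if (is.null(topology)) {
    return(list(bonds = matrix(0, 0, 4), tethers = matrix(0, 0, 5)))
  }
  b <- topology$bonds
  t <- topology$tethers
  list(bonds = cbind(b$i, b$j, b$r0, b$k),
       tethers = if (nrow(t)) cbind(t$i, t$px, t$py, t$pz, t$k)
                 else matrix(0, 0, 5))
}

# largest stable timestep for the stiffest bond present
.stable_dt <- function(dt, topology) {
  if (is.null(topology) || !nrow(topology$bonds)) return(dt)
  kmax <- max(topology$bonds$k)
  if (kmax <= 0) return(dt)
  min(dt, 0.2 / sqrt(kmax))
}

#' Run Langevin dynamics
#'
#' Advances the system `n_steps` steps, recording observables every
#' `obs_stride` steps and full snapshots every `frame_stride` steps.
#' The timestep is automatically reduced below `settings$dt` when stiff
#' bonds require it. Any single-step displacement above 1 sigma aborts with
#' a blow-up error naming the step and worst particle. When
#' `checkpoint_path` is given, the full state is written every
#' `checkpoint_every` steps and at the end.
#'
#' @param system a `particle_system`
#' @param topology a `filament_topology` or NULL
#' @param settings an [integrator_settings()]
#' @param n_steps number of steps
#' @param membrane a [membrane_params()]
#' @param adhesion an [adhesion_params()]
#' @param tension a [tension_settings()]
#' @param obs_stride observable recording stride (0 disables)
#' @param frame_stride snapshot stride (0 disables)
#' @param observers optional named list of functions `f(system, step)`
#'   returning a single numeric; evaluated at every recorded frame
#' @param checkpoint_path optional RDS path for checkpoints
#' @param checkpoint_every checkpoint interval in steps
#' @param max_move when positive, per-step displacements are clamped to this
#'   length (sigma): a settling mode for freshly assembled systems with
#'   residual overlaps; blow-up detection is disabled while clamping
#' @param cargo_diam cargo sphere diameter in sigma
#' @return list with `system` (final state), `obs` (data.frame of
#'   observable series), `frames` (list of snapshots), `observer_series`
#' @export
run_dynamics <- function(system, topology = NULL, settings =
                           integrator_settings(), n_steps,
                         membrane = membrane_params(),
                         adhesion = adhesion_params(),
                         tension = tension_settings(),
                         obs_stride = 200, frame_stride = 0,
                         observers = NULL,
                         checkpoint_path = NULL, checkpoint_every = NULL,
                         max_move = 0, cargo_diam = 4) {
  stopifnot(inherits(system, "particle_system"), n_steps >= 0)
  settings$dt <- .stable_dt(settings$dt, topology)
  cp <- .cpp_params(membrane, adhesion, settings, tension,
                    self_excl = is.null(topology) ||
                      isTRUE(topology$self_exclusion))
  cp$max_move <- max_move
  cp$cargo_diam <- cargo_diam
  bt <- .bond_matrix(topology)
  if (!is.null(checkpoint_path)) {
    dir <- dirname(checkpoint_path)
    if (!dir.exists(dir) || file.access(dir, 2) != 0)
      stop("run_dynamics: checkpoint path not writable: ", checkpoint_path,
           call. = FALSE)
  }
  if (n_steps == 0) {
    return(list(system = system, obs = .obs_df(matrix(numeric(0), 0, 12)),
                frames = list(.system_frame(system)),
                observer_series = NULL))
  }
  chunk <- if (is.null(checkpoint_every)) n_steps else
    max(1L, as.integer(checkpoint_every))
  done <- 0
  obs_all <- NULL
  frames_all <- list()
  while (done < n_steps) {
    todo <- min(chunk, n_steps - done)
    res <- cpp_run(system$pos, system$vel, system$ornt, system$species,
                   system$box, system$images, bt$bonds, bt$tethers, cp,
                   as.integer(todo), system$step, as.integer(frame_stride),
                   as.integer(obs_stride))
    system$pos <- res$pos
    system$vel <- res$vel
    system$ornt <- res$ornt
    system$images <- res$images
    system$box <- res$box
    system$step <- system$step + todo
    if (nrow(res$obs)) obs_all <- rbind(obs_all, res$obs)
    frames_all <- c(frames_all, res$frames)
    if (res$status != 0)
      stop(sprintf(
        "run_dynamics: blow-up at step %g (particle %d moved > 1 sigma in one step)",
        res$bad_step, res$bad_particle), call. = FALSE)
    done <- done + todo
    if (!is.null(checkpoint_path))
      saveRDS(list(system = system, topology = topology,
                   settings = settings, step = system$step),
              checkpoint_path)
  }
  obs <- .obs_df(if (is.null(obs_all)) matrix(numeric(0), 0, 12) else obs_all)
  observer_series <- NULL
  if (!is.null(observers) && length(frames_all)) {
    observer_series <- do.call(rbind, lapply(frames_all, function(fr) {
      sys_fr <- system
      sys_fr$pos <- fr$pos
      sys_fr$ornt <- fr$ornt
      sys_fr$box <- fr$box
      vals <- vapply(observers, function(f) as.numeric(f(sys_fr, fr$step)),
                     numeric(1))
      c(step = fr$step, vals)
    }))
    observer_series <- as.data.frame(observer_series)
  }
  list(system = system, obs = obs, frames = frames_all,
       observer_series = observer_series)
}

.obs_df <- function(m) {
  df <- as.data.frame(m)
  names(df) <- c("step", "e_pot", "e_bond", "e_mem", "e_wca", "e_adh",
                 "e_tether", "e_kin", "temperature", "box_x", "tension",
                 "e_total")
  df
}

.system_frame <- function(system) {
  list(step = system$step, box = system$box, pos = system$pos,
       ornt = system$ornt, images = system$images)
}

#' Advance the system by one integration step
#'
#' @inheritParams run_dynamics
#' @return the updated `particle_system`
#' @export
sim_step <- function(system, topology = NULL,
                     settings = integrator_settings(),
                     membrane = membrane_params(),
                     adhesion = adhesion_params(),
                     tension = tension_settings(on = FALSE)) {
  run_dynamics(system, topology, settings, n_steps = 1, membrane = membrane,
               adhesion = adhesion, tension = tension, obs_stride = 0,
               frame_stride = 0)$system
}

#' Resume a run from a checkpoint
#'
#' Continues a checkpointed run; because random streams are keyed by
#' absolute step number, the resumed trajectory is identical to the
#' uninterrupted one.
#'
#' @param checkpoint_path RDS checkpoint written by [run_dynamics()]
#' @param n_steps further steps to run
#' @param ... passed to [run_dynamics()]
#' @return as [run_dynamics()]
#' @export
resume_run <- function(checkpoint_path, n_steps, ...) {
  ck <- readRDS(checkpoint_path)
  run_dynamics(ck$system, ck$topology, ck$settings, n_steps, ...)
}
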