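# Run configuration: defaults, validation, geometry state, stiffness map.

# Calibration of filament rigidity: for the standard triplet geometry
# (unit spacing 1 sigma, binder separation 1 sigma across the ribbon,
# intra-unit bonds 10x stiffer) every inter-unit deformation mode is
# harmonic with stiffness proportional to k_bond; the quadratic mode
# constants of the 9-bond pair energy are c_in ~ 0.48 (in-plane bend) and
# c_oop ~ 0.64 (out-of-plane bend) in units of k_bond (angle in radians per
# unit spacing). The wormlike-chain persistence length of tangent
# correlations then follows as
#   1/l_p = ( 1/(2 c_in k) + 1/(2 c_oop k) ) / 2  =>  l_p ~= 1.1 k_bond sigma.
# Tangent-correlation estimates from finite Langevin trajectories scatter
# around (and typically below) this harmonic value; see the methods
# vignette.
.lp_per_k <- 1.1

#' Map inter-triplet bond stiffness to nominal persistence length
#'
#' @param k_bond bond stiffness in kT/sigma^2
#' @return persistence length in sigma
#' @export
kbond_to_lp <- function(k_bond) {
  stopifnot(is.numeric(k_bond), all(k_bond >= 0))
  .lp_per_k * k_bond
}

#' Map nominal persistence length to inter-triplet bond stiffness
#'
#' @param l_p persistence length in sigma
#' @return bond stiffness in kT/sigma^2
#' @export
lp_to_kbond <- function(l_p) {
  stopifnot(is.numeric(l_p), all(l_p >= 0))
  l_p / .lp_per_k
}

#' Filament geometry state
#'
#' The two-state model's switchable target geometry: a closed ring of radius
#' `R` whose units are rotated about the local ring tangent by the tilt angle
#' `tau`. `tau = 0` is the flat state (membrane-binding face in the ring
#' plane); positive `tau` tips the binding face onto a downward cone of
#' aperture `90 - tau` degrees, negative `tau` onto an upward (everted) cone.
#' Rigidity is set either directly through the inter-triplet bond stiffness
#' `k_bond` or through the nominal persistence length `l_p_nm`.
#'
#' @param R_nm target ring radius in nm
#' @param tau_deg signed tilt angle in degrees, in [-90, 90]
#' @param l_p_nm nominal persistence length in nm (used when `k_bond` is NULL)
#' @param k_bond inter-triplet bond stiffness in kT/sigma^2
#' @param units a [unit_system()]
#' @return an object of class `geometry_state` with elements `R` (sigma),
#'   `tau` (degrees), `k_bond` (kT/sigma^2), `l_p` (sigma)
#' @export
geometry_state <- function(R_nm, tau_deg = 0, l_p_nm = 1.8e3, k_bond = NULL,
                           units = unit_system()) {
  if (!is.numeric(tau_deg) || tau_deg < -90 || tau_deg > 90)
    stop("geometry_state: tau must be in [-90, 90] degrees", call. = FALSE)
  R <- to_reduced(R_nm, units)
  if (R <= 1)
    stop("geometry_state: R must exceed the filament bead diameter",
         call. = FALSE)
  if (is.null(k_bond)) {
    l_p <- to_reduced(l_p_nm, units)
    k_bond <- lp_to_kbond(l_p)
  } else {
    l_p <- kbond_to_lp(k_bond)
  }
  structure(list(R = R, tau = tau_deg, k_bond = k_bond, l_p = l_p,
                 units = units),
            class = "geometry_state")
}

#' @export
print.geometry_state <- function(x, ...) {
  cat(sprintf(
    "geometry state: R = %.3g sigma (%.3g nm), tau = %g deg, k_bond = %.3g kT/sigma^2 (l_p ~ %.3g nm)\n",
    x$R, to_nm(x$R, x$units), x$tau, x$k_bond, to_nm(x$l_p, x$units)))
  invisible(x)
}

# ---------------------------------------------------------------------------

.default_config <- function() {
  list(
    units = list(sigma_nm = 2.55, timestep = 0.01),
    geometry = list(R_nm = 20.4, tau_deg = 0, l_p_nm = 1.8e3, k_bond = NA),
    filament = list(n_turns = 3, n_triplets = NA, spacing = 1, gap = 1.1,
                    intra_factor = 10, self_exclusion = TRUE,
                    bind_all3 = FALSE, present = TRUE),
    membrane = list(box_x = 40, box_y = 40, epsilon = 4.34, mu = 3, zeta = 4,
                    r_cut = 2.6, density = 1),
    interactions = list(eps_binder = 4, eps_cargo = 8, adh_range = 0.5,
                        eps_rep = 1, receptor_fraction = 0.5),
    cargo = list(present = FALSE, diameter = 4, receptor_disc = 3),
    run = list(steps = 2e5, equil_steps = NA, seed = 1, temperature = 1,
               gamma_t = 1, gamma_r = 3, skin = 0.4, obs_stride = 200,
               frame_stride = 0, scenario = "flat_relaxation"),
    tension = list(on = TRUE, coupling = 0.002, target = 0)
  )
}

.check_range <- function(errors, value, key, lo = -Inf, hi = Inf,
                         lo_open = FALSE, hi_open = FALSE) {
  bad <- !is.numeric(value) || length(value) != 1L || is.na(value) ||
    (lo_open && value <= lo) || (!lo_open && value < lo) ||
    (hi_open && value >= hi) || (!hi_open && value > hi)
  if (bad)
    errors <- c(errors, sprintf("%s: value %s outside allowed range %s%g, %g%s",
                                key, paste(format(value), collapse = ","),
                                if (lo_open) "(" else "[", lo, hi,
                                if (hi_open) ")" else "]"))
  errors
}

#' Validate a raw run configuration
#'
#' Fills defaults and range-checks every physical parameter. Unknown keys are
#' rejected; all violations are collected and reported together. Validation
#' is pure: the same input always yields the identical parameter object.
#'
#' @param raw_config a (possibly nested) named list of parameter overrides,
#'   e.g. from [read_config()]; `NULL` or an empty list yields all defaults
#' @return an object of class `sim_params`
#' @export
validate_config <- function(raw_config = NULL) {
  cfg <- .default_config()
  errors <- character()
  if (!is.null(raw_config)) {
    if (!is.list(raw_config))
      stop("validate_config: configuration must be a named list", call. = FALSE)
    for (section in names(raw_config)) {
      if (!section %in% names(cfg)) {
        errors <- c(errors, sprintf("%s: unknown configuration section", section))
        next
      }
      sub <- raw_config[[section]]
      if (!is.list(sub)) {
        errors <- c(errors, sprintf("%s: section must be a named list", section))
        next
      }
      for (key in names(sub)) {
        if (!key %in% names(cfg[[section]])) {
          errors <- c(errors, sprintf("%s.%s: unknown configuration key",
                                      section, key))
          next
        }
        cfg[[section]][[key]] <- sub[[key]]
      }
    }
  }
  e <- errors
  e <- .check_range(e, cfg$units$sigma_nm, "units.sigma_nm", 0, Inf, TRUE)
  e <- .check_range(e, cfg$units$timestep, "units.timestep", 0, 0.05, TRUE)
  e <- .check_range(e, cfg$geometry$R_nm, "geometry.R_nm", 0, Inf, TRUE)
  e <- .check_range(e, cfg$geometry$tau_deg, "geometry.tau_deg", -90, 90)
  e <- .check_range(e, cfg$geometry$l_p_nm, "geometry.l_p_nm", 0, Inf, TRUE)
  e <- .check_range(e, cfg$filament$n_turns, "filament.n_turns", 1, 20)
  e <- .check_range(e, cfg$filament$spacing, "filament.spacing", 0.5, 3)
  e <- .check_range(e, cfg$filament$gap, "filament.gap", 1, 5)
  e <- .check_range(e, cfg$filament$intra_factor, "filament.intra_factor",
                    1, 100)
  e <- .check_range(e, cfg$membrane$box_x, "membrane.box_x", 10, Inf)
  e <- .check_range(e, cfg$membrane$box_y, "membrane.box_y", 10, Inf)
  e <- .check_range(e, cfg$membrane$epsilon, "membrane.epsilon", 0, Inf, TRUE)
  e <- .check_range(e, cfg$membrane$mu, "membrane.mu", 0, Inf, TRUE)
  e <- .check_range(e, cfg$membrane$r_cut, "membrane.r_cut", 2 ^ (1 / 6), 5,
                    TRUE)
  e <- .check_range(e, cfg$membrane$density, "membrane.density", 0, 1, TRUE)
  e <- .check_range(e, cfg$interactions$eps_binder, "interactions.eps_binder",
                    0, Inf)
  e <- .check_range(e, cfg$interactions$eps_cargo, "interactions.eps_cargo",
                    0, Inf)
  e <- .check_range(e, cfg$interactions$adh_range, "interactions.adh_range",
                    0, 2, TRUE)
  e <- .check_range(e, cfg$interactions$receptor_fraction,
                    "interactions.receptor_fraction", 0, 1)
  e <- .check_range(e, cfg$run$steps, "run.steps", 0, Inf)
  if (!is.na(cfg$run$equil_steps))
    e <- .check_range(e, cfg$run$equil_steps, "run.equil_steps", 0, Inf)
  e <- .check_range(e, cfg$run$temperature, "run.temperature", 0, Inf)
  e <- .check_range(e, cfg$run$gamma_t, "run.gamma_t", 0, Inf)
  e <- .check_range(e, cfg$run$gamma_r, "run.gamma_r", 0, Inf, TRUE)
  e <- .check_range(e, cfg$run$skin, "run.skin", 0.05, 2)
  e <- .check_range(e, cfg$cargo$diameter, "cargo.diameter", 2, 6)
  if (!cfg$run$scenario %in% c("flat_relaxation", "tilt_switch", "sweep",
                               "cargo_budding"))
    e <- c(e, sprintf("run.scenario: unknown scenario '%s'", cfg$run$scenario))
  if (length(e))
    stop("invalid configuration:\n  - ", paste(e, collapse = "\n  - "),
         call. = FALSE)
  cfg$units <- unit_system(cfg$units$sigma_nm, cfg$units$timestep)
  structure(cfg, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("simulation parameters (", x$run$scenario, " scenario)\n", sep = "")
  cat(sprintf("  geometry: R = %g nm, tau = %g deg, l_p = %g nm\n",
              x$geometry$R_nm, x$geometry$tau_deg, x$geometry$l_p_nm))
  cat(sprintf("  membrane: %g x %g sigma box, epsilon = %g kT\n",
              x$membrane$box_x, x$membrane$box_y, x$membrane$epsilon))
  cat(sprintf("  run: %g steps, seed %d, T = %g\n",
              x$run$steps, as.integer(x$run$seed), x$run$temperature))
  invisible(x)
}

#' Read a YAML run configuration
#'
#' Configuration files are nested YAML maps mirroring the sections of
#' [validate_config()] (geometry, filament, membrane, interactions, cargo,
#' run, tension, units).
#'
#' @param path file path
#' @return a validated `sim_params` object
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  validate_config(yaml::read_yaml(path))
}

# geometry_state from a sim_params, honouring an explicit k_bond override
.state_from_params <- function(params, tau = NULL, R_nm = NULL) {
  g <- params$geometry
  kb <- if (is.na(g$k_bond)) NULL else g$k_bond
  geometry_state(R_nm = if (is.null(R_nm)) g$R_nm else R_nm,
                 tau_deg = if (is.null(tau)) g$tau_deg else tau,
                 l_p_nm = g$l_p_nm, k_bond = kb, units = params$units)
}
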