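# Solvent-free one-particle-thick membrane: parameters, pair interaction
# wrapper, patch construction and equilibration.

#' Membrane interaction parameters
#'
#' Parameters of the anisotropic pair potential between membrane particles.
#' Each particle carries an orientation vector; the pair energy has a soft
#' repulsive core below `r_min`, an attractive tail vanishing smoothly at
#' `r_cut`, and is deepest (-epsilon) when both orientations are parallel to
#' each other and perpendicular to the inter-particle vector, which makes
#' flat, fluid sheets the ground state. `mu` sets how steeply misalignment is
#' penalised and thereby the bending rigidity. Spontaneous curvature is zero
#' throughout (theta0 = 0).
#'
#' @param epsilon pair energy depth in kT
#' @param mu orientation sensitivity weight
#' @param zeta exponent of the attractive-tail distance kernel
#' @param r_cut interaction cutoff in sigma
#' @return an object of class `membrane_params` (r_min is fixed at
#'   2^(1/6) sigma)
#' @export
membrane_params <- function(epsilon = 4.34, mu = 3, zeta = 4, r_cut = 2.6) {
  stopifnot(epsilon > 0, mu > 0, zeta >= 1, r_cut > 2^(1 / 6))
  structure(list(epsilon = epsilon, mu = mu, zeta = as.integer(zeta),
                 r_min = 2^(1 / 6), r_cut = r_cut, theta0 = 0),
            class = "membrane_params")
}

#' Membrane pair interaction (single pair)
#'
#' Energy, forces and orientation torques for one membrane particle pair.
#' Forces are exact negative gradients of the energy with respect to the
#' positions; the returned torques are -dU/dn (unprojected gradients with
#' respect to the orientation vectors; the integrator projects them onto the
#' tangent plane of the unit sphere).
#'
#' @param r_vec displacement x_j - x_i
#' @param n_i,n_j unit orientation vectors
#' @param params a [membrane_params()]
#' @return list with `energy`, `force_j` (force on j; force on i is its
#'   negative), `torque_i`, `torque_j`
#' @export
membrane_pair_interaction <- function(r_vec, n_i, n_j,
                                      params = membrane_params()) {
  stopifnot(length(r_vec) == 3, length(n_i) == 3, length(n_j) == 3)
  if (sum(r_vec^2) == 0)
    stop("membrane_pair_interaction: coincident particles", call. = FALSE)
  cpp_pair_membrane(as.numeric(r_vec), as.numeric(n_i), as.numeric(n_j),
                    params$epsilon, params$mu, params$zeta, params$r_min,
                    params$r_cut)
}

# ---------------------------------------------------------------------------
# particle system container

.SPECIES <- c(membrane = 1L, receptor = 2L, binder = 3L, core = 4L,
              cargo = 5L)

#' Create a particle system
#'
#' @param pos N x 3 positions
#' @param species integer codes (1 membrane, 2 receptor, 3 binder, 4 core,
#'   5 cargo) or character labels
#' @param box periodic box lengths c(Lx, Ly); z is open
#' @param vel N x 3 velocities (default zero)
#' @param ornt N x 3 unit orientation vectors (membrane particles only;
#'   zero rows elsewhere)
#' @return an object of class `particle_system`
#' @export
particle_system <- function(pos, species, box, vel = NULL, ornt = NULL) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  if (is.character(species)) species <- .SPECIES[species]
  species <- as.integer(species)
  stopifnot(ncol(pos) == 3, length(species) == n, length(box) == 2,
            all(box > 0), all(species >= 1L & species <= 5L))
  if (is.null(vel)) vel <- matrix(0, n, 3)
  if (is.null(ornt)) {
    ornt <- matrix(0, n, 3)
    ornt[species <= 2L, 3] <- 1
  }
  mem <- species <= 2L
  if (any(mem)) {
    nrm <- sqrt(rowSums(ornt[mem, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-9))
      stop("particle_system: orientation vectors must have unit norm",
           call. = FALSE)
  }
  pos[, 1] <- pos[, 1] %% box[1]
  pos[, 2] <- pos[, 2] %% box[2]
  structure(list(pos = pos, vel = as.matrix(vel), ornt = as.matrix(ornt),
                 species = species, box = as.numeric(box),
                 images = matrix(0L, n, 2), step = 0),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  tab <- table(factor(x$species, levels = 1:5,
                      labels = names(.SPECIES)))
  cat(sprintf("particle system: %d particles in %.3g x %.3g box (step %g)\n",
              nrow(x$pos), x$box[1], x$box[2], x$step))
  print(tab[tab > 0])
  invisible(x)
}

# number of particles in a triangular lattice patch commensurate with the box
.lattice_dims <- function(box_x, box_y, a) {
  nx <- max(1L, round(box_x / a))
  ny <- max(2L, 2L * round(box_y / (a * sqrt(3))))
  c(nx = nx, ny = ny)
}

#' Build a flat membrane patch
#'
#' Triangular lattice at the model's preferred spacing (r_min, scaled by
#' `density^(-1/2)`), at z = 0, all orientations +z. The lattice is made
#' commensurate with the periodic box, so the particle count is a
#' deterministic function of the box and density.
#'
#' @param box_x,box_y box lengths in sigma (at least 20)
#' @param params a [membrane_params()]
#' @param density areal density relative to the r_min triangular lattice
#' @return a `particle_system` of membrane particles
#' @export
build_flat_patch <- function(box_x, box_y, params = membrane_params(),
                             density = 1) {
  stopifnot(box_x >= 20, box_y >= 20, density > 0, density <= 1)
  a <- params$r_min / sqrt(density)
  nd <- .lattice_dims(box_x, box_y, a)
  ax <- box_x / nd["nx"]
  ay <- box_y / nd["ny"]
  ii <- rep(seq_len(nd["nx"]) - 1L, times = nd["ny"])
  jj <- rep(seq_len(nd["ny"]) - 1L, each = nd["nx"])
  x <- (ii + 0.5 * (jj %% 2L)) * ax
  y <- (jj + 0.5) * ay
  pos <- cbind(x %% box_x, y %% box_y, 0)
  particle_system(pos, rep(1L, length(x)), c(box_x, box_y))
}

#' Neighbour counts within a cutoff (PBC in x, y)
#'
#' @param system a `particle_system`
#' @param cutoff neighbour distance in sigma
#' @param subset optional particle indices
#' @return integer vector of neighbour counts
#' @export
neighbor_counts <- function(system, cutoff, subset = NULL) {
  idx <- if (is.null(subset)) seq_len(nrow(system$pos)) else subset
  p <- system$pos[idx, , drop = FALSE]
  n <- nrow(p)
  dx <- outer(p[, 1], p[, 1], "-")
  dy <- outer(p[, 2], p[, 2], "-")
  dz <- outer(p[, 3], p[, 3], "-")
  Lx <- system$box[1]; Ly <- system$box[2]
  dx <- dx - Lx * round(dx / Lx)
  dy <- dy - Ly * round(dy / Ly)
  d2 <- dx^2 + dy^2 + dz^2
  rowSums(d2 < cutoff^2) - 1L
}

#' Equilibrate a membrane patch
#'
#' Runs thermostatted Langevin dynamics with lateral box rescaling toward
#' zero lateral tension, and checks the outcome: the sheet must stay flat on
#' average and must not rupture (every particle keeps at least 3 neighbours
#' within the interaction cutoff).
#'
#' @param system a patch from [build_flat_patch()]
#' @param steps number of integration steps
#' @param seed RNG seed
#' @param params a [membrane_params()]
#' @param settings an [integrator_settings()]; the seed argument overrides
#'   its seed
#' @param tension a [tension_settings()]
#' @return the equilibrated `particle_system`
#' @export
equilibrate_patch <- function(system, steps = 2e4, seed = 1,
                              params = membrane_params(),
                              settings = integrator_settings(seed = seed),
                              tension = tension_settings()) {
  settings$seed <- seed
  res <- run_dynamics(system, topology = NULL, settings = settings,
                      n_steps = steps, membrane = params, tension = tension,
                      obs_stride = max(1L, as.integer(steps / 50)))
  out <- res$system
  nb <- neighbor_counts(out, params$r_cut)
  if (any(nb == 0))
    stop("equilibrate_patch: membrane ruptured (isolated particles); ",
         "reduce temperature or increase epsilon", call. = FALSE)
  if (any(nb < 3))
    warning("equilibrate_patch: membrane has under-coordinated particles")
  zc <- out$pos[, 3] - mean(out$pos[, 3])
  if (mean(abs(zc)) > 1)
    warning("equilibrate_patch: patch is not flat (mean |z| > 1 sigma)")
  out
}
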