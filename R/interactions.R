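# Non-membrane interactions: bonds, excluded volume, adhesion, cargo set-up.

#' Adhesion parameters
#'
#' Short-range isotropic attractions: binder beads adhere to every membrane
#' particle with depth `eps_binder`; the cargo sphere adheres only to
#' receptor-labelled membrane particles with depth `eps_cargo`. Both are a
#' purely repulsive core vanishing at the contact distance sigma_ij plus a
#' smooth cos^2 tail of width `adh_range` sigma.
#'
#' @param eps_binder binder-membrane depth in kT
#' @param eps_cargo cargo-receptor depth in kT
#' @param adh_range attractive tail width in sigma
#' @param receptor_fraction fraction of membrane particles labelled receptor
#'   inside the receptor disc
#' @param bind_all3 when TRUE the core bead adheres like the binders
#' @param eps_rep energy scale of all repulsive cores (kT)
#' @return an object of class `adhesion_params`
#' @export
adhesion_params <- function(eps_binder = 4, eps_cargo = 8, adh_range = 0.5,
                            receptor_fraction = 0.5, bind_all3 = FALSE,
                            eps_rep = 1) {
  stopifnot(eps_binder >= 0, eps_cargo >= 0, adh_range > 0,
            receptor_fraction >= 0, receptor_fraction <= 1, eps_rep > 0)
  structure(list(eps_binder = eps_binder, eps_cargo = eps_cargo,
                 adh_range = adh_range,
                 receptor_fraction = receptor_fraction,
                 bind_all3 = isTRUE(bind_all3), eps_rep = eps_rep),
            class = "adhesion_params")
}

#' Harmonic bond energy and force (single pair)
#'
#' E = k/2 (|r| - rest)^2, force along the bond.
#'
#' @param r_vec displacement x_j - x_i
#' @param rest rest length
#' @param k stiffness (kT/sigma^2)
#' @return list with `energy` and `force_j` (force on j)
#' @export
bond_force <- function(r_vec, rest, k) {
  stopifnot(length(r_vec) == 3, rest > 0, k >= 0)
  cpp_pair_bond(as.numeric(r_vec), rest, k)
}

#' Excluded-volume energy and force (single pair)
#'
#' Purely repulsive core, exactly zero at and beyond the contact distance
#' `sigma_c` and strictly decreasing inside it.
#'
#' @param r_vec displacement x_j - x_i
#' @param sigma_c contact distance (mean of the two bead diameters)
#' @param eps_rep repulsion energy scale (kT)
#' @return list with `energy` and `force_j`
#' @export
excluded_volume_force <- function(r_vec, sigma_c = 1, eps_rep = 1) {
  stopifnot(length(r_vec) == 3, sigma_c > 0)
  cpp_pair_wca(as.numeric(r_vec), sigma_c, eps_rep)
}

#' Adhesion energy and force (single pair)
#'
#' Repulsive core with a smooth attractive tail: energy -eps at the contact
#' distance, zero at and beyond `sigma_c + adh_range`.
#'
#' @param r_vec displacement x_j - x_i
#' @param eps adhesion depth (kT)
#' @param sigma_c contact distance
#' @param adh_range tail width (sigma)
#' @param eps_rep repulsive core scale (kT)
#' @return list with `energy` and `force_j`
#' @export
adhesion_force <- function(r_vec, eps, sigma_c = 1, adh_range = 0.5,
                           eps_rep = 1) {
  stopifnot(length(r_vec) == 3, eps >= 0, sigma_c > 0, adh_range > 0)
  cpp_pair_adhesion(as.numeric(r_vec), sigma_c, eps, adh_range, eps_rep)
}

# ---------------------------------------------------------------------------
# cargo and receptor set-up

#' Add a cargo sphere with membrane receptors
#'
#' Places a single cargo sphere (diameter 4 sigma) at `xy` resting on the
#' membrane, and labels membrane particles within a disc of radius
#' `receptor_disc` under the cargo as receptors, each with probability
#' `receptor_fraction`. Receptor labelling is the only route by which the
#' cargo can adhere: it interacts with plain membrane particles purely
#' repulsively.
#'
#' @param system a `particle_system` containing the membrane
#' @param xy cargo centre in the membrane plane
#' @param receptor_disc receptor disc radius in sigma
#' @param receptor_fraction labelling probability within the disc
#' @param seed RNG seed for the labelling draw
#' @param diameter cargo diameter in sigma (fixed bead diameters elsewhere
#'   assume the default 4)
#' @return the augmented `particle_system` (cargo appended last)
#' @export
add_cargo <- function(system, xy = NULL, receptor_disc = 3,
                      receptor_fraction = 0.5, seed = 1, diameter = 4) {
  stopifnot(inherits(system, "particle_system"))
  if (is.null(xy)) xy <- system$box / 2
  mem <- which(system$species <= 2L)
  if (!length(mem)) stop("add_cargo: no membrane present", call. = FALSE)
  dx <- system$pos[mem, 1] - xy[1]
  dy <- system$pos[mem, 2] - xy[2]
  dx <- dx - system$box[1] * round(dx / system$box[1])
  dy <- dy - system$box[2] * round(dy / system$box[2])
  in_disc <- which(dx^2 + dy^2 < receptor_disc^2)
  old <- .Random.seed_save()
  set.seed(as.integer(seed %% .Machine$integer.max))
  lab <- in_disc[runif(length(in_disc)) < receptor_fraction]
  .Random.seed_restore(old)
  system$species[mem[lab]] <- 2L
  z0 <- mean(system$pos[mem, 3][dx^2 + dy^2 < receptor_disc^2])
  if (!is.finite(z0)) z0 <- mean(system$pos[mem, 3])
  cargo_z <- z0 + (diameter + 1) / 2 + 0.3 # just above contact; adhesion
                                           # pulls it in during settling
  system$pos <- rbind(system$pos, c(xy[1], xy[2], cargo_z))
  system$vel <- rbind(system$vel, c(0, 0, 0))
  system$ornt <- rbind(system$ornt, c(0, 0, 0))
  system$species <- c(system$species, 5L)
  system$images <- rbind(system$images, c(0L, 0L))
  system
}

# save/restore the global RNG state so builders do not disturb user code
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Merge a filament (and its topology) into a membrane system
#'
#' Appends the filament beads to the system and offsets the topology's
#' particle indices accordingly.
#'
#' @param system a `particle_system`
#' @param filament result of [build_flat_spiral()]
#' @return list with the merged `system` and global-index `topology`
#' @export
add_filament <- function(system, filament) {
  stopifnot(inherits(system, "particle_system"))
  off <- nrow(system$pos)
  n <- nrow(filament$pos)
  species <- rep(c(3L, 3L, 4L), n / 3)
  system$pos <- rbind(system$pos, filament$pos)
  system$vel <- rbind(system$vel, matrix(0, n, 3))
  system$ornt <- rbind(system$ornt, matrix(0, n, 3))
  system$species <- c(system$species, species)
  system$images <- rbind(system$images, matrix(0L, n, 2))
  system$pos[, 1] <- system$pos[, 1] %% system$box[1]
  system$pos[, 2] <- system$pos[, 2] %% system$box[2]
  topo <- filament$topology
  topo$triplets <- topo$triplets + off
  topo$bonds$i <- topo$bonds$i + off
  topo$bonds$j <- topo$bonds$j + off
  list(system = system, topology = topo)
}

#' Total potential energy decomposition
#'
#' Single force evaluation on the current configuration; the components sum
#' to the engine's total potential energy.
#'
#' @param system a `particle_system`
#' @param topology a `filament_topology` or NULL
#' @param membrane a [membrane_params()]
#' @param adhesion an [adhesion_params()]
#' @param all_pairs use the O(N^2) reference path instead of neighbour lists
#' @return list with forces, torques and energy components
#' @export
energy_breakdown <- function(system, topology = NULL,
                             membrane = membrane_params(),
                             adhesion = adhesion_params(),
                             all_pairs = FALSE) {
  cp <- .cpp_params(membrane, adhesion, integrator_settings(),
                    tension_settings(on = FALSE),
                    self_excl = is.null(topology) ||
                      isTRUE(topology$self_exclusion))
  bt <- .bond_matrix(topology)
  cpp_compute_forces(system$pos, system$vel, system$ornt, system$species,
                     system$box, bt$bonds, bt$tethers, cp, all_pairs)
}
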