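# Filament geometry: target rings, tilt, rest-length tables, initial spirals,
# and the two-state geometry switch.
#
# A filament is a chain of rigid three-bead units: two membrane-binding
# "binder" beads side by side ACROSS the filament axis (one on the inner,
# one on the outer edge of the ribbon) and one "core" bead stacked above
# their midpoint. The stress-free configuration is a closed ring of radius
# R; rotating every unit about its local ring tangent by the tilt angle tau
# moves the binding face onto a cone of aperture 90 - tau degrees. All
# inter-unit elasticity lives in 9 bonds connecting every bead pair of
# adjacent units; the full 3 x 3 bond set is the minimal arrangement that
# makes every rigid-body mode of a unit pair (stretch, two bends, twist)
# harmonically stiff and locks the chirality of the spiral.

.BINDER_SEP <- 1.0   # binder-binder separation across the ribbon (sigma)
.CORE_LIFT <- 1.0    # core bead height above the binder midpoint (sigma)

# rotation matrix about unit axis, right-hand rule, angle in radians
.rot_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) * c_ + s_ * K + (1 - c_) * (a %*% t(a))
}

# bead offsets of one unit in its local frame (tangent, radial, vertical),
# after tilting by tau about the tangent. Rows: binderA (inner edge),
# binderB (outer edge), core (stacked above the midline).
.unit_offsets <- function(tau_deg) {
  base <- rbind(c(0, -.BINDER_SEP / 2, 0),
                c(0, +.BINDER_SEP / 2, 0),
                c(0, 0, .CORE_LIFT))
  th <- tau_deg * pi / 180
  # rotation about the local tangent; positive tau tips the core bead
  # outward and the membrane-binding face inward-and-down, which buckles the
  # membrane away from the cytoplasm (downward)
  Rm <- matrix(c(1, 0, 0,
                 0, cos(th), -sin(th),
                 0, sin(th), cos(th)), 3, 3, byrow = TRUE)
  base %*% t(Rm)
}

#' Construct a target ring geometry
#'
#' Places `n = round(2*pi*R / spacing)` three-bead units at uniform angular
#' intervals on a circle of radius `R` in the z = 0 plane, each unit rotated
#' by the tilt angle `tau` about its local ring tangent. The construction is
#' deterministic; its inter-unit bead distances define the bond rest lengths
#' of the geometry state (see [compute_rest_lengths()]).
#'
#' @param R ring radius in sigma
#' @param tau signed tilt angle in degrees, in [-90, 90]
#' @param spacing inter-unit arc distance in sigma
#' @return an object of class `target_ring` with per-unit frames and bead
#'   coordinates (matrix of n_triplets x 3 beads)
#' @export
build_target_ring <- function(R, tau = 0, spacing = 1) {
  if (tau < -90 || tau > 90)
    stop("build_target_ring: tau must be in [-90, 90] degrees", call. = FALSE)
  if (R <= spacing / pi)
    stop("build_target_ring: R too small to fit at least 3 units",
         call. = FALSE)
  n <- round(2 * pi * R / spacing)
  if (n < 3)
    stop("build_target_ring: R too small to fit at least 3 units",
         call. = FALSE)
  phi <- 2 * pi * (seq_len(n) - 1) / n
  off <- .unit_offsets(tau)
  beads <- array(NA_real_, dim = c(n, 3, 3),
                 dimnames = list(NULL, c("binderA", "binderB", "core"), NULL))
  centers <- cbind(R * cos(phi), R * sin(phi), 0)
  for (k in seq_len(n)) {
    tangent <- c(-sin(phi[k]), cos(phi[k]), 0)
    radial <- c(cos(phi[k]), sin(phi[k]), 0)
    vert <- c(0, 0, 1)
    M <- cbind(tangent, radial, vert)       # local -> lab
    beads[k, , ] <- sweep(off %*% t(M), 2, centers[k, ], "+")
  }
  structure(list(R = R, tau = tau, spacing = spacing, n_triplets = n,
                 centers = centers, beads = beads),
            class = "target_ring")
}

#' @export
print.target_ring <- function(x, ...) {
  cat(sprintf("target ring: R = %g sigma, tau = %g deg, %d triplets\n",
              x$R, x$tau, x$n_triplets))
  invisible(x)
}

#' Cone aperture of a tilted state
#'
#' The membrane attachment sites of a filament tilted by `tau` lie on a cone
#' of aperture `90 - tau` degrees: 90 (a flat plane) at `tau = 0`, 0 (a
#' tubule) at `tau = 90`.
#'
#' @param tau tilt angle in degrees, in [-90, 90]
#' @return aperture angle in degrees
#' @export
aperture_of_tilt <- function(tau) {
  if (any(!is.finite(tau)) || any(tau < -90) || any(tau > 90))
    stop("aperture_of_tilt: tau must be in [-90, 90] degrees", call. = FALSE)
  90 - tau
}

#' Bond rest lengths of a target geometry
#'
#' The 3 intra-unit rest lengths are the within-unit bead distances; the 9
#' inter-unit rest lengths are the pairwise distances between the beads of
#' two adjacent units in the target ring. By ring symmetry the table is
#' identical for every consecutive pair and depends only on (R, tau,
#' spacing).
#'
#' @param ring a [build_target_ring()] object
#' @return a list with `intra` (length-3 vector, AB, AC, BC) and `inter`
#'   (3 x 3 matrix; entry [a, b] is the distance from bead a of unit k to
#'   bead b of unit k + 1)
#' @export
compute_rest_lengths <- function(ring) {
  stopifnot(inherits(ring, "target_ring"))
  u1 <- ring$beads[1, , ]
  u2 <- ring$beads[2, , ]
  intra <- c(AB = sqrt(sum((u1[1, ] - u1[2, ])^2)),
             AC = sqrt(sum((u1[1, ] - u1[3, ])^2)),
             BC = sqrt(sum((u1[2, ] - u1[3, ])^2)))
  inter <- matrix(NA_real_, 3, 3,
                  dimnames = list(c("binderA", "binderB", "core"),
                                  c("binderA", "binderB", "core")))
  for (a in 1:3)
    for (b in 1:3)
      inter[a, b] <- sqrt(sum((u1[a, ] - u2[b, ])^2))
  if (any(c(intra, inter) <= 0) || any(c(intra, inter) > 3))
    stop("compute_rest_lengths: degenerate rest-length table", call. = FALSE)
  list(intra = intra, inter = inter)
}

# ---------------------------------------------------------------------------
# topology assembly

# Builds the bond table for n_total units laid head-to-tail, using the rest
# lengths of the TARGET ring (not the actual positions). Indices are local
# (1 .. 3 * n_total); bead order within unit k: binderA, binderB, core.
.filament_bonds <- function(n_total, rest, k_bond, intra_factor) {
  # intra-unit stiffness: intra_factor times the inter-unit stiffness, capped
  # at 2000 kT/sigma^2 (units are already effectively rigid there, and the
  # stable timestep scales as 1/sqrt(k_max))
  k_intra <- min(intra_factor * k_bond, max(k_bond, 2000))
  nb <- (n_total) * 3 + (n_total - 1) * 9
  bi <- integer(nb); bj <- integer(nb); r0 <- numeric(nb); kk <- numeric(nb)
  row <- 0L
  pairs_intra <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  for (u in seq_len(n_total)) {
    base <- (u - 1L) * 3L
    for (p in 1:3) {
      row <- row + 1L
      bi[row] <- base + pairs_intra[p, 1]
      bj[row] <- base + pairs_intra[p, 2]
      r0[row] <- rest$intra[p]
      kk[row] <- k_intra
    }
  }
  for (u in seq_len(n_total - 1L)) {
    b1 <- (u - 1L) * 3L
    b2 <- u * 3L
    for (a in 1:3)
      for (b in 1:3) {
        row <- row + 1L
        bi[row] <- b1 + a
        bj[row] <- b2 + b
        r0[row] <- rest$inter[a, b]
        kk[row] <- k_bond
      }
  }
  data.frame(i = bi, j = bj, r0 = r0, k = kk)
}

#' Build the initial planar spiral filament
#'
#' Lays `n_triplets_total` units along an Archimedean spiral (inter-arm gap
#' `min_gap`) with all binder faces down, and builds the bond topology whose
#' rest lengths are those of the TARGET ring, so the spiral starts with
#' strictly positive stored bond energy whenever it is longer than the target
#' circumference.
#'
#' @param n_triplets_total number of three-bead units (> ring$n_triplets for
#'   a true spiral; equal gives the degenerate single ring)
#' @param ring the target [build_target_ring()] (flat state for the
#'   standard initial condition)
#' @param min_gap centre-to-centre distance between neighbouring spiral arms
#'   in sigma
#' @param intra_factor intra-unit bonds are `intra_factor` times stiffer than
#'   the inter-unit stiffness of the geometry state
#' @param k_bond inter-unit bond stiffness (kT/sigma^2)
#' @param center xy centre of the spiral
#' @param z_binder height of the binder beads (contact distance above a
#'   membrane mid-plane at z = 0)
#' @param inner_radius innermost arm radius; default fits the target radius
#'   turn count; raise it to corral a cargo sphere
#' @param self_exclusion logical; volume exclusion between non-bonded
#'   filament beads
#' @return a list with `pos` (3 n x 3 bead coordinates), `topology` (a
#'   `filament_topology`: triplet table, bonds, state, flags)
#' @export
build_flat_spiral <- function(n_triplets_total, ring, min_gap = 1.1,
                              k_bond, intra_factor = 10,
                              center = c(0, 0), z_binder = 1.0,
                              inner_radius = NULL, self_exclusion = TRUE) {
  stopifnot(inherits(ring, "target_ring"))
  n <- as.integer(n_triplets_total)
  if (n < ring$n_triplets)
    stop("build_flat_spiral: filament shorter than the target circumference",
         call. = FALSE)
  d <- ring$spacing
  if (n == ring$n_triplets && is.null(inner_radius)) {
    # degenerate case: the filament exactly fits its target ring
    pos <- do.call(rbind, lapply(seq_len(n), function(k) ring$beads[k, , ]))
    pos[, 1] <- pos[, 1] + center[1]
    pos[, 2] <- pos[, 2] + center[2]
    pos[, 3] <- pos[, 3] + z_binder
    rest <- compute_rest_lengths(ring)
    bonds <- .filament_bonds(n, rest, k_bond, intra_factor)
    topology <- structure(
      list(triplets = matrix(seq_len(3 * n), ncol = 3, byrow = TRUE,
                             dimnames = list(NULL, c("binderA", "binderB",
                                                     "core"))),
           bonds = bonds, n_triplets = n,
           state = list(R = ring$R, tau = ring$tau, spacing = ring$spacing,
                        k_bond = k_bond),
           intra_factor = intra_factor,
           self_exclusion = isTRUE(self_exclusion),
           tethers = data.frame(i = integer(), px = numeric(),
                                py = numeric(), pz = numeric(),
                                k = numeric())),
      class = "filament_topology")
    return(list(pos = pos, topology = topology, outer_radius = ring$R))
  }
  b <- min_gap / (2 * pi)                   # Archimedean r = r0 + b*theta
  r0 <- if (is.null(inner_radius)) max(1.5, ring$R - min_gap) else inner_radius
  # place unit centres at uniform arc spacing d along the spiral
  centers <- matrix(NA_real_, n, 3)
  tangents <- matrix(NA_real_, n, 3)
  theta <- 0
  for (k in seq_len(n)) {
    r <- r0 + b * theta
    centers[k, ] <- c(center[1] + r * cos(theta), center[2] + r * sin(theta),
                      z_binder)
    tv <- c(-r * sin(theta) + b * cos(theta),
            r * cos(theta) + b * sin(theta), 0)
    tangents[k, ] <- tv / sqrt(sum(tv^2))
    theta <- theta + d / sqrt(r^2 + b^2)
  }
  off <- .unit_offsets(0)                    # flat state placement
  pos <- matrix(NA_real_, 3 * n, 3)
  for (k in seq_len(n)) {
    tangent <- tangents[k, ]
    radial <- c(tangent[2], -tangent[1], 0)  # outward-ish; flat state: unused tilt
    vert <- c(0, 0, 1)
    M <- cbind(tangent, radial, vert)
    pos[(3 * (k - 1) + 1):(3 * k), ] <-
      sweep(off %*% t(M), 2, centers[k, ], "+")
  }
  rest <- compute_rest_lengths(ring)
  bonds <- .filament_bonds(n, rest, k_bond, intra_factor)
  topology <- structure(
    list(triplets = matrix(seq_len(3 * n), ncol = 3, byrow = TRUE,
                           dimnames = list(NULL, c("binderA", "binderB",
                                                   "core"))),
         bonds = bonds,
         n_triplets = n,
         state = list(R = ring$R, tau = ring$tau, spacing = ring$spacing,
                      k_bond = k_bond),
         intra_factor = intra_factor,
         self_exclusion = isTRUE(self_exclusion),
         tethers = data.frame(i = integer(), px = numeric(), py = numeric(),
                              pz = numeric(), k = numeric())),
    class = "filament_topology")
  list(pos = pos, topology = topology,
       outer_radius = max(sqrt((centers[, 1] - center[1])^2 +
                               (centers[, 2] - center[2])^2)))
}

#' @export
print.filament_topology <- function(x, ...) {
  cat(sprintf(
    "filament topology: %d triplets, %d bonds, state (R = %g, tau = %g deg), self-exclusion %s\n",
    x$n_triplets, nrow(x$bonds), x$state$R, x$state$tau,
    if (x$self_exclusion) "on" else "off"))
  invisible(x)
}

#' Build a stress-free filament arc
#'
#' Places the first `n_triplets` units of the target ring as an open chain
#' with zero initial bond energy. Used for free-filament reference runs
#' (persistence-length calibration, energy-conservation checks); with a
#' large-radius ring this yields a nearly straight filament.
#'
#' @param n_triplets number of units (at most `ring$n_triplets`)
#' @param ring the target [build_target_ring()]
#' @param k_bond inter-unit bond stiffness (kT/sigma^2)
#' @param intra_factor intra-unit stiffness multiplier
#' @param self_exclusion volume exclusion between non-bonded beads
#' @return list with `pos` and `topology` as [build_flat_spiral()]
#' @export
build_filament_arc <- function(n_triplets, ring, k_bond, intra_factor = 10,
                               self_exclusion = TRUE) {
  stopifnot(inherits(ring, "target_ring"))
  n <- as.integer(n_triplets)
  if (n < 2 || n > ring$n_triplets)
    stop("build_filament_arc: need 2 <= n_triplets <= ring$n_triplets",
         call. = FALSE)
  pos <- do.call(rbind, lapply(seq_len(n), function(k) ring$beads[k, , ]))
  rest <- compute_rest_lengths(ring)
  bonds <- .filament_bonds(n, rest, k_bond, intra_factor)
  topology <- structure(
    list(triplets = matrix(seq_len(3 * n), ncol = 3, byrow = TRUE,
                           dimnames = list(NULL, c("binderA", "binderB",
                                                   "core"))),
         bonds = bonds, n_triplets = n,
         state = list(R = ring$R, tau = ring$tau, spacing = ring$spacing,
                      k_bond = k_bond),
         intra_factor = intra_factor,
         self_exclusion = isTRUE(self_exclusion),
         tethers = data.frame(i = integer(), px = numeric(), py = numeric(),
                              pz = numeric(), k = numeric())),
    class = "filament_topology")
  list(pos = pos, topology = topology)
}

#' Switch the filament between geometry states
#'
#' Globally and instantly replaces every inter-unit bond rest length with the
#' table of the new state, leaving particle positions untouched. This is the
#' model's energy input step: the stored elastic energy of the filament
#' changes discontinuously, mimicking a change in filament composition.
#'
#' @param topology a `filament_topology` built by [build_flat_spiral()]
#' @param new_state a [geometry_state()] or a `target_ring`
#' @return the updated topology
#' @export
switch_geometry_state <- function(topology, new_state) {
  stopifnot(inherits(topology, "filament_topology"))
  if (inherits(new_state, "geometry_state")) {
    ring <- build_target_ring(new_state$R, new_state$tau,
                              spacing = topology$state$spacing)
    k_bond <- new_state$k_bond
  } else if (inherits(new_state, "target_ring")) {
    ring <- new_state
    k_bond <- topology$state$k_bond
  } else stop("switch_geometry_state: new_state must be a geometry_state or target_ring",
              call. = FALSE)
  if (is.null(topology$n_triplets) || topology$n_triplets < 2)
    stop("switch_geometry_state: topology has no triplet chain", call. = FALSE)
  rest <- compute_rest_lengths(ring)
  n <- topology$n_triplets
  n_intra <- 3L * n
  inter_rows <- seq(n_intra + 1L, nrow(topology$bonds))
  # inter bonds were laid down unit by unit in (a, b) row-major order
  topology$bonds$r0[inter_rows] <- rep(as.vector(t(rest$inter)), n - 1L)
  topology$bonds$k[inter_rows] <- k_bond
  topology$state <- list(R = ring$R, tau = ring$tau, spacing = ring$spacing,
                         k_bond = k_bond)
  topology
}
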