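# Measurement of everything the model predicts: deformation depth and shape,
# filament conformation, persistence length, scission, membrane mechanics.
#
# Sign convention: the cytoplasm (filament side) is at z > 0; deformations
# "away from the cytoplasm" are negative depths.

# lateral-position mask of the largest connected membrane component: the
# occasional particle (or small cluster) knocked out of the sheet would
# otherwise masquerade as an extreme deformation. After scission this also
# gives the depth field its natural meaning: the state of the parent sheet.
# The mask cutoff (2 sigma) is looser than the scission contact cutoff so
# that steep but continuous deformations stay connected.
.main_component_rows <- function(p, L, cutoff = 2.0) {
  n <- nrow(p)
  if (n < 3) return(rep(TRUE, n))
  pairs <- .contact_pairs(p, L, cutoff)
  if (!nrow(pairs)) return(rep(TRUE, n))
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  comp$membership == which.max(comp$csize)
}

# membrane height field on a square lateral grid (bin width `bin` sigma),
# restricted to the largest connected membrane component; bins holding
# fewer than `min_count` particles are dropped.
.height_field <- function(system, bin = 2, min_count = 2) {
  mem <- system$species <= 2L
  if (!any(mem)) stop("no membrane present", call. = FALSE)
  p <- system$pos[mem, , drop = FALSE]
  p <- p[.main_component_rows(p, system$box), , drop = FALSE]
  nx <- max(4L, floor(system$box[1] / bin))
  ny <- max(4L, floor(system$box[2] / bin))
  ix <- pmin(nx, 1L + floor(p[, 1] / system$box[1] * nx))
  iy <- pmin(ny, 1L + floor(p[, 2] / system$box[2] * ny))
  idx <- (iy - 1L) * nx + ix
  sums <- tapply(p[, 3], idx, mean)
  cnts <- tapply(p[, 3], idx, length)
  sums[cnts < min_count] <- NA_real_
  h <- matrix(NA_real_, nx, ny)
  h[as.integer(names(sums))] <- sums
  list(h = h, nx = nx, ny = ny,
       cx = (seq_len(nx) - 0.5) * system$box[1] / nx,
       cy = (seq_len(ny) - 0.5) * system$box[2] / ny)
}

#' Signed membrane deformation depth
#'
#' Bins the membrane into a lateral grid (bin width 2 sigma) of mean
#' heights. The reference plane is the median of the bins in the outer 20
#' percent annulus of the box; the depth is the extremal bin mean relative
#' to that reference, reported with its sign (negative = away from the
#' cytoplasm). Binning suppresses single-particle thermal noise.
#'
#' @param system a `particle_system` (or a frame coerced to one)
#' @param bin bin width in sigma
#' @return signed depth in sigma
#' @export
deformation_depth <- function(system, bin = 2) {
  hf <- .height_field(system, bin)
  ctr <- system$box / 2
  rx <- abs(hf$cx - ctr[1])
  ry <- abs(hf$cy - ctr[2])
  r <- sqrt(outer(rx^2, ry^2, "+"))
  r_annulus <- 0.8 * min(system$box) / 2
  ref_bins <- hf$h[r >= r_annulus]
  ref_bins <- ref_bins[!is.na(ref_bins)]
  if (!length(ref_bins))
    stop("deformation_depth: no occupied bins in the reference annulus ",
         "(box too small)", call. = FALSE)
  ref <- median(ref_bins)
  dev <- hf$h - ref
  lo <- min(dev, na.rm = TRUE)
  hi <- max(dev, na.rm = TRUE)
  if (abs(lo) >= abs(hi)) lo else hi
}

#' Classify a membrane deformation
#'
#' Fits the radius-versus-height profile of the deformed region: a
#' near-constant radius is a tubule (aperture below 15 degrees), a linearly
#' shrinking radius a cone; the sign comes from the depth. Deformations
#' shallower than 2 sigma are classified `none`.
#'
#' @param system a `particle_system`
#' @param bin depth-field bin width in sigma
#' @return list with `shape_class` (none, cone_down, cone_up, tubule_down,
#'   tubule_up), `aperture_est` (degrees, NA for none) and `depth` (sigma)
#' @export
classify_deformation <- function(system, bin = 2) {
  depth <- deformation_depth(system, bin)
  if (abs(depth) <= 2)
    return(list(shape_class = "none", aperture_est = NA_real_,
                depth = depth))
  mem <- system$species <= 2L
  p <- system$pos[mem, , drop = FALSE]
  p <- p[.main_component_rows(p, system$box), , drop = FALSE]
  hf <- .height_field(system, bin)
  ctr <- system$box / 2
  r_annulus <- 0.8 * min(system$box) / 2
  rx <- abs(hf$cx - ctr[1]); ry <- abs(hf$cy - ctr[2])
  rr <- sqrt(outer(rx^2, ry^2, "+"))
  ref <- median(hf$h[rr >= r_annulus], na.rm = TRUE)
  sgn <- sign(depth)
  z <- (p[, 3] - ref) * sgn                # deformed side positive
  # consider only the band the (outlier-robust) depth vouches for
  sel <- z > 1 & z <= abs(depth) + 2
  if (sum(sel) < 10)
    return(list(shape_class = if (sgn < 0) "cone_down" else "cone_up",
                aperture_est = NA_real_, depth = depth))
  pd <- p[sel, , drop = FALSE]
  zd <- z[sel]
  # lateral axis of the deformation: centroid of the deepest quartile
  deep <- zd >= stats::quantile(zd, 0.75)
  ax <- c(mean(pd[deep, 1]), mean(pd[deep, 2]))
  rho <- sqrt((pd[, 1] - ax[1])^2 + (pd[, 2] - ax[2])^2)
  # mean radius per height slab
  nslab <- max(3L, min(10L, floor(max(zd) - 1)))
  brk <- seq(1, max(zd) + 1e-9, length.out = nslab + 1L)
  sl <- cut(zd, brk, include.lowest = TRUE)
  rmean <- tapply(rho, sl, mean)
  zmean <- tapply(zd, sl, mean)
  ok <- is.finite(rmean) & is.finite(zmean)
  if (sum(ok) < 3)
    return(list(shape_class = if (sgn < 0) "cone_down" else "cone_up",
                aperture_est = NA_real_, depth = depth))
  fit <- lm(rmean[ok] ~ zmean[ok])
  slope <- abs(coef(fit)[2])
  aperture <- atan(slope) * 180 / pi
  shape <- if (aperture < 15) "tubule" else "cone"
  list(shape_class = paste0(shape, if (sgn < 0) "_down" else "_up"),
       aperture_est = as.numeric(aperture), depth = depth)
}

#' Full deformation report for a final frame
#'
#' @param system a `particle_system`
#' @param topology optional `filament_topology` for filament metrics
#' @param plateau_reached logical flag from the protocol driver
#' @param units a [unit_system()] used to report the depth in nm
#' @return an object of class `deformation_report`
#' @export
deformation_report <- function(system, topology = NULL,
                               plateau_reached = NA, units = unit_system()) {
  cls <- classify_deformation(system)
  sc <- detect_scission(system)
  rep <- list(depth = cls$depth, depth_nm = to_nm(cls$depth, units),
              shape_class = cls$shape_class,
              aperture_est = cls$aperture_est,
              plateau_reached = plateau_reached,
              scission = sc$scission,
              cargo_in_vesicle = sc$cargo_in_vesicle,
              n_components = sc$n_components)
  if (!is.null(topology)) rep$filament <- filament_metrics(system, topology)
  structure(rep, class = "deformation_report")
}

#' @export
print.deformation_report <- function(x, ...) {
  cat(sprintf("deformation: %.2f sigma (%.2f nm), class %s", x$depth,
              x$depth_nm, x$shape_class))
  if (is.finite(x$aperture_est))
    cat(sprintf(", aperture %.1f deg", x$aperture_est))
  cat(sprintf("\nscission: %s; cargo in vesicle: %s; membrane components: %d\n",
              x$scission, x$cargo_in_vesicle, x$n_components))
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Filament conformation metrics
#'
#' @param system a `particle_system`
#' @param topology a `filament_topology`
#' @param axis `"vertical"` measures the winding about the z axis (the
#'   membrane normal); `"principal"` about the best-fit plane normal of the
#'   backbone, appropriate for free filaments that may have tumbled
#' @return list with `mean_radius` (unit centres about the filament axis),
#'   `z_extent`, `turn_count` (total winding of the backbone), `planarity`
#'   (RMS z-deviation of the binder beads) and `mean_z`
#' @export
filament_metrics <- function(system, topology,
                             axis = c("vertical", "principal")) {
  axis <- match.arg(axis)
  stopifnot(inherits(topology, "filament_topology"))
  tri <- topology$triplets
  # unwrap filament coordinates around the first bead (bonded chain; PBC)
  pos <- system$pos
  L <- system$box
  centers <- matrix(NA_real_, nrow(tri), 3)
  for (k in seq_len(nrow(tri))) {
    centers[k, ] <- colMeans(pos[tri[k, ], , drop = FALSE])
  }
  for (d in 1:2) {
    dd <- diff(centers[, d])
    dd <- dd - L[d] * round(dd / L[d])
    centers[, d] <- centers[1, d] + c(0, cumsum(dd))
  }
  cc <- sweep(centers, 2, colMeans(centers))
  if (axis == "principal") {
    ax <- prcomp(cc)$rotation[, 3]
    if (ax[3] < 0) ax <- -ax
    e1 <- c(ax[2], -ax[1], 0)
    if (sum(e1^2) < 1e-12) e1 <- c(1, 0, 0)
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(ax[2] * e1[3] - ax[3] * e1[2], ax[3] * e1[1] - ax[1] * e1[3],
            ax[1] * e1[2] - ax[2] * e1[1])
    uv <- cbind(cc %*% e1, cc %*% e2)
  } else {
    uv <- cc[, 1:2, drop = FALSE]
  }
  rho <- sqrt(rowSums(uv^2))
  ang <- atan2(uv[, 2], uv[, 1])
  dang <- diff(ang)
  dang <- dang - 2 * pi * round(dang / (2 * pi))
  binder_idx <- as.vector(tri[, 1:2])
  bz <- pos[binder_idx, 3]
  list(mean_radius = mean(rho),
       z_extent = diff(range(centers[, 3])),
       turn_count = abs(sum(dang)) / (2 * pi),
       planarity = sd(bz),
       mean_z = mean(centers[, 3]))
}

#' Persistence length from tangent correlations
#'
#' Fits <t(s) . t(s + ds)> = exp(-ds / l_p) over backbone tangent vectors,
#' averaged over frames. When the correlation does not decay below
#' `floor_corr` over the available contour (rod limit) the estimate is a
#' flagged lower bound equal to the contour length.
#'
#' @param frames list of backbone coordinate matrices (ordered points,
#'   one matrix per decorrelated frame)
#' @param floor_corr smallest correlation value used in the fit
#' @param max_s largest contour separation used in the fit; restricting the
#'   window to short separations confines the fit to locally equilibrated
#'   bending modes (long-wavelength modes of stiff filaments relax slowly)
#' @return list with `l_p` (in the same length unit as the input), `se`
#'   (fit standard error), `flagged` (TRUE for the rod-limit lower bound)
#'   and `contour_length`
#' @export
persistence_length_estimate <- function(frames, floor_corr = 0.2,
                                        max_s = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(length(frames) >= 1)
  nseg <- nrow(frames[[1]]) - 1L
  corr_sum <- numeric(nseg)
  corr_n <- numeric(nseg)
  seglen <- 0
  for (fr in frames) {
    t_vec <- diff(fr)
    lens <- sqrt(rowSums(t_vec^2))
    seglen <- seglen + mean(lens)
    t_hat <- t_vec / lens
    cmat <- t_hat %*% t(t_hat)
    for (ds in 0:(nseg - 1L)) {
      v <- cmat[cbind(seq_len(nseg - ds), seq_len(nseg - ds) + ds)]
      corr_sum[ds + 1L] <- corr_sum[ds + 1L] + sum(v)
      corr_n[ds + 1L] <- corr_n[ds + 1L] + length(v)
    }
  }
  d <- seglen / length(frames)
  corr <- corr_sum / corr_n
  s <- (seq_along(corr) - 1L) * d
  contour <- nseg * d
  usable <- which(corr > floor_corr)
  usable <- usable[corr[usable] > 0 & s[usable] > 0]
  if (!is.null(max_s)) usable <- usable[s[usable] <= max_s]
  if (length(usable) < 3) usable <- utils::head(which(s > 0 & corr > 0), 3)
  # the fit keeps a free intercept: uncorrelated within-unit jitter rescales
  # the correlation by a constant factor without changing the decay length
  sf <- s[usable]
  fit <- lm(log(corr[usable]) ~ sf)
  slope <- coef(fit)[2]
  if (!is.finite(slope) || slope >= 0)
    return(list(l_p = contour, se = NA_real_, flagged = TRUE,
                contour_length = contour))
  lp <- -1 / slope
  se <- summary(fit)$coefficients[2, 2] * lp^2
  weak_decay <- length(usable) == length(corr) && corr[length(corr)] > exp(-1)
  if (weak_decay && lp > 10 * contour)
    return(list(l_p = contour, se = NA_real_, flagged = TRUE,
                contour_length = contour))
  list(l_p = as.numeric(lp), se = as.numeric(se),
       flagged = weak_decay && lp > contour, contour_length = contour)
}

#' Backbone coordinates of the filament (triplet centres)
#'
#' @param system a `particle_system`
#' @param topology a `filament_topology`
#' @return matrix of unwrapped triplet-centre coordinates
#' @export
filament_backbone <- function(system, topology) {
  tri <- topology$triplets
  centers <- t(vapply(seq_len(nrow(tri)), function(k)
    colMeans(system$pos[tri[k, ], , drop = FALSE]), numeric(3)))
  L <- system$box
  for (d in 1:2) {
    dd <- diff(centers[, d])
    dd <- dd - L[d] * round(dd / L[d])
    centers[, d] <- centers[1, d] + c(0, cumsum(dd))
  }
  centers
}

# ---------------------------------------------------------------------------

#' Detect membrane scission
#'
#' Builds the membrane contact graph (edge when the distance is below
#' `cutoff`, periodic in x and y) and reports scission when it splits into
#' at least two components of 50+ particles. A component is a vesicle when
#' it spans neither periodic direction; the cargo is "in" a vesicle when its
#' nearest membrane component is a vesicle and the cargo lies inside that
#' component's surface.
#'
#' @param system a `particle_system`
#' @param cutoff contact distance in sigma (between first and second
#'   neighbour shells of the cohesive membrane)
#' @param min_size smallest component counted
#' @return list with `scission`, `n_components`, `component_sizes`,
#'   `cargo_in_vesicle`
#' @export
detect_scission <- function(system, cutoff = 1.5, min_size = 50) {
  mem <- which(system$species <= 2L)
  if (!length(mem)) stop("detect_scission: no membrane", call. = FALSE)
  p <- system$pos[mem, , drop = FALSE]
  n <- nrow(p)
  L <- system$box
  # neighbour pairs via lateral cell binning
  cw <- cutoff
  nx <- max(1L, floor(L[1] / cw)); ny <- max(1L, floor(L[2] / cw))
  pairs <- .contact_pairs(p, L, cutoff)
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  sizes <- comp$csize
  big <- which(sizes >= min_size)
  scission <- length(big) >= 2
  # vesicle test: circular gap > 2 sigma in both x and y
  is_vesicle <- vapply(seq_along(sizes), function(ci) {
    if (sizes[ci] < min_size) return(FALSE)
    q <- p[comp$membership == ci, , drop = FALSE]
    gap_x <- .max_circular_gap(q[, 1], L[1])
    gap_y <- .max_circular_gap(q[, 2], L[2])
    gap_x > 2 && gap_y > 2
  }, logical(1))
  cargo_in_vesicle <- FALSE
  ci_cargo <- NA_integer_
  cargo <- which(system$species == 5L)
  if (length(cargo)) {
    cp <- system$pos[cargo[1], ]
    dx <- p[, 1] - cp[1]; dy <- p[, 2] - cp[2]; dz <- p[, 3] - cp[3]
    dx <- dx - L[1] * round(dx / L[1]); dy <- dy - L[2] * round(dy / L[2])
    d2 <- dx^2 + dy^2 + dz^2
    ci_cargo <- comp$membership[which.min(d2)]
    if (is_vesicle[ci_cargo]) {
      q <- p[comp$membership == ci_cargo, , drop = FALSE]
      # unwrap the component about the cargo
      qx <- cp[1] + (q[, 1] - cp[1]) - L[1] * round((q[, 1] - cp[1]) / L[1])
      qy <- cp[2] + (q[, 2] - cp[2]) - L[2] * round((q[, 2] - cp[2]) / L[2])
      ctr <- c(mean(qx), mean(qy), mean(q[, 3]))
      r_shell <- sqrt((qx - ctr[1])^2 + (qy - ctr[2])^2 + (q[, 3] - ctr[3])^2)
      r_cargo <- sqrt(sum((cp - ctr)^2))
      cargo_in_vesicle <- r_cargo < mean(r_shell)
    }
  }
  list(scission = scission, n_components = length(big),
       component_sizes = sort(sizes[big], decreasing = TRUE),
       cargo_in_vesicle = cargo_in_vesicle)
}

.contact_pairs <- function(p, L, cutoff) {
  n <- nrow(p)
  # coarse lateral binning to keep the pair search near-linear
  cw <- max(cutoff, 1)
  nx <- max(1L, floor(L[1] / cw)); ny <- max(1L, floor(L[2] / cw))
  ix <- pmin(nx - 1L, floor(p[, 1] / L[1] * nx))
  iy <- pmin(ny - 1L, floor(p[, 2] / L[2] * ny))
  cell <- iy * nx + ix
  ord <- order(cell)
  out_i <- integer(0); out_j <- integer(0)
  cells <- split(ord, cell[ord])
  key <- function(cx, cy) ((cy %% ny) * nx + (cx %% nx))
  for (nm in names(cells)) {
    c0 <- as.integer(nm)
    cx <- c0 %% nx; cy <- c0 %/% nx
    idx <- cells[[nm]]
    neigh <- unique(unlist(lapply(-1:1, function(ox)
      lapply(-1:1, function(oy) cells[[as.character(key(cx + ox, cy + oy))]])),
      use.names = FALSE))
    neigh <- neigh[!is.na(neigh)]
    for (i in idx) {
      cand <- neigh[neigh > i]
      if (!length(cand)) next
      dx <- p[cand, 1] - p[i, 1]; dy <- p[cand, 2] - p[i, 2]
      dz <- p[cand, 3] - p[i, 3]
      dx <- dx - L[1] * round(dx / L[1]); dy <- dy - L[2] * round(dy / L[2])
      hit <- cand[dx^2 + dy^2 + dz^2 < cutoff^2]
      out_i <- c(out_i, rep.int(i, length(hit)))
      out_j <- c(out_j, hit)
    }
  }
  cbind(out_i, out_j)
}

.max_circular_gap <- function(x, L) {
  xs <- sort(x %% L)
  if (length(xs) < 2) return(L)
  gaps <- c(diff(xs), xs[1] + L - xs[length(xs)])
  max(gaps)
}

# ---------------------------------------------------------------------------

#' Membrane mechanics from a patch trajectory
#'
#' Bending rigidity from the small-q Helfrich fluctuation spectrum
#' <|h_q|^2> = kT / (A kappa q^4), and the in-plane diffusion coefficient
#' from the mean-square displacement slope over the final half of the
#' trajectory.
#'
#' @param frames list of snapshot frames from [run_dynamics()] (positions,
#'   box, images)
#' @param species species vector of the system (membrane particles are used)
#' @param dt_frame time between frames in reduced time
#' @param kT temperature
#' @param n_modes number of smallest nonzero q-modes averaged for kappa
#' @return list with `kappa` (kT), `kappa_se`, `diffusion` (sigma^2/time),
#'   `spectrum` (data.frame q, S)
#' @export
membrane_mechanics <- function(frames, species, dt_frame = NULL, kT = 1,
                               n_modes = 6) {
  stopifnot(length(frames) >= 2)
  mem <- which(species <= 2L)
  spec <- .fluctuation_spectrum(frames, mem)
  ord <- order(spec$q)
  sel <- ord[seq_len(min(n_modes, length(ord)))]
  kap_q <- kT / (spec$A * spec$q[sel]^4 * spec$S[sel])
  kappa <- mean(kap_q)
  kappa_se <- sd(kap_q) / sqrt(length(kap_q))
  diffusion <- NA_real_
  if (!is.null(dt_frame)) {
    nf <- length(frames)
    half <- frames[seq(ceiling(nf / 2), nf)]
    f0 <- half[[1]]
    L <- f0$box
    ux0 <- f0$pos[mem, 1] + f0$images[mem, 1] * L[1]
    uy0 <- f0$pos[mem, 2] + f0$images[mem, 2] * L[2]
    msd <- vapply(half, function(fr) {
      ux <- fr$pos[mem, 1] + fr$images[mem, 1] * fr$box[1]
      uy <- fr$pos[mem, 2] + fr$images[mem, 2] * fr$box[2]
      mean((ux - ux0)^2 + (uy - uy0)^2)
    }, numeric(1))
    tt <- (seq_along(half) - 1) * dt_frame
    fit <- lm(msd ~ tt)
    diffusion <- as.numeric(coef(fit)[2] / 4)
  }
  list(kappa = kappa, kappa_se = kappa_se, diffusion = diffusion,
       spectrum = data.frame(q = spec$q, S = spec$S))
}

# average height-field power spectrum over frames
.fluctuation_spectrum <- function(frames, mem, grid_bin = 1.5) {
  f1 <- frames[[1]]
  L <- f1$box
  ng <- max(8L, 2L * floor(min(L) / grid_bin / 2))
  S_acc <- NULL
  A_acc <- 0
  for (fr in frames) {
    p <- fr$pos[mem, , drop = FALSE]
    Lx <- fr$box[1]; Ly <- fr$box[2]
    ix <- pmin(ng, 1L + floor(p[, 1] / Lx * ng))
    iy <- pmin(ng, 1L + floor(p[, 2] / Ly * ng))
    idx <- (iy - 1L) * ng + ix
    hm <- tapply(p[, 3], idx, mean)
    h <- matrix(mean(p[, 3]), ng, ng)
    h[as.integer(names(hm))] <- hm
    h <- h - mean(h)
    hq <- fft(h) / (ng * ng)
    P <- Mod(hq)^2
    if (is.null(S_acc)) S_acc <- P * 0
    S_acc <- S_acc + P
    A_acc <- A_acc + Lx * Ly
  }
  nf <- length(frames)
  S <- S_acc / nf
  A <- A_acc / nf
  Lx <- sqrt(A)                            # frames share a near-square box
  kx <- c(0:(ng / 2), -((ng / 2 - 1):1)) * 2 * pi / Lx
  qmat <- sqrt(outer(kx^2, kx^2, "+"))
  keep <- qmat > 0 & qmat <= (pi / grid_bin) / 2
  data_q <- qmat[keep]
  data_S <- S[keep]                        # <|h_q|^2> in DFT normalisation
  agg <- tapply(data_S, round(data_q, 10), mean)
  list(q = as.numeric(names(agg)), S = as.numeric(agg), A = A)
}
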