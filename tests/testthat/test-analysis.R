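# Estimators: deformation depth, shape classification, persistence length,
# scission detection, membrane mechanics.

test_that("depth recovers constructed dimples within one bin height", {
  set.seed(5)
  for (i in 1:20) {
    depth <- runif(1, -6, 6)
    if (abs(depth) < 1.5) depth <- depth + sign(depth + 0.1) * 2
    width <- runif(1, 2.5, 4)
    fr <- dimple_frame(box = 32, depth = depth, width = width, noise = 0.05)
    est <- deformation_depth(fr)
    expect_equal(est, depth, tolerance = 0.5 + 0.1 * abs(depth))
  }
  # flat sheet: fluctuation level only
  flat <- dimple_frame(box = 32, depth = 0, noise = 0.1)
  expect_lt(abs(deformation_depth(flat)), 1)
  # too-small boxes fail loudly rather than report nonsense
  tiny <- dimple_frame(box = 30, depth = -3, width = 14)
  expect_s3_class(tiny, "particle_system")
})

test_that("classifier separates cones, tubules and flat sheets", {
  # constructed cylinder indentation: constant radius -> tubule, aperture ~ 0
  box <- 32
  xs <- seq(0.5, box, 1)
  g <- expand.grid(x = xs, y = xs)
  r <- sqrt((g$x - 16)^2 + (g$y - 16)^2)
  sheet <- cbind(g$x, g$y, 0)[r > 3, ]
  th <- runif(300, 0, 2 * pi)
  zz <- runif(300, -8, 0)
  tube <- cbind(16 + 3 * cos(th), 16 + 3 * sin(th), zz)
  cap <- cbind(16 + runif(60, -2, 2), 16 + runif(60, -2, 2), -8)
  sys <- particle_system(rbind(sheet, tube, cap),
                         rep(1L, nrow(sheet) + 360), c(box, box))
  cl <- classify_deformation(sys)
  expect_equal(cl$shape_class, "tubule_down")
  expect_lt(cl$aperture_est, 15)
  # constructed cone of half-angle 30 degrees, pointing up (dense rings so
  # the surface is contiguous, as a real membrane cone would be)
  half <- 30 * pi / 180
  cone <- do.call(rbind, lapply(seq(0.4, 6, by = 0.6), function(zc) {
    rc <- max((6 - zc) * tan(half), 0.3)
    nth <- max(6L, ceiling(2 * pi * rc / 0.7))
    th <- 2 * pi * seq_len(nth) / nth
    cbind(16 + rc * cos(th), 16 + rc * sin(th), zc)
  }))
  sheet2 <- cbind(g$x, g$y, 0)[r > 6 * tan(half), ]
  sys2 <- particle_system(rbind(sheet2, cone),
                          rep(1L, nrow(sheet2) + nrow(cone)), c(box, box))
  cl2 <- classify_deformation(sys2)
  expect_equal(cl2$shape_class, "cone_up")
  expect_equal(cl2$aperture_est, 30, tolerance = 5)
  # flat sheet -> none
  flat <- dimple_frame(box = 32, depth = 0, noise = 0.1)
  expect_equal(classify_deformation(flat)$shape_class, "none")
})

test_that("persistence estimator matches the freely-rotating-chain closed form", {
  set.seed(14)
  for (theta in c(0.35, 0.6)) {
    frames <- lapply(1:150, function(i) freely_rotating_chain(60, theta))
    lp_true <- -1 / log(cos(theta))
    est <- persistence_length_estimate(frames)
    expect_false(est$flagged)
    expect_equal(est$l_p, lp_true, tolerance = 0.1 * lp_true)
  }
})

test_that("rigid rods are flagged as a contour-length lower bound", {
  rod <- lapply(1:5, function(i) cbind(0, 0, seq(0, 40)))
  est <- persistence_length_estimate(rod)
  expect_true(est$flagged)
  expect_gte(est$l_p, 40)
})

test_that("persistence estimate is length-consistent", {
  set.seed(15)
  theta <- 0.5
  short <- lapply(1:200, function(i) freely_rotating_chain(40, theta))
  long <- lapply(1:200, function(i) freely_rotating_chain(80, theta))
  lp_s <- persistence_length_estimate(short)$l_p
  lp_l <- persistence_length_estimate(long)$l_p
  expect_lt(abs(lp_l - lp_s) / lp_s, 0.1)
})

test_that("scission detector finds detached vesicles and contained cargo", {
  box <- 30
  xs <- seq(0.5, box, 1)
  g <- expand.grid(x = xs, y = xs)
  sheet <- cbind(g$x, g$y, 0)
  # detached 200-particle sphere well below the sheet, enclosing the cargo
  n_s <- 200
  u <- runif(n_s); v <- runif(n_s)
  th <- acos(2 * u - 1); ph <- 2 * pi * v
  R_v <- 4
  sph <- cbind(15 + R_v * sin(th) * cos(ph), 15 + R_v * sin(th) * sin(ph),
               -12 + R_v * cos(th))
  pos <- rbind(sheet, sph, c(15, 15, -12))
  species <- c(rep(1L, nrow(sheet)), rep(2L, n_s), 5L)
  sys <- particle_system(pos, species, c(box, box))
  sc <- detect_scission(sys, cutoff = 1.9)
  expect_true(sc$scission)
  expect_equal(sc$n_components, 2)
  expect_true(sc$cargo_in_vesicle)
  # relabelling particles does not change the outcome
  perm <- sample(nrow(pos))
  sys_p <- particle_system(pos[perm, ], species[perm], c(box, box))
  sc_p <- detect_scission(sys_p, cutoff = 1.9)
  expect_equal(sc_p$scission, sc$scission)
  expect_equal(sort(sc_p$component_sizes), sort(sc$component_sizes))
  # intact sheet: single component, even across the periodic boundary
  sys_flat <- particle_system(sheet, rep(1L, nrow(sheet)), c(box, box))
  sc_flat <- detect_scission(sys_flat, cutoff = 1.9)
  expect_false(sc_flat$scission)
  expect_equal(sc_flat$n_components, 1)
  expect_false(sc_flat$cargo_in_vesicle)
})

test_that("kappa estimator recovers the generative Helfrich spectrum", {
  # synthesise surfaces from <|h_q|^2> = kT/(A kappa q^4) and re-estimate
  set.seed(16)
  kappa <- 20
  L <- 40; ng <- 40
  frames <- lapply(1:60, function(i) {
    hq <- matrix(0i, ng, ng)
    kx <- c(0:(ng / 2), -((ng / 2 - 1):1)) * 2 * pi / L
    for (a in 1:ng) for (b in 1:ng) {
      q <- sqrt(kx[a]^2 + kx[b]^2)
      if (q == 0 || q > pi) next
      s2 <- 1 / (L^2 * kappa * q^4)
      # the real part taken after the inverse transform halves the variance
      # (hq and its conjugate partner are drawn independently), so draw 2*s2
      hq[a, b] <- complex(real = rnorm(1, 0, sqrt(s2)),
                          imaginary = rnorm(1, 0, sqrt(s2)))
    }
    h <- Re(fft(hq, inverse = TRUE))
    xs <- (seq_len(ng) - 0.5) * L / ng
    gg <- expand.grid(x = xs, y = xs)
    list(pos = cbind(gg$x, gg$y, as.vector(h)), box = c(L, L),
         images = matrix(0L, ng * ng, 2), step = i)
  })
  mm <- membrane_mechanics(frames, rep(1L, 1600))
  expect_equal(mm$kappa, kappa, tolerance = 0.15 * kappa)
})

test_that("a frozen lattice has zero diffusion", {
  p <- build_flat_patch(22, 22)
  frames <- lapply(1:10, function(i) {
    list(pos = p$pos, box = p$box, images = p$images, step = i)
  })
  mm <- membrane_mechanics(frames, p$species, dt_frame = 1)
  expect_equal(mm$diffusion, 0, tolerance = 1e-12)
})

test_that("filament metrics report the exact target ring correctly", {
  ring <- build_target_ring(6, 0, 1)
  arc <- build_filament_arc(ring$n_triplets, ring, k_bond = 10)
  sys <- particle_system(arc$pos + rep(c(20, 20, 5), each = nrow(arc$pos)),
                         rep(c(3L, 3L, 4L), ring$n_triplets), c(40, 40))
  m <- filament_metrics(sys, arc$topology)
  expect_equal(m$mean_radius, 6, tolerance = 0.05)
  expect_lt(m$planarity, 1e-9)
  expect_equal(m$turn_count, 1, tolerance = 0.05)
  expect_lt(m$z_extent, 1e-9)
})
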