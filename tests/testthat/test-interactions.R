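# Bonds, excluded volume, adhesion; species-selective contracts.

test_that("bond energy and force follow the harmonic closed form", {
  out <- bond_force(c(1.3, 0, 0), rest = 1.3, k = 50)
  expect_equal(out$energy, 0)
  expect_equal(out$force_j, c(0, 0, 0))
  d <- 0.2
  out2 <- bond_force(c(1.3 + d, 0, 0), rest = 1.3, k = 50)
  expect_equal(out2$energy, 0.5 * 50 * d^2)
  expect_equal(out2$force_j[1], -50 * d)
  # finite-difference oracle on random displacements
  set.seed(3)
  h <- 1e-7
  for (i in 1:50) {
    r <- runit() * runif(1, 0.5, 2)
    out <- bond_force(r, 1.1, 30)
    for (k in 1:3) {
      rp <- r; rp[k] <- rp[k] + h
      rm <- r; rm[k] <- rm[k] - h
      fd <- -(bond_force(rp, 1.1, 30)$energy -
              bond_force(rm, 1.1, 30)$energy) / (2 * h)
      expect_equal(out$force_j[k], fd, tolerance = 1e-6)
    }
  }
})

test_that("excluded volume vanishes at contact and is strictly repulsive", {
  for (sig in c(1, 2.5)) {
    expect_identical(excluded_volume_force(c(sig, 0, 0), sig)$energy, 0)
    expect_identical(excluded_volume_force(c(sig * 1.5, 0, 0), sig)$energy, 0)
    rr <- seq(0.4 * sig, sig * 0.999, length.out = 200)
    ee <- vapply(rr, function(r)
      excluded_volume_force(c(r, 0, 0), sig)$energy, numeric(1))
    expect_true(all(diff(ee) < 0))
    expect_true(all(ee > 0))
  }
})

test_that("adhesion reaches -eps at contact and vanishes past its range", {
  eps <- 4; w <- 0.5
  out <- adhesion_force(c(1, 0, 0), eps, sigma_c = 1, adh_range = w)
  expect_equal(out$energy, -eps, tolerance = 1e-12)
  expect_identical(adhesion_force(c(1 + w, 0, 0), eps, 1, w)$energy, 0)
  expect_identical(adhesion_force(c(3, 0, 0), eps, 1, w)$energy, 0)
  # smooth attractive well in between
  mid <- adhesion_force(c(1 + w / 2, 0, 0), eps, 1, w)
  expect_lt(mid$energy, 0)
  expect_lt(mid$force_j[1], 0)  # pulls j toward i
})

test_that("cargo adheres to receptors only; binders adhere to any membrane", {
  # cargo resting at contact (2.5 sigma) on one membrane particle
  pos <- rbind(c(10, 10, 2.5), c(10, 10, 0), c(16, 16, 0))
  sys <- particle_system(pos, c(5L, 2L, 1L), c(20, 20))
  eb <- energy_breakdown(sys, NULL)
  ap <- adhesion_params()
  expect_equal(eb$e_adh, -ap$eps_cargo, tolerance = 1e-9)
  # the same geometry with a plain membrane particle: no adhesion at all
  sys2 <- particle_system(pos, c(5L, 1L, 1L), c(20, 20))
  expect_equal(energy_breakdown(sys2, NULL)$e_adh, 0)
})

test_that("pair forces obey Newton's third law and energies decompose", {
  # random mixed-species system evaluated through the engine
  set.seed(9)
  n <- 40
  pos <- cbind(runif(n, 0, 15), runif(n, 0, 15), runif(n, -1, 1))
  species <- sample(c(1L, 1L, 1L, 3L, 4L), n, replace = TRUE)
  sys <- particle_system(pos, species, c(15, 15))
  eb <- energy_breakdown(sys, NULL, all_pairs = TRUE)
  expect_equal(colSums(eb$forces), c(0, 0, 0), tolerance = 1e-10)
  expect_equal(eb$e_pot, eb$e_mem + eb$e_wca + eb$e_adh + eb$e_bond +
                 eb$e_tether, tolerance = 1e-10)
})

test_that("disabling self-exclusion removes filament-filament repulsion", {
  ring <- build_target_ring(4.5, 0, 1)
  n <- ring$n_triplets
  fil_on <- build_flat_spiral(n, ring, k_bond = 10, self_exclusion = TRUE)
  fil_off <- build_flat_spiral(n, ring, k_bond = 10, self_exclusion = FALSE)
  # squash the ring onto itself so non-bonded beads overlap
  pos <- fil_on$pos
  pos[, 1] <- pos[, 1] * 0.3
  sys <- particle_system(pos + 10, rep(c(3L, 3L, 4L), n), c(40, 40))
  e_on <- energy_breakdown(sys, fil_on$topology)$e_wca
  e_off <- energy_breakdown(sys, fil_off$topology)$e_wca
  expect_gt(e_on, 0)
  expect_equal(e_off, 0)
})
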