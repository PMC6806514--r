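# Shared fixtures: tiny systems built in code, plus a cache so expensive
# simulations are run once per test session.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# a small equilibrated membrane patch (shared across tests)
small_patch <- function(seed = 11) {
  cached(paste0("patch", seed), {
    p <- build_flat_patch(22, 22)
    equilibrate_patch(p, steps = 8000, seed = seed)
  })
}

# random unit vector
runit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# a freely rotating chain with fixed bond angle theta and random dihedrals:
# closed-form persistence length -d / log(cos(theta))
freely_rotating_chain <- function(n, theta, d = 1) {
  pos <- matrix(0, n, 3)
  t_prev <- c(0, 0, 1)
  pos[2, ] <- d * t_prev
  for (i in 3:n) {
    # orthonormal frame around t_prev
    a <- if (abs(t_prev[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- a - sum(a * t_prev) * t_prev
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(t_prev[2] * e1[3] - t_prev[3] * e1[2],
            t_prev[3] * e1[1] - t_prev[1] * e1[3],
            t_prev[1] * e1[2] - t_prev[2] * e1[1])
    phi <- runif(1, 0, 2 * pi)
    t_new <- cos(theta) * t_prev +
      sin(theta) * (cos(phi) * e1 + sin(phi) * e2)
    pos[i, ] <- pos[i - 1, ] + d * t_new
    t_prev <- t_new
  }
  pos
}

# synthetic membrane frame with a Gaussian dimple of given depth
dimple_frame <- function(box = 30, depth = -2, width = 3, spacing = 1,
                         noise = 0, center = c(box / 2, box / 2)) {
  xs <- seq(spacing / 2, box, by = spacing)
  g <- expand.grid(x = xs, y = xs)
  r2 <- (g$x - center[1])^2 + (g$y - center[2])^2
  z <- depth * exp(-r2 / (2 * width^2))
  if (noise > 0) z <- z + rnorm(length(z), 0, noise)
  particle_system(cbind(g$x, g$y, z), rep(1L, nrow(g)), c(box, box))
}
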