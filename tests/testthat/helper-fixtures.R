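# Shared fixture builders; everything is generated in code at test time.

# Two-level noiseless VOI: background block with an axis-aligned FG box.
two_level_voi <- function(shape = c(8, 8, 8), fg = 10, bg = 5,
                          fg_idx = list(4:5, 4:5, 4:5)) {
  x <- array(bg, shape)
  x[fg_idx[[1]], fg_idx[[2]], fg_idx[[3]]] <- fg
  x
}

# Small single-sphere phantom (fast to rasterize/simulate).
mini_sphere_spec <- function(diameter_mm = 22, fg = 90.90, bg = 9.68,
                             noise = noise_gaussian(0.1), seed = 1L) {
  phantom_spec(grid_shape = c(24, 24, 24),
               objects = list(phantom_object("sphere", diameter_mm,
                                             c(49.7, 49.1, 36.8))),
               fg_activity = fg, bg_activity = bg, noise = noise,
               seed = seed)
}

# Exact Gibbs distribution of the binary label field on a tiny grid, by
# enumeration of all 2^n labelings: energy = gamma * (# discordant face
# pairs, each pair counted once) + sum_n (x_n - mu_{z_n})^2 / (2 sigma^2).
exact_gibbs <- function(x, dims, params, gamma) {
  n <- prod(dims)
  stopifnot(n <= 16, length(x) == n)
  idx <- function(i, j, k) 1 + i + dims[1] * (j + dims[2] * k)
  pairs <- list()
  for (k in 0:(dims[3] - 1)) for (j in 0:(dims[2] - 1))
    for (i in 0:(dims[1] - 1)) {
      if (i < dims[1] - 1)
        pairs[[length(pairs) + 1]] <- c(idx(i, j, k), idx(i + 1, j, k))
      if (j < dims[2] - 1)
        pairs[[length(pairs) + 1]] <- c(idx(i, j, k), idx(i, j + 1, k))
      if (k < dims[3] - 1)
        pairs[[length(pairs) + 1]] <- c(idx(i, j, k), idx(i, j, k + 1))
    }
  E <- numeric(2^n)
  for (s in 0:(2^n - 1)) {
    z <- as.integer(intToBits(s))[seq_len(n)]
    mu_z <- ifelse(z == 1, params$mu[1], params$mu[2])
    sig_z <- ifelse(z == 1, params$sigma[1], params$sigma[2])
    lik <- sum((x - mu_z)^2 / (2 * sig_z^2))
    dis <- sum(vapply(pairs, function(p) z[p[1]] != z[p[2]], TRUE))
    E[s + 1] <- gamma * dis + lik
  }
  p <- exp(-(E - min(E)))
  p / sum(p)
}

# Voxel-wise maximum-likelihood classification (gamma = 0 reference).
ml_classify <- function(x, params) {
  d1 <- dnorm(x, params$mu[1], params$sigma[1], log = TRUE)
  d2 <- dnorm(x, params$mu[2], params$sigma[2], log = TRUE)
  array(as.integer(d1 >= d2), dim(x))
}

# Full NEMA sweep (5 SBR sessions x 20 seeds, EMGMM + GMRF), computed once
# per test run and cached; the geometry is rasterized a single time.
.sweep_cache <- new.env(parent = emptyenv())
phantom_sweep_records <- function() {
  if (!is.null(.sweep_cache$records)) return(.sweep_cache$records)
  tab <- nema_activity_table()
  geom <- rasterize_phantom(nema_phantom_spec())
  out <- list()
  for (r in seq_len(nrow(tab))) for (s in 1:20) {
    spec <- nema_phantom_spec(fg_activity = tab$fg[r], bg_activity = tab$bg[r],
                              seed = 1000L * r + s)
    set.seed(1000L * r + s)
    rec <- benchmark_phantom(spec, methods = c("emgmm", "gmrf"), truth = geom)
    rec$seed <- s
    out[[length(out) + 1]] <- rec
  }
  .sweep_cache$records <- do.call(rbind, out)
  .sweep_cache$records
}
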