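test_that("interaction energy counts discordant face neighbors", {
  g <- coupling_matrix(2)
  lab <- array(1L, c(3, 3, 3))
  expect_equal(interaction_energy(lab, c(2, 2, 2), g), 0)
  lab[2, 2, 2] <- 0L
  expect_equal(interaction_energy(lab, c(2, 2, 2), g), 6 * 2)
  # free boundary: corner voxel has only 3 neighbors
  lab2 <- array(0L, c(3, 3, 3)); lab2[1, 1, 1] <- 1L
  expect_equal(interaction_energy(lab2, c(1, 1, 1), g), 3 * 2)
  # brute-force pairwise oracle with the explicit coupling matrix
  set.seed(21)
  lab3 <- array(rbinom(64, 1, 0.5), c(4, 4, 4))
  G <- matrix(c(0, 2, 2, 0), 2)
  onehot <- function(z) if (z == 1) c(1, 0) else c(0, 1)
  for (n in c(1, 17, 33, 64)) {
    ijk <- arrayInd(n, c(4, 4, 4))
    e <- 0
    for (a in 1:3) for (s in c(-1, 1)) {
      m <- ijk; m[a] <- m[a] + s
      if (all(m >= 1 & m <= 4))
        e <- e + onehot(lab3[ijk[1], ijk[2], ijk[3]]) %*% G %*%
          onehot(lab3[m[1], m[2], m[3]])
    }
    expect_equal(interaction_energy(lab3, n, g), as.numeric(e))
  }
})

test_that("local probability reduces to the likelihood ratio at gamma 0", {
  p <- mixture_params(c(0.5, 0.5), mu = c(10, 5), sigma = c(1.3, 1.3))
  lab <- array(0L, c(3, 3, 3))
  x <- 8.2
  labf <- lab; labf[2, 2, 2] <- 1L
  lr <- local_log_probability(x, labf, c(2, 2, 2), p, 0) -
        local_log_probability(x, lab, c(2, 2, 2), p, 0)
  expect_equal(lr, -(x - 10)^2 / (2 * 1.3^2) + (x - 5)^2 / (2 * 1.3^2))
  # at the class mean with concordant neighbors the log-probability is 0
  expect_equal(local_log_probability(5, lab, c(2, 2, 2), p, 1000), 0)
  # brute-force evaluation with an interaction term
  g <- 3.1
  set.seed(2)
  labr <- array(rbinom(27, 1, 0.4), c(3, 3, 3))
  for (z in 0:1) {
    labr[2, 2, 2] <- z
    k <- if (z == 1) 1 else 2
    manual <- -g * sum(vapply(list(c(1,2,2), c(3,2,2), c(2,1,2), c(2,3,2),
                                   c(2,2,1), c(2,2,3)),
                              function(m) labr[m[1], m[2], m[3]] != z, TRUE)) -
      (7.7 - p$mu[k])^2 / (2 * p$sigma[k]^2)
    expect_equal(local_log_probability(7.7, labr, c(2, 2, 2), p, g), manual)
  }
  expect_error(local_log_probability(1, lab, c(2, 2, 2),
    structure(list(mu = c(1, 0), sigma = c(0, 1), tau = c(.5, .5)),
              class = "mixture_params"), 0), "sigma")
})

test_that("a sweep never flips a frozen well-separated labeling", {
  x <- two_level_voi(fg = 10, bg = 5)
  p <- mixture_params(c(0.5, 0.5), mu = c(10, 5), sigma = c(0.1, 0.1))
  lab <- array(as.integer(x == 10), dim(x))
  set.seed(99)
  res <- metropolis_sweep(x, lab, p, 0)
  expect_equal(res$accepted, 0)
  expect_identical(res$labels, lab)
})

test_that("improving proposals are always accepted", {
  # single voxel mislabeled BG amid concordant FG: flip strictly improves
  x <- array(10, c(3, 3, 3))
  p <- mixture_params(c(0.5, 0.5), mu = c(10, 5), sigma = c(0.5, 0.5))
  lab <- array(1L, c(3, 3, 3)); lab[2, 2, 2] <- 0L
  for (seed in 1:5) {
    set.seed(seed)
    res <- metropolis_sweep(x, lab, p, 2)
    expect_equal(res$labels[2, 2, 2], 1L)
  }
})

test_that("single-proposal acceptance frequencies match the analytic rule", {
  # two-voxel chain: the first proposal's acceptance probability is
  # min(1, exp(dlog)) with dlog from the local conditional probability
  dims <- c(2L, 1L, 1L)
  x <- c(0.35, 0.30)
  p <- mixture_params(c(0.5, 0.5), mu = c(1, 0), sigma = c(0.8, 0.8))
  g <- 0.3
  lik <- function(v, z) -(v - if (z == 1) 1 else 0)^2 / (2 * 0.8^2)
  d1 <- (-g + lik(x[1], 1)) - lik(x[1], 0)   # neighbor is BG
  a1 <- min(1, exp(d1))
  d2f <- lik(x[2], 1) - (-g + lik(x[2], 0))  # v1 flipped to FG
  d2n <- (-g + lik(x[2], 1)) - lik(x[2], 0)  # v1 stayed BG
  pv2 <- a1 * min(1, exp(d2f)) + (1 - a1) * min(1, exp(d2n))
  nrep <- 20000
  set.seed(31)
  f1 <- f2 <- 0
  for (r in seq_len(nrep)) {
    res <- metropolis_sweep(array(x, dims), array(0L, dims), p, g)
    f1 <- f1 + res$labels[1, 1, 1]
    f2 <- f2 + res$labels[2, 1, 1]
  }
  expect_lt(abs(f1 / nrep - a1), 3 * sqrt(a1 * (1 - a1) / nrep))
  expect_lt(abs(f2 / nrep - pv2), 3 * sqrt(pv2 * (1 - pv2) / nrep))
})

test_that("the chain's stationary distribution matches exact enumeration", {
  # 2x2x2 instance, all 256 labelings enumerated; neighbor pairs counted
  # once in the energy, matching the local acceptance ratio
  dims <- c(2L, 2L, 2L)
  set.seed(7)
  x <- rnorm(8, mean = c(2, 0, 0, 2, 0, 2, 2, 0), sd = 0.5)
  p <- mixture_params(c(0.5, 0.5), mu = c(2, 0), sigma = c(1, 1))
  g <- 0.4
  p_exact <- exact_gibbs(x, dims, p, g)
  set.seed(123)
  st <- petseg:::cpp_chain_states(x, integer(8), dims, p$mu, p$sigma, g,
                                  300000L)
  keep <- st[seq(101, length(st), by = 10)]   # discard burn-in, thin
  N <- length(keep)
  obs <- tabulate(keep + 1L, 256)
  expd <- N * p_exact
  sig <- pmax(sqrt(N * p_exact * (1 - p_exact)), 1e-9)
  # per-state 3-sigma multinomial check, allowing for the ~0.7 states
  # expected to exceed 3 sigma among 256 comparisons
  expect_lte(sum(abs(obs - expd) > 3 * sig), 3)
  # global goodness of fit
  chi2 <- sum((obs - expd)^2 / pmax(expd, 1e-12))
  expect_lt(chi2, 255 + 5 * sqrt(2 * 255))
})

test_that("zero-coupling sweep lands on the maximum-likelihood labeling", {
  set.seed(17)
  truth <- array(rbinom(5 * 5 * 5, 1, 0.3), c(5, 5, 5))
  x <- array(ifelse(truth == 1, 1, 0) + rnorm(125, 0, 0.02), c(5, 5, 5))
  p <- mixture_params(c(0.5, 0.5), mu = c(1, 0), sigma = c(0.1, 0.1))
  init <- array(rbinom(125, 1, 0.5), c(5, 5, 5))
  set.seed(18)
  res <- metropolis_sweep(x, init, p, 0)
  expect_identical(res$labels, ml_classify(x, p))
})

test_that("strong coupling removes isolated foreground islands", {
  spec <- mini_sphere_spec(22, seed = 12)
  vol <- simulate_phantom(spec)
  em <- run_em(vol$data)
  lab <- array(as.integer(em$fg_prob >= 0.5), dim(vol$data))
  lab[3, 3, 3] <- 1L    # plant an isolated island far from the sphere
  set.seed(1)
  cor <- run_correction(vol$data, array(lab, dim(vol$data)),
                        params = em$params, gamma = 1000)
  expect_equal(cor$labels[3, 3, 3], 0L)
  expect_equal(cor$average[3, 3, 3], 0)
})

test_that("correction is rng-deterministic and bounded in [0,1]", {
  spec <- mini_sphere_spec(17, seed = 5)
  vol <- simulate_phantom(spec)
  em <- run_em(vol$data)
  set.seed(77); c1 <- run_correction(vol$data, em)
  set.seed(77); c2 <- run_correction(vol$data, em)
  expect_identical(c1$average, c2$average)
  expect_true(all(c1$average >= 0 & c1$average <= 1))
  # averages are exact multiples of 1/L; a voxel FG in every sample is 1
  expect_true(all(abs(c1$average * c1$L - round(c1$average * c1$L)) < 1e-9))
  # L = 1 average equals the single retained hard field
  set.seed(3)
  c3 <- run_correction(vol$data, em, burn_in = 0, L = 1)
  expect_identical(c3$average, array(as.numeric(c3$labels), dim(c3$labels)))
})

test_that("empty initial foreground yields a flagged all-background result", {
  x <- array(5, c(4, 4, 4))
  p <- mixture_params(c(0.5, 0.5), mu = c(10, 5), sigma = c(1, 1))
  cor <- run_correction(x, array(0, c(4, 4, 4)), params = p)
  expect_false(cor$detected)
  expect_true(all(cor$average == 0))
})

test_that("soft volume is the membership-weighted voxel sum", {
  expect_equal(soft_volume(array(1, c(10, 10, 1)), 0.048), 4.8)
  expect_equal(soft_volume(array(0.5, c(10, 10, 1)), 0.048), 2.4)
  set.seed(6)
  f <- array(runif(60), c(5, 4, 3))
  expect_equal(soft_volume(f, 0.01), sum(f) * 0.01)
  expect_error(soft_volume(array(1.5, c(2, 2, 2)), 0.048), "0, 1")
})

test_that("foreground volume is non-increasing in the coupling strength", {
  spec <- nema_phantom_spec(seed = 2)
  geom <- rasterize_phantom(spec)
  vol <- simulate_phantom(spec, truth = geom)
  box <- voi_box_around(spec$objects[[5]]$center_mm, c(14, 14, 20),
                        spec$grid_shape, spec$voxel_spacing_mm)
  xv <- extract_voi(vol$data, box)
  em <- run_em(xv)
  vols <- vapply(c(0, 1, 10, 100, 1000), function(g) {
    set.seed(5)
    soft_volume(run_correction(xv, em, gamma = g), 0.048)
  }, 0)
  expect_true(all(diff(vols) <= 1e-9))
})
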