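test_that("E-step responsibilities match the direct Bayes formula", {
  # identical components: every voxel gets the priors back
  p <- mixture_params(c(0.3, 0.7), mu = c(5, 5), sigma = c(1, 1))
  z <- e_step(c(1, 5, 9), p)
  expect_equal(unname(z), matrix(c(0.3, 0.3, 0.3, 0.7, 0.7, 0.7), 3))
  # midway voxel with equal sigma and tau: exactly 1/2
  p2 <- mixture_params(c(0.5, 0.5), mu = c(10, 5), sigma = c(2, 2))
  expect_equal(unname(e_step(7.5, p2)), matrix(c(0.5, 0.5), 1))
  # hand-picked voxels vs direct (non-log) evaluation of the ratio
  p3 <- mixture_params(c(0.2, 0.8), mu = c(12.5, 4.1), sigma = c(1.7, 1.7))
  x <- c(3.2, 5.9, 8.3, 11.0, 14.7)
  num <- p3$tau[1] * dnorm(x, p3$mu[1], p3$sigma[1])
  den <- num + p3$tau[2] * dnorm(x, p3$mu[2], p3$sigma[2])
  expect_equal(e_step(x, p3)[, 1], num / den, tolerance = 1e-12)
  # rows always normalized
  expect_equal(rowSums(e_step(x, p3)), rep(1, 5))
})

test_that("E-step guards against joint density underflow", {
  p <- mixture_params(c(0.5, 0.5), mu = c(1, 0), sigma = c(1e-3, 1e-3))
  expect_warning(z <- e_step(c(1e160, 0.4), p), "underflow")
  expect_equal(z[1, ], c(FG = 1, BG = 0))   # nearer (in fact only) option
})

test_that("M-step matches the weighted-average oracle and ties sigma", {
  # hard-label limit: group means and proportions
  x <- c(rep(10, 4), rep(5, 12))
  zb <- cbind(rep(c(1, 0), c(4, 12)), rep(c(0, 1), c(4, 12)))
  p <- m_step(x, zb)
  expect_equal(p$mu, c(10, 5))
  expect_equal(p$tau, c(0.25, 0.75))
  # tying rule holds exactly for any valid input
  set.seed(1)
  x <- rnorm(50, 6, 2)^2 / 5
  z1 <- runif(50)
  zb <- cbind(z1, 1 - z1)
  p <- m_step(x, zb)
  expect_identical(p$sigma[1], p$sigma[2])
  # direct-formula oracle
  mu2 <- sum(x * zb[, 2]) / sum(zb[, 2])
  s2 <- sqrt(sum((x - mu2)^2 * zb[, 2]) / sum(zb[, 2]))
  expect_equal(p$mu[2], mu2, tolerance = 1e-10)
  expect_equal(p$sigma[2], s2, tolerance = 1e-10)
  expect_equal(p$tau, unname(colSums(zb)) / 50, tolerance = 1e-10)
  # untied diagnostic update uses the FG ensemble for sigma1
  pu <- m_step(x, zb, tie_sigma = FALSE)
  mu1 <- sum(x * zb[, 1]) / sum(zb[, 1])
  expect_equal(pu$sigma[1],
               sqrt(sum((x - mu1)^2 * zb[, 1]) / sum(zb[, 1])),
               tolerance = 1e-10)
  # degenerate class
  expect_error(m_step(x, cbind(rep(0, 50), rep(1, 50))), "degenerate")
})

test_that("initialization brackets the true levels and rejects flat input", {
  x <- two_level_voi()
  p <- em_initialize(x)
  expect_equal(p$mu, c(10, 5), tolerance = 0.01)
  expect_error(em_initialize(array(3, c(5, 5, 5))), "contrast")
  expect_error(em_initialize(1:10), "20 voxels")
  for (s in c("quantile", "kmeans")) {
    set.seed(2)
    ps <- em_initialize(x, s)
    expect_gt(ps$mu[1], ps$mu[2])
  }
})

test_that("EM terminates immediately at a fixed point", {
  # construct a fixed point: run EM to convergence, restart from it
  set.seed(4)
  x <- c(rnorm(300, 10, 0.5), rnorm(700, 5, 0.5))
  fit <- run_em(x, tol = 1e-8, max_iter = 500)
  refit <- run_em(x, init = fit$params, tol = 0.01)
  expect_lte(refit$iterations, 2)
  expect_equal(refit$params$mu, fit$params$mu, tolerance = 0.01)
})

test_that("EM recovers parameters of a well-separated tied mixture", {
  set.seed(7)
  x <- c(rnorm(500, 10, 0.5), rnorm(500, 5, 0.5))
  fit <- run_em(x)
  expect_true(fit$converged)
  se <- 0.5 / sqrt(500)
  expect_lt(abs(fit$params$mu[1] - 10), 3 * se)
  expect_lt(abs(fit$params$mu[2] - 5), 3 * se)
  expect_equal(fit$params$tau[1], 0.5, tolerance = 0.05)
  expect_true(fit$detected)
  # tied sigma after every M-step along the trace
  expect_equal(fit$trace$sigma_fg, fit$trace$sigma_bg)
})

test_that("EM estimates are permutation- and scale-equivariant", {
  set.seed(11)
  x <- c(rnorm(200, 9, 0.6), rnorm(600, 4, 0.6))
  fit <- run_em(x)
  perm <- sample(length(x))
  fitp <- run_em(x[perm])
  expect_equal(fitp$params$mu, fit$params$mu, tolerance = 1e-8)
  expect_equal(fitp$zbar[, 1], fit$zbar[perm, 1], tolerance = 1e-10)
  c0 <- 3.7
  fits <- run_em(c0 * x, init = mixture_params(c(0.05, 0.95),
                                               c0 * em_initialize(x)$mu,
                                               c0 * em_initialize(x)$sigma),
                 tol = 0.01 * c0)
  expect_equal(fits$params$mu, c0 * fit$params$mu, tolerance = 0.05)
  expect_equal(fits$zbar[, 1], fit$zbar[, 1], tolerance = 1e-6)
})

test_that("untied EM has a non-decreasing observed-data log-likelihood", {
  set.seed(5)
  x <- c(rnorm(150, 8, 1.5), rnorm(850, 5, 0.5))
  fit <- run_em(x, tie_sigma = FALSE, tol = 1e-6, max_iter = 100)
  expect_true(all(diff(fit$trace$loglik) > -1e-8))
})

test_that("all init strategies reach the same fixed point on a sphere VOI", {
  spec <- mini_sphere_spec(22, seed = 8)
  vol <- simulate_phantom(spec)
  mus <- sapply(c("default", "quantile", "kmeans"), function(s) {
    set.seed(1)
    run_em(vol$data, init = s)$params$mu
  })
  expect_lt(max(mus[1, ]) - min(mus[1, ]), 0.1)
  expect_lt(max(mus[2, ]) - min(mus[2, ]), 0.1)
})

test_that("pure background yields no connected lesion", {
  # on featureless noise the mixture may still split off an upper tail;
  # what rejects it is the downstream connectivity rule: the hardened FG
  # is scattered, not a single interior object
  set.seed(3)
  x <- array(rnorm(10 * 10 * 10, 5, 0.5), c(10, 10, 10))
  fit <- run_em(x)
  hard <- array(fit$fg_prob >= 0.5, dim(x))
  expect_false(detect_object(hard)$detected)
})
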