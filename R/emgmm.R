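#' Two-class Gaussian mixture parameters
#'
#' Class 1 is the foreground (lesion, brighter), class 2 the background.
#' The modified M-step ties the standard deviations, `sigma[1] == sigma[2]`.
#'
#' @param tau Prior probabilities, length 2, summing to 1.
#' @param mu Class means (kBq/ml), length 2.
#' @param sigma Class standard deviations (kBq/ml), length 2, positive.
#' @return A `mixture_params` object.
#' @export
mixture_params <- function(tau, mu, sigma) {
  stopifnot(length(tau) == 2, length(mu) == 2, length(sigma) == 2)
  if (abs(sum(tau) - 1) > 1e-8 || any(tau <= 0) || any(tau >= 1))
    stop("tau must be two probabilities in (0,1) summing to 1")
  if (any(sigma <= 0)) stop("sigma must be positive")
  structure(list(tau = as.numeric(tau), mu = as.numeric(mu),
                 sigma = as.numeric(sigma)),
            class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf("mixture_params  FG: tau=%.3f mu=%.4g sigma=%.4g | BG: tau=%.3f mu=%.4g sigma=%.4g\n",
              x$tau[1], x$mu[1], x$sigma[1], x$tau[2], x$mu[2], x$sigma[2]))
  invisible(x)
}

# log pointwise mixture component densities, N x 2
.log_component_density <- function(x, params) {
  cbind(log(params$tau[1]) + dnorm(x, params$mu[1], params$sigma[1], log = TRUE),
        log(params$tau[2]) + dnorm(x, params$mu[2], params$sigma[2], log = TRUE))
}

#' E-step: per-voxel class responsibilities
#'
#' Computes the posterior probability that each voxel belongs to the
#' foreground or background class,
#' \deqn{\bar z_{nk} = \tau_k N(x_n;\mu_k,\sigma_k) /
#'       \sum_j \tau_j N(x_n;\mu_j,\sigma_j),}
#' evaluated in log space with max-subtraction. If both component densities
#' underflow at a voxel, the voxel is assigned to the class with the nearer
#' mean (probability 1) and a warning is issued.
#'
#' @param x Numeric vector (or array) of VOI activity values.
#' @param params A [mixture_params()].
#' @return An N x 2 matrix of responsibilities; rows sum to 1.
#' @export
e_step <- function(x, params) {
  x <- as.numeric(x)
  stopifnot(all(is.finite(x)), inherits(params, "mixture_params"))
  lg <- .log_component_density(x, params)
  bad <- !is.finite(lg[, 1]) & !is.finite(lg[, 2])
  m <- pmax(lg[, 1], lg[, 2])
  w <- exp(lg - m)
  zbar <- w / rowSums(w)
  if (any(bad)) {
    warning("component densities underflowed at ", sum(bad),
            " voxel(s); assigning nearer-mean class")
    nearer_fg <- abs(x[bad] - params$mu[1]) <= abs(x[bad] - params$mu[2])
    zbar[bad, ] <- cbind(as.numeric(nearer_fg), as.numeric(!nearer_fg))
  }
  colnames(zbar) <- c("FG", "BG")
  zbar
}

#' M-step with tied standard deviations
#'
#' Mixing weights are responsibility means, class means are
#' responsibility-weighted averages. The standard deviation is estimated
#' from the background class only (the background is the large, reliable
#' ensemble) and copied to the foreground: `sigma[1] <- sigma[2]`. A floor
#' of `1e-6 * mean(x)` guards against collapse on noiseless input.
#'
#' @param x Activity values.
#' @param zbar Responsibility matrix from [e_step()].
#' @param tie_sigma If `FALSE`, each class gets its own standard deviation
#'   (the textbook GMM update; diagnostic use only).
#' @return A [mixture_params()].
#' @export
m_step <- function(x, zbar, tie_sigma = TRUE) {
  x <- as.numeric(x)
  stopifnot(is.matrix(zbar), nrow(zbar) == length(x), ncol(zbar) == 2)
  wsum <- colSums(zbar)
  if (any(wsum <= 0))
    stop("degenerate class: zero total responsibility",
         call. = FALSE)
  tau <- wsum / length(x)
  mu <- colSums(x * zbar) / wsum
  sig_floor <- 1e-6 * mean(x)
  s2 <- sqrt(sum((x - mu[2])^2 * zbar[, 2]) / wsum[2])
  if (tie_sigma) {
    sigma <- rep(max(s2, sig_floor), 2)
  } else {
    s1 <- sqrt(sum((x - mu[1])^2 * zbar[, 1]) / wsum[1])
    sigma <- pmax(c(s1, s2), sig_floor)
  }
  mixture_params(tau, mu, sigma)
}

#' Initialize the mixture for a lesion VOI
#'
#' The default strategy assumes the VOI is mostly background with a small
#' bright lesion: the background mean is the VOI median, the foreground
#' mean the maximum after clipping at the 99.5th percentile, the common
#' standard deviation 10% of the background mean (the background
#' coefficient of variation typical of clinical OSEM reconstructions), and
#' the priors (0.05, 0.95).
#'
#' @param x VOI activity values (>= 20 voxels with positive spread).
#' @param strategy `"default"`, `"quantile"` (means at the 99th and 40th
#'   percentiles) or `"kmeans"` (2-means centers).
#' @return A [mixture_params()].
#' @export
em_initialize <- function(x, strategy = c("default", "quantile", "kmeans")) {
  strategy <- match.arg(strategy)
  x <- as.numeric(x)
  if (length(x) < 20) stop("VOI too small: need >= 20 voxels")
  if (max(x) - min(x) <= 0 || sd(x) == 0)
    stop("no contrast: constant VOI", call. = FALSE)
  mu <- switch(strategy,
    default = c(max(pmin(x, quantile(x, 0.995))), median(x)),
    quantile = as.numeric(quantile(x, c(0.99, 0.40))),
    kmeans = {
      km <- kmeans(x, centers = 2, nstart = 5)
      sort(as.numeric(km$centers), decreasing = TRUE)
    })
  if (mu[1] <= mu[2]) mu[1] <- mu[2] + sd(x)    # degenerate split guard
  sigma <- rep(max(0.1 * mu[2], 1e-6 * mean(x)), 2)
  mixture_params(tau = c(0.05, 0.95), mu = mu, sigma = sigma)
}

#' Run the modified EM algorithm
#'
#' Alternates [e_step()] and [m_step()] until both class means move by
#' less than `tol` between iterations, or `max_iter` is reached. The FG
#' class is kept the brighter one by relabeling if the means cross.
#'
#' After convergence the fit is flagged as a *non-detection* when the
#' hardened (responsibility >= 0.5) foreground is empty or the class means
#' are separated by less than one background standard deviation — the
#' mixture then has not found a distinct lesion.
#'
#' @param x VOI activity values (vector or 3-D array; shape is preserved
#'   in the returned soft labels).
#' @param init A [mixture_params()] or a strategy name for
#'   [em_initialize()].
#' @param tol Convergence tolerance on the mean updates (kBq/ml).
#' @param max_iter Iteration cap.
#' @param tie_sigma Passed to [m_step()].
#' @return A `petseg_em` list: `zbar` (soft labels, FG column reshaped to
#'   the input shape in `fg_prob`), `params`, `trace` (per-iteration data
#'   frame with parameters and observed-data log-likelihood), `iterations`,
#'   `converged`, `detected`.
#' @export
run_em <- function(x, init = "default", tol = 0.01, max_iter = 200,
                   tie_sigma = TRUE) {
  shp <- dim(x)
  xv <- as.numeric(x)
  params <- if (inherits(init, "mixture_params")) init
            else em_initialize(xv, init)
  trace <- vector("list", max_iter)
  converged <- FALSE
  zbar <- NULL
  for (i in seq_len(max_iter)) {
    zbar <- e_step(xv, params)
    new <- tryCatch(m_step(xv, zbar, tie_sigma = tie_sigma),
                    error = function(e) e)
    if (inherits(new, "error")) {
      # degenerate class: report as non-detection with the last valid state
      res <- .em_result(xv, shp, zbar, params, trace[seq_len(i - 1)],
                        i - 1L, FALSE)
      res$detected <- FALSE
      res$degenerate <- TRUE
      return(res)
    }
    if (new$mu[1] < new$mu[2]) {   # keep FG the brighter class
      new <- mixture_params(rev(new$tau), rev(new$mu), rev(new$sigma))
      zbar <- zbar[, 2:1, drop = FALSE]
      colnames(zbar) <- c("FG", "BG")
    }
    lg <- .log_component_density(xv, new)
    mx <- pmax(lg[, 1], lg[, 2])
    ll <- sum(log(exp(lg[, 1] - mx) + exp(lg[, 2] - mx)) + mx)
    trace[[i]] <- data.frame(iter = i, tau_fg = new$tau[1],
                             mu_fg = new$mu[1], mu_bg = new$mu[2],
                             sigma_fg = new$sigma[1], sigma_bg = new$sigma[2],
                             loglik = ll)
    delta <- abs(new$mu - params$mu)
    params <- new
    if (all(delta < tol)) { converged <- TRUE; break }
  }
  zbar <- e_step(xv, params)   # final soft labels at the converged params
  .em_result(xv, shp, zbar, params, trace[seq_len(i)], i, converged)
}

.em_result <- function(xv, shp, zbar, params, trace, iterations, converged) {
  fg_hard <- !is.null(zbar) && any(zbar[, 1] >= 0.5)
  detected <- isTRUE(converged) && fg_hard &&
    (params$mu[1] - params$mu[2]) >= params$sigma[2]
  fg_prob <- zbar[, 1]
  if (!is.null(shp)) dim(fg_prob) <- shp
  structure(list(zbar = zbar, fg_prob = fg_prob, params = params,
                 trace = do.call(rbind, trace), iterations = iterations,
                 converged = converged, detected = detected,
                 degenerate = FALSE),
            class = "petseg_em")
}

#' @export
print.petseg_em <- function(x, ...) {
  cat(sprintf("petseg_em: %d iteration(s), %s, %s\n", x$iterations,
              if (x$converged) "converged" else "not converged",
              if (x$detected) "lesion detected" else "no detection"))
  print(x$params)
  invisible(x)
}

#' Write an EM trace to CSV
#' @param fit A `petseg_em` object.
#' @param path Output CSV path.
#' @export
write_em_trace <- function(fit, path) {
  stopifnot(inherits(fit, "petseg_em"))
  write.csv(fit$trace, path, row.names = FALSE)
  invisible(path)
}
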