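#' Coupling matrix of the boundary-only Gibbs prior
#'
#' The two-class coupling matrix is `[[0, gamma], [gamma, 0]]`: only pairs
#' of face-adjacent voxels carrying *different* labels contribute energy,
#' so the prior penalizes foreground/background boundary surface.
#'
#' @param gamma Nonnegative coupling strength.
#' @return A `coupling_matrix` object (2 x 2 matrix with `gamma` attribute).
#' @export
coupling_matrix <- function(gamma) {
  stopifnot(is.numeric(gamma), length(gamma) == 1, gamma >= 0)
  structure(matrix(c(0, gamma, gamma, 0), 2, 2),
            gamma = gamma, class = c("coupling_matrix", "matrix"))
}

.gamma_of <- function(coupling) {
  if (inherits(coupling, "coupling_matrix")) attr(coupling, "gamma")
  else as.numeric(coupling)
}

#' Gibbs interaction energy of one voxel
#'
#' Sum over the 6-voxel face neighborhood of `z_n' Gamma z_m`: with the
#' boundary-only coupling this is `gamma` times the number of neighbors
#' whose label differs from voxel `n`'s. Neighbors outside the grid are
#' skipped (free boundary).
#'
#' @param labels 3-D integer/logical array, 1 = FG, 0 = BG.
#' @param n Voxel index, either a scalar linear index (1-based,
#'   column-major) or an integer triple.
#' @param coupling A [coupling_matrix()] or a bare `gamma`.
#' @return Energy scalar.
#' @export
interaction_energy <- function(labels, n, coupling) {
  gamma <- .gamma_of(coupling)
  d <- dim(labels)
  stopifnot(length(d) == 3)
  ijk <- if (length(n) == 3) as.integer(n) else as.integer(arrayInd(n, d))
  stopifnot(all(ijk >= 1), all(ijk <= d))
  z <- labels[ijk[1], ijk[2], ijk[3]]
  e <- 0
  for (a in 1:3) for (s in c(-1L, 1L)) {
    m <- ijk; m[a] <- m[a] + s
    if (m[a] >= 1 && m[a] <= d[a] && labels[m[1], m[2], m[3]] != z)
      e <- e + gamma
  }
  e
}

#' Local conditional log-probability of a voxel label
#'
#' Up to a voxel-wise constant, the log of the quantity the Metropolis
#' acceptance rule compares:
#' `-interaction_energy - (x_n - mu_k)^2 / (2 sigma_k^2)` with
#' `(mu_k, sigma_k)` picked by the voxel's label.
#'
#' @param x_n Activity at the voxel.
#' @param labels Label array with the proposed label already in place at
#'   `n` (only its neighbors are read besides `n` itself).
#' @param n Voxel index (linear or triple).
#' @param params Converged [mixture_params()] (held fixed).
#' @param coupling A [coupling_matrix()] or bare `gamma`.
#' @return Log of the unnormalized local probability.
#' @export
local_log_probability <- function(x_n, labels, n, params, coupling) {
  stopifnot(inherits(params, "mixture_params"))
  if (any(params$sigma <= 0)) stop("invalid params: sigma must be positive")
  d <- dim(labels)
  ijk <- if (length(n) == 3) as.integer(n) else as.integer(arrayInd(n, d))
  z <- labels[ijk[1], ijk[2], ijk[3]]
  k <- if (z == 1) 1L else 2L
  -interaction_energy(labels, ijk, coupling) -
    (x_n - params$mu[k])^2 / (2 * params$sigma[k]^2)
}

#' One Metropolis sweep over the VOI
#'
#' Visits every voxel once in deterministic raster order (first axis
#' fastest) and proposes flipping its label. A proposal whose local
#' conditional probability does not decrease is always accepted; otherwise
#' it is accepted with probability `P_new / P_old`. Updates are sequential
#' and in place: later proposals see earlier accepted flips. Uses R's RNG
#' (`set.seed()` for reproducibility).
#'
#' @param x 3-D activity array (the VOI).
#' @param labels 3-D 0/1 label array of the same shape.
#' @param params Converged [mixture_params()].
#' @param coupling A [coupling_matrix()] or bare `gamma`.
#' @return List with `labels` (updated array) and `accepted` (flip count).
#' @export
metropolis_sweep <- function(x, labels, params, coupling) {
  stopifnot(all(dim(x) == dim(labels)))
  res <- cpp_metropolis_sweep(as.numeric(x),
                              as.integer(labels), as.integer(dim(x)),
                              params$mu, params$sigma, .gamma_of(coupling))
  lab <- array(res$labels, dim(x))
  list(labels = lab, accepted = res$accepted)
}

#' Markov-random-field correction of a coarse segmentation
#'
#' Hardens the EM soft labels (FG iff responsibility >= 0.5), then runs
#' `burn_in` discarded Metropolis sweeps followed by `L` retained sweeps
#' with the mixture parameters held fixed. The result is the arithmetic
#' mean of the `L` retained label fields — a soft segmentation whose
#' per-voxel values are posterior foreground frequencies — plus the final
#' hard field.
#'
#' @param x 3-D VOI activity array.
#' @param init_soft EM result ([run_em()]), a soft FG-probability array, or
#'   a hard 0/1 array.
#' @param params Converged [mixture_params()]; defaults to `init_soft$params`
#'   when `init_soft` is a [run_em()] fit.
#' @param gamma Gibbs coupling (default 1000, the stable plateau).
#' @param burn_in Discarded sweeps (default 10; equilibrium is reached
#'   within the first few sweeps when initialized from the EM labeling).
#' @param L Retained sweeps entering the average (default 70; more does
#'   not change the result).
#' @return A `petseg_gmrf` list: `average` (soft field in \[0,1\]),
#'   `labels` (final hard field), `accepted` (flips per sweep),
#'   `detected` (FALSE iff the initial FG was empty), `gamma`, `L`,
#'   `burn_in`.
#' @export
run_correction <- function(x, init_soft, params = NULL, gamma = 1000,
                           burn_in = 10, L = 70) {
  if (inherits(init_soft, "petseg_em")) {
    if (is.null(params)) params <- init_soft$params
    init_soft <- init_soft$fg_prob
  }
  stopifnot(inherits(params, "mixture_params"), gamma >= 0,
            burn_in >= 0, L >= 1)
  if (is.null(dim(init_soft)) || !all(dim(init_soft) == dim(x)))
    stop("init_soft must match the VOI shape")
  hard <- array(as.integer(init_soft >= 0.5), dim(x))
  if (!any(hard == 1)) {
    return(structure(list(average = array(0, dim(x)), labels = hard,
                          accepted = integer(0), detected = FALSE,
                          gamma = gamma, burn_in = burn_in, L = L),
                     class = "petseg_gmrf"))
  }
  res <- cpp_run_chain(as.numeric(x), as.integer(hard), as.integer(dim(x)),
                       params$mu, params$sigma, gamma, as.integer(burn_in),
                       as.integer(L))
  structure(list(average = array(res$average, dim(x)),
                 labels = array(res$labels, dim(x)),
                 accepted = as.integer(res$accepted), detected = TRUE,
                 gamma = gamma, burn_in = burn_in, L = L),
            class = "petseg_gmrf")
}

#' @export
print.petseg_gmrf <- function(x, ...) {
  cat(sprintf("petseg_gmrf: gamma=%g, %d+%d sweeps; soft FG volume %s voxels\n",
              x$gamma, x$burn_in, x$L, format(sum(x$average))))
  invisible(x)
}

#' Foreground volume of a soft (or hard) label field
#'
#' Partial classifications contribute fractionally:
#' `sum(FG membership) * voxel volume`.
#'
#' @param field A `petseg_gmrf` result, a numeric array of FG memberships
#'   in \[0,1\], or an [e_step()]/[run_em()] soft labeling.
#' @param voxel_volume_ml Volume of one voxel in ml.
#' @return Volume in ml.
#' @export
soft_volume <- function(field, voxel_volume_ml) {
  if (inherits(field, "petseg_gmrf")) field <- field$average
  if (inherits(field, "petseg_em")) field <- field$fg_prob
  if (is.matrix(field) && ncol(field) == 2) field <- field[, 1]
  if (any(field < -1e-12) || any(field > 1 + 1e-12))
    stop("memberships must lie in [0, 1]")
  sum(field) * voxel_volume_ml
}
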