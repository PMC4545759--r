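#' Fixed-percentage local thresholding
#'
#' Labels as foreground every voxel at or above `pct`% of the VOI maximum.
#' "Local" means the maximum is taken over the VOI, not the whole image;
#' clinically quoted values are 36% to 42%.
#'
#' @param x 3-D VOI activity array (or vector).
#' @param pct Threshold percentage in (0, 100].
#' @return Integer 0/1 array of the same shape.
#' @export
fixed_threshold <- function(x, pct) {
  stopifnot(pct > 0, pct <= 100)
  if (max(x) - min(x) <= 0)
    stop("no contrast: constant VOI", call. = FALSE)
  lab <- as.integer(x >= pct / 100 * max(x))
  dim(lab) <- dim(x)
  lab
}

#' Tabulated threshold regression curve %Thr = f(V, SBR)
#'
#' Builds a bilinear interpolator over a rectangular (volume, SBR) grid
#' from a long-format table; queries outside the grid are clamped to its
#' hull. At fixed SBR the curve should be non-increasing in volume
#' (smaller objects need higher thresholds because of partial-volume
#' dilution); violations trigger a warning, not an error.
#'
#' @param table Data frame with columns `volume_ml`, `sbr`, `pct`, covering
#'   a full grid (every volume at every SBR).
#' @return A `regression_curve` function `f(volume_ml, sbr) -> pct`.
#' @export
regression_curve <- function(table) {
  stopifnot(all(c("volume_ml", "sbr", "pct") %in% names(table)))
  if (any(table$pct <= 0 | table$pct >= 100))
    stop("curve percentages must lie in (0, 100)")
  vols <- sort(unique(table$volume_ml))
  sbrs <- sort(unique(table$sbr))
  Z <- matrix(NA_real_, length(sbrs), length(vols))
  for (r in seq_len(nrow(table))) {
    Z[match(table$sbr[r], sbrs), match(table$volume_ml[r], vols)] <-
      table$pct[r]
  }
  if (anyNA(Z)) stop("table must cover the full volume x SBR grid")
  if (any(apply(Z, 1, diff) > 1e-9))
    warning("curve is not non-increasing in volume at fixed SBR")
  f <- function(volume_ml, sbr) {
    v <- min(max(volume_ml, vols[1]), vols[length(vols)])
    s <- min(max(sbr, sbrs[1]), sbrs[length(sbrs)])
    if (length(vols) == 1 && length(sbrs) == 1) return(Z[1, 1])
    if (length(vols) == 1) return(approx(sbrs, Z[, 1], s)$y)
    if (length(sbrs) == 1) return(approx(vols, Z[1, ], v)$y)
    pracma::interp2(vols, sbrs, Z, v, s, method = "linear")
  }
  structure(f, class = c("regression_curve", "function"),
            table = table[order(table$sbr, table$volume_ml), ])
}

#' Constant regression curve (reduces ITM to fixed thresholding)
#' @param pct The constant percentage.
#' @export
constant_curve <- function(pct) {
  structure(function(volume_ml, sbr) pct,
            class = c("regression_curve", "function"))
}

#' Read/write a regression curve as CSV
#' @param path CSV with columns `volume_ml`, `sbr`, `pct`.
#' @export
read_regression_curve <- function(path) regression_curve(read.csv(path))

# 1-voxel dilation with the 6-neighborhood, by shift-or
.dilate6 <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (a in 1:3) for (s in c(-1L, 1L)) {
    shifted <- array(FALSE, d)
    src <- dst <- lapply(d, seq_len)
    if (s == 1L) { dst[[a]] <- 2:d[a]; src[[a]] <- 1:(d[a] - 1) }
    else         { dst[[a]] <- 1:(d[a] - 1); src[[a]] <- 2:d[a] }
    shifted[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
    out <- out | shifted
  }
  out
}

#' Iterative thresholding method (ITM)
#'
#' Applies an initial percentage threshold, measures the resulting volume
#' `V` (foreground voxel count times voxel volume) and SBR (mean
#' foreground activity over a background estimate), looks up the next
#' percentage from the regression curve, and repeats until two successive
#' percentages differ by at most `tol_pct` (default 0.1). The background
#' is estimated as the mean over VOI voxels outside a 1-voxel dilation of
#' the current foreground. ITM labels whole voxels only.
#'
#' @param x 3-D VOI activity array.
#' @param curve A [regression_curve()].
#' @param voxel_volume_ml Volume of one voxel in ml.
#' @param init_pct Starting percentage (default 42).
#' @param tol_pct Stopping tolerance on the percentage.
#' @param max_iter Iteration cap; exceeding it sets `converged = FALSE`.
#' @return List: `labels` (0/1 array), `pct` (final percentage),
#'   `iterations`, `converged`, `detected` (FALSE iff the foreground
#'   emptied out).
#' @export
itm <- function(x, curve, voxel_volume_ml, init_pct = 42, tol_pct = 0.1,
                max_iter = 100) {
  stopifnot(is.function(curve), voxel_volume_ml > 0)
  pct <- init_pct
  labels <- NULL
  for (i in seq_len(max_iter)) {
    labels <- fixed_threshold(x, pct)
    fg <- labels == 1
    if (!any(fg))
      return(list(labels = labels, pct = pct, iterations = i,
                  converged = FALSE, detected = FALSE))
    v <- sum(fg) * voxel_volume_ml
    bg_vox <- x[!.dilate6(array(fg, dim(x)))]
    bg <- if (length(bg_vox)) mean(bg_vox) else NA_real_
    sbr <- if (is.finite(bg) && bg > 0) mean(x[fg]) / bg else Inf
    new_pct <- as.numeric(curve(v, sbr))
    done <- abs(new_pct - pct) <= tol_pct
    pct <- new_pct
    if (done)
      return(list(labels = fixed_threshold(x, pct), pct = pct,
                  iterations = i, converged = TRUE, detected = TRUE))
  }
  list(labels = labels, pct = pct, iterations = max_iter,
       converged = FALSE, detected = any(labels == 1))
}

#' Calibrate a synthetic threshold regression curve in silico
#'
#' Re-enacts, on the digital phantom, the calibration a physicist performs
#' with phantom scans: for each SBR session and each sphere, sweep the
#' threshold percentage and record the one whose segmented volume is
#' closest to the true insert volume.
#'
#' @param sbr_table Data frame with columns `fg`, `bg` (kBq/ml), one row
#'   per calibration session; default [nema_activity_table()].
#' @param pct_grid Candidate percentages.
#' @param voi_shape VOI voxel counts used around each sphere.
#' @param seed Simulation seed.
#' @param ... Passed to [nema_phantom_spec()].
#' @return A [regression_curve()].
#' @export
calibrate_threshold_curve <- function(sbr_table = nema_activity_table(),
                                      pct_grid = seq(20, 90, by = 1),
                                      voi_shape = c(14, 14, 20),
                                      seed = 1L, ...) {
  rows <- list()
  truth <- NULL
  for (r in seq_len(nrow(sbr_table))) {
    spec <- nema_phantom_spec(fg_activity = sbr_table$fg[r],
                              bg_activity = sbr_table$bg[r],
                              seed = seed, ...)
    if (is.null(truth)) truth <- rasterize_phantom(spec)
    vol <- simulate_phantom(spec, truth = truth)
    vv <- voxel_volume_ml(spec$voxel_spacing_mm)
    for (i in seq_along(spec$objects)) {
      box <- voi_box_around(spec$objects[[i]]$center_mm, voi_shape,
                            spec$grid_shape, spec$voxel_spacing_mm)
      xv <- extract_voi(vol, box)
      tv <- truth$true_volume_ml[i]
      err <- vapply(pct_grid, function(p)
        abs(sum(fixed_threshold(xv, p)) * vv - tv), 0)
      rows[[length(rows) + 1]] <-
        data.frame(volume_ml = tv, sbr = spec$sbr,
                   pct = pct_grid[which.min(err)])
    }
  }
  tab <- do.call(rbind, rows)
  # enforce a proper curve: pool duplicate cells, then make each SBR row
  # non-increasing in volume (isotonic sweep) before interpolating
  tab <- aggregate(pct ~ volume_ml + sbr, tab, mean)
  tab <- tab[order(tab$sbr, tab$volume_ml), ]
  for (s in unique(tab$sbr)) {
    i <- which(tab$sbr == s)
    tab$pct[i] <- rev(cummax(rev(tab$pct[i])))
  }
  regression_curve(tab)
}
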