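#' Connected components of a binary mask (6-connectivity)
#'
#' Face connectivity matches the Markov-random-field neighborhood.
#'
#' @param mask Logical (or 0/1) 3-D array.
#' @return Integer array of component ids (0 outside the mask), with the
#'   component count as attribute `"n"`.
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3)
  mask <- as.logical(mask)
  nx <- d[1]; ny <- d[2]; nz <- d[3]; nxy <- nx * ny
  comp <- integer(length(mask))
  queue <- integer(length(mask))
  ncomp <- 0L
  for (start in which(mask)) {
    if (comp[start] != 0L) next
    ncomp <- ncomp + 1L
    comp[start] <- ncomp
    queue[1] <- start; head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      v0 <- v - 1L
      i <- v0 %% nx; j <- (v0 %/% nx) %% ny; k <- v0 %/% nxy
      nb <- c(if (i > 0L) v - 1L, if (i < nx - 1L) v + 1L,
              if (j > 0L) v - nx, if (j < ny - 1L) v + nx,
              if (k > 0L) v - nxy, if (k < nz - 1L) v + nxy)
      for (w in nb) if (mask[w] && comp[w] == 0L) {
        comp[w] <- ncomp
        tail <- tail + 1L; queue[tail] <- w
      }
    }
  }
  dim(comp) <- d
  attr(comp, "n") <- ncomp
  comp
}

.touches_boundary <- function(mask) {
  d <- dim(mask)
  any(mask[c(1, d[1]), , ]) || any(mask[, c(1, d[2]), ]) ||
    any(mask[, , c(1, d[3])])
}

#' Detection by morphological connectivity
#'
#' A lesion counts as detected when the segmentation consists of exactly
#' two morphologically connected objects: one foreground component that
#' is fully surrounded by background (it does not touch any VOI face) and
#' one background component.
#'
#' @param labels 0/1 (or logical, or soft — hardened at 0.5) 3-D array.
#' @return List: `detected`, `fg_components`, `bg_components`.
#' @export
detect_object <- function(labels) {
  fg <- if (is.numeric(labels) && !all(labels %in% c(0, 1)))
    labels >= 0.5 else labels == 1
  dim(fg) <- dim(labels)
  nfg <- attr(label_components(fg), "n")
  nbg <- attr(label_components(!fg), "n")
  list(detected = nfg == 1L && nbg == 1L && !.touches_boundary(fg),
       fg_components = nfg, bg_components = nbg)
}

#' Dice similarity coefficient
#'
#' `2 |A n B| / (|A| + |B|)` on hard masks; soft fields are hardened at
#' 0.5 first. Two empty masks give 1, exactly one empty mask gives 0.
#'
#' @param a,b Masks (logical/0-1/soft arrays) of identical shape.
#' @return DSC in \[0, 1\].
#' @export
dsc <- function(a, b) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    stop("mask shapes differ")
  A <- if (is.logical(a)) a else a >= 0.5
  B <- if (is.logical(b)) b else b >= 0.5
  sa <- sum(A); sb <- sum(B)
  if (sa + sb == 0) return(1)
  2 * sum(A & B) / (sa + sb)
}

#' Relative volume error in percent
#'
#' @param est_ml Estimated volume (ml).
#' @param true_ml True volume (ml), positive.
#' @return `100 * (est - true) / true`.
#' @export
volume_error <- function(est_ml, true_ml) {
  if (any(true_ml <= 0)) stop("true volume must be positive")
  100 * (est_ml - true_ml) / true_ml
}

#' Run segmentation methods over every phantom object
#'
#' Simulates (or reuses) a phantom acquisition, draws a VOI around each
#' insert, runs each requested method, and reports one evaluation record
#' per (object, method): estimated volume (soft for the mixture/MRF
#' methods, whole voxels for thresholds), relative volume error, Dice
#' coefficient against the rasterized ground truth, and the
#' connectivity-based detection flag. A method failure is recorded as
#' not-detected, never raised.
#'
#' @param spec A [phantom_spec()].
#' @param methods Subset of `"fixed36"`, `"fixed42"`, `"itm"`, `"emgmm"`,
#'   `"gmrf"`.
#' @param voi_shape VOI voxel counts (default 14 x 14 x 20).
#' @param curve [regression_curve()] for ITM (required if `"itm"` used).
#' @param gamma,burn_in,L Passed to [run_correction()].
#' @param em_init Initialization strategy for [run_em()].
#' @param vol Optional precomputed [simulate_phantom()] output for `spec`.
#' @param truth Optional precomputed [rasterize_phantom()] output.
#' @return Data frame of evaluation records.
#' @export
benchmark_phantom <- function(spec, methods = c("fixed42", "emgmm", "gmrf"),
                              voi_shape = c(14, 14, 20), curve = NULL,
                              gamma = 1000, burn_in = 10, L = 70,
                              em_init = "default", vol = NULL, truth = NULL) {
  methods <- match.arg(methods, c("fixed36", "fixed42", "itm", "emgmm",
                                  "gmrf"), several.ok = TRUE)
  if ("itm" %in% methods && is.null(curve))
    stop("ITM requires a regression curve")
  if (is.null(vol)) vol <- simulate_phantom(spec, truth = truth)
  if (is.null(truth)) truth <- attr(vol, "truth")
  vv <- voxel_volume_ml(spec$voxel_spacing_mm)
  rows <- list()
  for (i in seq_along(spec$objects)) {
    ob <- spec$objects[[i]]
    box <- voi_box_around(ob$center_mm, voi_shape, spec$grid_shape,
                          spec$voxel_spacing_mm)
    xv <- extract_voi(vol$data, box)
    gt <- extract_voi(truth$masks[[i]], box)
    tv <- truth$true_volume_ml[i]
    em_fit <- NULL
    if (any(c("emgmm", "gmrf") %in% methods))
      em_fit <- tryCatch(run_em(xv, init = em_init),
                         error = function(e) NULL)
    for (m in methods) {
      rec <- tryCatch(
        .run_one_method(m, xv, em_fit, curve, vv, gamma, burn_in, L),
        error = function(e) list(labels = array(0L, dim(xv)),
                                 est_ml = 0, ok = FALSE))
      det <- rec$ok && detect_object(rec$labels)$detected
      rows[[length(rows) + 1]] <- data.frame(
        object = i, shape = ob$shape, diameter_mm = ob$diameter_mm,
        sbr = spec$sbr, method = m, true_volume_ml = tv,
        est_volume_ml = rec$est_ml, detected = det,
        rel_error_pct = if (det) volume_error(rec$est_ml, tv) else NA_real_,
        dsc = dsc(rec$labels, gt),
        em_iterations = if (m %in% c("emgmm", "gmrf") && !is.null(em_fit))
          em_fit$iterations else NA_integer_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.run_one_method <- function(m, xv, em_fit, curve, vv, gamma, burn_in, L) {
  switch(m,
    fixed36 = { lab <- fixed_threshold(xv, 36)
                list(labels = lab, est_ml = sum(lab) * vv, ok = TRUE) },
    fixed42 = { lab <- fixed_threshold(xv, 42)
                list(labels = lab, est_ml = sum(lab) * vv, ok = TRUE) },
    itm = { r <- itm(xv, curve, vv)
            list(labels = r$labels, est_ml = sum(r$labels) * vv,
                 ok = r$detected) },
    emgmm = {
      if (is.null(em_fit)) stop("EM failed")
      lab <- array(as.integer(em_fit$fg_prob >= 0.5), dim(xv))
      list(labels = lab, est_ml = soft_volume(em_fit$fg_prob, vv),
           ok = em_fit$detected)
    },
    gmrf = {
      if (is.null(em_fit) || !em_fit$detected) stop("EM failed")
      cor <- run_correction(xv, em_fit, gamma = gamma,
                            burn_in = burn_in, L = L)
      list(labels = cor$labels, est_ml = soft_volume(cor, vv),
           ok = cor$detected)
    })
}

#' Detection summary table by SBR
#'
#' Collapses [benchmark_phantom()] records into a detection-count table
#' (one row per SBR, one column per method), the format of the phantom
#' detection overviews.
#'
#' @param records One or more row-bound [benchmark_phantom()] outputs.
#' @return Data frame: `sbr`, then one detected-count column per method.
#' @export
detection_summary <- function(records) {
  agg <- aggregate(detected ~ sbr + method, records, sum)
  methods <- unique(records$method)
  sbrs <- sort(unique(agg$sbr))
  out <- data.frame(sbr = sbrs)
  for (m in methods)
    out[[m]] <- agg$detected[match(paste(sbrs, m),
                                   paste(agg$sbr, agg$method))]
  out
}
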