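#' Analytic volume of a phantom insert
#'
#' Spheres have volume \eqn{(\pi/6) d^3}, cylinders \eqn{(\pi/4) d^2 h}.
#' Dimensions are in mm; the returned volume is in ml (1 ml = 1000 mm^3).
#'
#' @param shape `"sphere"` or `"cylinder"`.
#' @param diameter_mm Object diameter in mm.
#' @param height_mm Cylinder height in mm (required iff `shape = "cylinder"`).
#' @return Volume in ml.
#' @examples
#' true_object_volume("sphere", 28)   # 11.49 ml NEMA sphere
#' true_object_volume("cylinder", 10, height_mm = 51.93)
#' @export
true_object_volume <- function(shape = c("sphere", "cylinder"),
                               diameter_mm, height_mm = NULL) {
  shape <- match.arg(shape)
  if (!is.numeric(diameter_mm) || diameter_mm < 0)
    stop("invalid geometry: diameter must be nonnegative")
  if (shape == "sphere") {
    if (!is.null(height_mm))
      warning("height_mm ignored for spheres")
    return(pi / 6 * diameter_mm^3 / 1000)
  }
  if (is.null(height_mm) || !is.numeric(height_mm) || height_mm < 0)
    stop("invalid geometry: cylinder requires a nonnegative height_mm")
  pi / 4 * diameter_mm^2 * height_mm / 1000
}

#' Voxel volume in ml
#'
#' @param spacing_mm Numeric triple of voxel edge lengths in mm.
#' @return Volume of one voxel in ml.
#' @examples
#' voxel_volume_ml(c(4, 4, 3))  # 0.048 ml
#' @export
voxel_volume_ml <- function(spacing_mm) {
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("invalid geometry: spacing must be three positive numbers")
  prod(spacing_mm) / 1000
}

#' Describe one phantom insert
#'
#' Centers are given in mm in a corner-origin physical frame; the center of
#' voxel `(i, j, k)` (0-based) sits at `(i + 0.5) * spacing`.
#'
#' @param shape `"sphere"` or `"cylinder"` (cylinder axis along z).
#' @param diameter_mm Diameter in mm.
#' @param center_mm Numeric triple, object center in mm.
#' @param height_mm Cylinder height in mm.
#' @return A `phantom_object` list.
#' @export
phantom_object <- function(shape = c("sphere", "cylinder"), diameter_mm,
                           center_mm, height_mm = NULL) {
  shape <- match.arg(shape)
  if (diameter_mm <= 0) stop("invalid geometry: diameter must be positive")
  if (shape == "cylinder" && (is.null(height_mm) || height_mm <= 0))
    stop("invalid geometry: cylinder requires positive height_mm")
  if (length(center_mm) != 3) stop("center_mm must have length 3")
  structure(list(shape = shape, diameter_mm = diameter_mm,
                 center_mm = as.numeric(center_mm),
                 height_mm = if (shape == "cylinder") height_mm else NULL),
            class = "phantom_object")
}

#' Noise model constructors
#'
#' `noise_none()` leaves the blurred field untouched; `noise_gaussian(cv)`
#' adds zero-mean Gaussian noise with standard deviation `cv` times the
#' local (noiseless, blurred) mean, emulating the roughly 10% background
#' coefficient of variation seen in clinical OSEM reconstructions;
#' `noise_poisson(scale)` draws `rpois(scale * x) / scale`.
#'
#' @param cv Coefficient of variation relative to the local mean.
#' @param scale Counts per activity unit for the Poisson model.
#' @return A noise-model list consumed by [simulate_phantom()].
#' @export
noise_gaussian <- function(cv = 0.1) {
  stopifnot(cv >= 0)
  list(type = "gaussian", cv = cv)
}

#' @rdname noise_gaussian
#' @export
noise_none <- function() list(type = "none")

#' @rdname noise_gaussian
#' @export
noise_poisson <- function(scale = 10) {
  stopifnot(scale > 0)
  list(type = "poisson", scale = scale)
}

#' Specify a digital phantom
#'
#' A phantom is a warm homogeneous background with hot inserts (spheres
#' and/or cylinders), imaged at finite resolution: the rasterized activity
#' field is blurred with an isotropic Gaussian point-spread function and
#' optionally degraded with noise. Defaults mirror a clinical whole-body
#' protocol: 4 x 4 x 3 mm voxels and a 5-mm FWHM Gaussian filter.
#'
#' @param grid_shape Integer triple, voxel counts per axis.
#' @param objects List of [phantom_object()]s; must be pairwise disjoint and
#'   lie fully inside the grid.
#' @param fg_activity,bg_activity Activity concentrations in kBq/ml; must
#'   satisfy `fg_activity > bg_activity > 0`.
#' @param voxel_spacing_mm Voxel edge lengths in mm.
#' @param psf_fwhm_mm Full width at half maximum of the isotropic Gaussian
#'   point-spread function, in mm (0 disables blurring).
#' @param noise Noise model, see [noise_gaussian()].
#' @param seed Integer seed used by [simulate_phantom()].
#' @return A `phantom_spec` with derived field `sbr = fg / bg`.
#' @export
phantom_spec <- function(grid_shape, objects, fg_activity, bg_activity,
                         voxel_spacing_mm = c(4, 4, 3), psf_fwhm_mm = 5,
                         noise = noise_gaussian(0.1), seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape > 0))
  if (!(is.numeric(fg_activity) && is.numeric(bg_activity) &&
        fg_activity > bg_activity && bg_activity > 0))
    stop("require fg_activity > bg_activity > 0")
  voxel_volume_ml(voxel_spacing_mm)  # validates spacing
  if (psf_fwhm_mm < 0) stop("psf_fwhm_mm must be nonnegative")
  extent <- grid_shape * voxel_spacing_mm
  for (ob in objects) {
    if (!inherits(ob, "phantom_object")) stop("objects must be phantom_object")
    r <- ob$diameter_mm / 2
    half <- c(r, r, if (ob$shape == "cylinder") ob$height_mm / 2 else r)
    if (any(ob$center_mm - half < 0) || any(ob$center_mm + half > extent))
      stop("invalid geometry: object extends outside the grid")
  }
  structure(list(grid_shape = grid_shape,
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 objects = objects,
                 fg_activity = fg_activity, bg_activity = bg_activity,
                 sbr = fg_activity / bg_activity,
                 psf_fwhm_mm = psf_fwhm_mm, noise = noise,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: %d x %d x %d voxels (%g x %g x %g mm)\n",
              x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
              x$voxel_spacing_mm[1], x$voxel_spacing_mm[2],
              x$voxel_spacing_mm[3]))
  cat(sprintf("  %d object(s); FG %g, BG %g kBq/ml (SBR %.2f); PSF %g mm\n",
              length(x$objects), x$fg_activity, x$bg_activity, x$sbr,
              x$psf_fwhm_mm))
  invisible(x)
}

#' Activity concentrations of the modified NEMA sphere phantom sessions
#'
#' Foreground/background activity concentration pairs (kBq/ml) of the five
#' measurement sessions, with the resulting signal-to-background ratios.
#'
#' @return A data frame with columns `fg`, `bg`, `sbr`.
#' @export
nema_activity_table <- function() {
  tab <- data.frame(fg = c(10.94, 20.37, 26.13, 66.56, 90.90),
                    bg = c(5.30, 5.30, 5.30, 9.90, 9.68))
  tab$sbr <- round(tab$fg / tab$bg, 2)
  tab
}

#' Sphere diameters (mm) of the modified NEMA IEC body phantom
#'
#' The largest original sphere (37 mm) is replaced by an 8-mm one.
#' @return Integer vector of diameters in mm.
#' @export
nema_sphere_diameters <- function() c(8L, 10L, 13L, 17L, 22L, 28L)

#' Build a NEMA-style six-sphere phantom specification
#'
#' Six spheres (8, 10, 13, 17, 22, 28 mm) on a warm background, laid out on
#' a 2 x 3 grid with generous spacing so that a 14 x 14 x 20-voxel VOI
#' around each sphere contains no other insert.
#'
#' @param fg_activity,bg_activity Activity concentrations in kBq/ml;
#'   defaults are the highest-SBR session of [nema_activity_table()].
#' @param grid_shape,voxel_spacing_mm,psf_fwhm_mm,noise,seed See
#'   [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
nema_phantom_spec <- function(fg_activity = 90.90, bg_activity = 9.68,
                              grid_shape = c(64, 64, 48),
                              voxel_spacing_mm = c(4, 4, 3),
                              psf_fwhm_mm = 5, noise = noise_gaussian(0.1),
                              seed = 1L) {
  d <- nema_sphere_diameters()
  # generic sub-voxel alignment: a physical phantom never sits on the
  # reconstruction lattice, and exact corner/center alignment produces
  # degenerate half-fraction masks for the small spheres
  xs <- c(52, 128, 204) + 1.7; ys <- c(80, 176) + 1.1; z <- 72 + 0.8
  centers <- expand.grid(x = xs, y = ys)
  objects <- lapply(seq_along(d), function(i)
    phantom_object("sphere", d[i],
                   c(centers$x[i], centers$y[i], z)))
  phantom_spec(grid_shape, objects, fg_activity, bg_activity,
               voxel_spacing_mm, psf_fwhm_mm, noise, seed)
}

#' Build the four-cylinder phantom specification
#'
#' Cylinders of 10/15/25/38 mm diameter with heights chosen to reproduce
#' the insert volumes 4.08, 12.23, 37.71 and 103.95 ml; axes along z.
#'
#' @inheritParams nema_phantom_spec
#' @export
cylinder_phantom_spec <- function(fg_activity = 75.30, bg_activity = 9.40,
                                  grid_shape = c(64, 64, 48),
                                  voxel_spacing_mm = c(4, 4, 3),
                                  psf_fwhm_mm = 5,
                                  noise = noise_gaussian(0.1), seed = 1L) {
  d <- c(10, 15, 25, 38)
  v <- c(4.08, 12.23, 37.71, 103.95)              # ml
  h <- 1000 * v / (pi / 4 * d^2)                  # back out heights in mm
  xs <- c(76, 180) + 1.7; ys <- c(76, 180) + 1.1; z <- 72 + 0.8
  centers <- expand.grid(x = xs, y = ys)
  objects <- lapply(seq_along(d), function(i)
    phantom_object("cylinder", d[i],
                   c(centers$x[i], centers$y[i], z), height_mm = h[i]))
  phantom_spec(grid_shape, objects, fg_activity, bg_activity,
               voxel_spacing_mm, psf_fwhm_mm, noise, seed)
}

# voxel-center coordinates (mm) along one axis
.axis_centers <- function(n, spacing) (seq_len(n) - 0.5) * spacing

# Partial-volume fractions of one object over its bounding box, by
# supersampling each voxel with s^3 regularly spaced subpoints.
.object_fractions <- function(ob, grid_shape, spacing, s) {
  r <- ob$diameter_mm / 2
  half <- c(r, r, if (ob$shape == "cylinder") ob$height_mm / 2 else r)
  lo <- pmax(1L, floor((ob$center_mm - half) / spacing - 1) + 1L)
  hi <- pmin(grid_shape, ceiling((ob$center_mm + half) / spacing + 1))
  idx <- lapply(1:3, function(a) lo[a]:hi[a])
  nbox <- vapply(idx, length, 1L)
  # subpoint offsets within a voxel, in (0,1)
  off <- (seq_len(s) - 0.5) / s
  frac <- array(0, nbox)
  sub <- expand.grid(ox = off, oy = off, oz = off)
  for (p in seq_len(nrow(sub))) {
    cx <- (idx[[1]] - 1 + sub$ox[p]) * spacing[1] - ob$center_mm[1]
    cy <- (idx[[2]] - 1 + sub$oy[p]) * spacing[2] - ob$center_mm[2]
    cz <- (idx[[3]] - 1 + sub$oz[p]) * spacing[3] - ob$center_mm[3]
    if (ob$shape == "sphere") {
      d2 <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
      frac <- frac + (d2 <= r^2)
    } else {
      in_xy <- outer(cx^2, cy^2, "+") <= r^2
      in_z <- abs(cz) <= ob$height_mm / 2
      frac <- frac + outer(in_xy, in_z, "&")
    }
  }
  list(frac = frac / s^3, lo = lo, hi = hi)
}

#' Rasterize a phantom onto its voxel grid
#'
#' Computes per-voxel partial-volume fractions of every insert by regular
#' supersampling, the noiseless activity field
#' `bg + (fg - bg) * fraction`, and ground-truth masks (fraction >= 0.5).
#'
#' @param spec A [phantom_spec()].
#' @param supersampling Subpoints per voxel edge (default 8).
#' @return A list of class `phantom_truth` with elements `activity`
#'   (noiseless unblurred array), `fraction` (summed fractions),
#'   `masks` (list of logical arrays per object), `mask` (union),
#'   `true_volume_ml` (analytic, per object), `fraction_volume_ml`
#'   (fraction-sum estimate, per object) and `voxel_volume_ml`.
#' @export
rasterize_phantom <- function(spec, supersampling = 8) {
  stopifnot(inherits(spec, "phantom_spec"), supersampling >= 1)
  s <- as.integer(supersampling)
  gs <- spec$grid_shape
  vv <- voxel_volume_ml(spec$voxel_spacing_mm)
  fraction <- array(0, gs)
  masks <- vector("list", length(spec$objects))
  fvol <- tvol <- numeric(length(spec$objects))
  for (i in seq_along(spec$objects)) {
    ob <- spec$objects[[i]]
    of <- .object_fractions(ob, gs, spec$voxel_spacing_mm, s)
    sl <- lapply(1:3, function(a) of$lo[a]:of$hi[a])
    fraction[sl[[1]], sl[[2]], sl[[3]]] <-
      fraction[sl[[1]], sl[[2]], sl[[3]]] + of$frac
    m <- array(FALSE, gs)
    m[sl[[1]], sl[[2]], sl[[3]]] <- of$frac >= 0.5
    masks[[i]] <- m
    fvol[i] <- sum(of$frac) * vv
    tvol[i] <- true_object_volume(ob$shape, ob$diameter_mm, ob$height_mm)
  }
  if (any(fraction > 1 + 1e-9))
    stop("invalid geometry: foreground objects overlap")
  activity <- spec$bg_activity +
    (spec$fg_activity - spec$bg_activity) * fraction
  structure(list(activity = activity, fraction = fraction, masks = masks,
                 mask = Reduce(`|`, masks, array(FALSE, gs)),
                 true_volume_ml = tvol, fraction_volume_ml = fvol,
                 voxel_volume_ml = vv),
            class = "phantom_truth")
}

# Separable Gaussian convolution along one array dimension with replicate
# (clamped) edge handling, as an n x n band matrix product.
.conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  w <- dnorm(-r:r, sd = sigma_vox)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmin(pmax(i + (-r:r), 1L), n)   # clamp = replicate padding
    for (t in seq_along(j)) K[i, j[t]] <- K[i, j[t]] + w[t]
  }
  K
}

#' Blur a 3-D field with an isotropic Gaussian point-spread function
#'
#' FWHM is converted to a per-axis standard deviation in voxel units,
#' `sigma = fwhm / (2 sqrt(2 log 2)) / spacing`, and applied as three
#' separable 1-D convolutions with replicate edge handling.
#'
#' @param x 3-D numeric array.
#' @param fwhm_mm PSF full width at half maximum in mm.
#' @param spacing_mm Voxel spacing triple in mm.
#' @return Blurred array of the same shape.
#' @export
psf_blur <- function(x, fwhm_mm, spacing_mm) {
  stopifnot(length(dim(x)) == 3, fwhm_mm >= 0)
  if (fwhm_mm == 0) return(x)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d <- dim(x)
  for (a in 1:3) {
    K <- .conv_matrix(d[a], sigma_mm / spacing_mm[a])
    x <- aperm(x, c(a, setdiff(1:3, a)))
    dm <- dim(x)
    x <- array(K %*% matrix(x, nrow = dm[1]), dm)
    x <- aperm(x, order(c(a, setdiff(1:3, a))))
  }
  x
}

#' Simulate a PET acquisition of a digital phantom
#'
#' Rasterizes the phantom, convolves the activity field with the Gaussian
#' PSF, applies the noise model with the spec's seed, and clips at zero.
#'
#' @param spec A [phantom_spec()].
#' @param supersampling Passed to [rasterize_phantom()].
#' @param truth Optional precomputed [rasterize_phantom()] result for this
#'   spec's geometry (fractions only depend on geometry, so one
#'   rasterization can serve many noise realizations and activity levels).
#' @return An [activity_volume()]; the ground truth is attached as
#'   attribute `"truth"`.
#' @export
simulate_phantom <- function(spec, supersampling = 8, truth = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(truth)) truth <- rasterize_phantom(spec, supersampling)
  noiseless <- spec$bg_activity +
    (spec$fg_activity - spec$bg_activity) * truth$fraction
  blurred <- psf_blur(noiseless, spec$psf_fwhm_mm, spec$voxel_spacing_mm)
  set.seed(spec$seed)
  x <- switch(spec$noise$type,
    none = blurred,
    gaussian = blurred + rnorm(length(blurred),
                               sd = spec$noise$cv * blurred),
    poisson = {
      sc <- spec$noise$scale
      array(rpois(length(blurred), sc * blurred) / sc, dim(blurred))
    },
    stop("unknown noise model: ", spec$noise$type))
  x[x < 0] <- 0
  vol <- activity_volume(x, spec$voxel_spacing_mm)
  attr(vol, "truth") <- truth
  vol
}
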