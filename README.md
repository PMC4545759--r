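# petseg

Two-stage segmentation of lesions in 3-D PET activity volumes: a
two-class Gaussian mixture model fitted by a modified EM algorithm with
tied standard deviations, followed by a Markov-random-field correction
sampled with a Metropolis scheme. The package also provides the fixed and
iterative thresholding baselines such methods are compared against,
evaluation metrics (connectivity-based detection, Dice similarity,
relative volume error), NIfTI I/O, and a digital NEMA-style sphere and
cylinder phantom simulator with analytic ground truth, so the complete
pipeline can be exercised and validated without scanner data.

## Who this is for

Medical-physics and image-analysis work where a lesion volume must be
delineated on PET inside a volume of interest (VOI) without
scanner-specific calibration: fixed thresholds (36-42% of the VOI
maximum) fail at low signal-to-background ratio (SBR) and small
diameters because of the partial volume effect, and iterative
thresholding needs a regression curve measured on phantoms for every
scanner/reconstruction/tracer combination. The statistical pipeline here
needs neither.

## The model

Within a VOI of `N` voxels with activities `x_n`, a two-class Gaussian
mixture (class 1 = lesion/FG, class 2 = background/BG) is fitted by EM
with one modification in the M-step: the standard deviation is estimated
from the background responsibilities only and copied to the foreground,

    sigma_1 <- sigma_2,

which stops PVE boundary voxels from inflating the lesion class. The EM
stops when both class means move by less than 0.01 kBq/ml.

The coarse labeling is then refined on a binary Markov random field whose
Gibbs prior couples only face-adjacent voxels with *different* labels
(coupling matrix `[[0, g], [g, 0]]`, default `g = 1000`). With mixture
parameters held fixed, a Metropolis sweep proposes flipping each voxel in
raster order and accepts by the ratio of local conditional probabilities

    log P_n = -g * (# discordant face neighbors) - (x_n - mu_k)^2 / (2 sigma_k^2).

After 10 burn-in sweeps, the mean of 70 retained label fields is a soft
segmentation in [0, 1]; its foreground sum times the voxel volume (0.048
ml at 4 x 4 x 3 mm) is the lesion volume estimate.

## Worked example

Simulate the six-sphere phantom at SBR 9.39 and segment the 22-mm sphere
(true volume 5.58 ml):

```r
library(petseg)
tab  <- nema_activity_table()
spec <- nema_phantom_spec(fg_activity = tab$fg[5], bg_activity = tab$bg[5],
                          seed = 3)                       # SBR 9.39
vol  <- simulate_phantom(spec)

ob  <- spec$objects[[5]]                                  # 22-mm sphere
box <- voi_box_around(ob$center_mm, c(14, 14, 20), spec$grid_shape,
                      spec$voxel_spacing_mm)
x   <- extract_voi(vol, box)

em <- run_em(x)                     # coarse stage
em
#> petseg_em: 8 iteration(s), converged, lesion detected
#> mixture_params  FG: tau=0.030 mu=71.67 sigma=3.04 | BG: tau=0.970 mu=10.24 sigma=3.04

set.seed(2)
cor <- run_correction(x, em)        # MRF correction
vv  <- voxel_volume_ml(spec$voxel_spacing_mm)
soft_volume(em, vv)                 # 5.700 ml  (mixture alone)
soft_volume(cor, vv)                # 5.545 ml  (after correction)
```

The mixture alone overestimates slightly (5.70 ml) because boundary PVE
voxels lean foreground; the boundary-penalizing correction pulls the
estimate to 5.55 ml, within half a voxel of the truth, with a Dice
coefficient of 0.965 against the rasterized ground-truth mask.
`benchmark_phantom(spec, methods = c("fixed42", "emgmm", "gmrf"))` runs
all methods over every insert and returns one record per object and
method (estimated volume, signed volume error in percent, detection by
the two-connected-components rule, Dice coefficient).

A command-line front end with the verbs `simulate`, `segment`,
`threshold`, `itm` and `evaluate` is installed at `inst/cli/petseg.R`:

```sh
Rscript inst/cli/petseg.R simulate --out phantom.nii.gz --sbr-row 5 --seed 3
Rscript inst/cli/petseg.R segment  --in phantom.nii.gz --voi 25:39,37:51,14:34 \
        --gamma 1000 --burn-in 10 --samples 70 --seed 2 --out seg
#> gmrf volume: 5.545 ml (EM converged in 8 iterations)
```

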