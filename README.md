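# csym — circular-symmetry subpixel particle localization

`csym` localizes spherical particles in microscopy images to a small
fraction of a pixel by finding the point of maximal mirror symmetry of the
intensity pattern. It is written for people who track beads and
particle-like objects in noisy video — optical-tweezers and tethered-DNA
experiments, colloid dynamics, fluorescent point emitters — and for people
who benchmark such trackers: the package ships the C-Sym locator, three
reference baselines (threshold centroid, 1-D cross-correlation symmetry,
2-D Gaussian fit), a fully seeded synthetic-image generator with known
ground truth and SNR-calibrated noise, and the benchmark protocols that
compare them.

## The method

A radially symmetric particle's image is mirror-symmetric about the
vertical and horizontal axes through its center, whatever its profile,
background or polarity. For each integer candidate $(x, y)$ in a search
area around an initial estimate, an odd-sided ROI is split at the
candidate axis and each half is mirrored onto itself, giving template
pairs $(T_L, T_R)$ and $(T_T, T_B)$; the candidate's symmetry is their
Pearson correlation

$$\mathrm{Corr}_X(x,y) = \frac{\sum_{i,j}(T_L(i,j)-\mu_L)(T_R(i,j)-\mu_R)}{(n^2-1)\,\sigma_L\sigma_R} \in [-1, 1].$$

Averaging the maps along the orthogonal axis gives 1-D symmetry profiles
$\mathrm{Sym}_X$, $\mathrm{Sym}_Y$; each is interpolated by a piecewise
cubic Hermite curve sampled at 0.01 px, a quadratic
$q_1 x^2 + q_2 x + q_3$ is least-squares fitted around the profile peak,
and the subpixel center is its vertex $c = -q_2/(2q_1)$. Correlation is
affine-invariant, so changing background, contrast or polarity changes
nothing. Noise calibration throughout uses
$\mathrm{SNR} = (I_{\max}-I_{\min})/(4\sigma) - 1$ (note the $-1$: SNR 0.1
means noise of nearly a quarter of the dynamic range).

## A worked example

Generate one randomized trial (radius-10 ringed bead, random background,
inverted contrast, SNR 1 — the particle is barely visible) and localize it
from a deliberately wrong integer guess:

```r
library(csym)
scene <- make_trial(radius = 10, snr = 1, seed = 7, width = 128, height = 128)
scene
#> <scene_image> 128 x 128 px, background 0.744, noise sigma 0.06746 (SNR 1)
#> <particle_spec> rings, radius 10 px, center (57.456, 39.405), amplitude 0.285, inverted
#>   initial guess (57, 41)

loc <- locate_csym(scene)
tidy(loc)
#> # A tibble: 1 × 6
#>   method     x     y converged peak_corr_x peak_corr_y
#>   <chr>  <dbl> <dbl> <lgl>           <dbl>       <dbl>
#> 1 csym    57.3  39.3 TRUE            0.774       0.802

sqrt(sum((c(loc$x, loc$y) - scene$truth$center)^2))
#> [1] 0.1634984
```

The located center is 0.16 px from the ground truth, recovered from a
guess that was 1.6 px off, at a noise level where the peak mirror
correlation is only ~0.8. `autoplot(loc)` draws the two symmetry profiles
with their interpolants and the fitted center.

Benchmarks compare locators cell by cell over radius × SNR, sharing trials
within a cell so comparisons are paired:

```r
run_grid(radii = 10, snrs = c(0.1, 10), n_trials = 25,
         methods = c("csym", "com"), seed = 1)
#>   method radius  snr mean_error sd_error  n failures
#> 1   csym     10  0.1     0.1346   0.0686 25        0
#> 2    com     10  0.1     0.8938   0.4461 25        0
#> 3   csym     10 10.0     0.0366   0.0230 25        0
#> 4    com     10 10.0     0.0407   0.0252 25        0
```

At SNR 10 the centroid is competitive; at SNR 0.1 it is 6–7× worse, which
is the regime the symmetry method is for. `autoplot()` on the returned
grid draws the mean-error curves with SD bars. Other entry points:
`make_pair_trial()`/`run_overlap_grid()` for interfering particle pairs,
`run_sinusoid_experiment()` + `fit_sinusoid()` for subpixel oscillation
amplitudes, `calibrate_projection()` for the degree-5 image-to-stage
calibration, and `roi_correlation_series()` for the ground-truth-free
consecutive-ROI robustness metric. Thin command-line wrappers live in
`inst/cli/` (`csym-locate.R`, `csym-bench.R`); images move as multi-page
TIFF via `read_image_stack()`/`write_image_stack()`, results as tidy CSV.

The methods vignette (`vignettes/csym-methods.Rmd`) documents the model,
every tunable parameter with its default and rationale, the generator's
scope, and known limitations.

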