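# flicmseg

Noise-robust segmentation of 2-D brain MRI slices into white matter (WM),
gray matter (GM) and cerebrospinal fluid (CSF) with **fuzzy local information
C-means (FLICM)** clustering, plus the surrounding toolchain a tissue-
segmentation study needs: Canny edge detection built from separable
Gaussian-derivative filters, skull stripping, level-set initialization
diagnostics, Fourier shape descriptors for picking out the H-shaped
ventricular CSF region, Jaccard/Dice/PSNR/SSIM evaluation, and a synthetic
brain-phantom generator with calibrated noise for end-to-end robustness
experiments.

It is written for image-analysis researchers who want a self-contained,
reproducible testbed for fuzzy clustering of tissue intensities: every
experiment in the package runs from seeded synthetic data, with exact ground
truth, in seconds.

## The model

FLICM segments an image `x` into `K` intensity clusters by minimizing

    J = sum_i sum_j  mu_ij^m ( ||x_i - v_j||^2 + B_ij )

where `mu_ij` is the fuzzy membership of pixel `i` in cluster `j` (rows sum
to 1), `v_j` the cluster center, `m > 1` the fuzzifier, and

    B_ij = sum_{r in N_i}  (1 / (1 + c_ir)) (1 - mu_rj)^m ||x_r - v_j||^2

the *fuzzy local-information factor*: a penalty accumulated over the 3x3
neighbourhood `N_i` (center excluded), spatially discounted by the
coordinate distance `c_ir`. `B_ij` is large when the neighbours of `i`
disagree with cluster `j`, so isolated noise pixels are pulled to the local
consensus without any tuning parameter. Setting `B = 0` recovers classical
fuzzy C-means (FCM), which the package exposes as the nested baseline. The
fit alternates the closed-form membership update, the weighted-mean center
update and the fuzzy-factor refresh until the centers stop moving.

`flicm()` is the fitting function; it returns a classed object with
`print`, `summary`, `coef` (centers), `fitted` (labels / memberships / soft
reconstruction), `predict`, `residuals` and `plot` methods.

## Worked example

```r
library(flicmseg)

ph    <- generate_phantom(phantom_spec(128, 128, geometry_seed = 42))
noisy <- add_noise(ph$image, noise_spec("gaussian", level = 15, seed = 7))
fit   <- flicm(noisy, K = 5)
fit
#> FLICM segmentation fit
#> Call: flicm(image = noisy, K = 5)
#> Clusters: 5   fuzzifier m = 2   image: 128 x 128
#> Converged: yes after 83 iteration(s) (tol 1e-05 on max center shift)
#> Centers:   5.99623   58.95149  125.21831  190.10276  219.66477
```

Despite noise with a standard deviation of 15 intensity units, the five
centers land within a few units of the true class means (0, 60, 125, 190,
230 for background, CSF, GM, WM, skull). Evaluating against the ground
truth:

```r
matched <- match_labels(fit$labels, ph$labels)
metric_report(ph$labels, matched, classes = 2:4,
              reference = ph$image, test = fitted(fit, "response"))
#> Segmentation metrics
#>  class jaccard   dice
#>      2  0.7347 0.8471
#>      3  0.8389 0.9124
#>      4  0.7126 0.8322
#> Pixel accuracy: 0.8950   PSNR: 21.07 dB   SSIM: 0.6787
```

Classes 2/3/4 are WM/GM/CSF; the overlap that is lost sits almost entirely
in a 1-2 pixel band at class interfaces (see the methods vignette for why
the local term trades boundary pixels for noise immunity). The full
pipeline adds denoising, skull stripping, level-set diagnostics and the
Fourier-descriptor search for the H-shaped CSF region:

```r
pp <- run_pipeline(ph$image, truth = ph$labels, reference = ph$image)
pp$level_set
#> Level-set statistics: length 480.673, area 1442, beta 0.33334
pp$h$matched      # H-shaped ventricular region identified
#> [1] TRUE
```

`run_noise_experiment(pipeline_config())` reruns the whole FCM-vs-FLICM
comparison over the gaussian noise ladder {0, 5, 10, 15, 20} with 10 seeded
replicates and returns a tidy results table (`write_experiment_csv()` makes
it byte-reproducible).

## Command line

A thin launcher over the same functions ships with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "flicmseg.R", package = "flicmseg"))')" \
    segment --in slice.png --k 4 --out-labels labels.png --trace trace.csv
```

Subcommands: `phantom`, `segment`, `edges`, `levelset-stats`, `h-region`,
`evaluate`, `experiment`. All are deterministic for a fixed seed.

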