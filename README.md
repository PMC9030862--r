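# ribmnlm

Speckle reduction for B-mode ultrasound images by **rotation-invariant
block-matching non-local means**: K-means pre-classification of image patches
on Hu moment invariants restricts each pixel's non-local-means candidate set
to its own cluster, and every candidate patch is rotation- and
mirror-aligned — via centroid-derived rotation frames and bilinear
resampling — before its similarity to the target is measured. The package is
aimed at researchers working on ultrasound image enhancement who need a
reproducible, fully scriptable de-speckling pipeline with its evaluation
metrics and a self-contained synthetic test bed.

## Method

Each pixel $i$ of the noisy image $v$ is restored as

$$\mathrm{NLM}_p(v)(i) \;=\; \sum_{j \in \mathrm{cluster}(i)} w_R(i,j)\, v(j),
\qquad
w_R(i,j) \;=\; \frac{1}{Z_R(i)}\, e^{-d_R(i,j)/h^2},$$

where the candidate list is the look-up table entry of $i$'s K-means cluster
(clusters are fitted on per-patch Hu invariant vectors $\phi_1..\phi_7$
computed from a Gaussian-blurred guide image), and the distance

$$d_R(i,j) \;=\; \sum_{q \in \mathcal{C}_r}
\big( v_i(q) - \mathrm{In}(v_j,\, m(R\,q)) \big)^2$$

is taken over the circular patch support $\mathcal{C}_r$ after rotating (and,
when the $\phi_7$ signs disagree, mirroring) the candidate into the target's
orientation; $R$ is built from the patches' unit intensity-centroid
directions and $\mathrm{In}$ is bilinear interpolation. Defaults follow the
reference setting: 15 × 15 patches, $h = 12\sigma$, pre-filter width
$0.5\sigma$ with radius 4, and 675 clusters per 225 × 225 image (scaled with
pixel count). A conventional all-candidate NLM baseline, SSIM/PSNR/MSE/RMSE
metrics, a phantom-and-noise generator, and experiment/K-sweep runners are
included. See the methods vignette (`vignettes/ribm-nlm-methods.Rmd`) for the
full model, parameter meanings, and design rationale.

## Worked example

```r
library(ribmnlm)

clean <- example_phantom(128, 128, seed = 1)          # anatomy-like phantom
noisy <- add_noise(clean, sigma = 20, seed = 2)       # additive Gaussian, 0-255 scale
den   <- despeckle_ribm_nlm(noisy, denoise_config(sigma = 20, seed = 3))

evaluate_images(clean, noisy)
#> # A tibble: 1 × 4
#>    ssim  psnr   mse  rmse
#>   <dbl> <dbl> <dbl> <dbl>
#> 1 0.357  22.1  403.  20.1
evaluate_images(clean, den)
#> # A tibble: 1 × 4
#>    ssim  psnr   mse  rmse
#>   <dbl> <dbl> <dbl> <dbl>
#> 1 0.684  28.8  85.9  9.27
```

The filter raises PSNR by ~6.7 dB and nearly doubles SSIM on this phantom:
the mean squared error against the clean image drops from 403 to 86 gray²
levels while lesion boundaries stay sharp (SSIM rewards exactly that
structure preservation). The resolved parameter set, including the
auto-scaled cluster count (here `K = 218`), travels with the result as
`attr(den, "config")`.

Choosing the cluster count for a new image class:

```r
k_sweep(example_phantom(64, 64, seed = 1), sigma = 20,
        k_values = c(5, 25, 55, 200), seed = 1)
#>     K     psnr       mse failed
#> 1   5 28.00847 102.85680  FALSE
#> 2  25 29.00656  81.73809  FALSE
#> 3  55 29.11802  79.66694  FALSE
#> 4 200 28.11244 100.42363  FALSE
```

Quality rises with `K`, peaks (here near the auto-scaled default of 55 for a
64 × 64 image), then degrades once clusters no longer hold enough candidates.

A thin command-line front end with `phantom`, `addnoise`, `despeckle`,
`evaluate`, `experiment` and `ksweep` subcommands lives at
`inst/cli/ribmnlm.R`.

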