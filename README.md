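# cementochron

Life-history inference from dental cementum increments.

Dental cementum is deposited around tooth roots continuously through
life and is almost never remodelled. Each year leaves one *growth layer
group* (GLG): a thick light increment from the favorable season and a
thin dark one from the unfavorable season. Counting GLGs gives an
individual's age at death; measuring their radial widths gives annual
growth rates; and the texture of the tissue changes where growth
truncates at sexual maturity. `cementochron` implements this whole
inferential chain for grayscale images of cementum (tomographic or
histological), aimed at paleobiologists and zooarchaeologists studying
growth, metabolism and life history in fossil and extant mammals:

- **Image handling** — virtual thin sections by z-projection of slice
  stacks, ROI-based straightening of cementum into radial ×
  circumferential arrays, screening for cellular-cementum voids.
- **Increment measurement** — radial grayscale transects; peak
  detection by the five-segment rule (a light increment is a run of
  samples above its segment's mean + SD); widths as distances between
  successive peak centers, the final incomplete year excluded;
  consensus life spans as the modal GLG count across transects.
- **Growth rates and allometry** — mass-specific growth rates
  (msGR, µm year g⁻¹) via the first-increment allometry
  log₁₀ w₁ = 0.270·exp(0.340·log₁₀ M) + 0.564; metabolic rates from
  life span, log₁₀ msSMR = −0.237·log₁₀ L − 0.083 (mammals) and
  −0.83·log₁₀ L − 0.31 (reptiles); dentary length from lm1,
  dentary = 10.184·lm1 + 8.026, with a configurable dentary-mass
  regression.
- **Growth patterns** — AIC selection among ten nonlinear growth
  families (Hill sigmoid, quadratic, Gaussian, exponential, von
  Bertalanffy, Gompertz, logistic, linear, power, logarithmic);
  truncation-window detection from consecutive-year slope drops;
  maturity-age ranges from extant calibration offsets.
- **Texture** — 21 ISO-25178-style areal texture measures on cementum
  patches, juvenile-vs-adult ANOVA screening, PCA, and convex-hull
  overlap in PC1–PC2 to test for distinct texture-space occupation.
- **Phylogenetics** — closed-form Brownian PGLS (exactly OLS on a star
  tree), phylogenetic nonlinear regression with BM/OU error models
  compared by AIC and rejection ABC, phylogenetic ANCOVA, and pooled
  one-way ANOVA with Cohen's d.
- **Synthetic data** — a seeded generator for banded cementum images
  with ground-truth sidecars (peak positions, spacings, maturity
  boundary, voids), specimen cohorts with censored life spans, and
  Brownian trait simulation on trees.

## Worked example

Render a synthetic specimen with a decreasing Hill-sigmoid growth
schedule (first-year width 15 µm, 10 years), measure it, and estimate
its life history:

```r
library(cementochron)

sch  <- growth_schedule("hill_sigmoid", c(11, 4.5, 5, 5), 10, base_width_um = 15)
spec <- synthetic_spec(sch, texture_params(contrast = 0.65, anisotropy = 30,
                                           noise_sd = 4),
                       image_shape = c(160, 96), seed = 42)
out <- render_cementum(spec)

# measure between the hyaline layer and the outer phase fringe
reg    <- trim_region(out$image, out$ground_truth$hyaline_um,
                      out$ground_truth$fringe_start_um)
series <- measure_region(reg)          # 8 transects: peaks -> widths

specimen_lifespan(series)$lifespan_years
#> [1] 10
round(series[[1]]$widths_um, 2)        # measured annual widths, transect 1
#> [1] 14.53 14.99 13.54 11.97 10.00  8.49  7.46  6.07  6.95
round(out$ground_truth$widths_um, 2)   # true band spacings
#> [1] 14.97 14.69 13.74 11.92  9.81  8.22  7.28  6.78  6.51

round(msgr(series[[1]]$widths_um, mass_g = 130), 2)   # mass-specific rates
#> [1] 7.55 7.79 7.04 6.22 5.20 4.42 3.88 3.16 3.62
round(lifespan_to_mssmr(10, "mammal"), 3)  # msSMR (ml O2 h^-1 g^-1) at 10 yr
#> [1] 0.479
round(predict_first_width(17.9), 2)        # predicted w1 for a 17.9 g taxon
#> [1] 9.49
```

The consensus count recovers the true 10-year life span exactly; every
measured width is within one voxel of the true band spacing. Fitting
the ten growth families to the pooled msGR series of such a taxon
selects the Hill sigmoid, and `find_truncation()` places the
growth-rate reduction at years 4–5, bracketing the schedule's
inflection.

The `analysis/` directory holds the numbered workflow scripts
(`01_simulate_cohort.R` … `05_validation.R`) that run the same chain at
cohort scale — simulation, measurement, pooling, model selection,
life-history inference, texture comparison and the phylogenetic layer —
writing their tables under `results/`.

## Documentation

The methods vignette
(`vignettes/cementochron-methods.Rmd`) documents the models and their
assumptions, every tunable parameter with units and defaults, what the
synthetic generator does and does not emulate, numerical choices, and
known limitations.
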