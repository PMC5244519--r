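# retinomapper

Analysis pipeline for **phase-encoded retinotopic mapping of mouse visual
cortex with widefield intrinsic signal optical imaging (ISOI)**, for labs
quantifying stimulus-evoked activity in primary visual cortex (V1) and the
higher visual areas (HVAs: LM, LI, AL, RL, and merged AM/PM), e.g. when
comparing genotypes, sexes, or developmental ages.

A periodic stimulus (a bar sweeping the screen once per 8-s cycle, or a
drifting-grating patch) modulates cortical reflectance at the stimulus
frequency *f* = 1/8 Hz. Each pixel's time course *x*[t] is reduced to the
complex coefficient

    c_p = (2/T) Σ_t (x_p[t] − x̄_p) · exp(+i 2π f t),

whose **magnitude** (in fractional ΔR/R-like units, |c|/x̄) measures evoked
activity and whose **phase** encodes the time of response — hence, through
the bar sweep, the pixel's preferred azimuth or elevation. Area borders are
reversals of retinotopic progression, computed as the **visual field
sign** — the sign of the Jacobian of the cortical map, sign(∂ₓa·∂ᵧe −
∂ᵧa·∂ₓe). Per-area amplitudes are measured inside a responsive-cortex mask
(thresholded Gaussian-filtered magnitude map) and normalized to each
animal's V1; cohorts are compared with one-way/two-way ANOVA and
Bonferroni post hoc tests.

The package includes a forward simulator (`build_default_sheet()`,
`simulate_movie()`, `simulate_cohort_responses()`) that generates 12-bit
multi-page TIFF movies with known retinotopy, area polygons, amplitudes,
hemodynamic delay and noise, so every stage is validated by parameter
recovery. See `vignettes/retinotopy-methods.Rmd` for the model,
assumptions, and design decisions.

## Pipeline

```
raw movies (TIFF + JSON sidecar, 12-bit @ 30 fps)
  └─ bin_movie()            4x temporal, 2x2 spatial SUM  → 16-bit @ 7.5 fps
     └─ extract_response()  per-pixel complex coefficient at f_stim
        ├─ map_fidelity()   spectral SNR gate (animal exclusion)
        ├─ retinotopy_from_phases() → field_sign() → segment_areas()
        └─ response_magnitude() → responsive_mask() → region_means()
           └─ normalize_to_v1() → run_cohort() → ANOVA + Bonferroni
```

## Worked example

Simulate one noisy animal (three movies: azimuth bar, elevation bar,
grating) and run the full per-animal analysis:

```r
library(retinomapper)
sheet <- build_default_sheet()                     # V1 + 5 HVAs, known truth
cfg   <- default_config(n_cycles = 10, delay_s = sheet$delay_s)
sim   <- function(kind, seed)
  simulate_movie(sheet, cfg$stimuli[[kind]], cfg$screen,
                 noise_model(), seed = seed)$movie
res <- run_animal(sim("azimuth", 1), sim("elevation", 2),
                  sim("grating", 3), cfg, animal_id = "demo01")
round(unlist(res$table[grep("^norm_", names(res$table))]), 3)
#>   norm_V1   norm_LM   norm_LI   norm_AL   norm_RL norm_AMPM
#>     1.000     0.742     0.577     0.681     0.697     0.664
```

The fidelity gate reported SNR 17.2 (threshold 3: the animal is kept), all
six areas were recovered, and the normalized amplitudes sit near the
programmed ratios (LM 0.75, LI 0.625, dorsal areas 0.75) up to noise and
border dilution; `norm_V1` is exactly 1 by construction.

Cohort statistics on a simulated genotype effect (30% dorsal reduction in
KO males, n = 7 per genotype, between-animal SD 15%):

```r
tab <- simulate_cohort_responses(
  adult_design(n_per_cell = 7, ko_dorsal_scale = 0.7), seed = 1)
m <- tab[tab$sex == "M", ]
one_way_anova(m$norm_AMPM, m$genotype, effect_name = "genotype")
#> genotype     F(2,18) = 13.29, p = 0.000285
bonferroni_posthoc(m$norm_AMPM, m$genotype)
#>        pair    estimate         t df        p_raw        p_adj
#> 1 Het vs KO  0.15316406  3.702347 18 0.0016301146 0.0048903437
#> 2 Het vs WT -0.05197911 -1.256461 18 0.2250110837 0.6750332511
#> 3  KO vs WT -0.20514318 -4.958809 18 0.0001015065 0.0003045196
```

The KO reduction is detected (F(2,18), the df of a 3-genotype × 7-animal
design); the Bonferroni-adjusted KO-vs-WT comparison is significant while
Het-vs-WT is not — the programmed truth.

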