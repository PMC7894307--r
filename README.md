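# beetlescape

Do bark beetle outbreaks amplify or dampen *future* bark beetle
disturbance? `beetlescape` is an R package for exploring this question in a
fully synthetic, desk-scale world. It couples

* a cohort-based forest landscape simulator on a 100-m grid (growth,
  mortality, self-thinning, neighbourhood-fed regeneration, windthrow),
* an annual *Ips typographus* outbreak model (degree-day voltinism, logistic
  winter survival, windthrow-fuelled brood amplification, exponential
  dispersal, colonization against drought-modulated tree defence, host
  depletion),
* the eight structural/compositional diversity indicators commonly used for
  such landscapes (Shannon α diversity of 4-m height and 4-cm dbh classes,
  canopy cover, rumple index, multiplicative β diversity, spruce proportion,
  host aggregation index), and
* a factorial climate × disturbance scenario engine with a random-forest
  counterfactual analysis that isolates the disturbance-mediated feedback.

The core quantity is the feedback estimate

```
percent_effect = 100 · (Σŷ_disturbed − Σŷ_counterfactual) / Σŷ_counterfactual
```

where a random forest trained on disturbed runs (response: beetle-killed
volume per 50-yr window; predictors: the eight indicators at window start
plus window climate) predicts once with factual covariates and once with the
indicator columns swapped to the matched undisturbed run's values (climate
always factual). Negative values mean the vegetation changes wrought by
disturbance *dampen* future beetle activity.

This package is intended for methodologists and students of disturbance
ecology who want a transparent, fully testable implementation of the
simulation + surrogate-model counterfactual design; it deliberately does not
reproduce any real landscape's magnitudes (see the methods vignette,
`vignettes/beetlescape-methods.Rmd`).

## Worked example

```r
library(beetlescape)

cfg <- default_config("desk")          # 50 x 50 cells, 300 yr, 5 replicate pairs
cfg$experiment$climates <- c("BC", "HC")
cfg$experiment$replicates <- 2L        # quick demonstration
exp <- run_experiment(cfg)             # ~1 min

cumulative_contrast(exp, "HC", "BC")$percent
#> [1] 1360.056
```

The hot-scenario landscape loses an order of magnitude more growing stock
to beetles than the baseline-climate landscape. The analysis proper uses
the full desk preset:

```r
cfg <- default_config("desk")
exp <- run_experiment(cfg)             # 40 runs, ~4 min on one core
tab <- build_training_table(exp, 50)   # 120 rows
model <- fit_surrogate(tab, seed = 1)
model
#> <bl_surrogate> 10 features, OOB R2 = 0.815

cumulative_contrast(exp, "HC", "BC")$percent
#> [1] 1326.17

decompose_feedback(model, exp, climates = c("BC", "HC"))[, c(1, 2, 5)]
#>   climate         swap_set percent_effect
#> 1      BC              all        -45.818
#> 2      BC composition_only          3.523
#> 3      BC   structure_only        -52.175
#> 4      HC              all        -59.792
#> 5      HC composition_only        -46.848
#> 6      HC   structure_only        -44.218
```

Reading the feedback table: under hot climate the disturbed landscape is
predicted to lose about 60 % less growing stock to future beetle outbreaks
than the same landscape with its undisturbed structure and composition — a
strong dampening feedback, driven by host depletion (composition) and
structural diversification in roughly equal measure. The composition-only
effect is near zero under baseline climate, where outbreaks are too small
to deplete the host. All numbers above are actual package output
(base seed 42); they change with the configured seed.

## Command line

```sh
Rscript -e 'beetlescape::cli_main(commandArgs(TRUE))' run --preset desk --out out/
Rscript -e 'beetlescape::cli_main(commandArgs(TRUE))' feedback --dir out/
Rscript -e 'beetlescape::cli_main(commandArgs(TRUE))' fixtures --out tmp/   # 10x10 mini bundle
```

Bundles contain `kill_series.csv`, `indicators.csv`, `events.csv`, the
config echo and a cached experiment object that the analysis subcommands
(`contrast`, `attribute`, `feedback`, `pca`, `ema`) operate on.

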