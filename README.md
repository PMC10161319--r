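# stratcost

Bottom-up micro-costing of risk-stratified breast cancer screening.

When a screening programme predicts each woman's breast cancer risk at her
first mammogram — from a risk questionnaire, automated volumetric breast
density, and optionally a 142-SNP polygenic test — the prediction itself
consumes resources: mailed invitations, data entry, density measurements,
batched array genotyping, risk letters, and clinician consultations for
women at raised risk. `stratcost` is for health economists and screening
analysts who need the expected per-woman cost of such a strategy, its
uncertainty, its sensitivity to genotyping batch size, and its annual cost
at national scale.

## The model

The delivery pathway is a decision tree of chance nodes and activities.
For strategy *s* (TC, TC+VBD, TC+VBD+SNP) in setting *d* (as delivered in
a research trial, or routinely in the health service), the expected
per-woman cost is

> E[C_sd] = Σ_a Pr(a fires) · c_a

summed over the activities *a* of the strategy's pathway, with each
activity cost c_a built from resource quantities priced at 2021-GBP unit
costs. Around this engine sit:

* **PSA** — seeded Monte Carlo over beta/uniform parameter distributions,
  with 2.5th/97.5th-centile pseudo confidence intervals (type-7 quantiles);
* **DSA** — re-costing under discrete alternative (per-informant) resource
  use sets;
* **batch costing** — a step-cost model for array genotyping (48-sample
  chips, one control per batch, box-purchased consumables, fixed +
  per-slot staff time) reproducing the per-sample cost curve over batch
  sizes 1–95;
* **rollout** — annual programme cost and the value of perfect/actual
  implementation at 240,000 first screens per year.

All published parameters ship as a plain-text fixture
(`inst/extdata/bcpredict/`); rows reconstructed from aggregates are
flagged `reconstructed`, the one assumed cost row `assumed`. See the
vignette `vignettes/costing-methods.Rmd` for the model's assumptions and
every design choice.

## Worked example

```r
library(stratcost)

m <- paper_model()        # the packaged fixture, validated
m
#> Risk-stratification pathway cost model
#>   24 resource items, 10 unit costs, 12 probability parameters
#>   strategies: TC, TC_VBD, TC_VBD_SNP
#>   settings:   trial, nhs

predict(m, "TC_VBD", "trial")
#> Expected per-woman cost: strategy TC_VBD, setting trial
#>   invitation               GBP     4.42
#>   questionnaire            GBP     0.73
#>   density                  GBP     1.15
#>   density_implementation   GBP     2.77
#>   risk_letter              GBP     6.44
#>   consultation             GBP     7.01
#>   total                    GBP    22.52
```

Adding breast density to the questionnaire strategy costs 22.52 GBP per
woman as delivered in the trial (published value 21.82; the residual is
per-item detail only published in aggregate). The implementation issues —
failed image transfers, manual density reads, van aerials — contribute the
2.77 GBP `density_implementation` stage and vanish in the `nhs` setting,
where the same strategy costs 5.98 GBP.

Genotyping batch economics: a 48th sample forces a second 1,343.77-GBP
chip, so the per-sample cost jumps until batches approach the two-chip
optimum of 95 samples + 1 control:

```r
per_sample_cost(c(47, 48, 95), paper_batch_schedule())
#>   batch_size chips_used batch_total per_sample_cost
#> 1         47          1    4557.426        96.96651
#> 2         48          2    6374.090       132.79355
#> 3         95          2    7659.932        80.63087
```

Parameter uncertainty, reproducibly seeded:

```r
specs <- read.csv(file.path(paper_fixture_path(), "distributions.csv"))
run_psa(m, "TC_VBD_SNP", "trial", specs, n_sims = 10000, seed = 1)
#> PSA (10000 simulations, seed 1): TC_VBD_SNP / trial
#>   mean GBP 102.92 (pseudo-CI 98.29 to 108.08)
```

A command-line wrapper with subcommands `evaluate`, `psa`, `dsa`,
`batch-curve`, `rollout` and `make-fixture` is installed at
`system.file("scripts", "stratcost", package = "stratcost")`.

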