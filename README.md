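# lampreysmr

Evaluation toolkit for **sterile-male-release (SMR)** suppression of invasive
sea lamprey (*Petromyzon marinus*) populations, built around the decade-long
field program in the Pigeon, Sturgeon and Maple Rivers of the Cheboygan River
watershed (Lake Huron). It is aimed at invasive-species control analysts who
need to (1) audit the adult-stage accounting of an SMR program and (2)
estimate how strongly releases depressed recruitment of age-1 larvae, with
honest uncertainty.

## What it computes

**Adult assessment.** Sterile males are fin-clipped and released; assessment
traps then yield, for each stream-year, M males released, R of them
recaptured, and C wild captures. The package chains:

- Lincoln–Petersen abundance from the sterile-male recapture rate,
  `N̂ = round(C·M/R)`;
- the realized overflooding ratio `r = R / m` with `m` the wild-male count
  (sexed when recorded, else `C·(1 − p_female)`);
- viable eggs before release, `N̂ · p_female · fecundity` (defaults 50% and
  51,000 eggs), and after release, `eggs_before / r` under the assumption
  that every egg could be fertilized by a different male (a
  `random-mating` convention dividing by `r + 1` is available);
- the implied percent reduction `100·(1 − 1/r)`.

**Recruitment effect.** Age-1 larval densities (assigned by length–month
bands, indexed as `round(density·1000)`) are modelled hierarchically:

    log(A_yr,s) = a_s + a'_yr,s − q_s · E_yr,s ,   a'_yr,s ~ Normal(0, σ_a)
    index_yr,s,l ~ NegBinomial(mean = A_yr,s, dispersion = θ)

where `E` is release effort (sterile males / 1000) in the spawning year
(survey year − 1) and `q_s` is instantaneous mortality per unit effort. The
posterior is sampled by an adaptive Metropolis-within-Gibbs sampler
(non-centered deviations, split-R-hat diagnostics) and effects are reported
as percent reduction in recruitment per 1000 males, `100·(1 − e^(−qE))`.

A seeded synthetic-data generator reproduces the whole stated world — adult
runs, equal-catchability trapping, random-mating egg viability, overdispersed
surveys — so every stage runs and is tested without any external data.

## Worked example

```r
library(lampreysmr)

seasons    <- read_trap_seasons(system.file("extdata", "table1_trap_seasons.csv",
                                            package = "lampreysmr"))
assessment <- assess_table(seasons)
subset(assessment, sterile_released > 0 & !ambiguous & !is.na(eggs_after))
#>      stream year abundance_wild ratio_sterile_to_wild_male eggs_before eggs_after egg_reduction_pct
#> 9    Pigeon 2021             90                          6     2295000     382500             83.33
#> 10   Pigeon 2022            110                         10     2805000     280500             90.00
#> 16 Sturgeon 2018              5                        514      127500        248             99.81
#> 17 Sturgeon 2019             33                         54      841500      15583             98.15
#> 20 Sturgeon 2022             60                         35     1530000      43714             97.14
#> 29    Maple 2021              5                         40      127500       3188             97.50
```

Reading: in Pigeon 2021 only ~275 sterile males were released against an
unusually large wild run (estimated 90 adults), so the realized ratio fell to
6:1 and "only" 83% of the 2.3 million deposited eggs were neutralized; in
Sturgeon 2018 a 514:1 ratio left an estimated 248 viable eggs of 127,500.
Across release years viable eggs fell 83–99%.

```r
cfg    <- simulation_config(seed = 7)      # 3 streams x 10 years, true q = 1.1
bundle <- generate_bundle(cfg)
dat    <- recruitment_data(bundle$larval_surveys, bundle$releases)
fit    <- fit_mcmc(dat, seed = 7)          # 4 chains x 5000, warmup 2000
fit
#> Recruitment-model posterior: 4 chains x 3000 kept draws ( 5000 iterations, warmup 2000 )
#> Split-R-hat: max 1.028 (a[Pigeon])
#>     stream E median lower95 upper95
#> 1    Maple 1   59.3    8.64    86.7
#> 2   Pigeon 1   72.1   23.43    90.6
#> 3 Sturgeon 1   50.4    5.33    82.9
```

The generating mortality `q = 1.1` corresponds to a 67% reduction per 1000
males released; the posterior medians (50–72%) straddle it and the wide 95%
credible intervals are the honest consequence of ten years of overdispersed,
year-to-year variable recruitment — matching the field program's experience
that effect sizes are real but imprecise.

## Command line

```sh
Rscript inst/scripts/smr assess   --trap trap_seasons.csv --out assessment.csv
Rscript inst/scripts/smr simulate --config sim.yaml --out data/ --seed 1
Rscript inst/scripts/smr fit      --surveys data/larval_surveys.csv \
    --releases data/releases.csv --chains 4 --iter 5000 --warmup 2000 \
    --seed 1 --out posterior/
Rscript inst/scripts/smr report   --assessment assessment.csv \
    --posterior posterior/summary.json --out report.md
```

Every run writes a `run_metadata.json` (version, seed, config hash) beside
its outputs.

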