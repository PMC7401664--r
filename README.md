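# warmbloodsim

Forward-in-time stochastic simulation of a German Warmblood riding-horse
breeding program, built to study how recording and selecting against
osteochondrosis dissecans (OCD) — osseous fragments in the fetlock and hock
joints — changes disease prevalence, riding-horse performance, estimation
accuracy and kinship over twenty years of breeding.

## Who this is for

Quantitative geneticists and breeding-program designers who want a tested,
reusable implementation of a realistic horse selection cascade: overlapping
generations with age-structured culling, foal shows, studbook registration,
mare performance tests, stallion licensing, 14-day and 50-day performance
tests, annual BLUP/single-step evaluation, and EBV-dependent stallion usage.

## The model in brief

* **Population**: anchored to the registered Hanoverian population — 15,658
  breeding mares, ≈540 breeding stallions, ≈9,500 foals/year; every cohort
  size scales with one factor for desk-scale studies.
* **Genome**: 50,000 biallelic SNPs on 31 autosomes (2,500 cM), Haldane
  recombination, founders in linkage equilibrium.
* **Traits**: 22 performance traits (per recording event), two binary OCD
  liability traits and height at withers, all driven by 2,500 shared
  additive pleiotropic QTL. Per trait, founder TBV variance equals
  `h² σ_P²`; binary traits follow a liability threshold model,
  `P(liability > t) = prevalence`.
* **Evaluation**: multi-trait animal model (Henderson's MME) with the
  Meuwissen–Luo pedigree inverse; binary traits on the 0/1 scale with
  Robertson-transformed components `h²_obs = h² z² / (K(1−K))`; single-step
  GBLUP with `H⁻¹ = A⁻¹ + blockdiag(0, G_b⁻¹ − A₂₂⁻¹)`,
  `G_b = 0.95·G + 0.05·A₂₂`, VanRaden `G = ZZ′/(2Σp(1−p))`.
* **Selection**: males on EBV indices (components scaled by the candidate
  cohort's EBV SD), mares on phenotypes; threshold selection against OCD at
  licensing or OCD EBVs in the index with the weight of one performance
  trait; the best selected stallion is used about 100× more often than the
  worst (`w_i = 100^{(s_i − s_min)/(s_max − s_min)}`).
* **Scenarios**: `Reference`, `ThreshSel1/2/FJ/HJ`, `IndexBVE1/2`,
  `IndexLicensing1/2`, and genomic variants `ReferenceG`, `IndexBVEG2`,
  `IndexLicensingG1/2`.

See `vignettes/breeding-program-methods.Rmd` for assumptions, parameter
defaults, numerical methods and limitations.

## Worked example

Simulate the strict threshold scenario (exclusion of licensing candidates
with OCD in fetlock *or* hock joints) at one tenth of the population scale:

```r
library(warmbloodsim)

cfg <- scenario_config("ThreshSel2", years = 20, replicates = 10,
                       scale = 0.1, seed = 1)
res <- run_scenario(cfg)

fj <- scenario_trend(res, "ocd_fj_prev")
round(100 * fj$change, 2)       # fitted 20-year change, percentage points
#> [1] -2.61
round(metric_at_year(res, "gain", 20), 2)  # founder genetic SDs
#> [1] 1.69
```

The first number is the trend-fitted 20-year change in fetlock-joint OCD
prevalence among unselected foals (negative = fewer affected foals; at this
scale a single replicate carries a drift SD of 3–4 percentage points, so
10-replicate means still move by ±1 point between seeds). The second is the
20-year gain of the equal-weighted six-trait 50-day performance index in
founder genetic standard deviations.

Lower-level building blocks are exported too:

```r
map  <- build_genetic_map(31, 50000, 2500)
fnd  <- generate_founders(1000, map, seed = 1)
ts   <- build_trait_set(map, fnd)
ped  <- pedigree(sire = c(0, 0, 1), dam = c(0, 0, 2))
a_inverse(ped)           # Henderson/Meuwissen-Luo sparse inverse
liability_threshold(0.1) # 1.2816 on the liability scale
```

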