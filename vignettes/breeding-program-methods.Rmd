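---
title: "Simulating selection against osteochondrosis in a Warmblood breeding program: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating selection against osteochondrosis in a Warmblood breeding program: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The simulated breeding program

`warmbloodsim` is a forward-in-time stochastic simulator of a German
Warmblood riding-horse breeding program with overlapping generations. The
population is anchored to the registered Hanoverian breeding population:
15,658 breeding mares, about 540 breeding stallions, and a yearly foal crop
of about 9,500. One simulated year runs the full selection cascade:

1. the foal crop is born from the previous year's matings and assessed at a
   foal show (type, exterior, movement);
2. three-year-old fillies are registered in the studbook (walk, trot,
   canter), about one third take the mare performance test (adding
   rideability and free jumping), and broodmare replacements are selected
   on a phenotype index;
3. two-year-old colts are preselected for stallion licensing on a foal-show
   EBV index (600 candidates); osteochondrosis status is recorded at
   licensing in all scenarios that use it, a threshold rule or a
   licensing-stage index is applied, and about 90 colts are licensed;
4. licensed stallions take the 14-day performance test the following year
   (80 pass and receive a one-year breeding assignment) and the 50-day test
   the year after (walk, trot, canter, rideability, free jumping, course
   jumping); about 45 join the breeding-stallion cohort, half selected on a
   dressage index and half on a jumping index;
5. breeding values are estimated annually; stallion usage follows the EBV
   index so that the best selected stallion is used about 100 times more
   often than the worst; each mated dam produces one foal;
6. breeding animals survive to the next year with an age-class probability
   (plateau survival 0.85 per year for mares from age 4, 0.92 for breeding
   stallions from age 3, hard maximum age 20).

The stallion plateau survival is calibrated so that an inflow of 45 new
breeding stallions per year sustains a pool of about 540, consistent with
the population anchor; mares turn over faster, with roughly 2,350
replacements per year.

All cohort sizes scale with a single `scale` factor so that desk-scale
studies (default 0.1) preserve selection proportions, progeny group sizes,
and the usage-weight distribution.

# Genome and trait architecture

Each animal carries a phased diploid genome of 50,000 biallelic SNPs on 31
autosomes spanning 2,500 cM. Founders are unrelated and in linkage
equilibrium with allele frequencies uniform on [0.05, 0.5]; meiosis follows
the Haldane model (Poisson crossovers with no interference, uniform
positions, independent chromosomes). In scenarios whose evaluation never
touches marker genotypes the stored genomes are restricted to the QTL
subset of loci while crossovers are still sampled along the full
chromosome lengths; the marginal gamete process at the QTL is exactly the
same, which keeps memory and runtime proportional to what the scenario
actually uses. Single-step scenarios always store the full marker panel.

Twenty-two performance traits (per recording event), two binary
osteochondrosis dissecans traits (bone fragments in fetlock joints, OCD-FJ,
and in hock joints, OCD-HJ), and height at withers share one set of 2,500
purely additive pleiotropic QTL. Per-locus effect vectors are multivariate
normal with the assembled genetic correlation matrix, so pleiotropy
generates all genetic correlations. Effects are rescaled so the founder
variance of true genomic values equals `h2 * sigma_P^2` per trait (unit
phenotypic variance on the liability scale for the binary traits), and
residual standard deviations are `sigma_P * sqrt(1 - h2)`.

Published correlations (the OCD/height block and the OCD-performance
correlations) are inserted verbatim; the OCD-performance values are applied
to the trait of the same name at every recording event, since the same
trait at different events is itself assumed to have a genetic correlation
of 0.85. Unknown performance-performance entries default to 0.40 within an
event and 0.34 across events; residual correlations default to 0.20 within
and 0 across events; OCD and height entries without an estimate default to
0. The matrix is projected to the nearest positive semi-definite
correlation matrix by eigenvalue clipping at 1e-6 and rescaling to unit
diagonal; the projection must not move a published entry by more than
0.02 (with the default configuration the assembled matrices are already
positive definite and the projection is the identity). These fill rules are
a single configuration block (`inst/extdata/trait_config.yaml`) and can be
overridden wholesale.

Binary OCD phenotypes arise from a liability threshold model: the liability
is the true genomic value plus a correlated normal residual; the threshold
is the standard normal quantile of the assumed baseline prevalence,
anchored at the founder TBV mean so the configured prevalence holds exactly
in founders. Baseline prevalences are not published for this population;
the defaults, 0.25 for fetlock and 0.10 for hock joints, are package
assumptions motivated by the reported 31.6% any-finding rate among auction
horses. All reported comparisons therefore use *changes* in prevalence,
which are insensitive to the assumed levels, not the levels themselves.
Height at withers (mean 166.5 cm, assumed phenotypic SD 2.0 cm) is
simulated but excluded from every selection index.

# Breeding value estimation

Males are selected on estimated breeding values, mares on phenotypes.
EBVs come from Henderson's mixed model equations with known variance
components, one overall mean per trait, and the pedigree relationship
inverse built by Henderson's rules with Meuwissen-Luo inbreeding
coefficients. Binary OCD records enter as 0/1 observations in a linear
animal model; their variance components are moved to the observed scale
with the Robertson transformation `h2_obs = h2_liab * z^2 / (K (1 - K))`,
which keeps the equations linear.

The evaluation is block-multivariate: the same trait name across recording
events forms one block (e.g. walk at studbook registration, mare test,
14-day and 50-day test, with genetic correlation 0.85 between events), and
the two OCD traits form a bivariate block. This partition carries the
dominant channel of information -- mass mare records informing young
stallion EBVs of the corresponding 50-day traits -- at a fraction of the
cost of one joint system over all 24 traits; correlations between different
trait names (0.3-0.4) are ignored by the evaluator but present in the
simulated data, a mild and realistic model misspecification. The solver
API accepts any partition, including a single block containing all traits.

The evaluation uses a pedigree of up to seven ancestral generations
behind the youngest candidate cohorts; since twenty reporting years plus
burn-in span only four to five generations at the simulated generation
intervals, this window retains the entire simulated pedigree, and
`truncate_pedigree()` is provided for deeper external pedigrees.

Numerically, each block is decorrelated with the Cholesky factor of its
genetic covariance, which turns the genetic penalty into the identity Kronecker-product
with the relationship inverse and gives univariate-like conditioning.
Two exact solution paths exist:

* **Pedigree scenarios.** Animals without offspring in the evaluated
  pedigree are absorbed by an exact Schur complement (record-less leaves
  cancel entirely; leaves with records leave a small coupling between
  their parents and a right-hand-side carry). The reduced system over
  breeding animals plus the trait means is factorized with a sparse
  supernodal Cholesky, and leaf EBVs are recovered by back-substitution.
  Each block is additionally restricted to the ancestor closure of its
  record holders; animals outside the closure receive exact recursive
  parent-average EBVs.
* **Single-step scenarios.** The relationship inverse is
  `H^-1 = A^-1 + blockdiag(0, Gb^-1 - A22^-1)` with
  `Gb = 0.95 G + 0.05 A22` (VanRaden G centred by founder allele
  frequencies; blending for invertibility; tau = omega = 1). The system is
  solved by conjugate gradients with symmetric Gauss-Seidel (SSOR)
  preconditioning in Eisenstat form, warm-started from the previous year,
  to a relative residual of 1e-8; the trait means are eliminated by a
  rank-m Schur correction inside the operator and recovered afterwards.
  Genotypes are assumed available for all stallions presented for
  licensing from the first reporting year on.

Both paths agree with a dense direct solve of the full equations to
numerical precision; this equivalence is part of the test suite. Traits
without any record keep a zero mean and obtain EBVs purely through the
covariance structure. The annual evaluation runs once per year before the
stallion selections; for the licensing-stage index scenarios the OCD block
alone is re-solved immediately after OCD recording at licensing, so the
candidates' own radiographs inform the licensing index in the same year.

# Selection scenarios

Thirteen scenarios are configured, differing only in how OCD enters
selection: a reference without any measure against OCD; four threshold
selections at licensing (exclusion if both joints, either joint, only the
fetlock, or only the hock joint is affected, applied to the recorded
radiographic status before the licensing index); index selection in which
the two OCD EBVs enter the breeding-stallion usage index with the weight of
one performance trait each (negative sign), with OCD recorded either for
licensing candidates only or additionally for a random 50% of the birth
cohort; the same plus an OCD-bearing index at the licensing stage itself;
and four genomic (single-step) variants. Every index scales each component
by the standard deviation of the EBVs in the current candidate cohort.

# Reported metrics

Per reporting year, on the complete unselected foal crop: OCD prevalences
(the fraction whose underlying liability exceeds the threshold, evaluated
for every foal regardless of recording so reference trajectories exist);
the equal-weighted six-trait 50-day performance index of true genomic
values, standardized by the founder genetic SD and referenced to the
year-0 cohort; mean kinship (including self-kinship, derived exactly from
the tracked parent kinship matrix); mean height; and, where OCD is
evaluated, the correlation between OCD EBVs and true genomic values in the
active breeding-stallion cohort (the accuracy, averaged over the final
five reporting years). Reported 20-year changes are the slope of an
ordinary least-squares regression of across-replicate yearly means on
year, times twenty, with 95% confidence intervals from the t-distribution.
Gains are reported on true genomic values rather than EBVs so that
comparisons across evaluation modes use a common yardstick; an EBV-based
variant can be computed from the exported EBV tables.

# Burn-in and baseline

Each replicate starts from an age-structured founder population (herd and
stallion pool at their stationary age distributions, young cohorts filling
the pipeline) and runs eight burn-in years under the reference scheme
before year 0. During the first burn-in years male selection uses
phenotype indices; the annual BLUP evaluation starts two years before
reporting, so all reported years select on warmed-up EBVs. Scenario
treatments (OCD recording, threshold rules, OCD indices, genotyping)
activate after year 0; burn-in is therefore identical across scenarios and
replicate r of every scenario uses seed `master + r`, making scenario
contrasts paired comparisons under common random numbers.

# Problem sizes, runtimes and replication

The package's scenario battery runs at cohort scale 0.1 (1,566 mares, a
950-foal crop, 60 licensing candidates, about 54 breeding stallions) for
20 reporting years after burn-in. At this scale one pedigree-BVE replicate
simulates about 30,000 animals and takes on the order of ten seconds; a
single-step replicate stores the full 50k marker panel for all animals and
genotypes about 1,200 candidates, and costs roughly a minute. The seven
scenarios that carry quantitative prevalence and accuracy checks run with
10 replicates; the licensing-index and genomic scenarios, which enter the
battery summary only through the across-scenario bound on performance gain
and directional comparisons, run with 3 and 1 replicates respectively.
This keeps the complete battery within a desktop time budget while leaving
the quantitative checks at full replication; all replicate counts are
arguments of `run_acceptance_battery()`.

# What the generator does and does not emulate

The simulation reproduces the structure that drives selection response:
overlapping generations with realistic age distributions, the multi-stage
male selection cascade with its very high cumulative intensity, mass mare
recording feeding the animal-model evaluation, pleiotropy-generated
genetic correlations, and usage-weighted sire contributions. It does not
emulate historical linkage disequilibrium (founders are in linkage
equilibrium, so absolute single-step accuracies at a given panel density
should be read as optimistic), mutation, dominance or epistasis,
genotype-by-environment interaction, pedigree errors, or clinical
recording error beyond the residual term. Scaled-down populations drift
faster than the full population (the kinship trajectories are
correspondingly steeper), and the emergent maximum stallion usage is
larger relative to the crop; prevalence *changes* and scenario contrasts
are robust to this, absolute inbreeding levels are not.

# Degenerate inputs and tie-breaking

Selection ties are broken towards the lower animal id, so replicates are
bit-reproducible under fixed seeds. Zero-variance residuals draw exact
zeros; index scaling falls back to unit SDs when a candidate cohort has no
EBV spread; traits with no records anywhere are frozen at a zero mean;
empty genotyped sets reduce the single-step path exactly to pedigree BLUP.
The positive semi-definite projection of user-edited correlation matrices
fails loudly if it would move a published entry by more than 0.02.
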