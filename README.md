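# rloopkmc

Sequence-dependent kinetics of CRISPR-Cas9 R-loop formation.

When Cas9 interrogates a DNA site next to a PAM, its guide RNA invades the
protospacer duplex base pair by base pair, displacing one DNA strand as an
R-loop. `rloopkmc` models that invasion as a continuous-time, discrete-state
birth–death walk of the R-loop length *m* ∈ {0, …, N} in a nearest-neighbour
free-energy landscape, simulated exactly with a Gillespie algorithm, and
builds from it the stability observables that explain guide-RNA specificity:
equilibrium occupancy profiles, threshold occupancies, re-annealing
lifetimes, fall-off probabilities and mismatch re-trapping counts. A
permutation-tested correlation pipeline links simulated R-loop stability at
PAM-distal positions to experimental cleavage frequencies at single-mismatch
off-target sites, and a separate set of estimators handles single-molecule
(AFM-style) binding statistics: 1/k-weighted binding histograms, empirical
Gaussian peak fits, and apparent dissociation/association constants. Seeded
synthetic-data generators produce every input with known ground truth.

It is written for quantitative CRISPR researchers and single-molecule
biophysicists who want a reproducible, tested reference implementation of
this class of model.

## The model

Each position *m* (counted 1…N from the PAM) carries an exchange free energy

ΔΔG(m) = ΔG°(m)₍RNA:DNA₎ − ΔG°(m)₍DNA:DNA₎,

the nearest-neighbour stack attributed to extending the hybrid to *m* minus
the duplex stack it replaces (doublet spanning *m−1, m*; position 1 carries
no stack). Transition rates are

- v_f(m) = k₀ · exp(−ΔΔG(m+1) / 2RT)  for m → m+1,
- v_r(m) = k₀ · exp(+ΔΔG(m) / 2RT)  for m → m−1,

with the ½ split chosen so that v_f(m)/v_r(m+1) = exp(−ΔΔG(m+1)/RT), i.e.
detailed balance with the Boltzmann stationary law π(m) ∝ exp(−G(m)/RT),
G(m) = Σ_{j≤m} ΔΔG(j). Watson–Crick ΔG°₃₇ tables (unified DNA:DNA and
Sugimoto RNA:DNA hybrid parameters, 1 M NaCl, 37 °C) ship as JSON under
`inst/extdata/`; the four hybrid mismatch classes rG·dG, rC·dC, rA·dA and
rU·dT are scored with a synthetic per-type stack-offset table (see the
vignette for the calibration and its limits). Whole-duplex binding energies
add a −3.1 kcal/mol initiation term.

Binding statistics follow the single-molecule occupancy method: with Θ the
fraction of DNA molecules carrying protein and n̄ the mean proteins per
molecule at incubation concentrations [P]₀ and [DNA]₀,

K_d = (1 − Θ)([P]₀ − n̄[DNA]₀)/Θ,  K_a,site = Θ_site / ((1 − Θ_site)[P]free),

and histogram peaks are fit to the empirical Gaussian A·exp(−((x−μ)/w)²)
with w = √2·σ.

## Worked example

```r
library(rloopkmc)

sg  <- aavs1_pair("sgRNA")     # canonical AAVS1 target, 20-nt guide
tru <- aavs1_pair("tru-gRNA")  # same target, guide truncated 2 nt at the 5' end

sys <- rloop_system(sg)
st  <- stability_metric(sg, m_star = 19, reps = 100, m0 = 20,
                        max_t = 10000, seed = 1)
st
#> mean fraction of time m >= 19: 0.9552 (SEM 0.0007, 100 replicates)

lt_sg  <- lifetime_to_below(sys, start_m = 20, m_star = 16,
                            reps = 2000, max_t = 1e5, seed = 2)
lt_tru <- lifetime_to_below(rloop_system(tru), start_m = 18, m_star = 16,
                            reps = 2000, max_t = 1e5, seed = 3)
lt_sg$mean / lt_tru$mean
#> [1] 31.57676
```

The first number says the matched 20-nt guide stays invaded up to the 19th
protospacer position ~95% of the simulated time at equilibrium. The second
says truncating two PAM-distal nucleotides collapses the mean lifetime from
full invasion to re-annealing below position 16 by more than an order of
magnitude — the kinetic signature that makes truncated guides both more
specific and less stably activating.

The off-target pipeline runs on TSV tables of guide/target pairs with
cleavage frequencies (`read_pairs_tsv()` loads published datasets, which are
not redistributed here; `synth_cleavage_dataset()` generates synthetic ones
with known ground truth):

```r
ds  <- synth_cleavage_dataset(generator_spec(seed = 5, n_pairs = 60))
fit <- specificity_analysis(ds$records, reps = 1000, n_perm = 100000, seed = 7)
fit
#> Specificity analysis: 60 records after filtering
#>   rejections: multiple_or_no_mismatch=0, pam_proximal=0, unparameterized_type=0
#>   KMC: m0 = 10, m_star = 16, reps = 1000, max_t = 100
#>   pearson correlation r = 0.9045, permutation p = 1e-05 (n = 60, 100000 permutations)
```

A thin command-line wrapper over the same functions lives at
`inst/scripts/rloopkmc-cli.R` (subcommands `simulate`, `profile`,
`specificity`, `fit-binding`, `synth`).

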