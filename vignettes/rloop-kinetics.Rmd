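---
title: "Modelling R-loop strand-invasion kinetics and Cas9 specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling R-loop strand-invasion kinetics and Cas9 specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rloopkmc)
```

## The model and its assumptions

Cas9 specificity is set not only by how strongly a guide RNA can bind a DNA
site but by how the R-loop — the hybrid formed as the guide displaces one
strand of the protospacer duplex — forms and fluctuates. `rloopkmc` reduces
that process to a single dynamical variable: the R-loop length $m \in \{0,
\dots, N\}$, the number of PAM-proximal protospacer positions currently
paired with the guide. Strand invasion is a nucleotide-by-nucleotide
competition between forming one RNA:DNA base pair (breaking the
corresponding DNA:DNA pair) and the reverse, so $m$ performs a
continuous-time birth–death walk with sequence-dependent rates

$$v_f(m) = k_0\, e^{-\Delta\Delta G(m+1)/2RT}, \qquad
  v_r(m) = k_0\, e^{+\Delta\Delta G(m)/2RT},$$

where $\Delta\Delta G(m)$ is the RNA:DNA minus DNA:DNA nearest-neighbour
stack free energy attributed to position $m$. The symmetric $1/2$ split
makes the rate ratio $v_f(m)/v_r(m+1) = e^{-\Delta\Delta G(m+1)/RT}$, so the
walk satisfies detailed balance and its stationary law is Boltzmann in the
cumulative landscape $G(m) = \sum_{j \le m}\Delta\Delta G(j)$. Trajectories
are drawn exactly (no time discretization) with a Gillespie algorithm,
implemented in compiled code against R's RNG so every run is reproducible
from a seed.

Assumptions worth keeping in mind: $m$ is the only degree of freedom — PAM
search, 3-D diffusion, supercoiling and protein conformational states are
not modelled; rates derive from equilibrium stack energies to first order,
so all times are in arbitrary units of $1/k_0$; and the landscape is strictly
local (one stack per step).

### Energy attribution

Nearest-neighbour tables score doublets, not positions, and the mapping to
single positions is a modelling choice. We assign the stack spanning
positions $m-1, m$ to position $m$; position 1 carries no stack, and the
duplex initiation term is handled separately. This makes the telescoping
identity exact — the sum of $\Delta\Delta G(m)$ over the footprint equals the
hybrid total minus the duplex total — and gives the walk a well-defined state
energy, which the test suite exploits as an oracle (simulated occupancy must
converge to the closed-form Boltzmann law).

### Parameter provenance and the mismatch table

Watson–Crick $\Delta G^\circ_{37}$ doublet tables (unified DNA:DNA;
RNA:DNA hybrid, both at 1 M NaCl, 37 °C) are transcribed into
`inst/extdata/nn_dg37.json` and treated as data — swap the file to use a
different parameter set. Two caveats are deliberate:

- **Initiation sign.** The whole-duplex hybrid binding energy adds a
  $-3.1$ kcal/mol initiation term. The published hybrid initiation term has
  the opposite sign ($+3.1$, a penalty); we keep the negative value used by
  the strand-invasion model this package implements, expose it as
  configuration, and note the discrepancy here. It shifts every pair's
  binding energy by a constant, so it never affects rates, occupancies or
  correlations — only the absolute $\Delta G^\circ_{37}$ scale.
- **Mismatch stacks are synthetic.** Context-resolved nearest-neighbour
  parameters for hybrid stacks containing rG·dG, rC·dC, rA·dA or rU·dT
  mismatches were not available to transcribe. The shipped
  `mismatch_offsets_synthetic.json` instead scores a mismatch-containing
  stack as the Watson–Crick hybrid stack of the guide doublet plus a
  per-type destabilization offset (rG·dG +0.45, rU·dT +0.70, rA·dA +0.90,
  rC·dC +1.05 kcal/mol, applied to each flanking stack). The offsets were
  calibrated once so that a single internal mismatch destabilizes a 20-mer
  hybrid by roughly 1.5 kcal/mol on average (a few percent of its binding
  energy, the scale reported for these mismatch types), with the commonly
  observed tolerance ordering. Quantitative per-context mismatch energetics
  are therefore approximate; replace the file with measured parameters for
  serious mismatch thermodynamics. Mismatches outside the four classes are
  annotated as `other` and refuse to be scored rather than silently
  defaulting to zero.

Note that injecting an rX·dX mismatch also changes the genomic duplex: the
stored guide-matching strand letter becomes the complement of the new
target-strand base, so both the hybrid and the DNA:DNA reference stacks move.

### Boundaries

Reaching $m = 0$ means the guide has fully re-annealed out of the
protospacer. Both an absorbing boundary (dissociation; the default, with
post-absorption time counted at $m = 0$ so time fractions stay normalized
over the window) and a reflecting boundary are provided, because stable
equilibrium "breathing" and fall-off statistics are both of interest and the
right choice depends on the question. At $m = N$ the chain simply has no
forward move. For well-matched guides the absorbing and reflecting
equilibrium answers coincide to within Monte-Carlo error, because the
landscape makes absorption astronomically rare on simulation timescales.

## Key settings and defaults

| Setting | Default | Meaning |
|---|---|---|
| `k0` | 1 | rate prefactor; sets the (arbitrary) time unit |
| `m0` | 20/18 (equilibrium), 10 (invasion) | initial R-loop length |
| `max_t` | 10000 (equilibrium), 100 (invasion) | censoring horizon |
| `reps` | 1000 | replicate trajectories per stability metric |
| `m_star` | 16 | threshold position for stability metrics |
| `n_perm` | 100000 | permutations for the correlation p-value |
| `distal_cutoff` | 10 | minimum mismatch position kept by the filter |
| `dg_init` | −3.1 kcal/mol | duplex initiation term |
| `T` | 310.15 K | temperature (37 °C) |

Equilibrium stability runs start from full invasion with a long horizon;
invasion runs start from $m_0 = 10$ — mid-invasion, past the PAM-proximal
seed — with a short horizon, which is what makes them sensitive to the
kinetics of traversing a PAM-distal mismatch rather than to equilibrium
binding. The PAM-distal filter keeps mismatches at positions ≥ 10 even
though $m_0 = 10$ pre-invades position 10; a mismatch at 10 then mostly
affects re-annealing below the threshold, which is intended.

## Observables

- `occupancy_profile()` — time-weighted fraction of the window spent at each
  $m$, averaged over replicates (sums to 1).
- `threshold_occupancy()` / `stability_metric()` — mean fraction of time
  $m \ge m^\*$, with SEM across replicates (replicates are i.i.d.; no
  within-trajectory variance estimate is attempted).
- `lifetime_to_below()` — first-passage time from full invasion to
  $m < m^\*$; censored replicates are reported separately and excluded from
  the mean rather than imputed.
- `falloff_probability()` — probability of absorption at $m = 0$ before a
  stop event (full invasion, or traversing a mismatch), with an exact
  binomial CI; replicates censored before either event are excluded from the
  point estimate and counted.
- `retrap_count()` — excursions back behind a mismatch after first passing
  it, the signature of volatile truncated-guide R-loops.

## The specificity pipeline

`specificity_analysis()` filters records to isolated, PAM-distal,
single-mismatch pairs of the four parameterized classes, computes each
record's stability metric under a seed derived from (master seed, record
index) — so adding records never changes existing metrics — and correlates
stability with cleavage frequency. Pearson correlation is the default
(Spearman is a flag), and significance comes from a pairing-permutation
test: $p = (1 + \#\{|r_{perm}| \ge |r_{obs}|\})/(1 + n_{perm})$, add-one
smoothed so $p$ can never be zero; an exact enumeration mode over all $n!$
pairings exists for small $n$ and is used as a test oracle. Raw frequencies
are used by default, with a `transform` hook for callers who prefer, e.g.,
log frequencies.

## Binding statistics

Footprint tables map each bound protein onto the bp it overlaps; a protein
appearing to contact $k$ sites contributes weight $1/k$ to each, so its
total weight is 1. Peaks are fit to the empirical Gaussian
$A e^{-((x-\mu)/w)^2}$ ($w = \sqrt{2}\sigma$; the amplitude is a nuisance
parameter), optionally with a constant baseline term for windows that carry
appreciable uniform background. Two confidence-interval routes are provided
deliberately:

- a heteroscedasticity-consistent (sandwich) covariance, appropriate when
  histogram bins are independent counts;
- a protein-resampling bootstrap (pass the event table and `n_boot`),
  appropriate for real binding histograms, where every protein paints a
  whole footprint of adjacent bp and per-bin errors are therefore strongly
  correlated — per-bin formulas understate the uncertainty many-fold there.

`overall_kd()` implements the occupancy estimator
$K_d = (1-\Theta)([P]_0 - \bar n[\mathrm{DNA}]_0)/\Theta$ verbatim; the same
routine serves site-restricted $K_d$ when the caller supplies an occupancy
restricted to one peak width ($|x-\mu| \le w$) of a site, and
`site_affinity()` returns $K_a = K_d^{-1}$ from per-site occupancies. The
free-protein term uses total bound protein regardless of where it is bound,
as the printed formula does.

## The synthetic-data generators

`generator_spec()` fixes the emulated study conditions once:

- **Cleavage datasets** (`synth_cleavage_dataset()`): 60 random 20-nt
  guide/target pairs at balanced GC, each with one isolated PAM-distal
  mismatch (position 10–20, type dictated by the guide base), ground-truth
  stability computed by the generator's own seeded KMC (300 replicates), and
  observed frequency = logistic(−2 + 6·stability) plus Gaussian noise
  (sd 0.1) truncated at zero. Truncation, not censoring, is used, which
  slightly biases the null upward near zero — documented because type-I
  calibration tests ride on it (the permutation test is exchangeable under a
  zero-slope link regardless, so uniform p-values survive the truncation).
- **Binding datasets** (`synth_binding_dataset()`): a 989-bp substrate with
  one specific site at bp 151.3 of association constant $1/44.67$ nM$^{-1}$,
  footprints of 78 bp, apparent peak sd `sigma_bp = 36.4` (all three within
  the ranges single-molecule imaging reports for this system), occupancies
  drawn from the single-site isotherm with self-consistent free-protein
  depletion, plus Poisson uniform background. Because each footprint smears
  its weight over 78 bp, drawing centers with sd 36.4 would produce a peak
  visibly wider than intended; the generator instead solves numerically for
  the center noise that makes the fitted empirical-Gaussian width of the
  noiseless profile exactly $\sqrt{2}\,\sigma$. `sigma_bp` therefore
  parameterizes the *apparent fitted* peak width — the quantity such
  histograms actually report.

Ground truth is always written separately from observations so pipeline
inputs can never leak it.

What the generators do *not* emulate: real datasets have shared guide
backbones (records are not independent), position- and context-dependent
mismatch penetrance beyond the four parameterized classes, non-Gaussian
footprint localization errors, and cleavage-frequency error structure far
from additive Gaussian. Passing tests on synthetic data therefore validate
the machinery and its statistical calibration, not the biological accuracy
of the energy tables.

## Numerical choices

- Exponentials in the rate law are overflow-guarded; a position whose
  scaled energy exceeds the representable range raises an error naming it.
- A state with zero total rate freezes legally until the horizon (it is not
  an error), which is what makes `k0 = 0` a useful degenerate test case.
- Exact exponential waiting times; no tie-breaking is needed because state
  changes are ±1 and the two rates are compared against one uniform draw.
- Per-replicate and per-record seeds derive from the master seed via a
  multiplicative-congruential map (`derive_seed()`), keeping all derived
  seeds below $2^{31}$ and streams non-overlapping by construction.
- The Gaussian peak fit runs Levenberg–Marquardt from moment-based starting
  values with bounded parameters; a window with fewer than five occupied
  bins, or flat mass, refuses to fit.

## Simulation sizes used in the shipped studies

The packaged tests and the acceptance script run the power study at 100
generator seeds (60 pairs each, 200 KMC replicates per pair, 999
permutations), the null calibration at 300 generator draws, Boltzmann-oracle
comparisons at 30 × 20000 time units on 8-state chains, and lifetime
comparisons at 3000 replicates per guide. These sizes were chosen to keep
Monte-Carlo standard errors comfortably inside the assertion margins while
remaining quick on a single CPU; all are parameters, and users reproducing
individual figures can scale them up freely.

## Known limitations

- Mismatch energetics are a calibrated synthetic stand-in (above); absolute
  mismatch-specific predictions should not be over-interpreted.
- Time is in arbitrary units; nothing maps $1/k_0$ to seconds.
- Only single-position mismatch annotation is parameterized; multi-mismatch
  energetics are out of scope and such records are filtered out.
- The published single-mismatch cleavage dataset this pipeline was designed
  around is not redistributed; `read_pairs_tsv()` loads it if you obtain it,
  and the synthetic generator stands in for it everywhere else.
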