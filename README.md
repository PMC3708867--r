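# allelopop

Stochastic population-balance simulation of allelically regulated gene
expression in proliferating stem cell populations.

## The problem

NANOG, a core pluripotency factor, is expressed in mouse embryonic stem
cells (mESCs) under *allelic* control: each of the two gene copies switches
between a transcriptionally active and an inactive state independently, so
a culture contains four subpopulations — biallelic (type 1), monoallelic
(types 2 and 3) and silent (type 4) cells. `allelopop` implements a
multiscale model of this system for anyone studying how allelic switching,
asynchronous proliferation and random partitioning at mitosis shape the
protein heterogeneity seen in flow cytometry, and how faithfully knock-in
reporter lines (e.g. GFP in one *Nanog* locus) track the native protein.

## The model

Three coupled layers:

1. **Allelic switching chain.** A four-state continuous-time Markov chain
   built by detailed balance from observable quantities: the equilibrium
   composition `Z* = (0.14, 0.28, 0.28, 0.30)` and the fractions of the
   population shuttling between linked states per cell cycle (12% per
   linked pair by default; states 1 and 4 are not linked directly).
   Per-cycle probabilities are `p_ij = (w_ij / 2) / z_i`, rates
   `k_ij = p_ij / T_d` with doubling time `T_d = 10 h`, and every state
   proliferates at `λ = ln 2 / T_d`. Composition evolves as `dZ/dt = Z K`
   with stationary law `Z*`.

2. **Single-cell expression.** Each allele produces protein with
   zeroth-order kinetics — `s_on = 1000` molecules/h when active,
   `s_off = 10` (1% leak) when silent — against first-order degradation
   (`t_1/2 = 2 h` for the native protein, 20 h for a GFP-like reporter):
   `dN_j/dt = s_j − γ N_j`, solved in closed form, or as an SDE with
   multiplicative noise `η N dW` integrated by Euler–Maruyama.

3. **Population balance / kinetic Monte Carlo.** One population balance
   equation per subpopulation over the state vector `(N_1, N_2, v)` (the
   two allele-attributed protein pools and cell size) is solved by an
   event-driven Monte Carlo: exponential waiting times over the summed
   switching and division propensities; size grows as
   `dv/dt = (ln 2 / T_d) v`; division intensity is the Gaussian
   division-size hazard `Γ(v) = r_v(v) φ(v) / (1 − Φ(v))` with
   `μ = 0.465`, `σ = 0.104`; at mitosis every state component is split by
   independent symmetric `Beta(q, q)` fractions (`q = 39`). The sample
   grows freely to a cap (constant-volume phase), after which each
   division's daughters replace the mother and a random cell
   (constant-number phase).

Scenario drivers reproduce the in-silico experiments: reconstitution of
the equilibrium mixture from any uniform starting pattern, tri-/bimodal
protein distributions, reporter fidelity under single/double-allele
insertion and half-life mismatch, transcriptional shutoff, and
single-allele deletion (*Nanog*⁺/⁻).

## Worked example

```r
library(allelopop)

rate_matrices(transition_spec())
#> Allelic switching chain (t_d = 10 h)
#> Per-cycle transition probabilities:
#>        1      2      3      4
#> 1 0.1429 0.4286 0.4286 0.0000
#> 2 0.2143 0.5714 0.0000 0.2143
#> 3 0.2143 0.0000 0.5714 0.2143
#> 4 0.0000 0.2000 0.2000 0.6000
#> ...

sim <- simulate_population(n_initial = 400, n_cap = 2000, t_end = 150,
                           seed = 1)
summary(sim)
#> Population at t = 150.0 h: 2000 cells
#>   composition (types 1-4): 0.144 0.295 0.260 0.301
#>   mean total protein: 2026 molecules (CV 0.76)
#>   fraction above positivity threshold: 0.734
```

The composition sits at the stationary mixture, the total-protein CV of
0.76 reflects the three expression regimes plus division noise, and 73% of
cells clear the 500-molecule positivity gate. A GFP-like reporter knocked
into one allele tracks the native protein only loosely:

```r
run_reporter_study("one", reporter_half_life = 20, seed = 1)
#> Scenario: reporter_one_t12_20
#>   rho                    0.5792
#>   cv_nanog               0.6964
#>   cv_reporter            1.008
#>   ...
```

i.e. a Pearson correlation of about 0.58 between reporter and native
totals, with the reporter distribution markedly noisier (CV ≈ 1.0 vs 0.70)
— both alleles plus a matched half-life are needed for ρ ≈ 1.

A command-line front end over the same drivers lives in
`inst/scripts/allelopop.R` (`run`, `sweep`, `stats` verbs).

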