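---
title: "Modelling allelically regulated expression in proliferating stem cell populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling allelically regulated expression in proliferating stem cell populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelopop)
```

`allelopop` simulates a gene whose two chromosomal copies switch
independently between transcriptionally active and silent states inside a
proliferating cell population, with NANOG in mouse embryonic stem cells as
the model system. This vignette explains the model, the choices behind its
defaults, what the simulations do and do not demonstrate, and the
numerical details a user changing parameters should know.

## The allelic switching chain

Four subpopulations are defined by the on/off pattern of the two alleles:
type 1 (on/on), types 2 and 3 (the two monoallelic patterns) and type 4
(off/off). The chain is *constructed from observables* rather than from
microscopic rates: given the equilibrium composition
$Z^* = (0.14, 0.28, 0.28, 0.30)$ and the fraction $w_{ij}$ of the total
population that shuttles between states $i$ and $j$ per cell cycle, the
switching counts in the two directions are taken equal — the detailed
balance condition — which fixes the per-cycle transition probabilities

$$p_{ij} = \frac{w_{ij}/2}{z_i^*}, \qquad
  p_{ii} = 1 - \sum_{j \ne i} p_{ij}.$$

Rates follow as $k_{ij} = p_{ij}/T_d$ because the shuttle data refer to
one doubling time ($T_d = 10$ h); this first-order approximation (rather
than a matrix-logarithm embedding) is the standard treatment when the
observation unit equals the cell cycle. Every subpopulation proliferates
at the same $\lambda = \ln 2 / T_d$, so composition dynamics reduce to
$dZ/dt = Z K$; the stationary solution of the constructed chain is $Z^*$
by detailed balance, which `stationary_composition()` recovers from the
null space of $K^\top$ (inputs whose null space has dimension > 1 —
disconnected chains — are rejected rather than resolved by a tie-break).

Only the 1–2 pair's shuttle fraction (12%) is known from text; the 1–3
pair takes the same value because no allelic bias exists, and the 2–4 and
3–4 pairs mirror each other for the same reason. Direct 1–4 switching is
excluded (it would require both alleles to flip simultaneously), and the
same argument sets the default 2–3 fraction to zero. All of these are
config-overridable (`transition_spec()`, YAML key `shuttle`).

## Single-cell expression

Each allele $j$ produces protein by zeroth-order kinetics at
$s_\text{on} = 1000$ molecules/h when active and at a 1% leak
($s_\text{off} = 10$) when silent, against first-order degradation:
$dN_j/dt = s_j - \gamma N_j$ with $\gamma = \ln 2 / t_{1/2}$,
$t_{1/2} = 2$ h. The closed-form solution is used everywhere noise is off,
so propagation carries no integration error and composes exactly across
subintervals. The implied steady states are 5771 (biallelic), 2914
(monoallelic) and 58 (silent) molecules — the silent state two orders of
magnitude below the expressing ones, and the expressing-cell average at
the observed 1:4 biallelic:monoallelic ratio about 3500 molecules.

With transcriptional noise the same dynamics become an SDE whose noise
amplitude is linear in the protein level, $\eta N\,dW$, integrated by
Euler–Maruyama with reflection at zero (molecule counts cannot be
negative; clipping is the simplest contract-preserving boundary). The
alternative reading — noise proportional to the production term — is
available via `noise_model = "production"`. The default step
$dt = 0.01$ h sits far below both the protein half-life (2 h) and the
cell cycle (10 h); in the population engine the effective step is usually
the inter-event interval, which is shorter still. Protein amounts are
continuous throughout: the model is an ODE/SDE description, not a
chemical master equation, which is appropriate at thousands of molecules
per cell.

A knock-in reporter shares the allele's on/off state and production
constants but degrades at its own rate ($t_{1/2} = 20$ h for GFP). The
knock-in does not abolish native production from the targeted allele —
the co-expression reading is required for the NANOG-high/GFP-low
subpopulation that single-allele reporter simulations produce.

## The population engine

One population balance equation per subpopulation governs the number
density over $(N_1, N_2, v)$; the package solves the system by the
kinetic Monte Carlo scheme standard for such models:

* an *interval of quiescence* is drawn from an exponential law with the
  summed propensity of all switching and division channels, the
  propensities being frozen over the interval and refreshed after every
  event (the usual first-order KMC approximation);
* the triggering cell and channel are found by inverse-CDF lookup over
  the per-cell event-rate matrix (rows: the three switch channels out of
  the cell's state plus its division propensity);
* between events, sizes grow exponentially ($dv/dt = \lambda v$) and
  protein pools follow the closed form (updated lazily, only when a cell
  is touched) or, with noise, an Euler–Maruyama sweep over all cells;
* a division splits $N_1, N_2, R_1, R_2, v$ by five independent
  symmetric $\mathrm{Beta}(q, q)$ fractions ($q = 39$, partition-fraction
  SD $0.5/\sqrt{2q+1} \approx 0.056$), conserving each component exactly;
  both daughters inherit the allelic pattern;
* below the population cap both daughters are kept (constant-volume
  phase); at the cap one daughter replaces the mother and the other
  overwrites a uniformly chosen other cell (constant-number phase), the
  standard scheme for representing an exponentially growing culture at a
  fixed sample size.

The inner loop is compiled (Rcpp) and draws all randomness from R's RNG,
so a run is bit-reproducible from `set.seed()`. A single seed drives one
global stream; per-purpose sub-streams were considered and dropped as R
has one global generator and no contract here requires stream isolation.

### Division: two rate laws

The event-matrix description of the algorithm uses the constant rate
$\lambda = \ln 2 / T_d$ per cell, while the population balance equation
itself contains a size-dependent dividing rate. Both are implemented
(`division_mode`). The default `size_hazard` mode derives the intensity
from the observation that division sizes are Gaussian
($\mu = 0.465$, $\sigma = 0.104$):

$$\Gamma(v) = r_v(v)\,\frac{\varphi(v)}{1 - \Phi(v)},
  \qquad r_v(v) = \frac{\ln 2}{T_d}\,v,$$

the classical hazard construction (division-size density over its
survival function, times the speed at which a cell moves through size).
Emergent birth-to-division intervals then average $T_d$ without further
calibration. In the compiled loop $\Gamma$ is evaluated from a dense
4096-node lookup table with linear interpolation; where the survival
function underflows the hazard is capped at 50/h so that waiting times
stay finite for abnormally large cells — at the cap a cell divides within
minutes, so the bulk dynamics are unaffected. The exported R
`division_hazard()` computes the exact closed form.

### Initial conditions and burn-in

The initial population is newborn-like: division sizes are sampled from
the Gaussian law and beta-split; protein pools start at the deterministic
steady state of each cell's assigned pattern (reporter pools likewise).
Statistics are read from late snapshots; runs allow at least 50 h —
several protein half-lives, reporter relaxation times and switching
times — before any equilibrium quantity is measured.

## Scenario design choices

**Reporter studies** compute the Pearson correlation between per-cell
reporter and native totals on one equilibrium snapshot of the raw
(unlogged) levels; the near-perfect correlation of the matched
both-allele design only holds on the raw scale, which fixes the
convention.

**Transcriptional shutoff** (a gene *without* allelic regulation; all
cells biallelic, switching disabled, single-allele reporter) drops all
production to the leak value at $t = 0$ and, by default, arrests
division at the same moment — the experimental situation mimicked is a
transcriptional-inhibitor treatment, under which cells stop cycling.
This choice matters: with divisions arrested, each cell's levels remain
affine functions of its pre-shutoff levels, so the reporter–native
correlation (≈ 0.82) is preserved over the 20 h follow-up even as the
native mean collapses ~75× faster than the reporter's; with divisions
continuing, fresh partitioning noise erases the native protein's memory
within a few half-lives and the correlation decays (≈ 0.5 at 20 h).
Only the arrested variant reproduces both the sustained correlation and
the reporter's clean one-half-life decay; `arrest_division = FALSE`
gives the other behaviour.

**Single-allele deletion** keeps the *full* four-state chain: chromatin
at the deleted locus still switches (the switching kinetics belong to
the locus, not the coding sequence), but production from allele 1 is
pinned at the leak value throughout. The expressing fraction is then the
type 1+3 share (42%) plus cells that recently switched off and still
hold protein, giving ≈ 45% above the 500-molecule gate, CV ≈ 1.1 and a
mean about half the wild-type value. The alternative — restricting the
chain to states 3 and 4 — was implemented and rejected: its stationary
expressing share is $z_3/(z_3+z_4) = 0.483$ *for any* shuttle values,
which overshoots the observed knockout positive fraction and
under-disperses the distribution.

**Positivity gate.** Cells are scored positive above 500 molecules, a
line between the silent and monoallelic peaks mimicking an isotype
control; shifting it across 300–800 moves the positive fraction by only
a few percentage points (tested).

**Mode counting.** "How many peaks" is made reproducible as: histogram
of $\log_{10}(N + 1)$, 60 equal bins, 3-bin moving average, then local
maxima kept if their topographic prominence exceeds 5% of the modal bin
height. The two-dimensional analogue (for the $N_1$–$N_2$ pattern map)
uses a 20 × 20 binning, 3 × 3 box smoothing and 0-dimensional
persistence (union-find over bins in decreasing height): a candidate
mode's persistence is its peak height minus the saddle at which it
merges into higher terrain, which suppresses shoulder bumps produced by
cells in transit between patterns. Bin counts were fixed from the sample
sizes used (~2,000–5,000 cells): finer 2-D grids leave so few cells per
bin that shot noise fabricates modes.

**Switching lags.** Because inter-event protein dynamics are
deterministic when $\eta = 0$, the build-up and depletion lags after a
pattern switch follow from the closed form: a silent cell activating one
allele passes 80% of the monoallelic steady state in ≈ 4.6 h, while a
cell silencing both alleles needs ≈ 11–13 h to fall within twice the
leak level and ≈ 20 h to come within 10% of it. The asymmetry (loss
slower than gain) holds whenever expression dominates leak and is
verified property-style over random parameterisations.

## What the simulations show — and what they do not

The simulator doubles as the package's data generator: every tested
claim is measured on populations it produces under the default
parameters above. Passing tests therefore demonstrate internal
consistency of the model with the published observables it was built
from (composition, shuttle fractions, half-lives, division parameters),
not goodness-of-fit to any raw dataset. Features of real cytometry data
deliberately absent: measurement/instrument noise (only transcriptional
noise $\eta$ is modelled), autofluorescence background, cell death,
differentiation (out of scope by design), mRNA dynamics and promoter
bursting within an "on" state, and any coupling to the wider
pluripotency network.

## Problem sizes and tolerances

Test simulations use 400 → 2,000 cells and 100–150 simulated hours; the
acceptance script uses 1,000 → 5,000 cells, 150 h and averages each
stochastic statistic over three seeds. These sizes put Monte Carlo error
on composition fractions near 0.007 and on correlations/CVs near 0.01,
comfortably inside the tolerances asserted; the reconstitution
convergence check (composition within 0.02 of $Z^*$ by 100 h) is run at
5,000 cells because at 2,000 the sampling noise alone approaches the
band. Equilibrium tests read the final snapshot of a 150 h run — three
times the slowest chain relaxation time (~20 h) past the 50 h burn-in.

## Known limitations

* The detailed-balance construction assumes equal two-way switching
  counts; asymmetric shuttle data would need a different estimator.
* Transition rates are the per-cycle probabilities divided by $T_d$;
  for much faster switching a proper generator embedding would be
  required.
* The hazard lookup table introduces interpolation error ~10⁻⁶ relative,
  invisible next to Monte Carlo noise but present.
* Constant-number replacement censors cell lineages at random; completed
  birth-to-division intervals are therefore measured in the freely
  growing phase.
* With $\eta > 0$ every cell is stepped across every quiescence
  interval, so noisy runs scale roughly as (cells × events) and are kept
  to ~1,000 cells in the tests.
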