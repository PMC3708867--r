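#' Single-cell expression parameters
#'
#' Production and degradation constants for the per-allele protein dynamics.
#' Each allele produces protein with zeroth-order kinetics at `s_on`
#' molecules/hour while active and at the leak rate `s_off` while inactive;
#' degradation is first order. A knock-in reporter driven by the same
#' promoter shares the production constants and the allele on/off state but
#' has its own degradation rate, set from its half-life.
#'
#' Defaults: `s_on = 1000` molecules/h, `s_off = 10` (1% of the on rate, so
#' even silent cells keep a baseline of expression), native protein
#' half-life 2 h (NANOG), reporter half-life 20 h (GFP).
#'
#' @param s_on production rate of an active allele (molecules/hour).
#' @param s_off production rate of an inactive allele (molecules/hour);
#'   must satisfy `0 <= s_off < s_on`.
#' @param half_life native protein half-life in hours.
#' @param half_life_reporter reporter protein half-life in hours.
#' @param eta transcriptional noise fraction (>= 0); the SDE noise term has
#'   intensity proportional to the current protein level via `eta`.
#' @param dt Euler-Maruyama step in hours used by [propagate_sde()] and the
#'   population engine when `eta > 0`.
#' @param noise_model `"state"` (noise amplitude `eta * N`, default) or
#'   `"production"` (amplitude `eta * s`).
#' @return An object of class `expression_params` with derived fields
#'   `gamma_n` and `gamma_r` (1/hour).
#' @export
expression_params <- function(s_on = 1000, s_off = 10,
                              half_life = 2, half_life_reporter = 20,
                              eta = 0, dt = 0.01,
                              noise_model = c("state", "production")) {
  noise_model <- match.arg(noise_model)
  if (!isTRUE(s_on > s_off) || !isTRUE(s_off >= 0))
    stop("need s_on > s_off >= 0", call. = FALSE)
  if (!isTRUE(half_life > 0) || !isTRUE(half_life_reporter > 0))
    stop("half-lives must be positive", call. = FALSE)
  if (!isTRUE(eta >= 0)) stop("eta must be >= 0", call. = FALSE)
  if (!isTRUE(dt > 0)) stop("dt must be > 0", call. = FALSE)
  structure(list(s_on = s_on, s_off = s_off,
                 half_life = half_life,
                 half_life_reporter = half_life_reporter,
                 gamma_n = log(2) / half_life,
                 gamma_r = log(2) / half_life_reporter,
                 eta = eta, dt = dt, noise_model = noise_model),
            class = "expression_params")
}

#' Allelic pattern of a cell type
#'
#' Maps between the integer cell type and the on/off state of the two
#' alleles: type 1 = on/on, type 2 = on/off, type 3 = off/on,
#' type 4 = off/off.
#'
#' @param type integer vector of cell types in 1..4.
#' @return `type_alleles()`: logical matrix with columns `allele1`,
#'   `allele2`; `pattern_type()`: integer vector of types.
#' @export
type_alleles <- function(type) {
  type <- as.integer(type)
  if (any(is.na(type)) || any(type < 1L) || any(type > 4L))
    stop("type must be in 1..4", call. = FALSE)
  cbind(allele1 = type %in% c(1L, 2L), allele2 = type %in% c(1L, 3L))
}

#' @rdname type_alleles
#' @param allele1,allele2 logical; is the allele active?
#' @export
pattern_type <- function(allele1, allele2) {
  ifelse(allele1, ifelse(allele2, 1L, 2L), ifelse(allele2, 3L, 4L))
}

#' Per-allele production rate
#'
#' @param active logical; is the allele transcriptionally active?
#' @param params an [expression_params()] object.
#' @param species `"nanog"` or `"reporter"`; both use the same production
#'   constants (the reporter is driven by the native promoter), the
#'   distinction exists for interface symmetry with degradation.
#' @return production rate in molecules/hour.
#' @export
allele_production <- function(active, params,
                              species = c("nanog", "reporter")) {
  species <- match.arg(species)
  ifelse(active, params$s_on, params$s_off)
}

#' Closed-form protein propagation
#'
#' Solves `dN/dt = s - gamma N` exactly:
#' `N(t) = s/gamma + (N0 - s/gamma) exp(-gamma t)`. Vectorised over `n0`.
#'
#' @param n0 initial molecule count(s).
#' @param s production rate (molecules/hour).
#' @param gamma degradation rate (1/hour), > 0.
#' @param t elapsed time in hours, >= 0.
#' @return molecule count(s) after `t` hours.
#' @export
propagate_deterministic <- function(n0, s, gamma, t) {
  stopifnot(gamma > 0, t >= 0)
  ss <- s / gamma
  ss + (n0 - ss) * exp(-gamma * t)
}

#' Steady-state protein level
#'
#' @param s_total total production rate across alleles (molecules/hour).
#' @param gamma degradation rate (1/hour), > 0.
#' @return `s_total / gamma`.
#' @export
steady_state <- function(s_total, gamma) {
  stopifnot(gamma > 0)
  s_total / gamma
}

#' Stochastic protein propagation (Euler-Maruyama)
#'
#' Integrates `dN = (s - gamma N) dt + noise dW` with unit Gaussian white
#' noise, where the noise amplitude is `eta * N` (`noise_model = "state"`,
#' intensity linear in the protein level) or `eta * s`
#' (`noise_model = "production"`). Steps of length `dt`; a final shortened
#' step covers the remainder, and a horizon shorter than `dt` is integrated
#' in a single shortened step. Negative excursions are clipped to zero
#' (molecule counts are non-negative).
#'
#' Vectorised over `n0`: each entry follows an independent noise path, so a
#' vector input yields an ensemble of trajectories. Uses R's global RNG.
#'
#' @inheritParams propagate_deterministic
#' @param eta noise fraction (>= 0); `eta = 0` recovers the deterministic
#'   Euler scheme.
#' @param dt time step in hours.
#' @param noise_model `"state"` or `"production"`.
#' @return molecule count(s) after `t` hours.
#' @export
propagate_sde <- function(n0, s, gamma, eta, t, dt = 0.01,
                          noise_model = c("state", "production")) {
  noise_model <- match.arg(noise_model)
  stopifnot(gamma > 0, t >= 0, dt > 0, eta >= 0)
  n <- as.numeric(n0)
  remaining <- t
  while (remaining > 1e-12) {
    h <- min(dt, remaining)
    amp <- if (noise_model == "state") eta * n else eta * s
    n <- n + (s - gamma * n) * h + amp * sqrt(h) * rnorm(length(n))
    n <- pmax(n, 0)
    remaining <- remaining - h
  }
  n
}

#' Total protein content of cells
#'
#' Sums the two allele-attributed pools. Accepts a single cell (list with
#' `n1`, `n2`) or a population snapshot data frame.
#'
#' @param cell list or data frame with numeric fields/columns `n1`, `n2`.
#' @return numeric vector of per-cell totals.
#' @export
total_nanog <- function(cell) {
  if (is.null(cell$n1) || is.null(cell$n2))
    stop("cell must carry n1 and n2", call. = FALSE)
  cell$n1 + cell$n2
}
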