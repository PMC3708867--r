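#' @importFrom stats median
NULL

scenario_result <- function(label, stats, sim, extra = list()) {
  structure(c(list(label = label, stats = stats, sim = sim), extra),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario:", x$label, "\n")
  sc <- x$stats[vapply(x$stats, function(s)
    is.numeric(s) && length(s) == 1L, logical(1))]
  for (nm in names(sc)) cat(sprintf("  %-22s %s\n", nm,
                                    format(sc[[nm]], digits = 4)))
  invisible(x)
}

#' Wild-type equilibrium scenario
#'
#' Simulates the full allelically regulated population to dynamic
#' equilibrium and summarises the protein distribution of the final
#' snapshot: composition, mean and CV of total protein, positive fraction
#' at the cytometry threshold, and the mode count of the distribution.
#'
#' @param spec a [transition_spec()].
#' @param expr an [expression_params()] (set `eta` here for transcriptional
#'   noise).
#' @param div a [division_params()].
#' @param n_initial,n_cap,t_end,snapshot_every population size and schedule
#'   settings passed to [simulate_population()].
#' @param threshold positivity cutoff in molecules.
#' @param seed integer seed.
#' @return A `scenario_result` with stats `composition`, `mean_nanog`,
#'   `cv_nanog`, `frac_positive`, `peak_count`, `peak_count_2d`.
#' @export
run_equilibrium_study <- function(spec = transition_spec(),
                                  expr = expression_params(),
                                  div = division_params(),
                                  n_initial = 400, n_cap = 2000,
                                  t_end = 150, snapshot_every = 10,
                                  threshold = 500, seed = 1) {
  sim <- simulate_population(spec, expr, div, n_initial, n_cap, t_end,
                             snapshot_every = snapshot_every, seed = seed)
  snap <- snapshot_at(sim)
  pk <- histogram_peaks(snap$n_total)
  pk2 <- histogram_peaks_2d(snap$n1, snap$n2)
  scenario_result(
    "equilibrium",
    list(composition = composition_fractions(snap),
         mean_nanog = mean(snap$n_total),
         cv_nanog = coefficient_of_variation(snap$n_total),
         frac_positive = nanog_positive_fraction(snap, threshold),
         peak_count = as.integer(pk),
         peak_positions = attr(pk, "positions"),
         peak_count_2d = as.integer(pk2)),
    sim)
}

#' Population reconstitution from a uniform allelic pattern
#'
#' Starts 100% of cells in one allelic state and tracks the composition as
#' switching and proliferation rebuild the equilibrium mixture. Convergence
#' is declared at the first snapshot from which the maximum absolute
#' deviation from the stationary composition stays below `tol` for at least
#' `sustain` hours.
#'
#' @inheritParams run_equilibrium_study
#' @param initial_type starting allelic state (1..4) for every cell.
#' @param tol composition deviation defining convergence (default 0.02).
#' @param sustain hours the deviation must remain below `tol`.
#' @return A `scenario_result` with stats `composition_trace` (matrix),
#'   `final_composition`, `max_deviation_final`, `convergence_time_h` and,
#'   for runs started all-silent, `frac_positive_5cycles` (the positive
#'   fraction after five doubling times).
#' @export
run_reconstitution_study <- function(initial_type,
                                     spec = transition_spec(),
                                     expr = expression_params(),
                                     div = division_params(),
                                     n_initial = 400, n_cap = 2000,
                                     t_end = 150, snapshot_every = 5,
                                     threshold = 500,
                                     tol = 0.02, sustain = 20, seed = 1) {
  stopifnot(initial_type %in% 1:4)
  sim <- simulate_population(spec, expr, div, n_initial, n_cap, t_end,
                             initial_type = initial_type,
                             snapshot_every = snapshot_every, seed = seed)
  zs <- stationary_composition(rate_matrices(spec)$k)
  times <- sim$times
  comp <- t(vapply(times, function(tt)
    composition_fractions(snapshot_at(sim, tt)), numeric(4)))
  dev <- apply(abs(sweep(comp, 2, zs)), 1, max)
  conv <- NA_real_
  for (i in seq_along(times)) {
    horizon <- times >= times[i] & times <= times[i] + sustain
    if (all(dev[horizon] < tol) &&
        (times[i] + sustain) <= max(times) + 1e-9) {
      conv <- times[i]
      break
    }
  }
  stats <- list(composition_trace = cbind(time_h = times, comp),
                final_composition = comp[nrow(comp), ],
                max_deviation_final = dev[length(dev)],
                convergence_time_h = conv)
  t5 <- 5 * spec$t_d
  if (max(times) >= t5) {
    stats$frac_positive_5cycles <-
      nanog_positive_fraction(snapshot_at(sim, t5), threshold)
  }
  scenario_result(paste0("reconstitute_type", initial_type), stats, sim)
}

#' Knock-in reporter fidelity scenario
#'
#' Co-expresses a reporter from one or both alleles of the regulated gene
#' (same production constants and on/off state as the native gene; knock-in
#' does not abolish native production) and measures how faithfully the
#' per-cell reporter total tracks the native total at equilibrium.
#'
#' @inheritParams run_equilibrium_study
#' @param insertion `"one"` (allele 1) or `"both"`.
#' @param reporter_half_life reporter half-life in hours (2 = matched to
#'   the native protein, 20 = GFP-like mismatch).
#' @return A `scenario_result` with stats `rho` (Pearson correlation of
#'   reporter vs native totals), `cv_nanog`, `cv_reporter`, `mean_nanog`,
#'   `mean_reporter`.
#' @export
run_reporter_study <- function(insertion = c("one", "both"),
                               reporter_half_life = 2,
                               spec = transition_spec(),
                               expr = expression_params(),
                               div = division_params(),
                               n_initial = 400, n_cap = 2000, t_end = 150,
                               snapshot_every = 25, seed = 1) {
  insertion <- match.arg(insertion)
  expr <- expression_params(s_on = expr$s_on, s_off = expr$s_off,
                            half_life = expr$half_life,
                            half_life_reporter = reporter_half_life,
                            eta = expr$eta, dt = expr$dt,
                            noise_model = expr$noise_model)
  sim <- simulate_population(spec, expr, div, n_initial, n_cap, t_end,
                             reporter = insertion,
                             snapshot_every = snapshot_every, seed = seed)
  snap <- snapshot_at(sim)
  scenario_result(
    sprintf("reporter_%s_t12_%g", insertion, reporter_half_life),
    list(rho = pearson_correlation(snap$r_total, snap$n_total),
         cv_nanog = coefficient_of_variation(snap$n_total),
         cv_reporter = coefficient_of_variation(snap$r_total),
         mean_nanog = mean(snap$n_total),
         mean_reporter = mean(snap$r_total)),
    sim)
}

#' Transcriptional shutoff without allelic regulation
#'
#' A gene not subject to allelic control: switching is disabled (all cells
#' stay in the both-alleles-active state) and a reporter is carried on one
#' allele. After equilibration, production of both the native and reporter
#' genes drops to the leak ("off") rate at t = 0 — as under a
#' transcriptional inhibitor or at the onset of differentiation — and the
#' decaying protein distributions are followed. Reports the
#' reporter/native correlation at shutoff and after `t_follow` hours, plus
#' mean trajectories.
#'
#' By default proliferation is arrested together with transcription
#' (`arrest_division = TRUE`), as for inhibitor-treated cells; the decay of
#' both species is then purely degradative, each cell's levels remain
#' affine in its pre-shutoff levels and the reporter/native correlation is
#' preserved over the follow-up window. With divisions continuing, fresh
#' partitioning noise progressively decorrelates the fast-decaying native
#' protein from the slow reporter.
#'
#' @inheritParams run_equilibrium_study
#' @param reporter_half_life reporter half-life in hours (default 20).
#' @param t_eq equilibration hours before the shutoff.
#' @param t_follow hours tracked after the shutoff.
#' @param arrest_division suppress division after the shutoff (default
#'   `TRUE`).
#' @return A `scenario_result` with stats `rho_t0`, `rho_t20`,
#'   `native_ratio_20h`, `reporter_ratio_20h` (means at 20 h relative to
#'   t = 0) and `trajectory` (time, mean and st.dev. of both species).
#' @export
run_shutoff_study <- function(reporter_half_life = 20,
                              spec = transition_spec(),
                              expr = expression_params(),
                              div = division_params(),
                              n_initial = 400, n_cap = 2000,
                              t_eq = 100, t_follow = 20,
                              arrest_division = TRUE, seed = 1) {
  set.seed(seed)
  expr <- expression_params(s_on = expr$s_on, s_off = expr$s_off,
                            half_life = expr$half_life,
                            half_life_reporter = reporter_half_life,
                            eta = expr$eta, dt = expr$dt,
                            noise_model = expr$noise_model)
  no_switch <- matrix(0, 4, 4)
  eq <- simulate_population(spec, expr, div, n_initial, n_cap, t_end = t_eq,
                            initial_type = 1, reporter = "one",
                            k_matrix = no_switch, snapshot_every = t_eq)
  snap0 <- snapshot_at(eq)
  off <- simulate_population(spec, expr, div, t_end = t_follow,
                             n_initial = n_initial, n_cap = n_cap,
                             init_state = eq$final_state, reporter = "one",
                             k_matrix = no_switch, production_off = TRUE,
                             division_off = arrest_division,
                             snapshot_every = 2)
  traj <- do.call(rbind, lapply(off$times, function(tt) {
    s <- snapshot_at(off, tt)
    data.frame(time_h = tt - t_eq,
               native_mean = mean(s$n_total),
               native_sd = sd(s$n_total),
               reporter_mean = mean(s$r_total),
               reporter_sd = sd(s$r_total))
  }))
  snap20 <- snapshot_at(off, t_eq + t_follow)
  scenario_result(
    "shutoff",
    list(rho_t0 = pearson_correlation(snap0$r_total, snap0$n_total),
         rho_t20 = pearson_correlation(snap20$r_total, snap20$n_total),
         native_ratio_20h = traj$native_mean[nrow(traj)] /
           traj$native_mean[1],
         reporter_ratio_20h = traj$reporter_mean[nrow(traj)] /
           traj$reporter_mean[1],
         trajectory = traj),
    off, extra = list(equilibration = eq))
}

#' Single-allele deletion (heterozygous knockout) scenario
#'
#' Allele 1 is a deleted locus: its chromatin state keeps cycling through
#' the wild-type four-pattern chain (the switching kinetics are a property
#' of the locus, not of the coding sequence), but protein production from
#' it stays at the off-state leak value for the whole simulation; only the
#' intact allele 2 contributes expression. Reports the positive fraction,
#' CV and mean of the mutant population, either at dynamic equilibrium or
#' after five doubling times from an all-silent start.
#'
#' @inheritParams run_equilibrium_study
#' @param start `"equilibrium"` (start at the chain's stationary mixture)
#'   or `"all_off"` (every cell with both alleles silent, at the leak
#'   steady state).
#' @return A `scenario_result` with stats `frac_positive`, `cv_nanog`,
#'   `mean_nanog`, `composition` and, for `start = "all_off"`,
#'   `frac_positive_5cycles`.
#' @export
run_knockout_study <- function(start = c("equilibrium", "all_off"),
                               spec = transition_spec(),
                               expr = expression_params(),
                               div = division_params(),
                               n_initial = 400, n_cap = 2000,
                               t_end = 150, snapshot_every = 10,
                               threshold = 500, seed = 1) {
  start <- match.arg(start)
  if (start == "all_off") {
    sim <- simulate_population(spec, expr, div, n_initial, n_cap,
                               t_end = max(t_end, 5 * spec$t_d),
                               initial_type = 4, allele1_deleted = TRUE,
                               snapshot_every = snapshot_every, seed = seed)
  } else {
    sim <- simulate_population(spec, expr, div, n_initial, n_cap, t_end,
                               allele1_deleted = TRUE,
                               snapshot_every = snapshot_every, seed = seed)
  }
  snap <- snapshot_at(sim)
  stats <- list(frac_positive = nanog_positive_fraction(snap, threshold),
                cv_nanog = coefficient_of_variation(snap$n_total),
                mean_nanog = mean(snap$n_total),
                composition = composition_fractions(snap))
  if (start == "all_off")
    stats$frac_positive_5cycles <-
      nanog_positive_fraction(snapshot_at(sim, 5 * spec$t_d), threshold)
  scenario_result(paste0("knockout_", start), stats, sim)
}

#' Run a named scenario
#'
#' Dispatcher used by the command-line interface; forwards `...` to the
#' matching driver.
#'
#' @param scenario one of `"equilibrium"`, `"reconstitute"`, `"reporter"`,
#'   `"shutoff"`, `"knockout"`.
#' @param ... arguments for the scenario driver.
#' @return the driver's `scenario_result`.
#' @export
run_scenario <- function(scenario = c("equilibrium", "reconstitute",
                                      "reporter", "shutoff", "knockout"),
                         ...) {
  scenario <- match.arg(scenario)
  switch(scenario,
         equilibrium = run_equilibrium_study(...),
         reconstitute = run_reconstitution_study(...),
         reporter = run_reporter_study(...),
         shutoff = run_shutoff_study(...),
         knockout = run_knockout_study(...))
}
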