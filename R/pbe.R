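#' Division and partitioning parameters
#'
#' The size of dividing cells follows a Gaussian with mean `mu` and standard
#' deviation `sigma` (dimensionless volume units), and every component of
#' the cell state (the two allele-attributed protein pools, reporter pools
#' and size) is split between the daughters by independent draws from a
#' symmetric beta distribution with shape `q`.
#'
#' @param mu mean division size (default 0.465).
#' @param sigma standard deviation of the division size (default 0.104).
#' @param q symmetric beta shape parameter for partitioning (default 39;
#'   partition fraction st.dev. `0.5/sqrt(2q+1)`, about 0.056).
#' @return An object of class `division_params`.
#' @export
division_params <- function(mu = 0.465, sigma = 0.104, q = 39) {
  if (!isTRUE(sigma > 0)) stop("sigma must be > 0", call. = FALSE)
  if (!isTRUE(q > 0)) stop("q must be > 0", call. = FALSE)
  if (!isTRUE(mu > 0)) stop("mu must be > 0", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, q = q), class = "division_params")
}

#' Exponential single-cell growth
#'
#' Cell size grows proportionally to itself at the population growth rate,
#' `v(t) = v0 exp((ln 2 / t_d) t)`, so a cell doubles its size over one
#' doubling time.
#'
#' @param v0 initial size(s), > 0.
#' @param t elapsed hours, >= 0.
#' @param t_d doubling time in hours.
#' @return size(s) after `t` hours.
#' @export
grow_size <- function(v0, t, t_d) {
  stopifnot(all(v0 > 0), all(t >= 0), t_d > 0)
  v0 * exp((log(2) / t_d) * t)
}

#' Size-dependent division hazard
#'
#' Division intensity of a cell of size `v`, derived from the Gaussian
#' distribution of division sizes: `Gamma(v) = r_v(v) phi(v) / (1 - Phi(v))`
#' with size growth rate `r_v(v) = (ln 2 / t_d) v`, where `phi` and `Phi`
#' are the Gaussian density and CDF of division sizes. This is the classical
#' hazard-rate construction: among cells still undivided at size `v`, the
#' division intensity per unit time equals the division-size density times
#' the size growth speed over the survival function. Where the survival
#' function underflows (abnormally large cells) the hazard is capped so
#' waiting times stay finite.
#'
#' @param v cell size(s), > 0.
#' @param t_d doubling time in hours.
#' @param params a [division_params()] object.
#' @param cap hazard ceiling in 1/hour (default 50).
#' @return division rate(s) in 1/hour.
#' @export
division_hazard <- function(v, t_d, params = division_params(), cap = 50) {
  stopifnot(all(v > 0), t_d > 0)
  rv <- (log(2) / t_d) * v
  surv <- pnorm(v, params$mu, params$sigma, lower.tail = FALSE)
  h <- rv * dnorm(v, params$mu, params$sigma) / surv
  h[!is.finite(h) | h > cap] <- cap
  h
}

#' Sample division partition fractions
#'
#' Draws from the symmetric beta partitioning law: the fraction of a
#' conserved quantity inherited by one daughter.
#'
#' @param q symmetric beta shape parameter.
#' @param n number of draws.
#' @return numeric vector of fractions in (0, 1).
#' @export
sample_partition_fraction <- function(q, n = 1) {
  stopifnot(q > 0)
  rbeta(n, q, q)
}

#' Divide a cell into two daughters
#'
#' Each component of the state vector (`n1`, `n2`, `r1`, `r2`, `v`) is
#' partitioned by an independent symmetric-beta fraction; one daughter
#' receives fraction `x`, the other `1 - x`, so every component is conserved
#' exactly. Both daughters inherit the mother's allelic pattern.
#'
#' @param mother list with numeric fields `n1`, `n2`, `r1`, `r2`, `v` and
#'   integer `type`.
#' @param params a [division_params()] object.
#' @return list of two cells with the same fields as `mother`.
#' @export
divide_cell <- function(mother, params = division_params()) {
  fields <- c("n1", "n2", "r1", "r2", "v")
  x <- sample_partition_fraction(params$q, length(fields))
  a <- mother
  b <- mother
  for (f in seq_along(fields)) {
    tot <- mother[[fields[f]]]
    a[[fields[f]]] <- x[f] * tot
    b[[fields[f]]] <- tot - x[f] * tot
  }
  list(a, b)
}

#' Per-cell event rate matrix
#'
#' One row per living cell holding the three allelic switching propensities
#' out of the cell's current state (in increasing destination-state order)
#' and, in the fourth column, the division propensity: the size-dependent
#' hazard in `"size_hazard"` mode or the constant rate `ln 2 / t_d` in
#' `"constant_rate"` mode.
#'
#' @param population data frame (or list) with fields `type` and `v`.
#' @param rates a [rate_matrices()] object.
#' @param division_mode `"size_hazard"` or `"constant_rate"`.
#' @param div_params a [division_params()] object (size_hazard mode).
#' @return An object of class `event_rate_matrix`: list with `rates`
#'   (n x 4 matrix), `targets` (n x 3 integer matrix of destination states)
#'   and `total_rate`.
#' @export
build_event_rates <- function(population, rates,
                              division_mode = c("size_hazard",
                                                "constant_rate"),
                              div_params = division_params()) {
  division_mode <- match.arg(division_mode)
  type <- as.integer(population$type)
  n <- length(type)
  if (n == 0L) stop("population is extinct (no cells)", call. = FALSE)
  k <- rates$k
  targets <- t(vapply(type, function(i) setdiff(1:4, i), integer(3)))
  sw <- matrix(k[cbind(rep(type, 3L), as.vector(targets))], nrow = n)
  div <- if (division_mode == "size_hazard") {
    division_hazard(population$v, rates$t_d, div_params)
  } else {
    rep(log(2) / rates$t_d, n)
  }
  m <- cbind(sw, div)
  dimnames(m) <- NULL
  structure(list(rates = m, targets = targets, total_rate = sum(m)),
            class = "event_rate_matrix")
}

#' Sample an interval of quiescence
#'
#' Waiting time until the next discrete event (division or allelic switch):
#' exponential with mean `1 / total_rate`.
#'
#' @param total_rate summed event rate of the population (1/hour), > 0.
#' @return waiting time in hours.
#' @export
sample_quiescence <- function(total_rate) {
  stopifnot(total_rate > 0)
  rexp(1, total_rate)
}

#' Select the cell and event ending quiescence
#'
#' Deterministic inverse-CDF lookup: the rows of the event rate matrix are
#' scanned in order (within a row: the three switch entries, then division)
#' and the unique entry whose cumulative interval contains
#' `ran2 * total_rate` identifies the cell and the event kind.
#'
#' @param e an [build_event_rates()] result.
#' @param ran2 uniform variate in `[0, 1)`.
#' @return list with `cell` (row index), `kind` (`"divide"` or `"switch"`)
#'   and `target` (destination state for a switch, `NA` for a division).
#' @export
select_event <- function(e, ran2) {
  stopifnot(ran2 >= 0, ran2 < 1)
  x <- ran2 * e$total_rate
  flat <- as.vector(t(e$rates))
  idx <- findInterval(x, cumsum(flat), left.open = FALSE) + 1L
  idx <- min(idx, length(flat))
  cell <- (idx - 1L) %/% 4L + 1L
  col <- (idx - 1L) %% 4L + 1L
  if (col == 4L) {
    list(cell = cell, kind = "divide", target = NA_integer_)
  } else {
    list(cell = cell, kind = "switch", target = e$targets[cell, col])
  }
}

#' Initialise a population state
#'
#' Newborn-like initial condition: each cell draws a division size from the
#' Gaussian division-size law and a symmetric-beta split of it as its size;
#' molecular content starts at the deterministic steady state of the cell's
#' allelic pattern (reporter pools likewise for reporter-carrying alleles).
#'
#' @param n number of cells.
#' @param types integer vector (length 1 or `n`) of initial cell types, or
#'   `NULL` to sample from `composition`.
#' @param composition length-4 probability vector used when `types` is
#'   `NULL`.
#' @param expr an [expression_params()] object.
#' @param div a [division_params()] object.
#' @param reporter `"none"`, `"one"` (allele 1) or `"both"`.
#' @param production_off logical; if `TRUE` all alleles start at the leak
#'   production level.
#' @param allele1_deleted logical; if `TRUE` allele 1 is a deleted locus:
#'   its protein pool starts at the leak steady state whatever the nominal
#'   pattern.
#' @return list of state vectors (`time`, `cell_id`, `type`, `n1`, `n2`,
#'   `r1`, `r2`, `v`).
#' @export
init_population <- function(n, types = NULL,
                            composition = c(0.14, 0.28, 0.28, 0.30),
                            expr = expression_params(),
                            div = division_params(),
                            reporter = c("none", "one", "both"),
                            production_off = FALSE,
                            allele1_deleted = FALSE) {
  reporter <- match.arg(reporter)
  stopifnot(n >= 1)
  if (is.null(types)) {
    types <- sample.int(4L, n, replace = TRUE, prob = composition)
  } else {
    types <- rep_len(as.integer(types), n)
  }
  act <- type_alleles(types)
  if (production_off) act[] <- FALSE
  if (allele1_deleted) act[, 1L] <- FALSE
  s1 <- allele_production(act[, 1L], expr)
  s2 <- allele_production(act[, 2L], expr)
  dsize <- rnorm(n, div$mu, div$sigma)
  while (any(dsize <= 0)) {
    bad <- dsize <= 0
    dsize[bad] <- rnorm(sum(bad), div$mu, div$sigma)
  }
  v <- dsize * sample_partition_fraction(div$q, n)
  rep1 <- reporter %in% c("one", "both")
  rep2 <- reporter == "both"
  list(time = 0,
       cell_id = seq_len(n),
       type = types,
       n1 = s1 / expr$gamma_n,
       n2 = s2 / expr$gamma_n,
       r1 = if (rep1) s1 / expr$gamma_r else numeric(n) * 0,
       r2 = if (rep2) s2 / expr$gamma_r else rep(0, n),
       v = v)
}

#' Simulate the cell population (kinetic Monte Carlo PBE solver)
#'
#' Event-driven solver of the coupled population balance equations. Between
#' events every cell grows exponentially in size and its per-allele protein
#' pools follow the closed-form production/degradation solution (or an
#' Euler-Maruyama step when `eta > 0`). Waiting times between events are
#' exponential with the summed propensity of all switching and division
#' channels; the triggering cell and channel are chosen by inverse-CDF
#' lookup. A division splits every state component by independent
#' symmetric-beta fractions. While the population is below `n_cap` both
#' daughters are kept (constant-volume phase); at the cap one daughter
#' replaces the mother and the other overwrites a uniformly chosen other
#' cell (constant-number phase), so the sample represents a growing culture
#' at fixed sample size.
#'
#' @param spec a [transition_spec()]; its rate matrix drives allelic
#'   switching unless `k_matrix` overrides it.
#' @param expr an [expression_params()] object.
#' @param div a [division_params()] object.
#' @param n_initial starting cell count.
#' @param n_cap population ceiling for the constant-number switch.
#' @param t_end simulated hours.
#' @param initial_type if non-`NULL`, start 100% of cells in this type.
#' @param init_composition initial composition when `initial_type` is
#'   `NULL`; defaults to the stationary composition of the chain.
#' @param init_state resume from the `final_state` of a previous run
#'   (overrides the initialisation arguments; simulation continues from its
#'   `time`).
#' @param reporter `"none"`, `"one"` (knock-in on allele 1) or `"both"`.
#' @param division_mode `"size_hazard"` (default; the population-balance
#'   division law) or `"constant_rate"` (`ln 2 / t_d` per cell).
#' @param production_off if `TRUE`, all alleles produce at the leak rate
#'   (transcriptional shutoff).
#' @param division_off if `TRUE`, cell division is suppressed (e.g. cells
#'   arrested by a transcriptional inhibitor); growth and protein dynamics
#'   continue.
#' @param allele1_deleted if `TRUE`, allele 1 is a deleted locus: its
#'   chromatin keeps switching through the four patterns, but its protein
#'   production stays at the off-state (leak) value throughout.
#' @param k_matrix optional 4x4 rate-matrix override (e.g. all zeros to
#'   disable switching, or a restricted chain for allele deletion).
#' @param snapshot_every interval in hours between recorded population
#'   snapshots.
#' @param seed integer seed; if non-`NULL`, `set.seed(seed)` is called so
#'   the run is fully reproducible.
#' @return An object of class `pbe_sim`: list with `snapshots` (long data
#'   frame: `time_h`, `cell_id`, `type`, `n1`, `n2`, `r1`, `r2`, `n_total`,
#'   `r_total`, `v`), `times`, `final_state`, `event_counts` (divisions and
#'   a 4x4 switch-count matrix) and the call parameters.
#' @examples
#' sim <- simulate_population(n_initial = 50, n_cap = 200, t_end = 30,
#'                            snapshot_every = 10, seed = 1)
#' summary(sim)
#' @export
simulate_population <- function(spec = transition_spec(),
                                expr = expression_params(),
                                div = division_params(),
                                n_initial = 400, n_cap = 2000, t_end = 150,
                                initial_type = NULL,
                                init_composition = NULL,
                                init_state = NULL,
                                reporter = c("none", "one", "both"),
                                division_mode = c("size_hazard",
                                                  "constant_rate"),
                                production_off = FALSE,
                                division_off = FALSE,
                                allele1_deleted = FALSE,
                                k_matrix = NULL,
                                snapshot_every = 10,
                                seed = NULL) {
  reporter <- match.arg(reporter)
  division_mode <- match.arg(division_mode)
  if (!isTRUE(n_cap >= n_initial) || !isTRUE(n_initial >= 1))
    stop("need n_cap >= n_initial >= 1", call. = FALSE)
  if (!isTRUE(t_end > 0)) stop("t_end must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rm_ <- rate_matrices(spec)
  k <- if (is.null(k_matrix)) rm_$k else k_matrix
  if (is.null(init_state)) {
    comp <- if (!is.null(initial_type)) NULL else
      if (is.null(init_composition)) stationary_composition(rm_$k) else
        init_composition
    st <- init_population(n_initial,
                          types = initial_type, composition = comp,
                          expr = expr, div = div, reporter = reporter,
                          production_off = production_off,
                          allele1_deleted = allele1_deleted)
  } else {
    st <- init_state
  }
  t0 <- st$time
  t_stop <- t0 + t_end
  snapshot_times <- seq(t0, t_stop, by = snapshot_every)
  if (snapshot_times[length(snapshot_times)] < t_stop - 1e-9)
    snapshot_times <- c(snapshot_times, t_stop)
  res <- pbe_engine_cpp(
    n1 = st$n1, n2 = st$n2, r1 = st$r1, r2 = st$r2, v = st$v,
    type = as.integer(st$type), cell_id = as.integer(st$cell_id),
    next_id = max(st$cell_id) + 1L,
    kmat = k, t_d = spec$t_d,
    s_on = expr$s_on, s_off = expr$s_off,
    gamma_n = expr$gamma_n, gamma_r = expr$gamma_r,
    eta = expr$eta, dt_sde = expr$dt,
    noise_production = identical(expr$noise_model, "production"),
    rep1 = reporter %in% c("one", "both"), rep2 = reporter == "both",
    production_off = production_off,
    division_off = division_off,
    allele1_deleted = allele1_deleted,
    size_hazard = division_mode == "size_hazard",
    mu = div$mu, sigma = div$sigma, q = div$q, hazard_cap = 50,
    n_cap = as.integer(n_cap), t0 = t0, t_end = t_stop,
    snapshot_times = snapshot_times)
  snaps <- lapply(res$snapshots, function(s) {
    data.frame(time_h = s$time, cell_id = s$cell_id, type = s$type,
               n1 = s$n1, n2 = s$n2, r1 = s$r1, r2 = s$r2,
               n_total = s$n1 + s$n2, r_total = s$r1 + s$r2, v = s$v)
  })
  structure(list(
    snapshots = do.call(rbind, snaps),
    times = vapply(res$snapshots, function(s) s$time, numeric(1)),
    final_state = res$final_state,
    event_counts = res$event_counts,
    spec = spec, expr = expr, div = div,
    reporter = reporter, division_mode = division_mode,
    production_off = production_off, n_cap = n_cap, seed = seed),
    class = "pbe_sim")
}

#' Extract one population snapshot
#'
#' @param sim a `pbe_sim` object.
#' @param time requested time in hours; the nearest recorded snapshot is
#'   returned (default: the last one).
#' @return data frame with one row per cell.
#' @export
snapshot_at <- function(sim, time = NULL) {
  stopifnot(inherits(sim, "pbe_sim"))
  tt <- if (is.null(time)) max(sim$times) else
    sim$times[which.min(abs(sim$times - time))]
  sim$snapshots[abs(sim$snapshots$time_h - tt) < 1e-9, , drop = FALSE]
}

#' @export
print.pbe_sim <- function(x, ...) {
  last <- snapshot_at(x)
  cat("Kinetic Monte Carlo population simulation\n")
  cat(sprintf("  time span: %.1f - %.1f h, %d snapshots\n",
              min(x$times), max(x$times), length(x$times)))
  cat(sprintf("  final population: %d cells (cap %d)\n",
              nrow(last), x$n_cap))
  cat(sprintf("  events: %.0f divisions, %d allelic switches\n",
              x$event_counts$divisions, sum(x$event_counts$switches)))
  invisible(x)
}

#' @export
summary.pbe_sim <- function(object, ...) {
  last <- snapshot_at(object)
  comp <- composition_fractions(last)
  out <- list(
    time = max(object$times),
    n_cells = nrow(last),
    composition = comp,
    mean_nanog = mean(last$n_total),
    cv_nanog = coefficient_of_variation(last$n_total),
    frac_positive = nanog_positive_fraction(last),
    event_counts = object$event_counts)
  class(out) <- "summary.pbe_sim"
  out
}

#' @export
print.summary.pbe_sim <- function(x, ...) {
  cat(sprintf("Population at t = %.1f h: %d cells\n", x$time, x$n_cells))
  cat("  composition (types 1-4):",
      paste(sprintf("%.3f", x$composition), collapse = " "), "\n")
  cat(sprintf("  mean total protein: %.0f molecules (CV %.2f)\n",
              x$mean_nanog, x$cv_nanog))
  cat(sprintf("  fraction above positivity threshold: %.3f\n",
              x$frac_positive))
  invisible(x)
}

#' @export
#' @importFrom graphics hist
plot.pbe_sim <- function(x, time = NULL, breaks = 60, ...) {
  snap <- snapshot_at(x, time)
  hist(log10(snap$n_total + 1), breaks = breaks,
       xlab = "log10(total protein + 1)",
       main = sprintf("Protein distribution at t = %.0f h",
                      snap$time_h[1]), ...)
  invisible(x)
}
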