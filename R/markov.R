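#' Allelic-switching transition specification
#'
#' Bundles the observable ingredients of the four-state allelic switching
#' Markov chain: the equilibrium subpopulation composition, the fractions of
#' the total population shuttling between pairs of states per cell cycle, and
#' the population doubling time.
#'
#' The four states label the on/off pattern of the two gene copies:
#' state 1 = both alleles active (biallelic), states 2 and 3 = exactly one
#' allele active (monoallelic, allele 1 or allele 2 respectively), state
#' 4 = both alleles inactive. States 1 and 4 are not linked directly (a
#' direct transition would require simultaneous switching of both alleles),
#' so `shuttle[1,4]` must be zero; the same default applies to the 2--3 pair.
#'
#' @param z_star numeric length-4 vector of equilibrium fractions, summing
#'   to 1. Default `c(0.14, 0.28, 0.28, 0.30)`: 14% biallelic, 28% for each
#'   monoallelic pattern, 30% silent, the composition observed for mouse ES
#'   cells cultured with LIF and serum.
#' @param shuttle symmetric 4x4 matrix; entry `[i, j]` is the fraction of
#'   the *total* population that shuttles between states i and j per cell
#'   cycle (counting both directions). May also be given as a named list
#'   with keys like `"1-2"`; unspecified pairs default to 0. Default: 0.12
#'   on the linked pairs 1-2, 1-3, 2-4, 3-4 and 0 on 1-4 and 2-3.
#' @param t_d population doubling time in hours (default 10).
#' @return An object of class `transition_spec`.
#' @seealso [transition_probabilities()], [rate_matrices()]
#' @examples
#' spec <- transition_spec()
#' transition_probabilities(spec)
#' @export
transition_spec <- function(z_star = c(0.14, 0.28, 0.28, 0.30),
                            shuttle = default_shuttle(),
                            t_d = 10) {
  z_star <- as.numeric(z_star)
  if (length(z_star) != 4L || any(!is.finite(z_star)) || any(z_star < 0))
    stop("z_star must be 4 non-negative finite fractions", call. = FALSE)
  if (abs(sum(z_star) - 1) > 1e-12)
    stop("z_star must sum to 1 (within 1e-12); got sum = ",
         format(sum(z_star), digits = 15), call. = FALSE)
  shuttle <- as_shuttle_matrix(shuttle)
  if (any(shuttle < 0) || any(shuttle > 1))
    stop("shuttle fractions must lie in [0, 1]", call. = FALSE)
  if (shuttle[1, 4] != 0)
    stop("shuttle(1,4) must be 0: states 1 and 4 are not linked directly",
         call. = FALSE)
  if (!isTRUE(t_d > 0)) stop("t_d must be a positive number of hours",
                             call. = FALSE)
  structure(list(z_star = z_star, shuttle = shuttle, t_d = as.numeric(t_d)),
            class = "transition_spec")
}

#' Default pairwise shuttle fractions
#'
#' 12% of the total population shuttles between the biallelic state and each
#' monoallelic state per cell cycle, and likewise between each monoallelic
#' state and the silent state; no direct 1-4 or 2-3 edge. The two pairs not
#' reported explicitly take the 1-2 value by allele symmetry (no allelic
#' bias), and the monoallelic-to-silent pairs mirror each other for the same
#' reason.
#'
#' @return symmetric 4x4 matrix of per-cell-cycle shuttle fractions.
#' @export
default_shuttle <- function() {
  as_shuttle_matrix(list(`1-2` = 0.12, `1-3` = 0.12,
                         `2-4` = 0.12, `3-4` = 0.12))
}

as_shuttle_matrix <- function(x) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(4L, 4L))) stop("shuttle matrix must be 4x4",
                                        call. = FALSE)
    if (max(abs(x - t(x))) > 1e-12) stop("shuttle matrix must be symmetric",
                                         call. = FALSE)
    m <- (x + t(x)) / 2
    diag(m) <- 0
    dimnames(m) <- list(as.character(1:4), as.character(1:4))
    return(m)
  }
  if (!is.list(x)) stop("shuttle must be a 4x4 matrix or a named list",
                        call. = FALSE)
  m <- matrix(0, 4, 4, dimnames = list(as.character(1:4), as.character(1:4)))
  for (key in names(x)) {
    ij <- as.integer(strsplit(key, "-", fixed = TRUE)[[1]])
    if (length(ij) != 2L || any(is.na(ij)) || any(ij < 1L) || any(ij > 4L) ||
        ij[1] == ij[2])
      stop("bad shuttle pair key: '", key, "' (expected e.g. \"1-2\")",
           call. = FALSE)
    m[ij[1], ij[2]] <- m[ij[2], ij[1]] <- as.numeric(x[[key]])
  }
  m
}

#' Per-cell-cycle transition probability matrix by detailed balance
#'
#' The fraction of cells switching i -> j per cell cycle is taken equal to
#' the fraction switching j -> i (half of the reported two-way shuttle
#' fraction each), which is the detailed-balance condition
#' `z_i * p_ij = z_j * p_ji`. Hence `p_ij = (shuttle_ij / 2) / z_i` for
#' i != j, and the diagonal completes each row to 1.
#'
#' @param spec a [transition_spec()].
#' @return 4x4 row-stochastic matrix of per-cell-cycle transition
#'   probabilities; `p[1,4] = p[4,1] = 0`.
#' @export
transition_probabilities <- function(spec) {
  stopifnot(inherits(spec, "transition_spec"))
  z <- spec$z_star
  linked <- spec$shuttle > 0
  if (any(linked & (outer(z, z, function(a, b) a == 0))))
    stop("z_star must be positive for every linked pair", call. = FALSE)
  p <- matrix(0, 4, 4, dimnames = dimnames(spec$shuttle))
  for (i in 1:4) for (j in 1:4) if (i != j && spec$shuttle[i, j] > 0)
    p[i, j] <- (spec$shuttle[i, j] / 2) / z[i]
  diag(p) <- 1 - rowSums(p)
  bad <- which(diag(p) < 0)
  if (length(bad))
    stop("shuttle fractions too large for z_star: negative staying ",
         "probability in row(s) ", paste(bad, collapse = ", "), call. = FALSE)
  p
}

#' Transition rate matrix from per-cycle probabilities
#'
#' The shuttle data refer to one cell cycle (the unit time of observation),
#' so off-diagonal rates are approximated as `k_ij = p_ij / t_d`; diagonal
#' entries make every row sum to zero, as required of a continuous-time
#' Markov generator.
#'
#' @param p 4x4 row-stochastic matrix (see [transition_probabilities()]).
#' @param t_d doubling time in hours.
#' @return 4x4 rate matrix (1/hour) with zero row sums.
#' @export
transition_rate_matrix <- function(p, t_d) {
  if (!isTRUE(t_d > 0)) stop("t_d must be > 0", call. = FALSE)
  if (!is.matrix(p) || !all(dim(p) == c(4L, 4L)))
    stop("p must be a 4x4 matrix", call. = FALSE)
  if (max(abs(rowSums(p) - 1)) > 1e-9)
    stop("p must be row-stochastic", call. = FALSE)
  k <- p / t_d
  diag(k) <- 0
  diag(k) <- -rowSums(k)
  k
}

#' Proliferation rate vector
#'
#' Every cell proliferates with the same kinetics regardless of its allelic
#' pattern, so each of the four states carries the identical exponential
#' growth rate `ln(2) / t_d`.
#'
#' @param t_d doubling time in hours.
#' @return length-4 numeric vector of growth rates (1/hour).
#' @export
growth_rates <- function(t_d) {
  if (!isTRUE(t_d > 0)) stop("t_d must be > 0", call. = FALSE)
  rep(log(2) / t_d, 4L)
}

#' Assemble all chain matrices from a transition specification
#'
#' @param spec a [transition_spec()].
#' @return An object of class `rate_matrices`: list with elements `p`
#'   (per-cycle probabilities), `k` (rates, 1/h), `lam` (growth rates, 1/h),
#'   `a` (`k + diag(lam)`, the generator of the cell-number dynamics) and
#'   `t_d`.
#' @export
rate_matrices <- function(spec) {
  stopifnot(inherits(spec, "transition_spec"))
  p <- transition_probabilities(spec)
  k <- transition_rate_matrix(p, spec$t_d)
  lam <- growth_rates(spec$t_d)
  structure(list(p = p, k = k, lam = lam, a = k + diag(lam), t_d = spec$t_d),
            class = "rate_matrices")
}

#' @export
print.rate_matrices <- function(x, ...) {
  cat("Allelic switching chain (t_d =", x$t_d, "h)\n")
  cat("Per-cycle transition probabilities:\n")
  print(round(x$p, 4))
  cat("Transition rates (1/h):\n")
  print(round(x$k, 5))
  cat("Growth rate:", round(x$lam[1], 5), "1/h (all states)\n")
  invisible(x)
}

#' Stationary composition of the switching chain
#'
#' Solves `Z k = 0` subject to non-negativity and unit sum, i.e. the left
#' null space of the rate matrix. The chain must have a single communicating
#' class: a null space of dimension greater than one is rejected.
#'
#' @param k 4x4 transition rate matrix (zero row sums), e.g.
#'   `rate_matrices(spec)$k`, or a `rate_matrices` object.
#' @return length-4 numeric vector of stationary fractions.
#' @export
stationary_composition <- function(k) {
  if (inherits(k, "rate_matrices")) k <- k$k
  if (!is.matrix(k) || !all(dim(k) == c(4L, 4L)))
    stop("k must be a 4x4 rate matrix", call. = FALSE)
  if (max(abs(rowSums(k))) > 1e-9)
    stop("rows of a rate matrix must sum to 0", call. = FALSE)
  sv <- svd(t(k))
  scale <- max(sv$d, 1)
  null_dim <- sum(sv$d < 1e-10 * scale)
  if (null_dim != 1L)
    stop("rate matrix has a ", null_dim, "-dimensional null space; ",
         "the chain must have exactly one communicating class", call. = FALSE)
  z <- sv$v[, 4L]
  z <- z / sum(z)
  if (any(z < -1e-10))
    stop("stationary solution has negative entries; invalid rate matrix",
         call. = FALSE)
  pmax(z, 0) / sum(pmax(z, 0))
}

#' Evolve subpopulation fractions in time
#'
#' With equal proliferation rates across states the growth terms cancel from
#' the composition dynamics, which reduce to the linear system
#' `dZ/dt = Z k` solved here with a matrix exponential,
#' `Z(t) = Z(0) exp(k t)`.
#'
#' @param z0 length-4 initial composition (sums to 1).
#' @param rates a `rate_matrices` object or a bare 4x4 rate matrix.
#' @param t time(s) in hours; scalar or vector.
#' @return If `t` is scalar, a length-4 vector; otherwise a
#'   `length(t)` x 4 matrix with one row per time point.
#' @export
evolve_fractions <- function(z0, rates, t) {
  k <- if (inherits(rates, "rate_matrices")) rates$k else rates
  z0 <- as.numeric(z0)
  if (length(z0) != 4L || abs(sum(z0) - 1) > 1e-9)
    stop("z0 must be a 4-vector summing to 1", call. = FALSE)
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  out <- t(vapply(t, function(tt) {
    z <- as.numeric(z0 %*% as.matrix(Matrix::expm(k * tt)))
    pmax(z, 0) / sum(pmax(z, 0))
  }, numeric(4)))
  colnames(out) <- as.character(1:4)
  if (length(t) == 1L) out[1L, ] else out
}
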