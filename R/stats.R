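#' Composition of a population snapshot
#'
#' @param snapshot data frame with a `type` column (integer 1..4).
#' @return length-4 vector of per-type fractions (sums to 1).
#' @export
composition_fractions <- function(snapshot) {
  type <- as.integer(snapshot$type)
  if (length(type) == 0L) stop("empty snapshot", call. = FALSE)
  tabulate(type, nbins = 4L) / length(type)
}

#' Fraction of protein-positive cells
#'
#' Mimics a flow-cytometry gate: cells whose total protein exceeds the
#' threshold are scored positive. The default 500 molecules sits between
#' the silent and monoallelic peaks of the equilibrium distribution.
#'
#' @param snapshot data frame with an `n_total` column.
#' @param threshold positivity cutoff in molecules (default 500).
#' @return fraction in `[0, 1]`.
#' @export
nanog_positive_fraction <- function(snapshot, threshold = 500) {
  if (!isTRUE(threshold > 0)) stop("threshold must be > 0", call. = FALSE)
  mean(snapshot$n_total > threshold)
}

#' Coefficient of variation
#'
#' Population (not sample) standard deviation divided by the mean, the
#' standard cytometry heterogeneity metric.
#'
#' @param values numeric vector with positive mean.
#' @return dimensionless CV.
#' @export
coefficient_of_variation <- function(values) {
  m <- mean(values)
  if (!isTRUE(m > 0)) stop("mean must be positive for a CV", call. = FALSE)
  sqrt(mean((values - m)^2)) / m
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 2 with nonzero variance.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must have equal length >= 2", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("x and y must have nonzero variance", call. = FALSE)
  cor(x, y, method = "pearson")
}

ma_smooth <- function(h, window = 3L) {
  n <- length(h)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i)
    mean(h[max(1L, i - half):min(n, i + half)]), numeric(1))
}

#' Count modes of a protein distribution
#'
#' Operationalises visual peak counting: the values are histogrammed on a
#' `log10(x + 1)` axis with `bins` equal-width bins, smoothed with a
#' `window`-bin moving average, and local maxima are kept if their
#' topographic prominence (height above the higher of the two saddles
#' separating them from higher terrain; edges count as zero ground) is at
#' least `prominence` times the modal bin height.
#'
#' @param values numeric vector of at least 100 protein totals.
#' @param bins number of histogram bins (default 60).
#' @param window moving-average smoothing window in bins (default 3).
#' @param prominence prominence floor as a fraction of the modal smoothed
#'   bin height (default 0.05).
#' @param log_scale histogram on `log10(x + 1)` (default) or raw values.
#' @return integer peak count, with attribute `"positions"` giving the peak
#'   locations on the original scale.
#' @export
histogram_peaks <- function(values, bins = 60, window = 3L,
                            prominence = 0.05, log_scale = TRUE) {
  if (length(values) < 100L)
    stop("need at least 100 values to count peaks", call. = FALSE)
  x <- if (log_scale) log10(values + 1) else values
  br <- seq(min(x), max(x), length.out = bins + 1L)
  br[1] <- br[1] - 1e-9
  br[length(br)] <- br[length(br)] + 1e-9
  counts <- tabulate(findInterval(x, br, left.open = FALSE,
                                  rightmost.closed = TRUE), nbins = bins)
  s <- ma_smooth(counts, window)
  n <- length(s)
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i > 1L) s[i - 1L] else -Inf
    right <- if (i < n) s[i + 1L] else -Inf
    s[i] > left && s[i] >= right && s[i] > 0
  }, logical(1))
  cand <- which(is_max)
  floor_h <- prominence * max(s)
  keep <- vapply(cand, function(i) {
    hi <- s[i]
    side_col <- function(idx) {
      m <- Inf
      for (j in idx) {
        if (s[j] > hi) return(m)
        m <- min(m, s[j])
      }
      if (is.infinite(m)) 0 else min(m, 0)
    }
    colL <- side_col(rev(seq_len(i - 1L)))
    colR <- side_col(if (i < n) seq(i + 1L, n) else integer(0))
    (hi - max(colL, colR)) >= floor_h
  }, logical(1))
  peaks <- cand[keep]
  mids <- (br[-1] + br[-length(br)]) / 2
  pos <- mids[peaks]
  if (log_scale) pos <- 10^pos - 1
  structure(length(peaks), positions = pos)
}

#' Count modes of a two-dimensional protein map
#'
#' Two-dimensional analogue of [histogram_peaks()] for per-allele scatter
#' data (e.g. allele-1 versus allele-2 protein content): values are binned
#' on `log10(x + 1)` axes, smoothed with a 3x3 box filter, and local maxima
#' over the 8-neighbourhood with height at least `prominence` times the
#' modal smoothed bin are counted.
#'
#' @param x,y numeric vectors of equal length (>= 100).
#' @param bins bins per axis (default 20).
#' @param prominence height floor as a fraction of the modal smoothed bin.
#' @return integer mode count with attribute `"positions"` (matrix of mode
#'   coordinates on the original scale).
#' @export
histogram_peaks_2d <- function(x, y, bins = 20, prominence = 0.05) {
  if (length(x) != length(y) || length(x) < 100L)
    stop("need equal-length x and y with at least 100 values", call. = FALSE)
  bins <- as.integer(bins)
  lx <- log10(x + 1)
  ly <- log10(y + 1)
  brx <- seq(min(lx), max(lx), length.out = bins + 1L)
  bry <- seq(min(ly), max(ly), length.out = bins + 1L)
  brx[c(1, bins + 1L)] <- brx[c(1, bins + 1L)] + c(-1e-9, 1e-9)
  bry[c(1, bins + 1L)] <- bry[c(1, bins + 1L)] + c(-1e-9, 1e-9)
  ix <- findInterval(lx, brx, rightmost.closed = TRUE)
  iy <- findInterval(ly, bry, rightmost.closed = TRUE)
  h <- matrix(0, bins, bins)
  for (k in seq_along(ix)) h[ix[k], iy[k]] <- h[ix[k], iy[k]] + 1
  # 3x3 box smoothing with edge truncation
  s <- matrix(0, bins, bins)
  for (i in seq_len(bins)) for (j in seq_len(bins)) {
    ii <- max(1L, i - 1L):min(bins, i + 1L)
    jj <- max(1L, j - 1L):min(bins, j + 1L)
    s[i, j] <- mean(h[ii, jj])
  }
  # 0-dimensional topographic persistence: sweep bins from the highest
  # down, growing components; when a component is absorbed by one with a
  # higher peak, its persistence is (its peak height - merge level).
  # Shoulder bumps on the flank of a large mode die immediately; genuine
  # modes persist down to the valley floor.
  nb_cells <- function(c0) {
    i <- (c0 - 1L) %% bins + 1L
    j <- (c0 - 1L) %/% bins + 1L
    ii <- max(1L, i - 1L):min(bins, i + 1L)
    jj <- max(1L, j - 1L):min(bins, j + 1L)
    setdiff(as.vector(outer(ii, jj, function(a, b) a + (b - 1L) * bins)),
            c0)
  }
  vals <- as.vector(s)
  ord <- order(vals, decreasing = TRUE)
  ord <- ord[vals[ord] > 0]
  parent <- integer(bins * bins) # 0 = not yet visited
  find_root <- function(c0) {
    while (parent[c0] != c0) c0 <- parent[c0]
    c0
  }
  peak_cell <- integer(0)
  peak_height <- numeric(0)
  persistence <- numeric(0)
  comp_of_root <- integer(bins * bins)
  for (c0 in ord) {
    roots <- unique(vapply(Filter(function(nn) parent[nn] > 0L,
                                  nb_cells(c0)), find_root, integer(1)))
    if (length(roots) == 0L) {
      parent[c0] <- c0
      peak_cell <- c(peak_cell, c0)
      peak_height <- c(peak_height, vals[c0])
      persistence <- c(persistence, NA_real_)
      comp_of_root[c0] <- length(peak_cell)
    } else {
      comps <- comp_of_root[roots]
      main <- roots[which.max(peak_height[comps])]
      parent[c0] <- main
      for (r in setdiff(roots, main)) {
        dying <- comp_of_root[r]
        persistence[dying] <- peak_height[dying] - vals[c0]
        parent[r] <- main
      }
    }
  }
  persistence[is.na(persistence)] <- peak_height[is.na(persistence)]
  floor_h <- prominence * max(s)
  keep <- persistence >= floor_h
  midx <- (brx[-1] + brx[-length(brx)]) / 2
  midy <- (bry[-1] + bry[-length(bry)]) / 2
  pc <- peak_cell[keep]
  pos <- cbind(x = 10^midx[(pc - 1L) %% bins + 1L] - 1,
               y = 10^midy[(pc - 1L) %/% bins + 1L] - 1)
  structure(sum(keep), positions = pos)
}

#' Time to cross a protein level under deterministic dynamics
#'
#' Inverts the closed-form solution of `dN/dt = s - gamma N`: the time at
#' which a trajectory starting at `n0` reaches `target` while relaxing
#' towards `s_total / gamma`. Returns 0 if `target` already lies at or
#' behind `n0` in the direction of motion, and `Inf` if the target is not
#' reachable (beyond the steady state).
#'
#' @param n0 starting level (molecules).
#' @param target level to cross (molecules).
#' @param s_total total production rate (molecules/hour).
#' @param gamma degradation rate (1/hour).
#' @return crossing time in hours.
#' @export
crossing_time <- function(n0, target, s_total, gamma) {
  stopifnot(gamma > 0)
  ss <- s_total / gamma
  a <- n0 - ss
  b <- target - ss
  if (a == 0) return(0)           # already resting at the steady state
  ratio <- b / a
  if (ratio >= 1) return(0)       # already at least as close as the target
  if (ratio <= 0) return(Inf)     # target on the far side of steady state
  log(a / b) / gamma
}

#' Characteristic lags after allelic switching
#'
#' Summarises the asymmetry between losing and gaining protein after a
#' change of allelic pattern, using the deterministic single-cell dynamics
#' (which are exact between discrete events when transcriptional noise is
#' off). Depletion: a cell at a high-expression steady state switches both
#' alleles off and decays towards the silent steady state; the time to come
#' within `depletion_factor` times the silent level is reported, from both
#' the biallelic and the monoallelic starting state. Build-up: a silent
#' cell at the off/off steady state activates one allele; the time to reach
#' `buildup_fraction` of the monoallelic steady state is reported.
#'
#' @param expr an [expression_params()] object.
#' @param depletion_factor multiple of the silent steady state defining
#'   "depleted" (default 2).
#' @param buildup_fraction fraction of the monoallelic steady state
#'   defining "built up" (default 0.8).
#' @return named list: `depletion_from_biallelic_h`,
#'   `depletion_from_monoallelic_h`, `buildup_to_monoallelic_h`, and the
#'   steady-state levels used.
#' @export
switching_timing <- function(expr = expression_params(),
                             depletion_factor = 2,
                             buildup_fraction = 0.8) {
  g <- expr$gamma_n
  ss_bi <- steady_state(2 * expr$s_on, g)
  ss_mono <- steady_state(expr$s_on + expr$s_off, g)
  ss_off <- steady_state(2 * expr$s_off, g)
  list(
    depletion_from_biallelic_h =
      crossing_time(ss_bi, depletion_factor * ss_off, 2 * expr$s_off, g),
    depletion_from_monoallelic_h =
      crossing_time(ss_mono, depletion_factor * ss_off, 2 * expr$s_off, g),
    buildup_to_monoallelic_h =
      crossing_time(ss_off, buildup_fraction * ss_mono,
                    expr$s_on + expr$s_off, g),
    steady_states = c(biallelic = ss_bi, monoallelic = ss_mono,
                      silent = ss_off))
}
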