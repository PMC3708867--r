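#' Default configuration bundle
#'
#' All model parameters with their default values, as used by
#' [load_config()] to fill unspecified keys.
#'
#' @return named list of class `allelopop_config`.
#' @export
default_config <- function() {
  structure(list(
    z_star = c(0.14, 0.28, 0.28, 0.30),
    shuttle = list(`1-2` = 0.12, `1-3` = 0.12, `2-4` = 0.12, `3-4` = 0.12),
    t_d_hours = 10,
    s_on = 1000,
    s_off = 10,
    half_life_nanog_hours = 2,
    half_life_reporter_hours = 20,
    noise_eta = 0,
    sde_dt_hours = 0.01,
    noise_model = "state",
    mu = 0.465,
    sigma = 0.104,
    q = 39,
    n_cap = 10000,
    nanog_positive_cutoff = 500),
    class = "allelopop_config")
}

#' Load and validate a configuration file
#'
#' Reads a YAML file of model parameters, fills unspecified keys with the
#' defaults of [default_config()], rejects unknown keys, and validates the
#' combination by constructing the corresponding parameter objects (so e.g.
#' shuttle fractions inconsistent with the equilibrium composition are
#' caught here, with the offending field named).
#'
#' @param path path to a YAML file; an empty file yields the full default
#'   bundle.
#' @return validated named list of class `allelopop_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- default_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- modifyList(unclass(defaults), raw)
  class(cfg) <- "allelopop_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  # constructing the parameter objects runs every invariant check
  spec <- config_spec(cfg)
  transition_probabilities(spec)
  config_expression(cfg)
  config_division(cfg)
  if (!isTRUE(cfg$n_cap >= 1)) stop("n_cap must be >= 1", call. = FALSE)
  if (!isTRUE(cfg$nanog_positive_cutoff > 0))
    stop("nanog_positive_cutoff must be > 0", call. = FALSE)
  invisible(cfg)
}

#' Parameter objects from a configuration bundle
#'
#' @param cfg an `allelopop_config` list.
#' @return `config_spec()`: a [transition_spec()]; `config_expression()`:
#'   an [expression_params()]; `config_division()`: a [division_params()].
#' @export
config_spec <- function(cfg) {
  transition_spec(z_star = cfg$z_star, shuttle = as_shuttle_matrix(
    cfg$shuttle), t_d = cfg$t_d_hours)
}

#' @rdname config_spec
#' @export
config_expression <- function(cfg) {
  expression_params(s_on = cfg$s_on, s_off = cfg$s_off,
                    half_life = cfg$half_life_nanog_hours,
                    half_life_reporter = cfg$half_life_reporter_hours,
                    eta = cfg$noise_eta, dt = cfg$sde_dt_hours,
                    noise_model = cfg$noise_model)
}

#' @rdname config_spec
#' @export
config_division <- function(cfg) {
  division_params(mu = cfg$mu, sigma = cfg$sigma, q = cfg$q)
}

#' Write a configuration bundle to YAML
#'
#' @param cfg an `allelopop_config` list.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write a population snapshot as CSV
#'
#' Fixed header `time_h,cell_id,type,n1,n2,n_total,r_total,v`, one row per
#' cell, C-locale decimal points.
#'
#' @param snapshot data frame as returned by [snapshot_at()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(snapshot, path) {
  cols <- c("time_h", "cell_id", "type", "n1", "n2", "n_total",
            "r_total", "v")
  for (cc in setdiff(cols, names(snapshot))) snapshot[[cc]] <- numeric(0)
  out <- snapshot[, cols, drop = FALSE]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a snapshot CSV
#'
#' @param path file written by [write_snapshot()].
#' @return data frame.
#' @export
read_snapshot <- function(path) {
  read.csv(path)
}

# 64-bit-free FNV-1a over the serialized object; stable fingerprint for
# run manifests without external digest dependencies
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h1 <- 2166136261
  h2 <- 16777619
  m <- 2^31
  acc <- h1
  for (b in bytes) acc <- (bitwXor(as.integer(acc %% m), b) * h2) %% m
  sprintf("%08x", as.integer(acc))
}

#' Run manifest
#'
#' Metadata sufficient to reproduce a run bit-exactly: the configuration
#' fingerprint and echo, the seed, the simulated time span and the package
#' version.
#'
#' @param cfg an `allelopop_config` list.
#' @param seed integer seed of the run.
#' @param t_start,t_end simulated time span in hours.
#' @param scenario scenario label.
#' @return named list of class `run_manifest`.
#' @export
run_manifest <- function(cfg, seed, t_start, t_end, scenario = "run") {
  structure(list(
    scenario = scenario,
    config_hash = config_hash(unclass(cfg)),
    seed = seed,
    t_start = t_start,
    t_end = t_end,
    package_version = as.character(utils::packageVersion("allelopop")),
    config = unclass(cfg)),
    class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Run manifest:", x$scenario, "\n")
  cat("  config hash:", x$config_hash, "  seed:", x$seed, "\n")
  cat(sprintf("  simulated %.1f - %.1f h, allelopop %s\n",
              x$t_start, x$t_end, x$package_version))
  invisible(x)
}
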