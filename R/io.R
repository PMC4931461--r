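# Configuration loading and deterministic output writing shared by all
# modules. CSVs are comma-separated with a header row, '.' decimal, no
# index column, floats at 12 significant digits, so identical seed and
# parameters give byte-identical files.

config_keys <- c("scenario", "phi", "k_plus", "k_minus", "K", "h", "mu",
                 "L", "dt", "w", "t_dry", "t_wet", "n_cycles", "t_end",
                 "b", "mu_max", "influx_phase", "seed", "record_every",
                 "mode", "scramble_every_step")

config_ranges <- list(
  phi = c(0, 1), k_plus = c(0, Inf), k_minus = c(0, Inf), K = c(0, Inf),
  h = c(0, Inf), mu = c(0, Inf), L = c(1, Inf), dt = c(1e-12, Inf),
  w = c(0, Inf), t_dry = c(0, Inf), t_wet = c(0, Inf),
  n_cycles = c(1, Inf), t_end = c(0, Inf), b = c(0, Inf),
  mu_max = c(1e-12, Inf), record_every = c(0, Inf))

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) mapping of run parameters, rejects unknown
#' keys, range-checks every value against the model invariants, and
#' completes the rate pair: a config giving `K` and `k_plus` but not
#' `k_minus` has `k_minus` derived from the identity `K =
#' k_plus / k_minus` (and vice versa).
#'
#' @param path Path to a YAML/JSON configuration file.
#' @return Named list of validated parameters.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines(c("scenario: polymer-diffusion", "mu: 2", "K: 54.598",
#'              "k_plus: 1"), f)
#' load_config(f)$k_minus
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' Validate a parameter set against the model invariants
#'
#' The checking backend of [load_config()], usable directly on an
#' in-memory list: rejects unknown keys and out-of-range values, and
#' completes the `K = k_plus / k_minus` identity.
#'
#' @param cfg Named list of parameters.
#' @return The validated (possibly completed) list.
#' @export
validate_config <- function(cfg) {
  if (!is.list(cfg)) stop("configuration must be a mapping", call. = FALSE)
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown))
    stop("configuration error: unknown key(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (key in intersect(names(cfg), names(config_ranges))) {
    v <- cfg[[key]]
    r <- config_ranges[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < r[1] || v > r[2])
      stop(sprintf(
        "configuration error: range violation for \"%s\" (allowed [%g, %g])",
        key, r[1], r[2]), call. = FALSE)
  }
  if (!is.null(cfg$scenario) && !cfg$scenario %in% scenario_names)
    stop("configuration error: unknown scenario \"", cfg$scenario, "\"",
         call. = FALSE)
  kp <- cfg$k_plus
  if (!is.null(kp)) {
    if (is.null(cfg$k_minus) && !is.null(cfg$K))
      cfg$k_minus <- kp / cfg$K
    if (is.null(cfg$K) && !is.null(cfg$k_minus) && cfg$k_minus > 0)
      cfg$K <- kp / cfg$k_minus
    if (!is.null(cfg$K) && !is.null(cfg$k_minus) && cfg$k_minus > 0 &&
        abs(cfg$K - kp / cfg$k_minus) > 1e-8 * max(1, cfg$K))
      stop("configuration error: K != k_plus / k_minus", call. = FALSE)
  }
  cfg
}

#' Save a configuration to YAML
#'
#' Inverse of [load_config()]: `load_config(save_config(cfg, f))`
#' returns `cfg` (up to derived fields already present).
#'
#' @param cfg Named list of parameters.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

fmt_num <- function(x) {
  if (is.numeric(x) && !is.integer(x)) signif(x, 12) else x
}

write_csv_det <- function(df, path) {
  df[] <- lapply(df, fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write the standard output files of a run
#'
#' Emits, in a fixed column order: `timeseries.csv` (`time, phase,
#' mean_length, total_strands, total_monomers` for lattice runs; the
#' per-cycle table for the dimer scenario), `length_histogram.csv`
#' (`length, count, concentration_per_site`), `occupancy.csv`
#' (`n, site_count`), and `metadata.json` (parameters, seed, software
#' version, clamp count). Identical seed and parameters produce
#' byte-identical CSVs.
#'
#' @param run A `drywet_run` from [run_scenario()].
#' @param out_dir Output directory, created if needed.
#' @return Character vector of the files written, invisibly.
#' @export
write_run_outputs <- function(run, out_dir) {
  stopifnot(inherits(run, "drywet_run"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  files <- character()
  ts <- file.path(out_dir, "timeseries.csv")
  write_csv_det(run$series, ts)
  files <- ts
  if (!is.null(run$state)) {
    hist_df <- measure_length_distribution(run$state)
    names(hist_df) <- c("length", "count", "concentration_per_site")
    hp <- file.path(out_dir, "length_histogram.csv")
    write_csv_det(hist_df, hp)
    occ <- site_occupancy_distribution(run$state)
    names(occ) <- c("n", "site_count")
    op <- file.path(out_dir, "occupancy.csv")
    write_csv_det(occ, op)
    files <- c(files, hp, op)
  }
  meta <- run_metadata(run)
  mp <- file.path(out_dir, "metadata.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, mp))
}

#' Run metadata record
#'
#' Flattened parameters plus seed, package version, clamp counter and
#' convergence flags; serializes losslessly to JSON.
#'
#' @param run A `drywet_run`.
#' @return Named list.
#' @export
run_metadata <- function(run) {
  list(scenario = run$scenario,
       parameters = run$params[!vapply(run$params, is.list, logical(1))],
       seed = run$seed,
       software_version =
         as.character(utils::packageVersion("drywet")),
       clamp_count = if (!is.null(run$state)) run$state$clamp_count else 0,
       converged = if (!is.null(attr(run$series, "converged")))
         attr(run$series, "converged") else NA)
}
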