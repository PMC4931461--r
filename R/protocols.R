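# Named scenario presets composing dry phases, wet phases, scrambling
# and influx, with the matching analytic overlays. Presets pin the
# canonical parameter sets (k_plus = 1, K = exp(4) or exp(2), phi = 0.2,
# mu = 2, w, t_dry = 8, t_wet = 0.5, b = 5, mu_max = 20); any field can
# be overridden per call.

#' Wet-dry cycling protocol for the lattice model
#'
#' @param t_dry,t_wet Phase durations (time, >= 0).
#' @param w Wet-phase hydrolysis rate per bond (1/time).
#' @param n_cycles Number of cycles (>= 1).
#' @param scramble_every_step Run in the well-mixed limit (scramble
#'   after every sweep) instead of cycling; mutually exclusive with
#'   multi-cycle schedules.
#' @param influx Optional `list(b =, mu_max =)` monomer influx.
#' @param influx_phase Phase during which influx operates: `"wet"` (the
#'   cycling interpretation) or `"dry"` (the diffusive interpretation).
#' @param h_dry Dry-phase hopping rate (1/time).
#' @param dt Timestep (time).
#' @return An object of class `cycle_protocol`.
#' @export
cycle_protocol <- function(t_dry = 8, t_wet = 0.5, w = 0.2, n_cycles = 1,
                           scramble_every_step = FALSE, influx = NULL,
                           influx_phase = c("wet", "dry"), h_dry = 0,
                           dt = 0.01) {
  influx_phase <- match.arg(influx_phase)
  stopifnot(t_dry >= 0, t_wet >= 0, w >= 0, n_cycles >= 1, dt > 0,
            h_dry >= 0)
  if (scramble_every_step && n_cycles > 1)
    stop("'scramble_every_step' is mutually exclusive with cycling",
         call. = FALSE)
  if (!is.null(influx) && (is.null(influx$b) || is.null(influx$mu_max)))
    stop("configuration error: 'influx' needs fields 'b' and 'mu_max'",
         call. = FALSE)
  structure(list(t_dry = t_dry, t_wet = t_wet, w = w,
                 n_cycles = as.integer(n_cycles),
                 scramble_every_step = scramble_every_step,
                 influx = influx, influx_phase = influx_phase,
                 h_dry = h_dry, dt = dt),
            class = "cycle_protocol")
}

scenario_names <- c("dimer-cycling", "polymer-diffusion",
                    "polymer-nodiffusion", "polymer-cycling",
                    "polymer-cycling-nohydrolysis", "polymer-influx")

scenario_preset <- function(name) {
  switch(name,
    "dimer-cycling" = list(phi = 0.2, k_plus = 1, K = exp(2), w = 1,
                           t_dry = 8, t_wet = 0.5, n_cycles = 30,
                           mode = "local-equilibrium"),
    "polymer-diffusion" = list(L = 100, mu = 2, k_plus = 1, K = exp(4),
                               h = 1, dt = 0.01, t_end = 400),
    "polymer-nodiffusion" = list(L = 100, mu = 2, k_plus = 1, K = exp(4),
                                 h = 0, dt = 0.01, t_end = 400),
    "polymer-cycling" = list(L = 100, mu = 2, k_plus = 1, K = exp(4),
                             w = 0.2, t_dry = 8, t_wet = 0.5, dt = 0.01,
                             n_cycles = 50),
    "polymer-cycling-nohydrolysis" = list(L = 100, mu = 2, k_plus = 1,
                                          K = exp(4), w = 0, t_dry = 8,
                                          t_wet = 0, dt = 0.01,
                                          n_cycles = 50),
    "polymer-influx" = list(L = 100, mu = 2, k_plus = 1, K = exp(4),
                            b = 5, mu_max = 20, w = 0.2, t_dry = 8,
                            t_wet = 0.5, dt = 0.01, n_cycles = 50,
                            influx_phase = "wet", h = 0, t_end = 400),
    stop(sprintf("unknown scenario '%s'", name), call. = FALSE))
}

require_fields <- function(p, fields, name) {
  missing <- setdiff(fields, names(p))
  if (length(missing))
    stop(sprintf("configuration error for scenario '%s': missing %s",
                 name, paste(missing, collapse = ", ")), call. = FALSE)
  bad <- fields[vapply(p[fields], function(v) is.null(v) || any(is.na(v)),
                       logical(1))]
  if (length(bad))
    stop(sprintf("configuration error for scenario '%s': missing %s",
                 name, paste(bad, collapse = ", ")), call. = FALSE)
  invisible(p)
}

#' Run a named simulation scenario with its theory overlay
#'
#' The five canonical experiments: `"dimer-cycling"` (analytic cycling
#' map of the dimer model with the closed-form limit as overlay),
#' `"polymer-diffusion"` (single dry phase, hopping at `h`),
#' `"polymer-nodiffusion"` (single dry phase, `h = 0`),
#' `"polymer-cycling"` (dry phases with `h = 0` alternating with wet
#' hydrolysis and repositioning), `"polymer-cycling-nohydrolysis"`
#' (`t_wet = 0`: repositioning only) and `"polymer-influx"` (monomer
#' influx up to `mu_max`, either during wet phases of a cycling run,
#' `influx_phase = "wet"`, or during a diffusive dry run,
#' `influx_phase = "dry"`). Every preset parameter can be overridden
#' through `...`.
#'
#' @param name Scenario name (see above).
#' @param ... Preset overrides (e.g. `L = 50`, `t_end = 200`,
#'   `scramble_every_step = TRUE`).
#' @param seed Optional integer seed applied via [set.seed()].
#' @param record_every Recording interval in sweeps for the lattice
#'   scenarios.
#' @return An object of class `drywet_run`: list with `scenario`,
#'   `params`, `series` (time series or per-cycle data frame), `state`
#'   (final `polymer_state`, lattice scenarios only), and `theory`
#'   (analytic overlay values).
#' @examples
#' run <- run_scenario("dimer-cycling", n_cycles = 10)
#' head(run$series)
#' @export
run_scenario <- function(name, ..., seed = NULL, record_every = 25L) {
  name <- match.arg(name, scenario_names)
  p <- utils::modifyList(scenario_preset(name), list(...))
  if (!is.null(seed)) set.seed(seed)
  out <- switch(name,
    "dimer-cycling" = run_dimer_cycling(p),
    "polymer-diffusion" = ,
    "polymer-nodiffusion" = run_polymer_dry(p, name, record_every),
    "polymer-cycling" = ,
    "polymer-cycling-nohydrolysis" = ,
    "polymer-influx" = run_polymer_cycling(p, name, record_every))
  out$scenario <- name
  out$params <- p
  out$seed <- seed
  class(out) <- "drywet_run"
  out
}

run_dimer_cycling <- function(p) {
  require_fields(p, c("phi", "K", "w", "t_dry", "t_wet", "n_cycles"),
                 "dimer-cycling")
  sch <- cycle_schedule(p$t_dry, p$t_wet, p$w, p$n_cycles)
  cyc <- dimer_cycles(p$phi, p$K, sch, mode = p$mode,
                      k_plus = p$k_plus,
                      k_minus = if (!is.null(p$k_plus)) p$k_plus / p$K)
  lim <- dimer_cycling_limit(p$phi, p$K, p$w, p$t_wet)
  cyc$PD_dry_limit <- lim[["PD_dry"]]
  cyc$PD_wet_limit <- lim[["PD_wet"]]
  list(series = cyc,
       theory = list(cycling_limit = lim,
                     PD_equilibrium_diffusion =
                       dimer_equilibrium_diffusion(p$phi, p$K)[["PD"]],
                     PD_local_equilibrium =
                       dimer_local_equilibrium(p$phi, p$K)))
}

polymer_theory <- function(p, mu_eq) {
  list(eq_mean_length = mean_length_equilibrium(p$K, mu_eq),
       eq_x = equilibrium_x(p$K, mu_eq),
       eq_lambda = equilibrium_lambda(p$K, mu_eq))
}

run_polymer_dry <- function(p, name, record_every) {
  require_fields(p, c("L", "mu", "k_plus", "K", "h", "dt", "t_end"), name)
  sp <- sim_params(p$k_plus, p$k_plus / p$K, p$h, p$dt)
  st <- lattice_init(p$L, mu = p$mu)
  scr <- isTRUE(p$scramble_every_step)
  st <- dry_run(st, sp, t = p$t_end, scramble_each = scr,
                influx = if (identical(p$influx_phase, "dry"))
                  list(b = p$b, mu_max = p$mu_max),
                record_every = record_every)
  list(series = attr(st, "series"), state = st,
       theory = polymer_theory(p, p$mu))
}

run_polymer_cycling <- function(p, name, record_every) {
  require_fields(p, c("L", "mu", "k_plus", "K", "w", "t_dry", "t_wet",
                      "dt", "n_cycles"), name)
  influx <- if (name == "polymer-influx") {
    require_fields(p, c("b", "mu_max", "influx_phase"), name)
    list(b = p$b, mu_max = p$mu_max)
  }
  if (!is.null(influx) && identical(p$influx_phase, "dry"))
    return(run_polymer_dry(p, name, record_every))
  sp <- sim_params(p$k_plus, p$k_plus / p$K,
                   if (is.null(p$h_dry)) 0 else p$h_dry, p$dt)
  st <- lattice_init(p$L, mu = p$mu)
  pieces <- vector("list", 2L * p$n_cycles)
  for (i in seq_len(p$n_cycles)) {
    st <- dry_run(st, sp, t = p$t_dry, record_every = record_every)
    pieces[[2L * i - 1L]] <- attr(st, "series")
    st <- wet_phase(st, p$w, p$t_wet, p$dt, influx = influx,
                    record_every = min(record_every,
                                       max(1, ceiling(p$t_wet / p$dt))))
    pieces[[2L * i]] <- attr(st, "series")
  }
  mu_eq <- if (is.null(influx)) p$mu else p$mu_max
  list(series = do.call(rbind, pieces), state = st,
       theory = polymer_theory(p, mu_eq))
}

#' @export
print.drywet_run <- function(x, ...) {
  cat(sprintf("drywet run: scenario '%s'\n", x$scenario))
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  if (!is.null(x$series))
    cat(sprintf("  series: %d rows\n", nrow(x$series)))
  if (!is.null(x$state))
    cat(sprintf("  final mean length: %.4g (theory equilibrium %.4g)\n",
                measure_mean_length(x$state), x$theory$eq_mean_length))
  invisible(x)
}

#' Long-run mean length of a scenario run
#'
#' Averages the recorded mean length over the final quarter of the run,
#' the package's equilibration convention for "long-run" comparisons
#' against analytic limits.
#'
#' @param run A `drywet_run` from [run_scenario()], or its `series`
#'   data frame.
#' @param frac Fraction of the series (by time, from the end) to
#'   average over.
#' @param phase Optional phase filter (`"dry"` or `"wet"`).
#' @return Mean of `mean_length` over the selected window.
#' @export
long_run_mean <- function(run, frac = 0.25, phase = NULL) {
  ser <- if (inherits(run, "drywet_run")) run$series else run
  if (!is.null(phase)) ser <- ser[ser$phase == phase, ]
  t1 <- max(ser$time)
  t0 <- t1 - frac * (t1 - min(ser$time))
  mean(ser$mean_length[ser$time >= t0])
}

#' Long-run mean lengths over replicate seeds
#'
#' Runs a scenario once per seed and returns each replicate's long-run
#' mean length, the basis for confidence-interval comparisons with the
#' analytic equilibrium values.
#'
#' @param name Scenario name for [run_scenario()].
#' @param seeds Integer vector of seeds.
#' @param ... Preset overrides passed to [run_scenario()].
#' @param frac Averaging window passed to [long_run_mean()].
#' @return Numeric vector, one long-run mean length per seed.
#' @export
replicate_longrun <- function(name, seeds, ..., frac = 0.25) {
  vapply(seeds,
         function(s) long_run_mean(run_scenario(name, ..., seed = s),
                                   frac = frac),
         numeric(1))
}
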