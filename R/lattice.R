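# Stochastic lattice model of reversible polymerization. A state is a
# set of strands, each with a site (1..N on an L x L torus) and a length
# in monomers. All stochastic updates use R's global RNG, so set.seed()
# makes entire runs reproducible.

#' Simulation parameters for the lattice polymerization model
#'
#' @param k_plus Dry-phase bond-formation rate per strand pair on a site
#'   (1/time).
#' @param k_minus Dry-phase hydrolysis rate per bond (1/time).
#' @param h Strand hopping rate (1/time); a hop moves a strand to one of
#'   the 8 Moore neighbours and is always accepted (sites have no
#'   occupancy limit).
#' @param dt Timestep (time, > 0). The per-event probabilities
#'   `k_plus*n*(n-1)*dt`, `k_minus*(m-1)*dt` and `h*dt` should stay well
#'   below 1; any clamped probability is counted in the state's
#'   `clamp_count`.
#' @return An object of class `sim_params`.
#' @examples
#' sim_params(k_plus = 1, k_minus = exp(-4), h = 1)
#' @export
sim_params <- function(k_plus = 1, k_minus = exp(-4), h = 0, dt = 0.01) {
  stopifnot(k_plus >= 0, k_minus >= 0, h >= 0, dt > 0)
  structure(list(k_plus = k_plus, k_minus = k_minus, h = h, dt = dt),
            class = "sim_params")
}

#' Random initial lattice state
#'
#' Places `m_tot` monomers (strands of length 1) independently and
#' uniformly over the `L * L` sites of a periodic square lattice, so
#' per-site counts are multinomial (Poisson in the large-lattice limit)
#' with mean `mu = m_tot / L^2`.
#'
#' @param L Lattice side length (>= 1 site).
#' @param m_tot Total number of monomers (>= 0); alternatively give
#'   `mu`.
#' @param mu Mean monomers per site; used as `m_tot = round(mu * L^2)`
#'   when `m_tot` is missing.
#' @return An object of class `polymer_state`: a list with integer
#'   vectors `site` and `len` (one entry per strand), lattice side `L`,
#'   site count `N`, current `time`, and cumulative `clamp_count`.
#' @examples
#' set.seed(1)
#' lattice_init(L = 10, mu = 2)
#' @export
lattice_init <- function(L, m_tot = NULL, mu = NULL) {
  stopifnot(L >= 1)
  N <- as.integer(L)^2
  if (is.null(m_tot)) {
    if (is.null(mu)) stop("supply 'm_tot' or 'mu'", call. = FALSE)
    m_tot <- round(mu * N)
  }
  if (m_tot < 0) stop("'m_tot' must be non-negative", call. = FALSE)
  new_polymer_state(site = sample.int(N, m_tot, replace = TRUE),
                    len = rep(1L, m_tot), L = as.integer(L))
}

#' Lattice state with explicit strand placement
#'
#' Builds a state from given strand lengths and site assignments, e.g.
#' to start from a prepared configuration (all strands on one site,
#' a given length distribution, ...).
#'
#' @param lengths Integer vector of strand lengths (all >= 1).
#' @param sites Integer vector of site indices in `1..L^2`, recycled to
#'   `length(lengths)`.
#' @param L Lattice side length.
#' @return A `polymer_state`.
#' @export
lattice_state_from <- function(lengths, sites, L) {
  stopifnot(L >= 1, all(lengths >= 1))
  sites <- rep_len(as.integer(sites), length(lengths))
  if (length(lengths) && (min(sites) < 1 || max(sites) > L^2))
    stop("'sites' must lie in 1..L^2", call. = FALSE)
  new_polymer_state(site = sites, len = as.integer(lengths),
                    L = as.integer(L))
}

new_polymer_state <- function(site, len, L, time = 0, clamp_count = 0) {
  structure(list(site = as.integer(site), len = as.integer(len),
                 L = L, N = L^2L, time = time, clamp_count = clamp_count),
            class = "polymer_state")
}

#' @export
print.polymer_state <- function(x, ...) {
  cat(sprintf("polymer_state: %d x %d lattice, t = %g\n", x$L, x$L, x$time))
  cat(sprintf("  %d strands, %d monomers (mu = %.4g), mean length %.4g\n",
              length(x$len), sum(x$len), sum(x$len) / x$N,
              measure_mean_length(x)))
  if (x$clamp_count > 0)
    cat(sprintf("  warning: %g clamped event probabilities\n", x$clamp_count))
  invisible(x)
}

#' @export
summary.polymer_state <- function(object, ...) {
  h <- measure_length_distribution(object)
  cat(sprintf("polymer_state on %d sites at t = %g\n", object$N, object$time))
  cat(sprintf("  monomer density mu = %.4g, strands = %d, mean length = %.4g\n",
              sum(object$len) / object$N, length(object$len),
              measure_mean_length(object)))
  cat(sprintf("  length range %d..%d over %d length classes\n",
              if (nrow(h)) min(h$length) else 0L,
              if (nrow(h)) max(h$length) else 0L, nrow(h)))
  invisible(h)
}

unpack_run <- function(state, res) {
  state$site <- res$site + 1L
  state$len <- res$len
  state$clamp_count <- state$clamp_count + res$clamp_count
  state
}

run_series <- function(res, phase) {
  if (!length(res$rec_time)) return(NULL)
  data.frame(time = res$rec_time, phase = phase,
             mean_length = res$rec_monomers / res$rec_strands,
             total_strands = res$rec_strands,
             total_monomers = res$rec_monomers)
}

#' Advance the dry-phase dynamics
#'
#' Runs `n_steps` fixed-timestep Monte Carlo sweeps. Each sweep, in
#' order: (1) every site holding `n >= 2` strands forms one bond with
#' probability `min(1, k_plus*n*(n-1)*dt)`, joining two distinct
#' uniformly chosen strands on the site; (2) every strand of length
#' `m >= 2` breaks with probability `min(1, k_minus*(m-1)*dt)` at a
#' uniformly chosen bond, both fragments staying on the site (fragments
#' are not re-broken within the sweep); (3) every strand hops with
#' probability `h*dt` to a uniform Moore neighbour. The total monomer
#' count is conserved (unless `influx` is given) and clamped
#' probabilities are accumulated in `clamp_count`.
#'
#' @param state A `polymer_state`.
#' @param params A [sim_params()] object.
#' @param n_steps Number of sweeps; alternatively give `t` (duration),
#'   rounded up to whole sweeps.
#' @param t Duration in model time (used when `n_steps` is missing).
#' @param scramble_each If `TRUE`, every strand is moved to a uniformly
#'   random site after each sweep — the well-mixed limit `h >> 1`.
#' @param influx Optional list `list(b =, mu_max =)`: after each sweep,
#'   a Poisson-distributed number of new monomers with mean
#'   `N*b*(1 - mu/mu_max)*dt` is added at uniform sites (none once
#'   `mu >= mu_max`).
#' @param record_every Record `(time, mean_length, ...)` every this many
#'   sweeps into the `series` attribute of the result (0 = no record).
#' @return The updated `polymer_state`; if `record_every > 0` the
#'   time series is attached as `attr(, "series")`.
#' @examples
#' set.seed(1)
#' st <- lattice_init(L = 10, mu = 2)
#' st <- dry_run(st, sim_params(h = 1), n_steps = 100)
#' measure_mean_length(st)
#' @export
dry_run <- function(state, params, n_steps = NULL, t = NULL,
                    scramble_each = FALSE, influx = NULL,
                    record_every = 0L) {
  stopifnot(inherits(state, "polymer_state"), inherits(params, "sim_params"))
  if (is.null(n_steps)) {
    if (is.null(t)) stop("supply 'n_steps' or 't'", call. = FALSE)
    n_steps <- ceiling(t / params$dt)
  }
  if (n_steps < 0) stop("'n_steps' must be non-negative", call. = FALSE)
  b <- if (is.null(influx)) -1 else influx$b
  mu_max <- if (is.null(influx)) 1 else influx$mu_max
  res <- cpp_dry_run(state$site - 1L, state$len, state$L,
                     params$k_plus, params$k_minus, params$h,
                     params$dt, as.integer(n_steps), state$time,
                     scramble_each, b, mu_max, as.integer(record_every))
  series <- run_series(res, "dry")
  state <- unpack_run(state, res)
  state$time <- state$time + n_steps * params$dt
  if (!is.null(series)) attr(state, "series") <- series
  state
}

#' Single dry-phase sweep
#'
#' Convenience wrapper for one fixed-timestep sweep of [dry_run()].
#'
#' @inheritParams dry_run
#' @return The updated `polymer_state`.
#' @export
dry_step <- function(state, params) dry_run(state, params, n_steps = 1L)

#' Scramble strand positions
#'
#' Moves every strand independently to a uniformly random site, leaving
#' the multiset of strand lengths untouched. Applying this after every
#' sweep realizes the well-mixed limit; applying it once models the
#' random repositioning at the end of a wet phase.
#'
#' @param state A `polymer_state`.
#' @return The state with randomized positions.
#' @export
scramble <- function(state) {
  stopifnot(inherits(state, "polymer_state"))
  state$site <- cpp_scramble(length(state$len), state$N)
  state
}

#' Wet phase: dilute hydrolysis followed by repositioning
#'
#' For `ceiling(t_wet/dt)` sweeps, each strand of length `m` breaks with
#' probability `min(1, w*(m-1)*dt)` at a uniform bond; there is no bond
#' formation and no hopping (the wet phase is dilute and positions are
#' irrelevant). At the end of the phase every strand is moved to a
#' random site. With `t_wet = 0` only the repositioning occurs.
#'
#' @param state A `polymer_state`.
#' @param w Wet-phase hydrolysis rate per bond (1/time).
#' @param t_wet Wet-phase duration (time, >= 0).
#' @param dt Timestep (time).
#' @param influx Optional `list(b =, mu_max =)` monomer influx applied
#'   during wet sweeps (see [dry_run()]).
#' @param record_every Recording interval in sweeps (0 = none).
#' @return The updated `polymer_state` (series attached as in
#'   [dry_run()] when recording).
#' @export
wet_phase <- function(state, w, t_wet, dt = 0.01, influx = NULL,
                      record_every = 0L) {
  stopifnot(inherits(state, "polymer_state"), w >= 0, t_wet >= 0, dt > 0)
  if (t_wet > 0 || !is.null(influx)) {
    n_steps <- ceiling(t_wet / dt)
    b <- if (is.null(influx)) -1 else influx$b
    mu_max <- if (is.null(influx)) 1 else influx$mu_max
    res <- cpp_wet_run(state$site - 1L, state$len, state$N, w, dt,
                       as.integer(n_steps), state$time, b, mu_max,
                       as.integer(record_every))
    series <- run_series(res, "wet")
    state <- unpack_run(state, res)
    state$time <- state$time + n_steps * dt
    if (!is.null(series)) attr(state, "series") <- series
  }
  scramble(state)
}

#' Add monomers by influx for one timestep
#'
#' Draws `k ~ Poisson(N*b*(1 - mu/mu_max)*dt)` with `mu` the current
#' monomer density and adds `k` new monomers at uniformly random sites;
#' nothing is added once `mu >= mu_max`. The ensemble mean density
#' follows `dmu/dt = b*(1 - mu/mu_max)`, i.e. influx balanced by efflux
#' (or synthesis balanced by breakdown) at `mu = mu_max`.
#'
#' @param state A `polymer_state`.
#' @param b Influx rate (monomers per site per time).
#' @param mu_max Ceiling density (monomers per site, > 0).
#' @param dt Timestep (time).
#' @return The updated `polymer_state` (time unchanged; influx is part
#'   of a sweep, not a sweep itself).
#' @export
apply_influx <- function(state, b, mu_max, dt = 0.01) {
  stopifnot(inherits(state, "polymer_state"), b >= 0, mu_max > 0, dt > 0)
  mu <- sum(state$len) / state$N
  if (mu >= mu_max) return(state)
  k <- stats::rpois(1, state$N * b * (1 - mu / mu_max) * dt)
  if (k > 0) {
    state$site <- c(state$site, sample.int(state$N, k, replace = TRUE))
    state$len <- c(state$len, rep(1L, k))
  }
  state
}

#' Mean strand length
#'
#' Total monomers divided by total strands; `NaN` for an empty state.
#'
#' @param state A `polymer_state`.
#' @return Mean length in monomers.
#' @export
measure_mean_length <- function(state) {
  if (length(state$len) == 0L) return(NaN)
  sum(state$len) / length(state$len)
}

#' Strand length histogram
#'
#' @param state A `polymer_state`.
#' @return Data frame with columns `length`, `count` and `conc`
#'   (count per lattice site), restricted to lengths present;
#'   `sum(length * count)` equals the total monomer count exactly.
#' @export
measure_length_distribution <- function(state) {
  if (length(state$len) == 0L)
    return(data.frame(length = integer(), count = integer(),
                      conc = numeric()))
  tab <- tabulate(state$len)
  keep <- which(tab > 0L)
  data.frame(length = keep, count = tab[keep], conc = tab[keep] / state$N)
}

#' Site occupancy histogram
#'
#' Number of lattice sites holding `n = 0, 1, 2, ...` strands. After a
#' scramble this is multinomial, Poisson(`total_strands / N`) for large
#' lattices.
#'
#' @param state A `polymer_state`.
#' @return Data frame with columns `n` and `sites`;
#'   `sum(n * sites)` equals the total strand count.
#' @export
site_occupancy_distribution <- function(state) {
  per_site <- tabulate(state$site, nbins = state$N)
  tab <- table(per_site)
  data.frame(n = as.integer(names(tab)), sites = as.integer(tab))
}
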