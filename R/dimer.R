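# Mean-field theory of dimer formation on a partially occupied lattice.
# Sites hold 0, 1 or 2 monomers or 1 dimer; two monomers on a site can
# condense into a dimer (rate k+), dimers break at rate k-, and monomers
# hop between sites at rate h. All results here are analytic or ODE-based;
# the stochastic machinery lives in the polymer lattice simulator.

#' Parameter set for the dimer-formation model
#'
#' Bundles the monomer density and the reaction/hopping rates of the
#' dimer model. Exactly one of `k_minus` and `K` may be omitted; the
#' other is derived from the identity `K = k_plus / k_minus`.
#'
#' @param phi Monomer density relative to the maximum occupancy of two
#'   monomers per site (dimensionless, in `[0, 1]`).
#' @param k_plus Dimerization rate (1/time).
#' @param k_minus Dimer breakup rate (1/time). If `NULL`, derived as
#'   `k_plus / K`.
#' @param K Equilibrium constant `k_plus / k_minus` (dimensionless). If
#'   `NULL`, derived from the rates. `k_minus = 0` corresponds to
#'   `K = Inf`.
#' @param h Monomer hopping rate (1/time); `h = 0` disables diffusion.
#' @return An object of class `dimer_params`.
#' @examples
#' dimer_params(phi = 0.2, k_plus = 1, k_minus = exp(-2), h = 1)
#' @export
dimer_params <- function(phi, k_plus = 1, k_minus = NULL, K = NULL, h = 0) {
  stopifnot(is.numeric(phi), length(phi) == 1L)
  if (phi < 0 || phi > 1) stop("'phi' must lie in [0, 1]", call. = FALSE)
  if (k_plus < 0 || h < 0) stop("rates must be non-negative", call. = FALSE)
  if (is.null(k_minus) && is.null(K))
    stop("supply at least one of 'k_minus' and 'K'", call. = FALSE)
  if (is.null(k_minus)) k_minus <- if (is.infinite(K)) 0 else k_plus / K
  if (k_minus < 0) stop("rates must be non-negative", call. = FALSE)
  if (is.null(K)) K <- if (k_minus == 0) Inf else k_plus / k_minus
  if (is.finite(K) && k_minus > 0 &&
      abs(K - k_plus / k_minus) > 1e-8 * max(1, K))
    stop("inconsistent parameters: K != k_plus / k_minus", call. = FALSE)
  structure(list(phi = phi, k_plus = k_plus, k_minus = k_minus, K = K, h = h),
            class = "dimer_params")
}

#' Site-type fractions for randomly placed monomers
#'
#' The state of the dimer model is the vector of fractions of sites
#' holding 0 monomers, 1 monomer, 2 monomers, or 1 dimer. When `m`
#' monomers are dropped independently at random onto the lattice at
#' density `phi` with no dimers present, the per-site occupancy is
#' binomial, giving `(P0, P1, P2, PD) = ((1-phi)^2, 2*phi*(1-phi),
#' phi^2, 0)`.
#'
#' @param phi Monomer density in `[0, 1]`.
#' @return Named numeric vector `c(P0, P1, P2, PD)` summing to 1.
#' @examples
#' dimer_initial_probs(0.2)
#' @export
dimer_initial_probs <- function(phi) {
  if (!is.numeric(phi) || length(phi) != 1L || is.na(phi) || phi < 0 || phi > 1)
    stop("'phi' must be a single number in [0, 1]", call. = FALSE)
  c(P0 = (1 - phi)^2, P1 = 2 * phi * (1 - phi), P2 = phi^2, PD = 0)
}

#' Integrate the mean-field rate equations of the dimer model
#'
#' Solves the four coupled ODEs for the site-type fractions:
#' hopping exchanges `2 + 0 <-> 1 + 1` (the only hopping process that
#' changes site counts in mean field), dimerization `P2 -> PD` at
#' `k_plus` and breakup at `k_minus`. The trajectory conserves both the
#' vacancy fraction `P0 + P1/2` and the occupied fraction
#' `P1/2 + P2 + PD`.
#'
#' @param params A [dimer_params()] object.
#' @param init Initial state, e.g. [dimer_initial_probs()].
#' @param t_end Final time (> 0).
#' @param report_dt Output spacing; defaults to `t_end / 200`.
#' @param rtol,atol Integrator tolerances passed to [deSolve::ode()].
#' @return Data frame with columns `time, P0, P1, P2, PD`.
#' @examples
#' p <- dimer_params(0.2, k_plus = 1, K = exp(2), h = 1)
#' tail(dimer_meanfield(p, dimer_initial_probs(0.2), t_end = 200), 1)
#' @export
dimer_meanfield <- function(params, init, t_end, report_dt = NULL,
                            rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(params, "dimer_params"), t_end > 0)
  check_site_probs(init)
  if (is.null(report_dt)) report_dt <- t_end / 200
  times <- unique(c(seq(0, t_end, by = report_dt), t_end))
  rhs <- function(t, y, p) {
    hop <- p$h * (0.5 * y[2]^2 - 2 * y[1] * y[3])
    react <- p$k_plus * y[3] - p$k_minus * y[4]
    list(c(hop, -2 * hop, hop - react, react))
  }
  out <- deSolve::ode(y = unname(init), times = times, func = rhs,
                      parms = params, rtol = rtol, atol = atol)
  if (any(!is.finite(out)))
    stop(sprintf("integration produced non-finite state near t = %g",
                 out[which(!is.finite(out[, 2]))[1], 1]), call. = FALSE)
  out <- as.data.frame(out)
  names(out) <- c("time", "P0", "P1", "P2", "PD")
  out
}

check_site_probs <- function(p, tol = 1e-7) {
  if (length(p) != 4L || any(!is.finite(p)) || any(p < -tol) || any(p > 1 + tol))
    stop("site probabilities must be 4 values in [0, 1]", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6)
    stop("site probabilities must sum to 1", call. = FALSE)
  invisible(p)
}

#' Dimer-model equilibrium when diffusion is permitted
#'
#' Closed-form solution of the simultaneous equilibrium conditions:
#' constant vacancy fraction, constant occupied fraction, dimer balance
#' `PD = K * P2`, and diffusion balance `4 * P0 * P2 = P1^2`. The
#' quadratic is evaluated in the cancellation-safe conjugate form so the
#' `K -> 0` and `K -> Inf` limits are exact.
#'
#' @param phi Monomer density in `[0, 1]`.
#' @param K Equilibrium constant (> 0, `Inf` allowed).
#' @return Named vector `c(P0, P1, P2, PD)`.
#' @examples
#' dimer_equilibrium_diffusion(0.2, exp(2))
#' @export
dimer_equilibrium_diffusion <- function(phi, K) {
  if (phi < 0 || phi > 1) stop("'phi' must lie in [0, 1]", call. = FALSE)
  if (!(K > 0)) stop("'K' must be positive", call. = FALSE)
  if (is.infinite(K))
    return(c(P0 = 1 - phi, P1 = 0, P2 = 0, PD = phi))
  s <- sqrt(1 + 4 * K * phi * (1 - phi))
  # P1 = (-1 + s)/K rewritten to avoid cancellation at small K
  P1 <- 4 * phi * (1 - phi) / (1 + s)
  # 1 + 2*K*phi - s = 4*K*phi^2*(1+K) / (1 + 2*K*phi + s)
  P2 <- 2 * phi^2 / (1 + 2 * K * phi + s)
  PD <- K * P2
  c(P0 = 1 - phi - P1 / 2, P1 = P1, P2 = P2, PD = PD)
}

#' Local reaction equilibrium without diffusion
#'
#' With no hopping, dimers can only form on sites that start with two
#' monomers, so `P2 + PD` is pinned at its initial value `phi^2` and the
#' stationary dimer fraction is `K * phi^2 / (1 + K)` — always below the
#' diffusive equilibrium, which can reach `phi`.
#'
#' @inheritParams dimer_equilibrium_diffusion
#' @return Stationary dimer fraction `PD`.
#' @examples
#' dimer_local_equilibrium(0.2, exp(2))
#' @export
dimer_local_equilibrium <- function(phi, K) {
  if (phi < 0 || phi > 1) stop("'phi' must lie in [0, 1]", call. = FALSE)
  if (!(K > 0)) stop("'K' must be positive", call. = FALSE)
  if (is.infinite(K)) return(phi^2)
  K * phi^2 / (1 + K)
}

#' First-order relaxation of the dimer fraction on isolated sites
#'
#' Without diffusion the dimer fraction obeys the linear ODE
#' `dPD/dt = k_plus * (S - PD) - k_minus * PD` where `S = P2 + PD` is
#' conserved. This is its exact solution: exponential relaxation toward
#' `PD_eq = K * S / (1 + K)` with rate `k_plus + k_minus`.
#'
#' @param pd0 Initial dimer fraction (`0 <= pd0 <= S`).
#' @param S Conserved fraction `P2 + PD`.
#' @param k_plus,k_minus Reaction rates (1/time).
#' @param t Elapsed time (vectorized, `t >= 0`).
#' @return Dimer fraction at time `t`.
#' @export
dimer_relax <- function(pd0, S, k_plus, k_minus, t) {
  if (pd0 < 0 || pd0 > S || S > 1)
    stop("require 0 <= pd0 <= S <= 1", call. = FALSE)
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  rate <- k_plus + k_minus
  pd_eq <- if (rate == 0) pd0 else k_plus * S / rate
  pd_eq + (pd0 - pd_eq) * exp(-rate * t)
}

#' Two-monomer site fraction at the start of a dry phase
#'
#' At the end of a wet phase the surviving dimers (fraction `pd_init` of
#' sites) are dropped at random, and the remaining free monomers are
#' distributed over the other sites at effective density
#' `xi = (phi - pd_init) / (1 - pd_init)`. The fraction of sites holding
#' two monomers, which is the reactive pool for the coming dry phase, is
#' `(1 - pd_init) * xi^2 = (phi - pd_init)^2 / (1 - pd_init)`.
#'
#' @param pd_init Dimer site fraction carried over from the wet phase.
#' @param phi Overall monomer density.
#' @return Fraction of sites with two monomers.
#' @export
dimer_cycle_start <- function(pd_init, phi) {
  if (pd_init < 0 || phi >= 1 || pd_init > phi)
    stop("require 0 <= pd_init <= phi < 1", call. = FALSE)
  (phi - pd_init)^2 / (1 - pd_init)
}

#' Schedule for wet-dry cycling
#'
#' @param t_dry Dry-phase duration (time, >= 0).
#' @param t_wet Wet-phase duration (time, >= 0).
#' @param w Wet-phase bond hydrolysis rate (1/time).
#' @param n_cycles Number of cycles (>= 1).
#' @return An object of class `cycle_schedule`.
#' @export
cycle_schedule <- function(t_dry, t_wet, w, n_cycles) {
  stopifnot(t_dry >= 0, t_wet >= 0, w >= 0, n_cycles >= 1)
  structure(list(t_dry = t_dry, t_wet = t_wet, w = w,
                 n_cycles = as.integer(n_cycles)),
            class = "cycle_schedule")
}

#' Iterate the dimer wet-dry cycling map
#'
#' Each cycle (i) redistributes molecules, giving a reactive pool
#' `S = pd + dimer_cycle_start(pd, phi)`, (ii) runs the dry phase —
#' either all the way to local equilibrium `PD_dry = K*S/(1+K)`
#' (`mode = "local-equilibrium"`) or for a finite `t_dry` via
#' [dimer_relax()] (`mode = "finite"`) — then (iii) applies exponential
#' wet-phase decay `PD_wet = PD_dry * exp(-w * t_wet)`. Iteration stops
#' at `n_cycles` or when the relative change in `PD_wet` drops below
#' `tol`.
#'
#' @param phi Monomer density in `(0, 1)`.
#' @param K Equilibrium constant (> 0).
#' @param schedule A [cycle_schedule()].
#' @param mode `"local-equilibrium"` (dry phase runs to completion, the
#'   regime in which the closed-form cycling limit holds) or `"finite"`.
#' @param k_plus,k_minus Rates, required for `mode = "finite"`.
#' @param pd_init Dimer fraction entering the first dry phase.
#' @param tol Relative-change convergence threshold.
#' @return Data frame with columns `cycle, PD_dry, PD_wet`; attribute
#'   `converged` records whether `tol` was reached before `n_cycles`.
#' @examples
#' sch <- cycle_schedule(t_dry = 8, t_wet = 0.5, w = 1, n_cycles = 30)
#' head(dimer_cycles(0.2, exp(2), sch), 3)
#' @export
dimer_cycles <- function(phi, K, schedule,
                         mode = c("local-equilibrium", "finite"),
                         k_plus = NULL, k_minus = NULL,
                         pd_init = 0, tol = 1e-12) {
  mode <- match.arg(mode)
  stopifnot(inherits(schedule, "cycle_schedule"), phi > 0, phi < 1, K > 0)
  if (mode == "finite" && (is.null(k_plus) || is.null(k_minus)))
    stop("mode = \"finite\" requires 'k_plus' and 'k_minus'", call. = FALSE)
  n <- schedule$n_cycles
  pd_dry <- pd_wet <- numeric(n)
  pd <- pd_init
  converged <- FALSE
  last <- n
  for (i in seq_len(n)) {
    S <- pd + dimer_cycle_start(pd, phi)
    pd_dry[i] <- if (mode == "local-equilibrium") {
      if (is.infinite(K)) S else K * S / (1 + K)
    } else {
      dimer_relax(pd, S, k_plus, k_minus, schedule$t_dry)
    }
    pd_new <- pd_dry[i] * exp(-schedule$w * schedule$t_wet)
    pd_wet[i] <- pd_new
    if (i > 1 && abs(pd_new - pd) <= tol * max(pd_new, .Machine$double.xmin)) {
      converged <- TRUE
      last <- i
      break
    }
    pd <- pd_new
  }
  out <- data.frame(cycle = seq_len(last),
                    PD_dry = pd_dry[seq_len(last)],
                    PD_wet = pd_wet[seq_len(last)])
  attr(out, "converged") <- converged
  out
}

#' Closed-form limit of the dimer cycling map
#'
#' The fixed point of the local-equilibrium cycling map satisfies a
#' quadratic in the end-of-wet-phase dimer fraction; with
#' `f = K * exp(-w * t_wet) / (1 + K)` the limit is
#' `PD_wet = (B - sqrt(B^2 - 4*f*phi^2)) / 2`, `B = 1 - f + 2*f*phi`,
#' evaluated here in the conjugate form `2*f*phi^2 / (B + sqrt(...))`
#' which is stable when the discriminant is close to `B^2`. The
#' end-of-dry-phase limit is `PD_wet * exp(w * t_wet)`. With
#' `w * t_wet = 0` the dry limit equals the diffusive equilibrium `PD`:
#' cycling can approach, but never beat, the diffusive dry phase.
#'
#' @param phi Monomer density in `(0, 1)`.
#' @param K Equilibrium constant (> 0, `Inf` allowed).
#' @param w Wet-phase hydrolysis rate (1/time).
#' @param t_wet Wet-phase duration (time).
#' @return Named vector `c(PD_wet, PD_dry)`.
#' @examples
#' dimer_cycling_limit(0.2, exp(2), w = 1, t_wet = 0.5)
#' @export
dimer_cycling_limit <- function(phi, K, w, t_wet) {
  stopifnot(phi > 0, phi < 1, K > 0, w >= 0, t_wet >= 0)
  f <- if (is.infinite(K)) exp(-w * t_wet) else K * exp(-w * t_wet) / (1 + K)
  B <- 1 - f + 2 * f * phi
  disc <- B^2 - 4 * f * phi^2
  pd_wet <- 2 * f * phi^2 / (B + sqrt(max(disc, 0)))
  c(PD_wet = pd_wet, PD_dry = pd_wet * exp(w * t_wet))
}
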