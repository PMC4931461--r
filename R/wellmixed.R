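# Well-mixed theory of reversible polymerization: any two strands can
# join at rate k+, any bond hydrolyzes at rate k-. At equilibrium the
# length distribution is the Flory-type geometric C_m = a * x^(m-1),
# and the total strand concentration obeys a closed kinetic equation.

#' Parameter set for the polymerization model
#'
#' @param k_plus Bond-formation rate (1/time).
#' @param k_minus Bond hydrolysis rate (1/time). If `NULL`, derived as
#'   `k_plus / K`.
#' @param K Equilibrium constant `k_plus / k_minus`. If `NULL`, derived
#'   from the rates.
#' @param mu Total monomer concentration (monomers per site or per unit
#'   volume, >= 0).
#' @return An object of class `polymer_params`.
#' @examples
#' polymer_params(k_plus = 1, K = exp(4), mu = 2)
#' @export
polymer_params <- function(k_plus = 1, k_minus = NULL, K = NULL, mu) {
  if (is.null(k_minus) && is.null(K))
    stop("supply at least one of 'k_minus' and 'K'", call. = FALSE)
  if (is.null(k_minus)) k_minus <- if (is.infinite(K)) 0 else k_plus / K
  if (is.null(K)) K <- if (k_minus == 0) Inf else k_plus / k_minus
  if (k_plus < 0 || k_minus < 0 || mu < 0)
    stop("rates and 'mu' must be non-negative", call. = FALSE)
  if (is.finite(K) && k_minus > 0 &&
      abs(K - k_plus / k_minus) > 1e-8 * max(1, K))
    stop("inconsistent parameters: K != k_plus / k_minus", call. = FALSE)
  structure(list(k_plus = k_plus, k_minus = k_minus, K = K, mu = mu),
            class = "polymer_params")
}

#' Geometric decay ratio of the equilibrium length distribution
#'
#' At equilibrium the strand concentrations are `C_m = a * x^(m-1)` with
#' `a = x / K`, and fixing the total monomer concentration gives the
#' quadratic `(1 - x)^2 = x / (K * mu)`. The root in `(0, 1)` is
#' `x = q - sqrt(q^2 - 1)` with `q = 1 + 1/(2*K*mu)`, computed here as
#' `1 / (q + sqrt(q^2 - 1))` so no cancellation occurs for large
#' `K * mu` (where `x -> 1`).
#'
#' @param K Equilibrium constant (> 0).
#' @param mu Total monomer concentration (> 0).
#' @return The decay ratio `x` in `(0, 1)`.
#' @examples
#' equilibrium_x(exp(4), 2)
#' @export
equilibrium_x <- function(K, mu) {
  if (!(K > 0) || !(mu > 0))
    stop("'K' and 'mu' must be positive", call. = FALSE)
  d <- 1 / (2 * K * mu)                 # q - 1
  1 / (1 + d + sqrt(d * (d + 2)))
}

#' Equilibrium strand concentration (total strands per site)
#'
#' The positive root of the formation/breakup balance
#' `K * lambda^2 = mu - lambda`, evaluated in stable form.
#'
#' @inheritParams equilibrium_x
#' @return Total strand concentration `lambda`; equals `mu * (1 - x)`.
#' @export
equilibrium_lambda <- function(K, mu) {
  if (!(K > 0) || !(mu > 0))
    stop("'K' and 'mu' must be positive", call. = FALSE)
  if (is.infinite(K)) return(0)
  2 * mu / (1 + sqrt(1 + 4 * K * mu))
}

#' Equilibrium mean strand length
#'
#' `1 / (1 - x)`, equivalently `mu / lambda`; strictly increasing in
#' both `K` and `mu`.
#'
#' @inheritParams equilibrium_x
#' @return Mean length in monomers (>= 1).
#' @examples
#' mean_length_equilibrium(exp(4), 2)   # ~ 10.96
#' @export
mean_length_equilibrium <- function(K, mu) {
  mu / equilibrium_lambda(K, mu)
}

#' Equilibrium length distribution
#'
#' Concentrations `C_m = a * x^(m-1)` for `m = 1..m_max`, with
#' `a = x / K`. By construction the geometric form satisfies detailed
#' balance `k_plus * C_n * C_m = k_minus * C_(n+m)` for every split.
#' The default cutoff is the smallest `m_max` whose retained monomer
#' mass `sum(m * C_m)` is at least `(1 - 1e-9) * mu`; the excluded tail
#' mass is reported in the `truncation_error` attribute.
#'
#' @inheritParams equilibrium_x
#' @param m_max Length cutoff (>= 1), or `NULL` for the mass-based
#'   default.
#' @return Data frame with columns `length` and `conc`; attributes
#'   `x`, `a`, `truncation_error`.
#' @examples
#' head(equilibrium_length_distribution(exp(4), 2))
#' @export
equilibrium_length_distribution <- function(K, mu, m_max = NULL) {
  x <- equilibrium_x(K, mu)
  a <- x / K
  if (is.null(m_max)) {
    # tail mass beyond M: a * x^M * (M*(1-x) + 1) / (1-x)^2
    m_max <- 1L
    while (a * x^m_max * (m_max * (1 - x) + 1) / (1 - x)^2 > 1e-9 * mu)
      m_max <- m_max + 1L
  }
  if (m_max < 1) stop("'m_max' must be >= 1", call. = FALSE)
  m <- seq_len(m_max)
  tail_mass <- a * x^m_max * (m_max * (1 - x) + 1) / (1 - x)^2
  structure(data.frame(length = m, conc = a * x^(m - 1)),
            x = x, a = a, truncation_error = tail_mass)
}

#' Kinetics of the total strand concentration
#'
#' In the well-mixed limit the total strand concentration obeys
#' `dC_tot/dt = -k_plus * C_tot^2 + k_minus * (mu - C_tot)`:
#' every pair of strands can join, and `mu - C_tot` is the
#' concentration of hydrolyzable bonds. The mean length at any time is
#' `mu / C_tot`. The stationary point is the equilibrium `lambda`.
#'
#' @param params A [polymer_params()] object.
#' @param c0 Initial strand concentration (`0 < c0 <= mu`); starting
#'   from free monomers means `c0 = mu`.
#' @param t_end Final time (> 0).
#' @param report_dt Linear output spacing; ignored when `log_times` is
#'   `TRUE`.
#' @param log_times Report on a log-spaced time grid (natural for the
#'   slow approach to equilibrium).
#' @param n_report Number of reported points for the log grid.
#' @param rtol,atol Tolerances passed to [deSolve::ode()].
#' @return Data frame with columns `time, C_tot, mean_length`.
#' @examples
#' p <- polymer_params(k_plus = 1, K = exp(4), mu = 2)
#' tail(integrate_ctot(p, c0 = 2, t_end = 100), 1)
#' @export
integrate_ctot <- function(params, c0, t_end, report_dt = NULL,
                           log_times = FALSE, n_report = 200,
                           rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(params, "polymer_params"), t_end > 0)
  mu <- params$mu
  if (c0 <= 0 || c0 > mu)
    stop("'c0' must satisfy 0 < c0 <= mu", call. = FALSE)
  times <- if (log_times) {
    c(0, exp(seq(log(t_end) - log(1e4), log(t_end), length.out = n_report)))
  } else {
    if (is.null(report_dt)) report_dt <- t_end / 200
    unique(c(seq(0, t_end, by = report_dt), t_end))
  }
  rhs <- function(t, y, p)
    list(-p$k_plus * y^2 + p$k_minus * (p$mu - y))
  out <- deSolve::ode(y = c0, times = times, func = rhs, parms = params,
                      rtol = rtol, atol = atol)
  data.frame(time = out[, 1], C_tot = out[, 2],
             mean_length = mu / out[, 2])
}

#' Poisson site-occupancy distribution
#'
#' When strands are distributed at random over the lattice (fast
#' diffusion, or after scrambling), the number of strands on a site is
#' Poisson with mean `lambda`. Its second factorial moment
#' `E[n(n-1)] = lambda^2` is what makes the per-site bond-formation rate
#' `k_plus * n * (n-1)` average to the well-mixed rate
#' `k_plus * lambda^2`.
#'
#' @param lambda Mean strands per site (>= 0).
#' @param n_max Largest occupancy reported.
#' @return Data frame with columns `n` and `prob` for `n = 0..n_max`.
#' @export
poisson_occupancy <- function(lambda, n_max) {
  if (lambda < 0) stop("'lambda' must be non-negative", call. = FALSE)
  n <- 0:n_max
  data.frame(n = n, prob = stats::dpois(n, lambda))
}
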