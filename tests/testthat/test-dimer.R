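test_that("random placement gives binomial site fractions", {
  expect_equal(dimer_initial_probs(0), c(P0 = 1, P1 = 0, P2 = 0, PD = 0))
  expect_equal(dimer_initial_probs(1), c(P0 = 0, P1 = 0, P2 = 1, PD = 0))
  expect_equal(dimer_initial_probs(0.2),
               c(P0 = 0.64, P1 = 0.32, P2 = 0.04, PD = 0))
  for (phi in c(0.05, 0.3, 0.77))
    expect_equal(sum(dimer_initial_probs(phi)), 1)
  expect_error(dimer_initial_probs(1.2), "0, 1")
  expect_error(dimer_initial_probs(-0.1), "0, 1")
})

test_that("mean-field trajectories conserve vacancies, occupancy and norm", {
  for (case in list(c(0.2, exp(2), 1), c(0.5, exp(4), 0.3),
                    c(0.8, 0.5, 2))) {
    phi <- case[1]
    p <- dimer_params(phi, k_plus = 1, K = case[2], h = case[3])
    tr <- dimer_meanfield(p, dimer_initial_probs(phi), t_end = 50)
    expect_lt(max(abs(tr$P0 + tr$P1 + tr$P2 + tr$PD - 1)), 1e-8)
    expect_lt(max(abs(tr$P1 / 2 + tr$P2 + tr$PD - phi)), 1e-8)
    expect_lt(max(abs(tr$P0 + tr$P1 / 2 - (1 - phi))), 1e-8)
  }
})

test_that("long-time integration reaches the diffusive equilibrium", {
  p <- dimer_params(0.2, k_plus = 1, k_minus = exp(-2), h = 1)
  tr <- dimer_meanfield(p, dimer_initial_probs(0.2), t_end = 500)
  final <- unlist(tr[nrow(tr), c("P0", "P1", "P2", "PD")])
  expect_equal(final[["PD"]], 0.0931029, tolerance = 1e-5)
  expect_lt(max(abs(final - rootfind_dimer_eq(0.2, exp(2)))), 1e-6)
})

test_that("without hopping the trajectory stops at local equilibrium", {
  p <- dimer_params(0.2, k_plus = 1, k_minus = exp(-2), h = 0)
  tr <- dimer_meanfield(p, dimer_initial_probs(0.2), t_end = 500)
  expect_equal(tr$PD[nrow(tr)], 0.0352319, tolerance = 1e-5)
  expect_equal(tr$PD[nrow(tr)], dimer_local_equilibrium(0.2, exp(2)),
               tolerance = 1e-6)
  # P2 + PD pinned at phi^2 with no diffusion
  expect_lt(max(abs(tr$P2 + tr$PD - 0.04)), 1e-8)
})

test_that("with no reaction channel the dimer fraction stays zero", {
  p <- dimer_params(0.3, k_plus = 0, k_minus = 1, h = 1)
  tr <- dimer_meanfield(p, dimer_initial_probs(0.3), t_end = 20)
  expect_lt(max(abs(tr$PD)), 1e-12)
  expect_lt(max(abs(tr$P2 + tr$PD - (tr$P2[1] + tr$PD[1]))), 1e-8)
})

test_that("diffusive equilibrium satisfies all four balance conditions", {
  for (phi in c(0.05, 0.2, 0.5, 0.9)) {
    for (K in c(1e-3, 0.5, exp(2), exp(6), 1e6)) {
      eq <- dimer_equilibrium_diffusion(phi, K)
      expect_lt(abs(eq[["P0"]] + eq[["P1"]] / 2 - (1 - phi)), 1e-10)
      expect_lt(abs(eq[["P1"]] / 2 + eq[["P2"]] + eq[["PD"]] - phi), 1e-10)
      expect_lt(abs(eq[["PD"]] - K * eq[["P2"]]), 1e-10)
      expect_lt(abs(4 * eq[["P0"]] * eq[["P2"]] - eq[["P1"]]^2), 1e-10)
    }
  }
  eq <- dimer_equilibrium_diffusion(0.2, exp(2))
  expect_equal(unname(eq[c("P1", "P2", "PD")]),
               c(0.188594, 0.012600, 0.093103), tolerance = 1e-5)
  expect_error(dimer_equilibrium_diffusion(0.2, -1), "positive")
})

test_that("diffusive equilibrium limits: no binding and full conversion", {
  expect_equal(dimer_equilibrium_diffusion(0.2, 1e-12),
               dimer_initial_probs(0.2), tolerance = 1e-6)
  hi <- dimer_equilibrium_diffusion(0.2, 1e8)
  expect_equal(hi[["PD"]], 0.2, tolerance = 1e-3)
  expect_lt(hi[["P2"]], 1e-4)
  expect_equal(dimer_equilibrium_diffusion(0.2, Inf),
               c(P0 = 0.8, P1 = 0, P2 = 0, PD = 0.2))
})

test_that("local equilibrium without diffusion is K*phi^2/(1+K)", {
  expect_equal(dimer_local_equilibrium(0.2, exp(2)), 0.0352319,
               tolerance = 1e-5)
  expect_equal(dimer_local_equilibrium(0.2, Inf), 0.04)
  expect_equal(dimer_local_equilibrium(0, exp(2)), 0)
  # always below the diffusive equilibrium for 0 < phi < 1
  for (phi in c(0.1, 0.5, 0.9))
    for (K in c(0.1, 1, 50))
      expect_lt(dimer_local_equilibrium(phi, K),
                dimer_equilibrium_diffusion(phi, K)[["PD"]])
})

test_that("no-diffusion relaxation is exact first-order kinetics", {
  expect_equal(dimer_relax(0.01, 0.04, 1, exp(-2), 0), 0.01)
  expect_equal(dimer_relax(0, 0.04, 1, exp(-2), 1e4),
               dimer_local_equilibrium(0.2, exp(2)), tolerance = 1e-12)
  # half-life property of linear relaxation
  kp <- 1; km <- exp(-2)
  pd_eq <- kp * 0.04 / (kp + km)
  half <- dimer_relax(0, 0.04, kp, km, log(2) / (kp + km))
  expect_equal(half, pd_eq / 2, tolerance = 1e-12)
  # monotone in t
  pd <- dimer_relax(0, 0.04, kp, km, seq(0, 10, by = 0.5))
  expect_true(all(diff(pd) > 0))
  expect_error(dimer_relax(0.1, 0.04, 1, 1, 1), "pd0 <= S")
})

test_that("dry-phase initial pool follows the redistribution formula", {
  expect_equal(dimer_cycle_start(0, 0.2), 0.04)
  expect_equal(dimer_cycle_start(0.2, 0.2), 0)
  expect_equal(dimer_cycle_start(0.021368, 0.2), 0.032606,
               tolerance = 1e-5)
  expect_error(dimer_cycle_start(0.3, 0.2), "pd_init <= phi")
})

test_that("cycling map reproduces the first cycle and its fixed point", {
  sch <- cycle_schedule(t_dry = 8, t_wet = 0.5, w = 1, n_cycles = 100)
  cyc <- dimer_cycles(0.2, exp(2), sch)
  expect_equal(cyc$PD_dry[1], 0.0352319, tolerance = 1e-5)
  expect_equal(cyc$PD_wet[1], 0.021369, tolerance = 1e-4)
  lim <- dimer_cycling_limit(0.2, exp(2), 1, 0.5)
  expect_equal(cyc$PD_wet[nrow(cyc)], lim[["PD_wet"]], tolerance = 1e-8)
  expect_true(attr(cyc, "converged"))
})

test_that("with no wet hydrolysis the cycling map approaches the diffusive equilibrium", {
  sch <- cycle_schedule(t_dry = 8, t_wet = 0, w = 1, n_cycles = 500)
  cyc <- dimer_cycles(0.2, exp(2), sch)
  expect_equal(cyc$PD_dry[nrow(cyc)],
               dimer_equilibrium_diffusion(0.2, exp(2))[["PD"]],
               tolerance = 1e-6)
})

test_that("finite dry phases long enough for local equilibrium match the analytic map", {
  kp <- 1; km <- exp(-2)
  t_dry <- 25 / (kp + km)
  sch <- cycle_schedule(t_dry = t_dry, t_wet = 0.5, w = 1, n_cycles = 20)
  a <- dimer_cycles(0.2, exp(2), sch, mode = "local-equilibrium")
  b <- dimer_cycles(0.2, exp(2), sch, mode = "finite",
                    k_plus = kp, k_minus = km)
  n <- min(nrow(a), nrow(b))
  expect_lt(max(abs(a$PD_wet[1:n] - b$PD_wet[1:n])), 1e-6)
  expect_error(dimer_cycles(0.2, exp(2), sch, mode = "finite"), "requires")
})

test_that("cycling map converges geometrically to the closed-form limit", {
  lim <- dimer_cycling_limit(0.2, exp(2), 1, 0.5)[["PD_wet"]]
  sch <- cycle_schedule(t_dry = 8, t_wet = 0.5, w = 1, n_cycles = 15)
  cyc <- dimer_cycles(0.2, exp(2), sch, tol = 0)
  gap <- abs(cyc$PD_wet - lim)
  ratio <- gap[-1] / gap[-length(gap)]
  expect_true(all(diff(gap) < 0))
  expect_lt(max(ratio), 1)
  expect_lt(diff(range(ratio[5:10])), 0.05)  # near-constant contraction
})

test_that("closed-form cycling limit matches independent fixed-point iteration", {
  for (phi in c(0.1, 0.2, 0.6)) {
    for (K in c(1, exp(2), exp(4))) {
      for (wt in c(0.1, 0.5, 2)) {
        f <- K * exp(-wt) / (1 + K)
        pd <- 0
        for (i in 1:2000)
          pd <- f * (pd + (phi - pd)^2 / (1 - pd))
        lim <- dimer_cycling_limit(phi, K, w = wt, t_wet = 1)
        expect_equal(lim[["PD_wet"]], pd, tolerance = 1e-10)
        expect_equal(lim[["PD_dry"]], pd * exp(wt), tolerance = 1e-10)
      }
    }
  }
  # complete wet-phase hydrolysis removes all dimers
  expect_equal(dimer_cycling_limit(0.2, exp(2), 1, 1e4)[["PD_wet"]], 0,
               tolerance = 1e-12)
})

test_that("parameter constructors enforce the K = k_plus/k_minus identity", {
  p <- dimer_params(0.2, k_plus = 1, K = exp(2))
  expect_equal(p$k_minus, exp(-2))
  p2 <- dimer_params(0.2, k_plus = 2, k_minus = 0)
  expect_identical(p2$K, Inf)
  expect_error(dimer_params(0.2, k_plus = 1, k_minus = 1, K = 5),
               "inconsistent")
  expect_error(dimer_params(1.4, k_plus = 1, K = 1), "phi")
})
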