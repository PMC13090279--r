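test_that("age averaging agrees with direct quadrature on a random density", {
  p <- model_parameters()
  g <- age_grid(0.05, 1, 30)
  set.seed(5)
  U <- runif(g$N_max + 1, 0.01, 1)
  avg <- age_averaged_parameters(U, 0.4, g, p)
  # independent quadrature with plain trapezoids on each segment
  trap <- function(f, idx) {
    w <- rep(1, length(idx)); w[c(1, length(idx))] <- 0.5
    g$h * sum(w * f[idx])
  }
  j <- 1:(g$N1 + 1)                 # juvenile nodes
  ad <- (g$N1 + 1):(g$N_max + 1)    # adult nodes
  muB <- base_death_rate(g$ages, p)
  Bt <- base_birth_rate(g$ages, p)
  expect_equal(avg$m1, trap(muB * U, j) / trap(U, j), tolerance = 1e-12)
  expect_equal(avg$m2, trap(muB * U, ad) / trap(U, ad), tolerance = 1e-12)
  expect_equal(avg$b2, trap(Bt * U, ad) / trap(U, ad), tolerance = 1e-12)
  expect_equal(avg$D, U[g$N1 + 1] / trap(U, j), tolerance = 1e-12)
  # M_B: trapezoid of mu_B over the juvenile ages vs the closed form
  expect_equal(avg$M_B,
               p$d_p / p$d_ep * (exp(p$d_ep * (1 - 30)) - exp(-p$d_ep * 30)),
               tolerance = 1e-4)
  # transition-rate consistency D * y1 = u(tau*)
  expect_equal(avg$D * trap(U, j), avg$u_tau_star, tolerance = 1e-12)
  expect_error(age_averaged_parameters(numeric(g$N_max + 1), 1, g, p),
               "degenerate")
})

test_that("dropping natural birth and hunger recovers the unstructured ODE", {
  p <- model_parameters()
  avg <- structure(list(D = 1.3, b2 = 0, m1 = 0.02, m2 = 0.04, M_B = 0.1),
                   class = "agepp_averaged")
  p0 <- p; p0$mu_M <- 1e-300   # hunger off (mu_M must stay positive)
  li_rhs <- function(x, y1, y2, D, m1, m2)
    c(x * (p$r - p$a * x + p$s * y1 - p$b * y2),
      p$k * x * y2 - y1 * (p$g * x + D + m1),
      D * y1 - m2 * y2)
  set.seed(9)
  for (i in 1:20) {
    x <- runif(1, 0, 50); y1 <- runif(1, 0, 10); y2 <- runif(1, 0, 10)
    expect_equal(ode_rhs(x, y1, y2, p0, avg),
                 li_rhs(x, y1, y2, avg$D, avg$m1, avg$m2),
                 tolerance = 1e-10)
  }
  # equilibria of the right-hand side
  expect_equal(ode_rhs(0, 0, 0, p0, avg), c(0, 0, 0))
  expect_equal(ode_rhs(p$r / p$a, 0, 0, p0, avg), c(0, 0, 0))
})

test_that("the juvenile-adult transfer conserves predators in the ODE sum", {
  p <- model_parameters()
  avg1 <- structure(list(D = 0.7, b2 = 0.08, m1 = 0.02, m2 = 0.04,
                         M_B = 0.1), class = "agepp_averaged")
  avg2 <- avg1; avg2$D <- 3.1
  set.seed(13)
  for (i in 1:15) {
    st <- runif(3, 0, 20)
    r1 <- ode_rhs(st[1], st[2], st[3], p, avg1)
    r2 <- ode_rhs(st[1], st[2], st[3], p, avg2)
    # dy1 + dy2 does not depend on the transition rate D
    expect_equal(r1[2] + r1[3], r2[2] + r2[3], tolerance = 1e-12)
  }
})

test_that("the delayed maturation flux collapses to its closed forms", {
  p <- model_parameters()
  avg <- structure(list(D = 1, b2 = 0.08, m1 = 0.02, m2 = 0.04,
                        M_B = 0.37), class = "agepp_averaged")
  born <- function(x, y2) p$k * x * y2 + (1 - exp(-p$zeta * x)) * avg$b2 * y2
  # g = 0 and no hunger: pure base-death attenuation
  p0 <- model_parameters(g = 1e-300, mu_M = 1e-300)
  expect_equal(dde_delayed_transition(2, 3, 1.5, p0, avg),
               (p0$k * 3 * 1.5 + (1 - exp(-p0$zeta * 3)) * avg$b2 * 1.5) *
                 exp(-avg$M_B), tolerance = 1e-10)
  # constant history: the trapezoid exponent is exact
  xc <- 0.8; y2c <- 0.6
  expect_equal(dde_delayed_transition(xc, xc, y2c, p, avg),
               born(xc, y2c) * exp(-p$g * p$tau_star * xc - avg$M_B -
                                     p$mu_M * p$tau_star * exp(-p$rho * xc)),
               tolerance = 1e-12)
  # vanishing delay: flux approaches the newborn flux
  p_small <- model_parameters(tau_star = 1e-8)
  avg0 <- avg; avg0$M_B <- 0
  expect_equal(dde_delayed_transition(1, 1, 2, p_small, avg0),
               born(1, 2), tolerance = 1e-6)
  expect_error(dde_delayed_transition(-1, 1, 1, p, avg), "nonnegative")
})

test_that("the reduced ODE reproduces an independent unstructured run", {
  p <- model_parameters()
  p$mu_M <- 1e-300
  avg <- structure(list(D = 0.9, b2 = 0, m1 = 0.021, m2 = 0.042,
                        M_B = 0.3), class = "agepp_averaged")
  tr <- integrate_reduced("ode", c(x = 0.5, y1 = 0.1, y2 = 1.45), p, avg,
                          T = 50, record_every = 0.5)
  # independent oracle: the unstructured role-reversal ODE via deSolve
  oracle <- deSolve::ode(
    y = c(x = 0.5, y1 = 0.1, y2 = 1.45), times = seq(0, 50, by = 0.5),
    func = function(t, y, q)
      list(c(y[1] * (0.4 - 0.01 * y[1] + 0.2 * y[2] - 0.8 * y[3]),
             0.3 * y[1] * y[3] - y[2] * (0.2 * y[1] + 0.9 + 0.021),
             0.9 * y[2] - 0.042 * y[3])),
    parms = NULL)
  expect_equal(tr$series$x, unname(oracle[, "x"]), tolerance = 1e-5)
  expect_equal(tr$series$y2, unname(oracle[, "y2"]), tolerance = 1e-5)
})

test_that("a stable reduced equilibrium holds its ground over a long run", {
  # short maturation: the age-averaged ODE equilibrium is a stable focus
  p <- model_parameters(tau_star = 0.05, g = 0.3)
  surf <- averaged_parameter_surface(0.05, 0.3, params = p, h = 0.025)
  avg <- structure(as.list(surf[1, c("D", "b2", "m1", "m2", "M_B")]),
                   class = "agepp_averaged")
  eq <- reduced_equilibrium("ode", c(x = surf$x_eq, y1 = 0.1, y2 = 0.5),
                            p, avg)
  expect_lt(eq$residual_norm, 1e-10)
  expect_true(eq$stable)
  tr <- integrate_reduced("ode", eq$state, p, avg, T = 100)
  fin <- c(tr$final$X, tr$final$Y1, tr$final$Y2)
  expect_equal(fin, unname(eq$state), tolerance = 1e-8)
})

test_that("ODE and DDE reductions have different equilibria", {
  p <- model_parameters(tau_star = 1, g = 0.1)
  surf <- averaged_parameter_surface(1, 0.1, params = p, h = 0.025)
  avg <- structure(as.list(surf[1, c("D", "b2", "m1", "m2", "M_B")]),
                   class = "agepp_averaged")
  st <- c(x = surf$x_eq, y1 = 0.1, y2 = 0.5)
  eo <- reduced_equilibrium("ode", st, p, avg)
  ed <- reduced_equilibrium("dde", st, p, avg)
  expect_lt(eo$residual_norm, 1e-8)
  expect_lt(ed$residual_norm, 1e-8)
  expect_gt(max(abs(eo$state - ed$state)), 1e-6)
})

test_that("the DDE integrates through and beyond the initial delay window", {
  p <- model_parameters(tau_star = 1, g = 0.1)
  surf <- averaged_parameter_surface(1, 0.1, params = p, h = 0.025)
  avg <- structure(as.list(surf[1, c("D", "b2", "m1", "m2", "M_B")]),
                   class = "agepp_averaged")
  tr <- integrate_reduced("dde", c(x = 0.5, y1 = 0.1, y2 = 1.45), p, avg,
                          T = 100)
  expect_identical(tr$status, "completed")
  expect_true(all(is.finite(tr$series$x)))
  expect_true(all(tr$series$x >= 0))
})

test_that("age structure destabilizes coexistence more than the delay,
          and the delay more than the plain ODE", {
  # equilibrium growth rates at matched age-averaged parameters:
  # age-structured > delayed > unstructured, cell by cell
  cells <- list(c(0.5, 0.05), c(1.0, 0.3), c(1.5, 0.05), c(2.0, 0.3))
  for (cell in cells) {
    ts <- cell[1]; g <- cell[2]
    p <- model_parameters(tau_star = ts, g = g)
    surf <- averaged_parameter_surface(ts, g, params = p, h = 0.025)
    avg <- structure(as.list(surf[1, c("D", "b2", "m1", "m2", "M_B")]),
                     class = "agepp_averaged")
    gr <- age_grid(0.025, ts, 30)
    cand <- coexistence_equilibria(gr, p)
    eqP <- newton_equilibrium(list(X = cand[[1]]$X, U = cand[[1]]$U),
                              gr, p)
    stP <- assess_stability(map_jacobian(eqP$X_star, eqP$U_star, gr, p),
                            gr$h)
    growth_pde <- max(Re(stP$exponents))
    st0 <- c(x = surf$x_eq, y1 = 0.2, y2 = 0.5)
    eqO <- reduced_equilibrium("ode", st0, p, avg)
    fo <- function(z) ode_rhs(z[1], z[2], z[3], p, avg)
    z0 <- unname(eqO$state)
    JO <- vapply(1:3, function(j) {
      dz <- z0; s <- 1e-7 * max(1, abs(z0[j])); dz[j] <- dz[j] + s
      (fo(dz) - fo(z0)) / s
    }, numeric(3))
    growth_ode <- max(Re(eigen(JO, only.values = TRUE)$values))
    eqD <- reduced_equilibrium("dde", st0, p, avg)
    growth_dde <- Re(dde_equilibrium_stability(eqD$state, p, avg)$rightmost)
    expect_gt(growth_pde, growth_dde)
    expect_gt(growth_dde, growth_ode)
  }
})
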