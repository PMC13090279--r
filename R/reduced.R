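#' Age-averaged parameters for the reduced models
#'
#' Collapses the age structure at an equilibrium density into the constants
#' used by the reduced ODE and DDE models: the juvenile-to-adult transition
#' rate `D = u(tau_star)/y1`, the density-weighted averages `b2` (base
#' birth rate over adults), `m1`, `m2` (base death rate over juveniles and
#' adults), and the integrated juvenile base death burden
#' `M_B = int_0^{tau*} mu_B`.  All integrals use the same trapezoid weights
#' (half weight at the maturation node) as [population_sizes()].
#'
#' @param U equilibrium age density on the grid nodes.
#' @param x_eq prey size at the equilibrium (stored for reference).
#' @param grid `agepp_grid`.
#' @param params `agepp_parameters`.
#' @return An `agepp_averaged`: list with `D`, `b2`, `m1`, `m2`, `M_B`,
#'   `u_tau_star`, `x_eq`.
#' @export
age_averaged_parameters <- function(U, x_eq, grid, params) {
  h <- grid$h; N1 <- grid$N1; NM <- grid$N_max
  stopifnot(length(U) == NM + 1L)
  muB <- base_death_rate(grid$ages, params)
  Bt <- base_birth_rate(grid$ages, params)

  w1 <- numeric(NM + 1); w1[1:(N1 + 1)] <- 1; w1[c(1, N1 + 1)] <- 0.5
  w2 <- numeric(NM + 1); w2[(N1 + 1):(NM + 1)] <- 1
  w2[c(N1 + 1, NM + 1)] <- 0.5

  y1 <- h * sum(w1 * U)
  y2 <- h * sum(w2 * U)
  if (y1 <= 0 || y2 <= 0)
    stop("degenerate density: zero total weight on an age segment",
         call. = FALSE)

  structure(list(
    D = U[N1 + 1] / y1,
    b2 = sum(w2 * Bt * U) / sum(w2 * U),
    m1 = sum(w1 * muB * U) / sum(w1 * U),
    m2 = sum(w2 * muB * U) / sum(w2 * U),
    M_B = h * sum(w1 * muB),
    u_tau_star = U[N1 + 1],
    x_eq = x_eq
  ), class = "agepp_averaged")
}

#' @export
print.agepp_averaged <- function(x, ...) {
  cat("Age-averaged parameters: D =", format(x$D, digits = 4),
      " b2 =", format(x$b2, digits = 4),
      " m1 =", format(x$m1, digits = 4),
      " m2 =", format(x$m2, digits = 4),
      " M_B =", format(x$M_B, digits = 4), "\n")
  invisible(x)
}

#' Right-hand side of the reduced ODE model
#'
#' The age-structured system collapsed by age-averaging (sharp maturity
#' indicators): setting `b2 = 0` and `mu_M = 0` recovers the classical
#' unstructured role-reversal ODE exactly.
#'
#' @param x,y1,y2 nonnegative state.
#' @param params `agepp_parameters`.
#' @param avg `agepp_averaged` (fields `D`, `b2`, `m1`, `m2`).
#' @return numeric vector `c(dx, dy1, dy2)`.
#' @export
ode_rhs <- function(x, y1, y2, params, avg) {
  hunger <- params$mu_M * exp(-params$rho * x)
  kx <- if (params$variant == "saturated")
    params$k * params$x_hat * tanh(x / params$x_hat) else params$k * x
  sy1 <- if (params$variant == "saturated")
    params$s * params$y1_hat * tanh(y1 / params$y1_hat) else params$s * y1
  c(
    x * (params$r - params$a * x + sy1 - params$b * y2),
    kx * y2 + (1 - exp(-params$zeta * x)) * avg$b2 * y2 -
      avg$D * y1 - params$g * x * y1 - avg$m1 * y1 - hunger * y1,
    avg$D * y1 - avg$m2 * y2 - hunger * y2
  )
}

# Closed-form integral of the base death rate over [lo, hi].
mu_base_integral <- function(lo, hi, params) {
  with(params, d_p / d_ep * (exp(d_ep * (hi - L)) - exp(d_ep * (lo - L))))
}

#' Maturation flux of the DDE model
#'
#' The density of predators reaching the maturation age at time `t`,
#' obtained by integrating the renewal equation along the characteristic
#' from the birth time `t - tau_star` with the trapezoid rule in the prey
#' dependence: the newborn flux
#' `u(t - tau*, 0) = k x_del y2_del + (1 - exp(-zeta x_del)) b2 y2_del`
#' attenuated by juvenile predation, the base death burden `M_B`, and
#' hunger, each evaluated from the endpoint prey sizes.
#'
#' @param x_now prey size at time `t`.
#' @param x_delayed,y2_delayed prey and adult predator sizes at `t - tau*`.
#' @param params `agepp_parameters`.
#' @param avg `agepp_averaged`.
#' @return the flux `u(t, tau_star)` (a nonnegative scalar).
#' @export
dde_delayed_transition <- function(x_now, x_delayed, y2_delayed,
                                   params, avg) {
  if (any(c(x_now, x_delayed, y2_delayed) < 0))
    stop("state components must be nonnegative", call. = FALSE)
  born <- params$k * x_delayed * y2_delayed +
    (1 - exp(-params$zeta * x_delayed)) * avg$b2 * y2_delayed
  ts <- params$tau_star
  born * exp(-params$g * ts / 2 * (x_delayed + x_now) - avg$M_B -
               params$mu_M * ts / 2 *
               (exp(-params$rho * x_delayed) + exp(-params$rho * x_now)))
}

#' Integrate a reduced (ODE or DDE) model
#'
#' The ODE model is the age-averaged three-variable system; the DDE model
#' replaces the constant transition rate `D*y1` by the maturation flux
#' delayed by `tau_star`.  For times before one delay has elapsed the flux
#' is taken from the initial age density: the cohort maturing at time
#' `t < tau_star` was at age `tau_star - t` initially.  The history of `x`
#' and `y2` before time zero is constant at the initial values.
#'
#' @param model `"ode"` or `"dde"`.
#' @param state0 named numeric `c(x =, y1 =, y2 =)`.
#' @param params `agepp_parameters`.
#' @param avg `agepp_averaged`.
#' @param T final time.
#' @param u0 initial age density function (DDE only; defaults to the
#'   standard study profile).
#' @param blowup_threshold trajectory is truncated with status `"blowup"`
#'   at the first sample exceeding it.
#' @param record_every output sampling interval.
#' @return An `agepp_trajectory` (series of `x`, `y1`, `y2`).
#' @export
integrate_reduced <- function(model = c("ode", "dde"), state0, params, avg,
                              T, u0 = NULL, blowup_threshold = 1000,
                              record_every = 0.25) {
  model <- match.arg(model)
  times <- seq(0, T, by = record_every)
  y0 <- c(x = unname(state0["x"]), y1 = unname(state0["y1"]),
          y2 = unname(state0["y2"]))

  if (model == "ode") {
    deriv <- function(t, y, p) {
      list(ode_rhs(max(y[1], 0), max(y[2], 0), max(y[3], 0), params, avg))
    }
    sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                        method = "lsoda")
  } else {
    if (is.null(u0))
      u0 <- default_initial_condition(params)$u0
    ts <- params$tau_star
    x0 <- unname(y0["x"])
    deriv <- function(t, y, p) {
      x <- max(y[1], 0); y1 <- max(y[2], 0); y2 <- max(y[3], 0)
      hunger <- params$mu_M * exp(-params$rho * x)
      born_now <- params$k * x * y2 +
        (1 - exp(-params$zeta * x)) * avg$b2 * y2
      if (t >= ts) {
        lag <- deSolve::lagvalue(max(t - ts, times[1]), c(1, 3))
        flux <- dde_delayed_transition(x, max(lag[1], 0), max(lag[2], 0),
                                       params, avg)
      } else {
        # cohort at age tau* now was at age tau* - t initially
        flux <- u0(ts - t) *
          exp(-params$g * t / 2 * (x0 + x) -
                mu_base_integral(ts - t, ts, params) -
                params$mu_M * t / 2 *
                (exp(-params$rho * x0) + exp(-params$rho * x)))
      }
      list(c(
        x * (params$r - params$a * x + params$s * y1 - params$b * y2),
        born_now - flux - params$g * x * y1 - avg$m1 * y1 - hunger * y1,
        flux - avg$m2 * y2 - hunger * y2
      ))
    }
    sol <- deSolve::dede(y = y0, times = times, func = deriv, parms = NULL)
  }

  df <- as.data.frame(sol)
  names(df) <- c("time", "x", "y1", "y2")
  status <- "completed"
  over <- which(df$x > blowup_threshold | df$y1 > blowup_threshold |
                  df$y2 > blowup_threshold)
  if (length(over)) {
    df <- df[seq_len(over[1]), ]
    status <- "blowup"
  } else if (nrow(df) < length(times)) {
    status <- "solver_failure"
  }
  last <- df[nrow(df), ]
  structure(list(
    series = df, status = status, t_end = last$time,
    snapshots = NULL, snapshot_times = numeric(0),
    final = list(X = last$x, Y1 = last$y1, Y2 = last$y2),
    grid = NULL, params = params
  ), class = "agepp_trajectory")
}

#' Equilibrium of a reduced model
#'
#' Solves the stationary equations by nonlinear least squares
#' (Levenberg-Marquardt).  For the DDE model the stationary maturation flux
#' uses the constant-history form of the delayed transition.
#'
#' @inheritParams integrate_reduced
#' @param start starting point `c(x =, y1 =, y2 =)`.
#' @return list with `state`, `residual_norm`, `stable` (ODE: all Jacobian
#'   eigenvalues have negative real part; DDE: `NA`, use
#'   [reduced_stability_by_perturbation()]).
#' @export
reduced_equilibrium <- function(model = c("ode", "dde"), start, params, avg) {
  model <- match.arg(model)
  rhs <- function(z) {
    x <- z[1]; y1 <- z[2]; y2 <- z[3]
    if (model == "ode") {
      ode_rhs(x, y1, y2, params, avg)
    } else {
      hunger <- params$mu_M * exp(-params$rho * x)
      flux <- dde_delayed_transition(x, x, y2, params, avg)
      c(x * (params$r - params$a * x + params$s * y1 - params$b * y2),
        params$k * x * y2 + (1 - exp(-params$zeta * x)) * avg$b2 * y2 -
          flux - params$g * x * y1 - avg$m1 * y1 - hunger * y1,
        flux - avg$m2 * y2 - hunger * y2)
    }
  }
  fit <- minpack.lm::nls.lm(par = unname(start[c("x", "y1", "y2")]),
                            fn = rhs,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-15, ptol = 1e-15))
  z <- fit$par
  stable <- NA
  if (model == "ode") {
    J <- numeric_jacobian(function(w) rhs(w), z)
    stable <- all(Re(eigen(J, only.values = TRUE)$values) < 0)
  }
  list(state = c(x = z[1], y1 = z[2], y2 = z[3]),
       residual_norm = max(abs(rhs(z))),
       stable = stable)
}

#' Stability of a reduced-model equilibrium by perturbation
#'
#' Perturbs each component by a relative amount, integrates for `T`, and
#' reports whether the trajectory returned to the equilibrium.
#'
#' @inheritParams reduced_equilibrium
#' @param eq equilibrium state `c(x=, y1=, y2=)`.
#' @param rel relative perturbation size (default 1%).
#' @param T integration horizon.
#' @param tol return tolerance on the final relative deviation.
#' @export
reduced_stability_by_perturbation <- function(model, eq, params, avg,
                                              rel = 0.01, T = 300,
                                              tol = 0.02) {
  tr <- integrate_reduced(model, eq * (1 + rel), params, avg, T = T)
  if (tr$status != "completed") return(FALSE)
  fin <- c(tr$final$X, tr$final$Y1, tr$final$Y2)
  all(abs(fin - eq) <= tol * pmax(abs(eq), 1e-8))
}

# Forward-difference Jacobian of a small dense map (used for the reduced
# models; the scheme's own Jacobian convention lives in fd_jacobian()).
numeric_jacobian <- function(f, z, eps = 1e-7) {
  f0 <- f(z)
  J <- matrix(0, length(f0), length(z))
  for (j in seq_along(z)) {
    dz <- z
    step <- eps * max(1, abs(z[j]))
    dz[j] <- dz[j] + step
    J[, j] <- (f(dz) - f0) / step
  }
  J
}

# Linearization of the DDE about an equilibrium: instantaneous (A) and
# delayed (B) Jacobians of the right-hand side, by forward differences.
dde_linearization <- function(eq, params, avg) {
  tau <- params$tau_star
  f <- function(z, w) {
    x <- z[1]; y1 <- z[2]; y2 <- z[3]
    hx <- params$mu_M * exp(-params$rho * x)
    born <- params$k * x * y2 + (1 - exp(-params$zeta * x)) * avg$b2 * y2
    flux <- dde_delayed_transition(x, w[1], w[3], params, avg)
    c(x * (params$r - params$a * x + params$s * y1 - params$b * y2),
      born - flux - (params$g * x + avg$m1 + hx) * y1,
      flux - (avg$m2 + hx) * y2)
  }
  A <- matrix(0, 3, 3); B <- matrix(0, 3, 3)
  e <- 1e-7
  for (j in 1:3) {
    s <- e * max(1, abs(eq[j]))
    dz <- eq; dz[j] <- dz[j] + s
    A[, j] <- (f(dz, eq) - f(eq, eq)) / s
    dw <- eq; dw[j] <- dw[j] + s
    B[, j] <- (f(eq, dw) - f(eq, eq)) / s
  }
  list(A = A, B = B, tau = tau)
}

#' Linear stability of a DDE equilibrium via characteristic roots
#'
#' Linearizes the delay model about the equilibrium,
#' `v'(t) = A v(t) + B v(t - tau_star)`, and polishes the roots of the
#' characteristic equation `det(lambda I - A - B exp(-lambda tau)) = 0`
#' by Newton iteration started from the eigenvalues of `A + B` (the
#' zero-delay limit).  Growth rates of order `1e-4`, far below what a
#' perturb-and-integrate check can resolve, are decided reliably.
#'
#' @param eq equilibrium state `c(x, y1, y2)`.
#' @param params `agepp_parameters`.
#' @param avg `agepp_averaged`.
#' @return list with `stable`, `rightmost` (complex root with the largest
#'   real part), and all polished `roots`.
#' @export
dde_equilibrium_stability <- function(eq, params, avg) {
  lin <- dde_linearization(unname(eq), params, avg)
  h <- function(l) {
    M <- l * diag(3) - lin$A - lin$B * exp(-l * lin$tau)
    M[1, 1] * (M[2, 2] * M[3, 3] - M[2, 3] * M[3, 2]) -
      M[1, 2] * (M[2, 1] * M[3, 3] - M[2, 3] * M[3, 1]) +
      M[1, 3] * (M[2, 1] * M[3, 2] - M[2, 2] * M[3, 1])
  }
  newton <- function(l0) {
    l <- l0 + 0i
    for (i in 1:80) {
      hl <- h(l)
      dl <- (h(l + 1e-7) - hl) / 1e-7
      step <- hl / dl
      l <- l - step
      if (Mod(step) < 1e-13) break
    }
    l
  }
  roots <- vapply(eigen(lin$A + lin$B)$values, newton, complex(1))
  rightmost <- roots[which.max(Re(roots))]
  list(stable = Re(rightmost) < 0, rightmost = rightmost, roots = roots)
}
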