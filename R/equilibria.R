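# One application of the discrete one-step map Phi to (X, U), with the
# population integrals computed synchronously from U (at a fixed point the
# printed scheme's one-step lag is immaterial).
scheme_step_map <- function(X, U, grid, params) {
  st <- structure(list(n = 0L, t = 0, X = X, U = U,
                       Y1 = NA_real_, Y2 = NA_real_),
                  class = "agepp_state")
  y <- population_sizes(U, grid)
  st$Y1 <- unname(y["y1"]); st$Y2 <- unname(y["y2"])
  out <- advance_step(st, grid, params, lag_y = FALSE, negative = "clamp")
  list(X = out$X, U = out$U)
}

#' Fixed-point residual of the discretized system
#'
#' `F(X*, U*) = (X*, U*) - Phi(X*, U*)`, where `Phi` is one step of the
#' scheme (prey update, density shift/decay, newborn node) with the
#' population integrals computed from `U*`.  `F` vanishes exactly at fixed
#' points of the discrete dynamics, e.g. the extinction state and the
#' predator-free state `(r/a, 0)`.
#'
#' @param X_star prey value.
#' @param U_star age density on the grid nodes.
#' @param grid `agepp_grid`.
#' @param params `agepp_parameters`.
#' @return residual vector of length `N_max + 2` (prey first, then nodes).
#' @export
scheme_residual <- function(X_star, U_star, grid, params) {
  img <- scheme_step_map(X_star, U_star, grid, params)
  c(X_star - img$X, U_star - img$U)
}

#' Forward-difference Jacobian with relative density perturbations
#'
#' The prey column uses an absolute perturbation `eps`; each density column
#' uses the relative perturbation `eps * U_star[k]`, falling back to the
#' absolute `eps` at nodes where the density vanishes (otherwise the column
#' would be identically zero, e.g. at the predator-free state).
#'
#' @param F function of `(X, U)` returning a numeric vector.
#' @param X_star,U_star base point.
#' @param eps perturbation scale (default `1e-6`).
#' @return matrix with `length(F(X_star, U_star))` rows and
#'   `1 + length(U_star)` columns.
#' @export
fd_jacobian <- function(F, X_star, U_star, eps = 1e-6) {
  f0 <- F(X_star, U_star)
  m <- length(f0)
  n <- length(U_star)
  J <- matrix(0, m, n + 1L)
  J[, 1] <- (F(X_star + eps, U_star) - f0) / eps
  for (k in seq_len(n)) {
    step <- eps * U_star[k]
    if (step == 0) step <- eps
    Up <- U_star
    Up[k] <- Up[k] + step
    J[, k + 1L] <- (F(X_star, Up) - f0) / step
  }
  J
}

#' Locate an equilibrium of the discretized system by Newton iteration
#'
#' Newton's method on the fixed-point residual with the forward-difference
#' Jacobian.  Warm starts matter: use the state after a long integration,
#' or continuation from a neighbouring parameter value.  No line search is
#' used.
#'
#' @param start warm start: an `agepp_state`, an `agepp_trajectory` (its
#'   final state is used), or a list with `X` and `U`.
#' @param grid `agepp_grid`.
#' @param params `agepp_parameters`.
#' @param tol convergence tolerance on the residual max-norm.
#' @param max_iter Newton iteration cap.
#' @return An `agepp_equilibrium`: `X_star`, `U_star`, `residual_norm`,
#'   `converged`, `iterations`, and the population sizes at the solution.
#' @export
newton_equilibrium <- function(start, grid, params, tol = 1e-10,
                               max_iter = 50L) {
  if (inherits(start, "agepp_trajectory")) start <- start$final
  X <- start$X
  U <- start$U
  F <- function(X, U) scheme_residual(X, U, grid, params)
  res <- F(X, U)
  it <- 0L
  converged <- max(abs(res)) < tol
  while (!converged && it < max_iter) {
    J <- fd_jacobian(F, X, U)
    dz <- tryCatch(solve(J, res), error = function(e) NULL)
    if (is.null(dz)) break
    X <- X - dz[1]
    U <- U - dz[-1]
    res <- F(X, U)
    it <- it + 1L
    converged <- max(abs(res)) < tol
  }
  y <- population_sizes(pmax(U, 0), grid)
  structure(list(X_star = X, U_star = U,
                 residual_norm = max(abs(res)),
                 converged = converged, iterations = it,
                 y1 = unname(y["y1"]), y2 = unname(y["y2"]),
                 grid = grid, params = params),
            class = "agepp_equilibrium")
}

#' @export
print.agepp_equilibrium <- function(x, ...) {
  cat("Equilibrium (converged:", x$converged, ") X* =",
      format(x$X_star, digits = 6),
      " y1 =", format(x$y1, digits = 4),
      " y2 =", format(x$y2, digits = 4),
      " |F| =", format(x$residual_norm, digits = 3), "\n")
  invisible(x)
}

#' Jacobian of the one-step map at a state
#'
#' Forward differences of `Phi` with the same perturbation conventions as
#' [fd_jacobian()].  Feed the result to [assess_stability()].
#'
#' @inheritParams scheme_residual
#' @param eps perturbation scale.
#' @export
map_jacobian <- function(X_star, U_star, grid, params, eps = 1e-6) {
  Phi <- function(X, U) {
    img <- scheme_step_map(X, U, grid, params)
    c(img$X, img$U)
  }
  fd_jacobian(Phi, X_star, U_star, eps)
}

#' Stability of a fixed point of the one-step map
#'
#' A fixed point of the discrete map `Phi` is linearly stable iff the
#' spectral radius of its Jacobian is below one.  The eigenvalues of
#' `(dPhi - I)/h` approximate the continuous-time exponents and are stable
#' iff their real parts are negative; both views are reported.
#'
#' @param jacobian_of_map square Jacobian of the one-step map `Phi`
#'   (not of the residual `z - Phi(z)`).
#' @param h time step used to convert multipliers to exponents.
#' @param n_report number of leading exponents to return.
#' @return list with `stable`, `spectral_radius`, `multipliers` (leading),
#'   `exponents` (leading, by real part).
#' @export
assess_stability <- function(jacobian_of_map, h, n_report = 6L) {
  ev <- eigen(jacobian_of_map, only.values = TRUE)$values
  rad <- max(Mod(ev))
  expo <- (ev - 1) / h
  ord <- order(Re(expo), decreasing = TRUE)
  list(stable = rad < 1,
       spectral_radius = rad,
       multipliers = ev[order(Mod(ev), decreasing = TRUE)][
         seq_len(min(n_report, length(ev)))],
       exponents = expo[ord][seq_len(min(n_report, length(ev)))])
}

#' Semi-analytic coexistence equilibrium candidates
#'
#' At a fixed point of the scheme the density recursion makes `U` a known
#' survival profile scaled by the newborn level `U[0]`, so the fixed-point
#' equations collapse to a scalar renewal condition on the prey size
#' (the discrete lifetime reproduction integral equals one) plus a linear
#' equation for `U[0]` from the stationary prey balance.  The renewal
#' condition is scanned for sign changes over a log-spaced prey interval;
#' each root with a positive newborn level is returned.  The results are
#' exact fixed points up to root tolerance and serve as Newton warm starts
#' ([newton_equilibrium()] then converges in 0-2 iterations).
#'
#' @param grid `agepp_grid`.
#' @param params `agepp_parameters`.
#' @param x_interval prey interval scanned for roots.
#' @param n_scan number of scan points (log-spaced).
#' @return list of candidates, each `list(X, U, y1, y2)`, ordered by
#'   increasing prey value; empty when no coexistence state exists.
#' @export
coexistence_equilibria <- function(grid, params,
                                   x_interval = c(1e-3, 300),
                                   n_scan = 200) {
  h <- grid$h; tau <- grid$ages; NM <- grid$N_max
  phiB <- smooth_indicator(tau, params$tau_star, params$nu, "below")
  muB <- base_death_rate(tau, params)
  survival <- function(X) {
    mu <- params$g * X * phiB + muB + params$mu_M * exp(-params$rho * X)
    c(1, cumprod(pmax(1 - h * mu[seq_len(NM)], 0)))
  }
  w <- rep(1, NM + 1); w[c(1, NM + 1)] <- 0.5
  repro <- function(X)
    h * sum(w * birth_rate(X, tau, params) * survival(X))
  xs <- exp(seq(log(x_interval[1]), log(x_interval[2]),
                length.out = n_scan))
  Rv <- vapply(xs, repro, numeric(1)) - 1
  out <- list()
  for (i in seq_len(length(xs) - 1L)) {
    if (!is.finite(Rv[i]) || !is.finite(Rv[i + 1])) next
    if (Rv[i] * Rv[i + 1] >= 0) next
    X <- stats::uniroot(function(X) repro(X) - 1, c(xs[i], xs[i + 1]),
                        tol = 1e-13)$root
    S <- survival(X)
    y <- population_sizes(S, grid)
    denom <- params$s * y[["y1"]] - params$b * y[["y2"]]
    if (params$variant == "saturated") {
      # prey balance is nonlinear in U0; solve the scalar equation
      f <- function(U0) params$r - params$a * X +
        params$s * params$y1_hat * tanh(U0 * y[["y1"]] / params$y1_hat) -
        params$b * U0 * y[["y2"]]
      hi <- 1
      while (f(hi) > 0 && hi < 1e8) hi <- hi * 10
      U0 <- if (f(0) * f(hi) < 0)
        stats::uniroot(f, c(0, hi), tol = 1e-13)$root else NA_real_
    } else {
      U0 <- (params$a * X - params$r) / denom
    }
    if (is.finite(U0) && U0 > 0)
      out[[length(out) + 1L]] <-
        list(X = X, U = U0 * S,
             y1 = U0 * y[["y1"]], y2 = U0 * y[["y2"]])
  }
  out[order(vapply(out, `[[`, numeric(1), "X"))]
}
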