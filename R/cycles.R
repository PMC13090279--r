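#' First-return (Poincare) map on the section X = X*
#'
#' Starting from the density `U` on the hyperplane `X = X_star`, integrates
#' the scheme until the prey next crosses `X_star` in the upward direction;
#' the crossing density and time are obtained by linear interpolation
#' between the bracketing steps.
#'
#' @param U age density on the section.
#' @param X_star section level (the prey value of the unstable coexistence
#'   equilibrium).
#' @param grid `agepp_grid`.
#' @param params `agepp_parameters`.
#' @param max_time time budget before declaring no return.
#' @param lag_y population-integral convention, see [advance_step()].
#' @return list with `U` (density at return), `time` (return time, the
#'   period when `U` is a fixed point), and `status` (`"ok"`,
#'   `"no_return"`, or `"negative_density"`).
#' @export
poincare_map <- function(U, X_star, grid, params, max_time = 400,
                         lag_y = TRUE) {
  rt <- rate_tables(grid, params)
  res <- cpp_poincare(X_star, U, grid$h,
                      as.integer(round(max_time / grid$h)), grid$N1,
                      rt$phiA, rt$phiB, rt$muB, rt$Bt, params[], lag_y)
  if (res$status != "ok")
    return(list(U = NULL, time = NA_real_, status = res$status))
  list(U = res$U, time = res$time, status = "ok")
}

#' Locate a limit cycle as a fixed point of the Poincare map
#'
#' Minimises `f(U) = 0.5 * ||U - G(U)||^2` (with `G` the first-return map)
#' by Levenberg-Marquardt with a forward-difference Jacobian using relative
#' density perturbations.  Plain Newton on this system needs warmer starts
#' than long integration provides; the damped iteration is robust from the
#' density recorded at any section crossing of the attractor.
#'
#' @param U0 starting density on the section (e.g. from a crossing of a
#'   long trajectory).
#' @param X_star section level, the prey component of the (unstable)
#'   coexistence equilibrium.
#' @param grid,params grid and parameters.
#' @param tol stop when `f(U) < tol`.
#' @param grad_tol stop when the gradient max-norm falls below this.
#' @param max_iter Levenberg-Marquardt iteration cap.
#' @param settle number of plain Poincare-map iterations applied before
#'   the Levenberg-Marquardt refinement.  The unstable equilibrium is also
#'   a fixed point of the map; settling onto the (attracting) cycle first
#'   keeps the optimiser in the cycle's basin.
#' @param max_time per-return time budget passed to [poincare_map()].
#' @return An `agepp_cycle`: section density `U`, `X_star`, `period`,
#'   objective `f`, per-variable `extrema` over one period, the one-period
#'   `series`, convergence flag and iteration count.
#' @export
find_limit_cycle <- function(U0, X_star, grid, params, tol = 1e-14,
                             grad_tol = 1e-10, max_iter = 30L,
                             settle = 5L, max_time = 400) {
  G <- function(U) {
    r <- poincare_map(U, X_star, grid, params, max_time = max_time)
    if (r$status != "ok")
      stop("Poincare map failed: ", r$status, call. = FALSE)
    r$U
  }
  resid <- function(U) U - G(U)

  U <- U0
  for (i in seq_len(settle)) U <- G(U)
  R <- resid(U)
  f <- 0.5 * sum(R^2)
  lambda <- 1e-3
  it <- 0L
  converged <- f < tol
  eps <- 1e-6
  while (!converged && it < max_iter) {
    # forward-difference Jacobian of U - G(U), relative perturbations
    n <- length(U)
    J <- matrix(0, n, n)
    for (k in seq_len(n)) {
      step <- eps * U[k]
      if (step == 0) step <- eps
      Up <- U
      Up[k] <- Up[k] + step
      J[, k] <- (resid(Up) - R) / step
    }
    grad <- drop(crossprod(J, R))
    if (max(abs(grad)) < grad_tol) break
    JtJ <- crossprod(J)
    improved <- FALSE
    for (try in 1:12) {
      dU <- tryCatch(
        solve(JtJ + lambda * diag(n), -grad),
        error = function(e) NULL)
      if (!is.null(dU)) {
        Un <- U + dU
        Rn <- tryCatch(resid(Un), error = function(e) NULL)
        if (!is.null(Rn)) {
          fn <- 0.5 * sum(Rn^2)
          if (fn < f) {
            U <- Un; R <- Rn; f <- fn
            lambda <- lambda / 10
            improved <- TRUE
            break
          }
        }
      }
      lambda <- lambda * 10
    }
    it <- it + 1L
    converged <- f < tol
    if (!improved && !converged) break
  }

  per <- poincare_map(U, X_star, grid, params, max_time = max_time)
  period <- per$time
  series <- NULL
  extrema <- NULL
  if (per$status == "ok") {
    st <- structure(list(n = 0L, t = 0, X = X_star, U = U,
                         Y1 = NA_real_, Y2 = NA_real_),
                    class = "agepp_state")
    y <- population_sizes(U, grid)
    st$Y1 <- unname(y["y1"]); st$Y2 <- unname(y["y2"])
    tr <- integrate_age_model(st, grid, params, T_max = period,
                              blowup_threshold = Inf,
                              record_every = grid$h)
    series <- tr$series
    extrema <- data.frame(
      variable = c("x", "y1", "y2"),
      min = c(min(series$x), min(series$y1), min(series$y2)),
      max = c(max(series$x), max(series$y1), max(series$y2)))
  }
  structure(list(U = U, X_star = X_star, period = period, f = f,
                 converged = converged, iterations = it,
                 extrema = extrema, series = series,
                 grid = grid, params = params),
            class = "agepp_cycle")
}

#' @export
print.agepp_cycle <- function(x, ...) {
  cat("Limit cycle (converged:", x$converged, ") period =",
      format(x$period, digits = 5), " f(U) =", format(x$f, digits = 3), "\n")
  if (!is.null(x$extrema)) print(x$extrema)
  invisible(x)
}

#' Cyclic order of the six extremal events over one period
#'
#' For a one-period series of `x`, `y1`, `y2`, finds the times of the
#' maximum and minimum of each variable and returns the six events sorted
#' cyclically, starting at `max_y2`.  On the periodic coexistence attractor
#' the expected order is `max_y2, min_x, min_y1, min_y2, max_x, max_y1`.
#'
#' @param series data frame with columns `time`, `x`, `y1`, `y2` covering
#'   one period.
#' @return character vector of the six event names in cyclic order.
#' @export
cycle_extrema_order <- function(series) {
  ev <- c(
    max_x = series$time[which.max(series$x)],
    min_x = series$time[which.min(series$x)],
    max_y1 = series$time[which.max(series$y1)],
    min_y1 = series$time[which.min(series$y1)],
    max_y2 = series$time[which.max(series$y2)],
    min_y2 = series$time[which.min(series$y2)])
  ord <- names(sort(ev))
  i0 <- which(ord == "max_y2")
  ord[((seq_along(ord) - 1 + i0 - 1) %% length(ord)) + 1]
}
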