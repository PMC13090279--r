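# Rate functions sampled once on the grid nodes; the stepper recombines
# them with the prey-dependent factors at every step.
rate_tables <- function(grid, params, kmre = NULL) {
  tau <- grid$ages
  if (!is.null(kmre)) {
    list(phiA = numeric(length(tau)), phiB = numeric(length(tau)),
         muB = kmre$mu(tau), Bt = kmre$B(tau), kmre = TRUE)
  } else {
    list(phiA = smooth_indicator(tau, params$tau_star, params$nu, "above"),
         phiB = smooth_indicator(tau, params$tau_star, params$nu, "below"),
         muB = base_death_rate(tau, params),
         Bt = base_birth_rate(tau, params),
         kmre = FALSE)
  }
}

#' Advance the discrete state by one step
#'
#' Pure-R reference implementation of one step of the scheme: forward-Euler
#' prey update, interior density shift with Euler decay along the
#' characteristics, newborn node from the trapezoid birth integral, and the
#' population integrals.  By default the integrals follow the printed
#' scheme's one-step lag (`Y[n+1]` is the trapezoid of the pre-update
#' density); `lag_y = FALSE` recomputes them from the updated density.
#' Both converge to the same limit as `h` shrinks.
#'
#' @param state `agepp_state`.
#' @param grid `agepp_grid`.
#' @param params `agepp_parameters`.
#' @param lag_y use the printed one-step lag for `Y1`, `Y2` (default TRUE).
#' @param negative `"abort"` (raise an error listing the offending node, the
#'   signal that `h` is too large) or `"clamp"` (floor the Euler decay
#'   factor and the prey at zero; the exact decay factor `exp(-h*mu)` is
#'   essentially zero wherever `1 - h*mu` goes negative).
#' @return the advanced `agepp_state`.
#' @export
advance_step <- function(state, grid, params, lag_y = TRUE,
                         negative = c("abort", "clamp")) {
  negative <- match.arg(negative)
  h <- grid$h; N1 <- grid$N1; NM <- grid$N_max
  rt <- rate_tables(grid, params)
  X <- state$X; U <- state$U

  sy1 <- if (params$variant == "saturated")
    params$s * params$y1_hat * tanh(state$Y1 / params$y1_hat)
  else params$s * state$Y1
  Xn <- X * (1 + h * (params$r - params$a * X + sy1 - params$b * state$Y2))

  kx <- if (params$variant == "saturated")
    params$k * params$x_hat * tanh(X / params$x_hat) else params$k * X
  Bvec <- kx * rt$phiA + (1 - exp(-params$zeta * X)) * rt$Bt
  w <- rep(1, NM + 1); w[1] <- w[NM + 1] <- 0.5
  newborn <- h * sum(w * Bvec * U)

  mu <- params$g * X * rt$phiB + rt$muB + params$mu_M * exp(-params$rho * X)
  fac <- 1 - h * mu[seq_len(NM)]          # at ages 0 .. (NM-1)
  if (any(fac < 0) || Xn < 0) {
    if (negative == "abort") {
      bad <- which(fac < 0)
      stop("negative density produced (first at age ",
           if (length(bad)) grid$ages[bad[1]] else "prey",
           "); reduce the step h", call. = FALSE)
    }
    fac <- pmax(fac, 0)
    Xn <- max(Xn, 0)
  }
  Un <- c(newborn, U[seq_len(NM)] * fac)

  y <- if (lag_y) population_sizes(U, grid) else population_sizes(Un, grid)
  structure(list(n = state$n + 1L, t = (state$n + 1L) * h, X = Xn, U = Un,
                 Y1 = unname(y["y1"]), Y2 = unname(y["y2"])),
            class = "agepp_state")
}

#' Integrate the age-structured system
#'
#' Runs the compiled stepper from an initial condition (or an existing
#' discrete state) up to `T_max`, terminating early with status `"blowup"`
#' the first step any of `X`, `Y1`, `Y2` (optionally any density node)
#' exceeds `blowup_threshold`, or with status `"negative_density"` under
#' the `"abort"` policy.
#'
#' @param ic an `agepp_initial_condition` or `agepp_state`.
#' @param grid `agepp_grid`.
#' @param params `agepp_parameters`.
#' @param T_max maximal integration time (snapped to the grid).
#' @param blowup_threshold early-termination threshold on the solution
#'   components (default 1000).
#' @param snapshot_times times at which to record the full age density.
#' @param record_every record the `(t, x, y1, y2)` series every this many
#'   time units (default: every 0.25 time units, and always the final step).
#' @param check_density also apply the blow-up check to every density node.
#' @param kmre optional list `list(mu = function(tau), B = function(tau))`
#'   switching the stepper to prey-independent (decoupled renewal-equation)
#'   rates; used by the analytic-oracle and convergence tests.
#' @inheritParams advance_step
#' @return An `agepp_trajectory`: list with the sampled `series` data frame,
#'   `status`, termination time `t_end`, `snapshots` (matrix, one column per
#'   requested time), and the final state.
#' @export
integrate_age_model <- function(ic, grid, params, T_max,
                                blowup_threshold = 1000,
                                snapshot_times = NULL,
                                record_every = 0.25,
                                check_density = FALSE,
                                lag_y = TRUE,
                                negative = c("abort", "clamp"),
                                kmre = NULL) {
  negative <- match.arg(negative)
  state <- if (inherits(ic, "agepp_state")) ic
           else initialize_state(ic, grid, params)
  nsteps <- as.integer(round(T_max / grid$h))
  stride <- max(1L, as.integer(round(record_every / grid$h)))
  snap_steps <- if (is.null(snapshot_times)) integer(0)
                else as.integer(round(snapshot_times / grid$h))
  rt <- rate_tables(grid, params, kmre)

  res <- cpp_integrate(state$X, state$U, grid$h, nsteps, grid$N1,
                       rt$phiA, rt$phiB, rt$muB, rt$Bt,
                       params[], rt$kmre,
                       blowup_threshold, check_density,
                       negative == "clamp", lag_y,
                       stride, snap_steps)

  snaps <- NULL
  if (length(res$snapshot_times)) {
    snaps <- do.call(cbind, res$snapshots)
    colnames(snaps) <- format(res$snapshot_times)
  }
  structure(list(
    series = data.frame(time = res$time, x = res$x,
                        y1 = res$y1, y2 = res$y2),
    status = res$status,
    t_end = res$steps_done * grid$h,
    snapshots = snaps,
    snapshot_times = res$snapshot_times,
    final = structure(list(n = res$steps_done,
                           t = res$steps_done * grid$h,
                           X = res$X_final, U = res$U_final,
                           Y1 = res$y1[length(res$y1)],
                           Y2 = res$y2[length(res$y2)]),
                      class = "agepp_state"),
    grid = grid, params = params
  ), class = "agepp_trajectory")
}

#' @export
print.agepp_trajectory <- function(x, ...) {
  n <- nrow(x$series)
  cat("Trajectory to t =", x$t_end, "(", x$status, "),",
      n, "recorded points\n")
  cat("  final: x =", format(x$final$X, digits = 5),
      " y1 =", format(x$final$Y1, digits = 5),
      " y2 =", format(x$final$Y2, digits = 5), "\n")
  invisible(x)
}
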