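#' Phase diagram of the age-structured model in the (tau*, g) plane
#'
#' For every cell of the grid (all other parameters at their selected
#' values) the scheme is integrated from the standard initial condition
#' (juvenile level on `tau <= tau_star`, the sweep convention).  A cell
#' whose predator population stays below the extinction threshold over the
#' whole tail window is `predator_free`.  Otherwise the coexistence
#' equilibrium of the branch continued from the stable large-`g` region
#' (the smallest-prey branch; its age-averaged parameters vary smoothly
#' over the plane) is located by Newton, warm-started from the
#' semi-analytic candidates of [coexistence_equilibria()] with the
#' previous cell as continuation fallback, and classified by the
#' eigenvalues of the one-step-map Jacobian: stable gives
#' `equilibrial_coexistence`, unstable `periodic_coexistence`
#' (`classify = "eigen"`, the default).  The
#' cheaper `classify = "amplitude"` rule labels by the relative prey
#' oscillation amplitude over the tail instead.  Age-averaged parameters
#' are recorded for every cell with a converged equilibrium.
#'
#' @param tau_values maturation-age grid values.
#' @param g_values juvenile-predation grid values (swept in decreasing
#'   order within each `tau_star` column, carrying the equilibrium as a
#'   continuation warm start).
#' @param params base parameters (all but `tau_star`, `g` held fixed).
#' @param h time/age step of the sweep.
#' @param T_max integration horizon per cell.
#' @param classify `"eigen"` (Newton + map-Jacobian spectrum, the
#'   reference protocol) or `"amplitude"` (tail oscillation test).
#' @param extinction predator sizes below this count as extinct.
#' @param amplitude relative prey tail amplitude separating periodic from
#'   equilibrial under `classify = "amplitude"`.
#' @param tail_window tail window length (time units).
#' @param progress print one line per cell.
#' @return An `agepp_phase_diagram`: data frame with one row per cell:
#'   `tau_star`, `g`, `label`, equilibrium components, age-averaged
#'   parameters (`NA` where not applicable), `newton_converged`.
#' @export
phase_diagram <- function(tau_values, g_values, params = model_parameters(),
                          h = 0.025, T_max = 500,
                          classify = c("eigen", "amplitude"),
                          extinction = 1e-6, amplitude = 1e-3,
                          tail_window = 100, progress = FALSE) {
  classify <- match.arg(classify)
  g_values <- sort(g_values, decreasing = TRUE)
  rows <- list()
  for (ts in tau_values) {
    prev_eq <- NULL
    for (g in g_values) {
      pars <- params
      pars$tau_star <- ts
      pars$g <- g
      validate_parameters(pars)
      grid <- age_grid(h, pars$tau_star, pars$L)
      tr <- integrate_age_model(
        default_initial_condition(pars, convention = "closed"),
        grid, pars, T_max = T_max, blowup_threshold = 1000,
        negative = "clamp")
      row <- data.frame(tau_star = ts, g = g, label = NA_character_,
                        x_eq = NA_real_, y1_eq = NA_real_, y2_eq = NA_real_,
                        D = NA_real_, b2 = NA_real_, m1 = NA_real_,
                        m2 = NA_real_, M_B = NA_real_,
                        newton_converged = NA)
      s <- tr$series
      tl <- s[s$time >= tr$t_end - tail_window, ]
      extinct <- tr$status == "completed" &&
        max(tl$y1 + tl$y2) < extinction
      if (tr$status == "blowup") {
        row$label <- "blowup"
        prev_eq <- NULL
      } else if (extinct) {
        row$label <- "predator_free"
        prev_eq <- NULL
      } else {
        eq <- cell_equilibrium(prev_eq, grid, pars)
        if (!is.null(eq)) {
          prev_eq <- eq
          row$newton_converged <- TRUE
          avg <- age_averaged_parameters(pmax(eq$U_star, 0), eq$X_star,
                                         grid, pars)
          row$x_eq <- eq$X_star; row$y1_eq <- eq$y1; row$y2_eq <- eq$y2
          row$D <- avg$D; row$b2 <- avg$b2
          row$m1 <- avg$m1; row$m2 <- avg$m2; row$M_B <- avg$M_B
        } else {
          row$newton_converged <- FALSE
          prev_eq <- NULL
        }
        if (classify == "eigen" && !is.null(eq)) {
          st <- assess_stability(
            map_jacobian(eq$X_star, eq$U_star, grid, pars), grid$h)
          row$label <- if (st$stable) "equilibrial_coexistence"
                       else "periodic_coexistence"
        } else {
          amp <- (max(tl$x) - min(tl$x)) / mean(tl$x)
          row$label <- if (amp > amplitude) "periodic_coexistence"
                       else "equilibrial_coexistence"
        }
      }
      if (progress)
        message("tau*=", ts, " g=", g, " -> ", row$label)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("agepp_phase_diagram", "data.frame")
  out
}

# Coexistence equilibrium for one sweep cell.  The sweep follows the
# branch continued from the stable region at large g — the branch with the
# smallest prey value, whose age-averaged parameters vary smoothly over
# the plane.  Newton is warm-started from the semi-analytic candidate,
# with the previous cell's equilibrium as the continuation fallback.
cell_equilibrium <- function(prev_eq, grid, pars) {
  ok <- function(eq) !is.null(eq) && eq$converged && eq$X_star > 0 &&
    min(eq$U_star) > -1e-8 && eq$y1 + eq$y2 > 1e-10
  cand <- coexistence_equilibria(grid, pars)
  if (length(cand)) {
    eq <- newton_equilibrium(list(X = cand[[1]]$X, U = cand[[1]]$U),
                             grid, pars)
    if (ok(eq)) return(eq)
  }
  if (!is.null(prev_eq)) {
    eq <- newton_equilibrium(list(X = prev_eq$X_star, U = prev_eq$U_star),
                             grid, pars)
    if (ok(eq)) return(eq)
  }
  NULL
}

#' Age-averaged parameter surface over the (tau*, g) plane
#'
#' Computes the coexistence equilibrium (stable or unstable, the branch
#' with the smallest prey value) and its age-averaged parameters at every
#' grid cell where one exists, independently of which attractor the
#' standard initial condition reaches.  This is the surface the reduced
#' ODE/DDE models inherit their constants from.
#'
#' @inheritParams phase_diagram
#' @return data frame: `tau_star`, `g`, `x_eq`, `D`, `b2`, `m1`, `m2`,
#'   `M_B` (rows only for cells with an equilibrium).
#' @export
averaged_parameter_surface <- function(tau_values, g_values,
                                       params = model_parameters(),
                                       h = 0.0125) {
  rows <- list()
  for (ts in tau_values) for (g in g_values) {
    pars <- params
    pars$tau_star <- ts
    pars$g <- g
    grid <- age_grid(h, pars$tau_star, pars$L)
    cand <- coexistence_equilibria(grid, pars)
    if (!length(cand)) next
    eq <- newton_equilibrium(list(X = cand[[1]]$X, U = cand[[1]]$U),
                             grid, pars)
    if (!eq$converged) next
    avg <- age_averaged_parameters(pmax(eq$U_star, 0), eq$X_star,
                                   grid, pars)
    rows[[length(rows) + 1L]] <-
      data.frame(tau_star = ts, g = g, x_eq = eq$X_star, D = avg$D,
                 b2 = avg$b2, m1 = avg$m1, m2 = avg$m2, M_B = avg$M_B)
  }
  do.call(rbind, rows)
}

#' Phase diagram of a reduced model mimicking the age-structured one
#'
#' Re-labels the cells of an age-structured phase diagram by running the
#' reduced ODE or DDE model with that cell's age-averaged parameters from
#' a matching initial state.  The ODE cells are classified through the
#' equilibrium (nonlinear least squares + Jacobian eigenvalues); the DDE
#' cells by long integration, mirroring how each reduced model is analysed
#' in practice.  Cells the age-structured model labels `predator_free`
#' (or without averaged parameters) are carried over unchanged.
#'
#' @param pde_diagram an `agepp_phase_diagram` with averaged parameters.
#' @param model `"ode"` or `"dde"`.
#' @param params base parameters (as used for the diagram).
#' @param T_max integration horizon.
#' @param extinction,amplitude,tail_window classification thresholds.
#' @return data frame `tau_star`, `g`, `label` for the reduced model.
#' @export
reduced_phase_diagram <- function(pde_diagram, model = c("ode", "dde"),
                                  params = model_parameters(), T_max = 500,
                                  extinction = 1e-6, amplitude = 1e-3,
                                  tail_window = 100) {
  model <- match.arg(model)
  out <- pde_diagram[, c("tau_star", "g", "label")]
  for (i in seq_len(nrow(pde_diagram))) {
    cell <- pde_diagram[i, ]
    if (!cell$label %in% c("equilibrial_coexistence",
                           "periodic_coexistence") || is.na(cell$D))
      next
    pars <- params
    pars$tau_star <- cell$tau_star
    pars$g <- cell$g
    avg <- structure(list(D = cell$D, b2 = cell$b2, m1 = cell$m1,
                          m2 = cell$m2, M_B = cell$M_B,
                          u_tau_star = NA, x_eq = cell$x_eq),
                     class = "agepp_averaged")
    state0 <- c(x = 0.5, y1 = 0.1 * pars$tau_star,
                y2 = 0.05 * (pars$L - pars$tau_star))
    tr <- integrate_reduced(model, state0, pars, avg, T = T_max)
    s <- tr$series
    tl <- s[s$time >= tr$t_end - tail_window, ]
    lab <- if (tr$status == "blowup") "blowup"
    else if (max(tl$y1 + tl$y2) < extinction) "predator_free"
    else if (model == "ode") {
      eqr <- reduced_equilibrium("ode",
                                 c(x = mean(tl$x), y1 = mean(tl$y1),
                                   y2 = mean(tl$y2)), pars, avg)
      if (isTRUE(eqr$stable) && eqr$residual_norm < 1e-8)
        "equilibrial_coexistence" else "periodic_coexistence"
    } else {
      if ((max(tl$x) - min(tl$x)) / mean(tl$x) > amplitude)
        "periodic_coexistence" else "equilibrial_coexistence"
    }
    out$label[i] <- lab
  }
  out
}

#' Bifurcation branches along g at fixed maturation age
#'
#' Sweeps `g` (decreasing, with continuation): per sweep value the
#' coexistence equilibrium components with the eigenvalue stability flag,
#' and — on unstable (periodic) branches — the oscillation envelope
#' (per-variable min/max over the trajectory tail).
#'
#' @param tau_star fixed maturation age.
#' @param g_values sweep values of `g`.
#' @param params base parameters.
#' @param h,T_max solver settings.
#' @param tail_window envelope window at the end of the trajectory.
#' @return data frame: `g`, `label`, `x_eq`, `y1_eq`, `y2_eq`, `stable`,
#'   and `x_min`, `x_max`, `y1_min`, `y1_max`, `y2_min`, `y2_max` (`NA`
#'   on equilibrial branches).
#' @export
bifurcation_branches <- function(tau_star, g_values,
                                 params = model_parameters(),
                                 h = 0.025, T_max = 500, tail_window = 100) {
  pd <- phase_diagram(tau_values = tau_star, g_values = g_values,
                      params = params, h = h, T_max = T_max)
  env <- matrix(NA_real_, nrow(pd), 6,
                dimnames = list(NULL, c("x_min", "x_max", "y1_min",
                                        "y1_max", "y2_min", "y2_max")))
  for (i in seq_len(nrow(pd))) {
    if (pd$label[i] != "periodic_coexistence") next
    pars <- params
    pars$tau_star <- pd$tau_star[i]
    pars$g <- pd$g[i]
    grid <- age_grid(h, pars$tau_star, pars$L)
    tr <- integrate_age_model(default_initial_condition(pars, "closed"),
                              grid, pars, T_max = T_max,
                              blowup_threshold = 1000, negative = "clamp")
    s <- tr$series
    tl <- s[s$time >= tr$t_end - tail_window, ]
    env[i, ] <- c(min(tl$x), max(tl$x), min(tl$y1), max(tl$y1),
                  min(tl$y2), max(tl$y2))
  }
  data.frame(g = pd$g, label = pd$label,
             x_eq = pd$x_eq, y1_eq = pd$y1_eq, y2_eq = pd$y2_eq,
             stable = pd$label == "equilibrial_coexistence",
             env)
}
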