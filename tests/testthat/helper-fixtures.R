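# Shared, lazily computed fixtures.  The ensemble run is the expensive one;
# it is computed once per session and reused by the ensemble, LDA and
# acceptance tests.
.fixtures <- new.env(parent = emptyenv())

baseline_ensemble <- function() {
  if (is.null(.fixtures$ens)) {
    design <- latin_hypercube(300, seed = 1)
    .fixtures$ens <- run_ensemble(design, variant = "baseline",
                                  h = 0.025, T_max = 500)
  }
  .fixtures$ens
}

# Limit cycle on the periodic coexistence attractor at (tau* = 1, g = 0.1),
# nu = 100, h = 0.05; shared by the cycle unit tests and the acceptance
# checks.
periodic_cycle <- function() {
  if (is.null(.fixtures$cycle)) {
    params <- model_parameters(g = 0.1)
    grid <- age_grid(0.05, params$tau_star, params$L)
    tr <- integrate_age_model(default_initial_condition(params, "closed"),
                              grid, params, T_max = 500,
                              negative = "clamp")
    cand <- coexistence_equilibria(grid, params)
    X_star <- cand[[1]]$X
    cyc <- find_limit_cycle(tr$final$U, X_star, grid, params,
                            settle = 8L)
    .fixtures$cycle <- list(params = params, grid = grid, cycle = cyc,
                            X_star = X_star)
  }
  .fixtures$cycle
}

# A piecewise-smooth decoupled renewal problem with a closed-form solution
# along characteristics: mu(tau) = m0 + m1*tau, no births.
kmre_problem <- function() {
  list(
    mu = function(tau) 0.1 + 0.05 * tau,
    B = function(tau) numeric(length(tau)),
    u0 = function(tau) exp(-((tau - 3) / 1.5)^2),
    exact = function(t, tau) {
      tau0 <- tau - t
      ifelse(tau0 < 0, 0,
             exp(-((tau0 - 3) / 1.5)^2) *
               exp(-(0.1 + 0.05 * tau0) * t - 0.025 * t^2))
    }
  )
}
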