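test_that("grid construction snaps the maturation age and lifespan", {
  g <- age_grid(0.0125, 1, 30)
  expect_equal(g$N1, 80L)
  expect_equal(g$N_max, 2400L)
  expect_equal(age_grid(0.005, 1, 30)$N1, 200L)
  expect_error(age_grid(0.3, 1, 30, strict = TRUE), "commensurable")
  # non-strict mode snaps and reports the error
  g2 <- age_grid(0.3, 1, 30)
  expect_equal(g2$tau_star, 0.9)
  expect_gt(g2$snap_error, 0)
})

test_that("initialisation reproduces exact trapezoid integrals", {
  p <- model_parameters()
  g <- age_grid(0.025, 1, 30)
  # constant density: integrals are exact
  ic <- initial_condition(0.5, 0.3)
  st <- initialize_state(ic, g, p)
  expect_equal(st$X, 0.5)
  expect_equal(st$Y1, 0.3 * 1)
  expect_equal(st$Y2, 0.3 * 29)
  # zero density
  st0 <- initialize_state(initial_condition(1, 0), g, p)
  expect_identical(st0$Y1 + st0$Y2, 0)
  # default study profile starts the prey at 0.5
  std <- initialize_state(default_initial_condition(p), g, p)
  expect_equal(std$X, 0.5)
  expect_error(initialize_state(
    initial_condition(1, function(tau) tau - 10), g, p), "nonnegative")
})

test_that("juvenile and adult integrals share the maturation node exactly", {
  p <- model_parameters()
  g <- age_grid(0.05, 1, 30)
  set.seed(11)
  for (i in 1:10) {
    U <- runif(g$N_max + 1)
    y <- population_sizes(U, g)
    w <- rep(g$h, g$N_max + 1); w[c(1, g$N_max + 1)] <- g$h / 2
    expect_equal(unname(y["y1"] + y["y2"]), sum(w * U), tolerance = 1e-13)
  }
  # density supported strictly above tau*: y1 only sees the half-weight
  U <- numeric(g$N_max + 1)
  U[(g$N1 + 1):(g$N_max + 1)] <- 2
  y <- population_sizes(U, g)
  expect_equal(unname(y["y1"]), g$h / 2 * 2)
})

test_that("a single step matches the printed scheme evaluated by hand", {
  p <- model_parameters()
  g <- age_grid(0.005, 1, 30)
  st <- initialize_state(initial_condition(0.5, 0), g, p)
  st1 <- advance_step(st, g, p)
  expect_equal(st1$X, 0.5 * (1 + 0.005 * (0.4 - 0.01 * 0.5)))
  expect_identical(max(st1$U), 0)
})

test_that("the R step and the compiled integrator agree step for step", {
  p <- model_parameters(tau_star = 0.5, g = 0.3, nu = 5)
  g <- age_grid(0.05, 0.5, 30)
  ic <- default_initial_condition(p)
  st <- initialize_state(ic, g, p)
  n <- 40
  for (i in seq_len(n)) st <- advance_step(st, g, p)
  tr <- integrate_age_model(ic, g, p, T_max = n * g$h,
                            record_every = g$h)
  expect_equal(tr$final$X, st$X, tolerance = 1e-14)
  expect_equal(tr$final$U, st$U, tolerance = 1e-14)
  expect_equal(tr$final$Y1, st$Y1, tolerance = 1e-14)
})

test_that("with no predators the prey approaches its carrying capacity", {
  p <- model_parameters()
  g <- age_grid(0.05, 1, 30)
  tr <- integrate_age_model(initial_condition(0.5, 0), g, p, T_max = 500)
  expect_equal(tr$final$X, p$r / p$a, tolerance = 1e-6)
  expect_identical(tr$status, "completed")
})

test_that("pure advection shifts the density without altering values", {
  p <- model_parameters()
  g <- age_grid(0.1, 1, 30)
  set.seed(3)
  U0 <- runif(g$N_max + 1)
  ic <- initial_condition(1, function(tau) {
    idx <- round(tau / g$h) + 1
    U0[pmin(pmax(idx, 1), length(U0))]
  })
  kmre <- list(mu = function(tau) numeric(length(tau)),
               B = function(tau) numeric(length(tau)))
  n <- 25
  tr <- integrate_age_model(ic, g, p, T_max = n * g$h, kmre = kmre,
                            record_every = g$h)
  # interior values are the initial ones shifted by n nodes, bitwise
  expect_identical(tr$final$U[(n + 1):(g$N_max + 1)],
                   U0[1:(g$N_max + 1 - n)])
  expect_identical(tr$final$U[1:n], rep(0, n))
})

test_that("decoupled renewal solution converges to the analytic one at O(h)", {
  p <- model_parameters()
  prob <- kmre_problem()
  errs <- vapply(c(0.1, 0.05, 0.025), function(h) {
    g <- age_grid(h, 1, 30)
    tr <- integrate_age_model(initial_condition(1, prob$u0), g, p,
                              T_max = 5, kmre = prob,
                              record_every = 5)
    exact <- prob$exact(5, g$ages)
    sel <- g$ages - 5 >= 0 & exact > 1e-6   # characteristics from t = 0
    max(abs(tr$final$U[sel] - exact[sel]) / exact[sel])
  }, numeric(1))
  ratios <- errs[-length(errs)] / errs[-1]
  expect_true(all(ratios > 1.7 & ratios < 2.3))
})

test_that("self-convergence of the coupled solution is first order", {
  p <- model_parameters()
  ic <- initial_condition(0.5, function(tau)
    0.1 * exp(-tau / 5) * (tau <= 30))
  sol <- lapply(c(0.1, 0.05, 0.025), function(h) {
    g <- age_grid(h, 1, 30)
    tr <- integrate_age_model(ic, g, p, T_max = 20, record_every = 20)
    list(g = g, X = tr$final$X, U = tr$final$U)
  })
  # ||(x,u)|| = |x| + L1(u), comparing on the coarse grid nodes
  dnorm <- function(a, b) {
    idx <- seq(1, length(b$U), by = 2)   # b has half the step of a
    w <- rep(a$g$h, a$g$N_max + 1); w[c(1, a$g$N_max + 1)] <- a$g$h / 2
    abs(a$X - b$X) + sum(w * abs(a$U - b$U[idx]))
  }
  d1 <- dnorm(sol[[1]], sol[[2]])
  d2 <- dnorm(sol[[2]], sol[[3]])
  expect_gt(d1 / d2, 1.7)
  expect_lt(d1 / d2, 2.3)
})

test_that("solution components stay nonnegative when h*mu stays below one", {
  p <- model_parameters()
  g <- age_grid(0.01, 1, 30)
  tr <- integrate_age_model(default_initial_condition(p), g, p,
                            T_max = 50, record_every = 0.5)
  expect_true(all(tr$series$x >= 0))
  expect_true(all(tr$series$y1 >= 0))
  expect_true(all(tr$series$y2 >= 0))
  expect_true(all(tr$final$U >= 0))
})

test_that("blow-up terminates the run early with the offending time", {
  p <- model_parameters(g = 0)   # runaway prey-juvenile feedback
  g <- age_grid(0.025, 1, 30)
  tr <- integrate_age_model(default_initial_condition(p, "closed"), g, p,
                            T_max = 500, blowup_threshold = 1000,
                            negative = "clamp")
  expect_identical(tr$status, "blowup")
  expect_lt(tr$t_end, 500)
  expect_true(max(tr$series$x, tr$series$y1, tr$series$y2) > 1000)
})

test_that("too-large steps signal negative densities instead of continuing", {
  p <- model_parameters(g = 1, mu_M = 5)
  g <- age_grid(0.5, 1, 30)
  st <- initialize_state(default_initial_condition(p), g, p)
  st$X <- 50   # makes h * mu exceed one on the juvenile segment
  expect_error(advance_step(st, g, p, negative = "abort"), "reduce the step")
  tr <- integrate_age_model(st, g, p, T_max = 5, negative = "abort")
  expect_identical(tr$status, "negative_density")
})

test_that("density snapshots are recorded at the requested times", {
  p <- model_parameters()
  g <- age_grid(0.05, 1, 30)
  tr <- integrate_age_model(default_initial_condition(p), g, p,
                            T_max = 10, snapshot_times = c(0, 5, 10))
  expect_equal(ncol(tr$snapshots), 3)
  expect_equal(nrow(tr$snapshots), g$N_max + 1)
  expect_equal(tr$snapshot_times, c(0, 5, 10))
  expect_equal(tr$snapshots[, 1], initialize_state(
    default_initial_condition(p), g, p)$U)
})
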