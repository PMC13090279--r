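#' Smoothed maturity indicator
#'
#' Logistic approximation of the indicator of adulthood (`direction =
#' "above"`, increasing in age) or of juvenility (`"below"`, decreasing).
#' The two directions form an exact partition of unity: the `"below"` value
#' is computed as one minus the `"above"` value, so their sum is exactly 1
#' in floating point for any age.
#'
#' @param tau age (vectorised).
#' @param tau_star maturation age.
#' @param nu positive smoothness parameter; as `nu` grows the indicator
#'   approaches a sharp switch at `tau_star`.
#' @param direction `"above"` for the adult indicator, `"below"` for the
#'   juvenile indicator.
#' @return values in (0, 1), same length as `tau`.
#' @examples
#' smooth_indicator(0, tau_star = 1, nu = 1)   # ~0.269
#' smooth_indicator(0, tau_star = 1, nu = 100) # ~3.7e-44
#' @export
smooth_indicator <- function(tau, tau_star, nu,
                             direction = c("above", "below")) {
  direction <- match.arg(direction)
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu <= 0)
    stop("nu must be a positive scalar", call. = FALSE)
  above <- plogis(nu * (tau - tau_star))
  if (direction == "above") above else 1 - above
}

#' Base (prey-independent) birth rate of adult predators
#'
#' Zero before the maturation age; for adults it decays exponentially from
#' `2*b_p` at maturation towards the floor `b_p` at old age.  This sharp
#' cutoff at `tau_star` is deliberate: the age-averaged reductions assume
#' the base birth rate vanishes on the juvenile ages.
#'
#' @param tau age (vectorised).
#' @param params `agepp_parameters`.
#' @return nonnegative rates bounded by `2*b_p`.
#' @export
base_birth_rate <- function(tau, params) {
  with(params, ifelse(tau < tau_star, 0,
                      b_p * (exp(-b_ep * (tau - tau_star)) + 1)))
}

#' Base (age-related) death rate of predators
#'
#' Strictly positive and increasing in age; equals `d_p` at the lifespan `L`.
#'
#' @inheritParams base_birth_rate
#' @export
base_death_rate <- function(tau, params) {
  with(params, d_p * exp(d_ep * (tau - L)))
}

#' Predator birth rate
#'
#' `B(x, tau) = k*x*phi_above(tau) + Btilde(tau)*(1 - exp(-zeta*x))` in the
#' baseline variant; the saturated variant replaces `k*x` by
#' `k*x_hat*tanh(x/x_hat)`, bounding reproduction at high prey abundance.
#' The rate is zero for all ages when the prey is absent.
#'
#' @param x prey population size (scalar, nonnegative).
#' @param tau age (vectorised).
#' @param params `agepp_parameters`.
#' @export
birth_rate <- function(x, tau, params) {
  if (any(x < 0)) stop("prey size x must be nonnegative", call. = FALSE)
  kx <- if (params$variant == "saturated")
    params$k * params$x_hat * tanh(x / params$x_hat) else params$k * x
  kx * smooth_indicator(tau, params$tau_star, params$nu, "above") +
    base_birth_rate(tau, params) * (1 - exp(-params$zeta * x))
}

#' Predator death rate
#'
#' Sum of predation on juveniles by the prey (`g*x*phi_below`), the
#' age-related base death rate, and a hunger term `mu_M*exp(-rho*x)` that
#' fades as prey becomes plentiful.  Strictly positive everywhere, with
#' lower bound `d_p*exp(-d_ep*L)`.
#'
#' @inheritParams birth_rate
#' @export
death_rate <- function(x, tau, params) {
  if (any(x < 0)) stop("prey size x must be nonnegative", call. = FALSE)
  params$g * x * smooth_indicator(tau, params$tau_star, params$nu, "below") +
    base_death_rate(tau, params) + params$mu_M * exp(-params$rho * x)
}

#' Prey growth rate
#'
#' Right-hand side of the prey ODE: logistic growth plus a gain from eating
#' juvenile predators and a loss to adult predators,
#' `x*(r - a*x + s*y1 - b*y2)`.  The saturated variant bounds the juvenile
#' gain by `s*y1_hat*tanh(y1/y1_hat)`.
#'
#' @param x prey population size.
#' @param y1 juvenile predator population size.
#' @param y2 adult predator population size.
#' @param params `agepp_parameters`.
#' @export
prey_growth_rate <- function(x, y1, y2, params) {
  if (any(c(x, y1, y2) < 0))
    stop("state components must be nonnegative", call. = FALSE)
  sy1 <- if (params$variant == "saturated")
    params$s * params$y1_hat * tanh(y1 / params$y1_hat) else params$s * y1
  x * (params$r - params$a * x + sy1 - params$b * y2)
}
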