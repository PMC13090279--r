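#' Model parameters for the age-structured role-reversal system
#'
#' Constructs the full parameter set of the coupled prey-ODE / predator
#' renewal-equation model.  Defaults are the selected values of the model's
#' reference parameter table; every value can be overridden by name.
#'
#' The parameters are:
#' \describe{
#'   \item{tau_star}{maturation age of the predator (time units); separates
#'     juveniles (eaten by the prey, unable to reproduce) from adults.}
#'   \item{g}{consumption rate of juvenile predators by the prey
#'     (1/(prey x time)).}
#'   \item{nu}{smoothness of the logistic maturity indicator (1/time);
#'     large `nu` approaches a sharp juvenile/adult switch.}
#'   \item{r}{intrinsic growth rate of the prey (1/time).}
#'   \item{a}{intraspecific competition rate of the prey (1/(prey x time)).}
#'   \item{k}{reproduction rate of the predator per unit prey.}
#'   \item{b}{consumption rate of prey by adult predators.}
#'   \item{s}{growth rate of prey due to eating juvenile predators.}
#'   \item{zeta}{exponential factor in the prey-limited base birth term.}
#'   \item{mu_M}{prefactor of the hunger death rate of the predator.}
#'   \item{rho}{exponential factor of the hunger death rate.}
#'   \item{d_p}{prefactor of the base (age-related) death rate.}
#'   \item{b_p}{prefactor of the base birth rate of adult predators.}
#'   \item{b_ep}{exponential factor of the base birth rate.}
#'   \item{d_ep}{exponential factor of the base death rate.}
#'   \item{L}{maximal predator lifespan (time units); the age density is
#'     truncated at this age.}
#'   \item{variant}{`"baseline"` or `"saturated"`; the saturated variant
#'     replaces the unbounded birth terms `k*x` and `s*y1` by
#'     `k*x_hat*tanh(x/x_hat)` and `s*y1_hat*tanh(y1/y1_hat)`.}
#'   \item{x_hat, y1_hat}{saturation scales of the saturated variant.}
#' }
#'
#' @param ... named parameter overrides, e.g. `model_parameters(g = 0.1)`.
#' @param variant `"baseline"` (default) or `"saturated"`.
#' @return An object of class `agepp_parameters` (a validated named list).
#' @examples
#' p <- model_parameters(tau_star = 1, g = 0.1)
#' p$r
#' @export
model_parameters <- function(..., variant = c("baseline", "saturated")) {
  variant <- match.arg(variant)
  p <- default_parameter_values()
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("all parameter overrides must be named", call. = FALSE)
    unknown <- setdiff(names(over), c(names(p), "variant"))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    p[names(over)] <- over
  }
  p$variant <- variant
  p <- structure(p, class = "agepp_parameters")
  validate_parameters(p)
  p
}

default_parameter_values <- function() {
  list(
    tau_star = 1, g = 0.2, nu = 100, r = 0.4, a = 0.01, k = 0.3, b = 0.8,
    s = 0.2, zeta = 10, mu_M = 1, rho = 5, d_p = 0.4, b_p = 0.05,
    b_ep = 0.1, d_ep = 0.1,
    L = 30, x_hat = 20, y1_hat = 10,
    variant = "baseline"
  )
}

#' Sampling ranges of the 15 biological parameters
#'
#' Lower and upper bounds used for ensemble (Latin hypercube) studies.
#' The smoothness parameter `nu` spans gradual (1) to essentially sharp
#' (100) maturation; the other ranges bracket the selected values while
#' keeping their order of magnitude.
#'
#' @return A data.frame with columns `parameter`, `lower`, `upper`
#'   (15 rows, in canonical parameter order).
#' @export
parameter_ranges <- function() {
  data.frame(
    parameter = c("tau_star", "g", "nu", "r", "a", "k", "b", "s",
                  "zeta", "mu_M", "rho", "d_p", "b_p", "b_ep", "d_ep"),
    lower = c(0, 0, 1, 0.1, 0.005, 0.1, 0.1, 0.1, 5, 0.5, 3, 0.1, 0.03,
              0.05, 0.05),
    upper = c(2, 1, 100, 0.6, 0.05, 1, 1, 1, 20, 5, 7, 1, 0.1, 0.15, 0.15),
    stringsAsFactors = FALSE
  )
}

validate_parameters <- function(p) {
  pos <- c("r", "a", "s", "b", "mu_M", "nu", "zeta", "rho",
           "d_p", "b_p", "b_ep", "d_ep", "L", "tau_star")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a positive finite scalar",
           call. = FALSE)
  }
  for (nm in c("k", "g")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("parameter '", nm, "' must be a nonnegative finite scalar",
           call. = FALSE)
  }
  if (p$tau_star >= p$L)
    stop("maturation age tau_star must be smaller than the lifespan L",
         call. = FALSE)
  if (!p$variant %in% c("baseline", "saturated"))
    stop("variant must be 'baseline' or 'saturated'", call. = FALSE)
  if (p$variant == "saturated") {
    for (nm in c("x_hat", "y1_hat"))
      if (!is.numeric(p[[nm]]) || p[[nm]] <= 0)
        stop("saturation scale '", nm, "' must be positive", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.agepp_parameters <- function(x, ...) {
  cat("Age-structured predator-prey parameters (", x$variant,
      " variant)\n", sep = "")
  nm <- setdiff(names(x), "variant")
  vals <- unlist(x[nm])
  cat(paste0("  ", format(nm, width = 9), " = ", format(vals)),
      sep = "\n")
  invisible(x)
}

#' Initial condition of the coupled system
#'
#' @param x0 initial prey population size (positive scalar).
#' @param u0 initial predator age density: either a function of age, or a
#'   list `list(levels=, breaks=)` describing a piecewise-constant profile
#'   (`levels[i]` on `[breaks[i], breaks[i+1])`), or a single nonnegative
#'   constant.  Must be nonnegative and supported on `[0, L]`.
#' @return Object of class `agepp_initial_condition`.
#' @seealso [default_initial_condition()] for the study's standard profile.
#' @export
initial_condition <- function(x0, u0) {
  if (!is.numeric(x0) || length(x0) != 1L || !is.finite(x0) || x0 <= 0)
    stop("x0 must be a positive scalar", call. = FALSE)
  if (is.numeric(u0) && length(u0) == 1L) {
    lev <- u0
    u0 <- function(tau) rep_len(lev, length(tau))
  } else if (is.list(u0) && !is.function(u0)) {
    if (!all(c("levels", "breaks") %in% names(u0)))
      stop("piecewise u0 needs 'levels' and 'breaks'", call. = FALSE)
    if (length(u0$breaks) != length(u0$levels) + 1L)
      stop("need length(breaks) == length(levels) + 1", call. = FALSE)
    if (any(u0$levels < 0)) stop("u0 must be nonnegative", call. = FALSE)
    lv <- u0$levels; br <- u0$breaks
    u0 <- function(tau) {
      idx <- findInterval(tau, br, rightmost.closed = TRUE)
      out <- numeric(length(tau))
      inside <- idx >= 1L & idx <= length(lv)
      out[inside] <- lv[idx[inside]]
      out
    }
  } else if (!is.function(u0)) {
    stop("u0 must be a function, a constant, or a piecewise-constant list",
         call. = FALSE)
  }
  structure(list(x0 = x0, u0 = u0), class = "agepp_initial_condition")
}

#' Standard initial condition of the numerical studies
#'
#' Prey starts at 0.5; the predator age density is 0.1 on the juvenile ages
#' and 0.05 on the adult ages up to the lifespan `L`, zero beyond.
#'
#' @param params `agepp_parameters` supplying `tau_star` and `L`.
#' @param convention boundary convention at the maturation age: the
#'   half-open default assigns the juvenile level on `[0, tau_star)`;
#'   `"closed"` assigns it on `[0, tau_star]` (the convention used by the
#'   phase-diagram sweeps).
#' @return `agepp_initial_condition`.
#' @export
default_initial_condition <- function(params = model_parameters(),
                                      convention = c("half_open", "closed")) {
  convention <- match.arg(convention)
  ts <- params$tau_star; L <- params$L
  u0 <- if (convention == "half_open") {
    function(tau) ifelse(tau < 0 | tau > L, 0, ifelse(tau < ts, 0.1, 0.05))
  } else {
    function(tau) ifelse(tau < 0 | tau > L, 0, ifelse(tau <= ts, 0.1, 0.05))
  }
  initial_condition(x0 = 0.5, u0 = u0)
}
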