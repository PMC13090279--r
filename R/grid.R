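#' Build the common time/age grid
#'
#' The scheme advances time and age with the same step `h`, so generations
#' propagate exactly along characteristics.  The maturation age and the age
#' cap must be (approximately) commensurable with `h`; both are snapped to
#' the nearest grid node and the relative snap error is recorded.
#'
#' @param h time/age step (positive).
#' @param tau_star maturation age.
#' @param L maximal predator lifespan; density advected beyond this age is
#'   discarded (equivalent to an infinite death rate past `L`).  In
#'   `"theory"` mode the grid instead extends to `tau0_max + T`, the support
#'   reachable from a compactly supported initial density — used by the
#'   convergence test problems where nothing is truncated.
#' @param T optional maximal integration time (snapped to the grid).
#' @param tau0_max support bound of the initial density (`"theory"` mode).
#' @param mode `"lifespan"` (default) or `"theory"`.
#' @param strict error (rather than snap) when `tau_star` or `L` is not
#'   h-commensurable to within `1e-6 * h`.
#' @return An `agepp_grid`: list with `h`, `N1` (index of `tau_star`),
#'   `N_max` (last node index), `ages`, snapped `tau_star`, `L`, and the
#'   relative snap error.
#' @examples
#' g <- age_grid(h = 0.0125, tau_star = 1, L = 30)
#' c(g$N1, g$N_max)  # 80, 2400
#' @export
age_grid <- function(h, tau_star, L, T = NULL, tau0_max = NULL,
                     mode = c("lifespan", "theory"), strict = FALSE) {
  mode <- match.arg(mode)
  if (!is.numeric(h) || length(h) != 1L || h <= 0)
    stop("h must be a positive scalar", call. = FALSE)
  if (tau_star <= 0 || tau_star >= L)
    stop("need 0 < tau_star < L", call. = FALSE)
  snap <- function(x, what) {
    n <- max(1, round(x / h))   # at least one node (tau_star below h snaps up)
    err <- abs(x - n * h)
    if (strict && err > 1e-6 * h)
      stop(what, " = ", x, " is not commensurable with h = ", h,
           " (snap error ", format(err), ")", call. = FALSE)
    list(n = as.integer(n), err = err)
  }
  s1 <- snap(tau_star, "tau_star")
  sL <- snap(L, "L")
  N1 <- s1$n
  N_max <- sL$n
  N <- NULL
  if (!is.null(T)) N <- snap(T, "T")$n
  if (mode == "theory") {
    if (is.null(tau0_max) || is.null(T))
      stop("theory mode needs tau0_max and T", call. = FALSE)
    N0 <- snap(tau0_max, "tau0_max")$n
    N_max <- N0 + N
  }
  if (N1 >= N_max)
    stop("tau_star must lie strictly inside the age grid", call. = FALSE)
  structure(list(
    h = h, N1 = N1, N_max = N_max, N = N,
    tau_star = N1 * h, L = sL$n * h,
    ages = (0:N_max) * h,
    mode = mode,
    snap_error = max(s1$err, sL$err) / h
  ), class = "agepp_grid")
}

#' @export
print.agepp_grid <- function(x, ...) {
  cat("Age/time grid: h =", x$h, "| nodes 0..", x$N_max,
      "| tau* at node", x$N1, "(", x$tau_star, ")\n")
  invisible(x)
}

#' Juvenile and adult population sizes from an age density
#'
#' Trapezoid-rule integrals of the density over the juvenile segment
#' `[0, tau_star]` and the adult segment `[tau_star, L]`.  The node at the
#' maturation age carries half weight in each integral, so `y1 + y2` equals
#' the single trapezoid integral over the full grid exactly.
#'
#' @param U density values at the grid nodes.
#' @param grid `agepp_grid`.
#' @return named vector `c(y1 = , y2 = )`.
#' @export
population_sizes <- function(U, grid) {
  h <- grid$h; N1 <- grid$N1; NM <- grid$N_max
  stopifnot(length(U) == NM + 1L)
  y1 <- h * (0.5 * U[1] + 0.5 * U[N1 + 1] +
               sum(U[seq_len(N1 - 1) + 1]))
  idx <- if (N1 + 1 <= NM - 1) (N1 + 1):(NM - 1) else integer(0)
  y2 <- h * (0.5 * U[N1 + 1] + 0.5 * U[NM + 1] + sum(U[idx + 1]))
  c(y1 = y1, y2 = y2)
}

#' Initialise the discrete state from an initial condition
#'
#' Samples the initial age density at the grid nodes and computes the
#' initial juvenile/adult population integrals by the trapezoid rule.
#'
#' @param ic `agepp_initial_condition`.
#' @param grid `agepp_grid`.
#' @param params `agepp_parameters`.
#' @return An `agepp_state`: list with step index `n`, time `t`, prey `X`,
#'   density `U`, and integrals `Y1`, `Y2`.
#' @export
initialize_state <- function(ic, grid, params) {
  U <- ic$u0(grid$ages)
  if (length(U) != length(grid$ages))
    stop("u0 must return one value per grid node", call. = FALSE)
  if (any(!is.finite(U)) || any(U < 0))
    stop("initial age density must be finite and nonnegative", call. = FALSE)
  y <- population_sizes(U, grid)
  structure(list(n = 0L, t = 0, X = ic$x0, U = U,
                 Y1 = unname(y["y1"]), Y2 = unname(y["y2"])),
            class = "agepp_state")
}
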