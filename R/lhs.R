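#' Latin hypercube design over the model parameter box
#'
#' Stratified design: each column has exactly one sample per bin
#' `[lo + j*(hi-lo)/n, lo + (j+1)*(hi-lo)/n)`, with independent random
#' permutations across columns.  Reproducible under a fixed seed.
#'
#' @param n number of samples.
#' @param ranges data frame with columns `parameter`, `lower`, `upper`
#'   (default [parameter_ranges()], the 15 biological parameters).
#' @param seed optional integer seed.
#' @return An `agepp_lhs`: list with the `n x d` `samples` matrix (columns
#'   named by parameter), `ranges`, `n`, `seed`.
#' @export
latin_hypercube <- function(n, ranges = parameter_ranges(), seed = NULL) {
  stopifnot(n >= 1, all(ranges$upper > ranges$lower))
  if (!is.null(seed)) set.seed(seed)
  d <- nrow(ranges)
  Z <- lhs::randomLHS(n, d)
  X <- sweep(sweep(Z, 2, ranges$upper - ranges$lower, `*`),
             2, ranges$lower, `+`)
  colnames(X) <- ranges$parameter
  structure(list(samples = X, ranges = ranges, n = n, seed = seed),
            class = "agepp_lhs")
}

#' Classify the long-term behaviour of a trajectory
#'
#' Four outcomes: `blowup` (a solution component exceeded the threshold
#' before the final time), `predator_free` (terminal total predator
#' population below the extinction threshold), `periodic_coexistence`
#' (relative oscillation amplitude of the prey over the tail window above
#' `amplitude`), else `equilibrial_coexistence`.
#'
#' @param trajectory `agepp_trajectory`.
#' @param extinction terminal `y1 + y2` below this is predator extinction.
#' @param amplitude relative prey amplitude `(max-min)/mean` over the tail
#'   separating periodic from equilibrial.
#' @param tail_window length of the tail window (time units).
#' @return a length-1 character label, with attribute `diagnostics`.
#' @export
classify_attractor <- function(trajectory, extinction = 1e-6,
                               amplitude = 1e-3, tail_window = 100) {
  if (trajectory$status == "blowup")
    return(structure("blowup",
                     diagnostics = list(t_end = trajectory$t_end)))
  s <- trajectory$series
  yTot <- s$y1[nrow(s)] + s$y2[nrow(s)]
  if (!is.finite(yTot) || yTot < extinction)
    return(structure("predator_free", diagnostics = list(y_final = yTot)))
  tail <- s[s$time >= trajectory$t_end - tail_window, ]
  if (nrow(tail) < 5)
    return(structure("inconclusive",
                     diagnostics = list(t_end = trajectory$t_end)))
  m <- mean(tail$x)
  amp <- if (m > 0) (max(tail$x) - min(tail$x)) / m else 0
  lab <- if (amp > amplitude) "periodic_coexistence"
         else "equilibrial_coexistence"
  structure(lab, diagnostics = list(relative_amplitude = amp))
}

#' Run the age-structured model over a Latin hypercube design
#'
#' Integrates the scheme for every parameter sample from the standard
#' initial condition and classifies each trajectory.  The Euler decay
#' factor is floored at zero (`negative = "clamp"`): at ensemble step sizes
#' the juvenile death rate `g*x` can make `1 - h*mu` negative where the
#' exact decay `exp(-h*mu)` is essentially zero.
#'
#' @param design `agepp_lhs` (or a bare samples matrix with the 15 columns).
#' @param variant `"baseline"` or `"saturated"`.
#' @param h time/age step.
#' @param T_max integration horizon.
#' @param blowup_threshold blow-up declaration threshold.
#' @param extinction,amplitude,tail_window see [classify_attractor()].
#' @param progress print a progress line every so many samples (0 = quiet).
#' @return data frame: the sampled parameters plus `label`, `t_end`, and
#'   the tail amplitude diagnostic.
#' @export
run_ensemble <- function(design, variant = c("baseline", "saturated"),
                         h = 0.005, T_max = 500, blowup_threshold = 1000,
                         extinction = 1e-6, amplitude = 1e-3,
                         tail_window = 100, progress = 0) {
  variant <- match.arg(variant)
  X <- if (inherits(design, "agepp_lhs")) design$samples else design
  n <- nrow(X)
  labels <- character(n)
  t_end <- numeric(n)
  amp <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    pars <- do.call(model_parameters,
                    c(as.list(X[i, ]), list(variant = variant)))
    grid <- age_grid(h, pars$tau_star, pars$L)
    ic <- default_initial_condition(pars)
    tr <- integrate_age_model(ic, grid, pars, T_max = T_max,
                              blowup_threshold = blowup_threshold,
                              negative = "clamp")
    lab <- classify_attractor(tr, extinction, amplitude, tail_window)
    labels[i] <- as.character(lab)
    t_end[i] <- tr$t_end
    dg <- attr(lab, "diagnostics")
    if (!is.null(dg$relative_amplitude)) amp[i] <- dg$relative_amplitude
    if (progress > 0 && i %% progress == 0)
      message("sample ", i, "/", n, " (", labels[i], ")")
  }
  out <- as.data.frame(X)
  out$label <- labels
  out$t_end <- t_end
  out$tail_amplitude <- amp
  out
}

#' Class counts and fractions of an ensemble
#'
#' @param labels character vector of attractor labels (or an ensemble data
#'   frame with a `label` column).
#' @return data frame with one row per class (`blowup`, `predator_free`,
#'   `equilibrial_coexistence`, `periodic_coexistence`): `count` and
#'   `fraction` (fractions sum to 1).
#' @export
ensemble_summary <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  classes <- c("equilibrial_coexistence", "periodic_coexistence",
               "predator_free", "blowup")
  extra <- setdiff(unique(labels), classes)
  classes <- c(classes, extra)
  counts <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  data.frame(class = classes, count = counts,
             fraction = counts / length(labels),
             row.names = NULL)
}
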