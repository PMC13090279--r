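#' Multiclass Fisher linear discriminant analysis
#'
#' Finds the subspace that separates labelled classes the most: the
#' dominant eigenvectors of the generalized eigenproblem of the
#' between-class scatter `Sb = sum_i n_i (mu_i - mu)(mu_i - mu)^T` against
#' the pooled within-class scatter `Sw`.  The eigenvectors are not
#' orthogonal; one Gram-Schmidt step orthonormalises the returned
#' projection matrix `W`.  With `c` classes at most `c - 1` generalized
#' eigenvalues are nonzero.
#'
#' To rank raw parameters whose ranges differ by orders of magnitude, the
#' range-adjusted loadings `RW` multiply `W` by the diagonal matrix of
#' per-column ranges (`max - min`, or the design ranges when supplied), so
#' a loading reflects the effect of traversing a parameter's whole range.
#'
#' @param x numeric matrix (samples in rows).
#' @param labels class label per row (>= 2 classes present).
#' @param n_components dimension of the projection (default 2).
#' @param ranges optional data frame as in [parameter_ranges()] giving the
#'   per-column ranges for `RW`; defaults to the observed `max - min`.
#' @param ridge regularisation added to `Sw` (relative to its trace) when
#'   it is numerically singular.
#' @return An `agepp_lda`: `W` (orthonormal `d x n_components`),
#'   `loadings_RW`, `projections` (`n x n_components`), `eigenvalues`,
#'   `class_means` (in the projected space), `classes`.
#' @export
fisher_lda <- function(x, labels, n_components = 2L, ranges = NULL,
                       ridge = 1e-10) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop("need at least two classes", call. = FALSE)
  d <- ncol(x)
  mu <- colMeans(x)
  Sb <- matrix(0, d, d)
  Sw <- matrix(0, d, d)
  for (cl in classes) {
    xi <- x[labels == cl, , drop = FALSE]
    ni <- nrow(xi)
    mi <- colMeans(xi)
    Sb <- Sb + ni * tcrossprod(mi - mu)
    Sw <- Sw + crossprod(sweep(xi, 2, mi))
  }
  # symmetric-definite reduction: Sw = LL', eigen of L^-1 Sb L^-T
  Lc <- tryCatch(chol(Sw), error = function(e) NULL)
  if (is.null(Lc)) {
    warning("within-class scatter is singular; ridge-regularised")
    Sw <- Sw + ridge * sum(diag(Sw)) * diag(d)
    Lc <- chol(Sw)
  }
  Y <- forwardsolve(t(Lc), Sb)        # L^-1 Sb
  M <- forwardsolve(t(Lc), t(Y))      # L^-1 Sb L^-T (symmetric)
  M <- (M + t(M)) / 2
  es <- eigen(M, symmetric = TRUE)
  nc <- min(n_components, d)
  Wraw <- backsolve(Lc, es$vectors[, seq_len(nc), drop = FALSE])
  # one Gram-Schmidt pass
  W <- Wraw
  for (j in seq_len(nc)) {
    v <- W[, j]
    if (j > 1)
      for (i in seq_len(j - 1)) v <- v - sum(W[, i] * v) * W[, i]
    W[, j] <- v / sqrt(sum(v^2))
  }
  rng <- if (is.null(ranges)) {
    apply(x, 2, function(col) diff(range(col)))
  } else {
    setNames(ranges$upper - ranges$lower, ranges$parameter)[colnames(x)]
  }
  proj <- x %*% W
  cm <- t(vapply(classes,
                 function(cl) colMeans(proj[labels == cl, , drop = FALSE]),
                 numeric(nc)))
  rownames(W) <- colnames(x)
  RW <- diag(as.numeric(rng), nrow = d) %*% W
  rownames(RW) <- colnames(x)
  structure(list(W = W,
                 loadings_RW = RW,
                 projections = proj,
                 eigenvalues = es$values[seq_len(nc)],
                 class_means = cm, classes = classes),
            class = "agepp_lda")
}

#' @export
print.agepp_lda <- function(x, ...) {
  cat("Fisher LDA:", length(x$classes), "classes,",
      ncol(x$W), "components; leading eigenvalues:",
      paste(format(x$eigenvalues, digits = 4), collapse = ", "), "\n")
  invisible(x)
}
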