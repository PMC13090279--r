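test_that("Latin hypercube columns are stratified exactly", {
  rng <- data.frame(parameter = "u", lower = 0, upper = 1)
  d <- latin_hypercube(4, rng, seed = 1)
  bins <- sort(floor(d$samples[, 1] * 4))
  expect_equal(bins, 0:3)
  # every column, arbitrary ranges, larger n
  d2 <- latin_hypercube(50, seed = 7)
  rr <- parameter_ranges()
  for (j in seq_len(ncol(d2$samples))) {
    z <- (d2$samples[, j] - rr$lower[j]) / (rr$upper[j] - rr$lower[j])
    expect_equal(sort(floor(z * 50)), 0:49)
  }
})

test_that("designs are reproducible under a fixed seed and span the box", {
  d1 <- latin_hypercube(25, seed = 99)
  d2 <- latin_hypercube(25, seed = 99)
  expect_identical(d1$samples, d2$samples)
  d3 <- latin_hypercube(200, seed = 3)
  expect_true(all(d3$samples[, "tau_star"] >= 0 &
                    d3$samples[, "tau_star"] <= 2))
  expect_true(all(d3$samples[, "g"] >= 0 & d3$samples[, "g"] <= 1))
  expect_true(all(d3$samples[, "nu"] >= 1 & d3$samples[, "nu"] <= 100))
})

test_that("trajectory classification distinguishes the four outcomes", {
  mk <- function(status, x, y1, y2, t_end = 500) {
    structure(list(series = data.frame(
      time = seq(0, t_end, length.out = length(x)),
      x = x, y1 = y1, y2 = y2),
      status = status, t_end = t_end), class = "agepp_trajectory")
  }
  n <- 2001
  expect_equal(as.character(classify_attractor(
    mk("blowup", rep(2, 5), rep(1, 5), rep(1, 5), t_end = 42))), "blowup")
  expect_equal(as.character(classify_attractor(
    mk("completed", rep(40, n), rep(0, n), rep(0, n)))), "predator_free")
  expect_equal(as.character(classify_attractor(
    mk("completed", rep(5, n), rep(1, n), rep(1, n)))),
    "equilibrial_coexistence")
  wob <- 5 + sin(seq(0, 200 * pi, length.out = n))
  expect_equal(as.character(classify_attractor(
    mk("completed", wob, rep(1, n), rep(1, n)))), "periodic_coexistence")
})

test_that("ensemble summaries count every class and sum to one", {
  s <- ensemble_summary(rep("blowup", 10))
  expect_equal(s$fraction[s$class == "blowup"], 1)
  expect_equal(sum(s$fraction), 1)
  labs <- c(rep("predator_free", 3), rep("blowup", 1),
            rep("equilibrial_coexistence", 4),
            rep("periodic_coexistence", 2))
  s2 <- ensemble_summary(labs)
  expect_equal(sum(s2$count), 10)
  expect_equal(sum(s2$fraction), 1)
  expect_equal(s2$count[s2$class == "equilibrial_coexistence"], 4L)
})

test_that("LDA recovers a separation direction planted along an axis", {
  set.seed(31)
  n <- 600
  x <- rbind(matrix(rnorm(n * 5), n, 5),
             matrix(rnorm(n * 5), n, 5) +
               cbind(rep(8, n), 0, 0, 0, 0))
  labels <- rep(c("a", "b"), each = n)
  ld <- fisher_lda(x, labels, n_components = 2)
  w1 <- ld$W[, 1]
  angle <- acos(min(abs(sum(w1 * c(1, 0, 0, 0, 0))), 1)) * 180 / pi
  expect_lt(angle, 5)
  # closed-form two-class direction: Sw^-1 (mu1 - mu2)
  mu_d <- colMeans(x[labels == "a", ]) - colMeans(x[labels == "b", ])
  Sw <- crossprod(scale(x[labels == "a", ], scale = FALSE)) +
    crossprod(scale(x[labels == "b", ], scale = FALSE))
  w_ref <- solve(Sw, mu_d)
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  expect_gt(abs(sum(w1 * w_ref)), cos(0.5 * pi / 180))
})

test_that("LDA projections are orthonormal and rank-limited", {
  set.seed(32)
  n <- 120
  x <- matrix(rnorm(4 * n * 6), 4 * n, 6)
  x[, 1] <- x[, 1] + rep(c(0, 3, 6, 9), each = n)
  x[, 2] <- x[, 2] + rep(c(0, 2, 0, 2), each = n)
  labels <- rep(letters[1:4], each = n)
  ld <- fisher_lda(x, labels, n_components = 6)
  expect_equal(crossprod(ld$W), diag(6), tolerance = 1e-12)
  # four classes: at most three nonzero generalized eigenvalues
  expect_lt(abs(ld$eigenvalues[4]) / ld$eigenvalues[1], 1e-8)
})

test_that("LDA agrees with an established implementation on two classes", {
  skip_if_not_installed("MASS")
  set.seed(33)
  n <- 300
  x <- rbind(matrix(rnorm(n * 3), n, 3),
             sweep(matrix(rnorm(n * 3), n, 3), 2, c(2, 1, 0), `+`))
  labels <- rep(c("a", "b"), each = n)
  ld <- fisher_lda(x, labels)
  m <- MASS::lda(x, grouping = labels)
  w_mass <- m$scaling[, 1] / sqrt(sum(m$scaling[, 1]^2))
  expect_gt(abs(sum(ld$W[, 1] * w_mass)), 0.999)
})

test_that("range-adjusted loadings rescale rows by the parameter ranges", {
  set.seed(34)
  x <- matrix(runif(200 * 3), 200, 3)
  x[, 2] <- x[, 2] * 100   # wide-range column
  colnames(x) <- c("p1", "p2", "p3")
  labels <- rep(c("a", "b"), 100)
  rng <- data.frame(parameter = c("p1", "p2", "p3"),
                    lower = c(0, 0, 0), upper = c(1, 100, 1))
  ld <- fisher_lda(x, labels, ranges = rng)
  expect_equal(unname(ld$loadings_RW[, 1] / ld$W[, 1]),
               c(1, 100, 1))
})
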