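kb <- 0.0083145

make_cv_pair <- function(x, y, dt = 0.4) {
  tm <- seq_along(x) * dt
  list(cv_series("beta_rmsd", "", tm, x), cv_series("distance", "A", tm, y))
}

test_that("a 200 ns series with discard 50 and 10 ns windows yields 15 windows", {
  set.seed(1)
  cv <- make_cv_pair(runif(500), runif(500))   # 0.4 ns sampling -> 200 ns
  stack <- block_histograms(cv[[1]], cv[[2]], discard_ns = 50, window_ns = 10)
  expect_identical(stack$n_windows, 15L)
  expect_true(all(abs(apply(stack$H, 3, sum) - 1) < 1e-12))
})

test_that("a constant CV pair puts all window mass in one bin", {
  cv <- make_cv_pair(rep(1.5, 300), rep(12, 300))
  stack <- block_histograms(cv[[1]], cv[[2]], discard_ns = 20, window_ns = 10)
  expect_true(all(apply(stack$H, 3, max) == 1))
})

test_that("histogram counts match manual binning on a small fixture", {
  set.seed(8)
  x <- runif(20, 0, 1)
  y <- runif(20, 0, 1)
  cv <- make_cv_pair(x, y, dt = 1)
  br <- list(seq(0, 1, by = 0.25), seq(0, 1, by = 0.25))
  stack <- block_histograms(cv[[1]], cv[[2]], discard_ns = 0, window_ns = 10,
                            bins = br)
  # brute force: loop over samples, find bins by comparison
  manual <- array(0, c(4, 4, 2))
  for (k in 1:20) {
    w <- if (k <= 10) 1 else 2
    i <- max(which(x[k] >= br[[1]][-5])) ; j <- max(which(y[k] >= br[[2]][-5]))
    manual[i, j, w] <- manual[i, j, w] + 1
  }
  manual[, , 1] <- manual[, , 1] / 10
  manual[, , 2] <- manual[, , 2] / 10
  expect_equal(stack$H, manual, tolerance = 1e-12)
})

test_that("too few windows is an error", {
  cv <- make_cv_pair(runif(30), runif(30), dt = 1)
  expect_error(block_histograms(cv[[1]], cv[[2]], discard_ns = 0, window_ns = 40),
               "at least 2")
})

test_that("average_histogram is the elementwise window mean", {
  set.seed(3)
  cv <- make_cv_pair(runif(300), runif(300))
  stack <- block_histograms(cv[[1]], cv[[2]], discard_ns = 0, window_ns = 40)
  hbar <- average_histogram(stack)
  # independent mean
  expect_equal(hbar, (stack$H[, , 1] + stack$H[, , 2] + stack$H[, , 3]) / 3,
               tolerance = 1e-14)
  expect_equal(sum(hbar), 1, tolerance = 1e-12)
  # two windows with disjoint single-bin mass average to 0.5 each
  st2 <- stack
  st2$H <- array(0, c(2, 2, 2))
  st2$H[1, 1, 1] <- 1
  st2$H[2, 2, 2] <- 1
  st2$n_windows <- 2L
  h2 <- average_histogram(st2)
  expect_equal(h2[1, 1], 0.5)
  expect_equal(h2[2, 2], 0.5)
})

test_that("Boltzmann inversion hits its analytic anchors", {
  h <- c(0.5, 0.5 / exp(1), 0.25, 0.25 - 0.5 / exp(1))
  f <- boltzmann_invert(h, 298.15)
  expect_identical(f[1], 0)
  expect_equal(f[2], kb * 298.15, tolerance = 1e-9)
  expect_equal(f[3], kb * 298.15 * log(2), tolerance = 1e-9)
  expect_error(boltzmann_invert(c(0, 0)), "all-zero")
  # zero bins are masked, not zero
  f2 <- boltzmann_invert(c(0.7, 0.3, 0))
  expect_true(is.na(f2[3]))
  # scale invariance: common positive factor leaves F unchanged
  expect_equal(boltzmann_invert(h * 3), boltzmann_invert(h), tolerance = 1e-12)
})

test_that("fes_error is zero for identical windows and matches hand propagation", {
  cv <- make_cv_pair(rep(c(0.2, 0.8), 150), rep(c(10, 18), 150))
  stack <- block_histograms(cv[[1]], cv[[2]], discard_ns = 0, window_ns = 40,
                            bins = list(c(0, 0.5, 1), c(8, 14, 20)))
  err <- fes_error(stack, 298.15)
  expect_true(all(err[average_histogram(stack) > 0] < 1e-12))

  # two-window hand case on a single-axis bin
  st2 <- stack
  st2$H <- array(0, c(2, 2, 2))
  st2$H[1, 1, 1] <- 0.6; st2$H[2, 2, 1] <- 0.4
  st2$H[1, 1, 2] <- 0.8; st2$H[2, 2, 2] <- 0.2
  st2$n_windows <- 2L
  err2 <- fes_error(st2, 298.15)
  hbar11 <- 0.7
  sem11 <- sd(c(0.6, 0.8)) / sqrt(2)
  expect_equal(err2[1, 1], kb * 298.15 * sem11 / hbar11, tolerance = 1e-12)
})

test_that("the block error shrinks like 1/sqrt(N) for iid windows", {
  set.seed(14)
  errs <- vapply(c(5, 20, 80), function(nw) {
    n <- nw * 50
    cv <- make_cv_pair(runif(n), runif(n), dt = 1)
    stack <- block_histograms(cv[[1]], cv[[2]], discard_ns = 0, window_ns = 50,
                              bins = list(c(0, 0.5, 1), c(0, 0.5, 1)))
    mean(fes_error(stack), na.rm = TRUE)
  }, numeric(1))
  # quadrupling N should roughly halve the error
  expect_equal(errs[1] / errs[2], 2, tolerance = 0.35)
  expect_equal(errs[2] / errs[3], 2, tolerance = 0.35)
})

test_that("the invert-first error variant is available and labeled", {
  set.seed(2)
  cv <- make_cv_pair(runif(200), runif(200), dt = 1)
  stack <- block_histograms(cv[[1]], cv[[2]], discard_ns = 0, window_ns = 50,
                            bins = list(c(0, 0.5, 1), c(0, 0.5, 1)))
  e <- fes_error(stack, method = "invert_first")
  expect_identical(attr(e, "method"), "invert_first")
  expect_true(all(is.finite(e[average_histogram(stack) > 0])))
})

test_that("1D projection equals inversion of the averaged marginal", {
  set.seed(4)
  cv <- make_cv_pair(rnorm(600, 1, 0.3), rnorm(600, 14, 2))
  stack <- block_histograms(cv[[1]], cv[[2]], discard_ns = 0, window_ns = 40)
  p <- project_1d(stack, 1L, 298.15)
  marg <- rowSums(average_histogram(stack))
  expect_equal(p$prob, marg, tolerance = 1e-12)
  expect_equal(p$F, boltzmann_invert(marg, 298.15), tolerance = 1e-12)
  expect_equal(min(p$F, na.rm = TRUE), 0)
})

test_that("a single-column distribution projects to that column's inversion", {
  x <- rep(0.5, 200)
  set.seed(6)
  y <- rnorm(200, 14, 2)
  cv <- make_cv_pair(x, y, dt = 1)
  stack <- block_histograms(cv[[1]], cv[[2]], discard_ns = 0, window_ns = 50,
                            bins = list(c(0, 1), seq(6, 22, length.out = 9)))
  p2 <- project_1d(stack, 2L, 298.15)
  col <- average_histogram(stack)[1, ]
  expect_equal(p2$F, boltzmann_invert(col, 298.15), tolerance = 1e-12)
})

test_that("a separable distribution projects to the known marginal", {
  # product distribution: x and y independent -> marginal of x known
  set.seed(10)
  n <- 4000
  x <- sample(c(0.25, 0.75), n, replace = TRUE, prob = c(0.3, 0.7))
  y <- runif(n, 10, 20)
  cv <- make_cv_pair(x, y, dt = 0.1)
  stack <- block_histograms(cv[[1]], cv[[2]], discard_ns = 0, window_ns = 40,
                            bins = list(c(0, 0.5, 1), seq(10, 20, 2)))
  p <- project_1d(stack, 1L, 298.15)
  df_got <- p$F[1] - p$F[2]
  df_true <- -kb * 298.15 * log(0.3 / 0.7)
  expect_equal(df_got, df_true, tolerance = 0.15)
})

test_that("a Markov two-state CV series recovers its designed free-energy gap", {
  spec <- two_state_spec()
  cv <- gen_two_state_cv(spec, seed = 42)
  stack <- block_histograms(cv$beta, cv$dist, discard_ns = 50, window_ns = 10)
  expect_identical(stack$n_windows, 15L)
  bd <- basin_delta_f(stack, 2L, c(-Inf, 14.75), c(14.75, Inf))
  true_df <- -kb * 298.15 * log((1 - spec$p_folded) / spec$p_folded)
  expect_lt(abs(bd$delta_f - true_df), bd$band)
})
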