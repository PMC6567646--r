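# independent hand-coded transcription of the PSRF estimator
psrf_oracle <- function(X, correct = TRUE) {
  m <- ncol(X); n <- nrow(X)
  means <- colMeans(X)
  W <- sum(apply(X, 2, function(col) sum((col - mean(col))^2))) /
    (m * (n - 1))
  B <- n * sum((means - mean(means))^2) / (m - 1)
  sig2 <- (n - 1) / n * W + B / n
  V <- if (correct) sig2 + B / (m * n) else sig2
  sqrt(V / W)
}

test_that("gelman_rubin matches the reference formula to 1e-10", {
  set.seed(404)
  X <- cbind(rnorm(200, 0, 1), rnorm(200, 0.3, 1.4), rnorm(200, -0.2, 0.8))
  r <- gelman_rubin(X)
  expect_equal(as.numeric(r), psrf_oracle(X), tolerance = 1e-10)
  expect_equal(attr(r, "R_uncorrected"), psrf_oracle(X, correct = FALSE),
               tolerance = 1e-10)
})

test_that("gelman_rubin regimes: copies, converged, separated", {
  set.seed(8)
  x <- rnorm(100)
  copies <- cbind(x, x, x)
  r <- gelman_rubin(copies)
  expect_equal(as.numeric(r), sqrt(99 / 100), tolerance = 1e-12)
  expect_lt(as.numeric(r), 1)

  two <- cbind(rnorm(1e4), rnorm(1e4))
  expect_lt(as.numeric(gelman_rubin(two)), 1.05)

  apart <- cbind(rnorm(200), rnorm(200, 10, 1))  # 10 within-chain sd apart
  expect_gt(as.numeric(gelman_rubin(apart)), 1.2)

  expect_error(gelman_rubin(matrix(rnorm(10), 10, 1)), "multiple chains")
  expect_error(gelman_rubin(cbind(1, 2)), "at least 2 samples")
})

test_that("gelman_rubin is invariant to a common affine transform", {
  set.seed(12)
  X <- cbind(rnorm(150), rnorm(150, 0.5), rnorm(150, -0.5))
  expect_equal(as.numeric(gelman_rubin(X)),
               as.numeric(gelman_rubin(3.2 * X - 7)), tolerance = 1e-12)
})

test_that("shrink_evolution follows the 50-then-bins-of-10 schedule", {
  set.seed(3)
  X <- cbind(rnorm(100), rnorm(100))
  se <- shrink_evolution(X)
  expect_identical(se$series$checkpoint, seq(50L, 100L, by = 10L))
  expect_error(shrink_evolution(X[1:40, ]), "at least 50")

  x <- rnorm(120)
  copies <- cbind(x, x)
  se2 <- shrink_evolution(copies)
  expect_true(all(se2$series$R < 1))
  expect_identical(se2$converged_at, 50L)

  # chains drifting apart: tail of R values increases
  n <- 150
  div <- cbind(rnorm(n) + 0.05 * seq_len(n), rnorm(n) - 0.05 * seq_len(n))
  se3 <- shrink_evolution(div)
  tail_r <- utils::tail(se3$series$R, 5)
  expect_true(all(diff(tail_r) > 0))
  expect_true(is.na(se3$converged_at))
})

test_that("welch_t_test matches stats::t.test", {
  a <- c(1, 2, 3)
  b <- c(1, 2, 3, 4, 5, 6)
  res <- welch_t_test(a, b)
  ref <- stats::t.test(a, b)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)

  set.seed(15)
  x <- rnorm(40, 1, 2); y <- rnorm(25, 0.4, 0.7)
  res2 <- welch_t_test(x, y)
  ref2 <- stats::t.test(x, y)
  expect_equal(res2$statistic, unname(ref2$statistic), tolerance = 1e-12)
  expect_equal(res2$p_value, ref2$p.value, tolerance = 1e-12)

  ident <- welch_t_test(c(2, 3, 4), c(2, 3, 4))
  expect_identical(ident$statistic, 0)
  expect_identical(ident$p_value, 1)
  # zero variance in both samples
  expect_identical(welch_t_test(c(5, 5), c(5, 5))$p_value, 1)
  expect_identical(welch_t_test(c(5, 5), c(6, 6))$p_value, 0)
  # large effect
  set.seed(16)
  expect_lt(welch_t_test(rnorm(50, 0, 1), rnorm(50, 5, 1))$p_value, 1e-6)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("cv_schedule tiles 60-100% in 5% bins", {
  folds <- cv_schedule(100)
  expect_length(folds, 8)
  expect_identical(vapply(folds, function(f) length(f$train), integer(1)),
                   as.integer(seq(60, 95, by = 5)))
  tests <- lapply(folds, `[[`, "test")
  expect_identical(sort(unlist(tests)), 61:100)         # exact tiling
  expect_identical(anyDuplicated(unlist(tests)), 0L)    # no overlap
  expect_true(all(vapply(folds, function(f)
    max(f$train) < min(f$test), logical(1))))
  # flipped orientation trains from the posterior pole
  rev_folds <- cv_schedule(100, posterior_first = TRUE)
  expect_identical(sort(unlist(lapply(rev_folds, `[[`, "test"))), 1:40)
  expect_error(cv_schedule(10), "at least 20")
})

test_that("noiseless self-evaluation gives the closed-form fold value", {
  ds <- test_dataset()
  m <- build_model("B7r")
  th <- pack_params(ds$theta_star, m)
  res <- sequential_cv(ds$clean, m, ds$grid, ds$inputs, refit = FALSE,
                       theta = th, sigma = ds$sigma, dt = 0.005)
  expect_length(res$fold_log_liks, 8)
  expect_equal(res$fold_log_liks,
               rep(-0.5 * log(2 * pi * ds$sigma^2), 8), tolerance = 1e-9)
  expect_equal(res$mean, -0.5 * log(2 * pi * ds$sigma^2), tolerance = 1e-9)
})

test_that("refitted CV runs end to end and does not flag over-fitting", {
  ds <- test_dataset()
  m <- build_model("B7r")
  res <- sequential_cv(ds$observed, m, ds$grid, ds$inputs, refit = TRUE,
                       n_iter = 120, ladder = make_ladder(5, 5),
                       n_draws = 25, sigma = ds$sigma, dt = 0.02, seed = 4)
  expect_length(res$fold_log_liks, 8)
  expect_true(all(is.finite(res$fold_log_liks)))
  expect_length(res$full_draw_means, 25)
  expect_true(!is.null(res$welch))
  # fitting the generating model to its own data should not over-fit
  expect_gt(res$welch$p_value, 0.05)
})
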