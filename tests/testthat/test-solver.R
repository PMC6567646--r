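test_that("neumann_laplacian has DCT-II eigenstructure", {
  g5 <- spatial_grid(5, L = 5)  # dx = 1
  op <- neumann_laplacian(g5)
  expect_equal(sort(op$values, decreasing = TRUE),
               sort(-2 * (1 - cos((0:4) * pi / 5)), decreasing = TRUE))
  # closed-form pairs actually diagonalize the matrix
  expect_equal(op$matrix %*% op$vectors,
               op$vectors %*% diag(op$values), tolerance = 1e-12)
  # orthonormal basis
  expect_equal(crossprod(op$vectors), diag(5), tolerance = 1e-12)

  g <- spatial_grid(100)
  op <- neumann_laplacian(g)
  expect_equal(max(op$values), 0)           # negative semidefinite
  expect_true(all(op$values <= 0))
  expect_identical(sum(abs(op$values) < 1e-9), 1L)  # single constant mode
  expect_equal(drop(op$matrix %*% rep(3, g$n)), rep(0, g$n),
               tolerance = 1e-12)
  expect_error(neumann_laplacian(spatial_grid(3))$matrix, NA)
  expect_error(spatial_grid(2), "at least 3")
})

make_state <- function(grid, model, u) {
  statics <- matrix(0, grid$n, 4,
                    dimnames = list(NULL, c("Bcd", "Cad", "Tll",
                                            "Hb_maternal")))
  list(u = u, statics = statics, grid = grid, time = 0, clipped = 0L)
}

test_that("pure decay and Neumann mass conservation are exact", {
  g <- test_grid()
  m <- build_model("B7r")
  u0 <- matrix(rep(maternal_inputs(g)[, "Hb_maternal"], 4), g$n, 4,
               dimnames = list(NULL, c("Hb", "Kr", "Kni", "Gt")))
  # alpha = 0, D = 0: exact exponential decay at every point
  th <- plain_params(alpha = 0, beta = 0.7, D = 0)
  st <- rd_step(make_state(g, m, u0), m, th, dt = 0.3)
  expect_equal(st$u, u0 * exp(-0.7 * 0.3), tolerance = 1e-14)
  # alpha = 0, beta = 0: spatial mean conserved to machine precision
  th2 <- plain_params(alpha = 0, beta = 0, D = 0.2)
  st2 <- make_state(g, m, u0)
  for (i in 1:20) st2 <- rd_step(st2, m, th2, dt = 0.05)
  expect_equal(colMeans(st2$u), colMeans(u0), tolerance = 1e-13)
})

test_that("cosine-mode decay matches the analytic heat equation", {
  g <- spatial_grid(100)
  m <- build_model("B7r")
  D <- 0.05; t_end <- 1
  u0 <- matrix(rep(10 + 5 * cos(pi * g$x / g$L), 4), g$n, 4,
               dimnames = list(NULL, c("Hb", "Kr", "Kni", "Gt")))
  th <- plain_params(alpha = 0, beta = 0, D = D)
  inp <- matrix(0, g$n, 4,
                dimnames = list(NULL, c("Bcd", "Cad", "Tll", "Hb_maternal")))
  sol <- rd_solve(inp, m, th, g, T_final = t_end, u0 = u0)
  amp <- (max(sol$profiles[, 1]) - min(sol$profiles[, 1])) / 2
  expect_equal(amp, 5 * exp(-D * (pi / g$L)^2 * t_end), tolerance = 1e-3)
})

test_that("frozen production matches variation-of-constants exactly", {
  # with a static activator only, f is state-independent and the
  # exponential-Euler step is the exact semigroup solution; the oracle uses
  # base eigen() on the operator matrix, independent of the solver's basis
  g <- spatial_grid(24)
  topo <- toy_topology()
  m <- build_model("A6", topo)
  th <- plain_params(alpha = 2, beta = 0.8, D = 0.1, Co = 2, Ns = 3)
  inp <- matrix(0, g$n, 4,
                dimnames = list(NULL, c("Bcd", "Cad", "Tll", "Hb_maternal")))
  inp[, "Bcd"] <- seq(40, 1, length.out = g$n)
  sol <- rd_solve(inp, m, th, g, T_final = 0.7, dt = 0.7 / 3)  # 3 big steps

  op <- neumann_laplacian(g)
  A <- th$D * op$matrix - th$beta * diag(g$n)
  eg <- eigen(A, symmetric = TRUE)
  f <- th$alpha * site_occupancy(inp[, "Bcd"], th$logK[["K"]], th$Co, th$Ns)
  propagate <- function(u, t) {
    co_u <- crossprod(eg$vectors, u)
    co_f <- crossprod(eg$vectors, f)
    lam <- eg$values
    drop(eg$vectors %*% (exp(lam * t) * co_u +
                           co_f * (exp(lam * t) - 1) / lam))
  }
  expect_equal(unname(sol$profiles[, "Hb"]),
               propagate(rep(0, g$n), 0.7), tolerance = 1e-10)
})

test_that("uniform forcing approaches the alpha*c/beta steady state", {
  g <- spatial_grid(24)
  m <- build_model("A6", toy_topology())
  th <- plain_params(alpha = 3, beta = 5, D = 0.1, Co = 1, Ns = 1)
  inp <- matrix(0, g$n, 4,
                dimnames = list(NULL, c("Bcd", "Cad", "Tll", "Hb_maternal")))
  inp[, "Bcd"] <- 25  # uniform static activator -> constant P_A
  cc <- site_occupancy(25, th$logK[["K"]], 1, 1)
  sol <- rd_solve(inp, m, th, g, T_final = 3, dt = 0.01)  # T >> 1/beta
  expect_equal(unname(sol$profiles[, "Hb"]), rep(th$alpha * cc / th$beta,
                                                 g$n), tolerance = 0.01)
  # zero initial condition and zero activators -> identically zero
  inp[, "Bcd"] <- 0
  sol0 <- rd_solve(inp, m, th, g, T_final = 1, dt = 0.01)
  expect_identical(max(abs(sol0$profiles)), 0)
})

test_that("self-convergence in dt is at least first order", {
  g <- test_grid()
  m <- build_model("B7r")
  th <- default_truth(m)
  inp <- test_inputs()
  ref <- rd_solve(inp, m, th, g, dt = 1e-4)$profiles
  e1 <- max(abs(rd_solve(inp, m, th, g, dt = 0.02)$profiles - ref))
  e2 <- max(abs(rd_solve(inp, m, th, g, dt = 0.01)$profiles - ref))
  expect_gt(e1 / e2, 1.7)  # observed order >= ~1
  # halving from the default changes the solution by < 1e-3 relative
  a <- rd_solve(inp, m, th, g, dt = 1e-3)$profiles
  b <- rd_solve(inp, m, th, g, dt = 5e-4)$profiles
  expect_lt(max(abs(a - b)) / max(abs(a)), 1e-3)
})

test_that("compiled and pure-R solvers agree; outputs stay non-negative", {
  g <- test_grid()
  m <- build_model("C8")
  th <- default_truth(m)
  inp <- test_inputs()
  a <- rd_solve(inp, m, th, g, dt = 0.01, use_cpp = TRUE)
  b <- rd_solve(inp, m, th, g, dt = 0.01, use_cpp = FALSE)
  expect_equal(a$profiles, b$profiles, tolerance = 1e-12)
  expect_identical(a$clipped, as.numeric(b$clipped))
  expect_true(all(a$profiles >= 0))
  expect_identical(a$clipped, 0)  # nominal regime: no clipping
})

test_that("instability is reported with the offending parameters", {
  g <- test_grid()
  m <- build_model("B7r")
  inp <- test_inputs()
  # enormous negative decay via decoupled beta forces blow-up
  th <- plain_params(alpha = 5, beta = -80, D = 0.01,
                     logK = c(K = -2, K1 = -2, K3 = -1), Co = 2, Ns = 2)
  expect_error(rd_solve(inp, m, th, g, dt = 0.05, max_retries = 1),
               "unstable.*beta=-80", perl = TRUE)
})
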