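# Shared fixtures, built in code.  Heavier objects are memoized so several
# test files can reuse one forward solve / dataset without recomputing.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small grid used by most sampler-driven tests (masks keep >= 12 points/gene)
test_grid <- function() memo("grid32", spatial_grid(32))

test_inputs <- function() memo("inputs32", maternal_inputs(test_grid()))

# one B7r dataset at the default truth on the small grid
test_dataset <- function() memo("ds_b7r", {
  simulate_dataset("B7r", seed = 101, grid = test_grid(),
                   inputs = test_inputs(), dt = 0.005)
})

# a tiny custom topology: one activator edge and no repressors on Hb,
# two repressors and no activator on Gt (useful for combination-rule tests)
toy_topology <- function() {
  list(
    genes = list(dynamic = c("Hb", "Kr", "Kni", "Gt"),
                 static = c("Bcd", "Cad", "Tll", "Hb_maternal")),
    max_concentration = 50,
    edges = list(
      list(regulator = "Bcd", target = "Hb", mode = "activator",
           class = "Bcd_A"),
      list(regulator = "Kr", target = "Gt", mode = "repressor",
           class = "Kr_R"),
      list(regulator = "Tll", target = "Gt", mode = "repressor",
           class = "Tll_R")),
    extra_edges = NULL,
    affinity_base = list(Hb_R = "K1"),
    affinity_overrides = list(A6 = list(Kr_R = "K1"))
  )
}

# parameters with decay decoupled from synthesis (for analytic solver tests)
plain_params <- function(alpha, beta, D,
                         logK = c(K = -2, K1 = -2, K2 = -2, K3 = -2),
                         Co = 1, Ns = 1) {
  gap_params(logK = logK, Co = Co, Ns = Ns, alpha = alpha, D = D,
             beta = beta)
}

# 1-D conjugate-Gaussian toy: y_i = mu + e, e ~ N(0,1), mu ~ N(0,1).
# Closed-form log evidence; used as the thermodynamic-integration oracle.
gaussian_toy <- function(n = 5, seed = 42) {
  set.seed(seed)
  y <- rnorm(n, 0.5, 1)
  list(
    y = y,
    target = pt_target(
      log_lik = function(th) sum(dnorm(y, th[1], 1, log = TRUE)),
      log_prior = function(th) dnorm(th[1], 0, 1, log = TRUE),
      sample_prior = function() rnorm(1),
      par_names = "mu"),
    log_Z = -(n / 2) * log(2 * pi) - 0.5 * log(n + 1) -
      0.5 * sum(y^2) + sum(y)^2 / (2 * (n + 1)),
    # E_t[log L] in closed form (posterior at temperature t is conjugate)
    E_t = function(t) {
      mbar <- t * sum(y) / (t * n + 1)
      -(n / 2) * log(2 * pi) -
        0.5 * (sum((y - mbar)^2) + n / (t * n + 1))
    })
}
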