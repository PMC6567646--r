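# toy targets ---------------------------------------------------------------

flat_target <- function(d = 1, lower = -1e6, upper = 1e6, ns_index = NA) {
  pt_target(log_lik = function(th) 0,
            log_prior = function(th)
              if (all(th >= lower & th <= upper)) 0 else -Inf,
            sample_prior = function() runif(d, -1, 1),
            ns_index = ns_index)
}

gauss2d_target <- function() {
  pt_target(log_lik = function(th) -0.5 * sum(th^2),
            log_prior = function(th) 0,
            sample_prior = function() rnorm(2))
}

test_that("make_ladder is the exponential schedule", {
  lad <- make_ladder(10, 5)
  expect_length(lad, 10)
  expect_identical(lad[10], 1)
  expect_equal(lad[5], 0.03125)   # (5/10)^5
  expect_equal(lad[1], 1e-5)      # (1/10)^5
  expect_true(all(diff(lad) > 0))
  expect_error(make_ladder(1), "at least 2")
})

test_that("proposal mixes the discrete and continuous branches as specified", {
  set.seed(11)
  n <- 20000
  th <- c(0.3, -0.2, 4)  # Ns in slot 3
  props <- t(vapply(seq_len(n), function(i) propose(th, ns_index = 3)$theta,
                    numeric(3)))
  moved_ns <- props[, 3] != 4
  # branch frequency 1/10
  expect_equal(mean(moved_ns), 0.1, tolerance = 3 * sqrt(0.1 * 0.9 / n) / 0.1)
  # discrete branch: +/-1 with equal probability, continuous part untouched
  expect_setequal(unique(props[moved_ns, 3]), c(3, 5))
  tab <- table(props[moved_ns, 3])
  expect_gt(stats::chisq.test(tab, p = c(0.5, 0.5))$p.value, 1e-4)
  expect_true(all(props[moved_ns, 1] == th[1]))
  # continuous branch: increments have variance 0.1, Ns untouched
  inc <- props[!moved_ns, 1] - th[1]
  expect_equal(var(inc), 0.1, tolerance = 0.035)  # 3 x se of a variance
  expect_equal(mean(inc), 0, tolerance = 3 * sqrt(0.1 / length(inc)))
  # log q-ratio is identically zero; no discrete branch without ns_index
  expect_identical(propose(th)$log_q_ratio, 0)
  set.seed(2)
  cont_only <- t(vapply(seq_len(500),
                        function(i) propose(th)$theta, numeric(3)))
  expect_true(all(cont_only[, 3] != 4 | cont_only[, 1] != th[1]))
})

test_that("mh_step accepts by the Hastings rule", {
  # integer random walk on log target -log(2) * theta via the Ns branch:
  # downhill (-1) proposals always accepted, uphill (+1) accepted w.p. 1/2
  tgt <- pt_target(log_lik = function(th) -log(2) * th[1],
                   log_prior = function(th) 0,
                   sample_prior = function() 0,
                   ns_index = 1)
  set.seed(21)
  n <- 40000
  st <- list(theta = 0, log_lik = tgt$log_lik(0), log_prior = 0)
  steps <- integer(n)
  for (i in seq_len(n)) {
    new <- mh_step(st, tgt, temperature = 1, p_ns = 1)
    steps[i] <- new$theta - st$theta
    st <- new
  }
  # proposals are +1/-1 with prob 1/2; acceptance(+1) = exp(-log 2) = 0.5
  up_rate <- mean(steps == 1)    # = 0.5 * 0.5
  down_rate <- mean(steps == -1) # = 0.5 * 1
  expect_equal(up_rate, 0.25, tolerance = 3 * sqrt(0.25 * 0.75 / n) / 0.25)
  expect_equal(down_rate, 0.5, tolerance = 3 * sqrt(0.25 / n) / 0.5)
  # a proposal outside the prior support is rejected without moving
  boxed <- pt_target(log_lik = function(th) 0,
                     log_prior = function(th) if (th[1] <= 0.5) 0 else -Inf,
                     sample_prior = function() 0, ns_index = 1)
  st <- list(theta = 0, log_lik = 0, log_prior = 0)
  for (i in 1:50) st <- mh_step(st, boxed, p_ns = 1)
  expect_lte(st$theta, 0.5)
})

test_that("plain MH samples a 2-D Gaussian", {
  set.seed(5)
  ens <- mh_run(gauss2d_target(), n_iter = 30000, seed = 31, prop_sd = 1)
  draws <- posterior_samples(ens, burn_in = 0.2)
  expect_equal(unname(colMeans(draws)), c(0, 0), tolerance = 0.12)
  expect_equal(unname(cov(draws)), diag(2), tolerance = 0.15)
})

test_that("exchange acceptance ratio matches the printed formula", {
  # interior pair example: (0.2 - 1.0) * (-8 - (-10)) = -1.6
  expect_equal(exchange_log_accept(0.2, 1.0, -10, -8), -1.6)
  expect_identical(exchange_log_accept(0.3, 0.3, -10, -8), 0)  # t_i = t_j
  expect_identical(exchange_log_accept(0.2, 1.0, -7, -7), 0)   # equal log L
  expect_identical(exchange_log_accept(0.2, 1.0, -Inf, -Inf), -Inf)
})

test_that("exchange sweeps only relabel temperatures", {
  set.seed(9)
  states <- lapply(1:5, function(k)
    list(theta = rnorm(3), log_lik = rnorm(1, -10, 3), log_prior = 0))
  lad <- make_ladder(5, 5)
  before <- sort(vapply(states, function(s) s$theta[1], numeric(1)))
  ex <- exchange_step(states, lad)
  after <- sort(vapply(ex$states, function(s) s$theta[1], numeric(1)))
  expect_identical(after, before)
  expect_identical(ex$proposed, 5L)
  expect_error(exchange_step(states[1], lad[1]), "at least 2")
})

test_that("pt_run is reproducible and reduces to MH for one chain", {
  tgt <- gauss2d_target()
  a <- pt_run(tgt, 200, ladder = make_ladder(4, 5), seed = 77)
  b <- pt_run(tgt, 200, ladder = make_ladder(4, 5), seed = 77)
  expect_identical(a$theta, b$theta)
  expect_identical(a$log_lik, b$log_lik)
  one <- pt_run(tgt, 150, ladder = 1, seed = 5)
  mh <- mh_run(tgt, 150, seed = 5)
  expect_identical(one$theta, mh$theta)
})

test_that("detailed balance on a discrete 3-state target", {
  # states 0, 1, 2 with target weights 1, 2, 4 reached by +/-1 moves
  w <- c(1, 2, 4)
  tgt <- pt_target(log_lik = function(th) log(w[th[1] + 1]),
                   log_prior = function(th)
                     if (th[1] %in% 0:2) 0 else -Inf,
                   sample_prior = function() 1,
                   ns_index = 1)
  ens <- mh_run(tgt, 30000, seed = 13, p_ns = 1)
  counts <- table(factor(posterior_samples(ens, 0.1), levels = 0:2))
  expect_gt(stats::chisq.test(counts, p = w / sum(w))$p.value, 1e-4)
})

test_that("PT crosses the modes of a separated mixture where MH cannot", {
  # 0.7 N(0, 2^2) + 0.3 N(16, 2^2): modes 8 component-sd apart, under a
  # uniform prior on (-10, 26)
  mix_ll <- function(th) {
    log(0.7 * dnorm(th[1], 0, 2) + 0.3 * dnorm(th[1], 16, 2))
  }
  tgt <- pt_target(log_lik = mix_ll,
                   log_prior = function(th)
                     if (th[1] > -10 && th[1] < 26) -log(36) else -Inf,
                   sample_prior = function() runif(1, -10, 26))
  n_iter <- 6000
  lad <- make_ladder(10, 2)  # gentler ladder: high-t chains near the prior
  pt <- pt_run(tgt, n_iter, ladder = lad, seed = 3, prop_sd = 1)
  minor <- mean(posterior_samples(pt, 0.25) > 8)
  expect_gt(minor, 0.2)   # occupancy matches the 0.3 weight within MC error
  expect_lt(minor, 0.45)
  # plain MH with the same total likelihood budget stays in one mode
  mh <- mh_run(tgt, n_iter * length(lad), seed = 3, prop_sd = 1)
  mh_draws <- posterior_samples(mh, 0.25)
  expect_lt(min(mean(mh_draws > 8), mean(mh_draws < 8)), 0.02)
})
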