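#' Generic sampling target
#'
#' Minimal interface consumed by [mh_step()], [pt_run()] and
#' [estimate_evidence()]: a log likelihood, a log prior, a prior sampler, and
#' (optionally) the index of a discrete binding-site-count coordinate that
#' receives the +/-1 random-walk proposal instead of the Gaussian one.
#'
#' @param log_lik Function(theta) -> scalar log likelihood (`-Inf` allowed).
#' @param log_prior Function(theta) -> scalar log prior (`-Inf` outside
#'   support).
#' @param sample_prior Function() -> a draw from the prior (numeric vector).
#' @param par_names Optional parameter names.
#' @param ns_index Index of the integer-valued coordinate, or `NA` if all
#'   coordinates are continuous.
#' @return Object of class `pt_target`.
#' @export
pt_target <- function(log_lik, log_prior, sample_prior, par_names = NULL,
                      ns_index = NA_integer_) {
  structure(list(log_lik = log_lik, log_prior = log_prior,
                 sample_prior = sample_prior, par_names = par_names,
                 ns_index = as.integer(ns_index)),
            class = "pt_target")
}

#' Exponential temperature ladder
#'
#' `t_i = (i / N)^exponent`, i = 1..N: strictly increasing, ending exactly at
#' 1.  The default N = 10, exponent = 5 concentrates temperatures near zero
#' where the tempered path integrand changes fastest.
#'
#' @param N Number of temperatures, >= 2.
#' @param exponent Ladder exponent (default 5).
#' @return Numeric vector of temperatures.
#' @export
make_ladder <- function(N = 10, exponent = 5) {
  if (N < 2) stop("ladder needs at least 2 temperatures")
  (seq_len(N) / N)^exponent
}

#' Mixed discrete/continuous symmetric proposal
#'
#' With probability `p_ns` the integer coordinate (binding-site count) moves
#' by +/-1 (each direction with probability 1/2) and the continuous
#' coordinates stay put; otherwise every continuous coordinate receives an
#' independent Gaussian increment with variance `prop_sd^2` (default 0.1) and
#' the integer coordinate stays put.  Both branches are symmetric, so the
#' log proposal ratio is 0.  Out-of-bounds proposals are left to the prior's
#' `-Inf` (simpler than reflecting, and keeps symmetry at the range edges).
#'
#' @param theta Current parameter vector.
#' @param ns_index Index of the integer coordinate, or `NA` for none (the
#'   discrete branch is then never taken).
#' @param prop_sd Gaussian proposal sd per coordinate (default `sqrt(0.1)`).
#' @param p_ns Probability of the discrete branch (default 1/10).
#' @return List with `theta` (proposal) and `log_q_ratio` (always 0).
#' @export
propose <- function(theta, ns_index = NA_integer_, prop_sd = sqrt(0.1),
                    p_ns = 0.1) {
  new <- theta
  if (!is.na(ns_index) && runif(1) < p_ns) {
    new[ns_index] <- theta[ns_index] + sample(c(-1, 1), 1L)
  } else {
    cont <- if (is.na(ns_index)) seq_along(theta)
            else seq_along(theta)[-ns_index]
    new[cont] <- theta[cont] + rnorm(length(cont), 0, prop_sd)
  }
  list(theta = new, log_q_ratio = 0)
}

#' One Metropolis-Hastings update of a (possibly tempered) chain
#'
#' Proposes with [propose()] and accepts with probability
#' `min(1, exp(t * (logL' - logL) + (logPrior' - logPrior)))` — the Hastings
#' ratio for a symmetric proposal targeting the tempered kernel
#' `L(theta)^t pi(theta)`.  A proposal outside the prior support is rejected
#' without evaluating the likelihood.
#'
#' @param state List with `theta`, `log_lik`, `log_prior` (cached values at
#'   `theta`).
#' @param target A `pt_target`.
#' @param temperature Tempering exponent in `[0, 1]` (default 1).
#' @param prop_sd,p_ns Proposal settings, see [propose()].
#' @return Updated state with an `accepted` flag.
#' @export
mh_step <- function(state, target, temperature = 1, prop_sd = sqrt(0.1),
                    p_ns = 0.1) {
  if (is.na(target$ns_index)) p_ns <- 0
  prop <- propose(state$theta, target$ns_index, prop_sd, p_ns)
  lp_new <- target$log_prior(prop$theta)
  if (!is.finite(lp_new)) {
    state$accepted <- FALSE
    return(state)
  }
  ll_new <- target$log_lik(prop$theta)
  lik_term <- if (temperature == 0) 0 else {
    if (!is.finite(ll_new)) -Inf else temperature * (ll_new - state$log_lik)
  }
  log_ratio <- lik_term + (lp_new - state$log_prior) + prop$log_q_ratio
  if (is.finite(log_ratio) && (log_ratio >= 0 || log(runif(1)) < log_ratio)) {
    state$theta <- prop$theta
    state$log_lik <- ll_new
    state$log_prior <- lp_new
    state$accepted <- TRUE
  } else {
    state$accepted <- FALSE
  }
  state
}

#' Log acceptance ratio of a replica-exchange swap
#'
#' `log a_e = (t_i - t_j) * (logL_j - logL_i)`: the likelihood factor of the
#' Metropolis rule for swapping the states of chains at temperatures t_i and
#' t_j.  The pair-selection Q-ratio is exactly 1 (selection probabilities
#' depend only on the chain indices, unchanged by the swap), so this is the
#' whole log ratio.  Equal temperatures or equal log likelihoods give 0.
#'
#' @param t_i,t_j Temperatures of the two chains.
#' @param ll_i,ll_j Their current log likelihoods.
#' @return Scalar log acceptance ratio.
#' @export
exchange_log_accept <- function(t_i, t_j, ll_i, ll_j) {
  la <- (t_i - t_j) * (ll_j - ll_i)
  if (is.nan(la)) -Inf else la  # both log-liks -Inf: nothing to gain
}

#' One sweep of replica-exchange (swap) moves
#'
#' Proposes `N` swaps per sweep: each time, a chain index i is drawn
#' uniformly, its partner is j = i +/- 1 (probability 1/2 each for interior
#' chains, the single neighbour with probability 1 at the ladder ends), and
#' the pair's states are exchanged with probability `min(1, a_e)` where
#'
#'   log a_e = (t_i - t_j) * (logL_j - logL_i).
#'
#' The Hastings Q-ratio for the pair-selection step is exactly 1: the
#' probability of proposing the swap of a given index pair depends only on
#' the indices, which are unchanged by the swap.
#'
#' @param states List of chain states (each with `theta`, `log_lik`,
#'   `log_prior`).
#' @param ladder Temperatures, one per chain, strictly increasing.
#' @return List with updated `states`, and counts `proposed`, `accepted`.
#' @export
exchange_step <- function(states, ladder) {
  N <- length(states)
  if (N < 2) stop("exchange needs at least 2 chains")
  accepted <- 0L
  for (rep in seq_len(N)) {
    i <- sample.int(N, 1L)
    j <- if (i == 1L) 2L else if (i == N) N - 1L
         else i + sample(c(-1L, 1L), 1L)
    la <- exchange_log_accept(ladder[i], ladder[j],
                              states[[i]]$log_lik, states[[j]]$log_lik)
    if (la >= 0 || log(runif(1)) < la) {
      tmp <- states[[i]]
      states[[i]] <- states[[j]]
      states[[j]] <- tmp
      accepted <- accepted + 1L
    }
  }
  list(states = states, proposed = N, accepted = accepted)
}

#' Parallel-tempered MCMC run
#'
#' Runs one chain per ladder temperature, alternating a local
#' Metropolis-Hastings sweep (one [mh_step()] per chain) with one
#' [exchange_step()] sweep, recording full traces.  Chains are initialized
#' independently from the prior (redrawn until the prior density is finite).
#' With a length-one ladder `c(1)` this degenerates to plain MH.  The
#' posterior is read from the t = 1 chain (the last, untempered one).
#'
#' @param target A `pt_target`.
#' @param n_iter Number of iterations (sweeps), >= 1.
#' @param ladder Temperatures; default `make_ladder(10, 5)`.
#' @param seed Integer seed for full reproducibility (optional).
#' @param init Optional list of start vectors, one per chain.
#' @param prop_sd,p_ns Proposal settings, see [propose()].
#' @return Object of class `pt_ensemble`: `theta` (list of n_iter x d trace
#'   matrices, one per chain), `log_lik` / `log_prior` (n_iter x N matrices),
#'   `ladder`, `acc_mh` (per-chain acceptance rates), `acc_ex` (swap
#'   acceptance rate), `par_names`, `seed`.
#' @export
pt_run <- function(target, n_iter, ladder = make_ladder(10, 5), seed = NULL,
                   init = NULL, prop_sd = sqrt(0.1), p_ns = 0.1) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (is.unsorted(ladder, strictly = TRUE))
    stop("ladder must be strictly increasing")
  if (!is.null(seed)) set.seed(seed)
  N <- length(ladder)
  d <- NULL
  states <- vector("list", N)
  for (k in seq_len(N)) {
    theta <- if (!is.null(init)) init[[k]] else target$sample_prior()
    tries <- 0
    while (!is.finite(target$log_prior(theta))) {
      theta <- target$sample_prior()
      tries <- tries + 1
      if (tries > 1000) stop("cannot initialize chain inside prior support")
    }
    states[[k]] <- list(theta = theta, log_lik = target$log_lik(theta),
                        log_prior = target$log_prior(theta))
    d <- length(theta)
  }
  theta_tr <- lapply(seq_len(N), function(k)
    matrix(NA_real_, n_iter, d,
           dimnames = list(NULL, target$par_names)))
  ll_tr <- matrix(NA_real_, n_iter, N)
  lp_tr <- matrix(NA_real_, n_iter, N)
  acc_mh <- integer(N)
  acc_ex <- 0L
  prop_ex <- 0L
  for (it in seq_len(n_iter)) {
    for (k in seq_len(N)) {
      states[[k]] <- mh_step(states[[k]], target, ladder[k], prop_sd, p_ns)
      acc_mh[k] <- acc_mh[k] + states[[k]]$accepted
    }
    if (N >= 2) {
      ex <- exchange_step(states, ladder)
      states <- ex$states
      acc_ex <- acc_ex + ex$accepted
      prop_ex <- prop_ex + ex$proposed
    }
    for (k in seq_len(N)) {
      theta_tr[[k]][it, ] <- states[[k]]$theta
      ll_tr[it, k] <- states[[k]]$log_lik
      lp_tr[it, k] <- states[[k]]$log_prior
    }
  }
  structure(list(theta = theta_tr, log_lik = ll_tr, log_prior = lp_tr,
                 ladder = ladder, n_iter = n_iter,
                 acc_mh = acc_mh / n_iter,
                 acc_ex = if (prop_ex > 0) acc_ex / prop_ex else NA_real_,
                 par_names = target$par_names, seed = seed),
            class = "pt_ensemble")
}

#' Plain Metropolis-Hastings run (single untempered chain)
#'
#' Convenience wrapper: [pt_run()] with the single-temperature ladder `c(1)`.
#'
#' @inheritParams pt_run
#' @return A `pt_ensemble` with one chain.
#' @export
mh_run <- function(target, n_iter, seed = NULL, init = NULL,
                   prop_sd = sqrt(0.1), p_ns = 0.1) {
  pt_run(target, n_iter, ladder = 1, seed = seed,
         init = if (is.null(init)) NULL else list(init),
         prop_sd = prop_sd, p_ns = p_ns)
}

#' Posterior draws from the untempered chain
#'
#' @param ens A `pt_ensemble`.
#' @param burn_in Fraction of initial iterations to discard (default 0.5), or
#'   an integer count.
#' @return Matrix of post-burn-in draws from the t = 1 chain.
#' @export
posterior_samples <- function(ens, burn_in = 0.5) {
  n <- ens$n_iter
  nb <- if (burn_in < 1) floor(burn_in * n) else as.integer(burn_in)
  if (nb >= n) stop("burn-in leaves no samples")
  ens$theta[[length(ens$ladder)]][(nb + 1):n, , drop = FALSE]
}

#' @export
print.pt_ensemble <- function(x, ...) {
  cat("Parallel-tempered ensemble:", length(x$ladder), "chains x",
      x$n_iter, "iterations\n")
  cat("  ladder:", paste(signif(x$ladder, 3), collapse = " "), "\n")
  cat("  MH acceptance:", paste(round(x$acc_mh, 2), collapse = " "), "\n")
  cat("  swap acceptance:", round(x$acc_ex, 3), "\n")
  invisible(x)
}
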