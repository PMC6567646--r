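#' Mean log likelihood of a tempered chain
#'
#' Monte-Carlo estimate of E_t[log L] from a chain's log-likelihood trace,
#' after discarding burn-in.
#'
#' @param ll_trace Numeric vector of log-likelihood values.
#' @param burn_in Fraction of initial samples to discard (default 0.5), or an
#'   integer count.
#' @return Scalar mean.
#' @export
expected_log_lik <- function(ll_trace, burn_in = 0.5) {
  n <- length(ll_trace)
  nb <- if (burn_in < 1) floor(burn_in * n) else as.integer(burn_in)
  if (nb >= n) stop("burn-in leaves no samples in the trace")
  mean(ll_trace[(nb + 1):n])
}

#' Thermodynamic (path-sampling) integral over the temperature ladder
#'
#' Trapezoid quadrature of E_t[log L] over t in [0, 1]:
#' `log p(Y) = sum 0.5 (t_{i+1} - t_i) (E_{i+1} + E_i)`.  The sampled ladder
#' starts at (1/N)^exponent rather than 0; when `E0` (the prior expectation
#' of the log likelihood, estimable from cheap prior draws) is supplied the
#' node t = 0 is prepended, otherwise quadrature runs over the given nodes
#' only.
#'
#' @param ladder Strictly increasing temperatures within `[0, 1]`.
#' @param E Mean log likelihoods, one per ladder node.
#' @param E0 Optional E_t at t = 0 (prior mean log likelihood).
#' @return Scalar estimate of the log marginal likelihood.
#' @export
thermodynamic_integral <- function(ladder, E, E0 = NULL) {
  if (length(ladder) != length(E))
    stop("ladder and E must have the same length")
  if (is.unsorted(ladder, strictly = TRUE))
    stop("ladder must be strictly increasing")
  if (any(ladder < 0) || any(ladder > 1))
    stop("ladder temperatures must lie in [0, 1]")
  t <- ladder
  if (!is.null(E0)) {
    if (ladder[1] <= 0) stop("E0 given but ladder already starts at 0")
    t <- c(0, ladder)
    E <- c(E0, E)
  }
  sum(0.5 * diff(t) * (E[-1] + E[-length(E)]))
}

#' Estimate the log marginal likelihood by PT-MCMC + thermodynamic integration
#'
#' Runs [pt_run()] `n_runs` times with distinct seeds; each run yields one
#' thermodynamic-integration estimate (per-temperature mean log likelihoods,
#' trapezoid over the ladder, with the t = 0 node estimated from independent
#' prior draws unless `augment_zero = FALSE`).  The reported `log_Z` is the
#' mean over runs and `se` the standard deviation over runs (the run-to-run
#' spread).  Runs that fail are excluded and counted.
#'
#' @param target A `pt_target`.
#' @param n_iter Iterations per run.
#' @param ladder Temperature ladder (default `make_ladder(10, 5)`).
#' @param n_runs Number of independent runs (default 10).
#' @param seed Base seed; run r uses `seed + r - 1`.
#' @param burn_in Burn-in fraction (default 0.5).
#' @param augment_zero Prepend the t = 0 node using prior draws (default
#'   TRUE).
#' @param n_prior Number of prior draws for the t = 0 node.
#' @param prop_sd,p_ns Proposal settings, see [propose()].
#' @return Object of class `evidence_estimate`: `log_Z`, `se`, `per_run`
#'   (per-run estimates), `per_temperature_E` (runs x ladder matrix of
#'   E_t[log L]), `E0` (per-run prior node), `ladder`, `n_runs`, `failed`.
#' @export
estimate_evidence <- function(target, n_iter, ladder = make_ladder(10, 5),
                              n_runs = 10, seed = 1, burn_in = 0.5,
                              augment_zero = TRUE, n_prior = 500,
                              prop_sd = sqrt(0.1), p_ns = 0.1) {
  per_run <- numeric(0)
  E_mat <- matrix(NA_real_, 0, length(ladder))
  E0s <- numeric(0)
  failed <- 0L
  for (r in seq_len(n_runs)) {
    res <- tryCatch({
      ens <- pt_run(target, n_iter, ladder, seed = seed + r - 1,
                    prop_sd = prop_sd, p_ns = p_ns)
      E <- vapply(seq_along(ladder),
                  function(k) expected_log_lik(ens$log_lik[, k], burn_in),
                  numeric(1))
      E0 <- NA_real_
      if (augment_zero) {
        ll0 <- vapply(seq_len(n_prior),
                      function(i) target$log_lik(target$sample_prior()),
                      numeric(1))
        ll0 <- ll0[is.finite(ll0)]
        if (length(ll0) == 0L) stop("no finite prior log-likelihood draws")
        E0 <- mean(ll0)
      }
      list(lz = thermodynamic_integral(ladder, E,
                                       if (augment_zero) E0 else NULL),
           E = E, E0 = E0)
    }, error = function(e) NULL)
    if (is.null(res)) {
      failed <- failed + 1L
      next
    }
    per_run <- c(per_run, res$lz)
    E_mat <- rbind(E_mat, res$E)
    E0s <- c(E0s, res$E0)
  }
  if (length(per_run) == 0L) stop("all evidence runs failed")
  structure(list(log_Z = mean(per_run),
                 se = if (length(per_run) > 1) stats::sd(per_run) else 0,
                 per_run = per_run,
                 per_temperature_E = E_mat,
                 E0 = E0s,
                 ladder = ladder,
                 n_runs = length(per_run),
                 failed = failed),
            class = "evidence_estimate")
}

#' @export
print.evidence_estimate <- function(x, ...) {
  cat("log marginal likelihood:", signif(x$log_Z, 6), "+/-",
      signif(x$se, 3), "(sd over", x$n_runs, "runs")
  if (x$failed > 0) cat(",", x$failed, "failed")
  cat(")\n")
  invisible(x)
}

#' Kass-Raftery evidence category for 2 ln(B)
#'
#' Left-closed bands: `[0, 2)` not worth more than a bare mention, `[2, 6)`
#' substantial, `[6, 10)` strong, `[10, Inf)` very strong.  A negative value
#' is classified by its magnitude's band but counts as evidence for the other
#' model (see [bayes_factor()]).
#'
#' @param two_ln_bf Scalar 2*ln(Bayes factor).
#' @return Category label.
#' @export
classify_bf <- function(two_ln_bf) {
  v <- abs(two_ln_bf)
  if (v < 2) "Not worth more than a bare mention"
  else if (v < 6) "Substantial"
  else if (v < 10) "Strong"
  else "Very strong"
}

#' Bayes factor between two evidence estimates
#'
#' `log BF = log_Z(a) - log_Z(b)`; reported with `2 ln(B)` and its
#' Kass-Raftery category.  A negative `log_BF` is evidence for model `b`.
#'
#' @param a,b `evidence_estimate` objects (or bare log-evidence scalars).
#' @param names Optional pair of model names for the report.
#' @return Object of class `bf_report`: `models`, `log_BF`, `two_ln_BF`,
#'   `category`, `favours`.
#' @export
bayes_factor <- function(a, b, names = c("a", "b")) {
  lza <- if (inherits(a, "evidence_estimate")) a$log_Z else a
  lzb <- if (inherits(b, "evidence_estimate")) b$log_Z else b
  log_bf <- lza - lzb
  structure(list(models = names,
                 log_BF = log_bf,
                 two_ln_BF = 2 * log_bf,
                 category = classify_bf(2 * log_bf),
                 favours = if (log_bf >= 0) names[1] else names[2]),
            class = "bf_report")
}

#' @export
print.bf_report <- function(x, ...) {
  cat("Bayes factor ", x$models[1], " vs ", x$models[2], ": 2 ln(B) = ",
      signif(x$two_ln_BF, 4), " (", x$category, "; favours ", x$favours,
      ")\n", sep = "")
  invisible(x)
}
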