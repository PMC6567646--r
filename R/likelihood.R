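#' Default per-gene trust domains (percent egg length)
#'
#' Intervals over which the observation model is applied: Hb 30-70, Kni
#' 40-90, Kr 20-80, Gt 10-90 percent egg length (boundaries inclusive).
#'
#' @return Named list of `c(lower, upper)` intervals.
#' @export
default_domains <- function() {
  list(Hb = c(30, 70), Kni = c(40, 90), Kr = c(20, 80), Gt = c(10, 90))
}

#' Grid index sets for the per-gene trust domains
#'
#' @param grid A `gap_grid`.
#' @param domains Named list of intervals in percent egg length; both
#'   endpoints inclusive.
#' @return Named list of integer index vectors into the grid.
#' @export
domain_mask <- function(grid, domains = default_domains()) {
  out <- lapply(domains, function(iv) {
    if (iv[1] < 0 || iv[2] > 100 || iv[1] >= iv[2])
      stop("domain interval must lie within [0, 100]")
    idx <- which(grid$positions >= iv[1] & grid$positions <= iv[2])
    if (length(idx) == 0L) stop("empty domain mask on this grid")
    idx
  })
  out
}

#' Gaussian log-likelihood of observed profiles given model parameters
#'
#' Solves the reaction-diffusion system at `params` and sums the iid Gaussian
#' log density of the observed values over the masked grid points of all four
#' gap genes.  Solver instability yields `-Inf` (the state is rejected by the
#' sampler) rather than an error.
#'
#' @param params A `gap_params` (or a packed free-parameter vector, which is
#'   unpacked against `model`).
#' @param obs n x 4 matrix of observed profiles, columns Hb, Kr, Kni, Gt.
#' @param model A `gap_model`.
#' @param grid A `gap_grid`.
#' @param inputs Static input profile matrix (see [rd_solve()]).
#' @param mask Index sets from [domain_mask()].
#' @param sigma Observation noise sd; defaults to the value in `params`.
#' @param dt Solver time step.
#' @param ... Further arguments to [rd_solve()].
#' @return Scalar log likelihood.
#' @export
log_likelihood <- function(params, obs, model, grid, inputs,
                           mask = domain_mask(grid), sigma = NULL,
                           dt = 1e-3, ...) {
  if (!inherits(params, "gap_params"))
    params <- unpack_params(params, model)
  if (is.null(sigma)) sigma <- params$sigma
  sol <- tryCatch(rd_solve(inputs, model, params, grid, dt = dt, ...),
                  error = function(e) NULL)
  if (is.null(sol)) return(-Inf)
  ll <- 0
  for (g in model$genes$dynamic) {
    idx <- mask[[g]]
    ll <- ll + sum(dnorm(obs[idx, g], sol$profiles[idx, g], sigma,
                         log = TRUE))
  }
  ll
}

#' Bounded-uniform log prior over the free parameters
#'
#' Inside all bounds the density is constant: minus the sum of log interval
#' widths of the continuous parameters, minus the log count of admissible
#' binding-site values.  Outside any bound (including a non-integer or
#' out-of-range Ns) the log prior is `-Inf`.
#'
#' @param theta Packed free-parameter vector (or a `gap_params`).
#' @param model A `gap_model`.
#' @param bounds Named list of `c(lower, upper)`; see [default_bounds()].
#' @return Scalar log prior density.
#' @export
log_prior <- function(theta, model, bounds = default_bounds(model)) {
  if (inherits(theta, "gap_params")) theta <- pack_params(theta, model)
  if (length(theta) != length(model$free_params))
    stop("theta has wrong length for model ", model$name)
  names(theta) <- model$free_params
  for (p in model$free_params) {
    b <- bounds[[p]]
    if (theta[[p]] < b[1] || theta[[p]] > b[2]) return(-Inf)
  }
  ns <- theta[["Ns"]]
  if (abs(ns - round(ns)) > 1e-9) return(-Inf)
  cont <- setdiff(model$free_params, "Ns")
  widths <- vapply(cont, function(p) diff(bounds[[p]]), numeric(1))
  n_ns <- floor(bounds$Ns[2]) - ceiling(bounds$Ns[1]) + 1
  -sum(log(widths)) - log(n_ns)
}

#' Tempered log posterior kernel
#'
#' `t * log_likelihood + log_prior` for a tempering exponent t in `[0, 1]`:
#' t = 0 is the prior, t = 1 the full posterior kernel.
#'
#' @inheritParams log_likelihood
#' @param t Temperature in `[0, 1]`.
#' @param bounds Prior bounds.
#' @return Scalar tempered log density.
#' @export
log_posterior_tempered <- function(params, t, obs, model, grid, inputs,
                                   mask = domain_mask(grid),
                                   bounds = default_bounds(model),
                                   sigma = NULL, dt = 1e-3, ...) {
  if (t < 0 || t > 1) stop("temperature t must be in [0, 1]")
  lp <- log_prior(params, model, bounds)
  if (!is.finite(lp)) return(-Inf)
  if (t == 0) return(lp)
  t * log_likelihood(params, obs, model, grid, inputs, mask, sigma, dt,
                     ...) + lp
}

#' Sampling target for a gap-gene posterior
#'
#' Bundles the tempered posterior of one model variant into the generic
#' target interface consumed by [pt_run()]: cached solver setup (eigenbasis,
#' edge encoding, flat mask indices) makes repeated likelihood evaluations
#' cheap.
#'
#' @param obs n x 4 observed profile matrix (columns Hb, Kr, Kni, Gt).
#' @param model A `gap_model`.
#' @param grid A `gap_grid`.
#' @param inputs Static input matrix.
#' @param mask Domain mask (list of index vectors per gene).
#' @param bounds Prior bounds.
#' @param sigma Observation noise sd (fixed, not sampled).
#' @param dt Solver step used inside the likelihood.
#' @param T_final Solver end time.
#' @return A `pt_target` (see [pt_target()]).
#' @export
gap_target <- function(obs, model, grid, inputs, mask = domain_mask(grid),
                       bounds = default_bounds(model), sigma = 5, dt = 0.01,
                       T_final = 1) {
  genes <- model$genes$dynamic
  op <- neumann_laplacian(grid)
  edges <- encode_edges(model, model$genes$static)
  statics <- inputs[, model$genes$static, drop = FALSE]
  u0 <- matrix(0, grid$n, length(genes), dimnames = list(NULL, genes))
  u0[, "Hb"] <- inputs[, "Hb_maternal"]
  n_steps <- as.integer(ceiling(T_final / dt))
  dt_eff <- T_final / n_steps
  flat_idx <- unlist(lapply(seq_along(genes), function(j)
    (j - 1L) * grid$n + mask[[genes[j]]]))
  obs_flat <- obs[, genes, drop = FALSE][flat_idx]
  edge_labels <- model$affinity_map[model$edges$class]
  label_idx <- match(edge_labels, model$free_params)
  ns_index <- match("Ns", model$free_params)
  cont <- setdiff(seq_along(model$free_params), ns_index)
  lo <- vapply(bounds[model$free_params], `[`, numeric(1), 1L)
  hi <- vapply(bounds[model$free_params], `[`, numeric(1), 2L)
  widths <- (hi - lo)[cont]
  n_ns <- floor(hi[ns_index]) - ceiling(lo[ns_index]) + 1
  lp_const <- unname(-sum(log(widths)) - log(n_ns))
  i_alpha <- match("alpha", model$free_params)
  i_D <- match("D", model$free_params)
  i_Co <- match("Co", model$free_params)

  log_prior_fn <- function(theta) {
    if (any(theta < lo) || any(theta > hi)) return(-Inf)
    if (abs(theta[ns_index] - round(theta[ns_index])) > 1e-9) return(-Inf)
    lp_const
  }
  log_lik_fn <- function(theta) {
    alpha <- theta[i_alpha]
    res <- rd_solve_cpp(u0, statics, edges, 10^theta[label_idx],
                        alpha, alpha / model$max_conc, theta[i_D],
                        theta[i_Co], as.integer(round(theta[ns_index])),
                        op$vectors, op$values, dt_eff, n_steps,
                        model$max_conc)
    if (res$unstable) return(-Inf)
    sum(dnorm(obs_flat, res$u[flat_idx], sigma, log = TRUE))
  }
  sample_prior_fn <- function() {
    theta <- lo + runif(length(lo)) * (hi - lo)
    theta[ns_index] <- sample(seq(ceiling(lo[ns_index]),
                                  floor(hi[ns_index])), 1L)
    theta
  }
  pt_target(log_lik_fn, log_prior_fn, sample_prior_fn,
            par_names = model$free_params, ns_index = ns_index)
}
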