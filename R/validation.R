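#' Gelman-Rubin potential scale reduction factor
#'
#' Classic PSRF from m parallel chains of length n: with W the mean
#' within-chain variance and B/n the variance of the chain means,
#' `var+ = (n-1)/n W + B/n` and `R = sqrt(V / W)` where V includes the
#' (m+1)/m sampling-variability correction, `V = var+ + (B/n)/m`, matching
#' the standard diagnostic's definition.  Exact copies of one chain give
#' `B = 0` and `R = sqrt((n-1)/n) < 1`.
#'
#' @param traces n x m matrix (one column per chain) or list of m
#'   equal-length numeric vectors; the pipeline's convention is to monitor
#'   the model log-likelihood trace.
#' @param correct Apply the (m+1)/m correction (default TRUE).
#' @return Scalar R, with attributes `R_uncorrected`, `W` and `B_over_n`.
#' @export
gelman_rubin <- function(traces, correct = TRUE) {
  X <- if (is.list(traces)) do.call(cbind, traces) else as.matrix(traces)
  m <- ncol(X)
  n <- nrow(X)
  if (m < 2) stop("gelman_rubin uses multiple chains (m >= 2)")
  if (n < 2) stop("chains must have at least 2 samples")
  W <- mean(apply(X, 2, var))
  B_over_n <- var(colMeans(X))
  var_plus <- (n - 1) / n * W + B_over_n
  V <- if (correct) var_plus + B_over_n / m else var_plus
  R <- sqrt(V / W)
  R_unc <- sqrt(var_plus / W)
  structure(R, R_uncorrected = R_unc, W = W, B_over_n = B_over_n)
}

#' Evolution of the shrink factor with growing trace length
#'
#' Recomputes [gelman_rubin()] on the first 50 samples, then adding bins of
#' 10 iteratively (checkpoints 50, 60, 70, ...), and flags the first
#' checkpoint from which R stays below the threshold.
#'
#' @param traces n x m matrix or list of chains (n >= 50).
#' @param first First checkpoint (default 50).
#' @param bin Bin width (default 10).
#' @param threshold Convergence threshold on R (default 1.2).
#' @param correct Passed to [gelman_rubin()].
#' @return Object of class `shrink_series`: data.frame `series` (checkpoint,
#'   R, R_uncorrected), `threshold`, `converged_at` (first checkpoint where R
#'   drops and stays below threshold, or NA).
#' @export
shrink_evolution <- function(traces, first = 50, bin = 10, threshold = 1.2,
                             correct = TRUE) {
  X <- if (is.list(traces)) do.call(cbind, traces) else as.matrix(traces)
  n <- nrow(X)
  if (n < first) stop("need at least ", first, " samples per chain")
  checkpoints <- as.integer(seq(first, n, by = bin))
  R <- numeric(length(checkpoints))
  R_unc <- numeric(length(checkpoints))
  for (k in seq_along(checkpoints)) {
    r <- gelman_rubin(X[seq_len(checkpoints[k]), , drop = FALSE], correct)
    R[k] <- as.numeric(r)
    R_unc[k] <- attr(r, "R_uncorrected")
  }
  below <- R < threshold
  converged_at <- NA_integer_
  for (k in seq_along(below)) {
    if (all(below[k:length(below)])) { converged_at <- checkpoints[k]; break }
  }
  structure(list(series = data.frame(checkpoint = checkpoints, R = R,
                                     R_uncorrected = R_unc),
                 threshold = threshold, converged_at = converged_at),
            class = "shrink_series")
}

#' @export
print.shrink_series <- function(x, ...) {
  cat("Gelman-Rubin shrink factor at", nrow(x$series), "checkpoints; ")
  if (is.na(x$converged_at)) cat("never settles below", x$threshold, "\n")
  else cat("below", x$threshold, "from checkpoint", x$converged_at, "\n")
  print(x$series, row.names = FALSE)
  invisible(x)
}

#' Welch two-sample t-test (unequal variances)
#'
#' Textbook Welch statistic `t = (mean(a) - mean(b)) / sqrt(va/na + vb/nb)`
#' with Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#' If both samples have zero variance and equal means, p = 1 by convention.
#'
#' @param a,b Numeric samples of size >= 2 (e.g. predictive log-likelihoods).
#' @return List with `statistic`, `df`, `p_value`, `means`.
#' @export
welch_t_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("both samples need at least 2 observations")
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(statistic = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                df = na + nb - 2,
                p_value = if (eq) 1 else 0,
                means = c(mean(a), mean(b))))
  }
  t_stat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(statistic = t_stat, df = df,
       p_value = 2 * pt(-abs(t_stat), df),
       means = c(mean(a), mean(b)))
}

#' Sequential spatial cross-validation fold schedule
#'
#' Training sets grow from the anterior-most 60% of grid positions per gene
#' in 5% steps; each fold predicts the next 5% bin.  On 100 positions per
#' gene this yields 8 folds whose test bins tile positions 61..100 exactly.
#'
#' @param n Number of grid positions per gene.
#' @param train_start Initial training fraction (default 0.6).
#' @param step Fold increment (default 0.05).
#' @param posterior_first Flip the axis orientation (train from the
#'   posterior pole instead).
#' @return List of folds, each with `train` and `test` index vectors.
#' @export
cv_schedule <- function(n, train_start = 0.6, step = 0.05,
                        posterior_first = FALSE) {
  n <- as.integer(n)
  if (n < 20) stop("need at least 20 positions per gene for 5% bins")
  fracs <- seq(train_start, 1 - step, by = step)
  folds <- lapply(fracs, function(f) {
    m <- as.integer(round(f * n))
    hi <- as.integer(round((f + step) * n))
    if (hi <= m) stop("insufficient points for a ", 100 * step, "% bin")
    list(train = seq_len(m), test = (m + 1L):hi)
  })
  if (posterior_first) {
    folds <- lapply(folds, function(fd)
      list(train = rev(n + 1L - fd$train), test = rev(n + 1L - fd$test)))
  }
  folds
}

#' Sequential spatial cross-validation with over-fitting test
#'
#' The paper's over-fitting check: per fold, the model is fitted (PT-MCMC) to
#' the training positions (intersected with the per-gene trust domains),
#' `n_draws` samples are drawn from the posterior, and the mean predictive
#' log density per point is computed on the next 5% of positions of each gap
#' gene.  The fold means are compared against the per-draw mean predictive
#' log densities of a full-data fit by [welch_t_test()]; a non-significant
#' difference (p > 0.05) indicates no over-fitting.  The prediction accuracy
#' measure is the mean log-likelihood (per point), so with zero residuals it
#' equals `-0.5 log(2 pi sigma^2)` exactly.
#'
#' @param obs n x 4 observed profile matrix.
#' @param model A `gap_model`.
#' @param grid A `gap_grid`.
#' @param inputs Static input matrix.
#' @param refit Fit per fold by PT-MCMC (`TRUE`, the paper's procedure) or
#'   evaluate at fixed parameters `theta` (cheap mechanics/calibration mode).
#' @param theta Packed parameter vector used when `refit = FALSE` (and as
#'   solver truth in the noiseless check).
#' @param n_iter,ladder,burn_in,prop_sd,p_ns PT-MCMC settings per fold.
#' @param n_draws Posterior draws per fold (default 100).
#' @param mask Trust-domain mask used for training likelihoods.
#' @param bounds,sigma,dt Model configuration (see [gap_target()]).
#' @param train_start,step,posterior_first Fold schedule, see
#'   [cv_schedule()].
#' @param seed Seed (fold r uses `seed + r`).
#' @return Object of class `cv_result`: `fold_log_liks`, `mean`,
#'   `full_draw_means`, `welch`, `folds` (the schedule).
#' @export
sequential_cv <- function(obs, model, grid, inputs, refit = TRUE,
                          theta = NULL, n_iter = 200,
                          ladder = make_ladder(10, 5), burn_in = 0.5,
                          n_draws = 100, mask = domain_mask(grid),
                          bounds = default_bounds(model), sigma = 5,
                          dt = 0.01, train_start = 0.6, step = 0.05,
                          posterior_first = FALSE, seed = 1,
                          prop_sd = sqrt(0.1), p_ns = 0.1) {
  genes <- model$genes$dynamic
  folds <- cv_schedule(grid$n, train_start, step, posterior_first)

  draws_for <- function(train_idx, fold_seed) {
    if (!refit) {
      if (is.null(theta)) stop("refit = FALSE requires theta")
      return(matrix(theta, 1, length(theta)))
    }
    fold_mask <- lapply(mask, function(ix) intersect(ix, train_idx))
    if (any(vapply(fold_mask, length, integer(1)) == 0L))
      stop("a training split empties a gene's trust domain")
    tg <- gap_target(obs, model, grid, inputs, mask = fold_mask,
                     bounds = bounds, sigma = sigma, dt = dt)
    ens <- pt_run(tg, n_iter, ladder, seed = fold_seed,
                  prop_sd = prop_sd, p_ns = p_ns)
    post <- posterior_samples(ens, burn_in)
    take <- if (nrow(post) >= n_draws)
      round(seq(1, nrow(post), length.out = n_draws)) else seq_len(nrow(post))
    post[take, , drop = FALSE]
  }

  # mean log density per point of `idx_list` positions, averaged over draws
  predictive_mean <- function(draws, idx_list) {
    per_draw <- apply(draws, 1, function(th) {
      p <- unpack_params(th, model, sigma = sigma)
      sol <- tryCatch(rd_solve(inputs, model, p, grid, dt = dt),
                      error = function(e) NULL)
      if (is.null(sol)) return(NA_real_)
      vals <- unlist(lapply(genes, function(g)
        dnorm(obs[idx_list[[g]], g], sol$profiles[idx_list[[g]], g],
              sigma, log = TRUE)))
      mean(vals)
    })
    per_draw
  }

  fold_vals <- vapply(seq_along(folds), function(r) {
    fd <- folds[[r]]
    draws <- draws_for(fd$train, seed + r)
    test_idx <- setNames(rep(list(fd$test), length(genes)), genes)
    mean(predictive_mean(draws, test_idx), na.rm = TRUE)
  }, numeric(1))

  full_draws <- draws_for(seq_len(grid$n), seed)
  full_vals <- predictive_mean(full_draws, mask)
  full_vals <- full_vals[is.finite(full_vals)]
  welch <- if (length(full_vals) >= 2)
    welch_t_test(fold_vals, full_vals) else NULL

  structure(list(fold_log_liks = fold_vals, mean = mean(fold_vals),
                 full_draw_means = full_vals, welch = welch, folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Sequential spatial CV over", length(x$fold_log_liks), "folds\n")
  cat("  mean predictive log-likelihood:", signif(x$mean, 4), "\n")
  if (!is.null(x$welch))
    cat("  Welch test vs full-data predictive: t =",
        signif(x$welch$statistic, 4), ", p =", signif(x$welch$p_value, 4),
        "\n")
  invisible(x)
}
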