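#' Build and validate a pipeline run configuration
#'
#' Aggregates every tunable of an end-to-end run (models to compare, ladder,
#' iteration counts, prior bounds, noise sd, grid size, seeds, output
#' directory) with the published defaults: N = 10 exponent-5 ladder, 10
#' independent evidence runs, 100 posterior draws, sigma = 5, 100 grid
#' points.
#'
#' @param config A named list of overrides, or a path to a YAML file of the
#'   same structure.
#' @return Object of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    models = c("A6", "B7r"),
    ladder_n = 10, ladder_exponent = 5,
    n_iter = 1000, burn_in = 0.5, n_runs = 10,
    n_draws = 100, sigma = 5, n_points = 100,
    dt = 0.01, sim_dt = 1e-3,
    seed = 1, outdir = NULL,
    data_csv = NULL, simulate = NULL,
    prop_sd = sqrt(0.1), p_ns = 0.1,
    cv_train_start = 0.6, cv_step = 0.05, cv_n_iter = 200,
    topology = NULL)
  cfg <- utils::modifyList(defaults, config)
  bad <- setdiff(cfg$models, gap_model_names())
  if (length(bad) > 0L)
    stop("unknown model name(s) in config: ", paste(bad, collapse = ", "))
  if (!is.null(cfg$data_csv) && !file.exists(cfg$data_csv))
    stop("input data file not found: ", cfg$data_csv)
  structure(cfg, class = "run_config")
}

resolve_data <- function(config) {
  grid <- spatial_grid(config$n_points)
  if (!is.null(config$data_csv)) {
    prof <- read_profiles(config$data_csv)
    if (length(prof$positions) != grid$n)
      grid <- spatial_grid(length(prof$positions))
    genes <- c("Hb", "Kr", "Kni", "Gt")
    statics <- c("Bcd", "Cad", "Tll", "Hb_maternal")
    missing <- setdiff(c(genes, statics), colnames(prof$values))
    if (length(missing) > 0L)
      stop("data file lacks profiles: ", paste(missing, collapse = ", "))
    return(list(grid = grid,
                obs = prof$values[, genes, drop = FALSE],
                inputs = prof$values[, statics, drop = FALSE]))
  }
  sim <- config$simulate %||% list()
  ds <- simulate_dataset(model_name = sim$model %||% "B7r",
                         sigma = sim$sigma %||% config$sigma,
                         seed = sim$seed %||% config$seed,
                         grid = grid, dt = config$sim_dt,
                         topology = config$topology)
  list(grid = grid, obs = ds$observed, inputs = ds$inputs, dataset = ds)
}

ensure_outdir <- function(outdir) {
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  outdir
}

#' Simulate a dataset and write it to disk
#'
#' @param config A `run_config` (or list/path accepted by [run_config()]).
#' @param dry_run Validate the configuration without computing.
#' @return The `gap_dataset`, invisibly (file paths attached when an output
#'   directory is configured).
#' @export
cmd_simulate <- function(config, dry_run = FALSE) {
  config <- if (inherits(config, "run_config")) config else run_config(config)
  if (dry_run) return(invisible(config))
  sim <- config$simulate %||% list()
  ds <- simulate_dataset(model_name = sim$model %||% "B7r",
                         sigma = sim$sigma %||% config$sigma,
                         seed = sim$seed %||% config$seed,
                         grid = spatial_grid(config$n_points),
                         dt = config$sim_dt, topology = config$topology)
  if (!is.null(ensure_outdir(config$outdir))) {
    write_profiles(ds, file.path(config$outdir, "profiles.csv"))
    write_manifest(ds, file.path(config$outdir, "manifest.json"))
  }
  invisible(ds)
}

#' Fit one model by PT-MCMC and write traces
#'
#' One CSV per ladder temperature (iteration, free parameters, log_lik,
#' log_prior) plus a metadata JSON (seed, ladder, acceptance rates).
#'
#' @param config A `run_config`; the first entry of `config$models` is
#'   fitted.
#' @param data Optional list (grid, obs, inputs); resolved from the config
#'   otherwise.
#' @param dry_run Validate only.
#' @return The `pt_ensemble`, invisibly.
#' @export
cmd_fit <- function(config, data = NULL, dry_run = FALSE) {
  config <- if (inherits(config, "run_config")) config else run_config(config)
  if (dry_run) return(invisible(config))
  if (is.null(data)) data <- resolve_data(config)
  model <- build_model(config$models[1], config$topology)
  target <- gap_target(data$obs, model, data$grid, data$inputs,
                       sigma = config$sigma, dt = config$dt)
  ladder <- make_ladder(config$ladder_n, config$ladder_exponent)
  ens <- pt_run(target, config$n_iter, ladder, seed = config$seed,
                prop_sd = config$prop_sd, p_ns = config$p_ns)
  if (!is.null(ensure_outdir(config$outdir))) {
    for (k in seq_along(ladder)) {
      tr <- data.frame(iteration = seq_len(ens$n_iter), ens$theta[[k]],
                       log_lik = ens$log_lik[, k],
                       log_prior = ens$log_prior[, k])
      utils::write.csv(tr, file.path(config$outdir,
                                     sprintf("trace_t%02d.csv", k)),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      list(model = model$name, seed = config$seed, ladder = ladder,
           acc_mh = ens$acc_mh, acc_exchange = ens$acc_ex),
      file.path(config$outdir, "fit_meta.json"),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(ens)
}

#' Estimate marginal likelihoods for the configured models
#'
#' @inheritParams cmd_fit
#' @return Named list of `evidence_estimate` objects, invisibly.
#' @export
cmd_evidence <- function(config, data = NULL, dry_run = FALSE) {
  config <- if (inherits(config, "run_config")) config else run_config(config)
  if (dry_run) return(invisible(config))
  if (is.null(data)) data <- resolve_data(config)
  ladder <- make_ladder(config$ladder_n, config$ladder_exponent)
  out <- list()
  for (m in config$models) {
    model <- build_model(m, config$topology)
    target <- gap_target(data$obs, model, data$grid, data$inputs,
                         sigma = config$sigma, dt = config$dt)
    out[[m]] <- estimate_evidence(target, config$n_iter, ladder,
                                  n_runs = config$n_runs,
                                  seed = config$seed,
                                  burn_in = config$burn_in,
                                  prop_sd = config$prop_sd,
                                  p_ns = config$p_ns)
  }
  if (!is.null(ensure_outdir(config$outdir))) {
    jsonlite::write_json(
      lapply(out, function(e) list(log_Z = e$log_Z, se = e$se,
                                   per_run = e$per_run, ladder = e$ladder,
                                   per_temperature_E =
                                     colMeans(e$per_temperature_E))),
      file.path(config$outdir, "evidence.json"),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}

#' Compare models: evidence, pairwise Bayes factors, convergence flags
#'
#' Runs [estimate_evidence()] per configured model, tabulates all pairwise
#' Bayes factors with Kass-Raftery categories, and attaches a Gelman-Rubin
#' diagnostic computed across the runs' untempered log-likelihood traces;
#' models whose final shrink factor is at or above 1.2 are flagged (never
#' silently dropped).
#'
#' @inheritParams cmd_fit
#' @return Report list: `evidence` (per model), `pairs` (data.frame of
#'   pairwise comparisons), `diagnostics` (per-model R and convergence flag).
#' @export
cmd_compare <- function(config, data = NULL, dry_run = FALSE) {
  config <- if (inherits(config, "run_config")) config else run_config(config)
  if (dry_run) return(invisible(config))
  if (is.null(data)) data <- resolve_data(config)
  ladder <- make_ladder(config$ladder_n, config$ladder_exponent)
  evidence <- list()
  diagnostics <- list()
  for (m in config$models) {
    model <- build_model(m, config$topology)
    target <- gap_target(data$obs, model, data$grid, data$inputs,
                         sigma = config$sigma, dt = config$dt)
    # keep the untempered log-lik trace of each run for the G-R diagnostic
    ll_traces <- vector("list", config$n_runs)
    E_runs <- matrix(NA_real_, config$n_runs, length(ladder))
    per_run <- numeric(config$n_runs)
    for (r in seq_len(config$n_runs)) {
      ens <- pt_run(target, config$n_iter, ladder,
                    seed = config$seed + r - 1,
                    prop_sd = config$prop_sd, p_ns = config$p_ns)
      ll_traces[[r]] <- ens$log_lik[, length(ladder)]
      E_runs[r, ] <- vapply(seq_along(ladder), function(k)
        expected_log_lik(ens$log_lik[, k], config$burn_in), numeric(1))
      ll0 <- vapply(seq_len(500),
                    function(i) target$log_lik(target$sample_prior()),
                    numeric(1))
      per_run[r] <- thermodynamic_integral(ladder, E_runs[r, ],
                                           mean(ll0[is.finite(ll0)]))
    }
    evidence[[m]] <- structure(
      list(log_Z = mean(per_run), se = stats::sd(per_run),
           per_run = per_run, per_temperature_E = E_runs,
           ladder = ladder, n_runs = config$n_runs, failed = 0L),
      class = "evidence_estimate")
    R <- if (config$n_runs >= 2)
      as.numeric(gelman_rubin(do.call(cbind, ll_traces))) else NA_real_
    diagnostics[[m]] <- list(R = R,
                             converged = !is.na(R) && R < 1.2)
  }
  combos <- utils::combn(config$models, 2)
  pairs <- do.call(rbind, lapply(seq_len(ncol(combos)), function(j) {
    a <- combos[1, j]; b <- combos[2, j]
    bf <- bayes_factor(evidence[[a]], evidence[[b]], names = c(a, b))
    data.frame(model_a = a, model_b = b, log_BF = bf$log_BF,
               two_ln_BF = bf$two_ln_BF, category = bf$category,
               favours = bf$favours, stringsAsFactors = FALSE)
  }))
  report <- list(evidence = evidence, pairs = pairs,
                 diagnostics = diagnostics)
  if (!is.null(ensure_outdir(config$outdir))) {
    utils::write.csv(pairs, file.path(config$outdir, "bayes_factors.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(evidence = lapply(evidence, function(e)
             list(log_Z = e$log_Z, se = e$se, per_run = e$per_run)),
           diagnostics = diagnostics),
      file.path(config$outdir, "compare.json"),
      auto_unbox = TRUE, digits = NA)
  }
  report
}

#' Sequential spatial cross-validation of the first configured model
#'
#' @inheritParams cmd_fit
#' @return A `cv_result`, invisibly.
#' @export
cmd_cv <- function(config, data = NULL, dry_run = FALSE) {
  config <- if (inherits(config, "run_config")) config else run_config(config)
  if (dry_run) return(invisible(config))
  if (is.null(data)) data <- resolve_data(config)
  model <- build_model(config$models[1], config$topology)
  res <- sequential_cv(data$obs, model, data$grid, data$inputs,
                       n_iter = config$cv_n_iter,
                       ladder = make_ladder(config$ladder_n,
                                            config$ladder_exponent),
                       burn_in = config$burn_in, n_draws = config$n_draws,
                       sigma = config$sigma, dt = config$dt,
                       train_start = config$cv_train_start,
                       step = config$cv_step, seed = config$seed,
                       prop_sd = config$prop_sd, p_ns = config$p_ns)
  if (!is.null(ensure_outdir(config$outdir))) {
    jsonlite::write_json(
      list(fold_log_liks = res$fold_log_liks, mean = res$mean,
           welch = res$welch[c("statistic", "df", "p_value")]),
      file.path(config$outdir, "cv.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}

#' Convergence diagnostics from multi-run log-likelihood traces
#'
#' Fits the first configured model `n_runs` times from random prior starts
#' and reports the evolution of the Gelman-Rubin shrink factor on the
#' untempered log-likelihood traces (checkpoints 50, 60, 70, ...).
#'
#' @inheritParams cmd_fit
#' @return A `shrink_series`, invisibly.
#' @export
cmd_diagnose <- function(config, data = NULL, dry_run = FALSE) {
  config <- if (inherits(config, "run_config")) config else run_config(config)
  if (dry_run) return(invisible(config))
  if (is.null(data)) data <- resolve_data(config)
  model <- build_model(config$models[1], config$topology)
  target <- gap_target(data$obs, model, data$grid, data$inputs,
                       sigma = config$sigma, dt = config$dt)
  ladder <- make_ladder(config$ladder_n, config$ladder_exponent)
  traces <- vapply(seq_len(max(2, config$n_runs)), function(r) {
    ens <- pt_run(target, config$n_iter, ladder, seed = config$seed + r - 1,
                  prop_sd = config$prop_sd, p_ns = config$p_ns)
    ens$log_lik[, length(ladder)]
  }, numeric(config$n_iter))
  res <- shrink_evolution(traces)
  if (!is.null(ensure_outdir(config$outdir))) {
    utils::write.csv(res$series,
                     file.path(config$outdir, "gelman_rubin.csv"),
                     row.names = FALSE)
  }
  invisible(res)
}
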