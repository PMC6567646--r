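#' Parametric maternal/terminal input profiles
#'
#' FlyEx-like static inputs on the grid, scaled to the fixed maximum
#' concentration 50: an anterior exponential Bicoid gradient
#' `max_conc * exp(-(x - x_1)/lambda)` (maximum exactly 50 at the
#' anterior-most point, strictly decreasing), a posterior Caudal sigmoid, an
#' anterior maternal-Hunchback sigmoid step, and two terminal Tailless
#' domains (anterior and posterior bumps).  Profile shapes are standard
#' gradient forms chosen to reproduce qualitative gap-gene geography; no test
#' depends on matching real FlyEx curves.
#'
#' @param grid A `gap_grid`.
#' @param max_conc Maximum concentration (default 50).
#' @param bcd_lambda Bicoid decay length (fraction of embryo length; default
#'   0.2).  `Inf` gives a constant profile.
#' @param cad_mid,cad_scale Caudal sigmoid midpoint and width (default 0.5,
#'   0.1).
#' @param hb_mid,hb_scale Maternal Hb step midpoint and width (default 0.45,
#'   0.05).
#' @param tll_post_width,tll_ant_height Tailless posterior bump width and
#'   anterior bump height fraction (defaults 0.1 and 0.4).
#' @return n x 4 matrix with columns Bcd, Cad, Tll, Hb_maternal; all values
#'   in `[0, max_conc]`.
#' @export
maternal_inputs <- function(grid, max_conc = 50, bcd_lambda = 0.2,
                            cad_mid = 0.5, cad_scale = 0.1, hb_mid = 0.45,
                            hb_scale = 0.05, tll_post_width = 0.1,
                            tll_ant_height = 0.4) {
  x <- grid$x / grid$L
  bcd <- max_conc * exp(-(x - x[1]) / bcd_lambda)
  cad <- max_conc / (1 + exp(-(x - cad_mid) / cad_scale))
  hbm <- max_conc / (1 + exp((x - hb_mid) / hb_scale))
  tll <- max_conc * (tll_ant_height * exp(-(x / 0.05)^2) +
                       exp(-((1 - x) / tll_post_width)^2))
  out <- cbind(Bcd = bcd, Cad = cad, Tll = pmin(tll, max_conc),
               Hb_maternal = hbm)
  if (max(out) > max_conc + 1e-9)
    stop("input profile exceeds the maximum concentration ", max_conc)
  out
}

#' Default ground-truth parameters for synthetic experiments
#'
#' Mid-prior values for every free parameter, with two exceptions.  The
#' node-specific Bicoid affinity K3 (when the model has one) sits one log10
#' unit above the global K — the contrast the model-ranking experiments
#' exercise.  And the diffusion constant is 0.05 rather than its prior
#' midpoint 0.5: a diffusion length sqrt(D T) of 70% embryo length erases
#' all spatial pattern, defeating the generator's purpose of emulating
#' gap-gene geography, whereas 0.05 (about 22% EL) preserves the anterior
#' Hb domain and the central/posterior zygotic domains.  Ns is the rounded
#' midpoint of its integer range.
#'
#' @param model A `gap_model`.
#' @param bounds Prior bounds (see [default_bounds()]).
#' @param sigma Observation noise sd attached to the parameter set.
#' @return A `gap_params` within the bounds.
#' @export
default_truth <- function(model, bounds = default_bounds(model), sigma = 5) {
  mid <- vapply(model$free_params,
                function(p) mean(bounds[[p]]), numeric(1))
  names(mid) <- model$free_params
  if ("K3" %in% model$free_params) mid[["K3"]] <- mid[["K"]] + 1
  mid[["Ns"]] <- round(mid[["Ns"]])
  mid[["D"]] <- 0.05
  unpack_params(mid, model, sigma = sigma)
}

#' Simulate a FlyEx-like synthetic dataset
#'
#' Runs the forward model at the ground-truth parameters and adds iid
#' Gaussian observation noise: `Y = U(x, T) + eps`, `eps ~ N(0, sigma^2 I)`.
#' Fully reproducible from the seed.
#'
#' @param model_name One of [gap_model_names()] (default "B7r").
#' @param theta_star Ground-truth `gap_params`; default [default_truth()].
#'   Must lie within the prior bounds.
#' @param sigma Noise sd (default 5, 10% of the maximum concentration).
#' @param seed Integer seed.
#' @param grid A `gap_grid` (default 100 points).
#' @param inputs Static inputs; default [maternal_inputs()].
#' @param dt Solver step (default 1e-3).
#' @param topology Optional topology override for [build_model()].
#' @return Object of class `gap_dataset`: `grid`, `inputs`, `clean` (solver
#'   output), `observed` (clean + noise), `theta_star`, `sigma`, `seed`,
#'   `model_name`.
#' @export
simulate_dataset <- function(model_name = "B7r", theta_star = NULL,
                             sigma = 5, seed = 1, grid = spatial_grid(100),
                             inputs = NULL, dt = 1e-3, topology = NULL) {
  model <- build_model(model_name, topology)
  if (is.null(theta_star)) theta_star <- default_truth(model, sigma = sigma)
  bounds <- default_bounds(model)
  packed <- pack_params(theta_star, model)
  for (p in model$free_params) {
    b <- bounds[[p]]
    if (packed[[p]] < b[1] || packed[[p]] > b[2])
      stop("theta_star parameter ", p, " = ", packed[[p]],
           " is outside its prior bounds [", b[1], ", ", b[2], "]")
  }
  if (is.null(inputs)) inputs <- maternal_inputs(grid, model$max_conc)
  sol <- rd_solve(inputs, model, theta_star, grid, dt = dt)
  set.seed(seed)
  noise <- matrix(rnorm(length(sol$profiles), 0, sigma),
                  nrow(sol$profiles), ncol(sol$profiles))
  observed <- sol$profiles + noise
  dimnames(observed) <- dimnames(sol$profiles)
  structure(list(grid = grid, inputs = inputs, clean = sol$profiles,
                 observed = observed, theta_star = theta_star,
                 sigma = sigma, seed = seed, model_name = model_name),
            class = "gap_dataset")
}

#' @export
print.gap_dataset <- function(x, ...) {
  cat("Synthetic gap-gene dataset (model ", x$model_name, ", n = ",
      x$grid$n, " positions, sigma = ", x$sigma, ", seed = ", x$seed,
      ")\n", sep = "")
  invisible(x)
}

gene_universe <- function() {
  c("Bcd", "Cad", "Tll", "Hb_maternal", "Hb", "Kr", "Kni", "Gt")
}

#' Write expression profiles to CSV
#'
#' Long format with header `gene,position_percent_el,value`, full float
#' precision (round-trips exactly through [read_profiles()]).  A
#' `gap_dataset` writes its observed gap-gene profiles together with the
#' static inputs.
#'
#' @param x A `gap_dataset`, or a list with `positions` (percent egg length)
#'   and `values` (n x genes matrix with column names).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(x, path) {
  if (inherits(x, "gap_dataset")) {
    x <- list(positions = x$grid$positions,
              values = cbind(x$observed, x$inputs))
  }
  genes <- colnames(x$values)
  if (is.null(genes)) stop("profile matrix must have gene column names")
  df <- data.frame(
    gene = rep(genes, each = length(x$positions)),
    position_percent_el = sprintf("%.17g", rep(x$positions, length(genes))),
    value = sprintf("%.17g", as.vector(x$values)))
  writeLines(c("gene,position_percent_el,value",
               paste(df$gene, df$position_percent_el, df$value, sep = ",")),
             path)
  invisible(path)
}

#' Read expression profiles from CSV
#'
#' Expects the `gene,position_percent_el,value` layout written by
#' [write_profiles()]: per gene, strictly increasing positions within
#' `[0, 100]`, all genes on one shared grid.  Unknown gene names and
#' malformed rows are rejected with informative errors.
#'
#' @param path CSV path.
#' @param expected_genes Admissible gene names (default: the four gap genes
#'   plus the static inputs).
#' @return List with `positions` and `values` (n x genes matrix).
#' @export
read_profiles <- function(path, expected_genes = gene_universe()) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "position_percent_el", "value")
  if (!identical(names(df), need))
    stop("expected CSV header ", paste(need, collapse = ","))
  bad <- which(!is.finite(df$position_percent_el) | !is.finite(df$value))
  if (length(bad) > 0L)
    stop("malformed profile row(s): ", paste(utils::head(bad, 5) + 1L,
                                             collapse = ", "))
  unknown <- setdiff(unique(df$gene), expected_genes)
  if (length(unknown) > 0L)
    stop("unexpected gene name(s): ", paste(unknown, collapse = ", "))
  if (any(df$position_percent_el < 0 | df$position_percent_el > 100)) {
    bad <- which(df$position_percent_el < 0 |
                   df$position_percent_el > 100)[1]
    stop("position out of [0, 100] at data row ", bad)
  }
  split_df <- split(df, df$gene)
  positions <- NULL
  for (g in names(split_df)) {
    p <- split_df[[g]]$position_percent_el
    if (is.unsorted(p, strictly = TRUE))
      stop("non-monotone positions for gene ", g)
    if (is.null(positions)) positions <- p
    else if (length(p) != length(positions) ||
             max(abs(p - positions)) > 1e-9)
      stop("gene ", g, " is not on the shared position grid")
  }
  genes <- unique(df$gene)  # preserve file order
  values <- vapply(genes, function(g) split_df[[g]]$value,
                   numeric(length(positions)))
  list(positions = positions, values = values)
}

#' Write a dataset manifest (JSON)
#'
#' Records everything needed to regenerate a synthetic dataset: model name,
#' seed, sigma, and the ground-truth parameter vector.
#'
#' @param ds A `gap_dataset`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(ds, path) {
  model <- build_model(ds$model_name)
  jsonlite::write_json(
    list(model = ds$model_name, seed = ds$seed, sigma = ds$sigma,
         n_points = ds$grid$n,
         theta_star = as.list(pack_params(ds$theta_star, model))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
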