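#' Names of the six competing model variants
#'
#' @return Character vector `c("A6","B7","B7r","C8","D7","D8")`.
#' @export
gap_model_names <- function() c("A6", "B7", "B7r", "C8", "D7", "D8")

#' Path to the packaged default network topology
#'
#' The topology (which regulator acts on which target, with what mode and
#' affinity class) is shipped as a YAML data file so it can be corrected or
#' extended without code changes.
#'
#' @return Path to the installed `gap_topology.yaml`.
#' @export
default_topology_file <- function() {
  system.file("extdata", "gap_topology.yaml", package = "gapbayes",
              mustWork = TRUE)
}

#' Read a network topology file
#'
#' @param path YAML file in the format of [default_topology_file()].
#' @return A topology list (genes, edges, affinity maps).
#' @export
read_topology <- function(path = default_topology_file()) {
  topo <- yaml::read_yaml(path)
  needed <- c("genes", "edges", "affinity_base", "affinity_overrides")
  missing <- setdiff(needed, names(topo))
  if (length(missing) > 0L)
    stop("topology file lacks required fields: ",
         paste(missing, collapse = ", "))
  topo
}

edges_to_frame <- function(edge_list) {
  data.frame(
    regulator = vapply(edge_list, function(e) e$regulator, character(1)),
    target    = vapply(edge_list, function(e) e$target, character(1)),
    mode      = vapply(edge_list, function(e) e$mode, character(1)),
    class     = vapply(edge_list, function(e) e$class, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Build one of the six gap-gene model specifications
#'
#' Constructs the model variant's regulatory edge set and affinity map.  The
#' variants share a base network; B7 adds an edge-specific affinity K2 for
#' Kruppel-as-repressor, B7r instead gives Bicoid-as-activator its own
#' affinity K3, C8 has both, and D7/D8 add a Bcd -> Kr activation edge to
#' B7/C8 respectively.  Free-parameter counts are 6, 7, 7, 8, 7, 8.
#'
#' Shared (global) parameters across all four gap genes: affinity K,
#' cooperativity Co, binding-site count Ns, synthesis/decay rate alpha, and
#' diffusion D.  The maximum concentration is fixed at 50; the decay rate is
#' tied to synthesis as beta = alpha / max_conc so that the saturated steady
#' state equals the maximum concentration (exactly one open synthesis/decay
#' parameter).
#'
#' @param name One of `gap_model_names()`.
#' @param topology A topology list from [read_topology()], a path to a YAML
#'   topology file, or `NULL` for the packaged default.
#' @return An object of class `gap_model` with fields `name`, `edges`
#'   (data.frame: regulator, target, mode, class), `affinity_map` (class ->
#'   label), `free_params`, `genes`, `max_conc`, `has_bcd_kr`.
#' @examples
#' m <- build_model("A6")
#' m$free_params  # K, K1, Co, Ns, alpha, D
#' @export
build_model <- function(name, topology = NULL) {
  if (!is.character(name) || length(name) != 1L ||
      !(name %in% gap_model_names()))
    stop("invalid model name '", paste(name, collapse = ","),
         "': must be one of ", paste(gap_model_names(), collapse = ", "))
  topo <- if (is.null(topology)) read_topology()
          else if (is.character(topology)) read_topology(topology)
          else topology

  edges <- edges_to_frame(topo$edges)
  extra <- topo$extra_edges[[name]]
  if (!is.null(extra)) edges <- rbind(edges, edges_to_frame(extra))

  classes <- unique(edges$class)
  amap <- setNames(rep("K", length(classes)), classes)
  for (cl in names(topo$affinity_base))
    if (cl %in% classes) amap[[cl]] <- topo$affinity_base[[cl]]
  ovr <- topo$affinity_overrides[[name]]
  for (cl in names(ovr))
    if (cl %in% classes) amap[[cl]] <- ovr[[cl]]

  labels <- intersect(c("K", "K1", "K2", "K3"), unique(unname(amap)))
  free <- c(labels, "Co", "Ns", "alpha", "D")

  structure(
    list(name = name,
         edges = edges,
         affinity_map = amap,
         free_params = free,
         genes = topo$genes,
         max_conc = topo$max_concentration %||% 50,
         has_bcd_kr = any(edges$regulator == "Bcd" & edges$target == "Kr")),
    class = "gap_model")
}

#' @export
print.gap_model <- function(x, ...) {
  cat("Gap gene model", x$name, "--", nrow(x$edges), "edges,",
      length(x$free_params), "free parameters:\n  ",
      paste(x$free_params, collapse = ", "), "\n")
  invisible(x)
}

#' Construct a parameter set for the gap-gene model
#'
#' @param logK Named numeric vector of log10 binding affinities; names are a
#'   subset of `c("K","K1","K2","K3")`.
#' @param Co Cooperativity rate, >= 1 (dimensionless).
#' @param Ns Number of binding sites, positive integer (shared by all genes).
#' @param alpha Production rate (concentration per unit time).
#' @param D Diffusion constant (nondimensional length^2 per unit time).
#' @param beta Linear decay rate (1/time); defaults to `alpha / max_conc`
#'   so that the saturated steady state alpha/beta equals `max_conc`.
#' @param sigma Observation noise standard deviation (concentration units);
#'   fixed at 5 (10% of the maximum concentration) by default, not sampled.
#' @param max_conc Fixed maximum concentration (50).
#' @return Object of class `gap_params`.
#' @export
gap_params <- function(logK, Co, Ns, alpha, D, beta = NULL, sigma = 5,
                       max_conc = 50) {
  if (is.null(names(logK)) || !all(names(logK) %in% c("K", "K1", "K2", "K3")))
    stop("logK must be a named vector with names among K, K1, K2, K3")
  if (Co < 1) stop("cooperativity Co must be >= 1")
  if (Ns < 1 || Ns != round(Ns)) stop("Ns must be a positive integer")
  structure(
    list(logK = logK, Co = Co, Ns = as.integer(round(Ns)),
         alpha = alpha, D = D,
         beta = beta %||% (alpha / max_conc),
         sigma = sigma, max_conc = max_conc),
    class = "gap_params")
}

#' Default prior bounds for a model's free parameters
#'
#' Bounded uniform priors: log10 affinities on (-4, 0), cooperativity on
#' (1, 10), binding sites uniform on the integers 1..10, synthesis rate on
#' (0.01, 10), diffusion on (0, 1) (nondimensional units).  Bounds are
#' configuration, not code: pass a modified list anywhere a `bounds`
#' argument is accepted.
#'
#' @param model A `gap_model`.
#' @return Named list of `c(lower, upper)` pairs, one per free parameter.
#' @export
default_bounds <- function(model) {
  bound_of <- function(p) {
    if (p %in% c("K", "K1", "K2", "K3")) return(c(-4, 0))
    switch(p,
      Co = c(1, 10),
      Ns = c(1, 10),
      alpha = c(0.01, 10),
      beta = c(0.01, 10),
      D = c(0, 1),
      stop("no default bound for parameter ", p))
  }
  setNames(lapply(model$free_params, bound_of), model$free_params)
}

#' Resolve the affinity used by a regulatory edge
#'
#' Looks up the edge's affinity class in the model's affinity map and returns
#' the corresponding log10 affinity from the parameter set (e.g. the
#' Kruppel-as-repressor edge resolves to K2 under B7 but to K1 under A6).
#'
#' @param model A `gap_model`.
#' @param params A `gap_params`.
#' @param regulator,target Gene names identifying the edge.
#' @return The log10 affinity value.
#' @export
resolve_affinity <- function(model, params, regulator, target) {
  hit <- model$edges$regulator == regulator & model$edges$target == target
  if (!any(hit))
    stop("edge ", regulator, " -> ", target, " is not part of model ",
         model$name)
  label <- model$affinity_map[[model$edges$class[which(hit)[1L]]]]
  if (!(label %in% names(params$logK)))
    stop("parameter set lacks affinity ", label, " required by model ",
         model$name)
  unname(params$logK[[label]])
}

#' Pack a parameter set into the model's free-parameter vector
#'
#' @param params A `gap_params`.
#' @param model A `gap_model`.
#' @return Named numeric vector ordered as `model$free_params` (Ns is stored
#'   as a numeric but is integer-valued).
#' @export
pack_params <- function(params, model) {
  vapply(model$free_params, function(p) {
    if (p %in% c("K", "K1", "K2", "K3")) {
      if (!(p %in% names(params$logK)))
        stop("parameter set lacks affinity ", p)
      unname(params$logK[[p]])
    } else {
      as.numeric(params[[p]])
    }
  }, numeric(1))
}

#' Unpack a free-parameter vector into a parameter set
#'
#' Inverse of [pack_params()]: fixed quantities (max concentration, noise
#' sigma, the beta = alpha/max_conc tie) are restored from configuration.
#'
#' @param theta Numeric vector of length `length(model$free_params)`.
#' @param model A `gap_model`.
#' @param sigma Observation noise sd (fixed configuration value).
#' @param max_conc Maximum concentration.
#' @param beta Decay rate override; `NULL` ties beta = alpha/max_conc.
#' @return A `gap_params`.
#' @export
unpack_params <- function(theta, model, sigma = 5, max_conc = model$max_conc,
                          beta = NULL) {
  if (length(theta) != length(model$free_params))
    stop("theta has length ", length(theta), " but model ", model$name,
         " has ", length(model$free_params), " free parameters")
  names(theta) <- model$free_params
  labels <- intersect(c("K", "K1", "K2", "K3"), model$free_params)
  gap_params(logK = theta[labels],
             Co = unname(theta[["Co"]]),
             Ns = round(unname(theta[["Ns"]])),
             alpha = unname(theta[["alpha"]]),
             D = unname(theta[["D"]]),
             beta = beta, sigma = sigma, max_conc = max_conc)
}
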