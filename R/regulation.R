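#' Fractional occupancy of a regulatory target's binding sites
#'
#' Partition-function occupancy for `Ns` identical binding sites with
#' homotypic cooperativity: with v = u * 10^logKa, the statistical weight of
#' the configuration with j sites bound is choose(Ns, j) * Co^(j-1) * v^j, so
#'
#'   S = sum_{j=1..Ns} choose(Ns, j) Co^(j-1) v^j,   occupancy = S / (1 + S).
#'
#' The occupancy is 0 at u = 0, tends to 1 as u grows, and is monotone
#' non-decreasing in u, Co and Ns.  For Co = 1 it reduces to the binomial
#' closed form 1 - (1 + v)^(-Ns).
#'
#' @param u Regulator concentration(s), >= 0 (vectorized).
#' @param logKa log10 binding affinity.
#' @param Co Cooperativity rate, >= 1.
#' @param Ns Number of binding sites, integer >= 1.
#' @return Occupancy fraction(s) in `[0, 1]`.
#' @export
site_occupancy <- function(u, logKa, Co, Ns) {
  if (any(u < 0)) stop("regulator concentration u must be non-negative")
  if (Ns < 1 || Ns != round(Ns)) stop("Ns must be an integer >= 1")
  if (Co < 1) stop("cooperativity Co must be >= 1")
  v <- u * 10^logKa
  j <- seq_len(Ns)
  coef <- choose(Ns, j) * Co^(j - 1)
  S <- drop(outer(v, j, `^`) %*% coef)
  S / (1 + S)
}

# Fully-bound fraction under the same partition function: the statistical
# weight Co^(Ns-1) v^Ns of the all-sites-bound configuration over 1 + S.
# Used as the repressive arm of dual regulation (high regulator -> repression).
site_occupancy_full <- function(u, logKa, Co, Ns) {
  if (any(u < 0)) stop("regulator concentration u must be non-negative")
  if (Ns < 1 || Ns != round(Ns)) stop("Ns must be an integer >= 1")
  v <- u * 10^logKa
  j <- seq_len(Ns)
  coef <- choose(Ns, j) * Co^(j - 1)
  S <- drop(outer(v, j, `^`) %*% coef)
  (Co^(Ns - 1) * v^Ns) / (1 + S)
}

#' Combined activation and repression inputs for a gap gene
#'
#' Combines the occupancies of all edges targeting `target` into the
#' activation probability P_A and repression probability P_B by the noisy-OR
#' rule 1 - prod(1 - phi) (independent regulators).  A dual edge (Hunchback
#' on Kruppel) contributes its ordinary occupancy to P_A and its fully-bound
#' fraction to P_B, so low regulator activates while high regulator
#' represses.
#'
#' @param state Named list (or named matrix columns) of regulator
#'   concentration vectors, covering every regulator with an edge into
#'   `target` (dynamic gap genes and static maternal/terminal inputs alike).
#' @param model A `gap_model`.
#' @param params A `gap_params`.
#' @param target A gap gene name.
#' @return List with vectors `P_A` and `P_B`, both in `[0, 1]`.
#' @export
regulatory_input <- function(state, model, params, target) {
  if (is.matrix(state)) state <- as.list(as.data.frame(state))
  ed <- model$edges[model$edges$target == target, , drop = FALSE]
  one_minus_a <- 1
  one_minus_b <- 1
  for (k in seq_len(nrow(ed))) {
    reg <- ed$regulator[k]
    u <- state[[reg]]
    if (is.null(u))
      stop("state does not provide regulator ", reg, " needed for ", target)
    logKa <- resolve_affinity(model, params, reg, ed$target[k])
    mode <- ed$mode[k]
    if (mode == "activator") {
      one_minus_a <- one_minus_a *
        (1 - site_occupancy(u, logKa, params$Co, params$Ns))
    } else if (mode == "repressor") {
      one_minus_b <- one_minus_b *
        (1 - site_occupancy(u, logKa, params$Co, params$Ns))
    } else if (mode == "dual") {
      one_minus_a <- one_minus_a *
        (1 - site_occupancy(u, logKa, params$Co, params$Ns))
      one_minus_b <- one_minus_b *
        (1 - site_occupancy_full(u, logKa, params$Co, params$Ns))
    } else {
      stop("unknown edge mode '", mode, "'")
    }
  }
  list(P_A = 1 - one_minus_a, P_B = 1 - one_minus_b)
}

#' Production rate of a gap gene
#'
#' The synthesis term of the reaction-diffusion equation:
#' `alpha * P_A * (1 - P_B)`.  Zero whenever activation is absent (P_A = 0)
#' or repression saturates (P_B = 1); never exceeds alpha.
#'
#' @inheritParams regulatory_input
#' @return Production rate vector (concentration per unit time).
#' @export
production_rate <- function(state, model, params, target) {
  p <- regulatory_input(state, model, params, target)
  params$alpha * p$P_A * (1 - p$P_B)
}
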