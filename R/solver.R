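#' Uniform cell-centred spatial grid along the A-P axis
#'
#' `n_points` cells on `[0, L]` with centres at `(i - 1/2) * L / n_points`.
#' Cell centres (rather than vertices) are used because the zero-flux
#' second-difference operator is then diagonalized exactly by the DCT-II
#' cosine modes with second-order accurate eigenvalues.  Positions are also
#' reported in percent egg length for masking and I/O.
#'
#' @param n_points Number of grid points (default 100, about 5 micrometres
#'   apart on a real embryo).
#' @param L Embryo length; nondimensionalized to 1 by default.
#' @return Object of class `gap_grid` with fields `n`, `L`, `dx`, `x`,
#'   `positions` (percent egg length).
#' @export
spatial_grid <- function(n_points = 100, L = 1) {
  if (n_points < 3) stop("grid needs at least 3 points")
  dx <- L / n_points
  x <- (seq_len(n_points) - 0.5) * dx
  structure(list(n = as.integer(n_points), L = L, dx = dx, x = x,
                 positions = 100 * x / L),
            class = "gap_grid")
}

#' Zero-flux (Neumann) discrete Laplacian and its eigendecomposition
#'
#' Second-difference operator with reflecting boundary rows on the
#' cell-centred grid.  Its eigenvectors are the discrete cosine (DCT-II)
#' modes `cos(k pi (i - 1/2) / n)` and its eigenvalues are
#' `-(2/dx^2) (1 - cos(k pi / n))`, k = 0..n-1: negative semidefinite with a
#' single zero eigenvalue for the constant mode, so spatial mass is conserved
#' in the pure-diffusion limit.
#'
#' @param grid A `gap_grid`.
#' @return List with `matrix` (n x n operator), `values` (eigenvalues,
#'   decreasing from 0), and `vectors` (orthonormal eigenvector matrix).
#' @export
neumann_laplacian <- function(grid) {
  n <- grid$n
  if (n < 3) stop("grid needs at least 3 points")
  dx <- grid$dx
  A <- diag(-2, n)
  A[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- 1
  A[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- 1
  A[1, 1] <- -1
  A[n, n] <- -1
  A <- A / dx^2
  k <- seq_len(n) - 1
  values <- -(2 / dx^2) * (1 - cos(k * pi / n))
  i <- seq_len(n)
  V <- outer(i - 0.5, k, function(ii, kk) cos(kk * pi * ii / n))
  V <- sweep(V, 2, c(sqrt(1 / n), rep(sqrt(2 / n), n - 1)), `*`)
  list(matrix = A, values = values, vectors = V)
}

# phi-1 function of exponential integrators: (e^z - 1)/z with the z -> 0 limit.
phi1 <- function(z) {
  out <- ifelse(abs(z) < 1e-8, 1 + z / 2, expm1(z) / z)
  out
}

#' One exponential-Euler step of the reaction-diffusion system
#'
#' Advances all four gap genes by `dt` using the semigroup (variation of
#' constants) form: the linear diffusion-decay part `D Lap - beta I` is
#' propagated exactly in the cosine eigenbasis, and the nonlinear production
#' field f(u) = alpha P_A (1 - P_B), frozen at the current state, enters
#' through the phi-1 filter:
#'
#'   u <- exp(dt A) u + dt phi1(dt A) f(u),   A = D Lap_N - beta I.
#'
#' This is the pure-R reference stepper; [rd_solve()] calls an equivalent
#' compiled fast path by default and the two are cross-checked in the tests.
#' Negative undershoots from the nonlinear term are clipped to zero and
#' counted.
#'
#' @param state List with `u` (n x 4 matrix, dynamic gene columns),
#'   `statics` (n x k matrix of static input profiles), `grid` (a
#'   `gap_grid`), and `time`.
#' @param model A `gap_model`.
#' @param params A `gap_params`.
#' @param dt Time step, > 0.
#' @param op Optional precomputed [neumann_laplacian()] of the grid.
#' @return Updated state with incremented `time` and a `clipped` counter.
#' @export
rd_step <- function(state, model, params, dt, op = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (any(!is.finite(state$u)))
    stop("non-finite state entering rd_step at t = ", state$time)
  if (is.null(op)) op <- neumann_laplacian(state$grid)
  genes <- model$genes$dynamic
  reg_state <- c(as.list(as.data.frame(state$u)),
                 as.list(as.data.frame(state$statics)))
  f <- vapply(genes,
              function(g) production_rate(reg_state, model, params, g),
              numeric(state$grid$n))
  lam <- params$D * op$values - params$beta
  E <- exp(dt * lam)
  P <- dt * phi1(dt * lam)
  Vt <- t(op$vectors)
  u_new <- op$vectors %*% (E * (Vt %*% state$u) + P * (Vt %*% f))
  clipped <- sum(u_new < 0)
  u_new[u_new < 0] <- 0
  dimnames(u_new) <- dimnames(state$u)
  state$u <- u_new
  state$time <- state$time + dt
  state$clipped <- (state$clipped %||% 0L) + clipped
  state
}

encode_edges <- function(model, statics_names) {
  genes <- model$genes$dynamic
  ed <- model$edges
  mode_code <- c(activator = 1L, repressor = 2L, dual = 3L)
  tgt <- match(ed$target, genes) - 1L
  kind <- ifelse(ed$regulator %in% genes, 0L, 1L)
  src <- ifelse(kind == 0L,
                match(ed$regulator, genes) - 1L,
                match(ed$regulator, statics_names) - 1L)
  if (any(is.na(tgt)) || any(is.na(src)))
    stop("topology references genes absent from the dynamic/static sets")
  cbind(target = tgt, kind = kind, source = src,
        mode = unname(mode_code[ed$mode]))
}

edge_affinities <- function(model, params) {
  labels <- model$affinity_map[model$edges$class]
  vapply(labels, function(l) {
    if (!(l %in% names(params$logK)))
      stop("parameter set lacks affinity ", l)
    10^unname(params$logK[[l]])
  }, numeric(1))
}

#' Solve the gap-gene reaction-diffusion system to the final time
#'
#' Integrates the four coupled equations from the cleavage-cycle-14.1 initial
#' condition to `T_final` (cc14.4) with zero-flux boundaries, using the
#' exponential-Euler stepper (compiled fast path by default).  Zygotic Hb is
#' initialized at the maternal Hb input profile; Kr, Kni and Gt start at
#' zero; the static inputs (Bcd, Cad, Tll) are held constant in time.  On
#' instability (any concentration exceeding 10x the maximum) the step size is
#' halved and the solve retried; persistent blow-up raises an error naming
#' the offending parameters.
#'
#' @param inputs n x k matrix of static input profiles with column names
#'   covering `model$genes$static`.
#' @param model A `gap_model`.
#' @param params A `gap_params`.
#' @param grid A `gap_grid` (rows of `inputs` must match).
#' @param T_final End time (cc14.4; nondimensionalized to 1).
#' @param dt Time step; default `1e-3 * T_final`.
#' @param u0 Optional n x 4 initial condition matrix overriding the default.
#' @param use_cpp Use the compiled stepper (default) or the pure-R reference.
#' @param max_retries Number of dt-halving retries on instability.
#' @return Object of class `rd_solution`: list with `profiles` (n x 4 matrix,
#'   columns Hb, Kr, Kni, Gt), `clipped` (count of negative undershoots set
#'   to zero), `dt` (step actually used), `n_steps`.
#' @export
rd_solve <- function(inputs, model, params, grid, T_final = 1,
                     dt = 1e-3 * T_final, u0 = NULL, use_cpp = TRUE,
                     max_retries = 3) {
  if (T_final <= 0) stop("T_final must be positive")
  genes <- model$genes$dynamic
  if (nrow(inputs) != grid$n)
    stop("inputs must have one row per grid point")
  missing_statics <- setdiff(model$genes$static, colnames(inputs))
  if (length(missing_statics) > 0L)
    stop("inputs lack static profiles: ",
         paste(missing_statics, collapse = ", "))
  if (is.null(u0)) {
    u0 <- matrix(0, grid$n, length(genes), dimnames = list(NULL, genes))
    u0[, "Hb"] <- inputs[, "Hb_maternal"]
  }
  op <- neumann_laplacian(grid)

  attempt <- function(dt_try) {
    n_steps <- as.integer(ceiling(T_final / dt_try))
    dt_eff <- T_final / n_steps
    if (use_cpp) {
      res <- rd_solve_cpp(u0, inputs[, model$genes$static, drop = FALSE],
                          encode_edges(model, model$genes$static),
                          edge_affinities(model, params),
                          params$alpha, params$beta, params$D,
                          params$Co, params$Ns,
                          op$vectors, op$values,
                          dt_eff, n_steps, model$max_conc)
      list(u = res$u, clipped = res$clipped, unstable = res$unstable,
           dt = dt_eff, n_steps = n_steps)
    } else {
      st <- list(u = u0, statics = inputs[, model$genes$static, drop = FALSE],
                 grid = grid, time = 0, clipped = 0L)
      unstable <- FALSE
      for (s in seq_len(n_steps)) {
        st <- rd_step(st, model, params, dt_eff, op)
        if (any(!is.finite(st$u)) ||
            max(st$u) > 10 * model$max_conc) { unstable <- TRUE; break }
      }
      list(u = st$u, clipped = st$clipped, unstable = unstable,
           dt = dt_eff, n_steps = n_steps)
    }
  }

  dt_try <- dt
  for (r in 0:max_retries) {
    res <- attempt(dt_try)
    if (!res$unstable) {
      colnames(res$u) <- genes
      return(structure(list(profiles = res$u, clipped = res$clipped,
                            dt = res$dt, n_steps = res$n_steps),
                       class = "rd_solution"))
    }
    dt_try <- dt_try / 2
  }
  stop("reaction-diffusion solve unstable (blow-up beyond 10x max ",
       "concentration) for parameters: alpha=", signif(params$alpha, 4),
       " beta=", signif(params$beta, 4), " D=", signif(params$D, 4),
       " Co=", signif(params$Co, 4), " Ns=", params$Ns,
       " logK=[", paste(signif(params$logK, 4), collapse = ","), "]")
}
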