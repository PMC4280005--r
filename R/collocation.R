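#' Three-point right-Radau collocation abscissae
#'
#' Normalized collocation points on `(0, 1]`: the roots of the cubic
#' right-Radau polynomial, with the right endpoint included exactly. Closed
#' form: `(4 - sqrt(6))/10`, `(4 + sqrt(6))/10`, `1`.
#'
#' @return numeric vector of length 3.
#' @export
radau_points <- function() {
  c((4 - sqrt(6)) / 10, (4 + sqrt(6)) / 10, 1)
}

#' Collocation grid on the measurement times
#'
#' Finite-element borders sit at the measurement time points (`n_time - 1`
#' elements); inside each element the differential states are cubic Lagrange
#' polynomials collocated at the three right-Radau points, so each element
#' carries 4 coefficients per state: the value at the element start plus the
#' three Radau nodes. Because the last Radau point is the right endpoint,
#' element-end values are coefficients themselves and continuity is a plain
#' equality between neighbours.
#'
#' @param measurement_times sorted vector of at least two distinct times.
#' @return An object of class `collocation_grid` with `borders`,
#'   `normalized_points`, `n_elements`, and the absolute interior node times
#'   `node_times` (3 per element).
#' @export
radau_grid <- function(measurement_times) {
  t <- as.numeric(measurement_times)
  if (length(t) < 2) stop("need at least two measurement times")
  if (is.unsorted(t, strictly = TRUE)) stop("times must be sorted and distinct")
  cpts <- radau_points()
  nel <- length(t) - 1L
  h <- diff(t)
  node_times <- as.numeric(t(outer(t[-length(t)], rep(1, 3)) + outer(h, cpts)))
  structure(list(borders = t, normalized_points = cpts, n_elements = nel,
                 element_widths = h, node_times = node_times),
            class = "collocation_grid")
}

#' @export
print.collocation_grid <- function(x, ...) {
  cat("<collocation_grid> ", x$n_elements, " elements on [",
      x$borders[1], ", ", x$borders[length(x$borders)], "]\n", sep = "")
  invisible(x)
}

# Lagrange differentiation: L'_j(c_i) for nodes tau (here (0, c1, c2, c3)),
# evaluated at the interior points c. Rows: evaluation points, cols: nodes.
lagrange_diff_matrix <- function(tau, at) {
  n <- length(tau)
  D <- matrix(0, length(at), n)
  for (j in seq_len(n)) {
    others <- tau[-j]
    denom <- prod(tau[j] - others)
    for (ii in seq_along(at)) {
      s <- 0
      for (m in seq_along(others)) {
        s <- s + prod(at[ii] - others[-m])
      }
      D[ii, j] <- s / denom
    }
  }
  D
}

colloc_diff_matrix <- function() {
  cpts <- radau_points()
  lagrange_diff_matrix(c(0, cpts), cpts)
}

#' Dimensions of the collocation NLP
#'
#' Named variable and constraint counts of the discretized estimation problem
#' for a grid with `n_time` measurement points, a network, and the current
#' knot structure. With cubic Lagrange states and spline degree `k = 2`:
#' 4 coefficients per element per differential and per algebraic state,
#' 3 collocation constraints per element per differential state, one extra
#' algebraic constraint at the global initial point, and continuity at the
#' `n_time - 2` interior borders. Optimal-K mode adds the `n * d` basis
#' entries with `m_int * d` null-space and `d(d+1)/2` orthogonality
#' constraints.
#'
#' @param net a [metabolic_network()].
#' @param grid a [radau_grid()].
#' @param flux_set a [free_flux_set()] (or a `g_vec` integer vector).
#' @param optimal_K include the optimized-basis variables and constraints.
#' @param k spline degree (pipeline default 2).
#' @return named list with `variables`, `constraints` and totals.
#' @export
dimension_report <- function(net, grid, flux_set, optimal_K = FALSE, k = 2) {
  stopifnot(inherits(net, "metabolic_network"), inherits(grid, "collocation_grid"))
  g_vec <- if (inherits(flux_set, "free_flux_set")) flux_set$g_vec else as.integer(flux_set)
  d <- length(g_vec)
  n_g <- sum(g_vec)
  n_time <- length(grid$borders)
  n_x <- net$m_ext + 1L
  vars <- list(
    p_x = 4L * (n_time - 1L) * n_x,
    p_z = 4L * (n_time - 1L) * net$n_irr,
    p_u = n_g + d * (k + 1L),
    t_knot = n_g,
    x_0 = n_x
  )
  cons <- list(
    coll_diff = 3L * (n_time - 1L) * n_x,
    cont_diff = (n_time - 2L) * n_x,
    coll_alg = (3L * (n_time - 1L) + 1L) * net$n_irr,
    cont_alg = (n_time - 2L) * net$n_irr,
    init = n_x
  )
  if (optimal_K) {
    vars$K <- net$n * d
    cons$null_space <- net$m_int * d
    cons$orthogonality <- d * (d + 1L) / 2L
  }
  list(variables = vars, constraints = cons,
       n_variables = sum(unlist(vars)), n_constraints = sum(unlist(cons)))
}

#' Discretize the dynamic estimation problem
#'
#' Assembles the collocation representation of the reduced dynamic model on a
#' grid: index maps for the coefficient arrays `p_x` (differential states)
#' and `p_z` (irreversible algebraic fluxes), and residual functions for the
#' two equality blocks - `h_coll`, which enforces the ODE at every interior
#' Radau point and the algebraic definition `z = I_irr K u` at the
#' collocation points plus the global initial point, and `h_cont`, which
#' equates element end states with the next element's start coefficient.
#'
#' @param model a [dynamic_model()].
#' @param flux_set a [free_flux_set()] covering the grid horizon.
#' @param grid a [radau_grid()].
#' @return An object of class `discretized_system` with the grid, dimension
#'   report, and a `residuals(p_x, p_z, flux_set, x0)` function. `p_x` is an
#'   `n_x x 4 x n_elements` array (coefficient order: element start, then the
#'   three Radau nodes), `p_z` likewise with `n_irr` rows.
#' @export
discretize <- function(model, flux_set, grid) {
  stopifnot(inherits(model, "dynamic_model"), inherits(flux_set, "free_flux_set"),
            inherits(grid, "collocation_grid"))
  tb <- grid$borders
  if (flux_set$t0 > tb[1] + 1e-12 || flux_set$t_end < tb[length(tb)] - 1e-12)
    stop("spline horizon does not cover the collocation grid")
  net <- model$net
  dims <- dimension_report(net, grid, flux_set)
  Dm <- colloc_diff_matrix()
  cpts <- grid$normalized_points
  nel <- grid$n_elements
  n_x <- model$n_x
  n_irr <- net$n_irr

  residuals <- function(p_x, p_z, flux_set, x0) {
    IirrK <- model$IirrK
    h_coll_x <- numeric(0); h_coll_z <- numeric(0)
    h_cont_x <- numeric(0); h_cont_z <- numeric(0)
    u_fun <- function(t) evaluate_fluxes(flux_set, t)
    for (e in seq_len(nel)) {
      h <- tb[e + 1] - tb[e]
      tc <- tb[e] + cpts * h
      uc <- u_fun(tc)
      for (i in 1:3) {
        xdot <- as.numeric(p_x[, , e] %*% Dm[i, ]) / h
        rhs <- model_rhs(model, p_x[, i + 1, e], uc[, i], tc[i])
        h_coll_x <- c(h_coll_x, xdot - rhs)
        h_coll_z <- c(h_coll_z, p_z[, i + 1, e] - as.numeric(IirrK %*% uc[, i]))
      }
      if (e < nel) {
        h_cont_x <- c(h_cont_x, p_x[, 1, e + 1] - p_x[, 4, e])
        h_cont_z <- c(h_cont_z, p_z[, 1, e + 1] - p_z[, 4, e])
      }
    }
    u0 <- u_fun(tb[1])
    h_coll_z <- c(h_coll_z, p_z[, 1, 1] - as.numeric(IirrK %*% u0[, 1]))
    h_init <- p_x[, 1, 1] - x0
    list(h_coll = c(h_coll_x, h_coll_z),
         h_cont = c(h_cont_x, h_cont_z),
         h_init = h_init)
  }

  structure(list(model = model, grid = grid, dims = dims,
                 diff_matrix = Dm, residuals = residuals,
                 n_x = n_x, n_irr = n_irr, n_elements = nel),
            class = "discretized_system")
}

#' Solve the collocation equations of the reduced model
#'
#' For fixed free-flux profiles the reduced model is linear in the states, so
#' the collocation equations are square linear systems solved exactly element
#' by element. Returns the coefficient arrays `p_x`/`p_z`; the residual
#' blocks of [discretize()] vanish at this solution to round-off.
#'
#' @param disc a `discretized_system`.
#' @param flux_set a [free_flux_set()].
#' @param x0 initial state vector.
#' @return list with `p_x`, `p_z` (coefficient arrays), `states_borders`
#'   (`n_x x n_time`) and `u_borders`.
#' @export
solve_collocation <- function(disc, flux_set, x0) {
  stopifnot(inherits(disc, "discretized_system"))
  model <- disc$model
  grid <- disc$grid
  u_nodes <- evaluate_fluxes(flux_set, grid$node_times)
  W <- model$SeK %*% u_nodes
  dil <- dilution_rate(model, grid$borders[-length(grid$borders)])
  sol <- solve_colloc_states(grid$borders, disc$diff_matrix, W,
                             as.numeric(x0), model$bio_index, dil, model$feed)
  nel <- grid$n_elements
  n_x <- disc$n_x
  p_x <- array(0, c(n_x, 4, nel))
  for (e in seq_len(nel)) {
    p_x[, 1, e] <- sol$borders[, e]
    p_x[, 2:4, e] <- sol$nodes[, (3 * e - 2):(3 * e), drop = FALSE]
  }
  z_nodes <- model$IirrK %*% u_nodes
  u_b <- evaluate_fluxes(flux_set, grid$borders)
  z_b <- model$IirrK %*% u_b
  p_z <- array(0, c(disc$n_irr, 4, nel))
  for (e in seq_len(nel)) {
    p_z[, 1, e] <- z_b[, e]
    p_z[, 2:4, e] <- z_nodes[, (3 * e - 2):(3 * e), drop = FALSE]
  }
  list(p_x = p_x, p_z = p_z,
       states_borders = sol$borders, states_nodes = sol$nodes,
       u_borders = u_b)
}

#' Collocation solve of a general linear ODE (reference path)
#'
#' Solves `x' = A(t) x + b(t)` on a collocation grid with the same cubic
#' Lagrange / right-Radau scheme, entirely in R. Used for verification
#' against analytic solutions and for order studies.
#'
#' @param A_fun function of `t` returning the `n x n` system matrix.
#' @param b_fun function of `t` returning the forcing vector (default 0).
#' @param x0 initial state.
#' @param grid a [radau_grid()].
#' @return matrix of border states (`n x n_time`).
#' @export
collocation_solve_linear <- function(A_fun, x0, grid, b_fun = NULL) {
  stopifnot(inherits(grid, "collocation_grid"))
  n <- length(x0)
  if (is.null(b_fun)) b_fun <- function(t) numeric(n)
  Dm <- colloc_diff_matrix()
  cpts <- grid$normalized_points
  tb <- grid$borders
  out <- matrix(0, n, length(tb))
  out[, 1] <- x0
  xs <- x0
  for (e in seq_len(grid$n_elements)) {
    h <- tb[e + 1] - tb[e]
    tc <- tb[e] + cpts * h
    M <- matrix(0, 3 * n, 3 * n)
    rhs <- numeric(3 * n)
    for (i in 1:3) {
      ri <- ((i - 1) * n + 1):(i * n)
      for (j in 1:3) {
        cj <- ((j - 1) * n + 1):(j * n)
        M[ri, cj] <- M[ri, cj] + diag(Dm[i, j + 1] / h, n)
      }
      M[ri, ri] <- M[ri, ri] - A_fun(tc[i])
      rhs[ri] <- -Dm[i, 1] / h * xs + b_fun(tc[i])
    }
    sol <- solve(M, rhs)
    xs <- sol[(2 * n + 1):(3 * n)]
    out[, e + 1] <- xs
  }
  out
}
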