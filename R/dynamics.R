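#' Reduced extracellular dynamic model
#'
#' Under the pseudo-steady-state assumption the extracellular state vector
#' `x = (c_ext, c_bio)` evolves as
#' `dx/dt = S_e K u(t) (q_bio' x)` in batch mode, with the dilution term
#' `D(t) (x_in - x)` added for a continuous reactor. The biomass concentration
#' multiplies the specific fluxes because fluxes are per gram dry weight while
#' concentrations are per litre of medium.
#'
#' @param net a [metabolic_network()].
#' @param basis a null-space basis from [rational_basis()] or
#'   [orthonormal_basis()].
#' @param mode `"batch"` or `"continuous"`.
#' @param dilution for continuous mode, a data frame with columns `time` and
#'   `D` (1/h) defining a right-continuous step profile, or a single number.
#' @param feed for continuous mode, feed concentration vector `x_in`
#'   (mmol/L, length `m_ext + 1`; biomass entry normally 0).
#' @return An object of class `dynamic_model`.
#' @export
dynamic_model <- function(net, basis, mode = c("batch", "continuous"),
                          dilution = NULL, feed = NULL) {
  stopifnot(inherits(net, "metabolic_network"), inherits(basis, "null_space_basis"))
  mode <- match.arg(mode)
  n_x <- net$m_ext + 1L
  if (mode == "continuous") {
    if (is.null(dilution)) stop("continuous mode needs a dilution profile")
    if (is.numeric(dilution) && length(dilution) == 1L)
      dilution <- data.frame(time = -Inf, D = dilution)
    dilution <- as.data.frame(dilution)
    if (!all(c("time", "D") %in% names(dilution)))
      stop("dilution profile needs columns 'time' and 'D'")
    if (any(dilution$D < 0)) stop("dilution rate must be nonnegative")
    if (is.null(feed)) feed <- numeric(n_x)
    if (length(feed) != n_x) stop("feed vector must have length m_ext + 1")
  } else {
    dilution <- NULL
    feed <- numeric(n_x)
  }
  structure(list(net = net, basis = basis, mode = mode,
                 dilution = dilution, feed = as.numeric(feed),
                 n_x = n_x, bio_index = n_x,
                 SeK = net$S_e %*% basis$K,
                 IirrK = net$I_irr %*% basis$K),
            class = "dynamic_model")
}

# right-continuous step dilution rate at times t
dilution_rate <- function(model, t) {
  if (model$mode == "batch") return(rep(0, length(t)))
  tb <- model$dilution$time
  Dv <- model$dilution$D
  idx <- findInterval(t, tb)
  out <- rep(0, length(t))
  out[idx > 0] <- Dv[idx[idx > 0]]
  out
}

#' Model right-hand side
#'
#' Evaluates `dx/dt` for a state `x`, free-flux vector `u` and time `t`.
#' Batch: `S_e K u (q_bio' x)`; continuous adds `D(t) (x_in - x)`.
#'
#' @param model a [dynamic_model()].
#' @param x state vector (`m_ext + 1`; biomass last).
#' @param u free-flux vector (length `d`).
#' @param t time (needed only for the dilution profile).
#' @return state derivative vector.
#' @export
model_rhs <- function(model, x, u, t = 0) {
  stopifnot(inherits(model, "dynamic_model"))
  dx <- as.numeric(model$SeK %*% u) * x[model$bio_index]
  if (model$mode == "continuous")
    dx <- dx + dilution_rate(model, t) * (model$feed - x)
  dx
}

#' Irreversible (algebraic) fluxes
#'
#' `z = I_irr K u`: the values of the thermodynamically irreversible fluxes
#' implied by a free-flux vector. The estimator constrains these nonnegative.
#'
#' @param basis a null-space basis.
#' @param net a [metabolic_network()].
#' @param u free-flux vector or `d x n_t` matrix.
#' @return vector (or matrix) of length/rows `n_irr`.
#' @export
irreversible_fluxes <- function(basis, net, u) {
  stopifnot(inherits(basis, "null_space_basis"), inherits(net, "metabolic_network"))
  (net$I_irr %*% basis$K) %*% u
}

#' Measurement output map
#'
#' Outputs are linear selections of states and of fluxes: concentrations are
#' picked directly from `x`, flux outputs (typically off-gas rates such as
#' oxygen uptake and carbon-dioxide production) are signed selections of
#' `v = K u`.
#'
#' @param state_idx indices of measured states (within `x`).
#' @param flux_idx indices of measured fluxes (within `v`); may be empty.
#' @param flux_sign per-flux sign (+1/-1) so measured off-gas values are
#'   nonnegative for uptake/production; recycled.
#' @param output_ids optional labels, defaults to `x<i>`/`v<j>`.
#' @return An object of class `output_map` with `n_out` outputs.
#' @export
output_map <- function(state_idx, flux_idx = integer(), flux_sign = 1,
                       output_ids = NULL) {
  state_idx <- as.integer(state_idx)
  flux_idx <- as.integer(flux_idx)
  n_out <- length(state_idx) + length(flux_idx)
  if (n_out < 1) stop("at least one output required")
  flux_sign <- rep_len(flux_sign, length(flux_idx))
  if (is.null(output_ids))
    output_ids <- c(paste0("x", state_idx),
                    if (length(flux_idx)) paste0("v", flux_idx))
  structure(list(state_idx = state_idx, flux_idx = flux_idx,
                 flux_sign = as.numeric(flux_sign),
                 output_ids = output_ids, n_out = n_out),
            class = "output_map")
}

#' Evaluate the outputs
#'
#' `y = [x[state_idx]; sign * (K u)[flux_idx]]`, in the fixed configuration
#' order: states first, then flux outputs.
#'
#' @param map an [output_map()].
#' @param basis a null-space basis.
#' @param x state vector (or `n_x x n_t` matrix).
#' @param u free-flux vector (or `d x n_t` matrix).
#' @return output vector (or `n_out x n_t` matrix).
#' @export
evaluate_outputs <- function(map, basis, x, u) {
  stopifnot(inherits(map, "output_map"))
  x <- as.matrix(x); u <- as.matrix(u)
  ys <- x[map$state_idx, , drop = FALSE]
  if (length(map$flux_idx)) {
    v <- basis$K %*% u
    yf <- map$flux_sign * v[map$flux_idx, , drop = FALSE]
    y <- rbind(ys, yf)
  } else y <- ys
  rownames(y) <- map$output_ids
  if (ncol(y) == 1) drop(y) else y
}
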