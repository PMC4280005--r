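#' Percentile confidence bands from replicate curves
#'
#' Pointwise lower/upper percentiles across replicate curves, computed by
#' sorting with linear interpolation between order statistics. Exposed
#' separately from the bootstrap driver so the banding rule can be validated
#' against closed-form references.
#'
#' @param replicate_matrix `n_replicates x n_points` matrix.
#' @param probs two probabilities (default `c(0.025, 0.975)` for 95% bands).
#' @return `2 x n_points` matrix (rows: lower, upper).
#' @export
percentile_bands <- function(replicate_matrix, probs = c(0.025, 0.975)) {
  apply(replicate_matrix, 2, stats::quantile, probs = probs, type = 7,
        names = FALSE)
}

#' Monte-Carlo bootstrap confidence bands
#'
#' Parametric bootstrap under the measurement-noise model: each replicate
#' draws every measurement from `N(m_ij, sigma_ij^2)`, re-estimates the
#' continuous parameters (control points, knot locations within their
#' windows, initial state, basis rotations) at the point estimate's frozen
#' knot structure, warm-started from the point estimate, and the 2.5th/97.5th
#' percentiles of the replicate flux profiles form pointwise 95% bands.
#'
#' The knot structure is not re-selected per replicate; the bands quantify
#' parameter uncertainty of the accepted model, not model-selection
#' uncertainty.
#'
#' @param fit a converged `dmfa_fit`.
#' @param measurements the [measurement_set()] used for the fit.
#' @param n_replicates number of bootstrap draws (default 1000).
#' @param seed integer seed; bands are reproducible given the seed.
#' @param times evaluation grid for the bands (default 101 points).
#' @param probs band probabilities.
#' @return An object of class `dmfa_bootstrap`: `bands` tibble (`time`,
#'   `flux`, `lower`, `point`, `upper`), the replicate parameter matrix,
#'   `n_failed`, and the seed.
#' @export
bootstrap_confidence <- function(fit, measurements, n_replicates = 1000,
                                 seed = 1L, times = NULL,
                                 probs = c(0.025, 0.975)) {
  stopifnot(inherits(fit, "dmfa_fit"), inherits(measurements, "measurement_set"))
  fs <- fit$flux_set
  if (is.null(times)) times <- seq(fs$t0, fs$t_end, length.out = 101)
  control <- fit$control
  template <- fs
  n_rot <- n_rotations(template$d, control$optimal_K)
  warm <- list(x0 = fit$x0_hat, flux_set = template, angles = fit$angles)
  n_flux <- nrow(fit$K_hat)
  flux_ids <- rownames(fit$K_hat) %||% paste0("v", seq_len(n_flux))

  set.seed(seed)
  par_list <- vector("list", n_replicates)
  curves <- array(NA_real_, c(n_replicates, n_flux, length(times)))
  n_failed <- 0L
  for (b in seq_len(n_replicates)) {
    ms_b <- measurements
    ms_b$mean <- stats::rnorm(nrow(ms_b), ms_b$mean, ms_b$sd)
    ms_b <- measurement_set(ms_b)
    prob <- estimation_problem(fit$model, fit$map, ms_b, template, control)
    res <- solve_subproblem(prob, warm)
    if (!res$ok) { n_failed <- n_failed + 1L; next }
    par_list[[b]] <- res$par
    u <- evaluate_fluxes(res$flux_set, times)
    curves[b, , ] <- as.matrix(res$K %*% u)
  }
  if (n_failed > 0.2 * n_replicates)
    warning("more than 20% of bootstrap replicates failed (",
            n_failed, "/", n_replicates, ")")
  ok <- !vapply(par_list, is.null, TRUE)
  params <- do.call(rbind, par_list[ok])
  u_hat <- evaluate_fluxes(fs, times)
  v_hat <- fit$K_hat %*% u_hat
  bands <- vector("list", n_flux)
  for (i in seq_len(n_flux)) {
    bb <- percentile_bands(curves[ok, i, , drop = TRUE], probs)
    bands[[i]] <- tibble::tibble(
      time = times, flux = flux_ids[i],
      lower = bb[1, ], point = as.numeric(v_hat[i, ]), upper = bb[2, ])
  }
  structure(list(bands = dplyr::bind_rows(bands), params = params,
                 n_replicates = n_replicates, n_failed = n_failed,
                 seed = seed, probs = probs, flux_ids = flux_ids),
            class = "dmfa_bootstrap")
}

#' @export
print.dmfa_bootstrap <- function(x, ...) {
  cat("<dmfa_bootstrap> ", x$n_replicates, " replicates (",
      x$n_failed, " failed), ", length(unique(x$bands$flux)),
      " flux bands\n", sep = "")
  invisible(x)
}
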