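#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a dMFA fit
#'
#' One row per estimated spline parameter: control points and internal knot
#' locations per free flux, the initial states, and the basis rotation
#' angles when the null-space basis was optimized.
#'
#' @param x a `dmfa_fit`.
#' @param ... unused.
#' @return a tibble with columns `term`, `flux`, `type`, `estimate`.
#' @method tidy dmfa_fit
#' @export
tidy.dmfa_fit <- function(x, ...) {
  fs <- x$flux_set
  rows <- list(tibble::tibble(
    term = paste0("x0[", seq_along(x$x0_hat), "]"),
    flux = NA_character_, type = "initial_state", estimate = x$x0_hat))
  for (j in seq_len(fs$d)) {
    s <- fs$splines[[j]]
    id <- fs$flux_ids[j]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      term = paste0(id, ".p[", seq_along(s$control), "]"),
      flux = id, type = "control_point", estimate = s$control)
    if (length(s$knots))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        term = paste0(id, ".t[", seq_along(s$knots), "]"),
        flux = id, type = "knot", estimate = s$knots)
  }
  if (length(x$angles))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      term = paste0("theta[", seq_along(x$angles), "]"),
      flux = NA_character_, type = "basis_rotation", estimate = x$angles)
  dplyr::bind_rows(rows)
}

#' One-row fit summary
#'
#' @param x a `dmfa_fit`.
#' @param ... unused.
#' @return tibble with `f` (weighted SSE), `n_p`, `n_meas`, `aic`,
#'   `chi2_pass`, `chi2_critical`, `dof`, `n_knots`, `n_solves`.
#' @method glance dmfa_fit
#' @export
glance.dmfa_fit <- function(x, ...) {
  tibble::tibble(
    f = x$f, n_p = x$n_p, n_meas = x$n_meas, aic = x$aic,
    chi2_pass = x$chi2$pass, chi2_critical = x$chi2$critical,
    dof = x$chi2$dof, n_knots = sum(x$flux_set$g_vec),
    n_solves = x$n_solves)
}

#' Measurements with fitted values and residuals
#'
#' @param x a `dmfa_fit`.
#' @param ... unused.
#' @return the fit's measurement tibble with `.fitted`, `.resid` and
#'   `.std.resid` columns.
#' @method augment dmfa_fit
#' @export
augment.dmfa_fit <- function(x, ...) {
  ms <- x$measurements
  outputs <- attr(ms, "outputs")
  times <- attr(ms, "times")
  fitted <- x$y_hat[cbind(match(ms$output, outputs), match(ms$time, times))]
  out <- tibble::as_tibble(ms)
  out$.fitted <- fitted
  out$.resid <- out$mean - fitted
  out$.std.resid <- out$.resid / out$sd
  out
}

#' Plot estimated flux profiles
#'
#' @param object a `dmfa_fit`.
#' @param times evaluation grid (default 200 points over the horizon).
#' @param free_only plot only the free fluxes (default all reconstructed
#'   fluxes `v = K u`).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot dmfa_fit
#' @export
autoplot.dmfa_fit <- function(object, times = NULL, free_only = FALSE, ...) {
  prof <- flux_profiles(object, times)
  if (free_only && !is.null(object$model$basis$free_flux_ids))
    prof <- prof[prof$flux %in% object$model$basis$free_flux_ids, ]
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~flux, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "specific flux (mmol/gDW/h)") +
    ggplot2::theme_minimal()
}

#' Plot bootstrap confidence bands
#'
#' @param object a `dmfa_bootstrap`.
#' @param fluxes optional subset of flux ids.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot dmfa_bootstrap
#' @export
autoplot.dmfa_bootstrap <- function(object, fluxes = NULL, ...) {
  b <- object$bands
  if (!is.null(fluxes)) b <- b[b$flux %in% fluxes, ]
  ggplot2::ggplot(b, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$point)) +
    ggplot2::facet_wrap(~flux, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "specific flux (mmol/gDW/h)") +
    ggplot2::theme_minimal()
}

#' Plot measurements against fitted outputs
#'
#' @param fit a `dmfa_fit`.
#' @return a ggplot object with measurement points (error bars of one sigma)
#'   and the fitted output trajectories.
#' @export
plot_fit_outputs <- function(fit) {
  aug <- augment(fit)
  ggplot2::ggplot(aug, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean), size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), colour = "firebrick") +
    ggplot2::facet_wrap(~output, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "output") +
    ggplot2::theme_minimal()
}
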