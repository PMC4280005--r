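#' Clamped B-spline flux profile
#'
#' A single free-flux profile is a polynomial spline of degree `k` on
#' `[t0, t_end]` written in the B-spline basis: `u(t) = sum_i p_i B_{i,k}(t)`
#' with `q = g + k + 1` control points for `g` internal knots. The total knot
#' vector is clamped: `k + 1` copies of `t0` in front and `k + 1` copies of
#' `t_end` at the back, so the spline interpolates nothing implicitly and the
#' basis sums to one everywhere on the horizon.
#'
#' Each internal knot may carry a window `[lo, hi]`; optimizers treat windows
#' as box bounds that keep a knot inside the measurement interval it was
#' accepted in.
#'
#' @param degree polynomial degree `k >= 0` (the estimation pipeline fixes
#'   `k = 2`, the smallest degree with a continuous first derivative).
#' @param t0,t_end horizon bounds (h), `t0 < t_end`.
#' @param knots sorted internal knots, each strictly inside `(t0, t_end)`.
#' @param control control points; length must be `g + k + 1`. Defaults to
#'   zeros.
#' @param windows optional `g x 2` matrix of per-knot bounds (`NA` rows mean
#'   unbounded).
#' @return An object of class `bspline`.
#' @export
bspline <- function(degree = 2, t0, t_end, knots = numeric(),
                    control = NULL, windows = NULL) {
  stopifnot(degree >= 0, t_end > t0)
  knots <- as.numeric(knots)
  if (is.unsorted(knots)) stop("internal knots must be nondecreasing")
  if (length(knots) && (min(knots) <= t0 || max(knots) >= t_end))
    stop("internal knots must lie strictly inside (t0, t_end)")
  q <- length(knots) + degree + 1
  if (is.null(control)) control <- numeric(q)
  if (length(control) != q)
    stop("need q = g + k + 1 = ", q, " control points, got ", length(control))
  if (is.null(windows)) {
    windows <- matrix(NA_real_, length(knots), 2)
  } else {
    windows <- matrix(as.numeric(windows), ncol = 2)
    if (nrow(windows) != length(knots)) stop("one window row per internal knot")
  }
  colnames(windows) <- c("lo", "hi")
  structure(list(degree = degree, t0 = t0, t_end = t_end, knots = knots,
                 control = as.numeric(control), windows = windows),
            class = "bspline")
}

#' @export
print.bspline <- function(x, ...) {
  cat("<bspline> degree ", x$degree, " on [", x$t0, ", ", x$t_end, "], ",
      length(x$knots), " internal knot(s)\n", sep = "")
  invisible(x)
}

#' Number of B-spline basis functions
#'
#' The spline space of degree `k` with `g` internal knots has dimension
#' `q = g + k + 1`; this is also the number of control points.
#'
#' @param g number of internal knots, `>= 0`.
#' @param k degree, `>= 0`.
#' @return integer `q`.
#' @export
count_basis_functions <- function(g, k) {
  if (any(g < 0) || any(k < 0)) stop("g and k must be nonnegative")
  g + k + 1
}

#' Total clamped knot vector
#'
#' Returns the full knot sequence of length `g + 2k + 2`: `k + 1` copies of
#' `t0`, the internal knots, and `k + 1` copies of `t_end`.
#'
#' @param s a [bspline()].
#' @return numeric vector.
#' @export
clamped_knot_vector <- function(s) {
  stopifnot(inherits(s, "bspline"))
  k <- s$degree
  c(rep(s$t0, k + 1), s$knots, rep(s$t_end, k + 1))
}

# Cox-de Boor basis value B_{i,k}(t) under the right-continuity convention:
# at an interior knot the basis of the right span is active, except at t_end
# where the last span is closed. Vectorized over t; returns (length(t) x q).
bspline_basis <- function(knot_vector, degree, t) {
  tv <- knot_vector
  k <- degree
  q <- length(tv) - k - 1
  n0 <- length(tv) - 1
  # degree-0 indicators: [tv[i], tv[i+1]) with the last nonempty span closed
  B <- matrix(0, length(t), n0)
  last_span <- max(which(tv < tv[length(tv)]))  # index of last nonempty span
  for (i in seq_len(n0)) {
    if (tv[i + 1] > tv[i]) {
      hit <- t >= tv[i] & (if (i == last_span) t <= tv[i + 1] else t < tv[i + 1])
      B[hit, i] <- 1
    }
  }
  if (k == 0) return(B[, seq_len(q), drop = FALSE])
  for (p in seq_len(k)) {
    nb <- n0 - p
    Bp <- matrix(0, length(t), nb)
    for (i in seq_len(nb)) {
      den1 <- tv[i + p] - tv[i]
      den2 <- tv[i + p + 1] - tv[i + 1]
      a <- if (den1 > 0) (t - tv[i]) / den1 * B[, i] else 0
      b <- if (den2 > 0) (tv[i + p + 1] - t) / den2 * B[, i + 1] else 0
      Bp[, i] <- a + b
    }
    B <- Bp
  }
  B[, seq_len(q), drop = FALSE]
}

#' Evaluate a B-spline flux profile
#'
#' Cox-de Boor evaluation of `u(t)`. Evaluation at an interior knot follows
#' the right-limit convention; `t_end` is included. Points outside
#' `[t0, t_end]` are a domain error: flux profiles are never extrapolated.
#'
#' @param s a [bspline()].
#' @param t time or vector of times within the horizon.
#' @return numeric vector of flux values.
#' @export
evaluate_spline <- function(s, t) {
  stopifnot(inherits(s, "bspline"))
  if (any(t < s$t0 - 1e-12) || any(t > s$t_end + 1e-12))
    stop("evaluation outside the spline horizon [", s$t0, ", ", s$t_end, "]")
  t <- pmin(pmax(t, s$t0), s$t_end)
  B <- bspline_basis(clamped_knot_vector(s), s$degree, t)
  as.numeric(B %*% s$control)
}

#' Insert a knot without changing the profile
#'
#' Boehm's single-knot insertion: the new control polygon is a convex
#' combination of the old one, chosen so the represented curve is unchanged
#' to machine precision. `g` and `q` both grow by one; existing knot windows
#' are preserved and the new knot starts unbounded.
#'
#' This identity is what makes the incremental estimator's warm starts exact:
#' the refined spline reproduces the accepted profile, so the next
#' optimization starts at the previous optimum.
#'
#' @param s a [bspline()].
#' @param t_new location in `(t0, t_end)`; inserting at an existing knot of
#'   multiplicity `k` is refused (the spline would lose continuity).
#' @return a new [bspline()].
#' @export
insert_knot <- function(s, t_new) {
  stopifnot(inherits(s, "bspline"))
  if (t_new <= s$t0 || t_new >= s$t_end)
    stop("new knot must lie strictly inside (t0, t_end)")
  k <- s$degree
  if (sum(abs(s$knots - t_new) < 1e-14) >= max(k, 1))
    stop("knot multiplicity would exceed the spline degree")
  tv <- clamped_knot_vector(s)
  q <- length(s$control)
  # span index l (1-based): largest l with tv[l] <= t_new
  l <- max(which(tv <= t_new))
  p_old <- s$control
  p_new <- numeric(q + 1)
  for (i in seq_len(q + 1)) {
    if (i <= l - k) {
      p_new[i] <- p_old[i]
    } else if (i > l) {
      p_new[i] <- p_old[i - 1]
    } else {
      alpha <- (t_new - tv[i]) / (tv[i + k] - tv[i])
      p_new[i] <- alpha * p_old[i] + (1 - alpha) * p_old[i - 1]
    }
  }
  pos <- sum(s$knots <= t_new)
  knots <- append(s$knots, t_new, after = pos)
  windows <- rbind(
    s$windows[seq_len(pos), , drop = FALSE],
    c(NA_real_, NA_real_),
    if (pos < nrow(s$windows)) s$windows[(pos + 1):nrow(s$windows), , drop = FALSE]
  )
  bspline(k, s$t0, s$t_end, knots, p_new, windows)
}

#' Prolongate a spline to a longer horizon
#'
#' Moves the end knot to `t_end_new`, keeping control points and internal
#' knots. The profile on the old horizon changes only through the stretching
#' of the last basis functions, so it stays close to the previous one - the
#' warm-start mechanism used when the estimation horizon grows by one
#' measurement.
#'
#' @param s a [bspline()].
#' @param t_end_new new end time, larger than both `t_end` and the last
#'   internal knot.
#' @return a new [bspline()].
#' @export
prolongate <- function(s, t_end_new) {
  stopifnot(inherits(s, "bspline"))
  if (t_end_new <= s$t_end) stop("t_end_new must extend the horizon")
  if (length(s$knots) && t_end_new <= max(s$knots))
    stop("t_end_new must exceed the last internal knot")
  bspline(s$degree, s$t0, t_end_new, s$knots, s$control, s$windows)
}

#' Constrain an internal knot to a window
#'
#' Records box bounds for one internal knot; downstream optimizers honor the
#' window, which pins an accepted knot to the measurement interval it was
#' inserted in.
#'
#' @param s a [bspline()].
#' @param knot_index which internal knot (1-based).
#' @param lo,hi window bounds; the current knot value must lie inside.
#' @return a new [bspline()] with the window recorded.
#' @export
constrain_knot <- function(s, knot_index, lo, hi) {
  stopifnot(inherits(s, "bspline"))
  if (knot_index < 1 || knot_index > length(s$knots)) stop("no such internal knot")
  x <- s$knots[knot_index]
  if (x < lo || x > hi)
    stop("knot at ", x, " lies outside the window [", lo, ", ", hi, "]")
  s$windows[knot_index, ] <- c(lo, hi)
  s
}

#' Bundle of free-flux splines
#'
#' Container for the `d` spline profiles of the free fluxes. All splines must
#' share the horizon; `g_vec` and `n_g` summarize the knot structure that the
#' incremental algorithm grows.
#'
#' @param splines list of [bspline()] objects, one per free flux.
#' @param flux_ids optional labels (defaults to `u1..ud`).
#' @return An object of class `free_flux_set`.
#' @export
free_flux_set <- function(splines, flux_ids = NULL) {
  stopifnot(length(splines) >= 1, all(vapply(splines, inherits, TRUE, "bspline")))
  t0 <- unique(vapply(splines, `[[`, 0, "t0"))
  te <- unique(vapply(splines, `[[`, 0, "t_end"))
  if (length(t0) != 1 || length(te) != 1) stop("all splines must share the horizon")
  if (is.null(flux_ids)) flux_ids <- paste0("u", seq_along(splines))
  g_vec <- vapply(splines, function(s) length(s$knots), 0L)
  structure(list(splines = splines, flux_ids = flux_ids, d = length(splines),
                 g_vec = g_vec, n_g = sum(g_vec), t0 = t0, t_end = te),
            class = "free_flux_set")
}

#' Evaluate all free fluxes of a set
#'
#' @param fs a [free_flux_set()].
#' @param t times within the shared horizon.
#' @return a `d x length(t)` matrix of free-flux values.
#' @export
evaluate_fluxes <- function(fs, t) {
  stopifnot(inherits(fs, "free_flux_set"))
  out <- vapply(fs$splines, evaluate_spline, numeric(length(t)), t = t)
  matrix(t(out), nrow = fs$d, dimnames = list(fs$flux_ids, NULL))
}

#' @export
print.free_flux_set <- function(x, ...) {
  cat("<free_flux_set> ", x$d, " free fluxes on [", x$t0, ", ", x$t_end,
      "], internal knots: ", paste(x$g_vec, collapse = "/"), "\n", sep = "")
  invisible(x)
}

# serializable plain-list form (JSON round trips)
spline_to_list <- function(s) {
  list(degree = s$degree, t0 = s$t0, t_end = s$t_end,
       knots = s$knots, control = s$control,
       windows_lo = s$windows[, 1], windows_hi = s$windows[, 2])
}

spline_from_list <- function(x) {
  g <- length(x$knots)
  w <- cbind(as.numeric(x$windows_lo), as.numeric(x$windows_hi))
  if (g == 0) w <- matrix(NA_real_, 0, 2)
  bspline(x$degree, x$t0, x$t_end, as.numeric(x$knots), as.numeric(x$control), w)
}
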