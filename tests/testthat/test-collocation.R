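test_that("radau points are the roots of the cubic right-Radau polynomial", {
  cpts <- radau_points()
  expect_equal(cpts[3], 1)
  # oracle: roots of P2(2x-1) - P3(2x-1) where P are Legendre polynomials;
  # in monomials of x: P2 - P3 = -20 x^3 + 36 x^2 - 18 x + 2 (scaled)
  rr <- polyroot(c(2, -18, 36, -20))
  rr <- sort(Re(rr[abs(Im(rr)) < 1e-9]))
  expect_equal(cpts, rr, tolerance = 1e-12)
})

test_that("grids map measurement intervals to finite elements", {
  g1 <- radau_grid(c(0, 1))
  expect_equal(g1$n_elements, 1L)
  expect_length(g1$node_times, 3L)
  expect_equal(g1$node_times[3], 1)
  g20 <- radau_grid(seq(0, 20, 1))
  expect_equal(g20$n_elements, 20L)
  expect_error(radau_grid(c(0, 2, 1)), "sorted")
  expect_error(radau_grid(c(0, 1, 1)), "sorted")
})

test_that("collocation residuals vanish for trivial and consistent systems", {
  net <- small_network()
  b <- rational_basis(net, c("v1", "v4", "v5"))
  mod <- dynamic_model(net, b, "batch")
  grid <- radau_grid(seq(0, 4, 1))
  fs <- free_flux_set(lapply(1:3, function(j)
    bspline(2, 0, 4, control = rep(0, 3))))
  disc <- discretize(mod, fs, grid)
  # u = 0 and constant coefficients: all residual blocks are exactly zero
  x0 <- c(10, 15, 0, 0.1)
  p_x <- array(rep(x0, 4 * 4), c(4, 4, 4))
  p_z <- array(0, c(net$n_irr, 4, 4))
  res <- disc$residuals(p_x, p_z, fs, x0)
  expect_equal(max(abs(res$h_coll)), 0)
  expect_equal(max(abs(res$h_cont)), 0)
  expect_equal(max(abs(res$h_init)), 0)

  # a solved system satisfies the assembled constraints to round-off
  fs2 <- free_flux_set(lapply(1:3, function(j)
    bspline(2, 0, 4, control = runif(3, 0.1, 0.5))))
  disc2 <- discretize(mod, fs2, grid)
  sol <- solve_collocation(disc2, fs2, x0)
  res2 <- disc2$residuals(sol$p_x, sol$p_z, fs2, x0)
  expect_lt(max(abs(res2$h_coll)), 1e-9)
  expect_lt(max(abs(res2$h_cont)), 1e-12)
})

test_that("collocation reproduces the analytic exponential decay", {
  grid <- radau_grid(seq(0, 1, length.out = 11))  # 10 elements
  xs <- collocation_solve_linear(function(t) matrix(-1, 1, 1), 1, grid)
  expect_lt(max(abs(xs[1, ] - exp(-grid$borders))), 1e-6)
})

test_that("border error decays at the Radau-IIA rate under refinement", {
  A <- matrix(c(-1, 0.5, 0, -2), 2, 2)
  x0 <- c(1, 0.5)
  ev <- eigen(A)
  expm_t <- function(t)
    Re(ev$vectors %*% diag(exp(ev$values * t)) %*% solve(ev$vectors))
  errs <- sapply(c(4, 8, 16, 32), function(nel) {
    grid <- radau_grid(seq(0, 2, length.out = nel + 1))
    xs <- collocation_solve_linear(function(t) A, x0, grid)
    ref <- sapply(grid$borders, function(t) as.numeric(expm_t(t) %*% x0))
    max(abs(xs - ref))
  })
  slopes <- diff(log(errs)) / diff(log(2 / c(4, 8, 16, 32)))
  expect_gt(mean(slopes), 4.5)
})

test_that("dimension report matches the closed-form counts", {
  net <- small_network()
  grid <- radau_grid(seq(0, 20, 1))  # n_time = 21
  fs <- free_flux_set(lapply(1:3, function(j) bspline(2, 0, 20)))
  dr <- dimension_report(net, grid, fs)
  expect_equal(dr$variables$p_x, 4L * 20L * 4L)       # 320
  expect_equal(dr$constraints$coll_diff, 3L * 20L * 4L)  # 240
  expect_equal(dr$constraints$cont_diff, 19L * 4L)       # 76
  expect_equal(dr$constraints$coll_alg, (3L * 20L + 1L) * net$n_irr)
  dro <- dimension_report(net, grid, fs, optimal_K = TRUE)
  expect_equal(dro$constraints$orthogonality, 6L)     # d(d+1)/2
  expect_equal(dro$variables$K, net$n * 3L)
  # single element: no continuity constraints
  dr2 <- dimension_report(net, radau_grid(c(0, 1)), fs)
  expect_equal(dr2$constraints$cont_diff, 0L)
  expect_equal(dr2$constraints$cont_alg, 0L)
})

test_that("assembled residual lengths equal the dimension report", {
  set.seed(53)
  net <- small_network()
  b <- rational_basis(net, c("v1", "v4", "v5"))
  mod <- dynamic_model(net, b, "batch")
  for (i in 1:20) {
    n_time <- sample(3:12, 1)
    times <- sort(runif(n_time, 0, 10))
    while (min(diff(times)) < 1e-3) times <- sort(runif(n_time, 0, 10))
    grid <- radau_grid(times)
    g_vec <- sample(0:2, 3, replace = TRUE)
    fs <- free_flux_set(lapply(g_vec, function(g) {
      kn <- sort(runif(g, times[1] + 0.01, times[n_time] - 0.01))
      bspline(2, times[1], times[n_time], kn, rnorm(g + 3))
    }))
    disc <- discretize(mod, fs, grid)
    dr <- disc$dims
    nel <- grid$n_elements
    p_x <- array(rnorm(4 * 4 * nel), c(4, 4, nel))
    p_z <- array(rnorm(net$n_irr * 4 * nel), c(net$n_irr, 4, nel))
    res <- disc$residuals(p_x, p_z, fs, rnorm(4))
    expect_length(res$h_coll, dr$constraints$coll_diff + dr$constraints$coll_alg)
    expect_length(res$h_cont, dr$constraints$cont_diff + dr$constraints$cont_alg)
    expect_length(res$h_init, dr$constraints$init)
    expect_equal(length(p_x), dr$variables$p_x)
    expect_equal(length(p_z), dr$variables$p_z)
    expect_equal(sum(vapply(fs$splines, function(s) length(s$control), 0)),
                 dr$variables$p_u)
  }
})

test_that("projected high-accuracy trajectories satisfy the collocation blocks", {
  # integrate the small-scale reference model very accurately, project the
  # trajectory onto the per-element representation, and check that h_coll
  # shrinks under grid refinement
  tw <- small_truth()
  mod <- tw$bp$model
  resid_norm <- sapply(c(5, 10, 20), function(nel) {
    grid <- radau_grid(seq(0, 20, length.out = nel + 1))
    # represent the true flux u1 on the grid via a fine interpolation spline
    tr <- simulate_truth(mod, tw$bp$kinetics,
                         experiment_protocol(grid$borders, tw$bp$protocol$x0))
    ufun <- list(
      stats::splinefun(tr$times, tr$u[1, ]),
      stats::splinefun(tr$times, tr$u[2, ]),
      stats::splinefun(tr$times, tr$u[3, ]))
    xfun <- lapply(1:4, function(i) stats::splinefun(tr$times, tr$states[i, ]))
    nelg <- grid$n_elements
    p_x <- array(0, c(4, 4, nelg))
    for (e in seq_len(nelg)) {
      tpts <- c(grid$borders[e], grid$borders[e] +
                  radau_points() * (grid$borders[e + 1] - grid$borders[e]))
      for (i in 1:4) p_x[i, , e] <- xfun[[i]](tpts)
    }
    Dm <- fluxspline:::colloc_diff_matrix()
    r <- c()
    for (e in seq_len(nelg)) {
      h <- grid$borders[e + 1] - grid$borders[e]
      tc <- grid$borders[e] + radau_points() * h
      for (i in 1:3) {
        u <- c(ufun[[1]](tc[i]), ufun[[2]](tc[i]), ufun[[3]](tc[i]))
        xdot <- as.numeric(p_x[, , e] %*% Dm[i, ]) / h
        r <- c(r, xdot - model_rhs(mod, p_x[, i + 1, e], u, tc[i]))
      }
    }
    max(abs(r))
  })
  expect_true(all(diff(resid_norm) < 0))  # monotone decrease under refinement
  expect_lt(resid_norm[3], resid_norm[1] / 5)
})
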