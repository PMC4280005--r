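test_that("clamped knot vector has k+1 copies of each boundary", {
  s0 <- bspline(2, 0, 20)
  expect_equal(clamped_knot_vector(s0), c(0, 0, 0, 20, 20, 20))
  s2 <- bspline(2, 0, 20, knots = c(5, 12))
  expect_equal(clamped_knot_vector(s2), c(0, 0, 0, 5, 12, 20, 20, 20))
  set.seed(3)
  s5 <- bspline(2, 0, 10, knots = sort(runif(5, 0.5, 9.5)))
  expect_length(clamped_knot_vector(s5), 5 + 2 * 2 + 2)
})

test_that("basis function count is g + k + 1", {
  expect_equal(count_basis_functions(2, 2), 5)
  expect_equal(count_basis_functions(0, 0), 1)
  expect_equal(count_basis_functions(7, 3), 11)
  expect_error(count_basis_functions(-1, 2), "nonnegative")
})

test_that("evaluation reproduces constants, steps and the spline space", {
  # partition of unity: equal control points give a constant function
  s <- bspline(2, 0, 10, knots = c(2, 7), control = rep(3.25, 5))
  expect_equal(evaluate_spline(s, seq(0, 10, 0.1)), rep(3.25, 101))
  # degree 0, single control point: a step of that height
  s0 <- bspline(0, 0, 1, control = 2.5)
  expect_equal(evaluate_spline(s0, c(0, 0.3, 1)), rep(2.5, 3))
  # random splines match the independent design-matrix evaluation
  set.seed(17)
  for (k in 1:3) {
    g <- sample(0:4, 1)
    kn <- sort(runif(g, 0.5, 9.5))
    p <- rnorm(g + k + 1)
    s <- bspline(k, 0, 10, kn, p)
    tt <- sort(runif(200, 0, 10))
    B <- splines::splineDesign(clamped_knot_vector(s), tt, ord = k + 1)
    expect_equal(evaluate_spline(s, tt), as.numeric(B %*% p), tolerance = 1e-12)
  }
  expect_error(evaluate_spline(s, 11), "horizon")
})

test_that("partition of unity holds on dense grids for degrees 0 to 3", {
  set.seed(23)
  for (k in 0:3) {
    g <- 3
    s <- bspline(k, 0, 5, sort(runif(g, 0.5, 4.5)), rep(1, g + k + 1))
    tt <- seq(0, 5, length.out = 501)
    expect_lt(max(abs(evaluate_spline(s, tt) - 1)), 1e-12)
  }
})

test_that("knot insertion preserves the profile to machine precision", {
  # constant spline stays constant with identical control points
  sc <- bspline(2, 0, 10, control = c(4, 4, 4))
  sc2 <- insert_knot(sc, 3.7)
  expect_equal(sc2$control, rep(4, 4))

  set.seed(29)
  for (i in 1:100) {
    k <- sample(1:3, 1)
    g <- sample(0:3, 1)
    kn <- sort(runif(g, 1, 9))
    s <- bspline(k, 0, 10, kn, rnorm(g + k + 1))
    t_new <- runif(1, 0.5, 9.5)
    s2 <- insert_knot(s, t_new)
    expect_length(s2$knots, g + 1)
    expect_length(s2$control, g + k + 2)
    tt <- seq(0, 10, length.out = 1000)
    # independent check: evaluate both through the design-matrix route
    v1 <- splines::splineDesign(clamped_knot_vector(s), tt, ord = k + 1) %*% s$control
    v2 <- splines::splineDesign(clamped_knot_vector(s2), tt, ord = k + 1) %*% s2$control
    expect_lt(max(abs(v1 - v2)), 1e-12 * max(1, max(abs(s$control))))
    expect_lt(max(abs(evaluate_spline(s, tt) - evaluate_spline(s2, tt))),
              1e-12 * max(1, max(abs(s$control))))
  }
})

test_that("knot insertion preserves windows and refuses excess multiplicity", {
  s <- bspline(2, 0, 10, knots = 4, control = rnorm(4))
  s <- constrain_knot(s, 1, 3, 5)
  s2 <- insert_knot(s, 7)
  expect_equal(s2$windows[1, ], c(lo = 3, hi = 5))
  expect_true(all(is.na(s2$windows[2, ])))
  s3 <- insert_knot(s2, 7)  # multiplicity 2 allowed at degree 2
  expect_error(insert_knot(s3, 7), "multiplicity")
})

test_that("prolongation moves only the end knot", {
  sc <- bspline(2, 0, 10, control = c(2, 2, 2))
  expect_equal(evaluate_spline(prolongate(sc, 11), seq(0, 11, 0.5)),
               rep(2, 23))
  s <- bspline(2, 0, 10, knots = 7.94, control = c(1, 3, -2, 0.5))
  s2 <- prolongate(s, 11)
  expect_equal(s2$knots, 7.94)
  expect_equal(s2$control, s$control)
  expect_equal(s2$t_end, 11)
  expect_error(prolongate(s, 9), "extend")
  s9 <- bspline(2, 0, 10, knots = 9.5, control = rnorm(4))
  expect_error(prolongate(s9, 9.4), "extend")
  # profile on the old horizon stays inside the control polygon hull
  tt <- seq(0, 10, length.out = 400)
  v <- evaluate_spline(s2, tt)
  expect_true(all(v >= min(s$control) - 1e-12 & v <= max(s$control) + 1e-12))
})

test_that("knot windows record bounds and reject violations", {
  s <- bspline(2, 0, 10, knots = 7.94, control = rnorm(4))
  s <- constrain_knot(s, 1, 7, 8)
  expect_equal(s$windows[1, ], c(lo = 7, hi = 8))
  s_full <- constrain_knot(s, 1, 0, 10)  # whole horizon: no-op semantics
  expect_equal(s_full$knots, s$knots)
  expect_error(constrain_knot(s, 1, 8.5, 9), "outside the window")
  expect_error(constrain_knot(s, 2, 0, 1), "no such")
})

test_that("quadratic splines have a continuous first derivative at knots", {
  set.seed(31)
  s <- bspline(2, 0, 10, knots = c(2.5, 6), control = rnorm(5))
  h <- 1e-7
  for (tk in s$knots) {
    left <- (evaluate_spline(s, tk) - evaluate_spline(s, tk - h)) / h
    right <- (evaluate_spline(s, tk + h) - evaluate_spline(s, tk)) / h
    expect_lt(abs(left - right), 1e-5)
  }
})

test_that("perturbing one control point only changes k+1 knot spans", {
  k <- 2
  kn <- c(2, 4, 6, 8)
  s1 <- bspline(k, 0, 10, kn, rep(1, 7))
  p2 <- rep(1, 7); p2[4] <- 2  # interior basis function index 4
  s2 <- bspline(k, 0, 10, kn, p2)
  tt <- seq(0, 10, length.out = 1001)
  diffmask <- abs(evaluate_spline(s1, tt) - evaluate_spline(s2, tt)) > 1e-14
  # support of B_{3,2} is (t_3, t_6) of the total knot vector = (2, 8)
  expect_true(all(tt[diffmask] >= 2 - 1e-9 & tt[diffmask] <= 8 + 1e-9))
  expect_false(any(diffmask & (tt < 2 | tt > 8)))
})

test_that("free flux sets track the shared horizon and knot totals", {
  fs <- free_flux_set(list(bspline(2, 0, 10, c(3, 7), rnorm(5)),
                           bspline(2, 0, 10),
                           bspline(2, 0, 10, 5, rnorm(4))))
  expect_equal(fs$g_vec, c(2L, 0L, 1L))
  expect_equal(fs$n_g, 3L)
  u <- evaluate_fluxes(fs, c(0, 5, 10))
  expect_equal(dim(u), c(3L, 3L))
  expect_error(free_flux_set(list(bspline(2, 0, 10), bspline(2, 0, 9))),
               "horizon")
})
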