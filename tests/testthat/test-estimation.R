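test_that("weighted SSE matches the naive double loop", {
  times <- 0:4
  out <- c("a", "b")
  set.seed(61)
  m <- matrix(rnorm(10, 5), 2, 5)
  s <- matrix(runif(10, 0.1, 1), 2, 5)
  ms <- measurement_set(tibble::tibble(
    time = rep(times, each = 2), output = rep(out, 5),
    mean = as.numeric(m), sd = as.numeric(s)))
  expect_equal(weighted_sse(ms, m), 0)
  pred <- m; pred[1, 1] <- m[1, 1] + 2 * s[1, 1]
  expect_equal(weighted_sse(ms, pred), 4)
  for (i in 1:10) {
    pred <- m + matrix(rnorm(10), 2, 5)
    expect_equal(weighted_sse(ms, pred), naive_sse(m, s, pred))
  }
  expect_error(measurement_set(tibble::tibble(
    time = c(0, 0), output = c("a", "b"), mean = 1:2, sd = c(1, 0))),
    "must be > 0")
})

test_that("AICc arithmetic matches its printed reference values", {
  expect_equal(aic_c(0, 0, 10), 0)
  expect_equal(aic_c(49.50, 33, 84), 160.38, tolerance = 1e-4)
  expect_equal(aic_c(14.41, 33, 84), 125.29, tolerance = 1e-4)
  expect_error(aic_c(1, 10, 11), "infeasible")
})

test_that("minimum start horizon solves the smallest-l inequality", {
  expect_equal(min_start_timepoints(4, 3, 3), 4L)
  expect_equal(min_start_timepoints(15, 3, 3), 1L)
  set.seed(67)
  for (i in 1:50) {
    n_out <- sample(1:12, 1); d <- sample(1:8, 1); m_ext <- sample(0:9, 1)
    expect_equal(min_start_timepoints(n_out, d, m_ext),
                 min_l_oracle(n_out, d, m_ext))
  }
})

test_that("parameter counts cover knots, splines, x0 and basis rotations", {
  expect_equal(count_parameters(c(4, 0, 2), 3, 2, 3), 25L)
  expect_equal(count_parameters(c(3, 3, 4), 3, 2, 3), 33L)
  expect_equal(count_parameters(c(4, 0, 2), 3, 2, 3, optimal_K = TRUE), 28L)
  expect_equal(count_parameters(c(0, 0, 0), 3, 2, 3), 13L)
})

test_that("chi-square gate uses the exact quantile", {
  expect_true(chi_square_gof(0, 64, 5)$pass)
  g <- chi_square_gof(10, 84, 25)
  expect_equal(g$dof, 59)
  expect_equal(g$critical, chisq_quantile_oracle(0.95, 59), tolerance = 1e-8)
  just_above <- g$critical + 1e-6
  expect_false(chi_square_gof(just_above, 84, 25)$pass)
  expect_error(chi_square_gof(1, 10, 10), "degrees of freedom")
})

test_that("a subproblem recovers a truth inside the model class", {
  # dense grid: the collocation discretization error must sit well below
  # the 1e-6 recovery tolerance
  ts <- toy_setup(n_time = 15)
  tmpl <- free_flux_set(list(bspline(2, 0, 7)))
  ctl <- est_control()
  prob <- estimation_problem(ts$model, ts$map, ts$ms, tmpl, ctl)
  guess <- list(x0 = c(4.8, 0.25),
                flux_set = free_flux_set(list(
                  bspline(2, 0, 7, control = c(0.4, 0.4, 0.4)))))
  res <- solve_subproblem(prob, guess)
  expect_true(res$ok)
  expect_equal(res$flux_set$splines[[1]]$control, ts$s_true$control,
               tolerance = 1e-6)
  expect_equal(res$x0, ts$x0, tolerance = 1e-6)
  expect_lt(res$violation, 1e-8)
})

test_that("optimal-K solutions stay orthonormal and dominate fixed bases", {
  tw <- small_truth("small_realistic")
  ms <- sample_measurements(tw$truth, tw$bp$map, seed = 71)
  ms6 <- measurement_set(ms[ms$time <= 5 + 1e-9, ])
  net <- tw$bp$net
  ob <- orthonormal_basis(net)
  mod <- dynamic_model(net, ob, "batch")
  tmpl <- free_flux_set(lapply(1:3, function(j) bspline(2, 0, 5)))
  ctl <- est_control()
  pr_fix <- estimation_problem(mod, tw$bp$map, ms6, tmpl, ctl)
  g0 <- fluxspline:::cold_start(mod, tw$bp$map, ms6, tmpl, ctl)
  r_fix <- solve_subproblem(pr_fix, g0)
  expect_true(r_fix$ok)
  ctl_opt <- est_control(optimal_K = TRUE)
  pr_opt <- estimation_problem(mod, tw$bp$map, ms6, tmpl, ctl_opt)
  r_opt <- solve_subproblem(pr_opt, list(x0 = r_fix$x0,
                                         flux_set = r_fix$flux_set,
                                         angles = numeric(3)))
  expect_true(r_opt$ok)
  # feasibility of the basis constraints at the optimum
  expect_true(check_basis(net, r_opt$K, orthonormal_required = TRUE)$ok)
  # enlarged feasible set: the optimized basis can only improve the fit
  expect_lte(r_opt$f, r_fix$f + 1e-8)
})

test_that("the objective is invariant under orthonormal basis rotation", {
  tw <- small_truth("small_low_noise")
  ms <- sample_measurements(tw$truth, tw$bp$map, seed = 71)
  ms6 <- measurement_set(ms[ms$time <= 5 + 1e-9, ])
  net <- tw$bp$net
  ob <- orthonormal_basis(net)
  mod1 <- dynamic_model(net, ob, "batch")
  tmpl <- free_flux_set(lapply(1:3, function(j) bspline(2, 0, 5)))
  ctl <- est_control(restarts = 8)
  pr1 <- estimation_problem(mod1, tw$bp$map, ms6, tmpl, ctl)
  g0 <- fluxspline:::cold_start(mod1, tw$bp$map, ms6, tmpl, ctl)
  r1 <- solve_subproblem(pr1, g0)
  set.seed(73)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  mod2 <- dynamic_model(net, fluxspline:::new_basis(ob$K %*% Q, "orthonormal"),
                        "batch")
  pr2 <- estimation_problem(mod2, tw$bp$map, ms6, tmpl, ctl)
  # transport between parameterizations: u2(t) = Q' u1(t), so control points
  # transform linearly while v(t) = K u(t) is untouched
  transport <- function(res, Qm) {
    P <- sapply(res$flux_set$splines, `[[`, "control") %*% Qm
    fs <- tmpl
    for (j in 1:3) fs$splines[[j]]$control <- P[, j]
    list(x0 = res$x0, flux_set = fs)
  }
  # identical objective value at the transported point (model invariance)
  w2 <- transport(r1, Q)
  expect_equal(pr2$objective(fluxspline:::pack_par(w2$x0, w2$flux_set)),
               pr1$objective(fluxspline:::pack_par(r1$x0, r1$flux_set)),
               tolerance = 1e-8)
  # after polishing in both parameterizations, the optima and the
  # reconstructed full-space flux profiles agree
  r2 <- solve_subproblem(pr2, w2)
  r1 <- solve_subproblem(pr1, transport(r2, t(Q)))
  r2 <- solve_subproblem(pr2, transport(r1, Q))
  expect_equal(r1$f, r2$f, tolerance = 1e-3)
  tt <- seq(0, 5, 0.25)
  v1 <- r1$K %*% evaluate_fluxes(r1$flux_set, tt)
  v2 <- r2$K %*% evaluate_fluxes(r2$flux_set, tt)
  expect_lt(max(abs(v1 - v2)), 1e-4)
})

test_that("incremental estimation keeps a knotless truth knotless", {
  ts <- toy_setup(n_time = 10, t_end = 9)
  fit <- incremental_estimate(ts$ms, ts$model, ts$map)
  expect_s3_class(fit, "dmfa_fit")
  expect_equal(sum(fit$flux_set$g_vec), 0L)
  expect_equal(fit$n_p, count_parameters(0, 1, 2, 1))
  expect_true(fit$chi2$pass)
  expect_equal(fit$flux_set$splines[[1]]$control, ts$s_true$control,
               tolerance = 1e-4)
})

test_that("accepted insertions always beat the incumbent AICc", {
  run <- small_run()
  h <- run$fit$history
  ins <- h[h$action == "knot inserted", ]
  expect_gt(nrow(ins), 0)
  expect_true(all(ins$min_aic < ins$aic_before))
  # rejected rounds keep the incumbent
  rej <- h[h$action == "no better minimum", ]
  expect_true(all(rej$min_aic >= rej$aic_before | is.na(rej$min_aic)))
  # the very first horizon cannot take a knot yet (n_p would violate the
  # AICc feasibility bound)
  expect_equal(h$action[1], "no new knot possible")
  expect_equal(h$n_time[1], 4L)
  expect_equal(h$n_p[1], 13L)
})

test_that("the incremental run spans the full horizon and recovers the fluxes", {
  run <- small_run()
  fit <- run$fit
  expect_equal(max(fit$history$n_time), 21L)
  expect_equal(fit$n_meas, 84L)
  # flux-wise integrated deviation within 5% of the reference magnitude
  times <- run$bp$protocol$times
  idx <- match(times, run$truth$times)
  est <- flux_profiles(fit, times)
  ref <- tibble::tibble(
    time = rep(times, each = 7),
    flux = rep(paste0("v", 1:7), length(times)),
    value = as.numeric(run$truth$v[, idx]))
  dev <- flux_deviation(est, ref)
  expect_true(all(dev$ratio <= 0.05))
})

test_that("fit accessors expose tidy parameter and summary tables", {
  run <- small_run()
  td <- tidy(run$fit)
  expect_true(all(c("term", "flux", "type", "estimate") %in% names(td)))
  expect_equal(sum(td$type == "initial_state"), 4L)
  expect_equal(sum(td$type == "knot"), sum(run$fit$flux_set$g_vec))
  gl <- glance(run$fit)
  expect_equal(gl$n_p, run$fit$n_p)
  expect_equal(gl$f, run$fit$f)
  aug <- augment(run$fit)
  expect_equal(nrow(aug), 84L)
  expect_equal(weighted_sse(run$ms, run$fit$y_hat), run$fit$f, tolerance = 1e-10)
  expect_equal(sum(aug$.std.resid^2), run$fit$f, tolerance = 1e-8)
  p1 <- autoplot(run$fit)
  expect_s3_class(p1, "ggplot")
  p2 <- plot_fit_outputs(run$fit)
  expect_s3_class(p2, "ggplot")
})

test_that("stored AICc is recomputable from its parts", {
  run <- small_run()
  fit <- run$fit
  expect_equal(fit$aic, aic_c(fit$f, fit$n_p, fit$n_meas), tolerance = 1e-9)
  expect_equal(fit$chi2$critical, stats::qchisq(0.95, fit$n_meas - fit$n_p))
})
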