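# Expensive shared fixtures, computed once per test run.
.cache <- new.env(parent = emptyenv())

cache_get <- function(key, value_fn) {
  if (!exists(key, envir = .cache)) assign(key, value_fn(), envir = .cache)
  get(key, envir = .cache)
}

small_truth <- function(name = "small_low_noise") {
  cache_get(paste0("truth_", name), function() {
    bp <- builtin_protocol(name)
    list(bp = bp, truth = simulate_truth(bp$model, bp$kinetics, bp$protocol))
  })
}

# the full incremental run on the near-noiseless small-scale batch study
small_run <- function() {
  cache_get("small_run", function() {
    tw <- small_truth("small_low_noise")
    ms <- sample_measurements(tw$truth, tw$bp$map, seed = 20260930)
    fit <- incremental_estimate(ms, tw$bp$model, tw$bp$map)
    list(bp = tw$bp, truth = tw$truth, ms = ms, fit = fit)
  })
}

# toy data: quadratic knotless free flux, so the model class contains the
# truth exactly
toy_setup <- function(sigma = 1e-6, n_time = 8, t_end = 7) {
  net <- toy_network()
  basis <- rational_basis(net, "v1")
  model <- dynamic_model(net, basis, "batch")
  times <- seq(0, t_end, length.out = n_time)
  s_true <- bspline(2, 0, t_end, control = c(0.5, 0.9, 0.3))
  # lsoda may probe slightly beyond t_end; clamp to the spline horizon
  rhs <- function(t, x, p) {
    tc <- min(max(t, 0), t_end)
    list(model_rhs(model, x, evaluate_spline(s_true, tc), tc))
  }
  sol <- deSolve::ode(c(5, 0.2), times, rhs, NULL, rtol = 1e-11, atol = 1e-13)
  y <- t(unname(sol[, -1]))
  map <- output_map(1:2, output_ids = c("A_ext", "X"))
  ms <- measurement_set(tibble::tibble(
    time = rep(times, each = 2),
    output = rep(c("A_ext", "X"), n_time),
    mean = as.numeric(y), sd = sigma))
  list(net = net, basis = basis, model = model, map = map, ms = ms,
       s_true = s_true, x0 = c(5, 0.2), times = times, y = y)
}
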