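#' Reference kinetics for a synthetic experiment
#'
#' A set of rate laws, one per free flux, evaluated on the extracellular
#' state vector. Saturating (Monod), constant and product-inhibition forms
#' cover both bundled case studies; any function of the state is accepted.
#'
#' @param ... functions `u_j(x)` returning one specific flux value
#'   (mmol/gDW/h) from the state vector `x`.
#' @return An object of class `reference_kinetics`.
#' @export
reference_kinetics <- function(...) {
  fns <- list(...)
  if (length(fns) == 1L && is.list(fns[[1]]) && !is.function(fns[[1]]))
    fns <- fns[[1]]
  stopifnot(all(vapply(fns, is.function, TRUE)))
  structure(fns, class = "reference_kinetics")
}

#' @export
print.reference_kinetics <- function(x, ...) {
  cat("<reference_kinetics> ", length(x), " rate law(s)\n", sep = "")
  invisible(x)
}

# rate-law builders
monod <- function(vmax, km, state) {
  force(vmax); force(km); force(state)
  function(x) vmax * x[state] / (km + x[state])
}
constant_rate <- function(v) { force(v); function(x) v }
product_inhibition <- function(vmax, ki, state) {
  force(vmax); force(ki); force(state)
  function(x) vmax / (ki + x[state])
}

#' Experiment protocol
#'
#' Everything a synthetic experiment needs besides the network: sampling
#' design, initial state, reactor mode, and the noise model.
#'
#' @param times sampling times (h), sorted.
#' @param x0 initial state vector (mmol/L; biomass gDW/L, last entry).
#' @param mode `"batch"` or `"continuous"`.
#' @param dilution,feed continuous-mode dilution profile and feed vector
#'   (see [dynamic_model()]).
#' @param noise `"low"` for near-noiseless data (sigma `1e-4`, i.e. variance
#'   `1e-8`) or `"realistic"` for the relative-plus-floor model
#'   `sigma_ij = max(rel |m_ij|, floor)`.
#' @param rel,floor parameters of the realistic noise model (defaults 0.05
#'   and 0.05 in each output's units).
#' @param sigma_low sigma used by the low-noise setting.
#' @return list of class `experiment_protocol`.
#' @export
experiment_protocol <- function(times, x0, mode = "batch", dilution = NULL,
                                feed = NULL, noise = c("low", "realistic"),
                                rel = 0.05, floor = 0.05, sigma_low = 1e-4) {
  noise <- match.arg(noise)
  stopifnot(!is.unsorted(times, strictly = TRUE))
  structure(list(times = as.numeric(times), x0 = as.numeric(x0), mode = mode,
                 dilution = dilution, feed = feed, noise = noise,
                 rel = rel, floor = floor, sigma_low = sigma_low),
            class = "experiment_protocol")
}

#' Simulate the true trajectories of a synthetic experiment
#'
#' Integrates the reduced model with `u(t) = kinetics(x(t))` using an
#' adaptive high-order method (lsoda, relative tolerance `1e-9`), returning
#' states and all `n` reaction fluxes on a dense grid that contains the
#' sampling times.
#'
#' @param model a [dynamic_model()].
#' @param kinetics a [reference_kinetics()] with one rate law per free flux.
#' @param protocol an [experiment_protocol()].
#' @param n_dense number of additional dense evaluation points.
#' @param rtol relative tolerance of the integrator.
#' @return An object of class `flux_truth`: `times`, `states`
#'   (`n_x x n_t`), `u` (`d x n_t`), `v` (`n x n_t`), plus the inputs.
#' @export
simulate_truth <- function(model, kinetics, protocol, n_dense = 201,
                           rtol = 1e-9) {
  stopifnot(inherits(model, "dynamic_model"),
            inherits(kinetics, "reference_kinetics"),
            inherits(protocol, "experiment_protocol"))
  if (length(kinetics) != model$basis$d)
    stop("need one rate law per free flux")
  st <- protocol$times
  tgrid <- sort(unique(c(st, seq(st[1], st[length(st)], length.out = n_dense))))
  u_of_x <- function(x) vapply(kinetics, function(f) f(x), 0)
  rhs <- function(t, x, p) {
    u <- u_of_x(x)
    list(model_rhs(model, x, u, t))
  }
  sol <- deSolve::ode(y = protocol$x0, times = tgrid, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = rtol / 100)
  if (attr(sol, "istate")[1] < 0) stop("integration of the reference model failed")
  states <- t(unname(sol[, -1, drop = FALSE]))
  u <- apply(states, 2, u_of_x)
  if (is.null(dim(u))) u <- matrix(u, nrow = 1)
  v <- model$basis$K %*% u
  structure(list(times = tgrid, states = states, u = u, v = v,
                 model = model, kinetics = kinetics, protocol = protocol),
            class = "flux_truth")
}

#' Sample noisy measurements from simulated truth
#'
#' Draws `m_ij = y_j(t_i) + e_ij` with `e_ij ~ N(0, sigma_ij^2)` at the
#' protocol's sampling times, for the outputs selected by `map`. The sigma
#' table is emitted alongside in the returned measurement set. Deterministic
#' under `seed`.
#'
#' @param truth a [simulate_truth()] result.
#' @param map an [output_map()].
#' @param seed integer RNG seed.
#' @param output_ids optional output labels.
#' @return a [measurement_set()] (columns `time`, `output`, `mean`, `sd`,
#'   plus the noiseless `truth` column for reference).
#' @export
sample_measurements <- function(truth, map, seed, output_ids = NULL) {
  stopifnot(inherits(truth, "flux_truth"), inherits(map, "output_map"))
  protocol <- truth$protocol
  st <- protocol$times
  idx <- match(st, truth$times)
  if (anyNA(idx)) stop("sampling times missing from the simulated grid")
  y <- evaluate_outputs(map, truth$model$basis,
                        truth$states[, idx, drop = FALSE],
                        truth$u[, idx, drop = FALSE])
  y <- matrix(y, nrow = map$n_out)
  ids <- output_ids %||% map$output_ids
  if (protocol$noise == "low") {
    sig <- matrix(protocol$sigma_low, nrow(y), ncol(y))
  } else {
    sig <- pmax(protocol$rel * abs(y), protocol$floor)
  }
  set.seed(seed)
  m <- y + matrix(stats::rnorm(length(y), sd = as.numeric(sig)),
                  nrow(y), ncol(y))
  measurement_set(tibble::tibble(
    time = rep(st, each = nrow(y)),
    output = rep(ids, length(st)),
    mean = as.numeric(m),
    sd = as.numeric(sig),
    truth = as.numeric(y)))
}

# ---- bundled synthetic case-study networks ---------------------------------

#' Synthetic small-scale batch network
#'
#' A 7-reaction network with 4 internal metabolites, 3 extracellular
#' metabolites (A, E, F) and biomass, built in code. It is a synthetic
#' reconstruction (the published network of this layout is available only as
#' a figure): it reproduces every stated structural fact - degrees of
#' freedom `d = 3`, valid free-flux sets \{1,4,5\} and \{3,6,7\}, fluxes 3
#' and 6 the only reversible reactions - and all irreversible fluxes stay
#' nonnegative along the bundled reference kinetics. A is taken up and
#' processed through two internal branches; F is an excreted product whose
#' accumulation inhibits its own formation; biomass draws on both branches.
#'
#' @return a [metabolic_network()].
#' @export
small_network <- function() {
  # columns v1..v7; internal metabolites M1..M4; a = b = 2 in the biomass draw
  a <- 2; b <- 2
  S <- rbind(
    M1    = c( 1, -1,  0,  0,  0,  0,  0),
    M2    = c( 0,  1, -1,  0,  0,  0, -a),
    M3    = c( 0,  0,  1,  0, -1,  1,  0),
    M4    = c( 0,  0,  0,  1,  0, -1, -b),
    A_ext = c(-1,  0,  0,  0,  0,  0,  0),
    E_ext = c( 0,  0,  0, -1,  0,  0,  0),
    F_ext = c( 0,  0,  0,  0,  1,  0,  0),
    X     = c( 0,  0,  0,  0,  0,  0,  1))
  metabolic_network(
    S,
    metabolite_ids = rownames(S),
    reaction_ids = paste0("v", 1:7),
    roles = c(rep("internal", 4), rep("external", 3), "biomass"),
    reversible = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE))
}

#' Synthetic medium-scale continuous-culture network
#'
#' A 68-reaction network with 62 internal metabolites and 10 extracellular
#' species (glucose, glycerol, ammonia, sulphate, citrate, 1,3-propanediol,
#' acetate, carbon dioxide, oxygen, biomass), built in code as a synthetic
#' stand-in with the published dimensions: `d = 6` free fluxes chosen as the
#' exchanges 62 (glycerol), 63 (glucose), 65 (ammonia), 66 (citrate,
#' reversible), 67 (acetate) and 68 (oxygen), and 44 irreversible reactions.
#' Internally it consists of four linear pathways (carbon, respiration,
#' nitrogen, sulphur) feeding a lumped biomass reaction; 1,3-propanediol,
#' carbon dioxide and acetate are products, sulphate uptake balances the
#' biomass draw. Acetate exchange is oriented as production (its reference
#' rate law is product-inhibited and the initial acetate pool is empty).
#'
#' @return a [metabolic_network()].
#' @export
medium_network <- function() {
  n_int <- 62L; n_rxn <- 68L
  met_int <- sprintf("N%02d", 1:n_int)
  met_ext <- c("Gluc", "Glyc", "NH3", "SO4", "Cit", "PDO", "Ac", "CO2", "O2")
  mets <- c(met_int, met_ext, "X")
  S <- matrix(0, length(mets), n_rxn, dimnames = list(mets, paste0("v", 1:n_rxn)))
  # internal chain edges: four linear pathways
  chains <- list(A = 1:38, B = 39:44, C = 45:52, D = 53:62)
  r <- 0L
  for (ch in chains) {
    for (i in seq_len(length(ch) - 1L)) {
      r <- r + 1L
      S[ch[i], r] <- -1; S[ch[i + 1], r] <- 1
    }
  }
  stopifnot(r == 58L)
  # v59 biomass: draws the four pathway termini (carbon, respiration,
  # nitrogen, sulphur); coefficients keep every irreversible flux
  # nonnegative along the bundled reference kinetics
  S[38, 59] <- -1; S[44, 59] <- -0.5; S[52, 59] <- -1; S[62, 59] <- -0.5
  S["X", 59] <- 1
  # exchange reactions
  S[35, 60] <- -1; S["PDO", 60] <- 1    # 1,3-propanediol production
  S[42, 61] <- -1; S["CO2", 61] <- 1    # carbon-dioxide production
  S[30, 62] <- 1;  S["Glyc", 62] <- -1  # glycerol uptake
  S[1, 63] <- 1;   S["Gluc", 63] <- -1  # glucose uptake
  S[53, 64] <- 1;  S["SO4", 64] <- -1   # sulphate uptake
  S[45, 65] <- 1;  S["NH3", 65] <- -1   # ammonia uptake
  S[37, 66] <- 1;  S["Cit", 66] <- -1   # citrate exchange (reversible)
  S[36, 67] <- -1; S["Ac", 67] <- 1     # acetate production
  S[39, 68] <- 1;  S["O2", 68] <- -1    # oxygen uptake
  reversible <- rep(FALSE, n_rxn)
  reversible[36:58] <- TRUE   # 23 reversible interconversions
  reversible[66] <- TRUE      # citrate exchange
  metabolic_network(
    S, metabolite_ids = mets, reaction_ids = paste0("v", 1:n_rxn),
    roles = c(rep("internal", n_int), rep("external", 9), "biomass"),
    reversible = reversible)
}

#' Built-in synthetic experiment setups
#'
#' Fully populated (network, basis, kinetics, protocol, model, output map)
#' bundles for the three study conditions: `small_low_noise` and
#' `small_realistic` are a 20 h batch experiment on the small network with
#' free fluxes \{1,4,5\}, Monod/inhibition reference kinetics and all 4
#' states sampled at 21 equidistant times (84 measurements); `medium` is a
#' 10 h dilution-controlled continuous experiment on the 68-flux network
#' with free fluxes \{62,63,65,66,67,68\}, 8 concentrations and 2 off-gas
#' fluxes sampled at 31 equidistant times (310 measurements), glucose-only
#' feed at 20 mmol/L.
#'
#' The default dilution schedule of the medium setup is a piecewise-constant
#' stand-in (0, 0.5, 0.2, 0.8 1/h switching at quarter-horizon marks) and
#' can be overridden via `dilution`.
#'
#' @param name one of `"small_low_noise"`, `"small_realistic"`, `"medium"`.
#' @param dilution optional replacement dilution profile for the medium
#'   setup (data frame with `time`, `D`).
#' @return list with `net`, `basis`, `kinetics`, `protocol`, `model`, `map`.
#' @export
builtin_protocol <- function(name = c("small_low_noise", "small_realistic",
                                      "medium"), dilution = NULL) {
  name <- match.arg(name)
  if (name %in% c("small_low_noise", "small_realistic")) {
    net <- small_network()
    basis <- rational_basis(net, c("v1", "v4", "v5"))
    kinetics <- reference_kinetics(
      monod(1, 1.5, 1),              # u1: A uptake, saturating in A_ext
      monod(0.2, 3, 2),              # u4: E uptake, saturating in E_ext
      product_inhibition(1, 1, 3))   # u5: F formation, inhibited by F_ext
    protocol <- experiment_protocol(
      times = seq(0, 20, length.out = 21),
      x0 = c(10, 15, 0, 0.1),
      mode = "batch",
      noise = if (name == "small_low_noise") "low" else "realistic")
    model <- dynamic_model(net, basis, mode = "batch")
    map <- output_map(state_idx = 1:4,
                      output_ids = c("A_ext", "E_ext", "F_ext", "X"))
  } else {
    net <- medium_network()
    basis <- rational_basis(net, paste0("v", c(62, 63, 65, 66, 67, 68)))
    kinetics <- reference_kinetics(
      constant_rate(0.0995),              # u62: glycerol uptake
      monod(0.5605, 9.89, 1),             # u63: glucose uptake
      monod(0.122, 0.1919, 3),            # u65: ammonia uptake
      monod(0.0207, 5.575, 5),            # u66: citrate exchange
      product_inhibition(0.8834, 10, 7),  # u67: acetate production
      monod(0.438, 9.706, 9))             # u68: oxygen uptake
    if (is.null(dilution))
      dilution <- data.frame(time = c(0, 2.5, 5, 7.5), D = c(0, 0.5, 0.2, 0.8))
    feed <- c(20, rep(0, 9))
    protocol <- experiment_protocol(
      times = seq(0, 10, length.out = 31),
      x0 = c(100, 53.15, 38.45, 62.61, 0, 0, 0, 6.78, 100, 2.14),
      mode = "continuous", dilution = dilution, feed = feed,
      noise = "realistic")
    model <- dynamic_model(net, basis, mode = "continuous",
                           dilution = dilution, feed = feed)
    map <- output_map(state_idx = c(1:7, 10), flux_idx = c(68, 61),
                      flux_sign = c(1, 1),
                      output_ids = c("Gluc", "Glyc", "NH3", "SO4", "Cit",
                                     "PDO", "Ac", "X", "qO2", "qCO2"))
  }
  list(net = net, basis = basis, kinetics = kinetics, protocol = protocol,
       model = model, map = map)
}
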