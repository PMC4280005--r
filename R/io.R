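#' Read a metabolic network from TSV files
#'
#' The network file has one header row of reaction ids and one row per
#' metabolite (first column the metabolite id, then the stoichiometric
#' coefficients, exact decimals). The annotation file has columns
#' `metabolite_id`, `role` and `reaction_id`, `reversible` (0/1); metabolite
#' and reaction annotation rows may be mixed, rows with an empty id in one
#' of the pairs are ignored for that pair.
#'
#' @param network_file path to the stoichiometry TSV.
#' @param annotation_file path to the roles/reversibility TSV.
#' @return a [metabolic_network()].
#' @export
read_network <- function(network_file, annotation_file) {
  tab <- utils::read.delim(network_file, check.names = FALSE,
                           stringsAsFactors = FALSE)
  met_ids <- as.character(tab[[1]])
  S <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(S) <- "double"
  rxn_ids <- colnames(tab)[-1]
  ann <- utils::read.delim(annotation_file, stringsAsFactors = FALSE)
  mrow <- ann[!is.na(ann$metabolite_id) & nzchar(ann$metabolite_id), ]
  rrow <- ann[!is.na(ann$reaction_id) & nzchar(ann$reaction_id), ]
  roles <- mrow$role[match(met_ids, mrow$metabolite_id)]
  if (anyNA(roles)) stop("missing role for metabolite(s): ",
                         paste(met_ids[is.na(roles)], collapse = ", "))
  rev <- rrow$reversible[match(rxn_ids, rrow$reaction_id)]
  if (anyNA(rev)) stop("missing reversibility for reaction(s): ",
                       paste(rxn_ids[is.na(rev)], collapse = ", "))
  metabolic_network(S, met_ids, rxn_ids, roles, as.logical(as.integer(rev)))
}

#' Write a metabolic network to TSV files
#'
#' @param net a [metabolic_network()].
#' @param network_file,annotation_file output paths.
#' @return `net`, invisibly.
#' @export
write_network <- function(net, network_file, annotation_file) {
  stopifnot(inherits(net, "metabolic_network"))
  Sc <- net$S
  tab <- data.frame(metabolite_id = net$metabolite_ids,
                    matrix(sprintf("%.17g", Sc), nrow(Sc), ncol(Sc),
                           dimnames = dimnames(Sc)),
                    check.names = FALSE)
  utils::write.table(tab, network_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  nmax <- max(length(net$metabolite_ids), length(net$reaction_ids))
  pad <- function(x, fill = "") c(x, rep(fill, nmax - length(x)))
  ann <- data.frame(
    metabolite_id = pad(net$metabolite_ids),
    role = pad(net$roles),
    reaction_id = pad(net$reaction_ids),
    reversible = pad(as.integer(net$reversible), NA))
  utils::write.table(ann, annotation_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(net)
}

#' Read measurements from CSV
#'
#' Expects columns `time`, `output_id` (or `output`), `mean`, `sd`.
#'
#' @param file CSV path.
#' @return a [measurement_set()].
#' @export
read_measurements <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if ("output_id" %in% names(df) && !"output" %in% names(df))
    names(df)[names(df) == "output_id"] <- "output"
  for (col in c("time", "output", "mean", "sd"))
    if (!col %in% names(df)) stop("measurements file lacks column '", col, "'")
  for (col in c("time", "mean", "sd")) df[[col]] <- as.double(df[[col]])
  measurement_set(df)
}

#' Write measurements to CSV
#'
#' Numeric columns are written with 17 significant digits so the reader
#' recovers bitwise-identical doubles.
#'
#' @param ms a [measurement_set()].
#' @param file CSV path.
#' @return `ms`, invisibly.
#' @export
write_measurements <- function(ms, file) {
  df <- as.data.frame(ms)
  names(df)[names(df) == "output"] <- "output_id"
  utils::write.csv(fmt_num_cols(df), file, row.names = FALSE, quote = FALSE)
  invisible(ms)
}

# full-precision decimal text for exact numeric round trips
fmt_num_cols <- function(df) {
  for (i in seq_along(df))
    if (is.double(df[[i]])) df[[i]] <- sprintf("%.17g", df[[i]])
  df
}

#' Serialize a fit to JSON
#'
#' Stores the knot structure, windows, control points, initial state, basis,
#' goodness-of-fit quantities and the iteration history at full precision.
#'
#' @param fit a `dmfa_fit`.
#' @param file JSON path.
#' @return `fit`, invisibly.
#' @export
write_fit <- function(fit, file) {
  stopifnot(inherits(fit, "dmfa_fit"))
  obj <- list(
    splines = lapply(fit$flux_set$splines, spline_to_list),
    flux_ids = fit$flux_set$flux_ids,
    x0 = fit$x0_hat, K = fit$K_hat, angles = fit$angles,
    f = fit$f, n_p = fit$n_p, n_meas = fit$n_meas, aic = fit$aic,
    chi2 = fit$chi2, history = fit$history,
    optimal_K = fit$control$optimal_K)
  jsonlite::write_json(obj, file, digits = I(17), auto_unbox = TRUE,
                       na = "null")
  invisible(fit)
}

#' Read a serialized fit
#'
#' Restores the parts of a `dmfa_fit` needed for reporting and bootstrap
#' band evaluation (spline profiles, basis, goodness-of-fit, history).
#'
#' @param file JSON path written by [write_fit()].
#' @return list of class `dmfa_fit_summary`.
#' @export
read_fit <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  raw <- jsonlite::read_json(file, simplifyVector = FALSE)
  num_or_na <- function(x)
    vapply(x, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 0)
  splines <- lapply(raw$splines, function(s)
    spline_from_list(list(
      degree = s$degree, t0 = s$t0, t_end = s$t_end,
      knots = unlist(s$knots) %||% numeric(),
      control = unlist(s$control),
      windows_lo = num_or_na(s$windows_lo),
      windows_hi = num_or_na(s$windows_hi))))
  K <- do.call(rbind, lapply(raw$K, unlist))
  structure(list(
    flux_set = free_flux_set(splines, unlist(raw$flux_ids)),
    x0_hat = unlist(raw$x0), K_hat = K, angles = unlist(raw$angles),
    f = obj$f, n_p = obj$n_p, n_meas = obj$n_meas, aic = obj$aic,
    chi2 = obj$chi2, history = tibble::as_tibble(obj$history)),
    class = "dmfa_fit_summary")
}

#' Write bootstrap bands to CSV
#'
#' @param boot a `dmfa_bootstrap`.
#' @param file CSV path (columns `time`, `flux_id`, `lower`, `point`,
#'   `upper`).
#' @return `boot`, invisibly.
#' @export
write_bands <- function(boot, file) {
  df <- as.data.frame(boot$bands)
  names(df)[names(df) == "flux"] <- "flux_id"
  utils::write.csv(fmt_num_cols(df), file, row.names = FALSE, quote = FALSE)
  invisible(boot)
}

#' Read or validate a run configuration
#'
#' YAML schema with known keys only: `k_mode` (rational / orthonormal /
#' optimal), `free_fluxes`, `degree`, solver settings (`max_iter`,
#' `rel_tol`, `penalty`), `level`, bootstrap settings (`n_replicates`,
#' `seed`), reactor block (`mode`, `dilution_file`, `feed`), and paths.
#' Unknown keys are rejected so typos fail loudly.
#'
#' @param file YAML path.
#' @return named list of class `run_config`.
#' @export
read_run_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  known <- c("k_mode", "free_fluxes", "degree", "max_iter", "rel_tol",
             "penalty", "level", "n_replicates", "seed", "mode",
             "dilution_file", "feed", "network", "annotation",
             "measurements", "out_dir", "x0_guess")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  if (!is.null(cfg$k_mode) &&
      !cfg$k_mode %in% c("rational", "orthonormal", "optimal"))
    stop("k_mode must be rational, orthonormal or optimal")
  structure(cfg, class = "run_config")
}

#' Write a run configuration
#'
#' @param cfg named list (validated as in [read_run_config()]).
#' @param file YAML path.
#' @return `cfg`, invisibly.
#' @export
write_run_config <- function(cfg, file) {
  yaml::write_yaml(unclass(cfg), file)
  invisible(cfg)
}

#' Deviation of estimated from reference flux profiles
#'
#' The summary statistic used to compare estimates against the generating
#' kinetics: the trapezoid-rule integral of the absolute deviation
#' `int |v_est - v_ref| dt` per flux, together with the reference magnitude
#' `int |v_ref| dt` and their ratio.
#'
#' @param est tibble with `time`, `flux`, `value` (e.g. [flux_profiles()]).
#' @param ref tibble with the same columns for the reference profiles on the
#'   same time grid.
#' @return tibble with one row per flux: `deviation`, `magnitude`, `ratio`,
#'   plus a `total` attribute (summed deviation).
#' @export
flux_deviation <- function(est, ref) {
  trap <- function(t, y) sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  fluxes <- unique(est$flux)
  out <- lapply(fluxes, function(fl) {
    e <- est[est$flux == fl, ]
    r <- ref[ref$flux == fl, ]
    e <- e[order(e$time), ]; r <- r[order(r$time), ]
    if (!isTRUE(all.equal(e$time, r$time)))
      stop("estimate and reference grids differ for flux ", fl)
    dev <- trap(e$time, abs(e$value - r$value))
    mag <- trap(r$time, abs(r$value))
    tibble::tibble(flux = fl, deviation = dev, magnitude = mag,
                   ratio = dev / max(mag, .Machine$double.eps))
  })
  res <- dplyr::bind_rows(out)
  attr(res, "total") <- sum(res$deviation)
  res
}
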