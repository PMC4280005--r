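#' Construct a metabolic network
#'
#' Builds the stoichiometric description used throughout the package: the full
#' matrix `S` (one row per metabolite, one column per reaction), its partition
#' into intracellular rows `S_int`, extracellular rows `S_ext` and the biomass
#' pseudo-metabolite row `s_bio`, the stacked extracellular system
#' `S_e = rbind(S_ext, s_bio)`, and the 0/1 irreversibility selector `I_irr`
#' that extracts the irreversible fluxes from the full flux vector.
#'
#' Under the pseudo-steady-state assumption the intracellular pools satisfy
#' `S_int %*% v = 0`, so the admissible flux space is the null space of
#' `S_int`; the dynamic model only ever sees `S_e` and a null-space basis.
#'
#' @param S numeric matrix of stoichiometric coefficients, metabolites in rows
#'   (in the order of `metabolite_ids`), reactions in columns.
#' @param metabolite_ids character vector of metabolite labels.
#' @param reaction_ids character vector of reaction labels.
#' @param roles character vector, one of `"internal"`, `"external"`,
#'   `"biomass"` per metabolite; exactly one metabolite must be the biomass
#'   pseudo-metabolite.
#' @param reversible logical vector, one entry per reaction.
#' @return An object of class `metabolic_network` with components `S`,
#'   `S_int`, `S_ext`, `s_bio`, `S_e`, `I_irr`, `roles`, `reversible`,
#'   `reaction_ids`, `metabolite_ids` and the counts `n`, `m_int`, `m_ext`,
#'   `n_irr`, `n_rev`.
#' @export
metabolic_network <- function(S, metabolite_ids, reaction_ids, roles, reversible) {
  S <- as.matrix(S)
  if (length(metabolite_ids) != nrow(S))
    stop("number of metabolite ids does not match rows of S")
  if (length(reaction_ids) != ncol(S))
    stop("number of reaction ids does not match columns of S")
  if (anyDuplicated(metabolite_ids)) stop("duplicate metabolite ids")
  if (anyDuplicated(reaction_ids)) stop("duplicate reaction ids")
  if (length(roles) != nrow(S)) stop("one role per metabolite required")
  if (!all(roles %in% c("internal", "external", "biomass")))
    stop("roles must be 'internal', 'external' or 'biomass'")
  if (sum(roles == "biomass") == 0L) stop("no biomass pseudo-metabolite")
  if (sum(roles == "biomass") > 1L) stop("more than one biomass pseudo-metabolite")
  if (length(reversible) != ncol(S)) stop("one reversibility flag per reaction required")
  reversible <- as.logical(reversible)

  dimnames(S) <- list(metabolite_ids, reaction_ids)
  int <- roles == "internal"; ext <- roles == "external"; bio <- roles == "biomass"
  S_int <- S[int, , drop = FALSE]
  S_ext <- S[ext, , drop = FALSE]
  s_bio <- S[bio, , drop = FALSE]
  irr <- which(!reversible)
  I_irr <- matrix(0, length(irr), ncol(S),
                  dimnames = list(reaction_ids[irr], reaction_ids))
  for (i in seq_along(irr)) I_irr[i, irr[i]] <- 1

  structure(list(
    S = S, S_int = S_int, S_ext = S_ext, s_bio = s_bio,
    S_e = rbind(S_ext, s_bio), I_irr = I_irr,
    metabolite_ids = metabolite_ids, reaction_ids = reaction_ids,
    roles = roles, reversible = reversible,
    n = ncol(S), m_int = sum(int), m_ext = sum(ext),
    n_irr = length(irr), n_rev = sum(reversible)
  ), class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", x$n, " reactions, ",
      x$m_int, " internal + ", x$m_ext, " external metabolites + biomass\n",
      "  irreversible: ", x$n_irr, ", reversible: ", x$n_rev,
      ", degrees of freedom: ", degrees_of_freedom(x, warn = FALSE), "\n", sep = "")
  invisible(x)
}

#' Degrees of freedom of the pseudo-steady-state flux space
#'
#' The number of free fluxes `d = n - rank(S_int)`. The rank is computed from
#' the singular values of `S_int`; values below `tol` times the largest
#' singular value count as zero, a safe threshold for the well-separated
#' spectra of integer stoichiometries.
#'
#' @param net a [metabolic_network()].
#' @param tol relative singular-value threshold (default `1e-10`).
#' @param warn warn when the system is fully determined (`d = 0`).
#' @return integer `d >= 0`.
#' @export
degrees_of_freedom <- function(net, tol = 1e-10, warn = TRUE) {
  stopifnot(inherits(net, "metabolic_network"))
  if (nrow(net$S_int) == 0L) stop("S_int is empty")
  sv <- svd(net$S_int, nu = 0, nv = 0)$d
  r <- sum(sv > tol * max(sv, 1e-300))
  d <- net$n - r
  if (d == 0L && warn) warning("fully determined system; no free fluxes")
  d
}

#' Rational null-space basis from a free-flux selection
#'
#' Splits the fluxes into a user-chosen set of `d` free fluxes and `n - d`
#' dependent fluxes and solves the dependent subsystem, which is the reduced
#' row echelon construction: the rows of `K` at the free fluxes form the
#' identity, so the free fluxes are actual network reactions and retain their
#' biological meaning.
#'
#' @param net a [metabolic_network()].
#' @param free_fluxes reaction ids (character) or column indices (numeric) of
#'   the `d` free fluxes.
#' @return A `null_space_basis` object with components `K` (n x d), `d`,
#'   `mode = "rational"` and `free_flux_ids`.
#' @export
rational_basis <- function(net, free_fluxes) {
  stopifnot(inherits(net, "metabolic_network"))
  d <- degrees_of_freedom(net, warn = FALSE)
  idx <- if (is.character(free_fluxes)) match(free_fluxes, net$reaction_ids) else as.integer(free_fluxes)
  if (anyNA(idx) || any(idx < 1L | idx > net$n)) stop("unknown free flux")
  if (length(idx) != d)
    stop("need exactly d = ", d, " free fluxes, got ", length(idx))
  dep <- setdiff(seq_len(net$n), idx)
  K <- matrix(0, net$n, d, dimnames = list(net$reaction_ids, net$reaction_ids[idx]))
  K[idx, ] <- diag(d)
  if (length(dep)) {
    A <- net$S_int[, dep, drop = FALSE]
    B <- net$S_int[, idx, drop = FALSE]
    X <- tryCatch(-solve(qr(A, LAPACK = TRUE), B), error = function(e) NULL)
    if (is.null(X) || qr(A)$rank < length(dep))
      stop("invalid free-flux set: dependent subsystem is singular")
    K[dep, ] <- X
  }
  new_basis(K, mode = "rational", free_flux_ids = net$reaction_ids[idx])
}

#' Orthonormal null-space basis of the intracellular stoichiometry
#'
#' Columns are the right singular vectors of `S_int` belonging to (numerically)
#' zero singular values, so `t(K) %*% K = I` exactly up to round-off. For
#' reproducibility each column's sign is fixed so that its largest-magnitude
#' entry is positive.
#'
#' @inheritParams degrees_of_freedom
#' @return A `null_space_basis` with `mode = "orthonormal"`.
#' @export
orthonormal_basis <- function(net, tol = 1e-10) {
  stopifnot(inherits(net, "metabolic_network"))
  d <- degrees_of_freedom(net, tol = tol, warn = FALSE)
  if (d < 1L) stop("no free fluxes; null space is trivial")
  sv <- svd(net$S_int, nv = net$n)
  K <- sv$v[, (net$n - d + 1L):net$n, drop = FALSE]
  for (j in seq_len(ncol(K))) {
    i <- which.max(abs(K[, j]))
    if (K[i, j] < 0) K[, j] <- -K[, j]
  }
  rownames(K) <- net$reaction_ids
  new_basis(K, mode = "orthonormal")
}

new_basis <- function(K, mode, free_flux_ids = NULL) {
  structure(list(K = K, d = ncol(K), mode = mode, free_flux_ids = free_flux_ids),
            class = "null_space_basis")
}

#' @export
print.null_space_basis <- function(x, ...) {
  cat("<null_space_basis> mode ", x$mode, ", ", nrow(x$K), " x ", x$d, sep = "")
  if (!is.null(x$free_flux_ids))
    cat("  free fluxes: ", paste(x$free_flux_ids, collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' Validate a candidate null-space basis
#'
#' Checks the two constraint blocks a basis must satisfy: `S_int %*% K = 0`
#' (null space) and, when requested, `t(K) %*% K - I = 0` (orthonormality).
#' Also reports column rank so a rank-deficient `K` fails even if both
#' residuals are small.
#'
#' @param net a [metabolic_network()].
#' @param K numeric matrix of shape `(n, d)`.
#' @param orthonormal_required also require `t(K) K = I`.
#' @param tol_null,tol_orth pass tolerances for the two residual blocks.
#' @return list with `ok`, `null_residual`, `orth_residual`, `full_rank`.
#' @export
check_basis <- function(net, K, orthonormal_required = FALSE,
                        tol_null = 1e-10, tol_orth = 1e-8) {
  stopifnot(inherits(net, "metabolic_network"))
  K <- as.matrix(K)
  if (nrow(K) != net$n) stop("K must have n = ", net$n, " rows")
  scale <- max(1, max(abs(net$S_int) %*% abs(K)))
  null_res <- max(abs(net$S_int %*% K)) / scale
  orth_res <- max(abs(crossprod(K) - diag(ncol(K))))
  full_rank <- qr(K)$rank == ncol(K)
  ok <- null_res <= tol_null && full_rank &&
    (!orthonormal_required || orth_res <= tol_orth)
  list(ok = ok, null_residual = null_res, orth_residual = orth_res,
       full_rank = full_rank)
}
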