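# Independent reference computations used across the suite.

# exact rank of an integer matrix by fraction-free (Bareiss) elimination;
# all intermediate values stay integers, so double arithmetic is exact for
# the small stoichiometries used in tests
bareiss_rank <- function(A) {
  A <- as.matrix(A)
  n <- nrow(A); m <- ncol(A)
  prev <- 1
  r <- 0L
  row <- 1L
  for (col in seq_len(m)) {
    piv <- which(abs(A[row:n, col]) > 0.5)
    if (!length(piv)) next
    piv <- row + piv[1] - 1L
    if (piv != row) { tmp <- A[row, ]; A[row, ] <- A[piv, ]; A[piv, ] <- tmp }
    for (i in seq_len(n)) {
      if (i == row) next
      A[i, ] <- (A[i, ] * A[row, col] - A[i, col] * A[row, ]) / prev
    }
    prev <- A[row, col]
    r <- r + 1L
    row <- row + 1L
    if (row > n) break
  }
  r
}

# principal angles between the column spans of two bases; computed from the
# sines (projection residuals), which stay accurate for very small angles
principal_angles <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  resid <- qb - qa %*% crossprod(qa, qb)
  asin(pmin(svd(resid)$d, 1))
}

# chi-square quantile by inverting the regularized incomplete gamma function
chisq_quantile_oracle <- function(p, dof) {
  stats::uniroot(function(x) stats::pgamma(x / 2, dof / 2) - p,
                 c(1e-12, 1e4), tol = 1e-12)$root
}

# plain double-loop weighted SSE
naive_sse <- function(m, sd, pred) {
  f <- 0
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m)))
      f <- f + ((pred[i, j] - m[i, j]) / sd[i, j])^2
  f
}

# smallest l with l * n_out >= 3 d + m_ext + 3, by linear scan
min_l_oracle <- function(n_out, d, m_ext) {
  l <- 1L
  while (l * n_out < 3 * d + m_ext + 3) l <- l + 1L
  l
}

# random integer stoichiometry wrapped in a network (biomass + one external
# row appended so the constructor invariants hold; they do not affect rank)
random_int_network <- function(m_int, n, density = 0.5) {
  S_int <- matrix(sample(c(-2:-1, 1:2), m_int * n, replace = TRUE) *
                    (stats::runif(m_int * n) < density), m_int, n)
  S <- rbind(S_int, matrix(0, 2, n))
  metabolic_network(S, c(paste0("M", seq_len(m_int)), "EXT", "BIO"),
                    paste0("v", seq_len(n)),
                    c(rep("internal", m_int), "external", "biomass"),
                    rep(FALSE, n))
}

# toy 2-state network: substrate uptake feeding growth; d = 1
toy_network <- function() {
  S <- rbind(M1 = c(1, -2), A_ext = c(-1, 0), X = c(0, 1))
  metabolic_network(S, rownames(S), c("v1", "v2"),
                    c("internal", "external", "biomass"), c(FALSE, FALSE))
}
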