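# Independent oracles and small simulators used across the suite.
# These deliberately avoid the package's own computational paths:
# the REML oracle uses dense matrix algebra over a lambda grid, the
# q-value oracle a literal min-over-tail double loop.

# REML log-likelihood at one lambda via dense V = I + lambda ZZ'.
dense_reml_loglik <- function(lambda, y, x, g) {
  g <- factor(g)
  N <- length(y)
  X <- cbind(1, x)
  Z <- stats::model.matrix(~ g - 1)
  V <- diag(N) + lambda * tcrossprod(Z)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  s2 <- as.numeric(t(r) %*% Vi %*% r) / (N - 2)
  ll <- -0.5 * ((N - 2) * (log(2 * pi * s2) + 1) +
                determinant(V, logarithm = TRUE)$modulus +
                determinant(XtViX, logarithm = TRUE)$modulus)
  list(loglik = as.numeric(ll), b0 = beta[1], b1 = beta[2], sigma_e2 = s2)
}

# Brute-force profile over a dense lambda grid (includes the OLS limit 0).
dense_reml_grid <- function(y, x, g,
                            grid = c(0, 10^seq(-8, 6, length.out = 200))) {
  lls <- vapply(grid, function(l) dense_reml_loglik(l, y, x, g)$loglik,
                numeric(1))
  i <- which.max(lls)
  c(dense_reml_loglik(grid[i], y, x, g), list(lambda = grid[i],
                                              loglik_max = lls[i]))
}

# Literal Storey/BH step-up: min over the tail, scanned element-wise.
brute_qvalues <- function(p, pi0 = 1) {
  m <- length(p)
  o <- order(p)
  ranks <- match(seq_len(m), o)  # rank of each p in ascending order
  sapply(seq_len(m), function(i) {
    tail_js <- which(p[o] >= p[i])
    min(1, pi0 * min(m * p[o][tail_js] / tail_js))
  })
}

# Plain mixed-data simulator independent of the package generator.
sim_mixed <- function(seed, n_groups, per_group, b0 = 0, b1 = 0,
                      sigma_B = 0.4, sigma_e = 0.5) {
  set.seed(seed)
  g <- rep(seq_len(n_groups), each = per_group)
  x <- stats::rnorm(length(g))
  y <- b0 + b1 * x + stats::rnorm(n_groups, 0, sigma_B)[g] +
    stats::rnorm(length(g), 0, sigma_e)
  list(y = y, x = x, g = g)
}

# Minimal carotenoid_table constructor for hand-built fixtures.
make_ctab <- function(conc, below = NULL) {
  if (is.null(below)) below <- matrix(FALSE, nrow(conc), ncol(conc),
                                      dimnames = dimnames(conc))
  structure(list(concentrations = conc, below_lod = below,
                 analytes = colnames(conc)),
            class = "carotenoid_table")
}
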