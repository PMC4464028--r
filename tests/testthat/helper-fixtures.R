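# Random-but-reproducible CSC parameter sets for property tests. Rates are
# drawn on scales where the invasion threshold stays inside (0, 1).
randomCscParameters <- function(seed, gamma_PC = NULL) {
  set.seed(seed)
  cscParameters(
    P_sy = runif(1),
    omega_CSC = runif(1, 0.5, 1.5),
    omega_PC = runif(1, 0.3, 1.2),
    eta_1 = runif(1, 0.005, 0.05),
    eta_2 = runif(1, 0.05, 0.4),
    eta_3 = runif(1, 0.1, 0.5),
    gamma_PC = if (is.null(gamma_PC)) runif(1, 0, 0.05) else gamma_PC,
    delta_1 = runif(1, 0.005, 0.05),
    delta_2 = runif(1, 0.01, 0.1),
    delta_3 = runif(1, 0.005, 0.05),
    delta_4 = runif(1, 0.05, 0.5),
    h_CSC = runif(1, 5e-5, 5e-4),
    h_PC = runif(1, 5e-5, 5e-4))
}

randomCscState <- function(seed) {
  set.seed(seed)
  stats::setNames(runif(5, 0, 1e5),
                  c("N_CSC", "N_PC1", "N_PC2", "N_TC", "N_DC"))
}

# Independent finite-difference oracle for Jacobian checks (central
# differences; never calls the analytic Jacobian).
fdOracle <- function(f, x, h = 1e-6) {
  n <- length(x)
  J <- matrix(0, length(f(x)), n)
  for (i in seq_len(n)) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    J[, i] <- (f(xp) - f(xm)) / (2 * hi)
  }
  J
}

# Partial rank correlation via inversion of the (k+1)x(k+1) Spearman
# correlation matrix: entry -C_jy / sqrt(C_jj * C_yy) of the inverse.
# Independent oracle for the residual-regression implementation.
prccMatrixOracle <- function(X, y) {
  R <- cbind(apply(X, 2, rank), rank(y))
  C <- solve(stats::cor(R))
  k <- ncol(X)
  vapply(seq_len(k), function(j) {
    -C[j, k + 1] / sqrt(C[j, j] * C[k + 1, k + 1])
  }, numeric(1))
}

shortGrid <- function(t_end = 50, points = 26) timeGrid(0, t_end, points = points)
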