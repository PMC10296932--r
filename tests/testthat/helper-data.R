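# shared fixtures, all generated in code under fixed seeds

# small well-conditioned dataset with both classes guaranteed
make_small_dataset <- function(n = 60, p = 5, seed = 101, rho = 0) {
  spec <- model_spec(n = n, p = p, rho = rho,
                     true_indices = c(1L, 2L), beta = c(1.5, -1),
                     beta0 = 0.2)
  simulate_dataset(spec, seed = seed)
}

# Monte-Carlo draw of the two-class Gaussian mixture behind the
# point-biserial population theory: mu0 = 0, mu1 = delta, sigma = 1
draw_mixture <- function(n, delta, p1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- rbinom(n, 1, p1)
  x <- rnorm(n, mean = delta * y)
  list(x = x, y = y)
}

# penalized logistic objective on the standardized scale:
# (1/n) * negative log-likelihood + lambda * ||beta||_1
lasso_objective <- function(Z, y, intercept, beta, lambda) {
  eta <- intercept + as.vector(Z %*% beta)
  mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
    lambda * sum(abs(beta))
}

standardize <- function(X) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  scl <- sqrt(colMeans(Xc^2))
  sweep(Xc, 2, scl, "/")
}
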