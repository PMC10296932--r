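test_that("soft threshold follows sign(z) * (|z| - gamma)+", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-3, 1), -2)
  expect_equal(soft_threshold(0.5, 1), 0)
  z <- seq(-2, 2, by = 0.25)
  expect_equal(soft_threshold(-z, 0.4), -soft_threshold(z, 0.4))
  expect_true(all(abs(soft_threshold(z, 0.4)) <= abs(z)))
  expect_error(soft_threshold(1, -0.1), "nonnegative")
})

test_that("working response and weights implement the quadratic expansion", {
  r1 <- irls_working_response(0, 1)
  expect_equal(r1$z, 2)
  expect_equal(r1$w, 0.25)
  r0 <- irls_working_response(0, 0)
  expect_equal(r0$z, -2)

  # clamping keeps everything finite at extreme linear predictors
  rext <- irls_working_response(40, 1)
  expect_equal(rext$w, 1e-5 * (1 - 1e-5))
  expect_true(is.finite(rext$z))
})

test_that("at lambda >= lambda_max the lasso fit is intercept-only", {
  d <- make_small_dataset(n = 60, p = 5, seed = 31)
  lmax <- lambda_path(d)[1]
  f <- fit_penalized_logistic(d, penalty_spec("lasso", lmax * 1.001))
  expect_equal(f$df, 0L)
  expect_equal(f$intercept, qlogis(mean(d$y)), tolerance = 1e-6)
})

test_that("the unpenalized fit matches the logistic MLE", {
  d <- make_small_dataset(n = 200, p = 3, seed = 32)
  f <- fit_penalized_logistic(d, penalty_spec("lasso", 0))
  ref <- glm(d$y ~ d$X, family = binomial)
  expect_equal(unname(coef(f)), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(f$deviance, unname(deviance(ref)), tolerance = 1e-6)
})

test_that("lambda grid construction matches its definition", {
  # lambda_max by hand: standardized x = (1,-1,1,-1), y = (1,0,1,0)
  d <- binary_dataset(cbind(x = c(1, -1, 1, -1)), c(1, 0, 1, 0))
  expect_equal(lambda_path(d, n_lambda = 2, lambda_min_ratio = 0.1),
               c(0.5, 0.05))

  d2 <- make_small_dataset(n = 50, p = 4, seed = 33)
  grid <- lambda_path(d2, n_lambda = 20)
  expect_length(grid, 20)
  expect_true(all(diff(grid) < 0))
  path <- penalized_path(d2, "lasso", lambdas = grid)
  expect_equal(path$df[1], 0L)

  expect_error(lambda_path(binary_dataset(matrix(1, 10, 2),
                                          rep(c(0, 1), 5))),
               "constant")
})

test_that("lasso solutions satisfy the KKT conditions along the path", {
  d <- make_small_dataset(n = 80, p = 8, seed = 34)
  Z <- standardize(d$X)
  path <- penalized_path(d, "lasso", n_lambda = 30)
  for (i in c(5, 15, 25)) {
    lam <- path$lambdas[i]
    eta <- path$intercepts[i] + as.vector(d$X %*% path$coefs[, i])
    grad <- abs(crossprod(Z, d$y - plogis(eta))) / nrow(Z)
    active <- path$coefs[, i] != 0
    if (any(active)) {
      expect_true(max(abs(grad[active] - lam)) < 1e-4)
    }
    if (any(!active)) {
      expect_true(max(grad[!active]) <= lam + 1e-4)
    }
  }
})

test_that("lasso minimizers match an independent solver's objective", {
  skip_if_not_installed("glmnet")
  set.seed(35)
  worse <- 0
  for (i in 1:20) {
    n <- sample(30:60, 1)
    p <- sample(3:8, 1)
    d <- make_small_dataset(n = n, p = p, seed = 350 + i)
    Z <- standardize(d$X)
    lam <- 0.05 + runif(1, 0, 0.1)
    mine <- fit_penalized_logistic(binary_dataset(Z, d$y),
                                   penalty_spec("lasso", lam))
    ref <- glmnet::glmnet(Z, d$y, family = "binomial",
                          lambda = c(2 * lam, lam), standardize = FALSE,
                          thresh = 1e-14)
    rb <- as.matrix(ref$beta)[, 2]
    ra <- ref$a0[2]
    f_mine <- lasso_objective(Z, d$y, mine$intercept, mine$coef, lam)
    f_ref <- lasso_objective(Z, d$y, ra, rb, lam)
    expect_lt(abs(f_mine - f_ref), 1e-5)
    if (f_mine > f_ref + 1e-8) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("a brute-force convex solve confirms the penalized objective", {
  # direct minimization of the lasso objective via a smooth
  # reformulation (beta = u - v, u, v >= 0) with L-BFGS-B
  d <- make_small_dataset(n = 50, p = 5, seed = 36)
  Z <- standardize(d$X)
  y <- d$y
  lam <- 0.1
  n <- nrow(Z)
  obj_split <- function(par) {
    b0 <- par[1]
    u <- par[2:6]
    v <- par[7:11]
    lasso_objective(Z, y, b0, u - v, 0) + lam * sum(u + v)
  }
  best <- optim(rep(0.01, 11), obj_split, method = "L-BFGS-B",
                lower = c(-Inf, rep(0, 10)),
                control = list(maxit = 2000, factr = 1e3))
  mine <- fit_penalized_logistic(binary_dataset(Z, y),
                                 penalty_spec("lasso", lam))
  f_mine <- lasso_objective(Z, y, mine$intercept, mine$coef, lam)
  expect_lt(f_mine, best$value + 1e-6)
  expect_lt(abs(f_mine - best$value), 1e-4)
})

test_that("SCAD and MCP approach the lasso as the shape grows", {
  d <- make_small_dataset(n = 70, p = 6, seed = 37)
  lam <- lambda_path(d)[10]
  fl <- fit_penalized_logistic(d, penalty_spec("lasso", lam))
  fs <- fit_penalized_logistic(d, penalty_spec("scad", lam, shape = 1e6))
  fm <- fit_penalized_logistic(d, penalty_spec("mcp", lam, shape = 1e6))
  expect_equal(coef(fs), coef(fl), tolerance = 1e-3)
  expect_equal(coef(fm), coef(fl), tolerance = 1e-3)
})

test_that("nonconvex penalties shrink less than the lasso on the active set", {
  d <- make_small_dataset(n = 100, p = 6, seed = 38)
  lam <- lambda_path(d)[15]
  fl <- fit_penalized_logistic(d, penalty_spec("lasso", lam))
  fm <- fit_penalized_logistic(d, penalty_spec("mcp", lam))
  shared <- which(fl$coef != 0 & fm$coef != 0)
  expect_true(length(shared) >= 1)
  expect_true(all(abs(fm$coef[shared]) >= abs(fl$coef[shared]) - 1e-8))
})

test_that("warm starts never increase the objective along the path", {
  d <- make_small_dataset(n = 80, p = 8, seed = 39)
  path <- penalized_path(d, "lasso", n_lambda = 40)
  Z <- standardize(d$X)
  scl <- sqrt(colMeans(sweep(d$X, 2, colMeans(d$X))^2))
  for (i in 2:length(path$lambdas)) {
    lam <- path$lambdas[i]
    b_prev <- path$coefs[, i - 1] * scl  # standardized scale
    b0_prev <- path$intercepts[i - 1] +
      sum(path$coefs[, i - 1] * colMeans(d$X))
    b_cur <- path$coefs[, i] * scl
    b0_cur <- path$intercepts[i] + sum(path$coefs[, i] * colMeans(d$X))
    f_prev <- lasso_objective(Z, d$y, b0_prev, b_prev, lam)
    f_cur <- lasso_objective(Z, d$y, b0_cur, b_cur, lam)
    expect_lte(f_cur, f_prev + 1e-8)
  }
})

test_that("tuning criteria order models as their penalties dictate", {
  d <- simulate_dataset(model_spec(1, n = 100, p = 100), seed = 40)
  scr <- screen_pbsis(d, 21)
  sub <- binary_dataset(d$X[, scr$selected], d$y,
                        d$feature_names[scr$selected])
  path <- penalized_path(sub, "lasso")

  faic <- select_tuning(path, "aic", sub)
  fbic <- select_tuning(path, "bic", sub)
  febic <- select_tuning(path, "ebic", sub)
  expect_lte(febic$df, faic$df)  # EBIC is the most stringent
  expect_lte(fbic$df, faic$df)

  # a single-lambda path leaves no choice
  single <- penalized_path(sub, "lasso", lambdas = path$lambdas[10])
  for (crit in c("cv", "aic", "bic", "ebic")) {
    expect_equal(select_tuning(single, crit, sub, seed = 1)$penalty$lambda,
                 path$lambdas[10])
  }
})

test_that("cross-validation is stratified, seeded and reproducible", {
  d <- simulate_dataset(model_spec(1, n = 100, p = 60), seed = 41)
  scr <- screen_pbsis(d, 15)
  sub <- binary_dataset(d$X[, scr$selected], d$y)
  path <- penalized_path(sub, "lasso")
  f1 <- select_tuning(path, "cv", sub, seed = 9)
  f2 <- select_tuning(path, "cv", sub, seed = 9)
  expect_equal(f1$penalty$lambda, f2$penalty$lambda)
  expect_equal(f1$criterion_values, f2$criterion_values)

  # the 1-SE rule never selects a denser model than the CV minimum
  fmin <- select_tuning(path, "cv", sub, seed = 9, cv_rule = "min")
  expect_gte(f1$penalty$lambda, fmin$penalty$lambda)

  # too few positives for the requested folds
  tiny <- binary_dataset(matrix(rnorm(40), 20, 2),
                         c(rep(1, 3), rep(0, 17)))
  tpath <- penalized_path(tiny, "lasso", n_lambda = 10)
  expect_error(select_tuning(tpath, "cv", tiny, folds = 10),
               "stratified")
})
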