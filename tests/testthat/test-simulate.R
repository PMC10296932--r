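test_that("the AR(1) design reproduces its covariance", {
  X <- generate_design(1e5, 3, rho = 0.8, seed = 61)
  expect_equal(cor(X[, 1], X[, 2]), 0.8, tolerance = 0.01)
  expect_equal(cor(X[, 1], X[, 3]), 0.64, tolerance = 0.01)
  expect_equal(sd(X[, 3]), 1, tolerance = 0.01)

  X0 <- generate_design(5e4, 4, rho = 0, seed = 62)
  off <- cor(X0)[upper.tri(diag(4))]
  expect_true(all(abs(off) < 4 / sqrt(5e4)))

  expect_identical(generate_design(20, 5, 0.4, seed = 1),
                   generate_design(20, 5, 0.4, seed = 1))
  expect_error(generate_design(10, 2, rho = 1), "rho")
})

test_that("responses follow the linked success probabilities", {
  spec <- model_spec(n = 10, p = 3, true_indices = 1L, beta = 2,
                     beta0 = 1)
  # all-zero design row: success probability is plogis(1) = 0.731
  X <- matrix(0, 2e4, 3)
  y <- generate_response(X, spec, seed = 63)
  expect_equal(mean(y), plogis(1), tolerance = 0.01)

  # probit link uses the normal CDF
  spec_p <- model_spec(n = 10, p = 3, true_indices = 1L, beta = 2,
                       beta0 = 1, link = "probit")
  yp <- generate_response(X, spec_p, seed = 64)
  expect_equal(mean(yp), pnorm(1), tolerance = 0.01)

  # a huge linear predictor saturates the probability
  Xbig <- matrix(20, 100, 3)
  expect_true(all(generate_response(Xbig, spec, seed = 65) == 1))

  expect_error(generate_response(matrix(0, 5, 1),
                                 model_spec(n = 5, p = 3,
                                            true_indices = 3L, beta = 1)),
               "exceeds")
})

test_that("opposite-sign coefficients cancel on the AR(1) diagonal", {
  # model 2 has beta = (2, -3): along x1 = x6 = t the predictor drops
  spec2 <- model_spec(2, n = 10, p = 6)
  t_grid <- c(-1, 0, 1)
  eta <- 1 + 2 * t_grid - 3 * t_grid
  expect_true(all(diff(plogis(eta)) < 0))
})

test_that("screening studies are reproducible and monotone in d", {
  spec <- model_spec(1, n = 60, p = 40, rho = 0.2)
  r1 <- run_screening_study(spec, methods = "pbsis", d_values = c(3, 8, 15),
                            n_replicates = 30, base_seed = 77)
  r2 <- run_screening_study(spec, methods = "pbsis", d_values = c(3, 8, 15),
                            n_replicates = 30, base_seed = 77)
  expect_identical(r1, r2)

  # P1 cannot decrease as the kept submodel grows
  expect_true(all(diff(r1$P1[order(r1$d)]) >= 0))
  # minimum model size is bounded below by the number of true predictors
  expect_true(all(attr(r1, "min_sizes") >= 2))
  expect_gte(r1$mmms[1], 2)
})

test_that("an ideal screen yields P1 = 1, MMMS = s and RSD = 0", {
  # strong signal, tiny dimension: the true pair always ranks on top
  spec <- model_spec(n = 200, p = 3, true_indices = c(1L, 2L),
                     beta = c(6, 6), beta0 = 0)
  r <- run_screening_study(spec, methods = "pbsis", d_values = 2,
                           n_replicates = 20, base_seed = 78)
  expect_equal(r$P1, 1)
  expect_equal(r$mmms, 2)
  expect_equal(r$rsd, 0)
})

test_that("two-stage studies aggregate containment and size per cell", {
  spec <- model_spec(1, n = 80, p = 40)
  r <- run_two_stage_study(spec, penalty_families = c("lasso", "mcp"),
                           criteria = c("bic", "ebic"), d = 10,
                           n_replicates = 8, base_seed = 79)
  expect_equal(nrow(r), 4)
  expect_true(all(r$P2 >= 0 & r$P2 <= 1))
  expect_true(all(r$mean_size >= 0))
  sizes <- attr(r, "final_sizes")
  expect_equal(colMeans(sizes), r$mean_size)
  r2 <- run_two_stage_study(spec, penalty_families = c("lasso", "mcp"),
                            criteria = c("bic", "ebic"), d = 10,
                            n_replicates = 8, base_seed = 79)
  expect_identical(r, r2)
})
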