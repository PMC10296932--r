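test_that("point-biserial correlation matches its closed form and Pearson", {
  expect_equal(point_biserial(c(1, 2, 3, 4), c(0, 0, 1, 1)), 2 / sqrt(5))
  y <- c(0, 1, 0, 1, 1)
  expect_equal(point_biserial(y, y), 1)

  expect_error(point_biserial(1:4, c(1, 1, 1, 1)), "zero variance")
  expect_error(point_biserial(rep(2, 4), c(0, 1, 0, 1)), "zero variance")

  # Pearson equivalence on random instances
  set.seed(7)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    x <- rnorm(n)
    expect_equal(point_biserial(x, y), cor(x, y), tolerance = 1e-12)
  }
})

test_that("point-biserial is invariant to affine rescaling up to sign", {
  set.seed(8)
  for (i in 1:20) {
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    x <- rnorm(30)
    a <- runif(1, -3, 3)
    if (abs(a) < 0.1) a <- 0.5
    expect_equal(point_biserial(a * x + 2, y),
                 sign(a) * point_biserial(x, y), tolerance = 1e-12)
  }
})

test_that("population correlation follows the mixture-model formula", {
  expect_equal(population_rho(0, 0.3), 0)
  expect_equal(population_rho(2, 0.5), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(population_rho(1, 0.5), 0.5 / sqrt(1.25), tolerance = 1e-12)
  expect_error(population_rho(1, 1.2), "\\(0, 1\\)")

  # odd and increasing in delta, bounded by 1
  deltas <- seq(-4, 4, by = 0.5)
  vals <- population_rho(deltas, 0.3)
  expect_equal(vals, -rev(vals))
  expect_true(all(diff(vals) > 0))
  expect_true(all(abs(vals) < 1))
})

test_that("sample point-biserial converges to the population value", {
  # consistency under the mixture model
  m <- draw_mixture(1e5, delta = 1.2, p1 = 0.4, seed = 99)
  expect_equal(point_biserial(m$x, m$y), population_rho(1.2, 0.4),
               tolerance = 0.01)
})

test_that("asymptotic variance reduces to 1/n at rho = 0 and scales as 1/n", {
  expect_equal(asymptotic_variance_rpb(0, 0.5, 25), 0.04)
  expect_equal(asymptotic_variance_rpb(0, 0.3, 100), 0.01)
  expect_equal(asymptotic_variance_rpb(0.4, 0.3, 50) * 50,
               asymptotic_variance_rpb(0.4, 0.3, 500) * 500)
  expect_error(asymptotic_variance_rpb(1.1, 0.5, 10), "rho")
  expect_error(asymptotic_variance_rpb(0.2, 0, 10), "p1")
})

test_that("default threshold uses the natural log rule", {
  expect_identical(default_threshold(100), 21L)
  expect_identical(default_threshold(100, 2), 43L)
  expect_identical(default_threshold(100, 3), 65L)
  expect_identical(default_threshold(3), 2L)
  expect_error(default_threshold(1), "at least 2")
})

test_that("screening ranks by absolute score with deterministic ties", {
  d <- make_small_dataset(n = 80, p = 10, seed = 5)
  res <- screen_pbsis(d, d = 10)
  expect_equal(sort(res$selected), 1:10)
  expect_true(all(diff(abs(res$scores[res$ranking])) <= 1e-15))

  # d = 1 selects the largest absolute score
  expect_equal(screen_pbsis(d, 1)$selected,
               which.max(abs(res$scores)))

  # nestedness of the selected sets in d
  sel <- lapply(1:10, function(k) screen_pbsis(d, k)$selected)
  for (k in 1:9) expect_true(all(sel[[k]] %in% sel[[k + 1]]))

  # exact ties break toward the lower predictor index
  X <- cbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1), c = c(1, 2, 3, 4))
  tie <- screen_pbsis(binary_dataset(X, c(0, 0, 1, 1)), 3)
  expect_equal(tie$ranking, c(1L, 2L, 3L))
})

test_that("zero-variance predictors score zero with a warning", {
  d <- make_small_dataset(n = 40, p = 4, seed = 6)
  d$X[, 3] <- 7
  expect_warning(res <- screen_pbsis(d, 2), "zero-variance")
  expect_equal(res$scores[3], 0)

  # a constant response still aborts
  d$y <- rep(1, 40)
  expect_error(screen_pbsis(d, 2), "degenerate")
})

test_that("screening results tabulate with ranks and selection flags", {
  d <- make_small_dataset(n = 50, p = 6, seed = 12)
  tab <- as.data.frame(screen_pbsis(d, 3))
  expect_equal(nrow(tab), 6)
  expect_equal(sum(tab$selected), 3)
  expect_equal(sort(tab$abs_rank), 1:6)
  expect_true(all(tab$abs_rank[tab$selected] <= 3))
})
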