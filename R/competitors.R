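#' Marginal maximum-likelihood (MMLE) screening
#'
#' For each predictor `j`, fits the one-predictor logistic regression of
#' `y` on the standardized column `X[, j]` by Newton-Raphson and scores
#' the predictor by the fitted slope; predictors are ranked by absolute
#' slope and the top `d` retained.  Columns are standardized before
#' fitting so slope magnitudes are comparable across predictors.
#'
#' Marginal fits use at most 25 Newton iterations with tolerance `1e-8`
#' on the log-likelihood change and probabilities clamped to
#' `[1e-10, 1 - 1e-10]`.  A completely separable marginal problem has no
#' finite maximizer; such slopes are capped at magnitude 30 (on the
#' standardized scale) and flagged, which preserves their top-of-ranking
#' position without infinite estimates.
#'
#' @inheritParams screen_pbsis
#' @return A `pbsis_screening` object (see [screen_pbsis()]) with
#'   additional attributes `converged` and `capped` (logical vectors of
#'   length `p`).
#' @export
screen_mmle <- function(data, d = default_threshold(nrow(data$X))) {
  stopifnot(inherits(data, "binary_dataset"))
  check_two_classes(data)
  check_d(d, ncol(data$X))
  X <- data$X
  y <- data$y
  n <- nrow(X)
  p <- ncol(X)

  mu <- colMeans(X)
  sdev <- sqrt(colMeans(sweep(X, 2L, mu)^2))
  zero_var <- sdev == 0
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance predictor column(s) scored 0: ",
            paste(utils::head(data$feature_names[zero_var], 5),
                  collapse = ", "))
    sdev[zero_var] <- 1  # placeholder; slope forced to 0 below
  }
  Z <- sweep(sweep(X, 2L, mu), 2L, sdev, "/")

  fit <- marginal_logistic_newton(Z, y)
  slope <- fit$slope
  slope[zero_var] <- 0

  out <- new_screening_result(slope, d, "mmle", data$feature_names)
  attr(out, "converged") <- fit$converged
  attr(out, "capped") <- fit$capped
  if (any(fit$capped)) {
    warning(sum(fit$capped),
            " marginal fit(s) were completely separable; slope capped at 30")
  }
  out
}

# Newton-Raphson for all p one-predictor logistic regressions at once.
# Z: n x p standardized design; y: 0/1 response.  Returns slopes,
# intercepts and convergence/separation flags.
marginal_logistic_newton <- function(Z, y, max_iter = 25L, tol = 1e-8,
                                     cap = 30) {
  n <- nrow(Z)
  p <- ncol(Z)
  a <- rep(qlogis(max(min(mean(y), 1 - 1e-10), 1e-10)), p)
  b <- numeric(p)
  active <- rep(TRUE, p)
  converged <- rep(FALSE, p)
  ll_old <- rep(-Inf, p)
  for (it in seq_len(max_iter)) {
    idx <- which(active)
    if (length(idx) == 0L) break
    Zi <- Z[, idx, drop = FALSE]
    E <- sweep(Zi * rep(b[idx], each = n), 2L, a[idx], "+")
    P <- pmin(pmax(plogis(E), 1e-10), 1 - 1e-10)
    W <- P * (1 - P)
    R <- y - P
    g1 <- colSums(R)
    g2 <- colSums(Zi * R)
    h11 <- colSums(W)
    h12 <- colSums(Zi * W)
    h22 <- colSums(Zi^2 * W)
    det <- h11 * h22 - h12^2
    det[det < 1e-12] <- 1e-12
    a[idx] <- a[idx] + (h22 * g1 - h12 * g2) / det
    b[idx] <- b[idx] + (h11 * g2 - h12 * g1) / det
    # stable log-likelihood: y*eta - log(1 + exp(eta))
    E <- sweep(Zi * rep(b[idx], each = n), 2L, a[idx], "+")
    ll <- colSums(y * E - (pmax(E, 0) + log1p(exp(-abs(E)))))
    done <- abs(ll - ll_old[idx]) < tol
    converged[idx[done]] <- TRUE
    ll_old[idx] <- ll
    active[idx[done]] <- FALSE
  }
  capped <- abs(b) > cap
  b[capped] <- sign(b[capped]) * cap
  list(slope = b, intercept = a, converged = converged, capped = capped)
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The exact supremum distance between the empirical CDFs of `x` within
#' class 1 and class 0, evaluated at the pooled sample points (the sup of
#' a difference of step functions is attained there).  Tied values are
#' handled by evaluating the difference only after all observations at a
#' tied point have been absorbed.
#'
#' @param x Numeric vector.
#' @param y Binary 0/1 class labels of the same length; both classes
#'   must be present.
#' @return The KS statistic in `[0, 1]`.
#' @examples
#' ks_statistic(c(1, 2, 3, 4), c(0, 1, 0, 1))  # 0.5
#' @export
ks_statistic <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length",
                                   call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("'y' must be 0/1 coded", call. = FALSE)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("degenerate input: both classes must be present", call. = FALSE)
  }
  ord <- order(x)
  xs <- x[ord]
  step <- ifelse(y[ord] == 1, 1 / n1, -1 / n0)
  cum <- cumsum(step)
  n <- length(x)
  last_of_run <- c(xs[-1L] != xs[-n], TRUE)
  max(abs(cum[last_of_run]))
}

#' Kolmogorov-filter screening
#'
#' Scores each predictor by the exact two-sample Kolmogorov-Smirnov
#' statistic between its class-conditional samples and keeps the `d`
#' predictors with the largest statistics.  The score is invariant under
#' strictly increasing transforms of the predictor.
#'
#' @inheritParams screen_pbsis
#' @return A `pbsis_screening` object (see [screen_pbsis()]).
#' @export
screen_kolmogorov <- function(data, d = default_threshold(nrow(data$X))) {
  stopifnot(inherits(data, "binary_dataset"))
  check_two_classes(data)
  check_d(d, ncol(data$X))
  scores <- unname(apply(data$X, 2L, ks_statistic, y = data$y))
  new_screening_result(scores, d, "kolmogorov", data$feature_names)
}
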