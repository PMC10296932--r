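#' Specify a simulation scenario
#'
#' The six benchmark models pair a sparse coefficient vector with fixed
#' true-predictor positions inside an autoregressive Gaussian design:
#'
#' | model | true predictors    | coefficients    |
#' |-------|--------------------|-----------------|
#' | 1     | x1, x3             | (2, 3)          |
#' | 2     | x1, x6             | (2, -3)         |
#' | 3     | x1, x3, x6         | (2, 3, 3)       |
#' | 4     | x1, x4, x8         | (2, -3, 3)      |
#' | 5     | x1, x3, x6, x10    | (2, 3, 3, 3)    |
#' | 6     | x1, x4, x8, x12    | (2, -3, 3, -3)  |
#'
#' All models share the intercept `beta0 = 1`.  Rows of the design are
#' i.i.d. `N(0, Sigma)` with AR(1) covariance `Sigma_jk = rho^|j-k|`,
#' and the response is Bernoulli with success probability given by the
#' logit (or probit) link applied to the sparse linear predictor.
#'
#' @param model_id Integer 1-6 selecting a benchmark model, or `NULL`
#'   when `true_indices` and `beta` are given directly.
#' @param n,p Sample size and number of predictors.
#' @param rho AR(1) correlation parameter, `|rho| < 1`.
#' @param link `"logit"` or `"probit"`.
#' @param true_indices,beta Optional custom sparse truth overriding
#'   `model_id`.
#' @param beta0 Intercept of the linear predictor (default 1).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(model_id = NULL, n = 100L, p = 200L, rho = 0,
                       link = c("logit", "probit"), true_indices = NULL,
                       beta = NULL, beta0 = 1) {
  link <- match.arg(link)
  if (is.null(true_indices) || is.null(beta)) {
    if (is.null(model_id) || !model_id %in% 1:6) {
      stop("'model_id' must be 1..6 unless a custom truth is given",
           call. = FALSE)
    }
    true_indices <- list(c(1L, 3L), c(1L, 6L), c(1L, 3L, 6L),
                         c(1L, 4L, 8L), c(1L, 3L, 6L, 10L),
                         c(1L, 4L, 8L, 12L))[[model_id]]
    beta <- list(c(2, 3), c(2, -3), c(2, 3, 3), c(2, -3, 3),
                 c(2, 3, 3, 3), c(2, -3, 3, -3))[[model_id]]
  }
  if (length(true_indices) != length(beta)) {
    stop("'true_indices' and 'beta' must have equal length", call. = FALSE)
  }
  if (max(true_indices) > p) {
    stop("true predictor index exceeds p", call. = FALSE)
  }
  if (abs(rho) >= 1) stop("'rho' must satisfy |rho| < 1", call. = FALSE)
  structure(list(model_id = model_id, true_indices = as.integer(true_indices),
                 beta = beta, beta0 = beta0, link = link,
                 n = as.integer(n), p = as.integer(p), rho = rho),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Simulation scenario",
      if (!is.null(x$model_id)) paste0("(model ", x$model_id, ")"), "\n")
  cat("  n =", x$n, ", p =", x$p, ", rho =", x$rho, ", link =", x$link, "\n")
  cat("  truth: eta = ", x$beta0, " + ",
      paste0(ifelse(x$beta >= 0, "+", "-"), abs(x$beta), "*x",
             x$true_indices, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Generate an AR(1) Gaussian design matrix
#'
#' Rows are i.i.d. `N(0, Sigma)` with `Sigma_jk = rho^|j-k|`, generated
#' by the AR(1) recursion `X_1 ~ N(0, 1)`,
#' `X_j = rho X_{j-1} + sqrt(1 - rho^2) e_j`, which reproduces this
#' covariance exactly in `O(np)` time.
#'
#' @param n,p Dimensions of the design.
#' @param rho AR(1) parameter, `|rho| < 1`.
#' @param seed Optional integer seed; when given, the draw is
#'   deterministic.
#' @return An `n x p` numeric matrix.
#' @export
generate_design <- function(n, p, rho = 0, seed = NULL) {
  if (abs(rho) >= 1) stop("'rho' must satisfy |rho| < 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  if (rho != 0 && p > 1L) {
    sc <- sqrt(1 - rho^2)
    for (j in 2:p) X[, j] <- rho * X[, j - 1L] + sc * X[, j]
  }
  colnames(X) <- paste0("X", seq_len(p))
  X
}

#' Generate a binary response from a sparse linear predictor
#'
#' Computes `eta_i = beta0 + sum_j beta_j X[i, true_j]`, maps it through
#' the logit (`1 / (1 + exp(-eta))`) or probit (`Phi(eta)`) link and
#' draws `Y_i ~ Bernoulli(pi_i)`.
#'
#' @param X Design matrix with at least `max(true_indices)` columns.
#' @param spec A [model_spec()].
#' @param seed Optional integer seed.
#' @return A 0/1 vector of length `nrow(X)`.
#' @export
generate_response <- function(X, spec, seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (max(spec$true_indices) > ncol(X)) {
    stop("true predictor index exceeds ncol(X)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  eta <- spec$beta0 +
    as.vector(X[, spec$true_indices, drop = FALSE] %*% spec$beta)
  pi <- switch(spec$link, logit = plogis(eta), probit = pnorm(eta))
  rbinom(nrow(X), 1L, pi)
}

#' Simulate one dataset from a scenario
#'
#' Draws a fresh design and response.  A replicate whose response is
#' degenerate (one class absent) is redrawn from the continuing random
#' stream; the number of redraws is recorded as an attribute.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed; the whole draw is deterministic given it.
#' @return A [binary_dataset] with attribute `n_redraws`.
#' @export
simulate_dataset <- function(spec, seed) {
  stopifnot(inherits(spec, "model_spec"))
  set.seed(seed)
  redraws <- 0L
  repeat {
    X <- generate_design(spec$n, spec$p, spec$rho)
    y <- generate_response(X, spec)
    if (sum(y) >= 1L && sum(1 - y) >= 1L) break
    redraws <- redraws + 1L
    if (redraws > 100L) {
      stop("response degenerate in 100 consecutive draws; ",
           "check the scenario's success probabilities", call. = FALSE)
    }
  }
  out <- binary_dataset(X, y)
  attr(out, "n_redraws") <- redraws
  out
}

# deterministic per-replicate seed, kept inside 32-bit integer range
replicate_seed <- function(base_seed, r) {
  as.integer((as.numeric(base_seed) + 1000003 * r) %% 2147483647)
}

#' Monte-Carlo study of stage-1 screening accuracy
#'
#' For each replicate a fresh dataset is drawn, each requested screen is
#' run once to obtain its full ranking, and the per-replicate minimum
#' model size (worst rank of a true predictor) is recorded.  Containment
#' in the top `d` is equivalent to `minimum model size <= d`, so a
#' single ranking serves all thresholds.
#'
#' @param spec A [model_spec()].
#' @param methods Subset of `c("pbsis", "mmle", "kolmogorov")`.
#' @param d_values Submodel sizes at which to report P1; defaults to
#'   `floor(n / log n)` times 1, 2, 3.
#' @param n_replicates Number of Monte-Carlo replicates.
#' @param base_seed Base seed; replicate `r` uses a seed derived from
#'   `base_seed + 1000003 r`, so studies are order-independent.
#' @return A data.frame with one row per (method, d): `method`, `d`,
#'   `P1`, `mmms`, `rsd`, `n_replicates`, plus the scenario identifiers.
#'   The raw per-replicate minimum model sizes are attached as attribute
#'   `min_sizes` (a matrix, replicates x methods).
#' @export
run_screening_study <- function(spec,
                                methods = c("pbsis", "mmle", "kolmogorov"),
                                d_values = NULL,
                                n_replicates = 1000L,
                                base_seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(d_values)) {
    d_values <- vapply(1:3, function(m) default_threshold(spec$n, m),
                       integer(1))
  }
  screen_fun <- list(pbsis = screen_pbsis, mmle = screen_mmle,
                     kolmogorov = screen_kolmogorov)
  mms <- matrix(NA_integer_, n_replicates, length(methods),
                dimnames = list(NULL, methods))
  for (r in seq_len(n_replicates)) {
    data <- simulate_dataset(spec, replicate_seed(base_seed, r))
    for (m in methods) {
      res <- screen_fun[[m]](data, d = spec$p)
      mms[r, m] <- minimum_model_size(res$ranking, spec$true_indices)
    }
  }
  rows <- expand.grid(method = methods, d = d_values,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    m <- rows$method[i]
    d <- rows$d[i]
    data.frame(method = m,
               model_id = if (is.null(spec$model_id)) NA_integer_
                          else spec$model_id,
               n = spec$n, p = spec$p, rho = spec$rho, link = spec$link,
               d = d,
               P1 = mean(mms[, m] <= d),
               mmms = median(mms[, m]),
               rsd = rsd(mms[, m]),
               n_replicates = n_replicates,
               stringsAsFactors = FALSE)
  }))
  attr(out, "min_sizes") <- mms
  out
}

#' Monte-Carlo study of the two-stage procedure
#'
#' Per replicate: draw a dataset, run PB-SIS screening once, fit one
#' regularization path per penalty family on the screened submodel, and
#' apply every tuning criterion to each path.  P2 is the proportion of
#' replicates whose final support contains all true predictors; the
#' mean final model size is reported alongside.
#'
#' @param spec A [model_spec()].
#' @param penalty_families Subset of `c("lasso", "scad", "mcp")`.
#' @param criteria Subset of `c("cv", "aic", "bic", "ebic")`.
#' @param d Stage-1 submodel size; defaults to `floor(n / log n)`.
#' @param n_replicates Number of Monte-Carlo replicates.
#' @param base_seed Base seed (see [run_screening_study()]).
#' @param folds CV folds.
#' @param gamma_ebic EBIC concentration parameter.
#' @param cv_rule CV selection rule, `"1se"` or `"min"`; see
#'   [select_tuning()].
#' @return A data.frame with one row per (penalty, criterion): `P2`,
#'   `mean_size`, `n_replicates`, `n_nonconverged`, plus scenario
#'   identifiers.
#' @export
run_two_stage_study <- function(spec,
                                penalty_families = c("lasso", "scad", "mcp"),
                                criteria = c("cv", "aic", "bic", "ebic"),
                                d = NULL,
                                n_replicates = 1000L,
                                base_seed = 1L,
                                folds = 10L,
                                gamma_ebic = 1,
                                cv_rule = c("1se", "min")) {
  stopifnot(inherits(spec, "model_spec"))
  penalty_families <- match.arg(penalty_families, several.ok = TRUE)
  criteria <- match.arg(criteria, several.ok = TRUE)
  cv_rule <- match.arg(cv_rule)
  if (is.null(d)) d <- default_threshold(spec$n)
  if (d > spec$p) stop("'d' exceeds p", call. = FALSE)
  cells <- expand.grid(penalty = penalty_families, criterion = criteria,
                       stringsAsFactors = FALSE)
  contain <- matrix(FALSE, n_replicates, nrow(cells))
  size <- matrix(NA_integer_, n_replicates, nrow(cells))
  nonconv <- integer(nrow(cells))
  for (r in seq_len(n_replicates)) {
    seed_r <- replicate_seed(base_seed, r)
    data <- simulate_dataset(spec, seed_r)
    screening <- screen_pbsis(data, d)
    sub <- binary_dataset(data$X[, screening$selected, drop = FALSE],
                          data$y,
                          data$feature_names[screening$selected])
    for (fam in penalty_families) {
      path <- penalized_path(sub, fam)
      for (crit in criteria) {
        i <- which(cells$penalty == fam & cells$criterion == crit)
        fit <- select_tuning(path, crit, sub, folds = folds, seed = seed_r,
                             gamma_ebic = gamma_ebic, cv_rule = cv_rule)
        support <- screening$selected[fit$coef != 0]
        contain[r, i] <- all(spec$true_indices %in% support)
        size[r, i] <- length(support)
        if (!fit$converged) nonconv[i] <- nonconv[i] + 1L
      }
    }
  }
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(penalty = cells$penalty[i],
               criterion = cells$criterion[i],
               model_id = if (is.null(spec$model_id)) NA_integer_
                          else spec$model_id,
               n = spec$n, p = spec$p, rho = spec$rho, link = spec$link,
               d = d,
               P2 = mean(contain[, i]),
               mean_size = mean(size[, i]),
               n_replicates = n_replicates,
               n_nonconverged = nonconv[i],
               stringsAsFactors = FALSE)
  }))
  attr(out, "containment") <- contain
  attr(out, "final_sizes") <- size
  out
}
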