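#' Two-stage PB-SIS variable selection
#'
#' Stage 1 ranks all `p` predictors by absolute point-biserial
#' correlation and keeps the top `d`; stage 2 fits a penalized logistic
#' regression path on the retained predictors and selects the tuning
#' parameter by the requested criterion.  The final support is reported
#' in the original predictor indexing, so a true predictor discarded by
#' stage 1 can never reappear in the final model.
#'
#' @param data A [binary_dataset].
#' @param d Submodel size for stage 1; defaults to
#'   `floor(n / log(n))`.
#' @param penalty_family `"lasso"`, `"scad"` or `"mcp"`.
#' @param criterion Tuning criterion, see [select_tuning()].
#' @param seed Seed for the cross-validation fold assignment.
#' @param folds Number of CV folds.
#' @param shape Penalty concavity parameter (see [penalty_spec()]).
#' @param gamma_ebic EBIC concentration parameter.
#' @param cv_rule CV selection rule, `"1se"` or `"min"`; see
#'   [select_tuning()].
#' @param n_lambda,lambda_min_ratio Path grid controls, see
#'   [lambda_path()].
#' @return An object of class `pbsis_two_stage` with elements
#'   `screening` (the stage-1 [screen_pbsis()] result), `fit` (the
#'   selected stage-2 `pbsis_fit`), `final_support` (original indices of
#'   the nonzero stage-2 coefficients) and `final_support_names`.
#' @examples
#' d <- simulate_dataset(model_spec(1, n = 100, p = 100), seed = 3)
#' two_stage_pbsis(d, d = 21, penalty_family = "lasso", criterion = "bic")
#' @export
two_stage_pbsis <- function(data, d = default_threshold(nrow(data$X)),
                            penalty_family = c("lasso", "scad", "mcp"),
                            criterion = c("cv", "aic", "bic", "ebic"),
                            seed = 1L, folds = 10L, shape = NULL,
                            gamma_ebic = 1, cv_rule = c("1se", "min"),
                            n_lambda = 100L, lambda_min_ratio = NULL) {
  stopifnot(inherits(data, "binary_dataset"))
  penalty_family <- match.arg(penalty_family)
  criterion <- match.arg(criterion)
  screening <- screen_pbsis(data, d)
  sub <- binary_dataset(data$X[, screening$selected, drop = FALSE],
                        data$y,
                        data$feature_names[screening$selected])
  path <- penalized_path(sub, penalty_family, shape = shape,
                         n_lambda = n_lambda,
                         lambda_min_ratio = lambda_min_ratio)
  fit <- select_tuning(path, criterion, sub, folds = folds, seed = seed,
                       gamma_ebic = gamma_ebic, cv_rule = cv_rule)
  final_support <- sort(screening$selected[fit$coef != 0])
  structure(list(screening = screening,
                 fit = fit,
                 final_support = final_support,
                 final_support_names = data$feature_names[final_support]),
            class = "pbsis_two_stage")
}

#' @export
print.pbsis_two_stage <- function(x, ...) {
  cat("Two-stage PB-SIS selection\n")
  cat("  stage 1: kept d =", x$screening$d, "of",
      length(x$screening$scores), "predictors\n")
  cat("  stage 2: ", x$fit$penalty$family, " + ", x$fit$criterion,
      ", lambda = ", signif(x$fit$penalty$lambda, 4), "\n", sep = "")
  cat("  final support (", length(x$final_support), "): ",
      paste(x$final_support_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}
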