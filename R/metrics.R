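#' Minimum model size of a ranking
#'
#' The smallest submodel size that contains every true predictor under a
#' given ranking — equivalently, the worst (largest, 1-based) rank
#' position held by a true predictor.
#'
#' @param ranking Permutation of predictor indices, best first.
#' @param true_indices Indices of the true predictors; all must appear
#'   in `ranking`.
#' @return A positive integer, at least `length(true_indices)`.
#' @examples
#' minimum_model_size(c(3, 1, 2, 4), c(1, 3))  # 2
#' @export
minimum_model_size <- function(ranking, true_indices) {
  pos <- match(true_indices, ranking)
  if (anyNA(pos)) {
    stop("true predictor(s) absent from ranking: ",
         paste(true_indices[is.na(pos)], collapse = ", "), call. = FALSE)
  }
  max(pos)
}

#' Robust standard deviation (IQR / 1.34)
#'
#' The interquartile range divided by 1.34, the factor equating the IQR
#' of a normal distribution to its standard deviation
#' (`qnorm(0.75) - qnorm(0.25)` is about 1.349).  Quartiles use linear
#' interpolation between order statistics (quantile type 7).
#'
#' @param values Nonempty numeric vector.
#' @return A nonnegative scalar.
#' @examples
#' rsd(rep(2, 10))  # 0
#' @export
rsd <- function(values) {
  if (length(values) == 0L) stop("'values' must be nonempty", call. = FALSE)
  diff(quantile(values, c(0.25, 0.75), names = FALSE, type = 7)) / 1.34
}

#' Aggregate per-replicate study records
#'
#' Reduces per-replicate outcomes to the summary statistics reported by
#' the Monte-Carlo studies: the containment proportion (P1 or P2), the
#' median and robust spread of minimum model sizes, and the mean final
#' model size.
#'
#' @param records A data.frame with a logical column `contained` and
#'   optional numeric columns `min_size` and `final_size`.
#' @return A one-row data.frame with columns `P`, `mmms`, `rsd`,
#'   `mean_size` and `n_replicates` (`NA` where the input column was
#'   absent).
#' @export
aggregate_study <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L,
            "contained" %in% names(records))
  data.frame(
    P = mean(records$contained),
    mmms = if ("min_size" %in% names(records)) median(records$min_size)
           else NA_real_,
    rsd = if ("min_size" %in% names(records)) rsd(records$min_size)
          else NA_real_,
    mean_size = if ("final_size" %in% names(records))
                  mean(records$final_size) else NA_real_,
    n_replicates = nrow(records))
}
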