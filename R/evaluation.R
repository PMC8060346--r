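#' Observed/predicted ratio
#'
#' The basic model-evaluation statistic: observed value divided by
#' predicted value, both strictly positive. [fold_error()] is the same
#' quantity under its other conventional name; both are kept for
#' traceability to the two named statistics they implement.
#'
#' @param observed,predicted Positive numeric vectors.
#' @return `observed / predicted`, unrounded.
#' @export
ratio_obs_pred <- function(observed, predicted) {
  if (any(!is.finite(observed)) || any(!is.finite(predicted)) ||
      any(observed <= 0) || any(predicted <= 0))
    stop("observed and predicted values must be positive")
  observed / predicted
}

#' @rdname ratio_obs_pred
#' @export
fold_error <- ratio_obs_pred

#' Average fold error
#'
#' `AFE = 10 ^ (mean(log10(observed/predicted)))`: the geometric mean of
#' the signed observed/predicted ratios, a measure of overall prediction
#' bias (1 = unbiased; below 1 = over-prediction).
#'
#' @param observed,predicted Positive numeric vectors; alternatively pass
#'   precomputed ratios via `ratios`.
#' @param ratios Optional precomputed ratios (overrides
#'   `observed`/`predicted`).
#' @return The average fold error.
#' @export
average_fold_error <- function(observed, predicted, ratios = NULL) {
  if (is.null(ratios)) ratios <- ratio_obs_pred(observed, predicted)
  if (length(ratios) < 1) stop("at least one ratio is required")
  if (any(ratios <= 0)) stop("ratios must be positive")
  10^mean(log10(ratios))
}

#' Mean observed/predicted ratio with confidence interval
#'
#' Arithmetic mean of the ratios with a Student-t confidence interval,
#' `mean +/- t(1 - alpha/2, n - 1) * sd / sqrt(n)`. The default
#' (`style = "exact"`) computes on unrounded ratios and returns
#' full-precision bounds. `style = "printed"` reproduces the display
#' convention of the packaged reference tables: ratios rounded to
#' `digits` decimals before averaging, and the interval bounds truncated
#' (floored) to `digits` decimals.
#'
#' @param observed,predicted Positive numeric vectors; or pass `ratios`.
#' @param ratios Optional precomputed ratios.
#' @param conf Confidence level (default 0.95).
#' @param style `"exact"` or `"printed"`.
#' @param digits Display precision for `style = "printed"`.
#' @return List with `n`, `mean_ratio`, `ci_low`, `ci_high`, `sd`. With a
#'   single ratio the interval is `NA` (flagged via `ci_low`/`ci_high`).
#' @export
mean_ratio_ci <- function(observed, predicted, ratios = NULL, conf = 0.95,
                          style = c("exact", "printed"), digits = 2) {
  style <- match.arg(style)
  if (is.null(ratios)) ratios <- ratio_obs_pred(observed, predicted)
  if (style == "printed") ratios <- round(ratios, digits)
  n <- length(ratios)
  m <- mean(ratios)
  if (n < 2)
    return(list(n = n, mean_ratio = m, ci_low = NA_real_,
                ci_high = NA_real_, sd = NA_real_))
  s <- stats::sd(ratios)
  hw <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * s / sqrt(n)
  lo <- m - hw
  hi <- m + hw
  if (style == "printed") {
    lo <- floor(lo * 10^digits) / 10^digits
    hi <- floor(hi * 10^digits) / 10^digits
  }
  list(n = n, mean_ratio = m, ci_low = lo, ci_high = hi, sd = s)
}

#' Twofold-error assessment
#'
#' Flags each observed/predicted pair as inside the closed twofold
#' interval `0.5 <= ratio <= 2` and reports the fraction inside.
#'
#' @param observed,predicted Positive numeric vectors; or pass `ratios`.
#' @param ratios Optional precomputed ratios.
#' @return List with `within` (logical vector) and
#'   `fraction_within_twofold`.
#' @export
twofold_assessment <- function(observed, predicted, ratios = NULL) {
  if (is.null(ratios)) ratios <- ratio_obs_pred(observed, predicted)
  within <- ratios >= 0.5 & ratios <= 2
  list(within = within, fraction_within_twofold = mean(within))
}

#' Visual-predictive-check summary of simulated profiles
#'
#' Per-timepoint mean, 5th and 95th percentiles (linear-interpolation
#' quantiles) and minimum/maximum of the simulated concentrations across
#' subjects. All profiles must share the sampling schedule.
#'
#' @param profiles Tidy profile data frame (`trial_id`, `subject_id`,
#'   `time_h`, `conc_ng_per_ml`) or a `pbpk_trial_set`.
#' @param probs Lower and upper percentile probabilities.
#' @return Data frame with columns `time_h`, `mean`, `p_lo`, `p_hi`,
#'   `min`, `max` (ng/mL).
#' @export
vpc_summary <- function(profiles, probs = c(0.05, 0.95)) {
  if (inherits(profiles, "pbpk_trial_set")) profiles <- profiles$profiles
  stopifnot(length(probs) == 2, probs[1] < probs[2])
  n_subj <- nrow(unique(profiles[, c("trial_id", "subject_id")]))
  if (n_subj < 2) stop("VPC summaries need at least 2 profiles")
  counts <- table(profiles$time_h)
  if (length(unique(as.integer(counts))) != 1 ||
      counts[1] != n_subj)
    stop("profiles are not aligned on a common sampling schedule")
  agg <- function(f) tapply(profiles$conc_ng_per_ml, profiles$time_h, f)
  times <- as.numeric(names(agg(length)))
  out <- data.frame(
    time_h = times,
    mean = as.numeric(agg(mean)),
    p_lo = as.numeric(tapply(profiles$conc_ng_per_ml, profiles$time_h,
                             stats::quantile, probs = probs[1], type = 7)),
    p_hi = as.numeric(tapply(profiles$conc_ng_per_ml, profiles$time_h,
                             stats::quantile, probs = probs[2], type = 7)),
    min = as.numeric(agg(min)),
    max = as.numeric(agg(max)))
  out[order(out$time_h), , drop = FALSE]
}

#' Grouped evaluation summary
#'
#' Aggregates observed/predicted pairs into the evaluation table used
#' throughout: for each group x parameter cell, the number of pairs, the
#' mean ratio with t-based confidence interval, the average fold error
#' and the fraction of pairs within twofold.
#'
#' @param pairs Data frame with columns `observed`, `predicted` and the
#'   grouping columns.
#' @param by Character vector of grouping column names.
#' @param conf Confidence level.
#' @return Data frame, one row per group.
#' @export
summarize_evaluation <- function(pairs, by = c("group", "parameter"),
                                 conf = 0.95) {
  stopifnot(all(c("observed", "predicted", by) %in% names(pairs)))
  key <- interaction(pairs[, by, drop = FALSE], drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(levels(key), function(k) {
    g <- pairs[key == k, ]
    ci <- mean_ratio_ci(g$observed, g$predicted, conf = conf)
    tf <- twofold_assessment(g$observed, g$predicted)
    cbind(g[1, by, drop = FALSE],
          data.frame(n = ci$n, mean_ratio = ci$mean_ratio,
                     ci_low = ci$ci_low, ci_high = ci$ci_high,
                     afe = average_fold_error(g$observed, g$predicted),
                     fraction_within_twofold = tf$fraction_within_twofold),
          row.names = NULL)
  }))
  out[do.call(order, out[, by, drop = FALSE]), , drop = FALSE]
}
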