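#' Terminal slope by log-linear regression
#'
#' Estimates the terminal elimination rate constant by fitting log
#' concentration against time over the best contiguous terminal window:
#' among all windows ending at the last positive concentration with at
#' least three points (strictly after Tmax for oral routes; from the
#' first point onward for iv bolus), the window with the highest adjusted
#' R-squared wins; ties go to the window with more points. Zero and
#' negative concentrations are excluded from the regression.
#'
#' @param time,conc Numeric vectors of sampling times (h) and
#'   concentrations (ng/mL).
#' @param route `"oral"` or `"iv_bolus"` (controls Tmax exclusion).
#' @return List with `lambda_z` (1/h, `NA` when not estimable),
#'   `n_points`, `r2_adj` and `intercept` (log scale).
#' @export
estimate_lambda_z <- function(time, conc, route = c("oral", "iv_bolus")) {
  route <- match.arg(route)
  stopifnot(length(time) == length(conc))
  not_estimable <- list(lambda_z = NA_real_, n_points = 0L,
                        r2_adj = NA_real_, intercept = NA_real_)
  pos <- which(conc > 0)
  if (length(pos) < 3) return(not_estimable)
  i_max <- pos[which.max(conc[pos])]
  first <- if (route == "oral") i_max + 1L else pos[1]
  usable <- pos[pos >= first]
  if (length(usable) < 3) return(not_estimable)
  t_u <- time[usable]
  lc_u <- log(conc[usable])
  m <- length(usable)
  best <- NULL
  for (start in 1:(m - 2)) {
    tw <- t_u[start:m]
    lw <- lc_u[start:m]
    fit <- stats::lm.fit(cbind(1, tw), lw)
    k <- length(tw)
    rss <- sum(fit$residuals^2)
    tss <- sum((lw - mean(lw))^2)
    r2 <- if (tss > 0) 1 - rss / tss else 1
    r2a <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (fit$coefficients[2] >= 0) next
    if (is.null(best) || r2a > best$r2_adj + 1e-10 ||
        (abs(r2a - best$r2_adj) <= 1e-10 && k > best$n_points)) {
      best <- list(lambda_z = -unname(fit$coefficients[2]),
                   n_points = as.integer(k), r2_adj = r2a,
                   intercept = unname(fit$coefficients[1]))
    }
  }
  if (is.null(best)) not_estimable else best
}

#' Area under the concentration-time curve
#'
#' Linear trapezoidal AUC from time zero to the last observation, with
#' extrapolation to infinity as `Clast / lambda_z` (`Clast` the last
#' positive concentration). Zero concentrations contribute to the
#' trapezoid as zeros but never to the extrapolation.
#'
#' @param time,conc Numeric vectors (h, ng/mL).
#' @param lambda_z Terminal rate constant; `NA`/`NULL` leaves the
#'   extrapolated quantities `NA`.
#' @param warn_extrapolation Warn when more than 20% of AUC0-inf is
#'   extrapolated.
#' @return List with `auc_0_t`, `auc_0_inf`, `extrapolated_fraction`.
#' @export
compute_auc <- function(time, conc, lambda_z = NULL,
                        warn_extrapolation = TRUE) {
  stopifnot(length(time) == length(conc), length(time) >= 2)
  if (any(conc < 0)) stop("negative concentrations")
  auc_t <- sum(diff(time) * (utils::head(conc, -1) + utils::tail(conc, -1)) / 2)
  if (is.null(lambda_z) || is.na(lambda_z) || !any(conc > 0))
    return(list(auc_0_t = auc_t, auc_0_inf = NA_real_,
                extrapolated_fraction = NA_real_))
  c_last <- conc[max(which(conc > 0))]
  tail_area <- c_last / lambda_z
  auc_inf <- auc_t + tail_area
  frac <- tail_area / auc_inf
  if (warn_extrapolation && frac > 0.2)
    warning(sprintf("%.0f%% of AUC0-inf is extrapolated", 100 * frac))
  list(auc_0_t = auc_t, auc_0_inf = auc_inf, extrapolated_fraction = frac)
}

#' Clearance from dose and exposure
#'
#' `CL = dose / AUC0-inf` with unit bookkeeping mg -> ng and mL -> L, i.e.
#' `CL (L/h) = dose_mg * 1000 / auc (ng/mL.h)`. For oral profiles this is
#' the apparent clearance CL/F.
#'
#' @param dose_mg Dose, mg.
#' @param auc_0_inf Exposure, ng/mL.h.
#' @return Clearance, L/h.
#' @export
compute_clearance <- function(dose_mg, auc_0_inf) {
  if (any(!is.finite(auc_0_inf)) || any(auc_0_inf <= 0))
    stop("AUC0-inf must be positive")
  dose_mg * 1000 / auc_0_inf
}

#' Non-compartmental analysis of one profile
#'
#' @param time,conc Numeric vectors (h, ng/mL).
#' @param dose_mg Administered dose, mg.
#' @param route `"oral"` or `"iv_bolus"`.
#' @param warn_extrapolation See [compute_auc()].
#' @return One-row data frame: `auc_0_t`, `auc_0_inf`,
#'   `extrapolated_fraction`, `cmax`, `tmax`, `lambda_z`,
#'   `n_lambda_points`, `r2_adj`, `cl_over_f` (equals CL for iv).
#' @export
nca_profile <- function(time, conc, dose_mg, route = c("oral", "iv_bolus"),
                        warn_extrapolation = TRUE) {
  route <- match.arg(route)
  lz <- estimate_lambda_z(time, conc, route)
  auc <- compute_auc(time, conc, lz$lambda_z, warn_extrapolation)
  i_max <- which.max(conc)
  data.frame(auc_0_t = auc$auc_0_t, auc_0_inf = auc$auc_0_inf,
             extrapolated_fraction = auc$extrapolated_fraction,
             cmax = conc[i_max], tmax = time[i_max],
             lambda_z = lz$lambda_z, n_lambda_points = lz$n_points,
             r2_adj = lz$r2_adj,
             cl_over_f = if (is.na(auc$auc_0_inf)) NA_real_ else
               compute_clearance(dose_mg, auc$auc_0_inf))
}

#' Non-compartmental analysis of a trial set
#'
#' Runs [nca_profile()] on every subject profile of a
#' [run_trial_set()] result (or any tidy profile data frame with columns
#' `trial_id`, `subject_id`, `time_h`, `conc_ng_per_ml`).
#'
#' @param x A `pbpk_trial_set` or a tidy profiles data frame.
#' @param dose_mg Dose, mg (taken from the trial set's regimen when
#'   omitted).
#' @param route Route (taken from the regimen when omitted).
#' @return Data frame with one row per subject, keyed by `trial_id` and
#'   `subject_id`.
#' @export
run_nca <- function(x, dose_mg = NULL, route = NULL) {
  if (inherits(x, "pbpk_trial_set")) {
    if (is.null(dose_mg)) dose_mg <- x$regimen$amount_mg
    if (is.null(route)) route <- x$regimen$route
    x <- x$profiles
  }
  if (is.null(dose_mg) || is.null(route))
    stop("dose_mg and route are required for plain profile tables")
  keys <- unique(x[, c("trial_id", "subject_id")])
  do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    p <- x[x$trial_id == keys$trial_id[i] &
             x$subject_id == keys$subject_id[i], ]
    cbind(keys[i, , drop = FALSE],
          nca_profile(p$time_h, p$conc_ng_per_ml, dose_mg, route,
                      warn_extrapolation = FALSE),
          row.names = NULL)
  }))
}
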