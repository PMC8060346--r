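#' Virtual population specification
#'
#' Describes how virtual subjects are sampled: demographic ranges, the
#' glomerular filtration rate (GFR) band, disease scaling factors and the
#' between-subject variability model. Demographics are sampled uniformly
#' within their ranges; clearance, volume, absorption rate and hepatic
#' blood flow get median-preserving lognormal between-subject variability
#' (a CV of 0 switches variability off); the absorbed fraction gets
#' logit-normal variability so it stays inside (0, 1).
#'
#' @param name Population label, one of `"healthy"`, `"geriatric"`,
#'   `"ckd_mild"`, `"ckd_moderate"`, `"ckd_severe"`, `"chf"`.
#' @param age_range,weight_range Numeric length-2 ranges (years, kg).
#' @param fraction_female Proportion of female subjects.
#' @param gfr_range GFR sampling band, mL/min.
#' @param hepatic_sf Disease scaling factor on hepatic (non-renal)
#'   clearance, fraction of the healthy value.
#' @param vss_sf Multiplier on the steady-state volume of distribution.
#' @param flow_fractions Named vector `c(hepatic=, renal=, peripheral=)`
#'   of organ blood flows as fractions of normal (used by the heart
#'   failure scaling; the renal and peripheral fractions are recorded on
#'   the subject but do not alter clearances).
#' @param chf_severity_mix For `"chf"`: proportions of the
#'   moderate/severe severity tags, named vector summing to one.
#' @param variability List of between-subject variability settings:
#'   `clearance`, `volume`, `ka`, `qh` (lognormal CVs) and `fa_logit_sd`
#'   (SD on the logit scale).
#' @return A `population_spec` object.
#' @seealso [default_population_spec()], [sample_population()]
#' @export
population_spec <- function(name, age_range, weight_range,
                            fraction_female = 0, gfr_range = c(90, 140),
                            hepatic_sf = 1, vss_sf = 1,
                            flow_fractions = c(hepatic = 1, renal = 1,
                                               peripheral = 1),
                            chf_severity_mix = c(moderate = 0.5,
                                                 severe = 0.5),
                            variability = list(clearance = 0.30,
                                               volume = 0.25, ka = 0.30,
                                               qh = 0.15,
                                               fa_logit_sd = 0.4)) {
  name <- match.arg(name, c("healthy", "geriatric", "ckd_mild",
                            "ckd_moderate", "ckd_severe", "chf"))
  chk_range <- function(r, what, lo = 0) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2] || r[1] < lo)
      stop(what, " must be an ordered, non-negative length-2 range")
  }
  chk_range(age_range, "age_range")
  chk_range(weight_range, "weight_range")
  chk_range(gfr_range, "gfr_range")
  if (gfr_range[1] <= 0) stop("gfr_range must be positive")
  if (fraction_female < 0 || fraction_female > 1)
    stop("fraction_female must be in [0, 1]")
  if (hepatic_sf <= 0 || hepatic_sf > 1)
    stop("hepatic_sf must be in (0, 1]")
  if (vss_sf <= 0) stop("vss_sf must be positive")
  if (any(flow_fractions <= 0 | flow_fractions > 1.2))
    stop("flow_fractions must be in (0, 1.2]")
  vdef <- list(clearance = 0.30, volume = 0.25, ka = 0.30, qh = 0.15,
               fa_logit_sd = 0.4)
  vdef[names(variability)] <- variability
  if (any(unlist(vdef) < 0)) stop("variability settings must be >= 0")
  if (abs(sum(chf_severity_mix) - 1) > 1e-8)
    stop("chf_severity_mix must sum to 1")
  structure(list(name = name, age_range = age_range,
                 weight_range = weight_range,
                 fraction_female = fraction_female, gfr_range = gfr_range,
                 hepatic_sf = hepatic_sf, vss_sf = vss_sf,
                 flow_fractions = flow_fractions,
                 chf_severity_mix = chf_severity_mix,
                 variability = vdef),
            class = "population_spec")
}

#' Built-in population specifications
#'
#' Returns the default specification for each supported population. CKD
#' bands are mild 60-90, moderate 30-60, severe 15-30 mL/min (sampled
#' uniformly), with hepatic scaling factors 0.80 / 0.55 / 0.35 of the
#' healthy hepatic clearance and a Vss scaling factor of 2.51 for all
#' three severities. CHF reduces hepatic blood flow to 54% (moderate) or
#' 46% (severe) of normal, hepatic clearance to 55%, and records renal
#' (55% / 63%) and peripheral (44% / 28%) flow fractions. Healthy adults:
#' GFR 90-140 mL/min, hepatic blood flow 90 L/h typical.
#'
#' @param name Population label (see [population_spec()]).
#' @param age_range,weight_range,fraction_female Optional demographic
#'   overrides (e.g. from a study design row).
#' @param variability Optional variability overrides.
#' @return A `population_spec`.
#' @export
default_population_spec <- function(name, age_range = NULL,
                                    weight_range = NULL,
                                    fraction_female = NULL,
                                    variability = list()) {
  name <- match.arg(name, c("healthy", "geriatric", "ckd_mild",
                            "ckd_moderate", "ckd_severe", "chf"))
  base <- switch(name,
    healthy      = list(age = c(20, 50), gfr = c(90, 140), sf = 1, vsf = 1),
    geriatric    = list(age = c(65, 80), gfr = c(90, 140), sf = 1, vsf = 1),
    ckd_mild     = list(age = c(19, 60), gfr = c(60, 90), sf = 0.80,
                        vsf = 2.51),
    ckd_moderate = list(age = c(21, 55), gfr = c(30, 60), sf = 0.55,
                        vsf = 2.51),
    ckd_severe   = list(age = c(19, 62), gfr = c(15, 30), sf = 0.35,
                        vsf = 2.51),
    chf          = list(age = c(47, 71), gfr = c(90, 140), sf = 0.55,
                        vsf = 1))
  population_spec(
    name = name,
    age_range = if (is.null(age_range)) base$age else age_range,
    weight_range = if (is.null(weight_range)) c(55, 85) else weight_range,
    fraction_female = if (is.null(fraction_female)) 0 else fraction_female,
    gfr_range = base$gfr, hepatic_sf = base$sf, vss_sf = base$vsf,
    variability = variability)
}

# median-preserving lognormal multiplier with coefficient of variation cv
.lognormal_multiplier <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  exp(stats::rnorm(n, 0, sqrt(log(1 + cv^2))))
}

#' Sample a virtual population
#'
#' Samples `n` virtual subjects according to a [population_spec()] and a
#' drug parameter set, then applies the population's disease scaling
#' (CKD, CHF or geriatric). All subjects of a draw share the drug's
#' typical values; between-subject variability multiplies clearances
#' (one shared multiplier for hepatic and renal clearance, so total
#' clearance carries the clearance CV), the steady-state volume, the
#' absorption rate and hepatic blood flow, and perturbs the absorbed
#' fraction on the logit scale. Hepatic clearance is capped at 95% of the
#' subject's hepatic blood flow to keep the well-stirred contract valid.
#'
#' @param spec A [population_spec()].
#' @param drug A [drug_parameters()] object.
#' @param n Number of subjects.
#' @param seed Optional integer seed; if `NULL` the current RNG state is
#'   used (so callers that seed once stay deterministic).
#' @param q_h_typical Typical healthy hepatic blood flow, L/h.
#' @param gfr_ref Reference healthy GFR, mL/min, used for renal-clearance
#'   scaling in CKD and the geriatric decline.
#' @return Data frame, one row per subject, with demographics, `gfr`,
#'   `q_h`, `cl_h`, `cl_r`, `vss_total` (L), `ka_i`, `fa_i`, the severity
#'   tag, recorded flow fractions, and a `scaled` flag guarding against
#'   double application of disease scaling.
#' @export
sample_population <- function(spec, drug, n, seed = NULL,
                              q_h_typical = 90, gfr_ref = 120) {
  stopifnot(inherits(spec, "population_spec"),
            inherits(drug, "drug_parameters"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  v <- spec$variability
  subj <- data.frame(
    subject_id = seq_len(n),
    population = spec$name,
    severity = NA_character_,
    age = stats::runif(n, spec$age_range[1], spec$age_range[2]),
    sex = ifelse(stats::runif(n) < spec$fraction_female, "F", "M"),
    weight = stats::runif(n, spec$weight_range[1], spec$weight_range[2]),
    gfr = stats::runif(n, spec$gfr_range[1], spec$gfr_range[2]),
    stringsAsFactors = FALSE)
  m_cl <- .lognormal_multiplier(n, v$clearance)
  m_v  <- .lognormal_multiplier(n, v$volume)
  m_ka <- .lognormal_multiplier(n, v$ka)
  subj$q_h <- q_h_typical * .lognormal_multiplier(n, v$qh)
  subj$cl_h <- drug$cl_h * m_cl
  subj$cl_r <- drug$cl_r * m_cl
  subj$vss_total <- drug$vss_per_kg * subj$weight * m_v
  subj$ka_i <- drug$ka * m_ka
  subj$fa_i <- if (v$fa_logit_sd == 0) rep(drug$fa, n) else
    stats::plogis(stats::qlogis(drug$fa) + stats::rnorm(n, 0, v$fa_logit_sd))
  subj$flow_renal <- 1
  subj$flow_peripheral <- 1
  subj$scaled <- FALSE
  subj <- switch(spec$name,
    healthy = subj,
    geriatric = apply_geriatric_scaling(subj, drug),
    ckd_mild = apply_ckd_scaling(subj, "mild", drug, gfr_ref),
    ckd_moderate = apply_ckd_scaling(subj, "moderate", drug, gfr_ref),
    ckd_severe = apply_ckd_scaling(subj, "severe", drug, gfr_ref),
    chf = apply_chf_scaling(subj, spec$chf_severity_mix, drug))
  subj$cl_h <- pmin(subj$cl_h, 0.95 * subj$q_h)
  subj
}

#' Apply chronic kidney disease scaling to sampled subjects
#'
#' Hepatic clearance is scaled to 80% (mild), 55% (moderate) or 35%
#' (severe) of the subject's healthy value; renal clearance is scaled in
#' proportion to GFR (`gfr / gfr_ref`); the steady-state volume (and
#' implicitly every Kp) is scaled by 2.51 for all severities.
#'
#' @param subjects Subject data frame from [sample_population()],
#'   unscaled, with `gfr` inside the severity band.
#' @param severity `"mild"`, `"moderate"` or `"severe"`.
#' @param drug A [drug_parameters()] object (unused numerically; kept for
#'   interface symmetry and validation).
#' @param gfr_ref Healthy reference GFR, mL/min.
#' @return The scaled subject data frame (with `scaled = TRUE`).
#' @export
apply_ckd_scaling <- function(subjects, severity, drug, gfr_ref = 120) {
  severity <- match.arg(severity, c("mild", "moderate", "severe"))
  if (any(subjects$scaled))
    stop("disease scaling already applied to these subjects")
  band <- switch(severity, mild = c(60, 90), moderate = c(30, 60),
                 severe = c(15, 30))
  if (any(subjects$gfr < band[1] | subjects$gfr > band[2]))
    stop("GFR outside the ", severity, " band [", band[1], ", ", band[2],
         "] mL/min")
  sf <- switch(severity, mild = 0.80, moderate = 0.55, severe = 0.35)
  subjects$cl_h <- subjects$cl_h * sf
  subjects$cl_r <- subjects$cl_r * (subjects$gfr / gfr_ref)
  subjects$vss_total <- subjects$vss_total * 2.51
  subjects$severity <- severity
  subjects$scaled <- TRUE
  subjects
}

#' Apply chronic heart failure scaling to sampled subjects
#'
#' Assigns each subject a severity tag (moderate/severe, in the given
#' proportions), reduces hepatic blood flow to 54% (moderate) or 46%
#' (severe) of the subject's value, reduces hepatic clearance to 55% of
#' the healthy value, and records the renal (55% / 63%) and peripheral
#' (44% / 28%) flow fractions without altering renal clearance.
#'
#' @param subjects Subject data frame, unscaled.
#' @param severity_mix Named proportions over `c("moderate", "severe")`,
#'   or a character vector of per-subject tags.
#' @param drug A [drug_parameters()] object (interface symmetry).
#' @return The scaled subject data frame.
#' @export
apply_chf_scaling <- function(subjects,
                              severity_mix = c(moderate = 0.5, severe = 0.5),
                              drug = NULL) {
  if (any(subjects$scaled))
    stop("disease scaling already applied to these subjects")
  n <- nrow(subjects)
  if (is.character(severity_mix)) {
    sev <- severity_mix
    if (length(sev) != n) stop("severity tag vector length mismatch")
  } else {
    if (!all(names(severity_mix) %in% c("moderate", "severe")))
      stop("unknown CHF severity tag: ",
           paste(setdiff(names(severity_mix), c("moderate", "severe")),
                 collapse = ", "))
    sev <- sample(names(severity_mix), n, replace = TRUE,
                  prob = severity_mix)
  }
  if (!all(sev %in% c("moderate", "severe")))
    stop("unknown CHF severity tag: ",
         paste(unique(setdiff(sev, c("moderate", "severe"))), collapse = ", "))
  qh_frac <- c(moderate = 0.54, severe = 0.46)[sev]
  subjects$q_h <- subjects$q_h * qh_frac
  subjects$cl_h <- subjects$cl_h * 0.55
  subjects$flow_renal <- unname(c(moderate = 0.55, severe = 0.63)[sev])
  subjects$flow_peripheral <- unname(c(moderate = 0.44, severe = 0.28)[sev])
  subjects$severity <- sev
  subjects$scaled <- TRUE
  subjects
}

#' Apply geriatric scaling to sampled subjects
#'
#' GFR, hepatic metabolic clearance and hepatic blood flow (cardiac
#' output) decline by 1% per year of age above 40, floored at 50% of the
#' adult value; renal clearance follows the GFR ratio. Age 40 or below is
#' unchanged. Because flow and metabolic clearance decline together, the
#' hepatic extraction ratio -- and hence oral bioavailability -- is
#' age-invariant while absolute clearance falls.
#'
#' @param subjects Subject data frame, unscaled.
#' @param drug A [drug_parameters()] object (interface symmetry).
#' @return The scaled subject data frame.
#' @export
apply_geriatric_scaling <- function(subjects, drug = NULL) {
  if (any(subjects$scaled))
    stop("disease scaling already applied to these subjects")
  fac <- pmax(0.5, 1 - 0.01 * pmax(subjects$age - 40, 0))
  subjects$gfr <- subjects$gfr * fac
  subjects$cl_r <- subjects$cl_r * fac
  subjects$cl_h <- subjects$cl_h * fac
  subjects$q_h <- subjects$q_h * fac
  subjects$severity <- "geriatric"
  subjects$scaled <- TRUE
  subjects
}

#' Per-subject oral bioavailability
#'
#' `F_i = fa_i * (1 - cl_h_i / q_h_i)` under the well-stirred liver model.
#'
#' @param subjects Subject data frame from [sample_population()].
#' @return Numeric vector of per-subject oral bioavailability.
#' @export
subject_bioavailability <- function(subjects) {
  subjects$fa_i * hepatic_availability(subjects$cl_h, subjects$q_h)
}
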