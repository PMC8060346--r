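#' Drug-specific model parameters
#'
#' Constructs and validates the full set of drug-specific inputs of the
#' minimal PBPK model: physicochemistry (molecular weight, logP, pKa with
#' its ionization class), first-order absorption (`ka`, `tlag`, `fa`),
#' minimal-PBPK distribution (`kin`, `kout`, blood-to-plasma ratio,
#' fraction unbound, steady-state volume per kg) and elimination (total
#' intravenous plasma clearance `cl_iv` and renal plasma clearance `cl_r`;
#' hepatic clearance is their difference).
#'
#' @param molecular_weight Molar mass, g/mol.
#' @param logp Octanol-water log partition coefficient.
#' @param pka Acid dissociation constant.
#' @param ionization_class One of `"monoprotic_acid"`, `"monoprotic_base"`,
#'   `"neutral"`. Only the acid and neutral branches of the partitioning
#'   method are implemented.
#' @param ka First-order absorption rate constant, 1/h.
#' @param tlag Absorption lag time, h.
#' @param fa Fraction of the oral dose absorbed.
#' @param kin,kout First-order exchange rates between the systemic
#'   compartment and the single adjusting compartment, 1/h.
#' @param bp_ratio Blood-to-plasma concentration ratio.
#' @param fu Fraction unbound in plasma.
#' @param vss_per_kg Steady-state volume of distribution, L/kg.
#' @param cl_iv Total systemic plasma clearance, L/h.
#' @param cl_r Renal plasma clearance, L/h.
#' @return An object of class `drug_parameters` (a validated named list
#'   with the additional derived element `cl_h = cl_iv - cl_r`).
#' @seealso [captopril_parameters()], [load_drug_parameters()]
#' @export
drug_parameters <- function(molecular_weight, logp, pka, ionization_class,
                            ka, tlag, fa, kin, kout, bp_ratio, fu,
                            vss_per_kg, cl_iv, cl_r) {
  x <- list(
    molecular_weight = molecular_weight, logp = logp, pka = pka,
    ionization_class = match.arg(ionization_class,
      c("monoprotic_acid", "monoprotic_base", "neutral")),
    ka = ka, tlag = tlag, fa = fa, kin = kin, kout = kout,
    bp_ratio = bp_ratio, fu = fu, vss_per_kg = vss_per_kg,
    cl_iv = cl_iv, cl_r = cl_r)
  num <- x[setdiff(names(x), "ionization_class")]
  if (!all(vapply(num, function(v) is.numeric(v) && length(v) == 1 &&
                    is.finite(v), logical(1))))
    stop("all drug parameters must be finite numeric scalars")
  if (x$fa <= 0 || x$fa > 1) stop("fa must be in (0, 1]")
  if (x$fu <= 0 || x$fu > 1) stop("fu must be in (0, 1]")
  if (x$bp_ratio <= 0) stop("bp_ratio must be positive")
  if (x$ka <= 0 || x$kin <= 0 || x$kout <= 0)
    stop("ka, kin and kout must be positive")
  if (x$tlag < 0) stop("tlag must be non-negative")
  if (x$vss_per_kg <= 0) stop("vss_per_kg must be positive")
  if (x$cl_r < 0 || x$cl_iv <= 0) stop("clearances must be positive")
  if (x$cl_r > x$cl_iv)
    stop("cl_r exceeds cl_iv: hepatic clearance would be negative")
  x$cl_h <- x$cl_iv - x$cl_r
  structure(x, class = "drug_parameters")
}

#' @export
print.drug_parameters <- function(x, ...) {
  cat("<drug_parameters>\n")
  cat(sprintf("  MW %.2f g/mol, logP %.2f, pKa %.2f (%s)\n",
              x$molecular_weight, x$logp, x$pka, x$ionization_class))
  cat(sprintf("  absorption: ka %.3g/h, tlag %.2g h, fa %.2g\n",
              x$ka, x$tlag, x$fa))
  cat(sprintf("  distribution: kin/kout %.3g/%.3g 1/h, B/P %.2g, fu %.2g, Vss %.3g L/kg\n",
              x$kin, x$kout, x$bp_ratio, x$fu, x$vss_per_kg))
  cat(sprintf("  elimination: CLiv %.3g L/h (renal %.3g, hepatic %.3g)\n",
              x$cl_iv, x$cl_r, x$cl_h))
  invisible(x)
}

#' Load drug parameters from a YAML configuration
#'
#' The YAML keys mirror the argument names of [drug_parameters()].
#'
#' @param path Path to a YAML file.
#' @return A `drug_parameters` object.
#' @export
load_drug_parameters <- function(path) {
  if (!file.exists(path)) stop("drug parameter file not found: ", path)
  cfg <- yaml::read_yaml(path)
  need <- setdiff(names(formals(drug_parameters)), names(cfg))
  if (length(need))
    stop("drug parameter file is missing: ", paste(need, collapse = ", "))
  do.call(drug_parameters, cfg[names(formals(drug_parameters))])
}

#' Packaged captopril model parameters
#'
#' @return The captopril `drug_parameters` set shipped with the package
#'   (MW 217.29, logP 0.34, pKa 4.02 monoprotic acid, ka 1.75/h, tlag
#'   0.2 h, fa 0.7, kin = kout = 0.25/h, B/P 1, fu 0.73, Vss 0.267 L/kg,
#'   CLiv 49.5 L/h, CLR 22.2 L/h).
#' @export
captopril_parameters <- function() {
  load_drug_parameters(
    system.file("extdata", "captopril.yaml", package = "captopbpk",
                mustWork = TRUE))
}

#' Tissue composition table for partition-coefficient prediction
#'
#' Loads the packaged tissue composition constants (fractional
#' extracellular/intracellular water, neutral lipid and neutral
#' phospholipid volumes, intracellular pH and albumin tissue-to-plasma
#' ratios per tissue, plus fractional organ volumes per kg body weight and
#' the plasma and erythrocyte volume fractions).
#'
#' @param path Optional path to an alternative CSV with the same columns.
#' @return A `tissue_composition` object: a list with elements `tissues`
#'   (data frame, one row per tissue), `v_plasma` and `v_ery` (L/kg body
#'   weight).
#' @export
load_tissue_composition <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "tissue_composition.csv",
                        package = "captopbpk", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("tissue", "f_ew", "f_iw", "f_nl", "f_np", "ph_iw",
            "albumin_ratio", "volume_frac")
  if (!all(need %in% names(tab)))
    stop("tissue composition table lacks columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  vp <- tab$volume_frac[tab$tissue == "plasma"]
  ve <- tab$volume_frac[tab$tissue == "erythrocytes"]
  if (length(vp) != 1 || length(ve) != 1)
    stop("tissue composition table must contain one plasma and one erythrocytes row")
  tissues <- tab[!tab$tissue %in% c("plasma", "erythrocytes"), , drop = FALSE]
  tissue_composition(tissues, v_plasma = vp, v_ery = ve)
}

#' @rdname load_tissue_composition
#' @param tissues Data frame of per-tissue composition (see
#'   [load_tissue_composition()] for columns).
#' @param v_plasma,v_ery Plasma and erythrocyte volume fractions, L/kg.
#' @export
tissue_composition <- function(tissues, v_plasma, v_ery) {
  frac_cols <- c("f_ew", "f_iw", "f_nl", "f_np")
  fr <- as.matrix(tissues[, frac_cols])
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("tissue composition fractions must lie in [0, 1]")
  if (any(tissues$volume_frac < 0) || v_plasma < 0 || v_ery < 0)
    stop("tissue volumes must be non-negative")
  if (sum(tissues$volume_frac) >= 1)
    stop("per-tissue body volume fractions must sum to < 1")
  rownames(tissues) <- NULL
  structure(list(tissues = tissues, v_plasma = v_plasma, v_ery = v_ery),
            class = "tissue_composition")
}

#' Tissue-to-plasma partition coefficients by the Rodgers-Rowland method
#'
#' Implements the acids/neutrals branch: ionization-corrected partitioning
#' into tissue water, neutral-lipid and neutral-phospholipid partitioning
#' driven by the octanol-water coefficient, and albumin-type protein
#' binding scaled from `1/fu - 1` corrected for plasma lipid binding.
#' For a monoprotic acid the ionized fraction at pH `ph` is
#' `10^(ph - pKa) / (1 + 10^(ph - pKa))`; neutrals use no correction.
#'
#' @param drug A [drug_parameters()] object with `ionization_class`
#'   `"monoprotic_acid"` or `"neutral"`.
#' @param tissues A [tissue_composition()] object.
#' @param ph_plasma Plasma pH (default 7.4).
#' @param f_nl_plasma,f_np_plasma Neutral lipid and neutral phospholipid
#'   volume fractions of plasma (defaults 0.0023 and 0.0013).
#' @return Named numeric vector of Kp (plasma-referenced, i.e. the
#'   unbound-referenced coefficient multiplied by `fu`), one per tissue.
#' @export
compute_kp_rodgers_rowland <- function(drug, tissues, ph_plasma = 7.4,
                                       f_nl_plasma = 0.0023,
                                       f_np_plasma = 0.0013) {
  stopifnot(inherits(drug, "drug_parameters"),
            inherits(tissues, "tissue_composition"))
  if (!drug$ionization_class %in% c("monoprotic_acid", "neutral"))
    stop("only the monoprotic_acid and neutral branches are implemented; got ",
         drug$ionization_class)
  if (drug$fu <= 0) stop("fraction unbound must be positive")
  tt <- tissues$tissues
  if (any(is.na(tt$f_ew) | is.na(tt$albumin_ratio)))
    stop("tissue composition incomplete for: ",
         paste(tt$tissue[is.na(tt$f_ew) | is.na(tt$albumin_ratio)],
               collapse = ", "))
  p <- 10^drug$logp
  ion <- function(ph) {
    if (drug$ionization_class == "neutral") return(1)
    1 + 10^(ph - drug$pka)             # 1 + ionized:neutral ratio (acid)
  }
  y <- ion(ph_plasma)
  x <- ion(tt$ph_iw)
  lip_t <- (p * tt$f_nl + (0.3 * p + 0.7) * tt$f_np) / y
  lip_p <- (p * f_nl_plasma + (0.3 * p + 0.7) * f_np_plasma) / y
  prot <- (1 / drug$fu - 1 - lip_p) * tt$albumin_ratio
  kpu <- tt$f_ew + (x / y) * tt$f_iw + lip_t + prot
  kp <- kpu * drug$fu
  if (any(!is.finite(kp)) || any(kp <= 0))
    stop("non-finite or non-positive Kp computed")
  stats::setNames(kp, tt$tissue)
}

#' Erythrocyte-to-plasma partition from the blood-to-plasma ratio
#'
#' `E:P = (B/P - (1 - Hct)) / Hct`; with B/P = 1 this is 1 at any
#' hematocrit.
#'
#' @param bp_ratio Blood-to-plasma concentration ratio.
#' @param hematocrit Volume fraction of erythrocytes in blood.
#' @return The erythrocyte-to-plasma concentration ratio.
#' @export
erythrocyte_plasma_ratio <- function(bp_ratio, hematocrit = 0.45) {
  stopifnot(hematocrit > 0, hematocrit < 1, bp_ratio > 0)
  (bp_ratio - (1 - hematocrit)) / hematocrit
}

#' Steady-state volume of distribution from partition coefficients
#'
#' `Vss = Vplasma + Very * (E:P) + sum_t Vt * Kp_t`, per kg body weight.
#'
#' @param kp Named Kp vector as returned by
#'   [compute_kp_rodgers_rowland()]; must cover every tissue in `tissues`.
#' @param tissues A [tissue_composition()] object.
#' @param erythrocyte_partition Erythrocyte-to-plasma ratio (see
#'   [erythrocyte_plasma_ratio()]).
#' @return Vss in L/kg body weight.
#' @export
compute_vss <- function(kp, tissues, erythrocyte_partition = 1) {
  stopifnot(inherits(tissues, "tissue_composition"))
  tt <- tissues$tissues
  missing <- setdiff(tt$tissue, names(kp))
  if (length(missing))
    stop("Kp missing for tissue(s): ", paste(missing, collapse = ", "))
  tissues$v_plasma + tissues$v_ery * erythrocyte_partition +
    sum(tt$volume_frac * kp[tt$tissue])
}

#' Predict captopril-style Vss from drug parameters
#'
#' Convenience wrapper: Kp by [compute_kp_rodgers_rowland()], erythrocyte
#' partition from the blood-to-plasma ratio, then [compute_vss()].
#'
#' @inheritParams compute_kp_rodgers_rowland
#' @param hematocrit Hematocrit used to derive the erythrocyte partition.
#' @return List with elements `kp` (named vector) and `vss_per_kg`.
#' @export
predict_vss <- function(drug, tissues = load_tissue_composition(),
                        hematocrit = 0.45) {
  kp <- compute_kp_rodgers_rowland(drug, tissues)
  ep <- erythrocyte_plasma_ratio(drug$bp_ratio, hematocrit)
  list(kp = kp, vss_per_kg = compute_vss(kp, tissues, ep))
}

#' Hepatic availability under the well-stirred model
#'
#' `Fh = 1 - CLh,blood / Qh`; the extraction ratio `CLh/Qh` must be below
#' one.
#'
#' @param cl_h_blood Hepatic blood clearance, L/h.
#' @param q_h Hepatic blood flow, L/h.
#' @return Hepatic availability in (0, 1].
#' @export
hepatic_availability <- function(cl_h_blood, q_h) {
  stopifnot(all(q_h > 0), all(cl_h_blood >= 0))
  if (any(cl_h_blood >= q_h))
    stop("hepatic clearance must be below hepatic blood flow ",
         "(extraction cannot exceed flow)")
  1 - cl_h_blood / q_h
}

#' Oral bioavailability
#'
#' `F = fa * Fh` with gut availability fixed at one; the drug's hepatic
#' plasma clearance equals its blood clearance here because the
#' blood-to-plasma ratio is one.
#'
#' @param drug A [drug_parameters()] object.
#' @param q_h Hepatic blood flow, L/h (scalar or vector).
#' @return Oral bioavailability in (0, `fa`].
#' @export
oral_bioavailability <- function(drug, q_h) {
  drug$fa * hepatic_availability(drug$cl_h, q_h)
}
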