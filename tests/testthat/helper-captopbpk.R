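# shared fixtures: a typical 70-kg subject at the drug's central values,
# and a variability set that switches all between-subject spread off
typical_subject <- function(drug = captopril_parameters(), weight = 70,
                            q_h = 90) {
  data.frame(subject_id = 1L, population = "healthy",
             severity = NA_character_, age = 30, sex = "M",
             weight = weight, gfr = 120, q_h = q_h,
             cl_h = drug$cl_h, cl_r = drug$cl_r,
             vss_total = drug$vss_per_kg * weight,
             ka_i = drug$ka, fa_i = drug$fa,
             flow_renal = 1, flow_peripheral = 1, scaled = FALSE,
             stringsAsFactors = FALSE)
}

zero_cv <- list(clearance = 0, volume = 0, ka = 0, qh = 0, fa_logit_sd = 0)

# a minimal two-tissue composition for analytic limit checks
toy_composition <- function(f_nl = c(0, 0), f_np = c(0, 0)) {
  tissue_composition(
    data.frame(tissue = c("alpha", "beta"),
               f_ew = c(0.2, 0.3), f_iw = c(0.5, 0.4),
               f_nl = f_nl, f_np = f_np, ph_iw = 7.0,
               albumin_ratio = c(0.1, 0.2),
               volume_frac = c(0.3, 0.2)),
    v_plasma = 0.04, v_ery = 0.03)
}

# dense long schedule for closed-form NCA checks
dense_schedule <- function(end = 24, by = 0.02) {
  sampling_schedule(seq(0, end, by = by))
}
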