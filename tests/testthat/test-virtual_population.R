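drug <- captopril_parameters()

test_that("zero variability yields the drug's typical values exactly", {
  spec <- default_population_spec("healthy", variability = zero_cv)
  s <- sample_population(spec, drug, 25, seed = 3)
  expect_equal(s$cl_h + s$cl_r, rep(49.5, 25))
  expect_equal(s$ka_i, rep(1.75, 25))
  expect_equal(s$fa_i, rep(0.7, 25))
  expect_equal(s$q_h, rep(90, 25))
  expect_equal(s$vss_total, 0.267 * s$weight)
})

test_that("sampling is deterministic under a fixed seed", {
  spec <- default_population_spec("healthy")
  expect_identical(sample_population(spec, drug, 50, seed = 11),
                   sample_population(spec, drug, 50, seed = 11))
  expect_false(identical(sample_population(spec, drug, 50, seed = 11),
                         sample_population(spec, drug, 50, seed = 12)))
})

test_that("lognormal clearance variability reproduces its nominal CV", {
  spec <- default_population_spec("healthy")
  s <- sample_population(spec, drug, 10000, seed = 5)
  cl <- s$cl_h + s$cl_r
  expect_equal(stats::sd(cl) / mean(cl), 0.30, tolerance = 0.02 / 0.30)
  expect_true(all(s$cl_h < s$q_h))  # well-stirred contract guard
  expect_true(all(s$fa_i > 0 & s$fa_i < 1))
  expect_true(all(s$gfr >= 90 & s$gfr <= 140))
})

test_that("CKD scaling applies the published factors", {
  s <- typical_subject(drug)
  s$gfr <- 22.5
  severe <- apply_ckd_scaling(s, "severe", drug)
  expect_equal(severe$cl_h, 0.35 * 27.3)        # 9.555 L/h
  expect_equal(severe$cl_r, 22.2 * 22.5 / 120)
  expect_equal(severe$vss_total, 0.267 * 70 * 2.51)
  expect_equal(severe$vss_total / severe$weight, 0.267 * 2.51)  # 0.670 L/kg
  s$gfr <- 45
  moderate <- apply_ckd_scaling(s, "moderate", drug)
  expect_equal(moderate$cl_h, 0.55 * 27.3)
  expect_equal(moderate$cl_r, 8.325)
  s$gfr <- 75
  mild <- apply_ckd_scaling(s, "mild", drug)
  expect_equal(mild$cl_h, 0.80 * 27.3)
  expect_equal(mild$vss_total, 0.267 * 70 * 2.51)  # Vss factor in all bands
  s$gfr <- 100
  expect_error(apply_ckd_scaling(s, "severe", drug), "band")
})

test_that("CHF scaling reduces hepatic flow and clearance, not renal clearance", {
  s <- typical_subject(drug)
  mod <- apply_chf_scaling(s, "moderate", drug)
  expect_equal(mod$q_h, 0.54 * 90)              # 48.6 L/h
  expect_equal(mod$cl_h, 0.55 * 27.3)           # 15.015 L/h
  expect_equal(mod$cl_r, 22.2)
  expect_equal(mod$flow_renal, 0.55)
  expect_equal(mod$flow_peripheral, 0.44)
  sev <- apply_chf_scaling(typical_subject(drug), "severe", drug)
  expect_equal(sev$q_h, 0.46 * 90)
  expect_equal(sev$flow_renal, 0.63)
  expect_error(apply_chf_scaling(typical_subject(drug), "mild", drug),
               "severity")
  # severity assignment is reproducible under a fixed seed
  spec <- default_population_spec("chf")
  s1 <- sample_population(spec, drug, 60, seed = 9)
  s2 <- sample_population(spec, drug, 60, seed = 9)
  expect_identical(s1$severity, s2$severity)
  expect_setequal(unique(s1$severity), c("moderate", "severe"))
})

test_that("geriatric scaling declines 1% per year above 40 with a 50% floor", {
  s <- typical_subject(drug)
  s$age <- 40
  expect_equal(apply_geriatric_scaling(s, drug)$gfr, s$gfr)
  s$age <- 70
  g <- apply_geriatric_scaling(s, drug)
  expect_equal(g$gfr, 0.70 * 120)
  expect_equal(g$cl_r, 0.70 * 22.2)
  expect_equal(g$cl_h, 0.70 * 27.3)
  expect_equal(g$q_h, 0.70 * 90)
  # flow and metabolic clearance fall together: extraction (and F) unchanged
  expect_equal(subject_bioavailability(g), subject_bioavailability(s))
  s$age <- 100
  expect_equal(apply_geriatric_scaling(s, drug)$q_h, 0.5 * 90)
})

test_that("disease scaling refuses to run twice", {
  s <- typical_subject(drug)
  s$gfr <- 45
  once <- apply_ckd_scaling(s, "moderate", drug)
  expect_error(apply_ckd_scaling(once, "moderate", drug), "already")
  expect_error(apply_chf_scaling(once, "moderate", drug), "already")
  expect_error(apply_geriatric_scaling(once, drug), "already")
})

test_that("median total clearance decreases with CKD severity", {
  meds <- vapply(c("healthy", "ckd_mild", "ckd_moderate", "ckd_severe"),
                 function(p) {
                   s <- sample_population(default_population_spec(p), drug,
                                          200, seed = 21)
                   stats::median(s$cl_h + s$cl_r)
                 }, numeric(1))
  expect_true(all(diff(meds) < 0))
})

test_that("renal clearance is GFR-proportional in CKD at zero variability", {
  spec <- default_population_spec("ckd_moderate", variability = zero_cv)
  s <- sample_population(spec, drug, 50, seed = 2)
  expect_equal(s$cl_r / s$gfr, rep(22.2 / 120, 50))
})

test_that("degenerate specification ranges are rejected", {
  expect_error(population_spec("healthy", age_range = c(50, 20),
                               weight_range = c(55, 85)), "range")
  expect_error(population_spec("healthy", age_range = c(20, 50),
                               weight_range = c(55, 85),
                               hepatic_sf = 1.5), "hepatic_sf")
})

test_that("geriatric apparent clearance falls below healthy at matched dose", {
  ger <- sample_population(default_population_spec("geriatric"), drug, 300,
                           seed = 31)
  hea <- sample_population(default_population_spec("healthy"), drug, 300,
                           seed = 31)
  clf <- function(s) (s$cl_h + s$cl_r) / subject_bioavailability(s)
  expect_lt(stats::median(clf(ger)), stats::median(clf(hea)))
  expect_lt(stats::median(ger$cl_r), stats::median(hea$cl_r))
})
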