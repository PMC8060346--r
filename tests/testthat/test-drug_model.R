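test_that("captopril parameter set loads, validates and derives hepatic clearance", {
  drug <- captopril_parameters()
  expect_s3_class(drug, "drug_parameters")
  expect_equal(drug$molecular_weight, 217.29)
  expect_equal(drug$cl_iv, 49.5)
  expect_equal(drug$cl_r, 22.2)
  expect_equal(drug$cl_h, 27.3)
  expect_equal(drug$vss_per_kg, 0.267)
  bad <- function(...) {
    args <- utils::modifyList(unclass(drug), list(...))
    args$cl_h <- NULL
    do.call(drug_parameters, args)
  }
  expect_error(bad(fa = 1.2), "fa")
  expect_error(bad(fu = 0), "fu")
  expect_error(bad(cl_r = 60), "hepatic")
  expect_error(bad(tlag = -1), "tlag")
})

test_that("Kp reduces to total tissue water in the no-binding limit", {
  tis <- toy_composition()
  drug <- captopril_parameters()
  drug$fu <- 1
  drug$logp <- -30      # no lipid partitioning
  drug$pka <- 20        # fully un-ionized acid at physiological pH
  kp <- compute_kp_rodgers_rowland(drug, tis,
                                   f_nl_plasma = 0, f_np_plasma = 0)
  expect_equal(unname(kp), c(0.2 + 0.5, 0.3 + 0.4), tolerance = 1e-12)
})

test_that("captopril Kp values match an independent transcription of the method", {
  # frozen from a separate spreadsheet-style transcription of the
  # acid-branch equations over the packaged composition table
  expected <- c(adipose = 0.117250, bone = 0.200667, brain = 0.311574,
                gut = 0.386689, heart = 0.408610, kidney = 0.374867,
                liver = 0.307413, lung = 0.432224, muscle = 0.286644,
                skin = 0.438296, spleen = 0.345695)
  kp <- compute_kp_rodgers_rowland(captopril_parameters(),
                                   load_tissue_composition())
  expect_equal(kp[names(expected)], expected, tolerance = 1e-5)
  expect_true(all(kp > 0.1 & kp < 1))  # small Kp, low-Vss drug
})

test_that("Kp increases with logP and with tissue neutral lipid content", {
  tis <- load_tissue_composition()
  lo <- captopril_parameters()
  hi <- captopril_parameters()
  hi$logp <- 1.5
  expect_true(all(compute_kp_rodgers_rowland(hi, tis) >
                    compute_kp_rodgers_rowland(lo, tis)))
  fat <- tis
  i <- which(fat$tissues$tissue == "muscle")
  fat$tissues$f_nl[i] <- 2 * fat$tissues$f_nl[i]
  kp0 <- compute_kp_rodgers_rowland(lo, tis)
  kp1 <- compute_kp_rodgers_rowland(lo, fat)
  expect_gt(kp1["muscle"], kp0["muscle"])
  expect_equal(kp1[names(kp1) != "muscle"], kp0[names(kp0) != "muscle"])
})

test_that("Vss is additive in tissue contributions with exact limiting cases", {
  tis <- load_tissue_composition()
  tt <- tis$tissues
  ones <- stats::setNames(rep(1, nrow(tt)), tt$tissue)
  expect_equal(compute_vss(ones, tis, erythrocyte_partition = 1),
               tis$v_plasma + tis$v_ery + sum(tt$volume_frac))
  zeros <- stats::setNames(rep(0, nrow(tt)), tt$tissue)
  expect_equal(compute_vss(zeros, tis, erythrocyte_partition = 0),
               tis$v_plasma)
  # removing one tissue removes exactly Vt * Kp_t
  kp <- compute_kp_rodgers_rowland(captopril_parameters(), tis)
  keep <- tt$tissue != "liver"
  smaller <- tissue_composition(tt[keep, ], tis$v_plasma, tis$v_ery)
  expect_equal(compute_vss(kp, tis) - compute_vss(kp[keep], smaller),
               unname(kp["liver"]) * tt$volume_frac[!keep])
  expect_error(compute_vss(kp[keep], tis), "liver")
})

test_that("predicted captopril Vss lands near the reported 0.267 L/kg", {
  pv <- predict_vss(captopril_parameters())
  expect_equal(pv$vss_per_kg, 0.275467, tolerance = 1e-5)  # frozen oracle
  expect_lt(abs(pv$vss_per_kg - 0.267) / 0.267, 0.15)
  expect_gt(pv$vss_per_kg, 0.04)  # at least the plasma space
})

test_that("erythrocyte partition from B/P = 1 is 1 at any hematocrit", {
  expect_equal(erythrocyte_plasma_ratio(1, 0.45), 1)
  expect_equal(erythrocyte_plasma_ratio(1, 0.40), 1)
  expect_equal(erythrocyte_plasma_ratio(0.8, 0.45), (0.8 - 0.55) / 0.45)
})

test_that("well-stirred hepatic availability follows 1 - CLh/Qh", {
  expect_equal(hepatic_availability(0, 90), 1)
  expect_equal(hepatic_availability(27.3, 90), 1 - 27.3 / 90)
  expect_equal(hepatic_availability(27.3, 1e9), 1, tolerance = 1e-7)
  expect_error(hepatic_availability(90, 90), "flow")
  expect_error(hepatic_availability(100, 90), "flow")
})

test_that("oral bioavailability is fa times hepatic availability", {
  drug <- captopril_parameters()
  expect_equal(oral_bioavailability(drug, 90), 0.7 * (1 - 27.3 / 90))
  expect_equal(round(oral_bioavailability(drug, 90), 1), 0.5)
  expect_equal(oral_bioavailability(drug, 48.6), 0.7 * (1 - 27.3 / 48.6))
  no_hep <- drug
  no_hep$cl_h <- 0
  no_hep$fa <- 1
  expect_equal(oral_bioavailability(no_hep, 90), 1)
  # monotone in flow, decreasing in hepatic clearance
  qs <- seq(40, 200, by = 10)
  expect_true(all(diff(oral_bioavailability(drug, qs)) > 0))
  worse <- drug
  worse$cl_h <- 40
  expect_lt(oral_bioavailability(worse, 90), oral_bioavailability(drug, 90))
})

test_that("only the implemented ionization branches are dispatched", {
  drug <- captopril_parameters()
  drug$ionization_class <- "monoprotic_base"
  expect_error(compute_kp_rodgers_rowland(drug, load_tissue_composition()),
               "monoprotic_base")
})
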