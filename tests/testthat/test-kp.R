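# straight-line reimplementation of the tissue-composition equations for
# ionizable bases with erythrocyte-derived acidic-phospholipid binding,
# kept deliberately independent of the package implementation
kp_oracle_base <- function(rec, comp, hct) {
  P <- 10^rec$logP
  fu <- rec$fu_plasma
  bp <- rec$blood_plasma_ratio
  pka1 <- max(rec$pKa_list); pka2 <- min(rec$pKa_list)
  X <- function(pH) 10^(pka1 - pH) + 10^(pka1 + pka2 - 2 * pH)
  Xp <- X(comp$ph$plasma); Xiw <- X(comp$ph$intracellular); Xbc <- X(comp$ph$blood_cells)
  bc <- comp$blood_cells
  kpu_bc <- (bp - (1 - hct)) / (hct * fu)
  lip <- function(fnl, fnpl) (P * fnl + (0.3 * P + 0.7) * fnpl) / (1 + Xp)
  ka_ap <- (kpu_bc - (1 + Xbc) / (1 + Xp) * bc$f_iw - lip(bc$f_nl, bc$f_npl)) *
    (1 + Xp) / (bc$ap * Xbc)
  tis <- comp$tissues
  kpu <- sapply(seq_len(nrow(tis)), function(i) {
    t <- tis[i, ]
    t$f_ew + (1 + Xiw) / (1 + Xp) * t$f_iw +
      ka_ap * t$ap * Xiw / (1 + Xp) +
      lip(t$f_nl, t$f_npl)
  })
  stats::setNames(kpu * fu, tis$tissue)
}

test_that("partition prediction agrees with an independent transcription of the equations", {
  comp <- tissue_composition()
  set.seed(11)
  for (i in 1:5) {
    rec <- random_base_record()
    # keep within the erythrocyte-association regime of the oracle
    rec$blood_plasma_ratio <- runif(1, 1.2, 2.2)
    got <- predict_kp(rec, comp, hct = 0.45)
    want <- kp_oracle_base(rec, comp, 0.45)
    expect_equal(unclass(got)[names(want)], want, tolerance = 1e-9)
  }
})

test_that("a fully neutral unbound compound partitions like tissue water", {
  rec <- compound_record("waterlike", molecular_weight = 200, logP = 0,
                         pKa_list = numeric(0), compound_type = "neutral",
                         blood_plasma_ratio = 1, fu_plasma = 1,
                         fa = 1, ka = 1)
  kp <- predict_kp(rec)
  expect_true(all(kp > 0))
  expect_true(all(kp < 1.3))  # water fractions plus a unit-logP lipid term
})

test_that("Kp scalar application is uniform and Vss responds linearly", {
  sys <- ref_system()
  das <- dasatinib_record()
  kp <- predict_kp(das, hct = sys$hct)
  expect_false(attr(kp, "scalar_applied"))
  kp07 <- apply_kp_scalar(kp, 0.7)
  expect_true(attr(kp07, "scalar_applied"))
  expect_equal(as.numeric(kp07), as.numeric(kp) * 0.7)

  ones <- structure(stats::setNames(rep(1, 11), pbpk_tissues_names()), class = "kp_set")
  expect_equal(as.numeric(apply_kp_scalar(ones, 0.7)), rep(0.7, 11))

  # tissue term of Vss scales linearly with the scalar
  blood_term <- function(k) vss_from_kp(structure(unclass(k) * 0, class = "kp_set"), sys, das)
  v1 <- vss_from_kp(kp, sys, das) - blood_term(kp)
  v07 <- vss_from_kp(kp07, sys, das) - blood_term(kp)
  expect_equal(v07, 0.7 * v1, tolerance = 1e-12)

  expect_error(apply_kp_scalar(kp, 0), "scalar")
  expect_error(apply_kp_scalar(kp, -1), "scalar")
})

test_that("Vss limiting cases behave", {
  sys <- ref_system()
  # a compound with B/P equal to the plasma fraction has no erythrocyte
  # partitioning; with all tissue Kp zero, Vss is the plasma space
  rec <- inert_compound()
  rec$blood_plasma_ratio <- 1 - sys$hct
  kp0 <- stats::setNames(rep(0, 11), pbpk_tissues_names())
  v_blood <- sys$volumes[["arterial"]] + sys$volumes[["venous"]] + sys$volumes[["portal"]]
  expect_equal(vss_from_kp(kp0, sys, rec),
               (1 - sys$hct) * v_blood / sys$body_weight)
  # all Kp = 1 with B/P 1: whole-body water-equivalent space
  rec$blood_plasma_ratio <- 1
  kp1 <- stats::setNames(rep(1, 11), pbpk_tissues_names())
  tn <- pbpk_tissues_names()
  expect_equal(vss_from_kp(kp1, sys, rec),
               (v_blood + sum(sys$volumes[tn])) / sys$body_weight)
})

test_that("Kp-scalar calibration solves the Vss target exactly", {
  sys <- ref_system()
  das <- dasatinib_record()
  kp <- predict_kp(das, hct = sys$hct)
  s <- calibrate_kp_scalar(kp, sys, das, vss_target = 5.2)
  expect_equal(vss_from_kp(apply_kp_scalar(kp, s), sys, das), 5.2, tolerance = 1e-12)
  expect_error(calibrate_kp_scalar(kp, sys, das, vss_target = 1e-6), "unreachable")
})
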