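test_that("population simulation is seed-reproducible and collapses at zero CV", {
  mod <- pravastatin_model()
  des0 <- trial_design(n_subjects = 3, n_trials = 1, cv_cl = 0, cv_ka = 0, cv_kp = 0,
                       seed = 4, dt = 0.2)
  pop <- run_population(mod, des0, dosing_regimen(40), end_time = 12)
  # all subjects identical to each other (and to the reference individual)
  expect_equal(pop$nca$cmax, rep(pop$nca$cmax[1], 3))
  ref <- simulate_pk(mod, dosing_regimen(40), end_time = 12, dt = 0.2,
                     rtol = des0$rtol, atol = des0$atol)
  expect_equal(pop$nca$cmax[1], max(ref$plasma[-1]), tolerance = 1e-9)

  des <- trial_design(n_subjects = 4, n_trials = 1, seed = 11, dt = 0.2)
  a <- run_population(mod, des, dosing_regimen(40), end_time = 12)
  b <- run_population(mod, des, dosing_regimen(40), end_time = 12)
  expect_identical(a$nca, b$nca)
  expect_false(all(a$nca$auc == a$nca$auc[1]))  # variability is real
})

test_that("geometric-mean exposure converges to the reference individual", {
  mod <- pravastatin_model()
  des <- trial_design(n_subjects = 40, n_trials = 1, cv_ka = 0, cv_kp = 0,
                      seed = 21, dt = 0.25)
  pop <- run_population(mod, des, dosing_regimen(40), end_time = 10)
  ref <- simulate_pk(mod, dosing_regimen(40), end_time = 10, dt = 0.25,
                     rtol = des$rtol, atol = des$atol)
  m_ref <- pk_metrics(ref$time[-1], ref$plasma[-1])
  gm_auc <- exp(mean(log(pop$nca$auc)))
  # median-preserving lognormal variability on clearance: geometric mean
  # AUC matches the reference within Monte-Carlo error (~ cv/sqrt(n))
  expect_equal(gm_auc / m_ref$auc_0_t, 1, tolerance = 3 * 0.30 / sqrt(40))
})

test_that("GMR is exactly 1 without a perpetrator and seeds pin the result", {
  des <- trial_design(n_subjects = 2, n_trials = 1, seed = 31, dt = 0.25)
  r0 <- ddi_gmr(pravastatin_model(), NULL, des, victim_dose = 40, window = 12)
  expect_equal(r0$summary$gmr, c(1, 1))
  expect_true(all(is.na(r0$summary$ci_lo)) || all(r0$summary$ci_lo == 1))

  r1 <- ddi_gmr(pravastatin_model(), dasatinib_model(), des, victim_dose = 40,
                perp_regimen = dosing_regimen(100), co_dose_time = 0, window = 12)
  r2 <- ddi_gmr(pravastatin_model(), dasatinib_model(), des, victim_dose = 40,
                perp_regimen = dosing_regimen(100), co_dose_time = 0, window = 12)
  expect_identical(r1$summary, r2$summary)
  expect_error(trial_design(n_subjects = 2), "seed")
})

test_that("victim exposure ratios are monotone in inhibition potency", {
  des <- trial_design(n_subjects = 2, n_trials = 1, seed = 41, dt = 0.25)
  res <- ddi_scenarios(pravastatin_model(), dasatinib_model(), des, 40,
                       scenarios = list(list(label = "x1"),
                                        list(label = "x10", ki_fold = c(OATP1B1 = 10, OATP1B3 = 10)),
                                        list(label = "x30", ki_fold = c(OATP1B1 = 30, OATP1B3 = 30))),
                       perp_regimen = dosing_regimen(100), co_dose_time = 0, window = 12)
  aucs <- vapply(res, function(r) r$summary$gmr[r$summary$metric == "auc"], numeric(1))
  expect_true(all(diff(aucs) > 0))
  expect_true(all(aucs >= 1))
})

test_that("within-subject pairing drives the narrow confidence intervals", {
  des <- trial_design(n_subjects = 12, n_trials = 1, seed = 51, dt = 0.25)
  r <- ddi_gmr(pravastatin_model(), dasatinib_model(), des, victim_dose = 40,
               perp_regimen = dosing_regimen(100), co_dose_time = 0, window = 12)
  s <- r$subjects
  paired <- log(s$auc_ddi / s$auc_ref)
  set.seed(1)
  shuffled <- log(s$auc_ddi[sample(nrow(s))] / s$auc_ref)
  expect_lt(stats::sd(paired), stats::sd(shuffled) / 3)
})

test_that("confidence-interval width shrinks like 1/sqrt(n)", {
  des <- trial_design(n_subjects = 16, n_trials = 2, seed = 61, dt = 0.25)
  r <- ddi_gmr(pravastatin_model(), dasatinib_model(), des, victim_dose = 40,
               perp_regimen = dosing_regimen(100), co_dose_time = 0, window = 12)
  lr <- log(r$subjects$auc_ddi / r$subjects$auc_ref)
  width <- function(x) {
    g <- pbpkddi:::gmr_summary(exp(x), "auc")
    log(g$ci_hi / g$ci_lo)
  }
  w8 <- width(lr[1:8]); w32 <- width(lr)
  # se scales 1/sqrt(n); allow slack for the t quantile and sampling noise
  expect_gt(w8 / w32, 1.3)
})

test_that("sensitivity sweep resolves parameter paths and flags bad ones", {
  das <- dasatinib_record()
  expect_error(
    sensitivity_sweep(das, "no_such_param", 1, dosing_regimen(100)),
    "does not resolve"
  )
  sw <- sensitivity_sweep(das, "fu_gut", c(0.04, 1), dosing_regimen(100),
                          end_time = 24, dt = 0.1)
  expect_equal(nrow(sw), 2)
  expect_lt(sw$auc[2], sw$auc[1])  # worst-case fu_gut lowers exposure
})
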