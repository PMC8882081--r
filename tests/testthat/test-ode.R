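test_that("mass is conserved with zero clearance and exact with elimination", {
  sys <- ref_system()
  mod0 <- pbpk_model(inert_compound(), system = sys)
  prof <- simulate_pk(mod0, dosing_regimen(50, route = "iv"), end_time = 48)
  am <- attr(prof, "amounts")
  body_cols <- setdiff(colnames(am), c("cum_gutmet", "cum_hepmet", "cum_renal"))
  total <- rowSums(am[, body_cols])[-1]  # first row precedes the t = 0 bolus
  expect_lt(max(abs(total - 50)) / 50, 1e-8)
  expect_equal(sum(am[nrow(am), c("cum_gutmet", "cum_hepmet", "cum_renal")]), 0)

  # oral multiple dose with full elimination bookkeeping
  prof2 <- dasatinib_single_dose()
  expect_lt(mass_balance(prof2), 1e-6)
  prof3 <- simulate_pk(dasatinib_model(), dosing_regimen(100, n_doses = 3, interval = 24),
                       end_time = 72, dt = 0.1)
  expect_lt(mass_balance(prof3), 1e-6)
})

test_that("the assembled linear system matches a matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  sys <- ref_system()
  mod <- pbpk_model(metformin_record(), system = sys)  # linear, mechanistic kidney
  ode_sys <- pbpkddi:::build_disposition_odes(mod)
  ns <- length(ode_sys$state0)
  A <- matrix(0, ns, ns)
  for (j in seq_len(ns)) {
    e <- ode_sys$state0; e[j] <- 1
    A[, j] <- ode_sys$rhs(0, e, NULL)[[1]]
  }
  x0 <- ode_sys$state0
  x0[["venous"]] <- 20  # 20 mg iv bolus
  for (tt in c(2, 12, 36)) {
    x_exact <- as.numeric(Matrix::expm(A * tt) %*% x0)
    sol <- deSolve::ode(x0, c(0, tt), ode_sys$rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
    x_ode <- as.numeric(sol[2, -1])
    denom <- pmax(abs(x_exact), 1e-6 * max(abs(x_exact)))
    expect_lt(max(abs(x_ode - x_exact) / denom), 1e-3)
  }
})

test_that("linear elimination obeys its steady-state and AUC identities", {
  sys <- ref_system()
  rec <- inert_compound(renal_cl = 5)
  mod <- pbpk_model(rec, system = sys)
  # systemic clearance referenced to plasma, corrected for kidney extraction
  qb <- sys$flows[["kidney"]] * rec$blood_plasma_ratio
  cl_eff <- 5 / (1 + 5 / qb)
  # single iv bolus: Dose/AUC_inf equals the closed-form clearance (the
  # initial mixing spike limits the trapezoid accuracy to ~1%)
  p1 <- simulate_pk(mod, dosing_regimen(50, route = "iv"), end_time = 120, dt = 0.02)
  m1 <- pk_metrics(p1$time[-1], p1$plasma[-1])
  expect_equal(50 / m1$auc_inf, cl_eff, tolerance = 0.02)
  # repeat oral dosing to steady state: average concentration over a dosing
  # interval = fa*Dose/(CL*tau)
  p2 <- simulate_pk(mod, dosing_regimen(10, n_doses = 100, interval = 6),
                    end_time = 580, dt = 0.05)
  sel <- p2$time >= 570 & p2$time <= 576
  tt <- p2$time[sel]; cc <- p2$plasma[sel]
  css <- sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2) / 6
  expect_equal(css, rec$fa * 10 / (cl_eff * 6), tolerance = 1e-3)
})

test_that("exposure is dose-proportional across the therapeutic range", {
  doses <- c(15, 50, 100, 240)
  auc <- cmax <- numeric(length(doses))
  for (i in seq_along(doses)) {
    p <- simulate_pk(dasatinib_model(), dosing_regimen(doses[i]), end_time = 48, dt = 0.1)
    m <- pk_metrics(p$time[-1], p$plasma[-1])
    auc[i] <- m$auc_0_t; cmax[i] <- m$cmax
  }
  fit <- stats::lm(log(auc) ~ log(doses))
  expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 0.01)
  expect_gt(summary(fit)$r.squared, 0.99)
  fit2 <- stats::lm(log(cmax) ~ log(doses))
  expect_equal(unname(stats::coef(fit2)[2]), 1, tolerance = 0.01)
})

test_that("simulated dasatinib terminal half-life and repeat-dose linearity", {
  m <- pk_metrics(dasatinib_single_dose()$time[-1], dasatinib_single_dose()$plasma[-1])
  expect_gt(m$t_half, 3); expect_lt(m$t_half, 5)
  # CL/F invariant across QD doses (linear PK; autoinactivation negligible)
  prof <- simulate_pk(dasatinib_model(), dosing_regimen(100, n_doses = 5, interval = 24),
                      end_time = 120, dt = 0.1)
  auc_day <- function(day) {
    sel <- prof$time >= (day - 1) * 24 & prof$time <= day * 24
    pk_metrics(prof$time[sel], prof$plasma[sel])$auc_0_t
  }
  expect_equal(auc_day(5) / auc_day(4), 1, tolerance = 0.01)
})

test_that("profile containers behave: printing, plotting, tidy CSV", {
  prof <- dasatinib_single_dose()
  expect_output(print(prof), "dasatinib")
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, path, subject = 3)
  df <- utils::read.csv(path)
  expect_identical(sort(unique(df$compartment)),
                   sort(c("plasma", "portal_plasma", "liver")))
  expect_true(all(df$subject == 3))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(prof, compartments = c("plasma", "liver")))
})
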