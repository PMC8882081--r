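#' Virtual-trial design
#'
#' Population size, between-subject variability and the random seed for a
#' virtual PK/DDI trial. Variability is log-normal with median 1
#' (meanlog 0), so the reference individual is the geometric-median
#' subject: `cv_cl` applies to all clearance pathways, `cv_ka` to the
#' absorption rate constant and `cv_kp` to the tissue Kp scalar. The seed
#' is mandatory and fixes the full random stream.
#'
#' @param n_subjects Subjects per trial.
#' @param n_trials Number of trials (subjects total = product).
#' @param cv_cl,cv_ka,cv_kp Coefficients of variation (>= 0).
#' @param seed Integer seed (required).
#' @param dt Output grid step for population simulations, h.
#' @param rtol,atol Integrator tolerances for population simulations.
#' @return Object of class `trial_design`.
#' @export
trial_design <- function(n_subjects = 10, n_trials = 10,
                         cv_cl = 0.30, cv_ka = 0.30, cv_kp = 0.20,
                         seed, dt = 0.1, rtol = 1e-6, atol = 1e-9) {
  if (missing(seed) || is.null(seed)) stop("trial_design: 'seed' is required")
  stopifnot(n_subjects >= 1, n_trials >= 1, cv_cl >= 0, cv_ka >= 0, cv_kp >= 0)
  structure(list(n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
                 cv_cl = cv_cl, cv_ka = cv_ka, cv_kp = cv_kp,
                 seed = as.integer(seed), dt = dt, rtol = rtol, atol = atol),
            class = "trial_design")
}

# lognormal sdlog from a CV
sdlog_from_cv <- function(cv) sqrt(log(1 + cv^2))

# Draw subject multipliers for one compound: matrix n x 3
draw_subject_tweaks <- function(design, n) {
  cbind(
    cl_mult = stats::rlnorm(n, 0, sdlog_from_cv(design$cv_cl)),
    ka_mult = stats::rlnorm(n, 0, sdlog_from_cv(design$cv_ka)),
    kp_mult = stats::rlnorm(n, 0, sdlog_from_cv(design$cv_kp))
  )
}

#' Simulate a virtual population on one compound
#'
#' Draws per-subject parameter multipliers under the design's seed and
#' simulates each subject. Identical designs and fixtures give identical
#' output.
#'
#' @param model A [pbpk_model()].
#' @param design A [trial_design()].
#' @param regimen A [dosing_regimen()].
#' @param end_time Simulation end, h.
#' @param inhibition Optional inhibition wiring applied to every subject.
#' @return List with `profiles` (list of `pbpk_profile`), `tweaks`
#'   (matrix), and `nca` (data frame of per-subject Cmax/AUC).
#' @export
run_population <- function(model, design, regimen, end_time, inhibition = NULL) {
  n <- design$n_subjects * design$n_trials
  set.seed(design$seed)
  tw <- draw_subject_tweaks(design, n)
  profiles <- vector("list", n)
  nca <- data.frame(subject = seq_len(n), cmax = NA_real_, auc = NA_real_)
  for (i in seq_len(n)) {
    prof <- simulate_pk(model, regimen, end_time, dt = design$dt,
                        inhibition = inhibition,
                        tweaks = as.list(tw[i, ]),
                        rtol = design$rtol, atol = design$atol)
    m <- pk_metrics(prof$time[-1], prof$plasma[-1])
    nca$cmax[i] <- m$cmax
    nca$auc[i] <- m$auc_0_t
    profiles[[i]] <- prof
  }
  list(profiles = profiles, tweaks = tw, nca = nca)
}

# shift inhibition functions so victim time 0 aligns with co-dose time
shift_inhibition <- function(inh, offset) {
  if (is.null(inh)) return(NULL)
  sh <- function(f) {
    force(f)
    function(t) f(t + offset)
  }
  list(factor = lapply(inh$factor, sh),
       activity = lapply(inh$activity, sh),
       ki_used = inh$ki_used)
}

#' Paired-crossover DDI trial: geometric mean ratios
#'
#' Simulates every virtual subject twice - with and without the
#' perpetrator, under identical parameter draws (within-subject crossover)
#' - and summarizes the geometric mean ratios of victim Cmax and AUC with
#' 90% t-interval confidence limits on the log ratios.
#'
#' The perpetrator is dosed to steady state and the victim is co-dosed
#' with a perpetrator dose (`co_dose_time`); victim PK is followed for
#' `window` hours. Subject variability is drawn separately for victim and
#' perpetrator parameters from the design's seed.
#'
#' @param victim,perpetrator [pbpk_model()] objects.
#' @param design A [trial_design()].
#' @param victim_dose Victim dose, mg (single oral dose).
#' @param perp_regimen Perpetrator regimen (default 100 mg QD x 6).
#' @param co_dose_time Victim dose time on the perpetrator clock, h
#'   (default 96: the day-5 perpetrator dose).
#' @param window Victim follow-up, h.
#' @param ki_overrides,ki_fold Ki override table, see
#'   [perpetrator_inhibition()].
#' @param site_oct2,site_mate Inhibitor-site conventions, see
#'   [perpetrator_inhibition()].
#' @param scenario Label carried into the result.
#' @return Object of class `ddi_result`.
#' @export
ddi_gmr <- function(victim, perpetrator, design,
                    victim_dose,
                    perp_regimen = dosing_regimen(100, n_doses = 6, interval = 24),
                    co_dose_time = 96, window = 36,
                    ki_overrides = NULL, ki_fold = NULL,
                    site_oct2 = "plasma", site_mate = "kidney",
                    scenario = "") {
  ddi_scenarios(victim, perpetrator, design, victim_dose,
                scenarios = list(list(label = scenario,
                                      ki_overrides = ki_overrides,
                                      ki_fold = ki_fold,
                                      site_oct2 = site_oct2,
                                      site_mate = site_mate)),
                perp_regimen = perp_regimen,
                co_dose_time = co_dose_time, window = window)[[1]]
}

#' Run several Ki scenarios of the same DDI trial efficiently
#'
#' Same paired-crossover design as [ddi_gmr()], but the perpetrator
#' simulation and the victim reference simulation of each subject are
#' shared across all Ki scenarios (only the inhibited victim arm is
#' re-simulated per scenario).
#'
#' @inheritParams ddi_gmr
#' @param scenarios List of scenario descriptors: each a list with
#'   optional `label`, `ki_overrides`, `ki_fold`, `site_oct2`,
#'   `site_mate`.
#' @return A list of `ddi_result`, one per scenario.
#' @export
ddi_scenarios <- function(victim, perpetrator, design, victim_dose,
                          scenarios,
                          perp_regimen = dosing_regimen(100, n_doses = 6, interval = 24),
                          co_dose_time = 96, window = 36) {
  stopifnot(inherits(victim, "pbpk_model"), length(scenarios) >= 1)
  has_perp <- !is.null(perpetrator)
  if (has_perp) stopifnot(inherits(perpetrator, "pbpk_model"))
  n <- design$n_subjects * design$n_trials
  set.seed(design$seed)
  tw_v <- draw_subject_tweaks(design, n)
  tw_p <- draw_subject_tweaks(design, n)

  ns <- length(scenarios)
  vic_reg <- dosing_regimen(victim_dose, n_doses = 1)
  res <- lapply(seq_len(ns), function(j) {
    data.frame(subject = seq_len(n),
               cmax_ref = NA_real_, auc_ref = NA_real_,
               cmax_ddi = NA_real_, auc_ddi = NA_real_)
  })
  ki_used <- vector("list", ns)
  for (i in seq_len(n)) {
    pp <- NULL
    if (has_perp) {
      pp <- simulate_pk(perpetrator, perp_regimen,
                        end_time = co_dose_time + window, dt = design$dt,
                        tweaks = as.list(tw_p[i, ]),
                        rtol = design$rtol, atol = design$atol)
    }
    ref <- simulate_pk(victim, vic_reg, end_time = window, dt = design$dt,
                       tweaks = as.list(tw_v[i, ]),
                       rtol = design$rtol, atol = design$atol)
    m_ref <- pk_metrics(ref$time[-1], ref$plasma[-1])
    for (j in seq_len(ns)) {
      sc <- scenarios[[j]]
      inh <- NULL
      if (has_perp) {
        inh0 <- perpetrator_inhibition(
          pp,
          ki_overrides = sc$ki_overrides, ki_fold = sc$ki_fold,
          site_oct2 = if (is.null(sc$site_oct2)) "plasma" else sc$site_oct2,
          site_mate = if (is.null(sc$site_mate)) "kidney" else sc$site_mate)
        ki_used[[j]] <- inh0$ki_used
        inh <- shift_inhibition(inh0, co_dose_time)
      }
      ddi <- simulate_pk(victim, vic_reg, end_time = window, dt = design$dt,
                         inhibition = inh, tweaks = as.list(tw_v[i, ]),
                         rtol = design$rtol, atol = design$atol)
      m_ddi <- pk_metrics(ddi$time[-1], ddi$plasma[-1])
      res[[j]]$cmax_ref[i] <- m_ref$cmax; res[[j]]$auc_ref[i] <- m_ref$auc_0_t
      res[[j]]$cmax_ddi[i] <- m_ddi$cmax; res[[j]]$auc_ddi[i] <- m_ddi$auc_0_t
    }
  }
  lapply(seq_len(ns), function(j) {
    r <- res[[j]]
    bad <- r$auc_ref <= 0 | r$auc_ddi <= 0
    if (any(bad)) {
      warning(sprintf("ddi_scenarios: excluding %d subject(s) with zero AUC", sum(bad)))
      r <- r[!bad, , drop = FALSE]
    }
    summ <- rbind(
      gmr_summary(r$cmax_ddi / r$cmax_ref, "cmax"),
      gmr_summary(r$auc_ddi / r$auc_ref, "auc")
    )
    structure(list(scenario = if (is.null(scenarios[[j]]$label)) "" else scenarios[[j]]$label,
                   victim = victim$compound$name,
                   perpetrator = if (has_perp) perpetrator$compound$name else NA_character_,
                   ki_used = ki_used[[j]],
                   subjects = r,
                   summary = summ),
              class = "ddi_result")
  })
}

# GMR and 90% CI from paired ratios (t interval on log ratios)
gmr_summary <- function(ratio, metric) {
  lr <- log(ratio)
  n <- length(lr)
  gmr <- exp(mean(lr))
  if (n > 1 && stats::sd(lr) > 0) {
    se <- stats::sd(lr) / sqrt(n)
    tq <- stats::qt(0.95, n - 1)
    lo <- exp(mean(lr) - tq * se); hi <- exp(mean(lr) + tq * se)
  } else {
    lo <- NA_real_; hi <- NA_real_
  }
  data.frame(metric = metric, gmr = gmr, ci_lo = lo, ci_hi = hi, n = n)
}

#' @export
print.ddi_result <- function(x, ...) {
  cat(sprintf("<ddi_result> %s + %s%s\n", x$victim,
              if (is.na(x$perpetrator)) "(no perpetrator)" else x$perpetrator,
              if (nzchar(x$scenario)) paste0(" [", x$scenario, "]") else ""))
  if (!is.null(x$ki_used)) {
    cat("  Ki (uM):", paste(sprintf("%s %.4g", names(x$ki_used), x$ki_used),
                            collapse = ", "), "\n")
  }
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  GMR %-4s %.3f (90%% CI %.3f-%.3f), n = %d\n",
                toupper(s$metric[i]), s$gmr[i], s$ci_lo[i], s$ci_hi[i], s$n[i]))
  }
  invisible(x)
}

#' Sensitivity sweep over a compound or model parameter
#'
#' Rebuilds the model for each value of a parameter (addressed by a path
#' into the compound record, e.g. `"fu_gut"` or
#' `c("kidney_model", "ps_oct2")`), simulates a reference subject and
#' tabulates exposure.
#'
#' @param compound A [compound_record()].
#' @param param Character vector path into the record.
#' @param values Numeric values to sweep.
#' @param regimen A [dosing_regimen()].
#' @param end_time Simulation end, h.
#' @param system A [physiology_system()].
#' @param dt Output step, h.
#' @param ... Passed to [pbpk_model()].
#' @return Data frame with `value`, `cmax`, `auc` (one row per value).
#' @export
sensitivity_sweep <- function(compound, param, values, regimen, end_time = 24,
                              system = physiology_system(), dt = 0.05, ...) {
  if (!is.character(param) || length(param) < 1) {
    stop("sensitivity_sweep: 'param' must be a character path")
  }
  rec0 <- compound
  # validate the path resolves
  probe <- rec0
  for (p in param) {
    if (!is.list(probe) || !(p %in% names(probe))) {
      stop(sprintf("sensitivity_sweep: parameter path '%s' does not resolve in the record",
                   paste(param, collapse = "$")))
    }
    probe <- probe[[p]]
  }
  # Calibrated/derived quantities (gut CLint, retrograde CLints, Kp scalar)
  # are frozen at their base-model values so the sweep varies only the
  # chosen parameter, not the calibrations that depend on it.
  base_mod <- pbpk_model(rec0, system = system, ...)
  rec0 <- freeze_derived(rec0, base_mod)
  out <- data.frame(value = values, cmax = NA_real_, auc = NA_real_)
  for (j in seq_along(values)) {
    rec <- rec0
    rec[[param]] <- values[j]
    rec <- validate_compound_record(rec)
    mod <- pbpk_model(rec, system = system, clearance = "library", ...)
    prof <- simulate_pk(mod, regimen, end_time, dt = dt)
    m <- pk_metrics(prof$time[-1], prof$plasma[-1])
    out$cmax[j] <- m$cmax
    out$auc[j] <- m$auc_0_t
  }
  out
}

# Materialize a model's calibrated quantities back into its record so a
# rebuilt record reproduces the model without re-running calibrations.
freeze_derived <- function(record, model) {
  record$clu_int_gut <- model$gut$clu_int_gut
  record$kp_scalar <- model$kp_scalar
  record$vss_target <- NULL
  sc <- liver_scaling(model$system)
  if (length(model$hepatic_enzyme_clint)) {
    record$cyp_clint <- model$hepatic_enzyme_clint / sc$pmol * 1e6 / 60
  }
  record$additional_hlm_clint <- model$hepatic_additional_clint / sc$mg * 1e6 / 60
  record$retrograde <- NULL
  if (!is.null(model$kidney)) {
    record$kidney_model <- unclass(model$kidney)
  }
  record
}
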