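#' Assemble a whole-body PBPK model for a compound
#'
#' Builds the perfusion-limited whole-body disposition model for one
#' compound in a reference physiology: predicts tissue:plasma partition
#' coefficients, applies (or calibrates) the Kp scalar, sets up the oral
#' first-pass (Q_gut) model, and resolves the elimination terms (per-enzyme
#' hepatic intrinsic clearance - retrograde-derived or taken from the
#' library record - plus renal clearance, the mechanistic kidney model or
#' hepatic-uptake model where parameterized).
#'
#' Distribution calibration: when the record carries `vss_target`, the
#' uniform Kp scalar is solved so the model Vss equals it (re-performing
#' the fit-to-observed-PK step under this package's physiology); otherwise
#' the record's `kp_scalar` is applied as given.
#'
#' @param compound A [compound_record()].
#' @param system A [physiology_system()].
#' @param clearance `"auto"` (retrograde when the record has a retrograde
#'   block, else library CLints), `"retrograde"` or `"library"`.
#' @param composition Tissue-composition table from [tissue_composition()].
#' @param rtol,atol Default integrator tolerances for this model.
#' @return An object of class `pbpk_model`.
#' @examples
#' \donttest{
#' mod <- pbpk_model(pbpk_example_compound("dasatinib"))
#' mod
#' }
#' @export
pbpk_model <- function(compound, system = physiology_system(),
                       clearance = c("auto", "retrograde", "library"),
                       composition = tissue_composition(),
                       rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(compound, "compound_record"))
  clearance <- match.arg(clearance)

  kp_raw <- predict_kp(compound, composition, hct = system$hct)
  if (!is.null(compound$vss_target)) {
    scalar <- calibrate_kp_scalar(kp_raw, system, compound, compound$vss_target)
    scalar_source <- "vss_calibrated"
  } else {
    scalar <- compound$kp_scalar
    scalar_source <- "record"
  }
  kp <- apply_kp_scalar(kp_raw, scalar)
  vss <- vss_from_kp(kp, system, compound)

  gut <- compound_gut_params(compound, system)

  use_retro <- switch(clearance,
    retrograde = TRUE,
    library = FALSE,
    auto = !is.null(compound$retrograde) && !is.null(compound$clpo)
  )
  if (use_retro) {
    if (is.null(compound$retrograde) || is.null(compound$clpo)) {
      stop("pbpk_model: retrograde clearance requested but the record has no retrograde block")
    }
    rg <- retrograde_clint(compound$clpo, compound$retrograde$fm,
                           compound$retrograde$fa, compound$renal_cl,
                           compound, system)
    hep_enz <- clint_per_pmol_to_whole(rg$cyp_clint, system)
    hep_addl <- clint_per_mg_to_whole(rg$additional_hlm_clint, system)
  } else {
    hep_enz <- if (is.null(compound$cyp_clint)) numeric(0) else
      clint_per_pmol_to_whole(compound$cyp_clint, system)
    hep_addl <- if (is.null(compound$additional_hlm_clint)) 0 else
      clint_per_mg_to_whole(compound$additional_hlm_clint, system)
  }

  kidney <- NULL
  if (!is.null(compound$kidney_model)) {
    kidney <- calibrate_kidney_model(compound$kidney_model, compound, system)
  }

  mbi <- get_interaction(compound, "CYP3A4", "mechanism_based")
  ind <- get_interaction(compound, "CYP3A4", "induction")
  self_mbi <- if (!is.null(mbi)) list(kapp = mbi$kapp, kinact = mbi$kinact * 60) else NULL
  self_ind <- if (!is.null(ind)) list(ind_max = ind$ind_max, ind_c50 = ind$ind_c50) else NULL

  structure(list(
    compound = compound,
    system = system,
    kp = kp,
    kp_scalar = scalar,
    kp_scalar_source = scalar_source,
    vss = vss,
    gut = gut,
    fg = gut_fg(gut),
    clearance_source = if (use_retro) "retrograde" else "library",
    hepatic_enzyme_clint = hep_enz,     # whole-liver L/h per enzyme
    hepatic_additional_clint = hep_addl, # whole-liver L/h
    hepatic_uptake = compound$hepatic_uptake,
    renal_cl = compound$renal_cl,
    kidney = kidney,
    self_mbi = self_mbi,               # kinact converted to 1/h
    self_induction = self_ind,
    rtol = rtol, atol = atol
  ), class = "pbpk_model")
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat(sprintf("<pbpk_model> %s in %0.f-kg reference human\n",
              x$compound$name, x$system$body_weight))
  cat(sprintf("  Vss %.2f L/kg (Kp scalar %.3g, %s)\n",
              x$vss, x$kp_scalar, x$kp_scalar_source))
  cat(sprintf("  fa %.4g, ka %.3g 1/h, Fg %.3f (fu_gut %.3g)\n",
              x$gut$fa, x$gut$ka, x$fg, x$gut$fu_gut))
  clint <- sum(x$hepatic_enzyme_clint) + x$hepatic_additional_clint
  fu_b <- x$compound$fu_plasma / x$compound$blood_plasma_ratio
  qh <- derived_flows(x$system)[["q_liver"]]
  hp <- hepatic_cl(qh, fu_b, clint + sum(x$hepatic_uptake))
  cat(sprintf("  hepatic CLint_u %.4g L/h (%s), Fh %.3f; renal CL %.3g L/h%s\n",
              clint + sum(x$hepatic_uptake), x$clearance_source, hp$fh, x$renal_cl,
              if (!is.null(x$kidney)) " [mechanistic kidney]" else ""))
  if (is_perpetrator_capable(x$compound)) {
    tg <- vapply(x$compound$interaction_set, function(i) i$target, character(1))
    cat("  perpetrator of:", paste(unique(tg), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.pbpk_model <- function(object, ...) {
  c(vss_L_per_kg = object$vss,
    kp_scalar = object$kp_scalar,
    fg = object$fg,
    fa = object$gut$fa,
    ka_per_h = object$gut$ka,
    hepatic_clint_u_L_per_h = sum(object$hepatic_enzyme_clint) +
      object$hepatic_additional_clint + sum(object$hepatic_uptake),
    renal_cl_L_per_h = object$renal_cl)
}

#' @export
summary.pbpk_model <- function(object, ...) {
  out <- list(compound = object$compound$name,
              coef = coef(object),
              kp = unclass(object$kp),
              availability = oral_availability(object))
  class(out) <- "summary.pbpk_model"
  out
}

#' @export
print.summary.pbpk_model <- function(x, ...) {
  cat(sprintf("PBPK model summary: %s\n", x$compound))
  print(round(x$coef, 4))
  cat("Oral availability:\n"); print(round(x$availability, 4))
  cat("Tissue Kp:\n"); print(round(x$kp, 3))
  invisible(x)
}

#' @export
simulate.pbpk_model <- function(object, nsim = 1, seed = NULL, ...,
                                regimen, end_time, design = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nsim == 1 && is.null(design)) return(simulate_pk(object, regimen, end_time, ...))
  if (is.null(design)) {
    design <- trial_design(n_subjects = nsim, n_trials = 1,
                           seed = if (is.null(seed)) stop("simulate: 'seed' required for nsim > 1") else seed)
  }
  run_population(object, design, regimen, end_time)$profiles
}

#' Oral-availability summary of a model
#'
#' F = fa * Fg * Fh and the implied steady-state oral clearance CL/F.
#'
#' @param model A [pbpk_model()].
#' @param fa Optional override of the fraction absorbed (e.g. the value
#'   assumed in a retrograde derivation).
#' @return Named vector with `fa`, `fg`, `fh`, `F`, `cl_over_f` (L/h).
#' @export
oral_availability <- function(model, fa = NULL) {
  if (is.null(fa)) fa <- model$gut$fa
  cmp <- model$compound
  bp <- cmp$blood_plasma_ratio
  fu_b <- cmp$fu_plasma / bp
  qh <- derived_flows(model$system)[["q_liver"]]
  clint <- sum(model$hepatic_enzyme_clint) + model$hepatic_additional_clint +
    sum(model$hepatic_uptake)
  hp <- hepatic_cl(qh, fu_b, clint)
  f <- fa * model$fg * hp$fh
  x <- cmp$fu_plasma * clint
  clf <- (x + model$renal_cl * (1 + x / (bp * qh))) / (fa * model$fg)
  c(fa = fa, fg = model$fg, fh = hp$fh, F = f, cl_over_f = clf)
}
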