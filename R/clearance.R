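#' Competitive inhibition factor
#'
#' `1 + I_u / Ki`; the affected intrinsic clearance or
#' permeability-surface term is divided by this factor.
#'
#' @param i_unbound Unbound inhibitor concentration at the site, uM (>= 0).
#' @param ki Inhibition constant, uM (> 0).
#' @return Factor >= 1.
#' @export
inhibition_factor <- function(i_unbound, ki) {
  if (!is.numeric(ki) || any(ki <= 0)) stop("'ki' must be > 0")
  if (!is.numeric(i_unbound) || any(i_unbound < 0)) stop("'i_unbound' must be >= 0")
  1 + i_unbound / ki
}

#' Rate of change of enzyme activity under inactivation and induction
#'
#' Enzyme turnover with mechanism-based inactivation and induction:
#' `dE/dt = kdeg * (1 + ind_max * I/(ind_c50 + I))
#'          - E * (kdeg + kinact * I/(kapp + I))`,
#' with baseline activity `E = 1`. With constant inhibitor the steady state
#' is the ratio of the synthesis and loss rates.
#'
#' @param E Current activity (fraction of baseline, > 0).
#' @param i_unbound Unbound inhibitor concentration at the enzyme site, uM.
#' @param mbi `NULL` or list with `kapp` (uM) and `kinact` (1/h).
#' @param induction `NULL` or list with `ind_max` and `ind_c50` (uM).
#' @param kdeg First-order enzyme degradation rate, 1/h.
#' @return dE/dt (1/h).
#' @seealso [enzyme_activity_steady_state()]
#' @export
enzyme_activity_ode <- function(E, i_unbound, mbi = NULL, induction = NULL, kdeg) {
  synth <- kdeg
  if (!is.null(induction)) {
    synth <- kdeg * (1 + induction$ind_max * i_unbound / (induction$ind_c50 + i_unbound))
  }
  loss <- kdeg
  if (!is.null(mbi)) {
    loss <- loss + mbi$kinact * i_unbound / (mbi$kapp + i_unbound)
  }
  synth - E * loss
}

#' Closed-form steady state of the enzyme-activity equation
#'
#' @inheritParams enzyme_activity_ode
#' @return E at steady state for constant `i_unbound`.
#' @export
enzyme_activity_steady_state <- function(i_unbound, mbi = NULL, induction = NULL, kdeg) {
  synth <- kdeg
  if (!is.null(induction)) {
    synth <- kdeg * (1 + induction$ind_max * i_unbound / (induction$ind_c50 + i_unbound))
  }
  loss <- kdeg
  if (!is.null(mbi)) {
    loss <- loss + mbi$kinact * i_unbound / (mbi$kapp + i_unbound)
  }
  synth / loss
}

#' Well-stirred hepatic clearance
#'
#' `CLh = Qh * fu_b * CLint_u / (Qh + fu_b * CLint_u)` (blood clearance)
#' and hepatic availability `Fh = 1 - CLh/Qh`.
#'
#' @param q_h Hepatic blood flow, L/h.
#' @param fu_b Fraction unbound in blood (fu_plasma / blood:plasma ratio).
#' @param clint_u Whole-liver unbound intrinsic clearance, L/h.
#' @return List with `clh` (L/h blood) and `fh`.
#' @export
hepatic_cl <- function(q_h, fu_b, clint_u) {
  stopifnot(q_h > 0, fu_b > 0, clint_u >= 0)
  clh <- q_h * fu_b * clint_u / (q_h + fu_b * clint_u)
  list(clh = clh, fh = 1 - clh / q_h)
}

# liver scaling factor: pmol CYP in whole liver, and mg microsomal protein
liver_scaling <- function(system) {
  mg <- system$mppgl * system$liver_weight              # mg microsomal protein
  list(mg = mg, pmol = system$cyp3a4_abundance * mg)    # pmol CYP3A4
}

# uL/min/pmol -> whole-liver L/h
clint_per_pmol_to_whole <- function(clint, system) {
  clint * liver_scaling(system)$pmol * 60 / 1e6
}

# uL/min/mg -> whole-liver L/h
clint_per_mg_to_whole <- function(clint, system) {
  clint * liver_scaling(system)$mg * 60 / 1e6
}

#' Retrograde derivation of intrinsic clearance from oral clearance
#'
#' Solves the plasma-referenced well-stirred oral-clearance relation
#' `CL/F = fu * CLint_u / (fa * Fg) + CLr / (fa * Fg * Fh)` for the
#' whole-liver unbound intrinsic clearance, partitions it across enzymes by
#' their fractions metabolized `fm`, and scales the CYP shares to
#' uL/min/pmol enzyme (via hepatic abundance x MPPGL x liver weight) and the
#' non-attributed remainder to uL/min/mg microsomal protein. Forward
#' simulation with the returned clearances reproduces the input CL/F
#' (round-trip identity) when run with the same `fa` and gut model.
#'
#' @param clpo Observed oral clearance CL/F, L/h.
#' @param fm_by_enzyme Named fractions metabolized per CYP enzyme
#'   (e.g. `c(CYP3A4 = 0.825)`); values in `[0, 1]`, sum <= 1. The
#'   remainder `1 - sum(fm)` becomes additional HLM clearance.
#' @param fa Fraction absorbed assumed in the derivation.
#' @param renal_cl Renal clearance, L/h (plasma-referenced); must satisfy
#'   `clpo * fa * Fg > renal_cl`.
#' @param compound A [compound_record()] supplying binding and gut-model
#'   parameters.
#' @param system A [physiology_system()].
#' @return List with `cyp_clint` (named, uL/min/pmol),
#'   `additional_hlm_clint` (uL/min/mg), `clint_u_whole` (L/h),
#'   `fg` and `fh` used.
#' @export
retrograde_clint <- function(clpo, fm_by_enzyme, fa, renal_cl, compound, system) {
  stopifnot(clpo > 0, fa > 0, fa <= 1, renal_cl >= 0)
  if (any(fm_by_enzyme < 0) || any(fm_by_enzyme > 1) || sum(fm_by_enzyme) > 1 + 1e-12) {
    stop("retrograde_clint: fm values must lie in [0,1] and sum to <= 1")
  }
  gp <- compound_gut_params(compound, system)
  fg <- gut_fg(gp)
  d <- derived_flows(system)
  qh <- d[["q_liver"]]
  bp <- compound$blood_plasma_ratio
  fu <- compound$fu_plasma
  fu_b <- fu / bp
  # plasma-referenced oral clearance: CLpo*fa*Fg = fu*CLint_u + CLr*(1 + fu*CLint_u/(bp*Qh))
  x <- (clpo * fa * fg - renal_cl) / (1 + renal_cl / (bp * qh))  # x = fu * CLint_u
  if (x <= 0) {
    stop(sprintf(
      "retrograde_clint: CL/F %.3g L/h is unreachable (fa*Fg oral availability cannot exceed renal clearance %.3g L/h)",
      clpo, renal_cl))
  }
  clint_u <- x / fu
  sc <- liver_scaling(system)
  cyp <- fm_by_enzyme * clint_u                      # whole-liver L/h
  cyp_per_pmol <- cyp / sc$pmol * 1e6 / 60           # uL/min/pmol
  addl <- (1 - sum(fm_by_enzyme)) * clint_u
  addl_per_mg <- addl / sc$mg * 1e6 / 60             # uL/min/mg
  fh <- hepatic_cl(qh, fu_b, clint_u)$fh
  list(cyp_clint = cyp_per_pmol, additional_hlm_clint = addl_per_mg,
       clint_u_whole = clint_u, fg = fg, fh = fh)
}

# Gut-model parameters for a compound: CLu_int,gut is calibrated once per
# compound so that the fu_gut = 1 scenario gives 50% of the base-case
# exposure when the compound has enteric CYP3A4 metabolism (dasatinib); for
# compounds without gut metabolism it is 0.
compound_gut_params <- function(compound, system, fu_gut = NULL) {
  if (is.null(fu_gut)) fu_gut <- compound$fu_gut
  clu <- compound$clu_int_gut
  if (is.null(clu)) {
    clu <- if (isTRUE(compound$gut_cyp3a4)) {
      calibrate_gut_clint(system$q_gut, fu_base = compound$fu_gut)
    } else 0
  }
  gut_model_params(fa = compound$fa, ka = compound$ka, fu_gut = fu_gut,
                   q_gut = system$q_gut, clu_int_gut = clu)
}
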