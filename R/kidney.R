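#' Mechanistic kidney victim model (electrochemical-gradient-driven)
#'
#' Proximal-tubule secretion model for renally secreted cations: OCT2
#' mediates basolateral uptake from kidney blood into tubule cells (favoured
#' by the membrane electrochemical gradient, folded into the uptake
#' permeability-surface product), MATE mediates proton-coupled apical efflux
#' into urine, with a bidirectional passive term and glomerular filtration.
#'
#' `ps_mate` may be `NULL`, in which case [calibrate_kidney_model()] solves
#' it so that the baseline (no inhibitor) net renal clearance, referenced to
#' arterial plasma, equals the victim's reference `renal_cl`.
#'
#' @param ps_oct2 OCT2-mediated basolateral uptake PS, L/h (unbound,
#'   gradient multiplier included).
#' @param ps_passive Bidirectional passive basolateral PS, L/h.
#' @param ps_mate MATE-mediated apical efflux PS, L/h, or `NULL` to
#'   calibrate.
#' @param cell_volume Tubule-cell compartment volume, L.
#' @param vasc_volume Kidney vascular (blood) compartment volume, L.
#' @param fu_cell Fraction unbound in tubule cells.
#' @return An object of class `kidney_victim_model`.
#' @export
kidney_victim_model <- function(ps_oct2, ps_passive, ps_mate = NULL,
                                cell_volume = 0.15, vasc_volume = 0.08,
                                fu_cell = 1) {
  stopifnot(ps_oct2 >= 0, ps_passive >= 0, cell_volume > 0, vasc_volume > 0,
            fu_cell > 0, fu_cell <= 1)
  if (!is.null(ps_mate)) stopifnot(ps_mate >= 0)
  structure(list(ps_oct2 = ps_oct2, ps_passive = ps_passive, ps_mate = ps_mate,
                 cell_volume = cell_volume, vasc_volume = vasc_volume,
                 fu_cell = fu_cell),
            class = "kidney_victim_model")
}

#' Steady-state renal clearance of the kidney victim model
#'
#' Closed form used for calibration and testing. The local clearance with
#' respect to unbound kidney-blood concentration is
#' `GFR + PS_mate * (PS_oct2 + PS_pass) / (PS_mate + PS_pass)`; with plasma
#' binding and vascular extraction the systemic renal clearance referenced
#' to arterial plasma is `CL_local / (1 + CL_local / (Q_kidney * B/P))`.
#'
#' @param km A [kidney_victim_model()] (with `ps_mate` set).
#' @param compound A [compound_record()].
#' @param system A [physiology_system()].
#' @param f_oct2,f_mate Optional constant inhibition factors (>= 1).
#' @return Renal clearance, L/h, referenced to arterial plasma.
#' @export
kidney_model_renal_cl <- function(km, compound, system, f_oct2 = 1, f_mate = 1) {
  pso <- km$ps_oct2 / f_oct2
  psm <- km$ps_mate / f_mate
  psp <- km$ps_passive
  clsec_u <- if (psm + psp > 0) psm * (pso + psp) / (psm + psp) else 0
  cl_local <- compound$fu_plasma * (system$gfr + clsec_u)
  qb <- system$flows[["kidney"]] * compound$blood_plasma_ratio
  cl_local / (1 + cl_local / qb)
}

#' Calibrate the MATE efflux PS to a reference renal clearance
#'
#' @param km_spec List or [kidney_victim_model()]; `ps_mate` may be `NULL`.
#' @param compound A [compound_record()]; its `renal_cl` is the target.
#' @param system A [physiology_system()].
#' @return A `kidney_victim_model` with `ps_mate` filled in.
#' @export
calibrate_kidney_model <- function(km_spec, compound, system) {
  km <- do.call(kidney_victim_model, km_spec[intersect(names(km_spec),
    c("ps_oct2", "ps_passive", "ps_mate", "cell_volume", "vasc_volume", "fu_cell"))])
  target <- compound$renal_cl
  if (target <= 0) stop("calibrate_kidney_model: victim has no reference renal clearance")
  if (!is.null(km$ps_mate)) return(km)
  qb <- system$flows[["kidney"]] * compound$blood_plasma_ratio
  if (target >= qb) {
    stop("calibrate_kidney_model: renal clearance target exceeds kidney blood flow")
  }
  cl_local <- target / (1 - target / qb)
  clsec_u <- (cl_local - compound$fu_plasma * system$gfr) / compound$fu_plasma
  if (clsec_u < 0) {
    stop("calibrate_kidney_model: target renal clearance is below filtration alone")
  }
  if (km$ps_passive <= 0) {
    stop("calibrate_kidney_model: calibration needs a positive passive PS (secretion is otherwise insensitive to the efflux PS)")
  }
  denom <- km$ps_oct2 + km$ps_passive - clsec_u
  if (denom <= 0) {
    stop("calibrate_kidney_model: basolateral uptake too small to sustain the target secretion")
  }
  km$ps_mate <- clsec_u * km$ps_passive / denom
  km
}
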