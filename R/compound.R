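#' Interaction parameter for an enzyme or transporter
#'
#' One entry of a compound's interaction set: the target protein, the
#' mechanism, and exactly the constants that mechanism needs.
#'
#' @param target Identifier such as `"CYP3A4"`, `"OCT2"`, `"MATE"`,
#'   `"OATP1B1"`, `"OATP1B3"`.
#' @param mechanism `"reversible"` (needs `ki`), `"mechanism_based"` (needs
#'   `kapp` and `kinact`) or `"induction"` (needs `ind_max` and `ind_c50`).
#' @param ki Reversible inhibition constant, uM.
#' @param kapp Inhibitor concentration at half-maximal inactivation, uM.
#' @param kinact Maximal inactivation rate, 1/min.
#' @param ind_max Maximal fold-increase in enzyme synthesis (dimensionless).
#' @param ind_c50 Inducer concentration at half-maximal induction, uM.
#' @return An object of class `interaction_param`.
#' @export
interaction_param <- function(target, mechanism = c("reversible", "mechanism_based", "induction"),
                              ki = NULL, kapp = NULL, kinact = NULL,
                              ind_max = NULL, ind_c50 = NULL) {
  mechanism <- match.arg(mechanism)
  need <- switch(mechanism,
    reversible = list(ki = ki),
    mechanism_based = list(kapp = kapp, kinact = kinact),
    induction = list(ind_max = ind_max, ind_c50 = ind_c50)
  )
  for (nm in names(need)) {
    v <- need[[nm]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop(sprintf("interaction_param: '%s' must be a single positive number for mechanism '%s'",
                   nm, mechanism))
    }
  }
  extra <- setdiff(c("ki", "kapp", "kinact", "ind_max", "ind_c50"), names(need))
  for (nm in extra) {
    if (!is.null(get(nm))) {
      stop(sprintf("interaction_param: '%s' is not a field of mechanism '%s'", nm, mechanism))
    }
  }
  structure(c(list(target = as.character(target), mechanism = mechanism), need),
            class = "interaction_param")
}

#' Compound parameter record
#'
#' Validated container for all per-drug inputs of the PBPK model:
#' physicochemistry, plasma/blood binding, oral absorption, distribution,
#' elimination and the interaction constants the compound exerts on enzymes
#' and transporters.
#'
#' A record is *victim-capable* when it carries elimination parameters
#' (metabolic or renal clearance, or a mechanistic kidney / hepatic-uptake
#' block); it is *perpetrator-capable* when its interaction set is non-empty.
#'
#' @param name Compound name.
#' @param molecular_weight g/mol.
#' @param logP Octanol-water log partition coefficient.
#' @param pKa_list Numeric vector of acid dissociation constants (may be
#'   empty for neutral compounds).
#' @param compound_type One of `"neutral"`, `"monoprotic base"`,
#'   `"diprotic base"`, `"monoprotic acid"`, `"diprotic acid"`.
#' @param blood_plasma_ratio Blood:plasma concentration ratio.
#' @param fu_plasma Fraction unbound in plasma, (0, 1].
#' @param fa Fraction absorbed, (0, 1].
#' @param ka First-order absorption rate constant, 1/h.
#' @param fu_gut Fraction unbound in enterocytes, (0, 1].
#' @param gut_cyp3a4 Logical; does the compound undergo enteric CYP3A4
#'   metabolism (activates the Q_gut first-pass model)?
#' @param clu_int_gut Optional unbound intestinal intrinsic clearance, L/h.
#'   When absent and `gut_cyp3a4` is `TRUE`, model assembly calibrates it
#'   from the exposure-ratio anchor (see [calibrate_gut_clint()]).
#' @param kp_scalar Uniform scalar applied to predicted tissue Kps (> 0).
#' @param vss_target Optional observed steady-state volume (L/kg). When
#'   present, model assembly re-solves the Kp scalar so the predicted Vss
#'   matches this value (the distribution-calibration step); when absent,
#'   `kp_scalar` is applied as given.
#' @param clpo Observed oral clearance CL/F, L/h (optional; input to the
#'   retrograde clearance derivation).
#' @param retrograde Optional list with elements `fm` (named fractions
#'   metabolized per CYP enzyme) and `fa` (fraction absorbed assumed in the
#'   retrograde derivation).
#' @param cyp_clint Named numeric vector of per-enzyme intrinsic clearances,
#'   uL/min/pmol enzyme.
#' @param additional_hlm_clint Additional (non-attributed) human liver
#'   microsomal intrinsic clearance, uL/min/mg protein.
#' @param renal_cl Renal clearance referenced to plasma, L/h.
#' @param kidney_model Optional list parameterizing the mechanistic kidney
#'   victim model; see [kidney_victim_model()].
#' @param hepatic_uptake Optional named numeric vector of sinusoidal uptake
#'   intrinsic clearances in L/h, e.g.
#'   `c(OATP1B1 = 122, OATP1B3 = 51, passive = 30)`.
#' @param interaction_set List of [interaction_param()] objects.
#' @return An object of class `compound_record`.
#' @examples
#' rec <- compound_record("drugX", molecular_weight = 300, logP = 2,
#'   pKa_list = numeric(0), compound_type = "neutral",
#'   blood_plasma_ratio = 1, fu_plasma = 0.5, fa = 0.9, ka = 1,
#'   fu_gut = 1, kp_scalar = 1, renal_cl = 2)
#' @export
compound_record <- function(name,
                            molecular_weight,
                            logP,
                            pKa_list = numeric(0),
                            compound_type = "neutral",
                            blood_plasma_ratio = 1,
                            fu_plasma,
                            fa,
                            ka,
                            fu_gut = 1,
                            gut_cyp3a4 = FALSE,
                            clu_int_gut = NULL,
                            kp_scalar = 1,
                            vss_target = NULL,
                            clpo = NULL,
                            retrograde = NULL,
                            cyp_clint = NULL,
                            additional_hlm_clint = NULL,
                            renal_cl = 0,
                            kidney_model = NULL,
                            hepatic_uptake = NULL,
                            interaction_set = list()) {
  rec <- structure(list(
    name = as.character(name),
    molecular_weight = molecular_weight,
    logP = logP,
    pKa_list = as.numeric(pKa_list),
    compound_type = compound_type,
    blood_plasma_ratio = blood_plasma_ratio,
    fu_plasma = fu_plasma,
    fa = fa,
    ka = ka,
    fu_gut = fu_gut,
    gut_cyp3a4 = isTRUE(gut_cyp3a4),
    clu_int_gut = clu_int_gut,
    kp_scalar = kp_scalar,
    vss_target = vss_target,
    clpo = clpo,
    retrograde = retrograde,
    cyp_clint = cyp_clint,
    additional_hlm_clint = additional_hlm_clint,
    renal_cl = renal_cl,
    kidney_model = kidney_model,
    hepatic_uptake = hepatic_uptake,
    interaction_set = interaction_set
  ), class = "compound_record")
  validate_compound_record(rec)
}

#' @rdname compound_record
#' @param x A `compound_record`.
#' @export
validate_compound_record <- function(x) {
  chk_frac <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0 || v > 1) {
      stop(sprintf("compound_record '%s': field '%s' must be a fraction in (0, 1]",
                   x$name, nm), call. = FALSE)
    }
  }
  chk_pos <- function(v, nm, strict = TRUE) {
    ok <- is.numeric(v) && all(is.finite(v)) && (if (strict) all(v > 0) else all(v >= 0))
    if (!ok) {
      stop(sprintf("compound_record '%s': field '%s' must be %s",
                   x$name, nm, if (strict) "positive" else "non-negative"), call. = FALSE)
    }
  }
  required <- c("molecular_weight", "logP", "blood_plasma_ratio", "fu_plasma",
                "fa", "ka", "fu_gut", "kp_scalar")
  for (nm in required) {
    if (is.null(x[[nm]])) {
      stop(sprintf("compound_record '%s': missing required field '%s'", x$name, nm),
           call. = FALSE)
    }
  }
  chk_pos(x$molecular_weight, "molecular_weight")
  if (!is.numeric(x$logP) || !is.finite(x$logP)) {
    stop(sprintf("compound_record '%s': field 'logP' must be finite", x$name), call. = FALSE)
  }
  chk_pos(x$blood_plasma_ratio, "blood_plasma_ratio")
  chk_frac(x$fu_plasma, "fu_plasma")
  chk_frac(x$fa, "fa")
  chk_pos(x$ka, "ka")
  chk_frac(x$fu_gut, "fu_gut")
  if (!is.null(x$clu_int_gut)) chk_pos(x$clu_int_gut, "clu_int_gut", strict = FALSE)
  chk_pos(x$kp_scalar, "kp_scalar")
  if (!is.null(x$vss_target)) chk_pos(x$vss_target, "vss_target")
  if (!is.null(x$clpo)) chk_pos(x$clpo, "clpo")
  if (!is.null(x$cyp_clint)) {
    chk_pos(x$cyp_clint, "cyp_clint", strict = FALSE)
    if (is.null(names(x$cyp_clint)) || any(names(x$cyp_clint) == "")) {
      stop(sprintf("compound_record '%s': 'cyp_clint' must be named by enzyme", x$name),
           call. = FALSE)
    }
  }
  if (!is.null(x$additional_hlm_clint)) chk_pos(x$additional_hlm_clint, "additional_hlm_clint", strict = FALSE)
  chk_pos(x$renal_cl, "renal_cl", strict = FALSE)
  if (!is.null(x$hepatic_uptake)) chk_pos(x$hepatic_uptake, "hepatic_uptake", strict = FALSE)
  if (!is.null(x$retrograde)) {
    fm <- x$retrograde$fm
    if (is.null(fm) || any(fm < 0) || any(fm > 1) || sum(fm) > 1 + 1e-12) {
      stop(sprintf("compound_record '%s': retrograde 'fm' values must lie in [0,1] and sum to <= 1",
                   x$name), call. = FALSE)
    }
  }
  for (ip in x$interaction_set) {
    if (!inherits(ip, "interaction_param")) {
      stop(sprintf("compound_record '%s': interaction_set entries must be interaction_param objects",
                   x$name), call. = FALSE)
    }
  }
  x
}

#' @export
print.compound_record <- function(x, ...) {
  cat(sprintf("<compound_record> %s\n", x$name))
  cat(sprintf("  MW %.2f g/mol, logP %.2f, %s (pKa %s)\n",
              x$molecular_weight, x$logP, x$compound_type,
              if (length(x$pKa_list)) paste(x$pKa_list, collapse = "/") else "-"))
  cat(sprintf("  B/P %.2f, fu %.3g | fa %.4g, ka %.3g 1/h, fu_gut %.3g\n",
              x$blood_plasma_ratio, x$fu_plasma, x$fa, x$ka, x$fu_gut))
  if (!is.null(x$clpo)) cat(sprintf("  CLpo %.4g L/h", x$clpo))
  cat(sprintf("  renal CL %.3g L/h\n", x$renal_cl))
  if (!is.null(x$cyp_clint)) {
    cat("  CLint:", paste(sprintf("%s %.4g", names(x$cyp_clint), x$cyp_clint),
                          collapse = ", "), "uL/min/pmol\n")
  }
  cat(sprintf("  victim-capable: %s; perpetrator-capable: %s\n",
              is_victim_capable(x), is_perpetrator_capable(x)))
  invisible(x)
}

#' Capability predicates for a compound record
#'
#' @param record A [compound_record()].
#' @return Logical scalar.
#' @export
is_victim_capable <- function(record) {
  !is.null(record$cyp_clint) || record$renal_cl > 0 ||
    !is.null(record$kidney_model) || !is.null(record$hepatic_uptake) ||
    !is.null(record$clpo)
}

#' @rdname is_victim_capable
#' @export
is_perpetrator_capable <- function(record) {
  length(record$interaction_set) > 0
}

#' Scale the metabolic intrinsic clearances of a library record
#'
#' Multiplies all metabolic CLint fields (per-enzyme and additional HLM) by a
#' common factor, leaving every other field untouched. Used, e.g., to apply a
#' 40% reduction in microsomal elimination to a library compound file
#' (factor 0.6: 2284 -> 1370.4 and 254 -> 152.4 uL/min).
#'
#' @param record A [compound_record()].
#' @param factor Scaling factor in (0, 1].
#' @return The scaled `compound_record`.
#' @export
scale_library_clearance <- function(record, factor) {
  stopifnot(inherits(record, "compound_record"))
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) ||
      factor <= 0 || factor > 1) {
    stop("'factor' must be a single value in (0, 1]")
  }
  if (!is.null(record$cyp_clint)) record$cyp_clint <- record$cyp_clint * factor
  if (!is.null(record$additional_hlm_clint)) {
    record$additional_hlm_clint <- record$additional_hlm_clint * factor
  }
  validate_compound_record(record)
}

#' Find an interaction parameter by target and mechanism
#'
#' @param record A [compound_record()].
#' @param target Target identifier.
#' @param mechanism Optional mechanism filter.
#' @return The matching `interaction_param` or `NULL`.
#' @keywords internal
get_interaction <- function(record, target, mechanism = NULL) {
  for (ip in record$interaction_set) {
    if (identical(ip$target, target) &&
        (is.null(mechanism) || identical(ip$mechanism, mechanism))) {
      return(ip)
    }
  }
  NULL
}
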