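#' Load the tissue-composition table
#'
#' Fractional tissue composition (water, neutral lipid, phospholipid,
#' acidic phospholipid, binding-protein ratio) used by the mechanistic
#' tissue:plasma partition prediction.
#'
#' @param path Optional path to an alternative YAML table.
#' @return A list with `ph`, `plasma`, `blood_cells` and a per-tissue
#'   data frame `tissues`.
#' @export
tissue_composition <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "physiology", "tissue_composition.yaml",
                        package = "pbpkddi")
  }
  y <- yaml::read_yaml(path)
  tis <- do.call(rbind, lapply(y$tissues, function(t) as.data.frame(t)))
  tis <- cbind(tissue = names(y$tissues), tis)
  rownames(tis) <- tis$tissue
  list(ph = y$ph, plasma = y$plasma, blood_cells = y$blood_cells, tissues = tis)
}

# Ionization factor X at a given pH: sum over ionized species relative to
# the neutral species, for the supported compound types.
ionization_X <- function(pKa, compound_type, pH) {
  if (length(pKa) == 0 || compound_type == "neutral") return(0)
  pKa <- sort(pKa, decreasing = TRUE)
  switch(compound_type,
    "monoprotic base" = 10^(pKa[1] - pH),
    "diprotic base" = 10^(pKa[1] - pH) + 10^(pKa[1] + pKa[2] - 2 * pH),
    "monoprotic acid" = 10^(pH - min(pKa)),
    "diprotic acid" = 10^(pH - min(pKa)) + 10^(2 * pH - min(pKa) - max(pKa)),
    stop(sprintf("unsupported compound type '%s'", compound_type))
  )
}

#' Predict tissue-to-plasma partition coefficients
#'
#' Mechanistic tissue-composition (Rodgers-Rowland-class) prediction of
#' per-tissue Kp from lipophilicity, ionization and binding. For ionizable
#' bases with measurable erythrocyte association (blood:plasma ratio above
#' the plasma fraction) the acidic-phospholipid association constant is
#' derived from blood-cell partitioning and drives the ionic term; for
#' neutrals, acids and bases without erythrocyte association, the
#' protein-binding route is used. The compound's `kp_scalar` is *not*
#' applied here; see [apply_kp_scalar()].
#'
#' @param compound A [compound_record()] with `logP`, `pKa_list`,
#'   `compound_type`, `fu_plasma` and `blood_plasma_ratio`.
#' @param composition Tissue-composition table from [tissue_composition()].
#' @param hct Haematocrit.
#' @return A named numeric vector of Kp values (class `kp_set`), with
#'   attributes `kpu` (unbound Kp), `kp_bc` (blood cell:plasma ratio) and
#'   `scalar_applied = FALSE`.
#' @export
predict_kp <- function(compound, composition = tissue_composition(), hct = 0.45) {
  for (nm in c("logP", "fu_plasma", "blood_plasma_ratio", "compound_type")) {
    if (is.null(compound[[nm]])) {
      stop(sprintf("predict_kp: compound '%s' is missing '%s'", compound$name, nm))
    }
  }
  P <- 10^compound$logP
  fu <- compound$fu_plasma
  bp <- compound$blood_plasma_ratio
  ph <- composition$ph
  tis <- composition$tissues
  bc <- composition$blood_cells
  pl <- composition$plasma
  type <- compound$compound_type
  pKa <- compound$pKa_list

  X_p <- ionization_X(pKa, type, ph$plasma)
  X_iw <- ionization_X(pKa, type, ph$intracellular)
  X_bc <- ionization_X(pKa, type, ph$blood_cells)

  lipid_term <- function(f_nl, f_npl) (P * f_nl + (0.3 * P + 0.7) * f_npl) / (1 + X_p)
  water_term <- function(f_ew, f_iw) f_ew + (1 + X_iw) / (1 + X_p) * f_iw

  kp_bc <- (bp - (1 - hct)) / hct
  kpu_bc <- kp_bc / fu

  is_base <- grepl("base", type) && length(pKa) > 0
  ka_ap <- 0
  if (is_base && X_bc > 0 && kpu_bc > 0) {
    resid <- kpu_bc - (1 + X_bc) / (1 + X_p) * bc$f_iw - lipid_term(bc$f_nl, bc$f_npl)
    ka_ap <- resid * (1 + X_p) / (bc$ap * X_bc)
  }

  kpu <- numeric(nrow(tis))
  names(kpu) <- tis$tissue
  if (is_base && ka_ap > 0) {
    for (i in seq_len(nrow(tis))) {
      t <- tis[i, ]
      kpu[i] <- water_term(t$f_ew, t$f_iw) +
        ka_ap * t$ap * X_iw / (1 + X_p) +
        lipid_term(t$f_nl, t$f_npl)
    }
  } else {
    # protein-binding route (neutrals, acids, bases without AP association)
    assoc <- max(0, 1 / fu - 1 - (P * pl$f_nl + (0.3 * P + 0.7) * pl$f_npl))
    for (i in seq_len(nrow(tis))) {
      t <- tis[i, ]
      kpu[i] <- water_term(t$f_ew, t$f_iw) +
        lipid_term(t$f_nl, t$f_npl) +
        assoc * t$protein_ratio
    }
  }
  kp <- kpu * fu
  structure(kp, kpu = kpu, kp_bc = kp_bc, scalar_applied = FALSE, class = "kp_set")
}

#' Apply a uniform scalar to a Kp set
#'
#' @param kps A `kp_set` from [predict_kp()] (or any named numeric vector).
#' @param scalar Positive scalar.
#' @return The scaled `kp_set`, flagged `scalar_applied = TRUE`.
#' @export
apply_kp_scalar <- function(kps, scalar) {
  if (!is.numeric(scalar) || length(scalar) != 1 || !is.finite(scalar) || scalar <= 0) {
    stop("'scalar' must be a single positive number")
  }
  out <- unclass(kps) * scalar
  attributes(out) <- attributes(kps)
  attr(out, "scalar_applied") <- TRUE
  out
}

#' Steady-state volume of distribution from a Kp set
#'
#' Plasma-referenced Vss per kg body weight:
#' `Vss = (V_plasma + V_bc * Kp_bc + sum(V_t * Kp_t)) / BW`, where the
#' erythrocyte term uses the blood-cell:plasma ratio implied by the
#' compound's blood:plasma ratio.
#'
#' @param kps Named Kp vector over the tissue set.
#' @param system A [physiology_system()].
#' @param compound A [compound_record()] (supplies the blood:plasma ratio).
#' @return Vss in L/kg.
#' @export
vss_from_kp <- function(kps, system, compound) {
  v <- system$volumes
  blood <- v[["arterial"]] + v[["venous"]] + v[["portal"]]
  v_plasma <- (1 - system$hct) * blood
  v_bc <- system$hct * blood
  kp_bc <- (compound$blood_plasma_ratio - (1 - system$hct)) / system$hct
  tn <- pbpk_tissues()
  if (!all(tn %in% names(kps))) stop("vss_from_kp: Kp set does not cover the tissue set")
  (v_plasma + v_bc * kp_bc + sum(v[tn] * kps[tn])) / system$body_weight
}

#' Solve the Kp scalar that reproduces an observed Vss
#'
#' Linearity of the Vss sum in the tissue Kps gives the scalar in closed
#' form. Used when a compound record carries `vss_target`: the
#' distribution-calibration step of model assembly.
#'
#' @param kps Unscaled Kp set.
#' @param system A [physiology_system()].
#' @param compound A [compound_record()].
#' @param vss_target Observed Vss, L/kg.
#' @return The scalar (> 0).
#' @export
calibrate_kp_scalar <- function(kps, system, compound, vss_target) {
  v <- system$volumes
  blood <- v[["arterial"]] + v[["venous"]] + v[["portal"]]
  v_plasma <- (1 - system$hct) * blood
  v_bc <- system$hct * blood
  kp_bc <- (compound$blood_plasma_ratio - (1 - system$hct)) / system$hct
  tn <- pbpk_tissues()
  s <- (vss_target * system$body_weight - v_plasma - v_bc * kp_bc) /
    sum(v[tn] * kps[tn])
  if (!is.finite(s) || s <= 0) {
    stop(sprintf("calibrate_kp_scalar: Vss target %.3g L/kg is unreachable", vss_target))
  }
  s
}
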