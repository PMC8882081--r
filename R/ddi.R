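#' Site-concentration interpolants of a perpetrator simulation
#'
#' Builds functions of time returning unbound perpetrator concentrations
#' (uM) at the inhibition-relevant sites, and the CYP3A4 activity fraction
#' when the enzyme state is dynamic.
#'
#' @param profile A `pbpk_profile` of the perpetrator.
#' @return List of functions: `plasma_unbound`, `portal_unbound`,
#'   `kidney_unbound` (tissue total times fu, the tissue free fraction
#'   being taken equal to the plasma free fraction), `liver_unbound`,
#'   `liver_inlet_unbound`, and `e_cyp3a4`.
#' @export
perpetrator_sites <- function(profile) {
  model <- attr(profile, "model")
  cmp <- model$compound
  fu <- cmp$fu_plasma
  mw <- cmp$molecular_weight
  to_uM <- function(conc_mg_L) conc_mg_L / mw * 1000
  tt <- profile$time
  d <- derived_flows(model$system)
  q_ha <- model$system$flows[["hepatic_artery"]]
  inlet_plasma <- (q_ha * profile$arterial_plasma +
                   d[["q_portal"]] * profile$portal_plasma) / d[["q_liver"]]
  mk <- function(v) stats::approxfun(tt, v, rule = 2)
  kid_total <- if (!is.null(profile$kidney)) profile$kidney else profile$kidney_vasc
  out <- list(
    plasma_unbound = mk(to_uM(fu * profile$arterial_plasma)),
    portal_unbound = mk(to_uM(fu * profile$portal_plasma)),
    kidney_unbound = mk(to_uM(fu * kid_total)),
    liver_unbound = mk(to_uM(profile$liver_unbound_plasma)),
    liver_inlet_unbound = mk(to_uM(fu * inlet_plasma))
  )
  out$e_cyp3a4 <- if (!is.null(profile$e_cyp3a4)) mk(profile$e_cyp3a4) else NULL
  out
}

#' Build the inhibition wiring a perpetrator exerts on a victim
#'
#' Translates a perpetrator's simulated exposure and interaction constants
#' into the time-dependent competitive inhibition factors and enzyme
#' activity functions consumed by [simulate_pk()]. Inhibitor site
#' conventions: OCT2 is driven by unbound plasma at the basolateral face,
#' MATE by unbound intracellular kidney concentration, OATP1B1/1B3 by the
#' unbound liver-inlet (portal-weighted) concentration, and CYP enzymes by
#' unbound liver concentration. The OCT2/MATE site conventions can be
#' switched.
#'
#' @param perp_profile A `pbpk_profile` of the perpetrator.
#' @param ki_overrides Optional named numeric vector of absolute Ki values
#'   (uM) replacing the perpetrator record's values per target.
#' @param ki_fold Optional named numeric vector of fold-reductions applied
#'   to the record's Ki (e.g. `c(OCT2 = 10, MATE = 10)`).
#' @param site_oct2 `"plasma"` (default) or `"kidney"`.
#' @param site_mate `"kidney"` (default) or `"plasma"`.
#' @return An inhibition list with elements `factor`, `activity` and
#'   `ki_used` (the named Ki values after overrides).
#' @export
perpetrator_inhibition <- function(perp_profile, ki_overrides = NULL,
                                   ki_fold = NULL,
                                   site_oct2 = c("plasma", "kidney"),
                                   site_mate = c("kidney", "plasma")) {
  site_oct2 <- match.arg(site_oct2)
  site_mate <- match.arg(site_mate)
  model <- attr(perp_profile, "model")
  perp <- model$compound
  if (!is_perpetrator_capable(perp)) {
    stop("perpetrator_inhibition: compound has an empty interaction set")
  }
  sites <- perpetrator_sites(perp_profile)
  site_for <- function(target) {
    switch(target,
      OCT2 = if (site_oct2 == "plasma") sites$plasma_unbound else sites$kidney_unbound,
      MATE = if (site_mate == "kidney") sites$kidney_unbound else sites$plasma_unbound,
      OATP1B1 = sites$liver_inlet_unbound,
      OATP1B3 = sites$liver_inlet_unbound,
      sites$liver_unbound   # CYP enzymes and anything else: liver
    )
  }
  factor <- list()
  ki_used <- c()
  for (ip in perp$interaction_set) {
    if (ip$mechanism != "reversible") next
    ki <- ip$ki
    if (!is.null(ki_overrides) && ip$target %in% names(ki_overrides)) {
      ki <- ki_overrides[[ip$target]]
    }
    if (!is.null(ki_fold) && ip$target %in% names(ki_fold)) {
      ki <- ki / ki_fold[[ip$target]]
    }
    if (ki <= 0) stop("perpetrator_inhibition: overridden Ki must be positive")
    iu <- site_for(ip$target)
    local({
      ki_loc <- ki; iu_loc <- iu
      factor[[ip$target]] <<- function(t) 1 + iu_loc(t) / ki_loc
    })
    ki_used[ip$target] <- ki
  }
  activity <- list()
  if (!is.null(sites$e_cyp3a4)) activity$CYP3A4 <- sites$e_cyp3a4
  list(factor = factor, activity = activity, ki_used = ki_used)
}

#' Perpetrator exposure report
#'
#' Site concentrations relevant to DDI risk assessment: Cmax (with units as
#' printed in DDI practice) and time above a threshold for plasma (total
#' and unbound), portal vein, liver inlet and kidney tissue (unbound, the
#' tissue free fraction being assumed equal to the plasma free fraction).
#'
#' @param profile A `pbpk_profile` of the perpetrator.
#' @param thresholds Optional named numeric vector (uM) of thresholds; for
#'   each, the time the matching site concentration exceeds it is reported.
#'   Names must be among `plasma_total`, `plasma_unbound`, `portal_total`,
#'   `kidney_unbound`.
#' @return List with `cmax` (named: `plasma_total_nM`, `plasma_unbound_nM`,
#'   `portal_total_uM`, `kidney_unbound_nM`, `liver_inlet_unbound_uM`) and
#'   `time_above` (named, h).
#' @export
perpetrator_exposure_report <- function(profile, thresholds = NULL) {
  model <- attr(profile, "model")
  cmp <- model$compound
  fu <- cmp$fu_plasma
  mw <- cmp$molecular_weight
  to_uM <- function(x) x / mw * 1000
  kid_total <- if (!is.null(profile$kidney)) profile$kidney else profile$kidney_vasc
  series <- list(
    plasma_total = to_uM(profile$plasma),
    plasma_unbound = to_uM(fu * profile$plasma),
    portal_total = to_uM(profile$portal_plasma),
    kidney_unbound = to_uM(fu * kid_total)
  )
  cmax <- c(
    plasma_total_nM = 1000 * max(series$plasma_total),
    plasma_unbound_nM = 1000 * max(series$plasma_unbound),
    portal_total_uM = max(series$portal_total),
    kidney_unbound_nM = 1000 * max(series$kidney_unbound),
    liver_inlet_unbound_uM = max(perpetrator_sites(profile)$liver_inlet_unbound(profile$time))
  )
  time_above <- c()
  if (!is.null(thresholds)) {
    dt <- diff(profile$time)
    for (nm in names(thresholds)) {
      s <- series[[nm]]
      if (is.null(s)) stop(sprintf("perpetrator_exposure_report: unknown site '%s'", nm))
      above <- (utils::head(s, -1) > thresholds[[nm]]) &
               (utils::tail(s, -1) > thresholds[[nm]])
      time_above[nm] <- sum(dt[above])
    }
  }
  list(cmax = cmax, time_above = time_above)
}
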