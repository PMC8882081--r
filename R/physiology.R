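#' Reference-human physiology system
#'
#' Tissue volumes and regional blood flows for the standard
#' perfusion-limited tissue set, plus hepatic enzyme-scaling constants,
#' glomerular filtration rate and enzyme turnover, for a 70-kg reference
#' adult. Values are read from the annotated YAML fixture shipped with the
#' package (`inst/extdata/physiology/reference_human.yaml`), each with its
#' literature source.
#'
#' The liver receives the hepatic artery plus the portal vein, and the
#' portal vein drains gut and spleen; cardiac output is the sum of all
#' tissue flows (lung flow equals cardiac output). These consistency
#' conditions are validated on construction.
#'
#' @param path Optional path to an alternative physiology YAML file.
#' @return An object of class `physiology_system` with elements
#'   `volumes` (L), `flows` (L/h blood), `hct`, `gfr` (L/h),
#'   `body_weight` (kg), `cyp3a4_abundance` (pmol/mg), `mppgl` (mg/g),
#'   `liver_weight` (g), `kdeg_cyp3a4` (1/h), `q_gut` (L/h).
#' @examples
#' sys <- physiology_system()
#' sys$gfr
#' @export
physiology_system <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "physiology", "reference_human.yaml",
                        package = "pbpkddi")
  }
  y <- yaml::read_yaml(path)
  sys <- structure(list(
    volumes = unlist(y$volumes),
    flows = unlist(y$flows),
    hct = y$hct,
    gfr = y$gfr,
    body_weight = y$body_weight,
    cyp3a4_abundance = y$cyp3a4_abundance,
    mppgl = y$mppgl,
    liver_weight = y$liver_weight,
    kdeg_cyp3a4 = y$kdeg_cyp3a4,
    q_gut = y$q_gut
  ), class = "physiology_system")
  validate_physiology_system(sys)
}

pbpk_tissues <- function() {
  c("adipose", "bone", "brain", "gut", "heart", "kidney", "liver",
    "lung", "muscle", "skin", "spleen")
}

#' @rdname physiology_system
#' @param x A `physiology_system`.
#' @export
validate_physiology_system <- function(x) {
  need_v <- c(pbpk_tissues(), "arterial", "venous", "portal")
  need_q <- c(setdiff(pbpk_tissues(), c("liver", "lung")), "hepatic_artery")
  if (!all(need_v %in% names(x$volumes))) {
    stop("physiology_system: missing volume(s): ",
         paste(setdiff(need_v, names(x$volumes)), collapse = ", "))
  }
  if (!all(need_q %in% names(x$flows))) {
    stop("physiology_system: missing flow(s): ",
         paste(setdiff(need_q, names(x$flows)), collapse = ", "))
  }
  if (any(x$volumes <= 0) || any(x$flows <= 0)) {
    stop("physiology_system: volumes and flows must be positive")
  }
  for (nm in c("hct", "gfr", "body_weight", "cyp3a4_abundance", "mppgl",
               "liver_weight", "kdeg_cyp3a4", "q_gut")) {
    if (is.null(x[[nm]]) || !is.finite(x[[nm]]) || x[[nm]] <= 0) {
      stop(sprintf("physiology_system: '%s' must be positive", nm))
    }
  }
  x
}

#' Derived flows of a physiology system
#'
#' Portal-vein flow (gut + spleen), total liver inflow (portal + hepatic
#' artery) and cardiac output (sum of tissue flows).
#'
#' @param sys A [physiology_system()].
#' @return Named numeric vector with `q_portal`, `q_liver`, `co`, all L/h.
#' @export
derived_flows <- function(sys) {
  q <- sys$flows
  q_portal <- q[["gut"]] + q[["spleen"]]
  q_liver <- q_portal + q[["hepatic_artery"]]
  co <- sum(q[setdiff(names(q), "hepatic_artery")]) + q[["hepatic_artery"]]
  c(q_portal = q_portal, q_liver = q_liver, co = co)
}

#' @export
print.physiology_system <- function(x, ...) {
  d <- derived_flows(x)
  cat("<physiology_system> 70-kg-class reference human\n")
  cat(sprintf("  body weight %.0f kg, Hct %.2f, GFR %.2f L/h\n",
              x$body_weight, x$hct, x$gfr))
  cat(sprintf("  cardiac output %.0f L/h; liver inflow %.0f L/h (portal %.0f + artery %.0f)\n",
              d[["co"]], d[["q_liver"]], d[["q_portal"]], x$flows[["hepatic_artery"]]))
  cat(sprintf("  CYP3A4 %.0f pmol/mg, MPPGL %.0f mg/g, liver %.0f g, kdeg %.3g 1/h\n",
              x$cyp3a4_abundance, x$mppgl, x$liver_weight, x$kdeg_cyp3a4))
  invisible(x)
}
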