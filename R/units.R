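#' Convert a mass concentration to a molar concentration
#'
#' Converts ng/mL to nM given a molecular weight. For dasatinib
#' (MW 488.01 g/mol) a plasma Cmax of 80 ng/mL corresponds to about 164 nM.
#'
#' @param conc_ng_ml Concentration in ng/mL (>= 0).
#' @param mw Molecular weight in g/mol (> 0).
#' @return Concentration in nM.
#' @seealso [molar_to_mass()], [unbound_conc()]
#' @examples
#' mass_to_molar(80, 488.01) # ~164 nM
#' @export
mass_to_molar <- function(conc_ng_ml, mw) {
  stopifnot(is.numeric(conc_ng_ml), is.numeric(mw))
  if (any(conc_ng_ml < 0)) stop("'conc_ng_ml' must be >= 0")
  if (any(mw <= 0)) stop("'mw' must be > 0")
  1000 * conc_ng_ml / mw
}

#' Convert a molar concentration to a mass concentration
#'
#' Exact inverse of [mass_to_molar()].
#'
#' @param conc_nM Concentration in nM (>= 0).
#' @param mw Molecular weight in g/mol (> 0).
#' @return Concentration in ng/mL.
#' @export
molar_to_mass <- function(conc_nM, mw) {
  stopifnot(is.numeric(conc_nM), is.numeric(mw))
  if (any(conc_nM < 0)) stop("'conc_nM' must be >= 0")
  if (any(mw <= 0)) stop("'mw' must be > 0")
  conc_nM * mw / 1000
}

#' Unbound concentration from total concentration
#'
#' @param total Total concentration (any unit).
#' @param fu Fraction unbound in (0, 1].
#' @return Unbound concentration in the same unit as `total`.
#' @examples
#' unbound_conc(164, 0.04) # ~6.6 nM
#' @export
unbound_conc <- function(total, fu) {
  stopifnot(is.numeric(total), is.numeric(fu))
  if (any(fu <= 0) || any(fu > 1)) stop("'fu' must be in (0, 1]")
  total * fu
}

#' Convert an IC50 to an inhibition constant Ki
#'
#' Competitive-inhibition conversion Ki = IC50 / (S/Km + 1). Enzyme assays
#' are typically run at S = Km so Ki = IC50/2; transporter assays at
#' S << Km so Ki = IC50. `assay_kind` selects these shortcuts; the general
#' form is used when `assay_kind = "general"`.
#'
#' @param ic50 IC50 in uM (> 0).
#' @param substrate_conc Substrate concentration S in uM (>= 0), used for
#'   `assay_kind = "general"`.
#' @param km Michaelis constant Km in uM (> 0), used for
#'   `assay_kind = "general"`.
#' @param assay_kind One of `"general"`, `"enzyme"` (Ki = IC50/2) or
#'   `"transporter"` (Ki = IC50).
#' @return Ki in uM.
#' @examples
#' ki_from_ic50(9.18, assay_kind = "transporter") # 9.18
#' ki_from_ic50(10, assay_kind = "enzyme")        # 5
#' ki_from_ic50(9, substrate_conc = 10, km = 5)   # 3
#' @export
ki_from_ic50 <- function(ic50, substrate_conc = 0, km = 1,
                         assay_kind = c("general", "enzyme", "transporter")) {
  assay_kind <- match.arg(assay_kind)
  if (!is.numeric(ic50) || any(ic50 <= 0)) stop("'ic50' must be > 0")
  switch(assay_kind,
    enzyme = ic50 / 2,
    transporter = ic50,
    general = {
      if (!is.numeric(km) || any(km <= 0)) stop("'km' must be > 0")
      if (!is.numeric(substrate_conc) || any(substrate_conc < 0)) {
        stop("'substrate_conc' must be >= 0")
      }
      ic50 / (substrate_conc / km + 1)
    }
  )
}
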