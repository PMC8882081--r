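#' Dosing regimen
#'
#' @param dose Dose per administration, mg (> 0; 0 allowed for a
#'   placebo/no-dose regimen).
#' @param n_doses Number of doses.
#' @param interval Dosing interval, h.
#' @param start Time of first dose, h.
#' @param route `"oral"` (into the absorption depot, scaled by fa) or
#'   `"iv"` (bolus into venous blood).
#' @return Object of class `dosing_regimen`: data frame with `time`,
#'   `amount`, `route`.
#' @examples
#' dosing_regimen(100, n_doses = 5, interval = 24) # 100 mg QD x 5
#' @export
dosing_regimen <- function(dose, n_doses = 1, interval = 24, start = 0,
                           route = c("oral", "iv")) {
  route <- match.arg(route)
  if (!is.numeric(dose) || any(dose < 0)) stop("dosing_regimen: negative dose")
  stopifnot(n_doses >= 1, interval > 0)
  out <- data.frame(
    time = start + (seq_len(n_doses) - 1) * interval,
    amount = rep_len(dose, n_doses),
    route = route,
    stringsAsFactors = FALSE
  )
  class(out) <- c("dosing_regimen", "data.frame")
  out
}

#' @export
print.dosing_regimen <- function(x, ...) {
  cat(sprintf("<dosing_regimen> %d x %.4g mg %s, t = %s h\n",
              nrow(x), x$amount[1], x$route[1],
              paste(utils::head(x$time, 6), collapse = ", ")))
  invisible(x)
}
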