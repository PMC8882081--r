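#' Noncompartmental PK metrics
#'
#' Standard NCA on a concentration-time profile: Cmax/Tmax, AUC by the
#' linear-up/log-down trapezoid, terminal half-life from the best-fit
#' log-linear tail (>= 3 points after Tmax, adjusted-R^2 criterion), and
#' AUC extrapolated to infinity.
#'
#' @param time Sampling times, h (strictly increasing).
#' @param conc Concentrations (same length as `time`, >= 3 positive values
#'   required).
#' @return Object of class `pk_nca`: list with `cmax`, `tmax`, `auc_0_t`,
#'   `auc_inf`, `t_half` (NA when no terminal phase can be identified),
#'   `lambda_z`, `n_tail`.
#' @examples
#' t <- 0:24
#' m <- pk_metrics(t, 10 * exp(-0.2 * t))
#' m$t_half # ~3.47 h
#' @export
pk_metrics <- function(time, conc) {
  if (length(time) != length(conc)) stop("pk_metrics: time/conc length mismatch")
  if (is.unsorted(time, strictly = TRUE)) stop("pk_metrics: time must be strictly increasing")
  keep <- is.finite(conc) & conc >= 0
  time <- time[keep]; conc <- conc[keep]
  if (sum(conc > 0) < 3) stop("pk_metrics: need at least 3 positive observations")

  imax <- which.max(conc)
  cmax <- conc[imax]; tmax <- time[imax]

  # linear-up / log-down trapezoid
  auc <- 0
  for (i in seq_len(length(time) - 1)) {
    dt <- time[i + 1] - time[i]
    c1 <- conc[i]; c2 <- conc[i + 1]
    auc <- auc + if (c2 < c1 && c2 > 0 && c1 > 0) {
      dt * (c1 - c2) / log(c1 / c2)
    } else {
      dt * (c1 + c2) / 2
    }
  }

  # terminal log-linear fit: best adjusted R^2 over tails of >= 3 points
  # strictly after Tmax
  tail_idx <- which(time > tmax & conc > 0)
  lambda_z <- NA_real_; t_half <- NA_real_; n_tail <- 0L; best <- -Inf
  if (length(tail_idx) >= 3) {
    for (start in seq_len(length(tail_idx) - 2)) {
      ii <- tail_idx[start:length(tail_idx)]
      x <- time[ii]; z <- log(conc[ii])
      fit <- stats::lm(z ~ x)
      sl <- unname(stats::coef(fit)[2])
      if (!is.finite(sl) || sl >= 0) next
      r2 <- suppressWarnings(summary(fit)$adj.r.squared)
      if (r2 > best + 1e-10) {
        best <- r2; lambda_z <- -sl; n_tail <- length(ii)
      }
    }
    if (is.finite(lambda_z)) t_half <- log(2) / lambda_z
  }

  clast <- conc[max(which(conc > 0))]
  auc_inf <- if (is.finite(lambda_z)) auc + clast / lambda_z else NA_real_

  structure(list(cmax = cmax, tmax = tmax, auc_0_t = auc, auc_inf = auc_inf,
                 t_half = t_half, lambda_z = lambda_z, n_tail = n_tail),
            class = "pk_nca")
}

#' @export
print.pk_nca <- function(x, ...) {
  cat(sprintf("<pk_nca> Cmax %.4g at %.2f h; AUC0-t %.4g; AUCinf %s; t1/2 %s h\n",
              x$cmax, x$tmax, x$auc_0_t,
              if (is.na(x$auc_inf)) "NA" else sprintf("%.4g", x$auc_inf),
              if (is.na(x$t_half)) "NA" else sprintf("%.3g", x$t_half)))
  invisible(x)
}
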