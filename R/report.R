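#' Run a DDI scenario from a configuration file
#'
#' Executes one victim-perpetrator scenario described by a YAML config and
#' writes a reproducible artifact bundle: the DDI result table (TSV), a
#' reference-subject victim profile (CSV) and a manifest (JSON) recording
#' the package version, seed and a hash of the configuration. Validation
#' failures are collected and reported together before aborting.
#'
#' Config keys: `label`, `victim` (shipped compound name or path to a
#' compound YAML, resolved relative to the config file), `perpetrator`
#' (optional), `victim_dose` (mg), `perp_dose`/`perp_n_doses`/
#' `perp_interval`, `co_dose_time`, `window`, `n_subjects`, `n_trials`,
#' `seed` (required, never defaulted), `ki_fold` / `ki_overrides` (maps
#' target -> fold factor / absolute uM), `site_oct2`, `site_mate`.
#'
#' @param config_path Path to the scenario YAML.
#' @param out_dir Output directory (created if needed).
#' @param system A [physiology_system()].
#' @return The [ddi_gmr()] result, invisibly, with the bundle paths in
#'   attribute `bundle`.
#' @export
run_scenario <- function(config_path, out_dir = tempfile("scenario"),
                         system = physiology_system()) {
  if (!file.exists(config_path)) stop("run_scenario: config not found: ", config_path)
  cfg <- yaml::read_yaml(config_path)
  problems <- character(0)
  if (is.null(cfg$seed)) problems <- c(problems, "missing required field 'seed'")
  if (is.null(cfg$victim)) problems <- c(problems, "missing required field 'victim'")
  if (is.null(cfg$victim_dose)) problems <- c(problems, "missing required field 'victim_dose'")
  resolve_compound <- function(spec, role) {
    if (grepl("\\.ya?ml$", spec)) {
      p <- if (file.exists(spec)) spec else file.path(dirname(config_path), spec)
      if (!file.exists(p)) {
        problems <<- c(problems, sprintf("%s compound file not found: %s", role, spec))
        return(NULL)
      }
      load_compound(p)
    } else {
      tryCatch(pbpk_example_compound(spec), error = function(e) {
        problems <<- c(problems, conditionMessage(e)); NULL
      })
    }
  }
  victim_rec <- if (!is.null(cfg$victim)) resolve_compound(cfg$victim, "victim") else NULL
  perp_rec <- if (!is.null(cfg$perpetrator)) resolve_compound(cfg$perpetrator, "perpetrator") else NULL
  known_targets <- if (!is.null(perp_rec)) {
    vapply(perp_rec$interaction_set, function(ip) ip$target, character(1))
  } else character(0)
  for (nm in names(cfg$ki_fold)) {
    if (!(nm %in% known_targets)) {
      problems <- c(problems, sprintf("ki_fold target '%s' is not in the perpetrator's interaction set", nm))
    }
  }
  for (nm in names(cfg$ki_overrides)) {
    if (!(nm %in% known_targets)) {
      problems <- c(problems, sprintf("ki_overrides target '%s' is not in the perpetrator's interaction set", nm))
    }
  }
  if (length(problems)) {
    stop("run_scenario: invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  }

  design <- trial_design(
    n_subjects = if (is.null(cfg$n_subjects)) 10 else cfg$n_subjects,
    n_trials = if (is.null(cfg$n_trials)) 10 else cfg$n_trials,
    seed = cfg$seed
  )
  victim <- pbpk_model(victim_rec, system = system)
  perp <- if (!is.null(perp_rec)) pbpk_model(perp_rec, system = system) else NULL
  if (is.null(perp)) {
    warning("run_scenario: no perpetrator configured; this is a plain PK simulation and GMRs are exactly 1")
  }
  perp_reg <- dosing_regimen(
    if (is.null(cfg$perp_dose)) 100 else cfg$perp_dose,
    n_doses = if (is.null(cfg$perp_n_doses)) 6 else cfg$perp_n_doses,
    interval = if (is.null(cfg$perp_interval)) 24 else cfg$perp_interval
  )
  res <- ddi_gmr(
    victim = victim, perpetrator = perp, design = design,
    victim_dose = cfg$victim_dose,
    perp_regimen = perp_reg,
    co_dose_time = if (is.null(cfg$co_dose_time)) 96 else cfg$co_dose_time,
    window = if (is.null(cfg$window)) 36 else cfg$window,
    ki_fold = unlist(cfg$ki_fold), ki_overrides = unlist(cfg$ki_overrides),
    site_oct2 = if (is.null(cfg$site_oct2)) "plasma" else cfg$site_oct2,
    site_mate = if (is.null(cfg$site_mate)) "kidney" else cfg$site_mate,
    scenario = if (is.null(cfg$label)) basename(config_path) else cfg$label
  )

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv_path <- file.path(out_dir, "ddi_result.tsv")
  tab <- cbind(scenario = res$scenario, victim = res$victim,
               perpetrator = res$perpetrator, res$summary)
  names(tab) <- c("scenario", "victim", "perpetrator", "metric",
                  "gmr", "ci90_lo", "ci90_hi", "n_subjects")
  utils::write.table(tab, tsv_path, sep = "\t", row.names = FALSE, quote = FALSE)
  subj_path <- file.path(out_dir, "subjects.tsv")
  utils::write.table(res$subjects, subj_path, sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(
    package = "pbpkddi",
    version = as.character(utils::packageVersion("pbpkddi")),
    seed = cfg$seed,
    config = basename(config_path),
    config_hash = config_hash(config_path),
    generated = "run_scenario"
  )
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE)
  attr(res, "bundle") <- c(ddi = tsv_path, subjects = subj_path, manifest = man_path)
  invisible(res)
}

# order-stable content hash of a config file (no digest dependency)
config_hash <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Forest-style table of DDI results
#'
#' One row per scenario and metric with the GMR and its confidence limits,
#' suitable for a forest plot.
#'
#' @param results A list of `ddi_result` objects (>= 1).
#' @param path Optional TSV output path.
#' @return Data frame with `scenario`, `victim`, `perpetrator`, `metric`,
#'   `gmr`, `ci90_lo`, `ci90_hi`. Degenerate CIs (single subject) are
#'   written as empty fields with a warning.
#' @export
forest_table <- function(results, path = NULL) {
  if (!length(results)) stop("forest_table: need at least one result")
  if (inherits(results, "ddi_result")) results <- list(results)
  rows <- do.call(rbind, lapply(results, function(r) {
    data.frame(scenario = r$scenario, victim = r$victim,
               perpetrator = r$perpetrator,
               metric = r$summary$metric, gmr = r$summary$gmr,
               ci90_lo = r$summary$ci_lo, ci90_hi = r$summary$ci_hi)
  }))
  if (anyNA(rows$ci90_lo)) {
    warning("forest_table: some confidence intervals are undefined (single subject); left empty")
  }
  if (!is.null(path)) {
    out <- rows
    out$ci90_lo <- ifelse(is.na(out$ci90_lo), "", sprintf("%.6g", out$ci90_lo))
    out$ci90_hi <- ifelse(is.na(out$ci90_hi), "", sprintf("%.6g", out$ci90_hi))
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  rows
}

#' Forest plot of DDI results
#'
#' @param results List of `ddi_result` objects.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_forest <- function(results, ...) {
  tab <- forest_table(results)
  n <- nrow(tab)
  ylim <- c(0.5, n + 0.5)
  xlim <- range(c(tab$gmr, tab$ci90_lo, tab$ci90_hi, 1), na.rm = TRUE)
  graphics::plot(tab$gmr, seq_len(n), xlim = xlim, ylim = ylim, pch = 19,
                 xlab = "GMR (90% CI)", ylab = "", yaxt = "n", ...)
  graphics::segments(tab$ci90_lo, seq_len(n), tab$ci90_hi, seq_len(n))
  graphics::abline(v = 1, lty = 2, col = "grey50")
  graphics::axis(2, at = seq_len(n),
                 labels = paste(tab$scenario, tab$metric), las = 1, cex.axis = 0.7)
  invisible(tab)
}
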